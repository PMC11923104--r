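test_that("scene generation is deterministic and classes are exact", {
  p <- sceneParams(imageSize = c(64, 64), tumorGlands = 2,
                   lymphClusters = 1, seed = 11)
  a <- generateTileScene(p)
  b <- generateTileScene(p)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)

  # absence of other classes -> pure stroma
  p0 <- sceneParams(imageSize = c(48, 48), tumorGlands = 0,
                    lymphClusters = 0, seed = 3)
  sc <- generateTileScene(p0)
  expect_true(all(sc$mask == classCodes()[["stroma"]]))

  # class pixel counts partition the canvas
  expect_equal(sum(table(a$mask)), 64 * 64)
  expect_true(all(a$mask %in% 0:2))

  # invalid size rejected
  expect_error(sceneParams(imageSize = c(0, 64)), "positive")
})

test_that("tumor mask equals the rasterized gland union (polygon oracle)", {
  p <- sceneParams(imageSize = c(96, 96), tumorGlands = 3,
                   lymphClusters = 0, seed = 7)
  sc <- generateTileScene(p)
  oracle <- matrix(FALSE, 96, 96)
  for (poly in sc$glands)
    oracle <- oracle | pipOracle(poly, 96, 96)
  expect_identical(unname(sc$mask == 1L), unname(oracle))
})

test_that("slides assemble from abutting scenes with a strict-interior ROI", {
  p <- sceneParams(imageSize = c(48, 48), seed = 5)
  # identity case: 1x1 grid equals the single scene
  single <- generateSlide(c(1, 1), p)
  sc <- generateTileScene(p)
  expect_identical(single$image, sc$image)
  expect_identical(single$mask, sc$mask)

  sl <- generateSlide(c(2, 2), p)
  expect_equal(dim(sl$image), c(96, 96, 3))
  expect_equal(dim(sl$mask), c(96, 96))
  # scene (1,1) block of the slide is the first scene
  expect_identical(sl$mask[1:48, 1:48], sc$mask)
  # ROI strictly inside the slide
  expect_true(all(sl$roi[, 1] > 0 & sl$roi[, 1] < 96))
  expect_true(all(sl$roi[, 2] > 0 & sl$roi[, 2] < 96))
  expect_error(generateSlide(c(0, 1), p), "sceneGrid")
})

test_that("ROI restricted to one scene reproduces that scene's fractions", {
  p <- sceneParams(imageSize = c(48, 48), seed = 9)
  sl <- generateSlide(c(2, 2), p)
  # ROI = exactly the top-left scene
  roi <- cbind(x = c(0, 48, 48, 0), y = c(0, 0, 48, 48))
  q <- quantifySlide(sl$mask, roi)
  sc <- generateTileScene(p)
  direct <- quantifySlide(sc$mask)
  expect_equal(sip(q), sip(direct))
  expect_equal(lip(q), lip(direct))
  expect_equal(tip(q), tip(direct))
})

test_that("cohort generation is deterministic with the stated censoring", {
  p <- cohortParams(nPatients = 200, seed = 21)
  a <- generateCohort(p)
  b <- generateCohort(p)
  expect_identical(a, b)
  expect_true(all(a$sip >= 0 & a$sip <= 1))
  expect_true(all(a$event %in% 0:1))

  # no censoring process -> every record is an event
  p2 <- cohortParams(nPatients = 100, seed = 4, censoringRate = 0,
                     adminCensorMonths = Inf)
  expect_true(all(generateCohort(p2)$event == 1))

  expect_error(cohortParams(hazardByGroup = c(int.high = -1, int.low = 1,
                                              lh.high = 1, lh.low = 1)),
               "> 0")
})

test_that("single-rate cohorts reproduce the exponential median", {
  lambda <- 0.04
  p <- cohortParams(nPatients = 3000, seed = 13, censoringRate = 0,
                    adminCensorMonths = Inf,
                    hazardByGroup = c(int.high = lambda, int.low = lambda,
                                      lh.high = lambda, lh.low = lambda))
  d <- generateCohort(p)
  s <- kmFit(d$os_months, d$event)
  expect_lt(abs(medianOS(s) - log(2) / lambda) / (log(2) / lambda), 0.1)
})

test_that("cohort Cox fit recovers a generating hazard ratio of 0.5", {
  p <- cohortParams(nPatients = 2000, seed = 31,
                    hazardByGroup = c(int.high = 0.025, int.low = 0.05,
                                      lh.high = 0.05, lh.low = 0.05))
  d <- generateCohort(p)
  d$g1 <- as.integer(d$sip_group_true == "SIP-intermediate" &
                       d$lip_group_true == "LIP-high")
  fit <- coxUnivariate(d, "g1")
  expect_lt(abs(fit$hr - 0.5), 0.1)
})
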