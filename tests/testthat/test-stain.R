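# Synthetic two-stain fixture: concentrations include near-pure pixels of
# each stain so the percentile angle extremes can reach the true vectors.
makeTwoStainImage <- function(n = 64, seed = 1) {
  h <- c(0.65, 0.70, 0.29); h <- h / sqrt(sum(h^2))
  e <- c(0.07, 0.99, 0.11); e <- e / sqrt(sum(e^2))
  set.seed(seed)
  N <- n * n
  kind <- sample(1:3, N, replace = TRUE, prob = c(0.3, 0.3, 0.4))
  Ch <- ifelse(kind == 1, runif(N, 0.4, 1.2),
               ifelse(kind == 2, runif(N, 0, 0.01), runif(N, 0.1, 0.8)))
  Ce <- ifelse(kind == 2, runif(N, 0.3, 0.9),
               ifelse(kind == 1, runif(N, 0, 0.01), runif(N, 0.1, 0.6)))
  od <- cbind(h, e) %*% rbind(Ch, Ce)
  list(image = array(t(10^(-od)), c(n, n, 3)), h = h, e = e)
}

angleDeg <- function(a, b) acos(min(1, sum(a * b))) * 180 / pi

test_that("stain vectors are recovered from a known two-stain image", {
  fx <- makeTwoStainImage(seed = 1)
  pr <- estimateStainProfile(fx$image, betaOD = 0.05)
  expect_lt(angleDeg(pr@stainMatrix[, 1], fx$h), 1)
  expect_lt(angleDeg(pr@stainMatrix[, 2], fx$e), 1)
  # unit norms by construction and validity
  expect_equal(unname(sqrt(colSums(pr@stainMatrix^2))), c(1, 1))
  expect_true(validObject(pr))
})

test_that("degenerate single-stain images collapse both extreme angles", {
  h <- c(0.65, 0.70, 0.29); h <- h / sqrt(sum(h^2))
  set.seed(2)
  C <- runif(32 * 32, 0.3, 1.2)
  img <- array(t(10^(-(h %o% C))), c(32, 32, 3))
  pr <- estimateStainProfile(img, betaOD = 0.05)
  expect_lt(angleDeg(pr@stainMatrix[, 1], h), 1)
  expect_lt(angleDeg(pr@stainMatrix[, 2], h), 1)
})

test_that("near-blank tiles raise an estimation error", {
  white <- array(1, c(16, 16, 3))
  expect_error(estimateStainProfile(white), "estimation error")
})

test_that("normalization is an identity for matching profiles", {
  sc <- generateTileScene(sceneParams(imageSize = c(64, 64), seed = 5))
  pr <- estimateStainProfile(sc$image)
  out <- normalizeTile(sc$image, pr, pr)
  expect_lte(max(abs(out - sc$image)) * 255, 1)
  # idempotence: re-normalizing an already-normalized tile to the same
  # reference changes nothing beyond one level
  ref <- stainProfile(cbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11)),
                      c(1.2, 0.9))
  out1 <- normalizeTile(sc$image, pr, ref)
  out2 <- normalizeTile(out1, ref, ref)
  expect_lte(max(abs(out2 - out1)) * 255, 1)
})

test_that("normalization round-trips between two known profiles", {
  fx <- makeTwoStainImage(seed = 3)
  A <- stainProfile(cbind(fx$h, fx$e), c(1.2, 0.9))
  B <- stainProfile(cbind(c(0.55, 0.75, 0.37), c(0.10, 0.95, 0.20)),
                    c(1.0, 1.1))
  ab <- normalizeTile(fx$image, A, B)
  aba <- normalizeTile(ab, B, A)
  expect_lte(max(abs(aba - round(fx$image * 255) / 255)) * 255, 2 + 1e-9)
  # shape preserved, deterministic
  expect_equal(dim(ab), dim(fx$image))
  expect_identical(ab, normalizeTile(fx$image, A, B))
})

test_that("stain profiles serialize to JSON and back", {
  p <- stainProfile(cbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11)),
                    c(1.5, 1.2))
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeStainProfile(p, f)
  q <- readStainProfile(f)
  expect_equal(p@stainMatrix, q@stainMatrix, tolerance = 1e-12)
  expect_equal(p@maxConcentrations, q@maxConcentrations)
})
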