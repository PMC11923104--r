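test_that("tile physical geometry follows pixel size", {
  ts <- tileSpec()
  expect_identical(physicalSideUm(ts), 99)
  expect_identical(tileMargin(ts), 92L)
  # invariant for other parameters
  ts2 <- tileSpec(inputPx = 512, outputPx = 256, micronsPerPx = 0.5)
  expect_identical(physicalSideUm(ts2), 256)
  expect_error(tileSpec(inputPx = 100, outputPx = 101), "smaller")
  expect_error(tileSpec(inputPx = 101, outputPx = 100), "even")
})

test_that("plan covers simple rectangular ROIs with stride arithmetic", {
  ts <- tileSpec()
  roi1 <- cbind(x = c(0, 212, 212, 0), y = c(0, 0, 212, 212))
  expect_equal(nrow(planTiles(roi1, ts, c(212, 212))), 1L)
  roi2 <- cbind(x = c(0, 424, 424, 0), y = c(0, 0, 212, 212))
  pl <- planTiles(roi2, ts, c(212, 424))
  expect_equal(nrow(pl), 2L)
  expect_setequal(pl$x0, c(0, 212))
  # empty ROI -> empty plan
  expect_equal(nrow(planTiles(cbind(x = c(-5, -1, -1), y = c(-5, -1, -5)),
                              ts, c(100, 100))), 0L)
})

test_that("output windows partition arbitrary blob ROIs exactly", {
  ts <- tileSpec(inputPx = 32, outputPx = 16)
  set.seed(42)
  for (rep in 1:5) {
    th <- seq(0, 2 * pi, length.out = 13)[-13]
    r <- runif(12, 8, 30)
    poly <- cbind(x = 40 + r * cos(th), y = 38 + r * sin(th))
    slideDim <- c(80, 80)
    pl <- planTiles(poly, ts, slideDim)
    roi <- pipOracle(poly, slideDim[2], slideDim[1])
    cover <- matrix(0L, slideDim[1], slideDim[2])
    for (i in seq_len(nrow(pl))) {
      r1 <- pl$y0[i] + 1; r2 <- min(pl$y0[i] + 16, slideDim[1])
      c1 <- pl$x0[i] + 1; c2 <- min(pl$x0[i] + 16, slideDim[2])
      cover[r1:r2, c1:c2] <- cover[r1:r2, c1:c2] + 1L
    }
    expect_true(all(cover <= 1L))          # pairwise disjoint
    expect_true(all(cover[roi] == 1L))     # every ROI pixel covered
  }
})

test_that("input windows mirror-reflect at slide borders", {
  set.seed(1)
  img <- array(runif(60 * 70 * 3), c(60, 70, 3))
  ts <- tileSpec(inputPx = 32, outputPx = 16)
  # interior window equals a direct crop
  w <- extractInputWindow(img, list(x0 = 24, y0 = 24), ts)
  expect_identical(w, img[17:48, 17:48, ])
  # determinism
  expect_identical(w, extractInputWindow(img, list(x0 = 24, y0 = 24), ts))
  # full window at the slide corner against an explicit reflection oracle
  w0 <- extractInputWindow(img, list(x0 = 0, y0 = 0), ts)
  m <- tileMargin(ts)
  refl <- function(pos, n) { # 0-based to 1-based mirrored index
    if (pos < 0) -pos else if (pos > n - 1) 2 * n - 1 - pos else pos + 1
  }
  oracle <- array(0, c(32, 32, 3))
  for (rr in 1:32) for (cc in 1:32)
    oracle[rr, cc, ] <- img[refl(rr - 1 - m, 60), refl(cc - 1 - m, 70), ]
  expect_identical(w0, oracle)

  # default-geometry margin: 92 px mirror of the first 92 columns
  big <- array(runif(400 * 400 * 3), c(400, 400, 3))
  wd <- extractInputWindow(big, list(x0 = 0, y0 = 100), tileSpec())
  expect_identical(wd[, 92:1, ], wd[, 93:184, ])
})

test_that("stitching reassembles tiles and flags missing coverage", {
  ts <- tileSpec(inputPx = 32, outputPx = 16)
  roi <- cbind(x = c(0, 32, 32, 0), y = c(0, 0, 16, 16))
  m1 <- matrix(1L, 16, 16); m0 <- matrix(0L, 16, 16)
  st <- stitchTiles(list(m1, m0), data.frame(x0 = c(0, 16), y0 = 0),
                    roi, ts, c(16, 32))
  expect_true(all(st[, 1:16] == 1L))
  expect_true(all(st[, 17:32] == 0L))
  expect_error(
    stitchTiles(list(m1), data.frame(x0 = 0, y0 = 0), roi, ts, c(16, 32)),
    "incomplete coverage")
})

test_that("extract-crop-stitch round trip reproduces ground truth exactly", {
  ts <- tileSpec(inputPx = 32, outputPx = 16)
  sl <- generateSlide(c(2, 2), sceneParams(imageSize = c(40, 40), seed = 3),
                      roiMargin = 0.1)
  coords <- planTiles(sl$roi, ts, dim(sl$mask))
  masks <- lapply(seq_len(nrow(coords)), function(i)
    cropToOutput(extractInputWindow(sl$mask, coords[i, ], ts), ts))
  st <- stitchTiles(masks, coords, sl$roi, ts, dim(sl$mask))
  roi <- rasterizePolygon(sl$roi, ncol(sl$mask), nrow(sl$mask))
  expect_identical(st[roi], sl$mask[roi])
  expect_true(all(st[!roi] == classCodes()[["ignore"]]))
})

test_that("polygon rasterization matches the per-pixel oracle", {
  set.seed(7)
  for (rep in 1:4) {
    th <- seq(0, 2 * pi, length.out = 9)[-9]
    r <- runif(8, 3, 14)
    poly <- cbind(x = 15 + r * cos(th), y = 16 + r * sin(th))
    expect_identical(rasterizePolygon(poly, 32, 32), pipOracle(poly, 32, 32))
  }
})
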