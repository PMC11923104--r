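## Synthetic H&E-like scenes with exact ground-truth ternary masks.
## Appearance is procedural (parametric colors + noise): tumor glands are
## ring-shaped structures with a pale lumen, lymphocytes are clusters of
## small dark basophilic discs, stroma is a pink fibrous background.
## Ground truth is exact because the mask is painted by the same geometry
## that paints the image.

# Pixel-center convention used everywhere in the package: pixel (row r,
# col c), 1-based, has continuous coordinates (x, y) = (c - 0.5, r - 0.5);
# the image spans [0, W] x [0, H].

#' Rasterize a polygon with even-odd fill at pixel centers
#'
#' A pixel belongs to the polygon when its center lies inside under the
#' even-odd rule.  Scanline implementation; deterministic.
#'
#' @param poly numeric matrix with columns \code{x}, \code{y} (pixel
#'   coordinates, see Details in \code{\link{generateTileScene}}).
#' @param width,height raster dimensions in pixels.
#' @return Logical \code{height x width} matrix.
#' @examples
#' sq <- cbind(x = c(1, 5, 5, 1), y = c(1, 1, 5, 5))
#' sum(rasterizePolygon(sq, 8, 8))   # 16 pixel centers inside
#' @export
rasterizePolygon <- function(poly, width, height) {
  poly <- as.matrix(poly)
  out <- matrix(FALSE, nrow = height, ncol = width)
  if (nrow(poly) < 3L) return(out)
  px <- poly[, 1]; py <- poly[, 2]
  nx <- c(px[-1], px[1]); ny <- c(py[-1], py[1])
  for (r in seq_len(height)) {
    y <- r - 0.5
    crosses <- (py <= y) != (ny <= y)
    if (!any(crosses)) next
    xc <- px[crosses] + (y - py[crosses]) *
      (nx[crosses] - px[crosses]) / (ny[crosses] - py[crosses])
    xc <- sort(xc)
    for (k in seq(1L, length(xc) - 1L, by = 2L)) {
      # pixel centers c - 0.5 in (xc[k], xc[k+1])
      c1 <- max(1L, floor(xc[k] + 0.5) + 1L)
      c2 <- min(width, ceiling(xc[k + 1L] + 0.5) - 1L)
      if (c1 <= c2) out[r, c1:c2] <- TRUE
    }
  }
  out
}

# Perturbed-circle polygon (gland outline).
glandPolygon <- function(cx, cy, r, nVert = 28L) {
  th <- seq(0, 2 * pi, length.out = nVert + 1L)[-(nVert + 1L)]
  a1 <- runif(1, 0.05, 0.22); p1 <- runif(1, 0, 2 * pi)
  a2 <- runif(1, 0.03, 0.12); p2 <- runif(1, 0, 2 * pi)
  rr <- r * (1 + a1 * sin(2 * th + p1) + a2 * sin(3 * th + p2))
  cbind(x = cx + rr * cos(th), y = cy + rr * sin(th))
}

scalePolygon <- function(poly, factor) {
  cx <- mean(poly[, 1]); cy <- mean(poly[, 2])
  cbind(x = cx + (poly[, 1] - cx) * factor,
        y = cy + (poly[, 2] - cy) * factor)
}

# Logical disc mask at pixel centers.
discMask <- function(cx, cy, rad, width, height) {
  r1 <- max(1L, floor(cy - rad)); r2 <- min(height, ceiling(cy + rad) + 1L)
  c1 <- max(1L, floor(cx - rad)); c2 <- min(width, ceiling(cx + rad) + 1L)
  out <- matrix(FALSE, height, width)
  if (r1 > r2 || c1 > c2) return(out)
  rows <- r1:r2; cols <- c1:c2
  dy2 <- (rows - 0.5 - cy)^2
  dx2 <- (cols - 0.5 - cx)^2
  out[rows, cols] <- outer(dy2, dx2, "+") <= rad^2
  out
}

# H&E-ish palette (RGB in [0, 1]).
.heColors <- list(
  stromaLight = c(0.93, 0.78, 0.86),
  stromaDeep  = c(0.84, 0.52, 0.68),
  tumorRim    = c(0.55, 0.34, 0.62),
  tumorLumen  = c(0.95, 0.91, 0.97),
  lymphocyte  = c(0.24, 0.16, 0.50)
)

paintRegion <- function(img, region, color) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[region] <- color[ch]
    img[, , ch] <- plane
  }
  img
}

#' Generate a synthetic H&E-like tile scene with ground truth
#'
#' Paints a pink fibrous stroma background, \code{tumorGlands} gland-like
#' tumor structures (dark rim, pale lumen; the whole gland counts as
#' tumor), and \code{lymphClusters} clusters of small dark lymphocyte
#' discs (drawn last, so they override tumor where they overlap).  The
#' ternary mask is painted by exactly the same geometry, so class pixel
#' counts equal the painted geometry.  Identical parameters (including
#' seed) give bit-identical output; the caller's RNG state is untouched.
#'
#' @param params a \code{\link{sceneParams}} object.
#' @return List with \code{image} (numeric \code{H x W x 3} array in
#'   \[0, 1\], quantized to the 8-bit grid), \code{mask} (integer matrix,
#'   encoding of \code{\link{classCodes}} without the ignore sentinel),
#'   \code{glands} (list of gland outline polygons) and \code{lymphocytes}
#'   (data.frame of disc centers/radii), the latter two for geometric
#'   verification.
#' @examples
#' sc <- generateTileScene(sceneParams(imageSize = c(64, 64), seed = 2))
#' table(sc$mask)
#' @export
generateTileScene <- function(params) {
  stopifnot(is(params, "SceneParams"))
  validObject(params)
  H <- params@imageSize[1]; W <- params@imageSize[2]
  withSeed(params@seed, {
    ## stroma texture: superposed oriented waves, contrast set by density
    xs <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
    ys <- matrix(rep(seq_len(H) - 0.5, times = W), H, W)
    tex <- matrix(0, H, W)
    for (k in 1:3) {
      th <- runif(1, 0, pi); lam <- runif(1, 6, 18); ph <- runif(1, 0, 2 * pi)
      tex <- tex + sin(2 * pi * (cos(th) * xs + sin(th) * ys) / lam + ph)
    }
    tex <- (tex / 3 + 1) / 2                    # -> [0, 1]
    t <- tex * params@stromaFiberDensity
    img <- array(0, c(H, W, 3))
    for (ch in 1:3)
      img[, , ch] <- .heColors$stromaLight[ch] +
        (.heColors$stromaDeep[ch] - .heColors$stromaLight[ch]) * t
    mask <- matrix(classCodes()[["stroma"]], H, W)

    ## tumor glands
    glands <- list()
    if (params@tumorGlands > 0L) {
      for (g in seq_len(params@tumorGlands)) {
        cx <- runif(1, 0.12, 0.88) * W
        cy <- runif(1, 0.12, 0.88) * H
        r <- runif(1, 0.07, 0.14) * min(H, W)
        poly <- glandPolygon(cx, cy, r)
        glands[[g]] <- poly
        region <- rasterizePolygon(poly, W, H)
        lumen <- rasterizePolygon(scalePolygon(poly, 0.55), W, H) & region
        img <- paintRegion(img, region & !lumen, .heColors$tumorRim)
        img <- paintRegion(img, lumen, .heColors$tumorLumen)
        mask[region] <- classCodes()[["tumor"]]
      }
    }

    ## lymphocyte clusters (override tumor)
    cells <- data.frame(x = numeric(), y = numeric(), r = numeric())
    if (params@lymphClusters > 0L) {
      for (cl in seq_len(params@lymphClusters)) {
        ccx <- runif(1, 0.10, 0.90) * W
        ccy <- runif(1, 0.10, 0.90) * H
        nCell <- 8L + rpois(1, 10)
        off <- 0.035 * min(H, W)
        for (j in seq_len(nCell)) {
          cx <- ccx + rnorm(1, 0, off); cy <- ccy + rnorm(1, 0, off)
          rad <- runif(1, 1.8, 3.4)
          cells <- rbind(cells, data.frame(x = cx, y = cy, r = rad))
          d <- discMask(cx, cy, rad, W, H)
          img <- paintRegion(img, d, .heColors$lymphocyte)
          mask[d] <- classCodes()[["lymphocyte"]]
        }
      }
    }

    ## pixel noise + multiplicative stain jitter, then 8-bit quantization
    img <- img + array(rnorm(H * W * 3, 0, 0.015), c(H, W, 3))
    if (params@stainJitter > 0) {
      jit <- exp(rnorm(3, 0, params@stainJitter))
      for (ch in 1:3) img[, , ch] <- img[, , ch] * jit[ch]
    }
    img <- round(pmin(pmax(img, 0), 1) * 255) / 255
    list(image = img, mask = mask, glands = glands, lymphocytes = cells)
  })
}

#' Assemble a synthetic slide from a grid of scenes
#'
#' Scenes are generated with seeds derived deterministically from
#' \code{params@seed} and abutted into a \code{sceneGrid[1] x
#' sceneGrid[2]} slide.  A rectangular region of interest strictly inside
#' the slide stands in for the pathologist's ROI outline.
#'
#' @param sceneGrid integer pair: rows and columns of scenes.
#' @param params a \code{\link{sceneParams}} object describing each scene.
#' @param roiMargin fraction of the smaller slide side kept outside the
#'   ROI on every edge (0 gives a 1-pixel inset so the polygon stays
#'   strictly inside the slide).
#' @return List with \code{image} (slide RGB array), \code{mask} (full
#'   ground-truth ternary mask, no ignore sentinel), and \code{roi}
#'   (polygon vertex matrix with columns \code{x}, \code{y}).
#' @examples
#' sl <- generateSlide(c(1, 2), sceneParams(imageSize = c(48, 48), seed = 1))
#' dim(sl$image)   # 48 x 96 x 3
#' @export
generateSlide <- function(sceneGrid, params, roiMargin = 0.08) {
  stopifnot(is(params, "SceneParams"))
  sceneGrid <- as.integer(sceneGrid)
  if (length(sceneGrid) != 2L || any(sceneGrid < 1L))
    stop("sceneGrid must be two integers >= 1")
  H <- params@imageSize[1]; W <- params@imageSize[2]
  SH <- H * sceneGrid[1]; SW <- W * sceneGrid[2]
  image <- array(0, c(SH, SW, 3))
  mask <- matrix(classCodes()[["stroma"]], SH, SW)
  idx <- 0L
  for (gr in seq_len(sceneGrid[1])) {
    for (gc in seq_len(sceneGrid[2])) {
      idx <- idx + 1L
      p <- params
      # first scene keeps the caller's seed (so a 1x1 slide equals the
      # single scene); later scenes get derived seeds
      p@seed <- if (idx == 1L) params@seed
                else (params@seed %% 1000000L) * 1000L + idx
      sc <- generateTileScene(p)
      rows <- ((gr - 1L) * H + 1L):(gr * H)
      cols <- ((gc - 1L) * W + 1L):(gc * W)
      image[rows, cols, ] <- sc$image
      mask[rows, cols] <- sc$mask
    }
  }
  m <- max(1, round(roiMargin * min(SH, SW)))
  roi <- cbind(x = c(m, SW - m, SW - m, m), y = c(m, m, SH - m, SH - m))
  list(image = image, mask = mask, roi = roi)
}
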