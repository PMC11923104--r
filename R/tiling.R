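## ROI tessellation with the overlapping-tile strategy: non-overlapping
## output windows at stride outputPx partition the ROI; each is fed to the
## network as the larger centered input window, with mirror reflection
## where the input window leaves the slide.
##
## Coordinates are 0-based with half-open windows: the output window of a
## tile is [x0, x0 + outputPx) x [y0, y0 + outputPx) in slide pixels.

roiRaster <- function(roiPolygon, slideDim) {
  rasterizePolygon(roiPolygon, width = slideDim[2], height = slideDim[1])
}

#' Plan the tile grid covering an ROI
#'
#' Output windows lie on a fixed grid with stride \code{outputPx} anchored
#' at the slide origin; a tile is kept when its output window contains at
#' least one ROI pixel.  Kept output windows are pairwise disjoint and
#' cover every ROI pixel exactly once; the corresponding input windows
#' (each output window dilated by \code{\link{tileMargin}} pixels per
#' side) overlap.
#'
#' @param roiPolygon ROI polygon, matrix with columns \code{x}, \code{y}.
#' @param spec a \code{\link{tileSpec}}.
#' @param slideDim integer pair: slide height and width in pixels.
#' @return \code{data.frame} with columns \code{x0}, \code{y0} (0-based
#'   slide coordinates of each output window's top-left corner); zero rows
#'   for an empty ROI.
#' @examples
#' roi <- cbind(x = c(0, 212, 212, 0), y = c(0, 0, 212, 212))
#' planTiles(roi, tileSpec(), c(212, 212))
#' @export
planTiles <- function(roiPolygon, spec, slideDim) {
  stopifnot(is(spec, "TileSpec"))
  slideDim <- as.integer(slideDim)
  roi <- roiRaster(roiPolygon, slideDim)
  if (!any(roi))
    return(data.frame(x0 = integer(), y0 = integer()))
  out <- spec@outputPx
  rows <- which(rowSums(roi) > 0); cols <- which(colSums(roi) > 0)
  ty <- seq((min(rows) - 1L) %/% out, (max(rows) - 1L) %/% out)
  tx <- seq((min(cols) - 1L) %/% out, (max(cols) - 1L) %/% out)
  grid <- expand.grid(x0 = tx * out, y0 = ty * out)
  keep <- vapply(seq_len(nrow(grid)), function(i) {
    r1 <- grid$y0[i] + 1L; r2 <- min(grid$y0[i] + out, slideDim[1])
    c1 <- grid$x0[i] + 1L; c2 <- min(grid$x0[i] + out, slideDim[2])
    r1 <= r2 && c1 <= c2 && any(roi[r1:r2, c1:c2])
  }, logical(1))
  res <- grid[keep, , drop = FALSE]
  res <- res[order(res$y0, res$x0), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Mirror-reflected 1-based indices for 0-based positions `pos` into an axis
# of length n: position -1 maps to index 1 (0-based 0), -2 to 2, ...;
# position n maps to n, n+1 to n-1, ...
mirrorIndex <- function(pos, n) {
  idx <- pos
  neg <- idx < 0L
  idx[neg] <- -idx[neg] - 1L
  over <- idx > (n - 1L)
  idx[over] <- 2L * n - 1L - idx[over]
  if (any(idx < 0L | idx > n - 1L))
    stop("window extends beyond one full mirror period")
  idx + 1L
}

#' Extract the input window of a tile with mirror padding
#'
#' Returns the \code{inputPx}-sized window centered on the tile's output
#' window.  Pixels falling outside the slide are filled by mirror
#' reflection about the slide edge; interior pixels are copied verbatim.
#'
#' @param slideImage numeric \code{H x W x 3} array (or \code{H x W}
#'   matrix).
#' @param coord list or one-row data.frame with \code{x0}, \code{y0} from
#'   \code{\link{planTiles}}.
#' @param spec a \code{\link{tileSpec}}.
#' @return Array of size \code{inputPx x inputPx x 3} (or matrix).
#' @examples
#' img <- array(runif(64 * 64 * 3), c(64, 64, 3))
#' w <- extractInputWindow(img, list(x0 = 0, y0 = 0),
#'                         tileSpec(inputPx = 32, outputPx = 16))
#' dim(w)
#' @export
extractInputWindow <- function(slideImage, coord, spec) {
  stopifnot(is(spec, "TileSpec"))
  m <- tileMargin(spec)
  H <- dim(slideImage)[1]; W <- dim(slideImage)[2]
  rows <- mirrorIndex(seq(coord$y0 - m, length.out = spec@inputPx), H)
  cols <- mirrorIndex(seq(coord$x0 - m, length.out = spec@inputPx), W)
  if (length(dim(slideImage)) == 3L) slideImage[rows, cols, , drop = FALSE]
  else slideImage[rows, cols, drop = FALSE]
}

#' Crop the central output window of a full-size label tile
#'
#' Helper pairing ground-truth masks with network outputs: crops the
#' central \code{outputPx} window out of an \code{inputPx}-sized mask (or
#' image).
#'
#' @param tile matrix (or \code{H x W x C} array) of side \code{inputPx}.
#' @param spec a \code{\link{tileSpec}} (or \code{UNetSpec}-compatible
#'   sizes via \code{inputPx}/\code{outputPx}).
#' @return The central \code{outputPx}-sized crop.
#' @examples
#' m <- matrix(0L, 396, 396)
#' dim(cropToOutput(m, tileSpec()))
#' @export
cropToOutput <- function(tile, spec) {
  m <- tileMargin(spec)
  idx <- (m + 1L):(m + spec@outputPx)
  if (length(dim(tile)) == 3L) tile[idx, idx, , drop = FALSE]
  else tile[idx, idx, drop = FALSE]
}

#' Stitch per-tile masks into a slide-level classification map
#'
#' Each ROI pixel receives the class predicted by the unique output window
#' containing it; pixels outside the ROI are set to the ignore sentinel
#' (255).  An ROI pixel not covered by any supplied tile raises an
#' incomplete-coverage error.
#'
#' @param tileMasks list of integer matrices of side \code{outputPx}, one
#'   per row of \code{coords} (in the same order).
#' @param coords \code{data.frame} with \code{x0}, \code{y0} as returned
#'   by \code{\link{planTiles}}.
#' @param roiPolygon ROI polygon.
#' @param spec a \code{\link{tileSpec}}.
#' @param slideDim integer pair: slide height and width.
#' @return Integer \code{H x W} matrix with classes inside the ROI and 255
#'   outside.
#' @examples
#' roi <- cbind(x = c(0, 16, 16, 0), y = c(0, 0, 16, 16))
#' sp <- tileSpec(inputPx = 32, outputPx = 16)
#' stitched <- stitchTiles(list(matrix(1L, 16, 16)),
#'                         data.frame(x0 = 0, y0 = 0), roi, sp, c(16, 16))
#' @export
stitchTiles <- function(tileMasks, coords, roiPolygon, spec, slideDim) {
  stopifnot(is(spec, "TileSpec"), length(tileMasks) == nrow(coords))
  slideDim <- as.integer(slideDim)
  out <- spec@outputPx
  stitched <- matrix(classCodes()[["ignore"]], slideDim[1], slideDim[2])
  covered <- matrix(FALSE, slideDim[1], slideDim[2])
  for (i in seq_along(tileMasks)) {
    tm <- tileMasks[[i]]
    if (!all(dim(tm) == c(out, out)))
      stop("tile mask ", i, " is not ", out, " x ", out)
    r1 <- coords$y0[i] + 1L; c1 <- coords$x0[i] + 1L
    r2 <- min(r1 + out - 1L, slideDim[1])
    c2 <- min(c1 + out - 1L, slideDim[2])
    if (r1 > slideDim[1] || c1 > slideDim[2]) next
    stitched[r1:r2, c1:c2] <- tm[seq_len(r2 - r1 + 1L),
                                 seq_len(c2 - c1 + 1L)]
    covered[r1:r2, c1:c2] <- TRUE
  }
  roi <- roiRaster(roiPolygon, slideDim)
  if (any(roi & !covered))
    stop("incomplete coverage: ", sum(roi & !covered),
         " ROI pixel(s) not covered by any tile")
  stitched[!roi] <- classCodes()[["ignore"]]
  stitched
}
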