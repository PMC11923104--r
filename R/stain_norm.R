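## Macenko stain normalization: optical-density conversion, low-OD
## filtering, SVD plane projection, percentile angle extremes, robust
## concentration scaling.  The two-stain concentration solve is an exact
## non-negative least squares for the 2-variable case (active set).

rgbToOD <- function(rgb) {
  # rgb in [0, 1]; avoid log(0) at the 8-bit floor
  -log10(pmax(rgb, 1 / 255))
}

odToRGB <- function(od) {
  pmin(pmax(10^(-od), 0), 1)
}

# Non-negative least squares of OD (3 x N) on stain matrix M (3 x 2),
# solved exactly per pixel: unconstrained 2x2 solve, then the 2-variable
# active set (if a coefficient is negative, refit the other alone).
solveConcentrations <- function(M, od) {
  G <- crossprod(M)                       # 2 x 2
  if (abs(det(G)) < 1e-12) stop("singular stain profile")
  C <- solve(G, crossprod(M, od))         # 2 x N unconstrained
  n1 <- C[1, ] < 0; n2 <- C[2, ] < 0
  if (any(n1)) {
    C[1, n1] <- 0
    C[2, n1] <- pmax(0, colSums(M[, 2] * od[, n1, drop = FALSE]) / G[2, 2])
  }
  if (any(n2)) {
    C[2, n2] <- 0
    C[1, n2] <- pmax(0, colSums(M[, 1] * od[, n2, drop = FALSE]) / G[1, 1])
  }
  C
}

#' Estimate a Macenko stain profile from an RGB tile
#'
#' Converts the tile to optical density, discards pixels with any channel
#' below \code{betaOD}, projects the remaining OD vectors onto the plane
#' of their two leading principal directions, and returns the unit vectors
#' at the \code{alphaPct} and \code{100 - alphaPct} percentiles of the
#' angle in that plane.  The first column is the hematoxylin-like stain
#' (larger blue-channel optical density); robust stain concentrations are
#' the 99th percentiles under the estimated matrix.
#'
#' @param rgbTile numeric \code{H x W x 3} array in \[0, 1\].
#' @param betaOD optical-density floor below which pixels are treated as
#'   unstained (default 0.15).
#' @param alphaPct robust angle percentile in percent (default 1: use the
#'   1st/99th percentile angles).
#' @param minPixels minimum number of stained pixels required (default
#'   100); fewer raises an estimation error so callers can fall back to a
#'   reference profile.
#' @return A \code{\link{stainProfile}}.
#' @examples
#' sc <- generateTileScene(sceneParams(imageSize = c(64, 64), seed = 1))
#' estimateStainProfile(sc$image)
#' @export
estimateStainProfile <- function(rgbTile, betaOD = 0.15, alphaPct = 1,
                                 minPixels = 100L) {
  od <- rgbToOD(rgbTile)
  odm <- t(matrix(od, ncol = 3))          # 3 x N
  keep <- colSums(odm < betaOD) == 0
  if (sum(keep) < minPixels)
    stop("stain estimation error: only ", sum(keep),
         " pixels with all OD channels above betaOD = ", betaOD)
  odh <- odm[, keep, drop = FALSE]
  # SVD of the raw (uncentered) OD cloud, as in the original method
  V <- svd(odh, nu = 3, nv = 0)$u[, 1:2, drop = FALSE]
  # orient the plane basis so projections are mostly positive
  if (sum(crossprod(V[, 1], odh)) < 0) V[, 1] <- -V[, 1]
  if (sum(crossprod(V[, 2], odh)) < 0) V[, 2] <- -V[, 2]
  proj <- crossprod(V, odh)               # 2 x N
  phi <- atan2(proj[2, ], proj[1, ])
  qs <- quantile(phi, c(alphaPct / 100, 1 - alphaPct / 100), names = FALSE)
  v1 <- V %*% c(cos(qs[1]), sin(qs[1]))
  v2 <- V %*% c(cos(qs[2]), sin(qs[2]))
  fix <- function(v) { if (sum(v) < 0) v <- -v; v <- pmax(v, 0); v / sqrt(sum(v^2)) }
  v1 <- fix(v1); v2 <- fix(v2)
  # hematoxylin-like stain first: larger blue-channel OD
  M <- if (v1[3] >= v2[3]) cbind(v1, v2) else cbind(v2, v1)
  if (abs(det(crossprod(M))) < 1e-10) {
    # degenerate single-stain geometry: both extreme angles collapsed;
    # attribute all concentration to the first stain
    C <- rbind(pmax(as.vector(crossprod(M[, 1, drop = FALSE], odm)), 0), 0)
  } else {
    C <- solveConcentrations(M, odm)
  }
  maxC <- apply(C, 1, quantile, probs = 0.99, names = FALSE)
  maxC <- pmax(maxC, 1e-6)
  stainProfile(M, maxC)
}

#' Normalize a tile to a reference stain profile
#'
#' Decomposes the tile into stain concentrations under \code{source},
#' rescales each stain by \code{reference} max concentration /
#' \code{source} max concentration, and re-composites with the reference
#' stain matrix.  Output is clipped to valid 8-bit RGB; normalizing with
#' \code{source == reference} changes no pixel by more than rounding.
#'
#' @param rgbTile numeric \code{H x W x 3} array in \[0, 1\].
#' @param source \code{\link{stainProfile}} of the tile itself.
#' @param reference target \code{\link{stainProfile}}.
#' @return Normalized RGB array, same shape, quantized to the 8-bit grid.
#' @examples
#' sc <- generateTileScene(sceneParams(imageSize = c(64, 64), seed = 1))
#' pr <- estimateStainProfile(sc$image)
#' out <- normalizeTile(sc$image, pr, pr)   # identity within rounding
#' @export
normalizeTile <- function(rgbTile, source, reference) {
  stopifnot(is(source, "StainProfile"), is(reference, "StainProfile"))
  dims <- dim(rgbTile)
  # identical profiles: the transform is the identity, so skip the
  # decompose/recomposite cycle (which would clamp the few pixels outside
  # the non-negative stain cone)
  if (isTRUE(all.equal(source@stainMatrix, reference@stainMatrix,
                       tolerance = 1e-12)) &&
      isTRUE(all.equal(source@maxConcentrations,
                       reference@maxConcentrations, tolerance = 1e-12)))
    return(round(rgbTile * 255) / 255)
  od <- rgbToOD(rgbTile)
  odm <- t(matrix(od, ncol = 3))
  C <- solveConcentrations(source@stainMatrix, odm)
  C <- C * (reference@maxConcentrations / source@maxConcentrations)
  odOut <- reference@stainMatrix %*% C    # 3 x N
  out <- array(odToRGB(t(odOut)), dims)
  round(out * 255) / 255
}

#' Read/write stain profiles as JSON
#'
#' @param profile a \code{\link{stainProfile}}.
#' @param path file path.
#' @return \code{writeStainProfile} returns \code{path} invisibly;
#'   \code{readStainProfile} returns the profile.
#' @examples
#' p <- stainProfile(cbind(c(0.65, 0.7, 0.29), c(0.07, 0.99, 0.11)), c(1, 1))
#' f <- tempfile(fileext = ".json")
#' writeStainProfile(p, f)
#' readStainProfile(f)
#' @export
writeStainProfile <- function(profile, path) {
  jsonlite::write_json(
    list(stain_matrix = unname(profile@stainMatrix),
         max_concentrations = profile@maxConcentrations),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeStainProfile
#' @export
readStainProfile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stainProfile(x$stain_matrix, x$max_concentrations)
}
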