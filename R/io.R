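## Plain-file interfaces: 8-bit PNG images, single-channel PNG masks with
## the integer class encoding, GeoJSON-style ROI polygons, cohort CSV.

#' Read and write RGB images and ternary masks as PNG
#'
#' Images are 8-bit RGB PNG; masks are single-channel 8-bit PNG holding
#' the integer class codes (0 stroma, 1 tumor, 2 lymphocyte, 255 ignore)
#' directly as gray levels, so they round-trip exactly.
#'
#' @param image numeric \code{H x W x 3} array in \[0, 1\].
#' @param mask integer matrix of class codes.
#' @param path file path.
#' @return Readers return the array/matrix; writers return \code{path}
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".png")
#' writeMaskPNG(matrix(c(0L, 1L, 2L, 255L), 2), f)
#' readMaskPNG(f)
#' @export
writeImagePNG <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' @rdname writeImagePNG
#' @export
readImagePNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] > 3L)
    img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

#' @rdname writeImagePNG
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname writeImagePNG
#' @export
readMaskPNG <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Read and write ROI polygons as GeoJSON-style JSON
#'
#' The polygon is stored as a list of \code{[x, y]} vertices in pixel
#' coordinates under \code{"vertices"}.
#'
#' @param roi matrix with columns \code{x}, \code{y}.
#' @param path file path.
#' @return \code{readROIJson} returns the vertex matrix;
#'   \code{writeROIJson} returns \code{path} invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeROIJson(cbind(x = c(0, 4, 4, 0), y = c(0, 0, 4, 4)), f)
#' readROIJson(f)
#' @export
writeROIJson <- function(roi, path) {
  jsonlite::write_json(list(vertices = unname(as.matrix(roi))), path,
                       digits = NA)
  invisible(path)
}

#' @rdname writeROIJson
#' @export
readROIJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- as.matrix(x$vertices)
  colnames(m) <- c("x", "y")
  m
}

#' Read and write cohort tables as CSV
#'
#' Column conventions: \code{patient_id}, \code{os_months}, \code{event}
#' (0/1), \code{sip}, \code{lip}, plus arbitrary covariates
#' (\code{age}, \code{sex}, ...).
#'
#' @param cohort \code{data.frame}.
#' @param path file path.
#' @return \code{readCohortCSV} returns the \code{data.frame};
#'   \code{writeCohortCSV} returns \code{path} invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeCohortCSV(generateCohort(cohortParams(nPatients = 5)), f)
#' head(readCohortCSV(f))
#' @export
writeCohortCSV <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortCSV
#' @export
readCohortCSV <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
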