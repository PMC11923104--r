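## Slide-level quantification: class areas and the SIP/LIP/TIP fractions.
## Stromal area follows A_Stroma = A_ROI - (A_Tumor + A_Lymphocytes);
## all arithmetic is on integer pixel counts before any division, so
## sip + lip + tip = 1 holds exactly.

#' Quantify a stitched classification map
#'
#' Counts ROI pixels per class and derives the stromal, lymphocyte and
#' tumor area fractions (SIP, LIP, TIP).  When \code{roiPolygon} is given
#' the ROI is its rasterization and every ROI pixel must carry a class
#' (the ignore sentinel inside the ROI is an incomplete-map error);
#' without it, the ROI is taken to be all non-sentinel pixels.
#'
#' @param mask integer matrix with values in \code{\{0, 1, 2, 255\}}
#'   (see \code{\link{classCodes}}).
#' @param roiPolygon optional ROI polygon (matrix with columns \code{x},
#'   \code{y}).
#' @return A \code{SlideQuantification} object; see \code{\link{sip}},
#'   \code{\link{lip}}, \code{\link{tip}}, \code{\link{classAreas}}.
#' @examples
#' m <- matrix(c(rep(0L, 50), rep(1L, 40), rep(2L, 10)), 10, 10)
#' q <- quantifySlide(m)
#' sip(q)   # 0.5
#' @export
quantifySlide <- function(mask, roiPolygon = NULL) {
  codes <- classCodes()
  bad <- setdiff(unique(as.integer(mask)), unname(codes))
  if (length(bad))
    stop("mask contains invalid class value(s): ", paste(bad, collapse = ", "))
  if (!is.null(roiPolygon)) {
    roi <- rasterizePolygon(roiPolygon, ncol(mask), nrow(mask))
    if (!any(roi)) stop("empty ROI")
    vals <- mask[roi]
    if (any(vals == codes[["ignore"]]))
      stop("mask does not cover the ROI (ignore sentinel inside ROI)")
  } else {
    vals <- mask[mask != codes[["ignore"]]]
    if (length(vals) == 0L) stop("empty ROI")
  }
  aROI <- length(vals)
  aTumor <- sum(vals == codes[["tumor"]])
  aLymph <- sum(vals == codes[["lymphocyte"]])
  aStroma <- aROI - (aTumor + aLymph)
  sipv <- aStroma / aROI
  lipv <- aLymph / aROI
  # tip as the exact complement: the three fractions then sum to exactly
  # one in floating point (tip equals aTumor/aROI to within one ulp)
  new("SlideQuantification",
      aROI = as.numeric(aROI), aTumor = as.numeric(aTumor),
      aLymph = as.numeric(aLymph), aStroma = as.numeric(aStroma),
      sip = sipv, lip = lipv, tip = 1 - (sipv + lipv))
}

#' Quantify a cohort of slides
#'
#' One row per patient; patients contributing several slides are
#' aggregated by ROI-area-weighted means of the fractions (and summed
#' areas), so a patient's SIP equals the SIP of the pooled pixels.
#'
#' @param slides list of entries \code{list(patient_id, mask, roi = NULL,
#'   meta = NULL)}; \code{meta} is an optional named list of per-patient
#'   covariates that must agree across a patient's slides.
#' @return \code{data.frame} with columns \code{patient_id}, \code{a_roi},
#'   \code{a_tumor}, \code{a_lymph}, \code{a_stroma}, \code{sip},
#'   \code{lip}, \code{tip}, plus any metadata columns.
#' @examples
#' m1 <- matrix(0L, 5, 5); m2 <- matrix(1L, 5, 5)
#' quantifyCohort(list(list(patient_id = "a", mask = m1),
#'                     list(patient_id = "a", mask = m2)))
#' @export
quantifyCohort <- function(slides) {
  stopifnot(length(slides) >= 1L)
  qs <- lapply(slides, function(s) {
    q <- quantifySlide(s$mask, s$roi)
    c(list(patient_id = s$patient_id,
           a_roi = q@aROI, a_tumor = q@aTumor, a_lymph = q@aLymph,
           a_stroma = q@aStroma), s$meta)
  })
  ids <- vapply(qs, function(x) as.character(x$patient_id), character(1))
  out <- NULL
  for (id in unique(ids)) {
    sub <- qs[ids == id]
    metas <- lapply(sub, function(x)
      x[setdiff(names(x), c("patient_id", "a_roi", "a_tumor", "a_lymph",
                            "a_stroma"))])
    if (length(sub) > 1L)
      for (m in metas[-1]) if (!identical(m, metas[[1]]))
        stop("duplicate patient '", id, "' with conflicting metadata")
    aROI <- sum(vapply(sub, `[[`, numeric(1), "a_roi"))
    aTum <- sum(vapply(sub, `[[`, numeric(1), "a_tumor"))
    aLym <- sum(vapply(sub, `[[`, numeric(1), "a_lymph"))
    aStr <- aROI - (aTum + aLym)
    sipv <- aStr / aROI
    lipv <- aLym / aROI
    row <- data.frame(patient_id = id, a_roi = aROI, a_tumor = aTum,
                      a_lymph = aLym, a_stroma = aStr,
                      sip = sipv, lip = lipv,
                      tip = 1 - (sipv + lipv), stringsAsFactors = FALSE)
    if (length(metas[[1]]))
      row <- cbind(row, as.data.frame(metas[[1]], stringsAsFactors = FALSE))
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  out
}
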