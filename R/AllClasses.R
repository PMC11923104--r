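## S4 classes for the package's central value objects.  Masks and RGB images
## stay plain matrices/arrays (see ?classCodes); everything with invariants
## worth enforcing gets a class with a validity method.

#' @name StromaSurv-classes
#' @title S4 value classes
#' @description Parameter and result containers with validity checks:
#'   \code{SceneParams}, \code{CohortParams}, \code{TileSpec},
#'   \code{StainProfile}, \code{UNetSpec}, \code{TrainConfig}, \code{UNet},
#'   \code{SlideQuantification}, \code{CutpointResult},
#'   \code{SurvivalSummary}.  Use the constructor functions
#'   (\code{\link{sceneParams}}, \code{\link{tileSpec}}, ...) rather than
#'   \code{new()}.
NULL

## ---- synthetic data ----

#' @rdname StromaSurv-classes
#' @export
setClass("SceneParams", representation(
  imageSize = "integer", tumorGlands = "integer", lymphClusters = "integer",
  stromaFiberDensity = "numeric", stainJitter = "numeric", seed = "integer"
))

setValidity("SceneParams", function(object) {
  msg <- character()
  if (length(object@imageSize) != 2L || any(!is.finite(object@imageSize)) ||
      any(object@imageSize < 32L))
    msg <- c(msg, "imageSize must be two finite integers >= 32")
  if (object@tumorGlands < 0L || object@lymphClusters < 0L)
    msg <- c(msg, "object counts must be non-negative")
  if (!is.finite(object@stromaFiberDensity) ||
      object@stromaFiberDensity < 0 || object@stromaFiberDensity > 1)
    msg <- c(msg, "stromaFiberDensity must be in [0, 1]")
  if (!is.finite(object@stainJitter) || object@stainJitter < 0)
    msg <- c(msg, "stainJitter must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Parameters for a synthetic H&E-like scene
#'
#' Describes one simulated tile scene: canvas size, number of gland-like
#' tumor structures, number of lymphocyte clusters, density of the fibrous
#' stroma texture, per-channel multiplicative stain jitter (log-normal sd),
#' and the RNG seed making generation fully deterministic.
#'
#' @param imageSize integer pair, canvas height and width in pixels
#'   (each >= 32).
#' @param tumorGlands number of gland-like tumor structures.
#' @param lymphClusters number of lymphocyte clusters.
#' @param stromaFiberDensity fraction in \[0, 1\]; contrast of the fibrous
#'   stroma texture.
#' @param stainJitter non-negative sd of per-channel multiplicative
#'   log-normal stain jitter.
#' @param seed integer RNG seed.
#' @return A \code{SceneParams} object.
#' @examples
#' sceneParams(imageSize = c(64, 64), tumorGlands = 1, seed = 7)
#' @export
sceneParams <- function(imageSize = c(396L, 396L), tumorGlands = 3L,
                        lymphClusters = 6L, stromaFiberDensity = 0.5,
                        stainJitter = 0.03, seed = 1L) {
  if (any(imageSize <= 0)) stop("imageSize must be positive")
  new("SceneParams", imageSize = as.integer(imageSize),
      tumorGlands = as.integer(tumorGlands),
      lymphClusters = as.integer(lymphClusters),
      stromaFiberDensity = as.numeric(stromaFiberDensity),
      stainJitter = as.numeric(stainJitter), seed = as.integer(seed))
}

#' @rdname StromaSurv-classes
#' @export
setClass("CohortParams", representation(
  nPatients = "integer", sipDistribution = "list", lipDistribution = "list",
  sipCutsTrue = "numeric", lipCutTrue = "numeric", hazardByGroup = "numeric",
  censoringRate = "numeric", adminCensorMonths = "numeric", seed = "integer"
))

setValidity("CohortParams", function(object) {
  msg <- character()
  if (object@nPatients < 1L) msg <- c(msg, "nPatients must be positive")
  cc <- object@sipCutsTrue
  if (length(cc) != 2L || !(0 < cc[1] && cc[1] < cc[2] && cc[2] < 1))
    msg <- c(msg, "sipCutsTrue must satisfy 0 < c1 < c2 < 1")
  if (!(object@lipCutTrue > 0 && object@lipCutTrue < 1))
    msg <- c(msg, "lipCutTrue must be in (0, 1)")
  hz <- object@hazardByGroup
  need <- c("int.high", "int.low", "lh.high", "lh.low")
  if (!all(need %in% names(hz)))
    msg <- c(msg, "hazardByGroup must name int.high, int.low, lh.high, lh.low")
  if (any(hz <= 0)) msg <- c(msg, "all hazard rates must be > 0")
  if (object@censoringRate < 0) msg <- c(msg, "censoringRate must be >= 0")
  if (object@adminCensorMonths <= 0)
    msg <- c(msg, "adminCensorMonths must be > 0")
  if (length(msg)) msg else TRUE
})

#' Parameters for a synthetic survival cohort
#'
#' The cohort carries the hazard structure the downstream analysis assumes:
#' patients whose stromal fraction (SIP) lies in the intermediate band
#' \code{(c1, c2]} have lower hazard than SIP-low/high patients (the
#' U-shaped stromal risk), and high lymphocyte fraction (LIP above
#' \code{lipCutTrue}) is protective.  Survival times are exponential with
#' the rate of the patient's true \{SIP-intermediate, SIP-LH\} x
#' \{LIP-low, LIP-high\} cell; censoring is an independent exponential plus
#' an administrative cutoff.
#'
#' Default rates are on the scale of published pancreatic-cancer medians
#' (median OS of roughly 28 months for the best group and 8 months for the
#' worst, via rate = ln 2 / median).
#'
#' @param nPatients cohort size.
#' @param sipDistribution,lipDistribution marker distributions on \[0, 1\]:
#'   \code{list(name, ...)} with \code{name} one of \code{"beta"}
#'   (\code{shape1}, \code{shape2}), \code{"uniform"} (\code{min},
#'   \code{max}) or \code{"fixed"} (\code{value}).
#' @param sipCutsTrue true SIP band boundaries \code{c(c1, c2)},
#'   0 < c1 < c2 < 1.
#' @param lipCutTrue true LIP threshold in (0, 1).
#' @param hazardByGroup named numeric: exponential event rates per month for
#'   \code{int.high}, \code{int.low}, \code{lh.high}, \code{lh.low}.
#' @param censoringRate per-month exponential censoring rate (>= 0).
#' @param adminCensorMonths administrative censoring time (months, may be
#'   \code{Inf}).
#' @param seed integer RNG seed.
#' @return A \code{CohortParams} object.
#' @examples
#' cohortParams(nPatients = 100, seed = 3)
#' @export
cohortParams <- function(nPatients = 500L,
                         sipDistribution = list(name = "beta",
                                                shape1 = 4, shape2 = 2),
                         lipDistribution = list(name = "beta",
                                                shape1 = 1.4, shape2 = 45),
                         sipCutsTrue = c(0.54, 0.75),
                         lipCutTrue = 0.02,
                         hazardByGroup = c(int.high = 0.025, int.low = 0.042,
                                           lh.high = 0.042, lh.low = 0.085),
                         censoringRate = 0.01,
                         adminCensorMonths = 84,
                         seed = 1L) {
  new("CohortParams", nPatients = as.integer(nPatients),
      sipDistribution = sipDistribution, lipDistribution = lipDistribution,
      sipCutsTrue = as.numeric(sipCutsTrue),
      lipCutTrue = as.numeric(lipCutTrue),
      hazardByGroup = hazardByGroup,
      censoringRate = as.numeric(censoringRate),
      adminCensorMonths = as.numeric(adminCensorMonths),
      seed = as.integer(seed))
}

## ---- tiling ----

#' @rdname StromaSurv-classes
#' @export
setClass("TileSpec", representation(
  inputPx = "integer", outputPx = "integer", micronsPerPx = "numeric"
))

setValidity("TileSpec", function(object) {
  msg <- character()
  if (object@inputPx <= 0L || object@outputPx <= 0L)
    msg <- c(msg, "tile sizes must be positive")
  if (object@outputPx >= object@inputPx)
    msg <- c(msg, "outputPx must be smaller than inputPx")
  if ((object@inputPx - object@outputPx) %% 2L != 0L)
    msg <- c(msg, "inputPx - outputPx must be even (symmetric margin)")
  if (object@micronsPerPx <= 0) msg <- c(msg, "micronsPerPx must be > 0")
  if (length(msg)) msg else TRUE
})

#' Tile geometry specification
#'
#' Input windows of \code{inputPx} pixels are fed to the network; only the
#' central \code{outputPx} window is predicted, so abutting output windows
#' tile the ROI while input windows overlap (the overlapping-tile
#' strategy).  The defaults give 396-pixel inputs at 0.25 micrometre per
#' pixel, i.e. a physical tile side of 99 micrometres, with 212-pixel
#' outputs.
#'
#' @param inputPx input window side in pixels.
#' @param outputPx output (prediction) window side in pixels.
#' @param micronsPerPx physical pixel size in micrometres.
#' @return A \code{TileSpec} object.
#' @examples
#' ts <- tileSpec()
#' physicalSideUm(ts)   # 99
#' tileMargin(ts)       # 92
#' @export
tileSpec <- function(inputPx = 396L, outputPx = 212L, micronsPerPx = 0.25) {
  new("TileSpec", inputPx = as.integer(inputPx),
      outputPx = as.integer(outputPx), micronsPerPx = as.numeric(micronsPerPx))
}

#' @describeIn tileSpec physical side length of the input tile in
#'   micrometres (\code{inputPx * micronsPerPx}).
#' @param spec a \code{TileSpec}.
#' @export
physicalSideUm <- function(spec) spec@inputPx * spec@micronsPerPx

#' @describeIn tileSpec margin between input and output windows,
#'   \code{(inputPx - outputPx) / 2} pixels on each side.
#' @export
tileMargin <- function(spec) (spec@inputPx - spec@outputPx) %/% 2L

## ---- stain normalization ----

#' @rdname StromaSurv-classes
#' @export
setClass("StainProfile", representation(
  stainMatrix = "matrix", maxConcentrations = "numeric"
))

setValidity("StainProfile", function(object) {
  msg <- character()
  M <- object@stainMatrix
  if (!all(dim(M) == c(3L, 2L))) msg <- c(msg, "stainMatrix must be 3 x 2")
  else {
    nrm <- sqrt(colSums(M^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "stain vectors must have unit Euclidean norm")
    if (any(M < -1e-8)) msg <- c(msg, "stain vectors must be non-negative")
  }
  if (length(object@maxConcentrations) != 2L ||
      any(object@maxConcentrations <= 0))
    msg <- c(msg, "maxConcentrations must be two positive values")
  if (length(msg)) msg else TRUE
})

#' Construct a stain profile
#'
#' @param stainMatrix 3 x 2 matrix of optical-density stain vectors
#'   (columns: hematoxylin-like, eosin-like); columns are renormalized to
#'   unit length.
#' @param maxConcentrations robust (99th percentile) concentration per
#'   stain, two positive values.
#' @return A \code{StainProfile} object.
#' @examples
#' stainProfile(cbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11)), c(1.5, 1.2))
#' @export
stainProfile <- function(stainMatrix, maxConcentrations) {
  M <- as.matrix(stainMatrix)
  M <- pmax(M, 0)
  M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
  new("StainProfile", stainMatrix = M,
      maxConcentrations = as.numeric(maxConcentrations))
}

## ---- segmentation ----

#' @rdname StromaSurv-classes
#' @export
setClass("UNetSpec", representation(
  depth = "integer", baseChannels = "integer", kernel = "integer",
  convsPerBlock = "integer", dropoutRate = "numeric", nClasses = "integer",
  inputPx = "integer"
))

setValidity("UNetSpec", function(object) {
  msg <- character()
  if (object@kernel %% 2L != 1L) msg <- c(msg, "kernel must be odd")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (object@depth < 0L) msg <- c(msg, "depth must be >= 0")
  if (object@baseChannels < 1L || object@convsPerBlock < 1L ||
      object@nClasses < 2L || object@inputPx < 1L)
    msg <- c(msg, "channels, convs per block, classes and input size must be positive")
  if (length(msg)) msg else TRUE
})

#' U-Net architecture specification
#'
#' Valid-convolution (unpadded) U-Net: \code{depth} pooling levels with
#' \code{convsPerBlock} 3x3 convolutions per block on both paths, 2x2
#' max-pooling, 2x transpose-convolution upsampling,
#' center-crop-and-concatenate skip connections, and a 1x1 softmax head
#' over \code{nClasses} classes.  With the defaults a 396-pixel input
#' yields a 212-pixel output (see \code{\link{unetOutputSize}}).
#'
#' @param depth number of pooling steps.
#' @param baseChannels channels of the first encoder level; doubled per
#'   level.
#' @param kernel odd convolution kernel size.
#' @param convsPerBlock convolutions per encoder/decoder block.
#' @param dropoutRate fraction of feature-map pixels dropped (element-wise) after each convolution
#'   during training.
#' @param nClasses number of output classes.
#' @param inputPx default input tile side.
#' @return A \code{UNetSpec} object.
#' @examples
#' unetOutputSize(396, unetSpec())   # 212
#' @export
unetSpec <- function(depth = 4L, baseChannels = 32L, kernel = 3L,
                     convsPerBlock = 2L, dropoutRate = 0.10, nClasses = 3L,
                     inputPx = 396L) {
  new("UNetSpec", depth = as.integer(depth),
      baseChannels = as.integer(baseChannels), kernel = as.integer(kernel),
      convsPerBlock = as.integer(convsPerBlock),
      dropoutRate = as.numeric(dropoutRate), nClasses = as.integer(nClasses),
      inputPx = as.integer(inputPx))
}

#' @rdname StromaSurv-classes
#' @export
setClass("TrainConfig", representation(
  batchSize = "integer", maxEpochs = "integer", lrInit = "numeric",
  plateauPatience = "integer", lrFactor = "numeric",
  earlyStopPatience = "integer", seed = "integer"
))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (any(c(object@batchSize, object@maxEpochs, object@plateauPatience,
            object@earlyStopPatience) < 1L))
    msg <- c(msg, "batchSize, maxEpochs and patiences must be positive")
  if (object@lrInit <= 0) msg <- c(msg, "lrInit must be > 0")
  if (object@lrFactor <= 0 || object@lrFactor >= 1)
    msg <- c(msg, "lrFactor must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Training configuration
#'
#' Defaults follow the published schedule: batch size 160, up to 50 epochs,
#' learning rate reduced by 90 percent (factor 0.1) after 3 consecutive
#' monitoring intervals without loss improvement, early stop after 5.
#' Monitoring intervals are epochs (see the methods vignette for why).
#'
#' @param batchSize tiles per gradient step.
#' @param maxEpochs maximum number of epochs.
#' @param lrInit initial Adam learning rate.
#' @param plateauPatience non-improving intervals before LR reduction.
#' @param lrFactor multiplicative LR reduction factor (0.1 = reduce by 90%).
#' @param earlyStopPatience non-improving intervals before stopping.
#' @param seed RNG seed for shuffling, dropout and initialization.
#' @return A \code{TrainConfig} object.
#' @examples
#' trainConfig(batchSize = 4, maxEpochs = 5)
#' @export
trainConfig <- function(batchSize = 160L, maxEpochs = 50L, lrInit = 1e-3,
                        plateauPatience = 3L, lrFactor = 0.10,
                        earlyStopPatience = 5L, seed = 1L) {
  new("TrainConfig", batchSize = as.integer(batchSize),
      maxEpochs = as.integer(maxEpochs), lrInit = as.numeric(lrInit),
      plateauPatience = as.integer(plateauPatience),
      lrFactor = as.numeric(lrFactor),
      earlyStopPatience = as.integer(earlyStopPatience),
      seed = as.integer(seed))
}

#' @rdname StromaSurv-classes
#' @export
setClass("UNet", representation(
  spec = "UNetSpec", weights = "list"
))

## ---- quantification ----

#' @rdname StromaSurv-classes
#' @export
setClass("SlideQuantification", representation(
  aROI = "numeric", aTumor = "numeric", aLymph = "numeric",
  aStroma = "numeric", sip = "numeric", lip = "numeric", tip = "numeric"
))

setValidity("SlideQuantification", function(object) {
  msg <- character()
  if (object@aROI <= 0) msg <- c(msg, "aROI must be > 0")
  if (any(c(object@aTumor, object@aLymph, object@aStroma) < 0))
    msg <- c(msg, "areas must be non-negative")
  if (object@aStroma != object@aROI - (object@aTumor + object@aLymph))
    msg <- c(msg, "aStroma must equal aROI - (aTumor + aLymph)")
  if (abs(object@sip + object@lip + object@tip - 1) > 1e-12)
    msg <- c(msg, "sip + lip + tip must equal 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn quantifySlide stromal area fraction of the ROI.
#' @param x a \code{SlideQuantification}.
#' @export
sip <- function(x) x@sip
#' @describeIn quantifySlide lymphocyte area fraction of the ROI.
#' @export
lip <- function(x) x@lip
#' @describeIn quantifySlide tumor area fraction of the ROI.
#' @export
tip <- function(x) x@tip
#' @describeIn quantifySlide named pixel areas
#'   (\code{roi}, \code{tumor}, \code{lymphocyte}, \code{stroma}).
#' @export
classAreas <- function(x) {
  c(roi = x@aROI, tumor = x@aTumor, lymphocyte = x@aLymph,
    stroma = x@aStroma)
}

## ---- cutpoints ----

#' @rdname StromaSurv-classes
#' @export
setClass("CutpointResult", representation(
  cuts = "numeric", maxStatistic = "numeric", pValue = "numeric",
  groupLabels = "factor", marker = "character"
))

setValidity("CutpointResult", function(object) {
  msg <- character()
  if (!length(object@cuts) %in% 1:2)
    msg <- c(msg, "cuts must hold 1 or 2 thresholds")
  if (length(object@cuts) == 2L && object@cuts[1] >= object@cuts[2])
    msg <- c(msg, "two-cut case requires c1 < c2")
  if (anyNA(object@groupLabels))
    msg <- c(msg, "every patient must be labeled")
  if (length(msg)) msg else TRUE
})

#' @describeIn maxstatBinary selected threshold(s) on the marker scale.
#' @param x a \code{CutpointResult}.
#' @export
cutValues <- function(x) x@cuts
#' @describeIn maxstatBinary maximized statistic (standardized log-rank
#'   statistic for the binary search, log-rank chi-square for the two-cut
#'   search).
#' @export
maxStatistic <- function(x) x@maxStatistic
#' @describeIn maxstatBinary per-patient group labels as a factor.
#' @export
groupLabels <- function(x) x@groupLabels
#' @describeIn maxstatBinary selection-adjusted p-value (binary search
#'   only; \code{NA} for the two-cut search).
#' @export
cutPValue <- function(x) x@pValue

## ---- survival ----

#' @rdname StromaSurv-classes
#' @export
setClass("SurvivalSummary", representation(
  medianOS = "numeric", medianCI = "numeric", curve = "data.frame",
  n = "integer", nEvents = "integer"
))

setValidity("SurvivalSummary", function(object) {
  msg <- character()
  s <- object@curve$surv
  if (length(s) && (any(diff(s) > 1e-12) || any(s < -1e-12 | s > 1 + 1e-12)))
    msg <- c(msg, "KM survival must be non-increasing within [0, 1]")
  if (length(object@medianCI) != 2L)
    msg <- c(msg, "medianCI must have length 2")
  if (length(msg)) msg else TRUE
})

#' @describeIn kmFit median overall survival in months (\code{NA} when not
#'   reached).
#' @param x a \code{SurvivalSummary}.
#' @export
medianOS <- function(x) x@medianOS
#' @describeIn kmFit 95 percent confidence interval of the median
#'   (log(-log) based).
#' @export
medianCI <- function(x) x@medianCI
#' @describeIn kmFit Kaplan-Meier step curve as a data.frame with columns
#'   \code{time}, \code{nRisk}, \code{nEvent}, \code{surv}, \code{lower},
#'   \code{upper}.
#' @export
kmCurve <- function(x) x@curve

## ---- show methods ----

setMethod("show", "SceneParams", function(object) {
  cat(sprintf(
    "SceneParams: %d x %d px, %d glands, %d lymphocyte clusters,\n  fiber density %.2f, stain jitter %.3f, seed %d\n",
    object@imageSize[1], object@imageSize[2], object@tumorGlands,
    object@lymphClusters, object@stromaFiberDensity, object@stainJitter,
    object@seed))
})

setMethod("show", "CohortParams", function(object) {
  cat(sprintf(
    "CohortParams: n = %d, SIP band (%.3f, %.3f], LIP cut %.3f, seed %d\n",
    object@nPatients, object@sipCutsTrue[1], object@sipCutsTrue[2],
    object@lipCutTrue, object@seed))
  cat("  hazards/month:",
      paste(names(object@hazardByGroup),
            sprintf("%.3f", object@hazardByGroup), collapse = ", "), "\n")
})

setMethod("show", "TileSpec", function(object) {
  cat(sprintf(
    "TileSpec: input %d px -> output %d px (margin %d px), %.2f um/px, physical side %.1f um\n",
    object@inputPx, object@outputPx, tileMargin(object),
    object@micronsPerPx, physicalSideUm(object)))
})

setMethod("show", "StainProfile", function(object) {
  cat("StainProfile (OD stain vectors, columns = H, E):\n")
  M <- object@stainMatrix
  dimnames(M) <- list(c("R", "G", "B"), c("hematoxylin", "eosin"))
  print(round(M, 4))
  cat("  max concentrations:",
      paste(sprintf("%.3f", object@maxConcentrations), collapse = ", "), "\n")
})

setMethod("show", "UNetSpec", function(object) {
  out <- tryCatch(unetOutputSize(object@inputPx, object),
                  error = function(e) NA_integer_)
  cat(sprintf(
    "UNetSpec: depth %d, base %d ch, %dx%d kernel, %d convs/block, dropout %.2f\n  input %d px -> output %s px, %d classes\n",
    object@depth, object@baseChannels, object@kernel, object@kernel,
    object@convsPerBlock, object@dropoutRate, object@inputPx,
    ifelse(is.na(out), "invalid", as.character(out)), object@nClasses))
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: batch %d, <= %d epochs, lr %.2g (x%.2f after %d flat intervals),\n  early stop after %d, seed %d\n",
    object@batchSize, object@maxEpochs, object@lrInit, object@lrFactor,
    object@plateauPatience, object@earlyStopPatience, object@seed))
})

setMethod("show", "UNet", function(object) {
  np <- sum(vapply(unlist(object@weights, recursive = TRUE), length,
                   numeric(1)))
  cat(sprintf("UNet model (%s parameters)\n", format(np, big.mark = ",")))
  show(object@spec)
})

setMethod("show", "SlideQuantification", function(object) {
  cat(sprintf(
    "SlideQuantification: A_ROI = %g px (tumor %g, lymphocyte %g, stroma %g)\n  SIP %.4f  LIP %.4f  TIP %.4f\n",
    object@aROI, object@aTumor, object@aLymph, object@aStroma,
    object@sip, object@lip, object@tip))
})

setMethod("show", "CutpointResult", function(object) {
  cat(sprintf("CutpointResult [%s]: cut%s %s, max statistic %.4f",
              object@marker, if (length(object@cuts) > 1) "s" else "",
              paste(sprintf("%.4f", object@cuts), collapse = ", "),
              object@maxStatistic))
  if (!is.na(object@pValue)) cat(sprintf(", p = %.4g", object@pValue))
  cat("\n  groups:", paste(sprintf("%s: %d", levels(object@groupLabels),
                                   tabulate(object@groupLabels)),
                           collapse = ", "), "\n")
})

setMethod("show", "SurvivalSummary", function(object) {
  med <- if (is.na(object@medianOS)) "not reached"
         else sprintf("%.1f months (95%%CI: %.1f-%.1f)", object@medianOS,
                      object@medianCI[1], object@medianCI[2])
  cat(sprintf("SurvivalSummary: n = %d, events = %d, median OS %s\n",
              object@n, object@nEvents, med))
})
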