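## Training loop (Adam, LR-on-plateau, early stopping), pixel-masked
## cross-entropy, and segmentation metrics.

zeroLike <- function(w) {
  if (is.list(w)) lapply(w, zeroLike) else w * 0
}

# Recursions pair elements by name when names are present (the decoder
# levels are stored deepest-first while gradients arrive shallowest-first).
mapPair <- function(a, b, f) {
  if (is.list(a)) {
    keys <- if (!is.null(names(a))) names(a) else seq_along(a)
    for (k in keys) a[[k]] <- mapPair(a[[k]], b[[k]], f)
    a
  } else f(a, b)
}

addGrads <- function(a, b) mapPair(a, b, `+`)
scaleGrads <- function(a, s) {
  if (is.list(a)) lapply(a, scaleGrads, s = s) else a * s
}

adamStep <- function(w, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  if (is.list(w)) {
    keys <- if (!is.null(names(w))) names(w) else seq_along(w)
    for (k in keys) {
      r <- adamStep(w[[k]], g[[k]], m[[k]], v[[k]], lr, t, beta1, beta2, eps)
      w[[k]] <- r$w; m[[k]] <- r$m; v[[k]] <- r$v
    }
    return(list(w = w, m = m, v = v))
  }
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g * g
  mh <- m / (1 - beta1^t)
  vh <- v / (1 - beta2^t)
  list(w = w - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

# Masked cross-entropy loss and logit gradient for one tile.
# probs: H x W x K; label: H x W with classes 0..K-1 and 255 = ignore.
maskedCELoss <- function(probs, label) {
  K <- dim(probs)[3]
  valid <- label != classCodes()[["ignore"]]
  nValid <- sum(valid)
  if (nValid == 0L)
    return(list(loss = NA_real_, dLogits = NULL, nValid = 0L, nCorrect = 0L))
  pm <- matrix(probs, ncol = K)
  li <- as.integer(label)
  vIdx <- which(as.vector(valid))
  pTrue <- pm[cbind(vIdx, li[vIdx] + 1L)]
  loss <- -mean(log(pmax(pTrue, 1e-12)))
  oneHot <- matrix(0, length(li), K)
  oneHot[cbind(vIdx, li[vIdx] + 1L)] <- 1
  dL <- (pm - oneHot) / nValid
  dL[-vIdx, ] <- 0
  pred <- max.col(pm, ties.method = "first") - 1L
  list(loss = loss, dLogits = array(dL, dim(probs)), nValid = nValid,
       nCorrect = sum(pred[vIdx] == li[vIdx]))
}

#' Learning-rate-on-plateau / early-stopping schedule semantics
#'
#' Pure function over a sequence of monitored losses (one per monitoring
#' interval, i.e. epoch): whenever the loss has failed to improve on the
#' best value for \code{plateauPatience} consecutive intervals the
#' learning rate is multiplied by \code{lrFactor} (and the plateau counter
#' resets); after \code{earlyStopPatience} consecutive intervals without
#' improvement training stops.
#'
#' @param losses numeric vector of monitored losses.
#' @param plateauPatience,earlyStopPatience,lrFactor,lrInit schedule
#'   parameters (see \code{\link{trainConfig}}).
#' @return \code{data.frame} with one row per processed interval:
#'   \code{epoch}, \code{loss}, \code{lr} (rate in force during that
#'   interval), \code{reduced} (was the LR reduced after it), and
#'   \code{stop} (did training halt after it).  Rows after a stop are not
#'   emitted.
#' @examples
#' plateauSchedule(c(1, 1, 1, 1), plateauPatience = 3)
#' @export
plateauSchedule <- function(losses, plateauPatience = 3L,
                            earlyStopPatience = 5L, lrFactor = 0.1,
                            lrInit = 1e-3) {
  lr <- lrInit
  best <- Inf
  plateau <- 0L
  noImprove <- 0L
  out <- NULL
  for (i in seq_along(losses)) {
    usedLr <- lr
    if (losses[i] < best) {
      best <- losses[i]
      plateau <- 0L
      noImprove <- 0L
    } else {
      plateau <- plateau + 1L
      noImprove <- noImprove + 1L
    }
    reduced <- FALSE
    if (plateau >= plateauPatience) {
      lr <- lr * lrFactor
      plateau <- 0L
      reduced <- TRUE
    }
    stop <- noImprove >= earlyStopPatience
    out <- rbind(out, data.frame(epoch = i, loss = losses[i], lr = usedLr,
                                 reduced = reduced, stop = stop))
    if (stop) break
  }
  out
}

#' Train a U-Net on labeled tiles
#'
#' Minimizes pixel-wise categorical cross-entropy over non-ignored pixels
#' with Adam, shuffled minibatches of \code{cfg@batchSize} tiles, spatial
#' dropout, learning-rate reduction on plateau and early stopping (see
#' \code{\link{plateauSchedule}}; the monitoring interval is one epoch).
#' All randomness (shuffling, dropout) derives from \code{cfg@seed}.
#'
#' @param model a \code{\link{buildUnet}} model.
#' @param tiles list of \code{list(x = input array, y = label matrix)}
#'   pairs; \code{y} has side \code{unetOutputSize(inputPx, spec)} with
#'   classes \code{0..nClasses-1} and 255 = ignore.
#' @param cfg a \code{\link{trainConfig}}.
#' @return List with \code{model} (trained) and \code{history}
#'   (\code{data.frame} of epoch, loss, accuracy, lr, reduced, stopped).
#' @examples
#' ## see the package vignette; training a toy model takes a few seconds
#' @export
trainUnet <- function(model, tiles, cfg) {
  stopifnot(is(model, "UNet"), is(cfg, "TrainConfig"))
  n <- length(tiles)
  if (n == 0L) stop("empty tile dataset")
  outPx <- unetOutputSize(model@spec@inputPx, model@spec)
  for (i in seq_len(n)) {
    if (!all(dim(tiles[[i]]$y) == c(outPx, outPx)))
      stop("label ", i, " is not ", outPx, " x ", outPx)
  }
  weights <- model@weights
  mState <- zeroLike(weights)
  vState <- zeroLike(weights)
  lr <- cfg@lrInit
  best <- Inf
  plateau <- 0L
  noImprove <- 0L
  tAdam <- 0L
  history <- NULL
  withSeed(cfg@seed, {
    for (epoch in seq_len(cfg@maxEpochs)) {
      ord <- sample(n)
      epochLoss <- 0
      epochValid <- 0
      epochCorrect <- 0
      nLossTiles <- 0L
      b0 <- 1L
      while (b0 <= n) {
        bIdx <- ord[b0:min(b0 + cfg@batchSize - 1L, n)]
        b0 <- b0 + cfg@batchSize
        gAcc <- NULL
        nUsed <- 0L
        for (i in bIdx) {
          model@weights <- weights
          fw <- unetForward(model, tiles[[i]]$x, train = TRUE)
          lo <- maskedCELoss(fw$probs, tiles[[i]]$y)
          if (lo$nValid == 0L) next
          g <- unetBackward(model, fw$cache, lo$dLogits)
          gAcc <- if (is.null(gAcc)) g else addGrads(gAcc, g)
          nUsed <- nUsed + 1L
          epochLoss <- epochLoss + lo$loss
          nLossTiles <- nLossTiles + 1L
          epochValid <- epochValid + lo$nValid
          epochCorrect <- epochCorrect + lo$nCorrect
        }
        if (nUsed == 0L) {
          warning("batch with all pixels ignored; skipped")
          next
        }
        gAcc <- scaleGrads(gAcc, 1 / nUsed)
        tAdam <- tAdam + 1L
        st <- adamStep(weights, gAcc, mState, vState, lr, tAdam)
        weights <- st$w; mState <- st$m; vState <- st$v
      }
      loss <- if (nLossTiles > 0L) epochLoss / nLossTiles else NA_real_
      acc <- if (epochValid > 0L) epochCorrect / epochValid else NA_real_
      usedLr <- lr
      if (is.finite(loss) && loss < best) {
        best <- loss; plateau <- 0L; noImprove <- 0L
      } else {
        plateau <- plateau + 1L; noImprove <- noImprove + 1L
      }
      reduced <- FALSE
      if (plateau >= cfg@plateauPatience) {
        lr <- lr * cfg@lrFactor
        plateau <- 0L
        reduced <- TRUE
      }
      stopNow <- noImprove >= cfg@earlyStopPatience
      history <- rbind(history, data.frame(
        epoch = epoch, loss = loss, accuracy = acc, lr = usedLr,
        reduced = reduced, stopped = stopNow))
      if (stopNow) break
    }
  })
  model@weights <- weights
  list(model = model, history = history)
}

poolClassCounts <- function(pred, truth, nClasses) {
  if (!is.list(pred)) pred <- list(pred)
  if (!is.list(truth)) truth <- list(truth)
  stopifnot(length(pred) == length(truth))
  inter <- pArea <- tArea <- numeric(nClasses)
  correct <- 0
  valid <- 0
  for (i in seq_along(pred)) {
    p <- as.integer(pred[[i]])
    t <- as.integer(truth[[i]])
    keep <- t != classCodes()[["ignore"]] & p != classCodes()[["ignore"]]
    p <- p[keep]; t <- t[keep]
    bad <- setdiff(unique(c(p, t)), 0:(nClasses - 1))
    if (length(bad)) stop("mask contains invalid class value(s): ",
                          paste(bad, collapse = ", "))
    valid <- valid + length(p)
    correct <- correct + sum(p == t)
    for (k in seq_len(nClasses)) {
      inter[k] <- inter[k] + sum(p == (k - 1L) & t == (k - 1L))
      pArea[k] <- pArea[k] + sum(p == (k - 1L))
      tArea[k] <- tArea[k] + sum(t == (k - 1L))
    }
  }
  list(inter = inter, pArea = pArea, tArea = tArea, correct = correct,
       valid = valid)
}

#' Segmentation metrics: per-class IoU, mean IoU, categorical accuracy
#'
#' Pixel counts are pooled over all supplied tiles, excluding ignored
#' pixels.  A class absent from both prediction and truth is excluded
#' from the mean IoU.
#'
#' @param pred,truth integer mask matrices or lists thereof.
#' @param nClasses number of classes (default 3).
#' @return List with \code{per_class_iou} (named, \code{NA} for absent
#'   classes), \code{mean_iou} and \code{categorical_accuracy}.
#' @examples
#' m <- matrix(c(0L, 1L, 2L, 0L), 2)
#' evaluateSegmentation(m, m)$mean_iou   # 1
#' @export
evaluateSegmentation <- function(pred, truth, nClasses = 3L) {
  cnt <- poolClassCounts(pred, truth, nClasses)
  if (cnt$valid == 0L) stop("no non-ignored pixels to evaluate")
  union <- cnt$pArea + cnt$tArea - cnt$inter
  iou <- ifelse(union > 0, cnt$inter / union, NA_real_)
  names(iou) <- names(classCodes())[seq_len(nClasses)]
  list(per_class_iou = iou,
       mean_iou = mean(iou, na.rm = TRUE),
       categorical_accuracy = cnt$correct / cnt$valid)
}

#' Per-class Dice coefficients
#'
#' @inheritParams evaluateSegmentation
#' @return Named numeric vector of Dice scores
#'   (\code{2|pred n truth| / (|pred| + |truth|)}; \code{NA} for classes
#'   absent from both).
#' @examples
#' m <- matrix(c(0L, 1L, 2L, 0L), 2)
#' diceScores(m, m)
#' @export
diceScores <- function(pred, truth, nClasses = 3L) {
  cnt <- poolClassCounts(pred, truth, nClasses)
  denom <- cnt$pArea + cnt$tArea
  dice <- ifelse(denom > 0, 2 * cnt$inter / denom, NA_real_)
  names(dice) <- names(classCodes())[seq_len(nClasses)]
  dice
}
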