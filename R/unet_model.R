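## Valid-convolution U-Net: weight containers, forward pass (with caches
## for backpropagation) and prediction.  Feature maps are H x W x C
## arrays; see src/unet_ops.cpp for the tensor primitives.

encChannels <- function(spec) {
  if (spec@depth == 0L) return(integer(0))
  spec@baseChannels * 2L^(seq_len(spec@depth) - 1L)
}

bottleneckChannels <- function(spec) {
  spec@baseChannels * 2L^spec@depth
}

heConv <- function(cOut, cIn, k) {
  fanIn <- cIn * k * k
  list(W = matrix(rnorm(cOut * cIn * k * k, 0, sqrt(2 / fanIn)),
                  nrow = cOut),
       b = numeric(cOut))
}

heUp <- function(cOut, cIn) {
  fanIn <- cIn * 4
  list(W = matrix(rnorm(cOut * cIn * 4, 0, sqrt(2 / fanIn)), nrow = cOut),
       b = numeric(cOut))
}

#' Build a randomly initialized U-Net
#'
#' Encoder: per level, \code{convsPerBlock} unpadded 3x3 convolutions with
#' ReLU (and element-wise dropout during training) followed by 2x2
#' max-pooling.
#' Bottleneck: the same convolution block.  Decoder: per level, 2x2
#' stride-2 transpose convolution, center-crop-and-concatenate skip from
#' the matching encoder level, then the convolution block.  Head: 1x1
#' convolution and per-pixel softmax over \code{nClasses}.  Weights use He
#' initialization under the given seed.
#'
#' @param spec a \code{\link{unetSpec}}; its geometry is validated for
#'   \code{spec@inputPx}.
#' @param seed RNG seed for weight initialization.
#' @return A \code{UNet} object.
#' @examples
#' m <- buildUnet(unetSpec(depth = 1, baseChannels = 2, inputPx = 16))
#' @export
buildUnet <- function(spec, seed = 1L) {
  stopifnot(is(spec, "UNetSpec"))
  unetGeometry(spec@inputPx, spec)  # errors propagate
  k <- spec@kernel
  ec <- encChannels(spec)
  withSeed(seed, {
    weights <- list()
    cIn <- 3L
    weights$enc <- list()
    if (spec@depth > 0L) for (l in seq_len(spec@depth)) {
      convs <- list()
      for (j in seq_len(spec@convsPerBlock)) {
        convs[[j]] <- heConv(ec[l], cIn, k)
        cIn <- ec[l]
      }
      weights$enc[[l]] <- list(convs = convs)
    }
    cb <- bottleneckChannels(spec)
    convs <- list()
    for (j in seq_len(spec@convsPerBlock)) {
      convs[[j]] <- heConv(cb, cIn, k)
      cIn <- cb
    }
    weights$bottleneck <- list(convs = convs)
    weights$dec <- list()
    if (spec@depth > 0L) for (l in rev(seq_len(spec@depth))) {
      up <- heUp(ec[l], cIn)
      cIn <- 2L * ec[l]  # skip concat
      convs <- list()
      for (j in seq_len(spec@convsPerBlock)) {
        convs[[j]] <- heConv(ec[l], cIn, k)
        cIn <- ec[l]
      }
      weights$dec[[as.character(l)]] <- list(up = up, convs = convs)
    }
    weights$head <- heConv(spec@nClasses, cIn, 1L)
    new("UNet", spec = spec, weights = weights)
  })
}

# Element-wise (inverted) dropout mask: 10% of feature-map pixels dropped,
# survivors rescaled by 1/(1-rate).
dropoutMask <- function(dims, rate) {
  m <- (runif(prod(dims)) >= rate) / (1 - rate)
  dim(m) <- dims
  m
}

convBlockFwd <- function(x, convs, k, rate, train) {
  caches <- vector("list", length(convs))
  for (j in seq_along(convs)) {
    xin <- x
    y <- conv_fwd_cpp(x, convs[[j]]$W, convs[[j]]$b, k)
    mask <- y > 0
    y[!mask] <- 0
    drop <- NULL
    if (train && rate > 0) {
      drop <- dropoutMask(dim(y), rate)
      y <- y * drop
    }
    caches[[j]] <- list(xin = xin, mask = mask, drop = drop)
    x <- y
  }
  list(out = x, caches = caches)
}

convBlockBwd <- function(dy, convs, caches, k) {
  grads <- vector("list", length(convs))
  for (j in rev(seq_along(convs))) {
    cc <- caches[[j]]
    if (!is.null(cc$drop)) dy <- dy * cc$drop
    dy[!cc$mask] <- 0
    g <- conv_bwd_cpp(cc$xin, convs[[j]]$W, dy, k)
    grads[[j]] <- list(W = g$dW, b = as.numeric(g$db))
    dy <- g$dx
  }
  list(dx = dy, grads = grads)
}

cropCenter <- function(x, size) {
  off <- (dim(x)[1] - size) %/% 2L
  x[(off + 1L):(off + size), (off + 1L):(off + size), , drop = FALSE]
}

# Full forward pass.  With train = TRUE, dropout is active (drawn from the
# current RNG stream) and all caches needed for backpropagation are kept.
unetForward <- function(model, x, train = FALSE) {
  spec <- model@spec
  k <- spec@kernel
  w <- model@weights
  cache <- list(skips = list(), enc = list(), dec = list())
  if (spec@depth > 0L) for (l in seq_len(spec@depth)) {
    bl <- convBlockFwd(x, w$enc[[l]]$convs, k, spec@dropoutRate, train)
    cache$skips[[l]] <- bl$out
    mp <- maxpool_fwd_cpp(bl$out)
    cache$enc[[l]] <- list(block = bl$caches, poolIdx = mp$idx)
    x <- mp$y
  }
  bl <- convBlockFwd(x, w$bottleneck$convs, k, spec@dropoutRate, train)
  cache$bottleneck <- bl$caches
  x <- bl$out
  if (spec@depth > 0L) for (l in rev(seq_len(spec@depth))) {
    dl <- w$dec[[as.character(l)]]
    upIn <- x
    u <- upconv_fwd_cpp(x, dl$up$W, dl$up$b)
    upMask <- u > 0
    u[!upMask] <- 0
    sk <- cropCenter(cache$skips[[l]], dim(u)[1])
    x <- array(c(sk, u), dim = c(dim(u)[1], dim(u)[2],
                                 dim(sk)[3] + dim(u)[3]))
    bl <- convBlockFwd(x, dl$convs, k, spec@dropoutRate, train)
    cache$dec[[as.character(l)]] <- list(
      upIn = upIn, upMask = upMask, concatIn = x, block = bl$caches,
      skipChannels = dim(sk)[3], upSize = dim(u)[1])
    x <- bl$out
  }
  cache$headIn <- x
  logits <- conv_fwd_cpp(x, w$head$W, w$head$b, 1L)
  mx <- apply(logits, c(1, 2), max)
  ex <- exp(sweep(logits, c(1, 2), mx, "-"))
  probs <- sweep(ex, c(1, 2), apply(ex, c(1, 2), sum), "/")
  list(probs = probs, cache = if (train) cache else NULL)
}

# Backward pass from the gradient at the logits; returns gradients with
# the same nested structure as model@weights.
unetBackward <- function(model, cache, dLogits) {
  spec <- model@spec
  k <- spec@kernel
  w <- model@weights
  grads <- list()
  g <- conv_bwd_cpp(cache$headIn, w$head$W, dLogits, 1L)
  grads$head <- list(W = g$dW, b = as.numeric(g$db))
  dy <- g$dx
  dSkip <- vector("list", spec@depth)
  grads$dec <- list()
  if (spec@depth > 0L) for (l in seq_len(spec@depth)) {
    dl <- w$dec[[as.character(l)]]
    dc <- cache$dec[[as.character(l)]]
    bb <- convBlockBwd(dy, dl$convs, dc$block, k)
    cs <- dc$skipChannels
    dSk <- bb$dx[, , seq_len(cs), drop = FALSE]
    dUp <- bb$dx[, , cs + seq_len(dim(bb$dx)[3] - cs), drop = FALSE]
    # scatter the cropped-skip gradient back into the full skip map
    full <- dim(cache$skips[[l]])[1]
    off <- (full - dc$upSize) %/% 2L
    dFull <- array(0, dim(cache$skips[[l]]))
    dFull[(off + 1L):(off + dc$upSize),
          (off + 1L):(off + dc$upSize), ] <- dSk
    dSkip[[l]] <- dFull
    dUp[!dc$upMask] <- 0
    gu <- upconv_bwd_cpp(dc$upIn, dl$up$W, dUp)
    grads$dec[[as.character(l)]] <- list(
      up = list(W = gu$dW, b = as.numeric(gu$db)), convs = bb$grads)
    dy <- gu$dx
  }
  bb <- convBlockBwd(dy, w$bottleneck$convs, cache$bottleneck, k)
  grads$bottleneck <- list(convs = bb$grads)
  dy <- bb$dx
  grads$enc <- vector("list", spec@depth)
  if (spec@depth > 0L) for (l in rev(seq_len(spec@depth))) {
    dPool <- maxpool_bwd_cpp(dy, cache$enc[[l]]$poolIdx)
    dPool <- dPool + dSkip[[l]]
    bb <- convBlockBwd(dPool, w$enc[[l]]$convs, cache$enc[[l]]$block, k)
    grads$enc[[l]] <- list(convs = bb$grads)
    dy <- bb$dx
  }
  grads
}

#' Predict the ternary mask of one tile
#'
#' Runs the network in evaluation mode (dropout off) and takes the
#' per-pixel argmax of the softmax output; ties break toward the lower
#' class index.
#'
#' @param model a trained \code{\link{buildUnet}} model.
#' @param rgbTile numeric array of side \code{spec@inputPx} (already stain
#'   normalized when a reference profile is used).
#' @return Integer matrix of side \code{\link{unetOutputSize}} with values
#'   in \code{0:(nClasses - 1)}.
#' @examples
#' sp <- unetSpec(depth = 0, baseChannels = 2, inputPx = 16)
#' m <- buildUnet(sp)
#' pred <- predictTile(m, array(runif(16 * 16 * 3), c(16, 16, 3)))
#' @export
predictTile <- function(model, rgbTile) {
  stopifnot(is(model, "UNet"))
  spec <- model@spec
  d <- dim(rgbTile)
  if (length(d) != 3L || d[1] != spec@inputPx || d[2] != spec@inputPx ||
      d[3] != 3L)
    stop("tile must be ", spec@inputPx, " x ", spec@inputPx, " x 3")
  probs <- unetForward(model, rgbTile, train = FALSE)$probs
  K <- dim(probs)[3]
  idx <- max.col(matrix(probs, ncol = K), ties.method = "first")
  matrix(as.integer(idx - 1L), dim(probs)[1], dim(probs)[2])
}

#' Segment a whole slide with the overlapping-tile strategy
#'
#' Plans the tile grid over the ROI, extracts mirror-padded input windows,
#' optionally Macenko-normalizes each to a reference profile, predicts
#' each tile and stitches the results into a slide-level classification
#' map with the ignore sentinel outside the ROI.
#'
#' @param model a \code{UNet}.
#' @param slideImage RGB slide array.
#' @param roiPolygon ROI polygon.
#' @param spec a \code{\link{tileSpec}} consistent with the model geometry.
#' @param reference optional reference \code{\link{stainProfile}}; when
#'   given, each input window is normalized to it (windows whose stain
#'   profile cannot be estimated are passed through unnormalized).
#' @return Integer slide mask (classes inside ROI, 255 outside).
#' @examples
#' ## see the package vignette for an end-to-end example
#' @export
segmentSlide <- function(model, slideImage, roiPolygon, spec = tileSpec(),
                         reference = NULL) {
  stopifnot(is(model, "UNet"))
  if (unetOutputSize(spec@inputPx, model@spec) != spec@outputPx)
    stop("tileSpec output size does not match the model geometry")
  slideDim <- dim(slideImage)[1:2]
  coords <- planTiles(roiPolygon, spec, slideDim)
  masks <- vector("list", nrow(coords))
  for (i in seq_len(nrow(coords))) {
    win <- extractInputWindow(slideImage, coords[i, ], spec)
    if (!is.null(reference)) {
      src <- tryCatch(estimateStainProfile(win), error = function(e) NULL)
      if (!is.null(src)) win <- normalizeTile(win, src, reference)
    }
    masks[[i]] <- predictTile(model, win)
  }
  stitchTiles(masks, coords, roiPolygon, spec, slideDim)
}
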