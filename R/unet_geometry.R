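## Shrinkage arithmetic of the valid-convolution U-Net.  Every unpadded
## k x k convolution loses (k - 1) pixels per spatial dimension; 2x2
## pooling halves (and therefore requires an even size); 2x transpose
## convolution doubles; each skip connection center-crops the encoder
## feature map to the decoder size (requiring an even size difference).

#' Trace the spatial geometry of a valid-convolution U-Net
#'
#' Walks the network stage by stage and records the spatial size after
#' every block, raising a geometry error naming the offending stage if any
#' intermediate size becomes non-positive, odd before pooling, or
#' incompatible with a centered skip crop.
#'
#' @param inputPx input tile side in pixels.
#' @param spec a \code{\link{unetSpec}}.
#' @return \code{data.frame} with columns \code{stage} and \code{size};
#'   rows \code{enc<l>} give encoder post-block sizes (before pooling),
#'   \code{up<l>} decoder sizes after upsampling (also the skip crop
#'   size), \code{dec<l>} decoder post-block sizes, and \code{output} the
#'   final size.
#' @examples
#' unetGeometry(396, unetSpec())
#' @export
unetGeometry <- function(inputPx, spec) {
  stopifnot(is(spec, "UNetSpec"))
  shrink <- spec@convsPerBlock * (spec@kernel - 1L)
  s <- as.integer(inputPx)
  if (s <= 0L) stop("geometry error at input: non-positive size")
  stages <- data.frame(stage = "input", size = s)
  encSize <- integer(spec@depth)
  if (spec@depth > 0L) for (l in seq_len(spec@depth)) {
    s <- s - shrink
    if (s <= 0L)
      stop("geometry error at encoder level ", l,
           ": size ", s, " after convolutions")
    encSize[l] <- s
    stages <- rbind(stages, data.frame(stage = paste0("enc", l), size = s))
    if (s %% 2L != 0L)
      stop("geometry error at encoder level ", l,
           ": odd size ", s, " before pooling")
    s <- s %/% 2L
  }
  s <- s - shrink
  if (s <= 0L)
    stop("geometry error at bottleneck: size ", s, " after convolutions")
  stages <- rbind(stages, data.frame(stage = "bottleneck", size = s))
  if (spec@depth > 0L) for (l in rev(seq_len(spec@depth))) {
    s <- s * 2L
    if (encSize[l] < s)
      stop("geometry error at decoder level ", l, ": skip feature (",
           encSize[l], ") smaller than upsampled size (", s, ")")
    if ((encSize[l] - s) %% 2L != 0L)
      stop("geometry error at decoder level ", l,
           ": skip crop margin not symmetric (", encSize[l], " vs ", s, ")")
    stages <- rbind(stages, data.frame(stage = paste0("up", l), size = s))
    s <- s - shrink
    if (s <= 0L)
      stop("geometry error at decoder level ", l,
           ": size ", s, " after convolutions")
    stages <- rbind(stages, data.frame(stage = paste0("dec", l), size = s))
  }
  stages <- rbind(stages, data.frame(stage = "output", size = s))
  rownames(stages) <- NULL
  stages
}

#' Output tile size of the U-Net for a given input size
#'
#' @inheritParams unetGeometry
#' @return Integer output side in pixels (212 for the default 396-pixel
#'   input with depth 4 and two 3x3 convolutions per block).
#' @examples
#' unetOutputSize(396, unetSpec())   # 212
#' unetOutputSize(572, unetSpec())   # 388
#' @export
unetOutputSize <- function(inputPx, spec = unetSpec()) {
  g <- unetGeometry(inputPx, spec)
  as.integer(g$size[g$stage == "output"])
}
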