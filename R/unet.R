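#' @include AllClasses.R
NULL

#' Network configuration for the attention U-Net
#'
#' Four encoder blocks (each: two 3x3 convolutions with batch-norm and
#' ReLU) connected by 2x2 max-pooling, a bottleneck block, and four
#' decoder blocks with bilinear x2 upsampling; filter counts double per
#' encoder stage from `baseFilters` and halve per decoder stage; each of
#' the four skip connections passes through an attention gate.  Input
#' height and width must be divisible by `2^depth`.
#'
#' @param baseFilters filters of the first encoder stage (default 16; 64
#'   gives full-scale parity, 8 a desk-scale model).
#' @param depth number of encoder/decoder stages (default 4).
#' @param inChannels input channels (1 for grayscale slices).
#' @param bilinearUpsampling must be TRUE (bilinear x2 upsampling is the
#'   implemented decoder expansion).
#' @return a list of class `"modelConfig"`.
#' @export
modelConfig <- function(baseFilters = 16L, depth = 4L, inChannels = 1L,
                        bilinearUpsampling = TRUE) {
  stopifnot(baseFilters >= 1, depth >= 1, inChannels >= 1)
  if (!isTRUE(bilinearUpsampling))
    stop("only bilinear upsampling is implemented")
  structure(list(baseFilters = as.integer(baseFilters),
                 depth = as.integer(depth),
                 inChannels = as.integer(inChannels),
                 bilinearUpsampling = TRUE),
            class = "modelConfig")
}

#' Initialise an attention U-Net
#'
#' He-normal initialisation of all convolution kernels, unit batch-norm
#' scale; deterministic for a given seed.
#'
#' @param config a [modelConfig()].
#' @param seed integer RNG seed for the initialisation.
#' @return an [AttentionUNet-class].
#' @export
unetCreate <- function(config = modelConfig(), seed = 1L) {
  stopifnot(inherits(config, "modelConfig"))
  params <- cpp_unet_init(config$baseFilters, config$depth,
                          config$inChannels, as.integer(seed))
  new("AttentionUNet", config = unclass(config), params = params,
      history = data.frame(), bestEpoch = NA_integer_)
}

setMethod("show", "AttentionUNet", function(object) {
  cfg <- object@config
  st <- countStages(object)
  cat(sprintf("AttentionUNet: depth %d, base filters %d (encoder %s; bottleneck %d)\n",
              cfg$depth, cfg$baseFilters,
              paste(st$encoderFilters, collapse = "-"), st$bottleneckFilters))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs; best epoch %d (val Jaccard %.1f%%)\n",
                nrow(object@history), object@bestEpoch,
                object@history$val_jaccard[object@bestEpoch]))
  else cat("  untrained\n")
})

#' Stage structure of a model
#'
#' @param model an [AttentionUNet-class].
#' @return list with `encoderStages`, `decoderStages`, `encoderFilters`
#'   (doubling from the base), `decoderFilters` (halving back) and
#'   `bottleneckFilters`.
#' @export
countStages <- function(model) {
  stopifnot(is(model, "AttentionUNet"))
  F <- model@config$baseFilters; d <- model@config$depth
  list(encoderStages = d, decoderStages = d,
       encoderFilters = F * 2^(seq_len(d) - 1L),
       decoderFilters = rev(F * 2^(seq_len(d) - 1L)),
       bottleneckFilters = F * 2^d)
}

#' Forward pass of the network
#'
#' @param model an [AttentionUNet-class].
#' @param batch numeric array of dim `(H, W, N)`: N single-channel
#'   slices.  H and W must be divisible by `2^depth` (checked before any
#'   computation).
#' @param gatesOn FALSE bypasses the attention gates (plain U-Net path,
#'   skip passed unweighted).
#' @param returnAlphas also return the per-gate attention coefficient
#'   arrays (each of dim `(h, w, 1, N)` at its skip resolution, values
#'   strictly inside (0,1)).
#' @param alphaOverride if finite, every attention coefficient is forced
#'   to this constant (1 reduces the gated network to the plain U-Net).
#' @return probability array of dim `(H, W, N)` with values in \[0, 1\],
#'   or (with `returnAlphas`) a list `probs`, `alphas`.  Deterministic in
#'   evaluation mode; batch-norm uses running statistics, so each sample
#'   is processed independently.
#' @export
unetForward <- function(model, batch, gatesOn = TRUE, returnAlphas = FALSE,
                        alphaOverride = NA_real_) {
  stopifnot(is(model, "AttentionUNet"))
  d <- dim(batch)
  if (is.null(d) || length(d) != 3L)
    stop("batch must be an array of dim (H, W, N)")
  div <- 2^model@config$depth
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop(sprintf("input %d x %d not divisible by 2^depth = %d", d[1], d[2], div))
  res <- cpp_unet_forward(model@params, batch, gatesOn, returnAlphas,
                          alphaOverride)
  if (returnAlphas) res else res$probs
}

#' Attention gate on a skip connection
#'
#' The gate combines a skip-path input signal of shape `(2h, 2w, Cx, N)`
#' with a coarser gating signal `(h, w, F, N)`: a 1x1 stride-2
#' convolution on the input and a 1x1 convolution on the gating signal
#' (both to F channels) are added, passed through ReLU, projected to one
#' channel by a third 1x1 convolution, squashed by a sigmoid and
#' bilinearly upsampled x2 to give the attention coefficient map
#' `alpha` of shape `(2h, 2w, 1, N)` with entries in (0, 1); the output
#' is `alpha * input` broadcast over channels.
#'
#' @param inputSignal numeric array `(2h, 2w, Cx, N)`.
#' @param gatingSignal numeric array `(h, w, Cg, N)`.
#' @param params list with `Wx (1,1,Cx,F)`, `bx (F)`, `Wg (1,1,Cg,F)`,
#'   `bg (F)`, `Wpsi (1,1,F,1)`, `bpsi (1)`; see [attentionGateParams()].
#' @return list with `output` (same shape as `inputSignal`) and `alpha`.
#' @examples
#' p <- attentionGateParams(Cx = 2, Cg = 4, Fint = 4)   # zero weights
#' x <- array(rnorm(8 * 16 * 2 * 3), c(8, 16, 2, 3))
#' g <- array(rnorm(4 * 8 * 4 * 3), c(4, 8, 4, 3))
#' r <- attentionGate(x, g, p)
#' all(r$alpha == 0.5)    # sigmoid(0): gate half-open everywhere
#' @export
attentionGate <- function(inputSignal, gatingSignal, params) {
  stopifnot(length(dim(inputSignal)) == 4L, length(dim(gatingSignal)) == 4L)
  cpp_attention_gate(inputSignal, gatingSignal,
                     params$Wx, params$bx, params$Wg, params$bg,
                     params$Wpsi, params$bpsi)
}

#' Parameters for a standalone attention gate
#'
#' @param Cx input-signal channels; `Cg` gating channels; `Fint`
#'   intermediate channels.
#' @param Cg,Fint see above.
#' @param seed if not NULL, He-normal random weights; default all-zero
#'   weights (which give alpha = 0.5 everywhere).
#' @return parameter list for [attentionGate()].
#' @export
attentionGateParams <- function(Cx, Cg, Fint, seed = NULL) {
  mk <- function(ci, co) {
    w <- array(0, c(1, 1, ci, co))
    if (!is.null(seed)) {
      w[] <- withSeed(seed + ci * 131L + co, stats::rnorm(ci * co, 0, sqrt(2 / ci)))
    }
    w
  }
  list(Wx = mk(Cx, Fint), bx = numeric(Fint),
       Wg = mk(Cg, Fint), bg = numeric(Fint),
       Wpsi = mk(Fint, 1), bpsi = numeric(1))
}

#' Save or load a model checkpoint
#'
#' The checkpoint embeds the configuration, parameters (including
#' batch-norm running statistics and optimiser state), history and
#' selected epoch.
#'
#' @param model an [AttentionUNet-class].
#' @param path checkpoint file path (RDS).
#' @return `loadModel()`: the restored [AttentionUNet-class].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "AttentionUNet"))
  saveRDS(list(config = model@config, params = model@params,
               history = model@history, bestEpoch = model@bestEpoch), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  new("AttentionUNet", config = x$config, params = x$params,
      history = x$history, bestEpoch = x$bestEpoch)
}
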