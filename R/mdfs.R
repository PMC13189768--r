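# Multi-scale Difference Fusion Stem (MDFS).
#
# The stem turns a clip into four parallel streams -- the original frames X
# and the s-frame differences D1, D2, D3 (zero-padded over the first s
# frames) -- pushes each through its own two-conv downsampling branch
# (stride-2 x 2, so H/4 x W/4), regularizes with spatial dropout, fuses the
# streams with learnable softmax weights and applies a final ReLU.

#' Multi-scale frame differencing
#'
#' For each temporal scale `s`, computes the `s`-frame difference
#' `D_s[t] = X[t] - X[t - s]` for `t >= s`, with the first `s` frames set to
#' zero so all streams stay temporally aligned.  The original stream is
#' returned unmodified as the first element.
#'
#' @param clip a [frame_clip()] (or bare `D x C x H x W` array).
#' @param scales positive integer scales, each `< D` (default `1:3`).
#' @return A `diff_stack`: list with element `streams`, a list of
#'   `1 + length(scales)` arrays named `"x"`, `"d1"`, `"d2"`, ...
#' @export
multi_scale_difference <- function(clip, scales = 1:3) {
  frames <- if (inherits(clip, "frame_clip")) clip$frames else clip
  stopifnot(length(dim(frames)) == 4)
  d <- dim(frames)[1]
  scales <- as.integer(scales)
  if (any(scales < 1)) stop("multi_scale_difference: scales must be >= 1")
  if (max(scales) >= d)
    stop("multi_scale_difference: scale must be smaller than clip length D")
  streams <- vector("list", 1 + length(scales))
  names(streams) <- c("x", paste0("d", scales))
  streams[["x"]] <- frames
  for (i in seq_along(scales)) {
    s <- scales[i]
    delta <- array(0, dim = dim(frames))
    idx <- (s + 1):d
    delta[idx, , , ] <- frames[idx, , , , drop = FALSE] -
      frames[idx - s, , , , drop = FALSE]
    streams[[i + 1]] <- delta
  }
  structure(list(streams = streams, scales = scales), class = "diff_stack")
}

# Batched differencing on the internal (C, H, W, B) layout; positions are
# frame indices within each clip (clip frames contiguous along B).
# Implemented on a flat (C*H*W) x B view for speed.
batch_diff <- function(x, d_per_clip, s) {
  d <- dim(x)
  delta <- batch_diff_cpp(x, prod(d[1:3]), d[4], d_per_clip, s)
  dim(delta) <- d
  delta
}

# Adjoint of batch_diff: given the gradient of the s-frame difference
# stream, scatter back onto the input frames.
batch_diff_adj <- function(dstream, d_per_clip, s) {
  d <- dim(dstream)
  dx <- batch_diff_adj_cpp(dstream, prod(d[1:3]), d[4], d_per_clip, s)
  dim(dx) <- d
  dx
}

#' Initialize stem parameters
#'
#' Each of the four streams gets an independent convolutional branch:
#' conv 3x3 stride 2 (C -> c_mid) -> batch norm -> ReLU -> conv 3x3 stride 2
#' (c_mid -> c_mid), so spatial dims shrink to `H/4 x W/4`.  The four fusion
#' logits start at zero (uniform softmax weights).
#'
#' @param c_in input channels, `c_mid` intermediate width, `scales` the
#'   difference scales (`1:3` by default), `dropout` spatial dropout rate.
#' @return A list with `params` (trainable) and `state` (batch-norm running
#'   statistics), plus the architecture constants as attributes.
#' @keywords internal
stem_init <- function(c_in, c_mid, scales = 1:3, dropout = 0.1) {
  n_streams <- 1 + length(scales)
  branches <- lapply(seq_len(n_streams), function(i) {
    b <- list(conv1 = conv_init(c_in, c_mid, 3),
              bn1 = bn_init(c_mid),
              conv2 = conv_init(c_mid, c_mid, 3))
    # Low-pass passthrough channel: the first channel of conv1 starts as a
    # spatial averaging kernel and conv2 forwards it with a center tap, so
    # the stream's local mean intensity is represented from the first step.
    # On the difference streams this channel is pulse-dominated (slow
    # illumination drift is suppressed by differencing), which makes the
    # waveform learnable long before the random filters specialize.
    # The channel is kept in the ReLUs' linear region at init (positive
    # batch-norm shift and conv bias): rectifying a zero-mean map would
    # break the near-cancellation of motion-jitter edge flicker under
    # global pooling and bury the pulse under in-band motion noise.
    b$conv1$W[1, ] <- 1 / (c_in * 9)
    b$bn1$beta[1] <- 2
    b$conv2$W[1, ] <- 0
    b$conv2$W[1, 4 * c_mid + 1] <- 1  # center tap (kh=kw=1) of channel 1
    b$conv2$b[1] <- 2
    b
  })
  names(branches) <- c("b0", paste0("b", scales))
  states <- lapply(seq_len(n_streams), function(i) bn_state_init(c_mid))
  names(states) <- names(branches)
  list(params = list(branches = branches, logits = numeric(n_streams)),
       state = states,
       scales = scales, c_mid = c_mid, dropout = dropout)
}

#' Run one convolutional branch of the stem
#'
#' @param stream a `D x C x H x W` array (one stream of a clip) or an
#'   internal `(C, H, W, B)` tensor.
#' @param branch one element of the stem's `branches` parameter list.
#' @param bn_state batch-norm running statistics for this branch.
#' @param training logical; batch statistics are used (and running stats
#'   updated) only in training mode.
#' @return A list with `out` (`c_mid x H/4 x W/4` features per frame, as a
#'   `(c_mid, H/4, W/4, B)` array), updated `state`, and an internal cache.
#' @export
branch_forward <- function(stream, branch, bn_state = NULL, training = FALSE) {
  stopifnot(length(dim(stream)) == 4)
  # user-facing layout is D x C x H x W; internal tensors are (C, H, W, B)
  x <- if (isTRUE(attr(stream, "internal"))) stream
       else aperm(stream, c(2, 3, 4, 1))
  dims <- dim(x)
  if (dims[2] %% 4 != 0 || dims[3] %% 4 != 0)
    stop("branch_forward: spatial dims must be divisible by 4")
  if (is.null(bn_state)) bn_state <- bn_state_init(length(branch$bn1$gamma))
  c1 <- conv2d_fw(x, branch$conv1, k = 3, stride = 2, pad = 1)
  b1 <- bn2d_fw(c1$out, branch$bn1, bn_state, training)
  r1 <- relu_fw(b1$out)
  c2 <- conv2d_fw(r1$out, branch$conv2, k = 3, stride = 2, pad = 1)
  list(out = c2$out, state = b1$state,
       cache = list(c1 = c1, b1 = b1, r1 = r1, c2 = c2))
}

branch_backward <- function(dout, branch, cache) {
  c2b <- conv2d_bw(dout, branch$conv2, cache$c2$cache)
  r1b <- relu_bw(c2b$dx, cache$r1$cache)
  b1b <- bn2d_bw(r1b, branch$bn1, cache$b1$cache)
  c1b <- conv2d_bw(b1b$dx, branch$conv1, cache$c1$cache)
  list(dx = c1b$dx,
       grads = list(conv1 = c1b$grads, bn1 = b1b$grads, conv2 = c2b$grads))
}

#' Spatial channel dropout
#'
#' In training mode each channel's entire spatial map (per frame) is zeroed
#' independently with probability `rate`, and surviving channels are scaled
#' by `1/(1 - rate)` so evaluation needs no rescaling.  In eval mode the
#' input passes through unchanged.
#'
#' @param features a `(C, H, W, B)` array (or any 4-D array whose first and
#'   last dims are channel and frame).
#' @param rate dropout probability in `[0, 1)`.
#' @param training logical.
#' @param seed optional seed for a reproducible mask.
#' @return Array of the same shape.
#' @export
channel_dropout <- function(features, rate, training = TRUE, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("channel_dropout: rate must be in [0, 1)")
  run <- function() dropout2d_fw(features, rate, training)$out
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Softmax fusion weights over the four streams
#'
#' `w_i = exp(l_i) / sum_j exp(l_j)`, computed with max subtraction so that
#' large-magnitude logits cannot overflow.
#'
#' @param logits finite numeric vector (length 4 for the standard stem).
#' @return Weights summing to 1, each in `(0, 1)`.
#' @export
fusion_weights <- function(logits) {
  if (any(!is.finite(logits))) stop("fusion_weights: logits must be finite")
  z <- exp(logits - max(logits))
  z / sum(z)
}

#' Fuse stream features and apply the output ReLU
#'
#' Computes `ReLU(sum_i w_i * f_i)` elementwise.
#'
#' @param stream_features list of equally-shaped feature arrays.
#' @param weights numeric weights, one per stream.
#' @return Fused, rectified feature array.
#' @export
fuse_and_activate <- function(stream_features, weights) {
  stopifnot(length(stream_features) == length(weights))
  dims <- lapply(stream_features, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("fuse_and_activate: stream shapes must match")
  acc <- stream_features[[1]] * weights[1]
  for (i in seq_along(stream_features)[-1])
    acc <- acc + stream_features[[i]] * weights[i]
  relu_fw(acc)$out
}

# Full stem forward on the internal (C, H, W, B) tensor.
# mode: "full" (learnable softmax fusion), "original_only", or "fixed"
# (constant weights supplied in fixed_weights).
stem_forward <- function(x, d_per_clip, stem, training = FALSE,
                         mode = "full", fixed_weights = NULL) {
  params <- stem$params
  scales <- stem$scales
  n_streams <- 1 + length(scales)
  if (mode == "fixed") {
    if (is.null(fixed_weights) || length(fixed_weights) != n_streams ||
        abs(sum(fixed_weights) - 1) > 1e-8)
      stop("stem_forward: fixed weights must sum to 1 (one per stream)")
  }
  if (max(scales) >= d_per_clip)
    stop("stem_forward: difference scale must be < clip length")

  if (mode == "original_only") {
    br <- branch_forward(structure(x, internal = TRUE), params$branches[[1]],
                         stem$state[[1]], training)
    dp <- dropout2d_fw(br$out, stem$dropout, training)
    rl <- relu_fw(dp$out)
    stem$state[[1]] <- br$state
    return(list(out = rl$out, stem = stem,
                cache = list(mode = mode, br = list(br), dp = list(dp),
                             relu = rl$cache)))
  }

  streams <- vector("list", n_streams)
  streams[[1]] <- x
  for (i in seq_along(scales))
    streams[[i + 1]] <- batch_diff(x, d_per_clip, scales[i])

  brs <- vector("list", n_streams)
  dps <- vector("list", n_streams)
  feats <- vector("list", n_streams)
  for (i in seq_len(n_streams)) {
    brs[[i]] <- branch_forward(structure(streams[[i]], internal = TRUE),
                               params$branches[[i]], stem$state[[i]], training)
    stem$state[[i]] <- brs[[i]]$state
    dps[[i]] <- dropout2d_fw(brs[[i]]$out, stem$dropout, training)
    feats[[i]] <- dps[[i]]$out
  }
  w <- if (mode == "fixed") fixed_weights else fusion_weights(params$logits)
  acc <- feats[[1]] * w[1]
  for (i in 2:n_streams) acc <- acc + feats[[i]] * w[i]
  rl <- relu_fw(acc)
  list(out = rl$out, stem = stem,
       cache = list(mode = mode, br = brs, dp = dps, feats = feats, w = w,
                    relu = rl$cache, scales = scales, d_per_clip = d_per_clip))
}

stem_backward <- function(dout, stem, cache) {
  params <- stem$params
  dacc <- relu_bw(dout, cache$relu)
  gb <- vector("list", length(params$branches))
  names(gb) <- names(params$branches)
  dlogits <- numeric(length(params$logits))

  if (cache$mode == "original_only") {
    ddp <- dropout2d_bw(dacc, cache$dp[[1]]$cache)
    bb <- branch_backward(ddp, params$branches[[1]], cache$br[[1]]$cache)
    dx <- bb$dx
    gb[[1]] <- bb$grads
    for (i in seq_along(gb)[-1])
      gb[[i]] <- tree_zeros_like(params$branches[[i]])
    return(list(dx = dx,
                grads = list(branches = gb, logits = dlogits)))
  }

  w <- cache$w
  n_streams <- length(w)
  dx <- NULL
  dfeat_dot <- numeric(n_streams)
  scales <- cache$scales
  for (i in seq_len(n_streams)) {
    dfeat <- dacc * w[i]
    dfeat_dot[i] <- sum(dacc * cache$feats[[i]])
    ddp <- dropout2d_bw(dfeat, cache$dp[[i]]$cache)
    bb <- branch_backward(ddp, params$branches[[i]], cache$br[[i]]$cache)
    gb[[i]] <- bb$grads
    dstream <- bb$dx
    # adjoint of the differencing: stream i>1 is x[t] - x[t-s]
    dxi <- if (i == 1) dstream
           else batch_diff_adj(dstream, cache$d_per_clip, scales[i - 1])
    dx <- if (is.null(dx)) dxi else dx + dxi
  }
  if (cache$mode == "full") {
    # d softmax: dl_i = w_i * (g_i - sum_j w_j g_j), g_i = <dacc, feats_i>
    dlogits <- w * (dfeat_dot - sum(w * dfeat_dot))
  }
  list(dx = dx, grads = list(branches = gb, logits = dlogits))
}

#' Run the multi-scale difference fusion stem on a clip batch
#'
#' Composes differencing, per-stream convolutional branches, spatial
#' dropout, softmax-weighted fusion and the output ReLU.  Three modes cover
#' the stem ablations: `"full"` (learnable fusion), `"original_only"` (only
#' the raw-frame branch) and `"fixed"` (constant fusion weights).
#'
#' @param batch a [clip_batch()].
#' @param stem a stem parameter bundle from `stem_init()` (built
#'   automatically when `NULL`, seeded by `seed`).
#' @param mode `"full"`, `"original_only"` or `"fixed"`.
#' @param fixed_weights constant weights (must sum to 1) for `mode="fixed"`.
#' @param training logical; enables batch statistics and dropout.
#' @param seed seed for parameter init / dropout reproducibility.
#' @return List with `features` (`(c_mid, H/4, W/4, B)` array) and `stem`
#'   (parameter bundle with updated batch-norm state).
#' @export
mdfs_forward <- function(batch, stem = NULL,
                         mode = c("full", "original_only", "fixed"),
                         fixed_weights = NULL, training = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(batch, "clip_batch"))
  s <- batch$shape
  if (s[3] %% 4 != 0 || s[4] %% 4 != 0)
    stop("mdfs_forward: spatial dims must be divisible by 4")
  if (is.null(stem))
    stem <- with_seed(seed, stem_init(s[2], c_mid = 16L))
  x <- batch_tensor(batch)
  res <- with_seed(derive_seed(seed, 977L),
                   stem_forward(x, batch$d, stem, training, mode, fixed_weights))
  list(features = res$out, stem = res$stem)
}
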