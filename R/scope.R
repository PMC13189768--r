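# Spatial-Channel Optimized Pulse Enhancement (SCOPE).
#
# A frame-level refinement block: spatial-aware channel attention (a shared
# two-layer MLP applied to the channel vector at every spatial location,
# terminal sigmoid), large-kernel spatial attention (two 7x7 convs with
# batch norm + ReLU, channel-preserving), and an adaptive channel gate
# (global average pooling -> 1x1 conv -> ReLU -> 1x1 conv -> sigmoid) that
# modulates a residual fusion: Xhat = g * Xspa + X.
#
# Variants implement the ablation contract: "channel_only", "spatial_only",
# "no_gate", and "cbam" (the standard sequential channel-then-spatial
# attention reference block, kept behind the same residual insertion).

scope_variants <- c("full", "cbam", "channel_only", "spatial_only", "no_gate")

#' Initialize SCOPE parameters
#'
#' @param c feature channels; must be divisible by `reduction`.
#' @param reduction bottleneck ratio `r` shared by the channel MLP and the
#'   gate (default 8).
#' @param variant one of `"full"`, `"cbam"`, `"channel_only"`,
#'   `"spatial_only"`, `"no_gate"`.
#' @param spatial_sigmoid add a terminal sigmoid to the spatial map (off by
#'   default: the block's spatial attention is BN+ReLU only, unbounded
#'   above).
#' @return List with `params`, batch-norm `state`, and settings.
#' @keywords internal
scope_init <- function(c, reduction = 8L, variant = "full",
                       spatial_sigmoid = FALSE) {
  variant <- match.arg(variant, scope_variants)
  if (variant != "cbam" && c %% reduction != 0)
    stop("scope_init: channels must be divisible by the reduction ratio")
  cr <- max(1L, c %/% reduction)
  params <- list()
  state <- list()
  if (variant %in% c("full", "channel_only", "no_gate")) {
    params$mlp <- list(fc1 = linear_init(c, cr), fc2 = linear_init(cr, c))
  }
  if (variant %in% c("full", "spatial_only", "no_gate")) {
    params$spa <- list(conv1 = conv_init(c, c, 7), bn1 = bn_init(c),
                       conv2 = conv_init(c, c, 7), bn2 = bn_init(c))
    state$bn1 <- bn_state_init(c)
    state$bn2 <- bn_state_init(c)
  }
  if (variant %in% c("full", "channel_only", "spatial_only")) {
    params$gate <- list(fc1 = linear_init(c, cr), fc2 = linear_init(cr, c))
    # start with the gate nearly closed (g ~ 0.05): the residual path then
    # dominates until the refinement branch has learned something useful,
    # the same bias convention as highway-style gated residual units
    params$gate$fc2$b[] <- -3
  }
  if (variant == "cbam") {
    params$mlp <- list(fc1 = linear_init(c, cr), fc2 = linear_init(cr, c))
    params$spa <- list(conv = conv_init(2L, 1L, 7))
  }
  list(params = params, state = state, variant = variant, c = c,
       reduction = reduction, spatial_sigmoid = spatial_sigmoid)
}

#' Spatial-aware channel attention
#'
#' The channel vector at every spatial location is passed through a shared
#' two-layer bottleneck MLP (`C -> C/r -> C`, ReLU between, sigmoid at the
#' end), yielding a per-location channel attention map in `(0, 1)` that
#' multiplies the input.
#'
#' @param x `(C, H, W, B)` feature array.
#' @param scope a bundle from `scope_init()` (or a bare `mlp` parameter
#'   list).
#' @return List with `a_chan` (attention map), `x_chan` (`x * a_chan`) and
#'   an internal cache.
#' @export
channel_attention <- function(x, scope) {
  mlp <- if (!is.null(scope$params)) scope$params$mlp else scope$mlp
  d <- dim(x)
  xm <- matrix(x, d[1])                # C x (H*W*B): every column a location
  f1 <- linear_fw(xm, mlp$fc1)
  r1 <- relu_fw(f1$out)
  f2 <- linear_fw(r1$out, mlp$fc2)
  a <- sigmoid(f2$out)
  am <- a; dim(am) <- d
  xc <- x * am
  list(a_chan = am, x_chan = xc,
       cache = list(x = x, f1 = f1, r1 = r1, f2 = f2, a = a, dim = d))
}

channel_attention_bw <- function(dxc, da_extra, mlp, cache) {
  # dxc: grad wrt x_chan; da_extra: optional grad wrt a_chan from elsewhere
  d <- cache$dim
  da <- cache$x * dxc
  if (!is.null(da_extra)) da <- da + da_extra
  dam <- matrix(da, d[1]) * cache$a * (1 - cache$a)   # sigmoid'
  f2b <- linear_bw(dam, mlp$fc2, cache$f2$cache)
  r1b <- relu_bw(f2b$dx, cache$r1$cache)
  f1b <- linear_bw(r1b, mlp$fc1, cache$f1$cache)
  am <- cache$a; dim(am) <- d
  dx <- dxc * am + array(f1b$dx, dim = d)
  list(dx = dx, grads = list(fc1 = f1b$grads, fc2 = f2b$grads))
}

#' Large-kernel spatial attention
#'
#' Two consecutive channel-preserving 7x7 convolutions (padding 3) with
#' batch normalization and ReLU produce a nonnegative per-channel spatial
#' map that multiplies the channel-refined features.
#'
#' @param x_chan `(C, H, W, B)` array (normally the channel-refined
#'   features).
#' @param scope bundle from `scope_init()`.
#' @param training logical (batch-norm mode).
#' @return List with `a_spa`, `x_spa`, updated `state`, cache.
#' @export
spatial_attention <- function(x_chan, scope, training = FALSE) {
  p <- scope$params$spa
  st <- scope$state
  c1 <- conv2d_fw(x_chan, p$conv1, k = 7, stride = 1, pad = 3)
  b1 <- bn2d_fw(c1$out, p$bn1, st$bn1, training)
  r1 <- relu_fw(b1$out)
  c2 <- conv2d_fw(r1$out, p$conv2, k = 7, stride = 1, pad = 3)
  b2 <- bn2d_fw(c2$out, p$bn2, st$bn2, training)
  r2 <- relu_fw(b2$out)
  a <- r2$out
  sg <- NULL
  if (isTRUE(scope$spatial_sigmoid)) {
    sg <- sigmoid(a)
    a <- sg
  }
  xs <- x_chan * a
  st$bn1 <- b1$state; st$bn2 <- b2$state
  list(a_spa = a, x_spa = xs, state = st,
       cache = list(x_chan = x_chan, c1 = c1, b1 = b1, r1 = r1, c2 = c2,
                    b2 = b2, r2 = r2, sg = sg, a = a))
}

spatial_attention_bw <- function(dxs, da_extra, scope, cache) {
  p <- scope$params$spa
  da <- cache$x_chan * dxs
  if (!is.null(da_extra)) da <- da + da_extra
  dxc_direct <- dxs * cache$a
  if (!is.null(cache$sg)) da <- da * cache$sg * (1 - cache$sg)
  dr2 <- relu_bw(da, cache$r2$cache)
  b2b <- bn2d_bw(dr2, p$bn2, cache$b2$cache)
  c2b <- conv2d_bw(b2b$dx, p$conv2, cache$c2$cache)
  dr1 <- relu_bw(c2b$dx, cache$r1$cache)
  b1b <- bn2d_bw(dr1, p$bn1, cache$b1$cache)
  c1b <- conv2d_bw(b1b$dx, p$conv1, cache$c1$cache)
  list(dx = dxc_direct + c1b$dx,
       grads = list(conv1 = c1b$grads, bn1 = b1b$grads,
                    conv2 = c2b$grads, bn2 = b2b$grads))
}

#' Adaptive channel gate
#'
#' Global average pooling over space followed by two 1x1 convolutions
#' (a channel bottleneck) with ReLU and sigmoid produces a per-channel,
#' per-frame gating coefficient in `(0, 1)`.
#'
#' @param x_spa `(C, H, W, B)` array to pool.
#' @param scope bundle from `scope_init()` (or bare `gate` params).
#' @return List with `g` (`C x B` matrix of gate values) and cache.
#' @export
scope_gate <- function(x_spa, scope) {
  gp <- if (!is.null(scope$params)) scope$params$gate else scope$gate
  d <- dim(x_spa)
  hw <- d[2] * d[3]
  x3 <- array(x_spa, dim = c(d[1], hw, d[4]))
  pooled <- matrix(0, d[1], d[4])
  for (j in seq_len(hw)) pooled <- pooled + x3[, j, ]
  pooled <- pooled / hw
  if (d[4] == 1) dim(pooled) <- c(d[1], 1)
  f1 <- linear_fw(pooled, gp$fc1)
  r1 <- relu_fw(f1$out)
  f2 <- linear_fw(r1$out, gp$fc2)
  g <- sigmoid(f2$out)
  list(g = g, cache = list(f1 = f1, r1 = r1, f2 = f2, g = g,
                           dim = d, hw = hw))
}

scope_gate_bw <- function(dg, gp, cache) {
  d <- cache$dim
  dpre <- dg * cache$g * (1 - cache$g)
  f2b <- linear_bw(dpre, gp$fc2, cache$f2$cache)
  r1b <- relu_bw(f2b$dx, cache$r1$cache)
  f1b <- linear_bw(r1b, gp$fc1, cache$f1$cache)
  dpool <- f1b$dx / cache$hw               # C x B
  dx <- aperm(array(dpool, dim = c(d[1], d[4], d[2], d[3])), c(1, 3, 4, 2))
  list(dx = dx, grads = list(fc1 = f1b$grads, fc2 = f2b$grads))
}

expand_cb <- function(m, d) {
  # expand a C x B matrix to a (C, H, W, B) array
  aperm(array(m, dim = c(d[1], d[4], d[2], d[3])), c(1, 3, 4, 2))
}

#' Run a SCOPE block
#'
#' Variant semantics (shapes always preserved):
#' * `full`: `Xhat = g * Xspa + X` with the gate pooled from `Xspa`.
#' * `no_gate`: `Xhat = Xspa + X`.
#' * `channel_only`: `Xhat = g * Xchan + X` (gate pooled from `Xchan`).
#' * `spatial_only`: spatial branch applied directly to `X`;
#'   `Xhat = g * Xspa + X`.
#' * `cbam`: sequential channel-then-spatial attention reference block
#'   (shared MLP over average- and max-pooled channel descriptors; one 7x7
#'   convolution over channel-pooled statistics), with the same outer
#'   residual for insertion parity.
#'
#' @param x `(C, H, W, B)` feature array (finite values).
#' @param scope bundle from `scope_init()`.
#' @param training logical.
#' @return List with `out` (same shape as `x`), updated `scope`, cache.
#' @export
scope_forward <- function(x, scope, training = FALSE) {
  v <- scope$variant
  if (!v %in% scope_variants) stop("scope_forward: unknown variant ", v)
  if (v == "cbam") return(cbam_forward(x, scope, training))
  cache <- list(variant = v, x = x)
  d <- dim(x)
  if (v %in% c("full", "channel_only", "no_gate")) {
    ca <- channel_attention(x, scope)
    cache$ca <- ca
    h <- ca$x_chan
  } else h <- x
  if (v %in% c("full", "spatial_only", "no_gate")) {
    sa <- spatial_attention(h, scope, training)
    scope$state <- sa$state
    cache$sa <- sa
    h <- sa$x_spa
  }
  if (v %in% c("full", "channel_only", "spatial_only")) {
    gt <- scope_gate(h, scope)
    cache$gt <- gt
    gmap <- expand_cb(gt$g, d)
    out <- gmap * h + x
    cache$gmap <- gmap
    cache$h <- h
  } else {
    out <- h + x
  }
  list(out = out, scope = scope, cache = cache)
}

scope_backward <- function(dout, scope, cache) {
  v <- cache$variant
  if (v == "cbam") return(cbam_backward(dout, scope, cache))
  p <- scope$params
  grads <- list()
  dx_residual <- dout
  if (v %in% c("full", "channel_only", "spatial_only")) {
    dh <- dout * cache$gmap
    dg <- matrix(0, dim(dout)[1], dim(dout)[4])
    dgm <- dout * cache$h
    d <- dim(dout)
    x3 <- array(dgm, dim = c(d[1], d[2] * d[3], d[4]))
    for (j in seq_len(d[2] * d[3])) dg <- dg + x3[, j, ]
    gb <- scope_gate_bw(dg, p$gate, cache$gt$cache)
    grads$gate <- gb$grads
    dh <- dh + gb$dx
  } else {
    dh <- dout
  }
  if (v %in% c("full", "spatial_only", "no_gate")) {
    sb <- spatial_attention_bw(dh, NULL, scope, cache$sa$cache)
    grads$spa <- sb$grads
    dh <- sb$dx
  }
  if (v %in% c("full", "channel_only", "no_gate")) {
    cb <- channel_attention_bw(dh, NULL, p$mlp, cache$ca$cache)
    grads$mlp <- cb$grads
    dh <- cb$dx
  }
  list(dx = dh + dx_residual, grads = grads)
}

# ---- CBAM reference block --------------------------------------------------

cbam_forward <- function(x, scope, training = FALSE) {
  p <- scope$params
  d <- dim(x); hw <- d[2] * d[3]
  x3 <- array(x, dim = c(d[1], hw, d[4]))
  avg <- matrix(0, d[1], d[4])
  for (j in seq_len(hw)) avg <- avg + x3[, j, ]
  avg <- avg / hw
  mxi <- apply(x3, c(1, 3), which.max)        # argmax index over locations
  mx <- apply(x3, c(1, 3), max)
  mlp_pass <- function(inp) {
    f1 <- linear_fw(inp, p$mlp$fc1); r1 <- relu_fw(f1$out)
    f2 <- linear_fw(r1$out, p$mlp$fc2)
    list(out = f2$out, f1 = f1, r1 = r1, f2 = f2)
  }
  pa <- mlp_pass(avg); pm <- mlp_pass(mx)
  mc <- sigmoid(pa$out + pm$out)               # C x B channel attention
  xc <- x * expand_cb(mc, d)
  # spatial: channel-mean and channel-max maps -> 7x7 conv -> sigmoid
  xc3 <- array(xc, dim = c(d[1], hw, d[4]))
  smean <- apply(xc3, c(2, 3), mean)           # hw x B
  smax <- apply(xc3, c(2, 3), max)
  smaxi <- apply(xc3, c(2, 3), which.max)
  sin <- array(0, dim = c(2L, d[2], d[3], d[4]))
  sin[1, , , ] <- array(smean, dim = c(d[2], d[3], d[4]))
  sin[2, , , ] <- array(smax, dim = c(d[2], d[3], d[4]))
  cs <- conv2d_fw(sin, p$spa$conv, k = 7, stride = 1, pad = 3)
  ms <- sigmoid(cs$out)                        # 1,H,W,B
  msx <- array(ms[1, , , ], dim = c(1L, d[2], d[3], d[4]))
  mfull <- array(0, dim = d)
  for (cc in seq_len(d[1])) mfull[cc, , , ] <- msx[1, , , ]
  out <- xc * mfull + x
  list(out = out, scope = scope,
       cache = list(variant = "cbam", x = x, avg = avg, mx = mx, mxi = mxi,
                    pa = pa, pm = pm, mc = mc, xc = xc, smean = smean,
                    smax = smax, smaxi = smaxi, sin = sin, cs = cs, ms = ms,
                    mfull = mfull, dim = d, hw = hw))
}

cbam_backward <- function(dout, scope, cache) {
  p <- scope$params
  d <- cache$dim; hw <- cache$hw
  dxc <- dout * cache$mfull
  dmfull <- dout * cache$xc
  # collapse channel dim of the broadcast spatial map
  dms <- array(0, dim = c(1L, d[2], d[3], d[4]))
  for (cc in seq_len(d[1])) dms[1, , , ] <- dms[1, , , ] + dmfull[cc, , , ]
  dcs <- dms * cache$ms * (1 - cache$ms)
  csb <- conv2d_bw(dcs, p$spa$conv, cache$cs$cache)
  dsin <- csb$dx                                # 2,H,W,B
  dsmean <- matrix(dsin[1, , , ], hw, d[4])
  dsmax <- matrix(dsin[2, , , ], hw, d[4])
  # scatter spatial mean/max back to xc
  dxc3 <- array(0, dim = c(d[1], hw, d[4]))
  for (b in seq_len(d[4])) {
    dxc3[, , b] <- dxc3[, , b] +
      matrix(dsmean[, b] / d[1], d[1], hw, byrow = TRUE)
    for (j in seq_len(hw)) {
      ci <- cache$smaxi[j, b]
      dxc3[ci, j, b] <- dxc3[ci, j, b] + dsmax[j, b]
    }
  }
  dxc <- dxc + array(dxc3, dim = d)
  # channel attention backward
  dmc_full <- dxc * cache$x
  dmc <- matrix(0, d[1], d[4])
  x3 <- array(dmc_full, dim = c(d[1], hw, d[4]))
  for (j in seq_len(hw)) dmc <- dmc + x3[, j, ]
  dx <- dxc * expand_cb(cache$mc, d) + dout     # residual path
  dpre <- dmc * cache$mc * (1 - cache$mc)
  back_mlp <- function(pass, dpre) {
    f2b <- linear_bw(dpre, p$mlp$fc2, pass$f2$cache)
    r1b <- relu_bw(f2b$dx, pass$r1$cache)
    f1b <- linear_bw(r1b, p$mlp$fc1, pass$f1$cache)
    list(dx = f1b$dx, g = list(fc1 = f1b$grads, fc2 = f2b$grads))
  }
  ba <- back_mlp(cache$pa, dpre)
  bm <- back_mlp(cache$pm, dpre)
  # avg pool adjoint
  dx <- dx + expand_cb(ba$dx / hw, d)
  # max pool adjoint: route to argmax locations
  dxm3 <- array(0, dim = c(d[1], hw, d[4]))
  for (b in seq_len(d[4])) for (cc in seq_len(d[1]))
    dxm3[cc, cache$mxi[cc, b], b] <- bm$dx[cc, b]
  dx <- dx + array(dxm3, dim = d)
  g_mlp <- tree_map2(`+`, ba$g, bm$g)
  list(dx = dx, grads = list(mlp = g_mlp, spa = list(conv = csb$grads)))
}
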