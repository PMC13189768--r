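# Minimal neural-network layer kit with analytic backprop.
#
# Tensors are (C, H, W, B) arrays (channel fastest, flattened frame axis B
# last); token matrices are (E, D*N) with the D frames of each clip
# contiguous.  Every *_fw returns list(out, cache); every *_bw consumes the
# cache and the upstream gradient and returns gradients for input and
# parameters.  Correctness is pinned by finite-difference tests.

# ---- convolution -----------------------------------------------------------

conv_init <- function(c_in, c_out, k, gain = sqrt(2)) {
  kk <- c_in * k * k
  list(W = matrix(rnorm(c_out * kk, sd = gain / sqrt(kk)), c_out, kk),
       b = numeric(c_out))
}

conv2d_fw <- function(x, params, k, stride, pad) {
  d <- dim(x)  # C,H,W,B
  out <- conv2d_direct(x, params$W, params$b, d[1], d[2], d[3], d[4],
                       k, stride, pad)
  oh <- (d[2] + 2 * pad - k) %/% stride + 1
  ow <- (d[3] + 2 * pad - k) %/% stride + 1
  dim(out) <- c(nrow(params$W), oh, ow, d[4])
  list(out = out, cache = list(x = x, k = k, stride = stride, pad = pad))
}

conv2d_bw <- function(dout, params, cache) {
  xd <- dim(cache$x)
  r <- conv2d_direct_bw(cache$x, params$W, dout, xd[1], xd[2], xd[3], xd[4],
                        cache$k, cache$stride, cache$pad)
  dx <- r$dx
  dim(dx) <- xd
  list(dx = dx, grads = list(W = r$dW, b = r$db))
}

# ---- batch norm over (H, W, B) per channel ---------------------------------

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c))
}

bn_state_init <- function(c) {
  list(mean = numeric(c), var = rep(1, c))
}

bn2d_fw <- function(x, params, state, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); C <- d[1]; M <- prod(d) / C
  if (training) {
    r <- bn_fw_cpp(x, C, M, params$gamma, params$beta, eps)
    state$mean <- (1 - momentum) * state$mean + momentum * r$mu
    ub <- if (M > 1) r$var * M / (M - 1) else r$var
    state$var <- (1 - momentum) * state$var + momentum * ub
    out <- r$out; xhat <- r$xhat; inv <- r$inv
  } else {
    # channel-fastest layout: length-C vectors recycle along the channel axis
    inv <- 1 / sqrt(state$var + eps)
    xhat <- (x - state$mean) * inv
    out <- params$gamma * xhat + params$beta
  }
  dim(out) <- d
  list(out = out, state = state,
       cache = list(xhat = xhat, inv = inv, dim = d, training = training))
}

bn2d_bw <- function(dout, params, cache) {
  d <- cache$dim; C <- d[1]; M <- prod(d) / C
  r <- bn_bw_cpp(dout, cache$xhat, cache$inv, params$gamma, C, M,
                 cache$training)
  dx <- r$dx
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
}

# ---- elementwise -----------------------------------------------------------

relu_fw <- function(x) {
  out <- relu_fw_cpp(x)
  attributes(out) <- attributes(x)
  # the rectified output itself encodes the active set for the adjoint
  list(out = out, cache = out)
}
relu_bw <- function(dout, mask) {
  dx <- relu_bw_cpp(dout, mask)
  attributes(dx) <- attributes(dout)
  dx
}

gelu_fw <- function(x) {
  p <- stats::pnorm(x)
  list(out = x * p, cache = list(x = x, p = p))
}
gelu_bw <- function(dout, cache) {
  dout * (cache$p + cache$x * stats::dnorm(cache$x))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Per-(channel, frame) spatial dropout mask; survivors scaled by 1/(1-rate).
# The (C, B) mask is applied without materializing its broadcast.
dropout2d_fw <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, cache = NULL))
  d <- dim(x); C <- d[1]; B <- d[4]
  keep <- matrix((runif(C * B) >= rate) / (1 - rate), C, B)
  out <- mul_mask_cb(x, keep, d[1], d[2], d[3], d[4])
  dim(out) <- d
  list(out = out, cache = keep)
}
dropout2d_bw <- function(dout, cache) {
  if (is.null(cache)) return(dout)
  d <- dim(dout)
  dx <- mul_mask_cb(dout, cache, d[1], d[2], d[3], d[4])
  dim(dx) <- d
  dx
}

# ---- dense -----------------------------------------------------------------

linear_init <- function(n_in, n_out, gain = 1) {
  list(W = matrix(rnorm(n_out * n_in, sd = gain / sqrt(n_in)), n_out, n_in),
       b = numeric(n_out))
}

linear_fw <- function(x, params) {
  list(out = params$W %*% x + params$b, cache = x)
}
linear_bw <- function(dout, params, cache) {
  list(dx = crossprod(params$W, dout),
       grads = list(W = dout %*% t(cache), b = rowSums(dout)))
}

# ---- layer norm over the embedding dimension (columns are tokens) ----------

ln_init <- function(e) list(gamma = rep(1, e), beta = numeric(e))

ln_fw <- function(x, params, eps = 1e-5) {
  e <- nrow(x)
  mu <- colMeans(x)
  xc <- x - rep(mu, each = e)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv, each = e)
  out <- params$gamma * xhat + params$beta
  list(out = out, cache = list(xhat = xhat, inv = inv))
}

ln_bw <- function(dout, params, cache) {
  e <- nrow(dout)
  dgamma <- rowSums(dout * cache$xhat)
  dbeta <- rowSums(dout)
  dxh <- dout * params$gamma
  m1 <- colMeans(dxh)
  m2 <- colMeans(dxh * cache$xhat)
  dx <- (dxh - rep(m1, each = e) - cache$xhat * rep(m2, each = e)) *
    rep(cache$inv, each = e)
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# ---- multi-head self-attention over the D tokens of each clip --------------

mhsa_init <- function(e) {
  list(q = linear_init(e, e), k = linear_init(e, e),
       v = linear_init(e, e), o = linear_init(e, e))
}

softmax_rows <- function(s) {
  s <- s - s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  es <- exp(s)
  es / rowSums(es)
}

mhsa_fw <- function(x, params, heads, d, n) {
  e <- nrow(x); hd <- e %/% heads
  q <- linear_fw(x, params$q); k <- linear_fw(x, params$k)
  v <- linear_fw(x, params$v)
  att <- vector("list", n * heads)
  ctx <- matrix(0, e, d * n)
  scale <- 1 / sqrt(hd)
  for (nn in seq_len(n)) {
    cols <- (nn - 1) * d + seq_len(d)
    for (h in seq_len(heads)) {
      rows <- (h - 1) * hd + seq_len(hd)
      qh <- q$out[rows, cols, drop = FALSE]
      kh <- k$out[rows, cols, drop = FALSE]
      vh <- v$out[rows, cols, drop = FALSE]
      a <- softmax_rows(crossprod(qh, kh) * scale)  # D x D, rows = queries
      ctx[rows, cols] <- vh %*% t(a)
      att[[(nn - 1) * heads + h]] <- a
    }
  }
  o <- linear_fw(ctx, params$o)
  list(out = o$out,
       cache = list(q = q, k = k, v = v, o = o, att = att, ctx = ctx,
                    heads = heads, d = d, n = n, scale = scale))
}

mhsa_bw <- function(dout, params, cache) {
  heads <- cache$heads; d <- cache$d; n <- cache$n
  e <- nrow(dout); hd <- e %/% heads
  ob <- linear_bw(dout, params$o, cache$ctx)
  dctx <- ob$dx
  dq <- matrix(0, e, d * n); dk <- dq; dv <- dq
  for (nn in seq_len(n)) {
    cols <- (nn - 1) * d + seq_len(d)
    for (h in seq_len(heads)) {
      rows <- (h - 1) * hd + seq_len(hd)
      a <- cache$att[[(nn - 1) * heads + h]]
      qh <- cache$q$out[rows, cols, drop = FALSE]
      kh <- cache$k$out[rows, cols, drop = FALSE]
      vh <- cache$v$out[rows, cols, drop = FALSE]
      dctxh <- dctx[rows, cols, drop = FALSE]
      dv[rows, cols] <- dctxh %*% a           # hd x D
      da <- crossprod(dctxh, vh)              # queries x keys
      ds <- a * (da - rowSums(a * da))        # softmax jacobian, per row
      ds <- ds * cache$scale
      dq[rows, cols] <- kh %*% t(ds)
      dk[rows, cols] <- qh %*% ds
    }
  }
  qb <- linear_bw(dq, params$q, cache$q$cache)
  kb <- linear_bw(dk, params$k, cache$k$cache)
  vb <- linear_bw(dv, params$v, cache$v$cache)
  list(dx = qb$dx + kb$dx + vb$dx,
       grads = list(q = qb$grads, k = kb$grads, v = vb$grads, o = ob$grads))
}

# ---- transformer encoder block (pre-norm, MLP ratio 4) ---------------------

block_init <- function(e) {
  b <- list(ln1 = ln_init(e), attn = mhsa_init(e), ln2 = ln_init(e),
            mlp = list(fc1 = linear_init(e, 4 * e), fc2 = linear_init(4 * e, e)))
  # zero-init both residual-branch output projections so each block starts
  # as the identity; the direct token-to-wave path then trains stably at
  # high learning rates while the attention blocks fade in
  b$attn$o$W[] <- 0
  b$mlp$fc2$W[] <- 0
  b
}

block_fw <- function(x, params, heads, d, n) {
  l1 <- ln_fw(x, params$ln1)
  at <- mhsa_fw(l1$out, params$attn, heads, d, n)
  x1 <- x + at$out
  l2 <- ln_fw(x1, params$ln2)
  f1 <- linear_fw(l2$out, params$mlp$fc1)
  g1 <- gelu_fw(f1$out)
  f2 <- linear_fw(g1$out, params$mlp$fc2)
  list(out = x1 + f2$out,
       cache = list(l1 = l1, at = at, l2 = l2, f1 = f1, g1 = g1, f2 = f2))
}

block_bw <- function(dout, params, cache) {
  f2b <- linear_bw(dout, params$mlp$fc2, cache$f2$cache)
  g1b <- gelu_bw(f2b$dx, cache$g1$cache)
  f1b <- linear_bw(g1b, params$mlp$fc1, cache$f1$cache)
  l2b <- ln_bw(f1b$dx, params$ln2, cache$l2$cache)
  dx1 <- dout + l2b$dx
  atb <- mhsa_bw(dx1, params$attn, cache$at$cache)
  l1b <- ln_bw(atb$dx, params$ln1, cache$l1$cache)
  list(dx = dx1 + l1b$dx,
       grads = list(ln1 = l1b$grads, attn = atb$grads, ln2 = l2b$grads,
                    mlp = list(fc1 = f1b$grads, fc2 = f2b$grads)))
}

# ---- parameter-tree utilities ---------------------------------------------

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) tree_map(f, x)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

tree_count <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, tree_count, numeric(1))) else length(tree)
}

tree_sum_abs <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, tree_sum_abs, numeric(1)))
  else sum(abs(tree))
}

# Scale-and-add used for gradient accumulation across streams.
tree_add <- function(a, b) tree_map2(`+`, a, b)

# ---- AdamW -----------------------------------------------------------------

adamw_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adamw_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  step <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + weight_decay * p)
    list(p = p, m = m, v = v)
  }
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      pp <- p; mm <- m; vv <- v
      nm <- names(p)
      for (i in seq_along(p)) {
        gi <- if (!is.null(nm) && nzchar(nm[i]) && !is.null(g[[nm[i]]]))
          g[[nm[i]]] else g[[i]]
        r <- rec(p[[i]], gi, m[[i]], v[[i]])
        pp[[i]] <- r$p; mm[[i]] <- r$m; vv[[i]] <- r$v
      }
      list(p = pp, m = mm, v = vv)
    } else step(p, g, m, v)
  }
  r <- rec(params, grads, opt$m, opt$v)
  list(params = r$p, opt = list(m = r$m, v = r$v, t = opt$t))
}

# Global-norm gradient clipping (optional training stabilizer).
tree_global_norm <- function(tree) {
  sq <- function(x) if (is.list(x)) sum(vapply(x, sq, numeric(1))) else sum(x * x)
  sqrt(sq(tree))
}

tree_clip_global <- function(tree, max_norm) {
  gn <- tree_global_norm(tree)
  if (is.finite(gn) && gn > max_norm) tree_map(function(x) x * (max_norm / gn), tree)
  else tree
}
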