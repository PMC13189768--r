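make_scope <- function(c = 8L, r = 2L, variant = "full", seed = 1L,
                       spatial_sigmoid = FALSE) {
  set.seed(seed)
  pulseforge:::scope_init(c, r, variant, spatial_sigmoid)
}

rand_map <- function(c = 8L, h = 4L, w = 4L, b = 6L, seed = 2L) {
  set.seed(seed)
  array(rnorm(c * h * w * b), dim = c(c, h, w, b))
}

test_that("channel attention is a per-location sigmoid MLP map", {
  sc <- make_scope()
  x <- rand_map()

  # all-zero MLP -> a_chan = 0.5 everywhere and x_chan = x / 2
  z <- sc
  z$params$mlp <- pulseforge:::tree_map(function(p) p * 0, z$params$mlp)
  ca <- channel_attention(x, z)
  expect_equal(max(abs(ca$a_chan - 0.5)), 0, tolerance = 1e-14)
  expect_equal(ca$x_chan, x / 2, tolerance = 1e-14)

  # bounds
  ca2 <- channel_attention(x, sc)
  expect_true(all(ca2$a_chan > 0 & ca2$a_chan < 1))

  # per-location oracle: hand-rolled two-layer MLP on two distinct columns
  mlp <- sc$params$mlp
  loc <- function(h, w, b) {
    v <- x[, h, w, b]
    h1 <- pmax(mlp$fc1$W %*% v + mlp$fc1$b, 0)
    plogis(as.numeric(mlp$fc2$W %*% h1 + mlp$fc2$b))
  }
  expect_equal(ca2$a_chan[, 1, 1, 1], loc(1, 1, 1), tolerance = 1e-12)
  expect_equal(ca2$a_chan[, 3, 2, 4], loc(3, 2, 4), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(ca2$a_chan[, 1, 1, 1], ca2$a_chan[, 3, 2, 4])))

  expect_error(pulseforge:::scope_init(6L, 4L), "divisible")
})

test_that("spatial attention composes two 7x7 conv/BN/ReLU blocks", {
  sc <- make_scope(c = 4L, seed = 3L)
  x <- rand_map(c = 4L, h = 8L, w = 8L, b = 1L, seed = 5L)
  sa <- spatial_attention(x, sc, training = TRUE)
  expect_true(all(sa$a_spa >= 0))
  expect_equal(dim(sa$x_spa), dim(x))

  # independent composition oracle from the primitive layers
  p <- sc$params$spa
  c1 <- pulseforge:::conv2d_fw(x, p$conv1, 7, 1, 3)
  b1 <- pulseforge:::bn2d_fw(c1$out, p$bn1, pulseforge:::bn_state_init(4L), TRUE)
  r1 <- pmax(b1$out, 0)
  c2 <- pulseforge:::conv2d_fw(r1, p$conv2, 7, 1, 3)
  b2 <- pulseforge:::bn2d_fw(c2$out, p$bn2, pulseforge:::bn_state_init(4L), TRUE)
  a <- pmax(b2$out, 0)
  expect_equal(sa$a_spa, a, tolerance = 1e-12)
  expect_equal(sa$x_spa, x * a, tolerance = 1e-12)
})

test_that("the gate pools globally and saturates as expected", {
  sc <- make_scope()
  z <- sc
  z$params$gate <- pulseforge:::tree_map(function(p) p * 0, z$params$gate)
  g0 <- scope_gate(rand_map(), z)
  expect_equal(max(abs(g0$g - 0.5)), 0, tolerance = 1e-14)

  zneg <- z
  zneg$params$gate$fc2$b[] <- -20
  gneg <- scope_gate(rand_map(), zneg)
  expect_lt(max(gneg$g), 1e-8)

  # constant map: GAP gives exactly v, then a scalar two-layer chain
  v <- 0.7
  xc <- array(v, dim = c(8, 4, 4, 2))
  gv <- scope_gate(xc, sc)
  gp <- sc$params$gate
  h1 <- pmax(gp$fc1$W %*% rep(v, 8) + gp$fc1$b, 0)
  oracle <- plogis(as.numeric(gp$fc2$W %*% h1 + gp$fc2$b))
  expect_equal(gv$g[, 1], oracle, tolerance = 1e-12)
  expect_equal(gv$g[, 2], oracle, tolerance = 1e-12)
})

test_that("scope_forward variants satisfy their algebraic identities", {
  x <- rand_map(seed = 7)

  # saturated-negative gate -> exact identity (full variant)
  sc <- make_scope(seed = 8)
  sc$params$gate$fc2$W[] <- 0
  sc$params$gate$fc2$b[] <- -40
  out <- scope_forward(x, sc, training = TRUE)
  expect_equal(out$out, x, tolerance = 1e-12)

  # no_gate with zeroed spatial+channel params: a_chan = 0.5, and a zeroed
  # spatial branch gives a_spa = 0, so x_spa = 0 and the output is x
  ng <- make_scope(variant = "no_gate", seed = 9)
  ng$params$spa <- pulseforge:::tree_map(function(p) p * 0, ng$params$spa)
  out2 <- scope_forward(x, ng, training = TRUE)
  expect_equal(out2$out, x, tolerance = 1e-12)

  # full variant equals the staged manual composition
  sc3 <- make_scope(seed = 10)
  r <- scope_forward(x, sc3, training = TRUE)
  ca <- channel_attention(x, sc3)
  sa <- spatial_attention(ca$x_chan, sc3, training = TRUE)
  gt <- scope_gate(sa$x_spa, sc3)
  manual <- pulseforge:::expand_cb(gt$g, dim(x)) * sa$x_spa + x
  expect_equal(r$out, manual, tolerance = 1e-12)
})

test_that("every scope variant preserves shape and stays finite", {
  x <- rand_map(seed = 11)
  for (v in c("full", "cbam", "channel_only", "spatial_only", "no_gate")) {
    sc <- make_scope(variant = v, seed = 12)
    out <- scope_forward(x, sc, training = TRUE)
    expect_equal(dim(out$out), dim(x))
    expect_true(all(is.finite(out$out)))
    out_eval <- scope_forward(x, sc, training = FALSE)
    out_eval2 <- scope_forward(x, sc, training = FALSE)
    expect_identical(out_eval$out, out_eval2$out)
  }
  bad <- make_scope()
  bad$variant <- "nope"
  expect_error(scope_forward(x, bad), "variant")
})

test_that("the residual-dominance bound holds for the gated variant", {
  set.seed(13)
  for (i in 1:5) {
    x <- rand_map(seed = 20 + i)
    sc <- make_scope(seed = 30 + i)
    r <- scope_forward(x, sc, training = TRUE)
    sa_gap <- max(abs(r$out - x))
    g <- r$cache$gt$g
    xspa_inf <- max(abs(r$cache$sa$x_spa))
    expect_lte(sa_gap, max(g) * xspa_inf + 1e-10)
  }
})

test_that("variant parameter counts drop exactly with removed components", {
  count <- function(v) pulseforge:::tree_count(make_scope(variant = v)$params)
  c_full <- count("full")
  c_chan <- count("channel_only")
  c_spat <- count("spatial_only")
  c_nogate <- count("no_gate")
  sc <- make_scope()
  n_spa <- pulseforge:::tree_count(sc$params$spa)
  n_mlp <- pulseforge:::tree_count(sc$params$mlp)
  n_gate <- pulseforge:::tree_count(sc$params$gate)
  expect_equal(c_full, n_spa + n_mlp + n_gate)
  expect_equal(c_chan, c_full - n_spa)   # no spatial convs
  expect_equal(c_spat, c_full - n_mlp)   # no channel MLP
  expect_equal(c_nogate, c_full - n_gate)  # no gate
})
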