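test_that("build_model validates config and seeds initialization", {
  cfg <- tiny_model_config()
  m1 <- build_model(cfg, seed = 7)
  m2 <- build_model(cfg, seed = 7)
  m3 <- build_model(cfg, seed = 8)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
  expect_gt(m1$n_params, 0)

  bad <- cfg; bad$backbone$heads <- 3L
  expect_error(build_model(bad), "divisible")
  bad2 <- cfg; bad2$stem$mode <- "fixed"
  expect_error(build_model(bad2), "fixed")
})

test_that("forward yields one finite length-D wave per clip", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 1)
  clips <- list(make_random_clip(1, d = 12L), make_random_clip(2, d = 12L))
  batch <- clip_batch(clips)
  out <- model_forward(m, batch)
  expect_equal(dim(out$wave), c(12, 2))
  expect_true(all(is.finite(out$wave)))

  # duplicated clips give identical outputs in eval mode
  dup <- clip_batch(list(clips[[1]], clips[[1]]))
  wd <- model_forward(m, dup)$wave
  expect_equal(wd[, 1], wd[, 2], tolerance = 1e-12)

  # eval-mode purity
  expect_identical(model_forward(m, batch)$wave, out$wave)

  expect_error(model_forward(m, clip_batch(list(make_random_clip(3, d = 12L,
                                                                 h = 12L,
                                                                 w = 12L)))),
               "divisible")
})

test_that("degenerate configs still produce waves", {
  cfg <- tiny_model_config()
  cfg$backbone$stages <- 0L
  cfg$backbone$depth <- 0L
  cfg$scope$insertions <- 0L
  cfg$scope$variant <- "none"
  m <- build_model(cfg, seed = 2)
  out <- model_forward(m, clip_batch(list(make_random_clip(4, d = 12L))))
  expect_equal(dim(out$wave), c(12, 1))
  expect_true(all(is.finite(out$wave)))
})

test_that("make_variant swaps exactly one component", {
  base <- model_config("desk")
  expect_identical(make_variant(base, "full"), base)

  ns <- make_variant(base, "no-SCOPE")
  d <- which(!mapply(identical, ns, base))
  expect_equal(names(ns)[d], "scope")
  same_but <- function(v, field) {
    cfg <- make_variant(base, v)
    for (nm in setdiff(names(cfg), field)) expect_identical(cfg[[nm]], base[[nm]])
    cfg
  }
  expect_equal(same_but("SCOPE-CBAM", "scope")$scope$variant, "cbam")
  expect_equal(same_but("SCOPE-ChannelOnly", "scope")$scope$variant,
               "channel_only")
  expect_equal(same_but("SCOPE-SpatialOnly", "scope")$scope$variant,
               "spatial_only")
  expect_equal(same_but("SCOPE-NoGate", "scope")$scope$variant, "no_gate")
  expect_equal(same_but("MDFS-OriginalOnly", "stem")$stem$mode,
               "original_only")
  fx <- same_but("MDFS-Fixed", "stem")
  expect_equal(fx$stem$mode, "fixed")
  expect_equal(fx$stem$fixed_weights, rep(0.25, 4))
  expect_error(make_variant(base, "bogus"), "unknown")

  # removing SCOPE strictly reduces the parameter count
  expect_lt(build_model(make_variant(tiny_model_config(), "no-SCOPE"))$n_params,
            build_model(tiny_model_config())$n_params)
})

test_that("all eight variants run forward and backward on a toy batch", {
  batch <- clip_batch(list(make_random_clip(11, d = 12L),
                           make_random_clip(12, d = 12L)))
  s_mat <- vapply(1:2, function(i) synth_bvp(70 + 10 * i, 30, 12L,
                                             seed = i)$wave, numeric(12))
  for (v in c("full", "no-SCOPE", "SCOPE-CBAM", "SCOPE-ChannelOnly",
              "SCOPE-SpatialOnly", "SCOPE-NoGate", "MDFS-OriginalOnly",
              "MDFS-Fixed")) {
    cfg <- make_variant(tiny_model_config(), v)
    m <- build_model(cfg, seed = 5)
    fw <- model_forward(m, batch, training = TRUE)
    expect_true(all(is.finite(fw$wave)), info = v)
    lg <- pulseforge:::batch_loss_grad(s_mat, fw$wave, 30, loss_config())
    gr <- model_backward(fw$model, fw$cache, lg$grad)
    gnorm <- pulseforge:::tree_global_norm(gr)
    expect_true(is.finite(gnorm) && gnorm > 0, info = v)
  }
})

test_that("analytic gradients match finite differences through the model", {
  cfg <- tiny_model_config()
  cfg$stem$dropout <- 0
  m <- build_model(cfg, seed = 4)
  batch <- clip_batch(list(make_random_clip(21, d = 12L)))
  s_mat <- matrix(synth_bvp(90, 30, 12L, seed = 2)$wave, 12, 1)
  lcfg <- loss_config()
  loss_of <- function(model) {
    fw <- model_forward(model, batch, training = TRUE)
    pulseforge:::batch_loss_grad(s_mat, fw$wave, 30, lcfg)$loss
  }
  fw <- model_forward(m, batch, training = TRUE)
  lg <- pulseforge:::batch_loss_grad(s_mat, fw$wave, 30, lcfg)
  gr <- model_backward(fw$model, fw$cache, lg$grad)
  get_leaf <- function(tree, path) { for (p in path) tree <- tree[[p]]; tree }
  set_leaf <- function(tree, path, val) {
    if (length(path) == 1) { tree[[path[[1]]]] <- val; return(tree) }
    tree[[path[[1]]]] <- set_leaf(tree[[path[[1]]]], path[-1], val)
    tree
  }
  probes <- list(list("stem", "branches", 2L, "conv1", "W"),
                 list("stem", "logits"),
                 list("scopes", 1L, "spa", "conv1", "W"),
                 list("scopes", 1L, "gate", "fc2", "b"),
                 list("stages", 1L, "conv", "W"),
                 list("pos"),
                 list("blocks", 1L, "attn", "q", "W"),
                 list("head", "fc1", "W"))
  set.seed(9)
  eps <- 1e-5
  for (pp in probes) {
    leaf <- get_leaf(m$params, pp)
    i <- sample(length(leaf), 1)
    up <- leaf; up[i] <- up[i] + eps
    dn <- leaf; dn[i] <- dn[i] - eps
    mu <- m; mu$params <- set_leaf(m$params, pp, up)
    md <- m; md$params <- set_leaf(m$params, pp, dn)
    fd <- (loss_of(mu) - loss_of(md)) / (2 * eps)
    an <- get_leaf(gr, pp)[i]
    expect_equal(an, fd, tolerance = 1e-4,
                 info = paste(unlist(pp), collapse = "."))
  }
})

test_that("checkpoints round-trip parameters and config", {
  m <- build_model(tiny_model_config(), seed = 3)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, m$params)
  expect_identical(back$config, m$config)
  batch <- clip_batch(list(make_random_clip(31, d = 12L)))
  expect_identical(model_forward(back, batch)$wave,
                   model_forward(m, batch)$wave)
})

test_that("a temporal shift of the input moves phase, not frequency", {
  # two overlapping windows of one long recording share their dominant
  # periodicity: the trained model's HR readout must agree across them
  model <- toy_study(101L, "full")$model
  cf <- synth_config(hr_bpm = 84, fps = 30, d = 75L, h = 32L, w = 32L,
                     noise_sd = 0.02, jitter_px = 1L, seed = 515L)
  smp <- synth_clip(cf)
  k <- 15L
  win1 <- frame_clip(smp$clip$frames[1:60, , , , drop = FALSE], 30)
  win2 <- frame_clip(smp$clip$frames[(k + 1):(k + 60), , , , drop = FALSE], 30)
  w1 <- model_forward(model, clip_batch(list(win1)))$wave[, 1]
  w2 <- model_forward(model, clip_batch(list(win2)))$wave[, 1]
  hr1 <- estimate_hr(bandpass(w1, 30), 30)
  hr2 <- estimate_hr(bandpass(w2, 30), 30)
  expect_lt(abs(hr1 - hr2), 2 * 30 * 60 / 512 + 1e-9)
})
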