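test_that("multi_scale_difference matches the exact subtraction contract", {
  # identical frames -> all difference streams are zero
  const <- frame_clip(array(0.3, dim = c(6, 3, 4, 4)), fps = 30)
  ds <- multi_scale_difference(const)
  for (s in 1:3) expect_equal(max(abs(ds$streams[[paste0("d", s)]])), 0)
  expect_identical(ds$streams$x, const$frames)

  # scalar ramp: delta_s[t] = s * step for t >= s, zeros before
  ramp <- make_ramp_clip(d = 6L)
  step <- 1 / 5
  dr <- multi_scale_difference(ramp)
  d2 <- dr$streams$d2
  expect_equal(max(abs(d2[1:2, , , ])), 0)
  expect_equal(d2[3:6, , , ], array(2 * step, dim = c(4, 3, 8, 8)),
               tolerance = 1e-12)

  # random clip vs a direct elementwise oracle
  clip <- make_random_clip(7, d = 9L)
  dd <- multi_scale_difference(clip, scales = c(1, 3))
  for (s in c(1, 3)) {
    oracle <- array(0, dim = dim(clip$frames))
    for (t in (s + 1):9)
      oracle[t, , , ] <- clip$frames[t, , , ] - clip$frames[t - s, , , ]
    expect_equal(dd$streams[[paste0("d", s)]], oracle, tolerance = 1e-14)
  }

  expect_error(multi_scale_difference(clip, scales = 9), "smaller")
})

test_that("difference streams are invariant to static offsets and zero-padded", {
  set.seed(31)
  for (i in 1:5) {
    clip <- make_random_clip(100 + i, d = 7L, h = 8L, w = 8L)
    shifted <- clip
    shifted$frames <- pmin(clip$frames * 0.5 + 0.25, 1)  # affine, stays valid
    base <- multi_scale_difference(clip$frames * 0.5)
    off <- multi_scale_difference(shifted$frames)
    for (s in 1:3) {
      expect_equal(off$streams[[paste0("d", s)]],
                   base$streams[[paste0("d", s)]], tolerance = 1e-12)
      expect_equal(max(abs(off$streams[[paste0("d", s)]][1:s, , , ])), 0)
    }
  }
})

test_that("fusion_weights is an overflow-safe softmax", {
  expect_equal(fusion_weights(c(0, 0, 0, 0)), rep(0.25, 4))
  expect_equal(fusion_weights(c(log(2), 0, 0, 0)), c(0.4, 0.2, 0.2, 0.2),
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:20) {
    w <- fusion_weights(rnorm(4, sd = 2))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w > 0 & w < 1))
  }
  # large-magnitude logits: no overflow, normalization still exact
  w <- fusion_weights(c(100, -100, 100, -100))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w[c(1, 3)], c(0.5, 0.5))
  expect_false(any(is.nan(w)))
  expect_error(fusion_weights(c(Inf, 0, 0, 0)), "finite")
})

test_that("fuse_and_activate obeys the one-hot and convexity identities", {
  set.seed(12)
  f <- lapply(1:4, function(i) array(rnorm(4 * 3 * 3 * 5), dim = c(4, 3, 3, 5)))
  one_hot <- fuse_and_activate(f, c(1, 0, 0, 0))
  expect_equal(one_hot, pmax(f[[1]], 0), tolerance = 1e-14)

  same <- lapply(1:4, function(i) f[[2]])
  for (w in list(rep(0.25, 4), c(0.7, 0.1, 0.1, 0.1))) {
    expect_equal(fuse_and_activate(same, w), pmax(f[[2]], 0),
                 tolerance = 1e-12)
  }
  # equal weights against a brute-force average-then-clip oracle
  avg <- (f[[1]] + f[[2]] + f[[3]] + f[[4]]) / 4
  expect_equal(fuse_and_activate(f, rep(0.25, 4)), pmax(avg, 0),
               tolerance = 1e-14)
  expect_error(fuse_and_activate(f[1:2], c(1, 0, 0)), "length")
})

test_that("channel_dropout zeroes whole channel maps and rescales survivors", {
  x <- array(1, dim = c(8, 4, 4, 3))
  expect_identical(channel_dropout(x, 0.5, training = FALSE), x)
  expect_identical(channel_dropout(x, 0, training = TRUE), x)
  out <- channel_dropout(x, 0.5, training = TRUE, seed = 42)
  for (cc in 1:8) for (b in 1:3) {
    m <- out[cc, , , b]
    expect_true(all(m == 0) || all(m == 2))  # zeroed or scaled by 1/(1-rate)
  }
  expect_gt(sum(out == 0), 0)
  expect_identical(out, channel_dropout(x, 0.5, training = TRUE, seed = 42))
  expect_error(channel_dropout(x, 1), "rate")
})

test_that("branch_forward meets the shape contract and zero propagation", {
  set.seed(3)
  st <- pulseforge:::stem_init(3L, 8L)
  br <- st$params$branches[[1]]
  stream <- array(runif(5 * 3 * 32 * 32), dim = c(5, 3, 32, 32))
  out <- branch_forward(stream, br, st$state[[1]], training = TRUE)
  expect_equal(dim(out$out), c(8, 8, 8, 5))

  zb <- br
  zb$conv1$b[] <- 0; zb$conv2$b[] <- 0; zb$bn1$beta[] <- 0
  zeros <- branch_forward(array(0, dim = c(2, 3, 8, 8)), zb,
                          pulseforge:::bn_state_init(8L), training = FALSE)
  expect_equal(max(abs(zeros$out)), 0, tolerance = 1e-12)

  expect_error(branch_forward(array(0, dim = c(2, 3, 6, 6)), br,
                              st$state[[1]]), "divisible")
})

test_that("mdfs_forward modes satisfy their defining identities", {
  clip1 <- make_random_clip(61, d = 6L, h = 16L, w = 16L)
  clip2 <- make_random_clip(62, d = 6L, h = 16L, w = 16L)
  batch <- clip_batch(list(clip1, clip2))
  set.seed(5)
  stem <- pulseforge:::stem_init(3L, 4L, dropout = 0)

  # zero logits (uniform softmax) must equal fixed uniform weights
  full <- mdfs_forward(batch, stem, mode = "full", training = FALSE)
  fixed <- mdfs_forward(batch, stem, mode = "fixed",
                        fixed_weights = rep(0.25, 4), training = FALSE)
  expect_equal(full$features, fixed$features, tolerance = 1e-12)

  # original_only equals branch0 + ReLU, independent of difference streams
  oo <- mdfs_forward(batch, stem, mode = "original_only", training = FALSE)
  x <- pulseforge:::batch_tensor(batch)
  b0 <- branch_forward(structure(x, internal = TRUE),
                       stem$params$branches[[1]], stem$state[[1]],
                       training = FALSE)
  expect_equal(oo$features, pmax(b0$out, 0), tolerance = 1e-12)
  expect_true(all(oo$features >= 0))

  # fixed weights must sum to one
  expect_error(mdfs_forward(batch, stem, mode = "fixed",
                            fixed_weights = c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")

  # static clip through a bias-free stem: difference features vanish, so
  # the output equals the weighted branch-0 path alone
  const <- frame_clip(array(0.4, dim = c(6, 3, 16, 16)), fps = 30)
  cb <- clip_batch(list(const))
  nb <- stem
  for (i in seq_along(nb$params$branches)) {
    nb$params$branches[[i]]$conv1$b[] <- 0
    nb$params$branches[[i]]$conv2$b[] <- 0
    nb$params$branches[[i]]$bn1$beta[] <- 0
  }
  st_full <- mdfs_forward(cb, nb, mode = "full", training = FALSE)
  xs <- pulseforge:::batch_tensor(cb)
  f0 <- branch_forward(structure(xs, internal = TRUE),
                       nb$params$branches[[1]], nb$state[[1]],
                       training = FALSE)
  w <- fusion_weights(nb$params$logits)
  expect_equal(st_full$features, pmax(w[1] * f0$out, 0), tolerance = 1e-10)
})

test_that("eval-mode stem is a pure function of batch and parameters", {
  batch <- clip_batch(list(make_random_clip(71, d = 6L, h = 16L, w = 16L)))
  set.seed(6)
  stem <- pulseforge:::stem_init(3L, 4L, dropout = 0.5)
  a <- mdfs_forward(batch, stem, training = FALSE)
  b <- mdfs_forward(batch, stem, training = FALSE)
  expect_identical(a$features, b$features)
})
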