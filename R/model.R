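# End-to-end BVP predictor: MDFS stem -> [SCOPE -> stride-2 conv stage] x S
# -> per-frame global average pooling -> linear token projection + learned
# temporal position embeddings -> pre-norm transformer blocks over the D
# tokens of each clip -> two-layer head -> one waveform sample per frame.
#
# The temporal backbone is a plain multi-head self-attention transformer: a
# deliberately simple, pluggable stand-in whose interface (frame-feature
# sequence in, wave out) isolates it from the stem and refinement blocks
# under study.

#' Default model configuration
#'
#' `preset = "desk"` is sized for CPU experimentation (32x32 inputs, 60-frame
#' clips); `preset = "paper"` is the full-scale setting (128x128 inputs,
#' 160-frame clips, 64 stem channels).
#'
#' @param preset `"desk"` or `"paper"`.
#' @return A nested configuration list (see fields in source).
#' @export
model_config <- function(preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  cfg <- list(
    input = list(c = 3L,
                 h = if (preset == "desk") 32L else 128L,
                 w = if (preset == "desk") 32L else 128L,
                 d = if (preset == "desk") 60L else 160L),
    stem = list(c_mid = if (preset == "desk") 12L else 64L,
                scales = 1:3, dropout = 0.1,
                mode = "full", fixed_weights = NULL),
    scope = list(variant = "full", reduction = if (preset == "desk") 4L else 8L,
                 spatial_sigmoid = FALSE,
                 insertions = NULL),  # NULL -> one before every conv stage
    backbone = list(stages = 2L, embed_dim = 96L, heads = 4L, depth = 4L),
    head = list(hidden = 64L)
  )
  cfg
}

validate_config <- function(cfg) {
  bb <- cfg$backbone
  if (bb$embed_dim %% bb$heads != 0)
    stop("model_config: embed_dim must be divisible by heads")
  if (bb$stages < 0) stop("model_config: stages must be >= 0")
  if (!cfg$scope$variant %in% c(scope_variants, "none"))
    stop("model_config: unknown scope variant ", cfg$scope$variant)
  if (!cfg$stem$mode %in% c("full", "original_only", "fixed"))
    stop("model_config: unknown stem mode ", cfg$stem$mode)
  if (cfg$stem$mode == "fixed") {
    fw <- cfg$stem$fixed_weights
    ns <- 1 + length(cfg$stem$scales)
    if (is.null(fw) || length(fw) != ns || abs(sum(fw) - 1) > 1e-8)
      stop("model_config: fixed stem weights must be length ", ns,
           " and sum to 1")
  }
  invisible(cfg)
}

n_scope_blocks <- function(cfg) {
  if (identical(cfg$scope$variant, "none")) return(0L)
  ins <- cfg$scope$insertions
  ins <- if (is.null(ins)) max(1L, cfg$backbone$stages) else as.integer(ins)
  # one insertion point exists before each conv stage (or after the stem
  # when there are no stages)
  min(ins, max(1L, cfg$backbone$stages))
}

#' Build a BVP prediction model
#'
#' Instantiates all parameter groups from a configuration, with a seeded,
#' reproducible initialization.
#'
#' @param config from [model_config()] (possibly modified or produced by
#'   [make_variant()]).
#' @param seed integer init seed; identical seeds give identical parameters.
#' @return An object of class `pf_model` with elements `params`, `state`,
#'   `config`, `n_params`.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  validate_config(config)
  cfg <- config
  with_seed(seed, {
    stem <- stem_init(cfg$input$c, cfg$stem$c_mid, cfg$stem$scales,
                      cfg$stem$dropout)
    ns <- n_scope_blocks(cfg)
    scopes <- if (ns > 0)
      lapply(seq_len(ns), function(i)
        scope_init(cfg$stem$c_mid, cfg$scope$reduction, cfg$scope$variant,
                   cfg$scope$spatial_sigmoid))
    else list()
    stages <- lapply(seq_len(cfg$backbone$stages), function(i) {
      cv <- conv_init(cfg$stem$c_mid, cfg$stem$c_mid, 3)
      # keep the stem's low-pass passthrough channel aggregating spatially
      # through the downsampling stages (3x3 averaging tap on channel 1)
      cv$W[1, ] <- 0
      cv$W[1, cfg$stem$c_mid * (0:8) + 1] <- 1 / 9
      bn <- bn_init(cfg$stem$c_mid)
      bn$beta[1] <- 2  # keep the passthrough channel in the ReLU's linear zone
      list(conv = cv, bn = bn)
    })
    stage_state <- lapply(seq_len(cfg$backbone$stages), function(i)
      bn_state_init(cfg$stem$c_mid))
    e <- cfg$backbone$embed_dim
    params <- list(
      stem = stem$params,
      scopes = lapply(scopes, function(s) s$params),
      stages = stages,
      proj = linear_init(cfg$stem$c_mid, e),
      pos = matrix(rnorm(e * cfg$input$d, sd = 0.02), e, cfg$input$d),
      blocks = lapply(seq_len(cfg$backbone$depth), function(i) block_init(e)),
      head = list(ln = ln_init(e),
                  fc1 = linear_init(e, cfg$head$hidden),
                  fc2 = linear_init(cfg$head$hidden, 1L))
    )
    state <- list(stem = stem$state,
                  scopes = lapply(scopes, function(s) s$state),
                  stages = stage_state)
    meta <- list(scope_variant = if (ns > 0) cfg$scope$variant else "none",
                 scope_settings = if (ns > 0) scopes[[1]][c("variant", "c",
                                                            "reduction",
                                                            "spatial_sigmoid")]
                 else NULL)
    structure(list(params = params, state = state, config = cfg, meta = meta,
                   n_params = tree_count(params)),
              class = "pf_model")
  })
}

#' @export
print.pf_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<pf_model: %dx%d D=%d | stem c_mid=%d mode=%s | scope %s x%d | %d stages | transformer E=%d H=%d depth=%d | %s params>\n",
    cfg$input$h, cfg$input$w, cfg$input$d, cfg$stem$c_mid, cfg$stem$mode,
    if (length(x$params$scopes)) cfg$scope$variant else "none",
    length(x$params$scopes), cfg$backbone$stages, cfg$backbone$embed_dim,
    cfg$backbone$heads, cfg$backbone$depth,
    format(x$n_params, big.mark = ",")))
  invisible(x)
}

# wrap a scope params+state pair back into the bundle scope_* functions expect
scope_bundle <- function(model, i) {
  list(params = model$params$scopes[[i]],
       state = model$state$scopes[[i]],
       variant = model$meta$scope_variant,
       c = model$config$stem$c_mid,
       reduction = model$config$scope$reduction,
       spatial_sigmoid = model$config$scope$spatial_sigmoid)
}

#' Forward pass: clips to predicted BVP waveforms
#'
#' @param model a [build_model()] result.
#' @param batch a [clip_batch()] (spatial dims must be divisible by
#'   `4 * 2^stages`).
#' @param training logical: enables batch statistics and dropout and returns
#'   a cache for [model_backward()].
#' @return List with `wave` (`D x N` matrix: one column per clip), updated
#'   `model` (batch-norm state), and `cache` when `training = TRUE` or
#'   `keep_cache = TRUE`.
#' @param keep_cache keep intermediate activations for a backward pass.
#' @export
model_forward <- function(model, batch, training = FALSE, keep_cache = training) {
  stopifnot(inherits(model, "pf_model"), inherits(batch, "clip_batch"))
  cfg <- model$config
  s <- batch$shape
  div <- 4L * 2L^cfg$backbone$stages
  if (s[3] %% div != 0 || s[4] %% div != 0)
    stop("model_forward: spatial dims must be divisible by ", div)
  if (s[1] != cfg$input$d)
    stop("model_forward: clip length ", s[1], " != configured D ", cfg$input$d)
  d <- batch$d; n <- batch$n
  x <- batch_tensor(batch)

  stem_bundle <- list(params = model$params$stem, state = model$state$stem,
                      scales = cfg$stem$scales, c_mid = cfg$stem$c_mid,
                      dropout = cfg$stem$dropout)
  st <- stem_forward(x, d, stem_bundle, training, cfg$stem$mode,
                     cfg$stem$fixed_weights)
  model$state$stem <- st$stem$state
  h <- st$out
  caches <- list(stem = st$cache)

  n_stage <- cfg$backbone$stages
  ns <- length(model$params$scopes)
  sc_caches <- vector("list", ns)
  stage_caches <- vector("list", n_stage)
  si <- 0L
  run_scope <- function(h, si) {
    sb <- scope_bundle(model, si)
    r <- scope_forward(h, sb, training)
    model$state$scopes[[si]] <<- r$scope$state
    sc_caches[[si]] <<- r$cache
    r$out
  }
  for (k in seq_len(max(n_stage, if (ns > 0) 1L else 0L))) {
    if (si < ns) { si <- si + 1L; h <- run_scope(h, si) }
    if (k <= n_stage) {
      p <- model$params$stages[[k]]
      cv <- conv2d_fw(h, p$conv, k = 3, stride = 2, pad = 1)
      bn <- bn2d_fw(cv$out, p$bn, model$state$stages[[k]], training)
      model$state$stages[[k]] <- bn$state
      rl <- relu_fw(bn$out)
      stage_caches[[k]] <- list(cv = cv, bn = bn, rl = rl)
      h <- rl$out
    }
  }
  caches$scopes <- sc_caches
  caches$stages <- stage_caches

  # per-frame global average pooling -> C x B tokens
  dh <- dim(h); hw <- dh[2] * dh[3]
  h3 <- array(h, dim = c(dh[1], hw, dh[4]))
  tok <- matrix(0, dh[1], dh[4])
  for (j in seq_len(hw)) tok <- tok + h3[, j, ]
  tok <- tok / hw
  caches$pool <- list(dim = dh, hw = hw)

  pj <- linear_fw(tok, model$params$proj)
  z <- pj$out + matrix(model$params$pos, nrow(pj$out), d * n)
  caches$proj <- pj

  blk_caches <- vector("list", cfg$backbone$depth)
  for (l in seq_len(cfg$backbone$depth)) {
    bl <- block_fw(z, model$params$blocks[[l]], cfg$backbone$heads, d, n)
    blk_caches[[l]] <- bl$cache
    z <- bl$out
  }
  caches$blocks <- blk_caches

  hl <- ln_fw(z, model$params$head$ln)
  h1 <- linear_fw(hl$out, model$params$head$fc1)
  g1 <- gelu_fw(h1$out)
  h2 <- linear_fw(g1$out, model$params$head$fc2)
  caches$head <- list(hl = hl, h1 = h1, g1 = g1, h2 = h2)
  wave <- matrix(h2$out, d, n)
  colnames(wave) <- vapply(batch$clips, function(cl) cl$clip_id, character(1))

  list(wave = wave, model = model,
       cache = if (keep_cache) c(caches, list(d = d, n = n)) else NULL)
}

#' Backward pass: waveform gradients to parameter gradients
#'
#' @param model the model used in the forward pass.
#' @param cache cache returned by [model_forward()] with
#'   `keep_cache = TRUE`.
#' @param dwave `D x N` matrix of loss gradients w.r.t. the predicted wave.
#' @return Gradient tree mirroring `model$params`.
#' @export
model_backward <- function(model, cache, dwave) {
  cfg <- model$config
  d <- cache$d; n <- cache$n
  grads <- list()
  hd <- cache$head
  dh2 <- matrix(dwave, 1L, d * n)
  h2b <- linear_bw(dh2, model$params$head$fc2, hd$h2$cache)
  g1b <- gelu_bw(h2b$dx, hd$g1$cache)
  h1b <- linear_bw(g1b, model$params$head$fc1, hd$h1$cache)
  hlb <- ln_bw(h1b$dx, model$params$head$ln, hd$hl$cache)
  grads$head <- list(ln = hlb$grads, fc1 = h1b$grads, fc2 = h2b$grads)
  dz <- hlb$dx

  grads$blocks <- vector("list", cfg$backbone$depth)
  for (l in rev(seq_len(cfg$backbone$depth))) {
    bb <- block_bw(dz, model$params$blocks[[l]], cache$blocks[[l]])
    grads$blocks[[l]] <- bb$grads
    dz <- bb$dx
  }
  # position embeddings are shared across the n clips
  dpos <- matrix(0, nrow(dz), d)
  for (nn in seq_len(n))
    dpos <- dpos + dz[, (nn - 1) * d + seq_len(d), drop = FALSE]
  grads$pos <- dpos
  pjb <- linear_bw(dz, model$params$proj, cache$proj$cache)
  grads$proj <- pjb$grads
  dtok <- pjb$dx

  pd <- cache$pool$dim; hw <- cache$pool$hw
  dh <- aperm(array(dtok / hw, dim = c(pd[1], pd[4], pd[2], pd[3])),
              c(1, 3, 4, 2))

  n_stage <- cfg$backbone$stages
  ns <- length(model$params$scopes)
  grads$stages <- vector("list", n_stage)
  grads$scopes <- vector("list", ns)
  si <- ns
  for (k in rev(seq_len(max(n_stage, if (ns > 0) 1L else 0L)))) {
    if (k <= n_stage) {
      sc <- cache$stages[[k]]
      drl <- relu_bw(dh, sc$rl$cache)
      bnb <- bn2d_bw(drl, model$params$stages[[k]]$bn, sc$bn$cache)
      cvb <- conv2d_bw(bnb$dx, model$params$stages[[k]]$conv, sc$cv$cache)
      grads$stages[[k]] <- list(conv = cvb$grads, bn = bnb$grads)
      dh <- cvb$dx
    }
    if (si >= 1 && si == k) {
      sb <- scope_bundle(model, si)
      scb <- scope_backward(dh, sb, cache$scopes[[si]])
      grads$scopes[[si]] <- scb$grads
      dh <- scb$dx
      si <- si - 1L
    }
  }
  stem_bundle <- list(params = model$params$stem, scales = cfg$stem$scales)
  stb <- stem_backward(dh, stem_bundle, cache$stem)
  grads$stem <- stb$grads
  # reorder to match params layout
  grads[names(model$params)]
}

#' Derive a named ablation configuration
#'
#' Returns `base` with exactly one component swapped, so every ablation is
#' trained under otherwise identical settings.
#'
#' @param base a [model_config()] list.
#' @param name one of `"full"`, `"no-SCOPE"`, `"SCOPE-CBAM"`,
#'   `"SCOPE-ChannelOnly"`, `"SCOPE-SpatialOnly"`, `"SCOPE-NoGate"`,
#'   `"MDFS-OriginalOnly"`, `"MDFS-Fixed"`.
#' @return A modified configuration list.
#' @export
make_variant <- function(base = model_config(), name) {
  ok <- c("full", "no-SCOPE", "SCOPE-CBAM", "SCOPE-ChannelOnly",
          "SCOPE-SpatialOnly", "SCOPE-NoGate", "MDFS-OriginalOnly",
          "MDFS-Fixed")
  if (!name %in% ok)
    stop("make_variant: unknown variant '", name, "'")
  cfg <- base
  switch(name,
    "full" = cfg,
    "no-SCOPE" = { cfg$scope$variant <- "none"; cfg$scope$insertions <- 0L; cfg },
    "SCOPE-CBAM" = { cfg$scope$variant <- "cbam"; cfg },
    "SCOPE-ChannelOnly" = { cfg$scope$variant <- "channel_only"; cfg },
    "SCOPE-SpatialOnly" = { cfg$scope$variant <- "spatial_only"; cfg },
    "SCOPE-NoGate" = { cfg$scope$variant <- "no_gate"; cfg },
    "MDFS-OriginalOnly" = { cfg$stem$mode <- "original_only"; cfg },
    "MDFS-Fixed" = {
      cfg$stem$mode <- "fixed"
      ns <- 1 + length(cfg$stem$scales)
      cfg$stem$fixed_weights <- rep(1 / ns, ns)
      cfg
    })
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the configuration so a model can be rebuilt and the
#' parameters restored from one file.
#'
#' @param model a `pf_model`; `path` an `.rds` file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `pf_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "pf_model"))
  saveRDS(list(format = "pulseforge-checkpoint", version = 1L,
               params = model$params, state = model$state,
               config = model$config, meta = model$meta), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "pulseforge-checkpoint"))
    stop("load_checkpoint: not a pulseforge checkpoint")
  structure(list(params = obj$params, state = obj$state, config = obj$config,
                 meta = obj$meta, n_params = tree_count(obj$params)),
            class = "pf_model")
}
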