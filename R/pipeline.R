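# Dataset split protocols, the training loop, the evaluation harness and
# the ablation runner.

#' Dataset split protocols
#'
#' * `pure_60_40`: first 60% of subjects (manifest order) train, the rest
#'   test; no subject overlap.
#' * `ubfc_30_12`: first 30 subjects train, the remainder test (requires
#'   more than 30 subjects).
#' * `sequential_7_1_2`: clips in manifest order split 70% / 10% / 20% by
#'   count (floors, remainder to test).
#' * `cross_80_20`: 80% / 20% train/validation split of the source clips;
#'   the test set is the entire `target_manifest`.
#'
#' @param manifest data.frame with `subject_id` and `clip_id` columns, in
#'   dataset-documented order.
#' @param protocol one of the four protocol names.
#' @param target_manifest target-dataset manifest (required for
#'   `cross_80_20`).
#' @return A `split_spec`: list with `protocol` and `train`, `val`, `test`
#'   clip-id character vectors (disjoint; subject-level protocols never put
#'   one subject in two partitions).
#' @export
make_splits <- function(manifest,
                        protocol = c("pure_60_40", "ubfc_30_12",
                                     "sequential_7_1_2", "cross_80_20"),
                        target_manifest = NULL) {
  protocol <- match.arg(protocol)
  stopifnot(is.data.frame(manifest), nrow(manifest) > 0,
            all(c("subject_id", "clip_id") %in% names(manifest)))
  subjects <- unique(manifest$subject_id)
  res <- switch(protocol,
    pure_60_40 = {
      n_tr <- floor(0.6 * length(subjects))
      if (n_tr < 1 || n_tr >= length(subjects))
        stop("make_splits: pure_60_40 needs at least 2 subjects")
      tr_s <- subjects[seq_len(n_tr)]
      list(train = manifest$clip_id[manifest$subject_id %in% tr_s],
           val = character(0),
           test = manifest$clip_id[!manifest$subject_id %in% tr_s])
    },
    ubfc_30_12 = {
      if (length(subjects) < 31)
        stop("make_splits: ubfc_30_12 needs more than 30 subjects")
      tr_s <- subjects[1:30]
      list(train = manifest$clip_id[manifest$subject_id %in% tr_s],
           val = character(0),
           test = manifest$clip_id[!manifest$subject_id %in% tr_s])
    },
    sequential_7_1_2 = {
      l <- nrow(manifest)
      n_tr <- floor(0.7 * l); n_va <- floor(0.1 * l)
      if (n_tr < 1 || l - n_tr - n_va < 1)
        stop("make_splits: sequential_7_1_2 manifest too small")
      list(train = manifest$clip_id[seq_len(n_tr)],
           val = manifest$clip_id[n_tr + seq_len(n_va)],
           test = manifest$clip_id[(n_tr + n_va + 1):l])
    },
    cross_80_20 = {
      if (is.null(target_manifest))
        stop("make_splits: cross_80_20 needs a target_manifest")
      l <- nrow(manifest)
      n_tr <- floor(0.8 * l)
      if (n_tr < 1 || n_tr >= l)
        stop("make_splits: cross_80_20 source manifest too small")
      list(train = manifest$clip_id[seq_len(n_tr)],
           val = manifest$clip_id[(n_tr + 1):l],
           test = target_manifest$clip_id)
    })
  spec <- structure(c(list(protocol = protocol), res), class = "split_spec")
  check_split(spec, manifest, target_manifest)
  spec
}

# invariant checks run on every split: disjoint partitions, no subject
# leakage for subject-level protocols
check_split <- function(spec, manifest, target_manifest = NULL) {
  parts <- list(spec$train, spec$val, spec$test)
  all_ids <- unlist(parts)
  if (spec$protocol != "cross_80_20" && anyDuplicated(all_ids))
    stop("make_splits: partitions overlap")
  if (spec$protocol %in% c("pure_60_40", "ubfc_30_12")) {
    subj <- function(ids) unique(manifest$subject_id[manifest$clip_id %in% ids])
    if (length(intersect(subj(spec$train), subj(spec$test))) > 0)
      stop("make_splits: subject leakage between train and test")
  }
  invisible(spec)
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: AdamW with a unified
#' learning rate of 9e-3, batch size 4, 30 epochs, hybrid time-frequency
#' loss; the final-epoch checkpoint is the evaluation model (no early
#' stopping).
#'
#' @param lr learning rate (default 9e-3).
#' @param batch_size clips per optimization step (default 4).
#' @param epochs training epochs (default 30).
#' @param seed RNG seed for shuffling, dropout and initialization.
#' @param loss a [loss_config()].
#' @param weight_decay AdamW weight decay (default 0.01).
#' @param clip_grad optional global-norm gradient clip (NULL = off).
#' @param feature_lr_mult learning-rate multiplier for the convolutional
#'   feature extractor (stem, refinement blocks, conv stages) relative to
#'   `lr`.  The extractor's structured initialization carries the pulse at a
#'   small parameter scale, so it is tuned more gently than the temporal
#'   backbone and head (default 0.1).
#' @param warmup number of linear learning-rate warmup steps (0 = constant
#'   schedule from the first step).
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 9e-3, batch_size = 4L, epochs = 30L, seed = 1L,
                         loss = loss_config(), weight_decay = 0.01,
                         clip_grad = NULL, feature_lr_mult = 0.1,
                         warmup = 0L) {
  stopifnot(lr > 0, batch_size >= 1, epochs >= 0, feature_lr_mult > 0,
            warmup >= 0)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 loss = loss, weight_decay = weight_decay,
                 clip_grad = clip_grad, feature_lr_mult = feature_lr_mult,
                 warmup = as.integer(warmup)),
            class = "train_config")
}

# learning rate per top-level parameter group
group_lr <- function(config) {
  mult <- c(stem = config$feature_lr_mult, scopes = config$feature_lr_mult,
            stages = config$feature_lr_mult,
            proj = 1, pos = 1, blocks = 1, head = 1)
  config$lr * mult
}

samples_to_batch <- function(samples) {
  clip_batch(lapply(samples, function(s) s$clip))
}

samples_wave_matrix <- function(samples) {
  vapply(samples, function(s) s$bvp$wave,
         numeric(length(samples[[1]]$bvp$wave)))
}

#' Train a model
#'
#' Mini-batch AdamW optimization of the hybrid time-frequency loss.  Runs
#' are reproducible: the same seed yields identical loss curves.  Training
#' aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param model a [build_model()] result.
#' @param train_samples list of `synth_sample`-like objects (each with
#'   `$clip` and `$bvp`).
#' @param val_samples optional validation list (loss logged per epoch, not
#'   used for selection).
#' @param config a [train_config()].
#' @param verbose print per-epoch losses.
#' @return List with `model` (final-epoch parameters), `history`
#'   (data.frame: epoch, train_loss, val_loss).
#' @export
train_model <- function(model, train_samples, val_samples = NULL,
                        config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "pf_model"), length(train_samples) >= 1)
  fps <- train_samples[[1]]$clip$fps
  n <- length(train_samples)
  opt <- lapply(model$params, adamw_init)
  step_i <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  if (config$epochs == 0) return(list(model = model, history = hist))
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, 7000L + ep), sample.int(n))
    starts <- seq(1, n, by = config$batch_size)
    ep_loss <- 0; n_batch <- 0L
    for (b0 in starts) {
      idx <- ord[b0:min(b0 + config$batch_size - 1, n)]
      batch <- samples_to_batch(train_samples[idx])
      s_mat <- samples_wave_matrix(train_samples[idx])
      step_seed <- derive_seed(config$seed, 90000L + ep * 500L + b0)
      fw <- with_seed(step_seed,
                      model_forward(model, batch, training = TRUE))
      model <- fw$model
      lg <- batch_loss_grad(s_mat, fw$wave, fps, config$loss)
      if (!is.finite(lg$loss))
        stop("train_model: non-finite loss at epoch ", ep,
             " (diverged); try a lower learning rate")
      grads <- model_backward(model, fw$cache, lg$grad)
      if (!is.null(config$clip_grad))
        grads <- tree_clip_global(grads, config$clip_grad)
      step_i <- step_i + 1L
      lrs <- group_lr(config)
      if (config$warmup > 0 && step_i <= config$warmup)
        lrs <- lrs * (step_i / config$warmup)
      for (g in names(model$params)) {
        if (tree_count(model$params[[g]]) == 0) next
        up <- adamw_step(model$params[[g]], grads[[g]], opt[[g]],
                         lr = lrs[[g]], weight_decay = config$weight_decay)
        model$params[[g]] <- up$params
        opt[[g]] <- up$opt
      }
      ep_loss <- ep_loss + lg$loss
      n_batch <- n_batch + 1L
    }
    tr <- ep_loss / n_batch
    vl <- if (!is.null(val_samples) && length(val_samples) > 0) {
      vb <- samples_to_batch(val_samples)
      vw <- model_forward(model, vb, training = FALSE)$wave
      batch_loss_grad(samples_wave_matrix(val_samples), vw, fps,
                      config$loss)$loss
    } else NA_real_
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %d/%d train %.4f val %s", ep, config$epochs, tr,
                      ifelse(is.na(vl), "-", sprintf("%.4f", vl))))
  }
  list(model = model, history = hist)
}

#' Evaluate a model on test clips
#'
#' For each clip: forward pass (eval mode) -> zero-phase band-pass ->
#' spectral-peak HR readout; the reference HR is read from the ground-truth
#' BVP through the same readout.  Clips whose prediction is constant
#' (degenerate) are flagged and excluded from the aggregate metrics.
#'
#' @param model a `pf_model`, or a function `clip -> wave` (model stub).
#' @param test_samples list of samples with `$clip` and `$bvp`.
#' @param band HR readout band in Hz.
#' @param eval_batch clips per forward pass (memory knob).
#' @return An `eval_result`: list with `rows` (data.frame: clip_id,
#'   subject_id, pred_bpm, ref_bpm, snr, degenerate) and `report`
#'   ([hr_metrics()] on the valid rows).
#' @export
evaluate_model <- function(model, test_samples, band = c(0.6, 3.3),
                           eval_batch = 8L) {
  stopifnot(length(test_samples) >= 1)
  fps <- test_samples[[1]]$clip$fps
  n <- length(test_samples)
  waves <- vector("list", n)
  if (is.function(model)) {
    for (i in seq_len(n)) waves[[i]] <- model(test_samples[[i]]$clip)
  } else {
    for (b0 in seq(1, n, by = eval_batch)) {
      idx <- b0:min(b0 + eval_batch - 1, n)
      batch <- samples_to_batch(test_samples[idx])
      w <- model_forward(model, batch, training = FALSE)$wave
      for (j in seq_along(idx)) waves[[idx[j]]] <- w[, j]
    }
  }
  rows <- lapply(seq_len(n), function(i) {
    smp <- test_samples[[i]]
    ref <- estimate_hr(bandpass(smp$bvp$wave, fps, band), fps, band)
    wv <- waves[[i]]
    degen <- sd(wv) == 0
    if (!degen) {
      filt <- bandpass(wv, fps, band)
      degen <- sd(filt) == 0 || max(abs(filt)) == 0
    }
    pred <- if (degen) NA_real_ else estimate_hr(filt, fps, band)
    snr <- if (degen) NA_real_ else snr_db(filt, ref, fps, band)
    data.frame(clip_id = smp$clip$clip_id, subject_id = smp$clip$subject_id,
               pred_bpm = pred, ref_bpm = ref, snr = snr,
               degenerate = degen)
  })
  rows <- do.call(rbind, rows)
  ok <- !rows$degenerate
  report <- if (any(ok))
    hr_metrics(rows$pred_bpm[ok], rows$ref_bpm[ok], snr = rows$snr[ok])
  else NULL
  structure(list(rows = rows, report = report, band = band),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result: %d clips (%d degenerate)>\n",
              nrow(x$rows), sum(x$rows$degenerate)))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Train and evaluate a set of ablation variants
#'
#' Each named variant (see [make_variant()]) is built, trained and
#' evaluated under an identical seed, data and schedule; duplicated variant
#' names are dropped with a warning.
#'
#' @param base_config a [model_config()].
#' @param variants character vector of variant names.
#' @param train_samples,test_samples sample lists.
#' @param config a [train_config()].
#' @param verbose print progress.
#' @return List with `table` (data.frame of metrics keyed by variant) and
#'   `results` (named list of `eval_result`).
#' @export
run_ablation <- function(base_config, variants, train_samples, test_samples,
                         config = train_config(), verbose = FALSE) {
  stopifnot(length(variants) >= 1)
  if (anyDuplicated(variants)) {
    warning("run_ablation: duplicated variant names dropped")
    variants <- unique(variants)
  }
  results <- list()
  rows <- list()
  for (v in variants) {
    cfg <- make_variant(base_config, v)
    model <- build_model(cfg, seed = config$seed)
    tr <- train_model(model, train_samples, config = config,
                      verbose = verbose)
    ev <- evaluate_model(tr$model, test_samples)
    results[[v]] <- ev
    rp <- ev$report
    rows[[v]] <- data.frame(variant = v, mae = rp$mae, rmse = rp$rmse,
                            mape = rp$mape, rho = rp$rho, snr = rp$snr,
                            n = rp$n, seed = config$seed)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       results = results)
}

#' Read / write a YAML run configuration
#'
#' A flat YAML mirror of [model_config()], [train_config()] and the
#' synthesizer settings, used by the command-line interface.
#'
#' @param path YAML file path; `config` a nested list.
#' @return `read_run_config` returns the list; `write_run_config` returns
#'   `path` invisibly.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
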