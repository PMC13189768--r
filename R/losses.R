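# Hybrid time-frequency training objective.
#
# Time term: negative Pearson correlation between predicted and reference
# waveforms (1 - rho, in [0, 2], invariant to positive affine transforms).
# Frequency term: cross-entropy between the predicted wave's in-band
# periodogram (bins used as class logits, temperature 1) and the class index
# of the reference wave's spectral peak in the same band.  Total loss:
# alpha * L_time + L_freq with alpha = 0.2 by default.

#' Loss configuration
#'
#' @param alpha weight of the time-domain (negative Pearson) term,
#'   default 0.2.
#' @param band frequency window in Hz for the spectral term; default
#'   `c(0.6, 3.3)` (36-198 BPM).
#' @param n_fft FFT length for the spectral-loss bin grid; `NULL` means the
#'   waveform length (rectangular-window periodogram without zero padding).
#' @return A `loss_config` list.
#' @export
loss_config <- function(alpha = 0.2, band = c(0.6, 3.3), n_fft = NULL) {
  stopifnot(alpha >= 0, length(band) == 2, band[1] > 0, band[2] > band[1])
  structure(list(alpha = alpha, band = band, n_fft = n_fft),
            class = "loss_config")
}

#' Negative Pearson waveform loss
#'
#' `1 - cor(s, s_hat)`: 0 for perfectly correlated waves, 2 for perfectly
#' anti-correlated ones.
#'
#' @param s reference wave (numeric vector or [bvp_record()]).
#' @param s_hat predicted wave of the same length.
#' @return Scalar in `[0, 2]`.
#' @export
pearson_loss <- function(s, s_hat) {
  if (inherits(s, "bvp_record")) s <- s$wave
  if (length(s) != length(s_hat)) stop("pearson_loss: length mismatch")
  if (length(s) < 2) stop("pearson_loss: need at least 2 samples")
  if (sd(s) == 0 || sd(s_hat) == 0)
    stop("pearson_loss: degenerate (constant) signal")
  1 - cor(s, s_hat)
}

# gradient of pearson_loss w.r.t. s_hat
pearson_loss_grad <- function(s, s_hat) {
  n <- length(s)
  a <- s - mean(s)
  b <- s_hat - mean(s_hat)
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  rho <- sum(a * b) / (na * nb)
  db <- a / (na * nb) - rho * b / (nb * nb)
  g <- -(db - mean(db))
  g
}

# In-band DFT projection matrices for a length-len wave on an n-point grid.
spectral_basis <- function(len, fps, n_fft, band) {
  freqs <- (0:(n_fft %/% 2)) * fps / n_fft
  bins <- which(freqs >= band[1] & freqs <= band[2]) - 1L  # 0-based indices
  if (length(bins) == 0) stop("spectral band is empty on this FFT grid")
  t <- 0:(len - 1)
  ang <- outer(bins, t, function(k, tt) 2 * pi * k * tt / n_fft)
  list(bins = bins, freqs = bins * fps / n_fft,
       C = cos(ang), S = sin(ang), scale = 1 / (fps * len))
}

# In-band periodogram (density scaling) used for spectral-peak detection.
inband_psd <- function(wave, basis) {
  a <- basis$C %*% wave
  b <- basis$S %*% wave
  list(p = as.numeric(a * a + b * b) * basis$scale, a = a, b = b)
}

# Spectral-loss class logits: the log in-band periodogram.  Softmax of log
# power is the power distribution itself, so the cross-entropy reduces to
# -log(P_target / sum(P)): scale-invariant in the wave amplitude, zero when
# all in-band power sits in the target bin, and with gradients that stay
# usable at any output scale.  The floor keeps empty bins finite.
inband_log_logits <- function(psd) {
  s <- sum(psd$p)
  eps <- 1e-9 * (s / length(psd$p)) + 1e-300
  log(psd$p + eps)
}

#' Spectral-peak cross-entropy loss
#'
#' The in-band periodogram bins of the predicted wave are treated as class
#' logits and scored with cross-entropy against the in-band spectral-peak
#' bin of the reference wave.  The loss is minimized as the predicted
#' spectrum concentrates on the true heart-rate bin.
#'
#' @param s reference wave; `s_hat` predicted wave of the same length.
#' @param fps sampling rate in Hz.
#' @param config a [loss_config()].
#' @return Positive scalar.
#' @export
spectral_loss <- function(s, s_hat, fps, config = loss_config()) {
  if (inherits(s, "bvp_record")) { fps <- s$fps; s <- s$wave }
  if (length(s) != length(s_hat)) stop("spectral_loss: length mismatch")
  n_fft <- config$n_fft %||% length(s)
  basis <- spectral_basis(length(s), fps, n_fft, config$band)
  target <- which.max(inband_psd(s, basis)$p)
  logits <- inband_log_logits(inband_psd(s_hat, basis))
  m <- max(logits)
  lse <- m + log(sum(exp(logits - m)))
  lse - logits[target]
}

spectral_loss_grad <- function(s, s_hat, fps, config = loss_config()) {
  n_fft <- config$n_fft %||% length(s)
  basis <- spectral_basis(length(s), fps, n_fft, config$band)
  target <- which.max(inband_psd(s, basis)$p)
  pred <- inband_psd(s_hat, basis)
  s_tot <- sum(pred$p)
  eps <- 1e-9 * (s_tot / length(pred$p)) + 1e-300
  # L = log(sum(P + eps)) - log(P_target + eps)
  dP <- rep(1 / (s_tot + length(pred$p) * eps), length(pred$p))
  dP[target] <- dP[target] - 1 / (pred$p[target] + eps)
  dP <- dP * basis$scale
  as.numeric(crossprod(basis$C, 2 * dP * pred$a) +
               crossprod(basis$S, 2 * dP * pred$b))
}

#' Total training loss
#'
#' `alpha * pearson_loss + spectral_loss`.
#'
#' @inheritParams spectral_loss
#' @return Scalar.
#' @export
total_loss <- function(s, s_hat, fps, config = loss_config()) {
  if (inherits(s, "bvp_record")) { fps <- s$fps; s <- s$wave }
  config$alpha * pearson_loss(s, s_hat) +
    spectral_loss(s, s_hat, fps, config)
}

# Batch loss and gradient over a D x N wave matrix (mean over clips).
batch_loss_grad <- function(s_mat, wave, fps, config) {
  n <- ncol(wave)
  loss <- 0
  grad <- matrix(0, nrow(wave), n)
  for (i in seq_len(n)) {
    s <- s_mat[, i]; sh <- wave[, i]
    if (sd(sh) == 0) {
      # degenerate constant prediction: only the spectral term is defined
      loss <- loss + spectral_loss(s, sh, fps, config)
      grad[, i] <- spectral_loss_grad(s, sh, fps, config)
    } else {
      loss <- loss + config$alpha * pearson_loss(s, sh) +
        spectral_loss(s, sh, fps, config)
      grad[, i] <- config$alpha * pearson_loss_grad(s, sh) +
        spectral_loss_grad(s, sh, fps, config)
    }
  }
  list(loss = loss / n, grad = grad / n)
}
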