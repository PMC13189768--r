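# Waveform post-processing and heart-rate evaluation: zero-phase band-pass
# filtering, periodogram power spectra, PSD-peak HR readout, the rPPG SNR
# convention (fundamental + first harmonic windows over in-band residual),
# MAE/RMSE/MAPE/Pearson metrics with Bland-Altman agreement, and the
# classical GREEN spatial-mean baseline.

#' Zero-phase band-pass filter
#'
#' Order-4 Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), so the output is phase-neutral and the same length
#' as the input.
#'
#' @param wave numeric vector or [bvp_record()].
#' @param fps sampling rate in Hz (taken from a `bvp_record` input).
#' @param band `c(f_lo, f_hi)` in Hz, inside the Nyquist range.
#' @return Filtered numeric vector.
#' @export
bandpass <- function(wave, fps, band = c(0.6, 3.3)) {
  if (inherits(wave, "bvp_record")) { fps <- wave$fps; wave <- wave$wave }
  check_band(band, fps)
  bf <- signal::butter(2, band * 2 / fps, type = "pass")
  as.numeric(signal::filtfilt(bf, wave - mean(wave)))
}

check_band <- function(band, fps) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= fps / 2)
    stop("band must satisfy 0 < f_lo < f_hi < fps/2")
  invisible(band)
}

#' One-sided periodogram
#'
#' Rectangular-window periodogram on an `n_fft`-point grid (the wave is
#' zero-padded or truncated to `n_fft`), scaled as a power spectral density
#' so that summing `power * (fps / n_fft)` recovers the mean squared signal
#' (Parseval-consistent).
#'
#' @param wave numeric vector (length >= 2) or [bvp_record()].
#' @param fps sampling rate (Hz).
#' @param n_fft grid length; default `max(512, length(wave))`.
#' @return A `spectrum_estimate`: list with `freqs` (Hz, strictly
#'   increasing), `power` (>= 0) and `method`.
#' @export
power_spectrum <- function(wave, fps, n_fft = NULL) {
  if (inherits(wave, "bvp_record")) { fps <- wave$fps; wave <- wave$wave }
  stopifnot(length(wave) >= 2)
  len <- length(wave)
  n_fft <- max(n_fft %||% 512L, len)  # zero-pad only, never truncate
  x <- c(wave, numeric(n_fft - len))
  sp <- fft(x)
  half <- n_fft %/% 2
  p <- Mod(sp[1:(half + 1)])^2 / (fps * len)
  # one-sided density: double every bin that has a mirrored counterpart
  inner <- 2:(half + if (n_fft %% 2 == 0) 0 else 1)
  p[inner] <- 2 * p[inner]
  structure(list(freqs = (0:half) * fps / n_fft, power = p,
                 method = "periodogram", n_fft = n_fft, fps = fps),
            class = "spectrum_estimate")
}

# Remove a least-squares linear trend (suppresses sub-band drift that a
# short window cannot otherwise separate from the pulse band).
detrend_linear <- function(wave) {
  n <- length(wave)
  t <- seq_len(n) - (n + 1) / 2
  wave - mean(wave) - t * (sum(t * wave) / sum(t * t))
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Heart rate from the in-band spectral peak
#'
#' Returns `60 *` the frequency of the in-band periodogram maximum (ties
#' broken toward the lower frequency).  The wave is linearly detrended and
#' Hann-windowed first, so slow illumination drift cannot leak into the
#' pulse band on short windows; the readout grid is zero-padded to `n_fft`
#' bins so its resolution is independent of the training loss grid.
#'
#' @param wave numeric vector or [bvp_record()].
#' @param fps sampling rate (Hz).
#' @param band HR search band in Hz, default `c(0.6, 3.3)` (36-198 BPM).
#' @param n_fft readout FFT length, default 512.
#' @return Heart rate in BPM.
#' @export
estimate_hr <- function(wave, fps, band = c(0.6, 3.3), n_fft = 512L) {
  if (inherits(wave, "bvp_record")) { fps <- wave$fps; wave <- wave$wave }
  check_band(band, fps)
  w <- detrend_linear(wave) * hann_window(length(wave))
  ps <- power_spectrum(w, fps, n_fft)
  sel <- ps$freqs >= band[1] & ps$freqs <= band[2]
  if (!any(sel)) stop("estimate_hr: band empty on the FFT grid")
  pw <- ps$power[sel]
  if (max(pw) <= 0) stop("estimate_hr: zero in-band power (degenerate signal)")
  60 * ps$freqs[sel][which.max(pw)]
}

#' Signal-to-noise ratio of a pulse wave (dB)
#'
#' The rPPG convention: the ratio of periodogram power inside windows of
#' half-width `win_hz` around the reference fundamental `f = ref_hr / 60`
#' and its first harmonic `2f`, over the remaining power inside `band`.
#'
#' @param wave numeric vector or [bvp_record()].
#' @param ref_hr reference heart rate (BPM); its fundamental must lie in
#'   `band`.
#' @param fps sampling rate (Hz).
#' @param band evaluation band in Hz (default `c(0.6, 3.3)`).
#' @param win_hz half-width of the signal windows (default 0.1 Hz).
#' @param n_fft FFT length for the readout grid (default 512).
#' @return SNR in dB.
#' @export
snr_db <- function(wave, ref_hr, fps, band = c(0.6, 3.3), win_hz = 0.1,
                   n_fft = 512L) {
  if (inherits(wave, "bvp_record")) { fps <- wave$fps; wave <- wave$wave }
  check_band(band, fps)
  f0 <- ref_hr / 60
  if (f0 < band[1] || f0 > band[2])
    stop("snr_db: reference HR outside the evaluation band")
  w <- detrend_linear(wave) * hann_window(length(wave))
  ps <- power_spectrum(w, fps, n_fft)
  inband <- ps$freqs >= band[1] & ps$freqs <= band[2]
  sig <- inband & ((abs(ps$freqs - f0) <= win_hz) |
                     (abs(ps$freqs - 2 * f0) <= win_hz))
  noise <- inband & !sig
  s <- sum(ps$power[sig]); n <- sum(ps$power[noise])
  10 * log10(s / max(n, .Machine$double.xmin))
}

#' Heart-rate agreement metrics
#'
#' MAE, RMSE, MAPE, the Pearson correlation of predicted vs reference HR
#' pairs, and Bland-Altman agreement (mean bias and 1.96 SD limits of
#' agreement of the paired differences).
#'
#' @param pred,ref equal-length numeric vectors of HR in BPM.
#' @param snr optional per-pair SNR values (dB) averaged into the report.
#' @return A `metric_report`: list with `mae`, `rmse`, `mape`, `rho`, `snr`,
#'   `bland_altman` (`bias`, `loa_low`, `loa_high`) and `n`.  `rho` is `NA`
#'   when the references are constant or `n < 2`.
#' @export
hr_metrics <- function(pred, ref, snr = NULL) {
  if (length(pred) != length(ref)) stop("hr_metrics: length mismatch")
  n <- length(pred)
  if (n < 1) stop("hr_metrics: need at least one pair")
  if (any(ref == 0)) stop("hr_metrics: reference HR of 0 is not allowed")
  d <- pred - ref
  mae <- mean(abs(d))
  rmse <- sqrt(mean(d^2))
  mape <- 100 * mean(abs(d) / abs(ref))
  rho <- if (n >= 2 && sd(ref) > 0 && sd(pred) > 0) cor(pred, ref) else NA_real_
  bias <- mean(d)
  sdd <- if (n >= 2) sd(d) else 0
  structure(list(mae = mae, rmse = rmse, mape = mape, rho = rho,
                 snr = if (is.null(snr)) NA_real_ else mean(snr),
                 bland_altman = list(bias = bias,
                                     loa_low = bias - 1.96 * sdd,
                                     loa_high = bias + 1.96 * sdd),
                 n = n),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "MAE %.3f BPM | RMSE %.3f BPM | MAPE %.2f%% | rho %s | SNR %s dB | n=%d\n",
    x$mae, x$rmse, x$mape,
    ifelse(is.na(x$rho), "NA", sprintf("%.3f", x$rho)),
    ifelse(is.na(x$snr), "NA", sprintf("%.2f", x$snr)), x$n))
  ba <- x$bland_altman
  cat(sprintf("Bland-Altman bias %.3f BPM, LoA [%.3f, %.3f]\n",
              ba$bias, ba$loa_low, ba$loa_high))
  invisible(x)
}

#' GREEN channel baseline
#'
#' The classical rPPG baseline: the spatial mean of the green channel per
#' frame, band-pass filtered.
#'
#' @param clip a 3-channel [frame_clip()].
#' @param band filter band in Hz.
#' @return Length-`D` numeric wave.
#' @export
green_baseline <- function(clip, band = c(0.6, 3.3)) {
  stopifnot(inherits(clip, "frame_clip"))
  d <- dim(clip$frames)
  if (d[2] != 3) stop("green_baseline: clip must have 3 channels")
  g <- apply(clip$frames[, 2, , , drop = FALSE], 1, mean)
  bandpass(g, clip$fps, band)
}
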