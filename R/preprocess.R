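# Signal conditioning chain: trial cutting -> notch -> bandpass ->
# downsampling -> drift removal -> region averaging. All filters are applied
# zero-phase (forward-backward), so the chain is linear and phase-free.

#' Preprocessing configuration
#'
#' Defaults follow the conditioning chain for mixed EEG/MMG recordings:
#' a 49-51 Hz power-line notch, a 25-tap Hamming-window FIR bandpass with
#' edges 0.016-256 Hz applied at the original 1 kHz rate, decimation to
#' 250 Hz behind an anti-alias lowpass, and drift removal by subtracting an
#' order-10 Butterworth lowpass at 1 Hz.
#'
#' @param notch_band Stop band of the power-line notch in Hz.
#' @param bandpass Passband edges in Hz.
#' @param bandpass_taps FIR length (window width) of the bandpass.
#' @param downsample_to Target rate in Hz; must divide the input rate.
#' @param drift_order,drift_cutoff_hz Order and cutoff of the drift lowpass.
#' @param min_trial_s Minimum usable trial duration in seconds.
#' @return An object of class `preproc_config`.
#' @export
preproc_config <- function(notch_band = c(49, 51), bandpass = c(0.016, 256),
                           bandpass_taps = 25, downsample_to = 250,
                           drift_order = 10, drift_cutoff_hz = 1,
                           min_trial_s = 3) {
  if (notch_band[1] < bandpass[1] || notch_band[2] > bandpass[2])
    stop_config("preproc_config: notch band must lie inside the bandpass")
  structure(list(notch_band = notch_band, bandpass = bandpass,
                 bandpass_taps = as.integer(bandpass_taps),
                 downsample_to = downsample_to, drift_order = drift_order,
                 drift_cutoff_hz = drift_cutoff_hz, min_trial_s = min_trial_s),
            class = "preproc_config")
}

# ---- zero-phase Butterworth as a cascade of biquads -------------------------
# High-order Butterworth lowpasses at very low normalized cutoffs (the drift
# filter runs order 10 at 1 Hz / 250 Hz) are numerically fragile in direct
# transfer-function form, so the filter is realised as second-order sections
# derived from the analog prototype poles via the bilinear transform.
butter_lowpass_sos <- function(order, cutoff_hz, fs) {
  stopifnot(order >= 1, cutoff_hz > 0, cutoff_hz < fs / 2)
  K <- 2 * fs
  wc <- K * tan(pi * cutoff_hz / fs)     # prewarped analog cutoff
  k <- seq_len(floor(order / 2))
  theta <- pi * (2 * k + order - 1) / (2 * order)
  sections <- lapply(theta, function(th) {
    re <- wc * cos(th)                   # Re of analog pole pair (negative)
    d0 <- K^2 - 2 * re * K + wc^2
    list(b = wc^2 * c(1, 2, 1) / d0,
         a = c(1, (-2 * K^2 + 2 * wc^2) / d0, (K^2 + 2 * re * K + wc^2) / d0))
  })
  if (order %% 2 == 1) {                 # one real pole at -wc
    d0 <- K + wc
    sections <- c(sections, list(list(b = wc * c(1, 1) / d0,
                                      a = c(1, (wc - K) / d0))))
  }
  sections
}

# Zero-phase (forward-backward) filtering with odd-reflection end padding,
# which suppresses the start-up transients that zero initial conditions
# would inject into signals with offsets or trends.
zero_phase <- function(b, a, x, npad) {
  n <- length(x)
  npad <- min(n - 1L, npad)
  g <- sum(b) / sum(a)                   # DC gain, to absorb the operating point
  one_pass <- function(v) {
    v0 <- v[1]
    as.numeric(signal::filter(b, a, v - v0)) + g * v0
  }
  xp <- c(2 * x[1] - x[(npad + 1L):2],
          x,
          2 * x[n] - x[(n - 1L):(n - npad)])
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  y[(npad + 1L):(npad + n)]
}

filtfilt_sos <- function(sections, x, npad) {
  for (s in sections) x <- zero_phase(s$b, s$a, x, npad)
  x
}

lowpass_zero_phase <- function(x, fs, cutoff_hz, order) {
  npad <- ceiling(4 * fs / cutoff_hz)
  filtfilt_sos(butter_lowpass_sos(order, cutoff_hz, fs), x, npad)
}

# Apply a single-channel filter to every channel of a record.
apply_channels <- function(record, fun, fs_out = record$fs_hz) {
  filtered <- t(apply(record$samples, 1, fun))
  signal_record(filtered, fs_hz = fs_out,
                channel_names = rownames(record$samples),
                triggers = record$triggers, subject_id = record$subject_id,
                trial_id = record$trial_id, task = record$task)
}

#' Cut a trial to its analysis window
#'
#' `"plateau"` restricts the record to the isometric plateau between triggers
#' 2 and 3. `"mvic"` does the same but, when the plateau is shorter than
#' `min_s`, shifts the start earlier (bounded by trigger 1, the force
#' increase) until at least `min_s` seconds are retained. `"full"` keeps the
#' whole record (resting trials with open eyes use the entire duration).
#'
#' @param record A [signal_record()] with triggers (for plateau/mvic).
#' @param mode One of `"plateau"`, `"mvic"`, `"full"`.
#' @param min_s Minimum duration in seconds enforced by `"mvic"`.
#' @return The cut [signal_record()]; triggers are shifted to the new origin.
#' @export
cut_trial <- function(record, mode = c("plateau", "mvic", "full"), min_s = 3) {
  mode <- match.arg(mode)
  if (mode == "full") return(record)
  if (is.null(record$triggers))
    stop_config("cut_trial: record has no triggers")
  t1 <- record$triggers[1]; t2 <- record$triggers[2]; t3 <- record$triggers[3]
  if (t3 <= t2)
    stop_config("invalid triggers: t3 (%g s) must exceed t2 (%g s)", t3, t2)
  start <- t2
  if (mode == "mvic" && t3 - t2 < min_s) {
    start <- max(t1, t3 - min_s)
    if (t3 - start < min_s - 1e-9)
      stop_config(paste0("cut_trial: cannot reach %g s within the record ",
                         "(plateau %g s, trigger 1 at %g s)"),
                  min_s, t3 - t2, t1)
  }
  fs <- record$fs_hz
  idx <- (round(start * fs) + 1L):round(t3 * fs)
  out <- record
  out$samples <- record$samples[, idx, drop = FALSE]
  out$triggers <- c(0, max(0, t2 - start), t3 - start)
  out
}

#' Power-line notch filter
#'
#' Zero-phase order-2 Butterworth band-stop over `band`. Attenuation at the
#' band centre exceeds 20 dB while tones one octave away pass within 1 dB.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param band Stop band `c(low, high)` in Hz, inside the Nyquist range.
#' @return Filtered signal of the same length.
#' @export
notch_filter <- function(x, fs, band = c(49, 51)) {
  if (band[2] >= fs / 2 || band[1] <= 0)
    stop_config("notch_filter: band [%g, %g] Hz outside (0, Nyquist = %g) Hz",
                band[1], band[2], fs / 2)
  bt <- signal::butter(2, band / (fs / 2), type = "stop")
  zero_phase(bt$b, bt$a, x, npad = ceiling(fs))
}

#' Windowed-sinc FIR bandpass
#'
#' A `taps`-tap Hamming-window FIR bandpass applied zero-phase. A kernel this
#' short cannot resolve the sub-hertz lower edge, so the exact DC component
#' is removed explicitly (mean subtraction) before filtering; sub-hertz
#' trends are handled later by [remove_drift()].
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz (the upper edge must stay below Nyquist,
#'   which ties this stage to the original 1 kHz rate for a 256 Hz edge).
#' @param band Passband edges `c(low, high)` in Hz.
#' @param taps FIR length.
#' @return Filtered signal of the same length.
#' @export
bandpass_filter <- function(x, fs, band = c(0.016, 256), taps = 25) {
  if (band[2] >= fs / 2)
    stop_config("bandpass_filter: upper edge %g Hz >= Nyquist %g Hz",
                band[2], fs / 2)
  h <- signal::fir1(taps - 1L, band / (fs / 2), type = "pass",
                    window = signal::hamming(taps))
  zero_phase(as.numeric(h), 1, x - mean(x), npad = 4L * taps)
}

#' Decimate a signal to a lower rate
#'
#' Applies an order-8 Butterworth anti-alias lowpass (cutoff `0.4 * to_hz`,
#' i.e. 100 Hz for 1000 -> 250 Hz) zero-phase, then keeps every
#' `from_hz / to_hz`-th sample.
#'
#' @param x Numeric signal sampled at `from_hz`.
#' @param from_hz,to_hz Input and target rates; their ratio must be integer.
#' @return Signal of length `ceiling(length(x) * to_hz / from_hz)`.
#' @export
downsample <- function(x, from_hz, to_hz) {
  ratio <- from_hz / to_hz
  if (abs(ratio - round(ratio)) > 1e-9)
    stop_config("downsample: %g Hz is not an integer multiple of %g Hz",
                from_hz, to_hz)
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(x)
  y <- lowpass_zero_phase(x, from_hz, 0.4 * to_hz, order = 8)
  y[seq(1L, length(y), by = ratio)]
}

#' Remove slow drift
#'
#' Subtracts the heavily lowpass-filtered signal (zero-phase Butterworth of
#' the given order and cutoff) so that the output oscillates around zero,
#' which the wavelet coherence estimator requires to avoid leakage.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz (normally the 250 Hz post-decimation rate).
#' @param order,cutoff_hz Drift lowpass parameters.
#' @return `x` minus its drift component.
#' @export
remove_drift <- function(x, fs, order = 10, cutoff_hz = 1) {
  x - lowpass_zero_phase(x, fs, cutoff_hz, order)
}

#' Cut several records to their common length
#'
#' All records are truncated to the shortest duration among them, keeping
#' the start. Needed whenever signals from different trials are paired.
#'
#' @param records Non-empty list of [signal_record()]s.
#' @return List of records, all with the minimum duration.
#' @export
truncate_to_common_length <- function(records) {
  if (length(records) == 0L)
    stop_config("truncate_to_common_length: empty record list")
  n_min <- min(vapply(records,
                      function(r) ncol(r$samples) / r$fs_hz, numeric(1)))
  lapply(records, function(r) {
    keep <- seq_len(round(n_min * r$fs_hz))
    r$samples <- r$samples[, keep, drop = FALSE]
    if (!is.null(r$triggers)) r$triggers <- pmin(r$triggers, n_min)
    r
  })
}

#' Run the full conditioning chain on one record
#'
#' Stages in fixed order: trial cut (mode chosen from the task label:
#' HIMA/PIMA use the plateau, MVIC the minimum-duration plateau rule, OpEy
#' the full record), notch, bandpass at the original rate, decimation,
#' drift removal, and finally EEG region averaging when a `region_map` is
#' given and the record carries raw electrode channels.
#'
#' @param record A raw [signal_record()].
#' @param config A [preproc_config()].
#' @param region_map Optional [default_region_map()]; skipped when `NULL` or
#'   when the record has no mapped electrode channels (e.g. synthetic records
#'   that already carry region-level channels).
#' @return The conditioned [signal_record()] at `config$downsample_to` Hz.
#' @export
preprocess_record <- function(record, config = preproc_config(),
                              region_map = NULL) {
  mode <- switch(record$task, MVIC = "mvic", OpEy = "full", "plateau")
  out <- cut_trial(record, mode, min_s = config$min_trial_s)
  fs <- out$fs_hz
  out <- apply_channels(out, function(x) {
    x <- notch_filter(x, fs, config$notch_band)
    x <- bandpass_filter(x, fs, config$bandpass, config$bandpass_taps)
    downsample(x, fs, config$downsample_to)
  }, fs_out = config$downsample_to)
  out <- apply_channels(out, function(x) {
    remove_drift(x, config$downsample_to, config$drift_order,
                 config$drift_cutoff_hz)
  })
  if (!is.null(region_map) &&
      any(unlist(region_map$channels) %in% rownames(out$samples)))
    out <- average_regions(out, region_map)
  out
}
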