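#' Specification of one synthetic two-subject trial
#'
#' A `trial_spec` bundles every tunable of the synthetic generator: the shared
#' mechanical drive (a ~10 Hz oscillator emulating the dominant frequency of
#' mechanical muscle-fibre oscillations), the coupling strength between the
#' two subjects, the EEG-like background model and the motor-task labels.
#'
#' @param duration_s Trial length in seconds (>= 3, the minimum usable trial).
#' @param fs_hz Sampling rate in samples per second; must exceed twice
#'   `osc_freq_hz`.
#' @param osc_freq_hz Centre frequency of the shared oscillator in Hz.
#' @param coupling Per-channel coupling coefficient in `[0, 1]`; 0 yields
#'   statistically independent subjects, 1 a noise-free common drive.
#' @param phase_jitter_sd Standard deviation (radians per sample) of the
#'   random-walk phase jitter of the oscillator. 0 gives a pure sinusoid.
#' @param alpha_band Two-element numeric, low/high edge in Hz of the EEG
#'   alpha-like rhythm added to the 1/f background.
#' @param one_over_f_exp Spectral exponent of the EEG background
#'   (power ~ 1/f^exp).
#' @param snr_db Named numeric with elements `mmg` and `eeg`: `mmg` is the
#'   signal-to-noise ratio (dB) of the MMG channels relative to the unit
#'   variance oscillation; `eeg` sets the power of the coupled component
#'   relative to the EEG background at `coupling = 1`. Use `Inf` for
#'   noise-free MMG channels.
#' @param seed Integer seed making the trial reproducible, or `NULL`.
#' @param task_a,task_b Motor-task label of subject A / B; one of
#'   `"HIMA"`, `"PIMA"`, `"MVIC"`, `"OpEy"`.
#'
#' @return An object of class `trial_spec`.
#' @export
#' @examples
#' spec <- trial_spec(duration_s = 10, seed = 1)
#' spec
trial_spec <- function(duration_s = 30, fs_hz = 1000, osc_freq_hz = 10,
                       coupling = 0.8, phase_jitter_sd = 0.05,
                       alpha_band = c(8, 15), one_over_f_exp = 1,
                       snr_db = c(mmg = 6, eeg = 0), seed = NULL,
                       task_a = "PIMA", task_b = "HIMA") {
  if (!is_scalar_num(duration_s) || duration_s < 3)
    stop_config("invalid spec: duration_s must be a number >= 3, got %s",
                format(duration_s))
  if (!is_scalar_num(fs_hz) || fs_hz <= 0)
    stop_config("invalid spec: fs_hz must be a positive number")
  if (!is_scalar_num(osc_freq_hz) || osc_freq_hz <= 0)
    stop_config("invalid spec: osc_freq_hz must be a positive number")
  if (fs_hz <= 2 * osc_freq_hz)
    stop_config("invalid spec: fs_hz (%g) must exceed 2 * osc_freq_hz (%g)",
                fs_hz, 2 * osc_freq_hz)
  if (!is_scalar_num(coupling) || coupling < 0 || coupling > 1)
    stop_config("invalid spec: coupling must lie in [0, 1]")
  if (!is_scalar_num(phase_jitter_sd) || phase_jitter_sd < 0)
    stop_config("invalid spec: phase_jitter_sd must be >= 0")
  if (length(alpha_band) != 2L || alpha_band[1] >= alpha_band[2])
    stop_config("invalid spec: alpha_band must be c(low, high) with low < high")
  snr <- c(mmg = 6, eeg = 0)
  snr[names(snr_db)] <- snr_db
  tasks <- c("HIMA", "PIMA", "MVIC", "OpEy")
  task_a <- match.arg(task_a, tasks)
  task_b <- match.arg(task_b, tasks)
  structure(
    list(duration_s = duration_s, fs_hz = fs_hz, osc_freq_hz = osc_freq_hz,
         coupling = coupling, phase_jitter_sd = phase_jitter_sd,
         alpha_band = as.numeric(alpha_band),
         one_over_f_exp = one_over_f_exp, snr_db = snr,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         task_a = task_a, task_b = task_b),
    class = "trial_spec")
}

#' @export
print.trial_spec <- function(x, ...) {
  cat("<trial_spec>", x$duration_s, "s @", x$fs_hz, "Hz;",
      "oscillator", x$osc_freq_hz, "Hz; coupling", x$coupling, "\n")
  cat("  tasks:", x$task_a, "(A) /", x$task_b, "(B);",
      "jitter sd", x$phase_jitter_sd, "rad;",
      "snr", paste(names(x$snr_db), x$snr_db, sep = "=", collapse = ", "),
      "dB\n")
  invisible(x)
}

n_samples <- function(spec) as.integer(round(spec$duration_s * spec$fs_hz))

#' Multichannel trial recording
#'
#' Container for one trial's samples from one subject: a channels x time
#' matrix, the sampling rate, the three synchronisation triggers (start of
#' measurement, start and end of the isometric plateau) and identifying
#' labels.
#'
#' @param samples Numeric matrix, channels in rows, samples in columns.
#' @param fs_hz Sampling rate in Hz.
#' @param channel_names Unique channel labels, one per row of `samples`.
#' @param triggers Numeric vector `c(t1, t2, t3)` in seconds with
#'   `t1 <= t2 < t3` and `t3` within the record.
#' @param subject_id,trial_id,task Labels carried through the pipeline.
#'
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(samples, fs_hz, channel_names = rownames(samples),
                          triggers = NULL, subject_id = "A",
                          trial_id = "trial1", task = "PIMA") {
  samples <- as.matrix(samples)
  if (is.null(channel_names))
    stop_config("signal_record: channel_names are required")
  if (anyDuplicated(channel_names))
    stop_config("signal_record: channel names must be unique")
  if (length(channel_names) != nrow(samples))
    stop_config("signal_record: %d channel names for %d rows",
                length(channel_names), nrow(samples))
  rownames(samples) <- channel_names
  dur <- ncol(samples) / fs_hz
  if (!is.null(triggers)) {
    triggers <- as.numeric(triggers)
    if (length(triggers) != 3L || triggers[1] > triggers[2] ||
        triggers[2] >= triggers[3])
      stop_config("signal_record: triggers must satisfy t1 <= t2 < t3")
    if (triggers[3] > dur + 1e-9)
      stop_config("signal_record: trigger t3 (%g s) beyond record end (%g s)",
                  triggers[3], dur)
  }
  structure(
    list(samples = samples, fs_hz = fs_hz, triggers = triggers,
         subject_id = subject_id, trial_id = trial_id, task = task),
    class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat("<signal_record>", x$subject_id, x$trial_id, paste0("(", x$task, "):"),
      nrow(x$samples), "channels x", ncol(x$samples), "samples @",
      x$fs_hz, "Hz\n")
  invisible(x)
}

record_duration <- function(record) ncol(record$samples) / record$fs_hz
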