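# Synthetic two-subject study generator.
#
# The generator emulates the statistical structure the coherence analysis
# assumes: a shared narrowband mechanical drive near 10 Hz, MMG-like channels
# that mix the shared drive with an independent local oscillation and sensor
# noise, EEG-like channels with a 1/f background plus alpha-band rhythm and a
# weak coupled component, and force/ACC channels recorded by one physical
# sensor and therefore identical in both records.

# Oscillator core without seed management; callers own the RNG state.
osc_core <- function(spec) {
  n <- n_samples(spec)
  tt <- (seq_len(n) - 1) / spec$fs_hz
  phase <- 2 * pi * spec$osc_freq_hz * tt + runif(1, 0, 2 * pi)
  if (spec$phase_jitter_sd > 0) {
    phase <- phase + cumsum(rnorm(n, 0, spec$phase_jitter_sd))
    # slow amplitude modulation: smooth interpolation through random knots
    knots <- max(4L, ceiling(spec$duration_s / 2))
    am <- 1 + 0.3 * approx(seq(0, spec$duration_s, length.out = knots),
                           rnorm(knots), xout = tt, rule = 2)$y
    x <- am * cos(phase)
  } else {
    x <- cos(phase)
  }
  x / sd(x)
}

# 1/f^exp background noise via spectral shaping of white noise (unit variance).
one_over_f_noise <- function(n, fs, exponent) {
  x <- rnorm(n)
  if (exponent <= 0) return(x)
  X <- fft(x)
  f <- fs * seq(0, n - 1) / n
  f[f > fs / 2] <- fs - f[f > fs / 2]     # fold to physical frequency
  g <- c(0, (f[-1] / f[2])^(-exponent / 2))
  y <- Re(fft(X * g, inverse = TRUE) / n)
  y / sd(y)
}

# Alpha-band rhythm: band-limited Gaussian noise (unit variance).
band_noise <- function(n, fs, band) {
  x <- rnorm(n)
  X <- fft(x)
  f <- fs * seq(0, n - 1) / n
  f[f > fs / 2] <- fs - f[f > fs / 2]
  keep <- f >= band[1] & f <= band[2]
  if (!any(keep)) stop_config("band_noise: band outside spectral grid")
  y <- Re(fft(X * keep, inverse = TRUE) / n)
  y / sd(y)
}

#' Shared narrowband oscillator of a coupled trial
#'
#' Generates the common mechanical drive of a synthetic trial pair: a
#' unit-variance oscillation centred at `spec$osc_freq_hz` whose phase follows
#' a random walk with per-sample jitter `spec$phase_jitter_sd` and whose
#' amplitude is slowly modulated. With zero jitter the deterministic limit is
#' returned, a pure (unit-variance) sinusoid.
#'
#' @param spec A [trial_spec()].
#' @return Numeric vector of `duration_s * fs_hz` samples, unit variance.
#' @export
#' @examples
#' x <- make_shared_oscillator(trial_spec(duration_s = 4, seed = 1))
#' sd(x)
make_shared_oscillator <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  with_seed(spec$seed, osc_core(spec))
}

eeg_region_names <- function() {
  c("FM", "C", "CP", "POc", "AFle", "TLle", "POle", "AFri", "TLri", "POri")
}

mmg_channel_names <- function() c("MMGtri", "MTGtri", "MMGobl")

# One subject's channels given the shared drive. RNG state owned by caller.
build_subject <- function(spec, osc, shared_force, shared_acc) {
  n <- n_samples(spec)
  cpl <- spec$coupling
  noise_sd <- 10^(-spec$snr_db[["mmg"]] / 20)
  mmg <- t(vapply(mmg_channel_names(), function(ch) {
    cpl * osc + noise_sd * rnorm(n)
  }, numeric(n)))
  eeg_gain <- cpl * 10^(spec$snr_db[["eeg"]] / 20)
  eeg <- t(vapply(eeg_region_names(), function(ch) {
    bg <- one_over_f_noise(n, spec$fs_hz, spec$one_over_f_exp) +
      0.6 * band_noise(n, spec$fs_hz, spec$alpha_band)
    bg / sd(bg) + eeg_gain * osc
  }, numeric(n)))
  rbind(eeg, mmg, force = shared_force, ACC = shared_acc)
}

#' Generate one coupled (or uncoupled) two-subject trial
#'
#' Builds the paired records of subjects A and B for one trial: per subject
#' ten EEG-region-like channels, three MMG-like channels, and the shared
#' force and ACC channels (identical in both records, as one physical sensor
#' serves both partners). Triggers are placed at 0, 5 % and 95 % of the
#' trial, so that the plateau cut retains the central 90 %.
#'
#' @param spec A [trial_spec()]; `spec$coupling` controls how strongly each
#'   subject's channels follow the shared oscillator.
#' @param trial_id Label stored in both records.
#' @return List with elements `a` and `b`, each a [signal_record()].
#' @export
#' @examples
#' pair <- make_trial_pair(trial_spec(duration_s = 5, seed = 42))
#' pair$a
make_trial_pair <- function(spec, trial_id = "trial1") {
  stopifnot(inherits(spec, "trial_spec"))
  with_seed(spec$seed, {
    n <- n_samples(spec)
    osc <- osc_core(spec)
    shared_force <- osc + 0.1 * rnorm(n)
    shared_acc <- osc + 0.1 * rnorm(n)
    trig <- c(0, 0.05, 0.95) * spec$duration_s
    rec <- function(subject, task) {
      signal_record(build_subject(spec, osc, shared_force, shared_acc),
                    fs_hz = spec$fs_hz, triggers = trig,
                    subject_id = subject, trial_id = trial_id, task = task)
    }
    list(a = rec("A", spec$task_a), b = rec("B", spec$task_b))
  })
}

#' Simulate a study of alternating-task trials
#'
#' Generates `n_trials` coupled trial pairs in the alternating task design:
#' odd trials have subject A pushing (PIMA) and B holding (HIMA), even trials
#' the reverse. Each trial draws its own child seed from `seed`.
#'
#' @param spec Base [trial_spec()]; task labels are overridden per trial.
#' @param n_trials Number of trials.
#' @param seed Study-level seed (or `NULL`).
#' @param durations_s Optional vector of per-trial durations in seconds.
#' @return List of trial pairs as returned by [make_trial_pair()], with a
#'   `configuration` attribute (`"A-PIMA_B-HIMA"` or `"B-PIMA_A-HIMA"`) each.
#' @export
simulate_study <- function(spec, n_trials = 6, seed = spec$seed,
                           durations_s = NULL) {
  stopifnot(inherits(spec, "trial_spec"), n_trials >= 1)
  seeds <- derive_seeds(seed, n_trials)
  lapply(seq_len(n_trials), function(i) {
    s <- spec
    s$seed <- seeds[[i]]
    if (!is.null(durations_s)) s$duration_s <- durations_s[[i]]
    if (i %% 2 == 1) {
      s$task_a <- "PIMA"; s$task_b <- "HIMA"
    } else {
      s$task_a <- "HIMA"; s$task_b <- "PIMA"
    }
    pair <- make_trial_pair(s, trial_id = sprintf("trial%02d", i))
    attr(pair, "configuration") <-
      if (i %% 2 == 1) "A-PIMA_B-HIMA" else "B-PIMA_A-HIMA"
    pair
  })
}
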