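# Wavelet coherence and the pointwise surrogate-data significance test.

#' Smoothed cross wavelet spectrum
#'
#' `CS(b, a) = <(Wx . Wy*)(b, a)>` where `< >` is an edge-normalized boxcar
#' running mean along time whose length is `smoothing_width` scales
#' (scale-proportional, so each frequency is smoothed over a fixed number of
#' oscillation cycles). `cross_spectrum(W, W)` is real and non-negative;
#' swapping the arguments conjugates the result.
#'
#' @param Wx,Wy `wavelet_cwt` objects (or complex matrices of equal shape)
#'   computed with the same configuration.
#' @param config The shared [wavelet_config()]; only needed when raw
#'   matrices are supplied together with `fs_map`.
#' @param fs_map Sampling rate of the coefficient time grid (taken from the
#'   `wavelet_cwt` objects when available).
#' @return Complex matrix of smoothed cross-spectral values.
#' @export
cross_spectrum <- function(Wx, Wy, config = wavelet_config(), fs_map = NULL) {
  if (inherits(Wx, "wavelet_cwt")) {
    fs_map <- Wx$fs_map
    hw <- Wx$plan$hw
    Wx <- Wx$W
  } else {
    if (is.null(fs_map))
      stop_config("cross_spectrum: fs_map required for raw matrices")
    hw <- pmax(1L, as.integer(round(
      config$smoothing_width * wavelet_scales(config) * fs_map / 2)))
  }
  if (inherits(Wy, "wavelet_cwt")) Wy <- Wy$W
  if (!all(dim(Wx) == dim(Wy)))
    stop_config("cross_spectrum: coefficient matrices differ in shape")
  P <- Wx * Conj(Wy)
  re <- .smooth_columns(Re(P), hw)
  im <- .smooth_columns(Im(P), hw)
  matrix(complex(real = re, imaginary = im), nrow = nrow(P))
}

new_coherence_map <- function(coh, freqs, times, fs_map, fs, config,
                              sig_mask = NULL, threshold = NULL) {
  stopifnot(nrow(coh) == length(times), ncol(coh) == length(freqs))
  structure(list(times = times, freqs = freqs, coh = coh,
                 sig_mask = sig_mask, threshold = threshold,
                 fs_map = fs_map, fs = fs, config = config),
            class = "coherence_map")
}

#' @export
print.coherence_map <- function(x, ...) {
  cat("<coherence_map>", length(x$times), "times x", length(x$freqs),
      "frequencies;", sprintf("%.1f-%.1f Hz over %.1f s;",
                              min(x$freqs), max(x$freqs), max(x$times)),
      if (is.null(x$sig_mask)) "no significance mask"
      else sprintf("%.1f%% significant", 100 * mean(x$sig_mask)), "\n")
  invisible(x)
}

#' Wavelet coherence of two signals
#'
#' Estimates the time-resolved coherence
#' `|<Wx Wy*>| / sqrt(<|Wx|^2> <|Wy|^2>)` on the 3-30 Hz (default)
#' time-frequency grid. The modulus lies in `[0, 1]`: 1 means a locally
#' fixed amplitude-and-phase relation over the smoothing window, values near
#' the null level mean no relation. Where an input is locally silent (both
#' auto-spectra vanish) the coherence is undefined and reported as 0 with a
#' warning.
#'
#' @param x,y Numeric signals of equal length (pair signals from different
#'   trials must first pass [truncate_to_common_length()]).
#' @param fs Sampling rate in Hz.
#' @param config A [wavelet_config()].
#' @return A `coherence_map` with fields `times` (s), `freqs` (Hz), `coh`
#'   (times x frequencies matrix in `[0, 1]`), and empty significance slots
#'   to be filled by [pointwise_significance()].
#' @export
#' @examples
#' fs <- 250; t <- seq(0, 8, by = 1 / fs)[-1]
#' x <- cos(2 * pi * 10 * t) + rnorm(length(t), 0, 0.5)
#' y <- cos(2 * pi * 10 * t + 1) + rnorm(length(t), 0, 0.5)
#' m <- wavelet_coherence(x, y, fs)
#' m
wavelet_coherence <- function(x, y, fs, config = wavelet_config()) {
  if (length(x) != length(y))
    stop_config("wavelet_coherence: signals differ in length (%d vs %d)",
                length(x), length(y))
  if (length(x) / fs < 3)
    stop_config("wavelet_coherence: insufficient data, need >= 3 s")
  plan <- cwt_plan(length(x), fs, config)
  Wx <- cwt_from_spectrum(kept_spectrum(x, plan), plan)
  Wy <- cwt_from_spectrum(kept_spectrum(y, plan), plan)
  if (sd(x) == 0 || sd(y) == 0)
    warning("wavelet_coherence: silent channel; coherence set to 0 where undefined")
  coh <- .coh_kernel(Wx, Wy, plan$hw)
  new_coherence_map(coh, plan$freqs, plan$times, plan$fs_map, fs, config)
}

# Phase-randomized surrogate: same amplitude spectrum, uniform random phases.
phase_randomize <- function(x) {
  n <- length(x)
  X <- fft(x)
  half <- seq(2L, ceiling(n / 2))
  X[half] <- Mod(X[half]) * exp(1i * runif(length(half), 0, 2 * pi))
  X[n + 2L - half] <- Conj(X[half])
  Re(fft(X, inverse = TRUE) / n)
}

surrogate_of <- function(x, type) {
  switch(type,
         phase = phase_randomize(x),
         white = rnorm(length(x), 0, sd(x)))
}

#' Pointwise surrogate-data significance test
#'
#' Marks the time-frequency pixels whose coherence exceeds what independent
#' surrogate pairs produce. For `n_surrogates` surrogate pairs the full
#' coherence is recomputed; per frequency row the empirical `1 - alpha`
#' quantile of all surrogate coherence values (pooled over time and
#' surrogates) forms the significance threshold, and `sig_mask = coh >
#' threshold` (strict). Deterministic under `config$seed`.
#'
#' @param x,y The signals the map was computed from.
#' @param map The `coherence_map` from [wavelet_coherence()] for `x`, `y`.
#' @param config The same [wavelet_config()]; `n_surrogates` must be at
#'   least 19 at `alpha = 0.05`.
#' @return The map with `sig_mask` (logical matrix) and `threshold`
#'   (per-frequency numeric) filled in.
#' @export
pointwise_significance <- function(x, y, map, config = map$config) {
  stopifnot(inherits(map, "coherence_map"))
  if (config$n_surrogates < ceiling(1 / config$alpha) - 1)
    stop_config("pointwise_significance: n_surrogates = %d insufficient at alpha = %g",
                config$n_surrogates, config$alpha)
  plan <- cwt_plan(length(x), map$fs, config)
  with_seed(config$seed, {
    nt <- plan$nt; nf <- length(plan$freqs)
    vals <- matrix(0, nt * config$n_surrogates, nf)
    for (s in seq_len(config$n_surrogates)) {
      xs <- surrogate_of(x, config$surrogate)
      ys <- surrogate_of(y, config$surrogate)
      Wx <- cwt_from_spectrum(kept_spectrum(xs, plan), plan)
      Wy <- cwt_from_spectrum(kept_spectrum(ys, plan), plan)
      vals[((s - 1) * nt + 1):(s * nt), ] <- .coh_kernel(Wx, Wy, plan$hw)
    }
    thr <- apply(vals, 2, quantile, probs = 1 - config$alpha, names = FALSE)
    map$threshold <- thr
    map$sig_mask <- sweep(map$coh, 2, thr, `>`)
    map
  })
}

# One-call convenience used by the significance-heavy loops: map + mask.
significant_coherence <- function(x, y, fs, config = wavelet_config()) {
  map <- wavelet_coherence(x, y, fs, config)
  pointwise_significance(x, y, map, config)
}
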