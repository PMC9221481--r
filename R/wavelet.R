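#' Wavelet analysis configuration
#'
#' Parameters of the Morlet continuous wavelet transform, the coherence
#' smoothing and the pointwise surrogate significance test. Frequency
#' borders default to 3-30 Hz, the band containing the mechanical muscle
#' oscillations (~10 Hz) and the sensorimotor EEG rhythms of interest.
#'
#' @param sigma Morlet bandwidth parameter (dimensionless); sigma = 6 gives
#'   roughly two-cycle time resolution near 10 Hz.
#' @param f_min,f_max Frequency borders of the analysis in Hz.
#' @param voices_per_octave Density of the logarithmic scale grid.
#' @param smoothing_width Length of the boxcar time-smoothing window in
#'   multiples of the scale `a = 1/(2 pi f)`. The default 24 corresponds to
#'   about two e-folding widths of the sigma = 6 Morlet envelope
#'   (~3.8 cycles) at every frequency.
#' @param n_surrogates Number of surrogate pairs for the significance test;
#'   at least 19 so the alpha = 0.05 null quantile is estimable.
#' @param alpha Pointwise significance level.
#' @param seed Seed for surrogate generation, or `NULL`.
#' @param surrogate Null model: `"phase"` randomizes the Fourier phases of
#'   each input (preserves the amplitude spectrum, destroys cross-phase),
#'   `"white"` uses variance-matched Gaussian white noise.
#' @param time_decim Decimation factor of the coherence time grid relative
#'   to the sampling rate. All analysis filters are band-limited well below
#'   the decimated Nyquist, so the decimated transform is exact (not an
#'   approximation); the factor is reduced automatically when the spectral
#'   support of the highest-frequency wavelet requires it.
#' @param coi Mask the cone of influence (edge region where the wavelet
#'   support leaves the record)? Off by default; coherence is reported on
#'   the full time-frequency rectangle.
#' @return An object of class `wavelet_config`.
#' @export
wavelet_config <- function(sigma = 6, f_min = 3, f_max = 30,
                           voices_per_octave = 12, smoothing_width = 24,
                           n_surrogates = 100, alpha = 0.05, seed = NULL,
                           surrogate = c("phase", "white"), time_decim = 4,
                           coi = FALSE) {
  if (f_min <= 0 || f_min >= f_max)
    stop_config("wavelet_config: need 0 < f_min < f_max")
  if (alpha <= 0 || alpha >= 1)
    stop_config("wavelet_config: alpha must lie in (0, 1)")
  if (n_surrogates < ceiling(1 / alpha) - 1)
    stop_config(paste0("wavelet_config: n_surrogates = %d too small to ",
                       "estimate the alpha = %g quantile (need >= %d)"),
                n_surrogates, alpha, ceiling(1 / alpha) - 1)
  if (sigma <= 0) stop_config("wavelet_config: sigma must be positive")
  structure(list(sigma = sigma, f_min = f_min, f_max = f_max,
                 voices_per_octave = voices_per_octave,
                 smoothing_width = smoothing_width,
                 n_surrogates = as.integer(n_surrogates), alpha = alpha,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 surrogate = match.arg(surrogate),
                 time_decim = as.integer(time_decim), coi = coi),
            class = "wavelet_config")
}

# Logarithmic frequency grid from f_min to f_max (f_max always included).
wavelet_freqs <- function(config) {
  f <- config$f_min *
    2^seq(0, log2(config$f_max / config$f_min), by = 1 / config$voices_per_octave)
  if (max(f) < config$f_max - 1e-12) f <- c(f, config$f_max)
  f
}

wavelet_scales <- function(config) 1 / (2 * pi * wavelet_freqs(config))

# Fourier transform of the Morlet wavelet g_sigma(x) = e^{ix} e^{-x^2/2s^2}:
# ghat(w) = sigma sqrt(2 pi) exp(-sigma^2 (w - 1)^2 / 2), real and positive.
morlet_ghat <- function(omega, sigma) {
  sigma * sqrt(2 * pi) * exp(-sigma^2 * (omega - 1)^2 / 2)
}

# Geometry of the transform: FFT length, kept-bin count, decimation and the
# filter bank evaluated on the kept bins. The analytic Morlet has no
# negative-frequency support and decays like a Gaussian above its centre
# frequency, so keeping the first nfft/decim bins is exact to < 1e-6 of the
# peak provided the decimated Nyquist clears the highest-frequency filter.
cwt_plan <- function(n, fs, config) {
  scales <- wavelet_scales(config)
  sigma <- config$sigma
  pad <- ceiling(4 * sigma * max(scales) * fs)
  nfft <- nextn(n + pad, 2)
  decim <- max(1L, config$time_decim)
  while (decim > 1L) {
    # filter value at the edge of the kept band, relative to peak 1
    edge <- exp(-sigma^2 * (fs / decim / config$f_max - 1)^2 / 2)
    if (fs / decim > config$f_max && edge < 1e-6) break
    decim <- decim %/% 2L
  }
  L <- nfft %/% decim
  fgrid <- fs * (seq_len(L) - 1) / nfft
  H <- vapply(scales, function(a) morlet_ghat(a * 2 * pi * fgrid, sigma),
              numeric(L))
  nt <- ceiling(n / decim)
  list(nfft = nfft, L = L, decim = decim, nt = nt, H = H,
       freqs = wavelet_freqs(config), scales = scales,
       fs_map = fs / decim,
       times = (seq_len(nt) - 1) * decim / fs,
       hw = pmax(1L, as.integer(round(
         config$smoothing_width * scales * fs / decim / 2))))
}

# CWT of one signal given a plan and its padded spectrum's kept bins.
cwt_from_spectrum <- function(Xkept, plan) {
  W <- mvfft(Xkept * plan$H, inverse = TRUE) / plan$nfft
  W[seq_len(plan$nt), , drop = FALSE]
}

kept_spectrum <- function(x, plan) {
  X <- fft(c(x, numeric(plan$nfft - length(x))))
  X[seq_len(plan$L)]
}

#' Morlet continuous wavelet transform
#'
#' Computes `W(b, a) = (1/a) \int g*((t - b)/a) s(t) dt` with the Morlet
#' mother wavelet `g_sigma(x) = exp(ix) exp(-x^2 / (2 sigma^2))` on a
#' logarithmic scale grid spanning `f_min` to `f_max`, via FFT convolution.
#' The transform is evaluated on a time grid decimated by
#' `config$time_decim` (exact, see [wavelet_config()]).
#'
#' @param x Numeric signal, at least 3 s long.
#' @param fs Sampling rate in Hz.
#' @param config A [wavelet_config()].
#' @return A list of class `wavelet_cwt`: complex coefficient matrix `W`
#'   (time in rows, frequencies in columns), `freqs` (Hz), `times` (s),
#'   `fs_map` (rate of the time grid), and the plan geometry.
#' @export
morlet_cwt <- function(x, fs, config = wavelet_config()) {
  if (length(x) / fs < 3)
    stop_config("morlet_cwt: insufficient data, need >= 3 s (got %.2f s)",
                length(x) / fs)
  plan <- cwt_plan(length(x), fs, config)
  W <- cwt_from_spectrum(kept_spectrum(x, plan), plan)
  structure(list(W = W, freqs = plan$freqs, times = plan$times,
                 fs_map = plan$fs_map, plan = plan, fs = fs),
            class = "wavelet_cwt")
}

#' @export
print.wavelet_cwt <- function(x, ...) {
  cat("<wavelet_cwt>", nrow(x$W), "times x", ncol(x$W), "frequencies (",
      round(min(x$freqs), 2), "-", round(max(x$freqs), 2), "Hz )\n")
  invisible(x)
}
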