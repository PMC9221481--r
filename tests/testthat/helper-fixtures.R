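# Fixture builders shared across test files.

# A coherence map built directly from a mask (and optional coherence values),
# for patch-extraction tests that need full control over the grid.
toy_map <- function(mask, coh = NULL, times = NULL, freqs = NULL,
                    f_lim = c(3, 30)) {
  nt <- nrow(mask); nf <- ncol(mask)
  if (is.null(times)) times <- seq(0, by = 0.2, length.out = nt)
  if (is.null(freqs)) freqs <- seq(f_lim[1], f_lim[2], length.out = nf)
  if (is.null(coh)) coh <- matrix(0.5, nt, nf) + 0.4 * mask
  cfg <- wavelet_config(f_min = f_lim[1], f_max = f_lim[2])
  m <- wavecoh:::new_coherence_map(coh, freqs, times,
                                   fs_map = 1 / diff(times[1:2]),
                                   fs = 4 / diff(times[1:2]), config = cfg)
  m$sig_mask <- mask
  m
}

fast_cfg <- function(...) {
  wavelet_config(n_surrogates = 24, ...)
}
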