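# Independent reference implementations used as oracles. These deliberately
# use brute force and stay independent of the package's code paths.

# Exhaustive flood-fill labeling of a logical matrix, 4-connectivity.
flood_fill_labels <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    comp <- comp + 1L
    queue <- list(c(i, j))
    lab[i, j] <- comp
    while (length(queue) > 0) {
      cur <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ni <- cur[1] + d[1]; nj <- cur[2] + d[2]
        if (ni >= 1 && ni <= nrow(mask) && nj >= 1 && nj <= ncol(mask) &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- comp
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# Canonical partition signature of a labeling (order-independent comparison).
partition_signature <- function(lab) {
  cells <- which(lab != 0L)
  groups <- split(cells, lab[cells])
  paste(sort(vapply(groups, function(g) paste(sort(g), collapse = ","),
                    character(1))), collapse = "|")
}

# Exact two-sided signed-rank p value by enumerating all 2^n sign vectors.
wilcoxon_enum_p <- function(d) {
  stopifnot(length(d) <= 12, all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  p <- mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
  min(1, p)
}

# Direct numerical evaluation of the Morlet CWT integral by trapezoid rule.
cwt_trapezoid <- function(x, fs, b, a, sigma = 6) {
  tt <- (seq_along(x) - 1) / fs
  u <- (tt - b) / a
  g <- exp(1i * u) * exp(-u^2 / (2 * sigma^2))
  w <- rep(1, length(x)); w[1] <- w[length(x)] <- 0.5
  sum(w * Conj(g) * x) / (a * fs)
}

# From-scratch repeated-measures sums of squares (two-way decomposition).
rm_ss_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_cond <- 0; ss_subj <- 0; ss_err <- 0
  for (j in seq_len(k)) ss_cond <- ss_cond + n * (mean(m[, j]) - grand)^2
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (mean(m[i, ]) - grand)^2
  for (i in seq_len(n)) for (j in seq_len(k))
    ss_err <- ss_err + (m[i, j] - mean(m[, j]) - mean(m[i, ]) + grand)^2
  c(cond = ss_cond, subj = ss_subj, err = ss_err)
}

# Dominant periodogram frequency of a signal.
peak_frequency <- function(x, fs) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          detrend = FALSE, plot = FALSE)
  sp$freq[which.max(sp$spec)]
}
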