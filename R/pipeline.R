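# End-to-end pipeline: simulate -> preprocess -> coherence -> patches ->
# compare, with a run manifest for reproducibility.

#' Pipeline run configuration
#'
#' Bundles the stage configurations, the analysis bands, the pair subset
#' and the output directory. The global seed is propagated deterministically
#' to the study generator, the random pairing and every surrogate test.
#'
#' @param trial A [trial_spec()] used for every simulated trial.
#' @param preproc A [preproc_config()].
#' @param wavelet A [wavelet_config()].
#' @param bands List of analysis bands in Hz, inside the wavelet borders.
#' @param n_trials Number of simulated trials.
#' @param pair_classes Which signal classes to pair (keeps runtime
#'   proportionate); any subset of `c("MMGs", "EEGcen", "EEGle", "EEGri",
#'   "force", "ACC")`.
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(trial = trial_spec(), preproc = preproc_config(),
                       wavelet = wavelet_config(),
                       bands = list(c(8, 15), c(3, 25)), n_trials = 6,
                       pair_classes = c("MMGs", "force", "ACC"),
                       out_dir = tempfile("wavecoh_run"), seed = 1L) {
  for (b in bands)
    if (b[1] < wavelet$f_min || b[2] > wavelet$f_max)
      stop_config("run_config: band [%g, %g] outside [f_min = %g, f_max = %g] Hz",
                  b[1], b[2], wavelet$f_min, wavelet$f_max)
  structure(list(trial = trial, preproc = preproc, wavelet = wavelet,
                 bands = bands, n_trials = n_trials,
                 pair_classes = pair_classes, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

pair_values_for <- function(signals, pairs, fs, wavelet, bands, seed0) {
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    cfg <- wavelet
    cfg$seed <- (seed0 + i) %% .Machine$integer.max
    map <- significant_coherence(signals[[pairs$side_a[i]]],
                                 signals[[pairs$side_b[i]]], fs, cfg)
    sm <- summarize_patches(map, bands)
    out[[i]] <- data.frame(side_a = pairs$side_a[i], side_b = pairs$side_b[i],
                           band_low_hz = sm$band_low_hz,
                           band_high_hz = sm$band_high_hz,
                           sum5pad_pct = sm$sum5pad_pct,
                           wfreq_hz = sm$wfreq_hz)
  }
  do.call(rbind, out)
}

#' Run the full analysis pipeline
#'
#' Simulates a coupled study, writes the raw signals, conditions every
#' record, computes wavelet coherence with pointwise significance for the
#' selected real and randomly matched signal pairs, summarizes patches per
#' band, aggregates per design and compares real against random pairs.
#' All tables are written as tab-separated text below `config$out_dir`
#' together with a JSON manifest listing every output file, the seeds and
#' the configuration. Reruns with the same configuration are identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, name)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # -- simulate ---------------------------------------------------------------
  study <- stage("simulate", {
    spec <- config$trial
    spec$seed <- config$seed
    simulate_study(spec, n_trials = config$n_trials)
  })
  stage("write-signals", {
    write_study(study, file.path(config$out_dir, "signals"))
    written <<- c(written, file.path("signals",
      list.files(file.path(config$out_dir, "signals"))))
  })

  # -- preprocess -------------------------------------------------------------
  prepped <- stage("preprocess", lapply(study, function(pair) {
    list(a = preprocess_record(pair$a, config$preproc),
         b = preprocess_record(pair$b, config$preproc),
         configuration = attr(pair, "configuration"))
  }))
  fs <- config$preproc$downsample_to

  # signals per trial, named with subject suffixes; shared channels once
  trial_signals <- lapply(prepped, function(p) {
    sig <- list()
    for (ch in rownames(p$a$samples))
      if (ch %in% c("force", "ACC")) sig[[ch]] <- p$a$samples[ch, ]
      else sig[[paste0(ch, "_A")]] <- p$a$samples[ch, ]
    for (ch in setdiff(rownames(p$b$samples), c("force", "ACC")))
      sig[[paste0(ch, "_B")]] <- p$b$samples[ch, ]
    sig
  })
  trial_ids <- vapply(prepped, function(p) p$a$trial_id, character(1))
  configurations <- vapply(prepped, `[[`, character(1), "configuration")
  tasks <- lapply(prepped, function(p) c(A = p$a$task, B = p$b$task))

  pairs <- classify_pairs(enumerate_signal_pairs())
  keep <- vapply(seq_len(nrow(pairs)), function(i) {
    all(c(signal_class(pairs$side_a[i]), signal_class(pairs$side_b[i]))
        %in% config$pair_classes) },
    logical(1))
  pairs <- pairs[keep, , drop = FALSE]

  # -- real pairs: coherence + patch summaries per trial ----------------------
  real_values <- stage("coherence-real", {
    do.call(rbind, lapply(seq_along(trial_signals), function(ti) {
      v <- pair_values_for(trial_signals[[ti]], pairs, fs, config$wavelet,
                           config$bands, seed0 = config$seed * 1000L + ti)
      v$trial_id <- trial_ids[ti]
      v$configuration <- configurations[ti]
      v
    }))
  })
  emit(real_values, "pair_values_real.tsv")

  # -- random pairs -----------------------------------------------------------
  rnd <- build_random_pairs(pairs, trial_ids, seed = config$seed + 77L)
  random_values <- stage("coherence-random", {
    out <- vector("list", nrow(rnd))
    for (i in seq_len(nrow(rnd))) {
      ta <- match(rnd$trial_a[i], trial_ids)
      tb <- match(rnd$trial_b[i], trial_ids)
      xa <- trial_signals[[ta]][[rnd$side_a[i]]]
      xb <- trial_signals[[tb]][[rnd$side_b[i]]]
      nmin <- min(length(xa), length(xb))
      cfg <- config$wavelet
      cfg$seed <- (config$seed * 2000L + i) %% .Machine$integer.max
      map <- significant_coherence(xa[seq_len(nmin)], xb[seq_len(nmin)],
                                   fs, cfg)
      sm <- summarize_patches(map, config$bands)
      out[[i]] <- data.frame(side_a = rnd$side_a[i], side_b = rnd$side_b[i],
                             trial_id = rnd$trial_a[i],
                             configuration = configurations[ta],
                             band_low_hz = sm$band_low_hz,
                             band_high_hz = sm$band_high_hz,
                             sum5pad_pct = sm$sum5pad_pct,
                             wfreq_hz = sm$wfreq_hz)
    }
    do.call(rbind, out)
  })
  emit(random_values, "pair_values_random.tsv")

  # -- aggregate and compare --------------------------------------------------
  to_long <- function(values) {
    cl <- classify_pairs(values[, c("side_a", "side_b")])
    long <- rbind(
      data.frame(values, parameter = "Sum5PaD", value = values$sum5pad_pct),
      data.frame(values, parameter = "WFreq", value = values$wfreq_hz))
    long$scope <- rep(cl$scope, 2)
    long$combo <- rep(cl$combo, 2)
    long$unit <- rep(cl$unit, 2)
    subj <- signal_subject(long$side_a)
    subj[is.na(subj)] <- signal_subject(long$side_b)[is.na(subj)]
    long$subject <- ifelse(long$scope == "interpersonal", NA, subj)
    ti <- match(long$trial_id, trial_ids)
    long$task <- vapply(seq_len(nrow(long)), function(i) {
      s <- long$subject[i]
      if (is.na(s)) NA_character_ else tasks[[ti[i]]][[s]]
    }, character(1))
    long
  }
  comparisons <- stage("compare", {
    long_real <- to_long(real_values)
    long_rand <- to_long(random_values)
    res <- list()
    for (param in c("Sum5PaD", "WFreq")) {
      for (scope in intersect(c("intrapersonal", "interpersonal", "force_acc"),
                              unique(long_real$scope))) {
        lr <- long_real[long_real$parameter == param &
                          long_real$band_low_hz == config$bands[[1]][1], ]
        lx <- long_rand[long_rand$parameter == param &
                          long_rand$band_low_hz == config$bands[[1]][1], ]
        ar <- aggregate_pairs(lr, scope)
        ax <- aggregate_pairs(lx, scope)
        if (nrow(ar) == 0 || any(is.na(ar$value)) || any(is.na(ax$value)))
          next
        cmp <- compare_real_vs_random(ar, ax)
        cmp$parameter <- param
        cmp$scope <- scope
        res[[paste(param, scope)]] <- cmp
      }
    }
    do.call(rbind, res)
  })
  emit(comparisons, "comparisons_real_vs_random.tsv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("wavecoh")),
    seed = config$seed,
    n_trials = config$n_trials,
    fs_analysis_hz = fs,
    bands = config$bands,
    pair_classes = config$pair_classes,
    files = written)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Plot a coherence map with significant patches outlined
#'
#' Heatmap of the coherence modulus over time and frequency; the colour
#' scale saturates above 0.9 so strong coherence reads uniformly red.
#' Bounding boxes of the significant patches are drawn on top.
#'
#' @param map A `coherence_map`.
#' @param patches Optional `patch_set`; extracted from the map when a
#'   significance mask is present and `patches` is `NULL`.
#' @param path Output PNG path.
#' @param width,height,res Device geometry passed to [grDevices::png()].
#' @return Invisibly, the number of patch outlines drawn.
#' @export
plot_coherence <- function(map, patches = NULL, path, width = 900,
                           height = 500, res = 96) {
  stopifnot(inherits(map, "coherence_map"))
  if (is.null(patches) && !is.null(map$sig_mask))
    patches <- extract_patches(map)
  n_out <- if (is.null(patches)) 0L else nrow(patches)
  breaks <- c(seq(0, 0.9, length.out = 64), 1)
  cols <- c(grDevices::colorRampPalette(c("#FFFFFF", "#FFD24D", "#E6442A"))(63),
            "#B30000")
  grDevices::png(path, width = width, height = height, res = res)
  on.exit(grDevices::dev.off())
  graphics::image(map$times, log2(map$freqs), map$coh, breaks = breaks,
                  col = cols, xlab = "time (s)", ylab = "frequency (Hz)",
                  yaxt = "n")
  at <- c(3, 5, 10, 20, 30)
  graphics::axis(2, at = log2(at), labels = at)
  if (n_out > 0)
    graphics::rect(patches$t_min, log2(patches$f_min), patches$t_max,
                   log2(patches$f_max), border = "black", lwd = 1.2)
  invisible(n_out)
}
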