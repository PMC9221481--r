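# Real and random signal pairing, region-combination bookkeeping and the
# aggregation tree feeding the statistical comparisons.
#
# Signal naming convention: per-subject channels carry an _A or _B suffix
# (MMGtri_A, ..., FM_A, ..., POri_B); the shared channels are "force" and
# "ACC". Region classes: the three MMG-type channels form class MMGs, the
# EEG sub-regions map to EEGcen / EEGle / EEGri, force and ACC are their own
# classes.

#' Default signal names of one two-subject trial
#'
#' The 28 signals entering the pairwise coherence analysis: force, ACC,
#' three MMG-type channels per subject and ten EEG sub-regions per subject.
#'
#' @return Character vector of length 28.
#' @export
default_signal_names <- function() {
  per_subject <- c(mmg_channel_names(), eeg_region_names())
  c("force", "ACC",
    paste0(per_subject, "_A"), paste0(per_subject, "_B"))
}

signal_subject <- function(name) {
  ifelse(grepl("_A$", name), "A", ifelse(grepl("_B$", name), "B", NA))
}

signal_base <- function(name) sub("_[AB]$", "", name)

signal_class <- function(name) {
  base <- signal_base(name)
  if (base %in% c("force", "ACC")) return(base)
  if (base %in% mmg_channel_names()) return("MMGs")
  map <- default_region_map()
  if (base %in% names(map$region)) return(unname(map$region[base]))
  stop_config("unknown signal name '%s'", name)
}

#' Enumerate all unordered signal pairs
#'
#' @param signal_names Unique signal labels.
#' @return Data frame with columns `side_a`, `side_b`, one row per
#'   unordered pair of distinct signals (28 signals give 378 pairs).
#' @export
enumerate_signal_pairs <- function(signal_names = default_signal_names()) {
  if (anyDuplicated(signal_names))
    stop_config("enumerate_signal_pairs: duplicate signal names")
  if (length(signal_names) < 2)
    stop_config("enumerate_signal_pairs: need at least two signals")
  cmb <- combn(signal_names, 2)
  data.frame(side_a = cmb[1, ], side_b = cmb[2, ])
}

# Classify one signal pair: analysis scope and region-combination label.
classify_pair <- function(side_a, side_b) {
  sub_a <- signal_subject(side_a); sub_b <- signal_subject(side_b)
  cls_a <- signal_class(side_a); cls_b <- signal_class(side_b)
  shared <- c("force", "ACC")
  if (cls_a %in% shared || cls_b %in% shared) {
    if (cls_a %in% shared && cls_b %in% shared)
      return(list(scope = "force_acc", combo = "force-ACC",
                  unit = "force-ACC"))
    # order: sensor first
    if (!(cls_a %in% shared)) {
      tmp <- side_a; side_a <- side_b; side_b <- tmp
      cls <- cls_a; cls_a <- cls_b; cls_b <- cls
      sub_b <- signal_subject(side_b)
    }
    return(list(scope = "force_acc",
                combo = paste0(cls_a, "-", cls_b),
                unit = paste0(signal_base(side_b), "_", sub_b)))
  }
  classes <- c("MMGs", "EEGcen", "EEGle", "EEGri")
  o <- order(match(c(cls_a, cls_b), classes))
  pair_sorted <- c(side_a, side_b)[o]
  cls_sorted <- c(cls_a, cls_b)[o]
  combo_cls <- if (cls_sorted[1] == cls_sorted[2]) cls_sorted[1]
               else paste0(cls_sorted[1], "-", cls_sorted[2])
  if (sub_a == sub_b) {
    unit <- paste(sort(signal_base(c(side_a, side_b))), collapse = "-")
    list(scope = "intrapersonal", combo = paste0("intra-", combo_cls),
         unit = unit)
  } else {
    # interpersonal unit: unordered sub-region combination, so that
    # AFle_A-TLle_B and TLle_A-AFle_B aggregate into one unit
    unit <- paste(sort(signal_base(c(side_a, side_b))), collapse = "-")
    list(scope = "interpersonal", combo = paste0("inter-", combo_cls),
         unit = unit)
  }
}

#' Classify signal pairs into scopes, region combinations and units
#'
#' Adds to each pair its analysis scope (`intrapersonal`, `interpersonal`
#' or `force_acc`), its region-combination label (e.g. `inter-MMGs-EEGcen`)
#' and its aggregation unit. Units pool the symmetric interpersonal
#' orientations (`X_A` vs `Y_B` with `Y_A` vs `X_B`) and the two subjects'
#' intrapersonal copies of the same sub-region pair.
#'
#' @param pairs Data frame from [enumerate_signal_pairs()].
#' @return The input with columns `scope`, `combo`, `unit` appended.
#' @export
classify_pairs <- function(pairs) {
  cl <- Map(classify_pair, pairs$side_a, pairs$side_b)
  pairs$scope <- vapply(cl, `[[`, character(1), "scope")
  pairs$combo <- vapply(cl, `[[`, character(1), "combo")
  pairs$unit <- vapply(cl, `[[`, character(1), "unit")
  pairs
}

#' Random (surrogate) trial assignment for every signal pair
#'
#' For the coincidence null every signal pair is re-assembled from two
#' different trials: for each pair two distinct trials are drawn uniformly
#' under the seed. Durations are equalized downstream via
#' [truncate_to_common_length()].
#'
#' @param pairs Data frame of signal pairs (see [enumerate_signal_pairs()]).
#' @param trial_ids At least two trial identifiers.
#' @param seed Seed making the assignment reproducible.
#' @return The pairs with columns `trial_a`, `trial_b` appended
#'   (`trial_a != trial_b` in every row).
#' @export
build_random_pairs <- function(pairs, trial_ids, seed = NULL) {
  if (length(unique(trial_ids)) < 2)
    stop_config("build_random_pairs: cannot randomize with a single trial")
  with_seed(seed, {
    picks <- t(vapply(seq_len(nrow(pairs)),
                      function(i) sample(unique(trial_ids), 2),
                      character(2)))
    pairs$trial_a <- picks[, 1]
    pairs$trial_b <- picks[, 2]
    pairs
  })
}

# ---- aggregation tree -------------------------------------------------------

#' Aggregate per-trial parameter values for statistical comparison
#'
#' Input is a long table of per-trial, per-signal-pair parameter values
#' (Sum5PaD or WFreq) with the columns `combo`, `unit`, `scope`,
#' `configuration` (`"A-PIMA_B-HIMA"` / `"B-PIMA_A-HIMA"`), `subject`
#' (for intrapersonal and force/ACC values: the subject the unit belongs
#' to; `NA` interpersonally), `parameter` and `value`.
#'
#' Designs:
#' \describe{
#'   \item{intrapersonal}{per unit and subject: mean over the trials of each
#'     configuration, then over configurations; the two subjects' values are
#'     averaged again (the AB_IMA value).}
#'   \item{interpersonal}{per unit: mean over the trials of each
#'     configuration, then the mean of the two configuration means.}
#'   \item{force_acc}{like intrapersonal but the subjects are pooled as
#'     separate units (not averaged), keeping usable sample sizes.}
#'   \item{task_grouped}{per unit and subject: mean over the trials in which
#'     that subject performed HIMA and PIMA respectively; returns one row
#'     per unit, subject and task.}
#' }
#'
#' @param values Long-format data frame as described above.
#' @param design One of `"intrapersonal"`, `"interpersonal"`, `"force_acc"`,
#'   `"task_grouped"`.
#' @return Data frame with columns `combo`, `unit` (plus `task` for
#'   `task_grouped`) and the aggregated `value`. Missing cells propagate as
#'   `NA` with a message.
#' @export
aggregate_pairs <- function(values, design = c("intrapersonal",
                                               "interpersonal", "force_acc",
                                               "task_grouped")) {
  design <- match.arg(design)
  dt <- data.table::as.data.table(values)
  if (anyNA(dt$value))
    message(sprintf("aggregate_pairs: %d missing values propagate as NA",
                    sum(is.na(dt$value))))
  value <- configuration <- unit <- combo <- subject <- task <- scope <- NULL # NSE
  out <- switch(design,
    intrapersonal = {
      cfg <- dt[scope == "intrapersonal",
                .(value = mean(value)),
                by = .(combo, unit, subject, configuration)]
      subj <- cfg[, .(value = mean(value)), by = .(combo, unit, subject)]
      subj[, .(value = mean(value)), by = .(combo, unit)]
    },
    interpersonal = {
      cfg <- dt[scope == "interpersonal",
                .(value = mean(value)),
                by = .(combo, unit, configuration)]
      cfg[, .(value = mean(value)), by = .(combo, unit)]
    },
    force_acc = {
      cfg <- dt[scope == "force_acc",
                .(value = mean(value)),
                by = .(combo, unit, configuration)]
      cfg[, .(value = mean(value)), by = .(combo, unit)]
    },
    task_grouped = {
      tg <- dt[!is.na(task), .(value = mean(value)),
               by = .(combo, unit, subject, task)]
      data.table::setorder(tg, combo, unit, subject, task)
      tg
    })
  data.table::setorder(out, combo, unit)
  as.data.frame(out)
}

#' Comparison cell summaries
#'
#' Per region combination: sample size, arithmetic mean, standard deviation
#' and coefficient of variation of the aggregated values.
#'
#' @param agg Aggregated values from [aggregate_pairs()].
#' @return Data frame with one row per `combo`.
#' @export
comparison_cells <- function(agg) {
  dt <- data.table::as.data.table(agg)
  value <- combo <- NULL
  as.data.frame(dt[, .(n = .N, mean = mean(value), sd = sd(value),
                       cv = coefficient_of_variation(value)),
                   by = combo])
}

#' Compare real against randomly matched pairs
#'
#' For every region combination the aggregated real (AB_IMA) and random
#' values are compared unit by unit: the Shapiro-Wilk gate on the paired
#' differences routes to the paired t test (effect size Cohen's dz) or the
#' Wilcoxon signed-rank test (effect size r = |z|/sqrt(n)); the output table
#' carries both groups' mean, SD and CV beside the test results.
#'
#' @param real,random Aggregated value tables from [aggregate_pairs()]
#'   with matching `combo`/`unit` sets.
#' @param alpha Significance level used for the `significant` flag.
#' @return Data frame, one row per region combination.
#' @export
compare_real_vs_random <- function(real, random, alpha = 0.05) {
  key <- function(d) paste(d$combo, d$unit)
  if (!setequal(key(real), key(random)))
    stop_config("compare_real_vs_random: unmatched combos/units: %s",
                paste(union(setdiff(key(real), key(random)),
                            setdiff(key(random), key(real))), collapse = ", "))
  random <- random[match(key(real), key(random)), ]
  do.call(rbind, lapply(split(seq_len(nrow(real)), real$combo), function(ix) {
    a <- real$value[ix]; b <- random$value[ix]
    n <- length(a)
    d <- a - b
    degenerate <- n < 3 || sd(d) == 0
    route <- if (degenerate) NA_character_ else normality_gate(d)
    res <- if (degenerate) NULL
           else if (route == "parametric") paired_t(a, b)
           else wilcoxon_signed_rank(a, b)
    data.frame(combo = real$combo[ix][1], n = n,
               mean_real = mean(a), sd_real = sd(a),
               cv_real = coefficient_of_variation(a),
               mean_rand = mean(b), sd_rand = sd(b),
               cv_rand = coefficient_of_variation(b),
               test = if (is.null(res)) NA_character_ else res$test,
               statistic = if (is.null(res)) NA_real_ else res$statistic,
               df = if (is.null(res)) NA_real_ else res$df[1],
               p = if (is.null(res)) NA_real_ else res$p,
               effect = if (is.null(res)) NA_character_ else res$effect,
               effect_value = if (is.null(res)) NA_real_ else res$effect_value,
               significant = if (is.null(res)) NA else res$p <= alpha)
  }))
}
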