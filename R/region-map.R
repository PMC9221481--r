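#' EEG sub-region averaging map
#'
#' The ten EEG sub-regions used throughout the pipeline: each sub-region is
#' the sample-wise average of a fixed set of 10/20-system electrode channels,
#' and each sub-region belongs to one of the three statistics regions
#' (`EEGcen`, `EEGle`, `EEGri`). The default map covers 63 electrodes of a
#' 64-channel montage; the reference electrode CPz carries no signal and is
#' excluded.
#'
#' @param path Optional path to a user map: a tab-separated file with columns
#'   `sub_region`, `region` and `channels` (comma-separated electrode list).
#' @return An object of class `region_map`: a list with `channels` (named
#'   list sub-region -> electrode labels) and `region` (named character,
#'   sub-region -> statistics region).
#' @export
#' @examples
#' map <- default_region_map()
#' names(map$channels)
default_region_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "eeg_region_map.tsv", package = "wavecoh")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sub_region", "region", "channels") %in% names(df)))
    stop_config("region map file needs columns sub_region, region, channels")
  channels <- lapply(strsplit(df$channels, ","), trimws)
  names(channels) <- df$sub_region
  all_ch <- unlist(channels, use.names = FALSE)
  if (anyDuplicated(all_ch))
    stop_config("region map: channel(s) %s appear in more than one sub-region",
                paste(unique(all_ch[duplicated(all_ch)]), collapse = ", "))
  if ("CPz" %in% all_ch)
    stop_config("region map: CPz is the reference electrode and must not be mapped")
  structure(list(channels = channels,
                 region = stats::setNames(df$region, df$sub_region)),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat("<region_map>", length(x$channels), "sub-regions,",
      length(unlist(x$channels)), "channels\n")
  invisible(x)
}

#' Average electrode channels into EEG sub-regions
#'
#' Replaces the raw electrode channels of a record by the ten sub-region
#' averages (sample-wise arithmetic means). Channels that are not part of any
#' sub-region (for example force, ACC and MMG channels) are passed through
#' unchanged, after the region channels.
#'
#' @param record A [signal_record()] containing all mapped electrode channels.
#' @param map A region map from [default_region_map()].
#' @return A [signal_record()] whose first channels are the sub-regions.
#' @export
average_regions <- function(record, map = default_region_map()) {
  stopifnot(inherits(record, "signal_record"), inherits(map, "region_map"))
  have <- rownames(record$samples)
  missing <- setdiff(unlist(map$channels), have)
  if (length(missing) > 0L)
    stop_config("average_regions: channel(s) missing from record: %s",
                paste(missing, collapse = ", "))
  regions <- t(vapply(map$channels, function(ch) {
    colMeans(record$samples[ch, , drop = FALSE])
  }, numeric(ncol(record$samples))))
  passthrough <- setdiff(have, unlist(map$channels))
  out <- rbind(regions, record$samples[passthrough, , drop = FALSE])
  signal_record(out, fs_hz = record$fs_hz,
                channel_names = c(names(map$channels), passthrough),
                triggers = record$triggers, subject_id = record$subject_id,
                trial_id = record$trial_id, task = record$task)
}
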