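# On-disk study format: one TSV per record (header = channel names, one row
# per sample) plus a flat key=value sidecar with sampling rate, triggers and
# labels. Plain text so studies round-trip across tools.

record_basename <- function(record) {
  sprintf("%s_%s", record$trial_id, record$subject_id)
}

write_record <- function(record, directory) {
  base <- file.path(directory, record_basename(record))
  dt <- data.table::as.data.table(t(record$samples))
  data.table::fwrite(dt, paste0(base, ".tsv"), sep = "\t")
  meta <- c(
    subject_id = record$subject_id,
    trial_id = record$trial_id,
    task = record$task,
    fs_hz = format(record$fs_hz, digits = 15),
    triggers = if (is.null(record$triggers)) "" else
      paste(format(record$triggers, digits = 15), collapse = ","),
    n_samples = ncol(record$samples))
  writeLines(paste0(names(meta), "=", meta), paste0(base, ".meta"))
  base
}

#' Write a study to delimited text files
#'
#' Writes every record of a study (a list of [signal_record()]s or of
#' `a`/`b` trial pairs) into `directory`: one tab-separated signal file and
#' one `key=value` metadata sidecar per record. The layout round-trips
#' losslessly through [read_study()] at text precision.
#'
#' @param records List of `signal_record`s, or list of trial pairs as
#'   produced by [simulate_study()].
#' @param directory Output directory, created if missing.
#' @return Invisibly, the vector of file basenames written.
#' @export
write_study <- function(records, directory) {
  records <- flatten_records(records)
  if (length(records) == 0L)
    stop_config("write_study: empty record list")
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop_config("write_study: cannot create directory '%s'", directory)
  invisible(vapply(records, write_record, character(1), directory = directory))
}

flatten_records <- function(records) {
  if (inherits(records, "signal_record")) return(list(records))
  out <- list()
  for (el in records) {
    if (inherits(el, "signal_record")) out <- c(out, list(el))
    else out <- c(out, Filter(function(x) inherits(x, "signal_record"), el))
  }
  out
}

#' Read a study written by [write_study()]
#'
#' @param directory Directory holding `*.tsv` / `*.meta` file pairs.
#' @return List of [signal_record()]s, ordered by file name.
#' @export
read_study <- function(directory) {
  metas <- sort(list.files(directory, pattern = "\\.meta$", full.names = TRUE))
  if (length(metas) == 0L)
    stop_config("read_study: no .meta files in '%s'", directory)
  lapply(metas, function(mf) {
    kv <- strsplit(readLines(mf), "=", fixed = TRUE)
    meta <- stats::setNames(
      vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)),
      vapply(kv, `[[`, character(1), 1))
    dt <- data.table::fread(sub("\\.meta$", ".tsv", mf), sep = "\t")
    trig <- if (nzchar(meta[["triggers"]]))
      as.numeric(strsplit(meta[["triggers"]], ",")[[1]]) else NULL
    signal_record(t(as.matrix(dt)), fs_hz = as.numeric(meta[["fs_hz"]]),
                  channel_names = names(dt), triggers = trig,
                  subject_id = meta[["subject_id"]],
                  trial_id = meta[["trial_id"]], task = meta[["task"]])
  })
}
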