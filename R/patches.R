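# Significant-patch extraction and the patch statistics Sum5PaD and WFreq.
#
# A patch is a 4-connected component of the significance mask. Components
# are labelled with a run-based union-find: runs of TRUE along time within
# each frequency row, merged across adjacent rows where they overlap.

# Union-find over run indices.
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

label_components <- function(mask) {
  nt <- nrow(mask); nf <- ncol(mask)
  runs <- vector("list", nf)  # per column: matrix [start, end, id]
  n_runs <- 0L
  for (j in seq_len(nf)) {
    col <- mask[, j]
    if (!any(col)) next
    r <- rle(col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    m <- cbind(start = starts[keep], end = ends[keep],
               id = n_runs + seq_len(sum(keep)))
    n_runs <- n_runs + nrow(m)
    runs[[j]] <- m
  }
  if (n_runs == 0L) return(list(labels = integer(0), runs = runs, n = 0L))
  parent <- seq_len(n_runs)
  for (j in seq_len(nf - 1L)) {
    a <- runs[[j]]; b <- runs[[j + 1L]]
    if (is.null(a) || is.null(b)) next
    for (ia in seq_len(nrow(a))) {
      hit <- which(b[, "start"] <= a[ia, "end"] & b[, "end"] >= a[ia, "start"])
      for (ib in hit) {
        ra <- uf_find(parent, a[ia, "id"]); rb <- uf_find(parent, b[ib, "id"])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n_runs), function(i) uf_find(parent, i), integer(1))
  list(labels = match(roots, sort(unique(roots))), runs = runs,
       n = length(unique(roots)))
}

#' Extract connected significant patches
#'
#' Finds the 4-connected components of the significance mask and computes
#' the patch descriptors: start/end/duration along time, minimal/maximal
#' frequency and frequency range, pixel count, mean coherence over member
#' pixels and the coherence-weighted mean frequency. The time extent of a
#' pixel is one grid step, so a single-pixel patch has positive duration.
#' Patches are sorted by duration (descending), ties broken by earlier
#' start.
#'
#' @param map A `coherence_map` with a filled `sig_mask`
#'   (see [pointwise_significance()]).
#' @return A data frame of class `patch_set` with one row per patch and an
#'   attribute `"pixels"`: a list of two-column matrices (time index,
#'   frequency index) of the member grid cells.
#' @export
extract_patches <- function(map) {
  stopifnot(inherits(map, "coherence_map"))
  if (is.null(map$sig_mask))
    stop_config("extract_patches: map has no significance mask")
  mask <- map$sig_mask
  dt <- if (length(map$times) > 1L) diff(map$times[1:2]) else 1 / map$fs_map
  lab <- label_components(mask)
  empty <- data.frame(id = integer(0), t_min = numeric(0), t_max = numeric(0),
                      duration = numeric(0), f_min = numeric(0),
                      f_max = numeric(0), f_range = numeric(0),
                      n_pixels = integer(0), mean_coh = numeric(0),
                      f_weighted = numeric(0))
  if (lab$n == 0L) {
    attr(empty, "pixels") <- list()
    class(empty) <- c("patch_set", "data.frame")
    attr(empty, "total_duration_s") <- length(map$times) * dt
    return(empty)
  }
  pixels <- vector("list", lab$n)
  k <- 0L
  for (j in seq_along(lab$runs)) {
    m <- lab$runs[[j]]
    if (is.null(m)) next
    for (r in seq_len(nrow(m))) {
      k <- k + 1L
      comp <- lab$labels[m[r, "id"]]
      px <- cbind(ti = m[r, "start"]:m[r, "end"], fj = j)
      pixels[[comp]] <- rbind(pixels[[comp]], px)
    }
  }
  desc <- do.call(rbind, lapply(seq_len(lab$n), function(comp) {
    px <- pixels[[comp]]
    tmin <- map$times[min(px[, "ti"])]
    tmax <- map$times[max(px[, "ti"])] + dt
    co <- map$coh[px]
    fr <- map$freqs[px[, "fj"]]
    data.frame(t_min = tmin, t_max = tmax, duration = tmax - tmin,
               f_min = min(fr), f_max = max(fr),
               f_range = max(fr) - min(fr), n_pixels = nrow(px),
               mean_coh = mean(co),
               f_weighted = sum(co * fr) / sum(co))
  }))
  ord <- order(-desc$duration, desc$t_min)
  desc <- desc[ord, , drop = FALSE]
  desc <- cbind(id = seq_len(nrow(desc)), desc)
  rownames(desc) <- NULL
  attr(desc, "pixels") <- pixels[ord]
  attr(desc, "total_duration_s") <- length(map$times) * dt
  class(desc) <- c("patch_set", "data.frame")
  desc
}

in_band <- function(patches, band) {
  patches$f_min <= band[2] & patches$f_max >= band[1]
}

top5_in_band <- function(patches, band) {
  sel <- patches[in_band(patches, band), , drop = FALSE]
  head(sel[order(-sel$duration, sel$t_min), , drop = FALSE], 5L)
}

#' Summed duration of the five longest in-band patches (Sum5PaD)
#'
#' The durations of the five longest significant patches whose frequency
#' extent intersects `band` are added and expressed as a percentage of the
#' whole trial duration. Because patches at different frequencies may
#' overlap in time, the value can exceed 100 %. Fewer than five in-band
#' patches contribute what is available; no in-band patch gives 0.
#'
#' @param patches A `patch_set` from [extract_patches()].
#' @param band Frequency band `c(low, high)` in Hz (default 8-15 Hz, where
#'   the mechanical muscle oscillations live).
#' @param total_duration_s Whole trial duration in seconds (taken from the
#'   patch set when omitted).
#' @return Percentage (may exceed 100).
#' @export
sum5pad <- function(patches, band = c(8, 15),
                    total_duration_s = attr(patches, "total_duration_s")) {
  if (is.null(total_duration_s) || !is_scalar_num(total_duration_s) ||
      total_duration_s <= 0)
    stop_config("sum5pad: total_duration_s must be a positive number")
  100 * sum(top5_in_band(patches, band)$duration) / total_duration_s
}

#' Duration-weighted mean frequency of the five longest patches (WFreq)
#'
#' Over the five longest in-band patches, returns
#' `sum(duration_i * f_i) / sum(duration_i)` where `f_i` is the patch's
#' representative frequency: by default the coherence-weighted mean
#' frequency over its member pixels, clipped to the band; alternatively the
#' midpoint of its frequency extent. Undefined (returned as `NA`) when no
#' patch intersects the band.
#'
#' @param patches A `patch_set` from [extract_patches()].
#' @param band Frequency band `c(low, high)` in Hz.
#' @param representative `"weighted"` (default) or `"midpoint"`.
#' @return Frequency in Hz, or `NA_real_` when undefined.
#' @export
wfreq <- function(patches, band = c(8, 15),
                  representative = c("weighted", "midpoint")) {
  representative <- match.arg(representative)
  top <- top5_in_band(patches, band)
  if (nrow(top) == 0L) return(NA_real_)
  f_i <- if (representative == "weighted") top$f_weighted
         else (top$f_min + top$f_max) / 2
  f_i <- pmin(pmax(f_i, band[1]), band[2])
  sum(top$duration * f_i) / sum(top$duration)
}

#' Export the patch table
#'
#' Writes the per-patch descriptor table as tab-separated text with a fixed
#' header: whole-series duration, patch count, and per patch the start/end
#' time points, total duration, minimal/maximal frequency and frequency
#' range. An empty patch set yields the whole-duration/zero-count row only.
#'
#' @param map The `coherence_map` the patches came from.
#' @param patches A `patch_set`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_patch_table <- function(map, patches, path) {
  total <- attr(patches, "total_duration_s")
  if (nrow(patches) == 0L) {
    df <- data.frame(total_duration_s = total, n_patches = 0L,
                     patch_id = NA_integer_, t_min_s = NA_real_,
                     t_max_s = NA_real_, duration_s = NA_real_,
                     f_min_hz = NA_real_, f_max_hz = NA_real_,
                     f_range_hz = NA_real_)
  } else {
    df <- data.frame(total_duration_s = total, n_patches = nrow(patches),
                     patch_id = patches$id, t_min_s = patches$t_min,
                     t_max_s = patches$t_max, duration_s = patches$duration,
                     f_min_hz = patches$f_min, f_max_hz = patches$f_max,
                     f_range_hz = patches$f_range)
  }
  utils::write.table(format(df, digits = 15, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an exported patch table
#'
#' @param path File written by [export_patch_table()].
#' @return Data frame of patch descriptors (empty when the export held no
#'   patches), with attribute `"total_duration_s"`.
#' @export
read_patch_table <- function(path) {
  df <- utils::read.delim(path)
  total <- df$total_duration_s[1]
  out <- df[!is.na(df$patch_id),
            c("patch_id", "t_min_s", "t_max_s", "duration_s",
              "f_min_hz", "f_max_hz", "f_range_hz")]
  names(out) <- c("id", "t_min", "t_max", "duration", "f_min", "f_max",
                  "f_range")
  rownames(out) <- NULL
  attr(out, "total_duration_s") <- total
  out
}

#' Patch summaries per frequency band
#'
#' One row per requested band with `sum5pad_pct`, `wfreq_hz`, the number of
#' in-band patches and the whole duration. Default bands are 8-15 Hz (the
#' primary band) and 3-25 Hz (the wider consideration).
#'
#' @param map A `coherence_map` with significance mask.
#' @param bands List of `c(low, high)` bands, all within the configured
#'   frequency borders.
#' @param representative Passed to [wfreq()].
#' @return Data frame with one `PatchSummary` row per band.
#' @export
summarize_patches <- function(map, bands = list(c(8, 15), c(3, 25)),
                              representative = "weighted") {
  lims <- c(map$config$f_min, map$config$f_max)
  for (b in bands)
    if (b[1] < lims[1] || b[2] > lims[2])
      stop_config("summarize_patches: band [%g, %g] outside [%g, %g] Hz",
                  b[1], b[2], lims[1], lims[2])
  patches <- extract_patches(map)
  do.call(rbind, lapply(bands, function(b) {
    data.frame(band_low_hz = b[1], band_high_hz = b[2],
               sum5pad_pct = sum5pad(patches, b),
               wfreq_hz = wfreq(patches, b, representative),
               n_patches = sum(in_band(patches, b)),
               total_duration_s = attr(patches, "total_duration_s"))
  }))
}
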