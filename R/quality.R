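#' Quality-screening rules
#'
#' Machine-checkable stand-ins for visual screening of PPG segments.  A
#' segment is accepted only when every rule passes:
#' \describe{
#'   \item{missing_reference}{both reference BPs must be present;}
#'   \item{flatline}{the sample SD must exceed `flatline_sd_frac` times the
#'     amplitude range (a zero range is always a flatline);}
#'   \item{clipping}{no run of `clip_run` or more consecutive samples sitting
#'     at the segment maximum or minimum (saturation plateaus pin the signal
#'     at its ceiling, dropouts at its floor);}
#'   \item{implausible_beat_count}{the number of detected beats per 5 s must
#'     lie within `beat_range` (default 3-15, i.e. 36-180 beats/min);}
#'   \item{out_of_range_amplitude}{the amplitude range must lie within
#'     `amp_range` (unbounded by default, since photodetector units are
#'     arbitrary).}
#' }
#'
#' @param flatline_sd_frac Flatline threshold as a fraction of the range.
#' @param clip_run Minimum length of a constant run flagged as clipping.
#' @param beat_range Plausible detected-beat count per segment.
#' @param amp_range Acceptable amplitude range (same units as the signal).
#' @return An object of class `quality_rules`.
#' @export
quality_rules <- function(flatline_sd_frac = 1e-6, clip_run = 25,
                          beat_range = c(3, 15), amp_range = c(0, Inf)) {
  structure(list(flatline_sd_frac = flatline_sd_frac,
                 clip_run = as.integer(clip_run),
                 beat_range = as.numeric(beat_range),
                 amp_range = as.numeric(amp_range)),
            class = "quality_rules")
}

#' Assess one segment against the quality rules
#'
#' Always returns a report; `accepted` is `TRUE` exactly when `reasons` is
#' empty, and `reasons` lists every violated rule, not just the first.
#'
#' @param segment A [ppg_segment].
#' @param rules A [quality_rules()].
#' @return An object of class `quality_report`: list with `segment_id`,
#'   `accepted`, `reasons`.
#' @export
assess_quality <- function(segment, rules = quality_rules()) {
  x <- segment$samples
  reasons <- character(0)
  if (is.na(segment$ref_sbp) || is.na(segment$ref_dbp))
    reasons <- c(reasons, "missing_reference")
  rng <- diff(range(x))
  flat <- rng <= 0 || stats::sd(x) < rules$flatline_sd_frac * rng
  if (flat) reasons <- c(reasons, "flatline")
  if (!flat && max_run_at_extreme(x) >= rules$clip_run)
    reasons <- c(reasons, "clipping")
  n_beats <- if (flat) 0L else tryCatch(
    length(detect_beats(sg_smooth(x), segment$rate)$peak_indices),
    error = function(e) 0L)
  if (!flat && (n_beats < rules$beat_range[1] || n_beats > rules$beat_range[2]))
    reasons <- c(reasons, "implausible_beat_count")
  if (rng < rules$amp_range[1] || rng > rules$amp_range[2])
    reasons <- c(reasons, "out_of_range_amplitude")
  structure(list(segment_id = segment$segment_id,
                 accepted = length(reasons) == 0L,
                 reasons = reasons),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %s: %s%s\n", x$segment_id,
              if (x$accepted) "accepted" else "REJECTED",
              if (length(x$reasons))
                paste0(" [", paste(x$reasons, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Screen a dataset of segments
#'
#' @param segments List of [ppg_segment] objects.
#' @param rules A [quality_rules()].
#' @return List with `accepted` (the accepted segments, input order
#'   preserved) and `reports` (one `quality_report` per input segment).
#' @export
filter_dataset <- function(segments, rules = quality_rules()) {
  reports <- lapply(segments, assess_quality, rules = rules)
  keep <- vapply(reports, function(r) r$accepted, logical(1))
  list(accepted = segments[keep], reports = reports)
}

#' Write quality reports as CSV
#'
#' @param reports List of `quality_report` objects.
#' @param path Output file.
#' @export
write_quality_reports <- function(reports, path) {
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(segment_id = r$segment_id, accepted = r$accepted,
               reasons = paste(r$reasons, collapse = ";"),
               stringsAsFactors = FALSE)))
  write_csv_plain(df, path)
  invisible(path)
}

# longest run of consecutive samples pinned at the segment max or min
max_run_at_extreme <- function(x, rel_tol = 1e-9) {
  rng <- diff(range(x))
  tol <- rel_tol * max(rng, 1)
  longest <- 0L
  for (lvl in range(x)) {
    at <- abs(x - lvl) <= tol
    r <- rle(at)
    runs <- r$lengths[r$values]
    if (length(runs)) longest <- max(longest, max(runs))
  }
  longest
}
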