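#' Construct a PPG segment
#'
#' A `ppg_segment` holds one fixed-length photoplethysmogram excerpt together
#' with its identity and, when available, the reference (cuff) blood pressures
#' recorded over the same interval.  Accepted segments are exactly
#' `seconds * rate` samples long (500 samples for the default 5 s at 100 Hz).
#'
#' @param case_id Character scalar identifying the recording subject.
#' @param segment_id Character scalar, unique within a dataset.
#' @param samples Numeric vector of photodetector readings (arbitrary units).
#' @param rate Sampling rate in Hz (default 100).
#' @param ref_sbp,ref_dbp Reference systolic/diastolic pressure in mmHg, or
#'   `NA` when the monitor produced no reading for this segment.
#' @param seconds Nominal segment duration in seconds (default 5).
#' @param validate If `TRUE` (default) enforce the length invariant.
#'
#' @return An object of class `ppg_segment`.
#' @export
ppg_segment <- function(case_id, segment_id, samples, rate = 100,
                        ref_sbp = NA_real_, ref_dbp = NA_real_,
                        seconds = 5, validate = TRUE) {
  samples <- as.numeric(samples)
  if (validate) {
    if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
      stop("`rate` must be a single positive number", call. = FALSE)
    if (any(!is.finite(samples)))
      stop("segment '", segment_id, "': samples must be finite", call. = FALSE)
    expected <- as.integer(round(rate * seconds))
    if (length(samples) != expected)
      stop("segment '", segment_id, "': expected ", expected,
           " samples (", seconds, " s at ", rate, " Hz), got ",
           length(samples), call. = FALSE)
  }
  structure(
    list(case_id = as.character(case_id),
         segment_id = as.character(segment_id),
         samples = samples, rate = rate,
         ref_sbp = as.numeric(ref_sbp), ref_dbp = as.numeric(ref_dbp),
         seconds = seconds),
    class = "ppg_segment")
}

#' @export
print.ppg_segment <- function(x, ...) {
  cat(sprintf("<ppg_segment> %s/%s: %d samples @ %g Hz, ref %s/%s mmHg\n",
              x$case_id, x$segment_id, length(x$samples), x$rate,
              ifelse(is.na(x$ref_sbp), "-", format(x$ref_sbp)),
              ifelse(is.na(x$ref_dbp), "-", format(x$ref_dbp))))
  invisible(x)
}

# Manifest dialect: comma-separated, header
# case_id,segment_id,waveform_path,rate_hz,ref_sbp_mmHg,ref_dbp_mmHg
manifest_cols <- c("case_id", "segment_id", "waveform_path",
                   "rate_hz", "ref_sbp_mmHg", "ref_dbp_mmHg")

#' Read a segment manifest and its waveform files
#'
#' The manifest is a CSV file with header columns
#' `case_id,segment_id,waveform_path,rate_hz,ref_sbp_mmHg,ref_dbp_mmHg`.
#' Waveform files hold one numeric sample per line.  Empty reference-BP cells
#' are parsed as missing (`NA`), not as zero; such segments are kept here and
#' left for the quality stage to reject.  Relative `waveform_path` entries are
#' resolved against the directory containing the manifest.
#'
#' @param path Path to the manifest CSV.
#' @param seconds Nominal duration used for the sample-count check.
#' @return A list of [ppg_segment] objects in manifest order.
#' @export
read_manifest <- function(path, seconds = 5) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  hdr <- names(utils::read.csv(path, nrows = 0L))
  missing_cols <- setdiff(manifest_cols, hdr)
  if (length(missing_cols))
    stop("manifest ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- utils::read.csv(path, colClasses = c(case_id = "character",
                                             segment_id = "character",
                                             waveform_path = "character"),
                        stringsAsFactors = FALSE)
  base <- dirname(path)
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (is.na(row$segment_id) || !nzchar(row$segment_id) ||
        is.na(row$waveform_path) || !nzchar(row$waveform_path) ||
        is.na(row$rate_hz))
      stop("manifest ", path, ": malformed row at line ", i + 1L, call. = FALSE)
    wf <- row$waveform_path
    if (!file.exists(wf)) wf <- file.path(base, row$waveform_path)
    if (!file.exists(wf))
      stop("waveform file not found for segment '", row$segment_id,
           "': ", row$waveform_path, call. = FALSE)
    samples <- read_waveform(wf)
    out[[i]] <- ppg_segment(row$case_id, row$segment_id, samples,
                            rate = row$rate_hz,
                            ref_sbp = row$ref_sbp_mmHg,
                            ref_dbp = row$ref_dbp_mmHg,
                            seconds = seconds)
  }
  out
}

#' Read / write a single waveform file (one sample per line)
#'
#' @param path File path.
#' @return `read_waveform` returns a numeric vector.
#' @export
read_waveform <- function(path) {
  x <- scan(path, what = double(), quiet = TRUE)
  if (length(x) == 0L) stop("empty waveform file: ", path, call. = FALSE)
  x
}

#' @rdname read_waveform
#' @param samples Numeric vector to write.
#' @export
write_waveform <- function(samples, path) {
  writeLines(format_num(samples), path)
  invisible(path)
}

#' Write a list of segments as manifest plus waveform files
#'
#' @param segments List of [ppg_segment] objects.
#' @param dir Output directory (created if absent); waveforms are written to
#'   `<dir>/waveforms/<segment_id>.txt`.
#' @param manifest Manifest file name within `dir`.
#' @return Path of the manifest file, invisibly.
#' @export
write_manifest <- function(segments, dir, manifest = "manifest.csv") {
  dir.create(file.path(dir, "waveforms"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(segments, function(s) {
    rel <- file.path("waveforms", paste0(s$segment_id, ".txt"))
    write_waveform(s$samples, file.path(dir, rel))
    data.frame(case_id = s$case_id, segment_id = s$segment_id,
               waveform_path = rel, rate_hz = s$rate,
               ref_sbp_mmHg = s$ref_sbp, ref_dbp_mmHg = s$ref_dbp,
               stringsAsFactors = FALSE)
  })
  path <- file.path(dir, manifest)
  write_csv_plain(do.call(rbind, rows), path)
  invisible(path)
}

feature_table_cols <- c("case_id", "segment_id", "area", "rising_time",
                        "width_25", "width_50", "width_75",
                        "ref_sbp", "ref_dbp")

#' Validate a feature table
#'
#' Checks the column contract of a morphology feature table: the five features
#' must lie in \[0, 1\] and every row must satisfy the fractional-width ordering
#' `width_25 >= width_50 >= width_75` (a wider pulse base than crest is a
#' geometric necessity for a single-peaked pulse).
#'
#' @param table A data.frame of per-segment features.
#' @return The table, invisibly, or an error describing the first violation.
#' @export
validate_feature_table <- function(table) {
  missing_cols <- setdiff(feature_table_cols, names(table))
  if (length(missing_cols))
    stop("feature table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(table)) {
    feats <- c("area", "rising_time", "width_25", "width_50", "width_75")
    vals <- as.matrix(table[feats])
    if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
      stop("feature table: features must be finite and within [0, 1]",
           call. = FALSE)
    tol <- 1e-9
    bad <- which(table$width_25 < table$width_50 - tol |
                 table$width_50 < table$width_75 - tol)
    if (length(bad))
      stop("feature table: width ordering violated for segment(s) ",
           paste(utils::head(table$segment_id[bad], 5L), collapse = ", "),
           call. = FALSE)
  }
  invisible(table)
}

#' Write / read a feature table
#'
#' Plain CSV with a fixed header; numbers are written with enough significant
#' digits that a write/read round trip is the identity to well below 1e-9.
#' Reading re-validates the table contract.
#'
#' @param table Feature table data.frame.
#' @param path File path.
#' @return `read_feature_table` returns the validated data.frame.
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  write_csv_plain(table[feature_table_cols], path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = c(case_id = "character",
                                             segment_id = "character"),
                        stringsAsFactors = FALSE)
  validate_feature_table(df)
  df
}

# ---- internal helpers -------------------------------------------------------

# Locale-independent numeric formatting: dot decimal separator, 15 significant
# digits, NA as empty cell.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else formatC(v, digits = 15, format = "g", decimal.mark = ".")
  }, character(1))
  out
}

write_csv_plain <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- format_num(df[[j]])
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}
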