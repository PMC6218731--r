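#' Pulse area
#'
#' Trapezoidal integral of a normalized pulse over normalized time \[0, 1\].
#' On the two-dimensionally normalized pulse this is a dimensionless number in
#' (0, 1) reflecting vascular tone: broader, fuller pulses have larger area.
#'
#' @param p A `normalized_pulse`.
#' @return Numeric scalar.
#' @export
pulse_area <- function(p) {
  v <- pulse_values(p)
  n <- length(v)
  sum((v[-1] + v[-n]) / 2) / (n - 1)
}

#' Pulse rising time (crest time)
#'
#' Normalized time from the pulse foot to the systolic peak: the position of
#' the first sample attaining the maximum (which is 1 after normalization).
#' Shorter rising times accompany higher systolic pressure.
#'
#' @param p A `normalized_pulse`.
#' @return Numeric scalar in (0, 1].
#' @export
rising_time <- function(p) {
  v <- pulse_values(p)
  (which.max(v) - 1) / (length(v) - 1)
}

#' Pulse width at a fractional amplitude
#'
#' Duration for which the normalized pulse exceeds `fraction` of its unit
#' peak: the distance from the first up-crossing to the last down-crossing of
#' the level, with crossings located by linear interpolation between adjacent
#' samples.  Using the outermost crossings means a dicrotic wave re-crossing
#' the level does not split the width.
#'
#' @param p A `normalized_pulse`.
#' @param fraction Level in (0, 1).
#' @return Numeric scalar in \[0, 1).
#' @export
width_at <- function(p, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("`fraction` must be a single number in (0, 1)", call. = FALSE)
  v <- pulse_values(p)
  n <- length(v)
  t <- seq(0, 1, length.out = n)
  above <- v >= fraction
  if (!any(above)) return(0)
  first_above <- which(above)[1L]
  last_above <- which(above)[sum(above)]
  t_up <- if (first_above == 1L) t[1L] else {
    i <- first_above - 1L
    t[i] + (fraction - v[i]) / (v[i + 1L] - v[i]) * (t[i + 1L] - t[i])
  }
  t_down <- if (last_above == n) t[n] else {
    i <- last_above
    t[i] + (v[i] - fraction) / (v[i] - v[i + 1L]) * (t[i + 1L] - t[i])
  }
  t_down - t_up
}

#' Extract the five morphology features of one segment
#'
#' Runs [segment_pulses()] and computes, per complete beat, the pulse area,
#' rising time and widths at 25/50/75% of the unit amplitude, then averages
#' each feature arithmetically across the segment's beats.  One feature vector
#' per segment matches the reference cuff pressure, which is constant over the
#' 5 s window.
#'
#' @inheritParams segment_pulses
#' @return A one-row data.frame with columns `case_id, segment_id, area,
#'   rising_time, width_25, width_50, width_75, ref_sbp, ref_dbp` and
#'   attribute `n_beats`.
#' @export
extract_segment_features <- function(segment, order = 4, window = 19,
                                     n_points = 100, duration_tol = 0.15) {
  pp <- segment_pulses(segment, order = order, window = window,
                       n_points = n_points, duration_tol = duration_tol)
  per_beat <- vapply(pp$pulses, function(p)
    c(area = pulse_area(p),
      rising_time = rising_time(p),
      width_25 = width_at(p, 0.25),
      width_50 = width_at(p, 0.50),
      width_75 = width_at(p, 0.75)), numeric(5))
  m <- rowMeans(per_beat)
  out <- data.frame(case_id = segment$case_id, segment_id = segment$segment_id,
                    area = m[["area"]], rising_time = m[["rising_time"]],
                    width_25 = m[["width_25"]], width_50 = m[["width_50"]],
                    width_75 = m[["width_75"]],
                    ref_sbp = segment$ref_sbp, ref_dbp = segment$ref_dbp,
                    stringsAsFactors = FALSE)
  attr(out, "n_beats") <- length(pp$pulses)
  out
}

#' Build a feature table for a list of segments
#'
#' @param segments List of [ppg_segment] objects (normally the quality-accepted
#'   subset).
#' @inheritParams extract_segment_features
#' @return A validated feature table (see [validate_feature_table()]).
#' @export
extract_features <- function(segments, order = 4, window = 19,
                             n_points = 100, duration_tol = 0.15) {
  rows <- lapply(segments, extract_segment_features, order = order,
                 window = window, n_points = n_points,
                 duration_tol = duration_tol)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_feature_table(out)
  out
}

#' Variance inflation factors
#'
#' For each column j of the feature matrix, `VIF_j = 1 / (1 - R^2_j)` where
#' `R^2_j` comes from the least-squares regression (with intercept) of column
#' j on all remaining columns.  Perfect collinearity is reported as `Inf`.
#' VIF > 10 is the conventional flag for severe multicollinearity.
#'
#' @param x Numeric matrix or data.frame of n rows by k >= 2 features, n > k.
#' @return An object of class `vif_report`: list with `vif` (named numeric),
#'   `elimination_order` (empty here) and `retained` (all columns).
#' @export
compute_vif <- function(x) {
  x <- as.matrix(x)
  k <- ncol(x)
  n <- nrow(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(k))
  if (k < 2L) stop("need at least 2 features", call. = FALSE)
  if (n <= k) stop("need more rows than features", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  vif <- vapply(seq_len(k), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(x)
  structure(list(vif = vif, elimination_order = character(0),
                 retained = colnames(x), threshold = NA_real_),
            class = "vif_report")
}

#' Iterative VIF-based feature selection
#'
#' While any variance inflation factor exceeds `threshold`, the feature with
#' the largest VIF is dropped (ties broken towards the later column in input
#' order) and the VIFs are recomputed on the survivors.  On pulse-morphology
#' tables this reproduces the elimination of the mutually collinear
#' `width_50` and `width_75`, leaving `area`, `rising_time` and `width_25`.
#'
#' @inheritParams compute_vif
#' @param threshold VIF threshold (default 10).
#' @return A `vif_report` whose `vif` holds the final (retained) VIFs and
#'   whose `elimination_order` lists dropped features in drop order.
#' @export
select_features <- function(x, threshold = 10) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  eliminated <- character(0)
  repeat {
    if (ncol(x) < 2L) {
      if (ncol(x) == 0L)
        stop("all features eliminated: degenerate design", call. = FALSE)
      # a single surviving feature has no collinearity left to measure
      rep <- structure(list(vif = stats::setNames(1, colnames(x)),
                            elimination_order = eliminated,
                            retained = colnames(x), threshold = threshold),
                       class = "vif_report")
      return(rep)
    }
    rep <- compute_vif(x)
    if (all(rep$vif <= threshold)) {
      rep$elimination_order <- eliminated
      rep$threshold <- threshold
      return(rep)
    }
    worst <- max(rep$vif)
    drop_j <- max(which(rep$vif == worst))  # tie: later column goes first
    eliminated <- c(eliminated, colnames(x)[drop_j])
    x <- x[, -drop_j, drop = FALSE]
  }
}

#' @export
print.vif_report <- function(x, ...) {
  cat("<vif_report>\n  VIF:\n")
  for (nm in names(x$vif))
    cat(sprintf("    %-12s %s\n", nm, formatC(x$vif[[nm]], digits = 4)))
  if (length(x$elimination_order))
    cat("  eliminated:", paste(x$elimination_order, collapse = " -> "), "\n")
  cat("  retained:  ", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

pulse_values <- function(p) {
  if (inherits(p, "normalized_pulse")) p$values
  else stop("expected a `normalized_pulse`", call. = FALSE)
}
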