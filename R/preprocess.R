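#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing with the filter order and frame length
#' used throughout this package's pipeline (4th order, 19 samples by default).
#' Each output sample is the centre value of the polynomial of degree `order`
#' fitted to the surrounding `window` samples; at the boundaries the window
#' polynomial is evaluated at the boundary positions rather than truncated, so
#' the signal length is preserved and polynomials up to degree `order` are
#' reproduced exactly everywhere.
#'
#' @param x Numeric signal.
#' @param order Polynomial order (default 4).
#' @param window Odd frame length, must exceed `order` (default 19).
#' @return Smoothed signal of the same length.
#' @export
sg_smooth <- function(x, order = 4, window = 19) {
  if (window %% 2 != 1) stop("`window` must be odd", call. = FALSE)
  if (window <= order) stop("`window` must exceed `order`", call. = FALSE)
  if (length(x) < window)
    stop("signal shorter than the smoothing window", call. = FALSE)
  as.numeric(signal::sgolayfilt(as.numeric(x), p = order, n = window))
}

#' Detect pulse feet and systolic peaks
#'
#' Peak picking on a smoothed PPG signal with an adaptive threshold (a fixed
#' fraction of the local signal range over a rolling window) and a refractory
#' period, followed by foot placement at the minimum between successive peaks.
#' Feet and peaks strictly alternate starting with a foot, and every peak lies
#' between its flanking feet.
#'
#' @param x Smoothed numeric signal.
#' @param rate Sampling rate in Hz.
#' @param refractory Minimum peak-to-peak spacing in seconds (default 0.3,
#'   i.e. at most 200 beats/min).
#' @param frac Threshold height as a fraction of the local range (default 0.5).
#' @param window_s Rolling-range window in seconds (default 2).
#' @return A list of class `beat_annotation` with strictly increasing integer
#'   vectors `foot_indices` and `peak_indices`.
#' @export
detect_beats <- function(x, rate, refractory = 0.3, frac = 0.5, window_s = 2) {
  n <- length(x)
  rng <- diff(range(x))
  if (n < 3L || !is.finite(rng) || rng <= 0)
    stop("NoBeatsDetected: flat or degenerate signal", call. = FALSE)

  half <- max(1L, as.integer(round(window_s * rate / 2)))
  roll_max <- roll_stat(x, half, max)
  roll_min <- roll_stat(x, half, min)
  thr <- roll_min + frac * (roll_max - roll_min)

  # strict local maxima: x rises into i and falls after i
  dx <- diff(x)
  cand <- which(dx[-(n - 1L)] > 0 & dx[-1L] < 0) + 1L
  cand <- cand[x[cand] >= thr[cand]]
  if (!length(cand)) stop("NoBeatsDetected: no peaks above threshold", call. = FALSE)

  # refractory pruning: keep the taller of two close peaks
  min_gap <- as.integer(round(refractory * rate))
  peaks <- integer(0)
  for (p in cand) {
    if (length(peaks) && p - peaks[length(peaks)] < min_gap) {
      if (x[p] > x[peaks[length(peaks)]]) peaks[length(peaks)] <- p
    } else peaks <- c(peaks, p)
  }

  # rough baseline (rolling mean over about one beat period) so that
  # respiratory wander cannot drag the inter-peak minima away from the
  # diastolic feet
  spacing <- if (length(peaks) > 1L) stats::median(diff(peaks)) else
    2L * min_gap
  base <- roll_mean_reflect(x, max(2L, as.integer(round(spacing / 2))))
  xf <- x - base

  # each foot is the minimum of the detrended signal in a window ending at
  # the steepest point of the following systolic upstroke; anchoring on the
  # upstroke keeps shallow diastolic tails and residual wander from pulling
  # the foot away from the true beat onset
  dxs <- diff(x)
  back <- max(2L, as.integer(round(0.35 * spacing)))
  foot_before <- function(lo, hi) {
    # steepest rise in (lo, hi], then argmin of xf shortly before it
    m <- lo + which.max(dxs[lo:min(hi - 1L, n - 1L)]) - 1L
    a <- max(lo, m - back)
    a + which.min(xf[a:m]) - 1L
  }
  feet <- integer(length(peaks) + 1L)
  feet[1L] <- foot_before(1L, peaks[1L])
  if (length(peaks) > 1L) {
    for (k in seq_len(length(peaks) - 1L)) {
      feet[k + 1L] <- foot_before(peaks[k], peaks[k + 1L])
    }
  }
  feet[length(feet)] <- if (peaks[length(peaks)] < n - 2L) {
    foot_before(peaks[length(peaks)], n)
  } else n

  # degenerate edge: a foot coinciding with its peak breaks alternation
  keep <- feet[1:length(peaks)] < peaks & peaks < feet[2:length(feet)]
  peaks <- peaks[keep]
  if (!length(peaks)) stop("NoBeatsDetected: no complete beats", call. = FALSE)
  feet <- sort(unique(c(feet[c(keep, FALSE)], feet[c(FALSE, keep)])))

  structure(list(foot_indices = feet, peak_indices = peaks,
                 rough_baseline = base),
            class = "beat_annotation")
}

#' Remove respiratory baseline wander
#'
#' Subtracts the piecewise-linear interpolant through the pulse-foot samples,
#' extended flat beyond the first and last foot.  After removal every foot
#' sample sits at zero, so sub-Hz respiratory drift is eliminated without
#' distorting within-beat morphology.
#'
#' @param x Numeric signal.
#' @param annotation A `beat_annotation` from [detect_beats()].
#' @return The detrended signal.
#' @export
remove_baseline <- function(x, annotation) {
  feet <- annotation$foot_indices
  if (length(feet) < 2L)
    stop("baseline removal needs at least 2 pulse feet", call. = FALSE)
  base <- stats::approx(x = feet, y = x[feet], xout = seq_along(x),
                        rule = 2)$y
  x - base
}

#' Two-dimensional pulse normalization
#'
#' Resamples one beat onto a uniform grid of `n_points` samples over
#' normalized time \[0, 1\] by linear interpolation, then rescales the
#' amplitude so that the minimum is exactly 0 and the maximum exactly 1.
#' Normalization is invariant to affine changes of the input amplitude.
#'
#' @param beat Numeric vector of one beat's samples (>= 4 samples).
#' @param n_points Grid length N (default 100).
#' @param source Optional `(segment_id, beat ordinal)` provenance.
#' @return An object of class `normalized_pulse` with fields `values`
#'   (length `n_points`) and `source`.
#' @export
normalize_pulse <- function(beat, n_points = 100, source = NULL) {
  beat <- as.numeric(beat)
  if (length(beat) < 4L) stop("beat must have at least 4 samples", call. = FALSE)
  if (!all(is.finite(beat))) stop("beat samples must be finite", call. = FALSE)
  rng <- diff(range(beat))
  if (rng <= 0) stop("beat has zero amplitude range", call. = FALSE)
  t_in <- seq(0, 1, length.out = length(beat))
  t_out <- seq(0, 1, length.out = n_points)
  v <- stats::approx(t_in, beat, xout = t_out)$y
  v <- (v - min(v)) / (max(v) - min(v))
  structure(list(values = v, source = source), class = "normalized_pulse")
}

#' @export
print.normalized_pulse <- function(x, ...) {
  cat(sprintf("<normalized_pulse> N=%d, peak at t=%.3f\n",
              length(x$values),
              (which.max(x$values) - 1) / (length(x$values) - 1)))
  invisible(x)
}

#' Full preprocessing of one segment into normalized pulses
#'
#' Applies the pipeline smoothing -> beat detection -> baseline removal ->
#' per-beat two-dimensional normalization.  Beats whose foot-to-foot duration
#' deviates more than `duration_tol` from the segment's median beat duration
#' are discarded as incomplete (typically the partial beats cut off at the
#' segment boundaries).
#'
#' @inheritParams sg_smooth
#' @param segment A [ppg_segment].
#' @param n_points Normalized grid length (default 100).
#' @param duration_tol Fractional tolerance on beat duration (default 0.15).
#' @return List with `pulses` (list of `normalized_pulse`), `annotation`, and
#'   `detrended` (the baseline-free smoothed signal).
#' @export
segment_pulses <- function(segment, order = 4, window = 19, n_points = 100,
                           duration_tol = 0.15) {
  sm <- sg_smooth(segment$samples, order = order, window = window)
  ann <- detect_beats(sm, segment$rate)
  ann <- refine_feet(ann, segment$samples)
  # beats are delineated on the smoothed signal but cut from the raw
  # detrended one: at 100 Hz the 19-sample filter displaces an asymmetric
  # systolic peak by 1-2 samples, which would bias the rising time
  det <- remove_baseline(segment$samples, ann)
  feet <- ann$foot_indices
  durs <- diff(feet)
  med <- stats::median(durs)
  pulses <- list()
  for (k in seq_along(durs)) {
    # a foot on the segment boundary marks a truncated beat, not a real
    # onset; the first and last beats are dropped too when enough remain,
    # since their outer feet border truncated beats
    if (feet[k] <= 1L || feet[k + 1L] >= length(det)) next
    if (length(durs) > 2L && (k == 1L || k == length(durs))) next
    if (abs(durs[k] - med) > duration_tol * med) next
    beat <- det[feet[k]:feet[k + 1L]]
    if (diff(range(beat)) <= 0) next
    pulses[[length(pulses) + 1L]] <-
      normalize_pulse(beat, n_points = n_points,
                      source = list(segment_id = segment$segment_id,
                                    beat = k))
  }
  if (!length(pulses)) {
    # fall back to the single most regular interior beat
    interior <- which(feet[-length(feet)] > 1L & feet[-1L] < length(det))
    if (length(interior)) {
      k <- interior[which.min(abs(durs[interior] - med))]
      beat <- det[feet[k]:feet[k + 1L]]
      if (diff(range(beat)) > 0)
        pulses <- list(normalize_pulse(beat, n_points = n_points,
                                       source = list(segment_id = segment$segment_id,
                                                     beat = k)))
    }
  }
  if (!length(pulses))
    stop("segment '", segment$segment_id, "': no complete beats", call. = FALSE)
  list(pulses = pulses, annotation = ann, detrended = det)
}

# Re-localize each foot as the raw-signal minimum within a few samples of the
# smoothed-signal foot: smoothing rounds the V-shaped diastolic foot and can
# shift its minimum by 1-2 samples.  A refined foot is kept only if it
# preserves the foot/peak alternation.
refine_feet <- function(annotation, raw, halfwin = 3L) {
  feet <- annotation$foot_indices
  peaks <- annotation$peak_indices
  if (!is.null(annotation$rough_baseline))
    raw <- raw - annotation$rough_baseline
  n <- length(raw)
  for (k in seq_along(feet)) {
    lo <- max(1L, feet[k] - halfwin)
    hi <- min(n, feet[k] + halfwin)
    cand <- lo - 1L + which.min(raw[lo:hi])
    prev_ok <- k == 1L || !any(peaks >= cand & peaks < feet[k])
    next_ok <- k == length(feet) || !any(peaks <= cand & peaks > feet[k])
    below <- peaks[peaks < cand]
    above <- peaks[peaks > cand]
    ok <- (k == 1L || length(below) >= k - 1L) &&
      (k == length(feet) || length(above) >= length(peaks) - (k - 1L))
    if (ok && prev_ok && next_ok) feet[k] <- cand
  }
  if (any(diff(feet) <= 0)) return(annotation)
  structure(list(foot_indices = feet, peak_indices = peaks),
            class = "beat_annotation")
}

# centred moving average with reflected ends, so the estimate is not biased
# by truncated windows at the segment boundaries
roll_mean_reflect <- function(x, half) {
  n <- length(x)
  half <- min(half, n - 1L)
  xp <- c(rev(x[2:(half + 1L)]), x, rev(x[(n - half):(n - 1L)]))
  m <- stats::filter(xp, rep(1 / (2L * half + 1L), 2L * half + 1L),
                     sides = 2)
  as.numeric(m[(half + 1L):(half + n)])
}

# rolling statistic with edge truncation (used for the adaptive threshold)
roll_stat <- function(x, half, fun) {
  n <- length(x)
  vapply(seq_len(n), function(i)
    fun(x[max(1L, i - half):min(n, i + half)]), numeric(1))
}
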