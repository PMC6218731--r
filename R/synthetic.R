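#' Default morphology map linking blood pressure to pulse shape
#'
#' The generator ties pulse morphology to the latent blood pressures through
#' an invertible linear map: each of the three primary shape targets
#' (rising time, width at 25% amplitude, pulse area) is an affine function of
#' (SBP, DBP).  Rising time decreases with SBP, width_25 increases with DBP,
#' and area is tied to both.  The default coefficients keep all shape targets
#' strictly inside (0, 1) for SBP in \[70, 190\] and DBP in \[40, 100\] mmHg.
#' The map is a modelling stand-in for the qualitative association between BP
#' and pulse shape, not a physiological law.
#'
#' @return A 3 x 3 numeric matrix; rows `rising_time`, `width_25`, `area`,
#'   columns `intercept`, `sbp`, `dbp`.
#' @export
default_morphology_map <- function() {
  m <- rbind(
    rising_time = c(0.3933,   -0.001333, 0),
    width_25    = c(0.10,      0,         0.003),
    area        = c(0.098480, -0.0000723, 0.0018384))
  colnames(m) <- c("intercept", "sbp", "dbp")
  m
}

#' Apply / invert the morphology map
#'
#' `apply_morphology` maps (SBP, DBP) to the shape targets; `invert_morphology`
#' recovers (SBP, DBP) from measured rising time and width_25 (the area row is
#' a linear combination of the other two under the default map, so the
#' inversion uses the two independent coordinates).
#'
#' @param map Morphology map matrix (see [default_morphology_map()]).
#' @param sbp,dbp Numeric vectors of pressures in mmHg.
#' @return `apply_morphology`: data.frame with columns `rising_time`,
#'   `width_25`, `area`; `invert_morphology`: data.frame with `sbp`, `dbp`.
#' @export
apply_morphology <- function(map, sbp, dbp) {
  X <- cbind(1, sbp, dbp)
  out <- X %*% t(map)
  data.frame(rising_time = out[, "rising_time"],
             width_25 = out[, "width_25"], area = out[, "area"])
}

#' @rdname apply_morphology
#' @param rising_time,width_25 Measured shape features.
#' @export
invert_morphology <- function(map, rising_time, width_25) {
  A <- map[c("rising_time", "width_25"), c("sbp", "dbp")]
  if (abs(det(A)) < 1e-12)
    stop("morphology map is not invertible in (rising_time, width_25)",
         call. = FALSE)
  rhs <- rbind(rising_time - map["rising_time", "intercept"],
               width_25 - map["width_25", "intercept"])
  sol <- solve(A, rhs)
  data.frame(sbp = sol[1, ], dbp = sol[2, ])
}

#' Synthetic-dataset configuration
#'
#' Collects every knob of the synthetic PPG generator.  The defaults describe
#' a plausible bedside-monitor population: 32 cases of 50 segments, 5 s at
#' 100 Hz, heart rate 55-95 beats/min, 0.25 Hz respiratory baseline wander at
#' 20% of pulse amplitude, additive Gaussian sensor noise at 0.8% of pulse
#' amplitude (screened bedside PPG is a clean signal), 5%
#' artifact-contaminated segments, and a category mix of 80% normotensive,
#' 12% hypertensive and 8% hypotensive segments.
#'
#' @param n_cases Number of simulated subjects.
#' @param segments_per_case Segments generated per subject.
#' @param category_mix Proportions (normotensive, hypertensive, hypotensive),
#'   non-negative, summing to 1.
#' @param heart_rate_range Heart-rate interval in beats/min.
#' @param wander_freq Respiratory wander frequency in Hz; must stay below the
#'   lowest heart-rate fundamental so wander and pulses are separable.
#' @param wander_amp Wander amplitude as a fraction of pulse amplitude.
#' @param noise_sd Additive noise SD as a fraction of pulse amplitude.
#' @param artifact_rate Probability that a segment carries an artifact
#'   (saturation plateau or dropout).
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the configuration.
#' @param morphology_map Linear (SBP, DBP) -> shape map; see
#'   [default_morphology_map()].
#' @param rate Sampling rate in Hz.
#' @param seconds Segment length in seconds.
#' @param morph_jitter SDs of per-segment deviations of the three shape
#'   targets from the map (rising_time, width_25, area) — within-subject
#'   vascular variability not explained by BP.
#' @param bp_jitter SD (mmHg) of per-segment BP around the case anchor.
#' @param missing_ref_rate Fraction of segments whose reference BPs are
#'   blanked, emulating monitor gaps.
#' @param thresholds Category thresholds, as in [classify_category()].
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_cases = 32, segments_per_case = 50,
                         category_mix = c(0.8, 0.12, 0.08),
                         heart_rate_range = c(55, 95),
                         wander_freq = 0.25, wander_amp = 0.2,
                         noise_sd = 0.008, artifact_rate = 0.05,
                         seed = 1L,
                         morphology_map = default_morphology_map(),
                         rate = 100, seconds = 5,
                         morph_jitter = c(0.004, 0.014, 0.009),
                         bp_jitter = 1.5,
                         missing_ref_rate = 0,
                         thresholds = bp_thresholds()) {
  cfg <- list(n_cases = as.integer(n_cases),
              segments_per_case = as.integer(segments_per_case),
              category_mix = as.numeric(category_mix),
              heart_rate_range = as.numeric(heart_rate_range),
              wander_freq = wander_freq, wander_amp = wander_amp,
              noise_sd = noise_sd, artifact_rate = artifact_rate,
              seed = as.integer(seed), morphology_map = morphology_map,
              rate = rate, seconds = seconds,
              morph_jitter = as.numeric(morph_jitter),
              bp_jitter = bp_jitter, missing_ref_rate = missing_ref_rate,
              thresholds = thresholds)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  mix <- cfg$category_mix
  if (length(mix) != 3L || any(mix < 0) || abs(sum(mix) - 1) > 1e-9)
    stop("category_mix must be three non-negative proportions summing to 1",
         call. = FALSE)
  if (cfg$n_cases < 1L || cfg$segments_per_case < 1L)
    stop("n_cases and segments_per_case must be positive", call. = FALSE)
  hr <- cfg$heart_rate_range
  if (length(hr) != 2L || hr[1] > hr[2] || hr[1] <= 0)
    stop("heart_rate_range must be a valid bpm interval", call. = FALSE)
  if (cfg$wander_freq >= hr[1] / 60)
    stop("wander_freq must lie below the heart-rate fundamental (",
         round(hr[1] / 60, 3), " Hz)", call. = FALSE)
  if (cfg$noise_sd < 0 || cfg$wander_amp < 0 ||
      cfg$artifact_rate < 0 || cfg$artifact_rate > 1)
    stop("noise_sd/wander_amp must be >= 0 and artifact_rate in [0, 1]",
         call. = FALSE)
  # shape targets must stay strictly inside (0,1) over the drawn BP ranges
  corners <- expand.grid(sbp = c(70, 190), dbp = c(40, 100))
  tg <- apply_morphology(cfg$morphology_map, corners$sbp, corners$dbp)
  if (any(tg$rising_time <= 0.02) || any(tg$rising_time >= 0.98) ||
      any(tg$width_25 <= 0.02) || any(tg$width_25 >= 0.98) ||
      any(tg$area <= 0) || any(tg$area >= 1))
    stop("morphology_map leaves (0,1) over the BP range", call. = FALSE)
  invisible(cfg)
}

# ---- analytic beat model ----------------------------------------------------
# One beat on normalized time u in [0,1):
#   * a two-sided Gaussian systolic wave (rising sigma sigma_L = r/5, steep
#     falling sigma s),
#   * a prominent dicrotic wave (Gaussian bump, height ~1/3 of the systolic
#     amplitude, attenuating with SBP as vessels stiffen) that re-crosses the
#     25% level, so the outermost 25%-width extends past the systolic
#     envelope by a controllable amount,
#   * a low diastolic "runoff" pedestal (a capped ramp, zero at both beat
#     boundaries) giving every beat a sharp V-shaped minimum at its foot.
# The parameterization is solved so that the peak sits at u = r, the
# outermost 25%-width of the amplitude-normalized beat equals w25, and the
# normalized area matches the requested target (the pedestal height c
# absorbs the area adjustment).  Because the 50% and 75% widths live on the
# steep systolic fall while the dicrotic extension moves only the 25% width,
# the upper widths are geometric consequences of the systolic wave alone.

RAMP_DELTA <- 0.05  # pedestal rise length, fraction of the beat

# mean dicrotic extension of the outermost 25% width beyond the systolic
# envelope, as a function of the map's width target (dicrotic timing scales
# with systolic duration)
dic_ext_mean <- function(w25_map) 0.04 + 0.15 * w25_map

# after amplitude normalization (peak = 1 + c), a fractional level q meets
# the systolic envelope where env = q (1 + c) - c
level_on_envelope <- function(q, c) q * (1 + c) - c

solve_beat_params <- function(r, w25, area, ext, hb = 0.33,
                              c_range = c(0.01, 0.09)) {
  sigma_L <- r / 5
  rise_area <- sigma_L * sqrt(2 * pi) / 2
  sigma2 <- 0.35 * ext
  geom <- function(c) {
    lvl <- level_on_envelope(0.25, c)
    cross <- sqrt(2 * log(1 / lvl))
    # the systolic envelope's falling 25%-crossing sits `ext` before the
    # target outermost width; the dicrotic wave supplies the rest
    v25 <- max(w25 - ext - cross * sigma_L, 0.02)
    s <- v25 / cross
    # dicrotic centre solved so that envelope + bump re-cross the 25% level
    # exactly at the target outermost width
    env_at_target <- exp(-((v25 + ext) / s)^2 / 2)
    bump_needed <- max(lvl - env_at_target, 0.02)
    mu2 <- r + v25 + ext - sigma2 * sqrt(2 * max(log(hb / bump_needed), 0.01))
    list(c = c, v25 = v25, s = s, mu2 = mu2,
         fall_area = s * sqrt(2 * pi) / 2,
         bump_area = hb * sigma2 * sqrt(2 * pi))
  }
  # pedestal height solved so the normalized area hits the target
  area_at <- function(g)
    (rise_area + g$fall_area + g$bump_area + g$c * (1 - RAMP_DELTA)) / (1 + g$c)
  cs <- seq(c_range[1], c_range[2], length.out = 33)
  gs <- lapply(cs, geom)
  dev <- vapply(gs, function(g) abs(area_at(g) - area), numeric(1))
  g <- gs[[which.min(dev)]]
  list(r = r, sigma_L = sigma_L, s = g$s, a2 = hb, mu2 = g$mu2,
       sigma2 = sigma2, c = g$c)
}

beat_value <- function(u, bp) {
  v <- numeric(length(u))
  left <- u < bp$r
  v[left] <- exp(-(bp$r - u[left])^2 / (2 * bp$sigma_L^2))
  v[!left] <- exp(-(u[!left] - bp$r)^2 / (2 * bp$s^2))
  v + bp$a2 * exp(-(u - bp$mu2)^2 / (2 * bp$sigma2^2)) +
    bp$c * pmin(1, pmin(u, 1 - u) / RAMP_DELTA)
}

# realized morphology of the analytic beat, measured on a fine grid with the
# same definitions the feature module uses
beat_truth <- function(bp, n = 2001) {
  u <- seq(0, 1, length.out = n)
  v <- beat_value(u, bp)
  v <- (v - min(v)) / (max(v) - min(v))
  p <- structure(list(values = v, source = NULL), class = "normalized_pulse")
  c(rising_time = rising_time(p),
    width_25 = width_at(p, 0.25),
    width_50 = width_at(p, 0.50),
    width_75 = width_at(p, 0.75),
    area = pulse_area(p))
}

# per-category BP anchor boxes: 2 mmHg inside the category thresholds so that
# segment-level jitter cannot flip the label
category_boxes <- function(th) {
  list(normotensive = list(sbp = c(th$hypo_sbp + 2, th$hyper_sbp - 5),
                           dbp = c(50, th$hyper_dbp - 5)),
       hypertensive = list(sbp = c(th$hyper_sbp, 185), dbp = c(75, 100)),
       hypotensive  = list(sbp = c(72, th$hypo_sbp - 2), dbp = c(42, 58)))
}

#' Generate a synthetic PPG dataset with known ground truth
#'
#' Simulates `n_cases x segments_per_case` five-second PPG segments whose
#' pulse morphology is deterministically linked to latent SBP/DBP through the
#' configuration's morphology map, with respiratory baseline wander, additive
#' sensor noise, and (optionally) artifact-contaminated segments carrying
#' saturation plateaus or signal dropouts.  Identical configurations produce
#' byte-identical datasets.
#'
#' Sensor noise and artifacts are drawn from a per-segment sub-stream whose
#' seed is itself drawn from the main stream, so two configurations differing
#' only in `noise_sd`, `wander_amp` or `artifact_rate` share exactly the same
#' latent BPs and pulse morphology.
#'
#' @param config A [synth_config()].
#' @return A list of `synth_segment` objects, each with fields `segment`
#'   ([ppg_segment], reference BPs filled from the ground truth), `true_sbp`,
#'   `true_dbp`, `true_category`, `artifact_flag`, and `true_morph` (realized
#'   rising time, widths and area of the segment's analytic beat).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(cfg$seed)

  boxes <- category_boxes(cfg$thresholds)
  cats <- names(boxes)
  n_samp <- as.integer(round(cfg$rate * cfg$seconds))
  t_abs <- (seq_len(n_samp) - 1) / cfg$rate
  out <- vector("list", cfg$n_cases * cfg$segments_per_case)
  idx <- 0L

  for (ci in seq_len(cfg$n_cases)) {
    case_id <- sprintf("case%03d", ci)
    # per-case anchors: one BP operating point per category, a heart rate and
    # an amplitude gain
    anchors <- lapply(boxes, function(b)
      c(sbp = stats::runif(1, b$sbp[1], b$sbp[2]),
        dbp = stats::runif(1, b$dbp[1], b$dbp[2])))
    case_hr <- stats::runif(1, cfg$heart_rate_range[1], cfg$heart_rate_range[2])
    case_amp <- stats::runif(1, 0.8, 1.2)

    for (si in seq_len(cfg$segments_per_case)) {
      idx <- idx + 1L
      seg_id <- sprintf("%s_seg%04d", case_id, si)
      cat_i <- sample.int(3L, 1L, prob = cfg$category_mix)
      box <- boxes[[cat_i]]
      a <- anchors[[cat_i]]
      sbp <- clamp(a[["sbp"]] + stats::rnorm(1, 0, cfg$bp_jitter),
                   box$sbp[1], box$sbp[2])
      dbp <- clamp(a[["dbp"]] + stats::rnorm(1, 0, cfg$bp_jitter),
                   box$dbp[1], box$dbp[2])

      tg <- apply_morphology(cfg$morphology_map, sbp, dbp)
      jit <- stats::rnorm(3, 0, cfg$morph_jitter)
      r_t <- clamp(tg$rising_time + jit[1], 0.06, 0.9)
      w_t <- clamp(tg$width_25 + jit[2], 0.08, 0.9)
      a_t <- clamp(tg$area + jit[3], 0.05, 0.95)
      # the width jitter is realized through the dicrotic extension, so it
      # moves only the outermost 25% width, not the crest widths
      ext0 <- dic_ext_mean(tg$width_25)
      ext <- clamp(ext0 + jit[2], 0.03, 0.16)
      w_t <- tg$width_25 + (ext - ext0)
      hb <- clamp(0.42 - 0.001 * sbp + stats::rnorm(1, 0, 0.015), 0.22, 0.36)
      bp_par <- solve_beat_params(r_t, w_t, a_t, ext = ext, hb = hb)

      hr <- clamp(case_hr + stats::rnorm(1, 0, 1.5),
                  cfg$heart_rate_range[1], cfg$heart_rate_range[2])
      period <- 60 / hr
      phase <- stats::runif(1)
      wander_phase <- stats::runif(1, 0, 2 * pi)
      noise_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      miss <- cfg$missing_ref_rate > 0 &&
        stats::runif(1) < cfg$missing_ref_rate

      u <- ((t_abs + phase * period) %% period) / period
      x <- case_amp * beat_value(u, bp_par)
      if (cfg$wander_amp > 0)
        x <- x + cfg$wander_amp * case_amp *
          sin(2 * pi * cfg$wander_freq * t_abs + wander_phase)

      # sub-stream: sensor noise and artifacts
      main_state <- get(".Random.seed", envir = globalenv())
      set.seed(noise_seed)
      if (cfg$noise_sd > 0)
        x <- x + stats::rnorm(n_samp, 0, cfg$noise_sd * case_amp)
      artifact <- stats::runif(1) < cfg$artifact_rate
      if (artifact) x <- inject_artifact(x, cfg$rate, case_amp)
      assign(".Random.seed", main_state, envir = globalenv())

      seg <- ppg_segment(case_id, seg_id, x, rate = cfg$rate,
                         ref_sbp = if (miss) NA_real_ else sbp,
                         ref_dbp = if (miss) NA_real_ else dbp,
                         seconds = cfg$seconds)
      out[[idx]] <- structure(
        list(segment = seg, true_sbp = sbp, true_dbp = dbp,
             true_category = classify_category(sbp, dbp, cfg$thresholds),
             artifact_flag = artifact,
             true_morph = beat_truth(bp_par),
             target_morph = c(rising_time = r_t, width_25 = w_t, area = a_t)),
        class = "synth_segment")
    }
  }
  out
}

# saturation plateau (constant run at the segment ceiling) or dropout
# (constant run below the running minimum); both emulate the classic
# unusable-segment morphologies seen on bedside monitors
inject_artifact <- function(x, rate, amp) {
  n <- length(x)
  len <- as.integer(round(stats::runif(1, 0.4, 1.0) * rate))
  start <- sample.int(n - len, 1L)
  win <- start:(start + len - 1L)
  if (stats::runif(1) < 0.5) {
    x[win] <- max(x) + 0.02 * amp
  } else {
    x[win] <- min(x) - 0.05 * amp
  }
  x
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Empirical category proportions of a synthetic dataset
#'
#' @param dataset List of `synth_segment` objects.
#' @return Named numeric vector of proportions
#'   (normotensive, hypertensive, hypotensive), summing to 1.
#' @export
category_mix_of <- function(dataset) {
  if (!length(dataset)) stop("empty dataset", call. = FALSE)
  cats <- vapply(dataset, function(s) s$true_category, character(1))
  lev <- c("normotensive", "hypertensive", "hypotensive")
  tab <- table(factor(cats, levels = lev))
  stats::setNames(as.numeric(tab) / length(dataset), lev)
}

#' Ground-truth table of a synthetic dataset
#'
#' @param dataset List of `synth_segment` objects.
#' @return data.frame with identity, true BPs, category, artifact flag and the
#'   realized morphology of the underlying analytic beat.
#' @export
truth_table <- function(dataset) {
  do.call(rbind, lapply(dataset, function(s) {
    data.frame(case_id = s$segment$case_id, segment_id = s$segment$segment_id,
               true_sbp = s$true_sbp, true_dbp = s$true_dbp,
               true_category = s$true_category,
               artifact_flag = s$artifact_flag,
               true_rising_time = s$true_morph[["rising_time"]],
               true_width_25 = s$true_morph[["width_25"]],
               true_width_50 = s$true_morph[["width_50"]],
               true_width_75 = s$true_morph[["width_75"]],
               true_area = s$true_morph[["area"]],
               stringsAsFactors = FALSE)
  }))
}

#' Write a synthetic dataset to disk
#'
#' Writes the manifest + waveform files (see [write_manifest()]) and a
#' sidecar `truth.csv` with the ground-truth table.
#'
#' @param dataset List of `synth_segment` objects.
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_synth_dataset <- function(dataset, dir) {
  segs <- lapply(dataset, function(s) s$segment)
  path <- write_manifest(segs, dir)
  write_csv_plain(truth_table(dataset), file.path(dir, "truth.csv"))
  invisible(path)
}
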