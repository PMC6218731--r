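#' Blood-pressure category thresholds
#'
#' Default rule: hypertensive when `sbp >= hyper_sbp` or `dbp >= hyper_dbp`;
#' otherwise hypotensive when `sbp < hypo_sbp`; otherwise normotensive.
#' Diastolic pressure is deliberately not used for the hypotensive rule,
#' since clinically normotensive monitor readings reach diastolic values in
#' the low 40s.
#'
#' @param hyper_sbp,hyper_dbp,hypo_sbp Threshold pressures in mmHg.
#' @return A list of class `bp_thresholds`.
#' @export
bp_thresholds <- function(hyper_sbp = 140, hyper_dbp = 90, hypo_sbp = 90) {
  structure(list(hyper_sbp = hyper_sbp, hyper_dbp = hyper_dbp,
                 hypo_sbp = hypo_sbp), class = "bp_thresholds")
}

#' Classify a blood pressure reading into a clinical category
#'
#' @param sbp,dbp Pressures in mmHg (vectorized).
#' @param thresholds A [bp_thresholds()].
#' @return Character vector: `"normotensive"`, `"hypertensive"` or
#'   `"hypotensive"`.
#' @export
classify_category <- function(sbp, dbp, thresholds = bp_thresholds()) {
  if (any(!is.finite(sbp)) || any(!is.finite(dbp)))
    stop("blood pressures must be finite", call. = FALSE)
  ifelse(sbp >= thresholds$hyper_sbp | dbp >= thresholds$hyper_dbp,
         "hypertensive",
         ifelse(sbp < thresholds$hypo_sbp, "hypotensive", "normotensive"))
}

#' Seeded k-fold assignment
#'
#' Random permutation followed by round-robin labelling, so fold sizes differ
#' by at most one (8133 rows over 10 folds gives three folds of 814 and seven
#' of 813).
#'
#' @param n Number of rows.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1..k`.
#' @export
kfold_assign <- function(n, k = 10, seed = 1L) {
  if (k < 2 || n < k) stop("need n >= k >= 2", call. = FALSE)
  perm <- local_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), length.out = n)
  fold
}

#' Cross-validated out-of-fold BP estimates
#'
#' For each fold, both targets (SBP and DBP) are fitted on the remaining
#' k-1 folds over the selected features and predicted on the held-out fold,
#' so every segment receives exactly one out-of-fold estimate per target.
#'
#' @param features A feature table (see [validate_feature_table()]) with
#'   non-missing `ref_sbp`/`ref_dbp`.
#' @param model Model spec: `"mlr"`, `"svr"` or `"tree"`, or a list
#'   `list(method = ..., <hyperparameters>)` passed on to the fitter.
#' @param feature_names Feature columns used as predictors (default the
#'   VIF-selected trio `area`, `rising_time`, `width_25`).
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param thresholds Category thresholds used to label each segment's
#'   reference category.
#' @return data.frame with one row per segment: identities, references,
#'   out-of-fold estimates `est_sbp`/`est_dbp`, `fold` and
#'   `ref_category`.
#' @export
cross_validate <- function(features, model = "tree",
                           feature_names = c("area", "rising_time", "width_25"),
                           k = 10, seed = 1L,
                           thresholds = bp_thresholds()) {
  spec <- model_spec(model)
  if (any(is.na(features$ref_sbp)) || any(is.na(features$ref_dbp)))
    stop("feature table contains segments without reference BPs; ",
         "screen with filter_dataset() first", call. = FALSE)
  n <- nrow(features)
  fold <- kfold_assign(n, k = k, seed = seed)
  X <- as.matrix(features[feature_names])
  est_sbp <- numeric(n)
  est_dbp <- numeric(n)
  for (fi in seq_len(k)) {
    test <- fold == fi
    fit_predict <- function(y) {
      m <- tryCatch(do.call(spec$fit, c(list(x = X[!test, , drop = FALSE],
                                             y = y[!test]), spec$args)),
                    error = function(e)
                      stop("fold ", fi, ": ", conditionMessage(e),
                           call. = FALSE))
      stats::predict(m, X[test, , drop = FALSE])
    }
    est_sbp[test] <- fit_predict(features$ref_sbp)
    est_dbp[test] <- fit_predict(features$ref_dbp)
  }
  data.frame(case_id = features$case_id, segment_id = features$segment_id,
             ref_sbp = features$ref_sbp, ref_dbp = features$ref_dbp,
             est_sbp = est_sbp, est_dbp = est_dbp, fold = fold,
             ref_category = classify_category(features$ref_sbp,
                                              features$ref_dbp, thresholds),
             stringsAsFactors = FALSE)
}

model_spec <- function(model) {
  if (is.character(model)) model <- list(method = model)
  method <- match.arg(model$method, c("tree", "mlr", "svr"))
  args <- model[setdiff(names(model), "method")]
  fit <- switch(method, tree = fit_tree, mlr = fit_mlr, svr = fit_svr)
  list(method = method, fit = fit, args = args)
}

#' Per-case averaged reference and estimated pressures
#'
#' Averages reference and estimated BPs over each case's qualifying segments
#' (optionally restricted to one reference category) and takes the
#' difference, reference minus estimate.  Cases with no qualifying segment
#' are omitted, mirroring how per-category clinical summaries leave gaps for
#' cases never observed in a category.
#'
#' @param records Estimate records from [cross_validate()].
#' @param category Optional category filter
#'   (`"normotensive"/"hypertensive"/"hypotensive"`).
#' @return data.frame with one row per case: `n_segments`, per-target mean
#'   reference, mean estimate and difference (mmHg).
#' @export
per_case_summary <- function(records, category = NULL) {
  if (!nrow(records)) stop("no records", call. = FALSE)
  if (!is.null(category)) records <- records[records$ref_category == category, ]
  if (!nrow(records)) {
    return(data.frame(case_id = character(0), n_segments = integer(0),
                      ref_sbp = numeric(0), est_sbp = numeric(0),
                      diff_sbp = numeric(0), ref_dbp = numeric(0),
                      est_dbp = numeric(0), diff_dbp = numeric(0),
                      stringsAsFactors = FALSE))
  }
  agg <- function(v) tapply(v, records$case_id, mean)
  ref_sbp <- agg(records$ref_sbp); est_sbp <- agg(records$est_sbp)
  ref_dbp <- agg(records$ref_dbp); est_dbp <- agg(records$est_dbp)
  out <- data.frame(case_id = names(ref_sbp),
                    n_segments = as.integer(table(records$case_id)[names(ref_sbp)]),
                    ref_sbp = as.numeric(ref_sbp), est_sbp = as.numeric(est_sbp),
                    diff_sbp = as.numeric(ref_sbp - est_sbp),
                    ref_dbp = as.numeric(ref_dbp), est_dbp = as.numeric(est_dbp),
                    diff_dbp = as.numeric(ref_dbp - est_dbp),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$case_id), , drop = FALSE]
}

#' Mean and SD of per-case differences
#'
#' @param differences Numeric vector of per-case differences
#'   (reference minus estimate, mmHg).
#' @return Named vector `c(mean, sd)` using the n-1 sample SD.
#' @export
difference_stats <- function(differences) {
  differences <- differences[!is.na(differences)]
  if (length(differences) < 2L)
    stop("need at least 2 per-case differences", call. = FALSE)
  c(mean = mean(differences), sd = stats::sd(differences))
}

#' Bland-Altman bias and limits of agreement
#'
#' @inheritParams difference_stats
#' @return Named vector `c(bias, lower, upper)` with
#'   `lower/upper = bias -/+ 1.96 * sd`.
#' @export
bland_altman <- function(differences) {
  st <- difference_stats(differences)
  c(bias = unname(st["mean"]),
    lower = unname(st["mean"] - 1.96 * st["sd"]),
    upper = unname(st["mean"] + 1.96 * st["sd"]))
}

#' ISO-style accuracy verdict
#'
#' Accuracy criterion for noninvasive BP devices: mean difference no greater
#' than 5 mmHg in magnitude and SD of difference no greater than 8 mmHg,
#' boundaries inclusive.
#'
#' @param mean_diff Mean of per-case differences (mmHg).
#' @param sd_diff SD of per-case differences (mmHg).
#' @param max_mean,max_sd Criterion bounds (defaults 5 and 8 mmHg).
#' @return Logical.
#' @export
iso_check <- function(mean_diff, sd_diff, max_mean = 5, max_sd = 8) {
  if (!is.finite(mean_diff) || !is.finite(sd_diff))
    stop("mean_diff and sd_diff must be finite", call. = FALSE)
  abs(mean_diff) <= max_mean && sd_diff <= max_sd
}

#' Per-category and overall agreement report
#'
#' Stratifies segments by their REFERENCE BP category, aggregates per case
#' within each stratum, and reports for each stratum (plus one unstratified
#' overall row, per target): number of cases, mean and n-1 SD of the
#' per-case differences, Bland-Altman bias and limits of agreement, and the
#' ISO verdict.  Strata with fewer than two cases get `NA` for the SD-based
#' quantities.
#'
#' @param records Estimate records from [cross_validate()].
#' @param thresholds Category thresholds (used only for labelling if
#'   `records` lacks `ref_category`).
#' @return data.frame with one row per (stratum, target).
#' @export
category_report <- function(records, thresholds = bp_thresholds()) {
  if (!nrow(records)) stop("no records", call. = FALSE)
  if (is.null(records$ref_category))
    records$ref_category <- classify_category(records$ref_sbp,
                                              records$ref_dbp, thresholds)
  strata <- c("overall", "normotensive", "hypertensive", "hypotensive")
  rows <- list()
  for (st in strata) {
    cs <- per_case_summary(records,
                           category = if (st == "overall") NULL else st)
    for (target in c("sbp", "dbp")) {
      d <- cs[[paste0("diff_", target)]]
      if (length(d) >= 2L) {
        stt <- difference_stats(d)
        ba <- bland_altman(d)
        rows[[length(rows) + 1L]] <- data.frame(
          category = st, target = toupper(target), n_cases = length(d),
          mean_diff = stt[["mean"]], sd_diff = stt[["sd"]],
          ba_bias = ba[["bias"]], ba_lower = ba[["lower"]],
          ba_upper = ba[["upper"]],
          iso_pass = iso_check(stt[["mean"]], stt[["sd"]]),
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          category = st, target = toupper(target), n_cases = length(d),
          mean_diff = if (length(d)) mean(d) else NA_real_,
          sd_diff = NA_real_, ba_bias = NA_real_, ba_lower = NA_real_,
          ba_upper = NA_real_, iso_pass = NA,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Round half away from zero (display convention of clinical tables)
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# evaluate an expression under a temporary seed, restoring the RNG state
local_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
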