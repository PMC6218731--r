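#' Packaged clinical reference tables
#'
#' Per-case results reported for a regression-tree BP estimator evaluated on
#' a 32-case clinical PPG dataset (8133 good-quality 5 s segments recorded on
#' bedside monitors), bundled as plain-text fixtures so the package's
#' agreement statistics can be validated against published clinical numbers
#' without access to the recordings themselves:
#' \describe{
#'   \item{`segment_counts`}{per-case segment counts by BP category, plus
#'     rejected (bad quality / missing reference) counts;}
#'   \item{`tree_overall`}{per-case averaged reference and estimated SBP/DBP
#'     with their differences, all segments pooled;}
#'   \item{`tree_sbp_by_category`, `tree_dbp_by_category`}{the same
#'     differences stratified by reference BP category (empty cells where a
#'     case has no segments in a category).}
#' }
#'
#' @param which One of `"segment_counts"`, `"tree_overall"`,
#'   `"tree_sbp_by_category"`, `"tree_dbp_by_category"`.
#' @return A data.frame; missing table cells are `NA`.
#' @export
clinical_table <- function(which = c("segment_counts", "tree_overall",
                                     "tree_sbp_by_category",
                                     "tree_dbp_by_category")) {
  which <- match.arg(which)
  file <- switch(which,
                 segment_counts = "clinical_segment_counts.csv",
                 tree_overall = "clinical_tree_overall.csv",
                 tree_sbp_by_category = "clinical_tree_sbp_by_category.csv",
                 tree_dbp_by_category = "clinical_tree_dbp_by_category.csv")
  path <- system.file("extdata", file, package = "ppgbp", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
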