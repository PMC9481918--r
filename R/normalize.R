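#' Control-anchored size factors
#'
#' Per-sample scaling factors computed by median-of-ratios over control
#' guides only, so that normalization is anchored on the screen's internal
#' null (non-targeting guides) rather than on targeting guides that are
#' under selection. For each control guide the geometric mean across
#' samples is the reference; a sample's factor is the median of its
#' count/reference ratios, rescaled so the factors have geometric mean 1.
#'
#' If every control guide contains a zero in some sample, the median of
#' ratios is undefined and the function falls back to ratios of total
#' control counts (with a warning). A sample with zero total control
#' counts is an error.
#'
#' @param table a `guide_count_table`.
#' @param control_guide_ids guide ids to anchor on (>= 2).
#' @return Numeric vector of positive per-sample factors, named by sample,
#'   geometric mean 1.
#' @export
control_size_factors <- function(table, control_guide_ids) {
  stopifnot(inherits(table, "guide_count_table"))
  missing <- setdiff(control_guide_ids, rownames(table$counts))
  if (length(missing) > 0) {
    is_abort(paste0("control guides absent from table: ",
                    paste(utils::head(missing, 5), collapse = ", ")),
             "isletscreen_data_error")
  }
  if (length(control_guide_ids) < 2) {
    is_abort("need >= 2 control guides for size factors",
             "isletscreen_data_error")
  }
  ctrl <- table$counts[control_guide_ids, , drop = FALSE]
  totals <- colSums(ctrl)
  if (any(totals == 0)) {
    is_abort(paste0("zero total control counts in sample(s): ",
                    paste(colnames(ctrl)[totals == 0], collapse = ", ")),
             "isletscreen_data_error")
  }
  positive <- rowSums(ctrl == 0) == 0
  if (!any(positive)) {
    warning("all control guides contain a zero; falling back to ",
            "total-control-count ratios")
    f <- totals / geometric_mean(totals)
    return(f)
  }
  use <- ctrl[positive, , drop = FALSE]
  ref <- apply(use, 1, geometric_mean)
  f <- apply(use / ref, 2, stats::median)
  f / geometric_mean(f)
}
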