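#' Construct and validate a guide count table
#'
#' The central container of the screen: a non-negative integer matrix of
#' guide-level read counts, guides in rows and mouse samples in columns,
#' with a sample sheet mapping each sample to a condition (`control` or
#' `hPi`) and a mouse id. Counts are stored per mouse sample, never
#' pre-pooled; pooling across mice happens only inside the statistics.
#'
#' @param counts integer matrix, rownames guide ids, colnames sample ids.
#' @param samples data frame with columns `sample_id`, `condition`,
#'   `mouse_id`; one row per column of `counts`, matched by `sample_id`.
#' @return A `guide_count_table`: list with elements `counts` and `samples`.
#' @export
guide_count_table <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    is_abort("counts must have guide rownames and sample colnames",
             "isletscreen_data_error")
  }
  if (anyDuplicated(rownames(counts))) {
    is_abort("duplicate guide ids in count matrix", "isletscreen_data_error")
  }
  if (anyDuplicated(colnames(counts))) {
    is_abort("duplicate sample ids in count matrix", "isletscreen_data_error")
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    is_abort("counts must be non-negative and complete",
             "isletscreen_data_error")
  }
  if (any(counts != floor(counts))) {
    is_abort("counts must be integers", "isletscreen_data_error")
  }
  storage.mode(counts) <- "integer"

  required <- c("sample_id", "condition", "mouse_id")
  if (!all(required %in% names(samples))) {
    is_abort(paste0("sample sheet needs columns: ",
                    paste(required, collapse = ", ")),
             "isletscreen_data_error")
  }
  samples <- as.data.frame(samples)[required]
  samples$sample_id <- as.character(samples$sample_id)
  samples$condition <- as.character(samples$condition)
  samples$mouse_id <- as.character(samples$mouse_id)
  if (anyDuplicated(samples$sample_id)) {
    is_abort("duplicate sample_id in sample sheet", "isletscreen_data_error")
  }
  bad_cond <- setdiff(unique(samples$condition), CONDITIONS)
  if (length(bad_cond) > 0) {
    is_abort(paste0("unknown condition(s): ",
                    paste(bad_cond, collapse = ", "),
                    " (expected control/hPi)"),
             "isletscreen_data_error")
  }
  missing_in_sheet <- setdiff(colnames(counts), samples$sample_id)
  missing_in_counts <- setdiff(samples$sample_id, colnames(counts))
  if (length(missing_in_sheet) > 0 || length(missing_in_counts) > 0) {
    is_abort(paste0(
      "sample sheet and count columns disagree",
      if (length(missing_in_sheet) > 0)
        paste0("; not in sheet: ", paste(missing_in_sheet, collapse = ", ")),
      if (length(missing_in_counts) > 0)
        paste0("; not in counts: ", paste(missing_in_counts, collapse = ", "))
    ), "isletscreen_data_error")
  }
  samples <- samples[match(colnames(counts), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples),
            class = "guide_count_table")
}

#' @export
print.guide_count_table <- function(x, ...) {
  cat(sprintf("guide_count_table: %d guides x %d samples (%d control, %d hPi)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$samples$condition == "control"),
              sum(x$samples$condition == "hPi")))
  invisible(x)
}

#' Sample ids belonging to one condition
#' @param table a `guide_count_table`.
#' @param condition `"control"` or `"hPi"`.
#' @return Character vector of sample ids.
#' @export
condition_samples <- function(table, condition) {
  stopifnot(inherits(table, "guide_count_table"))
  condition <- match.arg(condition, CONDITIONS)
  table$samples$sample_id[table$samples$condition == condition]
}

#' Check a count table against a guide library
#'
#' Every library guide must be present in the table (the screen sequences
#' the whole pool); extra rows unknown to the library are rejected.
#' @param table a `guide_count_table`.
#' @param library a `guide_library`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_counts_against_library <- function(table, library) {
  stopifnot(inherits(table, "guide_count_table"),
            inherits(library, "guide_library"))
  missing <- setdiff(library$guide_id, rownames(table$counts))
  if (length(missing) > 0) {
    is_abort(paste0("count table is missing ", length(missing),
                    " library guide(s): ",
                    paste(utils::head(missing, 5), collapse = ", "),
                    if (length(missing) > 5) ", ..."),
             "isletscreen_data_error")
  }
  extra <- setdiff(rownames(table$counts), library$guide_id)
  if (length(extra) > 0) {
    is_abort(paste0("count table has ", length(extra),
                    " guide(s) absent from the library: ",
                    paste(utils::head(extra, 5), collapse = ", ")),
             "isletscreen_data_error")
  }
  invisible(TRUE)
}
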