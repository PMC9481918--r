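#' Read and write guide library TSVs
#'
#' Libraries are UTF-8 tab-delimited files with header columns `guide_id`,
#' `gene`, `class`, `spacer`; `#` comment lines are ignored. `class` values
#' are mapped onto `targeting` / `non_targeting` / `intergenic` (common
#' spellings such as "NT", "non-targeting" or "control" are accepted).
#' Control guides may leave `gene` empty.
#'
#' @param path file path.
#' @return `read_library()` returns a validated `guide_library`;
#'   `write_library()` invisibly returns `path`.
#' @export
read_library <- function(path) {
  df <- read_tsv_strict(path, cols = c("guide_id", "gene", "class",
                                       "spacer"))
  df$class <- normalize_class(df$class)
  df$gene[df$gene %in% c("", "NA")] <- NA_character_
  guide_library(df)
}

#' @param library a `guide_library`.
#' @rdname read_library
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "guide_library"))
  out <- as.data.frame(library)
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

normalize_class <- function(x) {
  key <- gsub("[^a-z]", "", tolower(x))
  map <- c(targeting = "targeting", gene = "targeting",
           nontargeting = "non_targeting", nt = "non_targeting",
           control = "non_targeting",
           intergenic = "intergenic")
  out <- unname(map[key])
  bad <- which(is.na(out))
  if (length(bad) > 0) {
    is_abort(sprintf("unknown guide class '%s' at line %d", x[bad[1]],
                     bad[1]), "isletscreen_data_error")
  }
  out
}

#' Read and write guide count TSVs
#'
#' Count matrices are tab-delimited with a `guide_id` first column and one
#' column per sample; `#` comment lines are ignored. Reading requires a
#' sample sheet and enforces an exact match between sheet and table
#' samples; cells must be non-negative integers.
#'
#' @param path count TSV path.
#' @param sample_sheet data frame with `sample_id`, `condition`,
#'   `mouse_id` (e.g. from [read_sample_sheet()]).
#' @return `read_counts()` returns a `guide_count_table`; `write_counts()`
#'   invisibly returns `path`.
#' @export
read_counts <- function(path, sample_sheet) {
  df <- read_tsv_strict(path, first_col = "guide_id")
  counts <- as.matrix(df[-1])
  if (!is.numeric(counts)) {
    is_abort("count columns must be numeric", "isletscreen_data_error")
  }
  rownames(counts) <- df$guide_id
  guide_count_table(counts, sample_sheet)
}

#' @param table a `guide_count_table`.
#' @rdname read_counts
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "guide_count_table"))
  out <- data.frame(guide_id = rownames(table$counts),
                    table$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read and write sample sheets
#'
#' Tab-delimited, columns `sample_id`, `condition` (`control`/`hPi`),
#' `mouse_id`, and optionally `fastq` with per-sample read paths.
#'
#' @param path file path.
#' @return `read_sample_sheet()` returns a validated data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_strict(path, cols = c("sample_id", "condition",
                                       "mouse_id"))
  if (anyDuplicated(df$sample_id)) {
    is_abort("duplicate sample_id in sample sheet",
             "isletscreen_data_error")
  }
  bad <- setdiff(unique(df$condition), CONDITIONS)
  if (length(bad) > 0) {
    is_abort(paste0("unknown condition(s) in sample sheet: ",
                    paste(bad, collapse = ", ")),
             "isletscreen_data_error")
  }
  df
}

#' @param sheet a sample-sheet data frame.
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_tsv(as.data.frame(sheet), path)
  invisible(path)
}

#' Read and write ground-truth effect tables
#'
#' Two tab-delimited columns: `gene`, `theta`.
#' @param path file path.
#' @return `read_effects()` returns a `true_effects` vector.
#' @export
read_effects <- function(path) {
  df <- read_tsv_strict(path, cols = c("gene", "theta"))
  true_effects(df$gene, as.numeric(df$theta))
}

#' @param effects a `true_effects` vector.
#' @rdname read_effects
#' @export
write_effects <- function(effects, path) {
  readr::write_tsv(data.frame(gene = names(effects),
                              theta = as.numeric(effects)), path)
  invisible(path)
}

# Shared strict TSV reader: UTF-8, tab-delimited, '#' comments, all
# columns read as character unless coerced downstream; validates header.
read_tsv_strict <- function(path, cols = NULL, first_col = NULL) {
  if (!file.exists(path)) {
    is_abort(paste0("file not found: ", path), "isletscreen_config_error")
  }
  df <- suppressWarnings(
    readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE,
                    col_types = if (!is.null(cols))
                      readr::cols(.default = readr::col_character()))
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    is_abort(sprintf("malformed TSV %s (first problem at row %d: %s)",
                     path, probs$row[1], probs$expected[1]),
             "isletscreen_data_error")
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!is.null(cols) && !all(cols %in% names(df))) {
    is_abort(paste0(path, " is missing column(s): ",
                    paste(setdiff(cols, names(df)), collapse = ", ")),
             "isletscreen_data_error")
  }
  if (!is.null(first_col) && names(df)[1] != first_col) {
    is_abort(sprintf("%s: first column must be '%s'", path, first_col),
             "isletscreen_data_error")
  }
  df
}
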