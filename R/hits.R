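#' Hit sets and thresholded filters
#'
#' A hit set is a named set of gene symbols. Symbols are compared
#' case-sensitively after whitespace stripping; alias resolution is an
#' external concern.
#'
#' @param name set label.
#' @param genes character vector; duplicates collapse.
#' @return A `hit_set`.
#' @export
hit_set <- function(name, genes) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- unique(trimws(as.character(genes)))
  genes <- genes[nzchar(genes) & !is.na(genes)]
  structure(list(name = name, genes = genes), class = "hit_set")
}

#' @export
print.hit_set <- function(x, ...) {
  cat(sprintf("hit_set '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Significantly upregulated genes from a DE table
#'
#' Applies the strict thresholds used for cross-assay intersection:
#' `log2fc > lfc_min` AND `padj < padj_max` (defaults 1 and 0.05; both
#' inequalities strict, so boundary rows are excluded).
#'
#' @param table data frame with columns `gene`, `log2fc`, `padj`.
#' @param lfc_min log2 fold-change threshold (default 1).
#' @param padj_max adjusted-p threshold (default 0.05).
#' @param name label for the resulting set.
#' @return A `hit_set`.
#' @export
filter_de_up <- function(table, lfc_min = 1, padj_max = 0.05,
                         name = "DE_up") {
  required <- c("gene", "log2fc", "padj")
  if (!all(required %in% names(table))) {
    is_abort(paste0("DE table is missing column(s): ",
                    paste(setdiff(required, names(table)), collapse = ", ")),
             "isletscreen_data_error")
  }
  if (!is.finite(lfc_min) || !is.finite(padj_max)) {
    is_abort("thresholds must be finite", "isletscreen_config_error")
  }
  keep <- !is.na(table$log2fc) & !is.na(table$padj) &
    table$log2fc > lfc_min & table$padj < padj_max
  hit_set(name, table$gene[keep])
}

#' Screen genes positively enriched under immune attack
#'
#' Genes whose integrated screen statistic exceeds `lfc_min` (strict),
#' i.e. knockouts enriched in hPi mice. An optional q-value cutoff can be
#' layered on; it is off by default because the intersection rule is
#' defined by fold change alone.
#'
#' @param ranked_results ranked gene results (from [rank_genes()] or
#'   [analyze_screen()]).
#' @param lfc_min threshold on the gene statistic (default 1).
#' @param q_max optional q-value cutoff (requires a `q` column).
#' @param name label for the resulting set.
#' @return A `hit_set`.
#' @export
filter_screen_enriched <- function(ranked_results, lfc_min = 1,
                                   q_max = NULL, name = "screen_enriched") {
  if (!all(c("gene", "log2fc") %in% names(ranked_results))) {
    is_abort("ranked results need 'gene' and 'log2fc' columns",
             "isletscreen_data_error")
  }
  keep <- ranked_results$log2fc > lfc_min
  if (!is.null(q_max)) {
    if (!"q" %in% names(ranked_results)) {
      is_abort("q_max given but results have no 'q' column",
               "isletscreen_data_error")
    }
    keep <- keep & ranked_results$q < q_max
  }
  hit_set(name, ranked_results$gene[keep])
}

#' Exact Venn-region accounting over hit sets
#'
#' Partitions the union of 2-4 hit sets into all `2^k - 1` membership
#' regions, with the exact gene list of each region. Region counts always
#' sum to the size of the union.
#'
#' @param sets list of `hit_set`s with distinct names.
#' @return A `venn_result`: data frame with one row per region — `region`
#'   (e.g. `"A&B&!C"`), one logical membership column per set, `count`,
#'   and `genes` (comma-joined).
#' @export
venn <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 4 ||
      !all(vapply(sets, inherits, logical(1), "hit_set"))) {
    is_abort("venn needs a list of 2-4 hit_sets",
             "isletscreen_config_error")
  }
  set_names <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(set_names)) {
    is_abort("duplicate set names", "isletscreen_config_error")
  }
  universe <- sort(unique(unlist(lapply(sets, `[[`, "genes"))))
  membership <- vapply(sets, function(s) universe %in% s$genes,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  if (length(universe) == 0) {
    membership <- matrix(logical(0), nrow = 0, ncol = length(sets))
  }
  colnames(membership) <- set_names

  k <- length(sets)
  patterns <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), k)))[-(2^k), ,
                                                                   drop = FALSE]
  colnames(patterns) <- set_names
  rows <- lapply(seq_len(nrow(patterns)), function(i) {
    pat <- patterns[i, ]
    in_region <- if (length(universe) == 0) logical(0) else
      apply(membership, 1, function(m) all(m == pat))
    genes <- universe[in_region]
    label <- paste(ifelse(pat, set_names, paste0("!", set_names)),
                   collapse = "&")
    cbind(data.frame(region = label, stringsAsFactors = FALSE),
          as.data.frame(t(pat)),
          data.frame(count = length(genes),
                     genes = paste(genes, collapse = ","),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("venn_result", "data.frame")
  out
}

#' Merge per-cell-type DE hit sets into one circle
#'
#' Cross-assay comparisons pool the SC-alpha and SC-beta DE tables of one
#' assay into a single set; whether that pooling is a union or an
#' intersection is a reporting choice, so both are offered (union
#' default: a gene upregulated in either endocrine population counts).
#'
#' @param sets list of `hit_set`s to merge.
#' @param mode `"union"` or `"intersect"`.
#' @param name label of the merged set.
#' @return A `hit_set`.
#' @export
merge_hit_sets <- function(sets, mode = c("union", "intersect"), name) {
  mode <- match.arg(mode)
  stopifnot(all(vapply(sets, inherits, logical(1), "hit_set")))
  gene_lists <- lapply(sets, `[[`, "genes")
  genes <- if (mode == "union") {
    Reduce(union, gene_lists)
  } else {
    Reduce(intersect, gene_lists)
  }
  hit_set(name, genes)
}

#' Write a Venn result as TSV + JSON summary
#'
#' @param result a `venn_result`.
#' @param tsv_path,json_path output paths (either may be `NULL`).
#' @return Invisibly, the result.
#' @export
write_venn <- function(result, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "venn_result"))
  if (!is.null(tsv_path)) {
    readr::write_tsv(as.data.frame(result), tsv_path)
  }
  if (!is.null(json_path)) {
    regions <- lapply(seq_len(nrow(result)), function(i) {
      list(region = result$region[i], count = result$count[i],
           genes = if (nzchar(result$genes[i]))
             strsplit(result$genes[i], ",")[[1]] else character(0))
    })
    jsonlite::write_json(regions, json_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(result)
}

#' Read a DE table (gene, log2fc, padj) from TSV
#' @param path file path.
#' @return Data frame with validated columns.
#' @export
read_de_table <- function(path) {
  df <- read_tsv_strict(path, cols = c("gene", "log2fc", "padj"))
  df$log2fc <- as.numeric(df$log2fc)
  df$padj <- as.numeric(df$padj)
  if (anyDuplicated(df$gene)) {
    is_abort(paste0("duplicate genes in DE table ", path),
             "isletscreen_data_error")
  }
  if (any(df$padj < 0 | df$padj > 1, na.rm = TRUE)) {
    is_abort("padj must lie in [0, 1]", "isletscreen_data_error")
  }
  df
}
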