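#' Gene-level integrated log2 fold change
#'
#' The screen's core statistic: guide counts of a gene (typically four
#' guides) are summed across all mice of a condition, expressed relative
#' to the summed non-targeting (NT) guide counts of the same condition,
#' and the two condition ratios are contrasted:
#'
#' \deqn{L_g = \log_2\frac{(\sum_{hPi} c_g + pc)/(\sum_{hPi} c_{NT} + pc)}
#'                        {(\sum_{ctrl} c_g + pc)/(\sum_{ctrl} c_{NT} + pc)}}
#'
#' Positive values mean the knockout's cells are enriched under immune
#' attack (protective KO); negative values mean depletion (sensitizing
#' KO). Anchoring on NT counts cancels global rejection and depth; a
#' pseudocount (default 1) on each of the four sums keeps the statistic
#' finite under rejection-driven zeros.
#'
#' @param table a `guide_count_table` with both conditions present.
#' @param library a `guide_library`.
#' @param gene gene symbol to evaluate.
#' @param pseudocount added to each of the four sums (default 1).
#' @param nt_guide_ids optional explicit NT anchor set; defaults to all
#'   non-targeting guides in the library.
#' @return The scalar statistic `L_g`.
#' @export
gene_log2fc <- function(table, library, gene, pseudocount = 1,
                        nt_guide_ids = NULL) {
  stopifnot(inherits(table, "guide_count_table"),
            inherits(library, "guide_library"))
  guide_ids <- library$guide_id[!is.na(library$gene) &
                                  library$gene == gene]
  guide_ids <- intersect(guide_ids, rownames(table$counts))
  if (length(guide_ids) == 0) {
    is_abort(paste0("gene has no guides in the table: ", gene),
             "isletscreen_data_error")
  }
  if (is.null(nt_guide_ids)) {
    nt_guide_ids <- control_guides(library, "non_targeting")
  }
  nt_guide_ids <- intersect(nt_guide_ids, rownames(table$counts))
  if (length(nt_guide_ids) == 0) {
    is_abort("no non-targeting guides available as anchor",
             "isletscreen_data_error")
  }
  set_ratio_l2fc(table, guide_ids, nt_guide_ids, pseudocount)
}

# Shared kernel: L for an arbitrary guide set against an NT anchor set.
set_ratio_l2fc <- function(table, guide_ids, nt_guide_ids, pseudocount) {
  hpi <- condition_samples(table, "hPi")
  ctrl <- condition_samples(table, "control")
  if (length(hpi) == 0 || length(ctrl) == 0) {
    is_abort("both conditions need >= 1 sample", "isletscreen_data_error")
  }
  cg <- table$counts[guide_ids, , drop = FALSE]
  cn <- table$counts[nt_guide_ids, , drop = FALSE]
  g_hpi <- sum(cg[, hpi]) + pseudocount
  g_ctrl <- sum(cg[, ctrl]) + pseudocount
  n_hpi <- sum(cn[, hpi]) + pseudocount
  n_ctrl <- sum(cn[, ctrl]) + pseudocount
  log2(g_hpi / n_hpi) - log2(g_ctrl / n_ctrl)
}

#' Gene statistics for every gene at once
#'
#' Vectorized [gene_log2fc()] over all genes of the library (or a subset),
#' with the same NT anchoring and pseudocount. Guides with zero counts in
#' every sample are dropped first (with a message listing them); genes
#' keep an `n_guides` column so three-guide genes are computed, not
#' rejected.
#'
#' @inheritParams gene_log2fc
#' @param genes optional character vector restricting the genes evaluated.
#' @param method `"sum"` (default) integrates a gene's guides by summing
#'   their raw counts before forming ratios; `"median_guide"` is a robust
#'   sensitivity alternative taking the median of per-guide log2 fold
#'   changes.
#' @return Data frame with columns `gene`, `n_guides`, `log2fc`.
#' @export
gene_log2fc_all <- function(table, library, pseudocount = 1, genes = NULL,
                            method = c("sum", "median_guide")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "guide_count_table"),
            inherits(library, "guide_library"))
  counts <- table$counts
  dead <- rownames(counts)[rowSums(counts) == 0]
  if (length(dead) > 0) {
    message("dropping ", length(dead), " guide(s) with zero counts in ",
            "every sample: ",
            paste(utils::head(dead, 10), collapse = ", "),
            if (length(dead) > 10) ", ...")
    counts <- counts[!rownames(counts) %in% dead, , drop = FALSE]
  }
  nt_ids <- intersect(control_guides(library, "non_targeting"),
                      rownames(counts))
  if (length(nt_ids) == 0) {
    is_abort("no non-targeting guides with counts; cannot anchor",
             "isletscreen_data_error")
  }
  hpi <- condition_samples(table, "hPi")
  ctrl <- condition_samples(table, "control")
  if (length(hpi) == 0 || length(ctrl) == 0) {
    is_abort("both conditions need >= 1 sample", "isletscreen_data_error")
  }

  keep <- !is.na(library$gene) & library$guide_id %in% rownames(counts)
  lib_t <- library[keep, , drop = FALSE]
  if (!is.null(genes)) {
    lib_t <- lib_t[lib_t$gene %in% genes, , drop = FALSE]
  }
  if (nrow(lib_t) == 0) {
    is_abort("no targeting guides to evaluate", "isletscreen_data_error")
  }
  per_guide_hpi <- rowSums(counts[lib_t$guide_id, hpi, drop = FALSE])
  per_guide_ctrl <- rowSums(counts[lib_t$guide_id, ctrl, drop = FALSE])
  g_hpi <- rowsum(per_guide_hpi, lib_t$gene)
  g_ctrl <- rowsum(per_guide_ctrl, lib_t$gene)
  n_guides <- rowsum(rep(1L, nrow(lib_t)), lib_t$gene)
  n_hpi <- sum(counts[nt_ids, hpi]) + pseudocount
  n_ctrl <- sum(counts[nt_ids, ctrl]) + pseudocount
  if (method == "sum") {
    l2fc <- log2((g_hpi[, 1] + pseudocount) / n_hpi) -
      log2((g_ctrl[, 1] + pseudocount) / n_ctrl)
  } else {
    per_guide_l <- log2((per_guide_hpi + pseudocount) / n_hpi) -
      log2((per_guide_ctrl + pseudocount) / n_ctrl)
    l2fc <- vapply(split(per_guide_l, lib_t$gene), stats::median,
                   numeric(1))[rownames(g_hpi)]
  }
  data.frame(gene = rownames(g_hpi),
             n_guides = as.integer(n_guides[, 1]),
             log2fc = unname(l2fc),
             stringsAsFactors = FALSE)
}

#' Empirical null from control-guide pseudo-genes
#'
#' The screen's FDR is anchored on the only model-free null available in
#' this design: non-targeting guides. Each draw samples `set_size` NT
#' guides without replacement, treats them as a pseudo-gene, and computes
#' the gene statistic against the remaining NT guides as anchor. The
#' resulting statistic distribution captures guide-level sampling noise,
#' engraftment bottlenecks and sequencing dispersion under no selection.
#'
#' @inheritParams gene_log2fc
#' @param set_size guides per pseudo-gene (match the library's
#'   guides-per-gene, default 4).
#' @param n_draws number of pseudo-genes (>= 100).
#' @param seed integer seed.
#' @return A `null_distribution`: list with `stats`, `set_size`,
#'   `n_draws`, `seed`.
#' @export
build_empirical_null <- function(table, library, set_size = 4,
                                 n_draws = 1000, seed = 1,
                                 pseudocount = 1) {
  stopifnot(inherits(table, "guide_count_table"),
            inherits(library, "guide_library"))
  if (n_draws < 100) {
    is_abort("n_draws must be >= 100", "isletscreen_config_error")
  }
  nt_ids <- intersect(control_guides(library, "non_targeting"),
                      rownames(table$counts))
  if (length(nt_ids) <= set_size) {
    is_abort(sprintf(
      "need more than set_size (%d) non-targeting guides (have %d): the anchor remainder would be empty",
      set_size, length(nt_ids)), "isletscreen_data_error")
  }
  hpi <- condition_samples(table, "hPi")
  ctrl <- condition_samples(table, "control")
  nt_hpi <- rowSums(table$counts[nt_ids, hpi, drop = FALSE])
  nt_ctrl <- rowSums(table$counts[nt_ids, ctrl, drop = FALSE])
  tot_hpi <- sum(nt_hpi)
  tot_ctrl <- sum(nt_ctrl)
  stats_vec <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_draws), function(i) {
      pick <- sample.int(length(nt_ids), set_size)
      g_hpi <- sum(nt_hpi[pick]) + pseudocount
      g_ctrl <- sum(nt_ctrl[pick]) + pseudocount
      # anchor = remaining NT guides
      a_hpi <- tot_hpi - sum(nt_hpi[pick]) + pseudocount
      a_ctrl <- tot_ctrl - sum(nt_ctrl[pick]) + pseudocount
      log2(g_hpi / a_hpi) - log2(g_ctrl / a_ctrl)
    }, numeric(1))
  })
  structure(list(stats = stats_vec, set_size = as.integer(set_size),
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "null_distribution")
}

#' Empirical two-sided p-value against the null
#'
#' Two-sided around the null median `m`, with the add-one (permutation)
#' correction: `p = (#{|null_i - m| >= |L - m|} + 1) / (n_draws + 1)`.
#' Vectorized over `L`.
#'
#' @param l2fc gene statistic(s) `L_g`.
#' @param null a `null_distribution`.
#' @param one_sided optional `"greater"`/`"less"` tail instead of the
#'   two-sided default.
#' @return p-value(s) in (0, 1].
#' @export
gene_pvalue <- function(l2fc, null, one_sided = NULL) {
  stopifnot(inherits(null, "null_distribution"))
  ns <- null$stats
  if (length(ns) == 0) {
    is_abort("empty null distribution", "isletscreen_data_error")
  }
  m <- stats::median(ns)
  n <- length(ns)
  if (is.null(one_sided)) {
    dev <- abs(ns - m)
    vapply(l2fc, function(l) (sum(dev >= abs(l - m)) + 1) / (n + 1),
           numeric(1))
  } else {
    one_sided <- match.arg(one_sided, c("greater", "less"))
    if (one_sided == "greater") {
      vapply(l2fc, function(l) (sum(ns >= l) + 1) / (n + 1), numeric(1))
    } else {
      vapply(l2fc, function(l) (sum(ns <= l) + 1) / (n + 1), numeric(1))
    }
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement, order-preserving.
#' Input p-values must lie in (0, 1].
#'
#' @param pvalues numeric vector of p-values.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    is_abort("p-values must lie in (0, 1]", "isletscreen_data_error")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Rank genes by their survival statistic
#'
#' Descending sort by `log2fc` (most protective first), ties broken
#' lexicographically by gene symbol. When an expressed-gene list is given
#' (the screen evaluates only genes expressed in the grafted cells —
#' roughly 12,000 in the published analysis), genes outside it are
#' excluded before ranking.
#'
#' @param results data frame with at least `gene` and `log2fc` columns.
#' @param expressed_genes optional character vector of evaluable genes.
#' @return The filtered results, sorted, with a `rank` column added.
#' @export
rank_genes <- function(results, expressed_genes = NULL) {
  if (!all(c("gene", "log2fc") %in% names(results))) {
    is_abort("results need 'gene' and 'log2fc' columns",
             "isletscreen_data_error")
  }
  if (!is.null(expressed_genes)) {
    results <- results[results$gene %in% expressed_genes, , drop = FALSE]
  }
  if (nrow(results) == 0) {
    is_abort("no genes to rank", "isletscreen_data_error")
  }
  ord <- order(-results$log2fc, results$gene)
  results <- results[ord, , drop = FALSE]
  results$rank <- seq_len(nrow(results))
  rownames(results) <- NULL
  results
}

#' Full gene-level inference for a screen
#'
#' Convenience wrapper running the whole Fig-1G-style analysis: per-gene
#' integrated log2 fold changes, an NT pseudo-gene empirical null,
#' empirical p-values, BH q-values, and ranking (optionally restricted to
#' an expressed-gene list).
#'
#' @inheritParams gene_log2fc_all
#' @inheritParams build_empirical_null
#' @param expressed_genes optional expressed-gene filter applied before
#'   ranking.
#' @param one_sided optional tail passed to [gene_pvalue()].
#' @return List with `results` (ranked data frame: gene, n_guides,
#'   log2fc, p, q, rank) and `null` (the `null_distribution`).
#' @export
analyze_screen <- function(table, library, pseudocount = 1, set_size = 4,
                           n_draws = 1000, seed = 1,
                           expressed_genes = NULL, one_sided = NULL) {
  res <- gene_log2fc_all(table, library, pseudocount = pseudocount,
                         genes = expressed_genes)
  null <- build_empirical_null(table, library, set_size = set_size,
                               n_draws = n_draws, seed = seed,
                               pseudocount = pseudocount)
  res$p <- gene_pvalue(res$log2fc, null, one_sided = one_sided)
  res$q <- bh_adjust(res$p)
  res <- rank_genes(res)
  list(results = res, null = null)
}
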