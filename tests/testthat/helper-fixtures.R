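# Shared fixtures and independent brute-force oracles.

# A tiny hand-written library: 2 genes x 2 guides, 3 NT, 1 intergenic.
tiny_library <- function() {
  guide_library(data.frame(
    guide_id = c("A_g1", "A_g2", "B_g1", "B_g2",
                 "NT_1", "NT_2", "NT_3", "IG_1"),
    gene = c("A", "A", "B", "B", NA, NA, NA, NA),
    class = c(rep("targeting", 4), rep("non_targeting", 3), "intergenic"),
    spacer = c("ACGTACGTACGTACGTACGT", "TTTTACGTACGTACGTACGT",
               "CCCCACGTACGTACGTACGT", "GGGGACGTACGTACGTACGT",
               "AAAAAAAAAACCCCCCCCCC", "TTTTTTTTTTGGGGGGGGGG",
               "ACACACACACACACACACAC", "GTGTGTGTGTGTGTGTGTGT"),
    stringsAsFactors = FALSE
  ))
}

# Count table over the tiny library; counts supplied as a guide x sample
# matrix (2 control + 2 hPi samples by default).
tiny_table <- function(counts = NULL, n_ctrl = 2, n_hpi = 2) {
  lib <- tiny_library()
  n <- nrow(lib)
  ids <- c(sprintf("control_m%02d", seq_len(n_ctrl)),
           sprintf("hPi_m%02d", seq_len(n_hpi)))
  if (is.null(counts)) {
    counts <- matrix(10L, nrow = n, ncol = n_ctrl + n_hpi)
  }
  rownames(counts) <- lib$guide_id
  colnames(counts) <- ids
  guide_count_table(counts, data.frame(
    sample_id = ids,
    condition = rep(c("control", "hPi"), c(n_ctrl, n_hpi)),
    mouse_id = ids, stringsAsFactors = FALSE))
}

# Brute-force oracle for the gene statistic: scalar loops, no shared code
# with the implementation.
brute_gene_l2fc <- function(table, library, gene, pc = 1,
                            nt_ids = NULL) {
  if (is.null(nt_ids)) {
    nt_ids <- library$guide_id[library$class == "non_targeting"]
  }
  g_ids <- library$guide_id[!is.na(library$gene) & library$gene == gene]
  sums <- c(g_hpi = 0, g_ctrl = 0, n_hpi = 0, n_ctrl = 0)
  for (s in seq_len(ncol(table$counts))) {
    cond <- table$samples$condition[s]
    for (g in rownames(table$counts)) {
      v <- table$counts[g, s]
      if (g %in% g_ids) {
        sums[if (cond == "hPi") "g_hpi" else "g_ctrl"] <-
          sums[if (cond == "hPi") "g_hpi" else "g_ctrl"] + v
      }
      if (g %in% nt_ids) {
        sums[if (cond == "hPi") "n_hpi" else "n_ctrl"] <-
          sums[if (cond == "hPi") "n_hpi" else "n_ctrl"] + v
      }
    }
  }
  unname(log2((sums["g_hpi"] + pc) / (sums["n_hpi"] + pc)) -
           log2((sums["g_ctrl"] + pc) / (sums["n_ctrl"] + pc)))
}

# Hand-written BH step-up, independent of stats::p.adjust.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  q[ord] <- p[ord] * m / seq_len(m)
  # enforce monotone non-decreasing in p-order from the top down
  for (i in rev(seq_len(m - 1))) {
    q[ord[i]] <- min(q[ord[i]], q[ord[i + 1]])
  }
  pmin(q, 1)
}

# Exhaustive per-gene membership scan for Venn regions.
brute_venn_counts <- function(sets) {
  universe <- unique(unlist(lapply(sets, `[[`, "genes")))
  k <- length(sets)
  out <- list()
  for (gene in universe) {
    pat <- paste(vapply(sets, function(s) gene %in% s$genes, logical(1)),
                 collapse = "")
    out[[pat]] <- c(out[[pat]], gene)
  }
  out
}

# Rank-sum AUROC oracle.
brute_auroc <- function(score, truth) {
  rk <- rank(score)
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  (sum(rk[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# A scaled null-screen config at the study's replication structure.
null_study_config <- function(seed, ...) {
  scaled_config(n_genes = 1000, n_nt = 100, n_intergenic = 0,
                n_mice_per_condition = 6, rejection_survival = 0.5,
                seed = seed, ...)
}

write_fastq <- function(path, reads, ids = NULL) {
  ids <- ids %||% sprintf("r%d", seq_along(reads))
  lines <- unlist(Map(function(id, seq) {
    c(paste0("@", id), seq, "+", strrep("I", nchar(seq)))
  }, ids, reads))
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
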