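test_that("gene statistic reproduces hand-computed ratios", {
  # gene A sums 40 (hPi) / 80 (ctrl); NT sums 400 (hPi) / 800 (ctrl)
  counts <- matrix(0L, nrow = 8, ncol = 4)
  counts[1:2, ] <- c(20L, 20L, 10L, 10L)  # A_g1, A_g2: ctrl 40, hPi 20 each
  counts[1:2, 3:4] <- 10L
  counts[1:2, 1:2] <- 20L
  counts[5:7, 1:2] <- c(100L, 150L, 150L)
  counts[5:7, 3:4] <- c(50L, 75L, 75L)
  counts[3:4, ] <- 1L
  counts[8, ] <- 1L
  tab <- tiny_table(counts)
  lib <- tiny_library()
  # proportional change: L = 0 at pc = 0
  expect_equal(gene_log2fc(tab, lib, "A", pseudocount = 0), 0)

  # enrichment: quadruple gene counts in hPi
  counts2 <- counts
  counts2[1:2, 3:4] <- 40L  # hPi gene sum 160, ctrl 80; NT 400/800
  tab2 <- tiny_table(counts2)
  expect_equal(gene_log2fc(tab2, lib, "A", pseudocount = 0),
               log2((160 / 400) / (80 / 800)))
  expect_equal(gene_log2fc(tab2, lib, "A", pseudocount = 0), 2)

  # scale invariance at pc = 0
  tab3 <- tiny_table(counts2 * 2L)
  expect_equal(gene_log2fc(tab3, lib, "A", pseudocount = 0),
               gene_log2fc(tab2, lib, "A", pseudocount = 0))
})

test_that("gene statistic matches the brute-force oracle on random tables", {
  lib <- tiny_library()
  set.seed(77)
  for (i in 1:25) {
    counts <- matrix(rpois(8 * 4, 40), nrow = 8)
    storage.mode(counts) <- "integer"
    tab <- tiny_table(counts)
    for (gene in c("A", "B")) {
      expect_equal(gene_log2fc(tab, lib, gene),
                   brute_gene_l2fc(tab, lib, gene), tolerance = 1e-12)
    }
    all_res <- gene_log2fc_all(tab, lib)
    expect_equal(all_res$log2fc[all_res$gene == "A"],
                 brute_gene_l2fc(tab, lib, "A"), tolerance = 1e-12)
  }
})

test_that("vectorized and scalar gene statistics agree on a screen", {
  cfg <- scaled_config(n_genes = 40, n_nt = 25, n_mice_per_condition = 3,
                       seed = 13)
  ds <- simulate_screen(cfg)
  res <- gene_log2fc_all(ds$counts, ds$library)
  pick <- sample(res$gene, 5)
  for (g in pick) {
    expect_equal(res$log2fc[res$gene == g],
                 gene_log2fc(ds$counts, ds$library, g), tolerance = 1e-12)
  }
  # median_guide integration is a different, bounded-deviation summary
  res_med <- gene_log2fc_all(ds$counts, ds$library,
                             method = "median_guide")
  expect_equal(res_med$gene, res$gene)
  expect_gt(cor(res_med$log2fc, res$log2fc), 0.5)
})

test_that("all-zero guides are dropped with a message, genes retained", {
  counts <- matrix(20L, nrow = 8, ncol = 4)
  counts[2, ] <- 0L  # A_g2 dead in all samples
  tab <- tiny_table(counts)
  lib <- tiny_library()
  expect_message(res <- gene_log2fc_all(tab, lib), "A_g2")
  expect_equal(res$n_guides[res$gene == "A"], 1L)
  expect_equal(res$n_guides[res$gene == "B"], 2L)
})

test_that("empirical null is deterministic, centered, and validated", {
  cfg <- null_study_config(seed = 19)
  ds <- simulate_screen(cfg)
  n1 <- build_empirical_null(ds$counts, ds$library, set_size = 4,
                             n_draws = 300, seed = 5)
  n2 <- build_empirical_null(ds$counts, ds$library, set_size = 4,
                             n_draws = 300, seed = 5)
  expect_identical(n1$stats, n2$stats)
  expect_lt(abs(median(n1$stats)), 0.05)
  expect_error(build_empirical_null(ds$counts, ds$library, set_size = 100,
                                    n_draws = 300, seed = 1),
               "anchor remainder")
  expect_error(build_empirical_null(ds$counts, ds$library, set_size = 4,
                                    n_draws = 50, seed = 1), "n_draws")
})

test_that("NT pseudo-gene statistics are distributed like the null", {
  cfg <- null_study_config(seed = 23)
  ds <- simulate_screen(cfg)
  null <- build_empirical_null(ds$counts, ds$library, set_size = 4,
                               n_draws = 1000, seed = 2)
  # disjoint 4-guide NT subsets scored as pseudo-genes via the gene kernel
  nt <- control_guides(ds$library)
  set.seed(3)
  nt <- sample(nt)
  groups <- split(nt, ceiling(seq_along(nt) / 4))
  stats_disjoint <- vapply(groups, function(ids) {
    isletscreen:::set_ratio_l2fc(ds$counts, ids, setdiff(nt, ids), 1)
  }, numeric(1))
  ks <- suppressWarnings(ks.test(stats_disjoint, null$stats))
  expect_gt(ks$p.value, 0.001)
})

test_that("empirical p-values follow the add-one counting rule", {
  null <- structure(list(stats = c(-2, -1, 0, 1, 2), set_size = 4L,
                         n_draws = 5L, seed = 1L),
                    class = "null_distribution")
  # median 0; |L - 0| = 1.5 is beaten by |{-2, 2}| -> (2 + 1) / 6
  expect_equal(gene_pvalue(1.5, null), 0.5)
  expect_equal(gene_pvalue(0, null), 1)
  expect_equal(gene_pvalue(10, null), 1 / 6)
  # brute-force check on a random null
  set.seed(11)
  ns <- rnorm(201)
  nd <- structure(list(stats = ns, set_size = 4L, n_draws = 201L,
                       seed = 1L), class = "null_distribution")
  for (l in c(-1.3, 0.2, 2.5)) {
    m <- median(ns)
    expect_equal(gene_pvalue(l, nd),
                 (sum(abs(ns - m) >= abs(l - m)) + 1) / 202)
  }
  # one-sided tails
  expect_equal(gene_pvalue(1.5, null, one_sided = "greater"),
               (1 + 1) / 6)
  expect_equal(gene_pvalue(1.5, null, one_sided = "less"), (4 + 1) / 6)
})

test_that("BH adjustment matches a hand step-up implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.05, 7)), rep(0.05, 7))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(31)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("rank_genes orders, filters and breaks ties as documented", {
  res <- data.frame(gene = c("C", "A", "B"), log2fc = c(2, 0, -1))
  ranked <- rank_genes(res)
  expect_equal(ranked$gene, c("C", "A", "B"))
  expect_equal(ranked$rank, 1:3)
  # expressed filter promotes the next gene
  ranked2 <- rank_genes(res, expressed_genes = c("A", "B"))
  expect_equal(ranked2$gene[1], "A")
  expect_equal(ranked2$rank, 1:2)
  # ties lexicographic by gene
  tied <- rank_genes(data.frame(gene = c("Z", "M", "A"),
                                log2fc = c(1, 1, 1)))
  expect_equal(tied$gene, c("A", "M", "Z"))
  expect_error(rank_genes(data.frame(gene = character(0),
                                     log2fc = numeric(0))), "no genes")
})

test_that("protective and sensitizing effects carry the expected signs", {
  cfg <- null_study_config(seed = 37)
  genes <- sprintf("GENE%05d", 1:1000)
  eff <- true_effects(genes, c(rep(4, 25), rep(0.25, 25), rep(1, 950)))
  ds <- simulate_screen(cfg, effects = eff)
  res <- gene_log2fc_all(ds$counts, ds$library)
  prot <- res$log2fc[res$gene %in% genes[1:25]]
  sens <- res$log2fc[res$gene %in% genes[26:50]]
  expect_gt(mean(prot), 0)
  expect_lt(mean(sens), 0)
  # with r = 0.5, theta = 4 clips to certain survival: L ~ -log2(r) = 1
  expect_lt(abs(mean(prot) - 1), 0.3)
  expect_lt(abs(mean(sens) - log2(0.25)), 0.5)
})
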