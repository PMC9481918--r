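test_that("DE upregulation filter applies strict thresholds", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   log2fc = c(1.5, 0.9, 2.0, 1.0),
                   padj = c(0.01, 0.001, 0.06, 0.05))
  hs <- filter_de_up(de)
  expect_setequal(hs$genes, "a")           # b fails lfc, c fails padj,
  expect_equal(hs$name, "DE_up")           # d fails both (boundary strict)
  # idempotence: filtering a table already reduced to hits changes nothing
  de2 <- de[de$gene %in% hs$genes, ]
  expect_setequal(filter_de_up(de2)$genes, hs$genes)
  expect_error(filter_de_up(de[, 1:2]), "missing column")
})

test_that("screen enrichment filter is strict and monotone in lfc_min", {
  ranked <- data.frame(gene = c("w", "x", "y", "z"),
                       log2fc = c(2, 1.01, 1.0, -3),
                       q = c(0.01, 0.2, 0.01, 0.01))
  expect_setequal(filter_screen_enriched(ranked)$genes, c("w", "x"))
  expect_setequal(filter_screen_enriched(ranked, q_max = 0.05)$genes, "w")
  expect_length(filter_screen_enriched(ranked[0, ])$genes, 0)
  sizes <- vapply(c(2, 1, 0, -4), function(th) {
    length(filter_screen_enriched(ranked, lfc_min = th)$genes)
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("venn regions match the exhaustive membership oracle", {
  a <- hit_set("A", c("1", "2", "3"))
  b <- hit_set("B", c("2", "3", "4"))
  c_ <- hit_set("C", c("3", "4", "5"))
  v <- venn(list(a, b, c_))
  get <- function(pattern) {
    row <- v[v$A == pattern[1] & v$B == pattern[2] & v$C == pattern[3], ]
    strsplit(row$genes, ",")[[1]]
  }
  expect_setequal(get(c(TRUE, TRUE, TRUE)), "3")
  expect_setequal(get(c(TRUE, TRUE, FALSE)), "2")
  expect_setequal(get(c(TRUE, FALSE, FALSE)), "1")
  expect_setequal(get(c(FALSE, TRUE, TRUE)), "4")
  expect_setequal(get(c(FALSE, FALSE, TRUE)), "5")
  expect_equal(sum(v$count), 5)  # regions partition the union

  # identical sets: one full-overlap region
  v2 <- venn(list(a, hit_set("B", a$genes)))
  expect_equal(v2$count[v2$A & v2$B], 3)
  expect_true(all(v2$count[xor(v2$A, v2$B)] == 0))
  # disjoint sets: no shared regions
  v3 <- venn(list(a, hit_set("B", c("9", "10"))))
  expect_equal(v3$count[v3$A & v3$B], 0)
  expect_error(venn(list(a, a)), "duplicate set names")
  expect_error(venn(list(a)), "2-4")
})

test_that("region counts partition random unions (property)", {
  set.seed(17)
  for (i in 1:200) {
    k <- sample(2:4, 1)
    sets <- lapply(seq_len(k), function(j) {
      hit_set(LETTERS[j],
              sample(as.character(1:15), sample(0:10, 1)))
    })
    v <- venn(sets)
    expect_equal(nrow(v), 2^k - 1)
    expect_equal(sum(v$count),
                 length(unique(unlist(lapply(sets, `[[`, "genes")))))
    # cross-check each region against the brute membership scan
    oracle <- brute_venn_counts(sets)
    for (r in seq_len(nrow(v))) {
      pat <- paste(unlist(v[r, LETTERS[1:k]]), collapse = "")
      expected <- oracle[[pat]] %||% character(0)
      got <- if (nzchar(v$genes[r])) strsplit(v$genes[r], ",")[[1]]
      else character(0)
      expect_setequal(got, expected)
    }
  }
})

test_that("venn is permutation-invariant up to region relabeling", {
  a <- hit_set("A", c("1", "2", "3"))
  b <- hit_set("B", c("2", "4"))
  v1 <- venn(list(a, b))
  v2 <- venn(list(b, a))
  for (r in seq_len(nrow(v1))) {
    match_row <- v2[v2$A == v1$A[r] & v2$B == v1$B[r], ]
    expect_equal(match_row$count, v1$count[r])
  }
})

test_that("hit-set merging supports union and intersection", {
  a <- hit_set("alpha", c("STAT1", "B2M"))
  b <- hit_set("beta", c("B2M", "CXCL10"))
  expect_setequal(merge_hit_sets(list(a, b), "union", "both")$genes,
                  c("STAT1", "B2M", "CXCL10"))
  expect_setequal(merge_hit_sets(list(a, b), "intersect", "both")$genes,
                  "B2M")
})

test_that("hit sets strip whitespace and deduplicate", {
  hs <- hit_set("x", c(" STAT1", "STAT1 ", "B2M", "B2M"))
  expect_setequal(hs$genes, c("STAT1", "B2M"))
})
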