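test_that("transduce matches the Poisson infection model", {
  lib <- build_library(25, 4, 10, 0, seed = 1)
  n_cells <- 200000
  moi <- 0.3
  ab <- transduce(lib, n_cells, moi, seed = 2)
  expect_true(all(ab >= 0))
  # infected fraction ~ 1 - exp(-moi), binomial SE
  p_inf <- 1 - exp(-moi)
  se <- sqrt(p_inf * (1 - p_inf) / n_cells)
  expect_lt(abs(attr(ab, "n_infected") / n_cells - p_inf), 3 * se)
  # retained (single-integration) fraction ~ moi * exp(-moi)
  p1 <- moi * exp(-moi)
  se1 <- sqrt(p1 * (1 - p1) / n_cells)
  expect_lt(abs(sum(ab) / n_cells - p1), 3 * se1)
  # multi-integration fraction small at low moi and counted exactly
  expect_equal(attr(ab, "n_infected") - attr(ab, "n_multi"), sum(ab))
})

test_that("transduce spreads guides uniformly (chi-square GOF)", {
  lib <- build_library(25, 4, 0, 0, seed = 5)  # 100 guides
  ab <- transduce(lib, 1e6, 0.5, seed = 7)
  gof <- suppressWarnings(chisq.test(ab, p = rep(1 / length(ab),
                                                 length(ab))))
  expect_gt(gof$p.value, 0.001)
})

test_that("sample_graft is a multinomial bottleneck", {
  ab <- c(g1 = 1000L, g2 = 1000L, g3 = 1000L, g4 = 1000L)
  founders <- sample_graft(ab, 4000, seed = 1)
  expect_equal(sum(founders), 4000)
  # symmetry: each guide close to 1000 (4 sigma of multinomial)
  sd_f <- sqrt(4000 * 0.25 * 0.75)
  expect_true(all(abs(founders - 1000) < 4 * sd_f))
  # zero-abundance guide never drawn
  ab0 <- c(ab, g5 = 0L)
  f0 <- sample_graft(ab0, 2000, seed = 3)
  expect_equal(unname(f0["g5"]), 0L)
  expect_error(sample_graft(c(a = 0L), 10, seed = 1), "zero")
})

test_that("sample_graft founder variance matches multinomial moments", {
  ab <- stats::setNames(rep(100L, 50), paste0("g", 1:50))
  n_b <- 2000
  p <- 1 / 50
  draws <- vapply(1:1000, function(i) {
    sample_graft(ab, n_b, seed = i)[1]
  }, numeric(1))
  expected_var <- n_b * p * (1 - p)
  # chi-square bounds on a sample variance over 1000 draws (~9% at 3 sigma)
  expect_lt(abs(var(draws) / expected_var - 1), 0.15)
  expect_lt(abs(mean(draws) - n_b * p), 3 * sqrt(expected_var / 1000))
})

test_that("apply_selection thins hPi grafts and spares controls", {
  lib <- tiny_library()
  founders <- stats::setNames(rep(10000L, nrow(lib)), lib$guide_id)
  eff <- true_effects(c("A", "B"), c(4, 0.5))

  same <- apply_selection(founders, lib, eff, 0.5, "control", seed = 1)
  expect_identical(same, founders)

  surv <- apply_selection(founders, lib, eff, 0.5, "hPi", seed = 1)
  expect_true(all(surv <= founders))  # conservation
  # theta=4, r=0.5 clips to survival 1: no depletion possible beyond none
  sd_bin <- sqrt(10000 * 0.5 * 0.5)
  expect_true(all(surv[c("A_g1", "A_g2")] == 10000L))
  # NT guides thinned at r
  expect_lt(abs(surv[["NT_1"]] - 5000), 4 * sd_bin)
  # theta=0.5 -> survival 0.25
  expect_lt(abs(surv[["B_g1"]] - 2500), 4 * sqrt(10000 * 0.25 * 0.75))
})

test_that("increasing theta never decreases expected survival", {
  lib <- tiny_library()
  founders <- stats::setNames(rep(5000L, nrow(lib)), lib$guide_id)
  means <- vapply(c(0.25, 0.5, 1, 2, 4), function(th) {
    surv <- vapply(1:30, function(i) {
      eff <- true_effects(c("A", "B"), c(th, 1))
      sum(apply_selection(founders, lib, eff, 0.5, "hPi",
                          seed = 1000 + i)[c("A_g1", "A_g2")])
    }, numeric(1))
    mean(surv)
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("sequence_counts has negative binomial moments", {
  ab <- c(g1 = 100)
  # single nonzero guide takes the whole depth
  one <- sequence_counts(c(g1 = 50, g2 = 0), depth = 5000, dispersion = 0,
                         seed = 1)
  expect_equal(unname(one["g2"]), 0L)
  expect_lt(abs(one[["g1"]] - 5000), 4 * sqrt(5000))

  # alpha = 0.1: empirical variance ~ mu + alpha mu^2 over 1e4 draws
  mu <- 200
  ab_many <- stats::setNames(rep(1, 10000), paste0("g", 1:10000))
  counts <- sequence_counts(ab_many, depth = mu * 10000, dispersion = 0.1,
                            seed = 2)
  expect_lt(abs(mean(counts) / mu - 1), 0.05)
  expect_lt(abs(var(counts) / (mu + 0.1 * mu^2) - 1), 0.15)

  # alpha = 0 equals Poisson in distribution
  pois <- sequence_counts(ab_many, depth = mu * 10000, dispersion = 0,
                          seed = 3)
  ks <- suppressWarnings(ks.test(pois, rpois(10000, mu)))
  expect_gt(ks$p.value, 0.001)
  expect_error(sequence_counts(c(a = 0), 100, 0, seed = 1), "all-zero")
})

test_that("simulate_screen is reproducible and labels samples correctly", {
  cfg <- scaled_config(n_genes = 30, n_nt = 20, n_mice_per_condition = 3,
                       seed = 17)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$library, b$library)
  expect_equal(sum(a$counts$samples$condition == "control"), 3)
  expect_equal(sum(a$counts$samples$condition == "hPi"), 3)
  expect_equal(nrow(a$counts$counts), nrow(a$library))
})

test_that("adding mice extends, never reshuffles, earlier mice", {
  cfg3 <- scaled_config(n_genes = 30, n_nt = 20,
                        n_mice_per_condition = 3, seed = 21)
  cfg4 <- scaled_config(n_genes = 30, n_nt = 20,
                        n_mice_per_condition = 4, seed = 21)
  a <- simulate_screen(cfg3)$counts$counts
  b <- simulate_screen(cfg4)$counts$counts
  expect_identical(a, b[, colnames(a)])
})

test_that("a null configuration with no rejection is centered at zero", {
  cfg <- scaled_config(n_genes = 500, n_nt = 100,
                       rejection_survival = 1, seed = 31)
  ds <- simulate_screen(cfg)
  res <- gene_log2fc_all(ds$counts, ds$library)
  expect_lt(abs(median(res$log2fc)), 0.05)
  # null centering: mean within 3 SE of 0
  expect_lt(abs(mean(res$log2fc)),
            3 * sd(res$log2fc) / sqrt(nrow(res)))
})

test_that("global rejection depresses raw NT counts in hPi samples", {
  cfg <- null_study_config(seed = 41)
  ds <- simulate_screen(cfg)
  nt <- control_guides(ds$library, "non_targeting")
  nt_means <- colMeans(ds$counts$counts[nt, ])
  hpi <- condition_samples(ds$counts, "hPi")
  ctrl <- condition_samples(ds$counts, "control")
  expect_lt(mean(nt_means[hpi]), mean(nt_means[ctrl]))
  # equal-depth mode removes the absolute depression
  cfg_eq <- null_study_config(seed = 41, equal_depth = TRUE)
  ds_eq <- simulate_screen(cfg_eq)
  nt_means_eq <- colMeans(ds_eq$counts$counts[nt, ])
  expect_lt(abs(mean(nt_means_eq[hpi]) / mean(nt_means_eq[ctrl]) - 1),
            0.05)
})

test_that("sim_config validates its ranges", {
  expect_error(sim_config(moi = 0), "moi")
  expect_error(sim_config(rejection_survival = 0), "rejection_survival")
  expect_error(sim_config(rejection_survival = 1.5), "rejection_survival")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(simulate_screen(sim_config(n_genes = 5, n_nt = 2,
                                          n_intergenic = 0, n_cells = 1000,
                                          bottleneck = 100, depth = 1000,
                                          seed = 1),
                               effects = true_effects("NOPE", 2)),
               "absent from the library")
})
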