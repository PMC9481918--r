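#' Simulation configuration for a pooled in vivo screen
#'
#' Bundles the knobs of the generative model: library shape, transduction,
#' per-mouse engraftment bottleneck, condition-dependent selection, and
#' sequencing. Defaults reproduce the published screen design where it is
#' stated — a Brunello-scale pool (19,114 genes at four guides per gene,
#' 941 non-targeting + 59 intergenic controls), transduction at MOI < 1,
#' and six mice per condition — and use round placeholder values for the
#' quantities the design leaves open (founder cells per graft, sequencing
#' depth).
#'
#' @param n_genes targeted genes in the pool.
#' @param guides_per_gene targeting guides per gene.
#' @param n_nt non-targeting control guides.
#' @param n_intergenic intergenic control guides.
#' @param n_cells cells exposed to the lentiviral pool.
#' @param moi mean integrations per cell (Poisson rate); must be positive,
#'   and kept below 1 in practice so most transduced cells carry one guide.
#' @param bottleneck founder cells engrafting per mouse.
#' @param n_mice_per_condition mice per condition arm.
#' @param rejection_survival fraction `r` in (0, 1] of graft cells surviving
#'   immune attack in hPi mice, applied to every cell on top of per-gene
#'   effects.
#' @param depth expected total reads per sample at full graft survival; the
#'   realized per-sample depth scales with the surviving cell fraction
#'   unless `equal_depth` is set, so global rejection lowers absolute
#'   counts in hPi samples.
#' @param dispersion negative binomial dispersion `alpha` >= 0 of the
#'   sequencing step (0 degenerates to Poisson).
#' @param equal_depth if `TRUE`, sequence every sample at `depth` reads
#'   regardless of graft survival (pure-composition simulations).
#' @param seed master seed; all stage seeds are derived from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 19114, guides_per_gene = 4, n_nt = 941,
                       n_intergenic = 59, n_cells = 2e7, moi = 0.5,
                       bottleneck = 5e5, n_mice_per_condition = 6,
                       rejection_survival = 0.5, depth = 1e7,
                       dispersion = 0.1, equal_depth = FALSE, seed = 1) {
  cfg <- list(n_genes = n_genes, guides_per_gene = guides_per_gene,
              n_nt = n_nt, n_intergenic = n_intergenic, n_cells = n_cells,
              moi = moi, bottleneck = bottleneck,
              n_mice_per_condition = n_mice_per_condition,
              rejection_survival = rejection_survival, depth = depth,
              dispersion = dispersion, equal_depth = isTRUE(equal_depth),
              seed = seed)
  counts <- c("n_genes", "guides_per_gene", "n_nt", "n_cells", "bottleneck",
              "n_mice_per_condition")
  for (nm in counts) {
    if (!is_count1(cfg[[nm]])) {
      is_abort(sprintf("%s must be a positive integer (got %s)", nm,
                       format(cfg[[nm]])), "isletscreen_config_error")
    }
  }
  if (!is.numeric(n_intergenic) || n_intergenic < 0) {
    is_abort("n_intergenic must be >= 0", "isletscreen_config_error")
  }
  if (!is.numeric(moi) || moi <= 0) {
    is_abort("moi must be > 0", "isletscreen_config_error")
  }
  if (!is.numeric(rejection_survival) || rejection_survival <= 0 ||
      rejection_survival > 1) {
    is_abort("rejection_survival must be in (0, 1]",
             "isletscreen_config_error")
  }
  if (!is.numeric(depth) || depth <= 0) {
    is_abort("depth must be > 0", "isletscreen_config_error")
  }
  if (!is.numeric(dispersion) || dispersion < 0) {
    is_abort("dispersion must be >= 0", "isletscreen_config_error")
  }
  if (!is.numeric(seed) || length(seed) != 1 || seed != floor(seed)) {
    is_abort("seed must be an integer", "isletscreen_config_error")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Desk-scale study configuration
#'
#' The full pool is unnecessarily heavy for calibration and recovery
#' studies; this keeps the screen's statistical structure (four guides per
#' gene, six mice per condition, MOI 0.5, 50% global rejection survival)
#' while scaling the pool to `n_genes` genes and holding per-guide coverage
#' at realistic screen levels: ~150 transduced cells, ~12 founder cells per
#' mouse, and ~500 reads per guide.
#'
#' @param n_genes targeted genes (default 1000).
#' @param n_nt non-targeting controls (default 100).
#' @param n_intergenic intergenic controls (default 0).
#' @param ... overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
scaled_config <- function(n_genes = 1000, n_nt = 100, n_intergenic = 0,
                          ...) {
  n_guides <- n_genes * 4 + n_nt + n_intergenic
  defaults <- list(
    n_genes = n_genes, n_nt = n_nt, n_intergenic = n_intergenic,
    n_cells = ceiling(n_guides * 150 / stats::dpois(1, 0.5)),
    bottleneck = n_guides * 12,
    depth = n_guides * 500
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

#' Per-gene survival effects
#'
#' Ground truth for simulation: a survival multiplier `theta` per gene.
#' `theta = 1` is neutral, `theta > 1` a protective knockout (its cells
#' survive immune attack better), `theta < 1` sensitizing. Control guides
#' implicitly carry `theta = 1`. The realized per-cell survival probability
#' in hPi mice is `min(1, rejection_survival * theta)`.
#'
#' @param genes character vector of gene names.
#' @param theta positive multipliers, recycled if length 1.
#' @return A named numeric vector classed `true_effects`.
#' @export
true_effects <- function(genes, theta = 1) {
  if (length(theta) == 1) theta <- rep(theta, length(genes))
  stopifnot(length(theta) == length(genes))
  if (any(!is.finite(theta)) || any(theta <= 0)) {
    is_abort("theta must be finite and > 0", "isletscreen_config_error")
  }
  structure(stats::setNames(as.numeric(theta), genes),
            class = "true_effects")
}

#' Transduce the cell pool with the lentiviral guide library
#'
#' Integrations per cell are Poisson(`moi`). Cells with no integration are
#' not selected; cells with two or more are discarded to honour the
#' screen's single-perturbation assumption (the screen itself enforces this
#' by infecting at MOI < 1). Each retained cell carries one guide drawn
#' uniformly from the pool.
#'
#' @param library a `guide_library`.
#' @param n_cells cells exposed to the pool.
#' @param moi mean integrations per cell.
#' @param seed integer seed.
#' @return Integer vector of cells per guide (named by guide id), summing
#'   to the retained cell count, with attributes `n_infected` (cells with
#'   >= 1 integration) and `n_multi` (discarded multi-integration cells).
#' @export
transduce <- function(library, n_cells, moi, seed) {
  stopifnot(inherits(library, "guide_library"))
  if (!is.numeric(moi) || moi <= 0) {
    is_abort("moi must be > 0", "isletscreen_config_error")
  }
  if (!is_count1(n_cells)) {
    is_abort("n_cells must be a positive integer",
             "isletscreen_config_error")
  }
  n_guides <- nrow(library)
  withr::with_seed(as.integer(seed), {
    integrations <- stats::rpois(n_cells, moi)
    n_infected <- sum(integrations >= 1L)
    n_single <- sum(integrations == 1L)
    n_multi <- n_infected - n_single
    abundance <- as.integer(stats::rmultinom(1, n_single,
                                             rep(1 / n_guides, n_guides)))
    names(abundance) <- library$guide_id
    attr(abundance, "n_infected") <- n_infected
    attr(abundance, "n_multi") <- n_multi
    abundance
  })
}

#' Engraftment bottleneck: sample one mouse's founder cells
#'
#' Each graft represents a random subsample of the transduced pool — the
#' dominant noise source of in vivo screens. Founders are a multinomial
#' draw of size `bottleneck` with probabilities proportional to pool
#' abundance (sampling with replacement; the pool is much larger than any
#' graft).
#'
#' @param abundance named non-negative integer vector, cells per guide.
#' @param bottleneck founder cells for this mouse.
#' @param seed integer seed (one independent draw per mouse).
#' @return Named integer founder vector summing to `bottleneck`.
#' @export
sample_graft <- function(abundance, bottleneck, seed) {
  if (sum(abundance) <= 0) {
    is_abort("total abundance is zero; nothing to engraft",
             "isletscreen_data_error")
  }
  if (!is_count1(bottleneck)) {
    is_abort("bottleneck must be a positive integer",
             "isletscreen_config_error")
  }
  withr::with_seed(as.integer(seed), {
    founders <- as.integer(stats::rmultinom(1, bottleneck,
                                            abundance / sum(abundance)))
    names(founders) <- names(abundance)
    founders
  })
}

#' Apply condition-dependent selection to a graft
#'
#' Control mice receive no immune challenge and return their founders
#' unchanged. In hPi mice every cell survives independently with
#' probability `min(1, rejection_survival * theta_g)` — a global rejection
#' thinning modulated by the knockout's survival effect (`theta = 1` for
#' control guides and genes without an assigned effect). Selection acts
#' once: grafted islet cells are post-mitotic, so there is no growth phase
#' to amplify the signal.
#'
#' @param founders named integer founder vector (names = guide ids).
#' @param library the `guide_library` mapping guides to genes.
#' @param effects a `true_effects` vector (may omit neutral genes).
#' @param rejection_survival global survival fraction `r` in (0, 1].
#' @param condition `"control"` or `"hPi"`.
#' @param seed integer seed.
#' @return Named integer vector of surviving cells per guide.
#' @export
apply_selection <- function(founders, library, effects, rejection_survival,
                            condition, seed) {
  condition <- match.arg(condition, CONDITIONS)
  if (condition == "control") {
    return(founders)
  }
  stopifnot(inherits(library, "guide_library"))
  theta <- rep(1, nrow(library))
  names(theta) <- library$guide_id
  has_gene <- !is.na(library$gene) & library$gene %in% names(effects)
  theta[has_gene] <- unclass(effects)[library$gene[has_gene]]
  theta <- theta[names(founders)]
  p_survive <- pmin(1, rejection_survival * theta)
  if (any(p_survive < 0)) {
    is_abort("negative survival probability", "isletscreen_config_error")
  }
  withr::with_seed(as.integer(seed), {
    survivors <- stats::rbinom(length(founders), founders, p_survive)
    names(survivors) <- names(founders)
    survivors
  })
}

#' Sequence a graft: overdispersed read counts per guide
#'
#' Reads per guide follow a negative binomial with mean proportional to the
#' guide's share of surviving cells, `mu_i = depth * a_i / sum(a)`, and
#' dispersion `alpha` (variance `mu + alpha * mu^2`); `alpha = 0`
#' degenerates to Poisson.
#'
#' @param abundance named non-negative vector of surviving cells per guide.
#' @param depth expected total reads for this sample.
#' @param dispersion NB dispersion `alpha` >= 0.
#' @param seed integer seed.
#' @return Named integer read-count vector.
#' @export
sequence_counts <- function(abundance, depth, dispersion, seed) {
  if (sum(abundance) <= 0) {
    is_abort("all-zero abundance; nothing to sequence",
             "isletscreen_data_error")
  }
  if (!is.numeric(depth) || depth <= 0) {
    is_abort("depth must be > 0", "isletscreen_config_error")
  }
  if (!is.numeric(dispersion) || dispersion < 0) {
    is_abort("dispersion must be >= 0", "isletscreen_config_error")
  }
  mu <- depth * abundance / sum(abundance)
  withr::with_seed(as.integer(seed), {
    counts <- if (dispersion == 0) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    stats::setNames(as.integer(counts), names(abundance))
  })
}

#' Simulate a full pooled in vivo screen
#'
#' Composes the generative stages: one transduction of the pool, then for
#' every mouse an engraftment bottleneck, condition-dependent selection,
#' and sequencing. Per-sample depth scales with the surviving cell
#' fraction (so global rejection depresses absolute hPi counts) unless the
#' config sets `equal_depth`. Fully reproducible from the master seed; each
#' mouse runs under its own derived substream, so enlarging a cohort never
#' reshuffles existing animals.
#'
#' @param config a `sim_config`.
#' @param effects optional `true_effects`; defaults to all-neutral.
#' @param library optional pre-built `guide_library` matching the config;
#'   built from the config (and its seed) when omitted.
#' @return A `screen_dataset`: list with `counts` (a `guide_count_table`),
#'   `effects`, `library`, and `config`.
#' @examples
#' cfg <- scaled_config(n_genes = 20, n_nt = 10, n_mice_per_condition = 2,
#'                      seed = 7)
#' ds <- simulate_screen(cfg)
#' ds$counts
#' @export
simulate_screen <- function(config, effects = NULL, library = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(library)) {
    library <- build_library(config$n_genes, config$guides_per_gene,
                             config$n_nt, config$n_intergenic,
                             seed = sub_seed(config$seed, 1))
  }
  stopifnot(inherits(library, "guide_library"))
  genes <- unique(stats::na.omit(library$gene))
  if (is.null(effects)) {
    effects <- true_effects(genes, 1)
  }
  unknown <- setdiff(names(effects), genes)
  if (length(unknown) > 0) {
    is_abort(paste0("effects name genes absent from the library: ",
                    paste(utils::head(unknown, 5), collapse = ", ")),
             "isletscreen_config_error")
  }

  pool <- transduce(library, config$n_cells, config$moi,
                    seed = sub_seed(config$seed, 2))

  n_mice <- config$n_mice_per_condition
  sample_ids <- character(0)
  cols <- list()
  sheet <- list()
  for (condition in CONDITIONS) {
    for (m in seq_len(n_mice)) {
      stage <- mouse_stage(condition, m)
      mouse_seed <- sub_seed(config$seed, stage)
      founders <- sample_graft(pool, config$bottleneck, seed = mouse_seed)
      survivors <- apply_selection(founders, library, effects,
                                   config$rejection_survival, condition,
                                   seed = sub_seed(mouse_seed, 1))
      depth_s <- if (config$equal_depth) {
        config$depth
      } else {
        config$depth * sum(survivors) / config$bottleneck
      }
      reads <- sequence_counts(survivors, depth_s, config$dispersion,
                               seed = sub_seed(mouse_seed, 2))
      sid <- sprintf("%s_m%02d", condition, m)
      sample_ids <- c(sample_ids, sid)
      cols[[sid]] <- reads
      sheet[[sid]] <- data.frame(sample_id = sid, condition = condition,
                                 mouse_id = sprintf("mouse_%s_%02d",
                                                    condition, m),
                                 stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- library$guide_id
  table <- guide_count_table(counts, do.call(rbind, sheet))
  structure(list(counts = table, effects = effects, library = library,
                 config = config),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat("screen_dataset\n")
  print(x$counts)
  n_nonneutral <- sum(unclass(x$effects) != 1)
  cat(sprintf("  true effects: %d genes, %d non-neutral; r = %g\n",
              length(x$effects), n_nonneutral,
              x$config$rejection_survival))
  invisible(x)
}
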