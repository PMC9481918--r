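#' Read a run configuration
#'
#' A single YAML file drives a whole run. Top-level keys: `seed`, `outdir`,
#' and per-stage blocks `simulate` (fields of [sim_config()]), `analyze`
#' (`pseudocount`, `set_size`, `n_draws`, `expressed_genes` path,
#' `counts`, `library`, `sample_sheet` paths when analyzing external
#' data), and `intersect` (`de_tables` paths, `lfc_min`, `padj_max`,
#' `merge_mode`). Referenced files must exist; parameter ranges are
#' validated up front.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    is_abort(paste0("config not found: ", path),
             "isletscreen_config_error")
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed) || !is.numeric(cfg$seed)) {
    is_abort("config needs an integer 'seed'", "isletscreen_config_error")
  }
  if (is.null(cfg$outdir)) {
    is_abort("config needs an 'outdir'", "isletscreen_config_error")
  }
  for (key in c("expressed_genes", "counts", "library", "sample_sheet")) {
    p <- cfg$analyze[[key]]
    if (!is.null(p) && !file.exists(p)) {
      is_abort(sprintf("config references missing file %s = %s", key, p),
               "isletscreen_config_error")
    }
  }
  for (p in cfg$intersect$de_tables) {
    if (!file.exists(p)) {
      is_abort(paste0("config references missing DE table: ", p),
               "isletscreen_config_error")
    }
  }
  class(cfg) <- "run_config"
  cfg
}

write_manifest <- function(outdir, stage, params, inputs = list(),
                           outputs = list()) {
  manifest <- list(
    stage = stage,
    package = "isletscreen",
    version = as.character(utils::packageVersion("isletscreen")),
    parameters = params,
    inputs = inputs,
    outputs = outputs
  )
  path <- file.path(outdir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate a screen and write its files
#'
#' Wraps [simulate_screen()]: writes the library, counts, sample sheet,
#' ground-truth effects, a config snapshot, and a machine-readable
#' manifest under `outdir`. Rerunning with the same config reproduces the
#' files bit-exactly.
#'
#' @param config a `run_config` (uses its `simulate` block and `seed`), or
#'   a `sim_config` plus `outdir`.
#' @param effects optional `true_effects`.
#' @param outdir output directory (created if missing); defaults to the
#'   run config's `outdir`.
#' @return Invisibly, the `screen_dataset`.
#' @export
run_simulate <- function(config, effects = NULL, outdir = NULL) {
  if (inherits(config, "run_config")) {
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    scfg <- do.call(sim_config, sim_args)
    outdir <- outdir %||% config$outdir
  } else if (inherits(config, "sim_config")) {
    scfg <- config
    if (is.null(outdir)) {
      is_abort("outdir required when passing a sim_config directly",
               "isletscreen_config_error")
    }
  } else {
    is_abort("config must be a run_config or sim_config",
             "isletscreen_config_error")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ds <- simulate_screen(scfg, effects = effects)
  write_library(ds$library, file.path(outdir, "library.tsv"))
  write_counts(ds$counts, file.path(outdir, "counts.tsv"))
  write_sample_sheet(ds$counts$samples,
                     file.path(outdir, "sample_sheet.tsv"))
  write_effects(ds$effects, file.path(outdir, "effects.tsv"))
  yaml::write_yaml(unclass(ds$config),
                   file.path(outdir, "sim_config.yaml"))
  write_manifest(outdir, "simulate", unclass(ds$config),
                 outputs = list(counts = "counts.tsv",
                                library = "library.tsv",
                                sample_sheet = "sample_sheet.tsv",
                                effects = "effects.tsv"))
  invisible(ds)
}

#' Analyze a screen from files (or a dataset) and write ranked results
#'
#' Validates library/counts consistency, runs [analyze_screen()], fits
#' per-guide NB models for the top and bottom ranked genes' guides, and
#' writes `results.tsv`, `null.tsv`, `guide_fits.tsv` and a manifest.
#'
#' @param config a `run_config`; its `analyze` block may point at external
#'   `counts`/`library`/`sample_sheet` files, otherwise files written by
#'   [run_simulate()] in `outdir` are used.
#' @param outdir overrides the config's `outdir`.
#' @param n_fit_genes how many genes from each extreme of the ranking get
#'   per-guide NB fits (default 3).
#' @return Invisibly, the list from [analyze_screen()].
#' @export
run_analyze <- function(config, outdir = NULL, n_fit_genes = 3) {
  stopifnot(inherits(config, "run_config"))
  outdir <- outdir %||% config$outdir
  a <- config$analyze %||% list()
  lib_path <- a$library %||% file.path(outdir, "library.tsv")
  counts_path <- a$counts %||% file.path(outdir, "counts.tsv")
  sheet_path <- a$sample_sheet %||% file.path(outdir, "sample_sheet.tsv")
  library <- read_library(lib_path)
  sheet <- read_sample_sheet(sheet_path)
  table <- read_counts(counts_path, sheet)
  validate_counts_against_library(table, library)

  expressed <- NULL
  if (!is.null(a$expressed_genes)) {
    expressed <- trimws(readLines(a$expressed_genes, warn = FALSE))
    expressed <- expressed[nzchar(expressed)]
  }
  params <- list(pseudocount = a$pseudocount %||% 1,
                 set_size = a$set_size %||% 4,
                 n_draws = a$n_draws %||% 1000,
                 seed = config$seed)
  fit <- analyze_screen(table, library,
                        pseudocount = params$pseudocount,
                        set_size = params$set_size,
                        n_draws = params$n_draws,
                        seed = params$seed,
                        expressed_genes = expressed)

  sf <- control_size_factors(table, control_guides(library,
                                                   "non_targeting"))
  res <- fit$results
  extremes <- unique(c(utils::head(res$gene, n_fit_genes),
                       utils::tail(res$gene, n_fit_genes)))
  fit_ids <- library$guide_id[!is.na(library$gene) &
                                library$gene %in% extremes]
  fit_ids <- intersect(fit_ids, rownames(table$counts))
  guide_fits <- fit_guides_nb(table, sf, fit_ids)

  readr::write_tsv(res, file.path(outdir, "results.tsv"))
  readr::write_tsv(data.frame(stat = fit$null$stats),
                   file.path(outdir, "null.tsv"))
  readr::write_tsv(guide_fits, file.path(outdir, "guide_fits.tsv"))
  write_manifest(outdir, "analyze", params,
                 inputs = list(library = lib_path, counts = counts_path,
                               sample_sheet = sheet_path),
                 outputs = list(results = "results.tsv",
                                null = "null.tsv",
                                guide_fits = "guide_fits.tsv"))
  invisible(fit)
}

#' Intersect screen hits with DE gene sets
#'
#' Builds the screen-enriched hit set from ranked results, one upregulated
#' set per DE table (optionally merged by assay), and writes the exact
#' Venn-region report (TSV + JSON) plus a manifest.
#'
#' @param config a `run_config` whose `intersect` block lists
#'   `de_tables` (named paths); `lfc_min`, `padj_max`, `screen_lfc_min`
#'   optional.
#' @param outdir overrides the config's `outdir`.
#' @return Invisibly, the `venn_result`.
#' @export
run_intersect <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  outdir <- outdir %||% config$outdir
  i <- config$intersect %||% list()
  de_paths <- i$de_tables
  if (length(de_paths) < 1) {
    is_abort("intersect needs >= 1 DE table (plus the screen set)",
             "isletscreen_config_error")
  }
  res_path <- file.path(outdir, "results.tsv")
  if (!file.exists(res_path)) {
    is_abort("run_analyze results not found; run it first",
             "isletscreen_config_error")
  }
  ranked <- as.data.frame(readr::read_tsv(res_path,
                                          show_col_types = FALSE))
  screen_set <- filter_screen_enriched(ranked,
                                       lfc_min = i$screen_lfc_min %||% 1,
                                       name = "screen")
  de_names <- names(de_paths) %||% paste0("DE", seq_along(de_paths))
  de_sets <- Map(function(p, nm) {
    filter_de_up(read_de_table(p), lfc_min = i$lfc_min %||% 1,
                 padj_max = i$padj_max %||% 0.05, name = nm)
  }, de_paths, de_names)
  sets <- c(de_sets, list(screen_set))
  result <- venn(unname(sets))
  write_venn(result, file.path(outdir, "venn.tsv"),
             file.path(outdir, "venn.json"))
  write_manifest(outdir, "intersect",
                 list(lfc_min = i$lfc_min %||% 1,
                      padj_max = i$padj_max %||% 0.05,
                      screen_lfc_min = i$screen_lfc_min %||% 1),
                 inputs = c(list(results = res_path), as.list(de_paths)),
                 outputs = list(venn = "venn.tsv",
                                venn_json = "venn.json"))
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
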