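#' Per-guide negative binomial condition fit
#'
#' The per-guide "full model" behind replicate-level boxplots: a negative
#' binomial regression of a guide's counts on condition with log link and
#' offset `log(f_s)` (control-anchored size factors), exposing fitted
#' counts per sample. For a single two-level factor the mean structure's
#' point estimates coincide with the Poisson GLM solution (offset-weighted
#' group means), so coefficients come from a Poisson fit and the NB
#' dispersion is then estimated by method of moments on Pearson residuals,
#' floored at 1e-6. With six mice per arm a mean-dispersion trend fit
#' would be underdetermined, so no shrinkage across guides is attempted.
#'
#' @param table a `guide_count_table`.
#' @param size_factors named per-sample factors from
#'   [control_size_factors()].
#' @param guide_id guide to fit; needs counts in >= 2 samples per
#'   condition.
#' @return A `guide_model_fit`: list with `guide_id`, `beta0` (baseline
#'   log mean in control), `beta_cond` (natural-log condition effect;
#'   `log2fc = beta_cond / log(2)`), `alpha` (NB dispersion), `fitted`
#'   (predicted count per sample), and `converged`.
#' @export
fit_guide_nb <- function(table, size_factors, guide_id) {
  stopifnot(inherits(table, "guide_count_table"))
  if (!guide_id %in% rownames(table$counts)) {
    is_abort(paste0("unknown guide: ", guide_id), "isletscreen_data_error")
  }
  sf <- size_factors[table$samples$sample_id]
  if (any(is.na(sf)) || any(sf <= 0)) {
    is_abort("size factors must cover every sample and be positive",
             "isletscreen_data_error")
  }
  y <- table$counts[guide_id, ]
  condition <- factor(table$samples$condition, levels = CONDITIONS)
  if (any(table(condition) < 2)) {
    is_abort("guide fits need >= 2 samples per condition",
             "isletscreen_data_error")
  }
  fit <- tryCatch(
    stats::glm(y ~ condition, family = stats::poisson(),
               offset = log(sf)),
    error = function(e) NULL, warning = function(w) {
      suppressWarnings(stats::glm(y ~ condition,
                                  family = stats::poisson(),
                                  offset = log(sf)))
    })
  converged <- !is.null(fit) && isTRUE(fit$converged) &&
    all(is.finite(stats::coef(fit)))
  if (!converged) {
    return(structure(list(guide_id = guide_id, beta0 = NA_real_,
                          beta_cond = NA_real_, alpha = NA_real_,
                          fitted = rep(NA_real_, length(y)),
                          converged = FALSE),
                     class = "guide_model_fit"))
  }
  mu <- stats::fitted(fit)
  df_resid <- length(y) - 2L
  # moment estimator for Var = mu + alpha mu^2, floored
  alpha <- if (df_resid > 0) {
    sum((y - mu)^2 - mu) / sum(mu^2)
  } else {
    0
  }
  alpha <- max(alpha, 1e-6)
  structure(list(guide_id = guide_id,
                 beta0 = unname(stats::coef(fit)[1]),
                 beta_cond = unname(stats::coef(fit)[2]),
                 alpha = alpha,
                 fitted = stats::setNames(as.numeric(mu),
                                          table$samples$sample_id),
                 converged = TRUE),
            class = "guide_model_fit")
}

#' Fit every guide of a set and tabulate
#'
#' Runs [fit_guide_nb()] over a vector of guides and returns one row per
#' converged fit; non-converged guides are reported by id and excluded,
#' never silently imputed.
#'
#' @inheritParams fit_guide_nb
#' @param guide_ids guides to fit.
#' @return Data frame: guide_id, beta0, beta_cond, log2fc, alpha,
#'   converged.
#' @export
fit_guides_nb <- function(table, size_factors, guide_ids) {
  fits <- lapply(guide_ids, function(g) fit_guide_nb(table, size_factors, g))
  out <- data.frame(
    guide_id = guide_ids,
    beta0 = vapply(fits, `[[`, numeric(1), "beta0"),
    beta_cond = vapply(fits, `[[`, numeric(1), "beta_cond"),
    alpha = vapply(fits, `[[`, numeric(1), "alpha"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE
  )
  out$log2fc <- out$beta_cond / log(2)
  failed <- out$guide_id[!out$converged]
  if (length(failed) > 0) {
    message("excluding ", length(failed), " non-converged guide fit(s): ",
            paste(utils::head(failed, 10), collapse = ", "))
  }
  out[out$converged, c("guide_id", "beta0", "beta_cond", "log2fc",
                       "alpha", "converged")]
}
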