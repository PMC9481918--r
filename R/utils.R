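#' @keywords internal
"_PACKAGE"

GUIDE_CLASSES <- c("targeting", "non_targeting", "intergenic")
CONDITIONS <- c("control", "hPi")

#' Derive a stage seed from a master seed
#'
#' One master seed drives a whole simulated screen; each stochastic stage
#' (library build, transduction, each mouse) runs under its own derived
#' substream so that adding mice to a design extends, rather than
#' reshuffles, the stream of earlier mice. The rule is
#' `(master + 1000003 * stage) mod (2^31 - 1)`: deterministic, documented,
#' and collision-free for the handful of stage indices a screen uses.
#'
#' Stage indices: 1 = library, 2 = transduction, and mouse `m` of condition
#' `control`/`hPi` gets `100 + 2*m` / `101 + 2*m`, so the two cohorts
#' interleave and growing either cohort never renumbers existing animals.
#'
#' @param master integer master seed.
#' @param stage integer stage index (>= 1).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
sub_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(stage), length(stage) == 1L, stage >= 1)
  as.integer((as.double(master) + 1000003 * as.double(stage)) %% (2^31 - 1))
}

mouse_stage <- function(condition, mouse) {
  base <- if (condition == "control") 100L else 101L
  base + 2L * as.integer(mouse)
}

#' Stop with a classed condition
#'
#' All validation failures in the package signal conditions with class
#' `isletscreen_error` plus a specific subclass, so callers (and the
#' pipeline drivers) can distinguish config errors from data errors.
#' @noRd
is_abort <- function(msg, class) {
  stop(structure(class = c(class, "isletscreen_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_count1 <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

geometric_mean <- function(x) exp(mean(log(x)))
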