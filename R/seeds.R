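#' Derive a stage-specific child seed from a master seed
#'
#' All stochastic stages of the pipeline draw their own seed from one
#' master seed through this deterministic rule, so any single stage can be
#' reproduced in isolation. The rule is
#' \code{(seed + 10007 * stage_index) mod (2^31 - 1)} with a fixed table
#' of stage indices; it is intentionally simple and documented rather
#' than clever.
#'
#' @param seed integer master seed.
#' @param stage one of \code{"pancancer"}, \code{"survival"},
#'   \code{"treatment"}, \code{"dose"}, \code{"qpcr"}, \code{"perm"},
#'   \code{"boot"}, \code{"de"}.
#' @return an integer seed in \code{[0, 2^31 - 2]}.
#' @export
#' @examples
#' child_seed(1, "perm")
child_seed <- function(seed, stage) {
  stages <- c(pancancer = 1L, survival = 2L, treatment = 3L, dose = 4L,
              qpcr = 5L, perm = 6L, boot = 7L, de = 8L)
  stage <- match.arg(stage, names(stages))
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  (abs(seed) + 10007L * stages[[stage]]) %% 2147483647L
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
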