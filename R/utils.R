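#' @keywords internal
"_PACKAGE"

## Standard gravitational acceleration, m/s^2. Force math is SI; lengths at
## the user-facing interfaces are centimetres.
GRAVITY <- 9.80665

DIRECTIONS <- c("forward", "left", "right")
CUSHIONS <- c("air", "foam", "own")
START_POSITIONS <- c("backrest", "situp")
IMU_SENSORS <- c("sternum", "pelvis", "femur_l", "femur_r")

stop_if_not <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

match_direction <- function(direction) {
  match.arg(direction, DIRECTIONS)
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that callers' random streams are
#' untouched; every stochastic routine in the package funnels its randomness
#' through this helper, so a single seed fixes all simulator output.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  stop_if_not(is_number(seed), "seed must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## Derive a reproducible sub-seed stream: one base seed expands to n child
## seeds, each below 2^31, so per-trial simulation is order-independent.
child_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
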