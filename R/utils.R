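#' Corner labels used for target locations and directions
#'
#' The spatial Stroop target appears at one of the four internal corners of
#' the fixation square and points towards one of the same four corners.
#' Order is fixed and used everywhere rows/columns of count matrices are
#' interpreted.
#'
#' @return Character vector of the four corners.
#' @export
corners <- function() c("upper-left", "upper-right", "lower-right", "lower-left")

# response key associated with each direction (spatially compatible mapping)
.response_keys <- c("upper-left" = "E", "upper-right" = "O",
                    "lower-right" = "K", "lower-left" = "D")

#' Natural log-odds and its inverse
#'
#' @param p probability in (0,1).
#' @param x real number.
#' @return `logit()` returns log(p/(1-p)); `sigmoid()` returns 1/(1+exp(-x)).
#' @export
logit <- function(p) {
  stopifnot(all(p > 0 & p < 1))
  log(p / (1 - p))
}

#' @rdname logit
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive `n` distinct child seeds (< 2^31) from one master seed.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# standardize to mean 0, sd 1; optionally with fixed constants
standardize <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- mean(x)
  if (is.null(scale)) scale <- sd(x)
  if (!is.finite(scale) || scale <= 0)
    stop("cannot standardize a column with zero variance")
  (x - center) / scale
}
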