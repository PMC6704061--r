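#' @useDynLib hergsel, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor predict rnorm runif rbinom sd var
#' @importFrom utils head modifyList
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All package randomness flows through
# this so library calls never perturb user RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv())
    else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Derive a named sub-seed from a root seed
#'
#' All randomness in the package flows from one root seed through named
#' substreams (folds, GA, synthetic data, train/test split) so that modules
#' can be re-run independently with reproducible results.  The derived value
#' is always a valid 32-bit R integer seed.
#'
#' @param seed Integer root seed.
#' @param stream Character stream name, e.g. `"folds"`, `"ga"`.
#' @return An integer seed in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Half-up rounding to `digits` decimals, matching how the source tables were
# typeset (base round() is banker's rounding).
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) {
  stop(structure(class = c("hergsel_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
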