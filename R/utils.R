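#' @importFrom rlang abort warn %||%
#' @importFrom stats median quantile sd var setNames
NULL

# Deterministic sub-stream seeds: one master seed per pipeline run, one
# derived seed per operation, so e.g. adding replicates never perturbs the
# gene-level draws. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  s <- (abs(as.double(seed)) %% m)
  as.integer((s * 48271 + 11 * as.double(offset)) %% m)
}

# Evaluate `expr` under a local RNG state; restores the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  if (!is.null(seed)) set.seed(seed)
  force(expr)
}

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(as.double(x))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
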