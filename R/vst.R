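#' Two-component microarray error model
#'
#' The observed probe intensity is modelled as
#' \eqn{y = \alpha + u e^{\eta} + \epsilon}, with true signal \eqn{u},
#' background mean \eqn{\alpha}, multiplicative log-normal error
#' \eqn{\eta \sim N(0, \mathrm{sd}_\eta^2)} dominating at high intensity and
#' additive error \eqn{\epsilon \sim N(0, \mathrm{sd}_\epsilon^2)} dominating
#' near background. Its variance-stabilizing transformation (VST) is
#' \deqn{g(y) = \ln\left((y - \alpha) + \sqrt{(y - \alpha)^2 + c}\right),}
#' with \eqn{c = \mathrm{sd}_\epsilon / \mathrm{sd}(e^{\eta})}; on the
#' transformed scale the error spread is approximately constant across the
#' intensity range.
#'
#' @param alpha_bg Background mean (raw intensity units).
#' @param sd_eps Standard deviation of the additive error, > 0.
#' @param sd_eta Standard deviation of the multiplicative log error, > 0.
#' @return A `noise_model` object with fields `alpha_bg`, `sd_eps`, `sd_eta`
#'   and the derived VST constant `c`.
#' @examples
#' nm <- noise_model(alpha_bg = 50, sd_eps = 10, sd_eta = 0.25)
#' vst(nm$alpha_bg, nm) # == log(sqrt(c))
#' @export
noise_model <- function(alpha_bg, sd_eps, sd_eta) {
  check_scalar_number(alpha_bg, "alpha_bg")
  check_scalar_number(sd_eps, "sd_eps", positive = TRUE)
  check_scalar_number(sd_eta, "sd_eta", positive = TRUE)
  structure(
    list(
      alpha_bg = alpha_bg, sd_eps = sd_eps, sd_eta = sd_eta,
      c = sd_eps / sd_exp_normal(sd_eta)
    ),
    class = "noise_model"
  )
}

# sd of e^eta for eta ~ N(0, s^2), by the log-normal moments.
sd_exp_normal <- function(s) sqrt((exp(s^2) - 1) * exp(s^2))

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf(
    "Two-component error model: alpha_bg = %.4g, sd_eps = %.4g, sd_eta = %.4g, c = %.4g\n",
    x$alpha_bg, x$sd_eps, x$sd_eta, x$c
  ))
  invisible(x)
}

#' Variance-stabilizing transformation and its inverse
#'
#' `vst()` applies \eqn{g(y) = \ln((y-\alpha) + \sqrt{(y-\alpha)^2 + c})};
#' it is defined for every real \eqn{y - \alpha} because
#' \eqn{\sqrt{z^2+c} > |z|} when \eqn{c > 0}. `inverse_vst()` returns the
#' exact inverse on the background-subtracted scale,
#' \eqn{z = (e^{2g} - c) / (2 e^{g})}, so that
#' `inverse_vst(vst(y, model), model$c)` recovers `y - alpha_bg` to machine
#' precision.
#'
#' @param y Numeric vector of raw intensities.
#' @param model A [noise_model()] (or any list with `alpha_bg` and `c`).
#' @return `vst()`: the transformed values; `inverse_vst()`: the
#'   background-subtracted intensities \eqn{y - \alpha}.
#' @export
vst <- function(y, model) {
  check_scalar_number(model$c, "model$c", positive = TRUE)
  z <- y - model$alpha_bg
  s <- sqrt(z^2 + model$c)
  # z + s cancels catastrophically for z << 0; use the conjugate form there
  ifelse(z >= 0, log(z + s), log(model$c) - log(s - z))
}

#' @rdname vst
#' @param g Numeric vector on the transformed scale.
#' @param c Positive VST constant.
#' @export
inverse_vst <- function(g, c) {
  check_scalar_number(c, "c", positive = TRUE)
  eg <- exp(g)
  (eg^2 - c) / (2 * eg)
}

#' Estimate the two-component error model from paired raw/corrected data
#'
#' Given the raw probe intensities and a noise-corrected version of the same
#' table (background correction is upstream of this package; see
#' [percentile_shift_correct()] for a naive stand-in), the model parameters
#' are estimated from the distribution tails, ranking genes by their mean
#' corrected intensity:
#' * `sd_eps` — spread of the raw values of the bottom-1%-expressed genes,
#'   where the additive error dominates;
#' * `sd_eta` — spread of `log(corrected)` of the top-1% genes, where the
#'   multiplicative error dominates;
#' * `alpha_bg` — mean raw minus mean corrected intensity over the bottom-1%
#'   genes;
#' * `c` — `sd_eps / sd(e^eta)` via the log-normal moment relation.
#'
#' With two or more arrays the spreads are pooled within-gene (across
#' samples), so the tail's own between-gene signal spread does not inflate
#' the error estimates; with a single column the across-gene spread is used.
#'
#' @param raw,corrected Gene-by-sample numeric matrices (or `expr_tbl`s),
#'   aligned; at least 100 genes, well-populated tails.
#' @param tail_fraction Tail size used for both estimates (default 0.01).
#' @return A [noise_model()].
#' @export
estimate_noise_model <- function(raw, corrected, tail_fraction = 0.01) {
  raw <- if (inherits(raw, "expr_tbl")) expr_matrix(raw) else as.matrix(raw)
  corrected <- if (inherits(corrected, "expr_tbl")) expr_matrix(corrected) else as.matrix(corrected)
  if (!identical(dim(raw), dim(corrected))) {
    abort("`raw` and `corrected` must be aligned (same genes and samples).")
  }
  n <- nrow(raw)
  if (n < 100L) abort("at least 100 genes are required.")
  n_tail <- max(ceiling(tail_fraction * n), 1L)
  level <- rowMeans(corrected)
  ord <- order(level)
  bottom <- ord[seq_len(n_tail)]
  top <- ord[seq.int(n - n_tail + 1L, n)]
  if (length(bottom) < 2L || length(top) < 2L) {
    abort("fewer than 2 genes in a tail; cannot estimate the error model.")
  }
  top_corr <- corrected[top, , drop = FALSE]
  if (any(top_corr <= 0)) {
    abort("top-tail corrected intensities must be positive to take logs.")
  }
  sd_eps <- tail_spread(raw[bottom, , drop = FALSE])
  sd_eta <- tail_spread(log(top_corr))
  if (sd_eps == 0) abort("degenerate model: zero additive spread in the bottom tail.")
  if (sd_eta == 0) abort("degenerate model: zero multiplicative spread in the top tail.")
  alpha_bg <- mean(raw[bottom, , drop = FALSE]) - mean(corrected[bottom, , drop = FALSE])
  noise_model(alpha_bg, sd_eps, sd_eta)
}

# Pooled within-gene sd across samples; across-gene sd for a single column.
tail_spread <- function(block) {
  if (ncol(block) >= 2L) {
    ss <- rowSums((block - rowMeans(block))^2)
    sqrt(sum(ss) / (nrow(block) * (ncol(block) - 1L)))
  } else {
    stats::sd(block[, 1])
  }
}

#' Naive percentile-shift background correction
#'
#' Subtracts a low percentile of each array from its intensities (flooring at
#' zero plus `floor_at`). This is a deliberately simple stand-in used to
#' build fixtures for [estimate_noise_model()]; real analyses should feed a
#' properly background-corrected table from an upstream tool.
#'
#' @param raw Gene-by-sample numeric matrix.
#' @param probs Per-array percentile treated as background (default 0.005).
#' @param floor_at Lower floor applied after subtraction (default 1e-3,
#'   keeping the corrected table positive for log transforms).
#' @return Corrected matrix, same shape as `raw`.
#' @export
percentile_shift_correct <- function(raw, probs = 0.005, floor_at = 1e-3) {
  raw <- as.matrix(raw)
  bg <- apply(raw, 2L, stats::quantile, probs = probs)
  pmax(sweep(raw, 2L, bg, "-"), floor_at)
}
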