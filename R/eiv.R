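#' Paired replicate data for errors-in-variables regression
#'
#' Couples microarray (`x`) and RNA-Seq (`y`) measurements of the same genes
#' into the input for the functional errors-in-variables (Deming) model
#'
#' \deqn{Y_{ij} = \alpha + \beta \xi_i + \epsilon_{ij}, \qquad
#'       X_{ij} = \xi_i + \delta_{ij},}
#'
#' with independent errors \eqn{\delta_{ij} \sim N(0, \sigma_\delta^2)},
#' \eqn{\epsilon_{ij} \sim N(0, \lambda\sigma_\delta^2)} around the latent
#' per-gene level \eqn{\xi_i}. The error-variance ratio
#' \eqn{\lambda = \sigma_\epsilon^2/\sigma_\delta^2} is estimable because
#' both platforms measured replicate samples.
#'
#' @param x,y Gene-by-replicate numeric matrices (log2, unit-free), equal
#'   dimensions; rows are genes.
#' @param gene_ids Optional gene ids (defaults to `x` rownames, then
#'   `g1..gn`).
#' @return An `eiv_data` object.
#' @export
eiv_data <- function(x, y, gene_ids = NULL) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (!identical(dim(x), dim(y))) {
    abort("`x` and `y` must have identical dimensions (same genes, same replicate count).")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("values must be finite.")
  gene_ids <- gene_ids %||% rownames(x) %||% paste0("g", seq_len(nrow(x)))
  if (anyDuplicated(gene_ids)) abort("gene ids must be unique.")
  rownames(x) <- rownames(y) <- gene_ids
  structure(list(x = x, y = y, gene_ids = gene_ids), class = "eiv_data")
}

#' @export
print.eiv_data <- function(x, ...) {
  cat(sprintf(
    "EIV input: %d genes x %d replicates per platform\n",
    nrow(x$x), ncol(x$x)
  ))
  invisible(x)
}

# Per-gene sufficient statistics reused by the fit and the bootstrap.
eiv_gene_stats <- function(input) {
  m <- ncol(input$x)
  x_mean <- rowMeans(input$x)
  y_mean <- rowMeans(input$y)
  ss_x <- rowSums((input$x - x_mean)^2)
  ss_y <- rowSums((input$y - y_mean)^2)
  list(
    x_mean = x_mean, y_mean = y_mean, ss_x = ss_x, ss_y = ss_y,
    n_reps = m, df = m - 1L
  )
}

#' Variance trim and homoscedasticity check
#'
#' The errors-in-variables model assumes a common error variance across
#' genes. Genes are ranked by their pooled within-gene replicate variance
#' (both platforms combined) and the top `trim_fraction` are removed; the
#' remaining within-gene residuals of the two platforms are then compared
#' with the Brown–Forsythe variant of Levene's test (center = median). The
#' test is advisory — its p-value is reported, not enforced.
#'
#' @param input An [eiv_data()] object with at least 2 replicates.
#' @param trim_fraction Fraction of genes to remove (default 0.01, i.e. the
#'   top 1% most variable genes; `ceiling(trim_fraction * n)` genes are cut,
#'   ties broken by gene id).
#' @return The trimmed `eiv_data`, with a `"homoscedasticity"` attribute
#'   holding `trimmed_gene_ids`, `levene_statistic` and `levene_p`
#'   (retrieve with [homoscedasticity_report()]). When every residual is
#'   zero the test is vacuous and `levene_p` is 1 by convention.
#' @export
trim_and_check <- function(input, trim_fraction = 0.01) {
  stopifnot(inherits(input, "eiv_data"))
  if (ncol(input$x) < 2L) abort("at least 2 replicates are required to test error variances.")
  n <- nrow(input$x)
  if (n < 100L) {
    warn("fewer than 100 genes; the variance trim is hardly meaningful.")
  }
  st <- eiv_gene_stats(input)
  pooled_var <- (st$ss_x + st$ss_y) / (2 * st$df)
  ord <- order(-pooled_var, input$gene_ids)
  n_trim <- ceiling(trim_fraction * n)
  trimmed_ids <- input$gene_ids[sort(ord[seq_len(n_trim)])]
  keep <- setdiff(input$gene_ids, trimmed_ids)
  out <- eiv_data(input$x[keep, , drop = FALSE], input$y[keep, , drop = FALSE], keep)

  res_x <- as.vector(input$x[keep, , drop = FALSE] - rowMeans(input$x[keep, , drop = FALSE]))
  res_y <- as.vector(input$y[keep, , drop = FALSE] - rowMeans(input$y[keep, , drop = FALSE]))
  if (all(res_x == 0) && all(res_y == 0)) {
    stat <- NA_real_
    p <- 1
  } else {
    lev <- car::leveneTest(
      c(res_x, res_y),
      factor(rep(c("x", "y"), c(length(res_x), length(res_y)))),
      center = stats::median
    )
    stat <- lev$`F value`[1]
    p <- lev$`Pr(>F)`[1]
  }
  attr(out, "homoscedasticity") <- structure(
    list(
      trimmed_gene_ids = trimmed_ids,
      levene_statistic = stat,
      levene_p = p,
      trim_fraction = trim_fraction
    ),
    class = "homoscedasticity_report"
  )
  out
}

#' @rdname trim_and_check
#' @param x A trimmed `eiv_data`.
#' @export
homoscedasticity_report <- function(x) attr(x, "homoscedasticity")

#' @export
print.homoscedasticity_report <- function(x, ...) {
  cat(sprintf(
    "Trimmed %d genes (top %.1f%% pooled variance)\nLevene (Brown-Forsythe): F = %s, p = %s\n",
    length(x$trimmed_gene_ids), 100 * x$trim_fraction,
    format(x$levene_statistic, digits = 4), format(x$levene_p, digits = 4)
  ))
  invisible(x)
}

#' Estimate the error-variance ratio from replicates
#'
#' Pools within-gene replicate variances across genes on each platform:
#' \eqn{\hat\sigma_\delta^2} from the microarray side,
#' \eqn{\hat\sigma_\epsilon^2} from the RNA-Seq side, and
#' \eqn{\hat\lambda = \hat\sigma_\epsilon^2 / \hat\sigma_\delta^2}.
#' Genes whose replicates are identical contribute zero to the pooled sums
#' (they are not excluded).
#'
#' @inheritParams trim_and_check
#' @return One-row tibble with `lambda`, `sigma_delta2`, `sigma_eps2`.
#' @export
estimate_lambda <- function(input) {
  stopifnot(inherits(input, "eiv_data"))
  if (ncol(input$x) < 2L) abort("at least 2 replicates are required to estimate lambda.")
  st <- eiv_gene_stats(input)
  sigma_delta2 <- sum(st$ss_x) / (length(st$ss_x) * st$df)
  sigma_eps2 <- sum(st$ss_y) / (length(st$ss_y) * st$df)
  if (sigma_delta2 == 0) abort("degenerate input: pooled microarray replicate variance is zero.")
  tibble::tibble(
    lambda = sigma_eps2 / sigma_delta2,
    sigma_delta2 = sigma_delta2,
    sigma_eps2 = sigma_eps2
  )
}

# Maximum-likelihood Deming slope for known lambda, obtained numerically:
# after concentrating out alpha, the profile score in beta reduces to
# h(beta) = S_xy beta^2 + (lambda S_xx - S_yy) beta - lambda S_xy = 0,
# solved by bracketed root finding between the two limiting slopes
# (ordinary regression S_xy/S_xx and inverse regression S_yy/S_xy).
solve_eiv_slope <- function(s_xx, s_yy, s_xy, lambda) {
  if (s_xy == 0) abort("unidentifiable slope: covariance of the gene means is zero.")
  h <- function(b) s_xy * b^2 + (lambda * s_xx - s_yy) * b - lambda * s_xy
  b_ols <- s_xy / s_xx
  b_inv <- s_yy / s_xy
  lo <- min(b_ols, b_inv)
  hi <- max(b_ols, b_inv)
  pad <- 1e-8 * (1 + abs(lo) + abs(hi))
  lo <- lo - pad
  hi <- hi + pad
  # the ML slope lies between the two limits; widen defensively if rounding
  # pushed the sign change outside the bracket
  tries <- 0L
  while (h(lo) * h(hi) > 0 && tries < 60L) {
    span <- hi - lo
    lo <- lo - span
    hi <- hi + span
    tries <- tries + 1L
  }
  if (h(lo) == 0) return(lo)
  if (h(hi) == 0) return(hi)
  stats::uniroot(h, c(lo, hi), tol = 1e-12)$root
}

#' Fit the errors-in-variables regression for known lambda
#'
#' Maximum-likelihood fit of the functional errors-in-variables (Deming)
#' line through the per-gene replicate means, for a known error-variance
#' ratio `lambda`. The slope is obtained by numerically solving the profile
#' score equation; the intercept follows as
#' \eqn{\hat\alpha = \bar y - \hat\beta \bar x}. With balanced replicates the
#' mean-based fit coincides with the full replicate-level maximum likelihood.
#'
#' @param x_mean,y_mean Per-gene mean vectors (microarray, RNA-Seq); length
#'   at least 3.
#' @param lambda Positive error-variance ratio
#'   \eqn{\sigma_\epsilon^2/\sigma_\delta^2}.
#' @param sigma_delta2,sigma_eps2 Optional error-variance estimates to carry
#'   in the fit object (filled by [fit_eiv_replicates()]).
#' @return An `eiv_fit` object with components `alpha`, `beta`, `lambda`,
#'   `sigma_delta2`, `sigma_eps2`, `n_genes` and the fitted means; has
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' f <- fit_eiv(1:10, 3 + 2 * (1:10), lambda = 1)
#' tidy(f)
#' @export
fit_eiv <- function(x_mean, y_mean, lambda, sigma_delta2 = NA_real_,
                    sigma_eps2 = NA_real_) {
  if (length(x_mean) != length(y_mean)) abort("mean vectors must have equal length.")
  if (length(x_mean) < 3L) abort("at least 3 genes are required.")
  check_scalar_number(lambda, "lambda", positive = TRUE)
  xc <- x_mean - mean(x_mean)
  yc <- y_mean - mean(y_mean)
  s_xx <- sum(xc^2)
  s_yy <- sum(yc^2)
  s_xy <- sum(xc * yc)
  beta <- solve_eiv_slope(s_xx, s_yy, s_xy, lambda)
  alpha <- mean(y_mean) - beta * mean(x_mean)
  structure(
    list(
      alpha = alpha, beta = beta, lambda = lambda,
      sigma_delta2 = sigma_delta2, sigma_eps2 = sigma_eps2,
      n_genes = length(x_mean),
      x_mean = x_mean, y_mean = y_mean
    ),
    class = "eiv_fit"
  )
}

#' Fit the errors-in-variables model from replicate data
#'
#' Convenience pipeline: estimates `lambda` from the within-gene replicate
#' variances, averages replicates per gene, and fits the Deming line.
#'
#' @inheritParams trim_and_check
#' @return An `eiv_fit` (see [fit_eiv()]).
#' @export
fit_eiv_replicates <- function(input) {
  lam <- estimate_lambda(input)
  st <- eiv_gene_stats(input)
  fit_eiv(st$x_mean, st$y_mean, lam$lambda,
    sigma_delta2 = lam$sigma_delta2, sigma_eps2 = lam$sigma_eps2
  )
}

#' @export
print.eiv_fit <- function(x, ...) {
  cat(sprintf(
    "EIV (Deming) fit on %d genes\n  y = %.4f + %.4f x   (lambda = %.4g)\n",
    x$n_genes, x$alpha, x$beta, x$lambda
  ))
  invisible(x)
}

#' @rdname fit_eiv
#' @param x,object An `eiv_fit`.
#' @param ... Unused.
#' @method tidy eiv_fit
#' @export
tidy.eiv_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha, x$beta)
  )
}

#' @rdname fit_eiv
#' @method glance eiv_fit
#' @export
glance.eiv_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, sigma_delta2 = x$sigma_delta2,
    sigma_eps2 = x$sigma_eps2, n_genes = x$n_genes
  )
}

#' @rdname fit_eiv
#' @method autoplot eiv_fit
#' @export
autoplot.eiv_fit <- function(object, ...) {
  df <- tibble::tibble(x = object$x_mean, y = object$y_mean)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(colour = "grey55", alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed") +
    ggplot2::geom_abline(
      intercept = object$alpha, slope = object$beta,
      linewidth = 1
    ) +
    ggplot2::labs(
      x = "microarray (log2, unit-free)", y = "RNA-Seq (log2, unit-free)",
      subtitle = sprintf(
        "y = %.3f + %.3f x; dashed: y = x", object$alpha, object$beta
      )
    ) +
    ggplot2::theme_minimal()
}

#' Bootstrap confidence intervals and bias verdicts
#'
#' Resamples genes with replacement (paired rows kept together), re-estimates
#' `lambda` and refits the errors-in-variables line on each resample, and
#' forms percentile confidence intervals for the intercept and slope. A
#' confidence interval for \eqn{\alpha} that excludes 0 indicates a fixed
#' bias between the platforms; an interval for \eqn{\beta} that excludes 1
#' indicates a proportional bias. Degenerate resamples (zero covariance or
#' zero pooled replicate variance) are redrawn and counted; more than 10%
#' redraws triggers a warning.
#'
#' @inheritParams trim_and_check
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed for reproducibility.
#' @return An `eiv_bias` object: the full-data fit plus `alpha_ci`,
#'   `beta_ci`, `n_boot`, `level`, `fixed_bias_present`,
#'   `proportional_bias_present`, `n_redraws` and the bootstrap replicate
#'   tibble. Has a [tidy()] method.
#' @export
bootstrap_bias <- function(input, n_boot = 1000, level = 0.95, seed = NULL) {
  stopifnot(inherits(input, "eiv_data"))
  if (!is.numeric(n_boot) || length(n_boot) != 1L || n_boot < 1) {
    abort("`n_boot` must be a positive integer.")
  }
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  fit <- fit_eiv_replicates(input)
  st <- eiv_gene_stats(input)
  n <- length(st$x_mean)
  alpha_b <- beta_b <- numeric(n_boot)
  n_redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        sd2 <- sum(st$ss_x[idx])
        se2 <- sum(st$ss_y[idx])
        xm <- st$x_mean[idx]
        ym <- st$y_mean[idx]
        xc <- xm - mean(xm)
        yc <- ym - mean(ym)
        s_xy <- sum(xc * yc)
        if (sd2 > 0 && s_xy != 0) break
        n_redraws <- n_redraws + 1L
      }
      lam <- se2 / sd2
      beta_b[b] <- solve_eiv_slope(sum(xc^2), sum(yc^2), s_xy, lam)
      alpha_b[b] <- mean(ym) - beta_b[b] * mean(xm)
    }
  })
  if (n_redraws > 0.1 * n_boot) {
    warn(sprintf("%d degenerate resamples were redrawn (> 10%% of n_boot).", n_redraws))
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  alpha_ci <- unname(stats::quantile(alpha_b, probs))
  beta_ci <- unname(stats::quantile(beta_b, probs))
  structure(
    list(
      fit = fit,
      alpha_ci = alpha_ci, beta_ci = beta_ci,
      n_boot = as.integer(n_boot), level = level,
      fixed_bias_present = !(alpha_ci[1] <= 0 && 0 <= alpha_ci[2]),
      proportional_bias_present = !(beta_ci[1] <= 1 && 1 <= beta_ci[2]),
      n_redraws = n_redraws,
      replicates = tibble::tibble(alpha = alpha_b, beta = beta_b)
    ),
    class = "eiv_bias"
  )
}

#' @export
print.eiv_bias <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Bootstrap bias assessment (%d resamples, %.0f%% CIs)\n",
      "  alpha = %.4f  CI [%.4f, %.4f]  fixed bias: %s\n",
      "  beta  = %.4f  CI [%.4f, %.4f]  proportional bias: %s\n"
    ),
    x$n_boot, 100 * x$level,
    x$fit$alpha, x$alpha_ci[1], x$alpha_ci[2],
    if (x$fixed_bias_present) "present" else "absent",
    x$fit$beta, x$beta_ci[1], x$beta_ci[2],
    if (x$proportional_bias_present) "present" else "absent"
  ))
  invisible(x)
}

#' @rdname bootstrap_bias
#' @param x An `eiv_bias`.
#' @param ... Unused.
#' @method tidy eiv_bias
#' @export
tidy.eiv_bias <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta"),
    estimate = c(x$fit$alpha, x$fit$beta),
    conf.low = c(x$alpha_ci[1], x$beta_ci[1]),
    conf.high = c(x$alpha_ci[2], x$beta_ci[2]),
    null.value = c(0, 1),
    bias.present = c(x$fixed_bias_present, x$proportional_bias_present)
  )
}

#' Simulate replicate data from the errors-in-variables model
#'
#' Draws latent gene levels \eqn{\xi_i \sim N(\mu_\xi, \sigma_\xi^2)} and
#' generates `n_reps` replicate observations per platform under the model of
#' [eiv_data()]. Used for calibration studies (null and alternative recovery,
#' bootstrap coverage).
#'
#' @param n_genes,n_reps Problem size (replicates per platform).
#' @param alpha,beta,lambda True intercept, slope and error-variance ratio.
#' @param sigma_delta Microarray replicate error sd (RNA-Seq error sd is
#'   `sqrt(lambda) * sigma_delta`).
#' @param xi_mean,xi_sd Latent level distribution.
#' @param seed Optional integer seed.
#' @return An `eiv_data` object.
#' @export
simulate_eiv_data <- function(n_genes, n_reps = 3, alpha = 0, beta = 1,
                              lambda = 1, sigma_delta = 0.25,
                              xi_mean = 0, xi_sd = 1, seed = NULL) {
  with_seed(seed, {
    xi <- stats::rnorm(n_genes, xi_mean, xi_sd)
    x <- xi + matrix(stats::rnorm(n_genes * n_reps, 0, sigma_delta), n_genes)
    y <- alpha + beta * xi +
      matrix(stats::rnorm(n_genes * n_reps, 0, sqrt(lambda) * sigma_delta), n_genes)
    eiv_data(x, y)
  })
}
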