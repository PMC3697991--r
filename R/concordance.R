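#' Union-based overlap rate between two gene sets
#'
#' The overlap rate of two detectable-gene (or DEG) sets is the number of
#' shared genes divided by the size of the union, i.e. the Jaccard index.
#'
#' @param set_a,set_b Character vectors of gene ids (duplicates ignored).
#' @return One-row tibble with `n_a`, `n_b`, `n_common`, `overlap_rate`
#'   and `empty_union` (a warning flag; the rate is 0 when both sets are
#'   empty).
#' @examples
#' overlap_rate(c("a", "b", "c"), c("b", "c", "d"))
#' @export
overlap_rate <- function(set_a, set_b) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  n_common <- length(intersect(a, b))
  n_union <- length(union(a, b))
  empty <- n_union == 0L
  if (empty) warn("both sets are empty; overlap rate reported as 0.")
  tibble::tibble(
    n_a = length(a), n_b = length(b), n_common = n_common,
    overlap_rate = if (empty) 0 else n_common / n_union,
    empty_union = empty
  )
}

#' Pearson and Spearman correlation of paired platform measurements
#'
#' Computes both the product-moment and the rank correlation for a pair of
#' per-gene expression vectors (typically log2(FPKM + 1) against normalized
#' log2 microarray intensity). Genes missing on one platform must be excluded
#' pairwise by the caller; `n_pairs` is reported so the gene universe stays
#' auditable.
#'
#' @param x,y Numeric vectors of equal length (at least 3), no missing values.
#' @return One-row tibble with `pearson`, `spearman`, `n_pairs`.
#' @export
paired_correlations <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("at least 3 pairs are required.")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("values must be finite.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined: zero variance in one of the vectors.")
  }
  tibble::tibble(
    pearson = stats::cor(x, y, method = "pearson"),
    spearman = stats::cor(x, y, method = "spearman"),
    n_pairs = length(x)
  )
}

#' Cross-platform correlation from two expression tables
#'
#' Joins two gene-level tables on `gene_id`, averages each platform's
#' replicates (optionally within one group) and returns
#' [paired_correlations()] of the two per-gene profiles.
#'
#' @param a,b Gene-level `expr_tbl`s on comparable (log2) scales.
#' @param group Optional group name; defaults to all samples.
#' @return One-row tibble as for [paired_correlations()].
#' @export
platform_correlations <- function(a, b, group = NULL) {
  mean_profile <- function(m) {
    grp <- expr_groups(m)
    samples <- if (is.null(group)) names(grp) else names(grp)[grp == group]
    if (length(samples) == 0L) abort(sprintf("group `%s` has no samples.", group))
    tibble::tibble(
      gene_id = m$gene_id,
      value = rowMeans(expr_matrix(m)[, samples, drop = FALSE])
    )
  }
  merged <- dplyr::inner_join(mean_profile(a), mean_profile(b),
    by = "gene_id", suffix = c("_a", "_b")
  )
  paired_correlations(merged$value_a, merged$value_b)
}

#' Compare expression densities of two gene classes
#'
#' Builds histogram densities for two classes of genes (typically the
#' commonly detectable genes and the platform-exclusive ones) over a shared
#' set of equal-width bins spanning the pooled range, and reports class
#' medians. A lower exclusive-class median indicates the exclusive genes sit
#' at the low end of the expression scale — the signature of one platform's
#' superior sensitivity for weakly expressed genes.
#'
#' @param common_expr,exclusive_expr Numeric vectors on the log2 expression
#'   scale; both nonempty.
#' @param n_bins Number of shared bins (default 40).
#' @return A `density_comparison` object: a list with `bins` (tibble of
#'   `bin_lo`, `bin_hi`, `density_common`, `density_exclusive`, normalized to
#'   integrate to 1) plus `median_common`, `median_exclusive`. Has an
#'   [autoplot()] method.
#' @export
density_comparison <- function(common_expr, exclusive_expr, n_bins = 40) {
  if (length(common_expr) == 0L || length(exclusive_expr) == 0L) {
    abort("both vectors must be nonempty.")
  }
  pooled <- range(c(common_expr, exclusive_expr))
  if (diff(pooled) == 0) pooled <- pooled + c(-0.5, 0.5)
  edges <- seq(pooled[1], pooled[2], length.out = n_bins + 1L)
  width <- diff(edges)[1]
  dens <- function(v) {
    counts <- tabulate(
      pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), n_bins),
      nbins = n_bins
    )
    counts / (sum(counts) * width)
  }
  structure(
    list(
      bins = tibble::tibble(
        bin_lo = edges[-length(edges)],
        bin_hi = edges[-1],
        density_common = dens(common_expr),
        density_exclusive = dens(exclusive_expr)
      ),
      median_common = stats::median(common_expr),
      median_exclusive = stats::median(exclusive_expr)
    ),
    class = "density_comparison"
  )
}

#' @export
print.density_comparison <- function(x, ...) {
  cat(sprintf(
    "Density comparison over %d bins\n  median (common):    %.3f\n  median (exclusive): %.3f\n",
    nrow(x$bins), x$median_common, x$median_exclusive
  ))
  invisible(x)
}

#' @rdname density_comparison
#' @param object A `density_comparison`.
#' @param ... Unused.
#' @method autoplot density_comparison
#' @export
autoplot.density_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object$bins,
    cols = dplyr::starts_with("density_"),
    names_to = "class", names_prefix = "density_", values_to = "density"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = (.data$bin_lo + .data$bin_hi) / 2,
    y = .data$density, fill = .data$class
  )) +
    ggplot2::geom_col(position = "identity", alpha = 0.6) +
    ggplot2::scale_fill_manual(values = c(common = "black", exclusive = "grey60")) +
    ggplot2::labs(
      x = "expression (log2 scale)", y = "density",
      fill = NULL
    ) +
    ggplot2::theme_minimal()
}
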