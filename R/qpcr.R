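#' Delta-Ct relative to a reference gene
#'
#' Computes the per-sample reference-minus-target difference of qPCR
#' threshold cycles, `ct_ref - ct_gene` (an undetected gene, encoded `NA`,
#' propagates). With this orientation a *larger* delta-Ct means *higher*
#' expression of the test gene.
#'
#' @param ct_gene,ct_ref Numeric threshold cycles (technical replicates
#'   already averaged); `NA` marks an undetected gene.
#' @return `ct_ref - ct_gene`.
#' @export
delta_ct <- function(ct_gene, ct_ref) {
  if (any(ct_gene <= 0, na.rm = TRUE) || any(ct_ref <= 0, na.rm = TRUE)) {
    abort("Ct values must be positive (or NA for undetected).")
  }
  ct_ref - ct_gene
}

#' Delta-delta-Ct fold change with a two-group t-test
#'
#' Computes `ddct = mean(dct_treated) - mean(dct_control)` and turns it into
#' a linear fold change. Because [delta_ct()] is oriented reference minus
#' target, two sign conventions are offered:
#' * `"standard"` (default) — `2^(+ddct)`, the Livak orientation: an
#'   up-regulated gene gets a fold change above 1;
#' * `"literal"` — `2^(-ddct)`, applying the textbook `2^-ddCt` formula
#'   directly to the reference-minus-target delta-Ct, which inverts the
#'   ratio (the product of the two conventions is exactly 1 on the same
#'   data). A message notes the inversion when it is selected.
#'
#' Undetected measurements (`NA`) drive the flags: a fully undetected
#' control with a detected treated group yields an infinite fold change
#' (flag `"undetected_control"`); both groups undetected yields an undefined
#' result (flag `"undefined"`). The p-value is a two-sample t-test on the
#' delta-Ct vectors (Student pooled-variance by default) and requires at
#' least 2 detected values per group.
#'
#' @param dct_treated,dct_control Per-sample delta-Ct vectors.
#' @param convention `"standard"` or `"literal"` (see above).
#' @param var_equal Pooled-variance Student test (default `TRUE`); `FALSE`
#'   for Welch.
#' @return One-row tibble: `ddct`, `fold_change`, `p_value`, `n_treated`,
#'   `n_control`, `convention`, `flag`.
#' @examples
#' fold_change_ddct(c(3.1, 3.3, 2.9), c(1.9, 2.2, 2.0))
#' @export
fold_change_ddct <- function(dct_treated, dct_control,
                             convention = c("standard", "literal"),
                             var_equal = TRUE) {
  convention <- match.arg(convention)
  t_det <- dct_treated[!is.na(dct_treated)]
  c_det <- dct_control[!is.na(dct_control)]
  if (length(dct_treated) < 1L || length(dct_control) < 1L) {
    abort("at least one value per group is required.")
  }
  result <- function(ddct, fold_change, p_value, flag) {
    tibble::tibble(
      ddct = ddct, fold_change = fold_change, p_value = p_value,
      n_treated = length(t_det), n_control = length(c_det),
      convention = convention, flag = flag
    )
  }
  if (length(t_det) == 0L && length(c_det) == 0L) {
    return(result(NA_real_, NA_real_, NA_real_, "undefined"))
  }
  if (length(c_det) == 0L) {
    # expression appears only after treatment: infinite induction
    return(result(NA_real_, Inf, NA_real_, "undetected_control"))
  }
  if (length(t_det) == 0L) {
    return(result(NA_real_, 0, NA_real_, "undetected_treated"))
  }
  ddct <- mean(t_det) - mean(c_det)
  if (convention == "literal") {
    rlang::inform(
      "literal convention: 2^-ddCt on reference-minus-target delta-Ct inverts the ratio.",
      class = "crossplat_qpcr_convention"
    )
  }
  fc <- if (convention == "standard") 2^ddct else 2^(-ddct)
  p <- if (length(t_det) >= 2L && length(c_det) >= 2L) {
    tryCatch(
      stats::t.test(t_det, c_det, var.equal = var_equal)$p.value,
      error = function(e) if (ddct == 0) 1 else 0 # constant data
    )
  } else {
    NA_real_
  }
  result(ddct, fc, p, NA_character_)
}

#' Per-gene delta-delta-Ct analysis of a qPCR table
#'
#' Takes a long table of threshold cycles with one row per gene and sample
#' (columns `gene_id`, `sample`, `group`, `ct`, `ref_ct`; `NA` in `ct`
#' marks an undetected gene) and runs [delta_ct()] plus
#' [fold_change_ddct()] for every gene.
#'
#' @param tbl The long qPCR table.
#' @param treatment,control Group names in `tbl$group`.
#' @inheritParams fold_change_ddct
#' @return Tibble with one row per gene: the [fold_change_ddct()] columns.
#' @export
qpcr_analysis <- function(tbl, treatment, control,
                          convention = c("standard", "literal"),
                          var_equal = TRUE) {
  convention <- match.arg(convention)
  needed <- c("gene_id", "sample", "group", "ct", "ref_ct")
  if (!all(needed %in% names(tbl))) {
    abort(sprintf("table needs columns: %s.", paste(needed, collapse = ", ")))
  }
  tbl |>
    dplyr::mutate(dct = delta_ct(.data$ct, .data$ref_ct)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(df, key) {
      fold_change_ddct(
        df$dct[df$group == treatment],
        df$dct[df$group == control],
        convention = convention, var_equal = var_equal
      )
    }) |>
    dplyr::ungroup()
}
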