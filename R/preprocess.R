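#' Detectability filter for RNA-Seq count tables
#'
#' A gene is *detectable* in an experimental group when its maximum count over
#' that group's replicates reaches `min_count`; a gene is retained when it is
#' detectable in at least one group. Equivalently, a gene is removed only when
#' its within-group maximum falls below the threshold in every group.
#'
#' The filter report (attached as the `"filter_report"` attribute and
#' retrievable with [filter_report()]) records the per-group detectable gene
#' sets, which also feed the cross-platform overlap statistics.
#'
#' @param m An `expr_tbl` with `platform = "rnaseq"`, `scale = "counts"`.
#' @param min_count Detectability threshold on the within-group maximum
#'   (default 10 reads).
#' @return The filtered `expr_tbl`, with a `filter_report` attribute.
#' @examples
#' m <- expression_table(
#'   data.frame(gene_id = c("a", "b"), s1 = c(0L, 12L), s2 = c(3L, 0L)),
#'   platform = "rnaseq", scale = "counts",
#'   groups = c(s1 = "ctl", s2 = "ctl")
#' )
#' filter_report(filter_rnaseq_counts(m))
#' @export
filter_rnaseq_counts <- function(m, min_count = 10) {
  validate_expression_table(m)
  if (expr_platform(m) != "rnaseq" || expr_scale(m) != "counts") {
    abort("`m` must be an RNA-Seq count table.")
  }
  detectable <- detectable_sets(m, function(block) {
    apply(block, 1L, max) >= min_count
  })
  apply_detectability(m, detectable)
}

#' Detectability filter for microarray present/absent calls
#'
#' A gene is detectable in a group when it is flagged present in *all*
#' replicates of that group, and retained when detectable in at least one
#' group. Present/absent calling itself is upstream of this package: pass an
#' explicit logical presence table aligned to `m`, or let the default derive
#' presence as intensity above the `presence_quantile` of each chip
#' (`presence_quantile = 0` flags everything present).
#'
#' @param m An `expr_tbl` with `platform = "microarray"`, `scale = "log2"`.
#' @param presence Optional gene-by-sample logical matrix (dimensions and
#'   order matching `expr_matrix(m)`).
#' @param presence_quantile Per-chip intensity quantile used to derive
#'   presence when `presence` is not supplied. Default 0 (always present).
#' @return The filtered `expr_tbl` with a `filter_report` attribute.
#' @export
filter_microarray_present <- function(m, presence = NULL, presence_quantile = 0) {
  validate_expression_table(m)
  if (expr_platform(m) != "microarray") {
    abort("`m` must be a microarray table.")
  }
  v <- expr_matrix(m)
  if (is.null(presence)) {
    thresh <- apply(v, 2L, stats::quantile, probs = presence_quantile)
    presence <- sweep(v, 2L, thresh, ">=")
  }
  if (!is.logical(presence) || !identical(dim(presence), dim(v))) {
    abort("`presence` must be a logical matrix aligned to `m`.")
  }
  detectable <- detectable_sets_matrix(m, presence, function(block) {
    rowSums(block) == ncol(block)
  })
  apply_detectability(m, detectable)
}

# Per-group detectability from the expression values themselves.
detectable_sets <- function(m, predicate) {
  detectable_sets_matrix(m, expr_matrix(m), predicate)
}

detectable_sets_matrix <- function(m, mat, predicate) {
  grp <- expr_groups(m)
  purrr::map(split(names(grp), grp), function(samples) {
    block <- mat[, samples, drop = FALSE]
    m$gene_id[predicate(block)]
  })
}

apply_detectability <- function(m, detectable) {
  keep <- m$gene_id %in% unique(unlist(detectable))
  out <- restore_expr(m[keep, ], m)
  report <- structure(
    list(
      n_input = nrow(m),
      n_retained = sum(keep),
      detectable_per_group = detectable
    ),
    class = "filter_report"
  )
  attr(out, "filter_report") <- report
  out
}

#' @rdname filter_rnaseq_counts
#' @param x A filtered `expr_tbl`.
#' @export
filter_report <- function(x) attr(x, "filter_report")

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Detectability filter: %d of %d genes retained\n", x$n_retained, x$n_input))
  for (g in names(x$detectable_per_group)) {
    cat(sprintf("  %s: %d detectable\n", g, length(x$detectable_per_group[[g]])))
  }
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param report A `filter_report` as returned by [filter_report()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @export
filter_report_json <- function(report, path = NULL) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    invisible(path)
  } else {
    json
  }
}

#' Collapse probe-level rows to gene level
#'
#' When several probes interrogate the same gene, the probe with the highest
#' mean intensity across all samples represents the gene (ties broken by the
#' lexicographically smallest probe id). Probes absent from the map are not an
#' error; they are recorded in the `"skipped_probes"` attribute.
#'
#' @param m An `expr_tbl` whose rows are probes.
#' @param probe_map Data frame with columns `probe_id`, `gene_id`
#'   (many probes to one gene).
#' @return A gene-level `expr_tbl`, rows sorted by `gene_id`.
#' @export
collapse_probes <- function(m, probe_map) {
  validate_expression_table(m)
  if (!all(c("probe_id", "gene_id") %in% names(probe_map))) {
    abort("`probe_map` needs columns `probe_id` and `gene_id`.")
  }
  if (anyDuplicated(probe_map$probe_id)) {
    abort("every probe must map to exactly one gene.")
  }
  skipped <- setdiff(m$gene_id, probe_map$probe_id)
  mat <- expr_matrix(m)
  picked <- tibble::tibble(
    probe_id = m$gene_id,
    probe_mean = rowMeans(mat)
  ) |>
    dplyr::inner_join(tibble::as_tibble(probe_map[c("probe_id", "gene_id")]),
      by = "probe_id"
    ) |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$probe_mean), .data$probe_id) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
  values <- tibble::as_tibble(mat[picked$probe_id, , drop = FALSE])
  out <- restore_expr(
    dplyr::bind_cols(tibble::tibble(gene_id = picked$gene_id), values), m
  )
  attr(out, "skipped_probes") <- skipped
  attr(out, "representative_probe") <- setNames(picked$probe_id, picked$gene_id)
  out
}

#' Log2-transform an FPKM table
#'
#' Applies `log2(value + pseudocount)` elementwise; the default pseudocount of
#' 1 maps FPKM 0 to 0.
#'
#' @param m An `expr_tbl` with `scale = "fpkm"`.
#' @param pseudocount Added before taking logs (default 1).
#' @return An `expr_tbl` with `scale = "log2"`.
#' @export
log2_fpkm <- function(m, pseudocount = 1) {
  validate_expression_table(m)
  if (expr_scale(m) != "fpkm") abort("`m` must be on the fpkm scale.")
  out <- dplyr::mutate(tibble::as_tibble(as.data.frame(m)),
    dplyr::across(-"gene_id", ~ log2(.x + pseudocount))
  )
  restore_expr(out, m, scale = "log2")
}

#' Housekeeping-gene normalization to unit-free values
#'
#' Converts log2-scale expression to unit-free values relative to a
#' housekeeping gene, per sample. `mode = "divide"` divides each gene's log2
#' value by the housekeeping gene's log2 value (the housekeeping row becomes
#' all 1); `mode = "subtract"` subtracts it (housekeeping row all 0). The two
#' differ because the division acts on already-logged values; both are kept
#' because common usage is ambiguous between them. The applied mode and gene
#' are recorded in the `"normalization"` attribute.
#'
#' The default gene id is ENSG00000197935 (*ZNF311*), a moderately and
#' consistently expressed gene well suited as a reference; override as needed.
#'
#' @param m An `expr_tbl` with `scale = "log2"`.
#' @param gene Housekeeping gene id present in `m`.
#' @param mode `"divide"` or `"subtract"`.
#' @return A unit-free `expr_tbl` (still tagged `scale = "log2"`).
#' @export
normalize_housekeeping <- function(m, gene = "ENSG00000197935",
                                   mode = c("divide", "subtract")) {
  mode <- match.arg(mode)
  validate_expression_table(m)
  if (expr_scale(m) != "log2") abort("`m` must be on the log2 scale.")
  if (!gene %in% m$gene_id) {
    abort(sprintf("housekeeping gene `%s` not found.", gene))
  }
  mat <- expr_matrix(m)
  hk <- mat[gene, ]
  if (mode == "divide" && any(hk == 0)) {
    bad <- names(hk)[hk == 0][1]
    abort(sprintf(
      "housekeeping gene has zero log2 value in sample `%s`; cannot divide.", bad
    ))
  }
  norm <- if (mode == "divide") sweep(mat, 2L, hk, "/") else sweep(mat, 2L, hk, "-")
  out <- restore_expr(
    dplyr::bind_cols(
      tibble::tibble(gene_id = m$gene_id),
      tibble::as_tibble(norm)
    ), m
  )
  attr(out, "normalization") <- list(gene = gene, mode = mode, reference = hk)
  out
}
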