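#' Build an expression table
#'
#' An expression table is the package's basic container: a tibble with a
#' `gene_id` column followed by one numeric column per sample, carrying the
#' platform (`rnaseq` or `microarray`), the measurement scale (`counts`,
#' `fpkm` or `log2`) and the sample-to-group assignment as attributes. All
#' user-facing functions accept and return this shape so pipelines compose
#' with the pipe.
#'
#' @param values A data frame whose first column is `gene_id` (or a numeric
#'   matrix with gene ids as row names and samples as column names).
#' @param platform One of `"rnaseq"`, `"microarray"`.
#' @param scale One of `"counts"`, `"fpkm"`, `"log2"`. Raw read counts must be
#'   non-negative integers; FPKM must be non-negative.
#' @param groups Named character vector mapping sample name to group name.
#'   Every sample column must be named here.
#'
#' @return A tibble of class `expr_tbl`.
#' @examples
#' m <- expression_table(
#'   data.frame(gene_id = c("g1", "g2"), s1 = c(0, 5), s2 = c(3, 8)),
#'   platform = "rnaseq", scale = "counts",
#'   groups = c(s1 = "control", s2 = "treated")
#' )
#' expr_groups(m)
#' @export
expression_table <- function(values,
                             platform = c("rnaseq", "microarray"),
                             scale = c("counts", "fpkm", "log2"),
                             groups) {
  platform <- match.arg(platform)
  scale <- match.arg(scale)
  if (is.matrix(values)) {
    if (is.null(rownames(values)) || is.null(colnames(values))) {
      abort("matrix input needs gene ids as rownames and sample names as colnames.")
    }
    values <- tibble::as_tibble(values, rownames = "gene_id")
  }
  values <- tibble::as_tibble(values)
  if (names(values)[1] != "gene_id") {
    names(values)[1] <- "gene_id"
  }
  values$gene_id <- as.character(values$gene_id)
  out <- tibble::new_tibble(values,
    class = "expr_tbl",
    platform = platform, scale = scale, groups = groups
  )
  validate_expression_table(out)
  out
}

#' Validate an expression table's invariants
#'
#' Checks gene-id uniqueness, finiteness, scale-dependent non-negativity
#' (and integrality for counts), and that every sample carries a group with
#' at least one replicate.
#'
#' @param x An `expr_tbl`.
#' @return `x`, invisibly; aborts with an informative message on violation.
#' @export
validate_expression_table <- function(x) {
  if (!inherits(x, "expr_tbl")) abort("not an `expr_tbl`.")
  ids <- x$gene_id
  if (anyDuplicated(ids)) abort("gene ids must be unique.")
  v <- expr_matrix(x)
  if (!is.numeric(v)) abort("sample columns must be numeric.")
  if (any(!is.finite(v))) abort("expression values must be finite.")
  scale <- expr_scale(x)
  if (scale %in% c("counts", "fpkm") && any(v < 0)) {
    abort(sprintf("%s values must be non-negative.", scale))
  }
  if (scale == "counts" && any(v != round(v))) {
    abort("counts must be integers.")
  }
  grp <- expr_groups(x)
  samples <- setdiff(names(x), "gene_id")
  if (length(samples) == 0L) abort("at least one sample column is required.")
  missing <- setdiff(samples, names(grp))
  if (length(missing)) {
    abort(sprintf("samples without a group: %s", paste(missing, collapse = ", ")))
  }
  invisible(x)
}

#' @rdname expression_table
#' @param x An `expr_tbl`.
#' @export
expr_matrix <- function(x) {
  samples <- setdiff(names(x), "gene_id")
  m <- as.matrix(as.data.frame(x)[samples])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene_id
  m
}

#' @rdname expression_table
#' @export
expr_platform <- function(x) attr(x, "platform")

#' @rdname expression_table
#' @export
expr_scale <- function(x) attr(x, "scale")

#' @rdname expression_table
#' @export
expr_groups <- function(x) {
  grp <- attr(x, "groups")
  samples <- setdiff(names(x), "gene_id")
  grp[samples]
}

# Rebuild an expr_tbl from a plain tibble, carrying metadata over.
restore_expr <- function(values, template, scale = NULL) {
  tibble::new_tibble(values,
    class = "expr_tbl",
    platform = expr_platform(template),
    scale = scale %||% expr_scale(template),
    groups = attr(template, "groups")
  )
}

#' @export
print.expr_tbl <- function(x, ...) {
  cat(sprintf(
    "# Expression table: %d genes x %d samples [%s, %s]\n",
    nrow(x), ncol(x) - 1L, expr_platform(x), expr_scale(x)
  ))
  grp <- expr_groups(x)
  cat("# Groups:", paste(sprintf("%s (n=%d)", unique(grp), as.vector(table(grp)[unique(grp)])),
    collapse = ", "
  ), "\n")
  NextMethod()
}

#' Read and write delimited expression tables
#'
#' `read_expression_table()` reads a tab- or comma-delimited gene-by-sample
#' table with a header row and gene/probe ids in the first column.
#' `write_expression_table()` writes one back. `read_htseq_counts()` merges
#' per-sample two-column count files (gene id, count), dropping the trailing
#' summary rows whose ids start with `"__"` (e.g. `__no_feature`).
#'
#' @param path File path. Delimiter is inferred from the extension
#'   (`.csv` means comma, anything else tab) unless `delim` is given.
#' @param delim Field delimiter override.
#' @inheritParams expression_table
#' @return An `expr_tbl`.
#' @export
read_expression_table <- function(path, platform, scale, groups, delim = NULL) {
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  values <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    progress = FALSE
  )
  expression_table(values, platform = platform, scale = scale, groups = groups)
}

#' @rdname read_expression_table
#' @param x An `expr_tbl`.
#' @export
write_expression_table <- function(x, path, delim = "\t") {
  readr::write_delim(tibble::as_tibble(as.data.frame(x)), path, delim = delim)
  invisible(path)
}

#' @rdname read_expression_table
#' @param files Character vector of HTSeq-count style two-column files.
#' @param sample_labels Sample name per file (defaults to file base names).
#' @export
read_htseq_counts <- function(files, sample_labels = NULL, groups) {
  sample_labels <- sample_labels %||% sub("\\.[^.]*$", "", basename(files))
  stopifnot(length(files) == length(sample_labels))
  cols <- purrr::map2(files, sample_labels, function(f, lab) {
    tab <- readr::read_tsv(f,
      col_names = c("gene_id", lab), show_col_types = FALSE,
      progress = FALSE
    )
    tab[!startsWith(tab$gene_id, "__"), ]
  })
  values <- purrr::reduce(cols, dplyr::full_join, by = "gene_id")
  values[is.na(values)] <- 0
  expression_table(values, platform = "rnaseq", scale = "counts", groups = groups)
}
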