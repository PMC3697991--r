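#' Built-in differential-expression caller: Welch t-test with BH correction
#'
#' Runs a per-gene two-sample Welch t-test between two groups on the
#' appropriate analysis scale, adjusts p-values with Benjamini–Hochberg
#' across all tested genes, and reports fold changes on the linear scale
#' (ratio of treatment over control group means). Analysis scales:
#' * `"counts"` — tested on `log2(count + 1)`; fold change is the ratio of
#'   the raw-count group means (1 when both are zero);
#' * `"intensity"` — raw microarray intensities, tested on `log2` after
#'   clamping at 1 (an additive-background model can produce the odd
#'   non-positive value); fold change is the ratio of raw-intensity means;
#' * `"log2"` — used as is; fold change is `2^(mean difference)`.
#'
#' Genes with zero variance in both groups get p = 1 when the group means
#' are equal (and p = 0 otherwise). Welch (unequal-variance) is the default;
#' set `var_equal = TRUE` for the pooled-variance Student test.
#'
#' @param m An `expr_tbl`, or a gene-by-sample numeric matrix with row
#'   names.
#' @param groups Named character vector (sample to group); taken from `m`
#'   when it is an `expr_tbl`.
#' @param treatment,control Group names; default: the two groups in order of
#'   first appearance are control, treatment.
#' @param input_scale Analysis scale (see above); inferred from an
#'   `expr_tbl`'s scale tag (`counts` or `log2`).
#' @param var_equal Use the pooled-variance Student t-test instead of Welch.
#' @param method_name Label recorded in the result (default
#'   `"ttest_bh"`).
#' @return A `deg_result` tibble: `gene_id`, `fc` (linear), `direction`,
#'   `p`, `fdr`, plus a `called` column once [apply_thresholds()] has run.
#' @export
ttest_bh_caller <- function(m, groups = NULL, treatment = NULL, control = NULL,
                            input_scale = c("counts", "intensity", "log2"),
                            var_equal = FALSE, method_name = "ttest_bh") {
  if (inherits(m, "expr_tbl")) {
    groups <- groups %||% expr_groups(m)
    if (missing(input_scale)) {
      input_scale <- switch(expr_scale(m),
        counts = "counts",
        log2 = "log2",
        abort("cannot infer the analysis scale; pass `input_scale`.")
      )
    }
    m <- expr_matrix(m)
  }
  input_scale <- match.arg(input_scale)
  if (is.null(groups)) abort("`groups` is required for matrix input.")
  m <- as.matrix(m)
  groups <- groups[colnames(m)]
  lv <- unique(groups)
  if (length(lv) != 2L) abort("exactly two groups are required.")
  control <- control %||% lv[1]
  treatment <- treatment %||% setdiff(lv, control)[1]
  ctl <- m[, names(groups)[groups == control], drop = FALSE]
  trt <- m[, names(groups)[groups == treatment], drop = FALSE]
  if (ncol(ctl) < 2L || ncol(trt) < 2L) abort("at least 2 replicates per group.")

  analysis <- switch(input_scale,
    counts = function(x) log2(x + 1),
    intensity = function(x) log2(pmax(x, 1)),
    log2 = identity
  )
  a_ctl <- analysis(ctl)
  a_trt <- analysis(trt)
  tt <- row_welch(a_trt, a_ctl, var_equal = var_equal)

  fc <- switch(input_scale,
    counts = ,
    intensity = {
      mc <- rowMeans(ctl)
      mt <- rowMeans(trt)
      ifelse(mc == 0 & mt == 0, 1, mt / mc)
    },
    log2 = 2^(rowMeans(a_trt) - rowMeans(a_ctl))
  )

  out <- tibble::tibble(
    gene_id = rownames(m) %||% sim_gene_ids(nrow(m)),
    fc = fc,
    direction = ifelse(fc >= 1, "up", "down"),
    p = tt$p,
    fdr = stats::p.adjust(tt$p, method = "BH")
  )
  new_deg_result(out,
    method = method_name, significance = "fdr",
    treatment = treatment, control = control
  )
}

# Vectorized two-sample t-test across matrix rows (Welch by default).
row_welch <- function(a, b, var_equal = FALSE) {
  n1 <- ncol(a)
  n2 <- ncol(b)
  m1 <- rowMeans(a)
  m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  }
  tstat <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  list(statistic = tstat, df = df, p = p)
}

new_deg_result <- function(tbl, method, significance = "fdr",
                           q_cutoff = NA_real_, treatment = NA_character_,
                           control = NA_character_) {
  tibble::new_tibble(tbl,
    class = "deg_result",
    method = method, significance = significance, q_cutoff = q_cutoff,
    treatment = treatment, control = control
  )
}

#' Threshold a caller's result into a DEG list
#'
#' Keeps genes with fold change strictly above `fc` or strictly below
#' `1/fc`, and adjusted significance `fdr` at most the cutoff (a fold change
#' of exactly 2 is *not* called at the default threshold). Results whose
#' significance column is a q-score with larger-is-better semantics (see
#' [external_deg_caller()]) are filtered at their declared q cutoff
#' instead.
#'
#' @param r A `deg_result`.
#' @param fc Fold-change threshold (linear scale, default 2).
#' @param fdr Adjusted-significance cutoff (default 0.05).
#' @return The `deg_result` with a logical `called` column; the called ids
#'   are available via [called_set()].
#' @export
apply_thresholds <- function(r, fc = 2, fdr = 0.05) {
  stopifnot(inherits(r, "deg_result"))
  fc_pass <- (r$fc > fc | r$fc < 1 / fc)
  sig_pass <- if (identical(attr(r, "significance"), "q")) {
    r$fdr >= attr(r, "q_cutoff")
  } else {
    r$fdr <= fdr
  }
  r$called <- !is.na(fc_pass) & !is.na(sig_pass) & fc_pass & sig_pass
  attr(r, "thresholds") <- list(fc = fc, fdr = fdr)
  r
}

#' @rdname apply_thresholds
#' @export
called_set <- function(r) {
  stopifnot(inherits(r, "deg_result"))
  if (is.null(r$called)) abort("run `apply_thresholds()` first.")
  r$gene_id[r$called]
}

#' Run an external differential-expression tool through a shell adapter
#'
#' Wraps any command-line DEG method behind the same `deg_result` contract
#' as the built-in caller. The input table, group labels and an output path
#' are written to a scratch directory and substituted into the command
#' template at the placeholders `{input}`, `{groups}`, `{output}`; the
#' command must write a delimited table with a header containing columns
#' `gene_id`, `fc`, and either `fdr` (smaller is more significant) or `q`
#' (larger is more significant — declare `significance = "q"` and its
#' cutoff, e.g. 0.8).
#'
#' A nonzero exit status or an unparseable output raises a classed
#' `crossplat_adapter_error` carrying the captured log, so a benchmarking
#' loop can record the failure and continue with its other callers.
#'
#' @param command_template Shell command with `{input}`, `{groups}`,
#'   `{output}` placeholders.
#' @param m Gene-by-sample numeric matrix (or `expr_tbl`) handed to the
#'   tool as a TSV with a `gene_id` column.
#' @param groups Named character vector, sample to group.
#' @param significance `"fdr"` or `"q"`.
#' @param q_cutoff Cutoff used by [apply_thresholds()] when
#'   `significance = "q"`.
#' @param method_name Label recorded in the result.
#' @param work_dir Scratch directory (default a fresh `tempfile()`).
#' @return A `deg_result` tibble.
#' @export
external_deg_caller <- function(command_template, m, groups,
                                significance = c("fdr", "q"), q_cutoff = 0.8,
                                method_name = "external", work_dir = NULL) {
  significance <- match.arg(significance)
  if (inherits(m, "expr_tbl")) {
    groups <- groups %||% expr_groups(m)
    m <- expr_matrix(m)
  }
  work_dir <- work_dir %||% tempfile("deg_adapter_")
  dir.create(work_dir, showWarnings = FALSE, recursive = TRUE)
  input <- file.path(work_dir, "input.tsv")
  groups_file <- file.path(work_dir, "groups.tsv")
  output <- file.path(work_dir, "output.tsv")
  readr::write_tsv(tibble::as_tibble(m, rownames = "gene_id"), input, progress = FALSE)
  readr::write_tsv(
    tibble::tibble(sample = names(groups), group = unname(groups)),
    groups_file,
    progress = FALSE
  )
  cmd <- gsub("{input}", input, command_template, fixed = TRUE)
  cmd <- gsub("{groups}", groups_file, cmd, fixed = TRUE)
  cmd <- gsub("{output}", output, cmd, fixed = TRUE)
  log <- tryCatch(
    suppressWarnings(system(paste(cmd, "2>&1"), intern = TRUE)),
    error = function(e) structure(conditionMessage(e), status = 127L)
  )
  status <- attr(log, "status") %||% 0L
  if (status != 0L) {
    abort(
      sprintf("external caller `%s` exited with status %d.", method_name, status),
      class = "crossplat_adapter_error", log = log
    )
  }
  tab <- tryCatch(
    readr::read_tsv(output, show_col_types = FALSE, progress = FALSE),
    error = function(e) {
      abort(
        sprintf("external caller `%s` produced unreadable output: %s", method_name, conditionMessage(e)),
        class = "crossplat_adapter_error", log = log
      )
    }
  )
  sig_col <- if (significance == "q") "q" else "fdr"
  needed <- c("gene_id", "fc", sig_col)
  if (!all(needed %in% names(tab))) {
    abort(
      sprintf(
        "external caller `%s` output lacks columns: %s.", method_name,
        paste(setdiff(needed, names(tab)), collapse = ", ")
      ),
      class = "crossplat_adapter_error", log = log
    )
  }
  out <- tibble::tibble(
    gene_id = as.character(tab$gene_id),
    fc = as.numeric(tab$fc),
    direction = ifelse(tab$fc >= 1, "up", "down"),
    p = NA_real_,
    fdr = as.numeric(tab[[sig_col]])
  )
  new_deg_result(out,
    method = method_name, significance = significance,
    q_cutoff = if (significance == "q") q_cutoff else NA_real_
  )
}
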