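#' Score a DEG call set against simulation truth
#'
#' Confusion counts and derived metrics of a thresholded caller result
#' against the truth table: sensitivity `tp / (tp + fn)`, empirical FDR
#' `fp / max(tp + fp, 1)` (0 for an empty call set) and specificity
#' `tn / (fp + tn)`.
#'
#' @param r A `deg_result` after [apply_thresholds()] (or any character
#'   vector of called gene ids).
#' @param truth Truth tibble with `gene_id` and logical `is_deg` covering
#'   the same gene universe.
#' @return One-row tibble: `method`, `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `fdr`, `specificity`.
#' @export
evaluate_calls <- function(r, truth) {
  if (inherits(r, "deg_result")) {
    # external tools may report only the genes they call; the result must
    # at least live inside the truth's gene universe
    if (!all(r$gene_id %in% truth$gene_id)) {
      abort("gene universe mismatch between result and truth.")
    }
    called <- called_set(r)
    method <- attr(r, "method")
  } else {
    called <- as.character(r)
    if (!all(called %in% truth$gene_id)) {
      abort("called genes outside the truth's gene universe.")
    }
    method <- NA_character_
  }
  is_called <- truth$gene_id %in% called
  tp <- sum(is_called & truth$is_deg)
  fp <- sum(is_called & !truth$is_deg)
  fn <- sum(!is_called & truth$is_deg)
  tn <- sum(!is_called & !truth$is_deg)
  tibble::tibble(
    method = method, tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fdr = fp / max(tp + fp, 1),
    specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_
  )
}

#' Pairwise overlap-rate matrix of DEG lists
#'
#' Entry (a, b) is the union-based overlap rate (\eqn{|A \cap B|/|A \cup B|},
#' see [overlap_rate()]) of the two called sets; the diagonal is 1 for
#' nonempty sets. Used for intra- and cross-platform method comparison.
#'
#' @param results Named list of thresholded `deg_result`s (or character
#'   vectors of called gene ids).
#' @return Symmetric numeric matrix with method names as dimnames.
#' @export
overlap_matrix <- function(results) {
  sets <- purrr::imap(results, function(r, nm) {
    if (inherits(r, "deg_result")) called_set(r) else unique(as.character(r))
  })
  names(sets) <- names(sets) %||% paste0("method", seq_along(sets))
  k <- length(sets)
  out <- matrix(0, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    for (j in seq_len(i)) {
      rate <- suppressWarnings(overlap_rate(sets[[i]], sets[[j]])$overlap_rate)
      out[i, j] <- out[j, i] <- rate
    }
  }
  out
}

#' Benchmark callers on simulated paired datasets
#'
#' Generates `n_datasets` paired datasets from the simulation model, runs
#' each caller on its platform's matrix, applies the fold-change and FDR
#' thresholds, and scores against truth. [fc_sweep()] repeats this across a
#' grid of 95% minimum fold-change levels, averaging each metric per level
#' and caller — the sensitivity/FDR operating curves used to rank methods.
#'
#' Callers are named functions `function(sim)` returning a `deg_result`
#' over the simulated gene universe; the defaults run the built-in
#' t-test/BH caller on the counts (`ttest_rnaseq`) and on the raw
#' intensities (`ttest_microarray`). A caller failure on one dataset is
#' recorded (with a warning) and the affected level is averaged over the
#' remaining datasets.
#'
#' @param deg A [deg_spec()]; for `fc_sweep()` its `fc_level_log2` is
#'   replaced by each level in turn.
#' @param callers Named list of caller functions.
#' @param n_datasets Simulated datasets per configuration (default 10).
#' @param n_reps Replicates per group (default 5).
#' @param model Simulation model components, as from
#'   [default_parametric_model()].
#' @param fc,fdr Thresholds passed to [apply_thresholds()].
#' @param seed Master integer seed.
#' @return `benchmark_callers()`: tibble of per-dataset metrics.
#' @export
benchmark_callers <- function(deg = deg_spec(), callers = default_callers(),
                              n_datasets = 10, n_reps = 5,
                              model = default_parametric_model(),
                              fc = 2, fdr = 0.05, seed = NULL) {
  purrr::map_dfr(seq_len(n_datasets), function(d) {
    sim <- simulate_dataset(model$emp, model$noise, model$nb,
      deg = deg,
      n_reps = n_reps, seed = derive_seed(seed %||% 0, 100L + d)
    )
    purrr::imap_dfr(callers, function(caller, nm) {
      res <- tryCatch(caller(sim), error = function(e) {
        warn(sprintf("caller `%s` failed on dataset %d: %s", nm, d, conditionMessage(e)))
        NULL
      })
      if (is.null(res)) {
        return(tibble::tibble())
      }
      metrics <- evaluate_calls(apply_thresholds(res, fc = fc, fdr = fdr), sim$truth)
      dplyr::mutate(metrics, method = nm, dataset = d, .before = 1)
    })
  })
}

#' @rdname benchmark_callers
#' @export
default_callers <- function() {
  list(
    ttest_rnaseq = function(sim) {
      ttest_bh_caller(sim$counts,
        groups = sim$groups,
        treatment = "treatment", control = "control", input_scale = "counts"
      )
    },
    ttest_microarray = function(sim) {
      ttest_bh_caller(sim$intensities,
        groups = sim$groups,
        treatment = "treatment", control = "control", input_scale = "intensity"
      )
    }
  )
}

#' @rdname benchmark_callers
#' @param fc_levels 95% minimum fold-change levels, log2 scale (default 0.5
#'   to 4 by 0.5).
#' @param n_genes,n_deg Passed to [deg_spec()] per level.
#' @param sigma_logfc Fold-change spread per level (default 0.25).
#' @return `fc_sweep()`: a `sweep_curve` object — tibble of per-level,
#'   per-method mean `sensitivity`, `fdr` and `specificity` (with the
#'   per-dataset table as attribute `"per_dataset"`); has an [autoplot()]
#'   method.
#' @export
fc_sweep <- function(fc_levels = seq(0.5, 4, by = 0.5),
                     callers = default_callers(),
                     n_datasets = 10, n_genes = 10000, n_deg = 1000,
                     sigma_logfc = 0.25, n_reps = 5,
                     model = default_parametric_model(),
                     fc = 2, fdr = 0.05, seed = NULL) {
  per_dataset <- purrr::imap_dfr(fc_levels, function(level, li) {
    res <- benchmark_callers(
      deg = deg_spec(
        n_genes = n_genes, n_deg = n_deg,
        fc_level_log2 = level, sigma_logfc = sigma_logfc
      ),
      callers = callers, n_datasets = n_datasets, n_reps = n_reps,
      model = model, fc = fc, fdr = fdr,
      seed = derive_seed(seed %||% 0, 10000L * li)
    )
    dplyr::mutate(res, fc_level = level, .before = 1)
  })
  curve <- per_dataset |>
    dplyr::group_by(.data$fc_level, .data$method) |>
    dplyr::summarise(
      sensitivity = mean(.data$sensitivity),
      fdr = mean(.data$fdr),
      specificity = mean(.data$specificity),
      n_datasets = dplyr::n(),
      .groups = "drop"
    )
  tibble::new_tibble(curve, class = "sweep_curve", per_dataset = per_dataset)
}

#' @rdname benchmark_callers
#' @param object A `sweep_curve`.
#' @param ... Unused.
#' @method autoplot sweep_curve
#' @export
autoplot.sweep_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("fc_level", "method", "sensitivity", "fdr")],
    cols = c("sensitivity", "fdr"), names_to = "metric"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$fc_level, y = .data$value, colour = .data$method
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::labs(
      x = "95% minimum fold change (log2)", y = NULL,
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
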