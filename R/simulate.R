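#' Empirical distribution of the true microarray signal
#'
#' Builds a 500-bin histogram of variance-stabilized intensities, used as the
#' empirical distribution of the true signal \eqn{u} (on the VST scale) from
#' which simulated genes are drawn. Per-gene values are averaged across
#' replicates first, which approximately cancels the replicate-level error
#' terms.
#'
#' @param g_values Numeric vector of VST-scale values, or a gene-by-sample
#'   matrix (rows are averaged).
#' @param n_bins Number of equal-width bins (default 500).
#' @return An `empirical_signal` object with `bin_edges` (length
#'   `n_bins + 1`) and `bin_freq` (normalized to sum to 1). Constant input
#'   yields a flagged single-point distribution.
#' @export
build_empirical_u <- function(g_values, n_bins = 500) {
  if (is.matrix(g_values)) g_values <- rowMeans(g_values)
  g_values <- as.numeric(g_values)
  if (length(g_values) == 0L || any(!is.finite(g_values))) {
    abort("`g_values` must be nonempty and finite.")
  }
  single_point <- FALSE
  lo <- min(g_values)
  hi <- max(g_values)
  if (lo == hi) {
    single_point <- TRUE
    lo <- lo - 0.5
    hi <- hi + 0.5
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(pmax(findInterval(g_values, edges, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins
  )
  structure(
    list(bin_edges = edges, bin_freq = counts / sum(counts)),
    class = "empirical_signal", single_point = single_point
  )
}

# Parametric construction of an empirical_signal from a density function,
# used by default_parametric_model(); deterministic (no sampling).
empirical_from_density <- function(density_fun, lo, hi, n_bins = 500) {
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  freq <- density_fun(mids)
  structure(
    list(bin_edges = edges, bin_freq = freq / sum(freq)),
    class = "empirical_signal", single_point = FALSE
  )
}

#' @export
print.empirical_signal <- function(x, ...) {
  cat(sprintf(
    "Empirical signal distribution: %d bins on [%.3f, %.3f]%s\n",
    length(x$bin_freq), min(x$bin_edges), max(x$bin_edges),
    if (isTRUE(attr(x, "single_point"))) " (single point)" else ""
  ))
  invisible(x)
}

# Quantile function of the binned empirical distribution with linear
# interpolation inside each bin: for a uniform quantile the interpolation is
# exactly "bin value + uniform turbulence over the bin width", and it is
# monotone in the quantile, which is what makes cross-platform quantile
# coupling rank-exact.
empirical_quantile <- function(emp, u) {
  cum <- c(0, cumsum(emp$bin_freq))
  cum[length(cum)] <- 1 # guard rounding
  k <- findInterval(u, cum, rightmost.closed = TRUE)
  k <- pmin(pmax(k, 1L), length(emp$bin_freq))
  width <- diff(emp$bin_edges)
  frac <- ifelse(emp$bin_freq[k] > 0, (u - cum[k]) / emp$bin_freq[k], 0)
  emp$bin_edges[k] + pmin(pmax(frac, 0), 1) * width[k]
}

#' Negative-binomial count model parameters
#'
#' The RNA-Seq side of the simulator draws each gene's mean expression
#' \eqn{\lambda} from a gamma distribution (then linearly rescaled into
#' `lambda_range`, mimicking calibration to a real dataset's range) and its
#' over-dispersion \eqn{\varphi} from a second gamma distribution; counts are
#' negative binomial with variance \eqn{m + \varphi m^2}.
#'
#' The defaults are documented fixture values chosen to give a realistic
#' dynamic range (means from 1 to 3e5, mild over-dispersion around 0.1); they
#' are not estimates from any particular dataset.
#'
#' @param lambda_shape,lambda_scale Gamma parameters for the mean.
#' @param lambda_range Numeric `(lo, hi)`: range the sampled means are
#'   linearly rescaled into.
#' @param phi_shape,phi_scale Gamma parameters for the over-dispersion.
#' @return An `nb_params` object.
#' @export
nb_params <- function(lambda_shape = 0.7, lambda_scale = 500,
                      lambda_range = c(1, 3e5),
                      phi_shape = 1.2, phi_scale = 0.08) {
  for (nm in c("lambda_shape", "lambda_scale", "phi_shape", "phi_scale")) {
    check_scalar_number(get(nm), nm, positive = TRUE)
  }
  if (length(lambda_range) != 2L || lambda_range[1] >= lambda_range[2]) {
    abort("`lambda_range` must be (lo, hi) with lo < hi.")
  }
  structure(
    list(
      lambda_shape = lambda_shape, lambda_scale = lambda_scale,
      lambda_range = as.numeric(lambda_range),
      phi_shape = phi_shape, phi_scale = phi_scale
    ),
    class = "nb_params"
  )
}

#' Specification of preset differentially expressed genes
#'
#' Out of `n_genes` simulated genes, `n_deg` are preset as differentially
#' expressed with signed log2 fold changes drawn from a two-component mixture
#' of \eqn{\pm|N(\mu, \sigma)|}: up-regulated with probability `p_up`, and
#' the magnitude calibrated by the *95% minimum fold change* rule —
#' \eqn{\mu = } `fc_level_log2` \eqn{+ z_{0.95}\sigma}, so that 95% of the
#' preset genes have \eqn{|log_2 FC|} above the stated level.
#'
#' @param n_genes Total genes (default 10000).
#' @param n_deg Preset differentially expressed genes (default 1000).
#' @param fc_level_log2 The 95% minimum fold-change level, log2 units
#'   (default 2).
#' @param sigma_logfc Spread of the log2 fold-change magnitude (default
#'   0.25).
#' @param p_up Probability of up-regulation (default 0.5).
#' @return A `deg_spec` object.
#' @export
deg_spec <- function(n_genes = 10000, n_deg = 1000, fc_level_log2 = 2,
                     sigma_logfc = 0.25, p_up = 0.5) {
  stopifnot(n_genes >= 1, n_deg >= 0, n_deg <= n_genes)
  check_scalar_number(fc_level_log2, "fc_level_log2", positive = TRUE)
  if (sigma_logfc < 0) abort("`sigma_logfc` must be >= 0.")
  if (p_up <= 0 || p_up >= 1) abort("`p_up` must be in (0, 1).")
  structure(
    list(
      n_genes = as.integer(n_genes), n_deg = as.integer(n_deg),
      fc_level_log2 = fc_level_log2, sigma_logfc = sigma_logfc, p_up = p_up
    ),
    class = "deg_spec"
  )
}

#' Sample quantile-coupled true signals for both platforms
#'
#' One uniform quantile is drawn per gene and mapped through both inverse
#' CDFs: the empirical VST-scale signal distribution for the microarray side
#' (with uniform within-bin turbulence, via interpolation) and the gamma
#' distribution for the RNA-Seq mean (then linearly rescaled into
#' `nb$lambda_range`). Sharing the quantile makes the two true-signal
#' vectors rank-identical, i.e. their Spearman correlation is exactly 1.
#'
#' @param emp An [build_empirical_u()] distribution.
#' @param nb An [nb_params()] object.
#' @param n_genes Number of genes to draw.
#' @param seed Optional integer seed.
#' @return Tibble with `g_true` (microarray, VST scale), `lambda_gamma`
#'   (the raw gamma quantile, before rescaling) and `lambda_true` (RNA-Seq
#'   mean, rescaled).
#' @export
sample_coupled_signals <- function(emp, nb, n_genes, seed = NULL) {
  stopifnot(inherits(emp, "empirical_signal"), inherits(nb, "nb_params"))
  with_seed(seed, {
    u <- stats::runif(n_genes)
    g <- empirical_quantile(emp, u)
    q <- stats::qgamma(u, shape = nb$lambda_shape, scale = nb$lambda_scale)
    rng <- range(q)
    lambda <- if (n_genes > 1L && diff(rng) > 0) {
      nb$lambda_range[1] +
        (q - rng[1]) / diff(rng) * diff(nb$lambda_range)
    } else {
      rep(nb$lambda_range[1], n_genes)
    }
    tibble::tibble(g_true = g, lambda_gamma = q, lambda_true = lambda)
  })
}

#' Preset the truth table of differentially expressed genes
#'
#' Selects `spec$n_deg` genes uniformly without replacement and assigns them
#' signed log2 fold changes per the 95% minimum fold change rule (see
#' [deg_spec()]); magnitudes are truncated at zero (redrawn), signs are up
#' with probability `p_up`. All other genes get log2 fold change 0.
#'
#' @param spec A [deg_spec()].
#' @param seed Optional integer seed.
#' @return Truth tibble with `gene_id`, `is_deg`, `log2_fc`.
#' @export
preset_degs <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "deg_spec"))
  with_seed(seed, {
    ids <- sim_gene_ids(spec$n_genes)
    log2_fc <- rep(0, spec$n_genes)
    is_deg <- rep(FALSE, spec$n_genes)
    if (spec$n_deg > 0) {
      pick <- sample.int(spec$n_genes, spec$n_deg)
      is_deg[pick] <- TRUE
      mu <- spec$fc_level_log2 + stats::qnorm(0.95) * spec$sigma_logfc
      mag <- if (spec$sigma_logfc == 0) {
        rep(spec$fc_level_log2, spec$n_deg)
      } else {
        m <- stats::rnorm(spec$n_deg, mu, spec$sigma_logfc)
        while (any(m <= 0)) {
          m[m <= 0] <- stats::rnorm(sum(m <= 0), mu, spec$sigma_logfc)
        }
        m
      }
      sign <- ifelse(stats::runif(spec$n_deg) < spec$p_up, 1, -1)
      log2_fc[pick] <- sign * mag
    }
    tibble::tibble(gene_id = ids, is_deg = is_deg, log2_fc = log2_fc)
  })
}

sim_gene_ids <- function(n) {
  sprintf(paste0("g%0", max(nchar(as.character(n)), 1L), "d"), seq_len(n))
}

#' Simulate a paired microarray/RNA-Seq dataset with known truth
#'
#' Generates one coupled dataset: per gene, a shared quantile draws the true
#' microarray signal (VST scale) and the true RNA-Seq mean
#' ([sample_coupled_signals()]); preset fold changes ([preset_degs()]) are
#' applied to the treatment group — multiplicatively on the RNA-Seq mean
#' (\eqn{\lambda 2^{FC}}) and as `log2_fc * ln(2)` on the VST scale (a
#' multiplicative change of the true intensity, since the VST is
#' logarithmic at high signal). Observed data are then
#' * RNA-Seq: counts \eqn{\sim NB(m, m + \varphi_i m^2)} with per-gene
#'   \eqn{\varphi_i \sim} Gamma(`phi_shape`, `phi_scale`);
#' * microarray: raw intensities
#'   \eqn{y = \alpha_{bg} + u e^{\eta} + \epsilon} with \eqn{u} the
#'   inverse-VST of the group-level signal and fresh \eqn{\eta, \epsilon} per
#'   replicate.
#'
#' All randomness derives from `seed` through fixed per-operation
#' sub-streams, so the same seed is bit-reproducible and changing `n_reps`
#' does not perturb the gene-level draws.
#'
#' @param emp,noise,nb Model components (see [build_empirical_u()],
#'   [noise_model()], [nb_params()]); defaults from
#'   [default_parametric_model()].
#' @param deg A [deg_spec()].
#' @param n_reps Replicates per group (default 5).
#' @param seed Master integer seed.
#' @return A `sim_paired` object: integer `counts` and real `intensities`
#'   matrices (columns `ctl_*`, `trt_*`), the `truth` tibble, the `groups`
#'   assignment, the per-gene dispersions `phi` and a `provenance` list.
#' @export
simulate_dataset <- function(emp = NULL, noise = NULL, nb = NULL,
                             deg = deg_spec(), n_reps = 5, seed = NULL) {
  if (is.null(emp) || is.null(noise) || is.null(nb)) {
    defaults <- default_parametric_model()
    emp <- emp %||% defaults$emp
    noise <- noise %||% defaults$noise
    nb <- nb %||% defaults$nb
  }
  stopifnot(inherits(deg, "deg_spec"), n_reps >= 1)
  n <- deg$n_genes
  signals <- sample_coupled_signals(emp, nb, n, seed = derive_seed(seed %||% 0, 1L))
  truth <- preset_degs(deg, seed = derive_seed(seed %||% 0, 2L))
  phi <- with_seed(derive_seed(seed %||% 0, 3L), {
    pmax(stats::rgamma(n, shape = nb$phi_shape, scale = nb$phi_scale), 1e-8)
  })

  fc_lin <- 2^truth$log2_fc
  mu_ctl <- signals$lambda_true
  mu_trt <- pmin(mu_ctl * fc_lin, 1e9) # overflow guard for extreme draws
  counts <- with_seed(derive_seed(seed %||% 0, 4L), {
    draw <- function(mu) {
      matrix(
        stats::rnbinom(n * n_reps, mu = rep(mu, n_reps), size = rep(1 / phi, n_reps)),
        nrow = n
      )
    }
    cbind(draw(mu_ctl), draw(mu_trt))
  })

  g_ctl <- signals$g_true
  g_trt <- signals$g_true + truth$log2_fc * log(2)
  intensities <- with_seed(derive_seed(seed %||% 0, 5L), {
    draw <- function(g) {
      u <- inverse_vst(g, noise$c)
      eta <- matrix(stats::rnorm(n * n_reps, 0, noise$sd_eta), nrow = n)
      eps <- matrix(stats::rnorm(n * n_reps, 0, noise$sd_eps), nrow = n)
      noise$alpha_bg + u * exp(eta) + eps
    }
    cbind(draw(g_ctl), draw(g_trt))
  })

  sample_names <- c(paste0("ctl_", seq_len(n_reps)), paste0("trt_", seq_len(n_reps)))
  dimnames(counts) <- dimnames(intensities) <- list(truth$gene_id, sample_names)
  storage.mode(counts) <- "integer"
  groups <- setNames(rep(c("control", "treatment"), each = n_reps), sample_names)
  structure(
    list(
      counts = counts, intensities = intensities, truth = truth,
      groups = groups, phi = setNames(phi, truth$gene_id),
      provenance = list(
        seed = seed, n_reps = n_reps, deg = unclass(deg),
        noise = unclass(noise), nb = unclass(nb),
        emp_range = range(emp$bin_edges), emp_bins = length(emp$bin_freq)
      )
    ),
    class = "sim_paired"
  )
}

#' @export
print.sim_paired <- function(x, ...) {
  cat(sprintf(
    "Simulated paired dataset: %d genes, %d+%d samples, %d preset DEGs\n",
    nrow(x$counts), sum(x$groups == "control"), sum(x$groups == "treatment"),
    sum(x$truth$is_deg)
  ))
  invisible(x)
}

#' Default parametric simulation model
#'
#' A self-contained parameter set so the full simulation pipeline runs with
#' no external data: a deterministic 500-bin truncated-normal signal
#' distribution on the VST scale (location 6, spread 1.7, support chosen so
#' every true intensity is non-negative), the default two-component error
#' model (`alpha_bg` 50, `sd_eps` 10, `sd_eta` 0.25) and the default
#' negative-binomial parameters. These are documented fixture values, not
#' estimates from any dataset.
#'
#' @return List with components `emp`, `noise`, `nb`.
#' @export
default_parametric_model <- function() {
  noise <- noise_model(alpha_bg = 50, sd_eps = 10, sd_eta = 0.25)
  # support starts just above vst(alpha_bg) = log(sqrt(c)), where u = 0
  lo <- log(sqrt(noise$c)) + 0.05
  emp <- empirical_from_density(
    function(x) stats::dnorm(x, mean = 6, sd = 1.7),
    lo = lo, hi = 12.4
  )
  list(emp = emp, noise = noise, nb = nb_params())
}

#' Write and read a simulated dataset as plain text
#'
#' Serializes the count table, intensity table and truth table as TSV plus a
#' provenance JSON; `read_sim_dataset()` restores the object.
#'
#' @param sim A `sim_paired` object.
#' @param dir Output directory (created if missing).
#' @return `write_sim_dataset()`: `dir`, invisibly; `read_sim_dataset()`:
#'   a `sim_paired` object.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_paired"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mat <- function(m, path) {
    readr::write_tsv(
      tibble::as_tibble(m, rownames = "gene_id"), path,
      progress = FALSE
    )
  }
  write_mat(sim$counts, file.path(dir, "counts.tsv"))
  write_mat(sim$intensities, file.path(dir, "intensities.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  jsonlite::write_json(
    c(sim$provenance, list(groups = as.list(sim$groups))),
    file.path(dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname write_sim_dataset
#' @export
read_sim_dataset <- function(dir) {
  read_mat <- function(path, mode) {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(tab[-1])
    rownames(m) <- tab$gene_id
    storage.mode(m) <- mode
    m
  }
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"), simplifyVector = TRUE)
  groups <- unlist(prov$groups)
  prov$groups <- NULL
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
  structure(
    list(
      counts = read_mat(file.path(dir, "counts.tsv"), "integer"),
      intensities = read_mat(file.path(dir, "intensities.tsv"), "double"),
      truth = truth, groups = groups, provenance = prov
    ),
    class = "sim_paired"
  )
}
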