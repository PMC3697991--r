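test_that("identical groups produce no calls at any FDR below 1", {
  withr::with_seed(4, {
    half <- matrix(2^rnorm(50 * 3, 8), nrow = 50)
    m <- cbind(half, half)
    colnames(m) <- c(paste0("c", 1:3), paste0("t", 1:3))
    rownames(m) <- paste0("g", 1:50)
    groups <- setNames(rep(c("ctl", "trt"), each = 3), colnames(m))
    res <- ttest_bh_caller(m, groups, input_scale = "intensity")
    expect_true(all(res$p == 1))
    expect_length(called_set(apply_thresholds(res, fdr = 0.99)), 0L)
  })
})

test_that("strong shifts are called and nulls survive BH", {
  withr::with_seed(88, {
    n_null <- 100
    n_sig <- 10
    reps <- 5
    base <- matrix(rnorm((n_null + n_sig) * 2 * reps, mean = 8, sd = 0.5),
      nrow = n_null + n_sig
    )
    shifted <- seq_len(n_sig) + n_null
    base[shifted, (reps + 1):(2 * reps)] <-
      base[shifted, (reps + 1):(2 * reps)] + 8 * 0.5
    colnames(base) <- c(paste0("c", 1:reps), paste0("t", 1:reps))
    rownames(base) <- paste0("g", seq_len(n_null + n_sig))
    groups <- setNames(rep(c("ctl", "trt"), each = reps), colnames(base))
    res <- apply_thresholds(
      ttest_bh_caller(base, groups, input_scale = "log2"),
      fc = 2, fdr = 0.05
    )
    expect_setequal(called_set(res), paste0("g", shifted))
    expect_true(all(res$fdr[seq_len(n_null)] >= 0.05))
  })
})

test_that("adjusted significance follows the BH step-up rule", {
  # craft log2 data whose Welch p-values are then BH-adjusted; verify the
  # caller's fdr column against a by-hand step-up computation of its own p
  withr::with_seed(10, {
    m <- matrix(rnorm(40 * 8, 6, 1), nrow = 40)
    m[1:5, 5:8] <- m[1:5, 5:8] + 3
    colnames(m) <- c(paste0("c", 1:4), paste0("t", 1:4))
    rownames(m) <- paste0("g", 1:40)
    groups <- setNames(rep(c("a", "b"), each = 4), colnames(m))
    res <- ttest_bh_caller(m, groups, input_scale = "log2")
    p <- res$p
    n <- length(p)
    ord <- order(p)
    stepup <- rev(cummin(rev(p[ord] * n / seq_len(n))))
    expect_equal(res$fdr[ord], pmin(stepup, 1), tolerance = 1e-12)
  })
})

test_that("fold-change thresholding is strict and FDR inclusive", {
  r <- crossplat:::new_deg_result(
    tibble::tibble(
      gene_id = paste0("g", 1:5),
      fc = c(2.0, 0.4, 3.0, 2.5, 0.5),
      direction = c("up", "down", "up", "up", "down"),
      p = rep(0.001, 5),
      fdr = c(0.01, 0.01, 0.06, 0.05, 0.05)
    ),
    method = "fixture"
  )
  out <- apply_thresholds(r, fc = 2, fdr = 0.05)
  # g1: FC exactly 2 -> excluded; g2: 0.4 in -> called; g3: q 0.06 -> out;
  # g4: 2.5 & 0.05 -> called; g5: FC exactly 0.5 -> excluded
  expect_setequal(called_set(out), c("g2", "g4"))
})

test_that("q-score semantics keep high-q genes", {
  r <- crossplat:::new_deg_result(
    tibble::tibble(
      gene_id = c("a", "b", "c"),
      fc = c(3, 3, 3), direction = "up", p = NA_real_,
      fdr = c(0.9, 0.7, 0.85)
    ),
    method = "noiseq_like", significance = "q", q_cutoff = 0.8
  )
  expect_setequal(called_set(apply_thresholds(r)), c("a", "c"))
})

test_that("metrics match a hand tally and follow the conventions", {
  truth <- tibble::tibble(
    gene_id = paste0("g", 1:10),
    is_deg = c(rep(TRUE, 4), rep(FALSE, 6))
  )
  # call g1, g2 (true), g5, g6 (false): tp 2 fp 2 fn 2 tn 4
  res <- evaluate_calls(c("g1", "g2", "g5", "g6"), truth)
  expect_equal(res[c("tp", "fp", "tn", "fn")], tibble::tibble(tp = 2L, fp = 2L, tn = 4L, fn = 2L))
  expect_equal(res$sensitivity, 0.5)
  expect_equal(res$fdr, 0.5)
  expect_equal(res$specificity, 4 / 6)

  empty <- evaluate_calls(character(0), truth)
  expect_equal(empty$sensitivity, 0)
  expect_equal(empty$fdr, 0)
  expect_equal(empty$specificity, 1)

  expect_error(evaluate_calls(c("nope"), truth), "universe")
})

test_that("tightening thresholds never increases tp or fp", {
  withr::with_seed(14, {
    sim <- simulate_dataset(deg = deg_spec(n_genes = 1500, n_deg = 150), seed = 6)
    res <- ttest_bh_caller(sim$counts, sim$groups,
      treatment = "treatment",
      control = "control", input_scale = "counts"
    )
    grid <- expand.grid(fc = c(1.5, 2, 3), fdr = c(0.01, 0.05, 0.2))
    metrics <- purrr::pmap_dfr(grid, function(fc, fdr) {
      cbind(grid_fc = fc, grid_fdr = fdr,
        evaluate_calls(apply_thresholds(res, fc, fdr), sim$truth))
    })
    for (fdr_fix in unique(grid$fdr)) {
      sub <- metrics[metrics$grid_fdr == fdr_fix, ]
      sub <- sub[order(sub$grid_fc), ]
      expect_true(all(diff(sub$tp) <= 0))
      expect_true(all(diff(sub$fp) <= 0))
    }
    for (fc_fix in unique(grid$fc)) {
      sub <- metrics[metrics$grid_fc == fc_fix, ]
      sub <- sub[order(sub$grid_fdr), ]
      expect_true(all(diff(sub$tp) >= 0))
      expect_true(all(diff(sub$fp) >= 0))
    }
  })
})

test_that("overlap matrices are symmetric with unit diagonal", {
  lists <- list(
    a = paste0("g", 1:80),
    b = paste0("g", 41:120),
    c = paste0("g", 200:210)
  )
  om <- overlap_matrix(lists)
  expect_equal(om["a", "b"], 40 / 120)
  expect_equal(om["a", "c"], 0)
  expect_equal(diag(om), c(a = 1, b = 1, c = 1))
  expect_equal(om, t(om))
})

test_that("the fold-change sweep produces per-level means with the right shape", {
  curve <- fc_sweep(
    fc_levels = c(0.5, 3),
    n_datasets = 2, n_genes = 800, n_deg = 80, seed = 3
  )
  expect_equal(nrow(curve), 2 * 2) # levels x callers
  expect_setequal(unique(curve$method), c("ttest_rnaseq", "ttest_microarray"))
  expect_true(all(curve$n_datasets == 2))

  # sensitivity separates the easy from the hard regime for both callers
  for (m in unique(curve$method)) {
    sub <- curve[curve$method == m, ]
    expect_lt(sub$sensitivity[sub$fc_level == 0.5], sub$sensitivity[sub$fc_level == 3])
  }
  # at a high 95%-minimum level every preset change dwarfs the noise
  rna <- curve[curve$method == "ttest_rnaseq" & curve$fc_level == 3, ]
  expect_gt(rna$sensitivity, 0.9)
})

test_that("external callers are wrapped, parsed and fail loudly but safely", {
  dir <- withr::local_tempdir()
  script <- file.path(dir, "fake_deg.sh")
  writeLines(c(
    "#!/bin/sh",
    "printf 'gene_id\\tfc\\tfdr\\ng1\\t3.5\\t0.01\\ng2\\t0.2\\t0.20\\ng3\\t1.1\\t0.90\\n' > \"$1\""
  ), script)
  Sys.chmod(script, "0755")
  m <- matrix(1:12, nrow = 3, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  groups <- setNames(rep(c("a", "b"), each = 2), colnames(m))
  res <- external_deg_caller(
    paste("sh", script, "{output}"), m, groups,
    method_name = "fixture"
  )
  expect_s3_class(res, "deg_result")
  expect_equal(res$fc, c(3.5, 0.2, 1.1))
  expect_setequal(called_set(apply_thresholds(res)), "g1")

  expect_error(
    external_deg_caller("definitely_not_a_binary_xyz {output}", m, groups),
    class = "crossplat_adapter_error"
  )

  # a failing caller is recorded and the benchmark continues
  sim <- simulate_dataset(deg = deg_spec(n_genes = 200, n_deg = 20), seed = 2)
  callers <- list(
    ok = default_callers()$ttest_rnaseq,
    broken = function(sim) stop("boom")
  )
  expect_warning(
    out <- benchmark_callers(
      deg = deg_spec(n_genes = 200, n_deg = 20),
      callers = callers, n_datasets = 1, seed = 5
    ),
    "broken"
  )
  expect_equal(unique(out$method), "ok")
})

test_that("exported simulated tables round-trip through the adapter contract", {
  sim <- simulate_dataset(deg = deg_spec(n_genes = 150, n_deg = 10), seed = 44)
  dir <- withr::local_tempdir()
  script <- file.path(dir, "echo_input.sh")
  # caller that copies its input table back out with constant stats; the
  # round-trip checks the exported values are preserved
  writeLines(c(
    "#!/bin/sh",
    "awk 'BEGIN{FS=OFS=\"\\t\"} NR==1{print \"gene_id\",\"fc\",\"fdr\"; next} {print $1, $2, 0.5}' \"$1\" > \"$2\""
  ), script)
  Sys.chmod(script, "0755")
  res <- external_deg_caller(
    paste("sh", script, "{input}", "{output}"),
    sim$counts, sim$groups,
    method_name = "echo"
  )
  expect_equal(res$gene_id, rownames(sim$counts))
  expect_equal(res$fc, unname(sim$counts[, 1]), tolerance = 1e-9)
})
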