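test_that("count filter keeps genes detectable in at least one group", {
  m <- make_count_table(list(
    low = c(0L, 3L, 9L, 0L, 3L, 9L), # below threshold everywhere
    edge = c(0L, 0L, 10L, 0L, 0L, 0L) # boundary max == threshold in group A
  ))
  f <- filter_rnaseq_counts(m, min_count = 10)
  rep <- filter_report(f)
  expect_equal(f$gene_id, "edge")
  expect_equal(rep$n_input, 2L)
  expect_equal(rep$n_retained, 1L)
  expect_equal(rep$detectable_per_group$A, "edge")
  expect_equal(rep$detectable_per_group$B, character(0))
})

test_that("count filter matches hand enumeration on a 5-gene table", {
  # genes 1,2 detectable in A only; 2,3 in B only; 4,5 nowhere
  m <- make_count_table(list(
    g1 = c(12L, 0L, 0L, 9L, 9L, 9L),
    g2 = c(10L, 10L, 10L, 10L, 0L, 0L),
    g3 = c(1L, 2L, 3L, 0L, 0L, 99L),
    g4 = c(0L, 0L, 0L, 0L, 0L, 0L),
    g5 = c(9L, 9L, 9L, 9L, 9L, 9L)
  ))
  f <- filter_rnaseq_counts(m, min_count = 10)
  rep <- filter_report(f)
  expect_equal(rep$n_retained, 3L)
  expect_setequal(rep$detectable_per_group$A, c("g1", "g2"))
  expect_setequal(rep$detectable_per_group$B, c("g2", "g3"))
  expect_setequal(f$gene_id, c("g1", "g2", "g3"))
})

test_that("filters are idempotent", {
  m <- make_count_table(list(
    g1 = c(12L, 0L, 0L, 9L, 9L, 9L),
    g2 = c(0L, 1L, 2L, 3L, 4L, 5L)
  ))
  once <- filter_rnaseq_counts(m, min_count = 10)
  twice <- filter_rnaseq_counts(once, min_count = 10)
  expect_equal(twice$gene_id, once$gene_id)
  expect_equal(expr_matrix(twice), expr_matrix(once))
})

test_that("count tables reject non-integer or negative values", {
  groups <- c(s1 = "A", s2 = "A")
  expect_error(
    expression_table(data.frame(gene_id = "g", s1 = 1.5, s2 = 2),
      platform = "rnaseq", scale = "counts", groups = groups
    ),
    "integer"
  )
  expect_error(
    expression_table(data.frame(gene_id = "g", s1 = -1, s2 = 2),
      platform = "rnaseq", scale = "counts", groups = groups
    ),
    "non-negative"
  )
})

test_that("presence filter requires all replicates of one group", {
  mat <- matrix(8, nrow = 4, ncol = 6,
    dimnames = list(paste0("g", 1:4), c("A1", "A2", "A3", "B1", "B2", "B3"))
  )
  m <- make_log2_table(mat)
  presence <- matrix(FALSE, 4, 6, dimnames = dimnames(mat))
  presence["g1", c("A1", "A2", "A3")] <- TRUE # all of A
  presence["g2", c("A1", "A2", "B1")] <- TRUE # 2 of 3 in A, 1 of 3 in B
  presence["g3", c("B1", "B2", "B3")] <- TRUE # all of B
  presence["g4", c("A1", "B2")] <- TRUE
  f <- filter_microarray_present(m, presence)
  rep <- filter_report(f)
  expect_equal(rep$n_retained, 2L)
  expect_setequal(f$gene_id, c("g1", "g3"))
  # a gene present everywhere is retained; default presence keeps everything
  f_all <- filter_microarray_present(m)
  expect_equal(filter_report(f_all)$n_retained, 4L)
  # misaligned presence table is an input error
  expect_error(filter_microarray_present(m, presence[1:3, ]), "aligned")
})

test_that("probe collapsing picks the argmax-by-mean probe per gene", {
  withr::with_seed(7, {
    genes <- rep(paste0("G", 1:3), times = c(1, 2, 3))
    probes <- paste0("p", seq_along(genes))
    mat <- matrix(round(runif(6 * 4, 1, 12), 2), nrow = 6,
      dimnames = list(probes, c("A1", "A2", "B1", "B2"))
    )
    m <- make_log2_table(mat)
    map <- data.frame(probe_id = probes, gene_id = genes)
    out <- collapse_probes(m, map)
    # brute-force oracle: per gene, the row with the highest mean
    expected <- vapply(split(probes, genes), function(p) {
      p[which.max(rowMeans(mat[p, , drop = FALSE]))]
    }, character(1))
    for (g in names(expected)) {
      expect_equal(
        unlist(out[out$gene_id == g, -1], use.names = FALSE),
        unname(mat[expected[[g]], ])
      )
    }
    expect_equal(out$gene_id, sort(names(expected)))
  })
})

test_that("probe collapsing breaks ties by smallest probe id and reports skips", {
  mat <- matrix(c(5, 5, 5, 5, 1, 2), nrow = 3, byrow = TRUE,
    dimnames = list(c("p2", "p1", "px"), c("A1", "B1"))
  )
  m <- expression_table(mat,
    platform = "microarray", scale = "log2",
    groups = c(A1 = "A", B1 = "B")
  )
  out <- collapse_probes(m, data.frame(probe_id = c("p1", "p2"), gene_id = "G"))
  expect_equal(attr(out, "representative_probe")[["G"]], "p1")
  expect_equal(attr(out, "skipped_probes"), "px")
  expect_equal(nrow(out), 1L)
})

test_that("log2 FPKM transform applies log2(x + 1)", {
  m <- expression_table(
    data.frame(gene_id = c("a", "b", "c"), s1 = c(0, 1, 7), s2 = c(7, 0, 1)),
    platform = "rnaseq", scale = "fpkm", groups = c(s1 = "A", s2 = "A")
  )
  out <- log2_fpkm(m)
  expect_equal(out$s1, c(0, 1, 3))
  expect_equal(out$s2, c(3, 0, 1))
  expect_equal(expr_scale(out), "log2")
})

test_that("housekeeping normalization divides or subtracts and round-trips", {
  mat <- matrix(c(8, 6, 4, 2, 10, 5), nrow = 3, byrow = TRUE,
    dimnames = list(c("g1", "g2", "hk"), c("A1", "B1"))
  )
  m <- expression_table(mat,
    platform = "microarray", scale = "log2",
    groups = c(A1 = "A", B1 = "B")
  )
  div <- normalize_housekeeping(m, gene = "hk", mode = "divide")
  expect_equal(unlist(div[div$gene_id == "hk", -1], use.names = FALSE), c(1, 1))
  expect_equal(div$A1[div$gene_id == "g1"], 8 / 10)
  sub <- normalize_housekeeping(m, gene = "hk", mode = "subtract")
  expect_equal(unlist(sub[sub$gene_id == "hk", -1], use.names = FALSE), c(0, 0))
  expect_equal(sub$A1[sub$gene_id == "g1"], 8 - 10)

  # un-normalizing restores the input to within 1e-12
  ref <- attr(div, "normalization")$reference
  back <- sweep(expr_matrix(div), 2L, ref, "*")
  expect_equal(back, expr_matrix(m), tolerance = 1e-12)
  back_sub <- sweep(expr_matrix(sub), 2L, ref, "+")
  expect_equal(back_sub, expr_matrix(m), tolerance = 1e-12)

  # zero housekeeping log2 value in divide mode names the sample
  mat0 <- mat
  mat0["hk", "B1"] <- 0
  m0 <- expression_table(mat0,
    platform = "microarray", scale = "log2",
    groups = c(A1 = "A", B1 = "B")
  )
  expect_error(normalize_housekeeping(m0, gene = "hk", mode = "divide"), "B1")
  expect_error(normalize_housekeeping(m, gene = "nope"), "not found")
})

test_that("delimited and HTSeq-style readers round-trip tables", {
  dir <- withr::local_tempdir()
  m <- make_count_table(list(g1 = c(1L, 2L, 3L, 4L, 5L, 6L), g2 = rep(0L, 6)))
  path <- file.path(dir, "counts.tsv")
  write_expression_table(m, path)
  back <- read_expression_table(path,
    platform = "rnaseq", scale = "counts",
    groups = expr_groups(m)
  )
  expect_equal(as.data.frame(back), as.data.frame(m))

  # two-column per-sample files with trailing summary rows
  f1 <- file.path(dir, "s1.tsv")
  f2 <- file.path(dir, "s2.tsv")
  writeLines(c("g1\t5", "g2\t0", "__no_feature\t100"), f1)
  writeLines(c("g1\t7", "g2\t2", "__ambiguous\t3"), f2)
  merged <- read_htseq_counts(c(f1, f2), c("s1", "s2"),
    groups = c(s1 = "A", s2 = "A")
  )
  expect_equal(merged$gene_id, c("g1", "g2"))
  expect_equal(merged$s1, c(5, 0))
  expect_equal(merged$s2, c(7, 2))
})
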