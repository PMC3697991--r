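# Shared fixture builders and independent oracles for the test suite.

# Small count table: 2 groups x 3 replicates, values passed per gene as a
# named list of length-6 integer vectors (A1 A2 A3 B1 B2 B3).
make_count_table <- function(rows) {
  df <- data.frame(gene_id = names(rows), do.call(rbind, rows))
  names(df)[-1] <- c("A1", "A2", "A3", "B1", "B2", "B3")
  expression_table(
    df,
    platform = "rnaseq", scale = "counts",
    groups = c(
      A1 = "A", A2 = "A", A3 = "A",
      B1 = "B", B2 = "B", B3 = "B"
    )
  )
}

make_log2_table <- function(mat, platform = "microarray") {
  groups <- setNames(
    rep(c("A", "B"), each = ncol(mat) / 2),
    colnames(mat)
  )
  expression_table(mat, platform = platform, scale = "log2", groups = groups)
}

# Independent closed-form Deming oracle (kept out of the package code path):
# beta = [S_yy - lambda S_xx + sqrt((S_yy - lambda S_xx)^2 + 4 lambda S_xy^2)]
#        / (2 S_xy), alpha = ybar - beta xbar.
deming_closed_form <- function(x, y, lambda) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  s_xx <- sum(xc^2)
  s_yy <- sum(yc^2)
  s_xy <- sum(xc * yc)
  beta <- (s_yy - lambda * s_xx +
    sqrt((s_yy - lambda * s_xx)^2 + 4 * lambda * s_xy^2)) / (2 * s_xy)
  c(alpha = mean(y) - beta * mean(x), beta = beta)
}
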