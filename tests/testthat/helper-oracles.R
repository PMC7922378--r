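# Independent oracles and small fixture builders used across the suite.

# Term-by-term double-loop sum of within-cluster sample variances; the
# brute-force counterpart of global_variance().
brute_var_global <- function(mat, labels) {
  total <- 0
  for (g in sort(unique(labels))) {
    sub <- mat[labels == g, , drop = FALSE]
    for (j in seq_len(ncol(mat))) total <- total + stats::var(sub[, j])
  }
  total
}

# Exhaustive minimum of var_global over all assignments of n cases into
# n_groups labeled groups with every group >= min_size. Feasible for n <= 9.
best_partition_var <- function(mat, n_groups = 3L, min_size = 3L) {
  n <- nrow(mat)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n_groups)), n)))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    lab <- grid[i, ]
    if (any(tabulate(lab, n_groups) < min_size)) next
    v <- brute_var_global(mat, lab)
    if (v < best) best <- v
  }
  best
}

# TRUE when two label vectors induce the same partition (up to relabeling).
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# Every cluster of the finer labeling lies inside one coarse cluster.
refines <- function(fine, coarse) {
  all(tapply(coarse, fine, function(v) length(unique(v))) == 1L)
}

# Three tight 3-point groups in 3-D at pairwise center separation `sep`.
planted_nine <- function(sep = 6, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(sep, 0, 0), c(0, sep, 0), c(0, 0, sep))
  mat <- centers[rep(1:3, each = 3L), ] +
    matrix(rnorm(27, 0, sd), 9L, 3L)
  colnames(mat) <- c("a", "b", "c")
  mat
}

# Write a small table to a temp CSV and return the path.
write_fixture_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# A cluster of 3 values with exact mean m and exact sample SD s.
triple_with <- function(m, s) c(m - s, m, m + s)
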