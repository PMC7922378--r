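test_that("combination enumeration counts and order are exact", {
  c4 <- enumerate_combos(c("d", "b", "a", "c"), 3)
  expect_identical(ncol(c4), 4L)
  expect_identical(c4[, 1], c("a", "b", "c"))  # lexicographic

  c30 <- enumerate_combos(sprintf("v%02d", 1:30), 3)
  expect_identical(ncol(c30), 4060L)            # choose(30, 3)
  expect_equal(attr(c30, "n_ordered"), 24360)   # 30 * 29 * 28

  expect_identical(ncol(enumerate_combos(sprintf("v%02d", 1:26), 3)), 2600L)
  expect_identical(ncol(enumerate_combos(letters[1:5], 2)), 10L)
  expect_error(enumerate_combos(letters[1:2], 3), "exceeds")
})

test_that("complete-case selection picks exactly the fully observed cases", {
  vals <- matrix(1, 6, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
  vals <- vals * rnorm(24)
  vals[2, "A"] <- NA
  vals[5, "C"] <- NA
  tab <- clinical_table(vals)
  expect_identical(select_complete_cases(tab, c("A", "B", "C")),
                   c(1L, 3L, 4L, 6L))
  expect_identical(select_complete_cases(tab, c("B", "D")), 1:6)
  expect_error(select_complete_cases(tab, c("A", "nope")), "nope")
})

test_that("well-separated point clouds are recovered by every linkage", {
  set.seed(3)
  centers <- rbind(c(0, 0), c(20, 0), c(0, 20))
  mat <- centers[rep(1:3, each = 5), ] + matrix(rnorm(30), 15, 2)
  truth <- rep(1:3, each = 5)
  for (lk in c("centroid", "ward", "average", "lloyd_kmeans")) {
    lab <- cluster_cases(mat, search_config(linkage = lk, seed = 9))
    expect_true(same_partition(lab, truth), info = lk)
  }
})

test_that("too few cases signal unclusterable rather than erroring", {
  lab <- cluster_cases(matrix(rnorm(4), 2, 2), search_config())
  expect_true(is_unclusterable(lab))
  expect_match(lab$reason, "fewer cases")
})

test_that("centroid labels attain the exhaustive-minimum global variance", {
  # 9 points, 3 planted groups at 6 sigma: the agglomerative cut must find
  # the same partition as brute-force minimization over all valid 3-partitions
  for (seed in c(1, 2, 3)) {
    mat <- planted_nine(sep = 6, seed = seed)
    lab <- cluster_cases(mat, search_config())
    expect_true(same_partition(lab, rep(1:3, each = 3)), info = seed)
    gv <- global_variance(mat, lab)$var_global
    expect_equal(gv, best_partition_var(mat), tolerance = 1e-10)
  }
})

test_that("validity requires every cluster to reach the minimum size", {
  expect_false(check_validity(rep(1:3, times = c(1, 4, 4))))
  expect_false(check_validity(rep(1:3, times = c(2, 3, 4))))
  expect_true(check_validity(rep(1:3, times = c(3, 3, 3))))
  # a missing cluster counts as size zero
  expect_false(check_validity(rep(1:2, each = 5), n_clusters = 3))
  expect_true(check_validity(rep(1:3, times = c(1, 4, 4)),
                             min_cluster_size = 1))
})

test_that("global variance equals the double-loop oracle", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(9:15, 1)
    mat <- matrix(rnorm(3 * n), n, 3)
    labels <- sample(rep(1:3, length.out = n))
    while (any(tabulate(labels, 3) < 2))
      labels <- sample(rep(1:3, length.out = n))
    gv <- global_variance(mat, labels, 3)
    expect_equal(gv$var_global, brute_var_global(mat, labels),
                 tolerance = 1e-10)
    expect_equal(gv$var_global, sum(gv$var_matrix))
    expect_true(all(gv$var_matrix >= 0))
    expect_identical(dim(gv$var_matrix), c(3L, 3L))  # nine terms
  }
})

test_that("global variance is zero iff descriptors are constant in-cluster", {
  mat <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1), c(1, 1, 1),
               c(2, 2, 2), c(2, 2, 2))
  gv <- global_variance(mat, rep(1:3, each = 2))
  expect_identical(gv$var_global, 0)
  expect_error(global_variance(mat, c(1, 1, 1, 1, 1, 2)), ">= 2 members")
})

test_that("global variance ignores case order and cluster relabeling", {
  set.seed(5)
  mat <- matrix(rnorm(36), 12, 3)
  labels <- rep(1:3, each = 4)
  base <- global_variance(mat, labels)$var_global
  perm <- sample(12)
  expect_equal(global_variance(mat[perm, ], labels[perm])$var_global, base,
               tolerance = 1e-12)
  relab <- c(3L, 1L, 2L)[labels]
  expect_equal(global_variance(mat, relab)$var_global, base,
               tolerance = 1e-12)
})

test_that("ranking sorts ascending with lexicographic tie-break", {
  scores <- data.frame(
    combo = c("A+B+D", "A+B+C", "A+C+D", "B+C+D"),
    var_global = c(0.5, 0.5, 0.9, NA),
    n_used = 9L, valid = c(TRUE, TRUE, TRUE, FALSE))
  res <- rank_combos(scores, n_enumerated = 4L)
  expect_identical(res$ranked$combo, c("A+B+C", "A+B+D", "A+C+D"))
  expect_identical(res$n_combos_valid, 3L)
})

test_that("an empty valid set is reported, not silent", {
  scores <- data.frame(combo = "A+B+C", var_global = NA_real_,
                       n_used = 4L, valid = FALSE)
  expect_warning(res <- rank_combos(scores), "no valid clustering")
  expect_identical(nrow(res$ranked), 0L)
})

test_that("run_search composes the full pipeline on a small fixture", {
  set.seed(8)
  vals <- cbind(planted_nine(sep = 8, seed = 8),
                d = rnorm(9, 0, 1))
  tab <- clinical_table(vals)
  res <- run_search(tab)
  expect_identical(res$n_combos_enumerated, 4L)  # choose(4, 3)
  expect_identical(res$n_combos_valid + res$n_combos_invalid +
                     res$n_combos_skipped, 4L)
  expect_identical(res$ranked$combo[1], "a+b+c")
  out <- combo_outcome(tab, c("a", "b", "c"))
  expect_equal(out$var_global, res$ranked$var_global[1], tolerance = 1e-12)
  expect_equal(sum(out$per_cluster_variance), out$var_global)
  expect_true(out$valid)
})

test_that("combos with too few complete cases are skipped and counted", {
  set.seed(9)
  vals <- matrix(rnorm(15 * 4), 15, 4,
                 dimnames = list(NULL, c("a", "b", "c", "d")))
  vals[6:15, "d"] <- NA  # only 5 complete cases for any combo with d
  tab <- clinical_table(vals)
  res <- suppressWarnings(run_search(tab))
  expect_identical(unname(res$skip_reasons["too_few_cases"]), 3L)
  expect_false(any(grepl("d", res$ranked$combo)))
})

test_that("search scores are invariant to positive raw-column rescaling", {
  spec <- test_matrix_spec(p = 4, cases_per_group = 5, n_descriptors = 6,
                           seed = 31)
  tab <- generate_test_matrix(spec)
  res1 <- run_search(tab)
  vals <- tab$values
  vals[, "Y"] <- vals[, "Y"] * 1000
  vals[, "N02"] <- vals[, "N02"] * 0.003
  res2 <- run_search(clinical_table(vals))
  expect_identical(res1$ranked$combo, res2$ranked$combo)
  expect_equal(res1$ranked$var_global, res2$ranked$var_global,
               tolerance = 1e-9)
})

test_that("search ranking is invariant to case order", {
  spec <- test_matrix_spec(p = 5, cases_per_group = 5, n_descriptors = 6,
                           seed = 13)
  tab <- generate_test_matrix(spec)
  res1 <- run_search(tab)
  set.seed(99)
  perm <- sample(nrow(tab$values))
  tab2 <- clinical_table(tab$values[perm, ])
  res2 <- run_search(tab2)
  expect_equal(res1$ranked$var_global[1], res2$ranked$var_global[1],
               tolerance = 1e-10)
  expect_identical(res1$ranked$combo[1], res2$ranked$combo[1])
})

test_that("the planted triple wins on a benchmark matrix at 6 sigma", {
  tab <- generate_test_matrix(test_matrix_spec(p = 6, seed = 42))
  res <- run_search(tab)
  expect_identical(res$n_combos_enumerated, 4060L)
  expect_equal(res$n_ordered_selections, 24360)
  expect_identical(res$ranked$combo[1], "X+Y+Z")
})
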