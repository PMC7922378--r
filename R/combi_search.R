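#' Search configuration for the combinatorial descriptor search
#'
#' @param combo_size Number of descriptors per combination (2 or 3).
#' @param n_clusters Number of clusters `k` each combination is cut into.
#' @param linkage Clustering mode: `"centroid"` (default), `"ward"` or
#'   `"average"` agglomerative linkage under Euclidean distance cut to
#'   `n_clusters` flat clusters, or `"lloyd_kmeans"` for iterative
#'   centroid-refinement partitioning.
#' @param min_cluster_size A clustering is valid only if every cluster has at
#'   least this many members (default 3).
#' @param min_usable_cases Combinations with fewer complete cases than this
#'   are skipped; default `n_clusters * min_cluster_size`, the smallest count
#'   for which a valid clustering can exist.
#' @param seed Integer seed, used only by `"lloyd_kmeans"`.
#' @return A `search_config` list.
#' @export
search_config <- function(combo_size = 3L, n_clusters = 3L,
                          linkage = c("centroid", "ward", "average",
                                      "lloyd_kmeans"),
                          min_cluster_size = 3L, min_usable_cases = NULL,
                          seed = 1L) {
  linkage <- match.arg(linkage)
  combo_size <- as.integer(combo_size)
  n_clusters <- as.integer(n_clusters)
  min_cluster_size <- as.integer(min_cluster_size)
  if (!combo_size %in% c(2L, 3L))
    stop("`combo_size` must be 2 or 3", call. = FALSE)
  if (n_clusters < 2L) stop("`n_clusters` must be >= 2", call. = FALSE)
  if (min_cluster_size < 1L)
    stop("`min_cluster_size` must be >= 1", call. = FALSE)
  if (is.null(min_usable_cases))
    min_usable_cases <- n_clusters * min_cluster_size
  min_usable_cases <- as.integer(min_usable_cases)
  if (min_usable_cases < n_clusters * min_cluster_size)
    stop("`min_usable_cases` must be >= n_clusters * min_cluster_size",
         call. = FALSE)
  structure(list(combo_size = combo_size, n_clusters = n_clusters,
                 linkage = linkage, min_cluster_size = min_cluster_size,
                 min_usable_cases = min_usable_cases,
                 seed = as.integer(seed)),
            class = "search_config")
}

#' Enumerate descriptor combinations
#'
#' All unordered combinations of `combo_size` descriptor names, each emitted
#' once, in lexicographic (C-locale) order. The ordered-selection count
#' `D * (D-1) * ... * (D-combo_size+1)`, which counts each combination
#' `combo_size!` times, is attached as attribute `"n_ordered"` for reporting.
#'
#' @param descriptor_names Character vector of descriptor names.
#' @param combo_size Combination size.
#' @return A `combo_size` x `choose(D, combo_size)` character matrix, one
#'   combination per column.
#' @export
#' @examples
#' ncol(enumerate_combos(letters[1:4], 3))            # 4
#' attr(enumerate_combos(LETTERS[1:30], 3), "n_ordered")  # 24360
enumerate_combos <- function(descriptor_names, combo_size = 3L) {
  d <- length(descriptor_names)
  combo_size <- as.integer(combo_size)
  if (combo_size > d)
    stop("combo_size (", combo_size, ") exceeds number of descriptors (",
         d, ")", call. = FALSE)
  nm <- sort(descriptor_names, method = "radix")
  out <- utils::combn(nm, combo_size)
  attr(out, "n_ordered") <- ordered_selection_count(d, combo_size)
  out
}

#' Ordered-selection count for descriptor combinations
#'
#' `D * (D-1) * ... * (D-m+1)`: the number of ordered draws of `m` distinct
#' descriptors from `D`, i.e. `m!` times the number of unordered
#' combinations.
#'
#' @param n_descriptors Number of descriptors `D`.
#' @param combo_size Draw size `m`.
#' @return A number.
#' @export
ordered_selection_count <- function(n_descriptors, combo_size = 3L) {
  prod(seq(n_descriptors, by = -1, length.out = combo_size))
}

#' Select the complete cases for a descriptor combination
#'
#' The cases used for one combination are exactly those with all of its
#' descriptors observed, in input order; the maximum data available is used
#' for every combination.
#'
#' @param table A [clinical_table()] (or standardized table).
#' @param combo Character vector of descriptor names.
#' @return Integer vector of case indices (possibly empty).
#' @export
select_complete_cases <- function(table, combo) {
  stopifnot(inherits(table, "clinical_table"))
  idx <- match(combo, table$descriptor_names)
  if (anyNA(idx))
    stop("unknown descriptor(s): ",
         paste(combo[is.na(idx)], collapse = ", "), call. = FALSE)
  unname(which(rowSums(table$missing_mask[, idx, drop = FALSE]) == 0L))
}

#' Unclusterable sentinel
#'
#' [cluster_cases()] returns this sentinel instead of labels when a
#' combination's cases cannot be clustered; the search logs and skips such
#' combinations rather than aborting.
#'
#' @param reason Human-readable reason.
#' @return An object of class `unclusterable` with a `reason` field.
#' @export
unclusterable <- function(reason) {
  structure(list(reason = reason), class = "unclusterable")
}

#' @rdname unclusterable
#' @param x Object to test.
#' @export
is_unclusterable <- function(x) inherits(x, "unclusterable")

# Build a "dist" object from a precomputed lower-triangle vector without
# copying through as.dist().
dist_from_vec <- function(v, n) {
  attr(v, "Size") <- n
  attr(v, "Diag") <- FALSE
  attr(v, "Upper") <- FALSE
  attr(v, "method") <- "euclidean"
  class(v) <- "dist"
  v
}

# Flat cut at (at most) k clusters by monotonized merge height: heights are
# propagated to the subtree maximum, the threshold is the (n-k)-th smallest
# monotonized height, and every merge at or below it is applied. For
# monotone linkages this is the plain k-cluster cut; with centroid-linkage
# inversions, monotonization creates exact height ties, and applying the
# whole tie block can leave fewer than k clusters — such clusterings then
# fail the validity rule instead of being forced into k groups.
cut_max_height <- function(merge, height, n, k) {
  if (k >= n) return(seq_len(n))
  m <- n - 1L
  mh <- height
  for (i in seq_len(m)) {
    a <- merge[i, 1L]; b <- merge[i, 2L]
    if (a > 0L && mh[a] > mh[i]) mh[i] <- mh[a]
    if (b > 0L && mh[b] > mh[i]) mh[i] <- mh[b]
  }
  t_star <- sort(mh, partial = n - k)[n - k]
  comp <- seq_len(n)
  members <- vector("list", m)
  for (i in seq_len(m)) {
    a <- merge[i, 1L]; b <- merge[i, 2L]
    all_m <- c(if (a < 0L) -a else members[[a]],
               if (b < 0L) -b else members[[b]])
    members[[i]] <- all_m
    if (mh[i] <= t_star) comp[all_m] <- n + i
  }
  as.integer(factor(comp, levels = unique(comp)))
}

# Agglomerate a squared-Euclidean lower triangle and cut flat.
# hclust's centroid algorithm is defined on squared Euclidean distances;
# ward.D2 and average expect unsquared ones.
cut_agglomerative <- function(d2, n, k, linkage) {
  hc <- switch(linkage,
    centroid = stats::hclust(dist_from_vec(d2, n), method = "centroid"),
    ward     = stats::hclust(dist_from_vec(sqrt(d2), n), method = "ward.D2"),
    average  = stats::hclust(dist_from_vec(sqrt(d2), n), method = "average"))
  cut_max_height(hc$merge, hc$height, n, k)
}

#' Cluster the cases of one descriptor combination
#'
#' For the agglomerative modes (`centroid`, `ward`, `average`): Euclidean
#' distances, agglomeration under the named linkage, flat cut at the
#' smallest monotonized merge-height threshold yielding at most
#' `n_clusters` clusters. For monotone linkages this gives exactly
#' `n_clusters`; under centroid-linkage inversions the tie block at the
#' threshold can merge past `n_clusters`, leaving fewer clusters — the
#' validity rule rejects those rather than forcing a `k`-way split. For
#' `lloyd_kmeans`: seeded iterative centroid-refinement partitioning.
#' Deterministic given input order (and seed, for `lloyd_kmeans`).
#'
#' @param sub_matrix Numeric matrix of used cases x combination descriptors
#'   (standardized values).
#' @param config A [search_config()].
#' @return Integer labels in `1..n_clusters`, or an [unclusterable()]
#'   sentinel when the cases cannot be clustered (fewer than `n_clusters`
#'   cases, or a degenerate partition).
#' @export
cluster_cases <- function(sub_matrix, config = search_config()) {
  sub_matrix <- as.matrix(sub_matrix)
  n <- nrow(sub_matrix)
  k <- config$n_clusters
  if (n < k)
    return(unclusterable("fewer cases than clusters"))
  if (any(!is.finite(sub_matrix)))
    stop("sub_matrix must be finite (complete cases only)", call. = FALSE)
  if (config$linkage == "lloyd_kmeans") {
    labels <- tryCatch({
      set.seed(config$seed)
      suppressWarnings(
        stats::kmeans(sub_matrix, centers = k, iter.max = 100L,
                      nstart = 10L, algorithm = "Lloyd")$cluster)
    }, error = function(e) NULL)
    if (is.null(labels))
      return(unclusterable("kmeans failed"))
    return(as.integer(labels))
  }
  d2 <- as.vector(stats::dist(sub_matrix))^2
  as.integer(cut_agglomerative(d2, n, k, config$linkage))
}

#' Validity of a clustering
#'
#' A clustering is valid when every cluster holds at least
#' `min_cluster_size` members; undersized clusters would contribute
#' artificially low variances to the ranking criterion.
#'
#' @param labels Integer cluster labels in `1..n_clusters`.
#' @param min_cluster_size Minimum members per cluster (default 3).
#' @param n_clusters Number of clusters expected; defaults to `max(labels)`.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' check_validity(rep(1:3, each = 3))        # TRUE
#' check_validity(c(1, 2, 2, 3, 3, 3, 3, 3)) # FALSE (cluster 1 has 1 member)
check_validity <- function(labels, min_cluster_size = 3L,
                           n_clusters = max(labels)) {
  sizes <- tabulate(labels, nbins = n_clusters)
  all(sizes >= min_cluster_size)
}

#' Global within-cluster variance of a clustered combination
#'
#' The ranking criterion of the combinatorial search: the sum, over the
#' clusters and over the combination's descriptors, of the sample variance
#' of each descriptor within each cluster. With three descriptors and three
#' clusters the sum has exactly nine terms. Lower is better: the best
#' combination is the one whose clusters are internally most homogeneous.
#'
#' @param sub_matrix Numeric matrix of used cases x combination descriptors
#'   (standardized values).
#' @param labels Integer cluster labels in `1..n_clusters`, one per row.
#' @param n_clusters Number of clusters; defaults to `max(labels)`.
#' @return A list: `var_matrix` (`n_clusters` x `ncol(sub_matrix)` matrix of
#'   within-cluster sample variances) and `var_global` (their sum).
#' @export
global_variance <- function(sub_matrix, labels, n_clusters = max(labels)) {
  sub_matrix <- as.matrix(sub_matrix)
  labels <- as.integer(labels)
  sizes <- tabulate(labels, nbins = n_clusters)
  if (any(sizes < 2L))
    stop("every cluster needs >= 2 members to compute a sample variance",
         call. = FALSE)
  s <- rowsum(sub_matrix, labels)
  ss <- rowsum(sub_matrix^2, labels)
  vmat <- (ss - s^2 / sizes) / (sizes - 1L)
  vmat <- pmax(vmat, 0)  # guard tiny negative round-off
  rownames(vmat) <- paste0("cluster_", seq_len(n_clusters))
  list(var_matrix = vmat, var_global = sum(vmat))
}

combo_label <- function(combo) paste(combo, collapse = "+")

#' Rank evaluated combinations by global variance
#'
#' Valid combinations are sorted ascending by `var_global`; ties are broken
#' lexicographically on the combination label so the ranking is total and
#' deterministic. Invalid and skipped combinations are counted, never
#' ranked.
#'
#' @param scores Data frame with one row per evaluated combination; columns
#'   `combo`, `var_global`, `n_used`, `valid`, plus `size_*` columns.
#' @param n_enumerated Total number of combinations enumerated.
#' @param n_ordered Ordered-selection count for reporting.
#' @param skip_reasons Named integer vector counting skipped combinations by
#'   reason.
#' @param config The [search_config()] used.
#' @return A `search_result`: list with `ranked` (data frame of valid
#'   combinations in rank order), enumeration and validity counts, skip
#'   reasons and the config. If no combination is valid a warning
#'   `"no valid clustering"` is raised and `ranked` has zero rows.
#' @export
rank_combos <- function(scores, n_enumerated = nrow(scores),
                        n_ordered = NA_real_, skip_reasons = integer(0),
                        config = search_config()) {
  ranked <- scores[scores$valid, , drop = FALSE]
  ord <- order(ranked$var_global, ranked$combo, method = "radix")
  ranked <- ranked[ord, , drop = FALSE]
  rownames(ranked) <- NULL
  ranked$valid <- NULL
  res <- structure(
    list(ranked = ranked,
         n_combos_enumerated = n_enumerated,
         n_ordered_selections = n_ordered,
         n_combos_valid = nrow(ranked),
         n_combos_invalid = sum(!scores$valid) - sum(skip_reasons),
         n_combos_skipped = sum(skip_reasons),
         skip_reasons = skip_reasons,
         config = config),
    class = "search_result")
  if (nrow(ranked) == 0L)
    warning("no valid clustering: every combination was skipped or invalid",
            call. = FALSE)
  res
}

#' Exhaustive combinatorial descriptor search
#'
#' The full pipeline: scale-only standardization (divide each descriptor by
#' its sample SD), enumeration of all descriptor combinations, per-combination
#' complete-case selection, clustering, the minimum-cluster-size validity
#' rule, global-variance scoring, and ranking. The top-ranked combination is
#' the set of descriptors whose clusters are jointly most compact.
#'
#' @param table A [clinical_table()]; a `standardized_table` is used as-is.
#' @param config A [search_config()].
#' @return A `search_result`; see [rank_combos()].
#' @export
#' @examples
#' spec <- test_matrix_spec(p = 6, seed = 42)
#' res <- run_search(generate_test_matrix(spec))
#' res$ranked[1, c("combo", "var_global")]  # X+Y+Z ranked first
run_search <- function(table, config = search_config()) {
  stopifnot(inherits(table, "clinical_table"))
  std <- if (inherits(table, "standardized_table")) table
         else standardize(table, "scale_only")
  combos <- enumerate_combos(std$descriptor_names, config$combo_size)
  n_combos <- ncol(combos)
  k <- config$n_clusters
  m <- config$combo_size
  Z <- std$values
  mask <- std$missing_mask
  n_all <- nrow(Z)
  col_of <- stats::setNames(seq_along(std$descriptor_names),
                            std$descriptor_names)
  fully_observed <- !any(mask)
  agglomerative <- config$linkage != "lloyd_kmeans"
  # fast path: with no missing data every combination uses every case, and
  # each combination's squared distances are a sum of per-column triangles
  d2_cols <- NULL
  if (fully_observed && agglomerative)
    d2_cols <- lapply(seq_len(ncol(Z)),
                      function(j) as.vector(stats::dist(Z[, j]))^2)

  vg <- rep(NA_real_, n_combos)
  n_used <- integer(n_combos)
  valid <- logical(n_combos)
  sizes <- matrix(NA_integer_, n_combos, k)
  skip <- c(too_few_cases = 0L, unclusterable = 0L)

  for (ci in seq_len(n_combos)) {
    idx <- col_of[combos[, ci]]
    used <- if (fully_observed) seq_len(n_all)
            else which(rowSums(mask[, idx, drop = FALSE]) == 0L)
    n_used[ci] <- length(used)
    if (length(used) < config$min_usable_cases) {
      skip[["too_few_cases"]] <- skip[["too_few_cases"]] + 1L
      next
    }
    if (!is.null(d2_cols)) {
      d2 <- d2_cols[[idx[1L]]]
      for (j in idx[-1L]) d2 <- d2 + d2_cols[[j]]
      labels <- cut_agglomerative(d2, n_all, k, config$linkage)
    } else {
      labels <- cluster_cases(Z[used, idx, drop = FALSE], config)
      if (is_unclusterable(labels)) {
        skip[["unclusterable"]] <- skip[["unclusterable"]] + 1L
        next
      }
    }
    csize <- tabulate(labels, k)
    sizes[ci, ] <- csize
    if (all(csize >= config$min_cluster_size)) {
      valid[ci] <- TRUE
      sub <- Z[used, idx, drop = FALSE]
      s <- rowsum(sub, labels)
      ss <- rowsum(sub^2, labels)
      vg[ci] <- sum(pmax((ss - s^2 / csize) / (csize - 1L), 0))
    }
  }

  scores <- data.frame(combo = apply(combos, 2L, combo_label),
                       t(combos), n_used = n_used,
                       stringsAsFactors = FALSE)
  names(scores)[1L + seq_len(m)] <- paste0("descriptor_", seq_len(m))
  colnames(sizes) <- paste0("size_", seq_len(k))
  scores <- cbind(scores, sizes)
  scores$var_global <- vg
  scores$valid <- valid
  rank_combos(scores, n_enumerated = n_combos,
              n_ordered = attr(combos, "n_ordered"),
              skip_reasons = skip, config = config)
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf(
    "<search_result> %d combinations enumerated (%s ordered selections)\n",
    x$n_combos_enumerated, format(x$n_ordered_selections, big.mark = ",")))
  cat(sprintf("  valid: %d   invalid (undersized cluster): %d   skipped: %d\n",
              x$n_combos_valid, x$n_combos_invalid, x$n_combos_skipped))
  if (nrow(x$ranked)) {
    cat("  best combinations by global variance:\n")
    print(utils::head(x$ranked[, c("combo", "var_global", "n_used")], 5L),
          row.names = FALSE)
  } else cat("  no valid clustering\n")
  invisible(x)
}

#' @export
as.data.frame.search_result <- function(x, ...) x$ranked

#' Full clustering outcome for one descriptor combination
#'
#' Recomputes the complete per-combination detail that [run_search()]
#' summarizes: used cases, labels, cluster sizes, the per-cluster variance
#' matrix and its sum.
#'
#' @param table A [clinical_table()].
#' @param combo Character vector of descriptor names.
#' @param config A [search_config()].
#' @return A `combo_score`: list with `combo`, `used_case_indices`,
#'   `labels` (named by case id), `cluster_sizes`, `per_cluster_variance`,
#'   `var_global`, `n_used_cases`, `valid`.
#' @export
combo_outcome <- function(table, combo, config = search_config()) {
  stopifnot(inherits(table, "clinical_table"))
  std <- if (inherits(table, "standardized_table")) table
         else standardize(table, "scale_only")
  combo <- sort(as.character(combo), method = "radix")
  used <- select_complete_cases(std, combo)
  idx <- match(combo, std$descriptor_names)
  sub <- std$values[used, idx, drop = FALSE]
  labels <- cluster_cases(sub, config)
  if (is_unclusterable(labels))
    stop("combination cannot be clustered: ", labels$reason, call. = FALSE)
  sizes <- tabulate(labels, config$n_clusters)
  ok <- all(sizes >= config$min_cluster_size)
  gv <- if (all(sizes >= 2L)) global_variance(sub, labels, config$n_clusters)
        else list(var_matrix = NULL, var_global = NA_real_)
  structure(
    list(combo = combo,
         used_case_indices = used,
         labels = stats::setNames(labels, std$case_ids[used]),
         cluster_sizes = sizes,
         per_cluster_variance = gv$var_matrix,
         var_global = gv$var_global,
         n_used_cases = length(used),
         valid = ok,
         config = config),
    class = "combo_score")
}

#' @export
print.combo_score <- function(x, ...) {
  cat(sprintf("<combo_score> %s: var_global = %.4g, %d cases, sizes [%s]%s\n",
              combo_label(x$combo), x$var_global, x$n_used_cases,
              paste(x$cluster_sizes, collapse = ", "),
              if (x$valid) "" else " (invalid)"))
  invisible(x)
}

#' Write the ranked-combination report as CSV
#'
#' @param result A `search_result` from [run_search()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranked_csv <- function(result, path) {
  stopifnot(inherits(result, "search_result"))
  utils::write.csv(result$ranked, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON report with per-cluster variance matrices
#'
#' JSON variant of the ranked report: enumeration counts plus, for the top
#' `max_combos` ranked combinations, the full per-cluster variance matrix.
#'
#' @param result A `search_result` from [run_search()].
#' @param table The [clinical_table()] the search ran on.
#' @param path Output JSON path.
#' @param max_combos Number of top combinations to detail (default 100).
#' @return `path`, invisibly.
#' @export
write_ranked_json <- function(result, table, path, max_combos = 100L) {
  stopifnot(inherits(result, "search_result"))
  top <- utils::head(result$ranked, max_combos)
  details <- lapply(seq_len(nrow(top)), function(i) {
    combo <- strsplit(top$combo[i], "+", fixed = TRUE)[[1L]]
    out <- combo_outcome(table, combo, result$config)
    list(combo = out$combo, var_global = out$var_global,
         n_used_cases = out$n_used_cases,
         cluster_sizes = out$cluster_sizes,
         per_cluster_variance = out$per_cluster_variance)
  })
  jsonlite::write_json(
    list(n_combos_enumerated = result$n_combos_enumerated,
         n_ordered_selections = result$n_ordered_selections,
         n_combos_valid = result$n_combos_valid,
         n_combos_invalid = result$n_combos_invalid,
         n_combos_skipped = result$n_combos_skipped,
         combos = details),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write case-to-cluster assignments for one combination
#'
#' @param table A [clinical_table()].
#' @param combo Character vector of descriptor names.
#' @param config A [search_config()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_assignments_csv <- function(table, combo, config = search_config(),
                                  path) {
  out <- combo_outcome(table, combo, config)
  df <- data.frame(case_id = names(out$labels), cluster = unname(out$labels),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
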