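#' Confirmatory hierarchical clustering of cases
#'
#' Agglomerative hierarchical clustering of the complete cases of a chosen
#' descriptor set: z-standardization (center and scale, computed over the
#' complete cases), Euclidean distances, agglomeration under the chosen
#' linkage. Ward linkage is the confirmatory default; its merge heights are
#' monotone non-decreasing, so flat cuts by height are well defined.
#'
#' @param table A [clinical_table()] (raw units).
#' @param descriptors Descriptor names to cluster on; default all.
#' @param linkage One of `"ward"` (default), `"average"`, `"complete"`,
#'   `"single"`, `"centroid"`. Centroid linkage is run on squared Euclidean
#'   distances (its natural scale), so its heights are squared and may show
#'   inversions.
#' @return An `hca_fit`: list with the underlying `hclust` object, the case
#'   ids used, the descriptors, the linkage name, `n` leaves and `d_max`
#'   (maximum merge height).
#' @export
#' @examples
#' tab <- clinical_table(cbind(a = c(0, 1, 10, 11), b = c(0, 0, 5, 5)))
#' fit <- build_dendrogram(tab, linkage = "ward")
#' cut_clusters(fit, 2)
build_dendrogram <- function(table, descriptors = NULL,
                             linkage = c("ward", "average", "complete",
                                         "single", "centroid")) {
  stopifnot(inherits(table, "clinical_table"))
  linkage <- match.arg(linkage)
  if (is.null(descriptors)) descriptors <- table$descriptor_names
  used <- select_complete_cases(table, descriptors)
  if (length(used) < 2L)
    stop("fewer than 2 complete cases on the chosen descriptors",
         call. = FALSE)
  idx <- match(descriptors, table$descriptor_names)
  raw <- table$values[used, idx, drop = FALSE]
  sds <- apply(raw, 2L, stats::sd)
  if (any(!is.finite(sds) | sds <= 0))
    stop("zero-spread descriptor(s) on the complete cases: ",
         paste(descriptors[!is.finite(sds) | sds <= 0], collapse = ", "),
         call. = FALSE)
  z <- scale(raw)
  d <- stats::dist(z)
  hc <- switch(linkage,
               ward = stats::hclust(d, method = "ward.D2"),
               centroid = stats::hclust(d^2, method = "centroid"),
               stats::hclust(d, method = linkage))
  hc$labels <- table$case_ids[used]
  structure(
    list(hclust = hc, case_ids = table$case_ids[used],
         descriptors = descriptors, linkage = linkage,
         n = length(used), d_max = max(hc$height)),
    class = "hca_fit")
}

#' @export
print.hca_fit <- function(x, ...) {
  cat(sprintf("<hca_fit> %s linkage, %d cases, %d descriptors, D_max = %.4g\n",
              x$linkage, x$n, length(x$descriptors), x$d_max))
  invisible(x)
}

#' @export
plot.hca_fit <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "",
       main = sprintf("%s linkage dendrogram", x$linkage), ...)
  invisible(x)
}

#' Cut a dendrogram into a fixed number of flat clusters
#'
#' @param fit An `hca_fit` from [build_dendrogram()].
#' @param n_clusters Number of flat clusters, between 1 and the leaf count.
#' @return Integer labels named by case id.
#' @export
cut_clusters <- function(fit, n_clusters) {
  stopifnot(inherits(fit, "hca_fit"))
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 1L || n_clusters > fit$n)
    stop("`n_clusters` must be between 1 and ", fit$n, call. = FALSE)
  stats::cutree(fit$hclust, k = n_clusters)
}

#' Sneath-style significance cut of a dendrogram
#'
#' The conventional two-threshold reading of dendrogram significance: count
#' the flat clusters obtained by cutting at one third and at two thirds of
#' the maximum merge height. Intended for monotone linkages (Ward, average,
#' complete, single).
#'
#' @param fit An `hca_fit` from [build_dendrogram()].
#' @return A list: `d_max`, `cut_heights` (the two thresholds) and
#'   `n_clusters` (named vector of cluster counts at each threshold).
#' @export
sneath_significance <- function(fit) {
  stopifnot(inherits(fit, "hca_fit"))
  h <- c(`1/3` = fit$d_max / 3, `2/3` = 2 * fit$d_max / 3)
  counts <- vapply(h, function(th) {
    max(stats::cutree(fit$hclust, h = th))
  }, integer(1))
  list(d_max = fit$d_max, cut_heights = h, n_clusters = counts)
}

#' Export a dendrogram as a linkage matrix
#'
#' One row per merge: children (`1..n` are leaves, `n + i` is the cluster
#' formed at merge `i`), merge height and merged size.
#'
#' @param fit An `hca_fit` from [build_dendrogram()].
#' @return A data frame with columns `child_a`, `child_b`, `height`, `size`.
#' @export
linkage_matrix <- function(fit) {
  stopifnot(inherits(fit, "hca_fit"))
  hc <- fit$hclust
  n <- fit$n
  enc <- function(ch) ifelse(ch < 0, -ch, n + ch)
  sizes <- integer(n - 1L)
  for (i in seq_len(n - 1L)) {
    sz <- 0L
    for (ch in hc$merge[i, ])
      sz <- sz + if (ch < 0) 1L else sizes[ch]
    sizes[i] <- sz
  }
  data.frame(child_a = enc(hc$merge[, 1L]), child_b = enc(hc$merge[, 2L]),
             height = hc$height, size = sizes)
}

#' Export a dendrogram as a Newick string
#'
#' @param fit An `hca_fit` from [build_dendrogram()].
#' @param path Optional file path; when given the string is also written
#'   there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
as_newick <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "hca_fit"))
  phy <- ape::as.phylo(fit$hclust)
  str <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(str, path)
    return(invisible(str))
  }
  str
}
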