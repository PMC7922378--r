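#' Raw-unit per-cluster descriptor profile
#'
#' For each cluster and each descriptor of a combination, the mean and
#' sample standard deviation computed on the raw (unstandardized) observed
#' values of the cluster's members — the quantities a clinician reads.
#' A descriptor is flagged unavailable in a cluster with fewer than two
#' observed values.
#'
#' @param table A [clinical_table()] (raw units).
#' @param combo Character vector of descriptor names to profile.
#' @param labels Integer cluster labels, one per used case.
#' @param cases Integer indices of the used cases (rows of `table`) that
#'   `labels` refers to; defaults to all cases.
#' @return A `cluster_profile`: list with `combo`, `n_clusters`, matrices
#'   `mean`, `sd`, `n_obs` (clusters x descriptors), `cluster_sizes`, and
#'   logical matrix `available` (`n_obs >= 2`).
#' @export
#' @examples
#' tab <- clinical_table(cbind(a = c(27, 28, 29, 1, 2, 3),
#'                             b = c(1, 1, 2, 5, 6, 7)))
#' cluster_profile(tab, c("a", "b"), labels = rep(1:2, each = 3))$mean
cluster_profile <- function(table, combo, labels,
                            cases = seq_len(nrow(table$values))) {
  stopifnot(inherits(table, "clinical_table"))
  combo <- as.character(combo)
  idx <- match(combo, table$descriptor_names)
  if (anyNA(idx))
    stop("unknown descriptor(s): ", paste(combo[is.na(idx)], collapse = ", "),
         call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != length(cases))
    stop("`labels` must have one entry per used case", call. = FALSE)
  k <- max(labels)
  m <- length(combo)
  mu <- sdm <- matrix(NA_real_, k, m,
                      dimnames = list(paste0("cluster_", seq_len(k)), combo))
  nob <- matrix(0L, k, m, dimnames = dimnames(mu))
  raw <- table$values[cases, idx, drop = FALSE]
  for (g in seq_len(k)) {
    sub <- raw[labels == g, , drop = FALSE]
    for (j in seq_len(m)) {
      v <- sub[, j]
      v <- v[!is.na(v)]
      nob[g, j] <- length(v)
      if (length(v) >= 1L) mu[g, j] <- mean(v)
      if (length(v) >= 2L) sdm[g, j] <- stats::sd(v)
    }
  }
  structure(
    list(combo = combo, n_clusters = k, mean = mu, sd = sdm, n_obs = nob,
         cluster_sizes = tabulate(labels, k), available = nob >= 2L),
    class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf("<cluster_profile> %d clusters x %d descriptors\n",
              x$n_clusters, length(x$combo)))
  for (j in seq_along(x$combo)) {
    cells <- sprintf("%.3g (%.2g)", x$mean[, j], x$sd[, j])
    cat(sprintf("  %-12s %s\n", x$combo[j], paste(cells, collapse = "  ")))
  }
  invisible(x)
}

#' Pooled spread of a cluster pair
#'
#' The root-sum-of-squares of two cluster standard deviations — the
#' denominator of the standardized mean gap between the pair.
#'
#' @param sd_a,sd_b Nonnegative cluster standard deviations.
#' @return `sqrt(sd_a^2 + sd_b^2)`.
#' @export
#' @examples
#' pair_sigma(1, 1)  # sqrt(2)
#' pair_sigma(7, 9)  # sqrt(130)
pair_sigma <- function(sd_a, sd_b) {
  stopifnot(all(sd_a >= 0), all(sd_b >= 0))
  sqrt(sd_a^2 + sd_b^2)
}

#' Cluster-separation parameter of one descriptor
#'
#' For a three-cluster profile, each cluster pair gets a standardized mean
#' gap |mean_A - mean_B| / sqrt(sd_A^2 + sd_B^2); the separation parameter
#' is the maximum of the three. It quantifies how well the descriptor, on
#' its own scale, separates the two most-distant clusters relative to their
#' spread; it is invariant to shifting or positively rescaling the
#' descriptor. A pair with both SDs zero yields a gap of 0 when the means
#' coincide and `Inf` when they differ (flagged, not an error).
#'
#' @param profile A [cluster_profile()].
#' @param descriptor Descriptor name (one of `profile$combo`).
#' @return A list: `p_prime` (the max gap), `gaps` (named vector of the
#'   pairwise standardized gaps), `pair_sigmas`.
#' @export
separation_parameter <- function(profile, descriptor) {
  stopifnot(inherits(profile, "cluster_profile"))
  j <- match(descriptor, profile$combo)
  if (is.na(j))
    stop("descriptor '", descriptor, "' is not in the profile", call. = FALSE)
  if (!all(profile$available[, j]))
    stop("descriptor '", descriptor,
         "' is unavailable (a cluster has fewer than 2 observed values)",
         call. = FALSE)
  k <- profile$n_clusters
  pairs <- utils::combn(k, 2L)
  gap <- sig <- numeric(ncol(pairs))
  nm <- character(ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    a <- pairs[1L, q]; b <- pairs[2L, q]
    nm[q] <- paste0(a, "-", b)
    sig[q] <- pair_sigma(profile$sd[a, j], profile$sd[b, j])
    num <- abs(profile$mean[a, j] - profile$mean[b, j])
    gap[q] <- if (sig[q] == 0) { if (num == 0) 0 else Inf } else num / sig[q]
  }
  list(p_prime = max(gap), gaps = stats::setNames(gap, nm),
       pair_sigmas = stats::setNames(sig, nm))
}

#' Per-descriptor separation report for a clustered combination
#'
#' One row per descriptor: per-cluster raw mean and SD, the pairwise
#' standardized gaps and the separation parameter (max gap). Descriptors
#' unavailable in some cluster get `NA` gaps and a message.
#'
#' @param profile A [cluster_profile()].
#' @return A data frame, one row per descriptor of the profile.
#' @export
separation_report <- function(profile) {
  stopifnot(inherits(profile, "cluster_profile"))
  k <- profile$n_clusters
  pairs <- utils::combn(k, 2L)
  pair_nm <- apply(pairs, 2L, function(p) paste0("gap_", p[1L], p[2L]))
  rows <- lapply(seq_along(profile$combo), function(j) {
    d <- profile$combo[j]
    base <- c(stats::setNames(as.list(profile$mean[, j]),
                              paste0("mean_", seq_len(k))),
              stats::setNames(as.list(profile$sd[, j]),
                              paste0("sd_", seq_len(k))))
    if (all(profile$available[, j])) {
      sp <- separation_parameter(profile, d)
      gaps <- stats::setNames(as.list(sp$gaps), pair_nm)
      pp <- sp$p_prime
    } else {
      message("descriptor '", d,
              "' excluded from separation parameter: ",
              "a cluster has fewer than 2 observed values")
      gaps <- stats::setNames(as.list(rep(NA_real_, ncol(pairs))), pair_nm)
      pp <- NA_real_
    }
    cbind(data.frame(descriptor = d, stringsAsFactors = FALSE),
          as.data.frame(base), as.data.frame(gaps), p_prime = pp)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a separation report as CSV
#'
#' @param report Data frame from [separation_report()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_separation_csv <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
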