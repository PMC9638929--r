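#' Align peak-volume vectors on a common peak set
#'
#' Builds a matrix whose columns are the union of all peak labels in
#' canonical gradient order (40S, 60S, 1, 2, ...), with peaks absent
#' from a vector read as zero volume.
#'
#' @param vectors List of named peak-volume vectors.
#' @return Numeric matrix, one row per input vector.
#' @export
align_volumes <- function(vectors) {
  if (!is.list(vectors)) vectors <- list(vectors)
  labels <- unique(unlist(lapply(vectors, names)))
  if (is.null(labels) || any(labels == ""))
    pp_stop_invalid("all volume vectors must be fully named")
  labels <- order_peak_labels(labels)
  M <- matrix(0, nrow = length(vectors), ncol = length(labels),
              dimnames = list(names(vectors), labels))
  for (i in seq_along(vectors)) M[i, names(vectors[[i]])] <- vectors[[i]]
  M
}

#' Root-mean-square deviation between two peak-volume vectors
#'
#' The RMSD over the union of peak indices (absent peaks count as zero
#' volume) is the quantitative distance between two normalised
#' profiles.  Both inputs must be normalised to sum to 1.
#'
#' @param a,b Named peak-volume vectors.
#' @param tol Tolerance on the sum-to-one check.
#' @return Non-negative scalar; 0 iff the vectors are identical.
#' @examples
#' rmsd(c("1" = 1), c("2" = 1))  # 1
#' @export
rmsd <- function(a, b, tol = 1e-6) {
  for (v in list(a, b))
    if (abs(sum(v) - 1) > tol)
      pp_stop_invalid("peak-volume vectors must be normalised to sum to 1")
  M <- align_volumes(list(a, b))
  sqrt(mean((M[1, ] - M[2, ])^2))
}

#' Fit the RMSD null distribution from a known-good collection
#'
#' Computes the RMSD for every pairwise combination of a collection of
#' peak-volume vectors from datasets considered sound ("known good"),
#' and fits a normal distribution to the resulting values by maximum
#' likelihood (sample mean and population standard deviation).  The
#' fitted normal serves as the null against which a new profile's RMSD
#' is converted to a P-value.
#'
#' @param volume_vectors List of at least 3 named peak-volume vectors.
#' @return An `rmsd_null` with elements `mu`, `sd`, `n_pairs` and the
#'   raw pairwise `rmsds`.
#' @export
fit_null <- function(volume_vectors) {
  if (!is.list(volume_vectors) || length(volume_vectors) < 3)
    pp_stop_insufficient("at least 3 volume vectors are required to fit a null")
  n <- length(volume_vectors)
  pairs <- utils::combn(n, 2)
  r <- apply(pairs, 2, function(ij)
    rmsd(volume_vectors[[ij[1]]], volume_vectors[[ij[2]]]))
  mu <- mean(r)
  sd <- sqrt(mean((r - mu)^2))
  if (sd <= 0)
    pp_stop_degenerate("pairwise RMSDs have zero variance; null is degenerate")
  structure(list(mu = mu, sd = sd, n_pairs = ncol(pairs), rmsds = r),
            class = "rmsd_null")
}

#' @export
print.rmsd_null <- function(x, ...) {
  cat(sprintf("<rmsd_null> Normal(mu = %.4g, sd = %.4g) from %d pairwise RMSDs\n",
              x$mu, x$sd, x$n_pairs))
  invisible(x)
}

#' P-value of an RMSD under the fitted null
#'
#' The upper-tail probability of observing an RMSD at least as large as
#' `value` under the fitted normal null: a large RMSD (dissimilar
#' profiles) yields a small P-value.  Values below the null mean give
#' P > 0.5; they are reported as-is, being plain tail probabilities.
#'
#' @param value RMSD value (scalar or vector).
#' @param null An [fit_null()] result.
#' @return Tail probability in (0, 1), non-increasing in `value`.
#' @export
rmsd_pvalue <- function(value, null) {
  if (!inherits(null, "rmsd_null"))
    pp_stop_invalid("null must be an rmsd_null object")
  stats::pnorm(value, mean = null$mu, sd = null$sd, lower.tail = FALSE)
}

# Davies-Bouldin validity index. S_i is the mean distance of a cluster's
# points to its centroid, M_ij the distance between centroids;
# R_ij = (S_i + S_j) / M_ij and the index is the mean over clusters of
# the worst R_ij. Lower is better.
davies_bouldin <- function(M, labels) {
  ks <- sort(unique(labels))
  cent <- t(vapply(ks, function(k) colMeans(M[labels == k, , drop = FALSE]),
                   numeric(ncol(M))))
  S <- vapply(seq_along(ks), function(i) {
    rows <- M[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums((rows - rep(cent[i, ], each = nrow(rows)))^2)))
  }, numeric(1))
  K <- length(ks)
  if (K < 2) return(NA_real_)
  R <- matrix(0, K, K)
  for (i in seq_len(K - 1)) for (j in seq(i + 1, K)) {
    Mij <- sqrt(sum((cent[i, ] - cent[j, ])^2))
    R[i, j] <- R[j, i] <- if (Mij > 0) (S[i] + S[j]) / Mij else Inf
  }
  mean(vapply(seq_len(K), function(i) max(R[i, -i]), numeric(1)))
}

#' Cluster peak-volume vectors hierarchically
#'
#' Agglomerative clustering of aligned peak-volume vectors with
#' Euclidean distance and complete linkage (cluster distance is the
#' farthest pair of members), followed by automatic selection of the
#' number of clusters over `k_range` using the Davies-Bouldin validity
#' index.
#'
#' The standard Davies-Bouldin index is a within/between scatter ratio
#' that is minimised at the best partition; `db_mode = "min"` (the
#' default) selects the k with the smallest standard index.
#' `db_mode = "max_inverted"` instead maximises the inverted
#' between/within ratio, the reading in which the index is described as
#' being maximised; the two selections agree except near ties.
#'
#' @param vectors List of at least 3 named peak-volume vectors.
#' @param k_range Candidate cluster numbers, within `[2, n - 1]`.
#'   Default `2:min(n - 1, 10)`.
#' @param db_mode `"min"` or `"max_inverted"` (see Details).
#' @return A `cluster_result` with elements `labels` (integer cluster
#'   per profile, in 1..k), `k`, `db_scores` (named by candidate k),
#'   `hclust` (the merge history) and `db_mode`.
#' @export
cluster_profiles <- function(vectors, k_range = NULL,
                             db_mode = c("min", "max_inverted")) {
  db_mode <- match.arg(db_mode)
  if (!is.list(vectors) || length(vectors) < 3)
    pp_stop_invalid("at least 3 volume vectors are required for clustering")
  n <- length(vectors)
  if (is.null(k_range)) k_range <- 2:min(n - 1, 10)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > n - 1)
    pp_stop_invalid("k_range must lie within [2, n - 1]")
  M <- align_volumes(vectors)
  hc <- stats::hclust(stats::dist(M), method = "complete")
  scores <- vapply(k_range, function(k) {
    labels <- stats::cutree(hc, k = k)
    db <- davies_bouldin(M, labels)
    if (db_mode == "min") db else {
      # inverted between/within ratio, maximised
      ks <- sort(unique(labels))
      cent <- t(vapply(ks, function(kk)
        colMeans(M[labels == kk, , drop = FALSE]), numeric(ncol(M))))
      S <- vapply(seq_along(ks), function(i) {
        rows <- M[labels == ks[i], , drop = FALSE]
        mean(sqrt(rowSums((rows - rep(cent[i, ], each = nrow(rows)))^2)))
      }, numeric(1))
      K <- length(ks)
      B <- matrix(Inf, K, K)
      for (i in seq_len(K - 1)) for (j in seq(i + 1, K)) {
        Mij <- sqrt(sum((cent[i, ] - cent[j, ])^2))
        B[i, j] <- B[j, i] <- if (S[i] + S[j] > 0) Mij / (S[i] + S[j]) else Inf
      }
      mean(vapply(seq_len(K), function(i) min(B[i, -i]), numeric(1)))
    }
  }, numeric(1))
  names(scores) <- as.character(k_range)
  best <- if (db_mode == "min") k_range[which.min(scores)] else
    k_range[which.max(scores)]
  structure(list(labels = stats::cutree(hc, k = best), k = best,
                 db_scores = scores, hclust = hc, db_mode = db_mode),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d profiles in %d clusters (Davies-Bouldin, mode '%s')\n",
              length(x$labels), x$k, x$db_mode))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Meta-profiles: per-cluster average peak-volume vectors
#'
#' Averages the aligned peak-volume vectors within each cluster and
#' renormalises each average to sum to 1.
#'
#' @param vectors List of named peak-volume vectors.
#' @param labels Cluster assignment per vector (any label type).
#' @return Named list of peak-volume vectors, one per cluster label.
#' @export
meta_profile <- function(vectors, labels) {
  if (length(labels) != length(vectors))
    pp_stop_invalid("labels must have one entry per vector")
  M <- align_volumes(vectors)
  ks <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
  out <- lapply(ks, function(k) {
    rows <- M[labels == k, , drop = FALSE]
    if (nrow(rows) == 0)
      pp_stop_invalid(sprintf("cluster '%s' is empty", k))
    m <- colMeans(rows)
    m / sum(m)
  })
  names(out) <- as.character(ks)
  out
}
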