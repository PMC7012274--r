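#' Silhouette score of a partition
#'
#' Mean over samples of `(b - a) / max(a, b)`, where `a` is the mean
#' distance to the other members of the sample's own cluster and `b` the
#' smallest mean distance to the members of any other cluster. A sample in
#' a singleton cluster contributes 0 (standard convention). Ranges in
#' `[-1, 1]`; higher is better.
#'
#' @param features `n x p` feature matrix (rows are samples).
#' @param labels Cluster assignment of length `n` (at least 2 clusters).
#' @param metric Distance metric; only `"euclidean"`.
#' @return Mean silhouette width.
#' @examples
#' silhouette_score(cbind(c(0, 0.2, 10, 10.2)), c(1, 1, 2, 2))
#' @export
silhouette_score <- function(features, labels, metric = "euclidean") {
  metric <- match.arg(metric)
  X <- as.matrix(features)
  labels <- as.integer(factor(labels))
  n <- nrow(X)
  if (length(labels) != n) stop("labels must match the number of rows")
  if (length(unique(labels)) < 2)
    stop("silhouette is undefined for a single cluster")
  D <- as.matrix(dist(X))
  ks <- sort(unique(labels))
  # mean distance from every sample to every cluster, n x K
  M <- vapply(ks, function(k) rowSums(D[, labels == k, drop = FALSE]),
              numeric(n))
  sizes <- vapply(ks, function(k) sum(labels == k), integer(1))
  s <- numeric(n)
  for (i in seq_len(n)) {
    k <- match(labels[i], ks)
    if (sizes[k] == 1) { s[i] <- 0; next }
    a <- M[i, k] / (sizes[k] - 1)
    b <- min(M[i, -k] / sizes[-k])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Davies-Bouldin index of a partition
#'
#' Mean over clusters of the worst-case similarity
#' `max_{j != i} (S_i + S_j) / M_ij`, where `S_i` is the mean Euclidean
#' distance of cluster `i`'s members to its centroid and `M_ij` the distance
#' between centroids. Lower is better; coincident centroids give `Inf` with
#' a warning.
#'
#' @param features `n x p` feature matrix.
#' @param labels Cluster assignment (at least 2 clusters).
#' @return Nonnegative index.
#' @examples
#' davies_bouldin(cbind(c(0, 0.2, 10, 10.2)), c(1, 1, 2, 2))
#' @export
davies_bouldin <- function(features, labels) {
  X <- as.matrix(features)
  labels <- as.integer(factor(labels))
  if (length(labels) != nrow(X)) stop("labels must match the number of rows")
  ks <- sort(unique(labels))
  K <- length(ks)
  if (K < 2) stop("Davies-Bouldin is undefined for a single cluster")
  cents <- do.call(rbind, lapply(ks, function(k)
    colMeans(X[labels == k, , drop = FALSE])))
  S <- vapply(seq_len(K), function(k) {
    rows <- X[labels == ks[k], , drop = FALSE]
    mean(sqrt(rowSums((rows - matrix(cents[k, ], nrow(rows), ncol(X),
                                     byrow = TRUE))^2)))
  }, numeric(1))
  M <- as.matrix(dist(cents))
  R <- numeric(K)
  degenerate <- FALSE
  for (i in seq_len(K)) {
    r <- (S[i] + S[-i]) / M[i, -i]
    if (any(!is.finite(r))) {
      degenerate <- TRUE
      r[!is.finite(r)] <- Inf
    }
    R[i] <- max(r)
  }
  if (degenerate)
    warning("coincident cluster centroids; Davies-Bouldin is infinite")
  mean(R)
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples;
#' 1 for identical partitions (up to relabeling), about 0 for independent
#' ones. Used to compare recovered ROIs against simulation ground truth.
#'
#' @param a,b Two label vectors of equal length.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
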