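#' Embedding configuration
#'
#' Settings for projecting event series into two dimensions. UMAP (the
#' pipeline default) preserves the global structure of the event signals;
#' PCA is an exactly deterministic linear alternative useful for testing and
#' for small groups.
#'
#' @param method `"umap"` or `"pca"`.
#' @param n_neighbors UMAP neighbourhood size (default 15).
#' @param min_dist UMAP minimum embedded distance (default 0.1).
#' @param seed Integer seed for the stochastic optimizer.
#' @return A list of class `embedding_config`.
#' @export
embedding_config <- function(method = c("umap", "pca"), n_neighbors = 15,
                             min_dist = 0.1, seed = 1) {
  method <- match.arg(method)
  if (n_neighbors < 2) stop("n_neighbors must be >= 2")
  if (min_dist < 0) stop("min_dist must be nonnegative")
  structure(list(method = method, n_neighbors = n_neighbors,
                 min_dist = min_dist, seed = seed),
            class = "embedding_config")
}

#' Project event series into two dimensions
#'
#' @param events `T x n` matrix with one event series per column (as produced
#'   by [prepare_events()] groups), or an `n x T` matrix with
#'   `series_in = "rows"`.
#' @param cfg An [embedding_config()].
#' @param series_in Whether series are `"columns"` (default) or `"rows"`.
#' @return An `n x 2` coordinate matrix of class `embedded_set`. Fewer than
#'   three series are placed deterministically on a unit segment
#'   (passthrough), with a message.
#' @examples
#' X <- matrix(rnorm(200), 20, 10)
#' emb <- embed_2d(X, embedding_config("pca"))
#' dim(emb)
#' @export
embed_2d <- function(events, cfg = embedding_config(), series_in = "columns") {
  stopifnot(inherits(cfg, "embedding_config"))
  X <- if (series_in == "columns") t(events) else as.matrix(events)
  n <- nrow(X)
  if (n < 3) {
    message("fewer than 3 series: using fixed passthrough coordinates")
    pts <- cbind(seq_len(n) - 1, numeric(n))
  } else if (cfg$method == "pca") {
    pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = 2)
    pts <- pc$x
    if (ncol(pts) < 2) pts <- cbind(pts, 0)
  } else {
    nb <- min(cfg$n_neighbors, n - 1)
    pts <- with_seed(cfg$seed,
      uwot::umap(X, n_neighbors = nb, min_dist = cfg$min_dist,
                 n_threads = 1, n_sgd_threads = 0, verbose = FALSE))
  }
  pts <- unname(as.matrix(pts))
  colnames(pts) <- c("x", "y")
  structure(pts, class = c("embedded_set", class(pts)))
}

#' Rescale embedded coordinates to a fixed diameter
#'
#' Rescales a point set so its maximum pairwise Euclidean distance equals
#' `diameter` (1 by default), making the similarity scale `alpha` of the ant
#' dynamics comparable across anatomical regions regardless of the raw
#' embedding span. The clustering stage uses `diameter = 10`, the typical
#' span of a UMAP embedding and the scale against which the default
#' `alpha = 1.5` discriminates: well-separated groups then sit several
#' `alpha` units apart, so foreign objects contribute negative similarity
#' terms instead of weakly positive ones. An all-identical (zero-diameter)
#' point set is left unscaled and flagged.
#'
#' @param points An `n x 2` coordinate matrix.
#' @param diameter Target maximum pairwise distance (default 1).
#' @return The rescaled matrix; attribute `degenerate` is `TRUE` when all
#'   points coincide.
#' @export
normalize_distances <- function(points, diameter = 1) {
  P <- as.matrix(points)
  if (nrow(P) < 2) stop("need at least 2 points")
  dmax <- max_pairwise_distance(P)
  if (dmax == 0) {
    attr(P, "degenerate") <- TRUE
    return(P)
  }
  out <- P * (diameter / dmax)
  attr(out, "degenerate") <- FALSE
  out
}

# Diameter of a 2D point set; via convex hull for large n.
#' @noRd
max_pairwise_distance <- function(P) {
  if (nrow(P) > 600) {
    hull <- grDevices::chull(P[, 1], P[, 2])
    P <- P[hull, , drop = FALSE]
  }
  max(dist(P))
}

#' Build the k-nearest-neighbour digraph of an embedded point set
#'
#' Directed edges run from each point to its `k` nearest neighbours by
#' Euclidean distance (ties broken by lower point index). The digraph feeds
#' the density-based criterion that fixes the number of ROIs.
#'
#' @param points `n x 2` coordinate matrix.
#' @param k Number of neighbours; clamped to `n - 1` with a warning.
#' @return A list of class `knn_graph` with `edges` (data.frame `from`, `to`,
#'   `length`, sorted by length within each source) and `k`, `n`.
#' @examples
#' g <- build_knn_graph(cbind(c(0, 1, 3), 0), k = 1)
#' g$edges
#' @export
build_knn_graph <- function(points, k) {
  P <- as.matrix(points)
  n <- nrow(P)
  if (n < 2) stop("need at least 2 points")
  if (k < 1) stop("k must be >= 1")
  if (k >= n) {
    warning(sprintf("k = %d >= n = %d; clamped to %d", k, n, n - 1L))
    k <- n - 1L
  }
  D <- as.matrix(dist(P))
  from <- integer(n * k); to <- integer(n * k); len <- numeric(n * k)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    ord <- order(d, seq_len(n))[seq_len(k)]  # ties by lower index
    sl <- ((i - 1L) * k + 1L):(i * k)
    from[sl] <- i; to[sl] <- ord; len[sl] <- d[ord]
  }
  structure(list(edges = data.frame(from = from, to = to, length = len),
                 k = k, n = n),
            class = "knn_graph")
}
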