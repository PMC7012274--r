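# Independent textbook implementations of the validity indices, used as
# oracles against the package implementations.
silhouette_oracle <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(vapply(own, d, numeric(1), i = i))
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(k) {
      mean(vapply(which(labels == k), d, numeric(1), i = i))
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

db_oracle <- function(X, labels) {
  X <- as.matrix(X)
  ks <- unique(labels)
  cent <- lapply(ks, function(k) colMeans(X[labels == k, , drop = FALSE]))
  S <- vapply(seq_along(ks), function(k) {
    rows <- which(labels == ks[k])
    mean(vapply(rows, function(i) sqrt(sum((X[i, ] - cent[[k]])^2)),
                numeric(1)))
  }, numeric(1))
  mean(vapply(seq_along(ks), function(i) {
    max(vapply(setdiff(seq_along(ks), i), function(j) {
      (S[i] + S[j]) / sqrt(sum((cent[[i]] - cent[[j]])^2))
    }, numeric(1)))
  }, numeric(1)))
}
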