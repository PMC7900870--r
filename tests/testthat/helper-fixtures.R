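# random fully observed soft similarity matrix
random_soft_S <- function(n, seed) {
  set.seed(seed)
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- runif(n * (n - 1) / 2)
  v <- v + t(v)
  diag(v) <- NA_real_
  similarity_matrix(v)
}

random_partition_of <- function(n, k, seed) {
  set.seed(seed)
  partition(sample.int(k, n, replace = TRUE), k = k)
}

# independent from-scratch affinity (direct pair summation, no shared code
# with the package internals beyond field access)
affinity_direct <- function(p, S) {
  a <- as.integer(p)
  idx <- which(S$observed & upper.tri(S$observed), arr.ind = TRUE)
  terms <- ifelse(a[idx[, 1]] == a[idx[, 2]],
                  S$values[idx], 1 - S$values[idx])
  mean(terms)
}

# deterministic two-dimensional embedding fixture keyed by stem
fixture_embeddings <- function(ab_cos) {
  th <- acos(ab_cos)
  m <- rbind(
    alpha = c(1, 0),
    bravo = c(cos(th), sin(th)),
    charlie = c(0, 1),
    delta = c(-1, 0),
    echo = c(0, -1)
  )
  embedding_provider(m)
}
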