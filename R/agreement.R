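#' Rand index between two hard partitions
#'
#' The fraction of item pairs on which the two partitions agree: both items
#' placed together in both partitions, or apart in both. 1 is perfect
#' agreement.
#'
#' @param p,q Partitions over the same items (anything [as_partition()]
#'   accepts).
#' @return A double in \[0, 1\].
#' @examples
#' rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))
#' @export
rand_index <- function(p, q) {
  ct <- pair_contingency(p, q)
  (choose2(ct$n) + 2 * ct$sum_nij2 - ct$sum_ai2 - ct$sum_bj2) / choose2(ct$n)
}

#' Adjusted Rand index (Hubert-Arabie) between two hard partitions
#'
#' The Rand index corrected for chance agreement given the two partitions'
#' cluster sizes, so random partitions score about 0 regardless of the
#' number of clusters.
#'
#' @inheritParams rand_index
#' @return A double `<= 1`; 1 iff the partitions are identical up to
#'   relabeling.
#' @export
adjusted_rand_index <- function(p, q) {
  ct <- pair_contingency(p, q)
  exp_idx <- ct$sum_ai2 * ct$sum_bj2 / choose2(ct$n)
  max_idx <- (ct$sum_ai2 + ct$sum_bj2) / 2
  if (max_idx == exp_idx) return(1)  # both partitions degenerate and equal
  (ct$sum_nij2 - exp_idx) / (max_idx - exp_idx)
}

# pairwise-count pieces shared by RI and ARI
pair_contingency <- function(p, q) {
  p <- as_partition(p); q <- as_partition(q)
  if (length(p) != length(q)) stop("partitions must cover the same items")
  n <- length(p)
  if (n < 2L) stop("need at least two items")
  tab <- table(as.integer(p), as.integer(q))
  list(
    n = n,
    sum_nij2 = sum(choose2(tab)),
    sum_ai2 = sum(choose2(rowSums(tab))),
    sum_bj2 = sum(choose2(colSums(tab)))
  )
}

choose2 <- function(x) x * (x - 1) / 2

#' Affinity between a hard clustering and a soft similarity matrix
#'
#' The Rand index generalized to a soft validation target: each same-cluster
#' pair contributes its similarity `s_ij`, each split pair contributes
#' `1 - s_ij`, and the sum is normalized by the number of observed pairs.
#' With a fully observed binary matrix this reduces to the Rand index.
#'
#' @param p A partition.
#' @param S A [similarity_matrix()] over the same items.
#' @return A double in \[0, 1\].
#' @export
affinity <- function(p, S) {
  p <- as_partition(p)
  if (length(p) != n_items(S)) stop("partition and matrix sizes differ")
  M <- n_observed_pairs(S)
  if (M == 0L) stop("similarity matrix has no observed pairs")
  a <- as.integer(p)
  same <- outer(a, a, `==`)
  Q <- sum(w_matrix(S)[same & upper.tri(same)])
  (b_sum(S) + Q) / M
}

#' Soft-clustering adjusted Rand index
#'
#' Chance-corrects the affinity of a clustering against a soft similarity
#' matrix: `(RI_m - RI_r) / (1 - RI_r)` where `RI_m` is the affinity of `p`
#' and `RI_r` is the Monte-Carlo mean affinity of random clusterings with the
#' same number of non-empty clusters as `p`.
#'
#' @param p A partition (the model clustering).
#' @param S The validation [similarity_matrix()].
#' @param n_random Number of random clusterings for the chance term.
#' @param seed Optional integer seed; the calling RNG state is restored.
#' @param null Null model for the random clusterings: `"uniform"` assigns
#'   each item independently to one of `k` clusters (default); `"equal"`
#'   draws random clusters of near-equal size.
#' @return A double `<= 1` with attributes `ri_m`, `ri_r`, `n_random`,
#'   `seed`.
#' @export
soft_ari <- function(p, S, n_random = 1000L, seed = NULL,
                     null = c("uniform", "equal")) {
  null <- match.arg(null)
  p <- as_partition(p)
  if (n_random < 1L) stop("n_random must be >= 1")
  if (length(p) != n_items(S)) stop("partition and matrix sizes differ")
  M <- n_observed_pairs(S)
  if (M == 0L) stop("similarity matrix has no observed pairs")
  k <- n_clusters(p)
  ri_m <- affinity(p, S)
  W <- w_matrix(S); B <- b_sum(S)
  ri_r <- with_seed(seed, {
    if (null == "uniform") {
      mean(cpp_random_affinities(W, M, B, k, as.integer(n_random)))
    } else {
      n <- length(p)
      sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
      mean(vapply(seq_len(n_random), function(r) {
        q <- partition(rep(seq_len(k), sizes)[sample.int(n)])
        affinity(q, S)
      }, numeric(1)))
    }
  })
  if (isTRUE(all.equal(ri_r, 1))) {
    stop("degenerate chance term: random clusterings already agree perfectly")
  }
  structure((ri_m - ri_r) / (1 - ri_r),
            ri_m = ri_m, ri_r = ri_r, n_random = n_random, seed = seed)
}

# evaluate code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# bounded deterministic subseed stream (seed, index) -> int in [0, 2^31)
subseed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 69621) %%
               2147483647)
}
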