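#' Coordinate ascent on the affinity from one random start
#'
#' Starts from a uniform-random assignment of items to `k` clusters and
#' repeatedly proposes moving a randomly chosen item to a randomly chosen
#' other cluster, accepting only proposals that strictly increase the
#' affinity. After `n * (k - 1)` consecutive rejections, an exhaustive sweep
#' over all single-item moves either resumes the ascent or certifies that no
#' move improves the affinity (a verified local maximum). Clusters may empty
#' out during the ascent; `k` is an upper bound.
#'
#' @param S A [similarity_matrix()] with at least one observed pair.
#' @param k Maximum number of clusters (`>= 1`).
#' @param seed Optional integer seed (caller RNG state is restored).
#' @param init Optional initial assignment (integer vector in `1..k`);
#'   default is uniform random.
#' @return A `circa_fit`: list with `best` (the [partition()]), `alpha`,
#'   `k`, `restarts`, `proposals`, `accepted`, `seed`.
#' @export
coordinate_ascent <- function(S, k, seed = NULL, init = NULL) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  n <- n_items(S)
  M <- n_observed_pairs(S)
  if (M == 0L) stop("similarity matrix has no observed pairs")
  W <- w_matrix(S); B <- b_sum(S)
  res <- with_seed(seed, {
    if (is.null(init)) init <- sample.int(k, n, replace = TRUE)
    if (length(init) != n || any(init < 1L | init > k)) {
      stop("init must assign every item to a cluster in 1..k")
    }
    cpp_coordinate_ascent(W, M, B, k, as.integer(init) - 1L)
  })
  new_circa_fit(
    best = canonicalize_partition(
      partition(res$assign + 1L, k = k, items = S$items)),
    alpha = res$alpha, k = k, restarts = 1L,
    proposals = res$proposals, accepted = res$accepted, seed = seed
  )
}

#' Fit the consensus clustering by restarted coordinate ascent
#'
#' Runs [coordinate_ascent()] from `n_restarts` independent random
#' initializations and keeps the result with the highest affinity (first
#' occurrence wins ties). Restart `r` uses a subseed derived from `seed` and
#' `r`, so results are reproducible and independent of execution order.
#'
#' @inheritParams coordinate_ascent
#' @param n_restarts Number of random initializations (`>= 1`).
#' @return A `circa_fit` (see [coordinate_ascent()]) with aggregated
#'   `proposals`/`accepted` counters and `restarts = n_restarts`.
#' @export
circa_fit <- function(S, k, n_restarts = 100L, seed = NULL) {
  n_restarts <- as.integer(n_restarts)
  if (n_restarts < 1L) stop("n_restarts must be >= 1")
  best <- NULL
  props <- 0; accs <- 0
  for (r in seq_len(n_restarts)) {
    fit <- coordinate_ascent(
      S, k, seed = if (is.null(seed)) NULL else subseed(seed, r))
    props <- props + fit$proposals
    accs <- accs + fit$accepted
    if (is.null(best) || fit$alpha > best$alpha) best <- fit
  }
  new_circa_fit(best = best$best, alpha = best$alpha, k = as.integer(k),
                restarts = n_restarts, proposals = props, accepted = accs,
                seed = seed)
}

#' Exact affinity maximizer by enumeration (test oracle)
#'
#' Enumerates every partition of the items into at most `k` blocks (as
#' restricted-growth strings, so relabelings are visited once) and returns
#' the global affinity maximum. Only feasible for small instances; guarded
#' at `k^n <= 1e7` candidate assignments.
#'
#' @inheritParams coordinate_ascent
#' @return A `circa_fit` with the globally optimal partition.
#' @export
brute_force_best <- function(S, k) {
  k <- as.integer(k)
  n <- n_items(S)
  if (k^n > 1e7) stop("instance too large to enumerate")
  M <- n_observed_pairs(S)
  if (M == 0L) stop("similarity matrix has no observed pairs")
  W <- w_matrix(S); B <- b_sum(S)
  ut <- upper.tri(W)
  best_a <- NULL; best_alpha <- -Inf; count <- 0L
  a <- integer(n)
  recurse <- function(i, max_used) {
    if (i > n) {
      alpha <- (B + sum(W[outer(a, a, `==`) & ut])) / M
      count <<- count + 1L
      if (alpha > best_alpha) { best_alpha <<- alpha; best_a <<- a }
      return(invisible())
    }
    for (b in seq_len(min(max_used + 1L, k))) {
      a[i] <<- b
      recurse(i + 1L, max(max_used, b))
    }
  }
  recurse(1L, 0L)
  new_circa_fit(best = partition(best_a, k = k, items = S$items),
                alpha = best_alpha, k = k, restarts = count,
                proposals = count, accepted = 0, seed = NULL)
}

new_circa_fit <- function(best, alpha, k, restarts, proposals, accepted,
                          seed) {
  structure(list(best = best, alpha = alpha, k = k, restarts = restarts,
                 proposals = proposals, accepted = accepted, seed = seed),
            class = "circa_fit")
}

#' @export
print.circa_fit <- function(x, ...) {
  cat(sprintf(
    "<circa_fit> alpha = %.4f, %d/%d clusters used, %d restart(s)\n",
    x$alpha, n_clusters(x$best), x$k, x$restarts))
  invisible(x)
}

#' @export
tidy.circa_fit <- function(x, ...) {
  tidy(x$best)
}

#' @export
glance.circa_fit <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, k = x$k, k_used = n_clusters(x$best),
    restarts = x$restarts, proposals = x$proposals,
    accepted = x$accepted, seed = x$seed %||% NA_integer_
  )
}
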