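#' Soft similarity matrices
#'
#' A `circa_similarity` holds, for every item pair, the average co-membership
#' (a value in \[0, 1\]), an observed-pair mask, and the number of judgements
#' contributing to the pair. Free-sorting data yield fully observed matrices;
#' same-different trial data yield sparse ones. The diagonal is unused.
#'
#' @param values Symmetric numeric matrix of pairwise similarities in
#'   \[0, 1\]; `NA` where unobserved.
#' @param observed Symmetric logical matrix marking judged pairs. Defaults to
#'   `!is.na(values)` off the diagonal.
#' @param counts Symmetric integer matrix of judgement counts per pair
#'   (>= 1 wherever observed). Defaults to 1 on observed pairs.
#' @param items Optional character item ids (row/column names).
#' @return An object of class `circa_similarity`.
#' @export
similarity_matrix <- function(values, observed = NULL, counts = NULL,
                              items = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("values must be square")
  if (is.null(observed)) {
    observed <- !is.na(values)
    diag(observed) <- FALSE
  }
  observed <- as.matrix(observed)
  diag(observed) <- FALSE
  if (is.null(counts)) {
    counts <- matrix(0L, n, n)
    counts[observed] <- 1L
  }
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (!isTRUE(all.equal(values[observed & !is.na(values)],
                        t(values)[observed & !is.na(values)]))) {
    stop("values must be symmetric on observed pairs")
  }
  v <- values[observed]
  if (anyNA(v) || any(v < 0 | v > 1)) {
    stop("observed similarities must lie in [0, 1]")
  }
  if (any(counts[observed] < 1L)) stop("observed pairs need counts >= 1")
  values[!observed] <- NA_real_
  if (is.null(items)) items <- rownames(values) %||% as.character(seq_len(n))
  dimnames(values) <- dimnames(observed) <- dimnames(counts) <-
    list(items, items)
  structure(list(values = values, observed = observed, counts = counts,
                 items = as.character(items)),
            class = "circa_similarity")
}

#' @export
print.circa_similarity <- function(x, ...) {
  n <- n_items(x)
  cat(sprintf(
    "<circa_similarity> %d items, %d/%d pairs observed (%.2f%%)\n",
    n, n_observed_pairs(x), n * (n - 1L) / 2,
    100 * n_observed_pairs(x) / (n * (n - 1L) / 2)))
  invisible(x)
}

#' @rdname similarity_matrix
#' @param S A `circa_similarity`.
#' @export
n_items <- function(S) length(S$items)

#' @rdname similarity_matrix
#' @export
n_observed_pairs <- function(S) sum(S$observed[upper.tri(S$observed)])

#' @export
tidy.circa_similarity <- function(x, ...) {
  idx <- which(x$observed & upper.tri(x$observed), arr.ind = TRUE)
  tibble::tibble(
    item_i = x$items[idx[, 1L]],
    item_j = x$items[idx[, 2L]],
    value  = x$values[idx],
    count  = x$counts[idx]
  )
}

# centered agreement weights: w_ij = 2 s_ij - 1 on observed pairs, 0 elsewhere.
# affinity(c, S) = (b_sum + sum_{same-cluster observed pairs} w_ij) / n_obs
w_matrix <- function(S) {
  w <- 2 * S$values - 1
  w[!S$observed] <- 0
  diag(w) <- 0
  w
}

b_sum <- function(S) {
  ut <- upper.tri(S$values)
  sum(1 - S$values[ut & S$observed])
}

#' Binary co-membership matrix of a partition
#'
#' Codes each item pair as 1 if both items share a cluster and 0 otherwise —
#' the similarity matrix implied by a single participant's sort.
#'
#' @param p A [partition()] (or anything [as_partition()] accepts).
#' @return A fully observed binary `circa_similarity` with unit counts.
#' @examples
#' comembership(partition(c(1, 1, 2)))
#' @export
comembership <- function(p) {
  p <- as_partition(p)
  a <- as.integer(p)
  v <- 1 * outer(a, a, `==`)
  diag(v) <- NA_real_
  similarity_matrix(v, items = item_ids(p))
}

#' Average co-membership across participants' sorts
#'
#' Each sort is converted to a binary co-membership matrix and the matrices
#' are averaged, giving the soft consensus similarity matrix `S` whose entry
#' is the fraction of participants placing the pair in one category.
#'
#' @param sorts Either a list of partitions over a common item set, or a
#'   long-format data frame with columns `participant`, `item`, `cluster`.
#' @return A fully observed `circa_similarity`; counts equal the number of
#'   participants.
#' @export
average_sorts <- function(sorts) {
  parts <- sorts_as_partitions(sorts)
  if (length(parts) == 0L) stop("no sorts supplied")
  ids <- item_ids(parts[[1L]])
  acc <- matrix(0, length(ids), length(ids))
  for (p in parts) {
    if (!identical(item_ids(p), ids)) {
      stop("all sorts must cover the same item set")
    }
    a <- as.integer(p)
    acc <- acc + outer(a, a, `==`)
  }
  v <- acc / length(parts)
  diag(v) <- NA_real_
  cnt <- matrix(length(parts), length(ids), length(ids))
  diag(cnt) <- 0L
  similarity_matrix(v, counts = cnt, items = ids)
}

# normalize sorts input to a list of partitions over a shared, sorted item set
sorts_as_partitions <- function(sorts) {
  if (is.data.frame(sorts)) {
    req <- c("participant", "item", "cluster")
    if (!all(req %in% names(sorts))) {
      stop("sorts data frame needs columns participant, item, cluster")
    }
    items <- sort(unique(as.character(sorts$item)))
    split(sorts, sorts$participant) |>
      lapply(function(d) {
        d <- d[order(match(as.character(d$item), items)), , drop = FALSE]
        if (anyDuplicated(d$item)) stop("duplicate (participant, item) rows")
        if (!identical(as.character(d$item), items)) {
          stop("every participant must sort every item")
        }
        partition(d$cluster, items = items)
      }) |>
      unname()
  } else if (inherits(sorts, "circa_partition")) {
    list(sorts)
  } else {
    lapply(sorts, as_partition)
  }
}

#' Accumulate same-different trials into a sparse similarity matrix
#'
#' For each judged pair, the similarity is the fraction of trials answered
#' "same"; pairs never judged are unobserved. Contradictory judgements on a
#' pair are averaged, never discarded.
#'
#' @param trials Data frame with columns `item_i`, `item_j`, `same` (logical
#'   or 0/1); extra columns are ignored.
#' @param items Optional character vector fixing the item universe and order;
#'   defaults to the sorted union of ids seen in `trials`.
#' @return A sparse `circa_similarity`.
#' @export
accumulate_trials <- function(trials, items = NULL) {
  req <- c("item_i", "item_j", "same")
  if (!all(req %in% names(trials))) {
    stop("trials need columns item_i, item_j, same")
  }
  ii <- as.character(trials$item_i)
  jj <- as.character(trials$item_j)
  if (any(ii == jj)) stop("a trial must compare two distinct items")
  if (is.null(items)) items <- sort(unique(c(ii, jj)))
  items <- as.character(items)
  i <- match(ii, items)
  j <- match(jj, items)
  if (anyNA(i) || anyNA(j)) stop("trial item ids outside the item universe")
  lo <- pmin(i, j); hi <- pmax(i, j)
  same <- as.numeric(trials$same)
  if (anyNA(same) || any(!same %in% c(0, 1))) {
    stop("`same` must be logical or 0/1")
  }
  n <- length(items)
  key <- (lo - 1) * n + hi
  cnt_by <- tapply(same, key, length)
  sum_by <- tapply(same, key, sum)
  ks <- as.numeric(names(cnt_by))
  lo2 <- (ks - 1) %/% n + 1
  hi2 <- (ks - 1) %% n + 1
  v <- matrix(NA_real_, n, n)
  cnt <- matrix(0L, n, n)
  val <- as.numeric(sum_by) / as.numeric(cnt_by)
  v[cbind(lo2, hi2)] <- val
  v[cbind(hi2, lo2)] <- val
  cnt[cbind(lo2, hi2)] <- as.integer(cnt_by)
  cnt[cbind(hi2, lo2)] <- as.integer(cnt_by)
  similarity_matrix(v, observed = cnt > 0L, counts = cnt, items = items)
}

#' Greedily select the most densely judged subset of items
#'
#' Sparse same-different data leave most pairs unobserved; restricting
#' analysis to a densely connected subset reduces missingness. The seed item
#' has the largest number of unique observed pairings; each subsequent item
#' maximizes its judgement total (count-weighted connections) with the items
#' already selected. Ties go to the lowest item index.
#'
#' @param S A `circa_similarity`.
#' @param m Number of items to select (`m <= n_items(S)`).
#' @param growth Connection measure for the growth step: total judgement
#'   counts (`"judgements"`, default) or unique observed pairs (`"pairs"`).
#' @return Character vector of `m` selected item ids, in selection order.
#' @export
densest_subset <- function(S, m, growth = c("judgements", "pairs")) {
  growth <- match.arg(growth)
  n <- n_items(S)
  if (m > n) stop("m exceeds the number of items")
  if (n_observed_pairs(S) == 0L) stop("similarity matrix has no observed pairs")
  deg <- rowSums(S$observed)
  sel <- which.max(deg)  # ties -> lowest index
  weight <- if (growth == "judgements") S$counts else 1 * S$observed
  in_sel <- rep(FALSE, n)
  in_sel[sel] <- TRUE
  conn <- weight[, sel]
  while (sum(in_sel) < m) {
    conn[in_sel] <- -Inf
    nxt <- which.max(conn)
    in_sel[nxt] <- TRUE
    sel <- c(sel, nxt)
    conn <- conn + weight[, nxt]
  }
  S$items[sel]
}

#' Restrict a similarity matrix to a subset of items
#'
#' @param S A `circa_similarity`.
#' @param items Character ids (or integer indices) to keep.
#' @return The sub-matrix `circa_similarity` over `items`.
#' @export
subset_similarity <- function(S, items) {
  idx <- if (is.character(items)) match(items, S$items) else as.integer(items)
  if (anyNA(idx)) stop("unknown item ids")
  similarity_matrix(S$values[idx, idx, drop = FALSE],
                    observed = S$observed[idx, idx, drop = FALSE],
                    counts = S$counts[idx, idx, drop = FALSE],
                    items = S$items[idx])
}
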