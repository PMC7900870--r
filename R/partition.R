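#' Hard partition of items into categories
#'
#' A partition assigns each of `n` items to exactly one of at most `k`
#' clusters. Cluster ids are dense integers `1..k`; `k` is an upper bound, so
#' some clusters may be empty (the effective number of clusters is
#' [n_clusters()]). Items may carry external string ids via `items`.
#'
#' @param assignments Integer, character or factor vector of per-item cluster
#'   memberships. Non-integer inputs are coded to dense integers in order of
#'   first appearance.
#' @param k Upper bound on the number of clusters. Defaults to the number of
#'   distinct assignments.
#' @param items Optional character vector of item ids (same length as
#'   `assignments`).
#' @return An object of class `circa_partition`: an integer vector with
#'   attributes `k` and (optionally) `items`.
#' @examples
#' p <- partition(c(1, 1, 2, 2, 3))
#' n_clusters(p)
#' @export
partition <- function(assignments, k = NULL, items = NULL) {
  if (length(assignments) < 1L) stop("a partition needs at least one item")
  if (!is.numeric(assignments)) {
    assignments <- as.integer(factor(assignments, levels = unique(assignments)))
  }
  a <- as.integer(assignments)
  if (anyNA(a)) stop("assignments must not contain NA")
  if (any(a < 1L)) stop("cluster ids must be >= 1")
  if (is.null(k)) k <- max(a)
  k <- as.integer(k)
  if (k < max(a)) stop("k is smaller than the largest cluster id used")
  if (!is.null(items)) {
    if (length(items) != length(a)) stop("items must match assignments in length")
    names(a) <- as.character(items)
  }
  structure(a, k = k, class = "circa_partition")
}

#' @export
print.circa_partition <- function(x, ...) {
  cat(sprintf("<circa_partition> %d items, %d/%d non-empty clusters\n",
              length(x), n_clusters(x), attr(x, "k")))
  invisible(x)
}

#' Coerce to a partition
#'
#' @param x A `circa_partition`, a bare vector of cluster memberships, or a
#'   data frame with columns `item` and `cluster`.
#' @param ... Passed to [partition()].
#' @return A `circa_partition`.
#' @export
as_partition <- function(x, ...) {
  if (inherits(x, "circa_partition")) return(x)
  if (is.data.frame(x)) {
    if (!all(c("item", "cluster") %in% names(x))) {
      stop("data-frame input needs columns `item` and `cluster`")
    }
    x <- x[order(x$item), , drop = FALSE]
    return(partition(x$cluster, items = x$item, ...))
  }
  partition(x, ...)
}

#' Number of non-empty clusters of a partition
#'
#' @param p A `circa_partition`.
#' @return Integer count of clusters with at least one member.
#' @export
n_clusters <- function(p) {
  length(unique(as.integer(p)))
}

#' Allowed number of clusters (upper bound) of a partition
#'
#' @param p A `circa_partition`.
#' @return The `k` bound the partition was created with.
#' @export
k_bound <- function(p) {
  attr(p, "k") %||% max(as.integer(p))
}

#' Item ids of a partition
#'
#' @param p A `circa_partition`.
#' @return Character item ids; defaults to `"1".."n"` when none were given.
#' @export
item_ids <- function(p) {
  names(p) %||% as.character(seq_along(p))
}

# relabel clusters to dense 1..m in order of first appearance;
# agreement indices are invariant to this, optimizer output is canonicalized.
canonicalize_partition <- function(p) {
  a <- as.integer(factor(as.integer(p), levels = unique(as.integer(p))))
  partition(a, k = k_bound(p), items = names(p))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.circa_partition <- function(x, ...) {
  tibble::tibble(item = item_ids(x), cluster = as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
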