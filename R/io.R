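#' Read free-sorting data from CSV
#'
#' Expects a long-form CSV with header `participant,item,cluster` and,
#' optionally, a labels CSV with header `participant,cluster,label`. Every
#' participant must assign every item exactly once; duplicate
#' (participant, item) rows are an error reported with their line numbers.
#'
#' @param path Sorts CSV path.
#' @param labels_path Optional labels CSV path.
#' @return A list with `sorts` (tibble) and `labels` (tibble or `NULL`).
#' @export
read_sorts <- function(path, labels_path = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("participant", "item", "cluster")
  if (!all(req %in% names(d))) {
    stop("sorts file needs columns participant, item, cluster")
  }
  dup <- duplicated(d[, c("participant", "item")])
  if (any(dup)) {
    stop("duplicate (participant, item) rows at line(s): ",
         paste(which(dup) + 1L, collapse = ", "))  # +1 for the header line
  }
  d$participant <- as.character(d$participant)
  d$item <- as.character(d$item)
  sorts_as_partitions(d)  # validates coverage and cluster sanity
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- readr::read_csv(labels_path, show_col_types = FALSE)
    if (!all(c("participant", "cluster", "label") %in% names(labels))) {
      stop("labels file needs columns participant, cluster, label")
    }
    labels$participant <- as.character(labels$participant)
  }
  list(sorts = tibble::as_tibble(d), labels = labels)
}

#' Write free-sorting data to CSV
#'
#' @param sorts Tibble (`participant`, `item`, `cluster`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sorts <- function(sorts, path) {
  readr::write_csv(sorts[, c("participant", "item", "cluster")], path)
  invisible(path)
}

#' Read same-different trials from CSV
#'
#' Expects header `item_i,item_j,same` with optional `participant` and
#' `left_label` columns; `same` is 0/1.
#'
#' @param path Trials CSV path.
#' @return A tibble of trials.
#' @export
read_trials <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("item_i", "item_j", "same")
  if (!all(req %in% names(d))) {
    stop("trials file needs columns item_i, item_j, same")
  }
  bad <- which(!d$same %in% c(0, 1))
  if (length(bad) > 0) {
    stop("non-binary `same` at line(s): ", paste(bad + 1L, collapse = ", "))
  }
  d$item_i <- as.character(d$item_i)
  d$item_j <- as.character(d$item_j)
  tibble::as_tibble(d)
}

#' @rdname read_trials
#' @param trials Tibble of trials.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' Write a clustering to CSV
#'
#' Writes `item,cluster` rows (plus `primary_label`/`secondary_label`
#' columns when a label assignment is supplied), ordered by item id.
#'
#' @param p A [partition()] or `circa_fit`.
#' @param path Output CSV path.
#' @param labels Optional `circa_labels` (from
#'   [score_and_assign_labels()]).
#' @return `path`, invisibly.
#' @export
write_clustering <- function(p, path, labels = NULL) {
  if (inherits(p, "circa_fit")) p <- p$best
  d <- tidy(as_partition(p))
  d <- d[order(d$item), , drop = FALSE]
  if (!is.null(labels)) {
    a <- labels$assignments
    d$primary_label <- a$primary[match(d$cluster, a$group_category)]
    d$secondary_label <- a$secondary[match(d$cluster, a$group_category)]
  }
  readr::write_csv(d, path)
  invisible(path)
}

#' Read a clustering written by [write_clustering()]
#'
#' @param path Clustering CSV path.
#' @return A [partition()] (label columns, if present, are attached as the
#'   attribute `label_table`).
#' @export
read_clustering <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("item", "cluster") %in% names(d))) {
    stop("clustering file needs columns item, cluster")
  }
  p <- as_partition(as.data.frame(d[, c("item", "cluster")]))
  if ("primary_label" %in% names(d)) attr(p, "label_table") <- d
  p
}

#' Read/write a sparse similarity matrix as a triplet CSV
#'
#' The triplet format is `i,j,value,count` with one row per observed pair
#' (string item ids).
#'
#' @param S A [similarity_matrix()].
#' @param path CSV path.
#' @return `write_similarity`: `path` invisibly; `read_similarity`: a
#'   `circa_similarity`.
#' @export
write_similarity <- function(S, path) {
  d <- tidy(S)
  names(d) <- c("i", "j", "value", "count")
  readr::write_csv(d, path)
  invisible(path)
}

#' @rdname write_similarity
#' @param items Optional item universe (unobserved items are otherwise
#'   absent from the triplets and would be dropped).
#' @export
read_similarity <- function(path, items = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("i", "j", "value", "count") %in% names(d))) {
    stop("similarity file needs columns i, j, value, count")
  }
  if (is.null(items)) {
    items <- sort(unique(c(as.character(d$i), as.character(d$j))))
  }
  n <- length(items)
  ii <- match(as.character(d$i), items)
  jj <- match(as.character(d$j), items)
  if (anyNA(ii) || anyNA(jj)) stop("triplet ids outside the item universe")
  v <- matrix(NA_real_, n, n)
  cnt <- matrix(0L, n, n)
  v[cbind(ii, jj)] <- d$value; v[cbind(jj, ii)] <- d$value
  cnt[cbind(ii, jj)] <- as.integer(d$count)
  cnt[cbind(jj, ii)] <- as.integer(d$count)
  similarity_matrix(v, observed = cnt > 0, counts = cnt, items = items)
}

#' Write a run manifest
#'
#' Records a command name, configuration snapshot, seed(s), input file
#' digests, package version and output paths as JSON next to a run's
#' outputs, so deterministic runs can be reproduced bit for bit.
#'
#' @param path Manifest JSON path.
#' @param command Command or analysis name.
#' @param config List of effective parameters.
#' @param seed Seed(s) used.
#' @param inputs Character vector of input file paths (digested with md5).
#' @param outputs Character vector of output file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config = list(), seed = NULL,
                           inputs = character(0), outputs = character(0)) {
  digests <- vapply(inputs, function(f) {
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  }, character(1))
  jsonlite::write_json(list(
    command = command,
    config = config,
    seed = seed,
    inputs = as.list(digests),
    package_version = as.character(utils::packageVersion("circaclust")),
    outputs = outputs,
    timestamp = format(Sys.time(), tz = "UTC")
  ), path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}
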