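#' Reduce a free-text label to a stem
#'
#' Case-folds, trims, and strips common English inflectional suffixes
#' (plural -s/-es/-ies, -ing, -ed) token by token, so "Farm", "farms" and
#' "Farming" collapse to one stem. Multi-word labels are stemmed per token
#' and rejoined with single spaces. This is a deliberately light stemmer:
#' it handles the regular inflections participants produce when naming
#' categories, not irregular morphology.
#'
#' @param label Character vector of labels.
#' @return Character vector of stems.
#' @examples
#' stem_label(c("Farms", "farming", "Pebbly Beaches"))
#' @export
stem_label <- function(label) {
  vapply(as.character(label), function(s) {
    tokens <- strsplit(trimws(tolower(s)), "\\s+")[[1]]
    paste(vapply(tokens, stem_token, character(1)), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

stem_token <- function(w) {
  # plural endings
  if (grepl("sses$", w)) w <- sub("es$", "", w)
  else if (grepl("ies$", w) && nchar(w) > 4L) w <- sub("ies$", "y", w)
  else if (grepl("(ch|sh|x|z|s)es$", w)) w <- sub("es$", "", w)
  else if (grepl("[^su]s$", w)) w <- sub("s$", "", w)
  # participles
  if (grepl("ing$", w) && nchar(w) >= 6L) w <- sub("ing$", "", w)
  else if (grepl("ed$", w) && nchar(w) >= 5L) w <- sub("ed$", "", w)
  w
}

#' Deterministic word-embedding provider
#'
#' Wraps a table of word vectors behind the two queries the labeling
#' pipeline needs: `vector(label)` (unit vector) and `similarity(a, b)`
#' (cosine). Rows are keyed by stem ([stem_label()] is applied to queries).
#' Real embedding backends (GloVe, spaCy, word2vec) can be adapted by
#' supplying their vectors as the table; tests ship small deterministic
#' fixtures.
#'
#' @param vectors Numeric matrix, one row per label (rownames are the
#'   labels); rows are normalized to unit length.
#' @param strict Error on unknown labels (`TRUE`, default) or return `NA`.
#' @return An object of class `circa_embeddings` with elements `vector` and
#'   `similarity` (functions) and `labels`.
#' @export
embedding_provider <- function(vectors, strict = TRUE) {
  vectors <- as.matrix(vectors)
  if (is.null(rownames(vectors))) stop("vectors need rownames (the labels)")
  rownames(vectors) <- stem_label(rownames(vectors))
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) stop("zero-length embedding vector")
  vectors <- vectors / nrm
  lookup <- function(label) {
    key <- stem_label(label)
    if (!key %in% rownames(vectors)) {
      if (strict) stop(sprintf("no embedding for label '%s'", label))
      return(rep(NA_real_, ncol(vectors)))
    }
    vectors[key, ]
  }
  structure(list(
    vector = lookup,
    similarity = function(a, b) sum(lookup(a) * lookup(b)),
    labels = rownames(vectors)
  ), class = "circa_embeddings")
}

#' Read fixture embeddings from a TSV file
#'
#' Expects `label<TAB>v1<TAB>...<TAB>vd` rows without a header.
#'
#' @param path File path.
#' @return A numeric matrix with labels as rownames, ready for
#'   [embedding_provider()].
#' @export
read_embeddings <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  colnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

#' Agreement between one consensus category and one participant category
#'
#' Both partitions are binarized — the target cluster versus all other
#' clusters merged into a single second category — and compared with the
#' hard adjusted Rand index. This isolates how well the participant's
#' category describes the consensus category while holding everything else
#' constant.
#'
#' @param group Consensus partition.
#' @param g Cluster id of the consensus category.
#' @param sort A participant's partition.
#' @param c Cluster id of the participant category.
#' @return A double (the binarized ARI).
#' @export
partial_category_ari <- function(group, g, sort, c) {
  group <- as_partition(group); sort <- as_partition(sort)
  bg <- binarize_cluster(group, g, "group")
  bc <- binarize_cluster(sort, c, "participant")
  adjusted_rand_index(bg, bc)
}

binarize_cluster <- function(p, id, what) {
  inside <- as.integer(p) == id
  if (!any(inside)) stop(sprintf("empty %s cluster %s", what, id))
  if (all(inside)) {
    stop(sprintf("%s cluster %s spans all items: binarization degenerate",
                 what, id))
  }
  partition(ifelse(inside, 1L, 2L), items = item_ids(p))
}

#' Score participant labels against consensus categories and assign names
#'
#' For every consensus category, the partial ARI ([partial_category_ari()])
#' against every participant category credits that category's labels; labels
#' sharing a stem are pooled, and scores are summed across participants and
#' repeated uses. The top-scoring stem becomes the category's primary label.
#' A secondary label is added when a stem both scores at least
#' `norm_threshold` after min-max normalization within the category and has
#' embedding similarity to the primary below `sim_threshold` (it carries new
#' meaning and is strongly associated with the category).
#'
#' @param group Consensus partition.
#' @param sorts Long data frame (`participant`, `item`, `cluster`) or a
#'   named list of partitions.
#' @param labels Data frame (`participant`, `cluster`, `label`), 1-5 labels
#'   per participant cluster.
#' @param provider An [embedding_provider()] used for the semantic-novelty
#'   check.
#' @param sim_threshold Maximum similarity to the primary label for a
#'   secondary label (default 0.50).
#' @param norm_threshold Minimum normalized score for a secondary label
#'   (default 0.65).
#' @return A `circa_labels` object: `scores` (one row per category x stem:
#'   `group_category`, `stem`, `summed_ari`, `normalized_ari`) and
#'   `assignments` (`group_category`, `primary`, `secondary`).
#' @export
score_and_assign_labels <- function(group, sorts, labels, provider,
                                    sim_threshold = 0.50,
                                    norm_threshold = 0.65) {
  group <- as_partition(group)
  parts <- named_sorts(sorts)
  labels <- tibble::as_tibble(labels)
  req <- c("participant", "cluster", "label")
  if (!all(req %in% names(labels))) {
    stop("labels need columns participant, cluster, label")
  }
  if (any(!nzchar(trimws(labels$label)))) stop("empty label string")
  labels$participant <- as.character(labels$participant)
  labels$stem <- stem_label(labels$label)

  score_rows <- list()
  for (g in sort(unique(as.integer(group)))) {
    credit <- new.env(parent = emptyenv())
    for (pname in names(parts)) {
      part <- parts[[pname]]
      for (cl in sort(unique(as.integer(part)))) {
        if (all(as.integer(part) == cl)) next  # degenerate one-block sort
        a <- partial_category_ari(group, g, part, cl)
        stems <- labels$stem[labels$participant == pname &
                               labels$cluster == cl]
        for (st in stems) {
          credit[[st]] <- (credit[[st]] %||% 0) + a
        }
      }
    }
    stems <- sort(ls(credit))
    if (length(stems) == 0L) {
      stop(sprintf("no labels credited to consensus category %d", g))
    }
    summed <- vapply(stems, function(st) credit[[st]], numeric(1))
    rng <- range(summed)
    normalized <- if (diff(rng) == 0) rep(1, length(summed)) else
      (summed - rng[1]) / diff(rng)
    score_rows[[length(score_rows) + 1L]] <- tibble::tibble(
      group_category = g, stem = stems, summed_ari = unname(summed),
      normalized_ari = unname(normalized))
  }
  scores <- dplyr::bind_rows(score_rows)

  assignments <- scores |>
    dplyr::group_by(.data$group_category) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(-d$summed_ari, d$stem), , drop = FALSE]
      primary <- d$stem[1L]
      cand <- d[-1L, , drop = FALSE]
      cand <- cand[cand$normalized_ari >= norm_threshold, , drop = FALSE]
      secondary <- NA_character_
      for (st in cand$stem) {
        if (provider$similarity(st, primary) < sim_threshold) {
          secondary <- st
          break
        }
      }
      tibble::tibble(primary = primary, secondary = secondary)
    }) |>
    dplyr::ungroup()

  structure(list(scores = scores, assignments = assignments),
            class = "circa_labels")
}

named_sorts <- function(sorts) {
  if (is.data.frame(sorts)) {
    pids <- unique(as.character(sorts$participant))
    parts <- sorts_as_partitions(sorts)
    names(parts) <- sort(pids)  # split() orders by participant id
    parts
  } else {
    if (is.null(names(sorts))) names(sorts) <- as.character(seq_along(sorts))
    lapply(sorts, as_partition)
  }
}

#' @export
print.circa_labels <- function(x, ...) {
  print(x$assignments)
  invisible(x)
}

#' @export
tidy.circa_labels <- function(x, ...) x$scores

#' Labelled word-vector set
#'
#' Holds unit word vectors, each assigned to exactly one category — the
#' representation behind centroid naming and the between/within variance
#' F-ratio.
#'
#' @param vectors Numeric matrix, one row per label occurrence (rownames are
#'   labels); rows are normalized to unit length.
#' @param categories Category assignment per row.
#' @return An object of class `circa_wvs`.
#' @export
word_vector_set <- function(vectors, categories) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != length(categories)) {
    stop("one category per vector required")
  }
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) stop("zero-length word vector")
  vectors <- vectors / nrm
  structure(list(vectors = vectors,
                 categories = as.character(categories)),
            class = "circa_wvs")
}

#' Name categories by their centroid word vector
#'
#' Each category is summarized by the mean of its members' unit vectors and
#' named by the vocabulary entry with the highest cosine to that centroid
#' (ties broken lexicographically).
#'
#' @param wvs A [word_vector_set()].
#' @param vocabulary Numeric matrix of candidate labels (rownames) by
#'   embedding dimension.
#' @return A tibble with `category` and `label`.
#' @export
centroid_label <- function(wvs, vocabulary) {
  vocabulary <- as.matrix(vocabulary)
  if (nrow(vocabulary) == 0L) stop("empty vocabulary")
  vnorm <- vocabulary / sqrt(rowSums(vocabulary^2))
  ord <- order(rownames(vnorm))
  vnorm <- vnorm[ord, , drop = FALSE]  # lexicographic tie-break via which.max
  cats <- sort(unique(wvs$categories))
  labs <- vapply(cats, function(ct) {
    centroid <- colMeans(wvs$vectors[wvs$categories == ct, , drop = FALSE])
    cn <- sqrt(sum(centroid^2))
    if (cn == 0) return(rownames(vnorm)[1L])
    cos <- as.numeric(vnorm %*% (centroid / cn))
    rownames(vnorm)[which.max(round(cos, 12))]
  }, character(1))
  tibble::tibble(category = cats, label = unname(labs))
}

#' Between/within variance ratio of labelled word vectors
#'
#' Quantifies how well a category system separates label meanings:
#' `F = (D_between / (k - 1)) / (D_within / (N - k))`, with `D_between` the
#' summed squared Euclidean distance from the grand-mean vector to the
#' category means and `D_within` the summed squared distance from category
#' means to their member vectors. By default `D_between` terms are weighted
#' by category size, matching the one-way ANOVA between-group sum of
#' squares; `weighted = FALSE` gives each category mean unit weight.
#'
#' @param wvs A [word_vector_set()] with `N > k >= 2`.
#' @param weighted Weight between-category terms by category size
#'   (default `TRUE`).
#' @return A non-negative double; `Inf` when categories are internally
#'   identical but mutually distinct (`D_within = 0`).
#' @export
f_ratio <- function(wvs, weighted = TRUE) {
  cats <- unique(wvs$categories)
  k <- length(cats)
  N <- nrow(wvs$vectors)
  if (k < 2L) stop("need at least two categories")
  if (N <= k) stop("need more vectors than categories")
  grand <- colMeans(wvs$vectors)
  d_between <- 0; d_within <- 0
  for (ct in cats) {
    members <- wvs$vectors[wvs$categories == ct, , drop = FALSE]
    ctr <- colMeans(members)
    w <- if (weighted) nrow(members) else 1
    d_between <- d_between + w * sum((ctr - grand)^2)
    d_within <- d_within + sum(sweep(members, 2, ctr)^2)
  }
  if (d_within == 0) {
    if (d_between == 0) return(0)
    return(Inf)
  }
  (d_between / (k - 1)) / (d_within / (N - k))
}
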