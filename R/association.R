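#' Tally category votes per item and dimension
#'
#' Aggregates raw classification responses into per-(item, dimension)
#' category vote counts, the modal category (ties broken lexicographically)
#' and the interparticipant agreement (modal votes / total votes).
#'
#' @param responses Data frame with columns `item`, `dimension`, `category`,
#'   and optionally `count` (pre-tallied votes) and `participant`.
#' @return A tibble with one row per (item, dimension):
#'   `item`, `dimension`, `modal`, `agreement`, `total_votes`.
#' @export
vote_table <- function(responses) {
  v <- vote_counts(responses)
  v |>
    dplyr::group_by(.data$item, .data$dimension) |>
    dplyr::arrange(dplyr::desc(.data$votes), .data$category,
                   .by_group = TRUE) |>
    dplyr::summarise(
      modal = .data$category[1L],
      agreement = .data$votes[1L] / sum(.data$votes),
      total_votes = sum(.data$votes),
      .groups = "drop"
    )
}

vote_counts <- function(responses) {
  req <- c("item", "dimension", "category")
  if (!all(req %in% names(responses))) {
    stop("responses need columns item, dimension, category")
  }
  responses <- tibble::as_tibble(responses)
  if (!"count" %in% names(responses)) responses$count <- 1L
  responses |>
    dplyr::mutate(item = as.character(.data$item),
                  dimension = as.character(.data$dimension),
                  category = as.character(.data$category)) |>
    dplyr::group_by(.data$item, .data$dimension, .data$category) |>
    dplyr::summarise(votes = sum(.data$count), .groups = "drop")
}

#' Phi coefficients between two categorical labelings
#'
#' For every pair of categories (one from each labeling) the items are coded
#' as binary members/non-members and the Pearson correlation of the two
#' indicators — the phi coefficient — is computed. A category whose
#' indicator is constant (all items in, or all out) yields `NA`, not 0.
#'
#' @param memberships_a,memberships_b Data frames with columns `item` and
#'   `category` (one category per item), or named vectors keyed by item.
#' @return A numeric matrix, categories of `memberships_a` in rows and of
#'   `memberships_b` in columns.
#' @export
phi_matrix <- function(memberships_a, memberships_b) {
  a <- membership_vector(memberships_a)
  b <- membership_vector(memberships_b)
  items <- intersect(names(a), names(b))
  if (length(items) < 2L) stop("need at least two shared items")
  a <- a[items]; b <- b[items]
  cats_a <- sort(unique(a)); cats_b <- sort(unique(b))
  out <- matrix(NA_real_, length(cats_a), length(cats_b),
                dimnames = list(cats_a, cats_b))
  for (ca in cats_a) {
    x <- as.numeric(a == ca)
    if (stats::sd(x) == 0) next
    for (cb in cats_b) {
      y <- as.numeric(b == cb)
      if (stats::sd(y) == 0) next
      out[ca, cb] <- stats::cor(x, y)
    }
  }
  out
}

membership_vector <- function(m) {
  if (is.data.frame(m)) {
    if (!all(c("item", "category") %in% names(m))) {
      stop("memberships need columns item and category")
    }
    stats::setNames(as.character(m$category), as.character(m$item))
  } else {
    if (is.null(names(m))) stop("membership vectors must be named by item")
    stats::setNames(as.character(m), names(m))
  }
}

#' Bayes classification of one category dimension from others
#'
#' Predicts each item's modal category on a target dimension from its modal
#' categories on predictor dimensions, using MAP decisions under one of
#' three models: `prior_only` (always the most probable target category),
#' `naive` (the product of per-predictor conditional probabilities, treating
#' predictors as independent), or `joint` (the conditional given the full
#' predictor combination). Conditional tables use add-`smoothing` (Laplace)
#' regularization; MAP ties break toward the higher-prior category, then
#' lexicographically.
#'
#' Cross-validation is leave-one-out over `"images"` (hold out one item;
#' train on the remaining items' modal labels; score against the held-out
#' item's modal label) or over `"participants"` (hold out one participant;
#' train on the remaining participants' modal labels; score predictions
#' against the held-out participant's raw responses).
#'
#' @param responses Raw responses (`item`, `dimension`, `category`, plus
#'   `participant` for `loocv = "participants"`).
#' @param target Target dimension name.
#' @param predictors Character vector of predictor dimension names.
#' @param mode `"naive"`, `"joint"`, or `"prior_only"`.
#' @param loocv `"images"` or `"participants"`.
#' @param smoothing Additive smoothing constant (default 1).
#' @return A `circa_bayes` object with `accuracy`, `confusion` (true x
#'   predicted matrix), and the configuration.
#' @export
bayes_classify <- function(responses, target, predictors,
                           mode = c("naive", "joint", "prior_only"),
                           loocv = c("images", "participants"),
                           smoothing = 1) {
  mode <- match.arg(mode)
  loocv <- match.arg(loocv)
  responses <- tibble::as_tibble(responses)
  dims <- c(target, predictors)
  counts <- vote_counts(responses)
  target_cats <- sort(unique(counts$category[counts$dimension == target]))
  if (length(target_cats) < 2L) stop("need at least two target categories")

  if (loocv == "images") {
    modal <- modal_wide(counts, dims)
    truth <- character(0); pred <- character(0)
    for (i in seq_len(nrow(modal))) {
      model <- fit_bayes_tables(modal[-i, , drop = FALSE], target,
                                predictors, mode, smoothing, target_cats)
      pred <- c(pred, predict_bayes(model, modal[i, , drop = FALSE]))
      truth <- c(truth, modal[[target]][i])
    }
  } else {
    if (!"participant" %in% names(responses)) {
      stop("participant LOOCV needs a participant column")
    }
    pids <- unique(as.character(responses$participant))
    if (length(pids) < 2L) stop("need at least two participants")
    truth <- character(0); pred <- character(0)
    for (p in pids) {
      train <- responses[as.character(responses$participant) != p, ,
                         drop = FALSE]
      modal <- modal_wide(vote_counts(train), dims)
      model <- fit_bayes_tables(modal, target, predictors, mode, smoothing,
                                target_cats)
      held <- responses[as.character(responses$participant) == p &
                          responses$dimension == target, , drop = FALSE]
      held <- held[as.character(held$item) %in% modal$item, , drop = FALSE]
      idx <- match(as.character(held$item), modal$item)
      for (r in seq_len(nrow(held))) {
        pred <- c(pred, predict_bayes(model, modal[idx[r], , drop = FALSE]))
        truth <- c(truth, as.character(held$category[r]))
      }
    }
  }
  cats <- sort(unique(c(truth, pred, target_cats)))
  confusion <- table(factor(truth, levels = cats),
                     factor(pred, levels = cats))
  structure(list(
    accuracy = mean(truth == pred),
    confusion = unclass(as.matrix(confusion)),
    n = length(truth), mode = mode, loocv = loocv, target = target,
    predictors = predictors, smoothing = smoothing
  ), class = "circa_bayes")
}

# one row per item with complete modal labels on all requested dimensions
modal_wide <- function(counts, dims) {
  vt <- counts |>
    dplyr::filter(.data$dimension %in% dims) |>
    dplyr::group_by(.data$item, .data$dimension) |>
    dplyr::arrange(dplyr::desc(.data$votes), .data$category,
                   .by_group = TRUE) |>
    dplyr::summarise(modal = .data$category[1L], .groups = "drop")
  wide <- tidyr::pivot_wider(vt, names_from = "dimension",
                             values_from = "modal")
  wide[stats::complete.cases(wide[, dims, drop = FALSE]), , drop = FALSE]
}

fit_bayes_tables <- function(modal, target, predictors, mode, smoothing,
                             target_cats) {
  y <- modal[[target]]
  n_c <- length(target_cats)
  prior <- (vapply(target_cats, function(ct) sum(y == ct), numeric(1)) +
              smoothing) / (length(y) + smoothing * n_c)
  names(prior) <- target_cats
  cond <- NULL
  if (mode == "naive") {
    cond <- lapply(predictors, function(d) {
      x <- modal[[d]]
      vals <- sort(unique(x))
      tab <- vapply(vals, function(v) {
        (vapply(target_cats, function(ct) sum(y == ct & x == v),
                numeric(1)) + smoothing) / (sum(x == v) + smoothing * n_c)
      }, numeric(n_c))
      tab <- matrix(tab, nrow = n_c, dimnames = list(target_cats, vals))
      tab
    })
    names(cond) <- predictors
  } else if (mode == "joint") {
    combo <- do.call(paste, c(modal[predictors], sep = "\r"))
    vals <- sort(unique(combo))
    tab <- vapply(vals, function(v) {
      (vapply(target_cats, function(ct) sum(y == ct & combo == v),
              numeric(1)) + smoothing) / (sum(combo == v) + smoothing * n_c)
    }, numeric(n_c))
    cond <- matrix(tab, nrow = n_c, dimnames = list(target_cats, vals))
  }
  list(mode = mode, prior = prior, cond = cond, predictors = predictors,
       target_cats = target_cats, smoothing = smoothing, n_c = n_c)
}

predict_bayes <- function(model, row) {
  cats <- model$target_cats
  score <- switch(model$mode,
    prior_only = model$prior,
    naive = {
      s <- rep(1, length(cats)); names(s) <- cats
      for (d in model$predictors) {
        tab <- model$cond[[d]]
        v <- row[[d]]
        p <- if (v %in% colnames(tab)) tab[, v] else
          rep(1 / model$n_c, length(cats))  # unseen value: uniform
        s <- s * p
      }
      s
    },
    joint = {
      v <- do.call(paste, c(row[model$predictors], sep = "\r"))
      if (v %in% colnames(model$cond)) model$cond[, v] else
        stats::setNames(rep(1 / model$n_c, length(cats)), cats)
    })
  # MAP; ties toward higher prior, then lexicographic (cats are sorted)
  best <- which(score == max(score))
  if (length(best) > 1L) best <- best[order(-model$prior[best])][1L]
  cats[best]
}

#' @export
print.circa_bayes <- function(x, ...) {
  cat(sprintf("<circa_bayes> %s model, LOOCV over %s: accuracy %.2f%% (n=%d)\n",
              x$mode, x$loocv, 100 * x$accuracy, x$n))
  invisible(x)
}

#' @export
glance.circa_bayes <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = x$n, mode = x$mode,
                 loocv = x$loocv, target = x$target,
                 predictors = paste(x$predictors, collapse = "+"),
                 smoothing = x$smoothing)
}

#' @export
tidy.circa_bayes <- function(x, ...) {
  as.data.frame(as.table(x$confusion)) |>
    stats::setNames(c("true", "predicted", "n")) |>
    tibble::as_tibble()
}

#' Typical, atypical and random exemplar subsets
#'
#' Splits each category's items into three roles by interparticipant
#' agreement: the `m` most agreed-upon (typical), the `m` least agreed-upon
#' (atypical), and `m` drawn at random (seeded). Ties in agreement break by
#' item id.
#'
#' @param responses Raw responses or pre-tallied votes (see [vote_table()]).
#' @param dimension Dimension whose modal categories define membership.
#' @param m Items per category and role.
#' @param seed Optional integer seed for the random role.
#' @return A tibble with `role`, `category`, `item`, `agreement`.
#' @export
typicality_subsets <- function(responses, dimension, m, seed = NULL) {
  vt <- vote_table(responses) |>
    dplyr::filter(.data$dimension == !!dimension)
  if (nrow(vt) == 0L) stop("no votes for that dimension")
  out <- vt |>
    dplyr::group_by(category = .data$modal) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < m) {
        stop(sprintf("category '%s' has only %d items (< m = %d)",
                     key$category, nrow(d), m))
      }
      d_typ <- d[order(-d$agreement, d$item), ][seq_len(m), ]
      d_aty <- d[order(d$agreement, d$item), ][seq_len(m), ]
      d_rnd <- d[with_seed(
        if (is.null(seed)) NULL else
          subseed(seed, sum(utf8ToInt(as.character(key$category)))),
        sample.int(nrow(d), m)), ]
      dplyr::bind_rows(
        tibble::tibble(role = "typical", item = d_typ$item,
                       agreement = d_typ$agreement),
        tibble::tibble(role = "atypical", item = d_aty$item,
                       agreement = d_aty$agreement),
        tibble::tibble(role = "random", item = d_rnd$item,
                       agreement = d_rnd$agreement))
    }) |>
    dplyr::ungroup()
  out[, c("role", "category", "item", "agreement")]
}
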