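#' Select the number of categories by leave-one-participant-out CV
#'
#' For every candidate `k` and every participant: the consensus clustering is
#' fitted (by [circa_fit()]) to the similarity matrix averaged over the
#' *other* participants' sorts, and scored by the hard adjusted Rand index
#' against the left-out participant's partition. The chosen `k` maximizes the
#' mean cross-validated ARI (ties go to the smallest `k`); the raw means are
#' used, with kernel smoothing available via `smooth = TRUE`.
#'
#' @param sorts A list of partitions or a long data frame
#'   (`participant`, `item`, `cluster`); at least 2 participants.
#' @param k_grid Candidate numbers of clusters.
#' @param n_restarts Random restarts per fit.
#' @param seed Optional integer seed; every (fold, k) fit uses a derived
#'   subseed.
#' @param smooth Apply [smooth_ari_curve()] and choose `k` on the smoothed
#'   curve.
#' @return A `circa_kselect`: the ARI-vs-k curve (`mean_ari`, `se_ari`,
#'   optionally `smoothed`), the `chosen_k`, and bookkeeping fields.
#' @export
select_k_loocv_participants <- function(sorts, k_grid = 2:10,
                                        n_restarts = 100L, seed = NULL,
                                        smooth = FALSE) {
  parts <- sorts_as_partitions(sorts)
  n_p <- length(parts)
  if (n_p < 2L) stop("need at least two participants")
  if (length(k_grid) == 0L) stop("empty k grid")
  scores <- matrix(NA_real_, n_p, length(k_grid))
  for (fold in seq_len(n_p)) {
    S_train <- average_sorts(parts[-fold])
    for (ki in seq_along(k_grid)) {
      fit <- circa_fit(S_train, k_grid[ki], n_restarts = n_restarts,
                       seed = seed_for(seed, fold, ki))
      scores[fold, ki] <- adjusted_rand_index(fit$best, parts[[fold]])
    }
  }
  new_kselect(k_grid, scores, smooth, method = "loocv_participants",
              n_restarts = n_restarts, seed = seed)
}

#' Select the number of categories by k-fold CV over trials
#'
#' Individual same-different judgements are split into `n_folds` near-equal
#' folds (sizes differ by at most one). Per fold and candidate `k`, the
#' consensus clustering is fitted to the similarity matrix accumulated from
#' the training trials and scored with the soft-clustering ARI
#' ([soft_ari()]) against the left-out fold's sparse similarity matrix.
#' The ARI-vs-k curve is kernel-smoothed by default before choosing `k`.
#'
#' @param trials Data frame of trials (`item_i`, `item_j`, `same`, ...).
#' @param k_grid Candidate numbers of clusters.
#' @param n_folds Number of folds (default 10).
#' @param n_restarts Random restarts per fit.
#' @param n_random Monte-Carlo draws for each soft-ARI chance term.
#' @param seed Optional integer seed (fold split and all fits derive
#'   subseeds from it).
#' @param smooth Smooth the curve before choosing `k` (default `TRUE`).
#' @return A `circa_kselect` object.
#' @export
select_k_kfold_trials <- function(trials, k_grid = 2:10, n_folds = 10L,
                                  n_restarts = 100L, n_random = 100L,
                                  seed = NULL, smooth = TRUE) {
  n_t <- nrow(trials)
  if (n_t < n_folds) stop("fewer trials than folds")
  if (length(k_grid) == 0L) stop("empty k grid")
  items <- sort(unique(c(as.character(trials$item_i),
                         as.character(trials$item_j))))
  fold_of <- with_seed(if (is.null(seed)) NULL else subseed(seed, 0L), {
    sample(rep_len(seq_len(n_folds), n_t))
  })
  scores <- matrix(NA_real_, n_folds, length(k_grid))
  for (fold in seq_len(n_folds)) {
    S_train <- accumulate_trials(trials[fold_of != fold, , drop = FALSE],
                                 items = items)
    S_test <- accumulate_trials(trials[fold_of == fold, , drop = FALSE],
                                items = items)
    if (n_observed_pairs(S_test) == 0L) {
      stop("a validation fold has no observed pairs")
    }
    for (ki in seq_along(k_grid)) {
      fit <- circa_fit(S_train, k_grid[ki], n_restarts = n_restarts,
                       seed = seed_for(seed, fold, ki))
      scores[fold, ki] <- as.numeric(
        soft_ari(fit$best, S_test, n_random = n_random,
                 seed = seed_for(seed, fold, ki + length(k_grid))))
    }
  }
  new_kselect(k_grid, scores, smooth, method = "kfold_trials",
              n_restarts = n_restarts, seed = seed)
}

seed_for <- function(seed, fold, ki) {
  if (is.null(seed)) NULL else subseed(seed, fold * 1009L + ki)
}

new_kselect <- function(k_grid, scores, smooth, method, n_restarts, seed) {
  mean_ari <- colMeans(scores)
  se_ari <- apply(scores, 2, stats::sd) / sqrt(nrow(scores))
  smoothed <- rep(NA_real_, length(k_grid))
  bandwidth <- NA_real_
  if (smooth && length(k_grid) >= 3L) {
    sm <- smooth_ari_curve(k_grid, mean_ari)
    smoothed <- sm$smoothed
    bandwidth <- sm$bandwidth
    chosen_k <- k_grid[which.max(smoothed)]
  } else {
    chosen_k <- k_grid[which.max(mean_ari)]  # which.max -> smallest k on ties
  }
  structure(list(
    curve = tibble::tibble(k = as.integer(k_grid), mean_ari = mean_ari,
                           se_ari = se_ari, smoothed = smoothed),
    chosen_k = as.integer(chosen_k), bandwidth = bandwidth,
    fold_scores = scores, method = method, n_restarts = n_restarts,
    seed = seed
  ), class = "circa_kselect")
}

#' Kernel-smooth a cross-validated ARI-vs-k curve
#'
#' Nadaraya-Watson regression with a Gaussian kernel over `k`. The kernel
#' scale (bandwidth) minimizes the leave-one-out squared error on the mean
#' ARI points, searched on a log-spaced grid from a fraction of the smallest
#' grid spacing up to twice the grid range. A constant input curve is
#' returned unchanged with an `NA` bandwidth.
#'
#' @param k_grid Numeric grid of cluster counts (>= 3 points).
#' @param mean_ari Mean cross-validated ARI at each grid point.
#' @return A list with `smoothed` (fitted values on the grid) and
#'   `bandwidth`.
#' @export
smooth_ari_curve <- function(k_grid, mean_ari) {
  if (length(k_grid) < 3L) stop("need at least 3 grid points")
  if (length(mean_ari) != length(k_grid)) stop("length mismatch")
  if (stats::sd(mean_ari) == 0) {
    return(list(smoothed = mean_ari, bandwidth = NA_real_))
  }
  k <- as.numeric(k_grid)
  gaps <- diff(sort(k))
  h_grid <- exp(seq(log(0.25 * min(gaps)), log(2 * diff(range(k))),
                    length.out = 80L))
  loo_sse <- vapply(h_grid, function(h) {
    sum(vapply(seq_along(k), function(i) {
      w <- stats::dnorm(k[i] - k[-i], sd = h)
      if (sum(w) == 0) return(Inf)
      (mean_ari[i] - sum(w * mean_ari[-i]) / sum(w))^2
    }, numeric(1)))
  }, numeric(1))
  h <- h_grid[which.min(loo_sse)]
  smoothed <- vapply(k, function(k0) {
    w <- stats::dnorm(k0 - k, sd = h)
    sum(w * mean_ari) / sum(w)
  }, numeric(1))
  list(smoothed = smoothed, bandwidth = h)
}

#' @export
print.circa_kselect <- function(x, ...) {
  cat(sprintf("<circa_kselect> chosen k = %d (method: %s)\n",
              x$chosen_k, x$method))
  print(x$curve)
  invisible(x)
}

#' @export
tidy.circa_kselect <- function(x, ...) x$curve

#' @export
glance.circa_kselect <- function(x, ...) {
  tibble::tibble(
    chosen_k = x$chosen_k,
    peak_mean_ari = max(x$curve$mean_ari),
    bandwidth = x$bandwidth,
    n_folds = nrow(x$fold_scores),
    method = x$method
  )
}

#' Plot a cross-validated ARI-vs-k curve
#'
#' @param object A `circa_kselect` result.
#' @param ... Unused.
#' @return A ggplot: mean ARI with a standard-error ribbon, the smoothed
#'   curve when present, and a dashed line at the chosen `k`.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.circa_kselect <- function(object, ...) {
  d <- object$curve
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$mean_ari)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_ari - .data$se_ari,
                   ymax = .data$mean_ari + .data$se_ari),
      alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters k", y = "cross-validated ARI")
  if (!all(is.na(d$smoothed))) {
    gg <- gg + ggplot2::geom_line(ggplot2::aes(y = .data$smoothed),
                                  colour = "steelblue")
  }
  gg
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
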