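#' By-category similarity from same-different trials
#'
#' Given an existing category membership for every item, computes for each
#' pair of categories (including self-pairs) the proportion of trials
#' answered "same" and the number of contributing trials.
#'
#' @param trials Data frame of trials (`item_i`, `item_j`, `same`).
#' @param memberships Data frame with `item` and `category`.
#' @return A tibble `cat_i`, `cat_j`, `prop_same`, `n_trials` with
#'   `cat_i <= cat_j` lexicographically.
#' @export
category_similarity <- function(trials, memberships) {
  mv <- membership_vector(memberships)
  ci <- unname(mv[as.character(trials$item_i)])
  cj <- unname(mv[as.character(trials$item_j)])
  if (anyNA(ci) || anyNA(cj)) stop("trials reference items without a category")
  tibble::tibble(
    cat_i = pmin(ci, cj), cat_j = pmax(ci, cj),
    same = as.numeric(trials$same)
  ) |>
    dplyr::group_by(.data$cat_i, .data$cat_j) |>
    dplyr::summarise(prop_same = mean(.data$same),
                     n_trials = dplyr::n(), .groups = "drop")
}

#' Remove/merge refinement of an existing category system
#'
#' The baseline refinement operates on whole categories: categories whose
#' within-category "same" proportion falls below `within_min` are removed
#' (with their items), then surviving category pairs whose between-category
#' proportion exceeds `between_max` are merged. By default merging is a
#' single pass over the original between-similarities, so chains merge by
#' transitive closure (connected components); `method = "iterative"`
#' instead merges the strongest pair, re-pools similarities
#' (trial-count-weighted), and repeats until no pair exceeds the threshold.
#'
#' @param catsim A [category_similarity()] table; every category must have
#'   a within-category (self-pair) row.
#' @param within_min Removal threshold on within-category similarity
#'   (default 0.75).
#' @param between_max Merge threshold on between-category similarity
#'   (default 0.5).
#' @param method `"single_pass"` (default) or `"iterative"`.
#' @return A tibble mapping `category` to `refined` (an integer group id;
#'   `NA` for removed categories).
#' @export
greene_refine <- function(catsim, within_min = 0.75, between_max = 0.5,
                          method = c("single_pass", "iterative")) {
  method <- match.arg(method)
  catsim <- tibble::as_tibble(catsim)
  cats <- sort(unique(c(as.character(catsim$cat_i),
                        as.character(catsim$cat_j))))
  within <- catsim[as.character(catsim$cat_i) ==
                     as.character(catsim$cat_j), , drop = FALSE]
  missing <- setdiff(cats, as.character(within$cat_i))
  if (length(missing) > 0) {
    stop("categories without within-category similarity: ",
         paste(missing, collapse = ", "))
  }
  keep <- as.character(within$cat_i[within$prop_same >= within_min])
  if (length(keep) == 0L) stop("all categories removed")
  between <- catsim[as.character(catsim$cat_i) !=
                      as.character(catsim$cat_j) &
                      as.character(catsim$cat_i) %in% keep &
                      as.character(catsim$cat_j) %in% keep, , drop = FALSE]
  if (method == "single_pass") {
    edges <- between[between$prop_same > between_max, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges$cat_i),
                 to = as.character(edges$cat_j)),
      directed = FALSE, vertices = data.frame(name = keep))
    comp <- igraph::components(g)$membership
    refined <- stats::setNames(as.integer(comp[keep]), keep)
  } else {
    groups <- stats::setNames(as.list(keep), keep)
    sim <- between
    repeat {
      over <- sim[sim$prop_same > between_max, , drop = FALSE]
      if (nrow(over) == 0L) break
      top <- over[order(-over$prop_same, over$cat_i, over$cat_j), ][1L, ]
      a <- as.character(top$cat_i); b <- as.character(top$cat_j)
      groups[[a]] <- c(groups[[a]], groups[[b]])
      groups[[b]] <- NULL
      # pool b's similarities into a, weighting by trial counts
      sim$cat_i[sim$cat_i == b] <- a
      sim$cat_j[sim$cat_j == b] <- a
      ci <- pmin(sim$cat_i, sim$cat_j); cj <- pmax(sim$cat_i, sim$cat_j)
      sim$cat_i <- ci; sim$cat_j <- cj
      sim <- sim[sim$cat_i != sim$cat_j, , drop = FALSE] |>
        dplyr::group_by(.data$cat_i, .data$cat_j) |>
        dplyr::summarise(
          prop_same = sum(.data$prop_same * .data$n_trials) /
            sum(.data$n_trials),
          n_trials = sum(.data$n_trials), .groups = "drop")
    }
    refined <- integer(0)
    for (gi in seq_along(groups)) {
      refined[groups[[gi]]] <- gi
    }
    refined <- refined[keep]
    names(refined) <- keep
  }
  tibble::tibble(
    category = cats,
    refined = ifelse(cats %in% keep, refined[cats], NA_integer_)
  )
}

#' Clustering-method contracts for the benchmark harness
#'
#' Each constructor returns a function `(S, k, seed) -> partition`, the
#' contract [run_benchmark()] expects. `clusterer_circa()` wraps
#' [circa_fit()]; `clusterer_kmedoids()` wraps partitioning around medoids
#' on the dissimilarity `1 - s` (unobserved pairs imputed at 0.5);
#' `clusterer_spectral()` wraps spectral clustering using the similarity
#' matrix as the kernel (same imputation).
#'
#' @param n_restarts Restarts for the coordinate-ascent method.
#' @return A clusterer function.
#' @export
clusterer_circa <- function(n_restarts = 50L) {
  function(S, k, seed = NULL) circa_fit(S, k, n_restarts, seed = seed)$best
}

#' @rdname clusterer_circa
#' @export
clusterer_kmedoids <- function() {
  function(S, k, seed = NULL) {
    if (!requireNamespace("cluster", quietly = TRUE)) {
      stop("the 'cluster' package is required for the k-medoids baseline")
    }
    d <- 1 - S$values
    d[!S$observed] <- 0.5
    diag(d) <- 0
    fit <- with_seed(seed, cluster::pam(stats::as.dist(d), k = k,
                                        cluster.only = TRUE))
    partition(fit, k = k, items = S$items)
  }
}

#' @rdname clusterer_circa
#' @export
clusterer_spectral <- function() {
  function(S, k, seed = NULL) {
    if (!requireNamespace("kernlab", quietly = TRUE)) {
      stop("the 'kernlab' package is required for the spectral baseline")
    }
    m <- S$values
    m[!S$observed] <- 0.5
    diag(m) <- 1
    cl <- with_seed(seed, {
      kernlab::specc(kernlab::as.kernelMatrix(m), centers = k)
    })
    partition(as.integer(cl), k = k, items = S$items)
  }
}

#' Benchmark clustering methods on simulated noisy similarity data
#'
#' For every response-noise level and replicate, plants a ground-truth
#' partition, simulates same-different trials at that flip-noise level,
#' accumulates the similarity matrix, runs every supplied clusterer, and
#' scores the hard ARI against the planted truth. A method failing on an
#' instance is recorded as `NA`, not fatal. Fully seeded and reproducible
#' (wall-clock timings aside).
#'
#' @param config A [generator_config()] (its `flip_prob` is overridden by
#'   the grid).
#' @param methods Named list of clusterer contracts (see
#'   [clusterer_circa()]).
#' @param noise_grid Flip-noise levels to sweep.
#' @param n_replicates Replicates per noise level.
#' @param seed Optional integer master seed.
#' @return A `circa_benchmark`: tibble with `method`, `noise`, `replicate`,
#'   `ari`, `seconds`.
#' @export
run_benchmark <- function(config,
                          methods = list(circa = clusterer_circa(),
                                         kmedoids = clusterer_kmedoids(),
                                         spectral = clusterer_spectral()),
                          noise_grid = c(0, 0.25, 0.5),
                          n_replicates = 5L, seed = NULL) {
  if (is.null(names(methods)) || any(!nzchar(names(methods)))) {
    stop("methods must be a named list")
  }
  rows <- list()
  cell <- 0L
  for (noise in noise_grid) {
    for (rep in seq_len(n_replicates)) {
      cell <- cell + 1L
      cfg <- config
      cfg$flip_prob <- noise
      cfg$seed <- if (is.null(seed)) NULL else subseed(seed, cell)
      truth <- sample_truth(cfg)
      trials <- simulate_trials(truth, cfg)
      S <- accumulate_trials(trials, items = item_ids(truth))
      for (mname in names(methods)) {
        t0 <- proc.time()[["elapsed"]]
        p <- tryCatch(
          methods[[mname]](S, cfg$k_true,
                           seed = if (is.null(seed)) NULL else
                             subseed(seed, 100000L + cell)),
          error = function(e) NULL)
        secs <- proc.time()[["elapsed"]] - t0
        rows[[length(rows) + 1L]] <- tibble::tibble(
          method = mname, noise = noise, replicate = rep,
          ari = if (is.null(p)) NA_real_ else
            adjusted_rand_index(p, truth),
          seconds = secs)
      }
    }
  }
  structure(list(results = dplyr::bind_rows(rows), config = config,
                 seed = seed),
            class = "circa_benchmark")
}

#' @export
print.circa_benchmark <- function(x, ...) {
  print(glance(x))
  invisible(x)
}

#' @export
tidy.circa_benchmark <- function(x, ...) x$results

#' @export
glance.circa_benchmark <- function(x, ...) {
  x$results |>
    dplyr::group_by(.data$method, .data$noise) |>
    dplyr::summarise(
      mean_ari = mean(.data$ari, na.rm = TRUE),
      se_ari = stats::sd(.data$ari, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$ari))),
      mean_seconds = mean(.data$seconds),
      n = dplyr::n(), .groups = "drop")
}

#' Plot benchmark accuracy by noise level
#'
#' @param object A `circa_benchmark`.
#' @param ... Unused.
#' @return A ggplot of mean ARI (± SE) against noise per method.
#' @export
autoplot.circa_benchmark <- function(object, ...) {
  d <- glance(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$noise, y = .data$mean_ari,
                                  colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_ari - .data$se_ari,
                   ymax = .data$mean_ari + .data$se_ari)) +
    ggplot2::labs(x = "response noise (flip probability)",
                  y = "mean ARI to planted truth")
}
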