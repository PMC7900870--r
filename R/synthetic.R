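#' Configuration for the synthetic-data generator
#'
#' Bundles the ground-truth and noise parameters used to simulate
#' free-sorting and same-different data with a planted category structure.
#' Defaults mirror the free-sorting study design this package targets:
#' 80 items, 20 participants, between 3 and 10 categories per sort, at
#' least 2 items per category.
#'
#' @param n_items Number of items.
#' @param k_true Planted number of categories.
#' @param size_scheme `"equal"` (near-equal cluster sizes) or `"random"`
#'   (random sizes, each at least `min_size`).
#' @param min_size Minimum items per planted category (default 2).
#' @param n_participants Simulated participants for sorting data.
#' @param disagreement Fraction `d` of items each participant reassigns to a
#'   uniformly chosen *different* category (per-participant disagreement
#'   rate).
#' @param flip_prob Probability that a same-different response is flipped
#'   relative to the planted truth (response noise).
#' @param density Fraction of item pairs receiving at least one
#'   same-different trial.
#' @param pair_sampling `"uniform"` pair sampling or `"hub"` (hub-biased,
#'   emulating crowd-sourced sparsity where some items are judged far more
#'   often).
#' @param trials_per_pair Judgements per sampled pair.
#' @param labels_per_cluster Size of each planted category's label pool.
#' @param shared_labels Number of "confusable" label words shared across all
#'   categories (exercises the secondary-label rule).
#' @param category_bounds Admissible range for a participant's category
#'   count; sorts violating it are resampled.
#' @param seed Optional integer master seed.
#' @return A `circa_config` list.
#' @export
generator_config <- function(n_items = 80L, k_true = 4L,
                             size_scheme = c("equal", "random"),
                             min_size = 2L, n_participants = 20L,
                             disagreement = 0, flip_prob = 0, density = 1,
                             pair_sampling = c("uniform", "hub"),
                             trials_per_pair = 1L,
                             labels_per_cluster = 3L, shared_labels = 0L,
                             category_bounds = c(3L, 10L), seed = NULL) {
  size_scheme <- match.arg(size_scheme)
  pair_sampling <- match.arg(pair_sampling)
  stopifnot(disagreement >= 0, disagreement <= 1,
            flip_prob >= 0, flip_prob <= 1,
            density > 0, density <= 1, min_size >= 1, trials_per_pair >= 1)
  if (n_items < k_true * min_size) {
    stop("n_items too small for k_true clusters of min_size")
  }
  structure(list(
    n_items = as.integer(n_items), k_true = as.integer(k_true),
    size_scheme = size_scheme, min_size = as.integer(min_size),
    n_participants = as.integer(n_participants),
    disagreement = disagreement, flip_prob = flip_prob, density = density,
    pair_sampling = pair_sampling,
    trials_per_pair = as.integer(trials_per_pair),
    labels_per_cluster = as.integer(labels_per_cluster),
    shared_labels = as.integer(shared_labels),
    category_bounds = as.integer(category_bounds), seed = seed
  ), class = "circa_config")
}

item_names <- function(n) {
  sprintf(paste0("i%0", nchar(as.character(n)), "d"), seq_len(n))
}

#' Sample a planted ground-truth partition
#'
#' @param config A [generator_config()].
#' @return A [partition()] of `n_items` into `k_true` categories honoring
#'   the size scheme; a pure function of config and seed.
#' @export
sample_truth <- function(config) {
  n <- config$n_items; k <- config$k_true
  sizes <- with_seed(config$seed, {
    if (config$size_scheme == "equal") {
      base <- n %/% k
      base + as.integer(seq_len(k) <= n %% k)
    } else {
      extra <- n - k * config$min_size
      add <- if (extra > 0) {
        tabulate(sample.int(k, extra, replace = TRUE), nbins = k)
      } else rep(0L, k)
      config$min_size + add
    }
  })
  partition(rep(seq_len(k), sizes), k = k, items = item_names(n))
}

#' Simulate participants' sorts with controlled disagreement
#'
#' Each simulated participant starts from the planted truth and reassigns a
#' fraction `disagreement` of items (chosen uniformly) to a uniformly chosen
#' different category, then labels each of their categories with words from
#' that category's label pool (plus optional shared confusable words).
#' Sorts whose category count leaves `category_bounds` are resampled, with a
#' warning.
#'
#' @param truth A planted [partition()] (from [sample_truth()]).
#' @param config A [generator_config()].
#' @return A list with `sorts` (tibble `participant`, `item`, `cluster`),
#'   `labels` (tibble `participant`, `cluster`, `label`) and `partitions`
#'   (named list of `circa_partition`).
#' @export
simulate_sorts <- function(truth, config) {
  n <- length(truth); k <- k_bound(truth)
  pools <- label_pools(config)
  ids <- item_ids(truth)
  n_re <- round(config$disagreement * n)
  sorts <- list(); labels <- list(); partitions <- list()
  warned <- FALSE
  for (p in seq_len(config$n_participants)) {
    a <- with_seed(
      if (is.null(config$seed)) NULL else subseed(config$seed, p), {
        ok <- FALSE; tries <- 0L; a <- NULL
        while (!ok) {
          tries <- tries + 1L
          a <- as.integer(truth)
          if (n_re > 0) {
            idx <- sample.int(n, n_re)
            for (i in idx) {
              others <- setdiff(seq_len(k), a[i])
              a[i] <- if (length(others) == 1L) others else sample(others, 1L)
            }
          }
          used <- length(unique(a))
          ok <- used >= config$category_bounds[1] &&
            used <= config$category_bounds[2]
          if (!ok && tries == 1L && !warned) {
            warned <<- TRUE
            warning("resampling sorts that violate category-count bounds")
          }
          if (tries > 100L) stop("cannot satisfy category-count bounds")
        }
        a
      })
    pid <- sprintf("p%02d", p)
    partitions[[pid]] <- partition(a, k = k, items = ids)
    sorts[[pid]] <- tibble::tibble(participant = pid, item = ids,
                                   cluster = a)
    used <- sort(unique(a))
    lab <- with_seed(
      if (is.null(config$seed)) NULL else subseed(config$seed, 10000L + p), {
        dplyr::bind_rows(lapply(used, function(cl) {
          pool <- pools$per_cluster[[cl]]
          n_lab <- sample.int(min(length(pool), 2L), 1L)
          chosen <- sample(pool, n_lab)
          if (length(pools$shared) > 0 && stats::runif(1) < 0.5) {
            chosen <- c(chosen, sample(pools$shared, 1L))
          }
          tibble::tibble(participant = pid, cluster = cl, label = chosen)
        }))
      })
    labels[[pid]] <- lab
  }
  list(sorts = dplyr::bind_rows(sorts), labels = dplyr::bind_rows(labels),
       partitions = partitions)
}

label_pools <- function(config) {
  per_cluster <- lapply(seq_len(config$k_true), function(cl) {
    sprintf("word%02d%s", cl, letters[seq_len(config$labels_per_cluster)])
  })
  shared <- if (config$shared_labels > 0) {
    sprintf("common%s", letters[seq_len(config$shared_labels)])
  } else character(0)
  list(per_cluster = per_cluster, shared = shared)
}

#' Simulate sparse, noisy same-different trials
#'
#' Item pairs are sampled at the configured density (uniformly, or
#' hub-biased so a few items accumulate most judgements); each sampled pair
#' receives `trials_per_pair` judgements equal to the planted co-membership,
#' each independently flipped with probability `flip_prob`.
#'
#' @inheritParams simulate_sorts
#' @return A tibble of trials (`item_i`, `item_j`, `same`).
#' @export
simulate_trials <- function(truth, config) {
  n <- length(truth)
  ids <- item_ids(truth)
  a <- as.integer(truth)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  with_seed(
    if (is.null(config$seed)) NULL else subseed(config$seed, 20000L), {
      p_obs <- if (config$pair_sampling == "uniform") {
        rep(config$density, nrow(pr))
      } else {
        w <- 1 / sqrt(seq_len(n))  # hub-biased: low-index items are hubs
        raw <- w[pr[, 1]] * w[pr[, 2]]
        pmin(1, raw * config$density * nrow(pr) / sum(raw))
      }
      keep <- stats::runif(nrow(pr)) < p_obs
      if (!any(keep)) stop("density produced no observed pairs")
      pi_ <- rep(pr[keep, 1], each = config$trials_per_pair)
      pj_ <- rep(pr[keep, 2], each = config$trials_per_pair)
      truth_same <- a[pi_] == a[pj_]
      flip <- stats::runif(length(pi_)) < config$flip_prob
      tibble::tibble(item_i = ids[pi_], item_j = ids[pj_],
                     same = as.integer(xor(truth_same, flip)))
    })
}
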