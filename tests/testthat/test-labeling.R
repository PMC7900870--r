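test_that("stemming collapses inflected label variants", {
  expect_equal(stem_label(c("Farm", "farms", "Farming")),
               rep("farm", 3))
  expect_equal(stem_label("Beaches"), "beach")
  expect_equal(stem_label("  Pebbly   Beaches "), "pebbly beach")
  expect_equal(stem_label("Cluttered"), "clutter")
  expect_equal(stem_label("grass"), "grass")  # -ss is not a plural
})

test_that("partial category ARI compares binarized partitions", {
  group <- partition(c(1, 1, 1, 2, 2, 2, 3, 3))
  # identical single-category membership
  expect_equal(partial_category_ari(group, 1, group, 1), 1)
  # complementary equal halves binarize to the same two-block partition
  g2 <- partition(c(1, 1, 1, 1, 2, 2, 2, 2))
  expect_equal(partial_category_ari(g2, 1, g2, 2), 1)
  # cross-check an overlapping case against the reference ARI
  skip_if_not_installed("mclust")
  sort_p <- partition(c(1, 1, 2, 2, 2, 3, 3, 3))
  bg <- ifelse(as.integer(group) == 1, 1, 2)
  bc <- ifelse(as.integer(sort_p) == 2, 1, 2)
  expect_equal(partial_category_ari(group, 1, sort_p, 2),
               mclust::adjustedRandIndex(bg, bc))
  # a cluster spanning all items cannot be binarized
  expect_error(partial_category_ari(partition(rep(1, 4), k = 2), 1,
                                    partition(c(1, 1, 2, 2)), 1),
               "degenerate")
  expect_error(partial_category_ari(group, 9, sort_p, 1), "empty")
})

make_label_case <- function(ab_cos) {
  # 8 participants all sorting 9 items identically to the 3-category
  # consensus. Category 1 labels: alpha (4 uses, partial ARI 1 each), bravo
  # (3), charlie (1); categories 2/3 are uniformly "delta"/"echo". With
  # three equal disjoint categories the cross-category partial ARIs are
  # exactly 0, so category 1's summed scores are 4, 3, 1, 0, 0 and its
  # normalized scores 1, 0.75, 0.25, 0, 0.
  group <- partition(rep(1:3, each = 3), items = letters[1:9])
  sorts <- tibble::tibble(
    participant = rep(sprintf("p%d", 1:8), each = 9),
    item = rep(letters[1:9], 8),
    cluster = rep(rep(1:3, each = 3), 8))
  labels <- dplyr::bind_rows(
    tibble::tibble(participant = sprintf("p%d", 1:4), cluster = 1,
                   label = "alpha"),
    tibble::tibble(participant = sprintf("p%d", 5:7), cluster = 1,
                   label = "bravo"),
    tibble::tibble(participant = "p8", cluster = 1, label = "charlie"),
    tibble::tibble(participant = sprintf("p%d", 1:8), cluster = 2,
                   label = "delta"),
    tibble::tibble(participant = sprintf("p%d", 1:8), cluster = 3,
                   label = "echo"))
  score_and_assign_labels(group, sorts, labels,
                          provider = fixture_embeddings(ab_cos))
}

test_that("label scores sum partial ARIs over uses and pick the max", {
  res <- make_label_case(0.4)
  sc <- res$scores[res$scores$group_category == 1, ]
  expect_equal(sc$summed_ari[sc$stem == "alpha"], 4)
  expect_equal(sc$summed_ari[sc$stem == "bravo"], 3)
  expect_equal(sc$summed_ari[sc$stem == "charlie"], 1)
  expect_equal(sc$summed_ari[sc$stem == "delta"], 0)
  expect_equal(sc$normalized_ari[sc$stem == "alpha"], 1)
  expect_equal(sc$normalized_ari[sc$stem == "bravo"], 0.75)
  a <- res$assignments
  expect_equal(a$primary[a$group_category == 1], "alpha")
  expect_equal(a$primary[a$group_category == 2], "delta")
  expect_equal(a$primary[a$group_category == 3], "echo")
  expect_true(is.na(a$secondary[a$group_category == 2]))
})

test_that("secondary labels require novelty and strong association", {
  # similarity(alpha, bravo) = 0.4 < 0.5, normalized 0.75 >= 0.65: accept
  low_sim <- make_label_case(0.4)
  expect_equal(
    low_sim$assignments$secondary[low_sim$assignments$group_category == 1],
    "bravo")
  # similarity 0.6 >= 0.5: bravo is redundant; charlie fails the 0.65 bar
  high_sim <- make_label_case(0.6)
  expect_true(is.na(
    high_sim$assignments$secondary[
      high_sim$assignments$group_category == 1]))
})

test_that("label scoring is invariant to participant order", {
  group <- partition(rep(1:2, each = 3), items = letters[1:6])
  sorts <- tibble::tibble(
    participant = rep(c("p1", "p2"), each = 6),
    item = rep(letters[1:6], 2),
    cluster = c(1, 1, 1, 2, 2, 2, 1, 1, 2, 2, 2, 1))
  labels <- tibble::tibble(
    participant = c("p1", "p1", "p2", "p2"),
    cluster = c(1, 2, 1, 2),
    label = c("alpha", "delta", "bravo", "charlie"))
  prov <- fixture_embeddings(0.4)
  r1 <- score_and_assign_labels(group, sorts, labels, prov)
  r2 <- score_and_assign_labels(group, sorts[12:1, ], labels[4:1, ], prov)
  expect_equal(r1$scores, r2$scores)
})

test_that("centroid labels pick the vocabulary word nearest the mean", {
  vocab <- rbind(east = c(1, 0), north = c(0, 1),
                 northeast = c(1, 1) / sqrt(2))
  wvs <- word_vector_set(rbind(c(1, 0), c(0, 1)), c("A", "A"))
  expect_equal(centroid_label(wvs, vocab)$label, "northeast")
  # single-member category returns its own direction
  wvs1 <- word_vector_set(rbind(c(1, 0)), "B")
  expect_equal(centroid_label(wvs1, vocab)$label, "east")
  # duplicated labels drag the centroid toward the duplicate
  wvs2 <- word_vector_set(rbind(c(1, 0), c(1, 0), c(0, 1)), rep("C", 3))
  expect_equal(centroid_label(wvs2, vocab[c("east", "north"), ])$label,
               "east")
})

test_that("F-ratio matches a coordinate-wise ANOVA decomposition", {
  set.seed(14)
  theta <- c(rnorm(3, 0.3, 0.2), rnorm(3, 2.2, 0.2))
  vecs <- cbind(cos(theta), sin(theta))
  cats <- rep(c("A", "B"), each = 3)
  wvs <- word_vector_set(vecs, cats)
  # oracle: pool per-coordinate between/within sums of squares from aov
  ssb <- 0; ssw <- 0
  for (d in 1:2) {
    av <- summary(stats::aov(vecs[, d] ~ factor(cats)))[[1]]
    ssb <- ssb + av[["Sum Sq"]][1]
    ssw <- ssw + av[["Sum Sq"]][2]
  }
  f_oracle <- (ssb / 1) / (ssw / 4)
  expect_equal(f_ratio(wvs), f_oracle, tolerance = 1e-10)
})

test_that("F-ratio handles degenerate and invariant cases", {
  same <- word_vector_set(rbind(c(1, 0), c(1, 0), c(1, 0), c(1, 0)),
                          c("A", "A", "B", "B"))
  expect_equal(f_ratio(same), 0)
  split <- word_vector_set(rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)),
                           c("A", "A", "B", "B"))
  expect_equal(f_ratio(split), Inf)
  # rotation invariance
  set.seed(3)
  vecs <- matrix(rnorm(24), 8, 3)
  wvs <- word_vector_set(vecs, rep(c("A", "B"), 4))
  rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  wvs_rot <- word_vector_set(wvs$vectors %*% rot, wvs$categories)
  expect_equal(f_ratio(wvs_rot), f_ratio(wvs), tolerance = 1e-10)
  # widening between-category separation raises F
  sep_f <- vapply(c(0.4, 0.8, 1.4), function(gap) {
    set.seed(9)
    th <- c(rnorm(5, 0, 0.15), rnorm(5, gap, 0.15))
    f_ratio(word_vector_set(cbind(cos(th), sin(th)),
                            rep(c("A", "B"), each = 5)))
  }, numeric(1))
  expect_true(all(diff(sep_f) > 0))
  expect_error(f_ratio(word_vector_set(diag(3), c("A", "B", "C"))),
               "more vectors than categories")
})

test_that("embedding providers resolve stems and report cosines", {
  prov <- fixture_embeddings(0.4)
  expect_equal(prov$similarity("alpha", "bravo"), 0.4, tolerance = 1e-12)
  expect_equal(prov$similarity("Alphas", "alpha"), 1, tolerance = 1e-12)
  expect_error(prov$vector("zulu"), "no embedding")
  lenient <- embedding_provider(rbind(alpha = c(1, 0)), strict = FALSE)
  expect_true(all(is.na(lenient$vector("zulu"))))
})
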