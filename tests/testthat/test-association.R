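test_that("phi coefficients follow the 2x2 closed form", {
  # contingency (a,b,c,d) = (30,10,10,30) over 80 items -> phi = 0.5
  items <- sprintf("i%02d", 1:80)
  in_x <- c(rep(TRUE, 40), rep(FALSE, 40))
  in_y <- c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 30))
  a <- tibble::tibble(item = items, category = ifelse(in_x, "X", "notX"))
  b <- tibble::tibble(item = items, category = ifelse(in_y, "Y", "notY"))
  phi <- phi_matrix(a, b)
  expect_equal(phi["X", "Y"], 0.5)
  expect_equal(phi["X", "notY"], -0.5)
  # identical and complementary indicators
  expect_equal(phi_matrix(a, a)["X", "X"], 1)
  expect_equal(phi_matrix(a, a)["X", "notX"], -1)
})

test_that("constant category indicators give missing phi, not zero", {
  a <- tibble::tibble(item = c("1", "2", "3"),
                      category = c("X", "X", "X"))
  b <- tibble::tibble(item = c("1", "2", "3"),
                      category = c("Y", "Y", "Z"))
  expect_true(all(is.na(phi_matrix(a, b))))
})

# responses where predictor p1 determines the target and p2 is noise
make_factorized_responses <- function(n_per = 20, seed = 1) {
  set.seed(seed)
  items <- sprintf("i%03d", seq_len(2 * n_per))
  target <- rep(c("a", "b"), each = n_per)
  p2 <- rep(c("u", "v"), length.out = 2 * n_per)
  dplyr::bind_rows(
    tibble::tibble(item = items, dimension = "target", category = target),
    tibble::tibble(item = items, dimension = "p1", category = target),
    tibble::tibble(item = items, dimension = "p2", category = p2))
}

test_that("a determining predictor yields perfect accuracy", {
  resp <- make_factorized_responses()
  for (mode in c("naive", "joint")) {
    res <- bayes_classify(resp, "target", c("p1", "p2"), mode = mode,
                          loocv = "images")
    expect_equal(res$accuracy, 1)
  }
})

test_that("naive and joint predictions coincide for factorized tables", {
  resp <- make_factorized_responses()
  nv <- bayes_classify(resp, "target", c("p1", "p2"), mode = "naive")
  jt <- bayes_classify(resp, "target", c("p1", "p2"), mode = "joint")
  expect_identical(nv$confusion, jt$confusion)
})

test_that("naive equals joint with a single predictor", {
  set.seed(6)
  items <- sprintf("i%03d", 1:40)
  resp <- dplyr::bind_rows(
    tibble::tibble(item = items, dimension = "target",
                   category = sample(c("a", "b", "c"), 40, replace = TRUE)),
    tibble::tibble(item = items, dimension = "p1",
                   category = sample(c("x", "y"), 40, replace = TRUE)))
  nv <- bayes_classify(resp, "target", "p1", mode = "naive")
  jt <- bayes_classify(resp, "target", "p1", mode = "joint")
  expect_identical(nv$confusion, jt$confusion)
})

test_that("prior-only accuracy equals the modal category frequency", {
  resp <- make_factorized_responses()
  # unbalance the target: 25 a's, 15 b's
  resp$category[resp$dimension == "target"][21:25] <- "a"
  res <- bayes_classify(resp, "target", "p1", mode = "prior_only")
  expect_equal(res$accuracy, 25 / 40)
})

test_that("confusion matrices are consistent with accuracy", {
  resp <- make_factorized_responses(seed = 3)
  res <- bayes_classify(resp, "target", "p2", mode = "naive")
  cm <- res$confusion
  expect_equal(sum(diag(cm)) / sum(cm), res$accuracy)
  expect_equal(unname(rowSums(cm)[c("a", "b")]), c(20, 20))
  td <- tidy(res)
  expect_equal(sum(td$n), res$n)
})

test_that("participant LOOCV scores against raw held-out labels", {
  # three participants, two of whom agree perfectly; predictor determines
  # the majority target, so errors come only from the dissenting labels
  items <- sprintf("i%02d", 1:10)
  maj <- rep(c("a", "b"), each = 5)
  dissent <- c(rep("a", 4), "b", rep("b", 4), "a")
  resp <- dplyr::bind_rows(
    tibble::tibble(participant = "p1", item = items, dimension = "target",
                   category = maj),
    tibble::tibble(participant = "p2", item = items, dimension = "target",
                   category = maj),
    tibble::tibble(participant = "p3", item = items, dimension = "target",
                   category = dissent),
    tibble::tibble(participant = rep(c("p1", "p2", "p3"), each = 10),
                   item = rep(items, 3), dimension = "p1",
                   category = rep(maj, 3)))
  res <- bayes_classify(resp, "target", "p1", mode = "naive",
                        loocv = "participants")
  expect_equal(res$n, 30)
  expect_equal(res$accuracy, 28 / 30)
})

test_that("typicality subsets order items by agreement", {
  votes <- tibble::tibble(
    item = rep(sprintf("i%02d", 1:10), each = 4),
    dimension = "sem",
    category = c(rep("A", 40)))
  # agreement strictly decreasing in item id: item i gets 4 - floor((i-1)/4)
  # votes for A out of 4... simpler: explicit counts
  counts <- tibble::tibble(
    item = rep(sprintf("i%02d", 1:10), 2),
    dimension = "sem",
    category = rep(c("A", "B"), each = 10),
    count = c(10:1 + 10, 1:10))  # A always modal, agreement decreasing
  sub <- typicality_subsets(counts, "sem", m = 3, seed = 1)
  typ <- sub$item[sub$role == "typical"]
  aty <- sub$item[sub$role == "atypical"]
  expect_equal(sort(typ), sprintf("i%02d", 1:3))
  expect_equal(sort(aty), sprintf("i%02d", 8:10))
  expect_equal(nrow(sub), 9)
  # seeded random subset is reproducible
  sub2 <- typicality_subsets(counts, "sem", m = 3, seed = 1)
  expect_identical(sub, sub2)
  expect_error(typicality_subsets(counts, "sem", m = 11), "only")
})

test_that("typical exemplars classify better than atypical ones", {
  # planted structure: typical items have deterministic predictors,
  # atypical items have scrambled predictors
  set.seed(11)
  n_cat <- 2; n_item <- 12
  items <- sprintf("i%02d", seq_len(n_cat * n_item))
  target <- rep(c("a", "b"), each = n_item)
  typicality <- rep(rep(c("hi", "lo"), each = n_item / 2), n_cat)
  pred <- ifelse(typicality == "hi", target,
                 sample(c("a", "b"), length(target), replace = TRUE))
  votes <- dplyr::bind_rows(
    tibble::tibble(item = items, dimension = "target", category = target,
                   count = ifelse(typicality == "hi", 10L, 6L)),
    tibble::tibble(item = items, dimension = "target",
                   category = ifelse(target == "a", "b", "a"),
                   count = ifelse(typicality == "hi", 0L, 4L)),
    tibble::tibble(item = items, dimension = "pred", category = pred,
                   count = 10L))
  votes <- votes[votes$count > 0, ]
  sub <- typicality_subsets(votes, "target", m = 6, seed = 2)
  acc_for <- function(role) {
    keep <- sub$item[sub$role == role]
    bayes_classify(votes[votes$item %in% keep, ], "target", "pred",
                   mode = "naive")$accuracy
  }
  expect_gte(acc_for("typical"), acc_for("atypical"))
})

test_that("vote tables report modal categories and agreement", {
  counts <- tibble::tibble(
    item = c("x", "x", "y"), dimension = "d",
    category = c("A", "B", "B"), count = c(3, 1, 5))
  vt <- vote_table(counts)
  expect_equal(vt$modal[vt$item == "x"], "A")
  expect_equal(vt$agreement[vt$item == "x"], 0.75)
  # lexicographic tie-break
  tie <- tibble::tibble(item = "z", dimension = "d",
                        category = c("B", "A"), count = c(2, 2))
  expect_equal(vote_table(tie)$modal, "A")
})
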