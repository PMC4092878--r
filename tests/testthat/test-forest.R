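sim_two_class <- function(n_a, n_b, delta, seed) {
  set.seed(seed)
  data.frame(
    f1 = c(rnorm(n_a), rnorm(n_b, delta)),
    f2 = rnorm(n_a + n_b),
    label = rep(c("a", "b"), c(n_a, n_b)),
    stringsAsFactors = FALSE
  )
}

test_that("well-separated classes give high OOB balanced accuracy", {
  d <- sim_two_class(100, 100, 4, seed = 1)
  m <- suppressMessages(train_weighted_forest(
    d, d$label, forest_config(n_trees = 200, seed = 2),
    features = c("f1", "f2")))
  sc <- suppressMessages(oob_scores(m))
  pred <- classify_scores(sc)
  errs <- tapply(pred != m$labels, m$labels, mean)
  expect_gte(1 - mean(errs), 0.95)
})

test_that("permuted labels give chance-level OOB AUC", {
  set.seed(5)
  d <- sim_two_class(100, 100, 4, seed = 5)
  d$label <- sample(d$label)
  rep <- suppressMessages(run_two_group(
    d, d$label, "a", "b", forest_config(n_trees = 200, seed = 7),
    features = c("f1", "f2")))
  expect_gte(rep$auc, 0.4)
  expect_lte(rep$auc, 0.6)
})

test_that("reciprocal weights balance per-class errors at 10:1 imbalance", {
  d <- sim_two_class(500, 50, 0, seed = 9) # identical distributions
  m <- suppressMessages(train_weighted_forest(
    d, d$label, forest_config(n_trees = 300, seed = 11),
    features = c("f1", "f2")))
  pred <- classify_scores(suppressMessages(oob_scores(m)))
  errs <- tapply(pred != m$labels, m$labels, mean)
  expect_lt(abs(errs[["a"]] - errs[["b"]]), 0.15)
})

test_that("oob scores are normalized, single-tree scores one-hot", {
  d <- sim_two_class(60, 60, 2, seed = 3)
  m <- suppressMessages(train_weighted_forest(
    d, d$label, forest_config(n_trees = 50, seed = 4),
    features = c("f1", "f2")))
  sc <- suppressMessages(oob_scores(m))
  ok <- !is.na(sc[, 1])
  expect_true(all(abs(rowSums(sc[ok, , drop = FALSE]) - 1) < 1e-9))
  expect_true(all(sc[ok, ] >= 0))

  m1 <- suppressMessages(train_weighted_forest(
    d, d$label, forest_config(n_trees = 1, seed = 4),
    features = c("f1", "f2")))
  sc1 <- suppressMessages(oob_scores(m1))
  defined <- !is.na(sc1[, 1])
  expect_true(all(sc1[defined, ] %in% c(0, 1)))
  expect_gt(attr(sc1, "n_undefined"), 0) # in-bag rows have no OOB score
})

test_that("seed determinism and weight scale invariance", {
  d <- sim_two_class(80, 40, 1, seed = 6)
  cfg <- forest_config(n_trees = 100, seed = 13)
  m1 <- suppressMessages(train_weighted_forest(d, d$label, cfg,
                                               features = c("f1", "f2")))
  m2 <- suppressMessages(train_weighted_forest(d, d$label, cfg,
                                               features = c("f1", "f2")))
  expect_identical(m1$votes, m2$votes)

  w <- c(a = 1, b = 2)
  ma <- suppressMessages(train_weighted_forest(
    d, d$label, forest_config(n_trees = 100, seed = 13,
                              class_weights = w),
    features = c("f1", "f2")))
  mb <- suppressMessages(train_weighted_forest(
    d, d$label, forest_config(n_trees = 100, seed = 13,
                              class_weights = 4 * w),
    features = c("f1", "f2")))
  expect_identical(ma$votes, mb$votes)
})

test_that("input validation: single class, non-finite features, mtry", {
  d <- sim_two_class(20, 20, 1, seed = 2)
  expect_error(suppressMessages(train_weighted_forest(
    d, rep("a", 40), forest_config(n_trees = 5),
    features = c("f1", "f2"))), "2 classes")
  d2 <- d
  d2$f1[3] <- Inf
  expect_error(suppressMessages(train_weighted_forest(
    d2, d2$label, forest_config(n_trees = 5),
    features = c("f1", "f2"))), "non-finite")
  expect_error(suppressMessages(train_weighted_forest(
    d, d$label, forest_config(n_trees = 5, mtry = 10),
    features = c("f1", "f2"))), "mtry")
  expect_error(forest_config(class_weights = c(a = -1, b = 1)),
               "positive")
  # rows with NA features dropped with a message
  d3 <- d
  d3$f2[1] <- NA
  expect_message(train_weighted_forest(d3, d3$label,
                                       forest_config(n_trees = 5),
                                       features = c("f1", "f2")),
                 "dropped 1")
})

test_that("argmax classification equals the three-line simplex geometry", {
  # boundary lines in the neutral(x)-disease(y) plane: y = x,
  # 1 - 2x - y = 0, 1 - x - 2y = 0, meeting at (1/3, 1/3)
  geometric_rule <- function(x, y) {
    pgx <- 1 - x - y
    if (y > x && y > pgx) "disease"
    else if (x > y && x > pgx) "neutral"
    else if (pgx > x && pgx > y) "pgx"
    else NA_character_ # boundary, tie-break applies
  }
  set.seed(77)
  for (i in 1:1000) {
    p <- diff(c(0, sort(runif(2)), 1)) # uniform on the simplex
    sc <- matrix(p, 1, dimnames = list(NULL,
                                       c("neutral", "disease", "pgx")))
    geo <- geometric_rule(p[1], p[2])
    if (!is.na(geo)) {
      expect_equal(classify_three_group(sc), geo)
    }
  }
  # exact boundary point: alphabetical tie-break -> disease
  tie <- matrix(rep(1 / 3, 3), 1,
                dimnames = list(NULL, c("neutral", "disease", "pgx")))
  expect_equal(classify_three_group(tie), "disease")
  expect_equal(classify_scores(
    matrix(c(0.5, 0.3, 0.2), 1,
           dimnames = list(NULL, c("neutral", "disease", "pgx")))),
    "neutral")
})

test_that("equal-weight trees aggregate votes uniformly", {
  # three stumps that always predict class 0: scores are one-hot
  d <- data.frame(f1 = c(0, 1, 0, 1), f2 = c(1, 1, 0, 0),
                  label = c("a", "a", "b", "b"))
  m <- suppressMessages(train_weighted_forest(
    d, d$label, forest_config(n_trees = 3, seed = 1),
    features = c("f1", "f2")))
  sc <- suppressMessages(oob_scores(m))
  ok <- !is.na(sc[, 1])
  expect_true(all(rowSums(sc[ok, , drop = FALSE]) == 1))
})

test_that("raising the PGx weight lowers PGx error (monotone balancing)", {
  b <- gen_feature_table(schema = "structure", seed = 3)
  tab <- b$feature_table
  sizes <- table(tab$label)
  base_w <- 1 / as.numeric(sizes[c("disease", "neutral", "pgx")])
  names(base_w) <- c("disease", "neutral", "pgx")
  mult <- c(0.5, 1, 2, 4, 8)
  mean_err <- vapply(mult, function(k) {
    errs <- vapply(1:5, function(s) {
      w <- base_w
      w["pgx"] <- w["pgx"] * k
      cfg <- forest_config(n_trees = 150, seed = 100 + s,
                           class_weights = w)
      tg <- suppressMessages(run_three_group(tab, cfg))
      tg$per_class_error[["pgx"]]
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  # trend over the 5 weight settings: PGx error non-increasing overall
  expect_lt(mean_err[5], mean_err[1])
  expect_lt(cor(mult, mean_err, method = "spearman"), 0)
})

test_that("swapping positive and negative exchanges sensitivity/specificity", {
  d <- sim_two_class(80, 60, 1.5, seed = 21)
  cfg <- forest_config(n_trees = 150, seed = 8)
  ab <- suppressMessages(run_two_group(d, d$label, "a", "b", cfg,
                                       features = c("f1", "f2")))
  ba <- suppressMessages(run_two_group(d, d$label, "b", "a", cfg,
                                       features = c("f1", "f2")))
  expect_equal(ab$sensitivity, ba$specificity)
  expect_equal(ab$specificity, ba$sensitivity)
})
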