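test_that("threshold cutoff is the midpoint of the empty interval", {
  p <- fit_threshold(pos = c(2.0, 2.5), neg = c(0.5, 1.0), mirna_id = "m")
  expect_identical(p$orientation, "HIGHER_IS_DCV")
  expect_equal(p$cutoff, 1.5)
  expect_identical(predict(p, c(m = 1.6)), "DCV_POS")
  expect_identical(predict(p, c(m = 1.4)), "DCV_NEG")
  # boundary: exactly at the cutoff votes negative
  expect_identical(predict(p, c(m = 1.5)), "DCV_NEG")
  # missing value abstains
  expect_identical(predict(p, c(m = NA_real_)), "ABSTAIN")

  q <- fit_threshold(pos = c(-3, -2.5), neg = c(-1, 0), mirna_id = "m")
  expect_identical(q$orientation, "LOWER_IS_DCV")
  expect_equal(q$cutoff, (-2.5 + -1) / 2)
  expect_identical(predict(q, c(m = -1.5)), "DCV_NEG")
  expect_identical(predict(q, c(m = -1.75)), "DCV_NEG") # boundary
  expect_identical(predict(q, c(m = -3)), "DCV_POS")
})

test_that("an externally supplied cutoff is used verbatim", {
  p <- fit_threshold(pos = c(1, 2), neg = c(-2, -1),
                     mirna_id = "hsa-miR-19b-3p", cutoff = -0.481)
  expect_equal(p$cutoff, -0.481)
  expect_identical(predict(p, c(`hsa-miR-19b-3p` = -0.3)), "DCV_POS")
})

test_that("overlapping groups cannot make a threshold predictor", {
  expect_error(fit_threshold(pos = c(0, 2), neg = c(1, 3), mirna_id = "m"),
               "overlap")
})

test_that("threshold predictors are perfect on their training values", {
  fx <- train_fixture()
  x <- tibble::as_tibble(fx$nm)
  x <- x[x$fluid == "CSF" & !is.na(x$day) & x$day == "PBD3", ]
  for (m in fx$panel$separators) {
    p <- fx$panel$predictors[[m]]
    vals <- x[x$mirna_id == m & x$group != "HC", ]
    votes <- vapply(vals$delta_crt,
                    function(v) predict(p, stats::setNames(v, m)), "")
    expect_identical(votes, vals$group)
  }
})

test_that("a single separating variable gives a depth-1 perfect tree", {
  X <- data.frame(a = c(1, 2, 3, 10, 11, 12), b = c(5, 1, 4, 2, 6, 3))
  y <- rep(c("DCV_NEG", "DCV_POS"), each = 3)
  tree <- fit_cart(X, y)
  expect_identical(tree$root$type, "split")
  expect_identical(tree$root$var, "a")
  expect_identical(tree$root$left$type, "leaf")
  expect_identical(tree$root$right$type, "leaf")
  resub <- vapply(seq_len(nrow(X)),
                  function(i) predict(tree, as.list(X[i, ])), "")
  expect_identical(unname(resub), y)
})

test_that("pure labels give a single leaf; constant X cannot split", {
  t1 <- fit_cart(data.frame(a = rnorm(4)), rep("DCV_POS", 4))
  expect_identical(t1$root$type, "leaf")
  expect_identical(t1$root$class, "DCV_POS")
  t2 <- fit_cart(data.frame(a = rep(1, 4)),
                 c("DCV_POS", "DCV_POS", "DCV_NEG", "DCV_NEG"))
  expect_identical(t2$root$type, "leaf")
  expect_identical(t2$root$class, "DCV_NEG") # tie -> negative
})

test_that("the chosen root split matches exhaustive search on a toy table", {
  X <- data.frame(a = c(0.1, 0.4, 0.35, 0.8, 0.9, 0.75),
                  b = c(1.0, 2.0, 1.5, 1.8, 0.9, 2.2))
  y <- c("DCV_NEG", "DCV_NEG", "DCV_POS", "DCV_POS", "DCV_POS", "DCV_NEG")
  tree <- fit_cart(X, y)
  oracle <- brute_best_split(X, y)
  expect_identical(tree$root$var, oracle$var)
  expect_equal(tree$root$threshold, oracle$threshold)
})

test_that("root splits match the oracle on random small datasets", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    p <- sample(2:4, 1)
    X <- as.data.frame(matrix(rnorm(n * p), n))
    names(X) <- paste0("v", seq_len(p))
    y <- sample(c("DCV_POS", "DCV_NEG"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    tree <- fit_cart(X, y)
    oracle <- brute_best_split(X, y)
    expect_identical(tree$root$var, oracle$var)
    expect_equal(tree$root$threshold, oracle$threshold, tolerance = 1e-12)
  }
})

test_that("resubstitution predictions match a reference CART", {
  skip_if_not_installed("rpart")
  set.seed(43)
  for (i in 1:30) {
    n <- sample(6:14, 1)
    X <- data.frame(v1 = rnorm(n), v2 = rnorm(n), v3 = rnorm(n))
    y <- ifelse(X$v1 + 0.5 * X$v2 + rnorm(n, sd = 0.6) > 0,
                "DCV_POS", "DCV_NEG")
    if (length(unique(y)) < 2) next
    tree <- fit_cart(X, y)
    ref <- rpart::rpart(
      factor(y) ~ ., data = X, method = "class",
      control = rpart::rpart.control(minsplit = 2, minbucket = 1, cp = 0,
                                     maxdepth = 5, xval = 0)
    )
    ours <- vapply(seq_len(n), function(r) predict(tree, as.list(X[r, ])), "")
    theirs <- as.character(predict(ref, X, type = "class"))
    expect_identical(unname(ours), theirs)
  }
})

test_that("resubstitution accuracy is monotone in max_depth", {
  set.seed(47)
  X <- as.data.frame(matrix(rnorm(18 * 5), 18))
  y <- sample(c("DCV_POS", "DCV_NEG"), 18, replace = TRUE)
  acc <- vapply(1:5, function(d) {
    tree <- fit_cart(X, y, max_depth = d)
    mean(vapply(seq_len(18),
                function(r) predict(tree, as.list(X[r, ])), "") == y)
  }, 0)
  expect_true(all(diff(acc) >= 0))
})

test_that("tree prediction abstains on missing split variables", {
  X <- data.frame(a = c(1, 2, 10, 11), b = c(0, 0, 0, 0))
  y <- c("DCV_NEG", "DCV_NEG", "DCV_POS", "DCV_POS")
  tree <- fit_cart(X, y)
  expect_identical(predict(tree, list(a = NA_real_, b = 0)), "ABSTAIN")
  expect_identical(predict(tree, list(b = 0)), "ABSTAIN")
  expect_identical(predict(tree, list(a = 12, b = 0)), "DCV_POS")
})

test_that("consensus call needs at least k concordant votes", {
  expect_identical(
    consensus_call(c(rep("DCV_POS", 5), rep("DCV_NEG", 3)))$call, "DCV_POS")
  expect_identical(consensus_call(rep("DCV_NEG", 8))$call, "DCV_NEG")
  expect_identical(
    consensus_call(c(rep("DCV_POS", 4), rep("DCV_NEG", 4)))$call,
    "INDETERMINATE")
  # abstentions count for neither side
  expect_identical(
    consensus_call(c(rep("DCV_POS", 4), rep("ABSTAIN", 4)))$call,
    "INDETERMINATE")
})

test_that("consensus is monotone in single-vote flips", {
  set.seed(53)
  rank_of <- c(DCV_NEG = -1, INDETERMINATE = 0, DCV_POS = 1)
  for (i in 1:100) {
    votes <- sample(c("DCV_POS", "DCV_NEG", "ABSTAIN"), 8, replace = TRUE)
    flip <- which(votes == "DCV_NEG")
    if (length(flip) == 0) next
    votes2 <- votes
    votes2[sample(flip, 1)] <- "DCV_POS"
    expect_gte(rank_of[[consensus_call(votes2)$call]],
               rank_of[[consensus_call(votes)$call]])
  }
})

test_that("a fitted panel round-trips through JSON losslessly", {
  fx <- train_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  panel_to_json(fx$panel, path)
  back <- panel_from_json(path)
  expect_identical(back$separators, fx$panel$separators)
  expect_equal(tidy(back), tidy(fx$panel))

  test <- generate_pattern_cohort(fx$panel,
                                  list(case03 = names(fx$panel$predictors)))
  nm <- suppressWarnings(normalize_global_mean(
    test$crt, apply_detection_rules(test$crt)))
  profs <- subject_profiles(nm, fx$panel$fluid, fx$panel$day)
  for (prof in profs) {
    expect_identical(predict(back, prof), predict(fx$panel, prof))
  }
})
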