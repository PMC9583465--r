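test_that("rank AUC equals brute-force pair counting and pROC", {
  # oracle: count concordant pairs, half credit for ties
  pair_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (n in neg)
      tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
  }
  set.seed(20)
  for (i in 1:20) {
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(30), 1)  # rounding forces ties
    expect_equal(auc_score(s, y), pair_auc(s, y), tolerance = 1e-12)
    expect_equal(auc_score(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
  expect_error(auc_score(1:5, rep(1, 5)), "both classes")
})

test_that("pooled AUC is invariant to monotone transforms of scores", {
  set.seed(23)
  y <- rbinom(40, 1, 0.5)
  s <- rnorm(40)
  a <- auc_score(s, y)
  expect_equal(auc_score(exp(s), y), a)
  expect_equal(auc_score(rank(s), y), a)
  expect_equal(auc_score(2 * s + 10, y), a)
})

test_that("univariate AUC is orientation-corrected", {
  y <- rep(c(0, 1), each = 10)
  x <- c(rnorm(10, 5), rnorm(10, 0))  # lower in the positive class
  expect_gte(univariate_auc(x, y), 0.5)
  expect_equal(univariate_auc(y, y), 1.0)
  expect_equal(univariate_auc(-y, y), 1.0)
})

test_that("roc_points trace the empirical curve from (0,0) to (1,1)", {
  y <- c(0, 0, 1, 1)
  s <- c(0.1, 0.4, 0.35, 0.8)
  rc <- roc_points(s, y)
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1)
  expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  # trapezoid under the curve equals the rank AUC
  expect_equal(sum(diff(rc$fpr) * (head(rc$tpr, -1) + rc$tpr[-1]) / 2),
               auc_score(s, y))
})

test_that("stratified folds partition each class evenly", {
  y <- rep(c("control", "disease"), times = c(25, 24))
  f <- stratified_folds(y, 10, seed = 7)
  expect_length(f, 49)
  expect_setequal(unique(f), 1:10)
  for (k in 1:10) {
    expect_gte(sum(f == k & y == "control"), 2)
    expect_gte(sum(f == k & y == "disease"), 2)
  }
  expect_identical(f, stratified_folds(y, 10, seed = 7))
})

test_that("nested CV partitions subjects and fits preprocessing on training rows only", {
  features <- cached_features()
  sub <- analysis_subset(features, "normal")
  x <- sub[feature_names()]
  res <- nested_cv(x, sub$label, classifier_spec("LR", list(C = 1)),
                   seed = 7)
  # partition property: union of test folds is the cohort, no duplicates
  all_idx <- unlist(lapply(res$folds, `[[`, "test_idx"))
  expect_setequal(all_idx, seq_len(nrow(x)))
  expect_identical(length(all_idx), nrow(x))
  # leakage check by recomputation: each fold's normalization must equal
  # the one refit from that fold's training rows alone
  for (f in res$folds) {
    tr_rows <- setdiff(seq_len(nrow(x)), f$test_idx)
    pp <- oscml:::fit_preprocessor(x[tr_rows, ], "normalized")
    expect_equal(f$preprocessor$mu, pp$mu, tolerance = 1e-12)
    expect_equal(f$preprocessor$sd, pp$sd, tolerance = 1e-12)
  }
})

test_that("fuzzy-representation folds refit the scheme per training fold", {
  features <- cached_features()
  sub <- analysis_subset(features, "altered")
  x <- sub[feature_names()]
  res <- nested_cv(x, sub$label, classifier_spec("DT",
                                                 list(max_depth = 3,
                                                      criterion = "gini")),
                   representation = "fuzzy", seed = 7)
  for (f in res$folds[1:3]) {
    tr_rows <- setdiff(seq_len(nrow(x)), f$test_idx)
    sc <- fit_fuzzification(x[tr_rows, ])
    expect_equal(f$preprocessor$scheme$min, sc$min, tolerance = 1e-12)
    expect_equal(f$preprocessor$scheme$max, sc$max, tolerance = 1e-12)
  }
  expect_length(res$folds[[1]]$selected_features, 48L)
})

test_that("a perfectly separable cohort reaches pooled AUC 1 with LR", {
  set.seed(30)
  n <- 50
  x <- data.frame(sig = c(rnorm(n / 2, 0, 0.2), rnorm(n / 2, 5, 0.2)),
                  noise = rnorm(n))
  y <- rep(c(0L, 1L), each = n / 2)
  res <- nested_cv(x, y, classifier_spec("LR", list(C = c(1, 10))),
                   seed = 3)
  expect_equal(res$auc, 1.0)
})

test_that("RFE keeps the feature that carries all the signal", {
  set.seed(33)
  n <- 40
  x <- data.frame(a = rnorm(n), signal = rep(c(0, 4), each = n / 2) +
                    rnorm(n, 0, 0.3), b = rnorm(n), c = rnorm(n))
  y <- rep(c(0L, 1L), each = n / 2)
  sel <- rfe_select("LR", list(C = 1), x, y, n_features = 1, seed = 5)
  expect_identical(sel, "signal")
  # n_features = total - 1: exactly one elimination round
  path <- rfe_path("LR", list(C = 1), x, y, seed = 5,
                   min_features = ncol(x) - 1L)
  expect_length(path, ncol(x))
  sel3 <- rfe_select("LR", list(C = 1), x, y, n_features = 3, seed = 5,
                     path = path)
  expect_length(sel3, 3L)
  expect_true("signal" %in% sel3)
  expect_error(rfe_select("LR", list(C = 1), x, y, n_features = 4,
                          seed = 5, path = path), "n_features")
})

test_that("subset-size option lists follow the representation and engine", {
  expect_identical(rfe_n_options("LR", "normalized"), 1:15)
  expect_identical(rfe_n_options("SVM", "fuzzy"), 1:47)
  expect_identical(rfe_n_options("GP", "normalized"), c(4L, 8L, 12L))
  expect_identical(rfe_n_options("GE", "fuzzy"), c(12L, 24L, 36L))
})

test_that("group comparison flags separation and degeneracy correctly", {
  set.seed(40)
  n1 <- 25; n2 <- 23
  d <- data.frame(sep = c(rnorm(n1, 0), rnorm(n2, 3)),
                  null = rnorm(n1 + n2),
                  flat = rep(1, n1 + n2))
  y <- rep(c(0L, 1L), times = c(n1, n2))
  rep_tbl <- group_compare(d, y)
  expect_lt(rep_tbl$p_value[rep_tbl$feature == "sep"], 0.001)
  expect_true(rep_tbl$significant[rep_tbl$feature == "sep"])
  expect_gt(rep_tbl$p_value[rep_tbl$feature == "null"], 0.05)
  expect_equal(rep_tbl$p_value[rep_tbl$feature == "flat"], 1)
  expect_true(rep_tbl$degenerate[rep_tbl$feature == "flat"])
  # identical groups: no significance
  same <- data.frame(x = rep(seq_len(n1), 2))
  ident <- group_compare(same, rep(c(0L, 1L), each = n1))
  expect_gt(ident$p_value, 0.9)
})

test_that("fuzzy features are compared on membership values in the report format", {
  features <- cached_features()
  sub <- analysis_subset(features, "altered")
  sc <- fit_fuzzification(sub[feature_names()])
  fz <- fuzzify(sc, sub[feature_names()])
  rep_tbl <- group_compare(fz, sub$label)
  expect_identical(nrow(rep_tbl), 48L)
  sig <- rep_tbl[rep_tbl$significant, c("feature", "p_value")]
  expect_gt(nrow(sig), 0)
  expect_identical(names(sig), c("feature", "p_value"))
})

test_that("experiment 1 reports one orientation-corrected AUC per feature and analysis", {
  e1 <- experiment1(cached_features())
  expect_identical(nrow(e1), 32L)
  expect_setequal(unique(e1$analysis), c("normal", "altered"))
  expect_true(all(e1$auc >= 0.5 & e1$auc <= 1))
  expect_identical(e1$feature[e1$analysis == "normal"], feature_names())
})

test_that("selection frequency uses the algorithm-by-fold denominator", {
  fake_run <- function(feats_by_fold) {
    structure(list(folds = lapply(seq_along(feats_by_fold), function(i)
      list(fold = i, selected_features = feats_by_fold[[i]]))),
      class = "nested_cv_result")
  }
  runs <- list(fake_run(list(c("a", "b"), c("a"))),
               fake_run(list(c("b"), c("a", "c"))))
  sf <- selection_frequency(runs)
  expect_equal(sf$percent[sf$feature == "a"], 75)
  expect_equal(sf$percent[sf$feature == "b"], 50)
  expect_equal(sf$percent[sf$feature == "c"], 25)
  expect_true(all(sf$percent >= 0 & sf$percent <= 100))
})
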