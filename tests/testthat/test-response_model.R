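# Classification protocol: balanced subsampling, classifiers, forward
# selection, LOOCV evaluation, aggregation and univariate statistics.

test_that("balanced subsets keep all minority members plus an equal draw", {
  coh <- make_feature_cohort(n_per_class = 10, p = 4, seed = 1)
  # make it imbalanced: 14 R vs 6 NR
  coh$label <- c(rep("R", 14), rep("NR", 6))
  subs <- balanced_subsets(coh, n_subsets = 7, seed = 3)
  expect_length(subs, 7)
  for (s in subs) {
    expect_equal(sum(s$label == "NR"), 6)
    expect_equal(sum(s$label == "R"), 6)
    expect_true(all(coh$patient_id[coh$label == "NR"] %in% s$patient_id))
    expect_false(anyDuplicated(s$patient_id) > 0)
  }
  # subsets differ (majority draws differ across derived seed streams)
  expect_false(identical(subs[[1]]$patient_id, subs[[2]]$patient_id))
  # determinism
  subs2 <- balanced_subsets(coh, n_subsets = 7, seed = 3)
  expect_identical(lapply(subs, `[[`, "patient_id"),
                   lapply(subs2, `[[`, "patient_id"))

  # already balanced -> each subset is the full cohort
  bal <- make_feature_cohort(n_per_class = 5, p = 3, seed = 2)
  for (s in balanced_subsets(bal, 3, seed = 1)) {
    expect_setequal(s$patient_id, bal$patient_id)
  }
  expect_error(balanced_subsets(coh, 0), "n_subsets")
})

test_that("FLD separates blobs and respects affine-rescaling geometry", {
  set.seed(7)
  X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 4), 20))
  colnames(X) <- c("a", "b")
  y <- rep(c("R", "NR"), each = 20)
  m <- train_fld(X, y)
  pred <- ifelse(m$score(X) > m$threshold, "NR", "R")
  expect_equal(mean(pred == y), 1)

  # equal class means -> held-out AUC ~ 0.5 (null simulation)
  aucs <- vapply(1:10, function(s) {
    set.seed(100 + s)
    Xn <- matrix(rnorm(60 * 2), 60)
    yn <- rep(c("R", "NR"), 30)
    mn <- train_fld(Xn[1:40, ], yn[1:40])
    roc_curve(mn$score(Xn[41:60, ]), yn[41:60])$auc
  }, 0)
  expect_close(mean(aucs), 0.5, 0.12)

  # feature-wise affine rescaling is absorbed into Sw: projections of the
  # rescaled data equal the original up to overall scale
  D <- diag(c(3, 0.25))
  m2 <- train_fld(X %*% D, y)
  s1 <- m$score(X); s2 <- m2$score(X %*% D)
  expect_gt(abs(cor(s1, s2)), 1 - 1e-10)
})

test_that("KNN scoring recalls training labels and ignores duplication", {
  set.seed(8)
  X <- matrix(rnorm(30), 15, 2)
  y <- rep(c("R", "NR", "R"), 5)
  m1 <- train_knn(X, y, k = 1)
  expect_equal(ifelse(m1$score(X) > 0.5, "NR", "R"), y)

  # duplicating all training points (odd multiplicity) leaves scores alone
  m3 <- train_knn(rbind(X, X, X), c(y, y, y), k = 3)
  q <- matrix(rnorm(10), 5, 2)
  expect_equal(train_knn(X, y, k = 1)$score(q), m3$score(q))

  expect_error(train_knn(X, y, k = 20), "k must lie")
})

test_that("SVM-RBF solves XOR where FLD cannot", {
  set.seed(9)
  n <- 40
  X <- matrix(runif(2 * n, -1, 1), n, 2)
  y <- ifelse(X[, 1] * X[, 2] > 0, "NR", "R")
  z <- scale(X)
  svm <- train_svm_rbf(z, y, C = 10, gamma = 2)
  expect_gte(mean(ifelse(svm$score(z) > 0, "NR", "R") == y), 0.9)
  fld <- train_fld(z, y)
  expect_lte(mean(ifelse(fld$score(z) > fld$threshold, "NR", "R") == y), 0.7)
})

test_that("forward selection finds the informative feature and stops early", {
  hits <- vapply(1:10, function(s) {
    coh <- make_feature_cohort(n_per_class = 12, p = 10, shift = 3, seed = s)
    sel <- forward_select(cohort_features(coh), coh$label,
                          classifier_spec("fld"), max_k = 3)
    sel[1] == "F01"
  }, TRUE)
  expect_gte(mean(hits), 0.9)

  coh <- make_feature_cohort(n_per_class = 12, p = 6, shift = 3, seed = 3)
  one <- forward_select(cohort_features(coh), coh$label,
                        classifier_spec("fld"), max_k = 1)
  expect_length(one, 1)

  # deterministic under ties: duplicated informative column, canonical order
  X <- cohort_features(coh)
  X2 <- cbind(X, F01b = X[, "F01"])
  s1 <- forward_select(X2, coh$label, classifier_spec("fld"), max_k = 1)
  s2 <- forward_select(X2, coh$label, classifier_spec("fld"), max_k = 1)
  expect_identical(s1, s2)

  # all-degenerate candidates -> empty selection with a warning
  Xc <- matrix(1, 24, 3, dimnames = list(NULL, c("c1", "c2", "c3")))
  expect_warning(sel0 <- forward_select(Xc, coh$label, classifier_spec("fld")),
                 "degenerate")
  expect_length(sel0, 0)
})

test_that("LOOCV evaluation produces the six-metric panel and honest ROC", {
  coh <- make_feature_cohort(n_per_class = 8, p = 5, shift = 6, seed = 4)
  res <- loocv_evaluate(coh, classifier_spec("knn", k = 3))
  for (m in c("sensitivity", "specificity", "PPV", "NPV", "accuracy")) {
    expect_equal(res[[m]], 1, info = m)
  }
  expect_equal(res$AUC, 1)
  expect_s3_class(res$roc, "roc_curve")
  expect_equal(res$roc$fpr[1], 0)
  expect_equal(utils::tail(res$roc$tpr, 1), 1)
  expect_true(all(diff(res$roc$tpr) >= 0))
})

test_that("trapezoid AUC equals the Mann-Whitney U identity", {
  set.seed(10)
  for (i in 1:25) {
    n1 <- sample(5:20, 1); n0 <- sample(5:20, 1)
    sc <- c(rnorm(n1, 0.5), rnorm(n0))
    if (i %% 3 == 0) sc <- round(sc)  # force ties
    labs <- c(rep("NR", n1), rep("R", n0))
    auc <- roc_curve(sc, labs)$auc
    u <- unname(stats::wilcox.test(sc[labs == "NR"], sc[labs == "R"],
                                   exact = FALSE)$statistic)
    expect_equal(auc, u / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("no leakage: a held-out-only outlier cannot change selection", {
  coh <- make_feature_cohort(n_per_class = 6, p = 6, shift = 3, seed = 11)
  spec <- classifier_spec("fld")
  r1 <- loocv_evaluate(coh, spec, selection = "nested", max_features = 2)
  out <- coh
  fcols <- sprintf("F%02d", 1:6)
  out[3, fcols] <- out[3, fcols] * 1000 + 500
  r2 <- loocv_evaluate(out, spec, selection = "nested", max_features = 2)
  expect_identical(r1$per_fold[[3]], r2$per_fold[[3]])
})

test_that("subset aggregation averages metrics and keeps per-subset panels", {
  coh <- make_feature_cohort(n_per_class = 7, p = 4, shift = 4, seed = 12)
  subs <- balanced_subsets(coh, 3, seed = 1)
  res <- lapply(subs, loocv_evaluate, spec = classifier_spec("fld"),
                max_features = 1)
  agg <- aggregate_subsets(res, "mean")
  for (m in c("accuracy", "AUC")) {
    vals <- vapply(res, `[[`, 0, m)
    expect_gte(agg$panel[[m]], min(vals))
    expect_lte(agg$panel[[m]], max(vals))
  }
  # identical subset results -> aggregate equals them
  agg1 <- aggregate_subsets(res[c(1, 1)], "mean")
  expect_equal(agg1$panel$AUC, res[[1]]$AUC)
  # switching the rule changes the summary only, not per-subset results
  aggp <- aggregate_subsets(res, "pooled")
  expect_identical(aggp$per_subset, agg$per_subset)
  expect_s3_class(aggp$roc, "roc_curve")
})

test_that("univariate comparison gates between t and Mann-Whitney", {
  set.seed(13)
  n <- 40
  X <- cbind(shifted = c(rnorm(n), rnorm(n, 3)),
             heavy = rt(2 * n, df = 1),
             flat = rep(1, 2 * n),
             nullf = rnorm(2 * n))
  coh <- cohort_table(sprintf("p%d", 1:(2 * n)),
                      rep(c("R", "NR"), each = n), X)
  rep <- compare_feature_distributions(coh)
  expect_lt(rep$p_value[rep$feature == "shifted"], 1e-3)
  expect_equal(rep$test[rep$feature == "heavy"], "mann-whitney")
  expect_equal(rep$test[rep$feature == "shifted"], "t")
  expect_equal(rep$test[rep$feature == "flat"], "skipped")
  expect_true(is.na(rep$p_value[rep$feature == "flat"]))
})
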