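# Response-classification protocol: balanced subsampling of an imbalanced
# cohort, sequential forward feature selection (at most 3 features),
# FLD / KNN / SVM-RBF classifiers, leave-one-out cross-validation, and the
# sensitivity/specificity/PPV/NPV/accuracy/AUC evaluation panel.
#
# The positive class is the non-responder (NR) label throughout: the
# clinically critical event is treatment failure, and the panel orientation
# (high NPV, moderate PPV under 83/17 imbalance) matches that convention.

#' Build a cohort table
#'
#' @param ids character vector of unique patient ids
#' @param labels character/factor with two classes (conventionally "R" and
#'   "NR")
#' @param features numeric matrix or data.frame, one row per patient
#' @param rfs_months,event optional survival columns, carried through but
#'   unused by the classifier
#' @return data.frame of class `cohort_table` with columns patient_id,
#'   label, then features
#' @export
cohort_table <- function(ids, labels, features, rfs_months = NULL,
                         event = NULL) {
  assert(!anyDuplicated(ids), "patient ids must be unique")
  features <- as.data.frame(features)
  assert(nrow(features) == length(ids), "features rows must match ids")
  df <- data.frame(patient_id = as.character(ids),
                   label = as.character(labels),
                   stringsAsFactors = FALSE)
  if (!is.null(rfs_months)) df$rfs_months <- rfs_months
  if (!is.null(event)) df$event <- event
  df <- cbind(df, features)
  class(df) <- c("cohort_table", "data.frame")
  df
}

cohort_features <- function(cohort, feature_names = NULL) {
  meta <- c("patient_id", "label", "rfs_months", "event")
  fn <- setdiff(names(cohort), meta)
  if (!is.null(feature_names)) {
    assert(all(feature_names %in% fn),
           "requested features missing from cohort")
    fn <- feature_names
  }
  as.matrix(cohort[, fn, drop = FALSE])
}

#' Balanced subsampling of an imbalanced cohort
#'
#' Each subset contains every minority-class patient plus an equal-sized
#' random draw (without replacement within the subset) from the majority
#' class; subsets differ through derived seed streams. With an 83/17 cohort
#' each subset has 17 + 17 = 34 rows.
#'
#' @param cohort a [cohort_table()]
#' @param n_subsets number of subsets (default 7)
#' @param seed integer seed
#' @return list of `cohort_table` subsets
#' @export
balanced_subsets <- function(cohort, n_subsets = 7, seed = 1) {
  assert(n_subsets >= 1, "n_subsets must be >= 1")
  tab <- table(cohort$label)
  assert(length(tab) == 2, "cohort must contain exactly two classes")
  minority <- names(tab)[which.min(tab)]
  majority <- setdiff(names(tab), minority)
  n_min <- min(tab)
  assert(n_min >= 2, "minority class must have >= 2 patients")
  min_rows <- which(cohort$label == minority)
  maj_rows <- which(cohort$label == majority)
  lapply(seq_len(n_subsets), function(s) {
    set.seed(derive_seed(seed, s))
    draw <- if (length(maj_rows) == n_min) maj_rows else
      sample(maj_rows, n_min)
    sub <- cohort[sort(c(min_rows, draw)), , drop = FALSE]
    rownames(sub) <- NULL
    class(sub) <- class(cohort)
    sub
  })
}

# ---- classifiers -----------------------------------------------------------
# All scorers share the convention: higher score = more NR-like (positive).

#' Classifier specification
#'
#' @param type "fld", "knn" or "svm"
#' @param k neighbours for KNN (odd, default 5)
#' @param C,gamma SVM-RBF cost and kernel width; `gamma = NULL` uses 1/p on
#'   standardized features
#' @param positive positive-class label (default "NR")
#' @return list of class `classifier_spec`
#' @export
classifier_spec <- function(type = c("knn", "fld", "svm"), k = 5, C = 1,
                            gamma = NULL, positive = "NR") {
  type <- match.arg(type)
  structure(list(type = type, k = k, C = C, gamma = gamma,
                 positive = positive),
            class = "classifier_spec")
}

#' Fisher's linear discriminant scorer
#'
#' `w` is proportional to `Sw^-1 (mu1 - mu0)` with `Sw` the pooled
#' within-class covariance (ridge-regularized when singular); the decision
#' threshold is the midpoint of the projected class means.
#'
#' @param X numeric matrix (rows = samples)
#' @param y labels
#' @param positive positive-class label
#' @param ridge regularization added to Sw's diagonal when inversion fails
#' @return object of class `fld_model` with `$score(X)` and `$threshold`
#' @export
train_fld <- function(X, y, positive = "NR", ridge = 1e-8) {
  X <- as.matrix(X)
  pos <- y == positive
  assert(sum(pos) >= 2 && sum(!pos) >= 2, "need >= 2 samples per class")
  mu1 <- colMeans(X[pos, , drop = FALSE])
  mu0 <- colMeans(X[!pos, , drop = FALSE])
  S <- ((sum(pos) - 1) * stats::cov(X[pos, , drop = FALSE]) +
          (sum(!pos) - 1) * stats::cov(X[!pos, , drop = FALSE])) /
    (nrow(X) - 2)
  w <- tryCatch(solve(S, mu1 - mu0), error = function(e) {
    solve(S + diag(ridge * max(1, mean(diag(S))), ncol(X)), mu1 - mu0)
  })
  thr <- sum(w * (mu1 + mu0)) / 2
  structure(list(w = w, threshold = thr, positive = positive,
                 score = function(Xn) as.vector(as.matrix(Xn) %*% w)),
            class = "fld_model")
}

#' k-nearest-neighbour scorer
#'
#' Score of a query point is the fraction of its k nearest training
#' neighbours (Euclidean metric) carrying the positive label; the decision
#' threshold is 0.5.
#'
#' @inheritParams train_fld
#' @param k number of neighbours (must not exceed the training size)
#' @return object of class `knn_model` with `$score(X)`
#' @export
train_knn <- function(X, y, k = 5, positive = "NR") {
  X <- as.matrix(X)
  assert(k >= 1 && k <= nrow(X), "k must lie in [1, n_train]")
  ypos <- as.numeric(y == positive)
  score <- function(Xn) {
    Xn <- as.matrix(Xn)
    d2 <- outer(rowSums(Xn^2), rowSums(X^2), "+") - 2 * Xn %*% t(X)
    apply(d2, 1, function(dr) mean(ypos[order(dr)[seq_len(k)]]))
  }
  structure(list(k = k, positive = positive, threshold = 0.5, score = score),
            class = "knn_model")
}

# Platt-style simplified SMO with deterministic second-index choice.
smo_fit <- function(K, y, C, tol = 1e-3, max_passes = 10, max_iter = 2000) {
  n <- length(y)
  alpha <- numeric(n); b <- 0
  passes <- 0; iter <- 0
  fcache <- function() as.vector(K %*% (alpha * y)) + b
  while (passes < max_passes && iter < max_iter) {
    changed <- 0
    f <- fcache()
    E <- f - y
    for (i in seq_len(n)) {
      iter <- iter + 1
      Ei <- E[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        j <- which.max(abs(E - Ei) + ifelse(seq_len(n) == i, -Inf, 0))
        Ej <- E[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          Lb <- max(0, aj_old - ai_old); Hb <- min(C, C + aj_old - ai_old)
        } else {
          Lb <- max(0, ai_old + aj_old - C); Hb <- min(C, ai_old + aj_old)
        }
        if (Lb >= Hb) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - y[j] * (Ei - Ej) / eta
        aj <- min(Hb, max(Lb, aj))
        if (abs(aj - aj_old) < 1e-5) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
          y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
          y[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else
          (b1 + b2) / 2
        f <- as.vector(K %*% (alpha * y)) + b
        E <- f - y
        changed <- changed + 1
      }
    }
    passes <- if (changed == 0) passes + 1 else 0
  }
  list(alpha = alpha, b = b)
}

#' RBF-kernel support-vector-machine scorer
#'
#' Soft-margin SVM with Gaussian kernel `exp(-gamma ||x - x'||^2)` solved by
#' a deterministic SMO; the score is the decision-function value, threshold
#' 0.
#'
#' @inheritParams train_fld
#' @param C soft-margin cost
#' @param gamma kernel width; default 1/p
#' @return object of class `svm_model` with `$score(X)`
#' @export
train_svm_rbf <- function(X, y, C = 1, gamma = NULL, positive = "NR") {
  X <- as.matrix(X)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  yy <- ifelse(y == positive, 1, -1)
  assert(sum(yy == 1) >= 1 && sum(yy == -1) >= 1,
         "need both classes to train an SVM")
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * X %*% t(X)
  K <- exp(-gamma * pmax(d2, 0))
  fit <- smo_fit(K, yy, C)
  sv <- fit$alpha > 1e-8
  Xs <- X[sv, , drop = FALSE]; as_ <- fit$alpha[sv]; ys <- yy[sv]
  score <- function(Xn) {
    Xn <- as.matrix(Xn)
    if (!any(sv)) return(rep(fit$b, nrow(Xn)))
    dn <- outer(rowSums(Xn^2), rowSums(Xs^2), "+") - 2 * Xn %*% t(Xs)
    as.vector(exp(-gamma * pmax(dn, 0)) %*% (as_ * ys)) + fit$b
  }
  structure(list(C = C, gamma = gamma, positive = positive, threshold = 0,
                 score = score),
            class = "svm_model")
}

train_classifier <- function(X, y, spec) {
  switch(spec$type,
         fld = train_fld(X, y, spec$positive),
         knn = train_knn(X, y, spec$k, spec$positive),
         svm = train_svm_rbf(X, y, spec$C, spec$gamma, spec$positive))
}

# z-score parameters from training data only (leakage-free)
zscore_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}
zscore_apply <- function(X, z) sweep(sweep(as.matrix(X), 2, z$mu), 2, z$sd, "/")

# LOOCV accuracy of a classifier on (X, y) with per-fold standardization.
# Used as the forward-selection objective.
loocv_accuracy <- function(X, y, spec) {
  X <- as.matrix(X)
  n <- nrow(X)
  correct <- logical(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    if (length(unique(ytr)) < 2) { correct[i] <- NA; next }
    z <- zscore_fit(Xtr)
    mdl <- train_classifier(zscore_apply(Xtr, z), ytr, spec)
    sc <- mdl$score(zscore_apply(X[i, , drop = FALSE], z))
    pred <- if (sc > mdl$threshold) spec$positive else
      setdiff(unique(y), spec$positive)[1]
    correct[i] <- pred == y[i]
  }
  mean(correct, na.rm = TRUE)
}

#' Sequential forward feature selection
#'
#' Greedily adds the feature that maximizes LOOCV accuracy of the given
#' classifier on the training material, stopping early when no addition
#' strictly improves accuracy; at most `max_k` features (default 3). Ties
#' are broken by candidate (canonical) order.
#'
#' @param X training feature matrix with column names
#' @param y training labels
#' @param spec a [classifier_spec()]
#' @param candidates candidate feature names (default all columns)
#' @param max_k maximum number of features
#' @return character vector of selected names (length >= 1 unless all
#'   candidates are degenerate)
#' @export
forward_select <- function(X, y, spec = classifier_spec(),
                           candidates = colnames(X), max_k = 3) {
  X <- as.matrix(X)
  assert(length(candidates) >= 1, "need at least one candidate feature")
  usable <- candidates[apply(X[, candidates, drop = FALSE], 2, function(v)
    stats::sd(v) > 0 && all(is.finite(v)))]
  if (length(usable) == 0) {
    warning("all candidate features degenerate: empty selection")
    return(character(0))
  }
  selected <- character(0)
  best_acc <- -Inf
  while (length(selected) < max_k) {
    remaining <- setdiff(usable, selected)
    if (length(remaining) == 0) break
    accs <- vapply(remaining, function(f)
      loocv_accuracy(X[, c(selected, f), drop = FALSE], y, spec), 0)
    top <- which.max(accs)  # first maximum: canonical-order tie-break
    if (accs[top] > best_acc) {
      selected <- c(selected, remaining[top])
      best_acc <- accs[top]
    } else break
  }
  selected
}

#' ROC curve and trapezoid AUC from pooled scores
#'
#' @param scores numeric scores (higher = more positive)
#' @param labels class labels
#' @param positive positive-class label
#' @return object of class `roc_curve` with `fpr`, `tpr` (including the
#'   (0,0) and (1,1) endpoints) and `auc`
#' @export
roc_curve <- function(scores, labels, positive = "NR") {
  pos <- labels == positive
  assert(any(pos) && any(!pos), "need both classes for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # step only at distinct score values (ties grouped)
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(pos))
  fpr <- c(0, fp[last] / sum(!pos))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc, positive = positive),
            class = "roc_curve")
}

confusion_panel <- function(pred_pos, truth_pos) {
  tp <- sum(pred_pos & truth_pos); fn <- sum(!pred_pos & truth_pos)
  fp <- sum(pred_pos & !truth_pos); tn <- sum(!pred_pos & !truth_pos)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       NPV = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       accuracy = (tp + tn) / (tp + tn + fp + fn),
       confusion = c(TP = tp, FN = fn, FP = fp, TN = tn))
}

#' Leave-one-out cross-validated evaluation of one balanced subset
#'
#' For each left-out patient the remaining patients are standardized,
#' features are selected (nested mode, default) and the classifier trained;
#' the held-out score is pooled across folds into a ROC curve / AUC and a
#' confusion panel at the classifier's decision threshold. In "subset" mode
#' (the plausibly optimistic legacy protocol) selection happens once on the
#' whole subset before cross-validation; the mode is recorded in the result.
#'
#' @param subset a balanced `cohort_table`
#' @param spec a [classifier_spec()]
#' @param selection "nested" or "subset"
#' @param max_features maximum selected features (default 3)
#' @param feature_names candidate feature columns (default all)
#' @return object of class `eval_result`: the six-metric panel, `auc`,
#'   `roc`, `selected_features` (modal selection across folds), `per_fold`
#'   selections, `scores`, `labels`, `selection_mode`
#' @export
loocv_evaluate <- function(subset, spec = classifier_spec(),
                           selection = c("nested", "subset"),
                           max_features = 3, feature_names = NULL) {
  selection <- match.arg(selection)
  X <- cohort_features(subset, feature_names)
  y <- subset$label
  n <- nrow(X)
  assert(length(unique(y)) == 2, "subset must contain both classes")
  pre_selected <- if (selection == "subset")
    forward_select(X, y, spec, colnames(X), max_features) else NULL
  scores <- rep(NA_real_, n)
  fold_sel <- vector("list", n)
  skipped <- 0
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) { skipped <- skipped + 1; next }
    Xtr <- X[-i, , drop = FALSE]
    sel <- if (selection == "nested")
      forward_select(Xtr, ytr, spec, colnames(X), max_features) else
        pre_selected
    if (length(sel) == 0) { skipped <- skipped + 1; next }
    fold_sel[[i]] <- sel
    z <- zscore_fit(Xtr[, sel, drop = FALSE])
    mdl <- train_classifier(zscore_apply(Xtr[, sel, drop = FALSE], z), ytr,
                            spec)
    scores[i] <- mdl$score(zscore_apply(X[i, sel, drop = FALSE], z)) -
      mdl$threshold
  }
  ok <- is.finite(scores)
  assert(any(ok), "no usable LOOCV folds")
  roc <- roc_curve(scores[ok], y[ok], spec$positive)
  panel <- confusion_panel(scores[ok] > 0, y[ok] == spec$positive)
  sel_tab <- sort(table(vapply(fold_sel[ok], paste, "", collapse = "+")),
                  decreasing = TRUE)
  modal <- strsplit(names(sel_tab)[1], "+", fixed = TRUE)[[1]]
  structure(c(panel,
              list(AUC = roc$auc, roc = roc, selected_features = modal,
                   per_fold = fold_sel, scores = scores, labels = y,
                   selection_mode = selection, classifier = spec$type,
                   n = n, skipped_folds = skipped)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s (%s selection): sens %.2f, spec %.2f, PPV %.2f, NPV %.2f, acc %.2f, AUC %.3f\n",
              x$classifier, x$selection_mode, x$sensitivity, x$specificity,
              x$PPV, x$NPV, x$accuracy, x$AUC))
  cat("  selected:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate evaluation results across balanced subsets
#'
#' @param results list of `eval_result`
#' @param method "mean" (unweighted mean of each metric across subsets,
#'   default) or "pooled" (recompute the panel from all pooled
#'   cross-validated scores)
#' @return `eval_result`-like summary with `per_subset` retained
#' @export
aggregate_subsets <- function(results, method = c("mean", "pooled")) {
  method <- match.arg(method)
  assert(length(results) >= 1, "need at least one subset result")
  metrics <- c("sensitivity", "specificity", "PPV", "NPV", "accuracy", "AUC")
  if (method == "mean") {
    agg <- lapply(metrics, function(m)
      mean(vapply(results, function(r) r[[m]], 0), na.rm = TRUE))
    names(agg) <- metrics
    roc <- NULL
  } else {
    scores <- unlist(lapply(results, function(r) r$scores))
    labels <- unlist(lapply(results, function(r) as.character(r$labels)))
    ok <- is.finite(scores)
    pos <- results[[1]]$roc$positive
    roc <- roc_curve(scores[ok], labels[ok], pos)
    agg <- confusion_panel(scores[ok] > 0, labels[ok] == pos)
    agg$confusion <- NULL
    agg$AUC <- roc$auc
  }
  sel <- sort(table(unlist(lapply(results, function(r) r$selected_features))),
              decreasing = TRUE)
  structure(list(panel = agg, method = method, roc = roc,
                 selected_features = names(sel),
                 selection_counts = sel, per_subset = results),
            class = "subset_summary")
}

#' @export
print.subset_summary <- function(x, ...) {
  p <- x$panel
  cat(sprintf("<subset_summary> (%s over %d subsets): sens %.2f, spec %.2f, PPV %.2f, NPV %.2f, acc %.2f, AUC %.3f\n",
              x$method, length(x$per_subset), p$sensitivity, p$specificity,
              p$PPV, p$NPV, p$accuracy, p$AUC))
  invisible(x)
}

#' Univariate feature-distribution comparison between classes
#'
#' Per feature: Shapiro-Wilk normality in each class gates (at p >= 0.05 in
#' both) between an unpaired two-sample t-test and a Mann-Whitney test;
#' two-sided p-values, significance at p < alpha. Constant features are
#' skipped and flagged.
#'
#' @param cohort a [cohort_table()]
#' @param alpha significance level (default 0.05)
#' @param feature_names columns to test (default all features)
#' @return data.frame: feature, test ("t", "mann-whitney" or "skipped"),
#'   p_value, significant
#' @export
compare_feature_distributions <- function(cohort, alpha = 0.05,
                                          feature_names = NULL) {
  X <- cohort_features(cohort, feature_names)
  labs <- unique(cohort$label)
  assert(length(labs) == 2, "cohort must contain exactly two classes")
  g1 <- cohort$label == labs[1]
  assert(sum(g1) >= 3 && sum(!g1) >= 3, "need >= 3 samples per class")
  res <- lapply(colnames(X), function(f) {
    a <- X[g1, f]; b <- X[!g1, f]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 3 || length(b) < 3 ||
        stats::sd(a) == 0 || stats::sd(b) == 0) {
      return(data.frame(feature = f, test = "skipped", p_value = NA_real_,
                        significant = NA))
    }
    normal <- stats::shapiro.test(a)$p.value >= 0.05 &&
      stats::shapiro.test(b)$p.value >= 0.05
    p <- if (normal)
      stats::t.test(a, b, var.equal = TRUE)$p.value
    else
      stats::wilcox.test(a, b, exact = FALSE)$p.value
    data.frame(feature = f, test = if (normal) "t" else "mann-whitney",
               p_value = p, significant = p < alpha)
  })
  do.call(rbind, res)
}
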