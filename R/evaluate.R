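## Linear SVM classification with stratified five-fold cross-validation and
## nested grid search, metric panel, feature-importance ranking, attribution
## tables, single-site (SIFS) vs all-site (MIFS) comparison and per-feature
## group-difference tests. Positive class = moderate-severe pain.

POSITIVE_CLASS <- "moderate_severe"
NEGATIVE_CLASS <- "mild"

#' SVM / cross-validation configuration
#'
#' @param C_grid Positive regularization constants searched by the inner
#'   grid search.
#' @param inner_folds Folds of the inner (model-selection) cross-validation.
#' @param outer_folds Folds of the outer (evaluation) cross-validation.
#' @param seed Seed for the stratified fold assignment.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(C_grid = c(0.01, 0.1, 1, 10, 100), inner_folds = 5,
                       outer_folds = 5, seed = 1L) {
  if (length(C_grid) == 0 || any(C_grid <= 0)) {
    stop("C_grid must be non-empty and positive")
  }
  structure(list(C_grid = C_grid, inner_folds = as.integer(inner_folds),
                 outer_folds = as.integer(outer_folds),
                 seed = as.integer(seed)),
            class = "svm_config")
}

as_label_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c(NEGATIVE_CLASS, POSITIVE_CLASS))
  if (length(bad) > 0) stop("unknown class label(s): ",
                            paste(bad, collapse = ", "))
  factor(labels, levels = c(NEGATIVE_CLASS, POSITIVE_CLASS))
}

#' Train a linear soft-margin SVM
#'
#' Linear-kernel C-classification (L2-regularized hinge loss) via
#' \pkg{e1071}; the returned decision function is oriented so that positive
#' scores favour the moderate-severe class.
#'
#' @param x Numeric matrix (samples x features), already standardized and
#'   selected.
#' @param y Labels (`"mild"` / `"moderate_severe"`), both classes present.
#' @param C Regularization constant.
#' @return A list of class `linear_svm`: `weights` (named), `bias`, `C`.
#' @export
train_linear_svm <- function(x, y, C = 1) {
  x <- as.matrix(x)
  y <- as_label_factor(y)
  if (nlevels(droplevels(y)) < 2) {
    stop("training labels must contain both classes")
  }
  fit <- e1071::svm(x = x, y = y, kernel = "linear", cost = C,
                    scale = FALSE)
  w <- as.vector(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # e1071 orients decision values toward the first class in libsvm's
  # internal order; flip so that positive scores mean moderate-severe
  if (fit$levels[fit$labels[1]] != POSITIVE_CLASS) {
    w <- -w
    b <- -b
  }
  names(w) <- colnames(x)
  structure(list(weights = w, bias = b, C = C), class = "linear_svm")
}

#' Decision scores of a linear SVM
#'
#' @param model A [train_linear_svm()] fit.
#' @param x Feature matrix aligned with the training columns.
#' @return Numeric scores `w . x + b`; `> 0` predicts moderate-severe.
#' @export
svm_decision <- function(model, x) {
  as.vector(as.matrix(x) %*% model$weights + model$bias)
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  ifelse(svm_decision(object, newdata) > 0, POSITIVE_CLASS, NEGATIVE_CLASS)
}

#' Confusion counts with moderate-severe as the positive class
#'
#' @param pred,truth Label vectors.
#' @return Named vector `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  pos <- truth == POSITIVE_CLASS
  ppos <- pred == POSITIVE_CLASS
  c(tp = sum(pos & ppos), fp = sum(!pos & ppos),
    tn = sum(!pos & !ppos), fn = sum(pos & !ppos))
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' `P(score_pos > score_neg) + 0.5 P(tie)` computed from mid-ranks.
#'
#' @param scores Numeric decision scores.
#' @param labels True labels.
#' @return AUC in `[0, 1]`, or `NA` if a class is absent.
#' @export
auc_rank <- function(scores, labels) {
  pos <- labels == POSITIVE_CLASS
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metric panel
#'
#' Accuracy, sensitivity, specificity, precision, NPV from confusion counts
#' and AUC from decision scores. Ratios with a zero denominator are `NA`.
#'
#' @param counts Output of [confusion_counts()].
#' @param scores,labels Optional pooled decision scores and true labels for
#'   the rank-based AUC.
#' @return Named vector `accuracy`, `sensitivity`, `specificity`, `auc`,
#'   `precision`, `npv`.
#' @export
metric_panel <- function(counts, scores = NULL, labels = NULL) {
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  auc <- if (!is.null(scores)) auc_rank(scores, labels) else NA_real_
  c(accuracy = safe(tp + tn, tp + fp + tn + fn),
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    auc = auc,
    precision = safe(tp, tp + fp),
    npv = safe(tn, tn + fn))
}

# Stratified fold assignment: shuffle each class, deal round-robin.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  local_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        stop("class ", cl, " has fewer than ", k,
             " subjects; stratified ", k, "-fold split infeasible")
      }
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

# Inner grid search: mean inner-CV accuracy per C, ties to the smallest C.
grid_search_C <- function(x, y, svm_cfg) {
  if (length(svm_cfg$C_grid) == 1) return(svm_cfg$C_grid)
  folds <- stratified_folds(y, svm_cfg$inner_folds, svm_cfg$seed + 1L)
  acc <- vapply(svm_cfg$C_grid, function(C) {
    correct <- 0
    for (f in seq_len(svm_cfg$inner_folds)) {
      tr <- folds != f
      model <- train_linear_svm(x[tr, , drop = FALSE], y[tr], C)
      correct <- correct +
        sum(predict(model, x[!tr, , drop = FALSE]) == as.character(y[!tr]))
    }
    correct / length(y)
  }, numeric(1))
  svm_cfg$C_grid[which.max(acc)]
}

#' Cross-validated evaluation of the full pipeline
#'
#' Stratified outer five-fold cross-validation. Within each outer training
#' fold: fit standardization, score features by ANOVA F, keep the top
#' percentile, pick C by an inner stratified grid search on accuracy, refit,
#' and score the held-out fold. Confusion counts are pooled over the outer
#' folds and the AUC is computed from the pooled decision scores by rank
#' statistic. With `sel_cfg$fit_on_all = TRUE`, standardization and selection
#' are instead fit once on all data before the folds (single-pass mode).
#'
#' @param x Feature matrix (samples x features, named columns) or a feature
#'   table from [extract_cohort_features()].
#' @param labels Class labels; taken from the feature table's `group` column
#'   when `x` is a data.frame and `labels` is `NULL`.
#' @param sel_cfg A [selection_config()].
#' @param svm_cfg An [svm_config()].
#' @return A list of class `eval_report`: `pooled_counts`, `pooled_panel`,
#'   `folds` (per-fold panel, counts, best C, retained set, weight vector),
#'   `scores` (per-subject pooled decision scores), `importance` (per-feature
#'   mean |weight| ranking), `optimal_set` (whole-data selection),
#'   `attribution` (tallies of the optimal set), `mode`.
#' @export
cross_validate <- function(x, labels = NULL, sel_cfg = selection_config(),
                           svm_cfg = svm_config()) {
  if (is.data.frame(x)) {
    if (is.null(labels)) labels <- x$group
    x <- feature_matrix(x)
  }
  y <- as_label_factor(labels)
  k <- svm_cfg$outer_folds
  folds <- stratified_folds(y, k, svm_cfg$seed)
  p <- ncol(x)
  feat_names <- colnames(x)

  global_params <- NULL
  global_sel <- NULL
  if (sel_cfg$fit_on_all) {
    global_params <- standardize_fit(x)
    z <- standardize_apply(x, global_params)
    global_sel <- select_top_percentile(anova_f_scores(z, y),
                                        sel_cfg$percentile)
  }

  fold_out <- vector("list", k)
  score_all <- numeric(length(y))
  pred_all <- character(length(y))
  for (f in seq_len(k)) {
    tr <- folds != f
    if (sel_cfg$fit_on_all) {
      params <- global_params
      sel <- global_sel
    } else {
      params <- standardize_fit(x[tr, , drop = FALSE])
      ztr_full <- standardize_apply(x[tr, , drop = FALSE], params)
      sel <- select_top_percentile(anova_f_scores(ztr_full, y[tr]),
                                   sel_cfg$percentile)
    }
    ztr <- standardize_apply(x[tr, , drop = FALSE],
                             params)[, sel$retained_idx, drop = FALSE]
    zte <- standardize_apply(x[!tr, , drop = FALSE],
                             params)[, sel$retained_idx, drop = FALSE]
    best_C <- grid_search_C(ztr, y[tr], svm_cfg)
    model <- train_linear_svm(ztr, y[tr], best_C)
    sc <- svm_decision(model, zte)
    pr <- ifelse(sc > 0, POSITIVE_CLASS, NEGATIVE_CLASS)
    score_all[!tr] <- sc
    pred_all[!tr] <- pr
    counts <- confusion_counts(pr, as.character(y[!tr]))
    w_full <- numeric(p)
    names(w_full) <- feat_names
    w_full[sel$retained_idx] <- model$weights
    fold_out[[f]] <- list(
      fold = f,
      counts = counts,
      panel = metric_panel(counts, sc, as.character(y[!tr])),
      best_C = best_C,
      retained = sel$retained,
      weights = w_full,
      params = params)
  }

  pooled_counts <- confusion_counts(pred_all, as.character(y))
  pooled_panel <- metric_panel(pooled_counts, score_all, as.character(y))

  wmat <- do.call(rbind, lapply(fold_out, `[[`, "weights"))
  mean_abs <- colMeans(abs(wmat))
  importance <- data.frame(name = feat_names,
                           mean_weight = colMeans(wmat),
                           mean_abs_weight = mean_abs,
                           stringsAsFactors = FALSE)
  importance <- importance[order(-importance$mean_abs_weight), ]
  importance$rank <- seq_len(nrow(importance))
  rownames(importance) <- NULL

  params_all <- standardize_fit(x)
  optimal_sel <- select_top_percentile(
    anova_f_scores(standardize_apply(x, params_all), y), sel_cfg$percentile)
  # attribution only applies to protocol-named features
  attribution <- tryCatch(attribution_tables(optimal_sel$retained),
                          error = function(e) NULL)

  structure(list(
    pooled_counts = pooled_counts,
    pooled_panel = pooled_panel,
    folds = fold_out,
    fold_id = folds,
    scores = data.frame(score = score_all, pred = pred_all,
                        truth = as.character(y),
                        fold = folds, stringsAsFactors = FALSE),
    importance = importance,
    optimal_set = optimal_sel,
    attribution = attribution,
    mode = if (sel_cfg$fit_on_all) "fit_on_all" else "fold_wise",
    sel_cfg = sel_cfg, svm_cfg = svm_cfg),
    class = "eval_report")
}

#' Feature-importance ranking of an evaluation report
#'
#' Features ordered by the mean absolute SVM weight across the outer folds
#' (a feature not selected in a fold contributes weight 0 there).
#'
#' @param report An `eval_report`.
#' @param top Number of rows to return (default all).
#' @return Data.frame `name`, `mean_weight`, `mean_abs_weight`, `rank`.
#' @export
importance_ranking <- function(report, top = nrow(report$importance)) {
  utils::head(report$importance, top)
}

#' Attribution tallies of a retained feature set
#'
#' Counts retained features by family, muscle, level, side and position,
#' together with the denominators each category has in the 800-name universe.
#'
#' @param retained Character vector of serialized feature names.
#' @return Named list of data.frames (`family`, `muscle`, `level`, `side`,
#'   `position`), each with `category`, `selected`, `total`.
#' @export
attribution_tables <- function(retained) {
  parsed <- parse_feature_name(retained)
  uni <- feature_universe()
  tally <- function(field) {
    cats <- unique(uni[[field]])
    data.frame(category = cats,
               selected = vapply(cats, function(ct)
                 sum(parsed[[field]] == ct), 0L),
               total = vapply(cats, function(ct)
                 sum(uni[[field]] == ct), 0L),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(family = tally("family"), muscle = tally("muscle"),
       level = tally("level"), side = tally("side"),
       position = tally("position"))
}

#' Single-site (SIFS) evaluation
#'
#' Restricts the pipeline to the 57 features of one acquisition site and runs
#' the same cross-validation protocol.
#'
#' @param features Feature table from [extract_cohort_features()] or a named
#'   feature matrix.
#' @param site A `site_id` from [roi_protocol()], e.g. `"L2-L3_L_MF_prone"`.
#' @param labels,sel_cfg,svm_cfg As in [cross_validate()].
#' @return An `eval_report` for the single site.
#' @export
sifs_run <- function(features, site, labels = NULL,
                     sel_cfg = selection_config(), svm_cfg = svm_config()) {
  proto <- roi_protocol()
  if (!site %in% proto$site_id) {
    stop("unknown site '", site, "'; valid sites: ",
         paste(proto$site_id, collapse = ", "))
  }
  if (is.data.frame(features)) {
    if (is.null(labels)) labels <- features$group
    features <- feature_matrix(features)
  }
  parsed <- parse_feature_name(colnames(features))
  fsite <- paste(parsed$level, parsed$side, parsed$muscle, parsed$position,
                 sep = "_")
  keep <- fsite == site & parsed$family != "morphological"
  cross_validate(features[, keep, drop = FALSE], labels, sel_cfg, svm_cfg)
}

#' Single-site vs all-site comparison table
#'
#' One metric-panel row per acquisition site (SIFS) plus a `Total` row using
#' all 800 features (MIFS).
#'
#' @inheritParams sifs_run
#' @return Data.frame with `site` and the six panel metrics; 15 rows.
#' @export
sifs_table <- function(features, labels = NULL,
                       sel_cfg = selection_config(),
                       svm_cfg = svm_config()) {
  proto <- roi_protocol()
  if (is.data.frame(features)) {
    if (is.null(labels)) labels <- features$group
    features <- feature_matrix(features)
  }
  rows <- lapply(proto$site_id, function(s) {
    panel <- sifs_run(features, s, labels, sel_cfg, svm_cfg)$pooled_panel
    cbind(data.frame(site = s, stringsAsFactors = FALSE),
          as.data.frame(t(panel)))
  })
  total <- cross_validate(features, labels, sel_cfg, svm_cfg)$pooled_panel
  rows[[length(rows) + 1L]] <-
    cbind(data.frame(site = "Total", stringsAsFactors = FALSE),
          as.data.frame(t(total)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-feature two-group difference tests
#'
#' For each feature, `method = "auto"` applies a Shapiro-Wilk normality gate
#' at alpha = 0.05 per group: Student's t-test (equal variances) when both
#' groups pass, Mann-Whitney otherwise. `"t"` and `"wilcox"` force a branch.
#' Constant features are reported with `p = 1`.
#'
#' @param x Feature matrix or feature table.
#' @param labels Class labels (or `NULL` to use the table's `group`).
#' @param method `"auto"`, `"t"` or `"wilcox"`.
#' @param names Optional subset of feature names to test.
#' @return Data.frame `name`, `test`, `statistic`, `p`, `flag`
#'   (`"*"` p < 0.05, `"**"` p < 0.01).
#' @export
group_difference_tests <- function(x, labels = NULL,
                                   method = c("auto", "t", "wilcox"),
                                   names = NULL) {
  method <- match.arg(method)
  if (is.data.frame(x)) {
    if (is.null(labels)) labels <- x$group
    x <- feature_matrix(x)
  }
  x <- as.matrix(x)
  if (is.null(names)) names <- colnames(x)
  y <- as_label_factor(labels)
  rows <- lapply(names, function(nm) {
    v <- x[, nm]
    a <- v[y == NEGATIVE_CLASS]
    b <- v[y == POSITIVE_CLASS]
    if (max(v) - min(v) == 0) {
      return(data.frame(name = nm, test = "degenerate", statistic = NA_real_,
                        p = 1, stringsAsFactors = FALSE))
    }
    use_t <- switch(method, t = TRUE, wilcox = FALSE, auto = {
      normal <- function(g) {
        if (length(unique(g)) < 3 || length(g) < 3) return(FALSE)
        shapiro.test(g)$p.value > 0.05
      }
      normal(a) && normal(b)
    })
    if (use_t) {
      tt <- t.test(a, b, var.equal = TRUE)
      data.frame(name = nm, test = "t", statistic = unname(tt$statistic),
                 p = tt$p.value, stringsAsFactors = FALSE)
    } else {
      wt <- suppressWarnings(wilcox.test(a, b))
      data.frame(name = nm, test = "wilcoxon",
                 statistic = unname(wt$statistic), p = wt$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$flag <- ifelse(out$p < 0.01, "**", ifelse(out$p < 0.05, "*", ""))
  out
}
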