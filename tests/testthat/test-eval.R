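test_that("metric panel matches hand arithmetic and handles degenerate counts", {
  counts <- c(tp = 3, fp = 2, tn = 2, fn = 1)
  panel <- metric_panel(counts)
  expect_equal(panel[["accuracy"]], 0.625)
  expect_equal(panel[["sensitivity"]], 0.75)
  expect_equal(panel[["specificity"]], 0.5)
  expect_equal(panel[["precision"]], 0.6)
  expect_equal(panel[["npv"]], 2 / 3)
  perfect <- metric_panel(c(tp = 5, fp = 0, tn = 5, fn = 0),
                          scores = c(rep(1, 5), rep(-1, 5)),
                          labels = rep(c("moderate_severe", "mild"), each = 5))
  expect_true(all(perfect == 1))
  nopos <- metric_panel(c(tp = 0, fp = 0, tn = 4, fn = 0))
  expect_true(is.na(nopos[["sensitivity"]]))
  expect_true(is.na(nopos[["precision"]]))
})

test_that("rank AUC equals O(n^2) pair enumeration (with ties) and pROC", {
  set.seed(14)
  for (i in 1:5) {
    scores <- round(rnorm(30), 1)  # rounding forces ties
    labels <- sample(c("mild", "moderate_severe"), 30, replace = TRUE,
                     prob = c(0.45, 0.55))
    if (length(unique(labels)) < 2) next
    expect_equal(auc_rank(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    scores <- rnorm(40)
    labels <- rep(c("mild", "moderate_severe"), 20)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("mild",
                                                        "moderate_severe"),
      direction = "<", quiet = TRUE)))
    expect_equal(auc_rank(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("linear SVM solves the symmetric separable toy problem", {
  x <- rbind(c(-1, 0), c(-2, 0), c(1, 0), c(2, 0))
  colnames(x) <- c("u", "v")
  y <- c("mild", "mild", "moderate_severe", "moderate_severe")
  m <- train_linear_svm(x, y, C = 100)
  expect_equal(predict(m, x), y, ignore_attr = TRUE)
  expect_gt(m$weights[["u"]], 0)
  expect_lt(abs(m$weights[["v"]]), 1e-6)
  expect_lt(abs(m$bias), 1e-6)
  # duplicating every sample leaves the decision boundary unchanged
  m2 <- train_linear_svm(rbind(x, x), c(y, y), C = 100)
  expect_equal(m2$weights, m$weights, tolerance = 1e-6)
  expect_equal(m2$bias, m$bias, tolerance = 1e-6)
  expect_error(train_linear_svm(x, rep("mild", 4), C = 1), "both classes")
})

test_that("decision orientation favors moderate-severe regardless of row order", {
  set.seed(15)
  x <- matrix(rnorm(60), 30, 2)
  colnames(x) <- c("a", "b")
  y <- rep(c("mild", "moderate_severe"), 15)
  x[y == "moderate_severe", 1] <- x[y == "moderate_severe", 1] + 4
  for (ord in list(seq_len(30), order(y), rev(order(y)))) {
    m <- train_linear_svm(x[ord, ], y[ord], C = 10)
    sc <- svm_decision(m, x[ord, ])
    expect_gt(mean(sc[y[ord] == "moderate_severe"] > 0), 0.9)
    expect_gt(mean(sc[y[ord] == "mild"] < 0), 0.9)
  }
})

test_that("stratified folds partition subjects with balanced class proportions", {
  y <- c(rep("mild", 24), rep("moderate_severe", 28))
  folds <- sonolbp:::stratified_folds(y, 5, seed = 3)
  expect_length(folds, 52)
  expect_setequal(unique(folds), 1:5)
  for (f in 1:5) {
    held <- y[folds == f]
    expect_true(abs(sum(held == "mild") - 24 / 5) < 1)
    expect_true(abs(sum(held == "moderate_severe") - 28 / 5) < 1)
  }
  expect_error(sonolbp:::stratified_folds(rep(c("mild", "moderate_severe"),
                                              c(3, 20)), 5, 1),
               "infeasible")
})

test_that("a perfectly predictive feature yields a perfect pooled panel", {
  labels <- c(rep("mild", 10), rep("moderate_severe", 12))
  x <- matrix(ifelse(labels == "moderate_severe", 10, -10), ncol = 1)
  colnames(x) <- feature_universe()$name[1]
  rep <- cross_validate(x, labels,
                        sel_cfg = selection_config(percentile = 100),
                        svm_cfg = svm_config(C_grid = c(1)))
  expect_equal(rep$pooled_panel[["accuracy"]], 1)
  expect_equal(rep$pooled_panel[["auc"]], 1)
  expect_equal(sum(rep$pooled_counts), 22)
  # every subject held out exactly once; fold panels recombine to pooled
  expect_length(rep$fold_id, 22)
  expect_setequal(unique(rep$fold_id), 1:5)
  total <- Reduce(`+`, lapply(rep$folds, `[[`, "counts"))
  expect_equal(total, rep$pooled_counts)
})

test_that("permuted labels give chance-level pooled accuracy and AUC", {
  accs <- numeric(20)
  aucs <- numeric(20)
  for (s in 1:20) {
    syn <- synthetic_feature_matrix(24, 28, seed = 100 + s)
    set.seed(200 + s)
    lab <- sample(syn$labels)  # break any residual structure
    rep <- cross_validate(syn$x, lab, svm_cfg = svm_config(C_grid = c(1),
                                                           seed = s))
    accs[s] <- rep$pooled_panel[["accuracy"]]
    aucs[s] <- rep$pooled_panel[["auc"]]
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.07)
  # binomial 95% band around the majority-class rate 28/52
  prev <- 28 / 52
  half_width <- 1.96 * sqrt(prev * (1 - prev) / (52 * 20))
  expect_lt(mean(accs), prev + half_width)
})

test_that("importance ranking is sorted by mean absolute weight and parseable", {
  syn <- synthetic_feature_matrix(10, 12,
                                  shift_cols = feature_universe()$name[301:310],
                                  shift = 3, seed = 22)
  rep <- cross_validate(syn$x, syn$labels,
                        svm_cfg = svm_config(C_grid = c(1)))
  imp <- importance_ranking(rep, top = 20)
  expect_equal(nrow(imp), 20)
  expect_true(all(diff(rep$importance$mean_abs_weight) <= 1e-12))
  expect_equal(rep$importance$rank, seq_len(800))
  parsed <- parse_feature_name(imp$name)
  expect_equal(parsed$name, imp$name)
})

test_that("attribution tallies are conserved and use universe denominators", {
  uni <- feature_universe()
  set.seed(23)
  retained <- sample(uni$name, 48)
  att <- attribution_tables(retained)
  for (tab in att) {
    expect_equal(sum(tab$selected), 48)
  }
  expect_equal(sum(att$family$total), 800)
  expect_setequal(att$muscle$total, c(456, 114, 115, 115))
  full <- attribution_tables(uni$name)
  expect_equal(full$level$selected, full$level$total)
  expect_error(attribution_tables("garbage"), "unparseable")
})

test_that("group difference tests choose branches and match oracles", {
  x <- cbind(const = rep(1, 6), sep = c(1, 2, 3, 101, 102, 103))
  labels <- rep(c("mild", "moderate_severe"), each = 3)
  res <- group_difference_tests(x, labels, method = "wilcox")
  expect_equal(res$p[res$name == "const"], 1)
  # exact Mann-Whitney: U = 0, two-sided p = 2/choose(6,3) * 1 = 0.1
  expect_equal(res$p[res$name == "sep"], 0.1)
  expect_equal(res$flag[res$name == "sep"], "")
  set.seed(24)
  xr <- cbind(f = rnorm(20))
  lr <- rep(c("mild", "moderate_severe"), 10)
  rt <- group_difference_tests(xr, lr, method = "t")
  a <- xr[lr == "mild", 1]; b <- xr[lr == "moderate_severe", 1]
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  tstat <- (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  expect_equal(rt$statistic, tstat, tolerance = 1e-9)
  expect_equal(rt$p, 2 * pt(-abs(tstat), 18), tolerance = 1e-9)
  # identical groups: no flag
  xi <- cbind(f = rep(c(1, 2, 3, 4, 5), 2))
  li <- rep(c("mild", "moderate_severe"), each = 5)
  ri <- group_difference_tests(xi, li, method = "t")
  expect_equal(ri$p, 1)
  expect_equal(ri$flag, "")
  # auto gate: heavy-tailed data routes to the rank test
  set.seed(25)
  xh <- cbind(f = exp(rnorm(40, sd = 3)))
  lh <- rep(c("mild", "moderate_severe"), 20)
  rh <- group_difference_tests(xh, lh, method = "auto")
  expect_equal(rh$test, "wilcoxon")
})

test_that("single-site runs use exactly one ROI's features", {
  syn <- synthetic_feature_matrix(8, 9, seed = 26)
  rep <- sifs_run(syn$x, "L2-L3_L_TLF_prone", syn$labels,
                  sel_cfg = selection_config(percentile = 10),
                  svm_cfg = svm_config(C_grid = c(1)))
  # 57 features per site, 10% -> 5 retained
  expect_equal(rep$optimal_set$k, 5)
  parsed <- parse_feature_name(names(rep$optimal_set$f_scores))
  expect_true(all(parsed$muscle == "TLF" & parsed$side == "L"))
  expect_length(rep$optimal_set$f_scores, 57)
  expect_error(sifs_run(syn$x, "nonsense", syn$labels), "unknown site")
})
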