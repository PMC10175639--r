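## Feature standardization and ANOVA-percentile selection.
##
## Standardization is z-scoring with population moments (y = (x - mu) / sigma
## per feature). Selection scores each feature with the one-way ANOVA
## F-statistic between the two pain classes and keeps the top percentile
## (default 6%, i.e. 48 of 800 features).

#' Fit per-feature standardization parameters
#'
#' Population mean and standard deviation per column.
#'
#' @param x Numeric matrix (samples x features), at least 2 rows.
#' @return A list of class `standardization_params` with `mu`, `sigma` and
#'   `zero_var` (logical flag per column).
#' @export
standardize_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to fit standardization")
  mu <- colMeans(x)
  sigma <- sqrt(colMeans(sweep(x, 2, mu)^2))
  structure(list(mu = mu, sigma = sigma, zero_var = sigma == 0),
            class = "standardization_params")
}

#' Apply standardization parameters
#'
#' `y = (x - mu) / sigma`; zero-variance columns map to 0.
#'
#' @param x Numeric matrix with columns aligned to `params`.
#' @param params A [standardize_fit()] result.
#' @return Standardized matrix of the same shape.
#' @export
standardize_apply <- function(x, params) {
  x <- as.matrix(x)
  if (ncol(x) != length(params$mu)) {
    stop("column count does not match standardization parameters")
  }
  if (!is.null(colnames(x)) && !is.null(names(params$mu)) &&
      !identical(colnames(x), names(params$mu))) {
    stop("column names do not match standardization parameters")
  }
  denom <- ifelse(params$zero_var, 1, params$sigma)
  out <- sweep(sweep(x, 2, params$mu), 2, denom, "/")
  out[, params$zero_var] <- 0
  out
}

#' Per-feature one-way ANOVA F-scores for a two-class labeling
#'
#' `F = [SSB / (g - 1)] / [SSW / (n - g)]` with `g = 2`. A feature with zero
#' within-class variance but non-zero between-class separation scores `Inf`
#' (ranked above every finite score); an all-constant feature scores 0.
#'
#' @param x Numeric matrix (samples x features).
#' @param labels Two-class factor/character vector of length `nrow(x)`.
#' @return Named numeric vector of F-scores.
#' @export
anova_f_scores <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2) {
    stop("labels must contain exactly two classes")
  }
  if (min(table(labels)) < 2) stop("need at least 2 samples per class")
  n <- nrow(x)
  g1 <- labels == levels(labels)[1]
  n1 <- sum(g1)
  n2 <- n - n1
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  mu <- colMeans(x)
  ssb <- n1 * (m1 - mu)^2 + n2 * (m2 - mu)^2
  ssw <- colSums(sweep(x[g1, , drop = FALSE], 2, m1)^2) +
    colSums(sweep(x[!g1, , drop = FALSE], 2, m2)^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[ssw == 0 & ssb > 0] <- Inf
  f[ssw == 0 & ssb == 0] <- 0
  names(f) <- colnames(x)
  f
}

#' Keep the top-percentile features by F-score
#'
#' Retains `k = floor(n_features * percentile / 100)` features. Ties are
#' broken by position in the score vector (the canonical feature order), so
#' selection is deterministic.
#'
#' @param f_scores Named numeric vector of per-feature scores.
#' @param percentile Integer in `[1, 100]`, default 6.
#' @return A list of class `selection_result`: `f_scores`, `retained`
#'   (ordered names), `retained_idx`, `k`, `percentile`.
#' @export
#' @examples
#' sel <- select_top_percentile(
#'   stats::setNames(c(3, 1, 2, 5), letters[1:4]), percentile = 50)
#' sel$retained  # "d" "a"
select_top_percentile <- function(f_scores, percentile = 6) {
  if (percentile < 1 || percentile > 100) {
    stop("percentile must be in [1, 100]")
  }
  n <- length(f_scores)
  k <- floor(n * percentile / 100)
  if (k < 1) {
    stop("percentile ", percentile, " retains no feature out of ", n)
  }
  ord <- order(-f_scores, seq_len(n))  # stable: ties by canonical order
  idx <- sort(ord[seq_len(k)])
  structure(list(f_scores = f_scores,
                 retained = names(f_scores)[idx],
                 retained_idx = idx, k = k, percentile = percentile),
            class = "selection_result")
}

#' Cross-validated performance across selection percentiles
#'
#' Runs `eval_fn(x, labels, percentile)` for each requested percentile and
#' reports the resulting metric curve and its argmax.
#'
#' @param x Feature matrix (samples x features).
#' @param labels Two-class labels.
#' @param percentiles Integer vector of percentiles to try.
#' @param eval_fn Evaluator returning a single numeric metric; defaults to
#'   pooled cross-validated accuracy via [cross_validate()].
#' @return A data.frame `percentile`, `metric` with attribute `best`
#'   (percentile with the highest metric; ties to the smallest).
#' @export
percentile_sweep <- function(x, labels, percentiles = 1:100,
                             eval_fn = NULL) {
  if (is.null(eval_fn)) {
    eval_fn <- function(x, labels, percentile) {
      cross_validate(x, labels,
                     sel_cfg = selection_config(percentile = percentile),
                     svm_cfg = svm_config())$pooled_panel[["accuracy"]]
    }
  }
  metric <- vapply(percentiles, function(p) eval_fn(x, labels, p),
                   numeric(1))
  out <- data.frame(percentile = percentiles, metric = metric)
  attr(out, "best") <- percentiles[which.max(metric)]
  out
}

#' Selection configuration
#'
#' @param percentile Percentile of features to retain (default 6).
#' @param fit_on_all If `TRUE`, standardization and selection are fit once on
#'   the whole dataset before cross-validation (the literal single-pass
#'   procedure); the default `FALSE` refits both inside each training fold,
#'   which avoids information leaking from held-out folds.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(percentile = 6, fit_on_all = FALSE) {
  if (percentile < 1 || percentile > 100) {
    stop("percentile must be in [1, 100]")
  }
  structure(list(percentile = as.integer(percentile),
                 fit_on_all = isTRUE(fit_on_all)),
            class = "selection_config")
}
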