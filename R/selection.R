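#' Feature pre-filters and fold-wise selectors
#'
#' Inside every cross-validation fold the feature table is pre-filtered
#' (population variance < 0.01 dropped; one of every pair with Pearson
#' |r| > 0.95 dropped, later catalogue order losing), z-scored on training
#' statistics, and reduced by one of three selectors: PCA (components to
#' > 95% cumulative explained variance), LASSO-penalized logistic regression
#' (inner stratified 5-fold CV for the penalty), or bidirectional stepwise
#' logistic regression with likelihood-ratio chi-square entry/removal tests
#' (p_enter 0.05, p_remove 0.1). All fitted parameters are stored so held-out
#' rows are transformed without ever touching their labels.
#'
#' @name selection
NULL

#' Variance filter
#'
#' Drops columns whose population variance (denominator N) is below
#' `variance_min`. Idempotent.
#'
#' @param x numeric matrix (rows = cases) with column names.
#' @param variance_min threshold (default 0.01).
#' @return matrix with surviving columns; attribute `dropped` lists removed
#'   column names.
#' @export
variance_filter <- function(x, variance_min = 0.01) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  n <- nrow(x)
  v <- apply(x, 2, function(col) sum((col - mean(col))^2) / n)
  keep <- v >= variance_min
  if (!any(keep)) stop("empty table: all columns fall below the variance threshold")
  structure(x[, keep, drop = FALSE], dropped = colnames(x)[!keep])
}

#' Pairwise-correlation filter
#'
#' Greedy pass in column (catalogue) order: a column is kept only if its
#' absolute Pearson correlation with every already-kept column is <=
#' `correlation_max`; the later-ordered member of an offending pair is the
#' one dropped. Surviving pairs therefore all satisfy |r| <= threshold.
#'
#' @param x numeric matrix with >= 3 rows.
#' @param correlation_max threshold (default 0.95).
#' @return matrix of surviving columns; attribute `dropped`.
#' @export
correlation_filter <- function(x, correlation_max = 0.95) {
  stopifnot(is.matrix(x), nrow(x) >= 3)
  if (ncol(x) <= 1) return(structure(x, dropped = character(0)))
  r <- suppressWarnings(stats::cor(x))
  r[!is.finite(r)] <- 0
  keep <- logical(ncol(x))
  keep[1] <- TRUE
  for (jj in seq_len(ncol(x))[-1])
    keep[jj] <- all(abs(r[jj, keep]) <= correlation_max)
  structure(x[, keep, drop = FALSE], dropped = colnames(x)[!keep])
}

#' Z-scoring fitted on training rows
#'
#' @param x training matrix.
#' @return list with `center`, `scale` (zero-variance columns get scale 1)
#'   and class `zscore_fit`.
#' @export
fit_zscore <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  structure(list(center = ctr, scale = scl), class = "zscore_fit")
}

#' @rdname fit_zscore
#' @param fit a `zscore_fit`.
#' @param newx matrix (or single row) with the same columns.
#' @export
apply_zscore <- function(fit, newx) {
  if (is.null(dim(newx))) newx <- matrix(newx, 1, dimnames = list(NULL, names(newx)))
  sweep(sweep(newx[, names(fit$center), drop = FALSE], 2, fit$center), 2,
        fit$scale, "/")
}

new_selection_result <- function(selector, selected, params = list(),
                                 empty = FALSE, fold = NA_integer_) {
  structure(list(selector = selector, selected = selected, params = params,
                 empty_selection = empty, fold = fold),
            class = "selection_result")
}

#' PCA selector
#'
#' Principal components of the (already standardized) training rows; retains
#' the smallest number of leading components whose cumulative explained
#' variance ratio exceeds `cumulative_contribution` (at least 1).
#'
#' @param x standardized training matrix.
#' @param cumulative_contribution threshold (default 0.95).
#' @return `selection_result` whose `params$rotation` projects new rows.
#' @export
pca_select <- function(x, cumulative_contribution = 0.95) {
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(evr) > cumulative_contribution)[1]
  if (is.na(k)) k <- length(evr)
  k <- max(1L, k)
  new_selection_result("pca", colnames(x),
                       params = list(rotation = pc$rotation[, seq_len(k), drop = FALSE],
                                     n_components = k, explained = evr))
}

# Stratified fold ids for the inner LASSO cross-validation. Rows are ranked
# canonically (lexicographic feature order within class) before the seeded
# assignment, so the result is invariant to the row order of the input.
stratified_foldid <- function(x, y, nfolds, seed) {
  foldid <- integer(length(y))
  with_private_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      ord <- do.call(order, as.data.frame(x[idx, , drop = FALSE]))
      foldid[idx[ord]] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
  })
  foldid
}

#' LASSO selector
#'
#' L1-penalized logistic regression via glmnet; the penalty minimizes the
#' inner stratified 5-fold cross-validated binomial deviance on the training
#' rows only. Selected features are those with nonzero coefficients at the
#' chosen penalty; a fully shrunk model yields an empty selection flag.
#'
#' @param x standardized training matrix.
#' @param y binary labels (0/1), both classes present.
#' @param nfolds inner CV folds (default 5).
#' @param seed seed for the inner fold assignment.
#' @return `selection_result`; `params$lambda` records the penalty.
#' @export
lasso_select <- function(x, y, nfolds = 5L, seed = 1L) {
  if (length(unique(y)) < 2) stop("degenerate labels: both classes required")
  foldid <- stratified_foldid(x, y, nfolds, seed)
  # glmnet warns about small inner-fold class counts on LOOCV-sized cohorts;
  # that is inherent to the design, not a defect
  cv <- suppressWarnings(
    glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                      foldid = foldid, standardize = FALSE))
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, , drop = FALSE]
  sel <- rownames(co)[co[, 1] != 0]
  new_selection_result("lasso", sel, params = list(lambda = cv$lambda.min),
                       empty = length(sel) == 0)
}

# fast logistic deviance via glm.fit; returns deviance
logistic_deviance <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  fit$deviance
}

#' Bidirectional stepwise logistic selector
#'
#' Forward step: the candidate with the smallest likelihood-ratio chi-square
#' p-value enters if p < `p_enter`. Backward step: the included feature with
#' the largest removal p-value leaves if p > `p_remove`. Alternates until no
#' change, capped at `2 * ncol(x)` iterations. `criterion = "score"` swaps the
#' entry test for Rao's score test.
#'
#' @param x standardized training matrix.
#' @param y binary labels.
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.1).
#' @param criterion `"lr"` (likelihood ratio, default) or `"score"`.
#' @return `selection_result` (possibly flagged empty).
#' @export
stepwise_select <- function(x, y, p_enter = 0.05, p_remove = 0.1,
                            criterion = c("lr", "score")) {
  criterion <- match.arg(criterion)
  if (length(unique(y)) < 2) stop("degenerate labels: both classes required")
  feats <- colnames(x)
  sel <- character(0)
  ones <- matrix(1, nrow(x), 1)
  dev_of <- function(s) logistic_deviance(cbind(ones, x[, s, drop = FALSE]), y)
  dev_cur <- dev_of(character(0))
  max_iter <- 2L * ncol(x)
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    cand <- setdiff(feats, sel)
    if (length(cand) && p_enter > 0) {
      pvals <- vapply(cand, function(f) {
        if (criterion == "score") {
          score_test_p(x, y, sel, f)
        } else {
          d1 <- dev_of(c(sel, f))
          stats::pchisq(max(dev_cur - d1, 0), 1, lower.tail = FALSE)
        }
      }, 0)
      best <- which.min(pvals)
      if (pvals[best] < p_enter) {
        sel <- c(sel, cand[best])
        dev_cur <- dev_of(sel)
        changed <- TRUE
      }
    }
    if (length(sel) > 1) {
      pdrop <- vapply(sel, function(f) {
        d0 <- dev_of(setdiff(sel, f))
        stats::pchisq(max(d0 - dev_cur, 0), 1, lower.tail = FALSE)
      }, 0)
      worst <- which.max(pdrop)
      if (pdrop[worst] > p_remove) {
        sel <- setdiff(sel, sel[worst])
        dev_cur <- dev_of(sel)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  new_selection_result("stepwise", sel,
                       params = list(p_enter = p_enter, p_remove = p_remove),
                       empty = length(sel) == 0)
}

# Rao score test p-value for adding feature f to the model with features sel
score_test_p <- function(x, y, sel, f) {
  X0 <- cbind(1, x[, sel, drop = FALSE])
  fit0 <- suppressWarnings(stats::glm.fit(X0, y, family = stats::binomial()))
  mu <- fit0$fitted.values
  w <- mu * (1 - mu)
  z <- x[, f]
  # score statistic for one added column, adjusted for the fitted model
  u <- sum(z * (y - mu))
  zw <- z * w
  # variance of the score accounting for the projection on X0
  A <- crossprod(X0, X0 * w)
  b <- crossprod(X0, zw)
  v <- sum(z * zw) - crossprod(b, solve(A, b))[1]
  if (v <= 0) return(1)
  stats::pchisq(u^2 / v, 1, lower.tail = FALSE)
}

#' Greedy forward-AUC wrapper selector
#'
#' Generic wrapper alternative kept behind a flag (not the default
#' replication path): starting from the empty set, repeatedly adds the
#' feature whose inclusion most improves the training Mann-Whitney AUC of a
#' logistic model on the selected set, stopping when no candidate improves
#' the AUC by more than `min_gain` or `max_features` is reached.
#'
#' @param x standardized training matrix.
#' @param y binary labels.
#' @param max_features cap on the selected set size (default 10).
#' @param min_gain minimum AUC improvement to keep adding (default 0.01).
#' @return `selection_result` (possibly flagged empty).
#' @export
wrapper_select <- function(x, y, max_features = 10L, min_gain = 0.01) {
  if (length(unique(y)) < 2) stop("degenerate labels: both classes required")
  train_auc <- function(s) {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, x[, s, drop = FALSE]), y,
                     family = stats::binomial()))
    pos <- fit$fitted.values[y == 1]; neg <- fit$fitted.values[y == 0]
    r <- rank(c(pos, neg))
    (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
      (length(pos) * length(neg))
  }
  sel <- character(0)
  best <- 0.5
  while (length(sel) < max_features) {
    cand <- setdiff(colnames(x), sel)
    if (!length(cand)) break
    aucs <- vapply(cand, function(f) train_auc(c(sel, f)), 0)
    if (max(aucs) < best + min_gain) break
    sel <- c(sel, cand[which.max(aucs)])
    best <- max(aucs)
  }
  new_selection_result("wrapper", sel,
                       params = list(max_features = max_features),
                       empty = length(sel) == 0)
}

#' Transform rows with a fitted selection
#'
#' PCA projects onto the retained components; LASSO/stepwise subset to the
#' selected columns. An empty selection returns a zero-column matrix.
#'
#' @param sel a `selection_result`.
#' @param newx matrix (or named row vector) with the training columns.
#' @return numeric matrix ready for the classifier.
#' @export
transform_selection <- function(sel, newx) {
  stopifnot(inherits(sel, "selection_result"))
  if (is.null(dim(newx))) newx <- matrix(newx, 1, dimnames = list(NULL, names(newx)))
  if (sel$selector == "pca")
    return(newx[, rownames(sel$params$rotation), drop = FALSE] %*% sel$params$rotation)
  newx[, sel$selected, drop = FALSE]
}
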