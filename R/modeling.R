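#' Classification: univariate screening and SVM under leave-one-out CV
#'
#' Univariate screening fits a single-feature logistic model and reports the
#' Mann-Whitney AUC of the fitted probabilities with a DeLong confidence
#' interval. The multivariate classifier is a linear support vector machine
#' (L1-loss dual coordinate descent, cost C = 1 by default) whose decision
#' values are mapped to [0, 1] scores by Platt scaling fitted on the training
#' rows. Leave-one-out cross-validation re-runs the complete pre-filter /
#' z-score / selector / classifier stack on every training split; held-out
#' rows are only ever transformed with stored parameters.
#'
#' @name modeling
NULL

# Mann-Whitney AUC of scores for labels (1 = positive); ties count 1/2
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Univariate logistic AUC of one feature
#'
#' @param x numeric feature values.
#' @param y binary labels (0/1), >= 3 per class.
#' @return object of class `univariate_result`: `auc`, `ci` (95% DeLong),
#'   `slope` of the logistic fit, `flagged` for constant features.
#' @export
univariate_auc <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (min(table(y)) < 3) stop("need at least 3 cases per class")
  if (stats::sd(x) == 0)
    return(structure(list(auc = NA_real_, ci = c(NA_real_, NA_real_),
                          slope = NA_real_, flagged = TRUE),
                     class = "univariate_result"))
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  slope <- stats::coef(fit)[["x"]]
  scores <- if (is.na(slope) || slope >= 0) x else -x
  auc <- mann_whitney_auc(scores, y)
  v <- delong_auc_variance(scores, y)
  half <- stats::qnorm(0.975) * sqrt(v)
  structure(list(auc = auc,
                 ci = c(max(0, auc - half), min(1, auc + half)),
                 slope = slope, flagged = FALSE),
            class = "univariate_result")
}

#' Linear SVM by dual coordinate descent
#'
#' L1-loss (hinge) linear SVM in the dual, with the bias absorbed as an
#' always-one feature. Deterministic: coordinates are visited in fixed order
#' until the maximal projected-gradient violation falls below `tol`. Scores
#' are calibrated with Platt scaling (logistic fit of the training labels on
#' the training decision values).
#'
#' @param x standardized training matrix (rows = cases).
#' @param y binary labels (0/1), both classes present.
#' @param C soft-margin cost (default 1).
#' @param tol stopping tolerance on the projected gradient.
#' @param max_pass maximum passes over the data.
#' @return object of class `svm_fit`: weight vector `w` (last entry = bias),
#'   Platt coefficients, training metadata.
#' @export
svm_fit <- function(x, y, C = 1, tol = 1e-6, max_pass = 2000L) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (length(unique(y)) < 2) stop("single-class training set")
  if (ncol(x) == 0) {
    # Empty selection: no-information model scoring a constant 0.5. Scoring
    # the training prior instead would anti-correlate with the held-out label
    # under LOOCV (the held-out class is always the underrepresented one) and
    # bias null AUCs far below 0.5.
    return(structure(list(w = numeric(0), empty = TRUE,
                          platt = c(a = 0, b = 0)),
                     class = "svm_fit"))
  }
  yy <- ifelse(y == 1, 1, -1)
  X <- cbind(x, bias = 1)
  n <- nrow(X)
  Qd <- rowSums(X^2)
  alpha <- numeric(n)
  w <- numeric(ncol(X))
  for (pass in seq_len(max_pass)) {
    max_viol <- 0
    for (i in seq_len(n)) {
      G <- yy[i] * sum(w * X[i, ]) - 1
      if (alpha[i] == 0) pg <- min(G, 0)
      else if (alpha[i] == C) pg <- max(G, 0)
      else pg <- G
      if (abs(pg) > 1e-12) {
        max_viol <- max(max_viol, abs(pg))
        a_new <- min(max(alpha[i] - G / Qd[i], 0), C)
        w <- w + (a_new - alpha[i]) * yy[i] * X[i, ]
        alpha[i] <- a_new
      }
    }
    if (max_viol < tol) break
  }
  d <- as.numeric(X %*% w)
  platt <- tryCatch({
    pf <- suppressWarnings(stats::glm(y ~ d, family = stats::binomial()))
    c(a = stats::coef(pf)[["d"]], b = stats::coef(pf)[["(Intercept)"]])
  }, error = function(e) c(a = 1, b = 0))
  if (!all(is.finite(platt))) platt <- c(a = 1, b = 0)
  structure(list(w = w, empty = FALSE, platt = platt, C = C),
            class = "svm_fit")
}

#' @rdname svm_fit
#' @param fit an `svm_fit`.
#' @param newx matrix (or single named row) of standardized features.
#' @return numeric scores in `[0, 1]`.
#' @export
svm_score <- function(fit, newx) {
  stopifnot(inherits(fit, "svm_fit"))
  if (is.null(dim(newx))) newx <- matrix(newx, 1)
  if (isTRUE(fit$empty))
    return(rep(stats::plogis(fit$platt[["b"]]), nrow(newx)))
  d <- as.numeric(cbind(newx, 1) %*% fit$w)
  stats::plogis(fit$platt[["a"]] * d + fit$platt[["b"]])
}

# decision values (margin scale), used by tests
svm_decision <- function(fit, newx) {
  if (is.null(dim(newx))) newx <- matrix(newx, 1)
  if (isTRUE(fit$empty)) return(rep(0, nrow(newx)))
  as.numeric(cbind(newx, 1) %*% fit$w)
}

# fit the full fold pipeline on training rows; returns everything needed to
# score a held-out row without seeing it
fit_fold <- function(x_train, y_train, selector, variance_min, correlation_max,
                     cumulative_contribution, p_enter, p_remove, C, seed, fold) {
  xf <- variance_filter(x_train, variance_min)
  xf <- correlation_filter(xf, correlation_max)
  zs <- fit_zscore(xf)
  xz <- apply_zscore(zs, xf)
  sel <- switch(selector,
    none = new_selection_result("none", colnames(xz)),
    pca = pca_select(xz, cumulative_contribution),
    lasso = lasso_select(xz, y_train, seed = seed),
    stepwise = stepwise_select(xz, y_train, p_enter, p_remove),
    wrapper = wrapper_select(xz, y_train),
    stop("unknown selector: ", selector))
  sel$fold <- fold
  xt <- if (sel$selector == "none") xz else transform_selection(sel, xz)
  clf <- svm_fit(xt, y_train, C = C)
  list(zscore = zs, selection = sel, classifier = clf)
}

score_fold <- function(fold_fit, x_row) {
  xz <- apply_zscore(fold_fit$zscore, x_row)
  xt <- if (fold_fit$selection$selector == "none") xz
        else transform_selection(fold_fit$selection, xz)
  svm_score(fold_fit$classifier, xt)
}

#' Leave-one-out cross-validation with fold-wise selection
#'
#' For each case i the variance and correlation pre-filters, the z-scoring,
#' the selector and the SVM are all fitted on the other n-1 rows; case i is
#' then scored with the stored fold parameters. Selection counts accumulate
#' how often each original feature was selected over the n loops (PCA folds
#' count the features entering the retained components, i.e. all post-filter
#' columns).
#'
#' @param x numeric feature matrix (rows = cases, named columns).
#' @param y binary labels (0/1).
#' @param selector `"lasso"`, `"stepwise"`, `"pca"`, `"wrapper"` (greedy
#'   forward AUC, non-default path), or `"none"`.
#' @param variance_min,correlation_max pre-filter thresholds.
#' @param cumulative_contribution PCA threshold.
#' @param p_enter,p_remove stepwise thresholds.
#' @param C SVM cost.
#' @param seed run seed (drives only the LASSO inner folds).
#' @return object of class `cv_result`: `scores`, `labels`,
#'   `selection_counts` (named, full column set), `selector`, `seed`.
#' @export
loocv_run <- function(x, y,
                      selector = c("lasso", "stepwise", "pca", "wrapper", "none"),
                      variance_min = 0.01, correlation_max = 0.95,
                      cumulative_contribution = 0.95,
                      p_enter = 0.05, p_remove = 0.1, C = 1, seed = 1L) {
  selector <- match.arg(selector)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (nrow(x) < 10) stop("LOOCV needs at least 10 cases")
  if (length(unique(y)) < 2) stop("both classes must be present")
  n <- nrow(x)
  scores <- numeric(n)
  counts <- stats::setNames(integer(ncol(x)), colnames(x))
  sizes <- integer(n)
  for (i in seq_len(n)) {
    y_tr <- y[-i]
    if (length(unique(y_tr)) < 2)
      stop("fold ", i, " has a single-class training set")
    ff <- fit_fold(x[-i, , drop = FALSE], y_tr, selector,
                   variance_min, correlation_max, cumulative_contribution,
                   p_enter, p_remove, C, seed, i)
    scores[i] <- score_fold(ff, x[i, ])
    sel_names <- ff$selection$selected
    counts[sel_names] <- counts[sel_names] + 1L
    sizes[i] <- length(sel_names)
  }
  structure(list(scores = scores, labels = y, selection_counts = counts,
                 fold_sizes = sizes, selector = selector, seed = seed),
            class = "cv_result")
}

#' Feature importance by selection frequency
#'
#' Ranks features by how many LOOCV loops selected them; ties break by
#' catalogue (column) order.
#'
#' @param cv a `cv_result` from [loocv_run()].
#' @return data.frame with `feature` and `count`, descending.
#' @export
feature_importance <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  ord <- order(-cv$selection_counts, seq_along(cv$selection_counts))
  data.frame(feature = names(cv$selection_counts)[ord],
             count = as.integer(cv$selection_counts[ord]),
             row.names = NULL)
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result:", length(x$scores), "cases, selector =", x$selector,
      " LOOCV AUC =", round(mann_whitney_auc(x$scores, x$labels), 3), "\n")
  invisible(x)
}
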