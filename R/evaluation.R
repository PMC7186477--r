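#' Evaluation: ROC metrics, correlated-AUC test, contingency tests, ICC
#'
#' ROC analysis reports the Mann-Whitney AUC with a DeLong confidence
#' interval and the operating point maximizing Youden's J (ties resolved
#' toward higher specificity). Correlated AUCs on the same cases are compared
#' with DeLong's paired z-test. Cohort tables use the Yates-corrected
#' chi-square (all expected counts >= 5) or Fisher's exact test, and
#' inter-rater agreement uses the two-way random-effects absolute-agreement
#' single-measure ICC(2,1).
#'
#' @name evaluation
NULL

# DeLong placements: V10 (per positive) and V01 (per negative)
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  v10 <- vapply(pos, function(p) mean((p > neg) + 0.5 * (p == neg)), 0)
  v01 <- vapply(neg, function(q) mean((pos > q) + 0.5 * (pos == q)), 0)
  list(v10 = v10, v01 = v01,
       auc = mean(v10), m = length(pos), n = length(neg))
}

delong_auc_variance <- function(scores, labels) {
  pl <- delong_placements(scores, labels)
  s10 <- stats::var(pl$v10)
  s01 <- stats::var(pl$v01)
  s10 / pl$m + s01 / pl$n
}

#' ROC metrics at the Youden-optimal operating point
#'
#' @param scores numeric classification scores (higher = more positive).
#' @param labels binary labels (0/1), both classes present.
#' @return object of class `roc_result`: `auc`, `ci` (95% DeLong, truncated
#'   to `[0, 1]`), `sensitivity`, `specificity`, `accuracy` (percent),
#'   `threshold` (`NA`-flagged when all scores are tied).
#' @export
roc_metrics <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (length(unique(scores)) == 1) {
    return(structure(list(auc = 0.5, ci = c(NA_real_, NA_real_),
                          sensitivity = 100, specificity = 0,
                          accuracy = 100 * n_pos / (n_pos + n_neg),
                          threshold = NA_real_, flagged = TRUE),
                     class = "roc_result"))
  }
  auc <- mann_whitney_auc(scores, labels)
  v <- delong_auc_variance(scores, labels)
  half <- stats::qnorm(0.975) * sqrt(v)
  thr <- sort(unique(scores))
  best <- list(j = -Inf, sens = NA, spec = NA, thr = NA)
  for (t in thr) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    j <- sens + spec - 1
    # ties in J break toward higher specificity
    if (j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && !is.na(best$spec) && spec > best$spec)) {
      best <- list(j = j, sens = sens, spec = spec, thr = t)
    }
  }
  acc <- (best$sens * n_pos + best$spec * n_neg) / (n_pos + n_neg)
  structure(list(auc = auc, ci = c(max(0, auc - half), min(1, auc + half)),
                 sensitivity = 100 * best$sens, specificity = 100 * best$spec,
                 accuracy = 100 * acc, threshold = best$thr, flagged = FALSE),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f); sens %.1f%%, spec %.1f%%, acc %.1f%%\n",
              x$auc, x$ci[1], x$ci[2], x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Paired design: both score vectors refer to the same cases and labels.
#'
#' @param scores_a,scores_b score vectors from the two classifiers.
#' @param labels shared binary labels.
#' @return list: `auc_a`, `auc_b`, `z`, `p` (two-sided); `flagged` when the
#'   variance of the difference degenerates.
#' @export
compare_auc <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(labels), length(scores_b) == length(labels))
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / pa$m + s01 / pa$n
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- pa$auc - pb$auc
  if (v <= .Machine$double.eps) {
    return(list(auc_a = pa$auc, auc_b = pb$auc,
                z = if (abs(d) < 1e-12) 0 else NA_real_,
                p = if (abs(d) < 1e-12) 1 else NA_real_,
                flagged = TRUE))
  }
  z <- d / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)), flagged = FALSE)
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Continuity-corrected statistic `sum(max(|O - E| - 0.5, 0)^2 / E)` on one
#' degree of freedom. Refuses tables with any expected count < 5 (use
#' [fisher_exact()] there).
#'
#' @param t 2x2 integer matrix of counts.
#' @return list: `statistic`, `p`, `expected`.
#' @export
chi_square_yates <- function(t) {
  t <- as.matrix(t)
  stopifnot(all(dim(t) == c(2, 2)), all(t >= 0), sum(t) > 0)
  expected <- outer(rowSums(t), colSums(t)) / sum(t)
  if (any(expected < 5))
    stop("expected count < 5: use fisher_exact() for this table")
  stat <- sum(pmax(abs(t - expected) - 0.5, 0)^2 / expected)
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
       expected = expected)
}

# all r x 2 tables with the given margins, visited recursively
enumerate_rx2 <- function(row_sums, col1_total, fun) {
  r <- length(row_sums)
  rec <- function(i, remaining, acc) {
    if (i == r) {
      if (remaining >= 0 && remaining <= row_sums[r]) fun(c(acc, remaining))
      return(invisible(NULL))
    }
    lo <- max(0L, remaining - sum(row_sums[(i + 1):r]))
    hi <- min(row_sums[i], remaining)
    if (lo > hi) return(invisible(NULL))
    for (k in lo:hi) rec(i + 1L, remaining - k, c(acc, k))
  }
  rec(1L, col1_total, integer(0))
}

#' Fisher's exact test for r x 2 tables
#'
#' Two-sided p-value by summing, over all tables with the observed margins,
#' the (multivariate) hypergeometric probabilities no larger than that of the
#' observed table (with a relative tolerance of 1e-7 for ties).
#'
#' @param t r x 2 integer matrix of counts.
#' @return list: `p`, `p_observed_table`.
#' @export
fisher_exact <- function(t) {
  t <- as.matrix(t)
  stopifnot(ncol(t) == 2, all(t >= 0), sum(t) > 0)
  rs <- as.integer(rowSums(t)); cs <- as.integer(colSums(t)); n <- sum(t)
  log_prob <- function(col1) {
    # P(table | margins) = prod choose(rs_i, k_i) / choose(n, c1)
    sum(lchoose(rs, col1)) - lchoose(n, cs[1])
  }
  lp_obs <- log_prob(t[, 1])
  total <- 0
  enumerate_rx2(rs, cs[1], function(col1) {
    lp <- log_prob(col1)
    if (lp <= lp_obs + 1e-7) total <<- total + exp(lp)
  })
  list(p = min(total, 1), p_observed_table = exp(lp_obs))
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' two-way ANOVA decomposition, with the conventional agreement bands
#' (0-0.4 poor, 0.41-0.6 moderate, 0.61-0.8 good, 0.81-1 excellent).
#'
#' @param ratings numeric matrix, items in rows, >= 2 raters in columns.
#' @return list: `icc`, `band`, `flagged` when between-item variance is zero.
#' @export
icc_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  stopifnot(n >= 3, k >= 2)
  row_means <- rowMeans(ratings); col_means <- colMeans(ratings)
  grand <- mean(ratings)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (msr <= .Machine$double.eps && mse <= .Machine$double.eps)
    return(list(icc = NA_real_, band = NA_character_, flagged = TRUE))
  icc <- (msr - mse) / denom
  band <- if (is.na(icc)) NA_character_
          else if (icc <= 0.4) "poor"
          else if (icc <= 0.6) "moderate"
          else if (icc <= 0.8) "good"
          else "excellent"
  list(icc = icc, band = band, flagged = FALSE)
}
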