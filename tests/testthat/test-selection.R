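test_that("variance_filter drops exactly the sub-threshold columns", {
  n <- 20
  mk <- function(pop_var) {
    v <- rep(c(-1, 1), n / 2) * sqrt(pop_var)
    v  # population variance exactly pop_var
  }
  x <- cbind(constant = rep(5, n), low = mk(0.005), kept = mk(0.02))
  f <- variance_filter(x)
  expect_identical(colnames(f), "kept")
  expect_setequal(attr(f, "dropped"), c("constant", "low"))

  # surviving columns all have population variance >= 0.01 (direct oracle)
  set.seed(61)
  big <- matrix(rnorm(200, sd = rep(c(0.05, 0.3), each = 100)), 20, 10)
  colnames(big) <- paste0("f", 1:10)
  fb <- variance_filter(big)
  for (j in seq_len(ncol(fb))) {
    v <- fb[, j]
    expect_gte(sum((v - mean(v))^2) / length(v), 0.01)
  }
  # idempotence
  expect_identical(variance_filter(fb), structure(fb, dropped = character(0)))
  expect_error(variance_filter(cbind(a = rep(1, 5))), "empty table")
})

test_that("correlation_filter enforces pairwise |r| <= threshold", {
  set.seed(62)
  base <- rnorm(100)
  x <- cbind(a = base, b = base, c = rnorm(100), d = rnorm(100))
  f <- correlation_filter(x)
  expect_identical(attr(f, "dropped"), "b")       # duplicate: later copy dropped
  expect_true(all(c("c", "d") %in% colnames(f)))  # independent noise kept

  # post-condition under direct recomputation
  set.seed(63)
  z <- matrix(rnorm(300), 20, 15)
  z[, 8] <- z[, 1] + rnorm(20, 0, 0.01)
  colnames(z) <- paste0("g", 1:15)
  fz <- correlation_filter(z)
  r <- stats::cor(fz)
  expect_true(all(abs(r[upper.tri(r)]) <= 0.95))
  expect_true("g8" %in% attr(fz, "dropped"))
})

test_that("pca_select retains components to > 95% cumulative variance", {
  set.seed(64)
  # rank-1 latent factor plus tiny noise -> one component suffices
  f1 <- rnorm(50)
  x1 <- outer(f1, c(1, 2, -1, 0.5)) + matrix(rnorm(200, 0, 0.01), 50, 4)
  x1 <- scale(x1); colnames(x1) <- paste0("p", 1:4)
  s1 <- pca_select(x1)
  expect_equal(s1$params$n_components, 1)
  expect_equal(sum(s1$params$explained), 1, tolerance = 1e-9)

  # isotropic 4-D Gaussian: equal eigenvalues -> all 4 components needed
  x2 <- scale(matrix(rnorm(800), 200, 4)); colnames(x2) <- paste0("p", 1:4)
  expect_equal(pca_select(x2)$params$n_components, 4)

  # held-out rows are projected with the stored loadings
  proj <- transform_selection(s1, x1[1:3, ])
  expect_equal(dim(proj), c(3L, 1L))
})

test_that("lasso_select finds a strong feature and ignores duplicates of noise", {
  set.seed(65)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 20), n, 20)
  colnames(x) <- paste0("f", 1:20)
  x[, 7] <- x[, 7] + 2.5 * y   # strongly separating feature
  x <- scale(x); attributes(x)[c("scaled:center", "scaled:scale")] <- NULL
  sel <- lasso_select(x, y, seed = 5)
  expect_true("f7" %in% sel$selected)
  expect_false(sel$empty_selection)

  # duplicating a non-selected noise column leaves the selection unchanged
  unsel <- setdiff(paste0("f", 1:20), sel$selected)[1]
  x2 <- cbind(x, dup = x[, unsel])
  sel2 <- lasso_select(x2, y, seed = 5)
  expect_setequal(setdiff(sel2$selected, "dup"), sel$selected)

  expect_error(lasso_select(x, rep(1, n)), "degenerate")
})

test_that("strong feature is selected in >= 90% of LOOCV folds", {
  set.seed(66)
  n <- 30
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 15, sd = 1), n, 15)
  colnames(x) <- paste0("f", 1:15)
  x[, 3] <- x[, 3] + 3 * y
  cv <- loocv_run(x, y, selector = "lasso", variance_min = 0, seed = 9)
  expect_gte(cv$selection_counts[["f3"]] / n, 0.9)
})

test_that("stepwise_select behaves on null, signal, and degenerate settings", {
  set.seed(67)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  # null simulation: pure noise rarely admits more than one feature
  n_small <- vapply(1:20, function(k) {
    xn <- matrix(rnorm(n * 10), n, 10)
    colnames(xn) <- paste0("f", 1:10)
    length(stepwise_select(scale(xn), y)$selected)
  }, 0)
  expect_gte(mean(n_small <= 1), 0.9)

  # a single strong feature enters first and survives removal
  xs <- matrix(rnorm(n * 10), n, 10)
  colnames(xs) <- paste0("f", 1:10)
  xs[, 4] <- xs[, 4] + 3 * y
  sel <- stepwise_select(scale(xs), y)
  expect_true("f4" %in% sel$selected)

  # impossible entry threshold -> flagged empty selection
  sel0 <- stepwise_select(scale(xs), y, p_enter = 0)
  expect_true(sel0$empty_selection)
  expect_length(sel0$selected, 0)

  # score-test criterion also admits the strong feature
  sel_sc <- stepwise_select(scale(xs), y, criterion = "score")
  expect_true("f4" %in% sel_sc$selected)
})

test_that("z-scoring stores train statistics and transforms held-out rows", {
  set.seed(68)
  x <- matrix(rnorm(60, 10, 3), 20, 3)
  colnames(x) <- c("a", "b", "c")
  zs <- fit_zscore(x)
  xt <- apply_zscore(zs, x)
  expect_equal(colMeans(xt), c(a = 0, b = 0, c = 0), tolerance = 1e-12)
  row <- apply_zscore(zs, x[5, ])
  expect_equal(as.numeric(row), as.numeric(xt[5, ]))
})

test_that("the greedy forward-AUC wrapper finds the separating feature", {
  set.seed(69)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 8), n, 8)
  colnames(x) <- paste0("f", 1:8)
  x[, 5] <- x[, 5] + 2.5 * y
  sel <- wrapper_select(scale(x), y)
  expect_true("f5" %in% sel$selected)
  expect_lte(length(sel$selected), 10)
  cv <- loocv_run(x, y, selector = "wrapper", variance_min = 0, seed = 3)
  expect_gt(dcehabitat:::mann_whitney_auc(cv$scores, y), 0.7)
})
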