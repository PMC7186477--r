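test_that("feature catalogue has exactly 488 unique, stably ordered names", {
  cat488 <- feature_catalogue()
  expect_length(cat488, 488)
  expect_identical(anyDuplicated(cat488), 0L)
  # block arithmetic: 4 + 380 + 44 + 60
  expect_identical(cat488[1:4], c("mean", "variance", "skewness", "kurtosis"))
  expect_length(grep("°", cat488), 44)
  expect_length(grep("^(haar|deubechies2|symlet4) ", cat488), 60)
  # Named examples from the published feature tables exist in the catalogue
  expect_true(all(c("ACOR (0,1)", "IMC (-1,-1)", "haar HH_2", "deubechies2 HV_4",
                    "haar L_4", "0°LRE", "45°RLN", "45°GLN") %in% cat488))
})

test_that("quantize maps in-mask intensities to 1..n_levels", {
  img <- matrix(5, 4, 4)
  mask <- matrix(TRUE, 4, 4)
  q <- quantize(img, mask, 8)
  expect_true(all(q$levels == 1L))  # constant region -> level 1

  img2 <- matrix(0:63, 8, 8)
  q2 <- quantize(img2, matrix(TRUE, 8, 8), 64)
  expect_equal(as.vector(q2$levels), 1:64)  # identity mapping

  # floor-formula oracle pixel by pixel on seeded regions
  for (seed in 1:5) {
    reg <- random_region(seed)
    q3 <- quantize(reg$img, reg$mask, 16)
    v <- reg$img[reg$mask]
    mn <- min(v); mx <- max(v)
    oracle <- pmin(16, floor((v - mn) / (mx - mn) * 16) + 1)
    expect_equal(as.vector(q3$levels[reg$mask]), oracle)
  }
  expect_error(quantize(img, matrix(FALSE, 4, 4)), "empty")
})

test_that("histogram features match direct-summation moments", {
  img <- matrix(7, 5, 5)
  h <- histogram_features(img, matrix(TRUE, 5, 5))
  expect_equal(h[["variance"]], 0)
  expect_true(is.na(h[["skewness"]]) && is.na(h[["kurtosis"]]))

  # symmetric two-point region {a,a,b,b} x many -> skewness 0
  img2 <- matrix(rep(c(2, 2, 9, 9), 5), 4, 5)
  h2 <- histogram_features(img2, matrix(TRUE, 4, 5))
  expect_equal(h2[["skewness"]], 0)

  # seeded samples vs direct summation, 1e-10 relative
  for (seed in 1:20) {
    set.seed(seed)
    v <- rnorm(40, 50, 12)
    img3 <- matrix(v, 5, 8)
    h3 <- histogram_features(img3, matrix(TRUE, 5, 8))
    expect_equal(unname(h3), unname(oracle_moments(v)), tolerance = 1e-10)
  }

  # too-small region flagged, not raised
  small <- histogram_features(img, matrix(c(TRUE, rep(FALSE, 24)), 5, 5))
  expect_true(all(is.na(small)))
})

test_that("glcm matches exhaustive pair enumeration on seeded regions", {
  # 2x2 all-one-level region, offset (0,1): single entry 1 at (1,1)
  q <- quantize(matrix(1, 2, 2), matrix(TRUE, 2, 2), 4)
  P <- glcm(q, c(0, 1))
  expect_equal(P[1, 1], 1)
  expect_equal(sum(P), 1)

  for (seed in 1:50) {
    reg <- random_region(seed, 7, 7)
    q2 <- quantize(reg$img, reg$mask, 8)
    for (off in list(c(0, 1), c(-1, 1), c(-1, 0), c(-2, -2))) {
      P2 <- glcm(q2, off)
      expect_equal(P2, oracle_glcm(q2$levels, 8, off[1], off[2]),
                   tolerance = 1e-12)
      expect_equal(sum(P2), 1, tolerance = 1e-9)
    }
  }
})

test_that("glcm_features agree with closed forms and a double-loop oracle", {
  # delta distribution
  P <- matrix(0, 4, 4); P[2, 2] <- 1
  f <- glcm_features(P)
  expect_equal(f[["MP"]], 1); expect_equal(f[["ENE"]], 1)
  expect_equal(f[["ENT"]], 0); expect_equal(f[["CON"]], 0)
  expect_equal(f[["DIS"]], 0); expect_equal(f[["HOM"]], 1)

  # uniform 2-level matrix: ENT = ln 4, COR = 0
  U <- matrix(0.25, 2, 2)
  fu <- glcm_features(U)
  expect_equal(fu[["ENT"]], log(4))
  expect_equal(fu[["COR"]], 0)

  # direct double-loop oracle for every statistic
  oracle_stats <- function(P) {
    L <- nrow(P)
    px <- rowSums(P); py <- colSums(P)
    mux <- sum((1:L) * px); muy <- sum((1:L) * py)
    sx <- sqrt(sum((1:L - mux)^2 * px)); sy <- sqrt(sum((1:L - muy)^2 * py))
    acc <- stats::setNames(numeric(19), names(glcm_features(P)))
    psum <- numeric(2 * L); pdiff <- numeric(L)
    for (i in 1:L) for (j in 1:L) {
      p <- P[i, j]
      acc["ACOR"] <- acc["ACOR"] + i * j * p
      acc["CON"] <- acc["CON"] + (i - j)^2 * p
      acc["CP"] <- acc["CP"] + (i + j - mux - muy)^4 * p
      acc["CS"] <- acc["CS"] + (i + j - mux - muy)^3 * p
      acc["DIS"] <- acc["DIS"] + abs(i - j) * p
      acc["ENE"] <- acc["ENE"] + p^2
      if (p > 0) acc["ENT"] <- acc["ENT"] - p * log(p)
      acc["HOM"] <- acc["HOM"] + p / (1 + abs(i - j))
      acc["SOS"] <- acc["SOS"] + (i - mux)^2 * p
      acc["IDN"] <- acc["IDN"] + p / (1 + abs(i - j) / L)
      acc["IDMN"] <- acc["IDMN"] + p / (1 + (i - j)^2 / L^2)
      psum[i + j] <- psum[i + j] + p
      pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p
    }
    acc["MP"] <- max(P)
    acc["COR"] <- (acc[["ACOR"]] - mux * muy) / (sx * sy)
    acc["SA"] <- sum((1:(2 * L)) * psum)
    acc["SV"] <- sum(((1:(2 * L)) - acc[["SA"]])^2 * psum)
    acc["SE"] <- -sum(psum[psum > 0] * log(psum[psum > 0]))
    mud <- sum((0:(L - 1)) * pdiff)
    acc["DV"] <- sum(((0:(L - 1)) - mud)^2 * pdiff)
    acc["DE"] <- -sum(pdiff[pdiff > 0] * log(pdiff[pdiff > 0]))
    hx <- -sum(px[px > 0] * log(px[px > 0])); hy <- -sum(py[py > 0] * log(py[py > 0]))
    hxy1 <- 0
    for (i in 1:L) for (j in 1:L)
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log(px[i] * py[j])
    acc["IMC"] <- (acc[["ENT"]] - hxy1) / max(hx, hy)
    acc
  }
  for (seed in 1:20) {
    set.seed(seed)
    M <- matrix(stats::rexp(36), 6, 6)
    P2 <- (M + t(M)); P2 <- P2 / sum(P2)
    expect_equal(glcm_features(P2), oracle_stats(P2), tolerance = 1e-10)
  }
})

test_that("glcm_feature_block has 380 entries with correct angular means", {
  reg <- random_region(3, 12, 12)
  q <- quantize(reg$img, reg$mask, 8)
  blk <- glcm_feature_block(q)
  expect_length(blk, 380)
  # angular-mean entries equal the mean of the four directional values
  for (stat in c("ACOR", "ENT", "CON")) for (d in 1:2) {
    toks <- c(sprintf("%s (%d,0)", stat, d), sprintf("%s (%d,%d)", stat, d, d),
              sprintf("%s (0,%d)", stat, d), sprintf("%s (-%d,-%d)", stat, d, d))
    expect_equal(blk[[sprintf("%s d%d avg", stat, d)]], mean(blk[toks]))
  }
})

test_that("rotating a region by 90 degrees swaps 0- and 90-degree features", {
  reg <- random_region(9, 10, 10)
  q1 <- quantize(reg$img, reg$mask, 8)
  rot_img <- t(reg$img)[, nrow(reg$img):1]     # 90-degree rotation
  rot_mask <- t(reg$mask)[, nrow(reg$mask):1]
  q2 <- quantize(rot_img, rot_mask, 8)
  b1 <- glcm_feature_block(q1); b2 <- glcm_feature_block(q2)
  for (stat in glcm_stat_names_test <- c("ACOR", "CON", "ENT", "HOM")) {
    expect_equal(b1[[sprintf("%s (1,0)", stat)]], b2[[sprintf("%s (0,1)", stat)]],
                 tolerance = 1e-12)
    expect_equal(b1[[sprintf("%s (0,1)", stat)]], b2[[sprintf("%s (1,0)", stat)]],
                 tolerance = 1e-12)
  }
})

test_that("grlm run-length matrices match the scan-line oracle", {
  # checkerboard: along the axes every run has length 1 (SRE = LRE = 1);
  # along the diagonals the parity of i + j is constant, so the 8x8 board
  # decomposes into maximal runs of lengths 1..8 - computed by hand below
  img <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  q <- quantize(img, matrix(TRUE, 8, 8), 2)
  f <- grlm_features(q)
  for (a in c(0, 90)) {
    expect_equal(f[[sprintf("%d°SRE", a)]], 1)
    expect_equal(f[[sprintf("%d°LRE", a)]], 1)
  }
  # diagonal run lengths: two of each length 1..7 plus one of length 8
  lens <- c(rep(1:7, each = 2), 8)
  expect_equal(f[["45°LRE"]], sum(lens^2) / length(lens))
  expect_equal(f[["135°LRE"]], sum(lens^2) / length(lens))
  expect_length(f, 44)

  for (seed in 1:50) {
    reg <- random_region(seed, 8, 8)
    q2 <- quantize(reg$img, reg$mask, 6)
    for (a in c(0, 45, 90, 135)) {
      G <- dcehabitat:::grlm_matrix(q2, a)
      O <- oracle_grlm(q2$levels, 6, a)
      expect_equal(G, O)
    }
  }
})

test_that("dwt_features behave on constant and oriented signals", {
  # constant full-block image: details vanish, L_l = const x 2^l
  img <- matrix(4, 32, 32)
  mask <- matrix(TRUE, 32, 32)
  for (w in c("haar", "db2", "sym4")) {
    f <- dwt_features(img, mask, w)
    expect_length(f, 20)
    disp <- c(haar = "haar", db2 = "deubechies2", sym4 = "symlet4")[[w]]
    for (l in 1:4) {
      expect_equal(f[[sprintf("%s HH_%d", disp, l)]], 0, tolerance = 1e-10)
      expect_equal(f[[sprintf("%s HD_%d", disp, l)]], 0, tolerance = 1e-10)
      expect_equal(f[[sprintf("%s L_%d", disp, l)]], 4 * 2^l, tolerance = 1e-8)
    }
  }

  # vertical stripes: more energy in the vertical than the diagonal detail
  stripes <- matrix(rep(c(0, 100), 16), 32, 32, byrow = TRUE)
  fs <- dwt_features(stripes, mask, "haar")
  expect_gt(fs[["haar HV_1"]], fs[["haar HD_1"]])

  # three wavelets on the same region give 60 distinct entries
  reg <- random_region(4, 20, 20)
  all3 <- c(dwt_features(reg$img, reg$mask, "haar"),
            dwt_features(reg$img, reg$mask, "db2"),
            dwt_features(reg$img, reg$mask, "sym4"))
  expect_length(all3, 60)
  expect_identical(anyDuplicated(names(all3)), 0L)

  # too-small region flagged
  tiny <- matrix(FALSE, 32, 32); tiny[1:2, 1:2] <- TRUE
  expect_true(all(is.na(dwt_features(img, tiny, "haar"))))
})

test_that("extract_all assembles 488 features deterministically", {
  reg <- random_region(12, 16, 16)
  fv <- extract_all(reg$img, reg$mask)
  expect_length(fv, 488)
  expect_identical(names(fv), feature_catalogue())
  expect_false(anyNA(fv))
  expect_identical(fv, extract_all(reg$img, reg$mask))  # determinism

  # translation invariance: embed the same region elsewhere in a larger image
  big1 <- matrix(0, 40, 40); big1m <- matrix(FALSE, 40, 40)
  big1[3:18, 5:20] <- reg$img; big1m[3:18, 5:20] <- reg$mask
  big2 <- matrix(0, 40, 40); big2m <- matrix(FALSE, 40, 40)
  big2[21:36, 17:32] <- reg$img; big2m[21:36, 17:32] <- reg$mask
  expect_equal(unclass(extract_all(big1, big1m)), unclass(extract_all(big2, big2m)))

  # flagged vector for a too-small region
  tiny <- matrix(FALSE, 16, 16); tiny[1:2, 1] <- TRUE
  fvt <- extract_all(reg$img, tiny)
  expect_true(all(is.na(fvt)))
  expect_true(attr(fvt, "flagged"))
})
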