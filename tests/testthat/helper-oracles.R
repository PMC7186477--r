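# Independent brute-force oracles. These deliberately use naive loops (or
# base-stats reference functions) and share no code with the implementation.

# elementwise subtraction by explicit double loop
oracle_subtract <- function(pre, post) {
  out <- matrix(NA_real_, nrow(pre), ncol(pre))
  for (r in seq_len(nrow(pre))) for (c in seq_len(ncol(pre)))
    out[r, c] <- post[r, c] - pre[r, c]
  out
}

# symmetrized, normalized co-occurrence matrix by explicit pair enumeration
oracle_glcm <- function(lev, L, dr, dc) {
  M <- matrix(0, L, L)
  nr <- nrow(lev); nc <- ncol(lev)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
        !is.na(lev[r, c]) && !is.na(lev[r2, c2])) {
      M[lev[r, c], lev[r2, c2]] <- M[lev[r, c], lev[r2, c2]] + 1
      M[lev[r2, c2], lev[r, c]] <- M[lev[r2, c2], lev[r, c]] + 1
    }
  }
  M / sum(M)
}

# run-length matrix by walking each scan line pixel by pixel
oracle_grlm <- function(lev, L, angle) {
  nr <- nrow(lev); nc <- ncol(lev)
  maxlen <- max(nr, nc)
  G <- matrix(0, L, maxlen)
  step <- switch(as.character(angle),
                 "0" = c(0, 1), "45" = c(-1, 1), "90" = c(1, 0), "135" = c(1, 1))
  # starts: all pixels with no same-line predecessor
  visited <- matrix(FALSE, nr, nc)
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    rp <- r0 - step[1]; cp <- c0 - step[2]
    if (rp >= 1 && rp <= nr && cp >= 1 && cp <= nc) next  # not a line start
    r <- r0; c <- c0
    run_val <- NA; run_len <- 0
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- lev[r, c]
      if (!is.na(v) && !is.na(run_val) && v == run_val) {
        run_len <- run_len + 1
      } else {
        if (!is.na(run_val)) G[run_val, run_len] <- G[run_val, run_len] + 1
        run_val <- v; run_len <- if (is.na(v)) 0 else 1
      }
      r <- r + step[1]; c <- c + step[2]
    }
    if (!is.na(run_val) && run_len > 0) G[run_val, run_len] <- G[run_val, run_len] + 1
  }
  G
}

# moments by direct summation
oracle_moments <- function(v) {
  n <- length(v); mu <- sum(v) / n
  m2 <- sum((v - mu)^2) / n
  m3 <- sum((v - mu)^3) / n
  m4 <- sum((v - mu)^4) / n
  c(mean = mu, variance = m2,
    skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

# AUC by exhaustive positive x negative pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# two-sided Fisher p for a 2x2 table by full hypergeometric support enumeration
oracle_fisher_2x2 <- function(t) {
  rs <- rowSums(t); cs <- colSums(t); n <- sum(t)
  support <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  probs <- vapply(support, function(k)
    choose(rs[1], k) * choose(rs[2], cs[1] - k) / choose(n, cs[1]), 0)
  p_obs <- probs[support == t[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# plain FCM fixed point for symmetric two-point data {a (x n), b (x n)}:
# converged centers are exactly {a, b}

# small seeded random region: intensity matrix + blob mask
random_region <- function(seed, nr = 9, nc = 9, p_mask = 0.8) {
  set.seed(seed)
  img <- matrix(rnorm(nr * nc, 100, 25), nr, nc)
  mask <- matrix(runif(nr * nc) < p_mask, nr, nc)
  if (sum(mask) < 12) mask[sample(which(!mask), 12 - sum(mask))] <- TRUE
  list(img = img, mask = mask)
}

# tiny fast feature set used where full 488-feature extraction is too slow
cheap_features <- function(image, mask) {
  c(histogram_features(image, mask),
    grlm_features(quantize(image, mask, 16L)))
}

# small cohort -> feature matrix with cheap features at P-2 (truth masks)
cheap_feature_matrix <- function(cohort) {
  rows <- lapply(cohort, function(cs) {
    sub <- subtract_phases(cs$series$pre, cs$series$post[[4]])
    cheap_features(sub, cs$truth$lesion_mask)
  })
  x <- do.call(rbind, rows)
  rownames(x) <- NULL
  x
}
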