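# Minimal 2-D discrete wavelet transform (periodized, orthonormal) for the
# three wavelets used by the texture bank. Only the decomposition direction
# is needed; filters are the standard Daubechies/Symlet coefficients.

dwt_filters <- function(wavelet) {
  switch(wavelet,
    haar = list(
      lo = c(0.7071067811865476, 0.7071067811865476),
      hi = c(-0.7071067811865476, 0.7071067811865476)),
    db2 = list(
      lo = c(-0.12940952255126037, 0.2241438680420134,
             0.8365163037378079, 0.48296291314453416),
      hi = c(-0.48296291314453416, 0.8365163037378079,
             -0.2241438680420134, -0.12940952255126037)),
    sym4 = list(
      lo = c(-0.07576571478927333, -0.02963552764599851,
             0.49761866763201545, 0.8037387518059161,
             0.29785779560527736, -0.09921954357684722,
             -0.012603967262037833, 0.0322231006040427),
      hi = c(-0.0322231006040427, -0.012603967262037833,
             0.09921954357684722, 0.29785779560527736,
             -0.8037387518059161, 0.49761866763201545,
             0.02963552764599851, -0.07576571478927333)),
    stop("unknown wavelet: ", wavelet))
}

# one periodized analysis step along a vector: circular convolution with the
# time-reversed filter, downsampled by 2; length(x) must be even
dwt_step_1d <- function(x, f) {
  n <- length(x)
  L <- length(f)
  out <- numeric(n / 2)
  # y[k] = sum_m f[m] * x[(2k - 1 + m - 1) mod n + 1], k = 1..n/2
  for (m in seq_len(L)) {
    idx <- ((2 * seq_len(n / 2) - 2 + m - 1) %% n) + 1
    out <- out + f[m] * x[idx]
  }
  out
}

# one 2-D analysis level; returns L (lo/lo), HV (lo rows, hi cols: vertical
# structure), HH (hi rows, lo cols: horizontal structure), HD (hi/hi)
dwt_level_2d <- function(mat, filt) {
  # transform columns of each row (filter along x), then along y
  lo_c <- t(apply(mat, 1, dwt_step_1d, f = filt$lo))
  hi_c <- t(apply(mat, 1, dwt_step_1d, f = filt$hi))
  if (ncol(mat) == 2) { lo_c <- t(lo_c); hi_c <- t(hi_c) } # apply() drops dims
  list(
    L  = apply(lo_c, 2, dwt_step_1d, f = filt$lo),
    HH = apply(lo_c, 2, dwt_step_1d, f = filt$hi),
    HV = apply(hi_c, 2, dwt_step_1d, f = filt$lo),
    HD = apply(hi_c, 2, dwt_step_1d, f = filt$hi))
}

# 2x2 block-any downsampling of a logical matrix (mask pyramid)
downsample_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  m1 <- mask[seq(1, nr, 2), , drop = FALSE] | mask[seq(2, nr, 2), , drop = FALSE]
  m1[, seq(1, nc, 2), drop = FALSE] | m1[, seq(2, nc, 2), drop = FALSE]
}
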