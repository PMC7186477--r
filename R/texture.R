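#' The 488-feature texture bank
#'
#' Texture description of a masked region of a (subtraction) image:
#' 4 histogram moments, 380 gray-level co-occurrence matrix (GLCM) statistics
#' (19 statistics x 16 directed offsets x 4 per-distance angular means),
#' 44 gray-level run-length matrix (GRLM) statistics (11 x 4 angles) and
#' 60 discrete wavelet transform (DWT) subband scalars (20 per wavelet for
#' haar, Daubechies-2 and Symlet-4). Intensities are min-max quantized to
#' `n_levels` gray levels (default 64) for GLCM/GRLM; histogram and DWT
#' features use raw intensities.
#'
#' Direction labels follow the radiological naming convention in which the
#' offset token "(0,d)" denotes the 90 degree (vertical) direction — e.g.
#' feature `"ACOR (0,1)"` is autocorrelation at distance 1, 90 degrees —
#' with "(d,0)" horizontal, "(d,d)" 45 degrees and "(-d,-d)" 135 degrees.
#'
#' @name texture
NULL

glcm_stat_names <- c("ACOR", "CON", "COR", "CP", "CS", "DIS", "ENE", "ENT",
                     "HOM", "MP", "SOS", "SA", "SV", "SE", "DV", "DE",
                     "IMC", "IDN", "IDMN")
grlm_stat_names <- c("RLN", "GLN", "LRE", "SRE", "FIR", "LGRE", "HGRE",
                     "SRLGE", "SRHGE", "LRLGE", "LRHGE")
grlm_angles <- c(0L, 45L, 90L, 135L)
dwt_wavelet_names <- c(haar = "haar", db2 = "deubechies2", sym4 = "symlet4")
dwt_subbands <- c("HH", "HV", "HD", "L", "D")

# directed GLCM offset (dr, dc) and its display token for distance d
glcm_offsets <- function(d) {
  list(`0`   = list(offset = c(0L, d),   token = sprintf("(%d,0)", d)),
       `45`  = list(offset = c(-d, d),   token = sprintf("(%d,%d)", d, d)),
       `90`  = list(offset = c(-d, 0L),  token = sprintf("(0,%d)", d)),
       `135` = list(offset = c(-d, -d),  token = sprintf("(-%d,-%d)", d, d)))
}

#' Canonical ordered names of the 488 texture features
#'
#' @return character vector of length 488.
#' @export
feature_catalogue <- function() {
  if (!is.null(.texture_env$catalogue)) return(.texture_env$catalogue)
  hist_names <- c("mean", "variance", "skewness", "kurtosis")
  glcm_names <- character(0)
  for (d in 1:4)
    for (o in glcm_offsets(d))
      glcm_names <- c(glcm_names, paste(glcm_stat_names, o$token))
  for (d in 1:4)
    glcm_names <- c(glcm_names, sprintf("%s d%d avg", glcm_stat_names, d))
  grlm_names <- as.vector(vapply(grlm_angles, function(a)
    sprintf("%d°%s", a, grlm_stat_names), character(11)))
  dwt_names <- character(0)
  for (w in dwt_wavelet_names)
    for (l in 1:4)
      dwt_names <- c(dwt_names, sprintf("%s %s_%d", w, dwt_subbands, l))
  cat488 <- c(hist_names, glcm_names, grlm_names, dwt_names)
  stopifnot(length(cat488) == 488L, !anyDuplicated(cat488))
  .texture_env$catalogue <- cat488
  cat488
}
.texture_env <- new.env(parent = emptyenv())

#' Min-max quantization of a masked region
#'
#' In-mask intensities are linearly mapped to integer levels `1..n_levels`
#' (a constant region maps to level 1 everywhere).
#'
#' @param image intensity matrix.
#' @param mask logical matrix, non-empty.
#' @param n_levels number of gray levels (>= 2).
#' @return list of class `quantized_region`: `levels` (integer matrix, `NA`
#'   outside mask), `n_levels`, `range` (source min/max).
#' @export
quantize <- function(image, mask, n_levels = 64L) {
  stopifnot(is.matrix(image), is.logical(mask), all(dim(image) == dim(mask)),
            n_levels >= 2)
  if (!any(mask)) stop("empty region: mask has no pixels")
  v <- image[mask]
  mn <- min(v); mx <- max(v)
  lev <- matrix(NA_integer_, nrow(image), ncol(image))
  if (mx > mn) {
    lev[mask] <- pmin(n_levels,
                      as.integer(floor((v - mn) / (mx - mn) * n_levels)) + 1L)
  } else {
    lev[mask] <- 1L
  }
  structure(list(levels = lev, n_levels = as.integer(n_levels),
                 range = c(mn, mx)),
            class = "quantized_region")
}

#' First four histogram moments of a masked region
#'
#' Population-normalized moments of the raw in-mask intensities: mean,
#' population variance, standardized skewness, and excess kurtosis (a normal
#' sample gives ~0; set `excess_kurtosis = FALSE` for Pearson kurtosis).
#' Regions smaller than `min_region_pixels` give all-`NA` (flagged) values;
#' constant regions give variance 0 with skewness/kurtosis flagged.
#'
#' @param image intensity matrix.
#' @param mask logical matrix.
#' @param min_region_pixels minimum region size (default 10).
#' @param excess_kurtosis subtract 3 from the fourth standardized moment.
#' @return named numeric: mean, variance, skewness, kurtosis.
#' @export
histogram_features <- function(image, mask, min_region_pixels = 10L,
                               excess_kurtosis = TRUE) {
  v <- image[mask]
  out <- c(mean = NA_real_, variance = NA_real_,
           skewness = NA_real_, kurtosis = NA_real_)
  if (length(v) < min_region_pixels) return(out)
  n <- length(v)
  mu <- mean(v)
  m2 <- sum((v - mu)^2) / n
  out[["mean"]] <- mu
  out[["variance"]] <- m2
  if (m2 > 0) {
    s <- sqrt(m2)
    out[["skewness"]] <- sum((v - mu)^3) / n / s^3
    out[["kurtosis"]] <- sum((v - mu)^4) / n / s^4 - if (excess_kurtosis) 3 else 0
  }
  out
}

#' Gray-level co-occurrence matrix for one offset
#'
#' Counts level pairs `(p, p + offset)` with both pixels inside the mask,
#' symmetrized (each pair counted in both orders) and normalized to sum 1.
#'
#' @param q a [quantize()]d region.
#' @param offset integer `c(dr, dc)` pixel displacement.
#' @return `n_levels` x `n_levels` matrix summing to 1.
#' @export
glcm <- function(q, offset) {
  stopifnot(inherits(q, "quantized_region"), length(offset) == 2)
  lev <- q$levels; L <- q$n_levels
  nr <- nrow(lev); nc <- ncol(lev)
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  if (!length(r1) || !length(c1)) stop("empty co-occurrence matrix: offset too large")
  a <- lev[r1, c1, drop = FALSE]
  b <- lev[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("empty co-occurrence matrix: no in-mask pixel pairs")
  idx <- a[ok] + (b[ok] - 1L) * L
  M <- matrix(tabulate(idx, L * L), L, L)
  P <- M + t(M)
  P / sum(P)
}

#' The 19 GLCM statistics
#'
#' Haralick-family statistics with the Soh-Tsatsoulis/Clausi extensions
#' (IMC is the first information measure of correlation; IDN and IDMN are the
#' inverse-difference statistics normalized by the level count). Natural
#' logarithms; `0 log 0 := 0`. Degenerate matrices yield limit values
#' (correlation 0 when a marginal is constant).
#'
#' @param P normalized symmetric co-occurrence matrix from [glcm()].
#' @return named numeric vector of length 19.
#' @export
glcm_features <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(L) * px); muy <- sum(seq_len(L) * py)
  sx <- sqrt(sum((seq_len(L) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(L) - muy)^2 * py))
  nz <- P > 0
  ent <- -sum(P[nz] * log(P[nz]))
  acor <- sum(i * j * P)
  # sum / difference distributions
  psum <- vapply(2:(2 * L), function(k) sum(P[i + j == k]), 0)
  pdiff <- vapply(0:(L - 1), function(k) sum(P[abs(i - j) == k]), 0)
  ks <- 2:(2 * L); kd <- 0:(L - 1)
  sa <- sum(ks * psum)
  mud <- sum(kd * pdiff)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  pxy <- outer(px, py)
  hxy1 <- -sum(P[nz] * log(pxy[nz]))
  c(ACOR = acor,
    CON = sum((i - j)^2 * P),
    COR = if (sx > 0 && sy > 0) (acor - mux * muy) / (sx * sy) else 0,
    CP = sum((i + j - mux - muy)^4 * P),
    CS = sum((i + j - mux - muy)^3 * P),
    DIS = sum(abs(i - j) * P),
    ENE = sum(P^2),
    ENT = ent,
    HOM = sum(P / (1 + abs(i - j))),
    MP = max(P),
    SOS = sum((i - mux)^2 * P),
    SA = sa,
    SV = sum((ks - sa)^2 * psum),
    SE = -sum(psum[psum > 0] * log(psum[psum > 0])),
    DV = sum((kd - mud)^2 * pdiff),
    DE = -sum(pdiff[pdiff > 0] * log(pdiff[pdiff > 0])),
    IMC = if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0,
    IDN = sum(P / (1 + abs(i - j) / L)),
    IDMN = sum(P / (1 + (i - j)^2 / L^2)))
}

#' The 380-entry GLCM feature block
#'
#' 19 statistics at each of 16 directed offsets (distances 1-4 x angles
#' 0/45/90/135 degrees) plus, per distance, the arithmetic mean of the four
#' directional values (`"<STAT> d<d> avg"`), for 19 x 20 = 380 entries.
#'
#' @param q a [quantize()]d region.
#' @return named numeric vector of length 380 in catalogue order.
#' @export
glcm_feature_block <- function(q) {
  dir_vals <- vector("list", 4)
  out <- numeric(0)
  for (d in 1:4) {
    vals <- sapply(glcm_offsets(d), function(o) glcm_features(glcm(q, o$offset)))
    for (k in seq_along(glcm_offsets(d))) {
      o <- glcm_offsets(d)[[k]]
      out <- c(out, stats::setNames(vals[, k], paste(glcm_stat_names, o$token)))
    }
    dir_vals[[d]] <- vals
  }
  for (d in 1:4)
    out <- c(out, stats::setNames(rowMeans(dir_vals[[d]]),
                                  sprintf("%s d%d avg", glcm_stat_names, d)))
  out
}

# scan lines of a level matrix along one digital direction; NA breaks runs
grlm_lines <- function(lev, angle) {
  nr <- nrow(lev); nc <- ncol(lev)
  switch(as.character(angle),
    "0" = lapply(seq_len(nr), function(r) lev[r, ]),
    "90" = lapply(seq_len(nc), function(c) lev[, c]),
    "45" = lapply(2:(nr + nc), function(s) {
      r <- min(nr, s - 1):max(1, s - nc)
      lev[cbind(r, s - r)]
    }),
    "135" = lapply((1 - nc):(nr - 1), function(k) {
      r <- max(1, 1 + k):min(nr, nc + k)
      lev[cbind(r, r - k)]
    }),
    stop("angle must be one of 0, 45, 90, 135"))
}

# run-length matrix n(gray level, run length) for one angle
grlm_matrix <- function(q, angle) {
  lev <- q$levels; L <- q$n_levels
  maxlen <- max(dim(lev))
  G <- matrix(0, L, maxlen)
  for (line in grlm_lines(lev, angle)) {
    r <- rle(as.vector(line))
    keep <- !is.na(r$values)
    if (any(keep)) {
      gi <- r$values[keep]; li <- r$lengths[keep]
      for (k in seq_along(gi)) G[gi[k], li[k]] <- G[gi[k], li[k]] + 1
    }
  }
  G
}

#' The 44-entry GRLM feature block
#'
#' Eleven run-length statistics (RLN, GLN, LRE, SRE, FIR, LGRE, HGRE, SRLGE,
#' SRHGE, LRLGE, LRHGE) at each of the four angles, computed from maximal
#' same-level runs along the angle's digital direction; runs break at the
#' mask boundary. FIR (fraction of image in runs) is the run count divided by
#' the region pixel count.
#'
#' @param q a [quantize()]d region.
#' @return named numeric vector of length 44 in catalogue order.
#' @export
grlm_features <- function(q) {
  stopifnot(inherits(q, "quantized_region"))
  np <- sum(!is.na(q$levels))
  if (np == 0) stop("empty region")
  out <- numeric(0)
  for (angle in grlm_angles) {
    G <- grlm_matrix(q, angle)
    nr_runs <- sum(G)
    g <- matrix(seq_len(nrow(G)), nrow(G), ncol(G))
    l <- matrix(seq_len(ncol(G)), nrow(G), ncol(G), byrow = TRUE)
    vals <- c(RLN = sum(colSums(G)^2) / nr_runs,
              GLN = sum(rowSums(G)^2) / nr_runs,
              LRE = sum(G * l^2) / nr_runs,
              SRE = sum(G / l^2) / nr_runs,
              FIR = nr_runs / np,
              LGRE = sum(G / g^2) / nr_runs,
              HGRE = sum(G * g^2) / nr_runs,
              SRLGE = sum(G / (g^2 * l^2)) / nr_runs,
              SRHGE = sum(G * g^2 / l^2) / nr_runs,
              LRLGE = sum(G * l^2 / g^2) / nr_runs,
              LRHGE = sum(G * g^2 * l^2) / nr_runs)
    out <- c(out, stats::setNames(vals, sprintf("%d°%s", angle, grlm_stat_names)))
  }
  out
}

#' The 20-entry DWT feature block for one wavelet
#'
#' Four-level periodized 2-D wavelet decomposition of the mask-cropped,
#' zero-padded lesion bounding box (padded to a multiple of 16 so four dyadic
#' levels exist). Per level l: mean absolute coefficient of the horizontal
#' (HH_l), vertical (HV_l) and diagonal (HD_l) detail subbands and the
#' approximation (L_l), restricted to coefficients overlapping the
#' down-sampled mask, plus a pooled detail scalar D_l over the three detail
#' subbands — 5 x 4 = 20 scalars.
#'
#' @param image intensity matrix.
#' @param mask logical matrix.
#' @param wavelet one of `"haar"`, `"db2"`, `"sym4"`.
#' @param min_region_pixels regions smaller than this give flagged (`NA`)
#'   values.
#' @return named numeric vector of length 20.
#' @export
dwt_features <- function(image, mask, wavelet = c("haar", "db2", "sym4"),
                         min_region_pixels = 10L) {
  wavelet <- match.arg(wavelet)
  disp <- dwt_wavelet_names[[wavelet]]
  nm <- as.vector(vapply(1:4, function(l)
    sprintf("%s %s_%d", disp, dwt_subbands, l), character(5)))
  if (sum(mask) < min_region_pixels)
    return(stats::setNames(rep(NA_real_, 20), nm))
  rr <- range(which(rowSums(mask) > 0))
  cr <- range(which(colSums(mask) > 0))
  sub <- image[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  msk <- mask[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  sub[!msk] <- 0
  pad_to <- function(n) max(16L, as.integer(ceiling(n / 16) * 16))
  nr <- pad_to(nrow(sub)); nc <- pad_to(ncol(sub))
  block <- matrix(0, nr, nc); block[seq_len(nrow(sub)), seq_len(ncol(sub))] <- sub
  mblock <- matrix(FALSE, nr, nc)
  mblock[seq_len(nrow(sub)), seq_len(ncol(sub))] <- msk
  filt <- dwt_filters(wavelet)
  out <- numeric(0)
  cur <- block; curm <- mblock
  for (l in 1:4) {
    dec <- dwt_level_2d(cur, filt)
    curm <- downsample_mask(curm)
    inm <- which(curm)
    details <- c(abs(dec$HH[inm]), abs(dec$HV[inm]), abs(dec$HD[inm]))
    vals <- c(mean(abs(dec$HH[inm])), mean(abs(dec$HV[inm])),
              mean(abs(dec$HD[inm])), mean(abs(dec$L[inm])), mean(details))
    out <- c(out, vals)
    cur <- dec$L
  }
  stats::setNames(out, nm)
}

#' Extract the full 488-feature vector of a masked region
#'
#' Concatenates histogram (4), GLCM (380), GRLM (44) and DWT (60) blocks in
#' fixed catalogue order. Regions smaller than `min_region_pixels` return a
#' fully flagged (`NA`) vector with attribute `flagged = TRUE` rather than an
#' error, so small kinetic subregions degrade gracefully.
#'
#' @param image intensity matrix (typically a subtraction image).
#' @param mask logical region mask.
#' @param n_levels gray levels for GLCM/GRLM quantization (default 64).
#' @param min_region_pixels minimum region size (default 10).
#' @param excess_kurtosis see [histogram_features()].
#' @return named numeric vector of length 488.
#' @export
extract_all <- function(image, mask, n_levels = 64L, min_region_pixels = 10L,
                        excess_kurtosis = TRUE) {
  cat488 <- feature_catalogue()
  if (sum(mask) < min_region_pixels)
    return(structure(stats::setNames(rep(NA_real_, 488), cat488),
                     flagged = TRUE))
  q <- quantize(image, mask, n_levels)
  out <- c(histogram_features(image, mask, min_region_pixels, excess_kurtosis),
           glcm_feature_block(q),
           grlm_features(q),
           dwt_features(image, mask, "haar", min_region_pixels),
           dwt_features(image, mask, "db2", min_region_pixels),
           dwt_features(image, mask, "sym4", min_region_pixels))
  stopifnot(identical(names(out), cat488))
  structure(out, flagged = anyNA(out))
}
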