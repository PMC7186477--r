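#' Kinetic analysis: relative enhancement, time-to-peak, habitat partition
#'
#' The kinetic pipeline follows the standard habitat-imaging recipe: per-pixel
#' relative enhancement E(x,y,t) = (SI(x,y,t) - SI(x,y,t0)) / SI(x,y,t0) x 100
#' over the 8 post-contrast phases, time-to-peak TTP(x,y) = argmax_t E(x,y,t)
#' (earliest phase on ties), and a partition of the lesion into rapid
#' (TTP 1-4), medium (TTP 5-6) and slow (TTP 7-8) subregions.
#'
#' @name kinetics
NULL

#' DCE-MRI series container
#'
#' One case's pre-contrast image plus an ordered list of post-contrast phase
#' images (1-based phase indexing), all the same shape.
#'
#' @param pre pre-contrast intensity matrix (the t0 acquisition).
#' @param post list of post-contrast intensity matrices, phases 1..T.
#' @param phase_interval_s seconds between consecutive phases (default 80).
#' @return object of class `dce_series`.
#' @export
dce_series <- function(pre, post, phase_interval_s = 80) {
  stopifnot(is.matrix(pre), is.list(post), length(post) >= 1)
  for (p in post)
    if (!is.matrix(p) || !all(dim(p) == dim(pre)))
      stop("all post-contrast phases must be matrices with the shape of the pre-contrast image")
  structure(list(pre = pre, post = post, phase_interval_s = phase_interval_s),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  cat("dce_series:", nrow(x$pre), "x", ncol(x$pre), "pixels,",
      length(x$post), "post-contrast phases,",
      x$phase_interval_s, "s apart\n")
  invisible(x)
}

#' Per-pixel relative enhancement (percent)
#'
#' Pixels whose baseline intensity is below `epsilon_baseline` get `NA` at all
#' phases (flagged invalid, never an error): a near-zero baseline would make
#' the percentage blow up. The count of excluded pixels is attached as
#' attribute `n_invalid`.
#'
#' @param series a [dce_series()].
#' @param epsilon_baseline minimum baseline intensity (default 1).
#' @return object of class `enhancement_series`: numeric array
#'   `(rows, cols, phases)` of percentages, with attribute `valid` (logical
#'   matrix) and `n_invalid`.
#' @export
relative_enhancement <- function(series, epsilon_baseline = 1) {
  stopifnot(inherits(series, "dce_series"))
  pre <- series$pre
  valid <- is.finite(pre) & pre >= epsilon_baseline
  nt <- length(series$post)
  E <- array(NA_real_, c(nrow(pre), ncol(pre), nt))
  for (t in seq_len(nt)) {
    Et <- (series$post[[t]] - pre) / pre * 100
    Et[!valid] <- NA_real_
    E[, , t] <- Et
  }
  structure(E, valid = valid, n_invalid = sum(!valid),
            class = "enhancement_series")
}

#' Time-to-peak map
#'
#' Per pixel, the smallest phase index attaining the maximum relative
#' enhancement (earliest-phase tie break: the peak is *first attained* there).
#'
#' @param E an `enhancement_series` from [relative_enhancement()].
#' @return object of class `ttp_map`: integer matrix of phase indices with
#'   `NA` where enhancement is invalid; attribute `valid`.
#' @export
ttp_map <- function(E) {
  stopifnot(inherits(E, "enhancement_series"))
  d <- dim(E)
  flat <- matrix(as.numeric(E), d[1] * d[2], d[3])
  valid <- attr(E, "valid") & matrix(rowSums(is.na(flat)) == 0, d[1], d[2])
  ttp <- matrix(NA_integer_, d[1], d[2])
  ok <- which(valid)
  if (length(ok))
    ttp[ok] <- max.col(flat[ok, , drop = FALSE], ties.method = "first")
  structure(ttp, valid = valid, class = "ttp_map")
}

#' Partition a lesion into rapid / medium / slow subregions
#'
#' Inside the lesion mask, pixels peaking in the first four phases are rapid,
#' in phases 5-6 medium, in phases 7-8 slow. Pixels outside the mask, or with
#' undefined TTP, are background.
#'
#' @param ttp a [ttp_map()].
#' @param mask logical lesion mask, same shape.
#' @return object of class `subregion_labels`: integer matrix with 0 =
#'   background, 1 = rapid, 2 = medium, 3 = slow; attribute
#'   `n_invalid_in_mask` counts in-mask pixels without a valid TTP.
#' @export
partition_subregions <- function(ttp, mask) {
  stopifnot(inherits(ttp, "ttp_map"), is.logical(mask), all(dim(ttp) == dim(mask)))
  lab <- matrix(0L, nrow(ttp), ncol(ttp))
  inm <- mask & !is.na(unclass(ttp))
  t <- unclass(ttp)
  lab[inm & t <= 4L] <- 1L
  lab[inm & t >= 5L & t <= 6L] <- 2L
  lab[inm & t >= 7L] <- 3L
  structure(lab, n_invalid_in_mask = sum(mask & is.na(t)),
            class = "subregion_labels")
}

#' Subregion area fractions
#'
#' @param labels a [partition_subregions()] result.
#' @return named numeric (rapid, medium, slow) summing to 1.
#' @export
subregion_fractions <- function(labels) {
  stopifnot(inherits(labels, "subregion_labels"))
  counts <- tabulate(unclass(labels)[unclass(labels) > 0L], 3L)
  if (sum(counts) == 0) stop("empty label map: no labeled pixels")
  stats::setNames(counts / sum(counts), c("rapid", "medium", "slow"))
}

# logical matrix for one subregion (1 rapid, 2 medium, 3 slow)
subregion_mask <- function(labels, which) {
  stopifnot(inherits(labels, "subregion_labels"))
  unclass(labels) == as.integer(which)
}
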