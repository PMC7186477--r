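#' Semi-automatic lesion segmentation on subtraction images
#'
#' Lesion delineation mirrors the usual semi-automatic workflow: a rectangular
#' region of interest around the lesion, spatial fuzzy C-means clustering of
#' the subtraction-image intensities inside the ROI (two clusters, the
#' brighter one being lesion), then morphological refinement (largest
#' connected component, hole filling, one 3x3 binary opening).
#'
#' @name segmentation
NULL

#' Rectangular ROI box
#'
#' 0-based, half-open pixel coordinates `[row_min, row_max) x [col_min,
#' col_max)`, row-major.
#'
#' @param row_min,row_max,col_min,col_max integer bounds.
#' @return object of class `roi_box`.
#' @export
roi_box <- function(row_min, row_max, col_min, col_max) {
  b <- list(row_min = as.integer(row_min), row_max = as.integer(row_max),
            col_min = as.integer(col_min), col_max = as.integer(col_max))
  if (b$row_max <= b$row_min || b$col_max <= b$col_min)
    stop("ROI box must be non-empty")
  if (b$row_min < 0 || b$col_min < 0) stop("ROI box coordinates must be >= 0")
  structure(b, class = "roi_box")
}

roi_check_bounds <- function(roi, dims) {
  if (roi$row_max > dims[1] || roi$col_max > dims[2])
    stop("ROI box extends outside the image bounds")
  invisible(roi)
}

# 1-based index vectors of a 0-based half-open box
roi_rows <- function(roi) (roi$row_min + 1L):roi$row_max
roi_cols <- function(roi) (roi$col_min + 1L):roi$col_max

#' Phase subtraction
#'
#' Elementwise post minus pre; negative values are preserved.
#'
#' @param pre,post intensity matrices of identical shape.
#' @return intensity matrix.
#' @export
subtract_phases <- function(pre, post) {
  if (!all(dim(pre) == dim(post)))
    stop("dimension error: pre and post images differ in shape")
  post - pre
}

# windowed box sum of each column of a pixel x cluster membership matrix,
# on the image grid (w x w window, zero outside the image)
box_sum_grid <- function(u, nr, nc, w) {
  half <- (w - 1L) %/% 2L
  out <- u
  for (k in seq_len(ncol(u))) {
    m <- matrix(u[, k], nr, nc)
    # cumulative-sum box filter, rows then columns
    cs <- apply(rbind(0, apply(m, 2, cumsum)), 2, function(x) x)
    top <- pmax(seq_len(nr) - half - 1L, 0L) + 1L
    bot <- pmin(seq_len(nr) + half, nr) + 1L
    mr <- cs[bot, , drop = FALSE] - cs[top, , drop = FALSE]
    cs2 <- cbind(0, t(apply(mr, 1, cumsum)))
    left <- pmax(seq_len(nc) - half - 1L, 0L) + 1L
    right <- pmin(seq_len(nc) + half, nc) + 1L
    out[, k] <- as.vector(cs2[, right, drop = FALSE] - cs2[, left, drop = FALSE])
  }
  out
}

#' Spatial fuzzy C-means clustering of an intensity image
#'
#' Standard FCM (fuzzifier m) with the common spatial re-weighting: after the
#' usual membership update, each pixel's membership in cluster k is multiplied
#' by the sum of its neighbours' memberships raised to power `q` (its own
#' membership raised to `p`), then renormalized. `q = 0` degrades to plain
#' FCM. Cluster centers are initialized at evenly spaced intensity percentiles
#' (10th and 90th for two clusters), so the algorithm is fully deterministic.
#'
#' @param image intensity matrix (typically a subtraction image cropped to an
#'   ROI).
#' @param n_clusters number of clusters (>= 2).
#' @param fuzzifier fuzziness exponent m (> 1).
#' @param spatial_window odd window width for the neighbourhood sum.
#' @param spatial_weights numeric `c(p, q)` membership/spatial exponents.
#' @param tol convergence threshold on the max center displacement.
#' @param max_iter iteration cap.
#' @return list: `membership` array (rows, cols, clusters) summing to 1 per
#'   pixel, `centers` (ascending order not guaranteed), `objective` trace of
#'   the FCM objective, `iterations`.
#' @export
sfcm_cluster <- function(image, n_clusters = 2L, fuzzifier = 2,
                         spatial_window = 3L, spatial_weights = c(p = 1, q = 1),
                         tol = 1e-5, max_iter = 200L) {
  stopifnot(is.matrix(image), n_clusters >= 2, fuzzifier > 1,
            spatial_window %% 2 == 1)
  x <- as.numeric(image)
  if (diff(range(x)) == 0)
    stop("degenerate clustering: image is constant, cluster centers coincide")
  nr <- nrow(image); nc <- ncol(image); n <- length(x)
  p <- spatial_weights[[1]]; q <- spatial_weights[[2]]
  probs <- seq(0.1, 0.9, length.out = n_clusters)
  centers <- as.numeric(stats::quantile(x, probs, names = FALSE))
  m <- fuzzifier
  objective <- numeric(0)
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- outer(x, centers, function(a, b) (a - b)^2)
    d2 <- pmax(d2, 1e-12)
    w <- d2^(-1 / (m - 1))
    u <- w / rowSums(w)
    if (q != 0) {
      h <- box_sum_grid(u, nr, nc, spatial_window)
      u <- (u^p) * (h^q)
      u <- u / rowSums(u)
    }
    um <- u^m
    centers_new <- colSums(um * x) / colSums(um)
    objective <- c(objective, sum(um * d2))
    delta <- max(abs(centers_new - centers))
    centers <- centers_new
    if (delta < tol) break
  }
  list(membership = array(u, c(nr, nc, n_clusters)),
       centers = centers, objective = objective, iterations = length(objective))
}

# 8-connected component labelling by flood fill (iterative stack)
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  }
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      r0 <- ((i - 1L) %% nr) + 1L; c0 <- ((i - 1L) %/% nr) + 1L
      rn <- r0 + dr; cn <- c0 + dc
      ok <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
      j <- (cn[ok] - 1L) * nr + rn[ok]
      j <- j[mask[j] & lab[j] == 0L]
      if (length(j)) { lab[j] <- cur; stack <- c(stack, j) }
    }
  }
  lab
}

fill_holes <- function(mask) {
  # background connected (4-conn) to the border stays background; the rest
  # are interior holes
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- !mask
  reach <- matrix(FALSE, nr, nc)
  border <- unique(c(which(bg[1, ]) * nr - nr + 1L,
                     which(bg[nr, ]) * nr,
                     (which(bg[, 1]) - 1L) %% nr + 1L,
                     (nc - 1L) * nr + which(bg[, nc])))
  border <- border[bg[border]]
  stack <- border
  reach[stack] <- TRUE
  while (length(stack)) {
    i <- stack[length(stack)]; stack <- stack[-length(stack)]
    r0 <- ((i - 1L) %% nr) + 1L; c0 <- ((i - 1L) %/% nr) + 1L
    rn <- r0 + c(-1L, 1L, 0L, 0L); cn <- c0 + c(0L, 0L, -1L, 1L)
    ok <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
    j <- (cn[ok] - 1L) * nr + rn[ok]
    j <- j[bg[j] & !reach[j]]
    if (length(j)) { reach[j] <- TRUE; stack <- c(stack, j) }
  }
  mask | (bg & !reach)
}

erode3 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  out <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1)
    out <- out & pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  out
}

dilate3 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  out <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1)
    out <- out | pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  out
}

#' Morphological refinement of a raw binary segmentation
#'
#' Keeps the largest 8-connected component, fills interior holes, then applies
#' one binary opening with a 3x3 structuring element. If the opening splits
#' the mask, the largest piece is kept so the result is a single component.
#'
#' @param raw logical matrix, non-empty.
#' @param min_lesion_pixels minimum acceptable mask size (default 16).
#' @return object of class `lesion_mask`: logical matrix with attribute
#'   `pixel_count`.
#' @export
refine_mask <- function(raw, min_lesion_pixels = 16L) {
  stopifnot(is.logical(raw))
  if (!any(raw)) stop("raw mask is empty")
  lab <- label_components(raw, 8L)
  keep <- which.max(tabulate(lab[lab > 0L]))
  mask <- lab == keep
  mask <- fill_holes(mask)
  mask <- dilate3(erode3(mask))
  if (any(mask)) {
    lab <- label_components(mask, 8L)
    if (max(lab) > 1L) mask <- lab == which.max(tabulate(lab[lab > 0L]))
  }
  n <- sum(mask)
  if (n < min_lesion_pixels)
    stop("too-small lesion: refined mask has ", n, " pixels (< ",
         min_lesion_pixels, ")")
  structure(mask, pixel_count = n, class = c("lesion_mask", "matrix", "array"))
}

#' Segment a lesion on a subtraction image
#'
#' Spatial fuzzy C-means (2 clusters) inside the ROI; pixels hard-assigned to
#' the cluster with the highest center intensity form the raw lesion mask,
#' which is then morphologically refined. With `bypass_mask` an externally
#' supplied mask (e.g. phantom ground truth) is validated and returned
#' unchanged, so downstream stages can be tested independently of
#' segmentation quality.
#'
#' @param subtraction subtraction-image intensity matrix.
#' @param roi a [roi_box()].
#' @param bypass_mask optional logical matrix to pass through.
#' @param min_lesion_pixels minimum mask size.
#' @param ... further arguments to [sfcm_cluster()].
#' @return a `lesion_mask` (full image shape); all TRUE pixels lie inside the
#'   ROI.
#' @export
segment_lesion <- function(subtraction, roi, bypass_mask = NULL,
                           min_lesion_pixels = 16L, ...) {
  stopifnot(is.matrix(subtraction), inherits(roi, "roi_box"))
  roi_check_bounds(roi, dim(subtraction))
  if (!is.null(bypass_mask)) {
    stopifnot(is.logical(bypass_mask), all(dim(bypass_mask) == dim(subtraction)))
    return(structure(bypass_mask, pixel_count = sum(bypass_mask),
                     class = c("lesion_mask", "matrix", "array")))
  }
  crop <- subtraction[roi_rows(roi), roi_cols(roi), drop = FALSE]
  fit <- sfcm_cluster(crop, n_clusters = 2L, ...)
  lesion_cluster <- which.max(fit$centers)
  hard <- fit$membership[, , lesion_cluster] >=
    apply(fit$membership, c(1, 2), max) - 1e-12
  # a pure-noise ROI splits into two clusters ~1.6 noise-sd apart; a real
  # enhancing lesion separates by many multiples of the within-cluster spread
  within_sd <- sqrt(mean((crop - ifelse(hard, max(fit$centers), min(fit$centers)))^2))
  if (diff(range(fit$centers)) < 4 * within_sd)
    stop("too-small lesion: no enhancing cluster in the ROI ",
         "(cluster separation below 4 within-cluster standard deviations)")
  raw <- matrix(FALSE, nrow(subtraction), ncol(subtraction))
  raw[roi_rows(roi), roi_cols(roi)] <- hard
  refine_mask(raw, min_lesion_pixels = min_lesion_pixels)
}

#' Dice coefficient between two masks
#'
#' @param a,b logical matrices of identical shape.
#' @return Dice similarity in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
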