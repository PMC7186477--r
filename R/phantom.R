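#' Synthetic DCE-MRI phantom generator
#'
#' Builds two-class cohorts of dynamic contrast-enhanced breast MRI cases with
#' a known circular lesion, known kinetic habitat structure (rapid / medium /
#' slow time-to-peak subregions) and configurable class effects, so that every
#' downstream stage (segmentation, regionalization, texture extraction,
#' cross-validated classification) can be validated against ground truth.
#'
#' @name phantom
NULL

#' Phantom cohort configuration
#'
#' The defaults describe the stated world the package is tested in: a 76-case
#' cohort with the clinical class balance (42 positive / 34 negative), one
#' pre-contrast and 8 post-contrast phases 80 s apart, a 128x128 matrix
#' (desk-scale stand-in for a 1024x1024 scanner matrix), and peak relative
#' enhancement of 80-120% over baseline, typical of malignant breast lesions.
#'
#' Two class-effect channels are separately switchable:
#' \describe{
#'   \item{\code{texture_effect}}{separation multiplier (>= 0) for the
#'     intralesional spatial variability of the enhancement-amplitude field.
#'     The negative class has amplitude coefficient of variation
#'     \code{amplitude_cv}; the positive class has
#'     \code{amplitude_cv * (1 + texture_effect)}. Zero means no texture
#'     difference between classes.}
#'   \item{\code{kinetic_effect}}{shift (>= 0) of the positive class's habitat
#'     composition toward the rapid compartment: the positive rapid fraction
#'     becomes \code{r + kinetic_effect * (1 - r)} with medium/slow rescaled
#'     proportionally. Zero means identical kinetics in both classes.}
#' }
#' With both effects at zero the two classes are exchangeable, which is the
#' null world used for permutation-band calibration.
#'
#' @param n_cases number of cases in the cohort.
#' @param class_balance fraction of positive cases in `[0, 1]`.
#' @param image_size pixels per side of the (square) image.
#' @param n_phases number of post-contrast phases; must be >= 8 for the
#'   rapid/medium/slow partition rule to be well defined.
#' @param lesion_radius_range numeric length-2, lesion radius range in pixels.
#' @param habitat_fractions length-3 nonnegative vector (rapid, medium, slow)
#'   summing to 1: the negative-class habitat area fractions.
#' @param kinetic_params_by_class list with elements `negative` and `positive`,
#'   each a list with `amplitude` (length-2 range of peak relative enhancement,
#'   percent) and `washout_slope` (length-2 range, percent enhancement lost per
#'   phase after the peak; must be positive).
#' @param texture_effect class-separation multiplier for amplitude variability.
#' @param kinetic_effect habitat-fraction shift toward rapid for positives.
#' @param amplitude_cv baseline coefficient of variation of the per-pixel
#'   amplitude field (both classes when `texture_effect = 0`).
#' @param noise_sd additive Gaussian noise standard deviation, intensity units.
#' @param baseline pre-contrast signal intensity (constant across the image).
#' @param phase_interval_s seconds between post-contrast phases.
#' @param geometry habitat layout: `"concentric"` (rapid rim, slow core, the
#'   ring-enhancement pattern) or `"blobs"` (seeded nearest-centroid patches).
#' @param seed integer master seed; the cohort is a pure function of the
#'   configuration including this seed.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(n_cases = 76L,
                           class_balance = 42 / 76,
                           image_size = 128L,
                           n_phases = 8L,
                           lesion_radius_range = c(12, 20),
                           habitat_fractions = c(rapid = 0.5, medium = 0.3, slow = 0.2),
                           kinetic_params_by_class = list(
                             negative = list(amplitude = c(80, 120), washout_slope = c(8, 16)),
                             positive = list(amplitude = c(80, 120), washout_slope = c(8, 16))
                           ),
                           texture_effect = 0,
                           kinetic_effect = 0,
                           amplitude_cv = 0.10,
                           noise_sd = 2,
                           baseline = 100,
                           phase_interval_s = 80,
                           geometry = c("concentric", "blobs"),
                           seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(n_cases >= 1, image_size >= 16, length(lesion_radius_range) == 2,
            lesion_radius_range[1] > 0, diff(lesion_radius_range) >= 0,
            texture_effect >= 0, kinetic_effect >= 0, amplitude_cv >= 0,
            noise_sd >= 0, baseline > 0)
  if (n_phases < 8)
    stop("n_phases must be >= 8: the rapid/medium/slow partition rule needs phases 1..8")
  if (class_balance < 0 || class_balance > 1)
    stop("class_balance must lie in [0, 1]")
  if (length(habitat_fractions) != 3 || any(habitat_fractions < 0) ||
      abs(sum(habitat_fractions) - 1) > 1e-9)
    stop("habitat_fractions must be three nonnegative values summing to 1")
  for (cls in c("negative", "positive")) {
    kp <- kinetic_params_by_class[[cls]]
    if (is.null(kp) || length(kp$amplitude) != 2 || length(kp$washout_slope) != 2)
      stop("kinetic_params_by_class must give amplitude and washout_slope ranges per class")
    if (any(kp$amplitude <= 0) || any(kp$washout_slope <= 0))
      stop("amplitude and washout_slope ranges must be positive")
  }
  cfg <- list(n_cases = as.integer(n_cases), class_balance = class_balance,
              image_size = as.integer(image_size), n_phases = as.integer(n_phases),
              lesion_radius_range = lesion_radius_range,
              habitat_fractions = stats::setNames(as.numeric(habitat_fractions),
                                                  c("rapid", "medium", "slow")),
              kinetic_params_by_class = kinetic_params_by_class,
              texture_effect = texture_effect, kinetic_effect = kinetic_effect,
              amplitude_cv = amplitude_cv, noise_sd = noise_sd,
              baseline = baseline, phase_interval_s = phase_interval_s,
              geometry = geometry, seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  cfg
}

#' Piecewise-linear kinetic enhancement curve
#'
#' Relative-enhancement time course of one pixel: linear wash-in from 0 at the
#' (virtual) pre-contrast instant to `amplitude` at phase `ttp_phase`, then
#' linear wash-out at `washout_slope` per phase, floored at 0. The curve's
#' argmax (earliest phase on ties) is `ttp_phase` by construction; only the
#' peak location matters downstream, not the curve family.
#'
#' @param ttp_phase integer in `1..n_phases`, phase of peak enhancement.
#' @param amplitude peak relative enhancement (percent), > 0.
#' @param washout_slope enhancement lost per phase after the peak (>= 0; a
#'   zero slope gives a plateau whose first phase is still the argmax).
#' @param n_phases number of post-contrast phases.
#' @return numeric vector of length `n_phases`.
#' @export
kinetic_curve <- function(ttp_phase, amplitude, washout_slope, n_phases = 8L) {
  if (length(ttp_phase) != 1 || is.na(ttp_phase) || ttp_phase != round(ttp_phase) ||
      ttp_phase < 1 || ttp_phase > n_phases)
    stop("ttp_phase must be a single integer in 1..n_phases")
  stopifnot(amplitude > 0, washout_slope >= 0, n_phases >= 1)
  t <- seq_len(n_phases)
  curve <- ifelse(t <= ttp_phase,
                  amplitude * t / ttp_phase,
                  pmax(amplitude - washout_slope * (t - ttp_phase), 0))
  curve
}

# Run expr with a private RNG stream; the caller's RNG state is untouched.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Habitat area fractions for one class; positives shifted toward rapid.
class_habitat_fractions <- function(config, class_label) {
  f <- config$habitat_fractions
  if (class_label == 1L && config$kinetic_effect > 0) {
    r <- f[["rapid"]] + config$kinetic_effect * (1 - f[["rapid"]])
    rest <- f[["medium"]] + f[["slow"]]
    if (rest > 0) {
      f <- c(rapid = r, medium = f[["medium"]] / rest * (1 - r),
             slow = f[["slow"]] / rest * (1 - r))
    } else f <- c(rapid = 1, medium = 0, slow = 0)
  }
  f
}

# Assign habitat labels (1 rapid, 2 medium, 3 slow) to lesion pixels.
assign_habitats <- function(rows, cols, center, radius, fractions, geometry) {
  n <- length(rows)
  lab <- integer(n)
  if (geometry == "concentric") {
    # count-true concentric rings: slow core, medium ring, rapid rim; pixels
    # ranked by radius and cut at the exact target counts
    rho <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
    n_slow <- round(n * fractions[["slow"]])
    n_med <- round(n * fractions[["medium"]])
    ord <- order(rho, rows, cols)
    lab[ord] <- c(rep(3L, n_slow), rep(2L, n_med),
                  rep(1L, max(0L, n - n_slow - n_med)))[seq_len(n)]
  } else {
    # nearest-centroid blobs: seeds drawn inside the lesion, one batch per
    # habitat, pixel count per habitat matched to the requested fractions
    target <- round(n * fractions)
    target[1] <- n - sum(target[-1])
    seeds <- cbind(stats::runif(6, -radius, radius) + center[1],
                   stats::runif(6, -radius, radius) + center[2])
    hab_of_seed <- rep(1:3, each = 2)
    d <- outer(seq_len(n), seq_len(nrow(seeds)), function(i, s)
      sqrt((rows[i] - seeds[s, 1])^2 + (cols[i] - seeds[s, 2])^2))
    pref <- hab_of_seed[max.col(-d, ties.method = "first")]
    # enforce exact counts, reassigning surplus pixels to the nearest
    # under-filled habitat by seed distance
    lab <- pref
    for (h in 1:3) {
      excess <- sum(lab == h) - target[h]
      if (excess > 0) {
        idx <- which(lab == h)
        dh <- apply(d[idx, hab_of_seed != h, drop = FALSE], 1, min)
        move <- idx[order(dh)][seq_len(excess)]
        for (m in move) {
          deficit <- which(tabulate(lab, 3) < target)
          if (length(deficit)) lab[m] <- deficit[1]
        }
      }
    }
  }
  lab
}

#' Generate one synthetic DCE-MRI case
#'
#' @param config a [phantom_config()].
#' @param class_label 0 (negative) or 1 (positive).
#' @param case_seed integer seed private to this case.
#' @return list with `series` (a [dce_series()]) and `truth` (class
#'   `phantom_truth`: `class_label`, logical `lesion_mask`, integer
#'   `habitat_labels` 1 = rapid / 2 = medium / 3 = slow / 0 = background, and
#'   integer `true_ttp` in 1..8 inside the mask).
#' @export
generate_case <- function(config, class_label, case_seed) {
  stopifnot(inherits(config, "phantom_config"), class_label %in% c(0L, 1L))
  with_private_seed(case_seed, {
    sz <- config$image_size
    radius <- stats::runif(1, config$lesion_radius_range[1], config$lesion_radius_range[2])
    if (2 * radius + 4 > sz)
      stop("lesion of radius ", round(radius, 1), " does not fit in a ",
           sz, "x", sz, " image")
    center <- c(sz / 2 + 0.5, sz / 2 + 0.5)
    rr <- matrix(seq_len(sz), sz, sz)
    cc <- matrix(seq_len(sz), sz, sz, byrow = TRUE)
    mask <- (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
    idx <- which(mask)
    rows <- rr[idx]; cols <- cc[idx]

    fr <- class_habitat_fractions(config, as.integer(class_label))
    hab <- assign_habitats(rows, cols, center, radius, fr, config$geometry)
    ttp <- integer(length(idx))
    ttp[hab == 1L] <- sample(1:4, sum(hab == 1L), replace = TRUE)
    ttp[hab == 2L] <- sample(5:6, sum(hab == 2L), replace = TRUE)
    ttp[hab == 3L] <- sample(7:8, sum(hab == 3L), replace = TRUE)

    kp <- config$kinetic_params_by_class[[if (class_label == 1L) "positive" else "negative"]]
    amp_case <- stats::runif(1, kp$amplitude[1], kp$amplitude[2])
    slope_case <- stats::runif(1, kp$washout_slope[1], kp$washout_slope[2])
    cv <- config$amplitude_cv *
      (if (class_label == 1L) 1 + config$texture_effect else 1)
    amp_px <- amp_case * pmax(0.1, 1 + stats::rnorm(length(idx), 0, cv))

    pre <- matrix(config$baseline, sz, sz)
    post <- vector("list", config$n_phases)
    enh <- matrix(0, length(idx), config$n_phases)
    for (k in seq_along(idx))
      enh[k, ] <- kinetic_curve(ttp[k], amp_px[k], slope_case, config$n_phases)
    for (t in seq_len(config$n_phases)) {
      img <- matrix(config$baseline, sz, sz)
      img[idx] <- config$baseline * (1 + enh[, t] / 100)
      post[[t]] <- img
    }
    if (config$noise_sd > 0) {
      pre <- pre + matrix(stats::rnorm(sz * sz, 0, config$noise_sd), sz, sz)
      for (t in seq_len(config$n_phases))
        post[[t]] <- post[[t]] + matrix(stats::rnorm(sz * sz, 0, config$noise_sd), sz, sz)
    }

    habitat_labels <- matrix(0L, sz, sz)
    habitat_labels[idx] <- hab
    true_ttp <- matrix(NA_integer_, sz, sz)
    true_ttp[idx] <- ttp
    truth <- structure(list(class_label = as.integer(class_label),
                            lesion_mask = mask,
                            habitat_labels = habitat_labels,
                            true_ttp = true_ttp),
                       class = "phantom_truth")
    list(series = dce_series(pre, post, config$phase_interval_s), truth = truth)
  })
}

#' Generate a full phantom cohort
#'
#' The number of positive cases is `round(n_cases * class_balance)`; per-case
#' seeds are drawn from a stream keyed by `config$seed`, so the whole cohort
#' is a pure function of the configuration.
#'
#' @param config a [phantom_config()].
#' @return list of class `phantom_cohort`: per-case lists with `case_id`,
#'   `series`, `truth`, plus attributes `labels` and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$n_cases < 2) stop("cohort needs n_cases >= 2")
  n_pos <- round(config$n_cases * config$class_balance)
  n_neg <- config$n_cases - n_pos
  if (n_pos < 1 || n_neg < 1)
    stop("degenerate class balance: cohort must contain at least one case per class")
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  seeds <- with_private_seed(config$seed,
                             sample.int(.Machine$integer.max - 1L, config$n_cases))
  cohort <- vector("list", config$n_cases)
  for (i in seq_len(config$n_cases)) {
    cs <- generate_case(config, labels[i], seeds[i])
    cohort[[i]] <- list(case_id = sprintf("case_%03d", i),
                        series = cs$series, truth = cs$truth)
  }
  structure(cohort, labels = labels, config = config, class = "phantom_cohort")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("phantom_config:", x$n_cases, "cases,",
      round(x$class_balance * x$n_cases), "positive;",
      x$image_size, "px,", x$n_phases, "post-contrast phases\n")
  cat("  habitat fractions (rapid/medium/slow):",
      paste(round(x$habitat_fractions, 3), collapse = "/"),
      "; geometry:", x$geometry, "\n")
  cat("  texture_effect:", x$texture_effect, " kinetic_effect:", x$kinetic_effect,
      " noise_sd:", x$noise_sd, " seed:", x$seed, "\n")
  invisible(x)
}
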