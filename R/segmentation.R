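#' Threshold a brightfield image into foreground (aggregate) and background
#'
#' Global binarization of an 8-bit single-channel image: a pixel is foreground
#' when `intensity / 255 < threshold`, i.e. the dark (aggregate) phase of a
#' transmitted-light image. Thresholds are conventionally restricted to the
#' 0.4--0.6 window; values outside it require `allow_outside = TRUE`.
#'
#' @param image Integer matrix of 8-bit intensities (see [sim_field()] or
#'   [read_gray_image()]).
#' @param threshold Fraction of full scale in `[0.4, 0.6]` unless overridden.
#' @param allow_outside Set `TRUE` to permit thresholds outside `[0.4, 0.6]`.
#' @return A `binary_image`: list with `mask` (logical matrix, `TRUE` =
#'   foreground) and `threshold`.
#' @examples
#' f <- sim_field(n_aggregates = 2, width_px = 200, height_px = 200,
#'                radius_range_px = c(15, 25), noise_sd = 0, seed = 2)
#' b <- binarize(f$image)
#' sum(b$mask)
#' @export
binarize <- function(image, threshold = 0.5, allow_outside = FALSE) {
  check_gray_image(image)
  if ((threshold < 0.4 || threshold > 0.6) && !allow_outside) {
    abort("`threshold` outside [0.4, 0.6]; pass `allow_outside = TRUE` to override.")
  }
  structure(
    list(mask = image / 255 < threshold, threshold = threshold),
    class = "binary_image"
  )
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image> %d x %d px, %d foreground (threshold %.2f)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$threshold))
  invisible(x)
}

as_mask <- function(binary) {
  if (inherits(binary, "binary_image")) return(binary$mask)
  if (is.matrix(binary) && is.logical(binary)) return(binary)
  abort("Expected a `binary_image` (from `binarize()`) or a logical matrix.")
}

#' Exact circular Hough vote counts at given centers
#'
#' For each candidate center, counts the foreground pixels lying in the
#' one-pixel annulus around every integer radius: a foreground pixel at
#' Euclidean distance `d` from the center casts a vote at radius
#' `round(d)` (the +/- 0.5 px annulus tolerance of the circle equation
#' `(x - A)^2 + (y - B)^2 = R^2`). This is the accumulator that
#' [hough_detect()] evaluates at its candidate centers.
#'
#' @param binary A `binary_image` or logical matrix.
#' @param centers Two-column matrix (or data frame) of candidate centers as
#'   (row, col).
#' @param radius_max Largest radius (pixels) to accumulate.
#' @return A matrix of vote counts, one row per center, columns named by
#'   radius `1:radius_max`.
#' @export
hough_votes <- function(binary, centers, radius_max) {
  mask <- as_mask(binary)
  centers <- as.matrix(centers)
  fg <- which(mask, arr.ind = TRUE)
  votes <- matrix(0L, nrow = nrow(centers), ncol = radius_max,
                  dimnames = list(NULL, 1:radius_max))
  if (nrow(fg) == 0) return(votes)
  for (i in seq_len(nrow(centers))) {
    d <- sqrt((fg[, 1] - centers[i, 1])^2 + (fg[, 2] - centers[i, 2])^2)
    bin <- floor(d + 0.5)
    keep <- bin >= 1 & bin <= radius_max
    if (any(keep)) votes[i, ] <- tabulate(bin[keep], nbins = radius_max)
  }
  votes
}

# Candidate centers: local maxima of the distance transform of the mask.
# Disk-like blobs peak at their inscribed-circle centers; fused blobs yield
# one candidate per lobe. Nearby maxima (< 3 px apart) are merged.
hough_candidates <- function(mask, min_dist = 3) {
  dm <- as.matrix(EBImage::distmap(mask * 1))
  if (max(dm) < min_dist) return(matrix(numeric(0), ncol = 2))
  dil <- as.matrix(EBImage::dilate(dm, EBImage::makeBrush(5, "box")))
  idx <- which(dm >= dil & dm >= min_dist, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(numeric(0), ncol = 2))
  ord <- order(dm[idx], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  kept <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(idx))) {
    p <- idx[i, ]
    if (nrow(kept) == 0 ||
        all((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2 >= min_dist^2)) {
      kept <- rbind(kept, p)
    }
  }
  unname(kept)
}

# Full vote profiles at candidate centers, each refined over a +/-2 px
# window. A center's score is its best vote count among supported radii
# (those clearing the perimeter-support threshold), so stray annulus votes
# contributed by distant aggregates at implausible radii cannot steer the
# refinement. The vote peak is a discretization plateau; its centroid is
# reported as the subpixel center, with the argmax center's profile kept
# for radius selection. Returns a list of records (row, col, profile).
hough_profiles <- function(mask, radius_max, accept_frac = 0.5, refine = 2) {
  cand <- hough_candidates(mask)
  if (nrow(cand) == 0) return(list())
  out <- vector("list", nrow(cand))
  offs <- expand.grid(dr = -refine:refine, dc = -refine:refine)
  radii <- seq_len(radius_max)
  support <- accept_frac * 2 * pi * radii
  for (i in seq_len(nrow(cand))) {
    ctrs <- cbind(cand[i, 1] + offs$dr, cand[i, 2] + offs$dc)
    v <- hough_votes(mask, ctrs, radius_max)
    peaks <- apply(v, 1, function(vi) {
      ok <- vi >= support & vi > 0
      if (any(ok)) max(vi[ok]) else 0
    })
    if (max(peaks) == 0) next
    best <- which.max(peaks)
    top <- peaks >= 0.97 * peaks[best]
    out[[i]] <- list(row = mean(ctrs[top, 1]), col = mean(ctrs[top, 2]),
                     profile = v[best, ])
  }
  purrr::compact(out)
}

# Sensitivity rule on a radial vote profile restricted to [rmin, rmax].
# Candidate radii must individually clear the perimeter-support acceptance
# threshold (votes >= accept_frac * 2 pi R); among candidates, those with
# votes >= (1 - sensitivity) * max votes are eligible and the largest wins.
# sensitivity = 0 is the pure argmax, 1 always the largest candidate.
select_radius <- function(profile, rmin, rmax, sensitivity, accept_frac = 0.5) {
  radii <- rmin:rmax
  v <- profile[radii]
  supported <- v >= accept_frac * 2 * pi * radii & v > 0
  if (!any(supported)) return(NULL)
  vmax <- max(v[supported])
  eligible <- radii[supported & v >= (1 - sensitivity) * vmax]
  r <- max(eligible)
  list(radius = r, votes = unname(v[match(r, radii)]))
}

#' Single-pass rough circular Hough detection
#'
#' Accumulates votes over (center, radius) for circles satisfying
#' `(x - A)^2 + (y - B)^2 = R^2` on the foreground of a binarized image and
#' returns one detection per supported center. Votes at a center are exact
#' annulus counts ([hough_votes()]); candidate centers are proposed at local
#' maxima of the mask's distance transform and refined locally, so votes at
#' every reported center equal the full accumulator's. Among split votes the
#' sensitivity rule picks the radius: all radii within `sensitivity` x
#' max-votes of the per-center maximum are eligible and the largest wins, so
#' sensitivities near 1 favour larger radii. A detection is kept only if its
#' votes reach `accept_frac` of the ideal circle perimeter `2 pi R`.
#'
#' @param binary A `binary_image` from [binarize()] (or logical matrix).
#' @param radius_min,radius_max Radius search bounds in pixels,
#'   `0 < radius_min < radius_max <= min(dim)/2`.
#' @param sensitivity Split-vote radius selection hyperparameter in `[0, 1]`.
#' @param accept_frac Minimum fraction of the ideal perimeter that must vote.
#' @param pass_index Integer tag recorded with each detection.
#' @return Tibble of detections sorted by votes (descending): `row`, `col`,
#'   `radius_px`, `votes`, `pass_index`, `sensitivity`.
#' @examples
#' f <- sim_field(n_aggregates = 1, width_px = 220, height_px = 220,
#'                radius_range_px = c(30, 30), aspect_ratio_range = c(1, 1),
#'                blur_sigma_px = 0, noise_sd = 0, seed = 3)
#' hough_detect(binarize(f$image), radius_min = 20, radius_max = 100)
#' @export
hough_detect <- function(binary, radius_min = 20, radius_max = 200,
                         sensitivity = 0.8, accept_frac = 0.5,
                         pass_index = 1L) {
  mask <- as_mask(binary)
  check_pass(radius_min, radius_max, sensitivity, dim(mask))
  profs <- hough_profiles(mask, radius_max, accept_frac)
  detections_from_profiles(profs, radius_min, radius_max, sensitivity,
                           accept_frac, pass_index)
}

detections_from_profiles <- function(profs, radius_min, radius_max,
                                     sensitivity, accept_frac, pass_index) {
  rows <- purrr::map(profs, function(p) {
    sel <- select_radius(p$profile, radius_min, radius_max, sensitivity,
                         accept_frac)
    if (is.null(sel)) return(NULL)
    tibble(row = p$row, col = p$col, radius_px = sel$radius,
           votes = sel$votes, pass_index = as.integer(pass_index),
           sensitivity = sensitivity)
  })
  out <- list_rbind(purrr::compact(rows))
  if (nrow(out) == 0) return(empty_detections())
  arrange(out, desc(votes))
}

empty_detections <- function() {
  tibble(row = numeric(0), col = numeric(0), radius_px = numeric(0),
         votes = integer(0), pass_index = integer(0), sensitivity = numeric(0))
}

check_pass <- function(radius_min, radius_max, sensitivity, dims) {
  if (!(radius_min > 0 && radius_min < radius_max)) {
    abort("Radius bounds must satisfy 0 < radius_min < radius_max.")
  }
  if (radius_max > min(dims) / 2) {
    abort(sprintf(
      "`radius_max` (%g px) exceeds half the smaller image dimension (%g px).",
      radius_max, min(dims) / 2))
  }
  if (sensitivity < 0 || sensitivity > 1) abort("`sensitivity` must lie in [0, 1].")
  invisible(NULL)
}

#' Default five-pass Hough schedule
#'
#' The standard multi-pass schedule for aggregate segmentation: radius search
#' windows 20--200, 40--200, 60--200, 80--200 and 90--200 px with
#' sensitivities 0.72, 0.76, 0.80, 0.88 and 0.92, so later passes ignore the
#' smallest features and lean toward larger radii on split votes.
#'
#' @return Tibble with columns `radius_min`, `radius_max`, `sensitivity`.
#' @export
default_hough_passes <- function() {
  tibble(
    radius_min = c(20, 40, 60, 80, 90),
    radius_max = 200,
    sensitivity = c(0.72, 0.76, 0.80, 0.88, 0.92)
  )
}

#' Multi-pass Hough segmentation of a brightfield image
#'
#' Binarizes the image, runs [hough_detect()] once per pass of the schedule,
#' stacks the per-pass detections and collapses repeats with
#' [dedupe_detections()]. The default schedule is [default_hough_passes()].
#'
#' @param image Integer matrix of 8-bit intensities.
#' @param passes Tibble/data frame with columns `radius_min`, `radius_max`,
#'   `sensitivity`, one row per pass.
#' @param threshold Binarization threshold, see [binarize()].
#' @param accept_frac Vote acceptance threshold, see [hough_detect()].
#' @param allow_outside Passed to [binarize()].
#' @return Tibble of deduplicated detections (same columns as
#'   [hough_detect()]).
#' @export
multi_pass_segment <- function(image, passes = default_hough_passes(),
                               threshold = 0.5, accept_frac = 0.5,
                               allow_outside = FALSE) {
  if (is.null(passes) || nrow(passes) == 0) {
    abort("`passes` must contain at least one pass configuration.")
  }
  binary <- binarize(image, threshold, allow_outside = allow_outside)
  for (i in seq_len(nrow(passes))) {
    check_pass(passes$radius_min[i], passes$radius_max[i],
               passes$sensitivity[i], dim(binary$mask))
  }
  # The accumulator depends only on the mask: evaluate candidate profiles
  # once up to the largest searched radius, then apply each pass's radius
  # window and sensitivity to the shared profiles.
  profs <- hough_profiles(binary$mask, max(passes$radius_max), accept_frac)
  per_pass <- purrr::map(seq_len(nrow(passes)), function(i) {
    detections_from_profiles(profs, passes$radius_min[i], passes$radius_max[i],
                             passes$sensitivity[i], accept_frac, i)
  })
  dedupe_detections(list_rbind(per_pass))
}

#' Collapse repeat detections of the same aggregate
#'
#' Two detections are duplicates when their centers are closer than
#' `0.5 * min(R1, R2)` or when at least 60 percent of the smaller disk's area
#' lies inside the larger. Detections are ranked by votes (ties: larger
#' radius, then earlier pass) and kept greedily, so among duplicates the
#' best-supported detection survives. The operation is idempotent.
#'
#' @param detections Tibble of detections as produced by [hough_detect()].
#' @return Tibble of retained detections, sorted by votes descending.
#' @export
dedupe_detections <- function(detections) {
  if (nrow(detections) <= 1) return(detections)
  ord <- order(-detections$votes, -detections$radius_px, detections$pass_index)
  detections <- detections[ord, ]
  keep <- logical(nrow(detections))
  for (i in seq_len(nrow(detections))) {
    dup <- FALSE
    for (j in which(keep)) {
      if (is_duplicate(detections$row[i], detections$col[i], detections$radius_px[i],
                       detections$row[j], detections$col[j], detections$radius_px[j])) {
        dup <- TRUE
        break
      }
    }
    keep[i] <- !dup
  }
  detections[keep, ]
}

is_duplicate <- function(r1, c1, rad1, r2, c2, rad2) {
  d <- sqrt((r1 - r2)^2 + (c1 - c2)^2)
  if (d < 0.5 * min(rad1, rad2)) return(TRUE)
  small <- min(rad1, rad2)
  circle_overlap_area(d, rad1, rad2) >= 0.6 * pi * small^2
}

# Lens area of two intersecting circles at center distance d.
circle_overlap_area <- function(d, r1, r2) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos(pmin(1, pmax(-1, (d^2 + r1^2 - r2^2) / (2 * d * r1))))
  a2 <- r2^2 * acos(pmin(1, pmax(-1, (d^2 + r2^2 - r1^2) / (2 * d * r2))))
  tri <- 0.5 * sqrt(max(0, (-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2)))
  a1 + a2 - tri
}
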