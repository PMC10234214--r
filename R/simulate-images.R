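#' Simulate a brightfield field of dark aggregates with known ground truth
#'
#' Renders `n_aggregates` filled ellipses (dark foreground on a light
#' background, as in transmitted-light images of stem-cell aggregates),
#' optionally Gaussian-blurred and corrupted with additive camera-like noise,
#' and returns both the 8-bit image and a per-aggregate ground-truth table.
#' Ellipse placement uses rejection sampling so that every aggregate lies
#' fully inside the frame and pairs are separated by at least
#' `min_separation_px` between their bounding circles.
#'
#' @param n_aggregates Number of aggregates to place. `0` yields a blank field.
#' @param width_px,height_px Image size in pixels (columns, rows).
#' @param radius_range_px Length-2 numeric, range of semi-major axes in pixels.
#' @param aspect_ratio_range Length-2 numeric `>= 1`, range of semi-major to
#'   semi-minor axis ratios. `c(1, 1)` gives perfect disks.
#' @param foreground,background Aggregate and background intensities on the
#'   8-bit scale; `foreground` must be darker (smaller) than `background`.
#' @param blur_sigma_px Standard deviation of the Gaussian optical blur, in
#'   pixels. `0` disables blurring.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise, in
#'   intensity units. `0` disables noise.
#' @param min_separation_px Minimum gap between the bounding circles of any
#'   two aggregates, in pixels.
#' @param max_attempts Rejection-sampling cap per aggregate; exceeding it is
#'   an error reporting how many aggregates were placed.
#' @param seed Integer seed; identical arguments (including `seed`) reproduce
#'   the image byte for byte. The caller's RNG state is left untouched.
#'
#' @return A list with elements
#'   \describe{
#'     \item{image}{integer matrix (`height_px` rows by `width_px` columns)
#'       of 8-bit intensities, pixel centers at integer (row, col).}
#'     \item{truth}{tibble with one row per aggregate: `id`, `row`, `col`,
#'       `semi_major_px`, `semi_minor_px`, `orientation_rad` and
#'       `true_circularity` (the isoperimetric score of the continuous
#'       ellipse).}
#'   }
#' @examples
#' field <- sim_field(n_aggregates = 3, width_px = 256, height_px = 256,
#'                    radius_range_px = c(15, 30), seed = 1)
#' field$truth
#' @export
sim_field <- function(n_aggregates = 10,
                      width_px = 1024, height_px = 1024,
                      radius_range_px = c(20, 100),
                      aspect_ratio_range = c(1, 1.3),
                      foreground = 60, background = 200,
                      blur_sigma_px = 1.5, noise_sd = 10,
                      min_separation_px = 10,
                      max_attempts = 10000,
                      seed = 1L) {
  stopifnot(length(radius_range_px) == 2, length(aspect_ratio_range) == 2)
  if (foreground >= background) {
    abort("`foreground` must be darker (smaller) than `background`: aggregates are dark on a light field.")
  }
  if (radius_range_px[1] > radius_range_px[2] || radius_range_px[1] <= 0) {
    abort("`radius_range_px` must be positive with min <= max.")
  }
  if (aspect_ratio_range[1] < 1 || aspect_ratio_range[1] > aspect_ratio_range[2]) {
    abort("`aspect_ratio_range` must satisfy 1 <= min <= max.")
  }
  if (blur_sigma_px < 0 || noise_sd < 0) abort("`blur_sigma_px` and `noise_sd` must be non-negative.")

  with_seed(seed, {
    truth <- place_ellipses(n_aggregates, width_px, height_px,
                            radius_range_px, aspect_ratio_range,
                            min_separation_px, max_attempts)
    img <- matrix(as.numeric(background), nrow = height_px, ncol = width_px)
    if (nrow(truth) > 0) {
      for (k in seq_len(nrow(truth))) {
        img <- paint_ellipse(img, truth$row[k], truth$col[k],
                             truth$semi_major_px[k], truth$semi_minor_px[k],
                             truth$orientation_rad[k], foreground)
      }
    }
    if (blur_sigma_px > 0) {
      img <- as.matrix(EBImage::gblur(img, sigma = blur_sigma_px))
    }
    if (noise_sd > 0) {
      img <- img + rnorm(length(img), 0, noise_sd)
    }
    img <- matrix(as.integer(round(pmin(255, pmax(0, img)))),
                  nrow = height_px, ncol = width_px)
    list(image = img, truth = truth)
  })
}

# Rejection-sample ellipse centers/axes; error past `max_attempts` per ellipse.
place_ellipses <- function(n, width, height, radius_range, aspect_range,
                           min_sep, max_attempts) {
  rows <- cols <- a <- b <- theta <- numeric(0)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_attempts)) {
      ak <- runif(1, radius_range[1], radius_range[2])
      ar <- runif(1, aspect_range[1], aspect_range[2])
      bk <- ak / ar
      th <- runif(1, 0, pi)
      if (height - 2 * ak < 2 || width - 2 * ak < 2) next
      r0 <- runif(1, 1 + ak, height - ak)
      c0 <- runif(1, 1 + ak, width - ak)
      ok <- TRUE
      if (k > 1) {
        dd <- sqrt((rows - r0)^2 + (cols - c0)^2)
        ok <- all(dd >= a + ak + min_sep)
      }
      if (ok) {
        rows <- c(rows, r0); cols <- c(cols, c0)
        a <- c(a, ak); b <- c(b, bk); theta <- c(theta, th)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf(
        "Aggregate placement failed: placed %d of %d aggregates before exhausting %d attempts.",
        k - 1L, n, max_attempts))
    }
  }
  tibble(
    id = seq_len(n),
    row = rows, col = cols,
    semi_major_px = a, semi_minor_px = b,
    orientation_rad = theta,
    true_circularity = if (n > 0) {
      mapply(function(aa, bb) {
        isoperimetric_circularity(pi * aa * bb, ellipse_perimeter(aa, bb))
      }, a, b)
    } else numeric(0)
  )
}

# Set pixels whose centers fall inside the rotated ellipse to `value`.
paint_ellipse <- function(img, r0, c0, a, b, theta, value) {
  rr <- max(1, floor(r0 - a)):min(nrow(img), ceiling(r0 + a))
  cc <- max(1, floor(c0 - a)):min(ncol(img), ceiling(c0 + a))
  dr <- outer(rr - r0, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - c0)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  block <- img[rr, cc]
  block[inside] <- value
  img[rr, cc] <- block
  img
}

#' Exact perimeter of an ellipse
#'
#' Computed from the complete elliptic integral of the second kind,
#' `P = 4 a E(e^2)` with eccentricity `e^2 = 1 - (b/a)^2`.
#'
#' @param a,b Semi-major and semi-minor axes (`a >= b > 0`).
#' @return Perimeter in the same units as the axes.
#' @export
ellipse_perimeter <- function(a, b) {
  stopifnot(a >= b, b > 0)
  4 * a * pracma::ellipke(1 - (b / a)^2)$e
}

#' Write / read 8-bit single-channel images
#'
#' `write_gray_png()` stores an integer intensity matrix (0--255) as an 8-bit
#' grayscale PNG; `read_gray_image()` reads a PNG or TIFF back to the same
#' integer-matrix form, refusing multi-channel input.
#'
#' @param image Integer matrix of 8-bit intensities.
#' @param path File path (`.png` for writing; `.png`/`.tif`/`.tiff` for
#'   reading).
#' @return `read_gray_image()` returns an integer matrix; `write_gray_png()`
#'   returns `path` invisibly.
#' @export
write_gray_png <- function(image, path) {
  check_gray_image(image)
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' @rdname write_gray_png
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("Unsupported image format '%s': use PNG or TIFF.", ext))
  )
  if (length(dim(x)) == 3) {
    if (dim(x)[3] == 1) x <- x[, , 1] else {
      abort("Multi-channel image: expected a single-channel 8-bit grayscale image.")
    }
  }
  matrix(as.integer(round(x * 255)), nrow = nrow(x), ncol = ncol(x))
}

check_gray_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("Expected a single-channel image as a numeric matrix.")
  }
  if (any(image < 0 | image > 255, na.rm = TRUE)) {
    abort("Image intensities must lie in the 8-bit range 0-255.")
  }
  invisible(image)
}
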