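#' Read a pipeline configuration from YAML
#'
#' Loads and validates a configuration for [run_morphometry_pipeline()].
#' Recognized fields: `um_per_px` (required, positive), `threshold`
#' (default 0.5), `accept_frac` (default 0.5), and `passes` (list of
#' `radius_min`/`radius_max`/`sensitivity` entries; defaults to
#' [default_hough_passes()]). Unknown fields are an error, so typos fail at
#' startup rather than silently using defaults.
#'
#' @param path Path to a YAML file.
#' @return A named list configuration.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("um_per_px", "threshold", "accept_frac", "passes")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    abort(sprintf("Unknown config fields: %s", paste(extra, collapse = ", ")))
  }
  if (is.null(cfg$um_per_px) || cfg$um_per_px <= 0) {
    abort("Config must set a positive `um_per_px` (microns per pixel).")
  }
  cfg$threshold <- cfg$threshold %||% 0.5
  cfg$accept_frac <- cfg$accept_frac %||% 0.5
  cfg$passes <- if (is.null(cfg$passes)) {
    default_hough_passes()
  } else {
    list_rbind(purrr::map(cfg$passes, as_tibble))
  }
  if (cfg$threshold < 0.4 || cfg$threshold > 0.6) {
    abort("Config `threshold` must lie in [0.4, 0.6].")
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full segmentation-to-summary pipeline over a directory of images
#'
#' For every readable PNG/TIFF image: binarize, run the multi-pass Hough
#' segmentation, measure each detection, and finally summarize the pooled
#' distribution. Unreadable files are skipped with a logged warning; the run
#' fails only if no image can be processed. Identical inputs and
#' configuration reproduce identical outputs.
#'
#' @param image_dir Directory containing `.png`/`.tif`/`.tiff` images (at
#'   least one).
#' @param um_per_px Microns per pixel; required (the imaging scale is not
#'   inferable from the images).
#' @param threshold,passes,accept_frac Segmentation settings, see
#'   [multi_pass_segment()].
#' @return A list with
#'   \describe{
#'     \item{morphometry}{per-aggregate tibble (`image_id` + detection and
#'       measurement columns),}
#'     \item{summary}{one-row distribution summary
#'       ([summarize_distribution()]),}
#'     \item{log}{tibble of per-image events (`image_id`, `status`,
#'       `n_detections`, `message`).}
#'   }
#' @export
run_morphometry_pipeline <- function(image_dir, um_per_px,
                                     threshold = 0.5,
                                     passes = default_hough_passes(),
                                     accept_frac = 0.5) {
  stopifnot(um_per_px > 0)
  paths <- sort(list.files(image_dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(paths) == 0) {
    abort(sprintf("No readable images found in '%s'.", image_dir))
  }
  logs <- list(); morphs <- list()
  for (p in paths) {
    id <- basename(p)
    res <- tryCatch({
      img <- read_gray_image(p)
      det <- multi_pass_segment(img, passes = passes, threshold = threshold,
                                accept_frac = accept_frac)
      binary <- binarize(img, threshold)
      m <- measure_aggregates(det, binary, um_per_px)
      list(ok = TRUE, morph = mutate(m, image_id = id, .before = 1),
           n = nrow(m), msg = "ok")
    }, error = function(e) list(ok = FALSE, morph = NULL, n = 0L,
                                msg = conditionMessage(e)))
    if (!res$ok) warn(sprintf("Skipping '%s': %s", id, res$msg))
    logs[[id]] <- tibble(image_id = id,
                         status = if (res$ok) "ok" else "skipped",
                         n_detections = res$n, message = res$msg)
    if (res$ok) morphs[[id]] <- res$morph
  }
  log_tbl <- list_rbind(logs)
  if (length(morphs) == 0) {
    abort("Pipeline failed: no image could be processed.")
  }
  morph <- list_rbind(morphs)
  summary <- if (nrow(morph) > 0) summarize_distribution(morph) else NULL
  list(morphometry = morph, summary = summary, log = log_tbl)
}

#' Benchmark the segmentation pipeline on seeded synthetic fields
#'
#' Generates `n_images` ground-truthed synthetic fields, segments each with
#' the multi-pass Hough pipeline, matches detections to truth greedily by
#' center distance (a match must fall within half the true radius), and
#' reports detection quality. Unmatched true aggregates count as misses;
#' unmatched detections as false positives.
#'
#' @param n_images Number of synthetic fields (0 yields an empty report).
#' @param seed Base seed; image `i` uses `seed + i`.
#' @param threshold,passes,accept_frac Segmentation settings.
#' @param um_per_px Calibration used for the circularity bias measurement.
#' @param ... Passed to [sim_field()] (e.g. `n_aggregates`, `noise_sd`,
#'   `blur_sigma_px`, `radius_range_px`).
#' @return A list with `report` (one-row tibble: `n_true`, `n_detected`,
#'   `recall`, `precision`, `center_rmse_px`, `radius_rmse_px`,
#'   `circularity_bias`) and `matches` (per-aggregate match table).
#' @export
run_benchmark <- function(n_images = 20, seed = 1L,
                          threshold = 0.5,
                          passes = default_hough_passes(),
                          accept_frac = 0.5, um_per_px = 1, ...) {
  if (n_images == 0) {
    return(list(report = tibble(n_true = 0L, n_detected = 0L,
                                recall = NA_real_, precision = NA_real_,
                                center_rmse_px = NA_real_,
                                radius_rmse_px = NA_real_,
                                circularity_bias = NA_real_),
                matches = tibble()))
  }
  per_image <- purrr::map(seq_len(n_images), function(i) {
    field <- sim_field(seed = seed + i, ...)
    det <- multi_pass_segment(field$image, passes = passes,
                              threshold = threshold, accept_frac = accept_frac)
    binary <- binarize(field$image, threshold)
    det <- measure_aggregates(det, binary, um_per_px)
    match_detections(field$truth, det) %>% mutate(image = i, .before = 1)
  })
  matches <- list_rbind(per_image)
  truths <- filter(matches, !is.na(.data$true_id))
  hits <- filter(truths, .data$matched)
  fp <- filter(matches, is.na(.data$true_id))
  n_det <- nrow(hits) + nrow(fp)
  report <- tibble(
    n_true = nrow(truths),
    n_detected = n_det,
    recall = nrow(hits) / nrow(truths),
    precision = if (n_det > 0) nrow(hits) / n_det else NA_real_,
    center_rmse_px = sqrt(mean(hits$center_err^2)),
    radius_rmse_px = sqrt(mean(hits$radius_err^2)),
    circularity_bias = mean(hits$circ_harmonic - hits$true_circularity,
                            na.rm = TRUE)
  )
  list(report = report, matches = matches)
}

# Greedy nearest-center matching of detections to ground truth; a detection
# may claim at most one truth and must land within 0.5 x the true radius.
match_detections <- function(truth, detections) {
  det_used <- rep(FALSE, nrow(detections))
  rows <- purrr::map(seq_len(nrow(truth)), function(k) {
    res <- tibble(true_id = truth$id[k], matched = FALSE,
                  center_err = NA_real_, radius_err = NA_real_,
                  true_circularity = truth$true_circularity[k],
                  circ_harmonic = NA_real_)
    if (nrow(detections) == 0) return(res)
    d <- sqrt((detections$row - truth$row[k])^2 +
              (detections$col - truth$col[k])^2)
    d[det_used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= 0.5 * truth$semi_major_px[k]) {
      det_used[j] <<- TRUE
      res$matched <- TRUE
      res$center_err <- d[j]
      res$radius_err <- detections$radius_px[j] - truth$semi_major_px[k]
      if ("circ_harmonic" %in% names(detections)) {
        res$circ_harmonic <- detections$circ_harmonic[j]
      }
    }
    res
  })
  out <- list_rbind(rows)
  n_fp <- sum(!det_used)
  if (n_fp > 0) {
    out <- bind_rows(out, tibble(true_id = rep(NA_integer_, n_fp),
                                 matched = FALSE, center_err = NA_real_,
                                 radius_err = NA_real_,
                                 true_circularity = NA_real_,
                                 circ_harmonic = NA_real_))
  }
  out
}

#' Write / read a detections table as CSV
#'
#' Plain-text round trip for detection tables so segmentations can be stored
#' alongside the images they came from.
#'
#' @param detections Detections tibble.
#' @param path CSV path.
#' @return `read_detections()` returns the tibble; `write_detections()`
#'   returns `path` invisibly.
#' @export
write_detections <- function(detections, path) {
  readr::write_csv(detections, path)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
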