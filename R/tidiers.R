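#' Tidy a rheological fit
#'
#' Broom-style one-row-per-parameter summary of an [fit_hb()], [fit_fjm()]
#' or [fit_recovery()] object: estimates, Jacobian-based standard errors and
#' 95 percent confidence intervals.
#'
#' @param x A `rheo_fit` object.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.rheo_fit <- function(x, ...) {
  crit <- if (is.null(x$df) || is.na(x$df) || x$df < 1) {
    stats::qnorm(0.975)
  } else {
    stats::qt(0.975, x$df)
  }
  se <- if (is.null(x$se)) rep(NA_real_, length(x$params)) else x$se
  tibble(
    term = names(x$params),
    estimate = unname(x$params),
    std.error = unname(se),
    conf.low = unname(x$params - crit * se),
    conf.high = unname(x$params + crit * se)
  )
}

#' Glance at a rheological fit
#'
#' @param x A `rheo_fit` object.
#' @param ... Unused.
#' @return One-row tibble: residual sum of squares of the fit's residual
#'   space (log space for the constitutive fits), residual degrees of
#'   freedom, number of observations, convergence flag.
#' @export
glance.rheo_fit <- function(x, ...) {
  tibble(
    rss = x$rss,
    df.residual = if (is.null(x$df)) NA_integer_ else x$df,
    nobs = nrow(x$data),
    converged = isTRUE(x$converged)
  )
}

#' @export
print.rheo_fit <- function(x, ...) {
  cat(sprintf("<%s> parameters:\n", class(x)[1]))
  print(round(x$params, 5))
  cat(sprintf("residual norm %.4g on %s observations\n", x$rss, nrow(x$data)))
  invisible(x)
}

#' Plot a flow-curve fit
#'
#' Data points and fitted thixotropic Herschel-Bulkley curve on log-log
#' axes.
#'
#' @param object An `hb_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hb_fit <- function(object, ...) {
  p <- object$params
  grid <- tibble(
    shear_rate = exp(seq(log(min(object$data$shear_rate)),
                         log(max(object$data$shear_rate)), length.out = 200)))
  grid$stress <- hb_stress(grid$shear_rate, p[1], p[2], p[3], p[4])
  ggplot2::ggplot(object$data, ggplot2::aes(.data$shear_rate, .data$stress)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "shear rate (1/s)", y = "stress (Pa)",
                  title = "Thixotropic Herschel-Bulkley fit")
}

#' Plot a frequency-sweep fit
#'
#' Measured and fitted storage/loss moduli on log-log axes.
#'
#' @param object An `fjm_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fjm_fit <- function(object, ...) {
  long <- function(d, kind) {
    bind_rows(
      tibble(omega = d$omega, modulus = d$g_prime, which = "G'", kind = kind),
      tibble(omega = d$omega, modulus = d$g_double_prime, which = "G''", kind = kind))
  }
  dat <- long(object$data, "data")
  fit <- long(object$fitted, "fit")
  ggplot2::ggplot(dat, ggplot2::aes(.data$omega, .data$modulus,
                                    shape = .data$which)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fit,
                       ggplot2::aes(linetype = .data$which), colour = "firebrick") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "angular frequency (rad/s)", y = "modulus (Pa)",
                  title = "Fractional Jeffrey fit")
}

#' Overlay detections on a brightfield image
#'
#' Draws each detected aggregate as a circle over the image raster; useful
#' for eyeballing segmentation quality.
#'
#' @param image Integer intensity matrix.
#' @param detections Tibble from [multi_pass_segment()].
#' @return A ggplot.
#' @export
plot_detections <- function(image, detections) {
  img_df <- tibble(
    row = rep(seq_len(nrow(image)), times = ncol(image)),
    col = rep(seq_len(ncol(image)), each = nrow(image)),
    intensity = as.vector(image))
  ang <- seq(0, 2 * pi, length.out = 90)
  circles <- detections %>%
    mutate(.id = row_number()) %>%
    purrr::pmap(function(row, col, radius_px, .id, ...) {
      tibble(row = row + radius_px * sin(ang),
             col = col + radius_px * cos(ang), .id = .id)
    }) %>%
    list_rbind()
  ggplot2::ggplot(img_df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_path(data = circles,
                       ggplot2::aes(group = .data$.id), colour = "red") +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}
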