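#' Summarize an aggregate size and shape distribution
#'
#' Median and interquartile range (linear-interpolation, type-7 quantiles) of
#' diameters and circularity, plus the fraction of aggregates at or below the
#' differentiation-friendly 300 um diameter and the fraction at or above
#' circularity 0.73 (both thresholds inclusive).
#'
#' @param morphometry Tibble with columns `diameter_um` and the chosen
#'   circularity column (see [measure_aggregates()]).
#' @param circularity Which score to summarize: the harmonic-mean variant
#'   (`"harmonic"`, the default used for segmentation-based reporting) or
#'   `"isoperimetric"`. Ignored if the table has a plain `circularity`
#'   column.
#' @param diameter_max_um,circ_min Reporting thresholds (defaults 300 um and
#'   0.73).
#' @return One-row tibble: `n`, `median_diameter_um`, `iqr_diameter_um`,
#'   `median_circ`, `iqr_circ`, `frac_diameter_le_300um`,
#'   `frac_circ_ge_0p73`.
#' @export
summarize_distribution <- function(morphometry,
                                   circularity = c("harmonic", "isoperimetric"),
                                   diameter_max_um = 300, circ_min = 0.73) {
  if (nrow(morphometry) == 0) abort("Empty morphometry table: nothing to summarize.")
  circ_col <- if ("circularity" %in% names(morphometry)) {
    "circularity"
  } else {
    paste0("circ_", match.arg(circularity))
  }
  d <- morphometry$diameter_um
  circ <- morphometry[[circ_col]]
  if (is.null(d) || is.null(circ)) abort("Need `diameter_um` and a circularity column.")
  qd <- quantile(d, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  qc <- quantile(circ, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  tibble(
    n = length(d),
    median_diameter_um = qd[2],
    iqr_diameter_um = qd[3] - qd[1],
    median_circ = qc[2],
    iqr_circ = qc[3] - qc[1],
    frac_diameter_le_300um = mean(d <= diameter_max_um, na.rm = TRUE),
    frac_circ_ge_0p73 = mean(circ >= circ_min, na.rm = TRUE)
  )
}

#' Mann-Whitney rank-sum comparison of two distributions
#'
#' Two-sided Mann-Whitney U test with midrank tie handling. For combined
#' sample sizes of at most 20 the p-value is computed by exhaustive
#' enumeration of all group assignments of the pooled values (exact even
#' under ties); larger samples use the normal approximation with tie and
#' continuity corrections. The two-sided exact p-value is the permutation
#' probability of a U at least as far from its null mean `nA nB / 2` as the
#' observed one.
#'
#' @param group_a,group_b Numeric vectors of observations (e.g. diameters of
#'   two culture conditions); both non-empty.
#' @param exact_max Largest combined size for exhaustive enumeration.
#' @return One-row tibble: `u_a` (U statistic of the first group), `u_b`
#'   (`= nA nB - u_a`), `p_value`, `method`.
#' @examples
#' compare_distributions(c(1, 2, 3), c(10, 11, 12))
#' @export
compare_distributions <- function(group_a, group_b, exact_max = 20) {
  n_a <- length(group_a); n_b <- length(group_b)
  if (n_a == 0 || n_b == 0) abort("Both groups must be non-empty.")
  pooled <- c(group_a, group_b)
  u_a <- u_statistic(pooled, seq_len(n_a))
  u_b <- n_a * n_b - u_a
  if (n_a + n_b <= exact_max) {
    idx <- combn(n_a + n_b, n_a)
    u_all <- apply(idx, 2, function(ii) u_statistic(pooled, ii))
    center <- n_a * n_b / 2
    p <- mean(abs(u_all - center) >= abs(u_a - center) - 1e-12)
    method <- "exact enumeration"
  } else {
    p <- mw_normal_p(u_a, n_a, n_b, pooled)
    method <- "normal approximation (tie-corrected)"
  }
  tibble(u_a = u_a, u_b = u_b, p_value = p, method = method)
}

# U of the subset `idx` of `pooled`, via midranks.
u_statistic <- function(pooled, idx) {
  r <- rank(pooled)
  sum(r[idx]) - length(idx) * (length(idx) + 1) / 2
}

mw_normal_p <- function(u, n_a, n_b, pooled) {
  n <- n_a + n_b
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
  z_num <- abs(u - n_a * n_b / 2) - 0.5 # continuity correction
  z <- max(0, z_num) / sqrt(sigma2)
  min(1, 2 * pnorm(z, lower.tail = FALSE))
}

#' Fold expansion from culture records, corrected for sampled volume
#'
#' Computes total viable cells per day as `viable_density * vessel_volume`
#' plus the cells cumulatively removed in earlier sampling events (density at
#' the time of sampling times the volume withdrawn), then reports each day's
#' total relative to day 0. With no sampling and constant volume this is the
#' plain density ratio.
#'
#' @param records Tibble with columns `day`, `viable_density` (cells/mL),
#'   `vessel_volume` (mL) and optionally `sampled_volume` (mL withdrawn at
#'   that day's sampling, after the measurement; default 0) and `viability`.
#'   Must include day 0 with positive density.
#' @return The records tibble with `total_viable` and `fold` columns.
#' @examples
#' fold_expansion(tibble::tibble(
#'   day = c(0, 5), viable_density = c(0.2126e6, 4.89e6),
#'   vessel_volume = 250))
#' @export
fold_expansion <- function(records) {
  req <- c("day", "viable_density", "vessel_volume")
  if (!all(req %in% names(records))) {
    abort(sprintf("`records` needs columns %s.", paste(req, collapse = ", ")))
  }
  if (!0 %in% records$day) abort("Missing day 0 record: fold expansion undefined.")
  records <- arrange(records, .data$day)
  if (records$viable_density[records$day == 0] <= 0) {
    abort("Day 0 viable density must be positive.")
  }
  sampled <- if ("sampled_volume" %in% names(records)) records$sampled_volume else 0
  sampled <- ifelse(is.na(sampled), 0, sampled)
  removed <- cumsum(c(0, head(records$viable_density * sampled, -1)))
  records$total_viable <- records$viable_density * records$vessel_volume + removed
  records$fold <- records$total_viable / records$total_viable[records$day == 0]
  as_tibble(records)
}
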