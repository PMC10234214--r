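# Brute-force oracles kept deliberately independent of the package internals.

# Logical disk mask by per-pixel membership.
disk_mask <- function(n, ctr_row, ctr_col, r) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  (rows - ctr_row)^2 + (cols - ctr_col)^2 <= r^2
}

# Type-7 quantile from the textbook formula, written from scratch.
brute_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Mann-Whitney U of group A by direct pairwise comparison.
brute_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# Exact two-sided p by enumeration of every assignment of the pooled values,
# measuring distance of U from its null mean.
brute_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  center <- na * length(b) / 2
  u_obs <- brute_u(a, b)
  sets <- combn(length(pooled), na)
  u_all <- apply(sets, 2, function(ii) brute_u(pooled[ii], pooled[-ii]))
  mean(abs(u_all - center) >= abs(u_obs - center) - 1e-12)
}

# Brute-force circular Hough accumulator: every pixel a candidate center,
# one vote per foreground pixel whose rounded distance equals the radius.
brute_hough_votes <- function(mask, centers, radius_max) {
  fg <- which(mask, arr.ind = TRUE)
  out <- matrix(0L, nrow(centers), radius_max)
  for (i in seq_len(nrow(centers))) {
    for (k in seq_len(nrow(fg))) {
      d <- sqrt((fg[k, 1] - centers[i, 1])^2 + (fg[k, 2] - centers[i, 2])^2)
      r <- floor(d + 0.5)
      if (r >= 1 && r <= radius_max) out[i, r] <- out[i, r] + 1L
    }
  }
  out
}

# Small clean synthetic field shared by several segmentation tests.
clean_field <- function(radii, n = 420, seed = 1) {
  sim_field(n_aggregates = length(radii), width_px = n, height_px = n,
            radius_range_px = range(radii), aspect_ratio_range = c(1, 1),
            blur_sigma_px = 0, noise_sd = 0, min_separation_px = 12,
            seed = seed)
}
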