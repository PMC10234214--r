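test_that("binarization selects the dark phase and respects its window", {
  light <- matrix(255L, 32, 32)
  expect_equal(sum(binarize(light)$mask), 0)

  f <- clean_field(c(20, 35), seed = 9)
  b <- binarize(f$image, 0.5)
  truth_count <- sum(sapply(seq_len(nrow(f$truth)), function(k) {
    sum(disk_mask(420, f$truth$row[k], f$truth$col[k], f$truth$semi_major_px[k]))
  }))
  expect_equal(sum(b$mask), truth_count)

  # foreground is non-decreasing in the threshold
  noisy <- sim_field(n_aggregates = 3, width_px = 200, height_px = 200,
                     radius_range_px = c(15, 30), noise_sd = 25, seed = 2)$image
  counts <- sapply(c(0.4, 0.45, 0.5, 0.55, 0.6),
                   function(th) sum(binarize(noisy, th)$mask))
  expect_true(all(diff(counts) >= 0))

  expect_error(binarize(light, 0.3), "allow_outside")
  expect_equal(sum(binarize(light, 0.3, allow_outside = TRUE)$mask), 0)
  expect_error(binarize(array(0, c(4, 4, 3))), "matrix")
  expect_error(binarize(matrix(300, 4, 4)), "8-bit")
})

test_that("vote accumulator matches the brute-force oracle and peaks at the true radius", {
  for (r in c(8, 12)) {
    n <- 48
    mask <- disk_mask(n, 24, 24, r)
    centers <- rbind(c(24, 24), c(20, 28), c(10, 10), c(24, 30))
    expect_identical(hough_votes(mask, centers, 20),
                     matrix(brute_hough_votes(mask, centers, 20), 4, 20,
                            dimnames = list(NULL, 1:20)))
  }
  # vote maximality: the accumulator argmax at the true center tracks the
  # true radius to within the annulus quantization (+/- 0.5 px bins plus
  # lattice fluctuation of ring pixel counts, ~1.5 px in all)
  for (r in c(8.49, 12.49, 20.49, 30.49)) {
    n <- ceiling(2 * r) + 16
    ctr <- ceiling(r) + 8
    mask <- disk_mask(n, ctr, ctr, r)
    prof <- hough_votes(mask, rbind(c(ctr, ctr)), ceiling(r) + 6)[1, ]
    expect_lte(abs(which.max(prof) - r), 1.5)
  }
})

test_that("single-pass detection recovers clean disks to pixel accuracy", {
  blank <- binarize(matrix(255L, 420, 420))
  expect_equal(nrow(hough_detect(blank, 20, 200)), 0)

  img <- matrix(200L, 420, 420)
  img[disk_mask(420, 100, 100, 30)] <- 60L
  det <- hough_detect(binarize(img), radius_min = 20, radius_max = 200)
  expect_equal(nrow(det), 1)
  expect_lt(sqrt((det$row - 100)^2 + (det$col - 100)^2), 2)
  expect_lt(abs(det$radius_px - 30), 2)

  img2 <- matrix(200L, 420, 420)
  img2[disk_mask(420, 110, 120, 25)] <- 60L
  img2[disk_mask(420, 300, 290, 60)] <- 60L
  det2 <- hough_detect(binarize(img2), radius_min = 20, radius_max = 200)
  det2 <- det2[order(det2$radius_px), ]
  expect_equal(nrow(det2), 2)
  expect_true(all(abs(det2$radius_px - c(25, 60)) <= 2))
  expect_lt(sqrt((det2$row[1] - 110)^2 + (det2$col[1] - 120)^2), 2)
  expect_lt(sqrt((det2$row[2] - 300)^2 + (det2$col[2] - 290)^2), 2)

  expect_error(hough_detect(blank, 20, 300), "exceeds half")
  expect_error(hough_detect(blank, 50, 40), "radius_min < radius_max")
})

test_that("multi-pass stacking finds every scale once and reduces to a single pass", {
  f <- clean_field(c(25, 45, 95), seed = 31)
  det <- multi_pass_segment(f$image)
  expect_equal(nrow(det), 3)
  for (k in seq_len(3)) {
    d <- sqrt((det$row - f$truth$row[k])^2 + (det$col - f$truth$col[k])^2)
    j <- which.min(d)
    expect_lt(d[j], 2)
    expect_lte(abs(det$radius_px[j] - f$truth$semi_major_px[k]), 3)
  }

  one_pass <- tibble::tibble(radius_min = 20, radius_max = 200,
                             sensitivity = 0.8)
  expect_equal(multi_pass_segment(f$image, passes = one_pass),
               hough_detect(binarize(f$image), 20, 200, 0.8))

  expect_error(multi_pass_segment(f$image, passes = one_pass[0, ]),
               "at least one pass")
})

test_that("duplicate detections collapse to the best-supported circle", {
  two <- tibble::tibble(row = c(100, 100), col = c(100, 100.5),
                        radius_px = c(30, 31), votes = c(150L, 140L),
                        pass_index = c(1L, 2L), sensitivity = c(0.72, 0.76))
  kept <- dedupe_detections(two)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$votes, 150L)

  apart <- tibble::tibble(row = c(100, 300), col = c(100, 300),
                          radius_px = c(30, 40), votes = c(150L, 160L),
                          pass_index = 1L, sensitivity = 0.72)
  expect_equal(nrow(dedupe_detections(apart)), 2)

  # idempotence on a stack of random near-duplicates
  set.seed(14)
  stack <- tibble::tibble(
    row = rep(c(80, 200), each = 6) + runif(12, -3, 3),
    col = rep(c(90, 210), each = 6) + runif(12, -3, 3),
    radius_px = rep(c(30, 50), each = 6) + sample(-2:2, 12, TRUE),
    votes = as.integer(sample(100:200, 12)),
    pass_index = rep(1:6, 2), sensitivity = 0.8)
  once <- dedupe_detections(stack)
  expect_identical(dedupe_detections(once), once)
  expect_equal(nrow(once), 2)
})

test_that("detections translate with the image", {
  img <- matrix(200L, 420, 420)
  img[disk_mask(420, 120, 140, 30)] <- 60L
  img[disk_mask(420, 290, 270, 55)] <- 60L
  det <- multi_pass_segment(img)
  dr <- 7; dc <- -5
  shifted <- matrix(200L, 420, 420)
  shifted[(1 + dr):420, 1:(420 + dc)] <- img[1:(420 - dr), (1 - dc):420]
  det2 <- multi_pass_segment(shifted)
  expect_equal(nrow(det2), nrow(det))
  ord1 <- order(det$radius_px); ord2 <- order(det2$radius_px)
  expect_equal(det2$row[ord2], det$row[ord1] + dr, tolerance = 1e-8)
  expect_equal(det2$col[ord2], det$col[ord1] + dc, tolerance = 1e-8)
  expect_equal(det2$radius_px[ord2], det$radius_px[ord1])
})
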