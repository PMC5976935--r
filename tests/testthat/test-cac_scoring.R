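test_that("background normalization recovers a planted uniform offset", {
  # offsets below -24 HU saturate at the -1024 HU scanner floor, so the
  # planted value is only recoverable exactly above that
  for (off in c(-24, -10, 0, 15, 42)) {
    ph <- quick_phantom(seed = 41, background_offset = off)
    nb <- normalize_background(ph$volume)
    expect_equal(nb$offset, off)
    # oracle: median over the known painted air mask is restored to -1000
    air <- nb$volume$voxels[ph$labels == 0L]
    expect_equal(median(air), -1000)
  }
})

test_that("normalization refuses images without air background", {
  solid <- ct_volume(matrix(40, 32, 32), c(1, 1))
  expect_error(normalize_background(solid), "skip normalization")
})

test_that("calcified pixel count matches painted plaque enumeration", {
  ph <- quick_phantom(seed = 42)
  k <- count_calcified_pixels(ph$volume, ph$truth$heart_center,
                              ph$truth$heart_radius)
  expect_identical(k, ph$truth$calcified_pixel_count)
  # threshold above the maximum plaque HU -> zero (monotone endpoint)
  expect_identical(
    count_calcified_pixels(ph$volume, ph$truth$heart_center,
                           ph$truth$heart_radius, threshold = 3000), 0L)
  # count is monotone nonincreasing in the threshold
  counts <- vapply(c(-1000, 0, 130, 300, 600, 900), function(th)
    count_calcified_pixels(ph$volume, ph$truth$heart_center,
                           ph$truth$heart_radius, threshold = th),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("an ROI leaving the grid is a hard error", {
  ph <- quick_phantom(seed = 43)
  expect_error(count_calcified_pixels(ph$volume, c(5, 5), 20),
               "outside")
})

test_that("cutpoint calibration matches the midpoint oracle", {
  cp <- calibrate_cutpoints(c(0, 0, 10, 10, 100, 100, 1000, 1000),
                            c(0, 0, 1, 1, 2, 2, 3, 3))
  expect_equal(unlist(cp), c(c1 = 5, c2 = 55, c3 = 550))
})

test_that("separable calibration re-grades every training case", {
  set.seed(44)
  for (rep in 1:5) {
    # counts drawn from four well-separated bands
    n_per <- sample(2:6, 4, replace = TRUE)
    counts <- unlist(lapply(1:4, function(g)
      sample((g - 1) * 1000 + 0:200, n_per[g])))
    grades <- rep(0:3, n_per)
    ord <- sample(seq_along(counts))
    cp <- calibrate_cutpoints(counts[ord], grades[ord])
    expect_identical(assign_grade(counts[ord], cp), grades[ord])
  }
})

test_that("degenerate references are rejected", {
  expect_error(calibrate_cutpoints(c(1, 2, 3), c(0, 0, 0)), "one grade")
  expect_error(calibrate_cutpoints(c(1, 2, 3), c(0, 1, 3)), "missing")
  expect_error(calibrate_cutpoints(1:3, c(0, 1)), "equal length")
  # tied counts across every boundary cannot be separated
  expect_error(calibrate_cutpoints(rep(5, 8), c(0, 0, 1, 1, 2, 2, 3, 3)),
               "not separable")
})

test_that("grade assignment uses the inclusive-upward boundary rule", {
  cp <- grade_cutpoints(5, 55, 550)
  expect_identical(assign_grade(0, cp), 0L)
  expect_identical(assign_grade(55, cp), 2L)   # count == c2 -> grade 2
  expect_identical(assign_grade(5, cp), 1L)
  expect_identical(assign_grade(1e6, cp), 3L)
  # exhaustive sweep: nondecreasing and hits all four grades
  sweep_g <- assign_grade(0:600, cp)
  expect_true(all(diff(sweep_g) >= 0))
  expect_identical(sort(unique(sweep_g)), 0:3)
})

test_that("cutpoints must be strictly increasing", {
  expect_error(grade_cutpoints(5, 5, 10), "c1 < c2 < c3")
  expect_error(grade_cutpoints(-1, 5, 10), "c1 < c2 < c3")
})

test_that("grade agreement is squared Pearson correlation", {
  expect_equal(grade_agreement(c(0, 1, 2, 3), c(0, 1, 2, 3)), 1)
  expect_equal(grade_agreement(c(0, 1, 2, 3), c(3, 2, 1, 0)), 1)
  a <- c(0, 1, 2, 3); b <- c(0, 1, 1, 3)
  # oracle: direct Pearson formula evaluation
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(grade_agreement(a, b), r^2)
  expect_error(grade_agreement(c(1, 1, 1), c(0, 1, 2)), "zero variance")
  expect_error(grade_agreement(c(1, 2), c(0, 1)), "at least 3")
})

test_that("cac_score composes normalization, counting and grading", {
  ph <- quick_phantom(seed = 45, background_offset = 20)
  cp <- grade_cutpoints(5, 30, 60)
  res <- cac_score(ph$volume, ph$truth$heart_center,
                   ph$truth$heart_radius, cutpoints = cp)
  expect_s3_class(res, "cac_result")
  expect_equal(res$normalization_offset, 20)
  expect_identical(res$pixel_count, ph$truth$calcified_pixel_count)
  expect_identical(res$grade,
                   assign_grade(ph$truth$calcified_pixel_count, cp))
  expect_equal(res$grade_label,
               unname(cac_grade_labels()[as.character(res$grade)]))
})

test_that("counts are invariant to uniform offsets after normalization", {
  base <- quick_phantom(seed = 46)$truth$calcified_pixel_count
  for (off in seq(-50, 50, by = 20)) {
    ph <- quick_phantom(seed = 46, background_offset = off)
    nb <- normalize_background(ph$volume)
    expect_identical(
      count_calcified_pixels(nb$volume, ph$truth$heart_center,
                             ph$truth$heart_radius), base)
  }
})
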