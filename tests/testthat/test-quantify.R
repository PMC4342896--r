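make_spot_rows <- function(marker, type, intensity, conc = NA_real_,
                           sample_id = NA_character_) {
  k <- length(intensity)
  data.frame(marker = rep(marker, k), content_type = rep(type, k),
             sample_id = rep(sample_id, length.out = k),
             class_label = rep(NA_character_, k),
             replicate_index = seq_len(k),
             nominal_concentration = rep(conc, length.out = k),
             intensity = intensity, stringsAsFactors = FALSE)
}

test_that("blank_level averages BSA spots and refuses silent fallback", {
  tab <- make_spot_rows("m", "blank", c(10, 12, 8))
  expect_equal(blank_level(tab, "m"), 10)
  expect_equal(blank_level(make_spot_rows("m", "blank", 0), "m"), 0)
  expect_error(blank_level(tab, "other"), "no blank spots")
  expect_equal(blank_level(tab, "other", fallback_zero = TRUE), 0)
})

test_that("replicate aggregation reports mean and replicate CV", {
  expect_equal(aggregate_replicates(c(5, 5, 5, 5)),
               list(mean = 5, scv_percent = 0))
  a <- aggregate_replicates(c(90, 100, 110, 100))
  expect_equal(a$mean, 100)
  expect_equal(a$scv_percent, 8.165, tolerance = 1e-4)
  expect_equal(aggregate_replicates(c(1, 1)), list(mean = 1, scv_percent = 0))
  # undefined cases flagged missing, not invented
  expect_true(is.na(aggregate_replicates(5)$scv_percent))
  expect_true(is.na(aggregate_replicates(c(0, 0, 0))$scv_percent))
  # scale invariance of the CV
  x <- c(3, 4, 5, 6)
  expect_equal(aggregate_replicates(x * 17)$scv_percent,
               aggregate_replicates(x)$scv_percent)
})

test_that("standard-curve fit matches the normal-equations oracle", {
  # exact line
  conc <- c(0, 0.25, 0.5, 0.75, 1)
  cv <- fit_standard_curve(conc, 2 * conc + 1, "m")
  expect_equal(cv$slope, 2)
  expect_equal(cv$intercept, 1)
  expect_equal(cv$r_squared, 1)
  # fixture with scatter
  y <- c(1, 1.4, 2.1, 2.4, 3.1)
  cv2 <- fit_standard_curve(conc, y, "m")
  beta <- unname(ols_oracle(conc, y))
  expect_equal(cv2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(cv2$slope, beta[2], tolerance = 1e-10)
  # random fixtures
  set.seed(31)
  for (i in 1:20) {
    x <- runif(6); yy <- rnorm(6, 2 + 3 * x, 0.2)
    f <- fit_standard_curve(x, yy)
    b <- ols_oracle(x, yy)
    expect_equal(c(f$intercept, f$slope), unname(b), tolerance = 1e-10)
  }
  # degenerate cases
  expect_error(fit_standard_curve(rep(0.5, 4), 1:4), "singular")
  flat <- fit_standard_curve(conc, rep(7, 5))
  expect_false(flat$usable)
})

test_that("calibration inverts the curve, clamps below background", {
  curve <- fit_standard_curve(c(0, 0.5, 1), c(1, 2, 3), "m") # y = 2x + 1
  expect_equal(as.numeric(calibrate(1, curve)), 0)
  for (x in c(0.1, 0.5, 0.9))
    expect_equal(as.numeric(calibrate(curve$slope * x + curve$intercept, curve)), x)
  low <- calibrate(0.5, curve)
  expect_equal(as.numeric(low), 0)
  expect_true(attr(low, "below_background"))
  # affine in intensity with slope 1/curve.slope
  a1 <- as.numeric(calibrate(10, curve)); a2 <- as.numeric(calibrate(11, curve))
  expect_equal(a2 - a1, 1 / curve$slope)
  bad <- fit_standard_curve(c(0, 0.5, 1), c(3, 2, 1), "m")
  expect_error(calibrate(1, bad), "unusable")
})

test_that("noiseless simulate -> quantify round trip recovers expressions", {
  spec <- cohort_spec(reference_groups(c("CTR", "ComplexI")), seed = 21)
  expr <- simulate_cohort(spec, markers = c("bF1", "GAPDH", "PYGM"))
  tab <- simulate_spot_table(expr, array_layout(technical_cv_percent = 0, seed = 1))
  q <- quantify_table(tab)
  rec <- as_expression_matrix(q)
  rec <- rec[match(expr$sample_id, rec$sample_id), ]
  for (m in c("bF1", "GAPDH", "PYGM"))
    expect_equal(rec[[m]], expr[[m]], tolerance = 1e-9)
})

test_that("quantify_table handles empty input and reports array CV", {
  empty <- quantify_table(make_spot_rows("m", "sample", numeric(0)))
  expect_equal(nrow(empty$samples), 0L)
  spec <- cohort_spec(reference_groups(c("CTR", "DMD")), seed = 8)
  expr <- simulate_cohort(spec, markers = c("bF1", "LDHA"))
  tab <- simulate_spot_table(expr, array_layout(technical_cv_percent = 8.6, seed = 3))
  q <- quantify_table(tab)
  expect_true(q$array_scv_percent > 4 && q$array_scv_percent < 13)
  expect_equal(nrow(q$samples), nrow(expr) * 2)
})
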