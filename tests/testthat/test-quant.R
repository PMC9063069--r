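# Standard-curve quantification and triplicate QC.

perfect_curve <- function(slope = -3.321928, intercept = 30) {
  fit_standard_curve(tibble::tibble(
    quantity_ng = c(10, 1, 0.1),
    cq = intercept + slope * log10(c(10, 1, 0.1))
  ))
}

test_that("standard curve recovers perfect doubling chemistry", {
  cv <- perfect_curve()
  expect_s3_class(cv, "standard_curve")
  expect_equal(cv$slope, -3.321928, tolerance = 1e-9)
  expect_equal(cv$intercept, 30, tolerance = 1e-9)
  expect_equal(cv$efficiency, 100, tolerance = 1e-4)
  expect_equal(cv$r_squared, 1, tolerance = 1e-9)
})

test_that("noiseless fits over the reference dilution series are exact", {
  for (slope in c(-3.45, -3.1, -3.6)) {
    std <- simulate_dilution_series(slope, 30, noise_sd = 0)
    cv <- if (slope == -3.1) {
      expect_warning(fit_standard_curve(std), "efficiency")
      suppressWarnings(fit_standard_curve(std))
    } else {
      fit_standard_curve(std)
    }
    expect_equal(cv$slope, slope, tolerance = 1e-9)
    expect_equal(cv$intercept, 30, tolerance = 1e-9)
  }
  # efficiency at slope -3.10 by independent arithmetic
  cv <- suppressWarnings(
    fit_standard_curve(simulate_dilution_series(-3.10, 30, noise_sd = 0))
  )
  expect_equal(cv$efficiency, (10^(1 / 3.10) - 1) * 100, tolerance = 1e-9)
  expect_gt(cv$efficiency, 110)
})

test_that("degenerate standard input is rejected", {
  expect_error(
    fit_standard_curve(tibble::tibble(quantity_ng = c(1, 1), cq = c(30, 30.1))),
    "distinct"
  )
  expect_error(
    fit_standard_curve(tibble::tibble(quantity_ng = c(1, 10, 100),
                                      cq = c(30, 33, 36))),
    "slope"
  )
  expect_error(
    fit_standard_curve(tibble::tibble(quantity_ng = c(-1, 1), cq = c(30, 28))),
    "positive"
  )
})

test_that("quantity interpolation inverts the curve", {
  cv <- perfect_curve()
  expect_equal(interpolate_quantity(30, cv), 1.0, tolerance = 1e-12)
  expect_equal(interpolate_quantity(30 - 3.321928, cv), 10.0, tolerance = 1e-9)
  expect_equal(interpolate_quantity(28, cv), 4.0, tolerance = 1e-6)
  expect_warning(interpolate_quantity(10, cv), "outside the standard range")
})

test_that("Dixon's Q matches hand-computed examples", {
  qc <- dixon_q_test(c(1.0, 1.02, 2.5))
  expect_equal(qc$q_statistic, 1.48 / 1.50, tolerance = 1e-9)
  expect_equal(qc$removed_index, 3L)
  expect_equal(qc$kept_mean, 1.01, tolerance = 1e-9)

  qc <- dixon_q_test(c(1.0, 1.0, 1.0))
  expect_true(is.na(qc$removed_index))
  expect_equal(qc$kept_mean, 1.0)

  qc <- dixon_q_test(c(1.0, 1.1, 1.25))
  expect_equal(qc$q_statistic, 0.6, tolerance = 1e-9)
  expect_true(is.na(qc$removed_index))
  expect_equal(qc$kept_mean, mean(c(1.0, 1.1, 1.25)), tolerance = 1e-9)

  expect_error(dixon_q_test(c(1, 2, NA)), "finite")
  expect_error(dixon_q_test(c(1, 2)), "finite|3")
  expect_error(dixon_q_test(c(1, 2, 3), alpha = 0.2), "alpha")
})

test_that("at most one well is ever removed and alpha changes the cut", {
  set.seed(41)
  for (i in 1:200) {
    v <- rnorm(3, 1, runif(1, 0.001, 1))
    qc <- dixon_q_test(abs(v) + 0.01)
    expect_lte(length(qc$values) - length(qc$kept), 1)
    expect_equal(qc$kept_mean, mean(qc$kept))
  }
  # Q between the 0.10 and 0.05 critical values: removed only at alpha 0.10.
  v <- c(1.0, 1.005, 1.1)  # Q = 0.095/0.1 = 0.95
  expect_true(is.na(dixon_q_test(v, alpha = 0.05)$removed_index))
  expect_equal(dixon_q_test(v, alpha = 0.10)$removed_index, 3L)
})

test_that("sample quantification is symmetric, exact, and outlier-robust", {
  cv_t <- perfect_curve()
  cv_s <- perfect_curve(intercept = 28)
  cq_of <- function(q, cv) cv$intercept + cv$slope * log10(q)

  # identical quantities on both targets -> T/S = 1
  q3 <- c(5, 5.2, 4.9)
  r <- quantify_sample(cq_of(q3, cv_t), cq_of(q3, cv_s), cv_t, cv_s)
  expect_equal(r$raw_ts, 1.0, tolerance = 1e-9)

  # planted ratio 1.15, no noise -> exact
  r <- quantify_sample(cq_of(q3 * 1.15, cv_t), cq_of(q3, cv_s), cv_t, cv_s)
  expect_equal(r$raw_ts, 1.15, tolerance = 1e-9)

  # one 8-cycle outlier removed by QC -> same value as the clean pair
  clean <- quantify_sample(cq_of(c(5, 5, 5) * 1.15, cv_t), cq_of(q3, cv_s),
                           cv_t, cv_s)
  dirty_cq <- cq_of(c(5, 5, 5) * 1.15, cv_t) + c(0, 0, 8)
  dirty <- suppressWarnings(
    quantify_sample(dirty_cq, cq_of(q3, cv_s), cv_t, cv_s)
  )
  expect_equal(dirty$s_quantity, clean$s_quantity, tolerance = 1e-9)
  expect_equal(dirty$raw_ts, clean$raw_ts, tolerance = 1e-9)
  expect_equal(dirty$t_removed, 3L)

  # a low-quantity outlier is still caught when the good wells are noisy
  # (the test runs on the Cq scale, symmetric in displacement direction)
  noisy_t <- cq_of(c(5.0, 5.2, 5.1) * 1.15, cv_t)
  for (shift in c(-8, 5, 8)) {
    dirty2 <- suppressWarnings(
      quantify_sample(noisy_t + c(shift, 0, 0), cq_of(q3, cv_s), cv_t, cv_s)
    )
    expect_equal(dirty2$t_removed, 1L)
    expect_equal(dirty2$t_quantity,
                 mean(interpolate_quantity(noisy_t[2:3], cv_t)),
                 tolerance = 1e-9)
  }
})

test_that("T/S obeys the scale invariances", {
  cv_t <- perfect_curve()
  cv_s <- perfect_curve(intercept = 28)
  cq_of <- function(q, cv) cv$intercept + cv$slope * log10(q)
  qt <- c(6.1, 6.4, 5.9)
  qs <- c(5.0, 5.3, 5.1)
  base <- quantify_sample(cq_of(qt, cv_t), cq_of(qs, cv_s), cv_t, cv_s)
  for (c_mult in c(0.5, 2, 3.7)) {
    t_scaled <- suppressWarnings(
      quantify_sample(cq_of(qt * c_mult, cv_t), cq_of(qs, cv_s), cv_t, cv_s)
    )
    expect_equal(t_scaled$raw_ts, base$raw_ts * c_mult, tolerance = 1e-9)
    both <- suppressWarnings(
      quantify_sample(cq_of(qt * c_mult, cv_t), cq_of(qs * c_mult, cv_s),
                      cv_t, cv_s)
    )
    expect_equal(both$raw_ts, base$raw_ts, tolerance = 1e-9)
  }
})

test_that("plate-level quantification fits per-run curves and errors cleanly", {
  cfg <- sim_config(n_subjects = 6, cq_noise_sd = 0, outlier_rate = 0,
                    batch_drift_sd = 0, residual_log_sd = 0, seed = 3)
  sim <- simulate_cohort(cfg)
  samples <- sim$truth$draws[, c("sample_id", "true_ts")]
  run <- simulate_plate_run(cfg, 1, samples)
  q <- quantify_plates(run$plate)
  curves <- attr(q, "curves")
  expect_setequal(curves$target, c("T", "S"))
  expect_equal(curves$efficiency[curves$target == "T"], 93.2, tolerance = 1e-6)
  expect_equal(curves$efficiency[curves$target == "S"], 94.0, tolerance = 1e-6)
  # noiseless: recovered raw T/S equals planted truth x run multiplier (= 1)
  got <- q[match(samples$sample_id, q$sample_id), ]
  expect_equal(got$raw_ts, samples$true_ts, tolerance = 1e-9)
})
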