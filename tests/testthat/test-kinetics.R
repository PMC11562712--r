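test_that("a flat sorption control leaves the TEST series unchanged", {
  test <- make_series(0.5, reps = 3)
  sc <- make_series(0, reps = 2, vessel = "SC")
  out <- correct_for_sc(test, sc)
  expect_equal(out$series$area, test$area, tolerance = 1e-12)
  expect_identical(out$status, "ok")
})

test_that("SC division removes the abiotic rate exactly on exponentials", {
  test <- make_series(0.6, reps = 3)                 # k_total = 0.6/d
  sc <- make_series(0.1, reps = 2, vessel = "SC")    # abiotic = 0.1/d
  corr <- correct_for_sc(test, sc)$series
  est <- fit_pooled_loglinear(corr)
  expect_equal(est$k_observed, 0.5, tolerance = 1e-10)
})

test_that("SC correction at interpolated times matches a brute-force refit", {
  # SC sampled on a coarser grid than TEST: the log-linear interpolation of
  # the SC relative curve must reproduce the exact division of exponentials
  k_test <- 0.5; k_sc <- 0.2  # SC dissipation 2.5x slower than TEST
  test <- make_series(k_test, reps = 3)
  sc <- make_series(k_sc, times = c(0, 1, 4, 10), reps = 2, vessel = "SC")
  corr <- correct_for_sc(test, sc)$series
  est <- fit_pooled_loglinear(corr)
  # brute-force oracle: refit the analytically corrected areas
  oracle <- test
  oracle$area <- test$area / exp(-k_sc * test$time_days)
  est_o <- fit_pooled_loglinear(oracle)
  expect_equal(est$k_observed, est_o$k_observed, tolerance = 1e-10)
  expect_equal(est$k_observed, k_test - k_sc, tolerance = 1e-10)
})

test_that("noiseless pooled fit is exact with full point count", {
  est <- fit_pooled_loglinear(make_series(0.5, a0 = 1000, reps = 3))
  expect_equal(est$k_observed, 0.5, tolerance = 1e-12)
  expect_equal(est$n_points, 30L)
  expect_lt(est$p_value, 1e-12)
  expect_true(est$valid)
  expect_identical(est$reason_invalid, "none")
})

test_that("estimates resting on four points are flagged too_few_points", {
  d <- make_series(0.5, times = c(0, 1, 2, 4))
  est <- fit_pooled_loglinear(add_noise(d, 0.05, seed = 1))
  expect_false(est$valid)
  expect_identical(est$reason_invalid, "too_few_points")
  expect_identical(est$status, "ok")  # an estimate still exists
})

test_that("fewer than two uncensored points yields not_available", {
  d <- make_series(2, times = c(0, 4, 7, 10), loq = 1e5)  # only t=0 above
  est <- fit_pooled_loglinear(d)
  expect_identical(est$status, "not_available")
  expect_true(is.na(est$k_observed))
})

test_that("a significant positive slope is invalid, not 'valid growth'", {
  d <- make_series(-0.3, reps = 3)  # areas increase
  est <- fit_pooled_loglinear(add_noise(d, 0.02, seed = 2))
  expect_false(est$valid)
  expect_identical(est$reason_invalid, "not_significant")
})

test_that("pooled fit matches an independent normal-equations regression", {
  d <- add_noise(make_series(0.4, reps = 3), 0.10, seed = 31)
  est <- fit_pooled_loglinear(d)
  # oracle: hand-written normal equations on the same points
  use <- d[!d$censored & d$area > 0, ]
  x <- use$time_days; y <- log(use$area); n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  resid <- y - mean(y) - slope * (x - mean(x))
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  expect_equal(est$k_observed, -slope, tolerance = 1e-10)
  expect_equal(est$se, se, tolerance = 1e-10)
  expect_true(-slope > est$ci95_lo && -slope < est$ci95_hi)
})

test_that("confidence intervals nest: the 99% CI contains the 95% CI", {
  d <- add_noise(make_series(0.4, reps = 3), 0.10, seed = 7)
  est <- fit_pooled_loglinear(d)
  expect_lt(est$ci99_lo, est$ci95_lo)
  expect_gt(est$ci99_hi, est$ci95_hi)
})

test_that("raising the LOQ never increases the number of points used", {
  d <- add_noise(make_series(0.8, reps = 3), 0.09, seed = 5)
  n_pts <- vapply(c(0, 1e2, 1e3, 1e4, 1e5), function(loq) {
    dd <- d
    dd$censored <- dd$area < loq
    fit_pooled_loglinear(dd)$n_points
  }, integer(1))
  expect_true(all(diff(n_pts) <= 0))
})

test_that("noiseless simulated cells are recovered to 6+ significant digits", {
  env <- simulate_site_env(n_per_country = c(SE = 2, DE = 1), seed = 8)
  cmps <- lapply(c(-1, -0.3, 0.3), function(m) {
    true_compound(paste0("N", m), m, noise_rsd = 0)
  })
  cmps <- c(cmps, list(true_compound("BI", NA, noise_rsd = 0,
    biphasic = list(k_initial = 1, k_late = 0.05, break_time = 2))))
  ex <- generate_experiment(study_design(seed = 8), cmps, site_model(env))
  fits <- fit_rates(ex$areas)
  m <- merge(fits$rates, ex$truth_cells, by = c("site", "compound"))
  ok <- m$status == "ok"
  expect_true(all(abs(m$k_observed[ok] / m$k_true[ok] - 1) < 1e-6))
})

test_that("replicate fits agree with the pooled estimate in log space", {
  ex <- small_experiment()
  fits <- fit_rates(ex$areas)
  pooled <- fits$rates
  for (i in seq_len(nrow(pooled))) {
    if (!isTRUE(pooled$valid[i])) next
    rr <- fits$replicate_rates[
      fits$replicate_rates$site == pooled$site[i] &
        fits$replicate_rates$compound == pooled$compound[i], ]
    kk <- rr$k_observed[is.finite(rr$k_observed) & rr$k_observed > 0]
    if (length(kk) < 2L) next
    mean_log <- 10^mean(log10(kk))
    expect_lt(abs(mean_log - pooled$k_observed[i]), 2 * pooled$se[i])
  }
})

test_that("an entirely censored sorption control is skipped with a warning", {
  test <- make_series(0.5, reps = 3)
  sc <- make_series(0.1, reps = 2, vessel = "SC", loq = Inf)
  expect_warning(out <- correct_for_sc(test, sc), "censored")
  expect_identical(out$status, "sc_censored")
  expect_equal(out$series$area, test$area)
})
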