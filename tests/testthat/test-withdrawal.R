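test_that("depletion dataset: counting, strict LOQ boundary, insufficiency", {
  ml <- exact_milk_series(8, times = c(1, 2, 4, 6, 8, 12))
  ds <- build_depletion_dataset(ml, 0, loq = 0.9, mrl = 0.4)
  expect_equal(nrow(ds$records), 48) # 8 animals x 6 post-peak quantifiable

  # a value exactly at the LOQ is excluded ("greater than" is strict)
  s <- list(conc_series("a", "OH5", "milk", c(1, 2, 4), c(10, 5, 0.9)),
            conc_series("b", "OH5", "milk", c(1, 2, 4), c(10, 5, 2)))
  ds2 <- build_depletion_dataset(s, 0, loq = 0.9, mrl = 0.4)
  expect_equal(nrow(ds2$records), 5)
  expect_equal(ds2$excluded$at_or_below_loq, 1)

  below <- lapply(exact_milk_series(3, c0 = 0.5), identity)
  expect_error(build_depletion_dataset(below, 0, loq = 0.9, mrl = 0.4),
               class = "milkwdi_insufficient_data")
})

test_that("exact log-linear data give the analytic regression with zero residual", {
  ml <- exact_milk_series(2)
  ds <- build_depletion_dataset(ml, 0, loq = 0.9, mrl = 0.4)
  fit <- fit_depletion_regression(ds)
  expect_equal(fit$intercept, log(100), tolerance = 1e-10)
  expect_equal(fit$slope, -0.1155, tolerance = 1e-10)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-10)
})

test_that("pooled regression slope is unbiased over repeated simulations", {
  set.seed(77)
  slopes <- replicate(2000, {
    rec <- simulate_depletion_records(n_animals = 6,
                                      times = c(2, 6, 12, 24, 36, 48, 60, 72,
                                                84, 96), sigma = 0.15)
    fit_depletion_regression(rec)$slope
  })
  expect_equal(mean(slopes), -0.1155, tolerance = 0.01)
})

test_that("curved (biexponential) depletion is flagged by the lack-of-fit test", {
  times <- c(1, 2, 4, 8, 16, 24, 36, 48)
  set.seed(13)
  rec <- do.call(rbind, lapply(1:6, function(i) {
    cc <- 400 * exp(-0.4 * times) + 40 * exp(-0.05 * times)
    data.frame(animal_id = sprintf("g%d", i), time_h = times,
               log_conc = log(cc) + rnorm(length(times), 0, 0.02))
  }))
  fit <- fit_depletion_regression(rec)
  expect_lt(fit$lack_of_fit_p, 0.05)
})

test_that("non-negative or non-significant slopes are not calculable", {
  set.seed(3)
  flat <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(animal_id = sprintf("g%d", i), time_h = c(2, 6, 12, 24),
               log_conc = rnorm(4, 3, 0.3))
  }))
  expect_error(fit_depletion_regression(flat), class = "milkwdi_slope_failure")
})

test_that("tolerance limit collapses to the mean line at zero residual SD", {
  ds <- build_depletion_dataset(exact_milk_series(2), 0, loq = 0.9, mrl = 0.4)
  fit <- fit_depletion_regression(ds)
  x <- c(0, 10, 30, 47.8)
  expect_equal(tolerance_limit(fit, x, 0.95, 0.95),
               fit$intercept + fit$slope * x, tolerance = 1e-9)
  expect_equal(tolerance_limit(fit, x, 0.99, 0.99),
               fit$intercept + fit$slope * x, tolerance = 1e-9)
})

test_that("tolerance limit approaches mean + 1.6449 s for large n at the mean time", {
  set.seed(6)
  rec <- simulate_depletion_records(n_animals = 400,
                                    times = c(2, 6, 12, 24, 36), sigma = 0.3)
  fit <- fit_depletion_regression(rec)
  tl <- tolerance_limit(fit, fit$t_mean, p = 0.95, gamma = 0.95)
  mean_line <- fit$intercept + fit$slope * fit$t_mean
  expect_equal(tl - mean_line, qnorm(0.95) * fit$residual_sd, tolerance = 0.05)
})

test_that("tolerance limit sits above the mean line and grows with the percentile", {
  set.seed(41)
  rec <- simulate_depletion_records()
  fit <- fit_depletion_regression(rec)
  x <- seq(0, 80, by = 5)
  mean_line <- fit$intercept + fit$slope * x
  expect_true(all(tolerance_limit(fit, x, 0.95, 0.95) >= mean_line))
  w95 <- withdrawal_time(fit, 0.4, p = 0.95, gamma = 0.95)
  w99 <- withdrawal_time(fit, 0.4, p = 0.99, gamma = 0.95)
  expect_gt(w99, w95)
})

test_that("withdrawal time: analytic crossing, zero case, monotonicity in MRL", {
  ds <- build_depletion_dataset(exact_milk_series(2), 0, loq = 0.9, mrl = 0.4)
  fit <- fit_depletion_regression(ds)
  expect_equal(withdrawal_time(fit, 0.4), log(100 / 0.4) / 0.1155,
               tolerance = 1e-6)
  expect_equal(withdrawal_time(fit, 200), 0) # limit above the whole curve
  expect_lt(withdrawal_time(fit, 1), withdrawal_time(fit, 0.4))
})

test_that("base invariance: the log10-scaled problem yields the same crossing", {
  set.seed(19)
  rec <- simulate_depletion_records()
  fit_ln <- fit_depletion_regression(rec)
  rec10 <- rec
  rec10$log_conc <- rec$log_conc / log(10)
  fit10 <- fit_depletion_regression(rec10)
  w_ln <- withdrawal_time(fit_ln, 0.4)
  # crossing of the log10 tolerance limit against log10(mrl)
  tl10 <- function(x) tolerance_limit(fit10, x, 0.95, 0.95) - log10(0.4)
  w_10 <- uniroot(tl10, c(w_ln - 20, w_ln + 20), tol = 1e-12)$root
  expect_equal(w_ln, w_10, tolerance = 1e-9)
})

test_that("outlier screen flags a grossly deviant animal and only that one", {
  ml <- exact_milk_series(6)
  ml[[6]] <- conc_series("goat06", "OH5", "milk", ml[[6]]$time_h,
                         ml[[6]]$conc_ng_ml * 20)
  set.seed(55)
  noisy <- lapply(ml, function(s) {
    conc_series(attr(s, "animal_id"), "OH5", "milk", s$time_h,
                s$conc_ng_ml * rlnorm(nrow(s), 0, 0.05))
  })
  ds <- build_depletion_dataset(noisy, 0, loq = 0.9, mrl = 0.4)
  out <- detect_outlier_animals(ds, threshold = 3)
  expect_equal(out$excluded, "goat06")

  homo <- build_depletion_dataset(noisy[1:5], 0, loq = 0.9, mrl = 0.4)
  expect_length(detect_outlier_animals(homo, threshold = 3)$excluded, 0)
  expect_length(detect_outlier_animals(ds, threshold = Inf)$excluded, 0)
})

test_that("milking-interval rounding: ceiling to a multiple, exact multiples kept", {
  expect_equal(round_to_milking(34.1, 12), 36)
  expect_equal(round_to_milking(37.9, 12), 48)
  expect_equal(round_to_milking(51.5, 12), 60)
  expect_equal(round_to_milking(36.0, 12), 36)
  expect_equal(round_to_milking(0, 12), 0)
  expect_error(round_to_milking(-1, 12), class = "milkwdi_format_error")
  set.seed(8)
  w <- runif(50, 0, 100)
  r <- round_to_milking(w, 12)
  expect_true(all(r - w >= -1e-7 & r - w < 12))
})

test_that("EMA pipeline: analytic zero-noise crossing and noisy inflation", {
  ds <- build_depletion_dataset(exact_milk_series(8), 0, loq = 0.9, mrl = 0.4)
  res <- ema_sclr(ds)
  expect_equal(res$continuous_wdt_h, 47.80, tolerance = 1e-3)
  expect_equal(res$rounded_wdt_h, 48)
  expect_equal(res$method, "EMA_SCLR")

  set.seed(23)
  noisy <- lapply(exact_milk_series(8), function(s) {
    conc_series(attr(s, "animal_id"), "OH5", "milk", s$time_h,
                s$conc_ng_ml * rlnorm(nrow(s), 0, 0.15))
  })
  resn <- ema_sclr(build_depletion_dataset(noisy, 0, loq = 0.9, mrl = 0.4))
  expect_gt(resn$continuous_wdt_h, 47.80) # tolerance limit above mean line
})

test_that("FDA path enforces the 10-animal/triplicate contract", {
  milk <- series_list_to_long(exact_milk_series(8))
  expect_error(fda_milk_discard(milk, augmentation = NULL),
               class = "milkwdi_format_error")
  res <- fda_milk_discard(milk, augmentation_spec(intra_assay_cv = 0, seed = 2))
  expect_equal(res$diagnostics$n_animals, 10)
  expect_equal(res$diagnostics$n_virtual, 2)
  expect_equal(res$continuous_wdt_h, 47.80, tolerance = 1e-3) # s = 0 collapse
})

test_that("FDA (99/95) never undercuts EMA (95/95) on the same noisy data", {
  set.seed(61)
  noisy <- lapply(exact_milk_series(10), function(s) {
    conc_series(attr(s, "animal_id"), "OH5", "milk", s$time_h,
                s$conc_ng_ml * rlnorm(nrow(s), 0, 0.1))
  })
  ds <- build_depletion_dataset(noisy, 0, loq = 0.9, mrl = 0.4)
  ema <- ema_sclr(ds)
  fit <- ema$fit
  w99 <- withdrawal_time(fit, 0.4, p = 0.99, gamma = 0.95)
  expect_gte(w99, ema$continuous_wdt_h)
})
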