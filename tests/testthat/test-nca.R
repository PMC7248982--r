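test_that("terminal slope on exact mono-exponential data is recovered exactly", {
  tt <- c(6, 8, 12, 18, 24)
  s <- conc_series("a", "FLU", "plasma", tt, 1000 * exp(-0.2 * tt))
  fit <- select_lambda_z(s, "IV")
  expect_true(fit$accepted)
  expect_equal(fit$lambda_z, 0.2, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)
})

test_that("flat concentrations give a terminal-slope failure, not a number", {
  s <- conc_series("a", "FLU", "plasma", c(1, 2, 4, 8, 12), rep(50, 5))
  fit <- select_lambda_z(s, "IV")
  expect_false(fit$accepted)
  expect_true(is.na(fit$lambda_z))
})

test_that("terminal slope of a biexponential is the slow rate within 5%", {
  tt <- phase1_schedule()
  cc <- 10000 * exp(-0.5 * tt) + 2000 * exp(-0.1 * tt)
  s <- conc_series("a", "FLU", "plasma", tt, cc)
  fit <- select_lambda_z(s, "IV")
  # oracle: regression restricted to times where the fast phase is < 0.1%
  late <- tt[5 * exp(-0.4 * tt) < 0.001]
  late <- tail(late, 3)
  oracle <- -unname(coef(lm(log(10000 * exp(-0.5 * late) +
                                  2000 * exp(-0.1 * late)) ~ late))[2])
  expect_equal(fit$lambda_z, 0.1, tolerance = 0.05)
  expect_equal(fit$lambda_z, oracle, tolerance = 0.05)
})

test_that("trapezoid rules: flat, log-down closed form, and biexponential total", {
  expect_equal(auc_aumc(data.frame(time_h = c(0, 2), conc_ng_ml = c(1, 1)))[["auc"]],
               2, tolerance = 1e-12)
  expect_equal(auc_aumc(data.frame(time_h = c(0, 1), conc_ng_ml = c(10, 5)))[["auc"]],
               5 / log(2), tolerance = 1e-12)
  tt <- seq(0, 60, by = 0.01)
  cc <- 10 * exp(-0.5 * tt) + 2 * exp(-0.1 * tt)
  a <- auc_aumc(data.frame(time_h = tt, conc_ng_ml = cc))
  tail_auc <- cc[length(cc)] / 0.1 # slow phase dominates the tail
  expect_equal(a[["auc"]] + tail_auc, 40, tolerance = 0.005 * 40)
})

test_that("log trapezoid AUMC matches adaptive quadrature of the interpolant", {
  t1 <- 1; t2 <- 3; c1 <- 80; c2 <- 20
  lam <- log(c1 / c2) / (t2 - t1)
  oracle <- integrate(function(x) x * c1 * exp(-lam * (x - t1)), t1, t2,
                      rel.tol = 1e-12)$value
  got <- auc_aumc(data.frame(time_h = c(t1, t2), conc_ng_ml = c(c1, c2)))[["aumc"]]
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("linear-up/log-down AUC never exceeds the linear trapezoid on decreasing data", {
  set.seed(9)
  for (i in 1:20) {
    tt <- sort(runif(8, 0, 24))
    cc <- sort(runif(8, 1, 100), decreasing = TRUE)
    d <- data.frame(time_h = tt, conc_ng_ml = cc)
    expect_lte(auc_aumc(d, method = "loglinear")[["auc"]],
               auc_aumc(d, method = "linear")[["auc"]] + 1e-12)
  }
})

test_that("nonpositive concentrations inside the window are rejected by name", {
  expect_error(auc_aumc(data.frame(time_h = c(0, 1, 2), conc_ng_ml = c(5, 0, 3))),
               "t = 1", class = "milkwdi_format_error")
})

test_that("Cmax/Tmax are the observed argmax of the series", {
  s <- conc_series("a", "FLU", "plasma", c(1, 2, 4, 8),
                   c(5, 9, 6, 2))
  r <- nca_single_profile(s, 1.1, "SC")
  expect_equal(r$cmax_obs * 1000, 9) # reported in ug/ml
  expect_equal(r$tmax_obs, 2)
})

test_that("NCA identities hold exactly: t_half * lambda_z = ln 2, MRT * AUCinf = AUMCinf", {
  p <- true_pk_params(CL = 265, V = 1000)
  prof <- simulate_plasma_profile(p, regimen(0, 1.1, "IV"), phase1_schedule())
  r <- nca_single_profile(prof$parent, 1.1, "IV")
  expect_equal(r$t_half_z * r$lambda_fit$lambda_z, log(2), tolerance = 1e-12)
  expect_equal(r$mrt_inf * r$auc_inf, r$aumc_inf, tolerance = 1e-12)
})

test_that("noise-free IV NCA recovers CL within 5% and Vz within 8% at study sampling", {
  p <- true_pk_params(CL = 265, V = 1000)
  prof <- simulate_plasma_profile(p, regimen(0, 1.1, "IV"), phase1_schedule())
  r <- nca_single_profile(prof$parent, 1.1, "IV")
  expect_lt(abs(r$cl_or_clf - 265) / 265, 0.05)
  expect_lt(abs(r$vz_or_vzf - 1000) / 1000, 0.08)
})

test_that("rich sampling recovers CL, Vz and MRT within 2% of truth", {
  p <- true_pk_params(CL = 265, V = 1000)
  k <- 265 / 1000
  tt <- seq(0, 10 * log(2) / k, by = 0.25) # t = 0 carries the IV C0 = D/V
  prof <- simulate_plasma_profile(p, regimen(0, 1.1, "IV"), tt)
  r <- nca_single_profile(prof$parent, 1.1, "IV")
  expect_lt(abs(r$cl_or_clf - 265) / 265, 0.02)
  expect_lt(abs(r$vz_or_vzf - 1000) / 1000, 0.02)
  expect_lt(abs(r$mrt_inf - 1 / k) / (1 / k), 0.02)
})

test_that("half-life formula evaluates the printed relation", {
  expect_equal(log(2) / 0.21, 3.3007, tolerance = 1e-4)
})

test_that("extraction ratio: allometric cardiac output and identity", {
  # BW = 1 kg: cardiac output 180 ml/kg/min
  expect_equal(extraction_ratio(60 * 180, 1), 1, tolerance = 1e-12)
  expect_equal(180 * 76^(-0.19), 79.0529, tolerance = 1e-4)
  expect_equal(extraction_ratio(60 * 180 * 50^(-0.19), 50), 1, tolerance = 1e-12)
  expect_error(extraction_ratio(100, 76, route = "SC"),
               class = "milkwdi_format_error")
})

test_that("crossover bioavailability is the AUCinf ratio within animal", {
  p <- true_pk_params(CL = 200, V = 1000, ka = 2, F_bio = 1)
  tt <- phase1_schedule()
  iv <- nca_single_profile(simulate_plasma_profile(p, regimen(0, 1.1, "IV"), tt)$parent,
                           1.1, "IV")
  sc <- nca_single_profile(simulate_plasma_profile(p, regimen(0, 1.1, "SC"), tt)$parent,
                           1.1, "SC")
  f <- bioavailability(sc, iv)$f
  expect_equal(f, 1, tolerance = 0.02) # F = 1 truth, small trapezoid error

  # ratio of the trial-level mean AUCs (the per-animal mean differs)
  expect_equal(8.806 / 9.880, 0.8913, tolerance = 1e-4)

  iv2 <- iv; iv2$animal_id <- "other"
  expect_error(bioavailability(sc, iv2), class = "milkwdi_format_error")
})
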