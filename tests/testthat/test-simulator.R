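test_that("one-compartment closed forms are reproduced by the simulator", {
  # IV bolus: C(0+) = D/V = 1.1e6/440 = 2500 ng/ml
  p <- true_pk_params(CL = 265, V = 440)
  s <- simulate_plasma_profile(p, regimen(0, 1.1, "IV"), c(1e-9, 1, 2))
  expect_equal(s$parent$conc_ng_ml[1], 2500, tolerance = 1e-6)

  # SC Tmax = ln(ka/k)/(ka - k) for ka = 2, k = 0.2
  p2 <- true_pk_params(CL = 200, V = 1000, ka = 2)
  grid <- seq(0.5, 3, by = 1e-4)
  s2 <- simulate_plasma_profile(p2, regimen(0, 1.1, "SC"), grid)
  tmax <- grid[which.max(s2$parent$conc_ng_ml)]
  expect_equal(tmax, log(10) / 1.8, tolerance = 1e-3)

  # q12h x 6 IV: predose trough ratio dose6/dose1 ~ 1/(1 - exp(-k*12))
  reg6 <- regimen(seq(0, 60, 12), 1.1, "IV")
  tr <- simulate_plasma_profile(p2, reg6, c(12 - 1e-6, 72 - 1e-6))
  expect_equal(tr$parent$conc_ng_ml[2] / tr$parent$conc_ng_ml[1],
               1 / (1 - exp(-0.2 * 12)), tolerance = 1e-4)
})

test_that("superposition: multi-dose profile is the sum of shifted single doses", {
  p <- true_pk_params(CL = 265, V = 1500, ka = 1.5, km = 0.8)
  times <- seq(0.25, 90, by = 0.25)
  dose_times <- seq(0, 60, 12)
  multi <- simulate_plasma_profile(p, regimen(dose_times, 1.1, "SC"), times)
  manual_parent <- manual_metab <- numeric(length(times))
  for (td in dose_times) {
    single <- simulate_plasma_profile(p, regimen(0, 1.1, "SC"),
                                      seq(0.25, 90, by = 0.25))
    shift_idx <- match(round((times - td) * 4), round(single$parent$time_h * 4))
    on <- !is.na(shift_idx) & times >= td
    manual_parent[on] <- manual_parent[on] + single$parent$conc_ng_ml[shift_idx[on]]
    manual_metab[on] <- manual_metab[on] + single$metabolite$conc_ng_ml[shift_idx[on]]
  }
  expect_equal(multi$parent$conc_ng_ml, manual_parent, tolerance = 1e-10)
  expect_equal(multi$metabolite$conc_ng_ml, manual_metab, tolerance = 1e-10)
})

test_that("noise-free IV AUC0-inf equals Dose/CL; dense trapezoid agrees within 0.5%", {
  p <- true_pk_params(CL = 265, V = 1500)
  analytic <- 1.1e6 / 265 # h*ng/ml
  tt <- seq(0.01, 120, by = 0.01)
  s <- simulate_plasma_profile(p, regimen(0, 1.1, "IV"), tt)
  a <- auc_aumc(s$parent)
  k <- 265 / 1500
  tail <- s$parent$conc_ng_ml[length(tt)] / k
  head <- auc_aumc(data.frame(time_h = c(0, 0.01),
                              conc_ng_ml = c(1.1e6 / 1500,
                                             s$parent$conc_ng_ml[1])))["auc"]
  expect_lt(abs((a[["auc"]] + tail + head[[1]]) - analytic) / analytic, 0.005)
})

test_that("rate-coincidence limits are continuous (no division blow-up)", {
  k <- 0.2
  near <- true_pk_params(CL = k * 1000, V = 1000, ka = k + 1e-10, km = 0.9)
  off <- true_pk_params(CL = k * 1000, V = 1000, ka = k + 1e-5, km = 0.9)
  tt <- c(0.5, 2, 6, 12)
  a <- simulate_plasma_profile(near, regimen(0, 1.1, "SC"), tt)
  b <- simulate_plasma_profile(off, regimen(0, 1.1, "SC"), tt)
  expect_equal(a$parent$conc_ng_ml, b$parent$conc_ng_ml, tolerance = 1e-3)
  expect_true(all(is.finite(a$metabolite$conc_ng_ml)))
  # metabolite with km ~ k
  near_m <- true_pk_params(CL = k * 1000, V = 1000, ka = 2, km = k + 1e-10)
  off_m <- true_pk_params(CL = k * 1000, V = 1000, ka = 2, km = k + 1e-5)
  am <- simulate_plasma_profile(near_m, regimen(0, 1.1, "IV"), tt)
  bm <- simulate_plasma_profile(off_m, regimen(0, 1.1, "IV"), tt)
  expect_equal(am$metabolite$conc_ng_ml, bm$metabolite$conc_ng_ml,
               tolerance = 1e-3)
})

test_that("empirical milk mode depletes log-linearly from the last dose", {
  p <- true_pk_params(lambda_milk = 0.1155)
  m <- simulate_milk_profile(p, regimen(0, 1.1, "SC"), c(1, 2, 6, 12),
                             mode = "empirical", c0 = 100)
  # post-peak points sit on C0 * exp(-lambda * t) exactly
  expect_equal(m$conc_ng_ml[3], 100 * exp(-0.1155 * 6), tolerance = 1e-10)
  expect_equal(m$conc_ng_ml[4], 100 * exp(-0.1155 * 12), tolerance = 1e-10)
  # one half-life after the last dose: 100 * exp(-0.693) ~ 50
  expect_equal(100 * exp(-0.1155 * 6), 50, tolerance = 1e-3)
})

test_that("partition milk mode with P_milk = 1 reproduces the plasma metabolite", {
  p <- true_pk_params(P_milk = 1)
  times <- c(1, 2, 4, 6, 8, 18)
  m <- simulate_milk_profile(p, regimen(0, 1.1, "IV"), times, mode = "partition")
  pl <- simulate_plasma_profile(p, regimen(0, 1.1, "IV"), times)
  expect_identical(m$conc_ng_ml, pl$metabolite$conc_ng_ml)
})

test_that("milk simulation is refused for non-lactating cohorts", {
  expect_error(
    simulate_milk_profile(true_pk_params(), regimen(0, 1.1, "IV"), c(1, 2),
                          cohort = "pregnant_NL"),
    class = "milkwdi_format_error")
})

test_that("assay noise: zero CV passes values through with recomputed flags", {
  s <- conc_series("a", "OH5", "milk", c(1, 2, 3), c(10, 0.6, 0.2))
  nz <- assay_noise_model(0, 0, lod = 0.4, loq = 0.9)
  out <- apply_assay_noise(s, nz, seed = 1)
  expect_equal(out$conc_ng_ml[1:2], c(10, 0.6))
  expect_equal(out$censor, c("Q", "BLQ", "BLD"))
  expect_true(is.na(out$conc_ng_ml[3])) # below-LOD value suppressed
})

test_that("assay noise moments match the stated CV (law of large numbers)", {
  s <- conc_series("a", "OH5", "milk", seq_len(10000), rep(100, 10000))
  nz <- assay_noise_model(0.032, 0, lod = 0.4, loq = 0.9)
  out <- apply_assay_noise(s, nz, seed = 42)
  expect_equal(mean(out$conc_ng_ml), 100, tolerance = 0.001)
  expect_equal(sd(out$conc_ng_ml) / mean(out$conc_ng_ml), 0.032,
               tolerance = 0.0625) # 0.032 +/- 0.002
})

test_that("assay noise is deterministic under seed and distinct across seeds", {
  s <- conc_series("a", "FLU", "plasma", 1:20, 100 * exp(-0.2 * (1:20)))
  nz <- assay_noise_model(0.05, 0.03, lod = 0.1, loq = 0.5)
  a <- apply_assay_noise(s, nz, seed = 7)
  b <- apply_assay_noise(s, nz, seed = 7)
  c <- apply_assay_noise(s, nz, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$conc_ng_ml, c$conc_ng_ml))
})

test_that("censoring is monotone in the assay limits", {
  s <- conc_series("a", "OH5", "milk", 1:50, seq(0.05, 5, length.out = 50))
  lax <- apply_assay_noise(s, assay_noise_model(0, 0, 0.2, 0.5), seed = 1)
  strict <- apply_assay_noise(s, assay_noise_model(0, 0, 0.4, 0.9), seed = 1)
  rank <- c(Q = 3L, BLQ = 2L, BLD = 1L)
  expect_true(all(rank[strict$censor] <= rank[lax$censor]))
})

test_that("cohort generation: zero CV gives exact means, weights stay in range", {
  means <- true_pk_params(CL = 265, V = 1500)
  coh <- generate_cohort(8, "lactating", means, between_animal_cv = 0,
                         bw_range = c(75, 95), seed = 3)
  expect_length(coh, 8)
  for (an in coh) {
    expect_equal(an$true_params$CL, 265)
    expect_equal(an$true_params$V, 1500)
    expect_gte(an$body_weight_kg, 75)
    expect_lte(an$body_weight_kg, 95)
  }
})

test_that("cohort generation recovers the geometric mean of CL", {
  means <- true_pk_params(CL = 265)
  coh <- generate_cohort(5000, "lactating", means, between_animal_cv = 0.25,
                         bw_range = c(75, 95), seed = 11)
  cls <- vapply(coh, function(a) a$true_params$CL, numeric(1))
  expect_equal(exp(mean(log(cls))), 265, tolerance = 0.02)
})
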