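#' @title Regulatory milk-withdrawal-interval estimation
#' @description
#' Regression-based tolerance-limit withdrawal estimation: pooled ordinary
#' least squares of ln(marker residue) on time since last dose, a one-sided
#' upper tolerance limit on a population percentile via the noncentral t
#' distribution with leverage-dependent noncentrality, the crossing of that
#' limit against the operational residue limit, outlier screening, and
#' rounding up to the next milking. Two conventions are provided: the EMA
#' safe-concentration-from-linear-regression method (95th percentile, 95%
#' confidence) on the raw dataset, and the FDA method (99th percentile, 95%
#' confidence) on a Monte Carlo-augmented dataset meeting the >= 10 animal /
#' triplicate data contract.
#' @name withdrawal
NULL

#' Build a depletion dataset from milk series
#'
#' Retains, per animal, the post-last-dose, post-peak, quantifiable points of
#' the marker-residue milk series on the natural-log scale. "Quantifiable"
#' is strict: values must exceed the LOQ (a value exactly at the LOQ is
#' excluded). The post-peak restriction keeps, for each animal, the time of
#' its maximum post-dose concentration onward, so only the depletion phase
#' feeds the regression. Counts of points excluded by reason are recorded.
#'
#' @param milk_series list of [conc_series()] (matrix `"milk"`), or a long
#'   data.frame with `animal_id`, `time_h`, `conc_ng_ml`, optional `censor`
#' @param last_dose_time_h time of the last dose, hours on the series clock
#' @param loq limit of quantification, ng/ml
#' @param mrl operational residue limit (tolerance), ng/ml; with a zero
#'   tolerance the assay LOD stands in (0.4 ng/ml for the milk marker
#'   residue here)
#' @return list of class `"milkwdi_depletion"` with `records`
#'   (animal_id, time_h since last dose, log_conc), `loq`, `mrl`,
#'   `excluded` counts
#' @export
build_depletion_dataset <- function(milk_series, last_dose_time_h = 0,
                                    loq = 0.9, mrl = 0.4) {
  stopifnot(loq > 0, mrl > 0)
  long <- if (is.data.frame(milk_series)) milk_series else
    do.call(rbind, lapply(milk_series, function(s) {
      data.frame(animal_id = attr(s, "animal_id"), time_h = s$time_h,
                 conc_ng_ml = s$conc_ng_ml,
                 censor = s$censor, stringsAsFactors = FALSE)
    }))
  if (is.null(long$censor)) long$censor <- "Q"
  excl <- c(pre_dose = 0L, censored = 0L, at_or_below_loq = 0L, pre_peak = 0L)
  recs <- list()
  for (a in split(long, long$animal_id)) {
    a <- a[order(a$time_h), , drop = FALSE]
    post <- a[a$time_h >= last_dose_time_h, , drop = FALSE]
    excl["pre_dose"] <- excl["pre_dose"] + (nrow(a) - nrow(post))
    ok_cens <- post$censor == "Q" & !is.na(post$conc_ng_ml)
    excl["censored"] <- excl["censored"] + sum(!ok_cens)
    post <- post[ok_cens, , drop = FALSE]
    quant <- post$conc_ng_ml > loq # strictly greater than LOQ
    excl["at_or_below_loq"] <- excl["at_or_below_loq"] + sum(!quant)
    post <- post[quant, , drop = FALSE]
    if (nrow(post) == 0) next
    i_peak <- which.max(post$conc_ng_ml)
    excl["pre_peak"] <- excl["pre_peak"] + (i_peak - 1L)
    post <- post[i_peak:nrow(post), , drop = FALSE]
    recs[[length(recs) + 1L]] <- data.frame(
      animal_id = post$animal_id[1],
      time_h = post$time_h - last_dose_time_h,
      log_conc = log(post$conc_ng_ml), stringsAsFactors = FALSE)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(animal_id = character(), time_h = numeric(),
               log_conc = numeric())
  if (nrow(records) < 3 || length(unique(records$animal_id)) < 2) {
    not_calculable(
      "insufficient quantifiable depletion data (< 3 points or < 2 animals)",
      class = "milkwdi_insufficient_data",
      diagnostics = list(excluded = as.list(excl), n_points = nrow(records)))
  }
  rownames(records) <- NULL
  structure(list(records = records, loq = loq, mrl = mrl,
                 excluded = as.list(excl)),
            class = "milkwdi_depletion")
}

#' Pooled log-linear depletion regression with pre-checks
#'
#' Ordinary least squares of ln(concentration) on time since last dose,
#' pooled over animals (every point independent, matching the
#' safe-concentration-from-linear-regression convention). Stores the
#' intercept, slope, residual SD, degrees of freedom and the leverage
#' constants (mean time, centered sum of squares) from which tolerance
#' bounds are evaluated, plus two pre-checks: a lack-of-fit F test using
#' pure error at replicated times and a Bartlett test of variance
#' homogeneity across time groups. The slope must be significantly negative
#' (one-sided, alpha = 0.05) or the dataset is not calculable.
#'
#' @param dataset a [build_depletion_dataset()] result, or a data.frame with
#'   `time_h` and `log_conc` (and optionally `animal_id`)
#' @param slope_alpha one-sided significance level for the slope pre-check
#' @return list of class `"milkwdi_tolfit"` with `intercept`, `slope`,
#'   `residual_sd`, `n`, `df`, `t_mean`, `sxx`, `slope_p`, `lack_of_fit_p`,
#'   `variance_homogeneity_p`
#' @export
fit_depletion_regression <- function(dataset, slope_alpha = 0.05) {
  rec <- if (inherits(dataset, "milkwdi_depletion")) dataset$records else dataset
  stopifnot(all(c("time_h", "log_conc") %in% names(rec)))
  t <- rec$time_h; y <- rec$log_conc
  n <- length(t)
  if (n < 3) not_calculable("need >= 3 points for the depletion regression",
                            class = "milkwdi_insufficient_data")
  fit <- stats::lm(y ~ t)
  b <- unname(stats::coef(fit)[2]); a <- unname(stats::coef(fit)[1])
  df <- n - 2L
  s <- sqrt(sum(stats::resid(fit)^2) / df)
  sxx <- sum((t - mean(t))^2)
  if (sxx <= 0) not_calculable("all observations at one time; slope undefined",
                               class = "milkwdi_insufficient_data")
  se_b <- s / sqrt(sxx)
  slope_p <- if (se_b == 0) { # exact fit: significance is degenerate
    if (b < 0) 0 else 1
  } else stats::pt(b / se_b, df) # one-sided P(slope < 0 rejected region)
  if (b >= 0 || slope_p >= slope_alpha) {
    not_calculable(sprintf(
      "depletion slope not significantly negative (slope = %.4g, one-sided p = %.3g)",
      b, slope_p), class = "milkwdi_slope_failure",
      diagnostics = list(slope = b, slope_p = slope_p, n = n))
  }
  # lack-of-fit F test from pure error at replicated times
  grp <- factor(t)
  lof_p <- NA_real_
  if (any(table(grp) >= 2) && nlevels(grp) > 2) {
    sse <- sum(stats::resid(fit)^2)
    sspe <- sum(tapply(y, grp, function(v) sum((v - mean(v))^2)))
    df_pe <- n - nlevels(grp)
    df_lof <- nlevels(grp) - 2
    if (df_pe > 0 && df_lof > 0 && sspe > 0) {
      f_lof <- ((sse - sspe) / df_lof) / (sspe / df_pe)
      lof_p <- stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE)
    }
  }
  # variance homogeneity across time groups (needs >= 2 obs in >= 2 groups)
  bart_p <- NA_real_
  rep_grps <- names(which(table(grp) >= 2))
  if (length(rep_grps) >= 2) {
    sub <- t %in% as.numeric(rep_grps)
    resid_sub <- stats::resid(fit)[sub]
    if (stats::var(resid_sub) > 0) {
      bart_p <- tryCatch(
        stats::bartlett.test(resid_sub, droplevels(grp[sub]))$p.value,
        error = function(e) NA_real_)
    }
  }
  structure(list(intercept = a, slope = b, residual_sd = s, n = n, df = df,
                 t_mean = mean(t), sxx = sxx, slope_p = slope_p,
                 lack_of_fit_p = lof_p, variance_homogeneity_p = bart_p),
            class = "milkwdi_tolfit")
}

#' @export
print.milkwdi_tolfit <- function(x, ...) {
  cat(sprintf("<depletion regression> lnC = %.4g %+.4g * t | s = %.4g, n = %d\n",
              x$intercept, x$slope, x$residual_sd, x$n))
  cat(sprintf("  slope p (one-sided) = %.3g; lack-of-fit p = %.3g; Bartlett p = %.3g\n",
              x$slope_p, x$lack_of_fit_p, x$variance_homogeneity_p))
  invisible(x)
}

#' One-sided upper tolerance limit on the depletion line
#'
#' `TL(x) = a + b*x + s * sqrt(d(x)) * q`, where `d(x) = 1/n +
#' (x - t_mean)^2 / Sxx` is the prediction leverage and `q` is the
#' gamma-quantile of the noncentral t distribution with `df` degrees of
#' freedom and noncentrality `z_p / sqrt(d(x))` (`z_p` the standard-normal
#' p-quantile). With confidence gamma, `TL(x)` exceeds the p-th percentile
#' of the ln-concentration population at time x — the standard regression
#' tolerance bound underlying both regulatory conventions.
#'
#' @param fit a [fit_depletion_regression()] result
#' @param x time(s) since last dose, hours
#' @param p population percentile (0.95 EMA, 0.99 FDA)
#' @param gamma confidence level (0.95)
#' @return upper bound(s) on ln-concentration at `x`
#' @export
tolerance_limit <- function(fit, x, p = 0.95, gamma = 0.95) {
  stopifnot(p > 0, p < 1, gamma > 0, gamma < 1)
  d <- 1 / fit$n + (x - fit$t_mean)^2 / fit$sxx
  zp <- stats::qnorm(p)
  # qt() warns about reduced precision at large noncentrality (small leverage,
  # large n); the loss is far below the tolerances that matter here
  q <- suppressWarnings(stats::qt(gamma, df = fit$df, ncp = zp / sqrt(d)))
  fit$intercept + fit$slope * x + fit$residual_sd * sqrt(d) * q
}

#' Continuous withdrawal time: crossing of the tolerance limit and the limit
#'
#' Finds the smallest time `x >= 0` such that the upper tolerance limit stays
#' at or below `ln(mrl)` for all later times within the search horizon. The
#' tolerance-limit curve is eventually decreasing for a significantly
#' negative slope; the last up-crossing is located on a fine grid and
#' refined by root bracketing. Returns 0 when the limit already starts below
#' `ln(mrl)` and never rises above it.
#'
#' @param fit a [fit_depletion_regression()] result
#' @param mrl residue limit, ng/ml
#' @param p,gamma tolerance percentile and confidence, see [tolerance_limit()]
#' @param search_horizon_h upper end of the search window, hours (default
#'   10x the fitted time span, a generous bound for log-linear depletion)
#' @return continuous withdrawal time in hours
#' @export
withdrawal_time <- function(fit, mrl, p = 0.95, gamma = 0.95,
                            search_horizon_h = NULL) {
  stopifnot(mrl > 0)
  if (is.null(search_horizon_h)) {
    span <- max(fit$t_mean * 2, fit$sxx^(1 / 2) + fit$t_mean)
    search_horizon_h <- 10 * max(span, 1)
  }
  target <- log(mrl)
  tl <- function(x) tolerance_limit(fit, x, p = p, gamma = gamma)
  grid <- seq(0, search_horizon_h, length.out = 512L)
  above <- tl(grid) > target
  if (!any(above)) return(0)
  if (above[length(grid)]) {
    not_calculable(sprintf(
      "tolerance limit does not drop below ln(MRL) within the %g h search horizon",
      search_horizon_h), class = "milkwdi_no_crossing")
  }
  i_last <- max(which(above))
  stats::uniroot(function(x) tl(x) - target,
                 lower = grid[i_last], upper = grid[i_last + 1L],
                 tol = 1e-10)$root
}

#' Flag and exclude outlier animals
#'
#' For each animal the pooled regression is refitted without that animal's
#' points; the animal's residuals against the leave-one-animal-out fit are
#' studentized by that fit's residual SD and prediction leverage, and the
#' animal is flagged when the mean of these externally studentized residuals
#' exceeds `threshold` in absolute value (default 3). Studentizing against
#' the reduced fit keeps a gross outlier from inflating the residual SD and
#' masking itself. Flagged animals are removed and the regression refitted;
#' at most one exclusion round is performed.
#'
#' @param dataset a [build_depletion_dataset()] result
#' @param threshold absolute mean-studentized-residual cutoff
#' @return list with `excluded` (animal ids, possibly empty), `dataset`
#'   (after exclusion) and `fit` (refitted [fit_depletion_regression()])
#' @export
detect_outlier_animals <- function(dataset, threshold = 3) {
  rec <- dataset$records
  ids <- unique(rec$animal_id)
  by_animal <- vapply(ids, function(a) {
    keep <- rec$animal_id != a
    sub <- rec[keep, , drop = FALSE]
    if (nrow(sub) < 3 || length(unique(sub$time_h)) < 2) return(NA_real_)
    fit_lm <- stats::lm(log_conc ~ time_h, data = sub)
    # residual SD computed directly (summary.lm warns on exact fits)
    s_out <- sqrt(sum(stats::resid(fit_lm)^2) / fit_lm$df.residual)
    xm <- mean(sub$time_h)
    sxx <- sum((sub$time_h - xm)^2)
    xa <- rec$time_h[!keep]
    cf <- stats::coef(fit_lm)
    r <- rec$log_conc[!keep] - (cf[1] + cf[2] * xa)
    lev <- 1 + 1 / nrow(sub) + (xa - xm)^2 / sxx
    mean(r / (s_out * sqrt(lev)))
  }, numeric(1))
  names(by_animal) <- ids
  flagged <- names(by_animal)[abs(by_animal) > threshold & is.finite(by_animal)]
  if (length(flagged) > 0) {
    keep <- !(rec$animal_id %in% flagged)
    if (length(unique(rec$animal_id[keep])) < 2) {
      not_calculable("outlier exclusion would leave fewer than 2 animals",
                     class = "milkwdi_insufficient_data",
                     diagnostics = list(flagged = flagged))
    }
    dataset$records <- rec[keep, , drop = FALSE]
    rownames(dataset$records) <- NULL
  }
  list(excluded = flagged, dataset = dataset,
       fit = fit_depletion_regression(dataset))
}

#' Round a continuous withdrawal time up to the next milking
#'
#' Smallest nonnegative integer multiple of the milking interval at or above
#' the continuous estimate; an exact multiple is kept as is (36.0 h on a
#' 12-h schedule stays 36 h). A small numeric slack avoids spurious bumping
#' of values that are multiples up to floating error.
#'
#' @param continuous_wdt_h continuous withdrawal time, hours (>= 0)
#' @param milking_interval_h milking interval, hours (> 0; 12 h typical)
#' @return rounded withdrawal interval in hours
#' @export
round_to_milking <- function(continuous_wdt_h, milking_interval_h = 12) {
  if (any(continuous_wdt_h < 0)) format_error("withdrawal time must be nonnegative")
  stopifnot(milking_interval_h > 0)
  k <- continuous_wdt_h / milking_interval_h
  milking_interval_h * ceiling(k - 1e-9)
}

# Shared tolerance-limit pipeline behind both regulatory conventions.
.wdt_pipeline <- function(dataset, p, gamma, milking_interval_h,
                          outlier_threshold, method,
                          extra_diag = list()) {
  screened <- detect_outlier_animals(dataset, threshold = outlier_threshold)
  fit <- screened$fit
  cw <- withdrawal_time(fit, mrl = dataset$mrl, p = p, gamma = gamma)
  structure(list(
    method = method, percentile = p, confidence = gamma,
    continuous_wdt_h = cw,
    rounded_wdt_h = round_to_milking(cw, milking_interval_h),
    milking_interval_h = milking_interval_h, mrl_used = dataset$mrl,
    fit = fit,
    diagnostics = c(list(excluded_animals = screened$excluded,
                         lack_of_fit_p = fit$lack_of_fit_p,
                         variance_homogeneity_p = fit$variance_homogeneity_p,
                         slope_p = fit$slope_p,
                         excluded_points = dataset$excluded),
                    extra_diag)
  ), class = "milkwdi_wdt")
}

#' @export
print.milkwdi_wdt <- function(x, ...) {
  cat(sprintf("<withdrawal interval> %s (p = %.2f, gamma = %.2f)\n",
              x$method, x$percentile, x$confidence))
  cat(sprintf("  continuous %.2f h -> %g h at a %g-h milking interval (limit %g ng/ml)\n",
              x$continuous_wdt_h, x$rounded_wdt_h, x$milking_interval_h,
              x$mrl_used))
  if (length(x$diagnostics$excluded_animals)) {
    cat("  excluded animals:", paste(x$diagnostics$excluded_animals,
                                     collapse = ", "), "\n")
  }
  invisible(x)
}

#' EMA safe-concentration-from-linear-regression withdrawal interval
#'
#' Outlier screen, pooled log-linear regression with pre-checks, one-sided
#' 95th-percentile/95%-confidence tolerance limit, crossing against
#' `ln(mrl)`, and rounding up to the next milking. Not-calculable states
#' (non-significant slope, no crossing, insufficient data) propagate as
#' typed conditions, never as numbers.
#'
#' @param dataset a [build_depletion_dataset()] result
#' @param milking_interval_h milking interval, hours
#' @param outlier_threshold see [detect_outlier_animals()]
#' @return a `"milkwdi_wdt"` result, see [withdrawal_time()]
#' @export
ema_sclr <- function(dataset, milking_interval_h = 12, outlier_threshold = 3) {
  .wdt_pipeline(dataset, p = 0.95, gamma = 0.95,
                milking_interval_h = milking_interval_h,
                outlier_threshold = outlier_threshold, method = "EMA_SCLR")
}

#' FDA milk-discard withdrawal interval on augmented data
#'
#' Enforces the FDA data contract (>= 10 animals, >= 3 values per sample);
#' a sparse dataset must be expanded first via [generate_virtual_animals()]
#' (pass `augmentation` to do it here). The augmented records then run
#' through the same regression/tolerance machinery at the 99th percentile
#' and 95% confidence, with virtual/replicate provenance retained in the
#' diagnostics.
#'
#' @param milk_long data.frame with `animal_id`, `time_h`, `conc_ng_ml`
#'   (real measurements, one per sample), or a ready
#'   [generate_virtual_animals()] result
#' @param augmentation an [augmentation_spec()], or `NULL` to require
#'   already-conforming data
#' @param loq,mrl see [build_depletion_dataset()]
#' @param milking_interval_h milking interval, hours
#' @param outlier_threshold see [detect_outlier_animals()]
#' @return a `"milkwdi_wdt"` result
#' @export
fda_milk_discard <- function(milk_long, augmentation = NULL,
                             loq = 0.9, mrl = 0.4,
                             milking_interval_h = 12, outlier_threshold = 3) {
  if (!inherits(milk_long, "milkwdi_augmented")) {
    n_animals <- length(unique(milk_long$animal_id))
    reps_ok <- if ("replicate" %in% names(milk_long)) {
      all(table(milk_long$animal_id, milk_long$time_h) >= 3)
    } else FALSE
    if (n_animals < 10 || !reps_ok) {
      if (is.null(augmentation)) {
        format_error(sprintf(
          paste0("dataset has %d animals and no triplicates; the FDA method ",
                 "requires >= 10 animals with >= 3 values per sample - ",
                 "augment first (see augmentation_spec())"), n_animals))
      }
      milk_long <- generate_virtual_animals(milk_long, augmentation)
    }
  }
  if (is.null(milk_long$virtual)) milk_long$virtual <- FALSE
  n_virtual <- length(unique(milk_long$animal_id[milk_long$virtual]))
  n_total <- length(unique(milk_long$animal_id))
  dataset <- build_depletion_dataset(
    milk_long[, c("animal_id", "time_h", "conc_ng_ml")],
    last_dose_time_h = 0, loq = loq, mrl = mrl)
  .wdt_pipeline(dataset, p = 0.99, gamma = 0.95,
                milking_interval_h = milking_interval_h,
                outlier_threshold = outlier_threshold, method = "FDA",
                extra_diag = list(n_animals = n_total, n_virtual = n_virtual))
}
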