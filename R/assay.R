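#' @title Immunoassay calibration and method-agreement statistics
#' @description
#' Four-parameter logistic (4PL) calibration of competitive ELISA plates,
#' exact curve inversion with dilution correction, derivation of assay limits
#' (LOD from the IC10, working range from IC15-IC85), and the per-time-point
#' method-agreement test: a two-sided F pre-test of variance equality
#' followed by a pooled or Welch two-sample t test.
#' @name assay
NULL

#' Fit a four-parameter logistic calibration curve
#'
#' Least-squares fit of `y = D + (A - D) / (1 + (x / C)^B)` to
#' (concentration, absorbance) pairs from a competitive inhibition assay:
#' `A` is the absorbance at zero analyte (the zero-concentration calibrator
#' constrains it), `D` the absorbance at infinite analyte, `C` the IC50 and
#' `B > 0` the slope factor. Starting values come from the data range
#' (A = max y, D = min y, C = median positive x, B = 1), which is robust for
#' inhibition curves spanning several decades.
#'
#' @param conc_ng_ml calibrator concentrations (>= 5 distinct values,
#'   including 0)
#' @param absorbance measured absorbances
#' @return list of class `"milkwdi_4pl"` with `A`, `B`, `C`, `D`, `fit_rss`
#' @export
fit_4pl <- function(conc_ng_ml, absorbance) {
  stopifnot(length(conc_ng_ml) == length(absorbance))
  if (length(unique(conc_ng_ml)) < 5 || !any(conc_ng_ml == 0)) {
    format_error("4PL fit needs >= 5 distinct concentrations including 0")
  }
  if (diff(range(absorbance)) < 1e-9 * max(abs(absorbance), 1)) {
    not_calculable("flat absorbances: no inhibition signal, 4PL cannot converge",
                   class = "milkwdi_fit_failure")
  }
  df <- data.frame(x = conc_ng_ml, y = absorbance)
  start <- list(A = max(absorbance), B = 1,
                C = stats::median(conc_ng_ml[conc_ng_ml > 0]),
                D = min(absorbance))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ D + (A - D) / (1 + (x / C)^B),
                      data = df, start = start,
                      lower = c(A = -Inf, B = 1e-6, C = 1e-12, D = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      not_calculable(paste0("4PL fit did not converge: ", conditionMessage(e)),
                     class = "milkwdi_fit_failure",
                     diagnostics = list(start = start))
    }
  )
  cf <- stats::coef(fit)
  if (cf[["A"]] <= cf[["D"]]) {
    not_calculable("4PL fit converged to a non-descending curve (A <= D)",
                   class = "milkwdi_fit_failure",
                   diagnostics = list(coef = as.list(cf)))
  }
  structure(list(A = cf[["A"]], B = cf[["B"]], C = cf[["C"]], D = cf[["D"]],
                 fit_rss = sum(stats::resid(fit)^2)),
            class = "milkwdi_4pl")
}

#' Evaluate a 4PL curve
#'
#' @param curve a [fit_4pl()] result (or list with A, B, C, D)
#' @param conc_ng_ml concentrations
#' @return predicted absorbances
#' @export
predict_4pl <- function(curve, conc_ng_ml) {
  with(curve, D + (A - D) / (1 + (conc_ng_ml / C)^B))
}

#' Invert a 4PL calibration curve to a concentration
#'
#' Exact functional inverse `x = C * ((A - D)/(y - D) - 1)^(1/B)`, multiplied
#' by the dilution factor. Absorbances outside the open interval (D, A) are
#' out of range: the caller should re-dilute the sample and re-assay.
#'
#' @param curve a [fit_4pl()] result
#' @param absorbance measured absorbance(s), each strictly inside (D, A)
#' @param dilution_factor fold dilution applied before assay (>= 1 typical)
#' @return concentration(s) in ng/ml, dilution-adjusted
#' @export
invert_4pl <- function(curve, absorbance, dilution_factor = 1) {
  stopifnot(dilution_factor > 0)
  if (any(absorbance <= curve$D | absorbance >= curve$A)) {
    format_error(sprintf(
      "absorbance outside the invertible range (%.4g, %.4g); re-dilute and re-assay",
      curve$D, curve$A))
  }
  curve$C * ((curve$A - curve$D) / (absorbance - curve$D) - 1)^(1 / curve$B) *
    dilution_factor
}

#' Derive assay limits from one or more calibration curves
#'
#' Per curve, the ICq concentration is the inversion of the absorbance
#' `A - q*(A - D)` (the concentration reducing the zero-analyte absorbance by
#' the fraction q). The LOD is the IC10 averaged over plates; the working
#' range runs IC15 to IC85. All values are multiplied by the dilution factor.
#'
#' @param curves list of [fit_4pl()] results (>= 1)
#' @param dilution_factor fold dilution applied to samples
#' @return list of class `"milkwdi_assay_limits"` with `lod`, `range_low`,
#'   `range_high` (ng/ml)
#' @export
assay_limits <- function(curves, dilution_factor = 1) {
  if (inherits(curves, "milkwdi_4pl")) curves <- list(curves)
  stopifnot(length(curves) >= 1)
  icq <- function(curve, q) {
    invert_4pl(curve, curve$A - q * (curve$A - curve$D), dilution_factor = 1)
  }
  lod <- mean(vapply(curves, icq, numeric(1), q = 0.10)) * dilution_factor
  lo <- mean(vapply(curves, icq, numeric(1), q = 0.15)) * dilution_factor
  hi <- mean(vapply(curves, icq, numeric(1), q = 0.85)) * dilution_factor
  structure(list(lod = lod, range_low = lo, range_high = hi),
            class = "milkwdi_assay_limits")
}

# Two-sample t machinery from summary statistics. Returns the full record so
# printed summary tables can be replayed without raw data.
.t_from_summaries <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                              var_alpha = 0.05) {
  if (sd_a == 0 && sd_b == 0) {
    if (mean_a == mean_b) {
      return(list(variance_test_p = 1, t_statistic = 0, df = n_a + n_b - 2,
                  p_value = 1, test_used = "pooled_t",
                  flag = "zero variance in both samples with equal means"))
    }
    return(list(variance_test_p = 1, t_statistic = sign(mean_a - mean_b) * Inf,
                df = n_a + n_b - 2, p_value = 0, test_used = "pooled_t",
                flag = "zero variance in both samples"))
  }
  # two-sided F test of variance equality
  f <- sd_a^2 / sd_b^2
  pf_lower <- stats::pf(f, n_a - 1, n_b - 1)
  var_p <- 2 * min(pf_lower, 1 - pf_lower)
  var_p <- min(var_p, 1)
  if (var_p >= var_alpha) {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
    used <- "pooled_t"
  } else {
    se <- sqrt(sd_a^2 / n_a + sd_b^2 / n_b)
    df <- (sd_a^2 / n_a + sd_b^2 / n_b)^2 /
      ((sd_a^2 / n_a)^2 / (n_a - 1) + (sd_b^2 / n_b)^2 / (n_b - 1))
    used <- "welch_t"
  }
  t_stat <- (mean_a - mean_b) / se
  list(variance_test_p = var_p, t_statistic = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df), test_used = used,
       flag = NULL)
}

#' Per-time-point method agreement: variance pre-test then Student's t
#'
#' Compares two analytical methods at one time point with a two-sided F test
#' of variance equality at `var_alpha`; if equality is not rejected a pooled
#' two-sample t test is used, otherwise Welch's t. Accepts either raw values
#' or (mean, sd, n) summaries, so printed summary tables can be replayed.
#'
#' @param sample_a,sample_b raw numeric vectors (n >= 2 each), or `NULL`
#'   when summaries are given
#' @param summary_a,summary_b optional `c(mean, sd, n)` triples
#' @param time_h optional time label carried into the result
#' @param var_alpha significance level of the variance pre-test
#' @return list of class `"milkwdi_timepoint_cmp"` with the summaries,
#'   `variance_test_p`, `t_statistic`, `p_value`, `test_used`
#' @export
compare_methods_at_timepoint <- function(sample_a = NULL, sample_b = NULL,
                                         summary_a = NULL, summary_b = NULL,
                                         time_h = NA_real_, var_alpha = 0.05) {
  if (!is.null(sample_a)) {
    stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
    summary_a <- c(mean(sample_a), stats::sd(sample_a), length(sample_a))
    summary_b <- c(mean(sample_b), stats::sd(sample_b), length(sample_b))
  }
  stopifnot(length(summary_a) == 3, length(summary_b) == 3,
            summary_a[3] >= 2, summary_b[3] >= 2)
  res <- .t_from_summaries(summary_a[1], summary_a[2], summary_a[3],
                           summary_b[1], summary_b[2], summary_b[3],
                           var_alpha = var_alpha)
  structure(c(list(time_h = time_h,
                   mean_a = summary_a[1], sd_a = summary_a[2], n_a = summary_a[3],
                   mean_b = summary_b[1], sd_b = summary_b[2], n_b = summary_b[3]),
              res),
            class = "milkwdi_timepoint_cmp")
}
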