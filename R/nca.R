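#' @title Noncompartmental analysis engine
#' @description
#' Noncompartmental estimation of the standard plasma parameter block per
#' animal profile: Cmax/Tmax, AUC and AUMC by the linear-up/log-down
#' trapezoidal rule with Clast/lambda_z tail extrapolation, terminal slope by
#' best-adjusted-R2 window search, clearance, volumes, mean residence time,
#' crossover bioavailability and the whole-body extraction ratio against
#' allometric cardiac output.
#' @name nca
NULL

# Usable (quantified, positive) points of a series for NCA, as a data.frame.
# A pre-dose t=0 value below LOQ is treated as a true zero; censored interior
# points are dropped so trapezoids span the gap.
.nca_points <- function(series) {
  stopifnot(inherits(series, "milkwdi_series"))
  keep <- series$censor == "Q" & !is.na(series$conc_ng_ml)
  out <- series[keep, c("time_h", "conc_ng_ml"), drop = FALSE]
  class(out) <- "data.frame"
  if (nrow(series) > 0 && series$time_h[1] == 0 && series$censor[1] != "Q") {
    out <- rbind(data.frame(time_h = 0, conc_ng_ml = 0), out)
  }
  rownames(out) <- NULL
  out
}

#' Select the terminal elimination slope (lambda_z)
#'
#' Regresses ln(concentration) on time over every contiguous terminal window
#' of at least 3 quantified points and keeps the window with the largest
#' adjusted R-squared among those with a negative slope. For extravascular
#' routes candidate windows start strictly after Tmax; for IV they start
#' after the first sample. Ties on adjusted R-squared prefer the longer
#' window.
#'
#' @param series a [conc_series()]
#' @param route `"IV"` or `"SC"`
#' @return a list of class `"milkwdi_lambdaz"` with `lambda_z` (1/h),
#'   `intercept` (ln ng/ml), `n_points`, `t_first`, `t_last`, `adj_r2` and
#'   `accepted`. When no window has a negative slope, `accepted` is `FALSE`
#'   and the numeric fields are `NA` (downstream lambda_z-dependent
#'   parameters become unavailable; Cmax/Tmax/AUClast are unaffected).
#' @export
select_lambda_z <- function(series, route = c("IV", "SC")) {
  route <- match.arg(route)
  pts <- .nca_points(series)
  pts <- pts[pts$conc_ng_ml > 0, , drop = FALSE]
  n <- nrow(pts)
  fail <- structure(list(lambda_z = NA_real_, intercept = NA_real_,
                         n_points = 0L, t_first = NA_real_, t_last = NA_real_,
                         adj_r2 = NA_real_, accepted = FALSE),
                    class = "milkwdi_lambdaz")
  if (n < 3) return(fail)
  i_tmax <- which.max(pts$conc_ng_ml)
  first_start <- max(1L, if (route == "SC") i_tmax + 1L else 2L)
  if (first_start > n - 2L) return(fail)
  starts <- seq(from = first_start, to = n - 2L)
  best <- NULL
  for (s in starts) {
    tt <- pts$time_h[s:n]
    ly <- log(pts$conc_ng_ml[s:n])
    m <- length(tt)
    fit <- lm.fit(cbind(1, tt), ly)
    slope <- fit$coefficients[2]
    # require a genuinely negative slope; -1e-10/h is far below any real
    # terminal rate and screens out floating noise on flat data
    if (!is.finite(slope) || slope >= -1e-10) next
    ssr <- sum(fit$residuals^2)
    sst <- sum((ly - mean(ly))^2)
    r2 <- if (sst == 0) 1 else 1 - ssr / sst
    adj <- 1 - (1 - r2) * (m - 1) / (m - 2)
    # prefer higher adjusted R2; on (near-)ties prefer more points
    if (is.null(best) || adj > best$adj_r2 + 1e-12 ||
        (abs(adj - best$adj_r2) <= 1e-12 && m > best$n_points)) {
      best <- list(lambda_z = -as.numeric(slope),
                   intercept = as.numeric(fit$coefficients[1]),
                   n_points = m, t_first = tt[1], t_last = tt[m],
                   adj_r2 = adj, accepted = TRUE)
    }
  }
  if (is.null(best)) return(fail)
  structure(best, class = "milkwdi_lambdaz")
}

# One trapezoid interval under the linear-up/log-down convention.
# Returns c(auc, aumc) increments.
.trap_interval <- function(t1, t2, c1, c2, method) {
  dt <- t2 - t1
  if (method == "loglinear" && c2 < c1 && c2 > 0 && c1 > 0) {
    lr <- log(c1 / c2)
    auc <- (c1 - c2) * dt / lr
    aumc <- (t1 * c1 - t2 * c2) * dt / lr + (c1 - c2) * dt^2 / lr^2
  } else {
    auc <- dt * (c1 + c2) / 2
    aumc <- dt * (t1 * c1 + t2 * c2) / 2
  }
  c(auc, aumc)
}

#' Area under the curve and first-moment curve by trapezoidal integration
#'
#' Linear-up/log-down convention: an interval with falling concentrations uses
#' the logarithmic trapezoid `(C1 - C2) * dt / ln(C1/C2)` (and the matching
#' log first-moment rule); flat or rising intervals use the linear trapezoid.
#' `method = "linear"` forces linear trapezoids throughout.
#'
#' @param series a [conc_series()], or a data.frame with `time_h` and
#'   `conc_ng_ml`
#' @param t_start,t_end window bounds in hours (defaults: full series)
#' @param method `"loglinear"` (default) or `"linear"`
#' @return named numeric `c(auc = , aumc = )` in h*(conc) and h^2*(conc)
#' @export
auc_aumc <- function(series, t_start = NULL, t_end = NULL,
                     method = c("loglinear", "linear")) {
  method <- match.arg(method)
  pts <- if (inherits(series, "milkwdi_series")) .nca_points(series) else
    data.frame(time_h = series$time_h, conc_ng_ml = series$conc_ng_ml)
  if (is.null(t_start)) t_start <- min(pts$time_h)
  if (is.null(t_end)) t_end <- max(pts$time_h)
  pts <- pts[pts$time_h >= t_start & pts$time_h <= t_end, , drop = FALSE]
  if (nrow(pts) < 2) {
    format_error("need at least 2 quantified points inside the integration window")
  }
  bad <- which(pts$conc_ng_ml <= 0)
  if (length(bad) > 0) {
    format_error(sprintf("nonpositive concentration at t = %g h inside the integration window",
                         pts$time_h[bad[1]]))
  }
  auc <- 0; aumc <- 0
  for (i in seq_len(nrow(pts) - 1)) {
    inc <- .trap_interval(pts$time_h[i], pts$time_h[i + 1],
                          pts$conc_ng_ml[i], pts$conc_ng_ml[i + 1], method)
    auc <- auc + inc[1]; aumc <- aumc + inc[2]
  }
  c(auc = auc, aumc = aumc)
}

#' Noncompartmental analysis of one plasma profile
#'
#' Computes the full per-profile parameter block: observed Cmax/Tmax and
#' Clast/Tlast, AUClast/AUMClast by linear-up/log-down trapezoids, the
#' extrapolated AUCinf = AUClast + Clast/lambda_z (observed, not
#' regression-predicted, Clast), AUMCinf, percent extrapolation, MRT,
#' terminal half-life, clearance (CL, or apparent CL/F for SC), Vz (or Vz/F),
#' and for IV routes Vss = CL * MRT and, when a body weight is supplied, the
#' whole-body extraction ratio. Concentration-scale outputs are reported in
#' ug/ml (inputs are ng/ml); CL and volumes in ml/kg/h and ml/kg.
#'
#' A pre-dose t=0 sample below LOQ enters as a true zero; the leading rising
#' segment is integrated linearly. Percent extrapolation >= 20% is recorded
#' as a diagnostic warning, not a failure. A failed terminal-slope fit leaves
#' the lambda_z-dependent parameters `NA` while Cmax/Tmax/AUClast are still
#' reported.
#'
#' @param series a [conc_series()] (ng/ml)
#' @param dose_mg_kg administered dose, mg per kg body weight
#' @param route `"IV"` or `"SC"`
#' @param body_weight_kg optional body weight for the extraction ratio (IV)
#' @param lambda_fit optional precomputed [select_lambda_z()] result
#' @param method trapezoid convention, see [auc_aumc()]
#' @return list of class `"milkwdi_nca"`
#' @export
nca_single_profile <- function(series, dose_mg_kg, route = c("IV", "SC"),
                               body_weight_kg = NULL, lambda_fit = NULL,
                               method = c("loglinear", "linear")) {
  route <- match.arg(route)
  method <- match.arg(method)
  stopifnot(dose_mg_kg > 0)
  pts <- .nca_points(series)
  if (nrow(pts) < 2) format_error("need at least 2 usable points for NCA")
  dose_ng_kg <- dose_mg_kg * 1e6
  i_max <- which.max(pts$conc_ng_ml)
  cmax <- pts$conc_ng_ml[i_max]
  tmax <- pts$time_h[i_max]
  pos <- pts[pts$conc_ng_ml > 0, , drop = FALSE]
  clast <- pos$conc_ng_ml[nrow(pos)]
  tlast <- pos$time_h[nrow(pos)]

  # leading zero (pre-dose BLQ) integrates linearly; the rest via auc_aumc
  lead0 <- pts$conc_ng_ml[1] == 0
  area <- auc_aumc(pos, method = method)
  if (lead0 && nrow(pos) >= 1) {
    t0 <- pts$time_h[1]; t1 <- pos$time_h[1]; c1 <- pos$conc_ng_ml[1]
    area <- area + c((t1 - t0) * c1 / 2, (t1 - t0) * t1 * c1 / 2)
  }
  auc_last <- unname(area["auc"]); aumc_last <- unname(area["aumc"])

  lam <- if (is.null(lambda_fit)) select_lambda_z(series, route) else lambda_fit
  warnings <- character()
  if (lam$accepted) {
    lz <- lam$lambda_z
    auc_inf <- auc_last + clast / lz
    aumc_inf <- aumc_last + clast * tlast / lz + clast / lz^2
    pct_ext <- 100 * (auc_inf - auc_last) / auc_inf
    if (pct_ext >= 20) {
      warnings <- c(warnings, sprintf("AUC extrapolation %.1f%% >= 20%%", pct_ext))
    }
    mrt <- aumc_inf / auc_inf
    t_half <- log(2) / lz
    cl <- dose_ng_kg / auc_inf            # (ng/kg) / (h*ng/ml) = ml/kg/h
    vz <- dose_ng_kg / (auc_inf * lz)     # ml/kg
    vss <- if (route == "IV") cl * mrt else NA_real_
    e_body <- if (route == "IV" && !is.null(body_weight_kg)) {
      extraction_ratio(cl, body_weight_kg, route = route)
    } else NA_real_
  } else {
    warnings <- c(warnings, "terminal slope fit failed; lambda_z-dependent parameters unavailable")
    auc_inf <- aumc_inf <- pct_ext <- mrt <- t_half <- cl <- vz <- vss <-
      e_body <- NA_real_
  }
  structure(list(
    animal_id = attr(series, "animal_id"), analyte = attr(series, "analyte"),
    route = route, dose_mg_kg = dose_mg_kg,
    cmax_obs = cmax / 1000, tmax_obs = tmax,           # ug/ml, h
    clast_obs = clast / 1000, tlast_obs = tlast,
    auc_last = auc_last / 1000, auc_inf = auc_inf / 1000,   # h*ug/ml
    auc_pct_ext = pct_ext, aumc_inf = aumc_inf / 1000,      # h^2*ug/ml
    mrt_inf = mrt, t_half_z = t_half, lambda_fit = lam,
    cl_or_clf = cl, vz_or_vzf = vz, vss = vss, e_body = e_body,
    warnings = warnings
  ), class = "milkwdi_nca")
}

#' @export
print.milkwdi_nca <- function(x, ...) {
  cat(sprintf("<NCA result> animal %s | %s | route %s\n",
              x$animal_id, x$analyte, x$route))
  cat(sprintf("  Cmax %.4g ug/ml at %.3g h; AUCinf %.4g h*ug/ml (%.2g%% extrapolated)\n",
              x$cmax_obs, x$tmax_obs, x$auc_inf, x$auc_pct_ext))
  cat(sprintf("  t1/2 %.3g h; %s %.4g ml/kg/h; %s %.4g ml/kg\n",
              x$t_half_z,
              if (x$route == "IV") "CL" else "CL/F", x$cl_or_clf,
              if (x$route == "IV") "Vz" else "Vz/F", x$vz_or_vzf))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Whole-body extraction ratio against allometric cardiac output
#'
#' Cardiac output is taken allometrically as `180 * BW^(-0.19)` ml/kg/min and
#' converted to ml/kg/h; the extraction ratio is the dimensionless quotient
#' `CL / (60 * 180 * BW^(-0.19))`. Defined for systemic clearance only, so an
#' extravascular (CL/F) input is rejected.
#'
#' @param cl systemic clearance, ml/kg/h (from an IV profile)
#' @param body_weight_kg body weight, kg
#' @param route route of the profile the clearance came from
#' @return dimensionless extraction ratio
#' @export
extraction_ratio <- function(cl, body_weight_kg, route = "IV") {
  if (!identical(route, "IV")) {
    format_error("extraction ratio is defined for systemic (IV) clearance, not CL/F")
  }
  stopifnot(cl > 0, body_weight_kg > 0)
  co_ml_kg_h <- 60 * 180 * body_weight_kg^(-0.19)
  cl / co_ml_kg_h
}

#' Crossover bioavailability from paired IV and SC profiles
#'
#' `F = AUCinf(SC) / AUCinf(IV)`, computed within animal (the crossover
#' design makes each animal its own control).
#'
#' @param nca_sc,nca_iv [nca_single_profile()] results from the same animal
#' @return list of class `"milkwdi_crossover"` with `animal_id`, `f`,
#'   and both NCA results
#' @export
bioavailability <- function(nca_sc, nca_iv) {
  stopifnot(inherits(nca_sc, "milkwdi_nca"), inherits(nca_iv, "milkwdi_nca"))
  if (!identical(nca_sc$animal_id, nca_iv$animal_id)) {
    format_error(sprintf("crossover pair must come from one animal (got '%s' and '%s')",
                         nca_sc$animal_id, nca_iv$animal_id))
  }
  if (nca_sc$route != "SC" || nca_iv$route != "IV") {
    format_error("bioavailability() expects an SC result first and an IV result second")
  }
  f <- nca_sc$auc_inf / nca_iv$auc_inf
  structure(list(animal_id = nca_sc$animal_id, f = f,
                 nca_sc = nca_sc, nca_iv = nca_iv),
            class = "milkwdi_crossover")
}
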