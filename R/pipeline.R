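#' @title Study orchestration
#' @description
#' Binds simulator, NCA, method-agreement statistics, augmentation and
#' withdrawal estimation into one reproducible run: simulate a crossover
#' cohort, estimate per-animal PK parameters on both routes, compute
#' crossover bioavailability, compare parameter groups across cohorts, build
#' the milk depletion dataset, and produce EMA and FDA withdrawal results in
#' a single machine-readable report. All randomness descends from one root
#' seed with fixed per-stage offsets.
#' @name pipeline
NULL

#' Study configuration
#'
#' Defaults reproduce the study conditions the simulator emulates: eight
#' lactating goats of 75-95 kg, 1.1 mg/kg doses (single, and q12h x 6 for
#' the multiple-dose arm), rich early plasma sampling to 72 h, hand plus
#' machine milkings to 120 h post last dose, matrix/analyte-specific assay
#' CVs and LOD/LOQ censoring, an operational milk residue limit of
#' 0.4 ng/ml (the marker-residue LOD under a zero tolerance), milk LOQ
#' 0.9 ng/ml and a 12-h milking interval.
#'
#' @param seed root integer seed; every stochastic stage derives its own
#'   seed from it
#' @param cohorts list of cohort specs (name, n, bw_range, param_means,
#'   between_animal_cv)
#' @param dose_mg_kg dose per administration
#' @param plasma_times_h plasma sampling schedule, hours after (last) dose
#' @param milking_offsets_h milking times, hours after the last dose
#' @param noise named list of [assay_noise_model()]s per `matrix.analyte`
#'   (`NULL` disables noise and censoring)
#' @param milk_c0 nominal milk marker-residue concentration at the last
#'   dose, ng/ml (per-animal values drawn log-normally around it)
#' @param milk_c0_cv between-animal CV of the milk starting concentration
#' @param mrl,milk_loq residue limit and milk LOQ, ng/ml
#' @param milking_interval_h milking interval for rounding
#' @param arms which dosing arms to analyse for withdrawal
#' @param augmentation an [augmentation_spec()] for the FDA path
#' @param trapezoid `"loglinear"` or `"linear"` AUC convention
#' @return list of class `"milkwdi_config"`
#' @export
study_config <- function(seed = 1L,
                         cohorts = list(list(name = "lactating", n = 8,
                                             bw_range = c(75, 95),
                                             param_means = true_pk_params(),
                                             between_animal_cv = 0.2)),
                         dose_mg_kg = 1.1,
                         plasma_times_h = c(5, 10, 15, 30, 45, 60) / 60,
                         milking_offsets_h = c(1, 2, 4, 6, 8, 12, 18, 24, 36,
                                               48, 60, 72, 84, 96, 108, 120),
                         noise = default_assay_noise(),
                         milk_c0 = 100, milk_c0_cv = 0.2,
                         mrl = 0.4, milk_loq = 0.9,
                         milking_interval_h = 12,
                         arms = c("single", "multiple"),
                         augmentation = augmentation_spec(),
                         trapezoid = "loglinear") {
  plasma_times_h <- sort(unique(c(plasma_times_h,
                                  c(2, 4, 6, 8, 12, 18, 24, 30, 36, 48, 60, 72))))
  structure(list(seed = as.integer(seed), cohorts = cohorts,
                 dose_mg_kg = dose_mg_kg, plasma_times_h = plasma_times_h,
                 milking_offsets_h = milking_offsets_h, noise = noise,
                 milk_c0 = milk_c0, milk_c0_cv = milk_c0_cv,
                 mrl = mrl, milk_loq = milk_loq,
                 milking_interval_h = milking_interval_h, arms = arms,
                 augmentation = augmentation, trapezoid = trapezoid),
            class = "milkwdi_config")
}

#' Two-group PK parameter comparison with a normality pre-test
#'
#' Shapiro-Wilk per group at alpha = 0.05; if both groups look normal an
#' unpaired two-sided t test (equal variances) is used, otherwise a
#' Mann-Whitney test. Constant groups (Shapiro undefined) are treated as
#' non-normal and flagged; a degenerate all-ties Mann-Whitney returns p = 1
#' with a flag.
#'
#' @param values_a,values_b numeric vectors, >= 3 values each
#' @param parameter_name label carried into the result
#' @param labels group labels
#' @return list of class `"milkwdi_group_cmp"` with `normality_p` (length
#'   2), `test_used`, `p_value`, `flag`
#' @export
compare_parameter_groups <- function(values_a, values_b,
                                     parameter_name = "parameter",
                                     labels = c("A", "B")) {
  stopifnot(length(values_a) >= 3, length(values_b) >= 3)
  shap <- function(v) {
    if (stats::sd(v) == 0) return(NA_real_) # constant: normality undefined
    stats::shapiro.test(v)$p.value
  }
  np <- c(shap(values_a), shap(values_b))
  normal <- !is.na(np) & np >= 0.05
  flag <- NULL
  if (all(normal)) {
    test_used <- "unpaired_t"
    p <- stats::t.test(values_a, values_b, var.equal = TRUE)$p.value
  } else {
    test_used <- "mann_whitney"
    if (stats::sd(c(values_a, values_b)) == 0) {
      p <- 1; flag <- "all values tied; p = 1 by convention"
    } else {
      p <- suppressWarnings(
        stats::wilcox.test(values_a, values_b, exact = FALSE)$p.value)
    }
  }
  structure(list(parameter = parameter_name, labels = labels,
                 normality_p = np, test_used = test_used, p_value = p,
                 flag = flag),
            class = "milkwdi_group_cmp")
}

#' Injection-site reaction score (0-5)
#'
#' One point for swelling under 2 cm, two points for swelling over 2 cm,
#' plus one point each for heat, redness and signs of pain.
#'
#' @param swelling `"none"`, `"under_2cm"` or `"over_2cm"`
#' @param heat,redness,pain logical
#' @return integer score in 0..5
#' @export
injection_site_score <- function(swelling = c("none", "under_2cm", "over_2cm"),
                                 heat = FALSE, redness = FALSE, pain = FALSE) {
  swelling <- match.arg(swelling)
  sw <- c(none = 0L, under_2cm = 1L, over_2cm = 2L)[[swelling]]
  sw + as.integer(isTRUE(heat)) + as.integer(isTRUE(redness)) +
    as.integer(isTRUE(pain))
}

# Simulate plasma both routes for one animal and return NCA + crossover F.
.animal_crossover <- function(animal, cfg, seed_base) {
  reg_iv <- regimen(0, cfg$dose_mg_kg, "IV")
  reg_sc <- regimen(0, cfg$dose_mg_kg, "SC")
  run_route <- function(reg, route, offset) {
    prof <- simulate_plasma_profile(animal$true_params, reg,
                                    cfg$plasma_times_h, animal$id)
    parent <- prof$parent
    if (!is.null(cfg$noise)) {
      parent <- apply_assay_noise(parent, cfg$noise$plasma.FLU,
                                  seed = seed_base + offset)
    }
    nca_single_profile(parent, cfg$dose_mg_kg, route,
                       body_weight_kg = animal$body_weight_kg,
                       method = cfg$trapezoid)
  }
  nca_iv <- run_route(reg_iv, "IV", 1L)
  nca_sc <- run_route(reg_sc, "SC", 2L)
  f <- tryCatch(bioavailability(nca_sc, nca_iv)$f, error = function(e) NA_real_)
  list(nca_iv = nca_iv, nca_sc = nca_sc, f = f)
}

# Per-cohort NCA summary table (mean, sd) mirroring the PK parameter block.
.summarise_nca <- function(nca_list) {
  fields <- c("cmax_obs", "tmax_obs", "t_half_z", "auc_inf", "auc_pct_ext",
              "vz_or_vzf", "cl_or_clf", "aumc_inf", "mrt_inf")
  do.call(rbind, lapply(fields, function(f) {
    v <- vapply(nca_list, function(x) x[[f]], numeric(1))
    data.frame(parameter = f, mean = mean(v, na.rm = TRUE),
               sd = stats::sd(v, na.rm = TRUE), n = sum(!is.na(v)))
  }))
}

# Milk series (empirical mode, noisy) for every lactating animal in one arm.
.simulate_arm_milk <- function(animals, cfg, last_dose_h, seed_base) {
  reg <- if (last_dose_h == 0) regimen(0, cfg$dose_mg_kg, "SC") else
    regimen(seq(0, last_dose_h, by = 12), cfg$dose_mg_kg, "SC")
  lapply(seq_along(animals), function(i) {
    an <- animals[[i]]
    c0 <- if (cfg$milk_c0_cv == 0) cfg$milk_c0 else
      with_seed(seed_base + 7L * i, {
        stats::rlnorm(1, meanlog = log(cfg$milk_c0),
                      sdlog = sqrt(log(1 + cfg$milk_c0_cv^2)))
      })
    s <- simulate_milk_profile(an$true_params, reg,
                               last_dose_h + cfg$milking_offsets_h,
                               mode = "empirical", c0 = c0, animal_id = an$id)
    if (!is.null(cfg$noise)) {
      s <- apply_assay_noise(s, cfg$noise$milk.OH5, seed = seed_base + 977L * i)
    }
    s
  })
}

#' Run the full synthetic-study pipeline
#'
#' Simulates each configured cohort, runs per-animal NCA on both crossover
#' routes, computes per-animal bioavailability, compares clearance and
#' half-life across the first two cohorts when more than one is configured,
#' builds the milk depletion dataset per dosing arm, and computes EMA (95/95)
#' and FDA (99/95, augmented) withdrawal intervals. Not-calculable arms are
#' reported as such, never as numbers. Two runs with an identical config are
#' byte-identical.
#'
#' @param cfg a [study_config()]
#' @return a nested report list of class `"milkwdi_report"`
#' @export
run_study_pipeline <- function(cfg = study_config()) {
  stopifnot(inherits(cfg, "milkwdi_config"))
  report <- list(seed = cfg$seed, cohorts = list(), withdrawal = list())

  cohort_results <- list()
  for (ci in seq_along(cfg$cohorts)) {
    spec <- cfg$cohorts[[ci]]
    animals <- generate_cohort(spec$n, spec$name,
                               param_means = spec$param_means,
                               between_animal_cv = spec$between_animal_cv,
                               bw_range = spec$bw_range,
                               seed = cfg$seed + 101L * ci)
    cross <- lapply(seq_along(animals), function(ai) {
      .animal_crossover(animals[[ai]], cfg,
                        seed_base = cfg$seed + 10000L * ci + 100L * ai)
    })
    nca_iv <- lapply(cross, `[[`, "nca_iv")
    nca_sc <- lapply(cross, `[[`, "nca_sc")
    fs <- vapply(cross, `[[`, numeric(1), "f")
    cohort_results[[spec$name]] <- list(animals = animals,
                                        nca_iv = nca_iv, nca_sc = nca_sc,
                                        f = fs)
    report$cohorts[[spec$name]] <- list(
      n = spec$n,
      summary_iv = .summarise_nca(nca_iv),
      summary_sc = .summarise_nca(nca_sc),
      mean_f = mean(fs, na.rm = TRUE), sd_f = stats::sd(fs, na.rm = TRUE))
  }

  if (length(cfg$cohorts) >= 2) {
    g <- function(res, field) vapply(res, function(x) x[[field]], numeric(1))
    a <- cohort_results[[1]]; b <- cohort_results[[2]]
    labs <- names(cohort_results)[1:2]
    report$group_comparisons <- list(
      CL = compare_parameter_groups(g(a$nca_iv, "cl_or_clf"),
                                    g(b$nca_iv, "cl_or_clf"), "CL", labs),
      t_half = compare_parameter_groups(g(a$nca_iv, "t_half_z"),
                                        g(b$nca_iv, "t_half_z"), "t_half", labs))
  }

  lact <- Filter(function(x) x$animals[[1]]$cohort == "lactating",
                 cohort_results)
  if (length(lact) >= 1) {
    animals <- lact[[1]]$animals
    for (arm in cfg$arms) {
      last_dose_h <- if (arm == "single") 0 else 60
      milk <- .simulate_arm_milk(animals, cfg, last_dose_h,
                                 seed_base = cfg$seed + 555000L +
                                   1000L * match(arm, cfg$arms))
      ema <- tryNotCalculable({
        ds <- build_depletion_dataset(milk, last_dose_time_h = last_dose_h,
                                      loq = cfg$milk_loq, mrl = cfg$mrl)
        ema_sclr(ds, milking_interval_h = cfg$milking_interval_h)
      })
      # FDA path: numeric values for every sample keep the time grid
      # complete across animals (below-LOD values enter as 0; the depletion
      # builder re-censors at the LOQ afterwards)
      milk_long <- do.call(rbind, lapply(milk, function(s) {
        v <- ifelse(is.na(s$conc_ng_ml), 0, s$conc_ng_ml)
        data.frame(animal_id = attr(s, "animal_id"),
                   time_h = s$time_h - last_dose_h, conc_ng_ml = v,
                   stringsAsFactors = FALSE)
      }))
      aug <- cfg$augmentation
      aug$seed <- aug$seed + cfg$seed * 13L
      fda <- tryNotCalculable({
        fda_milk_discard(milk_long, augmentation = aug,
                         loq = cfg$milk_loq, mrl = cfg$mrl,
                         milking_interval_h = cfg$milking_interval_h)
      })
      report$withdrawal[[arm]] <- list(ema = ema, fda = fda)
    }
  }
  class(report) <- "milkwdi_report"
  report
}

#' @export
print.milkwdi_report <- function(x, ...) {
  cat("<study report> seed", x$seed, "\n")
  for (nm in names(x$cohorts)) {
    co <- x$cohorts[[nm]]
    cat(sprintf("cohort %s (n = %d): mean F = %.3f (sd %.3f)\n",
                nm, co$n, co$mean_f, co$sd_f))
  }
  for (arm in names(x$withdrawal)) {
    w <- x$withdrawal[[arm]]
    fmt <- function(r, tag) {
      if (r$ok) sprintf("%s %.1f h (rounded %g h)", tag,
                        r$result$continuous_wdt_h, r$result$rounded_wdt_h)
      else sprintf("%s not calculable (%s)", tag, r$message)
    }
    cat(sprintf("withdrawal [%s]: %s; %s\n", arm,
                fmt(w$ema, "EMA"), fmt(w$fda, "FDA")))
  }
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' @param report a [run_study_pipeline()] result
#' @param path output path
#' @return `path`, invisibly
#' @export
write_report_json <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "milkwdi_wdt")) {
      x <- list(method = x$method, percentile = x$percentile,
                confidence = x$confidence,
                continuous_wdt_h = x$continuous_wdt_h,
                rounded_wdt_h = x$rounded_wdt_h,
                milking_interval_h = x$milking_interval_h,
                mrl_used = x$mrl_used,
                slope = x$fit$slope, residual_sd = x$fit$residual_sd,
                diagnostics = x$diagnostics)
    }
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  jsonlite::write_json(strip(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
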