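#' @title Monte Carlo augmentation of milk residue data
#' @description
#' The FDA residue-depletion calculation requires at least 10 animals and
#' triplicate measurements per sample. Sparse studies (here: 8 animals, one
#' measurement per milk sample) are expanded by Monte Carlo simulation:
#' per-sample replicates drawn around each measured value with the assay's
#' intra-assay CV, and virtual animals drawn per time point from the real
#' animals' mean and SD. Real measurements always pass through unchanged.
#' @name augment
NULL

#' Augmentation specification
#'
#' @param n_replicates_per_sample additional replicates per real measurement
#'   (the study generated 2, for 3 total values per sample)
#' @param intra_assay_cv fraction; the milk marker-residue assay's 3.2%
#' @param n_target_animals required animal count after augmentation (>= 10
#'   for the FDA data contract)
#' @param truncate_at_zero truncate negative Monte Carlo draws to 0
#' @param seed explicit integer seed
#' @return list of class `"milkwdi_augspec"`
#' @export
augmentation_spec <- function(n_replicates_per_sample = 2,
                              intra_assay_cv = 0.032,
                              n_target_animals = 10,
                              truncate_at_zero = TRUE,
                              seed = 1L) {
  stopifnot(n_replicates_per_sample >= 1, intra_assay_cv >= 0,
            n_target_animals >= 1)
  structure(list(n_replicates_per_sample = as.integer(n_replicates_per_sample),
                 intra_assay_cv = intra_assay_cv,
                 n_target_animals = as.integer(n_target_animals),
                 truncate_at_zero = truncate_at_zero,
                 seed = as.integer(seed)),
            class = "milkwdi_augspec")
}

#' Monte Carlo replicate values around one measurement
#'
#' `k` draws from normal(mean = value, sd = cv * value), truncated at zero.
#' Deterministic under the explicit seed.
#'
#' @param value measured concentration, ng/ml (>= 0)
#' @param cv assay coefficient of variation, fraction
#' @param k number of replicates
#' @param seed explicit integer seed
#' @param truncate_at_zero truncate negative draws to 0
#' @return numeric vector of length `k`
#' @export
generate_replicates <- function(value, cv, k, seed, truncate_at_zero = TRUE) {
  stopifnot(value >= 0, cv >= 0, k >= 1)
  if (cv == 0 || value == 0) return(rep(value, k))
  draws <- with_seed(seed, rnorm(k, mean = value, sd = cv * value))
  if (truncate_at_zero) draws <- pmax(0, draws)
  draws
}

# Align observed times across animals onto a common grid within `tol` hours.
# Errors listing the offending times when grids do not match.
.align_time_grid <- function(milk_long, tol = 0.01) {
  animals <- split(milk_long, milk_long$animal_id)
  ref <- sort(animals[[1]]$time_h)
  for (a in animals[-1]) {
    tt <- sort(a$time_h)
    if (length(tt) != length(ref) || any(abs(tt - ref) > tol)) {
      bad <- if (length(tt) != length(ref)) tt else tt[abs(tt - ref) > tol]
      format_error(sprintf(
        "time grids are not alignable within %g h; offending times for animal %s: %s",
        tol, a$animal_id[1], paste(signif(bad, 6), collapse = ", ")))
    }
  }
  ref
}

#' Expand a milk dataset with Monte Carlo replicates and virtual animals
#'
#' Each real measurement contributes itself (replicate 0) plus
#' `n_replicates_per_sample` Monte Carlo replicates drawn with the
#' intra-assay CV. If fewer than `n_target_animals` real animals are present,
#' virtual animals are generated: at every time point on the common grid one
#' value is drawn from normal(mean, SD) of the real animals at that time,
#' truncated at zero, independently across time points. Real records pass
#' through byte-identical.
#'
#' @param milk_long data.frame with columns `animal_id`, `time_h`,
#'   `conc_ng_ml` (one measurement per real animal and time)
#' @param spec an [augmentation_spec()]
#' @param grid_tol time-grid matching tolerance in hours
#' @return data.frame of class `"milkwdi_augmented"` with columns
#'   `animal_id`, `virtual` (logical), `time_h`, `replicate` (0 = the real
#'   or drawn base value), `conc_ng_ml`
#' @export
generate_virtual_animals <- function(milk_long, spec = augmentation_spec(),
                                     grid_tol = 0.01) {
  stopifnot(all(c("animal_id", "time_h", "conc_ng_ml") %in% names(milk_long)))
  real_ids <- unique(milk_long$animal_id)
  n_real <- length(real_ids)
  if (n_real < 2) format_error("augmentation needs >= 2 real animals")
  if (spec$n_target_animals < n_real) {
    format_error(sprintf("n_target_animals (%d) is below the number of real animals (%d)",
                         spec$n_target_animals, n_real))
  }
  grid <- .align_time_grid(milk_long, tol = grid_tol)

  rows <- list()
  seed_i <- spec$seed
  # replicates for real measurements (replicate 0 is the untouched value)
  for (r in seq_len(nrow(milk_long))) {
    v <- milk_long$conc_ng_ml[r]
    rows[[length(rows) + 1L]] <- data.frame(
      animal_id = milk_long$animal_id[r], virtual = FALSE,
      time_h = milk_long$time_h[r],
      replicate = 0:spec$n_replicates_per_sample,
      conc_ng_ml = c(v, generate_replicates(v, spec$intra_assay_cv,
                                            spec$n_replicates_per_sample,
                                            seed = seed_i + r,
                                            spec$truncate_at_zero)),
      stringsAsFactors = FALSE)
  }
  # virtual animals from per-time-point moments of the real animals
  n_virtual <- spec$n_target_animals - n_real
  if (n_virtual > 0) {
    mom <- do.call(rbind, lapply(seq_along(grid), function(j) {
      at <- milk_long$conc_ng_ml[abs(milk_long$time_h - grid[j]) <= grid_tol]
      data.frame(time_h = grid[j], mean = mean(at), sd = stats::sd(at))
    }))
    for (vi in seq_len(n_virtual)) {
      vals <- with_seed(spec$seed + 100003L * vi, {
        rnorm(nrow(mom), mean = mom$mean, sd = mom$sd)
      })
      if (spec$truncate_at_zero) vals <- pmax(0, vals)
      vals[mom$mean == 0 & mom$sd == 0] <- 0 # all-zero times stay zero
      base <- data.frame(animal_id = sprintf("virtual_%02d", vi),
                         virtual = TRUE, time_h = mom$time_h,
                         replicate = 0L, conc_ng_ml = vals,
                         stringsAsFactors = FALSE)
      reps <- do.call(rbind, lapply(seq_len(nrow(base)), function(r) {
        data.frame(animal_id = base$animal_id[r], virtual = TRUE,
                   time_h = base$time_h[r],
                   replicate = seq_len(spec$n_replicates_per_sample),
                   conc_ng_ml = generate_replicates(
                     base$conc_ng_ml[r], spec$intra_assay_cv,
                     spec$n_replicates_per_sample,
                     seed = spec$seed + 100003L * vi + 17L * r,
                     spec$truncate_at_zero),
                   stringsAsFactors = FALSE)
      }))
      rows[[length(rows) + 1L]] <- rbind(base, reps)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$virtual, out$animal_id, out$time_h, out$replicate), ]
  rownames(out) <- NULL
  class(out) <- c("milkwdi_augmented", "data.frame")
  out
}
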