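# Shared fixture builders. All data are generated in code; no files.

# Plasma sampling schedule of the single-dose phase (min converted to h).
phase1_schedule <- function() {
  sort(unique(c(c(5, 10, 15, 30, 45) / 60,
                1, 1.5, 2, 4, 6, 8, 12, 18, 24, 30, 32, 36, 48)))
}

# Exact log-linear milk depletion series for `n_animals`, one series each.
exact_milk_series <- function(n_animals = 2, c0 = 100, lambda = 0.1155,
                              times = c(1, 2, 4, 6, 8, 12, 18, 24, 36, 48)) {
  lapply(seq_len(n_animals), function(i) {
    conc_series(sprintf("goat%02d", i), "OH5", "milk", times,
                c0 * exp(-lambda * times))
  })
}

# Long-format (animal_id, time_h, conc_ng_ml) view of a series list.
series_list_to_long <- function(series_list) {
  do.call(rbind, lapply(series_list, function(s) {
    data.frame(animal_id = attr(s, "animal_id"), time_h = s$time_h,
               conc_ng_ml = s$conc_ng_ml, stringsAsFactors = FALSE)
  }))
}

# Noisy log-linear depletion records on a fixed grid, pooled over animals.
simulate_depletion_records <- function(n_animals = 8,
                                       times = c(2, 6, 12, 24, 36, 48, 60, 72),
                                       log_c0 = log(100), lambda = 0.1155,
                                       sigma = 0.3) {
  do.call(rbind, lapply(seq_len(n_animals), function(i) {
    data.frame(animal_id = sprintf("a%02d", i), time_h = times,
               log_conc = log_c0 - lambda * times +
                 rnorm(length(times), 0, sigma))
  }))
}
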