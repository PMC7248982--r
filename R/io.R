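#' @title Long-format CSV readers and writers
#' @description
#' The pipeline's interchange format is a long-format concentration CSV with
#' header `animal_id,cohort,body_weight_kg,route,analyte,matrix,time_h,
#' conc_ng_ml,censor` (censor in Q/BLQ/BLD) plus a regimen CSV
#' `time_h,dose_mg_kg,route`. Readers validate the schema strictly and
#' report offending rows by line number.
#' @name io
NULL

.CONC_HEADER <- c("animal_id", "cohort", "body_weight_kg", "route", "analyte",
                  "matrix", "time_h", "conc_ng_ml", "censor")

#' Write concentration series to a long-format CSV
#'
#' @param rows data.frame with the canonical columns (see [read_concentration_csv()])
#' @param path output path
#' @return `path`, invisibly
#' @export
write_concentration_csv <- function(rows, path) {
  stopifnot(all(.CONC_HEADER %in% names(rows)))
  utils::write.csv(rows[, .CONC_HEADER], path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Collect simulated series into long-format rows
#'
#' @param series a [conc_series()]
#' @param cohort,body_weight_kg,route per-animal metadata
#' @return data.frame in the canonical column order
#' @export
series_to_rows <- function(series, cohort = NA_character_,
                           body_weight_kg = NA_real_, route = NA_character_) {
  data.frame(animal_id = attr(series, "animal_id"), cohort = cohort,
             body_weight_kg = body_weight_kg, route = route,
             analyte = attr(series, "analyte"), matrix = attr(series, "matrix"),
             time_h = series$time_h, conc_ng_ml = series$conc_ng_ml,
             censor = series$censor, stringsAsFactors = FALSE)
}

#' Read and validate a long-format concentration CSV
#'
#' Enforces the canonical header, known analyte (`FLU`/`OH5`) and matrix
#' (`plasma`/`milk`) values, censor flags in Q/BLQ/BLD, and nonnegative
#' quantified concentrations; violations are reported with data line
#' numbers.
#'
#' @param path CSV path
#' @return validated long data.frame
#' @export
read_concentration_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(raw), .CONC_HEADER)) {
    format_error(sprintf("header must be exactly: %s",
                         paste(.CONC_HEADER, collapse = ",")))
  }
  bad_analyte <- which(!raw$analyte %in% c("FLU", "OH5"))
  if (length(bad_analyte)) {
    format_error(sprintf("unknown analyte '%s' at data row %d",
                         raw$analyte[bad_analyte[1]], bad_analyte[1]))
  }
  bad_matrix <- which(!raw$matrix %in% c("plasma", "milk"))
  if (length(bad_matrix)) {
    format_error(sprintf("unknown matrix '%s' at data row %d",
                         raw$matrix[bad_matrix[1]], bad_matrix[1]))
  }
  bad_censor <- which(!raw$censor %in% c("Q", "BLQ", "BLD"))
  if (length(bad_censor)) {
    format_error(sprintf("unknown censor flag '%s' at data row %d",
                         raw$censor[bad_censor[1]], bad_censor[1]))
  }
  bad_conc <- which(raw$censor == "Q" &
                      (!is.finite(raw$conc_ng_ml) | raw$conc_ng_ml < 0))
  if (length(bad_conc)) {
    format_error(sprintf("invalid quantified concentration at data row %d (value %s)",
                         bad_conc[1], raw$conc_ng_ml[bad_conc[1]]))
  }
  raw
}

#' Split validated long rows back into concentration series
#'
#' @param rows output of [read_concentration_csv()]
#' @return named list of [conc_series()], keyed `animal_id.analyte.matrix`
#' @export
rows_to_series <- function(rows) {
  key <- interaction(rows$animal_id, rows$analyte, rows$matrix, drop = TRUE)
  lapply(split(rows, key), function(g) {
    g <- g[order(g$time_h), , drop = FALSE]
    conc_series(g$animal_id[1], g$analyte[1], g$matrix[1],
                g$time_h, g$conc_ng_ml, g$censor)
  })
}

#' Write / read a dosing-regimen CSV (`time_h,dose_mg_kg,route`)
#'
#' @param reg a [regimen()]
#' @param path CSV path
#' @return `path` / a [regimen()]
#' @export
write_regimen_csv <- function(reg, path) {
  utils::write.csv(as.data.frame(reg), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_regimen_csv
#' @export
read_regimen_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(raw), c("time_h", "dose_mg_kg", "route"))) {
    format_error("regimen header must be exactly: time_h,dose_mg_kg,route")
  }
  if (length(unique(raw$route)) != 1) {
    format_error("all routes must be identical within one regimen arm")
  }
  regimen(raw$time_h, raw$dose_mg_kg, raw$route[1])
}
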