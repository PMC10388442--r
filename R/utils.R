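#' Nutrient columns carried through the pipeline
#'
#' Column names of the food-composition table (per 100 g of food):
#' energy (kJ), protein (g), fat (g), carbohydrates (g), fibre (g),
#' vitamin B6 (mg), folate equivalents (ug), vitamin B12 (ug),
#' vitamin D (ug) and iron (mg).
#'
#' @return Character vector of nutrient column names.
#' @export
dietscreen_nutrients <- function() {
  c("energy_kj", "protein_g", "fat_g", "carb_g", "fibre_g",
    "vitb6_mg", "folate_eq_ug", "vitb12_ug", "vitd_ug", "iron_mg")
}

#' Round half away from zero
#'
#' Nearest-integer rounding with ties going away from zero, the convention
#' used for the percentage tables (e.g. 20/29 respondents -> 69 %).
#' Base [round()] rounds half to even and would disagree on exact halves.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# internal: stop with a classed condition so tests can target error types
ds_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "dietscreen_error"))
}

# internal: check a data frame has the named columns, else schema error
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    ds_abort(
      sprintf("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", ")),
      "dietscreen_schema_error"
    )
  }
  invisible(df)
}

# internal: path to a packaged config/fixture file
ds_extdata <- function(file) {
  path <- system.file("extdata", file, package = "dietscreen")
  if (identical(path, "")) {
    ds_abort(sprintf("packaged file '%s' not found", file),
             "dietscreen_config_error")
  }
  path
}
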