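#' INFOGEST pepsin unit calculator
#'
#' One pepsin unit (U) produces a delta-A280 of 0.001 per minute at
#' pH 2.0 and 37 degC, measured as TCA-soluble products of haemoglobin
#' digestion. Activity per mL of enzyme solution is
#' `(dA280 / minutes / 0.001) * dilution_factor / enzyme_volume_mL`,
#' i.e. the rate is attributed to the volume of enzyme solution added
#' to the reaction.
#'
#' @param a280_sample,a280_blank absorbances at 280 nm; where the blank
#'   exceeds the sample (assay noise), the difference is clamped to 0
#'   with a warning.
#' @param incubation_min incubation time, minutes, > 0.
#' @param enzyme_volume_mL volume of enzyme solution added, mL, > 0.
#' @param dilution_factor dilution of the enzyme solution, >= 1.
#' @return activity in U/mL (vectorized, >= 0).
#' @examples
#' pepsin_units(0.120, 0, incubation_min = 10, enzyme_volume_mL = 0.1)
#' # 120 U/mL
#' @export
pepsin_units <- function(a280_sample, a280_blank = 0, incubation_min,
                         enzyme_volume_mL, dilution_factor = 1) {
  if (any(incubation_min <= 0)) {
    stop("incubation_min must be > 0", call. = FALSE)
  }
  if (any(enzyme_volume_mL <= 0)) {
    stop("enzyme_volume_mL must be > 0", call. = FALSE)
  }
  if (any(dilution_factor < 1)) {
    stop("dilution_factor must be >= 1", call. = FALSE)
  }
  dA <- a280_sample - a280_blank
  if (any(dA < 0)) {
    warning("blank absorbance exceeds sample for some readings; ",
            "clamping delta-A280 to 0", call. = FALSE)
    dA <- pmax(dA, 0)
  }
  (dA / incubation_min / 0.001) * dilution_factor / enzyme_volume_mL
}

#' Specific activity of a powdered enzyme preparation
#'
#' @param u_per_mL activity in U/mL.
#' @param enzyme_conc_mg_per_mL enzyme concentration in mg/mL, > 0.
#' @return activity in U/mg.
#' @export
units_per_mg <- function(u_per_mL, enzyme_conc_mg_per_mL) {
  if (any(enzyme_conc_mg_per_mL <= 0)) {
    stop("enzyme concentration must be > 0", call. = FALSE)
  }
  u_per_mL / enzyme_conc_mg_per_mL
}

#' Activity as percent of a measured optimum
#'
#' `100 * activity / optimum`; values above 100% are allowed (activity
#' at some conditions can exceed the pH 2 / 37 degC reference).
#'
#' @param activity measured activity (same units as `optimum`).
#' @param optimum activity at the optimum condition, > 0.
#' @return percent of optimum.
#' @export
percent_of_optimum <- function(activity, optimum) {
  if (any(optimum <= 0)) stop("optimum must be > 0", call. = FALSE)
  100 * activity / optimum
}

#' Read spectrophotometric assay exports and compute units
#'
#' Expects a CSV with columns `sample_id, a280_sample, a280_blank,
#' incubation_min, enzyme_volume_mL, dilution_factor`.
#'
#' @param path CSV file path.
#' @return the input data.frame with an added `u_per_mL` column.
#' @export
read_assay_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("sample_id", "a280_sample", "a280_blank", "incubation_min",
            "enzyme_volume_mL", "dilution_factor")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("assay CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d$u_per_mL <- pepsin_units(d$a280_sample, d$a280_blank,
                             d$incubation_min, d$enzyme_volume_mL,
                             d$dilution_factor)
  d
}
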