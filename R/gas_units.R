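#' Gas-phase conditions for unit conversion
#'
#' Bundles the constants needed to move between dissolved-gas concentrations
#' and partial pressures at 25 degrees C: the ambient O2 partial pressure and
#' the Henry-law solubilities of CO2 and O2. The CO2 solubility default
#' (0.0334 M bar^-1) is the convention used throughout the kinetic tables;
#' the O2 solubility default (0.001259 M bar^-1) is the 25 degrees C
#' literature value consistent with a CO2/O2 solubility ratio of about 26.5,
#' which links the molar and pressure bases of the Rubisco specificity
#' factor.
#'
#' @param O ambient O2 partial pressure, mbar.
#' @param solubility_CO2 CO2 solubility, M bar^-1.
#' @param solubility_O2 O2 solubility, M bar^-1.
#' @param temperature temperature, degrees C (informational; the model and
#'   all constants are defined at 25).
#'
#' @return An object of class \code{gas_conditions}.
#' @examples
#' cond <- gas_conditions()
#' solubility_ratio(cond)
#' @export
gas_conditions <- function(O = 200, solubility_CO2 = 0.0334,
                           solubility_O2 = 0.001259, temperature = 25) {
  if (!is.numeric(O) || length(O) != 1L || is.na(O) || O < 0)
    stop("`O` must be a single non-negative partial pressure in mbar",
         call. = FALSE)
  if (!is.numeric(solubility_CO2) || solubility_CO2 <= 0 ||
      !is.numeric(solubility_O2) || solubility_O2 <= 0)
    stop("solubilities must be strictly positive (M bar^-1)", call. = FALSE)
  ratio <- solubility_CO2 / solubility_O2
  if (ratio < 20 || ratio > 35)
    stop(sprintf(paste0("CO2/O2 solubility ratio %.2f outside the physically ",
                        "plausible range [20, 35] at 25 degrees C"), ratio),
         call. = FALSE)
  structure(
    list(O = O, solubility_CO2 = solubility_CO2,
         solubility_O2 = solubility_O2, temperature = temperature),
    class = "gas_conditions"
  )
}

#' @export
print.gas_conditions <- function(x, ...) {
  cat("Gas conditions (", x$temperature, " degC)\n", sep = "")
  cat(sprintf("  O2 partial pressure : %g mbar\n", x$O))
  cat(sprintf("  CO2 solubility      : %g M bar^-1\n", x$solubility_CO2))
  cat(sprintf("  O2 solubility       : %g M bar^-1\n", x$solubility_O2))
  cat(sprintf("  solubility ratio    : %.2f\n", solubility_ratio(x)))
  invisible(x)
}

#' CO2/O2 solubility ratio
#'
#' @param cond a \code{\link{gas_conditions}} object.
#' @return The dimensionless ratio solubility_CO2 / solubility_O2.
#' @export
solubility_ratio <- function(cond = gas_conditions()) {
  stopifnot(inherits(cond, "gas_conditions"))
  cond$solubility_CO2 / cond$solubility_O2
}

#' Convert a partial pressure to a dissolved concentration
#'
#' Applies Henry's law at the working solubility: a partial pressure in ubar
#' times a solubility in M bar^-1 gives a dissolved concentration in uM
#' (the 10^-6 factors cancel).
#'
#' @param p partial pressure(s), ubar. Non-negative.
#' @param solubility gas solubility, M bar^-1. Strictly positive.
#' @return Dissolved concentration(s), uM.
#' @examples
#' dissolved_from_pressure(8234, 0.0334)  # ~275 uM CO2
#' @export
dissolved_from_pressure <- function(p, solubility = 0.0334) {
  check_pressure_args(p, solubility)
  p * solubility
}

#' Convert a dissolved concentration to a partial pressure
#'
#' Exact inverse of \code{\link{dissolved_from_pressure}}; the round trip is
#' an identity to machine precision.
#'
#' @param conc dissolved concentration(s), uM. Non-negative.
#' @param solubility gas solubility, M bar^-1. Strictly positive.
#' @return Partial pressure(s), ubar.
#' @examples
#' pressure_from_dissolved(275, 0.0334)  # ~8234 ubar
#' @export
pressure_from_dissolved <- function(conc, solubility = 0.0334) {
  check_pressure_args(conc, solubility)
  conc / solubility
}

check_pressure_args <- function(x, solubility) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0))
    stop("pressures/concentrations must be numeric and non-negative",
         call. = FALSE)
  if (!is.numeric(solubility) || length(solubility) != 1L ||
      is.na(solubility) || solubility <= 0)
    stop("`solubility` must be a single strictly positive value (M bar^-1)",
         call. = FALSE)
  invisible(TRUE)
}

#' Convert the Rubisco specificity factor between bases
#'
#' The CO2/O2 specificity factor S_C/O can be expressed on a dissolved-gas
#' basis (M M^-1) or a partial-pressure basis (bar bar^-1). The two differ by
#' the CO2/O2 solubility ratio: S(pressure) = S(molar) x sCO2/sO2.
#'
#' @param sco specificity factor(s), strictly positive.
#' @param cond a \code{\link{gas_conditions}} object supplying the
#'   solubilities.
#' @return The specificity factor on the other basis.
#' @examples
#' sco_molar_to_pressure(80)   # ~2123 bar bar^-1
#' sco_pressure_to_molar(2123) # ~80 M M^-1
#' @export
sco_molar_to_pressure <- function(sco, cond = gas_conditions()) {
  check_sco(sco)
  sco * solubility_ratio(cond)
}

#' @rdname sco_molar_to_pressure
#' @export
sco_pressure_to_molar <- function(sco, cond = gas_conditions()) {
  check_sco(sco)
  sco / solubility_ratio(cond)
}

check_sco <- function(sco) {
  if (!is.numeric(sco) || any(is.na(sco)) || any(sco <= 0))
    stop("specificity factors must be strictly positive", call. = FALSE)
  invisible(TRUE)
}

#' Small pressure-unit helpers
#'
#' All internal model math is in ubar partial pressure. Interfaces accept
#' mbar and percent (v/v) and convert on ingest; at 1 bar total pressure,
#' 1 percent (v/v) is 10 mbar.
#'
#' @param x value(s) to convert.
#' @return Converted value(s).
#' @examples
#' mbar_to_ubar(200)      # 2e5 ubar
#' percent_vv_to_mbar(2)  # 20 mbar
#' @export
mbar_to_ubar <- function(x) x * 1000

#' @rdname mbar_to_ubar
#' @export
ubar_to_mbar <- function(x) x / 1000

#' @rdname mbar_to_ubar
#' @export
percent_vv_to_mbar <- function(x) x * 10
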