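#' Leaf-level model parameters
#'
#' The leaf state used by the assimilation model: Rubisco active-site
#' content per unit leaf area E, non-photorespiratory CO2 release in the
#' light Rd, electron transport rate J, and ambient O2 partial pressure O.
#' The working defaults for Rd, J and O are the constants used throughout
#' the modelling here (Rd = 1 umol m^-2 s^-1, J = 140 umol m^-2 s^-1,
#' O = 200 mbar at 25 degrees C).
#'
#' @param E Rubisco active-site content, umol sites m^-2. Strictly positive.
#' @param Rd day respiration, umol m^-2 s^-1. Non-negative.
#' @param J electron transport rate, umol m^-2 s^-1. Strictly positive.
#' @param O ambient O2 partial pressure, mbar. Non-negative.
#' @return An object of class \code{leaf_parameters}.
#' @examples
#' leaf_parameters(E = 21.9)
#' @export
leaf_parameters <- function(E, Rd = 1, J = 140, O = 200) {
  if (!is.finite(E) || E <= 0) stop("`E` must be > 0", call. = FALSE)
  if (!is.finite(Rd) || Rd < 0) stop("`Rd` must be >= 0", call. = FALSE)
  if (!is.finite(J) || J <= 0) stop("`J` must be > 0", call. = FALSE)
  if (!is.finite(O) || O < 0) stop("`O` must be >= 0", call. = FALSE)
  structure(list(E = E, Rd = Rd, J = J, O = O), class = "leaf_parameters")
}

#' @export
print.leaf_parameters <- function(x, ...) {
  cat(sprintf(
    "Leaf parameters: E = %g umol sites m^-2, Rd = %g, J = %g umol m^-2 s^-1, O = %g mbar\n",
    x$E, x$Rd, x$J, x$O))
  invisible(x)
}

#' Photorespiratory CO2 compensation point Gamma*
#'
#' Gamma* = 0.5 O / S_C/O with O in ubar and S_C/O on the pressure basis.
#' It is the chloroplastic CO2 pressure at which carboxylation exactly
#' balances photorespiratory release, and appears in both limiting-rate
#' equations of the leaf model.
#'
#' @param sco_pressure specificity factor, bar bar^-1. Strictly positive.
#' @param O ambient O2 partial pressure, mbar.
#' @return Gamma* in ubar.
#' @examples
#' gamma_star(2123)  # ~47 ubar at 200 mbar O2
#' @export
gamma_star <- function(sco_pressure, O = 200) {
  if (any(!is.finite(sco_pressure)) || any(sco_pressure <= 0))
    stop("`sco_pressure` must be strictly positive", call. = FALSE)
  if (any(O < 0)) stop("`O` must be >= 0", call. = FALSE)
  0.5 * mbar_to_ubar(O) / sco_pressure
}

check_pressure_basis <- function(k) {
  stopifnot(inherits(k, "rubisco_kinetics"))
  if (k$basis != "ubar" || (!is.na(k$SCO) && k$sco_basis != "pressure"))
    stop(paste0("basis mismatch: kinetic parameters must be resolved to the ",
                "pressure basis (see resolve_to_pressure()) before model use"),
         call. = FALSE)
  if (is.na(k$SCO))
    stop("the leaf model needs S_C/O; this parameter set has none",
         call. = FALSE)
  invisible(TRUE)
}

#' Rubisco-limited net assimilation
#'
#' A = kcat E (Cc - Gamma*) / (Cc + KC^21\%O2) - Rd, the carboxylation-
#' capacity-limited branch of the leaf model, with KC the apparent (21
#' percent O2) Michaelis constant in ubar and Gamma* = 0.5 O / S_C/O.
#'
#' @param Cc chloroplastic CO2 partial pressure(s), ubar. Non-negative.
#' @param k a \code{\link{rubisco_kinetics}} object on the pressure basis.
#' @param leaf a \code{\link{leaf_parameters}} object.
#' @return Net assimilation, umol m^-2 s^-1 (vectorized over \code{Cc}).
#' @export
rubisco_limited_A <- function(Cc, k, leaf) {
  check_pressure_basis(k)
  stopifnot(inherits(leaf, "leaf_parameters"))
  if (any(Cc < 0)) stop("`Cc` must be non-negative", call. = FALSE)
  gs <- gamma_star(k$SCO, leaf$O)
  k$kcat * leaf$E * (Cc - gs) / (Cc + k$KC_21O2) - leaf$Rd
}

#' Electron-transport-limited net assimilation
#'
#' A = (Cc - Gamma*) J / (4 (Cc + O/S_C/O)) - Rd, the RuBP-regeneration-
#' limited branch. At Cc = Gamma* the numerator vanishes and A = -Rd
#' exactly; as Cc grows A approaches J/4 - Rd.
#'
#' @param Cc chloroplastic CO2 partial pressure(s), ubar.
#' @param sco_pressure specificity factor, bar bar^-1, or a
#'   \code{rubisco_kinetics} object on the pressure basis.
#' @param leaf a \code{\link{leaf_parameters}} object.
#' @return Net assimilation, umol m^-2 s^-1.
#' @export
electron_limited_A <- function(Cc, sco_pressure, leaf) {
  if (inherits(sco_pressure, "rubisco_kinetics")) {
    check_pressure_basis(sco_pressure)
    sco_pressure <- sco_pressure$SCO
  }
  if (any(!is.finite(sco_pressure)) || any(sco_pressure <= 0))
    stop("`sco_pressure` must be strictly positive", call. = FALSE)
  stopifnot(inherits(leaf, "leaf_parameters"))
  if (any(Cc < 0)) stop("`Cc` must be non-negative", call. = FALSE)
  O_ubar <- mbar_to_ubar(leaf$O)
  gs <- 0.5 * O_ubar / sco_pressure
  (Cc - gs) * leaf$J / (4 * (Cc + O_ubar / sco_pressure)) - leaf$Rd
}

#' Net assimilation as the minimum of the two limiting rates
#'
#' @inheritParams rubisco_limited_A
#' @return Pointwise minimum of \code{\link{rubisco_limited_A}} and
#'   \code{\link{electron_limited_A}}, umol m^-2 s^-1.
#' @examples
#' k <- resolve_to_pressure(genotype_kinetics("tobacco-WT"))
#' net_A(c(100, 300, 1000), k, leaf_parameters(E = 21.9))
#' @export
net_A <- function(Cc, k, leaf) {
  pmin(rubisco_limited_A(Cc, k, leaf),
       electron_limited_A(Cc, k$SCO, leaf))
}

#' CO2 compensation point
#'
#' The chloroplastic CO2 partial pressure Gamma at which net assimilation is
#' zero. On the Rubisco-limited branch this has the closed form
#' Gamma = (Vcmax Gamma* + Rd KC) / (Vcmax - Rd) with Vcmax = kcat E, which
#' requires Vcmax > Rd for a finite root. The closed form is cross-checked
#' against a bracketed numeric root of the full minimum model; if the
#' electron-transport branch turns out to be the limiting one at the root
#' (not the case for any of the packaged parameter sets) a warning is
#' emitted and the numeric root returned.
#'
#' @param k a \code{\link{rubisco_kinetics}} object on the pressure basis.
#' @param leaf a \code{\link{leaf_parameters}} object.
#' @return Gamma in ubar.
#' @examples
#' k <- resolve_to_pressure(genotype_kinetics("tobacco-WT"))
#' compensation_point(k, leaf_parameters(E = 21.9))  # ~56 ubar
#' @export
compensation_point <- function(k, leaf) {
  check_pressure_basis(k)
  stopifnot(inherits(leaf, "leaf_parameters"))
  Vcmax <- k$kcat * leaf$E
  if (Vcmax <= leaf$Rd)
    stop("no compensation point: kcat*E must exceed Rd", call. = FALSE)
  gs <- gamma_star(k$SCO, leaf$O)
  gamma <- (Vcmax * gs + leaf$Rd * k$KC_21O2) / (Vcmax - leaf$Rd)
  # which branch is operative at the root?
  if (electron_limited_A(gamma, k$SCO, leaf) <
      rubisco_limited_A(gamma, k, leaf)) {
    warning("electron-transport-limited at the compensation point; returning the numeric root of the minimum model")
    upper <- gamma * 2 + 10
    while (net_A(upper, k, leaf) < 0) upper <- upper * 2
    gamma <- stats::uniroot(function(cc) net_A(cc, k, leaf),
                            lower = gs, upper = upper,
                            tol = 1e-9)$root
  }
  gamma
}

#' Gas-exchange curve container
#'
#' A CO2-response curve: chloroplastic CO2 partial pressure against net
#' assimilation. Curves measured by open gas exchange report Ci, the
#' intercellular pressure; the model treats Cc ~ Ci, and the container
#' records which was actually supplied rather than silently conflating
#' them.
#'
#' @param Cc CO2 partial pressures, ubar. At least 4 distinct, non-negative
#'   values; the curve is stored sorted by increasing pressure.
#' @param A net assimilation, umol m^-2 s^-1, same length.
#' @param genotype genotype label.
#' @param source one of \code{"attached-leaf"}, \code{"leaf-disc-MIMS"},
#'   \code{"synthetic"}.
#' @param supplied_as whether the pressures are true \code{"Cc"} or measured
#'   \code{"Ci"} used under the Cc ~ Ci assumption.
#' @return An object of class \code{gas_exchange_curve} (a data.frame of
#'   \code{Cc} and \code{A} with metadata attributes).
#' @export
gas_exchange_curve <- function(Cc, A, genotype = "",
                               source = c("synthetic", "attached-leaf",
                                          "leaf-disc-MIMS"),
                               supplied_as = c("Cc", "Ci")) {
  source <- match.arg(source)
  supplied_as <- match.arg(supplied_as)
  if (length(Cc) != length(A))
    stop("`Cc` and `A` must have equal length", call. = FALSE)
  if (length(Cc) < 4L)
    stop("a gas-exchange curve needs at least 4 points", call. = FALSE)
  if (any(!is.finite(Cc)) || any(Cc < 0))
    stop("`Cc` must be finite and non-negative", call. = FALSE)
  ord <- order(Cc)
  Cc <- Cc[ord]; A <- A[ord]
  if (any(diff(Cc) <= 0))
    stop("`Cc` values must be distinct", call. = FALSE)
  out <- data.frame(Cc = as.numeric(Cc), A = as.numeric(A))
  attr(out, "genotype") <- genotype
  attr(out, "source") <- source
  attr(out, "supplied_as") <- supplied_as
  class(out) <- c("gas_exchange_curve", "data.frame")
  out
}

#' @export
print.gas_exchange_curve <- function(x, ...) {
  cat(sprintf("Gas-exchange curve [%s] (%s, supplied as %s): %d points, %g-%g ubar\n",
              attr(x, "genotype"), attr(x, "source"), attr(x, "supplied_as"),
              nrow(x), min(x$Cc), max(x$Cc)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Simulate a noiseless CO2-response curve
#'
#' Evaluates the minimum-of-two-rates model on a pressure grid. The forward
#' curve is deterministic and monotone non-decreasing above Gamma*.
#'
#' @param Cc_grid pressure grid, ubar. At least 4 distinct values.
#' @param k a \code{\link{rubisco_kinetics}} object on the pressure basis.
#' @param leaf a \code{\link{leaf_parameters}} object.
#' @param genotype genotype label carried on the output.
#' @return A \code{\link{gas_exchange_curve}} with \code{source =
#'   "synthetic"}.
#' @export
simulate_aci <- function(Cc_grid, k, leaf, genotype = k$label) {
  gas_exchange_curve(Cc_grid, net_A(Cc_grid, k, leaf),
                     genotype = genotype, source = "synthetic",
                     supplied_as = "Cc")
}
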