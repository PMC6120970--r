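#' Rubisco catalytic parameter set
#'
#' Container for the catalytic constants of a Rubisco preparation: turnover
#' rate kcat (s^-1), the Michaelis constant for CO2 measured under N2 and
#' under 21 percent O2 (the latter is the apparent, competitively inhibited
#' constant the leaf model uses), the Michaelis constant for RuBP, and the
#' CO2/O2 specificity factor. Michaelis constants carry a basis tag (uM
#' dissolved or ubar partial pressure) and S_C/O its own (molar or pressure);
#' tags must be resolved to the pressure basis before any leaf-model use,
#' which \code{\link{resolve_to_pressure}} does in one step.
#'
#' @param kcat catalytic turnover rate per active site, s^-1.
#' @param KC_21O2 Michaelis constant for CO2 at 21 percent O2 (apparent).
#' @param KC_N2 Michaelis constant for CO2 under N2, same basis; optional.
#' @param KM_RuBP Michaelis constant for RuBP, uM; optional.
#' @param SCO CO2/O2 specificity factor; optional for morphometry-only use.
#' @param basis basis of the CO2 Michaelis constants: \code{"uM"} or
#'   \code{"ubar"}.
#' @param sco_basis basis of \code{SCO}: \code{"molar"} (M M^-1) or
#'   \code{"pressure"} (bar bar^-1).
#' @param label provenance label (genotype / preparation).
#'
#' @return An object of class \code{rubisco_kinetics}.
#' @examples
#' k <- rubisco_kinetics(kcat = 9.8, KC_21O2 = 275, KC_N2 = 158,
#'                       KM_RuBP = 38, SCO = 55, basis = "uM",
#'                       sco_basis = "molar", label = "CyLS")
#' resolve_to_pressure(k)
#' @export
rubisco_kinetics <- function(kcat, KC_21O2, KC_N2 = NA_real_,
                             KM_RuBP = NA_real_, SCO = NA_real_,
                             basis = c("uM", "ubar"),
                             sco_basis = c("molar", "pressure"),
                             label = "") {
  basis <- match.arg(basis)
  sco_basis <- match.arg(sco_basis)
  for (nm in c("kcat", "KC_21O2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(sprintf("`%s` must be a single strictly positive number", nm),
           call. = FALSE)
  }
  for (nm in c("KC_N2", "KM_RuBP", "SCO")) {
    v <- get(nm)
    if (!is.na(v) && (!is.numeric(v) || v <= 0))
      stop(sprintf("`%s` must be strictly positive when present", nm),
           call. = FALSE)
  }
  # competitive O2 inhibition can only raise the apparent KC
  if (!is.na(KC_N2) && KC_21O2 < KC_N2)
    stop("KC_21O2 < KC_N2 is inconsistent with competitive O2 inhibition",
         call. = FALSE)
  structure(
    list(kcat = kcat, KC_21O2 = KC_21O2, KC_N2 = KC_N2, KM_RuBP = KM_RuBP,
         SCO = SCO, basis = basis, sco_basis = sco_basis, label = label),
    class = "rubisco_kinetics"
  )
}

#' @export
print.rubisco_kinetics <- function(x, ...) {
  cat("Rubisco kinetics", if (nzchar(x$label)) paste0("[", x$label, "]"),
      "\n")
  cat(sprintf("  kcat     : %.3g s^-1\n", x$kcat))
  cat(sprintf("  KC(21%%O2): %.4g %s\n", x$KC_21O2, x$basis))
  if (!is.na(x$KC_N2))
    cat(sprintf("  KC(N2)   : %.4g %s\n", x$KC_N2, x$basis))
  if (!is.na(x$KM_RuBP))
    cat(sprintf("  KM(RuBP) : %.4g uM\n", x$KM_RuBP))
  if (!is.na(x$SCO))
    cat(sprintf("  S_C/O    : %.4g (%s basis)\n", x$SCO, x$sco_basis))
  invisible(x)
}

#' Resolve a kinetic parameter set to the pressure basis
#'
#' Converts dissolved-basis (uM) CO2 Michaelis constants to ubar and a
#' molar-basis specificity factor to bar bar^-1, using the solubilities in
#' \code{cond}. Parameter sets already on the pressure basis are returned
#' unchanged, so the operation is idempotent.
#'
#' @param k a \code{\link{rubisco_kinetics}} object.
#' @param cond a \code{\link{gas_conditions}} object.
#' @return A \code{rubisco_kinetics} object with \code{basis = "ubar"} and
#'   \code{sco_basis = "pressure"}.
#' @export
resolve_to_pressure <- function(k, cond = gas_conditions()) {
  stopifnot(inherits(k, "rubisco_kinetics"))
  if (k$basis == "uM") {
    k$KC_21O2 <- pressure_from_dissolved(k$KC_21O2, cond$solubility_CO2)
    if (!is.na(k$KC_N2))
      k$KC_N2 <- pressure_from_dissolved(k$KC_N2, cond$solubility_CO2)
    k$basis <- "ubar"
  }
  if (!is.na(k$SCO) && k$sco_basis == "molar") {
    k$SCO <- sco_molar_to_pressure(k$SCO, cond)
    k$sco_basis <- "pressure"
  }
  k
}

#' Rubisco assay series
#'
#' A substrate-response series from a radiolabel assay: either a 14CO2
#' carboxylation series (dissolved CO2 30-440 uM is the typical design) or a
#' RuBP series (10-800 uM). Rates may be per leaf area or per active site;
#' when \code{site_content} is given, per-site rates are
#' \code{rate / site_content}.
#'
#' @param conc substrate concentrations, uM. Length >= 3, non-negative, not
#'   all equal.
#' @param rate measured rates, same length as \code{conc}.
#' @param substrate \code{"CO2"} or \code{"RuBP"}.
#' @param o2 assay atmosphere: \code{"21%"} or \code{"N2"}.
#' @param site_content Rubisco active-site content of the assayed material
#'   (umol sites per assay unit); optional.
#' @param replicate replicate identifier.
#' @param label provenance label.
#'
#' @return An object of class \code{assay_dataset} (a data.frame of
#'   \code{conc} and \code{rate} with metadata attributes).
#' @export
assay_dataset <- function(conc, rate, substrate = c("CO2", "RuBP"),
                          o2 = c("21%", "N2"), site_content = NA_real_,
                          replicate = 1L, label = "") {
  substrate <- match.arg(substrate)
  o2 <- match.arg(o2)
  if (length(conc) != length(rate))
    stop("`conc` and `rate` must have equal length", call. = FALSE)
  if (length(conc) < 3L)
    stop("an assay series needs at least 3 points", call. = FALSE)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and non-negative", call. = FALSE)
  if (length(unique(conc)) < 2L)
    stop("concentrations must not all be equal", call. = FALSE)
  out <- data.frame(conc = as.numeric(conc), rate = as.numeric(rate))
  attr(out, "substrate") <- substrate
  attr(out, "o2") <- o2
  attr(out, "site_content") <- site_content
  attr(out, "replicate") <- replicate
  attr(out, "label") <- label
  class(out) <- c("assay_dataset", "data.frame")
  out
}

#' Fit result container
#'
#' @param estimate named numeric vector of parameter estimates.
#' @param se named numeric vector of asymptotic standard errors.
#' @param rss residual sum of squares at the optimum.
#' @param converged logical convergence flag.
#' @param niter iteration count of the winning start.
#' @param seed seed used for multistart jitter, if any.
#' @param n number of observations.
#' @return An object of class \code{fit_result}.
#' @keywords internal
fit_result <- function(estimate, se, rss, converged, niter, seed = NA_integer_,
                       n = NA_integer_) {
  stopifnot(all(se >= 0 | is.na(se)))
  structure(list(estimate = estimate, se = se, rss = rss,
                 converged = converged, niter = niter, seed = seed, n = n),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Least-squares fit", if (!x$converged) "(NOT converged)", "\n")
  tab <- data.frame(estimate = x$estimate, se = x$se)
  print(tab, digits = 5)
  cat(sprintf("  RSS %.6g on n = %s, %d iterations\n", x$rss,
              ifelse(is.na(x$n), "?", x$n), x$niter))
  invisible(x)
}

#' @export
coef.fit_result <- function(object, ...) object$estimate

#' Serialize a fit result to JSON
#'
#' @param x a \code{fit_result}.
#' @param path optional file to write to; when missing the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
fit_result_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "fit_result"))
  obj <- list(parameters = as.list(x$estimate), se = as.list(x$se),
              rss = x$rss, converged = x$converged, iterations = x$niter,
              n = x$n, seed = x$seed)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Fit a Michaelis-Menten curve to an assay series
#'
#' Estimates Vmax and Km of v = Vmax S / (Km + S) by Levenberg-Marquardt
#' least squares with the analytic Jacobian. Starting values come from a
#' Hanes-Woolf linearization (S/v regressed on S); four additional starts
#' jittered up to +/-50 percent around it guard against the occasional bad
#' linearization on noisy designs, with a fixed documented seed so fits are
#' reproducible. Standard errors are the usual asymptotic ones from the
#' Jacobian at the optimum.
#'
#' @param data an \code{\link{assay_dataset}} (or data.frame with \code{conc}
#'   and \code{rate} columns).
#' @param n_starts number of starts (first is the Hanes-Woolf point).
#' @param seed seed for the start jitter.
#' @return A \code{fit_result} with estimates \code{Vmax} and \code{Km}
#'   (Km in the units of the supplied concentrations).
#' @examples
#' S <- c(30, 60, 110, 180, 270, 440)
#' d <- assay_dataset(S, 10 * S / (158 + S))
#' coef(fit_michaelis_menten(d))
#' @export
fit_michaelis_menten <- function(data, n_starts = 5L, seed = 101L) {
  if (!all(c("conc", "rate") %in% names(data)))
    stop("`data` must have `conc` and `rate` columns", call. = FALSE)
  S <- data$conc
  v <- data$rate
  if (length(unique(S)) < 3L)
    stop("invalid design: need at least 3 distinct substrate concentrations",
         call. = FALSE)

  resid_fn <- function(p) v - p[1] * S / (p[2] + S)
  jac_fn <- function(p) {
    # d(resid)/d(Vmax), d(resid)/d(Km); resid = v - model
    cbind(-S / (p[2] + S), p[1] * S / (p[2] + S)^2)
  }

  start0 <- hanes_woolf_start(S, v)
  starts <- matrix(rep(start0, n_starts), ncol = 2, byrow = TRUE)
  if (n_starts > 1L) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    fac <- matrix(stats::runif(2L * (n_starts - 1L), 0.5, 1.5), ncol = 2)
    starts[-1L, ] <- starts[-1L, , drop = FALSE] * fac
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = pmax(starts[i, ], 1e-8), fn = resid_fn, jac = jac_fn,
      lower = c(1e-10, 1e-10),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("Michaelis-Menten fit failed from every start", call. = FALSE)

  conv <- best$info %in% 1:4
  est <- stats::setNames(best$par, c("Vmax", "Km"))
  se <- mm_se(est, S, v)
  res <- fit_result(est, se, best$deviance, conv, best$niter, seed,
                    n = length(S))
  if (!conv) {
    cnd <- simpleError(sprintf("Michaelis-Menten fit did not converge (%s)",
                               best$message))
    cnd$best_attempt <- res
    stop(cnd)
  }
  res
}

hanes_woolf_start <- function(S, v) {
  ok <- v > 0 & S > 0
  if (sum(ok) >= 3L) {
    # S/v = S/Vmax + Km/Vmax  =>  slope = 1/Vmax, intercept = Km/Vmax
    cf <- stats::coef(stats::lm(I(S[ok] / v[ok]) ~ S[ok]))
    Vmax <- 1 / cf[2]
    Km <- cf[1] * Vmax
    if (is.finite(Vmax) && Vmax > 0 && is.finite(Km) && Km > 0)
      return(c(Vmax, Km))
  }
  c(max(v) * 1.2, stats::median(S))
}

mm_se <- function(p, S, v) {
  J <- cbind(S / (p[2] + S), -p[1] * S / (p[2] + S)^2)
  rss <- sum((v - p[1] * S / (p[2] + S))^2)
  df <- length(S) - 2L
  if (df <= 0) return(stats::setNames(c(NA_real_, NA_real_), names(p)))
  sigma2 <- rss / df
  cov <- try(solve(crossprod(J)) * sigma2, silent = TRUE)
  if (inherits(cov, "try-error"))
    return(stats::setNames(c(NA_real_, NA_real_), names(p)))
  stats::setNames(sqrt(pmax(diag(cov), 0)), names(p))
}

# save/restore the global RNG so seeded fits do not perturb user streams
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Catalytic turnover rate from Vmax and site content
#'
#' kcat is the maximal carboxylation rate divided by the Rubisco active-site
#' content of the assayed material (sites titrated by 14C-CABP binding in
#' the laboratory workflow this mirrors).
#'
#' @param Vmax maximal carboxylase activity (e.g. umol CO2 m^-2 s^-1).
#' @param sites active-site content in matching units (e.g. umol sites m^-2).
#' @return kcat, s^-1.
#' @examples
#' kcat_from_vmax(67.89, 21.9)  # ~3.1 s^-1
#' @export
kcat_from_vmax <- function(Vmax, sites) {
  if (any(!is.finite(Vmax)) || any(Vmax < 0))
    stop("`Vmax` must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(sites)) || any(sites <= 0))
    stop("`sites` must be strictly positive", call. = FALSE)
  Vmax / sites
}

#' Michaelis constant for O2 from paired KC measurements
#'
#' Under the competitive model the apparent CO2 Michaelis constant at an O2
#' partial pressure is KC_app = KC (1 + O/KO). Given KC under N2 (no
#' inhibition) and at 21 percent O2, KO = O / (KC_app/KC - 1). When the two
#' KC values coincide there is no detectable inhibition and \code{Inf} is
#' returned as a sentinel.
#'
#' @param KC_N2 Michaelis constant for CO2 under N2, uM.
#' @param KC_21O2 apparent Michaelis constant at the assay O2 level, uM.
#' @param O_dissolved dissolved O2 at the assay condition, uM.
#' @return KO in uM (\code{Inf} when no inhibition is detectable).
#' @examples
#' infer_KO(9.7, 18.3, 252)  # tobacco: ~284 uM
#' @export
infer_KO <- function(KC_N2, KC_21O2, O_dissolved) {
  if (!is.finite(KC_N2) || KC_N2 <= 0 || !is.finite(KC_21O2))
    stop("KC values must be finite and positive", call. = FALSE)
  if (KC_21O2 < KC_N2)
    stop("inconsistent data: KC_21O2 < KC_N2 contradicts competitive O2 inhibition",
         call. = FALSE)
  if (!is.finite(O_dissolved) || O_dissolved <= 0)
    stop("`O_dissolved` must be strictly positive", call. = FALSE)
  if (KC_21O2 == KC_N2) return(Inf)
  O_dissolved / (KC_21O2 / KC_N2 - 1)
}

#' Specificity factor from a labelled-product ratio
#'
#' In the product-ratio determination, RuBP is consumed under a known CO2/O2
#' atmosphere and the labelled 3-PGA and 2-phosphoglycolate are separated
#' and counted. Under the default stoichiometry each carboxylation yields
#' two 3-PGA and each oxygenation one 3-PGA plus one 2-PG, so
#' vc/vo = (PGA/PG - 1)/2; with \code{stoichiometry_mode = "direct"} the
#' signal ratio is taken as vc/vo unchanged. The pressure-basis specificity
#' is then S_C/O = (vc/vo) x (O/C) at the gas-phase partial pressures.
#'
#' @param pga_signal 3-PGA signal (counts), > 0.
#' @param pg_signal 2-phosphoglycolate signal (counts), > 0.
#' @param C_gas CO2 partial pressure of the assay atmosphere, ubar.
#' @param O_gas O2 partial pressure, ubar.
#' @param stoichiometry_mode \code{"2PGA+1PGA/1PG"} (default) or
#'   \code{"direct"}.
#' @return S_C/O on the pressure basis (bar bar^-1), with attribute
#'   \code{basis = "pressure"}.
#' @examples
#' # 500 ppm CO2 in O2: C = 500 ubar, O = 999500 ubar
#' sco_from_product_ratio(3.124, 1, 500, 999500)
#' @export
sco_from_product_ratio <- function(pga_signal, pg_signal, C_gas, O_gas,
                                   stoichiometry_mode = c("2PGA+1PGA/1PG",
                                                          "direct")) {
  stoichiometry_mode <- match.arg(stoichiometry_mode)
  if (pga_signal <= 0 || pg_signal <= 0)
    stop("product signals must be strictly positive", call. = FALSE)
  if (C_gas <= 0 || O_gas <= 0)
    stop("gas partial pressures must be strictly positive", call. = FALSE)
  ratio <- pga_signal / pg_signal
  vcvo <- switch(stoichiometry_mode,
    "2PGA+1PGA/1PG" = {
      if (ratio <= 1)
        stop("invalid ratio: PGA/PG <= 1 implies no carboxylation under the default stoichiometry",
             call. = FALSE)
      (ratio - 1) / 2
    },
    "direct" = ratio
  )
  structure(vcvo * (O_gas / C_gas), basis = "pressure")
}
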