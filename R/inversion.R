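#' Inversion specification for leaf-parameter fitting
#'
#' Declares which model quantities are free in a least-squares fit of the
#' minimum-of-two-rates model to a CO2-response curve. The leaf site
#' content E, the turnover rate kcat, or both may be freed; everything else
#' is fixed by the supplied kinetics and leaf parameters. Because E and
#' kcat enter the Rubisco-limited branch only through their product, they
#' are jointly identifiable only when part of the curve is electron-
#' transport limited.
#'
#' @param free character vector, subset of \code{c("E", "kcat")}.
#' @param lower,upper named bounds per free parameter. Defaults:
#'   E in [0.01, 50] umol sites m^-2, kcat in [0.1, 20] s^-1.
#' @return An object of class \code{inversion_spec}.
#' @examples
#' inversion_spec("E")
#' @export
inversion_spec <- function(free = "E",
                           lower = c(E = 0.01, kcat = 0.1),
                           upper = c(E = 50, kcat = 20)) {
  free <- match.arg(free, c("E", "kcat"), several.ok = TRUE)
  free <- unique(free)
  lower <- lower[free]; upper <- upper[free]
  if (any(is.na(lower)) || any(is.na(upper)))
    stop("bounds must be supplied for every free parameter", call. = FALSE)
  if (any(lower <= 0) || any(!is.finite(upper)) || any(upper <= lower))
    stop("bounds must be positive, finite and ordered", call. = FALSE)
  structure(list(free = free, lower = lower, upper = upper),
            class = "inversion_spec")
}

# substitute free-parameter values into (k, leaf)
apply_free <- function(par, free, k, leaf) {
  if ("E" %in% free) leaf$E <- unname(par["E"])
  if ("kcat" %in% free) k$kcat <- unname(par["kcat"])
  list(k = k, leaf = leaf)
}

#' Fit leaf parameters to a gas-exchange curve
#'
#' Least-squares inversion of the minimum-of-two-rates assimilation model:
#' minimizes the sum of squared residuals between observed A and the model
#' over the free parameters of an \code{\link{inversion_spec}}. The exact
#' hard minimum of the two branches is used (no smoothing of the kink), so
#' the search is derivative-free: golden-section/parabolic search for a
#' single free parameter, Nelder-Mead with seeded multistart for two.
#' Standard errors come from a finite-difference Jacobian of the model at
#' the optimum.
#'
#' When E and kcat are both free and the curve is Rubisco-limited at every
#' point, only their product is identified and the fit aborts with an
#' unidentifiability error; when both are free an identifiability warning
#' is emitted regardless, since the product still dominates the fit.
#'
#' @param curve a \code{\link{gas_exchange_curve}}.
#' @param k a \code{\link{rubisco_kinetics}} object on the pressure basis
#'   (fixed values; \code{kcat} is overwritten when freed).
#' @param leaf a \code{\link{leaf_parameters}} object (fixed values;
#'   \code{E} is overwritten when freed).
#' @param spec an \code{\link{inversion_spec}}.
#' @param n_starts number of Nelder-Mead starts when two parameters are
#'   free.
#' @param seed seed for the multistart jitter.
#' @return A \code{fit_result} with one entry per free parameter.
#' @examples
#' k <- resolve_to_pressure(genotype_kinetics("CyLS"))
#' leaf <- leaf_parameters(E = 1.8)
#' curve <- simulate_aci(seq(50, 1500, length.out = 10), k, leaf)
#' coef(fit_leaf_parameters(curve, k, leaf_parameters(E = 5)))
#' @export
fit_leaf_parameters <- function(curve, k, leaf, spec = inversion_spec("E"),
                                n_starts = 5L, seed = 202L) {
  stopifnot(inherits(curve, "gas_exchange_curve"),
            inherits(spec, "inversion_spec"))
  check_pressure_basis(k)
  if (nrow(curve) < 4L)
    stop("need at least 4 curve points", call. = FALSE)
  if (any(!is.finite(curve$A)))
    stop("curve assimilation values must be finite", call. = FALSE)

  rss_fn <- function(par) {
    par <- stats::setNames(par, spec$free)
    m <- apply_free(par, spec$free, k, leaf)
    sum((curve$A - net_A(curve$Cc, m$k, m$leaf))^2)
  }

  if (length(spec$free) == 2L) {
    warning(paste0("E and kcat enter the Rubisco-limited rate only as a ",
                   "product; the joint fit is weakly identified"),
            call. = FALSE)
  }

  if (length(spec$free) == 1L) {
    opt <- stats::optimize(function(x) rss_fn(x),
                           lower = spec$lower, upper = spec$upper,
                           tol = 1e-10)
    est <- stats::setNames(opt$minimum, spec$free)
    rss <- opt$objective
    niter <- NA_integer_
  } else {
    est <- rss <- NULL
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    mid <- sqrt(spec$lower * spec$upper)
    starts <- rbind(mid,
                    t(replicate(n_starts - 1L,
                                mid * stats::runif(2L, 0.5, 1.5))))
    niter <- 0L
    for (i in seq_len(nrow(starts))) {
      o <- stats::optim(pmin(pmax(starts[i, ], spec$lower), spec$upper),
                        rss_fn, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
      if (is.null(rss) || o$value < rss) {
        est <- stats::setNames(o$par, spec$free)
        rss <- o$value
        niter <- o$counts[["function"]]
      }
    }
    # identifiability: purely Rubisco-limited data cannot split E from kcat
    m <- apply_free(est, spec$free, k, leaf)
    aj <- electron_limited_A(curve$Cc, m$k$SCO, m$leaf)
    ac <- rubisco_limited_A(curve$Cc, m$k, m$leaf)
    if (all(ac <= aj))
      stop(paste0("unidentifiable: curve is Rubisco-limited at every point, ",
                  "so jointly free E and kcat are determined only through ",
                  "their product"), call. = FALSE)
  }

  se <- leaf_fit_se(est, spec$free, curve, k, leaf, rss)
  fit_result(est, se, rss, converged = TRUE,
             niter = if (is.na(niter)) 0L else as.integer(niter),
             seed = seed, n = nrow(curve))
}

leaf_fit_se <- function(est, free, curve, k, leaf, rss) {
  n <- nrow(curve); p <- length(est)
  if (n - p <= 0)
    return(stats::setNames(rep(NA_real_, p), names(est)))
  J <- matrix(0, n, p)
  for (j in seq_len(p)) {
    h <- max(1e-6 * abs(est[j]), 1e-8)
    up <- est; up[j] <- up[j] + h
    dn <- est; dn[j] <- dn[j] - h
    mu <- apply_free(up, free, k, leaf)
    md <- apply_free(dn, free, k, leaf)
    J[, j] <- (net_A(curve$Cc, mu$k, mu$leaf) -
               net_A(curve$Cc, md$k, md$leaf)) / (2 * h)
  }
  sigma2 <- rss / (n - p)
  cov <- try(solve(crossprod(J)) * sigma2, silent = TRUE)
  if (inherits(cov, "try-error"))
    return(stats::setNames(rep(NA_real_, p), names(est)))
  stats::setNames(sqrt(pmax(diag(cov), 0)), names(est))
}

#' Per-point residuals and RMSE of a curve against the model
#'
#' @param curve a \code{\link{gas_exchange_curve}}.
#' @param k a \code{\link{rubisco_kinetics}} object on the pressure basis.
#' @param leaf a \code{\link{leaf_parameters}} object.
#' @return A list with \code{residuals} (observed minus modelled, umol m^-2
#'   s^-1, in curve order), \code{rmse} (root of the mean squared residual)
#'   and \code{n}.
#' @export
residual_report <- function(curve, k, leaf) {
  stopifnot(inherits(curve, "gas_exchange_curve"))
  res <- curve$A - net_A(curve$Cc, k, leaf)
  list(residuals = res, rmse = sqrt(mean(res^2)), n = length(res))
}
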