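#' Default substrate design grids
#'
#' The carboxylation design spans 30-440 uM dissolved 14CO2 and the RuBP
#' design 10-800 uM, each as 8 roughly geometric steps — the working ranges
#' of the radiolabel assays the generator emulates.
#'
#' @param substrate \code{"CO2"} or \code{"RuBP"}.
#' @return Concentration grid, uM.
#' @export
assay_design_grid <- function(substrate = c("CO2", "RuBP")) {
  substrate <- match.arg(substrate)
  rng <- switch(substrate, CO2 = c(30, 440), RuBP = c(10, 800))
  round(exp(seq(log(rng[1]), log(rng[2]), length.out = 8L)), 1)
}

#' Generate a synthetic Michaelis-Menten assay series
#'
#' Rates are exact Michaelis-Menten values Vmax S/(Km+S) with Vmax =
#' kcat x site content, perturbed by multiplicative lognormal-free noise
#' rate x (1 + CV x z), z standard normal. CV = 0 returns the exact curve.
#' Output is bit-reproducible under a fixed seed.
#'
#' @param k a \code{\link{rubisco_kinetics}} object; \code{KC_21O2} or
#'   \code{KC_N2} (per \code{o2}) must be on the uM basis for a CO2 series.
#' @param site_content active-site content of the assayed material; sets
#'   Vmax = kcat x site_content.
#' @param substrate \code{"CO2"} or \code{"RuBP"}.
#' @param o2 atmosphere tag; for CO2 series selects which KC generates the
#'   data.
#' @param conc substrate grid, uM.
#' @param cv multiplicative noise coefficient of variation (>= 0).
#' @param seed integer seed.
#' @param replicate replicate id stamped on the output.
#' @return An \code{\link{assay_dataset}}.
#' @examples
#' k <- genotype_kinetics("CyLS")
#' make_assay(k, site_content = 2.1, cv = 0)
#' @export
make_assay <- function(k, site_content, substrate = c("CO2", "RuBP"),
                       o2 = c("21%", "N2"),
                       conc = assay_design_grid(substrate),
                       cv = 0.05, seed = 1L, replicate = 1L) {
  substrate <- match.arg(substrate)
  o2 <- match.arg(o2)
  stopifnot(inherits(k, "rubisco_kinetics"))
  if (length(conc) == 0L) stop("empty concentration grid", call. = FALSE)
  if (cv < 0) stop("`cv` must be >= 0", call. = FALSE)
  if (!is.finite(site_content) || site_content <= 0)
    stop("`site_content` must be > 0", call. = FALSE)
  Km <- if (substrate == "RuBP") {
    if (is.na(k$KM_RuBP)) stop("kinetics carry no KM_RuBP", call. = FALSE)
    k$KM_RuBP
  } else {
    if (k$basis != "uM")
      stop("CO2 assay generation needs uM-basis kinetics", call. = FALSE)
    if (o2 == "21%") k$KC_21O2 else {
      if (is.na(k$KC_N2)) stop("kinetics carry no KC_N2", call. = FALSE)
      k$KC_N2
    }
  }
  Vmax <- k$kcat * site_content
  mu <- Vmax * conc / (Km + conc)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  rate <- mu * (1 + cv * stats::rnorm(length(conc)))
  assay_dataset(conc, rate, substrate = substrate, o2 = o2,
                site_content = site_content, replicate = replicate,
                label = k$label)
}

#' Generate a synthetic CO2-response curve
#'
#' Evaluates the minimum-of-two-rates model on the grid and adds additive
#' Gaussian noise of standard deviation \code{noise_sd} (default 0.25
#' umol m^-2 s^-1, a free knob chosen to resemble attached-leaf gas-
#' exchange scatter, not a measured quantity). In MIMS mode the grid is
#' extended to 20 mbar (20000 ubar), emulating leaf-disc CO2 responses in
#' the membrane-inlet mass spectrometer.
#'
#' @param k a \code{\link{rubisco_kinetics}} object on the pressure basis.
#' @param leaf a \code{\link{leaf_parameters}} object.
#' @param Cc_grid pressure grid, ubar.
#' @param noise_sd additive noise standard deviation, umol m^-2 s^-1.
#' @param mims logical; extend the grid to 20000 ubar.
#' @param seed integer seed.
#' @return A \code{\link{gas_exchange_curve}}.
#' @examples
#' k <- resolve_to_pressure(genotype_kinetics("CyLS"))
#' make_aci(k, leaf_parameters(E = 1.8), seed = 7)
#' @export
make_aci <- function(k, leaf, Cc_grid = seq(50, 1500, length.out = 12L),
                     noise_sd = 0.25, mims = FALSE, seed = 1L) {
  if (length(Cc_grid) < 4L || any(Cc_grid < 0))
    stop("invalid grid", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (mims) {
    hi <- seq(max(Cc_grid), 20000, length.out = 8L)[-1]
    Cc_grid <- c(Cc_grid, hi)
    if (max(Cc_grid) < 20000) Cc_grid <- c(Cc_grid, 20000)
  }
  mu <- net_A(Cc_grid, k, leaf)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  A <- mu + noise_sd * stats::rnorm(length(mu))
  gas_exchange_curve(Cc_grid, A, genotype = k$label,
                     source = if (mims) "leaf-disc-MIMS" else "synthetic",
                     supplied_as = "Cc")
}

#' Generate a synthetic two-population particle sample
#'
#' Emulates a purified carboxysome preparation: an isometric population
#' whose diameter follows a lognormal law parameterized by its target mode
#' (width = length = diameter), plus an elongated-rod subpopulation with
#' normal width (mean 59, sd 5 nm) and length (mean 437, sd 190 nm)
#' truncated to positive values by resampling. Negative draws are never
#' emitted.
#'
#' @param n total particle count.
#' @param rod_fraction expected fraction of rods (per-particle Bernoulli).
#' @param carb_mode target mode of the carboxysome diameter law, nm.
#' @param carb_sdlog lognormal shape of the carboxysome law.
#' @param rod_width_mean,rod_width_sd rod width law, nm.
#' @param rod_length_mean,rod_length_sd rod length law, nm.
#' @param source source tag for the records.
#' @param seed integer seed.
#' @return Classified-ready \code{\link{particle_records}}.
#' @examples
#' p <- make_particles(200, rod_fraction = 0.16, seed = 3)
#' class_proportions(classify_particles(p))
#' @export
make_particles <- function(n, rod_fraction = 0.04, carb_mode = 100.3,
                           carb_sdlog = 0.08,
                           rod_width_mean = 59, rod_width_sd = 5,
                           rod_length_mean = 437, rod_length_sd = 190,
                           source = "purified", seed = 1L) {
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (rod_fraction < 0 || rod_fraction > 1)
    stop("`rod_fraction` must lie in [0, 1]", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  is_rod <- stats::runif(n) < rod_fraction
  n_rod <- sum(is_rod)
  # lognormal with mode m: meanlog = log(m) + sdlog^2
  d <- stats::rlnorm(n - n_rod, log(carb_mode) + carb_sdlog^2, carb_sdlog)
  w <- rtruncnorm_pos(n_rod, rod_width_mean, rod_width_sd)
  l <- rtruncnorm_pos(n_rod, rod_length_mean, rod_length_sd)
  particle_records(width = c(d, w), length = c(d, l),
                   source = source,
                   replicate = 1L)
}

# positive-truncated normal by resampling; never emits non-positive values
rtruncnorm_pos <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  out <- stats::rnorm(n, mean, sd)
  while (any(out <= 0)) {
    bad <- out <= 0
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  out
}

#' Generate tracking-analysis replicate distributions
#'
#' Emulates repeated nanoparticle-tracking runs over independent
#' preparations: each replicate draws its diameters from the carboxysome
#' lognormal law with a per-replicate multiplicative location jitter
#' (lognormal, CV \code{replicate_cv}) representing preparation-to-
#' preparation variation. With the defaults (19 replicates of 200
#' particles, 6 percent replicate CV) the standard error of the mean
#' replicate mode is of order 1.5 nm, the precision at which such modes
#' are customarily reported.
#'
#' @param n_replicates number of instrument runs.
#' @param n_per particles tracked per run.
#' @param mode target diameter mode, nm.
#' @param sdlog within-run lognormal shape.
#' @param replicate_cv between-replicate location CV.
#' @param seed integer seed.
#' @return A list of \code{\link{size_distribution}} objects.
#' @examples
#' reps <- make_tracking_replicates(seed = 5)
#' distribution_mode(reps)$mode
#' @export
make_tracking_replicates <- function(n_replicates = 19L, n_per = 200L,
                                     mode = 100.3, sdlog = 0.08,
                                     replicate_cv = 0.06, seed = 1L) {
  if (n_replicates < 1L || n_per < 1L)
    stop("replicate and particle counts must be >= 1", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  lapply(seq_len(n_replicates), function(i) {
    shift <- exp(stats::rnorm(1, 0, replicate_cv))
    d <- shift * stats::rlnorm(n_per, log(mode) + sdlog^2, sdlog)
    size_distribution(d, replicate = i)
  })
}
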