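#' Packaged genotype parameter fixtures
#'
#' The package ships catalytic and leaf parameter sets for the wild-type
#' tobacco, CyLS (free cyanobacterial Rubisco) and CyLS-S1S2 (carboxysome-
#' forming) preparations, keyed by genotype. Values are stored on the
#' measurement bases (uM Michaelis constants, molar-basis S_C/O). The two
#' CyLS-S1S2 entries carry the CyLS specificity value, flagged by
#' \code{sco_assumed_from}, because no specificity was determined for
#' those preparations and the enzyme is the same.
#'
#' @param genotype optional genotype key; when missing the whole list is
#'   returned.
#' @return A named list of parameter records (or a single record).
#' @examples
#' names(genotype_params())
#' genotype_params("CyLS")$kcat
#' @export
genotype_params <- function(genotype = NULL) {
  path <- system.file("extdata", "genotype_params.json",
                      package = "carboxyfit", mustWork = TRUE)
  all <- jsonlite::fromJSON(path, simplifyVector = TRUE)$genotypes
  if (is.null(genotype)) return(all)
  if (!genotype %in% names(all))
    stop(sprintf("unknown genotype '%s'; available: %s", genotype,
                 paste(names(all), collapse = ", ")), call. = FALSE)
  all[[genotype]]
}

#' Kinetic parameter set for a packaged genotype
#'
#' @param genotype genotype key (see \code{\link{genotype_params}}).
#' @return A \code{\link{rubisco_kinetics}} object on the measurement bases
#'   (uM / molar); pass through \code{\link{resolve_to_pressure}} before
#'   model use.
#' @examples
#' genotype_kinetics("tobacco-WT")
#' @export
genotype_kinetics <- function(genotype) {
  p <- genotype_params(genotype)
  rubisco_kinetics(
    kcat = p$kcat, KC_21O2 = p$KC_21O2_uM,
    KC_N2 = if (is.null(p$KC_N2_uM)) NA_real_ else p$KC_N2_uM,
    KM_RuBP = if (is.null(p$KM_RuBP)) NA_real_ else p$KM_RuBP,
    SCO = if (is.null(p$SCO_molar)) NA_real_ else p$SCO_molar,
    basis = "uM", sco_basis = "molar", label = genotype)
}

#' Leaf parameters for a packaged genotype
#'
#' @param genotype genotype key.
#' @param use_fitted use the model-fit site content (\code{E_fitted}) where
#'   one exists, instead of the directly measured content.
#' @param ... further arguments passed to \code{\link{leaf_parameters}}
#'   (Rd, J, O).
#' @return A \code{\link{leaf_parameters}} object.
#' @export
genotype_leaf <- function(genotype, use_fitted = FALSE, ...) {
  p <- genotype_params(genotype)
  E <- if (use_fitted && !is.null(p$E_fitted)) p$E_fitted else p$E
  if (is.null(E))
    stop(sprintf("genotype '%s' has no leaf site content", genotype),
         call. = FALSE)
  leaf_parameters(E = E, ...)
}

# ---- delimited-text IO ------------------------------------------------------

#' Read and write gas-exchange curves as delimited text
#'
#' Curve files are tab-separated with a header of \code{Cc_ubar} (or
#' \code{Ci_ubar}), \code{A_umol_m2_s} and optionally \code{genotype}; the
#' pressure column name records whether chloroplastic or intercellular
#' pressure was supplied.
#'
#' @param path file path.
#' @return \code{read_curve} returns a \code{\link{gas_exchange_curve}};
#'   \code{write_curve} returns \code{path} invisibly.
#' @export
read_curve <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  pc <- intersect(c("Cc_ubar", "Ci_ubar"), names(d))
  if (length(pc) == 0L || !"A_umol_m2_s" %in% names(d))
    stop("curve file needs columns Cc_ubar (or Ci_ubar) and A_umol_m2_s",
         call. = FALSE)
  gas_exchange_curve(
    d[[pc[1]]], d$A_umol_m2_s,
    genotype = if ("genotype" %in% names(d)) as.character(d$genotype[1]) else "",
    source = "attached-leaf",
    supplied_as = if (pc[1] == "Ci_ubar") "Ci" else "Cc")
}

#' @rdname read_curve
#' @param curve a \code{\link{gas_exchange_curve}}.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "gas_exchange_curve"))
  pc <- if (attr(curve, "supplied_as") == "Ci") "Ci_ubar" else "Cc_ubar"
  d <- data.frame(curve$Cc, curve$A, attr(curve, "genotype"))
  names(d) <- c(pc, "A_umol_m2_s", "genotype")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write assay series as delimited text
#'
#' Assay files are tab-separated with header \code{substrate_kind},
#' \code{conc_uM}, \code{rate}, \code{o2_condition}, \code{replicate}.
#'
#' @param path file path.
#' @param site_content site content to attach (supplied per dataset in
#'   configuration, not stored in the data file).
#' @return \code{read_assay} returns an \code{\link{assay_dataset}}.
#' @export
read_assay <- function(path, site_content = NA_real_) {
  d <- utils::read.delim(path, check.names = FALSE)
  need <- c("substrate_kind", "conc_uM", "rate", "o2_condition", "replicate")
  if (!all(need %in% names(d)))
    stop("assay file needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  assay_dataset(d$conc_uM, d$rate,
                substrate = as.character(d$substrate_kind[1]),
                o2 = as.character(d$o2_condition[1]),
                site_content = site_content,
                replicate = d$replicate[1])
}

#' @rdname read_assay
#' @param assay an \code{\link{assay_dataset}}.
#' @export
write_assay <- function(assay, path) {
  stopifnot(inherits(assay, "assay_dataset"))
  d <- data.frame(substrate_kind = attr(assay, "substrate"),
                  conc_uM = assay$conc, rate = assay$rate,
                  o2_condition = attr(assay, "o2"),
                  replicate = attr(assay, "replicate"))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read particle measurements as delimited text
#'
#' Particle files are tab-separated with header \code{width_nm},
#' \code{length_nm} (or a single \code{diameter_nm}), \code{source},
#' \code{replicate}.
#'
#' @param path file path.
#' @return A \code{\link{particle_records}} data.frame.
#' @export
read_particles <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  src <- if ("source" %in% names(d)) as.character(d$source[1]) else "section"
  rep_ <- if ("replicate" %in% names(d)) d$replicate else 1L
  if ("diameter_nm" %in% names(d))
    return(particle_records(d$diameter_nm, d$diameter_nm,
                            source = src, replicate = rep_))
  if (!all(c("width_nm", "length_nm") %in% names(d)))
    stop("particle file needs width_nm+length_nm or diameter_nm columns",
         call. = FALSE)
  particle_records(d$width_nm, d$length_nm, source = src, replicate = rep_)
}

# ---- batch reports ----------------------------------------------------------

#' Derived catalytic-parameter table from assay batches
#'
#' Fits a Michaelis-Menten curve to every assay series, derives kcat from
#' the fitted Vmax and the per-dataset site content, and lays the result
#' out with Michaelis constants in uM alongside their bracketed ubar
#' conversions and, where supplied, S_C/O on both bases. Full-precision
#' values are returned; rounding to the reporting convention (three
#' significant figures, whole ubar) is left to the caller or the CLI.
#'
#' @param assays a list of \code{\link{assay_dataset}} objects (CO2 or RuBP
#'   series; each carries its site content and labels).
#' @param sco optional named numeric vector of molar-basis specificity
#'   factors keyed by assay label.
#' @param cond a \code{\link{gas_conditions}} object for the conversions.
#' @return A data.frame with one row per assay series. Fit failures are
#'   reported per row (\code{converged = FALSE}) without aborting the
#'   batch. An empty assay list yields an empty table with a warning.
#' @export
run_kinetics_table <- function(assays, sco = NULL, cond = gas_conditions()) {
  cols <- c("genotype", "substrate", "o2_condition", "n_points",
            "Vmax", "kcat_s", "Km_uM", "Km_ubar",
            "SCO_M_M", "SCO_bar_bar", "converged")
  if (length(assays) == 0L) {
    warning("no assay series supplied; returning an empty table")
    out <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(cols)), cols))
    return(out)
  }
  rows <- lapply(assays, function(a) {
    lab <- attr(a, "label"); sub <- attr(a, "substrate")
    sites <- attr(a, "site_content")
    fit <- tryCatch(fit_michaelis_menten(a), error = function(e) e)
    failed <- inherits(fit, "error")
    Vmax <- if (failed) NA_real_ else unname(coef(fit)["Vmax"])
    Km <- if (failed) NA_real_ else unname(coef(fit)["Km"])
    s <- if (!is.null(sco) && lab %in% names(sco)) sco[[lab]] else NA_real_
    data.frame(
      genotype = lab, substrate = sub, o2_condition = attr(a, "o2"),
      n_points = nrow(a),
      Vmax = Vmax,
      kcat_s = if (!failed && is.finite(sites) && sites > 0)
        kcat_from_vmax(Vmax, sites) else NA_real_,
      Km_uM = Km,
      Km_ubar = if (!failed && sub == "CO2")
        pressure_from_dissolved(Km, cond$solubility_CO2) else NA_real_,
      SCO_M_M = s,
      SCO_bar_bar = if (is.na(s)) NA_real_ else sco_molar_to_pressure(s, cond),
      converged = !failed,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Model report: compensation points, fits and simulated curves
#'
#' For each requested packaged genotype, resolves its kinetics to the
#' pressure basis, computes Gamma* and the CO2 compensation point, and
#' simulates a dense forward curve for plotting. When observed curves are
#' supplied they are refit for the free parameter and a residual report is
#' attached; per-genotype fit failures are recorded without aborting the
#' batch.
#'
#' @param genotypes character vector of packaged genotype keys that carry a
#'   leaf site content.
#' @param curves optional named list of \code{\link{gas_exchange_curve}}
#'   objects keyed by genotype, each refit for \code{E}.
#' @param cond a \code{\link{gas_conditions}} object.
#' @param Cc_max upper end of the simulated pressure grid, ubar.
#' @param use_fitted use fitted site contents where available (see
#'   \code{\link{genotype_leaf}}).
#' @return A list with \code{gamma_table} (genotype, Gamma*, Gamma in
#'   ubar), \code{curves} (dense simulated curves) and \code{fits}
#'   (per-genotype \code{fit_result} or error message).
#' @examples
#' rep <- run_model_report(c("tobacco-WT", "CyLS"))
#' rep$gamma_table
#' @export
run_model_report <- function(genotypes = c("tobacco-WT", "CyLS",
                                           "CyLS-S1S2-free"),
                             curves = NULL, cond = gas_conditions(),
                             Cc_max = 2000, use_fitted = FALSE) {
  sims <- list(); fits <- list()
  tab <- lapply(genotypes, function(g) {
    k <- resolve_to_pressure(genotype_kinetics(g), cond)
    leaf <- genotype_leaf(g, use_fitted = use_fitted, O = cond$O)
    gs <- gamma_star(k$SCO, leaf$O)
    gamma <- tryCatch(compensation_point(k, leaf),
                      error = function(e) NA_real_)
    grid <- seq(0, Cc_max, length.out = 200L)
    sims[[g]] <<- simulate_aci(grid, k, leaf, genotype = g)
    if (!is.null(curves) && g %in% names(curves)) {
      fits[[g]] <<- tryCatch({
        f <- fit_leaf_parameters(curves[[g]], k, leaf)
        m <- apply_free(coef(f), "E", k, leaf)
        f$residual_report <- residual_report(curves[[g]], m$k, m$leaf)
        f
      }, error = function(e) conditionMessage(e))
    }
    data.frame(genotype = g, E = leaf$E, gamma_star_ubar = gs,
               gamma_ubar = gamma, stringsAsFactors = FALSE)
  })
  list(gamma_table = do.call(rbind, tab), curves = sims, fits = fits)
}

#' Write a run manifest
#'
#' Records the configuration, seed and package version of a pipeline run
#' alongside its outputs, so any run can be reproduced from its output
#' directory alone.
#'
#' @param dir output directory (created if needed).
#' @param config named list of configuration values.
#' @param seed the seed used for the run.
#' @return Path of the written manifest, invisibly.
#' @export
write_manifest <- function(dir, config = list(), seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "manifest.json")
  obj <- list(package = "carboxyfit",
              version = as.character(utils::packageVersion("carboxyfit")),
              seed = seed, timestamp = format(Sys.time(), tz = "UTC"),
              config = config)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), path)
  invisible(path)
}
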