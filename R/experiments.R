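#' Specify an in-silico drought experiment
#'
#' Three experiment families are supported: `"validation"` (irrigation
#' regimes WW/WL crossed with HC/LC soils, staged canopy development),
#' `"sensitivity"` (stem-VC parameter sets crossed with the E1-E3 drought
#' scenarios on the field-mean soil at fixed LAI 3.5), and `"gxe"` (two
#' contrasting genotypes crossed with HC/LC soils and E1-E3, the 12-run
#' factorial probing soil-by-genotype ranking flips).
#'
#' @param experiment `"validation"`, `"sensitivity"` or `"gxe"`.
#' @param genotypes Character names of genotype presets from
#'   [default_params()] (defaults depend on the experiment).
#' @param soils Character names of soil presets.
#' @param scenarios Subset of `c("E1", "E2", "E3")` (ignored for
#'   validation, which uses WW/WL irrigation regimes).
#' @param n_days Simulated days (default 81 = DOY 160-240).
#' @param drought_start_doy Day the scenarios diverge (default 188).
#' @param seed Integer seed for the synthetic forcing.
#' @param out_dir Optional directory for per-run output tables.
#' @return Object of class `experiment_spec`.
#' @export
experiment_spec <- function(experiment = c("validation", "sensitivity", "gxe"),
                            genotypes = NULL, soils = NULL, scenarios = NULL,
                            n_days = 81, drought_start_doy = 188, seed = 42L,
                            out_dir = NULL) {
  experiment <- match.arg(experiment)
  dp <- default_params()
  if (is.null(genotypes))
    genotypes <- switch(experiment,
      validation = "species",
      sensitivity = names(dp$genotypes),
      gxe = c("TipoChaco", "DP1549"))
  if (is.null(soils))
    soils <- switch(experiment,
      validation = c("HC", "LC"),
      sensitivity = "mean",
      gxe = c("HC", "LC"))
  if (is.null(scenarios))
    scenarios <- if (experiment == "validation") c("WW", "WL")
                 else c("E1", "E2", "E3")
  bad_g <- setdiff(genotypes, names(dp$genotypes))
  if (length(bad_g)) stop("unknown genotype preset(s): ",
                          paste(bad_g, collapse = ", "))
  bad_s <- setdiff(soils, names(dp$soils))
  if (length(bad_s)) stop("unknown soil preset(s): ",
                          paste(bad_s, collapse = ", "))
  structure(list(experiment = experiment, genotypes = genotypes,
                 soils = soils, scenarios = scenarios, n_days = n_days,
                 drought_start_doy = drought_start_doy,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_spec")
}

.scenario_forcings <- function(spec) {
  if (spec$experiment == "validation") {
    ww <- gen_meteo(n_days = spec$n_days,
                    irrigation = list(interval_days = 1, depth_mm = 18,
                                      hour = 6),
                    seed = spec$seed)
    wl <- ww
    late <- wl$doy >= spec$drought_start_doy
    wl$water_input[late] <- wl$water_input[late] * 0.25
    list(WW = ww, WL = wl)
  } else {
    base <- gen_meteo(n_days = spec$n_days,
                      irrigation = list(interval_days = 2, depth_mm = 16,
                                        hour = 6),
                      seed = spec$seed)
    ss <- build_scenarios(base, spec$drought_start_doy,
                          multipliers = c(1, 0.5, 0.25))
    list(E1 = ss$e1, E2 = ss$e2, E3 = ss$e3)
  }
}

#' Run a full factorial in-silico experiment
#'
#' Generates the forcing and drought scenarios, runs every
#' genotype x soil x scenario member of the factorial, computes per-day
#' stress metrics, and (for the G x E experiment) the midday transpiration
#' divergence report per scenario. A manifest records the configuration
#' signature and seed of every run; reruns with the same spec are
#' reproducible.
#'
#' @param spec An [experiment_spec()].
#' @param quiet Suppress progress messages.
#' @return Object of class `experiment_result`: `runs` (named list of
#'   `planthydro_sim`), `daily` (named list of per-day metrics),
#'   `divergence` (G x E only: per-scenario `divergence_report`),
#'   `manifest` (data.frame).
#' @export
run_experiment <- function(spec, quiet = TRUE) {
  stopifnot(inherits(spec, "experiment_spec"))
  dp <- default_params()
  forcings <- .scenario_forcings(spec)
  forcings <- forcings[spec$scenarios]
  lai <- if (spec$experiment == "validation") dp$lai_validation
         else dp$lai_sensitivity

  # anchor element conductances to the species-level parameterization per
  # soil, so genotype variants differ only in vulnerability-curve shape
  species_mult <- lapply(spec$soils, function(s) {
    hyd <- pedotransfer(dp$soils[[s]])
    build_continuum(dp$species, hyd, hyd$theta_s,
                    lai = lai_at(lai, 1e6),
                    root_profile = dp$root_profile)$calib_mult
  })
  names(species_mult) <- spec$soils

  grid <- expand.grid(genotype = spec$genotypes, soil = spec$soils,
                      scenario = spec$scenarios, stringsAsFactors = FALSE)
  runs <- vector("list", nrow(grid))
  daily <- vector("list", nrow(grid))
  ids <- character(nrow(grid))
  if (!is.null(spec$out_dir))
    dir.create(spec$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(grid))) {
    g <- grid$genotype[i]; s <- grid$soil[i]; sc <- grid$scenario[i]
    id <- paste(g, s, sc, sep = "_")
    ids[i] <- id
    if (!quiet) message("run ", i, "/", nrow(grid), ": ", id)
    cfg <- sim_config(dp$genotypes[[g]], pedotransfer(dp$soils[[s]]),
                      lai = lai, root_profile = dp$root_profile,
                      calib_mult = species_mult[[s]], seed = spec$seed)
    sim <- run_simulation(cfg, forcings[[sc]])
    runs[[i]] <- sim
    daily[[i]] <- daily_metrics(sim)
    if (!is.null(spec$out_dir)) {
      rd <- file.path(spec$out_dir, id)
      dir.create(rd, showWarnings = FALSE)
      utils::write.csv(sim$steps, file.path(rd, "steps.csv"),
                       row.names = FALSE)
      utils::write.csv(daily[[i]], file.path(rd, "daily.csv"),
                       row.names = FALSE)
    }
  }
  names(runs) <- ids
  names(daily) <- ids

  divergence <- NULL
  if (spec$experiment == "gxe" && length(spec$genotypes) == 2 &&
      all(c("HC", "LC") %in% spec$soils)) {
    ga <- spec$genotypes[1]; gb <- spec$genotypes[2]
    divergence <- lapply(spec$scenarios, function(sc) {
      d_soil <- lapply(c("HC", "LC"), function(s) {
        a <- daily[[paste(ga, s, sc, sep = "_")]]
        b <- daily[[paste(gb, s, sc, sep = "_")]]
        suppressWarnings(delta_series(a$e_c_md, b$e_c_md))
      })
      divergence_days(d_soil[[1]], d_soil[[2]],
                      doy = daily[[1]]$doy)
    })
    names(divergence) <- spec$scenarios
  }

  manifest <- data.frame(
    run_id = ids, genotype = grid$genotype, soil = grid$soil,
    scenario = grid$scenario, seed = spec$seed, n_days = spec$n_days,
    drought_start_doy = spec$drought_start_doy,
    config_signature = vapply(seq_len(nrow(grid)), function(i) {
      g <- dp$genotypes[[grid$genotype[i]]]
      paste0("gsref=", g$gsref, ";esat=", g$e_sat, ";b=", signif(g$vc_shoot$b, 6),
             ";c=", g$vc_shoot$c, ";soil=", grid$soil[i],
             ";scenario=", grid$scenario[i], ";seed=", spec$seed)
    }, character(1)))
  if (!is.null(spec$out_dir))
    utils::write.csv(manifest, file.path(spec$out_dir, "manifest.csv"),
                     row.names = FALSE)

  structure(list(runs = runs, daily = daily, divergence = divergence,
                 manifest = manifest, spec = spec),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment:", x$spec$experiment, "-", length(x$runs), "runs\n")
  cat("  factors: genotypes (", paste(x$spec$genotypes, collapse = ", "),
      ") x soils (", paste(x$spec$soils, collapse = ", "),
      ") x scenarios (", paste(x$spec$scenarios, collapse = ", "), ")\n")
  if (!is.null(x$divergence)) {
    for (sc in names(x$divergence)) {
      cat("  divergence under", sc, ":",
          length(x$divergence[[sc]]$flagged_days), "flagged day(s),",
          nrow(x$divergence[[sc]]$windows), "window(s)\n")
    }
  }
  invisible(x)
}
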