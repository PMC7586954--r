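#' Staged leaf area index schedule
#'
#' Canopy development approximated as a nondecreasing step function of day of
#' year, with 3-5 stages (or a single constant value).
#'
#' @param breakpoints data.frame with columns `doy` and `lai`, or a single
#'   numeric LAI for constant mode.
#' @return Object of class `lai_schedule`.
#' @export
lai_schedule <- function(breakpoints) {
  if (is.numeric(breakpoints) && length(breakpoints) == 1L)
    breakpoints <- data.frame(doy = 0, lai = breakpoints)
  bp <- as.data.frame(breakpoints)
  stopifnot(all(c("doy", "lai") %in% names(bp)))
  bp <- bp[order(bp$doy), , drop = FALSE]
  if (nrow(bp) > 5L) stop("at most 5 stages")
  if (is.unsorted(bp$lai)) stop("lai stages must be nondecreasing")
  if (any(bp$lai <= 0) || any(bp$lai > 8)) stop("lai must lie in (0, 8]")
  structure(list(breakpoints = bp), class = "lai_schedule")
}

#' Evaluate an LAI schedule
#' @param schedule A [lai_schedule()].
#' @param doy Day(s) of year.
#' @return LAI value(s).
#' @export
lai_at <- function(schedule, doy) {
  bp <- schedule$breakpoints
  idx <- findInterval(doy, bp$doy)
  bp$lai[pmax(1L, idx)]
}

#' Simulation configuration
#'
#' Bundles the genotype, soil and numerical settings for the half-hourly
#' season loop. Five 30-cm soil layers (0-150 cm) match the soil sampling
#' scheme; layer water capacity in mm is `theta * 300`.
#'
#' @param genotype A [genotype_params()].
#' @param soil A `soil_hydraulic_params` (uniform profile) or list of one per
#'   layer.
#' @param lai A [lai_schedule()] or single numeric (fixed LAI).
#' @param root_profile Per-layer root area fractions.
#' @param initial_theta `"fc"` (field capacity, the default) or a numeric
#'   vector of per-layer water contents.
#' @param drainage_rate Fraction of the above-field-capacity excess drained
#'   per day (default 0.5).
#' @param cap_frac Stomatal regulation cap as a fraction of instantaneous
#'   critical transpiration (default 0.9).
#' @param split Root share of saturated whole-plant resistance (default 0.5).
#' @param path_factor Rhizosphere path length in particle diameters.
#' @param layer_mm Layer thickness in mm (default 300).
#' @param n_layers Number of soil layers (default 5).
#' @param patm Atmospheric pressure, kPa.
#' @param oren_m Stomatal VPD sensitivity slope.
#' @param calib_mult Optional fixed element-conductance multiplier passed to
#'   [build_continuum()]. Used to anchor genotype-variant runs to a common
#'   (e.g. species-level) hydraulic plumbing so that runs differ only in
#'   vulnerability-curve shape; `NULL` (default) calibrates against this
#'   genotype's own curves.
#' @param seed Integer seed for any stochastic initialisation (unused by the
#'   deterministic defaults, recorded for reproducibility).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(genotype, soil, lai = 3.5,
                       root_profile = c(0.35, 0.25, 0.20, 0.12, 0.08),
                       initial_theta = "fc", drainage_rate = 0.5,
                       cap_frac = 0.9, split = 0.5, path_factor = 100,
                       layer_mm = 300, n_layers = 5, patm = 101.325,
                       oren_m = 0.6, calib_mult = NULL, seed = 1L) {
  stopifnot(inherits(genotype, "genotype_params"))
  if (!inherits(lai, "lai_schedule")) lai <- lai_schedule(lai)
  if (length(root_profile) != n_layers)
    stop("root_profile length must equal n_layers")
  if (inherits(soil, "soil_hydraulic_params"))
    soil <- rep(list(soil), n_layers)
  structure(list(genotype = genotype, soil = soil, lai = lai,
                 root_profile = root_profile / sum(root_profile),
                 initial_theta = initial_theta,
                 drainage_rate = drainage_rate, cap_frac = cap_frac,
                 split = split, path_factor = path_factor,
                 layer_mm = layer_mm, n_layers = n_layers, patm = patm,
                 oren_m = oren_m, calib_mult = calib_mult,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# mm of water transpired per half-hour step per unit of flux
# (mmol m-2 ground s-1): 18 mg/mmol over 1800 s = 0.0324 mm
.MM_PER_FLUX_STEP <- 18e-6 * 1800  # mm per (mmol m-2 s-1) per 30-min step

#' Advance the simulation by one half-hourly step
#'
#' Order of operations: (1) infiltrate water input top-down, filling each
#' layer to field capacity before passing excess (overflow past the bottom
#' layer leaves the profile as drainage); (2) stomatal demand from the
#' meteorological record; (3) supply-demand solve against current soil
#' potentials; (4) remove uptake from layers; (5) relax layers above field
#' capacity toward it at the configured drainage rate, cascading downward.
#' The water balance closes exactly by construction.
#'
#' @param state List with `theta` (per-layer water content) and `net` (the
#'   `hydraulic_network`), as produced by [init_sim_state()].
#' @param meteo One-row data.frame with `doy`, `hour`, `par`, `t_air`,
#'   `vpd`, `wind`, `water_input`.
#' @param config A [sim_config()].
#' @return Updated state; the step's fluxes are in `state$record`.
#' @export
step_halfhour <- function(state, meteo, config) {
  nl <- config$n_layers
  theta <- state$theta
  fc <- state$theta_fc
  lmm <- config$layer_mm

  # (1) infiltration: fill to field capacity top-down
  w <- meteo$water_input
  infil <- 0
  if (w > 0) {
    for (i in seq_len(nl)) {
      room <- max(0, (fc[i] - theta[i]) * lmm)
      add <- min(w, room)
      theta[i] <- theta[i] + add / lmm
      w <- w - add
      infil <- infil + add
      if (w <= 0) break
    }
  }
  overflow <- w  # water the profile could not hold

  # (2) demand
  lai <- lai_at(config$lai, meteo$doy)
  e_dem_ground <- if (meteo$par > 1e-9 && meteo$vpd > 0) {
    stomatal_demand(config$genotype, meteo$vpd, lai, meteo$par,
                    patm = config$patm, m = config$oren_m)
  } else 0

  # (3) supply-demand solve (fluxes per unit leaf area); zero-demand steps
  # with unchanged soil state reuse the previous solve (identical inputs)
  if (e_dem_ground <= 0 && !is.null(state$cache) &&
      isTRUE(all(abs(theta - state$cache$theta) < 1e-12))) {
    net <- state$net
    st <- state$cache$st
  } else {
    net <- update_soil_state(state$net, theta)
    st <- solve_demand(net, e_target = e_dem_ground / lai)
    if (e_dem_ground <= 0)
      state$cache <- list(theta = theta, st = st)
    else state$cache <- NULL
  }

  # (4) uptake removal, guarded against driving layers below residual
  upt_mm <- st$layer_uptake * lai * .MM_PER_FLUX_STEP
  max_mm <- pmax(0, (theta - state$theta_r - 1e-6) * lmm)
  upt_mm <- pmin(upt_mm, max_mm)
  theta <- theta - upt_mm / lmm
  transp <- sum(upt_mm)
  e_c_leaf <- transp / (lai * .MM_PER_FLUX_STEP)

  # (5) drainage toward field capacity, cascading downward
  drain_out <- overflow
  rate <- 1 - (1 - config$drainage_rate)^(1 / 48)
  for (i in seq_len(nl)) {
    excess <- (theta[i] - fc[i]) * lmm
    if (excess > 0) {
      d <- excess * rate
      theta[i] <- theta[i] - d / lmm
      if (i < nl) theta[i + 1L] <- theta[i + 1L] + d / lmm
      else drain_out <- drain_out + d
    }
  }

  if (any(theta < state$theta_r - 1e-9) || any(theta > state$theta_s + 1e-9))
    stop("soil water content left physical bounds at DOY ", meteo$doy,
         " hour ", meteo$hour)

  t_can <- canopy_temperature(meteo$t_air, e_c_leaf, lai, par = meteo$par,
                              wind = meteo$wind)
  gs_eff <- if (meteo$vpd > 0) e_c_leaf / ((meteo$vpd / config$patm) * 1000)
            else 0

  state$theta <- theta
  state$net <- net
  state$record <- c(
    doy = meteo$doy, hour = meteo$hour, lai = lai,
    psi_leaf = st$psi_leaf, psi_base = st$psi_base,
    e_c = st$e_c, e_crit = st$e_crit, e_demand = e_dem_ground / lai,
    g_s = gs_eff, k_plant = st$k_plant, t_canopy = t_can,
    capped = as.numeric(st$capped),
    transp_mm = transp, infil_mm = infil, drain_mm = drain_out,
    input_mm = meteo$water_input,
    stats::setNames(theta, paste0("theta_", seq_len(nl))),
    stats::setNames(net$psi_s, paste0("psi_soil_", seq_len(nl))),
    stats::setNames(st$layer_uptake, paste0("uptake_", seq_len(nl))))
  state
}

#' Initialise simulation state
#'
#' @param config A [sim_config()].
#' @return State list (`theta`, bounds, calibrated `net`).
#' @export
init_sim_state <- function(config) {
  fc <- vapply(config$soil, function(s) fc_pwp(s)[["theta_fc"]], numeric(1))
  tr <- vapply(config$soil, `[[`, numeric(1), "theta_r")
  ts <- vapply(config$soil, `[[`, numeric(1), "theta_s")
  theta0 <- if (identical(config$initial_theta, "fc")) fc
            else rep_len(config$initial_theta, config$n_layers)
  net <- build_continuum(config$genotype, config$soil, theta0,
                         lai = lai_at(config$lai, 1e6),
                         root_profile = config$root_profile,
                         split = config$split, cap_frac = config$cap_frac,
                         path_factor = config$path_factor,
                         calib_mult = config$calib_mult)
  list(theta = theta0, theta_fc = fc, theta_r = tr, theta_s = ts, net = net)
}

#' Run the half-hourly season simulation
#'
#' Integrates the soil-plant hydraulic continuum over the forcing series
#' (default day-of-year window 160-240 at 48 steps per day, 3840 records).
#' The run is deterministic given its configuration and forcing.
#'
#' @param config A [sim_config()].
#' @param forcing Half-hourly forcing data.frame from [gen_meteo()] or
#'   [read_forcing()], with columns `doy`, `hour`, `par`, `t_air`, `vpd`,
#'   `wind`, `water_input`.
#' @param start_doy,end_doy Simulation window (inclusive); defaults to the
#'   forcing extent.
#' @return Object of class `planthydro_sim`: `steps` (per-step data.frame),
#'   `water_balance`, `k_max`, `config`.
#' @export
run_simulation <- function(config, forcing, start_doy = NULL,
                           end_doy = NULL) {
  f <- as.data.frame(forcing)
  need <- c("doy", "hour", "par", "t_air", "vpd", "wind", "water_input")
  miss <- setdiff(need, names(f))
  if (length(miss)) stop("forcing lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(start_doy)) start_doy <- min(f$doy)
  if (is.null(end_doy)) end_doy <- max(f$doy)
  f <- f[f$doy >= start_doy & f$doy <= end_doy, , drop = FALSE]
  tt <- f$doy * 48 + f$hour * 2
  if (any(diff(tt) != 1)) {
    gaps <- which(diff(tt) != 1)[1]
    stop("forcing has gaps or irregular steps near doy ", f$doy[gaps],
         " hour ", f$hour[gaps], "; need strictly half-hourly coverage")
  }
  n_expected <- (end_doy - start_doy + 1L) * 48L
  if (nrow(f) != n_expected)
    stop("forcing covers ", nrow(f), " steps; expected ", n_expected)
  if (any(f$par < 0) || any(f$vpd < 0) || any(f$water_input < 0))
    stop("forcing violates nonnegativity invariants")

  state <- init_sim_state(config)
  theta_init <- state$theta
  n <- nrow(f)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    state <- step_halfhour(state, f[i, ], config)
    rows[[i]] <- state$record
  }
  steps <- as.data.frame(do.call(rbind, rows))

  lmm <- config$layer_mm
  wb <- list(
    input = sum(steps$input_mm),
    transpiration = sum(steps$transp_mm),
    drainage = sum(steps$drain_mm),
    delta_storage = sum((state$theta - theta_init) * lmm))
  wb$residual <- wb$input - wb$transpiration - wb$drainage - wb$delta_storage

  structure(list(steps = steps, water_balance = wb,
                 k_max = kmax_saturated(config$genotype),
                 calib_mult = state$net$calib_mult,
                 theta_final = state$theta, config = config),
            class = "planthydro_sim")
}

#' @export
print.planthydro_sim <- function(x, ...) {
  s <- x$steps
  cat("planthydro simulation:", nrow(s), "half-hourly steps, DOY",
      min(s$doy), "-", max(s$doy), "\n")
  wb <- x$water_balance
  cat(sprintf("  water balance [mm]: in %.1f, transpiration %.1f, drainage %.1f, storage %+.1f (residual %.2g)\n",
              wb$input, wb$transpiration, wb$drainage, wb$delta_storage,
              wb$residual))
  cat(sprintf("  min psi_leaf %.2f MPa; %d supply-capped steps\n",
              min(s$psi_leaf), sum(s$capped > 0)))
  invisible(x)
}

#' Root mean square error of matched simulated/observed pairs
#'
#' @param y_sim,y_obs Equal-length numeric vectors of simulated and observed
#'   values at matched timestamps.
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(y_sim, y_obs) {
  if (length(y_sim) != length(y_obs)) stop("length mismatch")
  if (!length(y_sim)) stop("need at least one pair")
  sqrt(mean((y_sim - y_obs)^2))
}

# nearest-step join of layered moisture observations onto simulation output;
# observations further than `tol_h` hours from any step are an error
.match_moisture <- function(sim, obs, tol_h = 1) {
  s <- sim$steps
  st <- s$doy * 24 + s$hour
  ot <- obs$doy * 24 + obs$hour
  idx <- vapply(ot, function(t0) which.min(abs(st - t0)), integer(1))
  if (any(abs(st[idx] - ot) > tol_h))
    stop("observations more than ", tol_h, " h from any simulated step")
  sim_theta <- mapply(function(i, l) s[[paste0("theta_", l)]][i],
                      idx, obs$layer)
  data.frame(layer = obs$layer, sim = sim_theta, obs = obs$theta)
}

#' Validate simulated soil moisture against observations
#'
#' @param sim A `planthydro_sim`.
#' @param obs data.frame with `doy`, `hour`, `layer`, `theta`.
#' @param tol_h Matching tolerance in hours (default 1).
#' @return data.frame of per-layer RMSE plus the across-layer mean.
#' @export
validate_moisture <- function(sim, obs, tol_h = 1) {
  if (!nrow(obs)) stop("empty observations")
  m <- .match_moisture(sim, obs, tol_h)
  per <- vapply(split(m, m$layer),
                function(d) rmse(d$sim, d$obs), numeric(1))
  data.frame(layer = c(names(per), "mean"),
             rmse = c(per, mean(per)), row.names = NULL)
}

#' Calibrate the root-to-leaf area ratio against soil moisture
#'
#' Re-runs the simulation over a grid of candidate ratios and returns the one
#' minimising the mean across-layer RMSE of volumetric soil water content,
#' with the full profile for audit.
#'
#' @param config A [sim_config()]; its genotype's ratio is replaced by each
#'   candidate.
#' @param forcing Forcing data.frame.
#' @param observed data.frame with `doy`, `hour`, `layer`, `theta`, spanning
#'   at least 2 layers.
#' @param ratios Numeric grid of candidate ratios (>= 2 values).
#' @return List with `best_ratio`, `profile` (ratio, mean RMSE), `runs`.
#' @export
calibrate_root_ratio <- function(config, forcing, observed, ratios) {
  if (length(ratios) < 2L) stop("need at least 2 candidate ratios")
  if (!nrow(observed)) stop("empty observations")
  if (length(unique(observed$layer)) < 2L)
    stop("observations must span at least 2 layers")
  res <- lapply(ratios, function(r) {
    g <- config$genotype
    g$root_to_leaf_area <- r
    cfg <- config
    cfg$genotype <- g
    sim <- run_simulation(cfg, forcing)
    v <- validate_moisture(sim, observed)
    list(ratio = r, rmse = v$rmse[v$layer == "mean"], sim = sim)
  })
  profile <- data.frame(ratio = ratios,
                        rmse = vapply(res, `[[`, numeric(1), "rmse"))
  list(best_ratio = profile$ratio[which.min(profile$rmse)],
       profile = profile)
}

#' Read half-hourly forcing from delimited text
#'
#' Accepts either `doy` + `hour` columns or an ISO `timestamp` column, plus
#' `par`, `t_air`, `vpd`, `wind`, `water_input`.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Forcing data.frame with `doy` and `hour` columns.
#' @export
read_forcing <- function(path, sep = ",") {
  f <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (!all(c("doy", "hour") %in% names(f))) {
    if (!"timestamp" %in% names(f))
      stop("need 'doy'+'hour' or a 'timestamp' column")
    ts <- as.POSIXct(sub("T", " ", f$timestamp), tz = "UTC")
    f$doy <- as.integer(strftime(ts, "%j", tz = "UTC"))
    f$hour <- as.integer(strftime(ts, "%H", tz = "UTC")) +
      as.integer(strftime(ts, "%M", tz = "UTC")) / 60
  }
  need <- c("doy", "hour", "par", "t_air", "vpd", "wind", "water_input")
  miss <- setdiff(need, names(f))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  f[need]
}

#' Write forcing to delimited text
#' @param forcing Forcing data.frame.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_forcing <- function(forcing, path, sep = ",") {
  utils::write.table(forcing, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
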