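## Seed-deterministic generators for every input class the pipeline
## consumes. Each generator saves and restores the caller's RNG state, so it
## is a pure function of its arguments.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.esat_kpa <- function(t_c) 0.6108 * exp(17.27 * t_c / (t_c + 237.3))

#' Generate half-hourly meteorological forcing
#'
#' Emulates an arid-summer station record: solar-geometry-driven PAR (zero
#' whenever solar elevation is non-positive), diurnal air temperature with an
#' afternoon peak, VPD from saturation deficit against a fixed dewpoint,
#' light day-to-day temperature variation, and scheduled irrigation pulses
#' with near-zero rain.
#'
#' @param n_days Number of days (default 81, covering DOY 160-240).
#' @param start_doy First day of year (default 160).
#' @param lat Site latitude in degrees (default 33.07, low-desert Arizona).
#' @param tmin,tmax Typical daily air temperature extremes, deg C.
#' @param dewpoint Dewpoint temperature, deg C, setting ambient vapor
#'   pressure.
#' @param wind_mean Mean wind speed, m s-1.
#' @param irrigation List with `interval_days`, `depth_mm`, `hour` and
#'   optionally `start_doy` for the pulse schedule; `NULL` for no
#'   irrigation.
#' @param day_sd Day-to-day temperature standard deviation, deg C.
#' @param seed Integer seed (the series is bitwise-reproducible given the
#'   seed).
#' @return Forcing data.frame (`doy`, `hour`, `par`, `t_air`, `vpd`,
#'   `wind`, `water_input`), 48 rows per day.
#' @export
gen_meteo <- function(n_days = 81, start_doy = 160, lat = 33.07, tmin = 23,
                      tmax = 36, dewpoint = 18, wind_mean = 2,
                      irrigation = list(interval_days = 2, depth_mm = 16,
                                        hour = 6),
                      day_sd = 1.5, seed = 1L) {
  if (n_days < 1) stop("n_days must be >= 1")
  if (!is.null(irrigation)) {
    if (is.null(irrigation$interval_days) || is.null(irrigation$depth_mm))
      stop("irrigation schedule needs 'interval_days' and 'depth_mm'")
    if (irrigation$interval_days < 1 || irrigation$depth_mm < 0)
      stop("invalid irrigation schedule")
  }
  .with_seed(seed, {
    doy <- rep(start_doy + seq_len(n_days) - 1L, each = 48L)
    hour <- rep(seq(0, 23.5, by = 0.5), times = n_days)

    decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
    latr <- lat * pi / 180
    ha <- pi / 12 * (hour - 12)  # hour angle, radians
    sin_el <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)
    par <- 2000 * pmax(0, sin_el)

    t_anom <- rep(stats::rnorm(n_days, 0, day_sd), each = 48L)
    tm <- (tmin + tmax) / 2
    amp <- (tmax - tmin) / 2
    t_air <- tm + amp * cos(2 * pi * (hour - 16) / 24) + t_anom

    ea <- .esat_kpa(dewpoint)
    vpd <- pmax(0.05, .esat_kpa(t_air) - ea)

    wind <- pmax(0.3, wind_mean + stats::rnorm(length(hour), 0, 0.4))

    water <- numeric(length(hour))
    if (!is.null(irrigation)) {
      first <- if (is.null(irrigation$start_doy)) start_doy
               else irrigation$start_doy
      ir_hour <- if (is.null(irrigation$hour)) 6 else irrigation$hour
      ir_days <- seq(first, start_doy + n_days - 1L,
                     by = irrigation$interval_days)
      hit <- doy %in% ir_days & hour == ir_hour
      water[hit] <- irrigation$depth_mm
    }
    data.frame(doy = doy, hour = hour, par = par, t_air = t_air, vpd = vpd,
               wind = wind, water_input = water)
  })
}

#' Generate noisy vulnerability-curve measurements
#'
#' PLC observations on a known Weibull truth curve plus Gaussian noise,
#' clipped to \[0, 100\], across segments whose Ksmax is drawn around the
#' truth value — emulating centrifuge measurement tables.
#'
#' @param truth A [vulnerability_curve()] (the generating parameters).
#' @param pressures Xylem pressures, MPa, all <= 0.
#' @param sigma PLC noise standard deviation (>= 0).
#' @param n_segments Biological replicates (segments).
#' @param ksmax_cv Coefficient of variation of per-segment Ksmax (only used
#'   when the truth carries a `ksmax`).
#' @param seed Integer seed.
#' @return Measurement data.frame (`genotype`, `organ`, `segment_id`,
#'   `pressure_mpa`, `plc`, and `ks` when the truth has a `ksmax`).
#' @export
gen_vc_measurements <- function(truth,
                                pressures = c(0, -0.25, -0.5, -1, -2, -4),
                                sigma = 5, n_segments = 3, ksmax_cv = 0.15,
                                seed = 1L) {
  stopifnot(inherits(truth, "vulnerability_curve"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (any(pressures > 0)) stop("pressures must be <= 0 MPa")
  .with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_segments), function(sg) {
      plc_true <- evaluate_vc(truth, pressures)$plc
      plc <- pmin(100, pmax(0, plc_true + stats::rnorm(length(pressures), 0,
                                                       sigma)))
      d <- data.frame(genotype = truth$genotype, organ = truth$organ,
                      segment_id = paste0("seg", sg),
                      pressure_mpa = pressures, plc = plc)
      if (!is.null(truth$ksmax)) {
        ksm <- truth$ksmax * exp(stats::rnorm(1, 0, ksmax_cv))
        d$ks <- ksm * (1 - plc / 100)
      }
      d
    }))
    out
  })
}

#' Generate a spatially correlated soil texture field
#'
#' Clay as a Gaussian random field with an exponential covariance (plus
#' nugget), silt co-varying weakly with clay, sand by closure — sampled at
#' random locations over the field extent in five 30-cm depth layers.
#'
#' @param extent `c(width, height)` of the field, m.
#' @param n_locations Number of boring locations (>= 10 recommended; the
#'   spec's field campaigns used 55-56).
#' @param mean_clay Field mean clay fraction.
#' @param sill Variance of the clay field (fraction^2).
#' @param range_m Correlation (e-folding) range, m.
#' @param nugget Nugget variance (fraction^2).
#' @param depth_trend Clay increase per layer going down (fraction).
#' @param seed Integer seed.
#' @return Sample data.frame (`x`, `y`, `depth_top`, `depth_bottom`, `clay`,
#'   `sand`, `silt`), fractions closing to 1 at every row.
#' @export
gen_soil_field <- function(extent = c(120, 60), n_locations = 56,
                           mean_clay = 0.24, sill = 0.0025, range_m = 30,
                           nugget = 0.00025, depth_trend = 0.005, seed = 1L) {
  if (any(extent <= 0)) stop("degenerate field extent")
  if (n_locations < 10) stop("need at least 10 sample locations")
  .with_seed(seed, {
    x <- stats::runif(n_locations, 0, extent[1])
    y <- stats::runif(n_locations, 0, extent[2])
    d <- as.matrix(stats::dist(cbind(x, y)))
    C <- sill * exp(-d / range_m)
    L <- chol(C + diag(1e-10, n_locations))
    layers <- lapply(1:5, function(l) {
      z <- as.vector(t(L) %*% stats::rnorm(n_locations)) +
        stats::rnorm(n_locations, 0, sqrt(nugget))
      clay <- pmin(0.55, pmax(0.05, mean_clay + (l - 1) * depth_trend + z))
      silt <- pmin(0.35, pmax(0.05, 0.18 + 0.2 * (clay - mean_clay) +
                                stats::rnorm(n_locations, 0, 0.01)))
      data.frame(x = x, y = y, depth_top = (l - 1) * 30, depth_bottom = l * 30,
                 clay = clay, sand = 1 - clay - silt, silt = silt)
    })
    do.call(rbind, layers)
  })
}

#' Generate noisy layered soil-moisture observations from a simulation
#'
#' Subsamples roughly biweekly timestamps from a simulation, adds Gaussian
#' noise to the per-layer volumetric water contents and clips to physical
#' bounds — emulating neutron-probe validation data.
#'
#' @param sim A `planthydro_sim`.
#' @param sigma Observation noise SD (volumetric content units).
#' @param n_timepoints Number of observation days (<= simulated days).
#' @param hour Observation hour (default 8).
#' @param seed Integer seed.
#' @return data.frame with `doy`, `hour`, `layer`, `theta`.
#' @export
gen_observed_moisture <- function(sim, sigma = 0.015, n_timepoints = 19,
                                  hour = 8, seed = 1L) {
  stopifnot(inherits(sim, "planthydro_sim"))
  days <- sort(unique(sim$steps$doy))
  if (n_timepoints > length(days))
    stop("n_timepoints exceeds available simulated days")
  .with_seed(seed, {
    pick <- days[round(seq(1, length(days), length.out = n_timepoints))]
    nl <- sum(grepl("^theta_", names(sim$steps)))
    rows <- sim$steps[sim$steps$doy %in% pick & sim$steps$hour == hour, ]
    out <- do.call(rbind, lapply(seq_len(nl), function(l) {
      th <- rows[[paste0("theta_", l)]] + stats::rnorm(nrow(rows), 0, sigma)
      data.frame(doy = rows$doy, hour = rows$hour, layer = l,
                 theta = pmin(0.7, pmax(0.01, th)))
    }))
    out
  })
}

#' Packaged default parameter sets
#'
#' The species-level cotton hydraulic trait set and the high-clay (HC),
#' low-clay (LC) and field-mean soil textures used throughout: Gsref 0.63
#' mol m-2 s-1, E_sat 11.4 mmol m-2 s-1, predawn/midday reference potentials
#' -0.8 / -2.4 MPa, shoot VC (b 1.55, c 0.75), root VC (b 0.29, c 0.59),
#' root:leaf area 2.5. Genotype-level stem-VC presets anchor the Weibull
#' scale to the measured genotype P50 values (PD3 -1.52 MPa, Tipo Chaco
#' -0.49 MPa) with the species shape c = 0.75; the DP1549 and Coker presets
#' are synthetic mid-range stand-ins (-1.20 and -1.05 MPa), since their
#' individual fits are not published.
#'
#' @return List with `species` ([genotype_params()]), `genotypes` (named
#'   list: species, DP1549, TipoChaco, PD3, Coker), `soils` (named list of
#'   [soil_texture()]: LC, HC, mean), `root_profile`, `lai_validation`
#'   (staged schedule) and `lai_sensitivity` (fixed 3.5).
#' @export
default_params <- function() {
  vc_root <- vulnerability_curve(0.29, 0.59, organ = "root",
                                 genotype = "species")
  mk <- function(name, b_shoot, sla = 30.5) {
    genotype_params(
      gsref = 0.63, e_sat = 11.4, psi_pd_sat = -0.8, psi_md_sat = -2.4,
      vc_shoot = vulnerability_curve(b_shoot, 0.75, organ = "stem",
                                     genotype = name),
      vc_root = vc_root, root_to_leaf_area = 2.5, sla = sla, genotype = name)
  }
  # b = |P50| / ln(2)^(1/c); species b = 1.55 reproduces P50 = -0.95
  ln2c <- log(2)^(1 / 0.75)
  genotypes <- list(
    species = mk("species", 1.55),
    DP1549 = mk("DP1549", 1.20 / ln2c),    # synthetic stand-in P50 -1.20
    TipoChaco = mk("TipoChaco", 0.49 / ln2c),
    PD3 = mk("PD3", 1.52 / ln2c),
    Coker = mk("Coker", 1.05 / ln2c))      # synthetic stand-in P50 -1.05
  soils <- list(
    LC = soil_texture(clay = 0.19, silt = 0.174, bulk_density = 1.59,
                      porosity = 0.401, gmd_mm = 0.1448, gsd = 12.226),
    HC = soil_texture(clay = 0.278, silt = 0.182, bulk_density = 1.56,
                      porosity = 0.4105, gmd_mm = 0.0764, gsd = 12.226),
    mean = soil_texture(clay = 0.24, sand = 0.58, bulk_density = 1.575,
                        porosity = 0.406, gmd_mm = 0.1106, gsd = 12.226))
  list(species = genotypes$species, genotypes = genotypes, soils = soils,
       root_profile = c(0.35, 0.25, 0.20, 0.12, 0.08),
       lai_validation = lai_schedule(data.frame(
         doy = c(160, 175, 190, 205), lai = c(1.5, 2.5, 3.5, 4.0))),
       lai_sensitivity = lai_schedule(3.5))
}
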