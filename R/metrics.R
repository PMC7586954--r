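#' Windowed per-day means of a simulated variable
#'
#' Averages a per-step output variable over the predawn (03:00-05:00) or
#' midday (12:00-14:00) window for every simulated day. Windows are
#' half-open `[start, end)` in local standard time, so each spans exactly
#' four half-hourly steps.
#'
#' @param output A `planthydro_sim` (or its `steps` data.frame).
#' @param variable Column name, e.g. `"e_c"`, `"psi_leaf"`, `"e_crit"`.
#' @param window `"predawn"`, `"midday"` or a numeric `c(start, end)` in
#'   hours.
#' @return data.frame with `doy` and the per-day mean.
#' @export
window_stats <- function(output, variable,
                         window = c("midday", "predawn")) {
  s <- if (inherits(output, "planthydro_sim")) output$steps
       else as.data.frame(output)
  if (!variable %in% names(s)) stop("no column '", variable, "'")
  if (is.character(window)) {
    window <- match.arg(window)
    window <- if (window == "midday") c(12, 14) else c(3, 5)
  }
  sel <- s$hour >= window[1] & s$hour < window[2]
  sub <- s[sel, , drop = FALSE]
  n_expected <- as.integer(round((window[2] - window[1]) * 2))
  counts <- table(sub$doy)
  bad <- names(counts)[counts != n_expected]
  days <- sort(unique(s$doy))
  missing_days <- setdiff(as.character(days), names(counts))
  if (length(bad) || length(missing_days))
    stop("incomplete window coverage on day(s): ",
         paste(c(bad, missing_days), collapse = ", "))
  agg <- stats::aggregate(sub[[variable]], by = list(doy = sub$doy),
                          FUN = mean)
  names(agg)[2] <- variable
  agg
}

#' Percent loss of whole-plant hydraulic conductance
#'
#' `100 * (1 - k_plant / k_max)`. Values of `k_plant` marginally above
#' `k_max` (numerical supersaturation in wet, low-flux states) are clamped
#' with a warning.
#'
#' @param k_plant Whole-plant conductance(s), mmol m-2 s-1 MPa-1.
#' @param k_max Saturated whole-plant conductance (> 0).
#' @return PLK in percent, within \[0, 100\].
#' @export
plk <- function(k_plant, k_max) {
  if (k_max <= 0) stop("k_max must be positive")
  if (any(k_plant < 0)) stop("k_plant must be >= 0")
  if (any(k_plant > k_max)) {
    warning("k_plant exceeds k_max for ", sum(k_plant > k_max),
            " value(s); clamping PLK at 0")
    k_plant <- pmin(k_plant, k_max)
  }
  100 * (1 - k_plant / k_max)
}

#' Relative hydraulic safety margin
#'
#' Normalizes a per-day series of safety margins (`e_crit - e_c`) by its
#' maximum, so the safest day maps to 1.
#'
#' @param margins Numeric per-day margins; at least one must be positive.
#' @return Per-day rho in \[0, 1\] (assuming nonnegative margins).
#' @export
relative_safety <- function(margins) {
  mx <- max(margins)
  if (mx <= 0) stop("all margins <= 0: relative safety margin undefined")
  margins / mx
}

#' Normalized midday transpiration difference between two runs
#'
#' \eqn{\delta_i = (a_i - b_i) / mean(a_i, b_i)} per day; positive means the
#' role-a run transpires more that day. Days with zero mean are returned as
#' `NA` and flagged in the `"undefined_days"` attribute (never dropped
#' silently).
#'
#' @param run_a,run_b Aligned per-day midday transpiration series (numeric
#'   vectors or the data.frames from [window_stats()]).
#' @return Per-day delta, with attribute `undefined_days`.
#' @export
delta_series <- function(run_a, run_b) {
  if (is.data.frame(run_a)) run_a <- run_a[[2]]
  if (is.data.frame(run_b)) run_b <- run_b[[2]]
  if (length(run_a) != length(run_b)) stop("series not aligned")
  m <- (run_a + run_b) / 2
  delta <- ifelse(m > 0, (run_a - run_b) / m, NA_real_)
  und <- which(!(m > 0))
  if (length(und))
    warning("delta undefined (zero mean) on ", length(und), " day(s)")
  attr(delta, "undefined_days") <- und
  delta
}

#' Detect soil-contingent genotype ranking flips
#'
#' A day is flagged when the delta series under the two soil conditions have
#' strictly opposite signs (a zero delta on either soil never flags).
#' Windows are maximal runs of two or more consecutive flagged days with the
#' same orientation.
#'
#' @param delta_hc,delta_lc Aligned per-day delta series under the high-clay
#'   and low-clay condition.
#' @param doy Optional day labels (defaults to 1..n).
#' @return Object of class `divergence_report`: `flagged_days`, `windows`
#'   (data.frame start/end/length/direction), and the input series.
#' @export
divergence_days <- function(delta_hc, delta_lc, doy = NULL) {
  if (length(delta_hc) != length(delta_lc)) stop("series not aligned")
  n <- length(delta_hc)
  if (is.null(doy)) doy <- seq_len(n)
  s_hc <- sign(delta_hc)
  s_lc <- sign(delta_lc)
  flag <- !is.na(s_hc) & !is.na(s_lc) & (s_hc * s_lc < 0)
  dir <- ifelse(flag, s_lc, 0)  # orientation: sign on the low-clay soil
  windows <- data.frame(start_doy = integer(0), end_doy = integer(0),
                        length = integer(0), direction = integer(0))
  if (any(flag)) {
    r <- rle(paste0(flag, dir))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- grepl("^TRUE", r$values) & r$lengths >= 2L
    if (any(keep))
      windows <- data.frame(start_doy = doy[starts[keep]],
                            end_doy = doy[ends[keep]],
                            length = r$lengths[keep],
                            direction = dir[starts[keep]])
  }
  structure(list(flagged_days = doy[flag], windows = windows,
                 delta_hc = delta_hc, delta_lc = delta_lc, doy = doy),
            class = "divergence_report")
}

#' @export
print.divergence_report <- function(x, ...) {
  cat("Soil x genotype divergence report\n")
  cat("  flagged days:",
      if (length(x$flagged_days)) paste(x$flagged_days, collapse = ", ")
      else "none", "\n")
  cat("  windows (>= 2 consecutive, same direction):", nrow(x$windows), "\n")
  if (nrow(x$windows)) print(x$windows)
  invisible(x)
}

#' Construct staged drought scenarios from base forcing
#'
#' E1 is the base forcing; E2 and E3 receive the stated multiples (default
#' 50% and 25%) of E1's per-step water input from the drought start day
#' onward. All non-water variables are untouched and the three forcings are
#' identical before the drought start.
#'
#' @param base_forcing Forcing data.frame (see [gen_meteo()]).
#' @param drought_start_doy Day of year when inputs diverge (default 188).
#' @param multipliers Water multipliers for the scenarios (default
#'   `c(1, 0.5, 0.25)`).
#' @return Object of class `scenario_set`: named list `e1`, `e2`, `e3` (one
#'   entry per multiplier) plus metadata.
#' @export
build_scenarios <- function(base_forcing, drought_start_doy = 188,
                            multipliers = c(1, 0.5, 0.25)) {
  f <- as.data.frame(base_forcing)
  if (drought_start_doy <= min(f$doy) || drought_start_doy > max(f$doy))
    stop("drought_start_doy outside the forcing window")
  scen <- lapply(multipliers, function(m) {
    g <- f
    late <- g$doy >= drought_start_doy
    g$water_input[late] <- g$water_input[late] * m
    g
  })
  names(scen) <- paste0("e", seq_along(multipliers))
  structure(c(scen, list(drought_start_doy = drought_start_doy,
                         multipliers = multipliers)),
            class = "scenario_set")
}

#' Per-day stress metrics from a simulation
#'
#' Predawn and midday leaf water potentials, midday transpiration and
#' critical transpiration, hydraulic safety margin (`e_crit - e_c`),
#' relative safety margin rho, and midday percent loss of whole-plant
#' conductance.
#'
#' @param sim A `planthydro_sim`.
#' @return data.frame with one row per day: `doy`, `psi_pd`, `psi_md`,
#'   `e_c_md`, `e_crit_md`, `margin`, `rho`, `plk`.
#' @export
daily_metrics <- function(sim) {
  stopifnot(inherits(sim, "planthydro_sim"))
  pd <- window_stats(sim, "psi_leaf", "predawn")
  md <- window_stats(sim, "psi_leaf", "midday")
  ec <- window_stats(sim, "e_c", "midday")
  ecr <- window_stats(sim, "e_crit", "midday")
  kp <- window_stats(sim, "k_plant", "midday")
  margin <- ecr$e_crit - ec$e_c
  out <- data.frame(doy = pd$doy, psi_pd = pd$psi_leaf, psi_md = md$psi_leaf,
                    e_c_md = ec$e_c, e_crit_md = ecr$e_crit, margin = margin,
                    rho = relative_safety(margin),
                    plk = suppressWarnings(plk(kp$k_plant, sim$k_max)))
  out
}

#' Write per-day metrics to delimited text
#' @param metrics data.frame from [daily_metrics()].
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_daily_metrics <- function(metrics, path, sep = ",") {
  utils::write.table(metrics, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
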