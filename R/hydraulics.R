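#' Genotype parameter set for the hydraulic model
#'
#' Bundles the traits that constrain the soil-plant hydraulic continuum:
#' reference stomatal conductance, transpiration and leaf water potentials in
#' the saturated reference state, root and shoot vulnerability curves, and the
#' root-to-leaf area ratio.
#'
#' @param gsref Stomatal conductance at VPD = 1 kPa, mol m-2 s-1 (leaf area).
#' @param e_sat Transpiration at saturated whole-plant conductance,
#'   mmol m-2 s-1 (leaf area).
#' @param psi_pd_sat,psi_md_sat Predawn and midday leaf water potential at
#'   saturated conductance, MPa (`psi_md_sat < psi_pd_sat < 0`).
#' @param vc_shoot,vc_root [vulnerability_curve()] objects.
#' @param root_to_leaf_area Root area per leaf area, cm2 cm-2.
#' @param sla Specific leaf area, m2 kg-1 C (metadata only).
#' @param genotype Label.
#' @return Object of class `genotype_params`.
#' @export
genotype_params <- function(gsref, e_sat, psi_pd_sat, psi_md_sat, vc_shoot,
                            vc_root, root_to_leaf_area = 2.5, sla = NA_real_,
                            genotype = NA_character_) {
  stopifnot(inherits(vc_shoot, "vulnerability_curve"),
            inherits(vc_root, "vulnerability_curve"))
  if (!(psi_md_sat < psi_pd_sat && psi_pd_sat < 0))
    stop("need psi_md_sat < psi_pd_sat < 0")
  if (e_sat <= 0) stop("e_sat must be positive")
  if (gsref <= 0) stop("gsref must be positive")
  structure(list(gsref = gsref, e_sat = e_sat, psi_pd_sat = psi_pd_sat,
                 psi_md_sat = psi_md_sat, vc_shoot = vc_shoot,
                 vc_root = vc_root, root_to_leaf_area = root_to_leaf_area,
                 sla = sla, genotype = genotype),
            class = "genotype_params")
}

#' @export
print.genotype_params <- function(x, ...) {
  cat("Genotype hydraulic parameters",
      if (!is.na(x$genotype)) paste0(" (", x$genotype, ")"), "\n", sep = "")
  cat(sprintf("  Gsref %.3g mol m-2 s-1, E_sat %.3g mmol m-2 s-1\n",
              x$gsref, x$e_sat))
  cat(sprintf("  psi_pd %.3g / psi_md %.3g MPa, k_max %.4g mmol m-2 s-1 MPa-1\n",
              x$psi_pd_sat, x$psi_md_sat, kmax_saturated(x)))
  cat(sprintf("  shoot VC (b %.3g, c %.3g), root VC (b %.3g, c %.3g), RA:LA %.3g\n",
              x$vc_shoot$b, x$vc_shoot$c, x$vc_root$b, x$vc_root$c,
              x$root_to_leaf_area))
  invisible(x)
}

#' Saturated whole-plant hydraulic conductance
#'
#' \eqn{k_{max} = E_{sat} / (\psi_{pd} - \psi_{md})}: the whole-plant
#' conductance when the hydraulic pathway is fully charged.
#'
#' @param params A [genotype_params()] object.
#' @return k_max in mmol m-2 s-1 MPa-1 (leaf area basis).
#' @examples
#' # Table-level cotton defaults: 11.4 / 1.6 = 7.125
#' @export
kmax_saturated <- function(params) {
  dd <- params$psi_pd_sat - params$psi_md_sat
  if (abs(dd) < .Machine$double.eps)
    stop("psi_pd_sat equals psi_md_sat: k_max undefined (division by zero)")
  params$e_sat / dd
}

## ---- Weibull element math (Kirchhoff / matric flux potential) -------------
## For an element with saturated conductance k and Weibull conductivity
## k * exp(-(-psi/b)^c), the matric flux potential per unit conductance is
##   W(psi) = b * Gamma(1 + 1/c) * Q(1/c, (-psi/b)^c)
## with Q the upper regularized incomplete gamma. Flux from psi_up to
## psi_down is k * (W(psi_up) - W(psi_down)); W is invertible in closed form
## via qgamma, so series compositions only ever need 1-D solves.

.wmax <- function(b, cc) b * gamma(1 + 1 / cc)

.kirch <- function(psi, b, cc, wmax = .wmax(b, cc)) {
  wmax * stats::pgamma((pmax(-psi, 0) / b)^cc, shape = 1 / cc,
                       lower.tail = FALSE)
}

.kirch_inv <- function(w, b, cc, wmax = .wmax(b, cc)) {
  p <- w / wmax
  out <- numeric(length(w))
  out[p <= 0] <- -Inf
  out[p >= 1] <- 0
  mid <- p > 0 & p < 1
  out[mid] <- -b * stats::qgamma(p[mid], shape = 1 / cc,
                                 lower.tail = FALSE)^(1 / cc)
  out
}

## per-network cache of quantities that are fixed while soil state is fixed
.net_prep <- function(net) {
  wmax_r <- .wmax(net$br, net$cr)
  wmax_s <- .wmax(net$bs, net$cs)
  ws <- .kirch(net$psi_s, net$br, net$cr, wmax_r)
  kws <- exp(-(pmax(-net$psi_s, 0) / net$br)^net$cr)
  list(wmax_r = wmax_r, wmax_s = wmax_s, ws = ws, kws = kws,
       hi = max(net$psi_s))
}

## flux delivered to the root crown (psi_base) from each soil layer:
## rhizosphere element (linear conductance g, possibly Inf) in series with a
## Weibull root element (saturated conductance kr). Safeguarded vectorized
## Newton on the per-layer flux; the initial guess is the linearized series
## split, which converges in a handful of iterations.
.layer_flux_prep <- function(psi_base, net, prep, wb = NULL, deriv = FALSE,
                             tol = 1e-11, maxit = 60) {
  if (is.null(wb)) wb <- .kirch(psi_base, net$br, net$cr, prep$wmax_r)
  kr <- net$kr; g <- net$g; ps <- net$psi_s
  fmax <- kr * (prep$ws - wb)
  act <- fmax > 0 & ps > psi_base & g > 0
  f <- numeric(length(ps))
  kwm <- prep$kws
  if (any(act)) {
    gi <- g[act]; ki <- kr[act]; psa <- ps[act]; fm <- fmax[act]
    # linearized series estimate as starting point (x/Inf = 0 handles an
    # unresisted rhizosphere); x stays in [0, fmax] so psi_m <= psi_s <= 0
    x <- fm * gi / (gi + ki * prep$kws[act])
    x[!is.finite(x)] <- fm[!is.finite(x)]
    lo <- numeric(length(x)); hi <- fm
    scale <- max(1, max(fm))
    ibr <- 1 / net$br
    shp <- 1 / net$cr
    u <- NULL
    for (it in seq_len(maxit)) {
      psi_m <- psa - x / gi
      u <- ((-psi_m) * ibr)^net$cr
      w_m <- prep$wmax_r * stats::pgamma(u, shape = shp, lower.tail = FALSE)
      r <- ki * (w_m - wb) - x
      pos <- r > 0
      lo[pos] <- x[pos]
      hi[!pos] <- x[!pos]
      if (max(abs(r)) < tol * scale) break
      dr <- -ki * exp(-u) / gi - 1
      xn <- x - r / dr
      bad <- !is.finite(xn) | xn <= lo | xn >= hi
      xn[bad] <- 0.5 * (lo[bad] + hi[bad])
      x <- xn
    }
    f[act] <- x
    kwm[act] <- exp(-u)
  }
  out <- list(f = f)
  if (deriv) {
    # dT/dpsi_base = -sum(kr kw(psi_base) / (1 + kr kw(psi_m)/g)), < 0
    kwb <- exp(-(pmax(-psi_base, 0) / net$br)^net$cr)
    denom <- ifelse(is.finite(g), 1 + kr * kwm / g, 1)
    out$dT <- -sum((kr * kwb / denom)[act])
    if (!is.finite(out$dT) || out$dT >= 0) out$dT <- -sum(kr * kwb) - 1e-12
  }
  out
}

.supply_base <- function(net, psi_base, prep = .net_prep(net)) {
  sum(.layer_flux_prep(psi_base, net, prep)$f)
}

# compatibility wrapper used by tests/diagnostics
.layer_flux <- function(psi_base, psi_s, g, kr, br, cr) {
  net <- list(psi_s = psi_s, g = g, kr = kr, br = br, cr = cr)
  .layer_flux_prep(psi_base, net, .net_prep(net))$f
}

## maximum flux the root system can deliver (psi_base -> -Inf)
.tmax_root <- function(net, prep = .net_prep(net)) {
  sum(net$kr * prep$ws)
}

## root-crown potential carrying flux e (assumes 0 < e <= Tmax):
## safeguarded Newton with analytic dT/dpsi_base, bisection fallback
.solve_psi_base <- function(net, e, prep = .net_prep(net)) {
  hi <- prep$hi   # supply is 0 here; root lies below
  lo <- NA_real_  # unknown until a point with T >= e is found
  step <- 0.5
  p <- hi - step
  for (it in 1:200) {
    lf <- .layer_flux_prep(p, net, prep, deriv = TRUE)
    r <- sum(lf$f) - e
    if (abs(r) < 1e-10 * max(1, e)) return(list(psi_base = p, flux = lf$f))
    pn <- p - r / lf$dT  # Newton (dT < 0)
    if (r > 0) {
      lo <- p  # supply too high: root is between p and hi
      p <- if (is.finite(pn) && pn > p && pn < hi) pn else (p + hi) / 2
    } else {
      hi <- p
      if (is.na(lo)) {
        p <- if (is.finite(pn) && pn < p) pn else p - step
        step <- step * 2
        if (p < -1e4) stop("bracketing failure in root-crown solve (e = ",
                           e, ")")
      } else {
        p <- if (is.finite(pn) && pn < p && pn > lo) pn else (p + lo) / 2
      }
    }
    if (!is.na(lo) && hi - lo < 1e-12 * max(1, abs(lo)))
      return(list(psi_base = 0.5 * (lo + hi),
                  flux = .layer_flux_prep(0.5 * (lo + hi), net, prep)$f))
  }
  stop("root-crown solve failed to converge (e = ", e, ")")
}

## critical transpiration: crossing of root supply (increasing as psi_base
## falls) with the shoot's remaining capacity k_s * W_s(psi_base)
## (decreasing as psi_base falls). h(p) = T(p) - ks W_s(p) is monotone
## decreasing in p, so safeguarded Newton applies.
.e_crit <- function(net, prep = .net_prep(net)) {
  hi <- prep$hi
  if (.tmax_root(net, prep) <= 1e-12)
    return(list(e_crit = 0, psi_base = hi))
  shoot_cap <- function(p) net$ks * .kirch(p, net$bs, net$cs, prep$wmax_s)
  lo <- NA_real_
  step <- 0.5
  p <- hi - step
  top <- hi
  for (it in 1:200) {
    lf <- .layer_flux_prep(p, net, prep, deriv = TRUE)
    kw_s <- exp(-(pmax(-p, 0) / net$bs)^net$cs)
    h <- sum(lf$f) - shoot_cap(p)
    if (abs(h) < 1e-11 * max(1, sum(lf$f)))
      return(list(e_crit = shoot_cap(p), psi_base = p))
    dh <- lf$dT - net$ks * kw_s  # both terms negative: h is decreasing
    if (h > 0) {
      lo <- p
      pn <- p - h / dh
      p <- if (is.finite(pn) && pn > p && pn < top) pn else (p + top) / 2
    } else {
      top <- p
      pn <- p - h / dh
      if (is.na(lo)) {
        p <- if (is.finite(pn) && pn < p) pn else p - step
        step <- step * 2
        if (p < -2e4) {
          # shoot never limits before the root system saturates
          return(list(e_crit = .tmax_root(net, prep), psi_base = p))
        }
      } else {
        p <- if (is.finite(pn) && pn < p && pn > lo) pn else (p + lo) / 2
      }
    }
    if (!is.na(lo) && top - lo < 1e-12 * max(1, abs(lo))) {
      pm <- 0.5 * (lo + top)
      return(list(e_crit = shoot_cap(pm), psi_base = pm))
    }
  }
  stop("critical-transpiration solve failed to converge")
}

## zero-flux state: potentials equilibrate to a conductance-weighted mean of
## layer potentials (weights = series conductance of rhizosphere + root
## elements at the prevailing potentials)
.zero_flux_state <- function(net) {
  kw <- net$kr * exp(-(pmax(-net$psi_s, 0) / net$br)^net$cr)
  ci <- 1 / (1 / net$g + 1 / kw)
  ci[!is.finite(ci)] <- kw[!is.finite(ci)]
  if (sum(ci) <= 0) {
    psi <- max(net$psi_s)
  } else {
    psi <- sum(ci * net$psi_s) / sum(ci)
  }
  kshoot <- net$ks * exp(-(pmax(-psi, 0) / net$bs)^net$cs)
  klay <- sum(ci)
  list(psi = psi, k_sat = 1 / (1 / klay + 1 / kshoot))
}

#' Build the soil-plant hydraulic continuum network
#'
#' Assembles a series shoot element (Weibull) above parallel per-layer root
#' elements (Weibull), each in series with a rhizosphere element whose linear
#' conductance follows the Brooks-Corey unsaturated conductivity at the
#' layer's water content, scaled by the root area in the layer and a
#' rhizosphere path length set by the soil's geometric mean particle
#' diameter.
#'
#' Element saturated conductances carry a 50/50 root/shoot resistance split
#' (configurable via `split`) times a scalar multiplier. By default the
#' multiplier is calibrated once, at build time, so that the saturated
#' reference state (all layers at `psi_soil = 0`, flux `e_sat`) reproduces
#' `psi_md_sat` exactly — the self-consistency the k_max parameterization
#' implies (see the methods vignette).
#'
#' @param params A [genotype_params()].
#' @param soil A single `soil_hydraulic_params` applied to all layers, or a
#'   list with one per layer.
#' @param theta Per-layer volumetric water content (recycled if length 1).
#' @param lai Leaf area index (m2 m-2); retained as metadata (fluxes in the
#'   network are per unit leaf area).
#' @param root_profile Per-layer root area fractions (summing to 1).
#' @param split Fraction of saturated whole-plant resistance residing in the
#'   root system (default 0.5).
#' @param cap_frac Stomatal regulation rule: demand is capped at this
#'   fraction of the instantaneous critical transpiration (default 0.9).
#' @param path_factor Rhizosphere path length expressed in multiples of the
#'   geometric mean particle diameter (default 100).
#' @param calibrate If `TRUE` (default) solve the saturated-reference
#'   multiplier; `calib_mult` overrides it.
#' @param calib_mult Optional fixed multiplier (skips calibration).
#' @return Object of class `hydraulic_network`.
#' @export
build_continuum <- function(params, soil, theta, lai = 3.5,
                            root_profile = c(0.35, 0.25, 0.20, 0.12, 0.08),
                            split = 0.5, cap_frac = 0.9, path_factor = 100,
                            calibrate = TRUE, calib_mult = NULL) {
  stopifnot(inherits(params, "genotype_params"))
  nl <- length(root_profile)
  if (all(root_profile <= 0)) stop("zero root area in all layers")
  if (any(root_profile < 0)) stop("negative root fraction")
  root_profile <- root_profile / sum(root_profile)
  if (inherits(soil, "soil_hydraulic_params")) soil <- rep(list(soil), nl)
  if (length(soil) != nl) stop("need one soil parameter set per layer")
  theta <- rep_len(theta, nl)

  kmax <- kmax_saturated(params)
  rai <- params$root_to_leaf_area * root_profile  # root area per leaf area
  g <- vapply(seq_len(nl), function(i)
    .g_rhiz(soil[[i]], theta[i], rai[i], path_factor), numeric(1))

  make_net <- function(mult) {
    list(ks = mult * kmax / (1 - split), bs = params$vc_shoot$b,
         cs = params$vc_shoot$c,
         kr = mult * kmax / split * root_profile, br = params$vc_root$b,
         cr = params$vc_root$c,
         g = g, psi_s = rep(0, nl))
  }

  if (is.null(calib_mult)) {
    if (calibrate) {
      g_sat <- vapply(seq_len(nl), function(i)
        .g_rhiz(soil[[i]], soil[[i]]$theta_s, rai[i], path_factor), numeric(1))
      obj <- function(lm) {
        net <- make_net(exp(lm))
        net$g <- g_sat
        prep <- .net_prep(net)
        ec <- .e_crit(net, prep)$e_crit
        if (params$e_sat >= ec) return(-20)
        pb <- .solve_psi_base(net, params$e_sat, prep)$psi_base
        wl <- .kirch(pb, net$bs, net$cs, prep$wmax_s) - params$e_sat / net$ks
        if (wl <= 0) return(-20)
        .kirch_inv(wl, net$bs, net$cs, prep$wmax_s) - params$psi_md_sat
      }
      sol <- stats::uniroot(obj, c(log(0.05), log(500)), tol = 1e-9)
      calib_mult <- exp(sol$root)
    } else {
      calib_mult <- 1
    }
  }

  net <- make_net(calib_mult)
  net$psi_s <- pmax(.theta_to_psi_layers(soil, theta), -1e3)
  net$kmax <- kmax
  net$e_sat <- params$e_sat
  net$cap_frac <- cap_frac
  net$split <- split
  net$calib_mult <- calib_mult
  net$path_factor <- path_factor
  net$rai <- rai
  net$root_profile <- root_profile
  net$soil <- soil
  net$lai <- lai
  class(net) <- "hydraulic_network"
  net
}

.theta_to_psi_layers <- function(soil, theta) {
  vapply(seq_along(theta), function(i)
    .theta_to_psi(soil[[i]], theta[i]), numeric(1))
}

## rhizosphere conductance, mmol m-2 (leaf) s-1 MPa-1:
## K(theta) [m s-1] * 101.97 [m head / MPa] * 5.551e7 [mmol m-3 -> flux unit]
## / path length [m] * root area index (per leaf area)
.g_rhiz <- function(hyd, theta, rai, path_factor) {
  L <- path_factor * hyd$gmd_mm * 1e-3
  unsat_conductivity(hyd, theta) * 101.97 * 5.551e7 / L * rai
}

#' @export
print.hydraulic_network <- function(x, ...) {
  cat("Soil-plant hydraulic network:", length(x$psi_s), "soil layers\n")
  cat(sprintf("  k_max %.4g, shoot k %.4g, root k %.4g (multiplier %.3g)\n",
              x$kmax, x$ks, sum(x$kr), x$calib_mult))
  cat(sprintf("  layer psi_soil [MPa]: %s\n",
              paste(signif(x$psi_s, 3), collapse = ", ")))
  invisible(x)
}

#' Update network soil state
#'
#' Refreshes per-layer soil water potential and rhizosphere conductance from
#' new water contents without re-calibrating element conductances.
#'
#' @param net A `hydraulic_network`.
#' @param theta Per-layer water contents.
#' @return The updated network.
#' @export
update_soil_state <- function(net, theta) {
  nl <- length(net$psi_s)
  theta <- rep_len(theta, nl)
  net$psi_s <- pmax(.theta_to_psi_layers(net$soil, theta), -1e3)
  net$g <- vapply(seq_len(nl), function(i)
    .g_rhiz(net$soil[[i]], theta[i], net$rai[i], net$path_factor), numeric(1))
  net
}

#' Hydraulic supply function E(psi_leaf)
#'
#' Composes element Kirchhoff transforms through the network to give the
#' steady-state transpiration sustainable at a given leaf water potential,
#' together with the critical transpiration `e_crit` (the supremum of the
#' supply curve, finite for Weibull elements).
#'
#' @param net A `hydraulic_network` (from [build_continuum()]).
#' @param layer_psis Optional per-layer soil water potentials (MPa, <= 0)
#'   overriding the network state.
#' @return List with `fun` (vectorized E(psi_leaf), mmol m-2 s-1 leaf area),
#'   `e_crit` and `psi_base_crit`.
#' @export
supply_function <- function(net, layer_psis = NULL) {
  if (!is.null(layer_psis)) {
    if (any(layer_psis > 0)) stop("layer_psis must be <= 0 MPa")
    net$psi_s <- rep_len(layer_psis, length(net$psi_s))
  }
  prep <- .net_prep(net)
  crit <- .e_crit(net, prep)
  hi <- prep$hi
  e_at <- function(pl) {
    if (pl >= hi) return(0)
    wl <- .kirch(pl, net$bs, net$cs, prep$wmax_s)
    gfun <- function(p)
      .supply_base(net, p, prep) -
        net$ks * (.kirch(p, net$bs, net$cs, prep$wmax_s) - wl)
    if (gfun(pl) <= 0) return(max(0, .supply_base(net, pl, prep)))
    root <- stats::uniroot(gfun, c(pl, hi), tol = 1e-10)$root
    .supply_base(net, root, prep)
  }
  list(fun = function(psi_leaf) vapply(psi_leaf, e_at, numeric(1)),
       e_crit = crit$e_crit, psi_base_crit = crit$psi_base)
}

#' Solve the continuum for a transpiration target
#'
#' Finds the leaf water potential, root-crown potential and per-layer uptake
#' carrying a target transpiration flux. Demand at or beyond the regulated
#' supply limit (`cap_frac * e_crit`) is capped and flagged — the stomatal
#' closure rule preventing runaway cavitation.
#'
#' @param net A `hydraulic_network`.
#' @param layer_psis Optional per-layer soil potentials overriding the
#'   network state.
#' @param e_target Target transpiration, mmol m-2 s-1 (leaf area), >= 0.
#' @return Object of class `continuum_state`: `psi_leaf`, `psi_base`, `e_c`,
#'   `e_crit`, `capped`, `layer_uptake` (fluxes, mmol m-2 s-1),
#'   `uptake_fraction`, `k_plant`, `psi_soil_eff`.
#' @export
solve_demand <- function(net, layer_psis = NULL, e_target) {
  if (e_target < 0) stop("e_target must be >= 0")
  if (!is.null(layer_psis)) {
    if (any(layer_psis > 0)) stop("layer_psis must be <= 0 MPa")
    net$psi_s <- rep_len(layer_psis, length(net$psi_s))
  }
  prep <- .net_prep(net)
  crit <- .e_crit(net, prep)
  cap <- net$cap_frac * crit$e_crit
  capped <- e_target > cap
  e <- min(e_target, cap)
  nl <- length(net$psi_s)
  if (e <= 1e-9) {
    zs <- .zero_flux_state(net)
    st <- list(psi_leaf = zs$psi, psi_base = zs$psi, e_c = 0,
               e_crit = crit$e_crit, capped = capped,
               layer_uptake = numeric(nl), uptake_fraction = numeric(nl),
               k_plant = zs$k_sat, psi_soil_eff = zs$psi)
    class(st) <- "continuum_state"
    return(st)
  }
  sol <- .solve_psi_base(net, e, prep)
  pb <- sol$psi_base
  flux <- sol$flux
  e_sum <- sum(flux)
  wl <- .kirch(pb, net$bs, net$cs, prep$wmax_s) - e / net$ks
  if (wl <= 0)
    stop("bracketing failure: shoot cannot carry flux ", signif(e, 6),
         " from psi_base ", signif(pb, 6))
  pl <- .kirch_inv(wl, net$bs, net$cs, prep$wmax_s)
  psi_eff <- sum(flux * net$psi_s) / e_sum
  st <- list(psi_leaf = pl, psi_base = pb, e_c = e, e_crit = crit$e_crit,
             capped = capped, layer_uptake = flux,
             uptake_fraction = flux / e_sum,
             k_plant = e / (psi_eff - pl), psi_soil_eff = psi_eff)
  class(st) <- "continuum_state"
  st
}

#' @export
print.continuum_state <- function(x, ...) {
  cat(sprintf("Continuum state: E_c %.4g (E_crit %.4g) mmol m-2 s-1%s\n",
              x$e_c, x$e_crit, if (x$capped) " [capped]" else ""))
  cat(sprintf("  psi_leaf %.4g, psi_base %.4g, k_plant %.4g\n",
              x$psi_leaf, x$psi_base, x$k_plant))
  invisible(x)
}

#' Stomatal conductance under the Oren VPD-response model
#'
#' \eqn{G_s = G_{sref} (1 - m \ln D)} clipped at zero, times a saturating
#' light factor equal to 1 at the reference PAR of the gas-exchange cuvette.
#'
#' @param params A [genotype_params()].
#' @param vpd Vapor pressure deficit, kPa (> 0).
#' @param par Photosynthetically active radiation, umol m-2 s-1.
#' @param m Oren sensitivity slope (default 0.6).
#' @param par_ref Reference PAR at which the light factor is 1 (default 2000).
#' @param par_shape e-folding PAR of the light response (default 400).
#' @return G_s in mol m-2 s-1 (leaf area), vectorized over `vpd`/`par`.
#' @export
stomatal_conductance <- function(params, vpd, par = 2000, m = 0.6,
                                 par_ref = 2000, par_shape = 400) {
  if (any(vpd <= 0)) stop("vpd must be > 0 kPa")
  light <- (1 - exp(-par / par_shape)) / (1 - exp(-par_ref / par_shape))
  pmax(0, params$gsref * (1 - m * log(vpd))) * light
}

#' Transpiration demand from the stomatal model
#'
#' \eqn{E = G_s (D / P_{atm}) \cdot LAI \cdot 10^3} in mmol m-2 s-1 on a
#' ground-area basis.
#'
#' @inheritParams stomatal_conductance
#' @param lai Leaf area index.
#' @param patm Atmospheric pressure, kPa.
#' @return Demand in mmol m-2 (ground) s-1.
#' @export
stomatal_demand <- function(params, vpd, lai, par = 2000, patm = 101.325,
                            m = 0.6, par_ref = 2000, par_shape = 400) {
  gs <- stomatal_conductance(params, vpd, par, m, par_ref, par_shape)
  gs * (vpd / patm) * lai * 1000
}

#' Canopy temperature from a single-leaf energy balance
#'
#' \eqn{T_c = T_{air} + (R_{n,abs} - \lambda E) / (\rho_a c_p g_H)}. When the
#' latent flux balances absorbed net radiation the canopy sits at air
#' temperature; zero transpiration under positive radiation load warms it.
#'
#' @param t_air Air temperature, deg C.
#' @param e_c Canopy transpiration, mmol m-2 s-1 on a **leaf-area** basis
#'   (multiplied internally by `lai` for the ground-area latent flux).
#' @param lai Leaf area index.
#' @param par PAR, umol m-2 s-1, used for the default absorbed net radiation
#'   `rn_abs = 0.217 * par / 0.45 * 0.5 * (1 - exp(-0.6 * lai))` (PAR energy
#'   upscaled to shortwave, half retained as net absorbed radiation).
#' @param wind Wind speed, m s-1, used for the default boundary-layer
#'   conductance `g_h = 0.04 * sqrt(max(wind, 0.3))`.
#' @param rn_abs,g_h Optional overrides of absorbed net radiation (W m-2) and
#'   heat conductance (m s-1).
#' @param rho_cp Volumetric heat capacity of air, J m-3 K-1.
#' @return Canopy temperature, deg C (vectorized).
#' @export
canopy_temperature <- function(t_air, e_c, lai, par = NULL, wind = NULL,
                               rn_abs = NULL, g_h = NULL, rho_cp = 1212) {
  if (is.null(rn_abs)) {
    if (is.null(par)) stop("supply 'par' or 'rn_abs'")
    rn_abs <- 0.217 * par / 0.45 * 0.5 * (1 - exp(-0.6 * lai))
  }
  if (is.null(g_h)) {
    if (is.null(wind)) stop("supply 'wind' or 'g_h'")
    g_h <- 0.04 * sqrt(pmax(wind, 0.3))
  }
  if (any(g_h <= 0)) stop("boundary-layer conductance must be positive")
  lambda_e <- 44 * e_c * lai  # 44 J per mmol H2O
  t_air + (rn_abs - lambda_e) / (rho_cp * g_h)
}

#' Read / write a genotype parameter file
#'
#' Structured key=value text mirroring the hydraulic trait table
#' field-for-field.
#'
#' @param path File path.
#' @return For `read_genotype_params`, a [genotype_params()] object.
#' @export
read_genotype_params <- function(path) {
  kv <- utils::read.table(path, sep = "=", strip.white = TRUE,
                          col.names = c("key", "value"),
                          stringsAsFactors = FALSE)
  v <- stats::setNames(kv$value, kv$key)
  num <- function(k) as.numeric(v[[k]])
  genotype_params(
    gsref = num("gsref"), e_sat = num("e_sat"),
    psi_pd_sat = num("psi_pd_sat"), psi_md_sat = num("psi_md_sat"),
    vc_shoot = vulnerability_curve(num("vc_shoot_b"), num("vc_shoot_c"),
                                   organ = "stem"),
    vc_root = vulnerability_curve(num("vc_root_b"), num("vc_root_c"),
                                  organ = "root"),
    root_to_leaf_area = num("root_to_leaf_area"),
    sla = if ("sla" %in% names(v)) num("sla") else NA_real_,
    genotype = if ("genotype" %in% names(v)) v[["genotype"]] else NA_character_)
}

#' @rdname read_genotype_params
#' @param params A [genotype_params()] object to write.
#' @export
write_genotype_params <- function(params, path) {
  lines <- c(
    paste0("genotype = ", params$genotype),
    paste0("gsref = ", params$gsref),
    paste0("e_sat = ", params$e_sat),
    paste0("psi_pd_sat = ", params$psi_pd_sat),
    paste0("psi_md_sat = ", params$psi_md_sat),
    paste0("vc_shoot_b = ", params$vc_shoot$b),
    paste0("vc_shoot_c = ", params$vc_shoot$c),
    paste0("vc_root_b = ", params$vc_root$b),
    paste0("vc_root_c = ", params$vc_root$c),
    paste0("root_to_leaf_area = ", params$root_to_leaf_area),
    paste0("sla = ", params$sla))
  writeLines(lines, path)
  invisible(path)
}
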