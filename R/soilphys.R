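#' Soil texture description
#'
#' @param clay,sand,silt Mass fractions of 1. Any one of the three may be
#'   omitted and is filled by closure; supplied fractions must sum to 1 within
#'   1e-6 when all three are given.
#' @param bulk_density Mg m-3 (0.9-2.0).
#' @param porosity m3 m-3; defaults to `1 - bulk_density / 2.65`.
#' @param gmd_mm Geometric mean particle diameter, mm (used as the rhizosphere
#'   characteristic length scale downstream; passed through, not derived).
#' @param gsd Geometric standard deviation of particle size (metadata).
#' @return Object of class `soil_texture`.
#' @examples
#' soil_texture(clay = 0.19, silt = 0.174, bulk_density = 1.59,
#'              porosity = 0.401)
#' @export
soil_texture <- function(clay, sand = NULL, silt = NULL, bulk_density = 1.5,
                         porosity = NULL, gmd_mm = 0.1, gsd = NA_real_) {
  if (is.null(sand) && is.null(silt))
    stop("supply at least two of clay, sand, silt")
  if (is.null(sand)) sand <- 1 - clay - silt
  if (is.null(silt)) silt <- 1 - clay - sand
  fr <- c(clay = clay, sand = sand, silt = silt)
  if (any(fr < -1e-9) || any(fr > 1))
    stop("fractions must lie in [0, 1]")
  if (abs(sum(fr) - 1) > 1e-6)
    stop("clay + sand + silt must equal 1 (got ", signif(sum(fr), 6), ")")
  if (bulk_density < 0.9 || bulk_density > 2.0)
    stop("bulk_density outside plausible range [0.9, 2.0] Mg m-3")
  if (is.null(porosity)) porosity <- 1 - bulk_density / 2.65
  if (porosity < 0.2 || porosity > 0.7)
    stop("porosity outside plausible range [0.2, 0.7]")
  if (abs(porosity - (1 - bulk_density / 2.65)) > 0.1)
    stop("porosity inconsistent with bulk density (|diff| > 0.1)")
  structure(list(clay = clay, sand = sand, silt = silt,
                 bulk_density = bulk_density, porosity = porosity,
                 gmd_mm = gmd_mm, gsd = gsd),
            class = "soil_texture")
}

#' @export
print.soil_texture <- function(x, ...) {
  cat(sprintf("Soil texture: clay %.3f / sand %.3f / silt %.3f\n",
              x$clay, x$sand, x$silt))
  cat(sprintf("  bulk density %.3g Mg m-3, porosity %.4g m3 m-3\n",
              x$bulk_density, x$porosity))
  invisible(x)
}

#' Construct Brooks-Corey soil hydraulic parameters directly
#'
#' Usually produced by [pedotransfer()]; this constructor supports building
#' parameter sets from literature values or for testing.
#'
#' @param psi_e Air-entry matric potential, MPa (< 0).
#' @param lambda_bc Pore-size distribution index (> 0).
#' @param ks_soil Saturated hydraulic conductivity, m s-1 (> 0).
#' @param theta_s,theta_r Saturated and residual water contents
#'   (`theta_r < theta_s`).
#' @param gmd_mm Geometric mean particle diameter, mm.
#' @return Object of class `soil_hydraulic_params`.
#' @export
soil_hydraulic_params <- function(psi_e, lambda_bc, ks_soil, theta_s,
                                  theta_r, gmd_mm = 0.1) {
  if (psi_e >= 0) stop("psi_e must be negative")
  if (lambda_bc <= 0) stop("lambda_bc must be positive")
  if (ks_soil <= 0) stop("ks_soil must be positive")
  if (theta_r >= theta_s) stop("need theta_r < theta_s")
  structure(list(psi_e = psi_e, lambda_bc = lambda_bc, ks_soil = ks_soil,
                 theta_s = theta_s, theta_r = theta_r, gmd_mm = gmd_mm,
                 variant = "manual"),
            class = "soil_hydraulic_params")
}

# Rawls-Brakensiek (1985-family) Brooks-Corey regression coefficients.
# Predictors: C = clay %, S = sand %, P = porosity (fraction).
# Terms are named so an alternative variant can be swapped in as another table.
.rb85 <- list(
  # ln(bubbling pressure, cm)
  psi_e = c(const = 5.3396738, C = 0.1845038, P = -2.48394546,
            C2 = -0.00213853, SP = -0.04356349, CP = -0.61745089,
            S2P2 = 0.00143598, C2P2 = -0.00855375, S2C = -0.00001282,
            C2P = 0.00895359, S2P = -0.00072472, C2S = 0.0000054,
            P2C = 0.50028060),
  # ln(pore-size distribution index, lambda)
  lambda = c(const = -0.7842831, S = 0.0177544, P = -1.062498,
             S2 = -0.00005304, C2 = -0.00273493, P2 = 1.11134946,
             SP = -0.03088295, S2P2 = 0.00026587, C2P2 = -0.00610522,
             S2C = -0.00000235, C2P = 0.00798746, P2C = -0.00674491),
  # residual water content (fraction)
  theta_r = c(const = -0.0182482, S = 0.00087269, C = 0.00513488,
              P = 0.02939286, C2 = -0.00015395, SP = -0.0010827,
              C2P2 = -0.00018233, C2P = 0.00030703, P2C = -0.0023584),
  # ln(saturated conductivity, cm/h)
  ks = c(const = -8.96847, P = 19.52348, C = -0.028212, S2 = 0.00018107,
         C2 = -0.0094125, P2 = -8.395215, SP = 0.077718, S2P2 = -0.00298,
         C2P2 = -0.019492, S2C = 0.0000173, C2P = 0.02733, S2P = 0.001434,
         C2S = -0.0000035)
)

.rb_terms <- function(C, S, P) {
  c(const = 1, C = C, S = S, P = P, C2 = C^2, S2 = S^2, P2 = P^2,
    SP = S * P, CP = C * P, S2P2 = S^2 * P^2, C2P2 = C^2 * P^2,
    S2C = S^2 * C, C2P = C^2 * P, S2P = S^2 * P, C2S = C^2 * S,
    P2C = P^2 * C)
}

.rb_eval <- function(coefs, C, S, P) {
  tt <- .rb_terms(C, S, P)
  sum(coefs * tt[names(coefs)])
}

#' Derive Brooks-Corey soil hydraulic parameters from texture
#'
#' Pedotransfer via the Rawls-Brakensiek regression family (clay, sand and
#' porosity as predictors), returning the air-entry potential, pore-size
#' index, saturated conductivity and residual/saturated water contents that
#' the rhizosphere element of the hydraulic model needs. Coefficients live in
#' an internal table keyed by `variant` so another regression family can be
#' swapped in.
#'
#' @param texture A [soil_texture()].
#' @param variant Coefficient table to use (only
#'   `"rawls_brakensiek_1985"` is shipped).
#' @return Object of class `soil_hydraulic_params` with fields `psi_e` (MPa,
#'   < 0), `lambda_bc` (> 0), `ks_soil` (m s-1), `theta_s`, `theta_r`, and
#'   the pass-through `gmd_mm`.
#' @export
pedotransfer <- function(texture, variant = "rawls_brakensiek_1985") {
  stopifnot(inherits(texture, "soil_texture"))
  variant <- match.arg(variant)
  clay <- texture$clay; sand <- texture$sand
  if (clay > 0.6 || sand > 0.95) {
    warning("texture outside regression validity; clamping clay <= 0.6, sand <= 0.95")
    clay <- min(clay, 0.6); sand <- min(sand, 0.95)
  }
  C <- 100 * clay; S <- 100 * sand; P <- texture$porosity
  hb_cm <- exp(.rb_eval(.rb85$psi_e, C, S, P))       # bubbling pressure, cm H2O
  lambda <- exp(.rb_eval(.rb85$lambda, C, S, P))
  theta_r <- max(0.001, .rb_eval(.rb85$theta_r, C, S, P))
  ks_cmh <- exp(.rb_eval(.rb85$ks, C, S, P))
  theta_s <- min(texture$porosity, P)                 # never exceeds porosity
  if (theta_r >= theta_s) theta_r <- 0.5 * theta_s
  out <- structure(list(psi_e = -hb_cm * 9.81e-5,     # cm H2O -> MPa
                        lambda_bc = lambda,
                        ks_soil = ks_cmh / 100 / 3600, # cm/h -> m/s
                        theta_s = theta_s,
                        theta_r = theta_r,
                        gmd_mm = texture$gmd_mm,
                        variant = variant),
                   class = "soil_hydraulic_params")
  out
}

#' @export
print.soil_hydraulic_params <- function(x, ...) {
  cat("Brooks-Corey soil hydraulic parameters (", x$variant, ")\n", sep = "")
  cat(sprintf("  psi_e = %.4g MPa, lambda = %.3g\n", x$psi_e, x$lambda_bc))
  cat(sprintf("  Ks = %.3g m s-1, theta_s = %.3f, theta_r = %.3f\n",
              x$ks_soil, x$theta_s, x$theta_r))
  invisible(x)
}

# fast unchecked vectorized retention helpers used in the simulation loop
.theta_to_psi <- function(p, theta) {
  se <- (theta - p$theta_r) / (p$theta_s - p$theta_r)
  se <- pmin(se, 1)
  ifelse(se <= 0, -Inf, p$psi_e * se^(-1 / p$lambda_bc))
}

.psi_to_theta <- function(p, psi) {
  ifelse(psi >= p$psi_e, p$theta_s,
         p$theta_r + (p$theta_s - p$theta_r) * (psi / p$psi_e)^(-p$lambda_bc))
}

#' Brooks-Corey water retention (both directions)
#'
#' \eqn{\psi = \psi_e S_e^{-1/\lambda}} with
#' \eqn{S_e = (\theta - \theta_r)/(\theta_s - \theta_r)}; the inverse is exact
#' so a round trip is the identity. Potentials wetter than the air entry
#' point map to saturation.
#'
#' @param params A `soil_hydraulic_params` object.
#' @param theta Volumetric water content(s), for the theta -> psi direction.
#' @param psi Matric potential(s) in MPa, for the psi -> theta direction.
#'   Supply exactly one of `theta` / `psi`.
#' @return Matric potential (MPa) or water content, matching the input.
#' @export
retention <- function(params, theta = NULL, psi = NULL) {
  stopifnot(inherits(params, "soil_hydraulic_params"))
  if (is.null(theta) == is.null(psi))
    stop("supply exactly one of 'theta' or 'psi'")
  if (!is.null(theta)) {
    if (any(theta > params$theta_s + 1e-9))
      stop("theta exceeds theta_s")
    if (any(theta <= params$theta_r))
      stop("theta at or below residual water content: matric potential is unbounded")
    .theta_to_psi(params, theta)
  } else {
    if (any(psi > 0)) stop("matric potential must be <= 0 MPa")
    .psi_to_theta(params, psi)
  }
}

#' Brooks-Corey unsaturated hydraulic conductivity
#'
#' \eqn{K(\theta) = K_s S_e^{3 + 2/\lambda}} (Campbell/Brooks-Corey form).
#'
#' @param params A `soil_hydraulic_params` object.
#' @param theta Volumetric water content(s).
#' @return Conductivity in m s-1.
#' @export
unsat_conductivity <- function(params, theta) {
  stopifnot(inherits(params, "soil_hydraulic_params"))
  if (any(theta > params$theta_s + 1e-9)) stop("theta exceeds theta_s")
  se <- pmin(1, pmax(0, (theta - params$theta_r) /
                       (params$theta_s - params$theta_r)))
  params$ks_soil * se^(3 + 2 / params$lambda_bc)
}

#' Field capacity and permanent wilting point
#'
#' Water contents at matric potentials of -33 kPa (field capacity) and
#' -1500 kPa (permanent wilting point) via the retention inverse.
#'
#' @param params A `soil_hydraulic_params` object.
#' @return Named numeric vector `c(theta_fc, theta_pwp)`.
#' @export
fc_pwp <- function(params) {
  stopifnot(inherits(params, "soil_hydraulic_params"))
  c(theta_fc = .psi_to_theta(params, -0.033),
    theta_pwp = .psi_to_theta(params, -1.5))
}
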