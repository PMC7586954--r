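# a single-Weibull-element network: shoot carries the curve, the root side is
# made non-limiting (huge conductance, near-flat curve, no rhizosphere)
single_element_net <- function(kmax, b, cc, psi_s = 0, cap_frac = 0.9) {
  structure(list(ks = kmax, bs = b, cs = cc,
                 kr = 1e9, br = 50, cr = 2,
                 g = Inf, psi_s = psi_s, kmax = kmax, cap_frac = cap_frac),
            class = "hydraulic_network")
}

test_that("saturated whole-plant conductance follows E_sat over the drawdown", {
  dp <- fixture_params()
  expect_equal(kmax_saturated(dp$species), 11.4 / 1.6)  # 7.125
  g2 <- dp$species; g2$e_sat <- 22.8
  expect_equal(kmax_saturated(g2), 2 * kmax_saturated(dp$species))
  g3 <- dp$species; g3$psi_md_sat <- -0.8
  expect_error(kmax_saturated(g3), "undefined")
})

test_that("critical transpiration of one Weibull element matches the closed form", {
  # E_crit = kmax * b * Gamma(1 + 1/c) for a saturated single element
  set.seed(12)
  for (i in 1:20) {
    b <- runif(1, 0.3, 4); cc <- runif(1, 0.4, 3); km <- runif(1, 2, 20)
    net <- single_element_net(km, b, cc)
    ec <- supply_function(net)$e_crit
    expect_lt(abs(ec - km * b * gamma(1 + 1 / cc)) / ec, 1e-3)
  }
  # the worked case: b = 1.55, c = 0.75 gives 1.846 kmax
  net <- single_element_net(1, 1.55, 0.75)
  expect_equal(supply_function(net)$e_crit, 1.846, tolerance = 1e-3)
  # cross-check the closed form itself by adaptive quadrature
  q <- integrate(function(x) exp(-(x / 1.55)^0.75), 0, Inf)$value
  expect_equal(1.55 * gamma(1 + 1 / 0.75), q, tolerance = 1e-6)
})

test_that("supply function vanishes at soil potential and E_crit falls as soil dries", {
  net <- single_element_net(10, 1.55, 0.75, psi_s = -0.5)
  sf <- supply_function(net)
  expect_equal(sf$fun(-0.5), 0)
  expect_equal(sf$fun(-0.2), 0)  # no reverse flow
  ecs <- vapply(c(0, -0.25, -0.5, -1, -2),
                function(p) supply_function(net, p)$e_crit, numeric(1))
  expect_true(all(diff(ecs) < 0))
  # supply curve is nondecreasing in drawdown
  e <- sf$fun(seq(-0.5, -6, length.out = 40))
  expect_true(all(diff(e) >= -1e-9))
})

test_that("solve_demand agrees with bisection on the tabulated supply curve", {
  dp <- fixture_params()
  hyd <- fixture_lc_hyd()
  net <- build_continuum(dp$species, hyd, theta = 0.23, lai = 3.5,
                         root_profile = dp$root_profile)
  sf <- supply_function(net)
  for (frac in c(0.2, 0.5, 0.8)) {
    e_t <- frac * 0.9 * sf$e_crit
    st <- solve_demand(net, e_target = e_t)
    # independent bisection on the supply curve E(psi_leaf) = e_target
    root <- uniroot(function(pl) sf$fun(pl) - e_t, c(-40, max(net$psi_s)),
                    tol = 1e-9)$root
    expect_lt(abs(st$psi_leaf - root), 1e-6)
    # flux conservation across layers
    expect_lt(abs(sum(st$layer_uptake) - st$e_c) / st$e_c, 1e-9)
  }
})

test_that("zero demand equilibrates to weighted soil potential; excess demand is capped", {
  dp <- fixture_params()
  hyd <- fixture_lc_hyd()
  net <- build_continuum(dp$species, hyd, theta = 0.25, lai = 3.5,
                         root_profile = dp$root_profile)
  st0 <- solve_demand(net, e_target = 0)
  expect_equal(st0$e_c, 0)
  expect_equal(st0$psi_leaf, net$psi_s[1], tolerance = 1e-6)  # uniform soil
  st2 <- solve_demand(net, e_target = 2 * st0$e_crit)
  expect_true(st2$capped)
  expect_equal(st2$e_c, net$cap_frac * st2$e_crit, tolerance = 1e-9)
  expect_error(solve_demand(net, e_target = -1), ">= 0")
})

test_that("per-layer uptake scales with root area fraction under uniform soil", {
  dp <- fixture_params()
  hyd <- fixture_lc_hyd()
  net2 <- build_continuum(dp$species, hyd, theta = 0.23, lai = 3.5,
                          root_profile = c(0.5, 0.5))
  st <- solve_demand(net2, e_target = 3)
  expect_equal(st$layer_uptake[1], st$layer_uptake[2], tolerance = 1e-9)
  net82 <- build_continuum(dp$species, hyd, theta = 0.23, lai = 3.5,
                           root_profile = c(0.8, 0.2))
  st82 <- solve_demand(net82, e_target = 3)
  expect_equal(st82$layer_uptake[1] / st82$layer_uptake[2], 4,
               tolerance = 1e-6)
  expect_error(build_continuum(dp$species, hyd, 0.23, 3.5,
                               root_profile = c(0, 0)), "zero root area")
})

test_that("the saturated reference state reproduces the midday potential", {
  dp <- fixture_params()
  for (soil in c("LC", "HC")) {
    hyd <- pedotransfer(dp$soils[[soil]])
    net <- build_continuum(dp$species, hyd, theta = hyd$theta_s, lai = 3.5,
                          root_profile = dp$root_profile)
    st <- solve_demand(net, layer_psis = rep(0, 5), e_target = 11.4)
    expect_lt(abs(st$psi_leaf - dp$species$psi_md_sat), 0.3)
    expect_false(st$capped)
  }
})

test_that("a steeper shoot VC transpires less under identical dry-soil forcing", {
  dp <- fixture_params()
  hyd <- fixture_lc_hyd()
  mult <- build_continuum(dp$species, hyd, hyd$theta_s, 3.5,
                          root_profile = dp$root_profile)$calib_mult
  th_dry <- 0.19
  e_dry <- sapply(c("TipoChaco", "PD3"), function(g) {
    net <- build_continuum(dp$genotypes[[g]], hyd, th_dry, 3.5,
                           root_profile = dp$root_profile, calib_mult = mult)
    solve_demand(net, e_target = 11)$e_c
  })
  expect_lt(e_dry[["TipoChaco"]], e_dry[["PD3"]])
})

test_that("stomatal model hits its reference point and closure", {
  dp <- fixture_params()
  expect_equal(stomatal_conductance(dp$species, vpd = 1), 0.63)
  expect_equal(stomatal_conductance(dp$species, vpd = exp(1 / 0.6) + 0.01), 0)
  e1 <- stomatal_demand(dp$species, vpd = 2, lai = 2)
  e2 <- stomatal_demand(dp$species, vpd = 2, lai = 4)
  expect_equal(e2, 2 * e1)
  expect_error(stomatal_demand(dp$species, vpd = 0, lai = 2), "> 0")
  # light scaling: 1 at the cuvette reference, below 1 in dimmer light
  g_ref <- stomatal_conductance(dp$species, 1, par = 2000)
  g_dim <- stomatal_conductance(dp$species, 1, par = 300)
  expect_equal(g_ref, 0.63)
  expect_lt(g_dim, g_ref)
})

test_that("canopy temperature follows the single-leaf energy balance", {
  # latent flux balancing absorbed radiation pins T_c at T_air
  e_bal <- 400 / 44  # mmol m-2 s-1 at lai = 1
  expect_equal(canopy_temperature(30, e_bal, lai = 1, rn_abs = 400,
                                  g_h = 1, rho_cp = 50), 30)
  # no transpiration under load warms the canopy
  expect_gt(canopy_temperature(30, 0, lai = 1, rn_abs = 400, g_h = 0.05), 30)
  # stated arithmetic: (400 - 200) / 50 = 4 K
  expect_equal(canopy_temperature(30, 200 / 44, lai = 1, rn_abs = 400,
                                  g_h = 1, rho_cp = 50) - 30, 4)
  expect_error(canopy_temperature(30, 1, 1, rn_abs = 400, g_h = 0),
               "positive")
})

test_that("genotype parameter files round-trip", {
  dp <- fixture_params()
  path <- tempfile(fileext = ".txt")
  write_genotype_params(dp$species, path)
  g <- read_genotype_params(path)
  expect_equal(g$gsref, 0.63)
  expect_equal(g$vc_shoot$b, 1.55)
  expect_equal(kmax_saturated(g), 7.125)
})
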