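# shared fixtures built in code; kept tiny so individual tests stay fast

fixture_params <- function() default_params()

fixture_lc_hyd <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- pedotransfer(default_params()$soils$LC)
    val
  }
})

fixture_hc_hyd <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- pedotransfer(default_params()$soils$HC)
    val
  }
})

# a short forcing window for fast simulation tests
fixture_forcing_short <- function(n_days = 10, depth_mm = 16,
                                  interval_days = 2, seed = 7) {
  gen_meteo(n_days = n_days, start_doy = 160, seed = seed,
            irrigation = list(interval_days = interval_days,
                              depth_mm = depth_mm, hour = 6))
}

fixture_config <- function(genotype = default_params()$species,
                           soil = fixture_lc_hyd(), lai = 3.5, ...) {
  sim_config(genotype, soil, lai = lai,
             root_profile = default_params()$root_profile, ...)
}
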