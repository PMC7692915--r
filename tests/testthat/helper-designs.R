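# Shared design helpers: small, noiseless or low-noise survey designs used
# across the unit tests.

zero_noise <- list(do_sd = 0, ts_sd = 0, mass_sd = 0)

noiseless_design <- function(n_sites = 4, strips = 2, seed = 1,
                             rate_params = default_rate_params(),
                             site_sd = 0, temp_daily_sd = 0) {
  survey_design(
    n_sites = n_sites, strips_per_location = strips,
    residual_sd = 0, site_sd = site_sd,
    temp_daily_sd = temp_daily_sd,
    measurement_noise = zero_noise,
    rate_params = rate_params, seed = seed
  )
}

# a rate_params list with one shared Ea across locations and no location
# offsets; channel intercepts keep their (very different) natural scales
flat_rate_params <- function(ea = 0.73, ln_ref_resp = -0.28) {
  loc <- c("U2", "U1", "D")
  chan <- function(ln_ref) {
    list(lnEF_at_Tref = ln_ref,
         ea_by_location = stats::setNames(rep(ea, 3), loc),
         location_offsets = stats::setNames(rep(0, 3), loc))
  }
  list(respiration = chan(ln_ref_resp), ts = chan(-3.7), mass = chan(-5.1))
}
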