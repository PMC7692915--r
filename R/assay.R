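#' Microbial respiration from a chamber dissolved-oxygen budget
#'
#' Computes the mass-specific oxygen consumption of the microbial biofilm on
#' a cotton strip from start/end dissolved-oxygen (DO) concentrations in a
#' closed incubation chamber, corrected for drift in a strip-free blank
#' chamber:
#' \deqn{R_{CS} = \frac{(DO_{S0} - DO_{CSt}) - (DO_{S0} - DO_{Ct})\,V_{H2O}}
#'   {m_{CS}\,t}}
#' i.e. the blank-corrected DO drawdown scaled by chamber volume and divided
#' by strip dry mass and incubation time. All arguments are vectorised;
#' recycling follows the usual rules.
#'
#' The result can legitimately be negative when blank drift exceeds the
#' sample drawdown (probe noise, photosynthesis in the blank); such values
#' are returned as-is so that callers can flag rather than silently drop
#' them (see [assay_table()]).
#'
#' @param do_stream_start DO in the stream water at the start (mg O2/L).
#' @param do_chamber_end DO in the strip chamber at the end (mg O2/L).
#' @param do_blank_end DO in the blank chamber at the end (mg O2/L).
#' @param chamber_volume Chamber water volume (L); must be > 0.
#' @param strip_mass Strip dry mass (g); must be > 0.
#' @param duration Incubation duration (hours); must be > 0.
#' @return Respiration rate, mg O2 hr^-1 g^-1 dry mass.
#' @seealso [o2_to_carbon()], [decay_coefficient()]
#' @examples
#' respiration_rate(10, 8, 9, chamber_volume = 0.05, strip_mass = 0.5,
#'                  duration = 1)
#' @export
respiration_rate <- function(do_stream_start, do_chamber_end, do_blank_end,
                             chamber_volume, strip_mass, duration) {
  if (any(chamber_volume <= 0)) stop("chamber_volume must be > 0", call. = FALSE)
  if (any(strip_mass <= 0)) stop("strip_mass must be > 0", call. = FALSE)
  if (any(duration <= 0)) stop("duration must be > 0", call. = FALSE)
  if (any(c(do_stream_start, do_chamber_end, do_blank_end) < 0)) {
    stop("dissolved-oxygen concentrations must be >= 0", call. = FALSE)
  }
  drawdown <- (do_stream_start - do_chamber_end) -
    (do_stream_start - do_blank_end)
  drawdown * chamber_volume / (strip_mass * duration)
}

#' Convert an oxygen consumption rate to carbon production
#'
#' Scales an O2 consumption rate to CO2-carbon production using a
#' respiratory quotient (RQ, mol CO2 per mol O2) and the molar masses of O2
#' (32 g/mol) and C (12 g/mol): `rate_o2 / 32 * RQ * 12`.
#'
#' @param rate_o2 O2 consumption (mg O2 hr^-1 g^-1 DM); vectorised.
#' @param rq Respiratory quotient (mol CO2 / mol O2); must be > 0. The
#'   default 1.2 is a calibration constant typical of humic-influenced
#'   running waters and should be set from local measurements when known.
#' @return Carbon production, mg C hr^-1 g^-1 DM.
#' @examples
#' o2_to_carbon(1, rq = 1)   # 0.375
#' @export
o2_to_carbon <- function(rate_o2, rq = 1.2) {
  if (!is.numeric(rq) || length(rq) != 1L || rq <= 0) {
    stop("rq must be a single value > 0", call. = FALSE)
  }
  rate_o2 / MOLAR_MASS_O2 * rq * MOLAR_MASS_C
}

MOLAR_MASS_O2 <- 32  # g/mol
MOLAR_MASS_C <- 12   # g/mol

#' Reference baseline from non-incubated strips
#'
#' Mean (with n and SD) of measurements on reference strips that were
#' sterilized and stored but never incubated; the mean is the `TS_0` (or
#' initial-mass) denominator of [decay_coefficient()].
#'
#' @param values Numeric vector of reference measurements; all > 0.
#' @return List with `mean`, `n`, `sd` (`sd` is `NA` for a single strip).
#' @export
reference_baseline <- function(values) {
  if (length(values) == 0L) stop("at least one reference value is required", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("reference values must be finite and > 0", call. = FALSE)
  }
  list(mean = mean(values), n = length(values),
       sd = if (length(values) > 1L) stats::sd(values) else NA_real_)
}

#' Exponential decay coefficient from loss of tensile strength or mass
#'
#' \deqn{k = -\ln(X_t / X_0) / t}
#' where `X_t` is the final measurement on an incubated strip, `X_0` the
#' mean of reference strips, and `t` the elapsed time. The same form serves
#' tensile strength and mass, and `t` may be days (giving `k_D`, day^-1) or
#' a temperature-day basis from [temperature_days()] (giving `k_TD`).
#'
#' @param final Final measurement(s); must be > 0 (total loss is not
#'   representable on the log scale).
#' @param baseline_mean Reference mean (scalar, > 0), e.g.
#'   `reference_baseline(x)$mean`.
#' @param t Elapsed time on the chosen basis; > 0. Vectorised with `final`.
#' @return List with `k` (per unit `t`) and `negative_flag` (`TRUE` where
#'   `final > baseline_mean`, i.e. an apparent strengthening; the value is
#'   retained, the flag lets model stages exclude it).
#' @examples
#' decay_coefficient(50, 100, t = 14)$k  # ln(2)/14
#' @export
decay_coefficient <- function(final, baseline_mean, t) {
  if (any(!is.finite(final)) || any(final <= 0)) {
    stop("final measurements must be finite and > 0", call. = FALSE)
  }
  if (length(baseline_mean) != 1L || !is.finite(baseline_mean) ||
      baseline_mean <= 0) {
    stop("baseline_mean must be a single value > 0", call. = FALSE)
  }
  if (any(t <= 0)) stop("t must be > 0", call. = FALSE)
  k <- -log(final / baseline_mean) / t
  list(k = k, negative_flag = final > baseline_mean)
}

#' Accumulated temperature-days over an incubation
#'
#' Two conventions over a daily mean water-temperature series:
#' `"degree_day"` is the classic sum of daily mean temperatures in Celsius;
#' `"boltzmann_inverse"` sums `1 / (k_B T)` over days with `T` in Kelvin and
#' `k_B = 8.6e-5` eV/K, placing the cumulative basis on the same inverse
#' Boltzmann temperature scale as the Arrhenius model, so decay per unit of
#' it ("k_TD") is temperature-corrected consistently with the activation
#' energy analysis.
#'
#' @param temps_celsius Daily mean temperatures (deg C), one per day;
#'   non-empty, all > -273.15.
#' @param convention `"boltzmann_inverse"` (default) or `"degree_day"`.
#' @return Scalar accumulated basis (deg C days, or eV^-1).
#' @examples
#' temperature_days(c(8, 9, 10), "degree_day")  # 27
#' @export
temperature_days <- function(temps_celsius,
                             convention = c("boltzmann_inverse", "degree_day")) {
  convention <- match.arg(convention)
  if (length(temps_celsius) == 0L) {
    stop("temperature series must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(temps_celsius)) || any(temps_celsius <= -273.15)) {
    stop("temperatures must be finite and above absolute zero", call. = FALSE)
  }
  switch(convention,
    degree_day = sum(temps_celsius),
    boltzmann_inverse = sum(1 / (BOLTZMANN_EV * (temps_celsius + 273.15)))
  )
}

#' Boltzmann constant in electron volts per Kelvin
#' @keywords internal
BOLTZMANN_EV <- 8.6e-5

#' Per-strip assay table: respiration, carbon, and decay coefficients
#'
#' Applies [respiration_rate()], [o2_to_carbon()] and [decay_coefficient()]
#' to every strip of a survey dataset (measured or simulated,
#' see [generate_survey()]), using each site x location's daily temperature
#' series for the temperature-day basis.
#'
#' @param dataset A `csa_survey` as returned by [generate_survey()] or
#'   [read_measurements()].
#' @param rq Respiratory quotient passed to [o2_to_carbon()].
#' @param td_convention Temperature-day convention for `k_td_ts`
#'   (see [temperature_days()]).
#' @return A data.frame with one row per strip: site, location, strip_id,
#'   `resp_o2`, `resp_c`, `k_d_ts`, `k_td_ts`, `k_d_mass`, and logical flag
#'   columns `flag_negative_resp`, `flag_negative_k` marking records that
#'   must be excluded from ln-scale model fits.
#' @export
assay_table <- function(dataset, rq = 1.2,
                        td_convention = "boltzmann_inverse") {
  stopifnot(inherits(dataset, "csa_survey"))
  strips <- dataset$strips
  resp_o2 <- respiration_rate(
    strips$do_stream_start, strips$do_chamber_end, strips$do_blank_end,
    strips$chamber_volume_L, strips$strip_mass_g, strips$assay_duration_hr
  )
  resp_c <- o2_to_carbon(resp_o2, rq = rq)

  ts0 <- reference_baseline(dataset$reference$ts)$mean
  m0 <- reference_baseline(dataset$reference$mass)$mean

  # temperature-day basis per site x location
  key <- paste(strips$site, strips$location, sep = "\r")
  temps <- dataset$temperature
  tkey <- paste(temps$site, temps$location, sep = "\r")
  td_by_key <- vapply(unique(key), function(k) {
    temperature_days(temps$temp_c[tkey == k], td_convention)
  }, 0)

  kd_ts <- decay_coefficient(strips$ts_final_N, ts0, strips$incubation_days)
  ktd_ts <- decay_coefficient(strips$ts_final_N, ts0, td_by_key[key])
  kd_m <- decay_coefficient(strips$mass_final_g, m0, strips$incubation_days)

  data.frame(
    site = strips$site, location = strips$location,
    strip_id = strips$strip_id,
    resp_o2 = resp_o2, resp_c = resp_c,
    k_d_ts = kd_ts$k, k_td_ts = ktd_ts$k, k_d_mass = kd_m$k,
    mean_temp_c = vapply(unique(key), function(k) {
      mean(temps$temp_c[tkey == k])
    }, 0)[key],
    flag_negative_resp = resp_o2 <= 0,
    flag_negative_k = kd_ts$negative_flag | kd_m$negative_flag,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
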