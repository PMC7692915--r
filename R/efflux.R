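#' Configuration for areal carbon evasion and national upscaling
#'
#' All scaling constants for the evasion chain are held here and never
#' hard-coded in formulas. The defaults are calibration constants for the
#' Swiss survey context:
#' \itemize{
#'   \item `areal_dm_density` (g DM m^-2): surrogate areal density of
#'     cotton-substrate dry mass that converts mass-specific respiration to
#'     an areal flux; 3350 g m^-2 maps a typical upstream respiration of
#'     0.811 mg C hr^-1 g^-1 to ~23.8 kg C m^-2 yr^-1.
#'   \item `national_baseline_flux` (Gg C yr^-1): baseline CO2 evasion from
#'     wastewater-affected small-to-medium (order 1-6) streams, used by the
#'     relative upscaling approach.
#'   \item `affected_fraction`: share of that baseline affected by effluent.
#'   \item `affected_surface_area` (m^2): surface area of affected reaches,
#'     used by the absolute upscaling approach.
#' }
#'
#' @param areal_dm_density Areal dry-mass density, g DM m^-2 (> 0).
#' @param hours_per_year Hours per year (8760).
#' @param national_baseline_flux Baseline national flux, Gg C yr^-1.
#' @param affected_surface_area Affected stream surface area, m^2.
#' @param affected_fraction Fraction in [0, 1].
#' @param bootstrap_reps Bootstrap resamples for CIs.
#' @param seed Integer seed for the bootstrap.
#' @return List of class `evasion_config`.
#' @export
evasion_config <- function(areal_dm_density = 3350,
                           hours_per_year = 8760,
                           national_baseline_flux = 77.1,
                           affected_surface_area = 3.7e7,
                           affected_fraction = 1,
                           bootstrap_reps = 10000,
                           seed = 1L) {
  if (areal_dm_density <= 0) stop("areal_dm_density must be > 0", call. = FALSE)
  if (hours_per_year <= 0) stop("hours_per_year must be > 0", call. = FALSE)
  if (national_baseline_flux < 0) stop("national_baseline_flux must be >= 0", call. = FALSE)
  if (affected_surface_area < 0) stop("affected_surface_area must be >= 0", call. = FALSE)
  if (affected_fraction < 0 || affected_fraction > 1) {
    stop("affected_fraction must be in [0, 1]", call. = FALSE)
  }
  if (bootstrap_reps < 1) stop("bootstrap_reps must be >= 1", call. = FALSE)
  structure(list(areal_dm_density = areal_dm_density,
                 hours_per_year = hours_per_year,
                 national_baseline_flux = national_baseline_flux,
                 affected_surface_area = affected_surface_area,
                 affected_fraction = affected_fraction,
                 bootstrap_reps = bootstrap_reps,
                 seed = as.integer(seed)),
            class = "evasion_config")
}

#' Areal carbon efflux from mass-specific respiration
#'
#' `resp_c * areal_dm_density * hours_per_year * 1e-6`, converting
#' mg C hr^-1 g^-1 DM to kg C m^-2 yr^-1 via the configured areal dry-mass
#' density. Linear in both the rate and the density; relative (downstream /
#' upstream) changes are therefore invariant to the density choice.
#'
#' @param resp_c Carbon production, mg C hr^-1 g^-1 DM (vectorised).
#' @param cfg An [evasion_config()].
#' @return Areal flux, kg C m^-2 yr^-1.
#' @export
areal_efflux <- function(resp_c, cfg = evasion_config()) {
  stopifnot(inherits(cfg, "evasion_config"))
  resp_c * cfg$areal_dm_density * cfg$hours_per_year * 1e-6
}

#' Median relative downstream change with a site bootstrap CI
#'
#' Per site, the relative change is `(D - U1) / U1`; the summary statistic
#' is the median across sites, with a seeded nonparametric percentile
#' bootstrap CI obtained by resampling sites (not strips) with replacement.
#'
#' @param u1 Upstream (U1) per-site values (e.g. median areal flux); no zeros.
#' @param d Downstream (D) per-site values, same order/length as `u1`.
#' @param reps Bootstrap resamples.
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @param sites Optional site labels used in error messages.
#' @return List with `rel_change` (per site), `median`, `ci` (percentile),
#'   `reps`.
#' @export
site_relative_change <- function(u1, d, reps = 10000, seed = 1L,
                                 conf = 0.95, sites = NULL) {
  if (length(u1) != length(d) || length(u1) < 1L) {
    stop("u1 and d must be equal-length, non-empty", call. = FALSE)
  }
  if (any(u1 == 0)) {
    lab <- if (is.null(sites)) which(u1 == 0) else sites[u1 == 0]
    stop("zero upstream value at site(s): ", paste(lab, collapse = ", "),
         call. = FALSE)
  }
  rel <- (d - u1) / u1
  n <- length(rel)
  med <- stats::median(rel)
  if (n == 1L) {
    ci <- c(med, med)
  } else {
    boot <- with_seed(seed, {
      idx <- matrix(sample.int(n, n * reps, replace = TRUE), nrow = reps)
      apply(idx, 1L, function(i) stats::median(rel[i]))
    })
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 7))
  }
  list(rel_change = rel, median = med, ci = ci, reps = reps)
}

#' National upscaling, relative approach
#'
#' Scales a baseline national flux by the affected fraction and the median
#' relative change: `national_baseline_flux * affected_fraction *
#' median_rel_change` (Gg C yr^-1). This is the headline approach: it only
#' needs the relative change, so it is invariant to the areal dry-mass
#' density used in [areal_efflux()].
#'
#' @param cfg An [evasion_config()].
#' @param median_rel_change Median relative change, e.g. 0.385 for +38.5%.
#' @return Additional national evasion, Gg C yr^-1.
#' @export
upscale_relative <- function(cfg, median_rel_change) {
  stopifnot(inherits(cfg, "evasion_config"))
  cfg$national_baseline_flux * cfg$affected_fraction * median_rel_change
}

#' National upscaling, absolute approach
#'
#' Multiplies the median absolute areal change (kg C m^-2 yr^-1) by the
#' affected stream surface area (m^2) and converts kg to Gg (1e-6).
#'
#' @param cfg An [evasion_config()].
#' @param median_areal_diff Median downstream - upstream areal flux
#'   difference, kg C m^-2 yr^-1.
#' @return Additional national evasion, Gg C yr^-1.
#' @export
upscale_absolute <- function(cfg, median_areal_diff) {
  stopifnot(inherits(cfg, "evasion_config"))
  median_areal_diff * cfg$affected_surface_area * 1e-6
}

#' Evasion summary for an assay table
#'
#' Computes per-strip areal fluxes, per-site medians by location, the
#' median relative downstream change with its bootstrap CI, and both
#' national upscaling approaches.
#'
#' @param assay An [assay_table()] data.frame (needs `resp_c`, `site`,
#'   `location`).
#' @param cfg An [evasion_config()].
#' @param upstream,downstream Location labels of the contrast (default
#'   `"U1"` vs `"D"`).
#' @return List of class `evasion_estimate`: `per_site` (data.frame of site,
#'   location, median flux), `rel` ([site_relative_change()] output),
#'   `median_areal_diff`, `national_A_Gg`, `national_B_Gg`.
#' @export
evasion_summary <- function(assay, cfg = evasion_config(),
                            upstream = "U1", downstream = "D") {
  flux <- areal_efflux(assay$resp_c, cfg)
  per_site <- stats::aggregate(
    list(median_flux = flux),
    by = list(site = assay$site, location = assay$location),
    FUN = stats::median
  )
  u <- per_site[per_site$location == upstream, c("site", "median_flux")]
  dn <- per_site[per_site$location == downstream, c("site", "median_flux")]
  common <- intersect(u$site, dn$site)
  if (length(common) == 0L) stop("no sites with both locations", call. = FALSE)
  u1 <- u$median_flux[match(common, u$site)]
  d <- dn$median_flux[match(common, dn$site)]
  rel <- site_relative_change(u1, d, reps = cfg$bootstrap_reps,
                              seed = cfg$seed, sites = common)
  diff_med <- stats::median(d - u1)
  structure(list(
    per_site = per_site, rel = rel,
    median_areal_diff = diff_med,
    median_flux_upstream = stats::median(u1),
    median_flux_downstream = stats::median(d),
    national_A_Gg = upscale_relative(cfg, rel$median),
    national_B_Gg = upscale_absolute(cfg, diff_med)
  ), class = "evasion_estimate")
}
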