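#' Design of a synthetic paired upstream/downstream field survey
#'
#' Describes the statistical structure of a wastewater-impact survey: sites
#' each carry two upstream sampling locations (U2, U1) and one downstream
#' location (D) below the treatment-plant outfall; cotton strips at each
#' location accumulate decomposition and respiration whose ln rates follow
#' a linearized Arrhenius model with location-specific activation energies,
#' a site random intercept, and ln-normal residual noise. Observable
#' measurements (dissolved-oxygen budgets, tensile strengths, masses) are
#' back-computed from the true rates by inverting the assay equations, with
#' Gaussian measurement noise truncated at zero.
#'
#' Default sizes and effects follow the survey the generator emulates:
#' 12 sites x 3 locations x 8 strips, 14-day incubations, site mean
#' temperatures around 8.3 +/- 1.7 deg C with downstream warming of
#' 0.44 deg C, and per-channel Arrhenius coefficients equal to the fitted
#' field values (respiration: intercept -0.28, reference slope -0.79,
#' slope interactions +0.14/+0.15 for U1/D; tensile-strength decay:
#' intercept -3.70, slope -1.73, interactions -0.17/+0.59). Nutrient and
#' toxic-unit summaries default to the observed upstream/downstream
#' medians (DIN 3.1 -> 5.0 mg/L, SRP 15.4 -> 49.1 ug/L).
#'
#' @param n_sites Number of sites (>= 2).
#' @param locations Ordered location labels, upstream to downstream;
#'   exactly three.
#' @param strips_per_location Strips per site x location (>= 1).
#' @param incubation_days Incubation length, days.
#' @param temp_baseline_mean,temp_baseline_sd Site mean temperature
#'   distribution, deg C.
#' @param temp_daily_sd Day-to-day SD within an incubation, deg C.
#' @param delta_temp_downstream Added warming at D, deg C.
#' @param rate_params Named list of response channels (`respiration`, `ts`,
#'   `mass`), each a list with `lnEF_at_Tref` (ln rate at the centering
#'   temperature), `ea_by_location` (named eV vector) and
#'   `location_offsets` (named ln-scale intercept shifts).
#' @param residual_sd,site_sd Strip-level and site-level SDs on the ln
#'   scale (>= 0).
#' @param measurement_noise List with `do_sd` (mg O2/L), `ts_sd` (N),
#'   `mass_sd` (g); set all to zero for exact round-trip generation.
#' @param assay List of chamber constants: `do_stream_start` (mg/L),
#'   `blank_drift` (mg/L DO lost in the blank), `chamber_volume_L`,
#'   `assay_duration_hr`, `rq` (respiratory quotient used to translate the
#'   carbon-rate channel into an oxygen budget), `ts0` (reference tensile
#'   strength, N), `mass0` (reference dry mass, g), `n_reference` strips.
#' @param nutrient_effects List of upstream/downstream medians for `din`
#'   (mg/L) and `srp` (ug/L).
#' @param tu_effects List of upstream/downstream toxic-unit levels for
#'   `fungicide` and `nonfungicide` (implementer-chosen magnitudes; the
#'   survey context reports only that they increase downstream).
#' @param pct_ww Median percent treated wastewater downstream.
#' @param std [temperature_standard()] used for the inverse-temperature
#'   covariate.
#' @param seed Master integer seed; split into named substreams so survey,
#'   OTU and flume stages regenerate independently.
#' @return List of class `survey_design`.
#' @seealso [generate_survey()]
#' @export
survey_design <- function(n_sites = 12,
                          locations = c("U2", "U1", "D"),
                          strips_per_location = 8,
                          incubation_days = 14,
                          temp_baseline_mean = 8.3,
                          temp_baseline_sd = 1.7,
                          temp_daily_sd = 0.8,
                          delta_temp_downstream = 0.44,
                          rate_params = default_rate_params(),
                          residual_sd = 0.3,
                          site_sd = 0.3,
                          measurement_noise = list(do_sd = 0.05, ts_sd = 8,
                                                   mass_sd = 0.005),
                          assay = list(do_stream_start = 10.5,
                                       blank_drift = 0.2,
                                       chamber_volume_L = 1,
                                       assay_duration_hr = 0.5,
                                       rq = 1.2,
                                       ts0 = 300, mass0 = 0.45,
                                       n_reference = 10),
                          nutrient_effects = list(din = c(up = 3.1, down = 5.0),
                                                  srp = c(up = 15.4, down = 49.1)),
                          tu_effects = list(fungicide = c(up = 0.01, down = 0.025),
                                            nonfungicide = c(up = 0.02, down = 0.08)),
                          pct_ww = 30,
                          std = temperature_standard(),
                          seed = 1L) {
  if (!is.numeric(n_sites) || n_sites < 2) {
    stop("invalid design field 'n_sites': need >= 2", call. = FALSE)
  }
  if (length(locations) != 3L) {
    stop("invalid design field 'locations': exactly three ordered labels",
         call. = FALSE)
  }
  if (strips_per_location < 1) {
    stop("invalid design field 'strips_per_location': need >= 1", call. = FALSE)
  }
  for (nm in c("residual_sd", "site_sd", "temp_baseline_sd", "temp_daily_sd")) {
    if (get(nm) < 0) stop("invalid design field '", nm, "': must be >= 0",
                          call. = FALSE)
  }
  for (ch in names(rate_params)) {
    p <- rate_params[[ch]]
    if (!all(locations %in% names(p$ea_by_location))) {
      stop("invalid design field 'rate_params$", ch,
           "$ea_by_location': must name every location", call. = FALSE)
    }
  }
  if (any(unlist(measurement_noise) < 0)) {
    stop("invalid design field 'measurement_noise': SDs must be >= 0",
         call. = FALSE)
  }
  structure(list(
    n_sites = as.integer(n_sites), locations = locations,
    strips_per_location = as.integer(strips_per_location),
    incubation_days = incubation_days,
    temp_baseline_mean = temp_baseline_mean,
    temp_baseline_sd = temp_baseline_sd,
    temp_daily_sd = temp_daily_sd,
    delta_temp_downstream = delta_temp_downstream,
    rate_params = rate_params,
    residual_sd = residual_sd, site_sd = site_sd,
    measurement_noise = measurement_noise, assay = assay,
    nutrient_effects = nutrient_effects, tu_effects = tu_effects,
    pct_ww = pct_ww, std = std, seed = as.integer(seed)
  ), class = "survey_design")
}

#' Default true Arrhenius coefficients for the survey generator
#'
#' One coefficient triple per response channel, on the ln scale at the
#' centering temperature; activation energies in eV per location.
#' `ea_by_location` entries are the negated reference slope plus the
#' location's slope interaction, e.g. the tensile-strength channel has
#' Ea(U2) = 1.73 and Ea(D) = 1.73 - 0.59 = 1.14 eV.
#'
#' @return Named list of channels (`respiration` in mg C hr^-1 g^-1 DM,
#'   `ts` and `mass` decay in day^-1).
#' @export
default_rate_params <- function() {
  list(
    respiration = list(
      lnEF_at_Tref = -0.28,
      ea_by_location = c(U2 = 0.79, U1 = 0.65, D = 0.64),
      location_offsets = c(U2 = 0, U1 = 0.01, D = 0.14)
    ),
    ts = list(
      lnEF_at_Tref = -3.70,
      ea_by_location = c(U2 = 1.73, U1 = 1.90, D = 1.14),
      location_offsets = c(U2 = 0, U1 = 0.14, D = 0.37)
    ),
    mass = list(
      lnEF_at_Tref = -5.1,
      ea_by_location = c(U2 = 1.0, U1 = 1.0, D = 0.8),
      location_offsets = c(U2 = 0, U1 = 0, D = 0.55)
    )
  )
}

#' Generate a synthetic survey dataset
#'
#' Simulates daily water temperatures, true ln rates per strip (Arrhenius
#' structure + site random intercept + residual), then inverts the assay
#' equations to produce the observable measurements with truncated Gaussian
#' measurement noise. Identical seed and design give identical output.
#'
#' @param design A [survey_design()].
#' @return List of class `csa_survey` with elements `strips` (one row per
#'   strip: the measurement schema consumed by [assay_table()]),
#'   `temperature` (site, location, day, temp_c), `chemistry` (site,
#'   location, din_mg_l, srp_ug_l, tu_fungicide, tu_nonfungicide, pct_ww),
#'   `reference` (lists of reference tensile strengths and masses), and
#'   `truth` (per-strip true rates and the design, for calibration
#'   studies).
#' @export
generate_survey <- function(design = survey_design()) {
  stopifnot(inherits(design, "survey_design"))
  with_seed(substream_seed(design$seed, "survey"), {
    d <- design
    sites <- sprintf("S%02d", seq_len(d$n_sites))
    locs <- d$locations
    n_loc <- length(locs)
    down <- locs[n_loc]

    # temperatures: site baseline + downstream warming + daily noise
    site_base <- stats::rnorm(d$n_sites, d$temp_baseline_mean, d$temp_baseline_sd)
    temp <- expand.grid(day = seq_len(d$incubation_days), location = locs,
                        site = sites, stringsAsFactors = FALSE)
    temp <- temp[, c("site", "location", "day")]
    shift <- ifelse(temp$location == down, d$delta_temp_downstream, 0)
    temp$temp_c <- site_base[match(temp$site, sites)] + shift +
      stats::rnorm(nrow(temp), 0, d$temp_daily_sd)
    temp$temp_c <- pmax(temp$temp_c, 0.1)

    mean_temp <- stats::aggregate(temp_c ~ site + location, data = temp,
                                  FUN = mean)
    key <- function(s, l) paste(s, l, sep = "\r")
    mt <- stats::setNames(mean_temp$temp_c,
                          key(mean_temp$site, mean_temp$location))

    # per-strip frame
    strips <- expand.grid(strip = seq_len(d$strips_per_location),
                          location = locs, site = sites,
                          stringsAsFactors = FALSE)
    strips <- strips[, c("site", "location", "strip")]
    ns <- nrow(strips)
    x <- standardize_temperature(mt[key(strips$site, strips$location)], d$std)

    site_re <- lapply(names(d$rate_params), function(ch) {
      stats::setNames(stats::rnorm(d$n_sites, 0, d$site_sd), sites)
    })
    names(site_re) <- names(d$rate_params)

    true_rate <- function(ch) {
      p <- d$rate_params[[ch]]
      ln <- p$lnEF_at_Tref + p$location_offsets[strips$location] -
        p$ea_by_location[strips$location] * x +
        site_re[[ch]][strips$site] +
        stats::rnorm(ns, 0, d$residual_sd)
      exp(unname(ln))
    }
    resp_c <- true_rate("respiration")   # mg C hr^-1 g^-1 DM
    k_ts <- true_rate("ts")              # day^-1
    k_mass <- true_rate("mass")          # day^-1

    a <- d$assay
    mn <- d$measurement_noise
    noisy <- function(x, sd, floor = 0) {
      if (sd > 0) x <- x + stats::rnorm(length(x), 0, sd)
      pmax(x, floor)
    }

    mass_final <- noisy(a$mass0 * exp(-k_mass * d$incubation_days), mn$mass_sd,
                        floor = 1e-4)
    ts_final <- noisy(a$ts0 * exp(-k_ts * d$incubation_days), mn$ts_sd,
                      floor = 1)

    # invert Eq. 1: DO drop in the strip chamber beyond the blank
    resp_o2 <- resp_c * MOLAR_MASS_O2 / (MOLAR_MASS_C * a$rq)
    do_blank_end <- a$do_stream_start - a$blank_drift
    drop <- resp_o2 * mass_final * a$assay_duration_hr / a$chamber_volume_L
    if (any(do_blank_end - drop <= 0)) {
      warning("chamber DO exhausted for ", sum(do_blank_end - drop <= 0),
              " strip(s): the assay configuration censors high rates; ",
              "shorten assay_duration_hr or enlarge chamber_volume_L",
              call. = FALSE)
    }
    strip_df <- data.frame(
      site = strips$site, location = strips$location,
      strip_id = sprintf("%s-%s-%02d", strips$site, strips$location,
                         strips$strip),
      do_stream_start = noisy(rep(a$do_stream_start, ns), mn$do_sd),
      do_chamber_end = noisy(do_blank_end - drop, mn$do_sd),
      do_blank_end = noisy(rep(do_blank_end, ns), mn$do_sd),
      chamber_volume_L = a$chamber_volume_L,
      strip_mass_g = mass_final,
      assay_duration_hr = a$assay_duration_hr,
      ts_final_N = ts_final,
      mass_final_g = mass_final,
      incubation_days = d$incubation_days,
      stringsAsFactors = FALSE
    )

    reference <- list(
      ts = noisy(rep(a$ts0, a$n_reference), mn$ts_sd, floor = 1),
      mass = noisy(rep(a$mass0, a$n_reference), mn$mass_sd, floor = 1e-4)
    )

    up_lab <- locs[-n_loc]
    chem <- expand.grid(location = locs, site = sites,
                        stringsAsFactors = FALSE)[, c("site", "location")]
    is_down <- chem$location == down
    pick <- function(pair) ifelse(is_down, pair[["down"]], pair[["up"]])
    chem$din_mg_l <- pmax(0, pick(d$nutrient_effects$din) *
                            exp(stats::rnorm(nrow(chem), 0, 0.2)))
    chem$srp_ug_l <- pmax(0, pick(d$nutrient_effects$srp) *
                            exp(stats::rnorm(nrow(chem), 0, 0.3)))
    chem$tu_fungicide <- pmax(0, pick(d$tu_effects$fungicide) *
                                exp(stats::rnorm(nrow(chem), 0, 0.3)))
    chem$tu_nonfungicide <- pmax(0, pick(d$tu_effects$nonfungicide) *
                                   exp(stats::rnorm(nrow(chem), 0, 0.3)))
    chem$pct_ww <- ifelse(is_down, pmax(5, d$pct_ww +
                                          stats::rnorm(nrow(chem), 0, 8)), 0)

    structure(list(
      strips = strip_df, temperature = temp, chemistry = chem,
      reference = reference,
      truth = list(resp_c = resp_c, k_ts = k_ts, k_mass = k_mass,
                   stdtemp = unname(x), site_re = site_re, design = d)
    ), class = "csa_survey")
  })
}

#' @export
print.csa_survey <- function(x, ...) {
  cat(sprintf("Cotton-strip survey: %d strips at %d sites x %s\n",
              nrow(x$strips), length(unique(x$strips$site)),
              paste(unique(x$strips$location), collapse = "/")))
  invisible(x)
}

#' Design of synthetic OTU tables for paired upstream/downstream samples
#'
#' The generator emulates amplicon community structure on cotton strips:
#' per site one upstream (U1) and one downstream (D) sample; downstream
#' expected richness is upstream divided by `downstream_richness_ratio`
#' (the incident-rate-ratio sense: ratio 1.22 means ~22% more OTUs
#' upstream); of the upstream taxa absent downstream, a fraction
#' `turnover_fraction` are replaced by taxa new to the site (turnover),
#' the remainder are pure losses (nestedness). Abundances follow a Fisher
#' log-series by default, and reads are drawn multinomially at fixed depth.
#'
#' Defaults emulate the study's two markers: bacteria-like (16S, upstream
#' richness ~616, ratio 1.12) and fungi-like (ITS, upstream richness ~559,
#' ratio 1.22), both with turnover fraction 0.63: solving the generator's
#' loss/replacement algebra for the observed within-site Simpson (turnover)
#' components (~0.21 bacterial, ~0.38 fungal) and nestedness components
#' (~0.05-0.07) at those richness levels gives a replacement share of the
#' count deviation of about 0.63 for both markers.
#'
#' @param n_taxa_pool Regional taxon pool size.
#' @param reads_per_sample Sequencing depth per sample.
#' @param upstream_richness_mean,upstream_richness_sd Upstream true
#'   richness distribution across sites.
#' @param downstream_richness_ratio Upstream : downstream expected richness
#'   ratio (> 0).
#' @param turnover_fraction Share of the downstream deviation that is
#'   replacement rather than loss, in [0, 1].
#' @param gross_turnover Fraction of upstream richness replaced when
#'   `turnover_fraction = 1` and the richness ratio is 1 (pure replacement
#'   has no net loss to scale from).
#' @param abundance Abundance model: `"logseries"` or `"lognormal"`.
#' @param lognormal_sdlog SD of ln abundance for the lognormal option.
#' @param marker Label stored in the sample metadata.
#' @param seed Integer seed.
#' @return List of class `otu_design`.
#' @export
otu_design <- function(n_taxa_pool = 4000,
                       reads_per_sample = 25000,
                       upstream_richness_mean = 559,
                       upstream_richness_sd = 60,
                       downstream_richness_ratio = 1.22,
                       turnover_fraction = 0.63,
                       gross_turnover = 0.25,
                       abundance = c("logseries", "lognormal"),
                       lognormal_sdlog = 1.5,
                       marker = "ITS-like",
                       seed = 1L) {
  abundance <- match.arg(abundance)
  if (downstream_richness_ratio <= 0) {
    stop("downstream_richness_ratio must be > 0", call. = FALSE)
  }
  if (turnover_fraction < 0 || turnover_fraction > 1) {
    stop("turnover_fraction must be in [0, 1]", call. = FALSE)
  }
  if (upstream_richness_mean > n_taxa_pool) {
    stop("richness cannot exceed the taxon pool", call. = FALSE)
  }
  structure(list(n_taxa_pool = as.integer(n_taxa_pool),
                 reads_per_sample = as.integer(reads_per_sample),
                 upstream_richness_mean = upstream_richness_mean,
                 upstream_richness_sd = upstream_richness_sd,
                 downstream_richness_ratio = downstream_richness_ratio,
                 turnover_fraction = turnover_fraction,
                 gross_turnover = gross_turnover,
                 abundance = abundance,
                 lognormal_sdlog = lognormal_sdlog,
                 marker = marker, seed = as.integer(seed)),
            class = "otu_design")
}

# Draw relative abundances for `s` present taxa under the design's
# abundance model. Log-series: alpha is chosen consistent with (s, reads),
# taxon abundances are drawn from the log-series species-abundance
# distribution P(k) ~ x^k / k with x = N / (N + alpha).
draw_abundances <- function(design, s) {
  if (design$abundance == "lognormal") {
    ab <- stats::rlnorm(s, 0, design$lognormal_sdlog)
  } else {
    n <- design$reads_per_sample
    alpha <- fisher_alpha(s, n)
    x <- n / (n + alpha)
    kmax <- 50000L
    k <- seq_len(kmax)
    logp <- k * log(x) - log(k)
    w <- exp(logp - max(logp))
    ab <- k[sample.int(kmax, s, replace = TRUE, prob = w)]
  }
  ab / sum(ab)
}

#' Generate paired upstream/downstream OTU tables
#'
#' For each site with both contrast locations in `dataset`, draws an
#' upstream taxon set from the regional pool (weighted so sites share
#' common taxa), derives the downstream set by the design's loss/replacement
#' rule, assigns abundances, and samples reads multinomially. Returns one
#' `csa_otu` per requested design (e.g. a bacteria-like and a fungi-like
#' table).
#'
#' @param designs A single [otu_design()] or a named list of them.
#' @param dataset A `csa_survey` (provides the site list); or `NULL` with
#'   `sites` given directly.
#' @param sites Character vector of site labels (used if `dataset` NULL).
#' @param locations The two contrast locations sampled (default U1, D).
#' @return A `csa_otu` (single design) or named list of them.
#' @export
generate_otu_tables <- function(designs, dataset = NULL, sites = NULL,
                                locations = c("U1", "D")) {
  single <- inherits(designs, "otu_design")
  if (single) designs <- list(table = designs)
  if (is.null(sites)) {
    if (is.null(dataset)) stop("supply dataset or sites", call. = FALSE)
    sites <- unique(dataset$strips$site)
    have <- vapply(sites, function(s) {
      all(locations %in% dataset$strips$location[dataset$strips$site == s])
    }, TRUE)
    if (!all(have)) {
      stop("sites missing a contrast location: ",
           paste(sites[!have], collapse = ", "), call. = FALSE)
    }
  }
  out <- lapply(designs, function(dsg) generate_one_otu(dsg, sites, locations))
  if (single) out[[1L]] else out
}

generate_one_otu <- function(design, sites, locations) {
  stopifnot(inherits(design, "otu_design"))
  with_seed(substream_seed(design$seed, "otu"), {
    pool <- design$n_taxa_pool
    # rank-weighted pool so that sites share common taxa
    pool_w <- 1 / seq_len(pool)
    samples <- list()
    meta <- list()
    for (s in sites) {
      s_up <- max(5L, round(stats::rnorm(1, design$upstream_richness_mean,
                                         design$upstream_richness_sd)))
      s_up <- min(s_up, pool)
      up_taxa <- sample.int(pool, s_up, prob = pool_w)

      s_down <- max(2L, round(s_up / design$downstream_richness_ratio))
      net_loss <- s_up - s_down
      tau <- design$turnover_fraction
      if (tau >= 1) {
        if (net_loss != 0) {
          stop("turnover_fraction = 1 requires a richness ratio of 1 ",
               "(pure replacement conserves richness)", call. = FALSE)
        }
        m_removed <- min(s_up - 1L, round(design$gross_turnover * s_up))
      } else {
        m_base <- max(0L, net_loss)
        m_removed <- min(s_up - 1L, max(m_base, round(m_base / (1 - tau))))
      }
      n_new <- m_removed - net_loss
      keep <- sample(up_taxa, s_up - m_removed)
      candidates <- setdiff(seq_len(pool), up_taxa)
      new_taxa <- if (n_new > 0)
        sample(candidates, min(n_new, length(candidates)),
               prob = pool_w[candidates]) else integer()
      down_taxa <- c(keep, new_taxa)

      for (loc in locations) {
        taxa <- if (loc == locations[1L]) up_taxa else down_taxa
        p <- draw_abundances(design, length(taxa))
        reads <- stats::rmultinom(1L, design$reads_per_sample, p)[, 1L]
        vec <- integer(pool)
        vec[taxa] <- reads
        sid <- paste(s, loc, sep = "_")
        samples[[sid]] <- vec
        meta[[sid]] <- data.frame(sample_id = sid, site = s, location = loc,
                                  marker = design$marker,
                                  stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(cbind, samples)
    rownames(counts) <- sprintf("OTU%05d", seq_len(pool))
    keep_taxa <- rowSums(counts) > 0
    otu_table(counts[keep_taxa, , drop = FALSE],
              do.call(rbind, meta))
  })
}

#' Specification of a flume or transplant experiment
#'
#' Three experiment templates mirror the flume facility designs:
#' `"dilution"` (river water vs 15/50/85% treated wastewater),
#' `"dosing"` (river, technical control, micropollutant mix, and
#' micropollutants + nutrients), and `"transplant"` (an inoculation x
#' transfer factorial where strips inoculated in one water source are
#' moved to the other, with a persistence parameter giving the share of
#' the inoculation effect carried through the transfer).
#'
#' Default treatment effects are qualitative calibrations: dilution
#' responses rise with the wastewater fraction but drop back at 85%;
#' dosing has a negative micropollutant effect masked by added nutrients.
#'
#' @param experiment `"dilution"`, `"dosing"` or `"transplant"`.
#' @param treatments Named numeric vector of ln-scale treatment effects
#'   (dilution/dosing); names are the treatment labels. Dilution labels
#'   must be WW percentages in [0, 100] followed by "% WW".
#' @param inoculation_effects Named ln-scale effects of the inoculation
#'   sources (transplant only).
#' @param persistence Share (0-1) of the inoculation effect retained after
#'   transfer (transplant only).
#' @param n_blocks Experimental blocks (>= 2).
#' @param strips_per_channel Strips per channel.
#' @param duration_days Incubation length.
#' @param baseline_ln Baseline ln response (control mean).
#' @param block_sd,residual_sd Block random-effect and strip residual SDs
#'   (ln scale).
#' @param seed Integer seed.
#' @return List of class `flume_spec`.
#' @export
flume_spec <- function(experiment = c("dilution", "dosing", "transplant"),
                       treatments = NULL,
                       inoculation_effects = c(River = 0, WW = 0.4),
                       persistence = 1,
                       n_blocks = 4,
                       strips_per_channel = 4,
                       duration_days = NULL,
                       baseline_ln = -3.4,
                       block_sd = 0.1,
                       residual_sd = 0.15,
                       seed = 1L) {
  experiment <- match.arg(experiment)
  if (is.null(treatments)) {
    treatments <- switch(experiment,
      dilution = c("0% WW" = 0, "15% WW" = 0.35, "50% WW" = 0.45,
                   "85% WW" = 0.25),
      dosing = c(River = 0, Control = -0.15, MPs = -0.45,
                 "MPs+Nutrients" = -0.05),
      transplant = NULL
    )
  }
  if (experiment == "dilution" && !is.null(treatments)) {
    fracs <- suppressWarnings(as.numeric(sub("% WW", "", names(treatments))))
    if (any(is.na(fracs)) || any(fracs < 0 | fracs > 100)) {
      stop("dilution treatments must be WW percentages in [0, 100]",
           call. = FALSE)
    }
  }
  if (n_blocks < 2) stop("n_blocks must be >= 2", call. = FALSE)
  if (persistence < 0 || persistence > 1) {
    stop("persistence must be in [0, 1]", call. = FALSE)
  }
  if (is.null(duration_days)) {
    duration_days <- switch(experiment, dilution = 13, dosing = 35,
                            transplant = 14)
  }
  structure(list(experiment = experiment, treatments = treatments,
                 inoculation_effects = inoculation_effects,
                 persistence = persistence,
                 n_blocks = as.integer(n_blocks),
                 strips_per_channel = as.integer(strips_per_channel),
                 duration_days = duration_days,
                 baseline_ln = baseline_ln,
                 block_sd = block_sd, residual_sd = residual_sd,
                 seed = as.integer(seed)),
            class = "flume_spec")
}

#' Generate a flume or transplant dataset
#'
#' Responses are built additively on the ln scale: baseline + treatment
#' effect + block random effect + strip residual. The transplant design
#' crosses inoculation source with transfer destination; a transferred
#' strip's mean carries `persistence` of its inoculation effect plus
#' `1 - persistence` of the destination effect, so `persistence = 1` means
#' the inoculated community fully determines the rate.
#'
#' @param spec A [flume_spec()].
#' @return Data frame with columns `experiment`, `block`, `channel`,
#'   `treatment` (and `inoculation`, `transfer` for transplants), `strip`,
#'   `ln_response`, `response`.
#' @export
generate_flume <- function(spec) {
  stopifnot(inherits(spec, "flume_spec"))
  with_seed(substream_seed(spec$seed, "flume"), {
    blocks <- seq_len(spec$n_blocks)
    block_re <- stats::rnorm(spec$n_blocks, 0, spec$block_sd)
    if (spec$experiment %in% c("dilution", "dosing")) {
      grid <- expand.grid(strip = seq_len(spec$strips_per_channel),
                          treatment = names(spec$treatments),
                          block = blocks, stringsAsFactors = FALSE)
      mu <- spec$baseline_ln + spec$treatments[grid$treatment] +
        block_re[grid$block]
      grid$channel <- paste0("B", grid$block, "-",
                             match(grid$treatment, names(spec$treatments)))
    } else {
      inoc <- names(spec$inoculation_effects)
      grid <- expand.grid(strip = seq_len(spec$strips_per_channel),
                          transfer = inoc, inoculation = inoc,
                          block = blocks, stringsAsFactors = FALSE)
      eff <- spec$persistence * spec$inoculation_effects[grid$inoculation] +
        (1 - spec$persistence) * spec$inoculation_effects[grid$transfer]
      mu <- spec$baseline_ln + eff + block_re[grid$block]
      grid$treatment <- paste(grid$inoculation, grid$transfer, sep = "->")
      grid$channel <- paste0("B", grid$block, "-", grid$transfer)
    }
    grid$ln_response <- mu + stats::rnorm(nrow(grid), 0, spec$residual_sd)
    grid$response <- exp(grid$ln_response)
    grid$experiment <- spec$experiment
    cols <- c("experiment", "block", "channel",
              intersect(c("treatment", "inoculation", "transfer"),
                        names(grid)),
              "strip", "ln_response", "response")
    grid[, cols]
  })
}
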