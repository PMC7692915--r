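#' Write a survey dataset to plain CSV files
#'
#' Writes `measurements.csv` (the per-strip schema), `temperature.csv`,
#' `chemistry.csv` and `reference.csv` into `dir`. These are the schemas
#' [read_measurements()] consumes, so write-then-read round-trips.
#'
#' @param dataset A `csa_survey`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_survey <- function(dataset, dir) {
  stopifnot(inherits(dataset, "csa_survey"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    measurements = file.path(dir, "measurements.csv"),
    temperature = file.path(dir, "temperature.csv"),
    chemistry = file.path(dir, "chemistry.csv"),
    reference = file.path(dir, "reference.csv")
  )
  utils::write.csv(dataset$strips, paths["measurements"], row.names = FALSE)
  utils::write.csv(dataset$temperature, paths["temperature"], row.names = FALSE)
  utils::write.csv(dataset$chemistry, paths["chemistry"], row.names = FALSE)
  ref <- data.frame(
    measure = rep(c("ts", "mass"),
                  times = c(length(dataset$reference$ts),
                            length(dataset$reference$mass))),
    value = c(dataset$reference$ts, dataset$reference$mass)
  )
  utils::write.csv(ref, paths["reference"], row.names = FALSE)
  invisible(paths)
}

MEASUREMENT_COLUMNS <- c(
  "site", "location", "strip_id", "do_stream_start", "do_chamber_end",
  "do_blank_end", "chamber_volume_L", "strip_mass_g", "assay_duration_hr",
  "ts_final_N", "mass_final_g", "incubation_days"
)

#' Read a survey dataset from CSV files
#'
#' Reads and validates the per-strip measurement schema (see
#' `MEASUREMENT_COLUMNS` in the package source: site, location in
#' U2/U1/D, strip_id, the DO triplet, chamber volume, strip mass, assay
#' duration, final tensile strength and mass, incubation days), plus the
#' daily temperature series and the reference-strip file. Malformed rows
#' are rejected with their line numbers; a missing column is an error
#' naming it.
#'
#' @param dir Directory containing `measurements.csv`, `temperature.csv`,
#'   `reference.csv` and optionally `chemistry.csv` (as written by
#'   [write_survey()]).
#' @return A `csa_survey`.
#' @export
read_measurements <- function(dir) {
  path <- file.path(dir, "measurements.csv")
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  strips <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(strips))
  if (length(missing_cols)) {
    stop("measurements.csv is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(MEASUREMENT_COLUMNS, c("site", "location", "strip_id"))
  for (col in num_cols) {
    v <- strips[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop(sprintf("non-numeric value(s) in column '%s' at data row(s): %s",
                   col, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("missing value(s) in column '%s' at data row(s): %s",
                   col, paste(utils::head(which(is.na(v)), 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad_loc <- which(!strips$location %in% c("U2", "U1", "D"))
  if (length(bad_loc)) {
    stop("unknown location label at data row(s): ",
         paste(utils::head(bad_loc, 5), collapse = ", "),
         " (expected U2, U1 or D)", call. = FALSE)
  }

  temperature <- utils::read.csv(file.path(dir, "temperature.csv"),
                                 stringsAsFactors = FALSE)
  for (col in c("site", "location", "temp_c")) {
    if (!col %in% names(temperature)) {
      stop("temperature.csv is missing required column(s): ", col,
           call. = FALSE)
    }
  }
  ref_df <- utils::read.csv(file.path(dir, "reference.csv"),
                            stringsAsFactors = FALSE)
  reference <- list(ts = ref_df$value[ref_df$measure == "ts"],
                    mass = ref_df$value[ref_df$measure == "mass"])
  chem_path <- file.path(dir, "chemistry.csv")
  chemistry <- if (file.exists(chem_path)) {
    utils::read.csv(chem_path, stringsAsFactors = FALSE)
  } else NULL

  # every strip must reference a site x location present in the series
  skey <- paste(strips$site, strips$location)
  tkey <- unique(paste(temperature$site, temperature$location))
  orphan <- which(!skey %in% tkey)
  if (length(orphan)) {
    stop("strip rows without a matching temperature series: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(strips = strips, temperature = temperature,
                 chemistry = chemistry, reference = reference,
                 truth = NULL),
            class = "csa_survey")
}

#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir Output directory for stage files.
#' @param design A [survey_design()] (used when `input_dir` is NULL).
#' @param input_dir Optional directory of measured CSVs (see
#'   [read_measurements()]); when given, the survey simulation stage is
#'   skipped.
#' @param evasion An [evasion_config()].
#' @param otu_designs Named list of [otu_design()]s (or NULL to skip the
#'   diversity stage when no OTU data are simulated).
#' @param rq Respiratory quotient for [assay_table()].
#' @param n_perm Permutations for PERMANOVA/dispersion tests.
#' @param seed Master seed; overrides the seeds in the design objects so
#'   one integer reproduces the whole run.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir,
                       design = survey_design(),
                       input_dir = NULL,
                       evasion = evasion_config(),
                       otu_designs = list(
                         bacteria = otu_design(upstream_richness_mean = 616,
                                               downstream_richness_ratio = 1.12,
                                               turnover_fraction = 0.63,
                                               marker = "16S-like"),
                         fungi = otu_design(upstream_richness_mean = 559,
                                            downstream_richness_ratio = 1.22,
                                            turnover_fraction = 0.63,
                                            marker = "ITS-like")
                       ),
                       rq = 1.2, n_perm = 999, seed = 1L) {
  if (!is.numeric(seed) || seed < 0) {
    stop("seed must be a non-negative integer", call. = FALSE)
  }
  structure(list(out_dir = out_dir, design = design, input_dir = input_dir,
                 evasion = evasion, otu_designs = otu_designs, rq = rq,
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full survey pipeline
#'
#' Executes simulate (or read) -> assay computations -> Arrhenius and
#' location mixed models -> carbon-efflux estimation and upscaling ->
#' community-diversity analyses, writing tidy CSV/JSON outputs for each
#' stage under `cfg$out_dir`. Later stages run even if an earlier
#' independent stage failed; failures are recorded in the report.
#'
#' @param cfg A [run_config()].
#' @return List of class `run_report`: `stages` (per-stage status and file
#'   paths), `summary` (headline numbers: per-location activation energies,
#'   effect sizes, median relative efflux change, upscaling totals,
#'   diversity tables), `warnings` (counts of flagged/excluded records),
#'   `config_hash`, `seed`, `version`.
#' @export
run_field_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  summary <- list()
  warns <- list()

  # --- stage: data ---
  design <- cfg$design
  design$seed <- cfg$seed
  dataset <- if (is.null(cfg$input_dir)) {
    generate_survey(design)
  } else {
    read_measurements(cfg$input_dir)
  }
  data_paths <- write_survey(dataset, file.path(cfg$out_dir, "data"))
  stages$data <- list(status = "ok", files = data_paths)

  # --- stage: assay ---
  assay <- assay_table(dataset, rq = cfg$rq)
  assay_path <- file.path(cfg$out_dir, "assay_per_strip.csv")
  utils::write.csv(assay, assay_path, row.names = FALSE)
  warns$flagged_negative_resp <- sum(assay$flag_negative_resp)
  warns$flagged_negative_k <- sum(assay$flag_negative_k)
  stages$assay <- list(status = "ok", files = c(per_strip = assay_path))

  # --- stage: metabolic models ---
  stages$metabolic <- tryCatch({
    ok_resp <- !assay$flag_negative_resp
    arr_data <- data.frame(
      ln_ef = log(assay$resp_c[ok_resp]),
      stdtemp = standardize_temperature(assay$mean_temp_c[ok_resp]),
      location = assay$location[ok_resp], site = assay$site[ok_resp]
    )
    fit_resp <- fit_arrhenius(arr_data)
    ok_k <- !assay$flag_negative_k & assay$k_d_ts > 0
    fit_ts <- fit_arrhenius(data.frame(
      ln_ef = log(assay$k_d_ts[ok_k]),
      stdtemp = standardize_temperature(assay$mean_temp_c[ok_k]),
      location = assay$location[ok_k], site = assay$site[ok_k]
    ))
    ea <- function(fit) {
      sapply(fit$locations, function(l) activation_energy(fit, l)$ea)
    }
    summary$ea_respiration <- ea(fit_resp)
    summary$ea_ts <- ea(fit_ts)

    # overall (common-slope) respiration Ea and its MTE verdict
    common <- fit_arrhenius_common(arr_data)
    summary$ea_respiration_overall <- common$ea
    summary$ea_respiration_overall_ci <- common$ci
    summary$mte_overlap <- mte_consistency(common$ci)

    # location contrasts and effect sizes on site means
    site_means <- stats::aggregate(resp_c ~ site + location, data = assay,
                                   FUN = mean)
    g <- hedges_g(site_means$resp_c[site_means$location == "D"],
                  site_means$resp_c[site_means$location == "U1"])
    summary$hedges_g_respiration <- g$g
    lme_resp <- fit_location_lme(assay, "resp_c")
    summary$respiration_site_var_pct <- lme_resp$site_var_pct

    path <- file.path(cfg$out_dir, "arrhenius.json")
    jsonlite::write_json(list(
      respiration = list(coef = as.list(fit_resp$coef),
                         ea = as.list(summary$ea_respiration),
                         r2_marginal = fit_resp$r2_marginal,
                         r2_conditional = fit_resp$r2_conditional),
      ts_decay = list(coef = as.list(fit_ts$coef),
                      ea = as.list(summary$ea_ts),
                      r2_marginal = fit_ts$r2_marginal,
                      r2_conditional = fit_ts$r2_conditional),
      overall_respiration_ea = list(ea = common$ea, ci = common$ci,
                                    mte_overlap = summary$mte_overlap)
    ), path, auto_unbox = TRUE, digits = NA)
    list(status = "ok", files = c(arrhenius = path))
  }, error = function(e) list(status = "failed", error = conditionMessage(e)))

  # --- stage: efflux ---
  stages$efflux <- tryCatch({
    ev_cfg <- cfg$evasion
    ev_cfg$seed <- substream_seed(cfg$seed, "bootstrap")
    ev <- evasion_summary(assay, ev_cfg)
    summary$median_rel_change <- ev$rel$median
    summary$median_rel_change_ci <- ev$rel$ci
    summary$national_A_Gg <- ev$national_A_Gg
    summary$national_B_Gg <- ev$national_B_Gg
    summary$median_flux_upstream <- ev$median_flux_upstream
    summary$median_flux_downstream <- ev$median_flux_downstream
    csv_path <- file.path(cfg$out_dir, "efflux_per_site.csv")
    utils::write.csv(ev$per_site, csv_path, row.names = FALSE)
    json_path <- file.path(cfg$out_dir, "efflux_summary.json")
    jsonlite::write_json(list(
      median_rel_change = ev$rel$median, ci = ev$rel$ci,
      national_A_Gg = ev$national_A_Gg, national_B_Gg = ev$national_B_Gg
    ), json_path, auto_unbox = TRUE, digits = NA)
    list(status = "ok", files = c(per_site = csv_path, summary = json_path))
  }, error = function(e) list(status = "failed", error = conditionMessage(e)))

  # --- stage: diversity ---
  stages$diversity <- if (is.null(cfg$otu_designs)) {
    list(status = "skipped", reason = "no OTU designs configured")
  } else tryCatch({
    designs <- lapply(cfg$otu_designs, function(d) {
      d$seed <- substream_seed(cfg$seed + match(d$marker,
        vapply(cfg$otu_designs, `[[`, "", "marker")), "otu")
      d
    })
    tables <- lapply(designs, generate_one_otu,
                     sites = unique(dataset$strips$site),
                     locations = c("U1", "D"))
    div <- lapply(names(tables), function(nm) {
      diversity_report(tables[[nm]], n_perm = cfg$n_perm,
                       seed = substream_seed(cfg$seed, "permutation"))
    })
    names(div) <- names(tables)
    for (nm in names(div)) {
      summary[[paste0("richness_irr_", nm)]] <- div[[nm]]$richness_irr
      summary[[paste0("beta_sim_", nm)]] <- div[[nm]]$beta_within_site$mean_sim
      summary[[paste0("beta_nes_", nm)]] <- div[[nm]]$beta_within_site$mean_nes
      summary[[paste0("permanova_p_", nm)]] <- div[[nm]]$permanova$p_value
    }
    alpha_path <- file.path(cfg$out_dir, "alpha_diversity.csv")
    utils::write.csv(do.call(rbind, lapply(names(div), function(nm) {
      cbind(table = nm, div[[nm]]$alpha)
    })), alpha_path, row.names = FALSE)
    json_path <- file.path(cfg$out_dir, "diversity_summary.json")
    jsonlite::write_json(lapply(div, function(d) {
      list(richness_irr = d$richness_irr,
           beta_within_site = d$beta_within_site,
           permanova = list(F = d$permanova$statistic,
                            p = d$permanova$p_value),
           dispersion = list(F = d$dispersion$statistic,
                             p = d$dispersion$p_value),
           nmds_stress = d$nmds$stress)
    }), json_path, auto_unbox = TRUE, digits = NA)
    list(status = "ok", files = c(alpha = alpha_path, summary = json_path))
  }, error = function(e) list(status = "failed", error = conditionMessage(e)))

  # hash the scientific configuration, not the output locations
  hash_fields <- setdiff(names(cfg), c("out_dir", "input_dir"))
  report <- structure(list(
    stages = stages, summary = summary, warnings = warns,
    config_hash = rlang::hash(unclass(cfg)[hash_fields]), seed = cfg$seed,
    version = as.character(utils::packageVersion("csaflux"))
  ), class = "run_report")
  report_path <- file.path(cfg$out_dir, "report.json")
  jsonlite::write_json(list(summary = summary, warnings = warns,
                            config_hash = report$config_hash,
                            seed = cfg$seed,
                            stages = lapply(stages, `[[`, "status")),
                       report_path, auto_unbox = TRUE, digits = NA)
  report
}

#' Common-slope Arrhenius fit across locations
#'
#' Fits `ln_ef ~ stdtemp + location + (1 | site)` (no slope interaction) to
#' estimate one overall activation energy across sampling locations, as
#' used when the per-location slopes do not differ.
#'
#' @param data Data frame with `ln_ef`, `stdtemp`, `location`, `site`.
#' @return List with `ea` (eV), `se`, `ci` (95% Wald) and `model`.
#' @export
fit_arrhenius_common <- function(data) {
  data$site <- factor(data$site)
  if (nlevels(data$site) >= 2L) {
    m <- lme4::lmer(ln_ef ~ stdtemp + location + (1 | site), data = data,
                    REML = TRUE)
    co <- lme4::fixef(m)
    se <- sqrt(diag(as.matrix(stats::vcov(m))))["stdtemp"]
  } else {
    m <- stats::lm(ln_ef ~ stdtemp + location, data = data)
    co <- stats::coef(m)
    se <- sqrt(diag(stats::vcov(m)))["stdtemp"]
  }
  ea <- -co[["stdtemp"]]
  list(ea = ea, se = unname(se),
       ci = c(ea - 1.96 * se, ea + 1.96 * se), model = m)
}

# Per-table diversity analyses used by the pipeline stage.
diversity_report <- function(tab, n_perm = 999, seed = 1L,
                             target_depth = 25000) {
  meta <- tab$metadata
  alpha <- do.call(rbind, lapply(seq_len(ncol(tab$counts)), function(j) {
    cbind(meta[j, c("sample_id", "site", "location")],
          alpha_profile(tab$counts[, j], target_depth))
  }))
  # richness IRR via the count mixed model (upstream relative to D reference)
  irr <- tryCatch({
    fit <- fit_location_lme(
      data.frame(richness = alpha$richness_obs,
                 location = factor(alpha$location, levels = c("D", "U1")),
                 site = alpha$site),
      "richness", family = "count")
    fit$fixed$irr[fit$fixed$term == "locationU1"]
  }, error = function(e) NA_real_)

  # within-site beta partition between the location pair
  pairs <- lapply(unique(meta$site), function(s) {
    i <- which(meta$site == s & meta$location == "U1")
    j <- which(meta$site == s & meta$location == "D")
    if (length(i) != 1L || length(j) != 1L) return(NULL)
    beta_pairwise(which(tab$counts[, i] > 0), which(tab$counts[, j] > 0))
  })
  pairs <- pairs[!vapply(pairs, is.null, TRUE)]
  beta_within <- list(
    mean_sor = mean(vapply(pairs, `[[`, 0, "beta_sor")),
    mean_sim = mean(vapply(pairs, `[[`, 0, "beta_sim")),
    mean_nes = mean(vapply(pairs, `[[`, 0, "beta_nes")),
    sd_sim = stats::sd(vapply(pairs, `[[`, 0, "beta_sim")),
    sd_nes = stats::sd(vapply(pairs, `[[`, 0, "beta_nes"))
  )

  pa <- normalize_table(tab, "presence_absence")
  dist_pa <- bray_curtis(pa)
  perm <- permanova_strata(dist_pa, groups = meta$location,
                           strata = meta$site, n_perm = n_perm, seed = seed)
  disp <- dispersion_test(dist_pa, groups = meta$location, n_perm = n_perm,
                          seed = seed)
  nmds <- tryCatch(ordinate_nmds(dist_pa, seed = seed),
                   error = function(e) list(scores = NULL, stress = NA_real_))
  list(alpha = alpha, richness_irr = irr, beta_within_site = beta_within,
       permanova = perm, dispersion = disp, nmds = nmds)
}

#' @export
print.run_report <- function(x, ...) {
  cat("csaflux pipeline report (seed ", x$seed, ", config ",
      substr(x$config_hash, 1, 8), ")\n", sep = "")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-10s %s%s\n", nm, st$status,
                if (!is.null(st$error)) paste0(": ", st$error) else ""))
  }
  s <- x$summary
  if (!is.null(s$ea_respiration_overall)) {
    cat(sprintf("  overall respiration Ea %.2f eV (%.2f-%.2f)\n",
                s$ea_respiration_overall, s$ea_respiration_overall_ci[1],
                s$ea_respiration_overall_ci[2]))
  }
  if (!is.null(s$median_rel_change)) {
    cat(sprintf("  median downstream efflux change %+.1f%% (%.1f to %.1f%%)\n",
                100 * s$median_rel_change, 100 * s$median_rel_change_ci[1],
                100 * s$median_rel_change_ci[2]))
    cat(sprintf("  national upscaling: A %.1f Gg C/yr, B %.2f Tg C/yr\n",
                s$national_A_Gg, s$national_B_Gg / 1000))
  }
  invisible(x)
}
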