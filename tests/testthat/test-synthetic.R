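test_that("survey generation is deterministic under a fixed seed", {
  d <- survey_design(n_sites = 3, strips_per_location = 2, seed = 99)
  a <- generate_survey(d)
  b <- generate_survey(d)
  expect_identical(a, b)
  c2 <- generate_survey(survey_design(n_sites = 3, strips_per_location = 2,
                                      seed = 100))
  expect_false(identical(a$strips, c2$strips))
})

test_that("null design yields identical rates at matched temperatures", {
  d <- noiseless_design(n_sites = 3, strips = 2, seed = 2,
                        rate_params = flat_rate_params())
  d$delta_temp_downstream <- 0
  ds <- generate_survey(d)
  truth <- data.frame(loc = ds$strips$location, rate = ds$truth$resp_c,
                      site = ds$strips$site)
  for (s in unique(truth$site)) {
    u1 <- truth$rate[truth$site == s & truth$loc == "U1"]
    dn <- truth$rate[truth$site == s & truth$loc == "D"]
    expect_equal(u1, dn, tolerance = 1e-12)
  }
})

test_that("downstream warming matches the designed offset in expectation", {
  d <- survey_design(n_sites = 40, strips_per_location = 1, seed = 21)
  ds <- generate_survey(d)
  mt <- aggregate(temp_c ~ site + location, data = ds$temperature, FUN = mean)
  delta <- mean(mt$temp_c[mt$location == "D"]) -
    mean(mt$temp_c[mt$location == "U1"])
  # designed +0.44 degC; averaging over 40 sites x 14 daily draws
  expect_equal(delta, 0.44, tolerance = 0.12)
})

test_that("effect injection is additive: zero effects remove the contrast", {
  p <- flat_rate_params()
  d <- survey_design(n_sites = 30, strips_per_location = 4, seed = 8,
                     rate_params = p, delta_temp_downstream = 0)
  ds <- generate_survey(d)
  ln_rate <- log(ds$truth$resp_c)
  m_u1 <- mean(ln_rate[ds$strips$location == "U1"])
  m_d <- mean(ln_rate[ds$strips$location == "D"])
  expect_lt(abs(m_d - m_u1), 0.1)
})

test_that("invalid designs fail naming the offending field", {
  expect_error(survey_design(n_sites = 1), "n_sites")
  expect_error(survey_design(strips_per_location = 0), "strips_per_location")
  expect_error(survey_design(residual_sd = -1), "residual_sd")
  expect_error(survey_design(locations = c("A", "B")), "locations")
  bad <- default_rate_params()
  names(bad$respiration$ea_by_location) <- c("X", "Y", "Z")
  expect_error(survey_design(rate_params = bad), "ea_by_location")
})

test_that("OTU generation hits the designed richness ratio", {
  ratios <- vapply(1:50, function(i) {
    tab <- generate_otu_tables(
      otu_design(upstream_richness_mean = 500, upstream_richness_sd = 40,
                 downstream_richness_ratio = 1.22, turnover_fraction = 0.85,
                 reads_per_sample = 20000, seed = i),
      sites = c("S1", "S2"))
    rich <- colSums(tab$counts > 0)
    loc <- tab$metadata$location
    mean(rich[loc == "U1"]) / mean(rich[loc == "D"])
  }, 0)
  expect_equal(mean(ratios), 1.22, tolerance = 0.05)
})

test_that("ratio 1 with zero turnover gives identical memberships", {
  tab <- generate_otu_tables(
    otu_design(upstream_richness_mean = 200, upstream_richness_sd = 0,
               downstream_richness_ratio = 1, turnover_fraction = 0,
               reads_per_sample = 50000, seed = 4),
    sites = "S1")
  up <- which(tab$counts[, tab$metadata$location == "U1"] > 0)
  # membership (before multinomial sampling) is identical; allow taxa that
  # drew zero reads on one side
  dn <- which(tab$counts[, tab$metadata$location == "D"] > 0)
  bp <- beta_pairwise(up, dn)
  # memberships are identical by construction; the residual dissimilarity is
  # multinomial sampling noise on rare log-series taxa
  expect_lt(bp$beta_sor, 0.1)
})

test_that("pure turnover at equal richness yields no nestedness", {
  tab <- generate_otu_tables(
    otu_design(upstream_richness_mean = 300, upstream_richness_sd = 0,
               downstream_richness_ratio = 1, turnover_fraction = 1,
               reads_per_sample = 100000, seed = 9),
    sites = "S1")
  up <- which(tab$counts[, tab$metadata$location == "U1"] > 0)
  dn <- which(tab$counts[, tab$metadata$location == "D"] > 0)
  bp <- beta_pairwise(up, dn)
  expect_gt(bp$beta_sim, 0.1)              # replacement happened
  expect_lt(bp$beta_nes / bp$beta_sor, 0.1)  # but almost no nestedness
})

test_that("invalid OTU designs are rejected", {
  expect_error(otu_design(downstream_richness_ratio = 0), "ratio")
  expect_error(otu_design(turnover_fraction = 1.5), "turnover_fraction")
  expect_error(otu_design(upstream_richness_mean = 10, n_taxa_pool = 5),
               "pool")
})

test_that("flume generation respects the treatment means and design", {
  spec <- flume_spec("dilution", seed = 3, residual_sd = 0.05)
  fl <- generate_flume(spec)
  expect_setequal(unique(fl$treatment), names(spec$treatments))
  means <- tapply(fl$ln_response, fl$treatment, mean)
  # nonmonotone design: 85% below 15% and 50%
  expect_lt(means[["85% WW"]], means[["50% WW"]])
  expect_lt(means[["85% WW"]], means[["15% WW"]])
  expect_gt(means[["15% WW"]], means[["0% WW"]])
  expect_error(flume_spec("mesocosm"), "arg")
})

test_that("transplant persistence = 1 keeps the inoculation mean", {
  spec <- flume_spec("transplant", persistence = 1, residual_sd = 0,
                     block_sd = 0, seed = 6)
  fl <- generate_flume(spec)
  ww <- fl$ln_response[fl$inoculation == "WW"]
  expect_equal(stats::sd(ww), 0, tolerance = 1e-12)
  expect_equal(unique(round(ww, 10)),
               round(spec$baseline_ln + spec$inoculation_effects[["WW"]], 10))
  # persistence = 0: transferred strips adopt the destination mean
  spec0 <- flume_spec("transplant", persistence = 0, residual_sd = 0,
                      block_sd = 0, seed = 6)
  fl0 <- generate_flume(spec0)
  moved <- fl0$ln_response[fl0$inoculation == "WW" & fl0$transfer == "River"]
  expect_equal(unique(round(moved, 10)), round(spec0$baseline_ln, 10))
})

test_that("null flume treatments give ~5% false positives in the LME", {
  spec <- flume_spec("dosing",
                     treatments = c(River = 0, Control = 0, MPs = 0,
                                    "MPs+Nutrients" = 0),
                     n_blocks = 4, strips_per_channel = 4)
  hits <- vapply(1:60, function(i) {
    spec$seed <- 1000 + i
    fl <- generate_flume(spec)
    fl$block <- factor(fl$block)
    m1 <- lme4::lmer(ln_response ~ treatment + (1 | block), data = fl,
                     REML = FALSE)
    m0 <- lme4::lmer(ln_response ~ 1 + (1 | block), data = fl, REML = FALSE)
    anova(m0, m1)$`Pr(>Chisq)`[2] < 0.05
  }, TRUE)
  expect_lt(mean(hits), 0.18)  # 60 null replicates; binomial 95% band
})
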