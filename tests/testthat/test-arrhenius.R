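test_that("temperature standardization centers at the reference", {
  expect_equal(standardize_temperature(6.748), 0, tolerance = 1e-12)
  expect_equal(standardize_temperature(16.75), -1.4333, tolerance = 1e-3)
  # warmer water gives strictly smaller x
  t_seq <- seq(1, 20, by = 0.5)
  expect_true(all(diff(standardize_temperature(t_seq)) < 0))
  expect_error(standardize_temperature(-300), "absolute zero")
})

test_that("the Kelvin value of the centering temperature is 279.9 K", {
  std <- temperature_standard()
  expect_equal(round(std$t_ref_kelvin, 1), 279.9)
})

make_arrhenius_data <- function(intercept, slope, offsets = NULL,
                                interactions = NULL, n_sites = 4,
                                strips = 4, resid_sd = 0, seed = 1) {
  locs <- c("U2", "U1", "D")
  offsets <- offsets %||% stats::setNames(rep(0, 3), locs)
  interactions <- interactions %||% stats::setNames(rep(0, 3), locs)
  set.seed(seed)
  grid <- expand.grid(strip = seq_len(strips), location = locs,
                      site = sprintf("S%d", seq_len(n_sites)),
                      stringsAsFactors = FALSE)
  temps <- runif(nrow(grid), 2, 14)
  x <- standardize_temperature(temps)
  grid$stdtemp <- x
  grid$location <- factor(grid$location, levels = locs)
  grid$ln_ef <- intercept + offsets[as.character(grid$location)] +
    (slope + interactions[as.character(grid$location)]) * x +
    rnorm(nrow(grid), 0, resid_sd)
  grid
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("noiseless Arrhenius data are recovered exactly", {
  d <- make_arrhenius_data(-0.28, -0.79)
  fit <- fit_arrhenius(d)
  expect_lt(abs(fit$coef[["(Intercept)"]] - (-0.28)), 1e-8)
  expect_lt(abs(fit$coef[["stdtemp"]] - (-0.79)), 1e-8)
  ea <- activation_energy(fit, "U2")
  expect_lt(abs(ea$ea - 0.79), 1e-8)
})

test_that("slope interactions translate into per-location Ea", {
  d <- make_arrhenius_data(-3.70, -1.73,
                           offsets = c(U2 = 0, U1 = 0.14, D = 0.37),
                           interactions = c(U2 = 0, U1 = -0.17, D = 0.59))
  fit <- fit_arrhenius(d)
  expect_lt(abs(fit$coef[["stdtemp"]] - (-1.73)), 1e-8)
  expect_lt(abs(fit$coef[["stdtemp:locationD"]] - 0.59), 1e-8)
  expect_lt(abs(activation_energy(fit, "U1")$ea - 1.90), 1e-8)
  expect_lt(abs(activation_energy(fit, "D")$ea - 1.14), 1e-8)
  expect_error(activation_energy(fit, "X"), "unknown location")
})

test_that("slope is invariant to a constant shift of ln EF", {
  d <- make_arrhenius_data(-0.5, -0.9, resid_sd = 0.2, seed = 7)
  f1 <- fit_arrhenius(d)
  d2 <- d
  d2$ln_ef <- d$ln_ef + 2.5
  f2 <- fit_arrhenius(d2)
  expect_equal(f1$coef[["stdtemp"]], f2$coef[["stdtemp"]], tolerance = 1e-8)
  expect_equal(f2$coef[["(Intercept)"]] - f1$coef[["(Intercept)"]], 2.5,
               tolerance = 1e-8)
})

test_that("degenerate Arrhenius inputs fail informatively", {
  d <- make_arrhenius_data(-0.3, -0.8)
  d$ln_ef[3] <- NaN
  expect_error(fit_arrhenius(d), "non-finite ln_ef")
  one_t <- data.frame(ln_ef = 1:4, stdtemp = 0,
                      location = c("U2", "U1", "D", "D"),
                      site = c("a", "a", "b", "b"))
  expect_error(fit_arrhenius(one_t), "distinct temperatures")
  one_site <- make_arrhenius_data(-0.3, -0.8, n_sites = 1, resid_sd = 0.1)
  expect_warning(fit_arrhenius(one_site), "fewer than two sites")
})

test_that("MTE overlap verdict uses closed intervals", {
  expect_true(mte_consistency(c(0.31, 1.14), c(0.6, 0.7)))
  expect_false(mte_consistency(c(1.2, 1.8), c(0.6, 0.7)))
  expect_true(mte_consistency(c(0.7, 0.9), c(0.6, 0.7)))
  expect_true(mte_consistency(c(0.9, 0.7), c(0.6, 0.7)))  # order-agnostic
})

test_that("Hedges g matches the closed form and its symmetries", {
  a <- rnorm(10) + 5
  expect_equal(hedges_g(a, a)$g, 0)
  set.seed(12)
  x <- rnorm(10, 2, 1)
  y <- rnorm(10, 1, 1)
  g_xy <- hedges_g(x, y)
  expect_equal(g_xy$g, -hedges_g(y, x)$g, tolerance = 1e-12)
  # scale invariance
  expect_equal(hedges_g(3 * x, 3 * y)$g, g_xy$g, tolerance = 1e-12)
  # closed form: means 2 vs 1, common SD 1 exactly, n = 10 each
  x0 <- scale(rnorm(10))[, 1] + 2   # mean 2, sd 1 exactly
  y0 <- scale(rnorm(10))[, 1] + 1
  expect_equal(hedges_g(x0, y0)$g, (1 - 3 / 71) * 1, tolerance = 1e-10)
  expect_error(hedges_g(1, c(1, 2)), "n >= 2")
  expect_error(hedges_g(rep(1, 3), rep(1, 3)), "pooled SD")
})

test_that("Holm adjustment reproduces the step-down rule", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  p <- c(0.04, 0.01, 0.02)
  expect_true(all(holm_adjust(p) >= p))
})

test_that("location LME recovers an injected downstream shift", {
  d <- noiseless_design(n_sites = 10, strips = 6, seed = 31)
  d$residual_sd <- 0.25
  d$site_sd <- 0.3
  ds <- generate_survey(d)
  at <- assay_table(ds)
  fit <- fit_location_lme(at, "resp_c")
  expect_s3_class(fit, "location_lme")
  # D offset of +0.14 on the ln scale was injected (default params)
  expect_equal(nrow(fit$contrasts), 3)  # three pairwise location contrasts
  expect_true(all(fit$contrasts$p.value >= 0 & fit$contrasts$p.value <= 1))
  expect_true(fit$site_var_pct >= 0 && fit$site_var_pct <= 100)
})

test_that("count-family location model reports IRRs", {
  set.seed(5)
  sites <- sprintf("S%d", 1:10)
  df <- data.frame(
    site = rep(sites, each = 2),
    location = rep(c("U1", "D"), times = 10)
  )
  mu <- ifelse(df$location == "U1", 550, 450)
  df$richness <- rpois(nrow(df), mu)
  fit <- fit_location_lme(df, "richness", family = "count")
  irr_term <- fit$fixed[fit$fixed$term == "locationD", ]
  expect_equal(irr_term$irr, 450 / 550, tolerance = 0.08)
})
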