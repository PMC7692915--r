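test_that("normalization produces proportions or occupancy", {
  m <- matrix(c(2, 2, 4, 0, 3, 1), nrow = 3,
              dimnames = list(paste0("t", 1:3), c("a", "b")))
  rel <- normalize_table(m, "relative")
  expect_equal(rel[, "a"], c(t1 = 0.25, t2 = 0.25, t3 = 0.5))
  pa <- normalize_table(m, "presence_absence")
  expect_equal(unname(pa[, "b"]), c(0, 1, 1))
  m0 <- cbind(m, z = c(0, 0, 0))
  expect_error(normalize_table(m0, "relative"), "z")
})

test_that("rarefaction interpolates exactly and matches vegan", {
  x <- c(5, 3, 2, 1, 1)
  n <- sum(x)
  expect_equal(rarefied_richness(x, n), 5)          # m = n gives S_obs
  expect_equal(rarefied_richness(x, 1), 1)          # one read sees one taxon
  # against the independent hypergeometric implementation in vegan
  for (m in 2:(n - 1)) {
    expect_equal(rarefied_richness(x, m), as.numeric(vegan::rarefy(x, m)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # monotone non-decreasing, with extrapolation above S_obs
  curve <- vapply(c(1:n, 15, 20, 40), function(m) rarefied_richness(x, m), 0)
  expect_true(all(diff(curve) >= -1e-12))
  expect_gte(rarefied_richness(x, 30), 5)
  expect_error(rarefied_richness(x, 0), "m must be")
})

test_that("Chao1 asymptote uses the (n-1)/n correction", {
  # counts [1,1,2]: n = 4, f1 = 2, f2 = 1 -> S + (3/4) * 4/2 = 4.5
  expect_equal(rarefied_richness(c(1, 1, 2), Inf), 4.5)
})

test_that("alpha profile reproduces closed-form special cases", {
  one <- alpha_profile(c(42))
  expect_equal(one$hill1, 1)
  expect_equal(one$berger_parker, 1)
  expect_true(is.na(one$pielou_j))
  k <- 8
  even <- alpha_profile(rep(10, k))
  expect_equal(even$hill1, k, tolerance = 1e-12)
  expect_equal(even$pielou_j, 1)
  expect_equal(even$berger_parker, 1 / k)
  expect_error(alpha_profile(c(0, 0)), "all-zero")
})

test_that("Fisher's alpha solves S = alpha ln(1 + n/alpha)", {
  # frozen from an independent 200-step bisection of the defining equation
  expect_equal(fisher_alpha(2, 10), 0.7517669, tolerance = 1e-6)
  a <- fisher_alpha(2, 10)
  expect_equal(a * log(1 + 10 / a), 2, tolerance = 1e-9)
  # agrees with vegan's implementation on a real-looking sample
  x <- c(30, 20, 10, 5, 3, 2, 1, 1, 1)
  expect_equal(fisher_alpha(length(x), sum(x)),
               unname(vegan::fisher.alpha(x)), tolerance = 1e-5)
})

test_that("singleton correction estimates f1 from f2 and f3", {
  counts <- c(rep(1, 20), rep(2, 6), rep(3, 4), rep(4, 2), 10, 20)
  corrected <- singleton_correct(counts, seed = 1)
  f1_hat <- round(2 * 6^2 / (3 * 4))
  expect_equal(sum(corrected == 1), min(20, f1_hat))
  expect_warning(singleton_correct(c(1, 1, 2, 2), seed = 1), "f3 = 0")
})

test_that("pairwise beta partition is additive with exact degenerate cases", {
  same <- beta_pairwise(1:5, 1:5)
  expect_equal(unlist(same), c(beta_sor = 0, beta_sim = 0, beta_nes = 0))
  disj <- beta_pairwise(1:5, 6:10)
  expect_equal(disj$beta_sor, 1)
  expect_equal(disj$beta_sim, 1)
  expect_equal(disj$beta_nes, 0)
  nested <- beta_pairwise(1:2, 1:4)  # s=2, u_a=0, u_b=2
  expect_equal(nested$beta_sim, 0)
  expect_equal(nested$beta_sor, 1 / 3)
  expect_equal(nested$beta_nes, 1 / 3)
  expect_error(beta_pairwise(integer(), 1:3), "non-empty")
})

test_that("beta additivity holds to 1e-12 on random pairs", {
  set.seed(99)
  for (i in 1:300) {
    a <- sample(50, sample(3:30, 1))
    b <- sample(50, sample(3:30, 1))
    bp <- beta_pairwise(a, b)
    expect_lt(abs(bp$beta_sor - (bp$beta_sim + bp$beta_nes)), 1e-12)
    expect_true(all(unlist(bp) >= -1e-12 & unlist(bp) <= 1 + 1e-12))
  }
})

test_that("multi-site partition handles the canonical configurations", {
  m_same <- matrix(1, nrow = 6, ncol = 4)
  expect_equal(unlist(beta_multisite(m_same)),
               c(beta_sor = 0, beta_sim = 0, beta_nes = 0))
  m_disj <- rbind(diag(3), diag(3) * 0)[, 1:3]
  m_disj <- matrix(0, 9, 3)
  m_disj[cbind(1:9, rep(1:3, each = 3))] <- 1
  bm <- beta_multisite(m_disj)
  expect_equal(bm$beta_sim, 1)
  expect_equal(bm$beta_nes, 0)
  expect_error(beta_multisite(matrix(1, 3, 2)), ">= 3 samples")
  # additivity on random triples
  set.seed(7)
  for (i in 1:100) {
    m <- matrix(rbinom(60, 1, 0.4), nrow = 20, ncol = 3)
    m[1, ] <- 1  # avoid empty samples
    bm <- beta_multisite(m)
    expect_lt(abs(bm$beta_sor - (bm$beta_sim + bm$beta_nes)), 1e-12)
  }
})

test_that("Bray-Curtis matches the formula and vegan", {
  m <- cbind(a = c(0.5, 0.5), b = c(1, 0))
  expect_equal(as.vector(bray_curtis(m)), 0.5)
  ident <- cbind(a = c(0.3, 0.7), b = c(0.3, 0.7))
  expect_equal(as.vector(bray_curtis(ident)), 0)
  disj <- cbind(a = c(1, 0), b = c(0, 1))
  expect_equal(as.vector(bray_curtis(disj)), 1)
  set.seed(2)
  m2 <- matrix(runif(40), nrow = 8)
  colnames(m2) <- paste0("s", 1:5)
  expect_equal(as.matrix(bray_curtis(m2)),
               as.matrix(vegan::vegdist(t(m2), method = "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
  d <- as.matrix(bray_curtis(m2))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
})

test_that("NMDS separates block-structured distances and is seeded", {
  # two tight pairs far apart
  pts <- rbind(c(0, 0), c(0.05, 0), c(10, 0), c(10.05, 0))
  d <- dist(pts)
  # vegan warns that stress is (nearly) zero for this deliberate fixture
  fit <- suppressWarnings(ordinate_nmds(d, seed = 3))
  expect_lt(fit$stress, 0.01)
  ax1 <- fit$scores[, 1]
  expect_true(sign(ax1[1]) == sign(ax1[2]) &&
              sign(ax1[3]) == sign(ax1[4]) &&
              sign(ax1[1]) != sign(ax1[3]))
  fit2 <- suppressWarnings(ordinate_nmds(d, seed = 3))
  expect_identical(fit$scores, fit2$scores)
  expect_error(ordinate_nmds(dist(pts[1:2, ]), k_axes = 2), "more points")
})

test_that("strata-restricted PERMANOVA detects extreme separation", {
  # two groups with disjoint taxa across 10 strata
  n_sites <- 10
  counts <- matrix(0, nrow = 40, ncol = 2 * n_sites)
  for (s in 1:n_sites) {
    counts[1:20, 2 * s - 1] <- rpois(20, 10) + 1   # U group taxa 1-20
    counts[21:40, 2 * s] <- rpois(20, 10) + 1      # D group taxa 21-40
  }
  colnames(counts) <- paste0("x", 1:(2 * n_sites))
  groups <- rep(c("U", "D"), n_sites)
  strata <- rep(seq_len(n_sites), each = 2)
  d <- bray_curtis(normalize_table(counts, "relative"))
  res <- permanova_strata(d, groups, strata, n_perm = 199, seed = 5)
  expect_equal(res$p_value, 1 / 200)  # minimum attainable p
  expect_gt(res$statistic, 1)
})

test_that("PERMANOVA pseudo-F matches vegan::adonis2 without strata", {
  set.seed(10)
  m <- matrix(abs(rnorm(60)), nrow = 6)
  colnames(m) <- paste0("s", 1:10)
  groups <- rep(c("A", "B"), 5)
  d <- bray_curtis(normalize_table(m, "relative"))
  mine <- permanova_strata(d, groups, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(d ~ groups, permutations = 99)
  expect_equal(mine$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$r2, ref$R2[1], tolerance = 1e-10)
})

test_that("within-strata permutation never crosses strata and is seeded", {
  set.seed(4)
  m <- matrix(abs(rnorm(80)), nrow = 4)
  colnames(m) <- paste0("s", 1:20)
  groups <- rep(c("A", "B"), 10)
  strata <- rep(1:10, each = 2)
  d <- bray_curtis(normalize_table(m, "relative"))
  r1 <- permanova_strata(d, groups, strata, n_perm = 99, seed = 7)
  r2 <- permanova_strata(d, groups, strata, n_perm = 99, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  # p resolution is 1/(n_perm + 1)
  expect_equal(r1$p_value * 100, round(r1$p_value * 100), tolerance = 1e-9)
  expect_error(permanova_strata(d, rep("A", 20)), ">= 2 levels")
})

test_that("dispersion test flags a zero-dispersion group", {
  tight <- matrix(rep(c(5, 5, 5, 5), 6), nrow = 4)  # identical points
  loose <- matrix(runif(24, 0, 10), nrow = 4)
  m <- cbind(tight, loose)
  colnames(m) <- paste0("s", 1:12)
  d <- dist(t(m))
  res <- dispersion_test(d, rep(c("tight", "loose"), each = 6),
                         n_perm = 199, seed = 2)
  expect_lt(res$p_value, 0.05)
  m3 <- cbind(tight, loose, lone = runif(4))
  colnames(m3) <- paste0("s", 1:13)
  expect_warning(
    dispersion_test(dist(t(m3)),
                    c(rep(c("tight", "loose"), each = 6), "lone"),
                    n_perm = 49),
    "size-1")
})
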