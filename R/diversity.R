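#' OTU table container
#'
#' A minimal container for taxa x samples count matrices with per-sample
#' metadata, in the style of community-ecology matrices: rows are OTUs,
#' columns are samples; metadata has one row per sample with at least
#' `sample_id`, `site`, `location` and `marker` columns.
#'
#' @param counts Non-negative integer matrix, taxa x samples, with row and
#'   column names.
#' @param metadata Data frame with one row per sample; `sample_id` must
#'   match `colnames(counts)`.
#' @return Object of class `csa_otu`.
#' @export
otu_table <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(colnames(counts))) stop("counts needs sample column names", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("sample ids must be unique", call. = FALSE)
  if (!"sample_id" %in% names(metadata)) {
    stop("metadata needs a sample_id column", call. = FALSE)
  }
  missing_meta <- setdiff(colnames(counts), metadata$sample_id)
  if (length(missing_meta)) {
    stop("metadata missing for samples: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(counts = counts, metadata = metadata), class = "csa_otu")
}

#' @export
print.csa_otu <- function(x, ...) {
  cat(sprintf("OTU table: %d taxa x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$metadata$marker), collapse = ", ")))
  invisible(x)
}

#' Normalize an OTU table
#'
#' `"relative"` divides every count by its sample's total read count so
#' columns sum to one; `"presence_absence"` converts counts to 0/1
#' occupancy.
#'
#' @param t A `csa_otu` (or bare counts matrix).
#' @param mode `"relative"` or `"presence_absence"`.
#' @return Same shape as the input counts (a `csa_otu` in, a `csa_otu` out).
#' @export
normalize_table <- function(t, mode = c("relative", "presence_absence")) {
  mode <- match.arg(mode)
  counts <- if (inherits(t, "csa_otu")) t$counts else as.matrix(t)
  totals <- colSums(counts)
  out <- switch(mode,
    relative = {
      zero <- colnames(counts)[totals == 0]
      if (length(zero)) {
        stop("zero-total sample(s): ", paste(zero, collapse = ", "),
             call. = FALSE)
      }
      sweep(counts, 2L, totals, "/")
    },
    presence_absence = (counts > 0) * 1
  )
  if (inherits(t, "csa_otu")) {
    structure(list(counts = out, metadata = t$metadata), class = "csa_otu")
  } else out
}

#' Rarefied or extrapolated species richness at a target depth
#'
#' Sample-size-based rarefaction/extrapolation of OTU richness. For
#' `m <= n` (interpolation) the expected richness in a random subsample of
#' `m` reads is
#' \deqn{S(m) = S_{obs} - \sum_k \binom{n - X_k}{m} / \binom{n}{m}}
#' For `m > n` (extrapolation) the Chao1-style estimator is used:
#' \deqn{S(m) = S_{obs} + \hat f_0 \left[1 - \left(1 -
#'   \frac{f_1}{n \hat f_0 + f_1}\right)^{m-n}\right]}
#' with \eqn{\hat f_0 = \frac{n-1}{n} \frac{f_1^2}{2 f_2}} (and the
#' bias-corrected \eqn{f_1 (f_1 - 1) / 2} form when `f2 = 0`).
#'
#' @param counts Integer vector of one sample's OTU counts.
#' @param m Target depth (reads); >= 1. `m = Inf` returns the asymptotic
#'   Chao1 richness.
#' @return Expected richness (not necessarily integer).
#' @export
rarefied_richness <- function(counts, m) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  s_obs <- length(counts)
  if (n == 0L) stop("sample has no reads", call. = FALSE)
  if (length(m) != 1L || m < 1) stop("m must be a single value >= 1", call. = FALSE)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  f0_hat <- if (f2 > 0) {
    (n - 1) / n * f1^2 / (2 * f2)
  } else {
    (n - 1) / n * f1 * (f1 - 1) / 2
  }
  if (is.infinite(m)) return(s_obs + f0_hat)
  if (m <= n) {
    # lchoose is stable for the large binomials involved
    absent <- exp(lchoose(n - counts, m) - lchoose(n, m))
    return(s_obs - sum(absent))
  }
  if (f0_hat == 0 || f1 == 0) return(s_obs)
  s_obs + f0_hat * (1 - (1 - f1 / (n * f0_hat + f1))^(m - n))
}

#' Good-Turing singleton correction for sequencing data
#'
#' Sequencing error inflates the observed singleton count `f1`. The
#' corrected count is estimated from the higher-order frequency counts by
#' the same moment argument that gives Chao1 its `f0 = f1^2 / (2 f2)`:
#' one order up, `f1_hat = 2 f2^2 / (3 f3)`. When `f3 = 0` the observed
#' `f1` is returned unchanged with a warning. The correction is applied by
#' randomly demoting surplus singletons (deterministic given `seed`).
#'
#' @param counts Integer vector of one sample's OTU counts.
#' @param seed Integer seed controlling which surplus singletons drop.
#' @return Corrected counts vector (surplus singletons set to zero).
#' @export
singleton_correct <- function(counts, seed = 1L) {
  f1_idx <- which(counts == 1)
  f1 <- length(f1_idx)
  f2 <- sum(counts == 2)
  f3 <- sum(counts == 3)
  if (f1 == 0L) return(counts)
  if (f3 == 0L) {
    warning("f3 = 0: singleton correction unavailable, keeping observed f1",
            call. = FALSE)
    return(counts)
  }
  f1_hat <- min(f1, round(2 * f2^2 / (3 * f3)))
  surplus <- f1 - f1_hat
  if (surplus > 0L) {
    drop <- with_seed(seed, sample(f1_idx, surplus))
    counts[drop] <- 0L
  }
  counts
}

#' Fisher's log-series alpha
#'
#' Solves `S = alpha * ln(1 + n / alpha)` for `alpha` by bracketed
#' root-finding (tolerance 1e-10), where `S` is observed richness and `n`
#' total reads.
#'
#' @param s Observed richness (>= 2 for a meaningful solution).
#' @param n Total reads (> s).
#' @return Fisher's alpha.
#' @export
fisher_alpha <- function(s, n) {
  if (s < 1 || n <= s) stop("need 1 <= s < n", call. = FALSE)
  f <- function(a) a * log(1 + n / a) - s
  # f is increasing in alpha; bracket grows until sign change
  lo <- 1e-8
  hi <- 2
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Alpha-diversity profile of one sample
#'
#' Observed richness, rarefied/extrapolated richness at `target_depth`,
#' Shannon H and the order-1 Hill number `exp(H)` (effective number of
#' equally abundant taxa), Pielou's evenness `J' = H / ln S` (reported as
#' `NA` when `S = 1`), Berger-Parker dominance (`max p`) and Fisher's
#' alpha.
#'
#' @param counts Integer vector of one sample's OTU counts (total > 0).
#' @param target_depth Depth for the R/E richness (default 25000 reads).
#' @return Data frame with one row of the metrics.
#' @export
alpha_profile <- function(counts, target_depth = 25000) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0) stop("all-zero counts", call. = FALSE)
  s <- length(counts)
  p <- counts / n
  h <- -sum(p * log(p))
  data.frame(
    richness_obs = s,
    richness_re = rarefied_richness(counts, target_depth),
    shannon = h,
    hill1 = exp(h),
    pielou_j = if (s > 1) h / log(s) else NA_real_,
    berger_parker = max(p),
    fisher_alpha = if (s >= 1 && n > s) fisher_alpha(s, n) else NA_real_
  )
}

#' Pairwise beta-diversity partition (Sorensen = turnover + nestedness)
#'
#' For presence/absence assemblages with `s` shared taxa and `u_a`, `u_b`
#' uniques:
#' \deqn{\beta_{sor} = \frac{u_a + u_b}{2s + u_a + u_b}, \quad
#'   \beta_{sim} = \frac{\min(u_a, u_b)}{s + \min(u_a, u_b)}, \quad
#'   \beta_{nes} = \beta_{sor} - \beta_{sim}}
#' The Simpson component captures spatial turnover (species replacement);
#' the nestedness-resultant component captures richness-difference
#' (ordered loss); they sum exactly to Sorensen dissimilarity.
#'
#' @param a,b Taxon identifier vectors (or logical/0-1 incidence vectors of
#'   equal length); both non-empty.
#' @return List with `beta_sor`, `beta_sim`, `beta_nes`.
#' @export
beta_pairwise <- function(a, b) {
  is_incidence <- function(v) {
    is.logical(v) || (is.numeric(v) && length(v) > 0 && all(v %in% c(0, 1)))
  }
  if (length(a) == length(b) && is_incidence(a) && is_incidence(b)) {
    a <- which(as.logical(a)); b <- which(as.logical(b))
  }
  if (length(a) == 0L || length(b) == 0L) {
    stop("both assemblages must be non-empty", call. = FALSE)
  }
  s <- length(intersect(a, b))
  u_a <- length(setdiff(a, b))
  u_b <- length(setdiff(b, a))
  beta_sor <- if (u_a + u_b == 0) 0 else (u_a + u_b) / (2 * s + u_a + u_b)
  u_min <- min(u_a, u_b)
  beta_sim <- if (u_min == 0) 0 else u_min / (s + u_min)
  list(beta_sor = beta_sor, beta_sim = beta_sim,
       beta_nes = beta_sor - beta_sim)
}

#' Multi-site beta-diversity partition
#'
#' The multiple-site generalisation over >= 3 assemblages: with
#' `b_ij` = taxa in sample i absent from j,
#' `Smin = sum over pairs of min(b_ij, b_ji)`, `Smax` likewise with max,
#' and `K = sum(S_i) - S_total` the overlap excess,
#' \deqn{\beta_{SIM} = \frac{\Sigma_{min}}{\Sigma_{min} + K}, \quad
#'   \beta_{SOR} = \frac{\Sigma_{min} + \Sigma_{max}}
#'     {2K + \Sigma_{min} + \Sigma_{max}}, \quad
#'   \beta_{SNE} = \beta_{SOR} - \beta_{SIM}}
#'
#' @param x Presence/absence matrix, taxa x samples (>= 3 samples), or a
#'   `csa_otu` (converted via occupancy).
#' @return List with `beta_sor`, `beta_sim`, `beta_nes`.
#' @export
beta_multisite <- function(x) {
  counts <- if (inherits(x, "csa_otu")) x$counts else as.matrix(x)
  pa <- (counts > 0) * 1
  n <- ncol(pa)
  if (n < 3L) {
    stop("need >= 3 samples; use beta_pairwise() for two", call. = FALSE)
  }
  shared <- crossprod(pa)                       # s_ij
  s_i <- diag(shared)
  b <- outer(s_i, rep(1, n)) - shared           # b_ij = S_i - s_ij
  up <- upper.tri(b)
  sum_min <- sum(pmin(b[up], t(b)[up]))
  sum_max <- sum(pmax(b[up], t(b)[up]))
  k <- sum(s_i) - sum(rowSums(pa) > 0)          # sum S_i - S_T
  beta_sim <- if (sum_min == 0) 0 else sum_min / (sum_min + k)
  denom <- 2 * k + sum_min + sum_max
  beta_sor <- if (denom == 0) 0 else (sum_min + sum_max) / denom
  list(beta_sor = beta_sor, beta_sim = beta_sim,
       beta_nes = beta_sor - beta_sim)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \deqn{d(x, y) = \frac{\sum_i |x_i - y_i|}{\sum_i (x_i + y_i)}}
#' over a relative-abundance or presence/absence table. On 0/1 data this
#' equals Sorensen dissimilarity. Symmetric, zero diagonal, range [0, 1]
#' (the triangle inequality is not guaranteed).
#'
#' @param table Numeric matrix, taxa x samples (e.g. from
#'   [normalize_table()]), or a `csa_otu`.
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(table) {
  m <- if (inherits(table, "csa_otu")) table$counts else as.matrix(table)
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      denom <- sum(m[, i] + m[, j])
      d[i, j] <- d[j, i] <- if (denom == 0) 0 else sum(abs(m[, i] - m[, j])) / denom
    }
  }
  stats::as.dist(d)
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Seeded wrapper around [vegan::metaMDS()] (monotone-regression stress
#' minimisation with multiple random starts); scores are centered by the
#' underlying implementation.
#'
#' @param dist A `dist` (e.g. from [bray_curtis()]).
#' @param k_axes Number of ordination axes (default 2).
#' @param seed Integer seed (fixes the random starts).
#' @param trymax Maximum random starts.
#' @return List with `scores` (n x k matrix) and `stress`.
#' @export
ordinate_nmds <- function(dist, k_axes = 2, seed = 1L, trymax = 20) {
  n <- attr(dist, "Size")
  if (is.null(n) || n <= k_axes) {
    stop("need more points than axes", call. = FALSE)
  }
  if (all(dist == 0)) stop("all dissimilarities are zero", call. = FALSE)
  fit <- with_seed(seed,
    vegan::metaMDS(dist, k = k_axes, trymax = trymax, trace = 0,
                   autotransform = FALSE, wascores = FALSE)
  )
  list(scores = vegan::scores(fit, display = "sites"), stress = fit$stress)
}

#' PERMANOVA with permutations restricted within strata
#'
#' One-way permutational multivariate ANOVA on a dissimilarity matrix. The
#' pseudo-F is computed from sums of squared dissimilarities,
#' `SS_total = sum d^2 / N` and `SS_within = sum over groups of
#' (sum of within-group d^2) / n_g`, with
#' `F = (SS_between / (a - 1)) / (SS_within / (N - a))`. The null
#' distribution permutes group labels only *within* each stratum (here,
#' site), respecting the paired upstream/downstream survey design, and
#' \deqn{p = \frac{1 + \#\{F_{perm} \ge F_{obs}\}}{1 + n_{perm}}}
#'
#' @param dist A `dist` over samples.
#' @param groups Group labels (length n, >= 2 levels, not constant).
#' @param strata Stratum labels (length n); `NULL` for free permutation.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List of class `permutation_test`: `statistic` (pseudo-F), `df`,
#'   `r2`, `p_value`, `n_perm`, `strata`.
#' @export
permanova_strata <- function(dist, groups, strata = NULL, n_perm = 999,
                             seed = 1L) {
  n <- attr(dist, "Size")
  groups <- as.factor(groups)
  if (length(groups) != n) stop("groups length must match dist", call. = FALSE)
  if (nlevels(droplevels(groups)) < 2L) {
    stop("groups must have >= 2 levels", call. = FALSE)
  }
  if (!is.null(strata) && length(strata) != n) {
    stop("strata length must match dist", call. = FALSE)
  }
  d2 <- as.matrix(dist)^2
  a <- nlevels(droplevels(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / n

  ss_within_of <- function(g) {
    ss_within <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      ng <- length(idx)
      if (ng > 1L) {
        sub <- d2[idx, idx]
        ss_within <- ss_within + sum(sub[upper.tri(sub)]) / ng
      }
    }
    ss_within
  }
  pseudo_f <- function(g) {
    ssw <- ss_within_of(g)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }

  ss_within_obs <- ss_within_of(groups)
  f_obs <- ((ss_total - ss_within_obs) / (a - 1)) / (ss_within_obs / (n - a))
  strata_f <- if (is.null(strata)) factor(rep("all", n)) else as.factor(strata)
  idx_by_stratum <- split(seq_len(n), strata_f)

  f_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      g <- groups
      for (idx in idx_by_stratum) {
        g[idx] <- g[idx[sample.int(length(idx))]]
      }
      pseudo_f(g)
    }, 0)
  })
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  structure(list(statistic = f_obs, df = c(a - 1L, n - a),
                 r2 = (ss_total - ss_within_obs) / ss_total,
                 p_value = p, n_perm = n_perm,
                 strata = if (is.null(strata)) "none" else "supplied"),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Permutation test: F = %.4g (df %d, %d), p = %.4g (%d permutations, strata: %s)\n",
              x$statistic, x$df[1L], x$df[2L], x$p_value, x$n_perm, x$strata))
  invisible(x)
}

#' Multivariate homogeneity of group dispersions
#'
#' Tests whether groups differ in their spread around group centroids in
#' principal-coordinate space (a multivariate Levene analogue), via
#' [vegan::betadisper()] with a permutation F test. Groups of size one are
#' excluded with a warning.
#'
#' @param dist A `dist` over samples.
#' @param groups Group labels (>= 2 usable groups).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List of class `permutation_test` with the dispersion F and
#'   permutation p, plus `distances` (per-sample distance to centroid).
#' @export
dispersion_test <- function(dist, groups, n_perm = 999, seed = 1L) {
  groups <- as.factor(groups)
  sizes <- table(groups)
  drop_lev <- names(sizes)[sizes < 2L]
  if (length(drop_lev)) {
    warning("excluding size-1 group(s): ", paste(drop_lev, collapse = ", "),
            call. = FALSE)
    keep <- !groups %in% drop_lev
    dist <- stats::as.dist(as.matrix(dist)[keep, keep])
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2L) stop("need >= 2 groups of size >= 2", call. = FALSE)
  bd <- vegan::betadisper(dist, groups)
  pt <- with_seed(seed, vegan::permutest(bd, permutations = n_perm))
  tab <- pt$tab
  structure(list(statistic = tab[1L, "F"],
                 df = c(tab[1L, "Df"], tab[2L, "Df"]),
                 r2 = NA_real_,
                 p_value = tab[1L, "Pr(>F)"],
                 n_perm = n_perm, strata = "none",
                 distances = bd$distances),
            class = "permutation_test")
}
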