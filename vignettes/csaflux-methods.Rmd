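---
title: "Methods: cotton-strip decomposition, activation energies, carbon efflux and microbial diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cotton-strip decomposition, activation energies, carbon efflux and microbial diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csaflux)
```

## The problem

Municipal wastewater treatment plants discharge warm, nutrient-rich,
micropollutant-laden effluent into streams. `csaflux` implements the
analysis chain used to quantify what that does to a core ecosystem
function — microbial decomposition of organic matter — using the
standardized cotton-strip assay (CSA): cellulose strips incubated in the
stream, scored by microbial respiration, tensile-strength loss and mass
loss, at paired sampling locations above (U2, U1) and below (D) the
outfall across many sites. Around that core it provides activation-energy
estimation on the metabolic-theory temperature scale, conversion of
respiration to areal CO~2~ evasion with national upscaling, and OTU-table
diversity analyses for the microbial communities on the strips.

## Assay computations

**Respiration.** Oxygen drawdown in a closed chamber, corrected for drift
in a strip-free blank, scaled by chamber volume and normalised by strip
dry mass and time:

$$R_{CS} = \frac{\left[(DO_{S0} - DO_{CSt}) - (DO_{S0} - DO_{Ct})\right] V_{H_2O}}{m_{CS}\, t}$$

in mg O~2~ hr^-1^ g^-1^ DM. Two properties anchor the tests: the rate is
linear in chamber volume and invariant to adding a constant to all three
DO readings. A negative value (blank drift exceeding drawdown) is
physically meaningful probe noise: it is *retained and flagged*, excluded
from ln-scale model fits but kept in raw summaries, because silently
dropping the left tail would bias every downstream mean.

**Carbon conversion.** O~2~ consumption becomes CO~2~-carbon production via
a respiratory quotient: `rate / 32 * RQ * 12`. RQ defaults to 1.2 — a
calibration constant typical of organic-matter-rich running waters — and is
an argument everywhere, never a hard-coded constant.

**Decay coefficients.** Tensile strength and mass decline exponentially;
with a final measurement $X_t$, the mean $X_0$ of ten never-incubated
reference strips, and elapsed time $t$:

$$k = -\ln(X_t / X_0)\, /\, t$$

$t$ may be days (`k_D`, day^-1^) or an accumulated temperature basis.
Two conventions are provided for the latter: classic degree-days
(sum of daily mean °C) and the default Boltzmann-inverse basis
$\sum_d 1/(k_B T_d)$ with $T_d$ in Kelvin, which puts the cumulative
correction on the same inverse-temperature scale as the Arrhenius model.
The sum (rather than the mean) over days is the default because a decay
*rate per unit of accumulated basis* requires an extensive quantity; the
per-day-sum choice is stated here because the convention is genuinely
ambiguous in the field literature.

## Activation energies

Rates are modelled on the linearized Arrhenius / metabolic-theory scale.
With the standardized inverse temperature

$$x(T) = \frac{1}{k_B T} - \frac{1}{k_B \bar{T}_x}, \qquad
k_B = 8.6\times10^{-5}\ \mathrm{eV/K},$$

centered at $\bar{T}_x$ = 6.748 °C = 279.9 K (the survey's mean incubation
temperature), the model is

$$\ln EF = \ln EF(\bar{T}_x) - E_a\, x + \text{location terms} + b_{site} + \varepsilon$$

fitted by REML as `ln_ef ~ stdtemp * location + (1 | site)`
(`fit_arrhenius()`). The slope on $x$ is $-E_a$ for the reference
location (U2, the furthest upstream); per-location slope interactions
shift it, so `activation_energy()` returns
$E_a(\ell) = -(\beta_{stdtemp} + \beta_{stdtemp:\ell})$ with a Wald CI
propagated from the coefficient covariance. `fit_arrhenius_common()` drops
the interaction for a single overall $E_a$, and `mte_consistency()`
reports whether an estimate's CI intersects the 0.6–0.7 eV respiration
range predicted by metabolic scaling theory (closed intervals: touching
endpoints overlap).

Numerical choices worth knowing:

* **Noiseless inputs.** When the responses are an exact linear function of
  the design (OLS residual variance < 1e-20) the mixed model sits on a
  variance boundary and lme4 becomes numerically fragile; `fit_arrhenius()`
  detects this and returns the exact least-squares solution with zero
  random-effect variance. Generating coefficients are then recovered to
  better than 1e-8.
* **R².** Marginal and conditional R² follow the variance-decomposition
  convention for mixed models: fixed-effect variance over (fixed + random
  + residual), and (fixed + random) over the same total.
* **Wald CIs** (±1.96 SE) match how such model tables are conventionally
  presented; with ~12 sites the slope is effectively identified from 12
  cluster-level temperatures, so CIs are mildly anti-conservative. The
  parameter-recovery tests quantify this: the 2-SE check covers the truth
  in ~95% of simulated surveys.

**Effect sizes.** `hedges_g()` is Cohen's *d* with the small-sample
correction $J = 1 - 3/(4\,df-1)$, computed on *site-level means* by default
in the pipeline (the downstream-vs-U1 contrast); a per-strip pooled option
exists but inflates effective sample size and is not the default.
Location contrasts use `fit_location_lme()`: a site-random-intercept model
with Gaussian responses (REML, Satterthwaite p values) or Poisson log-link
GLMMs for counts, whose exponentiated coefficients are incident rate
ratios (IRR); all pairwise location contrasts carry Holm-adjusted p values.

## Carbon efflux and upscaling

`areal_efflux()` converts mass-specific respiration to an areal flux:
`resp_c * areal_dm_density * 8760 * 1e-6` (kg C m^-2^ yr^-1^). Every
constant lives in `evasion_config()`:

* `areal_dm_density = 3350` g DM m^-2^ — a surrogate areal density of
  cotton substrate chosen so that a typical upstream respiration rate
  (~0.81 mg C hr^-1^ g^-1^) maps to a ~24 kg C m^-2^ yr^-1^ areal flux,
  the scale reported for such surveys. Because the headline statistic is
  a *relative* change, it is provably invariant to this density (linearity
  is tested).
* `national_baseline_flux = 77.1` Gg C yr^-1^ and `affected_fraction = 1`
  — the baseline CO~2~ evasion of wastewater-affected small-to-medium
  (order 1–6) streams used by the relative approach.
* `affected_surface_area = 3.7e7` m^2^ — the affected stream surface used
  by the absolute approach.

`site_relative_change()` computes per-site `(D - U1)/U1` on per-site
median fluxes, summarises with the median, and attaches a seeded
percentile bootstrap CI that resamples *sites* (not strips), because site
is the independent replicate. The two upscaling approaches are then
one-liners: A = baseline x fraction x median relative change;
B = median absolute areal difference x affected area. A uses a median of
ratios and B a difference of medians, so they agree exactly only when the
downstream/upstream ratio is constant across sites; the pipeline reports
both so the discrepancy is visible rather than averaged away.

The bootstrap-coverage calibration study simulates 40 sites per trial
(ln-normal site ratios with known median): the percentile bootstrap of a
median is discrete in the order statistics and its coverage oscillates at
small n, while at 40 sites the 95% interval's true coverage settles in the
93–97% band. That study size is the package's calibration choice; the
survey-sized bootstrap (12–20 sites) is still reported but its CI should
be read as approximate.

## Community diversity

OTU tables are plain taxa x samples count matrices with sample metadata
(`otu_table()`). `normalize_table()` gives relative abundances or 0/1
occupancy. The analyses:

* **Rarefaction/extrapolation** (`rarefied_richness()`): hypergeometric
  interpolation below the sample's depth; Chao1-style extrapolation above
  it, with $\hat f_0 = \frac{n-1}{n}\frac{f_1^2}{2 f_2}$ (bias-corrected
  form when $f_2 = 0$). Default target depth 25,000 reads. The curve is
  monotone, equals observed richness at the full depth and 1 at one read.
* **Singleton correction** (`singleton_correct()`): sequencing error
  inflates $f_1$; the corrected count $\hat f_1 = 2 f_2^2/(3 f_3)$ comes
  from the same Good–Turing moment argument that gives Chao1 its
  $\hat f_0 = f_1^2/(2 f_2)$, one frequency order up. When $f_3 = 0$ the
  observed $f_1$ is kept with a warning. Published variants of this
  correction differ in detail; this package states its formula and does
  not claim to reproduce any specific published table.
* **Alpha profile**: Shannon H, Hill-1 = exp(H) (the "effective taxa"
  diversity reported alongside richness), Pielou J' (NA for one taxon),
  Berger–Parker dominance, and Fisher's alpha solved from
  $S = \alpha \ln(1 + n/\alpha)$ by bracketed root-finding to 1e-10.
* **Beta partitioning**: Sørensen dissimilarity split exactly into a
  Simpson turnover component and a nestedness-resultant component,
  pairwise and multi-site (`beta_pairwise()`, `beta_multisite()`);
  additivity is exact and tested to 1e-12.
* **Ordination**: `ordinate_nmds()` wraps a monotone-regression NMDS with
  seeded random starts.
* **PERMANOVA with strata** (`permanova_strata()`): the pseudo-F is
  computed from sums of squared dissimilarities, and the null distribution
  permutes location labels *within sites only*, respecting the paired
  design; $p = (1 + \#\{F^\pi \ge F\})/(1 + n_\pi)$, so p has resolution
  $1/(n_\pi+1)$ and can never be zero. Calibration: type-I error 5.6% at
  nominal 5% over 1,000 null simulations (199 permutations each, 10 sites
  of paired samples). On presence/absence data the Bray–Curtis input
  distance equals Sørensen, matching the dual relative-abundance /
  occupancy analyses.
* **Dispersion** (`dispersion_test()`): multivariate homogeneity of group
  dispersions (distances to group centroids in principal-coordinate
  space), with a permutation F test; size-one groups are excluded with a
  warning.

## The synthetic generators

The generators exist so every stage is testable end-to-end without field
data; their defaults *are* the emulated study conditions.

**Survey** (`generate_survey()`): 12 sites x 3 locations x 8 strips,
14-day incubations; site mean temperatures ~N(8.3, 1.7²) °C with +0.44 °C
downstream warming and 0.8 °C daily noise; three response channels
(respiration, tensile-strength decay, mass decay) with ln rates built as
intercept + location offset − Ea x stdtemp + site random intercept
(SD 0.3) + residual (SD 0.3). Default channel coefficients are the fitted
field values (respiration intercept −0.28 with Ea 0.79/0.65/0.64 eV for
U2/U1/D; tensile decay intercept −3.70 with Ea 1.73/1.90/1.14 eV).
Observables are then *back-computed by inverting the assay equations*
— DO budgets from rates, final tensile strengths and masses from decay —
with truncated Gaussian measurement noise (DO 0.05 mg/L, TS 8 N,
mass 0.005 g; per-strip measurement-error magnitudes are implementer
choices, as no published values exist). Setting all noise to zero makes
generation exactly invertible, which the round-trip tests exploit. The
chamber constants (1 L, 0.5 h assay) leave ample oxygen headroom for the
hottest strips; the generator warns if a configuration would exhaust
chamber DO, since a clipped DO reading censors the rate.

**OTU tables** (`generate_otu_tables()`): per site, an upstream taxon set
drawn from a rank-weighted regional pool (so sites share common taxa);
downstream expected richness is upstream / ratio (IRR sense; defaults
1.12 bacteria-like, 1.22 fungi-like). Of the upstream taxa absent
downstream, a fraction `turnover_fraction` are replaced by pool taxa new
to the site, the rest are pure losses; the default 0.63 for both markers
is obtained by solving this loss/replacement algebra for the observed
within-site Simpson (~0.21/0.38) and nestedness (~0.05–0.07) components at
the observed richness levels. Abundances follow a Fisher log-series whose
alpha is consistent with the sample's richness and depth (log-normal
optional), and reads are multinomial at fixed depth — so realized richness
carries sampling noise on rare taxa, as real amplicon data do.

**Flumes** (`generate_flume()`): treatment + block random effect +
residual on the ln scale. The dilution template rises with the wastewater
fraction but drops back at 85% (nonmonotone by design); the dosing
template has a negative micropollutant effect partially masked by added
nutrients; the transplant template crosses inoculation with transfer, a
`persistence` parameter giving the share of the inoculation effect carried
through transfer (1 = the inoculated community fully determines the rate).

What the generators do *not* emulate: sequencing error profiles and
chimeras, within-day temperature cycles, flow disturbance, spatial
autocorrelation along the channel network, and taxon-specific
environmental responses. Passing tests therefore demonstrate the
*statistical machinery* — unbiased recovery, calibrated error rates,
exact algebraic identities — not field realism.

Seeding: one master integer seed is split into named substreams (survey,
otu, flume, bootstrap, permutation), so stages can be regenerated
independently and identical seeds give byte-identical outputs; all seeded
code restores the caller's RNG state.

## The pipeline

`run_field_pipeline()` chains simulate (or `read_measurements()`) → assay
→ Arrhenius and location models → efflux and upscaling → diversity,
writing tidy CSVs and JSON summaries per stage plus a report with a
configuration hash (output paths excluded, so runs into different
directories hash identically). Later stages run even when an earlier
independent stage fails; flagged negative rates and excluded records are
counted in the report's warnings. Problem sizes used by the shipped tests
and the acceptance script — 100-replicate recovery studies, 1,000-trial
permutation and bootstrap calibrations with 199/999 resamples, and the
12 x 3 x 8 default survey — are the package's chosen study sizes for
those calibrations.

## Known limitations

* The areal-flux chain compresses a full hydrogeomorphic scaling
  relationship into one configurable density constant; absolute areal
  fluxes are therefore order-of-magnitude surrogates, while relative
  changes are exact under the model.
* Wald CIs from ~12-site mixed models are mildly anti-conservative; use
  the simulation harness to calibrate coverage for other designs.
* Fisher's alpha and the log-series abundance model assume an open
  community; for strongly even communities the log-normal option is more
  appropriate.
* The PERMANOVA implementation is one-way (location) with strata; it does
  not support covariates (the published analyses' land-use control is out
  of scope here).
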