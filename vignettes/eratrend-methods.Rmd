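---
title: "Methods: estimating breeding progress, plasticity, selection signals and environmental sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating breeding progress, plasticity, selection signals and environmental sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eratrend)
```

eratrend analyses *era trials*: multi-environment experiments in which
cultivars released over several breeding decades are grown side by side, so
that regression on release year reads genetic change directly off the
phenotypes. The package covers five linked analyses — per-environment
adjusted means (BLUEs), breeding progress, a phenotypic plasticity index,
a polygenic selection-signal test, and a thermal-time windowed
environmental-sensitivity scan — plus anatomical maximum stomatal
conductance, and ships a synthetic-data generator with known ground truth
for every stage. This vignette documents the models, their assumptions,
the tunable parameters, and the numerical and design choices, including
the ones where the design was genuinely open.

## Per-environment BLUEs

Within one environment (a combination of data source, year, location and
treatment) the plot model is the two-way fixed-effects layout

$$y_{ijk} = \mu + g_i + b_j + \varepsilon_{ijk},$$

solved by least squares; a cultivar's BLUE is the model prediction
averaged over the block levels of its connected design component. With
balanced complete blocks this is exactly the arithmetic genotype mean, and
with a single block or a single plot per genotype it degenerates to the
plain mean. Technical replicates within a block are averaged before
fitting so they do not overweight a cell. We use fixed effects rather than
a mixed model with random blocks: the per-environment adjusted-mean
semantics do not require a variance model, and the fixed-effects solution
is exactly reproducible, which the test suite exploits (equivalence with a
pseudoinverse normal-equations oracle to $10^{-10}$ over exhaustive small
designs).

Genotype-block incidence is checked for connectivity with a union-find
pass over the bipartite incidence graph; disconnected components are
estimated separately. Block contrasts never cross components, so silent
aliasing cannot leak between them, and genotypes that remain inestimable
are flagged missing with a warning rather than reported. Standard errors
are omitted when a single plot supports a cell.

## Absolute and relative breeding progress

For each trait and environment, the cultivar BLUEs are regressed on
release year by ordinary least squares. The slope is the absolute breeding
progress (ABP, trait units per year); relative breeding progress (RBP) is
the ratio of the fitted value at the 2010 release year to the fitted value
at 1970, a unitless quantity comparable across traits. Regressions are
unweighted — the BLUE precisions are not used as weights — and years are
centered at 1990 internally for conditioning, with all reporting on the
calendar scale. The RBP confidence interval uses the delta method on the
coefficient covariance; a genotype-resampling bootstrap is available
(`ci = "bootstrap"`) but the delta method is the default because it is
deterministic. If the fitted 1970 value is not positive the ratio is
meaningless: RBP is flagged undefined while ABP is still reported.

Across environments, each trait's RBP distribution is summarised by mean,
median and the 10th/90th percentiles (type-7 linear interpolation).
Trends are classified with a two-layer rule: a median within `delta`
(default 0.02, i.e. 2%) of 1 is *no change*; otherwise the direction
follows the sign of the median minus one, and the trend is *clear* when
the p10–p90 interval excludes 1 and *moderate* when it straddles it. The
clear/moderate operationalisation via the p10–p90 interval is this
package's declared rule: the visual distinction it reproduces is not
accompanied by a printed criterion anywhere we could adopt.

Two facts about the estimand are worth noting because they shape the
recovery experiments. First, the per-environment regression targets that
environment's RBP, which differs from the marginal ratio whenever an
additive environment effect $E_j$ shifts both predictions:
$(v_{2010}+E_j)/(v_{1970}+E_j) \neq v_{2010}/v_{1970}$. The synthetic
generator therefore records the realized per-environment estimand
(`true_rbp_env`) in its truth record, and CI coverage is assessed against
it; the marginal truth is checked through the mean of the estimates.
Second, RBP is invariant to rescaling the trait while ABP scales with it —
both are property-tested.

## The range/mean plasticity index

A cultivar's plasticity for a trait is the range of its BLUEs across
environments divided by their mean — a unitless summary of how strongly
it responds to the environment, i.e. of the genotype-by-environment
interaction it expresses. Because the index is unitless, the OLS slope of
plasticity on release year ("breeding progress in plasticity") is
comparable across traits. Environments are never pooled across declared
classes (field vs controlled): when the cultivar sets differ between data
sources, the index and its progress are computed per class. The floor is
`min_envs = 2` cells, the mathematical minimum; three or more is
recommended in practice since a two-point range is maximally noisy. No
outlier trimming is applied before taking the range. A zero mean leaves
the index undefined (flagged), and a negative mean — impossible for the
positive-valued traits this index is meant for, but still a defined input
— uses the absolute mean with a warning.

**Known limitation (attenuation under additive noise).** Any noise that
is additive on the BLUE scale inflates the observed range, and it inflates
the range of weakly responsive cultivars *relatively* more than that of
strongly responsive ones. A declining true responsiveness trend is
therefore attenuated toward zero. At the package's study conditions
(80 cultivars, 8 environments, environment-effect and residual SDs of
0.15 on a trait mean of ~2, baseline index 0.25, true trend −0.002/yr)
the bias is about +0.0002/yr against a slope SE of about 0.0004, so the
nominal 95% CI covers the generating trend in roughly 85% of replicates
rather than 90%+. This is a structural property of range/mean indices,
not of the CI machinery: with the noise-free generator the trend is
recovered exactly (unit-tested), and the acceptance suite deliberately
reports the noisy-condition coverage as measured rather than widening the
interval or quieting the noise.

## Polygenic selection signal

The selection statistic couples two quantities estimated on the cultivar
panel: per-SNP additive effects $\hat\beta_i$ and per-SNP allele-frequency
changes $\Delta p_i$ over the span of release years, combined as
$\hat G = \sum_i \hat\beta_i \, \Delta p_i$ together with the Pearson
correlation between the two vectors. Directional selection on the trait
drags trait-increasing alleles up in frequency, pushing both quantities
into alignment.

$\Delta p$ defaults to a per-SNP regression of genotype allele frequency
(dosage/2) on release year, multiplied by the year span — using every
cohort rather than only the first and last years; the two-cohort
difference is available (`method = "cohort"`) and doubles as the test
oracle on two-cohort designs. Effects come from ridge-regression BLUP
(the rrBLUP model): $\min_b \|y - Xb - Z\beta\|^2 + \lambda\|\beta\|^2$
with mean-imputed, implicitly centered dosages. The default penalty
follows the kernel equivalence $\lambda = m(1-h^2)/h^2$, with $h^2$
estimated by a one-dimensional REML grid search (step 0.01) on the
spectral form of the $ZZ'/m$ kernel model. Two algebraically identical
solvers are provided — the n×n dual, preferred when markers outnumber
genotypes, and the m×m penalized normal equations — and their agreement
to $10^{-8}$ is part of the acceptance suite.

**The permutation null.** The classic null for this statistic shuffles
the $\Delta p$ vector against the effects. When both vectors are
estimated from the *same* dosage matrix this shuffle is structurally
anti-conservative: each $\Delta p_i$ is a fixed linear form $c'Z_i$ in
SNP column $Z_i$ (with $c$ the year contrast) and each effect is a linear
form $\alpha'Z_i$ in the same column, so the scalar alignment
$\alpha'c$ — a random quantity of order $1/\sqrt{n}$ — is shared by all
$m$ SNPs and survives summation, inflating $|\hat G|$ relative to any
label-shuffled null by a factor of order $\sqrt{m/n}$. In calibration
simulations (50 genotypes, 500 neutral SNPs) the naive combination
rejects a true null 61% of the time at $\alpha = 0.1$.

eratrend therefore defaults to a different null: permute the *release
years* across cultivars and recompute every $\Delta p$ from the shuffled
years. Under the null hypothesis that neither allele frequencies nor the
trait are associated with release year, the year labels are ancillary, so
this test is exact by exchangeability regardless of how the effects were
estimated — measured type-I error 0.104 at $\alpha = 0.1$ over 1000 null
panels, with full power at the calibration settings under selection. The
label shuffle is retained (`perm = "dp_labels"`) for comparability; if it
is used, the effects should be estimated with
`ridge_marker_effects(..., adjust_year = TRUE)`, which absorbs release
year as an unpenalized fixed covariate and thereby forces
$\alpha'c = 0$ exactly (Henderson's mixed-model equations; both solvers
operate on covariate-residualized data). That combination is calibrated
(type-I 0.122) but pays for the detrending with reduced power. One
caveat travels with the year-shuffling null: it treats *any* systematic
frequency-year association as signal, so in real panels neutral drift
aligned with strong effect estimates can contribute; the synthetic
generator draws neutral loci with constant frequencies, matching the
hypothesis being tested.

The permutation p-value is $(1 + \#\{|\hat G^*| \ge |\hat G|\})/(n_{perm}
+ 1)$, two-sided, never below $1/(n_{perm}+1)$, bit-reproducible under a
seed, and significant at $\alpha = 0.1$ by default. Panels with fewer than
10 complete SNPs are refused — the permutation null is too coarse to mean
anything there. SNP-label permutation ignores linkage disequilibrium; the
generator draws independent loci, so this is consistent in the synthetic
setting, but real wheat panels violate it and would need an LD-aware
block permutation.

## Thermal-time windowed sensitivity

Environments are aligned on a developmental clock: cumulative thermal
time $\sum \max(T_{mean} - T_{base}, 0)$ with base 0 °C, anchored at each
genotype's heading date (thermal time 0). Heading is anchored per
genotype per environment because phenology differs across eras; a shared
anchor would smear any stage-specific signal across windows. The default
scan grid places 100 °Cd-wide windows every 20 °Cd from −900 to
+900 °Cd — 91 windows, the step being inferred from the window count and
span. Windows are half-open intervals $[lo, hi)$ so a day at an exact
boundary is counted once; a day belongs to a window by its thermal-time
distance from heading, never calendar distance, and an in-season day
falls in width/step = 5 consecutive windows. Windows with no member day
are missing, not zero.

For each cultivar, window and weather variable (global radiation,
precipitation, and minimum/mean/maximum temperature), the cultivar's
per-environment trait values are regressed on the window-mean covariate
and compared against the intercept-only reduction — the reduced model is
deliberately bare, with no co-varying confounders. The coefficient's
two-sided t-test gives the p-value and the *sensitivity* is the
normalized coefficient $100\,\hat\beta/\bar{y}$ (% change per unit of the
variable). At least 4 complete environments are required per regression
and zero-variance covariates yield missing cells. The computation uses
the closed-form simple-regression algebra vectorised over the whole
window-variable grid; it is property-tested cell-by-cell against `lm()`.

Group maps contrast cultivars released before 1980 ("old") with those
released after 2010 ("modern"): per trait, group, window and variable the
map holds the median sensitivity and median $-\ln p$ over cultivars,
blanking cells supported by fewer than `min_cultivars` (default 5)
informative cultivars, plus a modern-minus-old difference layer. Medians
are reported raw; no multiple-testing correction is applied across the
91×5 grid.

## Anatomical maximum stomatal conductance

From object-detection counts and guard-cell dimensions: effective count
per image is complete + 0.5·incomplete (blurry classes and trichomes are
excluded — they indicate unmeasurable objects); density is the effective
count over the imaged area (default 0.806 mm²) with exact unit
conversion; stomatal size is length × width. The fully open pore is an
ellipse with major axis the pore length and minor axis half of it, giving
$pa_{max} = \pi\,SL^2/32$ with pore length $SL/2$; pore depth equals the
stomatal width. Conductance is

$$g_{max} = \frac{(d_w/v)\, SD \, pa_{max}}{pd + (\pi/2)\sqrt{pa_{max}/\pi}}$$

with $d_w = 2.49\times10^{-5}\,$m² s⁻¹ and $v = 0.0224\,$m³ mol⁻¹ (25 °C
values): mol m⁻² s⁻¹ in SI units, zero without stomata, exactly linear in
density. The source description of the pore length is internally
inconsistent ("half of the half" alongside "major axis as pore length");
we adopt pore length = SL/2, the convention of the anatomical-gmax
literature, and expose `pore_length = "quarter"` for the stricter
reading. For amphistomatous leaves gmax is computed per surface and
summed (parallel diffusion paths); pooling anatomy before applying the
formula is reported alongside for comparison since the two differ
whenever surfaces differ. Dimensions are averaged over technical
replicate images per surface.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions of the acceptance experiments.

*Panels.* Release years are uniform over 1963–2018 with both endpoints
forced, guaranteeing regression support at the era boundaries; old/modern
labels split at 1980 and 2010.

*Trials.* Plot values follow
$g_i(1 + s_i e_j) + E_j + B_{jk} + \varepsilon$: genetic value linear in
release year; G×E as a genotype-specific multiplicative response $s_i$ to
a latent environment index $e_j$ spaced over $[-0.5, 0.5]$, so a
genotype's range/mean index equals $s_i$ exactly in the noise-free limit
and the plasticity trend is controlled by a single per-year parameter;
additive environment, block and residual noise on top; incidence thinned
at a missing rate. The truth record carries the marginal ABP/RBP, the
realized per-environment RBP estimand, and both the generating
responsiveness and the realized noise-free index per genotype. The
latent-index construction is a stand-in for real G×E covariance, which
the trials it emulates do not identify; passing recovery tests on it
shows the estimators work where the index model holds, not that real G×E
is this simple.

*Markers.* Selected loci are the causal ones: their expected frequency
rises linearly with release year (clamped to $[0.02, 0.98]$ with a
warning, keeping dosage variance non-degenerate for the ridge), and they
carry positive effects drawn $|N(0,1)|$, so rising alleles increase the
trait; neutral loci have constant frequencies and zero effect. Dosages
are binomial(2, p); the phenotype is $Z\beta$ plus Gaussian noise scaled
to the requested heritability, with unit environmental variance when the
panel is entirely neutral. The default architecture for the calibration
experiments is 100 selected loci among 500 — a polygenic but not
infinitesimal architecture, fixed before any calibration was run.

*Weather and heading.* Daily temperature follows a seasonal sinusoid with
an environment-level regime shift and day-to-day noise; radiation a
co-varying sinusoid; precipitation intermittent exponential draws;
ordering $T_{min} \le T_{mean} \le T_{max}$ holds by construction.
Heading is the first day cumulative thermal time reaches the genotype's
target (default 1000 °Cd, chosen so the ±900 °Cd scan range is covered;
too-short seasons fail with the shortfall named in °Cd). A known window
effect can be injected: the trait gains coefficient × window-mean of a
chosen variable over one thermal window, which the scan should localize.

*Stomata.* Counts are Poisson with the effective-count expectation
matching density × area; lengths lognormal; widths a sub-unity fraction
of length.

All generators are bit-reproducible under a fixed seed and leave the
caller's RNG stream untouched.

## Orchestration and reproducibility

`run_pipeline()` executes synth → BLUEs → progress/plasticity → selection
→ sensitivity → stomata from one validated configuration (bounds are
checked before any stage runs), writes every stage output as TSV with
numeric columns serialised at 12 significant digits, and reports a
manifest with md5 checksums, a key-order-invariant config hash, per-stage
timings and collected warnings. Two runs with the same configuration and
seed produce identical checksums. `export_figures()` re-renders the
standard figure set from the TSVs alone, skipping absent stages with a
warning. Dedicated BLUE writers serialise at 17 significant digits and
parse via `strtod`, so a write/read round trip is bit-exact.

## Problem sizes of the verification experiments

The acceptance experiments use: exhaustive BLUE-oracle equivalence over
all connected missingness patterns up to 4 genotypes × 3 blocks plus
random larger designs; 100 replicates of 200 genotypes × 10 environments
for RBP recovery; 100 replicates of 80 genotypes × 8 environments for the
plasticity trend; 1000 null and 100 selection panels of 50 genotypes ×
500 SNPs at 200 permutations for the selection test; 100 replicates of 30
genotypes × 12 environments for window localization (50 in the acceptance
script); a 1000-point parameter lattice for gmax; and a double end-to-end
pipeline run for determinism. These sizes were chosen so each experiment
pins its property with comfortable Monte-Carlo margins.
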