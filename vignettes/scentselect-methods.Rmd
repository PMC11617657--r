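---
title: "Methods: from peak tables to adaptive-plasticity classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from peak tables to adaptive-plasticity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`scentselect` implements a complete analysis chain for a climate-manipulation
field experiment on a hummingbird-pollinated subalpine wildflower: floral
volatile emissions and other floral traits are measured under manipulated
snowmelt timing (whole-plot shade cloth) and summer precipitation (subplot
rainout shelters and water addition), female fitness is assembled from fruit
and seed censuses, and the package asks (i) how plastic the traits are,
(ii) whether soil moisture mediates that plasticity, (iii) how phenotypic
selection on the traits shifts with the environment, and (iv) whether the
plastic responses are adaptive. A synthetic-study generator with known truth
parameters stands in for the field data, so every stage is testable offline.

## The experimental design and its simulation

The design is a split plot: snowmelt (early vs control) is applied to
whole plots (3 per level), each split into four subplots receiving one of
four precipitation treatments (control, mock shelter, 50% reduction, 200%
addition), over three years. Control-plot snowmelt falls on days of year
119, 158 and 126; shade cloth advances melt by 3–11 d. Only the range and
mean (6 d) of the advancement are stated for the field system, so draws are
uniform on [3, 11], which matches both. Estimated summer precipitation is
the ambient amount of the year times the treatment multiplier
(0.5 / 1 / 1 / 2). Ambient precipitation per year (150, 220, 130 mm) and
the flower, fruit-fate and seed distributions below have no stated field
values; they were fixed once at values a field ecologist working in
subalpine meadows would call realistic, and they are documented here rather
than revisited.

Soil volumetric water content (VWC) is generated with a logistic link from
absolute precipitation and snowmelt date onto the observed 2–8% range of
season-average subplot VWC; plant-level snapshots scatter around the subplot
mean (sd 2% VWC) truncated to the instrument range 0–15%. The link
guarantees the observed ranges by construction and responds monotonically to
both drivers, which is exactly the structure the downstream soil-moisture
models assume; it does not claim to be a hydrological model.

## Emissions, traits, and the truth parameters

29 volatiles in four biosynthetic classes (monoterpenes, sesquiterpenes,
benzenoids, aliphatics) are drawn from a multivariate lognormal with a
common within-class correlation (default r = 0.5 on the log scale,
mirroring the many strongly correlated compound pairs seen in real
bouquets), times a per-compound Bernoulli detection gate (default p = 0.85)
that produces the zeros real peak tables contain. α-pinene dominates the
default bouquet, with a handful of mid-abundance compounds and a long tail,
mimicking the published composition. Morphology and reward traits
(corolla dimensions, style length, sepal width, nectar volume and
concentration, inflorescence height) are Gaussian.

Plasticity enters as multiplicative treatment effects on the trait mean and
an additive log-scale slope per %VWC of plant-level moisture. The default
truth is a *null* world (all effects zero, all gradients zero): the
package's baseline claim is calibration, and scenario worlds with
field-scale effects (0.2-SD shifts, gradients of 0.15, selection-by-snowmelt
slopes of 0.007 d⁻¹) are switched on explicitly in the tests so each claim
names the world it was measured in.

Fitness components chain as: flowers per plant ~ 1 + NegBin(μ = 40,
size = 4); a small fraction (2%) of flowers collected early; 30% of
remaining flowers abort; each nonaborted fruit is attacked with probability
logistic(logit(0.2) + Σ β_pred z) (fly : caterpillar attacks 7 : 1); 10% of
surviving fruits dehisce before collection; intact-fruit seed counts are
Poisson with mean chosen so that expected seeds initiated per flower equals
`base · exp(Σ β_poll z)`; fly eggs are Poisson with mean proportional to the
attack odds. The flowers-per-plant and seeds-per-fruit distributions are
explicitly placeholders (no field estimates are asserted for them), not
claims about any study organism. Truth gradients are defined on standardized traits
— square-root scale for volatiles, matching the analysis scale — so the
estimators' output is directly comparable to the truth.

## Volatile filtering and quantitation

A compound is retained iff its median retention time lies in [2, 17] min,
it is detected (area > 0; threshold configurable) in ≥ 10% of *floral*
samples (ambient samples never enter the denominator), its floral mean
*strictly* exceeds 4 × the ambient-control mean, and it is not a named
contaminant. The ratio rule is evaluated division-free
(`floral > 4 · ambient`), so a compound absent from ambient air passes
whenever it has any floral signal, and a table without ambient controls is
an error, never a silent pass. Every input compound appears exactly once in
the audit with the outcome of each rule.

Calibration lines are forced through the origin (zero dosage must give zero
area). Weighting is 1/dosage² by default: dilution-series detector noise is
close to a constant coefficient of variation, and under that noise the
uniform-weight slope SE is badly anticonservative (measured 2·SE coverage
0.675 in simulation vs ≈0.95 with 1/dosage² weights). Uniform weighting
remains available. Emission rates are `(area / slope) / 0.25 h` (15-min
sampling), averaged across a plant's repeated samples *before* any
transformation, then square-root transformed for plasticity analyses
(the order matters; the transform is flagged on the matrix). Class totals
are always computed on untransformed rates. Compounds map to the class
standard (α-pinene, β-caryophyllene, methyl salicylate,
(Z)-hex-3-en-1-ol) by default; because seven standards exist for four
classes the map is fully overridable, and no default is asserted for
ambiguous compounds such as linalool or indole.

## Constrained ordination (CAP)

Distances are Bray–Curtis on the square-root-transformed, plant-averaged
emission matrix. Principal coordinates come from the eigendecomposition of
the double-centred Gower matrix; axes with negative eigenvalues (inevitable
for a non-Euclidean coefficient) are discarded with a logged count, and a
square-root metricising correction is available. Total inertia is the trace
of the Gower matrix — the positive eigenvalue sum *plus* the negative sum —
which is the convention of the standard distance-based-RDA software, so the
"percent of total inertia explained" is comparable to published tables
computed that way. The package's CAP path is authored here and is checked
against an independent reference implementation (vegan) to 1e-6 in the test
suite; the package itself never calls vegan.

Terms are tested sequentially (order of entry) with pseudo-F equal to the
term's sequential inertia over the full-model residual inertia, each per
df. Permutations are free row permutations of the coordinate matrix;
p = (1 + #{F* ≥ F}) / (1 + n_perm), honouring the 1/(n_perm+1) floor. The
split-plot structure cannot be encoded in this permutation scheme — a
documented limitation of the method as commonly implemented — so the
companion mixed models carry the design's error structure instead. All
interactions can be tested as one block after the main effects. The number
of permutations is a user choice (default 999; the calibration tests use
199 for speed); published analyses of this kind rarely state their scheme, and no claim
is made that these defaults reproduce any particular one.

## Split-plot mixed models and marginal means

Total and per-class emissions (and any trait) are modelled with REML via
lme4, with random intercepts for plot and subplot-within-plot. Wald t tests
use *containment* denominator df — whole-plot terms against the plot-level
df, subplot terms against the subplot level, plant-varying covariates
against the residual — the classical split-plot ANOVA choice. A
Satterthwaite approximation would need machinery from packages not in this
stack; containment is exact in the balanced case and conservative
otherwise, and a normal-approximation option exists. Singular fits (a
variance component at zero) are reported with a warning, never silently
refit. Estimated marginal means average model predictions over the levels
of the other factors with equal weights (covariates at their means), with
delta-method SEs from the fixed-effect covariance.

Cohen's d for a treatment contrast uses the pooled SD of the two groups
within year; |d| is then averaged across years per trait (one of several
defensible aggregations; the choice is logged). The volatiles-vs-other
comparison of mean |d| treats traits as independent and is labelled
approximate.

## Fitness measures

Four female-fitness measures per plant: total seeds (counted seeds, plus
dehisced fruits imputed at the plant's mean seeds per intact fruit, plus
early-collected flowers imputed at the plant's mean seed production per
flower allowed to set seed; eaten fruits contribute zero); seeds initiated
per flower ((nonaborted fruits / flowers at risk) × mean seeds per noneaten
fruit — a pollination-success component insulated from predation); escape
from seed predation (1 − attacked/nonaborted, caterpillar attacks counted);
and fly eggs per surveyed flower (season sums, not per-survey means).
"Flowers at risk" excludes early-collected flowers, which could not set
fruit; the alternative reading is available as a switch. A plant whose
imputation is impossible (dehisced fruits but no intact fruit) is *missing*,
never zero, with a reason code, and missing values are excluded pairwise
from selection models. Each measure is relativized by its grand mean over
all plants and years pooled — per-year relativization would absorb exactly
the year-to-year fitness differences the environmental analyses are about,
and a regression test pins the pooled choice.

## Selection analyses

Traits are mean-centred and scaled by the sample SD (n−1) within the set of
plants entering each model. Three estimators:

1. **Class model**: relative fitness on the four standardized class totals,
   the design factors, and all class × factor interactions; per-context
   gradients are read off the coefficients, and each interaction block gets
   a marginal F test via explicit nested-model comparison.
2. **Univariate × environment**: `w ~ z + S + P + z:S + z:P` with snowmelt
   date and precipitation centred so the main effect is the gradient at the
   average environment. If both interactions have p > 0.05 they are dropped
   and the main effect reported. Year does not enter these models by
   default (a toggle exists).
3. **Elastic net** (α = 0.5, λ by 10-fold CV under a named fold seed,
   `lambda.min` as the default reading of "optimum λ"; `lambda.1se`
   available): direct gradients with exact zeros meaning "not selected".
   Environmental covariates enter unpenalized so shrinkage targets the
   traits. Traits are pre-standardized, so glmnet's internal standardization
   is disabled; no SEs or p-values are reported, mirroring standard
   practice for the method. Combined traits+volatiles runs are restricted
   to plants complete on everything and labelled a non-random subset.

Volatiles enter the univariate analysis when they occur (value > 0) in
≥ 75% of samples. No multiple-testing adjustment is applied anywhere —
unadjusted per-trait p-values are the convention for exploratory selection
scans — and the output metadata says so. Environmental
fitness effects (`w ~ S + P`, trait removed) are reported as percent change
of mean fitness per day of earlier melt and per mm precipitation.

## Adaptive-plasticity classification

For each trait × contrast (early snowmelt, reduced precipitation, added
precipitation) × year, plasticity is the fold change of EMMs from a model
containing both treatment factors, on the measurement scale (not the sqrt
analysis scale) for interpretability. Selection in the new environment is
the univariate gradient inside the corresponding treatment × year subset
(precipitation contrasts pool over snowmelt levels within year), with fitness re-relativized and the trait re-standardized
within the subset. The classification is the quadrant rule on (log fold
change, β): same sign = adaptive, opposite = maladaptive, either exactly
zero = neutral; log fold change is symmetric about 0, resolving the
uncentred-axis ambiguity. β is treated as zero only when exactly zero
(elastic net); significance is carried separately, and the *stringent* flag
requires significant plasticity, univariate p < 0.05 and a nonzero
elastic-net gradient. Fly eggs per flower is excluded from concordance as
the least direct fitness measure. Balance of adaptive vs maladaptive
responses is an exact binomial test of 0.5 among non-neutral records per
fitness measure.

## Numerical and testing notes

- Determinism: one master seed fans out to per-stage child seeds through a
  hash, so stages are individually reproducible and reruns are
  byte-identical.
- The permutation floor, inertia conservation (constrained + residual =
  positive inertia, to 1e-8), audit completeness, and the flower accounting
  identity are enforced by property tests.
- The simulation-based acceptance tests run at their stated scales (500
  null-calibration replicates, 200 gradient-recovery replicates, 100
  interaction-recovery replicates) under fixed seeds; rejection-rate bands
  are read as roughly two binomial Monte-Carlo standard errors around the
  nominal level.
- What a green test establishes: calibration and recovery *within the
  generator's world* — lognormal emissions, logistic attack, log-linear
  seed set. Real data add phenology, spatial autocorrelation within plots,
  pollinator behaviour and observation error that the generator explicitly
  does not model; the external-data targets were not reproducible offline
  and are therefore not asserted.

## Known limitations

No quadratic/correlational selection gradients; no male fitness; no
binomial GLMM for attack proportions (plant-level analysis only); CAP
permutations ignore the split-plot structure (by construction of the
method); containment df rather than Satterthwaite; the egg–attack coupling
in the generator (eggs Poisson in the attack odds) is one plausible link,
not a measured one.
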