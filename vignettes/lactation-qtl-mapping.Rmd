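---
title: "Mapping QTL for lactation persistency in a dairy-sheep backcross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping QTL for lactation persistency in a dairy-sheep backcross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactQTL)
```

## The problem

Dairy sheep lactations are short and steeply declining compared with
cattle. Two curve-shape traits matter for management and for cheese-making
merit: *lactation persistency* — how much of the peak daily yield is still
produced at the standard reference day — and *extended lactation* — how
much production is sustained after that day. Both are sex-limited and
expensive to measure, which makes marker-assisted selection attractive and
motivates mapping the quantitative trait loci (QTL) that influence them.

lactQTL implements the complete analysis chain for a single-sire backcross
family: an (Awassi × Merino) F1 sire mated to Merino ewes, so that every
daughter inherits either the Awassi (A) or the Merino (M) sire allele at
each locus. The study scale the package targets throughout is 172
daughters genotyped at 189 microsatellites across the 26 sheep autosomes,
with milk yield recorded every second day and milk composition weekly.

## Lactation curves and derived traits

Daily yield is summarized by the Wood curve

$$W(t) = a\,t^{b}e^{-ct}, \qquad k = \ln a,$$

where $a$ scales the curve (yield units), $b \ge 0$ controls the early
rise and $c > 0$ the decline rate (per day). The curve peaks at
$t_{\max} = b/c$ with $\mathrm{maxY} = a\,(b/c)^b e^{-b}$, and its
integral has the closed form
$a\,c^{-(b+1)}\gamma(b+1, cT)$ with $\gamma$ the lower incomplete gamma
function (`cumulativeYield()` evaluates it exactly via `pgamma`). Note
the exponent in $\mathrm{maxY}$ is $b$: this is forced by
$W(t_{\max})$ itself, and the package uses it consistently.

From a fitted curve we derive, per ewe and trait:

* **persistency** $= W(T)/\mathrm{maxY} \in (0, 1]$ at the reference day
  $T = 100$ — the standard lactation length for sheep used here (the
  cattle convention would be day 305). $T$ is configurable but
  default-locked to 100.
* **extended lactation**
  $= [\mathrm{CumY}(300) - \mathrm{CumY}(100)]/\mathrm{CumY}(100) \ge 0$,
  with the day-300 cut-off avoiding an unbounded window.

Composition traits are converted to yields before curve fitting:
PY = protein% × MY / 100 (likewise FY, LY), somatic cell score
SCS = log10(SCC), SCY = SCS × MY, and useful yield UY = FY + 1.85 PY, a
cheese-merit index. The division by 100 keeps component yields in mass
units; it cancels from every ratio trait, so persistency and extended
lactation are unaffected by the convention. Because composition is
sampled weekly while milk is recorded every other day,
`buildComponentRecords()` pairs each composition day with the nearest
milk record (at most one day away under the default scheme).

### Fitting

The Wood curve is log-linear, so `fitWoodLogLinear()` estimates
$(k, b, c)$ by ordinary least squares on
$\ln W = k + b \ln t - ct$ (zero yields cannot be logged; they are
excluded and counted). `fitWoodNLS()` then refines the estimate by
Levenberg–Marquardt least squares on the natural scale and is guaranteed
never to return a fit with larger natural-scale residual error than its
starting point. Fits with $c \le 0$ (no decline within the observed
window) are retained but flagged `non_declining`; persistency is
undefined for them and is propagated as missing with a reason code,
rather than silently dropping the ewe.

`fitPopulation()` approximates a nonlinear mixed-model fit of all curves
at once by a transparent two-stage scheme: per-curve estimates, then
shrinkage of each lactation's $(k, b, c)$ toward fixed-effect-adjusted
population means with weights inverse to the per-curve sampling variance
(method-of-moments between-lactation variance). We chose the two-stage
route over a simultaneous `nlme` fit because it is deterministic, fails
one curve at a time rather than globally, and each stage is unit-testable
against closed forms; the cost is a slight loss of efficiency when curves
are short. Fixed effects (age class, parity, birth type, milking
frequency, season) enter as additive adjustments on $(k, b, c)$ and
standardized parameters are reported at the reference level of every
factor; a factor level carried by a single lactation is non-estimable and
is pooled with the reference, with a flag.

## From genotypes to transmitted-allele probabilities

The map lives in centimorgans with the origin at the first mapped marker
of each chromosome. Haldane's map function (no crossover interference),
$r = \tfrac12(1 - e^{-2d/100})$, is the default everywhere — it matches
the regression tool convention in this field and makes every probability
exactly enumerable; Kosambi is available behind the `mapFunction` flag.

At an arbitrary position, `transmissionProb()` computes the probability
that a daughter inherited the A allele conditional on her *nearest
informative flanking markers* only (unknown genotypes are skipped when
choosing flanks). With microsatellite-density maps the difference from a
full hidden-Markov chain over all markers is negligible, and the
two-flank computation is exactly checkable by brute-force enumeration
over the transmitted states — which is how the tests verify it. The
probability is exactly 0 or 1 at an informative typed marker, falls back
to a single-flank transition beyond the last informative marker, and is
1/2 (with a coverage warning) when a chromosome carries no information
at all.

## The two mapping routes

All traits are natural-log transformed before mapping; a zero among
positive values receives an offset of half the smallest positive value
(zeros only), and the rule is recorded in the output attributes.

**Mixture maximum likelihood** (`scanMle()`). At each grid position the
trait is a two-component normal mixture over the transmitted allele,
$\sum_i \ln[p_i\phi(y_i;\mu_A,\sigma) + (1-p_i)\phi(y_i;\mu_M,\sigma)]$,
which mirrors the Mendelian segregation of the putative QTL rather than
averaging over it. The likelihood is maximized by EM with a single
pooled $\sigma$ (the standard interval-mapping variance structure),
initialized from the no-QTL fit split by $\pm 0.5$ SD, and iterated to a
relative log-likelihood change below 1e-8 or 200 iterations. The score
is $\mathrm{LOD} = [\ell_{\max} - \ell_0]/\ln 10$; because the no-QTL
model is nested, positions where EM stalls below the null optimum are
floored at LOD 0. Peaks are classified by the printed convention —
suggestive in [1.75, 2), significant in [2, 3], highly significant above
3 (the value 3.0 itself deliberately falls in "significant") — with
1-LOD drop support intervals (ties at the peak broken leftmost and
flagged) and effects expressed in units of the no-QTL phenotypic SD,
positive when the Awassi allele raises the trait.

**Half-sib regression** (`scanRegression()`). The trait is regressed on
$x_i = 2P_i(A) - 1$ position by position;
$F = (\mathrm{RSS}_0 - \mathrm{RSS}_1)/(\mathrm{RSS}_1/(n-2))$. In this
single-sire family the general multi-family half-sib regression reduces
to one within-family regression, so no across-family weighting appears.
At a fully informative marker the two routes are algebraically linked,
$\mathrm{LOD} = (n/2)\log_{10}(1 + F/(n-2))$, an identity the test suite
exploits as a cross-method oracle.

Significance for the regression route comes from permutation:
phenotypes are shuffled against genotype rows, the per-permutation
chromosome-maximum F is collected (1000 re-samplings by default), and
thresholds are its empirical quantiles. Experiment-wide levels use a
Bonferroni-style adjustment of the chromosome-wise tail over the 26
autosomes ($1 - \alpha/26$ quantile); the adjustment choice is a
reconstruction, stated here because genome-wide threshold constructions
vary. Bootstrap confidence intervals for peak position resample
daughters with replacement (percentile method; degenerate monomorphic
resamples are redrawn and counted). QTL heritability is
$1 - \mathrm{RMS}_{\mathrm{full}}/\mathrm{RMS}_{\mathrm{reduced}}$ from
the nested regression fits, clipped at zero with a flag.

**Two-QTL search** (`scanTwoQtl()`). The additive model
$y \sim x(A) + x(B)$ is fitted over ordered position pairs on a 2 cM
grid with a 5 cM minimum separation — both chosen to bound collinearity
of the two predictors and runtime; F(2vs0) tests the pair against no
QTL, F(2vs1) against the best single-QTL fit, and the phase
(repulsion/coupling) is read off the effect signs.

## What the generator emulates — and what it does not

`simConfig()` holds the whole study design in one object. The defaults
*are* the target design: 172 daughters, 189 markers on 26 autosomes
(lengths declining 240 to 50 cM, a sheep-like ~3800 cM genome, allocated
proportionally), marker informativeness 0.9 and missing-cell rate 0.05
(microsatellites in a backcross sire are usually but not always
informative), milk every 2 days, composition weekly. Wood population
means $(k, b, c) = (\ln 1.5, 0.45, 0.027)$ give a peak of ~2.7 L/day
near day 17 and milk persistency near 0.23, matching the low milk-yield
persistency characteristic of this breed cross; between-ewe SDs
(0.25, 0.08, 0.006) and log-scale measurement noise 0.15 produce
realistic curve-to-curve scatter. Composition percentages follow linear
day trends (protein 5.5% rising 1.2 points per 100 days, fat 6.5% rising
1.8, lactose 4.8% falling 0.3, SCC 150k cells/mL with a log-linear
rise), which reproduces the field observation that component-yield
persistency — useful yield above all — exceeds milk persistency.
Lactation length is min(300, 50 + Weibull(1.5, 120)) days, thinning the
cohort sharply after day 100 as real recording does.

Meiosis is simulated as the Haldane two-state switch process marker to
marker, which by construction matches the mapping model. A QTL can act
on a Wood parameter (biologically natural — e.g. on $c$, flattening the
decline) or, the default for calibration work, *directly* on the derived
trait: the decline rate of each ewe is adjusted so her analysis-scale
trait shifts by exactly half the configured contrast, calibrated so the
realized genotype contrast equals the configured effect in units of the
cohort's baseline SD. True transmitted states at the QTL and every true
parameter go into a truth file for automated recovery tests.

Passing tests on these bundles therefore demonstrate correctness of the
machinery under the model's own assumptions — they cannot certify
robustness to what the generator omits: genotyping errors beyond
missingness, dam-side genetic structure (the dam contribution is
absorbed into residual noise, consistent with the half-sib analysis
model), multi-generation pedigrees, population-level linkage
disequilibrium, or non-Wood curve shapes.

## Numerical choices and degenerate inputs

* Log-linear fits clamp a negative rise exponent to the boundary
  $b = 0$ (refit, flagged) so the Wood constraints always hold.
* EM tolerance 1e-8 (relative), 200 iterations; component weights are
  guarded against vanishing denominators; $\sigma$ floored at 1e-10.
* `supportInterval()` walks outward from the peak, so the interval is
  the widest contiguous region containing it; a flat profile returns
  the whole chromosome.
* Monomorphic scan positions (zero variance in $x$) are skipped and
  flagged rather than producing infinite F values.
* All resampling takes explicit seeds; identical seeds give
  bit-identical thresholds, bootstrap peaks and simulated studies. The
  pipeline derives per-stage seeds from one top-level seed and prints
  them in its manifest.

## Verification scale

The test suite validates each statistical claim at sizes chosen to keep
Monte-Carlo error well below the asserted tolerances while running on a
single CPU in about a minute: 2000 replicates for the design-power
check (binomial SE 0.01), 500 replicates for detection/heritability
recovery of a 0.6 SD QTL, 200 datasets for permutation-threshold
calibration, 200 curves for Wood-recovery bias, and 100 random parameter
draws for each closed-form-versus-quadrature identity.

## A worked example

```{r example, eval = FALSE}
cfg <- simConfig(seed = 11,
                 qtl = data.frame(chromosome = 11, position = 35,
                                  target = "direct", effectSD = 0.6))
out <- runPipeline(cfg, outdir = "run1", traits = "MY", step = 2,
                   nPermutations = 1000, nBootstrap = 1000)
out$mlePeaks      # Table-3-shaped: position [CI], flanks, LOD, effect (SD)
out$regPeaks      # regression peaks with permutation stars and h2
```

## Known limitations

The package maps within one sire family only: effects are contrasts
between the two sire haplotypes and do not generalize to population-wide
substitution effects. The two-flank transmission model slightly
underuses information when both flanking markers are missing but distant
markers are typed. The fixed-effect standardization is an additive
approximation on the parameter scale, not a re-fit of the full nonlinear
mixed model. Persistency of a non-declining curve is reported missing —
at cohort level this truncates the persistency distribution just below
1, which mirrors how such curves must be handled in practice but should
be remembered when comparing summary tables across cohorts.
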