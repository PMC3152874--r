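# lactQTL

Wood lactation-curve modelling and single-family QTL mapping for milk
persistency and extended-lactation traits in dairy sheep.

`lactQTL` is for geneticists and lactation biologists working with
single-sire half-sib or backcross families — the classic design for
mapping quantitative trait loci (QTL) in livestock. It implements the
full chain from longitudinal milk records to QTL peak tables:

1. **Lactation curves.** Per ewe-by-lactation fits of the Wood model
   `W(t) = a·t^b·exp(−c·t)` (log-linear least squares refined by
   nonlinear least squares), with fixed-effect standardization and
   inverse-variance shrinkage toward population means.
2. **Derived traits.** Lactation persistency `PersY(T) = W(T)/maxY` at
   the sheep reference day `T = 100`, extended lactation
   `[CumY(300) − CumY(100)]/CumY(100)` via the exact incomplete-gamma
   integral, component yields (PY, FY, LY), somatic cell score
   `SCS = log10(SCC)`, and useful yield `UY = FY + 1.85·PY`.
3. **QTL mapping, two routes.**
   *Mixture maximum likelihood*: at each map position the trait is a
   two-component normal mixture over the transmitted sire allele
   (Awassi vs Merino), maximized by EM;
   `LOD = [logLik_max − logLik_null]/ln 10`, with printed significance
   classes (suggestive ≥ 1.75, significant ≥ 2, highly significant > 3),
   1-LOD support intervals, and effects in phenotypic SD units.
   *Half-sib regression*: position-wise F tests on
   `x = 2·P(A) − 1`, permutation chromosome-/experiment-wide
   thresholds, bootstrap position confidence intervals, QTL
   heritability `1 − RMS_full/RMS_reduced`, and an additive two-QTL
   grid search.
4. **Synthetic studies.** A generator emulating the target design — a
   single-sire (Awassi × Merino) × Merino backcross of 172 daughters,
   189 microsatellites on 26 autosomes, milk recorded every second day
   and composition weekly — so the whole pipeline is testable without
   any external data.

Transmitted-allele probabilities use Haldane's map function (Kosambi
optional) conditioned on the nearest informative flanking markers, and
every resampling step takes an explicit seed for bit-reproducibility.

## Worked example

Simulate a study with one QTL of 0.6 phenotypic SD acting on milk
persistency at 35 cM on chromosome 11, then run the pipeline:

```r
library(lactQTL)
cfg <- simConfig(seed = 11,
                 qtl = data.frame(chromosome = 11, position = 35,
                                  target = "direct", effectSD = 0.6))
out <- runPipeline(cfg, outdir = "run1", traits = "MY", step = 2,
                   nPermutations = 200, chromosomes = c(10, 11, 12))
head(out$mlePeaks[order(-out$mlePeaks$value), ])
```

```
                 trait chromosome position     value ci_lo ci_hi  effect_sd              class
        persistency_MY         11       38 3.3493811    16    62  0.6709228 highly significant
 extended_lactation_MY         11       40 3.3274279    18    62  0.6692399 highly significant
        persistency_MY         12       98 0.8574407     0   156 -0.3269458               none
 extended_lactation_MY         10      160 0.8282658     0   172  0.3675326               none
```

The planted QTL is recovered 3 cM from its true position with LOD 3.35
("highly significant"), a 1-LOD support interval of 16–62 cM, and an
estimated effect of 0.67 SD; the undisturbed chromosomes stay far below
the suggestive threshold. The same run's descriptive table gives a milk
persistency cohort mean of 0.253 (SD 0.141, n = 172) — a low value
typical of this breed cross, whose milk yield falls steeply after an
early peak. `out$regPeaks` holds the regression-route peaks with
permutation stars and QTL heritability; `out$twoQtl` (with
`twoQtl = TRUE`) the two-QTL search.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/lactqtl.R` (subcommands `simulate`, `run`, `fit-curves`,
`derive-traits`, `scan-mle`, `scan-reg`, `thresholds`, `bootstrap`,
`two-qtl`).

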