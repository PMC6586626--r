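# rtkmet

Stable-isotope tracing and regulatory-network analysis of RTK-driven
metabolic reprogramming.

Oncogenic receptor tyrosine kinases (RTKs) rewire central carbon
metabolism in genotype-specific ways: EGFR activation branches glycolysis
into the serine synthesis pathway (PHGDH → PSAT1 → PSPH) feeding
nucleotide and glutathione production, FGFR activation accelerates
aerobic glycolysis and recycles lactate into the TCA cycle, and RET
activation leans on glutamine anaplerosis. Characterising these
phenotypes — and the transcription factors (ATF4, MYC, HIF1A, ...) that
orchestrate them — takes a chain of well-defined computations that this
package implements as tested, reusable functions for metabolism
researchers and bioinformaticians:

* **MID natural-abundance correction.** For a derivatized GC-MS fragment
  with formula-defined composition, the theoretical-spectrum matrix has
  column *j* equal to the convolution of Binomial(*j*, purity) over
  labeled positions with the natural-abundance distributions of every
  remaining atom (including tBDMS/TMS silicon). The corrected mass
  isotopomer distribution (MID) solves *M x ≈ raw* by non-negative least
  squares and renormalizes; fractional enrichment is Σ *i*·M*i* / *n*.
* **Metabolite-matrix statistics.** log-Z standardization, PCA,
  average-linkage clustering with deterministic tie-breaks, the
  1.5-fold / p < 0.01 differential filter (fold change on the linear
  scale, two-tailed Student *t* on the log scale), and one-sided Fisher
  overrepresentation with Benjamini–Hochberg adjustment.
* **TF regulon enrichment and network reconstruction.** DEG calling →
  case-insensitive metabolic-gene filtering → per-regulon one-sided
  Fisher test → BH adjustment with selection at adjusted p ≤ 0.0005 →
  TF–target + PPI sub-network export (TSV/SIF).
* **Genotype co-occurrence.** 2×2 contingency tabulation from patient
  call tables, Fisher's exact test (minimum-likelihood two-sided rule),
  sample odds ratio with signed direction (co-occurrence vs mutual
  exclusivity).
* **Assay metrics.** Tumor volume (L × W²/2), relative tumor volume
  V*t*/V₀, viability and growth-inhibition percentages, growth fold
  change, and 2^−ΔΔCt relative qPCR quantification.
* **Synthetic data with planted truth.** Generators for
  genotype-specific labeling regimes, raw spectra with multiplicative
  noise, expression matrices with planted programs, TF regulon databases
  with planted enrichment, and cohorts with a tunable co-occurrence odds
  ratio — everything needed to validate the pipeline end to end, plus a
  one-call demo (`runPipeline()`).

## Worked example

Simulate an FGFR-driven cell line labeled with uniformly ¹³C-labeled
glucose, emit noisy raw spectra, correct for natural abundance, and
summarise the labeled-fraction contributions:

```r
library(rtkmet)

glc   <- defaultTracers()$glucose_u13c6
panel <- defaultFragmentPanel()

sim  <- simulateLabeling(fluxRegime("FGFR"), glc)
raw  <- emitRawSpectra(sim$mids, panel, glc, samples = 3,
                       noiseCv = 0.05, seed = 42)
corr <- correctSpectraTable(raw, panel, glc)

grouping <- setNames(rep("FGFR", 3), unique(raw$sample))
tab <- fractionContributionTable(corr$corrected, grouping)
round(tab[c("lactate:M0", "lactate:M3", "citrate:M2", "serine:M3"), , drop = FALSE], 3)
#>             FGFR
#> lactate:M0 0.152
#> lactate:M3 0.822
#> citrate:M2 0.602
#> serine:M3  0.141

round(sim$mids$lactate, 3)                 # planted truth
#> [1] 0.150 0.000 0.025 0.825
```

The corrected group means sit on the planted truth (lactate is 85%
glucose-derived M3 in the FGFR regime, spread slightly by the 99% tracer
purity; citrate M2 reports lactate recycling into the TCA cycle; serine
M3 is low because FGFR cells run little serine synthesis). Per-sample
fractional enrichment of lactate from the same run:

```r
subset(corr$enrichment, metabolite == "lactate")$enrichment
#> [1] 0.824 0.853 0.841
```

The full synthetic study — five genotypes, metabolite and expression
matrices, TF enrichment, cohort analysis — runs in seconds and reports
its own planted-truth recovery:

```r
res <- runPipeline(defaultConfig(seed = 1), "demo_out")
res$report$tf_recovery
#> $planted: 5   $selected: 5   $recovered: 5
#> $false_positives: 0   $sensitivity: 1
```

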