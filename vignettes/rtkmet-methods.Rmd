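---
title: "Methods: isotope-tracing correction and regulatory-network statistics in rtkmet"
author: "rtkmet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope-tracing correction and regulatory-network statistics in rtkmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtkmet)
```

rtkmet implements the computational core of a genotype-to-metabolism
analysis for receptor tyrosine kinase (RTK)-driven cancer models: correction
of GC-MS isotopologue spectra for natural isotope abundance, fractional
^13^C enrichment, metabolite-matrix statistics, transcription-factor (TF)
regulon enrichment with sub-network reconstruction, genotype co-occurrence
testing, and the closed-form assay formulas of cell and xenograft
pharmacology. Every stage can be exercised on synthetic data with planted
ground truth, which is how the package validates itself. This vignette
documents the models, the tunable parameters, and the design decisions.

## Natural-abundance correction of mass isotopomer distributions

A measured fragment ion contains the metabolite backbone plus
derivatization atoms (tBDMS/TMS groups contribute C, H and Si), all of
which carry naturally occurring heavy isotopes (^13^C, ^29/30^Si, ^15^N,
^17/18^O, ^2^H). The raw isotopologue intensity vector M0..Mn therefore
mixes tracer incorporation with natural abundance. rtkmet removes the
natural-abundance contribution with the standard correction-matrix
approach:

* Column $j$ of the correction matrix is the theoretical mass-shift
  spectrum of the fragment when exactly $j$ labelable positions carry
  tracer: the convolution of a Binomial($j$, purity) over the labeled
  positions, the natural-abundance distribution of the remaining
  tracer-element atoms, and the natural-abundance distribution of every
  other atom in the fragment formula (`buildCorrectionMatrix()`).
  Convolutions are exact polynomial products (`convolveDist()`,
  `elementDistribution()`), with per-element blocks computed by binary
  exponentiation.
* The corrected MID solves $M x \approx \text{raw}$ by **non-negative least
  squares** (Lawson–Hanson, via pracma) followed by renormalization to
  unit sum (`correctMid()`). NNLS rather than matrix inversion is
  essential with noisy spectra: multiplicative measurement noise routinely
  drives the inverted solution negative, and truncating negatives after
  inversion biases the remaining fractions. The roundtrip accuracy with
  and without noise is quantified in the test suite and by
  `scripts/acceptance.R`.
* Spectra extend above Mn (heavy isotopes of the many derivatization
  atoms); the probability mass falling outside the measured window is
  truncated, not redistributed, and reported per column in the
  `truncationLoss` slot so users can see when a fragment's window is too
  narrow.

Two toggles are deliberately exposed because conventions differ between
laboratories. `correctTracerElement` controls whether natural abundance of
the tracer element in *unlabeled* positions is corrected (the default,
full correction — the strictest standard convention). `purityCorrection`
controls whether tracer impurity is deconvolved by the matrix. In the
package's own forward model the tracer purity is part of the *true* MID
(a labeled pool spreads as Binomial($k$, purity)), so `emitRawSpectra()`
convolves with natural abundance only and the roundtrip inverse is
`purityCorrection = FALSE`; switching it on additionally collapses the
impurity spread onto the nominal labeled state. Derivatization atoms must
be part of the user-supplied fragment formula: tBDMS/TMS chemistry changes
the composition per fragment, and guessing adducts silently is more
dangerous than requiring the formula.

Fractional enrichment is $\sum_i i \cdot M_i / n$, the average labeled
fraction of the $n$ labelable positions — 0 for an unlabeled pool, 1 for a
fully labeled one — and is invariant to uniform intensity scaling because
correction operates on the normalized spectrum.

The shipped abundance table (`naturalAbundances()`) uses representative
terrestrial isotopic abundances for C, H, N, O, Si, S and P and is fully
overridable, which the tests exploit (zero-abundance override ⇒ identity
matrix).

## The synthetic labeling model

The generator is intentionally **not** a kinetic flux model. The
experimental readouts it must reproduce are steady-state
fraction-contribution summaries, and those are captured exactly and
transparently by a two-component mixture per metabolite: a fraction $f$
of the pool sits in a defined labeled state (e.g. lactate M3 under
uniformly ^13^C-labeled glucose) and $1 - f$ is unlabeled, with tracer
impurity spreading the labeled state binomially. The genotype presets in
`fluxRegime()` encode the qualitative biology of the isogenic BAF3-RTK
panel: EGFR activation branches glycolysis into the serine synthesis
pathway (high `sspFraction`), FGFR activation maximises glycolytic lactate
and recycles it into the TCA cycle (high `glycolyticLactateFraction` and
`tcaFromLactateFraction`), RET relies on glutamine anaplerosis (high
`glutamineTcaFraction`), and MET/parental cells are moderate throughout.
The preset numbers (e.g. EGFR `sspFraction` 0.60 vs FGFR 0.15) were chosen
once as plausible steady-state fractions producing clear but not saturated
contrasts; they are the package's standing study conditions, not fitting
targets.

Purine nucleosides get a dedicated rule: the C10 skeleton is the
convolution of independently labeled moieties — ribose (M5 from glucose
via the pentose phosphate pathway, glucose-derived fraction fixed at 0.9),
glycine (M2) and two formate one-carbon units (M1 each) both tied to
`sspFraction`, plus one CO~2~-derived carbon treated as unlabeled. High
serine-pathway flux therefore populates the M6–M9 isotopologues, the
signature of glycine/formate carbon entering purines.

Labeling is treated as at steady state: the tracer-time dependence of a
real experiment (12 h vs 24 h labeling) is not modeled, and the branch
fractions are exposed directly instead.

`emitRawSpectra()` is the forward measurement model: theoretical spectrum
matrix × true MID, a per-sample total-intensity factor (uniform in
0.5–1.5 × 10^6^ ion counts), and multiplicative Gaussian noise of
coefficient of variation `noiseCv` truncated at zero — the truncation
deliberately creates the regime in which naive matrix inversion fails and
NNLS is required. What the generator does **not** emulate: chromatographic
peak shapes, detector saturation, correlated channel noise, and
metabolite-specific ionization efficiencies. Passing the roundtrip tests
therefore demonstrates correctness of the correction algebra and solver,
not robustness to every artifact of real chromatograms.

## Metabolite-matrix statistics

`logZscore()` log-transforms (pseudocount default: half the smallest
non-zero intensity, keeping zeros finite without dwarfing real signal) and
row-standardizes, dropping zero-variance features with a warning.
`pcaScores()` is plain SVD of the feature-centered sample matrix.
`hierarchicalCluster()` defaults to Euclidean average linkage (UPGMA); the
clustering metric for such heatmaps is rarely stated in publications, so
both are configurable. Items are sorted by identifier before
agglomeration so equal-height merges resolve to the lexicographically
smallest pair — a cheap way to make leaf order identical across platforms
and input orderings.

`differentialFeatures()` implements the classical altered-feature filter:
fold change computed on the **linear** intensity scale (so the 1.5× cutoff
means what a reader expects), p-value from a two-tailed two-sample
*t*-test on the log scale, pass = (FC ≥ 1.5 or ≤ 1/1.5) and p < 0.01. The
default test is the pooled-variance Student *t*. With n = 3 per group —
the replicate structure throughout this field — Welch's Satterthwaite
degrees of freedom are noticeably conservative, which breaks the nominal
type-I behavior the null-calibration tests demand, and the pooled test is
exact under the exchangeable-null, equal-variance model the generator
implements. Welch remains available via `varEqual = FALSE` for unequal
variance settings. Features with a zero control mean get an infinite fold
change and pass on the p-value alone, with a warning.

`oraFisher()` is one-sided (enrichment) overrepresentation: the
hypergeometric tail, identical to Fisher's exact test with
`alternative = "greater"`, with Benjamini–Hochberg adjustment across
tested sets. One-sided is the right sidedness because only enriched
pathways are reported in this kind of analysis.

## TF regulon enrichment and network reconstruction

The DEG-to-TF procedure is: call DEGs (1.5-fold, p < 0.01) → intersect
with a metabolic-gene universe (case-insensitively; mouse-style `Psph` and
human-style `PSPH` must match, so all identifiers are upper-cased) → test
every TF's regulon by one-sided Fisher → BH-adjust → select TFs with
adjusted p ≤ 0.0005. Up- and down-regulated DEGs are pooled by default;
restricting to up-regulated genes is a caller-side choice (pass
`degs$up`). The enrichment universe defaults to the measured genes
intersected with the metabolic annotation — the most conservative choice,
since genes that could never be called differential should not inflate
the background.

`buildSubnetwork()` assembles the directed TF→target edges (restricted to
the supplied target set) and undirected PPI edges among the included
targets, merging multi-source edges with a union of provenance tags. PPI
edges are stored with lexicographically sorted endpoints, which makes
deduplication orientation-independent and output deterministic. Export is
TSV and SIF; layout and rendering belong to dedicated viewers.

The synthetic regulon database plants TFs whose regulons draw 80% of
their members from the true differential set. Regulon size defaults to
~2.6% of the gene universe (15 targets for the 500-gene metabolic
universe in the standard fixture), matching the density of large public
TF-target compilations (order 10^6^ interactions for ~2,000 TFs over a
~20,000-gene genome); substantially denser regulons would make background
TFs collide with the differential set far more often than real databases
do.

## Genotype co-occurrence

Co-occurrence of two binary genotype events is tested on the 2×2 table
with Fisher's exact test; the two-sided p-value uses the
minimum-likelihood summation rule (every margin-fixed table with point
probability ≤ the observed is summed), the most common convention and the
one the enumeration oracle in the test suite reproduces exactly. The
reported effect is the sample cross-product odds ratio, with a
0.5-continuity value additionally reported (and flagged) when a zero cell
makes the plain ratio 0 or undefined. Direction is read off the odds
ratio: > 1 co-occurrence, < 1 mutual exclusivity — one signed statistic
rather than two separate tests.

The cohort generator draws from the joint Bernoulli distribution with
specified margins and odds ratio by solving the Plackett quadratic for
the both-events cell probability. For any finite log-odds the solution
exists inside the Fréchet bounds (extreme odds clamp to a bound), so the
generator rejects only genuinely malformed inputs (prevalence outside
[0, 1], non-finite log-odds).

One caution for users reading published co-occurrence percentages: a
printed rate and its printed numerator/denominator can disagree, and the
full 2×2 behind a quoted p-value is often not recoverable.
`cooccurrenceRate()` therefore returns the arithmetic ratio of whatever
table it is given, with an explicit choice of denominator (event-A
carriers or the whole cohort), and makes no attempt to guess unstated
denominators.

## Assay metrics

Closed-form formulas, implemented exactly as conventionally defined:
caliper tumor volume $L \times W^2 / 2$ (mm³; the larger measurement is
taken as length, swapped inputs are re-ordered with a warning), relative
tumor volume $V_t / V_0$, viability $(OD_t/OD_c) \times 100\%$, growth
inhibition $(1 - OD_t/OD_c) \times 100\%$ (negative values = stimulation,
passed through), growth fold change $N_t/N_0$, and relative qPCR
quantification $2^{-\Delta\Delta Ct}$ with replicate Ct values averaged
arithmetically before normalization. Viability and inhibition are exact
complements; $2^{-\Delta\Delta Ct}$ is invariant to adding a constant to
all four Ct values.

## The demo pipeline and reproducibility

`runPipeline()` chains simulate → correct → metabolite statistics → TF
network → co-occurrence under one configuration (`defaultConfig()`, YAML
round-trippable, validated before any stage runs). Every tabular output
carries a single `#` header line with the package version, a
configuration hash and the seed; no timestamps are written, so a re-run
with identical configuration is byte-identical, which the manifest's MD5
sums verify. Seeds are mandatory in the configuration — there is no
wall-clock seeding anywhere in the package. The run's JSON report states
the planted-truth recovery the run itself computed (MID recovery error,
altered-metabolite and TF recovery, cohort odds ratio and p-value).

Default problem sizes — 120 metabolites, 2,000 genes with a 500-gene
metabolic universe, 200 background TFs (1,000 in the recovery fixture),
cohorts of 400–1,000 patients, triplicate samples — were chosen as
representative desk-scale versions of a real study that keep any single
validation run in seconds.

## Known limitations

* The labeling model is a steady-state mixture; it cannot represent
  kinetic phenomena (isotopic non-stationarity, reversible exchange
  fluxes) and its branch fractions are phenomenological, not fitted
  fluxes.
* The correction assumes unit mass resolution; resolution-dependent
  separation of isobaric fine structure (e.g. ^13^C vs ^15^N shifts at
  high resolving power) is out of scope.
* Fold-change/t-test differential calling with n = 3 has limited power
  and no variance moderation; the planted-truth recoveries in the tests
  hold at the generator's noise level (log2 SD 0.25) and are not claims
  about weaker effects.
* The TF enrichment inherits every limitation of overrepresentation
  analysis: it ignores regulon edge weights, directionality of
  regulation, and correlation between regulons.
* The co-occurrence module tests one event pair at a time; multi-event
  mutual-exclusivity models with sample-weight permutation are not
  implemented.
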