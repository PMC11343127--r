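---
title: "Inferring synthesis- versus degradation-driven proteome change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring synthesis- versus degradation-driven proteome change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoturn)
```

## The kinetic model and its assumptions

`proteoturn` models each protein pool with zero-order synthesis and
first-order degradation,

$$\frac{d[P]}{dt} = k_{syn} - k_{deg}\,[P],$$

and assumes *proteostasis*: the regulating processes are in dynamic
equilibrium over the measurement window, so the rates are constant and
$[P] = k_{syn}/k_{deg}$. The assumptions worth keeping in view are:

* **Steady state.** Synthesis and degradation are exactly balanced;
  the turnover rate is then simultaneously the degradation rate
  constant and the per-molar synthesis rate $k_{syn}/[P]$.
* **Well-mixed, unregulated degradation.** Proteins are degraded at
  random, with no separately-degraded aggregate pool, no subunit
  exchange in complexes, and negligible import/export. These are known
  to fail for parts of any real proteome; the model is a deliberate,
  identifiable simplification.
* **Instantaneous, complete precursor labeling.** After heavy water is
  introduced at $t = 0$, newly made protein is labeled; the unlabeled
  pool decays as $[P](t) = (k_{syn}/k_{deg})e^{-k_{deg}t}$ while the
  labeled pool accumulates as its complement, keeping the total
  constant. The measurable *fraction new* is
  $1 - e^{-k_{deg} t}$ with asymptote fixed at 1 — appropriate for
  proteins, not for lipids with multiple precursor pools, which are
  out of scope.

Abundance alone identifies only the ratio $k_{syn}/k_{deg}$. The sign
pair of the two between-genotype contrasts — Δabundance (scaled log2
LFQ fold change) and Δturnover (scaled log2 fitted-rate difference) —
identifies the dominant driver: $(+,+)$ synthesis up, $(-,-)$
synthesis down, $(-,+)$ degradation up, $(+,-)$ degradation down. An
exact zero in either coordinate is classified `Indeterminate`: a zero
carries no direction, and under continuous noise it occurs with
probability zero, so the convention only matters for degenerate
fixtures.

## Parameters that matter

All cutoffs are configuration defaults (`validate_config()`), never
hard-coded downstream.

| Parameter | Default | Units / domain | Role |
|---|---|---|---|
| `enrichment` | 0.05 | fraction | body-water deuterium enrichment entering the M0-change filter |
| `min_n_value` | 5 (exclusive) | count | minimum deuterium-accessible positions per peptide |
| `min_peptide_length` | 6 | residues | minimum sequence length |
| `min_m0_change` | 0.04 | fraction | minimum theoretical monoisotopic-peak depletion |
| `rsq_min` | 0.6 | — | minimum fit R² |
| `min_unique_peptides` | 2 | count | peptides required per protein fit |
| `min_nonzero_timepoints` | 3 | count | distinct times with positive fraction-new |
| `max_rms_deviation` | 0.1 | fraction-new units | maximum RMS residual of the fit |
| `max_missing_per_genotype` | 1 | count | LFQ missingness tolerance |
| `f_test_alpha` | 0.05 | — | two-tailed variance-gate level |
| `min_coverage` | 0.25 | fraction | ontology observed/background floor |
| `bh_alpha` | 0.05 | — | significance on BH-adjusted p |
| `redundancy_overlap` | 0.75 | fraction | member overlap defining "highly similar" terms |

Three of these deserve comment. The **n-value rule is exclusive**
(`> 5`): n-values are fractional sums of empirical per-residue
deuterium accessibilities (`deuterium_site_counts`), so "greater than
5" and "at least 6" differ. The **M0-change filter** uses the
binomial-site closed form $1 - (1 - p)^n$ at enrichment $p$: with
every accessible site independently labeled at $p$, this is the
maximal relative depletion of the monoisotopic peak; at $p = 0.05$ it
is weaker than the n-value rule and only binds at lower enrichments.
The **measurement-deviation gate** is defined here as the RMS residual
of the fitted curve; "deviation" admits several readings (per-peptide
spread, per-timepoint spread), and the RMS residual was chosen because
it is the quantity the least-squares fit actually controls.

A fourth choice is statistical: the ontology stage both adjusts
p-values by Benjamini–Hochberg and calls significance at adjusted
p < 0.05. A looser FDR target (e.g. 0.25) can be explored by raising
`bh_alpha`; the two knobs are deliberately the same dial.

## The rate fit

All retained peptides of a protein are pooled into one point cloud and
a single rate is fitted by least squares over $k \in (10^{-6}, 20]$
day⁻¹ — pooling matches the "combined" peptide evidence the gates
refer to, and is stable when peptides cover different timepoints.
(Per-peptide fitting is available by grouping the input accordingly.)
The SSE is minimized on the $\log_{10} k$ scale, where it is smooth
and unimodal in practice: a 121-point grid scan brackets the minimum
and golden-section refinement (`stats::optimize`, tolerance $10^{-12}$)
finishes it, recovering noiseless rates to better than $10^{-7}$
relative. A minimum pinned in the first grid cell above the lower
bound is reported as a zero rate: such data carry no turnover signal,
and the remaining diagnostics (R², RMS, timepoint counts) are
meaningless without a curve, so `nonpositive_rate` is then the sole
rejection reason. R² is the conventional $1 - SS_{res}/SS_{tot}$
around the data mean.

## The abundance workflow

The stage order is fixed: missingness filter → log2 → per-sample mean
centering → slope normalization → imputation → tests and fold changes
→ cross-dataset averaging → range scaling. Centering removes
per-sample location (loading/injection) effects; slope normalization
divides each sample by the OLS slope of its values against the
per-protein mean profile, equalizing distribution widths. The
regression keeps an intercept — on centered data it is ≈ 0, and
retaining it makes the slope robust to residual centering error.
Imputation runs after normalization so distances are computed on
comparable values: each missing cell takes the mean of that sample's
values in the 2 nearest proteins, under a missing-aware Euclidean
distance rescaled by the fraction of co-observed samples, with donors
required to be observed in the target sample. Neighbors are proteins,
not samples — with four replicates per genotype, protein space is far
better populated. The F-test gate is two-tailed at α = 0.05 and routes
to a pooled or Welch t-test; protein p-values are reported but do not
gate ontology aggregation. Abundance fold changes are differences of
normalized log2 means, so the no-change null sits at 0.

Two scalings standardize fold changes before ontology work: range
scaling $(x - \bar{x})/(x_{max} - x_{min})$ for abundance — sensitive
to the dataset's full dynamic range — and auto scaling
$(x - \bar{x})/s$ (sample sd) for turnover, which damps the heavier
tails of rate estimates. Both center proteome-wide, which is why a
pseudo-ontology equal to the entire proteome must come out
non-significant (a property the tests assert).

## What the synthetic generator emulates — and what it does not

`synth_config()` defaults encode the study design this package
models: six labeling timepoints (0, 0.25, 1, 4, 16, 32 days; hour 6
encoded as 0.25 d), four LFQ replicates per genotype, 50 ontologies ×
20 proteins cycling through the five regulation classes, effect size
0.5 log2, fraction-new noise sd 0.03, LFQ noise 0.25 log2, per-sample
scale effects 0.5 log2, and 5% completely-at-random missingness. The
noise magnitudes and missing rate are package choices (no published
values exist for them); they sit in the realistic range for
brain-tissue LFQ and in vivo labeling data and are surfaced in the
config rather than buried.

Control kinetics are drawn with $k_{deg}$ log-uniform on 0.01–2 day⁻¹
(half-lives of ~8 hours to ~10 weeks) and lognormal steady-state
abundances (log2 mean 20, sd 2). Regulation classes act on the rates:
degradation classes move $k_{deg}$ alone by $\pm e$ log2, which moves
abundance by $\mp e$; synthesis classes move $k_{syn}$ by $\pm 2e$
with $k_{deg}$ following at $\pm e$, so abundance and turnover both
move by $\pm e$ with the class's characteristic sign pair. The
asymmetry is forced by the physics: the labeling curve measures only
$k_{deg}$, so a synthesis change with degradation held fixed would be
invisible on the turnover axis — a synthesis-*driven* shift is one
whose synthesis change outpaces its degradation change.

Peptides are uniform random sequences of length 6–30 over the 20
standard residues, so n-values straddle the `> 5` filter and every
peptide gate is exercised. Missingness is completely at random; real
LFQ missingness is intensity-dependent, so passing tests here do not
certify behavior under left-censored missingness. Likewise the
generator gives every protein a fittable labeling course, so the
synthetic turnover set is not the "smaller subset" it is in real
data, where signal-to-noise failures thin the rate fits; body-water
enrichment dynamics, isotope envelopes, and chromatography are not
simulated at all — enrichment enters only through the M0-change
filter.

## Numerical choices and degenerate inputs

* Fraction-new noise is additive Gaussian truncated to $[0, 1]$,
  matching the fit's least-squares assumption while keeping values
  physical; truncation introduces a small upward bias at early
  timepoints for slow proteins, visible as a few-percent median error
  in the noisy-recovery checks.
* Scaling functions raise on constant input (zero range or sd);
  ontology t-tests on fewer than two members or zero spread are
  flagged untestable rather than errored, and untestable terms are
  excluded from the BH family.
* Redundancy clustering joins significant terms transitively at
  member overlap ≥ 0.75 of the smaller set (the threshold is a package
  choice), keeps the term with the most quantified proteins, and
  breaks ties lexicographically for determinism.
* Overlap heatmaps are row-normalized
  ($100\,|A \cap B|/|A|$, asymmetric) by default; `normalize = "min"`
  gives the symmetric variant.
* Benjamini–Hochberg adjustment wraps `stats::p.adjust`; the test
  suite validates it against a brute-force step-up implementation on
  a thousand random p-vectors.

## Validation scale

The packaged checks run the default synthetic study (1,000 proteins,
2,000 protein×cohort fits, 50 ontologies), 200-protein noisy rate
recovery, and 10,000 null-protein test simulations — sizes chosen so
the full suite exercises every stage at meaningful power while
completing in about a minute. On these conditions the pipeline
recovers the injected quadrant class for ≥ 90% of significant
regulated ontologies and flags unregulated ontologies at no more than
the nominal rate.

## Known limitations

Beyond the modeling assumptions above: protein-group inference is not
reproduced (a precomputed `is_top_protein` flag is honored instead);
StringDB is never queried — only its export format is read, and its
own enrichment FDR column is ignored; GO graph structure is not used,
so redundancy is resolved by member overlap, not ontology ancestry;
and the analytic forms for turnover as the mean of per-molar synthesis
and degradation changes are exposed as model documentation, while the
pipeline reports what the data identify — fitted-rate fold changes.
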