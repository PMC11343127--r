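# proteoturn

Is a proteome-wide change in protein abundance driven by altered
**synthesis** or altered **degradation**? A single label-free
quantification (LFQ) experiment cannot say: the steady-state
concentration of a protein under first-order turnover is

```
[P] = ksyn / kdeg
```

so a higher abundance is equally consistent with more synthesis or less
degradation. Adding a deuterated-water (D2O) metabolic-labeling time
course resolves the ambiguity. After label introduction at `t = 0`, the
pre-existing pool decays and the newly synthesized (labeled) pool
accumulates, while their sum stays constant in homeostasis; the
measurable *fraction new* follows

```
P_D / (P + P_D) = 1 - exp(-k t)
```

where `k` is the turnover rate — in homeostasis equal to both the
degradation rate constant and the per-molar synthesis rate. The sign
pair of the two contrasts between an experimental genotype and its
control,

* **Δabundance** — scaled log2 fold change of LFQ areas, and
* **Δturnover** — scaled difference of log2 fitted turnover rates,

places each protein or ontology in a regulation quadrant: `(+, +)`
synthesis up, `(-, -)` synthesis down, `(-, +)` degradation up,
`(+, -)` degradation down.

`proteoturn` implements this inference end to end for R users working
with tabular proteomics exports:

* **Turnover kinetics** — peptide quality filters (n-value > 5, length
  ≥ 6, theoretical M0 change ≥ 0.04), pooled nonlinear least-squares
  fitting of `1 - exp(-k t)` per protein and cohort, fit gates
  (R² ≥ 0.6, > 1 unique peptide, rate > 0, ≥ 3 nonzero timepoints, RMS
  deviation < 0.1), log2 fold changes, auto scaling.
* **LFQ abundance** — per-genotype missingness filter, log2 transform,
  per-sample mean centering, slope normalization against the mean
  profile, two-nearest-neighbor imputation, variance-gated
  (F-test-routed) two-sample t-tests, cross-dataset averaging, range
  scaling.
* **Ontology synthesis** — StringDB multiprotein-export ingest, source
  whitelist and ≥ 25% coverage filter, member-mean fold changes,
  one-sample t-tests against zero, Benjamini–Hochberg adjustment,
  redundancy resolution, overlap heatmaps.
* **Synthetic data** — a seeded generator with known ground-truth
  kinetics and injected ontology-level regulation, used to validate the
  whole pipeline by quadrant-recovery scoring.

Everything takes and returns tibbles, chains with the pipe, and carries
broom-style `tidy()` / `glance()` methods plus ggplot2 `plot_*()` /
`autoplot()` functions.

## Worked example

A fully synthetic study: 1,000 proteins in 50 ontologies (10 each of
synthesis-up, synthesis-down, degradation-up, degradation-down, and
unregulated), a six-timepoint labeling design (day 0, hour 6, days 1,
4, 16, 32), four LFQ replicates per genotype, and a half-log2
regulation effect.

```r
library(proteoturn)
run <- run_pipeline(list(seed = 42))
run
#> <proteostasis_run>
#>   seed: 42  mode: simulate
#>   fits: 2000 ( 2000 passed )
#>   fold changes: 974 abundance / 1000 turnover
#>   ontology terms: 50 ( 40 significant )
#>   quadrant accuracy (significant non-Null): 1
```

All 40 regulated ontologies are recovered as significant and each lands
in its true quadrant; the unregulated ontologies are not called. The
top of the tidied ontology table:

```r
library(dplyr)
tidy(run) |>
  filter(significant) |>
  arrange(bh_adjusted_p) |>
  select(term_id, n_abundance, mean_abundance_fc, mean_turnover_fc,
         bh_adjusted_p, regulation_class) |>
  head(3)
#> # A tibble: 3 × 6
#>   term_id n_abundance mean_abundance_fc mean_turnover_fc bh_adjusted_p regulation_class
#>   <chr>         <int>             <dbl>            <dbl>         <dbl> <fct>
#> 1 T042             20            -0.217            -1.09      3.72e-11 SynDown
#> 2 T012             20            -0.251            -1.06      8.34e-11 SynDown
#> 3 T046             19             0.258             1.11      8.34e-11 SynUp
```

Here `mean_abundance_fc` and `mean_turnover_fc` are the ontology means
of the range-scaled abundance and auto-scaled turnover fold changes; a
term like T042 with both strongly negative is called synthesis-down.
`autoplot(run)` draws the quadrant-annotated proteostasis scatter;
`plot_ontology_bars()` and `plot_overlap_heatmap()` render the
per-ontology member bars and the percent-shared-protein heatmap.

To analyze your own exports, pass `mode = "real"` with
`paths = list(areas = ..., sample_info = ..., time_courses = ...,
ontology = ...)` — a protein-area CSV, a sample-to-genotype TSV, a long
peptide fraction-new TSV, and a StringDB multiprotein enrichment
export. `emit_fixture_files()` documents each dialect by example.

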