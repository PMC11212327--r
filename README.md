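# pscpipe

A tested, reusable R implementation of a multiomics analysis workflow for
pulmonary sarcomatoid carcinoma (PSC), a rare non-small-cell lung cancer
subtype. The pipeline covers five analysis stages plus a synthetic-data
module:

1. **Consensus variant filtering** — merge three callers' VCFs on
   normalized variant identity; retain mutations that pass a 2-of-3
   consensus with both strand-specific VAFs > 5% (F1) or a hotspot rescue
   on external evidence (F2); subtract pooled-normal artifacts; report
   tumor mutational burden.
2. **Driver curation** — rule-based classification of retained mutations
   against a cancer-gene role table, gene × tumor mutation matrix,
   Fisher-exact mutual exclusivity, driver–outcome association.
3. **Clonal evolution** — cancer cell fractions from VAFs and purity,
   1-D Gaussian-mixture clustering with BIC, constraint-based clonal tree,
   branched/linear classification, trunk mapping, convergent-evolution
   detection.
4. **Transcriptomic subtyping** — TMM normalization, consensus NMF with
   cophenetic rank selection, SAM permutation gene ranking, single-sample
   immune/stromal scoring, IM-H/IM-L labeling, nearest-centroid projection
   onto external cohorts.
5. **Outcome analysis** — Kaplan–Meier, log-rank, univariate and
   covariate-adjusted Cox models for the subtype–survival association.

Because no patient-level data are deposited for this tumor type's
reference cohort, `simulate_cohort()` generates complete cohorts (caller
VCFs, pooled normal, annotations, counts, gene sets, clinical table) with
serialized ground truth, so everything is testable offline. See the
`methods` vignette (`vignettes/methods.Rmd`) for models, parameter
rationale, and limitations.

## Worked example

Simulate a study-sized cohort (21 tumors, ~285 true somatic mutations each
over a 50 Mb target, a 17-sample two-subtype expression cohort, survival
with a planted hazard ratio of 10 against the immune-low group) and run the
full pipeline:

```r
library(pscpipe)

cfg <- cohort_config(seed = 1)          # study-scale defaults
dir <- file.path(tempdir(), "cohort")
simulate_cohort(cfg, out_dir = dir)

res <- run_pipeline(dir, out_dir = file.path(tempdir(), "results"), seed = 2)
res$summary
```

Actual output of this run (also produced by
`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`):

```json
{
  "n_tumors": 21,
  "n_retained_mutations": 5167,
  "mean_tmb": 4.92095238095238,
  "n_driver_calls": 16,
  "tp53_prevalence": 0.619047619047619,
  "kras_prevalence": 0.142857142857143,
  "met_prevalence": 0,
  "branched_fraction": 0.19047619047619,
  "chosen_nmf_rank": 4,
  "cophenetic_rank2": 0.859135703700519,
  "n_sam_significant": 217,
  "n_imh": 10,
  "subtype_ari_vs_truth": 1,
  "logrank_p_rfs": 0.00034927466414065,
  "hr_rfs_iml": 18.6114094157227,
  "logrank_p_os": 0.345177489403388,
  "hr_os_iml": 1.7636190855133
}
```

Reading this honestly: mean TMB is ≈ 4.9/Mb against ≈ 5.7 planted (caller
sensitivity < 1 loses true mutations); TP53/KRAS prevalences bracket their
planted 57%/28% rates at n = 21, and this seed planted no MET-mutant tumor
(14% prevalence under mutual exclusivity with TP53/KRAS), so none could be
called; the two expression subtypes are recovered exactly (adjusted Rand
index 1 vs planted labels, 10/17 IM-H) and immune-low carries a large
recurrence hazard (RFS log-rank p ≈ 3.5e-4, HR ≈ 18.6 — overshooting the
planted 10, as expected at 17 samples near separation), while the planted
weaker overall-survival effect is not significant at this cohort size.
Two quantities illustrate documented small-sample behavior rather than
recovery: at the default 30 NMF restarts the cophenetic rank choice is
noisy (rank 4 here; the two-subtype labels still come from the rank-2
solution), and the branched fraction (0.19 vs 0.5 planted) reflects that
one-sample CCF data only identify branching when sibling CCF sums exceed
the linear-chain bound — both are analyzed in the vignette.

Per-stage outputs (consensus variants, drivers, clonal trees, subtypes,
SAM ranking, centroids, survival summaries) are written as TSV/JSON to the
output directory. A thin shell wrapper is installed at
`inst/scripts/run_pipeline.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/run_pipeline.R", package = "pscpipe"))')" \
  --cohort /path/to/cohort --out /path/to/results --seed 2
```

## Reproducing results

All generators and analysis stages are deterministic given their seeds:
the same configuration produces byte-identical files across runs (this is
itself an acceptance-tested property). `scripts/acceptance.R --seed <int>
--out <path>` regenerates the cohort for any seed and reports the headline
quantities as bare JSON numbers.
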