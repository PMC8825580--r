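# episcore

Tidyverse-native tools for the computational core of histone-mark
ChIP-seq profiling of tumour cell panels: peak annotation,
super-enhancer calling, bivalent repressive-promoter discovery,
maxstat/Cox survival risk scores with cross-cohort transfer, and
differential binding between phenotype groups — plus seeded
synthetic-data generators with planted ground truth that make the whole
pipeline testable end to end.

## Who this is for

Computational biologists who have per-sample peak calls (BED), coverage
tracks (bedGraph-like), expression matrices and survival tables for a
panel of samples (e.g. cancer cell lines plus a patient cohort) and want
the downstream analyses that connect chromatin state to phenotype:
which features the peaks occupy, where the super-enhancers are and which
active genes they drive, which promoters carry both H3K9me3 and
H3K27me3, which genes carry prognostic information, and which regions
differ between drug-resistant and drug-sensitive groups.

## The core statistics

* **Super-enhancers** (ROSE-style): peaks outside TSS ± 2.5 kb exclusion
  zones are stitched at gaps ≤ 12.5 kb; domains are ranked by
  background-subtracted signal and the rank curve, rescaled to the unit
  square, is cut at its discrete inflection; active genes within 50 kb
  are attached.
* **Maximally selected rank statistics**: for gene expression *x* the
  cutpoint μ maximizes the standardized log-rank statistic of the split
  {x ≤ μ} vs {x > μ} over observed values in the 0.1–0.9 quantile
  window, with the Lausen–Schumacher selection-adjusted p-value (or a
  seeded permutation p).
* **Risk score**: per-gene Cox beta β_g on the maxstat dichotomy; a
  patient scores Σ_g β_g·w_g with w_g = ±1 for expression above/below
  the gene cutpoint; the score itself is split by maxstat into
  high/low-risk groups, and the model transfers to a validation cohort
  by quantile-matched cutpoints with betas and score cutoff copied
  verbatim.
* **Differential binding**: consensus regions (≥ min_overlap samples),
  coverage counts, and a variance-floored Welch t on log2 CPM with
  Benjamini–Hochberg FDR.

## Worked example

A complete synthetic run — enhancer landscape to transferred risk model:

```r
library(episcore)

cfg <- sim_config(seed = 42)
gen <- make_genome(cfg)

## super-enhancers from a planted landscape
land     <- make_enhancer_landscape(cfg, gen)
stitched <- stitch_enhancers(land$peaks, tss_exclusion_zones(gen$genes, 2500))
ranking  <- se_ranking(score_enhancers(stitched, land$coverage))
ranking
#> Super-enhancer ranking: 1000 enhancers, 50 super | signal cutoff: 84.21

## a training cohort with 10 planted prognostic genes
expr   <- make_expression(cfg, gene_ids = paste0("g", 1:200),
                          sample_ids = sprintf("P%04d", 1:600))
cohort <- make_survival_cohort(cfg, expr$expr)
cohort$cohort
#> Survival cohort: 600 patients, 200 genes, 232 events

genes <- select_prognostic(cohort$cohort, rownames(expr$expr),
                           fdr = 0.05, direction = "any")
dplyr::select(genes, gene_id, beta, cutpoint, prop_above, q_value)
#> # A tibble: 8 x 5
#>   gene_id  beta cutpoint prop_above  q_value
#> 1 g6      0.789     26.4      0.517 0.000118
#> 2 g17     0.674     73.8      0.617 0.00806
#> 3 g41     0.618    142.       0.348 0.0105
#> # 5 more rows

model  <- risk_model(genes)
scores <- score_patients(cohort$cohort$expression, model)
split  <- fit_score_cutoff(scores, cohort$cohort)
split
#> Score split at 0.4691 | high: 266 low: 334 | log-rank p = 1.36e-35

## transfer to an independent cohort: cutpoints by quantile matching,
## betas and score cutoff copied unchanged
valid <- make_expression(sim_config(seed = 43),
                         gene_ids = paste0("g", 1:200),
                         sample_ids = sprintf("V%03d", 1:100))
vscores <- score_patients(valid$expr, transfer_model(model, valid$expr))
mean(vscores$score > split$score_cutoff)
#> [1] 0.45
```

Reading the output: the rank-curve cutoff isolates exactly the 50
planted super-enhancers; the prognostic screen keeps 8 genes at
BH ≤ 0.05 (all with positive beta — high expression is adverse); the
score splits the 600 patients into 266 high-risk vs 334 low-risk with a
log-rank p of ~10⁻³⁵; and the transferred model puts 45% of the
validation cohort in the high-risk group, close to the training
fraction (44%). Each fitted object has `tidy()`, `glance()` and
`autoplot()` methods (`autoplot(ranking)` draws the hockey-stick,
`autoplot(split)` the Kaplan–Meier curves).

The methods vignette (`vignettes/epigenetic-risk-scores.Rmd`) documents
the models, parameter conventions, the synthetic-data design and its
limitations.

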