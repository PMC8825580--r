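---
title: "From histone-mark peaks to prognostic risk scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From histone-mark peaks to prognostic risk scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcore)
```

# The analysis this package implements

Chromatin immunoprecipitation sequencing (ChIP-seq) of histone
post-translational modifications characterizes the regulatory state of a
tumour cell panel: H3K4me1 and H3K27ac mark enhancers, H3K4me3 active
promoters, H3K36me3 transcribed gene bodies, and H3K9me3/H3K27me3
heterochromatic and Polycomb-repressed chromatin. `episcore` implements
the downstream computational chain that turns per-sample peak calls and
coverage tracks into biological and clinical read-outs:

1. **Peak annotation** — assigning each peak to a genomic feature
   (promoter, UTRs, exon, intron, downstream, distal intergenic) and
   profiling signal around transcription start sites (TSS).
2. **Super-enhancer (SE) identification** — stitching enhancer peaks into
   domains, ranking them by background-subtracted signal and cutting the
   rank curve at its inflection; active genes are attached by proximity.
3. **Repressive-domain discovery** — promoters carrying both H3K9me3 and
   H3K27me3, and their recurrence across the panel.
4. **Prognostic risk scores** — for a candidate gene set (SE-associated
   or repressed), per-gene survival cutpoints by maximally selected rank
   statistics, Cox log-hazard ratios on the dichotomies, and a per-patient
   score that transfers to independent cohorts.
5. **Differential binding** — consensus regions and a moderated per-region
   contrast between phenotype groups (e.g. drug-resistant vs -sensitive),
   controlled by the Benjamini–Hochberg false discovery rate.
6. **Synthetic data** — seeded generators that emulate each input with
   planted ground truth, so the full pipeline is testable end to end.

Peak calling, read alignment, and RNA-seq quantification are out of
scope: the package consumes BED peaks, bedGraph-like coverage, expression
matrices and survival tables.

# Interval conventions

All intervals are 0-based half-open (the BED dialect) in tibbles with
`chrom`/`start`/`end` columns; GenomicRanges performs the set arithmetic
behind this surface. Sets are *normalized* — sorted by (chrom, start,
end, name) with exact duplicates removed — before set-level operations.
Chromosome names are compared as exact strings.

Peak-to-feature assignment is decided at the **peak midpoint** with the
priority promoter > 5'UTR > 3'UTR > exon > intron > downstream > distal
intergenic. The promoter window defaults to TSS −3000/+3000 bp
(strand-aware), the downstream window to 3000 bp past the transcript end;
both are arguments everywhere they are consumed, because annotation tools
differ in these defaults and the choice visibly moves the promoter and
distal fractions. When no exon table is supplied a transcript is treated
as a single exon; intron calls therefore require exon structure.

# Super-enhancer identification

Stitching follows the rank-ordering approach for super-enhancers: peaks
fully contained in a TSS ± 2500 bp exclusion zone are removed (promoter
signal must not nucleate an enhancer domain; straddling peaks are kept
intact), and remaining same-chromosome peaks at gaps ≤ 12 500 bp merge
transitively. Domain signal is the coverage sum over the region,
optionally input-subtracted and clipped at zero.

**The cutoff rule.** Signals are sorted ascending and both ranks and
signals rescaled to [0, 1], giving the familiar hockey-stick whose average
slope is exactly 1. The super-enhancer boundary is placed at the
*discrete inflection*: the rank with the largest one-point forward
difference slope, considered only among ranks whose slope exceeds 1 (ties
take the lowest rank; if no slope exceeds 1 — an exactly linear ramp —
no enhancer is super). Enhancers with signal strictly above the boundary
signal are super, so supers always form a suffix of the ranking. We
evaluated two alternatives on simulated two-regime landscapes
(exponential bulk plus a planted high-signal tail): the "first slope
crossing 1" rule fires inside the noisy bulk tail (single large
order-statistic gaps are common) and over-calls severely, and the
continuous tangent construction places the boundary where the *expected*
gap reaches the average slope, which is still inside the bulk tail and
admits roughly `n / multiplier` bulk enhancers. The maximum-jump rule
places the boundary inside the signal gap between regimes whenever the
two regimes are separated at all, which is the behaviour the planted
ground truth calls correct; its known weakness — a single extreme
super-enhancer can dominate the jump — is mitigated by the suffix
property and is visible in the `autoplot()` diagnostic.

Genes are assigned to an SE when their TSS lies within the SE extended
by 50 kb on both sides *and* the gene is transcriptionally active;
activity defaults to expression above the sample median
(`active_genes()`), since "active" is otherwise undefined for a pure
peak input. An optional second evidence track (H3K4me1) demotes supers
that lack any overlapping peak.

# Survival machinery

Kaplan–Meier curves, the log-rank test and the univariate Cox model for
a binary covariate are delegated to the `survival` package (Breslow tie
handling throughout); the package adds the contracts: a signed log-rank
`z` (so label swaps negate it), argument validation, and monotone
likelihood (separation) detection — `|beta| > 10` is clamped and flagged
`converged = FALSE` rather than reported as a finite estimate.

**Maximally selected rank statistics.** For a continuous covariate every
observed value μ inside the ε-quantile window (default proportions
0.1–0.9) defines a split {x ≤ μ} vs {x > μ}. The statistic is the
standardized log-rank score statistic under the permutation distribution:
with Nelson–Aalen scores `a_i = δ_i − Λ̂(t_i)`,

S(μ) = Σ_{x_i ≤ μ} a_i,  Var = m(N−m)/(N(N−1)) Σ a_i²,  Z(μ) = S/√Var,

and the cutpoint maximizes |Z| (ties → smaller cutpoint). Candidate
cutpoints are observed values, not midpoints. Events precede censoring
at tied times. The selection-adjusted p-value uses the
improved-Bonferroni approximation of Lausen and Schumacher, which sums
the crossing contributions of adjacent candidate splits; a permutation
option (seeded) is available. Two properties of the approximation
matter in practice and are asserted by the test suite: it is an *upper
bound* — decidedly conservative in the mid-range (a mid-range |Z| with
~80 candidates can receive an adjusted p several times the permutation
value) — while in the decision-relevant region (p ≤ 0.1) it tracks the
permutation p closely; and its null rejection rate at 0.05 stays at or
below nominal.

# The risk score

Candidate genes (e.g. SE-associated and overexpressed, or repressed and
underexpressed — `diff_expression()` provides the one-sided Wilcoxon
filters) are screened with maxstat; BH-adjusted q ≤ 0.05 genes are
dichotomized at their cutpoint and a Cox beta fitted with "above
cutpoint" coded 1. A direction filter keeps adverse-high genes
(beta > 0) for activation-derived signatures and adverse-low for
repression-derived ones. The per-patient score is

score = Σ_g β_g · w_g,  w_g = +1 if expr_g > cut_g else −1,

with equality at the cutpoint coded as "below" (a symmetric option
exists). The score is split into high- and low-risk groups by applying
maxstat to the score itself; the high-risk group is `score > cutoff`.

**Cohort transfer** re-derives each gene's cutpoint on the validation
cohort by quantile matching: the largest observed value v with
fraction{expr > v} ≥ the training `prop_above`. Betas and the global
score cutoff are copied verbatim — the validation cohort re-estimates
nothing, which is what makes the transfer an honest external validation.

# Differential binding

Consensus regions are the merged union of all peak sets filtered to
those supported by ≥ `min_overlap` samples. Counts are coverage sums per
region; occupancy analyses binarize instead. The two-group contrast is a
deliberately transparent substitute for negative-binomial machinery:
log2 counts-per-million with pseudo-count 0.5, a Welch t-test per region
with each group's variance floored at the trimmed mean (trim 0.25) of
that group's per-region variances, and BH adjustment. The floor is the
moderation: it removes the small-sample variance lottery that dominates
per-region t-tests at n = 8 vs 8. Two consequences are documented and
tested: under a homogeneous permuted-label null the p-values are
near-uniform and essentially nothing is flagged at FDR 0.05, while under
strong planted fold-changes CPM normalization transfers some signal to
unaffected regions (composition bias), so recovered sets should be read
as enriched, not exclusive. Library-size scaling leaves directions
unchanged except where the pseudo-count dominates a near-zero fold
change.

# The synthetic-data generators

Every generator is a pure function of a `sim_config()` (seed included);
each draws from its own derived seed so editing one model block does not
perturb the others. Defaults emulate the study conditions the pipeline
targets:

* **Panel**: 16 ChIP-seq samples, mirroring a cell-line panel.
* **Genome**: 4 chromosomes × 30 Mb, 300 non-overlapping genes of
  8–20 kb with ≥ 10 kb clearance (so neighbouring promoter and
  downstream windows cannot swallow each other's planted labels), fixed
  relative exon slices.
* **Peaks**: feature labels drawn from configured proportions (default
  approximates an enhancer mark: 45.4% distal intergenic, 35.4% intron)
  and placed so the midpoint rule recovers them exactly; a configured
  subset of promoters receives both repressive marks in a configured
  subset of samples, with the two marks' background promoter peaks drawn
  from disjoint gene pools so the planted co-marked set is exactly the
  recoverable one.
* **Enhancers**: 1000 loci of 1–3 constituent peaks placed in intergenic
  space, spaced farther apart than the stitch gap; bulk signals
  Exponential(mean 10), 5% supers at 20 × the bulk mean (±10% jitter).
* **Expression**: log-normal with per-gene log-means, optional planted
  fold-changes in a second sample group.
* **Survival**: hazard h(patient) = h₀ · exp(Σ β_g 1[expr_g > cut_g])
  with exponential event times; h₀ = 0.01/month (median ~6 years at
  baseline, the scale of newly diagnosed myeloma); censoring is
  independent uniform, calibrated by root-finding to a configured rate,
  default 0.6 — realistic for a large newly diagnosed cohort whose
  follow-up is shorter than median survival.
* **Drug response**: IC50 linear in a planted score plus Gaussian noise,
  with a negative default slope (higher risk score, more sensitive), the
  direction relevant for agents targeting the highlighted biology.

What the generators deliberately do **not** emulate: read-level noise,
GC and mappability bias, copy-number effects, correlated gene modules,
and informative censoring. Passing recovery tests on these data
therefore demonstrates correctness of the algorithms under their own
model assumptions, not performance on real cohorts.

**A documented limitation of the planted-survival design.** Planting ten
simultaneous binary effects of β = 0.7 makes each gene's *marginal*
effect smaller than its conditional one: the other nine genes act as a
frailty and attenuate the marginal log-hazard ratio to roughly 0.4 (a
generic non-collapsibility property of proportional hazards, not an
implementation artifact). Combined with 60% censoring (~240 events at
n = 600), per-gene maxstat statistics sit at |Z| ≈ 3.5–4.5 and the
BH-controlled screen recovers on average about 6 of 10 planted genes
per cohort — with a false-selection rate well under 5% — rather than
nearly all of them. With complete follow-up the same screen recovers
8–9; with the frailty removed (a single planted gene) the Cox beta is
recovered without bias. The scoring, splitting and transfer stages are
unaffected: the score split separates survival at p far below 10⁻⁴ and
transfer reproduces the training high-risk fraction within a few
percent. We keep the censoring default at its realistic value rather
than inflating the event count to make the screen look sharper.

# Problem sizes and runtime

The test suite and the reproduction script run on a single CPU in a few
minutes total. The adopted sizes: 50 cohorts of n = 60 for the
maxstat-vs-exhaustive check; 20 cohorts of n = 500–600 for Cox and
signature recovery; 10 landscapes of 1000 enhancers; 100 random interval
instances up to 1000 intervals against quadratic oracles; 200 null
datasets of 2000 regions × 16 samples for FDR calibration and 500 null
cohorts of n = 100 for maxstat calibration. These sizes were chosen so
each Monte-Carlo bound has comfortable margin while the whole suite
stays quick enough to run on every change.

# Numerical choices, in one place

* Coordinates: 0-based half-open everywhere; BED read/write is native.
* Sorting ties broken by (start, end, name); deduplication is exact.
* SE cutoff: maximum forward-difference slope among slopes > 1, with a
  1e-8 tolerance so an exact ramp yields no supers; ties → lowest rank.
* Maxstat: candidates are observed values; ε defaults (0.1, 0.9);
  permutation p uses (B+1)-denominator counting; seeded.
* Cox: Breslow ties, score tolerance 1e-9, ≤ 50 iterations, separation
  clamp at |β| = 10.
* Risk score: equality at a gene cutpoint codes −1; the high-risk group
  is strictly above the score cutoff.
* Differential binding: pseudo-count 0.5, CPM denominator `lib + 1`,
  variance floor = trimmed mean (0.25) per group, Welch–Satterthwaite
  degrees of freedom.
* Censoring calibration: uniform C ~ U(0, τ) with τ solved by uniroot so
  the expected censored fraction matches the configured rate given the
  drawn latent times.

# Known limitations

* The differential-binding contrast is a moderated t on logCPM, not a
  negative-binomial GLM; exact agreement with count-model packages is
  not a goal, and composition bias under very asymmetric signal is
  inherited from CPM normalization.
* The improved-Bonferroni maxstat p is conservative in the mid-range;
  use the permutation method when the absolute p-value magnitude (rather
  than a 0.05-level decision) matters.
* The SE inflection rule assumes the rank curve has a single dominant
  regime change; landscapes with several distinct super-regimes should
  be inspected with `autoplot()`.
* Gene assignment uses TSS proximity only; enhancer–promoter looping
  data would reassign some genes.
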