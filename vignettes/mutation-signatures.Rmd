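---
title: "Mutation-associated expression signatures: model, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation-associated expression signatures: model, design and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticsig)
```

## The procedure

`somaticsig` screens a tumour cohort for genes whose somatic variants —
coding or non-coding — reorganise the transcriptome in a way that predicts
overall survival. The chain is deliberately simple and fully rank-based up
to the survival models:

1. Every variant is assigned a region class against strand-aware gene
   models. Classes are made disjoint by the precedence
   coding (CDS) > UTR > intron > promoter, so per-class compositions sum to
   100%. The promoter is the 2.5 kb window immediately upstream of the TSS
   on the gene's strand (`[tss − 2500, tss − 1]` on `+`,
   `[tss + 1, tss + 2500]` on `−`); the downstream side is excluded. A
   variant inside two overlapping genes' footprints contributes to both
   genes' carrier tables rather than being assigned arbitrarily to one.
2. Carrier status is collapsed to the gene × region-scope level (any
   variant of a sample in that gene and scope makes it a carrier), and
   genes are kept when recurrent. Both recurrence rules used in practice
   are exposed explicitly: an inclusive `>=` mode (so 19 carriers of 930,
   2.04%, pass an "at least 2%" rule) and a strict `>` mode for "> 5% of
   cases". An optional cancer-gene census restriction is a case-insensitive
   symbol intersection with a user-supplied list; no census data ships with
   the package.
3. Within each molecular subtype, carriers and wild-type samples are
   compared gene-by-gene with a two-sided Mann–Whitney U test. Members are
   the genes at raw P ≤ 0.01, ranked by P and truncated to 100 — an
   intentional *uncorrected* screen (documented caveat below). Direction is
   the sign of the carrier − wild-type median difference (mean difference
   on a median tie; a gene still tied is dropped).
4. The signature score is the mean of the members' cohort z-scored
   expression with down members negated, dichotomised at the cohort median
   (strictly above = high). Both the single-variant split and the signature
   split are tested with Kaplan–Meier/log-rank and Cox models, adjusted for
   T stage (1–4, ordinal numeric), N stage (0–3, ordinal numeric), M stage
   (binary) and z-scored log MKI67 expression.

## Statistical choices and their rationale

**Mann–Whitney exact path.** For combined group sizes ≤ 16 the two-sided P
is computed by exhaustive enumeration of all assignments of the observed
mid-ranks, so it is exact under ties; larger samples use the tie-corrected
normal approximation with continuity correction. The two-sided exact P is
the probability mass of assignments at least as far from the null mean of
U as observed; since the permutation distribution of U is symmetric, this
coincides with the doubled one-sided tail.

**"Inversion" of downregulated genes.** Averaging raw expression lets
high-magnitude genes dominate and makes "inverting" a nonnegative value
ill-defined. The default therefore z-scores each member across the cohort
and negates the z of down members; the mean of signed z-scores is scale-free
and inversion is an exact sign flip. A raw-scale variant (negate raw
values) is available via `score_samples(..., method = "raw")` for fidelity
comparisons. Note the Mann–Whitney member selection is rank-based and hence
unaffected by any monotone transformation of expression; only the score is.

**Source gene eligibility.** Whether the mutated gene's own expression may
join its signature is genuinely open; it is *included* by default (its
expression shift is real signal) and excludable with
`build_signature(..., exclude_source = TRUE)`.

**Cut-off boundary.** A marker value exactly at a subtype cut-off counts as
positive; HER2 ≥ cut-off dominates regardless of ER, since the
HER2-positive group includes both ER states. ROC-derived cut-offs maximise
Youden's J over all midpoints between consecutive sorted unique values
(plus open ends), with J ties resolved toward the lower cut-off
(maximising sensitivity).

**Cox details.** Efron tie handling throughout (the lower-bias default).
Complete separation and non-convergence are flagged
(`skip_reason`/`flag`), never silently reported; flagged units are
excluded from the significant set. Covariates constant in a subtype (M
stage frequently is, at a 3% M1 prevalence) are dropped with a warning.
Significance is raw multivariate P < 0.05 per unit with **no multiplicity
correction across units**, mirroring the screening practice the package
reproduces; treat the significant set as candidates, not confirmations.

**Determinism.** P-value ties at the signature cap are broken by gene ID;
probe-collapse range ties by probe ID; the pipeline manifest embeds no
timestamps — a rerun with the same config and seed is byte-identical.

## What the synthetic cohorts emulate

The generator (`simulation_config()` + `simulate_cohort()`) consumes a
single seeded random stream in a fixed order (gene models → subtype
markers → variants → expression → survival), so a seed fully determines
the cohort. It emulates:

* **Subtype structure** driven by two marker genes. Defaults: fractions
  0.5/0.2/0.3 (ER+/HER2−, ER−/HER2−, HER2+), marker expression log-normal
  around the classical cut-offs (ER 3,700; HER2 27,000) with a ±1 log-unit
  separation and sd 0.4 — under 1% misclassification against the cut-off,
  so configured fractions are met in expectation.
* **Recurrent variants**: Bernoulli carriers per driver at its configured
  fraction; one variant per carrier placed uniformly (length-weighted)
  inside the gene's CDS (coding scope) or promoter/UTR/intron intervals
  (non-coding scope); 85% substitutions / 15% indels by default.
* **Expression**: log-normal per gene (per-gene mean levels around
  `meanlog = 6`, within-gene `sdlog = 0.6`), heavy-tailed and nonnegative
  like RSEM-style values; planted effects are applied on the log scale in
  units of the gene's log-SD, so "1 SD" is scale-free.
* **Survival**: exponential proportional hazards with linear predictor
  `Σ log HR · 1{signature-high} + stage_effect · (T + N + M)`, where the
  signature-high flag is constructed from the planted targets (median
  split of their signed mean z-score) — the estimand of the downstream Cox
  fit is therefore exactly the planted log HR. The baseline hazard default
  is 0.01 events/month. Censoring is independent exponential, with the
  rate solved numerically (`mean c/(c + r_i) = target`) to hit the target
  censored fraction — 0.7 by default, reflecting the short-follow-up,
  few-events regime typical of such cohorts. Stage distributions are fixed
  categorical defaults (T: .25/.55/.12/.08; N: .50/.32/.12/.06; M:
  .97/.03); an optional log-odds tilt makes higher T/N stages more likely
  in signature-high samples to induce confounding on demand.

It deliberately does **not** simulate sequencing reads, allele fractions,
copy number, tumour purity, gene–gene expression correlation, or
subtype-specific expression programs beyond the two markers. Consequently,
passing recovery and calibration tests demonstrates the *statistical
machinery* is correct under the stated model — not that the biological
findings of any particular cohort are reproduced; those require the
controlled-access data themselves.

## Problem sizes used by the test-suite and acceptance checks

Chosen as the smallest sizes at which the properties are sharp: exhaustive
Mann–Whitney enumeration for all splits with combined n ≤ 12; 1,000 random
positions over 20 gene models for the region-classifier oracle; signature
recovery at n = 200 with 50 targets shifted 1.0 SD across 10 seeds; null
calibration from 50 replicates of a 500-gene screen and 12 replicates of a
null survival screen; hazard-ratio recovery at n = 500 over 20 seeds, with
and without a stage confounder; 50 × 10 matrices for the
quantile-normalization and probe-collapse references.

## Known limitations

* The screen's raw P ≤ 0.01 / P < 0.05 thresholds are faithful to common
  practice but anti-conservative; a false-discovery-controlled variant is
  a one-line `p.adjust` away from the returned tables.
* Promoters are gene-linked windows; distal enhancers and TF-binding sites
  that cannot be assigned to a gene are out of scope, so "non-coding"
  burden excludes unassignable intergenic variation.
* Validation transfer reuses discovery directions and never re-estimates
  them; a cohort with globally inverted regulation would score as
  anti-correlated rather than being refit.
* The generator's exponential survival satisfies proportional hazards by
  construction; the Cox models are not stress-tested against
  non-proportionality here (a Schoenfeld-style diagnostic is a natural
  extension).
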