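---
title: "Calling ctDNA molecular response: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling ctDNA molecular response: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnamr)
library(dplyr)
```

`ctdnamr` turns serial liquid-biopsy variant calls into a molecular response
label per patient and the statistics a response-adaptive trial needs around
that label. This vignette explains the models and rules, the tunable
parameters and their defaults, what the synthetic cohort generator does and
does not emulate, and the choices we made where the design was genuinely
open.

## The measurement model

A targeted error-corrected NGS assay reports, per sample and genomic
position, a mutant allele fraction (MAF, a fraction in [0, 1]), the number
of distinct mutant read families, and the distinct (error-corrected)
coverage. Plasma cell-free DNA mixes three variant sources: the tumor,
clonally expanded hematopoietic cells (CHIP), and the germline. Only the
tumor component carries treatment-response information, so classification
precedes everything else.

### Origin rules

For each unique (patient, chrom, pos, ref, alt) with at least one plasma
call, in strict precedence:

1. **Hotspot → tumor.** Canonical activating mutations (KRAS/NRAS codons
   12/13/61, BRAF V600, EGFR L858R/T790M, PIK3CA hotspots) are tumor
   derived even when present in the WBC sample — circulating tumor cells
   contaminate the buffy coat far more plausibly than a hotspot arises in
   blood lineage.
2. **Germline.** Non-hotspot, detected in WBC DNA, with MAF ≥ 25%
   (`germline_maf_threshold`) in the WBC sample *and* in every plasma
   sample in which it was called. A heterozygous germline variant sits near
   50% everywhere; 25% leaves room for copy-number skew.
3. **CHIP.** Any other non-hotspot variant detected in WBC DNA
   (`wbc_min_reads`, default 1 mutant read family — the scheme imposes no
   WBC read floor).
4. **Tumor** otherwise.

Two open points and how we resolved them. First, whether a timepoint at
which a variant was *not* called counts as 0% MAF for the germline rule
(vetoing germline) or is ignored: we ignore it. A germline variant may be
genuinely missing from a draw through sample quality alone, and the rule is
about evidence in the samples where the variant was measured. Second,
patients with no WBC sample at all: rules 2–3 are inapplicable, and rather
than dropping the patient we label all their variants tumor derived with a
`wbc_missing` provenance flag, so the pipeline degrades gracefully and the
flag travels into the output table. Multi-nucleotide substitutions are keyed
exactly as the caller wrote them (no re-normalisation; indel left-alignment
is assumed done upstream).

### Circulating tumor load

Load at a timepoint is summarised over the patient's tumor-derived
variants; we track every such variant at every available timepoint,
contributing MAF 0 where it was not called. The primary metric is maxMAF —
the maximum is robust to the assay's noisier low-MAF calls in a way the
mean is not — with mean and median carried alongside for the depth-of-
response comparison. A patient whose available samples never show a
tumor-derived variant is *undetectable*; that is a distinct state from
molecular response, and such patients are excluded from the response-rate
denominator.

## Molecular response

With draws at baseline (C1D1) and on therapy (C2D1 at ~3 weeks, C3D1 at
~6 weeks; draw labels are assigned by collection order, not nominal cycle
number), the status rules are:

* **not evaluable** — no baseline draw, or no on-therapy draw;
* **undetectable** — maxMAF 0 at every available draw;
* **mR** — maxMAF ≤ `clearance_threshold` at the *last available*
  on-therapy draw (C3D1, or C2D1 when C3D1 was missed);
* **mPD** — otherwise.

`clearance_threshold` defaults to exactly 0: response means reduction to
assay-undetectable, not "below some level". It is configurable for
sensitivity analyses. Clearance at C2D1 followed by a detectable C3D1 is
mPD — persistence at the last draw governs. A baseline-zero patient with
later detectable ctDNA is likewise mPD.

Kinetic patterns refine the statuses: clearance at C2, clearance at C3,
*deep reduction* (best on-therapy reduction of maxMAF strictly above
`reduction_threshold` = 0.85 without sustained clearance), and persistence.
The best on-therapy reduction is taken over both on-therapy draws — the
source material is silent on whether its ">85% but <100%" patients were
measured at C2, C3 or the best of both, and best-of-both is the only choice
that is monotone when a draw is missing. A transient complete clearance
that relapses at C3D1 counts as deep reduction (its best reduction is
100%), not persistence.

## Statistics

**Exact intervals.** Sensitivity P(mR | radiographic responder) and
specificity P(mPD | non-responder) use Clopper–Pearson intervals via the
beta-quantile identity: lower endpoint `qbeta(a, k, n-k+1)` with
`a = (1-level)/2`, clamped to 0 at k = 0 (symmetrically for the upper).
The two-sided 90% interval's lower endpoint is simultaneously the one-sided
95% bound, which is how the trial-style success criterion (> 50%) is
evaluated. We verified the construction against direct binomial-tail root
finding and `binom.test`. Interval endpoints render at one decimal; the
test tolerance against externally printed bounds is ±1.5 percentage points
because printed rounding conventions are not always recoverable.

**Exact test.** One-sided p-values are tail sums; the two-sided p-value
uses the minimum-likelihood rule (sum of probabilities of outcomes no more
likely than observed). Both sidedness conventions appear in trial reports —
a response rate of 16/50 against a presumed 45% gives 0.043 one-sided and
0.066 two-sided — so the sidedness is an explicit argument rather than a
hidden convention.

**Design bound.** `min_responders_for_bound(rate, level, bound)` returns
the smallest n such that, with k the smallest integer with k/n ≥ rate, the
exact lower bound exceeds the target. Note the bound is *not* monotone in
n: for (0.70, 90%, 0.50) the minimum is n = 13 (k = 10), yet n = 14 and 15
fail while n = 18 (k = 13) passes again. A design that quotes a larger
sufficient count is therefore not contradicted by the smaller minimum.

**Depth of response and ROC.** d = (m₁ − mₓ)/m₁ for baseline metric
m₁ > 0. When m₁ = 0 the ratio is undefined and the patient receives the
smallest d observed among the other patients at that timepoint — the
largest increase in the cohort — flagged `imputed`; this keeps such
patients (whose ctDNA appeared on therapy) in the ROC rather than silently
dropping them, and preserves the ranking of the defined entries. Patients
missing the on-therapy draw are excluded from that timepoint's ROC (the
conservative choice; imputing a depth for a sample that does not exist
would manufacture signal). The ROC sweeps all thresholds; the trapezoidal
AUC equals the pairwise Mann–Whitney statistic with ties counted ½ (an
identity our tests assert on a thousand randomized instances). The default
CI is the asymptotic DeLong placement variance truncated to [0, 1]; a
seeded bootstrap (2,000 resamples) is the alternative.

**Limit of detection.** Detection probability is P(X ≥ k) for
X ~ Bin(coverage, MAF) with k = 3 mutant read families, computed through
the binomial survival function — not by summing the upper tail naively,
which loses precision to cancellation at coverage in the thousands. The
assay-level sensitivity at a MAF is the median across profiled positions;
the positions are whatever baseline tumor-derived loci the cohort yields,
and the ingested `distinct_coverage` is used as the binomial denominator.
At ~3,000× distinct coverage the median sensitivity is ≈94% at 0.2% MAF
and >99% at 0.3%.

**Survival.** Kaplan–Meier estimation, log-rank tests and Cox regression
delegate to the survival package (Greenwood variance; log-log median CIs;
Efron tie handling — the source convention is unstated and Efron is the
less biased default). Medians report 90% CIs and hazard ratios 95% by
convention, both configurable. "Not reached" is an explicit state, never a
number. Time to molecular response puts the event at the clearance sample's
collection day, converted at 30.4375 days/month, censoring non-responders
at their last draw.

## The synthetic cohort generator

`simulation_config()` encodes the study conditions; `generate_cohort()`
draws a cohort plus a complete ground-truth table. Per patient: a
radiographic responder flag (p = 0.32; the "design" preset uses 0.45), an
undetectable flag (p = 0.20), missing-draw flags (6% lose all on-therapy
draws, 4% have non-evaluable radiology, 13% lose only C3D1), and a latent
molecular status with P(mR | responder) = 0.82 and
P(mR | non-responder) = 0.25. Molecular responders clear at C2D1 with
probability 13/15, else at C3D1; 10% of non-responders are deep reducers
(on-therapy MAF multipliers drawn so the reduction lands in 0.86–0.98);
the rest get log-normal multipliers clamped to [0.3, 2.5] so their
reduction stays safely below the 0.85 pattern threshold. Baseline MAFs are
log-normal (median 2%, log-SD 1) truncated to [0.001, 0.35]. CHIP variants
(0.5–8% MAF base, capped at 20%) and germline variants (40–60%) are injected
at per-patient rates calibrated so they make up ≈17% and ≈5% of unique
plasma variants; both appear in the WBC sample, as do one quarter of
hotspot variants (buffy-coat leak). PFS/OS are exponential with medians
5.03/2.6 months (mR/mPD PFS), 30/7.23 (OS) and 8.31/16.89 for undetectable
patients, administratively censored uniformly on 2.5–23 months. Draw days
are 0, ≈23 and ≈64 (SD 4); the later C3D1 centre reflects that response
determination in practice happens around two months once real-world delays
accumulate.

Three deliberate idealisations matter for interpreting green tests:

* **Margins are respected by construction.** Generated germline MAFs never
  fall below 40% and CHIP never above 20%, so the 25% rule classifies them
  unambiguously and the end-to-end identity test (pipeline labels ==
  ground truth, zero errors) is meaningful. Real cohorts have boundary
  cases; those are exercised by hand-built fixtures, not by the generator.
* **Detection is conditioned on the call.** For a latent-positive variant
  the generator draws mutant reads as Bin(coverage, MAF) truncated below at
  3 — i.e. it emulates the caller's output (calls that exist), not the
  caller's misses. Stochastic dropout of real assays near the LOD is
  therefore *not* emulated, and recovered sensitivity/specificity measure
  the pipeline's bookkeeping, not assay performance.
* **Missingness is independent of outcome** (except that a C3D1 clearance
  is definitionally observable only when the C3D1 draw exists, so that
  pattern never hits a latent C3-clearer). Informative missingness —
  sicker patients missing draws — is not modelled.

Trial-scale quantities that depend on per-patient data (the exact PFS/OS
medians, the 2.1-month median time to response, AUCs of 0.77/0.81) are
emulated in distribution, not reproduced: the tests assert the simulated
cohort lands in the right regime (time-to-response median inside 1.5–2.6
months, responders outliving non-responders, AUC well above chance), and
the stronger checks are parameter-recovery simulations at n = 500–2,000.

## Problem sizes and numerical choices

The test suite simulates cohorts of 50–3,000 patients; the end-to-end
recovery check uses ten seeds at n = 2,000 (about half a minute) and the
Cox coverage check 200 replicates at n = 400. Clopper–Pearson endpoints
come from `qbeta` (no iteration of our own); the Cox partial likelihood is
maximised by the survival package's Newton iterations and cross-checked in
tests against a grid-search oracle on tiny data; ROC ties are handled by
the midrank convention everywhere. Report-level percentages round half away
from zero (81.8% prints as 82%), matching trial-report convention rather
than R's round-half-even.

## Limitations

The package classifies variant origin from a single matched WBC draw; very
low-abundance CHIP below the WBC assay's detection floor will leak into the
tumor-derived set, and panels lacking canonical CHIP genes (DNMT3A is
absent from some liquid-biopsy panels) under-count CHIP. Tumor-informed
comparison (`tumor_plasma_origin_concordance()`) reports discordance but
never reclassifies — archival single-region tissue legitimately misses true
ctDNA variants. No lead-time analysis versus radiology is attempted, no
tumor-fraction deconvolution, and no read-level error simulation.
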