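---
title: "Predicting PARP-inhibitor benefit for HR-gene VUS: model and methods"
author: "parpvus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting PARP-inhibitor benefit for HR-gene VUS: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parpvus)
```

## The clinical problem

PARP inhibitors (olaparib, niraparib, rucaparib) exploit synthetic lethality
with homologous-recombination (HR) deficiency: tumors that have lost
functional BRCA1, BRCA2, PALB2, RAD51C/D, BRIP1, ATM or related genes cannot
repair the double-strand breaks that accumulate under PARP inhibition.
Prescription is normally tied to a *known pathogenic* variant — yet roughly
40% of the variants found in HR genes by panel, exome or genome sequencing
are variants of unknown significance (VUS), and patients carrying only a VUS
are shut out of the drug class while formal reclassification (functional
assays, segregation studies) takes years.

`parpvus` implements a desk-scale, rule-based classifier that uses only
quantities already present in a routine NGS report — variant allele
frequency (VAF), pathologist-assessed tumor cell content, categorical
PROVEAN and DANN in-silico calls, and the patient's ECOG Performance
Status — to label a VUS-carrying treatment episode as PARP-inhibitor
**S**ensitive, **R**esistant, or **U**ncertain, and validates the labels
against progression-free survival (PFS).

## The second-hit score

HR genes are tumor suppressors: both alleles must be hit. If the sequenced
variant is accompanied by loss of the remaining wild-type allele in the
tumor, its allele frequency rises above the heterozygous expectation. For a
heterozygous somatic variant with both alleles retained, the expected VAF is
half the tumor cell fraction *p* — at 60% tumor cells, about 30%
(`expectedHetVaf(0.60)` = 0.30). The package standardizes the observed VAF
by purity:

$$\mathrm{score} = \frac{\mathrm{VAF}}{p}$$

Under the diploid allele-count forward model (`alleleVaf()`):

| state                         | bulk VAF    | score        |
|-------------------------------|-------------|--------------|
| somatic heterozygote          | $p/2$       | $1/2$        |
| somatic het + wild-type loss  | $p/(2-p)$   | $1/(2-p)$    |
| germline heterozygote         | $1/2$       | $1/(2p)$     |
| germline het + wild-type loss | $1/(2-p)$   | $1/(p(2-p))$ |

The clinical tables this package transcribes print the resulting scores but
not the formula or the raw VAF/purity inputs. The ratio form used here is a
**reconstruction**, chosen because it (a) reproduces the published
heterozygous expectation of 0.5 exactly, (b) puts all ten published "Red"
scores (max 0.66) and all six "Green" scores (min 0.72) on opposite sides of
a single boundary, and (c) produces scores above 1 (1.12, 1.48 are printed)
only where a germline-heterozygote-with-loss state is plausible. The
green/red threshold defaults to **0.7**, the midpoint-ish value in the
published gap (0.66, 0.72]; a score exactly at the threshold calls D. The
threshold is exposed everywhere (`secondHitCall(..., threshold = )`,
CLI `--second-hit-threshold`).

`secondHitGrid()` renders the full purity × VAF lookup table (default 5%
steps, a 20 × 21 grid). Cells with score > 2 are flagged *implausible*: no
diploid model can put more than two variant alleles per tumor cell, so such
combinations indicate an inconsistent purity estimate.

Missing VAF or purity (and the niraparib-cohort rows that print only a
categorical call) yield the call U.

## In-silico evidence

PROVEAN (alignment-based; more negative = more damaging) and DANN
(neural-network score in [0,1]; higher = more damaging) were the only two of
eighteen tools surveyed in the source study that separated benefiting from
non-benefiting VUS carriers at all. The clinical fixtures carry the tools'
*categorical* calls as printed, and a categorical input always overrides a
raw score. When only scores are available the defaults are PROVEAN ≤ −2.5 →
D (the tool's published operating point) and DANN ≥ 0.96 → D (a widely used
operating point); both are parameters, and none of the packaged validations
depend on them. Variants that are not scoreable missense changes
(start-loss, frameshifts) and have no categorical call resolve to U. One
niraparib-cohort row prints the value "N", which no legend defines; it is
stored verbatim and treated as U.

## The classification rule

Per variant and per evidence model (*second hit + PROVEAN* or *second hit +
DANN*):

* **deleterious** as soon as either the second-hit call or the model's
  in-silico call is D;
* **benign** when both resolved calls are B;
* **unknown** otherwise. Unknown evidence never argues for sensitivity.

Per patient (episode): patients at or above the Performance-Status cutoff
(default **PS 3**) are labelled R outright — in the development cohort every
PS 3 patient progressed before 120 days regardless of molecular evidence.
Otherwise the episode is S as soon as *any* of its VUS classifies
deleterious under the model, else R.

The final label is the **consensus** of the two models: agreement passes
through, disagreement gives U — exactly the published "S or R" olaparib case
and the "U" niraparib case. The PS gate lives inside the VUS algorithm only;
`decisionTree()` routes known-pathogenic episodes to treatment without it
(a `gateKnownPathogenic` flag extends it on request), sends benign-only or
variant-free episodes away from PARP inhibition, and maps the consensus for
VUS carriers.

On the packaged fixtures this reproduces every published prediction: the
olaparib VUS cohort (12 patients) as 6 S / 5 R / 1 U with exactly two
episodes flipped to R by the PS gate, and the niraparib cohort (8 patients)
as 3 S / 4 R / 1 U.

## Survival validation

PFS is summarized by the Kaplan–Meier product-limit estimator and compared
between groups with the two-group log-rank (Mantel–Cox) test; both are
delegated to the `survival` package behind `kmFit()`/`logrankTest()`, with
the package fixing the conventions: the median is the smallest event time
with $S(t) \le 0.5$, and events precede censorings at tied days. Treatment
*benefit* is PFS **strictly greater than 120 days** — the dichotomization
boundary the source study derived from its benign-variant carriers — so a
PFS of exactly 120 days (one such episode exists) does not count.
`concordanceReport()` cross-tabulates final labels against the benefit flag;
on the olaparib VUS fixture all five R episodes sit below 120 days and all
six S episodes above.

Censoring in the transcribed cohort: the four episodes annotated "still
under olaparib" and the single day-1 stop for an allergic reaction are
censored (treatment stopped without progression or death); all other rows
are events.

### A transcription caveat

The source text quotes group medians of 81 / 127 / 190 days for benign /
VUS / pathogenic carriers and calls 120 days "the maximum PFS observed" for
benign carriers, but the per-patient PFS column it prints (benign: 81, 58,
62) cannot produce those numbers under any standard median convention. The
package therefore treats only the per-patient values as data; the group
medians are not used in any packaged check.

## The synthetic-cohort generator

`simulateCohort()` exists so that every stage is testable without any
external data and so that parameter recovery can be demonstrated. Its
defaults are the development-cohort conditions: 41 episodes; class mix
3 benign : 6 truly-benign VUS : 6 truly-deleterious VUS : 26 pathogenic
(the published census, with the VUS split at the observed 6/6 benefit
ratio); purities uniform on [0.2, 0.9] rounded to two decimals
(pathologist-style estimates); read depth 100× (the study's mean coverage);
a 50% germline fraction; wild-type-loss probability 0.9 given a truly
deleterious variant; in-silico calls correct for the true class up to a 10%
flip rate; PS drawn from (0.10, 0.55, 0.15, 0.15, 0.05) over 0–4
(smoothed from the twelve printed PS values); exponential PFS with medians
81 days (truly benign) and 190 days (truly deleterious) — the published
benign and pathogenic group medians — shrunk by a factor 0.25 at PS ≥ 3;
and 12% random censoring (5 of 41 episodes were censored). The exponential
is a simplicity choice; the source gives no survival model.

Observed VAF is binomial(depth, true VAF)/depth, so the noise shrinks as
$1/\sqrt{\text{depth}}$ (tested at two depths). A single RNG stream per run
makes identical seeds give byte-identical cohorts.

**What the generator does not emulate:** subclonal variants, copy-number
states beyond single-allele loss, purity estimation error, correlated
in-silico errors between tools, and non-exponential hazards. Passing
recovery tests therefore demonstrate the *pipeline's* correctness under the
model's own assumptions, not clinical performance on real data.

### A structural limitation worth knowing

A germline heterozygote *without* allele loss has bulk VAF 0.5 regardless of
purity, hence score $1/(2p)$ — at purity below 5/7 this exceeds the 0.7
threshold and the variant is flagged green even though nothing happened to
the wild-type allele. The VAF/purity ratio, in other words, systematically
over-calls LOH for germline variants in low-purity samples unless zygosity
is known. The noiseless-limit recovery demonstration (sensitivity =
specificity = 1) is accordingly run with somatic-only variants; with
germline benign variants in low-purity samples, specificity is structurally
below 1. Copy-number-aware LOH calling, which would resolve this, is out of
scope.

## Numerical and design choices

* **Threshold boundary values.** The loss-state score $1/(2-p)$ crosses 0.7
  exactly at $p = 2 - 1/0.7 \approx 0.571$; the monotonicity and
  loss-detection properties are tested from $p = 0.58$ upward.
* **Patient-level class precedence** (for cohort stratification):
  pathogenic > unknown > benign; "probably benign" counts as benign. An
  episode with no variants has no class (error) but is handled by
  `decisionTree()`.
* **Re-treatment.** One patient treated with olaparib twice appears as two
  distinct episodes, as in the source table.
* **HGVS strings** are carried verbatim and never validated or normalized —
  including one printed nucleotide/protein pair that is mutually
  inconsistent. Transcript mapping and ClinVar lookups are out of scope.
* **Missing PS** (not printed for non-VUS episodes) is treated as below the
  gate cutoff wherever classification is attempted.
* **Purity as a percentage** (> 1) is divided by 100 with a warning.
* **Problem sizes.** The packaged checks run the 41/12/8-episode fixtures,
  a 20 × 21 score grid, permutation oracles with 2000–4000 draws at
  n ≤ 12, and simulated cohorts of 25–400 episodes; the whole suite
  completes in well under a minute on one core.

## Reproducing the published validation

```{r validation}
t3 <- loadFixture("table3")
pred <- classifyCohort(t3)
table(pred$final_label)
rep <- concordanceReport(t3, pred)
rep$counts
```

The CLI (`inst/scripts/parpvus`) exposes the same pipeline as `classify`,
`loh-table`, `survival`, `simulate` and `fixtures` subcommands, and
`scripts/acceptance.R` recomputes the package's headline quantity from the
installed package.
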