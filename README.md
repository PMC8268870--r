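# parpvus

Rule-based prediction of PARP-inhibitor sensitivity for tumors whose only
finding in a homologous-recombination (HR) gene is a **variant of unknown
significance (VUS)**.

PARP inhibitors (olaparib, niraparib, rucaparib) work through synthetic
lethality with HR deficiency, and prescription is usually tied to a known
pathogenic variant in *BRCA1*, *BRCA2*, *PALB2*, *RAD51C/D*, *BRIP1*, *ATM*
and related genes. But around 40% of the variants reported by clinical NGS
in these genes are VUS, leaving their carriers without access to the drug
class. `parpvus` implements, tests and validates a desk-scale classifier
that uses only what a routine NGS report already contains.

## The model

**Second-hit (LOH) score.** HR genes are tumor suppressors, so response
requires loss of the second allele. For a heterozygous somatic variant with
both alleles retained, the expected variant allele frequency (VAF) is half
the tumor cell content *p* (at 60% tumor cells, VAF ≈ 30%). The score
standardizes the observed VAF:

```
score = VAF / p        0.5 = heterozygous baseline
```

Loss of the wild-type allele pushes the score up (a germline heterozygote
with loss has VAF 1/(2−p), score > 1). Scores ≥ 0.7 fall in the *green*
zone of the LOH lookup table (`secondHitGrid()`) and call **D**
(deleterious), scores below call **B**, missing data calls **U**. The
threshold 0.7 sits in the gap between all published red (≤ 0.66) and green
(≥ 0.72) scores.

**Per-variant rule**, per evidence model (*second hit + PROVEAN* or
*second hit + DANN*): deleterious as soon as either call is D; benign when
both are B; unknown otherwise — unknown never argues for sensitivity.

**Per-patient rule**: episodes with ECOG Performance Status ≥ 3 are
Resistant outright (the PS gate); otherwise Sensitive as soon as any VUS is
deleterious under the model.

**Consensus**: both models agree → that label (**S**/**R**); disagreement →
**U**. `decisionTree()` wraps the whole flow: known pathogenic → treat,
benign/no variants → no HRD-mediated response expected, VUS → consensus.

Validation is by Kaplan–Meier / log-rank analysis of progression-free
survival (PFS) dichotomized at a strict 120-day benefit boundary.

## Worked example

The packaged fixtures transcribe the published clinical tables verbatim
(`loadFixture("table2")`: 41 olaparib episodes; `"table3"`: its 12 VUS
carriers with evidence; `"table5"`: 8 niraparib VUS carriers).

```r
library(parpvus)
coh <- loadFixture("table3")
coh
#> ParpCohort 'table3': 12 episode(s), 16 variant(s)
#>   sites: breast=2, digestive_tract=5, ovary=4, skin=1

classifyConsensus(getCase(coh, "Ovarian #23"))
#> ClassificationResult Ovarian #23: final U (provean=S, dann=R)
#>   - BRCA2 p.Met990Lys: second-hit=B, PROVEAN=D, DANN=B -> deleterious (provean) / benign (dann)
#>   - per-model labels provean=S, dann=R -> final U
```

The two models disagree on this BRCA2 VUS (only PROVEAN calls it
deleterious), so the episode is Uncertain — the published table prints it
as "S or R". Classifying the whole cohort and cross-tabulating against the
120-day benefit flag:

```r
pred <- classifyCohort(coh)
table(pred$final_label)
#> R S U
#> 5 6 1

concordanceReport(coh, pred)$counts
#>      benefit
#> label FALSE TRUE
#>     R     5    0
#>     S     0    6
#>     U     1    0

kmFit(patients(coh)$pfs_days, patients(coh)$pfs_event)
#> KMCurve: n=12, events=12, median=93 days
```

Every Resistant-labelled episode progressed before 120 days and every
Sensitive-labelled one after — the headline validation property. A CLI
wrapper (`inst/scripts/parpvus`) exposes the same pipeline:

```sh
parpvus classify --fixture table3 --out results/
parpvus loh-table --purity-step 5 --vaf-step 5 --out results/
parpvus simulate --seed 1 --n 41 --out results/
```

## Cohort TSV schema

Patients file: `patient_id`, `site` (ovary/breast/digestive_tract/
endometrium/skin/other), `histology`, `ps` (0–4 or NA), `treatment`
(olaparib/niraparib/none), `platinum_response` (CR/PR/SD/PD/none/missing),
`pfs_days` (≥ 1), `pfs_event` (TRUE = progression/death, FALSE = censored).

Variants file: `patient_id`, `gene`, `cdna`, `protein` (HGVS verbatim,
never normalized), `known_class` (benign/probably_benign/unknown/
pathogenic), `vaf` [0,1], `purity` (0,1], `provean_score`, `provean_call`,
`dann_score`, `dann_call`, `second_hit_score`, `second_hit_call`
(calls in B/D/U).

`readCohort()` can instead take variants from a VCF 4.x file (one sample
column per patient; per-sample `AF`, or `AD` as alt/(ref+alt); annotation
via INFO keys `GENE`/`CDNA`/`PROTEIN`/`CLASS`).

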