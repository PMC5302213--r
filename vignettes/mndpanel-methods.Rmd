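---
title: "Methods: gene-panel burden and genotype-phenotype analysis for MND"
author: "mndpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-panel burden and genotype-phenotype analysis for MND}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mndpanel)
```

## Overview

mndpanel implements the analysis workflow of a targeted-panel genetic
epidemiology study of motor neuron disease (MND): five genes — *SOD1*,
*TARDBP*, *OPTN*, *TBK1*, *NEK1* — amplicon-sequenced in a case–control
cohort, with *C9orf72* hexanucleotide repeat expansion status available as
an external input. The pipeline runs, in order:

1. **Sample QC** against per-batch water-blank negative controls;
2. **Relatedness pruning** to an independent case set;
3. **Variant filtering** on consequence, population frequency, read depth,
   allele balance, and excluded regions;
4. **Tiered pathogenicity classification**;
5. **Burden testing** by Fisher exact tests against internal controls and a
   depth-adjusted ExAC reference, plus carrier-union and digenic accounting;
6. **Genotype–phenotype association** via a univariate screen, binomial
   logistic regression and Kaplan–Meier/log-rank survival comparison.

Because raw patient-level data of this kind cannot be redistributed, the
package ships a synthetic-cohort generator ([`simulateCohort()`]) with a
planted truth ledger, so every stage is verifiable end to end against known
ground truth.

## Sample QC

Amplicon coverage in a water blank estimates the background of
cross-contamination and primer artifacts for its batch. A sample is kept
only if its median per-amplicon coverage **strictly exceeds 10×** the
blank's median (`qcFilterSamples()`, `ratioThreshold = 10`). Ties at
exactly 10× are excluded — the rule is an excess requirement, not a
"at least" requirement. When a batch carries several blanks the reference
is the median of their medians; this is a convention chosen here for
robustness (the original design had one blank per batch of 48) and is
flagged as such rather than as the only defensible reading.

Related individuals violate the independence assumption of the carrier
tables, so each kinship group is pruned to its earliest-recruited member
(`pruneRelated()`). Groups larger than pairs are supported with the same
rule. Pruning is deterministic and idempotent.

## Variant filtering

Four independent rules define the analysis-ready rare-variant set
(`applyVariantFilters()`); because each rule inspects a different facet,
they commute and the cascade order is immaterial:

* **Consequence**: only stop-gain, frameshift, splice-site and missense
  variants are retained. An unrecognized consequence label raises an error —
  silent pass-through of unexpected annotation vocabularies is a classic
  source of spurious carriers.
* **Population frequency**: a variant is removed if its 1000 Genomes or
  ExAC frequency is strictly above 1%, or if strictly more than 5% of
  genotyped cohort samples carry it. The in-cohort rule counts *carriers*
  over QC-passing samples, cases and controls pooled; a missing reference
  frequency is treated as 0 (absent from the reference set), the standard
  rare-variant convention.
* **Call quality**: calls with read depth < 50 or allele balance < 0.3 are
  excluded. Allele balance is alternate reads divided by total reads at the
  site.
* **Region exclusion**: positions inside excluded intervals are removed;
  the default exclusion is the GC-rich first exon of *SOD1*
  (`sod1Exon1Region()`), a recurrent source of amplicon false positives.
  Coordinates are 1-based inclusive throughout (VCF convention); BED input
  is converted with `bedToRegions()`.

## Pathogenicity tiers

`classifyVariants()` assigns one of five mutually exclusive tiers by a
fixed decision order:

1. Stop-gain, frameshift and splice-site variants are **loss-of-function**
   on consequence alone, with two biology-driven exceptions that demote to
   **uncertain significance**: a stop-gain in the final exon (escapes
   nonsense-mediated decay) and a splice-site variant predicted to cause
   in-frame loss of a single exon. Both flags are annotation inputs — the
   package does not model transcripts.
2. A missense variant flagged as MND disease-causing in HGMD is
   **pathogenic**, regardless of in-silico scores.
3. Remaining missense variants are voted on by ten predictors
   (`predictorThresholds()`): SIFT = D, PolyPhen-2 HDIV = P/D, LRT = D,
   MutationTaster = D, MutationAssessor = M/H, FATHMM = D, CADD phred > 15,
   GERP > 2, phyloP > 2, SiPhy > 10. Supporting counts of 7–10, 4–6 and
   0–3 give **likely pathogenic**, **uncertain significance** and **likely
   benign**. Continuous thresholds are strict (CADD 15.0 does not support);
   a missing score never supports — the conservative reading of "measures
   supporting pathogenicity".

A *C9orf72* repeat count of ≥ 100 is a pathogenic expansion
(`classifyC9()`), inclusive at the boundary.

The tier bands partition the 2^10 vote patterns exactly; the test suite
verifies this by brute-force enumeration, along with both precedence rules.

## Burden testing

Carrier tables (`buildCarrierTable()`) count each sample once per gene and
once panel-wide, regardless of variant multiplicity. The Fisher kernels are
computed directly from the hypergeometric distribution:

* `fisherOneTailed()` returns the exact upper-tail probability
  P(X ≥ observed case carriers) under fixed margins — one-tailed because
  the prior hypothesis is that cases carry more qualifying variants than
  controls. When the observed deviation runs the other way (controls in
  excess), the convention of common statistical packages is to print the
  one-sided p in the observed direction; `alternative = "less"` provides
  that tail.
* `fisherTwoTailed()` uses the sum-of-small-probabilities definition (all
  tables with point probability ≤ the observed one), the common exact-test
  convention, not tail doubling.

The ExAC reference comparison adjusts for incomplete exome coverage: the
60,706-exome cohort is scaled per gene by the average fraction of
individuals covered at 30× (`exacEffectiveN()`, nearest integer), and the
reference carrier count is the floor of frequency × effective N
(`exacCarrierCount()`). The floor is a deliberate convention: the published
carrier frequencies are printed at one significant figure and floor
integerization reproduces the published *NEK1* comparison to three
decimals, while the *TBK1* comparison is reproducible only approximately
(the underlying integer is not printed); it is treated as accurate to
within ~10% relative. The comparison is carrier-based, not allele-based,
which likewise reproduces the printed values.

`carrierUnion()` merges panel pathogenic/LoF carriers with expansion
carriers as a set union (overlap counted once), and
`findMultivariantCases()` enumerates samples with ≥ 2 retained rare
variants — an expansion counting as one variant — flagging as digenic those
with at least two pathogenic/LoF variants.

## Genotype–phenotype association

The collinearity screen (`collinearityScreen()`) reports Pearson r between
onset- and diagnosis-anchored variables; diagnosis-related variables and
the derived time-to-diagnosis are excluded from modelling, since onset is
the biologically meaningful anchor while diagnosis timing reflects clinical
services.

The univariate screen (`univariateTests()`) uses a fixed test-per-variable
assignment: two-tailed Fisher (the burden module's kernel — a single tested
implementation) for sex, site of onset and family history; a two-sample
t-test (pooled variance, Welch by flag) for age of onset; Mann–Whitney U
(normal approximation with tie correction; exact below n = 30) for disease
duration. The assignment is fixed rather than decided by a normality test,
which the source analysis did not describe. Unknown values are dropped per
variable (complete-case), so denominators vary by row.

Variables at p ≤ 0.1 (boundary included) enter a binomial logistic model
(`logisticFit()`): maximum likelihood, onset age grouped by decade
(`floor(age / 10)`, ordinal — no bin edges were specified, so the natural
calendar decades are used), Wald 95% CIs on odds ratios, and Nagelkerke
R² = (1 − (L₀/L₁)^(2/n)) / (1 − L₀^(2/n)). Separation or non-convergence is
flagged in the returned object, never silently reported.

Survival uses the survival package: product-limit curves per genotype group
and the multi-group log-rank test (`kmLogrank()`), with censored cases
contributing time to last contact.

## The synthetic-cohort generator

`simulateCohort()` emulates the study conditions, not merely plausible
data. Defaults (`simConfig()`):

* 440 cases and 400 controls sequenced in batches of 48 with one water
  blank each; 7 case and 11 control coverage-QC failures and 2 related case
  pairs planted, leaving 431 independent cases and 389 controls — the
  analysis denominators of the source cohort.
* Per-gene, per-tier carrier frequencies from the observed carrier counts
  over those denominators (`defaultCarrierFrequencies()`), and a 10.2%
  expansion frequency in cases (controls were not screened for expansions,
  so their default is 0).
* Phenotypes: 41% female; onset age normal 59.5 (SD 12.9) truncated to
  14–94 years (the observed range); duration log-normal matched to median
  42 and IQR 25–73.5 months — log-normal because duration was summarized by
  median/IQR and is right-skewed; 29% bulbar onset; 10% family history;
  85% deceased. Time to diagnosis is simulated (log-normal, median 12, IQR
  6–22 months) but unused downstream, matching its exclusion from
  association testing; no distributional form was given for it, so the
  same family as duration was chosen.
* Noise: 5% of planted calls degraded to depth < 50, 5% to allele balance
  < 0.3; a 2% per-sample artifact rate split between synonymous/intronic
  calls, reference-common variants and *SOD1*-exon-1 false positives; plus
  one shared artifact planted in 8% of samples to trip the in-cohort
  frequency rule.

Every planted sample fate and call fate is recorded in a truth ledger that
the pipeline never reads; tests assert *exact* recovery — the retained call
set, the tier of every retained variant, and every carrier table must equal
the ledger, not merely approximate it.

Missense scores are generated by inverting the vote
(`generatePredictorScores()`): a support count is drawn uniformly inside
the intended band, supporting predictors are chosen uniformly, and
continuous scores sit a fixed margin past or short of their thresholds
(e.g. CADD 15 ± 1) — the band, not the score vector, is what the
classification depends on. Non-supporting predictors are occasionally
missing to exercise the missing-as-no-support convention.

What the generator does **not** emulate: read-level data, primer content,
sequencing error profiles, linkage between variants, genotype-driven
phenotype effects (phenotypes are independent of carrier status unless a
calibration model is requested via `simulateCarrierPhenotypes()`), and
population stratification. Passing tests therefore demonstrate the
correctness of the decision rules and statistics on data with the study's
structure, not robustness to upstream calling artifacts beyond the modelled
noise modes.

## Numerical and design choices

* Fisher kernels are computed from `dhyper`/`phyper`; `fisher.test` and a
  binomial-coefficient enumeration serve as independent cross-checks in the
  tests (all 2×2 tables with total ≤ 30, exhaustively).
* The two-tailed rule uses the 1 + 1e-7 relative tolerance when comparing
  point probabilities, avoiding floating-point ties.
* The independent-case denominator (431) is used for every burden test; the
  published p-values 0.145, 0.080 and 0.143 are reproduced with 431 and not
  with the pre-pruning 433.
* An empty carrier table is not an error: the burden p is exactly 1.
* A splice-site variant flagged both final-exon and in-frame-skip takes the
  in-frame-skip exception; the combination is not biologically defined in
  the source scheme and is noted rather than guessed.
* Problem sizes in the test suite: the full-cohort fixtures use the default
  840-sample configuration; calibration studies use 200 cohort-sized
  replicates for coefficient recovery and 300–1,000 replicates for null
  calibration — sizes at which binomial/KS checks have useful power while
  the suite stays quick to run.

## Command-line use

The package is function-first: `runPipeline()` composes the stages on an
in-memory cohort, `writeCohort()`/`readCohortVcf()` bridge to VCF/TSV/CSV
interchange, and `validateInputs()` provides report-only schema checking.
`scripts/acceptance.R` is a worked non-interactive driver that recomputes
the study's headline statistics from scratch.

## Known limitations

* No ACMG-2015 classification, segregation or functional evidence; the
  tiering is the in-silico/HGMD/consequence scheme described above.
* No covariate-adjusted burden tests (SKAT/CMC and relatives are out of
  scope), and no multiple-testing correction across genes, matching the
  source analysis.
* The ExAC comparison inherits the uncertainty of the printed one-
  significant-figure carrier frequencies.
* Cox modelling, imputation of missing phenotypes, and cognitive/FTD
  phenotyping are out of scope.
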