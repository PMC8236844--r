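---
title: "Methods: qualifying variants, novelty QC, consensus scoring and gene burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qualifying variants, novelty QC, consensus scoring and gene burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kpburden)
library(dplyr)
```

`kpburden` implements a candidate-gene rare-variant workflow for
case-control sequencing studies: a panel of 18 tryptophan-metabolism genes
(one for protein synthesis, four for serotonin synthesis, thirteen for the
kynurenine pathway) is screened in a case cohort for (i) a burden of rare
protein-altering "qualifying" variants relative to control datasets and
(ii) novel variants absent from public references, which are then scored
for predicted pathogenicity. This vignette documents the model, the
tunable parameters, the synthetic-data world used for validation, and the
numerical and design choices that were genuinely open.

## The qualifying-variant filter

A variant qualifies for burden testing when both of the following hold:

1. **Protein-altering consequence** — exactly the classes missense,
   stop gain, stop loss, frameshift indel, in-frame indel, splicing.
   Synonymous, UTR, intronic and intergenic variants never qualify at any
   frequency. Consequence strings from the annotation dialect (ANNOVAR
   refGene vocabulary by default) map through an editable YAML table;
   unknown strings map to `other` (a total function, so no row is ever
   dropped for vocabulary reasons).
2. **Rare in every control dataset** — minor allele frequency at or below
   the dataset's threshold. Defaults: 0.005, with an override of 0.0001
   for the gnomAD non-Finnish European non-neurological subset
   (n = 51,592), whose sample size would otherwise make 0.005 a very weak
   gate. Thresholds are *inclusive* ("equal to or less than"); a variant
   absent from a dataset has MAF exactly 0 and is therefore rare there.
   This forces the useful monotonicity property that adding control
   evidence can only disqualify, never qualify.

Zygosity never affects qualification: heterozygous and homozygous carriers
both count. When a control table carries only carrier counts (not allele
counts), MAF is approximated as `carriers / 2N` — a lower bound that is
exact when every carrier is heterozygous, which at MAF below 0.005 is
nearly always.

Multi-transcript annotations collapse to one row per variant: the gene's
configured canonical transcript wins; failing that, the most severe class
across transcripts (stop gain > frameshift > stop loss > splicing >
missense > in-frame > synonymous > UTR > intronic).

## Novel variants and sequencing QC

A qualifying variant observed in a case is *novel* when at most one
carrier exists across **all** control datasets combined (the stricter of
the two readings of "absent, or only present in a single individual"; a
per-dataset mode is one argument away). dbSNP membership is tracked but by
default does not veto novelty on its own — rs identifiers without any
frequency evidence exist — and a `dbsnp_vetoes = TRUE` switch enables the
stricter rule.

Novel calls are only reported when the supporting genotype passes
sequencing QC:

| check | rule | default |
|---|---|---|
| depth | `DP >= min_depth` | 25 reads |
| allele balance | alt fraction in window, het calls only | [0.35, 0.65] |
| genotype quality | `GQ >= min_gq` | 99 |

All three boundaries are inclusive, each has a dedicated boundary test,
and GQ 99 is encoded as `>= 99` because 99 is the cap standard callers
emit — an equality test would be caller-dependent. The balance window is
not applied to homozygous or hemizygous calls, where a 50:50 expectation
is meaningless (X-chromosome calls in males become hemizygous when a sex
sidecar is supplied; without one, X calls are treated as diploid).
Observations missing DP/AD/GQ are *unevaluable* — a third outcome distinct
from failure, flagged rather than dropped.

## Consensus pathogenicity score

The score is the fraction of in-silico predictors calling the variant
deleterious among predictors that returned any call, rounded
half-away-from-zero to two decimals; `1 (4)` reads "all 4 tools with
results predicted deleterious". The twelve missense tools and their
deleterious categories follow dbNSFP conventions (SIFT `D`; PolyPhen2
`D`/`P`; LRT `D`; MutationTaster `A`/`D`; MutationAssessor `H`/`M`;
FATHMM, PROVEAN, MetaSVM, MetaLR, M-CAP `D`; CADD phred ≥ 20). The
mapping is a shipped, editable YAML table because the tools — but not the
category conventions — are fixed by the study design; CADD has no
categorical output, so a phred cutoff is required and 20 is the
conventional, configurable choice.

Splicing variants have no missense predictions; their consensus runs over
the splice-capable set (NNSplice via MutationTaster, CADD, BayesDel, and
an *imported* Human Splicing Finder verdict column — the web service is
never queried). Tools without results drop out of the denominator; a
variant with no results at all has an undefined score (an error from the
scalar API, `NA` from the vectorised one).

REVEL (missense only) and BayesDel calls use the published cutoffs 0.5
and −0.057, both inclusive — the sources state the cutoffs without
strictness, and inclusive is the usual convention for published
thresholds. Both the rounded score (display) and the unrounded fraction
are available; statements like "pathogenic by more than 80% of tools" can
therefore be evaluated on either, and the package exposes both rather than
deciding.

## The exact burden test

For gene *g* and control dataset *d*, the 2×2 table is
`(a, n1 - a; c, n2 - c)` with `a` the case count, `c` the control count
and `n1`, `n2` the cohort sizes in individuals (an allele-based
construction against `2N` chromosomes is available via
`burden_config(unit = "alleles")` for allele-count control tables).
The default counting mode is **observations** — distinct
(variant, individual) pairs, a homozygote counting once — because the
report labels counts "variants" while percentages divide by cohort size;
**carriers** mode (distinct individuals) is one flag away.

Conditional on both margins, `a` follows a hypergeometric distribution.
Three two-sided definitions are implemented from the point masses
(log-space `dhyper`/`phyper`, relative tie tolerance 1e-7):

* **central** — `min(1, 2 * min(lower tail, upper tail))`; the package
  default, matching the default of the exact-2x2 test family the study
  design cites.
* **minlike** — the sum of the probabilities of outcomes no more likely
  than the observed one (the classic `fisher.test` rule).
* **blaker** — the observed minimal tail plus the largest opposite tail
  not exceeding it.

plus the one-sided `greater` (enrichment) test. Every method is verified
against a brute-force enumeration oracle over all small tables, and
`minlike` additionally against `stats::fisher.test`. Bonferroni
correction divides α = 0.05 by the number of *genes* (18 by default,
giving 0.00278), not genes × datasets, and significance is strict
(`p < threshold`).

### Which two-sided method was printed?

The published report's p = 1 rows reproduce exactly under the central and
Blaker methods; GOT2 and KYNU also reproduce under minlike. AADAT
(1/614 vs 80/51,592) does **not** give 1 under minlike: the observed cell
sits just off the hypergeometric mode, so the minimum-likelihood rule
excludes the x = 0 term:

```{r aadat}
sapply(c("central", "blaker", "minlike"),
       function(m) fisher_exact_2x2(1, 613, 80, 51512, method = m))
```

This pins the published method family to central (or Blaker), which is
why central is the default. The borderline printed p-values
(0.0023/0.0012/0.0001/0.0005/0.0022/0.0030) are *not* reproduced by any
supported method × construction combination on the printed counts — the
computed values agree in direction, significance calls and rank order but
not magnitude (the test suite computes the full grid in
`test-method-attribution.R`). A plausible cause is a difference in which
variant set was summed for the control counts; absent that information
the package documents the grid instead of hard-coding an attribution, and
the acceptance checks rest on the method-invariant rows.

### Insufficient data

A gene × dataset pair whose qualifying variants are all explicit no-call
records in that dataset (both counts "." — e.g. a gene absent from an
exome capture) is reported `n/a` with an "insufficient data" note rather
than as a spurious zero-count comparison.

## The synthetic cohort generator

`simulate_cohort()` emits every pipeline input — annotation TSV, case VCF
with GT:AD:DP:GQ, per-dataset control frequency tables, a dbSNP lookup,
gene-set YAML and a ground-truth JSON — from a seeded, parameterised
world:

* **Geometry** (defaults): 614 cases; controls nNFE 51,592, AOGC 967,
  MGRB 1,144; the 18-gene panel. These are the study's stated cohort
  sizes, so synthetic reports are shape-identical to the published table.
* **Site pool**: 36 sites per gene, 65% protein-altering. The pool is the
  *union* of case- and control-ascertained variants (control-only sites
  carry an empty carrier column), which is what keeps the case/control
  comparison unbiased; a pool ascertained from cases alone would make the
  burden test anti-conservative under the null. The union pool is
  protein-altering-rich because every rare coding variant segregating in
  a 51,592-sample panel enters it, while the non-coding complement is
  statistically inert and kept small for runtime.
* **Rarity**: per-gene qualifying-site MAFs are drawn (uniform, then
  rescaled) so that carrier probabilities sum to the per-gene baseline
  (default 0.002 — the mid-range of per-gene control carrier rates in
  screens of this geometry), capped at half the strictest MAF gate so
  realised binomial counts almost never breach the rarity threshold. One
  deliberately common protein-altering site per gene exercises the
  filter's reject path; non-coding MAFs are log-uniform on
  [1e-5, 4e-3].
* **Association**: control carriers are binomial draws from each site's
  MAF; case carriers are binomial with the site's odds multiplied by the
  gene's enrichment odds ratio (default 1 — the null), so the per-gene
  case/control odds ratio matches the configuration.
* **Predictions**: each categorical tool goes missing at the configured
  rate, otherwise calls deleterious with probability `sensitivity` for a
  latently deleterious variant and `1 - specificity` otherwise
  (defaults 0.9/0.9, missingness 0.05); CADD/REVEL/BayesDel are drawn
  from class-conditional ranges on either side of their cutoffs.
* **Planted novels**: the default plan places nine novel variants in six
  genes (two splicing), each in exactly one case with clean sequencing
  support; per-variant QC plans (`fail_depth`, `fail_balance`,
  `fail_gq`) let tests verify the exclusion path and its reasons.

Ground-truth qualifying/novel flags are computed arithmetically from the
*realised* tables inside the generator, not by calling the pipeline, so
the planted-truth recovery test exercises the full
write-files/read-files/qualify/report path end to end.

**What a green test does not establish.** The generator has no linkage
structure, no sequencing-read level errors, no population stratification,
no relatedness, and no ascertainment mismatch between datasets (the real
study compared PCR-free WGS cases against whole-exome and PCR-amplified
WGS controls — a known source of artefactual burden that the synthetic
world deliberately omits). Calibration and recovery results therefore
validate the statistical machinery, not robustness to those data
pathologies. Cohort-level counts of the original study (311 non-intergenic
variants, 84 qualifying, nine novel) depend on its undeposited WGS data
and are not reproduction targets; the synthetic defaults mirror their
*shape* only.

## Numerical choices

* **Rounding** of displayed percentages and scores is half-away-from-zero
  (`round_half_up()`), matching how the published tables print (1.79 from
  11/614, 0.83 from 10/12); stored values keep full precision.
* **Tie tolerance** in minlike/Blaker: point masses within relative 1e-7
  count as tied, following `fisher.test`'s convention.
* **Degenerate tables** (an empty margin) give p = 1; p-values are
  clamped to (0, 1].
* **Boundaries** are inclusive throughout (MAF thresholds, QC gates,
  REVEL/BayesDel cutoffs, CADD phred 20).
* **Determinism**: all simulation randomness flows from a single seed via
  `withr::with_seed`; identical parameters give byte-identical fixtures,
  and `run_pipeline()` is a pure function of its input files (the
  manifest records their checksums).

## Known limitations

* Control summary tables cannot distinguish one homozygote from two
  heterozygotes; carrier-based MAFs are documented lower bounds.
* The annotation dialect is package-owned; genuinely raw ANNOVAR
  multianno output needs a one-line column rename before ingestion.
* Human Splicing Finder is consumed only as a precomputed verdict column.
* Manual IGV review of novel calls is inherently out of scope; the report
  carries an `inspect` placeholder column for it.
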