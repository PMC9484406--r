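---
title: "Rare-variant triage for early-onset Alzheimer's disease cohorts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant triage for early-onset Alzheimer's disease cohorts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eoadtriage)
```

## The problem

Early-onset Alzheimer's disease (EOAD, onset before 65 years) is highly
heritable, yet dominant pathogenic variants in the three causative genes
(*APP*, *PSEN1*, *PSEN2*) explain only a minority of cases. Clinical panel
sequencing of EOAD cohorts therefore has to interpret a mixture of rare
variants: established pathogenic alleles, variants of uncertain significance
(VUS) in causative and AD-risk genes (*TREM2*, *ABCA7*, *SORL1*), variants
in genes causative for other dementias (the ALS/FTD spectrum and related
disorders), GWAS susceptibility genes, and the *APOE* ε4 genotype.
`eoadtriage` implements that interpretation pipeline as tested, reusable
code: from VCF to a per-variant clinical category and a per-patient
"genetically explained" status, stratified by family history.

## Selection filters

Calls are filtered in a fixed order — target region, depth, allelic
balance, rarity — and a rejected call records the first criterion it
failed, which keeps rejection reasons deterministic.

| parameter | default | meaning |
|---|---|---|
| `flank_bp` | 7 bp | intronic margin added to each coding interval |
| `min_depth` | 10 reads | minimum genotype-level depth (`FORMAT/DP`, falling back to site `INFO/DP`) |
| `ab_min`, `ab_max` | 0.30, 0.70 | inclusive allelic-balance band, heterozygous calls only |
| `max_maf` | 0.01 | exclusive ceiling on the reference-population allele frequency |

Two conventions deserve a note. The balance band is taken as *inclusive*:
the bounds are printed at one decimal, and an inclusive reading makes a
call with exactly 30% alternate reads self-consistent with the printed
band. Homozygous and hemizygous calls are exempt, since their expected
balance is not 0.5. Second, a variant absent from the reference population
("NR") counts as frequency zero and *passes* the rarity filter — absence of
evidence of commonness is treated as rarity, which is the only reading
under which never-reported variants remain interpretable at all. Missing
depth or allele-depth fields are a quality failure (`missing_quality`) by
default rather than silently passing; `keep_missing_quality = TRUE` relaxes
this.

Internally, region coordinates are 0-based half-open (the BED convention)
and conversion to VCF's 1-based positions happens only at the I/O boundary.
Indel alleles are trimmed (shared suffix, then shared prefix, adjusting the
position) so VCF keys match normalised annotation tables; full
left-alignment against a reference genome is out of scope and assumed done
upstream by the caller.

## Annotation and novelty

Variants join four non-overlapping gene panels (`AD_CAUSATIVE`, `AD_RISK`,
`OTHER_DEMENTIA` with twelve genes, `AD_GWAS` with 34). Seventeen of the
GWAS genes appear in the packaged cohort tables; the remaining seventeen
complete the panel from standard AD susceptibility loci and are explicitly
user-overridable in `gene_panels.yaml`, since different panel designs will
differ there. Knowledge tables are keyed by (gene, HGVS-c) — the keys the
curated tables actually print — with an optional coordinate adapter
(`chrom`/`pos`/`ref`/`alt` columns) for VCF mode. A variant is *novel* when
neither ClinVar nor HGMD reports it. "Conflicting interpretations of
pathogenicity" is a first-class ClinVar state carrying its vote multiset,
because the decision tree treats conflicting-with-pathogenic-votes
differently from a plain VUS.

## In-silico consensus for novel variants

Never-reported variants are graded by predictor consensus, with the tool
panel fixed by effect class: missense variants by PolyPhen-2, M-CAP, CADD
and MutationTaster (likely pathogenic at ≥ 3 of 4 damaging votes);
intronic/splice-region variants by NetGene2, MaxEntScan and Human Splicing
Finder; silent variants by MutationTaster, CADD and FATHMM-XF. The
three-tool classes use a simple majority (≥ 2 of 3) — the four-tool
threshold is the documented convention, the three-tool one is this
package's choice where no convention is stated, and both are configurable
arguments of `consensus_classify()`. `NO_CALL` verdicts count as
not-damaging (conservative toward benignity). Protein-truncating and
in-frame indel variants, for which no tool class is conventionally fixed,
use the four-tool missense panel. One positional rule overrides the votes:
a never-reported *APP* variant outside exons 16–17 — the exons encoding the
amyloid-β peptide — is likely benign regardless of predictions, and an
*APP* variant without an exon annotation is an error rather than a guess.
The package consumes verdict *labels*, not raw scores; thresholding scores
(e.g. a CADD cutoff) is the verdict provider's job.

## Enrichment statistics

Each variant testable against the reference population gets a 2×2
allele-count table: cohort alternate alleles (heterozygous carriers count
one, homozygous two, hemizygous one) over `2 × n_genotyped` (minus one per
hemizygous patient), versus the reference alternate/total counts. The
denominators assume every patient was genotyped at every panel site, which
is the panel-sequencing situation; per-site denominators can be supplied.

The two-sided Fisher exact p-value uses the point-probability
("minimum-likelihood") convention — the sum of hypergeometric point
probabilities not exceeding that of the observed table, with a 1e-7
relative tolerance on the comparison, matching the most common software
convention (this is documented because two-sided conventions genuinely
differ). A table with a zero margin is uninformative and returns p = 1.
Multiple testing is controlled with the Benjamini–Hochberg step-up within a
*family* defined as the variants of one results table (the per-table
reporting unit); the family definition is a configuration choice and every
result carries its family size. Variants absent from the reference are
excluded from the family rather than tested against a zero count. The test
suite validates both statistics against independent brute-force oracles —
exhaustive enumeration of all 2×2 tables with margins ≤ 30 for the Fisher
test, and a naive double-loop step-up for BH — rather than against any
printed p-value column: published per-variant adjusted p-values are
generally not recoverable without the exact cohort denominators and family
sizes used at publication time, and this package makes no attempt to
reproduce them.

## The clinical decision tree

Rules fire in a fixed order; the first match wins and the fired rule path
is recorded as the variant's rationale.

1. **Diagnostic** — in a causative gene: ClinVar pathogenic/likely
   pathogenic; or a definite HGMD disease annotation (an entry without a
   trailing "?" and not an "increased risk" association) when ClinVar does
   not contradict it with a benign-tier class; or conflicting ClinVar
   interpretations containing pathogenic votes together with HGMD disease
   support; or a novel variant with likely-pathogenic consensus.
2. **Contributor of disease / risk factor** — in a causative or AD-risk
   gene, a *risk candidate*: a VUS; conflicting interpretations without a
   pathogenic majority; a ClinVar-unreported variant with a questionable
   dementia-related HGMD annotation; or a benign-tier variant carrying a
   `prior_risk_report` literature flag. A candidate becomes a
   **contributor** only when both conditions hold — at least one carrier is
   familial *and* the BH-adjusted enrichment p-value is below 0.05
   (conjunctive by design); otherwise it is a **risk factor**. A novel
   AD-risk-gene variant with likely-pathogenic consensus is a risk factor
   directly.
3. **Weak risk** — in an other-dementia gene: pathogenic/likely
   pathogenic/VUS, conflicting-with-pathogenic-votes, a definite
   dementia-related HGMD annotation, or likely-pathogenic consensus.
4. **Benign tier** — known benign/likely benign, novel likely-benign
   consensus, or conflicting interpretations that are mostly benign.

The `prior_risk_report` literature flag exists because curated tables
distinguish identically-annotated variants by prior literature: a
benign-in-ClinVar variant that earlier reports described as possibly
pathogenic is treated as a risk candidate, while the same annotation
without such a report stays benign. The flag is data (a column in the
knowledge table), not code, so users can apply their own literature
judgement. Benign and likely-benign are reported as distinct categories but
should be compared as one tier: curated tables use the two labels
interchangeably for identically-annotated variants.

Per patient, the explained-status union has four sources: a causative
allele (diagnostic or contributor variant in a causative gene), APOE ε4/ε4
homozygosity, a moderate-risk allele (risk-factor variant in *APP*,
*PSEN1*, *PSEN2* or *TREM2*), and a weak-risk variant in a non-AD dementia
gene. Whether weak-risk variants alone count as "explaining" is genuinely
arguable; it is a flag (`include_weak_risk`, default `TRUE` to match the
four-source union). Percentages are rounded half-up to two decimals —
base R's round-half-to-even would change printed second decimals — and are
always recomputed from counts, never stored.

## APOE and family history

APOE ε alleles are haplotypes of rs429358/rs7412: T–C → ε3, T–T → ε2,
C–C → ε4, C–T → ε1. Unphased double heterozygotes (C/T at both sites) are
ambiguous between ε2/ε4 and ε1/ε3; they resolve to ε2/ε4 — ε1 is
vanishingly rare — and carry an explicit `ambiguous` flag rather than being
resolved silently. Unresolved genotypes are counted in an `unknown` bucket,
never dropped. The modified Goldman score is stored as its raw label
(S1, S1.5, S2, S3, S3.5, none); the strong (S1/S1.5) / moderate
(S2/S3/S3.5) / sporadic strata are always derived, never stored, so the two
can never disagree. The CSF AD-profile gate (p-tau/Aβ42 > 0.108 and
Aβ42/Aβ40 < 0.68) uses strict inequalities, so boundary values fail; a
missing ratio gives an indeterminate result distinct from a negative one.
The early-onset bound (onset < 65 years) is a configurable inclusion
parameter, not a hard-coded constant.

## The synthetic cohort generator

`generate_cohort()` emulates the study design the pipeline targets: a
~100-patient panel-sequenced EOAD cohort with planted variants in every
clinical category, APOE SNP genotypes, Goldman family-history labels, and
filter decoys. Defaults mirror the reference cohort profile: n = 102,
45.1% familial with 21.7% of familial cases strong, age at onset
56.88 ± 5.84 years (the generator compensates the < 65 truncation so the
realised mean matches the configured one), and category fractions equal to
the reported carrier fractions (8.8% diagnostic, 2.0% contributor, 7.8%
moderate-risk, 12.7% weak-risk, 7.8% APOE ε4/ε4). Depth is Poisson with
mean 50 — typical for amplicon panels — and heterozygous allele balance is
normal around 0.5 with SD 0.05, truncated (and integer-clamped) into the
selection band so that a planted variant cannot be lost to rounding noise.

Planted knowledge rows are constructed to be *deterministically sufficient*
for the intended category: a diagnostic patient receives either a
ClinVar-pathogenic causative-gene variant or a novel one with four damaging
verdicts; a contributor patient is forced familial (a scenario with
contributors but no familial patients is rejected as infeasible) and
receives a VUS whose reference count (1 allele) guarantees an FDR-adjusted
p below 0.05 at the default cohort size; risk-factor and weak-risk patients
receive VUS in *TREM2* and *MAPT*; decoys violate exactly one filter
criterion each. All randomness flows from one seed through a single stream
in a fixed generation order, so a seed fully determines the bundle,
byte-for-byte on disk.

What the generator does **not** emulate: linkage and haplotype structure,
population stratification, caller error profiles beyond depth/balance
noise, multi-variant interactions, or realistic gene-level mutation rates.
Passing the end-to-end recovery tests therefore demonstrates that the
pipeline's logic is faithful to its rules, not that the rules are robust to
every artefact of real sequencing data.

## Problem sizes and runtime choices

The test suite validates the Fisher implementation by exhaustive
enumeration over all 2×2 tables with margins ≤ 30 (about 10^5 tables), BH
over 10,000 random p-vectors, the filter contract over 1,000 random
decoy-bearing cohorts, and planted-fraction recovery over 200 synthetic
seeds at n = 102 — sizes chosen so the whole suite runs in about a minute
on one core while the recovery experiment still pools ~20,000 synthetic
patients.

## Known limitations

* Published per-variant adjusted p-values are not reproduced (see the
  enrichment section); the statistics are validated against oracles instead.
* The benign/likely-benign distinction is not meaningful across curated
  tables and should be read as one tier.
* Fixture mode keys variants by (gene, HGVS-c); it cannot detect that two
  different HGVS strings denote the same genomic change. VCF mode trims
  alleles but does not left-align against a reference genome.
* The Guerreiro-style grading of *PSEN1* variants referenced in the
  dementia literature is not emulated; only the consensus label is exposed.
* Carrier-level family-history strength drives the contributor rule; if
  metadata and knowledge tables disagree on a carrier's score, the
  knowledge table wins in fixture mode.
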