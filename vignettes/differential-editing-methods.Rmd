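---
title: "Methods: detecting and comparing A-to-I RNA editing between cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and comparing A-to-I RNA editing between cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editdiff)
```

## The problem

Adenosine deaminases acting on RNA (ADAR enzymes) convert adenosines to
inosines in double-stranded RNA. Reverse transcription and sequencing read
inosine as guanosine, so an edited position appears in RNA-Seq as an A>G
mismatch against the genome (or T>C on the forward reference when the
transcript comes from the minus strand). When matched genomic DNA is not
available, candidate editing sites must be mined from the RNA alignments
alone and cleaned of the two main impostors: genomic polymorphisms and
sequencing/alignment artifacts. `editdiff` implements that workflow for a
two-cohort design (control vs case) and asks two questions:

1. **Per site** — at which known editing positions does the fraction of
   edited individuals differ between cohorts?
2. **Per sample** — does the overall editing burden (number of detected
   A-to-I sites per sample, normalized to library size) differ between
   cohorts?

## Detection model

Candidate detection is deliberately *threshold-based*, not inferential: at
every reference position we count the A/C/G/T bases of reads surviving a
strict filter stack, and emit a candidate when coverage and variant
support reach configurable minima. The filters (see `filter_config()`)
and their defaults are:

| parameter | default | rationale |
|---|---|---|
| `min_base_quality` | 30 (phred) | base-call error ≤ 0.1% where mismatches are evidence |
| `min_mapping_quality` | 60 | the unique-mapping MAPQ of spliced aligners such as hisat2; treated as a *minimum*, not an equality, so other uniquely-mapping scores pass |
| `exclude_duplicates` | on | PCR duplicates inflate variant support |
| `exclude_multimappers` | on | secondary/supplementary flags, plus NH > 1 when the tag exists |
| `require_concordant_pairs` | on | discordant pairs are enriched in mapping artifacts |
| `min_coverage`, `min_variant_reads` | 1, 1 | maximal sensitivity; cohort-level statistics, not per-sample calls, carry the inference |

Three numerical conventions matter and are fixed:

* **Overlapping mates.** A fragment whose two mates both cover a position
  contributes **once**: the higher-quality base wins; on a quality tie the
  first mate wins. Double-counting a single cDNA molecule would bias
  variant frequencies toward whichever allele the fragment carries.
* **Substitution ordering.** A call's substitutions are listed by
  descending read support, ties broken alphabetically; the reported
  variation frequency is support of the most-supported substitution over
  filtered coverage. All substitution types are retained in the raw call
  table for diagnostics; only strand-resolved A>G calls enter the editing
  analysis.
* **Strand.** Aligners do not annotate transcript strand, so strand is
  taken from the gene annotation: a call gets the strand of the unique
  overlapping gene; positions covered by genes on both strands (or none)
  are marked unknown and excluded downstream. This is the simplest
  deterministic rule; it sacrifices positions in overlapping antisense
  genes rather than guessing. For minus-strand genes the observed T>C is
  complemented to A>G before classification.

Positions with an ambiguous (N) reference base are skipped with a message;
coverage is always exactly A+C+G+T (N base calls are never counted).

## Filtering cascade

Candidates flow through: strand/A-to-I classification → restriction to
protein-coding intervals → exclusion of catalogued SNV positions →
split by known-editing-site membership. The filters commute (this is
property-tested), so the order is a logging convention, not a modelling
choice. Two branches leave the cascade:

* the **known-matched branch** (position present in the
  known-editing-site catalog with substitution AG and a compatible
  strand) feeds the per-site differential test — restricting to
  catalogued sites keeps the tested family small and enriched for true
  editing;
* the **all-sites branch** (catalogued or not) feeds the burden
  comparison, where rare residual SNVs matter little because they are not
  shared across individuals the way editing sites are.

SNV exclusion is **positional** by default: a catalogued polymorphism
disqualifies the position regardless of allele, which is the conservative
choice when catalog alleles and strand-resolved calls are hard to compare.
`match_alleles = TRUE` restricts exclusion to allele-concordant records.

## Per-site differential statistics

For site *j*, let \(k_{1j}/n_1\) and \(k_{2j}/n_2\) be the edited-sample
fractions in the two cohorts ("edited" = the site survived that sample's
calling and filtering). The null of equal editing prevalence is tested
with the **two-sided Fisher exact test** on
\(\begin{pmatrix} k_{1j} & n_1-k_{1j} \\ k_{2j} & n_2-k_{2j} \end{pmatrix}\),
two-sided by the standard point-probability summation convention (sum of
the probabilities of all tables, under the hypergeometric null with fixed
margins, no more probable than the observed one). The implementation is
validated against exhaustive table enumeration for every margin with
\(n_1+n_2 \le 12\).

Multiplicity is handled by the **Benjamini–Hochberg step-up** adjustment,
\(\tilde p_{(i)} = \min_{j \ge i} \left( p_{(j)}\, m / j \right) \wedge 1\),
with the family size *m* equal to the number of tested sites.
`bh_adjust()` accepts `m_total` larger than the number of supplied
p-values for the case where only the smallest members of a family are at
hand; FDR control is the appropriate error rate for a discovery screen,
and a Bonferroni option (`method = "bonferroni"`) is kept for users who
want family-wise control. The step-up recursion is validated against an
independent running-minimum oracle.

## Burden comparison

Each sample's burden is its count of detected coding A-to-I sites; since
deeper libraries discover more sites, the primary comparison uses
**sites per million mapped reads** (raw counts are always reported
alongside). Cohorts are compared with the two-sided two-sample
Wilcoxon/Mann–Whitney rank-sum test — exact enumeration when the pooled
size is ≤ 25 with no ties, the normal approximation with tie and
continuity corrections otherwise. Normalization by library size is linear
in read count; it does not model saturation of site discovery, which is a
known limitation for strongly unequal library sizes.

## The synthetic-data generator

`simulation_config()` + `simulate_cohort()` build a complete, seeded
test-bed: a genome of alternating-strand single-exon genes (FASTA + GTF),
a known-editing-site catalog covering a configurable fraction of planted
sites, an SNV catalog (VCF), and per-sample coordinate-sorted BAMs of
proper 100 nt pairs (MAPQ 60, constant base quality 35). The generative
model per sample:

* site *j* is edited in the sample with probability \(\pi_{g}\) (its
  group's prevalence); given edited, each overlapping read carries the
  edited base independently with rate \(\varphi\);
* heterozygous SNVs put the alternate allele on each *fragment* with
  probability 0.5 (homozygous: always) — SNV alleles are deliberately
  chosen to mimic A-to-I so that only the catalog filter can remove them;
* every emitted base is replaced by a uniformly chosen wrong base with
  probability \(\varepsilon\) (default \(10^{-3}\), a typical
  post-filter Illumina error rate);
* per-sample library size varies through a uniform coverage multiplier
  (default 0.7–1.3 around a mean coverage of 50).

Default cohort sizes are 44 control and 29 case samples, matching the
scale of postmortem brain RNA-Seq cohorts this design targets; the default
site panel is 5 differential sites (prevalence 0.9 vs 0.2, \(\varphi=0.8\))
over 40 null sites (prevalence 0.5, \(\varphi=0.5\)) — effect sizes at
which the exact-test power for a 20+20 cohort at coverage 50 is
essentially 1, so recovery failures indicate bugs, not bad luck. Reads are
emitted already aligned (ungapped 100M pairs placed to need no clipping)
because alignment itself is out of scope; consequently the simulator does
not exercise splicing, clipping, indels, quality decay, GC bias or
alignment error, and passing tests say nothing about those failure modes
on real data. Mates overlap only when `insert_size < 2 * read_length`,
which the tests use to exercise the fragment-deduplication rule.

`simulate_profiles()` is a second, statistical-layer generator that draws
per-sample edited-site indicators directly from the same Bernoulli
prevalences (thinned by the analytic detection probability
\(1-(1-\varphi)^{c}\), ≈ 1 at default coverage) without emitting reads.
It exists for replicate-heavy calibration checks — e.g. the 200-replicate
null false-discovery experiment — where read emission adds hours of
runtime but no information about the property under test. Library sizes
at this layer are drawn uniformly from 20–60 million reads to mimic
production-scale sequencing.

Every stage seeds its own RNG substream derived from the configuration
seed, so outputs are byte-identical across runs and independent of
evaluation order.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run: the read-level pipeline on a
20 control + 20 case cohort (genome 5 kb, coverage 50, 45 sites); 200
statistical-layer null replicates for false-discovery calibration; and a
44 + 29 statistical-layer cohort with 200 sites at prevalence 0.5 vs 0.35
for the burden-direction check (rank-sum power ≈ 0.99 at these settings).
These sizes were chosen as the smallest at which the tested properties
have essentially deterministic outcomes.

## Known limitations

* Strand inference relies entirely on annotation; unannotated or
  bidirectionally transcribed loci are dropped.
* No repeat/Alu annotation, hyper-editing cluster detection, realignment,
  indel handling or base-quality recalibration.
* "Edited sample" is binary (≥ 1 supporting read); no per-site editing-
  frequency model (e.g. beta-binomial) and no covariate adjustment — the
  exact test conditions only on group labels.
* The burden normalization is linear in library size and ignores
  discovery saturation.
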