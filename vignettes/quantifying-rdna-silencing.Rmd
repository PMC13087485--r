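---
title: "Quantifying uniparental rDNA silencing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying uniparental rDNA silencing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnaquant)
```

## The problem

Allopolyploid plants carry two (or more) parental chromosome sets, each with
its own ribosomal RNA gene arrays. Nucleolar dominance — silencing of one
parent's 35S rDNA — is classical; whether the 5S component of the ribosome is
silenced the same way is much harder to see, because homeologous 5S rRNAs are
nearly identical. The opening the package exploits is that in some systems the
parental 5S genic regions diverge enough to carry a handful of *diagnostic
SNPs*: fixed differences that attribute any sequencing read to one subgenome.

`rdnaquant` implements the full quantification chain for a two-variant system
modeled on *Cardamine* allopolyploids, whose parental 5S variants differ at 7
of 120 genic positions (94% identity), sit in monomers of roughly 720 bp
(*C. amara*-like "type 2") and 650 bp (partner "type 1"), and are present at
hundreds to thousands of copies per 1C:

1. **Expression proportions.** Transcriptome reads are mapped to a parental
   genic reference; subgenome shares are estimated two independent ways —
   pooling allele counts at the diagnostic sites, and classifying
   reconstructed read variants into parental clades on a neighbor-joining
   tree.
2. **Dosage.** Genomic reads give the genome proportion (GP) of the rDNA,
   which converts to genome space and copies per 1C and is split by
   subgenome with the same diagnostic sites.
3. **Array structure.** Long reads are scanned for tandem genic hits; the
   spacing of hits recovers the monomer period and the per-read parental
   family.

Comparing (1) and (2) is the crux: a parent whose genomic share is large but
whose transcript share is a few percent is epigenetically silenced, not
deleted.

## Models and estimators

### Read mapping

Reads are aligned by exact Smith–Waterman local alignment under a fixed
scheme: match +1, mismatch −2, insertion −3, deletion −3. An alignment is
accepted when the aligned fraction of the read is at least the *length
fraction* and its identity (matches / alignment columns) at least the
*similarity fraction* (0.8). The length fraction is 0.9 for 5S transcript
work and 0.5 for 26S and for genome-proportion mapping (see below). Because
reference sets here are tiny (one or two genes of ≤ 3.4 kb), exhaustive DP
against every reference is affordable and makes mapping fully deterministic;
co-optimal alignments are resolved by smallest reference start, then smallest
read start, then shortest alignment. An optional exact k-mer prefilter
(default k = 11 in the dosage pipeline, off elsewhere) skips reads that share
no seed with any reference; reads that share a seed go through the identical
exhaustive scoring, so the filter can only skip reads that the thresholds
would reject anyway in practice — a test asserts prefilter/no-prefilter
agreement on simulated pools.

### SNP pooling

At every diagnostic site with sufficient depth, reads carrying the parent-A
or parent-B allele are counted; other bases are tallied separately and
deletions are never counted as alleles ("countable" reads are aligned reads
with a non-gap base at the site). The primary estimator pools counts over
sites, `p_B = N_B / (N_A + N_B)`; the denominator is classified evidence
only, which is the convention that reproduces the published table rows
(e.g. 66 and 444 of 519 total reads render as 13% / 87% only over the 510
classified reads). Per-site proportions are reported alongside for
heterogeneity diagnostics; whether a published figure pooled or averaged
per-site values is not stated, so both are available. Variant *calling*
(distinct from proportion estimation) applies descriptive thresholds —
coverage ≥ 400, supporting count ≥ 40, frequency ≥ 5%, with a low-input
preset of 100/10/5% for poorly represented libraries — with no
multiple-testing control, since these are filters, not tests.

### Clade classification and diversity

Reads overlapping the genic reference are trimmed to their aligned genic
interval (projected onto reference coordinates, minus strand normalized) and
kept when longer than 110 nt; pools are subsampled to about 200–600 reads.
Identical sequences over the common genic window collapse into variants.
Distances are pairwise mismatch fractions transformed with the Jukes–Cantor
model, `d = -(3/4) ln(1 - (4/3)p)`; since all sequences are coordinate-
trimmed to one frame, no multiple alignment is needed — for near-identical
120-mers the two are equivalent. A canonical Saitou–Nei neighbor-joining
tree is built over variants plus the two parental references, and each
variant is assigned to the nearer reference by tree path distance.

Two operational choices here were genuinely open:

* **"Rare, highly mutated" exclusion.** The protocol excludes rare
  (< 5% of input reads) highly mutated sequences outside the main clades but
  gives no distance threshold. We operationalize "outside both main clades"
  as tree distance to *both* references exceeding half the
  reference-to-reference path distance; only sequences beyond both clades
  can be excluded, and never an abundant variant.
* **Bootstrap.** Resampling support values never change read assignment
  (assignment depends only on the point-estimate tree), so they are omitted
  from classification and available only for display.

Haplotype diversity uses the modified Nei estimator
`h = (n/(n-1)) (1 - Σ (x_i/n)^2)` over variant counts, with the read count
`n` replacing the `2n` of diploid genotype data — read pools are haploid
observations. The companion "major variant share after exclusion of
singletons" column is computed as `major / (n - singleton reads)`; published
versions of this column cannot be reproduced exactly from printed counts
alone, so the convention is documented rather than claimed exact.

### Dosage

GP = 100 × mapped / total over all QC-passed input reads (single-end), then
genome space = GP/100 × GS and copies per 1C = GP/100 × GS / gene length,
with GS the 1C genome size supplied by the user (C-value databases are the
usual source; tetraploid GS values are interpreted per 1C). The mapping for
GP uses length fraction 0.5, not 0.9: with a 120-bp reference and ~120-nt
reads, demanding 90% of the read inside the gene shrinks the accepted
start-window to about a third of the gene length and deflates GP (hence
copies) threefold, while at 0.5 the window is gene length + 1 positions and
the estimator is unbiased — the only choice consistent with round-tripping
known copy numbers. Subgenome splits multiply total copies by the pooled
genomic diagnostic-site proportions and therefore conserve the total
exactly.

### Long-read arrays

Each parental genic reference is anchored by exact 12-mers to both strands
of a long read; each anchored window is aligned locally, hits covering at
least 90% of the gene are kept, and overlapping candidates are resolved
greedily by score (tandem genic hits are separated by the intergenic spacer,
so accepted hits never overlap). Reads are retained when longer than 2 kb
with at least one hit at ≥ 90% identity. The monomer period is the median
spacing of adjacent hit starts — for tandem genic repeats this carries the
same signal as the traditional self-dotplot, deterministically; reads with
hits on both strands are flagged irregular and excluded from period
statistics. A read's family is the majority of its per-hit best-parent
assignments (higher identity of the hit segment against each parental gene).
With standard rounding a 20:2 mixture renders as 91%/9%.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions, not tunable knobs:

| parameter | default | rationale |
|---|---|---|
| genic length | 120 bp | 5S gene length |
| diagnostic sites | 7 | observed divergence of the two variants (94% identity) |
| deamination bias | 0.7 | > 70% of the substitutions are C→T/G→A |
| monomer lengths | 720 / 650 bp | the two monomer classes seen in long reads |
| copies per 1C | 500 / 2000 | inside the observed ranges 114–543 and 580–4930 |
| transcript share of parent B | 0.976 | ≤ 4% minor-parent transcripts |
| read length | 120 nt | short-read regime in which near-complete 5S sequences are reconstructible |
| substitution error | 0.2% | a stated assumption; no per-base error model is published for these data |
| long reads | 22 of 2–20 kb | the retained long-read set size |
| genome size | 2.4 × 10⁸ bp | small-crucifer scale 1C value |

Parent A's genic region is random DNA; parent B applies exactly `n_diag`
substitutions, a ≥ `deamination_bias` fraction of them C→T or G→A.
Two placement constraints emulate the even distribution of the real
polymorphic sites and matter numerically: sites keep ≥ 3 bp from the genic
ends and ≥ 8 bp from each other. A mismatch needs three flanking matches to
survive local-alignment clipping, so a site flush with a molecule end — or
two sites clustered at a terminus — would be systematically unreadable from
the minor parent's reads, a geometry the modeled system does not have.

Transcript templates are genic-only (5S transcripts are ~120 nt, so no
spacer carryover); transcript reads therefore cannot exceed the gene length.
Genomic reads are drawn uniformly per base pair over a genome containing
both tandem arrays: the probability of hitting an array is
copies × monomer length / GS, positions inside the monomer are uniform
(arrays are circularized and linearized with a random phase, mimicking
random fragmentation), and everything else is random background sequence.
Uniform-per-bp sampling is what makes the GP → copy-number chain consistent;
the read count *ratio* between parents consequently follows array bp, while
the genic-overlapping (mapped) reads follow the copy ratio, which is what
the subgenome split measures. Long reads are k ≥ 3 tandem monomer copies
with a random phase, truncated to a length drawn from the configured range.
Errors are iid substitutions on both strands (an indel-rate hook exists,
default off — the short-read analyses tolerate far more divergence than
realistic indel rates introduce, so simulating them adds no tested
behavior). Identical seed and configuration reproduce every output
byte-for-byte.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: PCR duplicates, GC and coverage bias,
quality-score decay, chimeric or inverted long reads, intra-parental 5S
paralog variation beyond the consensus, and partial rDNA pseudogenes.
Real libraries also carry organellar and repeat reads that are neither rDNA
nor uniform background; they are absorbed here into the background class.

## Numerical choices

* Coordinates are 0-based half-open internally; all reports are 1-based.
* Percentages round half away from zero at 0 or 1 decimals, matching the
  published tables' renderings; 20/22 is therefore printed 91%, where the
  source text prints 90% (truncation or loose rounding of 90.9).
* Jukes–Cantor distances saturate at p ≥ 0.75 and are capped at a
  configurable value (default 5) with a warning.
* NJ ties in the Q criterion break on the lexicographically smallest sorted
  label pair; negative branch lengths are clamped to zero with the deficit
  moved to the sister branch, so leaf-to-leaf path lengths are preserved.
* Identical parental references yield an empty diagnostic set with a
  warning, and proportion estimation then fails loudly ("no informative
  sites") rather than silently returning NaN.
* IUPAC ambiguity codes in references are rejected, not resolved: the
  references are consensus sequences, and a silent resolution could flip a
  diagnostic allele. Unequal-length genic references are globally aligned
  with free end gaps before site derivation (not needed for the 120/120
  case, but the contract must not crash).
* Report provenance embeds package version, seed and the resolved
  configuration; wall-clock timestamps are opt-in because byte-identical
  reruns take precedence.

## Problem sizes

The shipped tests and the acceptance script run at desk scale by design:
transcript pools of 327–5000 reads, genomic pools of 2 × 10⁵ reads for the
acceptance script and 10⁶ reads for the copy-number recovery test,
classification subsamples of ≤ 600 reads, and 22 long reads of 2–12 kb.
These sizes put Monte Carlo error well inside the acceptance bands (binomial
SE at the configured depths) while keeping the full suite around a minute on
one core.

## Known limitations

* The attribution model assumes exactly two parental variants with fixed
  diagnostic alleles; intra-parental polymorphism at a diagnostic site is
  handled only downstream, by the ≥ 5% frequency filter.
* Sites within ~3 bp of a read or gene end lose minor-allele evidence to
  alignment clipping; the real protocol's mapper behaves the same way, but
  it means edge sites should not be relied on in new systems.
* GP-based copy numbers inherit the full uncertainty of the genome-size
  input, which is external to the package.
* The clade classifier trims all sequences to the *common* genic window of a
  read set; pools of very ragged reads shrink that window and can merge
  variants whose differences fall outside it. The > 110 nt length filter
  exists precisely to keep the window wide.
* Family classification of long reads uses genic identity only; spacer-level
  subfamilies (e.g. distinct IGS families within one parent) are out of
  scope, as is consensus monomer assembly.
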