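---
title: "Methods: comparative plastome analysis with plastomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome analysis with plastomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomics)
```

## Scope and model

Land-plant plastomes are circular molecules of roughly 120–170 kb with a
conserved quadripartite layout: a large single-copy region (LSC), a small
single-copy region (SSC), and two identical inverted repeats (IRa, IRb)
separating them. Comparative studies of a genus-level panel typically report
(i) region lengths and gene inventories, (ii) base composition and strand
skews, (iii) codon usage (RSCU) and cross-taxon codon-preference contrasts,
(iv) microsatellite (SSR) content, (v) gene placements at the four region
junctions, and (vi) summaries of predicted C-to-U RNA editing. `plastomics`
implements each of those stages over a shared record model, plus a synthetic
genome generator that makes every stage testable against exact ground truth.

Coordinates are 0-based half-open on the top strand throughout; GenBank's
1-based inclusive convention is converted only at the file boundary. This
makes junction arithmetic (distances, extensions, overlaps) exact integer
arithmetic with no ±1 ambiguity. Records are treated as circular unless a
file declares them linear.

## Quadripartite detection

`detect_partition()` recovers the structure from sequence alone: the IR pair
is defined as the longest pair of *disjoint, exact* reverse-complement
repeats on the circle, found by seed-and-extend over unit-step 31-mers on
the doubled sequence (a run of consecutive matching seeds is exactly a
maximal match — any extension by one base would imply one more matching
seed). Design choices that matter:

* **Exactness.** Mismatch tolerance is 0. Real plastome IRs are
  near-perfect, and junction statements like "the IRb extends 110 bp into
  rps19" presuppose a single well-defined boundary. A tolerance knob could
  be added later but would make every junction number alignment-dependent.
* **Ties are errors.** If two disjoint candidate pairs tie at the maximal
  length but induce different partitions, detection stops with an error
  listing both. A silent arbitrary choice would corrupt every downstream
  junction report.
* **`min_ir` defaults to 1000 bp** so that small dispersed repeats cannot
  masquerade as the IR. Tests use smaller values on small toy genomes.
* **Canonical orientation.** The longer single-copy gap is the LSC; IRb is
  the repeat copy immediately downstream of the LSC; junction positions
  JLB, JSB, JSA, JLA are the first bases of IRb, SSC, IRa and LSC. The
  partition is reported in the input record's coordinates together with the
  rotation that places the LSC start at the origin
  (`canonicalize_partition()` applies it).

The test suite checks detection against an independent quadratic oracle that
scores anti-diagonal runs of the full base-complementarity matrix, on random
circular sequences (with and without planted repeats) and on generator
output, where recovery must be exact.

## Composition and skews

AT-skew = (A−T)/(A+T) and GC-skew = (G−C)/(G+C). Both are scale-free, so
`composition()` accepts either a sequence or a named count/percentage
vector; recomputing published skews from printed percentages is therefore a
legitimate desk check, and the shipped eight-species reference table
(`sedum_reference_stats()`) reproduces all sixteen printed skews at 5
decimal places. A skew with a zero denominator is reported as missing, never
as 0. N bases are excluded from denominators and counted separately. Report
tables round percentages to 2 dp and skews to 5 dp (the precision of the
published tables); full precision is kept internally. The published
"Average" row is not reproducible as the arithmetic mean of the printed
per-species values, so it is excluded from all checks.

## Codon usage, RSCU and SVCs

Codon counting assembles each CDS from its exon parts in transcript order
(minus-strand parts reverse-complemented), under the bacterial/plant-plastid
genetic code (NCBI table 11). Table 11 translates identically to the
standard code; its wider initiator set is why start codons are audited
separately (`start_codon_inventory()`) and alternative initiators such as
ACG/GTG are counted as their sense codon rather than silently becoming Met.

For codon *i* in a synonymous family of size *k*,
RSCU_i = x_i / mean(x_family). Families with zero total get missing values
— not 0 and not 1 — and missing never participates in downstream
classification, because a preference statement about an unobserved family
is meaningless. A codon is a *significantly variable codon* (SVC) when at
least one taxon prefers it (RSCU > 1) and at least one does not
(RSCU ≤ 1); single-codon families (ATG, TGG) and stops never qualify. The
minority preference class defines the codon's exclusivity; an even split is
flagged rather than assigned. No minimum-count filter is applied by
default. IR-duplicated genes count per annotated copy by default;
`dedupe_ir = TRUE` collapses them, and both conventions are exposed because
published panels rarely state which was used.

## SSR scanning

A locus is a maximal perfect tandem run of a primitive 1–6 bp motif meeting
the repeat thresholds 8 / 4 / 4 / 3 / 3 / 3 for unit lengths 1–6 — the
MISA-style criteria used in plastome surveys. Primitivity ensures a run is
reported once at its smallest unit ((AT)₆, never (ATAT)₃); runs are trimmed
to complete units anchored at the run start; non-ACGT characters break
runs. In the rare case where two qualifying runs of different unit lengths
overlap, the earlier-starting (then longer, then smaller-unit) locus wins,
so reported loci never overlap — a deterministic rule stated here because
no published convention exists. Compound/interrupted SSRs are out of scope.

Whole-plastome scanning removes one IR copy first, on the linearized
LSC + IRb + SSC sequence. IRa (the copy after the SSC) is the removed copy
because that leaves the retained sequence contiguous; loci that span a
junction are assigned to the region containing their start. The scanner is
tested against an independent PCRE-backreference enumerator and against
planted SSR sets, where recall and precision must both be 1.

## Junction analysis

`junction_report()` intersects the *sequence-derived* partition with
annotation coordinates: an IR-extension figure is a statement about the
sequence-level boundary, so it must not depend on annotation conventions
alone. For each junction it reports spanning genes (bases on each side) and
genes within a window (default 1000 bp, the typical junction-plot context).
Multi-part genes are measured on their genomic span — introns included —
matching junction-diagram semantics, while `gene_overlap()` uses the union
of parts. Pseudogene fragments (the truncated ycf1 copy, the rps19 mirror
fragment) are included and flagged, and `compare_junctions()` turns named
predicates ("rps19 spans JLB with ≥ 100 bp inside the IRb") into a
taxon-by-diagnostic matrix.

## Editing summaries

Editing-site prediction is external to this package: homology-based
predictors with a confidence cutoff produce site tables, and reproducing
their internals is neither possible nor useful offline. `plastomics`
validates the canonical sense-strand representation (the two codons differ
exactly at the stated position, C→T), applies the score cutoff (default
0.8, kept even for sites with missing scores), and computes the summaries a
comparative paper reports: per-gene counts, codon-position fractions, the
amino-acid conversion matrix, and amino acids with multiple conversion
types. Filtering is monotone in the threshold and pooled summaries equal
the sum of per-taxon summaries; both are property-tested.

## Supermatrix preparation

`select_shared_pcgs()` intersects non-pseudo PCG names across records,
collapses IR duplicates to the longest copy (ties to the first in genome
order) and excludes genes failing translation sanity, with per-taxon
reasons. Multiple alignment is external (MAFFT or similar);
`concatenate_alignments()` then matches rows strictly by taxon label,
refuses ragged or mismatched inputs rather than gap-filling, and emits the
matrix in FASTA and relaxed PHYLIP plus a RAxML-style partition file. Gene
order defaults to the order given (the analysis drivers use alphabetical).

## The synthetic generator

`make_plastome()` emits a genome built as LSC + IRb + SSC + IRa with IRa
the exact reverse complement of IRb by construction, so planted content in
either repeat appears correctly mirrored in the other — which is precisely
how the truncated ycf1 copy and the rps19 fragment arise in real genomes.
Junction genes are placed with exact bp on each side of their junction;
where two planted genes legitimately share sequence (ndhF's tail inside the
IRb against the mirrored ycf1), the first writer wins and the annotation
overlap is preserved. CDSs are sampled i.i.d. from a codon profile with
forced ATG start, sampled stop and no internal stops; the default profile
makes leucine the most frequent amino acid, cysteine the rarest, and gives
every synonymous family a clear A/T-ending preference (within-family
weights 1.6 vs 0.4) so expected RSCU values sit well away from the
preference boundary at 1.

Background sequence is sampled base-wise at each region's GC target and
then *repaired by rejection*: the emitted genome contains exactly the
planted SSR set (accidental runs above threshold are resampled, planted
runs are protected and flanked by extension-blocking bases) and no stray
inverted repeat of half the planted IR length or more; the four bases
flanking the IR pair are constrained so the repeat cannot extend by chance.
This is what makes recall = precision = 1 assertions meaningful. Everything
is deterministic in the seed, to the byte.

Default parameters are the study conditions the package emulates: LSC
81,700 bp, SSC 16,700 bp, IR 25,600 bp (within the published 148.6–150.7 kb
range), GC targets 35.7/31.9/43% for LSC/SSC/IR, the conserved junction
layout rps19 (279 bp, 110 bp inside IRb), ndhF (2241 bp, 40 bp inside IRb)
and ycf1 (5598 bp spanning SSC/IRa, giving a 40 bp truncated-copy overlap
with ndhF, inside the 34–59 bp range reported for such overlaps), 60 coding
genes plus one IR-duplicated gene, and eight planted SSRs dominated by A/T
motifs. What the generator does *not* emulate: realistic gene density and
intergenic structure, tRNA/rRNA genes, introns beyond multi-part interval
support, indels, rearrangements, or background SSR abundance (real plastomes
carry 129–150 SSRs; generator output carries exactly the planted set, by
design). Passing tests therefore demonstrate correctness of the arithmetic
and the detection/scanning logic, not robustness to annotation noise or
repeat degeneration in real data.

## Problem sizes and numerical choices

The test suite runs its oracle comparisons at sizes where the quadratic
references are comfortable: 100 random circular sequences of ≤ 2 kb (plus
50 seeded small synthetic genomes) for partition detection, 200 random
sequences of ≤ 5 kb for the SSR scanner, panels of ≤ 10 taxa for SVC
enumeration, and 50 synthetic genomes for junction recovery. The analysis
drivers and the acceptance script run the full-size eight-taxon panel at
the default ~150 kb conditions. RSCU family sums are asserted at 1e-12;
region GC recovery on generator output at ±4 percentage points (≈3 σ for
the region lengths used); codon-profile recovery at ±3 percentage points,
which absorbs the handful of codons perturbed by SSR repair.

## Known limitations

* IR detection assumes exact repeats; genomes with degenerate or lost IRs
  (a real phenomenon in some lineages) yield a "no quadripartite structure"
  error rather than a gradient description.
* The GenBank writer emits a minimal feature table (gene/CDS/tRNA/rRNA with
  `/gene` and `/pseudo`), sufficient for round-tripping this package's
  model, not a general-purpose GenBank serializer.
* SSR scanning of the linearized sequence cannot report a run spanning the
  SSC/IRa boundary of the original circle; published pipelines have the
  same edge behaviour, and totals are treated as tolerance checks, not
  exact, when comparing across tools.
* Editing-site counts depend on the external predictor's internals and are
  validated only as summaries of a given table.
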