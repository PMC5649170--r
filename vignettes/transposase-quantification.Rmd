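---
title: "Quantifying transposase abundance and expression in size-fractionated meta-omes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transposase abundance and expression in size-fractionated meta-omes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Insertion sequences (ISs) are the simplest mobile genetic elements: a
transposase ORF of roughly a kilobase flanked by inverted repeats. In
environmental shotgun data, transposase content and transposase
*transcription* vary strongly between habitats, between cell-size fractions
(free-living versus particle-associated or colony-forming organisms),
and between bacterial groups. `tnpquant` implements a complete desk-scale
pipeline for this kind of analysis: identify transposase stretches on
assembled contigs from translated-search hits, quantify them at several
normalization levels for DNA (metagenome) and RNA (metatranscriptome)
samples alike, and test the contrasts of interest — with a
synthetic-community generator providing known ground truth for every stage.

## The identification model

Translated search (blastx-style) of contigs against a curated transposase
protein set typically produces many overlapping local alignments over the
same nucleotide stretch. The caller proceeds in three steps.

**Footprints.** Hits that survive the E-value filter (strict
`evalue < 1e-6` by default) are merged per contig and strand into
*footprints*: connected components of the interval overlap graph. Intervals
that merely touch end-to-start are treated as connected; since hit
coordinates are 0-based half-open, this matches the usual "no gap between
consecutive hits" reading and the behaviour of `IRanges::reduce()`.
Footprints are per-strand by default because opposite-strand hits represent
different ORFs; `merge_across_strands = TRUE` is available.

**Iterative highest-score resolution.** Within a footprint the occupying
transposase(s) are assigned greedily. Among the hits that intersect a
still-unassigned stretch of at least `min_residual_nt` (default 30 nt,
about 10 aa — below any meaningful transposase fragment), the hit with the
highest bit score claims its intersection with the unassigned region; ties
break by lower E-value, then longer query interval, then lexicographically
smaller reference id, so resolution is fully deterministic. Each disjoint
piece of the claimed intersection becomes its own call segment. The loop
ends when no sufficiently long unassigned stretch is touched by any hit.
The re-ranking uses the already-collected hits rather than re-running an
aligner over the footprint; the ranking information is the same and the
result is deterministic. The implementation is interval-arithmetic based
and is checked in the test suite against an independent brute-force
implementation that re-scans every hit against a per-base mask each
iteration.

**Filters.** A call's amino-acid coverage is the number of reference
residues its segment aligns — prorated from the originating hit under the
default `coverage_mode = "segment"` (an alternative `"hit"` mode scores the
full original hit) — divided by the reference ORF's amino-acid length.
Calls covering at least 30% are retained, and the boundary is inclusive:
90/300 stays, 89/300 goes. The E-value cutoff is exclusive: a hit at
exactly `1e-6` is rejected.

## Normalization levels

All quantities derive from per-sample profiles built from an
interval-based read map (contig, start, end, sample, count):

* **Fraction of bacterial reads** — transposase reads divided by all reads
  on contigs classified as Bacteria. Reads count as transposase reads when
  at least half of the read interval overlaps the union of call segments
  on its contig (strand-agnostic); the IS family attributed to a read is
  the family with the largest overlap. The half-overlap rule is a package
  decision (configurable via `min_read_overlap_frac`), since read-to-call
  attribution admits several reasonable conventions.
* **Per-taxon fraction** — the same quotient restricted to one lineage
  scope (e.g. cyanobacterial transposase transcripts over all
  cyanobacterial transcripts).
* **Per-genome count** — transposase reads divided by the mean read count
  over 35 single-copy marker genes; markers with zero hits stay in the
  denominator (the mean is over the fixed label set), and marker hits are
  treated as read counts, the same unit as the numerator. This estimates
  transposase copies per genome because single-copy markers estimate
  genome equivalents; it is invariant to uniform sequencing-depth
  rescaling.
* **Genome-size proxy** — total scope reads over the marker mean, a
  relative genome-size measure in arbitrary units.
* **Expression ratio** — the scope-restricted transposase fraction of an
  RNA sample divided by that of its matched DNA sample (matched on
  station, depth and size fraction); pairs with a zero DNA-side fraction
  are excluded with a warning. Cross-sample aggregation uses the median,
  as ratio distributions are heavy-tailed at low counts.

## Statistics

`wilcoxon_rank_sum()` is a two-sided Mann–Whitney test. The exact null
distribution of U is computed by the standard dynamic-programming count
recursion when both groups have at most 25 observations and no ties; with
ties or larger groups the normal approximation with tie correction and
continuity correction is used. When every pooled observation is identical
the statistic is degenerate and the p-value is reported as 1. The test
suite checks the exact path against exhaustive enumeration of all rank
assignments and both paths against `stats::wilcox.test()`. `linear_fit()`
is closed-form simple OLS with adjusted R², Pearson r and its t-based
p-value, checked against `stats::lm()` and `stats::cor.test()`. No
multiple-testing correction is applied by default: the contrasts report raw
p-values (apply `p.adjust()` downstream if a correction is wanted).
Two-sided alternatives are used throughout.

## What the synthetic generator emulates

`generate_community()` builds a taxon-structured contig pool (one pool,
shared by the metagenome and metatranscriptome, which therefore share
coordinates — the analysis consumes interval read maps, not base calls)
and emits per-sample read maps with known ground truth:

* a multi-station × three-size-fraction × DNA/RNA sampling design; the
  defaults place four brackish-transect stations and two marine stations,
  with planted transposase read fractions of 0.2% (small fraction), 0.7%
  (medium) and 1.0% (large) at brackish stations and 0.2% everywhere at
  marine stations, so that the default brackish-vs-marine medians are
  0.7% vs 0.2% and the overall range sits within the 0.1–2% window
  typical of transposase-rich coastal communities;
* a reference protein set with real IS family labels (IS3, IS5,
  IS200/IS605, IS256, IS66, ...), members of one family derived from a
  family prototype by 30% point substitution so that related references
  cross-align and exercise the resolver;
* planted ORFs reverse-translated with a fixed one-codon-per-amino-acid
  table, so the built-in search re-finds them without aligner
  stochasticity entering the truth; background sequence is i.i.d. uniform
  ACGT, which keeps spurious hits negligible at desk scale;
* 35 single-copy marker genes as labelled intervals, exactly one per
  marker per taxon genome (abstract labels M01–M35; 300 nt by default);
* RNA samples whose read intensity over a planted ORF is multiplied by a
  configurable `expression_multiplier[family, taxon]` (default 2.3 for
  the cyanobacterial taxon), so expression-ratio estimators can be
  validated against a known multiplier;
* an optional `"uniform"` allocation mode in which transposase reads are
  proportional to planted length (uniform genome depth), used to validate
  per-genome copy-number estimation.

Background reads are placed uniformly over start positions whose read
would overlap any planted ORF by less than half the read length, so no
background read can ever count as a transposase read under the default
rule, and recomputing transposase counts from the emitted read map
reproduces the stored truth exactly.

The generator deliberately omits sequencing error, chimeric assembly,
rRNA contamination, strain-level variation and non-uniform coverage.
Passing its recovery tests therefore demonstrates correctness of the
interval logic, the normalization arithmetic and the statistical
machinery — not robustness to noisy real-world alignments, where hit
boundaries are fuzzier and the coverage filter does real work.

## Numerical and design choices

* Coordinates are 0-based half-open on the forward strand everywhere
  inside the package; the 1-based, possibly reversed BLAST convention is
  confined to `read_blast_tab()`/`write_blast_tab()`.
* The built-in search is a six-frame Smith–Waterman (BLOSUM62, gap open
  11 / extend 1) intended as a correctness oracle for fixtures up to
  about a megabase of contig, not a BLAST replacement; each (frame,
  reference) pair contributes at most its single best local alignment.
  Bit scores use the Karlin–Altschul transform with λ = 0.267,
  K = 0.041 (the standard gapped BLOSUM62 parameters) and E-values use
  the total reference amino-acid count as database size.
* `generate_reference_db()` seeds the RNG with `seed` and
  `generate_community()` with `seed + 1`, so either stage is
  reproducible in isolation; identical configurations produce
  byte-identical FASTA/TSV outputs.
* Degenerate inputs fail loudly and early: contigs too short to host a
  planted ORF, taxon weights not summing to one, empty contrast groups,
  all-zero marker scopes and zero denominators are all named errors
  rather than silent NAs.
* Simulation sizes in the tests are chosen to keep each recovery suite in
  the seconds-to-a-few-minutes range: the default community is 4 taxa ×
  12 contigs of 2.5–4 kb (~150 kb of sequence), recovery suites use
  10,000 reads per sample, and seed-replication counts are 10–50 per
  property.

## Known limitations

* The resolver assigns segments, not IS boundaries: inverted repeats and
  target-site duplications are out of scope, as is composite-transposon
  classification.
* Coverage proration assumes roughly uniform alignment density along a
  hit; strongly gapped alignments can make a segment's prorated coverage
  an approximation.
* The per-genome estimator inherits the usual single-copy-marker caveats:
  it estimates population-average copy numbers and says nothing about
  strain-to-strain variance.
* With very low planted fractions (tens of expected reads) the
  expression-ratio estimator is noisy per pair; the median over matched
  pairs and seeds is the supported summary.
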