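---
title: "Fusion detection from long reads: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusion detection from long reads: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrfuse)
```

## The problem and the two-phase model

A fusion transcript splices exons of a 5' gene onto exons of a 3' gene.
A long read covering the junction aligns as two segments at distinct
genomic loci, but so do library chimeras, mapping artifacts around
repeats and paralogs, and reads from overlapping or neighboring genes.
The caller therefore separates a cheap, permissive genome-wide scan from
an expensive, strict re-evaluation on a per-candidate reference.

**Phase 1** treats alignment segments as evidence only when they behave
like spliced transcript fragments: each junction segment must be
assigned to a gene by maximal exonic overlap (a segment wholly inside an
intron or intergenic space is not evidence), must reach a minimum
alignment identity, and the pair's junction breakpoints must fall near
annotated exon boundaries. The exon-boundary retention rule is
deliberately asymmetric: one read with both breakpoints within 50 bp of
boundaries suffices, while a looser 50 bp / 1 kb combination needs at
least two independent reads. Expression filtering uses FFPM (fusion
reads per million total reads); with the default floor of 0.1 FFPM a
fusion needs one supporting read per ten million sequenced reads.

**Phase 2** builds, per candidate pair, a fusion contig: the collapsed
exon structure of the 5' gene then the 3' gene, both in transcribed
orientation, introns capped at 1 kb, and a 1 kb `N` spacer between the
genes. Realigning candidate reads to this supervised reference makes the
breakpoint geometry explicit: alignment ends within 3 bp of an exon
boundary are snapped onto it (tolerating ragged ends of noisy reads),
fusion evidence requires at least 25 bp of cumulative exonic alignment
in each gene, exonic bases recorded as sequence-similar between the two
genes do not count (guarding against homologous-exon mis-splits), and
breakpoints are tallied by their exact post-snap coordinates. Splice
context is read directly from the contig: the two bases 3' of the donor
break and 5' of the acceptor break, consensus being GT–AG by default.

The model's main assumptions are: the input aligner is splice-aware and
reports supplementary/split alignments; annotation is GENCODE-like
(gene/transcript/exon with stable ids); and fusion breakpoints of
interest predominantly occur at annotated exon boundaries — breakpoints
far inside exons survive only via the 1 kb arm of the retention rule
plus multi-read support.

## Tunable parameters

| Parameter (units) | Default | Rationale |
|---|---|---|
| `min_identity` (fraction) | 0.70 | permissive enough for noisy ONT reads, closes on garbage alignments |
| `max_locus_gap` (bp) | 100 000 | same-chromosome segments closer than this are one locus (cis-splicing territory) |
| `boundary_near` / `boundary_far` (bp) | 50 / 1000 | the single-read vs multi-read retention arms |
| `min_ffpm` (FFPM) | 0.1 | one read per 10 M total reads |
| `snap_dist` (bp) | 3 | ragged-end tolerance; HiFi reads rarely need it |
| `min_exon_bp` (bp) | 25 | minimum per-gene exonic anchor of a fusion read |
| `min_reads_consensus` / `min_reads_nonconsensus` | 1 / 2 | non-consensus junctions demand corroboration |
| `isoform_frac` (fraction) | 0.05 | minor isoforms under 5% of the dominant isoform are treated as noise |
| `intron_cap` / `intron_flank` (bp) | 1000 / 500 | two flanks meet the cap exactly; flanks preserve GT/AG context |
| `spacer_len` (bp) | 1000 | prevents realignments bridging the two genes through the junction gap |

All live in `fusion_config()` and every filter is monotone in its
threshold (tightening never adds a reported row) — a property the test
suite asserts.

## The simulator: what it emulates, and what it does not

`sim_spec()`/`simulate_fusion_dataset()` generate a toy genome (one gene
per chromosome, so any fused pair is inter-chromosomal), multi-exon
genes whose introns always carry GT..AG terminal dinucleotides on the
coding strand, fusion transcripts joined at exon junctions (donor never
the last exon, acceptor never the first, so both sides of the junction
retain genuine splice context), background transcripts, and reads with
i.i.d. per-base substitution/insertion/deletion errors, optional
3'-anchored truncation, optional antisense flipping, and optional
`barcode^umi^id` single-cell tags. Ideal alignments are emitted from the
planned placements: errors perturb bases, not positions, so alignment
identity — not breakpoint location — degrades with the error rate,
which is exactly what the caller's identity gate tests.

The defaults are the package's standard study conditions: 20 genes,
5 planned fusions of 3–10 reads each, 200 background reads, 1%
substitution error. Unit tests use smaller seeded instances (4–10
genes) of the same generator; the full 20-gene condition is exercised
in the acceptance suite. These sizes were chosen as the smallest
instances that still exercise every rule (multi-exon structure, both
strands, multiple isoforms, sub-threshold FFPM).

What the simulator does **not** model: realistic platform error
profiles (homopolymer indels, quality scores), concatemeric read
structure, alignment failure modes (a real aligner at high error rates
fragments or drops alignments rather than reporting full-length
low-identity ones), genomic repeats and true paralogy, and expression
variability beyond the fixed read plan. Passing tests therefore
demonstrate the *logic* of the caller — coordinate exactness, rule
thresholds, orientation handling, filter algebra — not its ranking
performance on real noisy data, which depends on the external aligner.

## Numerical and convention choices

* **Coordinates.** All internal intervals are 0-based half-open; every
  user-facing breakpoint string is 1-based (`chrom:pos:strand`). The
  boundary index stores exon starts (0-based) and exon ends (exclusive),
  so an alignment-segment endpoint equal to a boundary has distance 0
  without off-by-one adjustment.
* **Boundary index scope.** Boundaries from *all* transcripts of every
  gene, not one canonical transcript — phase 2 must accommodate any
  isoform, and a junction at a minor isoform's boundary is real evidence.
* **Identity.** Per segment, `matches / block_len` (PAF columns 10/11;
  for SAM, `(aligned_len − NM)/aligned_len`). The 70% gate applies to
  each junction segment separately; a read with one clean and one noisy
  segment is not evidence.
* **FFPM denominators.** Total input reads (FASTQ records). Phase-1 FFPM
  is computed per gene pair before annotation filtering; phase-2 FFPM is
  per breakpoint, with the per-pair aggregate recoverable by summation.
  The 5% isoform filter compares read counts, which at a fixed total is
  equivalent to comparing FFPM.
* **Snapping.** An end moves only if its distance to the nearest
  boundary is between 1 and `snap_dist`; ties go to the smaller
  coordinate; a snap that would invert a block is discarded. Snapping is
  idempotent.
* **Multi-segment reads.** Reads with more than two segments are
  evaluated over consecutive segment pairs; a read contributes at most
  one candidate per ordered gene pair, and a read supporting several
  reported fusions is flagged (`shared_supporting_reads`) rather than
  suppressed.
* **PR-AUC.** Points with no surviving predictions report precision 1
  with a flag and are excluded from integration. Remaining points are
  collapsed to the best precision per recall value, sorted by recall,
  extended horizontally from the highest-precision point to recall 0,
  and integrated by the trapezoid rule. The curve is not extrapolated
  beyond the largest observed recall. This convention is validated
  against an independent polygon-area oracle in the tests.
* **Neighbor distance.** Gap between gene spans (not midpoints); a gap
  exactly at the 100 kb threshold is removed.
* **UMI handling.** Exact-match deduplication only; read-level counting
  is available via `count = "reads"`.
* **Degenerate inputs.** An empty chromosome in a boundary query, an
  unknown gene in contig construction, a zero-read total in FFPM, and
  unparseable GTF/PAF/SAM records are errors naming the offending input;
  an absent similarity/paralog file disables that filter with a message
  rather than failing.

## Known limitations

Short-read integration, merged long+short reporting, and visualization
are out of scope. The caller does not model fusions of more than two
genes per contig. Overlapping-gene fusions are excluded by design (the
overlap filter), which also excludes genuine read-through chimeras of
overlapping loci. The similarity filter is only as good as the supplied
region table; no similarity search is run internally. At error rates
approaching `1 − min_identity` the identity gate begins to close on
genuine fusion reads; with the simulator's error model the gate closes
fully only above ~30% per-base error, since identity tracks
1 − error rate.
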