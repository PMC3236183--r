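---
title: "Reference-based assembly evaluation with asmgrade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-based assembly evaluation with asmgrade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmgrade)
```

# The problem

When a de novo assembly is built from reads whose source genome is known —
the situation in platform- and assembler-benchmarking studies, where reads
are simulated from a finished reference — the assembly can be graded
directly against that reference. Size statistics (N50 and friends) say how
*contiguous* an assembly is; they say nothing about whether the sequence is
*right*. The complementary fidelity battery asks: how much of the genome is
represented, how many consensus errors were introduced, where was the
assembly joined incorrectly, and how are the remaining holes distributed —
and asks all of this not only genome-wide but inside annotated region
classes (genes, repeats, large protein families), because repeats and
near-identical paralogs are exactly where plant-genome assemblies break.

`asmgrade` implements that battery end to end: a paired-end read simulator
with platform-style error models and ground-truth tags, contig/scaffold
statistics, alignment acquisition (MUMmer `show-coords` text, PAF, or a
built-in test-scale aligner), the fidelity metric engine, and a fixtures
module that manufactures genomes and deliberately corrupted assemblies so
that every metric can be verified against construction ground truth.

# The metric battery

All internal coordinates are 0-based half-open; conversion to and from the
1-based inclusive conventions of GFF3 and `show-coords` happens only at the
parser/writer boundary. One convention everywhere prevents off-by-one
drift.

## Representation

The fraction of the reference (or of a region class) covered by at least
one kept alignment block: `|union of block intervals ∩ region| / |region|`.
Overlapping members of a region class are merged before forming the
denominator, so representation cannot exceed 1. Interval arithmetic is
delegated to `IRanges`.

## Error rates

`mismatch_rate` and `indel_rate` are events per 100 kb of aligned reference
(configurable to a per-base fraction via `rate_scale`); `error_rate` is
their sum, exactly, by construction. The aligned-base denominator is summed
block by block, so a doubly-covered base counts twice — rates are per
aligned base, not per genome position. Blocks carry event counts but not
within-block event positions, so when a block half-overlaps a region its
events are apportioned proportionally to the overlap fraction. This is a
documented approximation; it is exact whenever blocks lie entirely inside
or outside the region, which is the common case at fixture scale.

## Misassembly detection

Benchmarking literature reports misassembly counts without always fixing
the detection algorithm; this package fixes one explicitly, the same
adjacency walk later quality-assessment tools converged on. For each query
(scaffold), kept blocks are walked in query order and every adjacent pair
is classified:

* different reference sequence → **translocation**;
* strand flip → **inversion**;
* otherwise, with `rgap` the strand-aware reference gap and `qgap` the
  query gap: `|rgap − qgap| > relocation_threshold` (default 1000 bases,
  configurable) or inverted reference order → **relocation**.

A query with any breakpoint is MISASSEMBLED. The misassembly rate is
breakpoints per 100 kb of aligned reference; `misassembled_contig_bases`
sums the scaffold lengths of misassembled queries.

Before the walk, weak blocks are dropped (identity < 0.90 or aligned query
length < 65 bases, both configurable — 65 tracks nucmer's default minimum
cluster), and a best tiling of the query is chosen greedily by
identity × length with ties broken by lower reference start, then `+`
strand. Greedy tiling rather than optimal chaining is a deliberate
simplification: at the scales this engine certifies, the two differ only
in pathological repeat arrangements, and the greedy rule is deterministic
and explainable.

## Ambiguity

Two names, two meanings, kept deliberately distinct:

* `ambiguous_bases` — `N` characters in the assembly consensus (an
  assembly property, identical on every record row);
* `ambiguously_aligned_bases` — query bases contested by near-equal
  alignments to multiple reference loci. Two blocks contest a region when
  they overlap ≥ 50% on the query and their identities differ by less than
  `ambiguity_margin` (default 0.02). A query whose contested bases reach
  the `partial_threshold` fraction (default 0.95) is AMBIGUOUS — the
  typical fate of a contig that is one repeat copy. Blocks of AMBIGUOUS
  queries are excluded from coverage and rates by default
  (`include_ambiguous = FALSE`), since assigning a repeat contig to one
  arbitrary copy would overstate local accuracy.

## Gap accounting

* **Gap** — maximal uncovered reference interval within the region
  (region-clipped). Conservation law, exact by construction:
  `covered_bases + total_gap_bases = region_bases` on every record.
* **Negative gap** — reference overlap between consecutive kept blocks of
  one query (adjacent blocks that claim overlapping reference).
* **Captured gap** — a gap spanned by a single scaffold: its containing
  interval lies between consecutive blocks of one query on the same
  reference and strand in consistent order. This is the signature of a
  scaffolder bridging a hole with an N run, and also of an interior
  deletion; both are "captured" in the sense that the scaffold asserts the
  locus even though no sequence aligns there.
* **Internal gaps / overlaps** — query-coordinate gaps/overlaps between
  consecutive kept blocks; assembly-level counts (no reference position),
  repeated on every record row like the other assembly-level fields.

Region records restrict all reference-positional metrics (representation,
rates, gaps, breakpoint counts) to the region; assembly-level fields
(ambiguous bases, unaligned and ambiguously-aligned counts, internal
gaps/overlaps) have no position and repeat on each row, mirroring the flat
one-row-per-(run, region) schema used for storage.

# Assembly statistics

`nxx()` fixes the N50 convention explicitly: sort descending, return the
first length at which the cumulative sum reaches the target fraction (the
"≥" rule). Size-class counts use strict `>` thresholds, matching the
printed symbols (`Contigs >1000 bp`). Scaffold lengths include N bases;
contigs are produced by splitting scaffolds at maximal N runs of at least
`min_n_run` bases (default 10 — scaffolders rarely emit shorter estimated
gaps; the threshold is configurable and the split is lossless: contigs
plus split N runs reconstruct the scaffold exactly).

# The read simulator

Datasets follow the two-platform benchmarking design: 454-style reads of
500 bases, Illumina-style reads of 50/75/100 bases; paired inserts from
the panel {2000, 8000, 20000, 40000} with 500 additionally allowed for
Illumina (any value via `allow_any_insert`); coverage is total read bases
over genome length; paired datasets come as an A/B pair of specs (e.g.
16× at one insert plus 24× at another for 40× total). Insert size means
the outer distance, mate-1 start to mate-2 end, and mates are FR
("innie"); 454 mate-pair circularization artifacts (linker read-through,
RF orientation) are not modeled. Insert lengths are Normal, truncated by
clamping to `[2 × read length, sequence length]`; reference sequences are
chosen length-proportionally; placements are uniform.

Error models are deliberately simple, typical-rate choices — they are this
package's defaults, not measured platform profiles:

* **Illumina**: substitution-only, with per-base probability ramping
  linearly 5′→3′ from 0.1% to 1.0% (the read-end degradation pattern);
* **454**: uniform substitutions at 0.1% plus homopolymer indels — every
  maximal run of length k ≥ 2 gains or loses one base of the run's
  nucleotide with probability `min(1, 0.01 × k)`. 454 reads keep their
  post-indel length; Illumina reads keep exactly the nominal length.

Every read carries a ground-truth tag (reference, 0-based start, strand,
serialized edit list); applying the edit list to the strand-oriented
template substring reproduces the emitted read byte-for-byte, which is the
property the test suite asserts for every read. Qualities are a constant
Q30 placeholder — nothing downstream consumes them. Identical
(reference, spec, seed) triples give byte-identical FASTQ output.

What the simulator does *not* emulate: GC-coverage bias, quality-correlated
errors, chimeras, optical duplicates, flowgram-level 454 noise. Passing
tests therefore certify the pipeline's bookkeeping and the analytical
properties of the stated models — not that downstream conclusions transfer
to any real instrument's idiosyncrasies.

# The built-in aligner

`toy_align()` exists so the whole pipeline is testable without external
binaries; it is a certification tool, not a genome-scale aligner (guarded
at 10 Mb total reference). Design: exact-match anchors of ≥ 21 bases found
through a reference k-mer index; greedy chaining of collinear anchors
(gap ≤ 2000 on both coordinates, diagonal drift ≤ 50); inter-anchor gaps
closed by global alignment at unit costs (via `pairwiseAlignment`), giving
exact mismatch and indel counts; unanchored chain-end stubs up to 3k bases
compared base-wise (longer stubs are structural junctions by construction —
a genuinely homologous stretch that long would have seeded anchors).
Chains never extend across query gaps containing `N`, and never bridge
long double-gaps whose sequences diverge beyond 30% — both rules make the
aligner break blocks where a real aligner would, instead of absorbing an
inversion or an N run as a smear of mismatches.

Known limits, by design: repeat copies diverged enough to leave no 21-base
exact seed are missed; indels beyond 50 bases split blocks rather than
being absorbed; sensitivity is not a goal. For real work, align with
`nucmer -o -p out ref.fasta asm.fasta` (then `parse_coords()` on the
`show-coords` text) or `minimap2 -c` (then `parse_paf()`); the test suite
cross-checks `toy_align` against minimap2 on a corrupted fixture.

A note on exactness: at a structural junction the first few assembled
bases can match the reference continuation by chance (junction
micro-homology), which legitimately shifts recovered block boundaries by a
base or two — every aligner does this. The fixture generator therefore
rejection-samples structural edit positions until every junction is
homology-free in both directions; that, plus isolation of edits (≥ 200
bases apart, ≥ 21 bases from contig ends), is what makes *exact* equality
between measured metrics and construction ground truth a fair assertion.
Scaffold cuts in random fixtures are kept ≥ 2 kb apart so no scaffold
falls below the engine's 65-base block-reporting threshold.

# Fixtures and ground truth

`make_toy_genome()` builds a uniform-GC background (default 0.5), plants
dispersed repeat families as near-identical copies (substitution-only
divergence, so planted error counts stay exact) and annotates toy gene
intervals. `corrupt_assembly()` cuts the reference into scaffolds and
applies a `corruption_plan()`: substitutions, small indels (±1–10),
dropped intervals, N-run replacements (the captured-gap generator),
in-place inversions, and within-scaffold relocations. Ground truth is
derived from the constructed segment structure: planted event counts are
counted directly, and expected breakpoints are obtained by applying the
engine's documented adjacency rule to the constructed segments — so the
dual routes share the *counting rule* (which is a definition, not a
measurement) while differing in the hard part, block discovery.

Random plans size each defect so it maps to exactly one expected signal:
indels ≤ 10 bases stay inside one block; dropped/N-replaced spans of
100–400 bases break blocks but stay under half the relocation threshold
(never breakpoints); relocated segments of 1200–2000 bases move > 2.5 ×
the threshold (always detected).

# Reporting

Records mirror a flat relational schema — one row per (run, genome
region), with run descriptors (dataset A/B ids, assembler, parameters,
k-value, resource fields) and the assembly-statistics block repeated per
row. Three lossless backends: TSV, JSON, SQLite (DDL shipped in
`inst/extdata/runs_schema.sql`; SQLite replaces a client–server database
with a zero-infrastructure file of the same shape). Resource fields are
nullable: no assembler is bundled, they exist for users wrapping external
assembler runs. `compare_runs()` gives per-group mean/sd/n of any numeric
metric (the shape of cross-platform comparison figures), and
`plot_comparison()` renders a minimal bar chart.

# Problem sizes and numerical choices

The test suite and the acceptance script use 20–25 kb fixture genomes for
the 200-fixture exact-recovery sweep, 100 kb for the identity pipeline and
simulator statistics, and 200 kb for the miniature A/B study
(16× + 24× = 40× at 75 bases — about 107,000 reads) — sizes chosen so the
full certification sweep completes in minutes on one core while every
code path (all defect kinds, both platforms, all three region classes)
is exercised. Statistical checks use 3-standard-error bands against
closed-form expectations (e.g. the Illumina ramp's 0.55 expected
substitutions per 100-base read) and a χ² placement-uniformity test at
α = 0.001.

Degenerate inputs: empty alignment sets yield a valid all-zero record
with representation 0; all-N scaffolds yield zero contigs; empty region
classes are skipped with a warning; zero-aligned regions report rates of
0 with a flag rather than NaN.

# Limitations

* The misassembly taxonomy and its 1000-base threshold are this package's
  operational definitions; published studies using other thresholds will
  count differently.
* `show-coords` input lacks per-event counts, so mismatch/indel splits
  from that dialect are reconstructed (all-mismatch beyond the length
  difference) — prefer PAF with `cg:Z` when exact counts matter.
* Error-model defaults are stylized; calibrate `error_model_params()`
  against your own platform data before quantitative read-level claims.
* Gene-completeness and orthologue-based assessment (BUSCO-style) are out
  of scope, as is running any assembler.
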