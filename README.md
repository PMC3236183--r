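# asmgrade

Reference-based evaluation of de novo genome assemblies, with a built-in
platform-style read simulator and synthetic-fixture generator.

## What it is for

Sequencing-and-assembly benchmarking studies simulate reads from a
finished genome, assemble them, and grade the result against the source.
Contiguity statistics (N50, largest scaffold) measure only size; the
interesting questions are about *fidelity*: how much of the genome the
assembly **represents**, how many consensus **mismatches and indels** it
introduced, where it was joined incorrectly (**misassemblies**), and how
the remaining holes are distributed (**gaps**, **negative gaps**,
scaffold-spanned **captured gaps**) — genome-wide and restricted to
annotated region classes (genes, repeats, large protein families such as
protein kinases or cytochromes P450, which is where plant assemblies
typically break).

`asmgrade` is a self-contained R toolkit for that workflow:

* **sequence IO** — FASTA in/out, scaffold→contig splitting at N runs,
  GFF3 region parsing with keyword-based protein-family classing;
* **read simulation** — 454-style (500 bp, homopolymer indels) and
  Illumina-style (50/75/100 bp, 5′→3′ substitution ramp) fragment or
  paired-end datasets on the standard insert panel
  (2/8/20/40 kb, +500 bp for Illumina), with per-read ground-truth tags
  and byte-deterministic output;
* **assembly statistics** — the classic 12-field contig/scaffold block
  with an explicitly fixed N50 convention;
* **alignment acquisition** — parsers/writers for MUMmer `show-coords`
  text and PAF (with `cg:Z` CIGAR refinement), plus `toy_align()`, a
  deterministic exact-anchor aligner for test-scale references so the
  pipeline runs with no external binaries;
* **fidelity metrics** — the full 23-field record: representation, error
  rates per 100 kb aligned, relocation/inversion/translocation breakpoint
  detection, ambiguity measures, gap accounting, per region class;
* **fixtures** — seeded toy genomes (with repeat families and gene
  annotation) and deliberately corrupted assemblies whose ground truth is
  exact, so every metric is certified by construction;
* **reporting** — flat run records (one row per run × region) with
  lossless TSV/JSON/SQLite round trips, group-wise comparison tables and
  a simple bar plot.

At its core, for kept alignment blocks *B* and a region *R*:

    representation(R) = | union of ref intervals of B  ∩  R | / |R|
    mismatch_rate(R)  = 10^5 · mismatches in R / aligned reference bases in R
    error_rate        = mismatch_rate + indel_rate          (exactly)
    covered(R) + total_gap_bases(R) = |R|                   (exactly)

Misassemblies are breakpoints in the query-order walk over a scaffold's
blocks: reference-sequence change → translocation, strand flip →
inversion, |ref gap − query gap| > 1000 bases (configurable) or inverted
order → relocation.

## Worked example

Build a 100 kb toy genome, corrupt a 3-scaffold copy of it with known
defects, and grade it:

```r
library(asmgrade)
g <- make_toy_genome(genome_plan(length = 100000, seed = 7))
set.seed(7)
plan <- corruption_plan(
  substitutions = c(12000L, 44000L, 81000L),
  indels        = data.frame(pos = 55000L, len = -4L),
  relocations   = data.frame(start = 75000L, len = 1500L, new_pos = 95000L),
  n_runs        = data.frame(start = 20000L, ref_span = 300L, n_len = 250L))
cor <- corrupt_assembly(g$ref, plan, scaffold_cuts = c(30000L, 70000L))
ev <- evaluate_assembly(g$ref, cor$assembly,
                        toy_align(g$ref, cor$assembly), g$regions)
ev
```

```
Assembly evaluation
  queries: 3 (ALIGNED:2, MISASSEMBLED:1)
  representation: 0.9970
  error rate: 4.012 /100kb (mismatch 3.009 + indel 1.003)
  misassembly rate: 3.009 /100kb (3 breakpoints)
  gaps: 1 (300 bases), captured: 1
  region classes: gene
```

Reading it off: the three planted substitutions and one deletion are the
3.009 + 1.003 events per 100 kb of aligned reference; the relocated 1.5 kb
segment produces relocation breakpoints (excision plus insertion
adjacencies) and marks one scaffold MISASSEMBLED; the N-replaced 300-base
span is the single gap, and because the same scaffold flanks it in
consistent order it is a *captured* gap — the assembly asserts the locus
without sequence. Per-region rows (here `all` and `gene`) carry the same
23 metric fields restricted to each region:

```
  genome_region representation mismatch_rate indel_rate misassembly_rate n_gaps
1           all          0.997      3.008967  1.0029889         3.008967      1
2          gene          1.000      2.553686  0.7930667         0.000000      0
```

Simulate the paired A/B read design for the same genome, record and
compare runs:

```r
spA <- read_dataset_spec("ILLUMINA", 75, insert_mean = 2000, coverage = 16, seed = 1)
spB <- read_dataset_spec("ILLUMINA", 75, insert_mean = 8000, coverage = 24, seed = 2)
simA <- simulate_reads(g$ref, spA, "reads_A")   # FASTQ pair + truth TSV
rec <- run_record(ev, summarize_assembly(cor$assembly),
                  dataset_id_a = "reads_A", dataset_id_b = "reads_B",
                  assembler = "myasm")
write_records(rec, "runs.sqlite")
compare_runs(rec, "assembler", "representation")
```

For genome-scale assemblies, align externally and feed the text in:
`nucmer -o -p out ref.fasta asm.fasta` → `parse_coords("out.coords")`, or
`minimap2 -c ref.fasta asm.fasta > out.paf` → `parse_paf("out.paf")`.

A thin command-line front end ships in `inst/cli/asmgrade.R`
(`stats`, `split`, `simulate`, `align`, `evaluate`, `fixture`, `report`).

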