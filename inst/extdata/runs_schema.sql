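-- Relational schema for assembly-run records (SQLite dialect).
-- One row per (run, genome_region); run descriptors and assembly
-- statistics are repeated on each row of a run (flat denormalized shape).
CREATE TABLE IF NOT EXISTS runs (
  dataset_id_a               TEXT NOT NULL,
  dataset_id_b               TEXT,
  assembler                  TEXT,
  assembler_parameters       TEXT,
  k_value                    REAL,
  processors_used            REAL,
  runtime                    REAL,
  processor_time             REAL,
  max_memory_used            REAL,
  final_disk_space_used      REAL,
  n_contigs                  INTEGER,
  total_contig_length        INTEGER,
  average_contig_length      REAL,
  contig_n50                 INTEGER,
  largest_contig_length      INTEGER,
  contigs_gt_1000            INTEGER,
  contigs_gt_5000            INTEGER,
  n_scaffolds                INTEGER,
  total_scaffold_length      INTEGER,
  average_scaffold_length    REAL,
  scaffold_n50               INTEGER,
  largest_scaffold_length    INTEGER,
  genome_region              TEXT NOT NULL,
  ambiguous_bases            INTEGER,
  error_rate                 REAL,
  indel_rate                 REAL,
  mismatch_rate              REAL,
  misassembly_rate           REAL,
  misassembled_contigs       INTEGER,
  misassembled_contig_bases  INTEGER,
  internal_overlaps          INTEGER,
  internal_gaps              INTEGER,
  representation             REAL,
  n_gaps                     INTEGER,
  n_negative_gaps            INTEGER,
  avg_gap_size               REAL,
  avg_negative_gap_size      REAL,
  total_gap_bases            INTEGER,
  n_captured_gaps            INTEGER,
  avg_captured_gap_size      REAL,
  total_captured_gap_bases   INTEGER,
  unaligned_contigs          INTEGER,
  unaligned_bases            INTEGER,
  ambiguously_aligned_contigs INTEGER,
  ambiguously_aligned_bases  INTEGER
);
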