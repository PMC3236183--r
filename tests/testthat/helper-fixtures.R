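# Shared fixture builders. Everything is generated in code; no data files.

# A small deterministic genome with no annotation.
plain_genome <- function(len = 20000, seed = 1) {
  make_toy_genome(genome_plan(length = len, gene_density = 0,
                              seed = seed))$ref
}

# Write a FASTA string set to a temp file and return the path.
tmp_fasta <- function(seqs) {
  f <- tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  f
}

# Write GFF3 text lines to a temp file.
tmp_gff <- function(lines) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), f)
  f
}

# Independent exhaustive Nxx oracle: scan every prefix of the sorted list.
nxx_oracle <- function(lengths, fraction) {
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  tot <- sum(s)
  for (i in seq_along(s)) if (sum(s[1:i]) >= fraction * tot) return(s[i])
  s[length(s)]
}

# Independent per-base coverage oracle for representation: mark covered
# bases in a logical vector.
representation_oracle <- function(blocks, ref_len) {
  cov <- logical(ref_len)
  for (i in seq_len(nrow(blocks)))
    cov[(blocks$ref_start[i] + 1):blocks$ref_end[i]] <- TRUE
  mean(cov)
}

# Reconstruct a read from its truth row (strand-oriented template + edits).
reconstruct_read <- function(ref, row) {
  tm <- substr(ref[[row$ref_id]], row$start + 1, row$start +
                 row$template_len)
  if (row$strand == "-")
    tm <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(tm)))
  apply_edits(tm, parse_edits(row$edits))
}
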