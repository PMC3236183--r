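#' Evaluate an assembly against its reference
#'
#' The top-level entry point of the fidelity engine. Runs
#' [classify_query()] on every scaffold's alignment blocks, then computes
#' the full metric record — representation, mismatch/indel/error rates,
#' misassembly measures, gap and captured-gap accounting, ambiguity and
#' unalignment measures — for the whole genome (`"all"`) and for every
#' region class present in `regions` (alphabetical after `"all"`).
#'
#' Reference-positional metrics (representation, rates, gaps, misassembly
#' counts) are restricted to each region; assembly-level metrics
#' (ambiguous N bases, unaligned and ambiguously-aligned contig counts,
#' internal gaps/overlaps) have no reference position and are repeated on
#' every row. `ambiguous_bases` counts N characters in the assembly
#' consensus and is distinct from `ambiguously_aligned_bases`, which
#' counts repeat-contested query bases. The misassembly rate is
#' breakpoints per 100 kb of aligned reference (configurable via
#' `rate_scale`).
#'
#' @param ref named character vector of reference sequences
#'   (see [read_fasta()]).
#' @param assembly an `assembly_set` from [split_scaffolds()] or a named
#'   character vector of scaffolds.
#' @param alignments alignment-block data.frame from [toy_align()],
#'   [parse_coords()] or [parse_paf()].
#' @param regions optional data.frame from [read_gff_regions()].
#' @param config a [fidelity_config()].
#' @return object of class `assembly_evaluation`: list with `records`
#'   (one metric row per region class), `verdicts` (per-query
#'   [classify_query()] results), `kept_blocks`, `breakpoints`, `covered`
#'   (whole-genome covered set), `config`.
#' @examples
#' ref <- c(chr1 = paste0(rep("ACGTTGCA", 50), collapse = ""))
#' asm <- c(s1 = substr(ref[[1]], 1, 200), s2 = substr(ref[[1]], 201, 400))
#' ev <- evaluate_assembly(ref, asm, toy_align(ref, asm))
#' ev$records$representation[1]
#' @export
evaluate_assembly <- function(ref, assembly, alignments, regions = NULL,
                              config = fidelity_config()) {
  if (!inherits(assembly, "assembly_set"))
    assembly <- split_scaffolds(assembly)
  scaffolds <- assembly$scaffolds
  ref_lengths <- nchar(ref)
  if (nrow(alignments)) {
    bad_r <- setdiff(unique(alignments$ref_id), names(ref))
    bad_q <- setdiff(unique(alignments$qry_id), names(scaffolds))
    if (length(bad_r) || length(bad_q))
      stop("alignments mention unknown sequence ids: ",
           paste(c(bad_r, bad_q), collapse = ", "), call. = FALSE)
  }
  # per-query verdicts (queries with no blocks are UNALIGNED)
  verdicts <- lapply(names(scaffolds), function(qid) {
    b <- alignments[alignments$qry_id == qid, , drop = FALSE]
    classify_query(b, nchar(scaffolds[[qid]]), config)
  })
  names(verdicts) <- names(scaffolds)
  status <- vapply(verdicts, `[[`, character(1), "status")
  use <- status != "AMBIGUOUS" | config$include_ambiguous
  kept <- do.call(rbind, lapply(verdicts[use], `[[`, "kept_blocks"))
  if (is.null(kept)) kept <- empty_blocks()
  rownames(kept) <- NULL
  bps <- do.call(rbind, lapply(names(verdicts), function(qid) {
    b <- verdicts[[qid]]$breakpoints
    if (nrow(b)) cbind(qry_id = qid, b) else NULL
  }))
  if (is.null(bps))
    bps <- data.frame(qry_id = character(0), qry_pos = integer(0),
                      kind = character(0), ref_id = character(0),
                      ref_pos = integer(0), stringsAsFactors = FALSE)
  # assembly-level quantities
  amb_bases <- sum(vapply(scaffolds, function(s)
    nchar(gsub("[^N]", "", s)), numeric(1)))
  unaligned_ids <- names(which(status == "UNALIGNED"))
  ambiguous_ids <- names(which(status == "AMBIGUOUS"))
  misassembled_ids <- names(which(status == "MISASSEMBLED"))
  scaffold_len <- nchar(scaffolds)
  global <- list(
    ambiguous_bases = amb_bases,
    unaligned_contigs = length(unaligned_ids),
    unaligned_bases = sum(vapply(verdicts, `[[`, numeric(1),
                                 "unaligned_bases")),
    ambiguously_aligned_contigs = length(ambiguous_ids),
    ambiguously_aligned_bases = sum(vapply(verdicts, `[[`, numeric(1),
                                           "contested_bases")))
  # region sets
  sets <- c(list(all = whole_genome_set(ref_lengths)),
            region_sets(regions, ref_lengths))
  if (length(sets) > 1L)
    sets <- sets[c("all", sort(setdiff(names(sets), "all")))]
  records <- lapply(names(sets), function(klass) {
    region <- sets[[klass]]
    if (set_width(region) == 0) {
      warning("region class '", klass, "' is empty; skipped",
              call. = FALSE)
      return(NULL)
    }
    rep_ <- compute_representation(kept, ref_lengths, region)
    er <- compute_error_rates(kept, ref_lengths, region, config)
    gp <- compute_gaps(kept, ref_lengths, region, covered = rep_$covered)
    # breakpoints whose reference position falls inside the region
    in_region <- if (nrow(bps)) vapply(seq_len(nrow(bps)), function(i) {
      rg <- region[region$seqid == bps$ref_id[i], , drop = FALSE]
      nrow(rg) > 0 && any(bps$ref_pos[i] >= rg$start0 &
                            bps$ref_pos[i] < rg$end0)
    }, logical(1)) else logical(0)
    mis_ids <- unique(bps$qry_id[in_region])
    mis_rate <- if (er$aligned_ref_bases > 0)
      config$rate_scale * sum(in_region) / er$aligned_ref_bases else 0
    data.frame(
      genome_region = klass,
      ambiguous_bases = global$ambiguous_bases,
      error_rate = er$error_rate,
      indel_rate = er$indel_rate,
      mismatch_rate = er$mismatch_rate,
      misassembly_rate = mis_rate,
      misassembled_contigs = length(mis_ids),
      misassembled_contig_bases = sum(scaffold_len[mis_ids]),
      internal_overlaps = gp$internal_overlaps,
      internal_gaps = gp$internal_gaps,
      representation = rep_$representation,
      n_gaps = gp$n_gaps,
      n_negative_gaps = gp$n_negative_gaps,
      avg_gap_size = gp$avg_gap_size,
      avg_negative_gap_size = gp$avg_negative_gap_size,
      total_gap_bases = gp$total_gap_bases,
      n_captured_gaps = gp$n_captured_gaps,
      avg_captured_gap_size = gp$avg_captured_gap_size,
      total_captured_gap_bases = gp$total_captured_gap_bases,
      unaligned_contigs = global$unaligned_contigs,
      unaligned_bases = global$unaligned_bases,
      ambiguously_aligned_contigs = global$ambiguously_aligned_contigs,
      ambiguously_aligned_bases = global$ambiguously_aligned_bases,
      aligned_ref_bases = er$aligned_ref_bases,
      region_bases = rep_$region_bases,
      covered_bases = rep_$covered_bases,
      stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, Filter(Negate(is.null), records))
  rownames(records) <- NULL
  covered_all <- compute_representation(kept, ref_lengths)$covered
  structure(list(records = records, verdicts = verdicts,
                 kept_blocks = kept, breakpoints = bps,
                 covered = covered_all, config = config,
                 n_misassembled = length(misassembled_ids)),
            class = "assembly_evaluation")
}

#' @export
print.assembly_evaluation <- function(x, ...) {
  all <- x$records[x$records$genome_region == "all", ]
  cat("Assembly evaluation\n")
  cat(sprintf("  queries: %d (%s)\n", length(x$verdicts),
              paste(names(table(vapply(x$verdicts, `[[`, character(1),
                                       "status"))),
                    table(vapply(x$verdicts, `[[`, character(1),
                                 "status")),
                    sep = ":", collapse = ", ")))
  cat(sprintf("  representation: %.4f\n", all$representation))
  cat(sprintf("  error rate: %.3f /100kb (mismatch %.3f + indel %.3f)\n",
              all$error_rate, all$mismatch_rate, all$indel_rate))
  cat(sprintf("  misassembly rate: %.3f /100kb (%d breakpoints)\n",
              all$misassembly_rate, nrow(x$breakpoints)))
  cat(sprintf("  gaps: %d (%d bases), captured: %d\n",
              all$n_gaps, all$total_gap_bases, all$n_captured_gaps))
  if (nrow(x$records) > 1L)
    cat("  region classes:",
        paste(setdiff(x$records$genome_region, "all"), collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
summary.assembly_evaluation <- function(object, ...) {
  object$records
}
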