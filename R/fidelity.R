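#' Configuration for the fidelity-metric engine
#'
#' @param relocation_threshold breakpoint threshold in bases: adjacent
#'   blocks of one query whose reference gap differs from their query gap
#'   by more than this are a relocation breakpoint (default 1000).
#' @param ambiguity_margin identity-score margin below which two
#'   overlapping alignments of one query region are considered
#'   indistinguishable repeat copies (default 0.02).
#' @param min_block_identity minimum identity for a block to be used
#'   (default 0.90).
#' @param min_block_length minimum aligned query length for a block
#'   (default 65, roughly nucmer's default minimum cluster).
#' @param partial_threshold fraction of query bases that must be aligned
#'   for a clean ALIGNED verdict; below it the verdict is PARTIAL
#'   (default 0.95). Also the contested fraction at which a query is
#'   called AMBIGUOUS.
#' @param include_ambiguous include blocks of AMBIGUOUS queries in
#'   coverage and rate computations (default FALSE).
#' @param rate_scale denominator scale for event rates; the default 1e5
#'   reports events per 100 kb of aligned reference, `1` gives per-base
#'   fractions.
#' @return list of class `fidelity_config`.
#' @export
fidelity_config <- function(relocation_threshold = 1000L,
                            ambiguity_margin = 0.02,
                            min_block_identity = 0.90,
                            min_block_length = 65L,
                            partial_threshold = 0.95,
                            include_ambiguous = FALSE,
                            rate_scale = 1e5) {
  stopifnot(relocation_threshold > 0,
            ambiguity_margin > 0, ambiguity_margin < 1,
            min_block_identity >= 0, min_block_identity <= 1,
            min_block_length >= 1,
            partial_threshold > 0, partial_threshold <= 1)
  structure(list(relocation_threshold = relocation_threshold,
                 ambiguity_margin = ambiguity_margin,
                 min_block_identity = min_block_identity,
                 min_block_length = min_block_length,
                 partial_threshold = partial_threshold,
                 include_ambiguous = include_ambiguous,
                 rate_scale = rate_scale),
            class = "fidelity_config")
}

# ---- interval helpers (0-based half-open, per reference sequence) ----------

# A "region set" is a data.frame(seqid, start0, end0) of disjoint merged
# intervals. The whole genome is one region set; each GFF class is another.

whole_genome_set <- function(ref_lengths) {
  data.frame(seqid = names(ref_lengths), start0 = 0L,
             end0 = unname(as.integer(ref_lengths)),
             stringsAsFactors = FALSE)
}

# Merge possibly-overlapping 1-based-inclusive regions of one class.
merge_region_rows <- function(rows) {
  out <- lapply(split(rows, rows$seqid), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    data.frame(seqid = d$seqid[1], start0 = IRanges::start(r) - 1L,
               end0 = IRanges::end(r), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# Turn a read_gff_regions() data.frame into a named list of region sets,
# one per class, with members merged (so representation cannot exceed 1).
#' Build merged per-class region sets from parsed GFF regions
#'
#' @param regions data.frame from [read_gff_regions()].
#' @param ref_lengths named lengths of the reference sequences; regions on
#'   unknown sequences or beyond the sequence end are a hard error.
#' @return named list of data.frames (`seqid`, `start0`, `end0`).
#' @export
region_sets <- function(regions, ref_lengths) {
  if (is.null(regions) || nrow(regions) == 0L) return(list())
  unknown <- setdiff(unique(regions$seqid), names(ref_lengths))
  if (length(unknown))
    stop("region seq-id(s) absent from reference: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  over <- regions$end > ref_lengths[regions$seqid]
  if (any(over))
    stop("region(s) extend beyond reference end on ",
         paste(unique(regions$seqid[over]), collapse = ", "),
         call. = FALSE)
  lapply(split(regions, regions$klass), merge_region_rows)
}

set_width <- function(set) sum(set$end0 - set$start0)

# Intersect a set with covered intervals given as data.frame(seqid,s0,e0).
set_intersect <- function(a, b) {
  out <- lapply(intersect(unique(a$seqid), unique(b$seqid)), function(sid) {
    ra <- with(a[a$seqid == sid, ], ir0(start0, end0))
    rb <- with(b[b$seqid == sid, ], ir0(start0, end0))
    r <- IRanges::intersect(ra, rb)
    if (length(r) == 0L) return(NULL)
    data.frame(seqid = sid, start0 = IRanges::start(r) - 1L,
               end0 = IRanges::end(r), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(df)) df <- data.frame(seqid = character(0), start0 = integer(0),
                                    end0 = integer(0))
  df
}

set_diff <- function(a, b) {
  out <- lapply(unique(a$seqid), function(sid) {
    ra <- with(a[a$seqid == sid, ], ir0(start0, end0))
    bb <- b[b$seqid == sid, , drop = FALSE]
    r <- if (nrow(bb)) IRanges::setdiff(ra, with(bb, ir0(start0, end0)))
         else ra
    if (length(r) == 0L) return(NULL)
    data.frame(seqid = sid, start0 = IRanges::start(r) - 1L,
               end0 = IRanges::end(r), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(df)) df <- data.frame(seqid = character(0), start0 = integer(0),
                                    end0 = integer(0))
  df
}

blocks_to_set <- function(blocks) {
  if (nrow(blocks) == 0L)
    return(data.frame(seqid = character(0), start0 = integer(0),
                      end0 = integer(0)))
  merge_region_rows(data.frame(seqid = blocks$ref_id,
                               start = blocks$ref_start + 1L,
                               end = blocks$ref_end,
                               stringsAsFactors = FALSE))
}

# ---- query classification --------------------------------------------------

#' Classify one query's alignment blocks
#'
#' Implements the per-query verdict logic: filter weak blocks; detect
#' repeat-contested (ambiguously aligned) regions as pairs of blocks that
#' overlap at least 50% on the query with identity scores within
#' `ambiguity_margin`; pick a best consistent tiling of the query (greedy
#' by identity x length, ties by lower reference start then `+` strand);
#' then walk adjacent kept blocks in query order and call breakpoints:
#' a reference-sequence change is a translocation, a strand flip an
#' inversion, and a reference jump (|ref gap - query gap| beyond
#' `relocation_threshold`, or reference order inverted) a relocation.
#'
#' Verdict precedence: no blocks = UNALIGNED; whole query contested =
#' AMBIGUOUS; any breakpoint = MISASSEMBLED; else ALIGNED, or PARTIAL when
#' less than `partial_threshold` of the query is covered.
#'
#' @param blocks alignment blocks of a single query.
#' @param qry_length query (scaffold) length in bases.
#' @param config a [fidelity_config()].
#' @return list of class `query_verdict`: `qry_id`, `status`,
#'   `kept_blocks`, `breakpoints` (data.frame `qry_pos`, `kind`, `ref_id`,
#'   `ref_pos`), `unaligned_bases`, `contested_bases`.
#' @export
classify_query <- function(blocks, qry_length, config = fidelity_config()) {
  if (nrow(blocks) > 0L && length(unique(blocks$qry_id)) != 1L)
    stop("classify_query expects blocks of a single query", call. = FALSE)
  qid <- if (nrow(blocks)) blocks$qry_id[1] else NA_character_
  bp0 <- data.frame(qry_pos = integer(0), kind = character(0),
                    ref_id = character(0), ref_pos = integer(0),
                    stringsAsFactors = FALSE)
  blocks <- blocks[blocks$identity >= config$min_block_identity &
                     blocks$aligned_qry_len >= config$min_block_length, ,
                   drop = FALSE]
  if (nrow(blocks) == 0L)
    return(structure(list(qry_id = qid, status = "UNALIGNED",
                          kept_blocks = empty_blocks(), breakpoints = bp0,
                          unaligned_bases = qry_length,
                          contested_bases = 0L),
                     class = "query_verdict"))
  # repeat-contested regions
  contested <- IRanges::IRanges()
  if (nrow(blocks) > 1L) {
    qr <- ir0(blocks$qry_start, blocks$qry_end)
    ov <- as.matrix(IRanges::findOverlaps(qr, qr))
    ov <- ov[ov[, 1] < ov[, 2], , drop = FALSE]
    for (r in seq_len(nrow(ov))) {
      i <- ov[r, 1]; j <- ov[r, 2]
      w <- IRanges::width(IRanges::pintersect(qr[i], qr[j]))
      if (w < 0.5 * min(IRanges::width(qr[i]), IRanges::width(qr[j])))
        next
      if (abs(blocks$identity[i] - blocks$identity[j]) <
            config$ambiguity_margin)
        contested <- c(contested, qr[i], qr[j])
    }
    contested <- IRanges::reduce(contested)
  }
  contested_bases <- sum(IRanges::width(contested))
  # greedy best tiling by identity x aligned length
  score <- blocks$identity * blocks$aligned_qry_len
  ord <- order(-score, blocks$ref_start, blocks$strand != "+")
  kept_idx <- integer(0)
  kept_cov <- IRanges::IRanges()
  for (i in ord) {
    iv <- ir0(blocks$qry_start[i], blocks$qry_end[i])
    ov_w <- sum(IRanges::width(IRanges::intersect(iv, kept_cov)))
    if (ov_w >= 0.5 * IRanges::width(iv)) next
    kept_idx <- c(kept_idx, i)
    kept_cov <- IRanges::reduce(c(kept_cov, iv))
  }
  kept <- blocks[sort(kept_idx), , drop = FALSE]
  kept <- kept[order(kept$qry_start, kept$ref_start), , drop = FALSE]
  rownames(kept) <- NULL
  aligned <- sum(IRanges::width(kept_cov))
  unaligned_bases <- qry_length - aligned
  if (contested_bases >= config$partial_threshold * qry_length)
    return(structure(list(qry_id = qid, status = "AMBIGUOUS",
                          kept_blocks = kept, breakpoints = bp0,
                          unaligned_bases = unaligned_bases,
                          contested_bases = contested_bases),
                     class = "query_verdict"))
  bps <- walk_breakpoints(kept, config)
  status <- if (nrow(bps)) "MISASSEMBLED"
    else if (aligned >= config$partial_threshold * qry_length) "ALIGNED"
    else "PARTIAL"
  structure(list(qry_id = qid, status = status, kept_blocks = kept,
                 breakpoints = bps, unaligned_bases = unaligned_bases,
                 contested_bases = contested_bases),
            class = "query_verdict")
}

# Walk adjacent kept blocks (query order) and call breakpoints.
walk_breakpoints <- function(kept, config) {
  out <- data.frame(qry_pos = integer(0), kind = character(0),
                    ref_id = character(0), ref_pos = integer(0),
                    stringsAsFactors = FALSE)
  n <- nrow(kept)
  if (n < 2L) return(out)
  for (i in 2:n) {
    p <- kept[i - 1L, ]; q <- kept[i, ]
    kind <- NULL
    if (p$ref_id != q$ref_id) kind <- "translocation"
    else if (p$strand != q$strand) kind <- "inversion"
    else {
      qgap <- q$qry_start - p$qry_end
      if (p$strand == "+") {
        rgap <- q$ref_start - p$ref_end
        inverted <- q$ref_start < p$ref_start
      } else {
        rgap <- p$ref_start - q$ref_end
        inverted <- q$ref_end > p$ref_end
      }
      if (abs(rgap - qgap) > config$relocation_threshold || inverted)
        kind <- "relocation"
    }
    if (!is.null(kind))
      out <- rbind(out, data.frame(qry_pos = p$qry_end, kind = kind,
                                   ref_id = p$ref_id, ref_pos = p$ref_end,
                                   stringsAsFactors = FALSE))
  }
  out
}

# ---- representation, rates, gaps -------------------------------------------

#' Representation: fraction of a region covered by kept alignment blocks
#'
#' @param blocks kept alignment blocks (all queries).
#' @param ref_lengths named reference sequence lengths.
#' @param region region set data.frame (`seqid`, `start0`, `end0`),
#'   defaulting to the whole genome.
#' @return list with `representation`, `covered` (interval set clipped to
#'   the region), `covered_bases`, `region_bases`.
#' @export
compute_representation <- function(blocks, ref_lengths, region = NULL) {
  if (is.null(region)) region <- whole_genome_set(ref_lengths)
  covered_all <- blocks_to_set(blocks)
  covered <- set_intersect(covered_all, region)
  cb <- set_width(covered); rb <- set_width(region)
  list(representation = if (rb > 0) cb / rb else 0,
       covered = covered, covered_bases = cb, region_bases = rb)
}

#' Mismatch, indel and total error rates over a region
#'
#' Rates are events per `rate_scale` bases (default 100 kb) of aligned
#' reference within the region; aligned bases are summed block-by-block
#' (overlapping blocks count each overlap). Blocks carry event counts but
#' not within-block positions, so a block's events are apportioned to the
#' region in proportion to the fraction of the block's reference span that
#' overlaps it. `error_rate` is exactly `mismatch_rate + indel_rate`.
#'
#' @inheritParams compute_representation
#' @param config a [fidelity_config()] (for `rate_scale`).
#' @return list with the three rates, `aligned_ref_bases`, apportioned
#'   event sums, and `zero_aligned` flag (rates are reported as 0 when no
#'   base aligns inside the region).
#' @export
compute_error_rates <- function(blocks, ref_lengths, region = NULL,
                                config = fidelity_config()) {
  if (is.null(region)) region <- whole_genome_set(ref_lengths)
  if (nrow(blocks) == 0L)
    return(list(mismatch_rate = 0, indel_rate = 0, error_rate = 0,
                aligned_ref_bases = 0, n_mismatch = 0, n_indel_events = 0,
                zero_aligned = TRUE))
  ov <- numeric(nrow(blocks))
  for (sid in unique(blocks$ref_id)) {
    sel <- blocks$ref_id == sid
    rg <- region[region$seqid == sid, , drop = FALSE]
    if (nrow(rg) == 0L) next
    rr <- with(rg, ir0(start0, end0))
    br <- ir0(blocks$ref_start[sel], blocks$ref_end[sel])
    hits <- IRanges::findOverlaps(br, rr)
    w <- IRanges::width(IRanges::pintersect(
      br[S4Vectors::queryHits(hits)], rr[S4Vectors::subjectHits(hits)]))
    ov[sel] <- as.numeric(tapply(w, factor(S4Vectors::queryHits(hits),
                                           levels = seq_len(sum(sel))),
                                 sum, default = 0))
  }
  aligned <- sum(ov)
  frac <- ifelse(blocks$aligned_ref_len > 0, ov / blocks$aligned_ref_len, 0)
  mm <- sum(blocks$n_mismatch * frac)
  ie <- sum(blocks$n_indel_events * frac)
  if (aligned == 0)
    return(list(mismatch_rate = 0, indel_rate = 0, error_rate = 0,
                aligned_ref_bases = 0, n_mismatch = 0, n_indel_events = 0,
                zero_aligned = TRUE))
  sc <- config$rate_scale
  mr <- sc * mm / aligned
  ir <- sc * ie / aligned
  list(mismatch_rate = mr, indel_rate = ir, error_rate = mr + ir,
       aligned_ref_bases = aligned, n_mismatch = mm, n_indel_events = ie,
       zero_aligned = FALSE)
}

# Adjacency table over consecutive kept blocks of each query.
block_adjacencies <- function(blocks) {
  empty <- data.frame(qry_id = character(0), ref_id = character(0),
                      same_ref = logical(0), same_strand = logical(0),
                      qgap = integer(0), rgap = integer(0),
                      span_lo = integer(0), span_hi = integer(0),
                      consistent = logical(0), stringsAsFactors = FALSE)
  if (nrow(blocks) < 2L) return(empty)
  blocks <- blocks[order(blocks$qry_id, blocks$qry_start,
                         blocks$ref_start), , drop = FALSE]
  rows <- list()
  for (qid in unique(blocks$qry_id)) {
    b <- blocks[blocks$qry_id == qid, , drop = FALSE]
    if (nrow(b) < 2L) next
    for (i in 2:nrow(b)) {
      p <- b[i - 1L, ]; q <- b[i, ]
      same_ref <- p$ref_id == q$ref_id
      same_strand <- p$strand == q$strand
      qgap <- q$qry_start - p$qry_end
      if (same_ref && same_strand) {
        if (p$strand == "+") {
          rgap <- q$ref_start - p$ref_end
          lo <- p$ref_end; hi <- q$ref_start
        } else {
          rgap <- p$ref_start - q$ref_end
          lo <- q$ref_end; hi <- p$ref_start
        }
      } else { rgap <- NA_integer_; lo <- NA_integer_; hi <- NA_integer_ }
      rows[[length(rows) + 1L]] <- data.frame(
        qry_id = qid, ref_id = p$ref_id, same_ref = same_ref,
        same_strand = same_strand, qgap = qgap, rgap = rgap,
        span_lo = lo, span_hi = hi,
        consistent = same_ref && same_strand && !is.na(rgap) && rgap >= 0,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Gap accounting over a region
#'
#' Gaps are maximal reference intervals inside the region not covered by
#' any kept block. Negative gaps are reference overlaps between consecutive
#' kept blocks of one query. Captured gaps are gaps spanned by a single
#' scaffold: their flanking blocks are consecutive blocks of one query on
#' the same reference and strand in consistent order (typically across an
#' N run). Internal gaps/overlaps count query-coordinate gaps/overlaps
#' between consecutive kept blocks (assembly-level, not region-clipped).
#'
#' @param blocks kept alignment blocks.
#' @param ref_lengths named reference sequence lengths.
#' @param region region set (default whole genome).
#' @param covered optional precomputed covered set clipped to the region.
#' @return list with the gap fields of the metric record.
#' @export
compute_gaps <- function(blocks, ref_lengths, region = NULL,
                         covered = NULL) {
  if (is.null(region)) region <- whole_genome_set(ref_lengths)
  if (is.null(covered))
    covered <- set_intersect(blocks_to_set(blocks), region)
  gaps <- set_diff(region, covered)
  adj <- block_adjacencies(blocks)
  # negative gaps within the region
  neg <- adj[adj$same_ref & adj$same_strand & !is.na(adj$rgap) &
               adj$rgap < 0, , drop = FALSE]
  if (nrow(neg)) {
    ns <- pmin(neg$span_lo, neg$span_hi); ne <- pmax(neg$span_lo,
                                                     neg$span_hi)
    in_region <- vapply(seq_len(nrow(neg)), function(i) {
      rg <- region[region$seqid == neg$ref_id[i], , drop = FALSE]
      nrow(rg) > 0 &&
        any(ns[i] < rg$end0 & ne[i] > rg$start0)
    }, logical(1))
    neg <- neg[in_region, , drop = FALSE]
  }
  n_neg <- nrow(neg)
  avg_neg <- if (n_neg) mean(-neg$rgap) else 0
  # captured gaps: gaps contained in a consistent same-query spanning pair
  span <- adj[adj$consistent & adj$rgap > 0, , drop = FALSE]
  captured <- logical(nrow(gaps))
  if (nrow(gaps) && nrow(span)) {
    for (i in seq_len(nrow(gaps))) {
      captured[i] <- any(span$ref_id == gaps$seqid[i] &
                           span$span_lo <= gaps$start0[i] &
                           span$span_hi >= gaps$end0[i])
    }
  }
  gw <- gaps$end0 - gaps$start0
  cw <- gw[captured]
  list(n_gaps = nrow(gaps),
       avg_gap_size = if (nrow(gaps)) mean(gw) else 0,
       total_gap_bases = sum(gw),
       n_negative_gaps = n_neg,
       avg_negative_gap_size = avg_neg,
       n_captured_gaps = sum(captured),
       avg_captured_gap_size = if (length(cw)) mean(cw) else 0,
       total_captured_gap_bases = sum(cw),
       internal_gaps = sum(adj$qgap > 0),
       internal_overlaps = sum(adj$qgap < 0),
       gaps = gaps)
}
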