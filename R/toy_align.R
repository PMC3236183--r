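#' Exact-anchor alignment of an assembly against a reference
#'
#' A small, fully deterministic aligner intended for test-scale references
#' (guarded at `max_ref_size`, default 10 Mb): it makes the whole evaluation
#' pipeline runnable without external aligner binaries. For each query and
#' each strand it finds maximal exact matches of at least `min_anchor` bases
#' via a reference k-mer index, chains collinear anchors greedily along
#' diagonals (gap limit `max_chain_gap` on both coordinates, diagonal drift
#' limit `max_indel`), closes the gaps between chained anchors with global
#' alignment at unit mismatch/indel costs, and emits one alignment block per
#' chain with exact mismatch and indel counts. Chains are never extended
#' across query gaps containing `N` (so scaffold N runs break blocks, as
#' they do for a real aligner). Chains whose match count falls below
#' `min_anchor` are dropped. Ties between equal-scoring chains are broken by
#' lower reference start, then `+` strand.
#'
#' This is not a sensitive aligner: diverged copies below ~`min_anchor`
#' exact-match seeds are missed, as are alignments whose indels exceed
#' `max_indel`. For genome-scale work align externally (e.g.
#' `nucmer -o -p out ref.fasta asm.fasta` then [parse_coords()], or
#' minimap2 PAF then [parse_paf()]).
#'
#' @param ref named character vector of reference sequences.
#' @param assembly an `assembly_set` from [split_scaffolds()], or a named
#'   character vector of query sequences.
#' @param min_anchor minimum exact-match seed length (default 21).
#' @param max_chain_gap maximum query/reference gap bridged within one
#'   chain (default 2000).
#' @param max_indel maximum diagonal drift (net indel) bridged within one
#'   chain (default 50).
#' @param max_ref_size guard on total reference size in bases.
#' @return data.frame of alignment blocks (see [parse_coords()] for the
#'   column contract).
#' @export
toy_align <- function(ref, assembly, min_anchor = 21L,
                      max_chain_gap = 2000L, max_indel = 50L,
                      max_ref_size = 10e6) {
  if (inherits(assembly, "assembly_set")) queries <- assembly$scaffolds
  else queries <- assembly
  stopifnot(is.character(ref), !is.null(names(ref)),
            is.character(queries), !is.null(names(queries)))
  if (sum(nchar(ref)) > max_ref_size)
    stop("reference exceeds the toy-aligner guard of ", max_ref_size,
         " bases; align externally (nucmer/minimap2) and use ",
         "parse_coords()/parse_paf()", call. = FALSE)
  k <- as.integer(min_anchor)
  index <- build_kmer_index(ref, k)
  out <- list()
  for (qid in names(queries)) {
    q <- queries[[qid]]
    for (st in c("+", "-")) {
      qs <- if (st == "+") q else revcomp(q)
      chains <- chain_query(qs, index, ref, k, max_chain_gap, max_indel)
      for (ch in chains) {
        b <- score_chain(ch, qs, ref, k, max_indel)
        if (is.null(b) || b$matches < k) next
        L <- nchar(q)
        qry_start <- if (st == "+") b$qs else L - b$qe
        qry_end <- if (st == "+") b$qe else L - b$qs
        out[[length(out) + 1L]] <- data.frame(
          ref_id = b$ref_id, ref_start = b$rs, ref_end = b$re,
          qry_id = qid, qry_start = qry_start, qry_end = qry_end,
          strand = st,
          aligned_ref_len = b$re - b$rs, aligned_qry_len = b$qe - b$qs,
          n_mismatch = b$n_mismatch, n_indel_events = b$n_indel_events,
          n_indel_bases = b$n_indel_bases,
          identity = b$matches / b$columns, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty_blocks())
  blocks <- do.call(rbind, out)
  blocks <- blocks[order(blocks$qry_id, blocks$qry_start, blocks$ref_start,
                         blocks$strand != "+"), , drop = FALSE]
  rownames(blocks) <- NULL
  blocks
}

# k-mer index: list mapping kmer string -> data.frame(ref_idx, pos0).
build_kmer_index <- function(ref, k) {
  tabs <- lapply(seq_along(ref), function(i) {
    s <- ref[[i]]
    L <- nchar(s)
    if (L < k) return(NULL)
    km <- substring(s, 1:(L - k + 1L), k:L)
    ok <- !grepl("N", km, fixed = TRUE)
    data.frame(kmer = km[ok], ref_idx = i, pos = which(ok) - 1L,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, Filter(Negate(is.null), tabs))
  list(map = split(seq_len(nrow(tab)), tab$kmer),
       ref_idx = tab$ref_idx, pos = tab$pos)
}

# Find anchors (maximal runs of consecutive k-mer hits on one diagonal) and
# chain them greedily. Returns a list of chains; each chain is a data.frame
# of anchors (ref_idx, qstart, qend, rstart, rend) in query order.
chain_query <- function(qs, index, ref, k, max_chain_gap, max_indel) {
  L <- nchar(qs)
  if (L < k) return(list())
  qk <- substring(qs, 1:(L - k + 1L), k:L)
  ok <- !grepl("N", qk, fixed = TRUE)
  hit_rows <- index$map[qk[ok]]
  qpos_all <- (which(ok) - 1L)
  nh <- lengths(hit_rows)
  if (sum(nh, na.rm = TRUE) == 0L) return(list())
  present <- !vapply(hit_rows, is.null, logical(1))
  rows <- unlist(hit_rows[present], use.names = FALSE)
  hits <- data.frame(qpos = rep(qpos_all[present], nh[present]),
                     ref_idx = index$ref_idx[rows],
                     rpos = index$pos[rows])
  hits$diag <- hits$rpos - hits$qpos
  hits <- hits[order(hits$ref_idx, hits$diag, hits$qpos), , drop = FALSE]
  # collapse consecutive-q runs on each diagonal into anchors
  new_run <- c(TRUE, diff(hits$qpos) != 1L |
                 diff(hits$diag) != 0L | diff(hits$ref_idx) != 0L)
  run_id <- cumsum(new_run)
  first <- !duplicated(run_id)
  last <- rev(!duplicated(rev(run_id)))
  anchors <- data.frame(ref_idx = hits$ref_idx[first],
                        qstart = hits$qpos[first],
                        qend = hits$qpos[last] + k,
                        rstart = hits$rpos[first],
                        rend = hits$rpos[last] + k)
  anchors <- anchors[order(anchors$qstart, anchors$rstart), , drop = FALSE]
  # greedy multi-chain attach
  chains <- list()   # each: list(anchors = df, tail row)
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    best <- 0L; best_pen <- Inf
    for (ci in seq_along(chains)) {
      t <- chains[[ci]]$tail
      if (t$ref_idx != a$ref_idx) next
      o <- max(0L, t$qend - a$qstart, t$rend - a$rstart)
      aq <- a$qstart + o; ar <- a$rstart + o
      if (aq >= a$qend) next              # anchor swallowed by overlap trim
      qgap <- aq - t$qend; rgap <- ar - t$rend
      if (qgap < 0L || rgap < 0L) next
      if (qgap > max_chain_gap || rgap > max_chain_gap) next
      if (abs(rgap - qgap) > max_indel) next
      if (qgap > 0L &&
          grepl("N", substr(qs, t$qend + 1L, aq), fixed = TRUE)) next
      # do not bridge long divergent double-gaps (e.g. across an inverted
      # segment): a real aligner breaks there, and so does the chain
      if (qgap > 2L * k && rgap > 2L * k) {
        m <- min(qgap, rgap)
        va <- strsplit(substr(qs, t$qend + 1L, t$qend + m), "")[[1]]
        vb <- strsplit(substr(ref[[a$ref_idx]], t$rend + 1L, t$rend + m),
                       "")[[1]]
        if (mean(va != vb) > 0.3) next
      }
      pen <- abs(rgap - qgap) * 1000 + qgap + rgap
      if (pen < best_pen) { best <- ci; best_pen <- pen }
    }
    if (best > 0L) {
      t <- chains[[best]]$tail
      o <- max(0L, t$qend - a$qstart, t$rend - a$rstart)
      a$qstart <- a$qstart + o; a$rstart <- a$rstart + o
      chains[[best]]$anchors <- rbind(chains[[best]]$anchors, a)
      chains[[best]]$tail <- a
    } else {
      chains[[length(chains) + 1L]] <- list(anchors = a, tail = a)
    }
  }
  lapply(chains, `[[`, "anchors")
}

# Turn one chain of anchors into block coordinates and exact edit counts:
# close inter-anchor gaps with global alignment at unit costs, then extend
# the chain head/tail over same-diagonal stubs (counting mismatches).
score_chain <- function(anchors, qs, ref, k, max_indel) {
  ref_id <- names(ref)[anchors$ref_idx[1]]
  rseq <- ref[[anchors$ref_idx[1]]]
  matches <- sum(anchors$qend - anchors$qstart)
  nmm <- 0L; nie <- 0L; nib <- 0L; columns <- matches
  n_anc <- nrow(anchors)
  if (n_anc > 1L) {
    for (i in 2:n_anc) {
      qgap <- anchors$qstart[i] - anchors$qend[i - 1L]
      rgap <- anchors$rstart[i] - anchors$rend[i - 1L]
      if (qgap == 0L && rgap == 0L) next
      qseq <- substr(qs, anchors$qend[i - 1L] + 1L, anchors$qstart[i])
      rgseq <- substr(rseq, anchors$rend[i - 1L] + 1L, anchors$rstart[i])
      g <- align_gap(qseq, rgseq)
      nmm <- nmm + g$n_mismatch; nie <- nie + g$n_indel_events
      nib <- nib + g$n_indel_bases
      matches <- matches + g$n_match
      columns <- columns + g$columns
    }
  }
  qsr <- anchors$qstart[1]; qer <- anchors$qend[n_anc]
  rsr <- anchors$rstart[1]; rer <- anchors$rend[n_anc]
  # head stub: same-diagonal mismatch-only extension. Stubs are capped at
  # 3k bases: a longer truly-homologous stretch would have seeded its own
  # anchors, so a long stub means a structural junction, not missed bases.
  if (qsr > 0L && qsr <= 3L * k && rsr >= qsr) {
    h <- stub_compare(substr(qs, 1L, qsr),
                      substr(rseq, rsr - qsr + 1L, rsr))
    if (!is.null(h)) {
      nmm <- nmm + h$n_mismatch; matches <- matches + h$n_match
      columns <- columns + h$columns
      qsr <- 0L; rsr <- rsr - h$columns
    }
  }
  Lq <- nchar(qs); Lr <- nchar(rseq)
  tail_len <- Lq - qer
  if (tail_len > 0L && tail_len <= 3L * k && Lr - rer >= tail_len) {
    t <- stub_compare(substring(qs, qer + 1L),
                      substr(rseq, rer + 1L, rer + tail_len))
    if (!is.null(t)) {
      nmm <- nmm + t$n_mismatch; matches <- matches + t$n_match
      columns <- columns + t$columns
      qer <- Lq; rer <- rer + t$columns
    }
  }
  list(ref_id = ref_id, qs = qsr, qe = qer, rs = rsr, re = rer,
       n_mismatch = nmm, n_indel_events = nie, n_indel_bases = nib,
       matches = matches, columns = columns)
}

# Mismatch-only comparison of equal-length stubs at chain ends; refuses
# (returns NULL) when the stub is mostly mismatch or contains N, leaving
# the stub unaligned instead.
stub_compare <- function(a, b) {
  if (nchar(a) == 0L) return(NULL)
  if (grepl("N", a, fixed = TRUE) || grepl("N", b, fixed = TRUE))
    return(NULL)
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  d <- sum(va != vb)
  if (d > 0.5 * length(va)) return(NULL)
  list(n_mismatch = d, n_match = length(va) - d, columns = length(va))
}

# End-to-end global alignment of two short gap segments at unit costs.
align_gap <- function(qseq, rseq) {
  nq <- nchar(qseq); nr <- nchar(rseq)
  if (nq == 0L) return(list(n_mismatch = 0L, n_indel_events = 1L,
                            n_indel_bases = nr, n_match = 0L, columns = nr))
  if (nr == 0L) return(list(n_mismatch = 0L, n_indel_events = 1L,
                            n_indel_bases = nq, n_match = 0L, columns = nq))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(qseq, rseq, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 1)
  ind <- Biostrings::nindel(aln)
  ins <- Biostrings::insertion(ind); del <- Biostrings::deletion(ind)
  # nindel reports per-alignment (gap count, total width) summaries
  n_ie <- ins[1, "Length"] + del[1, "Length"]
  n_ib <- ins[1, "WidthSum"] + del[1, "WidthSum"]
  nmm <- Biostrings::nmismatch(aln)
  nmatch <- Biostrings::nmatch(aln)
  list(n_mismatch = nmm, n_indel_events = n_ie, n_indel_bases = n_ib,
       n_match = nmatch, columns = nmatch + nmm + n_ib)
}
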