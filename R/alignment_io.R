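# Alignment blocks are plain data.frames with one row per contiguous
# assembly<->reference alignment segment. Internal convention everywhere:
# 0-based half-open coordinates, query interval on the forward query strand.
# Dialect quirks (1-based inclusive, reversed query coordinates) are
# normalized at the parser boundary and reintroduced only by the writers.

block_cols <- c("ref_id", "ref_start", "ref_end", "qry_id", "qry_start",
                "qry_end", "strand", "aligned_ref_len", "aligned_qry_len",
                "n_mismatch", "n_indel_events", "n_indel_bases", "identity")

empty_blocks <- function() {
  df <- data.frame(ref_id = character(0), ref_start = integer(0),
                   ref_end = integer(0), qry_id = character(0),
                   qry_start = integer(0), qry_end = integer(0),
                   strand = character(0), aligned_ref_len = integer(0),
                   aligned_qry_len = integer(0), n_mismatch = integer(0),
                   n_indel_events = integer(0), n_indel_bases = integer(0),
                   identity = numeric(0), stringsAsFactors = FALSE)
  df
}

#' Parse MUMmer show-coords output into alignment blocks
#'
#' Reads the pipe-separated tabular text written by `show-coords` (run on a
#' nucmer delta file), e.g. rows of the form
#' `1 100 | 1 100 | 100 100 | 100.00 | chr1 ctg1`. Header and ruler lines
#' are skipped. Coordinates are converted from 1-based inclusive to the
#' internal 0-based half-open convention; reverse-strand alignments (query
#' start > end) are flipped onto the forward query strand with strand `-`.
#'
#' show-coords rows carry no separate mismatch/indel counts, so counts are
#' reconstructed from the identity and the aligned lengths: indel bases are
#' taken as `|ref_len - qry_len|` (the minimum consistent with the
#' lengths, as one event), and the remaining error bases as mismatches.
#' This is a documented approximation; PAF input with a `cg:Z` tag carries
#' exact counts.
#'
#' @param path path to show-coords text output.
#' @return data.frame of alignment blocks (possibly zero rows).
#' @export
parse_coords <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- grepl("^\\s*\\d", lines) & grepl("|", lines, fixed = TRUE)
  if (!any(keep)) return(empty_blocks())
  rows <- lapply(which(keep), function(i) {
    f <- strsplit(gsub("\\|", " ", lines[i]), "[ \t]+")[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 9L)
      stop("malformed show-coords row at line ", i, call. = FALSE)
    num <- suppressWarnings(as.numeric(f[1:7]))
    if (anyNA(num))
      stop("malformed show-coords row at line ", i, call. = FALSE)
    s1 <- num[1]; e1 <- num[2]; s2 <- num[3]; e2 <- num[4]
    len1 <- num[5]; len2 <- num[6]; idy <- num[7] / 100
    fwd <- s2 <= e2
    qs <- if (fwd) s2 - 1 else e2 - 1
    qe <- if (fwd) e2 else s2
    cols <- max(len1, len2)
    nib <- abs(len1 - len2)
    nmm <- max(0, round(cols * (1 - idy)) - nib)
    data.frame(ref_id = f[8], ref_start = as.integer(s1 - 1),
               ref_end = as.integer(e1), qry_id = f[9],
               qry_start = as.integer(qs), qry_end = as.integer(qe),
               strand = if (fwd) "+" else "-",
               aligned_ref_len = as.integer(len1),
               aligned_qry_len = as.integer(len2),
               n_mismatch = as.integer(nmm),
               n_indel_events = as.integer(nib > 0),
               n_indel_bases = as.integer(nib),
               identity = idy, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write alignment blocks as show-coords tabular text
#'
#' Counterpart of [parse_coords()]; emits 1-based inclusive coordinates
#' with reverse-strand query intervals written start > end, identity as a
#' percentage with 4 decimals.
#'
#' @param blocks alignment-block data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coords <- function(blocks, path) {
  hdr <- c("NUCMER", "",
           "    [S1]     [E1]  |     [S2]     [E2]  |  [LEN 1]  [LEN 2]  |  [% IDY]  | [TAGS]",
           strrep("=", 80))
  fwd <- blocks$strand == "+"
  s2 <- ifelse(fwd, blocks$qry_start + 1L, blocks$qry_end)
  e2 <- ifelse(fwd, blocks$qry_end, blocks$qry_start + 1L)
  rows <- sprintf("%8d %8d  | %8d %8d  | %8d %8d  | %9.4f  | %s\t%s",
                  blocks$ref_start + 1L, blocks$ref_end, s2, e2,
                  blocks$aligned_ref_len, blocks$aligned_qry_len,
                  100 * blocks$identity, blocks$ref_id, blocks$qry_id)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# Count alignment events from a CIGAR string (=, X, M, I, D ops).
cigar_counts <- function(cg) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
  tok <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
  len <- as.integer(sub("[A-Z=]$", "", tok))
  op <- sub("^\\d+", "", tok)
  list(n_mismatch = sum(len[op == "X"]),
       n_match = sum(len[op %in% c("=", "M")]),
       n_indel_events = sum(op %in% c("I", "D")),
       n_indel_bases = sum(len[op %in% c("I", "D")]))
}

#' Parse PAF alignments into alignment blocks
#'
#' Accepts 12+ column PAF. PAF's native 0-based half-open, forward-query
#' coordinates are kept as-is. Column 10 (matches) and 11 (alignment block
#' length) give the identity; when a `cg:Z` CIGAR tag is present, exact
#' mismatch and indel event counts are taken from it, otherwise indel bases
#' are reconstructed as the aligned-length difference and the remaining
#' error bases counted as mismatches.
#'
#' @param path path to a PAF file.
#' @return data.frame of alignment blocks.
#' @export
parse_paf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_blocks())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L)
      stop("PAF line ", i, " has fewer than 12 columns", call. = FALSE)
    qs <- as.integer(f[3]); qe <- as.integer(f[4])
    ts <- as.integer(f[8]); te <- as.integer(f[9])
    matches <- as.integer(f[10]); blk <- as.integer(f[11])
    cg <- grep("^cg:Z:", f[-(1:12)], value = TRUE)
    if (length(cg) == 1L) {
      cc <- cigar_counts(sub("^cg:Z:", "", cg))
      nmm <- cc$n_mismatch; nie <- cc$n_indel_events; nib <- cc$n_indel_bases
    } else {
      nib <- abs((qe - qs) - (te - ts))
      nie <- as.integer(nib > 0)
      nmm <- max(0L, blk - matches - nib)
    }
    data.frame(ref_id = f[6], ref_start = ts, ref_end = te,
               qry_id = f[1], qry_start = qs, qry_end = qe,
               strand = f[5],
               aligned_ref_len = te - ts, aligned_qry_len = qe - qs,
               n_mismatch = as.integer(nmm),
               n_indel_events = as.integer(nie),
               n_indel_bases = as.integer(nib),
               identity = matches / blk, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write alignment blocks as PAF
#'
#' Counterpart of [parse_paf()]. Sequence lengths for PAF columns 2 and 7
#' are taken from the supplied length maps (0 when unknown).
#'
#' @param blocks alignment-block data.frame.
#' @param path output path.
#' @param qry_lengths,ref_lengths named integer vectors of sequence lengths.
#' @return `path`, invisibly.
#' @export
write_paf <- function(blocks, path, qry_lengths = NULL, ref_lengths = NULL) {
  ql <- if (is.null(qry_lengths)) rep(0L, nrow(blocks))
        else unname(qry_lengths[blocks$qry_id])
  tl <- if (is.null(ref_lengths)) rep(0L, nrow(blocks))
        else unname(ref_lengths[blocks$ref_id])
  cols <- pmax(blocks$aligned_ref_len, blocks$aligned_qry_len)
  matches <- cols - blocks$n_mismatch - blocks$n_indel_bases
  lines <- paste(blocks$qry_id, ql, blocks$qry_start, blocks$qry_end,
                 blocks$strand, blocks$ref_id, tl, blocks$ref_start,
                 blocks$ref_end, matches, cols, 60L, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
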