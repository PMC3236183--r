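#' Error-model parameters for simulated reads
#'
#' The Illumina model applies substitutions whose per-base probability ramps
#' linearly from the 5' to the 3' end of the read (no indels). The 454-style
#' model applies a uniform per-base substitution rate plus homopolymer
#' indels: each maximal homopolymer run of length k >= 2 suffers a +/-1 base
#' indel of the run's nucleotide with probability `min(1, k * slope)`.
#' Defaults are typical-rate choices, configurable per dataset.
#'
#' @param illumina_sub_rate_start substitution probability at the 5' base.
#' @param illumina_sub_rate_end substitution probability at the 3' base.
#' @param ls454_base_sub_rate uniform 454 substitution probability.
#' @param ls454_homopolymer_slope per-run-base indel probability increment.
#' @return list of class `error_model_params`.
#' @export
error_model_params <- function(illumina_sub_rate_start = 0.001,
                               illumina_sub_rate_end = 0.01,
                               ls454_base_sub_rate = 0.001,
                               ls454_homopolymer_slope = 0.01) {
  p <- list(illumina_sub_rate_start = illumina_sub_rate_start,
            illumina_sub_rate_end = illumina_sub_rate_end,
            ls454_base_sub_rate = ls454_base_sub_rate,
            ls454_homopolymer_slope = ls454_homopolymer_slope)
  bad <- vapply(p, function(v) v < 0 || v > 1, logical(1))
  if (any(bad)) stop("error-model probabilities must lie in [0,1]: ",
                     paste(names(p)[bad], collapse = ", "), call. = FALSE)
  structure(p, class = "error_model_params")
}

#' Specification of one simulated read dataset
#'
#' Mirrors the dataset design of platform-comparison studies: 454-style
#' reads are 500 bp; Illumina-style reads are 50, 75 or 100 bp; paired-end
#' insert sizes come from the panel {2000, 8000, 20000, 40000}, with 500 bp
#' additionally offered for Illumina only (any positive value is accepted
#' for non-panel experiments via `allow_any_insert`). Insert size means the
#' outer distance, mate-1 start to mate-2 end. Coverage is total read bases
#' divided by genome length.
#'
#' @param platform `"LS454"` or `"ILLUMINA"`.
#' @param read_length read length in bases (454 default 500).
#' @param paired logical; paired-end dataset?
#' @param insert_mean mean outer insert size in bases (paired only).
#' @param insert_sd insert-size standard deviation; defaults to 10% of
#'   the mean.
#' @param coverage fold-coverage of the reference (> 0).
#' @param seed integer RNG seed; identical (reference, spec, seed) gives
#'   byte-identical output.
#' @param error_params an [error_model_params()] object.
#' @param allow_any_insert accept insert sizes outside the standard panel.
#' @return list of class `read_dataset_spec`.
#' @export
read_dataset_spec <- function(platform = c("ILLUMINA", "LS454"),
                              read_length = if (platform == "LS454") 500L
                                            else 75L,
                              paired = TRUE,
                              insert_mean = 2000L,
                              insert_sd = NULL,
                              coverage = 20,
                              seed = 1L,
                              error_params = error_model_params(),
                              allow_any_insert = FALSE) {
  platform <- match.arg(platform)
  stopifnot(read_length > 0, coverage > 0)
  if (platform == "ILLUMINA" && !read_length %in% c(50L, 75L, 100L) &&
      !allow_any_insert)
    stop("Illumina read_length must be one of 50, 75, 100", call. = FALSE)
  if (paired) {
    if (insert_mean < 2 * read_length)
      stop("paired reads require insert_mean >= 2 * read_length",
           call. = FALSE)
    panel <- c(2000, 8000, 20000, 40000)
    if (platform == "ILLUMINA") panel <- c(500, panel)
    if (!allow_any_insert && !insert_mean %in% panel)
      stop("insert_mean ", insert_mean, " not in the standard panel for ",
           platform, " (", paste(panel, collapse = ", "),
           "); set allow_any_insert = TRUE to override", call. = FALSE)
  }
  if (is.null(insert_sd)) insert_sd <- 0.1 * insert_mean
  structure(list(platform = platform,
                 read_length = as.integer(read_length),
                 paired = isTRUE(paired),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 coverage = coverage, seed = as.integer(seed),
                 error_params = error_params),
            class = "read_dataset_spec")
}

#' Plan the read count for a dataset
#'
#' Coverage semantics: total read bases / genome length. The read count is
#' `ceiling(coverage * genome_length / read_length)`, rounded up to even
#' for paired datasets.
#'
#' @param spec a [read_dataset_spec()].
#' @param genome_length reference length in bases.
#' @return list with `n_reads` and `n_pairs` (`NA` for fragment datasets).
#' @export
plan_dataset <- function(spec, genome_length) {
  stopifnot(inherits(spec, "read_dataset_spec"), genome_length > 0)
  n <- ceiling(spec$coverage * genome_length / spec$read_length)
  if (spec$paired && n %% 2 == 1) n <- n + 1
  list(n_reads = as.integer(n),
       n_pairs = if (spec$paired) as.integer(n / 2) else NA_integer_)
}

#' Sample insert (or fragment) placements on a reference
#'
#' The reference sequence is chosen with probability proportional to its
#' length among sequences long enough to hold the minimum insert. Insert
#' lengths are drawn from Normal(insert_mean, insert_sd), truncated (by
#' clamping) to `[2 * read_length, sequence length]` and rounded. Start
#' positions are uniform over valid placements; strand is uniform.
#'
#' @param spec a [read_dataset_spec()].
#' @param ref named character vector of reference sequences.
#' @param n number of placements to draw.
#' @return data.frame with columns `ref_id`, `start` (0-based),
#'   `insert_len`, `strand`.
#' @export
sample_insert <- function(spec, ref, n) {
  lens <- nchar(ref)
  min_len <- if (spec$paired) 2L * spec$read_length else spec$read_length
  elig <- lens >= min_len
  if (!any(elig))
    stop("no reference sequence can hold the minimum ",
         if (spec$paired) "insert" else "read", " of ", min_len, " bases",
         call. = FALSE)
  if (spec$paired && all(lens[elig] < spec$insert_mean - 3 * spec$insert_sd))
    stop("insert_mean ", spec$insert_mean,
         " is impossible on references of max length ", max(lens),
         call. = FALSE)
  idx <- sample(which(elig), n, replace = TRUE, prob = lens[elig])
  if (spec$paired) {
    ins <- round(rnorm(n, spec$insert_mean, spec$insert_sd))
    ins <- pmax(2L * spec$read_length, pmin(ins, lens[idx]))
  } else {
    ins <- rep(spec$read_length, n)
  }
  start <- floor(runif(n) * (lens[idx] - ins + 1))
  data.frame(ref_id = names(ref)[idx], start = as.integer(start),
             insert_len = as.integer(ins),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# ---- edit lists ------------------------------------------------------------
# An edit list is a data.frame(op, pos, from, to, len): op "S" substitution
# (from > to at 0-based template position pos), "I" insertion (string `to`
# inserted before template position pos), "D" deletion (len bases removed at
# pos). Applying the list to the strand-oriented template substring of the
# reference reproduces the emitted read exactly.

empty_edits <- function() {
  data.frame(op = character(0), pos = integer(0), from = character(0),
             to = character(0), len = integer(0), stringsAsFactors = FALSE)
}

#' Apply an edit list to a template sequence
#'
#' @param template strand-oriented template substring.
#' @param edits edit-list data.frame (see [format_edits()]).
#' @return the mutated read sequence.
#' @export
apply_edits <- function(template, edits) {
  if (is.null(edits) || nrow(edits) == 0L) return(template)
  subs <- edits[edits$op == "S", , drop = FALSE]
  for (i in seq_len(nrow(subs)))
    substr(template, subs$pos[i] + 1L, subs$pos[i] + 1L) <- subs$to[i]
  indels <- edits[edits$op != "S", , drop = FALSE]
  indels <- indels[order(indels$pos, decreasing = TRUE), , drop = FALSE]
  for (i in seq_len(nrow(indels))) {
    p <- indels$pos[i]
    if (indels$op[i] == "I") {
      template <- paste0(substr(template, 1L, p), indels$to[i],
                         substring(template, p + 1L))
    } else {
      template <- paste0(substr(template, 1L, p),
                         substring(template, p + indels$len[i] + 1L))
    }
  }
  template
}

#' Serialize / parse edit lists
#'
#' Edits are serialized as semicolon-joined tokens: `S<pos>:<from>><to>`,
#' `I<pos>:<seq>`, `D<pos>:<len>` (0-based template positions).
#'
#' @param edits edit-list data.frame.
#' @return `format_edits`: a single string ("" when no edits);
#'   `parse_edits`: the data.frame back.
#' @export
format_edits <- function(edits) {
  if (is.null(edits) || nrow(edits) == 0L) return("")
  tok <- character(nrow(edits))
  s <- edits$op == "S"; i <- edits$op == "I"; d <- edits$op == "D"
  tok[s] <- paste0("S", edits$pos[s], ":", edits$from[s], ">", edits$to[s])
  tok[i] <- paste0("I", edits$pos[i], ":", edits$to[i])
  tok[d] <- paste0("D", edits$pos[d], ":", edits$len[d])
  paste(tok, collapse = ";")
}

#' @rdname format_edits
#' @param s serialized edit string.
#' @export
parse_edits <- function(s) {
  if (is.na(s) || s == "") return(empty_edits())
  tok <- strsplit(s, ";", fixed = TRUE)[[1]]
  op <- substr(tok, 1, 1)
  body <- substring(tok, 2)
  pos <- as.integer(sub(":.*", "", body))
  val <- sub("^[^:]*:", "", body)
  out <- empty_edits()
  for (j in seq_along(tok)) {
    row <- switch(op[j],
      S = data.frame(op = "S", pos = pos[j],
                     from = sub(">.*", "", val[j]),
                     to = sub(".*>", "", val[j]), len = 1L,
                     stringsAsFactors = FALSE),
      I = data.frame(op = "I", pos = pos[j], from = "", to = val[j],
                     len = nchar(val[j]), stringsAsFactors = FALSE),
      D = data.frame(op = "D", pos = pos[j], from = "", to = "",
                     len = as.integer(val[j]), stringsAsFactors = FALSE))
    out <- rbind(out, row)
  }
  out
}

# ---- error models ----------------------------------------------------------

#' Apply position-ramped Illumina substitution errors
#'
#' Each position i (0-based) of an L-base read is substituted with
#' probability `start + (end - start) * i / (L - 1)`; the substituted base
#' is uniform over the three alternatives. `N` bases are never mutated.
#'
#' @param reads character vector of equal-length read sequences.
#' @param params an [error_model_params()].
#' @return list with `reads` (mutated) and `edits` (data.frame with
#'   `read` index plus the edit-list columns).
#' @export
apply_illumina_errors <- function(reads, params) {
  n <- length(reads)
  if (n == 0L) return(list(reads = reads, edits = cbind(read = integer(0),
                                                        empty_edits())))
  L <- unique(nchar(reads))
  stopifnot(length(L) == 1L)
  p0 <- params$illumina_sub_rate_start
  p1 <- params$illumina_sub_rate_end
  p <- if (L == 1L) p0 else p0 + (p1 - p0) * (0:(L - 1)) / (L - 1)
  big <- strsplit(paste0(reads, collapse = ""), "", fixed = TRUE)[[1]]
  hit <- which(runif(n * L) < rep(p, n))
  from <- big[hit]
  ok <- from %in% c("A", "C", "G", "T")
  hit <- hit[ok]; from <- from[ok]
  alt <- matrix(c("C", "G", "T",  "A", "G", "T",
                  "A", "C", "T",  "A", "C", "G"), nrow = 3)
  to <- alt[cbind(sample.int(3, length(hit), replace = TRUE),
                  match(from, c("A", "C", "G", "T")))]
  big[hit] <- to
  bigstr <- paste0(big, collapse = "")
  starts <- seq(1L, by = L, length.out = n)
  out <- substring(bigstr, starts, starts + L - 1L)
  edits <- if (length(hit))
    data.frame(read = as.integer(ceiling(hit / L)), op = "S",
               pos = as.integer((hit - 1L) %% L),
               from = from, to = to, len = 1L, stringsAsFactors = FALSE)
  else cbind(read = integer(0), empty_edits())
  edits <- edits[order(edits$read, edits$pos), , drop = FALSE]
  rownames(edits) <- NULL
  list(reads = out, edits = edits)
}

#' Apply 454-style substitution and homopolymer-indel errors
#'
#' Substitutions occur uniformly at `ls454_base_sub_rate`. Independently,
#' every maximal homopolymer run of length k >= 2 (detected on the template)
#' receives a +/-1 base indel of the run's nucleotide with probability
#' `min(1, k * ls454_homopolymer_slope)`, direction equiprobable. Reads keep
#' their post-indel length (454 read lengths are intrinsically variable);
#' no re-trimming or padding is applied.
#'
#' @inheritParams apply_illumina_errors
#' @return list with `reads` and `edits` as in [apply_illumina_errors()].
#' @export
apply_454_errors <- function(reads, params) {
  sub_rate <- params$ls454_base_sub_rate
  slope <- params$ls454_homopolymer_slope
  out <- character(length(reads))
  all_edits <- vector("list", length(reads))
  alt <- matrix(c("C", "G", "T",  "A", "G", "T",
                  "A", "C", "T",  "A", "C", "G"), nrow = 3)
  for (j in seq_along(reads)) {
    tmpl <- reads[[j]]
    v <- strsplit(tmpl, "", fixed = TRUE)[[1]]
    ed <- list()
    # substitutions
    hit <- which(runif(length(v)) < sub_rate & v %in% c("A", "C", "G", "T"))
    if (length(hit)) {
      to <- alt[cbind(sample.int(3, length(hit), replace = TRUE),
                      match(v[hit], c("A", "C", "G", "T")))]
      ed[[length(ed) + 1L]] <- data.frame(op = "S", pos = hit - 1L,
                                          from = v[hit], to = to, len = 1L,
                                          stringsAsFactors = FALSE)
    }
    # homopolymer indels on template-run structure
    r <- rle(v)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    runs <- which(r$lengths >= 2L & r$values %in% c("A", "C", "G", "T"))
    if (length(runs)) {
      pr <- pmin(1, r$lengths[runs] * slope)
      ev <- runs[runif(length(runs)) < pr]
      for (k in ev) {
        if (runif(1) < 0.5) {
          ed[[length(ed) + 1L]] <- data.frame(op = "I",
            pos = run_start[k] - 1L, from = "", to = r$values[k], len = 1L,
            stringsAsFactors = FALSE)
        } else {
          ed[[length(ed) + 1L]] <- data.frame(op = "D",
            pos = run_start[k] - 1L, from = "", to = "", len = 1L,
            stringsAsFactors = FALSE)
        }
      }
    }
    edits <- if (length(ed)) do.call(rbind, ed) else empty_edits()
    edits <- edits[order(edits$pos), , drop = FALSE]
    out[j] <- apply_edits(tmpl, edits)
    if (nrow(edits)) all_edits[[j]] <- cbind(read = j, edits)
  }
  edits <- do.call(rbind, Filter(Negate(is.null), all_edits))
  if (is.null(edits)) edits <- cbind(read = integer(0), empty_edits())
  rownames(edits) <- NULL
  list(reads = out, edits = edits)
}

# ---- dataset simulation ----------------------------------------------------

#' Simulate a read dataset and write FASTQ plus a ground-truth table
#'
#' Generates the full dataset for `spec` from `ref`: placements via
#' [sample_insert()], platform error model applied per read, output as
#' Sanger FASTQ (Phred+33; constant Q30 placeholder qualities) — two
#' synchronized files with `/1` and `/2` mate naming for paired datasets,
#' one file for fragments — plus a tab-separated truth table
#' (`read_id`, `ref_id`, `start`, `strand`, `template_len`, `edits`)
#' written alongside. Output is byte-identical for identical
#' (reference, spec, seed).
#'
#' Mates are in FR ("innie") orientation: mate 1 from the 5' end of the
#' insert, mate 2 reverse-complemented from the 3' end. The truth `start`
#' is the 0-based forward-strand start of the mate's template; for `-`
#' strand mates the template is reverse-complemented before edits apply.
#'
#' @param ref named character vector of reference sequences.
#' @param spec a [read_dataset_spec()].
#' @param out_prefix output path prefix.
#' @param dataset_id id embedded in read names (defaults to the prefix
#'   basename).
#' @return invisibly, a list with `fastq` (paths), `truth` (path),
#'   `n_reads`, and the in-memory truth data.frame.
#' @export
simulate_reads <- function(ref, spec, out_prefix,
                           dataset_id = basename(out_prefix)) {
  stopifnot(inherits(spec, "read_dataset_spec"))
  plan <- plan_dataset(spec, sum(nchar(ref)))
  rl <- spec$read_length
  with_seed(spec$seed, {
    if (spec$paired) {
      pl <- sample_insert(spec, ref, plan$n_pairs)
      s <- pl$start; e <- pl$start + pl$insert_len
      five <- substring(ref[pl$ref_id], s + 1L, s + rl)
      three <- revcomp(substring(ref[pl$ref_id], e - rl + 1L, e))
      plus <- pl$strand == "+"
      m1 <- ifelse(plus, five, three)
      m2 <- ifelse(plus, three, five)
      m1_start <- ifelse(plus, s, e - rl)
      m2_start <- ifelse(plus, e - rl, s)
      m1_strand <- ifelse(plus, "+", "-")
      m2_strand <- ifelse(plus, "-", "+")
      reads <- as.vector(rbind(m1, m2))   # interleave pairs
      truth <- data.frame(
        read_id = paste0(dataset_id, "_", rep(seq_len(plan$n_pairs),
                                              each = 2), "/", c(1L, 2L)),
        ref_id = rep(pl$ref_id, each = 2),
        start = as.integer(as.vector(rbind(m1_start, m2_start))),
        strand = as.vector(rbind(m1_strand, m2_strand)),
        template_len = rl, stringsAsFactors = FALSE)
    } else {
      pl <- sample_insert(spec, ref, plan$n_reads)
      fwd <- substring(ref[pl$ref_id], pl$start + 1L, pl$start + rl)
      reads <- ifelse(pl$strand == "+", fwd, revcomp(fwd))
      truth <- data.frame(
        read_id = paste0(dataset_id, "_", seq_len(plan$n_reads)),
        ref_id = pl$ref_id, start = pl$start, strand = pl$strand,
        template_len = rl, stringsAsFactors = FALSE)
    }
    mut <- if (spec$platform == "ILLUMINA")
      apply_illumina_errors(reads, spec$error_params)
    else apply_454_errors(reads, spec$error_params)
    reads <- mut$reads
    es <- rep("", length(reads))
    if (nrow(mut$edits)) {
      by_read <- split(mut$edits[, -1, drop = FALSE], mut$edits$read)
      es[as.integer(names(by_read))] <-
        vapply(by_read, format_edits, character(1))
    }
    truth$edits <- es
  })
  # write outputs
  fastq_rec <- function(id, sq) as.vector(rbind(paste0("@", id), sq, "+",
                                                strrep("?", nchar(sq))))
  if (spec$paired) {
    i1 <- seq(1L, length(reads), by = 2L)
    f1 <- paste0(out_prefix, "_1.fastq"); f2 <- paste0(out_prefix, "_2.fastq")
    writeLines(fastq_rec(truth$read_id[i1], reads[i1]), f1)
    writeLines(fastq_rec(truth$read_id[i1 + 1L], reads[i1 + 1L]), f2)
    fastq <- c(f1, f2)
  } else {
    fastq <- paste0(out_prefix, ".fastq")
    writeLines(fastq_rec(truth$read_id, reads), fastq)
  }
  truth_path <- paste0(out_prefix, "_truth.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(fastq = fastq, truth = truth_path,
                 n_reads = length(reads), truth_table = truth,
                 reads = reads))
}

#' Read a simulator truth table
#' @param path path written by [simulate_reads()].
#' @return the truth data.frame.
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(edits = "character"))
}
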