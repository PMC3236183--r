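#' Read a FASTA file into a named vector of nucleotide sequences
#'
#' Sequences are uppercased and normalized to the alphabet {A,C,G,T,N}:
#' IUPAC ambiguity codes and any other residue are collapsed to `N`, with one
#' warning per file reporting how many residues were remapped. Sequence ids
#' are the first whitespace-delimited token of each header line, in file
#' order. Duplicate ids are an error.
#'
#' @param path path to a FASTA file (wrapped or unwrapped, multi-record).
#' @return named character vector of uppercase sequences; names are ids.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">chr1", "ACGTACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("no sequences in '", path, "'", call. = FALSE)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  if (any(ids == "")) stop("empty sequence id in '", path, "'", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  n_bad <- sum(vapply(seqs, function(s)
    nchar(s) - sum(charcount(s, c("A", "C", "G", "T", "N"))), numeric(1)))
  if (n_bad > 0) {
    warning(n_bad, " non-ACGTN residue(s) mapped to N in '", path, "'",
            call. = FALSE)
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  if (any(nchar(seqs) == 0L)) stop("zero-length sequence in '", path, "'",
                                   call. = FALSE)
  setNames(seqs, ids)
}

# Count occurrences of single characters in one string.
charcount <- function(s, chars) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  vapply(chars, function(ch) sum(v == ch), numeric(1))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Build an assembly set: scaffolds plus contigs split at long N runs
#'
#' A contig break is placed at every maximal run of `N` of length at least
#' `min_n_run`; shorter N runs are retained inside contigs. Contig start
#' offsets are 0-based within their scaffold. All-N scaffolds yield no
#' contigs. Concatenating each scaffold's contigs with the split N runs
#' reconstructs the scaffold exactly.
#'
#' @param scaffolds named character vector of scaffold sequences
#'   (as returned by [read_fasta()]).
#' @param min_n_run minimum N-run length that breaks a contig (default 10).
#' @return an object of class `assembly_set`: a list with elements
#'   `scaffolds` (the input) and `contigs` (data.frame with columns
#'   `scaffold_id`, `offset`, `sequence`, `length`), and the `min_n_run`
#'   used.
#' @examples
#' split_scaffolds(c(s1 = "ACGTNNNNNNNNNNACGT"), min_n_run = 10)
#' @export
split_scaffolds <- function(scaffolds, min_n_run = 10L) {
  stopifnot(is.character(scaffolds), length(scaffolds) >= 1L,
            min_n_run >= 1L)
  if (is.null(names(scaffolds)) || any(names(scaffolds) == ""))
    stop("scaffolds must be named", call. = FALSE)
  rows <- lapply(names(scaffolds), function(id) {
    s <- scaffolds[[id]]
    m <- gregexpr("N+", s)[[1]]
    cut_start <- integer(0); cut_len <- integer(0)
    if (m[1] != -1L) {
      len <- attr(m, "match.length")
      keep <- len >= min_n_run
      cut_start <- as.integer(m[keep]) - 1L   # 0-based
      cut_len <- len[keep]
    }
    # contig intervals = complement of cuts within [0, nchar)
    bounds <- c(0L, as.vector(rbind(cut_start, cut_start + cut_len)),
                nchar(s))
    st <- bounds[seq(1, length(bounds), by = 2)]
    en <- bounds[seq(2, length(bounds), by = 2)]
    ok <- en > st
    st <- st[ok]; en <- en[ok]
    if (length(st) == 0L) return(NULL)
    data.frame(scaffold_id = id, offset = st,
               sequence = substring(s, st + 1L, en),
               stringsAsFactors = FALSE)
  })
  contigs <- do.call(rbind, rows)
  if (is.null(contigs))
    contigs <- data.frame(scaffold_id = character(0), offset = integer(0),
                          sequence = character(0), stringsAsFactors = FALSE)
  contigs$length <- nchar(contigs$sequence)
  structure(list(scaffolds = scaffolds, contigs = contigs,
                 min_n_run = as.integer(min_n_run)),
            class = "assembly_set")
}

#' @export
print.assembly_set <- function(x, ...) {
  cat("Assembly set:", length(x$scaffolds), "scaffold(s),",
      nrow(x$contigs), "contig(s) (N-run split threshold ",
      x$min_n_run, ")\n", sep = " ")
  invisible(x)
}

#' Default keyword table for protein-family region classes
#'
#' Keywords matched (case-insensitively, as substrings) against a GFF
#' product/Note attribute to assign protein-family class labels. The default
#' list covers the large plant multi-gene families commonly profiled in
#' assembly-evaluation studies: protein kinases, Zn-fingers, bHLH, MADS,
#' ABC transporters, F-box, cytochromes P450, AP2, MYB, UDP-glucosyl
#' transferases, TPR, HMG, phosphatases, RNA-binding proteins, glycoside
#' hydrolases and leucine-rich repeat proteins.
#'
#' @return named character vector: names are class labels, values are the
#'   substrings matched against the attribute.
#' @export
protein_family_keywords <- function() {
  c("protein kinase" = "protein kinase",
    "Zn-finger" = "zn-finger",
    "bHLH" = "bhlh",
    "MADS" = "mads",
    "ABC transporter" = "abc transporter",
    "F-box" = "f-box",
    "Cytochrome P450" = "cytochrome p450",
    "AP2" = "ap2",
    "MYB" = "myb",
    "UDP-gluc" = "udp-gluc",
    "TPR" = "tpr",
    "HMG" = "hmg",
    "phosphatase" = "phosphatase",
    "RNA binding" = "rna binding",
    "Glycoside hydrolase" = "glycoside hydrolase",
    "Leucine-rich repeat" = "leucine-rich repeat")
}

#' Read region annotations from a GFF3 file
#'
#' Returns one region per retained GFF row (overlapping rows are kept, not
#' merged). Coordinates are 1-based inclusive as in the GFF standard. Rows
#' whose feature type (column 3) is not in `feature_filter` are dropped.
#' Rows with `start > end` are skipped with a warning. Strand is read but
#' downstream metrics are strand-agnostic.
#'
#' Class labels are assigned by `klass_from`:
#' * `"type"` — the feature type itself (e.g. `gene`, `repeat_region`);
#' * `"attribute"` — a keyword table is matched (case-insensitive substring)
#'   against the attribute named by `attribute`; unmatched rows get class
#'   `"other"`.
#'
#' @param path path to a GFF3 file.
#' @param feature_filter character vector of feature types to keep
#'   (default keeps every row).
#' @param klass_from `"type"` or `"attribute"`.
#' @param attribute attribute key holding the class-bearing text
#'   (default `"product"`, falling back to `Note`).
#' @param keywords named keyword table as from [protein_family_keywords()].
#' @return data.frame with columns `seqid`, `start`, `end`, `strand`,
#'   `type`, `klass` (1-based inclusive coordinates).
#' @export
read_gff_regions <- function(path, feature_filter = NULL,
                             klass_from = c("type", "attribute"),
                             attribute = "product",
                             keywords = protein_family_keywords()) {
  klass_from <- match.arg(klass_from)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  empty <- data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      type = character(0), klass = character(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 9L
  if (any(bad)) stop("malformed GFF3 row(s) at line(s): ",
                     paste(head(which(bad), 5), collapse = ", "),
                     call. = FALSE)
  m <- do.call(rbind, parts)
  df <- data.frame(seqid = m[, 1], type = m[, 3],
                   start = suppressWarnings(as.integer(m[, 4])),
                   end = suppressWarnings(as.integer(m[, 5])),
                   strand = m[, 7], attrs = m[, 9],
                   stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end))
    stop("non-numeric GFF coordinates", call. = FALSE)
  inv <- df$start > df$end
  if (any(inv)) {
    warning(sum(inv), " GFF row(s) with start > end skipped", call. = FALSE)
    df <- df[!inv, , drop = FALSE]
  }
  if (!is.null(feature_filter)) df <- df[df$type %in% feature_filter, ,
                                         drop = FALSE]
  if (nrow(df) == 0L) return(empty)
  if (klass_from == "type") {
    df$klass <- df$type
  } else {
    txt <- gff_attr(df$attrs, attribute)
    fallback <- gff_attr(df$attrs, "Note")
    txt <- ifelse(is.na(txt), fallback, txt)
    df$klass <- klass_from_keywords(txt, keywords)
  }
  rownames(df) <- NULL
  df[, c("seqid", "start", "end", "strand", "type", "klass")]
}

# Extract one key's value from GFF3 column-9 attribute strings.
gff_attr <- function(attrs, key) {
  pat <- paste0("(^|;)\\s*", key, "=([^;]*)")
  m <- regmatches(attrs, regexpr(pat, attrs))
  out <- rep(NA_character_, length(attrs))
  hit <- grepl(pat, attrs)
  out[hit] <- sub(pat, "\\2", regmatches(attrs, regexpr(pat, attrs)))
  out
}

# Map free-text descriptions onto class labels by substring keyword match.
klass_from_keywords <- function(txt, keywords) {
  out <- rep("other", length(txt))
  lt <- tolower(txt)
  for (k in names(keywords)) {
    hit <- !is.na(lt) & grepl(keywords[[k]], lt, fixed = TRUE) &
      out == "other"
    out[hit] <- k
  }
  out
}

#' Write regions to a GFF3 file
#'
#' Counterpart of [read_gff_regions()], used mainly by the fixtures module.
#'
#' @param regions data.frame with columns `seqid`, `start`, `end`,
#'   optionally `strand`, `type`, `klass`.
#' @param path output path.
#' @param source source tag for GFF column 2.
#' @return `path`, invisibly.
#' @export
write_gff_regions <- function(regions, path, source = "asmgrade") {
  strand <- regions$strand %||% rep("+", nrow(regions))
  type <- regions$type %||% regions$klass
  attrs <- paste0("ID=r", seq_len(nrow(regions)),
                  ";product=", regions$klass)
  lines <- paste(regions$seqid, source, type, regions$start, regions$end,
                 ".", strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
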