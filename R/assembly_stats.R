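#' Nxx length statistic
#'
#' The smallest sequence length such that all sequences at or above it hold
#' at least `fraction` of the total bases: lengths are sorted in decreasing
#' order and the first length at which the cumulative sum reaches
#' `fraction * total` is returned (the ">=" convention; conventions differ
#' between tools, so the rule is fixed here explicitly).
#'
#' @param lengths vector of positive sequence lengths.
#' @param fraction target fraction of total bases in (0, 1); 0.5 gives N50.
#' @return the Nxx length (integer-valued numeric).
#' @examples
#' nxx(c(5, 4, 3, 2, 1), 0.5)   # 4
#' nxx(c(5, 4, 3, 2, 1), 0.9)   # 2
#' @export
nxx <- function(lengths, fraction = 0.5) {
  stopifnot(length(lengths) >= 1L, all(lengths > 0),
            fraction > 0, fraction < 1)
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= fraction * sum(s))[1]]
}

#' Summarize contig and scaffold statistics of an assembly
#'
#' Computes the standard per-assembly statistics block: counts, total and
#' average lengths, N50 and largest length for both contigs and scaffolds,
#' and contig counts above 1000 bp and 5000 bp (strict `>` thresholds).
#' Scaffold lengths include N bases; contig lengths exclude the long N runs
#' removed at splitting but include any retained short N runs.
#'
#' @param assembly an `assembly_set` from [split_scaffolds()].
#' @return object of class `assembly_stats`: a named list of the 12
#'   statistics (averages to 1 decimal place in the print method).
#' @export
summarize_assembly <- function(assembly) {
  stopifnot(inherits(assembly, "assembly_set"))
  sc <- nchar(assembly$scaffolds)
  if (length(sc) == 0L) stop("empty assembly", call. = FALSE)
  ct <- assembly$contigs$length
  if (length(ct) == 0L) stop("assembly has no contigs (all-N scaffolds?)",
                             call. = FALSE)
  out <- list(
    n_contigs = length(ct),
    total_contig_length = sum(ct),
    average_contig_length = sum(ct) / length(ct),
    contig_n50 = nxx(ct, 0.5),
    largest_contig_length = max(ct),
    contigs_gt_1000 = sum(ct > 1000),
    contigs_gt_5000 = sum(ct > 5000),
    n_scaffolds = length(sc),
    total_scaffold_length = sum(sc),
    average_scaffold_length = sum(sc) / length(sc),
    scaffold_n50 = nxx(sc, 0.5),
    largest_scaffold_length = max(sc))
  structure(out, class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("Assembly statistics\n")
  fmt <- function(v) if (v %% 1 == 0) format(v, big.mark = ",")
    else formatC(v, format = "f", digits = 1, big.mark = ",")
  w <- max(nchar(names(x)))
  for (nm in names(x))
    cat(sprintf("  %-*s %s\n", w, nm, fmt(x[[nm]])))
  invisible(x)
}

#' @export
as.data.frame.assembly_stats <- function(x, ...) {
  as.data.frame(unclass(x))
}
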