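#' @importFrom stats rnorm runif setNames aggregate sd
#' @importFrom utils read.delim write.table head tail
NULL

# Reverse-complement a character vector of nucleotide strings.
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random nucleotide string at a given GC fraction.
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Run a block of code under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# IRanges helper: build from 0-based half-open (start0, end0) pairs.
ir0 <- function(start0, end0) {
  IRanges::IRanges(start = start0 + 1L, end = end0)
}

# Total width of the 0-based half-open interval union.
union_width <- function(start0, end0) {
  if (length(start0) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(ir0(start0, end0))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
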