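test_that("parse_coords converts 1-based inclusive rows and reversed queries", {
  f <- tempfile()
  writeLines(c(
    "NUCMER", "",
    "    1      100  |      1      100  |      100      100  |    100.00  | chr1\tctg1",
    "  501      700  |      200      101  |      200      100  |    98.00  | chr1\tctg2"),
    f)
  b <- parse_coords(f)
  expect_equal(b$ref_start, c(0, 500))
  expect_equal(b$ref_end, c(100, 700))
  expect_equal(b$qry_start, c(0, 100))
  expect_equal(b$qry_end, c(100, 200))
  expect_equal(b$strand, c("+", "-"))
  expect_equal(b$identity, c(1, 0.98))
  # header-only file yields an empty list, not an error
  writeLines(c("NUCMER", ""), f)
  expect_equal(nrow(parse_coords(f)), 0)
  # malformed rows are hard errors with the line number
  writeLines("  5  x | 1 2 | 3 4 | 99.0 | a\tb", f)
  expect_error(parse_coords(f), "line 1")
})

test_that("coords write -> parse is a fixed point", {
  ref <- plain_genome(10000, seed = 2)
  asm <- c(q1 = substr(ref[[1]], 1001, 4000), q2 = substr(ref[[1]], 4001, 9000))
  b <- toy_align(ref, asm)
  f <- tempfile()
  b1 <- parse_coords(write_coords(b, f))
  b2 <- parse_coords(write_coords(b1, tempfile()))
  expect_equal(b1, b2)
  # and coordinates survive the first conversion exactly
  expect_equal(b1$ref_start, b$ref_start)
  expect_equal(b1$qry_end, b$qry_end)
  expect_equal(b1$strand, b$strand)
})

test_that("parse_paf handles plain columns and cg:Z CIGAR refinement", {
  f <- tempfile()
  writeLines(c(
    paste("q1", 100, 0, 100, "+", "chr1", 1000, 0, 100, 100, 100, 60,
          sep = "\t"),
    paste("q2", 100, 0, 100, "+", "chr1", 1000, 200, 300, 95, 100, 60,
          sep = "\t"),
    paste("q3", 100, 0, 100, "-", "chr1", 1000, 400, 500, 99, 100, 60,
          "cg:Z:50=1X49=", sep = "\t")), f)
  b <- parse_paf(f)
  expect_equal(b$identity, c(1, 0.95, 0.99))
  expect_equal(b$n_mismatch[2], 5)          # no CIGAR: all-mismatch split
  expect_equal(b$n_mismatch[3], 1)          # CIGAR walk
  expect_equal(b$n_indel_events[3], 0)
  writeLines("q1\t100\t0\t100", f)
  expect_error(parse_paf(f), "12 columns")
})

test_that("paf write -> parse is a fixed point", {
  ref <- plain_genome(8000, seed = 5)
  asm <- c(q = substr(ref[[1]], 501, 7500))
  b <- toy_align(ref, asm)
  f <- tempfile()
  b1 <- parse_paf(write_paf(b, f, nchar(asm), nchar(ref)))
  b2 <- parse_paf(write_paf(b1, tempfile(), nchar(asm), nchar(ref)))
  expect_equal(b1, b2)
})

test_that("toy_align recovers exact substrings, reverse complements, and planted edits", {
  ref <- plain_genome(20000, seed = 9)
  # exact substring
  q <- c(a = substr(ref[[1]], 5001, 6000))
  b <- toy_align(ref, q)
  expect_equal(nrow(b), 1)
  expect_equal(b$ref_start, 5000)
  expect_equal(b$ref_end, 6000)
  expect_equal(b$identity, 1)
  expect_equal(b$strand, "+")
  # reverse complement
  qrc <- c(a = as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(q))))
  brc <- toy_align(ref, qrc)
  expect_equal(nrow(brc), 1)
  expect_equal(brc$strand, "-")
  expect_equal(brc$ref_start, 5000)
  # planted midpoint substitution: one block, one mismatch
  qs <- q
  mid <- 500
  cur <- substr(qs[[1]], mid, mid)
  substr(qs[[1]], mid, mid) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  bs <- toy_align(ref, qs)
  expect_equal(nrow(bs), 1)
  expect_equal(bs$n_mismatch, 1)
  expect_equal(bs$identity, 999 / 1000)
  expect_equal(bs$n_indel_events, 0)
})

test_that("toy_align covers an uncorrupted partition end-to-end at identity 1", {
  for (seed in c(1, 2)) {
    ref <- plain_genome(30000, seed = seed)
    cuts <- c(0, sort(sample(5000:25000, 2)), 30000)
    asm <- setNames(substring(ref[[1]], head(cuts, -1) + 1, cuts[-1]),
                    paste0("s", 1:3))
    b <- toy_align(ref, asm)
    expect_equal(nrow(b), 3)
    expect_true(all(b$identity == 1))
    expect_true(all(b$qry_start == 0))
    expect_equal(unname(b$qry_end[order(b$ref_start)]), diff(cuts))
    expect_equal(sum(b$aligned_ref_len), 30000)
  }
})

test_that("toy_align refuses references beyond its size guard", {
  ref <- c(chr = strrep("ACGT", 100))
  expect_error(toy_align(ref, c(q = "ACGTACGTACGTACGTACGTACGTACGT"),
                         max_ref_size = 100),
               "align externally")
})

test_that("toy_align agrees with minimap2 on a corrupted assembly", {
  g <- make_toy_genome(genome_plan(length = 50000, gene_density = 0,
                                   seed = 31))
  set.seed(31)
  plan <- random_corruption_plan(g$ref, c(25000L), n_sub = 4, n_indel = 2,
                                 n_drop = 1, n_nrun = 1)
  cor <- corrupt_assembly(g$ref, plan, c(25000L))
  b_toy <- toy_align(g$ref, cor$assembly)
  rf <- tmp_fasta(g$ref)
  qf <- tmp_fasta(cor$assembly$scaffolds)
  paf <- tempfile(fileext = ".paf")
  system2("minimap2", c("-c", "--eqx", "-x", "asm5", rf, qf),
          stdout = paf, stderr = FALSE)
  b_mm <- parse_paf(paf)
  ev_toy <- evaluate_assembly(g$ref, cor$assembly, b_toy)
  ev_mm <- evaluate_assembly(g$ref, cor$assembly, b_mm)
  r_toy <- ev_toy$records$representation[1]
  r_mm <- ev_mm$records$representation[1]
  expect_lt(abs(r_toy - r_mm), 0.01)
  expect_equal(sum(b_toy$n_mismatch), sum(b_mm$n_mismatch))
})
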