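mkblock <- function(ref_start, ref_end, qry_start, qry_end, qry_id = "q",
                    ref_id = "chr1", strand = "+", n_mismatch = 0,
                    n_indel_events = 0, n_indel_bases = 0,
                    identity = NULL) {
  arl <- ref_end - ref_start; aql <- qry_end - qry_start
  if (is.null(identity))
    identity <- (max(arl, aql) - n_mismatch - n_indel_bases) /
      max(arl, aql)
  data.frame(ref_id = ref_id, ref_start = ref_start, ref_end = ref_end,
             qry_id = qry_id, qry_start = qry_start, qry_end = qry_end,
             strand = strand, aligned_ref_len = arl,
             aligned_qry_len = aql, n_mismatch = n_mismatch,
             n_indel_events = n_indel_events,
             n_indel_bases = n_indel_bases, identity = identity,
             stringsAsFactors = FALSE)
}

test_that("classify_query verdicts cover the status taxonomy", {
  cfg <- fidelity_config()
  # single full-length block
  v <- classify_query(mkblock(0, 1000, 0, 1000), 1000, cfg)
  expect_equal(v$status, "ALIGNED")
  expect_equal(nrow(v$breakpoints), 0)
  # no blocks
  v <- classify_query(empty <- mkblock(0, 1, 0, 1)[0, ], 500, cfg)
  expect_equal(v$status, "UNALIGNED")
  expect_equal(v$unaligned_bases, 500)
  # relocation: halves 10 kb apart on the reference
  b <- rbind(mkblock(0, 500, 0, 500), mkblock(10500, 11000, 500, 1000))
  v <- classify_query(b, 1000, cfg)
  expect_equal(v$status, "MISASSEMBLED")
  expect_equal(v$breakpoints$kind, "relocation")
  # inversion: strand flip
  b <- rbind(mkblock(0, 500, 0, 500),
             mkblock(500, 1000, 500, 1000, strand = "-"))
  expect_equal(classify_query(b, 1000, cfg)$breakpoints$kind, "inversion")
  # translocation: reference sequence change
  b <- rbind(mkblock(0, 500, 0, 500),
             mkblock(0, 500, 500, 1000, ref_id = "chr2"))
  expect_equal(classify_query(b, 1000, cfg)$breakpoints$kind,
               "translocation")
  # partial: only 60% aligned
  v <- classify_query(mkblock(0, 600, 0, 600), 1000, cfg)
  expect_equal(v$status, "PARTIAL")
  expect_equal(v$unaligned_bases, 400)
})

test_that("near-equal repeat placements make a query ambiguous", {
  cfg <- fidelity_config()
  b <- rbind(mkblock(1000, 2000, 0, 1000, identity = 1.0),
             mkblock(8000, 9000, 0, 1000, identity = 0.995))
  v <- classify_query(b, 1000, cfg)
  expect_equal(v$status, "AMBIGUOUS")
  expect_equal(v$contested_bases, 1000)
  # a clear score difference is not ambiguous
  b$identity[2] <- 0.90
  v2 <- classify_query(b, 1000, cfg)
  expect_false(v2$status == "AMBIGUOUS")
})

test_that("relocation threshold separates jumps from small drifts", {
  cfg <- fidelity_config(relocation_threshold = 1000)
  mk2 <- function(jump) rbind(
    mkblock(0, 500, 0, 500),
    mkblock(500 + jump, 1000 + jump, 500, 1000))
  expect_equal(classify_query(mk2(2500), 1000, cfg)$status, "MISASSEMBLED")
  expect_equal(classify_query(mk2(400), 1000, cfg)$status, "ALIGNED")
})

test_that("representation matches interval-union arithmetic and the per-base oracle", {
  lens <- c(chr1 = 100L)
  b <- rbind(mkblock(0, 50, 0, 50), mkblock(40, 80, 0, 40, qry_id = "q2"))
  r <- compute_representation(b, lens)
  expect_equal(r$representation, 0.80)
  expect_equal(r$covered_bases, 80)
  expect_equal(compute_representation(b[0, ], lens)$representation, 0)
  # random blocks against the logical-vector oracle
  set.seed(33)
  for (i in 1:30) {
    n <- sample(1:8, 1)
    s <- sample(0:900, n, replace = TRUE)
    e <- s + sample(10:100, n, replace = TRUE)
    bb <- do.call(rbind, lapply(seq_len(n), function(j)
      mkblock(s[j], e[j], 0, e[j] - s[j], qry_id = paste0("q", j))))
    expect_equal(compute_representation(bb, c(chr1 = 1000L))$representation,
                 representation_oracle(bb, 1000))
  }
})

test_that("removing a block never increases representation", {
  set.seed(14)
  lens <- c(chr1 = 2000L)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    s <- sample(0:1800, n, replace = TRUE)
    e <- pmin(2000, s + sample(50:400, n, replace = TRUE))
    bb <- do.call(rbind, lapply(seq_len(n), function(j)
      mkblock(s[j], e[j], 0, e[j] - s[j], qry_id = paste0("q", j))))
    full <- compute_representation(bb, lens)$representation
    drop1 <- compute_representation(bb[-sample(n, 1), , drop = FALSE],
                                    lens)$representation
    expect_lte(drop1, full)
  }
})

test_that("error rates scale per 100 kb and apportion by region overlap", {
  lens <- c(chr1 = 100000L)
  b <- mkblock(0, 100000, 0, 100000, n_mismatch = 5, n_indel_events = 2,
               n_indel_bases = 2)
  er <- compute_error_rates(b, lens)
  expect_equal(er$mismatch_rate, 5)
  expect_equal(er$indel_rate, 2)
  expect_equal(er$error_rate, 7)
  # half-overlapping region gets half the events
  region <- data.frame(seqid = "chr1", start0 = 0L, end0 = 50000L)
  er2 <- compute_error_rates(mkblock(0, 100000, 0, 100000,
                                     n_mismatch = 10), lens, region)
  expect_equal(er2$n_mismatch, 5)
  # zero-aligned region is flagged, rates 0
  region0 <- data.frame(seqid = "chr1", start0 = 0L, end0 = 10L)
  er3 <- compute_error_rates(mkblock(100, 200, 0, 100), lens, region0)
  expect_true(er3$zero_aligned)
  expect_equal(er3$error_rate, 0)
})

test_that("gap accounting: plain, negative, and captured gaps", {
  lens <- c(chr1 = 100L)
  # one scaffold spans an uncovered hole -> captured gap
  b <- rbind(mkblock(0, 40, 0, 40), mkblock(60, 100, 50, 90))
  g <- compute_gaps(b, lens)
  expect_equal(g$n_gaps, 1)
  expect_equal(g$total_gap_bases, 20)
  expect_equal(g$n_captured_gaps, 1)
  expect_equal(g$total_captured_gap_bases, 20)
  expect_equal(g$internal_gaps, 1)          # query gap 40..50
  # consecutive blocks overlapping on the reference -> negative gap of 6
  b2 <- rbind(mkblock(0, 50, 0, 50), mkblock(44, 100, 50, 106))
  g2 <- compute_gaps(b2, lens)
  expect_equal(g2$n_negative_gaps, 1)
  expect_equal(g2$avg_negative_gap_size, 6)
  expect_equal(g2$n_gaps, 0)
  # full tiling: no gaps at all
  b3 <- rbind(mkblock(0, 50, 0, 50), mkblock(50, 100, 50, 100))
  g3 <- compute_gaps(b3, lens)
  expect_equal(g3$n_gaps, 0)
  expect_equal(g3$total_gap_bases, 0)
  expect_equal(g3$n_captured_gaps, 0)
  # a hole between two different scaffolds is a gap but not captured
  b4 <- rbind(mkblock(0, 40, 0, 40),
              mkblock(60, 100, 0, 40, qry_id = "q2"))
  g4 <- compute_gaps(b4, lens)
  expect_equal(g4$n_gaps, 1)
  expect_equal(g4$n_captured_gaps, 0)
})

test_that("evaluate_assembly on an identity partition is perfect everywhere", {
  g <- make_toy_genome(genome_plan(length = 40000, seed = 17))
  cuts <- c(12000L, 26000L)
  cor <- corrupt_assembly(g$ref, corruption_plan(), cuts)
  ev <- evaluate_assembly(g$ref, cor$assembly,
                          toy_align(g$ref, cor$assembly), g$regions)
  all_row <- ev$records[ev$records$genome_region == "all", ]
  expect_equal(all_row$representation, 1.0)
  expect_equal(all_row$error_rate, 0)
  expect_equal(all_row$misassembly_rate, 0)
  expect_equal(all_row$n_gaps, 0)
  expect_equal(all_row$unaligned_contigs, 0)
  # region rows are present, alphabetical after "all", also perfect
  expect_equal(ev$records$genome_region[1], "all")
  expect_true(all(ev$records$representation == 1))
  # region aligned bases never exceed the whole-genome aligned bases
  expect_true(all(ev$records$aligned_ref_bases <=
                    all_row$aligned_ref_bases))
})

test_that("a gene inside an uncovered interval lowers gene-class representation", {
  g <- make_toy_genome(genome_plan(length = 30000, gene_density = 0,
                                   seed = 19))
  # drop exactly one interval and put a "gene" inside it
  plan <- corruption_plan(dropped = data.frame(start = 10000L, len = 300L))
  cor <- corrupt_assembly(g$ref, plan, c(20000L))
  regions <- data.frame(seqid = "chr1",
                        start = c(10051L, 25001L), end = c(10250L, 25400L),
                        strand = "+", type = "gene", klass = "gene",
                        stringsAsFactors = FALSE)
  ev <- evaluate_assembly(g$ref, cor$assembly,
                          toy_align(g$ref, cor$assembly), regions)
  r <- ev$records
  expect_lt(r$representation[r$genome_region == "gene"],
            r$representation[r$genome_region == "all"])
  # the dropped interval is a captured gap of 300 bases
  expect_equal(r$n_captured_gaps[r$genome_region == "all"], 1)
  expect_equal(r$total_captured_gap_bases[r$genome_region == "all"], 300)
})

test_that("conservation law: covered + gap bases = region length, every record", {
  set.seed(23)
  for (s in 1:5) {
    g <- make_toy_genome(genome_plan(length = 20000, seed = s + 100))
    plan <- random_corruption_plan(g$ref, c(9000L), n_sub = 2, n_indel = 1,
                                   n_drop = 1, n_nrun = 1)
    cor <- corrupt_assembly(g$ref, plan, c(9000L))
    ev <- evaluate_assembly(g$ref, cor$assembly,
                            toy_align(g$ref, cor$assembly), g$regions)
    expect_true(all(ev$records$covered_bases + ev$records$total_gap_bases ==
                      ev$records$region_bases))
  }
})

test_that("error_rate is exactly mismatch_rate + indel_rate in every record", {
  set.seed(29)
  g <- make_toy_genome(genome_plan(length = 20000, seed = 77))
  plan <- random_corruption_plan(g$ref, integer(0), n_sub = 4, n_indel = 3,
                                 n_drop = 1, n_nrun = 0)
  cor <- corrupt_assembly(g$ref, plan)
  ev <- evaluate_assembly(g$ref, cor$assembly,
                          toy_align(g$ref, cor$assembly), g$regions)
  expect_identical(ev$records$error_rate,
                   ev$records$mismatch_rate + ev$records$indel_rate)
})

test_that("ambiguous N bases and ambiguously-aligned bases are distinct metrics", {
  g <- make_toy_genome(genome_plan(length = 20000, gene_density = 0,
                                   seed = 41))
  plan <- corruption_plan(n_runs = data.frame(start = 5000L,
                                              ref_span = 200L,
                                              n_len = 150L))
  cor <- corrupt_assembly(g$ref, plan)
  ev <- evaluate_assembly(g$ref, cor$assembly,
                          toy_align(g$ref, cor$assembly))
  expect_equal(ev$records$ambiguous_bases[1], 150)           # assembly Ns
  expect_equal(ev$records$ambiguously_aligned_bases[1], 0)   # no repeats
})

test_that("empty alignments yield a valid all-zero record", {
  ref <- plain_genome(5000, seed = 51)
  ev <- evaluate_assembly(ref, c(s1 = strrep("ACGT", 500)),
                          toy_align(ref, c(s1 = strrep("ACGT", 500)))[0, ])
  r <- ev$records
  expect_equal(r$representation, 0)
  expect_equal(r$total_gap_bases, 5000)
  expect_equal(r$unaligned_contigs, 1)
})
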