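test_that("dataset specs enforce the platform panel and pairing constraints", {
  expect_error(read_dataset_spec("ILLUMINA", 75, paired = TRUE,
                                 insert_mean = 100),
               "insert_mean >= 2")
  expect_error(read_dataset_spec("LS454", 100, paired = TRUE,
                                 insert_mean = 500),
               "not in the standard panel")  # 500 bp insert is Illumina-only
  expect_silent(read_dataset_spec("ILLUMINA", 75, paired = TRUE,
                                  insert_mean = 500))
  expect_error(read_dataset_spec("ILLUMINA", 75, coverage = 0))
  # insert sd defaults to 10% of the mean
  expect_equal(read_dataset_spec("ILLUMINA", 75,
                                 insert_mean = 2000)$insert_sd, 200)
})

test_that("plan_dataset computes read counts from coverage semantics", {
  sp <- read_dataset_spec("ILLUMINA", 75, paired = TRUE, insert_mean = 2000,
                          coverage = 40)
  p <- plan_dataset(sp, 1e6)
  expect_equal(p$n_reads, 533334)    # ceil(40e6/75), rounded up to even
  expect_equal(p$n_pairs, 266667)

  sp2 <- read_dataset_spec("LS454", 500, paired = FALSE, coverage = 16)
  expect_equal(plan_dataset(sp2, 1e5)$n_reads, 3200)
})

test_that("sample_insert respects truncation, placement bounds and length weighting", {
  ref1 <- c(r = strrep("ACGT", 250))       # single 1000 bp reference
  sp <- read_dataset_spec("ILLUMINA", 100, paired = TRUE, insert_mean = 500,
                          insert_sd = 0, coverage = 1)
  set.seed(1)
  pl <- sample_insert(sp, ref1, 2000)
  expect_true(all(pl$insert_len == 500))   # sd 0 puts every draw at 500
  expect_true(all(pl$start >= 0 & pl$start <= 500))
  expect_gt(length(unique(pl$start)), 100) # start spreads over [0, 500]

  # impossible placement is a hard error
  sp2 <- read_dataset_spec("ILLUMINA", 100, paired = TRUE,
                           insert_mean = 40000, coverage = 1)
  expect_error(sample_insert(sp2, c(r = strrep("A", 10000)), 10),
               "impossible|minimum")

  # reference chosen proportional to length: 900/100 split within 3 sigma
  ref2 <- c(big = strrep("AC", 450), small = strrep("GT", 50))
  sp3 <- read_dataset_spec("ILLUMINA", 50, paired = FALSE, coverage = 1)
  set.seed(2)
  pl2 <- sample_insert(sp3, ref2, 10000)
  frac <- mean(pl2$ref_id == "big")
  se <- sqrt(0.9 * 0.1 / 10000)
  expect_lt(abs(frac - 0.9), 3 * se)
})

test_that("illumina substitution ramp matches its closed-form mean", {
  set.seed(5)
  reads <- rep(strrep("ACGT", 25), 1e5)    # L = 100
  out <- apply_illumina_errors(reads, error_model_params(0.001, 0.01))
  # E[subs/read] = sum p(i) = 100 * mean(ramp) = 0.55
  expected <- sum(0.001 + (0.01 - 0.001) * (0:99) / 99)
  got <- nrow(out$edits) / 1e5
  se <- sqrt(expected / 1e5)               # Poisson-binomial approx
  expect_lt(abs(got - expected), 3 * se)
  # zero-rate limit is the identity
  none <- apply_illumina_errors(reads[1:100], error_model_params(0, 0))
  expect_identical(none$reads, reads[1:100])
  expect_equal(nrow(none$edits), 0)
})

test_that("454 homopolymer indels follow the Bernoulli run rule", {
  set.seed(6)
  reads <- rep(strrep("A", 6), 1e4)        # one k=6 run per read
  p <- error_model_params(ls454_base_sub_rate = 0,
                          ls454_homopolymer_slope = 0.05)
  out <- apply_454_errors(reads, p)
  frac <- length(unique(out$edits$read)) / 1e4     # expect ~ 6*0.05 = 0.30
  se <- sqrt(0.3 * 0.7 / 1e4)
  expect_lt(abs(frac - 0.3), 3 * se)
  expect_true(all(out$edits$op %in% c("I", "D")))
  # zero-slope, zero-sub limit is the identity
  none <- apply_454_errors(reads[1:50], error_model_params(
    ls454_base_sub_rate = 0, ls454_homopolymer_slope = 0))
  expect_identical(none$reads, reads[1:50])
})

test_that("simulated datasets hit requested coverage and are byte-deterministic", {
  ref <- plain_genome(50000, seed = 11)
  sp <- read_dataset_spec("ILLUMINA", 75, paired = TRUE, insert_mean = 2000,
                          coverage = 10, seed = 5)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  s1 <- simulate_reads(ref, sp, d1, dataset_id = "x")
  s2 <- simulate_reads(ref, sp, d2, dataset_id = "x")
  expect_lt(abs(s1$n_reads * 75 / 50000 - 10), 2 * 75 / 50000 + 1e-9)  # ceil + pair rounding
  expect_identical(readLines(s1$fastq[1]), readLines(s2$fastq[1]))
  expect_identical(readLines(s1$fastq[2]), readLines(s2$fastq[2]))

  # truth-table edit lists reproduce every emitted read exactly
  tt <- read_truth(s1$truth)
  idx <- sample(nrow(tt), 200)
  rec <- vapply(idx, function(i) reconstruct_read(ref, tt[i, ]),
                character(1))
  expect_identical(rec, s1$reads[idx])

  # empirical insert size (outer distance) within 3 standard errors
  m1 <- tt[seq(1, nrow(tt), 2), ]; m2 <- tt[seq(2, nrow(tt), 2), ]
  ins <- pmax(m1$start, m2$start) + 75 - pmin(m1$start, m2$start)
  se <- 200 / sqrt(length(ins))
  expect_lt(abs(mean(ins) - 2000), 3 * se)
})

test_that("zero-error reads are exact substrings (or reverse complements) of the reference", {
  ref <- plain_genome(30000, seed = 3)
  sp <- read_dataset_spec("ILLUMINA", 75, paired = TRUE, insert_mean = 2000,
                          coverage = 4, seed = 8,
                          error_params = error_model_params(0, 0, 0, 0))
  s <- simulate_reads(ref, sp, file.path(tempdir(), "sim_z"))
  tt <- s$truth_table
  tmpl <- substring(ref[tt$ref_id], tt$start + 1, tt$start + 75)
  neg <- tt$strand == "-"
  tmpl[neg] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(tmpl[neg])))
  expect_identical(unname(tmpl), s$reads)
  expect_true(all(tt$edits == ""))
})

test_that("placement starts are uniform (chi-square over deciles not rejected)", {
  ref <- c(r = plain_genome(20000, seed = 4)[[1]])
  sp <- read_dataset_spec("ILLUMINA", 50, paired = FALSE, coverage = 1)
  set.seed(9)
  pl <- sample_insert(sp, ref, 1e5)
  dec <- cut(pl$start, breaks = seq(0, 20000 - 50 + 1, length.out = 11),
             include.lowest = TRUE)
  p <- suppressWarnings(chisq.test(table(dec))$p.value)
  expect_gt(p, 0.001)
})

test_that("454 paired simulation writes faithful truth for homopolymer indels", {
  ref <- plain_genome(30000, seed = 13)
  sp <- read_dataset_spec("LS454", 500, paired = TRUE, insert_mean = 2000,
                          coverage = 2, seed = 14)
  s <- simulate_reads(ref, sp, file.path(tempdir(), "sim454"))
  tt <- s$truth_table
  with_edits <- which(tt$edits != "")
  expect_gt(length(with_edits), 0)
  rec <- vapply(with_edits, function(i) reconstruct_read(ref, tt[i, ]),
                character(1))
  expect_identical(rec, s$reads[with_edits])
})
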