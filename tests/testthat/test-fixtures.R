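test_that("make_toy_genome plants repeats and genes as annotated, deterministically", {
  plan <- genome_plan(length = 100000,
                      repeat_blocks = list(list(len = 1000, n = 5,
                                                divergence = 0.01)),
                      seed = 5)
  g1 <- make_toy_genome(plan)
  g2 <- make_toy_genome(plan)
  expect_identical(g1$ref, g2$ref)
  reps <- g1$regions[g1$regions$klass == "repeat", ]
  expect_equal(nrow(reps), 5)
  expect_true(all(reps$end - reps$start + 1 == 1000))
  expect_equal(nchar(g1$ref[[1]]), 100000)
})

test_that("generated GC content is within 3 sigma of binomial", {
  g <- make_toy_genome(genome_plan(length = 1e5, gc = 0.5,
                                   gene_density = 0, seed = 6))
  gc <- sum(charcount <- table(strsplit(g$ref[[1]], "")[[1]])[c("C", "G")]) /
    1e5
  se <- sqrt(0.5 * 0.5 / 1e5)
  expect_lt(abs(gc - 0.5), 3 * se)
})

test_that("corrupt_assembly with an empty plan partitions the reference exactly", {
  ref <- plain_genome(10000, seed = 7)
  cor <- corrupt_assembly(ref, corruption_plan(), c(3000L, 7000L))
  sc <- cor$assembly$scaffolds
  expect_equal(length(sc), 3)
  expect_equal(paste0(sc, collapse = ""), ref[[1]])
  expect_equal(cor$truth$n_mismatch, 0)
  expect_equal(nrow(cor$truth$breakpoints), 0)
  expect_equal(nrow(cor$truth$uncovered), 0)
})

test_that("planted substitutions and indels are counted in the ground truth", {
  ref <- plain_genome(10000, seed = 8)
  plan <- corruption_plan(substitutions = c(1000L, 2000L, 3000L),
                          indels = data.frame(pos = c(5000L, 6000L),
                                              len = c(4L, -3L)))
  cor <- corrupt_assembly(ref, plan)
  expect_equal(cor$truth$n_mismatch, 3)
  expect_equal(cor$truth$n_indel_events, 2)
  expect_equal(cor$truth$n_indel_bases, 7)
  # assembly length shifted by the net indel length
  expect_equal(nchar(cor$assembly$scaffolds[[1]]), 10000 + 4 - 3)
})

test_that("a relocated interior segment produces at most 2-3 adjacency breakpoints", {
  ref <- plain_genome(60000, seed = 9)
  plan <- corruption_plan(relocations = data.frame(start = 5000L,
                                                   len = 5000L,
                                                   new_pos = 55000L))
  cor <- corrupt_assembly(ref, plan)
  bp <- cor$truth$breakpoints
  expect_true(all(bp$kind == "relocation"))
  expect_gte(nrow(bp), 1)
  expect_lte(nrow(bp), 3)
})

test_that("overlapping or cut-crossing edits are hard errors", {
  ref <- plain_genome(10000, seed = 10)
  expect_error(corrupt_assembly(ref, corruption_plan(
    substitutions = 1000L,
    dropped = data.frame(start = 990L, len = 50L))),
    "overlapping")
  expect_error(corrupt_assembly(ref, corruption_plan(
    dropped = data.frame(start = 4990L, len = 50L)), c(5000L)),
    "crosses")
  expect_error(corrupt_assembly(ref, corruption_plan(
    substitutions = 10005L)), "bounds")
})

test_that("end-to-end: simulate -> toy_align -> evaluate recovers a perfect partition", {
  for (s in c(61, 62)) {
    g <- make_toy_genome(genome_plan(length = 25000, seed = s))
    cuts <- sort(sample(seq(5000L, 20000L, by = 2500L), 2))
    cor <- corrupt_assembly(g$ref, corruption_plan(), cuts)
    ev <- evaluate_assembly(g$ref, cor$assembly,
                            toy_align(g$ref, cor$assembly), g$regions)
    expect_true(all(ev$records$representation == 1))
    expect_true(all(ev$records$error_rate == 0))
    expect_true(all(ev$records$misassembly_rate == 0))
  }
})

test_that("measured metrics equal construction ground truth on random isolated-edit fixtures", {
  # the deep 200-fixture version runs in the acceptance suite; this is a
  # faster smoke of the same property across all defect kinds
  set.seed(71)
  for (s in 1:10) {
    g <- make_toy_genome(genome_plan(length = 20000, gene_density = 0,
                                     seed = 1000 + s))
    cuts <- sort(sample(seq(3000L, 17000L, by = 2000L), 2))
    plan <- random_corruption_plan(g$ref, cuts, n_sub = 3, n_indel = 2,
                                   n_reloc = 1, n_inv = 1, n_drop = 1,
                                   n_nrun = 1)
    cor <- corrupt_assembly(g$ref, plan, cuts)
    ev <- evaluate_assembly(g$ref, cor$assembly,
                            toy_align(g$ref, cor$assembly))
    tr <- cor$truth
    expect_equal(sum(ev$kept_blocks$n_mismatch), tr$n_mismatch)
    expect_equal(sum(ev$kept_blocks$n_indel_events), tr$n_indel_events)
    expect_equal(sum(ev$kept_blocks$n_indel_bases), tr$n_indel_bases)
    expect_equal(table(factor(ev$breakpoints$kind,
                              c("relocation", "inversion",
                                "translocation"))),
                 table(factor(tr$breakpoints$kind,
                              c("relocation", "inversion",
                                "translocation"))))
    rec <- ev$records
    expect_equal(rec$n_gaps[1], nrow(tr$uncovered))
    expect_equal(rec$total_gap_bases[1],
                 sum(tr$uncovered$end0 - tr$uncovered$start0))
    expect_equal(rec$n_captured_gaps[1], nrow(tr$captured))
  }
})
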