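test_that("an exact junction read aligns with both segments touching the junction", {
  sys <- toy_system()
  refs <- build_reference(sys$models$KMT2A, sys$models$AFF1, sys$genome)
  up <- sys$seq5[8]
  down <- sys$seq3[4]
  rd <- junction_read(up, down, 50L, 50L)
  aln <- align_read(rd, refs)
  expect_equal(aln$ref_id, "KMT2A|8|AFF1|4|direct")
  expect_equal(aln$a_ref_end, aln$junction_pos)
  expect_equal(aln$b_ref_start, aln$junction_pos)
  expect_equal(aln$overlap_a, 50L)
  expect_equal(aln$overlap_b, 50L)
  expect_equal(aln$mismatches_a + aln$mismatches_b, 0L)
  expect_equal(aln$strand_of_read, "forward")
})

test_that("reads entirely within one exon block do not produce junction alignments", {
  sys <- toy_system()
  refs <- build_reference(sys$models$KMT2A, sys$models$AFF1, sys$genome)
  inside <- substr(sys$seq5[8], 10L, 109L)
  res <- align_read(inside, refs)
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "status"), "no_alignment")
  short <- align_read("ACGTACG", refs)
  expect_equal(nrow(short), 0L)
  expect_equal(attr(short, "status"), "too_short")
})

test_that("a junction truncated before the exon end (not annotated) is placed like the brute-force optimum", {
  sys <- toy_system()
  refs <- build_reference(sys$models$KMT2A, sys$models$AFF1, sys$genome)
  up <- sys$seq5[8]
  # suffix of the exon-8 block truncated 20 nt before its end, joined to the
  # start of the exon-4 block of the partner
  up_trunc <- substr(up, 1L, nchar(up) - 20L)
  rd <- junction_read(up_trunc, sys$seq3[4], 50L, 50L)
  aln <- align_read(rd, refs)
  expect_equal(aln$ref_id, "KMT2A|8|AFF1|4|direct")
  expect_equal(aln$a_ref_end, aln$junction_pos - 20L)
  expect_equal(aln$b_ref_start, aln$junction_pos)
  expect_equal(aln$mismatches_a + aln$mismatches_b, 0L)

  # on a desk-size instance the same construction matches the brute-force
  # optimum over all (reference, split point, offsets) placements
  set.seed(5)
  mini <- random_align_instance(block_len = 22L, n_refs = 2L, n_mut = 0L)
  blockA <- substr(mini$refs$seq[1], 1L, 16L)  # ends 6 nt before junction
  blockB <- substr(mini$refs$seq[1], 23L, 44L)
  rd2 <- paste0(substr(blockA, 7L, 16L), substr(blockB, 1L, 10L))
  p <- align_params(min_total_aligned = 10L, min_overlap = 1L,
                    min_matches = 1L)
  a2 <- align_read(rd2, mini$refs, p)
  expect_equal(a2$a_ref_end, mini$refs$junction_pos[1] - 6L)
  expect_equal(a2$b_ref_start, mini$refs$junction_pos[1])
  score2 <- 2L * (a2$matches_a + a2$matches_b) - nchar(rd2)
  expect_equal(score2, brute_force_best_score(rd2, mini$refs))
})

test_that("split-aligner score matches the brute-force oracle on random small instances", {
  set.seed(202)
  params <- align_params(min_total_aligned = 10L, min_overlap = 1L,
                         min_matches = 1L)
  for (k in 1:40) {
    inst <- random_align_instance(n_mut = sample(0:3, 1))
    aln <- align_read(inst$read, inst$refs, params)
    oracle <- brute_force_best_score(inst$read, inst$refs)
    expect_false(is.null(aln))
    score <- 2L * (aln$matches_a + aln$matches_b) - nchar(inst$read)
    expect_equal(score, oracle)
  }
})

test_that("seeded and exhaustive search agree on error-free junction reads", {
  sys <- toy_system(m5 = 4L, m3 = 3L)
  refs <- build_reference(sys$models$KMT2A, sys$models$AFF1, sys$genome)
  seeded <- align_params(exhaustive_below = 0L)      # always k-mer seeding
  exhaustive <- align_params(exhaustive_below = .Machine$integer.max)
  set.seed(33)
  for (k in 1:25) {
    i <- sample(4L, 1L)
    j <- sample(3L, 1L)
    left <- sample(20:80, 1L)
    rd <- junction_read(sys$seq5[i], sys$seq3[j], left, 100L - left)
    a1 <- align_read(rd, refs, seeded)
    a2 <- align_read(rd, refs, exhaustive)
    expect_equal(a1$ref_id, a2$ref_id)
    expect_equal(a1$matches_a + a1$matches_b, a2$matches_a + a2$matches_b)
  }
})

test_that("alignment is deterministic and symmetric under reverse complement", {
  sys <- toy_system()
  refs <- build_reference(sys$models$KMT2A, sys$models$AFF1, sys$genome)
  rd <- junction_read(sys$seq5[9], sys$seq3[4], 60L, 40L)
  a1 <- align_read(rd, refs)
  a2 <- align_read(rd, refs)
  expect_identical(a1, a2)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rd)))
  a3 <- align_read(rc, refs)
  expect_equal(a3$ref_id, a1$ref_id)
  expect_equal(a3$matches_a + a3$matches_b, a1$matches_a + a1$matches_b)
  expect_equal(a3$strand_of_read, "revcomp")
  expect_equal(a1$strand_of_read, "forward")
})

test_that("junction-quality filters apply the documented thresholds and reason codes", {
  mk <- function(overlap_a, overlap_b, mm_a = 0L, mm_b = 0L) {
    data.frame(
      read_id = "r", ref_id = "x", pair = "A::B", geneA = "A", exonA = 1L,
      geneB = "B", exonB = 1L, derivative = "direct", junction_pos = 100L,
      strand_of_read = "forward", split = overlap_a,
      a_ref_start = 100L - overlap_a, a_ref_end = 100L, b_ref_start = 100L,
      b_ref_end = 100L + overlap_b, overlap_a = overlap_a,
      overlap_b = overlap_b, matches_a = overlap_a - mm_a,
      matches_b = overlap_b - mm_b, mismatches_a = mm_a, mismatches_b = mm_b,
      ambiguous = FALSE
    )
  }
  # 100 nt aligned with 17 mismatches is exactly at the 17% boundary
  ok <- passes_filters(mk(50L, 50L, mm_a = 17L))
  expect_true(ok)
  expect_equal(attr(ok, "reason"), "pass")
  expect_false(passes_filters(mk(50L, 50L, mm_a = 18L)))
  expect_equal(attr(passes_filters(mk(50L, 50L, mm_a = 18L)), "reason"),
               "max_mismatch_frac")
  expect_equal(attr(passes_filters(mk(25L, 24L)), "reason"),
               "min_total_aligned")
  expect_equal(attr(passes_filters(mk(4L, 96L)), "reason"), "min_overlap")
  short_weak <- mk(6L, 94L, mm_a = 2L)  # 4 matches in the shorter segment
  expect_equal(attr(passes_filters(short_weak), "reason"), "min_matches")
  amb <- mk(50L, 50L)
  amb$ambiguous <- TRUE
  expect_equal(attr(passes_filters(amb), "reason"), "ambiguous")
})

test_that("raising stringency never admits new reads (monotonicity)", {
  sys <- toy_system()
  refs <- build_reference(sys$models$KMT2A, sys$models$AFF1, sys$genome)
  set.seed(77)
  reads <- character(0)
  for (k in 1:30) {
    left <- sample(2:98, 1L)
    reads[sprintf("r%d", k)] <- junction_read(
      sys$seq5[sample(11L, 1L)], sys$seq3[sample(6L, 1L)], left, 100L - left)
  }
  aln <- align_reads(reads, refs)
  passing <- function(ov, mm) {
    flt <- filter_alignments(aln, align_params(min_overlap = ov,
                                               min_matches = mm))
    flt$read_id[flt$pass]
  }
  prev <- passing(1L, 1L)
  for (ov in c(2L, 5L, 10L, 20L)) {
    cur <- passing(ov, 1L)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  prev <- passing(1L, 1L)
  for (mm in c(4L, 5L, 10L, 20L)) {
    cur <- passing(1L, mm)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("N bases count as mismatches everywhere", {
  sys <- toy_system()
  refs <- build_reference(sys$models$KMT2A, sys$models$AFF1, sys$genome)
  rd <- junction_read(sys$seq5[8], sys$seq3[4], 50L, 50L)
  rd_n <- paste0("NNN", substr(rd, 4L, 100L))
  aln <- align_reads(rd_n, refs)
  expect_equal(aln$mismatches_a + aln$mismatches_b, 3L)
})
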