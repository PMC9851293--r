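# helper: run one synthetic junction read through align + filter + classify
classify_junction <- function(sys, refs, ctx, up, down, left = 50L,
                              right = 50L) {
  rd <- junction_read(up, down, left, right)
  aln <- filter_alignments(align_read(rd, refs))
  classify_reads(aln, ctx)
}

test_that("the multi-breakpoint KMT2A::AFF1 context classifies fusion, alternative and backsplice reads", {
  sys <- toy_system()
  refs <- build_reference(sys$models$KMT2A, sys$models$AFF1, sys$genome)
  refs$pair <- "KMT2A::AFF1"
  ctx <- resolve_context(rs411_specs(), sys$models)
  expect_equal(ctx$mode, "both_derivatives")
  expect_equal(ctx$p_max, 9L)
  expect_equal(ctx$q_min, 4L)
  expect_equal(ctx$r_min, 10L)
  expect_equal(ctx$s_max, 3L)

  # declared breakpoint K9-A4: fusion of the direct derivative
  ev <- classify_junction(sys, refs, ctx, sys$seq5[9], sys$seq3[4])
  expect_equal(ev$cls, "fusion")
  expect_equal(ev$attributed_derivative, "direct")

  # backsplice joining KMT2A exon 10 to AFF1 exon 2: f-circRNA of the
  # reciprocal derivative (reads map linearly on the direct-order reference)
  ev <- classify_junction(sys, refs, ctx, sys$seq5[10], sys$seq3[2])
  expect_equal(ev$cls, "f_circRNA")
  expect_equal(ev$attributed_derivative, "reciprocal")
  expect_equal(ev$gene5_exon, 10L)
  expect_equal(ev$gene3_exon, 2L)

  # K7-A4 crosses a junction upstream of both declared breakpoints:
  # alternative fusion transcript
  ev <- classify_junction(sys, refs, ctx, sys$seq5[7], sys$seq3[4])
  expect_equal(ev$cls, "alternative_fusion")
  expect_equal(ev$attributed_derivative, "direct")

  # reciprocal fusion A3-K11 is a declared reciprocal breakpoint
  ev <- classify_junction(sys, refs, ctx, sys$seq3[3], sys$seq5[11])
  expect_equal(ev$cls, "fusion")
  expect_equal(ev$attributed_derivative, "reciprocal")

  # backsplice of the direct derivative: AFF1 exon 5 joined back to KMT2A
  # exon 8 (j >= q_min, i <= p_max) read on a reciprocal-order reference
  ev <- classify_junction(sys, refs, ctx, sys$seq3[5], sys$seq5[8])
  expect_equal(ev$cls, "f_circRNA")
  expect_equal(ev$attributed_derivative, "direct")

  # incompatible exon pair: K11 -> A4 is outside every region
  ev <- classify_junction(sys, refs, ctx, sys$seq5[11], sys$seq3[4])
  expect_equal(ev$cls, "ambiguous")
})

test_that("classification agrees with a direct rule-by-rule reimplementation over the whole exon grid", {
  sys <- toy_system()
  ctx <- resolve_context(rs411_specs(), sys$models)
  # independent oracle: literal transcription of the compatibility rules
  oracle <- function(order, i, j) {
    if (order == "direct") {
      if ((i == 8 && j == 4) || (i == 9 && j == 4)) return("fusion")
      if (i <= 9 && j >= 4) return("alternative_fusion")
      if (i >= 10 && j <= 3) return("f_circRNA")
    } else {
      if ((j == 3 && i == 10) || (j == 3 && i == 11)) return("fusion")
      if (j <= 3 && i >= 10) return("alternative_fusion")
      if (j >= 4 && i <= 9) return("f_circRNA")
    }
    "ambiguous"
  }
  grid <- expand.grid(order = c("direct", "reciprocal"), i = 1:11, j = 1:6,
                      stringsAsFactors = FALSE)
  got <- fcircdetect:::classify_exon_pairs(grid$order, grid$i, grid$j, ctx)
  want <- mapply(oracle, grid$order, grid$i, grid$j)
  expect_equal(got$cls, unname(want))
})

test_that("linear and backsplice regions are disjoint whenever r_min > p_max and s_max < q_min", {
  set.seed(13)
  ri <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1)
  for (rep in 1:25) {
    p_max <- ri(1, 39)
    q_min <- ri(2, 40)
    r_min <- ri(p_max + 1, 40)
    s_max <- ri(1, q_min - 1)
    ctx <- structure(list(
      gene5 = "A", gene3 = "B", mode = "both_derivatives",
      direct = data.frame(p = p_max, q = q_min),
      reciprocal = data.frame(s = s_max, r = r_min),
      p_max = p_max, q_min = q_min, r_min = r_min, s_max = s_max
    ), class = "breakpoint_context")
    grid <- expand.grid(i = 1:40, j = 1:40)
    linear <- grid$i <= p_max & grid$j >= q_min
    circ <- grid$i >= r_min & grid$j <= s_max
    expect_equal(sum(linear & circ), 0L)
    # and the classifier maps each region to its class on direct-order refs
    res <- fcircdetect:::classify_exon_pairs(
      rep("direct", nrow(grid)), grid$i, grid$j, ctx)
    expect_true(all(res$cls[linear] %in% c("fusion", "alternative_fusion")))
    expect_true(all(res$cls[circ] == "f_circRNA"))
    expect_true(all(res$cls[!linear & !circ] == "ambiguous"))
  }
})

test_that("direct-only contexts infer the adjacent reciprocal junction", {
  sys <- toy_system()
  spec <- translocation_spec("KMT2A", "AFF1", direct_bp = c(6, 4))
  ctx <- resolve_context(list(spec), sys$models)
  expect_equal(ctx$mode, "direct_only")
  expect_equal(ctx$reciprocal$r, 7L)
  expect_equal(ctx$reciprocal$s, 3L)

  # q = 1 leaves no upstream partner exon: reciprocal detection disabled
  spec1 <- translocation_spec("KMT2A", "AFF1", direct_bp = c(6, 1))
  expect_message(ctx1 <- resolve_context(list(spec1), sys$models),
                 "disabled")
  expect_true(is.na(ctx1$r_min))
  expect_equal(nrow(ctx1$reciprocal), 0L)

  expect_error(
    resolve_context(list(translocation_spec("KMT2A", "AFF1", c(99, 1))),
                    sys$models),
    "out of range")
  expect_error(
    resolve_context(list(spec, translocation_spec("KMT2A", "MLLT3")),
                    sys$models),
    "inconsistent gene pairs")
})

test_that("discovery mode promotes the top junction and rescues backsplice candidates in a second pass", {
  sys <- toy_system()
  refs <- build_reference(sys$models$KMT2A, sys$models$AFF1, sys$genome)
  refs$pair <- "KMT2A::AFF1"
  ctx <- resolve_context(list(translocation_spec("KMT2A", "AFF1")),
                         sys$models)
  expect_equal(ctx$mode, "pair_only")

  reads <- character(0)
  # 10 reads over the direct junction K2-A5, 3 reads over the backsplice of
  # the direct derivative joining AFF1 exon 6 back to KMT2A exon 1 (they
  # map linearly on the reciprocal-order reference AFF1_6 + KMT2A_1)
  for (k in 1:10) {
    reads[sprintf("fus%d", k)] <- junction_read(sys$seq5[2], sys$seq3[5],
                                                20L + 5L * k, 100L)
  }
  for (k in 1:3) {
    reads[sprintf("bks%d", k)] <- junction_read(sys$seq3[6], sys$seq5[1],
                                                30L + 10L * k, 80L)
  }
  aln <- filter_alignments(align_reads(reads, refs))
  ev <- classify_discovery(aln[aln$pass, ], ctx)
  fus <- ev[grepl("^fus", ev$read_id), ]
  bks <- ev[grepl("^bks", ev$read_id), ]
  expect_true(all(fus$cls == "fusion"))
  expect_true(all(fus$attributed_derivative == "direct"))
  # j = 6 >= promoted q = 5 and i = 1 <= promoted p = 2: f-circRNA of the
  # direct derivative
  expect_true(all(bks$cls == "f_circRNA"))
  expect_true(all(bks$attributed_derivative == "direct"))
  ctx2 <- attr(ev, "promoted_context")
  expect_equal(ctx2$direct$p, 2L)
  expect_equal(ctx2$direct$q, 5L)

  # a single supported junction is promoted to fusion
  ev1 <- classify_discovery(aln[aln$pass & grepl("^fus", aln$read_id), ], ctx)
  expect_true(all(ev1$cls == "fusion"))
  # no reads: empty evidence, no promotion
  ev0 <- classify_discovery(aln[0, ], ctx)
  expect_equal(nrow(ev0), 0L)
})

test_that("every passing read receives exactly one class and counts are order-invariant", {
  sys <- toy_system()
  refs <- build_reference(sys$models$KMT2A, sys$models$AFF1, sys$genome)
  refs$pair <- "KMT2A::AFF1"
  ctx <- resolve_context(rs411_specs(), sys$models)
  set.seed(99)
  reads <- character(0)
  for (k in 1:40) {
    i <- sample(11L, 1L)
    j <- sample(6L, 1L)
    left <- sample(20:80, 1L)
    reads[sprintf("r%03d", k)] <- junction_read(sys$seq5[i], sys$seq3[j],
                                                left, 100L - left)
  }
  aln <- filter_alignments(align_reads(reads, refs))
  ev <- classify_reads(aln[aln$pass, ], ctx)
  expect_equal(nrow(ev), sum(aln$pass))
  expect_true(all(ev$cls %in% c("fusion", "alternative_fusion", "f_circRNA",
                                "ambiguous")))
  # permuting read order permutes but does not change the classification
  perm <- sample(nrow(aln))
  ev2 <- classify_reads(aln[perm, ][aln$pass[perm], ], ctx)
  ev2 <- ev2[order(ev2$read_id), ]
  ev1 <- ev[order(ev$read_id), ]
  rownames(ev1) <- rownames(ev2) <- NULL
  expect_equal(ev1, ev2)
})
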