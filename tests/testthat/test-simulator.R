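test_that("synthetic genes are deterministic under seed with exons in range", {
  g1 <- synth_gene("X", n_exons = 5L, exon_len_range = c(80L, 300L), seed = 1L)
  g2 <- synth_gene("X", n_exons = 5L, exon_len_range = c(80L, 300L), seed = 1L)
  expect_identical(g1$seq, g2$seq)
  expect_identical(g1$model$exons, g2$model$exons)
  len <- g1$model$exons$end - g1$model$exons$start
  expect_true(all(len >= 80L & len <= 300L))
  expect_error(synth_gene("X", n_exons = 1L), "n_exons")
  expect_error(synth_gene("X", exon_len_range = c(10L, 5L)), "degenerate")
})

test_that("paralog decoys diverge at about the requested substitution rate", {
  g <- synth_gene("Y", n_exons = 6L, seed = 3L)
  set.seed(4)
  d <- synth_paralog(g, "YP", divergence = 0.05)
  a <- strsplit(g$seq, "")[[1]]
  b <- strsplit(d$seq, "")[[1]]
  rate <- mean(a != b)
  n <- length(a)
  # binomial tolerance: 6 sigma around 5%
  sigma <- sqrt(0.05 * 0.95 / n)
  expect_true(abs(rate - 0.05) < 6 * sigma)
  expect_identical(d$model$exons, g$model$exons)
  expect_equal(d$model$chrom, "chr_YP")
})

test_that("each simulated junction is crossed by the configured number of error-free reads", {
  sim <- simulate_scenario("reciprocal", "annotated", read_len = 100L,
                           seed = 21L)
  counts <- table(paste(sim$truth$pair, sim$truth$cls, sim$truth$derivative,
                        sim$truth$gene5_exon, sim$truth$gene3_exon))
  per_class <- tapply(
    sim$truth$read_id,
    paste(sim$truth$cls, sim$truth$pair, sim$truth$gene5_exon,
          sim$truth$gene3_exon),
    length
  )
  # 4x fusion, 2x alternative, 2x backsplice
  cls_of <- sub(" .*", "", names(per_class))
  expect_true(all(per_class[cls_of == "fusion"] == 4L))
  expect_true(all(per_class[cls_of == "alternative_fusion"] == 2L))
  expect_true(all(per_class[cls_of == "f_circRNA"] == 2L))
  # every read crosses its junction with at least 1 nt on both sides and is
  # an exact substring construction (error-free by design)
  expect_true(all(sim$truth$split >= 1 &
                    sim$truth$split <= sim$read_len - 1))
  # truth is complete: every junction read has exactly one record
  jn_reads <- names(sim$reads)[!grepl("^decoy", names(sim$reads))]
  expect_setequal(sim$truth$read_id, jn_reads)
})

test_that("simulation is byte-identical under a fixed seed and FASTQ round-trips", {
  s1 <- simulate_scenario("single_breakpoint", "not_annotated", 150L, seed = 8L)
  s2 <- simulate_scenario("single_breakpoint", "not_annotated", 150L, seed = 8L)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "reads.fastq")
  write_fastq(s1$reads, fq)
  back <- read_fastq(fq)
  expect_identical(back, s1$reads)
  b1 <- add_background(s1$reads, 500L, read_len = 150L, seed = 5L)
  b2 <- add_background(s1$reads, 500L, read_len = 150L, seed = 5L)
  expect_identical(b1, b2)
  expect_equal(length(b1), length(s1$reads) + 500L)
})

test_that("no background read carries seedable junction context", {
  sim <- simulate_scenario("single_breakpoint", "annotated", 100L, seed = 31L)
  reads <- add_background(character(0), 2000L, read_len = 100L, seed = 32L)
  # junction 30-mers (one seed length on each side) from every simulated
  # junction read: background must not contain them in either orientation
  k_side <- align_params()$seed_len
  jn <- unique(vapply(seq_len(nrow(sim$truth)), function(k) {
    r <- sim$reads[[sim$truth$read_id[k]]]
    if (sim$truth$orientation[k] == "revcomp") {
      r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
    }
    s <- sim$truth$split[k]
    substr(r, s - k_side + 1L, s + k_side)
  }, character(1L)))
  jn <- c(jn, as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(jn))))
  hits <- vapply(jn, function(x) any(grepl(x, reads, fixed = TRUE)),
                 logical(1L))
  expect_false(any(hits))
})

test_that("scenario files materialize and reload consistently", {
  sim <- simulate_scenario("multiple_breakpoints", "annotated", 100L,
                           seed = 41L)
  dir <- withr::local_tempdir()
  paths <- write_scenario_files(sim, dir)
  expect_true(all(file.exists(paths)))
  genome <- read_genome(paths[["genome"]])
  expect_setequal(names(genome), names(sim$genome))
  models <- parse_gtf(paths[["gtf"]], names(sim$models), genome)
  for (nm in names(sim$models)) {
    expect_equal(models[[nm]]$exons, sim$models[[nm]]$exons)
    expect_equal(models[[nm]]$strand, sim$models[[nm]]$strand)
  }
  specs <- read_translocations(paths[["translocations"]])
  expect_length(specs, length(sim$specs))
})
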