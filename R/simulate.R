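# Synthetic benchmark generator.
#
# Emulates the simulation design used to evaluate the detector: four
# scenario kinds (single breakpoint, reciprocal, multiple breakpoints,
# paralog genes; 4/4/4/6 gene pairs respectively), fusion junctions placed
# either at annotated exon boundaries or in the middle of the fused exons,
# error-free reads of 100 or 150 nt tiling each junction at coverage 4x
# (fusion), 2x (alternative fusion) and 2x (f-circRNA backsplice), and a
# non-fusion background read set. Every junction read carries a truth
# record; background and paralog-decoy reads carry none.

#' Generate a synthetic gene on its own contig
#'
#' Exons alternate with introns on a random-sequence contig; coordinates are
#' recorded in a [gene_model()]. Deterministic under `seed`.
#'
#' @param symbol Gene symbol.
#' @param n_exons Number of exons (>= 2).
#' @param exon_len_range,intron_len_range Integer length ranges (min, max).
#' @param gc GC content of the random sequence.
#' @param strand `"+"` or `"-"`.
#' @param seed Optional RNG seed; when `NULL` the current RNG stream is used.
#' @return List with `contig` (name), `seq` (contig nucleotide string) and
#'   `model` (the [gene_model()]).
#' @export
synth_gene <- function(symbol, n_exons = 7L, exon_len_range = c(260L, 400L),
                       intron_len_range = c(80L, 200L), gc = 0.5,
                       strand = "+", seed = NULL) {
  if (n_exons < 2L) stop("n_exons must be >= 2")
  if (exon_len_range[1] > exon_len_range[2] || exon_len_range[1] < 1L ||
      intron_len_range[1] > intron_len_range[2] || intron_len_range[1] < 1L) {
    stop("degenerate length range")
  }
  if (!is.null(seed)) set.seed(seed)
  exon_len <- sample(exon_len_range[1]:exon_len_range[2], n_exons,
                     replace = TRUE)
  intron_len <- sample(intron_len_range[1]:intron_len_range[2],
                       n_exons - 1L, replace = TRUE)
  pad <- 50L
  total <- 2L * pad + sum(exon_len) + sum(intron_len)
  seq <- random_dna(total, gc)
  starts <- integer(n_exons)
  pos <- pad
  for (k in seq_len(n_exons)) {
    starts[k] <- pos
    pos <- pos + exon_len[k]
    if (k < n_exons) pos <- pos + intron_len[k]
  }
  contig <- paste0("chr_", symbol)
  model <- gene_model(
    gene_id = paste0("gene_", symbol), symbol = symbol, chrom = contig,
    strand = strand, starts = starts, ends = starts + exon_len
  )
  list(contig = contig, seq = seq, model = model)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a paralog decoy of a synthetic gene
#'
#' Copies the gene's contig applying independent per-base substitutions at
#' the given rate (every substitution changes the base), keeping the exon
#' coordinates; the decoy lives on its own contig under its own symbol.
#'
#' @param gene A [synth_gene()] result.
#' @param symbol Decoy symbol.
#' @param divergence Per-base substitution rate (default 0.05, approximating
#'   a close paralog).
#' @return A [synth_gene()]-shaped list.
#' @export
synth_paralog <- function(gene, symbol, divergence = 0.05) {
  bases <- strsplit(gene$seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(bases)) < divergence)
  alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
  for (k in hit) {
    choices <- strsplit(alt[[bases[k]]], "", fixed = TRUE)[[1]]
    bases[k] <- choices[sample.int(3L, 1L)]
  }
  contig <- paste0("chr_", symbol)
  model <- gene$model
  model$symbol <- symbol
  model$gene_id <- paste0("gene_", symbol)
  model$chrom <- contig
  list(contig = contig, seq = paste(bases, collapse = ""), model = model)
}

scenario_kinds <- function() {
  c("single_breakpoint", "reciprocal", "multiple_breakpoints", "paralog")
}

# number of gene pairs per scenario kind
scenario_n_pairs <- function(kind) {
  switch(kind, single_breakpoint = 4L, reciprocal = 4L,
         multiple_breakpoints = 4L, paralog = 6L,
         stop("unknown scenario kind: ", kind))
}

# junction flanks of a chimeric junction: upstream (5') flank sequence and
# downstream (3') flank sequence, honoring the junction style. Backsplice
# junctions always use complete exon ends (they are spliced at annotated
# splice sites); only linear fusion breakpoints can fall mid-exon.
junction_flanks <- function(up_seq, down_seq, style, is_backsplice) {
  if (style == "not_annotated" && !is_backsplice) {
    up <- substr(up_seq, 1L, nchar(up_seq) %/% 2L)
    down <- substr(down_seq, nchar(down_seq) %/% 2L + 1L, nchar(down_seq))
  } else {
    up <- up_seq
    down <- down_seq
  }
  list(up = up, down = down)
}

# error-free reads tiling one junction: `coverage` reads whose split points
# are evenly spread over [0.2, 0.8] of the read, every read crossing the
# junction; alternate reads are reverse-complemented.
tile_junction_reads <- function(flanks, read_len, coverage, id_prefix) {
  splits <- unique(round(seq(0.2, 0.8, length.out = coverage) * read_len))
  lu <- nchar(flanks$up)
  ld <- nchar(flanks$down)
  if (min(splits) > lu || (read_len - max(splits) > ld) ||
      max(splits) > lu) {
    stop("junction flanks too short for read length ", read_len)
  }
  reads <- character(0)
  meta <- list()
  for (k in seq_along(splits)) {
    s <- splits[k]
    seqr <- paste0(substr(flanks$up, lu - s + 1L, lu),
                   substr(flanks$down, 1L, read_len - s))
    orient <- if (k %% 2L == 0L) "revcomp" else "forward"
    if (orient == "revcomp") seqr <- revcomp(seqr)
    id <- sprintf("%s_r%d", id_prefix, k)
    reads[id] <- seqr
    meta[[k]] <- data.frame(read_id = id, split = s, orientation = orient)
  }
  list(reads = reads, meta = do.call(rbind, meta))
}

sample_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  sample(lo:hi, 1L)
}

# per-pair junction plan for one scenario kind; exon counts and breakpoints
# are drawn once from the current RNG stream
plan_pair <- function(kind, pair_idx, prefix) {
  m <- sample_range(7L, 9L)
  n <- sample_range(7L, 9L)
  p <- sample_range(3L, m - 4L)
  q <- sample_range(2L, n - 3L)
  g5 <- sprintf("%s%dA", prefix, pair_idx)
  g3 <- sprintf("%s%dB", prefix, pair_idx)
  junctions <- switch(
    kind,
    single_breakpoint = ,
    paralog = list(
      list(class = "fusion", derivative = "direct", i = p, j = q,
           coverage_key = "fusion"),
      list(class = "alternative_fusion", derivative = "direct",
           i = p - 1L, j = q, coverage_key = "alternative"),
      # f-circRNA of the direct derivative: backsplice joining gene3 exon
      # q+1 (donor) back to gene5 exon p-1 (acceptor)
      list(class = "f_circRNA", derivative = "direct", i = p - 1L,
           j = q + 1L, coverage_key = "f_circ")
    ),
    reciprocal = list(
      list(class = "fusion", derivative = "direct", i = p, j = q,
           coverage_key = "fusion"),
      list(class = "fusion", derivative = "reciprocal", i = p + 1L,
           j = q - 1L, coverage_key = "fusion"),
      list(class = "alternative_fusion", derivative = "direct",
           i = p - 1L, j = q, coverage_key = "alternative"),
      list(class = "f_circRNA", derivative = "reciprocal", i = p + 1L,
           j = q - 1L, coverage_key = "f_circ"),
      list(class = "f_circRNA", derivative = "direct", i = p - 1L,
           j = q + 1L, coverage_key = "f_circ")
    ),
    multiple_breakpoints = list(
      list(class = "fusion", derivative = "direct", i = p, j = q,
           coverage_key = "fusion"),
      list(class = "fusion", derivative = "direct", i = p + 1L, j = q,
           coverage_key = "fusion"),
      list(class = "alternative_fusion", derivative = "direct",
           i = p - 1L, j = q, coverage_key = "alternative"),
      list(class = "f_circRNA", derivative = "reciprocal", i = p + 2L,
           j = q - 1L, coverage_key = "f_circ"),
      list(class = "f_circRNA", derivative = "reciprocal", i = p + 3L,
           j = q - 1L, coverage_key = "f_circ")
    ),
    stop("unknown scenario kind: ", kind)
  )
  specs <- switch(
    kind,
    single_breakpoint = ,
    paralog = list(translocation_spec(g5, g3, direct_bp = c(p, q))),
    reciprocal = list(translocation_spec(
      g5, g3, direct_bp = c(p, q), reciprocal_bp = c(q - 1L, p + 1L))),
    multiple_breakpoints = list(
      translocation_spec(g5, g3, direct_bp = c(p, q),
                         reciprocal_bp = c(q - 1L, p + 2L)),
      translocation_spec(g5, g3, direct_bp = c(p + 1L, q),
                         reciprocal_bp = c(q - 1L, p + 3L))
    )
  )
  list(gene5 = g5, gene3 = g3, m = m, n = n, p = p, q = q,
       junctions = junctions, specs = specs)
}

#' Simulate one benchmark scenario
#'
#' Builds the synthetic genome and gene models for one scenario kind,
#' simulates error-free junction reads at the configured coverages, and (for
#' the paralog kind) adds decoy genes at ~5% divergence together with decoy
#' transcript fragments carrying no fusion.
#'
#' @param kind One of `scenario_kinds()`.
#' @param junction_style `"annotated"` (fusion breakpoints at exon
#'   boundaries) or `"not_annotated"` (breakpoints in the middle of the
#'   fused exons).
#' @param read_len Read length in nt (100 or 150 in the default battery).
#' @param coverages Named vector: junction-crossing reads per fusion,
#'   alternative-fusion and f-circRNA junction.
#' @param seed RNG seed.
#' @return List of class `sim_scenario` with `genome`
#'   ([Biostrings::DNAStringSet]), `models`, `specs`, `reads` (named
#'   character vector), `truth` (data frame), and the scenario parameters.
#' @export
simulate_scenario <- function(kind = "single_breakpoint",
                              junction_style = c("annotated", "not_annotated"),
                              read_len = 100L,
                              coverages = c(fusion = 4L, alternative = 2L,
                                            f_circ = 2L),
                              seed = 1L) {
  junction_style <- match.arg(junction_style)
  kind <- match.arg(kind, scenario_kinds())
  if (any(coverages < 1L)) stop("coverages must be positive")
  if (read_len < 50L) stop("read_len too short for the default filters")
  set.seed(seed)
  prefix <- switch(kind, single_breakpoint = "SB", reciprocal = "RC",
                   multiple_breakpoints = "MB", paralog = "PG")
  n_pairs <- scenario_n_pairs(kind)

  contigs <- character(0)
  models <- list()
  specs <- list()
  reads <- character(0)
  truth <- list()
  decoy_reads <- character(0)

  for (px in seq_len(n_pairs)) {
    plan <- plan_pair(kind, px, prefix)
    strand5 <- sample(c("+", "-"), 1L)
    strand3 <- sample(c("+", "-"), 1L)
    gene5 <- synth_gene(plan$gene5, n_exons = plan$m, strand = strand5)
    gene3 <- synth_gene(plan$gene3, n_exons = plan$n, strand = strand3)
    contigs[gene5$contig] <- gene5$seq
    contigs[gene3$contig] <- gene3$seq
    models[[plan$gene5]] <- gene5$model
    models[[plan$gene3]] <- gene3$model
    specs <- c(specs, plan$specs)

    genome_pair <- Biostrings::DNAStringSet(
      c(contigs[gene5$contig], contigs[gene3$contig]))
    names(genome_pair) <- c(gene5$contig, gene3$contig)
    seq5 <- model_exon_sequences(genome_pair, gene5$model)
    seq3 <- model_exon_sequences(genome_pair, gene3$model)

    for (jn in plan$junctions) {
      is_bks <- jn$class == "f_circRNA"
      # sequence blocks flanking the junction, in the order in which a read
      # traverses them; i is always the gene5 exon and j the gene3 exon
      if (jn$class == "f_circRNA") {
        if (jn$derivative == "reciprocal") {
          up <- seq5[jn$i]; down <- seq3[jn$j]
        } else {
          up <- seq3[jn$j]; down <- seq5[jn$i]
        }
      } else if (jn$derivative == "direct") {
        up <- seq5[jn$i]; down <- seq3[jn$j]
      } else {
        up <- seq3[jn$j]; down <- seq5[jn$i]
      }
      flanks <- junction_flanks(up, down, junction_style, is_bks)
      id_prefix <- sprintf("%s_%s_%s_%s_i%d_j%d", prefix, px, kind_tag(jn$class),
                           substr(jn$derivative, 1L, 3L), jn$i, jn$j)
      tiled <- tile_junction_reads(flanks, read_len,
                                   coverages[[jn$coverage_key]], id_prefix)
      reads <- c(reads, tiled$reads)
      truth[[length(truth) + 1L]] <- data.frame(
        read_id = tiled$meta$read_id,
        pair = paste(plan$gene5, plan$gene3, sep = "::"),
        cls = jn$class,
        derivative = jn$derivative,
        gene5_exon = jn$i,
        gene3_exon = jn$j,
        split = tiled$meta$split,
        orientation = tiled$meta$orientation,
        scenario = kind,
        junction_style = junction_style,
        read_len = read_len
      )
    }

    if (kind == "paralog") {
      for (gg in list(gene5, gene3)) {
        decoy <- synth_paralog(gg, paste0(gg$model$symbol, "P"))
        contigs[decoy$contig] <- decoy$seq
        models[[decoy$model$symbol]] <- decoy$model
        decoy_reads <- c(decoy_reads, decoy_fragment_reads(decoy, read_len))
      }
    }
  }

  genome <- Biostrings::DNAStringSet(contigs)
  names(genome) <- names(contigs)
  reads <- c(reads, decoy_reads)
  truth <- do.call(rbind, truth)
  structure(
    list(genome = genome, models = models, specs = specs, reads = reads,
         truth = truth, kind = kind, junction_style = junction_style,
         read_len = read_len, coverages = coverages, seed = seed),
    class = "sim_scenario"
  )
}

kind_tag <- function(cls) {
  c(fusion = "fus", alternative_fusion = "alt", f_circRNA = "circ")[[cls]]
}

# non-fusion fragments from a paralog decoy: exon-interior tiles plus two
# unspliced (pre-mRNA) fragments per internal exon boundary region, the
# read population most likely to fail linear alignment in real data
decoy_fragment_reads <- function(decoy, read_len) {
  genome1 <- Biostrings::DNAStringSet(decoy$seq)
  names(genome1) <- decoy$contig
  exseq <- model_exon_sequences(genome1, decoy$model)
  out <- character(0)
  sym <- decoy$model$symbol
  for (e in seq_along(exseq)) {
    len <- nchar(exseq[e])
    starts <- unique(c(1L, max(1L, len - read_len + 1L)))
    for (st in starts) {
      if (st + read_len - 1L > len) next
      id <- sprintf("decoy_%s_e%d_p%d", sym, e, st)
      out[id] <- substr(exseq[e], st, st + read_len - 1L)
    }
  }
  # pre-mRNA fragments across the first two exon/intron boundaries, offset
  # so roughly a quarter or three quarters of the read is intronic
  tx_strand_seq <- if (decoy$model$strand == "+") decoy$seq else
    revcomp(decoy$seq)
  n_ex <- nrow(decoy$model$exons)
  for (e in seq_len(min(2L, n_ex - 1L))) {
    ex <- decoy$model$exons[decoy$model$exons$exon == e, ]
    bnd <- if (decoy$model$strand == "+") ex$end else
      nchar(decoy$seq) - ex$start
    for (frac in c(0.25, 0.75)) {
      st <- bnd - read_len + as.integer(round(frac * read_len)) + 1L
      if (st < 1L || st + read_len - 1L > nchar(tx_strand_seq)) next
      id <- sprintf("decoy_%s_pre%d_f%d", sym, e, as.integer(frac * 100))
      out[id] <- substr(tx_strand_seq, st, st + read_len - 1L)
    }
  }
  out
}

#' Append a non-fusion background read set
#'
#' Appends reads drawn from non-fusion transcript models and from random
#' genomic-like sequence (a synthetic stand-in for the linearly unmapped
#' read background of a real sample), then shuffles all reads
#' deterministically.
#'
#' @param reads Named character vector of simulated reads.
#' @param n_background Number of background reads to add.
#' @param read_len Background read length.
#' @param n_bg_genes Number of background transcript models to synthesize.
#' @param seed RNG seed.
#' @return Named character vector of shuffled reads.
#' @export
add_background <- function(reads, n_background = 10000L, read_len = 100L,
                           n_bg_genes = 4L, seed = 1L) {
  set.seed(seed)
  bg <- character(0)
  if (n_background > 0L && n_bg_genes > 0L) {
    for (g in seq_len(n_bg_genes)) {
      gene <- synth_gene(sprintf("BG%d", g), n_exons = 6L)
      genome1 <- Biostrings::DNAStringSet(gene$seq)
      names(genome1) <- gene$contig
      tx <- paste(model_exon_sequences(genome1, gene$model), collapse = "")
      starts <- seq(1L, nchar(tx) - read_len + 1L, by = max(1L, read_len %/% 2L))
      frag <- vapply(starts, function(st) substr(tx, st, st + read_len - 1L),
                     character(1L))
      names(frag) <- sprintf("bg_tx%d_p%d", g, starts)
      bg <- c(bg, frag)
    }
    bg <- bg[seq_len(min(length(bg), n_background %/% 2L))]
  }
  n_rand <- n_background - length(bg)
  if (n_rand > 0L) {
    pool <- random_dna(n_rand * read_len)
    rand <- substring(pool, (seq_len(n_rand) - 1L) * read_len + 1L,
                      seq_len(n_rand) * read_len)
    names(rand) <- sprintf("bg_rand%d", seq_len(n_rand))
    bg <- c(bg, rand)
  }
  all <- c(reads, bg)
  all[sample.int(length(all))]
}

#' Write reads as FASTQ (error-free, constant quality)
#'
#' @param reads Named character vector.
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads)
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  names(seqs) <- names(reads)
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ path (optionally gzip-compressed).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write scenario annotation as GTF
#'
#' Emits gene/transcript/exon records (one transcript per gene spanning the
#' collapsed exons) with `gene_id`, `gene_name` and `transcript_id`
#' attributes, 1-based inclusive coordinates.
#'
#' @param models Named list of [gene_model()] objects.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- character(0)
  for (m in models) {
    span <- range(c(m$exons$start, m$exons$end))
    attrs <- sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s.t1";',
                     m$gene_id, m$symbol, m$gene_id)
    lines <- c(
      lines,
      paste(m$chrom, "synth", "gene", span[1] + 1L, span[2], ".", m$strand,
            ".", sprintf('gene_id "%s"; gene_name "%s";', m$gene_id, m$symbol),
            sep = "\t"),
      paste(m$chrom, "synth", "transcript", span[1] + 1L, span[2], ".",
            m$strand, ".", attrs, sep = "\t"),
      vapply(seq_len(nrow(m$exons)), function(k) {
        paste(m$chrom, "synth", "exon", m$exons$start[k] + 1L, m$exons$end[k],
              ".", m$strand, ".", attrs, sep = "\t")
      }, character(1L))
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write all scenario inputs as files
#'
#' Materializes a [simulate_scenario()] object as the file set the
#' command-line pipeline consumes: `genome.fa`, `annotation.gtf`,
#' `translocations.txt`, `reads.fastq` and `truth.csv`.
#'
#' @param sim A `sim_scenario`.
#' @param dir Output directory.
#' @return Named character vector of file paths, invisibly.
#' @export
write_scenario_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    translocations = file.path(dir, "translocations.txt"),
    fastq = file.path(dir, "reads.fastq"),
    truth = file.path(dir, "truth.csv")
  )
  Biostrings::writeXStringSet(sim$genome, paths[["genome"]])
  write_gtf(sim$models, paths[["gtf"]])
  lines <- vapply(sim$specs, function(s) {
    paste(c(s$gene5, s$gene3, s$direct_bp, s$reciprocal_bp), collapse = "\t")
  }, character(1L))
  writeLines(lines, paths[["translocations"]])
  write_fastq(sim$reads, paths[["fastq"]])
  utils::write.csv(sim$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
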