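# Shared fixtures and independent oracles, all built in code.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# two-gene toy system with deterministic structure, used across modules
toy_system <- function(seed = 11L, m5 = 11L, m3 = 6L) {
  g5 <- synth_gene("KMT2A", n_exons = m5, strand = "+", seed = seed)
  g3 <- synth_gene("AFF1", n_exons = m3, strand = "-", seed = seed + 1L)
  genome <- Biostrings::DNAStringSet(c(g5$seq, g3$seq))
  names(genome) <- c(g5$contig, g3$contig)
  models <- list(KMT2A = g5$model, AFF1 = g3$model)
  list(
    genome = genome,
    models = models,
    seq5 = model_exon_sequences(genome, g5$model),
    seq3 = model_exon_sequences(genome, g3$model)
  )
}

# the RS4;11-like breakpoint configuration: direct K8-A4 / K9-A4,
# reciprocal A3-K10 / A3-K11
rs411_specs <- function() {
  list(
    translocation_spec("KMT2A", "AFF1", direct_bp = c(8, 4),
                       reciprocal_bp = c(3, 10)),
    translocation_spec("KMT2A", "AFF1", direct_bp = c(9, 4),
                       reciprocal_bp = c(3, 11))
  )
}

# a junction read: last `left` nt of `up` followed by first `right` nt of
# `down`
junction_read <- function(up, down, left, right) {
  paste0(substr(up, nchar(up) - left + 1L, nchar(up)),
         substr(down, 1L, right))
}

# Brute-force split-alignment oracle, written independently of the package
# implementation: enumerates every reference, orientation, split point s and
# pair of segment placements (segment A of read[1..s] ending at ref position
# a <= junction, segment B of read[(s+1)..L] starting at ref position
# b >= junction), scoring matches - mismatches with full-length end-to-end
# placement, and returns the maximum score (or -Inf when no placement
# exists).
brute_force_best_score <- function(read, refs) {
  best <- -Inf
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  for (orient_read in c(read, rc(read))) {
    rb <- strsplit(orient_read, "", fixed = TRUE)[[1]]
    L <- length(rb)
    for (k in seq_len(nrow(refs))) {
      fb <- strsplit(refs$seq[k], "", fixed = TRUE)[[1]]
      Lr <- length(fb)
      J <- refs$junction_pos[k]
      for (s in 1:(L - 1L)) {
        if (s > J) next
        segA <- rb[1:s]
        segB <- rb[(s + 1L):L]
        lenB <- L - s
        if (Lr - lenB < J) next
        for (a in s:J) {
          mA <- sum(segA == fb[(a - s + 1L):a])
          for (b in J:(Lr - lenB)) {
            mB <- sum(segB == fb[(b + 1L):(b + lenB)])
            score <- 2L * (mA + mB) - L
            if (score > best) best <- score
          }
        }
      }
    }
  }
  best
}

# random small alignment instance: a handful of short two-block references
# plus a read sampled across one junction with point mutations
random_align_instance <- function(block_len = 20L, n_refs = 2L,
                                  read_len = 24L, n_mut = 2L) {
  refs <- do.call(rbind, lapply(seq_len(n_refs), function(k) {
    data.frame(
      ref_id = sprintf("G%d|1|H%d|1|direct", k, k),
      geneA = sprintf("G%d", k), exonA = 1L,
      geneB = sprintf("H%d", k), exonB = 1L,
      derivative = "direct",
      seq = paste0(rand_dna(block_len), rand_dna(block_len)),
      junction_pos = block_len,
      gene5 = sprintf("G%d", k), gene3 = sprintf("H%d", k),
      pair = sprintf("G%d::H%d", k, k)
    )
  }))
  src <- refs[sample.int(n_refs, 1L), ]
  left <- sample(3:(read_len - 3L), 1L)
  read <- paste0(
    substr(src$seq, src$junction_pos - left + 1L, src$junction_pos),
    substr(src$seq, src$junction_pos + 1L, src$junction_pos + read_len - left)
  )
  if (n_mut > 0L) {
    rb <- strsplit(read, "", fixed = TRUE)[[1]]
    pos <- sample(length(rb), n_mut)
    for (p in pos) {
      rb[p] <- sample(setdiff(c("A", "C", "G", "T"), rb[p]), 1L)
    }
    read <- paste(rb, collapse = "")
  }
  list(refs = refs, read = read)
}
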