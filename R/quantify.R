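# Aggregation of read-level junction evidence into fusion calls, read-count
# normalization, and plain-text/CSV/BED/JSON report writing.

# mate suffix ("/1", "/2") stripped so a fragment whose two mates both cross
# the same junction is counted once
fragment_id <- function(read_id) {
  sub("/[12]$", "", read_id)
}

#' Normalize a supporting read count over 10 M input reads
#'
#' `nr = n_reads / total_reads * 1e7`, the read support normalized over
#' 10 million linearly unmapped reads, reported to 2 decimals.
#'
#' @param n_reads Supporting read count(s).
#' @param total_reads Total number of linearly unmapped input reads.
#' @return Numeric vector of normalized supports.
#' @export
normalize_nr <- function(n_reads, total_reads) {
  if (length(total_reads) != 1L || is.na(total_reads) || total_reads < 1) {
    stop("total_reads must be a positive count")
  }
  round(n_reads / total_reads * 1e7, 2L)
}

fusion_call_name <- function(gene5, gene3, cls, gene5_exon, gene3_exon,
                             derivative) {
  a5 <- substr(gene5, 1L, 1L)
  a3 <- substr(gene3, 1L, 1L)
  ifelse(
    cls == "f_circRNA",
    # backsplice donor is always the gene5 exon block of the direct-order
    # reference pairing, named donor-acceptor: e.g. f-circK10-A2
    sprintf("f-circ%s%d-%s%d", a5, gene5_exon, a3, gene3_exon),
    ifelse(
      derivative == "direct",
      sprintf("%s%d-%s%d", a5, gene5_exon, a3, gene3_exon),
      sprintf("%s%d-%s%d", a3, gene3_exon, a5, gene5_exon)
    )
  )
}

# strand-aware junction coordinates (1-based base positions):
# donor = last transcribed base of the upstream exon, acceptor = first
# transcribed base of the downstream exon.
exon_donor_pos <- function(model, exon) {
  e <- model$exons[model$exons$exon == exon, ]
  if (nrow(e) != 1L) stop("unknown exon ", exon, " of gene ", model$symbol)
  if (model$strand == "+") e$end else e$start + 1L
}

exon_acceptor_pos <- function(model, exon) {
  e <- model$exons[model$exons$exon == exon, ]
  if (nrow(e) != 1L) stop("unknown exon ", exon, " of gene ", model$symbol)
  if (model$strand == "+") e$start + 1L else e$end
}

#' Aggregate classified read evidence into fusion calls
#'
#' One call per distinct (gene pair, derivative, class, exon pair), with the
#' number of distinct supporting fragments and strand-aware genomic junction
#' coordinates (for f-circRNAs these are the backsplice donor/acceptor
#' positions). Ambiguous reads are excluded. Calls are sorted by gene pair,
#' derivative, class and decreasing read support.
#'
#' @param evidence Classified alignment table from [classify_reads()]
#'   (filter-passing rows).
#' @param models Named list of [gene_model()] objects.
#' @param total_reads Total input read count, the normalization denominator.
#' @return Data frame of fusion calls with columns `name`, `pair`, `gene5`,
#'   `gene3`, `derivative`, `cls`, `gene5_exon`, `gene3_exon`, junction
#'   coordinates (`chrom5`, `strand5`, `donor_pos`, `chrom3`, `strand3`,
#'   `acceptor_pos`), `n_reads` and `nr`.
#' @export
aggregate_calls <- function(evidence, models, total_reads) {
  if (total_reads < 1) stop("total_reads must be >= 1")
  ev <- evidence[evidence$cls != "ambiguous", , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(empty_call_table())
  }
  ev$fragment <- fragment_id(ev$read_id)
  key <- paste(ev$pair, ev$attributed_derivative, ev$cls,
               ev$gene5_exon, ev$gene3_exon, sep = "\r")
  groups <- split(ev, key)
  calls <- lapply(groups, function(g) {
    g1 <- g[1L, ]
    pair <- strsplit(g1$pair, "::", fixed = TRUE)[[1]]
    m5 <- models[[pair[1]]]
    m3 <- models[[pair[2]]]
    if (is.null(m5) || is.null(m3)) {
      stop("evidence references unknown gene pair ", g1$pair)
    }
    # the upstream (donor) block of the junction: for linear fusions it is
    # the first gene of the attributed derivative; for f-circRNAs the
    # backsplice donor is the gene5 exon and the acceptor the gene3 exon of
    # the direct-order exon pairing, whatever the derivative
    if (g1$cls == "f_circRNA" || g1$attributed_derivative == "direct") {
      donor_model <- m5; donor_exon <- g1$gene5_exon
      acc_model <- m3; acc_exon <- g1$gene3_exon
    } else {
      donor_model <- m3; donor_exon <- g1$gene3_exon
      acc_model <- m5; acc_exon <- g1$gene5_exon
    }
    data.frame(
      name = fusion_call_name(pair[1], pair[2], g1$cls, g1$gene5_exon,
                              g1$gene3_exon, g1$attributed_derivative),
      pair = g1$pair,
      gene5 = pair[1], gene3 = pair[2],
      derivative = g1$attributed_derivative,
      cls = g1$cls,
      gene5_exon = g1$gene5_exon,
      gene3_exon = g1$gene3_exon,
      chrom5 = donor_model$chrom,
      strand5 = donor_model$strand,
      donor_pos = exon_donor_pos(donor_model, donor_exon),
      chrom3 = acc_model$chrom,
      strand3 = acc_model$strand,
      acceptor_pos = exon_acceptor_pos(acc_model, acc_exon),
      n_reads = length(unique(g$fragment))
    )
  })
  out <- do.call(rbind, calls)
  out$nr <- normalize_nr(out$n_reads, total_reads)
  cls_rank <- match(out$cls, c("fusion", "alternative_fusion", "f_circRNA"))
  out <- out[order(out$pair, out$derivative, cls_rank, -out$n_reads,
                   out$name, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_call_table <- function() {
  data.frame(
    name = character(0), pair = character(0), gene5 = character(0),
    gene3 = character(0), derivative = character(0), cls = character(0),
    gene5_exon = integer(0), gene3_exon = integer(0), chrom5 = character(0),
    strand5 = character(0), donor_pos = integer(0), chrom3 = character(0),
    strand3 = character(0), acceptor_pos = integer(0), n_reads = integer(0),
    nr = numeric(0)
  )
}

#' Write the detection reports
#'
#' Emits, under `out_dir`: `fusion_calls.csv` (call level),
#' `fusion_reads.csv` (read level), `fusion_junctions.bed` (BED6, one record
#' per junction side pair collapsed to the donor position interval, score =
#' supporting reads), one `summary_<GENE5>_<GENE3>.txt` per gene pair with
#' per-class counts, and `summary.json`. Output is deterministically ordered
#' and byte-identical across reruns on identical input.
#'
#' @param calls Call table from [aggregate_calls()].
#' @param evidence Classified read-level table.
#' @param out_dir Output directory (created if missing).
#' @param total_reads Total input read count (recorded in the JSON summary).
#' @return Character vector of the files written, invisibly.
#' @export
write_reports <- function(calls, evidence, out_dir, total_reads = NA) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)

  f_calls <- file.path(out_dir, "fusion_calls.csv")
  utils::write.csv(calls, f_calls, row.names = FALSE, quote = FALSE)
  files <- c(files, f_calls)

  read_cols <- intersect(
    c("read_id", "ref_id", "pair", "cls", "attributed_derivative",
      "gene5_exon", "gene3_exon", "strand_of_read", "overlap_a", "overlap_b",
      "matches_a", "matches_b", "mismatches_a", "mismatches_b", "reason"),
    names(evidence)
  )
  ev <- evidence[read_cols]
  ev <- ev[order(ev$pair, ev$read_id, method = "radix"), , drop = FALSE]
  f_reads <- file.path(out_dir, "fusion_reads.csv")
  utils::write.csv(ev, f_reads, row.names = FALSE, quote = FALSE)
  files <- c(files, f_reads)

  f_bed <- file.path(out_dir, "fusion_junctions.bed")
  if (nrow(calls) > 0L) {
    bed <- data.frame(
      chrom = calls$chrom5,
      start = calls$donor_pos - 1L,
      end = calls$donor_pos,
      name = sprintf("%s|%s|%s", calls$pair, calls$cls, calls$name),
      score = calls$n_reads,
      strand = calls$strand5
    )
  } else {
    bed <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0))
  }
  utils::write.table(bed, f_bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  files <- c(files, f_bed)

  pairs <- sort(unique(c(calls$pair, evidence$pair)))
  for (p in pairs) {
    cp <- calls[calls$pair == p, , drop = FALSE]
    ep <- evidence[evidence$pair == p, , drop = FALSE]
    g <- strsplit(p, "::", fixed = TRUE)[[1]]
    f_sum <- file.path(out_dir, sprintf("summary_%s_%s.txt", g[1], g[2]))
    lines <- c(
      sprintf("translocation: %s", p),
      sprintf("junction-crossing reads passing filters: %d", nrow(ep)),
      sprintf("reads classified ambiguous (excluded from calls): %d",
              sum(ep$cls == "ambiguous")),
      "",
      "fusions detected by type:",
      sprintf("  fusion transcripts: %d",
              sum(cp$cls == "fusion")),
      sprintf("  alternative fusion transcripts: %d",
              sum(cp$cls == "alternative_fusion")),
      sprintf("  f-circRNAs: %d", sum(cp$cls == "f_circRNA")),
      "",
      "supporting reads by type:",
      sprintf("  fusion transcripts: %d",
              sum(cp$n_reads[cp$cls == "fusion"])),
      sprintf("  alternative fusion transcripts: %d",
              sum(cp$n_reads[cp$cls == "alternative_fusion"])),
      sprintf("  f-circRNAs: %d", sum(cp$n_reads[cp$cls == "f_circRNA"]))
    )
    if (nrow(cp) > 0L) {
      lines <- c(lines, "", "calls:")
      lines <- c(lines, sprintf("  %s [%s, %s derivative] %s:%d-%s:%d reads=%d NR=%.2f",
                                cp$name, cp$cls, cp$derivative, cp$chrom5,
                                cp$donor_pos, cp$chrom3, cp$acceptor_pos,
                                cp$n_reads, cp$nr))
    } else {
      lines <- c(lines, "", "zero fusions detected")
    }
    writeLines(lines, f_sum)
    files <- c(files, f_sum)
  }
  if (length(pairs) == 0L) {
    f_sum <- file.path(out_dir, "summary_no_translocations.txt")
    writeLines(c("zero fusions detected", "no junction-crossing reads"),
               f_sum)
    files <- c(files, f_sum)
  }

  f_json <- file.path(out_dir, "summary.json")
  summary <- list(
    total_reads = total_reads,
    passing_reads = nrow(evidence),
    ambiguous_reads = if (nrow(evidence)) sum(evidence$cls == "ambiguous") else 0L,
    n_calls = nrow(calls),
    calls_by_class = as.list(table(factor(
      calls$cls, levels = c("fusion", "alternative_fusion", "f_circRNA")))),
    reads_by_class = as.list(tapply(
      calls$n_reads,
      factor(calls$cls, levels = c("fusion", "alternative_fusion", "f_circRNA")),
      sum, default = 0L))
  )
  jsonlite::write_json(summary, f_json, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, f_json)
  invisible(files)
}
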