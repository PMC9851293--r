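# Gene models: per-gene collapsed exon structures with deterministic
# transcription-order numbering, plus sequence extraction helpers.
#
# Conventions used throughout the package:
#   * genome coordinates are stored 0-based half-open ([start, end));
#     GTF input (1-based inclusive) is converted on read, BED output is
#     emitted 0-based half-open;
#   * exon numbering is 1..m in transcription order (ascending genomic
#     start on "+", descending on "-");
#   * genome sequence is uppercased so soft-masking cannot affect matching.

#' Read a genome FASTA into an uppercase DNAStringSet
#'
#' Contig names are truncated at the first whitespace, matching the usual
#' convention of annotation files that refer to bare contig identifiers.
#'
#' @param path Path to a (optionally gzip-compressed) FASTA file.
#' @return A named [Biostrings::DNAStringSet] with one entry per contig.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) {
    stop("genome FASTA not found: ", path)
  }
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome))) {
    stop("duplicate contig names in genome FASTA")
  }
  if (any(Biostrings::width(genome) == 0L)) {
    stop("empty contig sequence in genome FASTA")
  }
  toupper_genome(genome)
}

toupper_genome <- function(genome) {
  up <- Biostrings::DNAStringSet(toupper(as.character(genome)))
  names(up) <- names(genome)
  up
}

#' Construct a gene model from exon intervals
#'
#' Overlapping or adjacent exon intervals (the union over all transcripts of
#' the gene) are merged, then numbered in transcription order.
#'
#' @param gene_id Annotation identifier.
#' @param symbol Gene symbol used in translocation lists.
#' @param chrom Contig name.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends Integer vectors of exon bounds, 0-based half-open.
#' @return An object of class `gene_model`: a list with `gene_id`, `symbol`,
#'   `chrom`, `strand` and an `exons` data frame (`exon`, `start`, `end`)
#'   ordered 5' to 3' of the gene.
#' @export
gene_model <- function(gene_id, symbol, chrom, strand, starts, ends) {
  stopifnot(length(starts) == length(ends), length(starts) >= 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (any(starts < 0L) || any(ends <= starts)) {
    stop("invalid exon interval for gene ", symbol)
  }
  merged <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  start0 <- IRanges::start(merged) - 1L
  end0 <- IRanges::end(merged)
  ord <- if (strand == "+") order(start0) else order(start0, decreasing = TRUE)
  exons <- data.frame(
    exon = seq_along(ord),
    start = start0[ord],
    end = end0[ord]
  )
  structure(
    list(gene_id = gene_id, symbol = symbol, chrom = chrom, strand = strand,
         exons = exons),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%s, %d exon(s)\n",
              x$symbol, x$gene_id, x$chrom, x$strand, nrow(x$exons)))
  invisible(x)
}

n_exons <- function(model) nrow(model$exons)

#' Parse a GTF annotation into collapsed gene models
#'
#' Exons of all transcripts of each selected gene are collapsed (interval
#' union) into a single per-gene exon set, numbered in transcription order.
#' Genes are selected by `gene_name` first, falling back to `gene_id`, since
#' translocation lists are symbol-based.
#'
#' @param gtf_path Path to a GTF file with `gene_id`/`gene_name` attributes.
#' @param gene_selector Character vector of gene symbols (or ids) to load.
#' @param genome Optional genome [Biostrings::DNAStringSet] used to validate
#'   that exon coordinates fall within contig bounds.
#' @return Named list of [gene_model()] objects, one per selected gene, named
#'   by the selector entry that matched.
#' @export
parse_gtf <- function(gtf_path, gene_selector, genome = NULL) {
  if (!file.exists(gtf_path)) {
    stop("GTF file not found: ", gtf_path)
  }
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  is_exon <- !is.na(meta$type) & meta$type == "exon"
  gr <- gr[is_exon]
  meta <- S4Vectors::mcols(gr)
  gene_name <- if ("gene_name" %in% colnames(meta)) {
    as.character(meta$gene_name)
  } else {
    rep(NA_character_, length(gr))
  }
  gene_id <- as.character(meta$gene_id)
  models <- list()
  for (sel in unique(gene_selector)) {
    hit <- !is.na(gene_name) & gene_name == sel
    if (!any(hit)) hit <- !is.na(gene_id) & gene_id == sel
    if (!any(hit)) {
      stop("gene not found in annotation: ", sel)
    }
    sub <- gr[hit]
    chrom <- unique(as.character(GenomicRanges::seqnames(sub)))
    strand <- unique(as.character(BiocGenerics::strand(sub)))
    if (length(chrom) != 1L || length(strand) != 1L || !strand %in% c("+", "-")) {
      stop("inconsistent annotation for gene ", sel,
           ": exons on multiple contigs or strands")
    }
    ids <- unique(gene_id[hit])
    models[[sel]] <- gene_model(
      gene_id = ids[1L], symbol = sel, chrom = chrom, strand = strand,
      starts = GenomicRanges::start(sub) - 1L,
      ends = GenomicRanges::end(sub)
    )
    if (!is.null(genome)) validate_model_bounds(models[[sel]], genome)
  }
  models
}

validate_model_bounds <- function(model, genome) {
  if (!model$chrom %in% names(genome)) {
    stop("contig ", model$chrom, " (gene ", model$symbol,
         ") absent from genome")
  }
  len <- length(genome[[model$chrom]])
  if (any(model$exons$end > len)) {
    stop("exon of gene ", model$symbol, " exceeds contig ", model$chrom,
         " bounds")
  }
  invisible(model)
}

#' Extract an exon sequence in the gene's reading orientation
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param chrom Contig name.
#' @param start,end Exon bounds, 0-based half-open.
#' @param strand `"+"` or `"-"`; minus-strand exons are reverse-complemented
#'   so the returned string reads 5' to 3' of the gene.
#' @return Nucleotide string of length `end - start`.
#' @export
exon_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown contig: ", chrom)
  len <- length(genome[[chrom]])
  if (start < 0L || end > len || start >= end) {
    stop("exon [", start, ",", end, ") outside contig ", chrom,
         " bounds [0,", len, ")")
  }
  s <- Biostrings::subseq(genome[[chrom]], start = start + 1L, end = end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Extract all exon sequences of a gene model
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param model A [gene_model()].
#' @return Character vector of length `m`, element `i` being the sequence of
#'   exon `i` in the gene's 5' to 3' orientation.
#' @export
model_exon_sequences <- function(genome, model) {
  vapply(seq_len(nrow(model$exons)), function(i) {
    exon_sequence(genome, model$chrom, model$exons$start[i],
                  model$exons$end[i], model$strand)
  }, character(1L))
}

#' Write collapsed gene models to a BED6 file
#'
#' One record per exon, 0-based half-open, named `SYMBOL_exon<i>`, score 0.
#'
#' @param models List of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(models, path) {
  rows <- lapply(models, function(m) {
    data.frame(
      chrom = m$chrom,
      start = m$exons$start,
      end = m$exons$end,
      name = sprintf("%s_exon%d", m$symbol, m$exons$exon),
      score = 0L,
      strand = m$strand
    )
  })
  bed <- do.call(rbind, rows)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file of gene model exons written by [write_gene_bed()]
#'
#' @param path BED path.
#' @return Data frame with columns chrom, start, end, name, score, strand.
#' @export
read_gene_bed <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "name",
                                  "score", "strand"),
                    stringsAsFactors = FALSE)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
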