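# End-to-end detection pipeline: reference build -> split alignment ->
# classification -> aggregation -> reports.

#' Core detection on in-memory objects
#'
#' @param reads Named character vector (or [Biostrings::DNAStringSet]) of
#'   reads that failed linear alignment to the genome.
#' @param models Named list of [gene_model()] objects covering all genes
#'   named by `specs`.
#' @param specs List of [translocation_spec()] objects (possibly several per
#'   gene pair).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param params [align_params()].
#' @param total_reads Normalization denominator; defaults to the number of
#'   input reads.
#' @return List with `alignments` (raw best alignments with default-filter
#'   `pass`/`reason` columns), `evidence` (filter-passing classified reads),
#'   `calls` ([aggregate_calls()] output), `contexts` (per gene pair) and
#'   `total_reads`.
#' @export
detect_core <- function(reads, models, specs, genome,
                        params = align_params(), total_reads = NULL) {
  if (inherits(reads, "DNAStringSet")) {
    nm <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nm
  }
  if (is.null(total_reads)) total_reads <- length(reads)
  refs <- build_reference_set(specs, models, genome)
  pair_of <- function(s) paste(s$gene5, s$gene3, sep = "::")
  pairs <- unique(vapply(specs, pair_of, character(1L)))
  contexts <- lapply(pairs, function(p) {
    resolve_context(specs[vapply(specs, pair_of, character(1L)) == p], models)
  })
  names(contexts) <- pairs

  aln <- align_reads(reads, refs, params)
  aln <- filter_alignments(aln, params)
  classified <- classify_alignment_table(aln, contexts)
  evidence <- classified[classified$pass, , drop = FALSE]
  calls <- aggregate_calls(evidence, models, total_reads)
  list(alignments = classified, evidence = evidence, calls = calls,
       contexts = contexts, total_reads = total_reads)
}

#' Run the detection pipeline from files
#'
#' @param genome_path Genome FASTA.
#' @param gtf_path Gene annotation GTF.
#' @param translocations_path Translocation list (`GENE5 GENE3 [p q [s r]]`
#'   per line); mutually exclusive with `known_fusions_path`.
#' @param known_fusions_path Known fusion gene-pair list for discovery mode.
#' @param fastq_paths One or two FASTQ files (two are treated as mates and
#'   read together; fragments are deduplicated by read id stem).
#' @param params [align_params()].
#' @param total_reads Normalization denominator (the upstream count of
#'   linearly unmapped reads); defaults to the number of input reads.
#' @param out_dir Output directory for [write_reports()]; when `NULL`
#'   nothing is written.
#' @return Invisibly, the [detect_core()] result list.
#' @export
run_detect <- function(genome_path, gtf_path, translocations_path = NULL,
                       known_fusions_path = NULL, fastq_paths,
                       params = align_params(), total_reads = NULL,
                       out_dir = NULL) {
  if (is.null(translocations_path) == is.null(known_fusions_path)) {
    stop("give exactly one of translocations_path or known_fusions_path")
  }
  specs <- if (!is.null(translocations_path)) {
    read_translocations(translocations_path)
  } else {
    kf <- load_known_fusions(known_fusions_path)
    lapply(seq_len(nrow(kf)), function(k) {
      translocation_spec(kf$gene5[k], kf$gene3[k])
    })
  }
  genome <- read_genome(genome_path)
  symbols <- unique(unlist(lapply(specs, function(s) c(s$gene5, s$gene3))))
  if (!is.null(known_fusions_path)) {
    # discovery mode scans a catalogue; pairs absent from the annotation are
    # skipped rather than fatal
    models <- list()
    kept <- logical(length(specs))
    for (k in seq_along(specs)) {
      s <- specs[[k]]
      got <- tryCatch(parse_gtf(gtf_path, c(s$gene5, s$gene3), genome),
                      error = function(e) NULL)
      if (!is.null(got)) {
        models[names(got)] <- got
        kept[k] <- TRUE
      }
    }
    specs <- specs[kept]
    if (length(specs) == 0L) {
      stop("no known-fusion gene pair found in the annotation")
    }
  } else {
    models <- parse_gtf(gtf_path, symbols, genome)
  }

  reads <- unlist(lapply(fastq_paths, read_fastq))
  res <- detect_core(reads, models, specs, genome, params = params,
                     total_reads = total_reads)
  if (!is.null(out_dir)) {
    write_reports(res$calls, res$evidence, out_dir,
                  total_reads = res$total_reads)
  }
  invisible(res)
}
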