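# Split-read alignment against the chimeric reference set.
#
# Reads are placed end-to-end as two contiguous ungapped segments, the first
# ending at or before the reference's internal junction and the second
# starting at or after it, maximizing score = matches - mismatches over all
# references, both read orientations, split points and segment offsets.
# Candidate placements are found by exact k-mer seeding; for small reference
# sets every valid diagonal is enumerated instead, which makes the search
# provably exhaustive and is what the brute-force equivalence tests exercise.

#' Alignment and filtering parameters
#'
#' @param min_total_aligned Minimum aligned length in nt (default 50).
#' @param min_overlap Minimum segment length on each side of the junction in
#'   nt (default 5).
#' @param min_matches Minimum number of matching bases required in the
#'   shorter junction-side segment (default 5).
#' @param max_mismatch_frac Maximum fraction of mismatches over the whole
#'   alignment (default 0.17).
#' @param seed_len k-mer length used to seed candidate placements
#'   (default 15).
#' @param max_multimap Maximum reported references per read after
#'   tie-breaking (default 1, the single best hit; reads whose best score is
#'   tied across references of different gene pairs are flagged ambiguous
#'   and dropped).
#' @param exhaustive_below Total reference length (nt) below which seeding is
#'   replaced by exhaustive diagonal enumeration (default 20000).
#' @return A list of class `align_params`.
#' @export
align_params <- function(min_total_aligned = 50L, min_overlap = 5L,
                         min_matches = 5L, max_mismatch_frac = 0.17,
                         seed_len = 15L, max_multimap = 1L,
                         exhaustive_below = 20000L) {
  p <- list(
    min_total_aligned = as.integer(min_total_aligned),
    min_overlap = as.integer(min_overlap),
    min_matches = as.integer(min_matches),
    max_mismatch_frac = as.numeric(max_mismatch_frac),
    seed_len = as.integer(seed_len),
    max_multimap = as.integer(max_multimap),
    exhaustive_below = as.integer(exhaustive_below)
  )
  if (p$min_overlap < 1L) stop("min_overlap must be >= 1")
  if (p$max_mismatch_frac < 0 || p$max_mismatch_frac >= 1) {
    stop("max_mismatch_frac must be in [0, 1)")
  }
  if (p$seed_len < 8L) stop("seed_len must be >= 8")
  structure(p, class = "align_params")
}

#' Align reads against a chimeric reference set
#'
#' Returns the best junction-crossing two-segment alignment per read (if
#' any), before the junction-quality filters of [filter_alignments()] are
#' applied: the same alignments can therefore be re-filtered at different
#' stringencies, as the parameter-tuning sweep does.
#'
#' @param reads Character vector of read sequences, or a named
#'   [Biostrings::DNAStringSet].
#' @param read_ids Read identifiers (defaults to names of `reads`).
#' @param refs A `chimeric_reference_set` from [build_reference_set()].
#' @param params An [align_params()] object.
#' @return Data frame with one row per aligned read: `read_id`, `ref_id`,
#'   reference metadata columns, `strand_of_read` ("forward"/"revcomp"),
#'   `split`, segment reference coordinates (`a_ref_start`, `a_ref_end`,
#'   `b_ref_start`, `b_ref_end`), `overlap_a`, `overlap_b`, `matches_a`,
#'   `matches_b`, `mismatches_a`, `mismatches_b`, `ambiguous`. Reads with no
#'   candidate placement are absent; reads shorter than
#'   `2 * params$min_overlap` are skipped as too short.
#' @export
align_reads <- function(reads, refs, params = align_params(),
                        read_ids = NULL) {
  if (inherits(reads, "DNAStringSet")) {
    if (is.null(read_ids)) read_ids <- names(reads)
    reads <- as.character(reads)
  }
  if (is.null(read_ids)) read_ids <- names(reads)
  if (is.null(read_ids)) read_ids <- sprintf("read%d", seq_along(reads))
  stopifnot(length(read_ids) == length(reads))
  reads <- toupper(reads)

  # references in ref_id order so the C++ index tie-break is lexicographic
  refs <- refs[order(refs$ref_id), , drop = FALSE]
  pair_key <- if ("pair" %in% names(refs)) refs$pair else
    paste(refs$gene5, refs$gene3, sep = "::")
  pair_group <- as.integer(factor(pair_key))

  too_short <- nchar(reads) < max(2L, 2L * params$min_overlap)
  usable <- which(!too_short)
  if (length(usable) == 0L) {
    return(empty_alignment_table())
  }
  exhaustive <- sum(nchar(refs$seq)) < params$exhaustive_below
  hits <- .split_align_batch(
    reads[usable], refs$seq, as.integer(refs$junction_pos), pair_group,
    params$seed_len, exhaustive
  )
  if (nrow(hits) == 0L) {
    return(empty_alignment_table())
  }
  ridx <- usable[hits$read]
  len <- nchar(reads[ridx])
  out <- data.frame(
    read_id = read_ids[ridx],
    ref_id = refs$ref_id[hits$ref],
    pair = pair_key[hits$ref],
    geneA = refs$geneA[hits$ref],
    exonA = refs$exonA[hits$ref],
    geneB = refs$geneB[hits$ref],
    exonB = refs$exonB[hits$ref],
    derivative = refs$derivative[hits$ref],
    junction_pos = refs$junction_pos[hits$ref],
    strand_of_read = ifelse(hits$forward, "forward", "revcomp"),
    split = hits$split,
    a_ref_start = hits$a_ref_end - hits$split,
    a_ref_end = hits$a_ref_end,
    b_ref_start = hits$b_ref_start,
    b_ref_end = hits$b_ref_start + (len - hits$split),
    overlap_a = hits$split,
    overlap_b = len - hits$split,
    matches_a = hits$matches_a,
    matches_b = hits$matches_b,
    mismatches_a = hits$split - hits$matches_a,
    mismatches_b = (len - hits$split) - hits$matches_b,
    ambiguous = hits$ambiguous
  )
  rownames(out) <- NULL
  out
}

empty_alignment_table <- function() {
  data.frame(
    read_id = character(0), ref_id = character(0), pair = character(0),
    geneA = character(0), exonA = integer(0), geneB = character(0),
    exonB = integer(0), derivative = character(0), junction_pos = integer(0),
    strand_of_read = character(0), split = integer(0),
    a_ref_start = integer(0), a_ref_end = integer(0),
    b_ref_start = integer(0), b_ref_end = integer(0),
    overlap_a = integer(0), overlap_b = integer(0),
    matches_a = integer(0), matches_b = integer(0),
    mismatches_a = integer(0), mismatches_b = integer(0),
    ambiguous = logical(0)
  )
}

#' Align a single read
#'
#' Convenience wrapper around [align_reads()] honoring the single-read
#' contract: returns `NULL` with a `status` attribute (`"too_short"` or
#' `"no_alignment"`) when no alignment exists.
#'
#' @param read Read sequence (character scalar).
#' @param refs A `chimeric_reference_set`.
#' @param params An [align_params()] object.
#' @return One-row alignment data frame; when the read cannot be placed, a
#'   zero-row table whose `status` attribute is `"too_short"` or
#'   `"no_alignment"`.
#' @export
align_read <- function(read, refs, params = align_params()) {
  stopifnot(length(read) == 1L)
  if (nchar(read) < max(2L, 2L * params$min_overlap)) {
    return(structure(empty_alignment_table(), status = "too_short"))
  }
  aln <- align_reads(read, refs, params, read_ids = "read1")
  if (nrow(aln) == 0L) {
    return(structure(aln, status = "no_alignment"))
  }
  aln
}

#' Apply the junction-quality filters to an alignment table
#'
#' The criteria, in the order in which a failure is reported:
#' total aligned length >= `min_total_aligned`; both junction-side overlaps
#' >= `min_overlap`; matches in the shorter segment >= `min_matches` (ties in
#' segment length use the smaller match count); total mismatch fraction <=
#' `max_mismatch_frac`. Ambiguous reads (best score tied across gene pairs)
#' are also rejected.
#'
#' @param aln Alignment table from [align_reads()].
#' @param params An [align_params()] object.
#' @return `aln` with logical column `pass` and character column `reason`
#'   (`"pass"` or the first failing criterion).
#' @export
filter_alignments <- function(aln, params = align_params()) {
  if (nrow(aln) == 0L) {
    aln$pass <- logical(0)
    aln$reason <- character(0)
    return(aln)
  }
  total <- aln$overlap_a + aln$overlap_b
  shorter_matches <- ifelse(
    aln$overlap_a < aln$overlap_b, aln$matches_a,
    ifelse(aln$overlap_b < aln$overlap_a, aln$matches_b,
           pmin(aln$matches_a, aln$matches_b))
  )
  mism <- aln$mismatches_a + aln$mismatches_b
  reason <- rep("pass", nrow(aln))
  reason[mism / total > params$max_mismatch_frac] <- "max_mismatch_frac"
  reason[shorter_matches < params$min_matches] <- "min_matches"
  reason[pmin(aln$overlap_a, aln$overlap_b) < params$min_overlap] <- "min_overlap"
  reason[total < params$min_total_aligned] <- "min_total_aligned"
  reason[aln$ambiguous] <- "ambiguous"
  aln$pass <- reason == "pass"
  aln$reason <- reason
  aln
}

#' Test whether a single alignment passes the junction-quality filters
#'
#' @param aln One-row alignment table (from [align_read()]).
#' @param params An [align_params()] object.
#' @return Logical; attribute `reason` names the first failing criterion
#'   (or `"pass"`).
#' @export
passes_filters <- function(aln, params = align_params()) {
  stopifnot(nrow(aln) == 1L)
  flt <- filter_alignments(aln, params)
  structure(flt$pass, reason = flt$reason)
}
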