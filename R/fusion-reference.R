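# Chimeric reference construction: every pairwise exon combination of a
# translocation gene pair, in direct (gene5 exon + gene3 exon) and
# reciprocal (gene3 exon + gene5 exon) order. Reference ids follow the
# grammar GENEA|exonA|GENEB|exonB|derivative, which makes headers fully
# self-describing: the classifier never needs the builder's state.

#' Describe one translocation of interest
#'
#' @param gene5 Symbol of the 5' partner gene.
#' @param gene3 Symbol of the 3' partner gene.
#' @param direct_bp Optional `c(p, q)`: exon `p` of `gene5` joined to exon
#'   `q` of `gene3` in the direct derivative.
#' @param reciprocal_bp Optional `c(s, r)`: exon `s` of `gene3` joined to
#'   exon `r` of `gene5` in the reciprocal derivative.
#' @return An object of class `translocation_spec`.
#' @export
translocation_spec <- function(gene5, gene3, direct_bp = NULL,
                               reciprocal_bp = NULL) {
  if (identical(gene5, gene3)) {
    stop("self-fusion unsupported: ", gene5)
  }
  chk <- function(bp, what) {
    if (is.null(bp)) return(NULL)
    bp <- as.integer(bp)
    if (length(bp) != 2L || any(is.na(bp)) || any(bp < 1L)) {
      stop("invalid ", what, " breakpoint for ", gene5, "::", gene3)
    }
    bp
  }
  structure(
    list(gene5 = gene5, gene3 = gene3,
         direct_bp = chk(direct_bp, "direct"),
         reciprocal_bp = chk(reciprocal_bp, "reciprocal")),
    class = "translocation_spec"
  )
}

#' @export
print.translocation_spec <- function(x, ...) {
  fmt <- function(bp) if (is.null(bp)) "?" else paste(bp, collapse = "-")
  cat(sprintf("<translocation_spec> %s::%s direct %s reciprocal %s\n",
              x$gene5, x$gene3, fmt(x$direct_bp), fmt(x$reciprocal_bp)))
  invisible(x)
}

#' Read a translocation list
#'
#' One translocation per line: `GENE5 GENE3 [p q [s r]]` (whitespace
#' separated; `GENE5::GENE3` is also accepted for the gene pair). Several
#' lines may name the same gene pair to declare multiple breakpoints.
#'
#' @param path Path to the list.
#' @return List of [translocation_spec()] objects.
#' @export
read_translocations <- function(path) {
  if (!file.exists(path)) stop("translocation list not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty translocation list: ", path)
  lapply(seq_along(lines), function(i) {
    tok <- strsplit(lines[i], "[[:space:]]+")[[1]]
    if (grepl("::", tok[1], fixed = TRUE)) {
      tok <- c(strsplit(tok[1], "::", fixed = TRUE)[[1]], tok[-1])
    }
    if (!length(tok) %in% c(2L, 4L, 6L)) {
      stop("malformed translocation at line ", i,
           ": expected GENE5 GENE3 [p q [s r]]")
    }
    translocation_spec(
      gene5 = tok[1], gene3 = tok[2],
      direct_bp = if (length(tok) >= 4L) as.integer(tok[3:4]) else NULL,
      reciprocal_bp = if (length(tok) == 6L) as.integer(tok[5:6]) else NULL
    )
  })
}

#' Load a known-fusions gene-pair list for discovery mode
#'
#' Plain text, one pair per line, whitespace- or `::`-separated. Duplicate
#' pairs are removed keeping the first occurrence.
#'
#' @param path Path to the list.
#' @return Data frame with columns `gene5`, `gene3`.
#' @export
load_known_fusions <- function(path) {
  if (!file.exists(path)) stop("known-fusions list not found: ", path)
  lines <- trimws(readLines(path))
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  idx <- which(keep)
  pairs <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(gsub("::", " ", lines[i], fixed = TRUE),
                    "[[:space:]]+")[[1]]
    if (length(tok) != 2L) {
      stop("malformed known-fusions line ", idx[i], ": ", lines[i])
    }
    tok
  })
  df <- data.frame(
    gene5 = vapply(pairs, `[`, character(1L), 1L),
    gene3 = vapply(pairs, `[`, character(1L), 2L)
  )
  df[!duplicated(paste(df$gene5, df$gene3)), , drop = FALSE]
}

ref_id <- function(geneA, exonA, geneB, exonB, derivative) {
  sprintf("%s|%d|%s|%d|%s", geneA, exonA, geneB, exonB, derivative)
}

#' Build the chimeric reference set for one gene pair
#'
#' For a 5' partner with `m` exons and a 3' partner with `n` exons, returns
#' exactly `m * n` direct references (gene5 exon i followed by gene3 exon j)
#' and `m * n` reciprocal references (gene3 exon j followed by gene5 exon i),
#' `2 * m * n` in total. The junction offset of each reference equals the
#' length of its first exon block.
#'
#' @param model5,model3 [gene_model()] objects for the 5' and 3' partners.
#' @param genome Named [Biostrings::DNAStringSet].
#' @return Data frame of class `chimeric_reference_set` with columns
#'   `ref_id`, `geneA`, `exonA`, `geneB`, `exonB`, `derivative`, `seq`,
#'   `junction_pos`.
#' @export
build_reference <- function(model5, model3, genome) {
  if (identical(model5$symbol, model3$symbol)) {
    stop("self-fusion unsupported: ", model5$symbol)
  }
  seq5 <- model_exon_sequences(genome, model5)
  seq3 <- model_exon_sequences(genome, model3)
  m <- length(seq5)
  n <- length(seq3)
  grid <- expand.grid(i = seq_len(m), j = seq_len(n))
  direct <- data.frame(
    ref_id = ref_id(model5$symbol, grid$i, model3$symbol, grid$j, "direct"),
    geneA = model5$symbol, exonA = grid$i,
    geneB = model3$symbol, exonB = grid$j,
    derivative = "direct",
    seq = paste0(seq5[grid$i], seq3[grid$j]),
    junction_pos = nchar(seq5)[grid$i]
  )
  reciprocal <- data.frame(
    ref_id = ref_id(model3$symbol, grid$j, model5$symbol, grid$i,
                    "reciprocal"),
    geneA = model3$symbol, exonA = grid$j,
    geneB = model5$symbol, exonB = grid$i,
    derivative = "reciprocal",
    seq = paste0(seq3[grid$j], seq5[grid$i]),
    junction_pos = nchar(seq3)[grid$j]
  )
  refs <- rbind(direct, reciprocal)
  refs$gene5 <- model5$symbol
  refs$gene3 <- model3$symbol
  refs <- refs[order(refs$ref_id), , drop = FALSE]
  rownames(refs) <- NULL
  class(refs) <- c("chimeric_reference_set", "data.frame")
  refs
}

#' Build the union reference set over several translocation specs
#'
#' References of gene pairs shared by several specs are emitted once per
#' gene pair.
#'
#' @param specs List of [translocation_spec()] objects.
#' @param models Named list of [gene_model()] objects covering every gene.
#' @param genome Named [Biostrings::DNAStringSet].
#' @return A `chimeric_reference_set` data frame for all pairs, with an
#'   additional `pair` column (`"GENE5::GENE3"`).
#' @export
build_reference_set <- function(specs, models, genome) {
  pairs <- unique(vapply(specs, function(s) paste(s$gene5, s$gene3, sep = "::"),
                         character(1L)))
  sets <- lapply(pairs, function(p) {
    g <- strsplit(p, "::", fixed = TRUE)[[1]]
    for (sym in g) {
      if (is.null(models[[sym]])) stop("gene not found: ", sym)
    }
    refs <- build_reference(models[[g[1]]], models[[g[2]]], genome)
    refs$pair <- p
    refs
  })
  out <- do.call(rbind, sets)
  if (anyDuplicated(out$ref_id)) {
    stop("internal error: duplicated ref_id across gene pairs")
  }
  rownames(out) <- NULL
  class(out) <- c("chimeric_reference_set", "data.frame")
  out
}

#' Serialize a chimeric reference set as FASTA
#'
#' Headers have the form `ref_id junction=<pos> pair=<GENE5::GENE3>` so the
#' file round-trips losslessly through [read_reference_fasta()].
#'
#' @param refs A `chimeric_reference_set`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refs, path) {
  if (is.null(refs) || nrow(refs) == 0L) {
    stop("refusing to write an empty reference set")
  }
  seqs <- Biostrings::DNAStringSet(refs$seq)
  pair <- if ("pair" %in% names(refs)) refs$pair else
    paste(refs$gene5, refs$gene3, sep = "::")
  names(seqs) <- sprintf("%s junction=%d pair=%s",
                         refs$ref_id, refs$junction_pos, pair)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a chimeric reference FASTA written by [write_reference_fasta()]
#'
#' @param path FASTA path.
#' @return A `chimeric_reference_set` data frame.
#' @export
read_reference_fasta <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  hdr <- names(seqs)
  ref_ids <- sub("\\s.*$", "", hdr)
  junction <- as.integer(sub(".*junction=(\\d+).*", "\\1", hdr))
  pair <- sub(".*pair=(\\S+).*", "\\1", hdr)
  fields <- strsplit(ref_ids, "|", fixed = TRUE)
  bad <- lengths(fields) != 5L
  if (any(bad)) {
    stop("unparseable reference header: ", hdr[which(bad)[1]])
  }
  g <- strsplit(pair, "::", fixed = TRUE)
  refs <- data.frame(
    ref_id = ref_ids,
    geneA = vapply(fields, `[`, character(1L), 1L),
    exonA = as.integer(vapply(fields, `[`, character(1L), 2L)),
    geneB = vapply(fields, `[`, character(1L), 3L),
    exonB = as.integer(vapply(fields, `[`, character(1L), 4L)),
    derivative = vapply(fields, `[`, character(1L), 5L),
    seq = as.character(seqs),
    junction_pos = junction,
    gene5 = vapply(g, `[`, character(1L), 1L),
    gene3 = vapply(g, `[`, character(1L), 2L),
    pair = pair
  )
  class(refs) <- c("chimeric_reference_set", "data.frame")
  refs
}
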