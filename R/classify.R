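# Junction-crossing read classification.
#
# For one gene pair (gene5, gene3) with direct breakpoints (p, q) and
# reciprocal breakpoints (s, r), a read crossing the junction of a
# direct-order reference (gene5 exon i + gene3 exon j) is:
#   (a) fusion (direct derivative)        if (i, j) equals some declared (p, q);
#   (b) alternative fusion (direct)       if i <= p_max and j >= q_min;
#   (c) f-circRNA (reciprocal derivative) if i >= r_min and j <= s_max -- the
#       read spans a backsplice that joins gene5 exon i back to gene3 exon j
#       on the reciprocal derivative transcript;
#   (d) ambiguous otherwise.
# Reciprocal-order references are handled symmetrically with (s, r) taking
# the role of (p, q). Rules (a)/(b) and (c) are disjoint whenever
# r_min > p_max and s_max < q_min, which holds for every context derived
# from a balanced translocation (r = p + 1, s = q - 1).

#' Resolve a breakpoint context for one gene pair
#'
#' Determines the input mode from the supplied specs. With breakpoints for
#' both derivatives they are used as given; with only direct breakpoints the
#' reciprocal exons are inferred per spec as `r = p + 1` (clamped to the 5'
#' gene's exon count; absent when out of range) and `s = q - 1` (absent when
#' `q = 1`, which disables reciprocal-derivative f-circRNA detection); with
#' no breakpoints the context is `pair_only` and discovery classification
#' applies.
#'
#' @param specs List of [translocation_spec()] objects sharing one gene pair.
#' @param models Named list of [gene_model()] objects (used for exon-range
#'   validation and clamping).
#' @return An object of class `breakpoint_context` with fields `gene5`,
#'   `gene3`, `mode`, `direct` (data frame p, q), `reciprocal` (data frame
#'   s, r) and the bounds `p_max`, `q_min`, `r_min`, `s_max` (NA when a side
#'   is absent).
#' @export
resolve_context <- function(specs, models) {
  if (inherits(specs, "translocation_spec")) specs <- list(specs)
  g5 <- unique(vapply(specs, `[[`, character(1L), "gene5"))
  g3 <- unique(vapply(specs, `[[`, character(1L), "gene3"))
  if (length(g5) != 1L || length(g3) != 1L) {
    stop("inconsistent gene pairs across translocation specs")
  }
  m5 <- models[[g5]]
  m3 <- models[[g3]]
  if (is.null(m5) || is.null(m3)) {
    stop("gene models missing for pair ", g5, "::", g3)
  }
  has_direct <- vapply(specs, function(s) !is.null(s$direct_bp), logical(1L))
  has_recip <- vapply(specs, function(s) !is.null(s$reciprocal_bp), logical(1L))
  mode <- if (!any(has_direct) && !any(has_recip)) {
    "pair_only"
  } else if (all(has_direct) && all(has_recip)) {
    "both_derivatives"
  } else if (all(has_direct)) {
    "direct_only"
  } else {
    stop("specs for ", g5, "::", g3,
         " mix breakpoint modes; give the same fields on every line")
  }

  direct <- data.frame(p = integer(0), q = integer(0))
  reciprocal <- data.frame(s = integer(0), r = integer(0))
  if (mode != "pair_only") {
    direct <- data.frame(
      p = vapply(specs, function(s) s$direct_bp[1], integer(1L)),
      q = vapply(specs, function(s) s$direct_bp[2], integer(1L))
    )
    if (any(direct$p > n_exons(m5)) || any(direct$q > n_exons(m3))) {
      stop("direct breakpoint exon out of range for ", g5, "::", g3)
    }
    if (mode == "both_derivatives") {
      reciprocal <- data.frame(
        s = vapply(specs, function(s) s$reciprocal_bp[1], integer(1L)),
        r = vapply(specs, function(s) s$reciprocal_bp[2], integer(1L))
      )
      if (any(reciprocal$s > n_exons(m3)) || any(reciprocal$r > n_exons(m5))) {
        stop("reciprocal breakpoint exon out of range for ", g5, "::", g3)
      }
    } else {
      # infer the reciprocal junction adjacent to each direct breakpoint
      r <- direct$p + 1L
      s <- direct$q - 1L
      keep <- r <= n_exons(m5) & s >= 1L
      reciprocal <- data.frame(s = s[keep], r = r[keep])
      if (!all(keep)) {
        message("reciprocal-derivative detection disabled for ",
                g5, "::", g3, " (inferred exon out of range)")
      }
    }
  }
  structure(
    list(
      gene5 = g5, gene3 = g3, mode = mode,
      direct = direct, reciprocal = reciprocal,
      p_max = if (nrow(direct)) max(direct$p) else NA_integer_,
      q_min = if (nrow(direct)) min(direct$q) else NA_integer_,
      r_min = if (nrow(reciprocal)) min(reciprocal$r) else NA_integer_,
      s_max = if (nrow(reciprocal)) max(reciprocal$s) else NA_integer_
    ),
    class = "breakpoint_context"
  )
}

#' @export
print.breakpoint_context <- function(x, ...) {
  cat(sprintf("<breakpoint_context> %s::%s mode=%s p_max=%s q_min=%s r_min=%s s_max=%s\n",
              x$gene5, x$gene3, x$mode, x$p_max, x$q_min, x$r_min, x$s_max))
  invisible(x)
}

# vectorized core of the exon-compatibility rules; order = "direct" or
# "reciprocal" reference gene order; i = gene5 exon, j = gene3 exon.
classify_exon_pairs <- function(order, i, j, ctx) {
  n <- length(i)
  cls <- rep("ambiguous", n)
  derivative <- rep(NA_character_, n)
  is_dir <- order == "direct"

  dir_fusion <- rep(FALSE, n)
  for (k in seq_len(nrow(ctx$direct))) {
    dir_fusion <- dir_fusion |
      (is_dir & i == ctx$direct$p[k] & j == ctx$direct$q[k])
  }
  rec_fusion <- rep(FALSE, n)
  for (k in seq_len(nrow(ctx$reciprocal))) {
    rec_fusion <- rec_fusion |
      (!is_dir & j == ctx$reciprocal$s[k] & i == ctx$reciprocal$r[k])
  }
  dir_linear <- !is.na(ctx$p_max) & is_dir & i <= ctx$p_max & j >= ctx$q_min
  rec_linear <- !is.na(ctx$r_min) & !is_dir & j <= ctx$s_max & i >= ctx$r_min
  # backsplice compatibility: a circle of the reciprocal derivative is read
  # on a direct-order reference, and vice versa
  rec_circ <- !is.na(ctx$r_min) & is_dir & i >= ctx$r_min & j <= ctx$s_max
  dir_circ <- !is.na(ctx$p_max) & !is_dir & j >= ctx$q_min & i <= ctx$p_max

  set <- function(sel, class, deriv) {
    sel <- sel & cls == "ambiguous"
    cls[sel] <<- class
    derivative[sel] <<- deriv
  }
  set(dir_fusion, "fusion", "direct")
  set(rec_fusion, "fusion", "reciprocal")
  set(dir_linear, "alternative_fusion", "direct")
  set(rec_linear, "alternative_fusion", "reciprocal")
  set(rec_circ, "f_circRNA", "reciprocal")
  set(dir_circ, "f_circRNA", "direct")
  data.frame(cls = cls, attributed_derivative = derivative)
}

#' Classify filter-passing reads of one gene pair
#'
#' @param aln Filtered alignment table (rows with `pass == TRUE`) restricted
#'   to one gene pair.
#' @param ctx A [resolve_context()] object for that pair.
#' @return The alignment table with columns `cls` (fusion,
#'   alternative_fusion, f_circRNA or ambiguous), `attributed_derivative`,
#'   `gene5_exon`, `gene3_exon`.
#' @export
classify_reads <- function(aln, ctx) {
  if (nrow(aln) == 0L) {
    aln$cls <- character(0)
    aln$attributed_derivative <- character(0)
    aln$gene5_exon <- integer(0)
    aln$gene3_exon <- integer(0)
    return(aln)
  }
  if (ctx$mode == "pair_only") {
    return(classify_discovery(aln, ctx))
  }
  i <- ifelse(aln$derivative == "direct", aln$exonA, aln$exonB)
  j <- ifelse(aln$derivative == "direct", aln$exonB, aln$exonA)
  res <- classify_exon_pairs(aln$derivative, i, j, ctx)
  aln$cls <- res$cls
  aln$attributed_derivative <- res$attributed_derivative
  aln$gene5_exon <- i
  aln$gene3_exon <- j
  aln
}

#' Classify a single read alignment
#'
#' @param aln One-row filtered alignment.
#' @param ctx A [resolve_context()] object.
#' @return One-row data frame as in [classify_reads()].
#' @export
classify_read <- function(aln, ctx) {
  stopifnot(nrow(aln) == 1L)
  classify_reads(aln, ctx)
}

#' Discovery-mode classification (gene pair without breakpoints)
#'
#' Two-pass scheme: every junction-crossing read is first recorded as a
#' candidate linear junction for its reference gene order; the single
#' most-supported junction over both orders (ties: higher read count, then
#' smaller exon-number sum, then lexicographically smaller exon pair) is
#' promoted to putative breakpoint; the context is rebuilt with the adjacent
#' reciprocal-exon inference of [resolve_context()] and all reads are
#' re-classified, so candidates compatible with a backsplice of the promoted
#' junction become f-circRNAs.
#'
#' @param aln Filtered alignment table for one gene pair.
#' @param ctx A `pair_only` [resolve_context()] object.
#' @return Classified alignment table as in [classify_reads()].
#' @export
classify_discovery <- function(aln, ctx) {
  stopifnot(ctx$mode == "pair_only")
  if (nrow(aln) == 0L) {
    aln$cls <- character(0)
    aln$attributed_derivative <- character(0)
    aln$gene5_exon <- integer(0)
    aln$gene3_exon <- integer(0)
    return(aln)
  }
  i <- ifelse(aln$derivative == "direct", aln$exonA, aln$exonB)
  j <- ifelse(aln$derivative == "direct", aln$exonB, aln$exonA)
  key <- paste(aln$derivative, i, j, sep = ":")
  support <- table(key)
  cand <- data.frame(
    key = names(support),
    n = as.integer(support)
  )
  parts <- strsplit(cand$key, ":", fixed = TRUE)
  cand$order <- vapply(parts, `[`, character(1L), 1L)
  cand$i <- as.integer(vapply(parts, `[`, character(1L), 2L))
  cand$j <- as.integer(vapply(parts, `[`, character(1L), 3L))
  ord <- order(-cand$n, cand$i + cand$j, cand$i, cand$j,
               cand$order, method = "radix")
  top <- cand[ord[1L], ]

  # fake gene-model exon counts are irrelevant here: the promoted exons were
  # observed on real references, so clamping uses the observed maxima
  m5 <- max(i)
  m3 <- max(j)
  if (top$order == "direct") {
    direct <- data.frame(p = top$i, q = top$j)
    keep <- top$i + 1L <= m5 & top$j - 1L >= 1L
    reciprocal <- if (keep) data.frame(s = top$j - 1L, r = top$i + 1L) else
      data.frame(s = integer(0), r = integer(0))
  } else {
    reciprocal <- data.frame(s = top$j, r = top$i)
    keep <- top$i - 1L >= 1L & top$j + 1L <= m3
    direct <- if (keep) data.frame(p = top$i - 1L, q = top$j + 1L) else
      data.frame(p = integer(0), q = integer(0))
  }
  ctx2 <- structure(
    list(
      gene5 = ctx$gene5, gene3 = ctx$gene3, mode = "promoted",
      direct = direct, reciprocal = reciprocal,
      p_max = if (nrow(direct)) max(direct$p) else NA_integer_,
      q_min = if (nrow(direct)) min(direct$q) else NA_integer_,
      r_min = if (nrow(reciprocal)) min(reciprocal$r) else NA_integer_,
      s_max = if (nrow(reciprocal)) max(reciprocal$s) else NA_integer_
    ),
    class = "breakpoint_context"
  )
  res <- classify_exon_pairs(aln$derivative, i, j, ctx2)
  aln$cls <- res$cls
  aln$attributed_derivative <- res$attributed_derivative
  aln$gene5_exon <- i
  aln$gene3_exon <- j
  attr(aln, "promoted_context") <- ctx2
  aln
}
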