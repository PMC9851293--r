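# Performance scoring against simulation truth, the parameter-tuning sweep
# and the default benchmark battery.

#' Precision / recall / F1 from confusion counts
#'
#' Zero-denominator conventions: precision = 0 when tp + fp = 0, recall = 0
#' when tp + fn = 0, F1 = 0 when precision + recall = 0.
#'
#' @param tp,fp,fn Confusion counts.
#' @return One-row data frame `tp, fp, fn, precision, recall, f1`.
#' @export
perf_metrics <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  data.frame(tp = tp, fp = fp, fn = fn, precision = precision,
             recall = recall, f1 = f1)
}

class_group <- function(cls) {
  ifelse(cls == "f_circRNA", "f_circ",
         ifelse(cls %in% c("fusion", "alternative_fusion"), "linear", NA))
}

#' Score predictions against a simulation truth table
#'
#' At read level a true positive is a non-ambiguous predicted read present
#' in the truth table with matching gene pair and class; at junction level
#' predicted and true distinct (gene pair, class, exon pair) junctions are
#' intersected (exact exon-pair identity, no coordinate tolerance).
#'
#' @param evidence Classified read table ([classify_reads()] output).
#' @param truth Truth table from [simulate_scenario()].
#' @param level `"read"` or `"junction"`.
#' @param classes Optional class names to restrict both sides to (e.g.
#'   `c("fusion", "alternative_fusion")` for linear fusion transcripts).
#' @return One-row data frame from [perf_metrics()].
#' @export
score_predictions <- function(evidence, truth,
                              level = c("read", "junction"),
                              classes = NULL) {
  level <- match.arg(level)
  if (anyDuplicated(truth$read_id)) {
    stop("duplicated read_id in truth table")
  }
  pred <- evidence[evidence$cls != "ambiguous", , drop = FALSE]
  if (!is.null(classes)) {
    pred <- pred[pred$cls %in% classes, , drop = FALSE]
    truth <- truth[truth$cls %in% classes, , drop = FALSE]
  }
  if (level == "read") {
    pred_key <- paste(pred$read_id, pred$pair, pred$cls)
    truth_key <- paste(truth$read_id, truth$pair, truth$cls)
    tp <- sum(pred_key %in% truth_key)
    fp <- nrow(pred) - tp
    fn <- nrow(truth) - sum(truth_key %in% pred_key)
  } else {
    pred_j <- unique(paste(pred$pair, pred$cls, pred$gene5_exon,
                           pred$gene3_exon))
    truth_j <- unique(paste(truth$pair, truth$cls, truth$gene5_exon,
                            truth$gene3_exon))
    tp <- length(intersect(pred_j, truth_j))
    fp <- length(setdiff(pred_j, truth_j))
    fn <- length(setdiff(truth_j, pred_j))
  }
  perf_metrics(tp, fp, fn)
}

#' Run the parameter-tuning sweep
#'
#' Re-applies the junction-quality filters to a raw (unfiltered) alignment
#' table over a grid of minimum junction overlaps and minimum match counts,
#' re-scores each combination against the truth table, and reports one row
#' per (overlap, matches, transcript kind, level). Alignment itself does not
#' depend on these two parameters, so the sweep reuses the alignments. The
#' default grid (overlaps 1-10, 15, 20 nt; matches 4, 5, 10, 15, 20) has 60
#' combinations.
#'
#' @param aln Raw alignment table ([align_reads()] output) for all reads.
#' @param contexts Named list of [resolve_context()] objects by gene pair.
#' @param truth Truth table.
#' @param overlaps,min_matches_list Sweep grids.
#' @param params Base [align_params()].
#' @return Data frame with columns `min_overlap`, `min_matches`, `kind`
#'   (`linear` or `f_circ`), `level`, and the [perf_metrics()] columns.
#' @export
parameter_sweep <- function(aln, contexts, truth,
                            overlaps = c(1:10, 15L, 20L),
                            min_matches_list = c(4L, 5L, 10L, 15L, 20L),
                            params = align_params()) {
  if (length(overlaps) == 0L || length(min_matches_list) == 0L) {
    stop("empty sweep grid")
  }
  classified <- classify_alignment_table(aln, contexts)
  kinds <- list(linear = c("fusion", "alternative_fusion"),
                f_circ = "f_circRNA")
  rows <- list()
  for (ov in overlaps) {
    for (mm in min_matches_list) {
      p <- params
      p$min_overlap <- as.integer(ov)
      p$min_matches <- as.integer(mm)
      flt <- filter_alignments(classified, p)
      ev <- flt[flt$pass, , drop = FALSE]
      for (kind in names(kinds)) {
        for (level in c("read", "junction")) {
          m <- score_predictions(ev, truth, level = level,
                                 classes = kinds[[kind]])
          rows[[length(rows) + 1L]] <- cbind(
            data.frame(min_overlap = ov, min_matches = mm, kind = kind,
                       level = level),
            m
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# classify every alignment row (pass or not) by gene pair; rows of pairs
# without a context are dropped
classify_alignment_table <- function(aln, contexts) {
  pieces <- lapply(names(contexts), function(p) {
    sub <- aln[aln$pair == p, , drop = FALSE]
    classify_reads(sub, contexts[[p]])
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) out <- classify_reads(empty_alignment_table(),
                                          NULL)
  rownames(out) <- NULL
  out
}

#' The default benchmark battery configurations
#'
#' All four scenario kinds crossed with both junction styles and both read
#' lengths: 16 configurations.
#'
#' @return Data frame with columns `kind`, `junction_style`, `read_len`.
#' @export
battery_configs <- function() {
  expand.grid(
    kind = scenario_kinds(),
    junction_style = c("annotated", "not_annotated"),
    read_len = c(100L, 150L),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
}

#' Run the full simulation benchmark
#'
#' Simulates every battery configuration (error-free junction reads at
#' coverage 4x/2x/2x plus `n_background` non-fusion reads), runs detection
#' at the supplied parameters, scores each configuration at read and
#' junction level (combined and per transcript kind), and runs the pooled
#' 60-combination parameter-tuning sweep over all configurations.
#'
#' @param seed Integer seed; each configuration derives its own sub-seed.
#' @param n_background Background reads per configuration (default 10000).
#' @param params [align_params()] used for detection.
#' @param out_dir Optional directory for `benchmark_metrics.csv` and
#'   `parameter_sweep.csv`.
#' @param sweep Logical; run the pooled parameter sweep (default TRUE).
#' @return List with `metrics` (per-configuration scores), `sweep` (pooled
#'   sweep table or NULL), and `configs`.
#' @export
run_benchmark <- function(seed = 1L, n_background = 10000L,
                          params = align_params(), out_dir = NULL,
                          sweep = TRUE) {
  configs <- battery_configs()
  metrics <- list()
  pooled_aln <- list()
  pooled_truth <- list()
  pooled_ctx <- list()
  for (cf in seq_len(nrow(configs))) {
    sub_seed <- (seed * 131L + cf) %% .Machine$integer.max
    sim <- simulate_scenario(
      kind = configs$kind[cf],
      junction_style = configs$junction_style[cf],
      read_len = configs$read_len[cf],
      seed = sub_seed
    )
    reads <- add_background(sim$reads, n_background = n_background,
                            read_len = configs$read_len[cf],
                            seed = sub_seed + 7L)
    det <- detect_core(reads, sim$models, sim$specs, sim$genome,
                       params = params)
    strata <- list(combined = NULL,
                   linear = c("fusion", "alternative_fusion"),
                   f_circ = "f_circRNA")
    for (stratum in names(strata)) {
      for (level in c("read", "junction")) {
        m <- score_predictions(det$evidence, sim$truth, level = level,
                               classes = strata[[stratum]])
        metrics[[length(metrics) + 1L]] <- cbind(
          configs[cf, , drop = FALSE],
          data.frame(stratum = stratum, level = level),
          m
        )
      }
    }
    if (sweep) {
      tag <- sprintf("cfg%02d_", cf)
      aln <- det$alignments
      aln$read_id <- paste0(tag, aln$read_id)
      tr <- sim$truth
      tr$read_id <- paste0(tag, tr$read_id)
      # pair names are unique per kind but repeat across configurations of
      # the same kind; tag them so pooled contexts stay per-configuration
      aln$pair <- paste0(tag, aln$pair)
      tr$pair <- paste0(tag, tr$pair)
      ctx <- det$contexts
      names(ctx) <- paste0(tag, names(ctx))
      pooled_aln[[cf]] <- aln
      pooled_truth[[cf]] <- tr
      pooled_ctx <- c(pooled_ctx, ctx)
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  sweep_tab <- NULL
  if (sweep) {
    sweep_tab <- parameter_sweep(
      do.call(rbind, pooled_aln), pooled_ctx,
      do.call(rbind, pooled_truth), params = params
    )
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics, file.path(out_dir, "benchmark_metrics.csv"),
                     row.names = FALSE)
    if (!is.null(sweep_tab)) {
      utils::write.csv(sweep_tab, file.path(out_dir, "parameter_sweep.csv"),
                       row.names = FALSE)
    }
  }
  list(metrics = metrics, sweep = sweep_tab, configs = configs)
}
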