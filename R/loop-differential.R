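# Cross-condition loop filtering and CPM / log fold-change statistics.
#
# The published analysis obtained fold-changes from an edgeR-based
# association inside a loop package; that GLM is deliberately not
# re-implemented.  This module defines a transparent pseudocount-CPM log
# fold-change and validates it by planted-parameter recovery on synthetic
# truth.

#' Differential-analysis loop filters
#'
#' Flags each loop with the two published pre-filters: `passed_pet_filter`
#' (`FDR < fdr_max` and total PETs across all samples `>= min_total_pets`)
#' and `passed_consistency_filter` (a loop appearing strongly, more than
#' `strong_pets` PETs, in one replicate of a condition while the other
#' replicate of that condition has 0 PETs is removed; with more than two
#' replicates the rule generalises to max > `strong_pets` and min = 0).
#'
#' @param loops Loop table.
#' @param design Sample design (default parsed from PET columns).
#' @param fdr_max Strict FDR bound (default 0.01).
#' @param min_total_pets Inclusive total-PET bound (default 8).
#' @param strong_pets Strict single-replicate bound (default 5).
#' @param filter If `TRUE` (default) return only loops passing both flags;
#'   otherwise return all loops with the flag columns added.
#' @return Loop table, flagged and possibly subset.
#' @export
differential_filters <- function(loops, design = loop_design(loops),
                                 fdr_max = 0.01, min_total_pets = 8,
                                 strong_pets = 5, filter = TRUE) {
  pets <- as.matrix(loops[design$column])
  loops$passed_pet_filter <- loops$fdr < fdr_max & rowSums(pets) >= min_total_pets
  ok <- rep(TRUE, nrow(loops))
  for (cond in unique(design$condition)) {
    p <- pets[, design$column[design$condition == cond], drop = FALSE]
    if (ncol(p) < 2) next
    ok <- ok & !(apply(p, 1, max) > strong_pets & apply(p, 1, min) == 0)
  }
  loops$passed_consistency_filter <- ok
  if (filter) loops[loops$passed_pet_filter & ok, , drop = FALSE] else loops
}

#' Per-loop CPM, mean logCPM and log2 fold-change
#'
#' `CPM_s = PET_s / total_s * 1e6` with `total_s` the sample's summed PETs
#' over the (filtered) loop table; `mean_logcpm` is the mean over all
#' samples of `log2(CPM + pseudocount)`; `log2fc` is the treated-vs-baseline
#' difference of per-condition means of `log2(CPM + pseudocount)`.
#'
#' @param loops Filtered loop table.
#' @param design Sample design; its `condition` field must have exactly two
#'   levels.
#' @param contrast Character length-2: `c(treated, baseline)`; defaults to
#'   the design's conditions in reverse alphabetical order
#'   (so `dnmt1i` vs `dmso`).
#' @param pseudocount Pseudocount inside the log (default 0.5).
#' @return `data.frame(name, cpm_<sample>..., mean_logcpm, log2fc)`.
#' @export
loop_cpm_logfc <- function(loops, design = loop_design(loops),
                           contrast = NULL, pseudocount = 0.5) {
  conds <- sort(unique(design$condition), decreasing = TRUE)
  if (is.null(contrast)) contrast <- conds
  stopifnot(length(contrast) == 2, all(contrast %in% design$condition))
  pets <- as.matrix(loops[design$column])
  totals <- colSums(pets)
  if (any(totals == 0))
    stop("zero total PETs in sample(s): ",
         paste(design$sample[totals == 0], collapse = ", "))
  cpm <- sweep(pets, 2, totals, "/") * 1e6
  lg <- log2(cpm + pseudocount)
  mean_b <- rowMeans(lg[, design$column[design$condition == contrast[1]], drop = FALSE])
  mean_a <- rowMeans(lg[, design$column[design$condition == contrast[2]], drop = FALSE])
  out <- data.frame(name = loops$name, stringsAsFactors = FALSE)
  colnames(cpm) <- paste0("cpm_", design$sample)
  out <- cbind(out, as.data.frame(cpm))
  out$mean_logcpm <- rowMeans(lg)
  out$log2fc <- mean_b - mean_a
  rownames(out) <- NULL
  out
}

#' Stratify log fold-changes by a loop grouping
#'
#' Summarises `log2fc` per group (n, mean, median) and, for two groups,
#' reports a two-sided Mann-Whitney (rank-sum) p-value computed with the
#' normal approximation and tie correction.
#'
#' @param differentials Result of [loop_cpm_logfc()].
#' @param group Vector of group labels, one per loop (e.g. "anchor overlaps
#'   a condition-specific peak").
#' @return List of class `logfc_strata`: `summary` data.frame and `p_value`
#'   (NA unless exactly two non-empty groups).
#' @export
stratify_logfc <- function(differentials, group) {
  stopifnot(length(group) == nrow(differentials))
  lfc <- split(differentials$log2fc, group, drop = FALSE)
  summary <- do.call(rbind, lapply(names(lfc), function(gr)
    data.frame(group = gr, n = length(lfc[[gr]]),
               mean = if (length(lfc[[gr]])) mean(lfc[[gr]]) else NA_real_,
               median = if (length(lfc[[gr]])) stats::median(lfc[[gr]]) else NA_real_,
               stringsAsFactors = FALSE)))
  nonempty <- Filter(length, lfc)
  p <- if (length(nonempty) == 2)
    stats::wilcox.test(nonempty[[1]], nonempty[[2]], exact = FALSE)$p.value
  else NA_real_
  structure(list(summary = summary, p_value = p), class = "logfc_strata")
}

#' @export
print.logfc_strata <- function(x, ...) {
  print(x$summary)
  cat("rank-sum p =", format(x$p_value), "\n")
  invisible(x)
}

#' Does either anchor of each loop overlap a peak set?
#'
#' Convenience predicate used for the published groupings (anchor overlaps a
#' condition-specific peak; partner is highly looping).
#'
#' @param loops Loop table.
#' @param peaks Interval table.
#' @return Logical vector, one per loop.
#' @export
anchor_overlaps_peaks <- function(loops, peaks) {
  hit <- peak_anchor_hits(peaks, loops)
  seq_len(nrow(loops)) %in% hit$loop
}
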