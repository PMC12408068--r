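# Condition-specific peak set logic and genomic annotation.

#' Condition-specific peaks
#'
#' Returns the peaks called in condition B that have zero overlap with any
#' peak called in condition A (whole-peak non-overlap: a single shared bp
#' disqualifies), i.e. `bedtools intersect -v -wa` semantics.
#'
#' @param peaks_a Peaks called in the reference condition.
#' @param peaks_b Peaks called in the condition of interest.
#' @return The subset of `peaks_b` with no A overlap.
#' @export
condition_specific_peaks <- function(peaks_a, peaks_b) {
  if (nrow(peaks_b) == 0) return(peaks_b)
  if (nrow(peaks_a) == 0) return(peaks_b)
  hit <- interval_overlaps(peaks_b, peaks_a)
  peaks_b[!(seq_len(nrow(peaks_b)) %in% hit$query), , drop = FALSE]
}

#' Annotate peaks against a gene model
#'
#' Each peak gets exactly one category by the position of its midpoint, with
#' the standard priority order promoter > TTS > exon > intron > intergenic.
#' Promoter and TTS windows are strand-aware: promoter
#' `[TSS - promoter_up, TSS + promoter_down)`, TTS
#' `[TES - tts_up, TES + tts_down)`.
#'
#' @param peaks Interval table.
#' @param model A [gene_model()].
#' @param promoter_up,promoter_down Promoter window (bp upstream/downstream
#'   of the TSS; defaults 1000/100).
#' @param tts_up,tts_down TTS window (defaults 100/1000).
#' @param by `"center"` (midpoint, the default) or `"overlap"` (any overlap,
#'   same priority order).
#' @return Character vector of categories, one per peak.
#' @export
annotate_peaks <- function(peaks, model, promoter_up = 1000, promoter_down = 100,
                           tts_up = 100, tts_down = 1000,
                           by = c("center", "overlap")) {
  by <- match.arg(by)
  g <- model$genes
  plus <- g$strand != "-"
  tss <- ifelse(plus, g$start, g$end)
  tes <- ifelse(plus, g$end, g$start)
  win <- function(center, up, down) {
    s <- ifelse(plus, center - up, center - down)
    e <- ifelse(plus, center + down, center + up)
    data.frame(chrom = g$chrom, start = pmax(0, s), end = e,
               stringsAsFactors = FALSE)
  }
  prom <- win(tss, promoter_up, promoter_down)
  tts <- win(tes, tts_up, tts_down)
  q <- if (by == "center") {
    mid <- floor((peaks$start + peaks$end) / 2)
    data.frame(chrom = peaks$chrom, start = mid, end = mid + 1,
               stringsAsFactors = FALSE)
  } else peaks
  cat <- rep("intergenic", nrow(q))
  hit_any <- function(targets) seq_len(nrow(q)) %in% interval_overlaps(q, targets)$query
  in_gene <- hit_any(g)
  cat[in_gene] <- "intron"
  cat[hit_any(model$exons)] <- "exon"
  cat[hit_any(tts)] <- "TTS"
  cat[hit_any(prom)] <- "promoter"
  cat
}

#' Annotation category proportions per peak group
#'
#' @param category Character vector of categories (as from
#'   [annotate_peaks()]).
#' @param group Factor/vector of group labels (e.g. looping x specific).
#' @return `data.frame` of per-group fractions over the five categories;
#'   rows sum to 1; empty groups are omitted.
#' @export
annotation_proportions <- function(category, group) {
  lev <- c("promoter", "TTS", "exon", "intron", "intergenic")
  stopifnot(all(category %in% lev), length(category) == length(group))
  group <- as.character(group)
  out <- lapply(unique(group), function(gr) {
    cc <- category[group == gr]
    p <- as.numeric(table(factor(cc, levels = lev))) / length(cc)
    cbind(data.frame(group = gr, n = length(cc), stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(p, lev))))
  })
  do.call(rbind, out)
}

#' Attach covariates to a peak table
#'
#' Maps binned speckle signal (unweighted bin mean), an optional
#' subcompartment label BED (peaks overlapping multiple distinct labels are
#' set to `NA`, mirroring the discard rule for ambiguous overlaps), and an
#' optional TSA-seq-like track.
#'
#' @param peaks Interval table.
#' @param track Optional [signal_track()] (speckle signal).
#' @param subcompartments Optional interval table whose `name` column holds
#'   the label.
#' @param tsa Optional second [signal_track()].
#' @return `peaks` with added columns `speckle_signal`, `subcompartment`,
#'   `tsa_signal` (as supplied).
#' @export
attach_covariates <- function(peaks, track = NULL, subcompartments = NULL,
                              tsa = NULL) {
  if (!is.null(track)) peaks$speckle_signal <- map_binned_signal(track, peaks)
  if (!is.null(subcompartments)) {
    hit <- interval_overlaps(peaks, subcompartments)
    lab <- rep(NA_character_, nrow(peaks))
    if (nrow(hit)) {
      labs <- split(subcompartments$name[hit$subject], hit$query)
      u <- vapply(labs, function(x) if (length(unique(x)) == 1) x[1] else NA_character_, "")
      lab[as.integer(names(labs))] <- u
    }
    peaks$subcompartment <- lab
  }
  if (!is.null(tsa)) peaks$tsa_signal <- map_binned_signal(tsa, peaks)
  peaks
}
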