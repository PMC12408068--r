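# Per-peak loop statistics and the highly-looping caller.

#' Filter loops on FDR and summed PET counts
#'
#' Keeps loops with `FDR < fdr_max` (strict) and summed PETs `>= min_pets`
#' (the published rule "FDR<0.01 and >4 PETs", i.e. at least 5).
#'
#' @param loops Loop table.
#' @param fdr_max FDR upper bound (strict; default 0.01).
#' @param min_pets Minimum summed PET count, inclusive (default 5).
#' @param samples Optional character vector of sample names (from
#'   [loop_design()]) to sum over; default all samples.  Pass one
#'   condition's samples to filter per condition.
#' @return The filtered loop table.
#' @export
filter_loops <- function(loops, fdr_max = 0.01, min_pets = 5, samples = NULL) {
  cols <- pet_columns(loops)
  if (!is.null(samples)) {
    cols <- paste0("pet_", samples)
    if (!all(cols %in% names(loops)))
      stop("unknown sample(s): ", paste(setdiff(cols, names(loops)), collapse = ", "))
  }
  total <- rowSums(as.matrix(loops[cols]))
  loops[loops$fdr < fdr_max & total >= min_pets, , drop = FALSE]
}

#' Count distinct loops per peak
#'
#' Per peak, the number of distinct loop ids having at least 1 bp overlap
#' between the peak and either anchor.  A loop overlapping both anchors of
#' the same peak counts once (distinct-id semantics; set
#' `count_anchor_hits = TRUE` for the per-anchor-hit alternative).  The
#' looping flag marks peaks residing within at least one loop anchor.
#'
#' @param peaks Interval table with unique `name`s.
#' @param loops Loop table (already filtered).
#' @param count_anchor_hits Count each anchor hit instead of distinct loops.
#' @return `data.frame(name, n_distinct_loops, looping)`, one row per peak
#'   in input order.
#' @export
count_distinct_loops <- function(peaks, loops, count_anchor_hits = FALSE) {
  if (anyDuplicated(peaks$name)) stop("peak names must be unique")
  hits <- peak_anchor_hits(peaks, loops)
  key <- if (count_anchor_hits) paste(hits$loop, hits$anchor) else hits$loop
  n <- integer(nrow(peaks))
  if (nrow(hits)) {
    cnt <- vapply(split(key, hits$peak), function(x) length(unique(x)), 1L)
    n[as.integer(names(cnt))] <- cnt
  }
  data.frame(name = peaks$name, n_distinct_loops = n, looping = n >= 1,
             stringsAsFactors = FALSE)
}

## All (peak index, loop index, anchor side) triples with >= 1 bp overlap.
peak_anchor_hits <- function(peaks, loops) {
  out <- lapply(1:2, function(k) {
    h <- interval_overlaps(peaks, anchor_intervals(loops, k))
    if (nrow(h)) data.frame(peak = h$query, loop = h$subject, anchor = k) else NULL
  })
  res <- do.call(rbind, out)
  if (is.null(res)) data.frame(peak = integer(0), loop = integer(0), anchor = integer(0))
  else res
}

#' Maximum partner loop count per peak
#'
#' For each peak, over all loops touching it, looks at the peaks overlapping
#' the partner anchor and takes the maximum of their distinct-loop counts;
#' `NA` when no partner anchor contains a peak.
#'
#' @param peaks Interval table.
#' @param loops Loop table (same filter state used for `stats`).
#' @param stats Result of [count_distinct_loops()].
#' @return Numeric vector `max_partner_loops`, one per peak.
#' @export
max_partner_loops <- function(peaks, loops, stats = count_distinct_loops(peaks, loops)) {
  counts <- stats$n_distinct_loops[match(peaks$name, stats$name)]
  hits <- peak_anchor_hits(peaks, loops)
  out <- rep(NA_real_, nrow(peaks))
  if (nrow(hits) == 0) return(out)
  ## best count among the peaks sitting on each (loop, anchor) side, then
  ## per peak the max over the opposite sides of its hits
  amax <- tapply(counts[hits$peak], paste(hits$loop, hits$anchor), max)
  partner <- unname(amax[paste(hits$loop, 3L - hits$anchor)])
  vals <- tapply(partner, hits$peak, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  out[as.integer(names(vals))] <- unname(vals)
  out
}

#' Call highly looping peaks (tangent-slope-1 rank-curve cutoff)
#'
#' Peaks are ranked by their distinct-loop count; with rank and count both
#' scaled to `[0, 1]`, the cutoff sits where the tangent slope of the rank
#' curve reaches 1, computed as `argmin(y - x)` (exact for convex curves;
#' ties take the highest rank).  Peaks with counts strictly above the cutoff
#' count are highly looping.
#'
#' @param counts Integer distinct-loop counts.
#' @param ids Peak identifiers (default `names(counts)`); used for
#'   deterministic tie-breaking in the sort.
#' @return An object of class `elbow_result`: list with `n`, `curve`
#'   (`data.frame(rank, id, count, x, y)`), `cutoff_rank`, `cutoff_count`,
#'   and `highly_looping` (named logical in input order).
#' @export
call_highly_looping <- function(counts, ids = names(counts)) {
  if (is.null(ids)) ids <- as.character(seq_along(counts))
  n <- length(counts)
  empty <- function(msg) {
    warning(msg)
    structure(list(n = n, curve = NULL, cutoff_rank = NA_integer_,
                   cutoff_count = NA_real_,
                   highly_looping = stats::setNames(rep(FALSE, n), ids)),
              class = "elbow_result")
  }
  if (n < 3) return(empty("fewer than 3 peaks: no highly-looping call"))
  if (length(unique(counts)) == 1) return(empty("constant counts: no highly-looping call"))
  ord <- order(counts, ids)
  cs <- counts[ord]
  x <- (seq_len(n) - 1) / (n - 1)
  y <- cs / max(cs)
  d <- y - x
  cutoff <- max(which(d == min(d)))          # ties: highest rank
  cutoff_count <- unname(cs[cutoff])
  hl <- stats::setNames(counts > cutoff_count, ids)
  structure(list(n = n,
                 curve = data.frame(rank = seq_len(n), id = ids[ord],
                                    count = cs, x = x, y = y,
                                    stringsAsFactors = FALSE),
                 cutoff_rank = cutoff, cutoff_count = cutoff_count,
                 highly_looping = hl),
            class = "elbow_result")
}

#' @export
print.elbow_result <- function(x, ...) {
  cat("<elbow_result> n=", x$n, ", cutoff_count=", x$cutoff_count,
      ", highly looping: ", sum(x$highly_looping), "\n", sep = "")
  invisible(x)
}

#' Distance from peaks to a set of anchors
#'
#' Delegates to [closest_distance()]; when `group` is given a per-group
#' summary (n, median, mean) is attached as attribute `"summary"` (e.g.
#' highly- vs normal-looping peaks against stripe anchors).
#'
#' @param peaks Interval table.
#' @param anchors Interval table (externally supplied anchor list).
#' @param group Optional grouping vector.
#' @return Numeric distance per peak (`NA` where no same-chromosome anchor).
#' @export
distance_to_anchors <- function(peaks, anchors, group = NULL) {
  d <- if (nrow(anchors) == 0) rep(NA_real_, nrow(peaks))
       else closest_distance(peaks, anchors)
  if (!is.null(group)) {
    sm <- do.call(rbind, lapply(split(d, group), function(x)
      data.frame(n = sum(!is.na(x)), median = stats::median(x, na.rm = TRUE),
                 mean = mean(x, na.rm = TRUE))))
    sm <- cbind(group = rownames(sm), sm, stringsAsFactors = FALSE)
    rownames(sm) <- NULL
    attr(d, "summary") <- sm
  }
  d
}
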