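# Observed/expected aggregate pileups of the contact matrix.

#' Expected contact frequency by separation
#'
#' `expected(s)` is the mean of present (non-missing) entries at bin
#' separation `|i - j| = s` within the chromosome — the standard O/E
#' construction.
#'
#' @param cm A [contact_matrix()].
#' @return Numeric vector of length `n_bins` (`s = 0 .. n_bins - 1`); `NA`
#'   where a separation has no present entry.
#' @export
expected_by_distance <- function(cm) {
  n <- nrow(cm$mat)
  v <- as.vector(cm$mat)
  d <- abs(rep(seq_len(n), times = n) - rep(seq_len(n), each = n))
  present <- !is.na(v)
  sums <- rowsum(ifelse(present, v, 0), d)
  cnts <- rowsum(as.numeric(present), d)
  out <- rep(NA_real_, n)
  s <- as.integer(rownames(sums))
  ok <- cnts[, 1] > 0
  out[s[ok] + 1] <- sums[ok, 1] / cnts[ok, 1]
  out
}

#' Observed/expected matrix
#'
#' @param cm A [contact_matrix()].
#' @param expected Optional precomputed [expected_by_distance()] vector.
#' @return Matrix of O/E values (`NA` where observed or expected missing).
#' @export
oe_matrix <- function(cm, expected = expected_by_distance(cm)) {
  n <- nrow(cm$mat)
  d <- abs(rep(seq_len(n), times = n) - rep(seq_len(n), each = n))
  matrix(as.vector(cm$mat) / expected[d + 1], n, n)
}

#' Prepare pileup centers: blacklist exclusion and per-bin deduplication
#'
#' Drops peaks within `blacklist_dist` bp of a blacklist interval, then
#' among peaks whose midpoints share a matrix bin keeps the one with the
#' strongest signal.  Dropping order is blacklist, then dedup; edge drops
#' happen inside [pileup()].
#'
#' @param peaks Interval table carrying signal and strand.
#' @param bin_size Matrix bin size in bp.
#' @param blacklist Optional interval table.
#' @param signal_col Column holding the signal used for dedup (default
#'   `"score"`).
#' @param blacklist_dist Exclusion distance in bp (default 1000; a gap of
#'   exactly 1000 bp still excludes).
#' @return Centers `data.frame(chrom, bin, strand, name)` (bins 1-based),
#'   with attribute `"drops"` = `c(blacklist = , dedup = )`.
#' @export
prepare_centers <- function(peaks, bin_size, blacklist = NULL,
                            signal_col = "score", blacklist_dist = 1000) {
  n0 <- nrow(peaks)
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    d <- closest_distance(peaks, blacklist)
    keep <- is.na(d) | d > blacklist_dist
    peaks <- peaks[keep, , drop = FALSE]
  }
  n1 <- nrow(peaks)
  mid <- floor((peaks$start + peaks$end) / 2)
  bin <- floor(mid / bin_size) + 1
  key <- paste(peaks$chrom, bin)
  sig <- if (signal_col %in% names(peaks)) peaks[[signal_col]] else rep(0, n1)
  ord <- order(key, -sig)
  keep <- ord[!duplicated(key[ord])]
  keep <- sort(keep)
  centers <- data.frame(chrom = peaks$chrom[keep], bin = bin[keep],
                        strand = if ("strand" %in% names(peaks))
                          peaks$strand[keep] else ".",
                        name = peaks$name[keep], stringsAsFactors = FALSE)
  structure(centers, drops = c(blacklist = n0 - n1, dedup = n1 - nrow(centers)))
}

#' Aggregate observed/expected pileup
#'
#' For each center bin `b`, takes the `(2W+1)^2` O/E window centered at
#' `(b, b)`; windows of minus-strand centers are transposed (reflection
#' across the diagonal); cells are averaged over centers ignoring missing
#' values, and the mean is log2-transformed (mean-then-log).
#'
#' @param matrices A [contact_matrix()] or named list of them (per
#'   chromosome); expected values are computed per chromosome.
#' @param centers Result of [prepare_centers()].
#' @param W Window half-width in bins (default 10).
#' @return Object of class `pileup_result`: `log2_mean` ((2W+1)^2 matrix),
#'   `n_used`, `n_dropped_edge`, plus the center-preparation drop counts.
#' @export
pileup <- function(matrices, centers, W = 10) {
  if (inherits(matrices, "contact_matrix"))
    matrices <- stats::setNames(list(matrices), matrices$chrom)
  size <- 2 * W + 1
  acc <- matrix(0, size, size)
  cnt <- matrix(0, size, size)
  used <- 0L; edge <- 0L
  for (ch in unique(centers$chrom)) {
    cm <- matrices[[ch]]
    if (is.null(cm)) next
    oe <- oe_matrix(cm)
    n <- nrow(oe)
    cc <- centers[centers$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(cc))) {
      b <- cc$bin[i]
      if (b - W < 1 || b + W > n) { edge <- edge + 1L; next }
      win <- oe[(b - W):(b + W), (b - W):(b + W)]
      if (cc$strand[i] == "-") win <- t(win)
      ok <- !is.na(win)
      acc[ok] <- acc[ok] + win[ok]
      cnt <- cnt + ok
      used <- used + 1L
    }
  }
  log2_mean <- log2(acc / cnt)          # cells with cnt 0 become NaN -> NA
  log2_mean[cnt == 0] <- NA_real_
  drops <- attr(centers, "drops")
  structure(list(W = W, log2_mean = log2_mean, n_used = used,
                 n_dropped_edge = edge,
                 n_dropped_blacklist = unname(drops["blacklist"]),
                 n_dropped_dedup = unname(drops["dedup"])),
            class = "pileup_result")
}

#' @export
print.pileup_result <- function(x, ...) {
  cat("<pileup_result> W=", x$W, ", centers used=", x$n_used,
      " (edge-dropped ", x$n_dropped_edge, ")\n", sep = "")
  invisible(x)
}
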