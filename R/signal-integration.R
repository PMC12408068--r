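# Speckle-signal covariates: decile stratification, the 90th-percentile
# speckle-association rule, correlations and aggregate profiles.

#' Per-loop speckle signal
#'
#' Unweighted mean over the distinct bins overlapping either anchor (bins
#' shared by both anchors are counted once); loops touching no data bin get
#' `NA` and are excluded from downstream deciles.
#'
#' @param loops Loop table.
#' @param track A [signal_track()].
#' @return Numeric vector, one value per loop.
#' @export
loop_signal <- function(loops, track) {
  bs <- track$bin_size
  vapply(seq_len(nrow(loops)), function(i) {
    ch <- loops$chrom1[i]
    v <- track$values[[ch]]
    if (is.null(v)) return(NA_real_)
    bins <- function(s, e) {
      b0 <- max(1L, floor(s / bs) + 1L); b1 <- min(length(v), floor((e - 1) / bs) + 1L)
      if (b1 < b0) integer(0) else b0:b1
    }
    b <- unique(c(bins(loops$start1[i], loops$end1[i]),
                  bins(loops$start2[i], loops$end2[i])))
    b <- b[!track$missing[[ch]][b]]
    if (length(b) == 0) NA_real_ else mean(v[b])
  }, numeric(1))
}

#' Assign equal-count deciles
#'
#' Quantile-edge binning into `n` equal-count bins (label `n` = highest
#' signal); duplicate quantile edges are collapsed and labels renumbered
#' consecutively from 1 (pandas `qcut(duplicates = "drop")` behaviour).
#' Missing values get `NA`.
#'
#' @param values Numeric vector.
#' @param n Number of quantile bins (default 10).
#' @return Integer decile labels, same length as `values`.
#' @export
assign_deciles <- function(values, n = 10) {
  ok <- !is.na(values)
  out <- rep(NA_integer_, length(values))
  if (!any(ok)) return(out)
  edges <- unique(stats::quantile(values[ok], probs = seq(0, 1, length.out = n + 1),
                                  type = 7, names = FALSE))
  if (length(edges) < 2) {
    warning("all values identical: single decile bin")
    out[ok] <- 1L
    return(out)
  }
  lab <- cut(values[ok], breaks = edges, labels = FALSE, include.lowest = TRUE)
  ## quantile edges of tied data can leave a bin empty; renumber so the
  ## observed labels are consecutive from 1
  out[ok] <- match(lab, sort(unique(lab)))
  out
}

#' Speckle-associated peaks (90th-percentile rule)
#'
#' A peak is speckle-associated when its mapped signal is greater than or
#' equal to the 90th percentile of all genome-wide bin values (linear
#' interpolation between order statistics, quantile type 7).
#'
#' @param peaks Interval table.
#' @param track A [signal_track()].
#' @param probs Percentile defining the threshold (default 0.9).
#' @return Logical flag per peak (`NA` where the peak maps no signal), with
#'   the threshold attached as attribute `"threshold"`.
#' @export
speckle_associated_peaks <- function(peaks, track, probs = 0.9) {
  thr <- stats::quantile(track_values(track), probs, type = 7, names = FALSE)
  sig <- map_binned_signal(track, peaks)
  structure(sig >= thr, threshold = thr)
}

#' Correlate a looping quantity with a covariate
#'
#' Pearson r over paired non-missing values plus per-decile medians of the
#' looping quantity (deciles of the covariate).
#'
#' @param looping Numeric per-item looping quantity (distinct-loop count or
#'   logCPM).
#' @param covariate Numeric covariate (e.g. speckle signal).
#' @return List: `r` (NA for fewer than 3 pairs), `n`, and `deciles`
#'   (`data.frame(decile, n, median)`).
#' @export
correlate_looping_with_signal <- function(looping, covariate) {
  stopifnot(length(looping) == length(covariate))
  ok <- !is.na(looping) & !is.na(covariate)
  r <- if (sum(ok) < 3) NA_real_ else stats::cor(looping[ok], covariate[ok])
  dec <- assign_deciles(ifelse(ok, covariate, NA))
  tab <- do.call(rbind, lapply(sort(unique(dec[!is.na(dec)])), function(d)
    data.frame(decile = d, n = sum(dec == d, na.rm = TRUE),
               median = stats::median(looping[!is.na(dec) & dec == d]))))
  list(r = r, n = sum(ok), deciles = tab)
}

#' Aggregate signal profile around feature centers
#'
#' Mean signal versus offset around feature midpoints, in `bin`-bp steps
#' over `+/- flank` bp; rows for minus-strand features are reversed so
#' profiles are strand-aware.  Centers whose window leaves the chromosome
#' are dropped and counted.
#'
#' @param track A [signal_track()] (any bin size; each offset reads the bin
#'   containing that genomic position).
#' @param centers Interval table (with optional `strand`).
#' @param flank Half-window in bp (default 1000).
#' @param bin Step in bp (default 50).
#' @return List: `offsets` (bp, bin midpoints relative to center),
#'   `profile` (mean signal per offset), `n_used`, `n_dropped`.
#' @export
aggregate_profile <- function(track, centers, flank = 1000, bin = 50) {
  g <- unclass(track$genome); bs <- track$bin_size
  offs <- seq(-flank, flank - bin, by = bin) + bin / 2
  rows <- list(); dropped <- 0L
  for (i in seq_len(nrow(centers))) {
    ch <- centers$chrom[i]
    v <- track$values[[ch]]
    if (is.null(v)) { dropped <- dropped + 1L; next }
    mid <- floor((centers$start[i] + centers$end[i]) / 2)
    if (mid - flank < 0 || mid + flank > g[[ch]]) { dropped <- dropped + 1L; next }
    pos <- mid + offs
    b <- floor(pos / bs) + 1
    vals <- v[b]
    vals[track$missing[[ch]][b]] <- NA
    if (!is.null(centers$strand) && centers$strand[i] == "-") vals <- rev(vals)
    rows[[length(rows) + 1]] <- vals
  }
  profile <- if (length(rows)) colMeans(do.call(rbind, rows), na.rm = TRUE)
             else rep(NA_real_, length(offs))
  list(offsets = offs, profile = profile, n_used = length(rows), n_dropped = dropped)
}
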