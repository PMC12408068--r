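## Shared fixtures and independent oracles.  Everything here is built in
## code; no binary fixtures.

toy_genome <- function(n = 1, len = 1e6)
  genome(stats::setNames(rep(len, n), paste0("chr", seq_len(n))))

## A track from explicit per-chromosome value vectors (all bins present).
toy_track <- function(values, bin_size = 20000, len = NULL) {
  values <- lapply(values, as.numeric)
  if (is.null(len)) len <- vapply(values, length, 1L) * bin_size
  g <- genome(stats::setNames(len, names(values)))
  signal_track(g, bin_size, values,
               missing = lapply(values, function(v) rep(FALSE, length(v))))
}

## Loop table builder: anchors as (chrom, s1, e1, s2, e2); PET columns default
## to two conditions x two replicates.
mk_loops <- function(chrom, s1, e1, s2, e2,
                     pets = NULL, fdr = 0.001, name = NULL) {
  n <- length(s1)
  if (is.null(pets)) pets <- matrix(10, n, 4)
  pets <- matrix(pets, nrow = n)
  colnames(pets) <- c("pet_dmso_r1", "pet_dmso_r2",
                      "pet_dnmt1i_r1", "pet_dnmt1i_r2")[seq_len(ncol(pets))]
  chrom <- rep_len(chrom, n)
  x <- data.frame(chrom1 = chrom, start1 = s1, end1 = e1,
                  chrom2 = chrom, start2 = s2, end2 = e2,
                  name = if (is.null(name)) sprintf("L%d", seq_len(n)) else name,
                  score = rep(0, n), strand1 = rep(".", n), strand2 = rep(".", n),
                  stringsAsFactors = FALSE)
  x <- cbind(x, as.data.frame(pets))
  x$fdr <- rep_len(fdr, n)
  x
}

mk_peaks <- function(chrom, start, end, name = sprintf("P%d", seq_along(start)),
                     score = 0, strand = ".")
  gintervals(chrom, start, end, name = name, score = score, strand = strand)

## ---- independent oracles -------------------------------------------------

## Exhaustive peak x anchor overlap table, straight from the half-open
## definition (no interval machinery shared with the implementation).
oracle_hits <- function(peaks, loops, k) {
  ch <- loops[[paste0("chrom", k)]]
  s <- loops[[paste0("start", k)]]; e <- loops[[paste0("end", k)]]
  ## peaks x loops logical matrix
  outer(seq_len(nrow(peaks)), seq_len(nrow(loops)), function(i, j)
    peaks$chrom[i] == ch[j] & pmax(peaks$start[i], s[j]) < pmin(peaks$end[i], e[j]))
}

## Distinct-loop counts by definition (loop names assumed unique).
oracle_count_loops <- function(peaks, loops) {
  h <- oracle_hits(peaks, loops, 1) | oracle_hits(peaks, loops, 2)
  rowSums(h)
}

## Exhaustive max-partner oracle: per loop and side, the best count among
## peaks on the opposite anchor; per peak, the max over its anchor hits.
oracle_max_partner <- function(peaks, loops, counts = oracle_count_loops(peaks, loops)) {
  h1 <- oracle_hits(peaks, loops, 1); h2 <- oracle_hits(peaks, loops, 2)
  best <- function(h) apply(h, 2, function(col)
    if (any(col)) max(counts[col]) else NA_real_)
  b1 <- best(h1); b2 <- best(h2)      # best count on anchor 1 / anchor 2
  out <- rep(NA_real_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    vals <- c(b2[h1[i, ]], b1[h2[i, ]])
    if (length(vals) && any(!is.na(vals))) out[i] <- max(vals, na.rm = TRUE)
  }
  out
}

## Random peak/loop instance on one chromosome.
random_instance <- function(n_peaks = 20, n_loops = 40, len = 1e6) {
  pk <- mk_peaks("chr1", s <- sort(sample.int(len - 500, n_peaks)), s + 300)
  a <- sample.int(len - 2000, n_loops); b <- sample.int(len - 2000, n_loops)
  mk_loops("chr1", pmin(a, b), pmin(a, b) + 1500, pmax(a, b), pmax(a, b) + 1500)
}

## Slope-scan elbow oracle for strictly convex ascending scaled curves.
oracle_elbow_slope <- function(counts) {
  n <- length(counts)
  cs <- sort(counts)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- cs / max(cs)
  slope <- diff(y) / diff(x)
  j <- which(slope >= 1)[1]          # convex: slope increasing, crosses 1 once
  if (is.na(j)) n else j
}

## Per-feature brute-force bin scan matching map_binned_signal semantics.
oracle_map_signal <- function(track, features) {
  bs <- track$bin_size
  vapply(seq_len(nrow(features)), function(i) {
    ch <- features$chrom[i]
    v <- track$values[[ch]]
    if (is.null(v)) return(NA_real_)
    vals <- c()
    for (b in seq_along(v)) {
      bin_s <- (b - 1) * bs; bin_e <- b * bs
      if (max(bin_s, features$start[i]) < min(bin_e, features$end[i]) &&
          !track$missing[[ch]][b])
        vals <- c(vals, v[b])
    }
    if (length(vals)) mean(vals) else NA_real_
  }, numeric(1))
}

## Type-7 90th percentile, reimplemented from the interpolation formula.
oracle_p90 <- function(v) {
  v <- sort(v)
  h <- (length(v) - 1) * 0.9 + 1
  lo <- floor(h)
  v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
}

## ---- cached default-scale simulations (shared across acceptance tests) ---
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed, delta = 0.3) {
  key <- paste0("s", seed, "_d", delta)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_all(
      simulation_config(seed = seed, delta_logfc = delta),
      components = character(0))
  .sim_cache[[key]]
}

## Reduced-scale config for fast end-to-end runs (golden test + pipeline).
small_config <- function(seed = 11L)
  simulation_config(seed = seed, n_chrom = 1, chrom_length = 5e6,
                    n_genes = 80, n_constitutive_peaks = 150,
                    n_condition_specific_peaks = 40, n_hubs = 12,
                    n_speckle_centers = 12, n_decoy_loops = 30,
                    hub_partner_range = c(6L, 12L),
                    archetype_sizes = c(8L, 12L, 3L, 10L))
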