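# Differential-gene selection, z-scored K-means clustering (K = 4) and
# cluster-level covariate annotation.

#' Select differential genes by stated thresholds
#'
#' Keeps genes with adjusted p strictly below `p_adj_max` and absolute log2
#' fold-change strictly above `lfc_min` (the published "p-adj<0.05,
#' |log2(fold-change)|>0.5" rule).  Genes with missing statistics are
#' excluded with a warning giving the count.
#'
#' @param expr Expression table with `padj` and `log2fc` columns (or names
#'   given by `padj_col` / `lfc_col`).
#' @param p_adj_max Adjusted-p bound (strict; default 0.05).
#' @param lfc_min Absolute log2FC bound (strict; default 0.5).
#' @param padj_col,lfc_col Column names.
#' @return The selected subset of `expr`.
#' @export
select_differential_genes <- function(expr, p_adj_max = 0.05, lfc_min = 0.5,
                                      padj_col = "padj", lfc_col = "log2fc") {
  p <- expr[[padj_col]]; l <- expr[[lfc_col]]
  miss <- is.na(p) | is.na(l)
  if (any(miss)) warning(sum(miss), " gene(s) with missing statistics excluded")
  expr[!miss & p < p_adj_max & abs(l) > lfc_min, , drop = FALSE]
}

#' K-means clustering of z-scored expression
#'
#' Rows (genes) are z-scored across samples (mean 0, sd 1; zero-variance
#' rows are dropped with a warning), then clustered by Euclidean K-means
#' with `n_restarts` seeded restarts keeping the lowest inertia.  Cluster
#' labels are re-ordered deterministically by descending mean treated-minus-
#' baseline centroid difference so "cluster k" is stable across seeds.
#'
#' @param expr Expression table.
#' @param sample_cols Names of the abundance columns.
#' @param condition Condition label per sample column (two levels; the
#'   lexicographically later level is treated as "treated" unless
#'   `treated` is given).
#' @param K Number of clusters (default 4).
#' @param n_restarts Seeded K-means restarts (default 25).
#' @param seed RNG seed (default 1).
#' @param treated Optional treated-condition label.
#' @return Object of class `cluster_result`: `assignment`
#'   (`data.frame(gene_id, cluster, centroid_dist, order)`), `sizes`,
#'   `centers` (z-score space), `dropped` (zero-variance gene ids).
#' @export
cluster_genes <- function(expr, sample_cols, condition, K = 4,
                          n_restarts = 25, seed = 1, treated = NULL) {
  stopifnot(length(sample_cols) == length(condition))
  m <- as.matrix(expr[sample_cols])
  rownames(m) <- expr$gene_id
  sds <- apply(m, 1, stats::sd)
  dropped <- rownames(m)[sds == 0]
  if (length(dropped))
    warning(length(dropped), " zero-variance gene(s) dropped before z-scoring")
  m <- m[sds > 0, , drop = FALSE]
  if (nrow(m) < K) stop("fewer informative genes than clusters")
  z <- t(scale(t(m)))
  set.seed(seed)
  km <- stats::kmeans(z, centers = K, nstart = n_restarts, iter.max = 100)
  if (is.null(treated)) treated <- max(unique(condition))
  diffs <- rowMeans(km$centers[, condition == treated, drop = FALSE]) -
    rowMeans(km$centers[, condition != treated, drop = FALSE])
  relabel <- match(seq_len(K), order(diffs, decreasing = TRUE))
  cl <- relabel[km$cluster]
  centers <- km$centers[order(diffs, decreasing = TRUE), , drop = FALSE]
  rownames(centers) <- seq_len(K)
  cdist <- sqrt(rowSums((z - centers[cl, , drop = FALSE])^2))
  assignment <- data.frame(gene_id = rownames(m), cluster = cl,
                           centroid_dist = cdist, stringsAsFactors = FALSE)
  assignment <- assignment[order(assignment$cluster, assignment$centroid_dist), ]
  assignment$order <- seq_len(nrow(assignment))
  assignment <- assignment[match(rownames(m), assignment$gene_id), ]
  rownames(assignment) <- NULL
  structure(list(assignment = assignment,
                 sizes = as.integer(table(factor(cl, levels = seq_len(K)))),
                 centers = centers, dropped = dropped, K = K),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> K=", x$K, ", sizes: ",
      paste(x$sizes, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Cluster-level covariates: CTCF gain and speckle signal
#'
#' Maps peaks onto genes by overlap, then reports per cluster the mean peak
#' binding log2 fold-change over member genes' peaks and the distribution of
#' per-gene speckle signal, with pairwise Mann-Whitney p-values between
#' clusters on the speckle covariate.
#'
#' @param clusters A [cluster_genes()] result.
#' @param genes Gene interval table (with `gene_id`).
#' @param peaks Peak table carrying a per-peak binding log2FC column.
#' @param track [signal_track()] of speckle signal.
#' @param lfc_col Name of the peak log2FC column (default `"ctcf_log2fc"`).
#' @return List: `covariates` (`data.frame(cluster, n_genes, n_peaks,
#'   mean_peak_log2fc, mean_speckle, median_speckle)`), `pairwise_p`
#'   (matrix), `gene_speckle` (per-gene values).
#' @export
annotate_clusters <- function(clusters, genes, peaks, track,
                              lfc_col = "ctcf_log2fc") {
  asg <- clusters$assignment
  gi <- genes[match(asg$gene_id, genes$gene_id), , drop = FALSE]
  speckle <- map_binned_signal(track, gi)
  hit <- interval_overlaps(gi, peaks)
  K <- clusters$K
  rows <- lapply(seq_len(K), function(k) {
    in_k <- which(asg$cluster == k)
    pk <- hit$subject[hit$query %in% in_k]
    data.frame(cluster = k, n_genes = length(in_k), n_peaks = length(pk),
               mean_peak_log2fc = if (length(pk)) mean(peaks[[lfc_col]][pk],
                                                       na.rm = TRUE) else NA_real_,
               mean_speckle = mean(speckle[in_k], na.rm = TRUE),
               median_speckle = stats::median(speckle[in_k], na.rm = TRUE))
  })
  pw <- matrix(NA_real_, K, K, dimnames = list(seq_len(K), seq_len(K)))
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    xa <- speckle[asg$cluster == a]; xb <- speckle[asg$cluster == b]
    if (sum(!is.na(xa)) && sum(!is.na(xb)))
      pw[a, b] <- pw[b, a] <-
        stats::wilcox.test(xa, xb, exact = FALSE)$p.value
  }
  list(covariates = do.call(rbind, rows), pairwise_p = pw,
       gene_speckle = stats::setNames(speckle, asg$gene_id))
}

## Adjusted Rand index between two labelings (standard contingency-table
## formula).  Internal; used by tests and the pipeline summary.
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
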