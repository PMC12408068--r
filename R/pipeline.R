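# End-to-end orchestration on a simulated dataset.

#' Run the full analysis on a synthetic dataset
#'
#' Executes simulate -> peaks -> topology -> diffloops -> signal -> pileup
#' -> clusters and assembles a machine-readable summary.  Every
#' decision-bearing threshold is echoed in the summary's `thresholds` block
#' so runs are auditable.  Identical config (and therefore seed) gives a
#' byte-identical summary via [write_run_summary()].
#'
#' @param config A [simulation_config()].
#' @param outdir Optional directory; when given, the simulated inputs,
#'   per-stage TSVs and `summary.json` are written there.
#' @param stages Character vector of stages to run (default all, in order).
#'   Downstream stages fail fast, naming the missing prerequisite.
#' @param W Pileup window half-width in bins (default 10).
#' @return The summary as a named list (invisibly also written to
#'   `summary.json` under `outdir`).
#' @export
run_all <- function(config = simulation_config(), outdir = NULL,
                    stages = c("simulate", "peaks", "topology", "diffloops",
                               "signal", "pileup", "clusters"),
                    W = 10) {
  all_stages <- c("simulate", "peaks", "topology", "diffloops",
                  "signal", "pileup", "clusters")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  need <- function(x, stage, prereq)
    if (is.null(x)) stop("stage '", stage, "' requires output of stage '",
                         prereq, "' which did not run", call. = FALSE)
  thresholds <- list(loop_fdr_max = 0.01, loop_min_pets = 5,
                     diff_fdr_max = 0.01, diff_min_total_pets = 8,
                     diff_strong_pets = 5, cpm_pseudocount = 0.5,
                     speckle_percentile = 0.9, pileup_W = W,
                     pileup_blacklist_dist = 1000,
                     de_p_adj_max = 0.05, de_lfc_min = 0.5, kmeans_K = 4)
  summary <- list(seed = config$seed, thresholds = thresholds)
  sim <- NULL; peaks <- NULL; topo <- NULL; diffs <- NULL

  if ("simulate" %in% stages) {
    sim <- simulate_all(config, outdir = outdir)
    summary$simulate <- list(
      n_peaks = nrow(sim$peaks), n_loops = nrow(sim$loops),
      n_genes = nrow(sim$genes$genes), n_hubs = length(sim$truth$hub_peaks),
      n_specific_truth = length(sim$truth$specific_peaks))
  }

  if ("peaks" %in% stages) {
    need(sim, "peaks", "simulate")
    called_a <- sim$peaks[sim$peaks$called_dmso, , drop = FALSE]
    called_b <- sim$peaks[sim$peaks$called_dnmt1i, , drop = FALSE]
    specific <- condition_specific_peaks(called_a, called_b)
    pk <- sim$peaks
    pk$specific <- pk$name %in% specific$name
    pk$category <- annotate_peaks(pk, sim$genes)
    pk <- attach_covariates(pk, track = sim$tracks$dmso)
    pk$ctcf_log2fc <- log2(pk$signal_dnmt1i / pk$signal_dmso)
    peaks <- pk
    summary$peaks <- list(
      n_condition_specific = sum(pk$specific),
      category_proportions = annotation_proportions(
        pk$category, ifelse(pk$specific, "specific", "all")))
  }

  if ("topology" %in% stages) {
    need(peaks, "topology", "peaks")
    loops_b <- filter_loops(sim$loops,
                            samples = with(loop_design(sim$loops),
                                           sample[condition == "dnmt1i"]))
    stats <- count_distinct_loops(peaks, loops_b)
    stats$max_partner_loops <- max_partner_loops(peaks, loops_b, stats)
    elbow <- call_highly_looping(stats$n_distinct_loops, stats$name)
    peaks$n_distinct_loops <- stats$n_distinct_loops
    peaks$looping <- stats$looping
    peaks$max_partner_loops <- stats$max_partner_loops
    peaks$highly_looping <- unname(elbow$highly_looping)
    topo <- list(loops_b = loops_b, elbow = elbow)
    summary$topology <- list(
      n_loops_filtered = nrow(loops_b),
      fraction_specific_looping = mean(peaks$looping[peaks$specific]),
      fraction_all_looping = mean(peaks$looping),
      cutoff_count = elbow$cutoff_count,
      n_highly_looping = sum(peaks$highly_looping))
  }

  if ("diffloops" %in% stages) {
    need(sim, "diffloops", "simulate"); need(peaks, "diffloops", "peaks")
    kept <- differential_filters(sim$loops)
    lfc <- loop_cpm_logfc(kept)
    grp <- anchor_overlaps_peaks(kept, peaks[peaks$specific, , drop = FALSE])
    strata <- stratify_logfc(lfc, ifelse(grp, "specific_anchor", "other"))
    diffs <- list(kept = kept, lfc = lfc, specific_anchor = grp)
    summary$diffloops <- list(
      n_kept = nrow(kept),
      group_log2fc = strata$summary,
      rank_sum_p = strata$p_value)
  }

  if ("signal" %in% stages) {
    need(diffs, "signal", "diffloops"); need(peaks, "signal", "peaks")
    sig <- loop_signal(diffs$kept, sim$tracks$dmso)
    corr <- correlate_looping_with_signal(diffs$lfc$mean_logcpm, sig)
    spk <- speckle_associated_peaks(peaks, sim$tracks$dmso)
    peaks$speckle_associated <- unname(spk)
    summary$signal <- list(
      pearson_r = corr$r,
      decile_logcpm = corr$deciles,
      speckle_threshold = attr(spk, "threshold"),
      n_speckle_associated = sum(spk, na.rm = TRUE))
  }

  if ("pileup" %in% stages) {
    need(sim$matrices, "pileup", "simulate"); need(peaks, "pileup", "peaks")
    bin <- config$matrix_bin
    subsets <- list(specific = peaks[peaks$specific, , drop = FALSE],
                    highly = peaks[isTRUE_vec(peaks$highly_looping), , drop = FALSE],
                    all = peaks)
    summary$pileup <- lapply(subsets, function(ss) {
      if (nrow(ss) == 0) return(list(n_used = 0))
      ctr <- prepare_centers(ss, bin, blacklist = sim$blacklist,
                             signal_col = "signal_dnmt1i")
      pu <- pileup(sim$matrices, ctr, W = W)
      ctr_val <- pu$log2_mean[W + 1, W + 1]
      list(n_used = pu$n_used, n_dropped_edge = pu$n_dropped_edge,
           n_dropped_blacklist = pu$n_dropped_blacklist,
           n_dropped_dedup = pu$n_dropped_dedup,
           center_log2_oe = if (is.na(ctr_val)) NULL else ctr_val,
           mean_window_log2_oe = mean(pu$log2_mean, na.rm = TRUE),
           max_window_log2_oe = max(pu$log2_mean, na.rm = TRUE))
    })
  }

  if ("clusters" %in% stages) {
    need(sim$expression, "clusters", "simulate"); need(peaks, "clusters", "peaks")
    sel <- select_differential_genes(sim$expression)
    cols <- grep("^expr_", names(sel), value = TRUE)
    cond <- ifelse(grepl("^expr_dnmt1i", cols), "dnmt1i", "dmso")
    cl <- cluster_genes(sel, cols, cond, K = 4, seed = config$seed,
                        treated = "dnmt1i")
    genes <- sim$genes$genes
    ann <- annotate_clusters(cl, genes, peaks, sim$tracks$dmso)
    truth_arch <- sim$truth$gene_archetype[cl$assignment$gene_id]
    summary$clusters <- list(
      sizes = cl$sizes,
      ari_vs_truth = adjusted_rand_index(cl$assignment$cluster, truth_arch),
      covariates = ann$covariates)
  }

  if (!is.null(outdir)) {
    if (!is.null(peaks))
      utils::write.table(peaks, file.path(outdir, "peaks_annotated.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    write_run_summary(summary, file.path(outdir, "summary.json"))
  }
  invisible(summary)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Serialize a run summary deterministically
#'
#' Fixed-format JSON (8 significant digits, stable key order) so identical
#' runs produce byte-identical files.
#'
#' @param summary Result of [run_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(summary, path) {
  txt <- jsonlite::toJSON(summary, digits = 8, auto_unbox = TRUE,
                          pretty = TRUE, na = "null", dataframe = "columns")
  writeLines(txt, path)
  invisible(path)
}
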