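# Truth-labelled synthetic data generator.
#
# Emulates the statistical structure the downstream analysis assumes: hub
# anchors near high-speckle-signal bins, condition-specific peaks on gene
# bodies that appear only after treatment, distance-decay contact matrices
# with loop-pixel enrichment, overdispersed replicate PET counts, and four
# gene-expression archetypes.  Every planted effect is recorded in truth
# tables so recovery can be asserted.
#
# Conditions are labelled "dmso" (baseline) and "dnmt1i" (demethylated):
# condition-specific peaks exist only in the dnmt1i call set, and loops
# anchored at them strengthen by 2^delta_logfc in the dnmt1i samples.

#' Simulation configuration
#'
#' Defaults state the simulated world once: effect sizes mirror the reported
#' biology (planted loop-strength gain `delta_logfc = 0.3`, speckle-signal
#' gain `speckle_gain = 3`, loop-pixel enrichment 3, expression archetype
#' sizes 33/48/6/54); scale parameters (two 20 Mb chromosomes, 800
#' constitutive + 150 condition-specific peaks, 40 hubs) keep a full run
#' desk-sized while leaving every stage statistically resolvable.
#'
#' @param seed Master integer seed; a documented per-component stream split
#'   (track, genes, peaks, matrix, expression, blacklist) derives one
#'   sub-seed per generator so components can be regenerated independently.
#' @param n_chrom,chrom_length Number and length (bp) of chromosomes.
#' @param matrix_bin,signal_bin Contact-matrix (10 kb) and signal-track
#'   (20 kb) bin sizes.
#' @param n_genes Number of genes.
#' @param n_constitutive_peaks,n_condition_specific_peaks,n_hubs Peak counts;
#'   hubs are additional constitutive peaks planted at high-signal bins.
#' @param hub_partner_range,nonhub_partner_range Inclusive integer ranges of
#'   distinct-loop partner counts (hubs uniform; non-hubs weighted).
#' @param nonhub_partner_weights Sampling weights over the non-hub partner
#'   counts, one per value of `nonhub_partner_range`.  The skewed default
#'   makes roughly half of all peaks non-looping, matching the reported
#'   looping fractions (45% / 30% of condition-specific peaks residing in a
#'   loop anchor) far better than a uniform draw would.
#' @param loop_distance_range Anchor separation range in bp, sampled
#'   log-uniformly (candidate weighting ~ 1/distance).
#' @param pet_mean,pet_dispersion Negative-binomial PET mean (per sample, for
#'   a strength-1 loop) and dispersion (`size = 1/dispersion`).
#' @param delta_logfc Planted log2 strength ratio (treated vs baseline) of
#'   loops anchored at condition-specific peaks.  The ratio is realized
#'   symmetrically (2^(delta/2) in treated, 2^(-delta/2) in baseline
#'   samples): per-sample CPM only identifies the between-condition ratio,
#'   and the symmetric split keeps total PET mass balanced so the planted
#'   value is recoverable from CPM fold-changes without a compositional
#'   shift.
#' @param speckle_gain Multiplicative treated-condition signal gain over bins
#'   containing condition-specific peaks.
#' @param loop_pixel_enrichment Multiplicative contact enrichment at loop
#'   anchor-pair pixels (half effect over the 1-pixel neighbourhood).
#' @param n_replicates Replicates per condition.
#' @param n_decoy_loops High-FDR, low-PET decoy loops.
#' @param archetype_noise_sd Gaussian noise sd of the expression archetypes.
#' @param archetype_sizes Genes per expression archetype (4 classes).
#' @param specific_baseline_strength Baseline (dmso) strength multiplier of
#'   loops anchored at condition-specific peaks; below 1 because those
#'   anchors are methylation-masked at baseline, yet deep enough that the
#'   PET pre-filters do not select on noise within the group.
#' @param speckle_strength_beta Coupling between anchor speckle signal and
#'   loop strength: the multiplier is `exp(beta * tanh(z))` with `z` the
#'   z-scored anchor signal, i.e. smooth, monotone in the signal value and
#'   bounded in `[e^-beta, e^beta]`.  Plants the monotone
#'   decile-vs-strength association while keeping per-sample PET totals
#'   stable (an unbounded lognormal coupling would let a handful of
#'   mega-loops dominate library totals, which balanced HiChIP libraries do
#'   not show).
#' @param matrix_noise_sd sdlog of the mean-one multiplicative lognormal
#'   contact noise.
#' @param n_speckle_centers,speckle_bump_amplitude,speckle_bump_width
#'   Gaussian speckle bumps added to the lognormal track baseline
#'   (amplitude in signal units, width in bins).
#' @param baseline_meanlog,baseline_sdlog Lognormal track baseline.
#' @param peak_width,anchor_pad Peak width and anchor padding (bp).
#' @param min_peak_spacing Minimum distance between peak midpoints; keeps
#'   anchors peak-exclusive so planted partner counts are exact.
#' @param specific_placement Named fractions (nonintronic / intronic /
#'   intergenic) for condition-specific peak placement.
#' @param n_blacklist Random blacklist intervals per genome.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chrom = 2L,
                              chrom_length = 2e7,
                              matrix_bin = 1e4,
                              signal_bin = 2e4,
                              n_genes = 400L,
                              n_constitutive_peaks = 800L,
                              n_condition_specific_peaks = 150L,
                              n_hubs = 40L,
                              hub_partner_range = c(8L, 25L),
                              nonhub_partner_range = c(0L, 3L),
                              nonhub_partner_weights = c(0.5, 0.25, 0.15, 0.1),
                              loop_distance_range = c(5e4, 2e6),
                              pet_mean = 30,
                              pet_dispersion = 0.2,
                              delta_logfc = 0.3,
                              speckle_gain = 3,
                              loop_pixel_enrichment = 3,
                              n_replicates = 2L,
                              n_decoy_loops = 100L,
                              archetype_noise_sd = 0.3,
                              archetype_sizes = c(33L, 48L, 6L, 54L),
                              specific_baseline_strength = 0.4,
                              speckle_strength_beta = 1,
                              matrix_noise_sd = 0.2,
                              n_speckle_centers = 30L,
                              speckle_bump_amplitude = 4,
                              speckle_bump_width = 2,
                              baseline_meanlog = 0,
                              baseline_sdlog = 0.5,
                              peak_width = 400L,
                              anchor_pad = 2500L,
                              min_peak_spacing = 1e4,
                              specific_placement = c(nonintronic = 0.5,
                                                     intronic = 0.3,
                                                     intergenic = 0.2),
                              n_blacklist = 5L) {
  cfg <- as.list(environment())
  counts <- c("n_chrom", "n_genes", "n_constitutive_peaks",
              "n_condition_specific_peaks", "n_replicates")
  for (f in counts) if (cfg[[f]] < 1) stop("'", f, "' must be positive")
  for (f in c("n_hubs", "n_decoy_loops", "n_blacklist"))
    if (cfg[[f]] < 0) stop("'", f, "' must be >= 0")
  for (f in c("hub_partner_range", "nonhub_partner_range", "loop_distance_range"))
    if (length(cfg[[f]]) != 2 || cfg[[f]][1] > cfg[[f]][2])
      stop("'", f, "' must be an ordered range")
  if (length(cfg$nonhub_partner_weights) !=
      diff(cfg$nonhub_partner_range) + 1)
    stop("'nonhub_partner_weights' must match nonhub_partner_range")
  if (length(cfg$archetype_sizes) != 4) stop("'archetype_sizes' must have 4 classes")
  if (sum(cfg$archetype_sizes) > cfg$n_genes)
    stop("archetype_sizes exceed n_genes")
  if (abs(sum(cfg$specific_placement) - 1) > 1e-8)
    stop("'specific_placement' fractions must sum to 1")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config> seed=", x$seed, ", ", x$n_chrom, " x ",
      format(x$chrom_length, big.mark = ","), " bp, ",
      x$n_constitutive_peaks + x$n_hubs + x$n_condition_specific_peaks,
      " peaks, delta_logfc=", x$delta_logfc, "\n", sep = "")
  invisible(x)
}

## Documented stream split: one deterministic sub-seed per component so a
## component can be regenerated without replaying the others.
component_seed <- function(config, component) {
  offset <- match(component, c("track", "genes", "peaks", "matrix",
                               "expression", "blacklist"))
  if (is.na(offset)) stop("unknown component: ", component)
  as.integer((as.numeric(config$seed) * 1009 + offset * 101) %% 2147483647)
}

#' Genome implied by a simulation config
#'
#' @param config A [simulation_config()].
#' @return A [genome()] with chromosomes `chr1..chrN`.
#' @export
simulate_genome <- function(config) {
  genome(stats::setNames(rep(config$chrom_length, config$n_chrom),
                         paste0("chr", seq_len(config$n_chrom))))
}

#' Simulate the speckle (SON Cut&Tag-like) signal tracks
#'
#' Lognormal baseline plus Gaussian bumps at randomly placed speckle-center
#' bins.  The treated-condition track is the baseline track multiplied by
#' `speckle_gain` over bins containing condition-specific peaks (pass the
#' specific peak set once it exists; with `specific_peaks = NULL` the two
#' condition tracks are identical).
#'
#' @param config A [simulation_config()].
#' @param specific_peaks Optional interval table of condition-specific peaks.
#' @return List with per-condition tracks `dmso` and `dnmt1i` (class
#'   [signal_track()]) and `centers` (data.frame of speckle-center bins).
#' @export
simulate_speckle_tracks <- function(config, specific_peaks = NULL) {
  g <- simulate_genome(config)
  bs <- config$signal_bin
  set.seed(component_seed(config, "track"))
  values <- list(); centers <- list()
  for (ch in names(g)) {
    nb <- ceiling(unclass(g)[[ch]] / bs)
    v <- stats::rlnorm(nb, config$baseline_meanlog, config$baseline_sdlog)
    ctr <- sort(sample.int(nb, config$n_speckle_centers))
    w <- config$speckle_bump_width
    if (config$speckle_bump_amplitude > 0) {
      for (b in ctr) {
        span <- max(1, b - 3 * w):min(nb, b + 3 * w)
        v[span] <- v[span] +
          config$speckle_bump_amplitude * exp(-((span - b)^2) / (2 * w^2))
      }
    }
    values[[ch]] <- v
    centers[[ch]] <- data.frame(chrom = ch, bin = ctr,
                                start = (ctr - 1) * bs, end = pmin(ctr * bs, unclass(g)[[ch]]),
                                stringsAsFactors = FALSE)
  }
  missing <- lapply(values, function(v) rep(FALSE, length(v)))
  dmso <- signal_track(g, bs, values, missing)
  dnmt1i <- dmso
  if (!is.null(specific_peaks) && nrow(specific_peaks) > 0 &&
      config$speckle_gain != 1) {
    for (i in seq_len(nrow(specific_peaks))) {
      ch <- specific_peaks$chrom[i]
      b0 <- floor(specific_peaks$start[i] / bs) + 1
      b1 <- floor((specific_peaks$end[i] - 1) / bs) + 1
      dnmt1i$values[[ch]][b0:b1] <- dnmt1i$values[[ch]][b0:b1] * config$speckle_gain
    }
  }
  list(dmso = dmso, dnmt1i = dnmt1i,
       centers = do.call(rbind, c(centers, list(make.row.names = FALSE))))
}

#' Simulate a gene model with expression archetypes
#'
#' Genes are placed in non-overlapping slots with 3-7 exons each.  The
#' differential genes are pre-assigned to the four expression archetypes;
#' archetype-2 genes (the treatment-upregulated, perturbation-dependent
#' class) are the genes with the highest speckle signal, planting the
#' speckle-proximal covariate the cluster annotation stage must recover.
#'
#' @param config A [simulation_config()].
#' @param track Baseline [signal_track()] (for archetype placement).
#' @return List: `model` (a [gene_model()]) and `archetype` (named integer
#'   vector per gene; 0 = non-differential).
#' @export
simulate_genes <- function(config, track) {
  g <- simulate_genome(config)
  set.seed(component_seed(config, "genes"))
  per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chrom + 1)))
  genes <- list(); exons <- list()
  k <- 0
  for (ci in seq_along(per_chrom)) {
    ch <- names(g)[ci]
    n <- per_chrom[ci]
    if (n == 0) next
    slot <- floor(unclass(g)[[ch]] / n)
    gene_len <- round(exp(stats::runif(n, log(5e3), log(min(8e4, slot * 0.8)))))
    slot_off <- floor(stats::runif(n, 0, slot - gene_len - 1))
    start <- (seq_len(n) - 1) * slot + slot_off
    for (j in seq_len(n)) {
      k <- k + 1
      gid <- sprintf("gene_%04d", k)
      s <- start[j]; e <- s + gene_len[j]
      n_ex <- sample(3:7, 1)
      cuts <- sort(stats::runif(2 * n_ex - 2, s + 50, e - 50))
      bounds <- round(c(s, cuts, e))
      ex_s <- bounds[seq(1, length(bounds), by = 2)]
      ex_e <- bounds[seq(2, length(bounds), by = 2)]
      ok <- ex_e > ex_s
      genes[[k]] <- data.frame(chrom = ch, start = s, end = e,
                               name = gid, score = 0,
                               strand = sample(c("+", "-"), 1),
                               gene_id = gid, stringsAsFactors = FALSE)
      exons[[k]] <- data.frame(chrom = ch, start = ex_s[ok], end = ex_e[ok],
                               gene_id = gid, stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)
  model <- gene_model(genes, exons)

  sizes <- config$archetype_sizes
  sig <- map_binned_signal(track, genes)
  archetype <- stats::setNames(rep(0L, nrow(genes)), genes$gene_id)
  ord <- order(sig, decreasing = TRUE)
  arch2 <- ord[seq_len(sizes[2])]          # speckle-proximal class
  archetype[arch2] <- 2L
  rest <- sample(setdiff(seq_len(nrow(genes)), arch2))
  archetype[rest[seq_len(sizes[1])]] <- 1L
  archetype[rest[sizes[1] + seq_len(sizes[3])]] <- 3L
  archetype[rest[sizes[1] + sizes[3] + seq_len(sizes[4])]] <- 4L
  list(model = model, archetype = archetype)
}

## Sample positions on a genome respecting a minimum midpoint spacing.
## `existing` is a numeric vector of taken midpoints per chromosome.
place_with_spacing <- function(pos_fun, n, taken, spacing, max_tries = 200) {
  out <- numeric(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      p <- pos_fun(t)
      if (length(taken[[p$chrom]]) == 0 ||
          min(abs(taken[[p$chrom]] - p$pos)) >= spacing) {
        taken[[p$chrom]] <- c(taken[[p$chrom]], p$pos)
        out <- rbind(out, data.frame(chrom = p$chrom, pos = p$pos,
                                     stringsAsFactors = FALSE))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("infeasible placement: could not honour min_peak_spacing ",
                  "after ", max_tries, " tries (too many peaks for genome)")
  }
  list(placed = as.data.frame(out), taken = taken)
}

#' Simulate peak sets and the loop list
#'
#' Places hubs preferentially in top-decile speckle bins, condition-specific
#' peaks on gene bodies (default 50% non-intronic / 30% intronic / 20%
#' intergenic, biased toward archetype-2 genes), and constitutive peaks
#' uniformly, all with a minimum spacing so anchors stay peak-exclusive.
#' Loops are wired degree-sequence style: hubs draw their sampled partner
#' count from peaks with free capacity (inverse-distance weighted within
#' `loop_distance_range`), condition-specific peaks loop half the time to a
#' hub, and leftover non-hub capacity is paired up.  Per-sample PET counts
#' are negative binomial around planted loop strength; loops anchored at
#' condition-specific peaks carry `specific_baseline_strength` at baseline
#' and gain `2^delta_logfc` in treated samples.  Decoy loops get high FDR
#' and low PETs.
#'
#' @param config A [simulation_config()].
#' @param track Baseline [signal_track()].
#' @param genes Result of [simulate_genes()].
#' @return List: `peaks` (one table, with per-condition called flags and
#'   signal), `loops` (BEDPE-convention table), `truth` (truth tables).
#' @export
simulate_peaks_and_loops <- function(config, track, genes) {
  g <- simulate_genome(config)
  glen <- unclass(g)
  set.seed(component_seed(config, "peaks"))
  bs <- config$signal_bin
  half <- config$peak_width / 2
  model <- genes$model
  taken <- stats::setNames(rep(list(numeric(0)), length(g)), names(g))

  ## -- hubs at high-signal bins (>= 90th percentile of the genome-wide track)
  thr <- stats::quantile(track_values(track), 0.9, type = 7, names = FALSE)
  hub_pos <- NULL
  if (config$n_hubs > 0) {
    cand <- do.call(rbind, lapply(names(g), function(ch) {
      b <- which(track$values[[ch]] >= thr)
      data.frame(chrom = ch, pos = (b - 0.5) * bs, stringsAsFactors = FALSE)
    }))
    if (nrow(cand) < config$n_hubs) stop("infeasible placement: too few high-signal bins")
    pick <- sample.int(nrow(cand))
    i <- 0
    res <- list(placed = NULL, taken = taken)
    sel <- list()
    for (p in pick) {
      if (length(sel) == config$n_hubs) break
      pc <- cand$chrom[p]; pp <- cand$pos[p]
      if (length(res$taken[[pc]]) == 0 ||
          min(abs(res$taken[[pc]] - pp)) >= config$min_peak_spacing) {
        res$taken[[pc]] <- c(res$taken[[pc]], pp)
        sel[[length(sel) + 1]] <- cand[p, ]
      }
    }
    if (length(sel) < config$n_hubs)
      stop("infeasible placement: too few spaced high-signal bins for hubs")
    hub_pos <- do.call(rbind, sel)
    taken <- res$taken
  }

  ## -- condition-specific peaks on gene bodies / intergenic space
  n_spec <- config$n_condition_specific_peaks
  classes <- sample(rep(names(config$specific_placement),
                        times = round(config$specific_placement * n_spec))[seq_len(n_spec)])
  arch2_genes <- names(genes$archetype)[genes$archetype == 2L]
  gene_body <- which(classes != "intergenic")
  ## every archetype-2 gene hosts at least one gene-body specific peak
  host <- rep(NA_character_, n_spec)
  n_seed <- min(length(arch2_genes), length(gene_body))
  host[gene_body[seq_len(n_seed)]] <- arch2_genes[seq_len(n_seed)]
  spec_rows <- list()
  for (i in seq_len(n_spec)) {
    cls <- classes[i]
    pos_fun <- function(try = 1) {
      if (cls == "intergenic") {
        ch <- sample(names(g), 1)
        return(list(chrom = ch, pos = round(stats::runif(1, 1e4, glen[[ch]] - 1e4))))
      }
      ## fall back to a random gene when the seeded host is saturated
      gid <- if (!is.na(host[i]) && try <= 40) host[i]
             else sample(model$genes$gene_id, 1)
      gi <- match(gid, model$genes$gene_id)
      ex <- model$exons[model$exons$gene_id == gid, , drop = FALSE]
      if (cls == "nonintronic") {
        j <- sample.int(nrow(ex), 1)
        p <- round(stats::runif(1, ex$start[j] + half, max(ex$start[j] + half + 1, ex$end[j] - half)))
      } else {
        ## intron: a point in the gene not in any exon
        for (t in 1:50) {
          p <- round(stats::runif(1, model$genes$start[gi] + half,
                                  model$genes$end[gi] - half))
          inside <- any(p >= ex$start & p < ex$end)
          if (!inside) break
        }
      }
      list(chrom = model$genes$chrom[gi], pos = p)
    }
    res <- place_with_spacing(pos_fun, 1, taken, config$min_peak_spacing)
    taken <- res$taken
    spec_rows[[i]] <- data.frame(chrom = res$placed$chrom, pos = res$placed$pos,
                                 class = cls, stringsAsFactors = FALSE)
  }
  spec_pos <- do.call(rbind, spec_rows)

  ## -- constitutive peaks, uniform
  pos_fun <- function(try = 1) {
    ch <- sample(names(g), 1)
    list(chrom = ch, pos = round(stats::runif(1, 1e4, glen[[ch]] - 1e4)))
  }
  res <- place_with_spacing(pos_fun, config$n_constitutive_peaks, taken,
                            config$min_peak_spacing)
  const_pos <- res$placed

  ## -- assemble the peak table
  mk <- function(pos, kind) {
    if (is.null(pos) || nrow(pos) == 0) return(NULL)
    n <- nrow(pos)
    data.frame(chrom = pos$chrom, start = pos$pos - half, end = pos$pos + half,
               kind = kind, stringsAsFactors = FALSE)
  }
  peaks <- rbind(mk(hub_pos, "hub"), mk(spec_pos[1:2], "specific"),
                 mk(const_pos, "constitutive"))
  n_pk <- nrow(peaks)
  peaks$name <- sprintf("peak_%04d", seq_len(n_pk))
  peaks$strand <- sample(c("+", "-"), n_pk, replace = TRUE)
  is_spec <- peaks$kind == "specific"
  peaks$signal_dmso <- ifelse(is_spec, stats::rlnorm(n_pk, log(1), 0.3),
                              stats::rlnorm(n_pk, log(10), 0.3))
  peaks$signal_dnmt1i <- stats::rlnorm(n_pk, log(10), 0.3)
  peaks$called_dmso <- !is_spec
  peaks$called_dnmt1i <- TRUE
  peaks$score <- peaks$signal_dnmt1i
  peaks$placement <- NA_character_
  peaks$placement[is_spec] <- spec_pos$class

  ## -- degree sequence
  deg <- integer(n_pk)
  hubs <- which(peaks$kind == "hub")
  nonhubs <- which(peaks$kind != "hub")
  deg[hubs] <- sample(seq(config$hub_partner_range[1], config$hub_partner_range[2]),
                      length(hubs), replace = TRUE)
  deg[nonhubs] <- sample(seq(config$nonhub_partner_range[1], config$nonhub_partner_range[2]),
                         length(nonhubs), replace = TRUE,
                         prob = config$nonhub_partner_weights)

  mid <- (peaks$start + peaks$end) / 2
  free <- deg
  adj <- vector("list", n_pk)
  edges <- list()
  dmin <- config$loop_distance_range[1]; dmax <- config$loop_distance_range[2]
  candidates <- function(i, need_capacity = TRUE, hubs_only = FALSE) {
    j <- if (hubs_only) hubs else seq_len(n_pk)
    j <- j[peaks$chrom[j] == peaks$chrom[i] & j != i]
    d <- abs(mid[j] - mid[i])
    j <- j[d >= dmin & d <= dmax]
    if (need_capacity) j <- j[free[j] > 0]
    setdiff(j, adj[[i]])
  }
  add_edge <- function(i, j) {
    edges[[length(edges) + 1]] <<- c(min(i, j), max(i, j))
    adj[[i]] <<- c(adj[[i]], j); adj[[j]] <<- c(adj[[j]], i)
    free[i] <<- free[i] - 1L; free[j] <<- free[j] - 1L
  }
  ## hubs first: realize their sampled degree exactly where feasible
  for (i in hubs[sample.int(length(hubs))]) {
    while (free[i] > 0) {
      cand <- candidates(i)
      if (length(cand) == 0) cand <- candidates(i, need_capacity = FALSE)
      if (length(cand) == 0) break
      j <- cand[sample.int(length(cand), 1, prob = 1 / abs(mid[cand] - mid[i]))]
      add_edge(i, j)
    }
  }
  ## condition-specific peaks loop to hubs half the time (planted
  ## specific -> highly-looping partnership); hub capacity is allowed to
  ## overflow here, which only raises hub counts.
  spec_idx <- which(is_spec)
  for (i in spec_idx[sample.int(length(spec_idx))]) {
    while (free[i] > 0) {
      cand <- if (stats::runif(1) < 0.5) candidates(i, FALSE, hubs_only = TRUE)
              else candidates(i)
      if (length(cand) == 0) cand <- candidates(i)
      if (length(cand) == 0) break
      j <- cand[sample.int(length(cand), 1, prob = 1 / abs(mid[cand] - mid[i]))]
      add_edge(i, j)
    }
  }
  ## pair up leftover non-hub capacity
  for (i in nonhubs[sample.int(length(nonhubs))]) {
    while (free[i] > 0) {
      cand <- candidates(i)
      if (length(cand) == 0) break
      j <- cand[sample.int(length(cand), 1, prob = 1 / abs(mid[cand] - mid[i]))]
      add_edge(i, j)
    }
  }

  edges <- unique(do.call(rbind, edges))
  realized <- tabulate(c(edges[, 1], edges[, 2]), nbins = n_pk)

  ## -- loop table with planted strengths and PET counts
  n_loop <- nrow(edges)
  a1 <- edges[, 1]; a2 <- edges[, 2]
  spec_anchor <- is_spec[a1] | is_spec[a2]
  anchors <- function(i) {
    s <- pmax(0, peaks$start[i] - config$anchor_pad)
    e <- pmin(glen[peaks$chrom[i]], peaks$end[i] + config$anchor_pad)
    data.frame(chrom = peaks$chrom[i], start = s, end = e, stringsAsFactors = FALSE)
  }
  A1 <- anchors(a1); A2 <- anchors(a2)
  anchor_sig <- (map_binned_signal(track, A1) + map_binned_signal(track, A2)) / 2
  zsig <- as.numeric(scale(anchor_sig))
  zsig[!is.finite(zsig)] <- 0
  strength <- stats::rlnorm(n_loop, 0, 0.25) *
    exp(config$speckle_strength_beta * tanh(zsig)) *
    ifelse(spec_anchor, config$specific_baseline_strength, 1)

  conds <- c("dmso", "dnmt1i")
  size <- 1 / config$pet_dispersion
  pet <- list()
  for (cond in conds) for (r in seq_len(config$n_replicates)) {
    boost <- if (cond == "dnmt1i") 2^(config$delta_logfc / 2)
             else 2^(-config$delta_logfc / 2)
    mu <- config$pet_mean * strength * ifelse(spec_anchor, boost, 1)
    pet[[sprintf("pet_%s_r%d", cond, r)]] <- stats::rnbinom(n_loop, mu = mu, size = size)
  }
  loops <- data.frame(chrom1 = A1$chrom, start1 = A1$start, end1 = A1$end,
                      chrom2 = A2$chrom, start2 = A2$start, end2 = A2$end,
                      name = sprintf("loop_%05d", seq_len(n_loop)),
                      score = round(strength, 4),
                      strand1 = peaks$strand[a1], strand2 = peaks$strand[a2],
                      stringsAsFactors = FALSE)
  for (nm in names(pet)) loops[[nm]] <- pet[[nm]]
  loops$fdr <- stats::runif(n_loop, 0, 0.005)

  ## -- decoys: weak, high-FDR loop calls
  if (config$n_decoy_loops > 0) {
    dec <- list()
    while (length(dec) < config$n_decoy_loops) {
      i <- sample.int(n_pk, 1)
      cand <- candidates(i, need_capacity = FALSE)
      if (length(cand) == 0) next
      j <- cand[sample.int(length(cand), 1)]
      dec[[length(dec) + 1]] <- c(min(i, j), max(i, j))
    }
    dec <- do.call(rbind, dec)
    D1 <- anchors(dec[, 1]); D2 <- anchors(dec[, 2])
    nd <- nrow(dec)
    dl <- data.frame(chrom1 = D1$chrom, start1 = D1$start, end1 = D1$end,
                     chrom2 = D2$chrom, start2 = D2$start, end2 = D2$end,
                     name = sprintf("decoy_%05d", seq_len(nd)),
                     score = 0,
                     strand1 = peaks$strand[dec[, 1]], strand2 = peaks$strand[dec[, 2]],
                     stringsAsFactors = FALSE)
    for (nm in names(pet)) dl[[nm]] <- stats::rnbinom(nd, mu = 2, size = size)
    dl$fdr <- stats::runif(nd, 0.05, 1)
    loops <- rbind(loops, dl)
  }
  loops <- canonicalize_loops(loops, g, source = "simulated loops")

  truth <- list(
    hub_peaks = peaks$name[peaks$kind == "hub"],
    specific_peaks = peaks$name[is_spec],
    specific_placement = stats::setNames(peaks$placement[is_spec], peaks$name[is_spec]),
    strengthened_loops = if (config$delta_logfc != 0)
      loops$name[grepl("^loop_", loops$name)][spec_anchor] else character(0),
    partner_counts = stats::setNames(realized, peaks$name),
    true_loops = loops$name[grepl("^loop_", loops$name)]
  )
  peaks_out <- peaks[c("chrom", "start", "end", "name", "score", "strand",
                       "kind", "placement", "called_dmso", "called_dnmt1i",
                       "signal_dmso", "signal_dnmt1i")]
  list(peaks = peaks_out, loops = loops, truth = truth)
}

#' Simulate per-chromosome contact matrices
#'
#' Expected decay `c(s) = (1 + s)^-1` in bins, multiplicative enrichment
#' `loop_pixel_enrichment` at each true loop's anchor-pair pixel (half effect
#' over the 1-pixel neighbourhood), mean-one multiplicative lognormal noise,
#' diagonal set to missing.
#'
#' @param config A [simulation_config()].
#' @param loops Loop table (decoys, recognisable by name, are skipped).
#' @return Named list of [contact_matrix()] per chromosome.
#' @export
simulate_contact_matrix <- function(config, loops) {
  g <- simulate_genome(config)
  set.seed(component_seed(config, "matrix"))
  bs <- config$matrix_bin
  e <- config$loop_pixel_enrichment
  true <- loops[grepl("^loop_", loops$name), , drop = FALSE]
  out <- list()
  for (ch in names(g)) {
    n <- as.integer(ceiling(unclass(g)[[ch]] / bs))
    idx <- seq_len(n)
    d <- abs(outer(idx, idx, "-"))
    mat <- 1 / (1 + d)
    lch <- true[true$chrom1 == ch, , drop = FALSE]
    if (nrow(lch) > 0 && e != 1) {
      bi <- floor((lch$start1 + lch$end1) / 2 / bs) + 1
      bj <- floor((lch$start2 + lch$end2) / 2 / bs) + 1
      enr <- matrix(1, n, n)
      for (k in seq_along(bi)) {
        i <- bi[k]; j <- bj[k]
        ni <- max(1, i - 1):min(n, i + 1); nj <- max(1, j - 1):min(n, j + 1)
        enr[ni, nj] <- pmax(enr[ni, nj], 1 + (e - 1) / 2)
        enr[nj, ni] <- pmax(enr[nj, ni], 1 + (e - 1) / 2)
        enr[i, j] <- max(enr[i, j], e)
        enr[j, i] <- max(enr[j, i], e)
      }
      mat <- mat * enr
    }
    if (config$matrix_noise_sd > 0) {
      sdl <- config$matrix_noise_sd
      noise <- matrix(1, n, n)
      up <- upper.tri(noise, diag = TRUE)
      noise[up] <- stats::rlnorm(sum(up), -sdl^2 / 2, sdl)
      noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
      mat <- mat * noise
    }
    diag(mat) <- NA_real_
    out[[ch]] <- contact_matrix(ch, bs, mat)
  }
  out
}

#' Simulate the expression table
#'
#' Genes carry 2 conditions x 2 perturbation arms x `n_replicates` rlog-like
#' abundance columns.  The four archetype mean patterns (on top of a random
#' per-gene baseline) are, in condition/arm order (dmso_wt, dnmt1i_wt,
#' dmso_deg, dnmt1i_deg): archetype 1 up under treatment and up under
#' perturbation alone; archetype 2 up under treatment only when unperturbed
#' (the CTCF-dependent class); archetype 3 down under treatment; archetype 4
#' up under treatment regardless.  Differential statistics (log2FC, adjusted
#' p for the dnmt1i_wt vs dmso_wt contrast) are written consistently with
#' the planted classes.
#'
#' @param config A [simulation_config()].
#' @param genes Result of [simulate_genes()].
#' @return `data.frame` with gene coordinates, expression columns
#'   `expr_<cond>_<arm>_r<k>`, `log2fc` and `padj`.
#' @export
simulate_expression <- function(config, genes) {
  set.seed(component_seed(config, "expression"))
  model <- genes$model
  arch <- genes$archetype[model$genes$gene_id]
  n <- nrow(model$genes)
  ## unit patterns scaled by the archetype effect size.  1.25 is implied by
  ## the stated world: at noise sd 0.3 with two replicates, adjacent
  ## archetypes (differing in a single condition/arm slot) must stay
  ## separable at >= 0.9 adjusted Rand, which needs a slot step of ~4 sd.
  eff <- 1.25
  patterns <- eff * rbind(`0` = c(0, 0, 0, 0),
                          `1` = c(0, 1, 1, 1),
                          `2` = c(0, 1, 0, 0),
                          `3` = c(0, -1, 0, -1),
                          `4` = c(0, 1, 0, 1))
  cols <- expand.grid(rep = seq_len(config$n_replicates),
                      arm = c("wt", "deg"), cond = c("dmso", "dnmt1i"),
                      stringsAsFactors = FALSE)
  cols$slot <- match(paste(cols$cond, cols$arm), c("dmso wt", "dnmt1i wt",
                                                   "dmso deg", "dnmt1i deg"))
  base <- stats::runif(n, 4, 10)
  out <- model$genes[c("chrom", "start", "end", "strand", "gene_id")]
  for (i in seq_len(nrow(cols))) {
    mu <- base + patterns[as.character(arch), cols$slot[i]]
    nm <- sprintf("expr_%s_%s_r%d", cols$cond[i], cols$arm[i], cols$rep[i])
    out[[nm]] <- round(mu + stats::rnorm(n, 0, config$archetype_noise_sd), 6)
  }
  diff <- arch != 0
  lfc <- patterns[as.character(arch), 2] - patterns[as.character(arch), 1]
  out$log2fc <- round(ifelse(diff, lfc + stats::rnorm(n, 0, 0.05),
                             stats::rnorm(n, 0, 0.1)), 6)
  out$padj <- round(ifelse(diff, stats::runif(n, 0, 0.01),
                           stats::runif(n, 0.1, 1)), 8)
  out
}

## Random blacklist intervals (exercise the pileup exclusion path).
simulate_blacklist <- function(config) {
  g <- simulate_genome(config)
  set.seed(component_seed(config, "blacklist"))
  if (config$n_blacklist == 0)
    return(gintervals(character(0), numeric(0), numeric(0)))
  ch <- sample(names(g), config$n_blacklist, replace = TRUE)
  len <- round(stats::runif(config$n_blacklist, 2e4, 6e4))
  s <- floor(stats::runif(config$n_blacklist, 0, unclass(g)[ch] - len))
  gintervals(ch, s, s + len, name = sprintf("blacklist_%d", seq_len(config$n_blacklist)))
}

#' Generate a full synthetic dataset
#'
#' Runs all generators in their documented order (track, genes, peaks and
#' loops, treated track, matrix, expression, blacklist) and optionally
#' writes every on-disk artifact: `peaks_<cond>_r<k>.bed`, `loops.bedpe`,
#' `son_<cond>.bedgraph`, `matrix_<chrom>.txt.gz`, `genes.gff3`,
#' `expression.tsv`, `blacklist.bed`, `subcompartments.bed`, `truth.json`.
#'
#' @param config A [simulation_config()].
#' @param outdir Optional output directory.
#' @param components Character subset of
#'   `c("matrix", "expression")` to optionally skip heavy stages; the core
#'   track/genes/peaks/loops stages always run.
#' @return List with all in-memory objects plus `truth`.
#' @export
simulate_all <- function(config, outdir = NULL,
                         components = c("matrix", "expression")) {
  g <- simulate_genome(config)
  tr0 <- simulate_speckle_tracks(config)
  genes <- simulate_genes(config, tr0$dmso)
  pl <- simulate_peaks_and_loops(config, tr0$dmso, genes)
  spec <- pl$peaks[pl$peaks$name %in% pl$truth$specific_peaks, , drop = FALSE]
  tracks <- simulate_speckle_tracks(config, specific_peaks = spec)
  matrices <- if ("matrix" %in% components)
    simulate_contact_matrix(config, pl$loops) else NULL
  expression <- if ("expression" %in% components)
    simulate_expression(config, genes) else NULL
  blacklist <- simulate_blacklist(config)
  truth <- c(pl$truth, list(
    speckle_centers = tracks$centers,
    gene_archetype = genes$archetype,
    blacklist = blacklist$name))
  sim <- list(config = config, genome = g, tracks = tracks[c("dmso", "dnmt1i")],
              genes = genes$model, peaks = pl$peaks, loops = pl$loops,
              matrices = matrices, expression = expression,
              blacklist = blacklist, truth = truth)
  if (!is.null(outdir)) write_simulation(sim, outdir)
  sim
}

## Derived subcompartment-style labels: top signal quintile A1, next A2,
## rest B (a synthetic stand-in used only to exercise the covariate path).
subcompartment_bed <- function(track) {
  qs <- stats::quantile(track_values(track), c(0.8, 0.6), type = 7, names = FALSE)
  g <- unclass(track$genome); bs <- track$bin_size
  do.call(rbind, lapply(names(g), function(ch) {
    v <- track$values[[ch]]
    lab <- ifelse(v >= qs[1], "A1", ifelse(v >= qs[2], "A2", "B"))
    b <- seq_along(v)
    data.frame(chrom = ch, start = (b - 1) * bs, end = pmin(b * bs, g[[ch]]),
               name = lab, score = 0, strand = ".", stringsAsFactors = FALSE)
  }))
}

#' Write a simulated dataset to disk
#'
#' @param sim Result of [simulate_all()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$config
  for (cond in c("dmso", "dnmt1i")) {
    called <- sim$peaks[sim$peaks[[paste0("called_", cond)]], , drop = FALSE]
    for (r in seq_len(cfg$n_replicates)) {
      pk <- called
      pk$score <- round(called[[paste0("signal_", cond)]] *
                          stats::rlnorm(nrow(called), 0, 0.05), 4)
      write_bed(pk, file.path(outdir, sprintf("peaks_%s_r%d.bed", cond, r)))
    }
    write_bedgraph(sim$tracks[[cond]], file.path(outdir, sprintf("son_%s.bedgraph", cond)))
  }
  write_bedpe(sim$loops, file.path(outdir, "loops.bedpe"))
  write_gff3(sim$genes, file.path(outdir, "genes.gff3"))
  if (!is.null(sim$expression))
    utils::write.table(sim$expression, file.path(outdir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$matrices))
    for (ch in names(sim$matrices))
      write_matrix(sim$matrices[[ch]], file.path(outdir, sprintf("matrix_%s.txt.gz", ch)))
  write_bed(sim$blacklist, file.path(outdir, "blacklist.bed"))
  write_bed(subcompartment_bed(sim$tracks$dmso), file.path(outdir, "subcompartments.bed"))
  truth <- sim$truth
  truth$speckle_centers <- as.list(truth$speckle_centers)
  truth$gene_archetype <- as.list(truth$gene_archetype)
  truth$specific_placement <- as.list(truth$specific_placement)
  truth$partner_counts <- as.list(truth$partner_counts)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"), auto_unbox = TRUE)
  invisible(outdir)
}
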