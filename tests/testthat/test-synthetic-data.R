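test_that("config validates and seeds split per component", {
  expect_error(simulation_config(n_genes = 0), "positive")
  expect_error(simulation_config(hub_partner_range = c(5, 2)), "ordered range")
  expect_error(simulation_config(archetype_sizes = c(10L, 10L, 10L, 500L)),
               "exceed n_genes")
  cfg <- simulation_config(seed = 9)
  s <- vapply(c("track", "genes", "peaks", "matrix", "expression", "blacklist"),
              function(k) loophub:::component_seed(cfg, k), 1L)
  expect_false(anyDuplicated(s) > 0)
})

test_that("speckle tracks: gain, bumps and baseline moments", {
  cfg <- simulation_config(seed = 2, n_chrom = 1, chrom_length = 4e7,
                           speckle_gain = 1)
  tr <- simulate_speckle_tracks(cfg)
  expect_equal(tr$dmso, tr$dnmt1i)          # no planted effect
  ## bump amplitude 0: pure lognormal baseline, mean within 3 SE
  cfg0 <- simulation_config(seed = 2, n_chrom = 1, chrom_length = 4e7,
                            speckle_bump_amplitude = 0)
  v <- track_values(simulate_speckle_tracks(cfg0)$dmso)
  mu <- exp(cfg0$baseline_meanlog + cfg0$baseline_sdlog^2 / 2)
  sdv <- sqrt((exp(cfg0$baseline_sdlog^2) - 1)) * mu
  expect_lt(abs(mean(v) - mu), 3 * sdv / sqrt(length(v)))
  expect_lt(abs(stats::sd(v) - sdv), 0.2 * sdv)
  ## default: speckle-center bins exceed the genome median
  cfg1 <- simulation_config(seed = 2)
  tr1 <- simulate_speckle_tracks(cfg1)
  med <- stats::median(track_values(tr1$dmso))
  ctr <- tr1$centers
  at_ctr <- mapply(function(ch, b) tr1$dmso$values[[ch]][b], ctr$chrom, ctr$bin)
  expect_true(all(at_ctr > med))
  ## treated track gains speckle_gain over bins containing specific peaks
  spec <- mk_peaks("chr1", 100100, 100500)
  tr2 <- simulate_speckle_tracks(cfg1, specific_peaks = spec)
  expect_equal(tr2$dnmt1i$values$chr1[6], tr2$dmso$values$chr1[6] * cfg1$speckle_gain)
  expect_equal(tr2$dnmt1i$values$chr1[7], tr2$dmso$values$chr1[7])
})

test_that("peak and loop generator plants the advertised structure", {
  sim <- cached_sim(1)
  cfg <- sim$config
  peaks <- sim$peaks; loops <- sim$loops; truth <- sim$truth
  ## condition-specific peaks only called in the treated condition
  spec <- peaks$name %in% truth$specific_peaks
  expect_true(all(!peaks$called_dmso[spec]))
  expect_true(all(peaks$called_dnmt1i[spec]))
  expect_true(all(peaks$called_dmso[!spec]))
  ## all intervals in bounds, loops intra-chromosomal, distances in range
  validate_intervals(peaks, sim$genome)
  expect_true(all(loops$chrom1 == loops$chrom2))
  mid1 <- (loops$start1 + loops$end1) / 2
  mid2 <- (loops$start2 + loops$end2) / 2
  expect_true(all(mid2 - mid1 >= cfg$loop_distance_range[1] - 1))
  expect_true(all(mid2 - mid1 <= cfg$loop_distance_range[2] + 1))
  ## planted partner counts equal brute-force recounts from the loop table
  true_loops <- loops[grepl("^loop_", loops$name), ]
  recount <- count_distinct_loops(peaks, true_loops)
  expect_equal(recount$n_distinct_loops,
               unname(truth$partner_counts[recount$name]))
  ## hubs reach their range; non-hubs stay at or near theirs (a hub whose
  ## window runs out of free capacity may wire a few extra edges)
  hub <- peaks$name %in% truth$hub_peaks
  expect_true(all(truth$partner_counts[peaks$name[hub]] >= cfg$hub_partner_range[1]))
  nonhub_counts <- truth$partner_counts[peaks$name[!hub]]
  expect_gte(mean(nonhub_counts <= cfg$nonhub_partner_range[2]), 0.97)
  expect_lt(max(nonhub_counts), cfg$hub_partner_range[1])
  ## decoys: high FDR, true loops: low FDR
  expect_true(all(loops$fdr[grepl("^decoy_", loops$name)] >= 0.05))
  expect_true(all(true_loops$fdr < 0.005))
})

test_that("degenerate generator settings behave as stated", {
  base <- list(seed = 4, n_chrom = 1, chrom_length = 8e6, n_genes = 60,
               n_constitutive_peaks = 120, n_condition_specific_peaks = 20,
               archetype_sizes = c(5L, 8L, 2L, 6L), n_decoy_loops = 10)
  ## n_hubs = 0: no heavy tail beyond the non-hub range
  cfg <- do.call(simulation_config, c(base, list(n_hubs = 0)))
  tr <- simulate_speckle_tracks(cfg)
  gn <- simulate_genes(cfg, tr$dmso)
  pl <- simulate_peaks_and_loops(cfg, tr$dmso, gn)
  expect_lte(max(pl$truth$partner_counts), cfg$nonhub_partner_range[2])
  ## delta = 0: planted strengthened set empty
  cfg0 <- do.call(simulation_config, c(base, list(n_hubs = 6, delta_logfc = 0)))
  pl0 <- simulate_peaks_and_loops(cfg0, tr$dmso, simulate_genes(cfg0, tr$dmso))
  expect_length(pl0$truth$strengthened_loops, 0)
})

test_that("contact matrix: decay law, symmetry and planted pixels", {
  cfg <- simulation_config(seed = 3, n_chrom = 1, chrom_length = 2e6,
                           matrix_noise_sd = 0, loop_pixel_enrichment = 1)
  ## enrichment 1, noise 0: exactly the decay law off-diagonal
  loops <- mk_loops("chr1", 100000, 105000, 800000, 805000)
  loops$name <- "loop_00001"
  cm <- simulate_contact_matrix(cfg, loops)$chr1
  n <- nrow(cm$mat)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  expect_equal(cm$mat[d > 0], (1 / (1 + d))[d > 0])
  expect_true(all(is.na(diag(cm$mat))))
  ## planted pixel: M[i,j]/decay = enrichment (exact without noise)
  cfg2 <- simulation_config(seed = 3, n_chrom = 1, chrom_length = 2e6,
                            matrix_noise_sd = 0, loop_pixel_enrichment = 3)
  cm2 <- simulate_contact_matrix(cfg2, loops)$chr1
  i <- floor(102500 / 1e4) + 1; j <- floor(802500 / 1e4) + 1
  expect_equal(cm2$mat[i, j] / (1 / (1 + abs(i - j))), 3)
  expect_equal(cm2$mat[i + 1, j] / (1 / (1 + abs(i + 1 - j))), 2)  # half effect
  ## with noise: symmetric, ratio near enrichment
  cfg3 <- simulation_config(seed = 3, n_chrom = 1, chrom_length = 2e6)
  cm3 <- simulate_contact_matrix(cfg3, loops)$chr1
  expect_equal(cm3$mat, t(cm3$mat))
  expect_lt(abs(cm3$mat[i, j] / (1 / (1 + abs(i - j))) / 3 - 1), 0.8)
})

test_that("expression archetypes have configured sizes and structure", {
  cfg <- simulation_config(seed = 6)
  tr <- simulate_speckle_tracks(cfg)
  gn <- simulate_genes(cfg, tr$dmso)
  expect_equal(as.vector(table(factor(gn$archetype[gn$archetype > 0],
                                      levels = 1:4))),
               c(33L, 48L, 6L, 54L))
  ex <- simulate_expression(cfg, gn)
  ## flat genes planted above the p threshold; differential below with |lfc|>0.5
  flat <- gn$archetype[ex$gene_id] == 0
  expect_true(all(ex$padj[flat] >= 0.05))
  expect_true(all(ex$padj[!flat] < 0.05 & abs(ex$log2fc[!flat]) > 0.5))
  ## noise 0: within-archetype expression patterns identical up to baseline
  cfg0 <- simulation_config(seed = 6, archetype_noise_sd = 0)
  ex0 <- simulate_expression(cfg0, gn)
  cols <- grep("^expr_", names(ex0), value = TRUE)
  a2 <- ex0[gn$archetype[ex0$gene_id] == 2, cols]
  centered <- sweep(as.matrix(a2), 1, rowMeans(as.matrix(a2)))
  expect_true(all(apply(centered, 2, function(x) diff(range(x))) < 1e-9))
})

test_that("simulation writes byte-identical outputs for a fixed seed", {
  cfg <- small_config(3)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  simulate_all(cfg, outdir = d1)
  simulate_all(cfg, outdir = d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in setdiff(files, grep("\\.gz$", files, value = TRUE)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  for (f in grep("\\.gz$", files, value = TRUE))
    expect_identical(readLines(gzfile(file.path(d1, f))),
                     readLines(gzfile(file.path(d2, f))), label = f)
  ## emitted files parse back
  expect_s3_class(read_bedpe(file.path(d1, "loops.bedpe")), "data.frame")
  expect_s3_class(read_gff3(file.path(d1, "genes.gff3")), "gene_model")
  tr <- read_bedgraph(file.path(d1, "son_dmso.bedgraph"), simulate_genome(cfg))
  expect_s3_class(tr, "signal_track")
})
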