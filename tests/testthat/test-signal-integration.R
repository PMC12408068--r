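test_that("loop_signal pools distinct bins over both anchors", {
  tr <- toy_track(list(chr1 = c(2, 4, 5, 1, 3)))
  lp <- mk_loops("chr1", 1000, 2000, 25000, 26000)      # bins 1 and 2
  expect_equal(loop_signal(lp, tr), 3)
  both <- mk_loops("chr1", 41000, 42000, 45000, 46000)  # both anchors in bin 3
  expect_equal(loop_signal(both, tr), 5)
  straddle <- mk_loops("chr1", 15000, 45000, 85000, 86000)  # bins 1,2,3 + 5
  expect_equal(loop_signal(straddle, tr), mean(c(2, 4, 5, 3)))
  ## loop with no data bins -> NA
  tr$missing$chr1[] <- TRUE
  expect_true(is.na(loop_signal(lp, tr)))
})

test_that("deciles: equal counts, duplicate-edge collapse, degenerate input", {
  d <- assign_deciles(1:20)
  expect_equal(as.vector(table(d)), rep(2L, 10))
  expect_equal(d[20], 10L)                  # label 10 = highest signal
  expect_warning(one <- assign_deciles(rep(0, 15)), "identical")
  expect_equal(unique(one), 1L)
  ## many ties collapse edges; labels stay consecutive from 1
  v <- c(rep(0, 15), 1:5)
  dd <- assign_deciles(v)
  expect_equal(sort(unique(dd)), seq_len(max(dd)))
  edges <- unique(quantile(v, seq(0, 1, 0.1), type = 7, names = FALSE))
  expect_equal(max(dd), length(edges) - 1)
  ## partition property vs a sort oracle on random vectors
  set.seed(8)
  for (i in 1:100) {
    x <- sample(round(runif(sample(15:60, 1), 0, 10), sample(0:2, 1)))
    lab <- assign_deciles(x)
    expect_equal(sort(unique(lab)), seq_len(max(lab)))
    o <- order(x)
    expect_true(!is.unsorted(lab[o]))       # labels monotone in value
    if (!anyDuplicated(x))
      expect_lte(diff(range(table(lab))), 1)
  }
})

test_that("90th-percentile speckle association rule", {
  tr <- toy_track(list(chr1 = 1:10))
  pk <- mk_peaks("chr1", (0:9) * 20000 + 5000, (0:9) * 20000 + 6000)
  fl <- speckle_associated_peaks(pk, tr)
  expect_equal(attr(fl, "threshold"), 9.1)   # interpolated percentile
  expect_equal(which(fl), 10)
  ## constant track: threshold equals the constant, rule is >=, all flagged
  trc <- toy_track(list(chr1 = rep(4, 10)))
  expect_true(all(speckle_associated_peaks(pk, trc)))
  ## brute-force equivalence on random tracks
  set.seed(12)
  for (i in 1:100) {
    nb <- sample(10:40, 1)
    trr <- toy_track(list(chr1 = round(runif(nb, 0, 5), 2)))
    pkk <- mk_peaks("chr1", (seq_len(nb) - 1) * 20000 + 100, (seq_len(nb) - 1) * 20000 + 500)
    expect_equal(as.vector(speckle_associated_peaks(pkk, trr)),
                 trr$values$chr1 >= oracle_p90(trr$values$chr1))
  }
})

test_that("correlation helper: identity, null and affine invariance", {
  x <- c(1, 5, 3, 8, 2, 9, 4)
  expect_equal(correlate_looping_with_signal(x, x)$r, 1)
  expect_true(is.na(correlate_looping_with_signal(x[1:2], x[1:2])$r))
  set.seed(4)
  rs <- replicate(40, correlate_looping_with_signal(rnorm(1000), rnorm(1000))$r)
  expect_gt(mean(abs(rs) < 0.1), 0.9)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(correlate_looping_with_signal(a, b)$r,
               correlate_looping_with_signal(2 * a + 3, 0.5 * b - 1)$r)
})

test_that("aggregate profiles: flat, bump recovery, strand mirroring, edges", {
  flat <- toy_track(list(chr1 = rep(3, 50)), bin_size = 1000)
  ctr <- mk_peaks("chr1", 24000, 26000)
  pr <- aggregate_profile(flat, ctr, flank = 1000, bin = 50)
  expect_true(all(pr$profile == 3))
  ## planted bump at the center bin only
  v <- rep(0, 50); v[25:26] <- 7
  bump <- toy_track(list(chr1 = v), bin_size = 1000)
  pb <- aggregate_profile(bump, ctr, flank = 2000, bin = 100)
  expect_equal(max(pb$profile), 7)
  expect_equal(pb$profile[c(1, length(pb$profile))], c(0, 0))
  ## minus-strand center mirrors an asymmetric profile
  asym <- toy_track(list(chr1 = seq_len(50)), bin_size = 1000)
  plus <- mk_peaks("chr1", 24000, 26000, strand = "+")
  minus <- mk_peaks("chr1", 24000, 26000, strand = "-")
  expect_equal(aggregate_profile(asym, minus, 2000, 100)$profile,
               rev(aggregate_profile(asym, plus, 2000, 100)$profile))
  ## centers too close to the chromosome edge are dropped and counted
  edge <- mk_peaks("chr1", c(100, 24000), c(300, 26000))
  pe <- aggregate_profile(flat, edge, flank = 1000, bin = 50)
  expect_equal(pe$n_used, 1)
  expect_equal(pe$n_dropped, 1)
})
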