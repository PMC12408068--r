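test_that("filter_loops applies the FDR and PET boundaries", {
  lp <- mk_loops("chr1", rep(1000, 3), rep(1500, 3), rep(9e4, 3), rep(9.05e4, 3),
                 pets = rbind(c(2, 1, 1, 1),      # 5 total, fdr 0.009 -> kept
                              c(25, 25, 25, 25),  # fdr 0.01 -> dropped (strict)
                              c(1, 1, 1, 1)),     # 4 total -> dropped (>4 rule)
                 fdr = c(0.009, 0.01, 0.001))
  expect_equal(filter_loops(lp)$name, "L1")
  ## per-condition sums via the samples argument
  expect_equal(nrow(filter_loops(lp, samples = c("dmso_r1", "dmso_r2"))), 0)
})

test_that("count_distinct_loops: distinct-id semantics and examples", {
  pk <- mk_peaks("chr1", 100, 200)
  lp <- mk_loops("chr1", c(150, 4000), c(250, 4100), c(5000, 60000), c(5100, 60100))
  lp2 <- mk_loops("chr1", 4000, 4100, 60000, 60150)
  lp2[1, c("start1", "end1")] <- c(150, 250)
  got <- count_distinct_loops(pk, rbind(lp[1, ], lp2))
  expect_equal(got$n_distinct_loops, 2)          # anchors of two distinct loops
  ## peak spanning both anchors of one loop counts once
  wide <- mk_peaks("chr1", 100, 70000)
  expect_equal(count_distinct_loops(wide, lp)$n_distinct_loops, 2)
  one <- mk_loops("chr1", 200, 300, 50000, 50100)
  expect_equal(count_distinct_loops(wide, one)$n_distinct_loops, 1)
  expect_equal(count_distinct_loops(wide, one, count_anchor_hits = TRUE)$n_distinct_loops, 2)
  ## no loops
  none <- count_distinct_loops(pk, lp[0, ])
  expect_equal(none$n_distinct_loops, 0)
  expect_false(none$looping)
})

test_that("max_partner_loops: hub partners and multi-peak anchors", {
  ## P loops only to hub H; H makes 12 distinct loops (11 others + LP)
  pk <- mk_peaks("chr1", c(1000, 200000), c(1400, 200400), name = c("P", "H"))
  hub_loops <- mk_loops("chr1",
                        s1 = rep(199900, 11), e1 = rep(200500, 11),
                        s2 = 3e5 + (1:11) * 1e4, e2 = 3e5 + (1:11) * 1e4 + 100)
  p_loop <- mk_loops("chr1", 900, 1500, 199900, 200500, name = "LP")
  loops <- rbind(hub_loops, p_loop)
  st <- count_distinct_loops(pk, loops)
  expect_equal(st$n_distinct_loops, c(1, 12))
  mp <- max_partner_loops(pk, loops, st)
  expect_equal(mp[1], 12)
  ## non-looping peak -> missing
  lone <- rbind(pk, mk_peaks("chr1", 900000, 900200, name = "Q"))
  expect_true(is.na(max_partner_loops(lone, loops)[3]))
  ## partner anchor containing two peaks with counts 3 and 9 -> 9
  pk2 <- mk_peaks("chr1", c(1000, 50000, 50300), c(1400, 50200, 50500),
                  name = c("A", "B1", "B2"))
  base <- mk_loops("chr1", 900, 1500, 49900, 50600)      # A <-> {B1,B2}
  extra_b1 <- mk_loops("chr1", rep(49950, 2), rep(50150, 2),
                       c(700000, 710000), c(700100, 710100))
  extra_b2 <- mk_loops("chr1", rep(50250, 8), rep(50550, 8),
                       8e5 + (1:8) * 1e4, 8e5 + (1:8) * 1e4 + 100)
  loops2 <- rbind(base, extra_b1, extra_b2)
  loops2$name <- sprintf("M%d", seq_len(nrow(loops2)))
  st2 <- count_distinct_loops(pk2, loops2)
  expect_equal(st2$n_distinct_loops, c(1, 3, 9))
  expect_equal(max_partner_loops(pk2, loops2, st2)[1], 9)
})

test_that("oracle equivalence on random instances", {
  set.seed(99)
  for (i in 1:40) {
    inst <- random_instance(n_peaks = sample(5:15, 1), n_loops = sample(5:30, 1))
    pk <- mk_peaks("chr1", s <- sort(sample.int(1e6 - 500, 12)), s + 300)
    st <- count_distinct_loops(pk, inst)
    expect_equal(st$n_distinct_loops, oracle_count_loops(pk, inst))
    expect_equal(max_partner_loops(pk, inst, st), oracle_max_partner(pk, inst))
  }
})

test_that("tangent cutoff: worked example, degenerate cases, invariances", {
  counts <- c(a = 1, b = 2, c = 3, d = 10, e = 20)
  res <- call_highly_looping(counts)
  expect_equal(res$curve$y - res$curve$x, c(0.05, -0.15, -0.35, -0.25, 0))
  expect_equal(res$cutoff_count, 3)
  expect_equal(names(which(res$highly_looping)), c("d", "e"))
  ## degenerate: constant counts / too few peaks
  expect_warning(r0 <- call_highly_looping(c(x = 2, y = 2, z = 2)), "constant")
  expect_false(any(r0$highly_looping))
  expect_warning(r1 <- call_highly_looping(c(x = 1, y = 5)), "fewer than 3")
  expect_false(any(r1$highly_looping))
  set.seed(5)
  for (i in 1:50) {
    cs <- sample.int(30, sample(5:40, 1), replace = TRUE)
    names(cs) <- sprintf("p%03d", seq_along(cs))
    base <- call_highly_looping(cs)
    ## positive scaling leaves the flagged set unchanged
    scaled <- call_highly_looping(cs * 7)
    expect_equal(scaled$highly_looping, base$highly_looping)
    ## adding a new maximum cannot lower the cutoff count
    grown <- call_highly_looping(c(cs, zz = max(cs) + 5L))
    expect_gte(grown$cutoff_count, base$cutoff_count)
  }
})

test_that("distance_to_anchors delegates and summarizes per group", {
  pk <- mk_peaks("chr1", c(100, 5000, 100000), c(200, 5100, 100200))
  anchors <- mk_peaks("chr1", c(150, 7000), c(250, 7100))
  d <- distance_to_anchors(pk, anchors, group = c("hl", "hl", "bg"))
  expect_equal(as.numeric(d), c(0, 1900, 92900))
  sm <- attr(d, "summary")
  expect_equal(sm$median[sm$group == "hl"], 950)
  expect_true(all(is.na(distance_to_anchors(pk, anchors[0, ]))))
})
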