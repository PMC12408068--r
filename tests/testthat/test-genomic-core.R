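test_that("overlaps follows half-open semantics", {
  a <- function(s, e, ch = "chr1") list(chrom = ch, start = s, end = e)
  expect_true(overlaps(a(100, 200), a(199, 300)))   # 1-bp overlap
  expect_false(overlaps(a(100, 200), a(200, 300)))  # abutting
  expect_false(overlaps(a(100, 200), list(chrom = "chr2", start = 100, end = 200)))
  ## partition of an interval: total pairwise overlap equals its length
  whole <- mk_peaks("chr1", 1000, 2000)
  cuts <- sort(sample(1001:1999, 5))
  parts <- mk_peaks("chr1", c(1000, cuts), c(cuts, 2000))
  hit <- interval_overlaps(parts, whole)
  lens <- pmin(parts$end[hit$query], whole$end) - pmax(parts$start[hit$query], whole$start)
  expect_equal(sum(lens), 1000)
})

test_that("interval constructors validate", {
  expect_error(gintervals("chr1", 100, 100), "end must be > start")
  expect_error(gintervals("chr1", -1, 100), "start must be >= 0")
  expect_error(gintervals("", 0, 100), "empty chromosome")
  g <- toy_genome()
  expect_error(gintervals("chr1", 0, 2e6, genome = g), "outside chromosome bounds")
  expect_error(gintervals("chrX", 0, 10, genome = g), "not in genome")
  expect_error(genome(c(1e4, 2e4)), "named")
  expect_error(genome(c(chr1 = 1e4, chr1 = 2e4)), "duplicate")
})

test_that("closest_distance returns gaps, zeros and missing", {
  q <- mk_peaks("chr1", c(100, 350, 100), c(200, 360, 200))
  q$chrom[3] <- "chr2"
  t <- mk_peaks("chr1", 300, 400)
  expect_equal(closest_distance(q, t), c(100, 0, NA))
})

test_that("BED round trip and error reporting", {
  x <- mk_peaks("chr1", c(0, 500, 900), c(100, 700, 1200),
                score = c(1, 2.5, 3), strand = c("+", "-", "."))
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, p)
  expect_equal(read_bed(p), x)
  writeLines(c("chr1\t10\t20\ta\t0\t+", "chr1\t50\tforty"), p)
  expect_error(read_bed(p), "line 2: non-numeric")
  writeLines("chr1\t100\t90", p)
  expect_error(read_bed(p), "line 1: invalid interval")
})

test_that("BEDPE round trips, canonicalizes anchors, rejects inter-chromosomal", {
  lp <- mk_loops("chr1", c(1000, 8000), c(1500, 8500), c(5000, 20000),
                 c(5500, 20500), pets = matrix(c(3, 7, 0, 2, 9, 1, 4, 4), 2))
  lp$fdr <- c(0.004, 0.3)
  p <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(lp, p)
  expect_equal(read_bedpe(p), lp)
  ## anchor2 < anchor1 is swapped on read
  rev <- lp
  rev[1, c("start1", "end1", "start2", "end2")] <- rev[1, c("start2", "end2", "start1", "end1")]
  write_bedpe(rev, p)
  expect_equal(read_bedpe(p)[1, c("start1", "start2")], lp[1, c("start1", "start2")])
  ## inter-chromosomal row dropped with warning
  bad <- lp; bad$chrom2[2] <- "chr2"
  write_bedpe(bad, p)
  expect_warning(got <- read_bedpe(p), "inter-chromosomal")
  expect_equal(nrow(got), 1)
  expect_equal(loop_design(lp)$condition, c("dmso", "dmso", "dnmt1i", "dnmt1i"))
})

test_that("bedGraph gaps are zero-filled, flagged and round-trip", {
  g <- toy_genome(len = 1e5)              # 5 bins of 20 kb
  p <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t20000\t1.5", "chr1\t60000\t80000\t2.25"), p)
  tr <- read_bedgraph(p, g)
  expect_equal(tr$values$chr1, c(1.5, 0, 0, 2.25, 0))
  expect_equal(tr$missing$chr1, c(FALSE, TRUE, TRUE, FALSE, TRUE))
  p2 <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, p2)
  expect_equal(read_bedgraph(p2, g), tr)
  writeLines("chr1\t100\t20100\t1.0", p)
  expect_error(read_bedgraph(p, g), "not aligned")
})

test_that("matrix container round trips (plain and gz) with missing cells", {
  m <- matrix(runif(16), 4, 4)
  m <- (m + t(m)) / 2
  diag(m) <- NA
  cm <- contact_matrix("chr1", 1e4, m)
  for (ext in c(".txt", ".txt.gz")) {
    p <- withr::local_tempfile(fileext = ext)
    write_matrix(cm, p)
    got <- read_matrix(p)
    expect_equal(got$mat, cm$mat)
    expect_equal(got$bin_size, 1e4)
    expect_equal(got$chrom, "chr1")
  }
  expect_error(contact_matrix("chr1", 1e4, matrix(1:4, 2)), "symmetric")
})

test_that("format writers round-trip on random feature sets", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(1:12, 1)
    x <- mk_peaks(sample(c("chr1", "chr2"), n, TRUE),
                  s <- sample.int(1e5, n), s + sample.int(5e3, n),
                  score = round(runif(n), 4),
                  strand = sample(c("+", "-", "."), n, TRUE))
    p <- withr::local_tempfile(fileext = ".bed")
    write_bed(x, p)
    expect_equal(read_bed(p), x)
  }
})

test_that("gene model reads and writes GFF3, merging exons", {
  genes <- mk_peaks("chr1", c(1000, 10000), c(5000, 14000), strand = c("+", "-"))
  genes$gene_id <- c("gA", "gB")
  exons <- data.frame(chrom = "chr1",
                      start = c(1000, 1400, 3000, 10000),
                      end = c(1500, 2000, 3500, 14000),
                      gene_id = c("gA", "gA", "gA", "gB"))
  gm <- gene_model(genes, exons)
  ## overlapping exons [1000,1500) + [1400,2000) merged
  expect_equal(gm$exons$start[gm$exons$gene_id == "gA"], c(1000, 3000))
  expect_equal(gm$exons$end[gm$exons$gene_id == "gA"], c(2000, 3500))
  p <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(gm, p)
  got <- read_gff3(p)
  expect_equal(got$genes[c("chrom", "start", "end", "strand", "gene_id")],
               gm$genes[c("chrom", "start", "end", "strand", "gene_id")])
  expect_equal(got$exons, gm$exons)
  expect_error(gene_model(genes, transform(exons, end = end + 2e4)),
               "outside gene span")
})

test_that("map_binned_signal: stated examples and brute-force equivalence", {
  tr <- toy_track(list(chr1 = c(1, 3)))
  expect_equal(map_binned_signal(tr, mk_peaks("chr1", 10000, 30000)), 2)  # unweighted
  expect_equal(map_binned_signal(tr, mk_peaks("chr1", 21000, 22000)), 3)
  expect_equal(map_binned_signal(tr, mk_peaks("chr2", 0, 100)), NA_real_)
  expect_equal(map_binned_signal(tr, mk_peaks(character(0), numeric(0), numeric(0))),
               numeric(0))
  ## missing bins are skipped
  tr$missing$chr1[2] <- TRUE
  expect_equal(map_binned_signal(tr, mk_peaks("chr1", 10000, 30000)), 1)
  set.seed(7)
  for (i in 1:100) {
    nb <- sample(3:10, 1)
    tr <- toy_track(list(chr1 = runif(nb)))
    tr$missing$chr1 <- runif(nb) < 0.2
    n <- sample(1:6, 1)
    f <- mk_peaks("chr1", s <- sample.int(nb * 20000 - 100, n), s + sample.int(40000, n))
    f$end <- pmin(f$end, nb * 20000)
    expect_equal(map_binned_signal(tr, f), oracle_map_signal(tr, f))
  }
})
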