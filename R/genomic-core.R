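# Coordinate conventions, interval algebra and on-disk formats.
#
# Everything in this package is 0-based half-open ([start, end)) internally,
# the native convention of the BED family.  GFF3 input (1-based closed) is
# converted on read.  Overlap and nearest-neighbour machinery is delegated to
# IRanges behind this contract (+1 shift on entry), so half-open semantics are
# preserved exactly: [s, e) maps to the 1-based closed range [s + 1, e].

#' Construct a genome description
#'
#' A genome is an ordered set of named chromosome lengths (bp).  It anchors
#' bounds checking for intervals, binned signal tracks and contact matrices.
#'
#' @param lengths Named numeric vector of chromosome lengths in bp.
#' @return An object of class `genome` (a named numeric vector).
#' @examples
#' g <- genome(c(chr1 = 2e6, chr2 = 1e6))
#' @export
genome <- function(lengths) {
  if (!is.numeric(lengths) || length(lengths) == 0)
    stop("'lengths' must be a non-empty numeric vector")
  nm <- names(lengths)
  if (is.null(nm) || anyNA(nm) || any(!nzchar(nm)))
    stop("chromosome lengths must be named")
  if (anyDuplicated(nm)) stop("duplicate chromosome names")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be finite and > 0")
  structure(as.numeric(lengths), names = nm, class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome> ", length(x), " chromosome(s), ",
      format(sum(x), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Build an interval table
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`
#' (0-based half-open), `name`, `score`, `strand`; the unit of all set logic.
#'
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open coordinates (`end` exclusive).
#' @param name Feature identifiers (defaults to `feature_<i>`).
#' @param score Numeric score (default 0).
#' @param strand One of `"+"`, `"-"`, `"."` per feature (default `"."`).
#' @param genome Optional [genome()] for bounds checking.
#' @return A validated interval `data.frame`.
#' @export
gintervals <- function(chrom, start, end, name = NULL, score = 0, strand = ".",
                       genome = NULL) {
  n <- length(start)
  if (is.null(name)) name <- if (n) sprintf("feature_%d", seq_len(n)) else character(0)
  x <- data.frame(chrom = rep_len(as.character(chrom), n), start = as.numeric(start),
                  end = as.numeric(end), name = rep_len(as.character(name), n),
                  score = rep_len(as.numeric(score), n),
                  strand = rep_len(as.character(strand), n),
                  stringsAsFactors = FALSE)
  validate_intervals(x, genome)
  x
}

validate_intervals <- function(x, genome = NULL, what = "interval") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x)))
    stop(what, " table must have columns chrom/start/end")
  if (nrow(x) == 0) return(invisible(x))
  if (any(!nzchar(x$chrom))) stop(what, ": empty chromosome name")
  if (any(x$start < 0)) stop(what, ": start must be >= 0")
  if (any(x$end <= x$start)) stop(what, ": end must be > start")
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", ".")))
    stop(what, ": strand must be one of +, -, .")
  if (!is.null(genome)) {
    bad <- !(x$chrom %in% names(genome))
    if (any(bad)) stop(what, ": chromosome not in genome: ",
                       paste(unique(x$chrom[bad]), collapse = ", "))
    over <- x$end > unclass(genome)[x$chrom]
    if (any(over)) stop(what, ": interval outside chromosome bounds (",
                        paste(utils::head(x$name[over], 3), collapse = ", "), ")")
  }
  invisible(x)
}

#' Do two intervals overlap?
#'
#' Half-open semantics: `[100,200)` and `[200,300)` abut but do not overlap.
#'
#' @param a,b Single intervals (one-row data frames or lists with
#'   `chrom`, `start`, `end`).
#' @return `TRUE` iff same chromosome and intersection length >= 1 bp.
#' @export
overlaps <- function(a, b) {
  as.character(a$chrom[1]) == as.character(b$chrom[1]) &&
    max(a$start[1], b$start[1]) < min(a$end[1], b$end[1])
}

## Many-to-many overlap pairs (half-open).  Returns data.frame(query, subject)
## of row indices.  Backed by IRanges::findOverlaps.
interval_overlaps <- function(a, b) {
  out <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    ra <- IRanges::IRanges(as.integer(a$start[ia]) + 1L, as.integer(a$end[ia]))
    rb <- IRanges::IRanges(as.integer(b$start[ib]) + 1L, as.integer(b$end[ib]))
    hit <- IRanges::findOverlaps(ra, rb)
    out[[ch]] <- data.frame(query = ia[S4Vectors::queryHits(hit)],
                            subject = ib[S4Vectors::subjectHits(hit)])
  }
  if (length(out) == 0) return(data.frame(query = integer(0), subject = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$query, res$subject), , drop = FALSE]
}

#' Distance to the closest target interval
#'
#' Minimal gap in bp (0 if overlapping or abutting) from each query to any
#' target on the same chromosome; `NA` when the query's chromosome carries no
#' target.
#'
#' @param query,targets Interval tables.
#' @return Numeric vector, one distance per query row.
#' @export
closest_distance <- function(query, targets) {
  res <- rep(NA_real_, nrow(query))
  if (nrow(query) == 0 || nrow(targets) == 0) return(res)
  for (ch in intersect(unique(query$chrom), unique(targets$chrom))) {
    iq <- which(query$chrom == ch)
    it <- which(targets$chrom == ch)
    rq <- IRanges::IRanges(as.integer(query$start[iq]) + 1L, as.integer(query$end[iq]))
    rt <- IRanges::IRanges(as.integer(targets$start[it]) + 1L, as.integer(targets$end[it]))
    hit <- IRanges::distanceToNearest(rq, rt)
    d <- rep(NA_real_, length(iq))
    d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
    res[iq] <- d
  }
  res
}

## ---------------------------------------------------------------------------
## Signal tracks (fixed-width binned genome-wide signal, RPKM-like)

#' Construct a binned signal track
#'
#' @param genome A [genome()].
#' @param bin_size Bin width in bp (default 20 kb, the Cut&Tag bin size).
#' @param values Optional named list (per chromosome) of numeric bin values.
#' @param missing Optional named list of logical missing flags per bin.
#'   Bins flagged missing are skipped by all aggregators.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(genome, bin_size = 20000, values = NULL, missing = NULL) {
  nb <- ceiling(unclass(genome) / bin_size)
  if (is.null(values)) values <- lapply(nb, function(n) numeric(n))
  if (is.null(missing)) missing <- lapply(nb, function(n) rep(TRUE, n))
  stopifnot(identical(sort(names(values)), sort(names(genome))),
            identical(sort(names(missing)), sort(names(genome))))
  for (ch in names(genome)) {
    if (length(values[[ch]]) != nb[[ch]] || length(missing[[ch]]) != nb[[ch]])
      stop("track '", ch, "': expected ", nb[[ch]], " bins")
    if (any(!is.finite(values[[ch]][!missing[[ch]]])))
      stop("track '", ch, "': non-finite value in a non-missing bin")
  }
  structure(list(genome = genome, bin_size = bin_size,
                 values = values[names(genome)], missing = missing[names(genome)]),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  nb <- sum(vapply(x$values, length, 1L))
  cat("<signal_track> bin_size=", x$bin_size, ", ", nb, " bins, ",
      sum(vapply(x$missing, sum, 1L)), " missing\n", sep = "")
  invisible(x)
}

## All non-missing bin values of a track, as one vector.
track_values <- function(track) {
  unlist(lapply(names(track$values), function(ch)
    track$values[[ch]][!track$missing[[ch]]]), use.names = FALSE)
}

#' Map binned signal onto features
#'
#' Per feature, the unweighted mean (or another aggregator) over all bins
#' overlapping the feature; bins flagged missing are skipped; a feature
#' overlapping no data bin (or on a chromosome absent from the track) gets
#' `NA`.  The unweighted-bin semantics match `bedtools map -o mean` on a
#' binned bedGraph.
#'
#' @param track A [signal_track()].
#' @param features Interval table.
#' @param aggregator Function over the overlapped bin values (default `mean`).
#' @return Numeric vector, one value per feature.
#' @export
map_binned_signal <- function(track, features, aggregator = mean) {
  n <- nrow(features)
  if (n == 0) return(numeric(0))
  bs <- track$bin_size
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ch <- features$chrom[i]
    v <- track$values[[ch]]
    if (is.null(v)) next
    b0 <- max(1L, floor(features$start[i] / bs) + 1L)
    b1 <- min(length(v), floor((features$end[i] - 1) / bs) + 1L)
    if (b1 < b0) next
    keep <- !track$missing[[ch]][b0:b1]
    if (!any(keep)) next
    out[i] <- aggregator(v[b0:b1][keep])
  }
  out
}

## ---------------------------------------------------------------------------
## BED / bedGraph / BEDPE / matrix / GFF3 readers and writers

fmt_pos <- function(x) sprintf("%.0f", x)

parse_error <- function(path, line, msg) {
  stop(sprintf("%s line %d: %s", path, line, msg), call. = FALSE)
}

read_lines_keep <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  list(lines = lines, keep = keep)
}

#' Read / write BED files
#'
#' BED3/6; columns beyond the sixth are ignored on read.
#'
#' @param path File path.
#' @param genome Optional [genome()] for bounds checking.
#' @return `read_bed`: an interval `data.frame`.
#' @export
read_bed <- function(path, genome = NULL) {
  lk <- read_lines_keep(path)
  idx <- which(lk$keep)
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    f <- strsplit(lk$lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) parse_error(path, i, "fewer than 3 BED fields")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) parse_error(path, i, "non-numeric coordinate")
    if (s < 0 || e <= s) parse_error(path, i, "invalid interval (need 0 <= start < end)")
    rows[[k]] <- data.frame(
      chrom = f[1], start = s, end = e,
      name = if (length(f) >= 4) f[4] else sprintf("feature_%d", k),
      score = if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else 0,
      strand = if (length(f) >= 6 && f[6] %in% c("+", "-", ".")) f[6] else ".",
      stringsAsFactors = FALSE)
  }
  x <- if (length(rows)) do.call(rbind, rows) else
    gintervals(character(0), numeric(0), numeric(0))
  validate_intervals(x, genome, what = paste0("BED ", path))
  x
}

#' @rdname read_bed
#' @param x Interval table to write.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  lines <- if (nrow(x)) paste(x$chrom, fmt_pos(x$start), fmt_pos(x$end),
                              x$name, format(x$score, trim = TRUE, scientific = FALSE),
                              x$strand, sep = "\t") else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write BEDPE loop files
#'
#' The dialect carries a mandatory header line (prefixed `#`) naming all
#' columns: the ten standard BEDPE columns, then one or more per-sample PET
#' count columns named `pet_<condition>_r<replicate>`, then `fdr`.  Anchors
#' are canonicalized on read so that anchor1 is leftmost; inter-chromosomal
#' rows are rejected with a warning (every analysis here is
#' intra-chromosomal).
#'
#' @param path File path.
#' @param genome Optional [genome()] for bounds checking.
#' @return `read_bedpe`: a loop `data.frame` with columns
#'   `chrom1,start1,end1,chrom2,start2,end2,name,score,strand1,strand2`,
#'   `pet_*...`, `fdr`.
#' @export
read_bedpe <- function(path, genome = NULL) {
  lines <- readLines(path)
  hdr_i <- which(grepl("^#", lines) & nzchar(lines))[1]
  if (is.na(hdr_i)) stop(path, ": BEDPE header line (starting '#') is required")
  cols <- strsplit(sub("^#\\s*", "", lines[hdr_i]), "\t", fixed = TRUE)[[1]]
  std <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
           "name", "score", "strand1", "strand2")
  if (!identical(cols[seq_len(10)], std))
    stop(path, ": BEDPE header must begin with the 10 standard columns")
  pet_cols <- grep("^pet_", cols, value = TRUE)
  if (length(pet_cols) == 0 || cols[length(cols)] != "fdr")
    stop(path, ": BEDPE header must declare pet_* columns followed by fdr")
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  rows <- vector("list", length(body))
  for (k in seq_along(body)) {
    i <- body[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(cols))
      parse_error(path, i, sprintf("expected %d fields, found %d", length(cols), length(f)))
    num <- suppressWarnings(as.numeric(f[c(2, 3, 5, 6)]))
    if (anyNA(num)) parse_error(path, i, "non-numeric anchor coordinate")
    pf <- suppressWarnings(as.numeric(f[match(c(pet_cols, "fdr", "score"), cols)]))
    if (anyNA(pf)) parse_error(path, i, "non-numeric PET/FDR/score field")
    row <- as.list(f); names(row) <- cols
    row[c("start1", "end1", "start2", "end2")] <- as.list(num[c(1, 2, 3, 4)])
    row[c(pet_cols, "fdr", "score")] <-
      as.list(pf[seq_len(length(pet_cols) + 2)])
    rows[[k]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  x <- if (length(rows)) do.call(rbind, rows) else {
    tmpl <- stats::setNames(rep(list(numeric(0)), length(cols)), cols)
    tmpl[c("chrom1", "chrom2", "name", "strand1", "strand2")] <-
      rep(list(character(0)), 5)
    as.data.frame(tmpl, stringsAsFactors = FALSE)
  }
  canonicalize_loops(x, genome, source = path)
}

## Anchor ordering, intra-chromosomal restriction, validity.
canonicalize_loops <- function(x, genome = NULL, source = "loops") {
  inter <- x$chrom1 != x$chrom2
  if (any(inter)) {
    warning(source, ": dropping ", sum(inter), " inter-chromosomal loop(s)")
    x <- x[!inter, , drop = FALSE]
  }
  swap <- x$start2 < x$start1
  if (any(swap)) {
    tmp <- x[swap, c("start1", "end1", "strand1")]
    x[swap, c("start1", "end1", "strand1")] <- x[swap, c("start2", "end2", "strand2")]
    x[swap, c("start2", "end2", "strand2")] <- tmp
  }
  for (a in 1:2)
    validate_intervals(anchor_intervals(x, a), genome, what = paste0(source, " anchor", a))
  pet <- pet_columns(x)
  if (nrow(x)) {
    if (any(as.matrix(x[pet]) < 0)) stop(source, ": negative PET count")
    if (any(x$fdr < 0 | x$fdr > 1)) stop(source, ": FDR outside [0, 1]")
  }
  rownames(x) <- NULL
  x
}

#' @rdname read_bedpe
#' @param loops Loop table to write.
#' @export
write_bedpe <- function(loops, path) {
  cols <- names(loops)
  pet <- pet_columns(loops)
  hdr <- paste0("#", paste(cols, collapse = "\t"))
  fmt <- loops
  for (cc in c("start1", "end1", "start2", "end2")) fmt[[cc]] <- fmt_pos(fmt[[cc]])
  for (cc in pet) fmt[[cc]] <- fmt_pos(fmt[[cc]])
  fmt$fdr <- format(loops$fdr, trim = TRUE, scientific = FALSE, digits = 15)
  fmt$score <- format(loops$score, trim = TRUE, scientific = FALSE)
  body <- if (nrow(fmt)) do.call(paste, c(unname(as.list(fmt)), sep = "\t")) else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' PET count columns of a loop table
#'
#' @param loops Loop table.
#' @return Character vector of `pet_*` column names.
#' @export
pet_columns <- function(loops) grep("^pet_", names(loops), value = TRUE)

#' Sample design parsed from PET column names
#'
#' PET columns follow `pet_<condition>_r<replicate>`.
#'
#' @param loops Loop table.
#' @return `data.frame(sample, condition, replicate, column)`.
#' @export
loop_design <- function(loops) {
  pc <- pet_columns(loops)
  m <- regmatches(pc, regexec("^pet_(.+)_r(\\d+)$", pc))
  bad <- vapply(m, length, 1L) != 3
  if (any(bad))
    stop("PET columns not matching pet_<condition>_r<rep>: ",
         paste(pc[bad], collapse = ", "))
  data.frame(sample = sub("^pet_", "", pc),
             condition = vapply(m, `[`, "", 2),
             replicate = as.integer(vapply(m, `[`, "", 3)),
             column = pc, stringsAsFactors = FALSE)
}

## Anchor k of a loop table as a plain interval table (name = loop name).
anchor_intervals <- function(loops, k) {
  data.frame(chrom = loops[[paste0("chrom", k)]],
             start = loops[[paste0("start", k)]],
             end = loops[[paste0("end", k)]],
             name = loops$name, score = loops$score,
             strand = loops[[paste0("strand", k)]],
             stringsAsFactors = FALSE)
}

#' Read / write bedGraph signal as a binned track
#'
#' Rows must be aligned to the track's bins.  Bins absent from the file are
#' zero-filled and flagged missing; aggregators skip them, and
#' `write_bedgraph` omits them, so write-then-read round-trips.
#'
#' @param path File path.
#' @param genome A [genome()].
#' @param bin_size Bin width in bp (default 20 kb).
#' @return `read_bedgraph`: a [signal_track()].
#' @export
read_bedgraph <- function(path, genome, bin_size = 20000) {
  track <- signal_track(genome, bin_size)
  lk <- read_lines_keep(path)
  for (i in which(lk$keep)) {
    f <- strsplit(lk$lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4) parse_error(path, i, "fewer than 4 bedGraph fields")
    ch <- f[1]
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    v <- suppressWarnings(as.numeric(f[4]))
    if (is.na(s) || is.na(e) || is.na(v)) parse_error(path, i, "non-numeric field")
    if (!ch %in% names(genome)) parse_error(path, i, paste0("unknown chromosome ", ch))
    len <- unclass(genome)[[ch]]
    if (s %% bin_size != 0 || e != min(s + bin_size, len))
      parse_error(path, i, "row not aligned to track bins")
    b <- s %/% bin_size + 1
    track$values[[ch]][b] <- v
    track$missing[[ch]][b] <- FALSE
  }
  track
}

#' @rdname read_bedgraph
#' @param track Track to write.
#' @export
write_bedgraph <- function(track, path) {
  g <- unclass(track$genome); bs <- track$bin_size
  lines <- unlist(lapply(names(g), function(ch) {
    b <- which(!track$missing[[ch]])
    if (!length(b)) return(character(0))
    paste(ch, fmt_pos((b - 1) * bs), fmt_pos(pmin(b * bs, g[[ch]])),
          format(track$values[[ch]][b], trim = TRUE, scientific = FALSE, digits = 15),
          sep = "\t")
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Contact matrices (dense per-chromosome container)

#' Construct a per-chromosome contact matrix
#'
#' One dense symmetric matrix of balanced interaction frequencies per
#' chromosome; `NA` marks missing (unbalanced / diagonal) cells.
#'
#' @param chrom Chromosome name.
#' @param bin_size Bin width in bp (default 10 kb).
#' @param mat Square numeric matrix.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(chrom, bin_size, mat) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (any(mat[!is.na(mat)] < 0)) stop("contact matrix must be non-negative")
  if (!isTRUE(all.equal(mat, t(mat)))) stop("contact matrix must be symmetric")
  structure(list(chrom = as.character(chrom), bin_size = as.numeric(bin_size),
                 mat = mat), class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", x$chrom, ": ", nrow(x$mat), " x ", nrow(x$mat),
      " bins of ", x$bin_size, " bp\n", sep = "")
  invisible(x)
}

#' Read / write the dense matrix container
#'
#' Plain-text dialect: a header line
#' `#loophub_matrix chrom=<c> bin_size=<b> n_bins=<n>` followed by `n` rows of
#' `n` tab-separated values (`NA` for missing).  Files ending in `.gz` are
#' (de)compressed transparently.
#'
#' @param path File path (`.gz` honoured).
#' @return `read_matrix`: a [contact_matrix()].
#' @export
read_matrix <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  hdr <- readLines(con, n = 1)
  m <- regmatches(hdr, regexec(
    "^#loophub_matrix chrom=(\\S+) bin_size=(\\S+) n_bins=(\\d+)$", hdr))[[1]]
  if (length(m) != 4) stop(path, " line 1: malformed matrix header")
  n <- as.integer(m[4])
  vals <- scan(con, what = numeric(), n = n * n, quiet = TRUE, na.strings = "NA")
  if (length(vals) != n * n)
    stop(path, ": expected ", n * n, " matrix values, found ", length(vals))
  contact_matrix(m[2], as.numeric(m[3]), matrix(vals, n, n, byrow = TRUE))
}

#' @rdname read_matrix
#' @param cm Matrix to write.
#' @export
write_matrix <- function(cm, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#loophub_matrix chrom=%s bin_size=%s n_bins=%d",
                     cm$chrom, fmt_pos(cm$bin_size), nrow(cm$mat)), con)
  body <- apply(cm$mat, 1, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Gene models (GFF3, genes + exons only)

#' Construct a gene model
#'
#' Holds gene and exon intervals (0-based half-open).  Exons are merged per
#' gene on construction and must lie within their gene.
#'
#' @param genes Interval table with a `gene_id` column and strand.
#' @param exons Interval table with a `gene_id` column.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(genes, exons) {
  stopifnot("gene_id" %in% names(genes), "gene_id" %in% names(exons))
  validate_intervals(genes, what = "gene")
  validate_intervals(exons, what = "exon")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in gene table")
  merged <- list()
  for (gid in unique(exons$gene_id)) {
    ex <- exons[exons$gene_id == gid, , drop = FALSE]
    gi <- match(gid, genes$gene_id)
    if (is.na(gi)) stop("exon references unknown gene: ", gid)
    if (any(ex$start < genes$start[gi]) || any(ex$end > genes$end[gi]))
      stop("exon outside gene span: ", gid)
    r <- IRanges::reduce(IRanges::IRanges(as.integer(ex$start) + 1L, as.integer(ex$end)))
    merged[[gid]] <- data.frame(chrom = genes$chrom[gi],
                                start = IRanges::start(r) - 1,
                                end = IRanges::end(r),
                                gene_id = gid, stringsAsFactors = FALSE)
  }
  exons <- if (length(merged)) do.call(rbind, merged) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               gene_id = character(0), stringsAsFactors = FALSE)
  rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_model")
}

#' Read / write a minimal GFF3 gene model
#'
#' Only `gene` and `exon` features are consumed; 1-based closed GFF3
#' coordinates are converted to the internal 0-based half-open convention.
#' `gene_id` is taken from the attributes column.
#'
#' @param path File path.
#' @return `read_gff3`: a [gene_model()].
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  genes <- list(); exons <- list()
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) parse_error(path, i, "fewer than 9 GFF3 fields")
    type <- f[3]
    if (!type %in% c("gene", "exon")) next
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e) || s < 1 || e < s)
      parse_error(path, i, "invalid GFF3 coordinates")
    gid <- sub(".*gene_id=([^;]+).*", "\\1", f[9])
    if (identical(gid, f[9])) parse_error(path, i, "attributes lack gene_id=")
    rec <- data.frame(chrom = f[1], start = s - 1, end = e,
                      strand = if (f[7] %in% c("+", "-")) f[7] else ".",
                      gene_id = gid, stringsAsFactors = FALSE)
    if (type == "gene") genes[[length(genes) + 1]] <- rec
    else exons[[length(exons) + 1]] <- rec
  }
  g <- do.call(rbind, genes)
  g$name <- g$gene_id
  e <- if (length(exons)) do.call(rbind, exons) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               strand = character(0), gene_id = character(0))
  gene_model(g, e)
}

#' @rdname read_gff3
#' @param model A [gene_model()] to write.
#' @export
write_gff3 <- function(model, path) {
  g <- model$genes
  gl <- paste(g$chrom, "loophub", "gene", fmt_pos(g$start + 1), fmt_pos(g$end),
              ".", g$strand, ".", sprintf("ID=gene:%s;gene_id=%s", g$gene_id, g$gene_id),
              sep = "\t")
  e <- model$exons
  st <- g$strand[match(e$gene_id, g$gene_id)]
  el <- if (nrow(e)) paste(e$chrom, "loophub", "exon", fmt_pos(e$start + 1),
                           fmt_pos(e$end), ".", st, ".",
                           sprintf("Parent=gene:%s;gene_id=%s", e$gene_id, e$gene_id),
                           sep = "\t") else character(0)
  writeLines(c("##gff-version 3", gl, el), path)
  invisible(path)
}
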