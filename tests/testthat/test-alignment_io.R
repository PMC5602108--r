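test_that("filter_alignments drops flagged records and preserves order", {
  lines <- c(
    sam_rec("r1", 0L, "chr1", 100, "30M"),            # clean
    sam_rec("r2", 1024L, "chr1", 150, "30M"),         # duplicate
    sam_rec("r3", 256L, "chr1", 200, "30M"),          # secondary
    sam_rec("r4", 0L, "chr1", 250, "30M", mapq = 5L), # low mapq
    sam_rec("r5", 0L, "chr1", 300, "30M"))
  bam <- make_bam(lines)
  aln <- GenomicAlignments::readGAlignments(bam,
    param = Rsamtools::ScanBamParam(what = c("flag", "mapq")))

  out <- filter_alignments(aln, read_filter_config(min_mapq = 20L,
                                                   require_proper_pair = FALSE))
  expect_equal(length(out), 2L)
  d <- attr(out, "dropped")
  expect_equal(unname(d[c("duplicate", "secondary", "mapq")]),
               c(1L, 1L, 1L))
  # order preserved
  expect_equal(GenomicAlignments::start(out), c(100L, 300L))

  # all-off config is the identity
  off <- read_filter_config(skip_duplicates = FALSE, skip_secondary = FALSE,
                            min_mapq = 0L, require_proper_pair = FALSE)
  expect_equal(length(filter_alignments(aln, off)), length(aln))

  # idempotent
  cfg <- read_filter_config(min_mapq = 20L, require_proper_pair = FALSE)
  once <- filter_alignments(aln, cfg)
  twice <- filter_alignments(once, cfg)
  expect_equal(length(twice), length(once))
})

test_that("mapq-threshold filtering matches a direct scan", {
  set.seed(21)
  mapqs <- sample(0:60, 10)
  lines <- vapply(seq_along(mapqs), function(i)
    sam_rec(paste0("r", i), 0L, "chr1", 100 + 10 * i, "20M",
            mapq = mapqs[i]), character(1))
  bam <- make_bam(lines)
  aln <- GenomicAlignments::readGAlignments(bam,
    param = Rsamtools::ScanBamParam(what = c("flag", "mapq")))
  out <- filter_alignments(aln, read_filter_config(
    min_mapq = 30L, require_proper_pair = FALSE))
  expect_equal(length(out), sum(mapqs >= 30 | mapqs == 255))
})

test_that("unindexed BAM is a fatal error naming the file", {
  bam <- make_bam(sam_rec("r1", 0L, "chr1", 100, "30M"))
  bad <- sub("\\.bam$", "_noidx.bam", bam)
  file.copy(bam, bad)
  expect_error(infer_fragments(bad), "index")
})

test_that("paired mates merge into a single gap-filled fragment", {
  lines <- c(
    sam_rec("p1", 99L, "chr1", 101, "50M", rnext = "=", pnext = 201,
            tlen = 150L),
    sam_rec("p1", 147L, "chr1", 201, "50M", rnext = "=", pnext = 101,
            tlen = -150L))
  bam <- make_bam(lines)
  fr <- infer_fragments(bam, mode = "paired")
  expect_equal(length(fr), 1L)
  b <- fr[[1]]
  expect_equal(GenomicRanges::start(b), 101L)
  expect_equal(GenomicRanges::end(b), 250L)

  # overlapping mates count each base once
  lines2 <- c(
    sam_rec("p1", 99L, "chr1", 101, "50M", rnext = "=", pnext = 121,
            tlen = 70L),
    sam_rec("p1", 147L, "chr1", 121, "50M", rnext = "=", pnext = 101,
            tlen = -70L))
  fr2 <- infer_fragments(make_bam(lines2), mode = "paired")
  expect_equal(sum(GenomicRanges::width(fr2[[1]])), 70L)
})

test_that("annotation restricts mate-gap fill to exons", {
  em <- parse_gtf(make_gtf())  # exons chr1:51-140, 301-400
  lines <- c(
    sam_rec("p1", 99L, "chr1", 101, "30M", rnext = "=", pnext = 331,
            tlen = 260L),
    sam_rec("p1", 147L, "chr1", 331, "30M", rnext = "=", pnext = 101,
            tlen = -260L))
  bam <- make_bam(lines)
  fr <- infer_fragments(bam, mode = "paired", exons = em)
  b <- fr[[1]]
  # gap 131..330 intersected with exons: 131-140 and 301-330 join the
  # mate blocks; the intron 141-300 is excluded
  expect_equal(GenomicRanges::start(b), c(101L, 301L))
  expect_equal(GenomicRanges::end(b), c(140L, 360L))

  # without annotation the raw (sub-10kb) gap is filled
  fr2 <- infer_fragments(bam, mode = "paired")
  expect_equal(sum(GenomicRanges::width(fr2[[1]])), 260L)
})

test_that("single-end 3' extension respects intron-exon boundaries", {
  em <- parse_gtf(make_gtf())  # exons chr1:51-140 and 301-400
  # plus-strand read 101-130 extended to 100 nt: 10 nt to the exon end,
  # then 60 nt into the next exon
  bam <- make_bam(sam_rec("s1", 0L, "chr1", 101, "30M"))
  fr <- infer_fragments(bam, mode = "single", fragment_size = 100L,
                        exons = em)
  b <- fr[[1]]
  expect_equal(GenomicRanges::start(b), c(101L, 301L))
  expect_equal(GenomicRanges::end(b), c(140L, 360L))
  expect_true(S4Vectors::mcols(fr)$is_extended[1])
  expect_equal(sum(GenomicRanges::width(b)), 100L)

  # minus-strand mirror: read at the start of the downstream exon
  # extends toward lower coordinates across the intron
  bam2 <- make_bam(sam_rec("s2", 16L, "chr1", 301, "30M"))
  fr2 <- infer_fragments(bam2, mode = "single", fragment_size = 100L,
                         exons = em)
  b2 <- fr2[[1]]
  expect_equal(GenomicRanges::start(b2), c(71L, 301L))
  expect_equal(GenomicRanges::end(b2), c(140L, 330L))
  expect_equal(sum(GenomicRanges::width(b2)), 100L)
})

test_that("extension without annotation is linear and truncates at 1", {
  bam <- make_bam(sam_rec("s1", 0L, "chr1", 101, "30M"))
  fr <- infer_fragments(bam, mode = "single", fragment_size = 80L)
  expect_equal(GenomicRanges::end(fr[[1]]), 180L)
  bam2 <- make_bam(sam_rec("s2", 16L, "chr1", 11, "30M"))
  fr2 <- infer_fragments(bam2, mode = "single", fragment_size = 200L)
  expect_equal(GenomicRanges::start(fr2[[1]]), 1L)
})

test_that("compute_coverage counts fragment bases and respects introns", {
  gr <- GenomicRanges::GRangesList(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(10, 19)),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 30), c(14, 34))))
  cov <- compute_coverage(gr[1], "chr1", 1, 40)
  expect_equal(cov$values[10:19], rep(1L, 10))
  expect_equal(sum(cov$values), 10L)

  cov2 <- compute_coverage(gr[2], "chr1", 1, 40)
  expect_equal(cov2$values[15:29], rep(0L, 15))  # intronic gap
  expect_equal(sum(cov2$values), 10L)

  # conservation: unscaled sum equals total block length in interval
  both <- compute_coverage(gr, "chr1", 1, 40)
  expect_equal(sum(both$values), 20L)
  # empty input: all-zero track
  expect_equal(sum(compute_coverage(GenomicRanges::GRangesList(),
                                    "chr1", 1, 40)$values), 0L)
})

test_that("coverage is additive over fragment sets", {
  set.seed(31)
  frags <- GenomicRanges::GRangesList(lapply(1:12, function(i) {
    st <- sample(1:400, 1)
    GenomicRanges::GRanges("chr1", IRanges::IRanges(st, st + sample(20:60, 1)))
  }))
  total <- compute_coverage(frags, "chr1", 1, 500)$values
  singles <- Reduce(`+`, lapply(seq_along(frags), function(i)
    compute_coverage(frags[i], "chr1", 1, 500)$values))
  expect_equal(total, singles)
})

test_that("single-end extension reproduces paired fragment coverage", {
  # unspliced template of known length: extending the forward mate by
  # the true template length equals the paired fragment at every base
  tlen <- 120L
  pair <- c(
    sam_rec("p1", 99L, "chr1", 201, "40M", rnext = "=", pnext = 281,
            tlen = tlen),
    sam_rec("p1", 147L, "chr1", 281, "40M", rnext = "=", pnext = 201,
            tlen = -tlen))
  single <- sam_rec("s1", 0L, "chr1", 201, "40M")
  fr_p <- infer_fragments(make_bam(pair), mode = "paired")
  fr_s <- infer_fragments(make_bam(single), mode = "single",
                          fragment_size = tlen)
  expect_equal(compute_coverage(fr_p, "chr1", 1, 500)$values,
               compute_coverage(fr_s, "chr1", 1, 500)$values)
})

test_that("estimate_fragment_length returns the median template length", {
  mk_pair <- function(id, pos, tlen)
    c(sam_rec(id, 99L, "chr1", pos, "30M", rnext = "=",
              pnext = pos + tlen - 30L, tlen = tlen),
      sam_rec(id, 147L, "chr1", pos + tlen - 30L, "30M", rnext = "=",
              pnext = pos, tlen = -tlen))
  tlens <- rep(c(80L, 100L, 120L), each = 40)
  lines <- unlist(lapply(seq_along(tlens), function(i)
    mk_pair(paste0("p", i), 100L + 7L * i, tlens[i])))
  bam <- make_bam(lines)
  est <- estimate_fragment_length(bam)
  expect_equal(est$fragment_length, 100)
  expect_equal(est$expected_peak_width, 200)
  # brute-force oracle over all TLENs
  expect_equal(est$fragment_length, median(tlens))

  # single-end data: directs the user to a fragment-size argument
  se <- make_bam(sam_rec("r1", 0L, "chr1", 100, "30M"))
  expect_error(estimate_fragment_length(se), "fragment")
})
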