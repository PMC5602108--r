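test_that("smooth_coverage is a centred moving average with edge shrinkage", {
  expect_equal(smooth_coverage(c(1, 5, 2, 8), 1), c(1, 5, 2, 8))
  expect_equal(smooth_coverage(rep(3, 10), 5), rep(3, 10))
  expect_equal(smooth_coverage(c(0, 0, 6, 0, 0), 3), c(0, 2, 2, 2, 0))
  expect_warning(out <- smooth_coverage(c(0, 0, 6, 0, 0), 2), "odd")
  expect_equal(out, c(0, 2, 2, 2, 0))
  # interior mass preserved (edges shrink toward the boundary mean)
  x <- c(0, 0, 0, 10, 4, 2, 0, 0, 0)
  expect_equal(sum(smooth_coverage(x, 3)), sum(x))
})

test_that("find_local_maxima detects summits, plateaus and dips", {
  expect_equal(find_local_maxima(c(0, 1, 2, 3, 2, 1, 0), 4), 4L)
  # plateau reports the run centre
  expect_equal(find_local_maxima(c(0, 2, 5, 5, 5, 2, 0), 4), 4L)
  # flat track: nothing
  expect_length(find_local_maxima(rep(2, 20), 4), 0L)
  # floor suppresses low maxima
  expect_length(find_local_maxima(c(0, 1, 2, 3, 2, 1, 0), 4, floor = 10), 0L)
  # two lobes separated by a deep valley are both reported
  two <- c(0, 2, 8, 10, 8, 3, 1, 3, 8, 12, 8, 2, 0)
  expect_equal(find_local_maxima(two, 4), c(4L, 10L))
  # shallow dip (valley above 0.75 of the lower summit): merged
  shallow <- c(0, 2, 8, 10, 9.5, 9, 9.5, 10, 8, 2, 0)
  got <- find_local_maxima(shallow, 4)
  expect_length(got, 1L)
})

test_that("local maxima agree with a brute-force gradient-sign oracle", {
  set.seed(13)
  x <- smooth_coverage(cumsum(rnorm(300)), 9) + 50
  got <- find_local_maxima(x, 8, min_valley_fraction = 1)
  # oracle: strict sign change of the difference around each position,
  # plateau-aware, via run-length encoding
  r <- rle(x)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  k <- length(r$values)
  oracle <- integer(0)
  for (i in seq_len(k)) {
    left <- if (i == 1) -Inf else r$values[i - 1]
    right <- if (i == k) -Inf else r$values[i + 1]
    if (r$values[i] > left && r$values[i] > right)
      oracle <- c(oracle, (starts[i] + ends[i]) %/% 2L)
  }
  # the flank-trend check only removes jitter maxima; with
  # min_valley_fraction = 1 merging only removes the lower of adjacent
  # maxima, so every reported summit must be an oracle maximum
  expect_true(all(got %in% oracle))
  expect_true(length(got) >= 1L)
})

test_that("define_regions clips overlaps at the summit midpoint", {
  r1 <- define_regions(501L, 100L)
  expect_equal(unlist(r1[1, c("start", "end")], use.names = FALSE),
               c(401L, 600L))
  r2 <- define_regions(c(501L, 561L), 100L)
  expect_equal(r2$start, c(401L, 531L))
  expect_equal(r2$end, c(530L, 660L))
  # summits >= 2F apart are unmodified
  r3 <- define_regions(c(501L, 801L), 100L)
  expect_equal(r3$start, c(401L, 701L))
  expect_equal(r3$end, c(600L, 900L))
  # property: disjoint, each region contains its summit
  set.seed(17)
  s <- sort(sample(1000:5000, 25))
  r <- define_regions(s, 100L)
  expect_true(all(r$start <= r$summit & r$summit <= r$end))
  expect_true(all(r$end[-nrow(r)] < r$start[-1]))
})

test_that("test_enrichment is the one-sided hypergeometric tail", {
  # identical proportions: no evidence of enrichment
  expect_gte(test_enrichment(10, 10, 1000, 1000), 0.5)
  # extreme table (10,0; 0,10): p = 1 / C(20,10)
  expect_equal(test_enrichment(10, 0, 10, 10), 1 / choose(20, 10))
  # no IP reads: p = 1
  expect_equal(test_enrichment(0, 5, 100, 100), 1.0)
  # zero totals warn and return 1
  expect_warning(p <- test_enrichment(0, 0, 0, 10), "zero")
  expect_equal(p, 1.0)
  # agreement with fisher.test on random tables
  set.seed(19)
  for (i in 1:25) {
    N1 <- sample(5:150, 1); N2 <- sample(5:150, 1)
    a <- sample(0:N1, 1); b <- sample(0:N2, 1)
    ft <- stats::fisher.test(matrix(c(a, N1 - a, b, N2 - b), 2,
                                    byrow = TRUE),
                             alternative = "greater")
    expect_equal(test_enrichment(a, b, N1, N2), ft$p.value,
                 tolerance = 1e-9)
  }
})

test_that("adjust_fdr implements BH, BY and Bonferroni", {
  expect_equal(adjust_fdr(0.03, "bh"), 0.03)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03), "bh"), rep(0.03, 3))
  expect_equal(adjust_fdr(0.2, "bonferroni"), 0.2)
  expect_equal(adjust_fdr(rep(0.2, 10), "bonferroni"), rep(1.0, 10))
  expect_equal(adjust_fdr(c(0.5, 0.1), "none"), c(0.5, 0.1))
  expect_error(adjust_fdr(0.1, "qvalue"), "arg")
  # bonferroni dominates BH pointwise; BH q monotone in sorted p order
  set.seed(23)
  p <- runif(100)
  bh <- adjust_fdr(p, "bh")
  expect_true(all(adjust_fdr(p, "bonferroni") >= bh - 1e-12))
  expect_true(!is.unsorted(bh[order(p)]))
})

test_that("apply_filters flags low enrichment, coverage, significance", {
  peaks <- data.frame(chrom = "c", summit = 1:3, start = 1:3, end = 4:6,
                      ip_count = c(25L, 19L, 25L), input_count = 1L,
                      enrichment = c(1.5, 2.5, 2.5),
                      q_value = c(0.01, 0.01, 0.01),
                      p_value = 0.001, flags = "")
  out <- apply_filters(peaks, peak_config())
  expect_match(out$flags[1], "low_enrichment")
  expect_match(out$flags[2], "low_coverage")
  expect_true(out$retained[3])
  expect_equal(out$flags[3], "")
  out2 <- apply_filters(transform(peaks, q_value = 0.2), peak_config())
  expect_true(all(grepl("not_significant", out2$flags)))
})

test_that("reproducibility filter keeps peaks matched in all replicates", {
  mk <- function(summits) data.frame(
    chrom = "c", summit = summits, start = summits - 10L,
    end = summits + 10L, ip_count = 30L, input_count = 5L,
    enrichment = 3, p_value = 1e-5, q_value = 1e-4, flags = "",
    retained = TRUE)
  r <- reproducibility_filter(list(mk(c(1000L, 5000L)), mk(1005L)), 50L)
  expect_true(r[[1]]$retained[1])
  expect_match(r[[1]]$flags[2], "not_reproducible")
  expect_true(r[[2]]$retained[1])
  expect_warning(reproducibility_filter(list(mk(1L)), 50L), "replicates")

  # three replicates vs brute-force all-replicate matching
  sets <- list(mk(c(100L, 300L, 900L)), mk(c(120L, 310L)),
               mk(c(95L, 905L)))
  out <- reproducibility_filter(sets, 50L)
  brute <- function(i, k) {
    s <- sets[[i]]$summit[k]
    all(vapply(seq_along(sets)[-i], function(j)
      any(abs(sets[[j]]$summit - s) <= 50L), logical(1)))
  }
  for (i in seq_along(sets))
    for (k in seq_len(nrow(sets[[i]])))
      expect_equal(out[[i]]$retained[k], brute(i, k))
})

test_that("call_peaks finds planted sites and nothing on the null", {
  sim <- .shared_sim()
  peaks <- call_peaks(sim$exp$ip_bam, sim$exp$input_bam, peak_config(),
                      exons = sim$ref$exon_model)
  ev <- truth_eval(peaks, sim$ref$truth)
  expect_gte(ev$recall, 0.8)
  expect_gte(ev$precision, 0.8)

  # IP tested against itself: no retained peaks at defaults
  null_peaks <- call_peaks(sim$exp$ip_bam, sim$exp$ip_bam, peak_config())
  expect_equal(sum(null_peaks$retained), 0L)

  # determinism
  peaks2 <- call_peaks(sim$exp$ip_bam, sim$exp$input_bam, peak_config(),
                       exons = sim$ref$exon_model)
  expect_equal(peaks$summit, peaks2$summit)
  expect_equal(peaks$p_value, peaks2$p_value)
})

test_that("chromosome-disjoint BAMs are a fatal error", {
  b1 <- make_bam(sam_rec("r1", 0L, "chr1", 100, "30M"),
                 seqlens = c(chr1 = 10000L))
  b2 <- make_bam(sam_rec("r1", 0L, "chrOther", 100, "30M"),
                 seqlens = c(chrOther = 10000L))
  expect_error(call_peaks(b1, b2), "common chromosomes")
})
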