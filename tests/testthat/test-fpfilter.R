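mk_peaks <- function(summits, enrichment) {
  data.frame(chrom = "c", summit = summits, start = summits - 100L,
             end = summits + 99L, ip_count = 50L, input_count = 10L,
             enrichment = enrichment, p_value = 1e-6, q_value = 1e-5,
             flags = "", retained = TRUE)
}

test_that("knockdown labeling follows the detection and change rules", {
  ctrl <- mk_peaks(c(1000L, 3000L, 5000L), c(4, 4, 4))
  kd <- mk_peaks(c(3010L, 5020L), c(3.2, 1.5))
  lab <- label_training_peaks(ctrl, kd, match_window = 50L)
  # peak 1000: absent in knockdown -> TP
  expect_equal(lab$label[lab$summit == 1000L], "TP")
  # peak 3000: matched, |3.2-4|/4 = 0.2 < 0.5 -> FP
  expect_equal(lab$label[lab$summit == 3000L], "FP")
  # peak 5000: matched, |1.5-4|/4 = 0.625 -> unlabeled (dropped)
  expect_false(5000L %in% lab$summit)
  expect_error(label_training_peaks(ctrl[0, ], kd), "non-empty")
})

test_that("encode_peak_sequence centres the M and pads contig ends", {
  seqs <- Biostrings::DNAStringSet(c(chr = paste0(
    strrep("C", 4999), "A", strrep("G", 5000))))
  s <- encode_peak_sequence("chr", 5000L, seqs)
  expect_equal(nchar(s), 200L)
  expect_equal(substr(s, 101, 101), "M")
  expect_equal(substr(s, 100, 100), "C")
  expect_equal(substr(s, 102, 102), "G")
  # minus strand: reverse complement, M still at index 101
  sm <- encode_peak_sequence("chr", 5000L, seqs, strand = "-")
  expect_equal(substr(sm, 101, 101), "M")
  expect_equal(substr(sm, 100, 100), "C")  # complement of the G side
  # windows past the contig end are N-padded
  se <- encode_peak_sequence("chr", 9990L, seqs)
  expect_equal(substr(se, 101, 101), "M")
  expect_true(grepl("N+$", se))
})

test_that("a planted GGACT context surrounds the encoded site", {
  cfg <- sim_config(n_transcripts = 2L, depth = 100L, seed = 3L)
  ref <- simulate_reference(cfg)
  site <- ref$truth[1, ]
  s <- encode_peak_sequence(site$chrom, site$pos, ref$seqs)
  expect_equal(substr(s, 99, 103), "GGMCT")
})

test_that("MTD likelihood matches closed forms and a hand oracle", {
  # deterministic cycle A->C->G->T->A: one-hot rows give log-lik 0
  Q <- matrix(0, 5, 5, dimnames = list(meripeaks:::MTD_ALPHABET,
                                       meripeaks:::MTD_ALPHABET))
  Q["A", "C"] <- Q["C", "G"] <- Q["G", "T"] <- Q["T", "A"] <- 1
  Q["M", "A"] <- 1
  det_model <- structure(list(order = 1L, lambda = 1, Q = Q,
                              shared_q = TRUE), class = "mtd_model")
  expect_equal(mtd_loglik(det_model, "ACGTACGTACGT"), 0)

  # uniform model: (len - L) * log(1/5)
  Qu <- matrix(1 / 5, 5, 5)
  uni <- structure(list(order = 1L, lambda = 1, Q = Qu, shared_q = TRUE),
                   class = "mtd_model")
  expect_equal(mtd_loglik(uni, "ACGTACGTAC"), 9 * log(1 / 5))

  # order-2 hand-computed oracle on a 10-nt toy sequence
  lam <- c(0.7, 0.3)
  set.seed(8)
  Q2 <- matrix(runif(25), 5, 5); Q2 <- Q2 / rowSums(Q2)
  m2 <- structure(list(order = 2L, lambda = lam, Q = Q2, shared_q = TRUE),
                  class = "mtd_model")
  s <- "ACGTMACGTA"
  x <- match(strsplit(s, "")[[1]], meripeaks:::MTD_ALPHABET)
  oracle <- 0
  for (t in 3:10)
    oracle <- oracle + log(lam[1] * Q2[x[t - 1], x[t]] +
                             lam[2] * Q2[x[t - 2], x[t]])
  expect_equal(mtd_loglik(m2, s), oracle)

  # N positions are skipped
  expect_equal(mtd_loglik(uni, "ACNTA"), 2 * log(1 / 5))
  expect_error(mtd_loglik(uni, "ACXTA"), "symbol")
})

test_that("MTD training recovers a generating order-1 chain", {
  set.seed(12)
  Qg <- matrix(c(.6, .1, .1, .1, .1,
                 .2, .4, .2, .1, .1,
                 .1, .2, .4, .2, .1,
                 .1, .1, .2, .4, .2,
                 .2, .2, .2, .2, .2), 5, 5, byrow = TRUE)
  gen <- function(n) {
    x <- integer(n); x[1] <- 1L
    for (t in 2:n) x[t] <- sample.int(5L, 1L, prob = Qg[x[t - 1L], ])
    paste(meripeaks:::MTD_ALPHABET[x], collapse = "")
  }
  m <- mtd_train(list(gen(20000L)), order = 1L, min_seqs = 1L)
  expect_lt(max(abs(m$Q - Qg)), 0.05)
  expect_true(all(diff(m$loglik_trace) >= -1e-6))
  expect_equal(unname(rowSums(m$Q)), rep(1, 5), tolerance = 1e-9)
  expect_equal(sum(m$lambda), 1, tolerance = 1e-9)

  # near-uniform sequences give near-uniform rows over observed symbols
  set.seed(13)
  iid <- replicate(60, paste(sample(c("A", "C", "G", "T"), 300,
                                    replace = TRUE), collapse = ""))
  mu <- mtd_train(as.list(iid), order = 2L)
  expect_lt(max(abs(mu$Q[1:4, 1:4] - 0.25)), 0.05)

  # floor on the training set size
  expect_error(mtd_train(list("ACGT")), "at least")
})

test_that("feature extraction follows the documented schema", {
  schema <- feature_schema()
  expect_equal(length(schema), 7L + 4L + 16L + 64L)
  uni <- structure(list(order = 1L, lambda = 1,
                        Q = matrix(1 / 5, 5, 5), shared_q = TRUE),
                   class = "mtd_model")
  peak <- mk_peaks(5000L, 4)[1, ]
  win <- paste0(strrep("A", 100), "M", strrep("A", 99))
  f <- extract_features(peak, win, uni, uni)
  expect_equal(colnames(f), schema)
  # all-A window: A count is 199 (M is excluded from k-mer counting)
  expect_equal(f$kmer_A, 199)
  expect_equal(f$mtd_llr, 0)  # identical models
  # k = 1 counts sum to 200 - (#N) - 1 (the M)
  expect_equal(sum(f[paste0("kmer_", c("A", "C", "G", "T"))]), 199)
  # determinism
  f2 <- extract_features(peak, win, uni, uni)
  expect_identical(f, f2)
  # the AAACA context contains a consensus: distance 0 from the M
  win2 <- paste0(strrep("C", 98), "AA", "M", "CA", strrep("C", 97))
  f3 <- extract_features(peak, win2, uni, uni)
  expect_equal(f3$consensus_dist, 0)
})

test_that("classifier scoring is thresholdable and schema-checked", {
  set.seed(15)
  n <- 300
  X <- data.frame(f1 = c(rnorm(n / 2, 0), rnorm(n / 2, 2)),
                  f2 = rnorm(n))
  y <- rep(c("FP", "TP"), each = n / 2)
  m <- train_classifier(X, y, n_trees = 200L, mtry = 1L, seed = 4L)
  sc <- score_peaks(m, X)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  # threshold 0: everything TP; threshold 1: only unanimous votes
  expect_true(all(score_peaks(m, X, threshold = 0)$label == "TP"))
  hi <- score_peaks(m, X, threshold = 1)
  expect_true(all(hi$label[hi$score < 1] == "FP"))
  # raising the threshold never increases recall
  rec <- vapply(c(0.2, 0.5, 0.8), function(th)
    mean(score_peaks(m, X, th)$label[y == "TP"] == "TP"), numeric(1))
  expect_true(all(diff(rec) <= 0))
  # schema mismatch is fatal and names the difference
  expect_error(score_peaks(m, data.frame(f1 = 1, wrong = 2)), "schema")
  # single-class training refused
  expect_error(train_classifier(X, rep("TP", n)), "both classes")
})

test_that("fp filter flags scored-out peaks but keeps them in output", {
  peaks <- mk_peaks(c(100L, 200L), c(4, 4))
  scores <- data.frame(score = c(0.9, 0.2), label = c("TP", "FP"))
  out <- apply_fp_filter(peaks, scores)
  expect_equal(out$fp_score, c(0.9, 0.2))
  expect_true(out$retained[1])
  expect_false(out$retained[2])
  expect_match(out$flags[2], "fp_filtered")
  expect_equal(nrow(out), 2L)
})
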