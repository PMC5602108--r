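## Alphabet for peak sequences: the four nucleotides plus M, the called
## methylated adenosine. N marks missing bases and is excluded from
## likelihood computations.
MTD_ALPHABET <- c("A", "C", "G", "T", "M")

#' Label training peaks from a knockdown/control pair
#'
#' Builds a supervised training set from peaks called in a
#' methyltransferase-knockdown sample and its matched control. A control
#' peak with no knockdown peak within \code{match_window} nt of its
#' summit is a high-confidence true positive (methylation collapses when
#' the writer is depleted). A matched peak whose relative enrichment
#' change between knockdown and control is below 0.5-fold is a technical
#' false positive (insensitive to the knockdown). Matched peaks with
#' larger changes are left unlabeled and excluded.
#'
#' @param control_peaks,knockdown_peaks Peak data.frames.
#' @param match_window Summit distance (nt) counting as "detected in
#'   both" (default 50).
#' @return The control peak data.frame restricted to labeled rows, with a
#'   \code{label} column (\code{"TP"} / \code{"FP"}) and
#'   \code{kd_enrichment}.
#' @export
label_training_peaks <- function(control_peaks, knockdown_peaks,
                                 match_window = 50L) {
  if (nrow(control_peaks) == 0L || nrow(knockdown_peaks) == 0L)
    stop("both control and knockdown peak sets must be non-empty")
  lab <- character(nrow(control_peaks))
  kd_enr <- rep(NA_real_, nrow(control_peaks))
  for (i in seq_len(nrow(control_peaks))) {
    same <- which(knockdown_peaks$chrom == control_peaks$chrom[i])
    if (length(same) > 0L) {
      d <- abs(knockdown_peaks$summit[same] - control_peaks$summit[i])
      j <- same[which.min(d)]
      if (min(d) <= match_window) {
        kd_enr[i] <- knockdown_peaks$enrichment[j]
        change <- abs(kd_enr[i] - control_peaks$enrichment[i]) /
          control_peaks$enrichment[i]
        lab[i] <- if (change < 0.5) "FP" else ""
        next
      }
    }
    lab[i] <- "TP"
  }
  out <- control_peaks[lab != "", , drop = FALSE]
  out$label <- lab[lab != ""]
  out$kd_enrichment <- kd_enr[lab != ""]
  rownames(out) <- NULL
  out
}

#' Encode a peak as a 200-nt M-marked sequence
#'
#' Extracts the 200-nt window centred on the called site (deconvolved
#' site when available, else the adenosine nearest the summit, else the
#' summit itself), replaces the site base with \code{M}, and pads windows
#' running past contig ends with \code{N}. Minus-strand peaks are
#' reverse-complemented before marking, so the M is always at position
#' 101 (1-based) in 5'-to-3' orientation.
#'
#' @param chrom,site Site position.
#' @param seqs Reference sequences (see [deconvolute_peaks()]).
#' @param strand \code{"+"} (default) or \code{"-"}.
#' @param width Window width (default 200).
#' @return Character scalar of length \code{width} over
#'   \{A,C,G,T,M,N\}.
#' @export
encode_peak_sequence <- function(chrom, site, seqs, strand = "+",
                                 width = 200L) {
  seqs <- load_seqs(seqs)
  if (!(chrom %in% names(seqs))) stop("chromosome not in reference: ", chrom)
  half <- width %/% 2L
  ## the marked site must land at index half + 1 after any reverse
  ## complementing, so the minus-strand window is shifted by one
  st <- if (strand == "-") site - (width - half - 1L) else site - half
  en <- st + width - 1L
  clen <- length(seqs[[chrom]])
  a <- max(1L, st); b <- min(clen, en)
  core <- if (a <= b) as.character(Biostrings::subseq(seqs[[chrom]], a, b))
  else ""
  pad_l <- strrep("N", max(0L, a - st))
  pad_r <- strrep("N", max(0L, en - b))
  s <- paste0(pad_l, toupper(core), pad_r)
  if (nchar(s) != width) s <- strrep("N", width)
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(chartr("N", "N", s))))
  }
  m_at <- half + 1L
  substr(s, m_at, m_at) <- "M"
  s
}

## split sequences into integer symbol matrices; returns list of integer
## vectors (1..5, NA for N)
seq_to_int <- function(seqs) {
  lapply(seqs, function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    bad <- !(ch %in% c(MTD_ALPHABET, "N"))
    if (any(bad))
      stop("symbol outside {A,C,G,T,M,N} in sequence: ",
           paste(unique(ch[bad]), collapse = ","))
    match(ch, MTD_ALPHABET)  # N -> NA
  })
}

## stack all (context, target) transition rows across sequences:
## matrix with columns lag1..lagL, target; rows with any NA dropped
mtd_transitions <- function(int_seqs, order) {
  rows <- lapply(int_seqs, function(x) {
    n <- length(x)
    if (n <= order) return(NULL)
    t_idx <- (order + 1L):n
    ctx <- vapply(seq_len(order), function(l) x[t_idx - l], integer(length(t_idx)))
    cbind(matrix(ctx, ncol = order), x[t_idx])
  })
  m <- do.call(rbind, rows)
  if (is.null(m) || nrow(m) == 0L) stop("no usable transitions")
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Train a mixture transition distribution (MTD) sequence model
#'
#' The MTD model approximates an order-L Markov chain in linear
#' parameter space: \code{P(x_t | x_{t-L..t-1}) = sum_l lambda_l
#' Q[x_{t-l}, x_t]} with a single shared row-stochastic transition
#' matrix Q and lag weights lambda on the simplex. Parameters are
#' estimated by maximum likelihood using an EM ascent in which the
#' contributing lag is the latent variable; the training log-likelihood
#' is non-decreasing at every iteration. Initialisation is
#' deterministic: uniform lambda and Q from pooled lag-1 counts, so
#' training is reproducible. A per-lag-Q variant (MTDg) is available via
#' \code{shared_q = FALSE}.
#'
#' @param seqs Character vector of sequences over \{A,C,G,T,M,N\};
#'   N positions are excluded.
#' @param order Number of lags L (default 5).
#' @param max_iter,tol EM stopping rule.
#' @param pseudocount Additive smoothing for Q rows (default 0.5).
#' @param shared_q Classical MTD (single Q, default) or MTDg (one Q per
#'   lag).
#' @param min_seqs Floor on the number of training sequences (default 50).
#' @return An \code{mtd_model}: \code{order}, \code{lambda}, \code{Q}
#'   (or \code{Q_list}), \code{loglik_trace}, \code{converged},
#'   \code{n_transitions}.
#' @export
mtd_train <- function(seqs, order = 5L, max_iter = 100L, tol = 1e-6,
                      pseudocount = 0.5, shared_q = TRUE, min_seqs = 50L) {
  if (length(seqs) < min_seqs)
    stop("need at least ", min_seqs, " training sequences (got ",
         length(seqs), "); lower min_seqs to override")
  int_seqs <- seq_to_int(seqs)
  trans <- mtd_transitions(int_seqs, order)
  A <- length(MTD_ALPHABET)
  tgt <- trans[, order + 1L]
  n <- nrow(trans)

  ## init: uniform lambda, Q from pooled lag-1 bigram counts
  lambda <- rep(1 / order, order)
  cnt <- matrix(pseudocount, A, A)
  t1 <- table(factor(trans[, 1L], levels = 1:A),
              factor(tgt, levels = 1:A))
  cnt <- cnt + as.matrix(t1)
  Q <- cnt / rowSums(cnt)
  Qs <- if (shared_q) NULL else replicate(order, Q, simplify = FALSE)

  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ## per-lag component probabilities for every transition row
    P <- vapply(seq_len(order), function(l) {
      Ql <- if (shared_q) Q else Qs[[l]]
      lambda[l] * Ql[cbind(trans[, l], tgt)]
    }, numeric(n))
    denom <- rowSums(P)
    denom[denom < 1e-300] <- 1e-300
    ll <- sum(log(denom))
    ll_trace <- c(ll_trace, ll)
    if (it > 1L && abs(ll - ll_trace[it - 1L]) < tol * abs(ll)) {
      converged <- TRUE
      break
    }
    R <- P / denom
    lambda <- colMeans(R)
    lambda <- lambda / sum(lambda)
    if (shared_q) {
      cnt <- matrix(pseudocount, A, A)
      for (l in seq_len(order)) {
        acc <- rowsum(R[, l], group = (trans[, l] - 1L) * A + tgt)
        idx <- as.integer(rownames(acc))
        cnt[cbind((idx - 1L) %/% A + 1L, (idx - 1L) %% A + 1L)] <-
          cnt[cbind((idx - 1L) %/% A + 1L, (idx - 1L) %% A + 1L)] + acc[, 1L]
      }
      Q <- cnt / rowSums(cnt)
    } else {
      for (l in seq_len(order)) {
        cnt <- matrix(pseudocount, A, A)
        acc <- rowsum(R[, l], group = (trans[, l] - 1L) * A + tgt)
        idx <- as.integer(rownames(acc))
        cnt[cbind((idx - 1L) %/% A + 1L, (idx - 1L) %% A + 1L)] <-
          cnt[cbind((idx - 1L) %/% A + 1L, (idx - 1L) %% A + 1L)] + acc[, 1L]
        Qs[[l]] <- cnt / rowSums(cnt)
      }
    }
  }
  dimnames_q <- list(MTD_ALPHABET, MTD_ALPHABET)
  if (shared_q) dimnames(Q) <- dimnames_q
  else Qs <- lapply(Qs, function(q) { dimnames(q) <- dimnames_q; q })
  structure(list(order = order, lambda = lambda,
                 Q = if (shared_q) Q else NULL,
                 Q_list = if (shared_q) NULL else Qs,
                 shared_q = shared_q,
                 loglik_trace = ll_trace, converged = converged,
                 n_transitions = n),
            class = "mtd_model")
}

#' @export
print.mtd_model <- function(x, ...) {
  cat("mtd_model: order", x$order,
      if (x$shared_q) "(shared Q)" else "(per-lag Q)",
      "- lambda:", paste(format(x$lambda, digits = 3), collapse = ", "),
      "\n  trained on", x$n_transitions, "transitions,",
      length(x$loglik_trace), "EM iterations",
      if (x$converged) "(converged)" else "", "\n")
  invisible(x)
}

#' Log-likelihood of a sequence under an MTD model
#'
#' \code{sum_t log sum_l lambda_l Q[x_{t-l}, x_t]} for t from L+1 to the
#' sequence end; positions whose target or required context contains N
#' are skipped.
#'
#' @param model An \code{mtd_model}.
#' @param seq Character sequence over \{A,C,G,T,M,N\}.
#' @return Log-likelihood (0 transitions gives 0).
#' @export
mtd_loglik <- function(model, seq) {
  x <- seq_to_int(list(seq))[[1]]
  order <- model$order
  n <- length(x)
  if (n <= order) return(0)
  t_idx <- (order + 1L):n
  ctx <- vapply(seq_len(order), function(l) x[t_idx - l],
                integer(length(t_idx)))
  ctx <- matrix(ctx, ncol = order)
  tgt <- x[t_idx]
  ok <- stats::complete.cases(cbind(ctx, tgt))
  if (!any(ok)) return(0)
  ctx <- ctx[ok, , drop = FALSE]; tgt <- tgt[ok]
  P <- vapply(seq_len(order), function(l) {
    Ql <- if (model$shared_q) model$Q else model$Q_list[[l]]
    model$lambda[l] * Ql[cbind(ctx[, l], tgt)]
  }, numeric(length(tgt)))
  if (is.null(dim(P))) P <- matrix(P, nrow = length(tgt))
  sum(log(pmax(rowSums(P), 1e-300)))
}

#' Feature schema of the false-positive classifier
#'
#' Versioned, fixed-order column set. Categories: the MTD log-likelihood
#' ratio (TP model minus FP model), distance to the nearest RRACH
#' consensus, k-mer composition of the 200-nt window for k = 1..3
#' (k-mers containing M or N are skipped), peak attributes (enrichment,
#' IP count, region width), and transcript-level context (feature class,
#' exon length). Optional plug-in columns (e.g. conservation, miRNA
#' sites) can be appended by name at training and scoring time.
#'
#' @return Character vector of feature column names.
#' @export
feature_schema <- function() {
  b <- c("A", "C", "G", "T")
  k1 <- b
  k2 <- as.vector(outer(b, b, paste0))
  k3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  c("mtd_llr", "consensus_dist", "enrichment", "ip_count", "region_width",
    "exon_length", "feature_class",
    paste0("kmer_", c(k1, k2, k3)))
}

FEATURE_CLASS_LEVELS <- c("5UTR", "CDS", "3UTR", "exonic", "intronic",
                          "unknown")

count_kmers <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < k) return(table(factor(character(0))))
  idx <- seq_len(n - k + 1L)
  kmers <- vapply(idx, function(i) paste(ch[i:(i + k - 1L)], collapse = ""),
                  character(1))
  kmers <- kmers[!grepl("[MN]", kmers)]
  kmers
}

#' Extract the classifier feature vector for one peak
#'
#' @param peak Single-row peak data.frame.
#' @param seq 200-nt encoded peak sequence (from
#'   [encode_peak_sequence()]).
#' @param mtd_tp,mtd_fp Trained MTD models for the TP and FP classes.
#' @param exons Optional \code{exon_model}; without it transcript-level
#'   features take sentinel values (class \code{"unknown"}, exon length
#'   -1).
#' @param motif Consensus motif (default \code{"RRACH"}); distance
#'   sentinel 999 when no occurrence is in the window.
#' @return Single-row data.frame following [feature_schema()].
#' @export
extract_features <- function(peak, seq, mtd_tp, mtd_fp, exons = NULL,
                             motif = "RRACH") {
  llr <- mtd_loglik(mtd_tp, seq) - mtd_loglik(mtd_fp, seq)
  win <- chartr("M", "A", seq)  # M is an adenosine for motif purposes
  half <- nchar(seq) %/% 2L
  cd <- tryCatch(nearest_consensus(half + 1L, win, 1L, motif),
                 error = function(e) NA_integer_)
  if (is.na(cd)) cd <- 999L
  cls <- "unknown"; exlen <- -1
  if (!is.null(exons)) {
    cls <- feature_class(peak$chrom, peak$summit, exons)
    hit <- GenomicRanges::GRanges(peak$chrom,
                                  IRanges::IRanges(peak$summit, peak$summit))
    all_ex <- unlist(exons$exons, use.names = FALSE)
    ov <- GenomicRanges::findOverlaps(hit, all_ex, ignore.strand = TRUE)
    if (length(ov) > 0L)
      exlen <- max(GenomicRanges::width(all_ex[S4Vectors::subjectHits(ov)]))
  }
  out <- data.frame(mtd_llr = llr, consensus_dist = as.numeric(cd),
                    enrichment = peak$enrichment,
                    ip_count = as.numeric(peak$ip_count),
                    region_width = as.numeric(peak$end - peak$start + 1L),
                    exon_length = as.numeric(exlen),
                    feature_class = factor(cls, levels = FEATURE_CLASS_LEVELS),
                    stringsAsFactors = FALSE)
  for (k in 1:3) {
    km <- count_kmers(seq, k)
    lv <- feature_schema()
    lv <- sub("^kmer_", "", lv[startsWith(lv, "kmer_")])
    lv <- lv[nchar(lv) == k]
    tab <- table(factor(km, levels = lv))
    out[paste0("kmer_", lv)] <- as.numeric(tab)
  }
  out[, feature_schema(), drop = FALSE]
}

#' Build the feature matrix for a peak table
#'
#' @param peaks Peak data.frame; sites (if deconvolved) are used as the
#'   sequence centre, otherwise the summit-nearest adenosine, otherwise
#'   the summit.
#' @param seqs Reference sequences.
#' @param mtd_tp,mtd_fp Trained MTD models.
#' @param exons Optional \code{exon_model}.
#' @return data.frame of features, one row per peak, plus the encoded
#'   sequences as attribute \code{"sequences"}.
#' @export
peak_features <- function(peaks, seqs, mtd_tp, mtd_fp, exons = NULL) {
  seqs <- load_seqs(seqs)
  enc <- vapply(seq_len(nrow(peaks)), function(i)
    encode_peak_sequence(peaks$chrom[i], peak_site(peaks[i, ], seqs), seqs),
    character(1))
  rows <- lapply(seq_len(nrow(peaks)), function(i)
    extract_features(peaks[i, ], enc[i], mtd_tp, mtd_fp, exons))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sequences") <- enc
  out
}

#' Resolve the site position used for sequence encoding
#'
#' Deconvolved site when present, else the adenosine nearest the summit
#' (within 50 nt), else the summit itself.
#'
#' @param peak Single-row peak data.frame.
#' @param seqs Reference sequences.
#' @return Integer position.
#' @export
peak_site <- function(peak, seqs) {
  if (!is.null(peak$site_pos) && !is.na(peak$site_pos))
    return(peak$site_pos)
  seqs <- load_seqs(seqs)
  if (peak$chrom %in% names(seqs)) {
    clen <- length(seqs[[peak$chrom]])
    a <- max(1L, peak$summit - 50L); b <- min(clen, peak$summit + 50L)
    if (a <= b) {
      win <- Biostrings::subseq(seqs[[peak$chrom]], a, b)
      as_pos <- candidate_sites(win, origin = a)
      if (length(as_pos) > 0L)
        return(as_pos[which.min(abs(as_pos - peak$summit))])
    }
  }
  peak$summit
}

#' Train the false-positive random forest
#'
#' Bagged random-decision-tree ensemble over the documented feature
#' schema; the classifier score of a peak is the fraction of trees voting
#' TP. Defaults follow the published configuration: 1000 trees, six
#' candidate features per split.
#'
#' @param features Feature data.frame (rows = peaks).
#' @param labels Character/factor vector of \code{"TP"} / \code{"FP"}.
#' @param n_trees,mtry Forest size and per-split feature count.
#' @param seed Integer seed; training is reproducible.
#' @return An \code{fp_classifier}: the forest, the schema, out-of-bag
#'   error estimate.
#' @export
train_classifier <- function(features, labels, n_trees = 1000L, mtry = 6L,
                             seed = 1L) {
  labels <- factor(as.character(labels), levels = c("FP", "TP"))
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stop("both classes (TP and FP) must be present in the training labels")
  stopifnot(nrow(features) == length(labels))
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = features, y = labels,
                                   ntree = as.integer(n_trees),
                                   mtry = as.integer(mtry))
  structure(list(forest = rf, schema = colnames(features),
                 oob_error = mean(rf$err.rate[n_trees, "OOB"]),
                 n_trees = n_trees, mtry = mtry, seed = seed),
            class = "fp_classifier")
}

#' @export
print.fp_classifier <- function(x, ...) {
  cat("fp_classifier:", x$n_trees, "trees, mtry", x$mtry,
      "- OOB error", format(x$oob_error, digits = 3), "\n")
  invisible(x)
}

#' Score peaks with the false-positive classifier
#'
#' @param model An \code{fp_classifier}.
#' @param features Feature data.frame matching the training schema
#'   (mismatch is fatal and reports the column difference).
#' @param threshold Scores below this are labeled FP (default 0.5); the
#'   threshold is the precision/recall bias knob.
#' @return data.frame with \code{score} (TP vote fraction) and
#'   \code{label}.
#' @export
score_peaks <- function(model, features, threshold = 0.5) {
  missing <- setdiff(model$schema, colnames(features))
  extra <- setdiff(colnames(features), model$schema)
  if (length(missing) > 0L || length(extra) > 0L)
    stop("feature schema mismatch; missing: [",
         paste(missing, collapse = ", "), "] unexpected: [",
         paste(extra, collapse = ", "), "]")
  votes <- stats::predict(model$forest,
                          features[, model$schema, drop = FALSE],
                          type = "vote", norm.votes = TRUE)
  score <- votes[, "TP"]
  data.frame(score = as.numeric(score),
             label = ifelse(score >= threshold, "TP", "FP"),
             stringsAsFactors = FALSE)
}

#' Attach classifier scores to a peak table
#'
#' Peaks labeled FP gain the \code{fp_filtered} flag (they stay in the
#' full output).
#'
#' @param peaks Peak data.frame.
#' @param scores Output of [score_peaks()] for the same rows.
#' @return Updated peak data.frame with \code{fp_score} column.
#' @export
apply_fp_filter <- function(peaks, scores) {
  stopifnot(nrow(peaks) == nrow(scores))
  peaks$fp_score <- scores$score
  fp <- scores$label == "FP"
  peaks$flags[fp] <- paste_flag(peaks$flags[fp], "fp_filtered")
  peaks$retained <- peaks$retained & !fp
  peaks
}
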