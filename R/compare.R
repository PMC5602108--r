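#' Match peaks across samples
#'
#' Greedy nearest-summit matching: all cross-sample summit pairs within
#' \code{window} nt are considered in order of increasing distance and
#' merged into records, subject to each record holding at most one peak
#' per sample. Unmatched peaks become singleton records. The procedure
#' is symmetric in the sample order.
#'
#' @param peak_sets Named list of peak data.frames (names are sample
#'   ids).
#' @param window Maximum summit distance (nt) for a match (default 50).
#' @return data.frame of comparison records: \code{chrom},
#'   \code{matched_summit} (mean of member summits), per-sample
#'   \code{present_<s>}, \code{summit_<s>}, \code{enrichment_<s>},
#'   \code{p_<s>}, \code{q_<s>}, and for every sample pair
#'   \code{log2fc_<A>_vs_<B>}.
#' @export
match_peaks <- function(peak_sets, window = 50L) {
  stopifnot(length(peak_sets) >= 2L)
  if (is.null(names(peak_sets)) || any(names(peak_sets) == ""))
    names(peak_sets) <- paste0("sample", seq_along(peak_sets))
  samples <- names(peak_sets)
  all <- do.call(rbind, lapply(samples, function(s) {
    p <- peak_sets[[s]]
    if (nrow(p) == 0L) return(NULL)
    data.frame(sample = s, chrom = p$chrom, summit = p$summit,
               enrichment = p$enrichment, p_value = p$p_value,
               q_value = p$q_value, stringsAsFactors = FALSE)
  }))
  if (is.null(all) || nrow(all) == 0L)
    stop("no peaks in any sample")
  n <- nrow(all)
  cluster <- seq_len(n)

  ## candidate cross-sample pairs within window, closest first
  pairs <- list()
  for (chrom in unique(all$chrom)) {
    ix <- which(all$chrom == chrom)
    if (length(ix) < 2L) next
    cmb <- utils::combn(ix, 2L)
    d <- abs(all$summit[cmb[1, ]] - all$summit[cmb[2, ]])
    keep <- d <= window & all$sample[cmb[1, ]] != all$sample[cmb[2, ]]
    if (any(keep))
      pairs[[chrom]] <- data.frame(i = cmb[1, keep], j = cmb[2, keep],
                                   d = d[keep])
  }
  if (length(pairs) > 0L) {
    pr <- do.call(rbind, pairs)
    pr <- pr[order(pr$d, pr$i, pr$j), , drop = FALSE]
    for (r in seq_len(nrow(pr))) {
      ci <- cluster[pr$i[r]]; cj <- cluster[pr$j[r]]
      if (ci == cj) next
      si <- all$sample[cluster == ci]; sj <- all$sample[cluster == cj]
      if (length(intersect(si, sj)) > 0L) next  # one peak per sample
      cluster[cluster == cj] <- ci
    }
  }

  recs <- lapply(unique(cluster), function(cl) {
    m <- all[cluster == cl, , drop = FALSE]
    rec <- data.frame(chrom = m$chrom[1],
                      matched_summit = round(mean(m$summit)),
                      stringsAsFactors = FALSE)
    for (s in samples) {
      row <- m[m$sample == s, , drop = FALSE]
      present <- nrow(row) == 1L
      rec[[paste0("present_", s)]] <- present
      rec[[paste0("summit_", s)]] <- if (present) row$summit else NA_integer_
      rec[[paste0("enrichment_", s)]] <- if (present) row$enrichment else NA_real_
      rec[[paste0("p_", s)]] <- if (present) row$p_value else NA_real_
      rec[[paste0("q_", s)]] <- if (present) row$q_value else NA_real_
    }
    rec
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$chrom, out$matched_summit), , drop = FALSE]
  rownames(out) <- NULL
  cmb <- utils::combn(samples, 2L)
  for (k in seq_len(ncol(cmb))) {
    a <- cmb[1, k]; b <- cmb[2, k]
    out[[paste0("log2fc_", a, "_vs_", b)]] <-
      log_fold_change(out[[paste0("enrichment_", a)]],
                      out[[paste0("enrichment_", b)]])
  }
  out
}

#' Pairwise log2 fold enrichment change
#'
#' @param enr_a,enr_b Enrichment folds; nonpositive or missing values
#'   give \code{NA} (blank in text output, not 0).
#' @return \code{log2(enr_a / enr_b)}, antisymmetric under swapping.
#' @export
log_fold_change <- function(enr_a, enr_b) {
  out <- rep(NA_real_, max(length(enr_a), length(enr_b)))
  a <- rep_len(enr_a, length(out)); b <- rep_len(enr_b, length(out))
  ok <- !is.na(a) & !is.na(b) & a > 0 & b > 0
  out[ok] <- log2(a[ok] / b[ok])
  out
}

TSV_DIGITS <- 6L

fmt_num <- function(x) {
  ifelse(is.na(x), "", as.character(signif(x, TSV_DIGITS)))
}

#' Write a per-sample peak TSV
#'
#' One row per peak; positions are 1-based inclusive; numeric fields are
#' written at 6 significant digits; optional columns (gene, consensus
#' distance, classifier score, deconvolved sites) appear when present in
#' the table. Round-trips through [read_peaks_tsv()].
#'
#' @param peaks Peak data.frame.
#' @param path Output path.
#' @param retained_only Write only unflagged peaks (default FALSE: all
#'   peaks, with flags).
#' @return The path, invisibly.
#' @export
write_peaks_tsv <- function(peaks, path, retained_only = FALSE) {
  if (retained_only && nrow(peaks) > 0L)
    peaks <- peaks[peaks$retained, , drop = FALSE]
  base <- c("chrom", "summit", "start", "end", "ip_count", "input_count",
            "enrichment", "p_value", "q_value", "flags", "sample_id")
  opt <- intersect(c("gene", "consensus_dist", "fp_score", "sites",
                     "site_pos", "site_weight", "n_sites"),
                   colnames(peaks))
  cols <- c(base, opt)
  df <- peaks[, cols, drop = FALSE]
  for (cn in cols) {
    if (is.numeric(df[[cn]]) && !is.integer(df[[cn]]))
      df[[cn]] <- fmt_num(df[[cn]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a peak TSV written by [write_peaks_tsv()]
#'
#' @param path Input path.
#' @return Peak data.frame with a recomputed \code{retained} column.
#' @export
read_peaks_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "")
  if (nrow(df) > 0L) {
    df$flags[is.na(df$flags)] <- ""
    df$retained <- df$flags == ""
  } else {
    df$flags <- character(0)
    df$retained <- logical(0)
  }
  df
}

#' Write the cross-sample comparison TSV
#'
#' One row per matched peak key, with per-sample enrichment/significance
#' columns and one \code{log2fc_<A>_vs_<B>} column per sample pair.
#' Absent samples have empty fields (not zeros).
#'
#' @param records Comparison records from [match_peaks()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_comparison_tsv <- function(records, path) {
  df <- records
  for (cn in colnames(df)) {
    if (is.numeric(df[[cn]]) && !is.integer(df[[cn]]))
      df[[cn]] <- fmt_num(df[[cn]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a comparison TSV
#'
#' @param path Input path.
#' @return Comparison data.frame.
#' @export
read_comparison_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "")
}

#' Export peak regions as BED
#'
#' BED6+2: region (0-based half-open), peak name, score scaled from the
#' classifier score or enrichment, strand, and thickStart/thickEnd
#' marking the summit (or deconvolved site) base, for genome-browser
#' display.
#'
#' @param peaks Peak data.frame.
#' @param path Output path.
#' @param retained_only Write only unflagged peaks (default TRUE).
#' @return The path, invisibly.
#' @export
write_peaks_bed <- function(peaks, path, retained_only = TRUE) {
  if (retained_only && nrow(peaks) > 0L)
    peaks <- peaks[peaks$retained, , drop = FALSE]
  mark <- if (!is.null(peaks$site_pos))
    ifelse(is.na(peaks$site_pos), peaks$summit, peaks$site_pos)
  else peaks$summit
  score <- if (!is.null(peaks$fp_score) && !all(is.na(peaks$fp_score)))
    round(1000 * peaks$fp_score)
  else pmin(1000L, round(100 * peaks$enrichment))
  df <- data.frame(chrom = peaks$chrom, start = peaks$start - 1L,
                   end = peaks$end,
                   name = paste0("peak_", seq_len(nrow(peaks))),
                   score = score, strand = ".",
                   thickStart = mark - 1L, thickEnd = mark)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
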