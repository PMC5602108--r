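#' Peak-calling configuration
#'
#' Defaults follow the high-specificity settings of the method: a 0.05
#' significance cutoff after FDR control, at least twofold IP enrichment
#' over INPUT and at least 20 fragments of IP coverage in the peak
#' region.
#'
#' @param fragment_size Sequenced fragment length in nt (default 100);
#'   the expected peak width is twice this value. For paired-end data use
#'   [estimate_fragment_length()].
#' @param p_cutoff Significance cutoff applied to q-values (default 0.05).
#' @param min_enrichment Minimum IP/INPUT fold enrichment (default 2).
#' @param min_coverage Minimum IP fragment count in the region
#'   (default 20); also used as the coverage floor for summit detection.
#' @param fdr_method One of \code{"bh"}, \code{"by"}, \code{"bonferroni"},
#'   \code{"none"}.
#' @param smoothing_window Moving-average window (nt); default
#'   \code{fragment_size / 4} rounded up to odd.
#' @param min_valley_fraction Adjacent summits are kept separate only if
#'   the valley between them drops to at most this fraction of the lower
#'   summit (default 0.75); otherwise they are merged.
#' @param reproducibility Apply the replicate reproducibility filter
#'   (default off).
#' @param match_window Summit match window (nt) for the reproducibility
#'   filter.
#' @return A \code{peak_config} list.
#' @export
peak_config <- function(fragment_size = 100L, p_cutoff = 0.05,
                        min_enrichment = 2.0, min_coverage = 20L,
                        fdr_method = c("bh", "by", "bonferroni", "none"),
                        smoothing_window = NULL,
                        min_valley_fraction = 0.75,
                        reproducibility = FALSE, match_window = 50L) {
  fdr_method <- match.arg(fdr_method)
  stopifnot(fragment_size > 0, p_cutoff > 0, min_enrichment > 0,
            min_coverage > 0, min_valley_fraction > 0)
  if (is.null(smoothing_window)) {
    smoothing_window <- as.integer(fragment_size) %/% 4L
    if (smoothing_window %% 2L == 0L) smoothing_window <- smoothing_window + 1L
  }
  structure(list(fragment_size = as.integer(fragment_size),
                 p_cutoff = p_cutoff, min_enrichment = min_enrichment,
                 min_coverage = as.integer(min_coverage),
                 fdr_method = fdr_method,
                 smoothing_window = as.integer(smoothing_window),
                 min_valley_fraction = min_valley_fraction,
                 reproducibility = reproducibility,
                 match_window = as.integer(match_window)),
            class = "peak_config")
}

#' Smooth a coverage track with a centered moving average
#'
#' Edge positions use a window truncated at the track ends (edge
#' shrinkage), so a constant track is a fixed point and window 1 is the
#' identity.
#'
#' @param x Numeric vector or a \code{cov_track}.
#' @param window Odd window size in nt; an even value is incremented with
#'   a warning.
#' @return Same type as the input, smoothed values.
#' @export
smooth_coverage <- function(x, window) {
  if (inherits(x, "cov_track")) {
    x$values <- smooth_coverage(as.numeric(x$values), window)
    return(x)
  }
  window <- as.integer(window)
  stopifnot(window >= 1L)
  if (window %% 2L == 0L) {
    warning("smoothing window must be odd; using ", window + 1L)
    window <- window + 1L
  }
  if (window == 1L || length(x) == 0L) return(x)
  h <- window %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Find local coverage maxima (candidate peak summits)
#'
#' Detects positions (or runs of equal coverage, reported at the run
#' center) where the coverage trend turns from increasing to decreasing,
#' assessed over flanks of a quarter of the expected peak width. Maxima
#' below the coverage floor are suppressed. Adjacent maxima are treated as
#' distinct peaks only when separated by a local minimum that drops to at
#' most \code{min_valley_fraction} of the lower summit; otherwise the
#' lower one is merged away.
#'
#' @param values Numeric coverage vector (typically smoothed).
#' @param expected_width Expected peak width in nt (twice the fragment
#'   length).
#' @param floor Minimum summit coverage (default 0: keep all).
#' @param min_valley_fraction Valley depth rule for splitting adjacent
#'   maxima (default 0.75).
#' @return Integer vector of 1-based summit indices into \code{values}.
#' @export
find_local_maxima <- function(values, expected_width, floor = 0,
                              min_valley_fraction = 0.75) {
  n <- length(values)
  if (n == 0L || all(values == values[1])) return(integer(0))
  r <- rle(values)
  k <- length(r$values)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  prev <- c(-Inf, r$values[-k])
  nxt <- c(r$values[-1], -Inf)
  is_max <- r$values > prev & r$values > nxt
  idx <- which(is_max)
  if (length(idx) == 0L) return(integer(0))
  summits <- (run_start[idx] + run_end[idx]) %/% 2L
  heights <- r$values[idx]
  rs <- run_start[idx]; re <- run_end[idx]

  keep <- heights >= floor
  summits <- summits[keep]; heights <- heights[keep]
  rs <- rs[keep]; re <- re[keep]
  if (length(summits) == 0L) return(integer(0))

  ## flank-trend check: mean coverage over a quarter-width flank beyond
  ## each end of the summit run must lie below the summit (suppresses
  ## jitter bumps on slopes); a run touching the track edge passes on
  ## that side
  w <- max(1L, as.integer(expected_width) %/% 4L)
  ok <- vapply(seq_along(summits), function(i) {
    l_ok <- rs[i] == 1L ||
      mean(values[max(1L, rs[i] - w):(rs[i] - 1L)]) < heights[i]
    r_ok <- re[i] == n ||
      mean(values[(re[i] + 1L):min(n, re[i] + w)]) < heights[i]
    l_ok && r_ok
  }, logical(1))
  summits <- summits[ok]; heights <- heights[ok]
  if (length(summits) <= 1L) return(summits)

  ## valley rule: merge adjacent maxima not separated by a deep enough dip
  repeat {
    if (length(summits) <= 1L) break
    merged <- FALSE
    for (i in seq_len(length(summits) - 1L)) {
      valley <- min(values[summits[i]:summits[i + 1L]])
      lower <- min(heights[i], heights[i + 1L])
      if (valley > min_valley_fraction * lower) {
        drop_i <- if (heights[i] < heights[i + 1L]) i else i + 1L
        summits <- summits[-drop_i]; heights <- heights[-drop_i]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  summits
}

#' Define peak regions around summits
#'
#' Each region spans the fragment length to each side of its summit;
#' where consecutive regions would overlap, the shared boundary is the
#' midpoint between the two summits, so regions are pairwise disjoint.
#'
#' @param summits Sorted integer vector of 1-based summit positions.
#' @param fragment_size Fragment length F in nt; a lone region is
#'   \code{[summit - F, summit + F - 1]}.
#' @param lo,hi Optional track bounds for clipping.
#' @return data.frame with \code{summit}, \code{start}, \code{end}
#'   (1-based closed).
#' @export
define_regions <- function(summits, fragment_size, lo = 1L, hi = Inf) {
  if (length(summits) == 0L)
    return(data.frame(summit = integer(0), start = integer(0),
                      end = integer(0)))
  stopifnot(!is.unsorted(summits))
  F <- as.integer(fragment_size)
  start <- pmax(as.integer(lo), summits - F)
  end <- pmin(hi, summits + F - 1L)
  if (length(summits) > 1L) {
    for (i in seq_len(length(summits) - 1L)) {
      if (end[i] >= start[i + 1L]) {
        b <- (summits[i] + summits[i + 1L]) %/% 2L
        end[i] <- b - 1L
        start[i + 1L] <- b
      }
    }
  }
  data.frame(summit = summits, start = as.integer(start),
             end = as.integer(end))
}

#' One-sided Fisher's exact test for IP enrichment
#'
#' Tests, for each peak region, the null hypothesis that the fragment
#' proportion in the IP library is not higher than in the INPUT library,
#' on the 2x2 table \{(ip_count, ip_total - ip_count), (input_count,
#' input_total - input_count)\}. Equivalent to the upper hypergeometric
#' tail conditioned on the table margins. Vectorised over peaks.
#'
#' @param ip_count,input_count Fragment counts in the region.
#' @param ip_total,input_total Library totals.
#' @return One-sided p-value(s) in \code{[0, 1]}.
#' @export
test_enrichment <- function(ip_count, input_count, ip_total, input_total) {
  stopifnot(all(ip_count >= 0), all(input_count >= 0),
            all(ip_total >= ip_count), all(input_total >= input_count))
  n <- max(length(ip_count), length(input_count))
  a <- rep_len(as.numeric(ip_count), n)
  b <- rep_len(as.numeric(input_count), n)
  N1 <- rep_len(as.numeric(ip_total), n)
  N2 <- rep_len(as.numeric(input_total), n)
  p <- rep(1.0, n)
  zero <- N1 == 0 | N2 == 0
  if (any(zero)) warning("zero library total; p-value set to 1")
  ok <- !zero
  p[ok] <- stats::phyper(a[ok] - 1, a[ok] + b[ok],
                         N1[ok] + N2[ok] - a[ok] - b[ok], N1[ok],
                         lower.tail = FALSE)
  pmin(1, p)
}

#' Multiple-testing correction of peak p-values
#'
#' @param p Numeric vector of p-values.
#' @param method \code{"bh"} (Benjamini-Hochberg), \code{"by"}
#'   (Benjamini-Yekutieli), \code{"bonferroni"}, or \code{"none"}.
#' @return q-values in the input order.
#' @export
adjust_fdr <- function(p, method = c("bh", "by", "bonferroni", "none")) {
  method <- match.arg(method)
  stopifnot(all(p >= 0 & p <= 1))
  map <- c(bh = "BH", by = "BY", bonferroni = "bonferroni", none = "none")
  stats::p.adjust(p, method = map[[method]])
}

#' Apply enrichment, coverage and significance filters
#'
#' Peaks failing a filter are flagged (in the \code{flags} column) rather
#' than removed, so full output remains available; the default writers and
#' evaluation use only unflagged ("retained") peaks. Order is preserved.
#'
#' @param peaks Peak data.frame with \code{q_value}, \code{enrichment},
#'   \code{ip_count} columns.
#' @param cfg A [peak_config()].
#' @return The peak data.frame with updated \code{flags} and a logical
#'   \code{retained} column.
#' @export
apply_filters <- function(peaks, cfg = peak_config()) {
  if (nrow(peaks) == 0L) {
    peaks$flags <- character(0); peaks$retained <- logical(0)
    return(peaks)
  }
  f <- character(nrow(peaks))
  add <- function(f, cond, tag) ifelse(cond, ifelse(f == "", tag,
                                                    paste(f, tag, sep = ",")), f)
  f <- add(f, peaks$q_value > cfg$p_cutoff, "not_significant")
  f <- add(f, peaks$enrichment < cfg$min_enrichment, "low_enrichment")
  f <- add(f, peaks$ip_count < cfg$min_coverage, "low_coverage")
  peaks$flags <- f
  peaks$retained <- f == ""
  peaks
}

#' Replicate reproducibility filter
#'
#' A peak is reproducible when every replicate in the group has a peak
#' whose summit lies within \code{match_window} nt. Non-reproducible
#' peaks are flagged \code{not_reproducible}. Off by default in
#' [peak_config()].
#'
#' @param peak_sets List of peak data.frames, one per replicate.
#' @param match_window Summit match window in nt (default 50).
#' @return The list with updated \code{flags}/\code{retained}.
#' @export
reproducibility_filter <- function(peak_sets, match_window = 50L) {
  if (length(peak_sets) < 2L) {
    warning("reproducibility filter needs >= 2 replicates; no-op")
    return(peak_sets)
  }
  for (i in seq_along(peak_sets)) {
    p <- peak_sets[[i]]
    if (nrow(p) == 0L) next
    rep_ok <- rep(TRUE, nrow(p))
    for (j in seq_along(peak_sets)) {
      if (j == i) next
      q <- peak_sets[[j]]
      rep_ok <- rep_ok & vapply(seq_len(nrow(p)), function(k) {
        any(q$chrom == p$chrom[k] &
              abs(q$summit - p$summit[k]) <= match_window)
      }, logical(1))
    }
    tag <- "not_reproducible"
    p$flags <- ifelse(!rep_ok,
                      ifelse(p$flags == "", tag, paste(p$flags, tag, sep = ",")),
                      p$flags)
    p$retained <- p$flags == ""
    peak_sets[[i]] <- p
  }
  peak_sets
}

#' Call m6A peaks from matched IP and INPUT BAM files
#'
#' Orchestrates the full caller: fragment inference, library-size
#' scaling, coverage smoothing, summit detection, region definition,
#' Fisher's exact enrichment test, FDR control and filtering. INPUT
#' coverage is scaled to the IP library by the ratio of total filtered
#' fragment counts. Enrichment is the peak-height fold: the
#' pseudocounted ratio of smoothed IP to scaled smoothed INPUT fragment
#' coverage at the summit. The exact test uses raw region fragment
#' counts (smoothing affects summit finding only).
#'
#' @param ip_bam,input_bam Sorted, indexed BAM paths.
#' @param cfg A [peak_config()].
#' @param exons Optional \code{exon_model} for splice-aware fragments.
#' @param filter Alignment filters, a [read_filter_config()].
#' @param mode Read mode passed to [infer_fragments()].
#' @param sample_id Label recorded in the output.
#' @param verbose Per-chromosome progress messages.
#' @return Peak data.frame: \code{chrom}, \code{summit}, \code{start},
#'   \code{end}, \code{ip_count}, \code{input_count}, \code{ip_total},
#'   \code{input_total}, \code{enrichment}, \code{p_value},
#'   \code{q_value}, \code{flags}, \code{retained}, \code{sample_id}.
#' @export
call_peaks <- function(ip_bam, input_bam, cfg = peak_config(), exons = NULL,
                       filter = read_filter_config(),
                       mode = "auto", sample_id = "sample",
                       verbose = FALSE) {
  check_bam(ip_bam); check_bam(input_bam)
  si_ip <- GenomeInfoDb::seqnames(Rsamtools::seqinfo(Rsamtools::BamFile(ip_bam)))
  si_in <- GenomeInfoDb::seqnames(Rsamtools::seqinfo(Rsamtools::BamFile(input_bam)))
  common <- intersect(si_ip, si_in)
  if (length(common) == 0L)
    stop("no common chromosomes between IP (", paste(utils::head(si_ip, 3),
         collapse = ","), ") and INPUT (", paste(utils::head(si_in, 3),
         collapse = ","), ")")
  frag_ip <- infer_fragments(ip_bam, mode = mode, cfg = filter,
                             fragment_size = cfg$fragment_size, exons = exons)
  frag_in <- infer_fragments(input_bam, mode = mode, cfg = filter,
                             fragment_size = cfg$fragment_size, exons = exons)
  ip_total <- length(frag_ip)
  input_total <- length(frag_in)
  if (ip_total == 0L || input_total == 0L)
    stop("no fragments after filtering in ",
         if (ip_total == 0L) ip_bam else input_bam)
  scale_in <- ip_total / input_total

  seqlen <- GenomeInfoDb::seqlengths(Rsamtools::seqinfo(
    Rsamtools::BamFile(ip_bam)))
  ip_chr <- fragment_chroms(frag_ip)
  in_chr <- fragment_chroms(frag_in)

  out <- list()
  for (chrom in common) {
    fi <- frag_ip[ip_chr == chrom]
    if (length(fi) == 0L) next
    fn <- frag_in[in_chr == chrom]
    clen <- seqlen[[chrom]]
    cov <- compute_coverage(fi, chrom, 1L, clen)
    sm <- smooth_coverage(as.numeric(cov$values), cfg$smoothing_window)
    summits <- find_local_maxima(sm, expected_width = 2L * cfg$fragment_size,
                                 floor = cfg$min_coverage,
                                 min_valley_fraction = cfg$min_valley_fraction)
    if (verbose)
      message(chrom, ": ", length(fi), " IP fragments, ",
              length(summits), " candidate summits")
    if (length(summits) == 0L) next
    reg <- define_regions(summits, cfg$fragment_size, lo = 1L, hi = clen)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(reg$start, reg$end))
    ipc <- GenomicRanges::countOverlaps(gr, fi, ignore.strand = TRUE)
    inc <- GenomicRanges::countOverlaps(gr, fn, ignore.strand = TRUE)
    ## summit-level coverage fold: scaled, pseudocounted
    cov_in <- compute_coverage(fn, chrom, 1L, clen)
    sm_in <- smooth_coverage(as.numeric(cov_in$values), cfg$smoothing_window)
    enr <- (sm[reg$summit] + 1) / (sm_in[reg$summit] * scale_in + 1)
    out[[chrom]] <- data.frame(
      chrom = chrom, summit = reg$summit, start = reg$start, end = reg$end,
      ip_count = ipc, input_count = inc, enrichment = enr,
      stringsAsFactors = FALSE)
  }
  peaks <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(chrom = character(0), summit = integer(0), start = integer(0),
               end = integer(0), ip_count = integer(0),
               input_count = integer(0), enrichment = numeric(0),
               stringsAsFactors = FALSE)
  rownames(peaks) <- NULL
  peaks$ip_total <- rep(ip_total, nrow(peaks))
  peaks$input_total <- rep(input_total, nrow(peaks))
  peaks$p_value <- if (nrow(peaks) > 0L)
    test_enrichment(peaks$ip_count, peaks$input_count, ip_total, input_total)
  else numeric(0)
  peaks$q_value <- adjust_fdr(peaks$p_value, cfg$fdr_method)
  peaks$flags <- character(nrow(peaks))
  peaks <- apply_filters(peaks, cfg)
  peaks$sample_id <- rep(sample_id, nrow(peaks))
  peaks
}

## chromosome of each fragment (blocks of a fragment share one chromosome)
fragment_chroms <- function(frags) {
  if (length(frags) == 0L) return(character(0))
  rv <- S4Vectors::runValue(GenomicRanges::seqnames(frags))
  vapply(as.list(rv), function(v) as.character(v)[1], character(1))
}
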