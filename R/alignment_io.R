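#' Alignment filter configuration
#'
#' Controls which BAM records enter fragment inference. Defaults retain
#' only primary, non-duplicate alignments; in paired mode improper pairs
#' are dropped as well.
#'
#' @param skip_duplicates Drop records flagged as PCR/optical duplicates.
#' @param min_mapq Minimum mapping quality (records with missing MAPQ 255
#'   are kept).
#' @param skip_secondary Drop secondary alignments.
#' @param require_proper_pair Paired mode only: drop improper pairs.
#' @return A \code{read_filter_config} list.
#' @export
read_filter_config <- function(skip_duplicates = TRUE, min_mapq = 0L,
                               skip_secondary = TRUE,
                               require_proper_pair = TRUE) {
  stopifnot(min_mapq >= 0)
  structure(list(skip_duplicates = skip_duplicates,
                 min_mapq = as.integer(min_mapq),
                 skip_secondary = skip_secondary,
                 require_proper_pair = require_proper_pair),
            class = "read_filter_config")
}

#' Filter an alignment stream
#'
#' Applies the enabled filters to a \code{GAlignments} object whose
#' metadata columns include \code{flag} (and \code{mapq}). Order is
#' preserved; counts of dropped records per reason are attached as the
#' \code{"dropped"} attribute and reported via \code{message()}.
#'
#' @param aln \code{GAlignments} with \code{flag}/\code{mapq} mcols (as
#'   returned by \code{readGAlignments} with
#'   \code{ScanBamParam(what = c("flag", "mapq"))}).
#' @param cfg A [read_filter_config()].
#' @param verbose Emit a message with drop counts.
#' @return The filtered \code{GAlignments}.
#' @export
filter_alignments <- function(aln, cfg = read_filter_config(),
                              verbose = FALSE) {
  flag <- S4Vectors::mcols(aln)$flag
  mapq <- S4Vectors::mcols(aln)$mapq
  if (is.null(flag)) stop("alignments lack a 'flag' metadata column")
  keep <- rep(TRUE, length(aln))
  dropped <- c(duplicate = 0L, mapq = 0L, secondary = 0L, improper = 0L)
  if (isTRUE(cfg$skip_duplicates)) {
    d <- bitwAnd(flag, 1024L) != 0L
    dropped["duplicate"] <- sum(d & keep); keep <- keep & !d
  }
  if (isTRUE(cfg$skip_secondary)) {
    d <- bitwAnd(flag, 256L) != 0L
    dropped["secondary"] <- sum(d & keep); keep <- keep & !d
  }
  if (cfg$min_mapq > 0L && !is.null(mapq)) {
    d <- !is.na(mapq) & mapq != 255L & mapq < cfg$min_mapq
    dropped["mapq"] <- sum(d & keep); keep <- keep & !d
  }
  if (isTRUE(cfg$require_proper_pair)) {
    paired <- bitwAnd(flag, 1L) != 0L
    d <- paired & bitwAnd(flag, 2L) == 0L
    dropped["improper"] <- sum(d & keep); keep <- keep & !d
  }
  out <- aln[keep]
  attr(out, "dropped") <- dropped
  if (verbose)
    message("filtered alignments: kept ", length(out), "/", length(aln),
            " (dropped: ", paste(names(dropped), dropped, sep = "=",
                                 collapse = ", "), ")")
  out
}

check_bam <- function(path) {
  if (!file.exists(path)) stop("BAM file not found: ", path)
  bai <- c(paste0(path, ".bai"), sub("\\.bam$", ".bai", path))
  if (!any(file.exists(bai)))
    stop("BAM index (.bai) not found for: ", path,
         " (the file must be coordinate-sorted and indexed)")
  invisible(TRUE)
}

scan_flags <- function(cfg, paired) {
  Rsamtools::scanBamFlag(
    isSecondaryAlignment = if (isTRUE(cfg$skip_secondary)) FALSE else NA,
    isDuplicate = if (isTRUE(cfg$skip_duplicates)) FALSE else NA,
    isProperPair = if (paired && isTRUE(cfg$require_proper_pair)) TRUE else NA,
    isUnmappedQuery = FALSE)
}

#' Infer sequenced fragments from a BAM file
#'
#' MeRIP-seq signal is carried by the immunoprecipitated RNA fragment, not
#' by the sequenced read, so coverage is computed over inferred fragments.
#' In paired mode each proper pair becomes one fragment spanning from the
#' leftmost to the rightmost mate position; the interior not covered by
#' either mate is filled respecting annotated introns when an exon model
#' is supplied (otherwise the raw gap is included only when shorter than
#' \code{max_gap}). Overlapping mates contribute each base once. In single
#' mode each read is extended toward its 3' end up to
#' \code{fragment_size} total length, jumping introns via the exon model
#' when available; with \code{library_type = "unstranded"} the extension
#' is split symmetrically to both sides.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM.
#' @param mode \code{"auto"} (paired if the first records are paired),
#'   \code{"paired"} or \code{"single"}.
#' @param cfg A [read_filter_config()].
#' @param fragment_size Target fragment length (nt) for single-end
#'   extension. Default 100.
#' @param exons Optional \code{exon_model} for splice-aware extension and
#'   gap filling.
#' @param library_type \code{"fr-stranded"} (extend in alignment
#'   orientation) or \code{"unstranded"} (symmetric extension).
#' @param max_gap Without annotation, mate gaps at least this wide (nt)
#'   are excluded from the fragment instead of filled. Default 10000.
#' @param region Optional \code{GRanges} restricting the read window.
#' @return \code{GRangesList}: one element per fragment, ordered disjoint
#'   blocks; metadata column \code{is_extended} flags truncated/extended
#'   single-end fragments.
#' @export
infer_fragments <- function(bam, mode = c("auto", "paired", "single"),
                            cfg = read_filter_config(), fragment_size = 100L,
                            exons = NULL,
                            library_type = c("fr-stranded", "unstranded"),
                            max_gap = 10000L, region = NULL) {
  mode <- match.arg(mode)
  library_type <- match.arg(library_type)
  check_bam(bam)
  if (mode == "auto") mode <- if (bam_is_paired(bam)) "paired" else "single"
  param_which <- if (is.null(region)) Rsamtools::ScanBamParam(
    flag = scan_flags(cfg, mode == "paired"),
    mapqFilter = cfg$min_mapq,
    what = "flag")
  else Rsamtools::ScanBamParam(
    flag = scan_flags(cfg, mode == "paired"),
    mapqFilter = cfg$min_mapq, what = "flag", which = region)

  if (mode == "paired") {
    pairs <- GenomicAlignments::readGAlignmentPairs(bam, param = param_which)
    frags <- pair_fragments(pairs, exons, max_gap)
  } else {
    aln <- GenomicAlignments::readGAlignments(bam, param = param_which)
    frags <- single_fragments(aln, fragment_size, exons, library_type)
  }
  frags
}

bam_is_paired <- function(bam) {
  bf <- Rsamtools::BamFile(bam, yieldSize = 1000L)
  open(bf); on.exit(close(bf))
  res <- Rsamtools::scanBam(bf, param = Rsamtools::ScanBamParam(what = "flag"))
  flags <- res[[1]]$flag
  length(flags) > 0L && mean(bitwAnd(flags, 1L) != 0L) > 0.5
}

## one fragment per proper pair: union of mate blocks + interior fill
pair_fragments <- function(pairs, exons, max_gap) {
  if (length(pairs) == 0L) return(GenomicRanges::GRangesList())
  same_chr <- as.character(GenomicAlignments::seqnames(pairs)) ==
    as.character(GenomicAlignments::seqnames(GenomicAlignments::last(pairs)))
  if (!all(same_chr)) {
    warning(sum(!same_chr), " pair(s) with mates on different chromosomes skipped")
    pairs <- pairs[same_chr]
  }
  blocks <- GenomicRanges::reduce(GenomicAlignments::grglist(pairs),
                                  ignore.strand = TRUE)
  span <- unlist(range(blocks, ignore.strand = TRUE), use.names = FALSE)
  interior <- GenomicRanges::psetdiff(span, blocks, ignore.strand = TRUE)
  gap_w <- sum(IRanges::width(interior))
  fill_ranges <- GenomicRanges::GRanges()
  fill_grp <- integer(0)
  if (any(gap_w > 0L)) {
    flat <- unlist(interior, use.names = FALSE)
    grp <- rep(seq_along(interior), lengths(interior))
    if (!is.null(exons)) {
      ## keep only the exonic part of the interior
      red <- unlist(exons$reduced, use.names = FALSE)
      ov <- GenomicRanges::findOverlaps(flat, red, ignore.strand = TRUE)
      if (length(ov) > 0L) {
        fill_ranges <- IRanges::pintersect(
          flat[S4Vectors::queryHits(ov)], red[S4Vectors::subjectHits(ov)],
          ignore.strand = TRUE)
        fill_grp <- grp[S4Vectors::queryHits(ov)]
      }
    } else {
      small <- gap_w[grp] < max_gap
      fill_ranges <- flat[small]
      fill_grp <- grp[small]
    }
  }
  if (length(fill_ranges) > 0L) {
    base <- unlist(blocks, use.names = FALSE)
    all_grp <- c(rep(seq_along(blocks), lengths(blocks)), fill_grp)
    allr <- c(GenomicRanges::granges(base), GenomicRanges::granges(fill_ranges))
    blocks <- GenomicRanges::reduce(
      GenomicRanges::split(allr, factor(all_grp, levels = seq_along(blocks))),
      ignore.strand = TRUE)
    names(blocks) <- NULL
  }
  S4Vectors::mcols(blocks)$is_extended <- FALSE
  blocks
}

single_fragments <- function(aln, fragment_size, exons, library_type) {
  if (length(aln) == 0L) return(GenomicRanges::GRangesList())
  blocks <- GenomicRanges::reduce(GenomicAlignments::grglist(aln),
                                  ignore.strand = TRUE)
  strands <- as.character(GenomicAlignments::strand(aln))
  chroms <- as.character(GenomicAlignments::seqnames(aln))
  ## fast path: unspliced reads, no annotation, stranded library
  if (is.null(exons) && library_type == "fr-stranded" &&
      all(lengths(blocks) == 1L)) {
    gr <- unlist(blocks, use.names = FALSE)
    w <- GenomicRanges::width(gr)
    need_ext <- w < fragment_size
    GenomicRanges::strand(gr) <- strands
    gr <- suppressWarnings(GenomicRanges::resize(
      gr, width = pmax(w, fragment_size), fix = "start"))
    GenomicRanges::start(gr) <- pmax(1L, GenomicRanges::start(gr))
    gr <- GenomicRanges::trim(gr)
    GenomicRanges::strand(gr) <- "*"
    res <- GenomicRanges::split(gr, seq_along(gr))
    names(res) <- names(aln)
    S4Vectors::mcols(res)$is_extended <- need_ext
    return(res)
  }
  out <- vector("list", length(aln))
  ext <- logical(length(aln))
  for (i in seq_along(aln)) {
    chain <- exon_chain(exons, chroms[i])
    if (library_type == "unstranded") {
      half <- (fragment_size - sum(IRanges::width(blocks[[i]]))) %/% 2L
      b <- extend_blocks(blocks[[i]], "+",
                         sum(IRanges::width(blocks[[i]])) + max(0L, half),
                         chain)
      b <- extend_blocks(b, "-", fragment_size, chain)
    } else {
      b <- extend_blocks(blocks[[i]], strands[i], fragment_size, chain)
    }
    ext[i] <- sum(IRanges::width(b)) != sum(IRanges::width(blocks[[i]]))
    out[[i]] <- b
  }
  res <- GenomicRanges::GRangesList(out)
  names(res) <- names(aln)
  S4Vectors::mcols(res)$is_extended <- ext
  res
}

exon_chain <- function(exons, chrom) {
  if (is.null(exons)) return(NULL)
  if (!(chrom %in% names(exons$reduced))) return(NULL)
  exons$reduced[[chrom]]
}

#' Extend a fragment's blocks toward the 3' end
#'
#' Grows an aligned read's blocks to \code{target_len} total bases in the
#' direction implied by \code{strand} ("+" extends to higher coordinates,
#' "-" to lower). With an exon chain (reduced exon \code{GRanges} on the
#' same chromosome) the extension respects intron-exon boundaries, jumping
#' introns; without one it is linear in genome coordinates. Extension past
#' the end of the exon chain is truncated.
#'
#' @param blocks \code{GRanges} of ordered disjoint blocks (one fragment).
#' @param strand \code{"+"} or \code{"-"} (\code{"*"} treated as "+").
#' @param target_len Desired total fragment length (nt).
#' @param chain Optional reduced-exon \code{GRanges}, sorted.
#' @return Extended \code{GRanges} blocks (reduced, sorted).
#' @export
extend_blocks <- function(blocks, strand, target_len, chain = NULL) {
  cur <- sum(IRanges::width(blocks))
  need <- as.integer(target_len) - cur
  if (need <= 0L) return(blocks)
  chrom <- as.character(GenomicRanges::seqnames(blocks)[1])
  fwd <- !identical(strand, "-")
  tip <- if (fwd) max(GenomicRanges::end(blocks)) else
    min(GenomicRanges::start(blocks))
  add <- GenomicRanges::GRanges()
  if (is.null(chain)) {
    add <- if (fwd)
      GenomicRanges::GRanges(chrom, IRanges::IRanges(tip + 1L, tip + need))
    else
      GenomicRanges::GRanges(chrom,
                             IRanges::IRanges(max(1L, tip - need), tip - 1L))
  } else {
    st <- GenomicRanges::start(chain); en <- GenomicRanges::end(chain)
    ix <- which(st <= tip & en >= tip)
    if (length(ix) == 0L) {
      ## read outside annotation: linear fallback
      return(extend_blocks(blocks, strand, target_len, chain = NULL))
    }
    i <- ix[1]
    pos <- tip
    pieces <- list()
    while (need > 0L && i >= 1L && i <= length(chain)) {
      if (fwd) {
        avail <- en[i] - pos
        if (avail > 0L) {
          take <- min(avail, need)
          pieces[[length(pieces) + 1L]] <- IRanges::IRanges(pos + 1L, pos + take)
          need <- need - take
        }
        i <- i + 1L
        if (i <= length(chain)) pos <- st[i] - 1L
      } else {
        avail <- pos - st[i]
        if (avail > 0L) {
          take <- min(avail, need)
          pieces[[length(pieces) + 1L]] <- IRanges::IRanges(pos - take, pos - 1L)
          need <- need - take
        }
        i <- i - 1L
        if (i >= 1L) pos <- en[i] + 1L
      }
    }
    if (length(pieces) > 0L)
      add <- GenomicRanges::GRanges(chrom, do.call(c, pieces))
  }
  out <- GenomicRanges::reduce(c(GenomicRanges::granges(blocks),
                                 GenomicRanges::granges(add)),
                               ignore.strand = TRUE)
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Per-base fragment coverage over an interval
#'
#' @param fragments \code{GRangesList} of fragment blocks (from
#'   [infer_fragments()]).
#' @param chrom Chromosome name.
#' @param start,end 1-based closed interval bounds.
#' @param scale Positive library-size scale factor, stored alongside the
#'   raw counts (counts themselves are unscaled so that zero positions are
#'   invariant under scaling).
#' @return A \code{cov_track}: list with \code{chrom}, \code{start},
#'   \code{values} (integer counts, length \code{end - start + 1}) and
#'   \code{scale}.
#' @export
compute_coverage <- function(fragments, chrom, start, end, scale = 1) {
  stopifnot(scale > 0, end >= start)
  n <- end - start + 1L
  vals <- integer(n)
  if (length(fragments) > 0L) {
    bl <- unlist(fragments, use.names = FALSE)
    bl <- bl[as.character(GenomicRanges::seqnames(bl)) == chrom]
    if (length(bl) > 0L) {
      cov <- IRanges::coverage(IRanges::ranges(bl),
                               width = max(end, max(GenomicRanges::end(bl))))
      vals <- as.integer(S4Vectors::window(cov, start = start, end = end))
    }
  }
  structure(list(chrom = chrom, start = as.integer(start),
                 values = vals, scale = scale),
            class = "cov_track")
}

#' @export
print.cov_track <- function(x, ...) {
  cat("cov_track ", x$chrom, ":", x$start, "-",
      x$start + length(x$values) - 1L, " scale=", format(x$scale, digits = 4),
      " max=", max(x$values), "\n", sep = "")
  invisible(x)
}

#' Estimate the sequenced fragment length from paired-end data
#'
#' Returns the median absolute template length (TLEN) over sampled proper
#' pairs; the expected peak width used by the summit detector is twice
#' this value.
#'
#' @param bam Path to a paired-end BAM.
#' @param min_pairs Minimum number of proper pairs required (default 100).
#' @param sample_size Number of records to scan (default 100000).
#' @return List with \code{fragment_length} (median |TLEN|) and
#'   \code{expected_peak_width} (twice the median).
#' @export
estimate_fragment_length <- function(bam, min_pairs = 100L,
                                     sample_size = 100000L) {
  check_bam(bam)
  bf <- Rsamtools::BamFile(bam, yieldSize = sample_size)
  open(bf); on.exit(close(bf))
  res <- Rsamtools::scanBam(bf, param = Rsamtools::ScanBamParam(
    what = c("flag", "isize"),
    flag = Rsamtools::scanBamFlag(isProperPair = TRUE, isFirstMateRead = TRUE)))
  tlen <- abs(res[[1]]$isize)
  tlen <- tlen[!is.na(tlen) & tlen > 0L]
  if (length(tlen) < min_pairs)
    stop("fewer than ", min_pairs, " proper pairs found; for single-end ",
         "data supply fragment_size directly (default 100 nt)")
  med <- stats::median(tlen)
  list(fragment_length = med, expected_peak_width = 2 * med)
}
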