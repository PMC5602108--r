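#' Parse a GTF file into an exon model
#'
#' Reads exon features from a GTF annotation and organises them per
#' transcript, deriving 5'UTR/CDS/3'UTR feature classes where CDS records
#' are present. The exon model drives splice-aware read extension,
#' transcript-region feature classes for the false-positive filter, and
#' peak-matched control position sampling.
#'
#' @param path Path to a GTF file (Ensembl or UCSC dialect). Exon records
#'   must carry a \code{transcript_id} attribute; records without one are
#'   skipped with a warning.
#' @return An object of class \code{exon_model}: a list with
#'   \describe{
#'     \item{exons}{\code{GRangesList}, one element per transcript, exons
#'       ordered by genomic coordinate.}
#'     \item{tx}{\code{data.frame} of per-transcript metadata
#'       (\code{transcript_id}, \code{gene_id}, \code{chrom},
#'       \code{strand}).}
#'     \item{cds}{\code{GRangesList} of CDS intervals per transcript
#'       (may be empty).}
#'     \item{reduced}{per-chromosome \code{GRanges} of reduced (merged)
#'       exons, used for annotation-guided fragment extension.}
#'   }
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  build_exon_model(gr)
}

#' Build an exon model from a GRanges of GTF records
#'
#' Lower-level constructor used by [parse_gtf()] and by the simulator
#' (which holds its annotation in memory).
#'
#' @param gr \code{GRanges} with a \code{type} metadata column containing
#'   \code{"exon"} (and optionally \code{"CDS"}) records, plus
#'   \code{transcript_id} / \code{gene_id} attributes.
#' @return An \code{exon_model}; see [parse_gtf()].
#' @export
build_exon_model <- function(gr) {
  type <- as.character(gr$type)
  ex <- gr[type == "exon"]
  if (length(ex) == 0L) stop("no exon records in annotation")
  txid <- as.character(ex$transcript_id)
  bad <- is.na(txid) | txid == ""
  if (any(bad)) {
    warning(sum(bad), " exon record(s) without transcript_id skipped")
    ex <- ex[!bad]
    txid <- txid[!bad]
  }
  exl <- GenomicRanges::split(ex, txid)
  exl <- endoapply_sort(exl)
  ## deduplicate transcripts with identical exon coordinates
  key <- vapply(exl, function(g)
    paste(GenomicRanges::seqnames(g)[1],
          paste(GenomicRanges::start(g), GenomicRanges::end(g),
                sep = "-", collapse = ";"),
          as.character(GenomicRanges::strand(g)[1])),
    character(1))
  keep <- !duplicated(key)
  exl <- exl[keep]

  gene <- vapply(exl, function(g) {
    gid <- S4Vectors::mcols(g)$gene_id
    if (is.null(gid) || all(is.na(gid))) NA_character_ else as.character(gid[1])
  }, character(1))
  tx <- data.frame(
    transcript_id = names(exl),
    gene_id = gene,
    chrom = vapply(exl, function(g) as.character(GenomicRanges::seqnames(g)[1]),
                   character(1)),
    strand = vapply(exl, function(g) as.character(GenomicRanges::strand(g)[1]),
                    character(1)),
    stringsAsFactors = FALSE
  )
  rownames(tx) <- NULL

  cds <- gr[type == "CDS"]
  cdsl <- if (length(cds) > 0L) {
    ctx <- as.character(cds$transcript_id)
    GenomicRanges::split(cds, ctx)
  } else GenomicRanges::GRangesList()

  red <- GenomicRanges::reduce(unlist(exl, use.names = FALSE),
                               ignore.strand = TRUE)
  reduced <- GenomicRanges::split(red, GenomicRanges::seqnames(red))
  reduced <- reduced[lengths(reduced) > 0L]

  structure(list(exons = exl, tx = tx, cds = cdsl, reduced = reduced),
            class = "exon_model")
}

endoapply_sort <- function(exl) {
  S4Vectors::endoapply(exl, function(g) GenomicRanges::sort(g,
                                                            ignore.strand = TRUE))
}

#' @export
print.exon_model <- function(x, ...) {
  cat("exon_model:", length(x$exons), "transcripts,",
      sum(lengths(x$exons)), "exons,",
      length(x$cds), "with CDS\n")
  invisible(x)
}

#' Classify a genomic position against transcript regions
#'
#' Assigns one of \code{"5UTR"}, \code{"CDS"}, \code{"3UTR"},
#' \code{"exonic"}, \code{"intronic"} or \code{"unknown"}. UTR classes are
#' only derivable when the annotation carries CDS records for the
#' containing transcript; otherwise exonic/intronic is reported.
#'
#' @param chrom,pos Chromosome name and 1-based position.
#' @param exons An \code{exon_model}.
#' @return Character scalar feature class.
#' @export
feature_class <- function(chrom, pos, exons) {
  if (!(chrom %in% exons$tx$chrom)) return("unknown")
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hit_tx <- names(exons$exons)[overlaps_any_tx(q, exons$exons)]
  if (length(hit_tx) == 0L) {
    ## inside a transcript span but not an exon?
    spans <- range_tx(exons$exons)
    inside <- IRanges::overlapsAny(q, spans, ignore.strand = TRUE)
    return(if (inside) "intronic" else "unknown")
  }
  for (t in hit_tx) {
    if (!(t %in% names(exons$cds))) next
    cds <- exons$cds[[t]]
    if (length(cds) == 0L) next
    if (IRanges::overlapsAny(q, cds, ignore.strand = TRUE)) return("CDS")
    strand <- as.character(GenomicRanges::strand(cds)[1])
    cds_start <- min(GenomicRanges::start(cds))
    cds_end <- max(GenomicRanges::end(cds))
    upstream <- if (strand == "-") pos > cds_end else pos < cds_start
    return(if (upstream) "5UTR" else "3UTR")
  }
  "exonic"
}

overlaps_any_tx <- function(q, exl) {
  vapply(seq_along(exl), function(i)
    IRanges::overlapsAny(q, exl[[i]], ignore.strand = TRUE), logical(1))
}

range_tx <- function(exl) {
  unlist(GenomicRanges::reduce(range(exl, ignore.strand = TRUE)),
         use.names = FALSE)
}

#' Locate occurrences of an IUPAC consensus motif
#'
#' @param seq Character scalar or \code{DNAString}; U is normalised to T.
#' @param motif IUPAC motif string, default \code{"RRACH"}
#'   (R = A/G, H = A/C/T).
#' @return Integer vector of 1-based start positions of motif occurrences
#'   within \code{seq}.
#' @export
scan_motif <- function(seq, motif = "RRACH") {
  s <- normalize_seq(seq)
  m <- Biostrings::matchPattern(Biostrings::DNAString(motif), s,
                                fixed = FALSE)
  BiocGenerics::start(m)
}

normalize_seq <- function(seq) {
  if (is(seq, "DNAString")) return(seq)
  s <- chartr("uU", "tT", as.character(seq))
  Biostrings::DNAString(toupper(s))
}

## 1-based offset of the methylatable A inside the motif (3 for RRACH)
motif_a_offset <- function(motif) {
  off <- regexpr("A", motif, fixed = TRUE)
  if (off < 0) stop("motif contains no literal A: ", motif)
  as.integer(off)
}

#' Signed distance from a position to the nearest consensus motif
#'
#' Measures the distance from a query position (typically a peak summit or
#' deconvolved site) to the A of the nearest motif occurrence within a
#' sequence window. Negative distances are upstream (lower coordinate) in
#' the window's orientation.
#'
#' @param pos 1-based genomic position of the query.
#' @param seq Window sequence (character or \code{DNAString}).
#' @param origin 1-based genomic position of the first base of \code{seq}.
#' @param motif IUPAC motif, default \code{"RRACH"}.
#' @return Signed integer distance in nt, or \code{NA} when no occurrence
#'   lies within the window.
#' @export
nearest_consensus <- function(pos, seq, origin, motif = "RRACH") {
  s <- normalize_seq(seq)
  idx <- pos - origin + 1L
  if (idx < 1L || idx > length(s)) stop("pos outside the sequence window")
  starts <- scan_motif(s, motif)
  if (length(starts) == 0L) return(NA_integer_)
  a_pos <- starts + motif_a_offset(motif) - 1L
  d <- a_pos - idx
  d[which.min(abs(d))]
}

#' Peak-matched random control positions
#'
#' For each peak, draws one position uniformly from exonic positions of
#' the same transcript-region feature class (5'UTR/CDS/3'UTR/intronic),
#' emulating a class-matched background for consensus-distance
#' evaluations. Peaks whose class has no available positions fall back to
#' a whole-transcript draw and are flagged.
#'
#' @param peaks Peak data.frame (needs \code{chrom}, \code{summit}).
#' @param exons An \code{exon_model}.
#' @param seed Integer seed; the draw is reproducible.
#' @return data.frame with \code{chrom}, \code{pos}, \code{class},
#'   \code{fallback}.
#' @export
random_control_positions <- function(peaks, exons, seed = 1L) {
  stopifnot(nrow(peaks) > 0L)
  set.seed(as.integer(seed))
  cls <- mapply(feature_class, peaks$chrom, peaks$summit,
                MoreArgs = list(exons = exons))
  pools <- control_pools(exons)
  out <- data.frame(chrom = peaks$chrom, pos = NA_integer_, class = cls,
                    fallback = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks))) {
    pool <- pools[[cls[i]]]
    fb <- is.null(pool) || length(pool$pos) == 0L
    if (fb) pool <- pools[["exonic"]]
    j <- sample.int(length(pool$pos), 1L)
    out$chrom[i] <- pool$chrom[j]
    out$pos[i] <- pool$pos[j]
    out$fallback[i] <- fb
  }
  out
}

## flatten per-class position pools (sampled at single-base resolution)
control_pools <- function(exons) {
  all_ex <- unlist(exons$exons, use.names = FALSE)
  pools <- list()
  expand <- function(gr) {
    if (length(gr) == 0L) return(list(chrom = character(0), pos = integer(0)))
    pos <- unlist(mapply(seq, GenomicRanges::start(gr),
                         GenomicRanges::end(gr), SIMPLIFY = FALSE))
    chrom <- rep(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::width(gr))
    list(chrom = chrom, pos = as.integer(pos))
  }
  pools[["exonic"]] <- expand(GenomicRanges::reduce(all_ex,
                                                    ignore.strand = TRUE))
  cds_all <- if (length(exons$cds) > 0L)
    GenomicRanges::reduce(unlist(exons$cds, use.names = FALSE),
                          ignore.strand = TRUE)
  else GenomicRanges::GRanges()
  pools[["CDS"]] <- expand(cds_all)
  ## UTRs: exonic minus CDS, split by side of the CDS per transcript
  utr5 <- GenomicRanges::GRanges(); utr3 <- GenomicRanges::GRanges()
  for (t in names(exons$cds)) {
    if (!(t %in% names(exons$exons))) next
    cds <- exons$cds[[t]]
    if (length(cds) == 0L) next
    ex <- exons$exons[[t]]
    strand <- as.character(GenomicRanges::strand(ex)[1])
    non_cds <- GenomicRanges::setdiff(GenomicRanges::reduce(ex,
                                                            ignore.strand = TRUE),
                                      GenomicRanges::reduce(cds,
                                                            ignore.strand = TRUE),
                                      ignore.strand = TRUE)
    if (length(non_cds) == 0L) next
    cs <- min(GenomicRanges::start(cds)); ce <- max(GenomicRanges::end(cds))
    up <- non_cds[GenomicRanges::end(non_cds) < cs]
    dn <- non_cds[GenomicRanges::start(non_cds) > ce]
    if (strand == "-") { tmp <- up; up <- dn; dn <- tmp }
    utr5 <- c(utr5, up); utr3 <- c(utr3, dn)
  }
  pools[["5UTR"]] <- expand(GenomicRanges::reduce(utr5, ignore.strand = TRUE))
  pools[["3UTR"]] <- expand(GenomicRanges::reduce(utr3, ignore.strand = TRUE))
  spans <- range_tx(exons$exons)
  intr <- GenomicRanges::setdiff(spans, GenomicRanges::reduce(all_ex,
                                                              ignore.strand = TRUE),
                                 ignore.strand = TRUE)
  pools[["intronic"]] <- expand(intr)
  pools[["unknown"]] <- pools[["exonic"]]
  pools
}
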