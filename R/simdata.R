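#' Simulation configuration
#'
#' Defines the generative conditions for a synthetic MeRIP-seq
#' experiment: multi-exon transcripts on their own contigs, methylated
#' adenosines planted in RRACH context, INPUT fragments proportional to
#' expression, and IP fragments enriched over planted sites at a
#' configurable fold with a uniform-background noise fraction.
#'
#' @param n_transcripts Number of transcripts (one contig each).
#' @param exons_per_tx Integer range \code{c(min, max)} of exons.
#' @param tx_length Range of exonic (spliced) transcript length, nt.
#' @param n_sites Range of planted sites per transcript.
#' @param ip_enrichment_fold IP/INPUT coverage fold at planted sites
#'   (default 8).
#' @param expression_meanlog,expression_sdlog Log-normal expression
#'   distribution parameters.
#' @param fragment_length_mean,fragment_length_sd Sequenced fragment
#'   length distribution (nt).
#' @param read_length Read length (nt).
#' @param paired Emit paired-end reads (default TRUE).
#' @param noise_fraction Fraction of IP fragments drawn from the INPUT
#'   (background) model; 1.0 gives a null experiment.
#' @param depth Fragments per library.
#' @param intron_length Range of intron lengths, nt.
#' @param min_site_separation Minimum spacing between planted sites, nt.
#' @param site_margin Keep sites this far from transcript ends, nt.
#' @param plant_motif Plant sites inside a GGACT (RRACH) context; when
#'   FALSE the site base is an A with no consensus guarantee.
#' @param seed Mandatory integer seed.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_transcripts = 50L, exons_per_tx = c(1L, 3L),
                       tx_length = c(1500L, 3000L), n_sites = c(1L, 2L),
                       ip_enrichment_fold = 8, expression_meanlog = 0,
                       expression_sdlog = 0.5, fragment_length_mean = 100L,
                       fragment_length_sd = 10L, read_length = 50L,
                       paired = TRUE, noise_fraction = 0.1, depth = 2e5,
                       intron_length = c(200L, 800L),
                       min_site_separation = 250L, site_margin = 150L,
                       plant_motif = TRUE, seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  stopifnot(n_transcripts > 0, depth > 0, ip_enrichment_fold > 0,
            noise_fraction >= 0, noise_fraction <= 1,
            fragment_length_mean >= read_length)
  structure(as.list(environment()), class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a reference: FASTA, GTF and ground truth
#'
#' Each transcript occupies its own contig, with exons separated by
#' random introns and 50-nt genomic flanks. Site positions are drawn in
#' transcript coordinates with the configured spacing and a GGACT
#' consensus written over the surrounding bases (the A is the site), so
#' every ground-truth site lies on an A inside an RRACH occurrence.
#' A central 60% of each transcript is annotated as CDS, giving
#' derivable 5'UTR/CDS/3'UTR classes. Byte-identical under a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return A \code{sim_reference}: paths (\code{fasta}, \code{gtf}),
#'   in-memory \code{seqs} (\code{DNAStringSet}), \code{exon_model},
#'   \code{truth} data.frame (\code{chrom}, \code{pos}, \code{tx_pos},
#'   \code{transcript}, \code{fold}), \code{expression},
#'   \code{tx_map}, and the \code{cfg}.
#' @export
simulate_reference <- function(cfg, dir = tempfile("simref")) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(cfg$seed))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flank <- 50L
  seqs <- character(cfg$n_transcripts)
  gtf_lines <- character(0)
  truth <- list()
  tx_map <- list()
  expr <- stats::rlnorm(cfg$n_transcripts, cfg$expression_meanlog,
                        cfg$expression_sdlog)
  for (t in seq_len(cfg$n_transcripts)) {
    chrom <- sprintf("tx%03d", t)
    T_len <- sample(cfg$tx_length[1]:cfg$tx_length[2], 1L)
    n_ex <- sample(cfg$exons_per_tx[1]:cfg$exons_per_tx[2], 1L)
    ## exon lengths: random composition with >= 200 nt per exon
    if (n_ex > 1L) {
      repeat {
        cuts <- sort(sample(200:(T_len - 200L), n_ex - 1L))
        lens <- diff(c(0L, cuts, T_len))
        if (all(lens >= 200L)) break
      }
    } else lens <- T_len
    introns <- if (n_ex > 1L)
      sample(cfg$intron_length[1]:cfg$intron_length[2], n_ex - 1L,
             replace = TRUE)
    else integer(0)

    ## sites in transcript coordinates
    k <- sample(cfg$n_sites[1]:cfg$n_sites[2], 1L)
    lo <- cfg$site_margin; hi <- T_len - cfg$site_margin
    sites_tx <- integer(0)
    for (tries in 1:200) {
      cand <- sort(sample(lo:hi, k))
      if (k == 1L || min(diff(cand)) >= cfg$min_site_separation) {
        sites_tx <- cand; break
      }
    }
    if (length(sites_tx) == 0L)
      stop("could not place ", k, " sites with the configured spacing in ",
           chrom)

    tx_seq <- random_dna(T_len)
    for (s in sites_tx) {
      if (cfg$plant_motif) {
        substr(tx_seq, s - 2L, s + 2L) <- "GGACT"
      } else {
        substr(tx_seq, s, s) <- "A"
      }
    }

    ## assemble contig and the transcript->genome map
    c_start <- cumsum(c(1L, lens))[seq_len(n_ex)]          # tx coords
    g_start <- integer(n_ex)
    pos <- flank + 1L
    pieces <- character(0)
    tx_off <- 1L
    for (i in seq_len(n_ex)) {
      g_start[i] <- pos
      pieces <- c(pieces, substr(tx_seq, tx_off, tx_off + lens[i] - 1L))
      pos <- pos + lens[i]
      tx_off <- tx_off + lens[i]
      if (i < n_ex) {
        pieces <- c(pieces, random_dna(introns[i]))
        pos <- pos + introns[i]
      }
    }
    contig <- paste0(random_dna(flank), paste(pieces, collapse = ""),
                     random_dna(flank))
    seqs[t] <- contig
    map <- data.frame(tx_start = c_start, tx_end = c_start + lens - 1L,
                      g_start = g_start, g_end = g_start + lens - 1L)
    tx_map[[chrom]] <- map

    g_sites <- tx_to_genome(map, sites_tx)
    truth[[chrom]] <- data.frame(chrom = chrom, pos = g_sites,
                                 tx_pos = sites_tx, transcript = chrom,
                                 fold = cfg$ip_enrichment_fold,
                                 stringsAsFactors = FALSE)

    gid <- sprintf("gene%03d", t); tid <- sprintf("t%03d", t)
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
    for (i in seq_len(n_ex))
      gtf_lines <- c(gtf_lines, paste(chrom, "sim", "exon", map$g_start[i],
                                      map$g_end[i], ".", "+", ".", attrs,
                                      sep = "\t"))
    ## central 60% of the transcript as CDS
    cds_tx <- c(ceiling(T_len * 0.2), floor(T_len * 0.8))
    cds_g <- interval_to_blocks(map, cds_tx[1], cds_tx[2])
    for (i in seq_len(nrow(cds_g)))
      gtf_lines <- c(gtf_lines, paste(chrom, "sim", "CDS", cds_g$g_start[i],
                                      cds_g$g_end[i], ".", "+", ".", attrs,
                                      sep = "\t"))
  }
  names(seqs) <- sprintf("tx%03d", seq_len(cfg$n_transcripts))
  dss <- Biostrings::DNAStringSet(seqs)
  fasta <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(dss, fasta)
  Rsamtools::indexFa(fasta)
  gtf <- file.path(dir, "annotation.gtf")
  writeLines(gtf_lines, gtf)
  truth_df <- do.call(rbind, truth)
  rownames(truth_df) <- NULL
  ## exon model built in memory from the same records written to the GTF
  f <- strsplit(gtf_lines, "\t", fixed = TRUE)
  gr <- GenomicRanges::GRanges(
    vapply(f, `[`, "", 1L),
    IRanges::IRanges(as.integer(vapply(f, `[`, "", 4L)),
                     as.integer(vapply(f, `[`, "", 5L))),
    strand = vapply(f, `[`, "", 7L))
  gr$type <- vapply(f, `[`, "", 3L)
  at <- vapply(f, `[`, "", 9L)
  gr$gene_id <- sub('.*gene_id "([^"]+)".*', "\\1", at)
  gr$transcript_id <- sub('.*transcript_id "([^"]+)".*', "\\1", at)
  ref <- structure(list(
    fasta = fasta, gtf = gtf, seqs = dss,
    exon_model = build_exon_model(gr),
    truth = truth_df,
    expression = data.frame(chrom = names(seqs), expression = expr,
                            tx_length = vapply(tx_map, function(m)
                              sum(m$tx_end - m$tx_start + 1L), integer(1)),
                            stringsAsFactors = FALSE),
    tx_map = tx_map, cfg = cfg, dir = dir),
    class = "sim_reference")
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth_df, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ref$truth_path <- truth_path
  ref
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("sim_reference:", length(x$seqs), "transcripts,",
      nrow(x$truth), "planted sites, seed", x$cfg$seed, "\n  dir:", x$dir,
      "\n")
  invisible(x)
}

tx_to_genome <- function(map, pos) {
  i <- findInterval(pos, map$tx_start)
  map$g_start[i] + (pos - map$tx_start[i])
}

## genomic blocks covered by transcript interval [a, b]
interval_to_blocks <- function(map, a, b) {
  i1 <- findInterval(a, map$tx_start)
  i2 <- findInterval(b, map$tx_start)
  rows <- lapply(i1:i2, function(i) {
    ta <- max(a, map$tx_start[i]); tb <- min(b, map$tx_end[i])
    data.frame(g_start = map$g_start[i] + (ta - map$tx_start[i]),
               g_end = map$g_start[i] + (tb - map$tx_start[i]))
  })
  do.call(rbind, rows)
}

cigar_for <- function(map, a, b) {
  bl <- interval_to_blocks(map, a, b)
  if (nrow(bl) == 1L) return(sprintf("%dM", bl$g_end - bl$g_start + 1L))
  parts <- character(0)
  for (i in seq_len(nrow(bl))) {
    parts <- c(parts, sprintf("%dM", bl$g_end[i] - bl$g_start[i] + 1L))
    if (i < nrow(bl))
      parts <- c(parts, sprintf("%dN", bl$g_start[i + 1L] - bl$g_end[i] - 1L))
  }
  paste(parts, collapse = "")
}

#' Simulate a MeRIP-seq experiment: IP and INPUT BAM files
#'
#' INPUT fragments are placed uniformly along transcripts with
#' probability proportional to expression times length. IP fragments are
#' drawn from a mixture: a \code{noise_fraction} share follows the INPUT
#' model; the rest picks a transcript weighted by its site content and,
#' within it, either background placement or a planted site with weight
#' \code{(fold - 1) * fragment_length}, the fragment start being uniform
#' over the placements covering the site — the same admissible-placement
#' kernel the deconvolution likelihood assumes. This construction makes
#' the expected IP/INPUT coverage ratio at a site equal to
#' \code{(1 - noise) * fold + noise}. Fragments become single- or
#' paired-end reads with splice-aware CIGARs; BAMs are coordinate-sorted
#' and indexed. Deterministic under the configuration seed.
#'
#' @param ref A \code{sim_reference}.
#' @param dir Output directory (defaults to the reference directory).
#' @return List with \code{ip_bam}, \code{input_bam} paths and the
#'   per-library fragment count \code{depth}.
#' @export
simulate_experiment <- function(ref, dir = ref$dir) {
  cfg <- ref$cfg
  set.seed(as.integer(cfg$seed) + 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  D <- as.integer(cfg$depth)
  if (D <= 0L) stop("depth must be positive")
  chroms <- ref$expression$chrom
  T_len <- ref$expression$tx_length
  e <- ref$expression$expression
  Lbar <- cfg$fragment_length_mean
  fold <- cfg$ip_enrichment_fold

  sites_by_tx <- split(ref$truth$tx_pos, ref$truth$chrom)
  n_sites_tx <- vapply(chroms, function(ch)
    length(sites_by_tx[[ch]]), integer(1))

  draw_lengths <- function(n) {
    L <- as.integer(round(stats::rnorm(n, Lbar, cfg$fragment_length_sd)))
    pmax(cfg$read_length, pmin(L, min(T_len) - 1L))
  }

  ## INPUT model: transcript ~ expression x length, uniform placement
  draw_background <- function(n) {
    w <- e * T_len
    tx <- sample.int(length(chroms), n, replace = TRUE, prob = w)
    L <- draw_lengths(n)
    start <- 1L + as.integer(floor(stats::runif(n) * (T_len[tx] - L + 1L)))
    data.frame(tx = tx, start = start, len = L)
  }

  input_frags <- draw_background(D)

  ## IP model
  n_noise <- stats::rbinom(1L, D, cfg$noise_fraction)
  ip_noise <- if (n_noise > 0L) draw_background(n_noise) else NULL
  n_sig <- D - n_noise
  ip_sig <- NULL
  if (n_sig > 0L) {
    w_tx <- e * (T_len + n_sites_tx * (fold - 1) * Lbar)
    tx <- sample.int(length(chroms), n_sig, replace = TRUE, prob = w_tx)
    L <- draw_lengths(n_sig)
    ## background vs planted-site component, then uniform site choice
    p_site <- (n_sites_tx[tx] * (fold - 1) * Lbar) /
      (T_len[tx] + n_sites_tx[tx] * (fold - 1) * Lbar)
    at_site <- stats::runif(n_sig) < p_site
    start <- 1L + as.integer(floor(stats::runif(n_sig) * (T_len[tx] - L + 1L)))
    if (any(at_site)) {
      ix <- which(at_site)
      site_of <- vapply(ix, function(i) {
        ss <- sites_by_tx[[chroms[tx[i]]]]
        if (length(ss) == 1L) ss else sample(ss, 1L)
      }, integer(1))
      a <- pmax(1L, site_of - L[ix] + 1L)
      b <- pmin(site_of, T_len[tx[ix]] - L[ix] + 1L)
      start[ix] <- a + as.integer(floor(stats::runif(length(ix)) *
                                          (b - a + 1L)))
    }
    ip_sig <- data.frame(tx = tx, start = start, len = L)
  }
  ip_frags <- rbind(ip_sig, ip_noise)

  write_lib <- function(frags, name) {
    sam <- file.path(dir, paste0(name, ".sam"))
    write_sim_sam(frags, ref, sam)
    bam <- Rsamtools::asBam(sam, file.path(dir, name), overwrite = TRUE)
    unlink(sam)
    bam
  }
  ip_bam <- write_lib(ip_frags, "ip")
  input_bam <- write_lib(input_frags, "input")
  list(ip_bam = ip_bam, input_bam = input_bam, depth = D)
}

## vectorised transcript-interval -> (genomic pos, CIGAR) mapping
map_reads <- function(map, a, b) {
  i1 <- findInterval(a, map$tx_start)
  i2 <- findInterval(b, map$tx_start)
  pos <- map$g_start[i1] + (a - map$tx_start[i1])
  cig <- character(length(a))
  simple <- i1 == i2
  cig[simple] <- sprintf("%dM", b[simple] - a[simple] + 1L)
  for (j in which(!simple)) cig[j] <- cigar_for(map, a[j], b[j])
  list(pos = pos, cigar = cig)
}

## emit one SAM record set (paired or single) per fragment
write_sim_sam <- function(frags, ref, path) {
  cfg <- ref$cfg
  chroms <- ref$expression$chrom
  rl <- cfg$read_length
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref$seqs),
                      lengths(ref$seqs)))
  n <- nrow(frags)
  qname <- sprintf("f%07d", seq_len(n))
  by_tx <- split(seq_len(n), frags$tx)
  lines <- vector("list", length(by_tx))
  li <- 0L
  for (txs in names(by_tx)) {
    ix <- by_tx[[txs]]
    map <- ref$tx_map[[chroms[as.integer(txs)]]]
    chrom <- chroms[as.integer(txs)]
    a <- frags$start[ix]
    b <- a + frags$len[ix] - 1L
    if (cfg$paired) {
      m1 <- map_reads(map, a, pmin(b, a + rl - 1L))
      m2 <- map_reads(map, pmax(a, b - rl + 1L), b)
      gend <- tx_to_genome(map, b)
      tlen <- gend - m1$pos + 1L
      rec <- c(paste(qname[ix], 99L, chrom, m1$pos, 60L, m1$cigar,
                     "=", m2$pos, tlen, "*", "*", sep = "\t"),
               paste(qname[ix], 147L, chrom, m2$pos, 60L, m2$cigar,
                     "=", m1$pos, -tlen, "*", "*", sep = "\t"))
    } else {
      fwd <- stats::runif(length(ix)) < 0.5
      ra <- ifelse(fwd, a, pmax(a, b - rl + 1L))
      rb <- ifelse(fwd, pmin(b, a + rl - 1L), b)
      m <- map_reads(map, ra, rb)
      rec <- paste(qname[ix], ifelse(fwd, 0L, 16L), chrom, m$pos, 60L,
                   m$cigar, "*", 0L, 0L, "*", "*", sep = "\t")
    }
    li <- li + 1L
    lines[[li]] <- rec
  }
  writeLines(c(header, unlist(lines[seq_len(li)])), path)
  invisible(path)
}

#' Evaluate called peaks against simulated ground truth
#'
#' A planted site is recovered when a retained peak's region (expanded by
#' \code{tolerance}) contains it; a retained peak is a true positive when
#' it contains at least one planted site. Distances are measured from the
#' deconvolved site when present (and \code{use_sites = TRUE}), else the
#' summit, to the planted adenosine.
#'
#' @param peaks Peak data.frame.
#' @param truth Ground-truth data.frame (\code{chrom}, \code{pos}).
#' @param tolerance Region expansion in nt (default 10).
#' @param use_sites Use deconvolved \code{site_pos} for distances when
#'   available.
#' @return List: \code{recall}, \code{precision}, \code{distances}
#'   (per recovered site), \code{n_sites}, \code{n_peaks}.
#' @export
truth_eval <- function(peaks, truth, tolerance = 10L, use_sites = FALSE) {
  ret <- peaks[peaks$retained, , drop = FALSE]
  n_sites <- nrow(truth)
  if (nrow(ret) == 0L)
    return(list(recall = 0, precision = NA_real_,
                distances = numeric(0), n_sites = n_sites, n_peaks = 0L))
  est <- if (use_sites && !is.null(ret$site_pos))
    ifelse(is.na(ret$site_pos), ret$summit, ret$site_pos)
  else ret$summit
  recovered <- logical(n_sites)
  dist <- rep(NA_real_, n_sites)
  for (i in seq_len(n_sites)) {
    m <- which(ret$chrom == truth$chrom[i] &
                 ret$start - tolerance <= truth$pos[i] &
                 ret$end + tolerance >= truth$pos[i])
    if (length(m) > 0L) {
      recovered[i] <- TRUE
      dist[i] <- min(abs(est[m] - truth$pos[i]))
    }
  }
  peak_tp <- vapply(seq_len(nrow(ret)), function(j)
    any(truth$chrom == ret$chrom[j] &
          truth$pos >= ret$start[j] - tolerance &
          truth$pos <= ret$end[j] + tolerance), logical(1))
  list(recall = mean(recovered), precision = mean(peak_tp),
       distances = dist[recovered], n_sites = n_sites,
       n_peaks = nrow(ret))
}

#' Simulate fragments for a single enriched region
#'
#' Region-level generator used for deconvolution benchmarks: a random
#' sequence with RRACH-context adenosines planted at the requested
#' sites, and fragments drawn from the admissible-placement kernel (a
#' fragment attributed to a site starts uniformly among the placements
#' covering it) plus a uniform noise share.
#'
#' @param region_len Region length, nt (default 400).
#' @param sites Site positions within the region (default the centre).
#' @param n_frags Fragments to draw (default 100).
#' @param frag_len Fragment length, nt (default 50).
#' @param noise Noise fraction (default 0.1).
#' @param seed Optional seed (set by the caller when omitted).
#' @return List: \code{seq} (character), \code{sites}, \code{fragments}
#'   (data.frame \code{start}, \code{end}), \code{n_noise}.
#' @export
simulate_region <- function(region_len = 400L, sites = NULL, n_frags = 100L,
                            frag_len = 50L, noise = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(sites)) sites <- region_len %/% 2L
  stopifnot(all(sites > 3L), all(sites < region_len - 2L))
  s <- random_dna(region_len)
  for (p in sites) substr(s, p - 2L, p + 2L) <- "GGACT"
  is_noise <- stats::runif(n_frags) < noise
  start <- integer(n_frags)
  for (i in seq_len(n_frags)) {
    if (is_noise[i]) {
      start[i] <- sample.int(region_len - frag_len + 1L, 1L)
    } else {
      p <- if (length(sites) == 1L) sites else sample(sites, 1L)
      a <- max(1L, p - frag_len + 1L)
      b <- min(p, region_len - frag_len + 1L)
      start[i] <- sample(a:b, 1L)
    }
  }
  list(seq = s, sites = sites,
       fragments = data.frame(start = start, end = start + frag_len - 1L),
       n_noise = sum(is_noise))
}
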