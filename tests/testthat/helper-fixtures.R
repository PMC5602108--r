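# Shared fixtures built in code at test time.

# Write SAM lines (no header) for a contig set and return an indexed BAM.
make_bam <- function(lines, seqlens = c(chr1 = 10000L)) {
  sam <- tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), seqlens))
  writeLines(c(header, lines), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  unlink(sam)
  bam
}

sam_rec <- function(qname, flag, chrom, pos, cigar, mapq = 60L,
                    rnext = "*", pnext = 0L, tlen = 0L) {
  paste(qname, flag, chrom, pos, mapq, cigar, rnext, pnext, tlen, "*", "*",
        sep = "\t")
}

# A small two-exon GTF written to disk.
make_gtf <- function(path = tempfile(fileext = ".gtf")) {
  attrs <- function(g, t) sprintf('gene_id "%s"; transcript_id "%s";', g, t)
  lines <- c(
    paste("chr1", "test", "exon", 51, 140, ".", "+", ".",
          attrs("g1", "t1"), sep = "\t"),
    paste("chr1", "test", "exon", 301, 400, ".", "+", ".",
          attrs("g1", "t1"), sep = "\t"),
    paste("chr1", "test", "CDS", 101, 140, ".", "+", ".",
          attrs("g1", "t1"), sep = "\t"),
    paste("chr1", "test", "CDS", 301, 350, ".", "+", ".",
          attrs("g1", "t1"), sep = "\t"),
    paste("chr2", "test", "exon", 1001, 1500, ".", "-", ".",
          attrs("g2", "t2"), sep = "\t"))
  writeLines(lines, path)
  path
}

# One small simulated experiment shared across tests (built once).
.shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- meripeaks::sim_config(n_transcripts = 8L, depth = 30000L,
                                   seed = 11L)
      ref <- meripeaks::simulate_reference(cfg)
      exp <- meripeaks::simulate_experiment(ref)
      cache <<- list(ref = ref, exp = exp)
    }
    cache
  }
})

# The standard end-to-end fixture: 50 transcripts, 1-2 sites each,
# fold 8, 2e5 fragments per library, seed 7.
.standard_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- meripeaks::sim_config(seed = 7L)
      ref <- meripeaks::simulate_reference(cfg)
      exp <- meripeaks::simulate_experiment(ref)
      cache <<- list(ref = ref, exp = exp)
    }
    cache
  }
})

# Null experiment (pure noise IP) sized to give > 2000 testable tiles.
.null_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- meripeaks::sim_config(n_transcripts = 120L,
                                   tx_length = c(3000L, 4000L),
                                   depth = 200000L, noise_fraction = 1.0,
                                   seed = 42L)
      ref <- meripeaks::simulate_reference(cfg)
      exp <- meripeaks::simulate_experiment(ref)
      cache <<- list(ref = ref, exp = exp)
    }
    cache
  }
})
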