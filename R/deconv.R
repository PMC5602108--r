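#' Candidate methylation sites in a region
#'
#' Methylation can only occur at an adenosine, so the candidate site set
#' for deconvolution is the adenosine positions of the region's
#' sequence; optionally restricted to the A of RRACH consensus
#' occurrences.
#'
#' @param seq Region sequence (character or \code{DNAString}).
#' @param origin 1-based genomic position of the first base of \code{seq}.
#' @param restrict Restrict to consensus-context adenosines.
#' @param motif IUPAC motif used when \code{restrict = TRUE}.
#' @return Integer vector of 1-based genomic candidate positions (may be
#'   empty).
#' @export
candidate_sites <- function(seq, origin = 1L, restrict = FALSE,
                            motif = "RRACH") {
  s <- normalize_seq(seq)
  if (restrict) {
    starts <- scan_motif(s, motif)
    pos <- starts + motif_a_offset(motif) - 1L
  } else {
    pos <- BiocGenerics::start(Biostrings::matchPattern("A", s))
  }
  as.integer(pos + origin - 1L)
}

#' Fragment-given-site likelihood
#'
#' The generative model for an IP fragment attributed to a methylated
#' site: the fragment must cover the site, and its start is uniform over
#' the admissible placements, so the density is \code{1 / L} for a
#' fragment of total length L covering the site and 0 otherwise. The
#' noise component is uniform over the region
#' (\code{1 / region_length}).
#'
#' @param frag_start,frag_end Fragment span (1-based closed); for spliced
#'   fragments pass the covered-block representation via
#'   [fragment_lik_matrix()] instead.
#' @param frag_len Total fragment length (covered bases).
#' @param site Candidate site position.
#' @return Density value.
#' @export
fragment_site_likelihood <- function(frag_start, frag_end, frag_len, site) {
  stopifnot(frag_len > 0)
  ifelse(site >= frag_start & site <= frag_end, 1 / frag_len, 0)
}

#' Likelihood matrix of fragments against candidate sites
#'
#' @param fragments \code{GRangesList} of fragment blocks, or a
#'   data.frame with \code{start}, \code{end} columns (unspliced).
#' @param sites Integer vector of candidate positions.
#' @return Numeric matrix \code{[n_fragments x n_sites]} of densities.
#' @export
fragment_lik_matrix <- function(fragments, sites) {
  if (is.data.frame(fragments)) {
    n <- nrow(fragments)
    L <- fragments$end - fragments$start + 1
    D <- matrix(0, n, length(sites))
    for (j in seq_along(sites))
      D[, j] <- fragment_site_likelihood(fragments$start, fragments$end,
                                         L, sites[j])
    return(D)
  }
  n <- length(fragments)
  L <- sum(IRanges::width(fragments))
  D <- matrix(0, n, length(sites))
  if (n == 0L || length(sites) == 0L) return(D)
  chrom <- fragment_chroms(fragments)[1]
  sgr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(sites, sites))
  ov <- GenomicRanges::findOverlaps(sgr, fragments, ignore.strand = TRUE)
  D[cbind(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))] <-
    1 / L[S4Vectors::subjectHits(ov)]
  D
}

#' Greedy EM initialisation
#'
#' Repeatedly selects the candidate position covering the most
#' not-yet-assigned fragments (a greedy set-cover over the
#' fragment-covers-site relation); initial weights are proportional to
#' the number of fragments covering each chosen site, renormalised to
#' leave a small initial noise weight.
#'
#' @param D Likelihood matrix from [fragment_lik_matrix()].
#' @param n_sites Number of mixture components to initialise.
#' @param noise0 Initial noise weight (default 0.05).
#' @return List with \code{site_idx} (columns of D), \code{weights},
#'   \code{noise_weight}.
#' @export
init_em <- function(D, n_sites, noise0 = 0.05) {
  covers <- D > 0
  m <- ncol(D)
  if (n_sites > m) {
    warning("n_sites reduced to the number of candidates (", m, ")")
    n_sites <- m
  }
  unassigned <- rep(TRUE, nrow(D))
  chosen <- integer(0)
  for (k in seq_len(n_sites)) {
    gain <- colSums(covers & unassigned)
    gain[chosen] <- -1
    pick <- which.max(gain)
    chosen <- c(chosen, pick)
    unassigned <- unassigned & !covers[, pick]
  }
  w <- colSums(covers)[chosen]
  if (sum(w) == 0) w <- rep(1, n_sites)
  w <- w / sum(w) * (1 - noise0)
  list(site_idx = chosen, weights = w, noise_weight = noise0)
}

#' Fit a site mixture by expectation-maximization
#'
#' Alternates between computing fragment-to-component responsibilities
#' (over the candidate sites plus a uniform noise component) and
#' re-estimating mixture weights and site positions. Site relocation in
#' the M-step maximises each component's responsibility-weighted expected
#' log-likelihood over the candidate list (a generalized EM step), so the
#' observed-data log-likelihood is non-decreasing at every iteration.
#'
#' @param D Likelihood matrix (\code{[fragments x candidates]}).
#' @param sites Candidate positions (columns of D).
#' @param region_len Region length (noise density is its reciprocal).
#' @param n_sites Number of site components.
#' @param init Optional initialisation (as returned by [init_em()]).
#' @param tol Log-likelihood convergence tolerance (default 1e-4).
#' @param max_iter Maximum EM iterations (default 200).
#' @return A \code{site_mixture}: \code{sites}, \code{weights},
#'   \code{noise_weight}, \code{log_likelihood}, \code{bic} (with
#'   \code{k = 2 * n_sites}: site positions plus free weights),
#'   \code{n_fragments}, \code{converged}, \code{n_iterations},
#'   \code{ll_trace}.
#' @export
em_fit <- function(D, sites, region_len, n_sites, init = NULL,
                   tol = 1e-4, max_iter = 200L) {
  n <- nrow(D)
  if (n == 0L) stop("no fragments to fit")
  stopifnot(length(sites) == ncol(D), n_sites >= 1L)
  if (is.null(init)) init <- init_em(D, n_sites)
  n_sites <- length(init$site_idx)
  site_idx <- init$site_idx
  w <- init$weights
  w0 <- init$noise_weight
  noise_den <- 1 / region_len
  logD <- log(pmax(D, 1e-300))
  frozen <- rep(FALSE, n_sites)

  ll_of <- function(site_idx, w, w0) {
    mix <- D[, site_idx, drop = FALSE] %*% w + w0 * noise_den
    sum(log(pmax(mix, 1e-300)))
  }
  ll <- ll_of(site_idx, w, w0)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    ## E-step
    comp <- sweep(D[, site_idx, drop = FALSE], 2L, w, `*`)
    noise <- rep(w0 * noise_den, n)
    denom <- rowSums(comp) + noise
    denom[denom < 1e-300] <- 1e-300
    R <- comp / denom
    Rn <- noise / denom
    ## M-step: weights
    w <- colMeans(R)
    w0 <- mean(Rn)
    frozen <- frozen | w < 1e-6
    ## M-step: site relocation over candidates (skip frozen components)
    score <- t(R) %*% logD            # n_sites x candidates
    for (j in seq_len(n_sites)) {
      if (frozen[j]) next
      sc <- score[j, ]
      sc[setdiff(site_idx, site_idx[j])] <- -Inf  # keep sites distinct
      best <- which.max(sc)
      if (sc[best] > sc[site_idx[j]] + 1e-12) site_idx[j] <- best
    }
    ll_new <- ll_of(site_idx, w, w0)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < tol) { converged <- TRUE; ll <- ll_new; break }
    ll <- ll_new
  }
  ord <- order(sites[site_idx])
  k <- 2L * n_sites
  structure(list(sites = sites[site_idx][ord], weights = w[ord],
                 noise_weight = w0, log_likelihood = ll,
                 bic = k * log(n) - 2 * ll, n_fragments = n,
                 converged = converged, n_iterations = iter,
                 frozen = frozen[ord], ll_trace = trace),
            class = "site_mixture")
}

#' @export
print.site_mixture <- function(x, ...) {
  cat("site_mixture:", length(x$sites), "site(s) at",
      paste(x$sites, collapse = ", "), "\n  weights:",
      paste(format(x$weights, digits = 3), collapse = ", "),
      " noise:", format(x$noise_weight, digits = 3),
      "\n  logLik:", format(x$log_likelihood, digits = 6),
      " BIC:", format(x$bic, digits = 6),
      " iters:", x$n_iterations,
      if (x$converged) "(converged)" else "(max_iter)", "\n")
  invisible(x)
}

#' Select the number of sites by BIC
#'
#' Fits mixtures with 1 to \code{max_sites} site components and returns
#' the fit minimising the Bayesian information criterion
#' \code{k ln(n) - 2 lnL}; ties favour fewer sites.
#'
#' @param D Likelihood matrix.
#' @param sites Candidate positions.
#' @param region_len Region length.
#' @param max_sites Maximum components to consider (default 5).
#' @param ... Passed to [em_fit()].
#' @return The minimum-BIC \code{site_mixture}, with an \code{all_bic}
#'   attribute giving the BIC per model order.
#' @export
select_model <- function(D, sites, region_len, max_sites = 5L, ...) {
  max_n <- min(max_sites, length(sites))
  stopifnot(max_n >= 1L)
  fits <- lapply(seq_len(max_n), function(k)
    em_fit(D, sites, region_len, n_sites = k, ...))
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  best <- which.min(bics)  # which.min takes the first (fewest sites) on ties
  fit <- fits[[best]]
  attr(fit, "all_bic") <- bics
  fit
}

#' Deconvolute called peaks into candidate m6A sites
#'
#' For every retained peak, collects the IP fragments overlapping the
#' peak region, enumerates candidate adenosines from the reference
#' sequence, fits site mixtures by EM and attaches the BIC-selected sites
#' to the peak table. Peaks whose region contains no adenosine keep the
#' summit-only call and are flagged \code{no_candidate}.
#'
#' @param peaks Peak data.frame from [call_peaks()].
#' @param fragments IP fragments (\code{GRangesList}) or an IP BAM path.
#' @param seqs Reference sequences: named \code{DNAStringSet}, FASTA
#'   path, or \code{FaFile}.
#' @param max_sites Maximum sites per region (default 5).
#' @param restrict Restrict candidates to consensus-context adenosines.
#' @param retained_only Deconvolute only unflagged peaks (default TRUE).
#' @param ... Passed to [em_fit()].
#' @return The peak data.frame with added columns \code{sites}
#'   (semicolon-delimited \code{pos:weight}), \code{site_pos} (top site),
#'   \code{site_weight}, \code{noise_weight}, \code{n_sites}.
#' @export
deconvolute_peaks <- function(peaks, fragments, seqs, max_sites = 5L,
                              restrict = FALSE, retained_only = TRUE, ...) {
  seqs <- load_seqs(seqs)
  if (is.character(fragments)) fragments <- infer_fragments(fragments)
  peaks$sites <- NA_character_
  peaks$site_pos <- NA_integer_
  peaks$site_weight <- NA_real_
  peaks$noise_weight <- NA_real_
  peaks$n_sites <- NA_integer_
  if (nrow(peaks) == 0L) return(peaks)
  frag_chr <- fragment_chroms(fragments)
  todo <- if (retained_only) which(peaks$retained) else seq_len(nrow(peaks))
  for (i in todo) {
    chrom <- peaks$chrom[i]
    if (!(chrom %in% names(seqs))) next
    st <- peaks$start[i]; en <- min(peaks$end[i], length(seqs[[chrom]]))
    region_seq <- Biostrings::subseq(seqs[[chrom]], st, en)
    cand <- candidate_sites(region_seq, origin = st, restrict = restrict)
    if (length(cand) == 0L) {
      peaks$flags[i] <- paste_flag(peaks$flags[i], "no_candidate")
      next
    }
    fi <- fragments[frag_chr == chrom]
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(st, en))
    fi <- fi[IRanges::overlapsAny(fi, gr, ignore.strand = TRUE)]
    if (length(fi) == 0L) next
    D <- fragment_lik_matrix(fi, cand)
    fit <- select_model(D, cand, region_len = en - st + 1L,
                        max_sites = max_sites, ...)
    ord <- order(fit$weights, decreasing = TRUE)
    peaks$sites[i] <- paste(sprintf("%d:%.4f", fit$sites[ord],
                                    fit$weights[ord]), collapse = ";")
    peaks$site_pos[i] <- fit$sites[ord][1]
    peaks$site_weight[i] <- fit$weights[ord][1]
    peaks$noise_weight[i] <- fit$noise_weight
    peaks$n_sites[i] <- length(fit$sites)
  }
  peaks
}

paste_flag <- function(flags, tag) {
  ifelse(flags == "", tag, paste(flags, tag, sep = ","))
}

load_seqs <- function(seqs) {
  if (is(seqs, "DNAStringSet")) return(seqs)
  if (is(seqs, "FaFile")) return(Biostrings::readDNAStringSet(
    Rsamtools::path(seqs)))
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs)) {
    out <- Biostrings::readDNAStringSet(seqs)
    names(out) <- sub("\\s.*$", "", names(out))
    return(out)
  }
  stop("seqs must be a DNAStringSet, FaFile, or FASTA path")
}
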