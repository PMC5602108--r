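---
title: "Methods: m6A peak calling, deconvolution and false-positive filtering"
author: "meripeaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: m6A peak calling, deconvolution and false-positive filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

MeRIP-seq (m6A-seq) profiles N6-methyladenosine by immunoprecipitating
fragmented RNA with an anti-m6A antibody and sequencing the captured
fragments together with a matched non-IP (INPUT) RNA-seq control.
A methylated adenosine shows up as a local pile-up of IP fragment
coverage, roughly twice as wide at its base as the sequenced fragment,
that is enriched over the expression-matched INPUT signal. Three
practical difficulties shape the design of this package:

* coverage must be computed over the *sequenced fragment*, not the read —
  single-end reads under-reach the fragment and paired mates may overlap
  or straddle introns, both of which distort read-level coverage;
* enriched regions can span multiple nearby methylated residues, and the
  coverage summit of even a single-site peak rarely coincides with the
  methylated base;
* a substantial share of called peaks are technical false positives
  (non-specific antibody binding, low-complexity alignments,
  contamination).

`meripeaks` addresses these with (1) splice-aware fragment coverage,
(2) a local-maximum caller with a one-sided exact enrichment test,
(3) an EM mixture deconvolution of enriched regions restricted to
adenosine positions with BIC model selection, and (4) a supervised
false-positive filter combining a mixture transition distribution (MTD)
sequence model with a random forest.

## Fragment model

Paired-end: each proper pair yields one fragment spanning from the
leftmost to the rightmost mate base. The interior not covered by either
mate is filled; with a GTF annotation only the exonic part of the
interior is filled (mates in different exons do not create
kilobase-scale fragments), without annotation the raw gap is included
only when it is shorter than 10 kb. Overlapping mates contribute each
base once.

Single-end: reads are extended toward their 3' end to `fragment_size`
total bases (default 100 nt). With annotation the extension walks the
reduced exon chain, jumping introns; without it the extension is linear.
Unstranded libraries (`library_type = "unstranded"`) split the
extension symmetrically, which centres the bimodal coverage such
libraries produce. The INPUT library is processed identically to the IP
library.

Internally all coordinates are 1-based closed intervals (the native
convention of the GRanges containers the implementation is built on);
all text outputs are 1-based inclusive.

## Peak calling

Per chromosome, IP fragment coverage is smoothed with a centred moving
average (window `fragment_size / 4` rounded to odd — narrow enough to
preserve sub-peak structure for later deconvolution) and candidate
summits are the positions, or centres of equal-coverage runs, where the
trend turns from increasing to decreasing. The trend is assessed over
flanks of a quarter of the expected peak width (twice the fragment
length), which suppresses single-base jitter without hiding genuine
sub-peaks. Adjacent maxima count as separate peaks only when the valley
between them drops to at most `min_valley_fraction` (default 0.75) of
the lower summit. The minimum-coverage floor (default 20 fragments) is
applied at summit detection, pruning the number of statistical tests.

Each summit's region spans the fragment length to each side; where
regions would overlap, the boundary is the midpoint between the two
summits, so regions are disjoint. Fragment counts in each region (a
fragment counts if any of its blocks overlaps the region — integer
counts are required by the exact test) form a 2x2 table against the
library totals, tested one-sided with Fisher's exact test against the
null that the IP proportion is not higher. Raw, unsmoothed counts are
used for testing; smoothing only guides summit finding. FDR control is
Benjamini-Hochberg by default, with Benjamini-Yekutieli, Bonferroni and
no correction available.

Peak *enrichment* is reported as the summit coverage fold: smoothed IP
coverage over library-scaled smoothed INPUT coverage at the summit,
with a pseudocount of one on both sides. We use the summit fold rather
than a region-averaged ratio because a region twice the fragment length
wide dilutes a genuine site's fold with flanking background — under the
generative model below, a fold-8 site averages only ~2-2.6x over its
region while its summit fold is ~(1-noise)*fold + noise — and the
default twofold filter is meant to retain genuine peaks. INPUT is
scaled to the IP library by the ratio of total filtered fragment
counts. Filters (q <= 0.05, fold >= 2, >= 20 fragments, optional
replicate reproducibility) flag peaks rather than delete them; default
writers emit retained peaks.

## Deconvolution

An enriched region's fragment pile is modelled as a mixture over
candidate sites (the adenosines of the region, optionally restricted to
RRACH-context adenosines) plus a uniform noise component. A fragment of
total length L attributed to site m must cover m, and its start is
taken uniform over the L admissible placements, giving density 1/L;
the noise density is 1/region-length. This uniform-placement kernel is
the minimal model consistent with antibody capture of
site-overlapping fragments; an empirically weighted kernel can be
substituted through the likelihood matrix.

EM alternates responsibilities (E) with weight re-estimation and site
relocation (M). Relocation maximises each component's
responsibility-weighted expected log-likelihood over the candidate
list — a generalized EM step, so the observed-data log-likelihood is
non-decreasing every iteration (asserted in the tests). Initialisation
is a deterministic greedy set-cover: repeatedly pick the candidate
covering the most unassigned fragments; initial weights are
proportional to per-site coverage with a small (0.05) initial noise
weight. Components whose weight collapses below 1e-6 are frozen.
Convergence: change in log-likelihood below 1e-4, at most 200
iterations.

The number of sites is chosen by BIC, `k ln(n) - 2 lnL` with
`k = 2 * n_sites` (each site contributes a position and a free weight;
the noise weight is the simplex remainder), fitting 1..5 sites and
preferring fewer on ties.

## False-positive filter

Training labels come from a methyltransferase-knockdown / control pair:
a control peak with no knockdown peak within 50 nt of its summit is a
true positive (methylation collapses when the writer is depleted); a
matched peak whose relative enrichment change is below 0.5 is a
technical false positive; anything else is left unlabeled.

Each peak is encoded as a 200-nt sequence over {A,C,G,T,M} centred on
the called site (deconvolved site if available, else the
summit-nearest adenosine), with the site marked M and out-of-contig
positions padded N. Two MTD models — one per class — are fitted to
two-thirds of the training sequences. The MTD approximates an order-L
Markov chain in linear parameter space,
`P(x_t | context) = sum_l lambda_l Q[x_{t-l}, x_t]`, with a single
shared transition matrix Q (a per-lag-Q variant is available via
`shared_q = FALSE`). Parameters are maximum-likelihood, fitted by EM
with the contributing lag as the latent variable; initialisation is
deterministic (uniform lambda, Q from pooled bigram counts with 0.5
pseudocounts), so training is reproducible. Default order is L = 5, a
compromise between context length and parameter count. N positions are
excluded from all likelihoods.

The classifier itself is a random forest (1000 trees, six candidate
features per split) over a fixed, versioned feature schema: the MTD
log-likelihood ratio between the class models, signed distance from
the site to the nearest RRACH adenosine (sentinel 999 when absent),
k-mer counts for k = 1..3 over A/C/G/T (k-mers containing M or N are
skipped, so an all-A window has A-count 199), peak enrichment, IP
fragment count, region width, transcript-region class
(5'UTR/CDS/3'UTR/exonic/intronic/unknown) and containing-exon length.
Optional plug-in columns (conservation, miRNA sites) may be appended
by name; predicted RNA secondary structure is deliberately not part of
the schema. A peak's score is the fraction of trees voting TP; the
decision threshold (default 0.5) is the precision/recall bias knob.
Scored-out peaks are flagged `fp_filtered`, never deleted.

## The simulator

`simulate_reference()` puts each transcript on its own contig: 1-3
exons totalling 1.5-3 kb, introns of 200-800 nt, 50-nt genomic flanks,
log-normal expression (sdlog 0.5), and 1-2 sites per transcript planted
>= 250 nt apart and >= 150 nt from transcript ends, each written as a
GGACT so that every truth site is an RRACH adenosine. The central 60%
of each transcript is annotated CDS so UTR classes are derivable.

`simulate_experiment()` draws INPUT fragments uniformly along
transcripts with probability proportional to expression x length, and
IP fragments from a mixture: a `noise_fraction` share (default 0.1)
follows the INPUT model, the rest picks background or a planted site
with weight `(fold - 1) x fragment_length`, placing site fragments
uniformly among the placements covering the site — the same kernel the
deconvolution likelihood assumes, so parameter-recovery tests are
exact and kernel misspecification can be tested separately. This
construction gives an expected IP/INPUT coverage fold at a site of
`(1 - noise) * fold + noise` (7.3 at the default fold 8). Fragment
lengths are normal (mean 100, sd 10 nt); reads are 50 nt paired-end by
default with splice-aware CIGARs, written as SAM and converted to
sorted, indexed BAM. Everything is deterministic under the
configuration seed.

What the simulator does *not* emulate: sequencing errors and base
qualities, GC and positional coverage bias, PCR duplication structure,
overdispersed biological replication, and isoform complexity
(alternative splicing, overlapping genes). Passing tests on this
generator therefore demonstrate correctness of the algorithms under
the stated generative model, not performance on any particular real
data set.

## Verification sizes and numerical choices

The test-suite and the acceptance script size their computations to be
informative yet quick: the end-to-end fixture uses 50 transcripts at
2e5 fragments per library (seed 7); the null (type-I) experiment uses
120 transcripts at 2e5 fragments, giving > 2000 testable 200-nt tiles;
deconvolution resolution uses 200 independent single-site regions (100
fragments of 50 nt, 10% noise) plus 25 two-site replicates; the MTD
recovery uses 1e5 transitions; the classifier benchmark uses two
10-dimensional Gaussian classes, n = 2000, 10-fold cross-validation.

Numerical details worth knowing: the exact test is computed as the
upper hypergeometric tail (`phyper`), cross-checked in the tests
against explicit density summation and `fisher.test`; zero library
totals give p = 1 with a warning; empty candidate lists leave the
summit-only call flagged `no_candidate`; likelihoods are floored at
1e-300 before logging; EM ties in BIC go to the smaller model;
plateau summits report the run centre (integer division); an even
smoothing window is incremented with a warning.

## Limitations

The caller reports summit-anchored regions, not broad domains; the
pairwise comparison reports log2 enrichment changes without a
differential test; deconvolution assumes the uniform placement kernel
and a shared fragment-length scale; the false-positive filter requires
knockdown-derived labels and, like any sequence-trained model, is not
expected to transfer across distant species.
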