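---
title: "Clustering-free motif discovery from expression-space densities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering-free motif discovery from expression-space densities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redens)
```

## The problem and the model

Regulatory elements (REs) are short DNA motifs bound by regulatory
proteins. Given a gene expression matrix (n genes x p conditions) and one
nucleic-acid sequence per gene (upstream promoter or downstream 3'UTR
region), we want motifs whose presence/absence across genes shows
statistical dependency with the genes' positions in expression space.

The classical route clusters the expression data and scores motif
enrichment per cluster. That presumes a natural partition into disjoint
co-expressed gene sets, which many datasets (notably smooth periodic
time courses) do not have: cluster edges land arbitrarily and
motif-enriched regions of expression space overlap each other.

`redens` instead estimates a **motif density around every gene**: the
fraction n_mkg / k of the gene's k expression-space neighbors whose
sequence contains the motif m. Two dependency scores are built from
these densities, mirroring the two classical cluster-based criteria:

* **Hypergeometric (local)** — under the null that m is distributed
  independently of expression, the count of motif-positive genes among a
  k-neighborhood is hypergeometric(n, n_m, k). The score is
  max over genes g of −log P(X ≥ n_mkg). The per-gene quantity is
  deliberately *not* treated as a P value — only as a score, ranked
  against a shuffle null (below) — so the multiplicity of the max is not
  an issue.
* **Mutual information (global)** — I(M; X) is estimated by
  (1/n) Σ_g Σ_M P(M|X_g) log [P(M|X_g) / P(M)], with
  P(M=1|X_g) = n_mkg / k and P(M=1) = n_m / n, 0·log 0 ≡ 0. Each gene
  term is a Kullback–Leibler divergence, so the estimate is ≥ 0 and
  equals 0 iff every local density equals the global rate.

Both discrete (cluster-based) analogues are implemented in
`score_discrete()` as baselines, with `kmeans_partition()` (best of 100
restarts) supplying the partitions.

Logarithms: mutual information is reported in bits (base 2);
hypergeometric scores use the natural log of a log-space tail
(`stats::phyper(log.p = TRUE)`), never the linear tail. Only the ranking
and the empirical FDR consume these numbers, so the base is a reporting
convention; both are configurable and recorded in the run manifest.

## Neighborhoods and the hubness correction

The k-nearest-neighbor digraph Γ (arc g → g' if g' is among the k
nearest others; ties broken by gene input order; a gene is never its own
neighbor) suffers from *hubness* in high dimension: a few genes appear
in a disproportionate number of neighborhoods, skewing the in-degree
distribution and over-weighting hub genes in every density estimate.

The correction is a two-step construction:

1. **Symmetrize** — add the reverse of every arc (Γ*). Every gene now
   lies in ≥ k neighborhoods.
2. **Balanced sampling** — for each gene draw exactly k neighbors from
   its Γ* neighborhood, sequentially without replacement, with
   probability inversely proportional to the candidate's Γ* in-degree
   d(g'), renormalized over the not-yet-chosen candidates (Γ_k).

Design points: d(g') is the *static* Γ* in-degree, never recomputed as
Γ_k grows; "not yet chosen" is per-gene (otherwise later genes could
exhaust their candidates below k); genes are processed in input order
under a single seed, making the graph reproducible. R's
`sample(prob = ...)` implements exactly this sequential renormalized
draw.

On a 500-gene, 100-dimensional Gaussian fixture the balanced graph
roughly halves the in-degree spread (e.g. range [0, 253] → [25, 138] at
k = 50). The package's acceptance check measures the reduction as the
third-moment skewness at k = 20, i.e. k/n ≈ 4%, matching the regime in
which the method is used in practice (k = 200 against a
several-thousand-gene compendium). At k comparable to n/2 the in-degree
ceiling (n − 1) compresses the raw kNN skewness and the skewness
*coefficient* stops being a meaningful hubness summary even though the
spread still shrinks.

## Seeds: exhaustive q-mers and the shuffle FDR

Every non-degenerate q-mer (q = 7 by default; 4^q words, halved to one
canonical representative per reverse-complement pair in double-strand
mode) is scored. Significance is empirical: the gene↔sequence mapping is
shuffled (one shared permutation per round; ten rounds by default), all
q-mers are rescored against the fixed graph, and

FDR(s) = E[#null scores ≥ s] / #observed scores ≥ s,

capped at 1, with no monotonicity smoothing. q-mers with FDR strictly
below the threshold (0.001 by default) become seeds, ranked by score.
Presence is computed once per q-mer from the sequences (a single window
scan marking all contained q-mers per gene); shuffling only permutes the
presence rows.

## Greedy refinement

Each seed is optimized independently, in two phases that both require
*strict* score improvement (guaranteeing termination at a local
maximum):

1. **Generalization** — any single non-degenerate position may be
   replaced by one of the 7 IUPAC symbols strictly containing its base
   (N included: nothing in the procedure's logic excludes full
   degeneracy, and the elongation/length caps bound its triviality). A
   candidate is admissible only if the Pearson correlation between its
   density profile and the *original seed's* profile is ≥ α
   (0.75 default). Anchoring on the seed rather than the previous
   iterate prevents gradual drift toward a motif covering a different
   expression region.
2. **Elongation** — after generalization converges, any of the 15
   symbols may be prepended or appended, up to max_len (9 by default,
   15 at most). No α gate: an elongation can only shrink the word set.

One boundary nuance: appending N cannot change which *internal* windows
match, but a motif ending in N does exclude matches flush against the
sequence end (there is no base left for N to cover). An N-extension can
therefore occasionally be accepted when trimming terminal matches
sharpens the density contrast; this is a legitimate strict improvement
under the acceptance rule, not an artifact of the scorer.

## Redundancy filtering

Optimized motifs are sorted by score (ties by motif string) and accepted
greedily. Two motifs are redundant iff (a) their ungapped IUPAC overlap
— the longest offset alignment in which every aligned symbol pair has a
non-empty intersection, N–N included, both orientations in double-strand
mode — is ≥ 4, and (b) their density-profile Pearson correlation is
≥ γ (0.75 default). Both gates are needed: near-identical consensus
strings can occupy different expression regions and then represent
different factors.

## Outputs

Per motif: occurrence positions with ±10 bp context; a positional
histogram anchored at the codon-proximal sequence end (upstream: the 3'
end; downstream: the 5' end; occurrences are counted by default,
genes-per-bin optionally); an exact two-sided strand-bias sign test
(double the smaller binomial tail, capped at 1); a conditions × 25-bin
expression heatmap whose cells are density z-scores; and the
motif-positive genes ranked by density z-score

z = (n_mk − k n_m/n) / sqrt(k n_m (n−k)(n−n_m) / (n² (n−1))),

the standardized deviation of the neighborhood count from its
hypergeometric expectation. Genes with positive z sit in expression
regions where the motif is over-represented, which flags their
occurrences as more likely functional. Heatmap bins are equal-width per
condition (equal-frequency available); empty cells are NA.

## Database matching

For evaluation, IUPAC motifs convert to PWMs (each symbol → the uniform
distribution over its nucleotide set, rows in A,C,G,T order). The match
score between two PWMs is the maximum over ungapped offsets (≥ 4 aligned
columns, both orientations) of the summed per-column Pearson
correlations; zero-variance columns contribute 0. The null exchanges PWM
columns across the whole database (lengths preserved; within-motif
shuffling available), P = (1 + #{null best ≥ observed}) / (1 + shuffles)
with a +1 pseudo-count so P is never 0. Query sets are evaluated at a
global Benjamini–Hochberg FDR of 15%, and when several queries best-match
the same database motif only the lowest-P query counts — predicting many
variants of one motif earns a single match. MEME minimal format is the
interchange format.

## The synthetic generator

`simulate_expression()` emulates the smooth low-dimensional structure
the method targets: each gene is one sinusoid over p time points with a
gene-specific phase (a noisy circle; its noiseless version is exactly
two-dimensional), or optionally a mixture of Gaussian blobs.
`simulate_sequences()` draws i.i.d. background at a configurable A+T
fraction (0.6 by default; ~0.9 mimics extremely AT-rich intergenic
DNA) and plants at most one occurrence of each specified motif per gene:
genes whose profile lies within a radius of a focal gene's profile (the
radius is the `inside_fraction` distance quantile) receive a uniformly
chosen word of the motif's expansion at a uniform position (random
strand) with probability `p_inside`, others with `p_outside`. Every
plant is recorded; chance background occurrences are allowed and are
what make the shuffle FDR behave realistically at high A+T.

What the generator does *not* emulate: positional preference of real
REs, nucleosome/composition heterogeneity along the sequence,
correlated occurrences of cooperating motifs, and measurement structure
in expression beyond isotropic noise. Passing the recovery tests
therefore shows the pipeline's statistical machinery works under its own
model assumptions, not that it matches any particular genome's yield.

## Problem sizes and numerical choices

The packaged checks run at: 1,000 genes × 24 conditions, 600 bp, 60%
A+T, k = 200 and 10 shuffles for the end-to-end recovery (planted 7-mer
pair {AAGACAA, TAGACAA} = WAGACAA, p_inside 0.7 in a focal region
holding ~20% of genes, p_outside 0.05), plus twenty 1,000-gene null
fixtures for the false-positive rate; unit fixtures use 60–200 genes
with 100–150 bp sequences, where a planted 6-mer still clearly clears
the shuffle null. The whole-q-mer-space scorer aggregates neighborhood
counts in one C++ pass per shuffle round (identical, q-mer by q-mer, to
the plain-R profile scorer, which the tests verify).

Other choices: occurrence offsets are 0-based half-open, converted to
codon-anchored distances only in reports; masked bases (N) in input
sequences match no motif symbol; a motif equal to its own reverse
complement is scanned once per window; degenerate global presence
(n_m ∈ {0, n}) yields MI 0 by continuity and an undefined z-score
(signalled); zero-variance density profiles are excluded from α
candidacy and treated as correlation 0 in the redundancy filter; score
ties anywhere are broken by motif string order so every run is
deterministic given its seed.

## Worked example

```{r example, eval = FALSE}
X <- simulate_expression(n = 200, p = 12, noise_sd = 0.25, seed = 301)
sim <- simulate_sequences(X, length = 150, at_fraction = 0.5,
                          motifs = list(list(motif = "WAGACA",
                                             p_inside = 0.9,
                                             p_outside = 0.02,
                                             inside_fraction = 0.2)),
                          seed = 302)
fit <- discover_motifs(X, sim$records,
                       config = list(q = 6, k = 40, n_shuffles = 5,
                                     max_len = 8),
                       seed = 1)
fit
plot(fit)            # density z-score heatmap of the top motif
write_reports(fit, "reports")
```

## Known limitations

* The per-gene maxima of the hypergeometric score are score-calibrated
  only through the shuffle null; they are not P values.
* The FDR curve is the raw expected/observed ratio; it is not forced
  monotone, so a lower threshold does not always select a subset of a
  higher one at pathological score ties.
* With s shuffle rounds the smallest resolvable non-zero FDR at the top
  observed score is (1/s) / 1, so any threshold below that (e.g. 0.001
  at s = 10) is met exactly when the observed maximum exceeds *every*
  null score. On data with no real dependency the identity mapping is
  exchangeable with the shuffles, so at least one seed slips through
  with probability about 1/(s+1) per dataset (~9% at the default ten
  rounds) — a per-*dataset* false-discovery property to keep in mind
  when interpreting a single-seed result; the *per-q-mer* false rate
  stays far below the nominal threshold. Raising n_shuffles tightens
  this at linear cost.
* Greedy refinement finds local maxima; two seeds of one biological
  motif usually converge to near-identical solutions, which the
  redundancy filter then collapses, but convergence to the globally best
  consensus is not guaranteed.
* Densities ignore occurrence multiplicity (presence is binary), by
  design; motifs acting through occurrence counts are out of reach.
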