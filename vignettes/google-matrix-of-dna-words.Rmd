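---
title: "The Google matrix of DNA word-transition networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Google matrix of DNA word-transition networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(seqrank)
```

## The model

A DNA sequence is a long string over the alphabet \{A, C, G, T\}, possibly
interrupted by undetermined letters (N and other IUPAC codes). Reading the
string left to right in consecutive, non-overlapping blocks of $m$ letters
turns it into a trajectory over the $N = 4^m$ possible words. Each observed
step from word $w_k$ to the next word $w_{k+1}$ adds one count to the
transition matrix element $Q_{w_{k+1}, w_k}$ (columns index the source
word). Undetermined letters break the trajectory: no word and no transition
spans them, and the same rule applies across FASTA record boundaries.

Dividing every nonzero column of $Q$ by its sum gives the column-stochastic
matrix $S$; columns never observed as a source (dangling words) are
replaced by the uniform column $1/N$. With a damping factor
$\alpha \in (0, 1]$ the Google matrix is

$$G_{ji} = \alpha\, S_{ji} + \frac{1 - \alpha}{N},$$

a Perron–Frobenius operator whose leading eigenvalue is 1. Its right
eigenvector at $\lambda = 1$, normalized to total probability 1, is the
PageRank vector $P$: the stationary law of a random walker over words,
which for this construction equals the relative frequency of the words in
the sequence (exactly so on a circularized trajectory, and up to boundary
terms on a linear one). Sorting words by decreasing $P$ gives the rank
index $K$. Building the same object from the direction-reversed counts
$Q^* = Q^\top$ gives $G^*$, whose PageRank is the CheiRank of the sequence;
because only adjacent words are counted, reading direction barely matters
and $S^* \to S$ as the sequence grows (a detailed-balance-like property the
test suite verifies empirically at rate $L^{-1/2}$).

## Why the stride equals the word length

The walk advances by whole words (stride $m$), not by one letter. A
stride-1 walk would allow each word only 4 possible successors, forcing at
most 4 nonzero elements per column; the object studied here is instead an
almost-full matrix in which any word can follow any other, with roughly
$N_s/N^2$ transitions per element for $N_s$ counted transitions. The
tiling phase is fixed at the first letter of each determined segment; no
multi-phase averaging is done, as the single-phase reading is already the
deterministic interpretation of "moving along the string".

## Parameters that matter

* **`m` (word length, letters).** Sets $N = 4^m$. Statistical resolution
  of the matrix elements requires $N_s \gg N^2$, so for a sequence of $L$
  letters a practical ceiling is $m \approx \log_4 \sqrt{L/m}$. Dense
  diagonalization is capped at $N = 4096$ ($m = 6$) by default; `m = 7`
  works for PageRank (power iteration) but the full spectrum then needs an
  explicit override.
* **`alpha` (damping, dimensionless, default 0.85).** The word-transition
  spectrum already has a large gap below $\lambda_1 = 1$, so PageRank is
  insensitive to `alpha` over a broad range; 0.85 is the conventional
  value. All eigenvalues other than 1 scale exactly linearly in `alpha`
  and their eigenvectors do not depend on it — an algebraic identity the
  suite checks to $10^{-10}$.
* **`tol` (PageRank residual, default `1e-12`).** L1 self-consistency
  $\lVert GP - P \rVert_1$; with the observed spectral gaps the power
  iteration reaches it in tens of iterations.
* **Fit ranges.** Power-law exponents are read off integrated
  distributions by least squares in log–log scale, and the algebraic-decay
  window must be chosen by the user (the default is the full
  positive-fraction grid). The integrated curve for elements uses the
  *strict* exceedance count, so the differential exponent is
  $1 - \text{slope}$.

## Distributions and exponents

The integrated fraction of matrix elements above a threshold $g$ decays
algebraically with differential exponent $\mu$, the analogue of the
outgoing-link exponent of web-type networks. Because the matrix is almost
full, the analogue of in-degree is the *sum of ingoing elements*
$\tilde g_j = \sum_i S_{ji}$; its integrated distribution defines the
exponent $\nu$, and the scale-free relation $\beta = 1/(\nu - 1)$ links it
to the decay exponent $\beta$ of $P(K) \sim K^{-\beta}$. These
distributions are computed on the damping-free $S$ by default: every
element of $G$ has the floor $(1-\alpha)/N$, which buries the small-element
tail; a switch to the damped view of $G$ is available.

The planted-Zipf generator (`zipf_planted_matrix()`) makes this circle
testable with known truth: it builds the rank-one transition law whose
columns all equal a vector carrying mass $\propto K^{-\beta_0}$, so the
stationary law is exactly Zipf, the ingoing sums are $N p$, and
$\beta = \beta_0 = 1/(\nu - 1)$ holds identically. The suite recovers
$\beta_0 \in \{0.25, 0.5\}$ within 0.05 and the $\beta$–$\nu$ consistency
within 0.1.

## Spectrum, localization, null model

`full_spectrum()` densely diagonalizes the element view of $G$ (LAPACK via
`eigen()`), sorts eigenpairs by decreasing $|\lambda|$ (ties: decreasing
real part, then increasing imaginary part), and fixes each eigenvector's
phase by rotating its largest-modulus component onto the positive real
axis, so conjugate pairs are reproducible. The spectral gap $1-|\lambda_2|$
and cloud radius $|\lambda_2|$ summarize relaxation; the inverse
participation ratio $\xi = (\sum_i |\psi_i|^2)^2 / \sum_i |\psi_i|^4$
measures how many words support an eigenvector (1 for a delta, $N$ for a
uniform vector). PageRank is delocalized while subleading eigenvectors
concentrate on small word sets, which `top_words()` extracts.

As a null model, `shuffled_value_matrix()` permutes the multiset of all
$N^2$ element values over positions and renormalizes columns: it keeps the
value histogram but destroys the chain structure, collapsing the
eigenvalue cloud — on planted block chains the shuffled $|\lambda_2|$
drops by an order of magnitude.

## Comparing two sequences: the proximity correlator

For two sequences ranked at the same $m$, each word contributes a point
$(K_A, K_B)$; identical statistics put all points on the diagonal. The
average dispersion is

$$D = \frac{1}{N} \sum_w \left(K_A(w) - K_B(w)\right)^2,$$

normalized by the random-placement model in which the $N$ points occupy an
$N \times N$ square with one point per row and column — i.e. two
independent uniform permutations — whose exact expectation is
$D_{\mathrm{rnd}} = (N^2 - 1)/6$ (verified by exhaustive enumeration for
$N \le 6$). The dimensionless correlator $\zeta = D / D_{\mathrm{rnd}}$ is
0 for identical rankings and concentrates near 1 for unrelated ones. $D$
scales as $N^2$ across word lengths, so $\zeta$ is nearly $m$-independent;
the closed-form mean-squared normalization is used (rather than a
root-mean-square variant) because it divides out the random-model
expectation directly, and any monotone variant preserves the induced
ordering of sequence pairs. Reports include both $D$ and $\zeta$ so either
convention can be read off. Proximity tables carry the purine (A/G) and
weak (A/T) content of each word, the compositional covariates that
structure the rank axis.

## What the synthetic generators emulate — and what they do not

The generators produce (a) i.i.d. letter strings at given frequencies,
(b) word-level Markov chains with a known column-stochastic law (the exact
object the estimator targets, so parameter recovery is well defined),
(c) undetermined-letter runs injected at seeded positions, and
(d) structured null models (planted Zipf laws, block chains, value
shuffles). They deliberately do **not** emulate biological genome
structure — isochores, repeat families, coding/non-coding mosaic, strand
asymmetries — so green tests certify the estimator, the spectral and
distributional machinery, and the correlator algebra, not any biological
claim about real genomes. Applying the pipeline to real FASTA input is
supported but its interpretation is the user's.

Generator settings used by the validation suite were fixed once:
letter-level chains with clearly distinct transition structure for
separation/stability checks (the $m$-stability of $\zeta$ is a property of
well-separated statistics, as in cross-species comparison; for two nearly
identical i.i.d. generators $\zeta$ is dominated by sampling noise and has
no stable limit), sequence lengths of $10^5$–$10^6$ letters so that word
frequencies at $m \le 4$ are resolved, and four *distinct* letter
frequencies wherever an ordering is compared against PageRank (exact ties
make the reference ordering itself ill-defined).

## Numerical choices

* Counts are accumulated sparsely; $S$ stores only observed columns plus
  the dangling index set, and `gm_multiply()` applies
  $\alpha S v + (1-\alpha)\,\mathbf{1}\,\langle v\rangle$ without ever
  densifying. The dense element view exists only for diagonalization and
  distribution counting.
* Rank ties (equal $P$) break by ascending state index, making `K`
  deterministic.
* The power iteration renormalizes to unit total probability each step to
  absorb rounding drift; residuals are L1.
* Degenerate inputs: sequences shorter than $m$ tile to nothing; lists of
  length 1 contribute no transition; an input with no transitions is an
  error at build time; all-separator strings segment to an empty list.
* Problem sizes in the shipped validation runs (dense spectra at
  $N \le 4096$, chains of $10^5$–$10^6$ steps, 10–100 seeds per property)
  were chosen to make every check complete comfortably on a single desktop
  CPU core.

## Known limitations

* Dense full-spectrum analysis beyond $m = 6$ is impractical; no Arnoldi
  partial spectra are provided.
* One strand is read as given; reverse-complement canonicalization is out
  of scope.
* The power-law fits are ordinary least squares on the integrated curve;
  no MLE tail estimation, and the oscillations that real sequences show
  around algebraic decay are not smoothed.
* $\zeta$ compares rankings word-for-word at a fixed $m$; it is a pairwise
  correlator, not a distance on which tree building is attempted.
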