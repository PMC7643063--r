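---
title: "Measuring genome sequence complexity and testing its evolutionary trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring genome sequence complexity and testing its evolutionary trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SeqCompTrends)
```

## The question

Does genome *sequence* complexity — structure measurable on the naked DNA
string, independent of annotated function — increase over evolutionary time,
and if it does, is the increase *driven* (a per-lineage bias toward higher
values) or *passive* (diffusion away from a reflecting lower bound)?
SeqCompTrends implements both halves of that programme: alignment-free
complexity metrics computed per genome, and the comparative machinery that
regresses those metrics on a phylogeny and interrogates the trend.

## The metrics

**Sequence Compositional Complexity (SCC).** A genome is first cut into
compositionally homogeneous domains by recursive binary segmentation: for a
(sub)sequence, every admissible cut point is scored by the Jensen-Shannon
divergence

$$D(p) = H(f_{\mathrm{pool}}) - \tfrac{n_1}{n} H(f_{\mathrm{left}}) -
\tfrac{n_2}{n} H(f_{\mathrm{right}}),$$

where $H(f) = -\sum_a f_a \log_2 f_a$ is Shannon entropy in bits. The
maximal-divergence cut is accepted when its significance reaches the level
$s$, and accepted parts are re-scanned in isolation (no merging pass).
Given the resulting $n$ domains,

$$SCC = H(S) - \sum_{i=1}^{n} \frac{G_i}{G} H(S_i),$$

the entropy of the whole sequence minus the length-weighted entropies of its
domains. SCC is zero for a homogeneous sequence and grows with the number,
length and compositional contrast of domains. Besides the 4-letter alphabet,
the same procedure runs on three binary recodings — strong/weak
(`SW`: C,G vs A,T), purine/pyrimidine (`RY`: A,G vs C,T) and the `KM`
split (A,C vs G,T) — which isolate complementary compositional channels
(the labels K and M here follow the usage of the segmentation literature
for the {A,C}/{G,T} split rather than the IUPAC codes).

**Significance of a split.** The classical result that $2 N \ln 2 \cdot D$
is asymptotically $\chi^2_{|A|-1}$ holds for one fixed cut; the segmentation
statistic is the *maximum* over all cuts. We model the null of the maximal
statistic as $F_{\chi^2}(x)^{N_{\mathrm{eff}}}$ with an effective number of
independent cut points $N_{\mathrm{eff}}(N, \mathrm{df})$ calibrated by
seeded Monte-Carlo on i.i.d. sequences (500 replicates per grid point, grid
of lengths 50–50,000, frozen in `inst/extdata/jsd_null_neff.tsv`,
log-linear interpolation and extrapolation in $N$). The calibration is
verified behaviourally: at $s = 0.95$, i.i.d. genomes of 10 kb come out as
a single domain in ≥ 90% of replicates.

**Biobit (BB).** With $L = \log_4 G$, the genome's word entropy
$E_{2L}$ at word length $k = \mathrm{round}(2L)$ lies between $L$
(maximally repetitive) and $2L$ (random). The anti-entropic component
$A = \max(0, 2L - E_{2L})$ (clamped to $[0, L]$) and entropic component
$E = L - A$ satisfy $A + E = L$, and
$BB = \sqrt{L}\sqrt{A/L}\,(1 - 2A/L)^3$. Two conventions had to be pinned
here because the reference implementation is external: the word length
$2L$ is non-integer for most $G$ and is rounded to the nearest integer
(reported in the output), and the printed definition
$E = E_{2L} - 2L$ contradicts $A + E = L$, so $E = L - A$ is used, which
satisfies the printed constraint.

**Genomic Signature (GS).** For each word length $k$ the observed k-mer
counts $P_i$ are compared with the flat chaos-game expectation
$EV = (G-k+1)/4^k$, and $GS = \max_k \sum_i |P_i/EV - 1|$. Words are
counted on the given strand only. Because every absent word contributes 1,
the deviation sum degenerates once $4^k \gg G$; the k range is therefore an
explicit, reported parameter with default 1–8.

## The comparative machinery

All comparative steps work on a rooted tree with branch lengths, used *as
given* (no ultrametricisation): the regression axis is root-to-node path
length, exactly as when branch lengths are amino-acid substitutions.

* **Phylogenetic signal** is Blomberg's $K$ from the GLS formulation
  (observed $MSE_0/MSE$ over its Brownian expectation); $K = 1$ is the
  Brownian reference. Significance permutes trait values across tips and
  ranks the observed phylogenetic MSE, with the $(x+1)/(n+1)$ estimator so
  a p-value of 0 is never reported (999 permutations by default, matching
  the conventional $P = 0.001$ floor).
* **Phylogenetic correlation** is the GLS-centred cross-covariance under
  the Brownian covariance $C$, with a $t_{n-2}$ test and Benjamini-Hochberg
  correction across all pairs; on a star tree it reduces to the ordinary
  Pearson correlation, which the tests assert.
* **Ancestral states** under `ml_bm` are the maximum-likelihood (GLS
  conditional expectation) values; the root estimate is the GLS mean. The
  whole reconstruction is one fixed linear operator per tree, which is what
  makes the trend test's simulated null cheap. The `ridge` option fits one
  evolutionary rate per branch with an L2 penalty (lambda by
  leave-one-tip-out cross-validation) and accumulates rates along
  root-to-node paths; it follows the published description of phylogenetic
  ridge regression without claiming numerical identity to any specific
  implementation of it.
* **The trend test** regresses all tip + node values on root distance and
  calibrates the slope against `nSim` no-trend Brownian simulations
  re-analysed identically, with the Brownian rate estimated from the
  observed tips by GLS (default 10,000 simulations; the test suite uses 500
  where only calibration is at stake). Because reconstruction and
  regression are linear, each null slope is a linear functional of a
  multivariate-normal draw and the whole null is one matrix product.
  Note that the reconstruction step shrinks: even a trait that is exactly
  linear in depth at the tips does not reconstruct to depth-linear internal
  values, so the all-node slope is attenuated relative to the generative
  slope; the null calibration makes the test valid regardless.

## Driven versus passive

* **Minimum test.** (1) D'Agostino skewness of tip values (positive skew
  supports a lower wall); (2) chi-square on the counts of non-root,
  non-basal nodes above vs below the basal value $x_b$ (ties excluded,
  which is why totals can differ between metrics); (3) pooled-variance
  Student's t on $|x_d - x_b|$ between the two groups (Welch behind a
  flag). $x_b$ is the reconstructed value at the root child on the
  user-designated basal lineage (default: the smaller root subtree). A
  caveat the test suite documents explicitly: under Brownian evolution the
  above/below counts are unbiased but far more variable than binomial —
  whole clades cross $x_b$ together — so the chi-square proof is evidence
  about the observed configuration, not a calibrated test of the Brownian
  null.
* **Ancestor-descendant test.** Counts increases vs decreases over
  parent-child edges, restricted (following McShea) to edges with both
  endpoints above the mean tip value to avoid wall-proximity bias; exact
  two-sided binomial sign test by default. A measured property worth
  knowing: with *no* wall, the above-mean restriction itself inflates
  rejections (~15% at nominal 5% in our simulations) because conditioning
  the child above the threshold truncates the symmetric increment from the
  left. The unrestricted test is calibrated, and the package therefore
  treats the unrestricted variant (`threshold = -Inf`) as the null
  reference when there is no wall in play; with a reflecting wall the
  restricted test stays within 15%. A `fisher` option builds the observed
  (up, down) split against a balanced one — a non-canonical 2x2
  construction, provided for comparison and labelled as such.
* **Sub-clade test.** Re-runs the trend test inside designated monophyletic
  sub-clades; Mood's median test compares sub-clade tips against the whole
  clade; the skewness proof is applied only when the sub-clade median
  significantly exceeds the whole-clade median (the right-tail
  applicability rule — under plain Brownian motion the rule blocks the
  proof in most replicates).
* The `+/-/0` summary grid is a deterministic recoding of the component
  p-values at $\alpha = 0.05$.

## What the generators emulate — and what they do not

`makeDomainGenome` concatenates i.i.d. draws from per-domain base
compositions and returns the analytic truth alongside (breakpoints and the
mixture-entropy SCC bound $H(\sum w_i f_i) - \sum w_i H(f_i)$).
`makeIidGenome` is the homogeneous control. Real genomes are not piecewise
i.i.d.: long-range correlations, repeats and coding structure are absent,
so passing recovery tests demonstrates correctness of the segmentation
machinery, not that the significance model is exact on real DNA (the
long-range-correlation-aware segmentation variant is out of scope).
Trait regimes: `simulateBM` (null and drifted) and `simulateBoundedBM`
(reflection at a lower wall, per-branch discretisation into 20 steps —
reflection rather than absorption, the standard passive-trend model).
Ground-truth internal node values are retained so the driven/passive tests
can be validated with and without reconstruction error.

Study-scale choices made once and used throughout the tests: domain-genome
recovery uses 10 kb domains with a GC gap of 0.3 at $s = 0.95$ (at that
size the finite-sample bias of recovered SCC, about 2%, sits well below
the 5% accuracy target; the batch-mean SCC over ten seeded replicates is
the estimator held to that target, because a 5% per-test significance
level legitimately yields an occasional extra domain in single
replicates). Signal calibration uses a 64-tip Yule tree and 200 Brownian
replicates. Trend calibration and power use a 64-tip *non-ultrametric*
tree: on an ultrametric tree every tip is equidistant from the root, so a
depth-linear trait is constant at the tips and drift is unidentifiable —
the realistic regime is a substitutions tree with varying root-to-tip
distances. "Strong drift" in the power experiments is
$\mu = 3\sqrt{\sigma^2/T}$, i.e. a displacement of three Brownian standard
deviations over tree height $T$.

## Numerical choices

* Coordinates are 0-based half-open everywhere except BED output.
* All logarithms are base 2; SCC, BB components and entropies are in bits.
* Ties in the maximal-JSD scan break leftmost, for determinism.
* Entropy of 4-letter frequency vectors is accumulated as
  $(t_A + t_T) + (t_C + t_G)$, and the domain-entropy sum of SCC is summed
  in sorted order: both make SCC *bit-for-bit* invariant under reverse
  complement, not merely invariant up to rounding.
* GLS inverses go through Cholesky with a single 1e-10 jitter retry;
  permutation/simulation p-values always use $(x+1)/(n+1)$.
* Every stochastic operation takes an explicit seed; the pipeline derives
  stage seeds deterministically from one master seed, and two runs with the
  same configuration produce byte-identical JSON.

## Limitations

* The segmentation significance model is calibrated on i.i.d. nulls;
  long-range correlated sequences will be over-segmented at a given $s$.
* The value of $s$ materially changes SCC; it is a mandatory reported
  parameter, not a nuisance constant (0.95 by default, the conventional
  choice in the segmentation literature).
* The ridge ancestral-state variant is a faithful implementation of the
  published description, not a numerical clone of existing ridge-regression
  software; the trend test's simulated null makes it valid either way.
* The minimum test's chi-square proof is not calibrated against the
  phylogenetic null (see above); interpret it as descriptive.
* Reproducing published full-phylum tables requires the original genome
  set and tree; the package validates the machinery on synthetic data and
  accepts any precomputed profile + tree as input.
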