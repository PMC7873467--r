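---
title: "Inferring competing endogenous RNA networks from paired expression profiles"
author: "ceRNAnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring competing endogenous RNA networks from paired expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAnet)
```

## The scientific problem

Long non-coding RNAs (lncRNAs) can regulate messenger RNAs indirectly by
competing for a shared pool of microRNAs: when a lncRNA sponges a miRNA, the
miRNA's mRNA targets are released from repression.  A lncRNA-mRNA pair
connected through many shared miRNAs is a candidate *competing endogenous
RNA* (ceRNA) pair.  Given paired case/control expression profiles of mRNAs,
lncRNAs and miRNAs — the motivating design is eight patients with ovarian
endometriosis, each contributing one ectopic (EC, lesion) and one eutopic
(EU, intrauterine) endometrial sample — and a database of miRNA-target
interactions, the package builds the disease-associated ceRNA network and
prioritises lncRNAs in it by two complementary routes: network topology
(hubs) and proximity to known disease genes (network propagation).

The pipeline has five stages, each usable on its own:

1. **Paired differential expression** with empirical-Bayes variance
   moderation (`pairedModeratedTest`).
2. **Hypergeometric ceRNA pair selection** restricted to differentially
   expressed RNAs (`buildCernaNetwork`).
3. **Topological hub nomination** by degree, betweenness and closeness
   (`centralities`, `hubIntersection`).
4. **Random walk with restart** from disease seed genes, with a
   seed-shuffling permutation null (`rwrPermutationTest`).
5. **Correlation-gated over-representation analysis** of a hub lncRNA's
   positively co-expressed targets (`pearsonSelect`, `ora`).

## Differential expression: the moderated paired test

The contrast of interest is within-patient (EC versus EU), so the test
operates on per-patient differences \(d_{gi} = x^{EC}_{gi} - x^{EU}_{gi}\)
of log2 expression — a one-sample moderated t-test on the differences is
algebraically the paired blocking the design demands, and removes any
additive patient effect.  With \(n\) patients, \(d = n - 1\) residual
degrees of freedom and per-feature sample variance \(s_g^2\), empirical
Bayes shrinks each variance toward a common prior
\(s_0^2\) with prior degrees of freedom \(d_0\):

\[ \tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}, \qquad
   \tilde t_g = \frac{\bar d_g}{\tilde s_g / \sqrt n}, \]

with \(\tilde t_g\) referred to a t distribution on \(d_0 + d\) degrees of
freedom.  The hyperparameters are estimated by closed-form moments matching
on \(\log s_g^2\), using the exact mean and variance of the log chi-square
distribution: the excess of \(\mathrm{var}(\log s_g^2)\) over
\(\psi'(d/2)\) determines \(d_0\) through the inverse trigamma function,
and the location determines \(s_0^2\).  This is the standard hierarchical
model for expression variances; the package deliberately does not chase
numerical identity with any particular implementation of it — the contract
is the invariant suite (agreement with the ordinary paired t-test as
\(d_0 \to 0\), monotone shrinkage toward the pooled value as \(d_0\) grows,
calibrated null behaviour), and a cross-check against limma's empirical
Bayes moderation in the test suite shows near-perfect rank agreement.

A feature is called significant when its Benjamini-Hochberg adjusted
p-value is below `alpha` (default 0.05) **and** its absolute log2 fold
change exceeds 1 (fold change > 2; the strict reading of the gate, so a
fold change of exactly 2 does not pass).  If the paired differences carry
no variance at all (e.g. EC identical to EU), the test is undefined: the
function warns and returns `NA` p-values, and nothing is called
significant.

The input is declared to be already-normalised log2 expression; the package
performs no normalisation.  Count-model testing and
normalisation from raw counts are out of scope by design.

## The hypergeometric shared-miRNA test

Interaction edges are first restricted to differentially expressed miRNAs
and differentially expressed targets (both filters can be relaxed by
argument).  For a candidate pair whose mRNA has \(t\) miRNA partners, whose
lncRNA has \(N\) partners, and which shares \(r\) partners within a
universe of \(T\) miRNAs, the evidence is the upper tail

\[ P(X \ge r), \qquad X \sim \mathrm{Hypergeometric}(T, t, N), \]

equivalently \(1 - \sum_{k=0}^{r-1}\binom{t}{k}\binom{T-t}{N-k} /
\binom{T}{N}\).  The implementation sums the upper tail directly in log
space (no subtraction from one, hence no cancellation), shifting each
instance by its distribution mode so that large universes neither overflow
nor underflow; an exhaustive sweep of every valid instance with
\(T \le 60\) agrees with direct enumeration to better than \(10^{-12}\)
relative error.  Pairs with \(p <\) `alpha` (default 0.01, raw — the
conventional per-pair gate; Benjamini-Hochberg across pairs is available
via `adjust = TRUE`) form the undirected bipartite ceRNA network, each edge
retaining its \((T, t, N, r)\) evidence and shared miRNA identities so the
triple lncRNA-miRNA-mRNA sub-network of any lncRNA can be reconstructed
(`extractSubnetwork`).

**The universe size \(T\) matters: it changes every p-value.**  Three
definitions are supported.  The default, `interaction-union`, counts the
miRNAs present in either filtered interaction table, which keeps \(T, t, N,
r\) internally consistent — the same filtered universe generates all four
counts.  `de-only` uses all differentially expressed miRNAs;
`all-annotated` accepts an externally supplied count (e.g. the number of
annotated human miRNAs).  Published analyses are frequently ambiguous on
this point, which is why the choice is explicit and recorded on the network
object.

Positive co-expression is *not* required at this stage; correlation gating
enters only in functional annotation (below), mirroring common practice.

## Topology: hubs as the triple top-ten intersection

Degree, betweenness (Brandes accumulation over all shortest paths,
equal-length paths split evenly, normalised by \((n-1)(n-2)/2\)) and
closeness are computed on the network treated as undirected and unweighted
— ceRNA competition is symmetric and the model assigns no weights.  A node
is nominated as a hub when it appears in the top-\(k\) list (default
\(k = 10\)) of **all three** metrics; ranking uses a deterministic
lexicographic tie-break so results are reproducible under relabeling.

Closeness uses the Wasserman-Faust component-scaled form
\(\frac{r}{n-1}\cdot\frac{r}{\sum d}\), where \(r\) is the number of other
nodes reachable from the node.  On a connected graph this is ordinary
normalised closeness; on a disconnected graph the first factor downweights
small components.  The alternative — per-component closeness without the
size factor — awards an isolated two-node component a perfect score of 1.0,
and on sparse networks such satellites then flood the closeness top-ten and
eject genuine hubs from the intersection, which is why the scaled form is
the default.

`degreeDistribution` tabulates the per-class degree histogram and, when at
least five distinct degrees exist, fits log frequency against log degree by
least squares.  The slope and \(R^2\) are a quick shape check for
heavy-tailed ("power-law-like") wiring, not a rigorous power-law inference,
which is explicitly out of scope.

## Random walk with restart and the permutation null

The walk runs on the bipartite lncRNA-mRNA network exactly as built (miRNA
nodes are not part of the walk) and iterates

\[ P_{t+1} = (1 - r)\, W P_t + r P_0 \]

from \(P_t = P_0\), where \(W\) is the column-normalised adjacency matrix,
\(P_0\) places \(1/n\) on each of the \(n\) seed genes, and \(r\) is the
restart probability (default 0.5 — note this \(r\) is distinct from the
shared-miRNA count above).  Iteration stops when the L1 difference between
successive vectors falls below `tol` (default \(10^{-10}\); the norm is a
package choice, as "difference" alone does not fix one).  Isolated nodes
are pruned before the walk; were a dangling (all-zero) column ever present,
the mass a walker would lose there is returned through the restart term so
that \(\|P_t\|_1 = 1\) holds at every step.  On every random graph tried,
the iterative fixed point matches the direct linear solve
\(P_\infty = r\,(I - (1-r)W)^{-1} P_0\) to \(10^{-8}\) in max norm.

Significance comes from seed shuffling: each permutation draws \(|seeds|\)
mRNA nodes uniformly without replacement from the network's mRNA nodes
(only mRNAs can play the role of disease-gene seeds in this bipartite
network), reruns the walk, and records every lncRNA's score.  The
empirical p-value is \(M/N\), where \(M\) counts permutations whose score
*strictly* exceeds the real one and \(N\) is the number of permutations.
\(M/N\) can be exactly zero; that follows the conventional definition, and
a \((M+1)/(N+1)\) pseudocount mode is available for users who prefer
p-values bounded away from zero.  Uniform draws slightly favour low-degree
seed sets; a degree-matched draw is available via `degreeMatched = TRUE`.

## Functional annotation

For a focal lncRNA, `pearsonSelect` computes the Pearson correlation with
each competing mRNA over all 16 samples (both conditions pooled — ceRNA
co-expression is a dataset-level claim; an EC-only or EU-only analysis is
available via `conditions`), with the two-sided p from the usual
t-transform.  Targets with \(p < 0.05\) and PCC \(> 0\) are retained;
the selection p-values are deliberately not multiplicity-adjusted, as this
is a screening gate rather than an inferential endpoint.  The retained
targets feed `ora`, an offline over-representation test against
user-supplied GMT gene-set collections: per set, the same hypergeometric
upper tail as the pair test (one implementation, asserted identical in the
tests), Benjamini-Hochberg adjusted across sets.  Web-service annotation
tools cannot be a tested dependency, so reproducing any particular
database's term lists is out of scope.

## The synthetic-data generator

`generateDataset` emulates the paired study design so that every stage is
testable without external downloads, with planted ground truth recorded in
a machine-readable manifest:

* **Design**: 8 patients by default, one EC and one EU sample each, three
  RNA classes profiled on the same samples (300 mRNAs, 60 lncRNAs, 150
  miRNAs by default — desk-scale stand-ins for genome-wide profiles).
* **Expression**: per-feature baseline drawn uniformly on \([4, 12]\) log2
  units (the differential-expression stage operates on log-scale values, so
  the generator emits them directly); per-feature noise SD drawn from a
  scaled inverse chi-square centred on `noiseSd` (default 0.3, prior df 8),
  so feature variances genuinely differ and variance moderation is
  exercised rather than trivialised; a per-feature patient effect
  (SD 0.5) shared between a patient's two samples, which the paired
  differencing must remove.
* **Planted signal**: a fraction `fracDe` (default 0.25, in the range of
  published differential-expression yields) of each class receives an EC
  shift of `log2fcPlanted` (default 2.0) with random sign, exercising both
  Up and Down calls.
* **Interactions**: random background bipartite edges (3 mRNA and 1 lncRNA
  edge per miRNA) plus, for each of 40 planted ceRNA pairs, 5 shared
  miRNAs drawn from the planted-DE miRNA pool and wired to both members —
  far above the background sharing expectation.  One hub lncRNA
  participates in 12 pairs (non-hub lncRNAs are capped far below that, so
  the hub's ceRNA degree dominates by construction); one disease-proximal
  lncRNA is wired through a dedicated miRNA set to mRNAs that include the
  4 designated seed genes, giving the 2-hop lncRNA-miRNA-seed connectivity
  that restart-walk propagation rewards through the resulting competing
  edges.

Counts that describe planted structure may be zero (a null dataset has no
planted pairs, hubs or seeds); configurations whose planted structure
cannot fit the differential-expression budget — more pairs than available
DE features, more shared miRNAs than DE miRNAs — fail early with a sizing
error rather than generating an inconsistent dataset.

What the generator does **not** emulate: read-level sequencing noise,
count-distribution (negative binomial) behaviour, library-size artifacts,
correlated co-expression modules, or identifier-mapping noise between
expression and interaction resources.  Passing tests on synthetic data
therefore demonstrate that the inference chain recovers the structure it
models, not that real GEO/StarBase analyses are reproduced bit for bit.

## Numerical and design choices

* **Hypergeometric tail**: direct upper-tail summation in log space with a
  mode shift; domain violations (\(r > \min(t, N)\), \(t\) or \(N > T\))
  are errors, \(r = 0\) returns exactly 1.
* **Moderation degeneracies**: fewer than two positive variances, or log
  variance dispersion below the theoretical sampling floor, give
  \(d_0 = \infty\) (pure pooling); the inverse trigamma is solved by
  bisection-safe root finding on the log scale.
* **Ties**: all rankings break ties lexicographically on node ID; BH uses
  the standard step-up cumulative minimum.
* **Convergence**: L1 residual, monotone after the first step on these
  column-stochastic systems (property-tested).
* **Determinism**: generator and permutation test save and restore the
  caller's RNG state and are byte-reproducible for fixed seeds; the
  pipeline report carries a config fingerprint.
* **Identifiers** are plain strings; no symbol/Ensembl mapping is
  attempted, because silently guessing a mapping is worse than requiring
  the caller to provide consistent IDs.

## Problem sizes used in the shipped checks

The shipped test-and-acceptance material runs at desk scale, chosen so the
full suite completes in minutes on one CPU while every statistical claim
retains power: the default synthetic study (8 patients, 510 features, 40
planted pairs) for end-to-end recovery; 1,000 seed permutations (a
scaled-down stand-in for the 10,000 used in production-size analyses);
exhaustive hypergeometric verification to \(T \le 60\) plus randomised
spot checks at larger \(T\); 100-200 random graphs of up to 30 nodes for
the centrality and propagation oracles; and 50 null replicates of 400
features for false-positive-rate calibration.

## Known limitations

* The ceRNA test uses shared-partner counts only; it ignores binding-site
  multiplicity, expression magnitude and miRNA efficacy.
* Raw (unadjusted) per-pair p-values at 0.01 follow field convention but
  do not control FDR over the tens of thousands of candidate pairs a
  genome-wide analysis enumerates; the `adjust` flag exists for stricter
  use.
* The permutation null shuffles seed labels only; it conditions on the
  network, so topology misspecification propagates into the p-values.
* Power-law "fit" is a descriptive regression, not model selection.
* Headline counts from genome-wide analyses (thousands of DE RNAs, tens of
  thousands of pairs) depend on the specific expression matrices and
  interaction-database versions used and are not reproducible from
  synthetic data; the package's claims are therefore properties and
  worked examples, not dataset-level counts.
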