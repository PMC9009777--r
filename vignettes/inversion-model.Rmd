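---
title: "A quartet model and scan for inter-paralog amino-acid inversions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quartet model and scan for inter-paralog amino-acid inversions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invphy)
```

## The biological question

After a gene duplication, the two paralogous copies of a protein evolve side
by side in every descendant species.  At most alignment columns the copies
either stay identical or drift apart in familiar ways (one copy conserved and
the other variable, or each copy fixed on its own residue).  This package
looks for a much rarer pattern: columns where, in a subgroup of species, the
two copies have *swapped* their residues relative to the remaining species —
an **inter-paralog inversion**.  If group-1 sequences carry F in copy *a* and
H in copy *b*, while group-2 sequences carry H in copy *a* and F in copy *b*,
the most parsimonious explanations require either independent convergent
substitutions or an exchange of states between paralogs, and such columns are
candidates for sites where the copies have exchanged a functional role.

The mirrored pattern — both copies F in group 1, both copies H in group 2 —
is also scored, as **species-specific adaptation**: a residue change that
tracks the species split rather than the duplication.

## The quartet model

The model collapses the phylogeny to four leaves: copy *a* and copy *b* of a
group-1 lineage (`Xa`, `Xb`) and of a group-2 lineage (`Ya`, `Yb`).  The root
is the duplication; branches `b1`, `b2` of length `t1` lead to the two
pre-speciation ancestors, and branches `b3`–`b6` of length `t2` lead from
those ancestors to the four leaves.  Branch lengths are expected
substitutions per site.

Assumptions, stated explicitly:

* Each branch carries **at most one substitution**, with probability
  $1 - e^{-t}$ (the probability of at least one event under a Poisson
  process; multiple hits on one branch are collapsed into one).
* A substitution moves to each of the other $A - 1$ residues with equal
  probability ($A = 20$ by default).  This "uniform jump" ignores exchange
  preferences between amino acids; it is deliberately the simplest chemistry
  that still gives back-substitution and convergence their correct orders of
  magnitude.
* Sites evolve independently.

Every assignment of substitution / no-substitution to the six branches gives
one of $2^6 = 64$ configurations.  For each configuration, the probability
that a pair of leaves shows the same residue depends only on the number of
substitutions on each leaf's private path below the pair's common ancestor;
with at most one event per branch these counts are 0, 1 or 2, and the match
probabilities are exact under the uniform jump chain (for $A = 20$: one
substitution against none can never match; one against one matches with
probability $1/19$; two against one with $18/361$).

```{r match}
match_probability(1, 1)
match_probability(2, 1)
```

From the six pairwise match probabilities of a configuration, the model
assigns conditional probabilities to seven categories — conserved, type 1
divergence (one copy conserved, the other changed), type 2 divergence (both
copies internally conserved but different from each other), recent divergence,
**inter-paralog inversion**, **species-specific adaptation**, and a residual
non-conserved class — and sums them over the 64 configurations:

```{r categories}
round(category_probabilities(t1 = 0.3, t2 = 0.1), 5)
```

Inversions and adaptations are mirror images of each other: swapping the roles
of `Xb` and `Yb` exchanges the two formulas, and because the two
post-speciation branches are exchangeable the two categories have identical
marginal probabilities everywhere.

The central quantitative fact, and the package's headline number, is that the
inversion probability is *small everywhere*: over a $50 \times 50$ grid of
$(t_1, t_2) \in (0.02, 5]^2$ its maximum is about $0.65\%$ of columns
(`scripts/acceptance.R` recomputes this).  Observed counts of inversion-like
columns well above that ceiling would therefore not be explainable by this
neutral substitution geometry.

```{r heatmap}
hm <- category_heatmap(seq(0.1, 3, length.out = 8), seq(0.1, 3, length.out = 8))
max(hm$inversion)
```

## Scoring real alignments

Sequences are partitioned into four **cells** (species group 1 / 2 × paralog
*a* / *b*).  For each alignment column, each cell yields a length-20 residue
frequency array.  Raw frequencies are smoothed with pseudo-counts,

$$ f' = \frac{n f + \beta g}{n + \beta}, $$

where $n$ is the number of residues observed in the cell, $\beta = 5$ by
default, and the background $g$ is the stationary distribution of the LG
model.  Smoothing keeps small cells from producing degenerate 0/1 arrays;
as $n$ grows, $f'$ converges back to $f$.

The match probability of two cells is the dot product of their arrays.  The
**inversion score** is the joint probability that the cross-group,
cross-copy pairs match while the drawn residues do not all coincide:

$$ \sum_i X_a[i]\, Y_b[i] \left( M(Y_a, X_b) - Y_a[i]\, X_b[i] \right)
   = M(X_a, Y_b)\, M(Y_a, X_b) - \sum_i X_a[i] Y_b[i] Y_a[i] X_b[i]. $$

This closed form is algebraically identical to the two-step version
(condition on the cross matches, then multiply by their probabilities) but
needs no division and is therefore defined even when a cross match is zero.
It lies in $[0, 1]$, equals 1 exactly for a pure two-residue inversion
pattern and 0 for a conserved column.  The adaptation score is the same
expression with `Xb` and `Yb` exchanged.

Columns whose gap fraction (over the grouped sequences) reaches 0.60 are not
scored; columns with an entirely empty cell are skipped and reported.

## Calibration by simulated evolution

Scores have no analytic null distribution under realistic substitution
processes, so the threshold is empirical: `empirical_null()` simulates a
neutral alignment along the *actual* tree under JTT or LG — rate matrix
$Q_{ij} = S_{ij} \pi_j$ scaled to one expected substitution per site per unit
branch length, with discrete-gamma rate heterogeneity (four categories,
mean-1 multipliers) — scores it identically to the data, and takes a
percentile of the null scores (default the 99th, linear-interpolation
quantile, R type 7).  Sites strictly above the threshold are selected.

```{r fit}
ds <- synth_dataset(synth_config(n_sites = 500, n_planted_inversions = 5, seed = 2))
fit <- invphy(ds$msa, ds$tree, ds$groups, null_sites = 2000, seed = 1)
fit
sort(selected_sites(fit)$column)
sort(ds$truth$column)
```

## The synthetic generator

`synth_config()` / `synth_dataset()` build fully specified test beds: a
mirrored duplication tree (two paralog clades hanging off the root at stem
length `t1`, each containing the same species topology with every leaf `t2`
below the species-group split; crowns are coalescent-shaped), a neutral
alignment simulated along it, and planted inversion / adaptation columns
using a fixed residue pair (default F/H) with per-leaf noise (default 5%).
Defaults: 8 + 8 species, `t1 = 0.3`, `t2 = 0.1`, 2000 columns, 10 planted
inversions.  Everything is reproducible from the single seed.

The generator is intentionally idealised — its species tree is perfectly
mirrored across copies and its planted columns are two-residue patterns — so
it validates detection power and calibration, not robustness to annotation
error.

## Numerical conventions

* `t1` is estimated from a tree as the mean path length from the duplication
  node to the two paralog-clade ancestors; `t2` as the mean ancestor-to-leaf
  path length within each clade.
* Percentiles use `stats::quantile(type = 7)`; selection is *strictly above*
  the threshold.
* BLOSUM80 alignment distances (for the tree-comparison experiment) score
  each mutually ungapped column, min-max normalise the summed score between
  the matrix minimum and the smaller self-score, and take one minus the
  result; per-column components are additive, so bootstrap column subsets
  reuse them.
* The bipartition-matching tree similarity scores every internal edge of the
  first tree by its best Jaccard-style agreement (over both side pairings)
  with any edge of the second tree; the default is the one-sided sum, so a
  tree's self-similarity equals its internal edge count.
* Typical problem sizes: scanning 2000 columns of 32 sequences takes well
  under a second; a 5000-column null simulation on the same tree about one
  second; a 500-replicate bootstrap experiment under a minute.

## Limitations

* The quartet model's one-substitution-per-branch and uniform-jump
  assumptions make it a geometry of coincidence, not a full likelihood; it
  bounds how often inversion-like columns arise neutrally but does not test a
  specific alternative.
* Detection quality depends on the four-way grouping.  Automatic grouping
  (`auto_groupings()`) only proposes species clades that are monophyletic and
  mirrored in both copies.
* Pseudo-count smoothing biases scores of very small cells toward the
  background; with one sequence per cell, scores are informative only
  relatively.
* The simulated null inherits the tree and model it is given; misspecified
  branch lengths shift the threshold.
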