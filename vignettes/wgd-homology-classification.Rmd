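---
title: "Classifying gene homology after whole-genome duplication"
author: "wgdortho"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying gene homology after whole-genome duplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdortho)
```

## The problem

An ancient whole-genome duplication (WGD) leaves a genome with two copies of
every locus.  In well-studied descendant lineages these copies sort into two
reciprocally monophyletic "a" and "b" clades, and a newly sequenced gene from
a related lineage is usually assumed to be a 1:1 ortholog of one of them.
That assumption hides a biological subtlety: immediately after polyploidy the
duplicated loci still recombine with each other (tetrasomic inheritance), and
only when *diploidization* concludes do the two copies become independently
evolving paralogs.  If diploidization concluded in the common ancestor of the
query lineage and the duplicated reference clades, the query gene really is a
1:1 ortholog of "a" or "b".  If instead the query lineage separated while the
locus was still homogenising, and diploidization then concluded
*independently* in each lineage, the query's copies coalesce with each other
and fall *outside* the combined ("a","b") clade: the duplicates are related
2:2 ("tetralogy") and no 1:1 orthology statement is possible.  An
independent, lineage-specific second WGD produces exactly the same per-gene
topology, so the two histories cannot be distinguished gene by gene — but a
*cluster* of physically linked genes whose individual affinities interleave
between "a", "b" and outgroup placements, together with conflicting
("trifurcating") support among sites, is the signature of a shared WGD with
independent diploidization.

`wgdortho` implements this inference as a reusable pipeline: constrained
topology hypotheses, per-site likelihoods, the approximately unbiased (AU)
test, a three-axis site-likelihood-ratio decomposition, per-gene verdicts and
cluster-level tetralogy calls — together with a simulator that generates the
competing histories with exact ground truth, so every stage can be verified
at desk scale.

## Constrained hypotheses

The species relationships *within* the "a" clade, the "b" clade and the
pre-WGD outgroups are treated as known (a fixed backbone, supplied as newick,
with roles assigned by a two-column clade map).  Three hypotheses are
evaluated for a query gene:

* **A** — the query attaches on an edge inside, or on the stem of, the "a"
  subtree;
* **B** — likewise for "b";
* **O** — the query attaches strictly outside the smallest clade containing
  both duplicate clades (the stem of that clade is admissible: the query
  becomes sister to the whole duplication clade).

Rather than a heuristic constrained tree search, the package *enumerates*
every admissible attachment edge (for a clean binary clade of $k$ leaves
there are $2k-1$), re-optimises branch lengths for each candidate, and keeps
the maximum-likelihood placement per hypothesis.  This is deterministic,
exhaustive within the constraint, and exactly matches the constrained
setting: the only free quantity is where the query goes.  Designated
"unconstrained" taxa (lineages of genuinely uncertain affinity, e.g.
elopomorph-like lineages that also post-date the WGD) stay at their fixed
backbone positions and never restrict the query.  Two query copies can be
attached jointly as a cherry (default) or independently; both modes are
provided because either convention is defensible when a lineage retains two
copies.

## Likelihood model

Site log-likelihoods come from Felsenstein pruning under a reversible
amino-acid model: exchangeabilities $s_{ij}$ and stationary frequencies
$\pi$, $Q_{ij} = s_{ij}\pi_j$, normalised to one expected substitution per
site per unit branch length.  Rate heterogeneity uses the discrete-Gamma
approximation (4 categories, mean-of-category discretisation by default,
median by flag) optionally mixed with a proportion $p_{inv}$ of invariant
sites; the combined mixture always has mean rate 1, so branch lengths remain
in expected substitutions per site.  Gaps and `X` contribute uninformative
partial vectors; any other ambiguity code is rejected.  Transition
probabilities use the symmetric eigendecomposition of
$\mathrm{diag}(\sqrt\pi)\,Q\,\mathrm{diag}(\sqrt\pi)^{-1}$, and partials are
rescaled per internal node so long alignments cannot underflow.

The default matrix is the 20-state equal-exchangeability (Poisson) model
with uniform frequencies, chosen because it has closed forms that anchor the
test suite (for example, the probability that the two ends of a branch of
length $t$ differ is $\tfrac{19}{20}(1 - e^{-20t/19})$, and the pairwise
distance MLE inverts it).  Empirical matrices (LG, WAG, ...) are supported
through the standard PAML text layout via `read_paml_matrix()`; the engine
is matrix-agnostic and no empirical matrix is bundled.  Branch-length
optimisation on a fixed topology is delegated to phangorn's optimiser, with
a coordinate-wise bracketed search as fallback for degenerate cases
(two-taxon trees, median discretisation); lengths are clamped to
$[10^{-8}, 20]$ and the optimised likelihood never falls below the starting
value.  Per-site log-likelihoods reported everywhere are computed by the
package's own pruning pass on the optimised tree, so totals, AU inputs and
delta tables are mutually consistent by construction.

## The AU test

Each hypothesis is adjudicated with the approximately unbiased test computed
from the per-site log-likelihoods by multiscale resampling (RELL): at scale
$r \in \{0.5, 0.6, \dots, 1.4\}$, $\mathrm{round}(r\,n)$ sites are drawn with
replacement, the resampled totals are compared, and the bootstrap proportion
$BP_r$ of each topology is its win fraction (argmax ties split uniformly at
random, seeded).  The signed distance $d$ and curvature $c$ are estimated by
weighted least squares on the probit scale,
$\Phi^{-1}(1-BP_r) = d\sqrt r + c/\sqrt r$, with binomial-variance weights,
and $p_{AU} = 1 - \Phi(d - c)$.  Bootstrap proportions are clamped at
$1/(2B)$ ($B$ replicates per scale) to keep the probit finite; when every
$BP_r$ saturates on one side the curve is out of reach of the fit and the
p-value is pinned to the corresponding bound at clamp precision, with a
degenerate-fit flag.  Site resampling ignores partition structure by
default; a block mode resamples whole genes for concatenations, since both
conventions are in legitimate use.  Replicate counts defaults (1,000 per
scale in tests and the pipeline; 10,000 is a reasonable production setting)
are this package's choices.

Adjudication: hypotheses with $p_{AU} < \alpha$ (default 0.05) are rejected;
the test is never allowed to reject all three — if that happens the
maximum-likelihood hypothesis is retained with a warning, mirroring the
test's intended use as a screen of alternatives.

## Site-signal decomposition

For site $s$ with log-likelihoods $\ell_A, \ell_B, \ell_O$ the package
tabulates
$\delta_1 = 2(\ell_A - \ell_B)$, $\delta_2 = 2(\ell_A - \ell_O)$,
$\delta_3 = 2(\ell_B - \ell_O)$, so $\delta_2 = \delta_1 + \delta_3$
identically and the per-axis sums recover the total likelihood-ratio
statistics.  A site is *coloured* on an axis when its delta lies more than
$k$ standard deviations (default $k = 2$) from the axis centre; the joint
signed pattern maps to the supported topology (A: positive-extreme on
$\delta_1$ and $\delta_2$; B: negative on $\delta_1$, positive on
$\delta_3$; O: negative on $\delta_2$ and $\delta_3$).  Whether such a rule
should centre on the axis mean or on zero, and whether the threshold should
use signed deltas or magnitudes, is not uniquely determined; the package
centres on the per-axis mean with signed deltas by default and exposes both
choices (`center = "mean" | "zero"`, `sd_multiplier`).  A `conflict` class
exists for joint patterns matching more than one rule; under the default
signed rules it is unreachable and serves as a guard.  A cluster summary
flags *unidirectional* signal (exactly one non-empty class among coloured
sites) versus *trifurcation* (two or more), the latter being the
conflicting-signal signature that blocks 1:1 assignment.

## Verdicts and the tetralogy call

Per gene: the best hypothesis is the likelihood argmax; confidence counts AU
rejections of the two alternatives (both = *confident*, one = *supported*,
none = *ambiguous*).  Per cluster: verdicts are read in physical gene order;
the cluster is *mixed* when non-ambiguous verdicts span at least two
hypotheses, and the interleave count is the number of adjacent differing
pairs in the non-ambiguous subsequence.  The **tetralogy call** — this
package's explicit operationalisation of an inference that is usually made
narratively — is true when the cluster is mixed *and* the concatenation
either fails to reject at least two hypotheses or shows trifurcating site
signal.  All components are reported separately so users can apply a
different rule.

## The simulator

`scenario_config()` fixes a scenario; `simulate_cluster()` realises it.
Homogenisation is modelled as *complete* until the diploidization time — the
two homeologs are literally one lineage until then — so truth labels are
exact by construction rather than by a rate-based gene-conversion process;
partial homogenisation is available through per-gene mosaic tracts that
follow different scenario trees.  Gene trees are ultrametric in time and
converted to substitutions per site by a constant `rate_scale`; sequences
evolve by standard Markov simulation (root states from the stationary
distribution, a Gamma/invariant rate category drawn per site).

Default study conditions, chosen once as a realistic desk-scale rendering of
a deep teleost-like WGD and used unchanged throughout the tests: WGD at 1.0
time units, outgroup divergence 1.3, query speciation 0.6, shared
diploidization 0.85, per-lineage diploidization 0.3, clade crowns 0.25
(duplicates) and 0.5 (outgroups), `rate_scale` 0.5 expected
substitutions/site/unit (so the "a"–"b" divergence spans about 0.85
substitutions/site of path length), three species per duplicate clade, two
outgroups, one query lineage, 9 genes of 300 columns (tests mostly use 500
columns per the recovery analyses below), Poisson model.  The single-copy
classification problem (`drop_copy = TRUE`) is the default because it is the
hard and common case.  Mosaic tract lengths and rates are free
parameterisation — no empirical estimate exists to calibrate them.

What the simulator deliberately omits: coalescent population processes (no
incomplete lineage sorting), codon/nucleotide structure, alignment error,
rate variation across lineages, and compositional heterogeneity.  Passing
recovery tests therefore demonstrates correctness of the inference machinery
under the stated model, not robustness of the method to every feature of
real data.

## Numerical choices

* Branch-length clamps $[10^{-8}, 20]$; optimisation tolerance $10^{-6}$
  log-units; ties among placements broken by enumeration order.
* Impossible site patterns (probability 0 at zero branch length) return
  $-\infty$ site log-likelihood; the AU and delta stages require finite
  inputs and optimised trees keep lengths positive, so $-\infty$ only arises
  on degenerate fixed-length queries.
* Trimming follows the gap-threshold idiom with both readings of a
  "25% gap threshold" available (`min_residue_fraction`, the trimAl `-gt`
  convention, is the default; `max_gap_fraction` reads the phrase literally
  as "at most 25% gaps").  `X` counts as a residue.  Coordinates are 0-based
  half-open throughout.
* The conserved-element scan merges overlapping (and abutting) qualifying
  windows into maximal runs; the identity threshold is inclusive; gap
  columns count as mismatches by default.  Total conserved length is
  monotone under threshold sweeps, but a long run can split into two as the
  threshold rises, so the record *count* is not monotone in general.

## Problem sizes used in validation

The shipped validation uses: exhaustive-enumeration agreement on 20 random
trees of 3–5 leaves (10 sites each, agreement to $10^{-8}$);
pattern-probability conservation over all $20^3$ three-leaf patterns;
AU calibration and power on 100 truth-A replicates of one 500-column gene
(type-I rate for the true hypothesis at most 12%, rejection of each
alternative at least 80%); and cluster recovery on ten 9-gene 500-column
clusters with the interleaved truth
`[O, B, A, O, O, A, A, A, A]` (at least 7/9 verdicts correct with a positive
tetralogy call) plus ten 5-gene uniform-A clusters (no tetralogy call and
both alternatives rejected on the concatenation).  These sizes were chosen
as the smallest at which the statistical contracts are comfortably
resolvable; `scripts/acceptance.R` re-runs the same analyses from scratch at
a user-supplied seed.

## Limitations

* The backbone is trusted; a wrong backbone invalidates the constraint
  regions.  Unconstrained taxa mitigate this only for the lineages so
  designated.
* Model parameters ($\alpha$, $p_{inv}$) are user-supplied or defaulted, not
  estimated by ML (a coarse grid is the intended workflow when needed); the
  method itself is agnostic to the matrix used.
* dN/dS values are *summarised* (including the infinite-omega boundary when
  synonymous changes are absent), not estimated: codon-model fitting is out
  of scope and the ratios are consumed from external tools or simulation
  metadata.
* The AU implementation follows the classical multiscale-bootstrap
  formulation; newer least-squares variants of the reference tool are not
  reproduced.
* Real-data headline numbers from any particular study (bootstrap supports,
  per-cluster conserved-element counts, etc.) depend on external sequence
  databases and full tree searches and are outside what this package
  recomputes.

## A worked run

```{r example, eval = FALSE}
cfg <- scenario_config(n_genes = 9, gene_length = 500,
                       labels = c("O", "B", "A", "O", "O", "A", "A", "A", "A"),
                       seed = 42)
run <- run_pipeline(cfg, n_replicates = 1000)
print(run$report)
plot(run$concat)   # three-panel site-likelihood-ratio plot, A red / B blue / O green
```
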