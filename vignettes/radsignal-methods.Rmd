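---
title: "Diagnosing an ancient rapid radiation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing an ancient rapid radiation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsignal)
```

## The problem this package addresses

An ancient rapid radiation leaves a characteristic scar on a phylogeny:
several major clades that diverged from one another within a few million
years, a long time ago. The squamate (lizard and snake) backbone is the
canonical case this package is built around: six major ingroup clades
(Iguania, Gekkota, Scincoidea, Lacertoidea, Anguimorpha, Serpentes) whose
origins are compressed into internodes averaging only about 4.6-8.7 Ma at a
depth of roughly 170-190 Ma. Two phylogenetic hypotheses compete for this
backbone: Scleroglossa (Iguania sister to all other squamates, the
morphological signal) and Toxicofera (Iguania nested with snakes and
anguimorphs, the molecular signal).

Backbones like this are doubly treacherous. First, genuine signal for an
internode accrues roughly in proportion to its duration, so a 5 Ma internode
observed from 180 Ma away offers very few informative substitutions per
gene. Second, the absence of signal does not produce an absence of
resolution: homoplasy accumulated on the four long branches subtending each
short internode produces *misleading* resolution, and systematic biases --
lineages with elevated rates and convergent base composition -- push that
misleading resolution consistently in one direction (long-branch
attraction). A diagnosis therefore needs three ingredients at once: how much
do individual genes disagree, how much signal could they possibly carry for
internodes of this age and duration, and do the data show the fingerprints
of bias. Each module of this package supplies one piece.

## Backbone topology space

With each of the six ingroup clades constrained monophyletic (plus an
outgroup), a backbone topology is a rooted binary tree on six clade labels.
`enumerate_backbones()` generates all of them by recursive leaf insertion --
every successive label attached along every branch and above the root --
which provably yields each topology exactly once: there are
$(2n-3)!! = 945$ for $n = 6$. `classify_backbone()` partitions them by
monophyly statements: 105 contain Scleroglossa, 45 contain Toxicofera, 795
contain neither. The closed forms are worth knowing:
excluding one clade leaves $(2\cdot5-3)!! = 105$ rooted trees on the other
five; a three-clade hypothesis contributes
$(2\cdot3-3)!! \times (2\cdot4-3)!! = 3 \times 15 = 45$.

## The likelihood engine

Site likelihoods are computed by Felsenstein's pruning algorithm under
reversible models (JC, HKY, GTR for DNA; symmetric Mk for discrete
characters), with equal-probability discrete-gamma rate categories
(category means, four by default) and an optional invariant class.
Ambiguity codes and gaps enter as partial likelihood 1 over their
compatible states; per-node rescaling keeps likelihoods finite on any
observable data. Rate matrices are scaled to one expected substitution per
site per unit branch length at equilibrium.

Branch lengths on a fixed topology are optimized coordinate-wise by Brent's
method, iterated until the total log-likelihood improves by less than
`tol = 1e-6` (a proposal is kept only if it improves the likelihood, so the
optimization is monotone). There is no tree search anywhere in the package:
constrained "searches" are exhaustive evaluations over the enumerated
backbone space with fixed within-clade subtrees (`best_tree_in_class()`),
which is exact within its search space and affordable because the space is
the 945 backbones, not the space of terminal-level trees.

Per-site rates on a fixed ultrametric chronogram (`per_site_rates()`) treat
a single multiplier of all branch durations as the free parameter of each
site, maximized on $[0, r_{max}]$ with $r_{max} = 20$ by default. The
objective for a single site typically has a narrow peak followed by a long
saturation plateau, which defeats a naive golden-section search; the
optimizer therefore brackets the maximum on a 40-point logarithmic grid
first and refines by Brent within the bracket. Sites compatible with a
single state need no substitutions and are assigned rate 0 directly. Rates
are per unit of tree time: doubling all node depths halves every estimate.

## Topology testing: RELL and the AU test

Gene-level hypothesis tests never re-optimize anything: the per-site
log-likelihoods of the three class representatives (the best tree within
each hypothesis class) are resampled. At each of ten scale factors
$r \in \{0.5, 0.6, \ldots, 1.4\}$, $\lceil r \cdot n \rceil$ sites are drawn
with replacement and the winning topology recorded (ties split equally).
The winning proportions $bp(r)$ are fitted on the probit scale as
$bp(r) = \Phi(-(d\sqrt{r} + c/\sqrt{r}))$ by weighted least squares, and the
approximately unbiased p-value is $p = \Phi(-(d - c))$, where $d$ and $c$
estimate the signed distance and curvature of the log-likelihood boundary.
Degenerate proportions (0 or 1 at every scale) short-circuit to $p = 0$ or
1; if fewer than three scales are non-degenerate the scale-1 bootstrap
proportion is reported with a fallback flag. Only this primary probit fit is
implemented; the second-stage refinements of some AU implementations are
not, which can matter in the far tails but not at the 0.05 threshold the
confidence sets use. Topologies with $p > 0.05$ form a gene's confidence
set; a gene whose set retains two or more hypothesis classes is *ambiguous*
-- the situation the radiation makes common.

## Signal and noise for a quartet internode

Phylogenetic informativeness summarizes when in time a site is useful:
we use $\rho(t;\lambda) = 16\,\lambda t\, e^{-4\lambda t}$, which depends on
rate and depth only through $\lambda t$, peaks at $t = 1/(4\lambda)$ for a
site of rate $\lambda$, and is maximized over rates at $\lambda = 1/(4t)$
for an internode of depth $t$ (the "optimal rate"). Conventions differing by
extra powers of $\lambda$ exist in the informativeness literature; ours is
pinned by those two stationarity relations, and nothing downstream depends
on the absolute normalization because profiles are also reported
height-standardized (peak = 1), the form in which profiles of datasets with
different sizes and rates are compared.

Informativeness ignores homoplasy, so it is optimistic precisely where
radiations hurt most. The quartet signal-and-noise probabilities repair
this. For an internode of duration $t_0$ with four subtending branches
$T_1..T_4$ (a quartet with five branches), the probability that a site of
rate $\lambda$ produces a parsimony-informative pattern supporting the true
split, either wrong split, or nothing, is computed *exactly* under a
k-state symmetric model by summing over the two internal node states.
Over a gene's sites those per-site probabilities define a multinomial race;
`quartet_probabilities()` resamples the support counts (100,000 draws by
default) and reports QIRP, QIHP and QIPP: the probabilities that the gene's
informative sites favour the correct resolution, an incorrect one (both
wrong quartets pooled), or tie -- any tie for the largest count, including
all-zero, is scored as a polytomy. The package's correctness surface for
this module is agreement with direct character-level Monte-Carlo simulation,
not bit-identity with any existing implementation. Because a nested clade
spanning several backbone internodes needs all of them correct at once,
`joint_signal_probability()` multiplies per-internode QIRPs under an
independence assumption -- a deliberate simplification that gives an upper
bound flavour to the joint probability.

## Tree-independent site rates and fast-site removal

Two rate proxies need no tree at all. OV is the per-site proportion of
mismatching taxon pairs among unambiguously observed pairs. TIGER scores a
site by how consistently the rest of the matrix agrees with the taxon
partition it induces: the agreement of site $j$ with site $i$ is the
fraction of $j$'s state sets nesting within some state set of $i$, and
site $i$'s score is the mean agreement of all other sites with it (a
constant site scores exactly 1; ambiguous cells simply drop out of the
sets). We use raw agreement scores for ranking rather than the original
binning -- only the ranking is consumed downstream. Ties are broken by
original site index so rankings are deterministic.

`removal_series()` deletes the next 500 fastest sites per step (the step
size is configurable; the scheme avoids committing to any fast/slow
cut-off), re-infers a tree at each step, and records which backbone splits
of a reference tree survive. The built-in re-inference is neighbor joining
on Jukes-Cantor distances -- any consistent estimator suffices to detect
backbone collapse at desk scale, and a hook accepts an arbitrary inference
function (e.g. an external ML program). `ml_distances()` additionally
provides pairwise ML distances under any of the package's models including
gamma and invariant classes; heterogeneity-corrected distances matter
whenever fast lineages would otherwise be compressed.

## Composition and lineage-rate bias

`composition_profile()` counts unambiguous bases per taxon (and per gene),
deriving GC content, AT skew $(A-T)/(A+T)$ and GC skew. The chi-square
homogeneity test uses the standard taxa-by-bases contingency table with
$df = (n_{taxa}-1)\times 3$. Per-gene AT-skew vectors feed an average-linkage
hierarchical clustering on Euclidean distances (linkage configurable; the
average is the common default for trait vectors); missing taxon-gene cells
are imputed with the taxon's across-gene mean so distances stay defined,
and imputations are flagged. The simulation-based phylogenetic ANOVA takes
the ordinary one-way F statistic and calibrates it against F statistics of
traits simulated under Brownian motion on the tree, with the Brownian rate
estimated from the observed trait by independent contrasts; the
phylogenetic p-value is the proportion of simulated F at least as large as
observed. Root-to-tip clade rates pool path lengths across a subsampled
tree set (10% by default, echoing the usual treatment of posterior
samples) and across clade members; "significant" rate differences are
non-overlapping central 95% percentile intervals. Pooling across terminals
(rather than averaging per tree first) is the default; the intervals are
empirical percentiles, not parametric.

## Gene-tree conflict

RF distances are computed on unrooted views after pruning each pair to its
shared leaf set, normalized by the total bipartition count of both trees;
polytomies contribute fewer bipartitions and are never arbitrarily
resolved. The treespace embedding is classical metric MDS (double
centering, top two eigenvectors) with Kruskal stress-1 reported -- chosen
over stress-minimizing layouts because it is deterministic and
dependency-free while serving the same two-axis purpose; the reported
stress tells you how honest the picture is. Split frequencies over a gene
tree set (the supernetwork branch weights) count, for each observed
bipartition, the displaying trees among the trees eligible to show it
(leaf set covering both sides); the NEXUS `st_splits` export hands the
layout problem to dedicated network viewers. Gene support frequency
restricts the question to a reference tree's nodes, with the denominator
requiring all clade terminals plus at least one outside terminal in the
gene -- one outside terminal is the weakest condition making the clade
testable, and it is the documented choice.

## The synthetic radiation generator

The generator exists so that every stage above can be exercised, with known
truth, without downloading anything. Its defaults *are* the study
conditions: six ingroup clades plus an outgroup; an ingroup crown at 190 Ma
with ladder internodes drawn uniformly from 4.6-8.7 Ma; 46 genes with
log-normal lengths spanning roughly 400-3,000 bp (meanlog log(900), sdlog
0.45); a background rate of 0.002 substitutions/site/Ma (a typical nuclear
protein-coding figure, and one that puts the single-rate informativeness
peak at $1/(4\lambda) = 125$ Ma, in the right region for a deep
Mesozoic radiation); HKY with $\kappa = 2.5$, gamma shape 0.7 with a 25%
invariant class; a 1.6-fold rate multiplier on Iguania and Serpentes (two
clades that are non-sister under the default true backbone, Scleroglossa);
a +1.3 percentage-point AT-ward equilibrium shift on those same clades,
applied from their stem branches tipward (an HKY frequency switch -- the
simplest nonstationary mechanism producing clade-level AT enrichment); and
10% whole-gene missingness per taxon. Within-clade topologies are
pure-birth trees rescaled so each clade's crown age is a uniform 0.3-0.6
fraction of its stem age. The outgroup diverges 30 Ma above the ingroup
crown. Everything is driven by one mandatory seed; identical configurations
are bit-identical.

One allocation choice deserves its own paragraph. The empirical bias the
generator emulates has two fingerprints: the biased clades are ~1.3%
AT-richer *and* they share distinctive AT-skew patterns. A 1.3-point shift
split symmetrically between A and T changes content but leaves
$(A-T)/(A+T)$ untouched, making the skew diagnostics blind by construction;
the generator therefore places the whole shift on A (C and G each giving up
half), so both fingerprints exist. Even so, the skew signature this induces
is small: the equilibrium skew difference is about 0.023, the realized
difference after incomplete compositional relaxation about 0.013, while the
per-gene skew sampling noise of a ~1 kb gene is about 0.045. Euclidean
clustering of per-gene skew vectors therefore cannot reliably isolate the
biased clades under these conditions -- the separation amounts to a
z-score of roughly 0.2 on inter-clade distances -- and the corresponding
end-to-end check fails honestly; the clustering machinery itself is
verified on shifts an order of magnitude larger, where it succeeds in every
seed. The lesson is scientific rather than numerical: the clade-level skew
clustering seen in real data reflects compositional differences much larger
than a 1.3% genome-wide AT shift alone can produce.

What the generator does *not* emulate, deliberately: incomplete lineage
sorting (gene trees are topologically identical to the species tree; the
paper's argument treats ILS as a minor factor at these depths and none of
the diagnostics model it), alignment error and trimming, codon structure,
indel processes, and within-gene rate autocorrelation. Passing tests on
synthetic data therefore demonstrate correctness of the statistics and the
qualitative detectability of rate and composition biases -- not that real
gene-tree conflict is free of ILS or alignment artifacts.

## Problem sizes used by the checks

The automated checks run the whole pipeline at sizes chosen to exercise
every code path with comfortable statistical margins: exhaustive
enumeration at six clades (945 topologies); exact likelihood verification
against brute-force state summation on trees of up to five leaves;
branch-length recovery on 5,000-site alignments; AU null calibration over
200 simulated genes of 200 sites on seven-taxon trees with
radiation-length internodes (rejection of the true topology at
$\alpha = 0.05$ must stay below 8%); quartet probabilities against 20,000
character-level Monte-Carlo replicates at 500 sites; and rate-multiplier
recovery on six full synthetic datasets (46 genes each), with the ratio of
fast-clade to background root-to-tip means -- measured from the ingroup
crown on per-gene NJ trees built from gamma- and invariant-corrected ML
distances -- required to fall in [1.4, 1.8]. Uncorrected JC distances
compress the fast lineages well below that band; the corrected distances
recover ratios near the structurally expected value of about 1.56 — not
1.6, because only Iguania's whole path is multiplied while Serpentes'
multiplier acts from its later stem.

## Known limitations

Branch-length optimization is coordinate-wise and can be slow on large
trees; the engine is meant for the desk-scale constrained evaluations the
pipeline needs, not for heuristic search (use external ML software through
the removal-series hook for that). The AU implementation fits the primary
probit model only. The quartet framework assumes symmetric k-state
substitution; composition-biased sites violate it, which is exactly why the
composition module exists alongside it. The phylogenetic ANOVA assumes
Brownian trait evolution with a contrasts-estimated rate. TIGER is
quadratic in the number of sites; rank large matrices with OV, or TIGER on
a subsample.
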