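---
title: "Diagnosing gene-tree discordance and shopping for clock-like loci"
author: "phylodisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing gene-tree discordance and shopping for clock-like loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodisc)
```

## The problem

Phylogenomic datasets routinely show gene trees that disagree with each
other and with the species tree. Two biological processes dominate such
discordance at deep timescales: incomplete lineage sorting (ILS), where
ancestral polymorphism persists across speciation events, and
introgression, where hybridization moves genetic material between diverged
lineages. Telling them apart matters: ILS is a neutral expectation of the
multispecies coalescent (MSC), while introgression implies reticulate
evolution. A second, practical consequence of heterogeneous gene histories
is that divergence-time estimation suffers: loci vary in clock-likeness, so
which loci you date with can move the estimates. `phylodisc` implements
both halves of that workflow: a triplet branch-length mixture test that
attributes discordance to ILS or introgression, and a "gene shopping"
filter that stratifies loci by concordance and molecular-rate variance
ahead of dating.

## The triplet mixture model

For every triplet of ingroup species $\{i, j, k\}$ (all rooted with one and
the same outgroup), each gene tree resolves the triplet as one of three
topologies, identified by the "odd taxon out", with one internal branch of
length $t \ge 0$ between the two coalescences. Under the MSC, a triplet
with species-tree internal branch $T$ (coalescent units) shows each
discordant topology with frequency $\tfrac13 e^{-T}$, and the internal
branch of a discordant gene tree is exponential with mean 1 in coalescent
units — the waiting time between two coalescences in the ancestral
population.

Two models are fit per triplet topology to the observed branch lengths:

* ILS only: $f_1(t) = \frac{1}{\lambda} e^{-t/\lambda}$, whose MLE is
  closed-form ($\hat\lambda$ = sample mean).
* ILS + non-ILS mixture:
  $f_2(t) = \pi \frac{1}{\lambda} e^{-t/\lambda} +
  (1-\pi) \frac{1}{\lambda} e^{-(t-c)/\lambda}\,\mathbf 1[t \ge c]$.

The second component adds a hard lag $c$: branches produced by a discrete
event (an introgression pulse, or — for the topology matching the species
tree — the speciation interval itself) cannot be shorter than the time back
to that event, while ILS branches start at zero. The two components share
the exponential scale $\lambda$, the coalescent-motivated form: both kinds
of branch end with the same ancestral coalescent process, the non-ILS kind
merely starts later. Sharing $\lambda$ also keeps the mixture to three free
parameters $(\pi, \lambda, c)$, which BIC then penalizes against the
single-parameter exponential:

$$\mathrm{BIC}_1 = \ln(n) - 2\ln L_1, \qquad
  \mathrm{BIC}_2 = 3\ln(n) - 2\ln L_2, \qquad
  \mathrm{dBIC} = \mathrm{BIC}_2 - \mathrm{BIC}_1.$$

dBIC below $-10$ reads as decisive support for the mixture, above $+10$ as
decisive support for ILS only, anything between as ambiguous. Note that
BIC values are negative whenever $\ln L > 0$, which happens routinely
because branch lengths are small and the densities exceed 1.

A topology that matches the species tree and prefers the mixture reflects
*speciation* (its lag is the species-tree internal branch), not
introgression; only discordant topologies are read as introgression
(mixture preferred) or ILS (exponential preferred). Significant discordant
results are then collapsed into *events*: triplets that imply the same
unordered pair of taxon groups (the groups of the two cherry taxa) and
carry numerically equal fitted parameters reflect a single event ancestral
to the species involved. The direction of introgression is not identifiable
from branch lengths alone, so events are reported as unordered pairs.

### Fitting

The mixture likelihood is maximized by EM: responsibilities in the E-step,
closed-form updates of $\pi$ and $\lambda$ in the M-step, and a bounded
one-dimensional search for $c$ on $[0, \max t)$ — a coarse grid scan
followed by golden-section refinement, since the profile in $c$ is only
piecewise smooth — accepted only when it improves the observed likelihood
(a generalized EM step), so the log-likelihood never decreases. Each fit
runs from several seeded initializations ($\pi \sim U(0.05, 0.95)$, $c$
uniform over the 10–90% data quantiles, $\lambda$ = sample mean; 10
restarts by default) and the best restart is kept. Because the exponential
is nested in the mixture (at $\pi = 1$ or $c = 0$), the reported mixture
likelihood is floored at the exponential's. Zero-length internal branches
break the log-density and are jittered to half the smallest positive
observation, with the count reported. The inner loop is implemented in
C++ (`src/em_mixture.cpp`); convergence is declared when the
log-likelihood changes by less than `tol` in relative terms
($|\Delta \ln L| < \mathrm{tol}\,(|\ln L| + 1)$, default `1e-8`,
`max_iter` 2000) — log-likelihood magnitudes grow with $n$, so an absolute
test at that tolerance would keep the EM polishing numerical noise.

### Per-locus rate normalization

Gene-tree branch lengths arrive in substitutions/site, i.e. coalescent
time multiplied by a per-locus substitution rate. Among-locus rate
variation therefore smears the lag $c$ — a locus twice as fast shows a lag
twice as long — and can erase an otherwise clean introgression signal.
`run_discordance()` consequently divides every gene tree's branch lengths
by that tree's mean root-to-tip depth before extracting triplet branches
(`normalize_rates = TRUE`, the default). Rescaling preserves the
exponential form of the ILS component and simply re-expresses $\lambda$
and $c$ in units of relative tree depth; set `normalize_rates = FALSE` to
fit raw substitution-unit branch lengths.

### Known behavior of the dBIC rule

Threshold rules on dBIC have a small but nonzero false-positive rate on
truly exponential data (the acceptance script measures it at $n = 500$;
it is below 5% there and of order a few per mil at the smaller per-topology
counts typical of a full scan). A scan over many hundreds of triplet
topologies therefore occasionally flags a spurious low-weight event even
without introgression; genuine pulses are distinguished by their larger
non-ILS weight and lag, and by recurring across triplets of the same group
pair. Users should treat isolated single-triplet events with small
`total_nonils_pct` with caution.

## Gene shopping

For dating, loci are ranked by three per-locus statistics computed against
the species tree: the proportion of the gene tree's nontrivial
bipartitions shared with the species tree (both trees pruned to their
common taxa; the gene tree's split count is the denominator, a
species-tree denominator is available via `denominator = "species"`), the
root-to-tip variance (the $n-1$ sample variance of root-to-leaf path
lengths; 0 for a perfect clock), and the total tree length. Loci with a
shared-bipartition proportion of at least 0.3 (the rule is $\ge$) are
retained and split into three contiguous rank-based variance terciles —
rank-based grouping, rather than value-based quantile cuts, is what turns
123 retained loci into exactly 41/41/41. Ties in variance are broken by
descending tree length, then locus id, so outputs are deterministic.
`set1` (lowest variance) is the most clock-like stratum; a separate
5-locus minimum-variance set supports a strict-clock-style sensitivity
analysis. `build_dating_sets()` concatenates the per-set alignments into
supermatrices (gap-padding missing taxa) and writes relaxed PHYLIP, NEXUS
with a `sets` block, and a RAxML-style partition table; dating engines are
deliberately out of scope.

Quartet concordance complements the split-based metric:
`quartet_scores()` reports the fraction of (quartet, gene tree) pairs that
resolve as in the species tree, and per-branch support from quartets drawn
across each internal branch's four adjacent subtrees (exhaustive up to
roughly 25 taxa, seeded sampling beyond).

## Partitioned Bremer support

To quantify each locus's support or conflict for each node of a focal
tree, the package scores Fitch parsimony (gaps and `N` as missing data,
ambiguity codes as state sets, polytomies scored as-is) and, for every
internal node, searches for the best tree *lacking* that node's
bipartition (a reverse constraint). The per-locus value at a node is the
locus's parsimony-length difference between that anti-constraint tree and
the focal tree; values sum exactly to the node's overall Bremer support.
Search is exhaustive (exact) up to 9 taxa and seeded NNI steepest-descent
with sideways plateau moves and restarts beyond; score ties are broken by
lexicographic Newick so per-locus values are reproducible. The four
summary statistics per locus (nodes supported, nodes conflicted, their
difference, summed score) and the mirrored four per node come out of
`summarize_support()`.

## The synthetic-data generator

All inputs can be generated with known ground truth. `simulate_msc()`
runs the censored coalescent within species-tree branches (one haploid
sample per species; rate $k(k-1)/2$ per population in coalescent units)
with introgression as an instantaneous pulse: at the event time, each
lineage currently in the recipient branch traces back into the donor
branch with probability $\gamma$. The simulator is checked against the
closed forms above (topology frequencies at $T \in \{0, 1, 5\}$ and the
Exp(1) law of discordant internal branches) and a $\gamma = 0$ pulse is a
bitwise no-op. `apply_rate_heterogeneity()` converts coalescent units to
substitutions/site by a global scale (default 0.01 substitutions/site per
coalescent unit) times a lognormal per-locus rate times Gamma(shape,
shape) per-branch noise, producing the spread of root-to-tip variances the
gene-shopping stage stratifies. `simulate_sequences()` evolves JC69
alignments on the resulting trees.

`make_toy_study()` bundles the study-shaped fixture: nine groups
("subfamilies") of two taxa each plus one outgroup — 19 tips — arranged as
two major clades (four and five groups) whose radiations span short
internal branches (1.5 coalescent units, leaving visible ILS), group stems
from 2 coalescent units, the clade split at 11 and the outgroup at 16;
150 gene trees; per-locus lognormal rates (sdlog 0.5), per-branch
Gamma(10, 10) noise; and one planted pulse with $\gamma = 0.15$ at time 3
from group g2 into group g7. Donor and recipient sit in *different*
clades by design: a discordant donor–recipient triplet then has its third
taxon joining at the deep clade split, so introgressed branches carry a
lag of about 7 coalescent units against an ILS scale of 1 and the planted
pair is identifiable in principle. (On a pure ladder topology the
discordant triplets' third taxa join shallowly, the lag shrinks to 1–3
units, and rate noise swamps it — a fixture that cannot be recovered even
by a correct method.) The generator emulates topological discordance,
introgression lags and rate spread; it does **not** emulate gene-tree
estimation error from finite alignments, missing taxa patterns, alignment
error, or intralocus recombination, so passing the end-to-end tests shows
the inference machinery is correct under its own model, not that real
datasets of this size always yield this power.

## Problem sizes and reproducibility

Tests and the acceptance script use scaled problem sizes chosen to keep a
full run in minutes on one core: $10^4$ loci for simulator calibration,
$n = 2000$ observations for mixture recovery, 100–200 replicates of
$n = 500$ for model-selection calibration, and 150-locus toy studies
(restarts reduced to 3 there; the planted signal is far from the decision
boundary, so extra restarts change nothing). Every random operation takes
an explicit seed, and identical seeds give byte-identical outputs,
including the TSV reports.

The command-line surface is deliberately thin: the exported
functions (`run_discordance()`, `run_geneshop()`, `write_report()`,
`read_run_config()`) are the interface, and a YAML `run_config` carries
paths, thresholds and seeds for scripted use.

## A compact example

```{r example, eval = FALSE}
toy <- make_toy_study(seed = 1)
disc <- run_discordance(toy$subst_trees, toy$species_tree,
                        outgroup = toy$outgroup, taxon_map = toy$taxon_map,
                        restarts = 3, seed = 1,
                        fit_topologies = "discordant")
subset(disc$events, event_type == "introgression")

shop <- run_geneshop(toy$subst_trees, toy$species_tree, outgroup = "out",
                     min_bipartition = 0.3)
table(shop$metrics$set_label)
```

## Limitations

* Direction of introgression is not identifiable; events are unordered
  group pairs.
* The mixture assumes a single shared $\lambda$ and one lag per topology;
  multiple pulses onto the same triplet topology are absorbed into one
  averaged component.
* The dBIC threshold controls evidence per topology, not family-wise error
  across a scan (see above).
* Tercile stratification is rank-based; with heavy ties at the
  set boundaries membership follows the deterministic tie-break, not
  biology.
* Heuristic parsimony search is exact only in exhaustive mode; above 9
  taxa the NNI hill-climb can return a local optimum (ties and scores are
  still deterministic given the seed).
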