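---
title: "Copy-number alterations in metabolic networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number alterations in metabolic networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`metacna` analyses how gene copy numbers in a metabolic network evolve
across a phylogeny and whether those changes predict phenotypic traits.
The pipeline has five stages:

1. **Network reduction.** A genome-scale metabolic model (SBML) is
   collapsed into *isoenzyme groups*: sets of enzyme-coding genes whose
   reaction lists are identical or nested subsets of one another.  The
   groups become the nodes of a directed *enzyme orthology network*
   whose edges follow shared product-to-reactant metabolites.
2. **Genome projection.** Each target genome is projected onto the
   reference network through an orthology/homology table, yielding one
   integer *copy-number vector* per species (genes per group).
3. **Ancestral reconstruction.** Each group's copy number is treated as
   a continuous character and reconstructed at every internal node of a
   fixed, dated phylogeny by linear (Wagner) parsimony.  A *copy-number
   alteration* (CNA) is any group whose count differs between a node and
   its direct ancestor.
4. **Clustering test.** Whether CNAs cluster in the network is tested by
   removing all nodes without CNAs, measuring the connected components
   among the remainder, and comparing against uniform random placement
   of the same number of CNAs (topology is never randomized).
5. **Trait association.** Per-branch CNA deltas are used to predict
   per-branch trait changes via correlation-based feature selection
   (CFS) and least-median-of-squares (LMS) regression, scored by
   leave-one-species-out (LOO) prediction and a trait-reshuffling
   permutation test, with Benjamini-Hochberg FDR control across traits.

# Network reduction

## Isoenzyme grouping

Grouping is a two-step fixpoint.  Step one pools genes with identical
reaction sets.  Step two repeatedly merges any group whose reaction set
is a strict subset of another group's into that group; the absorbing
group keeps its own reaction set.  Groups with overlapping but
non-nested reaction sets are never merged.

When a group has several incomparable strict supersets the merge target
is genuinely ambiguous.  We resolve it deterministically: the absorber
is the smallest superset, ties broken on the sorted reaction-id key.
This makes the fixpoint independent of input order, which the test
suite verifies by shuffling gene order on random models.

## Edges and currency metabolites

An edge u&nbsp;&rarr;&nbsp;v exists when a directed orientation of a
reaction in u produces a species that an orientation of a reaction in v
consumes.  Reversible reactions contribute both orientations,
independently.  Metabolite identity is the compartment-specific species
id, so edges cross compartments only through transport reactions that
genuinely share a species.

Thirteen ubiquitous cofactors (H+, H2O, ATP, ADP, Pi, PPi, Na+,
coenzyme A, O2, NAD+, NADH, NADP+, NADPH) are removed in every
compartment before edge construction; otherwise they connect nearly
everything to everything.  Matching is by compartment-stripped base
name, case-insensitive and punctuation-free, with a configurable
synonym list, because SBML dialects suffix compartments differently.
Reactions emptied on both sides by the removal are kept but flagged, so
reaction counts stay stable; they simply contribute no edges.  Removal
is applied before edge construction only — grouping uses reaction
identity, which currency removal does not affect.

## Network statistics

Density is `E / (N (N - 1))` over ordered pairs.  Because isolated
nodes make global path statistics infinite, diameter and average
shortest path are computed over the reachable ordered pairs of the
largest weakly connected component.  That convention is ours; a
harmonic-mean alternative would also be defensible, and the choice is
configurable in the sense that the full distance matrix is one igraph
call away.

# Genome projection

Three assignment steps, each gene counted at most once:

1. orthologs join the group of their reference counterparts — if the
   orthologs span several groups the gene goes to the plurality group,
   exact ties to the lexicographically smallest id (with a warning);
2. orphans homologous to members of exactly one group join it; genes
   homologous to two or more groups stay unassigned;
3. remaining genes from families of at least `family_min_size` members
   (default 2, a configuration knob — no published value exists) whose
   annotated reference members all lie in one group join that group.

Target genes absent from the orthology table are ignored: most of a
genome is not metabolic.

# Ancestral reconstruction

## Linear parsimony

Linear (Wagner) parsimony minimizes the summed absolute change along
branches.  We chose it over squared-change parsimony because gene
counts are integers and CNA events are counted per branch; linear
parsimony preserves integer optima (an all-integer input always admits
an all-integer optimal labelling).  Squared-change reconstruction is
available as `method = "squared"`.

The implementation is the interval dynamic program.  On the up-pass
each node receives the interval of optimal states: the median interval
of its children's interval endpoints.  This is exact for arbitrary
multifurcations because a child's cost function, convolved with the
`|child - parent|` branch penalty, equals its minimum plus the distance
to its optimal interval (cost slopes outside the optimum are at least
one).  The test suite checks exact agreement of cost and optimal root
set with a brute-force Sankoff enumeration on every rooted topology up
to six tips.

Branch lengths play no role in the cost: this is standard unweighted
linear parsimony.  A branch-length-weighted variant was considered and
rejected — it breaks the exactness of the interval recursion (the
convolution argument needs unit slopes) and nothing downstream uses it.

## Resolution and rounding

Optimal states form intervals, so one resolution must be chosen and the
choice matters for CNA calling.  Our rules, fixed and documented: the
root takes its interval midpoint; every other node takes the value in
its interval closest to its resolved parent (clamping, which is always
optimal); missing tips inherit the parent value at no cost.  Raw real
resolutions are retained; for CNA calling values are rounded to the
nearest integer with exact halves rounded down.  Missing tip values
impose no cost and at least two observed tips are required per
character.

# The clustering permutation test

Weak connectivity (edge direction ignored) defines components: the
clustering question is adjacency, not reachability.  For each statistic
(component count, maximum and mean component size, mean in/out degree
of CNA nodes in the full network) two one-sided empirical p-values are
computed with the +1 correction, `p = (1 + #{null >= obs}) / (1 + n)`
and its mirror, classifying each statistic as bigger / smaller / not
significant at `alpha = 0.05`.  The null redistributes CNA labels
uniformly over nodes; network topology is never randomized.

A practical point discovered while designing the calibration
experiment: on small networks the null statistic (e.g. maximum
component size among a handful of nodes) takes few values, and an
empirical p-value that counts ties as extreme is then conservative —
its attainable rejection rate at nominal 0.05 can be 0.03 or far less.
The type-I calibration test therefore runs on a 300-node random
network with 60 CNA nodes, where the null support is wide enough that
the attainable level is close to nominal.  This is a property of
discrete permutation tests generally, not of this implementation.

# Trait association

## Branch changes as the unit of analysis

Both predictors (per-group copy deltas) and target (trait delta from
the trait's own parsimony reconstruction) are computed per branch, so
that shared ancestry does not masquerade as association.  Predictors
default to signed per-branch deltas; an absolute-copy-number mode
(`predictors = "absolute"`) exists as well.

## CFS

Feature subsets are scored by
`merit(S) = k r̄_cf / sqrt(k + k (k - 1) r̄_ff)` where `r̄_cf` is the
mean absolute feature-target Pearson correlation and `r̄_ff` the mean
absolute pairwise feature correlation: subsets correlated with the
target but not with each other are preferred.  The search is greedy
forward, continues through non-improving additions, stops after two
consecutive failures to improve, and returns the best subset seen.
Constant features are never selected.  A quirk worth knowing: when a
candidate's target correlation is large relative to the penalty, the
merit can increase even for a perfectly redundant duplicate (the
numerator grows linearly while the penalty grows as a square root);
with `r_cf` ratios above about 0.72 the duplicate always hurts, and the
test suite pins this behaviour with a hand-enumerated example.

## LMS

Least-median-of-squares regression minimizes the median squared
residual, which tolerates up to half the rows being arbitrarily wrong.
The implementation fits exact hyperplanes on (p+1)-point elemental
subsamples and keeps the fit with the smallest criterion; all
subsamples are enumerated when there are at most `n_subsamples` of
them (default `min(2000, all)`), otherwise that many seeded random
subsamples are drawn, skipping and redrawing degenerate ones.  Missing
predictor values are imputed with column medians and columns are
re-centered internally.  Inside the LOO/permutation pipeline the
subsample budget defaults to 200: with at most a handful of selected
predictors, the chance that 200 random elemental subsets contain no
clean one is negligible even at 40% contamination, and the budget is
what makes thousand-fold permutation re-fitting affordable.

## LOO scoring and permutation significance

For each species with an observed trait value, its terminal branch is
removed, the trait is re-reconstructed without that tip, CFS and LMS
are re-run, and the species' value is predicted as the reconstructed
parent value plus the predicted terminal-branch delta; the score `r` is
the Pearson correlation of predictions against observations.  Copy
numbers are never treated as missing, so their reconstruction stays
fixed.  Significance reshuffles the observed trait values among the
observed taxa and re-runs everything, one-tailed:
`p = (1 + #{r_perm >= r_obs}) / (1 + n)` with `n = 1000` by default.
Reshuffling happens at the tip level, before reconstruction, matching
the stated order of the procedure being reproduced.  `r` is Pearson
throughout.

**A calibration caveat.** The reassignment test's true null hypothesis
is exchangeability of trait values across taxa.  A trait that evolves
by Brownian motion on the tree but has no connection to any group
violates exchangeability: the reconstructed parent value predicts the
tip well, reshuffling destroys that, and the test rejects — it is
detecting phylogenetic signal, not CNA association.  We measured this
directly on synthetic Brownian null traits, where p-values pile up
near zero.  Calibration checks in this package therefore use
exchangeable (i.i.d.) null traits, for which uniformity holds by
symmetry; significance for real, phylogenetically structured traits
should be read as "more predictable than a random reassignment", which
is the published procedure's meaning, not as a pure test of
CNA-trait coupling.

## FDR, ANOSIM, PCA

Across traits, Benjamini-Hochberg step-up at `alpha = 0.05` flags
significant associations (`stats::p.adjust`).  ANOSIM (via
`vegan::anosim`, singleton groups excluded) and covariance-matrix PCA
(`stats::prcomp`, no scaling) are provided for the complementary
ordination summaries.

# The synthetic-data generator

The generator produces every input the pipeline consumes, with ground
truth, so each stage can be scored without downloads:

* a compartmentalized random metabolic model whose gene-reaction
  structure plants a known isoenzyme partition — each group owns a
  unique signature reaction (groups can never merge across the planted
  partition), at least one member carries the full reaction set, and
  other members carry identical sets or nested subsets, exercising both
  merge steps; currency metabolites are injected at a configurable
  frequency;
* a dated coalescent tree (default 16 taxa, root at 100 My);
* copy-number evolution: root counts `1 + Poisson(1)`; per branch of
  length `t`, gains ~ `Poisson(0.02 t)` and losses ~ `Poisson(0.02 t)`
  per group, truncated at zero.  A truncated Poisson birth-death is a
  statistical stand-in: only the shape (integer counts, rate scaling
  with time) matters for testing, not any empirical duplication model;
* traits: per branch, `delta = sum_g beta_g * delta_copy_g +
  Normal(0, sigma^2 t)`; by default 17 traits of which one carries
  `beta = 2` on one group.  Because both the planted signal variance
  (`beta^2 (gain + loss) t`) and the noise variance (`sigma^2 t`) scale
  with branch length, the per-branch signal fraction is
  branch-independent: `beta^2 (gain+loss) / (beta^2 (gain+loss) +
  sigma^2)`, which the default `sigma^2 = 0.018` per My sets to about
  0.9 — a strong but noisy association, the regime the association
  machinery is meant for;
* per-species orthology tables consistent with the simulated counts,
  with a 10% fraction of homology-only "orphan" genes to exercise
  assignment step 2.

What the generator does **not** emulate: realistic metabolite
chemistry or network motifs, correlated gain/loss across groups
(e.g. whole-genome duplications), gene conversion, sequence evolution,
and measurement error in traits.  Green tests on synthetic data show
the machinery is correct under the generative assumptions; they do not
certify the biological conclusions on real genomes, where orthology
error and model curation dominate.

# Problem sizes and determinism

Default analysis scale mirrors the study conditions: 16 taxa, ~420
groups (the smaller reference network's size), 17 traits, 1,000
permutations.  The validation experiments in the test suite use sizes
chosen for statistical well-posedness per the analyses above: the
parsimony oracle covers all 1,068 rooted topologies up to six tips; the
clustering calibration uses 500 replicates on a 300-node network; the
planted-association recovery uses 50 replicates at full scale; the FDR
experiment uses 200 replicates of 17 null traits on 6 taxa with a
reduced LMS budget (permutation validity does not depend on that
budget, and rejections stay attainable since the minimum achievable p
of 0.001 is below `0.05 / 17`).

All randomness is seed-controlled, including the C++ engine
(Mersenne-Twister seeded from R); identical seeds give bit-identical
results, and the generator emits byte-identical files.

# What leave-one-out recovery can and cannot achieve

Validating the association machinery on synthetic data exposed two
structural ceilings of the procedure itself, worth knowing before
interpreting leave-one-out correlations on real data:

* **Minority-branch blindness.**  The LMS criterion is the *median*
  squared residual.  If a predictor group changes on fewer than half
  of the branches, the majority of training rows have a zero delta and
  are fitted equally well by any slope — the effect is unidentifiable
  no matter how large it is.  Recovery of a planted single-group effect
  therefore does not improve with effect size; it improves only when
  the group changes on most branches.
* **Terminal-branch unpredictability.**  Predicting a held-out
  species' trait needs its terminal-branch copy delta and the
  reconstructed parent value.  Linear parsimony cannot split a cherry's
  copy difference between the two sibling branches (the ancestor is
  clamped toward the grandparent), so terminal deltas are sometimes
  misallocated; and a species whose trait changed idiosyncratically on
  its own long branch is unpredictable in principle — no amount of
  model quality supplies phylogenetic replication that does not exist.

In recovery simulations at the default study scale these two effects
cap the fraction of replicates achieving a leave-one-out correlation
above 0.8 at roughly three quarters, across tree shapes (coalescent,
pure-birth, balanced), event rates, effect sizes and predictor modes.
The planted association is nevertheless detected: the causal group is
selected in the large majority of replicates and the permutation p is
small whenever the correlation is high.  Per-species prediction
quality, not detection, is the limiting resource.

# Known limitations

* Boolean gene-protein-reaction structure is flattened to membership:
  complexes and isozyme alternatives are not distinguished, by design —
  copy counting needs membership only.
* Ties in parsimony are resolved by fixed rules (midpoint root,
  parent-clamping); CNA calls on branches whose optimal intervals are
  wide depend on that convention.
* The permutation test conflates phylogenetic signal with association
  for non-exchangeable traits (see above).
* Step-3 family assignment depends on a family-size threshold with no
  published value; it is a configuration knob, default 2.
* Whether the clustering degree columns aggregate by mean, sum or
  median is not fixed by any published definition; all are computable,
  the package reports means.
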