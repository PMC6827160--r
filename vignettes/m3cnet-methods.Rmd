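---
title: "Methods: causal network reconstruction from paired expression and copy-number cohorts"
author: "m3cnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal network reconstruction from paired expression and copy-number cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m3cnet)
```

## The problem

Multiple myeloma cohorts typically ship two molecular layers per patient:
log2 expression microarray/RNA-seq profiles and copy-number log-ratios from
circular binary segmentation (CBS). Three facts shape the analysis:

1. **Copy number drives expression in cis.** A large fraction of genes show
   expression significantly correlated with the copy number of their own
   locus. This is both a nuisance (co-localized genes look co-expressed
   merely because they share a CNV block) and an asset (a gene's cis-CNV is
   a naturally occurring perturbation of that gene).
2. **Sample labels are unreliable.** In multi-omics assemblies a few percent
   of patients carry swapped or mislabeled profiles between layers, which
   silently costs power.
3. **Observational expression data alone cannot orient edges.** The
   structures X→Y and Y→X are Markov equivalent. A cis-CNV node attached to
   one gene breaks the equivalence: p(Y|X, CNVy)·p(X) and p(X|Y, CNVx)·p(Y)
   are different models, so direction becomes identifiable.

m3cnet implements the full path: label QC and correction (`iterate_matching`),
cis association (`cis_test_all`, `conditional_association`), three-state
discretization and Bayesian-network structure search with CNV anchor nodes
(`discretize_matrix`, `learn_consensus`), consensus assembly with weakest-link
loop removal (`consensus`, `remove_loops`), signature projection and
key-regulator discovery (`enrich`, `key_regulators`, `signature_subnetwork`),
and survival risk stratification (`cluster_patients`, `compare_survival`).

## Sample matching

Cis genes are selected by per-gene Spearman correlation between expression
and gene-level CNV (Benjamini–Hochberg FDR < 0.01 by default). Profiles of
the cis genes are rank-transformed per gene, and the similarity
S(i, j) is the correlation between the rank profile of expression sample i
and CNV sample j. A sample is *self-matched* when S(i, i) is maximal in its
row and column and stands more than `z_thresh = 3` standard deviations above
the remaining entries of its row and column. For samples failing that, a
*cross match* (i, j) requires mutual maximality (row and column argmax),
significance of S(i, j), **and** a non-significant self score. The last
condition is not cosmetic: two patients can share nearly identical CNV block
states ("doppelgangers"), and without it the matcher occasionally swaps two
correctly labeled samples — we saw exactly one such false correction per few
hundred samples before adding the condition. Corrections are applied and the
cis set re-estimated until a fixed point (`max_iter` cap, non-convergence
flagged).

The significance rule (z > 3 against the empirical row/column distribution)
is our concrete stand-in for "most significant among all possible
permutations", which the original description leaves unspecified.

Sex (XIST vs RPS4Y1, k-means with k = 3), immunoglobulin isotype (argmax of
marker-set means with a call margin), and hyperdiploidy (median logR > 0.2
on ≥ 2 of chromosomes 3, 5, 7, 9, 11, 15, 19, 21; both values configurable
since the literature method is not fully specified) provide independent
metadata used by `attribute_error_layer` to decide which layer of a
cross-matched pair is mislabeled.

## Network learning

Profiles are discretized to low/normal/high by one-dimensional k-means
(k = 3) with deterministic decile/median/upper-decile initialization;
cutpoints are centroid midpoints. A cluster holding under `min_frac = 5%` of
samples triggers a two-state collapse: small outer clusters are absorbed by
the middle state, a small middle cluster splits to the nearer outer
centroid. This rule is ours; published "biologically meaningful cutoffs" are
not enumerated anywhere.

Candidate parents per gene are pruned by pairwise mutual information
(bottom 20% excluded, optional cap on the top scorers), and each cis gene
additionally receives its CNV node as a candidate parent. CNV nodes have no
candidate parents and may only point at their own gene, so anchors stay
anchors in every sampled structure.

Structures are scored with a decomposable BDeu marginal likelihood
(equivalent sample size κ = 1, three states per node) plus a parent-count
penalty (λ = 1 per parent, `max_parents = 3`). The search is
Metropolis–Hastings over candidate-respecting DAGs — uniform single-edge
add/delete/reverse proposals, acyclicity enforced at proposal time, the
best-visited structure returned — run as many independent seeded chains. The
consensus keeps directed edges whose across-chain frequency strictly exceeds
0.3, then removes directed cycles by repeatedly deleting the
minimum-frequency edge on the first cycle found (deterministic DFS order,
lexicographic tie-breaks). Within-chain averaging vs across-chain frequency
is an open reading of the source method; we use across-chain frequency.
Desk-scale defaults (50 chains, tens of thousands of proposals, ≤ a few
hundred nodes) replace the cluster-scale 1000 chains over ~11k nodes; both
are reachable through configuration.

The pure-R scorer `score_structure` is kept deliberately separate from the
compiled chain so tests can verify the Rcpp scoring against an independent
implementation, and the empty-graph score against a closed form.

## Synthetic cohorts

`simulate_cohort` generates the world the recovery tests assume:

* a DAG over a fixed topological order (upper-triangular adjacency, hence
  acyclic by construction) with signed edges;
* contiguous CNV blocks (default: ~4 adjacent genes per block, emulating
  focal CBS segments) sharing a per-sample loss/neutral/gain state; gene
  logR = state mean (−0.5/0/+0.5) + N(0, 0.1) noise. Block count matters:
  it is the effective dimensionality of the sample-similarity matching, and
  with unrealistically few blocks (say 10 per genome) no method can
  distinguish patients;
* three-state expression propagated through the DAG: a child's target state
  is the sign of the signed sum of parent state deviations **plus the
  cis-CNV term β·(copy state − 1) for cis genes**; the child lands on the
  target with probability 0.85. Continuous expression is the state mean
  (−1/0/+1) + N(0, 0.4). Note the cis term acts upstream of propagation —
  children see the CNV-perturbed state. The alternative (shifting the
  continuous value after propagation) makes the observed expression of an
  anchored gene a collider between its CNV and its latent state, and a
  correct learner then systematically *reverses* the gene's outgoing edges.
  We measured exactly that before settling on the present design;
* a prognostic module: `n_prognostic` genes receive a shared per-sample
  factor (loading 0.6). Prognostic signatures describe co-regulated
  modules; without shared variation the module mean cannot dominate any
  clustering of the signature subspace and stratification would be
  uninformative by construction;
* survival: exponential times with hazard ∝ exp(γ · standardized module
  mean), independent uniform censoring with the horizon solved from
  (1 − e^(−r·c))/(r·c) = target censoring rate — closed-form hazard ratios
  make the coverage tests exact;
* CNV-layer label swaps applied after generation, and signature gene sets
  overlapping the module at a configurable rate.

What the generator does **not** emulate: microarray noise models, probe
effects, translocations/fusions, subclonal copy number, and
microenvironment heterogeneity. A green recovery test therefore establishes
algorithmic correctness under the stated generative model, not performance
on any particular clinical cohort.

## Signature projection and stratification

Enrichment is the one-sided hypergeometric tail P(X ≥ k) with fold
(k/K)/(n/N); the universe defaults to the network's gene-node count.
Key regulators: every node's two-step downstream subnetwork is tested
against the signature, candidates pass BH-adjusted p < 0.05, and selection
is greedy from best p with exclusion of candidates inside an
already-selected regulator's subnetwork (ties: larger overlap, then node
id). Downstream direction is our choice — "regulator" semantics in a causal
DAG — with undirected mode retained as an option.

Risk stratification z-scores the signature genes, k-means the samples
(k = 3, 50 restarts, fixed seed), names groups High/Medium/Low by
*decreasing observed event rate* (the source never defines the mapping from
clusters to risk labels; hazard-ratio tables between named groups imply a
post-hoc ordering), and compares groups by the log-rank test plus pairwise
two-group Cox hazard ratios and Kaplan–Meier curves.

## Numerical and degenerate-input choices

* Correlations: Spearman for cis selection and similarity (robust to the
  heavy-tailed logR scale); conditioning = linear residualization on the
  CNV covariate (partial correlation), with a constant covariate flagged
  and passed through.
* Discretization needs ≥ 3 distinct values; otherwise everything is
  "normal" with a warning. Constant profiles are excluded from correlation
  tests, zero-variance genes from z-scoring.
* Segment→gene mapping: length-weighted mean of overlapping segments
  (1-based inclusive coordinates, strand ignored); how multi-segment genes
  were summarized originally is unstated, so this is our documented choice.
* All stochastic operations take explicit integer seeds; chain r of a
  consensus uses `seed_base + r − 1`.
* k-means clustering that cannot produce k non-empty clusters marks the
  stratification degenerate rather than failing.

## Known limitations

* The MH chain uses fixed-length runs with best-visited selection; no
  convergence diagnostics are computed. For the desk-scale problems in the
  test suite this is adequate (verified by recovery), but larger graphs
  need longer chains and more of them.
* Hypergeometric enrichment treats the network's gene set as the sampling
  universe; a cohort-specific expressed-gene universe can shift p-values.
* Orientation accuracy from anchoring is an average effect (it wins a
  paired comparison across seeds); individual cohorts can tie or lose when
  few anchored edges are recovered.
* The matcher assumes exactly two layers and swap-type errors; contamination
  and partial-identity errors are out of scope.
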