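# m3cnet

Causal gene-network reconstruction and prognostic signature analysis for
paired expression / copy-number cohorts, built around the multiple-myeloma
setting: a few hundred patients, log2 expression profiles, CBS copy-number
segments, published prognostic/treatment signatures, and survival follow-up.

## What it does

Copy-number variation in cis acts as a natural perturbation of a gene: while
the structures X→Y and Y→X are Markov equivalent for observational
expression data, attaching a gene's own CNV as a candidate parent
(`p(Y | X, CNVy)·p(X)` vs `p(X | Y, CNVx)·p(Y)`) breaks the equivalence and
lets a Bayesian network orient edges. The package implements the full
pipeline:

1. **Sample-label QC** (`iterate_matching`) — cis genes (expression ~ own
   CNV, Spearman, BH FDR < 0.01) are rank-transformed; the similarity
   S(i,j) between expression sample i and CNV sample j must be maximal and
   significant (z > 3) on the diagonal; failures are searched for mutually
   maximal cross matches, corrections applied, and the cis set refined to a
   fixed point.
2. **Cis association** (`cis_test_all`, `conditional_association`) —
   per-gene tests plus partial correlation given CNV, separating biological
   regulation from genomic co-localization.
3. **Network learning** (`discretize_matrix`, `learn_consensus`) — 3-state
   discretization (k-means, k = 3), mutual-information candidate pruning
   (bottom 20% dropped), BDeu-scored Metropolis–Hastings structure search
   over candidate-respecting DAGs with CNV anchor nodes, consensus over
   independent chains (edge frequency > 0.3), weakest-link loop removal.
4. **Signature projection** (`enrich`, `key_regulators`,
   `signature_subnetwork`, `chromosome_enrichment`) — one-sided
   hypergeometric enrichment P(X ≥ k) with fold (k/K)/(n/N); greedy
   key-regulator selection over 2-step subnetworks with nested-candidate
   exclusion.
5. **Risk stratification** (`cluster_patients`, `compare_survival`,
   `evaluate_signatures`) — per-gene z-scores, k-means (k = 3) over
   samples, High/Medium/Low by observed event rate, log-rank tests,
   pairwise Cox hazard ratios, Kaplan–Meier curves.
6. **Synthetic cohorts** (`simulate_cohort`) — DAG + CNV-block + swap +
   survival generator with full ground truth, so every stage above has a
   recovery test.

See `vignettes/m3cnet-methods.Rmd` for the model, parameter meanings, and
the design decisions behind the generator.

## Worked example

```r
library(m3cnet)

# default cohort: 600 genes, 200 samples, ~240 cis genes; swap 5% of the
# CNV-layer sample labels
co <- simulate_cohort(sim_config(swap_frac = 0.05, seed = 7))

# 1. label QC: the generator swapped 5 CNV column pairs; find and fix them
rep <- iterate_matching(co$expr, co$cnv, fdr = 0.01)
rep$corrections   # both directions of all 5 planted pairs, nothing else
#>    expr_sample cnv_column
#> 1         s009       s056
#> 2         s018       s068
#> ...
#> 10        s136       s119
rep$cis_counts    # 229 -> 233: corrections recover cis associations

# 2. cis association on the corrected pairing
tab <- cis_test_all(co$expr, rep$corrected_cnv, threshold = 0.01)
sum(tab$is_cis)   # 233 of 604 tested genes are cis-regulated

# 3. consensus network with CNV anchors on a 50-gene cohort
#    (25 chains here; scale runs/iterations as needed)
bn <- simulate_cohort(sim_config(n_genes = 50, n_samples = 300, n_blocks = 12,
                                 edge_density = 0.03, include_markers = FALSE,
                                 n_signatures = 0, module_sd = 0, seed = 11))
de <- discretize_matrix(bn$expr)
dc <- discretize_matrix(bn$cnv[names(bn$truth$cis_genes), ])
ns <- build_node_states(de$states, dc$states, names(bn$truth$cis_genes))
cand <- build_candidates(ns$states, ns$cis_map, max_candidates = 12)
net <- learn_consensus(ns$states, cand, n_runs = 25, n_iter = 30000, seed_base = 1)
nrow(net$edges)   # 50 consensus edges over 70 nodes (genes + CNV anchors);
                  # the 30 gene-gene edges hit the true skeleton at 93% precision

# 4. enrichment arithmetic (hypergeometric tail + fold)
e <- enrich(K = 6, n = 178, k = 1, N = 7920)
round(e$p, 2)     # 0.13 — one of six signature genes landing in a
                  # 178-node subnetwork of a 7920-gene network is chance

# 5. survival stratification on the cohort's prognostic signature
evaluate_signatures(co$expr, co$survival, co$signatures["prognostic_sig"],
                    seed = 1)
#>        signature endpoint   n logrank_p hr_high_low hr_high_med hr_med_low
#> 1 prognostic_sig       OS 200  3.63e-18        5.97        3.39       2.18
```

The log-rank p and hazard ratios say the three k-means groups built from the
planted prognostic module separate survival sharply (high- vs low-risk
hazard ratio ≈ 6 at the generator's γ = 1), which is what the module was
constructed to do; the matcher output lists exactly the planted swaps, and
the cis-association count rises after correction, the direction label
errors are expected to bias.

## Command line

```sh
inst/cli/m3cnet simulate --outdir run/ --seed 1
inst/cli/m3cnet match    --expr run/expression.tsv --cnv run/cnv.tsv --report run/match.json
inst/cli/m3cnet cis      --expr run/expression.tsv --cnv run/cnv.tsv --out run/cis.tsv
inst/cli/m3cnet learn    --expr run/expression.tsv --cnv run/cnv.tsv --cis run/cis.tsv \
                         --runs 50 --iters 20000 --out run/net.tsv --sif run/net.sif
inst/cli/m3cnet keyreg   --net run/net.tsv --gmt run/signatures.gmt --out run/kr.json
inst/cli/m3cnet stratify --expr run/expression.tsv --surv run/survival.tsv \
                         --gmt run/signatures.gmt --out run/strat.tsv
inst/cli/m3cnet run-all  --config cfg.yaml
```

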