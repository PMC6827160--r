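# m3cnet pipeline configuration template
# Thresholds default to the cohort-scale analysis values; learner settings
# are desk-scale (raise n_runs/n_iter for cluster-scale runs).

outdir: m3cn_run
seed: 1

stages:
  simulate: true      # generate a synthetic cohort; disable to use inputs
  match: true         # cross-layer sample-label correction
  cis: true           # cis-CNV association table
  learn: true         # discretize + MCMC consensus network
  keyreg: true        # key regulators per signature
  subnet: true        # largest connected signature subnetworks
  stratify: true      # k-means risk groups + survival comparison

inputs:               # used when simulate: false (paths to standard formats)
  expr: null          # gene x sample TSV, log2 expression
  cnv: null           # gene x sample TSV, gene-level logR
  annotation: null    # gene, chrom, start, end, strand TSV
  survival: null      # sample_id, time, event, endpoint TSV
  signatures: null    # GMT

simulate:
  n_genes: 60
  n_samples: 150
  frac_cis: 0.4       # fraction of genes cis-regulated by copy number
  swap_frac: 0.04     # fraction of samples with swapped CNV labels
  n_signatures: 3

match:
  fdr: 0.01           # BH threshold for cis-gene selection
  max_iter: 10
  z_thresh: 3         # similarity significance margin (SD units)

cis:
  fdr: 0.01           # BH threshold for the cis-association table

learn:
  informative_mean: -.inf   # mean-expression filter; 4.8 on log2 microarray scale
  informative_var: 0.05     # variance filter; 0.4 on log2 microarray scale
  exclude_frac: 0.2         # bottom-MI fraction excluded as candidate parents
  max_candidates: 15
  n_runs: 20                # independent MCMC chains (cluster scale: 1000)
  n_iter: 10000             # proposals per chain
  threshold: 0.3            # consensus edge-frequency cutoff (strict >)
  max_parents: 3
  kappa: 1                  # BDeu equivalent sample size
  lambda: 1                 # log-prior penalty per parent

keyreg:
  l: 2                # subnetwork radius for regulator search
  alpha: 0.05         # BH-adjusted candidate threshold

subnet:
  l: 1                # expansion radius before taking the largest component

stratify:
  k: 3                # risk groups
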