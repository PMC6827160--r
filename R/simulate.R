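## Synthetic-cohort generator: a sparse causal DAG over genes, block-structured
## copy number with cis effects, planted sample swaps between layers, a
## prognostic module driving proportional-hazards survival, and signature sets
## overlapping that module. Every stochastic step runs inside a local RNG
## scope seeded from cfg$seed.

#' Simulation configuration
#'
#' Defaults describe the cohort used throughout the recovery tests:
#' 600 genes, 200 samples, sparse DAG (expected ~0.9 parents/node), 40%
#' cis-regulated genes with copy-number effect `beta = 1`, 150 CNV blocks
#' (about four adjacent genes sharing a copy state, emulating focal CBS
#' segments; the resulting ~240 cis genes keep sample-similarity matching in
#' the operating regime the method assumes, where cis genes far outnumber
#' samples), a 20-gene co-regulated prognostic module, three-state
#' expression emission at means (-1, 0, +1) with SD 0.4, exponential
#' survival with log-hazard coefficient `gamma = 1` and ~30% uniform
#' censoring. Swaps are off by default (`swap_frac = 0`).
#'
#' @param n_genes,n_samples cohort dimensions.
#' @param edge_density probability an earlier gene (in the fixed topological
#'   order) is a parent of a later one.
#' @param frac_cis fraction of genes whose expression is shifted by their own
#'   copy number.
#' @param beta cis effect size: expression shift per copy state unit.
#' @param n_blocks number of contiguous CNV blocks sharing a copy state.
#' @param state_means,state_sd emission means (low/normal/high) and SD of
#'   continuous expression around the state mean.
#' @param cnv_means,cnv_sd per-state copy-number logR means and noise SD.
#' @param cnv_probs probabilities of loss/neutral/gain per block and sample.
#' @param cpt_strength probability a child lands in the state dictated by its
#'   parents (remainder split over the other two states).
#' @param swap_frac fraction of samples involved in CNV-layer label swaps.
#' @param n_prognostic size of the prognostic module (genes drawn from the
#'   DAG) whose mean expression drives the hazard.
#' @param module_sd loading of the shared per-sample factor added to the
#'   prognostic module genes. Prognostic signatures describe co-regulated
#'   modules; without shared variation the module mean cannot dominate any
#'   clustering of the signature subspace. Set 0 to disable.
#' @param gamma log hazard ratio per SD of the prognostic module score.
#' @param censor_rate target fraction of censored samples.
#' @param k_risk number of risk groups the cohort is meant to stratify into.
#' @param n_signatures,sig_size,sig_overlap signature sets sampled from the
#'   gene universe; the first one overlaps the prognostic module at rate
#'   `sig_overlap`.
#' @param include_markers add sex (XIST/RPS4Y1) and immunoglobulin isotype
#'   marker genes outside the DAG.
#' @param max_parents parent cap implied by the density check.
#' @param seed integer seed; same seed gives bit-identical cohorts.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 600L, n_samples = 200L, edge_density = 0.003,
                       frac_cis = 0.4, beta = 1.0, n_blocks = 150L,
                       state_means = c(-1, 0, 1), state_sd = 0.4,
                       cnv_means = c(-0.5, 0, 0.5), cnv_sd = 0.1,
                       cnv_probs = c(0.25, 0.5, 0.25), cpt_strength = 0.85,
                       swap_frac = 0, n_prognostic = 20L, module_sd = 0.6,
                       gamma = 1.0,
                       censor_rate = 0.3, k_risk = 3L,
                       n_signatures = 5L, sig_size = 20L, sig_overlap = 0.8,
                       include_markers = TRUE, max_parents = NULL, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              edge_density = edge_density, frac_cis = frac_cis, beta = beta,
              n_blocks = as.integer(n_blocks), state_means = state_means,
              state_sd = state_sd, cnv_means = cnv_means, cnv_sd = cnv_sd,
              cnv_probs = cnv_probs / sum(cnv_probs),
              cpt_strength = cpt_strength, swap_frac = swap_frac,
              n_prognostic = as.integer(n_prognostic), module_sd = module_sd,
              gamma = gamma,
              censor_rate = censor_rate, k_risk = as.integer(k_risk),
              n_signatures = as.integer(n_signatures),
              sig_size = as.integer(sig_size), sig_overlap = sig_overlap,
              include_markers = isTRUE(include_markers),
              max_parents = max_parents, seed = as.integer(seed))
  stopifnot(cfg$n_genes > 0L, cfg$n_samples > 0L, cfg$n_blocks > 0L)
  if (cfg$edge_density < 0 || cfg$edge_density > 1)
    .stopf("edge_density must lie in [0,1]")
  if (cfg$edge_density * (cfg$n_genes - 1L) > cfg$n_genes - 1L)
    .stopf("edge density implies more than n_genes - 1 parents")
  for (f in c("frac_cis", "swap_frac", "censor_rate", "sig_overlap", "cpt_strength"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) .stopf("%s must lie in [0,1]", f)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a paired expression/CNV cohort with known ground truth
#'
#' Generation order: (1) a DAG sampled over a fixed topological order
#' (upper-triangular adjacency, hence acyclic by construction) with signed
#' edges; (2) per-sample discrete copy states drawn per contiguous CNV block,
#' gene logR = state mean + noise; (3) each gene's three-state expression
#' drawn from a conditional table given its parents' states, cis genes
#' additionally shifted on the continuous scale by `beta * (copy state - 1)`;
#' (4) exponential survival with hazard proportional to
#' `exp(gamma * standardized prognostic-module score)` and independent
#' uniform censoring; (5) label swaps applied to the CNV layer.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `expr`, `cnv` (gene x sample matrices),
#'   `annotation`, `survival`, `signatures`, and `truth` (the ground-truth
#'   record: `true_dag`, `edge_sign`, `expr_states`, `cis_genes` with betas,
#'   `cnv_blocks`, `cnv_states`, `swap_pairs`, `prognostic_genes`, `risk`,
#'   `sex`, `isotype`, `gamma`, `seed`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes; N <- cfg$n_samples
  genes <- sprintf("g%03d", seq_len(G))
  samples <- sprintf("s%03d", seq_len(N))

  ## (1) DAG over fixed topological order
  max_pa <- cfg$max_parents %||% (G - 1L)
  from <- integer(0); to <- integer(0)
  for (j in seq_len(G)[-1L]) {
    pa <- which(runif(j - 1L) < cfg$edge_density)
    if (length(pa) > max_pa) pa <- sort(sample(pa, max_pa))
    from <- c(from, pa); to <- c(to, rep.int(j, length(pa)))
  }
  edge_sign <- if (length(from)) sample(c(-1, 1), length(from), replace = TRUE) else numeric(0)
  true_dag <- data.frame(from = genes[from], to = genes[to],
                         stringsAsFactors = FALSE)

  ## (2) CNV blocks and copy states
  n_blocks <- min(cfg$n_blocks, G)
  block_of <- sort(rep_len(seq_len(n_blocks), G))
  cnv_states <- matrix(1L, G, N)  # 0 loss / 1 neutral / 2 gain
  for (b in seq_len(n_blocks)) {
    st <- sample(0:2, N, replace = TRUE, prob = cfg$cnv_probs)
    cnv_states[block_of == b, ] <- matrix(st, sum(block_of == b), N, byrow = TRUE)
  }
  cnv <- matrix(cfg$cnv_means[cnv_states + 1L], G, N) +
    matrix(rnorm(G * N, 0, cfg$cnv_sd), G, N)
  dimnames(cnv) <- list(genes, samples)

  n_cis <- round(cfg$frac_cis * G)
  cis_idx <- if (n_cis > 0L) sort(sample.int(G, n_cis)) else integer(0)
  cis_genes <- setNames(rep(cfg$beta, length(cis_idx)), genes[cis_idx])

  ## (3) expression states from parent conditional tables. The cis-CNV term
  ## enters the state-generating score, upstream of propagation: children of
  ## a cis gene see its CNV-perturbed state, which is what lets an anchor
  ## orient edges (Y responds to X and CNVy jointly; targets of Y respond to
  ## the resulting Y). A post-hoc shift of the continuous value would instead
  ## turn the observation into a collider leaf and invert orientations.
  q <- cfg$cpt_strength
  states <- matrix(1L, G, N)
  parents_of <- split(from, factor(to, levels = seq_len(G)))
  signs_of <- split(edge_sign, factor(to, levels = seq_len(G)))
  root_probs <- c(0.3, 0.4, 0.3)
  is_cis <- logical(G); is_cis[cis_idx] <- TRUE
  for (j in seq_len(G)) {
    pa <- parents_of[[j]]
    sc <- rep(0, N)
    if (length(pa))
      sc <- sc + colSums(matrix(signs_of[[j]] * (states[pa, , drop = FALSE] - 1L),
                                nrow = length(pa)))
    if (is_cis[j]) sc <- sc + cfg$beta * (cnv_states[j, ] - 1L)
    if (length(pa) == 0L && !is_cis[j]) {
      states[j, ] <- sample(0:2, N, replace = TRUE, prob = root_probs)
    } else {
      target <- 1L + sign(sc)
      u <- runif(N); v <- runif(N)
      st <- target
      miss <- u > q
      ## off-target draws land uniformly on the two remaining states
      if (any(miss)) {
        o1 <- ifelse(target[miss] == 0L, 1L, 0L)
        o2 <- ifelse(target[miss] == 2L, 1L, 2L)
        st[miss] <- ifelse(v[miss] > 0.5, o2, o1)
      }
      states[j, ] <- st
    }
  }
  expr <- matrix(cfg$state_means[states + 1L], G, N) +
    matrix(rnorm(G * N, 0, cfg$state_sd), G, N)
  dimnames(expr) <- list(genes, samples)

  ## planted metadata marker genes (outside the DAG)
  sex <- isotype <- NULL
  if (cfg$include_markers) {
    sex <- sample(c("Female", "Male"), N, replace = TRUE)
    isotype <- sample(c("IgG", "IgA"), N, replace = TRUE)
    xist <- ifelse(sex == "Female", 3, 0) + rnorm(N, 0, 0.5)
    rps4y1 <- ifelse(sex == "Male", 3, 0) + rnorm(N, 0, 0.5)
    ighg1 <- ifelse(isotype == "IgG", 3, 0) + rnorm(N, 0, 0.5)
    igha1 <- ifelse(isotype == "IgA", 3, 0) + rnorm(N, 0, 0.5)
    mk <- rbind(XIST = xist, RPS4Y1 = rps4y1, IGHG1 = ighg1, IGHA1 = igha1)
    colnames(mk) <- samples
    expr <- rbind(expr, mk)
    mk_cnv <- matrix(rnorm(4L * N, 0, cfg$cnv_sd), 4L, N,
                     dimnames = list(rownames(mk), samples))
    cnv <- rbind(cnv, mk_cnv)
    sex <- setNames(sex, samples); isotype <- setNames(isotype, samples)
  }

  ## annotation: genes laid out consecutively, one chromosome per block
  all_genes <- rownames(expr)
  chrom <- c(as.character(block_of), rep("M", length(all_genes) - G))
  pos <- stats::ave(seq_along(all_genes), chrom, FUN = seq_along)
  ann <- data.frame(gene_id = all_genes, chrom = chrom,
                    start = (pos - 1L) * 10000L + 1L, end = pos * 10000L - 1000L,
                    strand = "+", stringsAsFactors = FALSE)

  ## (4) survival: prognostic module = co-regulated gene set (shared factor)
  ## whose standardized mean expression sets the hazard
  n_prog <- min(cfg$n_prognostic, G)
  prog_idx <- sort(sample.int(G, n_prog))
  prog_genes <- genes[prog_idx]
  if (cfg$module_sd > 0 && n_prog > 0L) {
    module_factor <- rnorm(N)
    expr[prog_idx, ] <- expr[prog_idx, ] +
      cfg$module_sd * matrix(module_factor, n_prog, N, byrow = TRUE)
  }
  score <- colMeans(expr[prog_genes, , drop = FALSE])
  risk <- as.numeric(scale(score))
  base_rate <- log(2) / 365
  times <- rexp(N, rate = base_rate * exp(cfg$gamma * risk))
  ctimes <- if (cfg$censor_rate > 0)
    runif(N, 0, .censor_horizon(base_rate, cfg$censor_rate))
  else rep(Inf, N)
  obs_time <- pmax(pmin(times, ctimes), 1e-3)
  event <- as.integer(times <= ctimes)
  surv <- data.frame(sample_id = samples, time = obs_time, event = event,
                     endpoint = "OS", stringsAsFactors = FALSE)

  ## (5) CNV-layer label swaps
  n_sw <- floor(round(cfg$swap_frac * N) / 2)
  swap_pairs <- NULL
  if (n_sw > 0L) {
    picked <- sample(samples, 2L * n_sw)
    swap_pairs <- cbind(picked[seq_len(n_sw)], picked[n_sw + seq_len(n_sw)])
    cnv <- inject_swaps(cnv, swap_pairs)
  }

  ## signatures
  sigs <- list()
  if (cfg$n_signatures > 0L) {
    sz <- min(cfg$sig_size, G)
    k_ov <- round(cfg$sig_overlap * min(sz, n_prog))
    pool <- setdiff(genes, prog_genes)
    n_fill <- min(max(sz - k_ov, 0L), length(pool))
    s1 <- c(sample(prog_genes, k_ov), sample(pool, n_fill))
    sigs[["prognostic_sig"]] <- sort(s1)
    for (i in seq_len(cfg$n_signatures - 1L))
      sigs[[sprintf("random_sig_%02d", i)]] <- sort(sample(genes, sz))
  }

  truth <- list(true_dag = true_dag, edge_sign = edge_sign,
                expr_states = states, cis_genes = cis_genes,
                cnv_blocks = setNames(block_of, genes),
                cnv_states = cnv_states, swap_pairs = swap_pairs,
                prognostic_genes = prog_genes, risk = risk,
                sex = sex, isotype = isotype,
                gamma = cfg$gamma, seed = cfg$seed)
  list(expr = expr, cnv = cnv, annotation = ann, survival = surv,
       signatures = sigs, truth = truth, config = cfg)
}

## horizon of the uniform censoring window solving
## P(C < T) = censor_rate for T ~ Exp(rate), C ~ U(0, cmax)
.censor_horizon <- function(rate, censor_rate) {
  if (censor_rate <= 0) return(Inf)
  f <- function(cm) (1 - exp(-rate * cm)) / (rate * cm) - censor_rate
  stats::uniroot(f, c(1e-6 / rate, 1e5 / rate))$root
}

#' Swap sample columns of a CNV matrix
#'
#' Models CNV-layer labeling errors: each pair's columns are exchanged.
#' Applying the same pairs twice restores the original matrix.
#'
#' @param cnv gene x sample matrix.
#' @param pairs 2-column matrix (or list of length-2 vectors) of sample ids.
#' @return the matrix with columns exchanged.
#' @export
inject_swaps <- function(cnv, pairs) {
  if (is.null(pairs) || NROW(pairs) == 0L) return(cnv)
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  ids <- as.vector(pairs)
  if (!all(ids %in% colnames(cnv)))
    .stopf("unknown sample(s) in swap pairs: %s",
           paste(setdiff(ids, colnames(cnv)), collapse = ", "))
  if (anyDuplicated(ids)) .stopf("swap pairs must be disjoint")
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    tmp <- cnv[, i]; cnv[, i] <- cnv[, j]; cnv[, j] <- tmp
  }
  cnv
}

#' Write a simulated cohort to a directory in standard formats
#' @param cohort output of [simulate_cohort()].
#' @param outdir directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expr, file.path(outdir, "expression.tsv"))
  write_expression(cohort$cnv, file.path(outdir, "cnv.tsv"))
  write_annotation(cohort$annotation, file.path(outdir, "annotation.tsv"))
  write_survival(cohort$survival, file.path(outdir, "survival.tsv"))
  if (length(cohort$signatures))
    write_gmt(cohort$signatures, file.path(outdir, "signatures.gmt"))
  tr <- cohort$truth
  tr$expr_states <- NULL; tr$cnv_states <- NULL  # bulky; regenerable from seed
  jsonlite::write_json(tr, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
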