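## End-to-end orchestration from a single config (YAML or list): simulate or
## load inputs, correct sample labels, select cis genes, learn the consensus
## network, project signatures, and stratify survival. Every stage writes
## standard-format files into the run directory and is recorded (parameters,
## seeds, file hashes) in manifest.json.

#' Default pipeline configuration
#'
#' Thresholds default to the cohort-scale analysis values: cis FDR 0.01,
#' informative-gene mean > 4.8 and variance > 0.4, consensus threshold 0.3,
#' subnetwork radius l = 2, k = 3 risk groups. Desk-scale learner settings
#' (50 chains) stand in for the cluster-scale 1000.
#'
#' @param outdir run directory.
#' @param seed master seed.
#' @return nested config list.
#' @export
default_pipeline_config <- function(outdir = tempfile("m3cn_run_"), seed = 1L) {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    stages = list(simulate = TRUE, match = TRUE, cis = TRUE, learn = TRUE,
                  keyreg = TRUE, subnet = TRUE, stratify = TRUE),
    inputs = list(expr = NULL, cnv = NULL, annotation = NULL, survival = NULL,
                  signatures = NULL),
    simulate = list(n_genes = 60L, n_samples = 150L, frac_cis = 0.4,
                    swap_frac = 0.04, n_signatures = 3L),
    match = list(fdr = 0.01, max_iter = 10L, z_thresh = 3),
    cis = list(fdr = 0.01),
    learn = list(informative_mean = -Inf, informative_var = 0.05,
                 exclude_frac = 0.2, max_candidates = 15L, n_runs = 20L,
                 n_iter = 10000L, threshold = 0.3, max_parents = 3L,
                 kappa = 1, lambda = 1),
    keyreg = list(l = 2L, alpha = 0.05),
    subnet = list(l = 1L),
    stratify = list(k = 3L)
  )
}

.read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  utils::modifyList(base, config)
}

#' Run the full pipeline
#'
#' Stages execute in dependency order; a disabled upstream stage requires the
#' corresponding inputs on disk, checked before any computation. Outputs are
#' written under `cfg$outdir`; `manifest.json` records parameters, seeds,
#' package version, and md5 hashes of every artifact. Re-running the same
#' config reproduces identical artifacts.
#'
#' @param config config list or YAML path; see [default_pipeline_config()].
#' @return manifest list, invisibly; artifacts under `cfg$outdir`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  cfg <- .read_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  st <- cfg$stages
  ## dependency check before any computation
  if (!isTRUE(st$simulate)) {
    needed <- c("expr", "cnv")
    if (isTRUE(st$stratify)) needed <- c(needed, "survival", "signatures")
    miss <- needed[vapply(needed, function(f)
      is.null(cfg$inputs[[f]]) || !file.exists(cfg$inputs[[f]]), logical(1))]
    if (length(miss))
      .stopf("stage dependency missing: simulate disabled but no input for %s",
             paste(miss, collapse = ", "))
  }
  manifest <- list(package = "m3cnet",
                   version = as.character(utils::packageVersion("m3cnet")),
                   seed = cfg$seed, parameters = cfg[setdiff(names(cfg),
                                                             c("outdir"))],
                   stages_run = character(0), artifacts = list())
  art <- function(path) {
    manifest$artifacts[[basename(path)]] <<-
      unname(tools::md5sum(path))
    path
  }

  if (isTRUE(st$simulate)) {
    sim_args <- cfg$simulate; sim_args$seed <- cfg$seed
    cohort <- simulate_cohort(do.call(sim_config, sim_args))
    write_cohort(cohort, cfg$outdir)
    for (f in c("expression.tsv", "cnv.tsv", "annotation.tsv", "survival.tsv",
                "signatures.gmt", "truth.json"))
      if (file.exists(file.path(cfg$outdir, f))) art(file.path(cfg$outdir, f))
    expr <- cohort$expr; cnv <- cohort$cnv
    surv <- cohort$survival; sigs <- cohort$signatures
    manifest$stages_run <- c(manifest$stages_run, "simulate")
  } else {
    expr <- read_expression(cfg$inputs$expr)
    cnv <- read_expression(cfg$inputs$cnv)
    surv <- if (!is.null(cfg$inputs$survival)) read_survival(cfg$inputs$survival)
    sigs <- if (!is.null(cfg$inputs$signatures)) read_gmt(cfg$inputs$signatures)
  }

  if (isTRUE(st$match)) {
    rep <- iterate_matching(expr, cnv, fdr = cfg$match$fdr,
                            max_iter = cfg$match$max_iter,
                            z_thresh = cfg$match$z_thresh)
    cnv <- rep$corrected_cnv
    jsonlite::write_json(
      list(self_matched = rep$self_matched, cross_matched = rep$cross_matched,
           unmatched = rep$unmatched, pairing = as.list(rep$pairing),
           cis_counts = rep$cis_counts, n_iter = rep$n_iter,
           converged = rep$converged),
      art_path <- file.path(cfg$outdir, "match_report.json"),
      auto_unbox = TRUE, digits = NA)
    art(art_path)
    manifest$stages_run <- c(manifest$stages_run, "match")
  }

  cis_tab <- NULL
  if (isTRUE(st$cis)) {
    cis_tab <- cis_test_all(expr, cnv, threshold = cfg$cis$fdr)
    write.table(cis_tab, cis_path <- file.path(cfg$outdir, "cis_associations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    art(cis_path)
    manifest$stages_run <- c(manifest$stages_run, "cis")
  }

  net <- NULL
  if (isTRUE(st$learn)) {
    lp <- cfg$learn
    genes <- tryCatch(select_informative_genes(expr, lp$informative_mean,
                                               lp$informative_var),
                      error = function(e) rownames(expr))
    cis_genes <- if (!is.null(cis_tab)) {
      intersect(cis_tab$gene_id[cis_tab$is_cis], genes)
    } else character(0)
    de <- discretize_matrix(expr[genes, , drop = FALSE])
    dc <- if (length(cis_genes))
      discretize_matrix(cnv[cis_genes, colnames(expr), drop = FALSE])
    ns <- build_node_states(de$states,
                            cnv_states = if (length(cis_genes)) dc$states,
                            cis_genes = cis_genes)
    cand <- build_candidates(ns$states, ns$cis_map,
                             exclude_frac = lp$exclude_frac,
                             max_candidates = lp$max_candidates)
    net <- learn_consensus(ns$states, cand, n_runs = lp$n_runs,
                           n_iter = lp$n_iter, seed_base = cfg$seed,
                           threshold = lp$threshold,
                           max_parents = lp$max_parents,
                           kappa = lp$kappa, lambda = lp$lambda)
    write_network(net, sif_path = art_sif <- file.path(cfg$outdir, "network.sif"),
                  tsv_path = art_tsv <- file.path(cfg$outdir, "network.tsv"))
    art(art_sif); art(art_tsv)
    manifest$stages_run <- c(manifest$stages_run, "learn")
  }

  if (isTRUE(st$keyreg) && !is.null(net) && length(sigs)) {
    ## key regulators act on the gene-gene part of the network
    gene_net <- drop_cnv_nodes(net)
    kr <- lapply(sigs, function(s)
      key_regulators(gene_net, s, l = cfg$keyreg$l, alpha = cfg$keyreg$alpha))
    jsonlite::write_json(
      lapply(kr, function(x) list(
        selected = x$regulators$node[x$regulators$selected],
        candidates = x$regulators)),
      art_kr <- file.path(cfg$outdir, "key_regulators.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    art(art_kr)
    manifest$stages_run <- c(manifest$stages_run, "keyreg")

    if (isTRUE(st$subnet)) {
      sn <- lapply(sigs, function(s)
        signature_subnetwork(gene_net, s, l = cfg$subnet$l))
      jsonlite::write_json(
        lapply(sn, function(x) list(nodes = x$nodes,
                                    n_edges = nrow(x$edges),
                                    p = x$enrichment$p %||% NA)),
        art_sn <- file.path(cfg$outdir, "signature_subnetworks.json"),
        auto_unbox = TRUE, digits = NA)
      art(art_sn)
      manifest$stages_run <- c(manifest$stages_run, "subnet")
    }
  }

  if (isTRUE(st$stratify) && length(sigs) && !is.null(surv)) {
    tab <- evaluate_signatures(expr, surv, sigs, k = cfg$stratify$k,
                               seed = cfg$seed)
    write.table(tab, art_tab <- file.path(cfg$outdir, "stratification.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    art(art_tab)
    manifest$stages_run <- c(manifest$stages_run, "stratify")
  }

  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Drop CNV anchor nodes from a consensus network
#'
#' Keeps gene nodes and gene-gene edges only (CNV nodes are anchors, not
#' regulators, for downstream network analysis).
#'
#' @param net `consensus_network`.
#' @param prefix CNV node name prefix.
#' @return `consensus_network` over gene nodes.
#' @export
drop_cnv_nodes <- function(net, prefix = "CNV:") {
  is_cnv_node <- startsWith(net$nodes, prefix)
  e <- net$edges[!startsWith(net$edges$from, prefix) &
                   !startsWith(net$edges$to, prefix), , drop = FALSE]
  rownames(e) <- NULL
  new_consensus_network(e, net$threshold, net$n_runs,
                        nodes = net$nodes[!is_cnv_node])
}
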