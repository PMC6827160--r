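## Structure learning around the compiled MCMC chain: candidate-parent
## construction with mutual-information pruning and cis-CNV anchor nodes, a
## pure-R reference BDeu scorer (used as the oracle route in tests), consensus
## assembly over independent chains, and deterministic weakest-link loop
## removal.

#' Assemble the node state matrix for structure learning
#'
#' Stacks discretized gene states and, when a cis map is given, the
#' discretized copy-number states of the anchored genes as extra nodes named
#' `CNV:<gene>`.
#'
#' @param gene_states integer matrix (genes x samples, states 0..2).
#' @param cnv_states optional integer matrix aligned to the same samples.
#' @param cis_genes genes whose CNV becomes an anchor node.
#' @return list with `states` (node x sample matrix) and `cis_map` (named
#'   vector gene -> CNV node).
#' @export
build_node_states <- function(gene_states, cnv_states = NULL, cis_genes = NULL) {
  cis_map <- NULL
  states <- gene_states
  if (!is.null(cnv_states) && length(cis_genes)) {
    cis_genes <- intersect(cis_genes, rownames(gene_states))
    cis_genes <- intersect(cis_genes, rownames(cnv_states))
    anchor <- cnv_states[cis_genes, colnames(gene_states), drop = FALSE]
    rownames(anchor) <- paste0("CNV:", cis_genes)
    states <- rbind(gene_states, anchor)
    cis_map <- setNames(rownames(anchor), cis_genes)
  }
  list(states = states, cis_map = cis_map)
}

#' Candidate parent sets with mutual-information pruning
#'
#' For every gene node, the other gene nodes are ranked by pairwise mutual
#' information; the bottom `exclude_frac` are excluded as candidate
#' regulators, and the list is optionally capped at the `max_candidates` top
#' scorers. A gene's cis-CNV anchor node (if any) is always a candidate.
#' CNV nodes have no candidate parents, so they can never acquire parents
#' and can only ever point at their own gene.
#'
#' @param states node x sample state matrix from [build_node_states()].
#' @param cis_map named vector gene -> CNV node (or NULL).
#' @param exclude_frac fraction of lowest-MI genes dropped (default 0.2).
#' @param max_candidates optional cap on gene candidates per node.
#' @return named list: per node, character vector of allowed parents.
#' @export
build_candidates <- function(states, cis_map = NULL, exclude_frac = 0.2,
                             max_candidates = NULL) {
  stopifnot(exclude_frac >= 0, exclude_frac < 1)
  nodes <- rownames(states)
  gene_nodes <- setdiff(nodes, unname(cis_map))
  M <- .mi_matrix(states[gene_nodes, , drop = FALSE])
  cand <- setNames(vector("list", length(nodes)), nodes)
  for (g in gene_nodes) {
    mi <- M[g, setdiff(gene_nodes, g)]
    keep <- names(mi)
    if (exclude_frac > 0 && length(mi) > 0L) {
      n_drop <- floor(exclude_frac * length(mi))
      if (n_drop > 0L)
        keep <- names(sort(mi, decreasing = TRUE))[seq_len(length(mi) - n_drop)]
    }
    if (!is.null(max_candidates) && length(keep) > max_candidates) {
      keep <- names(sort(mi[keep], decreasing = TRUE))[seq_len(max_candidates)]
    }
    if (!is.null(cis_map) && g %in% names(cis_map))
      keep <- c(keep, unname(cis_map[[g]]))
    cand[[g]] <- keep
  }
  for (cn in unname(cis_map)) cand[[cn]] <- character(0)
  attr(cand, "mi") <- M
  cand
}

## reference BDeu family score (pure R; oracle route for the compiled scorer)
.family_score_r <- function(states, child, parents, kappa = 1, lambda = 1) {
  np <- length(parents)
  q <- 3L^np
  child_s <- states[child, ]
  idx <- rep(0L, ncol(states))
  for (p in parents) idx <- idx * 3L + states[p, ]
  a_j <- kappa / q; a_jk <- kappa / (q * 3)
  sc <- -lambda * np
  tab <- table(factor(idx, levels = 0:(q - 1L)), factor(child_s, levels = 0:2))
  nj <- rowSums(tab)
  for (j in which(nj > 0)) {
    sc <- sc + lgamma(a_j) - lgamma(a_j + nj[j])
    cj <- tab[j, ]
    sc <- sc + sum(lgamma(a_jk + cj[cj > 0]) - lgamma(a_jk))
  }
  unname(sc)
}

#' Log score of a DAG structure (BDeu + parent-count prior)
#'
#' Decomposable score: the sum over nodes of the BDeu marginal likelihood of
#' the node given its parents (equivalent sample size `kappa`) minus
#' `lambda` per parent. This is the pure-R reference implementation; the
#' MCMC chain uses an equivalent compiled scorer.
#'
#' @param edges data.frame with columns from, to (node names), or NULL/empty
#'   for the empty graph.
#' @param states node x sample state matrix.
#' @param kappa BDeu equivalent sample size (default 1).
#' @param lambda parent-count penalty (default 1).
#' @return log score (scalar).
#' @export
score_structure <- function(edges, states, kappa = 1, lambda = 1) {
  nodes <- rownames(states)
  pa <- setNames(vector("list", length(nodes)), nodes)
  if (!is.null(edges) && nrow(edges)) {
    stopifnot(all(edges$from %in% nodes), all(edges$to %in% nodes))
    for (r in seq_len(nrow(edges)))
      pa[[edges$to[r]]] <- c(pa[[edges$to[r]]], edges$from[r])
  }
  sum(vapply(nodes, function(v)
    .family_score_r(states, v, pa[[v]] %||% character(0), kappa, lambda),
    numeric(1)))
}

#' One MCMC structure-search chain
#'
#' Metropolis-Hastings over candidate-respecting DAGs: proposals add, delete,
#' or reverse a single edge chosen uniformly; acyclicity and the parent cap
#' are enforced at proposal time; the best-scoring visited structure is
#' returned. Fully deterministic given `seed`.
#'
#' @param states node x sample state matrix (no NAs).
#' @param candidates candidate list from [build_candidates()].
#' @param seed chain seed.
#' @param n_iter proposals per chain (default 20000).
#' @param max_parents parent cap (default 3).
#' @param kappa,lambda score parameters.
#' @param anneal_from starting inverse temperature (< 1 ramps to 1 over the
#'   chain; default 1 = plain MH).
#' @return `dag_sample`: list with `edges` (data.frame from/to), `log_score`,
#'   `seed`, `accepted`.
#' @export
mcmc_search <- function(states, candidates, seed, n_iter = 20000L,
                        max_parents = 3L, kappa = 1, lambda = 1,
                        anneal_from = 1) {
  stopifnot(n_iter >= 1L)
  if (anyNA(states)) .stopf("state matrix contains NAs; complete-case first")
  nodes <- rownames(states)
  cand_idx <- lapply(nodes, function(v) match(candidates[[v]] %||% character(0), nodes))
  res <- .mcmc_chain(states, cand_idx, as.integer(seed), as.integer(n_iter),
                     as.integer(max_parents), kappa, lambda, anneal_from)
  e <- res$edges
  edges <- data.frame(from = nodes[e[, 1L]], to = nodes[e[, 2L]],
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, log_score = res$log_score, seed = seed,
                 accepted = res$accepted, n_iter = n_iter),
            class = "dag_sample")
}

new_consensus_network <- function(edges, threshold, n_runs, nodes = NULL) {
  nodes <- nodes %||% sort(unique(c(edges$from, edges$to)))
  structure(list(edges = edges, nodes = nodes, threshold = threshold,
                 n_runs = n_runs), class = "consensus_network")
}

#' Consensus network over independent structure samples
#'
#' The frequency of a directed edge is the fraction of structures containing
#' it; edges with frequency strictly greater than `threshold` are kept and
#' remaining directed cycles are removed by [remove_loops()].
#'
#' @param dag_samples list of `dag_sample` objects.
#' @param threshold posterior-frequency cutoff (default 0.3, strict >).
#' @param nodes node universe (defaults to the union over samples).
#' @return `consensus_network` with edges (from, to, frequency).
#' @export
consensus <- function(dag_samples, threshold = 0.3, nodes = NULL) {
  stopifnot(length(dag_samples) >= 1L)
  n <- length(dag_samples)
  keys <- unlist(lapply(dag_samples, function(s)
    if (nrow(s$edges)) paste(s$edges$from, s$edges$to, sep = "\r") else character(0)))
  if (length(keys) == 0L) {
    net <- new_consensus_network(
      data.frame(from = character(0), to = character(0), frequency = numeric(0),
                 stringsAsFactors = FALSE),
      threshold, n, nodes)
    return(net)
  }
  tab <- table(keys) / n
  keep <- tab[tab > threshold]
  parts <- strsplit(names(keep), "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[`, "", 1L),
                      to = vapply(parts, `[`, "", 2L),
                      frequency = as.numeric(keep), stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  if (is.null(nodes))
    nodes <- sort(unique(unlist(lapply(dag_samples, function(s)
      unique(c(s$edges$from, s$edges$to))))))
  remove_loops(new_consensus_network(edges, threshold, n, nodes))
}

## first directed cycle found by DFS with deterministic ordering
## (start nodes and neighbors visited in lexicographic order)
.find_cycle <- function(edges) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  adj <- lapply(setNames(nodes, nodes), function(v) sort(edges$to[edges$from == v]))
  color <- setNames(rep(0L, length(nodes)), nodes)  # 0 white 1 grey 2 black
  parent <- setNames(rep(NA_character_, length(nodes)), nodes)
  cycle <- NULL
  visit <- function(v) {
    color[v] <<- 1L
    for (w in adj[[v]]) {
      if (!is.null(cycle)) return()
      if (color[w] == 0L) { parent[w] <<- v; visit(w) }
      else if (color[w] == 1L) {
        path <- v
        while (path[1L] != w) path <- c(parent[path[1L]], path)
        cycle <<- c(path, w)
        return()
      }
    }
    color[v] <<- 2L
  }
  for (v in nodes) {
    if (color[v] == 0L) visit(v)
    if (!is.null(cycle)) break
  }
  cycle
}

#' Remove directed cycles by deleting weakest links
#'
#' While a cycle exists, the minimum-frequency edge on the first cycle found
#' (deterministic DFS order: smallest node id first, lexicographic
#' neighbors) is deleted; frequency ties break lexicographically on
#' (from, to).
#'
#' @param net `consensus_network`.
#' @return acyclic `consensus_network`; removed edges recorded in
#'   `net$removed_edges`.
#' @export
remove_loops <- function(net) {
  e <- net$edges
  removed <- e[0, , drop = FALSE]
  repeat {
    if (nrow(e) < 2L) break
    cyc <- .find_cycle(e)
    if (is.null(cyc)) break
    on_cycle <- which(paste(e$from, e$to) %in%
                        paste(cyc[-length(cyc)], cyc[-1L]))
    ec <- e[on_cycle, , drop = FALSE]
    ord <- order(ec$frequency, ec$from, ec$to)
    kill <- on_cycle[ord[1L]]
    removed <- rbind(removed, e[kill, , drop = FALSE])
    e <- e[-kill, , drop = FALSE]
  }
  rownames(e) <- NULL
  net$edges <- e
  net$removed_edges <- removed
  net
}

#' Run many chains and build the consensus network
#'
#' @inheritParams mcmc_search
#' @param n_runs number of independent chains.
#' @param seed_base chain r uses seed `seed_base + r - 1`.
#' @param threshold consensus cutoff.
#' @param nodes node universe for the result.
#' @return `consensus_network` (provenance in `$n_runs`, `$seed_base`).
#' @export
learn_consensus <- function(states, candidates, n_runs = 50L, n_iter = 20000L,
                            seed_base = 1L, threshold = 0.3, max_parents = 3L,
                            kappa = 1, lambda = 1, anneal_from = 1) {
  runs <- lapply(seq_len(n_runs), function(r)
    mcmc_search(states, candidates, seed = seed_base + r - 1L,
                n_iter = n_iter, max_parents = max_parents,
                kappa = kappa, lambda = lambda, anneal_from = anneal_from))
  net <- consensus(runs, threshold = threshold, nodes = rownames(states))
  net$seed_base <- seed_base
  net
}
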