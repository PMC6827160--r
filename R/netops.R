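## Operations on the consensus network: l-step subnetwork extraction,
## hypergeometric signature enrichment, greedy key-regulator selection, and
## chromosome enrichment. igraph supplies the graph container and BFS.

.net_graph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("from", "to")], directed = TRUE,
                                vertices = data.frame(name = net$nodes))
}

#' Extract the l-step subnetwork around seed nodes
#'
#' Nodes within `l` steps of any seed (following edge direction for
#' `mode = "downstream"`, ignoring it for `"undirected"`), plus the induced
#' edges among them.
#'
#' @param net `consensus_network`.
#' @param seeds character vector of node ids.
#' @param l step radius (>= 0; `Inf` reaches whole components).
#' @param mode "downstream" (default) or "undirected".
#' @return `subnetwork`: list with `nodes`, `edges`, `seeds`, `l`, `mode`.
#' @export
extract_subnetwork <- function(net, seeds, l = 2,
                               mode = c("downstream", "undirected")) {
  mode <- match.arg(mode)
  bad <- setdiff(seeds, net$nodes)
  if (length(bad)) .stopf("unknown seed node(s): %s", paste(bad, collapse = ", "))
  stopifnot(l >= 0)
  g <- .net_graph(net)
  nb <- igraph::ego(g, order = if (is.finite(l)) l else igraph::vcount(g),
                    nodes = seeds,
                    mode = if (mode == "downstream") "out" else "all")
  nodes <- sort(unique(unlist(lapply(nb, function(v) v$name))))
  e <- net$edges[net$edges$from %in% nodes & net$edges$to %in% nodes, ,
                 drop = FALSE]
  rownames(e) <- NULL
  structure(list(nodes = nodes, edges = e, seeds = seeds, l = l, mode = mode),
            class = "subnetwork")
}

#' One-sided hypergeometric enrichment
#'
#' Probability of observing `k` or more signature genes in a subnetwork of
#' `n` nodes when `K` of the `N` universe genes carry the signature, plus
#' fold enrichment (k/K) / (n/N).
#'
#' @param K signature genes in the universe.
#' @param n subnetwork size.
#' @param k overlap.
#' @param N universe size.
#' @return `enrichment_result`: list with k, K, n, N, p, fold.
#' @export
enrich <- function(K, n, k, N) {
  if (N <= 0) .stopf("empty universe")
  if (k > min(K, n) || min(K, n) > N || k < 0)
    .stopf("inconsistent contingency counts (k=%d, K=%d, n=%d, N=%d)", k, K, n, N)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (K == 0 || n == 0) 0 else (k / K) / (n / N)
  structure(list(k = k, K = K, n = n, N = N, p = p, fold = fold),
            class = "enrichment_result")
}

#' Key regulators of a signature
#'
#' Every node's `l`-step subnetwork is tested for signature enrichment
#' (universe = network nodes by default); nodes whose BH-adjusted p falls
#' below `alpha` are candidates. Candidates are then taken greedily from best
#' p upward (ties: larger overlap, then node id), excluding any remaining
#' candidate that lies inside an already-selected regulator's subnetwork.
#'
#' @param net `consensus_network`.
#' @param signature character vector of gene ids.
#' @param l subnetwork radius (default 2).
#' @param alpha BH-adjusted candidate threshold (default 0.05).
#' @param mode subnetwork direction mode (default "downstream").
#' @param universe optional universe size override.
#' @return `key_regulator_set`: list with `regulators` (data.frame: node, p,
#'   p_adj, overlap, subnet_size, selected), `subnet_nodes` (claimed node
#'   sets of selected regulators), `excluded` (exclusion trace),
#'   `unmapped_signature`.
#' @export
key_regulators <- function(net, signature, l = 2, alpha = 0.05,
                           mode = c("downstream", "undirected"),
                           universe = NULL) {
  mode <- match.arg(mode)
  sig_in <- sort(intersect(unique(signature), net$nodes))
  unmapped <- setdiff(unique(signature), net$nodes)
  N <- universe %||% length(net$nodes)
  K <- length(sig_in)
  g <- .net_graph(net)
  nb <- igraph::ego(g, order = l, nodes = net$nodes,
                    mode = if (mode == "downstream") "out" else "all")
  names(nb) <- net$nodes
  tab <- do.call(rbind, lapply(net$nodes, function(v) {
    sub_nodes <- nb[[v]]$name
    k <- length(intersect(sub_nodes, sig_in))
    data.frame(node = v, overlap = k, subnet_size = length(sub_nodes),
               p = enrich(K, length(sub_nodes), k, N)$p,
               stringsAsFactors = FALSE)
  }))
  tab$p_adj <- p.adjust(tab$p, method = "BH")
  cand <- tab[tab$p_adj < alpha, , drop = FALSE]
  cand <- cand[order(cand$p, -cand$overlap, cand$node), , drop = FALSE]
  selected <- character(0); claimed <- list(); trace <- list()
  available <- cand$node
  for (i in seq_len(nrow(cand))) {
    v <- cand$node[i]
    if (!v %in% available) next
    selected <- c(selected, v)
    sub_nodes <- nb[[v]]$name
    claimed[[v]] <- sort(sub_nodes)
    dropped <- intersect(setdiff(available, v), sub_nodes)
    trace[[v]] <- dropped
    available <- setdiff(available, c(v, dropped))
  }
  cand$selected <- cand$node %in% selected
  structure(list(regulators = cand, subnet_nodes = claimed, excluded = trace,
                 unmapped_signature = unmapped, l = l, alpha = alpha,
                 mode = mode),
            class = "key_regulator_set")
}

#' Largest connected subnetwork of a signature
#'
#' Expands the signature's network nodes by `l` undirected steps, induces
#' edges, and returns the largest weakly-connected component together with
#' its signature enrichment.
#'
#' @param net `consensus_network`.
#' @param signature gene ids.
#' @param l expansion radius (default 1).
#' @return `subnetwork` with extra fields `component_sizes` and `enrichment`.
#' @export
signature_subnetwork <- function(net, signature, l = 1) {
  sig_in <- intersect(unique(signature), net$nodes)
  if (length(sig_in) == 0L)
    return(structure(list(nodes = character(0),
                          edges = net$edges[0, , drop = FALSE],
                          seeds = character(0), l = l, mode = "undirected",
                          component_sizes = integer(0), enrichment = NULL),
                     class = "subnetwork"))
  sub <- extract_subnetwork(net, sig_in, l = l, mode = "undirected")
  g <- igraph::graph_from_data_frame(sub$edges[, c("from", "to")],
                                     directed = TRUE,
                                     vertices = data.frame(name = sub$nodes))
  comp <- igraph::components(g, mode = "weak")
  big <- which.max(comp$csize)
  nodes <- sort(names(comp$membership)[comp$membership == big])
  e <- sub$edges[sub$edges$from %in% nodes & sub$edges$to %in% nodes, ,
                 drop = FALSE]
  rownames(e) <- NULL
  enr <- enrich(K = length(sig_in), n = length(nodes),
                k = length(intersect(nodes, sig_in)), N = length(net$nodes))
  structure(list(nodes = nodes, edges = e, seeds = sig_in, l = l,
                 mode = "undirected", component_sizes = sort(comp$csize,
                                                             decreasing = TRUE),
                 enrichment = enr),
            class = "subnetwork")
}

#' Per-chromosome enrichment of a signature
#'
#' Hypergeometric test of the signature against each chromosome's gene set,
#' within the annotated universe.
#'
#' @param signature gene ids.
#' @param ann gene annotation data.frame (gene_id, chrom).
#' @param universe optional universe gene ids (default: all annotated genes).
#' @return data.frame: chrom, k, K, n, N, p, fold; attribute `n_unannotated`.
#' @export
chromosome_enrichment <- function(signature, ann, universe = NULL) {
  universe <- universe %||% ann$gene_id
  sig <- unique(signature)
  unann <- setdiff(sig, ann$gene_id)
  sig_u <- intersect(sig, universe)
  res <- do.call(rbind, lapply(sort(unique(ann$chrom)), function(ch) {
    chrom_genes <- intersect(ann$gene_id[ann$chrom == ch], universe)
    e <- enrich(K = length(sig_u), n = length(chrom_genes),
                k = length(intersect(chrom_genes, sig_u)),
                N = length(universe))
    data.frame(chrom = ch, k = e$k, K = e$K, n = e$n, N = e$N, p = e$p,
               fold = e$fold, stringsAsFactors = FALSE)
  }))
  attr(res, "n_unannotated") <- length(unann)
  res
}
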