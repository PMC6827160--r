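test_that("informative-gene filter applies strict thresholds", {
  m <- rbind(at_mean = rep(4.8, 10) + c(rep(-1, 5), rep(1, 5)) * 0.9,
             passes = rnorm(10, 6, 1.2),
             low_var = rnorm(10, 6, 0.01))
  colnames(m) <- paste0("s", 1:10)
  rownames(m) <- c("at_mean", "passes", "low_var")
  m["at_mean", ] <- 4.8 + (m["at_mean", ] - mean(m["at_mean", ]))  # mean exactly 4.8
  sel <- select_informative_genes(m, mean_min = 4.8, var_min = 0.4)
  expect_identical(sel, "passes")
  expect_error(select_informative_genes(matrix(1, 2, 5,
                                               dimnames = list(c("a", "b"), NULL))),
               "no informative genes")
})

test_that("discretization recovers separated groups and handles degeneracy", {
  x <- c(rep(-1, 10), rep(0, 10), rep(1, 10))
  d <- discretize_profile(x)
  expect_identical(d$states, rep(0:2, each = 10))
  expect_true(all(diff(d$cutpoints) > 0))
  expect_warning(d0 <- discretize_profile(rep(2, 10)), "distinct")
  expect_true(all(d0$states == 1L))
  # well-separated draws: states recover the generating component > 95%
  set.seed(5)
  comp <- sample(0:2, 400, replace = TRUE)
  x2 <- c(-1, 0, 1)[comp + 1] + rnorm(400, 0, 0.2)
  expect_gte(mean(discretize_profile(x2)$states == comp), 0.95)
})

test_that("discretization is invariant to affine increasing transforms", {
  set.seed(6)
  comp <- sample(0:2, 300, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  x <- c(-1, 0, 1)[comp + 1] + rnorm(300, 0, 0.25)
  s1 <- discretize_profile(x)$states
  s2 <- discretize_profile(3 * x + 10)$states
  expect_identical(s1, s2)
})

test_that("skewed vectors collapse toward two states deterministically", {
  set.seed(7)
  x <- c(rnorm(95, 0, 0.1), rnorm(5, 4, 0.1), rnorm(3, -4, 0.1))
  d <- discretize_profile(x, min_frac = 0.1)
  # both outer clusters are below 10% occupancy: absorbed into normal
  expect_true(all(d$states == 1L))
})

test_that("mutual information matches closed forms", {
  # identical vectors: MI equals the empirical entropy
  a <- c(0L, 0L, 1L, 1L, 2L, 2L, 2L)
  p <- table(a) / length(a)
  expect_equal(mutual_information(a, a), -sum(p * log(p)), tolerance = 1e-12)
  # diagonal 3x3 table {{2,0,0},{0,2,0},{0,0,2}}: MI = ln 3
  b <- rep(0:2, each = 2)
  expect_equal(mutual_information(b, b), log(3), tolerance = 1e-12)
  # independence: MI -> 0
  set.seed(8)
  mi <- replicate(100, mutual_information(sample(0:2, 1000, TRUE),
                                          sample(0:2, 1000, TRUE)))
  expect_lt(mean(mi), 0.01)
})

test_that("candidate construction prunes by MI and anchors cis CNV nodes", {
  co <- bn_cohort(71, n_genes = 30)
  de <- discretize_matrix(co$expr)
  dc <- discretize_matrix(co$cnv[names(co$truth$cis_genes), , drop = FALSE])
  ns <- build_node_states(de$states, dc$states, names(co$truth$cis_genes))
  cand <- build_candidates(ns$states, ns$cis_map, exclude_frac = 0.2)
  genes <- rownames(de$states)
  for (g in genes) {
    expect_false(g %in% cand[[g]])  # never its own candidate
    has_anchor <- g %in% names(ns$cis_map)
    expect_identical(paste0("CNV:", g) %in% cand[[g]], has_anchor)
    # bottom 20% excluded
    expect_lte(length(setdiff(cand[[g]], paste0("CNV:", g))),
               ceiling(0.8 * (length(genes) - 1)))
  }
  # CNV nodes have no parents ever
  for (cn in unname(ns$cis_map)) expect_length(cand[[cn]], 0L)
  # exclude_frac = 0: everybody else is a candidate
  cand0 <- build_candidates(de$states, NULL, exclude_frac = 0)
  expect_setequal(cand0[[genes[1]]], setdiff(genes, genes[1]))
})

test_that("planted parents survive MI pruning when informative", {
  co <- bn_cohort(72)
  de <- discretize_matrix(co$expr)
  cand <- build_candidates(de$states, NULL, exclude_frac = 0.2)
  M <- attr(cand, "mi")
  td <- co$truth$true_dag
  for (r in seq_len(nrow(td))) {
    child <- td$to[r]; parent <- td$from[r]
    if (M[parent, child] > median(M[child, setdiff(rownames(M), child)]))
      expect_true(parent %in% cand[[child]])
  }
})

test_that("empty-graph score matches a brute-force full-table computation", {
  co <- bn_cohort(73, n_genes = 4, n_samples = 100)
  st <- discretize_matrix(co$expr)$states
  # independent oracle: BDeu marginal likelihood of each node with no parents
  oracle_node <- function(x, kappa = 1) {
    nk <- tabulate(x + 1L, 3L)
    lgamma(kappa) - lgamma(kappa + length(x)) +
      sum(lgamma(kappa / 3 + nk) - lgamma(kappa / 3))
  }
  expect_equal(score_structure(NULL, st),
               sum(apply(st, 1L, oracle_node)), tolerance = 1e-9)
})

test_that("compiled family scores equal the pure-R reference", {
  co <- bn_cohort(74, n_genes = 10, n_samples = 80)
  st <- discretize_matrix(co$expr)$states
  nodes <- rownames(st)
  set.seed(9)
  for (rep in 1:20) {
    child <- sample(10, 1)
    np <- sample(0:3, 1)
    pa <- sample(setdiff(seq_len(10), child), np)
    expect_equal(m3cnet:::.family_score_cpp(st, child, pa, 1, 1),
                 m3cnet:::.family_score_r(st, nodes[child], nodes[pa], 1, 1),
                 tolerance = 1e-9)
  }
})

test_that("Markov-equivalent two-node structures score identically without anchors", {
  co <- bn_cohort(75, n_genes = 6, n_samples = 200)
  st <- discretize_matrix(co$expr)$states
  n1 <- rownames(st)[1]; n2 <- rownames(st)[2]
  s_xy <- score_structure(data.frame(from = n1, to = n2), st)
  s_yx <- score_structure(data.frame(from = n2, to = n1), st)
  expect_equal(s_xy, s_yx, tolerance = 1e-9)
})

test_that("adding a strong true parent raises the score", {
  hits <- vapply(1:20, function(seed) {
    co <- bn_cohort(200 + seed, n_genes = 20, n_samples = 300)
    td <- co$truth$true_dag
    # a child whose only influence is that single parent gives the clean case
    solo <- td[!(td$to %in% td$to[duplicated(td$to)]) &
                 !(td$to %in% names(co$truth$cis_genes)), , drop = FALSE]
    if (nrow(solo) == 0L) return(NA)
    st <- discretize_matrix(co$expr)$states
    e <- solo[1, , drop = FALSE]
    score_structure(e, st) > score_structure(NULL, st)
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.95)
})

test_that("mcmc_search is deterministic given the seed and respects candidates", {
  co <- bn_cohort(76, n_genes = 20, n_samples = 150)
  st <- discretize_matrix(co$expr)$states
  cand <- build_candidates(st, NULL, max_candidates = 8)
  a <- mcmc_search(st, cand, seed = 5, n_iter = 5000)
  b <- mcmc_search(st, cand, seed = 5, n_iter = 5000)
  expect_identical(a$edges, b$edges)
  expect_identical(a$log_score, b$log_score)
  # every edge respects the candidate sets, and the result is acyclic
  for (r in seq_len(nrow(a$edges)))
    expect_true(a$edges$from[r] %in% cand[[a$edges$to[r]]])
  expect_false(has_cycle_bruteforce(a$edges))
  # best score reported equals a full rescore of the returned structure
  expect_equal(score_structure(a$edges, st), a$log_score, tolerance = 1e-7)
})

test_that("a 4-node chain is recovered across seeds", {
  # chain g1 -> g2 -> g3 -> g4 with strong CPTs, n = 500
  make_chain <- function(seed) {
    set.seed(seed)
    n <- 500
    flip <- function(target, q = 0.92) {
      miss <- runif(n) > q
      out <- target
      out[miss] <- (target[miss] + sample(1:2, sum(miss), TRUE)) %% 3L
      out
    }
    g1 <- sample(0:2, n, TRUE)
    g2 <- flip(g1); g3 <- flip(g2); g4 <- flip(g3)
    st <- rbind(g1 = g1, g2 = g2, g3 = g3, g4 = g4)
    storage.mode(st) <- "integer"
    st
  }
  ok <- vapply(1:20, function(seed) {
    st <- make_chain(seed)
    cand <- build_candidates(st, NULL, exclude_frac = 0)
    s <- mcmc_search(st, cand, seed = seed, n_iter = 4000)
    skel <- unique(apply(s$edges, 1L, function(e) paste(sort(e), collapse = "-")))
    setequal(skel, c("g1-g2", "g2-g3", "g3-g4"))
  }, logical(1))
  expect_gte(sum(ok), 18L)
})

test_that("consensus frequencies equal brute-force counts over tiny DAG lists", {
  mk <- function(...) {
    e <- list(...)
    structure(list(edges = data.frame(from = vapply(e, `[`, "", 1),
                                      to = vapply(e, `[`, "", 2),
                                      stringsAsFactors = FALSE),
                   log_score = 0, seed = 1), class = "dag_sample")
  }
  samples <- list(mk(c("a", "b"), c("b", "c")), mk(c("a", "b")),
                  mk(c("a", "b"), c("c", "b")), mk(c("b", "a")),
                  mk(c("a", "b"), c("b", "c")))
  net <- consensus(samples, threshold = 0.3)
  freq <- setNames(net$edges$frequency, paste(net$edges$from, net$edges$to))
  expect_equal(unname(freq["a b"]), 4 / 5)
  expect_equal(unname(freq["b c"]), 2 / 5)
  expect_false("c b" %in% names(freq))  # 1/5 below threshold
  expect_false("b a" %in% names(freq))
  # boundary: exactly at the threshold is dropped (strict >)
  net2 <- consensus(samples, threshold = 0.4)
  expect_false("b c" %in% paste(net2$edges$from, net2$edges$to))
})

test_that("CNV nodes never gain parents nor extra children in sampled structures", {
  co <- bn_cohort(77, n_genes = 25)
  de <- discretize_matrix(co$expr)
  dc <- discretize_matrix(co$cnv[names(co$truth$cis_genes), , drop = FALSE])
  ns <- build_node_states(de$states, dc$states, names(co$truth$cis_genes))
  cand <- build_candidates(ns$states, ns$cis_map, max_candidates = 10)
  for (seed in 1:5) {
    s <- mcmc_search(ns$states, cand, seed = seed, n_iter = 10000)
    cnv_in <- s$edges[startsWith(s$edges$to, "CNV:"), ]
    expect_identical(nrow(cnv_in), 0L)
    cnv_out <- s$edges[startsWith(s$edges$from, "CNV:"), ]
    expect_true(all(cnv_out$to == sub("^CNV:", "", cnv_out$from)))
  }
})

test_that("weakest-link loop removal is forced on a labeled 3-cycle", {
  net <- m3cnet:::new_consensus_network(
    data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"),
               frequency = c(0.9, 0.8, 0.4), stringsAsFactors = FALSE),
    threshold = 0.3, n_runs = 10L)
  out <- remove_loops(net)
  expect_identical(paste(out$edges$from, out$edges$to), c("a b", "b c"))
  expect_identical(paste(out$removed_edges$from, out$removed_edges$to), "c a")
})

test_that("acyclic networks pass through loop removal unchanged", {
  net <- m3cnet:::new_consensus_network(
    data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
               frequency = c(0.5, 0.6, 0.7), stringsAsFactors = FALSE),
    threshold = 0.3, n_runs = 10L)
  expect_identical(remove_loops(net)$edges, net$edges)
})

test_that("loop removal yields acyclic subsets of random cyclic graphs", {
  set.seed(10)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    nodes <- letters[1:n]
    e <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    e <- e[e$from != e$to, ]
    e <- e[runif(nrow(e)) < 0.35, ]
    if (nrow(e) == 0L) next
    e$frequency <- round(runif(nrow(e), 0.3, 1), 3)
    net <- m3cnet:::new_consensus_network(e, 0.3, 1L)
    out <- remove_loops(net)
    expect_false(has_cycle_bruteforce(out$edges))
    expect_true(all(paste(out$edges$from, out$edges$to) %in%
                      paste(e$from, e$to)))
  }
})

test_that("family-score bookkeeping matches full rescoring after long chains", {
  co <- bn_cohort(78, n_genes = 15, n_samples = 100)
  st <- discretize_matrix(co$expr)$states
  cand <- build_candidates(st, NULL, exclude_frac = 0)
  for (seed in 1:5) {
    s <- mcmc_search(st, cand, seed = seed, n_iter = 1000)
    expect_equal(score_structure(s$edges, st), s$log_score, tolerance = 1e-7)
  }
})

test_that("desk-scale consensus hits the regression band for skeleton recovery", {
  co <- bn_cohort(79)
  de <- discretize_matrix(co$expr)
  dc <- discretize_matrix(co$cnv[names(co$truth$cis_genes), , drop = FALSE])
  ns <- build_node_states(de$states, dc$states, names(co$truth$cis_genes))
  cand <- build_candidates(ns$states, ns$cis_map, max_candidates = 12)
  net <- learn_consensus(ns$states, cand, n_runs = 50, n_iter = 50000,
                         seed_base = 1)
  g <- drop_cnv_nodes(net)
  truth <- co$truth$true_dag
  undir <- function(f, t) ifelse(f < t, paste(f, t), paste(t, f))
  got <- unique(undir(g$edges$from, g$edges$to))
  want <- unique(undir(truth$from, truth$to))
  expect_gte(mean(got %in% want), 0.7)   # precision
  expect_gte(mean(want %in% got), 0.5)   # recall
})
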