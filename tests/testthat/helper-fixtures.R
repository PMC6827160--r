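# shared fixtures, all built in code

# small deterministic gene x sample matrix
toy_matrix <- function(n_genes = 5L, n_samples = 4L, seed = 42L) {
  set.seed(seed)
  m <- matrix(round(rnorm(n_genes * n_samples), 6), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# default 50-node cohort for structure-learning tests: DAG + CNV world only
# (no survival module factor, no marker genes)
bn_cohort <- function(seed, n_genes = 50L, n_samples = 300L) {
  simulate_cohort(sim_config(n_genes = n_genes, n_samples = n_samples,
                             n_blocks = max(2L, round(n_genes / 4)),
                             edge_density = 0.03, frac_cis = 0.4,
                             include_markers = FALSE, n_signatures = 0L,
                             module_sd = 0, seed = seed))
}

# brute-force one-sided hypergeometric tail by PMF summation (independent
# of phyper): P(X >= k) with X ~ Hypergeom(K successes, N - K failures, n draws)
hyper_tail_bruteforce <- function(K, n, k, N) {
  kmax <- min(K, n)
  if (k > kmax) return(0)
  i <- k:kmax
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# brute-force BH step-up adjusted p-values
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (r in n:1) {
    val <- min(prev, p[o[r]] * n / r)
    adj[o[r]] <- val
    prev <- val
  }
  adj
}

# exhaustive directed-cycle check via DFS over all simple paths (small n)
has_cycle_bruteforce <- function(edges) {
  nodes <- unique(c(edges$from, edges$to))
  adj <- split(edges$to, factor(edges$from, levels = nodes))
  visit <- function(v, stack) {
    for (w in adj[[v]]) {
      if (w %in% stack) return(TRUE)
      if (visit(w, c(stack, w))) return(TRUE)
    }
    FALSE
  }
  any(vapply(nodes, function(v) visit(v, v), logical(1)))
}

# shortest-path distances by repeated adjacency products (independent BFS oracle)
dist_bruteforce <- function(nodes, edges, directed = TRUE) {
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  A[cbind(edges$from, edges$to)] <- TRUE
  if (!directed) A[cbind(edges$to, edges$from)] <- TRUE
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  reach <- diag(TRUE, n)
  cur <- diag(TRUE, n)
  for (step in seq_len(n)) {
    nxt <- (cur %*% A) > 0
    new <- nxt & !reach
    D[new] <- step
    if (!any(new)) break
    reach <- reach | new
    cur <- new
  }
  D
}

# frequencies that are the minimum of at least one directed simple cycle,
# by exhaustive enumeration of cyclic orderings (small graphs only)
.acc_min_cycle_freqs <- function(edges) {
  nodes <- unique(c(edges$from, edges$to))
  key <- paste(edges$from, edges$to)
  mins <- numeric(0)
  for (size in 2:length(nodes)) {
    subsets <- combn(nodes, size, simplify = FALSE)
    for (s in subsets) {
      perms <- if (size == 2) list(s) else
        lapply(asplit(gtools_permutations(s[-1]), 1L), function(p) c(s[1], p))
      for (p in perms) {
        cyc <- paste(p, c(p[-1], p[1]))
        if (all(cyc %in% key))
          mins <- c(mins, min(edges$frequency[match(cyc, key)]))
      }
    }
  }
  unique(mins)
}

# tiny permutations helper (avoid a gtools dependency)
gtools_permutations <- function(x) {
  if (length(x) <= 1) return(matrix(x, nrow = 1))
  out <- NULL
  for (i in seq_along(x))
    out <- rbind(out, cbind(x[i], gtools_permutations(x[-i])))
  out
}

# Kaplan-Meier product-limit by hand at each distinct event time
km_bruteforce <- function(time, event) {
  ut <- sort(unique(time))
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (t in ut) {
    at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    if (d > 0) s <- s * (1 - d / at_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# two-group log-rank statistic (O - E)^2 / V summed over event times
logrank_bruteforce <- function(time, event, group) {
  g1 <- unique(group)[1L]
  ut <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ut) {
    n_t <- sum(time >= t)
    n1 <- sum(time >= t & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n_t
    if (n_t > 1)
      V <- V + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}
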