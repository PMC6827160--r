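## Three-state discretization of continuous profiles and plug-in mutual
## information, the substrate for structure learning.

#' Filter informative genes by mean and variance
#'
#' Keeps genes with mean expression strictly above `mean_min` and variance
#' strictly above `var_min` (cohort-scale defaults: 4.8 and 0.4 on the log2
#' microarray scale).
#'
#' @param expr gene x sample matrix.
#' @param mean_min,var_min strict lower thresholds.
#' @return character vector of gene ids.
#' @export
select_informative_genes <- function(expr, mean_min = 4.8, var_min = 0.4) {
  mu <- rowMeans(expr, na.rm = TRUE)
  v <- apply(expr, 1L, var, na.rm = TRUE)
  keep <- mu > mean_min & v > var_min
  if (!any(keep))
    .stopf("no informative genes (%d pass mean > %g, %d pass var > %g)",
           sum(mu > mean_min), mean_min, sum(v > var_min), var_min)
  rownames(expr)[keep]
}

#' Discretize a continuous profile into low/normal/high states
#'
#' One-dimensional k-means (k = 3) with deterministic quantile
#' initialization; clusters are ordered by centroid and mapped to states
#' 0 (low), 1 (normal), 2 (high). Cutpoints are midpoints between adjacent
#' centroids. If a cluster captures fewer than `min_frac` of the samples the
#' vector is collapsed toward two states: a small outer cluster is absorbed
#' by the middle state, a small middle cluster is split to the nearer outer
#' centroid. Fewer than three distinct values: everything is "normal".
#'
#' @param x numeric vector.
#' @param min_frac minimum cluster occupancy before collapsing (default 0.05).
#' @return list with `states` (integer 0/1/2) and `cutpoints` (length 2, or
#'   NULL when degenerate).
#' @export
discretize_profile <- function(x, min_frac = 0.05) {
  ok <- is.finite(x)
  if (length(unique(x[ok])) < 3L) {
    .warnf("fewer than 3 distinct values; all states set to normal")
    return(list(states = ifelse(ok, 1L, NA_integer_), cutpoints = NULL))
  }
  xs <- x[ok]
  ctr <- unname(quantile(xs, c(0.1, 0.5, 0.9)))
  if (anyDuplicated(ctr))
    ctr <- seq(min(xs), max(xs), length.out = 3L)
  km <- suppressWarnings(kmeans(xs, centers = matrix(ctr, ncol = 1L),
                                iter.max = 50L))
  o <- order(km$centers[, 1L])
  cent <- km$centers[o, 1L]
  state <- match(km$cluster, o) - 1L   # 0/1/2 by increasing centroid
  cut <- c(mean(cent[1:2]), mean(cent[2:3]))
  ## occupancy collapse
  n <- length(xs)
  occ <- tabulate(state + 1L, nbins = 3L) / n
  if (occ[1L] < min_frac) { state[state == 0L] <- 1L; cut[1L] <- -Inf }
  if (occ[3L] < min_frac) { state[state == 2L] <- 1L; cut[2L] <- Inf }
  if (occ[2L] < min_frac && occ[1L] >= min_frac && occ[3L] >= min_frac) {
    mid <- state == 1L
    nearer_low <- abs(xs - cent[1L]) <= abs(xs - cent[3L])
    state[mid & nearer_low] <- 0L
    state[mid & !nearer_low] <- 2L
  }
  out <- rep(NA_integer_, length(x))
  out[ok] <- state
  list(states = out, cutpoints = cut)
}

#' Discretize every row of a matrix
#' @param m gene/node x sample numeric matrix.
#' @param min_frac passed to [discretize_profile()].
#' @return list with `states` (integer matrix, same dimnames) and
#'   `cutpoints` (named list).
#' @export
discretize_matrix <- function(m, min_frac = 0.05) {
  st <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  cuts <- vector("list", nrow(m)); names(cuts) <- rownames(m)
  for (i in seq_len(nrow(m))) {
    d <- withCallingHandlers(discretize_profile(m[i, ], min_frac),
                             warning = function(w) invokeRestart("muffleWarning"))
    st[i, ] <- d$states
    cuts[[i]] <- d$cutpoints
  }
  list(states = st, cutpoints = cuts)
}

#' Plug-in mutual information of two discrete state vectors (nats)
#' @param a,b integer vectors of equal length (states 0..2; NAs dropped
#'   pairwise).
#' @return nonnegative scalar.
#' @export
mutual_information <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}

## MI matrix over rows of a state matrix (3-state, NAs tolerated)
.mi_matrix <- function(states) {
  G <- nrow(states)
  M <- matrix(0, G, G, dimnames = list(rownames(states), rownames(states)))
  for (i in seq_len(G - 1L)) {
    ai <- states[i, ]
    for (j in (i + 1L):G) {
      M[i, j] <- M[j, i] <- mutual_information(ai, states[j, ])
    }
  }
  M
}
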