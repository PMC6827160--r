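## Sample-label QC between expression and CNV layers. The scheme: find genes
## whose expression tracks their own copy number (cis genes), rank-transform
## their profiles, correlate every expression sample against every CNV sample,
## and demand that each sample be most similar to itself in both directions.
## Samples failing that are searched for cross matches (mutually maximal,
## significant off-diagonal similarity); corrections are applied and the cis
## set refined until a fixed point.

## row-wise Spearman correlation between paired matrices (same dims),
## returning estimate and two-sided p (t approximation, df = n - 2)
.row_spearman <- function(a, b) {
  n <- ncol(a)
  ra <- t(apply(a, 1L, rank)); rb <- t(apply(b, 1L, rank))
  ra <- ra - rowMeans(ra); rb <- rb - rowMeans(rb)
  sa <- sqrt(rowSums(ra^2)); sb <- sqrt(rowSums(rb^2))
  r <- rowSums(ra * rb) / (sa * sb)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(estimate = r, p = p, constant = sa == 0 | sb == 0)
}

#' Select cis genes: expression significantly correlated with own CNV
#'
#' Per-gene Spearman correlation between expression and gene-level CNV across
#' the paired samples, with Benjamini-Hochberg control across all testable
#' genes. Genes with a constant profile in either layer are excluded
#' (correlation undefined).
#'
#' @param expr,cnv gene x sample matrices; columns are assumed paired by name.
#' @param fdr BH-adjusted p-value threshold (default 0.01).
#' @return character vector of cis gene ids, with attributes `table`
#'   (per-gene statistic, p, adjusted p) and `n_excluded`.
#' @export
select_cis_genes <- function(expr, cnv, fdr = 0.01) {
  genes <- intersect(rownames(expr), rownames(cnv))
  samples <- intersect(colnames(expr), colnames(cnv))
  if (length(samples) < 10L)
    .stopf("need >= 10 shared samples for stable correlations (have %d)",
           length(samples))
  if (length(genes) < 1L) .stopf("no shared genes between layers")
  a <- expr[genes, samples, drop = FALSE]
  b <- cnv[genes, samples, drop = FALSE]
  ok <- complete.cases(a) & complete.cases(b)
  res <- .row_spearman(a[ok, , drop = FALSE], b[ok, , drop = FALSE])
  testable <- !res$constant
  tab <- data.frame(gene_id = genes[ok][testable],
                    rho = res$estimate[testable],
                    p = res$p[testable], stringsAsFactors = FALSE)
  tab$p_adj <- p.adjust(tab$p, method = "BH")
  cis <- tab$gene_id[tab$p_adj < fdr]
  structure(cis, table = tab,
            n_excluded = sum(!ok) + sum(res$constant))
}

#' Sample-by-sample similarity matrix on cis genes
#'
#' Profiles of the cis genes are rank-transformed per gene within each layer;
#' S(i, j) is the Pearson correlation (equivalently Spearman) between the
#' rank vector of expression sample i and CNV sample j.
#'
#' @param expr,cnv gene x sample matrices.
#' @param cis cis gene ids from [select_cis_genes()].
#' @return object of class `similarity_matrix`: list with `S` (rows =
#'   expression samples, columns = CNV samples), `cis`.
#' @export
similarity_matrix <- function(expr, cnv, cis) {
  if (length(cis) == 0L) .stopf("empty cis gene set")
  if (length(cis) < 20L)
    .warnf("only %d cis genes: similarity scores may be unstable", length(cis))
  samples <- intersect(colnames(expr), colnames(cnv))
  a <- expr[cis, samples, drop = FALSE]
  b <- cnv[cis, samples, drop = FALSE]
  ra <- t(apply(a, 1L, rank)); rb <- t(apply(b, 1L, rank))
  ## columns are samples; S(i, j) correlates expr sample i with CNV sample j
  S <- suppressWarnings(cor(ra, rb))
  dimnames(S) <- list(samples, samples)
  structure(list(S = S, cis = cis), class = "similarity_matrix")
}

## z-score of S[i, j] against the other entries of row i and column j
.sim_z <- function(S, i, j) {
  ref <- c(S[i, -j], S[-i, j])
  mu <- mean(ref); sdv <- sd(ref)
  if (!is.finite(sdv) || sdv == 0) return(0)
  (S[i, j] - mu) / sdv
}

#' Classify sample pairs as self-matched, cross-matched, or unmatched
#'
#' Self-matched: S(i,i) is the maximum of both row i and column i and stands
#' `z_thresh` standard deviations above the remaining entries of its row and
#' column. Cross-matched: for samples failing that, a pair (i, j) that is
#' mutually maximal (row and column argmax) and significant. Everything else
#' is unmatched.
#'
#' @param sim a [similarity_matrix()].
#' @param z_thresh significance margin in SD units (default 3).
#' @param z_margin required lead of the cross-match z-score over the
#'   diagonal z-score (default 3). A genuine mislabel leaves a noise-level
#'   diagonal, so the gap is large; two near-duplicate profiles
#'   ("doppelgangers") differ by a sliver and must not be swapped.
#' @return object of class `match_report`: `self_matched`, `cross_matched`
#'   (data.frame expr_sample / cnv_sample / z), `unmatched`, `pairing`
#'   (named vector: expression sample -> CNV sample label it matches).
#' @export
classify_matches <- function(sim, z_thresh = 3, z_margin = 3) {
  S <- sim$S
  n <- nrow(S)
  ids <- rownames(S)
  row_arg <- apply(S, 1L, which.max)
  col_arg <- apply(S, 2L, which.max)
  selfm <- logical(n)
  for (i in seq_len(n))
    selfm[i] <- row_arg[i] == i && col_arg[i] == i && .sim_z(S, i, i) > z_thresh
  cross <- data.frame(expr_sample = character(0), cnv_sample = character(0),
                      z = numeric(0), stringsAsFactors = FALSE)
  claimed <- selfm  # CNV columns already accounted for
  for (i in which(!selfm)) {
    j <- row_arg[i]
    if (j == i || selfm[j] || col_arg[j] != i) next
    ## cross matches must beat the self score by a clear margin; otherwise
    ## near-duplicate profiles would swap spuriously
    z <- .sim_z(S, i, j)
    if (z <= .sim_z(S, i, i) + z_margin) next
    if (z > z_thresh)
      cross <- rbind(cross, data.frame(expr_sample = ids[i],
                                       cnv_sample = ids[j], z = z,
                                       stringsAsFactors = FALSE))
  }
  matched_expr <- c(ids[selfm], cross$expr_sample)
  matched_cnv <- c(ids[selfm], cross$cnv_sample)
  unmatched <- setdiff(ids, matched_expr)
  pairing <- setNames(c(ids[selfm], cross$cnv_sample),
                      c(ids[selfm], cross$expr_sample))
  structure(list(self_matched = ids[selfm], cross_matched = cross,
                 unmatched = unmatched, pairing = pairing,
                 z_thresh = z_thresh),
            class = "match_report")
}

#' Iterative matching with cis-gene refinement
#'
#' Alternates: (1) cis-gene selection on the current pairing, (2) similarity
#' classification, (3) pairing correction from cross matches. Stops when an
#' iteration introduces no correction, or after `max_iter` iterations (then
#' flagged non-converged). Correcting genuine swaps can only sharpen
#' expression-CNV correlations, so the per-iteration cis-gene count is
#' reported for audit.
#'
#' @param expr,cnv gene x sample matrices (shared sample names define the
#'   initial label-based pairing).
#' @param fdr cis-gene FDR threshold.
#' @param max_iter maximum refinement iterations.
#' @param z_thresh significance margin for [classify_matches()].
#' @return `match_report` with extra fields: `pairing` (expression sample ->
#'   original CNV column), `cis_counts` per iteration, `n_iter`, `converged`,
#'   `corrected_cnv` (CNV matrix with columns relabeled per the final
#'   pairing).
#' @export
iterate_matching <- function(expr, cnv, fdr = 0.01, max_iter = 10L,
                             z_thresh = 3) {
  stopifnot(max_iter >= 1L)
  samples <- intersect(colnames(expr), colnames(cnv))
  pairing <- setNames(samples, samples)  # expr sample -> original cnv column
  cis_counts <- integer(0)
  converged <- FALSE
  rep_last <- NULL
  for (it in seq_len(max_iter)) {
    cnv_cur <- cnv[, pairing, drop = FALSE]
    colnames(cnv_cur) <- names(pairing)
    cis <- select_cis_genes(expr, cnv_cur, fdr = fdr)
    cis_counts <- c(cis_counts, length(cis))
    sim <- similarity_matrix(expr, cnv_cur, cis)
    rep_last <- classify_matches(sim, z_thresh = z_thresh)
    if (nrow(rep_last$cross_matched) == 0L) { converged <- TRUE; break }
    new_pairing <- pairing
    for (r in seq_len(nrow(rep_last$cross_matched))) {
      i <- rep_last$cross_matched$expr_sample[r]
      j <- rep_last$cross_matched$cnv_sample[r]
      new_pairing[i] <- pairing[j]
    }
    if (identical(new_pairing, pairing)) { converged <- TRUE; break }
    pairing <- new_pairing
  }
  corrected <- cnv[, pairing, drop = FALSE]
  colnames(corrected) <- names(pairing)
  rep_last$pairing <- pairing
  moved <- pairing != names(pairing)
  rep_last$corrections <- data.frame(expr_sample = names(pairing)[moved],
                                     cnv_column = unname(pairing[moved]),
                                     stringsAsFactors = FALSE)
  rep_last$cis_counts <- cis_counts
  rep_last$n_iter <- length(cis_counts)
  rep_last$converged <- converged
  rep_last$corrected_cnv <- corrected
  rep_last
}

#' Attribute cross-match errors to a layer by metadata concordance
#'
#' For each corrected pair, votes compare layer-derived metadata calls
#' (e.g. sex and isotype from expression, hyperdiploidy from CNV) against
#' annotated clinical labels; the layer whose calls disagree with the clinic
#' is declared mislabeled. Ties or missing votes give "unknown".
#'
#' @param pairs data.frame with expr_sample / cnv_sample.
#' @param expr_meta,cnv_meta,clinical data.frames indexed by sample id whose
#'   shared columns are compared.
#' @return `pairs` with an added `error_layer` column in
#'   {"expression", "CNV", "unknown"}.
#' @export
attribute_error_layer <- function(pairs, expr_meta, cnv_meta, clinical) {
  concordance <- function(meta, sample) {
    score <- 0L
    for (cc in intersect(colnames(meta), colnames(clinical))) {
      if (!sample %in% rownames(meta) || !sample %in% rownames(clinical)) next
      score <- score +
        if (identical(meta[sample, cc], clinical[sample, cc])) 1L else -1L
    }
    score
  }
  layer <- character(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    e <- pairs$expr_sample[r]
    cons_expr <- concordance(expr_meta, e)
    cons_cnv <- concordance(cnv_meta, e)
    ## the layer inconsistent with clinical labels is the mislabeled one
    layer[r] <- if (cons_expr < cons_cnv) "expression"
    else if (cons_cnv < cons_expr) "CNV"
    else "unknown"
  }
  pairs$error_layer <- layer
  pairs
}

#' Infer sample sex from X/Y marker gene expression
#'
#' Three-group k-means on the two marker expressions; the cluster with high
#' female marker and low male marker is called Female, the converse Male,
#' and low/low (or otherwise ambiguous) clusters NoCall.
#'
#' @param expr gene x sample expression matrix.
#' @param markers named vector with entries `female` (default "XIST") and
#'   `male` (default "RPS4Y1").
#' @param seed k-means seed.
#' @return named character vector of calls in {Female, Male, NoCall}.
#' @export
infer_sex <- function(expr, markers = c(female = "XIST", male = "RPS4Y1"),
                      seed = 1L) {
  calls <- setNames(rep("NoCall", ncol(expr)), colnames(expr))
  if (!all(markers %in% rownames(expr))) {
    .warnf("sex marker gene(s) missing: %s",
           paste(setdiff(markers, rownames(expr)), collapse = ", "))
    return(calls)
  }
  x <- expr[markers[["female"]], ]; y <- expr[markers[["male"]], ]
  dat <- cbind(x, y)
  if (nrow(unique(dat)) < 3L) return(calls)  # degenerate: one cloud
  set.seed(seed)
  km <- kmeans(dat, centers = 3L, nstart = 10L)
  cx <- km$centers[, 1L]; cy <- km$centers[, 2L]
  hi_x <- cx > (max(cx) + min(cx)) / 2
  hi_y <- cy > (max(cy) + min(cy)) / 2
  lab <- ifelse(hi_x & !hi_y, "Female", ifelse(!hi_x & hi_y, "Male", "NoCall"))
  calls[] <- lab[km$cluster]
  calls
}

#' Infer immunoglobulin isotype from marker gene sets
#'
#' Calls the isotype whose marker set has the highest mean expression;
#' margins below `margin` give NoCall.
#'
#' @param expr gene x sample expression matrix.
#' @param marker_sets named list of marker gene vectors, one per isotype.
#' @param margin minimum lead of the best mean over the runner-up.
#' @return named character vector of isotype calls (or "NoCall").
#' @export
infer_isotype <- function(expr, marker_sets, margin = 0.5) {
  if (any(lengths(marker_sets) == 0L)) .stopf("empty isotype marker set")
  means <- vapply(marker_sets, function(g) {
    g <- intersect(g, rownames(expr))
    if (length(g) == 0L) rep(NA_real_, ncol(expr))
    else colMeans(expr[g, , drop = FALSE])
  }, numeric(ncol(expr)))
  means <- matrix(means, nrow = ncol(expr),
                  dimnames = list(colnames(expr), names(marker_sets)))
  calls <- apply(means, 1L, function(v) {
    if (all(is.na(v))) return("NoCall")
    o <- order(v, decreasing = TRUE)
    if (length(v) > 1L && (v[o[1L]] - v[o[2L]]) < margin) "NoCall"
    else names(v)[o[1L]]
  })
  setNames(calls, colnames(expr))
}

#' Call hyperdiploidy from gene-level copy number
#'
#' A chromosome is "gained" in a sample when the median gene logR exceeds
#' `gain_thresh`; a sample is hyperdiploid when at least `min_gained` of the
#' canonical odd chromosomes are gained.
#'
#' @param cnv gene x sample logR matrix.
#' @param ann gene annotation mapping genes to chromosomes.
#' @param chroms chromosomes characteristic of hyperdiploidy.
#' @param gain_thresh logR gain threshold (default 0.2).
#' @param min_gained minimum number of gained listed chromosomes (default 2).
#' @return named logical vector per sample.
#' @export
infer_hyperdiploidy <- function(cnv, ann,
                                chroms = c("3", "5", "7", "9", "11", "15", "19", "21"),
                                gain_thresh = 0.2, min_gained = 2L) {
  gained <- matrix(FALSE, length(chroms), ncol(cnv),
                   dimnames = list(chroms, colnames(cnv)))
  for (ch in chroms) {
    g <- intersect(ann$gene_id[ann$chrom == ch], rownames(cnv))
    if (length(g) == 0L) {
      .warnf("no annotated genes on chromosome %s; skipped", ch)
      next
    }
    med <- apply(cnv[g, , drop = FALSE], 2L, median, na.rm = TRUE)
    gained[ch, ] <- med > gain_thresh
  }
  colSums(gained) >= min_gained
}
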