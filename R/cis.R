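## Cis-CNV association testing and CNV-conditioned pairwise association.
## Rank (Spearman) statistics for per-gene cis tests; conditioning is linear
## residualization on the copy-number covariate (partial correlation).

#' Test every gene's expression against its own copy number
#'
#' Spearman correlation per shared gene across shared samples, BH adjustment
#' across all testable genes. Genes constant in either layer are excluded and
#' counted.
#'
#' @param expr,cnv gene x sample matrices with paired columns.
#' @param threshold BH-adjusted significance threshold (default 0.01).
#' @return data.frame (class `cis_association_table`) with gene_id, rho, p,
#'   p_adj, is_cis; excluded genes reported via attribute `excluded`.
#' @export
cis_test_all <- function(expr, cnv, threshold = 0.01) {
  genes <- intersect(rownames(expr), rownames(cnv))
  samples <- intersect(colnames(expr), colnames(cnv))
  if (length(genes) == 0L || length(samples) == 0L)
    .stopf("no shared genes/samples between expression and CNV")
  a <- expr[genes, samples, drop = FALSE]
  b <- cnv[genes, samples, drop = FALSE]
  ok <- complete.cases(a) & complete.cases(b)
  res <- .row_spearman(a[ok, , drop = FALSE], b[ok, , drop = FALSE])
  keep <- !res$constant
  tab <- data.frame(gene_id = genes[ok][keep], rho = res$estimate[keep],
                    p = res$p[keep], stringsAsFactors = FALSE)
  tab$p_adj <- p.adjust(tab$p, method = "BH")
  tab$is_cis <- tab$p_adj < threshold
  attr(tab, "excluded") <- c(genes[!ok], genes[ok][!keep])
  attr(tab, "threshold") <- threshold
  class(tab) <- c("cis_association_table", "data.frame")
  tab
}

#' Pairwise association before and after conditioning on copy number
#'
#' The raw p-value comes from the Pearson correlation test of (x, y). The
#' conditioned p-value is the correlation test of the residuals of x and y
#' after linear regression of each on the copy-number vector c — the partial
#' correlation given c. When c is (near-)constant there is nothing to remove:
#' the conditioned p equals the raw p and the result is flagged.
#'
#' @param x,y expression vectors.
#' @param cvec copy-number covariate vector.
#' @return list with `raw_p`, `conditioned_p`, `raw_r`, `conditioned_r`,
#'   `constant_covariate` flag.
#' @export
conditional_association <- function(x, y, cvec) {
  n <- length(x)
  stopifnot(length(y) == n, length(cvec) == n)
  if (n < 10L) .stopf("need >= 10 observations (have %d)", n)
  cor_p <- function(u, v, df_loss = 2L) {
    r <- suppressWarnings(cor(u, v))
    if (!is.finite(r)) return(list(r = NA_real_, p = NA_real_))
    df <- n - df_loss
    tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    list(r = r, p = 2 * pt(abs(tstat), df = df, lower.tail = FALSE))
  }
  raw <- cor_p(x, y)
  if (sd(cvec) == 0) {
    return(list(raw_p = raw$p, conditioned_p = raw$p, raw_r = raw$r,
                conditioned_r = raw$r, constant_covariate = TRUE))
  }
  rx <- residuals(lm(x ~ cvec))
  ry <- residuals(lm(y ~ cvec))
  cond <- cor_p(rx, ry, df_loss = 3L)  # one df spent on the covariate
  list(raw_p = raw$p, conditioned_p = cond$p, raw_r = raw$r,
       conditioned_r = cond$r, constant_covariate = FALSE)
}
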