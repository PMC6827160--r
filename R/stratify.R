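## Risk stratification from a gene set: per-gene z-scores, k-means (k = 3)
## over samples, risk labels assigned by observed event rate, and survival
## comparison (log-rank, pairwise Cox hazard ratios, Kaplan-Meier curves).
## The survival package supplies the fits; closed-form oracles in the test
## suite verify the KM and log-rank arithmetic independently.

#' Per-gene z-score standardization
#'
#' Rows restricted to `genes` are centered and scaled across samples;
#' zero-variance genes are dropped with a warning, missing genes reported.
#'
#' @param expr gene x sample matrix.
#' @param genes gene ids to keep (default: all).
#' @return standardized matrix (attribute `dropped` lists removed genes).
#' @export
zscore_by_gene <- function(expr, genes = rownames(expr)) {
  found <- intersect(genes, rownames(expr))
  missing <- setdiff(genes, found)
  if (length(missing))
    .warnf("%d gene(s) not in matrix: %s", length(missing),
           paste(head(missing, 5L), collapse = ", "))
  if (length(found) == 0L) .stopf("no requested genes present")
  m <- expr[found, , drop = FALSE]
  sds <- apply(m, 1L, sd, na.rm = TRUE)
  if (any(sds == 0 | !is.finite(sds))) {
    .warnf("dropping %d zero-variance gene(s)", sum(sds == 0 | !is.finite(sds)))
    m <- m[sds > 0 & is.finite(sds), , drop = FALSE]
  }
  z <- t(scale(t(m)))
  attr(z, "dropped") <- c(missing, found[!(found %in% rownames(m))])
  z
}

#' Cluster patients into risk groups
#'
#' k-means (k = 3, 50 restarts, fixed seed) on the sample vectors of the
#' standardized matrix; clusters are labeled High/Medium/Low by decreasing
#' observed event rate in the survival table (ties broken by shorter mean
#' follow-up = higher risk). Hierarchical clustering (Ward, Euclidean) is
#' available for heatmap-style ordering via `method = "hclust"`.
#'
#' @param z standardized gene x sample matrix from [zscore_by_gene()].
#' @param surv survival data.frame (single endpoint) used to order labels.
#' @param k number of groups (default 3).
#' @param method "kmeans" (default) or "hclust".
#' @param seed RNG seed for k-means restarts.
#' @param nstart k-means restarts.
#' @return `risk_stratification`: list with `group` (named factor
#'   High/Medium/Low), `sizes`, `event_rates`, `method`, `seed`,
#'   `degenerate`.
#' @export
cluster_patients <- function(z, surv, k = 3L, method = c("kmeans", "hclust"),
                             seed = 7L, nstart = 50L) {
  method <- match.arg(method)
  X <- t(z)
  if (nrow(X) < k) .stopf("fewer samples (%d) than clusters (%d)", nrow(X), k)
  degenerate <- FALSE
  if (method == "kmeans") {
    set.seed(seed)
    km <- tryCatch(kmeans(X, centers = k, nstart = nstart, iter.max = 100L),
                   error = function(e) NULL)
    if (is.null(km)) { degenerate <- TRUE; cl <- rep(1L, nrow(X)) }
    else cl <- km$cluster
  } else {
    hc <- stats::hclust(stats::dist(X), method = "ward.D2")
    cl <- stats::cutree(hc, k = k)
  }
  names(cl) <- rownames(X)
  if (length(unique(cl)) != k || any(tabulate(cl, k) == 0L)) degenerate <- TRUE
  if (nrow(X) == k) degenerate <- TRUE  # every sample its own group
  ## order clusters by observed risk
  s <- surv[match(names(cl), surv$sample_id), , drop = FALSE]
  er <- vapply(seq_len(max(cl)), function(g) {
    idx <- which(cl == g & !is.na(s$event))
    if (!length(idx)) return(NA_real_)
    mean(s$event[idx])
  }, numeric(1))
  mt <- vapply(seq_len(max(cl)), function(g) {
    idx <- which(cl == g)
    if (!length(idx)) return(NA_real_)
    mean(s$time[idx], na.rm = TRUE)
  }, numeric(1))
  ord <- order(-er, mt)  # highest event rate first; shorter follow-up riskier
  labels <- c("High", "Medium", "Low", paste0("G", seq_len(max(0, k - 3L)) + 3L))
  lab_of <- character(max(cl)); lab_of[ord] <- labels[seq_along(ord)]
  group <- factor(lab_of[cl], levels = labels[seq_len(k)])
  names(group) <- names(cl)
  structure(list(group = group, sizes = table(group),
                 event_rates = setNames(er[ord], labels[seq_along(ord)]),
                 method = method, seed = seed, k = k, degenerate = degenerate),
            class = "risk_stratification")
}

## two-group Cox hazard ratio with 95% CI
.pair_hr <- function(time, event, grp, num, den) {
  idx <- grp %in% c(num, den)
  if (sum(event[idx & grp == num]) == 0L || sum(event[idx & grp == den]) == 0L)
    return(list(hr = NA_real_, lo = NA_real_, hi = NA_real_, unstable = TRUE))
  g <- factor(grp[idx], levels = c(den, num))
  fit <- suppressWarnings(survival::coxph(survival::Surv(time[idx], event[idx]) ~ g))
  ci <- suppressMessages(stats::confint(fit))
  co <- stats::coef(fit)[1L]
  list(hr = unname(exp(co)), lo = exp(ci[1L, 1L]), hi = exp(ci[1L, 2L]),
       unstable = !is.finite(co) || abs(co) > 10)  # monotone separation
}

#' Compare survival across risk groups
#'
#' Log-rank test over all groups, pairwise hazard ratios from two-group Cox
#' fits (High/Low, High/Medium, Medium/Low), and Kaplan-Meier curves per
#' group.
#'
#' @param strat `risk_stratification` from [cluster_patients()].
#' @param surv survival data.frame; rows matched to stratified samples.
#' @param endpoint optional endpoint filter (e.g. "OS").
#' @return `survival_comparison`: list with `logrank_p`, `logrank_chisq`,
#'   `hr` (data.frame comparison/hr/lo/hi/unstable), `km` (data.frame per
#'   group: time, n_risk, n_event, surv), `endpoint`, `n`.
#' @export
compare_survival <- function(strat, surv, endpoint = NULL) {
  if (!is.null(endpoint)) surv <- surv[surv$endpoint == endpoint, , drop = FALSE]
  ids <- intersect(names(strat$group), surv$sample_id)
  s <- surv[match(ids, surv$sample_id), , drop = FALSE]
  grp <- droplevels(strat$group[ids])
  has_event <- tapply(s$event, grp, sum)
  if (length(unique(grp)) < 2L || sum(has_event > 0, na.rm = TRUE) < 2L)
    .stopf("need >= 2 groups with >= 1 event each")
  sd_fit <- survival::survdiff(survival::Surv(s$time, s$event) ~ grp)
  df <- length(unique(grp)) - 1L
  p <- pchisq(sd_fit$chisq, df = df, lower.tail = FALSE)
  pairs <- list(c("High", "Low"), c("High", "Medium"), c("Medium", "Low"))
  hr <- do.call(rbind, lapply(pairs, function(pr) {
    if (!all(pr %in% levels(grp))) return(NULL)
    h <- .pair_hr(s$time, s$event, as.character(grp), pr[1L], pr[2L])
    data.frame(comparison = paste(pr, collapse = "/"), hr = h$hr, lo = h$lo,
               hi = h$hi, unstable = h$unstable, stringsAsFactors = FALSE)
  }))
  kf <- survival::survfit(survival::Surv(s$time, s$event) ~ grp)
  km <- data.frame(group = rep(sub("^grp=", "", names(kf$strata)), kf$strata),
                   time = kf$time, n_risk = kf$n.risk, n_event = kf$n.event,
                   surv = kf$surv, stringsAsFactors = FALSE)
  structure(list(logrank_p = p, logrank_chisq = sd_fit$chisq, hr = hr, km = km,
                 endpoint = endpoint %||% unique(s$endpoint)[1L],
                 n = length(ids)),
            class = "survival_comparison")
}

#' Stratify and compare survival for a set of signatures
#'
#' For each signature and endpoint: z-score the signature genes, k-means the
#' samples into `k` risk groups, and compare survival. Signatures with fewer
#' than two mapped genes are skipped with a warning.
#'
#' @param expr gene x sample matrix.
#' @param surv survival table (may hold several endpoints).
#' @param signatures named list of gene-id vectors.
#' @param k groups (default 3).
#' @param seed k-means seed.
#' @return data.frame: signature, endpoint, n, logrank_p, hr_high_low,
#'   hr_high_med, hr_med_low, degenerate.
#' @export
evaluate_signatures <- function(expr, surv, signatures, k = 3L, seed = 7L) {
  out <- list()
  for (nm in names(signatures)) {
    genes <- intersect(signatures[[nm]], rownames(expr))
    if (length(genes) < 2L) {
      .warnf("signature %s has < 2 mapped genes; skipped", nm)
      next
    }
    z <- suppressWarnings(zscore_by_gene(expr, genes))
    for (ep in unique(surv$endpoint)) {
      sv <- surv[surv$endpoint == ep, , drop = FALSE]
      strat <- cluster_patients(z[, colnames(z) %in% sv$sample_id, drop = FALSE],
                                sv, k = k, seed = seed)
      cmp <- compare_survival(strat, sv)
      get_hr <- function(cm) {
        r <- cmp$hr[cmp$hr$comparison == cm, "hr"]
        if (length(r)) r else NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        signature = nm, endpoint = ep, n = cmp$n, logrank_p = cmp$logrank_p,
        hr_high_low = get_hr("High/Low"), hr_high_med = get_hr("High/Medium"),
        hr_med_low = get_hr("Medium/Low"), degenerate = strat$degenerate,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(signature = character(0), endpoint = character(0),
                      n = integer(0), logrank_p = numeric(0),
                      hr_high_low = numeric(0), hr_high_med = numeric(0),
                      hr_med_low = numeric(0), degenerate = logical(0)))
  do.call(rbind, out)
}
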