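# matcher tests run on the default synthetic cohort: 600 genes / 150 CNV
# blocks, beta = 1 (see sim_config)

test_that("cis-gene selection recovers planted cis genes and excludes constants", {
  co <- simulate_cohort(sim_config(seed = 31))
  cis <- select_cis_genes(co$expr, co$cnv, fdr = 0.01)
  truth <- names(co$truth$cis_genes)
  expect_gte(mean(truth %in% cis), 0.9)

  expr <- co$expr
  cnv <- co$cnv
  cnv["g001", ] <- 0.3  # constant CNV: correlation undefined, must be excluded
  cis2 <- select_cis_genes(expr, cnv)
  expect_false("g001" %in% cis2)
  expect_false("g001" %in% attr(cis2, "table")$gene_id)
})

test_that("cis selection under the null flags about the FDR-level fraction", {
  co <- simulate_cohort(sim_config(n_genes = 2000, n_samples = 100,
                                   n_blocks = 500, frac_cis = 0, edge_density = 0,
                                   include_markers = FALSE, seed = 17))
  cis <- select_cis_genes(co$expr, co$cnv, fdr = 0.05)
  # under the complete null BH keeps the false positive fraction near zero;
  # the count must stay tiny (binomial bound at alpha on 2000 genes)
  expect_lte(length(cis), 10L)
})

test_that("select_cis_genes refuses tiny sample overlap", {
  m <- toy_matrix(20, 5)
  expect_error(select_cis_genes(m, m), ">= 10 shared samples")
})

test_that("similarity matrix is diagonally dominant and tracks injected swaps", {
  co <- simulate_cohort(sim_config(seed = 8))
  cis <- select_cis_genes(co$expr, co$cnv)
  sim <- similarity_matrix(co$expr, co$cnv, cis)
  S <- sim$S
  # self-similarity wins its row and column for (almost) all samples
  frac_dom <- mean(vapply(seq_len(nrow(S)), function(i)
    which.max(S[i, ]) == i && which.max(S[, i]) == i, logical(1)))
  expect_gte(frac_dom, 0.97)

  swapped <- inject_swaps(co$cnv, cbind("s005", "s017"))
  S2 <- similarity_matrix(co$expr, swapped, cis)$S
  expect_identical(colnames(S2)[which.max(S2["s005", ])], "s017")
  expect_identical(colnames(S2)[which.max(S2["s017", ])], "s005")
  expect_lt(S2["s005", "s005"], S2["s005", "s017"])
})

test_that("similarity matrix is equivariant under sample permutation", {
  co <- simulate_cohort(sim_config(n_genes = 100, n_samples = 40, n_blocks = 25,
                                   include_markers = FALSE, seed = 12))
  cis <- select_cis_genes(co$expr, co$cnv)
  S <- suppressWarnings(similarity_matrix(co$expr, co$cnv, cis))$S
  perm <- sample(colnames(co$expr))
  S2 <- suppressWarnings(similarity_matrix(co$expr[, perm], co$cnv[, perm], cis))$S
  expect_equal(S2, S[perm, perm], tolerance = 1e-12)
})

test_that("classify_matches handles clean, degenerate, and swapped cases", {
  ids <- sprintf("x%02d", 1:20)
  # identity-like S: strong diagonal
  S <- matrix(rnorm(400, 0, 0.05), 20, 20, dimnames = list(ids, ids))
  diag(S) <- 0.9
  rep <- classify_matches(structure(list(S = S, cis = letters),
                                    class = "similarity_matrix"))
  expect_setequal(rep$self_matched, ids)
  expect_identical(nrow(rep$cross_matched), 0L)

  # all-zero S: nothing is significant
  S0 <- matrix(0, 20, 20, dimnames = list(ids, ids))
  rep0 <- classify_matches(structure(list(S = S0, cis = letters),
                                     class = "similarity_matrix"))
  expect_setequal(rep0$unmatched, ids)

  # one swapped pair: mutual off-diagonal maxima
  S1 <- S
  S1[1, 1] <- S1[2, 2] <- 0.01
  S1[1, 2] <- S1[2, 1] <- 0.9
  rep1 <- classify_matches(structure(list(S = S1, cis = letters),
                                     class = "similarity_matrix"))
  expect_identical(sort(rep1$cross_matched$expr_sample), c("x01", "x02"))
  expect_identical(rep1$cross_matched$cnv_sample[
    rep1$cross_matched$expr_sample == "x01"], "x02")
})

test_that("iterate_matching corrects injected swaps and reaches a fixed point", {
  co <- simulate_cohort(sim_config(swap_frac = 0.05, seed = 23))
  rep <- suppressWarnings(iterate_matching(co$expr, co$cnv))
  tp <- co$truth$swap_pairs
  truth_map <- c(setNames(tp[, 2], tp[, 1]), setNames(tp[, 1], tp[, 2]))
  corr <- setNames(rep$corrections$cnv_column, rep$corrections$expr_sample)
  # single-seed bound; the 95% aggregate over 20 seeds is an acceptance test
  expect_gte(sum(names(corr) %in% names(truth_map) &
                   corr == truth_map[names(corr)]), 0.8 * length(truth_map))
  expect_identical(sum(!(names(corr) %in% names(truth_map))), 0L)
  expect_true(rep$converged)

  # idempotence: rerunning on corrected data changes nothing
  rep2 <- suppressWarnings(iterate_matching(co$expr, rep$corrected_cnv))
  expect_identical(nrow(rep2$corrections), 0L)
  # correcting real swaps cannot lose cis associations
  expect_gte(rep$cis_counts[rep$n_iter], rep$cis_counts[1L])
})

test_that("swap-free cohorts converge immediately with identity pairing", {
  co <- simulate_cohort(sim_config(swap_frac = 0, seed = 37))
  rep <- suppressWarnings(iterate_matching(co$expr, co$cnv))
  expect_identical(rep$n_iter, 1L)
  expect_true(rep$converged)
  expect_identical(nrow(rep$corrections), 0L)
  expect_identical(unname(rep$pairing), names(rep$pairing))
})

test_that("no false corrections on swap-free cohorts across 50 seeds", {
  n_false <- vapply(1:50, function(seed) {
    co <- simulate_cohort(sim_config(swap_frac = 0, include_markers = FALSE,
                                     seed = seed))
    rep <- suppressWarnings(iterate_matching(co$expr, co$cnv))
    nrow(rep$corrections)
  }, integer(1))
  expect_identical(sum(n_false), 0L)
})

test_that("classify_matches is permutation-equivariant in sample labels", {
  set.seed(77)
  ids <- sprintf("q%02d", 1:15)
  S <- matrix(rnorm(225, 0, 0.1), 15, 15, dimnames = list(ids, ids))
  diag(S) <- 0.8
  S[3, 3] <- S[9, 9] <- 0; S[3, 9] <- S[9, 3] <- 0.8  # one swapped pair
  rep1 <- classify_matches(structure(list(S = S), class = "similarity_matrix"))
  perm <- sample(ids)
  rep2 <- classify_matches(structure(list(S = S[perm, perm]),
                                     class = "similarity_matrix"))
  expect_setequal(rep1$self_matched, rep2$self_matched)
  expect_setequal(
    paste(rep1$cross_matched$expr_sample, rep1$cross_matched$cnv_sample),
    paste(rep2$cross_matched$expr_sample, rep2$cross_matched$cnv_sample))
})

test_that("sex inference recovers planted labels and degrades gracefully", {
  co <- simulate_cohort(sim_config(seed = 41))
  calls <- infer_sex(co$expr)
  truth <- co$truth$sex
  called <- calls != "NoCall"
  expect_gte(mean(calls[called] == truth[names(calls)[called]]), 0.98)
  expect_gte(mean(called), 0.9)

  expect_warning(calls2 <- infer_sex(co$expr[setdiff(rownames(co$expr), "XIST"), ]),
                 "XIST")
  expect_true(all(calls2 == "NoCall"))

  flat <- matrix(1, 3, 10, dimnames = list(c("XIST", "RPS4Y1", "g1"),
                                           paste0("s", 1:10)))
  expect_true(all(infer_sex(flat) == "NoCall"))
})

test_that("isotype inference calls the dominant marker set with a margin", {
  co <- simulate_cohort(sim_config(seed = 43))
  sets <- list(IgG = "IGHG1", IgA = "IGHA1")
  calls <- infer_isotype(co$expr, sets)
  truth <- co$truth$isotype
  called <- calls != "NoCall"
  expect_gte(mean(calls[called] == truth[names(calls)[called]]), 0.98)

  m <- matrix(c(2, 2), 2, 1, dimnames = list(c("A1", "B1"), "s1"))
  expect_identical(unname(infer_isotype(m, list(A = "A1", B = "B1"))), "NoCall")
  expect_error(infer_isotype(m, list(A = character(0))), "empty")
})

test_that("hyperdiploidy calls need gains on the listed chromosomes", {
  genes <- sprintf("g%02d", 1:40)
  ann <- data.frame(gene_id = genes,
                    chrom = rep(c("3", "5", "7", "9", "2"), each = 8),
                    start = 1L, end = 10L, strand = "+")
  cnv <- matrix(0, 40, 3, dimnames = list(genes, c("neutral", "hyper", "offtarget")))
  cnv[ann$chrom %in% c("3", "5", "7", "9"), "hyper"] <- 0.4
  cnv[ann$chrom == "2", "offtarget"] <- 0.4  # chromosome 2 is not in the set
  calls <- suppressWarnings(infer_hyperdiploidy(cnv, ann))
  expect_false(calls[["neutral"]])
  expect_true(calls[["hyper"]])
  expect_false(calls[["offtarget"]])
})

test_that("error-layer attribution votes with metadata concordance", {
  pairs <- data.frame(expr_sample = "p1", cnv_sample = "p2",
                      stringsAsFactors = FALSE)
  clinical <- data.frame(sex = "Female", row.names = "p1")
  em_ok <- data.frame(sex = "Female", row.names = "p1")
  em_bad <- data.frame(sex = "Male", row.names = "p1")
  cm <- data.frame(hyperdiploid = TRUE, row.names = "p1")[0, , drop = FALSE]
  expect_identical(attribute_error_layer(pairs, em_ok, cm, clinical)$error_layer,
                   "CNV")
  expect_identical(attribute_error_layer(pairs, em_bad, cm, clinical)$error_layer,
                   "expression")
  expect_identical(attribute_error_layer(pairs, em_ok[0, , drop = FALSE], cm,
                                         clinical)$error_layer, "unknown")
})
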