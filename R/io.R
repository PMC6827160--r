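## Readers/writers for the plain-text formats the pipeline touches, and the
## segment -> gene-level copy-number mapping. Coordinates are 1-based
## inclusive throughout (UCSC refGene convention). Missing values are "NA"
## on disk and NA internally; nothing is imputed.

#' Read a gene x sample matrix from TSV
#'
#' First column holds gene identifiers, header row holds sample identifiers.
#' Used for both expression (log2 scale) and gene-level CNV log-ratios.
#'
#' @param path TSV file path.
#' @return Numeric matrix with gene rownames and sample colnames, in file
#'   order. Missing cells ("NA") become `NA`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) .stopf("malformed matrix file (need gene column + >=1 sample): %s", path)
  genes <- as.character(df[[1L]])
  dup <- genes[duplicated(genes)]
  if (length(dup)) .stopf("duplicate gene id(s): %s", paste(unique(dup), collapse = ", "))
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) .stopf("duplicate sample id(s) in header")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2L, as.numeric))) &
                   !is.na(as.matrix(df[, -1L, drop = FALSE])), arr.ind = TRUE)
    .stopf("non-numeric cell(s), first at gene '%s'", genes[bad[1L, 1L]])
  }
  if (any(is.infinite(m))) .stopf("non-finite values in matrix")
  dimnames(m) <- list(genes, samples)
  m
}

#' Write a gene x sample matrix as TSV
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param id_col header label for the gene-id column.
#' @export
write_expression <- function(m, path, id_col = "gene_id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read CBS segments in SEG format
#'
#' Expects the conventional columns `ID`, `chrom`, `loc.start`, `loc.end`,
#' `seg.mean` (header names are matched case-insensitively by prefix).
#' Coordinates are 1-based inclusive.
#'
#' @param path SEG/TSV file path.
#' @return data.frame with columns sample, chrom, start, end, logR.
#' @export
read_seg <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 5L) .stopf("SEG file needs >= 5 columns: %s", path)
  out <- data.frame(sample = as.character(df[[1L]]),
                    chrom  = as.character(df[[2L]]),
                    start  = as.integer(df[[3L]]),
                    end    = as.integer(df[[4L]]),
                    logR   = as.numeric(df[[5L]]),
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$logR))) .stopf("non-finite seg.mean in %s", path)
  if (any(out$start > out$end)) .stopf("segment with start > end in %s", path)
  ## non-overlap within sample/chromosome is an invariant of CBS output
  sp <- split(out, list(out$sample, out$chrom), drop = TRUE)
  for (s in sp) {
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)]))
      .stopf("overlapping segments for sample %s chrom %s", s$sample[1L], s$chrom[1L])
  }
  out
}

#' Write segments in SEG format
#' @param segs data.frame as returned by [read_seg()].
#' @param path output path.
#' @export
write_seg <- function(segs, path) {
  df <- data.frame(ID = segs$sample, chrom = segs$chrom,
                   loc.start = segs$start, loc.end = segs$end,
                   seg.mean = segs$logR)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene coordinate annotation (BED-like TSV)
#'
#' Columns: gene_id, chrom, start, end, strand; 1-based inclusive.
#' @param path TSV path.
#' @return data.frame with those columns.
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  colnames(df)[1:5] <- c("gene_id", "chrom", "start", "end", "strand")
  if (anyDuplicated(df$gene_id)) .stopf("duplicate gene_id in annotation")
  if (any(df$start > df$end)) .stopf("annotation with start > end")
  df
}

#' @rdname read_annotation
#' @param ann annotation data.frame.
#' @export
write_annotation <- function(ann, path) {
  write.table(ann[, c("gene_id", "chrom", "start", "end", "strand")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map copy-number segments to gene-level log-ratios
#'
#' Each gene's value in a sample is the length-weighted mean logR of the
#' segments overlapping the gene body (strand ignored: copy number is
#' strand-agnostic). Genes with no overlapping segment in a sample are NA.
#'
#' @param segs data.frame from [read_seg()].
#' @param ann annotation data.frame from [read_annotation()].
#' @param samples character vector of sample ids to produce columns for;
#'   defaults to the samples present in `segs`.
#' @return gene x sample numeric matrix of log-ratios.
#' @export
map_segments_to_genes <- function(segs, ann, samples = NULL) {
  if (nrow(ann) == 0L) .stopf("annotation covers no genes")
  if (is.null(samples)) samples <- unique(segs$sample)
  out <- matrix(NA_real_, nrow(ann), length(samples),
                dimnames = list(ann$gene_id, samples))
  seg_by <- split(segs, segs$sample)
  for (s in samples) {
    ss <- seg_by[[s]]
    if (is.null(ss) || nrow(ss) == 0L) {
      .warnf("no segments for sample %s; gene CNVs set to NA", s)
      next
    }
    by_chr <- split(ss, ss$chrom)
    for (g in seq_len(nrow(ann))) {
      cs <- by_chr[[ann$chrom[g]]]
      if (is.null(cs)) next
      ov_start <- pmax(cs$start, ann$start[g])
      ov_end <- pmin(cs$end, ann$end[g])
      w <- ov_end - ov_start + 1
      keep <- w > 0
      if (any(keep))
        out[g, s] <- sum(w[keep] * cs$logR[keep]) / sum(w[keep])
    }
  }
  out
}

#' Read gene-set signatures from a GMT file
#'
#' Lines are `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes
#' within a set are collapsed.
#'
#' @param path GMT path.
#' @return named list of character vectors (gene ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sigs <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(f) < 3L || length(genes) == 0L)
      .stopf("GMT line %d ('%s') has an empty gene list", i, f[1L])
    sigs[[f[1L]]] <- genes
  }
  sigs
}

#' @rdname read_gmt
#' @param sigs named list of gene-id vectors.
#' @export
write_gmt <- function(sigs, path) {
  lines <- vapply(names(sigs), function(nm)
    paste(c(nm, nm, sigs[[nm]]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write survival tables
#'
#' TSV with columns sample_id, time (days, > 0), event (0/1), endpoint
#' (e.g. "OS" or "PFS").
#' @param path TSV path.
#' @return data.frame with those columns.
#' @export
read_survival <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  colnames(df)[1:4] <- c("sample_id", "time", "event", "endpoint")
  if (any(df$time <= 0)) .stopf("non-positive survival time")
  if (!all(df$event %in% c(0L, 1L))) .stopf("event must be 0/1")
  if (anyDuplicated(df[, c("sample_id", "endpoint")]))
    .stopf("duplicate (sample, endpoint) row in survival table")
  df
}

#' @rdname read_survival
#' @param surv survival data.frame.
#' @export
write_survival <- function(surv, path) {
  write.table(surv[, c("sample_id", "time", "event", "endpoint")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a consensus network as SIF and TSV edge list
#'
#' SIF rows are `src<TAB>regulates<TAB>dst` in lexicographic (src, dst)
#' order; the TSV adds the edge posterior frequency.
#'
#' @param net a `consensus_network` (see [consensus()]).
#' @param sif_path,tsv_path output paths (either may be NULL to skip).
#' @export
write_network <- function(net, sif_path = NULL, tsv_path = NULL) {
  e <- net$edges
  ord <- order(e$from, e$to)
  e <- e[ord, , drop = FALSE]
  if (!is.null(sif_path))
    writeLines(paste(e$from, "regulates", e$to, sep = "\t"), sif_path)
  if (!is.null(tsv_path)) {
    df <- data.frame(from = e$from, to = e$to, frequency = e$frequency)
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(net)
}

#' Read a network edge list (TSV with from, to, frequency)
#' @param tsv_path path written by [write_network()].
#' @return a `consensus_network`.
#' @export
read_network <- function(tsv_path) {
  df <- read.delim(tsv_path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  colnames(df)[1:3] <- c("from", "to", "frequency")
  new_consensus_network(df, threshold = NA_real_, n_runs = NA_integer_)
}
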