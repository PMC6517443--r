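# Shared domain types and generic statistics used by every pipeline stage.
#
# Coordinate convention: all intervals are 0-based half-open [start, end);
# 1-based inputs (GTF) are converted at the I/O boundary. Interval tables are
# data.frames with columns chrom, start, end and optionally strand.

#' Coefficient of variation
#'
#' Sample standard deviation (denominator n - 1) divided by the mean. This is
#' the tissue-variability statistic used to separate ubiquitously expressed
#' (housekeeping) genes from tissue-restricted ones.
#'
#' @param values Numeric vector of non-negative values (e.g. per-tissue FPKM).
#' @return The CV, or `NA_real_` when it is undefined (mean of zero, or fewer
#'   than two values).
#' @examples
#' coefficient_of_variation(c(1, 2, 3, 4))
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) == 0L) stop("`values` must be non-empty")
  if (anyNA(values)) stop("`values` must not contain NA")
  if (any(values < 0)) stop("`values` must be non-negative")
  if (length(values) < 2L) return(NA_real_)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  stats::sd(values) / m
}

#' Validate a 0-based half-open interval table
#'
#' @param x data.frame with columns `chrom`, `start`, `end` and optionally
#'   `strand` (one of `+`, `-`, `.`).
#' @return `x`, invisibly, after validation.
#' @export
validate_intervals <- function(x) {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stop("interval table needs columns chrom, start, end")
  if (nrow(x) > 0) {
    if (anyNA(x$start) || anyNA(x$end)) stop("interval coordinates must not be NA")
    if (any(x$start < 0)) stop("interval start must be >= 0")
    if (any(x$end <= x$start)) stop("intervals must satisfy end > start")
    if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", ".")))
      stop("strand must be one of '+', '-', '.'")
  }
  invisible(x)
}

# Convert a 0-based half-open interval table to GRanges (1-based closed).
as_granges0 <- function(x) {
  validate_intervals(x)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Total number of bases covered by both interval sets
#'
#' Bases covered by both `a` and `b` are counted once each, under 0-based
#' half-open semantics (abutting intervals share no base).
#'
#' @param a,b Interval tables (`chrom`, `start`, `end`).
#' @return Integer number of shared bases.
#' @examples
#' a <- data.frame(chrom = "chr1", start = c(0, 20), end = c(10, 30))
#' b <- data.frame(chrom = "chr1", start = 5, end = 25)
#' intersect_length(a, b) # 10
#' @export
intersect_length <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  ga <- GenomicRanges::reduce(as_granges0(a))
  gb <- GenomicRanges::reduce(as_granges0(b))
  ov <- GenomicRanges::intersect(ga, gb, ignore.strand = TRUE)
  sum(GenomicRanges::width(ov))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false discovery rate adjustment; output preserves input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, each `>=` its p-value and `<=` 1.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values)) stop("p-values must not be NA")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

new_stat_test <- function(statistic, p_value, method) {
  structure(
    list(statistic = unname(statistic), p_value = unname(p_value), method = method),
    class = "stat_test"
  )
}

#' @export
print.stat_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic),
      ", p = ", format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration for small untied samples, normal approximation with
#' midranks and tie correction otherwise (via [stats::wilcox.test()]).
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return A `stat_test` with the rank-sum statistic and two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("both samples need length >= 2")
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  new_stat_test(wt$statistic, wt$p.value, "Wilcoxon rank-sum")
}

#' Multi-tissue expression matrix
#'
#' Container for a genes-by-samples matrix of non-negative abundance values
#' (FPKM-like units) with a tissue label per sample.
#'
#' @param values Numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param tissue_of_sample Named character vector mapping each sample id to a
#'   tissue label. Defaults to one tissue per sample.
#' @return An object of class `expr_matrix`: list with elements `values` and
#'   `tissue`.
#' @export
expression_matrix <- function(values, tissue_of_sample = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (anyNA(values)) stop("`values` must not contain NA")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (is.null(tissue_of_sample))
    tissue_of_sample <- stats::setNames(colnames(values), colnames(values))
  missing <- setdiff(colnames(values), names(tissue_of_sample))
  if (length(missing))
    stop("samples without a tissue label: ", paste(missing, collapse = ", "))
  structure(
    list(values = values, tissue = tissue_of_sample[colnames(values)]),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expression matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", length(unique(x$tissue)), " tissues)\n", sep = "")
  invisible(x)
}

#' Gene model table
#'
#' One row per exon, 0-based half-open coordinates. Overlapping exons of a
#' gene (e.g. across transcripts) are merged so each gene's exons are sorted
#' and pairwise disjoint.
#'
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype` (one of `protein_coding`, `lincRNA`, `other`).
#' @return data.frame of class `gene_models` with merged, sorted exons.
#' @export
gene_models <- function(exons) {
  need <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
  if (!all(need %in% names(exons)))
    stop("exon table needs columns: ", paste(need, collapse = ", "))
  validate_intervals(exons)
  if (!all(exons$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  if (!all(exons$biotype %in% c("protein_coding", "lincRNA", "other")))
    stop("biotype must be protein_coding, lincRNA or other")
  per_gene <- unique(exons[, c("gene_id", "chrom", "strand", "biotype")])
  if (anyDuplicated(per_gene$gene_id))
    stop("a gene must have a single chrom/strand/biotype")
  merged <- do.call(rbind, lapply(split(exons, exons$gene_id), function(g) {
    ir <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    data.frame(
      gene_id = g$gene_id[1], chrom = g$chrom[1],
      start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
      strand = g$strand[1], biotype = g$biotype[1],
      stringsAsFactors = FALSE
    )
  }))
  rownames(merged) <- NULL
  merged <- merged[order(merged$gene_id, merged$start), ]
  class(merged) <- c("gene_models", "data.frame")
  merged
}

#' Per-gene span and strand-aware TSS
#'
#' The gene span is \[min exon start, max exon end); the transcription start
#' site is the 5' end of the span (span start on `+`, span end on `-`).
#'
#' @param models A `gene_models` table.
#' @return data.frame with one row per gene: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `biotype`, `tss`, `exonic_length`.
#' @export
gene_spans <- function(models) {
  out <- do.call(rbind, lapply(split(models, models$gene_id), function(g) {
    data.frame(
      gene_id = g$gene_id[1], chrom = g$chrom[1],
      start = min(g$start), end = max(g$end),
      strand = g$strand[1], biotype = g$biotype[1],
      exonic_length = sum(g$end - g$start),
      stringsAsFactors = FALSE
    )
  }))
  out$tss <- ifelse(out$strand == "-", out$end, out$start)
  rownames(out) <- NULL
  out
}
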