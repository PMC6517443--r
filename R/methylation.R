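# Stage 5: promoter-window probe aggregation to gene-level methylation betas
# and group-median comparison between gene sets.

#' Promoter windows around strand-aware TSSs
#'
#' The window spans `upstream` bases before to `downstream` bases after the
#' TSS, reflected through the TSS on the minus strand: `+` gives
#' \[tss - upstream, tss + downstream) and `-` gives
#' \[tss - downstream, tss + upstream), clipped at 0. With
#' `strand_aware = FALSE` every gene uses the `+` orientation.
#'
#' @param genes A `gene_models` table or [gene_spans()] output.
#' @param upstream,downstream Window extent in bp (defaults 2000 and 200).
#' @param strand_aware Reflect the window on minus-strand genes (default).
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
promoter_window <- function(genes, upstream = 2000, downstream = 200,
                            strand_aware = TRUE) {
  spans <- if ("tss" %in% names(genes)) genes else gene_spans(genes)
  minus <- strand_aware & spans$strand == "-"
  start <- ifelse(minus, spans$tss - downstream, spans$tss - upstream)
  end <- ifelse(minus, spans$tss + upstream, spans$tss + downstream)
  data.frame(
    gene_id = spans$gene_id, chrom = spans$chrom,
    start = pmax(start, 0), end = end, strand = spans$strand,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Aggregate probe betas to gene-level promoter methylation
#'
#' Per gene and sample, the arithmetic mean of all probes whose position
#' falls inside the gene's promoter window (half-open: a probe exactly at the
#' window end is outside). Genes with no probe in the window are absent from
#' the output, not zero-filled.
#'
#' @param probe_betas Numeric matrix (probes x samples) of betas in \[0, 1\].
#' @param probe_coords data.frame `probe_id`, `chrom`, `pos` (0-based).
#' @param genes A `gene_models` table or [gene_spans()] output.
#' @param ... Passed to [promoter_window()].
#' @return List with `betas` (gene x sample matrix) and `n_probes` (named
#'   integer vector of contributing probes per gene).
#' @export
gene_level_beta <- function(probe_betas, probe_coords, genes, ...) {
  if (!is.matrix(probe_betas)) stop("`probe_betas` must be a matrix")
  if (any(probe_betas < 0 | probe_betas > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  win <- promoter_window(genes, ...)
  coords <- probe_coords[match(rownames(probe_betas), probe_coords$probe_id), ]
  if (anyNA(coords$pos)) stop("probes without coordinates")
  gw <- as_granges0(win)
  gp <- GenomicRanges::GRanges(coords$chrom,
                               IRanges::IRanges(coords$pos + 1L, width = 1L))
  ov <- GenomicRanges::findOverlaps(gp, gw, ignore.strand = TRUE)
  if (length(ov) == 0L)
    return(list(betas = matrix(numeric(0), 0, ncol(probe_betas),
                               dimnames = list(NULL, colnames(probe_betas))),
                n_probes = integer(0)))
  gene_of_hit <- win$gene_id[S4Vectors::subjectHits(ov)]
  probe_of_hit <- S4Vectors::queryHits(ov)
  genes_hit <- unique(gene_of_hit)
  betas <- matrix(NA_real_, length(genes_hit), ncol(probe_betas),
                  dimnames = list(genes_hit, colnames(probe_betas)))
  for (g in genes_hit)
    betas[g, ] <- colMeans(probe_betas[probe_of_hit[gene_of_hit == g], ,
                                       drop = FALSE])
  n_probes <- vapply(genes_hit, function(g) sum(gene_of_hit == g), 0L)
  list(betas = betas, n_probes = n_probes)
}

#' Compare per-sample median methylation between two gene groups
#'
#' For every sample, the median gene-level beta is computed over each gene
#' group; because the same samples index both medians, the primary test is a
#' paired two-sided Wilcoxon signed-rank across samples, with the unpaired
#' rank-sum reported as secondary.
#'
#' @param gene_betas Output of [gene_level_beta()] (or a gene x sample
#'   matrix).
#' @param group_a_genes,group_b_genes Gene id vectors; both must intersect
#'   the table.
#' @return List with `medians` (data.frame `sample`, `median_a`, `median_b`),
#'   `paired` and `unpaired` (`stat_test` objects).
#' @export
group_median_comparison <- function(gene_betas, group_a_genes, group_b_genes) {
  m <- if (is.list(gene_betas) && !is.data.frame(gene_betas)) gene_betas$betas
       else gene_betas
  a <- intersect(group_a_genes, rownames(m))
  b <- intersect(group_b_genes, rownames(m))
  if (length(a) == 0L || length(b) == 0L)
    stop("both gene groups must be present in the table")
  med_a <- apply(m[a, , drop = FALSE], 2L, stats::median)
  med_b <- apply(m[b, , drop = FALSE], 2L, stats::median)
  paired <- suppressWarnings(
    stats::wilcox.test(med_a, med_b, paired = TRUE, alternative = "two.sided"))
  unpaired <- suppressWarnings(
    stats::wilcox.test(med_a, med_b, alternative = "two.sided"))
  list(
    medians = data.frame(sample = colnames(m), median_a = unname(med_a),
                         median_b = unname(med_b), stringsAsFactors = FALSE),
    paired = new_stat_test(paired$statistic,
                           ifelse(is.nan(paired$p.value), 1, paired$p.value),
                           "Wilcoxon signed-rank (paired)"),
    unpaired = new_stat_test(unpaired$statistic, unpaired$p.value,
                             "Wilcoxon rank-sum")
  )
}
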