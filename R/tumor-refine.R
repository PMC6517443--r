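# Stage 4: refine candidate housekeeping genes with tumour evidence —
# differential-expression flags, recurrent homozygous deletion, focal-deletion
# overlap — and emit the 'core' housekeeping set.

CNA_CATEGORIES <- c("homdel", "hetloss", "diploid", "gain", "amp")

#' Differential-expression flags across tumour types
#'
#' A gene is flagged down when some tumour type shows log2 FC < -log2(fc_min)
#' with q < q_max (both strict; |FC| > 2 with q < 0.05 by default), and
#' analogously up.
#'
#' @param de_table data.frame with `gene`, `tumour_type`, `log2_fc`, `q`.
#' @param fc_min Linear fold-change threshold (strict).
#' @param q_max q-value threshold (strict).
#' @return data.frame `gene`, `down_any`, `up_any`, `changed_any`.
#' @export
de_flags <- function(de_table, fc_min = 2, q_max = 0.05) {
  need <- c("gene", "tumour_type", "log2_fc", "q")
  if (!all(need %in% names(de_table)))
    stop("DE table needs columns: ", paste(need, collapse = ", "))
  lfc <- log2(fc_min)
  sig <- de_table$q < q_max
  genes <- unique(de_table$gene)
  f <- factor(de_table$gene, levels = genes)
  down <- tapply(sig & de_table$log2_fc < -lfc, f, any)
  up <- tapply(sig & de_table$log2_fc > lfc, f, any)
  data.frame(gene = genes, down_any = as.logical(down), up_any = as.logical(up),
             changed_any = as.logical(down | up),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Recurrent homozygous deletion
#'
#' True when the fraction of samples in the homozygous-deletion category is
#' at least `min_fraction` (inclusive). By default samples are pooled across
#' tumour types; with `sample_types`, recurrence within any single type
#' suffices.
#'
#' @param cna Character matrix (genes x samples) of copy-number categories
#'   among homdel/hetloss/diploid/gain/amp; NA allowed.
#' @param min_fraction Recurrence threshold (inclusive).
#' @param sample_types Optional character vector (one per sample column);
#'   when supplied, the fraction is computed per type.
#' @return Named logical vector over genes.
#' @export
recurrent_deletion <- function(cna, min_fraction = 0.01, sample_types = NULL) {
  if (!is.matrix(cna)) stop("`cna` must be a genes x samples matrix")
  vals <- cna[!is.na(cna)]
  if (!all(vals %in% CNA_CATEGORIES))
    stop("unknown copy-number category: ",
         paste(unique(setdiff(vals, CNA_CATEGORIES)), collapse = ", "))
  homdel <- cna == "homdel"
  if (is.null(sample_types)) {
    frac <- rowMeans(homdel, na.rm = TRUE)
    return(frac >= min_fraction)
  }
  if (length(sample_types) != ncol(cna))
    stop("`sample_types` must have one entry per sample")
  hit <- rep(FALSE, nrow(cna))
  for (tt in unique(sample_types)) {
    frac <- rowMeans(homdel[, sample_types == tt, drop = FALSE], na.rm = TRUE)
    hit <- hit | frac >= min_fraction
  }
  stats::setNames(hit, rownames(cna))
}

#' Overlap of gene spans with focal deletion regions
#'
#' Any shared base (>= 1 bp, half-open semantics: abutting regions do not
#' count) between a gene span and a deletion-type focal region is a hit.
#'
#' @param genes A `gene_models` table or [gene_spans()] output.
#' @param focal_regions data.frame `chrom`, `start`, `end`, `type` (amp/del)
#'   and optionally `region_id`.
#' @return data.frame `gene_id`, `region_ids` (comma-separated, "" if none),
#'   `in_focal_deletion`.
#' @export
focal_overlap <- function(genes, focal_regions) {
  spans <- if ("exonic_length" %in% names(genes)) genes else gene_spans(genes)
  if (!all(c("chrom", "start", "end", "type") %in% names(focal_regions)))
    stop("focal regions need chrom, start, end, type")
  dels <- focal_regions[focal_regions$type == "del", , drop = FALSE]
  if (is.null(dels$region_id)) dels$region_id <- sprintf("del%03d", seq_len(nrow(dels)))
  res <- data.frame(gene_id = spans$gene_id, region_ids = "",
                    in_focal_deletion = FALSE, stringsAsFactors = FALSE)
  if (nrow(dels) == 0L || nrow(spans) == 0L) return(res)
  ov <- GenomicRanges::findOverlaps(as_granges0(spans), as_granges0(dels),
                                    ignore.strand = TRUE, minoverlap = 1L)
  if (length(ov)) {
    hits <- tapply(dels$region_id[S4Vectors::subjectHits(ov)],
                   factor(spans$gene_id[S4Vectors::queryHits(ov)],
                          levels = spans$gene_id),
                   paste, collapse = ",")
    got <- !is.na(hits)
    res$region_ids[got] <- hits[got]
    res$in_focal_deletion <- res$region_ids != ""
  }
  res
}

#' Core housekeeping calls from combined tumour evidence
#'
#' A candidate gene is 'core' iff it is not downregulated in any tumour type,
#' not recurrently homozygously deleted, and not inside a focal deletion.
#' Evidence tables may each be omitted (or lack a gene); by default missing
#' evidence passes the gene through (`missing = "pass"`), or set
#' `missing = "exclude"` to drop genes lacking any evidence table.
#'
#' @param chk_genes Character vector of candidate housekeeping gene ids.
#' @param de_table Optional DE table, see [de_flags()].
#' @param cna Optional copy-number matrix, see [recurrent_deletion()].
#' @param gene_annotation Optional `gene_models`/span table (needed with
#'   `focal_regions`).
#' @param focal_regions Optional focal region table, see [focal_overlap()].
#' @param fc_min,q_max,min_fraction Thresholds for the underlying flags.
#' @param missing Policy for genes without evidence: `"pass"` or `"exclude"`.
#' @return data.frame `gene_id`, `downregulated_any`, `deleted_recurrent`,
#'   `in_focal_deletion`, `core`.
#' @export
refine_core_hk <- function(chk_genes, de_table = NULL, cna = NULL,
                           gene_annotation = NULL, focal_regions = NULL,
                           fc_min = 2, q_max = 0.05, min_fraction = 0.01,
                           missing = c("pass", "exclude")) {
  missing <- match.arg(missing)
  out <- data.frame(gene_id = chk_genes, downregulated_any = FALSE,
                    deleted_recurrent = FALSE, in_focal_deletion = FALSE,
                    covered = TRUE, stringsAsFactors = FALSE)
  if (!is.null(de_table)) {
    fl <- de_flags(de_table, fc_min = fc_min, q_max = q_max)
    idx <- match(out$gene_id, fl$gene)
    out$downregulated_any <- !is.na(idx) & fl$down_any[idx] %in% TRUE
    out$covered <- out$covered & !is.na(idx)
  }
  if (!is.null(cna)) {
    rec <- recurrent_deletion(cna, min_fraction = min_fraction)
    idx <- match(out$gene_id, rownames(cna))
    out$deleted_recurrent <- !is.na(idx) & rec[idx] %in% TRUE
    out$covered <- out$covered & !is.na(idx)
  }
  if (!is.null(focal_regions)) {
    if (is.null(gene_annotation))
      stop("focal_regions require gene_annotation")
    fo <- focal_overlap(gene_annotation, focal_regions)
    idx <- match(out$gene_id, fo$gene_id)
    out$in_focal_deletion <- !is.na(idx) & fo$in_focal_deletion[idx] %in% TRUE
    out$covered <- out$covered & !is.na(idx)
  }
  if (missing == "exclude") out <- out[out$covered, , drop = FALSE]
  out$core <- !out$downregulated_any & !out$deleted_recurrent &
    !out$in_focal_deletion
  out$covered <- NULL
  rownames(out) <- NULL
  out
}

#' Two-group differential expression stand-in
#'
#' A deliberately simple stand-in for a count-model DE fit, for synthetic
#' FPKM-like values: per-gene two-sided Welch t-test on log2(x + 1), BH
#' correction, and a fold change from linear group means. External DE tables
#' can be imported instead wherever a `de_table` is consumed.
#'
#' @param matrix An [expression_matrix()] or plain numeric matrix.
#' @param group_labels Two-level factor/character vector over samples; the
#'   fold change is second level over first level.
#' @param fc_min Linear fold-change threshold (strict).
#' @param q_max q-value threshold (strict).
#' @return data.frame `gene`, `log2_fc`, `p`, `q`, `significant`. Genes that
#'   are constant in both groups are excluded with a warning.
#' @export
simple_de <- function(matrix, group_labels, fc_min = 1.5, q_max = 0.05) {
  vals <- if (inherits(matrix, "expr_matrix")) matrix$values else matrix
  groups <- factor(group_labels)
  if (nlevels(groups) != 2L) stop("need exactly two groups")
  if (any(table(groups) < 2L)) stop("need >= 2 samples per group")
  a <- vals[, groups == levels(groups)[1], drop = FALSE]
  b <- vals[, groups == levels(groups)[2], drop = FALSE]
  lg <- log2(vals + 1)
  la <- lg[, groups == levels(groups)[1], drop = FALSE]
  lb <- lg[, groups == levels(groups)[2], drop = FALSE]
  p <- vapply(seq_len(nrow(vals)), function(i) {
    if (stats::sd(la[i, ]) == 0 && stats::sd(lb[i, ]) == 0) return(NA_real_)
    stats::t.test(lb[i, ], la[i, ])$p.value
  }, 0)
  if (anyNA(p))
    warning("excluding constant genes: ",
            paste(rownames(vals)[is.na(p)], collapse = ", "))
  keep <- !is.na(p)
  eps <- 1e-9
  log2_fc <- log2((rowMeans(b) + eps) / (rowMeans(a) + eps))
  out <- data.frame(
    gene = rownames(vals)[keep], log2_fc = log2_fc[keep], p = p[keep],
    q = bh_fdr(p[keep]), stringsAsFactors = FALSE
  )
  out$significant <- abs(out$log2_fc) > log2(fc_min) & out$q < q_max
  rownames(out) <- NULL
  out
}
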