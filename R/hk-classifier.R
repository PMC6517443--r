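# Stage 1: housekeeping / tissue-specific classification from a multi-tissue
# expression matrix, with the intergenic-distance prefilter.

#' Classification thresholds
#'
#' Defaults reproduce the published decision rules: detection at FPKM > 0.5
#' (strict), housekeeping requires detection in >= 75% of tissues with
#' CV < 1.5, tissue-specific requires detection in < 25% of tissues with
#' CV > 3.5, and lincRNAs within 1 kb of a protein-coding gene are excluded.
#'
#' @param detect_threshold Detection cutoff (tissue mean must exceed it).
#' @param hk_min_fraction Minimum detection fraction for HK (inclusive).
#' @param hk_max_cv Maximum CV for HK (strict).
#' @param ts_max_fraction Maximum detection fraction for TS (strict).
#' @param ts_min_cv Minimum CV for TS (strict).
#' @param min_coding_distance Minimum gap (bp, strict) to the nearest
#'   protein-coding gene.
#' @param aggregate Whether CV/detection use per-tissue means of a tissue's
#'   samples (`"tissue_mean"`, default) or pooled samples (`"pooled"`).
#' @param log_scale If `TRUE`, CV is computed on log2(x + 1) values.
#' @return A validated list of class `hk_class_params`.
#' @export
hk_class_params <- function(detect_threshold = 0.5, hk_min_fraction = 0.75,
                            hk_max_cv = 1.5, ts_max_fraction = 0.25,
                            ts_min_cv = 3.5, min_coding_distance = 1000,
                            aggregate = c("tissue_mean", "pooled"),
                            log_scale = FALSE) {
  aggregate <- match.arg(aggregate)
  if (!(ts_max_fraction > 0 && ts_max_fraction < hk_min_fraction &&
        hk_min_fraction <= 1))
    stop("need 0 < ts_max_fraction < hk_min_fraction <= 1")
  if (!(hk_max_cv < ts_min_cv)) stop("need hk_max_cv < ts_min_cv")
  structure(list(
    detect_threshold = detect_threshold, hk_min_fraction = hk_min_fraction,
    hk_max_cv = hk_max_cv, ts_max_fraction = ts_max_fraction,
    ts_min_cv = ts_min_cv, min_coding_distance = min_coding_distance,
    aggregate = aggregate, log_scale = log_scale
  ), class = "hk_class_params")
}

#' Per-gene detection profile across tissues
#'
#' A tissue's expression is the mean over that tissue's samples; a gene is
#' detected in a tissue when that mean strictly exceeds the detection
#' threshold. The CV is computed over all tissue values (zeros included).
#'
#' @param matrix An [expression_matrix()].
#' @param params An [hk_class_params()].
#' @param genes Optional subset of gene ids (default: all; unknown ids are an
#'   error).
#' @return data.frame with `gene_id`, `n_tissues`, `n_detected`,
#'   `detection_fraction`, `mean_expr`, `sd_expr`, `cv`.
#' @export
detection_profile <- function(matrix, params = hk_class_params(), genes = NULL) {
  stopifnot(inherits(matrix, "expr_matrix"))
  vals <- matrix$values
  if (!is.null(genes)) {
    unknown <- setdiff(genes, rownames(vals))
    if (length(unknown))
      stop("unknown genes: ", paste(unknown, collapse = ", "))
    vals <- vals[genes, , drop = FALSE]
  }
  if (params$aggregate == "tissue_mean") {
    tiss <- factor(matrix$tissue)
    agg <- t(apply(vals, 1L, function(v) tapply(v, tiss, mean)))
    if (nlevels(tiss) == 1L) agg <- matrix(agg, ncol = 1L,
                                           dimnames = list(rownames(vals), levels(tiss)))
  } else {
    agg <- vals
  }
  n_units <- ncol(agg)
  detected <- rowSums(agg > params$detect_threshold)
  cv_input <- if (params$log_scale) log2(agg + 1) else agg
  mean_expr <- rowMeans(cv_input)
  sd_expr <- apply(cv_input, 1L, stats::sd)
  cv <- ifelse(mean_expr > 0 & n_units >= 2L, sd_expr / mean_expr, NA_real_)
  data.frame(
    gene_id = rownames(agg), n_tissues = n_units, n_detected = detected,
    detection_fraction = detected / n_units,
    mean_expr = mean_expr, sd_expr = sd_expr, cv = cv,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Retain lincRNAs far enough from protein-coding genes
#'
#' A lincRNA is retained iff the minimum gap between its gene span and any
#' protein-coding gene span on the same chromosome strictly exceeds
#' `min_distance` (strand-agnostic). Overlap counts as a gap of 0; lincRNAs
#' on chromosomes without coding genes are retained.
#'
#' @param lincrnas,coding_genes `gene_models` tables (or span tables from
#'   [gene_spans()]).
#' @param min_distance Minimum gap in bp (strict).
#' @return Character vector of retained lincRNA gene ids.
#' @export
exclude_proximal_lincrnas <- function(lincrnas, coding_genes,
                                      min_distance = 1000) {
  spans_l <- if ("exonic_length" %in% names(lincrnas)) lincrnas else gene_spans(lincrnas)
  if (nrow(spans_l) == 0L) return(character(0))
  spans_c <- if ("exonic_length" %in% names(coding_genes)) coding_genes else gene_spans(coding_genes)
  if (nrow(spans_c) == 0L) return(spans_l$gene_id)
  lvl <- union(unique(spans_l$chrom), unique(spans_c$chrom))
  gl <- as_granges0(spans_l)
  gc <- as_granges0(spans_c)
  GenomeInfoDb::seqlevels(gl) <- lvl
  GenomeInfoDb::seqlevels(gc) <- lvl
  hit <- GenomicRanges::distanceToNearest(gl, gc, ignore.strand = TRUE)
  gap <- rep(NA_real_, nrow(spans_l))
  gap[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  spans_l$gene_id[is.na(gap) | gap > min_distance]
}

#' Classify genes as housekeeping, tissue-specific or neither
#'
#' Applies the proximity prefilter (when annotations are supplied), then
#' labels each gene: `HK` iff detection fraction >= `hk_min_fraction` and CV
#' defined and < `hk_max_cv`; `TS` iff detection fraction < `ts_max_fraction`
#' and CV > `ts_min_cv`; otherwise `neither`. LincRNAs removed by the
#' proximity filter are labelled `excluded_proximal`.
#'
#' @param matrix An [expression_matrix()].
#' @param annotations Optional `gene_models` table containing both lincRNAs
#'   and protein-coding genes; when `NULL` the proximity filter is skipped.
#' @param params An [hk_class_params()].
#' @return data.frame: the [detection_profile()] columns plus `label`.
#' @export
classify_lincrnas <- function(matrix, annotations = NULL,
                              params = hk_class_params()) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (length(unique(matrix$tissue)) < 2L)
    stop("need at least 2 tissues to classify")
  prof <- detection_profile(matrix, params)
  excluded <- character(0)
  if (!is.null(annotations)) {
    spans <- gene_spans(annotations)
    linc <- spans[spans$biotype == "lincRNA", , drop = FALSE]
    coding <- spans[spans$biotype == "protein_coding", , drop = FALSE]
    kept <- exclude_proximal_lincrnas(linc, coding, params$min_coding_distance)
    excluded <- intersect(setdiff(linc$gene_id, kept), prof$gene_id)
  }
  hk <- prof$detection_fraction >= params$hk_min_fraction &
    !is.na(prof$cv) & prof$cv < params$hk_max_cv
  ts <- prof$detection_fraction < params$ts_max_fraction &
    !is.na(prof$cv) & prof$cv > params$ts_min_cv
  prof$label <- ifelse(hk, "HK", ifelse(ts, "TS", "neither"))
  prof$label[prof$gene_id %in% excluded] <- "excluded_proximal"
  prof
}
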