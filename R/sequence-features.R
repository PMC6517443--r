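# Stage 2: exon-restricted conservation, SNP density, repeat-class coverage
# and cross-species orthologue summaries.

# Overlap counts of 0-based point positions against each gene's exon union.
points_in_exons <- function(models, chrom, pos) {
  gex <- as_granges0(models)
  gp <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  ov <- GenomicRanges::findOverlaps(gp, gex, ignore.strand = TRUE)
  ov
}

#' Mean conservation score over exonic bases
#'
#' Arithmetic mean of the available per-base scores across the union of a
#' gene's exons. Bases without a score are skipped, not zero-filled (sparse
#' tracks leave masked bases unscored).
#'
#' @param models A `gene_models` table.
#' @param scores data.frame with `chrom`, `pos` (0-based) and `score`.
#' @return data.frame `gene_id`, `mean_conservation`, `n_scored`; genes with
#'   no scored exonic base get `NA` with a warning.
#' @export
mean_exonic_conservation <- function(models, scores) {
  stopifnot(all(c("chrom", "pos", "score") %in% names(scores)))
  ov <- points_in_exons(models, scores$chrom, scores$pos)
  gene_of_hit <- models$gene_id[S4Vectors::subjectHits(ov)]
  score_of_hit <- scores$score[S4Vectors::queryHits(ov)]
  # a base in two merged exon rows cannot happen (exons disjoint per gene)
  genes <- unique(models$gene_id)
  means <- tapply(score_of_hit, factor(gene_of_hit, levels = genes), mean)
  ns <- tapply(score_of_hit, factor(gene_of_hit, levels = genes), length)
  ns[is.na(ns)] <- 0L
  if (any(ns == 0L))
    warning("genes with no scored exonic base: ",
            paste(genes[ns == 0L], collapse = ", "))
  data.frame(gene_id = genes, mean_conservation = as.numeric(means),
             n_scored = as.integer(ns), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' SNP density over exonic bases
#'
#' 1000 x (number of SNP positions falling inside the exon union) / exonic
#' length, i.e. SNPs per kb of exon. Positions are 0-based; a position equal
#' to an exon end coordinate lies outside it (half-open).
#'
#' @param models A `gene_models` table.
#' @param snps data.frame with `chrom` and `pos` (0-based), or a BED3-style
#'   table with `start` (then `start` is the position).
#' @return data.frame `gene_id`, `n_snps`, `exonic_length`, `snp_density`.
#' @export
snp_density <- function(models, snps) {
  pos <- if ("pos" %in% names(snps)) snps$pos else snps$start
  ov <- points_in_exons(models, snps$chrom, pos)
  genes <- unique(models$gene_id)
  counts <- table(factor(models$gene_id[S4Vectors::subjectHits(ov)], levels = genes))
  exlen <- tapply(models$end - models$start, factor(models$gene_id, levels = genes), sum)
  data.frame(
    gene_id = genes, n_snps = as.integer(counts),
    exonic_length = as.integer(exlen),
    snp_density = 1000 * as.integer(counts) / as.integer(exlen),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Exonic coverage fraction per repeat class
#'
#' Repeats of a class are merged before intersection, so overlapping copies
#' are not double counted; the fraction is shared bases / exonic length.
#'
#' @param models A `gene_models` table.
#' @param repeats Interval table with `chrom`, `start`, `end` and `class`
#'   (or BED6-style `name`) giving the repeat class.
#' @return data.frame in long form: `gene_id`, `class`, `fraction` (every
#'   gene x class combination, zeros included).
#' @export
repeat_coverage <- function(models, repeats) {
  cls_col <- if ("class" %in% names(repeats)) "class" else "name"
  if (!cls_col %in% names(repeats)) stop("repeats need a class/name column")
  validate_intervals(repeats)
  genes <- unique(models$gene_id)
  exlen <- tapply(models$end - models$start, factor(models$gene_id, levels = genes), sum)
  classes <- unique(repeats[[cls_col]])
  out <- expand.grid(gene_id = genes, class = classes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$fraction <- rep(0, nrow(out))
  for (cl in classes) {
    rcl <- GenomicRanges::reduce(as_granges0(repeats[repeats[[cls_col]] == cl, ]))
    gex <- as_granges0(models)
    ov <- GenomicRanges::findOverlaps(gex, rcl, ignore.strand = TRUE)
    if (length(ov) == 0L) next
    w <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(gex)[S4Vectors::queryHits(ov)],
      GenomicRanges::ranges(rcl)[S4Vectors::subjectHits(ov)]
    ))
    shared <- tapply(w, factor(models$gene_id[S4Vectors::queryHits(ov)], levels = genes), sum)
    shared[is.na(shared)] <- 0
    out$fraction[out$class == cl] <- as.numeric(shared / exlen)
  }
  out
}

#' Summarise cross-species orthologue calls from an alignment hit table
#'
#' Per (query gene, species), the best-identity hit is kept and an orthologue
#' is called when identity >= `identity_min` percent (inclusive). When
#' per-species expression matrices are supplied, the orthologue's detection
#' breadth and CV across that species' tissues are attached.
#'
#' @param hits data.frame in BLAST outfmt-6-like layout with at least
#'   `query`, `species`, `subject`, `identity_pct`.
#' @param expression_by_species Optional named list (species ->
#'   [expression_matrix()]) holding subject-gene expression.
#' @param identity_min Minimum percent identity (inclusive).
#' @param detect_threshold Detection cutoff used for `expressed_tissues`.
#' @return data.frame `query`, `species`, `subject`, `best_identity_pct`,
#'   `called`, `expressed_tissues`, `cv_in_species`.
#' @export
summarize_orthologues <- function(hits, expression_by_species = NULL,
                                  identity_min = 30, detect_threshold = 0.5) {
  need <- c("query", "species", "subject", "identity_pct")
  if (!all(need %in% names(hits)))
    stop("hit table needs columns: ", paste(need, collapse = ", "))
  if (any(hits$identity_pct < 0 | hits$identity_pct > 100))
    stop("identity_pct must lie in [0, 100]")
  key <- interaction(hits$query, hits$species, drop = TRUE)
  best <- do.call(rbind, lapply(split(hits, key), function(h) {
    h[which.max(h$identity_pct), c("query", "species", "subject", "identity_pct")]
  }))
  names(best)[names(best) == "identity_pct"] <- "best_identity_pct"
  best$called <- best$best_identity_pct >= identity_min
  best$expressed_tissues <- NA_integer_
  best$cv_in_species <- NA_real_
  if (!is.null(expression_by_species)) {
    for (i in seq_len(nrow(best))) {
      em <- expression_by_species[[best$species[i]]]
      if (is.null(em) || !best$subject[i] %in% rownames(em$values)) next
      prof <- detection_profile(
        em, hk_class_params(detect_threshold = detect_threshold),
        genes = best$subject[i]
      )
      best$expressed_tissues[i] <- prof$n_detected
      best$cv_in_species[i] <- prof$cv
    }
  }
  rownames(best) <- NULL
  best
}
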