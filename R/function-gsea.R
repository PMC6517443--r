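# Stage 6: correlation-ranked preranked enrichment per lincRNA, cross-lincRNA
# term filtering, and Wang semantic-similarity redundancy reduction.

#' Rank protein-coding genes by correlation to a lincRNA
#'
#' Pearson correlation of every coding gene's expression with the lincRNA's
#' across samples, sorted descending with ties broken by gene id.
#'
#' @param matrix An [expression_matrix()].
#' @param lincrna A gene id present in the matrix.
#' @param coding_genes Gene ids to correlate (default: all other genes).
#' @param log_scale Correlate on log2(x + 1) values instead of linear.
#' @return Named numeric vector of correlations in \[-1, 1\], sorted
#'   descending. Constant genes are dropped with a warning.
#' @export
correlation_rank <- function(matrix, lincrna, coding_genes = NULL,
                             log_scale = FALSE) {
  stopifnot(inherits(matrix, "expr_matrix"))
  vals <- matrix$values
  if (ncol(vals) < 3L) stop("need at least 3 samples")
  if (!lincrna %in% rownames(vals)) stop("unknown lincRNA: ", lincrna)
  if (is.null(coding_genes)) coding_genes <- setdiff(rownames(vals), lincrna)
  unknown <- setdiff(coding_genes, rownames(vals))
  if (length(unknown)) stop("unknown genes: ", paste(unknown, collapse = ", "))
  if (log_scale) vals <- log2(vals + 1)
  x <- vals[lincrna, ]
  if (stats::sd(x) == 0) stop("lincRNA profile is constant")
  m <- vals[coding_genes, , drop = FALSE]
  const <- apply(m, 1L, stats::sd) == 0
  if (any(const)) {
    warning("dropping constant genes: ",
            paste(coding_genes[const], collapse = ", "))
    m <- m[!const, , drop = FALSE]
  }
  r <- as.numeric(stats::cor(t(m), x))
  names(r) <- rownames(m)
  r[order(-r, names(r))]
}

# Signed maximum deviation of the weighted KS running statistic, computed
# from hit positions only (O(n_hits)). absrp = |score|^p over the ranking.
es_from_positions <- function(absrp, N, pos) {
  pos <- sort(pos)
  nh <- length(pos)
  w <- absrp[pos]
  W <- sum(w)
  if (W == 0) { w <- rep(1, nh); W <- nh }  # all-zero hit scores: flat weights
  ph <- cumsum(w) / W
  pm <- (pos - seq_len(nh)) / (N - nh)
  maxP <- max(ph - pm)            # peak at each hit
  minP <- min(c(0, ph[-nh]) - pm) # dip just before each hit
  # sign with the larger absolute extreme; ties give 0 (GSEA convention).
  # The tie check uses a small tolerance: equal-magnitude extremes arise from
  # rational step sizes and must not flip sign on floating-point noise.
  if (abs(maxP + minP) < 1e-9) 0
  else if (maxP > -minP) unname(maxP)
  else unname(minP)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walking down the ranking, member genes ("hits") add their normalised
#' weight |r|^p / sum of hit |r|^p and non-members subtract 1 / (N - N_hits);
#' the enrichment score is the signed maximum deviation of this running sum
#' from zero. `weight_p = 0` gives the classical KS statistic.
#'
#' @param ranked Named numeric vector from [correlation_rank()] (descending).
#' @param gene_set Character vector of member gene ids.
#' @param weight_p Weighting exponent (default 1).
#' @return The enrichment score in \[-1, 1\].
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  N <- length(ranked)
  pos <- which(names(ranked) %in% gene_set)
  if (length(pos) == 0L) stop("gene set has no gene in the ranking")
  if (length(pos) == N) stop("gene set covers the whole ranking")
  es_from_positions(abs(ranked)^weight_p, N, pos)
}

#' Preranked gene-set enrichment with permutation NES and FDR
#'
#' For every eligible gene set, computes the observed enrichment score, a
#' null of `n_perm` scores obtained by randomising set membership over the
#' ranking (gene-label permutation; scores stay fixed), a sign-matched
#' normalised score NES = ES / mean(|same-sign null ES|), a one-sided
#' add-one p-value from the same-sign null tail, and an FDR from the pooled
#' null-NES distribution (fraction of null NES at least as extreme,
#' normalised by the fraction of observed NES at least as extreme, clipped
#' to \[0, 1\]). Each set draws its permutations from a child seed keyed by
#' the set name, so results do not depend on set order.
#'
#' @param ranked Named numeric vector from [correlation_rank()].
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param n_perm Number of membership permutations per set.
#' @param min_set,max_set Eligible set-size bounds after intersection with
#'   the ranking (defaults 15 and 500).
#' @param weight_p Weighting exponent for [enrichment_score()].
#' @param seed Master seed.
#' @return data.frame `term`, `es`, `nes`, `p_value`, `fdr_q`, `size`,
#'   `direction` (+1/-1), one row per eligible set.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, min_set = 15,
                           max_set = 500, weight_p = 1, seed = 1) {
  N <- length(ranked)
  absrp <- abs(ranked)^weight_p
  sizes <- vapply(sets, function(s) sum(names(ranked) %in% s), 0L)
  eligible <- names(sets)[sizes >= min_set & sizes <= max_set & sizes < N]
  if (length(eligible) == 0L) stop("no eligible gene set")
  es <- numeric(length(eligible))
  null_es <- vector("list", length(eligible))
  for (i in seq_along(eligible)) {
    nm <- eligible[i]
    es[i] <- enrichment_score(ranked, sets[[nm]], weight_p)
    nh <- sizes[[nm]]
    null_es[[i]] <- local_seed(derive_seed(seed, nm), {
      vapply(seq_len(n_perm),
             function(j) es_from_positions(absrp, N, sample.int(N, nh)), 0)
    })
  }
  norm_mean <- function(null, sign_pos) {
    m <- if (sign_pos) mean(null[null >= 0]) else mean(abs(null[null < 0]))
    if (!is.finite(m) || m == 0) NA_real_ else m
  }
  nes <- numeric(length(eligible))
  pval <- numeric(length(eligible))
  null_nes_pool <- list()
  for (i in seq_along(eligible)) {
    null <- null_es[[i]]
    pos_mean <- norm_mean(null, TRUE)
    neg_mean <- norm_mean(null, FALSE)
    if (es[i] >= 0) {
      tail <- null[null >= 0]
      nes[i] <- if (is.na(pos_mean)) NA_real_ else es[i] / pos_mean
      pval[i] <- (1 + sum(tail >= es[i])) / (1 + length(tail))
    } else {
      tail <- null[null < 0]
      nes[i] <- if (is.na(neg_mean)) NA_real_ else es[i] / neg_mean
      pval[i] <- (1 + sum(tail <= es[i])) / (1 + length(tail))
    }
    nn <- ifelse(null >= 0,
                 if (is.na(pos_mean)) NA_real_ else null / pos_mean,
                 if (is.na(neg_mean)) NA_real_ else null / neg_mean)
    null_nes_pool[[i]] <- nn[!is.na(nn)]
  }
  pool <- unlist(null_nes_pool)
  fdr <- vapply(seq_along(eligible), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      denom_null <- sum(pool >= 0)
      num <- if (denom_null == 0) 1 else sum(pool >= nes[i]) / denom_null
      denom_obs_n <- sum(nes >= 0, na.rm = TRUE)
      denom <- if (denom_obs_n == 0) 1 else sum(nes >= nes[i], na.rm = TRUE) / denom_obs_n
    } else {
      denom_null <- sum(pool < 0)
      num <- if (denom_null == 0) 1 else sum(pool <= nes[i]) / denom_null
      denom_obs_n <- sum(nes < 0, na.rm = TRUE)
      denom <- if (denom_obs_n == 0) 1 else sum(nes <= nes[i], na.rm = TRUE) / denom_obs_n
    }
    min(1, max(0, num / max(denom, .Machine$double.eps)))
  }, 0)
  data.frame(
    term = eligible, es = es, nes = nes, p_value = pval, fdr_q = fdr,
    size = as.integer(sizes[eligible]), direction = ifelse(es >= 0, 1L, -1L),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Select significant gene sets from a ranked-list enrichment result
#'
#' The knockdown-analysis significance rule: absolute normalised enrichment
#' score strictly above `nes_min` and FDR strictly below `fdr_max`
#' (defaults |NES| > 1.7 and FDR < 10%).
#'
#' @param results A [gsea_preranked()] result.
#' @param nes_min Minimum |NES| (strict).
#' @param fdr_max Maximum FDR (strict).
#' @return The significant subset of `results`, with a `significant` column
#'   added to the full table in the `all` attribute.
#' @export
gsea_ranked_filter <- function(results, nes_min = 1.7, fdr_max = 0.10) {
  sig <- !is.na(results$nes) & abs(results$nes) > nes_min &
    !is.na(results$fdr_q) & results$fdr_q < fdr_max
  out <- results[sig, , drop = FALSE]
  full <- results
  full$significant <- sig
  attr(out, "all") <- full
  rownames(out) <- NULL
  out
}

#' Signed term x lincRNA significance matrix, filtered by recurrence
#'
#' Keeps terms significant (FDR strictly below `fdr_max`) in at least
#' `ceiling(min_lincrna_fraction * n_lincRNAs)` lincRNAs; cells hold the sign
#' of the enrichment (+1/-1) where significant and 0 elsewhere.
#'
#' @param results_by_linc Named list of [gsea_preranked()] results, one per
#'   lincRNA.
#' @param fdr_max FDR threshold (strict).
#' @param min_lincrna_fraction Minimum recurrence fraction (default 0.10).
#' @return Integer matrix terms x lincRNAs (possibly 0-row).
#' @export
term_matrix_filter <- function(results_by_linc, fdr_max = 0.05,
                               min_lincrna_fraction = 0.10) {
  n_linc <- length(results_by_linc)
  if (n_linc == 0L) stop("no results supplied")
  terms <- sort(unique(unlist(lapply(results_by_linc, `[[`, "term"))))
  m <- matrix(0L, length(terms), n_linc,
              dimnames = list(terms, names(results_by_linc)))
  for (l in names(results_by_linc)) {
    res <- results_by_linc[[l]]
    sig <- !is.na(res$fdr_q) & res$fdr_q < fdr_max
    m[res$term[sig], l] <- res$direction[sig]
  }
  need <- ceiling(min_lincrna_fraction * n_linc)
  m[rowSums(m != 0L) >= need, , drop = FALSE]
}

# S-values of Wang's measure: contribution of every ancestor of `term`,
# obtained by propagating S(term) = 1 upward with multiplicative edge weights
# (taking the maximum over paths).
wang_svalues <- function(onto, term, weights) {
  s <- stats::setNames(1, term)
  queue <- term
  while (length(queue)) {
    t <- queue[1L]; queue <- queue[-1L]
    e <- onto$edges[onto$edges$child == t, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      val <- s[[t]] * weights[[e$rel[i]]]
      p <- e$parent[i]
      if (is.na(s[p]) || val > s[[p]]) {
        s[p] <- val
        queue <- c(queue, p)
      }
    }
  }
  s
}

#' Wang-method semantic similarity between ontology terms
#'
#' Each term's ancestors receive S-values propagated from the term with edge
#' contribution 0.8 for `is_a` and 0.6 for `part_of`; similarity is the
#' shared S-mass over the total S-mass of the two terms.
#'
#' @param onto An `ontology` from [read_obo()].
#' @param terms Terms to compare (must be present in the ontology).
#' @param weights Named edge-contribution factors.
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
semantic_similarity <- function(onto, terms,
                                weights = c(is_a = 0.8, part_of = 0.6)) {
  missing <- setdiff(terms, onto$terms)
  if (length(missing))
    stop("terms not in ontology: ", paste(missing, collapse = ", "))
  sv <- lapply(terms, wang_svalues, onto = onto, weights = weights)
  names(sv) <- terms
  n <- length(terms)
  sim <- matrix(1, n, n, dimnames = list(terms, terms))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    shared <- intersect(names(sv[[i]]), names(sv[[j]]))
    sim[i, j] <- sim[j, i] <-
      sum(sv[[i]][shared] + sv[[j]][shared]) / (sum(sv[[i]]) + sum(sv[[j]]))
  }
  sim
}

#' Reduce redundant terms by similarity-tree cutting
#'
#' Average-linkage hierarchical clustering on distance 1 - similarity, cut at
#' `cut_height`; one representative is picked per cluster, either by seeded
#' RNG (`"random"`, mirroring a random pick among near-synonymous terms) or
#' deterministically as the lexicographically lowest id.
#'
#' @param sim Similarity matrix from [semantic_similarity()].
#' @param cut_height Tree cut height on the distance scale (default 0.85).
#' @param method `"random"` or `"lowest_id"`.
#' @param seed Seed for the random pick.
#' @return data.frame `term`, `cluster`, `representative` (logical).
#' @export
reduce_terms <- function(sim, cut_height = 0.85,
                         method = c("random", "lowest_id"), seed = 1) {
  method <- match.arg(method)
  terms <- rownames(sim)
  if (length(terms) == 1L)
    return(data.frame(term = terms, cluster = 1L, representative = TRUE,
                      stringsAsFactors = FALSE))
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  rep_of <- local_seed(derive_seed(seed, "reduce_terms"), {
    vapply(split(names(cl), cl), function(members) {
      if (method == "lowest_id") sort(members)[1L]
      else members[sample.int(length(members), 1L)]
    }, "")
  })
  data.frame(term = terms, cluster = unname(cl[terms]),
             representative = terms %in% rep_of,
             row.names = NULL, stringsAsFactors = FALSE)
}
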