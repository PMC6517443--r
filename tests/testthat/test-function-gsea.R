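toy_expr <- function(m) {
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  expression_matrix(m)
}

test_that("correlation ranking orders by Pearson r with id tie-break", {
  set.seed(1)
  base <- rnorm(10) + 10
  m <- rbind(linc = base, copy = base, anti = 20 - base,
             noise = rnorm(10) + 10)
  rk <- correlation_rank(toy_expr(pmax(m, 0)), "linc")
  expect_equal(names(rk)[1], "copy")
  expect_equal(unname(rk["copy"]), 1)
  expect_equal(names(rk)[length(rk)], "anti")
  expect_equal(unname(rk["anti"]), -1)
  m2 <- rbind(m, flat = rep(5, 10))
  expect_warning(rk2 <- correlation_rank(toy_expr(pmax(m2, 0)), "linc"),
                 "constant")
  expect_false("flat" %in% names(rk2))
})

test_that("enrichment score matches hand cases and the running-sum oracle", {
  r <- seq(1, 0.1, length.out = 10)
  names(r) <- sprintf("g%02d", 1:10)
  # equal-weight contiguous top hits reach the maximum deviation of 1
  r_eq <- setNames(rep(0.5, 10), names(r))
  expect_equal(enrichment_score(r_eq, c("g01", "g02", "g03")), 1)
  expect_error(enrichment_score(r, c("zz")), "no gene")
  expect_error(enrichment_score(r, names(r)), "whole ranking")

  set.seed(2)
  for (i in 1:200) {
    n <- sample(5:20, 1)
    rk <- sort(runif(n, -1, 1), decreasing = TRUE)
    names(rk) <- sprintf("g%02d", 1:n)
    set <- sample(names(rk), sample(1:min(8, n - 1), 1))
    p <- sample(c(0, 1, 2), 1)
    expect_equal(enrichment_score(rk, set, p),
                 oracle_enrichment_score(rk, set, p))
  }
})

test_that("with p = 0 reversing the ranking flips the ES sign", {
  set.seed(3)
  rk <- sort(rnorm(20), decreasing = TRUE)
  names(rk) <- sprintf("g%02d", 1:20)
  set <- sample(names(rk), 5)
  es_fwd <- enrichment_score(rk, set, weight_p = 0)
  rev_rk <- rev(rk)
  es_rev <- enrichment_score(rev_rk, set, weight_p = 0)
  expect_equal(es_fwd, -es_rev)
  # and ES is invariant under monotone rescaling of scores when p = 0
  rk2 <- sort(exp(rk), decreasing = TRUE)
  names(rk2) <- names(rk)
  expect_equal(enrichment_score(rk2, set, weight_p = 0), es_fwd)
})

test_that("ES agrees with fgsea's statistic on random instances", {
  skip_if_not_installed("fgsea")
  set.seed(4)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    rk <- sort(rnorm(n), decreasing = TRUE)
    names(rk) <- sprintf("g%03d", 1:n)
    set <- sample(names(rk), sample(3:10, 1))
    ours <- enrichment_score(rk, set, weight_p = 1)
    theirs <- fgsea::calcGseaStat(rk, selectedStats = which(names(rk) %in% set),
                                  gseaParam = 1, scoreType = "std")
    expect_equal(ours, theirs, tolerance = 1e-8)
  }
})

test_that("preranked GSEA is deterministic and keyed by set name", {
  set.seed(5)
  rk <- sort(rnorm(200), decreasing = TRUE)
  names(rk) <- sprintf("g%03d", 1:200)
  sets <- list(A = sample(names(rk), 20), B = sample(names(rk), 25))
  sets$A_copy <- sets$A
  res <- gsea_preranked(rk, sets, n_perm = 100, min_set = 5, seed = 9)
  res2 <- gsea_preranked(rk, sets, n_perm = 100, min_set = 5, seed = 9)
  expect_identical(res, res2)
  # same members, different name: same ES, NES within permutation noise
  expect_equal(res$es[res$term == "A"], res$es[res$term == "A_copy"])
  expect_lt(abs(res$nes[res$term == "A"] - res$nes[res$term == "A_copy"]), 0.4)
  expect_error(gsea_preranked(rk, list(tiny = "g001"), min_set = 15),
               "no eligible")
})

test_that("a planted pathway reaches small FDR; p is sane under the null", {
  co <- make_coexpression(n_pathways = 1, n_noise_genes = 200,
                          n_decoy_sets = 10, seed = 13)
  coding <- setdiff(rownames(co$matrix$values), "linc01")
  rk <- correlation_rank(co$matrix, "linc01", coding)
  res <- gsea_preranked(rk, co$gene_sets, n_perm = 200, seed = 3)
  expect_lt(res$fdr_q[res$term == "PATHWAY_1"], 0.05)
  expect_gt(res$nes[res$term == "PATHWAY_1"], 1.7)
  # decoys: no systematic enrichment
  expect_gt(min(res$p_value[res$term != "PATHWAY_1"]), 0.001)
})

test_that("term matrix filter applies the ceiling recurrence rule", {
  mk <- function(fdr) data.frame(term = "T1", es = 0.5, nes = 2,
                                 p_value = 0.01, fdr_q = fdr, size = 20L,
                                 direction = 1L, stringsAsFactors = FALSE)
  # significant in 5 of 52 lincRNAs: ceiling(5.2) = 6 -> dropped
  res5 <- c(replicate(5, mk(0.01), simplify = FALSE),
            replicate(47, mk(0.9), simplify = FALSE))
  names(res5) <- sprintf("l%02d", 1:52)
  expect_equal(nrow(term_matrix_filter(res5)), 0L)
  res6 <- c(replicate(6, mk(0.01), simplify = FALSE),
            replicate(46, mk(0.9), simplify = FALSE))
  names(res6) <- sprintf("l%02d", 1:52)
  tm <- term_matrix_filter(res6)
  expect_equal(nrow(tm), 1L)
  expect_equal(sum(tm == 1L), 6L)
})

test_that("knockdown significance needs |NES| > 1.7 and FDR < 10%, strictly", {
  res <- data.frame(
    term = c("a", "b", "c", "d"),
    es = c(0.5, -0.5, 0.5, 0.5),
    nes = c(1.7, -1.8, 2.5, 2.5),
    p_value = 0.01,
    fdr_q = c(0.01, 0.05, 0.10, 0.09),
    size = 20L, direction = c(1L, -1L, 1L, 1L)
  )
  kept <- gsea_ranked_filter(res)
  expect_setequal(kept$term, c("b", "d"))
})

test_that("Wang similarity matches hand-propagated S-values on a toy DAG", {
  onto <- structure(list(
    terms = c("R", "B", "A", "C", "D"),
    name = setNames(c("root", "b", "a", "c", "d"),
                    c("R", "B", "A", "C", "D")),
    edges = data.frame(
      child = c("B", "A", "C", "D"),
      parent = c("R", "B", "R", "B"),
      rel = c("is_a", "is_a", "is_a", "part_of"),
      stringsAsFactors = FALSE
    )
  ), class = "ontology")
  sim <- semantic_similarity(onto, c("A", "C", "D"))
  expect_equal(diag(sim), setNames(c(1, 1, 1), c("A", "C", "D")))
  expect_equal(sim, t(sim))
  # S_A = {A:1, B:0.8, R:0.64}; S_C = {C:1, R:0.8}; shared mass 1.44 of 4.24
  expect_equal(sim["A", "C"], 1.44 / 4.24)
  # S_D = {D:1, B:0.6, R:0.48}; shared with A: (0.8+0.6)+(0.64+0.48) of 4.52
  expect_equal(sim["A", "D"], 2.52 / 4.52)
})

test_that("term reduction partitions terms and shrinks with cut height", {
  set.seed(6)
  n <- 8
  sim <- matrix(runif(n * n, 0, 0.4), n, n)
  sim <- (sim + t(sim)) / 2
  sim[1, 2] <- sim[2, 1] <- 0.95
  diag(sim) <- 1
  dimnames(sim) <- list(sprintf("T%d", 1:n), sprintf("T%d", 1:n))
  red <- reduce_terms(sim, cut_height = 0.85, method = "lowest_id")
  expect_setequal(red$term, rownames(sim))
  expect_true(all(table(red$cluster[red$representative]) == 1))
  expect_equal(red$cluster[red$term == "T1"], red$cluster[red$term == "T2"])
  expect_true(red$representative[red$term == "T1"])  # lowest id of its cluster
  sizes <- vapply(c(0.2, 0.5, 0.85, 1), function(h)
    sum(reduce_terms(sim, cut_height = h)$representative), 0L)
  expect_true(all(diff(sizes) <= 0))
})
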