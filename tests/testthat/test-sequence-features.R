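toy_gene <- function(starts, ends, strand = "+", id = "g1") {
  gene_models(data.frame(gene_id = id, chrom = "c1", start = starts,
                         end = ends, strand = strand, biotype = "lincRNA"))
}

test_that("mean exonic conservation skips unscored bases", {
  g <- toy_gene(0, 10)
  sc <- data.frame(chrom = "c1", pos = 0:9, score = 0.5)
  expect_equal(mean_exonic_conservation(g, sc)$mean_conservation, 0.5)

  g2 <- toy_gene(c(0, 20), c(5, 25))
  sc2 <- data.frame(chrom = "c1", pos = c(0:4, 20:24),
                    score = rep(c(1, 0), each = 5))
  expect_equal(mean_exonic_conservation(g2, sc2)$mean_conservation, 0.5)

  # unscored half skipped, not zero-filled
  sc3 <- data.frame(chrom = "c1", pos = 0:4, score = 0.2)
  expect_equal(mean_exonic_conservation(g, sc3)$mean_conservation, 0.2)

  sc4 <- data.frame(chrom = "c1", pos = 100, score = 1)
  expect_warning(res <- mean_exonic_conservation(g, sc4), "no scored")
  expect_true(is.na(res$mean_conservation))
})

test_that("SNP density counts exonic positions per kb, half-open", {
  g <- toy_gene(0, 1000)
  snps <- data.frame(chrom = "c1", pos = c(10, 500))
  expect_equal(snp_density(g, snps)$snp_density, 2)
  # position equal to the exon end coordinate lies outside
  expect_equal(snp_density(g, data.frame(chrom = "c1", pos = 1000))$n_snps, 0L)
  expect_equal(snp_density(g, data.frame(chrom = "c1", pos = 999))$n_snps, 1L)

  set.seed(3)
  g2 <- toy_gene(c(10, 60), c(40, 90))
  pos <- sample(0:120, 40)
  base_in <- function(p) (p >= 10 & p < 40) | (p >= 60 & p < 90)
  expect_equal(snp_density(g2, data.frame(chrom = "c1", pos = pos))$n_snps,
               sum(base_in(pos)))
})

test_that("repeat coverage merges same-class copies before intersecting", {
  g <- toy_gene(100, 120)
  alu <- data.frame(chrom = "c1", start = 90, end = 130, class = "SINE/Alu")
  rc <- repeat_coverage(g, alu)
  expect_equal(rc$fraction[rc$class == "SINE/Alu"], 1)

  g20 <- toy_gene(0, 20)
  two <- data.frame(chrom = "c1", start = c(0, 5), end = c(10, 15),
                    class = "LINE/L1")
  expect_equal(repeat_coverage(g20, two)$fraction, 0.75)

  none <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), class = character(0))
  expect_equal(repeat_coverage(g, none)$fraction, numeric(0))
})

test_that("orthologue calls keep the best hit per species at >= 30% identity", {
  hits <- data.frame(
    query = c("q1", "q1", "q1", "q2", "q3"),
    species = c("mouse", "mouse", "rat", "mouse", "rat"),
    subject = c("m1", "m2", "r1", "m3", "r2"),
    identity_pct = c(40, 55, 30.0, 29.9, 80)
  )
  oc <- summarize_orthologues(hits)
  q1m <- oc[oc$query == "q1" & oc$species == "mouse", ]
  expect_equal(q1m$best_identity_pct, 55)
  expect_equal(q1m$subject, "m2")
  expect_true(oc$called[oc$query == "q1" & oc$species == "rat"])    # 30.0 inclusive
  expect_false(oc$called[oc$query == "q2"])                         # 29.9
  expect_error(summarize_orthologues(transform(hits, identity_pct = 120)),
               "\\[0, 100\\]")

  # monotone non-increasing in identity_min
  counts <- vapply(c(0, 30, 50, 80, 100), function(thr)
    sum(summarize_orthologues(hits, identity_min = thr)$called), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("orthologue expression summaries attach the subject gene's CV", {
  m <- matrix(c(5, 5, 5, 5, 9, 0, 0, 0), 2, 4, byrow = TRUE,
              dimnames = list(c("m1", "m2"), sprintf("t%d", 1:4)))
  hits <- data.frame(query = c("q1", "q2"), species = "mouse",
                     subject = c("m1", "m2"), identity_pct = c(50, 50))
  oc <- summarize_orthologues(hits, list(mouse = expression_matrix(m)))
  expect_equal(oc$cv_in_species[oc$query == "q1"], 0)
  expect_equal(oc$expressed_tissues[oc$query == "q2"], 1L)
})
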