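toy_matrix <- function(rows, tissues = sprintf("t%02d", seq_len(ncol(rows)))) {
  expression_matrix(rows, stats::setNames(tissues, colnames(rows)))
}

test_that("detection uses a strict threshold and CV covers all tissues", {
  m <- rbind(
    stable = rep(3.9, 16),
    border = rep(0.5, 16),
    narrow = c(rep(100, 3), rep(0, 13))
  )
  colnames(m) <- sprintf("t%02d", 1:16)
  prof <- detection_profile(toy_matrix(m))
  expect_equal(prof$n_detected[prof$gene_id == "stable"], 16)
  expect_equal(prof$cv[prof$gene_id == "stable"], 0)
  # exactly at the threshold is NOT detected
  expect_equal(prof$n_detected[prof$gene_id == "border"], 0)
  # 3/16 tissues: fraction 0.1875 but CV only ~2.15, so not TS
  nr <- prof[prof$gene_id == "narrow", ]
  expect_equal(nr$detection_fraction, 0.1875)
  expect_equal(nr$mean_expr, 18.75)
  expect_equal(nr$sd_expr, sqrt(24375 / 15))
  expect_equal(round(nr$cv, 4), 2.1499)
  cls <- classify_lincrnas(toy_matrix(m))
  expect_equal(cls$label[cls$gene_id == "narrow"], "neither")
  expect_error(detection_profile(toy_matrix(m), genes = "nope"), "unknown")
})

test_that("param invariants are enforced", {
  expect_error(hk_class_params(hk_min_fraction = 0.2, ts_max_fraction = 0.25),
               "ts_max_fraction")
  expect_error(hk_class_params(hk_max_cv = 4, ts_min_cv = 3.5), "hk_max_cv")
})

test_that("proximity filter uses a strict gap threshold", {
  linc <- function(s, e) gene_models(data.frame(
    gene_id = "l1", chrom = "c1", start = s, end = e, strand = "+",
    biotype = "lincRNA"))
  coding <- gene_models(data.frame(
    gene_id = "pc1", chrom = "c1", start = 10000, end = 20000, strand = "+",
    biotype = "protein_coding"))
  # gap exactly 1000 -> excluded; 1001 -> retained
  expect_equal(exclude_proximal_lincrnas(linc(8000, 9000), coding), character(0))
  expect_equal(exclude_proximal_lincrnas(linc(8000, 8999), coding), "l1")
  expect_equal(exclude_proximal_lincrnas(linc(15000, 16000), coding), character(0))
  other_chrom <- gene_models(data.frame(
    gene_id = "l2", chrom = "c9", start = 0, end = 100, strand = "+",
    biotype = "lincRNA"))
  expect_equal(exclude_proximal_lincrnas(other_chrom, coding), "l2")
})

test_that("classification labels follow the published rules", {
  m <- rbind(
    allzero = rep(0, 16),
    hk12 = c(rep(2, 12), rep(0.4, 4)),      # 12/16 detected
    onehit = c(50, rep(0, 15))
  )
  colnames(m) <- sprintf("t%02d", 1:16)
  cls <- classify_lincrnas(toy_matrix(m))
  expect_equal(cls$label[cls$gene_id == "allzero"], "neither")
  hk12 <- cls[cls$gene_id == "hk12", ]
  expect_equal(hk12$n_detected, 12)
  expect_lt(hk12$cv, 1.5)
  expect_equal(hk12$label, "HK")
  expect_equal(cls$label[cls$gene_id == "onehit"], "TS")
  one_tissue <- expression_matrix(m, stats::setNames(rep("t", 16), colnames(m)))
  expect_error(classify_lincrnas(one_tissue), "2 tissues")
})

test_that("the proximity filter feeds the excluded_proximal label", {
  m <- matrix(rep(2, 32), 2, 16,
              dimnames = list(c("near", "far"), sprintf("t%02d", 1:16)))
  ann <- gene_models(data.frame(
    gene_id = c("near", "far", "pc"), chrom = "c1",
    start = c(9500, 50000, 10000), end = c(9900, 51000, 20000),
    strand = "+", biotype = c("lincRNA", "lincRNA", "protein_coding")
  ))
  cls <- classify_lincrnas(toy_matrix(m), annotations = ann)
  expect_equal(cls$label[cls$gene_id == "near"], "excluded_proximal")
  expect_equal(cls$label[cls$gene_id == "far"], "HK")
})

test_that("HK/TS labels are disjoint, scale invariant and monotone in hk_max_cv", {
  tm <- make_tissue_matrix(20, 20, 40, seed = 5)
  p <- hk_class_params()
  cls <- classify_lincrnas(tm$matrix, params = p)
  hk_rule <- cls$detection_fraction >= p$hk_min_fraction &
    !is.na(cls$cv) & cls$cv < p$hk_max_cv
  ts_rule <- cls$detection_fraction < p$ts_max_fraction &
    !is.na(cls$cv) & cls$cv > p$ts_min_cv
  expect_false(any(hk_rule & ts_rule))

  scaled <- expression_matrix(tm$matrix$values * 7, tm$matrix$tissue)
  cls_scaled <- classify_lincrnas(
    scaled, params = hk_class_params(detect_threshold = 0.5 * 7))
  expect_equal(cls_scaled$label, cls$label)

  hk_sets <- lapply(c(0.5, 1.0, 1.5, 2.5), function(cv) {
    cl <- classify_lincrnas(tm$matrix, params = hk_class_params(hk_max_cv = cv))
    cl$gene_id[cl$label == "HK"]
  })
  for (i in 2:4) expect_true(all(hk_sets[[i - 1]] %in% hk_sets[[i]]))
})
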