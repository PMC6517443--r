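test_that("DE flags use strict |FC| > 2 and q < 0.05", {
  de <- data.frame(
    gene = c("a", "b", "c", "d"),
    tumour_type = "T1",
    log2_fc = c(-1.0, -1.1, -1.1, 2.0),
    q = c(0.01, 0.049, 0.05, 0.01)
  )
  fl <- de_flags(de)
  expect_false(fl$down_any[fl$gene == "a"])  # |FC| exactly 2
  expect_true(fl$down_any[fl$gene == "b"])
  expect_false(fl$down_any[fl$gene == "c"])  # q exactly 0.05
  expect_true(fl$up_any[fl$gene == "d"])
  expect_error(de_flags(de[, -4]), "columns")
})

test_that("recurrent deletion is inclusive at 1% and supports per-type mode", {
  cna <- matrix("diploid", 2, 1000,
                dimnames = list(c("g10", "g9"), sprintf("s%d", 1:1000)))
  cna["g10", 1:10] <- "homdel"
  cna["g9", 1:9] <- "homdel"
  rec <- recurrent_deletion(cna)
  expect_true(rec[["g10"]])   # exactly 1%: inclusive
  expect_false(rec[["g9"]])
  # 9 homdels concentrated in a 100-sample type exceed 1% there
  types <- rep(c("A", "B"), c(100, 900))
  rec_t <- recurrent_deletion(cna, sample_types = types)
  expect_true(rec_t[["g9"]])
  bad <- cna; bad[1, 1] <- "weird"
  expect_error(recurrent_deletion(bad), "unknown copy-number category")
})

test_that("focal overlap needs a shared base and matches a per-base oracle", {
  g <- gene_models(data.frame(gene_id = "g1", chrom = "c1", start = 100,
                              end = 200, strand = "+", biotype = "lincRNA"))
  abut <- data.frame(chrom = "c1", start = 200, end = 300, type = "del")
  expect_false(focal_overlap(g, abut)$in_focal_deletion)
  onebp <- data.frame(chrom = "c1", start = 199, end = 300, type = "del")
  expect_true(focal_overlap(g, onebp)$in_focal_deletion)
  amp <- data.frame(chrom = "c1", start = 150, end = 160, type = "amp")
  expect_false(focal_overlap(g, amp)$in_focal_deletion)

  set.seed(8)
  for (i in 1:20) {
    span <- rand_intervals(1)
    regions <- rand_intervals(4)
    regions$type <- "del"
    gm <- gene_models(data.frame(gene_id = "gx", chrom = "c1",
                                 start = span$start, end = span$end,
                                 strand = "+", biotype = "lincRNA"))
    expect_equal(focal_overlap(gm, regions)$in_focal_deletion,
                 oracle_intersect_length(span, regions) > 0)
  }
})

test_that("core calls combine the three evidence flags", {
  de <- data.frame(gene = c("g1", "g2"), tumour_type = "T1",
                   log2_fc = c(0, -2), q = c(0.5, 0.001))
  out <- refine_core_hk(c("g1", "g2", "g3"), de_table = de)
  expect_true(out$core[out$gene_id == "g1"])
  expect_false(out$core[out$gene_id == "g2"])   # down in 1 of the types
  expect_true(out$core[out$gene_id == "g3"])    # missing evidence passes
  out2 <- refine_core_hk(c("g1", "g3"), de_table = de, missing = "exclude")
  expect_equal(out2$gene_id, "g1")
})

test_that("core refinement is monotone: more evidence only removes genes", {
  genes <- sprintf("G%03d", 1:60)
  tt <- make_tumour_tables(genes, seed = 12)
  core1 <- refine_core_hk(genes, de_table = tt$de_table)
  core2 <- refine_core_hk(genes, de_table = tt$de_table, cna = tt$cna)
  core3 <- refine_core_hk(genes, de_table = tt$de_table, cna = tt$cna,
                          gene_annotation = tt$models,
                          focal_regions = tt$focal_regions)
  s1 <- core1$gene_id[core1$core]; s2 <- core2$gene_id[core2$core]
  s3 <- core3$gene_id[core3$core]
  expect_true(all(s2 %in% s1))
  expect_true(all(s3 %in% s2))
})

test_that("simple_de recovers planted fold changes and controls errors", {
  set.seed(9)
  m <- matrix(rlnorm(50 * 6, log(10), 0.1), 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:6)))
  m[1, 4:6] <- m[1, 4:6] * 4
  m[2, ] <- 7                    # constant -> excluded with warning
  groups <- rep(c("ctl", "trt"), each = 3)
  expect_warning(de <- simple_de(m, groups), "constant")
  expect_false("g02" %in% de$gene)
  expect_true(de$significant[de$gene == "g01"])
  expect_gt(de$log2_fc[de$gene == "g01"], 1)
  # identical groups: FDR keeps false positives down
  expect_lte(sum(de$significant), 0.05 * nrow(de) + 1)
})
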