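test_that("generators are pure functions of their seed", {
  a <- make_tissue_matrix(5, 5, 5, seed = 3)
  b <- make_tissue_matrix(5, 5, 5, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a$matrix$values,
                         make_tissue_matrix(5, 5, 5, seed = 4)$matrix$values))
  expect_identical(make_sequences(3, 3, seed = 5), make_sequences(3, 3, seed = 5))
  expect_identical(make_tumour_tables(letters, seed = 6),
                   make_tumour_tables(letters, seed = 6))
  expect_identical(make_survival(50, seed = 8), make_survival(50, seed = 8))
})

test_that("planted HK and TS genes satisfy the classification thresholds", {
  tm <- make_tissue_matrix(50, 50, 100, seed = 1)
  expect_equal(dim(tm$matrix$values), c(200L, 16L))
  cls <- classify_lincrnas(tm$matrix)
  merged <- merge(cls, tm$truth, by = "gene_id")
  hk_recall <- mean(merged$label[merged$class == "HK"] == "HK")
  ts_recall <- mean(merged$label[merged$class == "TS"] == "TS")
  expect_gte(hk_recall, 0.95)
  expect_gte(ts_recall, 0.95)
})

test_that("without planted HK genes none are classified HK across seeds", {
  n_with_hk <- vapply(1:100, function(s) {
    tm <- make_tissue_matrix(0, 10, 20, seed = s)
    sum(classify_lincrnas(tm$matrix)$label == "HK")
  }, 0)
  expect_gte(mean(n_with_hk == 0), 0.99)
})

test_that("random sequences follow the requested dinucleotide bias", {
  bias <- matrix(c(
    0.4, 0.2, 0.2, 0.2,
    0.1, 0.4, 0.4, 0.1,
    0.25, 0.25, 0.25, 0.25,
    0.2, 0.3, 0.1, 0.4
  ), 4, 4, byrow = TRUE, dimnames = list(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T")))
  sq <- make_sequences(0, 40, length_range = c(200, 200), dinuc_bias = bias,
                       seed = 2)
  counts <- matrix(0, 4, 4, dimnames = dimnames(bias))
  for (s in sq$sequences) {
    v <- strsplit(s, "")[[1]]
    t <- table(factor(v[-length(v)], rownames(bias)),
               factor(v[-1], colnames(bias)))
    counts <- counts + t
  }
  freq <- counts / rowSums(counts)
  expect_lt(max(abs(freq - bias)), 0.05)  # ~2000 transitions per row
})

test_that("structured sequences carry a long perfect inverted repeat", {
  sq <- make_sequences(5, 0, length_range = c(200, 200), seed = 9)
  for (s in sq$sequences) {
    expect_equal(nchar(s), 200L)
    # planted 30-pair stem makes the pair-max score much lower than a
    # composition-matched random sequence would typically reach
    expect_lte(fold_score(s), -30)
  }
})

test_that("tumour tables plant recoverable down/deleted/focal events", {
  genes <- sprintf("G%03d", 1:100)
  tt <- make_tumour_tables(genes, seed = 4)
  fl <- de_flags(tt$de_table)
  expect_true(all(fl$down_any[match(tt$truth$gene_id[tt$truth$down], fl$gene)]))
  expect_true(all(fl$up_any[match(tt$truth$gene_id[tt$truth$up], fl$gene)]))
  rec <- recurrent_deletion(tt$cna)
  expect_true(all(rec[tt$truth$gene_id[tt$truth$deleted]]))
  fo <- focal_overlap(tt$models, tt$focal_regions)
  expect_true(all(fo$in_focal_deletion[match(tt$truth$gene_id[tt$truth$focal],
                                             fo$gene_id)]))
  clean <- tt$truth$gene_id[tt$truth$clean]
  expect_false(any(fl$down_any[match(clean, fl$gene)]))
  expect_false(any(rec[clean]))
  expect_false(any(fo$in_focal_deletion[match(clean, fo$gene_id)]))
})

test_that("methylation generator plants a low-beta HK group", {
  me <- make_methylation(sprintf("hk%d", 1:10), sprintf("ts%d", 1:10),
                         n_samples = 20, seed = 5)
  expect_true(all(me$betas >= 0 & me$betas <= 1))
  gl <- gene_level_beta(me$betas, me$probe_coords, me$models)
  expect_setequal(rownames(gl$betas), me$truth$gene_id)
  expect_true(all(gl$n_probes == 5L))  # decoy probe excluded everywhere
  hk_mean <- mean(gl$betas[sprintf("hk%d", 1:10), ])
  ts_mean <- mean(gl$betas[sprintf("ts%d", 1:10), ])
  expect_lt(hk_mean, ts_mean)
})

test_that("co-expression generator hits the target correlation and ranks", {
  co <- make_coexpression(seed = 6)
  em <- co$matrix
  coding <- setdiff(rownames(em$values), co$truth$lincrna)
  rk <- correlation_rank(em, "linc01", coding)
  members <- co$gene_sets[["PATHWAY_1"]]
  r_members <- mean(rk[members])
  expect_gt(r_members, 0.5)   # target 0.7 minus sampling noise
  percentile <- 1 - mean(match(members, names(rk))) / length(rk)
  expect_gte(percentile, 0.9)
})

test_that("survival generator produces the planted hazard structure", {
  sv <- make_survival(400, hazard_ratio = 2, seed = 7)
  expect_true(all(sv$records$time > 0))
  cf <- 1 - mean(sv$records$event)
  expect_gt(cf, 0.3); expect_lt(cf, 0.7)
  rec <- sv$records
  rec$group <- sv$truth$group
  expect_lt(logrank_test(rec)$p_value, 0.05)
})

test_that("simulate_inputs writes every pipeline input plus truth", {
  dir <- withr::local_tempdir()
  files <- simulate_inputs(dir, seed = 2, n_hk = 4, n_ts = 4, n_bg = 4)
  expect_true(all(file.exists(unlist(files))))
  truth <- jsonlite::read_json(files[["truth"]], simplifyVector = TRUE)
  expect_setequal(names(truth), c("gene_class", "sequence", "tumour",
                                  "methylation", "coexpression", "survival"))
})
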