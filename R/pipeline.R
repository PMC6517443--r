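# Orchestration: run every stage in order on a config of file paths and
# thresholds, writing per-stage TSVs plus a JSON summary with the filter
# funnel, and a one-command synthetic end-to-end demo.

#' Pipeline configuration
#'
#' Bundles input paths, the output directory, the master seed and every
#' stage threshold. Defaults equal the published decision rules, so a bare
#' run reproduces them: detection FPKM > 0.5; HK = detected in >= 75% of
#' tissues with CV < 1.5; TS = detected in < 25% with CV > 3.5; more than
#' 1 kb from the nearest coding gene; |FC| > 2 with q < 0.05; homozygous
#' deletion in >= 1% of samples; structure FDR < 0.05; GSEA term FDR < 0.05
#' recurring in >= 10% of lincRNAs; similarity-tree cut at 0.85; survival
#' split at the 75th percentile.
#'
#' @param input_dir Directory holding the input files (layout of
#'   [simulate_inputs()]).
#' @param out_dir Output directory.
#' @param seed Master seed for every stochastic stage.
#' @param n_shuffles Shuffles for the structure permutation test.
#' @param n_perm Membership permutations for the enrichment stage.
#' @param structure_engine Folding engine, see [fold_score()].
#' @param params An [hk_class_params()].
#' @param structure_fdr,gsea_fdr,min_lincrna_fraction,cut_height,survival_q
#'   Stage thresholds (defaults as above).
#' @param fc_min,q_max,del_min_fraction Tumour-refinement thresholds.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir, seed = 1, n_shuffles = 99,
                            n_perm = 100, structure_engine = "nussinov",
                            params = hk_class_params(), structure_fdr = 0.05,
                            fc_min = 2, q_max = 0.05, del_min_fraction = 0.01,
                            gsea_fdr = 0.05, min_lincrna_fraction = 0.10,
                            cut_height = 0.85, survival_q = 0.75) {
  stopifnot(inherits(params, "hk_class_params"))
  thr01 <- c(structure_fdr = structure_fdr, q_max = q_max,
             del_min_fraction = del_min_fraction, gsea_fdr = gsea_fdr,
             min_lincrna_fraction = min_lincrna_fraction,
             survival_q = survival_q)
  if (any(thr01 < 0 | thr01 > 1))
    stop("thresholds out of [0, 1]: ",
         paste(names(thr01)[thr01 < 0 | thr01 > 1], collapse = ", "))
  if (fc_min <= 1) stop("fc_min must exceed 1")
  if (n_shuffles < 19) stop("n_shuffles must be >= 19")
  structure(list(
    input_dir = input_dir, out_dir = out_dir, seed = seed,
    n_shuffles = n_shuffles, n_perm = n_perm,
    structure_engine = structure_engine, params = params,
    structure_fdr = structure_fdr, fc_min = fc_min, q_max = q_max,
    del_min_fraction = del_min_fraction, gsea_fdr = gsea_fdr,
    min_lincrna_fraction = min_lincrna_fraction, cut_height = cut_height,
    survival_q = survival_q
  ), class = "pipeline_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline on a configuration
#'
#' Stages run in order: classify -> features -> structure -> refine ->
#' methylation -> function -> survival. Every stage writes a TSV under the
#' output directory; a `summary.json` records the filter funnel (gene counts
#' surviving each filter), all thresholds and the seed, so a rerun with the
#' same config is bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return The summary list, invisibly. Any stage failure aborts with the
#'   stage name in the error.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- function(f) file.path(config$input_dir, f)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # 1. classify ---------------------------------------------------------
  cls <- stage("classify", {
    em <- read_matrix(inp("expression.tsv"))
    classify_lincrnas(em, params = config$params)
  })
  write_tsv(cls, out("classification.tsv"))
  chk <- cls$gene_id[cls$label == "HK"]
  ts <- cls$gene_id[cls$label == "TS"]

  # 2. features ---------------------------------------------------------
  feats <- stage("features", {
    models <- read_gene_models(inp("tumour_genes.bed"), "bed12",
                               default_biotype = "lincRNA")
    cons <- utils::read.delim(inp("conservation.tsv"))
    snps <- utils::read.delim(inp("snps.tsv"))
    reps <- utils::read.delim(inp("repeats.tsv"))
    fc <- mean_exonic_conservation(models, cons)
    fs <- snp_density(models, snps)
    merge(fc, fs, by = "gene_id")
  })
  write_tsv(feats, out("features.tsv"))

  # 3. structure --------------------------------------------------------
  str_res <- stage("structure", {
    seqs <- read_fasta(inp("sequences.fa"))
    structure_test(seqs[names(seqs) %in% chk], n_shuffles = config$n_shuffles,
                   engine = config$structure_engine,
                   seed = derive_seed(config$seed, "structure"))
  })
  write_tsv(str_res, out("structure.tsv"))

  # 4. refine -----------------------------------------------------------
  core <- stage("refine", {
    de <- utils::read.delim(inp("de_table.tsv"))
    cna_tab <- utils::read.delim(inp("cna.tsv"), check.names = FALSE)
    cna <- as.matrix(cna_tab[, -1, drop = FALSE])
    rownames(cna) <- cna_tab[[1]]
    focal <- utils::read.delim(inp("focal_regions.tsv"))
    models <- read_gene_models(inp("tumour_genes.bed"), "bed12",
                               default_biotype = "lincRNA")
    refine_core_hk(chk, de_table = de, cna = cna, gene_annotation = models,
                   focal_regions = focal, fc_min = config$fc_min,
                   q_max = config$q_max,
                   min_fraction = config$del_min_fraction)
  })
  write_tsv(core, out("core_hk.tsv"))

  # 5. methylation ------------------------------------------------------
  meth <- stage("methylation", {
    btab <- utils::read.delim(inp("methylation_betas.tsv"), check.names = FALSE)
    betas <- as.matrix(btab[, -1, drop = FALSE])
    rownames(betas) <- btab[[1]]
    coords <- utils::read.delim(inp("probe_coords.tsv"))
    models <- read_gene_models(inp("methylation_genes.bed"), "bed12",
                               default_biotype = "lincRNA")
    gl <- gene_level_beta(betas, coords, models)
    hk_in <- intersect(chk, rownames(gl$betas))
    ts_in <- intersect(ts, rownames(gl$betas))
    group_median_comparison(gl, hk_in, ts_in)
  })
  write_tsv(meth$medians, out("methylation_medians.tsv"))

  # 6. function ---------------------------------------------------------
  fun <- stage("function", {
    em <- read_matrix(inp("coexpression.tsv"))
    sets <- read_gmt(inp("gene_sets.gmt"))
    lincs <- grep("^linc", rownames(em$values), value = TRUE)
    coding <- setdiff(rownames(em$values), lincs)
    res <- lapply(lincs, function(l) {
      rk <- correlation_rank(em, l, coding)
      gsea_preranked(rk, sets, n_perm = config$n_perm,
                     seed = derive_seed(config$seed, paste0("gsea_", l)))
    })
    names(res) <- lincs
    tm <- term_matrix_filter(res, fdr_max = config$gsea_fdr,
                             min_lincrna_fraction = config$min_lincrna_fraction)
    onto_path <- inp("ontology.obo")
    reduced <- if (file.exists(onto_path) && nrow(tm) > 1) {
      onto <- read_obo(onto_path)
      keep <- intersect(rownames(tm), onto$terms)
      if (length(keep) > 1) {
        sim <- semantic_similarity(onto, keep)
        reduce_terms(sim, cut_height = config$cut_height,
                     seed = derive_seed(config$seed, "reduce"))
      } else NULL
    } else NULL
    list(results = res, term_matrix = tm, reduced = reduced)
  })
  flat <- do.call(rbind, lapply(names(fun$results), function(l) {
    cbind(lincrna = l, fun$results[[l]])
  }))
  write_tsv(flat, out("enrichment.tsv"))
  if (nrow(fun$term_matrix) > 0)
    write_tsv(data.frame(term = rownames(fun$term_matrix), fun$term_matrix,
                         check.names = FALSE),
              out("term_matrix.tsv"))
  if (!is.null(fun$reduced)) write_tsv(fun$reduced, out("terms_reduced.tsv"))

  # 7. survival ---------------------------------------------------------
  surv <- stage("survival", {
    rec <- utils::read.delim(inp("survival.tsv"))
    grp <- stratify_by_quantile(
      stats::setNames(rec$expression, rec$patient_id), config$survival_q)
    rec$group <- grp[rec$patient_id]
    list(km = kaplan_meier(rec), test = logrank_test(rec))
  })
  write_tsv(surv$km, out("kaplan_meier.tsv"))

  summary <- list(
    seed = config$seed,
    thresholds = config[!names(config) %in% c("input_dir", "out_dir", "params")],
    classifier = config$params,
    funnel = list(
      n_genes = nrow(cls),
      n_chk = length(chk),
      n_ts = length(ts),
      n_structured_significant = sum(str_res$q_value < config$structure_fdr),
      n_core = sum(core$core)
    ),
    n_terms_kept = nrow(fun$term_matrix),
    n_terms_representative = if (!is.null(fun$reduced))
      sum(fun$reduced$representative) else NA,
    logrank_chisq = surv$test$statistic,
    logrank_p = surv$test$p_value
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(summary)
}

#' One-command synthetic end-to-end demo
#'
#' Generates a complete synthetic input set with planted ground truth, runs
#' every pipeline stage on it, and scores the filter funnel against the
#' truth: the recall of planted "clean" housekeeping genes (ubiquitous, never
#' downregulated, deleted or focally lost) in the final core set.
#'
#' @param seed Master seed.
#' @param dir Working directory (inputs under `inputs/`, outputs under
#'   `outputs/`); a temporary directory by default.
#' @param n_hk,n_ts,n_bg Planted gene-class sizes.
#' @param ... Overrides passed to [pipeline_config()].
#' @return The pipeline summary list, with `funnel_recall` and
#'   `funnel_precision` for planted clean-HK genes added.
#' @export
run_demo <- function(seed = 7, dir = tempfile("linchk_demo"),
                     n_hk = 30, n_ts = 30, n_bg = 60, ...) {
  files <- simulate_inputs(file.path(dir, "inputs"), seed = seed,
                           n_hk = n_hk, n_ts = n_ts, n_bg = n_bg)
  cfg <- pipeline_config(file.path(dir, "inputs"), file.path(dir, "outputs"),
                         seed = seed, ...)
  summary <- run_pipeline(cfg)
  truth <- jsonlite::read_json(files[["truth"]], simplifyVector = TRUE)
  clean <- with(truth$tumour, gene_id[clean])
  planted_hk <- truth$gene_class$gene_id[truth$gene_class$class == "HK"]
  clean_hk <- intersect(planted_hk, clean)
  core <- utils::read.delim(file.path(dir, "outputs", "core_hk.tsv"))
  core_set <- core$gene_id[core$core]
  summary$funnel_recall <- mean(clean_hk %in% core_set)
  summary$funnel_precision <- if (length(core_set))
    mean(core_set %in% clean_hk) else NA_real_
  summary$dir <- dir
  jsonlite::write_json(summary, file.path(dir, "outputs", "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  summary
}
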