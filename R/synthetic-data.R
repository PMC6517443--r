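# Synthetic-data generators with planted ground truth. Every generator is a
# pure function of its seed, and the truth objects are sufficient to score
# every downstream stage (precision/recall of planted classes and events).

DNA_BASES <- c("A", "C", "G", "T")

revcomp_chr <- function(v) rev(c(A = "T", C = "G", G = "C", T = "A")[v])

#' Simulate a multi-tissue expression matrix with planted gene classes
#'
#' Housekeeping (HK) genes get a lognormal per-gene baseline with mild
#' multiplicative per-tissue noise (realised CV well below 1.5, detected at
#' FPKM > 0.5 in all tissues). Tissue-specific (TS) genes are expressed in a
#' single dominant tissue and near zero elsewhere, so their realised CV sits
#' near `sqrt(n_tissues)` (4.0 for 16 tissues) and their detection fraction is
#' `1/n_tissues`. Background genes are detected in an intermediate fraction of
#' tissues (roughly half), so neither classification rule can fire.
#'
#' @param n_hk,n_ts,n_bg Numbers of planted housekeeping, tissue-specific and
#'   background genes.
#' @param n_tissues Number of tissues (>= 4); one sample per tissue.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return List with `matrix` (an [expression_matrix()]) and `truth`
#'   (data.frame `gene_id`, `class` in HK/TS/background).
#' @export
make_tissue_matrix <- function(n_hk = 50, n_ts = 50, n_bg = 100,
                               n_tissues = 16, seed = 1) {
  if (n_hk < 0 || n_ts < 0 || n_bg < 0) stop("gene counts must be >= 0")
  if (n_tissues < 4) stop("need at least 4 tissues")
  n <- n_hk + n_ts + n_bg
  if (n == 0L) stop("no genes requested")
  local_seed(seed, {
    tissues <- sprintf("tissue%02d", seq_len(n_tissues))
    ids <- c(sprintf("HK%04d", seq_len(n_hk)),
             sprintf("TS%04d", seq_len(n_ts)),
             sprintf("BG%04d", seq_len(n_bg)))
    cls <- rep(c("HK", "TS", "background"), c(n_hk, n_ts, n_bg))
    m <- matrix(0, n, n_tissues, dimnames = list(ids, tissues))
    for (i in seq_len(n_hk)) {
      base <- stats::rlnorm(1, log(20), 0.6)
      m[i, ] <- base * stats::rlnorm(n_tissues, 0, 0.3)
    }
    for (i in seq_len(n_ts)) {
      row <- abs(stats::rnorm(n_tissues, 0, 0.01))
      row[sample.int(n_tissues, 1L)] <- stats::rlnorm(1, log(50), 0.7)
      m[n_hk + i, ] <- row
    }
    for (i in seq_len(n_bg)) {
      k <- sample(7:9, 1L)
      row <- rep(0, n_tissues)
      row[sample.int(n_tissues, k)] <- stats::rlnorm(k, log(5), 0.5)
      m[n_hk + n_ts + i, ] <- row
    }
    list(
      matrix = expression_matrix(m),
      truth = data.frame(gene_id = ids, class = cls, stringsAsFactors = FALSE)
    )
  })
}

# One step of a first-order Markov chain over DNA_BASES.
markov_seq <- function(len, trans) {
  if (len <= 0L) return(character(0))
  stat <- Re(eigen(t(trans))$vectors[, 1])
  stat <- stat / sum(stat)
  out <- character(len)
  out[1] <- sample(DNA_BASES, 1L, prob = stat)
  for (i in seq_len(len - 1L))
    out[i + 1L] <- sample(DNA_BASES, 1L, prob = trans[out[i], ])
  out
}

#' Simulate sequences with and without planted inverted repeats
#'
#' Structured sequences carry a perfect stem (inverted repeat) whose two arms
#' total `stem_frac` of the sequence length, separated by a short loop;
#' flanks and random sequences are drawn from a first-order dinucleotide
#' Markov chain with transition matrix `dinuc_bias` (uniform by default).
#'
#' @param n_structured,n_random Sequence counts.
#' @param length_range Two integers, min/max sequence length (>= 40).
#' @param dinuc_bias 4x4 transition probability matrix (rows/cols A,C,G,T).
#' @param stem_frac Fraction of each structured sequence occupied by the two
#'   stem arms together (default 0.3).
#' @param seed Integer seed.
#' @return List with `sequences` (named uppercase character vector) and
#'   `truth` (data.frame `seq_id`, `structured`).
#' @export
make_sequences <- function(n_structured = 25, n_random = 25,
                           length_range = c(150, 300), dinuc_bias = NULL,
                           stem_frac = 0.3, seed = 1) {
  if (min(length_range) < 40) stop("sequence lengths must be >= 40")
  if (is.null(dinuc_bias))
    dinuc_bias <- matrix(0.25, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  if (!all(dim(dinuc_bias) == c(4, 4)) || any(dinuc_bias < 0))
    stop("dinuc_bias must be a non-negative 4x4 matrix")
  dinuc_bias <- dinuc_bias / rowSums(dinuc_bias)
  dimnames(dinuc_bias) <- list(DNA_BASES, DNA_BASES)
  local_seed(seed, {
    lenpool <- seq.int(length_range[1], length_range[2])
    lens <- lenpool[sample.int(length(lenpool), n_structured + n_random,
                               replace = TRUE)]
    seqs <- character(n_structured + n_random)
    for (i in seq_len(n_structured)) {
      L <- lens[i]
      arm <- ceiling(stem_frac * L / 2)
      loop <- 4L
      rest <- L - 2L * arm - loop
      pre <- markov_seq(ceiling(rest / 2), dinuc_bias)
      post <- markov_seq(rest - length(pre), dinuc_bias)
      armseq <- sample(DNA_BASES, arm, replace = TRUE)
      seqs[i] <- paste(c(pre, armseq, markov_seq(loop, dinuc_bias),
                         revcomp_chr(armseq), post), collapse = "")
    }
    for (i in seq_len(n_random))
      seqs[n_structured + i] <- paste(markov_seq(lens[n_structured + i], dinuc_bias),
                                      collapse = "")
    ids <- c(sprintf("struct%03d", seq_len(n_structured)),
             sprintf("rand%03d", seq_len(n_random)))
    names(seqs) <- ids
    list(
      sequences = seqs,
      truth = data.frame(
        seq_id = ids,
        structured = rep(c(TRUE, FALSE), c(n_structured, n_random)),
        stringsAsFactors = FALSE
      )
    )
  })
}

#' Simulate tumour evidence tables with planted events
#'
#' Plants three disjoint kinds of tumour evidence on a gene list: genes
#' downregulated in at least one tumour type (log2 FC <= -1.5 with tiny
#' q-value), genes recurrently homozygously deleted (homdel in 2-5% of
#' samples), and genes inside a focal deletion. Remaining genes are "clean":
#' near-zero fold changes, non-significant q-values, no homozygous deletions,
#' and no focal-deletion overlap. Also lays all genes out on one synthetic
#' chromosome (two exons each) so focal overlap is testable, and draws focal
#' amplifications that hit nothing.
#'
#' @param genes Character vector of gene ids.
#' @param n_tumour_types Number of tumour types in the DE table.
#' @param n_samples Number of copy-number samples.
#' @param frac_down,frac_deleted,frac_focal,frac_up Fractions of genes planted
#'   with each event (sampled without overlap between down/deleted/focal).
#' @param seed Integer seed.
#' @return List with `de_table` (gene, tumour_type, log2_fc, q), `cna`
#'   (character matrix genes x samples of the 5 copy-number categories),
#'   `focal_regions` (data.frame chrom, start, end, type, region_id),
#'   `models` (a [gene_models()] table for the synthetic chromosome) and
#'   `truth` (per gene: planted down/deleted/focal/clean flags).
#' @export
make_tumour_tables <- function(genes, n_tumour_types = 13, n_samples = 500,
                               frac_down = 0.2, frac_deleted = 0.1,
                               frac_focal = 0.05, frac_up = 0.15, seed = 1) {
  n <- length(genes)
  if (n == 0L) stop("no genes supplied")
  if (frac_down + frac_deleted + frac_focal > 1)
    stop("planted event fractions exceed 1")
  local_seed(seed, {
    types <- sprintf("TT%02d", seq_len(n_tumour_types))
    perm <- sample(genes)
    n_down <- round(frac_down * n)
    n_del <- round(frac_deleted * n)
    n_foc <- round(frac_focal * n)
    down_genes <- perm[seq_len(n_down)]
    del_genes <- perm[n_down + seq_len(n_del)]
    focal_genes <- perm[n_down + n_del + seq_len(n_foc)]
    up_genes <- sample(setdiff(genes, c(down_genes, del_genes, focal_genes)),
                       round(frac_up * n))

    # DE table: baseline noise everywhere, planted shifts in 1-3 types
    de <- expand.grid(gene = genes, tumour_type = types,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    de$log2_fc <- pmin(pmax(stats::rnorm(nrow(de), 0, 0.25), -0.9), 0.9)
    de$q <- stats::runif(nrow(de), 0.2, 1)
    plant <- function(de, gset, sign) {
      for (g in gset) {
        k <- sample(1:3, 1L)
        rows <- which(de$gene == g)[sample.int(n_tumour_types, k)]
        de$log2_fc[rows] <- sign * stats::runif(k, 1.5, 3)
        de$q[rows] <- stats::runif(k, 0, 0.01)
      }
      de
    }
    de <- plant(de, down_genes, -1)
    de <- plant(de, up_genes, +1)

    # copy-number category matrix
    cats <- c("hetloss", "diploid", "gain")
    cna <- matrix(
      sample(cats, n * n_samples, replace = TRUE, prob = c(0.1, 0.8, 0.1)),
      n, n_samples, dimnames = list(genes, sprintf("S%04d", seq_len(n_samples)))
    )
    for (g in del_genes) {
      rate <- stats::runif(1, 0.02, 0.05)
      k <- max(ceiling(rate * n_samples), ceiling(0.01 * n_samples))
      cna[g, sample.int(n_samples, k)] <- "homdel"
    }

    # genome layout: genes every 10 kb on chrS, two 400-bp exons each
    spacing <- 10000L
    starts <- spacing * (seq_len(n) - 1L) + 1000L
    models <- gene_models(data.frame(
      gene_id = rep(genes, each = 2L),
      chrom = "chrS",
      start = as.vector(rbind(starts, starts + 600L)),
      end = as.vector(rbind(starts + 400L, starts + 1000L)),
      strand = rep(sample(c("+", "-"), n, replace = TRUE), each = 2L),
      biotype = "lincRNA", stringsAsFactors = FALSE
    ))
    spans <- gene_spans(models)
    idx_foc <- match(focal_genes, spans$gene_id)
    focal_del <- data.frame(
      chrom = rep("chrS", length(idx_foc)),
      start = spans$start[idx_foc] - 100L,
      end = spans$end[idx_foc] + 100L,
      type = rep("del", length(idx_foc)),
      region_id = sprintf("FD%02d", seq_along(focal_genes)),
      stringsAsFactors = FALSE
    )
    # amplification regions placed in intergenic gaps (never overlap a gene)
    gap_idx <- sample.int(n, min(5L, n))
    focal_amp <- data.frame(
      chrom = "chrS",
      start = spacing * (gap_idx - 1L) + 5000L,
      end = spacing * (gap_idx - 1L) + 6000L,
      type = "amp",
      region_id = sprintf("FA%02d", seq_along(gap_idx)),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      gene_id = genes,
      down = genes %in% down_genes,
      up = genes %in% up_genes,
      deleted = genes %in% del_genes,
      focal = genes %in% focal_genes,
      stringsAsFactors = FALSE
    )
    truth$clean <- !(truth$down | truth$deleted | truth$focal)
    list(de_table = de, cna = cna,
         focal_regions = rbind(focal_del, focal_amp),
         models = models, truth = truth)
  })
}

#' Simulate promoter methylation probes with a low-methylation gene group
#'
#' Lays `hk_genes` and `ts_genes` out on a synthetic chromosome (alternating
#' strand), places `probes_per_gene` probes inside each promoter window
#' (-2000..+200 around the strand-aware TSS) plus one decoy probe outside it,
#' and draws Beta-distributed betas: low (Beta(2, 10)) for the HK group and
#' higher (Beta(5, 5)) for the TS group.
#'
#' @param hk_genes,ts_genes Gene id vectors.
#' @param n_samples Number of samples.
#' @param probes_per_gene Probes planted inside each promoter window.
#' @param seed Integer seed.
#' @return List with `betas` (probe x sample matrix), `probe_coords`
#'   (probe_id, chrom, pos), `models` (gene models) and `truth`.
#' @export
make_methylation <- function(hk_genes, ts_genes, n_samples = 30,
                             probes_per_gene = 5, seed = 1) {
  genes <- c(hk_genes, ts_genes)
  if (length(genes) == 0L) stop("no genes supplied")
  local_seed(seed, {
    n <- length(genes)
    spacing <- 20000L
    starts <- spacing * (seq_len(n) - 1L) + 5000L
    strands <- rep(c("+", "-"), length.out = n)
    models <- gene_models(data.frame(
      gene_id = genes, chrom = "chrM1",
      start = starts, end = starts + 2000L,
      strand = strands, biotype = "lincRNA", stringsAsFactors = FALSE
    ))
    spans <- gene_spans(models)
    coords <- list(); betas <- list()
    for (i in seq_len(n)) {
      tss <- spans$tss[match(genes[i], spans$gene_id)]
      # offsets relative to the strand-aware TSS, inside [-2000, 200)
      rel <- sample(seq(-1900L, 150L), probes_per_gene)
      pos <- if (strands[i] == "+") tss + rel else tss - rel - 1L
      pos <- c(pos, tss + if (strands[i] == "+") -5000L else 5000L) # decoy
      pid <- sprintf("%s_p%d", genes[i], seq_along(pos))
      coords[[i]] <- data.frame(probe_id = pid, chrom = "chrM1", pos = pos,
                                stringsAsFactors = FALSE)
      shp <- if (genes[i] %in% hk_genes) c(2, 10) else c(5, 5)
      betas[[i]] <- matrix(stats::rbeta(length(pos) * n_samples, shp[1], shp[2]),
                           length(pos), n_samples, dimnames = list(
                             pid, sprintf("samp%03d", seq_len(n_samples))))
    }
    list(
      betas = do.call(rbind, betas),
      probe_coords = do.call(rbind, coords),
      models = models,
      truth = data.frame(gene_id = genes,
                         group = rep(c("HK", "TS"),
                                     c(length(hk_genes), length(ts_genes))),
                         stringsAsFactors = FALSE)
    )
  })
}

#' Simulate pathway-driven co-expression of lincRNAs and coding genes
#'
#' Each pathway has a latent Gaussian factor per sample; its lincRNA and its
#' coding member genes load on the factor with loading `sqrt(r_target)`, so
#' pairwise Pearson correlation is approximately `r_target`. Noise coding
#' genes are independent. Values are shifted/scaled to a non-negative
#' FPKM-like range (an affine map, so Pearson correlations are preserved).
#'
#' @param n_samples Number of samples.
#' @param n_pathways Number of planted pathways (one lincRNA each).
#' @param genes_per_pathway Coding genes per pathway.
#' @param n_noise_genes Independent coding genes.
#' @param n_decoy_sets Random decoy gene sets added to the collection.
#' @param r_target Target lincRNA-member Pearson correlation.
#' @param seed Integer seed.
#' @return List with `matrix` (expression matrix over lincRNAs + coding
#'   genes), `gene_sets` (planted + decoy sets, GMT-style list) and `truth`
#'   (lincRNA -> planted set name).
#' @export
make_coexpression <- function(n_samples = 100, n_pathways = 3,
                              genes_per_pathway = 30, n_noise_genes = 500,
                              n_decoy_sets = 20, r_target = 0.7, seed = 1) {
  if (r_target <= 0 || r_target >= 1) stop("r_target must be in (0, 1)")
  local_seed(seed, {
    lam <- sqrt(r_target)
    lincs <- sprintf("linc%02d", seq_len(n_pathways))
    z <- function(n) stats::rnorm(n)
    rows <- list()
    sets <- list()
    for (p in seq_len(n_pathways)) {
      f <- z(n_samples)
      rows[[lincs[p]]] <- lam * f + sqrt(1 - lam^2) * z(n_samples)
      members <- sprintf("PW%d_g%03d", p, seq_len(genes_per_pathway))
      for (g in members)
        rows[[g]] <- lam * f + sqrt(1 - lam^2) * z(n_samples)
      sets[[sprintf("PATHWAY_%d", p)]] <- members
    }
    noise <- sprintf("NG%04d", seq_len(n_noise_genes))
    for (g in noise) rows[[g]] <- z(n_samples)
    for (d in seq_len(n_decoy_sets))
      sets[[sprintf("DECOY_%d", d)]] <- sample(noise, genes_per_pathway)
    m <- do.call(rbind, rows)
    m <- pmax(10 + 2 * m, 0)   # affine to FPKM-like scale; cor unchanged
    colnames(m) <- sprintf("samp%03d", seq_len(n_samples))
    attr(sets, "description") <- stats::setNames(
      rep("synthetic", length(sets)), names(sets))
    list(
      matrix = expression_matrix(m),
      gene_sets = sets,
      truth = data.frame(lincrna = lincs,
                         set = sprintf("PATHWAY_%d", seq_len(n_pathways)),
                         stringsAsFactors = FALSE)
    )
  })
}

#' Simulate survival records with an expression-dependent hazard
#'
#' Expression is lognormal; patients above its 75th percentile form the
#' high-expression group, whose exponential event hazard is multiplied by
#' `hazard_ratio`. Independent exponential censoring is tuned to roughly
#' `censor_frac` censored records.
#'
#' @param n_patients Number of patients (>= 8).
#' @param hazard_ratio Event-hazard multiplier for the high group.
#' @param censor_frac Approximate fraction censored.
#' @param seed Integer seed.
#' @return List with `records` (patient_id, time, event, expression) and
#'   `truth` (planted group per patient).
#' @export
make_survival <- function(n_patients = 400, hazard_ratio = 2,
                          censor_frac = 0.5, seed = 1) {
  if (n_patients < 8) stop("need at least 8 patients")
  local_seed(seed, {
    expr <- stats::rlnorm(n_patients, log(5), 0.6)
    thr <- stats::quantile(expr, 0.75, type = 7)
    high <- expr > thr
    base <- 1 / 365
    tte <- stats::rexp(n_patients, base * ifelse(high, hazard_ratio, 1))
    # censoring rate matched to the marginal event rate
    cens <- stats::rexp(n_patients,
                        base * mean(ifelse(high, hazard_ratio, 1)) *
                          censor_frac / max(1 - censor_frac, 0.05))
    time <- pmin(tte, cens)
    records <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n_patients)),
      time = time, event = as.integer(tte <= cens),
      expression = expr, stringsAsFactors = FALSE
    )
    list(records = records,
         truth = data.frame(patient_id = records$patient_id,
                            group = ifelse(high, "high", "low"),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate per-base annotation tracks over a set of gene models
#'
#' Draws a sparse per-base conservation-score track (a configurable fraction
#' of exonic bases scored, Gaussian scores), SNP positions at a target exonic
#' density, and labelled repeat intervals overlapping a subset of exons.
#'
#' @param models A [gene_models()] table.
#' @param seed Integer seed.
#' @param score_coverage Fraction of exonic bases with a conservation score.
#' @param snp_per_kb Expected SNPs per kb of exon.
#' @param repeat_classes Repeat class labels to draw from.
#' @return List with `conservation` (chrom, pos, score), `snps` (chrom, pos)
#'   and `repeats` (chrom, start, end, class).
#' @export
make_annotation_tracks <- function(models, seed = 1, score_coverage = 0.7,
                                   snp_per_kb = 19,
                                   repeat_classes = c("SINE/Alu", "LINE/L1", "LTR/ERV")) {
  local_seed(seed, {
    exon_bases <- unlist(lapply(seq_len(nrow(models)), function(i)
      seq(models$start[i], models$end[i] - 1L)))
    chrom <- models$chrom[1]
    scored <- sort(sample(exon_bases, round(score_coverage * length(exon_bases))))
    cons <- data.frame(chrom = chrom, pos = scored,
                       score = stats::rnorm(length(scored), 0.13, 0.3),
                       stringsAsFactors = FALSE)
    n_snp <- stats::rbinom(1, length(exon_bases), snp_per_kb / 1000)
    snps <- data.frame(chrom = chrom,
                       pos = sort(sample(exon_bases, n_snp)),
                       stringsAsFactors = FALSE)
    spans <- gene_spans(models)
    hit <- sample.int(nrow(spans), max(1L, nrow(spans) %/% 3L))
    reps <- data.frame(
      chrom = chrom,
      start = spans$start[hit] + sample(0:200, length(hit), replace = TRUE),
      class = sample(repeat_classes, length(hit), replace = TRUE),
      stringsAsFactors = FALSE
    )
    reps$end <- reps$start + sample(100:300, length(hit), replace = TRUE)
    list(conservation = cons, snps = snps,
         repeats = reps[, c("chrom", "start", "end", "class")])
  })
}

# Toy ontology over gene-set names: leaves under a few intermediate nodes
# under one root, so semantic-similarity reduction has structure to work on.
make_set_ontology <- function(set_names, seed = 1, n_mid = 3) {
  local_seed(seed, {
    mids <- sprintf("MID:%d", seq_len(n_mid))
    edges <- rbind(
      data.frame(child = mids, parent = "ROOT:1", rel = "is_a",
                 stringsAsFactors = FALSE),
      data.frame(child = set_names,
                 parent = sample(mids, length(set_names), replace = TRUE),
                 rel = sample(c("is_a", "part_of"), length(set_names),
                              replace = TRUE, prob = c(0.8, 0.2)),
                 stringsAsFactors = FALSE)
    )
    structure(list(
      terms = c("ROOT:1", mids, set_names),
      name = stats::setNames(c("root", mids, set_names),
                             c("ROOT:1", mids, set_names)),
      edges = edges
    ), class = "ontology")
  })
}

#' Write a full set of synthetic pipeline inputs to disk
#'
#' Generates all fixture files the pipeline consumes (expression matrix,
#' gene models, sequences, tumour tables, methylation, co-expression, gene
#' sets, survival) plus a `truth.json` describing every planted signal.
#'
#' @param dir Output directory (created if absent).
#' @param seed Master seed; each generator gets a derived child seed.
#' @param n_hk,n_ts,n_bg Gene-class sizes for the tissue matrix.
#' @return Invisibly, a named list of the written file paths.
#' @export
simulate_inputs <- function(dir, seed = 1, n_hk = 30, n_ts = 30, n_bg = 60) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  tm <- make_tissue_matrix(n_hk, n_ts, n_bg, seed = derive_seed(seed, "tissue"))
  write_matrix(tm$matrix, p("expression.tsv"))
  hk <- tm$truth$gene_id[tm$truth$class == "HK"]
  ts <- tm$truth$gene_id[tm$truth$class == "TS"]
  sq <- make_sequences(n_structured = length(hk), n_random = length(ts),
                       seed = derive_seed(seed, "seq"))
  seqs <- sq$sequences
  names(seqs) <- c(hk, ts)
  write_fasta(seqs, p("sequences.fa"))
  tt <- make_tumour_tables(hk, seed = derive_seed(seed, "tumour"))
  utils::write.table(tt$de_table, p("de_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = rownames(tt$cna), tt$cna,
                                check.names = FALSE),
                     p("cna.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tt$focal_regions, p("focal_regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gene_models(tt$models, p("tumour_genes.bed"))
  tr <- make_annotation_tracks(tt$models, seed = derive_seed(seed, "tracks"))
  utils::write.table(tr$conservation, p("conservation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tr$snps, p("snps.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(tr$repeats, p("repeats.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  me <- make_methylation(hk, ts, seed = derive_seed(seed, "methyl"))
  utils::write.table(data.frame(probe_id = rownames(me$betas), me$betas,
                                check.names = FALSE),
                     p("methylation_betas.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(me$probe_coords, p("probe_coords.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gene_models(me$models, p("methylation_genes.bed"))
  co <- make_coexpression(seed = derive_seed(seed, "coexpr"))
  write_matrix(co$matrix, p("coexpression.tsv"))
  write_gmt(co$gene_sets, p("gene_sets.gmt"))
  write_obo(make_set_ontology(names(co$gene_sets),
                              seed = derive_seed(seed, "onto")),
            p("ontology.obo"))
  sv <- make_survival(seed = derive_seed(seed, "survival"))
  utils::write.table(sv$records, p("survival.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(
    gene_class = tm$truth, sequence = sq$truth, tumour = tt$truth,
    methylation = me$truth, coexpression = co$truth, survival = sv$truth
  )
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns")
  files <- stats::setNames(
    lapply(c("expression.tsv", "sequences.fa", "de_table.tsv", "cna.tsv",
             "focal_regions.tsv", "tumour_genes.bed", "conservation.tsv",
             "snps.tsv", "repeats.tsv", "methylation_betas.tsv",
             "probe_coords.tsv", "methylation_genes.bed", "coexpression.tsv",
             "gene_sets.gmt", "ontology.obo", "survival.tsv", "truth.json"), p),
    c("expression", "sequences", "de_table", "cna", "focal_regions",
      "tumour_genes", "conservation", "snps", "repeats", "methylation_betas",
      "probe_coords", "methylation_genes", "coexpression", "gene_sets",
      "ontology", "survival", "truth")
  )
  invisible(files)
}
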