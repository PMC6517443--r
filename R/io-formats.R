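# Readers and writers for the on-disk formats the pipeline touches.
# All genomic coordinates are converted to 0-based half-open on the way in.

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and gene ids in the first column.
#'
#' @param path TSV file path.
#' @param tissue_of_sample Optional named character vector (sample -> tissue);
#'   defaults to one tissue per sample.
#' @param na Policy for missing values: `"error"` (default) or `"zero"`.
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, tissue_of_sample = NULL, na = c("error", "zero")) {
  na <- match.arg(na)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("matrix file needs a gene id column plus samples")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicate gene id in ", path)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    if (na == "error") stop("missing values in ", path)
    m[is.na(m)] <- 0
  }
  rownames(m) <- ids
  expression_matrix(m, tissue_of_sample)
}

#' Write an expression matrix as TSV
#' @param x An `expr_matrix`.
#' @param path Output path.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  tab <- data.frame(gene_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file
#'
#' Sequences are uppercased with U mapped to T; whether a record contained
#' lowercase (soft-masked) characters is kept in the `softmasked` attribute.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences over A, C, G, T, N.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  raw <- as.character(ss)
  masked <- grepl("[acgtun]", raw)
  seqs <- chartr("Uu", "Tt", toupper(raw))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in records: ",
         paste(names(seqs)[bad], collapse = ", "))
  attr(seqs, "softmasked") <- stats::setNames(masked, names(seqs))
  seqs
}

#' Write sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read gene models from GTF or BED12
#'
#' GTF exon rows (1-based closed) and BED12 blocks (already 0-based
#' half-open) are converted to the internal 0-based half-open convention.
#' Gene biotype is taken from the GTF `gene_biotype`/`gene_type` attribute
#' when present; values other than `protein_coding`/`lincRNA` collapse to
#' `other`.
#'
#' @param path Annotation file.
#' @param dialect `"gtf"` or `"bed12"`.
#' @param default_biotype Biotype used when the file carries none (BED12).
#' @return A [gene_models()] table.
#' @export
read_gene_models <- function(path, dialect = c("gtf", "bed12"),
                             default_biotype = "other") {
  dialect <- match.arg(dialect)
  if (dialect == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[!is.na(gr$type) & gr$type == "exon"]
    if (length(gr) == 0L) stop("no exon records in ", path)
    bt <- if ("gene_biotype" %in% names(S4Vectors::mcols(gr))) gr$gene_biotype
          else if ("gene_type" %in% names(S4Vectors::mcols(gr))) gr$gene_type
          else rep(default_biotype, length(gr))
    bt[is.na(bt)] <- default_biotype
    bt[!bt %in% c("protein_coding", "lincRNA")] <- "other"
    strand <- as.character(BiocGenerics::strand(gr))
    if (any(strand == "*")) stop("unknown strand in ", path)
    exons <- data.frame(
      gene_id = as.character(gr$gene_id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = strand, biotype = bt, stringsAsFactors = FALSE
    )
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    exons <- do.call(rbind, lapply(seq_along(fields), function(i) {
      f <- fields[[i]]
      if (length(f) < 12L)
        stop("BED12 needs 12 columns (line ", i, ")")
      if (!f[6] %in% c("+", "-", "."))
        stop("unknown strand '", f[6], "' (line ", i, ")")
      chrom_start <- as.integer(f[2])
      if (is.na(chrom_start) || chrom_start < 0)
        stop("bad start coordinate (line ", i, ")")
      n_blocks <- as.integer(f[10])
      sizes <- as.integer(strsplit(f[11], ",")[[1]])[seq_len(n_blocks)]
      offs <- as.integer(strsplit(f[12], ",")[[1]])[seq_len(n_blocks)]
      data.frame(
        gene_id = f[4], chrom = f[1],
        start = chrom_start + offs, end = chrom_start + offs + sizes,
        strand = f[6], biotype = default_biotype, stringsAsFactors = FALSE
      )
    }))
  }
  gene_models(exons)
}

#' Write gene models as BED12
#' @param models A `gene_models` table.
#' @param path Output path.
#' @export
write_gene_models <- function(models, path) {
  lines <- vapply(split(models, models$gene_id), function(g) {
    g <- g[order(g$start), ]
    s0 <- min(g$start); e0 <- max(g$end)
    paste(g$chrom[1], s0, e0, g$gene_id[1], 0, g$strand[1], s0, e0, "0,0,0",
          nrow(g), paste0(paste(g$end - g$start, collapse = ","), ","),
          paste0(paste(g$start - s0, collapse = ","), ","), sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3/BED6 file as an interval table
#'
#' @param path BED file (0-based half-open, as the format defines).
#' @return data.frame with `chrom`, `start`, `end` and, when present, `name`
#'   (e.g. a repeat class), `score`, `strand`.
#' @export
read_bed <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(tab)[seq_len(min(6L, ncol(tab)))] <-
    c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(6L, ncol(tab)))]
  validate_intervals(tab)
  tab
}

#' Read a GMT gene-set collection
#'
#' Tab-separated: set name, description, then member gene ids. Empty sets are
#' dropped with a warning; duplicate set names are an error.
#'
#' @param path GMT file.
#' @return Named list of gene-id character vectors with a `description`
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  fields <- fields[vapply(fields, length, 1L) > 0L]
  names <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(names)) stop("duplicate gene-set names in ", path)
  desc <- vapply(fields, function(f) if (length(f) >= 2L) f[2] else "", "")
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- names
  empty <- vapply(sets, length, 1L) == 0L
  if (any(empty)) {
    warning("dropping empty gene sets: ", paste(names[empty], collapse = ", "))
    sets <- sets[!empty]; desc <- desc[!empty]; names <- names[!empty]
  }
  attr(sets, "description") <- stats::setNames(desc, names)
  sets
}

#' Write a gene-set collection as GMT
#' @param sets Named list of gene-id vectors (optionally with a `description`
#'   attribute).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an OBO-subset ontology
#'
#' Parses `[Term]` stanzas for `id`, `name`, `is_a` and
#' `relationship: part_of` edges, and verifies the graph is acyclic.
#'
#' @param path OBO file.
#' @return List of class `ontology`: `terms` (character), `name` (named
#'   character), `edges` (data.frame `child`, `parent`, `rel`).
#' @export
read_obo <- function(path) {
  lines <- trimws(readLines(path))
  in_term <- FALSE
  id <- NULL
  terms <- character(0); nm <- character(0)
  edges <- list()
  for (ln in lines) {
    if (ln == "[Term]") { in_term <- TRUE; id <- NULL; next }
    if (startsWith(ln, "[")) { in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) {
      id <- trimws(sub("^id:", "", ln))
      terms <- c(terms, id)
    } else if (startsWith(ln, "name:")) {
      nm[id] <- trimws(sub("^name:", "", ln))
    } else if (startsWith(ln, "is_a:")) {
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      edges[[length(edges) + 1L]] <- c(id, p, "is_a")
    } else if (startsWith(ln, "relationship: part_of")) {
      p <- trimws(sub("!.*$", "", sub("^relationship: part_of", "", ln)))
      edges[[length(edges) + 1L]] <- c(id, p, "part_of")
    }
  }
  edges <- if (length(edges))
    stats::setNames(as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE),
                    c("child", "parent", "rel"))
  else data.frame(child = character(0), parent = character(0), rel = character(0))
  onto <- structure(list(terms = unique(terms), name = nm, edges = edges),
                    class = "ontology")
  check_acyclic(onto)
  onto
}

# Topological check; stops with an error if the parent graph has a cycle.
check_acyclic <- function(onto) {
  remaining <- onto$terms
  edges <- onto$edges
  repeat {
    if (length(remaining) == 0L) return(invisible(TRUE))
    has_child <- remaining %in% edges$parent[edges$child %in% remaining]
    leaves <- remaining[!has_child]
    if (length(leaves) == 0L)
      stop("cycle detected in ontology involving: ",
           paste(utils::head(remaining, 5L), collapse = ", "))
    remaining <- setdiff(remaining, leaves)
  }
}

#' Write an OBO-subset ontology
#' @param onto An `ontology`.
#' @param path Output path.
#' @export
write_obo <- function(onto, path) {
  out <- c("format-version: 1.2", "")
  for (t in onto$terms) {
    stanza <- c("[Term]", paste("id:", t))
    if (t %in% names(onto$name)) stanza <- c(stanza, paste("name:", onto$name[[t]]))
    e <- onto$edges[onto$edges$child == t, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      stanza <- c(stanza, if (e$rel[i] == "is_a") paste("is_a:", e$parent[i])
                  else paste("relationship: part_of", e$parent[i]))
    }
    out <- c(out, stanza, "")
  }
  writeLines(out, path)
  invisible(path)
}
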