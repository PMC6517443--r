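# Independent brute-force oracles used to validate the fast implementations.

# Per-base set-membership intersection length on small coordinate ranges.
oracle_intersect_length <- function(a, b, max_base = 1000L) {
  covered <- function(tab) {
    keys <- character(0)
    for (i in seq_len(nrow(tab)))
      if (tab$end[i] > tab$start[i])
        keys <- c(keys, paste(tab$chrom[i],
                              seq(tab$start[i], tab$end[i] - 1L)))
    unique(keys)
  }
  length(intersect(covered(a), covered(b)))
}

# Maximum nested base pairs by exhaustive recursion (no memoisation) over all
# valid structures; feasible for sequences up to ~12 bases.
oracle_max_pairs <- function(seq, min_loop = 3L) {
  v <- strsplit(seq, "")[[1]]
  ok <- function(a, b) paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j)
    for (k in seq(i + min_loop + 1L, j)) {
      if (ok(v[i], v[k]))
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  if (length(v) < 2L) return(0L)
  rec(1L, length(v))
}

# Weighted KS enrichment score by walking the full running sum.
oracle_enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  hit <- names(ranked) %in% gene_set
  nh <- sum(hit)
  w <- abs(ranked)^weight_p
  wh <- sum(w[hit])
  if (wh == 0) { w[] <- 1; wh <- nh }
  run <- cumsum(ifelse(hit, w / wh, -1 / (length(ranked) - nh)))
  maxP <- max(run)
  minP <- min(c(run, 0))
  if (abs(maxP + minP) < 1e-9) 0 else if (maxP > -minP) maxP else minP
}

# Dinucleotide count vector of a sequence.
dinuc_counts <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  if (length(v) < 2L) return(table(character(0)))
  table(paste0(v[-length(v)], v[-1L]))
}

rand_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Random interval table on one chromosome, for interval-oracle comparisons.
rand_intervals <- function(n, max_base = 100L, chrom = "c1") {
  s <- sample.int(max_base, n, replace = TRUE) - 1L
  w <- sample.int(20L, n, replace = TRUE)
  data.frame(chrom = chrom, start = s, end = s + w)
}
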