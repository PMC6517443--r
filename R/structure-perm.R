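# Stage 3: Randfold-style structure-stability test. A folding score is
# compared against a null built from dinucleotide-preserving shuffles of the
# same sequence; one-sided permutation p-values get BH FDR across genes.

#' Dinucleotide-preserving shuffle
#'
#' Random permutation of a sequence that preserves the exact multiset of
#' adjacent-pair (dinucleotide) counts, and hence also mononucleotide counts,
#' the first and last base, and the length. Uses the Altschul-Erickson
#' Eulerian-path construction: a random "last exit" edge is drawn for every
#' vertex until the last-edge graph is a tree into the terminal base, then the
#' remaining edges are walked in random order. Uses the R RNG; seed outside.
#'
#' @param seq A single string over A, C, G, T (U is mapped to T). `N` handling
#'   per `on_n`.
#' @param on_n `"error"` rejects sequences containing N; `"split"` shuffles
#'   each N-free segment independently, leaving the Ns in place.
#' @return The shuffled sequence string.
#' @export
dinucleotide_shuffle <- function(seq, on_n = c("error", "split")) {
  on_n <- match.arg(on_n)
  if (length(seq) != 1L || !is.character(seq)) stop("`seq` must be one string")
  s <- chartr("Uu", "Tt", toupper(seq))
  if (grepl("N", s, fixed = TRUE)) {
    if (on_n == "error") stop("sequence contains N")
    parts <- strsplit(s, "")[[1]]
    is_n <- parts == "N"
    runs <- split(seq_along(parts)[!is_n],
                  cumsum(is_n)[!is_n])
    for (r in runs)
      if (length(r) >= 2L)
        parts[r] <- strsplit(shuffle_core(paste(parts[r], collapse = "")), "")[[1]]
    return(paste(parts, collapse = ""))
  }
  shuffle_core(s)
}

shuffle_core <- function(s) {
  if (grepl("[^ACGT]", s)) stop("sequence must be over {A,C,G,T}")
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  if (n <= 3L) return(s)
  succ <- split(v[-1L], factor(v[-n], levels = DNA_BASES))
  last <- v[n]
  verts <- DNA_BASES[vapply(succ, length, 1L) > 0L]
  need_last <- setdiff(verts, last)
  if (length(need_last)) {
    repeat {
      last_edge <- vapply(need_last, function(x) {
        e <- succ[[x]]; e[sample.int(length(e), 1L)]
      }, "")
      ok <- TRUE
      for (x in need_last) {
        seen <- character(0); cur <- x
        while (cur != last) {
          if (cur %in% seen || !(cur %in% need_last)) { ok <- FALSE; break }
          seen <- c(seen, cur); cur <- last_edge[[cur]]
        }
        if (!ok) break
      }
      if (ok) break
    }
  }
  lists <- lapply(DNA_BASES, function(x) {
    e <- succ[[x]]
    if (length(e) == 0L) return(e)
    if (x %in% need_last) {
      idx <- match(last_edge[[x]], e)
      rest <- e[-idx]
      c(rest[sample.int(length(rest))], e[idx])
    } else e[sample.int(length(e))]
  })
  names(lists) <- DNA_BASES
  ptr <- stats::setNames(rep(1L, 4L), DNA_BASES)
  out <- character(n)
  out[1L] <- v[1L]
  cur <- v[1L]
  for (i in 2:n) {
    nxt <- lists[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Folding score of a sequence
#'
#' The default `nussinov` engine returns minus the maximum number of nested
#' Watson-Crick/GU base pairs with a minimum hairpin loop of 3 unpaired
#' bases, computed by the O(n^3) dynamic program; lower = more stable, like a
#' folding energy. The `vienna` engine shells out to RNAfold (ViennaRNA) and
#' returns the thermodynamic minimum free energy in kcal/mol.
#'
#' @param seqs Character vector of sequences (A/C/G/T; U mapped to T).
#' @param engine `"nussinov"` (default) or `"vienna"`.
#' @param min_loop Minimum number of unpaired bases in a hairpin loop
#'   (nussinov engine).
#' @param vienna_cmd Folding command for the vienna engine.
#' @return Numeric vector of scores, one per sequence.
#' @export
fold_score <- function(seqs, engine = c("nussinov", "vienna"), min_loop = 3,
                       vienna_cmd = "RNAfold") {
  engine <- match.arg(engine)
  seqs <- chartr("Uu", "Tt", toupper(seqs))
  if (engine == "nussinov")
    return(vapply(seqs, function(s) -as.numeric(.nussinov_pairs(s, min_loop)),
                  0, USE.NAMES = FALSE))
  if (Sys.which(vienna_cmd) == "")
    stop("external folding command not found: ", vienna_cmd)
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa))
  writeLines(as.vector(rbind(paste0(">q", seq_along(seqs)), seqs)), fa)
  out <- system2(vienna_cmd, c("--noPS", "--infile", fa), stdout = TRUE)
  mfel <- grep("\\(\\s*-?[0-9.]+\\)$", out, value = TRUE)
  if (length(mfel) != length(seqs))
    stop("could not parse ", vienna_cmd, " output")
  as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)$", "\\1", mfel))
}

#' Permutation test of secondary-structure stability
#'
#' For each sequence, compares the observed folding score against
#' `n_shuffles` dinucleotide-preserving shuffles. The one-sided (stability)
#' p-value uses the add-one convention p = (1 + #\{null <= observed\}) /
#' (n_shuffles + 1); q-values are BH-adjusted across all tested sequences.
#' Each sequence gets a child seed derived from its name, so results do not
#' depend on iteration order.
#'
#' @param seqs Named character vector of sequences.
#' @param n_shuffles Number of shuffles (>= 19; default 1000).
#' @param engine Folding engine, see [fold_score()].
#' @param seed Master seed.
#' @param min_loop,vienna_cmd Passed to [fold_score()].
#' @return data.frame `gene_id`, `observed_score`, `p_value`, `q_value`,
#'   `n_shuffles`, with the per-gene null scores in the `null_scores`
#'   attribute (a named list). Sequences shorter than 4 bases are skipped
#'   with a warning.
#' @export
structure_test <- function(seqs, n_shuffles = 1000,
                           engine = c("nussinov", "vienna"), seed = 1,
                           min_loop = 3, vienna_cmd = "RNAfold") {
  engine <- match.arg(engine)
  if (n_shuffles < 19) stop("need n_shuffles >= 19")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("`seqs` must have unique names")
  short <- nchar(seqs) < 4L
  if (any(short)) {
    warning("skipping sequences shorter than 4 bases: ",
            paste(names(seqs)[short], collapse = ", "))
    seqs <- seqs[!short]
  }
  ids <- names(seqs)
  obs <- numeric(length(seqs))
  pvals <- numeric(length(seqs))
  nulls <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    local_seed(derive_seed(seed, ids[i]), {
      shuf <- replicate(n_shuffles, dinucleotide_shuffle(seqs[[i]]))
      sc <- fold_score(c(seqs[[i]], shuf), engine = engine,
                       min_loop = min_loop, vienna_cmd = vienna_cmd)
      obs[i] <- sc[1L]
      nulls[[i]] <- sc[-1L]
      pvals[i] <- (1 + sum(sc[-1L] <= sc[1L])) / (n_shuffles + 1)
    })
  }
  res <- data.frame(
    gene_id = ids, observed_score = obs, p_value = pvals,
    q_value = bh_fdr(pvals), n_shuffles = n_shuffles,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "null_scores") <- stats::setNames(nulls, ids)
  res
}
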