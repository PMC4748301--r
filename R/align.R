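#' Parameters for the seed-and-extend nucleotide homology search
#'
#' Scoring is ungapped +1/-2 (match/mismatch); E-values use the
#' Karlin-Altschul formula E = K * m * n * exp(-lambda * S) with the
#' published ungapped parameters for +1/-2 (lambda = 1.28, K = 0.46).
#'
#' @param word_size exact-seed length in bp.
#' @param match,mismatch per-position scores.
#' @param x_drop extension stops when the running score drops this far below
#'   its maximum; the hit is trimmed back to the maximum.
#' @param lambda,k_const Karlin-Altschul parameters.
#' @param e_value_max hits with larger E-value are discarded.
#' @param min_identity hits with lower fractional identity are discarded.
#' @return named list of parameters.
#' @export
search_params <- function(word_size = 11L, match = 1, mismatch = -2,
                          x_drop = 20, lambda = 1.28, k_const = 0.46,
                          e_value_max = 1e-5, min_identity = 0.20) {
  stopifnot(word_size >= 4L, e_value_max > 0,
            min_identity >= 0, min_identity <= 1)
  list(word_size = as.integer(word_size), match = match, mismatch = mismatch,
       x_drop = x_drop, lambda = lambda, k_const = k_const,
       e_value_max = e_value_max, min_identity = min_identity)
}

#' Karlin-Altschul E-value for an ungapped score
#' @param score alignment raw score.
#' @param m,n query and subject lengths (bp).
#' @param params see [search_params()].
#' @return E-value.
#' @export
karlin_evalue <- function(score, m, n, params = search_params()) {
  params$k_const * m * n * exp(-params$lambda * score)
}

# positions (1-based) of every word_size-mer, keyed by k-mer string
index_kmers <- function(s, w) {
  n <- nchar(s)
  if (n < w) return(list())
  pos <- seq_len(n - w + 1L)
  split(pos, substring(s, pos, pos + w - 1L))
}

#' Seed-and-extend local alignment of one query against one subject
#'
#' Exact `word_size`-mer seeds are located via a subject k-mer index and
#' extended without gaps in both directions until the running score drops
#' `x_drop` below its maximum; the extension is trimmed back to the maximum.
#' Overlapping hits on the same diagonal are merged (best kept). Hits are
#' filtered by `e_value_max` and `min_identity`.
#'
#' @param query,subject nucleotide strings (or length-1 named `DNAStringSet`).
#' @param params see [search_params()].
#' @param query_id,subject_id IDs recorded in the output.
#' @return data.frame of hits in the layout of [read_blast_tabular()].
#' @export
local_align <- function(query, subject, params = search_params(),
                        query_id = "query", subject_id = "subject") {
  query <- single_seq(query)
  subject <- single_seq(subject)
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  w <- params$word_size
  idx <- index_kmers(subject, w)
  align_against_index(query, subject, idx, params, query_id, subject_id)
}

single_seq <- function(x) {
  if (methods::is(x, "XStringSet")) x <- as.character(x)[1]
  if (methods::is(x, "XString")) x <- as.character(x)
  toupper(x)
}

align_against_index <- function(query, subject, idx, params,
                                query_id, subject_id) {
  w <- params$word_size
  lq <- nchar(query)
  ls <- nchar(subject)
  if (lq < w || ls < w) return(empty_hits())
  qpos <- seq_len(lq - w + 1L)
  qk <- substring(query, qpos, qpos + w - 1L)
  hitlist <- list()
  qchars <- strsplit(query, "")[[1]]
  schars <- strsplit(subject, "")[[1]]
  present <- qk %in% names(idx)
  if (!any(present)) return(empty_hits())
  # group seeds by diagonal (s - q); keep the best extension per diagonal run
  seeds <- do.call(rbind, lapply(which(present), function(i) {
    cbind(q = i, s = idx[[qk[i]]])
  }))
  diag <- seeds[, "s"] - seeds[, "q"]
  out <- list()
  for (d in unique(diag)) {
    ds <- seeds[diag == d, , drop = FALSE]
    ds <- ds[order(ds[, "q"]), , drop = FALSE]
    # per-position +1/-2 scores along this diagonal
    qlo <- max(1L, 1L - d)
    qhi <- min(lq, ls - d)
    qi <- qlo:qhi
    mvec <- qchars[qi] == schars[qi + d] & qchars[qi] %in% DNA_BASES
    svec <- ifelse(mvec, params$match, params$mismatch)
    covered_to <- 0L
    for (r in seq_len(nrow(ds))) {
      qstart <- ds[r, "q"]
      if (qstart <= covered_to) next  # seed inside the previous extension
      seg <- extend_xdrop(svec, qstart - qlo + 1L, w, params$x_drop)
      if (is.null(seg)) next
      a <- seg$from + qlo - 1L
      b <- seg$to + qlo - 1L
      covered_to <- b
      nmatch <- sum(mvec[(a - qlo + 1L):(b - qlo + 1L)])
      len <- b - a + 1L
      e <- karlin_evalue(seg$score, lq, ls, params)
      out[[length(out) + 1L]] <- data.frame(
        query_id = query_id, subject_id = subject_id,
        percent_identity = nmatch / len, align_length = len,
        q_start = a, q_end = b, s_start = a + d, s_end = b + d,
        score = seg$score, e_value = e, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_hits())
  hits <- do.call(rbind, out)
  hits <- merge_diagonal_hits(hits)
  hits <- hits[hits$e_value <= params$e_value_max &
               hits$percent_identity >= params$min_identity, , drop = FALSE]
  rownames(hits) <- NULL
  hits[order(hits$e_value, hits$q_start), , drop = FALSE]
}

# x-drop ungapped extension of a seed occupying positions
# [seed_from, seed_from + w - 1] of the per-position score vector
extend_xdrop <- function(svec, seed_from, w, x_drop) {
  seed_to <- seed_from + w - 1L
  if (seed_to > length(svec)) return(NULL)
  seed_score <- sum(svec[seed_from:seed_to])
  right <- xdrop_one_side(svec, seed_to, 1L, x_drop)
  left <- xdrop_one_side(svec, seed_from, -1L, x_drop)
  list(from = seed_from - left$n, to = seed_to + right$n,
       score = seed_score + right$gain + left$gain)
}

xdrop_one_side <- function(svec, edge, dir, x_drop) {
  if (edge + dir < 1L || edge + dir > length(svec)) {
    return(list(n = 0L, gain = 0))
  }
  ids <- if (dir > 0) seq(edge + 1L, length(svec)) else seq(edge - 1L, 1L)
  cs <- cumsum(svec[ids])
  cm <- cummax(cs)
  stop_at <- which(cm - cs >= x_drop)
  lim <- if (length(stop_at)) stop_at[1L] else length(ids)
  best <- which.max(cs[seq_len(lim)])
  if (cs[best] <= 0) return(list(n = 0L, gain = 0))
  list(n = best, gain = cs[best])
}

# merge overlapping hits on the same diagonal, keeping the best score
merge_diagonal_hits <- function(hits) {
  d <- hits$s_start - hits$q_start
  keep <- rep(TRUE, nrow(hits))
  for (dd in unique(d)) {
    ids <- which(d == dd)
    if (length(ids) < 2L) next
    ids <- ids[order(hits$q_start[ids])]
    for (i in seq_along(ids)[-1L]) {
      a <- ids[i - 1L]; b <- ids[i]
      if (hits$q_start[b] <= hits$q_end[a]) {
        worse <- if (hits$score[a] >= hits$score[b]) b else a
        keep[worse] <- FALSE
      }
    }
  }
  hits[keep, , drop = FALSE]
}

#' Align a set of queries against a set of subject sequences
#' @param queries named `DNAStringSet` (or named character).
#' @param subjects named `DNAStringSet` (or named character or FASTA path).
#' @param params see [search_params()].
#' @return data.frame of all surviving hits.
#' @export
align_sets <- function(queries, subjects, params = search_params()) {
  queries <- as_named_seqs(queries)
  subjects <- as_named_seqs(as_genome_or_seqs(subjects))
  out <- list()
  for (sj in names(subjects)) {
    idx <- index_kmers(subjects[[sj]], params$word_size)
    for (qi in names(queries)) {
      h <- align_against_index(queries[[qi]], subjects[[sj]], idx, params,
                               qi, sj)
      if (nrow(h)) out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out)) return(empty_hits())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

as_genome_or_seqs <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(as_genome(x))
  }
  x
}

#' Multi-species conservation summary for a lincRNA catalog
#'
#' A lincRNA counts as conserved in a species iff it has at least one hit
#' surviving the E-value and identity filters against that species' genome.
#'
#' @param lincs named lincRNA sequences (`DNAStringSet`, named character, or
#'   FASTA path).
#' @param subjects named list of subject genomes (each a `DNAStringSet`,
#'   named character vector, or FASTA path), one entry per species.
#' @param params see [search_params()].
#' @param hits optional named list of pre-computed hits data.frames per
#'   species (used instead of running the aligner).
#' @return list with `per_species_conserved` (species -> lincRNA IDs),
#'   `intersection_all`, and `counts` (data.frame).
#' @export
conservation_summary <- function(lincs, subjects, params = search_params(),
                                 hits = NULL) {
  lincs <- as_named_seqs(as_genome_or_seqs(lincs))
  species <- names(hits %||% subjects)
  per <- lapply(species, function(sp) {
    h <- if (!is.null(hits)) {
      hh <- hits[[sp]]
      hh[hh$e_value <= params$e_value_max &
         hh$percent_identity >= params$min_identity, , drop = FALSE]
    } else {
      align_sets(lincs, subjects[[sp]], params)
    }
    sort(unique(h$query_id[h$query_id %in% names(lincs)]))
  })
  names(per) <- species
  inter <- if (length(per)) Reduce(intersect, per) else character()
  list(per_species_conserved = per,
       intersection_all = inter,
       counts = data.frame(species = species %||% character(),
                           n_conserved = vapply(per, length, integer(1)),
                           row.names = NULL, stringsAsFactors = FALSE))
}
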