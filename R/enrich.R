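#' Upper-tail hypergeometric probability
#'
#' p = P(X >= k) where X counts annotated genes in a random draw of n genes
#' from a background of N genes of which K are annotated. Computed through
#' the stable log-space tail of the hypergeometric distribution.
#'
#' @param k hits in the set.
#' @param K hits in the background.
#' @param n set size.
#' @param N background size.
#' @return probability in (0, 1].
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (K < 0 || K > N || n < 0 || n > N || k < 0 || k > min(n, K)) {
    stop("inconsistent hypergeometric arguments")
  }
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' GO-term enrichment of a gene set (hypergeometric + Bonferroni)
#'
#' One upper-tail hypergeometric test per term with at least one hit in the
#' set; Bonferroni correction over the tested terms. Both the raw p < 0.05
#' and the corrected p < 0.05 flags are reported. Term-to-gene annotation is
#' taken as given (no GO-graph ancestor propagation).
#'
#' @param gene_set character vector, subset of `background`.
#' @param background character vector of all eligible genes.
#' @param term_map data.frame with columns `gene` and `term` (optionally
#'   `name`), or path to such a two/three-column TSV.
#' @return data.frame sorted by p (ties by term ID): term, name, k, n, K, N,
#'   p, p_bonf, raw_significant, corrected_significant.
#' @export
go_enrich <- function(gene_set, background, term_map) {
  if (is.character(term_map)) {
    term_map <- utils::read.delim(term_map, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "term") %in% names(term_map)))
  background <- unique(background)
  gene_set <- unique(gene_set)
  stray <- setdiff(gene_set, background)
  if (length(stray)) {
    stop("genes in set missing from background: ",
         paste(utils::head(stray, 10), collapse = ", "))
  }
  term_map <- term_map[term_map$gene %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(gene_set)
  by_term <- split(term_map$gene, term_map$term)
  ks <- vapply(by_term, function(g) length(intersect(g, gene_set)),
               integer(1))
  tested <- names(by_term)[ks >= 1L]
  if (!length(tested)) {
    return(data.frame(term = character(), name = character(), k = integer(),
                      n = integer(), K = integer(), N = integer(),
                      p = numeric(), p_bonf = numeric(),
                      raw_significant = logical(),
                      corrected_significant = logical(),
                      stringsAsFactors = FALSE))
  }
  names_map <- if ("name" %in% names(term_map)) {
    tapply(term_map$name, term_map$term, `[`, 1L)
  } else NULL
  rows <- lapply(tested, function(tm) {
    K <- length(unique(by_term[[tm]]))
    k <- ks[[tm]]
    p <- hypergeom_upper(k, K, n, N)
    data.frame(term = tm,
               name = if (is.null(names_map)) NA_character_
                      else unname(names_map[tm]),
               k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  t_tested <- nrow(out)
  out$p_bonf <- pmin(1, out$p * t_tested)
  out$raw_significant <- out$p < 0.05
  out$corrected_significant <- out$p_bonf < 0.05
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
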