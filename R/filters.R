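#' Thresholds for the lincRNA identification cascade
#'
#' @param min_length minimum transcript length in bp (kept when `>=`).
#' @param orf_max_aa transcripts whose longest ORF is `>=` this many amino
#'   acids are removed.
#' @param flank_bp flank added to both sides of every protein-coding gene;
#'   transcripts overlapping the expanded interval are not intergenic.
#' @param hk_evalue remove candidates with a housekeeping-RNA hit at
#'   E-value `<=` this threshold (inclusive).
#' @param cluster_identity redundancy clustering identity threshold.
#' @return a named list of parameters.
#' @export
pipeline_config <- function(min_length = 200L, orf_max_aa = 100L,
                            flank_bp = 500L, hk_evalue = 1e-5,
                            cluster_identity = 0.95) {
  list(min_length = min_length, orf_max_aa = orf_max_aa, flank_bp = flank_bp,
       hk_evalue = hk_evalue, cluster_identity = cluster_identity)
}

filter_result <- function(surviving, removed_ids, reasons) {
  list(surviving = surviving,
       removed = data.frame(id = as.character(removed_ids),
                            reason = as.character(reasons),
                            stringsAsFactors = FALSE))
}

#' Length filter: keep transcripts of at least `min_length` bp
#' @param transcripts named `GRangesList` of exons per transcript.
#' @param min_length bp threshold; transcripts with summed exon length
#'   `>= min_length` survive.
#' @return list with `surviving` (subset, order preserved) and `removed`
#'   (data.frame id/reason).
#' @export
filter_length <- function(transcripts, min_length = 200L) {
  len <- transcript_lengths(transcripts)
  keep <- len >= min_length
  filter_result(transcripts[keep], names(transcripts)[!keep],
                sprintf("length %d < %d bp", len[!keep], min_length))
}

#' Intergenic filter: drop transcripts near annotated protein-coding genes
#'
#' A transcript survives iff its genomic span has zero overlap with every
#' protein-coding gene interval expanded by `flank_bp` on both sides. The
#' test is strand-blind (an antisense-overlapping transcript is not
#' intergenic).
#'
#' @param transcripts named `GRangesList`.
#' @param genes `GRanges` of genes with optional `biotype` metadata column;
#'   only protein-coding genes define the excluded space.
#' @param flank_bp flank in bp.
#' @param known_chroms optional character vector of valid chromosome names;
#'   transcripts elsewhere are removed with reason "unplaced".
#' @return list with `surviving` and `removed`.
#' @export
classify_intergenic <- function(transcripts, genes, flank_bp = 500L,
                                known_chroms = NULL) {
  if (!is.null(genes$biotype)) {
    genes <- genes[genes$biotype == "protein_coding"]
  }
  spans <- transcript_spans(transcripts)
  removed_ids <- character()
  reasons <- character()
  if (!is.null(known_chroms)) {
    chrom <- as.character(GenomeInfoDb::seqnames(spans))
    unplaced <- !(chrom %in% known_chroms)
    if (any(unplaced)) {
      warning(sum(unplaced), " transcript(s) on unknown chromosomes removed")
      removed_ids <- names(spans)[unplaced]
      reasons <- rep("unplaced", sum(unplaced))
      transcripts <- transcripts[!unplaced]
      spans <- spans[!unplaced]
    }
  }
  expanded <- suppressWarnings(GenomicRanges::trim(genes + flank_bp))
  ov <- IRanges::overlapsAny(spans, expanded, ignore.strand = TRUE)
  res <- filter_result(
    transcripts[!ov],
    c(removed_ids, names(spans)[ov]),
    c(reasons, rep(sprintf("within %d bp of a protein-coding gene", flank_bp),
                   sum(ov))))
  res
}

#' ORF-length filter: drop transcripts with a long open reading frame
#' @param seqs named character vector or `DNAStringSet` of spliced transcript
#'   sequences.
#' @param max_orf_aa transcripts with longest ORF `>=` this (amino acids,
#'   stop excluded) are removed.
#' @return list with `surviving` (names kept, input order), `removed`, and
#'   `orf` (per-transcript longest-ORF table).
#' @export
filter_orf <- function(seqs, max_orf_aa = 100L) {
  seqs <- as_named_seqs(seqs)
  orfs <- lapply(seqs, longest_orf)
  aa <- vapply(orfs, `[[`, integer(1), "longest_orf_aa")
  keep <- aa < max_orf_aa
  out <- filter_result(names(seqs)[keep], names(seqs)[!keep],
                       sprintf("ORF %d aa >= %d", aa[!keep], max_orf_aa))
  out$orf <- data.frame(
    transcript_id = names(seqs),
    longest_orf_aa = aa,
    frame = vapply(orfs, `[[`, character(1), "frame"),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Coding-potential filter (hexamer score, optional external coding calls)
#'
#' Eliminates transcripts whose coding-potential score is strictly greater
#' than zero. Externally produced coding ID lists (e.g. from third-party
#' classifiers) can be supplied and are unioned with the internal calls.
#'
#' @param seqs named sequences.
#' @param model hexamer model, see [hexamer_model()].
#' @param external_coding_ids optional character vector of transcript IDs
#'   called coding by an external classifier.
#' @return list with `surviving`, `removed`, and `scores` (per-transcript).
#' @export
filter_coding <- function(seqs, model = hexamer_model(),
                          external_coding_ids = NULL) {
  seqs <- as_named_seqs(seqs)
  scored <- lapply(seqs, coding_score, model = model)
  score <- vapply(scored, `[[`, numeric(1), "score")
  coding <- score > 0
  external <- names(seqs) %in% (external_coding_ids %||% character())
  drop <- coding | external
  reason <- ifelse(coding, sprintf("coding score %.3f > 0", score),
                   "external classifier call")
  out <- filter_result(names(seqs)[!drop], names(seqs)[drop], reason[drop])
  out$scores <- data.frame(transcript_id = names(seqs), score = unname(score),
                           label = ifelse(coding, "coding", "noncoding"),
                           stringsAsFactors = FALSE)
  out
}

#' Housekeeping-RNA filter
#'
#' Removes candidates with at least one alignment hit against the
#' housekeeping RNA database at E-value `<=` `e_value_max` (inclusive).
#' Either a FASTA/sequence set (searched with the built-in seed-and-extend
#' aligner) or pre-computed tabular hits may be supplied.
#'
#' @param seqs named candidate sequences.
#' @param hk_db housekeeping sequences (`DNAStringSet` or FASTA path);
#'   ignored when `hits` is given.
#' @param e_value_max inclusive E-value threshold.
#' @param params alignment parameters, see [search_params()].
#' @param hits optional pre-computed hits data.frame
#'   (see [read_blast_tabular()]).
#' @return list with `surviving` and `removed` (reason records the best hit).
#' @export
filter_housekeeping <- function(seqs, hk_db = NULL, e_value_max = 1e-5,
                                params = search_params(), hits = NULL) {
  seqs <- as_named_seqs(seqs)
  if (is.null(hits)) {
    if (is.null(hk_db)) stop("either hk_db or hits must be supplied")
    hk <- as_genome(hk_db)
    hits <- align_sets(Biostrings::DNAStringSet(seqs), hk, params)
  }
  hits <- hits[hits$e_value <= e_value_max & hits$query_id %in% names(seqs), ,
               drop = FALSE]
  drop <- names(seqs) %in% hits$query_id
  reason <- vapply(names(seqs)[drop], function(id) {
    h <- hits[hits$query_id == id, , drop = FALSE]
    h <- h[which.min(h$e_value), ]
    sprintf("housekeeping hit %s (E=%.3g)", h$subject_id, h$e_value)
  }, character(1))
  filter_result(names(seqs)[!drop], names(seqs)[drop], reason)
}

#' Greedy incremental redundancy clustering at an identity threshold
#'
#' Sequences are processed by length descending (ties by ID ascending); each
#' joins the first existing cluster whose representative it matches at
#' `>= identity`, else founds a new cluster. Identity is matching positions
#' of the best local alignment divided by the length of the shorter
#' sequence, so containment duplicates collapse. The representative is the
#' longest member (the founder).
#'
#' @param seqs named sequences.
#' @param identity fractional identity threshold.
#' @return list with `clusters` (list of `representative_id`, `member_ids`,
#'   `identity` map) and `representatives` (IDs in input order).
#' @export
cluster_redundant <- function(seqs, identity = 0.95) {
  seqs <- as_named_seqs(seqs)
  if (any(!nzchar(seqs))) stop("empty sequence in clustering input")
  ord <- order(-nchar(seqs), names(seqs))
  clusters <- list()
  for (i in ord) {
    id <- names(seqs)[i]
    placed <- FALSE
    for (k in seq_along(clusters)) {
      rep_id <- clusters[[k]]$representative_id
      idn <- seq_identity(seqs[[id]], seqs[[rep_id]])
      if (idn >= identity) {
        clusters[[k]]$member_ids <- c(clusters[[k]]$member_ids, id)
        clusters[[k]]$identity[id] <- idn
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <-
        list(representative_id = id, member_ids = id,
             identity = stats::setNames(1, id))
    }
  }
  reps <- vapply(clusters, `[[`, character(1), "representative_id")
  list(clusters = clusters,
       representatives = names(seqs)[names(seqs) %in% reps])
}

#' Fractional identity of the best local alignment
#'
#' Matching positions divided by the length of the shorter sequence
#' (containment convention). Scoring: match +1, mismatch -2, gap open 5,
#' gap extend 2.
#'
#' @param a,b nucleotide strings.
#' @return identity in \[0, 1\].
#' @export
seq_identity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 2)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

as_named_seqs <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || !all(nzchar(names(seqs)))) {
    stop("sequences must be named by transcript ID")
  }
  toupper(seqs)
}

#' Run the full lincRNA identification cascade
#'
#' Stages, in order: length, intergenic (with gene flanks), coding potential,
#' ORF length, housekeeping similarity, redundancy clustering. Each stage's
#' survivors are a subset of the previous stage's, and the per-stage removal
#' records partition the difference (audited by [check_filter_report()]).
#'
#' @param assembly assembled transcripts: GTF path or named `GRangesList`.
#' @param genome genome: FASTA path or named `DNAStringSet`.
#' @param annotation gene annotation: GTF path or `GRanges` of genes.
#' @param hk_db housekeeping RNA FASTA path or `DNAStringSet` (NULL skips
#'   the search when `hk_hits` is given).
#' @param config thresholds, see [pipeline_config()].
#' @param external_coding_ids optional coding calls from external tools.
#' @param hk_hits optional pre-computed housekeeping hits data.frame.
#' @return list with `catalog` (surviving `GRangesList`), `sequences`
#'   (`DNAStringSet` of catalog sequences), `clusters`, and `report` (a
#'   `filter_report`).
#' @export
run_pipeline <- function(assembly, genome, annotation, hk_db,
                         config = pipeline_config(),
                         external_coding_ids = NULL, hk_hits = NULL) {
  if (is.character(assembly)) assembly <- read_gtf(assembly)$transcripts
  if (is.character(annotation)) annotation <- read_gtf(annotation)$genes
  genome <- as_genome(genome)

  report <- new_filter_report(names(assembly), config)

  s1 <- filter_length(assembly, config$min_length)
  report <- add_stage(report, "length", names(s1$surviving), s1$removed)

  s2 <- classify_intergenic(s1$surviving, annotation, config$flank_bp,
                            known_chroms = names(genome))
  report <- add_stage(report, "intergenic", names(s2$surviving), s2$removed)

  seqs <- if (length(s2$surviving)) extract_sequences(genome, s2$surviving)
          else Biostrings::DNAStringSet()

  s3 <- if (length(seqs)) filter_coding(seqs,
                                        external_coding_ids = external_coding_ids)
        else list(surviving = character(), removed = empty_removed())
  report <- add_stage(report, "coding_potential", s3$surviving, s3$removed)

  s4 <- if (length(s3$surviving)) filter_orf(seqs[s3$surviving],
                                             config$orf_max_aa)
        else list(surviving = character(), removed = empty_removed())
  report <- add_stage(report, "orf", s4$surviving, s4$removed)

  s5 <- if (length(s4$surviving)) {
    filter_housekeeping(seqs[s4$surviving], hk_db = hk_db,
                        e_value_max = config$hk_evalue, hits = hk_hits)
  } else list(surviving = character(), removed = empty_removed())
  report <- add_stage(report, "housekeeping", s5$surviving, s5$removed)

  cl <- if (length(s5$surviving)) {
    cluster_redundant(seqs[s5$surviving], config$cluster_identity)
  } else list(clusters = list(), representatives = character())
  merged <- setdiff(s5$surviving, cl$representatives)
  merged_reason <- vapply(merged, function(id) {
    k <- which(vapply(cl$clusters, function(c) id %in% c$member_ids,
                      logical(1)))[1]
    sprintf("redundant with %s (identity %.3f)",
            cl$clusters[[k]]$representative_id, cl$clusters[[k]]$identity[id])
  }, character(1))
  report <- add_stage(report, "cluster", cl$representatives,
                      data.frame(id = merged, reason = unname(merged_reason),
                                 stringsAsFactors = FALSE))

  catalog_ids <- cl$representatives
  list(catalog = if (length(catalog_ids)) assembly[catalog_ids]
                 else assembly[integer()],
       sequences = if (length(catalog_ids)) seqs[catalog_ids]
                   else Biostrings::DNAStringSet(),
       clusters = cl$clusters,
       report = report)
}

empty_removed <- function() {
  data.frame(id = character(), reason = character(), stringsAsFactors = FALSE)
}

new_filter_report <- function(input_ids, config) {
  structure(list(stage_names = character(),
                 input_ids = as.character(input_ids),
                 surviving_ids = list(),
                 removed = list(),
                 params = config),
            class = "filter_report")
}

add_stage <- function(report, name, surviving, removed) {
  report$stage_names <- c(report$stage_names, name)
  report$surviving_ids[[name]] <- as.character(surviving)
  report$removed[[name]] <- removed
  report
}

#' Audit a filter report's subset/partition invariants
#'
#' Checks that every stage's survivors are a subset of the previous stage's,
#' and that survivors plus removals exactly partition the previous stage's
#' set.
#'
#' @param report a `filter_report` from [run_pipeline()].
#' @return `TRUE` invisibly; stops on violation.
#' @export
check_filter_report <- function(report) {
  prev <- report$input_ids
  for (st in report$stage_names) {
    surv <- report$surviving_ids[[st]]
    rem <- report$removed[[st]]$id
    if (!all(surv %in% prev)) stop("stage ", st, ": survivors not a subset")
    if (!setequal(c(surv, rem), prev) || length(intersect(surv, rem))) {
      stop("stage ", st, ": survivors and removals do not partition input")
    }
    prev <- surv
  }
  invisible(TRUE)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("lincRNA identification cascade\n")
  cat(sprintf("  input: %d transcripts\n", length(x$input_ids)))
  for (st in x$stage_names) {
    cat(sprintf("  %-16s kept %5d  removed %5d\n", st,
                length(x$surviving_ids[[st]]), nrow(x$removed[[st]])))
  }
  invisible(x)
}

#' Flatten a filter report to a per-stage counts data.frame
#' @param report a `filter_report`.
#' @return data.frame with stage, surviving, removed counts.
#' @export
report_counts <- function(report) {
  data.frame(stage = report$stage_names,
             surviving = vapply(report$surviving_ids, length, integer(1)),
             removed = vapply(report$removed, nrow, integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
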