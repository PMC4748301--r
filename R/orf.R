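#' Longest open reading frame over all six frames
#'
#' An ORF is ATG through the first in-frame stop (TAA/TAG/TGA), fully
#' contained in the sequence. The reported length is in amino acids and
#' excludes the stop. Codons containing N never match the start or a stop.
#' Ties across frames resolve to the first frame in the order
#' +1, +2, +3, -1, -2, -3.
#'
#' @param sequence nucleotide string over A/C/G/T/N.
#' @return list with `longest_orf_aa`, `frame` (one of "+1".."-3", NA when no
#'   ORF), and `orf_start`/`orf_end` (1-based positions of the ATG and the
#'   stop-codon end within the frame's reading orientation).
#' @export
longest_orf <- function(sequence) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
  frames <- list(`+1` = c(sequence, 0L), `+2` = c(sequence, 1L),
                 `+3` = c(sequence, 2L), `-1` = c(rc, 0L),
                 `-2` = c(rc, 1L), `-3` = c(rc, 2L))
  best <- list(longest_orf_aa = 0L, frame = NA_character_,
               orf_start = NA_integer_, orf_end = NA_integer_)
  for (fr in names(frames)) {
    s <- frames[[fr]][1L]
    off <- as.integer(frames[[fr]][2L])
    hit <- scan_frame(s, off)
    if (!is.null(hit) && hit$aa > best$longest_orf_aa) {
      best <- list(longest_orf_aa = hit$aa, frame = fr,
                   orf_start = hit$start, orf_end = hit$end)
    }
  }
  best
}

# longest ATG..stop in one reading frame; returns aa length (stop excluded)
# and 1-based coordinates in the given string, or NULL
scan_frame <- function(s, offset) {
  n <- nchar(s)
  ncod <- (n - offset) %/% 3L
  if (ncod < 2L) return(NULL)
  pos <- offset + 3L * (seq_len(ncod) - 1L) + 1L
  codons <- substring(s, pos, pos + 2L)
  starts <- which(codons == "ATG")
  stops <- which(codons %in% STOP_CODONS)
  if (!length(starts) || !length(stops)) return(NULL)
  best_aa <- 0L
  best <- NULL
  for (i in starts) {
    j <- stops[stops > i]
    if (!length(j)) next
    aa <- j[1L] - i
    if (aa > best_aa) {
      best_aa <- aa
      best <- list(aa = aa, start = pos[i], end = pos[j[1L]] + 2L)
    }
  }
  best
}

#' Build the fixed hexamer coding/noncoding log-ratio model
#'
#' The model is generated deterministically in code: a coding corpus is drawn
#' from a fixed codon-usage-biased codon distribution (codons ending in G or C
#' are three-fold preferred, mirroring the GC3 bias of real coding sequence),
#' a noncoding corpus from uniform random nucleotides. In-frame (stride 3)
#' hexamer frequencies are tabulated with a pseudocount of 1 and the model is
#' the per-hexamer log2(f_coding / f_noncoding). The build is memoized for
#' the session.
#'
#' @param n_train number of training sequences per class.
#' @param train_len nucleotides per training sequence.
#' @return named numeric vector of length 4096 (all DNA hexamers).
#' @export
hexamer_model <- function(n_train = 400L, train_len = 900L) {
  key <- sprintf("hexamer_%d_%d", n_train, train_len)
  if (!is.null(.lincscan_cache[[key]])) return(.lincscan_cache[[key]])
  model <- with_seed(20160210L, {
    codons <- all_kmers(3L)
    sense <- setdiff(codons, STOP_CODONS)
    w <- ifelse(substr(sense, 3L, 3L) %in% c("G", "C"), 3, 1)
    w <- w / sum(w)
    coding <- vapply(seq_len(n_train), function(i) {
      paste(sample(sense, train_len %/% 3L, replace = TRUE, prob = w),
            collapse = "")
    }, character(1))
    noncoding <- vapply(seq_len(n_train), function(i) random_dna(train_len),
                        character(1))
    hx <- all_kmers(6L)
    count_stride3 <- function(seqs) {
      counts <- stats::setNames(rep(1, length(hx)), hx)  # pseudocount
      for (s in seqs) {
        p <- seq(1L, nchar(s) - 5L, by = 3L)
        tab <- table(substring(s, p, p + 5L))
        counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
      }
      counts / sum(counts)
    }
    log2(count_stride3(coding) / count_stride3(noncoding))
  })
  .lincscan_cache[[key]] <- model
  model
}

.lincscan_cache <- new.env(parent = emptyenv())

all_kmers <- function(k) {
  grid <- do.call(expand.grid, rep(list(DNA_BASES), k))
  # leftmost position varies slowest so ordering is lexicographic
  sort(apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste, collapse = ""))
}

#' Hexamer log-likelihood coding-potential score
#'
#' The score is the mean hexamer log2 coding/noncoding ratio over the longest
#' ORF (ATG through stop, inclusive) read in frame with a stride of 3. When
#' the sequence contains no ORF, the mean is taken over the whole sequence in
#' frame +1. Transcripts with score > 0 are labelled coding; the
#' identification cascade eliminates exactly those.
#'
#' @param sequence nucleotide string, length >= 6.
#' @param model hexamer model from [hexamer_model()].
#' @return list with `score` and `label` ("coding" iff score > 0).
#' @export
coding_score <- function(sequence, model = hexamer_model()) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 6L) stop("sequence too short for hexamer scoring")
  if (length(model) != 4096L) stop("hexamer model must cover all 4096 hexamers")
  orf <- longest_orf(sequence)
  if (orf$longest_orf_aa > 0L) {
    s <- if (startsWith(orf$frame, "-")) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
    } else {
      sequence
    }
    sub <- substr(s, orf$orf_start, orf$orf_end)
  } else {
    sub <- sequence
  }
  p <- seq(1L, nchar(sub) - 5L, by = 3L)
  hx <- substring(sub, p, p + 5L)
  vals <- model[hx]
  vals <- vals[!is.na(vals)]  # hexamers containing N are skipped
  score <- if (length(vals)) mean(vals) else 0
  list(score = unname(score),
       label = if (score > 0) "coding" else "noncoding")
}
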