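#' Features expressed anywhere (max FPKM over samples >= threshold)
#' @param se expression container (`SummarizedExperiment`, assay `fpkm`).
#' @param min_fpkm inclusive threshold.
#' @return character vector of feature IDs.
#' @export
expressed_set <- function(se, min_fpkm = 1) {
  mat <- SummarizedExperiment::assay(se, "fpkm")
  rownames(mat)[apply(mat, 1L, max) >= min_fpkm]
}

#' Tissue-specificity index tau
#'
#' tau = sum_i (1 - x_i / x_max) / (N - 1) over the per-tissue expression
#' vector. tau is 1 iff the feature is expressed in exactly one tissue and 0
#' iff expression is perfectly uniform; it is invariant to rescaling.
#'
#' @param x non-negative per-tissue expression vector, length >= 2.
#' @return tau in \[0, 1\].
#' @export
tau <- function(x) {
  if (length(x) < 2L) stop("tau requires at least two tissues")
  if (any(is.na(x)) || any(x < 0)) stop("tau requires non-negative values")
  m <- max(x)
  if (m <= 0) stop("tau is undefined for an all-zero vector")
  sum(1 - x / m) / (length(x) - 1L)
}

#' Tissue-specific features by the tau > threshold rule
#'
#' Multi-sample tissues are averaged first; tau is computed on per-tissue
#' mean FPKM (`scale = "raw"`) or on log2(FPKM + 1) per-tissue means
#' (`scale = "log2p1"`). Only features expressed anywhere
#' (max FPKM >= `min_fpkm`) are scored. A feature is flagged tissue-specific
#' when tau is strictly greater than `tau_threshold`, and is assigned to its
#' argmax tissue.
#'
#' @param se expression container with `tissue` in the sample metadata.
#' @param tau_threshold strict threshold on tau.
#' @param min_fpkm expressed-set threshold.
#' @param scale "raw" (default) or "log2p1".
#' @return list with `results` (per-feature data.frame: feature_id, tau,
#'   argmax_tissue, specific) and `per_tissue_counts`.
#' @export
tissue_specific <- function(se, tau_threshold = 0.95, min_fpkm = 1,
                            scale = c("raw", "log2p1")) {
  scale <- match.arg(scale)
  meta <- SummarizedExperiment::colData(se)
  if (is.null(meta$tissue)) stop("sample metadata lacks a tissue column")
  mat <- SummarizedExperiment::assay(se, "fpkm")
  keep <- expressed_set(se, min_fpkm)
  mat <- mat[keep, , drop = FALSE]
  tissues <- unique(as.character(meta$tissue))
  per_tissue <- vapply(tissues, function(tt) {
    rowMeans(mat[, meta$tissue == tt, drop = FALSE])
  }, numeric(nrow(mat)))
  if (!is.matrix(per_tissue)) {
    per_tissue <- matrix(per_tissue, nrow = nrow(mat),
                         dimnames = list(rownames(mat), tissues))
  }
  if (scale == "log2p1") per_tissue <- log2(per_tissue + 1)
  taus <- apply(per_tissue, 1L, tau)
  argmax <- tissues[apply(per_tissue, 1L, which.max)]
  res <- data.frame(feature_id = rownames(mat), tau = unname(taus),
                    argmax_tissue = argmax,
                    specific = unname(taus > tau_threshold),
                    stringsAsFactors = FALSE, row.names = NULL)
  counts <- table(factor(res$argmax_tissue[res$specific], levels = tissues))
  list(results = res,
       per_tissue_counts = data.frame(tissue = tissues,
                                      n_specific = as.integer(counts),
                                      stringsAsFactors = FALSE))
}

#' Stage-expression calls and stage-specific features
#'
#' A feature is expressed in a stage iff its max FPKM over that stage's
#' samples is >= `min_fpkm`; it is stage-specific when exactly one stage
#' qualifies.
#'
#' @param se expression container with `stage` in the sample metadata.
#' @param min_fpkm inclusive threshold.
#' @return data.frame with feature_id, n_stages_expressed, stages_expressed
#'   (comma-joined), specific_stage (NA unless exactly one).
#' @export
stage_specific <- function(se, min_fpkm = 1) {
  meta <- SummarizedExperiment::colData(se)
  if (is.null(meta$stage)) stop("sample metadata lacks a stage column")
  mat <- SummarizedExperiment::assay(se, "fpkm")
  stages <- unique(as.character(meta$stage))
  on <- vapply(stages, function(st) {
    apply(mat[, meta$stage == st, drop = FALSE], 1L, max) >= min_fpkm
  }, logical(nrow(mat)))
  if (!is.matrix(on)) {
    on <- matrix(on, nrow = nrow(mat),
                 dimnames = list(rownames(mat), stages))
  }
  n_on <- rowSums(on)
  specific <- ifelse(n_on == 1L, stages[apply(on, 1L, which.max)],
                     NA_character_)
  data.frame(feature_id = rownames(mat),
             n_stages_expressed = unname(n_on),
             stages_expressed = apply(on, 1L, function(z)
               paste(stages[z], collapse = ",")),
             specific_stage = unname(specific),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' On/off settlement contrast between two stages
#'
#' First set: features with max FPKM >= `hi_fpkm` in `stage_a` samples and
#' max FPKM < `off_fpkm` in `stage_b` samples; second set symmetric.
#'
#' @param se expression container with `stage` metadata.
#' @param stage_a,stage_b stage names (e.g. eyed pediveliger larvae vs spat).
#' @param hi_fpkm "moderate and high expression" floor.
#' @param off_fpkm "not expressed" ceiling (strict).
#' @return list with `on_in_a_off_in_b` and `on_in_b_off_in_a`.
#' @export
settlement_contrast <- function(se, stage_a, stage_b, hi_fpkm = 5,
                                off_fpkm = 1) {
  meta <- SummarizedExperiment::colData(se)
  if (is.null(meta$stage)) stop("sample metadata lacks a stage column")
  for (st in c(stage_a, stage_b)) {
    if (!st %in% meta$stage) stop("stage absent from metadata: ", st)
  }
  mat <- SummarizedExperiment::assay(se, "fpkm")
  max_a <- apply(mat[, meta$stage == stage_a, drop = FALSE], 1L, max)
  max_b <- apply(mat[, meta$stage == stage_b, drop = FALSE], 1L, max)
  list(on_in_a_off_in_b = rownames(mat)[max_a >= hi_fpkm & max_b < off_fpkm],
       on_in_b_off_in_a = rownames(mat)[max_b >= hi_fpkm & max_a < off_fpkm])
}

#' Compare lincRNA and mRNA expression distributions (KDE + KS test)
#'
#' Both samples are transformed to log2(FPKM + 1); Gaussian kernel density
#' estimates use Silverman's bandwidth, and the two-sample
#' Kolmogorov-Smirnov statistic D = sup |F1 - F2| is tested with the
#' asymptotic p-value.
#'
#' @param linc_values,mrna_values non-empty FPKM vectors (length >= 2).
#' @param n_grid evaluation grid size for the KDE curves.
#' @return list with `curves` (data.frame x, density_linc, density_mrna),
#'   `D`, and `p_value`.
#' @export
density_compare <- function(linc_values, mrna_values, n_grid = 512L) {
  if (length(linc_values) < 2L || length(mrna_values) < 2L) {
    stop("both samples must have at least 2 values")
  }
  lx <- log2(linc_values + 1)
  mx <- log2(mrna_values + 1)
  rng <- range(c(lx, mx))
  kl <- stats::density(lx, bw = "nrd0", from = rng[1], to = rng[2],
                       n = n_grid)
  km <- stats::density(mx, bw = "nrd0", from = rng[1], to = rng[2],
                       n = n_grid)
  ks <- suppressWarnings(stats::ks.test(lx, mx, exact = FALSE))
  list(curves = data.frame(x = kl$x, density_linc = kl$y,
                           density_mrna = km$y),
       D = unname(ks$statistic), p_value = unname(ks$p.value))
}

#' Nearest protein-coding gene per lincRNA
#'
#' Distance is the gap between closest interval ends (0 when the intervals
#' overlap or abut), strand-blind. Features on chromosomes without any
#' annotated gene are excluded with a warning.
#'
#' @param lincs `GRangesList` of lincRNA transcripts (or `GRanges` spans).
#' @param genes `GRanges` of genes (`biotype` restricted to protein-coding
#'   when present).
#' @param window distances strictly below this count as "near" (bp).
#' @return list with `results` (linc_id, nearest_gene_id, distance_bp,
#'   within_window), `fraction_within` and `neighbor_gene_set` (unique
#'   nearest genes of near lincRNAs).
#' @export
neighbor_distances <- function(lincs, genes, window = 10000L) {
  if (!is.null(genes$biotype)) genes <- genes[genes$biotype == "protein_coding"]
  spans <- if (methods::is(lincs, "GRangesList")) transcript_spans(lincs)
           else lincs
  dtn <- suppressWarnings(
    GenomicRanges::distanceToNearest(spans, genes, ignore.strand = TRUE))
  hit <- S4Vectors::queryHits(dtn)
  if (length(hit) < length(spans)) {
    warning(length(spans) - length(hit),
            " lincRNA(s) on gene-free chromosomes excluded")
  }
  res <- data.frame(
    linc_id = names(spans)[hit],
    nearest_gene_id = genes$gene_id[S4Vectors::subjectHits(dtn)],
    distance_bp = S4Vectors::mcols(dtn)$distance,
    stringsAsFactors = FALSE, row.names = NULL)
  res$within_window <- res$distance_bp < window
  list(results = res,
       fraction_within = if (nrow(res)) mean(res$within_window) else NA_real_,
       neighbor_gene_set = sort(unique(res$nearest_gene_id[res$within_window])))
}
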