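#' Configuration of the synthetic study scene
#'
#' The defaults emulate the study design the pipeline targets: nine adult
#' tissues, 34 larval development time points grouped into six stages
#' (embryo through spat), planted lincRNA loci (>= 200 bp, no long ORF, far
#' from genes), protein-coding genes with genuine biased ORFs, five decoy
#' classes that each fail exactly one cascade filter, near-duplicate
#' transcripts, and development co-expression modules monotonically related
#' to the time rank.
#'
#' @param seed integer; all randomness flows from it.
#' @param n_coding_genes,n_linc_loci,n_decoys_per_class scene sizes.
#' @param chrom_length optional chromosome length (bp); auto-sized when
#'   NULL, error when too small for the requested loci.
#' @param flank_bp gene flank used both for placement and by the cascade.
#' @param tissue_panel nine tissue names.
#' @param n_timepoints,n_stages development design (>= 4 time points).
#' @param module_spec list of `list(size=, sign=)` planted modules.
#' @param noise_sd within-module residual SD on the log2 expression scale;
#'   the designated hub gets 0.2x and the designated hub-linked lincRNA
#'   0.3x of it.
#' @param linc_len_range planted lincRNA length range (bp).
#' @param gene_orf_codons coding-gene ORF length range (codons).
#' @param dup_mutation substitution rate of near-duplicate decoys.
#' @param n_tissue_specific,n_stage_specific,n_settlement planted counts
#'   (settlement: c(on-in-eyed, on-in-spat)).
#' @param lincs_per_module lincRNA members planted in each module.
#' @param n_subject_genomes,subject_genome_length,n_conserved,conservation_k,
#'   conservation_mutation cross-species conservation design: `n_conserved`
#'   lincRNAs are copied (with substitutions) into exactly
#'   `conservation_k` subject genomes.
#' @param n_housekeeping housekeeping-RNA database entries.
#' @return validated configuration list.
#' @export
sim_config <- function(seed = 1L,
                       n_coding_genes = 200L,
                       n_linc_loci = 50L,
                       n_decoys_per_class = 10L,
                       chrom_length = NULL,
                       flank_bp = 500L,
                       tissue_panel = c("gill", "hemolymph",
                                        "digestive_gland", "labial_palp",
                                        "female_gonad", "male_gonad",
                                        "mantle_inner", "mantle_edge",
                                        "adductor_muscle"),
                       n_timepoints = 34L,
                       n_stages = 6L,
                       module_spec = list(list(size = 50L, sign = 1),
                                          list(size = 50L, sign = -1),
                                          list(size = 50L, sign = 1)),
                       noise_sd = 0.5,
                       linc_len_range = c(300L, 600L),
                       gene_orf_codons = c(160L, 240L),
                       dup_mutation = 0.02,
                       n_tissue_specific = 18L,
                       n_stage_specific = 12L,
                       n_settlement = c(4L, 4L),
                       lincs_per_module = 5L,
                       n_subject_genomes = 4L,
                       subject_genome_length = 60000L,
                       n_conserved = 20L,
                       conservation_k = 4L,
                       conservation_mutation = 0.02,
                       n_housekeeping = 12L) {
  cfg <- as.list(environment())
  if (n_timepoints < 4L) stop("need at least 4 development time points")
  if (conservation_k > n_subject_genomes) stop("conservation_k too large")
  n_module_lincs <- length(module_spec) * lincs_per_module
  if (n_linc_loci > 0 &&
      n_module_lincs + n_stage_specific + sum(n_settlement) > n_linc_loci) {
    stop("module/stage/settlement lincRNA assignments exceed n_linc_loci")
  }
  n_module_mrna <- sum(vapply(module_spec, function(m)
    m$size - lincs_per_module, numeric(1)))
  if (n_module_mrna > n_coding_genes) {
    stop("module mRNA assignments exceed n_coding_genes")
  }
  if (n_conserved > n_linc_loci) stop("n_conserved exceeds n_linc_loci")
  cfg
}

STAGE_NAMES <- c("embryo", "trochophore", "d_shaped", "umbo",
                 "pediveliger", "spat")

stage_names_for <- function(n_stages) {
  if (n_stages <= length(STAGE_NAMES)) STAGE_NAMES[seq_len(n_stages)]
  else c(STAGE_NAMES, paste0("stage_", seq_len(n_stages -
                                               length(STAGE_NAMES)) +
                              length(STAGE_NAMES)))
}

# draw a random sequence until it passes all the filters a planted lincRNA
# must survive: no long ORF, non-positive coding score, no housekeeping hit
draw_linc_seq <- function(len, hk, model, params, max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    s <- random_dna(len)
    if (longest_orf(s)$longest_orf_aa >= 100L) next
    if (coding_score(s, model)$score > 0) next
    if (nrow(align_sets(c(q = s), hk, params))) next
    return(s)
  }
  stop("could not draw a lincRNA sequence passing all filters")
}

biased_codons <- function() {
  codons <- all_kmers(3L)
  sense <- setdiff(codons, STOP_CODONS)
  w <- ifelse(substr(sense, 3L, 3L) %in% c("G", "C"), 3, 1)
  list(codons = sense, prob = w / sum(w))
}

draw_coding_seq <- function(n_codons, model, max_tries = 20L) {
  cb <- biased_codons()
  for (i in seq_len(max_tries)) {
    orf <- paste0("ATG",
                  paste(sample(cb$codons, n_codons - 2L, replace = TRUE,
                               prob = cb$prob), collapse = ""),
                  sample(STOP_CODONS, 1L))
    s <- paste0(random_dna(30L), orf, random_dna(30L))
    if (coding_score(s, model)$score > 0) return(s)
  }
  stop("could not draw a coding gene with positive coding score")
}

draw_long_orf_decoy <- function() {
  cb <- biased_codons()
  n_codons <- sample(110:150, 1L)
  paste0(random_dna(20L), "ATG",
         paste(sample(cb$codons, n_codons, replace = TRUE), collapse = ""),
         sample(STOP_CODONS, 1L), random_dna(20L))
}

draw_dup_seq <- function(src, rate, model, hk, params, max_tries = 50L) {
  len <- nchar(src) - 30L
  core <- substr(src, 1L, len)
  for (i in seq_len(max_tries)) {
    s <- mutate_dna(core, rate)
    if (seq_identity(s, src) < 0.95) next
    if (longest_orf(s)$longest_orf_aa >= 100L) next
    if (coding_score(s, model)$score > 0) next
    if (nrow(align_sets(c(q = s), hk, params))) next
    return(s)
  }
  stop("could not draw a near-duplicate decoy")
}

draw_hk_like <- function(hk, model, params, max_tries = 50L) {
  long_enough <- which(nchar(hk) >= 220L)
  for (i in seq_len(max_tries)) {
    src <- as.character(hk[[sample(long_enough, 1L)]])
    wlen <- sample(150:min(250L, nchar(src)), 1L)
    at <- sample(seq_len(nchar(src) - wlen + 1L), 1L)
    core <- mutate_dna(substr(src, at, at + wlen - 1L), 0.05)
    s <- paste0(random_dna(50L), core, random_dna(50L))
    if (longest_orf(s)$longest_orf_aa >= 100L) next
    if (coding_score(s, model)$score > 0) next
    h <- align_sets(c(q = s), hk, params)
    if (!nrow(h)) next
    return(s)
  }
  stop("could not draw a housekeeping look-alike decoy")
}

#' Simulate the genome scene: chromosome, annotation, assembly, databases
#'
#' Plants protein-coding genes (biased ORFs of >= 150 codons), lincRNA loci
#' (>= 200 bp, > flank from any gene, longest ORF < 100 aa, non-positive
#' coding score, no housekeeping similarity — re-drawn until verified), and
#' five decoy classes: shorter than 200 bp; inside a gene; within the gene
#' flank; intergenic with an ORF >= 100 aa; and a housekeeping look-alike
#' (>= 90% identity to a database entry over >= 100 bp). Near-duplicates of
#' planted lincRNAs (>= 95% identity, shorter than their source) exercise
#' the redundancy clustering. Selected lincRNAs are copied, with
#' substitutions, into subject genomes for the conservation search.
#'
#' @param config see [sim_config()].
#' @return list with `genome` (`DNAStringSet`), `annotation` (genes
#'   `GRanges`), `assembly` (`GRangesList` of transcripts), `housekeeping`
#'   (`DNAStringSet`), `subjects` (named list of `DNAStringSet`), `truth`
#'   (ground-truth table) and `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  with_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(config) {
  params <- search_params()
  model <- hexamer_model()
  nd <- config$n_decoys_per_class
  nl <- config$n_linc_loci

  hk <- Biostrings::DNAStringSet(stats::setNames(
    vapply(sample(c(120:400, 1000:1500), config$n_housekeeping),
           random_dna, character(1)),
    sprintf("hk_rna_%02d", seq_len(config$n_housekeeping))))

  linc_seqs <- if (nl > 0) {
    stats::setNames(
      vapply(sample(seq(config$linc_len_range[1], config$linc_len_range[2]),
                    nl, replace = TRUE),
             draw_linc_seq, character(1), hk = hk, model = model,
             params = params),
      sprintf("TCONS_linc_%03d", seq_len(nl)))
  } else stats::setNames(character(), character())

  n_dup <- if (nl > 0) nd else 0L
  dup_src <- if (n_dup) sample(names(linc_seqs), n_dup,
                               replace = n_dup > nl) else character()
  dup_seqs <- stats::setNames(
    vapply(dup_src, function(s)
      draw_dup_seq(linc_seqs[[s]], config$dup_mutation, model, hk, params),
      character(1)),
    if (n_dup) sprintf("TCONS_dup_%03d", seq_len(n_dup)) else character())

  short_seqs <- stats::setNames(
    vapply(sample(80:199, nd, replace = TRUE), random_dna, character(1)),
    sprintf("TCONS_short_%03d", seq_len(nd)))
  long_orf_seqs <- stats::setNames(
    vapply(seq_len(nd), function(i) draw_long_orf_decoy(), character(1)),
    sprintf("TCONS_orf_%03d", seq_len(nd)))
  hk_like_seqs <- stats::setNames(
    vapply(seq_len(nd), function(i) draw_hk_like(hk, model, params),
           character(1)),
    sprintf("TCONS_hk_%03d", seq_len(nd)))

  gene_ids <- sprintf("gene_%04d", seq_len(config$n_coding_genes))
  gene_seqs <- stats::setNames(
    vapply(sample(seq(config$gene_orf_codons[1], config$gene_orf_codons[2]),
                  config$n_coding_genes, replace = TRUE),
           draw_coding_seq, character(1), model = model),
    gene_ids)
  gene_strand <- sample(c("+", "-"), config$n_coding_genes, replace = TRUE)

  # layout: every element is preceded by a gap comfortably larger than the
  # flank; at most one intergenic feature per inter-gene gap
  intergenic <- c(linc_seqs, dup_seqs, short_seqs, long_orf_seqs,
                  hk_like_seqs)
  intergenic <- intergenic[sample(length(intergenic))]
  if (length(intergenic) > config$n_coding_genes) {
    stop("infeasible packing: more intergenic features than inter-gene gaps")
  }
  gap_for <- function() config$flank_bp + 200L + sample(0:300, 1L)
  flank_hosts <- sample(gene_ids, nd)
  intra_hosts <- sample(setdiff(gene_ids, flank_hosts), nd)
  feat_gap <- if (length(intergenic)) {
    stats::setNames(
      round(seq(1L, config$n_coding_genes, length.out = length(intergenic))),
      names(intergenic))
  } else integer()

  parts <- character()
  cursor <- 0L
  rec <- list()
  add_part <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    cursor <<- cursor + nchar(s)
  }
  add_feature <- function(id, s, strand, class) {
    add_part(random_dna(gap_for()))
    start <- cursor + 1L
    add_part(if (strand == "-")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      else s)
    rec[[length(rec) + 1L]] <<- data.frame(
      id = id, class = class, start = start, end = cursor, strand = strand,
      stringsAsFactors = FALSE)
  }
  flank_i <- 0L
  intra <- list()
  for (g in seq_along(gene_ids)) {
    gid <- gene_ids[g]
    add_feature(gid, gene_seqs[[gid]], gene_strand[g], "gene")
    gstart <- rec[[length(rec)]]$start
    gend <- rec[[length(rec)]]$end
    if (gid %in% intra_hosts) {
      dl <- sample(200:min(300L, gend - gstart - 60L), 1L)
      at <- gstart + 30L
      intra[[length(intra) + 1L]] <- data.frame(
        id = sprintf("TCONS_intra_%03d", length(intra) + 1L),
        class = "intragenic_decoy", start = at, end = at + dl - 1L,
        strand = "*", stringsAsFactors = FALSE)
    }
    if (gid %in% flank_hosts) {
      flank_i <- flank_i + 1L
      add_part(random_dna(200L + sample(0:100, 1L)))  # inside the flank
      start <- cursor + 1L
      add_part(random_dna(sample(220:320, 1L)))
      rec[[length(rec) + 1L]] <- data.frame(
        id = sprintf("TCONS_flank_%03d", flank_i), class = "flank_decoy",
        start = start, end = cursor, strand = "*", stringsAsFactors = FALSE)
    }
    for (fid in names(feat_gap)[feat_gap == g]) {
      add_feature(fid, intergenic[[fid]], "*",
                  switch(substr(fid, 7L, 10L),
                         linc = "linc", dup_ = "duplicate",
                         shor = "short_decoy", orf_ = "long_orf_decoy",
                         hk_0 = "hk_like", hk_1 = "hk_like",
                         stop("unknown feature ", fid)))
    }
  }
  add_part(random_dna(gap_for()))
  needed <- cursor
  if (!is.null(config$chrom_length)) {
    if (config$chrom_length < needed) {
      stop(sprintf(
        "infeasible packing: loci plus flanks need %d bp > chrom_length %d",
        needed, config$chrom_length))
    }
    add_part(random_dna(config$chrom_length - needed))
  }
  chrom <- paste(parts, collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))

  rec <- do.call(rbind, c(rec, intra, list(make.row.names = FALSE)))
  gr_of <- function(d) {
    GenomicRanges::GRanges("chr1",
                           IRanges::IRanges(d$start, d$end),
                           strand = d$strand,
                           seqlengths = c(chr1 = nchar(chrom)))
  }
  genes_rec <- rec[rec$class == "gene", , drop = FALSE]
  genes <- gr_of(genes_rec)
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    gene_id = genes_rec$id, biotype = "protein_coding")

  tx_rec <- rec
  tx_rec$id[tx_rec$class == "gene"] <-
    sprintf("TCONS_cg_%04d", seq_len(sum(tx_rec$class == "gene")))
  assembly <- GenomicRanges::GRangesList(stats::setNames(
    lapply(seq_len(nrow(tx_rec)), function(i) gr_of(tx_rec[i, ])),
    tx_rec$id))

  # subject genomes with planted homologous copies
  conserved_ids <- if (config$n_conserved > 0 && nl > 0) {
    sample(names(linc_seqs), config$n_conserved)
  } else character()
  subject_names <- paste0("subject_", seq_len(config$n_subject_genomes))
  placements <- lapply(conserved_ids, function(id) {
    sample(subject_names, config$conservation_k)
  })
  names(placements) <- conserved_ids
  subjects <- lapply(subject_names, function(sp) {
    here <- conserved_ids[vapply(placements, function(p) sp %in% p,
                                 logical(1))]
    sparts <- character()
    slot <- if (length(here)) {
      max(200L, (config$subject_genome_length -
                 sum(nchar(linc_seqs[here]))) %/% (length(here) + 1L))
    } else config$subject_genome_length
    for (id in here) {
      sparts <- c(sparts, random_dna(slot),
                  mutate_dna(linc_seqs[[id]], config$conservation_mutation))
    }
    sparts <- c(sparts, random_dna(slot))
    Biostrings::DNAStringSet(stats::setNames(paste(sparts, collapse = ""),
                                             paste0(sp, "_scaffold1")))
  })
  names(subjects) <- subject_names

  truth <- list(
    planted_linc_ids = names(linc_seqs),
    coding_gene_ids = gene_ids,
    coding_tx_ids = tx_rec$id[tx_rec$class == "gene"],
    short_decoy_ids = names(short_seqs),
    intragenic_decoy_ids = rec$id[rec$class == "intragenic_decoy"],
    flank_decoy_ids = rec$id[rec$class == "flank_decoy"],
    long_orf_decoy_ids = names(long_orf_seqs),
    housekeeping_like_ids = names(hk_like_seqs),
    duplicate_pairs = data.frame(dup_id = names(dup_seqs),
                                 source_id = unname(dup_src),
                                 stringsAsFactors = FALSE),
    conserved_ids = sort(conserved_ids),
    conserved_in = lapply(stats::setNames(subject_names, subject_names),
                          function(sp) sort(conserved_ids[vapply(
                            placements, function(p) sp %in% p, logical(1))])))

  list(genome = genome, annotation = genes, assembly = assembly,
       housekeeping = hk, subjects = subjects, truth = truth,
       config = config)
}

#' Simulate tissue and development expression matrices with planted truth
#'
#' Tissue matrix: each tissue-specific lincRNA is high (log-normal) in its
#' tissue and below 0.5 FPKM elsewhere (guaranteeing tau > 0.95); broad
#' features vary mildly around a per-feature base (tau < 0.5, verified).
#' Development matrix: module members follow a module eigen-profile that is
#' strictly monotone in the development time rank (logistic ramps at
#' staggered onsets; decreasing for negative-sign modules) plus Gaussian
#' noise on the log2 scale; one designated hub per module has the lowest
#' noise, one designated lincRNA the next lowest. Stage-specific lincRNAs
#' are >= 5 FPKM in every sample of one stage and < 1 elsewhere; two
#' settlement sets are on in eyed larvae (pediveliger) but off in spat and
#' vice versa.
#'
#' @param truth truth table from [simulate_genome()].
#' @param config see [sim_config()].
#' @return list with `tissue` and `development`
#'   (`SummarizedExperiment`s) and the augmented `truth`.
#' @export
simulate_expression <- function(truth, config = sim_config()) {
  with_seed(config$seed + 7919L, simulate_expression_impl(truth, config))
}

simulate_expression_impl <- function(truth, config) {
  lincs <- truth$planted_linc_ids
  genes <- truth$coding_gene_ids
  feats <- c(genes, lincs)
  kind <- stats::setNames(c(rep("mRNA", length(genes)),
                            rep("lincRNA", length(lincs))), feats)

  ## ---- tissue matrix ----
  tp <- config$tissue_panel
  ts_lincs <- if (length(lincs)) {
    sample(lincs, min(config$n_tissue_specific, length(lincs)))
  } else character()
  ts_map <- stats::setNames(rep(tp, length.out = length(ts_lincs)), ts_lincs)
  tmat <- matrix(0, nrow = length(feats), ncol = length(tp),
                 dimnames = list(feats, paste0("ts_", tp)))
  for (f in feats) {
    if (f %in% ts_lincs) {
      v <- stats::runif(length(tp), 0, 0.4)
      v[match(ts_map[[f]], tp)] <- stats::rlnorm(1, log(30), 0.3)
    } else {
      base <- if (kind[[f]] == "mRNA") stats::rlnorm(1, log(40), 0.7)
              else stats::rlnorm(1, log(4), 0.5)
      repeat {
        v <- base * exp(stats::rnorm(length(tp), 0, 0.15))
        if (tau(v) < 0.5) break
      }
    }
    tmat[f, ] <- v
  }
  # generation-time guarantee of the planted specificity contrast
  stopifnot(all(apply(tmat[ts_lincs, , drop = FALSE], 1L, tau) > 0.95))
  tissue_meta <- data.frame(sample_id = colnames(tmat), tissue = tp,
                            stringsAsFactors = FALSE)
  tissue_se <- expression_matrix(tmat, tissue_meta, kind)

  ## ---- development matrix ----
  n <- config$n_timepoints
  ns <- config$n_stages
  stages <- stage_names_for(ns)
  sizes <- diff(round(seq(0, n, length.out = ns + 1)))
  stage_of <- rep(stages, times = sizes)
  time_days <- round(seq(0.25, 25, length.out = n), 2)
  meta <- data.frame(sample_id = sprintf("dev_%02d", seq_len(n)),
                     time_days = time_days, time_rank = seq_len(n),
                     stage = stage_of, stringsAsFactors = FALSE)

  m <- length(config$module_spec)
  linc_pool <- sample(lincs)
  gene_pool <- sample(genes)
  take <- function(pool, k) {
    if (k > length(pool)) stop("module sizes exceed available features")
    pool[seq_len(k)]
  }
  assignment <- stats::setNames(rep("background", length(feats)), feats)
  profiles <- matrix(0, nrow = n, ncol = m,
                     dimnames = list(meta$sample_id, paste0("M", seq_len(m))))
  hub_ids <- character(m)
  linked_linc_ids <- character(m)
  members_of <- list()
  for (j in seq_len(m)) {
    spec_j <- config$module_spec[[j]]
    n_linc_j <- min(config$lincs_per_module, spec_j$size, length(linc_pool))
    ml <- take(linc_pool, n_linc_j)
    linc_pool <- setdiff(linc_pool, ml)
    mg <- take(gene_pool, spec_j$size - n_linc_j)
    gene_pool <- setdiff(gene_pool, mg)
    members <- c(mg, ml)
    assignment[members] <- paste0("M", j)
    # steep logistic ramps with staggered onsets: strictly monotone in the
    # time rank (|Spearman| = 1 with time_order) yet mutually separable
    centre <- n * (2 * j - 1) / (2 * m)
    raw <- stats::plogis((seq_len(n) - centre) / max(1, n / 22))
    e <- as.numeric(scale(raw)) * sign(spec_j$sign)
    profiles[, j] <- e
    hub_ids[j] <- mg[1L]
    linked_linc_ids[j] <- if (length(ml)) ml[1L] else NA_character_
    members_of[[paste0("M", j)]] <- members
  }
  st_lincs <- take(linc_pool, min(config$n_stage_specific,
                                  length(linc_pool)))
  linc_pool <- setdiff(linc_pool, st_lincs)
  # stage-specific lincs live in the pre-settlement stages; the settlement
  # stages (eyed pediveliger and spat) are modeled by the dedicated on/off
  # sets below, keeping the two planted classes disjoint
  st_stages <- if (ns > 2L) stages[seq_len(ns - 2L)] else stages
  st_map <- stats::setNames(rep(st_stages, length.out = length(st_lincs)),
                            st_lincs)
  eyed <- stages[max(1L, ns - 1L)]
  spat <- stages[ns]
  set_a <- take(linc_pool, min(config$n_settlement[1], length(linc_pool)))
  linc_pool <- setdiff(linc_pool, set_a)
  set_b <- take(linc_pool, min(config$n_settlement[2], length(linc_pool)))
  linc_pool <- setdiff(linc_pool, set_b)

  dmat <- matrix(0, nrow = length(feats), ncol = n,
                 dimnames = list(feats, meta$sample_id))
  for (f in feats) {
    mod <- assignment[[f]]
    if (mod != "background") {
      j <- as.integer(sub("M", "", mod))
      nsd <- if (f == hub_ids[j]) config$noise_sd * 0.2
             else if (f == linked_linc_ids[j]) config$noise_sd * 0.3
             else config$noise_sd
      v <- stats::runif(1, 4, 7) +
        stats::runif(1, 0.9, 1.1) * profiles[, j] +
        stats::rnorm(n, 0, nsd)
      dmat[f, ] <- pmax(2^v - 1, 0)
    } else if (f %in% st_lincs) {
      v <- stats::runif(n, 0, 0.8)
      v[stage_of == st_map[[f]]] <- stats::runif(sum(stage_of == st_map[[f]]),
                                                 6, 20)
      dmat[f, ] <- v
    } else if (f %in% set_a || f %in% set_b) {
      on_stage <- if (f %in% set_a) eyed else spat
      off_stage <- if (f %in% set_a) spat else eyed
      v <- stats::runif(n, 1.5, 4)
      v[stage_of == on_stage] <- stats::runif(sum(stage_of == on_stage),
                                              6, 15)
      v[stage_of == off_stage] <- stats::runif(sum(stage_of == off_stage),
                                               0, 0.8)
      dmat[f, ] <- v
    } else {
      v <- stats::runif(1, 1, 6) + stats::rnorm(n, 0, 0.8)
      dmat[f, ] <- pmax(2^v - 1, 0)
    }
  }
  dev_se <- expression_matrix(dmat, meta, kind)

  truth$tissue_specific_map <- ts_map
  truth$stage_specific_map <- st_map
  truth$settlement_eyed_ids <- set_a
  truth$settlement_spat_ids <- set_b
  truth$settlement_stages <- c(eyed = eyed, spat = spat)
  truth$module_assignment <- assignment
  truth$module_profiles <- profiles
  truth$hub_ids <- stats::setNames(hub_ids, paste0("M", seq_len(m)))
  truth$linked_linc_ids <- stats::setNames(linked_linc_ids,
                                           paste0("M", seq_len(m)))
  truth$module_members <- members_of
  list(tissue = tissue_se, development = dev_se, truth = truth)
}

#' Simulate a GO-style term annotation with one planted enriched term per
#' module
#'
#' @param truth augmented truth from [simulate_expression()].
#' @param config see [sim_config()].
#' @param n_random_terms random (null) terms in addition to the planted
#'   ones.
#' @return list with `term_map` (data.frame gene/term/name) and
#'   `planted_terms` (module -> term ID).
#' @export
simulate_go_terms <- function(truth, config = sim_config(),
                              n_random_terms = 40L) {
  with_seed(config$seed + 104729L, {
    universe <- truth$coding_gene_ids
    rows <- list()
    planted <- character()
    mods <- names(truth$module_members %||% list())
    for (i in seq_along(mods)) {
      mm <- intersect(truth$module_members[[mods[i]]], universe)
      core <- sample(mm, max(2L, round(0.7 * length(mm))))
      extra <- sample(setdiff(universe, core), 5L)
      tid <- sprintf("GO:%07d", 9000000L + i)
      planted[mods[i]] <- tid
      rows[[length(rows) + 1L]] <- data.frame(
        gene = c(core, extra), term = tid,
        name = paste0("synthetic development process ", i),
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_random_terms)) {
      sz <- sample(10:60, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = sample(universe, min(sz, length(universe))),
        term = sprintf("GO:%07d", i),
        name = paste0("synthetic background process ", i),
        stringsAsFactors = FALSE)
    }
    list(term_map = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         planted_terms = planted)
  })
}
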