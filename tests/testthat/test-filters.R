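make_tx <- function(lengths, chrom = "chr1", start0 = 10000) {
  tx <- GenomicRanges::GRangesList(lapply(seq_along(lengths), function(i) {
    st <- start0 + (i - 1) * 5000
    GenomicRanges::GRanges(chrom, IRanges::IRanges(st, st + lengths[i] - 1),
                           strand = "*")
  }))
  names(tx) <- sprintf("t%03d", seq_along(lengths))
  tx
}

test_that("length filter keeps >= 200 bp and matches brute force", {
  tx <- make_tx(c(199, 200, 201))
  got <- filter_length(tx, 200)
  expect_equal(names(got$surviving), c("t002", "t003"))
  expect_equal(got$removed$id, "t001")

  all_long <- make_tx(c(300, 400))
  expect_equal(names(filter_length(all_long)$surviving), names(all_long))

  withr::local_seed(5)
  lens <- sample(50:500, 200, replace = TRUE)
  tx <- make_tx(lens)
  got <- filter_length(tx, 200)
  expect_equal(names(got$surviving), names(tx)[lens >= 200])
  expect_length(filter_length(make_tx(integer()))$surviving, 0)
})

test_that("intergenic filter expands genes by the flank, strand-blind", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000),
                                  strand = "+")
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    gene_id = "g1", biotype = "protein_coding")
  tx <- GenomicRanges::GRangesList(
    near = GenomicRanges::GRanges("chr1", IRanges::IRanges(1201, 1500)),
    far = GenomicRanges::GRanges("chr1", IRanges::IRanges(1601, 1900)),
    inside = GenomicRanges::GRanges("chr1", IRanges::IRanges(400, 700),
                                    strand = "-"))
  got <- classify_intergenic(tx, genes, flank_bp = 500)
  expect_equal(names(got$surviving), "far")
  expect_setequal(got$removed$id, c("near", "inside"))
})

test_that("transcripts on unknown chromosomes are removed as unplaced", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    gene_id = "g1", biotype = "protein_coding")
  tx <- GenomicRanges::GRangesList(
    ok = GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 5400)),
    lost = GenomicRanges::GRanges("chrUn", IRanges::IRanges(10, 400)))
  expect_warning(got <- classify_intergenic(tx, genes, 500,
                                            known_chroms = "chr1"),
                 "unknown")
  expect_equal(names(got$surviving), "ok")
  expect_equal(got$removed$reason[got$removed$id == "lost"], "unplaced")
})

test_that("non-protein-coding genes do not define excluded space", {
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(1, 4000),
                                                   c(1000, 5000)))
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    gene_id = c("g1", "nc1"), biotype = c("protein_coding", "lncRNA"))
  tx <- GenomicRanges::GRangesList(
    t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(4100, 4400)))
  expect_equal(names(classify_intergenic(tx, genes, 500)$surviving), "t1")
})

orf_seq <- function(n_internal) {
  paste0("ATG", strrep("AAA", n_internal), "TGA")
}

test_that("ORF filter boundary: 99 aa kept, 100 aa removed", {
  seqs <- c(keep = orf_seq(98), drop = orf_seq(99), noatg = strrep("C", 300))
  got <- filter_orf(seqs, max_orf_aa = 100)
  expect_setequal(got$surviving, c("keep", "noatg"))
  expect_equal(got$removed$id, "drop")
  expect_equal(got$orf$longest_orf_aa[got$orf$transcript_id == "keep"], 99L)
  expect_error(filter_orf(unname(seqs)), "named")
})

test_that("ORF filter matches the regex oracle on random transcripts", {
  withr::local_seed(17)
  seqs <- stats::setNames(
    vapply(1:150, function(i) rand_dna(sample(200:500, 1)), character(1)),
    sprintf("s%03d", 1:150))
  got <- filter_orf(seqs, 100)
  want <- names(seqs)[vapply(seqs, function(s)
    oracle_longest_orf(s)$longest_orf_aa < 100, logical(1))]
  expect_equal(got$surviving, want)
})

test_that("length and ORF stages commute", {
  withr::local_seed(23)
  lens <- sample(150:400, 60, replace = TRUE)
  seqs <- stats::setNames(vapply(lens, rand_dna, character(1)),
                          sprintf("s%02d", seq_along(lens)))
  tx <- make_tx(lens)
  names(tx) <- names(seqs)
  ab <- filter_orf(seqs[names(filter_length(tx, 200)$surviving)], 100)
  ba <- filter_length(tx[filter_orf(seqs, 100)$surviving], 200)
  expect_setequal(ab$surviving, names(ba$surviving))
})

test_that("housekeeping filter removes hits at E <= 1e-5 inclusive", {
  withr::local_seed(31)
  hk <- Biostrings::DNAStringSet(c(hk1 = rand_dna(200)))
  cand <- c(self = as.character(hk[[1]]), clean = rand_dna(250))
  got <- filter_housekeeping(cand, hk_db = hk)
  expect_equal(got$surviving, "clean")
  expect_match(got$removed$reason, "hk1")

  hits <- data.frame(query_id = c("a", "b"), subject_id = "hk1",
                     percent_identity = 0.9, align_length = 100,
                     q_start = 1, q_end = 100, s_start = 1, s_end = 100,
                     score = 50, e_value = c(1e-5, 1.01e-5))
  got <- filter_housekeeping(c(a = rand_dna(250), b = rand_dna(250)),
                             hits = hits)
  expect_equal(got$surviving, "b")  # E = 1e-5 exactly is removed
})

test_that("redundancy clustering collapses containment and near-duplicates", {
  withr::local_seed(41)
  a <- rand_dna(300)
  b <- substr(a, 1, 285)
  got <- cluster_redundant(c(A = a, B = b), 0.95)
  expect_length(got$clusters, 1)
  expect_equal(got$clusters[[1]]$representative_id, "A")
  expect_equal(unname(got$clusters[[1]]$identity["B"]), 1.0)
  expect_equal(got$representatives, "A")

  distinct <- c(x = rand_dna(300), y = rand_dna(300), z = rand_dna(300))
  got <- cluster_redundant(distinct, 0.95)
  expect_length(got$clusters, 3)

  near <- lincscan:::mutate_dna(substr(a, 1, 270), 0.03)   # ~97% identity
  far <- lincscan:::mutate_dna(substr(a, 1, 270), 0.10)    # ~90% identity
  expect_length(cluster_redundant(c(A = a, N = near), 0.95)$clusters, 1)
  expect_length(cluster_redundant(c(A = a, F = far), 0.95)$clusters, 2)
})

test_that("clustering identity boundary at matches/shorter = 0.95", {
  withr::local_seed(43)
  base <- rand_dna(200)
  flip <- function(s, at) {
    for (i in at) {
      substr(s, i, i) <- setdiff(c("A", "C", "G", "T"),
                                 substr(s, i, i))[1]
    }
    s
  }
  pos <- seq(10, 190, length.out = 11)
  ten <- flip(base, round(pos)[1:10])    # 190/200 = 0.95
  eleven <- flip(base, round(pos))       # 189/200 = 0.945
  expect_equal(seq_identity(ten, base), 0.95)
  expect_length(cluster_redundant(c(A = base, B = ten), 0.95)$clusters, 1)
  expect_length(cluster_redundant(c(A = base, B = eleven), 0.95)$clusters, 2)
})

test_that("cluster members reach the threshold and representatives differ", {
  pipe <- get_small_pipeline()
  for (cl in pipe$clusters) {
    expect_true(all(cl$identity >= 0.95))
  }
  reps <- vapply(pipe$clusters, `[[`, character(1), "representative_id")
  seqs <- extract_sequences(get_small_scene()$genome,
                            get_small_scene()$assembly[reps])
  if (length(reps) > 1) {
    for (i in seq_along(reps)[-1]) {
      expect_lt(seq_identity(as.character(seqs[[i]]),
                             as.character(seqs[[1]])), 0.95)
    }
  }
})

test_that("the full cascade recovers planted lincRNAs on the small scene", {
  scene <- get_small_scene()
  pipe <- get_small_pipeline()
  expect_setequal(names(pipe$catalog), scene$truth$planted_linc_ids)
  expect_silent(check_filter_report(pipe$report))
  # every decoy is removed at its designated stage
  rm_at <- function(stage) pipe$report$removed[[stage]]$id
  expect_true(all(scene$truth$short_decoy_ids %in% rm_at("length")))
  expect_true(all(c(scene$truth$flank_decoy_ids,
                    scene$truth$intragenic_decoy_ids,
                    scene$truth$coding_tx_ids) %in% rm_at("intergenic")))
  expect_true(all(scene$truth$long_orf_decoy_ids %in% rm_at("orf")))
  expect_true(all(scene$truth$housekeeping_like_ids %in%
                    rm_at("housekeeping")))
  expect_true(all(scene$truth$duplicate_pairs$dup_id %in% rm_at("cluster")))
})

test_that("empty assembly yields an empty catalog and zeroed report", {
  scene <- get_small_scene()
  res <- run_pipeline(GenomicRanges::GRangesList(), scene$genome,
                      scene$annotation, scene$housekeeping)
  expect_length(res$catalog, 0)
  expect_true(all(report_counts(res$report)$surviving == 0))
  expect_silent(check_filter_report(res$report))
})

test_that("report audit detects subset and partition violations", {
  rep_ok <- get_small_pipeline()$report
  broken <- rep_ok
  broken$surviving_ids$length <- c(broken$surviving_ids$length, "ghost")
  expect_error(check_filter_report(broken), "subset")
  broken2 <- rep_ok
  broken2$removed$orf <- broken2$removed$orf[0, ]
  expect_error(check_filter_report(broken2), "partition")
})
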