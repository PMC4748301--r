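se_from <- function(mat, meta) expression_matrix(mat, meta)

tissue_meta <- function(tissues) {
  data.frame(sample_id = paste0("s_", seq_along(tissues)), tissue = tissues)
}

test_that("expressed set uses the max-over-samples >= threshold rule", {
  mat <- rbind(zero = c(0, 0), edge = c(1, 0), low = c(0.5, 0.9))
  colnames(mat) <- c("s_1", "s_2")
  se <- se_from(mat, tissue_meta(c("a", "b")))
  expect_setequal(expressed_set(se, 1), "edge")

  withr::local_seed(71)
  big <- matrix(runif(600, 0, 3), 100, 6,
                dimnames = list(sprintf("f%03d", 1:100), paste0("s_", 1:6)))
  se <- se_from(big, tissue_meta(letters[1:6]))
  expect_setequal(expressed_set(se, 1),
                  rownames(big)[apply(big, 1, max) >= 1])
})

test_that("tau reproduces its closed-form limits and worked example", {
  expect_equal(tau(c(0, 0, 8, 0)), 1.0)
  expect_equal(tau(c(5, 5, 5, 5)), 0.0)
  expect_equal(tau(c(1, 2, 4)), 0.625)
  expect_error(tau(c(0, 0, 0)), "all-zero")
  expect_error(tau(5), "two")
  expect_error(tau(c(-1, 2)), "non-negative")
})

test_that("tau is scale-invariant and rises under concentration", {
  withr::local_seed(73)
  for (i in 1:50) {
    x <- runif(sample(3:9, 1), 0, 20)
    expect_equal(tau(x * runif(1, 0.1, 10)), tau(x))
    # move mass from a non-maximal tissue into the maximal one
    y <- x
    lo <- which.min(y)
    hi <- which.max(y)
    shift <- y[lo] * runif(1)
    y[hi] <- y[hi] + shift
    y[lo] <- y[lo] - shift
    expect_gte(tau(y), tau(x) - 1e-12)
  }
})

test_that("tissue specificity flags planted lincRNAs and only them", {
  ex <- get_small_expr()
  truth <- ex$truth
  lincs <- ex$tissue[truth$planted_linc_ids, ]
  tsp <- tissue_specific(lincs)
  flagged <- tsp$results$feature_id[tsp$results$specific]
  expect_setequal(flagged, names(truth$tissue_specific_map))
  hit <- tsp$results[match(flagged, tsp$results$feature_id), ]
  expect_equal(stats::setNames(hit$argmax_tissue, hit$feature_id),
               truth$tissue_specific_map[hit$feature_id])
  # broad features never reach tau 0.5 under the default noise
  broad <- setdiff(tsp$results$feature_id, flagged)
  expect_true(all(tsp$results$tau[tsp$results$feature_id %in% broad] < 0.5))
  # an impossible threshold flags nothing
  none <- tissue_specific(lincs, tau_threshold = 1.01)
  expect_equal(sum(none$results$specific), 0)
})

test_that("tau threshold is strict: tau = 0.95 is not tissue-specific", {
  mat <- matrix(c(20, 1, 1, 1), 1, 4,
                dimnames = list("f1", paste0("s_", 1:4)))
  se <- se_from(mat, tissue_meta(letters[1:4]))
  tsp <- tissue_specific(se)
  expect_equal(tsp$results$tau, 0.95)
  expect_false(tsp$results$specific)
  # features below the expression floor are absent from the results
  low <- matrix(0.5, 1, 4, dimnames = list("dim", paste0("s_", 1:4)))
  se2 <- se_from(rbind(mat, low), tissue_meta(letters[1:4]))
  expect_false("dim" %in% tissue_specific(se2)$results$feature_id)
})

test_that("stage-specific calls require exactly one expressed stage", {
  meta <- data.frame(sample_id = paste0("d", 1:6),
                     stage = rep(c("embryo", "larva", "spat"), each = 2))
  mat <- rbind(one = c(5, 7, 0, 0.4, 0, 0),
               two = c(5, 5, 3, 2, 0, 0),
               none = rep(0, 6))
  colnames(mat) <- meta$sample_id
  calls <- stage_specific(se_from(mat, meta))
  expect_equal(calls$specific_stage[calls$feature_id == "one"], "embryo")
  expect_true(is.na(calls$specific_stage[calls$feature_id == "two"]))
  expect_equal(calls$n_stages_expressed[calls$feature_id == "none"], 0)
})

test_that("planted stage-specific lincRNAs are recovered exactly", {
  ex <- get_small_expr()
  truth <- ex$truth
  calls <- stage_specific(ex$development[truth$planted_linc_ids, ])
  got <- calls[!is.na(calls$specific_stage), ]
  expect_setequal(got$feature_id, names(truth$stage_specific_map))
  expect_equal(stats::setNames(got$specific_stage, got$feature_id),
               truth$stage_specific_map[got$feature_id])
})

test_that("settlement contrast applies the moderate/off thresholds", {
  meta <- data.frame(sample_id = paste0("d", 1:4),
                     stage = rep(c("pediveliger", "spat"), each = 2))
  mat <- rbind(strong = c(10, 12, 0, 0.2),
               weak = c(3, 2, 0, 0),
               reverse = c(0.1, 0, 8, 9))
  colnames(mat) <- meta$sample_id
  got <- settlement_contrast(se_from(mat, meta), "pediveliger", "spat")
  expect_equal(got$on_in_a_off_in_b, "strong")  # weak < 5 FPKM: neither set
  expect_equal(got$on_in_b_off_in_a, "reverse")
  expect_error(settlement_contrast(se_from(mat, meta), "pediveliger",
                                   "missing"), "missing")

  ex <- get_small_expr()
  truth <- ex$truth
  st <- settlement_contrast(ex$development[truth$planted_linc_ids, ],
                            truth$settlement_stages[["eyed"]],
                            truth$settlement_stages[["spat"]])
  expect_setequal(st$on_in_a_off_in_b, truth$settlement_eyed_ids)
  expect_setequal(st$on_in_b_off_in_a, truth$settlement_spat_ids)
})

test_that("KDE/KS comparison has the right limits and matches the ECDF oracle", {
  same <- c(1, 2, 3, 4, 5)
  got <- density_compare(same, same)
  expect_equal(got$D, 0)
  expect_equal(got$p_value, 1)
  disjoint <- density_compare(c(0, 0, 0), c(7, 7, 7))
  expect_equal(disjoint$D, 1)

  withr::local_seed(79)
  x <- rlnorm(200, 0, 1)
  y <- rlnorm(150, 0.8, 1)
  got <- density_compare(x, y)
  expect_equal(got$D, oracle_ks_D(log2(x + 1), log2(y + 1)),
               tolerance = 1e-12)
  expect_equal(nrow(got$curves), 512)
  expect_error(density_compare(1, c(1, 2)), "at least 2")
})

test_that("neighbor distances use closest-end gaps and the 10 kb window", {
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(1001, 2000))
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    gene_id = "g1", biotype = "protein_coding")
  lincs <- GenomicRanges::GRangesList(
    near = GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 5300)),
    far = GenomicRanges::GRanges("chr1", IRanges::IRanges(12501, 12800)),
    over = GenomicRanges::GRanges("chr1", IRanges::IRanges(1500, 1800)))
  got <- neighbor_distances(lincs, genes)
  res <- got$results
  expect_equal(res$distance_bp[res$linc_id == "near"], 3000)
  expect_true(res$within_window[res$linc_id == "near"])
  expect_equal(res$distance_bp[res$linc_id == "far"], 10500)
  expect_false(res$within_window[res$linc_id == "far"])
  expect_equal(res$distance_bp[res$linc_id == "over"], 0)
  expect_equal(got$fraction_within, 2 / 3)
  expect_setequal(got$neighbor_gene_set, "g1")

  orphan <- GenomicRanges::GRangesList(
    alone = GenomicRanges::GRanges("chr9", IRanges::IRanges(100, 400)))
  expect_warning(res2 <- neighbor_distances(orphan, genes), "gene-free")
  expect_equal(nrow(res2$results), 0)
})
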