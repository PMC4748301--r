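test_that("spearman correlation matches the rank-Pearson oracle", {
  x <- 1:10
  expect_equal(spearman(x, x^2)$rho, 1.0)   # rank invariance
  expect_equal(spearman(x, rev(x))$rho, -1.0)
  expect_equal(spearman(x, x^2)$p, 0)
  got <- spearman(1:5, c(2, 1, 4, 3, 5))
  expect_equal(got$rho, oracle_spearman(1:5, c(2, 1, 4, 3, 5)))
  expect_equal(got$rho, 0.8)
  expect_true(is.na(spearman(rep(1, 5), 1:5)$rho))
  withr::local_seed(83)
  for (i in 1:25) {
    a <- rnorm(12)
    b <- rnorm(12) + sample(0:1, 1) * a
    expect_equal(spearman(a, b)$rho, oracle_spearman(a, b),
                 tolerance = 1e-12)
  }
})

test_that("adjacency applies the soft-threshold transform", {
  withr::local_seed(89)
  mat <- matrix(rlnorm(8 * 10), 8, 10,
                dimnames = list(paste0("f", 1:8), paste0("s", 1:10)))
  cfg <- network_config(beta = 6)
  a <- adjacency(mat, cfg)
  cc <- cor(t(log2(mat + 1)))
  expect_equal(a[2, 5], abs(cc[2, 5])^6, tolerance = 1e-12)
  expect_equal(unname(diag(a)), rep(1, 8))
  expect_true(isSymmetric(a))
  expect_true(all(a >= 0 & a <= 1))
  # perfectly correlated duplicate rows give adjacency 1
  dup <- rbind(mat, f9 = mat[1, ])
  expect_equal(adjacency(dup, cfg)["f1", "f9"], 1)
  # signed variant
  s <- adjacency(mat, network_config(beta = 6, signed = TRUE))
  expect_equal(s[2, 5], ((1 + cc[2, 5]) / 2)^6, tolerance = 1e-12)
  # cor -0.5 at beta 6 gives 0.5^6
  expect_equal(abs(-0.5)^6, 0.015625)
  # constant features are warned about and disconnected
  const <- rbind(mat, flat = rep(2, 10))
  expect_warning(ac <- adjacency(const, cfg), "constant")
  expect_equal(unname(ac["flat", "f1"]), 0)
})

test_that("topological overlap matches hand values and the cubic oracle", {
  ones <- matrix(1, 3, 3)
  tom <- topological_overlap(ones)
  expect_equal(tom[1, 2], 1)  # (1+1)/(2+1-1)
  eye <- diag(4)
  expect_true(all(topological_overlap(eye)[upper.tri(eye)] == 0))

  withr::local_seed(97)
  a <- matrix(runif(400), 20, 20)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  expect_lt(max(abs(topological_overlap(a) - oracle_tom(a))), 1e-12)
  expect_error(topological_overlap(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("module detection separates planted blocks deterministically", {
  n <- 60
  ids <- sprintf("f%02d", 1:n)
  tom <- matrix(0.02, n, n, dimnames = list(ids, ids))
  tom[1:25, 1:25] <- 0.7
  tom[26:45, 26:45] <- 0.6
  diag(tom) <- 1
  cfg <- network_config(min_module_size = 10, tree_cut_height = 0.9)
  got <- detect_modules(tom, cfg)
  expect_setequal(unique(got$module), c("turquoise", "blue", "grey"))
  expect_equal(got$module[1:25], rep("turquoise", 25))  # largest first
  expect_equal(got$module[26:45], rep("blue", 20))
  expect_equal(got$module[46:60], rep("grey", 15))
  expect_identical(detect_modules(tom, cfg), got)  # deterministic

  flat <- matrix(0.5, 30, 30, dimnames = list(ids[1:30], ids[1:30]))
  diag(flat) <- 1
  deg <- detect_modules(flat, cfg)
  expect_length(unique(deg$module), 1)  # documented degenerate outcome
})

test_that("module eigengene is the oriented first principal component", {
  p <- seq(1, 5, length.out = 12)
  # FPKM chosen so the internal log2(FPKM + 1) recovers affine images of p
  sub <- rbind(a = 2^(2 * p + 1) - 1, b = 2^(3 * p) - 1, c = 2^(p + 4) - 1)
  colnames(sub) <- paste0("s", 1:12)
  eg <- module_eigengene(sub)
  expect_equal(sum(eg^2), 1)
  expect_gt(cor(eg, p), 0.999)  # oriented along the shared profile

  withr::local_seed(101)
  mat <- matrix(rnorm(100, 5, 1), 10, 10,
                dimnames = list(paste0("f", 1:10), paste0("s", 1:10)))
  mat <- 2^mat - 1
  eg <- module_eigengene(mat)
  xs <- t(scale(t(log2(mat + 1))))
  explained <- function(v) sum((xs %*% v)^2)
  expect_equal(explained(eg), svd(xs)$d[1]^2, tolerance = 1e-8)
  for (i in 1:10) {
    member <- xs[i, ] / sqrt(sum(xs[i, ]^2))
    expect_gte(explained(eg), explained(member) - 1e-8)
  }
  expect_error(module_eigengene(mat[1, , drop = FALSE]), "2 members")
  expect_error(module_eigengene(rbind(a = rep(1, 6), b = rep(2, 6))),
               "degenerate")
})

test_that("planted modules are recovered and flagged against time order", {
  ex <- get_small_expr()
  truth <- ex$truth
  net <- get_small_network()
  det <- stats::setNames(net$assignment$module, net$assignment$feature_id)
  tr <- truth$module_assignment[names(det)]
  expect_gte(mclust::adjustedRandIndex(det, tr), 0.8)
  mt <- net$module_trait
  to <- mt[mt$trait == "time_order", ]
  planted_labels <- unique(det[names(truth$module_assignment)[
    truth$module_assignment != "background"]])
  planted_labels <- setdiff(planted_labels, "grey")
  for (lab in planted_labels) {
    expect_gte(abs(to$rho[to$module == lab]), 0.6)
    expect_lt(to$p[to$module == lab], 0.01)
    expect_true(unique(to$flagged[to$module == lab]))
  }
  # eigen-profiles themselves are strictly monotone in the time rank
  for (j in seq_len(ncol(truth$module_profiles))) {
    expect_gte(abs(cor(truth$module_profiles[, j],
                       seq_len(nrow(truth$module_profiles)),
                       method = "spearman")), 0.9)
  }
})

test_that("a constant trait yields an unflagged module with a warning", {
  eg <- matrix(rnorm(10), 10, 1, dimnames = list(NULL, "turquoise"))
  expect_warning(
    mt <- module_trait(eg, list(time_order = rep(1, 10))),
    "constant trait")
  expect_true(all(!mt$flagged))
  expect_true(all(is.na(mt$rho)))
})

test_that("gene-trait correlations carry sign and module-wise FDR", {
  ex <- get_small_expr()
  truth <- ex$truth
  net <- get_small_network()
  trait <- trait_vectors(ex$development)$time_order
  gt <- net$gene_trait
  expect_true(all(gt$p_fdr >= gt$p - 1e-15, na.rm = TRUE))
  expect_true(all(gt$p_fdr <= 1, na.rm = TRUE))
  expect_equal(gt$sign[!is.na(gt$rho)],
               ifelse(gt$rho[!is.na(gt$rho)] >= 0, "+", "-"))
  # a planted increasing member is significantly positive
  m1 <- truth$module_members[["M1"]]
  hit <- gt[gt$feature_id %in% m1, ]
  expect_true(all(hit$sign == "+"))
  expect_true(all(hit$significant))
  # BH matches the reference step-up implementation within each module
  for (m in unique(gt$module)) {
    sel <- gt$module == m
    expect_equal(gt$p_fdr[sel], p.adjust(gt$p[sel], "BH"))
  }
  # single feature: p_fdr equals p
  single <- gene_trait(
    SummarizedExperiment::assay(ex$development, "fpkm")[m1[1], ,
                                                        drop = FALSE],
    trait, data.frame(feature_id = m1[1], module = "solo"))
  expect_equal(single$p_fdr, single$p)
})

test_that("hubs use the ceiling rule and kIM matches brute force", {
  withr::local_seed(103)
  ids <- sprintf("f%02d", 1:10)
  a <- matrix(runif(100), 10, 10, dimnames = list(ids, ids))
  a <- (a + t(a)) / 2
  diag(a) <- 1
  assign10 <- data.frame(feature_id = ids, module = "turquoise")
  got <- hubs_and_links(a, assign10,
                        config = network_config(hub_percentile = 0.01))
  expect_equal(sum(got$connectivity$is_hub), 1)  # ceil(0.1) = 1
  for (i in seq_along(ids)) {
    expect_equal(got$connectivity$k_im[i], sum(a[i, -i]))
  }
  # the planted low-noise hub tops its module's intramodular connectivity
  net <- get_small_network()
  truth <- get_small_expr()$truth
  expect_true(all(truth$hub_ids %in% net$hubs$feature_id))
  # designated lincRNAs are directly connected to hubs via exported edges
  expect_true(all(truth$linked_linc_ids %in% net$linc_hub_links$linc_id))
})

test_that("soft power selection falls back on white noise and reports a
          recomputable fit", {
  withr::local_seed(107)
  noise <- matrix(rlnorm(40 * 20), 40, 20,
                  dimnames = list(paste0("f", 1:40), paste0("s", 1:20)))
  expect_warning(got <- pick_soft_power(noise, candidates = 1:6), "falling back")
  expect_equal(got$beta, 6L)
  ex <- get_small_expr()
  sel <- pick_soft_power(ex$development, candidates = 1:12)
  row <- sel$fit_table[sel$fit_table$power == sel$beta, ]
  cfg <- network_config(beta = sel$beta)
  k <- rowSums(suppressWarnings(adjacency(ex$development, cfg))) - 1
  refit <- scale_free_fit(k)
  if (!is.na(row$r_squared)) {
    expect_equal(row$r_squared, refit$r_squared, tolerance = 1e-12)
  }
})

test_that("identical inputs produce identical network outputs", {
  ex <- get_small_expr()
  n1 <- build_network(ex$development, ex$truth$planted_linc_ids,
                      config = small_network_config())
  n2 <- build_network(ex$development, ex$truth$planted_linc_ids,
                      config = small_network_config())
  expect_identical(n1$assignment, n2$assignment)
  expect_identical(n1$hubs, n2$hubs)
  expect_identical(n1$edges, n2$edges)
})
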