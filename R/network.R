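#' Configuration for the weighted co-expression network
#'
#' @param beta soft-thresholding power (integer), or "auto" to choose via
#'   [pick_soft_power()].
#' @param cor_method_genes gene-gene correlation: "pearson" (default, on
#'   log2(FPKM+1)) or "spearman".
#' @param signed signed or unsigned adjacency.
#' @param min_module_size clusters smaller than this join the unassigned
#'   ("grey") pool.
#' @param tree_cut_height static cut height on the 1 - TOM dissimilarity
#'   dendrogram.
#' @param module_trait_rho_min,module_trait_p_max a module is flagged
#'   trait-related when |Spearman rho| >= rho_min and p < p_max against a
#'   development-time trait.
#' @param gene_trait_fdr_max per-gene trait correlations significant when
#'   BH-adjusted p < this.
#' @param hub_percentile fraction of each module with the highest
#'   intramodular connectivity called hubs (1% or 5% conventionally).
#' @param edge_export_top_k strongest within-module edges exported per
#'   module; "directly connected" lincRNAs are read off this edge set.
#' @return named list of settings.
#' @export
network_config <- function(beta = 6L, cor_method_genes = c("pearson",
                                                           "spearman"),
                           signed = FALSE, min_module_size = 20L,
                           tree_cut_height = 0.90,
                           module_trait_rho_min = 0.6,
                           module_trait_p_max = 0.01,
                           gene_trait_fdr_max = 0.05,
                           hub_percentile = 0.05,
                           edge_export_top_k = 100L) {
  stopifnot(identical(beta, "auto") || beta >= 1,
            hub_percentile > 0, hub_percentile < 1)
  list(beta = beta, cor_method_genes = match.arg(cor_method_genes),
       signed = signed, min_module_size = min_module_size,
       tree_cut_height = tree_cut_height,
       module_trait_rho_min = module_trait_rho_min,
       module_trait_p_max = module_trait_p_max,
       gene_trait_fdr_max = gene_trait_fdr_max,
       hub_percentile = hub_percentile,
       edge_export_top_k = edge_export_top_k)
}

MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                   "grey60", "lightgreen", "lightyellow", "royalblue",
                   "darkred", "darkgreen", "darkturquoise", "darkgrey",
                   "orange", "darkorange", "white", "skyblue", "saddlebrown",
                   "steelblue")

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks; the p-value uses
#' t = rho * sqrt((n-2)/(1-rho^2)) with n-2 degrees of freedom.
#'
#' @param x,y equal-length numeric vectors (n >= 4; ties allowed).
#' @return list with `rho` and `p` (both NA when either vector is constant).
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p)
}

# features x samples FPKM -> standardized log2(FPKM + 1)
log_fpkm <- function(se_or_mat) {
  mat <- if (methods::is(se_or_mat, "SummarizedExperiment")) {
    SummarizedExperiment::assay(se_or_mat, "fpkm")
  } else se_or_mat
  log2(mat + 1)
}

#' Soft-threshold adjacency matrix
#'
#' Unsigned: A_ij = |cor(i, j)|^beta; signed: ((1 + cor) / 2)^beta.
#' Correlations are computed across samples on log2(FPKM + 1). Constant
#' features get zero adjacency (with a warning). A_ii = 1.
#'
#' @param se expression container or FPKM matrix (features x samples).
#' @param config see [network_config()]; `beta` must be numeric here.
#' @return symmetric adjacency matrix in \[0, 1\].
#' @export
adjacency <- function(se, config = network_config()) {
  x <- log_fpkm(se)
  if (ncol(x) < 4L) stop("need at least 4 samples")
  if (config$cor_method_genes == "spearman") {
    x <- t(apply(x, 1L, rank))
  }
  const <- apply(x, 1L, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant feature(s): correlations set to 0")
  }
  cc <- suppressWarnings(stats::cor(t(x)))
  cc[is.na(cc)] <- 0
  beta <- config$beta
  if (identical(beta, "auto")) stop("resolve beta with pick_soft_power first")
  a <- if (config$signed) ((1 + cc) / 2)^beta else abs(cc)^beta
  diag(a) <- 1
  a
}

#' Choose the soft power by the scale-free topology criterion
#'
#' For each candidate power, whole-network connectivities k_i are binned and
#' log10 p(k) is regressed on log10 mean(k) per bin; the smallest power with
#' fit R^2 >= `r2_min` and negative slope is returned. When no candidate
#' qualifies the conventional default 6 is returned with a warning.
#'
#' @param se expression container or FPKM matrix.
#' @param candidates candidate powers.
#' @param config base configuration (signed/correlation settings are used).
#' @param r2_min scale-free fit threshold.
#' @param n_bins connectivity histogram bins (fits require >= 8 non-empty).
#' @return list with `beta`, `fit_table` (power, r_squared, slope).
#' @export
pick_soft_power <- function(se, candidates = 1:20,
                            config = network_config(), r2_min = 0.8,
                            n_bins = 10L) {
  fits <- vapply(candidates, function(b) {
    cfg <- config
    cfg$beta <- b
    a <- suppressWarnings(adjacency(se, cfg))
    k <- rowSums(a) - 1
    unlist(scale_free_fit(k, n_bins))
  }, numeric(2))
  tab <- data.frame(power = candidates, r_squared = fits[1L, ],
                    slope = fits[2L, ])
  ok <- which(!is.na(tab$r_squared) & tab$r_squared >= r2_min &
              tab$slope < 0)
  if (length(ok)) {
    list(beta = candidates[ok[1L]], fit_table = tab)
  } else {
    warning("no candidate power reaches scale-free fit R^2 >= ", r2_min,
            "; falling back to 6")
    list(beta = 6L, fit_table = tab)
  }
}

#' Scale-free topology fit of a connectivity vector
#' @param k connectivity vector.
#' @param n_bins histogram bins.
#' @return list with `r_squared` and `slope` (NA when < 8 non-empty bins).
#' @export
scale_free_fit <- function(k, n_bins = 10L) {
  if (stats::sd(k) == 0) return(list(r_squared = NA_real_, slope = NA_real_))
  cuts <- cut(k, breaks = n_bins)
  mean_k <- tapply(k, cuts, mean)
  p_k <- as.numeric(table(cuts)) / length(k)
  keep <- !is.na(mean_k) & p_k > 0 & mean_k > 0
  if (sum(keep) < 8L) return(list(r_squared = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(p_k[keep]) ~ log10(mean_k[keep]))
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2L]))
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u A_iu A_uj + A_ij) / (min(k_i, k_j) + 1 - A_ij) with
#' k_i = sum_{u != i} A_iu (diagonal excluded); TOM_ii = 1.
#'
#' @param a symmetric adjacency matrix in \[0, 1\].
#' @return symmetric TOM matrix in \[0, 1\].
#' @export
topological_overlap <- function(a) {
  if (!isSymmetric(unname(a))) stop("adjacency must be symmetric")
  a0 <- a
  diag(a0) <- 0
  k <- rowSums(a0)
  num <- a0 %*% a0 + a0
  den <- outer(k, k, pmin) + 1 - a0
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect modules by average-linkage clustering of 1 - TOM
#'
#' A static tree cut at `tree_cut_height` defines clusters; clusters smaller
#' than `min_module_size` are pooled as "grey". Labels are assigned by
#' decreasing module size from the conventional module color sequence
#' (deterministic; size ties break by first member order).
#'
#' @param tom TOM matrix with feature dimnames.
#' @param config see [network_config()].
#' @return data.frame with `feature_id` and `module`.
#' @export
detect_modules <- function(tom, config = network_config()) {
  ids <- rownames(tom)
  if (is.null(ids)) stop("TOM must carry feature IDs as dimnames")
  if (length(ids) < 2L || length(ids) < config$min_module_size) {
    return(data.frame(feature_id = ids,
                      module = rep("grey", length(ids)),
                      stringsAsFactors = FALSE))
  }
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  # guard against floating-point inversions among tied merge heights
  if (is.unsorted(hc$height)) hc$height <- cummax(hc$height)
  cl <- stats::cutree(hc, h = config$tree_cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= config$min_module_size]
  # order by size desc, ties by first appearance in feature order
  first_at <- vapply(big, function(g) which(cl == as.integer(g))[1L],
                     integer(1))
  big <- big[order(-sizes[big], first_at)]
  labels <- rep("grey", length(ids))
  for (i in seq_along(big)) {
    lab <- if (i <= length(MODULE_COLORS)) MODULE_COLORS[i]
           else paste0("module", i)
    labels[cl == as.integer(big[i])] <- lab
  }
  data.frame(feature_id = ids, module = labels, stringsAsFactors = FALSE)
}

#' Module eigengene (first principal component of the module submatrix)
#'
#' Member profiles are standardized across samples; the eigengene is the
#' first right-singular vector, unit norm, sign-oriented so its correlation
#' with the members' mean standardized profile is non-negative.
#'
#' @param submat FPKM matrix of the module (members x samples); transformed
#'   to log2(FPKM+1) internally.
#' @return numeric eigengene vector over samples (unit norm).
#' @export
module_eigengene <- function(submat) {
  if (nrow(submat) < 2L) stop("module must have at least 2 members")
  x <- log_fpkm(submat)
  sds <- apply(x, 1L, stats::sd)
  x <- x[sds > 0, , drop = FALSE]
  if (nrow(x) == 0L) stop("degenerate module: all member profiles constant")
  xs <- t(scale(t(x)))
  sv <- svd(xs)
  if (sv$d[1L] <= .Machine$double.eps) stop("degenerate (rank-0) submatrix")
  eg <- sv$v[, 1L]
  eg <- eg / sqrt(sum(eg^2))
  if (stats::cor(eg, colMeans(xs)) < 0) eg <- -eg
  stats::setNames(eg, colnames(submat))
}

#' Development trait vectors from sample metadata
#' @param se expression container whose colData has `time_days`,
#'   `time_rank`, and/or `stage` columns.
#' @return named list of numeric trait vectors (`time_days`, `time_order`,
#'   `stage_ordinal` as available); `time_order` is the rank 1..n of
#'   development time.
#' @export
trait_vectors <- function(se) {
  meta <- SummarizedExperiment::colData(se)
  traits <- list()
  if (!is.null(meta$time_days)) traits$time_days <- as.numeric(meta$time_days)
  if (!is.null(meta$time_rank)) {
    traits$time_order <- as.numeric(meta$time_rank)
  } else if (!is.null(meta$time_days)) {
    traits$time_order <- rank(as.numeric(meta$time_days))
  }
  if (!is.null(meta$stage)) {
    stages <- unique(as.character(meta$stage))
    traits$stage_ordinal <- match(as.character(meta$stage), stages)
  }
  if (!length(traits)) stop("no usable trait columns in sample metadata")
  traits
}

#' Module-trait Spearman correlations and trait-related flags
#'
#' @param eigengenes matrix samples x modules (colnames = module labels).
#' @param traits named list of numeric trait vectors over the same samples.
#' @param config see [network_config()].
#' @param dev_traits trait names that count as development time for
#'   flagging.
#' @return data.frame with module, trait, rho, p, flagged (per module: TRUE
#'   when any development trait meets the rho/p rule).
#' @export
module_trait <- function(eigengenes, traits, config = network_config(),
                         dev_traits = c("time_days", "time_order")) {
  if (is.null(dim(eigengenes)) || ncol(eigengenes) == 0L) {
    return(data.frame(module = character(), trait = character(),
                      rho = numeric(), p = numeric(), flagged = logical(),
                      stringsAsFactors = FALSE))
  }
  rows <- list()
  for (m in colnames(eigengenes)) {
    for (tn in names(traits)) {
      tv <- traits[[tn]]
      if (length(tv) != nrow(eigengenes)) stop("trait/sample mismatch: ", tn)
      sp <- if (stats::sd(tv) == 0) {
        warning("constant trait ", tn, ": correlation undefined")
        list(rho = NA_real_, p = NA_real_)
      } else spearman(eigengenes[, m], tv)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, trait = tn, rho = sp$rho, p = sp$p,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  flag_tab <- tab[tab$trait %in% dev_traits & !is.na(tab$rho), , drop = FALSE]
  flagged_modules <- unique(flag_tab$module[
    abs(flag_tab$rho) >= config$module_trait_rho_min &
    flag_tab$p < config$module_trait_p_max])
  tab$flagged <- tab$module %in% flagged_modules
  tab
}

#' Per-gene Spearman correlation with a trait, BH-adjusted within modules
#'
#' @param se expression container or FPKM matrix.
#' @param trait numeric trait vector over samples.
#' @param assignment data.frame feature_id/module (from [detect_modules()]).
#' @param config see [network_config()].
#' @param scope "module" (BH within each module's feature set, default) or
#'   "global".
#' @return data.frame feature_id, module, rho, p, p_fdr, sign, significant.
#' @export
gene_trait <- function(se, trait, assignment, config = network_config(),
                       scope = c("module", "global")) {
  scope <- match.arg(scope)
  mat <- log_fpkm(se)
  mat <- mat[assignment$feature_id, , drop = FALSE]
  res <- t(apply(mat, 1L, function(v) {
    if (stats::sd(v) == 0) return(c(NA_real_, NA_real_))
    sp <- spearman(v, trait)
    c(sp$rho, sp$p)
  }))
  out <- data.frame(feature_id = assignment$feature_id,
                    module = assignment$module,
                    rho = res[, 1L], p = res[, 2L],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$p_fdr <- NA_real_
  groups <- if (scope == "module") unique(out$module) else "all"
  for (g in groups) {
    sel <- if (scope == "module") out$module == g else rep(TRUE, nrow(out))
    out$p_fdr[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  out$sign <- ifelse(is.na(out$rho), NA_character_,
                     ifelse(out$rho >= 0, "+", "-"))
  out$significant <- !is.na(out$p_fdr) & out$p_fdr < config$gene_trait_fdr_max
  out
}

#' Intramodular connectivity, hub genes and lincRNA-hub links
#'
#' kIM_i is the summed adjacency of feature i to the other members of its
#' module; the top `hub_percentile` (ceiling) per module are hubs (ties by
#' ID order). The strongest `edge_export_top_k` within-module edges are
#' exported; lincRNA members whose edge to a hub is within that set are the
#' "directly connected" lincRNAs.
#'
#' @param a adjacency matrix with feature dimnames.
#' @param assignment data.frame feature_id/module.
#' @param linc_ids character vector of lincRNA feature IDs.
#' @param config see [network_config()].
#' @return list with `connectivity` (feature_id, module, k_im, is_hub),
#'   `hubs` (per module), `edges` (from, to, weight, module), and
#'   `linc_hub_links` (linc_id, hub_id, weight, module).
#' @export
hubs_and_links <- function(a, assignment, linc_ids = character(),
                           config = network_config()) {
  conn <- list()
  edges <- list()
  links <- list()
  modules <- setdiff(unique(assignment$module), "grey")
  for (m in modules) {
    members <- assignment$feature_id[assignment$module == m]
    am <- a[members, members, drop = FALSE]
    diag(am) <- 0
    kim <- rowSums(am)
    n_hub <- ceiling(config$hub_percentile * length(members))
    ord <- order(-kim, members)
    hubs <- members[ord[seq_len(n_hub)]]
    conn[[m]] <- data.frame(feature_id = members, module = m,
                            k_im = unname(kim),
                            is_hub = members %in% hubs,
                            stringsAsFactors = FALSE)
    pairs <- which(upper.tri(am), arr.ind = TRUE)
    ew <- am[pairs]
    top <- order(-ew, members[pairs[, 1L]], members[pairs[, 2L]])
    top <- top[seq_len(min(config$edge_export_top_k, length(top)))]
    edges[[m]] <- data.frame(from = members[pairs[top, 1L]],
                             to = members[pairs[top, 2L]],
                             weight = ew[top], module = m,
                             stringsAsFactors = FALSE)
    e <- edges[[m]]
    is_link <- (e$from %in% hubs & e$to %in% linc_ids) |
               (e$to %in% hubs & e$from %in% linc_ids)
    if (any(is_link)) {
      le <- e[is_link, , drop = FALSE]
      links[[m]] <- data.frame(
        linc_id = ifelse(le$from %in% linc_ids, le$from, le$to),
        hub_id = ifelse(le$from %in% linc_ids, le$to, le$from),
        weight = le$weight, module = m, stringsAsFactors = FALSE)
    }
  }
  bind <- function(lst, proto) {
    if (length(lst)) do.call(rbind, c(lst, list(make.row.names = FALSE)))
    else proto
  }
  conn_df <- bind(conn, data.frame(feature_id = character(),
                                   module = character(), k_im = numeric(),
                                   is_hub = logical()))
  list(connectivity = conn_df,
       hubs = conn_df[conn_df$is_hub, , drop = FALSE],
       edges = bind(edges, data.frame(from = character(), to = character(),
                                      weight = numeric(),
                                      module = character())),
       linc_hub_links = bind(links, data.frame(linc_id = character(),
                                               hub_id = character(),
                                               weight = numeric(),
                                               module = character())))
}

#' Build the full co-expression network from a development matrix
#'
#' Convenience wrapper: adjacency, TOM, module detection, eigengenes,
#' module-trait and gene-trait correlations, hubs and lincRNA-hub links.
#'
#' @param se development expression container (needs `time_days`/`time_rank`
#'   and optionally `stage` in the metadata).
#' @param linc_ids lincRNA feature IDs (others are treated as mRNA).
#' @param config see [network_config()].
#' @return list with all intermediate and final network tables.
#' @export
build_network <- function(se, linc_ids = character(),
                          config = network_config()) {
  if (identical(config$beta, "auto")) {
    config$beta <- pick_soft_power(se, config = config)$beta
  }
  a <- adjacency(se, config)
  tom <- topological_overlap(a)
  assignment <- detect_modules(tom, config)
  mat <- SummarizedExperiment::assay(se, "fpkm")
  modules <- setdiff(unique(assignment$module), "grey")
  eigengenes <- vapply(modules, function(m) {
    module_eigengene(mat[assignment$feature_id[assignment$module == m], ,
                         drop = FALSE])
  }, numeric(ncol(mat)))
  if (!is.matrix(eigengenes)) {
    eigengenes <- matrix(eigengenes, ncol = length(modules),
                         dimnames = list(colnames(mat), modules))
  }
  traits <- trait_vectors(se)
  mt <- module_trait(eigengenes, traits, config)
  dev_trait <- traits$time_order %||% traits$time_days
  gt <- gene_trait(se, dev_trait, assignment, config)
  hl <- hubs_and_links(a, assignment, linc_ids, config)
  list(adjacency = a, tom = tom, assignment = assignment,
       eigengenes = eigengenes, module_trait = mt, gene_trait = gt,
       connectivity = hl$connectivity, hubs = hl$hubs, edges = hl$edges,
       linc_hub_links = hl$linc_hub_links, config = config)
}
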