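#' Assemble the full run configuration
#'
#' Collects every threshold of the analysis in one document: the cascade
#' thresholds (200 bp, 100 aa, 500 bp flank, E <= 1e-5, 0.95 identity), the
#' expression rules (expressed at FPKM >= 1, moderate/high at FPKM >= 5,
#' tissue-specific at tau > 0.95), the network rules (|rho| >= 0.6,
#' p < 0.01, FDR < 0.05, hub percentile), the 10 kb neighbor window, and
#' the simulation scene.
#'
#' @param seed master seed; forwarded into the simulation config.
#' @param out_dir output directory for [run_all()] artifacts.
#' @param sim,pipeline,network,search component configurations.
#' @param tau_threshold,min_fpkm,hi_fpkm,neighbor_window profiling rules.
#' @return nested configuration list.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("lincscan_run_"),
                       sim = sim_config(seed = seed),
                       pipeline = pipeline_config(),
                       network = network_config(),
                       search = search_params(),
                       tau_threshold = 0.95, min_fpkm = 1, hi_fpkm = 5,
                       neighbor_window = 10000L) {
  list(seed = seed, out_dir = out_dir, sim = sim, pipeline = pipeline,
       network = network, search = search, tau_threshold = tau_threshold,
       min_fpkm = min_fpkm, hi_fpkm = hi_fpkm,
       neighbor_window = neighbor_window)
}

#' Write / read a run configuration as YAML
#'
#' Round-trip stable; unknown keys are rejected on read.
#' @param config from [run_config()].
#' @param path YAML path.
#' @return the path / the configuration.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  template <- run_config()
  unknown <- setdiff(names(raw), names(template))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  for (sec in c("sim", "pipeline", "network", "search")) {
    if (!is.null(raw[[sec]])) {
      bad <- setdiff(names(raw[[sec]]), names(template[[sec]]))
      if (length(bad)) {
        stop("unknown keys in ", sec, ": ", paste(bad, collapse = ", "))
      }
    }
  }
  merged <- utils::modifyList(template, raw)
  merged$sim <- do.call(sim_config, raw$sim %||% list())
  merged
}

#' Run the complete analysis on a simulated scene
#'
#' simulate -> identify -> conserve -> profile -> network -> enrich. All
#' inputs and outputs are written under `config$out_dir` (standard
#' GTF/FASTA/BED/TSV plus a machine-readable `summary.json` of headline
#' counts). The run is fully deterministic given the seed.
#'
#' @param config see [run_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the scene, truth, pipeline result,
#'   conservation/profiles/network/enrichment tables, the summary list and
#'   the output directory.
#' @export
run_all <- function(config = run_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  out <- config$out_dir
  dir.create(file.path(out, "inputs"), recursive = TRUE, showWarnings = FALSE)

  say("simulate: planting scene (seed ", config$sim$seed, ")")
  scene <- simulate_genome(config$sim)
  expr <- simulate_expression(scene$truth, config$sim)
  truth <- expr$truth
  terms <- simulate_go_terms(truth, config$sim)

  Biostrings::writeXStringSet(scene$genome,
                              file.path(out, "inputs", "genome.fa"))
  write_genes_gtf(scene$annotation, file.path(out, "inputs",
                                              "annotation.gtf"))
  write_transcripts_gtf(scene$assembly, file.path(out, "inputs",
                                                  "assembly.gtf"))
  Biostrings::writeXStringSet(scene$housekeeping,
                              file.path(out, "inputs", "housekeeping.fa"))
  for (sp in names(scene$subjects)) {
    Biostrings::writeXStringSet(scene$subjects[[sp]],
                                file.path(out, "inputs",
                                          paste0(sp, ".fa")))
  }
  write_expression_table(expr$tissue,
                         file.path(out, "inputs", "tissue_fpkm.tsv"),
                         file.path(out, "inputs", "tissue_meta.tsv"))
  write_expression_table(expr$development,
                         file.path(out, "inputs", "development_fpkm.tsv"),
                         file.path(out, "inputs", "development_meta.tsv"))
  utils::write.table(terms$term_map, file.path(out, "inputs", "terms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("identify: running the filter cascade")
  res <- run_pipeline(scene$assembly, scene$genome, scene$annotation,
                      scene$housekeeping, config$pipeline)
  check_filter_report(res$report)
  catalog_ids <- names(res$catalog)
  write_transcripts_gtf(res$catalog, file.path(out, "catalog.gtf"))
  Biostrings::writeXStringSet(res$sequences, file.path(out, "catalog.fa"))
  write_spans_bed(res$catalog, file.path(out, "catalog.bed"))
  utils::write.table(report_counts(res$report),
                     file.path(out, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("conserve: homology search against ", length(scene$subjects),
      " subject genomes")
  cons <- conservation_summary(res$sequences, scene$subjects, config$search)
  utils::write.table(cons$counts, file.path(out, "conservation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("profile: tissue/stage expression")
  tissue_se <- expr$tissue
  linc_rows <- intersect(rownames(tissue_se), catalog_ids)
  mrna_rows <- rownames(tissue_se)[
    SummarizedExperiment::rowData(tissue_se)$kind == "mRNA"]
  tissue_lincs <- tissue_se[linc_rows, ]
  expressed_lincs <- expressed_set(tissue_lincs, config$min_fpkm)
  tsp <- tissue_specific(tissue_lincs, config$tau_threshold,
                         config$min_fpkm)
  utils::write.table(tsp$results, file.path(out, "tau_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tsp$per_tissue_counts,
                     file.path(out, "tissue_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  tmat <- SummarizedExperiment::assay(tissue_se, "fpkm")
  kde <- density_compare(as.numeric(tmat[expressed_lincs, , drop = FALSE]),
                         as.numeric(tmat[expressed_set(
                           tissue_se[mrna_rows, ], config$min_fpkm), ,
                           drop = FALSE]))
  utils::write.table(kde$curves, file.path(out, "kde_curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  dev_se <- expr$development
  dev_lincs <- dev_se[intersect(rownames(dev_se), catalog_ids), ]
  stage_calls <- stage_specific(dev_lincs, config$min_fpkm)
  utils::write.table(stage_calls, file.path(out, "stage_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_names <- unique(SummarizedExperiment::colData(dev_se)$stage)
  settle <- settlement_contrast(dev_lincs,
                                truth$settlement_stages[["eyed"]],
                                truth$settlement_stages[["spat"]],
                                config$hi_fpkm, config$min_fpkm)

  nb <- neighbor_distances(res$catalog, scene$annotation,
                           config$neighbor_window)
  utils::write.table(nb$results, file.path(out, "neighbors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("network: weighted co-expression over ", ncol(dev_se), " time points")
  net <- build_network(dev_se, linc_ids = catalog_ids, config$network)
  utils::write.table(net$assignment, file.path(out, "modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net$module_trait, file.path(out, "module_trait.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net$gene_trait, file.path(out, "gene_trait.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net$hubs, file.path(out, "hubs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_edge_list(net$edges, file.path(out, "edges.tsv"))

  say("enrich: flagged-module GO enrichment")
  flagged <- unique(net$module_trait$module[net$module_trait$flagged])
  enr <- do.call(rbind, c(lapply(flagged, function(mlab) {
    members <- net$assignment$feature_id[net$assignment$module == mlab]
    gene_set <- intersect(members, truth$coding_gene_ids)
    if (length(gene_set) < 2L) return(NULL)
    e <- go_enrich(gene_set, truth$coding_gene_ids, terms$term_map)
    if (nrow(e)) cbind(module = mlab, e) else NULL
  }), list(make.row.names = FALSE)))
  if (is.null(enr)) {
    enr <- data.frame(module = character(), term = character(),
                      p = numeric())
  }
  utils::write.table(enr, file.path(out, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  lengths_bp <- transcript_lengths(res$catalog)
  n_exons <- lengths(res$catalog)
  per_species <- vapply(cons$per_species_conserved, length, integer(1))
  summary <- list(
    seed = config$seed,
    n_input_transcripts = length(scene$assembly),
    catalog_size = length(catalog_ids),
    mean_linc_length_bp = round(mean(lengths_bp), 1),
    pct_single_exon = round(100 * mean(n_exons == 1L), 1),
    pct_within_10kb = round(100 * nb$fraction_within, 1),
    conserved_per_species = as.list(per_species),
    n_conserved_all_species = length(cons$intersection_all),
    n_expressed_tissue_lincs = length(expressed_lincs),
    n_tissue_specific = sum(tsp$results$specific),
    tissue_specific_counts = stats::setNames(
      as.list(tsp$per_tissue_counts$n_specific),
      tsp$per_tissue_counts$tissue),
    ks_D = round(kde$D, 4),
    ks_p = kde$p_value,
    n_stage_specific = sum(!is.na(stage_calls$specific_stage)),
    n_settlement_eyed_only = length(settle$on_in_a_off_in_b),
    n_settlement_spat_only = length(settle$on_in_b_off_in_a),
    n_modules = length(setdiff(unique(net$assignment$module), "grey")),
    flagged_modules = as.list(flagged),
    n_hub_genes = nrow(net$hubs),
    n_linc_hub_links = length(unique(net$linc_hub_links$linc_id)),
    n_enriched_terms_raw = sum(enr$p < 0.05, na.rm = TRUE))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", out)
  invisible(list(scene = scene, truth = truth, expression = expr,
                 pipeline = res, conservation = cons,
                 tissue_specificity = tsp, stage_calls = stage_calls,
                 settlement = settle, kde = kde, neighbors = nb,
                 network = net, enrichment = enr, summary = summary,
                 out_dir = out))
}
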