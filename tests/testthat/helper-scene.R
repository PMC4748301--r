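# Shared simulated scenes, built once per test run.

.scene_cache <- new.env(parent = emptyenv())

small_sim_config <- function() {
  sim_config(seed = 7L, n_coding_genes = 60L, n_linc_loci = 12L,
             n_decoys_per_class = 4L,
             module_spec = list(list(size = 12L, sign = 1),
                                list(size = 12L, sign = -1)),
             lincs_per_module = 3L, n_tissue_specific = 6L,
             n_stage_specific = 2L, n_settlement = c(1L, 1L),
             n_conserved = 5L, subject_genome_length = 20000L)
}

get_small_scene <- function() {
  if (is.null(.scene_cache$scene)) {
    .scene_cache$scene <- simulate_genome(small_sim_config())
  }
  .scene_cache$scene
}

get_small_expr <- function() {
  if (is.null(.scene_cache$expr)) {
    .scene_cache$expr <- simulate_expression(get_small_scene()$truth,
                                             small_sim_config())
  }
  .scene_cache$expr
}

get_small_pipeline <- function() {
  if (is.null(.scene_cache$pipe)) {
    sc <- get_small_scene()
    .scene_cache$pipe <- run_pipeline(sc$assembly, sc$genome, sc$annotation,
                                      sc$housekeeping)
  }
  .scene_cache$pipe
}

small_network_config <- function() network_config(min_module_size = 8L)

get_small_network <- function() {
  if (is.null(.scene_cache$net)) {
    ex <- get_small_expr()
    .scene_cache$net <- build_network(
      ex$development, linc_ids = ex$truth$planted_linc_ids,
      config = small_network_config())
  }
  .scene_cache$net
}

# full default study scene, used by the acceptance-style tests
get_default_run <- function() {
  if (is.null(.scene_cache$run)) {
    .scene_cache$run <- run_all(
      run_config(seed = 1L,
                 out_dir = file.path(tempdir(), "lincscan_accept_a")),
      quiet = TRUE)
  }
  .scene_cache$run
}
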