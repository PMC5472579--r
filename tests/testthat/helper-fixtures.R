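# Shared fixtures: a scaled-down simulation config for fast tests and a
# cached default-scale dataset reused by the planted-recovery tests.

small_config <- function(seed = 7, ...) {
  args <- list(n_mirs = 80, n_mrna_probes = 260, n_genes = 240,
               n_exclusive_mirs = 5, n_exclusive_absent_db = 1,
               n_activated_mirs = 6, n_planted_targets_per_mir = 12,
               n_down_pool = 50, n_up_pool = 50, n_act_pool = 25,
               n_decoy_targets_per_mir = 10, n_decoy_mirs = 25,
               n_decoy_targets_per_decoy_mir = 12,
               n_pathways = 4, pathway_size = 20, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# default-scale dataset + pipeline run, built once per test session
default_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_pipeline(pipeline_config(seed = 101), quiet = TRUE)
    cache
  }
})

# toy expression matrix helper
toy_expr <- function(values, groups, ...) {
  expr_matrix(values, groups = groups, ...)
}
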