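# End-to-end orchestration: (optionally simulated) inputs -> normalization
# -> moderated-t differential expression -> detection-call exclusivity and
# Venn logic -> target mapping -> enrichment, with a machine-readable run
# report.

#' Pipeline configuration
#'
#' @param simulate `NULL`, or a list of [sim_config()] arguments; when set
#'   the pipeline generates its inputs.
#' @param input_dir directory of dataset files (see [write_dataset()]);
#'   required when `simulate` is `NULL`.
#' @param alpha adjusted-p cutoff for differential expression.
#' @param exclusivity_policy `"all_all"` or `"all_any"` (see
#'   [exclusive_mirs()]).
#' @param calls_policy probe-to-feature call collapse policy (`"any"` or
#'   `"all"`).
#' @param enrichment_stat `"ease"` or `"fisher"`.
#' @param background `"measured_genes"` or `"db_genes"`.
#' @param log2_offset offset for the log2 transform after normalization.
#' @param seed integer seed forwarded to the simulator.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulate = list(), input_dir = NULL,
                            alpha = 0.05,
                            exclusivity_policy = c("all_all", "all_any"),
                            calls_policy = c("any", "all"),
                            enrichment_stat = c("ease", "fisher"),
                            background = c("measured_genes", "db_genes"),
                            log2_offset = 1, seed = 1L) {
  cfg <- list(simulate = simulate, input_dir = input_dir, alpha = alpha,
              exclusivity_policy = match.arg(exclusivity_policy),
              calls_policy = match.arg(calls_policy),
              enrichment_stat = match.arg(enrichment_stat),
              background = match.arg(background),
              log2_offset = log2_offset, seed = as.integer(seed))
  if (is.null(cfg$simulate) && is.null(cfg$input_dir))
    stop("configuration error: need either a `simulate` block or `input_dir`",
         call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, raw)
}

#' Run the full miRNA/mRNA integration pipeline
#'
#' Stages: simulate (optional) -> quantile normalization + log2 +
#' replicate-probe averaging -> sample clustering -> moderated-t
#' differential expression (miR at feature level, mRNA at probe level) ->
#' detection-call exclusivity + Venn partitions + cross-check -> target
#' mapping of the down- and up-regulated universes -> pathway enrichment
#' of the targeted downregulated genes. Deterministic given the seed.
#'
#' @param config a [pipeline_config()], or path to a YAML file.
#' @param out_dir optional directory; when given, per-stage TSV/JSON
#'   outputs and `report.json` are written there.
#' @param quiet suppress per-stage progress messages.
#' @return Object of class `"treg_report"`: all stage results plus a
#'   JSON-serializable `$report` summary.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[tregmir] ", sprintf(...))

  if (!is.null(config$simulate)) {
    args <- config$simulate
    if (is.null(args$seed)) args$seed <- config$seed
    ds <- simulate_treg_arrays(do.call(sim_config, args))
    say("simulated dataset (seed %d)", args$seed)
  } else {
    ds <- read_dataset(config$input_dir)
    say("loaded dataset from %s", config$input_dir)
  }

  # -- preprocess ---------------------------------------------------------
  mir_feat <- average_replicate_probes(
    log2_transform(quantile_normalize(ds$mir_matrix), config$log2_offset))
  mrna_log <- log2_transform(quantile_normalize(ds$mrna_matrix),
                             config$log2_offset)
  calls_feat <- collapse_calls(ds$mir_calls, policy = config$calls_policy)
  clust <- cluster_samples(mir_feat, metric = "spearman",
                           linkage = "average", k = 3)
  say("preprocessed: %d miRs, %d mRNA probes", nrow(mir_feat$values),
      nrow(mrna_log$values))

  # -- differential expression -------------------------------------------
  mir_fit <- modt_fit(mir_feat)
  mrna_fit <- modt_fit(mrna_log)
  mir_sets <- de_sets(mir_fit, alpha = config$alpha)
  mrna_sets <- de_sets(mrna_fit, alpha = config$alpha)
  say("DE: %d miRs, %d mRNA probes significant in any contrast",
      length(mir_sets$union), length(mrna_sets$union))

  # -- set logic ----------------------------------------------------------
  excl <- exclusive_mirs(calls_feat, policy = config$exclusivity_policy)
  venn_up <- venn3(mir_sets$per_contrast$tgf_vs_naive$up,
                   mir_sets$per_contrast$med_vs_naive$up,
                   mir_sets$per_contrast$tgf_vs_med$up,
                   names = c("tgf_vs_naive", "med_vs_naive", "tgf_vs_med"))
  venn_down <- venn3(mir_sets$per_contrast$tgf_vs_naive$down,
                     mir_sets$per_contrast$med_vs_naive$down,
                     mir_sets$per_contrast$tgf_vs_med$down,
                     names = c("tgf_vs_naive", "med_vs_naive", "tgf_vs_med"))
  cross <- cross_check_exclusive(mir_sets, excl)
  say("exclusivity: %d miRs exclusively detected", length(excl$mir_ids))

  # -- target mapping ------------------------------------------------------
  p2f <- mrna_log$probe_to_feature
  uni_down <- target_universe(mrna_sets, p2f, "down")
  uni_up <- target_universe(mrna_sets, p2f, "up")
  down_summary <- map_targets(excl$mir_ids, uni_down$genes, ds$target_db)
  up_summary <- map_targets(excl$mir_ids, uni_up$genes, ds$target_db)
  mult <- multiplicity_stats(down_summary)
  contrast <- coverage_contrast(down_summary, up_summary)
  say("targets: %d/%d down genes targeted (%.1f%%)",
      down_summary$n_targeted, down_summary$n_in_db,
      100 * down_summary$fraction_targeted)

  # -- enrichment ----------------------------------------------------------
  bg <- default_background(config$background, mrna = mrna_log,
                           db = ds$target_db)
  query <- intersect(down_summary$per_gene$gene, bg)
  enr <- enrich(query, bg, ds$gene_sets, stat = config$enrichment_stat)
  say("enrichment: top term %s (adj_p = %.3g)", enr$term[1], enr$adj_p[1])

  report <- list(
    version = as.character(utils::packageVersion("tregmir")),
    seed = config$seed,
    config = config[setdiff(names(config), "simulate")],
    n_mir_probes = nrow(ds$mir_matrix$values),
    n_mir_features = nrow(mir_feat$values),
    n_mrna_probes = nrow(mrna_log$values),
    n_samples = ncol(mir_feat$values),
    clustering_k3 = as.list(clust$clusters),
    de_mir = lapply(mir_sets$per_contrast, function(s)
      c(up = length(s$up), down = length(s$down))),
    de_mir_union = length(mir_sets$union),
    de_mrna = lapply(mrna_sets$per_contrast, function(s)
      c(up = length(s$up), down = length(s$down))),
    de_mrna_union = length(mrna_sets$union),
    venn_mir_up = as.list(venn_up$counts),
    venn_mir_down = as.list(venn_down$counts),
    exclusive_mir_count = length(excl$mir_ids),
    cross_check = as.list(cross$counts),
    down_universe_genes = length(uni_down$genes),
    up_universe_genes = length(uni_up$genes),
    down_in_db = down_summary$n_in_db,
    down_targeted = down_summary$n_targeted,
    down_fraction_targeted = down_summary$fraction_targeted,
    up_fraction_targeted = up_summary$fraction_targeted,
    multiplicity = mult,
    coverage_contrast = contrast[setdiff(names(contrast), "down_exceeds_up")],
    mirs_absent_from_db = down_summary$mirs_absent_from_db,
    enrichment_top = utils::head(
      enr[, c("term", "k", "K", "fold_enrichment", "p_value", "adj_p")], 5))

  res <- structure(list(
    dataset = ds, mir_feat = mir_feat, mrna_log = mrna_log,
    calls_feat = calls_feat, clustering = clust,
    mir_fit = mir_fit, mrna_fit = mrna_fit,
    mir_sets = mir_sets, mrna_sets = mrna_sets,
    exclusive = excl, venn_up = venn_up, venn_down = venn_down,
    cross_check = cross, down_universe = uni_down, up_universe = uni_up,
    down_summary = down_summary, up_summary = up_summary,
    enrichment = enr, report = report, config = config),
    class = "treg_report")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' @export
print.treg_report <- function(x, ...) {
  r <- x$report
  cat("tregmir pipeline run\n")
  cat(sprintf("  DE miRs (any contrast):   %d\n", r$de_mir_union))
  cat(sprintf("  DE mRNA probes (any):     %d\n", r$de_mrna_union))
  cat(sprintf("  exclusively detected miRs: %d\n", r$exclusive_mir_count))
  cat(sprintf("  down universe: %d genes, %d in db, %d targeted (%.1f%%)\n",
              r$down_universe_genes, r$down_in_db, r$down_targeted,
              100 * r$down_fraction_targeted))
  cat(sprintf("  up universe targeted fraction: %.1f%%\n",
              100 * r$up_fraction_targeted))
  cat(sprintf("  top enriched term: %s (adj_p = %.3g)\n",
              r$enrichment_top$term[1], r$enrichment_top$adj_p[1]))
  invisible(x)
}

#' Write per-stage pipeline outputs and the run report
#'
#' @param res a `"treg_report"` from [run_pipeline()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the output directory.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  stopifnot(inherits(res, "treg_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  for (ct in names(res$mir_fit$tables))
    wt(res$mir_fit$tables[[ct]], paste0("de_mir_", ct, ".tsv"))
  for (ct in names(res$mrna_fit$tables))
    wt(res$mrna_fit$tables[[ct]], paste0("de_mrna_", ct, ".tsv"))
  writeLines(res$exclusive$mir_ids,
             file.path(out_dir, "exclusive_mirs.txt"))
  jsonlite::write_json(
    list(up = res$venn_up$counts, down = res$venn_down$counts),
    file.path(out_dir, "venn_mir.json"), auto_unbox = TRUE, pretty = TRUE)
  wt(res$down_summary$per_gene, "targets_per_gene_down.tsv")
  wt(res$down_summary$per_mir, "targets_per_mir_down.tsv")
  wt(res$up_summary$per_gene, "targets_per_gene_up.tsv")
  wt(res$up_summary$per_mir, "targets_per_mir_up.tsv")
  wt(as.data.frame(res$enrichment), "enrichment_chart.tsv")
  jsonlite::write_json(res$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
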