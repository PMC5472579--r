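# Synthetic one-colour array generator with planted ground truth.
#
# Emulates the study design the pipeline expects: three conditions (naive,
# med = activation with IL-2 alone, tgf_atra = activation plus TGF-beta and
# all-trans retinoic acid), three donors shared across conditions (paired
# design), positive log-normal signals, replicated probes, per-sample binary
# detection calls, a planted set of miRs detected exclusively under
# tgf_atra, planted repression of their target genes, and a
# TargetScan-style site table with context++ scores.

#' Simulation configuration
#'
#' All magnitudes are on the log2 scale unless noted. The defaults define the
#' package's reference study conditions: an 851-miR platform, 2000 mRNA
#' probes over 1900 genes, three donors per condition, 30 miRs switched on
#' exclusively under TGF-beta/atRA, and -1.5 log2 units of planted repression
#' on their targets.
#'
#' @param n_mirs number of miRs on the simulated platform.
#' @param n_mrna_probes number of mRNA probes (>= `n_genes`; the surplus
#'   probes re-measure randomly chosen genes).
#' @param n_genes number of unique genes.
#' @param replicates_per_group donors per condition (shared across
#'   conditions: the design is paired).
#' @param n_exclusive_mirs miRs planted to be detected only in `tgf_atra`.
#' @param n_exclusive_absent_db how many of the exclusive miRs are left out
#'   of the simulated target database (emulating platform miRs missing from
#'   the prediction database).
#' @param n_activated_mirs miRs induced by activation in both `med` and
#'   `tgf_atra`.
#' @param n_tgf_up_mirs,n_tgf_down_mirs additional miRs induced or
#'   repressed in `tgf_atra` only (expressed and detected in every
#'   condition, unlike the exclusive set).
#' @param n_planted_targets_per_mir planted (repressed) target genes per
#'   exclusive miR, drawn from a shared repressed pool.
#' @param n_down_pool,n_up_pool genes repressed / induced in `tgf_atra` only.
#' @param n_act_pool genes induced, and (a second pool) repressed, by
#'   activation in both `med` and `tgf_atra`.
#' @param n_decoy_targets_per_mir random decoy target genes per exclusive miR
#'   (on top of the planted ones).
#' @param n_decoy_mirs,n_decoy_targets_per_decoy_mir non-exclusive miRs given
#'   random entries in the target database, and how many genes each gets.
#' @param repression_log2fc planted log2 fold change (negative) of target
#'   genes in `tgf_atra`.
#' @param activation_log2fc planted log2 fold change (positive) of the
#'   induced pools.
#' @param donor_sd,noise_sd donor-effect and residual noise standard
#'   deviations (log2 units).
#' @param baseline_log2_mean,baseline_log2_sd baseline gene abundance; the
#'   expressed miR component uses `baseline_log2_mean + 2` with
#'   `0.8 * baseline_log2_sd`.
#' @param mir_expressed_frac fraction of non-planted miRs drawn from the
#'   expressed (detected) abundance component.
#' @param detection_threshold log2 signal below which a probe is called
#'   undetected.
#' @param detection_margin half-gap (log2) between planted off- and on-state
#'   means of exclusive miRs and the detection threshold.
#' @param replicate_probe_copies printed probe copies per miR.
#' @param context_score_range range of the uniform distribution the per-site
#'   context++ scores are drawn from (both endpoints negative).
#' @param n_pathways,pathway_size random pathway gene sets emitted in the GMT
#'   file, in addition to one planted pathway enriched in repressed targets.
#' @param seed integer seed; the same config and seed yield byte-identical
#'   datasets.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_mirs = 851,
                       n_mrna_probes = 2000,
                       n_genes = 1900,
                       replicates_per_group = 3,
                       n_exclusive_mirs = 30,
                       n_exclusive_absent_db = 2,
                       n_activated_mirs = 20,
                       n_tgf_up_mirs = 20,
                       n_tgf_down_mirs = 20,
                       n_planted_targets_per_mir = 40,
                       n_down_pool = 300,
                       n_up_pool = 300,
                       n_act_pool = 150,
                       n_decoy_targets_per_mir = 25,
                       n_decoy_mirs = 300,
                       n_decoy_targets_per_decoy_mir = 30,
                       repression_log2fc = -1.5,
                       activation_log2fc = 1.5,
                       donor_sd = 0.3,
                       noise_sd = 0.4,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 1.5,
                       mir_expressed_frac = 0.6,
                       detection_threshold = 6,
                       detection_margin = 2.5,
                       replicate_probe_copies = 2,
                       context_score_range = c(-0.6, -0.05),
                       n_pathways = 10,
                       pathway_size = 50,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_mirs", "n_mrna_probes", "n_genes", "replicates_per_group",
              "n_planted_targets_per_mir", "replicate_probe_copies")
  for (nm in counts)
    if (cfg[[nm]] < 1) stop(nm, " must be >= 1", call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (cfg$repression_log2fc >= 0)
    stop("repression_log2fc must be negative", call. = FALSE)
  if (cfg$n_planted_targets_per_mir > cfg$n_genes)
    stop("planted targets per miR exceed the gene count", call. = FALSE)
  if (cfg$n_planted_targets_per_mir > cfg$n_down_pool)
    stop("planted targets per miR exceed the repressed pool", call. = FALSE)
  if (cfg$n_down_pool + cfg$n_up_pool + 2 * cfg$n_act_pool > cfg$n_genes)
    stop("planted gene pools exceed the gene count", call. = FALSE)
  if (cfg$n_mrna_probes < cfg$n_genes)
    stop("need at least one probe per gene", call. = FALSE)
  if (cfg$n_exclusive_mirs + cfg$n_activated_mirs + cfg$n_tgf_up_mirs +
        cfg$n_tgf_down_mirs + cfg$n_decoy_mirs > cfg$n_mirs)
    stop("planted + decoy miRs exceed n_mirs", call. = FALSE)
  if (cfg$n_exclusive_absent_db > cfg$n_exclusive_mirs)
    stop("n_exclusive_absent_db exceeds n_exclusive_mirs", call. = FALSE)
  if (any(cfg$context_score_range >= 0) || length(cfg$context_score_range) != 2)
    stop("context_score_range must be two negative numbers", call. = FALSE)
  cfg$groups <- c("naive", "med", "tgf_atra")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# run expr with the RNG seeded at `seed`, restoring the caller's RNG state
with_sim_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Generate a synthetic miRNA/mRNA array dataset with planted truth
#'
#' @param config a [sim_config()].
#' @return A list of class `"treg_dataset"` with elements:
#'   \describe{
#'     \item{mir_matrix}{[expr_matrix()] of linear-scale miR probe signals.}
#'     \item{mir_calls}{[detection_calls()] at the miR probe level.}
#'     \item{mrna_matrix}{[expr_matrix()] of linear-scale mRNA probe signals.}
#'     \item{target_db}{[target_db()] of simulated context++ sites.}
#'     \item{gene_sets}{named list of pathway gene sets.}
#'     \item{truth}{planted ground truth: `exclusive_mir_ids`,
#'       `planted_target_genes` (list miR -> genes), `per_gene_log2fc`
#'       (data.frame gene/contrast/log2fc for planted effects),
#'       `de_mirs_by_contrast`, `mirs_absent_from_db`, `planted_pathway`.}
#'     \item{config}{the config used.}
#'   }
#' @examples
#' ds <- simulate_treg_arrays(sim_config(n_mirs = 60, n_mrna_probes = 220,
#'   n_genes = 200, n_exclusive_mirs = 4, n_planted_targets_per_mir = 10,
#'   n_down_pool = 40, n_up_pool = 40, n_act_pool = 20, n_decoy_mirs = 20,
#'   seed = 7))
#' ds$mir_matrix
#' @export
simulate_treg_arrays <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, .simulate_impl(config))
}

.simulate_impl <- function(cfg) {
  groups <- cfg$groups
  nrep <- cfg$replicates_per_group
  donors <- paste0("d", seq_len(nrep))
  sample_ids <- as.vector(t(outer(groups, donors, paste, sep = "_")))
  sample_groups <- rep(groups, each = nrep)
  sample_donors <- rep(donors, times = length(groups))
  names(sample_groups) <- names(sample_donors) <- sample_ids
  ns <- length(sample_ids)

  mir_ids <- sprintf("hsa-miR-s%04d-5p", seq_len(cfg$n_mirs))
  idx <- sample.int(cfg$n_mirs,
                    cfg$n_exclusive_mirs + cfg$n_activated_mirs +
                      cfg$n_tgf_up_mirs + cfg$n_tgf_down_mirs +
                      cfg$n_decoy_mirs)
  take <- function(n, skip) mir_ids[idx[skip + seq_len(n)]]
  exclusive <- take(cfg$n_exclusive_mirs, 0)
  activated <- take(cfg$n_activated_mirs, cfg$n_exclusive_mirs)
  tgf_up <- take(cfg$n_tgf_up_mirs,
                 cfg$n_exclusive_mirs + cfg$n_activated_mirs)
  tgf_down <- take(cfg$n_tgf_down_mirs,
                   cfg$n_exclusive_mirs + cfg$n_activated_mirs +
                     cfg$n_tgf_up_mirs)
  decoy_mirs <- take(cfg$n_decoy_mirs,
                     cfg$n_exclusive_mirs + cfg$n_activated_mirs +
                       cfg$n_tgf_up_mirs + cfg$n_tgf_down_mirs)

  # baseline miR abundance: expressed / unexpressed mixture, with the planted
  # exclusive miRs forced to an off state below the detection threshold
  expressed <- stats::rbinom(cfg$n_mirs, 1, cfg$mir_expressed_frac) == 1
  mir_base <- ifelse(expressed,
                     stats::rnorm(cfg$n_mirs, cfg$baseline_log2_mean + 2,
                                  0.8 * cfg$baseline_log2_sd),
                     stats::rnorm(cfg$n_mirs, cfg$detection_threshold - 2.5, 0.5))
  names(mir_base) <- mir_ids
  mir_base[exclusive] <- cfg$detection_threshold - cfg$detection_margin
  # tgf-modulated (non-exclusive) miRs stay comfortably detected everywhere
  mir_base[c(tgf_up, tgf_down)] <-
    stats::rnorm(cfg$n_tgf_up_mirs + cfg$n_tgf_down_mirs,
                 cfg$baseline_log2_mean + 2.5, 0.5)

  # per-miR condition effect (log2), columns = groups
  mir_eff <- matrix(0, cfg$n_mirs, length(groups),
                    dimnames = list(mir_ids, groups))
  mir_eff[exclusive, "tgf_atra"] <- 2 * cfg$detection_margin
  mir_eff[activated, c("med", "tgf_atra")] <- cfg$activation_log2fc
  mir_eff[tgf_up, "tgf_atra"] <- cfg$activation_log2fc
  mir_eff[tgf_down, "tgf_atra"] <- -cfg$activation_log2fc

  mir_donor <- matrix(stats::rnorm(cfg$n_mirs * nrep, 0, cfg$donor_sd),
                      cfg$n_mirs, nrep, dimnames = list(mir_ids, donors))

  k <- cfg$replicate_probe_copies
  probe_ids <- as.vector(vapply(mir_ids, function(m)
    paste0(m, "_p", seq_len(k)), character(k)))
  probe_feature <- rep(mir_ids, each = k)
  names(probe_feature) <- probe_ids
  probe_offset <- stats::rnorm(length(probe_ids), 0, 0.15)

  mir_log2 <- matrix(0, length(probe_ids), ns,
                     dimnames = list(probe_ids, sample_ids))
  for (j in seq_len(ns)) {
    g <- sample_groups[j]; d <- sample_donors[j]
    mu <- mir_base[probe_feature] + mir_eff[probe_feature, g] +
      mir_donor[probe_feature, d] + probe_offset
    mir_log2[, j] <- mu + stats::rnorm(length(probe_ids), 0, cfg$noise_sd)
  }
  mir_matrix <- expr_matrix(2^mir_log2, groups = sample_groups,
                            probe_to_feature = probe_feature,
                            is_log2 = FALSE, donors = sample_donors)
  mir_calls <- detection_calls((mir_log2 > cfg$detection_threshold) + 0L,
                               groups = sample_groups,
                               probe_to_feature = probe_feature)

  # genes and planted effect pools
  gene_ids <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  pool_idx <- sample.int(cfg$n_genes,
                         cfg$n_down_pool + cfg$n_up_pool + 2 * cfg$n_act_pool)
  down_pool <- gene_ids[pool_idx[seq_len(cfg$n_down_pool)]]
  up_pool <- gene_ids[pool_idx[cfg$n_down_pool + seq_len(cfg$n_up_pool)]]
  act_up <- gene_ids[pool_idx[cfg$n_down_pool + cfg$n_up_pool +
                                seq_len(cfg$n_act_pool)]]
  act_down <- gene_ids[pool_idx[cfg$n_down_pool + cfg$n_up_pool +
                                  cfg$n_act_pool + seq_len(cfg$n_act_pool)]]

  gene_eff <- matrix(0, cfg$n_genes, length(groups),
                     dimnames = list(gene_ids, groups))
  gene_eff[down_pool, "tgf_atra"] <- cfg$repression_log2fc
  gene_eff[up_pool, "tgf_atra"] <- cfg$activation_log2fc
  gene_eff[act_up, c("med", "tgf_atra")] <- cfg$activation_log2fc
  gene_eff[act_down, c("med", "tgf_atra")] <- -cfg$activation_log2fc

  gene_base <- stats::rnorm(cfg$n_genes, cfg$baseline_log2_mean,
                            cfg$baseline_log2_sd)
  names(gene_base) <- gene_ids
  gene_donor <- matrix(stats::rnorm(cfg$n_genes * nrep, 0, cfg$donor_sd),
                       cfg$n_genes, nrep, dimnames = list(gene_ids, donors))

  extra <- cfg$n_mrna_probes - cfg$n_genes
  probe_gene <- c(gene_ids,
                  if (extra > 0) gene_ids[sample.int(cfg$n_genes, extra,
                                                     replace = TRUE)])
  mrna_probe_ids <- sprintf("mrna_p%05d", seq_len(cfg$n_mrna_probes))
  names(probe_gene) <- mrna_probe_ids
  mrna_offset <- stats::rnorm(cfg$n_mrna_probes, 0, 0.15)

  mrna_log2 <- matrix(0, cfg$n_mrna_probes, ns,
                      dimnames = list(mrna_probe_ids, sample_ids))
  for (j in seq_len(ns)) {
    g <- sample_groups[j]; d <- sample_donors[j]
    mu <- gene_base[probe_gene] + gene_eff[probe_gene, g] +
      gene_donor[probe_gene, d] + mrna_offset
    mrna_log2[, j] <- mu + stats::rnorm(cfg$n_mrna_probes, 0, cfg$noise_sd)
  }
  mrna_matrix <- expr_matrix(2^mrna_log2, groups = sample_groups,
                             probe_to_feature = probe_gene,
                             is_log2 = FALSE, donors = sample_donors)

  # target database: planted sites (exclusive miR -> repressed gene), decoy
  # sites of exclusive miRs on random genes, and decoy miRs on random genes
  absent_db <- exclusive[seq_len(cfg$n_exclusive_absent_db)]
  in_db_exclusive <- setdiff(exclusive, absent_db)
  planted <- stats::setNames(lapply(exclusive, function(m)
    sort(down_pool[sample.int(cfg$n_down_pool,
                              cfg$n_planted_targets_per_mir)])), exclusive)

  rows <- list()
  for (m in in_db_exclusive) {
    genes <- planted[[m]]
    n_sites <- 1L + stats::rbinom(length(genes), 1L, 0.3)
    decoys <- gene_ids[sample.int(cfg$n_genes, cfg$n_decoy_targets_per_mir)]
    decoys <- setdiff(decoys, genes)
    g_all <- c(rep(genes, n_sites), decoys)
    rows[[m]] <- data.frame(
      mir = m, gene_symbol = g_all,
      transcript_id = paste0(g_all, "-201"),
      context_score = stats::runif(length(g_all), cfg$context_score_range[1],
                                   cfg$context_score_range[2]),
      stringsAsFactors = FALSE)
  }
  for (m in decoy_mirs) {
    g_all <- gene_ids[sample.int(cfg$n_genes, cfg$n_decoy_targets_per_decoy_mir)]
    rows[[m]] <- data.frame(
      mir = m, gene_symbol = g_all,
      transcript_id = paste0(g_all, "-201"),
      context_score = stats::runif(length(g_all), cfg$context_score_range[1],
                                   cfg$context_score_range[2]),
      stringsAsFactors = FALSE)
  }
  db_df <- do.call(rbind, rows)
  rownames(db_df) <- NULL
  # site key: transcript + running site index within (mir, transcript)
  db_df$site_key <- paste0(db_df$transcript_id, ":s",
                           stats::ave(seq_len(nrow(db_df)),
                                      db_df$mir, db_df$transcript_id,
                                      FUN = seq_along))
  db <- target_db(db_df)

  # pathways: one planted set drawn from the repressed pool + random sets
  sets <- list(PW_PLANTED = sort(down_pool[sample.int(
    cfg$n_down_pool, min(cfg$pathway_size, cfg$n_down_pool))]))
  for (i in seq_len(cfg$n_pathways))
    sets[[sprintf("PW%03d", i)]] <-
      sort(gene_ids[sample.int(cfg$n_genes, cfg$pathway_size)])
  descriptions <- stats::setNames(
    c("planted repressed-target pathway",
      rep("random pathway", cfg$n_pathways)), names(sets))
  gene_sets <- structure(sets, descriptions = descriptions,
                         class = c("gene_sets", "list"))

  fc <- rbind(
    data.frame(gene = down_pool, contrast = "tgf_vs_naive",
               log2fc = cfg$repression_log2fc),
    data.frame(gene = down_pool, contrast = "tgf_vs_med",
               log2fc = cfg$repression_log2fc),
    data.frame(gene = up_pool, contrast = "tgf_vs_naive",
               log2fc = cfg$activation_log2fc),
    data.frame(gene = up_pool, contrast = "tgf_vs_med",
               log2fc = cfg$activation_log2fc),
    data.frame(gene = act_up, contrast = "tgf_vs_naive",
               log2fc = cfg$activation_log2fc),
    data.frame(gene = act_up, contrast = "med_vs_naive",
               log2fc = cfg$activation_log2fc),
    data.frame(gene = act_down, contrast = "tgf_vs_naive",
               log2fc = -cfg$activation_log2fc),
    data.frame(gene = act_down, contrast = "med_vs_naive",
               log2fc = -cfg$activation_log2fc))

  truth <- list(
    exclusive_mir_ids = sort(exclusive),
    planted_target_genes = planted,
    per_gene_log2fc = fc,
    de_mirs_by_contrast = list(
      tgf_vs_naive = sort(c(exclusive, activated, tgf_up, tgf_down)),
      tgf_vs_med = sort(c(exclusive, tgf_up, tgf_down)),
      med_vs_naive = sort(activated)),
    mirs_absent_from_db = sort(absent_db),
    planted_pathway = "PW_PLANTED")

  structure(list(mir_matrix = mir_matrix, mir_calls = mir_calls,
                 mrna_matrix = mrna_matrix, target_db = db,
                 gene_sets = gene_sets, truth = truth, config = cfg),
            class = "treg_dataset")
}

#' @export
print.treg_dataset <- function(x, ...) {
  cat("Synthetic iTreg array dataset\n")
  cat(sprintf("  miR probes : %d (%d miRs) x %d samples\n",
              nrow(x$mir_matrix$values),
              length(unique(x$mir_matrix$probe_to_feature)),
              ncol(x$mir_matrix$values)))
  cat(sprintf("  mRNA probes: %d (%d genes) x %d samples\n",
              nrow(x$mrna_matrix$values),
              length(unique(x$mrna_matrix$probe_to_feature)),
              ncol(x$mrna_matrix$values)))
  cat(sprintf("  target db  : %d sites, %d miRs, %d genes\n",
              nrow(x$target_db$records),
              length(unique(x$target_db$records$mir)),
              length(unique(x$target_db$records$gene_symbol))))
  cat(sprintf("  planted    : %d exclusive miRs, %d pathways\n",
              length(x$truth$exclusive_mir_ids), length(x$gene_sets)))
  invisible(x)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits `mir_signal.tsv`, `mrna_signal.tsv`, `mir_calls.tsv`, `samples.tsv`,
#' `targets.tsv`, `pathways.gmt` and `truth.json`; the TSVs round-trip
#' through the package readers losslessly.
#'
#' @param dataset a `"treg_dataset"` from [simulate_treg_arrays()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "treg_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  paths <- c(
    mir_signal = file.path(out_dir, "mir_signal.tsv"),
    mrna_signal = file.path(out_dir, "mrna_signal.tsv"),
    mir_calls = file.path(out_dir, "mir_calls.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    targets = file.path(out_dir, "targets.tsv"),
    pathways = file.path(out_dir, "pathways.gmt"),
    truth = file.path(out_dir, "truth.json"))
  write_signal_tsv(dataset$mir_matrix, paths["mir_signal"])
  write_signal_tsv(dataset$mrna_matrix, paths["mrna_signal"])
  write_signal_tsv(dataset$mir_calls, paths["mir_calls"])
  write_sample_sheet(dataset$mir_matrix, paths["samples"])
  utils::write.table(dataset$target_db$records[, c("mir", "gene_symbol",
                                                   "transcript_id",
                                                   "context_score")],
                     paths["targets"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(dataset$gene_sets, paths["pathways"])
  truth <- dataset$truth
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Read a dataset directory written by [write_dataset()]
#' @param dir directory containing the dataset files.
#' @return A list with the same elements as [simulate_treg_arrays()] output
#'   (without `config`).
#' @export
read_dataset <- function(dir) {
  samples <- read_sample_sheet(file.path(dir, "samples.tsv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  truth$planted_target_genes <- lapply(truth$planted_target_genes, unlist)
  structure(list(
    mir_matrix = read_signal_tsv(file.path(dir, "mir_signal.tsv"), samples),
    mir_calls = read_calls_tsv(file.path(dir, "mir_calls.tsv"), samples),
    mrna_matrix = read_signal_tsv(file.path(dir, "mrna_signal.tsv"), samples),
    target_db = load_targetscan(file.path(dir, "targets.tsv")),
    gene_sets = read_gmt(file.path(dir, "pathways.gmt")),
    truth = truth), class = "treg_dataset")
}
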