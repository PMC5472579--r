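# Predicted-target handling: parse a TargetScan-style site table with
# per-site context++ scores, normalize miR names between platform and
# database conventions, and compute per-gene targeting multiplicity and
# summed context++ scores, per-miR target counts, and the down- versus
# up-regulated coverage contrast.

#' Target database constructor
#'
#' @param records data.frame with columns `mir`, `gene_symbol`,
#'   `transcript_id`, `context_score`, and optionally `site_key` (generated
#'   from the transcript and row order when absent). Duplicate
#'   `(mir, site_key)` rows are dropped.
#' @return Object of class `"target_db"`: `records` plus the miR-to-gene
#'   and gene-to-miR indexes.
#' @export
target_db <- function(records) {
  need <- c("mir", "gene_symbol", "transcript_id", "context_score")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  records$mir_norm <- normalize_mir_name(records$mir)
  if (is.null(records$site_key))
    records$site_key <- paste0(records$transcript_id, ":s",
                               stats::ave(seq_len(nrow(records)),
                                          records$mir, records$transcript_id,
                                          FUN = seq_along))
  dup <- duplicated(records[, c("mir_norm", "site_key")])
  records <- records[!dup, , drop = FALSE]
  rownames(records) <- NULL
  structure(list(
    records = records,
    mir_to_genes = split(records$gene_symbol, records$mir_norm),
    gene_to_mirs = split(records$mir_norm, records$gene_symbol),
    n_deduplicated = sum(dup)),
    class = "target_db")
}

#' @export
print.target_db <- function(x, ...) {
  cat(sprintf("target_db: %d sites, %d miRs, %d genes (%d duplicates dropped)\n",
              nrow(x$records), length(x$mir_to_genes),
              length(x$gene_to_mirs), x$n_deduplicated))
  invisible(x)
}

#' Load a TargetScan-style predicted-targets file
#'
#' Accepts either the TargetScan release-7 "context++ scores" flat-file
#' header (columns `Gene Symbol`, `Transcript ID`, `miRNA`,
#' `context++ score`; extra columns tolerated) or the generic 4-column
#' dialect (`mir`, `gene_symbol`, `transcript_id`, `context_score`).
#' Rows with an empty or non-numeric score are dropped and counted.
#'
#' @param path tab-separated file.
#' @param dialect `"auto"` (default), `"targetscan"` or `"generic"`.
#' @return A [target_db()]; the number of dropped rows is available as
#'   `$n_dropped`.
#' @export
load_targetscan <- function(path, dialect = c("auto", "targetscan", "generic")) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ts_cols <- c(mir = "miRNA", gene_symbol = "Gene Symbol",
               transcript_id = "Transcript ID",
               context_score = "context++ score")
  gen_cols <- c(mir = "mir", gene_symbol = "gene_symbol",
                transcript_id = "transcript_id",
                context_score = "context_score")
  cols <- switch(dialect,
    targetscan = ts_cols,
    generic = gen_cols,
    auto = if (all(ts_cols %in% names(df))) ts_cols
           else if (all(gen_cols %in% names(df))) gen_cols
           else stop("unrecognized dialect; missing column(s): ",
                     paste(setdiff(gen_cols, names(df)), collapse = ", "),
                     call. = FALSE))
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  rec <- data.frame(mir = df[[cols["mir"]]],
                    gene_symbol = df[[cols["gene_symbol"]]],
                    transcript_id = df[[cols["transcript_id"]]],
                    context_score = suppressWarnings(
                      as.numeric(df[[cols["context_score"]]])),
                    stringsAsFactors = FALSE)
  ok <- is.finite(rec$context_score) & nzchar(rec$gene_symbol) &
    nzchar(rec$mir)
  db <- target_db(rec[ok, , drop = FALSE])
  db$n_dropped <- sum(!ok)
  db
}

#' Normalize a miR name for platform/database matching
#'
#' Strips a lowercase species prefix (e.g. `hsa-`), lowercases the
#' `miR`/`let` stem, and preserves the arm suffix, so that platform names
#' like `"miR-23a-5p"` match database names like `"hsa-miR-23a-5p"`.
#'
#' @param raw character vector of miR names.
#' @return Normalized ids (e.g. `"mir-23a-5p"`, `"let-7a-3p"`).
#' @export
normalize_mir_name <- function(raw) {
  x <- sub("^[a-z]{3}-(?=(?i:mir|let)-)", "", as.character(raw), perl = TRUE)
  sub("^((?i:mir|let))-", "\\L\\1-", x, perl = TRUE)
}

#' Map a miR set onto a gene universe through the target database
#'
#' Restricts the database to the query miRs and the universe genes found
#' in the database, then tabulates per-gene targeting multiplicity and
#' summed context++ scores (over all sites of all query miRs, across the
#' gene's transcripts), and per-miR target counts with mean context++
#' scores. Query miRs absent from the database are reported separately and
#' excluded from the per-miR averages.
#'
#' @param mirs character set of miR names (platform or database
#'   convention; normalized internally).
#' @param universe character set of gene symbols.
#' @param db a [target_db()].
#' @return Object of class `"target_summary"`: `per_gene` (gene,
#'   n_targeting_mirs, mir_list, total_context_score), `per_mir` (mir,
#'   n_targets, mean_context_score), `mirs_absent_from_db`, and the sizes
#'   `n_universe_genes`, `n_in_db`, `n_targeted`, `fraction_targeted`.
#' @export
map_targets <- function(mirs, universe, db) {
  stopifnot(inherits(db, "target_db"))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  universe <- unique(as.character(universe))
  mirs <- unique(as.character(mirs))
  mirs_norm <- normalize_mir_name(mirs)
  db_mirs <- unique(db$records$mir_norm)
  absent <- mirs[!(mirs_norm %in% db_mirs)]
  present_norm <- mirs_norm[mirs_norm %in% db_mirs]

  in_db_genes <- intersect(universe, unique(db$records$gene_symbol))
  rec <- db$records[db$records$mir_norm %in% present_norm &
                      db$records$gene_symbol %in% in_db_genes, ,
                    drop = FALSE]

  if (nrow(rec)) {
    pair <- unique(rec[, c("gene_symbol", "mir_norm")])
    n_mirs <- tapply(pair$mir_norm, pair$gene_symbol, length)
    mir_list <- tapply(pair$mir_norm, pair$gene_symbol,
                       function(v) paste(sort(v), collapse = ","))
    score <- tapply(rec$context_score, rec$gene_symbol, sum)
    genes <- sort(names(n_mirs))
    per_gene <- data.frame(gene = genes,
                           n_targeting_mirs = as.integer(n_mirs[genes]),
                           mir_list = as.character(mir_list[genes]),
                           total_context_score = as.numeric(score[genes]),
                           stringsAsFactors = FALSE, row.names = NULL)
    n_targets <- tapply(pair$gene_symbol, pair$mir_norm, length)
    mean_score <- tapply(rec$context_score, rec$mir_norm, mean)
    pm <- sort(unique(present_norm))
    per_mir <- data.frame(mir = pm,
                          n_targets = as.integer(ifelse(is.na(n_targets[pm]),
                                                        0L, n_targets[pm])),
                          mean_context_score = as.numeric(mean_score[pm]),
                          stringsAsFactors = FALSE, row.names = NULL)
  } else {
    per_gene <- data.frame(gene = character(0),
                           n_targeting_mirs = integer(0),
                           mir_list = character(0),
                           total_context_score = numeric(0))
    pm <- sort(unique(present_norm))
    per_mir <- data.frame(mir = pm,
                          n_targets = rep(0L, length(pm)),
                          mean_context_score = rep(NA_real_, length(pm)))
  }
  structure(list(per_gene = per_gene, per_mir = per_mir,
                 mirs_absent_from_db = sort(absent),
                 n_universe_genes = length(universe),
                 n_in_db = length(in_db_genes),
                 n_targeted = nrow(per_gene),
                 fraction_targeted = if (length(in_db_genes))
                   nrow(per_gene) / length(in_db_genes) else 0),
            class = "target_summary")
}

#' @export
print.target_summary <- function(x, ...) {
  cat(sprintf(
    "target_summary: %d universe genes, %d in db, %d targeted (%.1f%%)\n",
    x$n_universe_genes, x$n_in_db, x$n_targeted,
    100 * x$fraction_targeted))
  if (length(x$mirs_absent_from_db))
    cat("miRs absent from db:", paste(x$mirs_absent_from_db, collapse = ", "),
        "\n")
  invisible(x)
}

#' Targeting multiplicity statistics
#'
#' Fractions of genes targeted by at least 1 (relative to the genes found
#' in the database), at least 2, and at least 15 miRs (relative to the
#' targeted genes), plus the mean/min/max of targets per query miR.
#'
#' @param summary a [map_targets()] result.
#' @return Named list of the statistics.
#' @export
multiplicity_stats <- function(summary) {
  stopifnot(inherits(summary, "target_summary"))
  n <- summary$per_gene$n_targeting_mirs
  nt <- summary$per_mir$n_targets
  list(frac_ge1 = if (summary$n_in_db) summary$n_targeted / summary$n_in_db
                  else 0,
       frac_ge2 = if (length(n)) mean(n >= 2) else 0,
       frac_ge15 = if (length(n)) mean(n >= 15) else 0,
       targets_per_mir_mean = if (length(nt)) mean(nt) else NA_real_,
       targets_per_mir_min = if (length(nt)) min(nt) else NA_real_,
       targets_per_mir_max = if (length(nt)) max(nt) else NA_real_)
}

#' Down- versus up-regulated coverage contrast
#'
#' Compares how heavily the downregulated and upregulated gene universes
#' are targeted by the same miR set: targeted fractions, mean targets per
#' miR, their differences, and whether the expected direction
#' (down > up under planted repression) holds.
#'
#' @param down,up [map_targets()] summaries computed with the same miR set
#'   over the two universes.
#' @return Named list of the two fractions, per-miR means, differences,
#'   and the logical `down_exceeds_up`.
#' @export
coverage_contrast <- function(down, up) {
  stopifnot(inherits(down, "target_summary"), inherits(up, "target_summary"))
  md <- multiplicity_stats(down); mu <- multiplicity_stats(up)
  list(down_fraction = down$fraction_targeted,
       up_fraction = up$fraction_targeted,
       down_targets_per_mir = md$targets_per_mir_mean,
       up_targets_per_mir = mu$targets_per_mir_mean,
       fraction_diff = down$fraction_targeted - up$fraction_targeted,
       targets_per_mir_diff =
         md$targets_per_mir_mean - mu$targets_per_mir_mean,
       down_exceeds_up =
         down$fraction_targeted > up$fraction_targeted)
}
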