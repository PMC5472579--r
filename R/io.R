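# Readers and writers for the pipeline's plain-text interchange formats:
# signal/call TSVs (feature ids in column 1, sample-id header), a sample
# sheet, GMT gene sets, and the ground-truth JSON of the simulator.

#' Write a signal (or call) matrix as TSV
#'
#' First column `probe_id`, optional second column `feature_id`, then one
#' column per sample.
#'
#' @param x an [expr_matrix()] or [detection_calls()] object.
#' @param path output file path.
#' @export
write_signal_tsv <- function(x, path) {
  m <- if (inherits(x, "detection_calls")) x$calls else x$values
  df <- data.frame(probe_id = rownames(m),
                   feature_id = unname(x$probe_to_feature),
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the sample sheet (sample_id, group, donor) as TSV
#' @param x an [expr_matrix()] or [detection_calls()] object.
#' @param path output file path.
#' @export
write_sample_sheet <- function(x, path) {
  donors <- x$donors
  if (is.null(donors)) donors <- rep(NA_character_, length(x$groups))
  df <- data.frame(sample_id = names(x$groups), group = unname(x$groups),
                   donor = unname(donors), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet TSV
#' @param path file with columns sample_id, group and optionally donor.
#' @return data.frame with columns sample_id, group, donor.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(df$donor)) df$donor <- NA_character_
  df
}

#' Read a signal matrix TSV
#'
#' @param path TSV written by [write_signal_tsv()] (probe_id, optional
#'   feature_id, one column per sample).
#' @param samples sample sheet data.frame from [read_sample_sheet()].
#' @param is_log2 scale flag for the values read.
#' @return an [expr_matrix()].
#' @export
read_signal_tsv <- function(path, samples, is_log2 = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id")
    stop("first column of ", path, " must be probe_id", call. = FALSE)
  p2f <- NULL
  if (identical(names(df)[2], "feature_id")) {
    p2f <- stats::setNames(df$feature_id, df$probe_id)
    vals <- as.matrix(df[, -(1:2), drop = FALSE])
  } else {
    vals <- as.matrix(df[, -1, drop = FALSE])
  }
  rownames(vals) <- df$probe_id
  vals <- vals[, samples$sample_id, drop = FALSE]
  expr_matrix(vals, groups = stats::setNames(samples$group, samples$sample_id),
              probe_to_feature = p2f, is_log2 = is_log2,
              donors = stats::setNames(samples$donor, samples$sample_id))
}

#' Read a detection-call matrix TSV
#' @inheritParams read_signal_tsv
#' @return a [detection_calls()] object.
#' @export
read_calls_tsv <- function(path, samples) {
  em <- read_signal_tsv(path, samples, is_log2 = TRUE) # scale flag irrelevant
  detection_calls(em$values, groups = em$groups,
                  probe_to_feature = em$probe_to_feature)
}

#' Read gene sets in GMT format
#'
#' One set per line: term id, description, then member gene ids,
#' tab-separated.
#'
#' @param path GMT file.
#' @return a named list of character vectors (class `"gene_sets"`), with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line (need term, description, >=1 gene): ",
           substr(ln, 1, 40), call. = FALSE)
    sets[[parts[1]]] <- unique(parts[-(1:2)])
    desc[parts[1]] <- parts[2]
  }
  structure(sets, descriptions = desc, class = c("gene_sets", "list"))
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional named character vector of descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && !is.na(descriptions[nm]))
      descriptions[nm] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
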