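#' Expression matrix container
#'
#' Lightweight container for a one-colour array signal matrix: a numeric
#' probes-by-samples matrix together with the probe-to-feature map (miR name
#' or gene symbol per probe), the sample-to-group assignment, and a flag
#' recording whether values are on the log2 scale.
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param groups character or factor vector of condition labels, one per
#'   sample, named by sample id or in column order. Levels are expected to be
#'   among `"naive"`, `"med"`, `"tgf_atra"` but arbitrary labels are allowed.
#' @param probe_to_feature named character vector mapping probe id to feature
#'   id; defaults to the identity map (each probe is its own feature).
#' @param is_log2 logical flag: are `values` already log2-transformed?
#' @param donors optional vector of donor (replicate) labels per sample.
#'
#' @return An object of class `"expr_matrix"`: a list with elements
#'   `values`, `groups`, `probe_to_feature`, `is_log2`, `donors`.
#' @examples
#' m <- matrix(2^rnorm(12, 8), 4, 3,
#'             dimnames = list(paste0("p", 1:4), paste0("s", 1:3)))
#' em <- expr_matrix(m, groups = c("naive", "med", "tgf_atra"))
#' dim(em)
#' @export
expr_matrix <- function(values, groups, probe_to_feature = NULL,
                        is_log2 = FALSE, donors = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("probe_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample_", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids", call. = FALSE)
  if (any(!is.finite(values)))
    stop("`values` must be finite", call. = FALSE)
  if (!is_log2 && any(values <= 0))
    stop("linear-scale values must be positive", call. = FALSE)
  groups <- as.character(groups)
  if (length(groups) != ncol(values))
    stop("`groups` must have one label per sample", call. = FALSE)
  if (!is.null(names(groups))) groups <- groups[colnames(values)]
  names(groups) <- colnames(values)
  if (anyNA(groups)) stop("every sample must have a group", call. = FALSE)
  if (is.null(probe_to_feature)) {
    probe_to_feature <- stats::setNames(rownames(values), rownames(values))
  } else {
    probe_to_feature <- probe_to_feature[rownames(values)]
    if (anyNA(probe_to_feature))
      stop("`probe_to_feature` must cover every probe", call. = FALSE)
  }
  if (!is.null(donors)) {
    donors <- as.character(donors)
    if (length(donors) != ncol(values))
      stop("`donors` must have one label per sample", call. = FALSE)
    names(donors) <- colnames(values)
  }
  structure(list(values = values, groups = groups,
                 probe_to_feature = probe_to_feature,
                 is_log2 = isTRUE(is_log2), donors = donors),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_log2) "log2" else "linear"))
  cat("groups:", paste(sprintf("%s=%d", names(table(x$groups)),
                               table(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' Detection-call container
#'
#' Binary probes-by-samples matrix of per-sample detection flags
#' (the Agilent `gIsGeneDetected` analogue: 1 = signal reliably above
#' background in that sample, 0 = not detected).
#'
#' @param calls binary (0/1) matrix with probe rownames and sample colnames.
#' @param groups condition label per sample (see [expr_matrix()]).
#' @param probe_to_feature named character vector, probe id to feature id.
#' @return An object of class `"detection_calls"`.
#' @export
detection_calls <- function(calls, groups, probe_to_feature = NULL) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix", call. = FALSE)
  if (!all(calls %in% c(0, 1)))
    stop("calls must be 0/1", call. = FALSE)
  storage.mode(calls) <- "integer"
  em <- expr_matrix(matrix(1, nrow(calls), ncol(calls),
                           dimnames = dimnames(calls)),
                    groups = groups, probe_to_feature = probe_to_feature)
  structure(list(calls = calls, groups = em$groups,
                 probe_to_feature = em$probe_to_feature),
            class = "detection_calls")
}

#' @export
dim.detection_calls <- function(x) dim(x$calls)

#' @export
print.detection_calls <- function(x, ...) {
  cat(sprintf("detection_calls: %d probes x %d samples, %.1f%% detected\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(x$calls)))
  invisible(x)
}

# internal: check group labels present
.check_groups <- function(groups, required = c("naive", "med", "tgf_atra")) {
  missing <- setdiff(required, unique(groups))
  if (length(missing))
    stop("missing group(s): ", paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
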