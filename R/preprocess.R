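# Normalization and probe-level collapsing for one-colour arrays:
# quantile normalization across samples, log2 transform, mean-averaging of
# replicate probes, collapsing of probe-level detection calls, and
# unsupervised hierarchical clustering of the sample profiles.

#' Quantile normalization
#'
#' Forces the empirical signal distribution of every sample to be identical:
#' the reference distribution is the row mean of the column-sorted matrix,
#' and each value is replaced by the reference value at its within-column
#' rank. Tied values within a column receive the mean of the reference
#' values at their occupied ranks.
#'
#' @param m an [expr_matrix()] (either scale) with at least 2 samples.
#' @return An [expr_matrix()] with normalized values; ids and metadata
#'   preserved.
#' @examples
#' em <- expr_matrix(cbind(s1 = c(1, 3), s2 = c(2, 4)),
#'                   groups = c("naive", "med"))
#' quantile_normalize(em)$values  # both columns become (1.5, 3.5)
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  x <- m$values
  if (ncol(x) < 2) stop("need >= 2 samples", call. = FALSE)
  if (anyNA(x)) stop("NaN/NA in input", call. = FALSE)
  ref <- rowMeans(apply(x, 2, sort))
  n <- nrow(x)
  out <- apply(x, 2, function(col) {
    o <- order(col)
    v <- col[o]
    # runs of tied values share the mean of the reference values at the
    # ranks they jointly occupy
    grp <- cumsum(c(TRUE, v[-1] != v[-n]))
    means <- tapply(ref, grp, mean)
    res <- numeric(n)
    res[o] <- means[grp]
    res
  })
  dimnames(out) <- dimnames(x)
  m$values <- out
  m
}

#' Log2 transform
#'
#' @param m a linear-scale [expr_matrix()].
#' @param offset added before taking logs (default 1, guarding small
#'   signals).
#' @return The matrix with `values = log2(values + offset)` and
#'   `is_log2 = TRUE`.
#' @export
log2_transform <- function(m, offset = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$is_log2) stop("matrix is already log2", call. = FALSE)
  if (any(m$values + offset <= 0))
    stop("nonpositive value after offset", call. = FALSE)
  m$values <- log2(m$values + offset)
  m$is_log2 <- TRUE
  m
}

#' Mean-average replicate probes to one row per feature
#'
#' Collapses the probe-level matrix to feature level (miR name or gene
#' symbol) by the arithmetic mean over each feature's probes, per sample.
#' Output features are in lexicographic order.
#'
#' @param m an [expr_matrix()] with a probe-to-feature map.
#' @return An [expr_matrix()] with one row per feature (the probe map
#'   becomes the identity).
#' @export
average_replicate_probes <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  f <- factor(m$probe_to_feature, levels = sort(unique(m$probe_to_feature)))
  out <- rowsum(m$values, f) / as.vector(table(f))
  expr_matrix(out, groups = m$groups, is_log2 = m$is_log2, donors = m$donors)
}

#' Collapse probe-level detection calls to feature level
#'
#' @param c a probe-level [detection_calls()] object.
#' @param policy `"any"` (default; feature detected if any of its probes is)
#'   or `"all"` (all probes must be detected).
#' @return A feature-level [detection_calls()] object.
#' @export
collapse_calls <- function(c, policy = c("any", "all")) {
  stopifnot(inherits(c, "detection_calls"))
  policy <- match.arg(policy)
  f <- factor(c$probe_to_feature, levels = sort(unique(c$probe_to_feature)))
  sums <- rowsum(c$calls, f)
  n <- as.vector(table(f))
  out <- if (policy == "any") (sums > 0) + 0L else (sums == n) + 0L
  detection_calls(out, groups = c$groups)
}

#' Unsupervised hierarchical clustering of sample profiles
#'
#' Distance between samples is `1 - Spearman rank correlation` of their
#' full expression columns (default) or the Euclidean norm; agglomeration by
#' average (default) or complete linkage. A constant column under the
#' Spearman metric has undefined correlation; its distances are set to 1
#' with a warning.
#'
#' @param m an [expr_matrix()] with at least 3 samples.
#' @param metric `"spearman"` or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @param k number of flat clusters to cut (default 3, one per condition).
#' @return A list with `hclust` (the merge tree), `dist` (the sample
#'   distance matrix), `clusters` (flat labels at `k`), and `groups` (the
#'   sample condition labels, for external comparison).
#' @export
cluster_samples <- function(m, metric = c("spearman", "euclidean"),
                            linkage = c("average", "complete"), k = 3) {
  stopifnot(inherits(m, "expr_matrix"))
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  x <- m$values
  if (ncol(x) < 3) stop("need >= 3 samples", call. = FALSE)
  if (metric == "spearman") {
    const <- apply(x, 2, function(col) max(col) == min(col))
    rho <- suppressWarnings(stats::cor(x, method = "spearman"))
    d <- 1 - rho
    if (any(const)) {
      warning("constant sample column(s) under spearman; distance set to 1")
      d[const, ] <- 1; d[, const] <- 1
    }
    diag(d) <- 0
    d <- stats::as.dist(d)
  } else {
    d <- stats::dist(t(x))
  }
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, dist = as.matrix(d),
       clusters = stats::cutree(hc, k = k), groups = m$groups)
}
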