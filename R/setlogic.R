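# Detection-call exclusivity filtering and three-set Venn partitioning.

#' miRs detected exclusively under TGF-beta/atRA
#'
#' Applies the stringent detection-call rule: a miR qualifies when it is
#' detected (call = 1) in every `tgf_atra` sample and undetected (call = 0)
#' in the `naive` and `med` samples. Under the default `"all_all"` policy
#' absence is required in every naive and every med sample; the laxer
#' `"all_any"` policy requires complete absence in at least one of the two
#' comparison groups.
#'
#' @param calls feature-level [detection_calls()] (see [collapse_calls()]).
#' @param policy `"all_all"` (default) or `"all_any"`.
#' @return List of class `"exclusive_set"`: `mir_ids` (sorted), `policy`,
#'   and `provenance` (counts of candidates failing each clause).
#' @export
exclusive_mirs <- function(calls, policy = c("all_all", "all_any")) {
  stopifnot(inherits(calls, "detection_calls"))
  policy <- match.arg(policy)
  .check_groups(calls$groups)
  m <- calls$calls
  in_tgf <- calls$groups == "tgf_atra"
  in_naive <- calls$groups == "naive"
  in_med <- calls$groups == "med"
  all_tgf <- rowSums(m[, in_tgf, drop = FALSE]) == sum(in_tgf)
  none_naive <- rowSums(m[, in_naive, drop = FALSE]) == 0
  none_med <- rowSums(m[, in_med, drop = FALSE]) == 0
  keep <- if (policy == "all_all") all_tgf & none_naive & none_med
          else all_tgf & (none_naive | none_med)
  structure(list(
    mir_ids = sort(rownames(m)[keep]),
    policy = policy,
    provenance = c(n_features = nrow(m),
                   n_detected_all_tgf = sum(all_tgf),
                   n_failing_naive_absence = sum(all_tgf & !none_naive),
                   n_failing_med_absence = sum(all_tgf & !none_med))),
    class = "exclusive_set")
}

#' @export
print.exclusive_set <- function(x, ...) {
  cat(sprintf("%d exclusively detected miRs (policy %s)\n",
              length(x$mir_ids), x$policy))
  print(x$provenance)
  invisible(x)
}

#' Three-set Venn partition
#'
#' Decomposes three id sets into the 7 disjoint regions (only-A, only-B,
#' only-C, the three pairwise-only intersections, and the triple
#' intersection).
#'
#' @param a,b,c character id sets.
#' @param names labels for the three sets.
#' @return List of class `"venn3"`: `regions` (7 disjoint id sets, named
#'   by a binary membership pattern such as `"110"` = in A and B only),
#'   `counts`, and `totals` per input set.
#' @export
venn3 <- function(a, b, c, names = c("A", "B", "C")) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  c <- unique(as.character(c))
  universe <- unique(base::c(a, b, c))
  code <- paste0((universe %in% a) + 0L, (universe %in% b) + 0L,
                 (universe %in% c) + 0L)
  patterns <- c("100", "010", "001", "110", "101", "011", "111")
  regions <- lapply(patterns, function(p) sort(universe[code == p]))
  names(regions) <- patterns
  structure(list(regions = regions,
                 counts = vapply(regions, length, integer(1)),
                 totals = stats::setNames(c(length(a), length(b), length(c)),
                                          names),
                 set_names = names),
            class = "venn3")
}

#' @export
print.venn3 <- function(x, ...) {
  cat("3-set Venn partition (pattern = membership in",
      paste(x$set_names, collapse = "/"), ")\n")
  print(x$counts)
  cat("totals:\n"); print(x$totals)
  invisible(x)
}

#' Cross-check commonly induced miRs against the exclusivity filter
#'
#' Reports the miRs induced in `tgf_atra` against both comparison groups
#' (the intersection of `up(tgf_vs_naive)` and `up(tgf_vs_med)`), the
#' subset of those not induced in `med` versus naive, and the overlap of
#' that subset with the detection-call exclusive set.
#'
#' @param sets output of [de_sets()] on the miR fit.
#' @param exclusive an [exclusive_mirs()] result.
#' @return List with `common_induced`, `not_induced_in_med`, `overlap`
#'   (each an id set) and `counts`.
#' @export
cross_check_exclusive <- function(sets, exclusive) {
  per <- sets$per_contrast
  need <- c("tgf_vs_naive", "tgf_vs_med", "med_vs_naive")
  if (!all(need %in% names(per)))
    stop("de_sets must contain the three pairwise contrasts", call. = FALSE)
  common <- intersect(per$tgf_vs_naive$up, per$tgf_vs_med$up)
  not_med <- setdiff(common, per$med_vs_naive$up)
  overlap <- intersect(not_med, exclusive$mir_ids)
  list(common_induced = sort(common),
       not_induced_in_med = sort(not_med),
       overlap = sort(overlap),
       counts = c(common_induced = length(common),
                  not_induced_in_med = length(not_med),
                  overlap_with_exclusive = length(overlap),
                  exclusive_total = length(exclusive$mir_ids)))
}

#' Build the down- (or up-) regulated gene universe for target search
#'
#' Union of the probes significant in `tgf_vs_naive` and the additional
#' probes significant in `tgf_vs_med` in the given direction, mapped to
#' unique gene symbols; probes without a mapping are dropped and counted.
#'
#' @param sets output of [de_sets()] on the mRNA fit (probe level).
#' @param probe_to_feature named probe id to gene symbol map.
#' @param direction `"down"` (default) or `"up"`.
#' @return List: `genes` (unique sorted gene symbols), `probes` (the probe
#'   union), `n_unmapped`.
#' @export
target_universe <- function(sets, probe_to_feature,
                            direction = c("down", "up")) {
  direction <- match.arg(direction)
  per <- sets$per_contrast
  need <- c("tgf_vs_naive", "tgf_vs_med")
  if (!all(need %in% names(per)))
    stop("de_sets must contain tgf_vs_naive and tgf_vs_med", call. = FALSE)
  probes <- union(per$tgf_vs_naive[[direction]],
                  per$tgf_vs_med[[direction]])
  genes <- probe_to_feature[probes]
  n_unmapped <- sum(is.na(genes))
  list(genes = sort(unique(genes[!is.na(genes)])),
       probes = sort(probes), n_unmapped = n_unmapped)
}
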