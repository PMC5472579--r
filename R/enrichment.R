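# Local gene-set enrichment in the style of a Functional Annotation Chart:
# hypergeometric (Fisher one-sided) upper-tail p-values, the conservative
# EASE variant (overlap reduced by one), fold enrichment, and BH adjustment
# across terms.

#' Overlap enrichment of a gene query against pathway gene sets
#'
#' For each term, with background size `N`, term size within the background
#' `K`, query size `n`, and overlap `k`: `fisher_p = P(X >= k)` for
#' hypergeometric `X`; `ease_p` is the same tail computed with the overlap
#' reduced by one (`max(k - 1, 0)`), the conservative score used by DAVID's
#' annotation chart. Fold enrichment is `(k/n) / (K/N)`.
#'
#' @param query character gene set (must be a subset of `background`).
#' @param background character background gene set.
#' @param sets named list of term gene sets (e.g. from [read_gmt()]); each
#'   term is intersected with the background.
#' @param stat which p-value to sort and BH-adjust by: `"ease"` (default)
#'   or `"fisher"`.
#' @return data.frame of class `"enrichment_result"`, one row per term:
#'   term, description, k, K, n, N, fold_enrichment, fisher_p, ease_p,
#'   p_value (the chosen statistic), adj_p; sorted by `p_value`.
#' @examples
#' sets <- list(T1 = c("a", "b", "c"), T2 = c("d", "e"))
#' enrich(c("a", "b"), letters[1:10], sets)
#' @export
enrich <- function(query, background, sets, stat = c("ease", "fisher")) {
  stat <- match.arg(stat)
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  outside <- setdiff(query, background)
  if (length(outside))
    stop("query genes outside the background: ",
         paste(utils::head(outside, 5), collapse = ", "),
         if (length(outside) > 5) ", ...", call. = FALSE)
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(sets), function(term) {
    term_genes <- intersect(sets[[term]], background)
    K <- length(term_genes)
    k <- length(intersect(term_genes, query))
    fisher_p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    ke <- max(k - 1, 0)
    ease_p <- stats::phyper(ke - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N,
               fold_enrichment = if (k > 0) (k / n) / (K / N) else 0,
               fisher_p = fisher_p, ease_p = ease_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  desc <- attr(sets, "descriptions")
  out$description <- if (!is.null(desc)) unname(desc[out$term])
                     else NA_character_
  out$p_value <- if (stat == "ease") out$ease_p else out$fisher_p
  out$adj_p <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, -out$fold_enrichment), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "stat") <- stat
  out
}

#' Default enrichment background
#'
#' Either every unique gene measured on the mRNA platform (default; the
#' uploaded-universe convention) or every gene present in the target
#' database.
#'
#' @param choice `"measured_genes"` or `"db_genes"`.
#' @param mrna an [expr_matrix()] (used for `"measured_genes"`).
#' @param db a [target_db()] (used for `"db_genes"`).
#' @return Character vector of gene symbols.
#' @export
default_background <- function(choice = c("measured_genes", "db_genes"),
                               mrna = NULL, db = NULL) {
  choice <- match.arg(choice)
  if (choice == "measured_genes") {
    if (is.null(mrna)) stop("`mrna` required", call. = FALSE)
    sort(unique(unname(mrna$probe_to_feature)))
  } else {
    if (is.null(db)) stop("`db` required", call. = FALSE)
    sort(unique(db$records$gene_symbol))
  }
}
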