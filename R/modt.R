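# Empirical-Bayes moderated t-tests for the three pairwise condition
# contrasts. Per-feature residual variances are shrunk toward a common
# prior value s0^2 with prior degrees of freedom d0, both estimated by
# moment matching of log s^2 against a scaled F distribution; the moderated
# t uses the posterior variance and d0 + d_g degrees of freedom.

.default_contrasts <- list(
  tgf_vs_naive = c("tgf_atra", "naive"),
  med_vs_naive = c("med", "naive"),
  tgf_vs_med = c("tgf_atra", "med"))

#' Per-feature group means and pooled residual variance
#'
#' @param x numeric feature-by-sample matrix of log2 expression, or an
#'   [expr_matrix()] with `is_log2 = TRUE`.
#' @param groups condition label per sample (ignored when `x` is an
#'   [expr_matrix()]).
#' @return A list of class `"group_fit"`: `means` (features x groups),
#'   `s2` (pooled residual variance per feature), `df_residual`
#'   (`N - G`), `n_per_group`, `avg_expr`.
#' @examples
#' m <- rbind(f1 = c(0, 0, 0, 1, 1, 3))
#' fit_group_means(m, rep(c("naive", "tgf_atra"), each = 3))$s2  # 0.6667
#' @export
fit_group_means <- function(x, groups = NULL) {
  if (inherits(x, "expr_matrix")) {
    if (!x$is_log2) stop("expression must be log2", call. = FALSE)
    groups <- x$groups
    x <- x$values
  }
  stopifnot(is.matrix(x), length(groups) == ncol(x))
  if (is.null(rownames(x)))
    rownames(x) <- paste0("feature_", seq_len(nrow(x)))
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 samples each", call. = FALSE)
  g <- factor(groups)
  n_per <- as.vector(table(g)); names(n_per) <- levels(g)
  means <- t(rowsum(t(x), g) / n_per)
  fitted <- means[, as.integer(g), drop = FALSE]
  rss <- rowSums((x - fitted)^2)
  df <- ncol(x) - nlevels(g)
  structure(list(means = means, s2 = rss / df, df_residual = df,
                 n_per_group = n_per, avg_expr = rowMeans(x)),
            class = "group_fit")
}

# Newton solve of trigamma(y) = x (monotone decreasing)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

#' Estimate the variance-shrinkage hyperparameters (d0, s0^2)
#'
#' Moment matching on the log scale: with `e_g = log(s2_g) -
#' digamma(d_g/2) + log(d_g/2)`, the excess of `var(e_g)` over
#' `trigamma(d_g/2)` identifies `trigamma(d0/2)`, and `s0^2` is recovered
#' from `mean(e_g)`. Zero variances are excluded from the moment fit. When
#' the observed spread does not exceed the sampling variability the prior
#' df are infinite and `s0^2` is the geometric-mean-based estimate.
#'
#' @param s2 vector of per-feature residual variances.
#' @param df residual degrees of freedom (scalar, or one per feature).
#' @return List with `d0` (prior df, possibly `Inf`) and `s0_sq`.
#' @export
estimate_hyperparameters <- function(s2, df) {
  if (length(df) == 1) df <- rep(df, length(s2))
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) stop("all residual variances are zero", call. = FALSE)
  if (sum(ok) < 10)
    stop("need >= 10 features with positive variance", call. = FALSE)
  e <- log(s2[ok]) - digamma(df[ok] / 2) + log(df[ok] / 2)
  n <- length(e)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (n - 1)
  excess <- evar - mean(trigamma(df[ok] / 2))
  if (excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-statistics for one contrast
#'
#' Posterior variance `s2_post = (d0 s0^2 + d_g s2_g) / (d0 + d_g)`
#' (equal to `s0^2` when `d0 = Inf` and to `s2_g` when `d0 = 0`, the
#' classical pooled two-sample t); `t = (mean_A - mean_B) /
#' sqrt(s2_post (1/n_A + 1/n_B))` with `d0 + d_g` degrees of freedom,
#' two-sided p-values, BH-adjusted across features.
#'
#' @param fit a [fit_group_means()] result.
#' @param d0,s0_sq hyperparameters (see [estimate_hyperparameters()]).
#' @param contrast length-2 character `c(A, B)` naming the groups; the
#'   reported log2 fold change is `A - B`.
#' @return data.frame: feature_id, log2fc, avg_expr, s2, s2_post, t_mod,
#'   df_total, p_value, adj_p.
#' @export
moderated_t <- function(fit, d0, s0_sq, contrast) {
  stopifnot(inherits(fit, "group_fit"), length(contrast) == 2)
  if (!all(contrast %in% colnames(fit$means)))
    stop("contrast references missing group(s): ",
         paste(setdiff(contrast, colnames(fit$means)), collapse = ", "),
         call. = FALSE)
  dg <- fit$df_residual
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(fit$s2))
             else if (d0 == 0) fit$s2
             else (d0 * s0_sq + dg * fit$s2) / (d0 + dg)
  nA <- fit$n_per_group[contrast[1]]
  nB <- fit$n_per_group[contrast[2]]
  lfc <- fit$means[, contrast[1]] - fit$means[, contrast[2]]
  se <- sqrt(s2_post * (1 / nA + 1 / nB))
  t_mod <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  df_total <- d0 + dg
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  data.frame(feature_id = rownames(fit$means), log2fc = unname(lfc),
             avg_expr = unname(fit$avg_expr), s2 = unname(fit$s2),
             s2_post = unname(s2_post), t_mod = unname(t_mod),
             df_total = df_total, p_value = unname(p),
             adj_p = bh_adjust(unname(p)), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, delegated to
#' [stats::p.adjust()].
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Fit the moderated-t model for all pairwise condition contrasts
#'
#' The package's central estimator: group means and pooled variances per
#' feature, empirical-Bayes shrinkage hyperparameters shared across
#' features, and moderated t-tests with BH adjustment for each requested
#' contrast.
#'
#' @param x log2 [expr_matrix()] (feature level) or numeric matrix.
#' @param groups condition labels (when `x` is a bare matrix).
#' @param contrasts named list of length-2 group pairs; defaults to the
#'   three pairwise contrasts `tgf_vs_naive`, `med_vs_naive`, `tgf_vs_med`.
#' @param d0 optional forced prior df (e.g. `0` for the classical t,
#'   `Inf` for full shrinkage); estimated when `NULL`.
#' @return Object of class `"modt"`: the `group_fit`, hyperparameters
#'   `d0`/`s0_sq`, and one result table per contrast (`$tables`).
#' @seealso [de_sets()], [top_table()]
#' @export
modt_fit <- function(x, groups = NULL, contrasts = NULL, d0 = NULL) {
  fit <- fit_group_means(x, groups)
  if (is.null(contrasts)) {
    contrasts <- Filter(function(ct) all(ct %in% colnames(fit$means)),
                        .default_contrasts)
    if (!length(contrasts))
      stop("no default contrast matches the group labels; supply `contrasts`",
           call. = FALSE)
  }
  hyp <- estimate_hyperparameters(fit$s2, fit$df_residual)
  if (!is.null(d0)) {
    hyp$d0 <- d0
    if (d0 == 0) hyp$s0_sq <- NA_real_
  }
  tables <- lapply(contrasts, function(ct)
    moderated_t(fit, hyp$d0, hyp$s0_sq, ct))
  structure(list(fit = fit, d0 = hyp$d0, s0_sq = hyp$s0_sq,
                 contrasts = contrasts, tables = tables),
            class = "modt")
}

#' @export
print.modt <- function(x, ...) {
  cat(sprintf("Moderated-t fit: %d features, groups: %s\n",
              nrow(x$fit$means),
              paste(colnames(x$fit$means), collapse = ", ")))
  cat(sprintf("  prior df d0 = %s, prior variance s0^2 = %s\n",
              format(x$d0, digits = 4), format(x$s0_sq, digits = 4)))
  cat("  contrasts:", paste(names(x$tables), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.modt <- function(object, alpha = 0.05, ...) {
  sets <- de_sets(object, alpha = alpha)
  sizes <- t(vapply(names(object$tables), function(ct)
    c(up = length(sets$per_contrast[[ct]]$up),
      down = length(sets$per_contrast[[ct]]$down)), numeric(2)))
  out <- list(d0 = object$d0, s0_sq = object$s0_sq, alpha = alpha,
              df_residual = object$fit$df_residual, sizes = sizes,
              n_union = length(sets$union))
  class(out) <- "summary.modt"
  out
}

#' @export
print.summary.modt <- function(x, ...) {
  cat(sprintf("d0 = %s, s0^2 = %s, residual df = %d\n",
              format(x$d0, digits = 4), format(x$s0_sq, digits = 4),
              x$df_residual))
  cat(sprintf("significant features (adj_p < %g):\n", x$alpha))
  print(x$sizes)
  cat("union over contrasts:", x$n_union, "\n")
  invisible(x)
}

#' @export
coef.modt <- function(object, ...) {
  vapply(object$tables, function(tb) tb$log2fc,
         numeric(nrow(object$fit$means)))
}

#' @export
plot.modt <- function(x, ...) {
  graphics::plot(sqrt(x$fit$s2), sqrt(x$fit$tables[[1]]$s2_post),
                 xlab = "residual sd", ylab = "posterior sd",
                 main = "variance shrinkage", pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.5), ...)
  graphics::abline(0, 1, lty = 2)
  if (is.finite(x$d0) && !is.na(x$s0_sq))
    graphics::abline(h = sqrt(x$s0_sq), col = "firebrick", lty = 3)
  invisible(x)
}

#' Top-ranked features for one contrast
#' @param fit a [modt_fit()] object.
#' @param contrast contrast name (default: first fitted).
#' @param n number of rows (by ascending p-value).
#' @export
top_table <- function(fit, contrast = NULL, n = 10) {
  stopifnot(inherits(fit, "modt"))
  if (is.null(contrast)) contrast <- names(fit$tables)[1]
  tb <- fit$tables[[contrast]]
  if (is.null(tb)) stop("unknown contrast: ", contrast, call. = FALSE)
  utils::head(tb[order(tb$p_value), ], n)
}

#' Significant up/down sets per contrast
#'
#' @param fit a [modt_fit()] object.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return List with `per_contrast` (per contrast: `up`, `down` feature id
#'   sets, disjoint by construction) and `union` (features significant in
#'   any contrast, the "DE in any condition" set).
#' @export
de_sets <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "modt"))
  per <- lapply(fit$tables, function(tb) {
    sig <- tb$adj_p < alpha
    list(up = tb$feature_id[sig & tb$log2fc > 0],
         down = tb$feature_id[sig & tb$log2fc < 0])
  })
  union <- sort(unique(unlist(lapply(per, unlist), use.names = FALSE)))
  list(per_contrast = per, union = union, alpha = alpha)
}
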