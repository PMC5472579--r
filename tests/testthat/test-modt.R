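# Group-mean fits, empirical-Bayes hyperparameter estimation, moderated
# t-statistics and BH adjustment.

test_that("group means and pooled variance match the hand-computed oracle", {
  x <- rbind(f1 = c(0, 0, 0, 1, 1, 3), f2 = rep(2, 6))
  g <- rep(c("naive", "tgf_atra"), each = 3)
  fit <- fit_group_means(x, g)
  expect_equal(unname(fit$means["f1", c("naive", "tgf_atra")]), c(0, 5 / 3))
  expect_equal(unname(fit$s2["f1"]), 2 / 3)
  expect_equal(fit$df_residual, 4)
  expect_equal(unname(fit$s2["f2"]), 0)          # constant feature
  expect_equal(unname(fit$means["f2", ]), c(2, 2))
  # permuting samples within groups changes nothing
  perm <- c(3, 1, 2, 6, 4, 5)
  fit2 <- fit_group_means(x[, perm], g[perm])
  expect_equal(fit2$means, fit$means)
  expect_equal(fit2$s2, fit$s2)
  expect_error(fit_group_means(x[, 1:4], c("a", "a", "a", "b")), ">= 2")
})

test_that("hyperparameter estimation recovers simulated prior parameters", {
  dg <- 4
  # homogeneous variances: d0 should be large, s0^2 close to truth
  set.seed(10)
  recovered_large <- replicate(10, {
    s2 <- 0.05 * stats::rchisq(2000, dg) / dg
    h <- estimate_hyperparameters(s2, dg)
    c(h$d0, h$s0_sq)
  })
  expect_gte(sum(recovered_large[1, ] > 50), 8)
  expect_true(all(abs(recovered_large[2, ] / 0.05 - 1) < 0.1))
  # scaled-F prior with d0 = 4: estimates land in [2, 8]
  set.seed(11)
  d0_hat <- replicate(10, {
    s2 <- 0.05 * (stats::rchisq(2000, dg) / dg) /
      (stats::rchisq(2000, 4) / 4)
    estimate_hyperparameters(s2, dg)$d0
  })
  expect_true(all(d0_hat >= 2 & d0_hat <= 8))
})

test_that("a constant variance vector takes the infinite-d0 branch", {
  h <- estimate_hyperparameters(rep(0.3, 100), 4)
  expect_identical(h$d0, Inf)
  # bias-corrected geometric mean: exp(log(0.3) - digamma(2) + log(2))
  expect_equal(h$s0_sq, 0.3 * exp(log(2) - digamma(2)))
  expect_error(estimate_hyperparameters(rep(0, 100), 4), "zero")
})

test_that("hyperparameter estimates agree with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(12)
  s2 <- 0.1 * (stats::rchisq(3000, 4) / 4) / (stats::rchisq(3000, 6) / 6)
  h <- estimate_hyperparameters(s2, 4)
  ref <- limma::fitFDist(s2, df1 = 4)
  expect_equal(h$d0, ref$df2, tolerance = 1e-6)
  expect_equal(h$s0_sq, ref$scale, tolerance = 1e-6)
})

test_that("with d0 = 0 the moderated t equals the classical pooled t", {
  set.seed(13)
  n <- 2000
  x <- matrix(rnorm(n * 6, 8, 1), n, 6,
              dimnames = list(paste0("f", 1:n), paste0("s", 1:6)))
  g <- rep(c("naive", "tgf_atra"), each = 3)
  fit <- modt_fit(x, g, d0 = 0,
                  contrasts = list(tgf_vs_naive = c("tgf_atra", "naive")))
  classical <- apply(x, 1, function(row) {
    unname(stats::t.test(row[4:6], row[1:3], var.equal = TRUE)$statistic)
  })
  expect_lt(max(abs(fit$tables$tgf_vs_naive$t_mod - classical)), 1e-10)
})

test_that("identical residual variances make shrinkage a no-op for any d0", {
  x <- rbind(f1 = c(0, 2, 1, 4, 6, 5), f2 = c(1, 3, 2, 0, 2, 1))
  g <- rep(c("naive", "tgf_atra"), each = 3)
  fit <- fit_group_means(x, g)
  expect_equal(unname(diff(fit$s2)), 0)
  s2 <- fit$s2[1]
  ref <- moderated_t(fit, 0, NA, c("tgf_atra", "naive"))$t_mod
  for (d0 in c(2, 10, Inf)) {
    t_mod <- moderated_t(fit, d0, s2, c("tgf_atra", "naive"))$t_mod
    expect_equal(t_mod, ref, tolerance = 1e-12)
  }
})

test_that("moderated t matches limma's eBayes pipeline", {
  skip_if_not_installed("limma")
  set.seed(14)
  n <- 500
  feature_sd <- sqrt(0.5 / (stats::rchisq(n, 5) / 5))  # heteroscedastic
  x <- matrix(rnorm(n * 9, 8, rep(feature_sd, 9)), n, 9,
              dimnames = list(paste0("f", 1:n), paste0("s", 1:9)))
  x[1:50, 7:9] <- x[1:50, 7:9] + 2
  g <- rep(c("naive", "med", "tgf_atra"), each = 3)
  fit <- modt_fit(x, g)
  design <- stats::model.matrix(~ 0 + factor(g, levels = unique(g)))
  colnames(design) <- unique(g)
  lfit <- limma::lmFit(x, design)
  cfit <- limma::eBayes(limma::contrasts.fit(
    lfit, limma::makeContrasts(tgf_atra - naive, levels = design)))
  expect_equal(fit$d0, cfit$df.prior, tolerance = 1e-6)
  expect_equal(fit$s0_sq, cfit$s2.prior, tolerance = 1e-6)
  expect_equal(fit$tables$tgf_vs_naive$t_mod, unname(cfit$t[, 1]),
               tolerance = 1e-8)
  expect_equal(fit$tables$tgf_vs_naive$p_value, unname(cfit$p.value[, 1]),
               tolerance = 1e-8)
})

test_that("null simulations give uniform two-sided p-values", {
  set.seed(15)
  ks_pass <- replicate(10, {
    x <- matrix(rnorm(2000 * 6, 8, 0.7), 2000, 6)
    colnames(x) <- paste0("s", 1:6)
    g <- rep(c("naive", "tgf_atra"), each = 3)
    fit <- modt_fit(x, g)
    stats::ks.test(fit$tables$tgf_vs_naive$p_value, "punif")$p.value > 0.01
  })
  expect_gte(sum(ks_pass), 9)
})

test_that("the moderated t is antisymmetric in the contrast order", {
  set.seed(16)
  x <- matrix(rnorm(100 * 6, 8, 1), 100, 6,
              dimnames = list(paste0("f", 1:100), paste0("s", 1:6)))
  g <- rep(c("naive", "tgf_atra"), each = 3)
  fit <- fit_group_means(x, g)
  h <- estimate_hyperparameters(fit$s2, fit$df_residual)
  fwd <- moderated_t(fit, h$d0, h$s0_sq, c("tgf_atra", "naive"))
  rev <- moderated_t(fit, h$d0, h$s0_sq, c("naive", "tgf_atra"))
  expect_equal(fwd$t_mod, -rev$t_mod)
  expect_equal(fwd$p_value, rev$p_value)
  expect_error(moderated_t(fit, h$d0, h$s0_sq, c("tgf_atra", "plasma")),
               "missing group")
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.03, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # permutation invariance and monotonicity
  set.seed(17)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(bh_adjust(p) >= p))
})

test_that("de_sets partitions significant features by sign", {
  res <- default_run()
  sets <- de_sets(res$mir_fit, alpha = 0.05)
  for (s in sets$per_contrast)
    expect_length(intersect(s$up, s$down), 0)
  empty <- de_sets(res$mir_fit, alpha = 0)
  expect_true(all(vapply(empty$per_contrast,
                         function(s) length(s$up) + length(s$down),
                         numeric(1)) == 0))
  truth <- res$dataset$truth
  expect_true(all(truth$exclusive_mir_ids %in%
                    sets$per_contrast$tgf_vs_naive$up))
  expect_true(all(truth$exclusive_mir_ids %in%
                    sets$per_contrast$tgf_vs_med$up))
})

test_that("modt methods print, summarise and expose coefficients", {
  set.seed(18)
  x <- matrix(rnorm(50 * 9, 8, 1), 50, 9,
              dimnames = list(paste0("f", 1:50), paste0("s", 1:9)))
  g <- rep(c("naive", "med", "tgf_atra"), each = 3)
  fit <- modt_fit(x, g)
  expect_output(print(fit), "prior df")
  expect_output(print(summary(fit)), "union over contrasts")
  cf <- coef(fit)
  expect_equal(dim(cf), c(50L, 3L))
  expect_equal(cf[, "tgf_vs_naive"],
               stats::setNames(fit$tables$tgf_vs_naive$log2fc,
                               rownames(x)), ignore_attr = TRUE)
  tt <- top_table(fit, "tgf_vs_naive", n = 5)
  expect_equal(nrow(tt), 5)
  expect_true(!is.unsorted(tt$p_value))
})
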