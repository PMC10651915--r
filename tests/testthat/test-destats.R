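test_that("contrast estimates are the coefficients applied to group means", {
  gm <- rbind(g1 = c(WT_SELF = 0, WT_HOST = 2, MUT_SELF = 0,
                     MUT_HOST = -1))
  b <- make_bundle(gm, nrep = 3, noise_sd = 0)
  sl <- fit_gene_model(b, contrast_spec("SECOND_LEVEL"))
  expect_equal(sl$log2fc, -3)        # (+1,-1,-1,+1) . (0,2,0,-1)
  expect_equal(sl$s2, 0)
  expect_equal(sl$df, 8L)            # 12 arrays - 4 groups
  wt <- fit_gene_model(b, contrast_spec("WT_RESPONSE"))
  expect_equal(wt$log2fc, 2)

  # noisy fixture: estimate equals brute-force difference of group means
  set.seed(77)
  gm2 <- matrix(rnorm(40), nrow = 10,
                dimnames = list(NULL, names(gm[1, ])))
  b2 <- make_bundle(gm2, nrep = 4, noise_sd = 0.5, seed = 3)
  wt2 <- fit_gene_model(b2, contrast_spec("WT_RESPONSE"))
  grp <- b2$design$group
  bf <- rowMeans(b2$matrix[, grp == "WT_HOST"]) -
    rowMeans(b2$matrix[, grp == "WT_SELF"])
  expect_equal(wt2$log2fc, unname(bf), tolerance = 1e-12)

  expect_error(contrast_spec("custom", coef = c(1, 1, 0, 0)), "sum to 0")
  b3 <- b2
  b3$design$group <- factor(rep("WT_SELF", 16), levels = levels(grp))
  expect_error(fit_gene_model(b3, contrast_spec("WT_RESPONSE")),
               "no arrays")
})

test_that("moderation degenerates correctly and shrinks between bounds", {
  fit <- data.frame(log2fc = c(1, -2, 0.5), s2 = c(2, 2, 2), df = 4)
  mod <- ebayes_moderate(fit, se_mult = sqrt(1 / 2))
  # identical variances: prior equals the common value, t is ordinary t
  expect_equal(attr(mod, "s0_2"), 2)
  expect_equal(mod$s2_post, rep(2, 3))
  expect_equal(mod$t_mod, fit$log2fc / (sqrt(2) * sqrt(1 / 2)))

  set.seed(19)
  fit2 <- data.frame(log2fc = rnorm(200),
                     s2 = 0.05 * rf(200, 12, 6), df = 12)
  mod2 <- ebayes_moderate(fit2, se_mult = 1)
  d0 <- attr(mod2, "d0")
  s0 <- attr(mod2, "s0_2")
  expect_gt(d0, 0)
  # posterior variance lies between the observed variance and the prior
  lo <- pmin(fit2$s2, s0)
  hi <- pmax(fit2$s2, s0)
  expect_true(all(mod2$s2_post >= lo - 1e-12 & mod2$s2_post <= hi + 1e-12))

  # d0 forced to infinity: every posterior variance equals the prior
  mod3 <- ebayes_moderate(fit2, se_mult = 1, d0_override = Inf)
  expect_true(all(mod3$s2_post == attr(mod3, "s0_2")))

  # all-zero variances fall back to the configured floor
  fit4 <- data.frame(log2fc = c(1, 0), s2 = c(0, 0), df = 4)
  mod4 <- ebayes_moderate(fit4, se_mult = 1, var_floor = 1e-6)
  expect_true(attr(mod4, "zero_variance_fallback"))
  expect_equal(attr(mod4, "s0_2"), 1e-6)
})

test_that("moment-matched hyperparameters satisfy their estimating equations", {
  fit <- data.frame(log2fc = c(0, 0), s2 = c(1, 4), df = 4)
  mod <- ebayes_moderate(fit, se_mult = 1)
  d0 <- attr(mod, "d0")
  s0 <- attr(mod, "s0_2")
  z <- log(c(1, 4))
  # variance equation: var(log s2) = trigamma(df/2) + trigamma(d0/2)
  expect_equal(var(z), trigamma(2) + trigamma(d0 / 2), tolerance = 1e-8)
  # mean equation under the scaled-F model
  expect_equal(mean(z),
               log(s0) + digamma(2) - log(2) - digamma(d0 / 2) +
                 log(d0 / 2), tolerance = 1e-8)
})

test_that("hyperparameter estimates agree with independent references", {
  skip_if_not_installed("limma")
  set.seed(41)
  true_d0 <- 6
  true_s0 <- 0.05
  df <- 12
  s2 <- true_s0 * rf(600, df, true_d0)
  fit <- data.frame(log2fc = rnorm(600), s2 = s2, df = df)
  mod <- ebayes_moderate(fit, se_mult = 1)
  d0 <- attr(mod, "d0")
  s0 <- attr(mod, "s0_2")

  # same moment-matching estimator in limma
  lf <- limma::fitFDist(s2, df1 = df)
  expect_equal(d0, lf$df2, tolerance = 0.05)
  expect_equal(s0, lf$scale, tolerance = 0.05)

  # independent grid search maximizing the scaled-F marginal likelihood
  d0_grid <- exp(seq(log(1), log(60), length.out = 80))
  s0_grid <- exp(seq(log(0.01), log(0.2), length.out = 80))
  ll <- outer(d0_grid, s0_grid,
              Vectorize(function(a, b) scaled_f_loglik(s2, df, a, b)))
  best <- arrayInd(which.max(ll), dim(ll))
  expect_equal(log(d0), log(d0_grid[best[1]]), tolerance = 0.2)
  expect_equal(log(s0), log(s0_grid[best[2]]), tolerance = 0.1)
})

test_that("moderated statistics match the established reference pipeline", {
  skip_if_not_installed("limma")
  cfg <- synthetic_config(n_genes = 300, protein_fraction = 0, seed = 5)
  ex <- generate_experiment(cfg)
  mod <- ebayes_moderate(fit_gene_model(ex$bundle,
                                        contrast_spec("SECOND_LEVEL")))
  design <- stats::model.matrix(~ 0 + group, data = ex$bundle$design)
  colnames(design) <- levels(ex$bundle$design$group)
  eb <- limma::eBayes(limma::contrasts.fit(
    limma::lmFit(ex$bundle$matrix, design), c(1, -1, -1, 1)))
  expect_equal(mod$log2fc, unname(eb$coefficients[, 1]),
               tolerance = 1e-10)
  expect_equal(mod$t_mod, unname(eb$t[, 1]), tolerance = 0.05)
  expect_equal(mod$p, unname(eb$p.value[, 1]), tolerance = 0.01)
})

test_that("BY adjustment matches direct step-up evaluation and dominates BH", {
  expect_equal(by_adjust(0.03), 0.03)
  expect_equal(by_adjust(c(0.01, 0.02, 0.5)),
               c(0.055, 0.055, 11 / 12), tolerance = 1e-12)
  expect_equal(by_adjust(rep(1, 5)), rep(1, 5))
  expect_error(by_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(23)
  for (n in c(1, 7, 100, 1000)) {
    p <- runif(n)^2
    q <- by_adjust(p)
    expect_equal(q, bf_by_adjust(p), tolerance = 1e-12)
    expect_true(all(q >= bh_adjust(p) - 1e-12))  # BY dominates BH
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
  }
})
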