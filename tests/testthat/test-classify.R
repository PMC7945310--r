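well_separated_scores <- function(n = 4000, seed = 101) {
  set.seed(seed)
  comp <- sample.int(4, n, replace = TRUE, prob = c(0.15, 0.15, 0.5, 0.2))
  mu <- c(-2, -1, 0, 1)
  rnorm(n, mu[comp], 0.15)
}

test_that("the EM fit recovers well-separated component means", {
  x <- well_separated_scores()
  fit <- fit_score_mixture(x, k = 4, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$components$mean, c(-2, -1, 0, 1), tolerance = 0.05 / 2)
  expect_equal(sum(fit$components$weight), 1)
  expect_equal(fit$components$role, c("negative", "negative", "null_like",
                                      "positive"))
  # determinism given the seed
  fit2 <- fit_score_mixture(x, k = 4, seed = 1)
  expect_identical(fit$components, fit2$components)
})

test_that("the EM fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  x <- well_separated_scores(n = 2000, seed = 7)
  fit <- fit_score_mixture(x, k = 4, seed = 1)
  # the fitted solution must be a fixed point of an independent EM:
  # restarting mclust's EM from it should not move the parameters or
  # improve the log-likelihood noticeably
  par <- list(
    pro = fit$components$weight,
    mean = fit$components$mean,
    variance = list(modelName = "V", d = 1, G = 4,
                    sigmasq = fit$components$variance))
  me <- mclust::em(data = x, modelName = "V", parameters = par)
  expect_equal(as.numeric(me$parameters$mean), fit$components$mean,
               tolerance = 1e-3)
  expect_equal(as.numeric(me$parameters$pro), fit$components$weight,
               tolerance = 1e-3)
  expect_equal(me$loglik, fit$loglik, tolerance = 1e-5)
})

test_that("degenerate or tiny inputs are rejected", {
  expect_error(fit_score_mixture(rep(0.5, 100)), "degenerate")
  expect_error(fit_score_mixture(rnorm(20)), "at least 50")
})

test_that("posteriors sum to one and the LOF posterior behaves at the limits", {
  x <- well_separated_scores()
  fit <- fit_score_mixture(x, seed = 1)
  beta <- seq(-3, 2, length.out = 101)
  post <- posterior_matrix(fit, beta)
  expect_equal(rowSums(post), rep(1, length(beta)), tolerance = 1e-12)
  P <- lof_posterior(fit, beta)
  expect_gt(P[1], 0.999)        # far below the negative means
  expect_lt(P[beta == 0], 0.05) # at the null mean
})

test_that("the bisection cutoff matches a dense-grid oracle", {
  fit <- structure(
    list(
      components = tibble::tibble(
        component = 1:4,
        weight = c(0.05, 0.3, 0.6, 0.05),
        mean = c(-2.5, -1, 0, 0.8),
        variance = c(0.2^2, 0.2^2, 0.2^2, 0.2^2),
        role = c("negative", "negative", "null_like", "positive")
      ),
      k = 4L, n = 1000L, converged = TRUE
    ), class = "be_mixture")
  cut <- equivalent_beta_cutoff(fit, threshold = 0.8)
  grid <- seq(-2, 0, by = 1e-5)
  P <- lof_posterior(fit, grid)
  oracle <- grid[max(which(P > 0.8))]
  expect_lt(abs(cut - oracle), 1e-4)
  expect_true(all(lof_posterior(fit, cut - 0.05) > 0.8))
  expect_true(all(lof_posterior(fit, cut + 0.05) < 0.8))
})

test_that("a fit without exactly two negative means falls back with a warning", {
  set.seed(31)
  x <- c(rnorm(500, 0, 0.1), rnorm(200, 1, 0.1), rnorm(200, 2, 0.1),
         rnorm(100, 3, 0.1))
  expect_warning(fit <- fit_score_mixture(x, seed = 2),
                 "negative-mean component")
  expect_equal(sum(fit$components$role == "negative"), 2L)
  expect_equal(fit$components$role[1:2], c("negative", "negative"))
  expect_true(fit$negative_fallback)
})

test_that("model-selection diagnostics favour the generating component count", {
  x <- well_separated_scores(n = 1200, seed = 19)
  ms <- suppressWarnings(mixture_model_selection(x, k_range = 2:5,
                                                 n_init = 3, seed = 1))
  expect_equal(ms$k, 2:5)
  expect_true(all(ms$converged))
  # BIC should not prefer fewer components than the 4 that generated x
  expect_equal(ms$k[which.min(ms$BIC)], 4L)
})

test_that("Wald statistics and BH adjustment match oracles", {
  w <- wald_bh(-1.0, 0.5)
  expect_equal(w$z, -2)
  expect_equal(w$p, 2 * pnorm(-2))
  expect_equal(w$p, 0.0455, tolerance = 1e-3)

  w0 <- wald_bh(0, 0)
  expect_equal(w0$p, 1)
  expect_true(w0$degenerate_se)
  w1 <- wald_bh(-0.5, 0)
  expect_equal(w1$p, 0)

  expect_equal(wald_bh(c(-1, 1, 0.1, 2), c(1, 1, 1, 1))$bh_p,
               oracle_bh(2 * pnorm(-abs(c(-1, 1, 0.1, 2)))))
  # hand case: (0.01, 0.02, 0.03, 0.04) all adjust to 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(23)
  for (i in 1:5) {
    p <- runif(sample(5:40, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p))
  }
})

test_that("Fisher enrichment equals direct hypergeometric summation", {
  expect_equal(fisher.test(matrix(c(10, 90, 50, 50), 2))$p.value,
               oracle_fisher(10, 90, 50, 50), tolerance = 1e-10)
  expect_equal(fisher.test(matrix(c(3, 7, 12, 2), 2))$p.value,
               oracle_fisher(3, 7, 12, 2), tolerance = 1e-10)
})

test_that("evaluation reports type enrichment and ROC behaviour", {
  skip_if_not_installed("pROC")
  set.seed(41)
  calls <- tibble::tibble(
    guide_id = paste0("g", 1:200),
    mean_beta = c(rnorm(50, -1, 0.2), rnorm(150, 0, 0.2)),
    P = c(rep(0.95, 50), rep(0.05, 150)),
    lof_call = c(rep(TRUE, 50), rep(FALSE, 150)),
    wald_p = NA_real_, bh_p = NA_real_
  )
  labels <- tibble::tibble(
    guide_id = paste0("g", 1:200),
    label = c(rep("P/LP", 50), rep("B/LB", 150))
  )
  types <- tibble::tibble(
    guide_id = paste0("g", 1:200),
    mutational_type = c(rep("stop_gain", 50), rep("synonymous", 150))
  )
  ev <- evaluate_calls(calls, types = types, labels = labels)
  expect_equal(ev$roc$auc, 1)       # perfect separation
  expect_equal(ev$roc$call_sensitivity, 1)
  expect_equal(ev$roc$call_specificity, 1)
  sg <- ev$by_type[ev$by_type$mutational_type == "stop_gain", ]
  expect_equal(sg$lof_fraction, 1)
  expect_lt(sg$fisher_p, 1e-10)

  # permuted labels -> AUC near 0.5
  perm <- labels
  perm$label <- sample(perm$label)
  ev2 <- evaluate_calls(calls, labels = perm)
  expect_lt(abs(ev2$roc$auc - 0.5), 0.15)
})
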