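#' Fit a univariate Gaussian mixture to functional scores
#'
#' EM fit of a K-component (default 4) Gaussian mixture with unequal
#' variances, k-means initialisation and `n_init` random restarts,
#' converging on the change in mean log-likelihood. With K = 4 the fitted
#' components typically comprise one null-like component with mean near 0,
#' two negative-mean components (deleterious variants) and one
#' positive-mean component. Deterministic given `seed`.
#'
#' @param scores Numeric vector of (mean) beta scores; at least 50 finite
#'   values required.
#' @param k Number of components (default 4).
#' @param n_init Number of restarts (default 10; the first is k-means, the
#'   rest randomised).
#' @param seed Integer seed.
#' @param tol Convergence tolerance on the mean log-likelihood (default
#'   1e-6).
#' @param max_iter Maximum EM iterations per restart.
#' @return An object of class `be_mixture`: components tibble (`weight`,
#'   `mean`, `variance`, `role`), `loglik`, `AIC`, `BIC`, `converged`,
#'   the input `scores`, and role bookkeeping.
#' @export
fit_score_mixture <- function(scores, k = 4L, n_init = 10L, seed = 1L,
                              tol = 1e-6, max_iter = 1000L) {
  x <- scores[is.finite(scores)]
  if (length(x) < 50L) {
    stop("need at least 50 finite scores to fit the mixture", call. = FALSE)
  }
  if (sd(x) == 0) {
    stop("scores are degenerate (zero variance)", call. = FALSE)
  }
  set.seed(seed)
  n <- length(x)
  var_floor <- max(var(x) * 1e-8, 1e-12)
  best <- NULL
  for (r in seq_len(n_init)) {
    mu <- if (r == 1L) {
      km <- tryCatch(kmeans(x, centers = k, nstart = 1L),
                     error = function(e) NULL)
      if (is.null(km)) sort(sample(x, k)) else sort(as.vector(km$centers))
    } else {
      sort(sample(x, k))
    }
    if (anyDuplicated(mu)) mu <- mu + seq_len(k) * sd(x) * 1e-3
    fit <- em_gmm(x, mu, rep(var(x) / k, k), rep(1 / k, k), tol, max_iter,
                  var_floor)
    if (is.null(best) ||
        (fit$converged && !best$converged) ||
        (fit$converged == best$converged && fit$loglik > best$loglik)) {
      best <- fit
    }
  }
  if (!best$converged) {
    stop("EM failed to converge in all ", n_init, " restarts ",
         "(best log-likelihood ", format(best$loglik), ")", call. = FALSE)
  }
  ord <- order(best$mean)
  comp <- tibble::tibble(
    component = seq_len(k),
    weight = best$weight[ord],
    mean = best$mean[ord],
    variance = best$variance[ord]
  )
  roles <- assign_roles(comp$mean)
  comp$role <- as.vector(roles)
  n_par <- 3L * k - 1L
  structure(
    list(
      components = comp,
      k = k, n = n,
      loglik = best$loglik,
      AIC = 2 * n_par - 2 * best$loglik,
      BIC = log(n) * n_par - 2 * best$loglik,
      converged = TRUE,
      seed = seed,
      negative_fallback = attr(roles, "fallback"),
      scores = x
    ),
    class = "be_mixture"
  )
}

em_gmm <- function(x, mu, v, w, tol, max_iter, var_floor) {
  n <- length(x)
  k <- length(mu)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    lp <- vapply(seq_len(k), function(g)
      log(w[g]) + dnorm(x, mu[g], sqrt(v[g]), log = TRUE), numeric(n))
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    post <- exp(lp - lse)
    ll <- mean(lse)
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    nk <- colSums(post)
    w <- nk / n
    mu <- colSums(post * x) / nk
    v <- pmax(colSums(post * (outer(x, mu, "-")^2)) / nk, var_floor)
  }
  list(weight = w, mean = mu, variance = v, loglik = ll_old * n,
       converged = converged)
}

# component roles: two negative-mean components carry the LOF posterior;
# when the fit does not have exactly two, fall back to the two smallest
# means with a prominent warning
assign_roles <- function(means) {
  k <- length(means)
  neg <- which(means < 0)
  fallback <- length(neg) != 2L
  if (fallback) {
    warning("fitted mixture has ", length(neg),
            " negative-mean component(s), not 2; ",
            "using the two components with smallest means for LOF calling",
            call. = FALSE)
    neg <- order(means)[1:2]
  }
  roles <- rep("positive", k)
  roles[neg] <- "negative"
  rest <- setdiff(seq_len(k), neg)
  roles[rest[which.min(abs(means[rest]))]] <- "null_like"
  attr(roles, "fallback") <- fallback
  roles
}

#' @export
print.be_mixture <- function(x, ...) {
  cat("Gaussian mixture fit (", x$k, " components, n = ", x$n, ")\n",
      sep = "")
  cat("log-likelihood ", format(x$loglik), ", AIC ", format(x$AIC),
      ", BIC ", format(x$BIC), "\n", sep = "")
  print(x$components)
  invisible(x)
}

#' Posterior component membership at given scores
#' @param fit A `be_mixture`.
#' @param beta Numeric scores.
#' @return Matrix (length(beta) x k) of posterior probabilities; rows sum
#'   to 1.
#' @export
posterior_matrix <- function(fit, beta) {
  comp <- fit$components
  lp <- vapply(seq_len(fit$k), function(g)
    log(comp$weight[g]) +
      dnorm(beta, comp$mean[g], sqrt(comp$variance[g]), log = TRUE),
    numeric(length(beta)))
  lp <- matrix(lp, ncol = fit$k)
  m <- apply(lp, 1, max)
  exp(lp - (m + log(rowSums(exp(lp - m)))))
}

#' Loss-of-function posterior probability
#'
#' `P_i`: the summed posterior mass of the two negative-mean components at
#' each score.
#'
#' @inheritParams posterior_matrix
#' @return Numeric vector in `[0, 1]`.
#' @export
lof_posterior <- function(fit, beta) {
  post <- posterior_matrix(fit, beta)
  rowSums(post[, fit$components$role == "negative", drop = FALSE])
}

#' Equivalent beta-score cutoff of a library
#'
#' Locates, by bisection, the score at which the LOF posterior `P(beta)`
#' crosses the calling threshold; scores below the cutoff are called
#' loss-of-function. `P(beta)` is checked numerically for monotone
#' non-increase over the bracketing interval; a violation (possible for
#' poorly separated fits) triggers a warning.
#'
#' @param fit A `be_mixture`.
#' @param threshold Posterior threshold (default 0.8).
#' @param tol Bisection tolerance (default 1e-8).
#' @return The equivalent beta cutoff (numeric scalar), or `NA` if the
#'   posterior never crosses the threshold.
#' @export
equivalent_beta_cutoff <- function(fit, threshold = 0.8, tol = 1e-8) {
  comp <- fit$components
  lo <- min(comp$mean) - 8 * sqrt(max(comp$variance))
  hi <- max(comp$mean[comp$role != "negative"], 0)
  grid <- seq(lo, hi, length.out = 512L)
  pg <- lof_posterior(fit, grid)
  if (any(diff(pg) > 1e-8)) {
    warning("LOF posterior is not monotone non-increasing over [",
            format(lo), ", ", format(hi), "]; ",
            "equivalent cutoff may not be unique", call. = FALSE)
  }
  if (lof_posterior(fit, lo) < threshold) return(NA_real_)
  if (lof_posterior(fit, hi) >= threshold) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (lof_posterior(fit, mid) > threshold) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Wald test and Benjamini-Hochberg adjustment
#'
#' `z = mean / SE` compared to the standard normal (two-sided), adjusted
#' with the BH step-up procedure across all scored variants. A zero SE
#' yields p = 0 when the mean is non-zero and p = 1 otherwise, with a
#' degenerate-SE flag.
#'
#' @param mean_beta Mean scores.
#' @param se_beta Standard errors (sd across replicates / sqrt(n)).
#' @return Tibble `z`, `p`, `bh_p`, `degenerate_se`.
#' @export
wald_bh <- function(mean_beta, se_beta) {
  degen <- !is.na(se_beta) & se_beta == 0
  z <- mean_beta / se_beta
  z[degen] <- ifelse(mean_beta[degen] != 0, sign(mean_beta[degen]) * Inf, 0)
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(z = z, p = p, bh_p = p.adjust(p, method = "BH"),
                 degenerate_se = degen)
}

#' Classify loss-of-function variants
#'
#' Fits the score mixture (unless a fit is supplied), computes each
#' variant's LOF posterior `P_i`, and calls loss-of-function when
#' `P_i > threshold` (strict inequality, default 0.8). Wald/BH significance
#' is reported alongside but does not gate the call.
#'
#' @param scores Score tibble from [beta_scores()] (uses rows with
#'   `scored == TRUE`), or a plain tibble with `guide_id` and `mean_beta`.
#' @param fit Optional pre-computed `be_mixture`.
#' @param threshold Posterior calling threshold (default 0.8).
#' @param seed,k,n_init Passed to [fit_score_mixture()].
#' @return List of class `be_classification`: `calls` tibble (`guide_id`,
#'   `mean_beta`, `P`, `lof_call`, `wald_p`, `bh_p`), the `fit`, the
#'   equivalent `beta_cutoff`, and `threshold`.
#' @export
classify_lof <- function(scores, fit = NULL, threshold = 0.8, seed = 1L,
                         k = 4L, n_init = 10L) {
  sc <- if ("scored" %in% names(scores)) {
    dplyr::filter(scores, .data$scored)
  } else {
    scores
  }
  if (is.null(fit)) {
    fit <- fit_score_mixture(sc$mean_beta, k = k, n_init = n_init,
                             seed = seed)
  }
  P <- lof_posterior(fit, sc$mean_beta)
  calls <- tibble::tibble(
    guide_id = sc$guide_id,
    mean_beta = sc$mean_beta,
    P = P,
    lof_call = P > threshold,
    wald_p = sc$wald_p %||% rep(NA_real_, nrow(sc)),
    bh_p = sc$bh_p %||% rep(NA_real_, nrow(sc))
  )
  structure(
    list(calls = calls, fit = fit,
         beta_cutoff = equivalent_beta_cutoff(fit, threshold),
         threshold = threshold),
    class = "be_classification"
  )
}

#' @export
print.be_classification <- function(x, ...) {
  cat("LOF classification: ", sum(x$calls$lof_call), " / ",
      nrow(x$calls), " variants called (P > ", x$threshold,
      "; equivalent beta cutoff ", format(round(x$beta_cutoff, 3)), ")\n",
      sep = "")
  invisible(x)
}

#' Mixture model-selection diagnostics
#'
#' Fits mixtures over a range of component counts and reports AIC/BIC.
#' K = 4 remains fixed for calling; this is a diagnostic only.
#'
#' @param scores Numeric score vector.
#' @param k_range Component counts to fit (default 2:6).
#' @param ... Passed to [fit_score_mixture()].
#' @return Tibble with `k`, `loglik`, `AIC`, `BIC`, `converged`.
#' @export
mixture_model_selection <- function(scores, k_range = 2:6, ...) {
  purrr::map_dfr(k_range, function(kk) {
    f <- suppressWarnings(tryCatch(
      fit_score_mixture(scores, k = kk, ...), error = function(e) NULL))
    if (is.null(f)) {
      return(tibble::tibble(k = kk, loglik = NA_real_, AIC = NA_real_,
                            BIC = NA_real_, converged = FALSE))
    }
    tibble::tibble(k = kk, loglik = f$loglik, AIC = f$AIC, BIC = f$BIC,
                   converged = f$converged)
  })
}

#' Evaluate LOF calls against labels and mutational types
#'
#' Per-category LOF fractions with two-sided Fisher exact tests (each
#' category versus the rest), and -- when clinical-style labels are given
#' (`"P/LP"` true positives, `"B/LB"` true negatives) -- a ROC analysis
#' over the continuous mean beta score plus the binary call's sensitivity
#' and specificity.
#'
#' @param classification A `be_classification` (or its `calls` tibble).
#' @param types Optional tibble `guide_id`, `mutational_type`.
#' @param labels Optional tibble `guide_id`, `label` in
#'   `{"P/LP", "B/LB", "VUS"}`.
#' @param at_specificity Report ROC sensitivity at these specificities.
#' @return List with `by_type` (fractions + Fisher p), `roc` (AUC,
#'   sensitivities, binary-call operating point) or `NULL`.
#' @export
evaluate_calls <- function(classification, types = NULL, labels = NULL,
                           at_specificity = c(0.8, 0.9)) {
  calls <- if (inherits(classification, "be_classification"))
    classification$calls else classification
  by_type <- NULL
  if (!is.null(types)) {
    x <- dplyr::inner_join(calls, types, by = "guide_id") |>
      dplyr::filter(!is.na(.data$mutational_type))
    by_type <- x |>
      dplyr::group_by(.data$mutational_type) |>
      dplyr::summarise(n = dplyr::n(), n_lof = sum(.data$lof_call),
                       lof_fraction = mean(.data$lof_call),
                       .groups = "drop")
    by_type$fisher_p <- vapply(by_type$mutational_type, function(tp) {
      a <- sum(x$lof_call & x$mutational_type == tp)
      b <- sum(!x$lof_call & x$mutational_type == tp)
      c_ <- sum(x$lof_call & x$mutational_type != tp)
      d <- sum(!x$lof_call & x$mutational_type != tp)
      fisher.test(matrix(c(a, b, c_, d), 2))$p.value
    }, numeric(1))
  }
  roc <- NULL
  if (!is.null(labels)) {
    x <- dplyr::inner_join(calls, labels, by = "guide_id")
    pos <- x$label == "P/LP"; neg <- x$label == "B/LB"
    if (!any(pos) || !any(neg)) {
      warning("a label class is empty; ROC skipped", call. = FALSE)
    } else if (!requireNamespace("pROC", quietly = TRUE)) {
      warning("pROC not installed; ROC skipped", call. = FALSE)
    } else {
      y <- x[pos | neg, ]
      r <- pROC::roc(response = factor(y$label, levels = c("B/LB", "P/LP")),
                     predictor = y$mean_beta, direction = ">",
                     quiet = TRUE)
      sens <- vapply(at_specificity, function(s)
        as.numeric(pROC::coords(r, x = s, input = "specificity",
                                ret = "sensitivity")), numeric(1))
      roc <- list(
        auc = as.numeric(pROC::auc(r)),
        sensitivity_at_specificity = setNames(sens,
                                              paste0("spec", at_specificity)),
        call_sensitivity = mean(y$lof_call[y$label == "P/LP"]),
        call_specificity = mean(!y$lof_call[y$label == "B/LB"]),
        roc = r
      )
    }
  }
  list(by_type = by_type, roc = roc)
}
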