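#' Plot the score distribution with fitted mixture components
#'
#' Histogram of the scores a mixture was fitted to, overlaid with the
#' weighted component densities and the equivalent beta cutoff (scores
#' below the dashed line are called loss-of-function at the fitted
#' threshold).
#'
#' @param object A `be_mixture`.
#' @param threshold Posterior threshold used for the cutoff line.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot be_mixture
#' @export
autoplot.be_mixture <- function(object, threshold = 0.8, bins = 60, ...) {
  x <- object$scores
  grid <- seq(min(x), max(x), length.out = 400)
  dens <- purrr::pmap_dfr(object$components, function(component, weight,
                                                      mean, variance, role) {
    tibble::tibble(component = factor(component), beta = grid,
                   density = weight * dnorm(grid, mean, sqrt(variance)),
                   role = role)
  })
  cutoff <- equivalent_beta_cutoff(object, threshold)
  p <- ggplot2::ggplot(tibble::tibble(beta = x),
                       ggplot2::aes(x = .data$beta)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85",
                            colour = "grey60") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component)) +
    ggplot2::labs(x = expression(beta ~ "score"), y = "density",
                  colour = "component") +
    ggplot2::theme_minimal()
  if (is.finite(cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed")
  }
  p
}

#' @rdname autoplot.be_mixture
#' @method autoplot be_classification
#' @export
autoplot.be_classification <- function(object, ...) {
  autoplot.be_mixture(object$fit, threshold = object$threshold, ...)
}

#' Fold change versus editing activity
#'
#' Scatter of control-relative ln fold change `d` against scaled editing
#' activity `q`, with a linear fit: under the growth model guides sharing
#' a fitness effect fall on a line of slope `l (e^f - 1)`, the basis of
#' the efficiency correction.
#'
#' @param fold_changes Fold-change tibble from [compute_fold_changes()].
#' @param activity Activity tibble from [scale_activity()].
#' @return A ggplot object.
#' @export
plot_activity_vs_foldchange <- function(fold_changes, activity) {
  x <- dplyr::inner_join(
    fold_changes, activity[, c("guide_id", "q_scaled")], by = "guide_id")
  ggplot2::ggplot(x, ggplot2::aes(x = .data$q_scaled, y = .data$d)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "scaled editing activity q",
                  y = "control-relative ln fold change d") +
    ggplot2::theme_minimal()
}

#' Replicate concordance of ln fold changes
#'
#' @param fold_changes Fold-change tibble (needs exactly two replicates).
#' @return A ggplot object.
#' @export
plot_replicate_concordance <- function(fold_changes) {
  reps <- sort(unique(fold_changes$replicate))
  stopifnot(length(reps) == 2L)
  wide <- fold_changes |>
    dplyr::select("guide_id", "replicate", "d") |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "d")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data[[reps[1]]],
                                     y = .data[[reps[2]]])) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = paste("d,", reps[1]), y = paste("d,", reps[2])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
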