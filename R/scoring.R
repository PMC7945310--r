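#' Harmonise measured and predicted editing efficiencies
#'
#' Rank-maps the predicted-efficiency distribution onto the measured one
#' (empirical quantile mapping with linear interpolation between order
#' statistics, average ranks for ties). Guides with a measured efficiency
#' keep it; guides with only a prediction receive the quantile-mapped
#' prediction; guides with neither are excluded from scoring.
#'
#' @param efficiency Tibble with `guide_id`, `q_raw` (measured; `NA` when
#'   unmeasured) and optionally `passed_filters`.
#' @param predictions Optional tibble with `guide_id`, `q_predicted`.
#' @return Tibble `guide_id`, `q_measured`, `q_predicted`, `q_corrected`,
#'   `q_source` (`"measured"`/`"predicted"`).
#' @export
quantile_harmonize <- function(efficiency, predictions = NULL) {
  eff <- tibble::tibble(
    guide_id = efficiency$guide_id,
    q_measured = efficiency$q_raw
  )
  if ("passed_filters" %in% names(efficiency)) {
    eff$q_measured[!efficiency$passed_filters] <- NA_real_
  }
  if (is.null(predictions)) {
    out <- eff |>
      dplyr::mutate(q_predicted = NA_real_,
                    q_corrected = .data$q_measured,
                    q_source = dplyr::if_else(is.na(.data$q_measured),
                                              NA_character_, "measured"))
    return(dplyr::filter(out, !is.na(.data$q_corrected)))
  }
  out <- dplyr::full_join(eff, predictions[, c("guide_id", "q_predicted")],
                          by = "guide_id")
  measured <- out$q_measured[!is.na(out$q_measured)]
  if (length(measured) < 2L && any(is.na(out$q_measured) &
                                   !is.na(out$q_predicted))) {
    stop("need >= 2 measured efficiencies to quantile-map predictions",
         call. = FALSE)
  }
  mapped <- quantile_map(out$q_predicted, measured)
  out |>
    dplyr::mutate(
      q_corrected = dplyr::coalesce(.data$q_measured, mapped),
      q_source = dplyr::case_when(
        !is.na(.data$q_measured) ~ "measured",
        !is.na(mapped) ~ "predicted",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::filter(!is.na(.data$q_corrected))
}

# empirical quantile mapping of x onto the distribution of `target`
quantile_map <- function(x, target) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  if (!any(ok) || length(target) == 0L) return(out)
  n <- sum(ok)
  if (n == 1L) {
    p <- 0.5
  } else {
    p <- (rank(x[ok], ties.method = "average") - 1) / (n - 1)
  }
  out[ok] <- unname(quantile(target, probs = p, type = 7, names = FALSE))
  out
}

#' Scale editing activities to the unit interval
#'
#' Linear min-max scaling of the harmonised efficiencies across the
#' library, giving the relative editing activity `q` used for efficiency
#' correction. Guides below `activity_threshold` after scaling carry a
#' low-activity flag and are excluded from classification when the
#' activity filter is enabled.
#'
#' @param harmonized Output of [quantile_harmonize()] (needs
#'   `q_corrected`).
#' @param activity_threshold Low-activity flag threshold (default 0.2).
#' @return Input with `q_scaled` and `low_activity_flag` columns.
#' @export
scale_activity <- function(harmonized, activity_threshold = 0.2) {
  q <- harmonized$q_corrected
  rng <- range(q, na.rm = TRUE)
  if (!(rng[2] > rng[1])) {
    stop("editing efficiencies are degenerate (max == min): ",
         "no dynamic range to scale", call. = FALSE)
  }
  harmonized |>
    dplyr::mutate(
      q_scaled = (.data$q_corrected - rng[1]) / (rng[2] - rng[1]),
      low_activity_flag = .data$q_scaled < activity_threshold
    )
}

#' Efficiency-corrected functional scores (beta scores)
#'
#' Computes `beta_ij = d_ij / q_i` per replicate, where `d` is the
#' control-relative ln fold change and `q` the scaled editing activity,
#' then the across-replicate mean, standard error, Wald test and BH
#' adjustment. Under the exponential growth model `beta` estimates
#' `l (e^f - 1)` -- proportional to the variant's fitness effect, in units
#' of the experiment constant `l`. Guides with `q` below `q_floor` are
#' unscorable (the ratio diverges as `q -> 0`); guides with the
#' low-activity flag are excluded when `activity_filter` is on.
#'
#' @param fold_changes Fold-change tibble from [compute_fold_changes()].
#' @param activity Activity tibble from [scale_activity()].
#' @param q_floor Minimum `q_scaled` for a defined score (default 0.05).
#' @param activity_filter Drop guides with `low_activity_flag` (default
#'   TRUE, matching the low-activity filtering applied to relaxed-PAM
#'   screens).
#' @return Score tibble: `guide_id`, per-replicate `beta` (long column),
#'   summarised `mean_beta`, `se_beta`, `n_reps`, `q_scaled`, `wald_z`,
#'   `wald_p`, `bh_p`, flags.
#' @export
beta_scores <- function(fold_changes, activity, q_floor = 0.05,
                        activity_filter = TRUE) {
  x <- fold_changes |>
    dplyr::filter(.data$control_class %in% "targeting" |
                    is.na(.data$control_class)) |>
    dplyr::inner_join(
      activity[, c("guide_id", "q_scaled", "low_activity_flag")],
      by = "guide_id")
  x <- x |>
    dplyr::mutate(
      unscorable_low_q = .data$q_scaled < q_floor,
      filtered_low_activity = activity_filter & .data$low_activity_flag,
      beta = dplyr::if_else(.data$unscorable_low_q, NA_real_,
                            .data$d / .data$q_scaled)
    )
  per_rep <- x |>
    dplyr::select("guide_id", "replicate", "d", "beta", "q_scaled",
                  "low_activity_flag", "unscorable_low_q",
                  "filtered_low_activity")
  summ <- per_rep |>
    dplyr::group_by(.data$guide_id) |>
    dplyr::summarise(
      mean_beta = mean(.data$beta),
      n_reps = sum(!is.na(.data$beta)),
      se_beta = sd(.data$beta) / sqrt(.data$n_reps),
      q_scaled = .data$q_scaled[1],
      low_activity_flag = .data$low_activity_flag[1],
      unscorable_low_q = .data$unscorable_low_q[1],
      filtered_low_activity = .data$filtered_low_activity[1],
      .groups = "drop"
    )
  scored <- !summ$unscorable_low_q & !summ$filtered_low_activity &
    summ$n_reps >= 2L
  wt <- wald_bh(summ$mean_beta[scored], summ$se_beta[scored])
  summ$wald_z <- summ$wald_p <- summ$bh_p <- NA_real_
  summ$wald_z[scored] <- wt$z
  summ$wald_p[scored] <- wt$p
  summ$bh_p[scored] <- wt$bh_p
  summ$scored <- scored
  attr(summ, "per_replicate") <- per_rep
  summ
}

#' Linear-approximation diagnostic for the growth model
#'
#' Under exponential growth the exact control-relative ln fold change is
#' `d = ln(1 + p (e^f - 1))` with `p = q l`; the scoring model uses the
#' linearisation `d ~ p (e^f - 1) = q beta*`. This diagnostic reports both
#' quantities and their absolute and relative differences so users can
#' check the linear regime for their effect sizes: the absolute error is
#' below 0.03 whenever `|p (e^f - 1)| < 0.2`, while the relative error
#' stays below 3% only for `|p (e^f - 1)| < ~0.058`.
#'
#' @param p Fraction of cells carrying the variant (`q * l`).
#' @param exp_f Relative fitness `e^f` of the variant.
#' @return Tibble with `x = p*(e^f - 1)`, `exact`, `linear`, `abs_err`,
#'   `rel_err`.
#' @export
linearity_diagnostic <- function(p, exp_f) {
  x <- p * (exp_f - 1)
  exact <- log1p(x)
  tibble::tibble(
    p = p, exp_f = exp_f, x = x,
    exact = exact, linear = x,
    abs_err = abs(exact - x),
    rel_err = ifelse(exact == 0, 0, abs(exact - x) / abs(exact))
  )
}
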