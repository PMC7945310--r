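#' Count guides in screen reads
#'
#' Exact 20-mer spacer matching, either at a fixed read offset or by
#' scanning the whole read. Each read increments at most one guide; reads
#' matching no spacer, or more than one, are tallied as unmatched.
#'
#' @param reads Tibble with `sample_id`, `seq` (one row per read), or a
#'   character vector of sequences for a single sample.
#' @param guides Guide library with unique `spacer` values.
#' @param method `"offset"` (spacer at a fixed position) or `"scan"`.
#' @param offset 1-based read position of the spacer for `method="offset"`.
#' @return Tibble `guide_id` x `sample_id` with raw `count` (all guides
#'   present, zero-filled), plus an `unmatched` attribute per sample.
#' @export
count_guides <- function(reads, guides, method = c("offset", "scan"),
                         offset = 1L) {
  method <- match.arg(method)
  stopifnot(!anyDuplicated(guides$spacer))
  if (is.character(reads)) {
    reads <- tibble::tibble(sample_id = "sample1", seq = reads)
  }
  samples <- unique(reads$sample_id)
  res <- list(); unm <- setNames(integer(length(samples)), samples)
  for (s in samples) {
    sq <- toupper(reads$seq[reads$sample_id == s])
    if (length(sq) == 0L) {
      warning("no reads for sample ", s, call. = FALSE)
      hit <- integer(0)
    } else if (method == "offset") {
      hit <- match(substring(sq, offset, offset + 19L), guides$spacer)
    } else {
      nhit <- integer(length(sq))
      hit <- rep(NA_integer_, length(sq))
      for (k in seq_along(guides$spacer)) {
        has <- stringr::str_detect(sq, stringr::fixed(guides$spacer[k]))
        nhit <- nhit + has
        hit[has] <- k
      }
      hit[nhit != 1L] <- NA_integer_   # ambiguous reads stay unmatched
    }
    unm[s] <- sum(is.na(hit))
    cnt <- tabulate(hit, nbins = nrow(guides))
    res[[s]] <- tibble::tibble(guide_id = guides$guide_id, sample_id = s,
                               count = cnt)
  }
  out <- dplyr::bind_rows(res)
  attr(out, "unmatched") <- unm
  out
}

#' Normalise screen counts with negative-control anchoring
#'
#' Median-of-ratio style normalisation with the constant `w_j` estimated as
#' the geometric mean of the (pseudocounted) read counts of all
#' non-targeting negative-control guides in sample `j`; normalised count =
#' `(raw + pseudocount) / w_j`. Essential-stop controls are never used for
#' normalisation.
#'
#' @param counts Long count tibble (`guide_id`, `sample_id`, `count`).
#' @param guides Guide library with `control_class`.
#' @param pseudocount Added to every raw count before normalisation
#'   (default 1, avoiding `ln(0)` for dropped-out guides).
#' @return `counts` with `w` and `norm_count` columns.
#' @export
normalize_counts <- function(counts, guides, pseudocount = 1) {
  neg <- guides$guide_id[guides$control_class == "non_targeting"]
  if (length(neg) == 0L) {
    stop("no non-targeting negative-control guides: ",
         "normalisation is control-anchored", call. = FALSE)
  }
  w <- counts |>
    dplyr::filter(.data$guide_id %in% neg) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(w = exp(mean(log(.data$count + pseudocount))),
                     .groups = "drop")
  if (any(!unique(counts$sample_id) %in% w$sample_id)) {
    stop("sample(s) without negative-control counts", call. = FALSE)
  }
  counts |>
    dplyr::left_join(w, by = "sample_id") |>
    dplyr::mutate(norm_count = (.data$count + pseudocount) / .data$w)
}

#' Control-relative ln fold changes
#'
#' For each guide and replicate computes `ln(C/S)` between the endpoint and
#' day-0 normalised counts, the replicate growth baseline `b_hat` (median
#' `ln(C/S)` over non-targeting controls), and the control-relative
#' `d = ln(C/S) - b_hat`, so the median `d` over negative controls is
#' exactly 0 in every replicate.
#'
#' @param norm_counts Output of [normalize_counts()].
#' @param samples Sample sheet: `sample_id`, `timepoint`
#'   (`"day0"`/`"dayN"`), `replicate`.
#' @param guides Guide library with `control_class`.
#' @return Fold-change tibble: `guide_id`, `replicate`, `S`, `C`, `ln_fc`,
#'   `b_hat`, `d`, `control_class`.
#' @export
compute_fold_changes <- function(norm_counts, samples, guides) {
  stopifnot(all(c("sample_id", "timepoint", "replicate") %in% names(samples)))
  x <- norm_counts |>
    dplyr::left_join(samples, by = "sample_id") |>
    dplyr::select("guide_id", "timepoint", "replicate", "norm_count") |>
    tidyr::pivot_wider(names_from = "timepoint",
                       values_from = "norm_count")
  stopifnot(all(c("day0", "dayN") %in% names(x)))
  neg <- guides$guide_id[guides$control_class == "non_targeting"]
  x |>
    dplyr::rename(S = "day0", C = "dayN") |>
    dplyr::mutate(ln_fc = log(.data$C / .data$S)) |>
    dplyr::group_by(.data$replicate) |>
    dplyr::mutate(b_hat = median(.data$ln_fc[.data$guide_id %in% neg])) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      d = .data$ln_fc - .data$b_hat,
      control_class = guides$control_class[match(.data$guide_id,
                                                 guides$guide_id)]
    )
}

#' Quantify a screen from counts to control-relative fold changes
#'
#' Convenience wrapper: [normalize_counts()] then
#' [compute_fold_changes()].
#'
#' @inheritParams normalize_counts
#' @inheritParams compute_fold_changes
#' @return Fold-change tibble (see [compute_fold_changes()]).
#' @export
quantify_screen <- function(counts, samples, guides, pseudocount = 1) {
  nc <- normalize_counts(counts, guides, pseudocount)
  compute_fold_changes(nc, samples, guides)
}
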