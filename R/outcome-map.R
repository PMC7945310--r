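#' Jaro string similarity
#'
#' Standard Jaro similarity: characters match within a window of
#' `floor(max(|a|,|b|)/2) - 1`, and the score is
#' `(m/|a| + m/|b| + (m - t)/m) / 3` with `m` matches and `t` half the
#' number of out-of-order matched characters. Reads whose observed spacer
#' and the protospacer embedded in their target segment score below 0.75
#' are treated as recombination artifacts and removed.
#'
#' @param a,b Character vectors (recycled to common length).
#' @return Numeric vector of similarities in `[0, 1]`. An empty string
#'   scores 0 against a non-empty string and 1 against another empty string.
#' @export
jaro_similarity <- function(a, b) {
  n <- max(length(a), length(b))
  jaro_cpp(rep_len(as.character(a), n), rep_len(as.character(b), n))
}

#' Anchor reads on the sgRNA scaffold and extract spacer/target
#'
#' Locates the scaffold in each read by sliding-window Hamming distance
#' (no indels), keeping the best position. Reads are rejected when the best
#' distance exceeds `max_mismatch`, when two positions tie for best, or
#' when the flanks are too short for a full spacer (20 nt, 5' of the
#' scaffold) or target segment (`target_len` nt, 3' of the scaffold).
#'
#' @param reads Tibble with `read_id` and `seq` columns (optionally
#'   `sample_id`), or a character vector of read sequences.
#' @param scaffold Scaffold sequence; default the standard SpCas9 scaffold.
#' @param max_mismatch Maximum scaffold mismatches (default 3).
#' @param spacer_len Spacer length extracted 5' of the scaffold.
#' @param target_len Target segment length extracted 3' of the scaffold
#'   (default 26: 3 nt flank + 20 nt protospacer + 3 nt PAM).
#' @return The input tibble with columns `spacer_obs`, `target_obs`,
#'   `scaffold_mismatches`, `kept`, `reject_reason` added.
#' @export
anchor_and_extract <- function(reads, scaffold = SGRNA_SCAFFOLD,
                               max_mismatch = 3L, spacer_len = 20L,
                               target_len = 26L) {
  stopifnot(nchar(scaffold) >= 20L)
  if (is.character(reads)) {
    reads <- tibble::tibble(read_id = paste0("read", seq_along(reads)),
                            seq = reads)
  }
  seqs <- toupper(reads$seq)
  n <- length(seqs)
  slen <- nchar(scaffold)
  start <- rep(NA_integer_, n)
  mm <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)

  subj <- Biostrings::DNAStringSet(seqs)
  hits <- Biostrings::vmatchPattern(scaffold, subj,
                                    max.mismatch = max_mismatch, fixed = TRUE)
  starts_list <- Biostrings::startIndex(hits)
  widths <- nchar(seqs)
  nhit <- lengths(starts_list)
  reason[nhit == 0L] <- "no_scaffold"

  # fast path: a single in-bounds candidate position
  single <- which(nhit == 1L)
  if (length(single)) {
    st1 <- unlist(starts_list[single], use.names = FALSE)
    inb <- st1 >= 1L & st1 + slen - 1L <= widths[single]
    reason[single[!inb]] <- "no_scaffold"
    single <- single[inb]; st1 <- st1[inb]
    start[single] <- st1
    mm[single] <- hamming_to(substring(seqs[single], st1, st1 + slen - 1L),
                             scaffold)
  }
  # rare path: several candidates, keep a unique best by Hamming distance
  multi <- which(nhit > 1L)
  pat <- Biostrings::DNAString(scaffold)
  for (i in multi) {
    st <- starts_list[[i]]
    st <- st[st >= 1L & st + slen - 1L <= widths[i]]
    if (!length(st)) { reason[i] <- "no_scaffold"; next }
    d <- hamming_to(substring(seqs[i], st, st + slen - 1L), scaffold)
    best <- min(d)
    at <- st[d == best]
    if (length(at) > 1L) { reason[i] <- "ambiguous_scaffold"; next }
    start[i] <- at
    mm[i] <- best
  }

  ok <- !is.na(start)
  short5 <- ok & (start - 1L < spacer_len)
  short3 <- ok & (widths - (start + slen - 1L) < target_len)
  reason[short5] <- "short_5prime_flank"
  reason[short3 & !short5] <- "short_3prime_flank"
  keep <- ok & !short5 & !short3

  reads$spacer_obs <- ifelse(keep,
    substring(seqs, start - spacer_len, start - 1L), NA_character_)
  reads$target_obs <- ifelse(keep,
    substring(seqs, start + slen, start + slen + target_len - 1L),
    NA_character_)
  reads$scaffold_mismatches <- mm
  reads$kept <- keep
  reads$reject_reason <- reason
  reads
}

# vectorised Hamming distance of equal-length strings against one pattern
hamming_to <- function(x, pattern) {
  if (!length(x)) return(integer(0))
  pc <- utf8ToInt(pattern)
  m <- matrix(unlist(lapply(x, utf8ToInt), use.names = FALSE),
              ncol = length(pc), byrow = TRUE)
  as.integer(rowSums(sweep(m, 2, pc, FUN = "!=")))
}

#' Remove recombinant reads by Jaro similarity
#'
#' Compares each read's observed spacer with the protospacer embedded in its
#' target segment; reads with similarity below `threshold` are flagged as
#' recombinants (spacer and target from different library members) and
#' dropped.
#'
#' @param records Output of [anchor_and_extract()] (kept records).
#' @param threshold Similarity threshold (default 0.75).
#' @param flank Target-segment upstream flank length (default 3).
#' @return `records` with `jaro` and `recombinant` columns; recombinants
#'   have `kept = FALSE`, `reject_reason = "recombinant"`.
#' @export
filter_recombinants <- function(records, threshold = 0.75, flank = 3L) {
  emb <- substring(records$target_obs, flank + 1L, flank + 20L)
  j <- rep(NA_real_, nrow(records))
  idx <- which(records$kept)
  j[idx] <- jaro_similarity(records$spacer_obs[idx], emb[idx])
  rec <- !is.na(j) & j < threshold
  records$jaro <- j
  records$recombinant <- rec
  records$kept[rec] <- FALSE
  records$reject_reason[rec] <- "recombinant"
  records
}

#' Assign extracted reads to designed guides
#'
#' Exact spacer matches are assigned directly. Remaining reads are assigned
#' to the nearest library spacer by Hamming distance when identity is at
#' least `identity` (<= 3 mismatches over 20 nt at the default 0.85) and the
#' read's PAM is consistent with the designed PAM class. Distance ties and
#' failures are left unassigned.
#'
#' @param records Output of [filter_recombinants()].
#' @param guides Guide library tibble with unique `spacer` values.
#' @param identity Minimum spacer identity for inexact assignment.
#' @param flank Target-segment upstream flank length.
#' @return `records` with a `guide_id` column (NA when unassigned).
#' @export
assign_to_library <- function(records, guides, identity = 0.85, flank = 3L) {
  stopifnot(!anyDuplicated(guides$spacer))
  max_mm <- floor((1 - identity) * 20)
  gid <- rep(NA_character_, nrow(records))
  idx <- which(records$kept)
  sp <- records$spacer_obs[idx]
  hit <- match(sp, guides$spacer)
  gid[idx] <- guides$guide_id[hit]

  todo <- idx[is.na(hit)]
  if (length(todo)) {
    lib_mat <- vapply(guides$spacer, function(s) utf8ToInt(s), integer(20))
    uq <- unique(records$spacer_obs[todo])
    uq <- uq[nchar(uq) == 20L]
    assign_uq <- setNames(rep(NA_character_, length(uq)), uq)
    pam_ok_fun <- function(p, cls) {
      if (is.na(cls) || is.na(p) || nchar(p) < 3L) return(FALSE)
      ch <- strsplit(p, "")[[1]]
      ok <- ch[1] %in% c("A", "C", "G", "T") && ch[2] == "G"
      if (cls == "NGG") ok <- ok && ch[3] == "G"
      ok
    }
    for (u in uq) {
      d <- colSums(lib_mat != utf8ToInt(u))
      best <- min(d)
      if (best > max_mm) next
      cand <- which(d == best)
      if (length(cand) != 1L) next
      assign_uq[u] <- guides$guide_id[cand]
    }
    cand_gid <- assign_uq[records$spacer_obs[todo]]
    # PAM of the read: last 3 nt of the target segment
    read_pam <- substring(records$target_obs[todo], flank + 21L, flank + 23L)
    cls <- guides$pam_class[match(cand_gid, guides$guide_id)]
    pam_ok <- mapply(pam_ok_fun, read_pam, cls)
    cand_gid[!pam_ok] <- NA_character_
    gid[todo] <- unname(cand_gid)
  }
  records$guide_id <- gid
  records
}

#' Call editing outcomes for reads of one guide
#'
#' Compares target segments positionally to the guide's reference target
#' (no indels). A read carrying the editor's canonical transition (C->T for
#' CBE, A->G for ABE, protospacer strand) at any window position is called
#' an edit; its outcome key enumerates the converted window positions.
#' Reads with no mismatch are `"unedited"`; reads with only non-canonical
#' mismatches are `"other"` (they count toward the guide's read total but
#' never toward an outcome). Reads whose target length differs from the
#' reference are rejected (`NA`).
#'
#' @param target_obs Character vector of observed target segments.
#' @param target_ref The guide's reference target segment.
#' @param editor `"CBE"` or `"ABE"`.
#' @param window Editing window in protospacer coordinates.
#' @param flank Upstream flank length in the target segment.
#' @return Character vector: outcome key (e.g. `"p5:C>T"`, multi-position
#'   keys joined with `+`), `"unedited"`, `"other"`, or `NA` for rejected
#'   reads.
#' @export
call_edits <- function(target_obs, target_ref, editor = c("CBE", "ABE"),
                       window = c(4L, 8L), flank = 3L) {
  editor <- match.arg(editor)
  tr <- EDITOR_TRANSITIONS[[editor]]
  n <- length(target_obs)
  out <- rep(NA_character_, n)
  ok <- !is.na(target_obs) & nchar(target_obs) == nchar(target_ref)
  if (!any(ok)) return(out)
  obs <- target_obs[ok]
  ref_ch <- strsplit(target_ref, "", fixed = TRUE)[[1]]
  m <- matrix(unlist(strsplit(obs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(obs), byrow = TRUE)
  mism <- sweep(m, 2, ref_ch, FUN = "!=")
  any_mm <- rowSums(mism) > 0L
  win_pos <- flank + seq(window[1], window[2])   # segment positions
  editable <- win_pos[ref_ch[win_pos] == tr[["ref"]]]
  keys <- rep("other", length(obs))
  keys[!any_mm] <- "unedited"
  if (length(editable)) {
    conv <- matrix(FALSE, nrow = length(obs), ncol = length(editable))
    for (k in seq_along(editable)) {
      conv[, k] <- m[, editable[k]] == tr[["alt"]]
    }
    has_edit <- rowSums(conv) > 0L
    if (any(has_edit)) {
      offs <- editable - flank
      lab <- sprintf("p%d:%s>%s", offs, tr[["ref"]], tr[["alt"]])
      keys[has_edit] <- apply(conv[has_edit, , drop = FALSE], 1, function(z)
        paste(lab[z], collapse = "+"))
    }
  }
  out[ok] <- keys
  out
}

#' Tally outcome read counts per guide and sample
#'
#' @param records Assigned records (from [assign_to_library()]) with an
#'   `outcome_key` column (from [call_edits()]) and `sample_id`.
#' @return Tibble with `guide_id`, `sample_id`, `outcome_key`, `R` (reads
#'   with the outcome) and `D` (total assigned reads for the guide in the
#'   sample, including `"unedited"` and `"other"` reads).
#' @export
tally_outcomes <- function(records) {
  kept <- dplyr::filter(records, .data$kept, !is.na(.data$guide_id),
                        !is.na(.data$outcome_key))
  totals <- kept |>
    dplyr::count(.data$guide_id, .data$sample_id, name = "D")
  keycounts <- kept |>
    dplyr::count(.data$guide_id, .data$sample_id, .data$outcome_key,
                 name = "R") |>
    dplyr::filter(!.data$outcome_key %in% c("unedited", "other"))
  # complete grid: every observed outcome of a guide appears for every
  # sample in which the guide has reads (R = 0 where unobserved), so
  # zero-count samples enter the background and fraction means
  keys <- dplyr::distinct(keycounts, .data$guide_id, .data$outcome_key)
  dplyr::inner_join(keys, totals, by = "guide_id",
                    relationship = "many-to-many") |>
    dplyr::left_join(keycounts,
                     by = c("guide_id", "outcome_key", "sample_id")) |>
    dplyr::mutate(R = dplyr::coalesce(.data$R, 0L)) |>
    dplyr::select("guide_id", "sample_id", "outcome_key", "R", "D")
}

#' Background-corrected outcome fraction
#'
#' Implements the corrected fraction
#' `f_k = mean_j{ (R_kj - D_j h_c) / (D_j - D_j h_c) }` over edited samples
#' with `D_j > 0`, where `h_c` is the outcome's background error frequency
#' estimated from control (unedited) samples. Per-sample fractions are
#' clamped to `[0, 1]`.
#'
#' @param R Integer vector of outcome read counts per edited sample.
#' @param D Integer vector of total read counts per edited sample.
#' @param h_c Background error frequency in `[0, 1)`.
#' @return The corrected fraction, or `NA` when no sample has `D > 0`.
#' @export
outcome_fraction <- function(R, D, h_c = 0) {
  stopifnot(length(R) == length(D), h_c >= 0, h_c < 1)
  use <- D > 0
  if (!any(use)) return(NA_real_)
  f <- (R[use] - D[use] * h_c) / (D[use] - D[use] * h_c)
  mean(pmin(pmax(f, 0), 1))
}

#' Quantify outcomes with background correction across samples
#'
#' Computes, for every (guide, outcome): `h_c` (mean outcome fraction in
#' control samples; 0 when absent from controls), per-edited-sample
#' corrected fractions, and the averaged corrected fraction `f_k`.
#'
#' @param tallies Output of [tally_outcomes()].
#' @param samples Sample sheet tibble: `sample_id`, `condition`
#'   (`"edited"`/`"control"`), `replicate`.
#' @return Tibble with one row per guide/outcome/edited sample
#'   (`guide_id`, `outcome_key`, `sample_id`, `replicate`, `R`, `D`,
#'   `h_c`, `f_sample`) plus the across-sample mean `f_k`.
#' @export
outcome_fractions <- function(tallies, samples) {
  stopifnot(all(c("sample_id", "condition", "replicate") %in% names(samples)))
  tl <- dplyr::left_join(tallies, samples, by = "sample_id")
  h <- tl |>
    dplyr::filter(.data$condition == "control", .data$D > 0) |>
    dplyr::group_by(.data$guide_id, .data$outcome_key) |>
    dplyr::summarise(h_c = mean(.data$R / .data$D), .groups = "drop")
  tl |>
    dplyr::filter(.data$condition == "edited", .data$D > 0) |>
    dplyr::left_join(h, by = c("guide_id", "outcome_key")) |>
    dplyr::mutate(
      h_c = dplyr::coalesce(.data$h_c, 0),
      f_sample = pmin(pmax(
        (.data$R - .data$D * .data$h_c) / (.data$D - .data$D * .data$h_c),
        0), 1)
    ) |>
    dplyr::group_by(.data$guide_id, .data$outcome_key) |>
    dplyr::mutate(f_k = mean(.data$f_sample)) |>
    dplyr::ungroup()
}

#' Merge outcomes and pick each guide's major outcome
#'
#' Coding outcomes with identical amino-acid changes are merged (fractions
#' and read counts summed); noncoding outcomes are merged at identical
#' nucleotide changes. The major outcome is the merged outcome with the
#' highest fraction, ties broken by fewer edited positions then
#' lexicographic key. The measured efficiency `q_raw` is the major
#' outcome's corrected fraction averaged over edited replicates. A guide
#' fails the coverage filters only when, in every replicate, its major
#' outcome has coverage below `min_coverage` reads or frequency below
#' `min_frequency`.
#'
#' @param fractions Output of [outcome_fractions()].
#' @param annotations Optional tibble mapping (`guide_id`, `outcome_key`) to
#'   `aa_changes` and `mutational_type` (from [annotate_outcomes()]); when
#'   `NULL` all outcomes merge at the nucleotide level.
#' @param min_coverage,min_frequency Per-replicate filter thresholds
#'   (defaults 30 reads and 0.005).
#' @return A list with `outcomes` (merged outcomes, `is_major` flag) and
#'   `efficiency` (per guide: `q_raw`, per-replicate coverage and
#'   frequency, `passed_filters`).
#' @export
merge_and_pick_major <- function(fractions, annotations = NULL,
                                 min_coverage = 30L, min_frequency = 0.005) {
  fr <- fractions
  if (!is.null(annotations)) {
    fr <- dplyr::left_join(
      fr, annotations[, c("guide_id", "outcome_key", "aa_changes",
                          "mutational_type")],
      by = c("guide_id", "outcome_key"))
  } else {
    fr$aa_changes <- NA_character_
    fr$mutational_type <- NA_character_
  }
  coding_types <- c("stop_gain", "nonsynonymous", "synonymous")
  fr <- fr |>
    dplyr::mutate(
      merge_key = dplyr::if_else(
        !is.na(.data$mutational_type) &
          .data$mutational_type %in% coding_types,
        paste0("aa:", dplyr::coalesce(.data$aa_changes, "")),
        paste0("nt:", .data$outcome_key)),
      n_positions = stringr::str_count(.data$outcome_key,
                                       stringr::fixed("+")) + 1L
    )

  merged <- fr |>
    dplyr::group_by(.data$guide_id, .data$merge_key, .data$sample_id,
                    .data$replicate) |>
    dplyr::summarise(
      R_sum = sum(.data$R), D_tot = .data$D[1],
      f_sum = pmin(sum(.data$f_sample), 1),
      nt_keys = paste(sort(unique(.data$outcome_key)), collapse = ";"),
      aa_merged = .data$aa_changes[1],
      mt_merged = merged_type(.data$mutational_type),
      npos_min = min(.data$n_positions),
      rep_key = .data$outcome_key[order(-.data$f_k, .data$n_positions,
                                        .data$outcome_key)][1],
      .groups = "drop"
    ) |>
    dplyr::rename(R = "R_sum", D = "D_tot", f_sample = "f_sum",
                  nucleotide_changes = "nt_keys", aa_changes = "aa_merged",
                  mutational_type = "mt_merged", n_positions = "npos_min",
                  outcome_key = "rep_key") |>
    dplyr::group_by(.data$guide_id, .data$merge_key) |>
    dplyr::mutate(f_merged = mean(.data$f_sample)) |>
    dplyr::ungroup()

  # winner per guide among merged outcomes: highest mean fraction, ties by
  # fewer edited positions then lexicographic representative key
  winners <- merged |>
    dplyr::distinct(.data$guide_id, .data$merge_key, .data$f_merged) |>
    dplyr::left_join(
      merged |>
        dplyr::group_by(.data$guide_id, .data$merge_key) |>
        dplyr::summarise(n_positions = min(.data$n_positions),
                         rep_key = min(.data$outcome_key), .groups = "drop"),
      by = c("guide_id", "merge_key")) |>
    dplyr::group_by(.data$guide_id) |>
    dplyr::arrange(dplyr::desc(.data$f_merged), .data$n_positions,
                   .data$rep_key, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select("guide_id", "merge_key") |>
    dplyr::mutate(is_major = TRUE)

  per_outcome <- merged |>
    dplyr::left_join(winners, by = c("guide_id", "merge_key")) |>
    dplyr::mutate(is_major = dplyr::coalesce(.data$is_major, FALSE))

  eff <- per_outcome |>
    dplyr::filter(.data$is_major) |>
    dplyr::group_by(.data$guide_id) |>
    dplyr::summarise(
      outcome_key = .data$outcome_key[1],
      nucleotide_changes = .data$nucleotide_changes[1],
      aa_changes = .data$aa_changes[1],
      mutational_type = .data$mutational_type[1],
      q_raw = mean(.data$f_sample),
      coverage_by_rep = paste(sprintf("%s=%d", .data$replicate, .data$R),
                              collapse = ";"),
      frequency_by_rep = paste(sprintf("%s=%.6g", .data$replicate,
                                       .data$f_sample), collapse = ";"),
      min_coverage_obs = min(.data$R),
      passed_filters = !all(.data$R < min_coverage |
                              .data$f_sample < min_frequency),
      .groups = "drop"
    )
  list(outcomes = per_outcome, efficiency = eff)
}

merged_type <- function(types) {
  types <- types[!is.na(types)]
  if (!length(types)) return(NA_character_)
  MUTATIONAL_TYPE_PRIORITY[min(match(types, MUTATIONAL_TYPE_PRIORITY))]
}

#' Map editing outcomes and efficiencies from paired guide-target reads
#'
#' End-to-end outcome mapping: scaffold anchoring, recombinant filtering,
#' library assignment, edit calling, background-corrected fractions,
#' amino-acid-level merging, and major-outcome/efficiency extraction.
#'
#' @param reads Tibble with `sample_id`, `read_id`, `seq`.
#' @param samples Sample sheet (`sample_id`, `condition`, `replicate`).
#' @param guides Guide library with `target_ref` (see [guide_targets()]).
#' @param transcripts Optional transcript model (see [transcript_model()])
#'   for amino-acid annotation; requires reference sequences in `refs`.
#' @param refs Optional references (for annotation).
#' @param scaffold,max_mismatch,window,flank,jaro_threshold,identity
#'   Stage parameters; see the stage functions.
#' @param min_coverage,min_frequency Major-outcome filter thresholds.
#' @return A list with `outcomes`, `efficiency`, `records` (per-read
#'   bookkeeping) and `stats` (read-level counts).
#' @export
map_outcomes <- function(reads, samples, guides, transcripts = NULL,
                         refs = NULL, scaffold = SGRNA_SCAFFOLD,
                         max_mismatch = 3L, window = c(4L, 8L), flank = 3L,
                         jaro_threshold = 0.75, identity = 0.85,
                         min_coverage = 30L, min_frequency = 0.005) {
  stopifnot("target_ref" %in% names(guides))
  target_len <- nchar(guides$target_ref[1])
  rec <- anchor_and_extract(reads, scaffold, max_mismatch,
                            target_len = target_len)
  rec <- filter_recombinants(rec, jaro_threshold, flank)
  rec <- assign_to_library(rec, guides, identity, flank)
  rec$outcome_key <- NA_character_
  for (g in unique(rec$guide_id[!is.na(rec$guide_id)])) {
    idx <- which(rec$guide_id == g & rec$kept)
    tref <- guides$target_ref[guides$guide_id == g]
    ed <- guides$editor_class[guides$guide_id == g]
    rec$outcome_key[idx] <- call_edits(rec$target_obs[idx], tref, ed,
                                       window, flank)
  }
  tallies <- tally_outcomes(rec)
  fracs <- outcome_fractions(tallies, samples)
  ann <- NULL
  if (!is.null(transcripts) && !is.null(refs)) {
    ann <- annotate_outcomes(dplyr::distinct(fracs, .data$guide_id,
                                             .data$outcome_key),
                             guides, transcripts, refs, flank)
  }
  res <- merge_and_pick_major(fracs, ann, min_coverage, min_frequency)
  stats <- tibble::tibble(
    n_reads = nrow(rec),
    n_kept = sum(rec$kept),
    n_recombinant = sum(rec$recombinant, na.rm = TRUE),
    n_unassigned = sum(rec$kept & is.na(rec$guide_id))
  )
  c(res, list(records = rec, stats = stats))
}
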