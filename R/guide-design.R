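#' Enumerate base-editor sgRNAs over reference sequences
#'
#' Scans both strands of the supplied references for every targetable base
#' (C for a cytosine base editor, A for an adenine base editor) that lies in
#' the editing window -- protospacer positions 4-8, i.e. 13-17 bp upstream of
#' an `NGG` or `NG` PAM. When several candidate protospacers cover the same
#' base, the one placing the base farthest from the PAM (minimal target
#' offset) is selected. Guides selected by more than one base are collapsed
#' to a single row keeping the most PAM-distal intended base, so no two rows
#' share `(contig, protospacer_start, strand)`.
#'
#' @param refs References accepted by [as_reference_tbl()].
#' @param editor `"CBE"` (C.G -> T.A) or `"ABE"` (A.T -> G.C).
#' @param pam PAM class, `"NGG"` or `"NG"`.
#' @param window Integer length-2: editing window in protospacer coordinates
#'   (1 = PAM-distal end). Default `c(4, 8)`.
#' @return A tibble (one row per designed guide) with columns `guide_id`,
#'   `contig`, `protospacer_start` (0-based half-open), `strand`, `spacer`,
#'   `pam`, `target_offset`, `target_pos` (0-based position of the intended
#'   base on the forward strand), `editor_class`, `pam_class`, `is_unique`
#'   (NA until [filter_unique()]), `control_class`.
#' @seealso [filter_unique()], [guide_targets()], [write_guide_library()]
#' @export
design_guides <- function(refs, editor = c("CBE", "ABE"),
                          pam = c("NGG", "NG"), window = c(4L, 8L)) {
  editor <- match.arg(editor)
  pam <- match.arg(pam)
  stopifnot(length(window) == 2L, window[1] >= 1L, window[2] <= 20L,
            window[1] <= window[2])
  refs <- as_reference_tbl(refs)
  base <- EDITOR_TRANSITIONS[[editor]][["ref"]]

  rows <- purrr::pmap(refs, function(id, seq) {
    L <- nchar(seq)
    fw <- scan_strand(seq, base, pam, window)
    rv <- scan_strand(revcomp(seq), base, pam, window)
    out <- list()
    if (nrow(fw)) {
      fw$strand <- "+"
      fw$protospacer_start <- fw$start1 - 1L
      fw$target_pos <- fw$target1 - 1L
      out <- c(out, list(fw))
    }
    if (nrow(rv)) {
      rv$strand <- "-"
      # position i (1-based) on the reverse strand maps to forward
      # position L - i + 1 (1-based); protospacer occupies [i, i+19]
      rv$protospacer_start <- L - (rv$start1 + 19L)
      rv$target_pos <- L - rv$target1
      out <- c(out, list(rv))
    }
    if (!length(out)) return(NULL)
    res <- dplyr::bind_rows(out)
    res$contig <- id
    res
  })
  rows <- dplyr::bind_rows(rows)
  if (nrow(rows) == 0L) {
    return(empty_guide_tbl(editor, pam))
  }

  # one guide per protospacer: keep the most PAM-distal intended base
  rows <- rows |>
    dplyr::group_by(.data$contig, .data$protospacer_start, .data$strand) |>
    dplyr::arrange(.data$target_offset, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$contig, .data$protospacer_start, .data$strand)

  editor_arg <- editor
  pam_arg <- pam
  tibble::tibble(
    guide_id = sprintf(
      "%s_%d_%s", rows$contig, rows$protospacer_start + 1L,
      ifelse(rows$strand == "+", "fw", "rv")
    ),
    contig = rows$contig,
    protospacer_start = rows$protospacer_start,
    strand = rows$strand,
    spacer = rows$spacer,
    pam = rows$pam,
    target_offset = rows$target_offset,
    target_pos = rows$target_pos,
    editor_class = editor_arg,
    pam_class = pam_arg,
    is_unique = NA,
    control_class = "targeting"
  )
}

# Scan one strand-oriented sequence. Returns 1-based strand-local
# coordinates: start1 (protospacer start), target1 (intended base).
scan_strand <- function(s, base, pam, window) {
  L <- nchar(s)
  pam_len <- if (pam == "NGG") 3L else 2L
  if (L < 20L + pam_len) {
    return(tibble::tibble(start1 = integer(), target1 = integer(),
                          spacer = character(), pam = character(),
                          target_offset = integer()))
  }
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  max_start <- L - 19L - pam_len
  idx <- seq_len(max_start)
  pam_ok <- ch[idx + 20L] %in% c("A", "C", "G", "T")
  pam_ok <- pam_ok & (ch[idx + 21L] == "G")
  if (pam == "NGG") pam_ok <- pam_ok & (ch[idx + 22L] == "G")
  # exclude candidates whose protospacer contains N
  nN <- cumsum(ch == "N")
  protoN <- (nN[idx + 19L] - c(0L, nN)[idx]) > 0L
  if (any(protoN & pam_ok)) {
    warning(sum(protoN & pam_ok),
            " candidate protospacer(s) skipped: N in protospacer",
            call. = FALSE)
  }
  pam_ok <- pam_ok & !protoN

  targets <- which(ch == base)
  sel <- rep(NA_integer_, length(targets))
  for (o in seq(window[1], window[2])) {     # ascending offset = priority
    i <- targets - o + 1L
    elig <- is.na(sel) & i >= 1L & i <= max_start & pam_ok[pmax(i, 1L)]
    sel[elig] <- i[elig]
  }
  keep <- !is.na(sel)
  if (!any(keep)) {
    return(tibble::tibble(start1 = integer(), target1 = integer(),
                          spacer = character(), pam = character(),
                          target_offset = integer()))
  }
  start1 <- sel[keep]
  target1 <- targets[keep]
  tibble::tibble(
    start1 = start1,
    target1 = target1,
    spacer = substring(s, start1, start1 + 19L),
    pam = substring(s, start1 + 20L, pmin(start1 + 22L, L)),
    target_offset = target1 - start1 + 1L
  )
}

empty_guide_tbl <- function(editor, pam) {
  tibble::tibble(
    guide_id = character(), contig = character(),
    protospacer_start = integer(), strand = character(),
    spacer = character(), pam = character(), target_offset = integer(),
    target_pos = integer(), editor_class = editor, pam_class = pam,
    is_unique = logical(), control_class = character()
  )[0, ]
}

#' Flag guides whose spacer matches the references uniquely
#'
#' A guide is unique when its 20-nt spacer, followed by a PAM of the
#' configured class, has exactly one perfect-match occurrence across both
#' strands of the supplied references. The search is exact (0 mismatches)
#' and restricted to the supplied sequences; genome-scale uniqueness is
#' delegated to the user's choice of references. Non-unique guides should be
#' excluded from downstream scoring.
#'
#' @param guides Guide tibble from [design_guides()].
#' @param refs References accepted by [as_reference_tbl()].
#' @param pam PAM class used for the occurrence scan; defaults to the
#'   guides' own `pam_class`.
#' @return `guides` with `is_unique` filled in and an `n_matches` column.
#' @export
filter_unique <- function(guides, refs, pam = NULL) {
  refs <- as_reference_tbl(refs)
  pam <- pam %||% unique(guides$pam_class)
  stopifnot(length(pam) == 1L, pam %in% c("NGG", "NG"))
  spacers <- unique(guides$spacer)
  counts <- setNames(integer(length(spacers)), spacers)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(spacers))
  for (r in seq_len(nrow(refs))) {
    for (s in c(refs$seq[r], revcomp(refs$seq[r]))) {
      subj <- Biostrings::DNAString(s)
      hits <- Biostrings::matchPDict(pd, subj)
      starts <- Biostrings::startIndex(hits)
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      L <- length(ch)
      for (k in seq_along(spacers)) {
        st <- starts[[k]]
        if (is.null(st) || !length(st)) next
        counts[k] <- counts[k] + sum(pam_match_at(ch, st + 20L, pam, L))
      }
    }
  }
  guides$n_matches <- unname(counts[guides$spacer])
  guides$is_unique <- guides$n_matches == 1L
  guides
}

pam_match_at <- function(ch, pos, pam, L) {
  need <- if (pam == "NGG") 2L else 1L
  ok <- pos + need <= L
  res <- logical(length(pos))
  if (!any(ok)) return(res)
  p <- pos[ok]
  good <- ch[p] %in% c("A", "C", "G", "T") & ch[p + 1L] == "G"
  if (pam == "NGG") good <- good & ch[p + 2L] == "G"
  res[ok] <- good
  res
}

#' Reference target sequences for designed guides
#'
#' Builds, for each guide, the reference version of the integrated target
#' segment used in the paired guide-target assay: `flank` nt upstream of the
#' protospacer, the 20-nt protospacer, and 3 nt of PAM, all on the
#' protospacer strand (26 nt with the default flank). Guides too close to a
#' contig end for a full segment are dropped with a warning.
#'
#' @param guides Guide tibble from [design_guides()].
#' @param refs References accepted by [as_reference_tbl()].
#' @param flank Upstream flank length (default 3).
#' @return `guides` with a `target_ref` column added.
#' @export
guide_targets <- function(guides, refs, flank = 3L) {
  refs <- as_reference_tbl(refs)
  seqs <- setNames(refs$seq, refs$id)
  L <- nchar(seqs)[guides$contig]
  plus <- guides$strand == "+"
  # forward-strand window covering flank + protospacer + 3-nt PAM,
  # orientation-dependent because the flank sits 5' of the protospacer
  lo <- ifelse(plus, guides$protospacer_start + 1L - flank,
               guides$protospacer_start + 1L - 3L)
  hi <- ifelse(plus, guides$protospacer_start + 20L + 3L,
               guides$protospacer_start + 20L + flank)
  ok <- lo >= 1L & hi <= L
  if (any(!ok)) {
    warning(sum(!ok), " guide(s) dropped: target segment out of contig bounds",
            call. = FALSE)
  }
  out <- guides[ok, ]
  seg <- substring(seqs[out$contig], lo[ok], hi[ok])
  minus <- out$strand == "-"
  if (any(minus)) seg[minus] <- revcomp(seg[minus])
  out$target_ref <- unname(seg)
  out
}

#' Map a target-segment position to a forward-strand reference coordinate
#'
#' Position `m` is 1-based within the target segment (protospacer strand,
#' `flank` nt before the protospacer). Returns 1-based forward-strand
#' coordinates.
#'
#' @param guides Guide tibble rows (vectorised).
#' @param m Integer positions within the target segment.
#' @param flank Upstream flank length used when the segment was built.
#' @return Integer vector of 1-based forward-strand positions.
#' @export
target_pos_to_genomic <- function(guides, m, flank = 3L) {
  plus <- guides$strand == "+"
  out <- integer(length(m))
  out[plus] <- guides$protospacer_start[plus] + (m[plus] - flank)
  out[!plus] <- guides$protospacer_start[!plus] + 20L + flank - m[!plus] + 1L
  out
}

#' Attach user-supplied control guides to a library
#'
#' Control guides (non-targeting, essential-stop) are curated inputs, not
#' generated: they are appended with their declared `control_class`.
#'
#' @param guides Designed guide tibble.
#' @param controls Tibble with `guide_id`, `spacer`, `control_class`
#'   (values `non_targeting` or `essential_stop`).
#' @return Combined guide tibble.
#' @export
add_control_guides <- function(guides, controls) {
  stopifnot(all(c("guide_id", "spacer", "control_class") %in% names(controls)))
  bad <- setdiff(unique(controls$control_class),
                 c("non_targeting", "essential_stop"))
  if (length(bad)) stop("unknown control_class: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  dplyr::bind_rows(guides, tibble::as_tibble(controls))
}

#' Write / read a guide library TSV
#'
#' Coordinates are written 1-based inclusive (`protospacer_start` column in
#' the file is 1-based); in memory they are 0-based half-open.
#'
#' @param guides Guide tibble.
#' @param path Output path.
#' @export
write_guide_library <- function(guides, path) {
  out <- guides
  if ("protospacer_start" %in% names(out)) {
    out$protospacer_start <- out$protospacer_start + 1L
  }
  if ("target_pos" %in% names(out)) out$target_pos <- out$target_pos + 1L
  write_result_tsv(out, path, params = list(coordinates = "1-based"))
}

#' @rdname write_guide_library
#' @export
read_guide_library <- function(path) {
  out <- read_result_tsv(path)
  if ("protospacer_start" %in% names(out)) {
    out$protospacer_start <- out$protospacer_start - 1L
  }
  if ("target_pos" %in% names(out)) out$target_pos <- out$target_pos - 1L
  out
}
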