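#' Build a transcript model
#'
#' Minimal transcript representation for consequence annotation: ordered,
#' non-overlapping exons on a contig, a CDS span, and the transcript
#' strand. Coordinates are 1-based inclusive on the forward strand of the
#' contig. The CDS (the exonic positions between `cds_start` and `cds_end`)
#' must have length divisible by 3.
#'
#' @param gene Gene/transcript id.
#' @param contig Contig id the coordinates refer to.
#' @param strand `"+"` or `"-"`.
#' @param exons Tibble/data frame with `start`, `end` (1-based inclusive).
#' @param cds_start,cds_end Genomic CDS bounds (1-based inclusive); `NA` for
#'   a noncoding transcript.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene, contig, strand, exons,
                             cds_start = NA, cds_end = NA) {
  stopifnot(strand %in% c("+", "-"))
  exons <- tibble::as_tibble(exons[, c("start", "end")])
  exons <- exons[order(exons$start), ]
  stopifnot(all(exons$end >= exons$start))
  if (nrow(exons) > 1L &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("exons must be non-overlapping and ordered", call. = FALSE)
  }
  cds_pos <- integer(0)
  if (!is.na(cds_start)) {
    for (i in seq_len(nrow(exons))) {
      lo <- max(exons$start[i], cds_start)
      hi <- min(exons$end[i], cds_end)
      if (lo <= hi) cds_pos <- c(cds_pos, lo:hi)
    }
    if (length(cds_pos) %% 3L != 0L) {
      stop("CDS length must be divisible by 3", call. = FALSE)
    }
    if (strand == "-") cds_pos <- rev(cds_pos)
  }
  structure(
    list(gene = gene, contig = contig, strand = strand, exons = exons,
         cds_start = cds_start, cds_end = cds_end, cds_pos = cds_pos),
    class = "transcript_model"
  )
}

#' Read transcript models from a TSV
#'
#' Expected columns: `gene`, `contig`, `strand`, `exon_start`, `exon_end`,
#' `cds_start`, `cds_end` (one row per exon; 1-based inclusive).
#'
#' @param path TSV path (or a data frame in the same layout).
#' @return Named list of `transcript_model` objects.
#' @export
read_transcript_models <- function(path) {
  tb <- if (is.data.frame(path)) tibble::as_tibble(path) else
    read_result_tsv(path)
  out <- lapply(split(tb, tb$gene), function(g) {
    transcript_model(
      gene = g$gene[1], contig = g$contig[1], strand = g$strand[1],
      exons = tibble::tibble(start = g$exon_start, end = g$exon_end),
      cds_start = g$cds_start[1], cds_end = g$cds_end[1]
    )
  })
  out
}

#' Annotate nucleotide changes with protein consequences
#'
#' Translates a set of simultaneous nucleotide changes (one editing
#' outcome) on a transcript: coding changes are folded into their codons
#' (all changes of the outcome applied together) and translated with the
#' standard genetic code; intronic changes within 2 bp of an exon-intron
#' junction are `splicing`; exonic changes outside the CDS are `UTR`;
#' deeper intronic changes are `intronic`; positions outside the transcript
#' span are `intergenic` (excluded upstream with a warning). The outcome's
#' mutational type is the highest-priority consequence:
#' stop_gain > splicing > nonsynonymous > synonymous > UTR > intronic.
#'
#' @param changes Tibble with `pos` (1-based forward-strand), `ref`, `alt`
#'   (forward-strand bases).
#' @param tx A [transcript_model()].
#' @param refseq The contig sequence (character scalar).
#' @return List with `aa_changes` (e.g. `"Y2C"`, `+`-joined; `""` when the
#'   protein is unchanged), `mutational_type`, and `consequences` (per
#'   change).
#' @export
annotate_changes <- function(changes, tx, refseq) {
  stopifnot(inherits(tx, "transcript_model"))
  span <- range(c(tx$exons$start, tx$exons$end))
  refc <- strsplit(toupper(refseq), "", fixed = TRUE)[[1]]
  n <- nrow(changes)
  conseq <- character(n)
  cds_idx <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    p <- changes$pos[i]
    if (p < span[1] || p > span[2]) { conseq[i] <- "intergenic"; next }
    in_exon <- any(p >= tx$exons$start & p <= tx$exons$end)
    if (in_exon) {
      k <- match(p, tx$cds_pos)
      if (!is.na(k)) { conseq[i] <- "coding"; cds_idx[i] <- k }
      else conseq[i] <- "UTR"
    } else {
      near <- any(p >= tx$exons$start - 2L & p <= tx$exons$start - 1L) ||
        any(p >= tx$exons$end + 1L & p <= tx$exons$end + 2L)
      conseq[i] <- if (near) "splicing" else "intronic"
    }
  }

  aa <- character(0)
  types <- conseq[conseq != "coding" & conseq != "intergenic"]
  coding <- which(conseq == "coding")
  if (length(coding)) {
    codons <- unique((cds_idx[coding] - 1L) %/% 3L + 1L)
    any_diff <- FALSE
    for (cd in sort(codons)) {
      pos_idx <- ((cd - 1L) * 3L + 1L):(cd * 3L)
      gpos <- tx$cds_pos[pos_idx]
      ref_codon <- refc[gpos]
      if (tx$strand == "-") ref_codon <- comp_base(ref_codon)
      alt_codon <- ref_codon
      for (i in coding) {
        j <- match(cds_idx[i], pos_idx)
        if (!is.na(j)) {
          b <- changes$alt[i]
          if (tx$strand == "-") b <- comp_base(b)
          alt_codon[j] <- b
        }
      }
      ref_aa <- translate_codon(ref_codon)
      alt_aa <- translate_codon(alt_codon)
      if (!identical(ref_aa, alt_aa)) {
        any_diff <- TRUE
        aa <- c(aa, paste0(ref_aa, cd, alt_aa))
        types <- c(types,
                   if (alt_aa == "*" && ref_aa != "*") "stop_gain"
                   else "nonsynonymous")
      }
    }
    if (!any_diff) types <- c(types, "synonymous")
  }
  list(
    aa_changes = paste(aa, collapse = "+"),
    mutational_type = merged_type(types),
    consequences = conseq
  )
}

comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

translate_codon <- function(codon) {
  key <- paste(codon, collapse = "")
  if (grepl("N", key)) return("X")
  unname(Biostrings::GENETIC_CODE[key])
}

#' Annotate guide editing outcomes
#'
#' Decodes each outcome key into genomic nucleotide changes via the guide's
#' coordinates and annotates them against the transcript overlapping the
#' guide's contig. Outcomes entirely outside every transcript span are
#' excluded with a warning.
#'
#' @param outcomes Tibble with `guide_id`, `outcome_key`.
#' @param guides Guide library tibble with coordinates and `target_ref`.
#' @param transcripts A `transcript_model`, or a (named) list of them.
#' @param refs References accepted by [as_reference_tbl()].
#' @param flank Target-segment flank length.
#' @return Tibble `guide_id`, `outcome_key`, `nucleotide_changes` (genomic,
#'   forward strand, `pos:ref>alt` joined by `;`), `aa_changes`,
#'   `mutational_type`.
#' @export
annotate_outcomes <- function(outcomes, guides, transcripts, refs,
                              flank = 3L) {
  refs <- as_reference_tbl(refs)
  seqs <- setNames(refs$seq, refs$id)
  if (inherits(transcripts, "transcript_model")) {
    transcripts <- list(transcripts)
  }
  tx_contig <- vapply(transcripts, function(t) t$contig, "")
  gl <- guides[match(outcomes$guide_id, guides$guide_id), ]
  res <- vector("list", nrow(outcomes))
  n_intergenic <- 0L
  for (i in seq_len(nrow(outcomes))) {
    key <- outcomes$outcome_key[i]
    g <- gl[i, ]
    ch <- decode_outcome_key(key, g, flank)
    if (nrow(ch) == 0L) {
      res[[i]] <- tibble::tibble(
        guide_id = g$guide_id, outcome_key = key,
        nucleotide_changes = "", aa_changes = "",
        mutational_type = NA_character_)
      next
    }
    txs <- transcripts[tx_contig == g$contig]
    ann <- NULL
    for (tx in txs) {
      a <- annotate_changes(ch, tx, seqs[[g$contig]])
      if (!all(a$consequences == "intergenic")) { ann <- a; break }
    }
    if (is.null(ann)) {
      n_intergenic <- n_intergenic + 1L
      next
    }
    res[[i]] <- tibble::tibble(
      guide_id = g$guide_id, outcome_key = key,
      nucleotide_changes = paste(
        sprintf("%d:%s>%s", ch$pos, ch$ref, ch$alt), collapse = ";"),
      aa_changes = ann$aa_changes,
      mutational_type = ann$mutational_type
    )
  }
  if (n_intergenic > 0L) {
    warning(n_intergenic,
            " outcome(s) outside every transcript span excluded",
            call. = FALSE)
  }
  dplyr::bind_rows(res)
}

# outcome key ("p5:C>T+p7:C>T") -> genomic changes on the forward strand
decode_outcome_key <- function(key, guide, flank = 3L) {
  if (is.na(key) || key %in% c("unedited", "other") || !nzchar(key)) {
    return(tibble::tibble(pos = integer(), ref = character(),
                          alt = character()))
  }
  parts <- strsplit(key, "+", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^p(\\d+):([ACGT])>([ACGT])$", parts))
  stopifnot(all(lengths(m) == 4L))
  off <- as.integer(vapply(m, `[`, "", 2L))
  ref <- vapply(m, `[`, "", 3L)
  alt <- vapply(m, `[`, "", 4L)
  gpos <- target_pos_to_genomic(guide[rep(1L, length(off)), ], off + flank,
                                flank)
  if (guide$strand == "-") {
    ref <- comp_base(ref)
    alt <- comp_base(alt)
  }
  ord <- order(gpos)
  tibble::tibble(pos = gpos[ord], ref = ref[ord], alt = alt[ord])
}
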