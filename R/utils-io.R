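#' Normalise reference sequences to a tibble
#'
#' Accepts a named character vector, a [Biostrings::DNAStringSet], a tibble
#' with `id`/`seq` columns, or a path to a FASTA file, and returns a tibble
#' with one row per contig. Sequences are uppercased and validated against
#' the DNA alphabet `A,C,G,T,N`.
#'
#' @param refs References in any of the accepted forms.
#' @return A tibble with columns `id`, `seq`.
#' @export
as_reference_tbl <- function(refs) {
  if (inherits(refs, "DNAStringSet")) {
    refs <- setNames(as.character(refs), names(refs))
  }
  if (is.character(refs) && length(refs) == 1L && file.exists(refs)) {
    refs <- read_reference_fasta(refs)
  }
  if (is.character(refs)) {
    if (is.null(names(refs))) {
      names(refs) <- paste0("contig", seq_along(refs))
    }
    refs <- tibble::tibble(id = names(refs), seq = unname(refs))
  }
  stopifnot(is.data.frame(refs), all(c("id", "seq") %in% names(refs)))
  refs <- tibble::as_tibble(refs[, c("id", "seq")])
  refs$seq <- toupper(refs$seq)
  if (nrow(refs) == 0L || any(!nzchar(refs$seq))) {
    stop("reference sequences must be non-empty", call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", refs$seq)
  if (any(bad)) {
    stop(
      "reference sequences contain characters outside {A,C,G,T,N}: ",
      paste(refs$id[bad], collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(refs$id)) stop("duplicated contig ids", call. = FALSE)
  refs
}

#' Read reference sequences from a FASTA file
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write sequences to a FASTA file
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_reference_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, format = "fasta"
  )
  invisible(path)
}

#' Reverse complement of DNA strings
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x))
  )
  unname(out)
}

#' Read single-end reads from a FASTQ file
#'
#' Reads a plain (uncompressed or gzipped) FASTQ file into a tibble. Paired
#' mates are expected to be merged upstream; this reader is deliberately
#' single-end.
#'
#' @param path Path to the FASTQ file.
#' @param sample_id Optional sample id attached to every read.
#' @return Tibble with columns `read_id`, `seq` (and `sample_id` if given).
#' @export
read_fastq_reads <- function(path, sample_id = NULL) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- tibble::tibble(
    read_id = sub("\\s.*$", "", names(x)),
    seq = toupper(as.character(x))
  )
  if (!is.null(sample_id)) out <- dplyr::mutate(out, sample_id = sample_id, .before = 1)
  out
}

#' Write reads to a FASTQ file
#' @param reads Tibble with `read_id` and `seq` columns.
#' @param path Output path.
#' @export
write_fastq_reads <- function(reads, path) {
  qual <- strrep("I", nchar(reads$seq))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV with a provenance header
#'
#' Every emitted TSV carries `#`-prefixed header lines naming the producing
#' package version and the parameters used, so outputs are self-describing.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param params Named list of parameters recorded in the header.
#' @export
write_result_tsv <- function(x, path, params = list()) {
  hdr <- paste0("# bescreen ", as.character(packageVersion("bescreen")))
  if (length(params)) {
    kv <- paste(names(params), vapply(params, function(p)
      paste(format(p, trim = TRUE), collapse = ","), ""), sep = "=")
    hdr <- c(hdr, paste0("# ", paste(kv, collapse = "; ")))
  }
  writeLines(hdr, path)
  suppressMessages(readr::write_tsv(x, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

#' Read a TSV written by [write_result_tsv()]
#' @param path Input path.
#' @return A tibble.
#' @export
read_result_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
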