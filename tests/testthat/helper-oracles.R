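# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately share no code with the package internals.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# nested-loop enumeration over every (position, strand, offset) triple:
# for each target base select the protospacer placing it most PAM-distal,
# then collapse duplicated protospacers keeping the smallest offset
oracle_enumerate <- function(seqs, editor, pam, window = c(4, 8)) {
  base <- if (editor == "CBE") "C" else "A"
  pam_len <- if (pam == "NGG") 3L else 2L
  rows <- list()
  for (contig in names(seqs)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqs[[contig]] else oracle_revcomp(seqs[[contig]])
      L <- nchar(s)
      ch <- strsplit(s, "")[[1]]
      for (t in seq_len(L)) {
        if (ch[t] != base) next
        for (o in window[1]:window[2]) {       # most PAM-distal first
          i <- t - o + 1
          if (i < 1 || i + 19 + pam_len > L) next
          pam_ok <- ch[i + 20] %in% c("A", "C", "G", "T") &&
            ch[i + 21] == "G" && (pam == "NG" || ch[i + 22] == "G")
          if (!pam_ok) next
          spacer <- substr(s, i, i + 19)
          if (grepl("N", spacer)) next
          start0 <- if (strand == "+") i - 1 else L - (i + 19)
          rows[[length(rows) + 1]] <- data.frame(
            contig = contig, protospacer_start = start0, strand = strand,
            spacer = spacer,
            pam = substr(s, i + 20, min(i + 22, L)),
            target_offset = o, stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  if (!length(rows)) return(NULL)
  df <- do.call(rbind, rows)
  df <- df[order(df$contig, df$protospacer_start, df$strand,
                 df$target_offset), ]
  df <- df[!duplicated(df[, c("contig", "protospacer_start", "strand")]), ]
  df[order(df$contig, df$protospacer_start, df$strand), ]
}

# exhaustive substring scan for spacer+PAM occurrences on both strands
oracle_spacer_matches <- function(spacer, seqs, pam) {
  total <- 0L
  for (contig in names(seqs)) {
    for (s in c(seqs[[contig]], oracle_revcomp(seqs[[contig]]))) {
      L <- nchar(s)
      if (L < 22) next
      for (i in seq_len(L - 20 + 1)) {
        if (substr(s, i, i + 19) != spacer) next
        p1 <- substr(s, i + 20, i + 20)
        p2 <- substr(s, i + 21, i + 21)
        p3 <- substr(s, i + 22, i + 22)
        ok <- p1 %in% c("A", "C", "G", "T") && p2 == "G" &&
          (pam == "NG" || p3 == "G")
        if (ok) total <- total + 1L
      }
    }
  }
  total
}

# textbook BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# two-sided Fisher exact p by direct hypergeometric summation
oracle_fisher <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, function(x)
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)), numeric(1))
  p_obs <- probs[match(a, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small paired-read fixture: explicit reads around a scaffold
make_read <- function(spacer, target, scaffold = bescreen:::SGRNA_SCAFFOLD) {
  paste0(spacer, scaffold, target)
}

# substitute a different base at the given positions
sub_at <- function(s, pos) {
  for (p in pos) {
    cur <- substr(s, p, p)
    substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  s
}

toy_transcript <- function() {
  # contig: 5' UTR (1..6), CDS ATG TAC CAA TGG TAA split over two exons,
  # intron 22..31, 3' UTR tail
  exon1 <- "TTTTTTATGTACCAATGG"              # positions 1..18, CDS 7..18
  intron <- "GTAAGTATAG"                      # positions 19..28
  exon2 <- "TAAACCCCCC"                       # positions 29..38, CDS 29..31
  seq <- paste0(exon1, intron, exon2)
  tx <- transcript_model(
    gene = "toy", contig = "ctg", strand = "+",
    exons = data.frame(start = c(1L, 29L), end = c(18L, 38L)),
    cds_start = 7L, cds_end = 31L
  )
  list(seq = c(ctg = seq), tx = tx)
}
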