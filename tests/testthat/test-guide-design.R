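test_that("a single-site sequence yields the expected guide and no reverse hit", {
  g <- design_guides(c(ctg = "AAAAACAAAAAAAAAAAAAAAGG"), "CBE", "NGG")
  expect_equal(nrow(g), 1L)
  expect_equal(g$spacer, "AAAAACAAAAAAAAAAAAAA")
  expect_equal(g$pam, "AGG")
  expect_equal(g$strand, "+")
  expect_equal(g$target_offset, 6L)
  expect_equal(g$protospacer_start, 0L)
})

test_that("a target base is eligible iff it sits 13-17 bp upstream of the PAM", {
  # C at protospacer offset o is 21 - o bp upstream of the PAM start;
  # slide a single C through a poly-A protospacer and check the window
  for (o in 1:20) {
    sp <- rep("A", 20)
    sp[o] <- "C"
    seq <- paste0(paste(sp, collapse = ""), "TGG")
    g <- design_guides(c(x = seq), "CBE", "NGG")
    if (o >= 4 && o <= 8) {
      expect_equal(g$target_offset, o, info = paste("offset", o))
    } else {
      expect_equal(nrow(g), 0L, info = paste("offset", o))
    }
  }
})

test_that("the most PAM-distal protospacer is selected when several cover a base", {
  # PAMs available for two placements of the same C; offset 4 must win
  seq <- paste0(strrep("T", 10), "C", strrep("T", 16), "AGGAGG", strrep("T", 5))
  g <- design_guides(c(x = seq), "CBE", "NGG")
  expect_true(all(g$target_offset == 4L |
                    !duplicated(paste(g$contig, g$target_pos))))
  expect_true(4L %in% g$target_offset)
})

test_that("enumeration matches the brute-force oracle on random sequences", {
  set.seed(42)
  seqs <- c(c1 = random_dna(2000), c2 = random_dna(800))
  for (editor in c("CBE", "ABE")) {
    for (pam in c("NGG", "NG")) {
      g <- design_guides(seqs, editor, pam)
      o <- oracle_enumerate(as.list(seqs), editor, pam)
      expect_equal(nrow(g), nrow(o), info = paste(editor, pam))
      expect_equal(g$protospacer_start, o$protospacer_start,
                   info = paste(editor, pam))
      expect_equal(g$spacer, o$spacer, info = paste(editor, pam))
      expect_equal(g$strand, o$strand, info = paste(editor, pam))
      expect_equal(g$target_offset, o$target_offset,
                   info = paste(editor, pam))
    }
  }
})

test_that("emitted guides re-validate against the reference", {
  set.seed(7)
  seqs <- c(z = random_dna(1500))
  g <- design_guides(seqs, "ABE", "NG")
  expect_false(any(duplicated(
    g[, c("contig", "protospacer_start", "strand")])))
  for (i in seq_len(nrow(g))) {
    s <- if (g$strand[i] == "+") seqs[[g$contig[i]]] else
      oracle_revcomp(seqs[[g$contig[i]]])
    L <- nchar(s)
    start1 <- if (g$strand[i] == "+") g$protospacer_start[i] + 1 else
      L - g$protospacer_start[i] - 19
    expect_equal(substr(s, start1, start1 + 19), g$spacer[i])
    expect_equal(substr(s, start1 + 20, start1 + 19 + nchar(g$pam[i])),
                 g$pam[i])
    # the intended base is the editor's target base at the stored offset
    expect_equal(substr(g$spacer[i], g$target_offset[i], g$target_offset[i]),
                 "A")
  }
})

test_that("short references and N-containing candidates are handled", {
  expect_equal(nrow(design_guides(c(s = "ACGTACGTACGTACGTACGTAG"), "CBE",
                                  "NGG")), 0L)
  seq <- paste0("AAAAACAAAANAAAAAAAAA", "AGG")
  expect_warning(g <- design_guides(c(s = seq), "CBE", "NGG"),
                 "N in protospacer")
  expect_equal(nrow(g), 0L)
})

test_that("uniqueness flags match an exhaustive substring-scan oracle", {
  single <- c(r = paste0("TTTT", "ACGTACGTACGTACGTACCA", "TGG", "TTTT"))
  g <- design_guides(single, "CBE", "NGG")
  g <- filter_unique(g, single)
  expect_true(all(g$is_unique))

  dup <- c(r = paste0(strrep(paste0("ACGTACGTACGTACGTACCA", "TGG"), 2),
                      "AAAA"))
  g2 <- filter_unique(design_guides(dup, "CBE", "NGG"), dup)
  expect_true(any(!g2$is_unique))

  set.seed(11)
  ref <- c(big = random_dna(10000))
  g3 <- design_guides(ref, "CBE", "NGG")
  g3 <- g3[sample(nrow(g3), min(100, nrow(g3))), ]
  g3 <- filter_unique(g3, ref)
  for (i in seq_len(nrow(g3))) {
    expect_equal(g3$n_matches[i],
                 oracle_spacer_matches(g3$spacer[i], as.list(ref), "NGG"),
                 info = g3$spacer[i])
  }
  expect_equal(g3$is_unique, g3$n_matches == 1L)
})

test_that("guide target segments embed flank, spacer and PAM on both strands", {
  set.seed(3)
  ref <- c(k = random_dna(500))
  for (ed in c("CBE", "ABE")) {
    # guides too close to the contig edge are dropped with a warning
    g <- suppressWarnings(guide_targets(design_guides(ref, ed, "NGG"), ref))
    expect_true(all(nchar(g$target_ref) == 26))
    expect_equal(substr(g$target_ref, 4, 23), g$spacer)
    expect_equal(substr(g$target_ref, 24, 26), g$pam)
  }
})

test_that("control guides join the library with their declared class", {
  g <- design_guides(c(ctg = "AAAAACAAAAAAAAAAAAAAAGG"), "CBE", "NGG")
  ctrl <- tibble::tibble(guide_id = "nt1", spacer = strrep("G", 20),
                         control_class = "non_targeting")
  out <- add_control_guides(g, ctrl)
  expect_equal(nrow(out), 2L)
  expect_error(add_control_guides(g, dplyr::mutate(ctrl,
                                                   control_class = "bogus")),
               "control_class")
})

test_that("guide library TSVs round-trip with 1-based coordinates", {
  ref <- c(ctg = "TTTTAAAAACAAAAAAAAAAAAAAAGGTTTT")
  g <- guide_targets(design_guides(ref, "CBE", "NGG"), ref)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_guide_library(g, path)
  txt <- readLines(path)
  expect_true(startsWith(txt[1], "# bescreen"))
  back <- read_guide_library(path)
  expect_equal(back$protospacer_start, g$protospacer_start)
  expect_equal(back$spacer, g$spacer)
})
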