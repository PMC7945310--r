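scaf <- bescreen:::SGRNA_SCAFFOLD

test_that("Jaro similarity reproduces hand-evaluated values and conventions", {
  expect_equal(jaro_similarity("ACGT", "ACGT"), 1)
  expect_equal(jaro_similarity("MARTHA", "MARHTA"), 17 / 18)
  expect_equal(jaro_similarity("DIXON", "DICKSONX"), 0.7666667,
               tolerance = 1e-6)
  expect_equal(jaro_similarity("", ""), 1)
  expect_equal(jaro_similarity("", "ACGT"), 0)
  expect_equal(jaro_similarity("ACGT", ""), 0)
  # symmetry on random pairs
  set.seed(5)
  a <- replicate(20, random_dna(sample(10:30, 1)))
  b <- replicate(20, random_dna(sample(10:30, 1)))
  expect_equal(jaro_similarity(a, b), jaro_similarity(b, a))
})

test_that("scaffold anchoring extracts flanks and applies the mismatch cap", {
  spacer <- random_dna(20)
  target <- random_dna(26)
  read <- make_read(spacer, target)
  rec <- anchor_and_extract(read)
  expect_true(rec$kept)
  expect_equal(rec$spacer_obs, spacer)
  expect_equal(rec$target_obs, target)
  expect_equal(rec$scaffold_mismatches, 0L)

  mutate_at <- function(s, pos) {
    for (p in pos) {
      cur <- substr(s, p, p)
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
    }
    s
  }
  scaf3 <- mutate_at(scaf, c(5, 20, 40))
  rec3 <- anchor_and_extract(make_read(spacer, target, scaf3))
  expect_true(rec3$kept)
  expect_equal(rec3$scaffold_mismatches, 3L)

  scaf4 <- mutate_at(scaf, c(5, 20, 40, 60))
  rec4 <- anchor_and_extract(make_read(spacer, target, scaf4))
  expect_false(rec4$kept)
  expect_equal(rec4$reject_reason, "no_scaffold")

  # two equally good scaffold copies -> ambiguous
  amb <- paste0(spacer, scaf, target, scaf, target)
  reca <- anchor_and_extract(amb)
  expect_false(reca$kept)
  expect_equal(reca$reject_reason, "ambiguous_scaffold")

  # flanks too short
  short <- paste0(substr(spacer, 1, 10), scaf, target)
  recs <- anchor_and_extract(short)
  expect_equal(recs$reject_reason, "short_5prime_flank")
})

test_that("recombinant reads are removed at the 0.75 Jaro threshold", {
  lib <- sim_guide_library(n = 6, seed = 21, dissimilar_threshold = 0.72)
  own <- make_read(lib$spacer[1], lib$target_ref[1])
  cross <- make_read(lib$spacer[1], lib$target_ref[2])
  rec <- filter_recombinants(anchor_and_extract(c(own, cross)))
  expect_equal(rec$recombinant, c(FALSE, TRUE))
  expect_equal(rec$kept, c(TRUE, FALSE))
  expect_equal(rec$reject_reason[2], "recombinant")
})

test_that("reads are assigned to the library by exact then nearest match", {
  set.seed(9)
  lib <- sim_guide_library(n = 10, seed = 9)
  reads <- c(
    make_read(lib$spacer[1], lib$target_ref[1]),                  # exact
    make_read(sub_at(lib$spacer[2], c(3, 11)), lib$target_ref[2]),# 2 mm
    make_read(sub_at(lib$spacer[3], c(1, 5, 9, 13)), lib$target_ref[3])
  )
  rec <- anchor_and_extract(reads) |>
    filter_recombinants() |>
    assign_to_library(lib)
  expect_equal(rec$guide_id[1], lib$guide_id[1])
  expect_equal(rec$guide_id[2], lib$guide_id[2])
  expect_true(is.na(rec$guide_id[3]))  # 4 mismatches: identity < 0.85

  # PAM inconsistency blocks inexact assignment
  bad_pam <- sub("AGG$", "ATT", lib$target_ref[4])
  rec2 <- anchor_and_extract(
    make_read(sub_at(lib$spacer[4], 2), bad_pam)) |>
    filter_recombinants() |>
    assign_to_library(lib)
  expect_true(is.na(rec2$guide_id))

  # equidistant between two designs -> unassigned
  lib2 <- lib
  lib2$spacer[2] <- sub_at(lib2$spacer[1], 1)
  lib2$target_ref[2] <- paste0(substr(lib2$target_ref[1], 1, 3),
                               lib2$spacer[2], "AGG")
  # a spacer one mismatch from BOTH designs: a third base at position 1
  third <- setdiff(c("A", "C", "G", "T"),
                   c(substr(lib2$spacer[1], 1, 1),
                     substr(lib2$spacer[2], 1, 1)))[1]
  mid <- lib2$spacer[1]
  substr(mid, 1, 1) <- third
  rec3 <- anchor_and_extract(make_read(mid, lib2$target_ref[1])) |>
    filter_recombinants() |>
    assign_to_library(lib2)
  expect_true(is.na(rec3$guide_id))
})

test_that("edit calling classifies canonical, other and unedited reads", {
  ref <- paste0("TTT", "AACCTAAAAAAAAAAAAAAA", "AGG")  # Cs at offsets 3,4
  # window 4-8: only the C at offset 4 is editable
  obs_single <- ref
  substr(obs_single, 3 + 4, 3 + 4) <- "T"
  expect_equal(call_edits(obs_single, ref, "CBE"), "p4:C>T")
  expect_equal(call_edits(ref, ref, "CBE"), "unedited")

  ref2 <- paste0("TTT", "AAACCAAAAAAAAAAAAAAA", "AGG")  # Cs at offsets 4,5
  obs_both <- ref2
  substr(obs_both, 7, 8) <- "TT"
  expect_equal(call_edits(obs_both, ref2, "CBE"), "p4:C>T+p5:C>T")

  # non-canonical only (G -> A under ABE) -> other
  refA <- paste0("TTT", "AAAGAAAAAAAAAAAAAAAA", "AGG")
  obsA <- refA
  substr(obsA, 7, 7) <- "A"   # G>A at offset 4, not A>G
  expect_equal(call_edits(obsA, refA, "ABE"), "other")

  # length mismatch -> rejected
  expect_true(is.na(call_edits("ACGT", ref, "CBE")))
})

test_that("background-corrected fractions follow the stated formula", {
  expect_equal(outcome_fraction(30, 100, 0), 0.30)
  expect_equal(outcome_fraction(30, 100, 0.1), (30 - 10) / (100 - 10))
  expect_equal(outcome_fraction(10, 100, 0.1), 0)       # background only
  expect_equal(outcome_fraction(c(30, 0), c(100, 0), 0), 0.30) # D=0 dropped
  expect_true(is.na(outcome_fraction(0, 0, 0)))
  # negative corrected fractions clamp at 0
  expect_equal(outcome_fraction(5, 100, 0.1), 0)
})

test_that("outcomes with the same amino-acid change merge and filters apply", {
  # two distinct nucleotide outcomes that both produce Y2C
  fracs <- tibble::tibble(
    guide_id = "g1",
    outcome_key = c("p7:A>G", "p7:A>G+p8:A>G", "p7:A>G", "p7:A>G+p8:A>G"),
    sample_id = c("e1", "e1", "e2", "e2"),
    replicate = c("r1", "r1", "r2", "r2"),
    R = c(30L, 15L, 36L, 9L), D = 300L, h_c = 0,
    f_sample = c(0.10, 0.05, 0.12, 0.03),
    f_k = c(0.11, 0.04, 0.11, 0.04)
  )
  ann <- tibble::tibble(
    guide_id = "g1", outcome_key = c("p7:A>G", "p7:A>G+p8:A>G"),
    aa_changes = "Y2C", mutational_type = "nonsynonymous"
  )
  res <- merge_and_pick_major(fracs, ann)
  expect_equal(nrow(res$outcomes), 2L)  # one merged outcome x two samples
  expect_equal(res$outcomes$f_sample, c(0.15, 0.15))
  expect_true(all(res$outcomes$is_major))
  expect_equal(res$efficiency$q_raw, 0.15)
  expect_equal(res$efficiency$aa_changes, "Y2C")
  expect_true(res$efficiency$passed_filters)

  # merged coverage < 30 in every replicate -> removed by the filter
  fr_low <- dplyr::mutate(fracs, R = c(10L, 5L, 12L, 3L),
                          f_sample = R / 300)
  res_low <- merge_and_pick_major(fr_low, ann, min_coverage = 30L)
  expect_false(res_low$efficiency$passed_filters)
  # but passing in one replicate keeps the guide
  fr_mix <- dplyr::mutate(fracs, R = c(35L, 5L, 12L, 3L),
                          f_sample = R / 300)
  expect_true(merge_and_pick_major(fr_mix, ann)$efficiency$passed_filters)
})

test_that("major outcome and efficiency recover simulator truth", {
  lib <- sim_guide_library(n = 20, seed = 2)
  sim <- simulate_target_reads(
    lib, sim_reads_config(reads_per_guide = 600, error_rate = 0.001,
                          recombination_frac = 0), seed = 3)
  mo <- map_outcomes(sim$reads, sim$samples, lib)
  x <- dplyr::inner_join(mo$efficiency, sim$guide_truth, by = "guide_id")
  expect_equal(x$outcome_key, x$major_key)
  truth <- x$q_true * x$major_frac_given_edit
  # multinomial sampling error: 4 sd of a binomial at depth ~1200
  tol <- 4 * sqrt(truth * (1 - truth) / 1200)
  expect_true(all(abs(x$q_raw - truth) < pmax(tol, 0.02)))
})

test_that("co-editing tallies conserve the total edited count", {
  lib <- sim_guide_library(n = 15, seed = 4)
  sim <- simulate_target_reads(
    lib, sim_reads_config(reads_per_guide = 500, error_rate = 0,
                          recombination_frac = 0), seed = 5)
  mo <- map_outcomes(sim$reads, sim$samples, lib)
  tal <- tally_outcomes(mo$records)
  per_key <- tal |>
    dplyr::group_by(guide_id, sample_id) |>
    dplyr::summarise(edited = sum(R), .groups = "drop")
  direct <- mo$records |>
    dplyr::filter(kept, !is.na(guide_id),
                  !outcome_key %in% c("unedited", "other")) |>
    dplyr::count(guide_id, sample_id, name = "edited_direct")
  j <- dplyr::inner_join(per_key, direct, by = c("guide_id", "sample_id"))
  expect_equal(j$edited, j$edited_direct)
})
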