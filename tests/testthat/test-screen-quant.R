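toy_library <- function() {
  tibble::tibble(
    guide_id = c("t1", "t2", "nt1", "nt2"),
    spacer = c(strrep("A", 20), strrep("C", 20), strrep("G", 20),
               strrep("T", 20)),
    control_class = c("targeting", "targeting", "non_targeting",
                      "non_targeting")
  )
}

toy_samples <- function() {
  tibble::tibble(
    sample_id = c("d0r1", "dNr1", "d0r2", "dNr2"),
    timepoint = rep(c("day0", "dayN"), 2),
    replicate = rep(c("r1", "r2"), each = 2)
  )
}

make_counts <- function(lib, counts_by_sample) {
  purrr::imap_dfr(counts_by_sample, function(cnt, sid)
    tibble::tibble(guide_id = lib$guide_id, sample_id = sid, count = cnt))
}

test_that("guide counting matches reads exactly and flags unmatched", {
  lib <- toy_library()
  reads <- c(rep(strrep("A", 20), 10), rep(strrep("C", 20), 3),
             random_dna(20))
  cnt <- count_guides(tibble::tibble(sample_id = "s", seq = reads), lib,
                      method = "offset")
  expect_equal(cnt$count[match(c("t1", "t2", "nt1"), cnt$guide_id)],
               c(10L, 3L, 0L))
  expect_equal(attr(cnt, "unmatched")[["s"]], 1L)

  # scan mode finds embedded spacers; ambiguous reads stay unmatched
  reads2 <- c(paste0("TT", strrep("A", 20), "GG"),
              paste0(strrep("A", 20), strrep("C", 20)))
  cnt2 <- count_guides(tibble::tibble(sample_id = "s", seq = reads2), lib,
                       method = "scan")
  expect_equal(cnt2$count[cnt2$guide_id == "t1"], 1L)
  expect_equal(attr(cnt2, "unmatched")[["s"]], 1L)
})

test_that("normalisation anchors on the geometric mean of negative controls", {
  lib <- toy_library()
  counts <- make_counts(lib, list(d0r1 = c(50L, 80L, 100L, 100L)))
  nc <- normalize_counts(counts, lib, pseudocount = 0)
  expect_equal(unique(nc$w), 100)

  counts2 <- make_counts(lib, list(d0r1 = c(50L, 80L, 10L, 1000L)))
  nc2 <- normalize_counts(counts2, lib, pseudocount = 0)
  expect_equal(unique(nc2$w), 100)  # sqrt(10 * 1000)

  no_ctrl <- lib
  no_ctrl$control_class <- "targeting"
  expect_error(normalize_counts(counts, no_ctrl), "control-anchored")
})

test_that("fold changes are control-relative with the stated arithmetic", {
  lib <- toy_library()
  base <- c(100L, 100L, 100L, 100L)
  # C = S everywhere -> d = 0
  fc0 <- quantify_screen(
    make_counts(lib, list(d0r1 = base, dNr1 = base, d0r2 = base,
                          dNr2 = base)),
    toy_samples(), lib)
  expect_equal(fc0$d, rep(0, 8))

  # one guide halves, controls unchanged -> d = -ln 2
  fc1 <- quantify_screen(
    make_counts(lib, list(d0r1 = base, dNr1 = c(50L, 100L, 100L, 100L),
                          d0r2 = base, dNr2 = c(50L, 100L, 100L, 100L))),
    toy_samples(), lib, pseudocount = 0)
  expect_equal(fc1$d[fc1$guide_id == "t1"], rep(-log(2), 2))

  # controls uniformly double, guide unchanged -> d = -ln 2
  fc2 <- quantify_screen(
    make_counts(lib, list(d0r1 = base, dNr1 = c(100L, 200L, 200L, 200L),
                          d0r2 = base, dNr2 = c(100L, 200L, 200L, 200L))),
    toy_samples(), lib, pseudocount = 0)
  expect_equal(fc2$d[fc2$guide_id == "t1"], rep(-log(2), 2))
})

test_that("median d over negative controls is exactly zero per replicate", {
  sim <- simulate_screen(sim_screen_config(n_guides = 400L,
                                           depth_day0 = 5e4,
                                           depth_dayn = 5e4), seed = 4)
  fc <- quantify_screen(sim$counts, sim$samples, sim$guides)
  med <- fc |>
    dplyr::filter(control_class == "non_targeting") |>
    dplyr::group_by(replicate) |>
    dplyr::summarise(m = median(d))
  expect_equal(med$m, rep(0, nrow(med)))
})

test_that("per-sample depth rescaling leaves d unchanged to machine precision", {
  sim <- simulate_screen(sim_screen_config(n_guides = 300L,
                                           depth_day0 = 5e4,
                                           depth_dayn = 5e4), seed = 6)
  fc <- quantify_screen(sim$counts, sim$samples, sim$guides)
  scaled <- sim$counts
  mult <- c(day0_r1 = 7L, dayN_r1 = 3L, day0_r2 = 11L, dayN_r2 = 2L)
  scaled$count <- unname(scaled$count * mult[sim$counts$sample_id])
  # pseudocount 0 keeps the rescaling exact
  fc_s <- quantify_screen(scaled, sim$samples, sim$guides, pseudocount = 0)
  fc_0 <- quantify_screen(sim$counts, sim$samples, sim$guides,
                          pseudocount = 0)
  expect_equal(fc_s$d, fc_0$d, tolerance = 1e-12)
})

test_that("essential-stop controls deplete on average", {
  sim <- simulate_screen(sim_screen_config(n_guides = 1000L,
                                           depth_day0 = 2e5,
                                           depth_dayn = 2e5), seed = 8)
  fc <- quantify_screen(sim$counts, sim$samples, sim$guides)
  es <- fc$d[fc$control_class == "essential_stop"]
  expect_gt(length(es), 0)
  expect_lt(mean(es), 0)
})
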