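#' Configuration for a simulated base-editing screen
#'
#' Defaults describe the standard synthetic screen used throughout the
#' package tests: 5,000 guides of which 10% are non-targeting controls,
#' 2% essential-stop controls, 15% deleterious variants with relative
#' fitness `e^f` uniform on \[0.3, 0.8\], 5% advantageous variants with
#' `e^f` on \[1.1, 1.4\], editing activity `q` uniform on \[0.05, 0.95\],
#' experiment editing scale `l = 1`, growth factor `b = ln 10`, lognormal
#' initial abundances (sdlog 0.3) and two replicates sequenced at a total
#' depth of 1e6 reads per sample.
#'
#' @param n_guides Library size.
#' @param frac_nontargeting,frac_essential_stop,frac_deleterious,frac_advantageous
#'   Composition fractions (the remainder are null targeting guides).
#' @param fitness_deleterious,fitness_advantageous Ranges of relative
#'   fitness `e^f` for the non-null classes.
#' @param fitness_essential_stop Relative fitness of essential-stop
#'   controls.
#' @param q_range Range of the true editing activity `q`.
#' @param l Experiment editing scale (`p = q l`), in (0, 1].
#' @param b Growth factor per experiment (cancels in control anchoring).
#' @param abundance_sdlog Lognormal sd of initial abundances.
#' @param depth_day0,depth_dayn Total reads per sample.
#' @param replicates Number of replicates.
#' @return A list of class `sim_screen_config`.
#' @export
sim_screen_config <- function(n_guides = 5000L,
                              frac_nontargeting = 0.10,
                              frac_essential_stop = 0.02,
                              frac_deleterious = 0.15,
                              frac_advantageous = 0.05,
                              fitness_deleterious = c(0.3, 0.8),
                              fitness_advantageous = c(1.1, 1.4),
                              fitness_essential_stop = 0.2,
                              q_range = c(0.05, 0.95),
                              l = 1.0, b = log(10),
                              abundance_sdlog = 0.3,
                              depth_day0 = 1e6, depth_dayn = 1e6,
                              replicates = 2L) {
  stopifnot(frac_nontargeting + frac_essential_stop + frac_deleterious +
              frac_advantageous <= 1,
            l > 0, l <= 1, depth_day0 > 0, depth_dayn > 0, replicates >= 1)
  structure(as.list(environment()), class = "sim_screen_config")
}

#' Simulate a pooled base-editing screen
#'
#' Draws day-0 counts from the initial abundance distribution and
#' endpoint counts from the exponential growth model
#' `C = S p e^(b+f) + S (1-p) e^b` with `p = q l`, multinomial sampling at
#' the configured depths. Non-targeting controls have `f = 0`, `p = 0`.
#' Ground truth (`f`, `q`, `p`, `beta* = l (e^f - 1)`) is returned for
#' recovery tests.
#'
#' @param config A [sim_screen_config()].
#' @param seed Integer seed; all randomness is derived from it.
#' @return List of class `be_sim_screen`: `counts` (long tibble),
#'   `samples`, `guides` (minimal library with `control_class`), `truth`.
#' @export
simulate_screen <- function(config = sim_screen_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_screen_config"))
  set.seed(seed)
  n <- config$n_guides
  n_nt <- round(n * config$frac_nontargeting)
  n_es <- round(n * config$frac_essential_stop)
  n_del <- round(n * config$frac_deleterious)
  n_adv <- round(n * config$frac_advantageous)
  n_null <- n - n_nt - n_es - n_del - n_adv
  stopifnot(n_null >= 0)
  class_vec <- sample(rep(c("non_targeting", "essential_stop", "deleterious",
                            "advantageous", "null"),
                          c(n_nt, n_es, n_del, n_adv, n_null)))
  exp_f <- rep(1, n)
  exp_f[class_vec == "deleterious"] <-
    runif(n_del, config$fitness_deleterious[1], config$fitness_deleterious[2])
  exp_f[class_vec == "advantageous"] <-
    runif(n_adv, config$fitness_advantageous[1],
          config$fitness_advantageous[2])
  exp_f[class_vec == "essential_stop"] <- config$fitness_essential_stop
  q <- runif(n, config$q_range[1], config$q_range[2])
  p <- q * config$l
  p[class_vec == "non_targeting"] <- 0
  q[class_vec == "non_targeting"] <- NA_real_

  guide_id <- sprintf("g%04d", seq_len(n))
  truth <- tibble::tibble(
    guide_id = guide_id,
    class = class_vec,
    exp_f = exp_f,
    f = log(exp_f),
    q = q,
    p = p,
    beta_star = config$l * (exp_f - 1)
  )
  guides <- tibble::tibble(
    guide_id = guide_id,
    control_class = dplyr::case_when(
      class_vec == "non_targeting" ~ "non_targeting",
      class_vec == "essential_stop" ~ "essential_stop",
      TRUE ~ "targeting"
    )
  )

  a0 <- rlnorm(n, 0, config$abundance_sdlog)
  a0 <- a0 / sum(a0)
  # endpoint expected abundance: common factor e^b cancels in the
  # multinomial proportions, the (1 + p (e^f - 1)) term is the signal
  aN <- a0 * (1 + p * (exp_f - 1))
  aN <- aN / sum(aN)

  counts <- list()
  samples <- list()
  for (r in seq_len(config$replicates)) {
    s0 <- as.vector(rmultinom(1, config$depth_day0, a0))
    sN <- as.vector(rmultinom(1, config$depth_dayn, aN))
    id0 <- sprintf("day0_r%d", r); idN <- sprintf("dayN_r%d", r)
    counts[[id0]] <- tibble::tibble(guide_id = guide_id, sample_id = id0,
                                    count = s0)
    counts[[idN]] <- tibble::tibble(guide_id = guide_id, sample_id = idN,
                                    count = sN)
    samples[[r]] <- tibble::tibble(
      sample_id = c(id0, idN), timepoint = c("day0", "dayN"),
      replicate = sprintf("r%d", r))
  }
  structure(
    list(counts = dplyr::bind_rows(counts),
         samples = dplyr::bind_rows(samples),
         guides = guides, truth = truth, config = config, seed = seed),
    class = "be_sim_screen"
  )
}

#' Configuration for simulated paired guide-target assay reads
#'
#' @param reads_per_guide Reads per guide per sample.
#' @param error_rate Per-base substitution sequencing-error rate.
#' @param recombination_frac Fraction of reads whose target segment is
#'   swapped with another guide's (template switching).
#' @param q_range Range of true editing probabilities.
#' @param co_edit_frac Probability, given editing and a second editable
#'   window base, that both bases are converted.
#' @param alt_single_frac Probability, given editing and a second editable
#'   base, of converting only the secondary base.
#' @param edited_samples,control_samples Number of edited / control
#'   (unedited) samples; edited samples are the replicates.
#' @param low_activity_frac Fraction of guides given a near-zero editing
#'   probability drawn from `low_activity_range` (these should fail the
#'   coverage/frequency filters downstream).
#' @param low_activity_range Editing-probability range for low-activity
#'   guides.
#' @param scaffold Scaffold placed between spacer and target.
#' @return A list of class `sim_reads_config`.
#' @export
sim_reads_config <- function(reads_per_guide = 1500L,
                             error_rate = 0.002,
                             recombination_frac = 0.05,
                             q_range = c(0.05, 0.9),
                             co_edit_frac = 0.15,
                             alt_single_frac = 0.1,
                             edited_samples = 2L, control_samples = 2L,
                             low_activity_frac = 0,
                             low_activity_range = c(0.001, 0.004),
                             scaffold = SGRNA_SCAFFOLD) {
  stopifnot(error_rate >= 0, error_rate < 1,
            recombination_frac >= 0, recombination_frac < 1)
  structure(as.list(environment()), class = "sim_reads_config")
}

#' Simulate paired guide-target assay reads with known truth
#'
#' Generates merged single-end reads `spacer + scaffold + target` for each
#' guide: in edited samples a read is edited with the guide's true
#' probability `q` and carries an outcome drawn from a per-guide outcome
#' distribution over the editable window bases; control samples are
#' unedited. A configured fraction of reads are recombinants (the target
#' segment comes from a different random guide), and every base is
#' substituted with the sequencing error rate.
#'
#' @param guides Guide library with `spacer`, `target_ref`,
#'   `editor_class`, `target_offset` (see [guide_targets()]).
#' @param config A [sim_reads_config()].
#' @param seed Integer seed.
#' @param window Editing window (protospacer coordinates).
#' @param flank Target-segment flank length.
#' @return List of class `be_sim_reads`: `reads` (tibble `sample_id`,
#'   `read_id`, `seq`), `samples` sheet, `guide_truth` (per guide: `q_true`,
#'   outcome keys and probabilities, `major_key`, `major_frac_given_edit`),
#'   `read_truth` (per read: guide, recombinant flag, true outcome).
#' @export
simulate_target_reads <- function(guides, config = sim_reads_config(),
                                  seed = 1L, window = c(4L, 8L),
                                  flank = 3L) {
  stopifnot(inherits(config, "sim_reads_config"),
            all(c("spacer", "target_ref", "editor_class",
                  "target_offset") %in% names(guides)))
  set.seed(seed)
  ng <- nrow(guides)
  q_true <- runif(ng, config$q_range[1], config$q_range[2])
  n_low <- round(ng * config$low_activity_frac)
  if (n_low > 0L) {
    low <- sample.int(ng, n_low)
    q_true[low] <- runif(n_low, config$low_activity_range[1],
                         config$low_activity_range[2])
  }

  # per-guide outcome distribution over editable window positions
  outs <- vector("list", ng)
  for (g in seq_len(ng)) {
    tr <- EDITOR_TRANSITIONS[[guides$editor_class[g]]]
    ref_ch <- strsplit(guides$target_ref[g], "", fixed = TRUE)[[1]]
    win_pos <- flank + seq(window[1], window[2])
    editable <- win_pos[ref_ch[win_pos] == tr[["ref"]]] - flank
    target_off <- guides$target_offset[g]
    stopifnot(target_off %in% editable)
    second <- setdiff(editable, target_off)
    if (length(second)) {
      second <- second[1]
      keys <- c(key_for(target_off, tr), key_for(c(target_off, second), tr),
                key_for(second, tr))
      prob <- c(1 - config$co_edit_frac - config$alt_single_frac,
                config$co_edit_frac, config$alt_single_frac)
    } else {
      keys <- key_for(target_off, tr)
      prob <- 1
    }
    outs[[g]] <- tibble::tibble(guide_id = guides$guide_id[g],
                                outcome_key = keys, prob = prob)
  }
  outcome_dist <- dplyr::bind_rows(outs)
  major <- outcome_dist |>
    dplyr::group_by(.data$guide_id) |>
    dplyr::arrange(dplyr::desc(.data$prob), .by_group = TRUE) |>
    dplyr::summarise(major_key = .data$outcome_key[1],
                     major_frac_given_edit = .data$prob[1],
                     .groups = "drop")
  guide_truth <- tibble::tibble(guide_id = guides$guide_id,
                                q_true = q_true) |>
    dplyr::left_join(major, by = "guide_id")

  sample_ids <- c(sprintf("edited_r%d", seq_len(config$edited_samples)),
                  sprintf("control_r%d", seq_len(config$control_samples)))
  samples <- tibble::tibble(
    sample_id = sample_ids,
    condition = rep(c("edited", "control"),
                    c(config$edited_samples, config$control_samples)),
    replicate = c(sprintf("r%d", seq_len(config$edited_samples)),
                  sprintf("r%d", seq_len(config$control_samples)))
  )

  all_reads <- list(); all_truth <- list()
  for (s in seq_along(sample_ids)) {
    edited_sample <- samples$condition[s] == "edited"
    gidx <- rep(seq_len(ng), each = config$reads_per_guide)
    nr <- length(gidx)
    targ <- guides$target_ref[gidx]
    key <- rep("unedited", nr)
    if (edited_sample) {
      is_edit <- runif(nr) < q_true[gidx]
      for (g in which(tabulate(gidx[is_edit], ng) > 0)) {
        ridx <- which(is_edit & gidx == g)
        od <- outs[[g]]
        pick <- sample.int(nrow(od), length(ridx), replace = TRUE,
                           prob = od$prob)
        key[ridx] <- od$outcome_key[pick]
        targ[ridx] <- apply_outcome(targ[ridx], od$outcome_key[pick], flank)
      }
    }
    recomb <- runif(nr) < config$recombination_frac
    if (any(recomb)) {
      donor <- sample.int(ng, sum(recomb), replace = TRUE)
      clash <- donor == gidx[recomb]
      donor[clash] <- (donor[clash] %% ng) + 1L
      targ[recomb] <- guides$target_ref[donor]
      key[recomb] <- "recombinant"
    }
    seqs <- paste0(guides$spacer[gidx], config$scaffold, targ)
    seqs <- add_seq_errors(seqs, config$error_rate)
    rid <- sprintf("%s_%07d", sample_ids[s], seq_len(nr))
    all_reads[[s]] <- tibble::tibble(sample_id = sample_ids[s],
                                     read_id = rid, seq = seqs)
    all_truth[[s]] <- tibble::tibble(
      sample_id = sample_ids[s], read_id = rid,
      guide_id = guides$guide_id[gidx],
      recombinant = recomb, true_outcome = key)
  }
  structure(
    list(reads = dplyr::bind_rows(all_reads), samples = samples,
         guide_truth = guide_truth,
         outcome_dist = outcome_dist,
         read_truth = dplyr::bind_rows(all_truth),
         config = config, seed = seed),
    class = "be_sim_reads"
  )
}

key_for <- function(offsets, tr) {
  paste(sprintf("p%d:%s>%s", sort(offsets), tr[["ref"]], tr[["alt"]]),
        collapse = "+")
}

# apply outcome keys (segment offsets) to target segments, grouped by key
apply_outcome <- function(targets, keys, flank = 3L) {
  for (k in unique(keys)) {
    idx <- which(keys == k)
    parts <- strsplit(k, "+", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^p(\\d+):[ACGT]>([ACGT])$", parts))
    off <- as.integer(vapply(m, `[`, "", 2L)) + flank
    alt <- vapply(m, `[`, "", 3L)
    for (j in seq_along(off)) {
      substr(targets[idx], off[j], off[j]) <- alt[j]
    }
  }
  targets
}

# iid per-base substitution errors (vectorised by error index)
add_seq_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  len <- nchar(seqs)
  n_err <- rbinom(length(seqs), len, rate)
  bases <- c("A", "C", "G", "T")
  max_err <- max(n_err)
  if (max_err == 0L) return(seqs)
  for (j in seq_len(max_err)) {
    idx <- which(n_err >= j)
    pos <- 1L + floor(runif(length(idx)) * len[idx])
    cur <- substr(seqs[idx], pos, pos)
    shift <- sample.int(3L, length(idx), replace = TRUE)
    new <- bases[((match(cur, bases) - 1L + shift) %% 4L) + 1L]
    substr(seqs[idx], pos, pos) <- new
  }
  seqs
}

#' Build a small random guide library for read-level simulation
#'
#' Constructs synthetic guides directly (random unique spacers with the
#' editor's target base at a known window offset, `AGG` PAM and random
#' 3-nt flank), bypassing genome design. Useful for testing outcome
#' mapping without a reference.
#'
#' @param n Number of guides.
#' @param editor `"CBE"` or `"ABE"`.
#' @param seed Integer seed.
#' @param window Editing window.
#' @param flank Flank length.
#' @param dissimilar_threshold When non-`NULL`, spacers are additionally
#'   required to be pairwise dissimilar (Jaro similarity below this value),
#'   so that recombinant reads fall below the 0.75 recombination filter.
#'   Practical only for small `n` (rejection sampling).
#' @return Guide tibble compatible with [map_outcomes()].
#' @export
sim_guide_library <- function(n = 60L, editor = c("CBE", "ABE"), seed = 1L,
                              window = c(4L, 8L), flank = 3L,
                              dissimilar_threshold = NULL) {
  editor <- match.arg(editor)
  set.seed(seed)
  tr <- EDITOR_TRANSITIONS[[editor]]
  bases <- c("A", "C", "G", "T")
  other <- setdiff(bases, tr[["ref"]])
  spacers <- character(0)
  offs <- integer(0)
  tries <- 0L
  while (length(spacers) < n) {
    tries <- tries + 1L
    if (tries > 5e5) {
      stop("could not sample ", n, " spacers under the dissimilarity ",
           "constraint", call. = FALSE)
    }
    off <- sample(seq(window[1], window[2]), 1)
    if (is.null(dissimilar_threshold)) {
      sp <- sample(other, 20, replace = TRUE)
      sp[off] <- tr[["ref"]]
      # occasionally allow a second editable base in the window
      if (runif(1) < 0.5) {
        o2 <- sample(setdiff(seq(window[1], window[2]), off), 1)
        sp[o2] <- tr[["ref"]]
      }
    } else {
      # full-alphabet spacers keep pairwise Jaro low enough to be
      # rejection-sampled into a mutually dissimilar set
      sp <- sample(bases, 20, replace = TRUE)
      sp[off] <- tr[["ref"]]
    }
    sp <- paste(sp, collapse = "")
    if (sp %in% spacers) next
    if (!is.null(dissimilar_threshold) && length(spacers) &&
        any(jaro_similarity(rep(sp, length(spacers)), spacers) >=
              dissimilar_threshold)) {
      next
    }
    spacers <- c(spacers, sp)
    offs <- c(offs, off)
  }
  flanks <- vapply(seq_len(n), function(i)
    paste(sample(bases, flank, replace = TRUE), collapse = ""), "")
  tibble::tibble(
    guide_id = sprintf("sg%03d", seq_len(n)),
    spacer = spacers,
    pam = "AGG",
    target_offset = offs,
    editor_class = editor,
    pam_class = "NGG",
    control_class = "targeting",
    target_ref = paste0(flanks, spacers, "AGG")
  )
}
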