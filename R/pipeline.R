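#' Run the full analysis pipeline
#'
#' Orchestrates design -> outcome mapping -> quantification -> scoring ->
#' classification over file-based inputs, writing one TSV per stage plus a
#' JSON run manifest (package version, parameters, input checksums, stage
#' status). Any prefix of the pipeline is resumable: with `resume = TRUE`
#' stages whose outputs already exist are reloaded instead of recomputed.
#'
#' @param config A named list (or path to a YAML file) with elements:
#'   * `out_dir`: output directory.
#'   * `fasta`: reference FASTA path (or sequences).
#'   * `transcripts`: transcript-model TSV path (optional).
#'   * `controls`: control-guide TSV path (optional).
#'   * `editor`, `pam`: editor and PAM class for design.
#'   * `assay_reads`: named character vector of FASTQ paths per assay
#'     sample, with `assay_samples` a sample-sheet TSV (`sample_id`,
#'     `condition`, `replicate`); or `efficiency` with a precomputed
#'     efficiency TSV.
#'   * `screen_counts`: raw count TSV (`guide_id`, `sample_id`, `count`);
#'     or `screen_reads` (named FASTQ paths) -- with `screen_samples` a
#'     sample sheet (`sample_id`, `timepoint`, `replicate`).
#'   * `predictions`: TSV with `guide_id`, `q_predicted` (optional).
#'   * `params`: overrides for thresholds (`pseudocount`, `q_floor`,
#'     `activity_threshold`, `activity_filter`, `min_coverage`,
#'     `min_frequency`, `lof_threshold`, `seed`, `window`).
#' @param resume Reuse existing stage outputs (default FALSE).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  par <- utils::modifyList(
    list(pseudocount = 1, q_floor = 0.05, activity_threshold = 0.2,
         activity_filter = TRUE, min_coverage = 30L, min_frequency = 0.005,
         lof_threshold = 0.8, seed = 1L, window = c(4L, 8L), flank = 3L),
    config$params %||% list())
  manifest <- list(
    package = "bescreen",
    version = as.character(packageVersion("bescreen")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    params = par, stages = list()
  )
  inputs <- unlist(config[intersect(names(config),
                                    c("fasta", "transcripts", "controls",
                                      "screen_counts", "predictions",
                                      "assay_reads", "screen_reads"))])
  inputs <- inputs[vapply(inputs, function(p)
    is.character(p) && file.exists(p), TRUE)]
  manifest$input_md5 <- as.list(tools::md5sum(unlist(inputs)))

  stage <- function(name, file, fn, reader = read_result_tsv) {
    path <- file.path(out, file)
    if (resume && file.exists(path)) {
      message("[bescreen] ", name, ": reusing ", path)
      manifest$stages[[name]] <<- list(status = "reused", output = path)
      return(reader(path))
    }
    message("[bescreen] ", name, " ...")
    res <- fn(path)
    manifest$stages[[name]] <<- list(status = "completed", output = path)
    res
  }

  refs <- if (!is.null(config$fasta)) as_reference_tbl(config$fasta)

  # --- design ---------------------------------------------------------
  guides <- stage("design", "guides.tsv", function(path) {
    stopifnot(!is.null(refs))
    g <- design_guides(refs, editor = config$editor %||% "CBE",
                       pam = config$pam %||% "NGG", window = par$window)
    g <- filter_unique(g, refs)
    g <- guide_targets(g, refs, flank = par$flank)
    if (!is.null(config$controls)) {
      ctrl <- if (is.character(config$controls))
        read_result_tsv(config$controls) else config$controls
      g <- add_control_guides(g, ctrl)
    }
    write_guide_library(g, path)
    g
  }, reader = read_guide_library)

  txs <- if (!is.null(config$transcripts))
    read_transcript_models(config$transcripts)

  # --- outcome mapping / efficiency -----------------------------------
  if (!is.null(config$assay_reads)) {
    eff <- stage("map_outcomes", "efficiency.tsv", function(path) {
      smp <- if (is.character(config$assay_samples))
        read_result_tsv(config$assay_samples) else
          tibble::as_tibble(config$assay_samples)
      reads <- purrr::imap_dfr(as.list(config$assay_reads),
                               function(p, sid) read_fastq_reads(p, sid))
      mo <- map_outcomes(reads, smp, guides, transcripts = txs, refs = refs,
                         window = par$window, flank = par$flank,
                         min_coverage = par$min_coverage,
                         min_frequency = par$min_frequency)
      write_result_tsv(
        dplyr::select(mo$outcomes, -dplyr::any_of("merge_key")),
        file.path(out, "outcomes.tsv"),
        params = par[c("window", "min_coverage", "min_frequency")])
      write_result_tsv(mo$efficiency, path,
                       params = par[c("min_coverage", "min_frequency")])
      mo$efficiency
    })
  } else if (!is.null(config$efficiency)) {
    eff <- if (is.character(config$efficiency))
      read_result_tsv(config$efficiency) else
        tibble::as_tibble(config$efficiency)
  } else {
    stop("pipeline needs either assay_reads (+ assay_samples) or an ",
         "efficiency table", call. = FALSE)
  }

  # --- screen quantification ------------------------------------------
  scr_samples <- if (is.character(config$screen_samples))
    read_result_tsv(config$screen_samples) else
      tibble::as_tibble(config$screen_samples)
  usable <- guides[is.na(guides$is_unique) | guides$is_unique |
                     guides$control_class != "targeting", ]
  fc <- stage("quantify", "foldchanges.tsv", function(path) {
    counts <- if (!is.null(config$screen_counts)) {
      if (is.character(config$screen_counts))
        read_result_tsv(config$screen_counts) else
          tibble::as_tibble(config$screen_counts)
    } else {
      reads <- purrr::imap_dfr(as.list(config$screen_reads), function(p, sid)
        dplyr::mutate(read_fastq_reads(p), sample_id = sid))
      count_guides(reads, usable, method = "scan")
    }
    counts <- counts[counts$guide_id %in% usable$guide_id, ]
    res <- quantify_screen(counts, scr_samples, usable,
                           pseudocount = par$pseudocount)
    write_result_tsv(res, path, params = par["pseudocount"])
    res
  })

  # --- scoring ---------------------------------------------------------
  preds <- if (!is.null(config$predictions)) {
    if (is.character(config$predictions))
      read_result_tsv(config$predictions) else
        tibble::as_tibble(config$predictions)
  }
  scores <- stage("score", "scores.tsv", function(path) {
    act <- quantile_harmonize(eff, preds) |>
      scale_activity(activity_threshold = par$activity_threshold)
    sc <- beta_scores(fc, act, q_floor = par$q_floor,
                      activity_filter = par$activity_filter)
    write_result_tsv(sc, path,
                     params = par[c("q_floor", "activity_threshold",
                                    "activity_filter")])
    sc
  })

  # --- classification --------------------------------------------------
  cls <- stage("classify", "lof_calls.tsv", function(path) {
    cl <- classify_lof(scores, threshold = par$lof_threshold,
                       seed = par$seed)
    write_result_tsv(cl$calls, path,
                     params = par[c("lof_threshold", "seed")])
    jsonlite::write_json(
      list(components = cl$fit$components, loglik = cl$fit$loglik,
           AIC = cl$fit$AIC, BIC = cl$fit$BIC,
           beta_cutoff = cl$beta_cutoff, threshold = cl$threshold),
      file.path(out, "mixture_fit.json"), auto_unbox = TRUE, digits = NA)
    cl$calls
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
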