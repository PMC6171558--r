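#' @title Workflow runners
#' @description `run_simulate()`, `run_process()` and `run_compare()` wire the
#'   package into a file-based simulate -> process -> compare workflow with a
#'   run manifest, mirroring how a participant study is analysed from the
#'   shell (see `inst/scripts/ftcdlat`). `simulate_cohort()` is the in-memory
#'   equivalent for simulation studies.
#' @name pipeline-runners
NULL

# 31-bit polynomial rolling hash of a character scalar, as 8 hex digits
poly_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

config_hash <- function(cfg) {
  poly_hash(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA))
}

write_manifest <- function(dir, seed, cfg, inputs, counts, outputs) {
  manifest <- list(
    package = "ftcdlat",
    version = as.character(utils::packageVersion("ftcdlat")),
    seed = seed,
    config_hash = config_hash(cfg),
    inputs = inputs,
    counts = counts,
    outputs = outputs
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Simulate a session and write it to disk
#'
#' Writes the signal TSV, the ground-truth CSV and a run manifest.
#'
#' @param cfg An [sim_config()].
#' @param out_dir Output directory (created if absent).
#' @param stem File-name stem, which downstream steps use as participant id.
#' @return Named character vector of the written paths, invisibly.
#' @rdname pipeline-runners
#' @export
run_simulate <- function(cfg = sim_config(), out_dir, stem = "sim") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_recording(cfg)
  signal <- file.path(out_dir, paste0(stem, ".tsv"))
  truth <- file.path(out_dir, paste0(stem, "_truth.csv"))
  write_recording(sim$recording, signal)
  utils::write.csv(sim$truth, truth, row.names = FALSE, quote = FALSE)
  manifest <- write_manifest(out_dir, cfg$rng_seed, cfg, inputs = list(),
                             counts = list(trials = nrow(sim$truth)),
                             outputs = c(signal, truth))
  message(sprintf("simulated %d trials -> %s", nrow(sim$truth), signal))
  invisible(c(signal = signal, truth = truth, manifest = manifest))
}

#' Process one or more signal files into laterality results
#'
#' Each signal file is one participant (id = file-name stem). Writes
#' `results.csv` (one row per participant x task x method), `qc.csv`,
#' `trial_lis.csv`, `waves.csv` and a manifest.
#'
#' @param signal_paths Character vector of signal TSV paths.
#' @param cfg An [ftcd_config()].
#' @return The results data frame, invisibly.
#' @rdname pipeline-runners
#' @export
run_process <- function(signal_paths, cfg = ftcd_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_results <- list(); all_qc <- list(); all_tl <- list(); all_waves <- list()
  for (path in signal_paths) {
    id <- sub("\\.[^.]*$", "", basename(path))
    rec <- read_recording(path)
    fit <- ftcd_laterality(rec, cfg, id = id)
    missing_tasks <- setdiff(task_names,
                             unique(fit$results$task))
    if (length(missing_tasks) &&
        any(missing_tasks %in% unique(fit$epochs$info$task)))
      stop(sprintf("participant %s: zero included trials for task(s) %s",
                   id, paste(missing_tasks, collapse = ", ")), call. = FALSE)
    all_results[[id]] <- fit$results
    qc <- qc_table(fit$epochs); qc$participant_id <- id
    all_qc[[id]] <- qc
    tl <- do.call(rbind, lapply(names(fit$trial_lis), function(tk)
      data.frame(participant_id = id, task = tk,
                 trial = seq_along(fit$trial_lis[[tk]]$peak),
                 li_peak = fit$trial_lis[[tk]]$peak,
                 li_mean = fit$trial_lis[[tk]]$mean,
                 stringsAsFactors = FALSE)))
    all_tl[[id]] <- tl
    wv <- do.call(rbind, lapply(fit$waves, function(w)
      data.frame(participant_id = id, task = w$task, time_s = w$time_s,
                 value = w$values, stringsAsFactors = FALSE)))
    all_waves[[id]] <- wv
    excl <- sum(!qc$included)
    message(sprintf("%s: %d/%d epochs included (%d excluded)",
                    id, sum(qc$included), nrow(qc), excl))
  }
  results <- do.call(rbind, all_results)
  write_results(results, file.path(out_dir, "results.csv"))
  utils::write.csv(do.call(rbind, all_qc), file.path(out_dir, "qc.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, all_tl), file.path(out_dir, "trial_lis.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, all_waves), file.path(out_dir, "waves.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, cfg$rng_seed, cfg, inputs = as.list(signal_paths),
                 counts = list(participants = length(signal_paths),
                               result_rows = nrow(results)),
                 outputs = file.path(out_dir, c("results.csv", "qc.csv",
                                                "trial_lis.csv", "waves.csv")))
  invisible(results)
}

wave_from_long <- function(df) {
  structure(list(task = df$task[1], time_s = df$time_s, values = df$value,
                 n_trials = 1L), class = "ftcd_diffwave")
}

#' Compare tasks across processed participants
#'
#' Reads `results.csv` and `waves.csv` from a [run_process()] output
#' directory and writes the comparison table (subtraction methods A/B/C per
#' participant), the word-vs-sentence Bland-Altman summary and a group
#' statistics summary (one-sample and paired signed-rank tests, task
#' correlations, split-half reliabilities, normality checks).
#'
#' @param results_dir Directory written by [run_process()].
#' @param out_dir Output directory (defaults to `results_dir`).
#' @return List with `comparison`, `bland_altman`, `stats`, invisibly.
#' @rdname pipeline-runners
#' @export
run_compare <- function(results_dir, cfg = ftcd_config(), out_dir = results_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- read_results(file.path(results_dir, "results.csv"))
  waves <- utils::read.csv(file.path(results_dir, "waves.csv"),
                           stringsAsFactors = FALSE)
  ids <- unique(results$participant_id)
  if (length(ids) < 3L)
    stop("at least 3 processed participants are required", call. = FALSE)
  comparison <- do.call(rbind, lapply(ids, function(id) {
    r <- results[results$participant_id == id & results$method == "peak", ]
    li <- stats::setNames(r$li, r$task)
    w <- waves[waves$participant_id == id, ]
    dws <- lapply(split(w, w$task), wave_from_long)
    b <- subtract_difference_waves(dws$sentence, dws$list, cfg)
    data.frame(participant_id = id,
               li_sg = li[["sentence"]], li_wg = li[["word"]],
               li_lg = li[["list"]],
               A = subtract_li(li[["sentence"]], li[["list"]]),
               B = b$li,
               C = subtract_poi_means(dws$sentence, dws$list, cfg),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE, quote = FALSE)

  ba <- bland_altman(comparison$li_wg, comparison$li_sg, cfg)
  jsonlite::write_json(unclass(ba), file.path(out_dir, "bland_altman.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  peak <- results[results$method == "peak", ]
  li_by_task <- split(peak$li, peak$task)
  pairs <- utils::combn(task_names, 2, simplify = FALSE)
  stats_summary <- list(
    one_sample = lapply(li_by_task, function(v)
      unclass(signed_rank_one_sample(v, 0))),
    paired = stats::setNames(lapply(pairs, function(p)
      unclass(signed_rank_paired(li_by_task[[p[1]]], li_by_task[[p[2]]]))),
      vapply(pairs, paste, "", collapse = "_vs_")),
    task_correlations = stats::setNames(lapply(pairs, function(p)
      spearman_ci(li_by_task[[p[1]]], li_by_task[[p[2]]], cfg)),
      vapply(pairs, paste, "", collapse = "_vs_")),
    split_half = lapply(split(peak, peak$task), function(r) {
      ok <- is.finite(r$split_half_odd) & is.finite(r$split_half_even)
      if (sum(ok) < 4L) return(NULL)
      spearman_ci(r$split_half_odd[ok], r$split_half_even[ok], cfg)
    }),
    normality = lapply(li_by_task, function(v) unclass(normality_check(v))),
    # directional test: subtraction-referenced sentence LI vs
    # resting-baseline sentence LI, one-tailed at alpha 0.025
    sentence_subtraction = unclass(
      signed_rank_paired(comparison$A, comparison$li_sg,
                         alternative = "greater"))
  )
  jsonlite::write_json(stats_summary, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(comparison = comparison, bland_altman = ba,
                 stats = stats_summary))
}

#' Simulate and fit a cohort of participants in memory
#'
#' Runs [simulate_recording()] and [ftcd_laterality()] for `n` independent
#' participants sharing one simulation configuration, with per-participant
#' seeds `base_seed + 1 .. base_seed + n`. Epoch matrices are dropped to keep
#' the cohort light; results, difference waves and per-trial LIs are kept.
#'
#' @param n Number of participants.
#' @param sim_cfg An [sim_config()] (its `rng_seed` is overridden per
#'   participant).
#' @param cfg An [ftcd_config()].
#' @param base_seed Integer offset for the per-participant seeds.
#' @return List of class `"ftcd_cohort"`: `results` (stacked data frame),
#'   `waves` (per participant), `trial_lis` (per participant), `n`.
#' @rdname pipeline-runners
#' @export
simulate_cohort <- function(n, sim_cfg = sim_config(), cfg = ftcd_config(),
                            base_seed = 1L) {
  results <- vector("list", n)
  waves <- vector("list", n)
  tl <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- sim_cfg
    sc$rng_seed <- as.integer(base_seed + i)
    id <- sprintf("S%03d", i)
    fit <- ftcd_laterality(simulate_recording(sc), cfg, id = id)
    results[[i]] <- fit$results
    waves[[i]] <- fit$waves
    tl[[i]] <- fit$trial_lis
  }
  structure(list(results = do.call(rbind, results), waves = waves,
                 trial_lis = tl, n = n),
            class = "ftcd_cohort")
}

#' Subtraction table for a simulated cohort
#'
#' Per-participant sentence-minus-list values by all three subtraction
#' methods, from an in-memory cohort.
#'
#' @param cohort An `"ftcd_cohort"` from [simulate_cohort()].
#' @param cfg An [ftcd_config()].
#' @return Data frame: participant, li_sg, li_wg, li_lg, A, B, C.
#' @rdname pipeline-runners
#' @export
cohort_subtractions <- function(cohort, cfg = ftcd_config()) {
  stopifnot(inherits(cohort, "ftcd_cohort"))
  do.call(rbind, lapply(seq_len(cohort$n), function(i) {
    r <- cohort$results
    r <- r[r$method == "peak" &
             r$participant_id == unique(r$participant_id)[i], ]
    li <- stats::setNames(r$li, r$task)
    dws <- cohort$waves[[i]]
    b <- subtract_difference_waves(dws$sentence, dws$list, cfg)
    data.frame(participant_id = r$participant_id[1],
               li_sg = li[["sentence"]],
               li_wg = if ("word" %in% names(li)) li[["word"]] else NA_real_,
               li_lg = li[["list"]],
               A = subtract_li(li[["sentence"]], li[["list"]]),
               B = b$li,
               C = subtract_poi_means(dws$sentence, dws$list, cfg),
               stringsAsFactors = FALSE)
  }))
}
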