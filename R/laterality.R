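#' Mean L-R difference wave for one task
#'
#' Pointwise mean over a task's included epochs of the left-minus-right
#' channel difference (percentage points of mean CBFV, baseline-corrected).
#'
#' @param epochs Baseline-corrected epochs.
#' @param task Task label.
#' @return An object of class `"ftcd_diffwave"`: `task`, `time_s`, `values`,
#'   `n_trials`.
#' @export
mean_difference_wave <- function(epochs, task) {
  require_state(epochs, "baselined")
  task <- match.arg(task, task_names)
  sel <- epochs$info$included & epochs$info$task == task
  if (!any(sel))
    stop(sprintf("no included epochs for task '%s'", task), call. = FALSE)
  d <- epochs$left[sel, , drop = FALSE] - epochs$right[sel, , drop = FALSE]
  structure(list(task = task, time_s = epochs$time_s, values = colMeans(d),
                 n_trials = sum(sel)),
            class = "ftcd_diffwave")
}

#' @export
print.ftcd_diffwave <- function(x, ...) {
  cat(sprintf("L-R difference wave (%s): %d trials, %d samples\n",
              x$task, x$n_trials, length(x$values)))
  invisible(x)
}

#' Locate the laterality peak within the period of interest
#'
#' The peak is the sample of maximal *absolute* difference within the POI
#' (so right-lateralised responses are found with correct latencies);
#' ties are broken by the earliest time.
#'
#' @param dw An `"ftcd_diffwave"`.
#' @param cfg An [ftcd_config()].
#' @return Peak latency in epoch seconds.
#' @export
find_peak <- function(dw, cfg = ftcd_config()) {
  stopifnot(inherits(dw, "ftcd_diffwave"))
  sel <- which(in_window(dw$time_s, cfg$poi_s))
  if (!length(sel))
    stop("period of interest contains no samples", call. = FALSE)
  dw$time_s[sel[which.max(abs(dw$values[sel]))]]
}

#' Peak-based laterality index
#'
#' Mean of the difference wave over a 2-s window (at defaults) centred at the
#' peak latency, clipped to the wave's support; the sign is preserved.
#'
#' @param dw An `"ftcd_diffwave"`.
#' @param latency Peak latency from [find_peak()], in epoch seconds.
#' @param cfg An [ftcd_config()].
#' @return LI in percentage points.
#' @export
li_peak <- function(dw, latency, cfg = ftcd_config()) {
  stopifnot(inherits(dw, "ftcd_diffwave"))
  hw <- cfg$peak_window_halfwidth_s
  sel <- in_window(dw$time_s, c(latency - hw, latency + hw))
  if (!any(sel)) stop("peak window contains no samples", call. = FALSE)
  mean(dw$values[sel])
}

#' Mean-based laterality index
#'
#' Mean of the difference wave over the whole period of interest; no peak is
#' identified, which avoids the bimodality the peak method induces near zero.
#'
#' @param dw An `"ftcd_diffwave"`.
#' @param cfg An [ftcd_config()].
#' @return LI in percentage points.
#' @export
li_mean_poi <- function(dw, cfg = ftcd_config()) {
  stopifnot(inherits(dw, "ftcd_diffwave"))
  sel <- in_window(dw$time_s, cfg$poi_s)
  if (!any(sel)) stop("period of interest contains no samples", call. = FALSE)
  mean(dw$values[sel])
}

#' Per-trial laterality indices at a fixed window
#'
#' One LI per included trial of the task: the mean of that trial's L-R
#' difference over the same window used for the group LI (the group-level
#' peak latency, or the POI for the mean method). Using one fixed window per
#' task makes the trial LIs estimates of the same quantity, so their CI
#' quantifies the group LI's uncertainty.
#'
#' @param epochs Baseline-corrected epochs.
#' @param task Task label.
#' @param latency Window centre in epoch seconds (from [find_peak()]); if
#'   `NULL`, the whole POI is used (mean method).
#' @param cfg An [ftcd_config()].
#' @return Numeric vector of per-trial LIs, one per included trial, in the
#'   task's presentation order.
#' @export
trial_lis <- function(epochs, task, latency = NULL, cfg = ftcd_config()) {
  require_state(epochs, "baselined")
  task <- match.arg(task, task_names)
  sel <- epochs$info$included & epochs$info$task == task
  if (!any(sel))
    stop(sprintf("no included epochs for task '%s'", task), call. = FALSE)
  win <- if (is.null(latency)) cfg$poi_s
  else c(latency - cfg$peak_window_halfwidth_s,
         latency + cfg$peak_window_halfwidth_s)
  w <- in_window(epochs$time_s, win)
  if (!any(w)) stop("LI window contains no samples", call. = FALSE)
  d <- epochs$left[sel, w, drop = FALSE] - epochs$right[sel, w, drop = FALSE]
  rowMeans(d)
}

#' Classify laterality from per-trial LIs
#'
#' Computes the t-based confidence interval of the mean per-trial LI
#' (`mean +/- t(1 - alpha/2, n-1) * sd / sqrt(n)`) and classifies:
#' left if the whole CI is above zero, right if below, bilateral otherwise.
#'
#' @param lis Numeric vector of per-trial LIs (n >= 2).
#' @param cfg An [ftcd_config()].
#' @return List with `li` (mean), `ci_low`, `ci_high`, `category`, `n`.
#' @export
classify_laterality <- function(lis, cfg = ftcd_config()) {
  lis <- as.numeric(lis)
  n <- length(lis)
  if (n < 2L)
    stop("at least 2 trial LIs are required for a confidence interval",
         call. = FALSE)
  m <- mean(lis)
  half <- stats::qt(1 - (1 - cfg$ci_level) / 2, n - 1) * stats::sd(lis) / sqrt(n)
  ci <- c(m - half, m + half)
  category <- if (ci[1] > 0) "left" else if (ci[2] < 0) "right" else "bilateral"
  list(li = m, ci_low = ci[1], ci_high = ci[2], category = category, n = n)
}

# within-task ordinal of every trial (presentation order, before exclusions)
task_ordinal <- function(info) {
  ord <- integer(nrow(info))
  for (tk in unique(info$task)) {
    i <- which(info$task == tk)
    ord[i] <- seq_along(i)
  }
  ord
}

#' Split-half laterality indices
#'
#' Runs the full group-level LI procedure independently on the odd- and
#' even-numbered trials of a task (ordinals taken in presentation order
#' within the task): each half gets its own mean difference wave, its own
#' peak and its own averaging window. A half with fewer than 2 included
#' trials yields `NA`.
#'
#' @param epochs Baseline-corrected epochs.
#' @param task Task label.
#' @param cfg An [ftcd_config()].
#' @param method `"peak"` or `"mean"`.
#' @return Named numeric: `li_odd`, `li_even`.
#' @export
split_half <- function(epochs, task, cfg = ftcd_config(),
                       method = c("peak", "mean")) {
  require_state(epochs, "baselined")
  method <- match.arg(method)
  task <- match.arg(task, task_names)
  ord <- task_ordinal(epochs$info)
  half_li <- function(parity) {
    keep <- epochs$info$task == task & ord %% 2L == parity
    sub <- epochs
    sub$info$included <- epochs$info$included & keep
    if (sum(sub$info$included) < 2L) return(NA_real_)
    dw <- mean_difference_wave(sub, task)
    if (method == "peak") li_peak(dw, find_peak(dw, cfg), cfg)
    else li_mean_poi(dw, cfg)
  }
  c(li_odd = half_li(1L), li_even = half_li(0L))
}

#' Fit laterality indices to an fTCD recording
#'
#' The package's central fitting function: preprocesses a raw recording
#' (see [preprocess()]) and estimates, for every task present, the
#' peak-based and mean-based laterality index, its peak latency, the
#' per-trial LIs with their t confidence interval, the
#' left/bilateral/right classification, and odd/even split-half LIs.
#'
#' @param recording A native-rate [ftcd_recording()] (or an
#'   `"ftcd_simulation"`, whose recording is used).
#' @param cfg An [ftcd_config()].
#' @param id Participant identifier stored in the results (default "P1").
#' @return An object of class `"ftcd_laterality"` with components
#'   `results` (data frame, one row per task x method), `waves` (named list
#'   of `"ftcd_diffwave"`), `trial_lis` (nested list by task and method),
#'   `epochs`, `config`, `id`.
#' @seealso [coef.ftcd_laterality()], [summary.ftcd_laterality()],
#'   [plot.ftcd_laterality()]
#' @export
#' @examples
#' sim <- simulate_recording(sim_config(n_trials_per_task = 4L, rng_seed = 7L))
#' fit <- ftcd_laterality(sim, id = "S01")
#' coef(fit)
ftcd_laterality <- function(recording, cfg = ftcd_config(), id = "P1") {
  if (inherits(recording, "ftcd_simulation")) recording <- recording$recording
  stopifnot(inherits(recording, "ftcd_recording"))
  epochs <- preprocess(recording, cfg)
  tasks <- intersect(task_names, unique(epochs$info$task[epochs$info$included]))
  if (!length(tasks))
    stop("no task has included epochs after preprocessing", call. = FALSE)
  rows <- list()
  waves <- list()
  tl <- list()
  for (tk in tasks) {
    dw <- mean_difference_wave(epochs, tk)
    waves[[tk]] <- dw
    lat <- find_peak(dw, cfg)
    res <- list(
      peak = list(latency = lat,
                  lis = trial_lis(epochs, tk, lat, cfg)),
      mean = list(latency = mean(cfg$poi_s),
                  lis = trial_lis(epochs, tk, NULL, cfg))
    )
    tl[[tk]] <- list()
    for (meth in names(res)) {
      cls <- classify_laterality(res[[meth]]$lis, cfg)
      sh <- split_half(epochs, tk, cfg, method = meth)
      tl[[tk]][[meth]] <- res[[meth]]$lis
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = id, task = tk, n_trials_included = cls$n,
        li = cls$li, latency_s = res[[meth]]$latency,
        ci_low = cls$ci_low, ci_high = cls$ci_high,
        category = cls$category, method = meth,
        split_half_odd = sh[["li_odd"]], split_half_even = sh[["li_even"]],
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(id = id, results = do.call(rbind, rows), waves = waves,
                 trial_lis = tl, epochs = epochs, config = cfg),
            class = "ftcd_laterality")
}

#' @export
print.ftcd_laterality <- function(x, ...) {
  cat(sprintf("fTCD laterality fit for %s\n", x$id))
  pk <- x$results[x$results$method == "peak", ]
  for (i in seq_len(nrow(pk)))
    cat(sprintf("  %-8s LI %6.2f [%5.2f, %5.2f]  %-9s (peak at %.2f s, %d trials)\n",
                pk$task[i], pk$li[i], pk$ci_low[i], pk$ci_high[i],
                pk$category[i], pk$latency_s[i], pk$n_trials_included[i]))
  invisible(x)
}

#' @export
summary.ftcd_laterality <- function(object, ...) {
  out <- list(id = object$id, results = object$results,
              qc = qc_table(object$epochs))
  class(out) <- "summary.ftcd_laterality"
  out
}

#' @export
print.summary.ftcd_laterality <- function(x, ...) {
  cat(sprintf("fTCD laterality fit for %s\n\n", x$id))
  print(x$results, row.names = FALSE, digits = 4)
  excl <- x$qc[!x$qc$included, ]
  cat(sprintf("\nEpochs: %d of %d included\n",
              sum(x$qc$included), nrow(x$qc)))
  if (nrow(excl)) {
    tab <- table(excl$exclusion_reason)
    cat("  excluded:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract laterality indices from a fit
#'
#' @param object An `"ftcd_laterality"` fit.
#' @param method `"peak"` (default) or `"mean"`.
#' @param ... Unused.
#' @return Named numeric vector of LIs, one per task.
#' @export
coef.ftcd_laterality <- function(object, method = c("peak", "mean"), ...) {
  method <- match.arg(method)
  r <- object$results[object$results$method == method, ]
  stats::setNames(r$li, r$task)
}

#' Confidence intervals of the laterality indices
#'
#' @param object An `"ftcd_laterality"` fit.
#' @param parm Tasks to include (default all).
#' @param level Unused; the level is fixed by the fit's configuration.
#' @param method `"peak"` (default) or `"mean"`.
#' @param ... Unused.
#' @return Matrix with columns `lower`, `upper` and one row per task.
#' @export
confint.ftcd_laterality <- function(object, parm = NULL, level = NULL,
                                    method = c("peak", "mean"), ...) {
  method <- match.arg(method)
  r <- object$results[object$results$method == method, ]
  if (!is.null(parm)) r <- r[r$task %in% parm, ]
  out <- cbind(lower = r$ci_low, upper = r$ci_high)
  rownames(out) <- r$task
  out
}

#' Plot the fitted difference waves
#'
#' Draws the mean L-R difference wave per task with the period of interest
#' shaded, the baseline window marked, and the peak-window LI annotated.
#'
#' @param x An `"ftcd_laterality"` fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ftcd_laterality <- function(x, ...) {
  waves <- x$waves
  tt <- waves[[1]]$time_s
  vals <- sapply(waves, function(w) w$values)
  cols <- stats::setNames(c("#D55E00", "#0072B2", "#009E73")[seq_along(waves)],
                          names(waves))
  graphics::matplot(tt, vals, type = "l", lty = 1, col = cols,
                    xlab = "epoch time (s)",
                    ylab = "L - R difference (% CBFV)", ...)
  graphics::rect(x$config$poi_s[1], graphics::par("usr")[3],
                 x$config$poi_s[2], graphics::par("usr")[4],
                 col = grDevices::adjustcolor("grey", 0.25), border = NA)
  graphics::abline(h = 0, col = "grey40", lty = 3)
  pk <- x$results[x$results$method == "peak", ]
  graphics::points(pk$latency_s, pk$li, pch = 19, col = cols[pk$task])
  graphics::legend("topleft", legend = names(waves), col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}
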