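#' @title Epoch container and preprocessing steps
#' @description The preprocessing chain transforms a raw recording into
#'   cleaned, normalised, heart-cycle-integrated, baseline-corrected epochs.
#'   Steps must run in the fixed order
#'   downsample -> segment_epochs -> despike -> normalise_epochs ->
#'   integrate_heart_cycles -> baseline_correct -> reject_artifacts;
#'   each step refuses epochs in the wrong processing state. Excluded epochs
#'   keep their data and carry an exclusion reason.
#' @name preprocess-steps
NULL

EPOCH_STATES <- c("raw", "despiked", "normalised", "integrated", "baselined")

new_epochs <- function(left, right, info, time_s, sample_rate, state) {
  structure(list(left = left, right = right, info = info, time_s = time_s,
                 sample_rate = sample_rate, state = state,
                 prebaseline = NULL),
            class = "ftcd_epochs")
}

require_state <- function(epochs, state) {
  stopifnot(inherits(epochs, "ftcd_epochs"))
  if (!identical(epochs$state, state))
    stop(sprintf("epochs are in state '%s'; this step requires state '%s'",
                 epochs$state, state), call. = FALSE)
  invisible(epochs)
}

exclude_epoch <- function(epochs, i, reason) {
  epochs$info$included[i] <- FALSE
  epochs$info$exclusion_reason[i] <- reason
  epochs
}

#' @export
print.ftcd_epochs <- function(x, ...) {
  inc <- sum(x$info$included)
  cat(sprintf("fTCD epochs: %d trials (%d included), %d samples at %g Hz, state '%s'\n",
              nrow(x$info), inc, ncol(x$left), x$sample_rate, x$state))
  excl <- table(x$info$exclusion_reason[!x$info$included])
  if (length(excl))
    cat("  exclusions:", paste(sprintf("%s=%d", names(excl), excl), collapse = ", "), "\n")
  invisible(x)
}

#' Down-sample a recording by block averaging
#'
#' Each output sample is the mean of a block of `factor` consecutive input
#' samples (a trailing partial block is discarded); trial markers are
#' relocated to the output block containing them.
#'
#' @param rec An [ftcd_recording()].
#' @param factor Positive integer decimation factor (default 4, 100 -> 25 Hz).
#' @return A new [ftcd_recording()] at `sample_rate / factor`.
#' @export
downsample <- function(rec, factor = 4L) {
  stopifnot(inherits(rec, "ftcd_recording"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("downsample factor must be a positive integer", call. = FALSE)
  n_out <- length(rec$left) %/% factor
  if (n_out < 1L) stop("recording shorter than one block", call. = FALSE)
  block_mean <- function(x)
    colMeans(matrix(x[seq_len(n_out * factor)], nrow = factor))
  marker <- integer(n_out)
  hits <- which(rec$marker != 0L)
  out_pos <- (hits - 1L) %/% factor + 1L
  keep <- out_pos <= n_out
  marker[out_pos[keep]] <- rec$marker[hits[keep]]
  ftcd_recording(block_mean(rec$left), block_mean(rec$right), marker,
                 rec$sample_rate / factor)
}

#' Segment a recording into 30-s trial epochs
#'
#' One epoch per trial marker, starting `epoch_start_s` seconds before the
#' trigger. Epochs overrunning either end of the recording are retained but
#' flagged `incomplete_epoch` (their missing samples are `NA`).
#'
#' @param rec A (down-sampled) [ftcd_recording()].
#' @param cfg An [ftcd_config()].
#' @return An `"ftcd_epochs"` object in state `"raw"`.
#' @export
segment_epochs <- function(rec, cfg = ftcd_config()) {
  stopifnot(inherits(rec, "ftcd_recording"))
  rate <- rec$sample_rate
  pre <- round_half_up(cfg$epoch_start_s * rate)
  len <- round_half_up(cfg$epoch_length_s * rate)
  n <- length(rec$left)
  hits <- which(rec$marker != 0L)
  if (!length(hits)) warning("recording contains no trial markers")
  n_ep <- length(hits)
  left <- matrix(NA_real_, n_ep, len)
  right <- matrix(NA_real_, n_ep, len)
  complete <- logical(n_ep)
  for (i in seq_len(n_ep)) {
    start <- hits[i] - pre
    idx <- start:(start + len - 1L)
    ok <- idx >= 1L & idx <= n
    complete[i] <- all(ok)
    left[i, ok] <- rec$left[idx[ok]]
    right[i, ok] <- rec$right[idx[ok]]
  }
  info <- data.frame(
    trial = seq_len(n_ep),
    task = if (n_ep) decode_task(rec$marker[hits]) else character(0),
    trigger_sample = hits,
    included = complete,
    exclusion_reason = ifelse(complete, "none", "incomplete_epoch"),
    stringsAsFactors = FALSE
  )
  new_epochs(left, right, info, time_s = (seq_len(len) - 1) / rate,
             sample_rate = rate, state = "raw")
}

# indices of out-of-range samples: isolated singles (interpolable) vs runs
classify_exceedances <- function(out) {
  r <- rle(out)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values)
  list(single = starts[hit][r$lengths[hit] == 1L],
       run = any(r$lengths[hit] >= 2L))
}

interp_singles <- function(x, singles, out) {
  ok <- which(!out)
  for (s in singles) {
    lo <- ok[ok < s]
    hi <- ok[ok > s]
    if (length(lo) && length(hi)) {
      l <- max(lo); h <- min(hi)
      x[s] <- x[l] + (x[h] - x[l]) * (s - l) / (h - l)
    } else if (length(lo)) {
      x[s] <- x[max(lo)]
    } else if (length(hi)) {
      x[s] <- x[min(hi)]
    }
  }
  x
}

#' Interpolate isolated signal spikes, exclude dropout runs
#'
#' Per channel, extreme values are those beyond the empirical
#' `spike_quantile_low` / `spike_quantile_high` quantiles computed over all
#' epoch samples of the recording. A single isolated extreme sample is
#' replaced by linear interpolation between its nearest in-range neighbours;
#' a run of two or more consecutive extreme samples marks a longer signal
#' loss and excludes the epoch (`dropout_run`).
#'
#' @param epochs Epochs in state `"raw"`.
#' @param cfg An [ftcd_config()].
#' @return Epochs in state `"despiked"`.
#' @export
despike <- function(epochs, cfg = ftcd_config()) {
  require_state(epochs, "raw")
  for (ch in c("left", "right")) {
    v <- epochs[[ch]]
    all_samples <- v[!is.na(v)]
    if (!length(all_samples)) next
    thr <- stats::quantile(all_samples,
                           c(cfg$spike_quantile_low, cfg$spike_quantile_high),
                           names = FALSE)
    for (i in which(epochs$info$included)) {
      x <- v[i, ]
      out <- x < thr[1] | x > thr[2]
      if (!any(out)) next
      if (all(out))
        stop("degenerate epoch: all samples extreme", call. = FALSE)
      exc <- classify_exceedances(out)
      if (exc$run) {
        epochs <- exclude_epoch(epochs, i, "dropout_run")
        next
      }
      v[i, ] <- interp_singles(x, exc$single, out)
    }
    epochs[[ch]] <- v
  }
  epochs$state <- "despiked"
  epochs
}

#' Normalise channels to a grand mean of 100
#'
#' Each channel is divided by its mean over all included epochs' samples and
#' multiplied by 100, making velocities independent of the insonation angle
#' and vessel diameter; after this step each channel's grand mean over
#' included epochs is exactly 100 (percent of mean CBFV).
#'
#' @param epochs Epochs in state `"despiked"`.
#' @return Epochs in state `"normalised"`.
#' @export
normalise_epochs <- function(epochs) {
  require_state(epochs, "despiked")
  inc <- epochs$info$included
  if (!any(inc)) stop("no included epochs to normalise", call. = FALSE)
  for (ch in c("left", "right")) {
    f <- mean(epochs[[ch]][inc, , drop = FALSE])
    if (!is.finite(f) || f <= 0)
      stop(sprintf("non-positive mean in %s channel; cannot normalise", ch),
           call. = FALSE)
    epochs[[ch]] <- epochs[[ch]] * (100 / f)
  }
  epochs$state <- "normalised"
  epochs
}

# local maxima with prominence >= prom_min, thinned to min_sep samples,
# returned in temporal order
find_systolic_peaks <- function(x, min_sep, prom_min) {
  n <- length(x)
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    v <- x[i]
    lmin <- v; j <- i
    while (j > 1L) {
      j <- j - 1L
      if (x[j] > v) break
      if (x[j] < lmin) lmin <- x[j]
    }
    rmin <- v; j <- i
    while (j < n) {
      j <- j + 1L
      if (x[j] > v) break
      if (x[j] < rmin) rmin <- x[j]
    }
    v - max(lmin, rmin)
  }, numeric(1))
  cand <- cand[prom >= prom_min]
  if (!length(cand)) return(integer(0))
  # greedy thinning, tallest first
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord)
    if (!length(kept) || all(abs(kept - p) >= min_sep)) kept <- c(kept, p)
  sort(kept)
}

#' Remove cardiac pulsatility by heart-cycle integration
#'
#' Systolic peaks are detected on the mean of the two channels (cardiac
#' cycles are common to both): local maxima separated by at least
#' `min_cycle_separation_s` with prominence of at least 25% of the epoch's
#' peak-to-trough pulse amplitude. Every sample within a peak-to-peak cycle
#' is replaced by that cycle's per-channel mean; samples before the first or
#' after the last peak take the nearest cycle's mean. Epochs with fewer than
#' 3 detected peaks cannot be integrated and are excluded.
#'
#' @param epochs Epochs in state `"normalised"`.
#' @param cfg An [ftcd_config()].
#' @return Epochs in state `"integrated"`.
#' @export
integrate_heart_cycles <- function(epochs, cfg = ftcd_config()) {
  require_state(epochs, "normalised")
  min_sep <- max(1L, round_half_up(cfg$min_cycle_separation_s * epochs$sample_rate))
  for (i in which(epochs$info$included)) {
    l <- epochs$left[i, ]; r <- epochs$right[i, ]
    m <- (l + r) / 2
    peaks <- find_systolic_peaks(m, min_sep, 0.25 * (max(m) - min(m)))
    if (length(peaks) < 3L) {
      epochs <- exclude_epoch(epochs, i, "cannot_integrate")
      next
    }
    cyc <- findInterval(seq_along(m), peaks)
    cyc <- pmin(pmax(cyc, 1L), length(peaks) - 1L)
    epochs$left[i, ] <- ave(l, cyc)
    epochs$right[i, ] <- ave(r, cyc)
  }
  epochs$state <- "integrated"
  epochs
}

#' Baseline-correct epochs against the pre-trigger rest period
#'
#' Subtracts, per channel and epoch, the mean over the baseline window, so
#' values become percentage-point change from rest and the baseline-window
#' mean is zero. The pre-baseline (integrated, normalised) values are kept
#' alongside for artifact screening.
#'
#' @param epochs Epochs in state `"integrated"`.
#' @param cfg An [ftcd_config()].
#' @return Epochs in state `"baselined"`.
#' @export
baseline_correct <- function(epochs, cfg = ftcd_config()) {
  require_state(epochs, "integrated")
  bsel <- in_window(epochs$time_s, cfg$baseline_window_s)
  if (!any(bsel)) stop("baseline window contains no samples", call. = FALSE)
  epochs$prebaseline <- list(left = epochs$left, right = epochs$right)
  for (i in which(epochs$info$included)) {
    if (anyNA(epochs$left[i, bsel]) || anyNA(epochs$right[i, bsel])) {
      epochs <- exclude_epoch(epochs, i, "incomplete_epoch")
      next
    }
    epochs$left[i, ] <- epochs$left[i, ] - mean(epochs$left[i, bsel])
    epochs$right[i, ] <- epochs$right[i, ] - mean(epochs$right[i, bsel])
  }
  epochs$state <- "baselined"
  epochs
}

#' Reject epochs containing out-of-range values
#'
#' An epoch is excluded (`artifact_out_of_range`) if, in either channel, any
#' heart-cycle-integrated normalised sample falls below `artifact_low_pct` or
#' above `artifact_high_pct` percent of the mean (the pre-baseline signal,
#' whose mean is 100).
#'
#' @param epochs Epochs in state `"baselined"`.
#' @param cfg An [ftcd_config()].
#' @return Epochs, still in state `"baselined"`, with rejections applied.
#' @export
reject_artifacts <- function(epochs, cfg = ftcd_config()) {
  require_state(epochs, "baselined")
  if (is.null(epochs$prebaseline))
    stop("pre-baseline values unavailable; run baseline_correct first",
         call. = FALSE)
  for (i in which(epochs$info$included)) {
    vals <- c(epochs$prebaseline$left[i, ], epochs$prebaseline$right[i, ])
    if (any(vals < cfg$artifact_low_pct | vals > cfg$artifact_high_pct,
            na.rm = TRUE))
      epochs <- exclude_epoch(epochs, i, "artifact_out_of_range")
  }
  epochs
}

#' Run the full preprocessing chain
#'
#' @param rec A native-rate [ftcd_recording()].
#' @param cfg An [ftcd_config()].
#' @return Baseline-corrected, artifact-screened epochs.
#' @export
preprocess <- function(rec, cfg = ftcd_config()) {
  rec |>
    downsample(cfg$downsample_factor) |>
    segment_epochs(cfg) |>
    despike(cfg) |>
    normalise_epochs() |>
    integrate_heart_cycles(cfg) |>
    baseline_correct(cfg) |>
    reject_artifacts(cfg)
}

#' Epoch-level quality-control table
#'
#' @param epochs An `"ftcd_epochs"` object at any state.
#' @return Data frame with one row per trial: trial, task, included,
#'   exclusion_reason.
#' @export
qc_table <- function(epochs) {
  stopifnot(inherits(epochs, "ftcd_epochs"))
  epochs$info[, c("trial", "task", "included", "exclusion_reason")]
}
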