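#' Analysis pipeline configuration
#'
#' Collects every timing window and threshold used by the fTCD laterality
#' pipeline in one validated object. All times are in seconds of epoch time,
#' where epoch time 0 is `epoch_start_s` seconds *before* the trigger stimulus
#' (so at the defaults the stimulus appears at epoch time 5 s). Windows are
#' half-open `[start, end)`.
#'
#' @param downsample_factor Integer block size for mean down-sampling
#'   (default 4: 100 Hz native -> 25 Hz working rate).
#' @param epoch_start_s Seconds of pre-trigger signal included in each epoch
#'   (default 5).
#' @param epoch_length_s Total epoch duration in seconds (default 30).
#' @param baseline_window_s Two-element numeric, the resting baseline window in
#'   epoch time used to zero each channel (default `c(0, 5)`).
#' @param poi_s Two-element numeric, the period of interest within which the
#'   L-R peak is sought (default `c(7, 17)`, the covert-generation phase).
#' @param peak_window_halfwidth_s Half-width of the averaging window centred on
#'   the peak, in seconds (default 1, i.e. a 2-s window).
#' @param artifact_low_pct,artifact_high_pct Rejection bounds as a percentage
#'   of mean normalised velocity (defaults 60 and 140).
#' @param spike_quantile_low,spike_quantile_high Empirical quantile
#'   probabilities defining extreme single-sample spikes (defaults 0.0001 and
#'   0.9999).
#' @param predetermined_loa Two-element numeric, predetermined Bland-Altman
#'   limits of agreement in LI units (default `c(-2.5, 2.5)`).
#' @param ci_level Confidence level for per-trial LI intervals and bootstrap
#'   intervals (default 0.95).
#' @param min_cycle_separation_s Minimum separation between detected systolic
#'   peaks in seconds (default 0.33, i.e. a ceiling near 180 bpm).
#' @param bootstrap_n Number of bootstrap resamples for Spearman confidence
#'   intervals (default 1999).
#' @param rng_seed Integer seed used by the seeded bootstrap.
#'
#' @return An object of class `"ftcd_config"` (a validated named list).
#' @seealso [load_config()] to read the same fields from a JSON file.
#' @export
#' @examples
#' cfg <- ftcd_config()
#' cfg$poi_s
ftcd_config <- function(downsample_factor = 4L,
                        epoch_start_s = 5,
                        epoch_length_s = 30,
                        baseline_window_s = c(0, 5),
                        poi_s = c(7, 17),
                        peak_window_halfwidth_s = 1,
                        artifact_low_pct = 60,
                        artifact_high_pct = 140,
                        spike_quantile_low = 0.0001,
                        spike_quantile_high = 0.9999,
                        predetermined_loa = c(-2.5, 2.5),
                        ci_level = 0.95,
                        min_cycle_separation_s = 0.33,
                        bootstrap_n = 1999L,
                        rng_seed = 1L) {
  cfg <- list(
    downsample_factor = as.integer(downsample_factor),
    epoch_start_s = as.numeric(epoch_start_s),
    epoch_length_s = as.numeric(epoch_length_s),
    baseline_window_s = as.numeric(baseline_window_s),
    poi_s = as.numeric(poi_s),
    peak_window_halfwidth_s = as.numeric(peak_window_halfwidth_s),
    artifact_low_pct = as.numeric(artifact_low_pct),
    artifact_high_pct = as.numeric(artifact_high_pct),
    spike_quantile_low = as.numeric(spike_quantile_low),
    spike_quantile_high = as.numeric(spike_quantile_high),
    predetermined_loa = as.numeric(predetermined_loa),
    ci_level = as.numeric(ci_level),
    min_cycle_separation_s = as.numeric(min_cycle_separation_s),
    bootstrap_n = as.integer(bootstrap_n),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  class(cfg) <- "ftcd_config"
  cfg
}

validate_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid configuration: ", msg, call. = FALSE)
  if (is.na(cfg$downsample_factor) || cfg$downsample_factor < 1L)
    stop_cfg("downsample_factor must be a positive integer")
  if (cfg$epoch_length_s <= 0) stop_cfg("epoch_length_s must be positive")
  if (cfg$epoch_start_s < 0 || cfg$epoch_start_s >= cfg$epoch_length_s)
    stop_cfg("epoch_start_s must lie within the epoch")
  for (w in c("baseline_window_s", "poi_s", "predetermined_loa")) {
    v <- cfg[[w]]
    if (length(v) != 2L || any(!is.finite(v)) || v[1] >= v[2])
      stop_cfg(sprintf("%s must be an increasing pair", w))
  }
  for (w in c("baseline_window_s", "poi_s")) {
    v <- cfg[[w]]
    if (v[1] < 0 || v[2] > cfg$epoch_length_s)
      stop_cfg(sprintf("%s must lie within [0, epoch_length_s]", w))
  }
  if (cfg$baseline_window_s[2] > cfg$poi_s[1])
    stop_cfg("baseline window must precede the period of interest")
  q <- c(cfg$spike_quantile_low, cfg$spike_quantile_high)
  if (any(q <= 0) || any(q >= 1) || q[1] >= q[2])
    stop_cfg("spike quantiles must satisfy 0 < low < high < 1")
  if (cfg$artifact_low_pct >= cfg$artifact_high_pct)
    stop_cfg("artifact_low_pct must be below artifact_high_pct")
  if (cfg$ci_level <= 0 || cfg$ci_level >= 1)
    stop_cfg("ci_level must lie in (0, 1)")
  if (cfg$peak_window_halfwidth_s <= 0)
    stop_cfg("peak_window_halfwidth_s must be positive")
  if (cfg$min_cycle_separation_s <= 0)
    stop_cfg("min_cycle_separation_s must be positive")
  if (is.na(cfg$bootstrap_n) || cfg$bootstrap_n < 1L)
    stop_cfg("bootstrap_n must be a positive integer")
  invisible(cfg)
}

#' Load a pipeline configuration from JSON
#'
#' Reads a JSON object whose keys are a subset of the [ftcd_config()]
#' arguments; absent keys take their defaults, unknown keys are rejected.
#'
#' @param path Path to a JSON file.
#' @return An `"ftcd_config"` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a JSON object", call. = FALSE)
  known <- names(formals(ftcd_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(ftcd_config, raw)
}

#' @export
print.ftcd_config <- function(x, ...) {
  cat("fTCD pipeline configuration\n")
  cat(sprintf("  working rate: native/%d; epoch %g s (%g s pre-trigger)\n",
              x$downsample_factor, x$epoch_length_s, x$epoch_start_s))
  cat(sprintf("  baseline [%g, %g) s; POI [%g, %g) s; peak window +/- %g s\n",
              x$baseline_window_s[1], x$baseline_window_s[2],
              x$poi_s[1], x$poi_s[2], x$peak_window_halfwidth_s))
  cat(sprintf("  artifacts outside [%g, %g]%% of mean; spike quantiles %g/%g\n",
              x$artifact_low_pct, x$artifact_high_pct,
              x$spike_quantile_low, x$spike_quantile_high))
  cat(sprintf("  LoA [%g, %g]; CI level %g; bootstrap n %d (seed %d)\n",
              x$predetermined_loa[1], x$predetermined_loa[2],
              x$ci_level, x$bootstrap_n, x$rng_seed))
  invisible(x)
}

# seconds -> number of samples at `rate`, rounding half-up
round_half_up <- function(x) floor(x + 0.5)

# logical index of epoch-time samples falling in half-open window [w1, w2)
in_window <- function(time_s, w) time_s >= w[1] & time_s < w[2]
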