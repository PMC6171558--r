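#' Simulation configuration for synthetic fTCD recordings
#'
#' Parameters of the generative model used by [simulate_recording()]:
#' a multiplicative cardiac pulse on a per-channel base velocity, a task-locked
#' bilateral evoked rise with a lateralised (left minus right) component,
#' Gaussian sample noise, slow per-channel random-walk drift, and occasional
#' single-sample spikes and multi-sample dropouts.
#'
#' @param n_trials_per_task Trials per task (default 20; three tasks).
#' @param task_order Optional explicit character vector of task labels
#'   (`"list"`, `"sentence"`, `"word"`); by default tasks are pseudorandomly
#'   interleaved in two balanced runs.
#' @param inter_trial_interval_s Stimulus-onset asynchrony in seconds
#'   (default 30).
#' @param heart_rate_bpm Mean heart rate (default 70).
#' @param heart_rate_jitter_bpm Beat-to-beat sd of the rate (default 3).
#' @param base_velocity_cms Length-2 numeric, baseline CBFV for the left and
#'   right channel (defaults 55 and 53 cm/s).
#' @param pulse_modulation_depth Cardiac modulation depth as a fraction of the
#'   base velocity (default 0.25).
#' @param evoked_amplitude_pct Bilateral task-evoked plateau rise, percent of
#'   base (default 3).
#' @param planted_li_pct Named numeric: target plateau L-R difference per task
#'   in percentage points (defaults list 0, sentence 5, word 2.5).
#' @param evoked_onset_delay_s Delay of the evoked rise after stimulus onset
#'   (default 2.5 s, the flow response latency).
#' @param noise_sd_pct Gaussian sample noise sd, percent of base (default 0.8).
#' @param drift_sd_pct Per-sample step sd of the per-channel random-walk drift,
#'   percent of base (default 0.02 at the native rate).
#' @param spike_prob_per_trial,dropout_prob_per_trial Probability that a trial
#'   carries an injected single-sample spike / a >= 0.5 s near-zero dropout
#'   (defaults 0.05 and 0.03).
#' @param rng_seed Integer seed; identical seeds give identical recordings.
#' @return An object of class `"ftcd_sim_config"`.
#' @export
sim_config <- function(n_trials_per_task = 20L,
                       task_order = NULL,
                       inter_trial_interval_s = 30,
                       heart_rate_bpm = 70,
                       heart_rate_jitter_bpm = 3,
                       base_velocity_cms = c(left = 55, right = 53),
                       pulse_modulation_depth = 0.25,
                       evoked_amplitude_pct = 3,
                       planted_li_pct = c(list = 0, sentence = 5, word = 2.5),
                       evoked_onset_delay_s = 2.5,
                       noise_sd_pct = 0.8,
                       drift_sd_pct = 0.02,
                       spike_prob_per_trial = 0.05,
                       dropout_prob_per_trial = 0.03,
                       rng_seed = 1L) {
  cfg <- list(n_trials_per_task = as.integer(n_trials_per_task),
              task_order = task_order,
              inter_trial_interval_s = as.numeric(inter_trial_interval_s),
              heart_rate_bpm = as.numeric(heart_rate_bpm),
              heart_rate_jitter_bpm = as.numeric(heart_rate_jitter_bpm),
              base_velocity_cms = as.numeric(base_velocity_cms),
              pulse_modulation_depth = as.numeric(pulse_modulation_depth),
              evoked_amplitude_pct = as.numeric(evoked_amplitude_pct),
              planted_li_pct = planted_li_pct,
              evoked_onset_delay_s = as.numeric(evoked_onset_delay_s),
              noise_sd_pct = as.numeric(noise_sd_pct),
              drift_sd_pct = as.numeric(drift_sd_pct),
              spike_prob_per_trial = as.numeric(spike_prob_per_trial),
              dropout_prob_per_trial = as.numeric(dropout_prob_per_trial),
              rng_seed = as.integer(rng_seed))
  stop_cfg <- function(msg) stop("invalid simulation config: ", msg, call. = FALSE)
  if (is.na(cfg$n_trials_per_task) || cfg$n_trials_per_task < 1L)
    stop_cfg("n_trials_per_task must be a positive integer")
  if (cfg$inter_trial_interval_s <= 0) stop_cfg("inter_trial_interval_s must be positive")
  if (cfg$heart_rate_bpm <= 0) stop_cfg("heart_rate_bpm must be positive")
  if (cfg$heart_rate_jitter_bpm < 0) stop_cfg("heart_rate_jitter_bpm must be >= 0")
  if (length(cfg$base_velocity_cms) != 2L || any(cfg$base_velocity_cms <= 0))
    stop_cfg("base_velocity_cms must be two positive values")
  if (cfg$pulse_modulation_depth < 0) stop_cfg("pulse_modulation_depth must be >= 0")
  if (cfg$evoked_amplitude_pct < 0) stop_cfg("evoked_amplitude_pct must be >= 0")
  if (!all(task_names %in% names(cfg$planted_li_pct)))
    stop_cfg("planted_li_pct must name all of list, sentence, word")
  if (cfg$evoked_onset_delay_s < 0) stop_cfg("evoked_onset_delay_s must be >= 0")
  if (cfg$noise_sd_pct < 0 || cfg$drift_sd_pct < 0)
    stop_cfg("noise and drift sd must be >= 0")
  for (p in c("spike_prob_per_trial", "dropout_prob_per_trial"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop_cfg(sprintf("%s must lie in [0, 1]", p))
  if (!is.null(task_order)) {
    if (!all(task_order %in% task_names))
      stop_cfg("task_order must use labels list/sentence/word")
    cfg$task_order <- as.character(task_order)
  }
  class(cfg) <- "ftcd_sim_config"
  cfg
}

# native acquisition rate of the simulated Doppler device
SIM_RATE_HZ <- 100
# rest before the first stimulus onset and after the last epoch ends
SIM_LEAD_IN_S <- 15
SIM_TAIL_S <- 30
# evoked envelope shape (seconds after stimulus onset): raised-cosine ramp to
# a plateau sustained through the 10-s covert-generation phase, then decay
SIM_EVOKED_RISE_S <- 2
SIM_EVOKED_PLATEAU_END_S <- 12
SIM_EVOKED_DECAY_S <- 4
# simulated mean words produced per trial (behavioural metadata only)
SIM_WORDS_MEAN <- c(list = 10, sentence = 9, word = 4)

#' Cardiac modulation waveform
#'
#' Zero-mean periodic pulse shape as a function of cardiac phase: a fast
#' systolic rise peaking at phase 0.2 followed by a slow diastolic decay.
#' Built as a Beta(3, 9) density minus 1, so its integral over one cycle is
#' exactly zero and cycle-averaged velocity equals the slow (non-pulsatile)
#' component.
#'
#' @param phase Numeric vector of cycle fractions in `[0, 1)`.
#' @return Dimensionless modulation factors (multiplied by the modulation
#'   depth and the base velocity in the generative model).
#' @export
cardiac_waveform <- function(phase) {
  if (any(phase < 0 | phase >= 1)) stop("phase must lie in [0, 1)", call. = FALSE)
  stats::dbeta(phase, 3, 9) - 1
}

# envelope of the evoked response, 0..1, as a function of seconds since onset
evoked_envelope <- function(t, onset_delay) {
  rise_end <- onset_delay + SIM_EVOKED_RISE_S
  decay_end <- SIM_EVOKED_PLATEAU_END_S + SIM_EVOKED_DECAY_S
  r <- numeric(length(t))
  i <- t >= onset_delay & t < rise_end
  r[i] <- 0.5 - 0.5 * cos(pi * (t[i] - onset_delay) / SIM_EVOKED_RISE_S)
  r[t >= rise_end & t < SIM_EVOKED_PLATEAU_END_S] <- 1
  i <- t >= SIM_EVOKED_PLATEAU_END_S & t < decay_end
  r[i] <- 0.5 + 0.5 * cos(pi * (t[i] - SIM_EVOKED_PLATEAU_END_S) / SIM_EVOKED_DECAY_S)
  r
}

#' Task-evoked velocity increase per channel
#'
#' The evoked model satisfies two constraints on the plateau: the mean of the
#' two channels equals `evoked_amplitude_pct` and the left-minus-right
#' difference equals the task's `planted_li_pct`. Hence plateau values are
#' `amplitude +/- planted/2` per channel.
#'
#' @param t_since_stimulus Seconds relative to stimulus onset (any real).
#' @param cfg An [sim_config()] object.
#' @param task Task label (`"list"`, `"sentence"` or `"word"`).
#' @return A two-column matrix (`left`, `right`) of velocity increases in
#'   percent of the channel base velocity; zero before the onset delay.
#' @export
evoked_response <- function(t_since_stimulus, cfg, task) {
  task <- match.arg(task, task_names)
  li <- as.numeric(cfg$planted_li_pct[[task]])
  r <- evoked_envelope(t_since_stimulus, cfg$evoked_onset_delay_s)
  cbind(left = (cfg$evoked_amplitude_pct + li / 2) * r,
        right = (cfg$evoked_amplitude_pct - li / 2) * r)
}

sim_task_order <- function(cfg) {
  if (!is.null(cfg$task_order)) return(cfg$task_order)
  n <- cfg$n_trials_per_task
  if (n %% 2L == 0L) {
    # two balanced runs of 3n/2 trials each, shuffled within run
    half <- rep(task_names, each = n %/% 2L)
    c(sample(half), sample(half))
  } else {
    sample(rep(task_names, each = n))
  }
}

#' Simulate a dual-channel fTCD recording with ground truth
#'
#' Generates a native-rate (100 Hz) recording of interleaved word, sentence
#' and list generation trials on the study's trial timing, with per-trial
#' ground truth (planted lateralisation, injected artifacts, simulated word
#' counts). Velocity is
#' `base * (1 + depth * cardiac + evoked/100 + drift/100) + noise`.
#' The same seed always yields an identical recording.
#'
#' @param cfg An [sim_config()] object.
#' @return A list of class `"ftcd_simulation"` with elements `recording`
#'   (an [ftcd_recording()]), `truth` (per-trial data frame: `trial`, `task`,
#'   `trigger_sample`, `planted_li`, `artifact`, `n_words`) and `config`.
#' @export
simulate_recording <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "ftcd_sim_config"))
  set.seed(cfg$rng_seed)
  fs <- SIM_RATE_HZ
  tasks <- sim_task_order(cfg)
  n_trials <- length(tasks)
  onsets_s <- SIM_LEAD_IN_S + (seq_len(n_trials) - 1) * cfg$inter_trial_interval_s
  duration_s <- onsets_s[n_trials] + SIM_TAIL_S
  n <- round_half_up(duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  # cardiac phase: piecewise-linear within beats of jittered duration
  mean_period <- 60 / cfg$heart_rate_bpm
  n_beats <- ceiling(duration_s / mean_period * 1.5) + 10L
  bpm <- stats::rnorm(n_beats, cfg$heart_rate_bpm, cfg$heart_rate_jitter_bpm)
  bpm <- pmax(bpm, cfg$heart_rate_bpm / 2)
  periods <- 60 / bpm
  starts <- c(0, cumsum(periods))
  beat <- findInterval(t, starts)
  phase <- (t - starts[beat]) / periods[beat]
  pulse <- cfg$pulse_modulation_depth * cardiac_waveform(phase)

  # task-evoked component, percent of base, accumulated per trial
  evoked_l <- numeric(n)
  evoked_r <- numeric(n)
  support_end <- SIM_EVOKED_PLATEAU_END_S + SIM_EVOKED_DECAY_S
  for (i in seq_len(n_trials)) {
    i0 <- round_half_up(onsets_s[i] * fs) + 1L
    i1 <- min(n, round_half_up((onsets_s[i] + support_end) * fs) + 1L)
    idx <- i0:i1
    ev <- evoked_response(t[idx] - onsets_s[i], cfg, tasks[i])
    evoked_l[idx] <- evoked_l[idx] + ev[, "left"]
    evoked_r[idx] <- evoked_r[idx] + ev[, "right"]
  }

  drift_l <- cumsum(stats::rnorm(n, 0, cfg$drift_sd_pct))
  drift_r <- cumsum(stats::rnorm(n, 0, cfg$drift_sd_pct))
  base <- cfg$base_velocity_cms
  left <- base[1] * (1 + pulse + evoked_l / 100 + drift_l / 100) +
    stats::rnorm(n, 0, cfg$noise_sd_pct / 100 * base[1])
  right <- base[2] * (1 + pulse + evoked_r / 100 + drift_r / 100) +
    stats::rnorm(n, 0, cfg$noise_sd_pct / 100 * base[2])

  trigger_sample <- as.integer(round_half_up(onsets_s * fs)) + 1L
  marker <- integer(n)
  marker[trigger_sample] <- task_codes[tasks]

  # artifact injection: at most one artifact per trial, anywhere in its epoch
  artifact <- rep("none", n_trials)
  u <- stats::runif(n_trials)
  for (i in seq_len(n_trials)) {
    chan_left <- stats::runif(1) < 0.5
    if (u[i] < cfg$spike_prob_per_trial) {
      artifact[i] <- "spike"
      at <- round_half_up((onsets_s[i] + stats::runif(1, -4, 24)) * fs) + 1L
      at <- min(max(at, 1L), n)
      spike_val <- 8 * base[if (chan_left) 1 else 2]
      if (chan_left) left[at] <- spike_val else right[at] <- spike_val
    } else if (u[i] < cfg$spike_prob_per_trial + cfg$dropout_prob_per_trial) {
      artifact[i] <- "dropout"
      dur <- stats::runif(1, 0.5, 1.5)
      at <- round_half_up((onsets_s[i] + stats::runif(1, -4, 23)) * fs) + 1L
      idx <- at:min(n, at + round_half_up(dur * fs))
      idx <- idx[idx >= 1L]
      lvl <- 0.02 * base[if (chan_left) 1 else 2]
      drop_vals <- abs(stats::rnorm(length(idx), lvl, lvl / 4))
      if (chan_left) left[idx] <- drop_vals else right[idx] <- drop_vals
    }
  }

  truth <- data.frame(
    trial = seq_len(n_trials),
    task = tasks,
    trigger_sample = trigger_sample,
    planted_li = as.numeric(cfg$planted_li_pct[tasks]),
    artifact = artifact,
    n_words = stats::rpois(n_trials, SIM_WORDS_MEAN[tasks]),
    stringsAsFactors = FALSE
  )

  structure(list(recording = ftcd_recording(left, right, marker, fs),
                 truth = truth, config = cfg),
            class = "ftcd_simulation")
}

#' @export
print.ftcd_simulation <- function(x, ...) {
  cat(sprintf("Simulated fTCD session: %d trials (%s), seed %d\n",
              nrow(x$truth),
              paste(sprintf("%s=%d", task_names,
                            tabulate(match(x$truth$task, task_names), 3L)),
                    collapse = ", "),
              x$config$rng_seed))
  n_art <- sum(x$truth$artifact != "none")
  cat(sprintf("  planted LI (%%): %s; %d artifact trial(s)\n",
              paste(sprintf("%s=%g", names(x$config$planted_li_pct),
                            x$config$planted_li_pct), collapse = ", "),
              n_art))
  invisible(x)
}
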