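# Shared fixtures: small, fast simulation configs and hand-built epoch
# containers for unit-level tests of single pipeline steps.

# a short session: 4 trials per task, defaults otherwise
quick_sim <- function(seed = 1L, ...) {
  sim_config(n_trials_per_task = 4L, rng_seed = seed, ...)
}

# artifact-, drift- and noise-free session; individual fields overridable
clean_sim <- function(seed = 1L, n_trials_per_task = 4L, ...) {
  args <- utils::modifyList(
    list(n_trials_per_task = n_trials_per_task,
         noise_sd_pct = 0, drift_sd_pct = 0,
         spike_prob_per_trial = 0, dropout_prob_per_trial = 0,
         rng_seed = seed),
    list(...))
  do.call(sim_config, args)
}

# build an epochs container directly (bypassing segmentation) from per-trial
# channel matrices; rows are trials
toy_epochs <- function(left, right, task = "sentence", rate = 25,
                       state = "baselined") {
  left <- rbind(left); right <- rbind(right)
  n_ep <- nrow(left)
  info <- data.frame(trial = seq_len(n_ep),
                     task = rep_len(task, n_ep),
                     trigger_sample = seq_len(n_ep) * 1000L,
                     included = TRUE,
                     exclusion_reason = "none",
                     stringsAsFactors = FALSE)
  ep <- ftcdlat:::new_epochs(left, right, info,
                             time_s = (seq_len(ncol(left)) - 1) / rate,
                             sample_rate = rate, state = state)
  ep
}

# difference wave on a 25 Hz, 30 s epoch grid from a function of time
toy_wave <- function(f, task = "sentence", rate = 25, length_s = 30) {
  tt <- (seq_len(length_s * rate) - 1) / rate
  structure(list(task = task, time_s = tt, values = f(tt), n_trials = 2L),
            class = "ftcd_diffwave")
}

# fitted laterality results for a whole simulated participant
fit_sim <- function(sim_cfg, cfg = ftcd_config(), id = "S1") {
  ftcd_laterality(simulate_recording(sim_cfg), cfg, id = id)
}
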