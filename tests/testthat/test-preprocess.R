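test_that("block-mean down-sampling averages, truncates and relocates markers", {
  m <- integer(3001); m[601] <- 2L
  rec <- ftcd_recording(rep(80, 3001), rep(70, 3001), m, 100)
  ds <- downsample(rec, 4L)
  expect_length(ds$left, 750L)
  expect_equal(ds$sample_rate, 25)
  expect_true(all(ds$left == 80))
  expect_true(all(ds$right == 70))
  # native sample 601 lies in block 151
  expect_identical(which(ds$marker != 0L), 151L)
  expect_identical(ds$marker[151L], 2L)

  expect_error(downsample(rec, 0L), "positive integer")
})

test_that("down-sampling a 1 Hz sinusoid matches the analytic block-mean gain", {
  fs <- 100; f0 <- 1; n <- 4000
  tt <- (seq_len(n) - 1) / fs
  x <- 100 + 10 * sin(2 * pi * f0 * tt)
  rec <- ftcd_recording(x, x, integer(n), fs)
  ds <- downsample(rec, 4L)
  # block mean of a sinusoid scales its amplitude by a Dirichlet-kernel gain
  gain <- sin(pi * f0 * 4 / fs) / (4 * sin(pi * f0 / fs))
  # Fourier inner product recovers the amplitude at 1 Hz exactly
  td <- (seq_along(ds$left) - 1) / ds$sample_rate
  a <- 2 * mean((ds$left - mean(ds$left)) * sin(2 * pi * f0 * td))
  b <- 2 * mean((ds$left - mean(ds$left)) * cos(2 * pi * f0 * td))
  expect_equal(sqrt(a^2 + b^2), 10 * gain, tolerance = 1e-6)
  expect_gt(gain, 0.99)  # < 1% attenuation at these rates
})

test_that("segmentation yields one epoch per marker and flags incomplete ones", {
  cfg <- ftcd_config()
  m <- integer(1000); m[250] <- 3L  # 10 s into a 40 s recording at 25 Hz
  rec <- ftcd_recording(rnorm(1000, 100), rnorm(1000, 100), m, 25)
  ep <- segment_epochs(rec, cfg)
  expect_identical(nrow(ep$info), 1L)
  expect_true(ep$info$included)
  expect_identical(ncol(ep$left), 750L)
  expect_identical(ep$info$task, "word")
  # epoch covers 5 s before the trigger
  expect_equal(ep$left[1, 126], rec$left[250])

  m2 <- integer(1000); m2[50] <- 1L  # 2 s in: needs data from -3 s
  rec2 <- ftcd_recording(rnorm(1000, 100), rnorm(1000, 100), m2, 25)
  ep2 <- segment_epochs(rec2, cfg)
  expect_false(ep2$info$included)
  expect_identical(ep2$info$exclusion_reason, "incomplete_epoch")

  rec3 <- ftcd_recording(rnorm(1000, 100), rnorm(1000, 100), integer(1000), 25)
  expect_warning(ep3 <- segment_epochs(rec3, cfg), "no trial markers")
  expect_identical(nrow(ep3$info), 0L)
})

test_that("a default simulated session segments into 60 epochs, 20 per task", {
  sim <- simulate_recording(sim_config(rng_seed = 4L))
  ep <- segment_epochs(downsample(sim$recording, 4L), ftcd_config())
  expect_identical(nrow(ep$info), 60L)
  expect_equal(unname(table(ep$info$task)), c(20L, 20L, 20L), ignore_attr = TRUE)
  expect_identical(ep$info$task, sim$truth$task)
})

# 20 epochs of structured in-range values with controlled extremes
make_raw_epochs <- function(base = NULL) {
  set.seed(8)
  if (is.null(base)) base <- matrix(runif(20 * 750, 99, 103), 20, 750)
  toy_epochs(base, base + 1, task = "sentence", state = "raw")
}

test_that("an isolated spike is replaced by linear interpolation", {
  ep <- make_raw_epochs()
  ep$left[3, 400] <- 1000      # far beyond the 0.9999 quantile
  ep$left[3, 399] <- 100
  ep$left[3, 401] <- 102
  out <- despike(ep, ftcd_config())
  expect_equal(out$left[3, 400], 101)
  expect_true(out$info$included[3])
  expect_identical(out$state, "despiked")
})

test_that("a 0.6-s signal-loss run excludes the epoch as a dropout", {
  ep <- make_raw_epochs()
  # V-shaped 15-sample (0.6 s at 25 Hz) dropout dipping to zero
  ep$right[5, 301:315] <- 50 * abs(seq(-1, 1, length.out = 15))
  out <- despike(ep, ftcd_config())
  expect_false(out$info$included[5])
  expect_identical(out$info$exclusion_reason[5], "dropout_run")
  # data retained for inspection
  expect_equal(out$right[5, 308], 0)
})

test_that("clean simulated epochs pass despiking nearly untouched", {
  sim <- simulate_recording(clean_sim(9L, n_trials_per_task = 6L,
                                      noise_sd_pct = 0.8))
  ep <- segment_epochs(downsample(sim$recording, 4L), ftcd_config())
  out <- despike(ep, ftcd_config())
  expect_true(all(out$info$included))
  # empirical 0.0001/0.9999 quantiles clip at most a handful of samples
  same <- vapply(seq_len(nrow(ep$info)), function(i)
    identical(out$left[i, ], ep$left[i, ]) &&
      identical(out$right[i, ], ep$right[i, ]), logical(1))
  expect_gte(sum(same), nrow(ep$info) - 8L)
})

test_that("normalisation fixes each channel's grand mean at exactly 100", {
  ep <- toy_epochs(matrix(54, 4, 750), matrix(27, 4, 750), state = "despiked")
  out <- normalise_epochs(ep)
  expect_true(all(out$left == 100))
  expect_true(all(out$right == 100))  # scale invariance: left was 2x right

  set.seed(21)
  ep2 <- toy_epochs(matrix(rnorm(8 * 750, 55, 5), 8),
                    matrix(rnorm(8 * 750, 40, 5), 8), state = "despiked")
  out2 <- normalise_epochs(ep2)
  expect_equal(mean(out2$left), 100, tolerance = 1e-9)
  expect_equal(mean(out2$right), 100, tolerance = 1e-9)

  ep3 <- toy_epochs(matrix(0, 2, 750), matrix(1, 2, 750), state = "despiked")
  expect_error(normalise_epochs(ep3), "non-positive mean")
})

test_that("heart-cycle integration flattens a synthetic pulse train", {
  rate <- 25; tt <- (0:749) / rate
  # smooth zero-mean 1.25 Hz (75 bpm) pulse at depth 0.25 on a flat 100
  cosine <- 100 * (1 + 0.25 * cos(2 * pi * 1.25 * tt))
  out_c <- integrate_heart_cycles(toy_epochs(cosine, cosine,
                                             state = "normalised"),
                                  ftcd_config())
  expect_identical(out_c$state, "integrated")
  core <- 30:720  # away from the edge cycles
  expect_true(all(abs(out_c$left[1, core] - 100) < 1))

  # sharp systolic waveform: cardiac-band spectral power drops >= 90%
  pulse <- 100 * (1 + 0.25 * cardiac_waveform((tt * 1.2) %% 1))
  out <- integrate_heart_cycles(toy_epochs(pulse, pulse, state = "normalised"),
                                ftcd_config())
  band_power <- function(x, f_lo = 1.0, f_hi = 1.4) {
    sp <- Mod(fft(x - mean(x)))^2
    fr <- (seq_along(x) - 1) * rate / length(x)
    sum(sp[fr >= f_lo & fr <= f_hi])
  }
  expect_lt(band_power(out$left[1, ]), 0.1 * band_power(pulse))
})

test_that("a 60 bpm epoch yields 30 +/- 1 detected systolic peaks", {
  rate <- 25; tt <- (0:749) / rate
  pulse <- 100 * (1 + 0.25 * cardiac_waveform((tt * 1.0) %% 1))
  peaks <- ftcdlat:::find_systolic_peaks(
    pulse, min_sep = round(0.33 * rate), prom_min = 0.25 * diff(range(pulse)))
  expect_gte(length(peaks), 29L)
  expect_lte(length(peaks), 31L)
})

test_that("pulseless epochs cannot be integrated and are excluded", {
  ep <- toy_epochs(matrix(100, 2, 750), matrix(100, 2, 750),
                   state = "normalised")
  out <- integrate_heart_cycles(ep, ftcd_config())
  expect_true(all(!out$info$included))
  expect_true(all(out$info$exclusion_reason == "cannot_integrate"))
})

test_that("baseline correction zeroes the rest window and keeps pre-baseline values", {
  ep <- toy_epochs(matrix(103, 2, 750), matrix(98, 2, 750),
                   state = "integrated")
  out <- baseline_correct(ep, ftcd_config())
  expect_true(all(out$left == 0))
  expect_true(all(out$right == 0))
  expect_true(all(out$prebaseline$left == 103))

  # baseline 100, covert-period 105 -> covert-period mean 5 after correction
  x <- matrix(100, 1, 750); x[1, 301:500] <- 105
  out2 <- baseline_correct(toy_epochs(x, x, state = "integrated"),
                           ftcd_config())
  expect_equal(mean(out2$left[1, 301:500]), 5)
  expect_equal(mean(out2$left[1, 1:125]), 0)
})

test_that("simulated bilateral rise appears in both channels after baseline", {
  sim <- simulate_recording(clean_sim(14L, n_trials_per_task = 4L))
  ep <- baseline_correct(
    integrate_heart_cycles(
      normalise_epochs(despike(
        segment_epochs(downsample(sim$recording, 4L), ftcd_config()),
        ftcd_config())),
      ftcd_config()),
    ftcd_config())
  covert <- ftcdlat:::in_window(ep$time_s, c(9.5, 17))
  base <- ftcdlat:::in_window(ep$time_s, c(0, 5))
  i <- which(ep$info$task == "list")  # planted L-R 0, bilateral rise 3
  expect_equal(mean(ep$left[i, covert]), 3, tolerance = 0.35)
  expect_equal(mean(ep$right[i, covert]), 3, tolerance = 0.35)
  expect_equal(mean(ep$left[i, base]), 0, tolerance = 1e-9)
})

test_that("artifact rejection screens the integrated pre-baseline signal", {
  mk <- function(spike = NA) {
    x <- matrix(100, 3, 750)
    if (!is.na(spike)) x[2, 400] <- spike
    ep <- toy_epochs(x, matrix(100, 3, 750), state = "integrated")
    reject_artifacts(baseline_correct(ep, ftcd_config()), ftcd_config())
  }
  out <- mk(150)  # above 140% of mean
  expect_false(out$info$included[2])
  expect_identical(out$info$exclusion_reason[2], "artifact_out_of_range")
  expect_true(all(out$info$included[c(1, 3)]))

  out2 <- mk(139)  # inside [61, 139]: retained
  expect_true(all(out2$info$included))

  out3 <- mk(55)  # below 60%
  expect_false(out3$info$included[2])
})

test_that("a clean simulated cohort suffers no artifact rejections", {
  sim <- simulate_recording(clean_sim(31L, n_trials_per_task = 6L,
                                      noise_sd_pct = 0.4))
  ep <- preprocess(sim$recording, ftcd_config())
  expect_true(all(ep$info$included))
  expect_identical(sum(ep$info$included), nrow(sim$truth))
})

test_that("steps refuse epochs in the wrong processing state", {
  ep <- toy_epochs(matrix(100, 2, 750), matrix(100, 2, 750), state = "raw")
  expect_error(normalise_epochs(ep), "state 'raw'")
  expect_error(integrate_heart_cycles(ep), "requires state 'normalised'")
  expect_error(baseline_correct(ep), "requires state 'integrated'")
  d <- despike(ep, ftcd_config())
  expect_error(despike(d, ftcd_config()), "requires state 'raw'")
})

test_that("swapping the input channels swaps every output epoch exactly", {
  sim <- simulate_recording(quick_sim(17L))
  rec <- sim$recording
  swapped <- ftcd_recording(rec$right, rec$left, rec$marker, rec$sample_rate)
  a <- preprocess(rec, ftcd_config())
  b <- preprocess(swapped, ftcd_config())
  expect_identical(a$left, b$right)
  expect_identical(a$right, b$left)
  expect_identical(a$info, b$info)
})

test_that("exclusion is monotone: adding an out-of-range sample never rescues an epoch", {
  x <- matrix(100, 3, 750)
  ep <- toy_epochs(x, matrix(100, 3, 750), state = "integrated")
  base <- reject_artifacts(baseline_correct(ep, ftcd_config()), ftcd_config())
  x2 <- x; x2[2, 10] <- 150
  ep2 <- toy_epochs(x2, matrix(100, 3, 750), state = "integrated")
  worse <- reject_artifacts(baseline_correct(ep2, ftcd_config()), ftcd_config())
  expect_true(all(worse$info$included <= base$info$included))
})
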