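test_that("the mean difference wave averages per-epoch L-R differences", {
  l <- rbind(rep(5, 750), rep(7, 750))
  r <- rbind(rep(3, 750), rep(3, 750))  # differences +2 and +4
  dw <- mean_difference_wave(toy_epochs(l, r), "sentence")
  expect_true(all(dw$values == 3))
  expect_identical(dw$n_trials, 2L)

  same <- matrix(rnorm(2 * 750), 2)
  dw0 <- mean_difference_wave(toy_epochs(same, same), "sentence")
  expect_true(all(dw0$values == 0))

  ep <- toy_epochs(l, r, task = "word")
  expect_error(mean_difference_wave(ep, "sentence"), "sentence")
})

test_that("the peak is the maximal absolute difference, earliest on ties", {
  cfg <- ftcd_config()
  w1 <- toy_wave(function(t) ifelse(abs(t - 12) < 0.02, 6, 0))
  expect_equal(find_peak(w1, cfg), 12)

  # negative extremum dominates by absolute value
  w2 <- toy_wave(function(t) -6 * (abs(t - 10) < 0.02) + 5 * (abs(t - 14) < 0.02))
  expect_equal(find_peak(w2, cfg), 10)

  # tie at equal magnitude: earliest sample wins
  w3 <- toy_wave(function(t) 4 * (abs(t - 9) < 0.02) + 4 * (abs(t - 15) < 0.02))
  expect_equal(find_peak(w3, cfg), 9)
})

test_that("find_peak agrees with an exhaustive scan on random waves", {
  cfg <- ftcd_config()
  set.seed(42)
  for (k in 1:25) {
    w <- toy_wave(function(t) stats::rnorm(length(t)))
    lat <- find_peak(w, cfg)
    # brute-force oracle over every POI sample
    sel <- which(w$time_s >= cfg$poi_s[1] & w$time_s < cfg$poi_s[2])
    best <- sel[1]
    for (i in sel) if (abs(w$values[i]) > abs(w$values[best])) best <- i
    expect_identical(lat, w$time_s[best])
  }
})

test_that("the peak LI averages a 2-s window and is antisymmetric", {
  cfg <- ftcd_config()
  wc <- toy_wave(function(t) rep(3.7, length(t)))
  expect_equal(li_peak(wc, 12, cfg), 3.7)
  expect_equal(li_peak(wc, 7.3, cfg), 3.7)

  # triangle apex 6 at t = 12 falling to 0 at +/- 2 s: the +/- 1 s window
  # spans values from 3 to 6, closed-form mean 4.5
  tri <- toy_wave(function(t) pmax(0, 6 - 3 * abs(t - 12)))
  expect_equal(li_peak(tri, 12, cfg), 4.5)

  neg <- tri; neg$values <- -neg$values
  expect_identical(li_peak(neg, 12, cfg), -li_peak(tri, 12, cfg))
})

test_that("the mean-POI LI is bounded by the peak LI on unimodal waves", {
  cfg <- ftcd_config()
  expect_equal(li_mean_poi(toy_wave(function(t) rep(2.2, length(t))), cfg), 2.2)
  expect_equal(li_mean_poi(toy_wave(function(t) numeric(length(t))), cfg), 0)
  bump <- toy_wave(function(t) exp(-(t - 12)^2 / 4))
  expect_lte(li_mean_poi(bump, cfg), li_peak(bump, find_peak(bump, cfg), cfg))
})

test_that("per-trial LIs are consistent with the group LI by linearity", {
  cfg <- ftcd_config()
  set.seed(13)
  l <- matrix(rnorm(6 * 750, 3), 6)
  r <- matrix(rnorm(6 * 750, 1), 6)
  ep <- toy_epochs(l, r)
  dw <- mean_difference_wave(ep, "sentence")
  lat <- find_peak(dw, cfg)
  tl <- trial_lis(ep, "sentence", lat, cfg)
  expect_length(tl, 6L)
  expect_equal(mean(tl), li_peak(dw, lat, cfg))

  ep1 <- toy_epochs(l[1, , drop = FALSE], r[1, , drop = FALSE])
  dw1 <- mean_difference_wave(ep1, "sentence")
  expect_equal(trial_lis(ep1, "sentence", lat, cfg)[1], li_peak(dw1, lat, cfg))
})

test_that("classification follows the t confidence interval sign rule", {
  cfg <- ftcd_config()
  # 20 values with mean exactly 2 and sd exactly 4
  z <- as.numeric(scale(1:20))
  cls <- classify_laterality(2 + 4 * z, cfg)
  expect_equal(cls$ci_low, 0.1279424, tolerance = 1e-6)
  expect_equal(cls$ci_high, 3.8720576, tolerance = 1e-6)
  expect_identical(cls$category, "left")

  cls2 <- classify_laterality(0.5 + 4 * z, cfg)
  expect_identical(cls2$category, "bilateral")
  expect_lt(cls2$ci_low, 0); expect_gt(cls2$ci_high, 0)

  cls3 <- classify_laterality(rep(-3, 12), cfg)
  expect_equal(c(cls3$ci_low, cls3$ci_high), c(-3, -3))
  expect_identical(cls3$category, "right")

  expect_error(classify_laterality(1.5, cfg), "at least 2")
})

test_that("split halves of duplicated trials agree exactly", {
  cfg <- ftcd_config()
  set.seed(5)
  one <- rnorm(750, 2)
  l <- matrix(rep(one, 6), 6, byrow = TRUE)
  r <- matrix(0, 6, 750)
  sh <- split_half(toy_epochs(l, r), "sentence", cfg)
  expect_identical(sh[["li_odd"]], sh[["li_even"]])

  # a half with fewer than 2 trials is flagged missing
  sh3 <- split_half(toy_epochs(l[1:3, ], r[1:3, ]), "sentence", cfg)
  expect_true(is.na(sh3[["li_even"]]))
  expect_false(is.na(sh3[["li_odd"]]))
})

test_that("split-half reliability tracks true between-participant differences", {
  planted <- seq(-4, 8, length.out = 10)
  odd <- even <- numeric(10)
  for (i in seq_along(planted)) {
    sc <- clean_sim(40L + i, n_trials_per_task = 6L, noise_sd_pct = 0.3)
    sc$planted_li_pct <- c(list = 0, sentence = planted[i], word = 2.5)
    fit <- fit_sim(sc)
    r <- fit$results[fit$results$task == "sentence" & fit$results$method == "peak", ]
    odd[i] <- r$split_half_odd
    even[i] <- r$split_half_even
  }
  expect_gt(cor(odd, even, method = "spearman"), 0.9)
})

test_that("channel swap negates the LI, mirrors the category, keeps the latency", {
  cfg <- ftcd_config()
  sim <- simulate_recording(quick_sim(23L))
  rec <- sim$recording
  swp <- ftcd_recording(rec$right, rec$left, rec$marker, rec$sample_rate)
  a <- ftcd_laterality(rec, cfg)
  b <- ftcd_laterality(swp, cfg)
  for (m in c("peak", "mean")) {
    ra <- a$results[a$results$method == m, ]
    rb <- b$results[b$results$method == m, ]
    expect_equal(rb$li, -ra$li)
    expect_equal(rb$ci_low, -ra$ci_high)
    expect_identical(rb$latency_s, ra$latency_s)
    mirror <- c(left = "right", bilateral = "bilateral", right = "left")
    expect_identical(rb$category, unname(mirror[ra$category]))
  }
})

test_that("fit accessors expose coefficients and confidence intervals", {
  fit <- fit_sim(quick_sim(31L))
  li <- coef(fit)
  expect_named(li, c("list", "sentence", "word"))
  ci <- confint(fit)
  expect_identical(colnames(ci), c("lower", "upper"))
  expect_true(all(ci[, "lower"] <= li & li <= ci[, "upper"]))
  expect_identical(names(coef(fit, method = "mean")), names(li))
  expect_output(print(fit), "fTCD laterality fit")
  expect_output(print(summary(fit)), "Epochs:")
})
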