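test_that("the wavelet bank spans 0.1-50 Hz geometrically with 6 cycles", {
  bank <- morlet_bank()
  expect_length(bank$freqs, 20)
  expect_equal(bank$freqs[1], 0.1)
  expect_equal(bank$freqs[20], 50)
  ratios <- bank$freqs[-1] / bank$freqs[-20]
  expect_equal(ratios, rep(500^(1 / 19), 19), tolerance = 1e-10)
  expect_equal(ratios[1], 1.3870, tolerance = 1e-4)
  expect_equal(bank$sigma_t, 6 / (2 * pi * bank$freqs))
})

test_that("band assignment duplicates exactly the four boundary wavelets", {
  bank <- morlet_bank()
  asg <- assign_bands(bank)
  expect_setequal(names(asg), c("delta", "theta", "alpha", "beta", "gamma"))
  dual <- attr(asg, "dual")
  expect_length(dual, 4)
  expect_equal(sort(bank$freqs[dual]),
               sort(vapply(c(4, 8, 13, 30), function(b)
                 bank$freqs[which.min(abs(bank$freqs - b))], 0)))
  # membership counts: every wavelet >= 0.3 Hz in >= 1 band, duals in 2
  counts <- table(factor(unlist(asg), levels = 1:20))
  expect_true(all(counts[as.character(dual)] == 2))
  expect_true(all(counts[setdiff(which(bank$freqs >= 0.3), dual)] == 1))
  expect_true(all(!(which(bank$freqs < 0.3) %in% unlist(asg))))
  # the wavelet nearest 10 Hz sits in alpha only
  k10 <- which.min(abs(bank$freqs - 10))
  expect_true(k10 %in% asg$alpha)
  expect_false(k10 %in% asg$theta || k10 %in% asg$beta)
  expect_true(20 %in% asg$gamma)   # 50 Hz endpoint
})

test_that("wavelet power peaks at the grid frequency nearest a pure tone and scales with amplitude squared", {
  bank <- morlet_bank()
  fs <- 250
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x1 <- sin(2 * pi * 10 * t)
  p1 <- tf_power(x1, fs, bank)
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  prof <- rowMeans(p1[, mid])
  expect_equal(which.max(prof), which.min(abs(bank$freqs - 10)))
  p2 <- tf_power(2 * x1, fs, bank)
  expect_equal(rowMeans(p2[, mid]), 4 * prof, tolerance = 1e-10)
})

test_that("white-noise band powers match the flat-spectrum oracle", {
  bank <- morlet_bank()
  fs <- 250
  ks <- 10:18            # wavelets comfortably inside a 60 s record
  set.seed(8)
  n_rep <- 8
  obs <- matrix(0, n_rep, length(ks))
  for (r in seq_len(n_rep)) {
    x <- rnorm(60 * fs)
    p <- tf_power(x, fs, bank)
    mid <- seq(3 * fs, 57 * fs)
    obs[r, ] <- rowMeans(p[ks, mid])
  }
  # analytic oracle: E power = N0 * integral |H(f)|^2 df with N0 the
  # two-sided noise density sigma^2 / fs and H a unit-peak Gaussian of SD
  # sigma_f = 1 / (2 pi sigma_t)
  sigma_f <- 1 / (2 * pi * bank$sigma_t[ks])
  expected <- (1 / fs) * sigma_f * sqrt(pi)
  z <- (colMeans(obs) - expected) / (apply(obs, 2, sd) / sqrt(n_rep))
  expect_true(all(abs(z) < 3))
})

test_that("dB normalization is exact on ratios and invariant to channel gain", {
  time_s <- seq(-10, 10, by = 0.01)
  base <- matrix(1, 3, length(time_s))
  expect_true(all(db_normalize(base, time_s) == 0))
  doubled <- base
  doubled[, time_s >= 0] <- 2
  db <- db_normalize(doubled, time_s)
  expect_equal(db[1, time_s >= 1], rep(10 * log10(2), sum(time_s >= 1)))
  expect_equal(max(abs(db[, time_s < -1])), 0)
  # multiplying a channel by a constant gain leaves dB unchanged
  p <- abs(matrix(rnorm(3 * length(time_s)), 3))^2 + 0.1
  expect_equal(db_normalize(p * 25, time_s), db_normalize(p, time_s))
  expect_error(db_normalize(base, time_s + 100), "baseline")
})

test_that("half-amplitude task power reads -6.02 dB through decomposition and normalization", {
  bank <- morlet_bank()
  fs <- 250
  time_s <- seq(-10, 30 - 1 / fs, by = 1 / fs)
  amp <- ifelse(time_s >= 0, 0.5, 1)
  set.seed(4)
  x <- amp * sin(2 * pi * 10 * time_s) + 1e-5 * rnorm(length(time_s))
  p <- tf_power(x, fs, bank)
  db <- db_normalize(p, time_s)
  k10 <- which.min(abs(bank$freqs - 10))
  task <- time_s > 2 & time_s < 28
  expect_equal(mean(db[k10, task]), 20 * log10(0.5), tolerance = 0.05)
})

test_that("band-period features reduce masked dB exactly as a hand-built oracle", {
  # two channels, constant task amplitudes differing between link and
  # non-link periods: features must equal the analytic dB values per band
  fs <- 200
  des <- task_design(trials_per_run = 1, runs = 1, include = "A",
                     tmta_duration_s = 30)
  time_s <- seq(-10, 32 - 1 / fs, by = 1 / fs)
  epochs <- structure(list(
    epochs = list(list(part = "A", trial = 2,
                       data = NULL, time_s = time_s)),
    labels = c("Cz", "Pz"), fs = fs, baseline_s = 10, pad_s = 2),
    class = "eeg_epochs")
  # links at 5-10 s and 15-20 s; alpha carrier with amplitude 1 in
  # baseline/non-link and 0.5 in link, on both channels
  link <- (time_s >= 5 & time_s < 10) | (time_s >= 15 & time_s < 20)
  amp <- ifelse(link, 0.5, 1)
  set.seed(5)
  x <- amp * sin(2 * pi * 10 * time_s) + 1e-5 * rnorm(length(time_s))
  epochs$epochs[[1]]$data <- rbind(x, 0.3 * x)
  masks <- list(tmt_a_trial02 = list(
    links = data.frame(start_ms = c(5000, 15000), end_ms = c(10000, 20000)),
    completion_ms = 30000))
  ft <- band_period_features(epochs, masks, participant = "px")
  alpha <- ft[ft$band == "alpha", ]
  la <- alpha$power_db[alpha$condition == "link_a"]
  na <- alpha$power_db[alpha$condition == "nonlink_a"]
  expect_equal(la[1] - na[1], 20 * log10(0.5), tolerance = 0.35)
  expect_equal(la[1], la[2], tolerance = 1e-9)   # gain-invariant across channels
})

test_that("a dual-assigned wavelet contributes to both of its bands", {
  bank <- morlet_bank()
  asg <- assign_bands(bank)
  k <- attr(asg, "dual")[2]    # wavelet nearest 8 Hz
  fs <- 200
  time_s <- seq(-10, 20 - 1 / fs, by = 1 / fs)
  amp <- ifelse(time_s >= 2 & time_s < 8, 0.5, 1)   # halved during the link
  set.seed(6)
  # dither floor large enough to dominate the step-transition splatter at
  # far-away low-frequency wavelets, small enough to leave the tone bands
  x <- amp * sin(2 * pi * bank$freqs[k] * time_s) +
    1e-2 * rnorm(length(time_s))
  epochs <- structure(list(
    epochs = list(list(part = "A", trial = 1, data = matrix(x, 1),
                       time_s = time_s)),
    labels = "Cz", fs = fs, baseline_s = 10, pad_s = 2),
    class = "eeg_epochs")
  masks <- list(tmt_a_trial01 = list(
    links = data.frame(start_ms = 2000, end_ms = 8000),
    completion_ms = 15000))
  ft <- band_period_features(epochs, masks, participant = "px")
  d_theta <- with(ft, power_db[band == "theta" & condition == "link_a"] -
                    power_db[band == "theta" & condition == "nonlink_a"])
  d_alpha <- with(ft, power_db[band == "alpha" & condition == "link_a"] -
                    power_db[band == "alpha" & condition == "nonlink_a"])
  expect_lt(d_theta, -1)
  expect_lt(d_alpha, -1)
})
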