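make_rec <- function(data, fs = 1000, labels = NULL,
                     events = data.frame(sample = integer(0), code = integer(0),
                                         condition = character(0))) {
  if (is.null(labels)) labels <- paste0("Ch", seq_len(nrow(data)))
  structure(list(labels = labels, fs = fs, data = data, events = events),
            class = "eeg_recording")
}

test_that("downsampling 5000 -> 1000 Hz preserves a 10 Hz tone and rescales triggers", {
  fs <- 5000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  rec <- make_rec(matrix(x, 1), fs = fs,
                  events = data.frame(sample = c(1L, 5001L), code = c(1L, 3L),
                                      condition = c("fixation", "tmt_a")))
  dn <- eeg_downsample(rec, 1000)
  expect_equal(dn$fs, 1000)
  expect_equal(ncol(dn$data), 20000)
  expect_equal(dn$events$sample, c(1L, 1001L))
  mid <- 2000:18000
  amp <- sqrt(2 * mean(dn$data[1, mid]^2))
  expect_equal(amp, 1, tolerance = 0.01)
  # identity at the target rate
  expect_identical(eeg_downsample(dn, 1000), dn)
  expect_error(eeg_downsample(make_rec(matrix(0, 1, 100), fs = 1500), 1000),
               "integer multiple")
})

test_that("band-pass removes DC, passes 10 Hz within 1%, suppresses 200 Hz", {
  fs <- 1000
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  x <- 100 + sin(2 * pi * 10 * t) + sin(2 * pi * 200 * t)
  rec <- eeg_bandpass(make_rec(matrix(x, 1)))   # default 0.1 Hz transition
  mid <- 5000:35000
  y <- rec$data[1, mid]
  expect_lt(abs(mean(y)), 0.5)            # DC gone
  # project onto the two tones to measure their surviving amplitudes
  a10 <- 2 * mean(y * sin(2 * pi * 10 * t[mid]))
  a200 <- 2 * mean(y * sin(2 * pi * 200 * t[mid]))
  expect_equal(a10, 1, tolerance = 0.01)
  expect_lt(abs(a200), 0.01)
  expect_error(eeg_bandpass(make_rec(matrix(0, 1, 100)), high_hz = 600),
               "Nyquist")
})

test_that("filtering and re-referencing are linear", {
  set.seed(2)
  a <- matrix(rnorm(4 * 8000), 4)
  b <- matrix(rnorm(4 * 8000), 4)
  labs <- c("Fz", "Cz", "TP9", "TP10")
  f <- function(m) {
    r <- eeg_bandpass(make_rec(m, labels = labs), trans_low_hz = 2)
    rereference_mastoids(r)$data
  }
  expect_equal(f(a + b), f(a) + f(b), tolerance = 1e-8)
})

test_that("mean-mastoid re-reference zeroes common signals and drops TP9/TP10", {
  set.seed(3)
  base <- matrix(rnorm(6 * 500), 6)
  labs <- c("Fz", "Cz", "Pz", "Oz", "TP9", "TP10")
  # quiet mastoids: re-reference leaves other channels unchanged
  data0 <- base; data0[5:6, ] <- 0
  rr <- rereference_mastoids(make_rec(data0, labels = labs))
  expect_equal(rr$data, data0[1:4, ])
  expect_equal(rr$labels, labs[1:4])
  # identical signal on every channel is removed entirely
  common <- matrix(rep(rnorm(500), 6), 6, byrow = TRUE)
  rc <- rereference_mastoids(make_rec(common, labels = labs))
  expect_equal(max(abs(rc$data)), 0)
  expect_error(rereference_mastoids(make_rec(base)), "TP9")
  # full montage keeps 30 analysis channels
  rec32 <- make_rec(matrix(0, 32, 10), labels = acticap32_labels())
  expect_length(rereference_mastoids(rec32)$labels, 30)
})

test_that("ICA with the default scorer removes injected frontal blinks", {
  des <- task_design(trials_per_run = 1, runs = 1, include = "A")
  chans <- c("Fp1", "Fp2", "F7", "F8", "Cz", "Pz", "Oz", "O2", "TP9", "TP10")
  pr <- eeg_sim_params(channels = chans, oscillators = list(), pink_rms_uv = 5,
                       blink_rate_per_min = 25, blink_amplitude_uv = 200)
  rec <- simulate_eeg(NULL, des, pr, seed = 31)
  clean <- remove_artifact_components(rec, seed = 1)
  expect_gt(length(attr(clean, "removed_components")), 0)
  prob <- attr(clean, "component_probabilities")
  expect_true(all(prob >= 0 & prob <= 1))
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(clean$data[1, ]), 0.5 * rms(rec$data[1, ]))   # Fp1
  expect_lt(abs(rms(clean$data[6, ]) / rms(rec$data[6, ]) - 1), 0.2)  # Pz kept
  # a no-op scorer returns the recording unchanged
  expect_identical(remove_artifact_components(rec, scorer = NULL), rec)
})

test_that("epochs span -10 s to block end + 2 s with trial exclusions applied", {
  fs <- 200   # reduced rate keeps the fixture small; spans scale with fs
  dur_total <- 8 * (10 + 40) + 10
  n <- dur_total * fs
  onsets <- (seq(0, 7) * 50 + 10) * fs + 1L
  events <- data.frame(sample = as.integer(onsets), code = 3L,
                       condition = "tmt_a")
  rec <- make_rec(matrix(rnorm(2 * n), 2), fs = fs, events = events)
  ep <- epoch_trials(rec, tmta_duration_s = 40)
  expect_equal(length(ep$epochs), 7)                    # trial 1 excluded
  expect_equal(ncol(ep$epochs[[1]]$data), 52 * fs)      # -10 .. 42 s
  expect_equal(ep$epochs[[1]]$time_s[10 * fs + 1], 0)   # sample fs*10+1 is onset
  expect_equal(vapply(ep$epochs, `[[`, 0, "trial"), 2:8)
  ep_all <- epoch_trials(rec, tmta_duration_s = 40,
                         exclude_trials = list(A = integer(0)))
  expect_equal(length(ep_all$epochs), 8)
  # an epoch running past the record end is a boundary error naming the trial
  short <- make_rec(matrix(0, 1, 30 * fs), fs = fs,
                    events = data.frame(sample = 25L * fs, code = 4L,
                                        condition = "tmt_b"))
  expect_error(epoch_trials(short, exclude_trials = list(B = integer(0))),
               "TMT-B trial 1")
})

test_that("TMT-B epochs cover a 72 s span at 1000 Hz", {
  n <- 80 * 1000
  rec <- make_rec(matrix(0, 1, n),
                  events = data.frame(sample = 11000L, code = 4L,
                                      condition = "tmt_b"))
  ep <- epoch_trials(rec, exclude_trials = list(B = integer(0)))
  expect_equal(ncol(ep$epochs[[1]]$data), 72000)
  expect_equal(range(ep$epochs[[1]]$time_s), c(-10, 62 - 1e-3))
})
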