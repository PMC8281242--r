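test_that("finite-difference speed matches an independent per-pair oracle", {
  # constant position
  tr <- data.frame(t_ms = seq(0, 975, by = 25), x_px = 5, y_px = 7,
                   pen_down = 1L)
  expect_true(all(compute_speed(tr)$v_px_s == 0))
  # uniform motion at 100 px/s
  t <- seq(0, 2000, by = 25)
  tr <- data.frame(t_ms = t, x_px = 100 * t / 1000, y_px = 0, pen_down = 1L)
  expect_equal(compute_speed(tr)$v_px_s, rep(100, length(t) - 1))
  # random trace vs direct recomputation
  set.seed(1)
  tr <- data.frame(t_ms = cumsum(runif(200, 20, 30)),
                   x_px = cumsum(rnorm(200)), y_px = cumsum(rnorm(200)),
                   pen_down = 1L)
  sp <- compute_speed(tr)
  oracle <- vapply(seq_len(199), function(i)
    sqrt((tr$x_px[i + 1] - tr$x_px[i])^2 + (tr$y_px[i + 1] - tr$y_px[i])^2) /
      ((tr$t_ms[i + 1] - tr$t_ms[i]) / 1000), 0)
  expect_identical(sp$v_px_s, oracle)
  expect_equal(sp$t_ms, (tr$t_ms[-1] + tr$t_ms[-200]) / 2)
})

test_that("degenerate traces are rejected and pen lifts zero the speed", {
  tr <- data.frame(t_ms = c(0, 25, 25, 50), x_px = 1:4, y_px = 0, pen_down = 1L)
  expect_error(compute_speed(tr), "increasing")
  expect_error(compute_speed(tr[1, ]), "2 samples")
  tr <- data.frame(t_ms = seq(0, 100, 25), x_px = seq(0, 40, 10), y_px = 0,
                   pen_down = c(1L, 1L, 0L, 1L, 1L))
  sp <- compute_speed(tr)
  expect_equal(sp$v_px_s[2:3], c(0, 0))     # pairs touching the lifted sample
  expect_gt(sp$v_px_s[1], 0)
})

test_that("sigma filter removes spikes, passes clean data, and equals the brute-force oracle", {
  t <- seq(0, 5000, by = 25)
  const <- sigma_filter(speed_series(t, rep(100, length(t))))
  expect_equal(const$v_px_s, rep(100, length(t)))
  v <- rep(100, length(t)); v[80] <- 1e4
  filt <- sigma_filter(speed_series(t, v))
  expect_equal(filt$v_px_s[80], 100, tolerance = 1e-6)
  set.seed(7)
  for (rep in 1:25) {
    tt <- cumsum(runif(150, 18, 32))
    vv <- abs(rnorm(150, 200, 80))
    vv[sample(150, 3)] <- vv[sample(150, 3)] + 3000
    expect_equal(sigma_filter(speed_series(tt, vv))$v_px_s,
                 sigma_filter_oracle(tt, vv), tolerance = 1e-12)
  }
})

test_that("sigma filter is idempotent on spike-free series", {
  t <- seq(0, 4000, by = 25)
  v <- 150 + 100 * sin(2 * pi * t / 2000)
  once <- sigma_filter(speed_series(t, v))
  twice <- sigma_filter(once)
  expect_equal(twice$v_px_s, once$v_px_s)
})

test_that("low-pass and resampling preserve the passband and suppress the stopband", {
  t <- seq(0, 10000, by = 25)
  dc <- lowpass_and_resample(speed_series(t, rep(50, length(t))))
  expect_equal(median(diff(dc$t_ms)), 1)
  interior <- dc$t_ms > 500 & dc$t_ms < 9500
  expect_equal(dc$v_px_s[interior], rep(50, sum(interior)), tolerance = 1e-6)
  expect_lt(max(abs(dc$v_px_s - 50)), 0.05)   # edge transients stay tiny
  s1 <- lowpass_and_resample(speed_series(t, 100 + 50 * sin(2 * pi * 1 * t / 1000)))
  mid <- s1$t_ms > 2000 & s1$t_ms < 8000
  amp1 <- (max(s1$v_px_s[mid]) - min(s1$v_px_s[mid])) / 2
  expect_gt(amp1, 50 * 0.9)
  s20 <- lowpass_and_resample(speed_series(t, 100 + 50 * sin(2 * pi * 15 * t / 1000)))
  amp20 <- (max(s20$v_px_s[mid]) - min(s20$v_px_s[mid])) / 2
  expect_lt(amp20, 50 * 0.05)
  expect_true(all(s20$v_px_s >= 0))
  expect_error(lowpass_and_resample(speed_series(1:5 * 25, rnorm(5))),
               "too short")
})

test_that("threshold segmentation recovers two clean bursts near their crossings", {
  tb <- two_burst_series()
  seg <- segment_by_threshold(tb$series, expected_links = 2)
  expect_equal(seg$n_links_found, 2)
  expect_equal(nrow(seg$linking), 2)
  thr <- seg$threshold_px_s
  for (k in 1:2) {
    b <- tb$bursts[[k]]
    u <- acos(1 - 2 * (thr - 0.2) / 400) / (2 * pi)
    true_start <- b[1] + u * (b[2] - b[1])
    true_end <- b[2] - u * (b[2] - b[1])
    expect_lt(abs(seg$linking$start_ms[k] - true_start), 5)
    expect_lt(abs(seg$linking$end_ms[k] - true_end), 5)
  }
  # linking and non-linking partition the extent
  durs <- sum(seg$linking$end_ms - seg$linking$start_ms) +
    sum(seg$nonlinking$end_ms - seg$nonlinking$start_ms)
  expect_equal(durs, diff(seg$extent_ms))
})

test_that("segmentation failure reports the achievable counts", {
  flat <- speed_series(seq(0, 2000), rep(0, 2001))
  expect_error(segment_by_threshold(flat, 1), "achievable counts")
})

test_that("coordinate scaling scales speeds and threshold but not boundaries", {
  # scaling all coordinates by c scales the speed series by c; with the
  # threshold grid expressed in the same scaled units the found threshold
  # scales by exactly c and the interval boundaries are unchanged
  tb <- two_burst_series()
  seg1 <- segment_by_threshold(tb$series, 2)
  scaled <- tb$series
  scaled$v_px_s <- scaled$v_px_s * 3
  seg3 <- segment_by_threshold(scaled, 2, step_px_s = 3)
  expect_equal(seg3$threshold_px_s, 3 * seg1$threshold_px_s)
  expect_equal(seg3$linking, seg1$linking)
  expect_equal(seg3$nonlinking, seg1$nonlinking)
})

test_that("link scoring identifies targets, errors, and crossed-over items", {
  lay <- fixture_layout("A")
  p <- behavior_params(error_rate = 0)
  tr <- simulate_trial_behavior(lay, p, block_duration_s = 500, seed = 13)
  an <- analyze_trial(tr$trace, lay, expected_links = 24,
                      block_duration_s = 500)
  expect_equal(nrow(an$links), 24)
  expect_true(all(an$links$resolved))
  expect_true(all(an$links$correct))
  expect_equal(an$links$target, tmt_labels("A")[-1])

  # an injected wrong-target link is scored as an error, its correction as
  # correct
  tre <- simulate_trial_behavior(lay, behavior_params(error_rate = 1),
                                 block_duration_s = 2000, seed = 17)
  ane <- analyze_trial(tre$trace, lay,
                       expected_links = nrow(tre$link_sequence),
                       block_duration_s = 2000)
  expect_equal(sum(!ane$links$correct), sum(!tre$link_sequence$correct))
  expect_equal(ane$metrics$n_correct_links, 24)
  expect_equal(ane$metrics$n_total_links,
               ane$metrics$n_correct_links + ane$metrics$n_errors)
})

test_that("items crossed mid-link without a pause are not scored", {
  # three stimuli on a line; one burst travels 1 -> 3 straight across 2
  lay <- fixture_layout("A")
  lay$items <- data.frame(label = c("1", "2", "3"),
                          x = c(100, 200, 300), y = c(100, 100, 100),
                          radius = 20)
  t <- seq(0, 3000, by = 25)
  u <- pmin(1, pmax(0, (t - 500) / 2000))
  s <- u - sin(2 * pi * u) / (2 * pi)
  trace <- data.frame(t_ms = t, x_px = 100 + 200 * s, y_px = 100,
                      pen_down = 1L)
  sp <- lowpass_and_resample(sigma_filter(compute_speed(trace)))
  seg <- segment_by_threshold(sp, 1)
  links <- extract_links(seg, trace, lay)
  expect_equal(nrow(links), 1)
  expect_equal(links$target, "3")
  expect_false(links$correct)     # successor of 1 is 2, so 1 -> 3 is an error
})

test_that("SPL divides completion time by correct links", {
  seg <- structure(list(linking = data.frame(start_ms = c(0, 2000),
                                             end_ms = c(1000, 3000)),
                        nonlinking = data.frame(start_ms = 1000, end_ms = 2000)),
                   class = "tmt_segmentation")
  mk_links <- function(n_ok, n_err = 0, last_end = 31200) {
    data.frame(start_ms = seq_len(n_ok + n_err) * 1000 - 1000,
               end_ms = c(rep(1000, n_ok + n_err - 1), last_end),
               source = "x", target = "y",
               correct = c(rep(TRUE, n_ok), rep(FALSE, n_err)),
               resolved = TRUE)
  }
  m <- compute_trial_metrics(seg, mk_links(10), block_duration_s = 40)
  expect_equal(m$spl_s, 4)           # incomplete trial: block / correct
  m24 <- compute_trial_metrics(seg, mk_links(24, last_end = 31200),
                               block_duration_s = 40)
  expect_equal(m24$completion_time_s, 31.2)
  expect_equal(m24$spl_s, 1.3)
  none <- mk_links(2); none$correct <- FALSE
  expect_error(compute_trial_metrics(seg, none, 40), "undefined")
})

test_that("segmentation recovers simulated trials with exact counts and high overlap", {
  lay <- fixture_layout("A")
  res <- vapply(1:12, function(s) {
    tr <- simulate_trial_behavior(lay, behavior_params(error_rate = 0),
                                  seed = 100 + s)
    ref <- visible_links(tr)
    an <- analyze_trial(tr$trace, lay, expected_links = nrow(ref),
                        block_duration_s = 40)
    c(ok = an$segmentation$n_links_found == nrow(ref),
      jac = interval_jaccard(an$segmentation$linking, ref))
  }, c(ok = 0, jac = 0))
  expect_true(all(res["ok", ] == 1))
  expect_gt(mean(res["jac", ]), 0.9)
})
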