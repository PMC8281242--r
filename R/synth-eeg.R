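#' Block design of a tablet-TMT EEG session
#'
#' Builds the phase timeline of a session: per run, `trials_per_run` cycles
#' of (fixation, control, fixation, TMT-A, fixation, TMT-B), with a final
#' fixation block appended so epochs extending 2 s past the last task block
#' stay inside the recording. Any of the three task types can be dropped to
#' build reduced designs.
#'
#' @param control_duration_s,tmta_duration_s,tmtb_duration_s,fixation_duration_s
#'   phase durations in seconds.
#' @param trials_per_run,runs block-design counts (defaults 4 and 2, i.e.
#'   8 trials per TMT part).
#' @param include which task types to include.
#' @return A list of class `task_design` with a `phases` data.frame
#'   (run, trial, condition, onset_s, duration_s) and the parameters.
#' @export
task_design <- function(control_duration_s = 19, tmta_duration_s = 40,
                        tmtb_duration_s = 60, fixation_duration_s = 10,
                        trials_per_run = 4, runs = 2,
                        include = c("control", "A", "B")) {
  stopifnot(control_duration_s > 0, tmta_duration_s > 0, tmtb_duration_s > 0,
            fixation_duration_s > 0, trials_per_run >= 1, runs >= 1)
  rows <- list()
  t <- 0
  add <- function(run, trial, condition, dur) {
    rows[[length(rows) + 1L]] <<- data.frame(run = run, trial = trial,
                                             condition = condition,
                                             onset_s = t, duration_s = dur,
                                             stringsAsFactors = FALSE)
    t <<- t + dur
  }
  for (r in seq_len(runs)) {
    for (k in seq_len(trials_per_run)) {
      trial <- (r - 1L) * trials_per_run + k
      if ("control" %in% include) {
        add(r, trial, "fixation", fixation_duration_s)
        add(r, trial, "control", control_duration_s)
      }
      if ("A" %in% include) {
        add(r, trial, "fixation", fixation_duration_s)
        add(r, trial, "tmt_a", tmta_duration_s)
      }
      if ("B" %in% include) {
        add(r, trial, "fixation", fixation_duration_s)
        add(r, trial, "tmt_b", tmtb_duration_s)
      }
    }
  }
  add(runs, trials_per_run * runs, "fixation", fixation_duration_s)
  phases <- do.call(rbind, rows)
  structure(list(phases = phases,
                 total_duration_s = t,
                 trials_per_part = trials_per_run * runs,
                 durations = c(control = control_duration_s,
                               tmt_a = tmta_duration_s,
                               tmt_b = tmtb_duration_s,
                               fixation = fixation_duration_s)),
            class = "task_design")
}

#' Condition trigger codes
#'
#' @return Named integer vector mapping phase conditions to trigger codes.
#' @export
trigger_codes <- function() {
  c(fixation = 1L, control = 2L, tmt_a = 3L, tmt_b = 4L)
}

#' EEG simulation parameters
#'
#' The synthetic EEG is, per channel, 1/f ("pink") background noise plus a
#' set of band-limited oscillators whose instantaneous amplitude depends on
#' the behavioural condition of the current sample: `baseline` (fixation,
#' control, and post-completion rest), `nonlink_a`/`nonlink_b` (non-linking
#' periods of TMT-A/B) and `link_a`/`link_b` (linking periods). Optional
#' stereotyped blink transients are added on frontal channels. This encodes
#' the effect structure of interest (e.g. alpha desynchronization during
#' linking movements) without any forward head model.
#'
#' @param channels channel labels; the default is a standard 32-channel
#'   10-20 montage including the mastoid electrodes TP9 and TP10.
#' @param sample_rate_hz simulation rate (1000 by default, matching the
#'   pipeline's post-downsample rate; use 5000 to exercise downsampling).
#' @param pink_rms_uv RMS amplitude of the 1/f background per channel.
#' @param pink_exponent spectral exponent of the background (PSD ~ 1/f^a).
#' @param oscillators list of oscillator specs as built by [oscillator()].
#' @param blink_rate_per_min expected blink rate; 0 disables blinks.
#' @param blink_amplitude_uv peak blink amplitude on Fp1/Fp2.
#' @return A list of class `eeg_sim_params`.
#' @export
eeg_sim_params <- function(channels = acticap32_labels(),
                           sample_rate_hz = 1000,
                           pink_rms_uv = 5,
                           pink_exponent = 1,
                           oscillators = list(
                             oscillator(10, bandwidth_hz = 5,
                                        amplitude_uv = c(baseline = 20,
                                                         nonlink_a = 20,
                                                         nonlink_b = 20,
                                                         link_a = 10,
                                                         link_b = 10))),
                           blink_rate_per_min = 0,
                           blink_amplitude_uv = 100) {
  stopifnot(all(c("TP9", "TP10") %in% channels), sample_rate_hz > 0,
            pink_rms_uv >= 0)
  for (o in oscillators) {
    if (o$center_hz <= 0 || o$center_hz >= sample_rate_hz / 2)
      stop2("oscillator at %g Hz outside (0, Nyquist)", o$center_hz)
    if (any(o$amplitude_uv < 0)) stop2("oscillator amplitudes must be >= 0")
  }
  structure(as.list(environment()), class = "eeg_sim_params")
}

#' Band-limited oscillator specification
#'
#' @param center_hz centre frequency.
#' @param bandwidth_hz full bandwidth of the flat band-limited carrier; 0
#'   gives a pure sinusoid with random phase.
#' @param amplitude_uv named vector of RMS amplitudes per condition
#'   (`baseline`, `nonlink_a`, `nonlink_b`, `link_a`, `link_b`); missing
#'   conditions fall back to `baseline`.
#' @param channels channel subset the oscillator projects onto. NULL means
#'   every non-mastoid channel: the mastoids are kept oscillation-free so
#'   they behave like the comparatively neutral reference sites they are
#'   chosen to be (a common carrier present on the mastoids too would be
#'   cancelled by the mean-mastoid re-reference).
#' @return Oscillator spec list.
#' @export
oscillator <- function(center_hz, bandwidth_hz = 0, amplitude_uv, channels = NULL) {
  if (is.null(names(amplitude_uv)) || !"baseline" %in% names(amplitude_uv))
    stop2("amplitude_uv must be a named vector including 'baseline'")
  list(center_hz = center_hz, bandwidth_hz = bandwidth_hz,
       amplitude_uv = amplitude_uv, channels = channels)
}

#' Standard 32-channel actiCAP montage labels
#' @return Character vector of 32 10-20 electrode labels (incl. TP9/TP10).
#' @export
acticap32_labels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10")
}

# 1/f^a noise via spectral shaping of white Gaussian noise, unit RMS.
pink_noise <- function(n, exponent = 1) {
  nfft <- stats::nextn(n, 2)
  w <- stats::rnorm(nfft)
  W <- stats::fft(w)
  f <- c(1, seq_len(nfft - 1))        # avoid DC blow-up
  f <- pmin(f, nfft - f + 1)          # two-sided frequency index
  W <- W * f^(-exponent / 2)
  x <- Re(stats::fft(W, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}

# flat band-limited Gaussian noise carrier, unit RMS
bandlimited_noise <- function(n, fs, lo, hi) {
  nfft <- stats::nextn(n, 2)
  W <- stats::fft(stats::rnorm(nfft))
  f <- seq(0, fs, length.out = nfft + 1)[1:nfft]
  f2 <- pmin(f, fs - f)
  W[f2 < lo | f2 > hi] <- 0
  x <- Re(stats::fft(W, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}

#' Simulate a multichannel EEG recording for a session
#'
#' @param behavior named list of `tmt_trial` objects keyed by phase row
#'   (see [simulate_session()]), or NULL for a no-task recording; each TMT
#'   phase present in `behavior` contributes its ground-truth link mask.
#' @param design a `task_design`.
#' @param params an `eeg_sim_params`.
#' @param seed integer seed.
#' @return An `eeg_recording`: list with `labels`, `fs`, `data` (channels x
#'   samples matrix, microvolts), `events` (data.frame sample, code,
#'   condition).
#' @export
simulate_eeg <- function(behavior, design, params = eeg_sim_params(),
                         seed = NULL) {
  stopifnot(inherits(design, "task_design"), inherits(params, "eeg_sim_params"))
  fs <- params$sample_rate_hz
  n <- round(design$total_duration_s * fs)
  labels <- params$channels
  nch <- length(labels)

  cond <- condition_per_sample(behavior, design, fs, n)

  with_seed(seed, {
    data <- matrix(0, nch, n)
    for (ch in seq_len(nch))
      data[ch, ] <- params$pink_rms_uv * pink_noise(n, params$pink_exponent)
    for (o in params$oscillators) {
      carrier <- if (o$bandwidth_hz > 0)
        bandlimited_noise(n, fs, o$center_hz - o$bandwidth_hz / 2,
                          o$center_hz + o$bandwidth_hz / 2)
      else
        sqrt(2) * sin(2 * pi * o$center_hz * seq_len(n) / fs +
                        stats::runif(1, 0, 2 * pi))
      amp <- o$amplitude_uv
      env <- amp[["baseline"]] * rep(1, n)
      for (cc in c("nonlink_a", "nonlink_b", "link_a", "link_b")) {
        a <- if (cc %in% names(amp)) amp[[cc]] else amp[["baseline"]]
        env[cond == cc] <- a
      }
      sig <- carrier * env
      chs <- if (is.null(o$channels))
        which(!labels %in% c("TP9", "TP10")) else match(o$channels, labels)
      data[chs, ] <- data[chs, , drop = FALSE] +
        matrix(sig, length(chs), n, byrow = TRUE)
    }
    if (params$blink_rate_per_min > 0) {
      n_blinks <- stats::rpois(1, params$blink_rate_per_min *
                                 design$total_duration_s / 60)
      frontal <- intersect(c("Fp1", "Fp2", "F7", "F8"), labels)
      wts <- c(Fp1 = 1, Fp2 = 1, F7 = 0.4, F8 = 0.4)[frontal]
      if (n_blinks > 0 && length(frontal)) {
        half <- round(0.2 * fs)
        tt <- seq(-half, half) / fs
        shape <- params$blink_amplitude_uv * exp(-tt^2 / (2 * 0.06^2))
        centers <- sort(sample.int(n - 2 * half, n_blinks) + half)
        for (c0 in centers) {
          idx <- (c0 - half):(c0 + half)
          data[match(frontal, labels), idx] <-
            data[match(frontal, labels), idx, drop = FALSE] +
            outer(wts, shape)
        }
      }
    }
    ph <- design$phases
    events <- data.frame(sample = round(ph$onset_s * fs) + 1L,
                         code = trigger_codes()[ph$condition],
                         condition = ph$condition,
                         stringsAsFactors = FALSE)
    rownames(events) <- NULL
    structure(list(labels = labels, fs = fs, data = data, events = events),
              class = "eeg_recording")
  })
}

# Per-sample condition labels: baseline everywhere except within TMT phases,
# where ground-truth link intervals mark link_a/link_b and the remaining
# performed time marks nonlink_a/nonlink_b (post-completion rest = baseline).
condition_per_sample <- function(behavior, design, fs, n) {
  cond <- rep("baseline", n)
  ph <- design$phases
  for (i in seq_len(nrow(ph))) {
    if (!ph$condition[i] %in% c("tmt_a", "tmt_b")) next
    key <- phase_key(ph$condition[i], ph$trial[i])
    tr <- behavior[[key]]
    if (is.null(tr)) next
    part <- if (ph$condition[i] == "tmt_a") "a" else "b"
    on <- round(ph$onset_s[i] * fs)
    comp <- min(round(tr$truth$completion_ms / 1000 * fs),
                round(ph$duration_s[i] * fs))
    if (comp >= 1) cond[(on + 1):(on + comp)] <- paste0("nonlink_", part)
    for (j in seq_len(nrow(tr$truth$links))) {
      a <- on + floor(tr$truth$links$start_ms[j] / 1000 * fs) + 1
      b <- min(on + ceiling(tr$truth$links$end_ms[j] / 1000 * fs), on + comp)
      if (b >= a) cond[a:b] <- paste0("link_", part)
    }
  }
  cond
}

phase_key <- function(condition, trial) sprintf("%s_trial%02d", condition, trial)

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples at %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events)))
  invisible(x)
}
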