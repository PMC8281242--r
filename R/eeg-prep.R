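# Zero-phase application of a linear-phase FIR filter via FFT: the signal is
# reflection-padded by the group delay on both sides, convolved in the
# frequency domain, and realigned by the group delay, so interval boundaries
# are not shifted. `b` must have odd length (type-I linear phase).
fir_zerophase <- function(x, b) {
  nb <- length(b)
  if (nb %% 2 == 0) stop2("FIR kernel must have odd length")
  gd <- (nb - 1) / 2
  n <- length(x)
  if (n <= nb) stop2("signal (%d samples) not longer than filter (%d taps)",
                     n, nb)
  pad_l <- 2 * x[1] - x[seq(gd + 1, 2)]
  pad_r <- 2 * x[n] - x[seq(n - 1, n - gd)]
  xp <- c(pad_l, x, pad_r)
  nfft <- stats::nextn(length(xp) + nb - 1, 2)
  y <- Re(stats::fft(stats::fft(c(xp, rep(0, nfft - length(xp)))) *
                       stats::fft(c(b, rep(0, nfft - nb))), inverse = TRUE)) / nfft
  y[(2 * gd + 1):(2 * gd + n)]
}

# windowed-sinc (Hamming) FIR design via signal::fir1 with odd length
design_fir <- function(order, w, type) {
  if (order %% 2 == 1) order <- order + 1
  as.numeric(signal::fir1(order, w, type))
}

#' Downsample an EEG recording
#'
#' Anti-alias low-pass filters (zero-phase windowed-sinc FIR, cut-off at
#' 80% of the target Nyquist) and decimates by an integer factor. Trigger
#' sample indices are rescaled with rounding to nearest.
#'
#' @param rec an `eeg_recording`.
#' @param target_hz target sampling rate; the source rate must be an
#'   integer multiple.
#' @return The downsampled `eeg_recording`.
#' @export
eeg_downsample <- function(rec, target_hz = 1000) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs == target_hz) return(rec)
  factor <- rec$fs / target_hz
  if (abs(factor - round(factor)) > 1e-9)
    stop2("source rate %g Hz is not an integer multiple of %g Hz",
          rec$fs, target_hz)
  factor <- round(factor)
  b <- design_fir(20 * factor, 0.8 / factor, "low")
  keep <- seq(1, ncol(rec$data), by = factor)
  out <- matrix(0, nrow(rec$data), length(keep))
  for (ch in seq_len(nrow(rec$data)))
    out[ch, ] <- fir_zerophase(rec$data[ch, ], b)[keep]
  rec$data <- out
  rec$fs <- target_hz
  rec$events$sample <- pmax(1L, as.integer(round((rec$events$sample - 1L) /
                                                   factor)) + 1L)
  rec
}

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) band-pass applied with zero phase. The filter
#' order is set by the low-edge transition width (order ~ 3.3 / normalized
#' transition), so the default 0.1 Hz edge implies a long kernel; the
#' recording must be longer than the kernel.
#'
#' @param rec an `eeg_recording`.
#' @param low_hz,high_hz band edges (default 0.1-100 Hz).
#' @param trans_low_hz low-edge transition width; drives the filter order.
#' @return The filtered `eeg_recording` (DC removed).
#' @export
eeg_bandpass <- function(rec, low_hz = 0.1, high_hz = 100,
                         trans_low_hz = 0.1) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (high_hz >= fs / 2) stop2("high edge %g Hz at or above Nyquist", high_hz)
  order <- ceiling(3.3 * fs / trans_low_hz)
  b <- design_fir(order, c(low_hz, high_hz) / (fs / 2), "pass")
  for (ch in seq_len(nrow(rec$data)))
    rec$data[ch, ] <- fir_zerophase(rec$data[ch, ], b)
  rec
}

#' Default artifact-component scorer
#'
#' Heuristic per-component artifact probability from three statistics of an
#' ICA decomposition: the fraction of mixing weight on frontal electrodes
#' (Fp1/Fp2/F7/F8), the excess kurtosis of the component time course
#' (blinks are sparse, heavy-tailed transients) and the fraction of
#' component power below 5 Hz. Components that are simultaneously frontal,
#' heavy-tailed and low-frequency score near 1.
#'
#' @param S components matrix (samples x components).
#' @param M mixing matrix (channels x components).
#' @param labels channel labels.
#' @param fs sampling rate.
#' @return Numeric vector of artifact probabilities in `[0, 1]`.
#' @export
frontal_kurtosis_scorer <- function(S, M, labels, fs) {
  frontal <- labels %in% c("Fp1", "Fp2", "F7", "F8")
  vapply(seq_len(ncol(S)), function(k) {
    w <- abs(M[, k])
    ffrac <- sum(w[frontal]) / sum(w)
    kur <- max(0, e1071::kurtosis(S[, k], type = 2))
    pw <- Mod(stats::fft(S[, k]))^2
    freqs <- seq(0, fs, length.out = length(pw) + 1)[seq_along(pw)]
    half <- freqs <= fs / 2
    lofrac <- sum(pw[half & freqs < 5]) / sum(pw[half])
    1 - exp(-(ffrac / 0.3) * (kur / 5) * lofrac)
  }, 0)
}

#' Remove artifact components by ICA
#'
#' Decomposes the recording with fast fixed-point ICA, scores every
#' component with a pluggable scorer, removes components whose artifact
#' probability exceeds the threshold, and reconstructs the cleaned
#' recording. With `scorer = NULL` the recording is returned unchanged.
#' If the decomposition fails (e.g. rank-deficient or non-converging
#' input), the recording is returned unchanged with a warning.
#'
#' @param rec an `eeg_recording`.
#' @param scorer function(S, M, labels, fs) -> artifact probability per
#'   component; defaults to [frontal_kurtosis_scorer()].
#' @param threshold components with probability above this are removed.
#' @param n_components number of components (default: number of channels).
#' @param seed integer seed for the ICA initialization.
#' @return The cleaned `eeg_recording`, with attribute `removed_components`.
#' @export
remove_artifact_components <- function(rec, scorer = frontal_kurtosis_scorer,
                                       threshold = 0.9, n_components = NULL,
                                       seed = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(scorer)) return(rec)
  nc <- n_components %||% nrow(rec$data)
  X <- t(rec$data)                       # samples x channels
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  dec <- try(with_seed(seed, ica::icafast(Xc, nc = nc)), silent = TRUE)
  if (inherits(dec, "try-error")) {
    warning("ICA failed; returning recording unchanged: ",
            attr(dec, "condition")$message)
    attr(rec, "removed_components") <- integer(0)
    return(rec)
  }
  prob <- scorer(dec$S, dec$M, rec$labels, rec$fs)
  rm_idx <- which(prob > threshold)
  if (length(rm_idx)) {
    artifact <- dec$S[, rm_idx, drop = FALSE] %*%
      t(dec$M[, rm_idx, drop = FALSE])
    Xc <- Xc - artifact
  }
  rec$data <- t(sweep(Xc, 2, -mu))
  attr(rec, "removed_components") <- rm_idx
  attr(rec, "component_probabilities") <- prob
  rec
}

#' Re-reference to the mean mastoids
#'
#' Subtracts the average of the TP9 and TP10 signals from every channel and
#' drops the two mastoid electrodes from the analysis set, leaving 30
#' analysis channels for the standard 32-channel montage.
#'
#' @param rec an `eeg_recording` whose labels include TP9 and TP10.
#' @return The re-referenced `eeg_recording`.
#' @export
rereference_mastoids <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  m <- match(c("TP9", "TP10"), rec$labels)
  if (anyNA(m)) stop2("mastoid electrodes TP9/TP10 not found in recording")
  ref <- colMeans(rec$data[m, , drop = FALSE])
  rec$data <- sweep(rec$data, 2, ref)[-m, , drop = FALSE]
  rec$labels <- rec$labels[-m]
  rec
}

#' Epoch a recording into baseline-anchored TMT trial segments
#'
#' Cuts one epoch per TMT-onset trigger, spanning -10 s (visual-fixation
#' baseline) to the block duration plus an extra 2 s (edge-artifact guard
#' for the wavelet decomposition): -10 to 42 s for TMT-A and -10 to 62 s
#' for TMT-B, with time 0 at the stimulus onset trigger. Excluded trials
#' (by default the first trial of each part, which carries habituation /
#' learning transients) are omitted.
#'
#' @param rec a preprocessed `eeg_recording`.
#' @param tmta_duration_s,tmtb_duration_s block durations.
#' @param baseline_s pre-stimulus seconds included.
#' @param pad_s seconds beyond the block end included.
#' @param exclude_trials per-part trial indices (in order of occurrence) to
#'   drop, e.g. `list(A = 1, B = 1)`.
#' @return An `eeg_epochs` object: list of epochs, each with `part`,
#'   `trial`, `data` (channels x time), `time_s`; plus `labels` and `fs`.
#' @export
epoch_trials <- function(rec, tmta_duration_s = 40, tmtb_duration_s = 60,
                         baseline_s = 10, pad_s = 2,
                         exclude_trials = list(A = 1, B = 1)) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  epochs <- list()
  for (part in c("A", "B")) {
    code <- if (part == "A") trigger_codes()[["tmt_a"]] else trigger_codes()[["tmt_b"]]
    dur <- if (part == "A") tmta_duration_s else tmtb_duration_s
    onsets <- rec$events$sample[rec$events$code == code]
    if (!length(onsets)) next
    excl <- exclude_trials[[part]] %||% integer(0)
    for (k in seq_along(onsets)) {
      if (k %in% excl) next
      i0 <- onsets[k] - baseline_s * fs
      i1 <- onsets[k] + (dur + pad_s) * fs - 1
      if (i0 < 1 || i1 > ncol(rec$data))
        stop2("epoch for TMT-%s trial %d [%d, %d] exceeds record bounds",
              part, k, i0, i1)
      epochs[[length(epochs) + 1L]] <- list(
        part = part, trial = k,
        data = rec$data[, i0:i1, drop = FALSE],
        time_s = seq(-baseline_s, dur + pad_s - 1 / fs, by = 1 / fs))
    }
  }
  structure(list(epochs = epochs, labels = rec$labels, fs = fs,
                 baseline_s = baseline_s, pad_s = pad_s),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  parts <- vapply(x$epochs, `[[`, "", "part")
  cat(sprintf("eeg_epochs: %d epochs (%d A, %d B), %d channels at %g Hz\n",
              length(x$epochs), sum(parts == "A"), sum(parts == "B"),
              length(x$labels), x$fs))
  invisible(x)
}

#' Standard EEG preprocessing chain
#'
#' Downsample to 1000 Hz, 0.1-100 Hz zero-phase FIR band-pass, ICA artifact
#' removal, mean-mastoid re-reference.
#'
#' @param rec raw `eeg_recording`.
#' @param target_hz rate after downsampling.
#' @param scorer artifact scorer (NULL skips the ICA step).
#' @param trans_low_hz band-pass low-edge transition width.
#' @param seed seed for the ICA step.
#' @return Preprocessed `eeg_recording` with 30 analysis channels.
#' @export
preprocess_eeg <- function(rec, target_hz = 1000, scorer = NULL,
                           trans_low_hz = 0.1, seed = NULL) {
  rec <- eeg_downsample(rec, target_hz)
  rec <- eeg_bandpass(rec, trans_low_hz = trans_low_hz)
  rec <- remove_artifact_components(rec, scorer = scorer, seed = seed)
  rereference_mastoids(rec)
}
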