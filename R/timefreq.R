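#' Complex Morlet wavelet bank
#'
#' Twenty wavelet frequencies spaced geometrically (exponentially) between
#' 0.1 and 50 Hz, each wavelet with 6 cycles irrespective of frequency, so
#' the Gaussian time SD is `n_cycles / (2 * pi * f)`.
#'
#' @param n_freqs number of frequencies.
#' @param fmin,fmax frequency range endpoints in Hz.
#' @param n_cycles cycles per wavelet.
#' @return A `wavelet_bank`: list with `freqs`, `n_cycles`, `sigma_t`.
#' @export
morlet_bank <- function(n_freqs = 20, fmin = 0.1, fmax = 50, n_cycles = 6) {
  freqs <- fmin * (fmax / fmin)^((seq_len(n_freqs) - 1) / (n_freqs - 1))
  structure(list(freqs = freqs, n_cycles = n_cycles,
                 sigma_t = n_cycles / (2 * pi * freqs)),
            class = "wavelet_bank")
}

#' Assign wavelets to EEG frequency bands
#'
#' Bands: delta 0.3-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-50 Hz.
#' Each wavelet belongs to the band containing its frequency; additionally,
#' for each interior boundary (4, 8, 13, 30 Hz) the single wavelet nearest
#' the boundary (ties toward the lower frequency) is assigned to both
#' adjacent bands, slightly expanding the band ranges to absorb individual
#' variability. Wavelets below 0.3 Hz stay unassigned.
#'
#' @param bank a `wavelet_bank`.
#' @return A `band_assignment`: named list mapping band -> wavelet indices,
#'   with attribute `dual` (indices assigned to two bands).
#' @export
assign_bands <- function(bank) {
  f <- bank$freqs
  edges <- c(delta = 0.3, theta = 4, alpha = 8, beta = 13, gamma = 30,
             upper = 50)
  bands <- names(edges)[1:5]
  assign <- lapply(seq_along(bands), function(b)
    which(f >= edges[b] & f < edges[b + 1]))
  names(assign) <- bands
  # 50 Hz endpoint belongs to gamma
  assign$gamma <- sort(union(assign$gamma, which(f == edges[["upper"]])))
  dual <- integer(0)
  for (b in 2:5) {
    boundary <- edges[[b]]
    d <- abs(f - boundary)
    k <- which(d == min(d))[1]          # tie broken toward lower frequency
    dual <- c(dual, k)
    assign[[bands[b - 1]]] <- sort(union(assign[[bands[b - 1]]], k))
    assign[[bands[b]]] <- sort(union(assign[[bands[b]]], k))
  }
  structure(assign, dual = dual, class = "band_assignment")
}

# complex Morlet wavelet FFT evaluated directly in the frequency domain:
# the Fourier transform of a unit-energy Morlet centred at f0 is a Gaussian
# in frequency with SD sigma_f = 1 / (2 pi sigma_t), amplitude-normalized
# so that every wavelet has equal energy.
morlet_fft <- function(f0, sigma_t, freqs_fft) {
  sigma_f <- 1 / (2 * pi * sigma_t)
  # analytic (one-sided) wavelet: response only at positive frequencies
  h <- exp(-(freqs_fft - f0)^2 / (2 * sigma_f^2))
  h[freqs_fft < 0] <- 0
  h
}

#' Morlet wavelet time-frequency power of an epoch
#'
#' Convolution by frequency-domain multiplication with analytic Morlet
#' wavelets; power is the squared magnitude of the complex result. Returns
#' the full time axis of the input; callers trim the edge-pad seconds.
#'
#' @param x numeric vector (one channel) or channels x time matrix.
#' @param fs sampling rate.
#' @param bank a `wavelet_bank`.
#' @return For a vector input, a freqs x time matrix; for a matrix, a
#'   channels x freqs x time array.
#' @export
tf_power <- function(x, fs, bank) {
  if (is.matrix(x)) {
    out <- array(0, c(nrow(x), length(bank$freqs), ncol(x)))
    for (ch in seq_len(nrow(x)))
      out[ch, , ] <- tf_power(x[ch, ], fs, bank)
    return(out)
  }
  n <- length(x)
  nfft <- stats::nextn(2 * n, 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  fft_freqs <- c(seq(0, nfft / 2), seq(-nfft / 2 + 1, -1)) * fs / nfft
  out <- matrix(0, length(bank$freqs), n)
  for (k in seq_along(bank$freqs)) {
    H <- morlet_fft(bank$freqs[k], bank$sigma_t[k], fft_freqs)
    y <- stats::fft(X * H, inverse = TRUE)[seq_len(n)] / nfft
    out[k, ] <- Mod(y)^2
  }
  out
}

#' Decibel baseline normalization
#'
#' `dB(t, f) = 10 * log10(power(t, f) / mean baseline power(f))`, with the
#' baseline mean taken over the pre-stimulus window (default -8 to -1 s,
#' trimming 2 s and 1 s from the 10 s fixation to avoid wavelet edge
#' artifacts).
#'
#' @param power freqs x time matrix (or channels x freqs x time array).
#' @param time_s time axis matching the last dimension.
#' @param baseline_window two-element window in seconds.
#' @return dB array of the same shape.
#' @export
db_normalize <- function(power, time_s, baseline_window = c(-8, -1)) {
  sel <- time_s >= baseline_window[1] & time_s <= baseline_window[2]
  if (!any(sel)) stop2("baseline window outside the epoch time axis")
  if (length(dim(power)) == 3) {
    base <- apply(power[, , sel, drop = FALSE], c(1, 2), mean)
    if (any(base <= 0)) stop2("non-positive baseline power")
    return(10 * log10(sweep(power, c(1, 2), base, "/")))
  }
  base <- rowMeans(power[, sel, drop = FALSE])
  if (any(base <= 0)) stop2("non-positive baseline power")
  10 * log10(power / base)
}

#' Linking / non-linking band-power features for a set of epochs
#'
#' For every epoch, channel and wavelet, computes the mean dB-normalized
#' power over the linking-period samples and over the non-linking samples
#' (both restricted to the performed duration), then averages over the
#' wavelets of each band (boundary wavelets contributing to both adjacent
#' bands) and finally over trials. This yields one value per condition
#' (link/non-link x part) x electrode x band -- the task-PLS input for one
#' participant.
#'
#' The per-channel computation is streamed one wavelet at a time, so the
#' full channels x freqs x time array is never materialized.
#'
#' @param epochs an `eeg_epochs` object.
#' @param masks named list (by `phase_key(part, trial)` as in sessions, or
#'   simply indexed in epoch order) of data.frames `links` with
#'   start_ms/end_ms and `completion_ms`; typically the ground truth or the
#'   kinematic segmentation of the matching tablet trial.
#' @param bank a `wavelet_bank`.
#' @param assignment a `band_assignment`.
#' @param baseline_window dB baseline window in seconds.
#' @param participant participant identifier stored in the output.
#' @return Long data.frame: participant, condition (link_a, nonlink_a,
#'   link_b, nonlink_b), electrode, band, power_db.
#' @export
band_period_features <- function(epochs, masks, bank = morlet_bank(),
                                 assignment = assign_bands(bank),
                                 baseline_window = c(-8, -1),
                                 participant = "p01") {
  stopifnot(inherits(epochs, "eeg_epochs"))
  fs <- epochs$fs
  labels <- epochs$labels
  nb <- length(assignment)
  acc <- list()  # per (part): list of trial matrices ch x band x {link, nonlink}
  for (e in epochs$epochs) {
    key <- phase_key(if (e$part == "A") "tmt_a" else "tmt_b", e$trial)
    mask <- masks[[key]]
    if (is.null(mask)) next
    comp_s <- mask$completion_ms / 1000
    task <- e$time_s >= 0 & e$time_s < comp_s
    link <- rep(FALSE, length(e$time_s))
    for (j in seq_len(nrow(mask$links)))
      link <- link | (e$time_s >= mask$links$start_ms[j] / 1000 &
                        e$time_s < mask$links$end_ms[j] / 1000)
    link <- link & task
    nonlink <- task & !link
    if (!any(link) || !any(nonlink)) {
      warning(sprintf("empty link or non-link mask for TMT-%s trial %d; trial skipped",
                      e$part, e$trial))
      next
    }
    base_sel <- e$time_s >= baseline_window[1] & e$time_s <= baseline_window[2]
    nfreq <- length(bank$freqs)
    db_link <- matrix(0, length(labels), nfreq)
    db_nonlink <- matrix(0, length(labels), nfreq)
    n <- ncol(e$data)
    nfft <- stats::nextn(2 * n, 2)
    fft_freqs <- c(seq(0, nfft / 2), seq(-nfft / 2 + 1, -1)) * fs / nfft
    Hs <- lapply(seq_len(nfreq), function(k)
      morlet_fft(bank$freqs[k], bank$sigma_t[k], fft_freqs))
    for (ch in seq_along(labels)) {
      X <- stats::fft(c(e$data[ch, ], rep(0, nfft - n)))
      for (k in seq_len(nfreq)) {
        p <- Mod(stats::fft(X * Hs[[k]], inverse = TRUE)[seq_len(n)] / nfft)^2
        base <- mean(p[base_sel])
        if (base <= 0) stop2("non-positive baseline power")
        # mean of per-sample dB values over each mask
        db_link[ch, k] <- 10 * (mean(log10(p[link])) - log10(base))
        db_nonlink[ch, k] <- 10 * (mean(log10(p[nonlink])) - log10(base))
      }
    }
    bl <- vapply(assignment, function(idx) rowMeans(db_link[, idx, drop = FALSE]),
                 numeric(length(labels)))
    bn <- vapply(assignment, function(idx) rowMeans(db_nonlink[, idx, drop = FALSE]),
                 numeric(length(labels)))
    acc[[e$part]] <- c(acc[[e$part]] %||% list(),
                       list(list(link = bl, nonlink = bn)))
  }
  rows <- list()
  for (part in names(acc)) {
    trials <- acc[[part]]
    for (period in c("link", "nonlink")) {
      m <- Reduce(`+`, lapply(trials, `[[`, period)) / length(trials)
      cond <- paste0(period, "_", tolower(part))
      rows[[length(rows) + 1L]] <- data.frame(
        participant = participant, condition = cond,
        electrode = rep(labels, times = nb),
        band = rep(names(assignment), each = length(labels)),
        power_db = as.vector(m), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
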