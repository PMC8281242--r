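#' Stylus speed from finite differences
#'
#' Estimates speed at each consecutive sample pair as the Euclidean
#' displacement divided by the sample period, assigned to the midpoint of
#' the pair. Pairs that span a pen lift (either sample has `pen_down = 0`)
#' get speed 0 and are flagged, so the gap interior counts as non-linking
#' time downstream.
#'
#' @param trace a `stylus_trace` (columns t_ms, x_px, y_px, pen_down).
#' @return A `speed_series`: data.frame with t_ms and v_px_s, attribute
#'   `pen_gap` marking pen-lift pairs.
#' @export
compute_speed <- function(trace) {
  if (nrow(trace) < 2) stop2("need at least 2 samples to estimate speed")
  dt <- diff(trace$t_ms)
  if (any(dt <= 0)) stop2("timestamps must be strictly increasing")
  if (any(!is.finite(trace$x_px)) || any(!is.finite(trace$y_px)))
    stop2("non-finite coordinates in trace")
  v <- sqrt(diff(trace$x_px)^2 + diff(trace$y_px)^2) / (dt / 1000)
  gap <- trace$pen_down[-nrow(trace)] == 0 | trace$pen_down[-1] == 0
  v[gap] <- 0
  out <- data.frame(t_ms = (trace$t_ms[-1] + trace$t_ms[-nrow(trace)]) / 2,
                    v_px_s = v)
  attr(out, "pen_gap") <- gap
  class(out) <- c("speed_series", "data.frame")
  out
}

#' Sigma filter for spike removal
#'
#' Sliding time-window outlier smoother: for each sample, using the mean and
#' standard deviation of all samples whose times fall within the centred
#' window, values farther than `k_sd` standard deviations from the window
#' mean are replaced by the mean of the window's non-outlier values;
#' everything else passes unchanged. If a window has no non-outlier values
#' the window median is used instead (and counted in the `fallbacks`
#' attribute).
#'
#' @param series a `speed_series`.
#' @param window_ms full window length in milliseconds.
#' @param k_sd outlier cut in standard deviations.
#' @return The filtered `speed_series`.
#' @export
sigma_filter <- function(series, window_ms = 151, k_sd = 2) {
  t <- series$t_ms
  v <- series$v_px_s
  n <- length(v)
  if (n >= 3) {
    med_dt <- stats::median(diff(t))
    if (window_ms < 3 * med_dt)
      stop2("window of %g ms covers fewer than 3 samples at the native rate",
            window_ms)
  }
  half <- window_ms / 2
  out <- v
  fallbacks <- 0L
  lo <- 1L
  hi <- 1L
  for (i in seq_len(n)) {
    while (t[lo] < t[i] - half) lo <- lo + 1L
    while (hi < n && t[hi + 1L] <= t[i] + half) hi <- hi + 1L
    w <- v[lo:hi]
    m <- mean(w)
    s <- stats::sd(w)
    if (!is.finite(s) || s == 0) next
    if (abs(v[i] - m) > k_sd * s) {
      keep <- abs(w - m) <= k_sd * s
      if (any(keep)) {
        out[i] <- mean(w[keep])
      } else {
        out[i] <- stats::median(w)
        fallbacks <- fallbacks + 1L
      }
    }
  }
  series$v_px_s <- out
  attr(series, "fallbacks") <- fallbacks
  series
}

#' Low-pass filter and resample a speed series to 1000 Hz
#'
#' Applies a zero-phase Butterworth low-pass at the cut-off frequency — a
#' 2nd-order design run forward and backward, giving a 4th-order zero-phase
#' response with little time-domain ringing around the speed bells (sharper
#' designs ring at a few percent of the burst peak, which inflates the
#' apparent noise floor of the pauses and with it the segmentation
#' threshold). The series is treated as uniformly sampled at its median
#' rate, then interpolated with cubic splines onto a uniform 1 ms grid;
#' negative interpolation artifacts are clipped to zero.
#'
#' @param series a `speed_series` at the native tablet rate.
#' @param cutoff_hz low-pass cut-off (default 5 Hz, below which 95% of the
#'   spectral content of stylus speed time-courses lies).
#' @param target_hz output rate.
#' @return A uniformly sampled `speed_series` (1 ms spacing by default).
#' @export
lowpass_and_resample <- function(series, cutoff_hz = 5, target_hz = 1000) {
  t <- series$t_ms
  v <- series$v_px_s
  fs <- 1000 / stats::median(diff(t))
  if (length(v) < 13)
    stop2("series too short (%d samples) for the filter warm-up", length(v))
  bf <- signal::butter(2, cutoff_hz / (fs / 2))
  # odd-reflection padding keeps filtfilt's zero initial conditions from
  # injecting edge transients into series with a nonzero baseline
  n <- length(v)
  pad <- min(n - 1, ceiling(3 * fs / cutoff_hz))
  vp <- c(2 * v[1] - v[(pad + 1):2], v, 2 * v[n] - v[(n - 1):(n - pad)])
  vf <- signal::filtfilt(bf, vp)[(pad + 1):(pad + n)]
  grid <- seq(ceiling(t[1]), floor(t[length(t)]), by = 1000 / target_hz)
  sp <- stats::splinefun(t, vf, method = "fmm")
  out <- data.frame(t_ms = grid, v_px_s = pmax(0, sp(grid)))
  class(out) <- c("speed_series", "data.frame")
  out
}

#' Segment a speed series into linking and non-linking periods
#'
#' Slowly increases a candidate speed threshold from 0 px/s in constant
#' steps until the number of supra-threshold excursions (after merging
#' excursions separated by brief sub-threshold gaps and discarding
#' excursions shorter than a minimum duration) equals the expected number
#' of links. The smallest matching threshold wins, so it sits just above
#' the peak speed of the fastest non-linking period.
#'
#' @param speed a uniformly resampled `speed_series`.
#' @param expected_links expected number of linking periods (from link
#'   scoring, or 24 for a completed error-free trial).
#' @param step_px_s threshold step size.
#' @param min_duration_ms minimum excursion duration retained as a link.
#' @param merge_gap_ms sub-threshold gaps shorter than this are merged into
#'   the surrounding excursion.
#' @param stability_steps the count match must hold for this many
#'   consecutive grid steps before a threshold is accepted, mirroring the
#'   manual requirement that linking periods be readily identifiable as a
#'   consistent pattern rather than a coincidental count at one threshold.
#' @return A `tmt_segmentation`: list with `linking` and `nonlinking`
#'   interval data.frames (start_ms/end_ms, half-open, partitioning the
#'   series extent), `threshold_px_s` and `n_links_found`.
#' @export
segment_by_threshold <- function(speed, expected_links, step_px_s = 1,
                                 min_duration_ms = 50, merge_gap_ms = 20,
                                 stability_steps = 3) {
  stopifnot(expected_links >= 1)
  t <- speed$t_ms
  v <- speed$v_px_s
  dt <- stats::median(diff(t))
  vmax <- max(v)
  counts_seen <- integer(0)
  grid <- seq(step_px_s, vmax + step_px_s * stability_steps, by = step_px_s)
  run_list <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    runs <- supra_runs(v, grid[g], dt, min_duration_ms, merge_gap_ms)
    run_list[[g]] <- runs
    counts_seen <- c(counts_seen, nrow(runs))
    ok_from <- g - stability_steps + 1L
    if (ok_from >= 1 &&
        all(counts_seen[ok_from:g] == expected_links)) {
      runs <- run_list[[ok_from]]
      thr <- grid[ok_from]
      linking <- data.frame(start_ms = t[runs$start] - dt / 2,
                            end_ms = t[runs$end] + dt / 2)
      return(build_segmentation(linking, t[1] - dt / 2, t[length(t)] + dt / 2,
                                thr, expected_links))
    }
  }
  stop2(paste0("no threshold on the %g px/s grid yields %d linking periods ",
               "(achievable counts: %s)"),
        step_px_s, expected_links,
        paste(sort(unique(counts_seen)), collapse = ", "))
}

# supra-threshold runs with gap merging and minimum-duration filtering;
# returns sample-index runs
supra_runs <- function(v, thr, dt, min_duration_ms, merge_gap_ms) {
  r <- rle(v > thr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  above <- r$values
  # merge: sub-threshold gaps shorter than merge_gap_ms between two
  # supra-threshold runs are absorbed
  keep_above <- above
  gap_idx <- which(!above & r$lengths * dt < merge_gap_ms)
  gap_idx <- gap_idx[gap_idx > 1 & gap_idx < length(above)]
  keep_above[gap_idx] <- TRUE
  rr <- rle(keep_above)
  ends2 <- cumsum(rr$lengths)
  starts2 <- ends2 - rr$lengths + 1L
  out <- data.frame(start = integer(0), end = integer(0))
  for (k in which(rr$values)) {
    s <- starts[starts2[k]]
    e <- ends[ends2[k]]
    if ((e - s + 1L) * dt >= min_duration_ms)
      out <- rbind(out, data.frame(start = s, end = e))
  }
  out
}

build_segmentation <- function(linking, t0, t1, thr, n_links) {
  linking$start_ms <- pmax(linking$start_ms, t0)
  linking$end_ms <- pmin(linking$end_ms, t1)
  bounds <- c(t0, as.vector(rbind(linking$start_ms, linking$end_ms)), t1)
  nl_start <- bounds[seq(1, length(bounds) - 1, by = 2)]
  nl_end <- bounds[seq(2, length(bounds), by = 2)]
  keep <- nl_end > nl_start
  structure(list(linking = linking,
                 nonlinking = data.frame(start_ms = nl_start[keep],
                                         end_ms = nl_end[keep]),
                 threshold_px_s = thr,
                 n_links_found = n_links,
                 extent_ms = c(t0, t1)),
            class = "tmt_segmentation")
}

#' @export
print.tmt_segmentation <- function(x, ...) {
  cat(sprintf("segmentation: %d linking periods, threshold %.1f px/s over [%.0f, %.0f) ms\n",
              x$n_links_found, x$threshold_px_s, x$extent_ms[1], x$extent_ms[2]))
  invisible(x)
}

#' Score links and errors from a segmentation
#'
#' Each linking period's target is the stimulus nearest the stylus position
#' at the period's end, within a capture radius; its source is the previous
#' target (or the start item). A link is correct when its target is the
#' next item of the sequence not yet reached; items merely crossed mid-link
#' (no segmentation boundary there) are ignored. Linking periods ending
#' farther than the capture radius from every stimulus are flagged as
#' unresolved and counted among the errors.
#'
#' @param segmentation a `tmt_segmentation`.
#' @param trace the `stylus_trace` of the same trial.
#' @param layout the trial's `tmt_layout`.
#' @param capture_factor capture radius as a multiple of the stimulus
#'   radius.
#' @return data.frame of link events: start_ms, end_ms, source, target,
#'   correct, resolved.
#' @export
extract_links <- function(segmentation, trace, layout, capture_factor = 1.5) {
  it <- layout$items
  capture <- capture_factor * it$radius[1]
  fx <- stats::approxfun(trace$t_ms, trace$x_px, rule = 2)
  fy <- stats::approxfun(trace$t_ms, trace$y_px, rule = 2)
  li <- segmentation$linking
  n <- nrow(li)
  source <- target <- character(n)
  correct <- resolved <- logical(n)
  progress <- 1L            # index of the last sequence item reached
  prev <- it$label[1]
  for (k in seq_len(n)) {
    ex <- fx(li$end_ms[k]); ey <- fy(li$end_ms[k])
    d <- sqrt((it$x - ex)^2 + (it$y - ey)^2)
    j <- which.min(d)
    source[k] <- prev
    if (d[j] <= capture) {
      resolved[k] <- TRUE
      target[k] <- it$label[j]
      if (j == progress + 1L) {
        correct[k] <- TRUE
        progress <- progress + 1L
      }
      prev <- it$label[j]
    } else {
      target[k] <- NA_character_
    }
  }
  data.frame(start_ms = li$start_ms, end_ms = li$end_ms,
             source = source, target = target,
             correct = correct, resolved = resolved,
             stringsAsFactors = FALSE)
}

#' Per-trial behavioural metrics
#'
#' Computes completion time, link/error counts, seconds per link (SPL), the
#' linking and non-linking period durations, and per-link average speeds.
#' SPL divides the completion time -- the end of the final link if all 24
#' correct links were made, otherwise the block duration -- by the number
#' of correct links.
#'
#' @param segmentation a `tmt_segmentation`.
#' @param links link events from [extract_links()].
#' @param block_duration_s block time limit in seconds.
#' @param speed optional resampled `speed_series` for per-link average
#'   speeds.
#' @param n_items number of stimuli (25 for the standard TMT).
#' @return A list of class `trial_kinematics`.
#' @export
compute_trial_metrics <- function(segmentation, links, block_duration_s,
                                  speed = NULL, n_items = 25) {
  n_correct <- sum(links$correct)
  if (n_correct == 0) stop2("SPL undefined: no correct links in trial")
  n_total <- nrow(links)
  n_errors <- n_total - n_correct
  all_links <- n_items - 1L
  completion_s <- if (n_correct == all_links)
    max(links$end_ms) / 1000 else block_duration_s
  avg_speed <- rep(NA_real_, n_total)
  if (!is.null(speed)) {
    for (k in seq_len(n_total)) {
      sel <- speed$t_ms >= links$start_ms[k] & speed$t_ms < links$end_ms[k]
      avg_speed[k] <- mean(speed$v_px_s[sel])
    }
  }
  structure(list(completion_time_s = completion_s,
                 n_errors = n_errors,
                 n_total_links = n_total,
                 n_correct_links = n_correct,
                 n_unresolved = sum(!links$resolved),
                 spl_s = completion_s / n_correct,
                 linking_period_ms =
                   segmentation$linking$end_ms - segmentation$linking$start_ms,
                 nonlinking_period_ms =
                   segmentation$nonlinking$end_ms - segmentation$nonlinking$start_ms,
                 avg_link_speed_px_s = avg_speed),
            class = "trial_kinematics")
}

#' Full kinematic analysis of one stylus trace
#'
#' Convenience wrapper chaining [compute_speed()], [sigma_filter()],
#' [lowpass_and_resample()], [segment_by_threshold()], [extract_links()]
#' and [compute_trial_metrics()].
#'
#' @param trace a `stylus_trace`.
#' @param layout the trial's `tmt_layout`.
#' @param expected_links expected number of linking periods.
#' @param block_duration_s block time limit in seconds.
#' @param ... passed to [segment_by_threshold()].
#' @return List with `speed`, `segmentation`, `links`, `metrics`.
#' @export
analyze_trial <- function(trace, layout, expected_links, block_duration_s,
                          ...) {
  sp <- lowpass_and_resample(sigma_filter(compute_speed(trace)))
  seg <- segment_by_threshold(sp, expected_links, ...)
  links <- extract_links(seg, trace, layout)
  metrics <- compute_trial_metrics(seg, links, block_duration_s, speed = sp)
  list(speed = sp, segmentation = seg, links = links, metrics = metrics)
}

#' Trial metrics straight from simulator ground truth
#'
#' Computes the same `trial_kinematics` summary from a simulated trial's
#' ground-truth segmentation and link sequence, bypassing speed-threshold
#' estimation. Used for large simulation studies where segmentation
#' recovery is established separately.
#'
#' @param trial a `tmt_trial`.
#' @param layout the trial's `tmt_layout` (for link distances / speeds).
#' @param n_items number of stimuli.
#' @return A `trial_kinematics`.
#' @export
metrics_from_truth <- function(trial, layout = NULL, n_items = 25) {
  links <- trial$truth$links
  seq_ok <- trial$link_sequence$correct
  # only links fully performed before truncation count
  done <- links$end_ms <= trial$truth$completion_ms
  n_correct <- sum(seq_ok & done)
  if (n_correct == 0) stop2("SPL undefined: no correct links in trial")
  n_total <- sum(done)
  completion_s <- if (n_correct == n_items - 1L)
    max(links$end_ms[done]) / 1000 else trial$block_duration_s
  avg_speed <- rep(NA_real_, n_total)
  if (!is.null(layout)) {
    it <- layout$items
    src <- match(trial$link_sequence$source[done], it$label)
    tgt <- match(trial$link_sequence$target[done], it$label)
    dist <- sqrt((it$x[tgt] - it$x[src])^2 + (it$y[tgt] - it$y[src])^2)
    avg_speed <- dist / ((links$end_ms[done] - links$start_ms[done]) / 1000)
  }
  nl <- trial$truth$nonlinks
  nl <- nl[nl$end_ms <= trial$truth$completion_ms, , drop = FALSE]
  structure(list(completion_time_s = completion_s,
                 n_errors = n_total - n_correct,
                 n_total_links = n_total,
                 n_correct_links = n_correct,
                 n_unresolved = 0L,
                 spl_s = completion_s / n_correct,
                 linking_period_ms = links$end_ms[done] - links$start_ms[done],
                 nonlinking_period_ms = nl$end_ms - nl$start_ms,
                 avg_link_speed_px_s = avg_speed),
            class = "trial_kinematics")
}

#' Ground-truth links visible to threshold segmentation
#'
#' When a trial is truncated by the block limit, the final link may survive
#' only as a fragment too short and slow to register as a supra-threshold
#' excursion (a raised-cosine stroke spends its first ~150 ms near zero
#' speed). For recovery scoring against ground truth, such a trailing
#' sliver is not a countable link — a human scorer watching the trial would
#' not count it either.
#'
#' @param trial a `tmt_trial`.
#' @param min_fragment_ms minimum performed duration of the final fragment.
#' @return The ground-truth link interval data.frame without an invisible
#'   trailing fragment.
#' @export
visible_links <- function(trial, min_fragment_ms = 150) {
  links <- trial$truth$links
  n <- nrow(links)
  if (n && !trial$truth$completed &&
      links$end_ms[n] - links$start_ms[n] < min_fragment_ms)
    links <- links[-n, , drop = FALSE]
  links
}

#' Temporal Jaccard overlap of two interval sets
#'
#' Intersection-over-union of the linking masks, evaluated on a 1 ms grid
#' over the union of both extents. Used to score segmentation recovery
#' against ground truth.
#'
#' @param a,b interval data.frames with start_ms/end_ms columns.
#' @return Jaccard index in `[0, 1]`.
#' @export
interval_jaccard <- function(a, b) {
  t0 <- floor(min(a$start_ms, b$start_ms))
  t1 <- ceiling(max(a$end_ms, b$end_ms))
  grid <- seq(t0 + 0.5, t1 - 0.5, by = 1)
  in_set <- function(iv) {
    m <- rep(FALSE, length(grid))
    for (k in seq_len(nrow(iv)))
      m <- m | (grid >= iv$start_ms[k] & grid < iv$end_ms[k])
    m
  }
  ma <- in_set(a); mb <- in_set(b)
  sum(ma & mb) / sum(ma | mb)
}

#' @export
print.trial_kinematics <- function(x, ...) {
  cat(sprintf("trial kinematics: completion %.1f s, SPL %.2f s, %d/%d correct links, %d errors\n",
              x$completion_time_s, x$spl_s, x$n_correct_links,
              x$n_total_links, x$n_errors))
  invisible(x)
}
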