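#' Behavioural simulation parameters
#'
#' Parameters of the generative model for stylus behaviour during a TMT
#' trial. Linking movements are straight item-to-item strokes whose speed
#' follows a raised-cosine (Hann) bell; the average speed of each link is
#' drawn from a log-normal distribution. Non-linking pauses have log-normal
#' (right-skewed) durations during which the stylus wanders slowly around
#' the current item. Part B slows both period types by multiplicative
#' scales, emulating its higher cognitive demand.
#'
#' @param link_speed_meanlog,link_speed_sdlog log-normal parameters of the
#'   average link speed in px/s (default mean around 284 px/s).
#' @param nonlink_meanlog,nonlink_sdlog log-normal parameters of the
#'   non-linking pause duration in seconds (default mean around 0.55 s,
#'   right-skewed).
#' @param part_b_link_scale,part_b_nonlink_scale multiplicative slowing of
#'   link and pause durations in part B; must be >= 1.
#' @param error_rate probability that any given link is preceded by a
#'   wrong-target link that is then corrected (sequence ... 2 -> 4 -> 3 ...).
#' @param sample_rate_hz nominal tablet logging rate.
#' @param timestamp_jitter_frac uniform jitter on each sampling interval as
#'   a fraction of the nominal interval.
#' @param pause_wander_sd,pause_wander_ar per-sample step SD (px) and AR(1)
#'   pull-back coefficient of the stylus wander during pauses.
#' @return A list of class `behavior_params`.
#' @export
behavior_params <- function(link_speed_meanlog = log(284),
                            link_speed_sdlog = 0.30,
                            nonlink_meanlog = log(0.40),
                            nonlink_sdlog = 0.80,
                            part_b_link_scale = 1.25,
                            part_b_nonlink_scale = 1.25,
                            error_rate = 0.01,
                            sample_rate_hz = 40,
                            timestamp_jitter_frac = 0.10,
                            pause_wander_sd = 0.05,
                            pause_wander_ar = 0.9) {
  stopifnot(part_b_link_scale >= 1, part_b_nonlink_scale >= 1,
            error_rate >= 0, error_rate <= 1, sample_rate_hz > 0,
            link_speed_sdlog >= 0, nonlink_sdlog >= 0)
  structure(as.list(environment()), class = "behavior_params")
}

#' Simulate stylus behaviour for one TMT trial
#'
#' Generates a continuous-time alternation of non-linking pauses and
#' raised-cosine linking bursts through the layout's item sequence, then
#' samples it at approximately the tablet rate with jittered timestamps.
#' The trial is truncated at the block duration if the sequence is not
#' finished in time. Linking errors are injected as wrong-target links that
#' are immediately corrected.
#'
#' @param layout a `tmt_layout`.
#' @param params a `behavior_params` object.
#' @param part TMT part; defaults to the layout's part.
#' @param block_duration_s block time limit in seconds (40 for A, 60 for B).
#' @param seed integer seed.
#' @return A list of class `tmt_trial` with elements
#'   \item{trace}{`stylus_trace`: data.frame t_ms, x_px, y_px, pen_down}
#'   \item{truth}{ground-truth segmentation: data.frames `links` and
#'     `nonlinks` with start_ms/end_ms (half-open), plus completion_ms}
#'   \item{link_sequence}{data.frame source, target, correct per performed link}
#' @export
simulate_trial_behavior <- function(layout, params = behavior_params(),
                                    part = layout$part,
                                    block_duration_s = if (part == "A") 40 else 60,
                                    seed = NULL) {
  stopifnot(inherits(layout, "tmt_layout"), inherits(params, "behavior_params"))
  if (part != layout$part)
    stop2("layout is for part %s but part %s requested", layout$part, part)
  with_seed(seed, {
    link_scale <- if (part == "B") params$part_b_link_scale else 1
    nonlink_scale <- if (part == "B") params$part_b_nonlink_scale else 1
    ev <- build_trial_events(layout, params, link_scale, nonlink_scale)
    sample_trial_events(ev, layout, params, block_duration_s)
  })
}

# Continuous-time event list: alternating pause / link segments visiting the
# item sequence, with optional error detours.
build_trial_events <- function(layout, params, link_scale, nonlink_scale) {
  it <- layout$items
  n <- nrow(it)
  events <- list()
  t <- 0
  cur <- 1L                        # index of item the stylus is at
  add <- function(type, dur, from, to, correct = NA) {
    events[[length(events) + 1L]] <<-
      list(type = type, t0 = t, t1 = t + dur, from = from, to = to,
           correct = correct)
    t <<- t + dur
  }
  pause <- function(from) {
    d <- stats::rlnorm(1, params$nonlink_meanlog, params$nonlink_sdlog) *
      nonlink_scale
    add("pause", d, from, from)
  }
  link <- function(from, to, correct) {
    dist <- sqrt((it$x[to] - it$x[from])^2 + (it$y[to] - it$y[from])^2)
    v <- stats::rlnorm(1, params$link_speed_meanlog, params$link_speed_sdlog) /
      link_scale
    add("link", dist / v, from, to, correct)
  }
  for (target in seq(2L, n)) {
    pause(cur)
    if (stats::runif(1) < params$error_rate) {
      wrong <- sample(setdiff(seq_len(n), c(cur, target)), 1L)
      link(cur, wrong, FALSE)
      cur <- wrong
      pause(cur)
    }
    link(cur, target, TRUE)
    cur <- target
  }
  events
}

# Sample the event list onto a jittered ~sample_rate_hz grid, truncating at
# the block duration, and assemble trace + ground truth.
sample_trial_events <- function(events, layout, params, block_duration_s) {
  it <- layout$items
  total_s <- events[[length(events)]]$t1
  completion_s <- min(total_s, block_duration_s)

  dt_nom <- 1 / params$sample_rate_hz
  n_max <- ceiling(completion_s / (dt_nom * (1 - params$timestamp_jitter_frac))) + 2L
  dts <- dt_nom * (1 + stats::runif(n_max, -params$timestamp_jitter_frac,
                                    params$timestamp_jitter_frac))
  ts <- cumsum(c(0, dts))
  ts <- ts[ts <= completion_s]

  x <- numeric(length(ts)); y <- numeric(length(ts))
  for (ev in events) {
    idx <- which(ts >= ev$t0 & ts < ev$t1)
    if (ev$t1 >= completion_s && ev$t0 <= completion_s)
      idx <- which(ts >= ev$t0)               # last (possibly truncated) event
    if (!length(idx)) next
    if (ev$type == "pause") {
      w <- length(idx)
      jx <- stats::filter(stats::rnorm(w, 0, params$pause_wander_sd),
                          params$pause_wander_ar, method = "recursive")
      jy <- stats::filter(stats::rnorm(w, 0, params$pause_wander_sd),
                          params$pause_wander_ar, method = "recursive")
      x[idx] <- it$x[ev$from] + as.numeric(jx)
      y[idx] <- it$y[ev$from] + as.numeric(jy)
    } else {
      # raised-cosine speed bell: progress s(u) = u - sin(2*pi*u)/(2*pi)
      u <- pmin(1, (ts[idx] - ev$t0) / (ev$t1 - ev$t0))
      s <- u - sin(2 * pi * u) / (2 * pi)
      x[idx] <- it$x[ev$from] + s * (it$x[ev$to] - it$x[ev$from])
      y[idx] <- it$y[ev$from] + s * (it$y[ev$to] - it$y[ev$from])
    }
  }

  trace <- data.frame(t_ms = ts * 1000, x_px = x, y_px = y,
                      pen_down = rep(1L, length(ts)))
  class(trace) <- c("stylus_trace", "data.frame")

  comp_ms <- completion_s * 1000
  keep <- vapply(events, function(e) e$t0 * 1000 < comp_ms, logical(1))
  ev <- events[keep]
  is_link <- vapply(ev, function(e) e$type == "link", logical(1))
  links <- data.frame(
    start_ms = vapply(ev[is_link], function(e) e$t0 * 1000, numeric(1)),
    end_ms = pmin(comp_ms, vapply(ev[is_link], function(e) e$t1 * 1000, numeric(1))))
  nonlinks <- data.frame(
    start_ms = vapply(ev[!is_link], function(e) e$t0 * 1000, numeric(1)),
    end_ms = pmin(comp_ms, vapply(ev[!is_link], function(e) e$t1 * 1000, numeric(1))))
  link_sequence <- data.frame(
    source = it$label[vapply(ev[is_link], function(e) e$from, integer(1))],
    target = it$label[vapply(ev[is_link], function(e) e$to, integer(1))],
    correct = vapply(ev[is_link], function(e) e$correct, logical(1)),
    stringsAsFactors = FALSE)

  structure(list(trace = trace,
                 truth = list(links = links, nonlinks = nonlinks,
                              completion_ms = comp_ms,
                              completed = total_s <= block_duration_s),
                 link_sequence = link_sequence,
                 part = layout$part,
                 block_duration_s = block_duration_s),
            class = "tmt_trial")
}

#' Simulate a perfect responder
#'
#' An idealized participant who links all items in order at a constant
#' stylus speed with no pauses (visual search takes no time) and no errors:
#' the trace is piecewise-linear item-to-item motion sampled at the regular
#' tablet rate. Used as the null model in which the two TMT parts differ
#' only in their labels, not in behaviour.
#'
#' @param layout a `tmt_layout`.
#' @param constant_speed stylus speed in px/s; must be positive.
#' @param sample_rate_hz regular sampling rate.
#' @return A `tmt_trial` (ground-truth pauses have zero duration).
#' @export
simulate_perfect_responder <- function(layout, constant_speed,
                                       sample_rate_hz = 40) {
  stopifnot(inherits(layout, "tmt_layout"))
  if (constant_speed <= 0) stop2("constant_speed must be positive")
  it <- layout$items
  seg_len <- sqrt(diff(it$x)^2 + diff(it$y)^2)
  cum_len <- c(0, cumsum(seg_len))
  total_s <- cum_len[length(cum_len)] / constant_speed
  ts <- seq(0, total_s, by = 1 / sample_rate_hz)
  if (ts[length(ts)] < total_s) ts <- c(ts, total_s)  # include final boundary
  s <- ts * constant_speed
  x <- stats::approx(cum_len, it$x, xout = s, rule = 2)$y
  y <- stats::approx(cum_len, it$y, xout = s, rule = 2)$y
  trace <- data.frame(t_ms = ts * 1000, x_px = x, y_px = y,
                      pen_down = rep(1L, length(ts)))
  class(trace) <- c("stylus_trace", "data.frame")
  t_item <- cum_len / constant_speed * 1000
  links <- data.frame(start_ms = t_item[-length(t_item)], end_ms = t_item[-1])
  structure(list(trace = trace,
                 truth = list(links = links,
                              nonlinks = data.frame(start_ms = numeric(0),
                                                    end_ms = numeric(0)),
                              completion_ms = total_s * 1000,
                              completed = TRUE),
                 link_sequence = data.frame(source = it$label[-25],
                                            target = it$label[-1],
                                            correct = TRUE,
                                            stringsAsFactors = FALSE),
                 part = layout$part,
                 block_duration_s = total_s),
            class = "tmt_trial")
}

#' @export
print.tmt_trial <- function(x, ...) {
  cat(sprintf("TMT-%s trial: %d samples over %.1f s, %d links (%d correct), %s\n",
              x$part, nrow(x$trace), x$truth$completion_ms / 1000,
              nrow(x$link_sequence), sum(x$link_sequence$correct),
              if (x$truth$completed) "completed" else "truncated at block end"))
  invisible(x)
}
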