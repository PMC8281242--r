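# Shared fixtures, built in code. Layouts are cached per (part, seed) since
# placement is deterministic and reused across many tests.

.fixture_env <- new.env(parent = emptyenv())

fixture_layout <- function(part = "A", seed = 42L) {
  key <- paste0(part, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_layout(part, seed = seed)
  .fixture_env[[key]]
}

# uniformly sampled speed series wrapper
speed_series <- function(t_ms, v) {
  out <- data.frame(t_ms = t_ms, v_px_s = v)
  class(out) <- c("speed_series", "data.frame")
  out
}

# two raised-cosine speed bursts over a near-zero floor, 1000 Hz grid;
# returns the series plus the ground-truth burst intervals
two_burst_series <- function(peak = 400, floor_v = 0.2,
                             bursts = list(c(1000, 1800), c(3000, 4000)),
                             total_ms = 5000) {
  t <- seq(0, total_ms - 1)
  v <- rep(floor_v, length(t))
  for (b in bursts) {
    idx <- t >= b[1] & t < b[2]
    u <- (t[idx] - b[1]) / (b[2] - b[1])
    v[idx] <- floor_v + peak / 2 * (1 - cos(2 * pi * u))
  }
  list(series = speed_series(t, v), bursts = bursts)
}

# brute-force O(n * w) reference implementation of the sigma filter,
# independent of the package's windowed implementation
sigma_filter_oracle <- function(t, v, window_ms = 151, k_sd = 2) {
  half <- window_ms / 2
  out <- v
  for (i in seq_along(v)) {
    w <- v[abs(t - t[i]) <= half]
    m <- mean(w)
    s <- stats::sd(w)
    if (!is.finite(s) || s == 0) next
    if (abs(v[i] - m) > k_sd * s) {
      keep <- abs(w - m) <= k_sd * s
      out[i] <- if (any(keep)) mean(w[keep]) else stats::median(w)
    }
  }
  out
}

# synthetic long-format band-power feature table: participant random effect
# plus i.i.d. cell noise, with an optional dB offset injected into chosen
# (condition, electrode, band) cells
synth_features <- function(n_participants = 16,
                           electrodes = paste0("E", sprintf("%02d", 1:30)),
                           bands = c("delta", "theta", "alpha", "beta", "gamma"),
                           conditions = c("nonlink_a", "nonlink_b",
                                          "link_a", "link_b"),
                           noise_sd = 0.5, participant_sd = 0.5,
                           effect_db = 0, effect_electrodes = character(0),
                           effect_bands = character(0),
                           effect_conditions = character(0),
                           seed = 1L) {
  set.seed(seed)
  grid <- expand.grid(participant = sprintf("p%02d", seq_len(n_participants)),
                      condition = conditions, electrode = electrodes,
                      band = bands, stringsAsFactors = FALSE)
  pt_eff <- stats::rnorm(n_participants, 0, participant_sd)
  names(pt_eff) <- sprintf("p%02d", seq_len(n_participants))
  grid$power_db <- pt_eff[grid$participant] +
    stats::rnorm(nrow(grid), 0, noise_sd)
  hit <- grid$electrode %in% effect_electrodes &
    grid$band %in% effect_bands & grid$condition %in% effect_conditions
  grid$power_db[hit] <- grid$power_db[hit] + effect_db
  grid
}

# ground-truth masks of a simulated session, keyed like its trials
session_masks <- function(session) {
  lapply(session$trials, function(tr)
    list(links = tr$truth$links, completion_ms = tr$truth$completion_ms))
}
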