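#' Simulate a complete tablet-TMT + EEG session for one participant
#'
#' Generates stimulus layout variants (cycling base / rotated arrangements
#' across trials), stylus behaviour for every TMT trial, and the synthetic
#' EEG recording with condition-onset triggers. All randomness derives from
#' `seed`, so a fixed seed reproduces the session exactly.
#'
#' @param design a [task_design()].
#' @param behav_params a [behavior_params()].
#' @param eeg_params an [eeg_sim_params()], or NULL to skip EEG simulation.
#' @param seed integer seed.
#' @param layout_seed seed of the base stimulus arrangement (shared across
#'   participants by default, as in a fixed test form).
#' @return A list of class `tmt_session`: `design`, `layouts`, `trials`
#'   (named list of `tmt_trial`), `eeg` (`eeg_recording` or NULL), `seed`.
#' @export
simulate_session <- function(design = task_design(),
                             behav_params = behavior_params(),
                             eeg_params = eeg_sim_params(),
                             seed = 1L, layout_seed = 99L) {
  ph <- design$phases
  trials <- list()
  layouts <- list()
  k <- 0L
  for (i in seq_len(nrow(ph))) {
    if (!ph$condition[i] %in% c("tmt_a", "tmt_b")) next
    k <- k + 1L
    part <- if (ph$condition[i] == "tmt_a") "A" else "B"
    variant <- ((ph$trial[i] - 1L) %% 4L) + 1L
    lay <- generate_layout(part, variant_id = variant, seed = layout_seed)
    trial <- simulate_trial_behavior(
      lay, behav_params, part = part,
      block_duration_s = ph$duration_s[i],
      seed = child_seed(seed, i))
    key <- phase_key(ph$condition[i], ph$trial[i])
    trials[[key]] <- trial
    layouts[[key]] <- lay
  }
  eeg <- if (!is.null(eeg_params))
    simulate_eeg(trials, design, eeg_params, seed = child_seed(seed, 10000L))
  structure(list(design = design, layouts = layouts, trials = trials,
                 eeg = eeg, seed = seed),
            class = "tmt_session")
}

#' @export
print.tmt_session <- function(x, ...) {
  cat(sprintf("tablet-TMT session: %d TMT trials, seed %d\n",
              length(x$trials), x$seed))
  if (!is.null(x$eeg)) print(x$eeg)
  invisible(x)
}

#' Write a session to disk
#'
#' Persists stylus logs as per-trial TSV files (columns t_ms, x_px, y_px,
#' pen_down; coordinate origin top-left, x right, y down, pixel units),
#' the EEG recording as EDF with trigger annotations, and layouts plus
#' ground truth as JSON sidecars. Output is byte-identical for a fixed
#' seed.
#'
#' @param session a `tmt_session`.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_session <- function(session, out_dir) {
  stopifnot(inherits(session, "tmt_session"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (key in names(session$trials)) {
    tr <- session$trials[[key]]
    p <- file.path(out_dir, paste0("stylus_", key, ".tsv"))
    write_stylus_tsv(tr$trace, p)
    paths <- c(paths, p)
    p <- file.path(out_dir, paste0("truth_", key, ".json"))
    jsonlite::write_json(
      list(part = tr$part,
           block_duration_s = tr$block_duration_s,
           completion_ms = tr$truth$completion_ms,
           completed = tr$truth$completed,
           links = tr$truth$links,
           nonlinks = tr$truth$nonlinks,
           link_sequence = tr$link_sequence),
      p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
    lay <- session$layouts[[key]]
    p <- file.path(out_dir, paste0("layout_", key, ".json"))
    jsonlite::write_json(
      list(part = lay$part, variant_id = lay$variant_id,
           width = lay$width, height = lay$height, items = lay$items),
      p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  if (!is.null(session$eeg)) {
    p <- file.path(out_dir, "eeg.edf")
    write_edf(session$eeg, p)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "design.json")
  jsonlite::write_json(list(phases = session$design$phases,
                            seed = session$seed),
                       p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}

#' Write / read a stylus trace TSV
#'
#' Tab-separated with a header line; columns t_ms, x_px, y_px, pen_down.
#' Coordinates use the display convention: origin top-left, x rightward,
#' y downward, in pixels.
#'
#' @param trace a `stylus_trace` data.frame.
#' @param path file path.
#' @return `read_stylus_tsv` returns a `stylus_trace`.
#' @export
write_stylus_tsv <- function(trace, path) {
  df <- data.frame(t_ms = sprintf("%.6f", trace$t_ms),
                   x_px = sprintf("%.6f", trace$x_px),
                   y_px = sprintf("%.6f", trace$y_px),
                   pen_down = trace$pen_down)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stylus_tsv
#' @export
read_stylus_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("t_ms", "x_px", "y_px", "pen_down") %in% names(df)))
  class(df) <- c("stylus_trace", "data.frame")
  df
}
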