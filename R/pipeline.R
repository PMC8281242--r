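#' Default pipeline configuration
#'
#' All tunable parameters of an end-to-end run: cohort size, task design,
#' behaviour and EEG generators, exclusion policy, and PLS settings. Saved
#' into every output bundle together with its hash and seed so artifacts
#' are traceable.
#'
#' @param n_participants cohort size.
#' @param seed master seed; per-stage seeds derive from it.
#' @param out_dir output directory.
#' @return A list of class `run_config`.
#' @export
default_config <- function(n_participants = 16, seed = 1L,
                           out_dir = "tmteeg_run") {
  structure(list(
    n_participants = n_participants,
    seed = seed,
    out_dir = out_dir,
    design = list(trials_per_run = 4, runs = 2, include = c("A", "B"),
                  control_duration_s = 19, tmta_duration_s = 40,
                  tmtb_duration_s = 60, fixation_duration_s = 10),
    behavior = unclass(behavior_params()),
    eeg = list(enabled = FALSE, sample_rate_hz = 1000, pink_rms_uv = 5,
               channels = acticap32_labels()),
    exclusion = list(metric = "spl_s", alpha = 0.05, min_later = 4),
    pls = list(n_perm = 1000, n_boot = 1000)),
    class = "run_config")
}

#' Load a pipeline configuration from JSON
#'
#' Values present in the file override the defaults; everything else keeps
#' its default, and the merged configuration is what every stage sees.
#'
#' @param path JSON file.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        merge_in(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  structure(merge_in(unclass(cfg), user), class = "run_config")
}

# hash of the scientific configuration; output location is excluded so the
# same parameters hash identically wherever the run lands
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  digest::digest(cfg, algo = "md5")
}

run_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

stage_meta <- function(config) {
  list(config_hash = config_hash(config), seed = config$seed,
       package_version = as.character(utils::packageVersion("tmteeg")))
}

cfg_behavior <- function(config) {
  do.call(behavior_params,
          config$behavior[names(config$behavior) %in%
                            names(formals(behavior_params))])
}

cfg_design <- function(config) {
  d <- config$design
  task_design(control_duration_s = d$control_duration_s,
              tmta_duration_s = d$tmta_duration_s,
              tmtb_duration_s = d$tmtb_duration_s,
              fixation_duration_s = d$fixation_duration_s,
              trials_per_run = d$trials_per_run, runs = d$runs,
              include = d$include)
}

#' Run pipeline stages
#'
#' Orchestrates the end-to-end analysis: `simulate` writes one session
#' directory per participant; `behavior` computes per-trial kinematic
#' metrics and the behavioural statistics report; `eeg` extracts band-power
#' features from the simulated EEG; `pls` fits the omnibus task PLS and the
#' four standard subtests. Stages consume only the files of earlier stages,
#' so a run can be restarted at any stage. All outputs carry the
#' configuration hash and seed.
#'
#' @param config a `run_config` (or path to a JSON config).
#' @param stages subset of c("simulate", "behavior", "eeg", "pls"), in
#'   order; "all" runs everything.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config = default_config(), stages = "all") {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "behavior", "eeg", "pls")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  for (s in stages)
    switch(s,
           simulate = run_simulate(config),
           behavior = run_behavior(config),
           eeg = run_eeg(config),
           pls = run_pls(config))
  invisible(config$out_dir)
}

#' @rdname run_pipeline
#' @export
run_simulate <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- cfg_design(config)
  bp <- cfg_behavior(config)
  ep <- if (isTRUE(config$eeg$enabled))
    eeg_sim_params(channels = config$eeg$channels,
                   sample_rate_hz = config$eeg$sample_rate_hz,
                   pink_rms_uv = config$eeg$pink_rms_uv)
  for (i in seq_len(config$n_participants)) {
    ses <- simulate_session(design, bp, ep, seed = child_seed(config$seed, i))
    pdir <- file.path(config$out_dir, sprintf("participant%02d", i))
    write_session(ses, pdir)
    run_log("simulate", "participant %02d -> %s", i, pdir)
  }
  jsonlite::write_json(c(stage_meta(config), list(config = unclass(config))),
                       file.path(config$out_dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

#' @rdname run_pipeline
#' @export
run_behavior <- function(config) {
  pdirs <- list.dirs(config$out_dir, recursive = FALSE)
  pdirs <- pdirs[grepl("participant[0-9]+$", pdirs)]
  if (!length(pdirs))
    stop2("no session directories under %s; run the simulate stage first",
          config$out_dir)
  metrics <- list(); pt <- part <- character(0); trial <- integer(0)
  for (pd in pdirs) {
    for (tf in list.files(pd, pattern = "^truth_.*\\.json$", full.names = TRUE)) {
      truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
      trial_obj <- truth_to_trial(truth)
      lay <- read_layout_json(sub("truth_", "layout_", tf))
      metrics[[length(metrics) + 1L]] <- metrics_from_truth(trial_obj, lay)
      pt <- c(pt, basename(pd))
      part <- c(part, truth$part)
      trial <- c(trial, as.integer(sub(".*trial([0-9]+)\\.json$", "\\1", tf)))
    }
  }
  tbl <- metric_table(metrics, pt, part, trial)
  screen <- trial_effect_screen(tbl, metric = config$exclusion$metric,
                                alpha = config$exclusion$alpha,
                                min_later = config$exclusion$min_later)
  excl <- lapply(screen, `[[`, "excluded_trials")
  keep <- !mapply(function(p, tr) tr %in% (excl[[p]] %||% integer(0)),
                  tbl$part, tbl$trial)
  tbl_kept <- tbl[keep, ]
  stats_out <- list(meta = stage_meta(config),
                    excluded_trials = excl,
                    comparisons = lapply(
                      c(spl_s = "spl_s", completion_time_s = "completion_time_s",
                        linking_period_ms = "linking_period_ms",
                        nonlinking_period_ms = "nonlinking_period_ms",
                        avg_link_speed_px_s = "avg_link_speed_px_s"),
                      function(m) {
                        cp <- compare_parts(tbl_kept, m)
                        list(means_p = cp$means$p_value,
                             distributions_p = cp$distributions$p_value,
                             skewness_p = cp$skewness$p_value)
                      }))
  scalar_cols <- c("participant", "part", "trial", "spl_s",
                   "completion_time_s", "n_errors", "n_total_links",
                   "n_correct_links")
  utils::write.table(as.data.frame(tbl)[, scalar_cols],
                     file.path(config$out_dir, "trial_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(stats_out, file.path(config$out_dir, "behavior_stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run_log("behavior", "%d trials scored, exclusions: %s",
          nrow(tbl), paste(names(excl), vapply(excl, paste, "", collapse = "+"),
                           collapse = ", "))
  invisible(config$out_dir)
}

read_layout_json <- function(path) {
  if (!file.exists(path)) return(NULL)
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(items = as.data.frame(l$items), width = l$width,
                 height = l$height, part = l$part,
                 variant_id = l$variant_id),
            class = "tmt_layout")
}

truth_to_trial <- function(truth) {
  structure(list(trace = NULL,
                 truth = list(links = as.data.frame(truth$links),
                              nonlinks = as.data.frame(truth$nonlinks),
                              completion_ms = truth$completion_ms,
                              completed = truth$completed),
                 link_sequence = as.data.frame(truth$link_sequence),
                 part = truth$part,
                 block_duration_s = truth$block_duration_s),
            class = "tmt_trial")
}

#' @rdname run_pipeline
#' @export
run_eeg <- function(config) {
  pdirs <- list.dirs(config$out_dir, recursive = FALSE)
  pdirs <- pdirs[grepl("participant[0-9]+$", pdirs)]
  feats <- list()
  for (pd in pdirs) {
    edf <- file.path(pd, "eeg.edf")
    if (!file.exists(edf))
      stop2("no EEG recording in %s; enable eeg in the simulate stage", pd)
    rec <- read_edf(edf)
    rec <- preprocess_eeg(rec, scorer = NULL,
                          trans_low_hz = 2)  # simulated data carry no drift
    ep <- epoch_trials(rec,
                       tmta_duration_s = config$design$tmta_duration_s,
                       tmtb_duration_s = config$design$tmtb_duration_s)
    masks <- list()
    for (tf in list.files(pd, pattern = "^truth_.*\\.json$", full.names = TRUE)) {
      truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
      key <- sub("^truth_(.*)\\.json$", "\\1", basename(tf))
      masks[[key]] <- list(links = as.data.frame(truth$links),
                           completion_ms = truth$completion_ms)
    }
    feats[[pd]] <- band_period_features(ep, masks, participant = basename(pd))
    run_log("eeg", "%s: features extracted", basename(pd))
  }
  features <- do.call(rbind, feats)
  utils::write.table(features, file.path(config$out_dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(config$out_dir)
}

#' @rdname run_pipeline
#' @export
run_pls <- function(config) {
  fpath <- file.path(config$out_dir, "features.tsv")
  if (!file.exists(fpath))
    stop2("features file %s not found; run the eeg stage first", fpath)
  features <- utils::read.table(fpath, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  np <- config$pls$n_perm; nb <- config$pls$n_boot
  present <- unique(features$condition)
  fits <- list(omnibus = task_pls(features, n_perm = np, n_boot = nb,
                                  seed = child_seed(config$seed, 101L)))
  subtests <- list(link_b_vs_link_a = c("link_b", "link_a"),
                   nonlink_b_vs_nonlink_a = c("nonlink_b", "nonlink_a"),
                   link_a_vs_nonlink_a = c("link_a", "nonlink_a"),
                   link_b_vs_nonlink_b = c("link_b", "nonlink_b"))
  sk <- 101L
  for (nm in names(subtests)) {
    if (!all(subtests[[nm]] %in% present)) next
    sk <- sk + 1L
    fits[[nm]] <- run_subtest(features, subtests[[nm]], n_perm = 0,
                              n_boot = nb, seed = child_seed(config$seed, sk))
  }
  if (all(c("link_a", "link_b", "nonlink_a", "nonlink_b") %in% present))
    fits$link_vs_nonlink <- run_subtest(features, "link_vs_nonlink",
                                        n_perm = 0, n_boot = nb,
                                        seed = child_seed(config$seed, 110L))
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    bundle <- list(meta = stage_meta(config),
                   analysis = nm,
                   subtest = fit$subtest,
                   singular_values = fit$d,
                   variance_explained =
                     if (fit$subtest) NULL else fit$variance_explained,
                   permutation_p = if (fit$subtest) NULL else fit$perm_p,
                   conditions = fit$design$conditions,
                   condition_loadings = fit$boot$v_mean[, 1],
                   condition_loadings_sd = fit$boot$v_sd[, 1],
                   contrasts = fit$contrasts)
    bundle <- Filter(Negate(is.null), bundle)
    jsonlite::write_json(bundle,
                         file.path(config$out_dir, paste0("pls_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    m <- threshold_map(fit)
    utils::write.table(cbind(band = rownames(m), as.data.frame(m)),
                       file.path(config$out_dir, paste0("bsr_map_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    run_log("pls", "%s: %d stable saliences", nm, sum(m != 0))
  }
  invisible(config$out_dir)
}
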