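#' Build a metric table from per-trial kinematics
#'
#' @param metrics_list list of `trial_kinematics`.
#' @param participant,part,trial vectors parallel to `metrics_list`.
#' @return A `metric_table` data.frame keyed by (participant, part, trial)
#'   with columns spl_s, completion_time_s, n_errors, n_total_links,
#'   n_correct_links, and list-columns of link speeds and period durations.
#' @export
metric_table <- function(metrics_list, participant, part, trial) {
  stopifnot(length(metrics_list) == length(participant),
            length(participant) == length(part),
            length(part) == length(trial))
  df <- data.frame(participant = participant, part = part, trial = trial,
                   spl_s = vapply(metrics_list, `[[`, 0, "spl_s"),
                   completion_time_s =
                     vapply(metrics_list, `[[`, 0, "completion_time_s"),
                   n_errors = vapply(metrics_list, `[[`, 0, "n_errors"),
                   n_total_links =
                     vapply(metrics_list, `[[`, 0, "n_total_links"),
                   n_correct_links =
                     vapply(metrics_list, `[[`, 0, "n_correct_links"),
                   stringsAsFactors = FALSE)
  df$linking_period_ms <- lapply(metrics_list, `[[`, "linking_period_ms")
  df$nonlinking_period_ms <- lapply(metrics_list, `[[`, "nonlinking_period_ms")
  df$avg_link_speed_px_s <- lapply(metrics_list, `[[`, "avg_link_speed_px_s")
  class(df) <- c("metric_table", "data.frame")
  df
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Compares the sample to a normal distribution with the sample's own mean
#' and standard deviation.
#'
#' @param values numeric vector (n >= 5).
#' @return A `stat_report` list: test, statistic, p_value, n.
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 5) stop2("need at least 5 values, got %d", length(values))
  s <- stats::sd(values)
  if (s == 0) stop2("degenerate sample: zero standard deviation")
  kt <- suppressWarnings(stats::ks.test(values, "pnorm", mean(values), s))
  stat_report("one-sample KS (normality)", kt$statistic, kt$p.value,
              n = length(values))
}

stat_report <- function(test, statistic, p_value, n, groups = NULL) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p_value), n = n, groups = groups),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$test, x$statistic, x$p_value, paste(x$n, collapse = ", ")))
  invisible(x)
}

# Dunn's rank-based pairwise z-tests after a Kruskal-Wallis test, with tie
# correction and Sidak-adjusted p-values. Returns one row per pair.
dunn_sidak <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  mr <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  lev <- levels(groups)
  m <- length(lev)
  n_pairs <- m * (m - 1) / 2
  out <- list()
  for (i in seq_len(m - 1)) {
    for (j in seq((i + 1), m)) {
      se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ng[i] + 1 / ng[j]))
      z <- (mr[i] - mr[j]) / se
      p <- 2 * stats::pnorm(-abs(z))
      out[[length(out) + 1L]] <- data.frame(
        group1 = lev[i], group2 = lev[j], z = unname(z), p = unname(p),
        p_sidak = 1 - (1 - unname(p))^n_pairs, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Trial-effect screening with post hoc exclusion
#'
#' For each TMT part, runs a Kruskal-Wallis test of the metric across trial
#' numbers; when significant, Dunn's pairwise comparisons with Sidak
#' correction identify leading trials significantly slower than at least
#' `min_later` later trials (habituation/learning transients). Flagged
#' trials are excluded and the Kruskal-Wallis test is repeated to confirm
#' that no residual trial effect remains.
#'
#' @param tbl a `metric_table`.
#' @param metric column to screen (default "spl_s").
#' @param alpha significance level.
#' @param min_later minimum number of later trials a leading trial must be
#'   significantly slower than to be flagged.
#' @return Named list per part with `kw` (stat_report), `pairwise`
#'   (data.frame or NULL), `excluded_trials`, `kw_after` (stat_report or
#'   NULL).
#' @export
trial_effect_screen <- function(tbl, metric = "spl_s", alpha = 0.05,
                                min_later = 4) {
  out <- list()
  for (p in unique(tbl$part)) {
    sub <- tbl[tbl$part == p, ]
    trials <- sort(unique(sub$trial))
    if (length(trials) < 2) stop2("part %s has a single trial", p)
    vals <- sub[[metric]]
    if (length(unique(vals)) == 1) {
      out[[p]] <- list(kw = stat_report("Kruskal-Wallis", NA, 1, nrow(sub)),
                       pairwise = NULL, excluded_trials = integer(0),
                       kw_after = NULL)
      next
    }
    kw <- stats::kruskal.test(vals, factor(sub$trial))
    res <- list(kw = stat_report("Kruskal-Wallis", kw$statistic, kw$p.value,
                                 nrow(sub)),
                pairwise = NULL, excluded_trials = integer(0),
                kw_after = NULL)
    if (kw$p.value < alpha) {
      pw <- dunn_sidak(vals, sub$trial)
      res$pairwise <- pw
      excl <- integer(0)
      for (tr in trials[-length(trials)]) {
        later <- trials[trials > tr]
        sig_slower <- vapply(later, function(l) {
          row <- pw[(pw$group1 == tr & pw$group2 == l) |
                      (pw$group1 == l & pw$group2 == tr), ]
          if (!nrow(row)) return(FALSE)
          slower <- mean(vals[sub$trial == tr]) > mean(vals[sub$trial == l])
          row$p_sidak[1] < alpha && slower
        }, logical(1))
        if (sum(sig_slower) >= min_later) excl <- c(excl, tr)
      }
      res$excluded_trials <- excl
      if (length(excl)) {
        keep <- !(sub$trial %in% excl)
        if (length(unique(sub$trial[keep])) >= 2) {
          kw2 <- stats::kruskal.test(vals[keep], factor(sub$trial[keep]))
          res$kw_after <- stat_report("Kruskal-Wallis (after exclusion)",
                                      kw2$statistic, kw2$p.value, sum(keep))
        }
      }
    }
    out[[p]] <- res
  }
  out
}

#' Compare a metric between TMT parts
#'
#' Three non-parametric reports per metric: a Wilcoxon signed rank test on
#' participant means (paired across parts), a two-sample Kolmogorov-Smirnov
#' test on the pooled trial-level distributions, and a Wilcoxon signed rank
#' test on the per-participant skewness of the distributions.
#'
#' @param tbl a `metric_table`.
#' @param metric scalar column name, or one of the list-columns
#'   ("linking_period_ms", "nonlinking_period_ms", "avg_link_speed_px_s")
#'   whose values are pooled within participant.
#' @param parts the two parts to compare (defaults to A and B).
#' @return List with `means`, `distributions`, `skewness` stat_reports and
#'   the participant mean vectors.
#' @export
compare_parts <- function(tbl, metric = "spl_s", parts = c("A", "B")) {
  vals <- function(p) {
    sub <- tbl[tbl$part == p, ]
    out <- if (is.list(sub[[metric]]))
      lapply(split(sub[[metric]], sub$participant),
             function(l) unlist(l, use.names = FALSE))
    else
      split(sub[[metric]], sub$participant)
    out <- lapply(out, function(v) v[is.finite(v)])
    out[vapply(out, length, 0L) > 0]
  }
  va <- vals(parts[1]); vb <- vals(parts[2])
  common <- intersect(names(va), names(vb))
  if (!length(common)) stop2("no participants present in both parts")
  va <- va[common]; vb <- vb[common]
  mean_a <- vapply(va, mean, 0); mean_b <- vapply(vb, mean, 0)
  pooled_a <- unlist(va, use.names = FALSE)
  pooled_b <- unlist(vb, use.names = FALSE)
  skew_a <- vapply(va, safe_skewness, 0)
  skew_b <- vapply(vb, safe_skewness, 0)

  w <- if (all(abs(mean_a - mean_b) < 1e-12))
    list(statistic = 0, p.value = 1)   # identical paired samples: no evidence
  else
    suppressWarnings(stats::wilcox.test(mean_a, mean_b, paired = TRUE,
                                        exact = FALSE))
  ks <- suppressWarnings(stats::ks.test(pooled_a, pooled_b))
  ok <- is.finite(skew_a) & is.finite(skew_b)
  sk <- if (sum(ok) >= 3 && any(skew_a[ok] != skew_b[ok]))
    suppressWarnings(stats::wilcox.test(skew_a[ok], skew_b[ok], paired = TRUE,
                                        exact = FALSE))
  else list(statistic = NA, p.value = 1)

  list(means = stat_report("Wilcoxon signed rank (participant means)",
                           w$statistic, w$p.value, length(common), parts),
       distributions = stat_report("two-sample KS (pooled distributions)",
                                   ks$statistic, ks$p.value,
                                   c(length(pooled_a), length(pooled_b)), parts),
       skewness = stat_report("Wilcoxon signed rank (skewness)",
                              sk$statistic, sk$p.value, sum(ok), parts),
       participant_means = data.frame(participant = common, mean_a = mean_a,
                                      mean_b = mean_b))
}

safe_skewness <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || stats::sd(x) == 0) return(NA_real_)
  e1071::skewness(x, type = 2)
}

#' Bootstrap confidence intervals for histogram bin means
#'
#' Estimates 95% percentile confidence intervals of the mean histogram
#' height at each sampling bin by resampling participants with replacement
#' (the participant, not the trial, is the exchangeable unit, respecting
#' within-participant dependence).
#'
#' @param values list of numeric vectors, one per participant.
#' @param breaks histogram bin breaks.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param conf confidence level.
#' @param seed integer seed.
#' @return data.frame with bin_lo, bin_hi, mean, ci_lo, ci_hi.
#' @export
bootstrap_bin_ci <- function(values, breaks, n_boot = 1000, conf = 0.95,
                             seed = NULL) {
  stopifnot(is.list(values), n_boot >= 100)
  np <- length(values)
  props <- t(vapply(values, function(v) {
    h <- graphics::hist(v[v >= breaks[1] & v <= breaks[length(breaks)]],
                        breaks = breaks, plot = FALSE)
    h$counts / max(1, length(v))
  }, numeric(length(breaks) - 1)))
  obs <- colMeans(props)
  qs <- with_seed(seed, {
    bm <- matrix(0, n_boot, ncol(props))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(np, np, replace = TRUE)
      bm[b, ] <- colMeans(props[idx, , drop = FALSE])
    }
    apply(bm, 2, stats::quantile,
          probs = c((1 - conf) / 2, 1 - (1 - conf) / 2))
  })
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             mean = obs, ci_lo = qs[1, ], ci_hi = qs[2, ])
}
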