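#' Assemble task-PLS data and design matrices from band-power features
#'
#' Stacks the feature table into the data matrix X (rows: participants
#' nested within conditions, condition-major; columns: electrode-major then
#' band) and the one-hot condition indicator matrix Y. X is column
#' mean-centred, so the cross-product `t(X) %*% Y` is proportional to the
#' condition-mean deviations -- the standard task-PLS effect matrix. For
#' the full cohort (16 participants, 4 conditions, 30 electrodes, 5 bands)
#' X is 64 x 150 and Y is 64 x 4.
#'
#' @param features long data.frame with columns participant, condition,
#'   electrode, band, power_db.
#' @param conditions condition order; defaults to the sorted unique values
#'   with the canonical omnibus order (nonlink_a, nonlink_b, link_a,
#'   link_b) when those are present.
#' @param center column mean-centre X.
#' @return A `pls_design`: list with X, Y, conditions, participants,
#'   electrodes, bands, feature_names, row_participant, row_condition.
#' @export
pls_assemble <- function(features, conditions = NULL, center = TRUE) {
  req <- c("participant", "condition", "electrode", "band", "power_db")
  if (!all(req %in% names(features)))
    stop2("features must have columns %s", paste(req, collapse = ", "))
  canonical <- c("nonlink_a", "nonlink_b", "link_a", "link_b")
  if (is.null(conditions)) {
    u <- unique(features$condition)
    conditions <- if (all(u %in% canonical)) canonical[canonical %in% u] else sort(u)
  }
  participants <- sort(unique(features$participant))
  electrodes <- unique(features$electrode)
  bands <- unique(features$band)
  p <- length(electrodes) * length(bands)
  feature_names <- paste(rep(electrodes, each = length(bands)),
                         rep(bands, times = length(electrodes)), sep = ".")
  key <- function(el, bd) match(el, electrodes) * 1000L + match(bd, bands)
  col_of <- setNames(seq_len(p),
                     key(rep(electrodes, each = length(bands)),
                         rep(bands, times = length(electrodes))))
  n <- length(participants) * length(conditions)
  X <- matrix(NA_real_, n, p)
  row_participant <- character(n)
  row_condition <- character(n)
  r <- 0L
  for (cond in conditions) {
    for (pt in participants) {
      r <- r + 1L
      sub <- features[features$condition == cond & features$participant == pt, ]
      if (!nrow(sub))
        stop2("missing cell: participant %s, condition %s", pt, cond)
      X[r, col_of[as.character(key(sub$electrode, sub$band))]] <- sub$power_db
      row_participant[r] <- pt
      row_condition[r] <- cond
    }
  }
  if (anyNA(X)) {
    bad <- feature_names[colSums(is.na(X)) > 0]
    stop2("incomplete feature table; gaps in: %s",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  if (center) X <- sweep(X, 2, colMeans(X))
  Y <- outer(row_condition, conditions, `==`) * 1
  colnames(Y) <- conditions
  colnames(X) <- feature_names
  structure(list(X = X, Y = Y, conditions = conditions,
                 participants = participants, electrodes = electrodes,
                 bands = bands, feature_names = feature_names,
                 row_participant = row_participant,
                 row_condition = row_condition, centered = center),
            class = "pls_design")
}

# SVD of the condition cross-product; the core decomposition E = U S V'
pls_core <- function(X, Y) {
  E <- crossprod(X, Y)
  if (all(abs(E) < 1e-12)) {
    k <- ncol(Y)
    return(list(d = rep(0, k), u = matrix(0, nrow(E), k),
                v = diag(k), zero_effect = TRUE))
  }
  s <- svd(E)
  list(d = s$d, u = s$u, v = s$v, zero_effect = FALSE)
}

#' Fit a task partial least squares model
#'
#' Decomposes the cross-product of the (column-centred) band-power matrix X
#' and the condition indicator matrix Y by singular value decomposition,
#' `E = t(X) Y = U S t(V)`: each latent variable (LV) pairs a spatial
#' salience pattern over electrode-by-band features (column of U) with a
#' task salience profile over conditions (column of V), with variance
#' explained `d_i^2 / sum(d^2)`. Inference is fully resampling-based:
#'
#' \itemize{
#'   \item permutation test: condition labels are shuffled within
#'     participant (respecting the repeated-measures design);
#'     `p_i = (1 + #\{perm d_i >= observed d_i\}) / (n_perm + 1)`;
#'   \item bootstrap: participants are resampled with replacement (all
#'     their condition rows together); each resample's LVs are sign-aligned
#'     to the observed saliences; bootstrap ratios (BSR) are the bootstrap
#'     mean loadings divided by their standard deviations;
#'   \item contrast saliences: for every condition pair, the bootstrap
#'     distribution of paired task-salience differences gives a mean, SD
#'     and BSR per contrast.
#' }
#'
#' @param features long feature data.frame (see [pls_assemble()]), or a
#'   ready `pls_design`.
#' @param conditions condition subset/order, or NULL for all.
#' @param n_perm number of permutation resamples (0 skips the test).
#' @param n_boot number of bootstrap resamples (0 skips).
#' @param seed integer seed for both resampling engines.
#' @param subtest mark the fit as a two-condition subtest, suppressing
#'   LV p-values and variance explained in reports (these are fixed by the
#'   algorithm when only two conditions enter).
#' @return An object of class `task_pls`; see [summary.task_pls()],
#'   [threshold_map()], [coef.task_pls()].
#' @export
task_pls <- function(features, conditions = NULL, n_perm = 1000,
                     n_boot = 1000, seed = NULL, subtest = NULL) {
  design <- if (inherits(features, "pls_design")) features
  else pls_assemble(features, conditions)
  X <- design$X
  Y <- design$Y
  k <- ncol(Y)
  if (is.null(subtest)) subtest <- k == 2
  core <- pls_core(X, Y)
  if (core$zero_effect)
    warning("degenerate all-zero effect matrix; zero-effect result returned")
  varexp <- if (sum(core$d^2) > 0) core$d^2 / sum(core$d^2) else rep(0, k)

  pt_rows <- split(seq_len(nrow(X)), design$row_participant)
  n_pt <- length(pt_rows)

  perm_p <- NULL
  if (n_perm > 0) {
    perm_p <- with_seed(if (is.null(seed)) NULL else child_seed(seed, 1L), {
      count <- rep(0, k)
      for (b in seq_len(n_perm)) {
        Yp <- Y
        for (rows in pt_rows) Yp[rows, ] <- Y[sample(rows), ]
        dp <- svd(crossprod(X, Yp), nu = 0, nv = 0)$d
        # relative tolerance so numerically-zero LVs count as ties
        count <- count + (dp >= core$d - 1e-9 * max(core$d))
      }
      (1 + count) / (n_perm + 1)
    })
  }

  boot <- NULL
  contrasts <- NULL
  if (n_boot > 0) {
    bs <- with_seed(if (is.null(seed)) NULL else child_seed(seed, 2L), {
      u_sum <- u_sq <- matrix(0, nrow(core$u), k)
      v_samples <- array(0, c(n_boot, k, k))  # resample x condition x LV
      for (b in seq_len(n_boot)) {
        idx <- unlist(pt_rows[sample.int(n_pt, n_pt, replace = TRUE)],
                      use.names = FALSE)
        Xb <- X[idx, , drop = FALSE]
        Xb <- sweep(Xb, 2, colMeans(Xb))
        s <- svd(crossprod(Xb, Y[idx, , drop = FALSE]))
        # sign-align each LV to the observed saliences
        for (j in seq_len(k)) {
          sgn <- sign(sum(s$u[, j] * core$u[, j]))
          if (sgn == 0) sgn <- 1
          s$u[, j] <- sgn * s$u[, j]
          s$v[, j] <- sgn * s$v[, j]
        }
        u_sum <- u_sum + s$u[, seq_len(k), drop = FALSE]
        u_sq <- u_sq + s$u[, seq_len(k), drop = FALSE]^2
        v_samples[b, , ] <- s$v
      }
      u_mean <- u_sum / n_boot
      u_sd <- sqrt(pmax(0, u_sq / n_boot - u_mean^2) * n_boot / (n_boot - 1))
      list(u_mean = u_mean, u_sd = u_sd, v_samples = v_samples)
    })
    bsr_u <- bs$u_mean / bs$u_sd
    bsr_u[bs$u_sd == 0] <- sign(bs$u_mean[bs$u_sd == 0]) * Inf
    v_mean <- apply(bs$v_samples, c(2, 3), mean)
    v_sd <- apply(bs$v_samples, c(2, 3), stats::sd)
    boot <- list(u_mean = bs$u_mean, u_sd = bs$u_sd, bsr_u = bsr_u,
                 v_mean = v_mean, v_sd = v_sd, bsr_v = v_mean / v_sd,
                 n_boot = n_boot)
    # contrast saliences: paired bootstrap differences of task saliences,
    # LV1, all condition pairs
    pairs <- utils::combn(seq_len(k), 2)
    contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; bq <- pairs[2, j]
      dsamp <- bs$v_samples[, a, 1] - bs$v_samples[, bq, 1]
      data.frame(contrast = paste(design$conditions[a], "vs",
                                  design$conditions[bq]),
                 mean = mean(dsamp), sd = stats::sd(dsamp),
                 bsr = mean(dsamp) / stats::sd(dsamp),
                 stringsAsFactors = FALSE)
    }))
  }

  structure(list(d = core$d, u = core$u, v = core$v,
                 variance_explained = varexp, perm_p = perm_p,
                 boot = boot, contrasts = contrasts,
                 design = design, n_perm = n_perm, n_boot = n_boot,
                 subtest = subtest, seed = seed,
                 zero_effect = core$zero_effect),
            class = "task_pls")
}

#' Run a two-condition task-PLS subtest
#'
#' Fits task PLS on a named condition pair (e.g. link_b vs link_a) or on
#' the combined period comparison `"link_vs_nonlink"` where the band power
#' of the two parts is first summed elementwise (link_a + link_b vs
#' nonlink_a + nonlink_b). LV p-values and variance explained are
#' suppressed in reports, as they are fixed by the algorithm in a
#' two-condition analysis.
#'
#' @param features long feature data.frame with the four omnibus
#'   conditions.
#' @param pair character vector of two condition names, or
#'   `"link_vs_nonlink"`.
#' @param ... passed to [task_pls()].
#' @return A `task_pls` fit with `subtest = TRUE`.
#' @export
run_subtest <- function(features, pair, ...) {
  four <- c("link_a", "link_b", "nonlink_a", "nonlink_b")
  if (identical(pair, "link_vs_nonlink")) {
    if (!all(four %in% features$condition))
      stop2("combined subtest needs all four omnibus conditions")
    combined <- combine_parts(features)
    return(task_pls(combined, conditions = c("nonlink_ab", "link_ab"),
                    subtest = TRUE, ...))
  }
  if (length(pair) != 2 || !all(pair %in% unique(features$condition)))
    stop2("unknown condition pair: %s", paste(pair, collapse = ", "))
  task_pls(features[features$condition %in% pair, ],
           conditions = pair, subtest = TRUE, ...)
}

# sum band power across parts for the combined Link(A+B) vs Nonlink(A+B)
combine_parts <- function(features) {
  out <- list()
  for (period in c("link", "nonlink")) {
    a <- features[features$condition == paste0(period, "_a"), ]
    b <- features[features$condition == paste0(period, "_b"), ]
    key <- function(d) paste(d$participant, d$electrode, d$band)
    b <- b[match(key(a), key(b)), ]
    a$power_db <- a$power_db + b$power_db
    a$condition <- paste0(period, "_ab")
    out[[period]] <- a
  }
  do.call(rbind, out)
}

#' FDR- and stability-thresholded electrode map
#'
#' Converts the spatial-salience bootstrap ratios of one LV to two-tailed
#' p-values via the standard normal tail, applies Benjamini-Hochberg FDR
#' across all electrode x band saliences of that LV, and zeroes entries
#' that are non-significant at `q` or unstable (`|BSR| <= bsr_min`).
#'
#' @param fit a `task_pls` fit with bootstrap results.
#' @param lv latent variable index.
#' @param q FDR level.
#' @param bsr_min stability threshold on `|BSR|`.
#' @return band x electrode matrix of surviving BSRs (zero elsewhere).
#' @export
threshold_map <- function(fit, lv = 1, q = 0.05, bsr_min = 2) {
  stopifnot(inherits(fit, "task_pls"))
  if (is.null(fit$boot)) stop2("fit has no bootstrap results")
  bsr <- fit$boot$bsr_u[, lv]
  finite <- is.finite(bsr)
  p <- rep(NA_real_, length(bsr))
  p[finite] <- 2 * stats::pnorm(-abs(bsr[finite]))
  p_adj <- rep(NA_real_, length(bsr))
  p_adj[finite] <- stats::p.adjust(p[finite], method = "BH")
  keep <- finite & p_adj <= q & abs(bsr) > bsr_min
  vals <- ifelse(keep, bsr, 0)
  des <- fit$design
  m <- matrix(vals, nrow = length(des$bands),
              dimnames = list(des$bands, des$electrodes))
  m
}

#' @export
print.task_pls <- function(x, ...) {
  k <- length(x$d)
  cat(sprintf("task PLS: %d conditions x %d participants, %d features\n",
              k, length(x$design$participants),
              length(x$design$feature_names)))
  if (x$subtest) {
    cat("two-condition subtest (LV p-value and variance explained not meaningful)\n")
  } else {
    for (i in seq_len(k)) {
      cat(sprintf("  LV%d: singular value %.3f, %.1f%% variance%s\n", i,
                  x$d[i], 100 * x$variance_explained[i],
                  if (!is.null(x$perm_p))
                    sprintf(", permutation p = %.4g", x$perm_p[i]) else ""))
    }
  }
  invisible(x)
}

#' Summarize a task-PLS fit
#'
#' @param object a `task_pls`.
#' @param lv latent variable to detail.
#' @param ... unused.
#' @return The fit, invisibly; prints LV statistics, condition loadings
#'   with bootstrap SDs, contrast saliences, and the count of stable
#'   electrode x band saliences.
#' @export
summary.task_pls <- function(object, lv = 1, ...) {
  print(object)
  if (!is.null(object$boot)) {
    cat(sprintf("\ncondition loadings (LV%d, bootstrap mean +/- SD):\n", lv))
    for (i in seq_along(object$design$conditions))
      cat(sprintf("  %-12s %8.3f +/- %.3f\n", object$design$conditions[i],
                  object$boot$v_mean[i, lv], object$boot$v_sd[i, lv]))
    if (!is.null(object$contrasts) && !object$subtest) {
      cat("\ncontrast saliences (LV1):\n")
      for (i in seq_len(nrow(object$contrasts)))
        cat(sprintf("  %-28s mean %8.3f, BSR %6.2f\n",
                    object$contrasts$contrast[i], object$contrasts$mean[i],
                    object$contrasts$bsr[i]))
    }
    mp <- threshold_map(object, lv = lv)
    cat(sprintf("\nthresholded map (LV%d): %d of %d saliences survive FDR q=0.05 and |BSR|>2\n",
                lv, sum(mp != 0), length(mp)))
  }
  invisible(object)
}

#' @export
coef.task_pls <- function(object, type = c("task", "spatial"), lv = NULL, ...) {
  type <- match.arg(type)
  k <- length(object$d)
  lv <- lv %||% seq_len(k)
  if (type == "task") {
    out <- object$v[, lv, drop = FALSE]
    rownames(out) <- object$design$conditions
  } else {
    out <- object$u[, lv, drop = FALSE]
    rownames(out) <- object$design$feature_names
  }
  colnames(out) <- paste0("LV", lv)
  out
}

#' Plot the thresholded BSR map of a task-PLS fit
#'
#' Tabular band x electrode image of the FDR- and stability-thresholded
#' bootstrap ratios (no scalp interpolation).
#'
#' @param x a `task_pls` fit.
#' @param lv latent variable index.
#' @param ... passed to [threshold_map()].
#' @return The map matrix, invisibly.
#' @export
plot.task_pls <- function(x, lv = 1, ...) {
  m <- threshold_map(x, lv = lv, ...)
  lim <- max(abs(m), 2)
  cols <- grDevices::hcl.colors(65, "Blue-Red 3")
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  zlim = c(-lim, lim), col = cols, axes = FALSE,
                  xlab = "electrode", ylab = "band",
                  main = sprintf("thresholded BSR map (LV%d)", lv))
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.6)
  graphics::axis(2, seq_len(nrow(m)), rownames(m), las = 1)
  graphics::box()
  invisible(m)
}
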