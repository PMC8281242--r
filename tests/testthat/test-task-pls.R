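test_that("the omnibus design matrix is 64 x 150 with one-hot conditions", {
  ft <- synth_features()
  des <- pls_assemble(ft)
  expect_equal(dim(des$X), c(64, 150))
  expect_equal(dim(des$Y), c(64, 4))
  expect_true(all(rowSums(des$Y) == 1))
  expect_equal(des$conditions, c("nonlink_a", "nonlink_b", "link_a", "link_b"))
  # rows grouped by condition with participants nested identically
  expect_equal(des$row_condition, rep(des$conditions, each = 16))
  expect_equal(des$row_participant, rep(sprintf("p%02d", 1:16), times = 4))
  expect_equal(unname(colMeans(des$X)), rep(0, 150), tolerance = 1e-12)

  des2 <- pls_assemble(ft[ft$condition %in% c("link_a", "link_b"), ])
  expect_equal(nrow(des2$X), 32)

  expect_error(pls_assemble(ft[-1, ]), "missing cell|incomplete")
})

test_that("singular values match a brute-force eigendecomposition oracle on toy designs", {
  for (s in 1:5) {
    ft <- synth_features(n_participants = 4, electrodes = paste0("E", 1:3),
                         bands = c("b1", "b2"), seed = 300 + s)
    fit <- task_pls(ft, n_perm = 0, n_boot = 0, subtest = FALSE)
    # oracle: cross-product assembled by explicit loops from the long table,
    # decomposed by a dense SVD
    conds <- c("nonlink_a", "nonlink_b", "link_a", "link_b")
    pts <- sort(unique(ft$participant))
    els <- unique(ft$electrode); bds <- unique(ft$band)
    X <- matrix(0, length(pts) * 4, length(els) * 2)
    Y <- matrix(0, length(pts) * 4, 4)
    r <- 0
    for (ci in seq_along(conds)) for (pi in seq_along(pts)) {
      r <- r + 1
      Y[r, ci] <- 1
      cidx <- 0
      for (el in els) for (bd in bds) {
        cidx <- cidx + 1
        X[r, cidx] <- ft$power_db[ft$participant == pts[pi] &
                                    ft$condition == conds[ci] &
                                    ft$electrode == el & ft$band == bd]
      }
    }
    Xc <- sweep(X, 2, colMeans(X))
    E <- matrix(0, ncol(X), 4)
    for (i in seq_len(ncol(X))) for (j in 1:4)
      E[i, j] <- sum(Xc[, i] * Y[, j])
    expect_lt(max(abs(fit$d - svd(E)$d)), 1e-10)
    expect_equal(sum(fit$variance_explained), 1)
  }
})

test_that("identical condition means give a zero effect and a rank-1 effect is recovered", {
  ft <- synth_features(noise_sd = 0, participant_sd = 1, seed = 2)
  expect_warning(fit0 <- task_pls(ft, n_perm = 0, n_boot = 0, subtest = FALSE),
                 "zero-effect")
  expect_equal(max(fit0$d), 0)

  # construct a rank-1 condition structure: mu[c, j] = tau[c] * w[j]
  ft1 <- synth_features(noise_sd = 0, participant_sd = 0, seed = 3)
  des <- pls_assemble(ft1, center = FALSE)
  tau <- c(-3, -1, 1, 3)
  w <- rnorm(150); w <- w / sqrt(sum(w^2))
  X <- (des$Y %*% tau) %*% t(w)
  ft1$power_db <- NA
  # rebuild the long table from X
  for (r in seq_len(nrow(X))) {
    sel <- ft1$participant == des$row_participant[r] &
      ft1$condition == des$row_condition[r]
    key <- paste(ft1$electrode[sel], ft1$band[sel], sep = ".")
    ft1$power_db[sel] <- X[r, match(key, des$feature_names)]
  }
  fit1 <- task_pls(ft1, n_perm = 0, n_boot = 0, subtest = FALSE)
  expect_gt(fit1$d[1], 0)
  expect_lt(fit1$d[2] / fit1$d[1], 1e-10)
  expect_equal(abs(sum(fit1$u[, 1] * w)), 1, tolerance = 1e-10)
})

test_that("permutation p-values respect their floor and detect strong effects", {
  inj <- paste0("E", sprintf("%02d", 1:10))
  ft <- synth_features(effect_db = -3, effect_electrodes = inj,
                       effect_bands = c("delta", "theta"),
                       effect_conditions = c("link_a", "link_b"),
                       noise_sd = 0.5, seed = 7)
  fit <- task_pls(ft, n_perm = 200, n_boot = 0, seed = 1, subtest = FALSE)
  expect_gte(min(fit$perm_p), 1 / 201)
  expect_lte(fit$perm_p[1], 0.005)
  expect_gt(fit$variance_explained[1], 0.5)
})

test_that("permuting feature columns permutes spatial saliences and keeps singular values", {
  ft <- synth_features(n_participants = 6, electrodes = paste0("E", 1:4),
                       bands = c("b1", "b2"), effect_db = 2,
                       effect_electrodes = "E2", effect_bands = "b1",
                       effect_conditions = c("link_a", "link_b"), seed = 9)
  des <- pls_assemble(ft)
  fit <- task_pls(des, n_perm = 0, n_boot = 0, subtest = FALSE)
  perm <- sample(ncol(des$X))
  des2 <- des
  des2$X <- des$X[, perm]
  des2$feature_names <- des$feature_names[perm]
  fit2 <- task_pls(des2, n_perm = 0, n_boot = 0, subtest = FALSE)
  expect_equal(fit2$d, fit$d, tolerance = 1e-12)
  # the dominant LV's spatial salience is permuted identically (up to sign;
  # higher LVs of this noisy design have near-equal singular values and may
  # rotate freely)
  sgn <- sign(sum(fit2$u[, 1] * fit$u[perm, 1]))
  expect_equal(sgn * fit2$u[, 1], fit$u[perm, 1], tolerance = 1e-9)
})

test_that("bootstrap ratios are sign-symmetric and flag injected electrodes", {
  inj <- paste0("E", sprintf("%02d", 1:10))
  ft <- synth_features(effect_db = -3, effect_electrodes = inj,
                       effect_bands = c("delta", "theta"),
                       effect_conditions = c("link_a", "link_b"),
                       noise_sd = 0.5, seed = 12)
  fit <- task_pls(ft, n_perm = 0, n_boot = 300, seed = 2, subtest = FALSE)
  flipped <- ft; flipped$power_db <- -flipped$power_db
  fitf <- task_pls(flipped, n_perm = 0, n_boot = 300, seed = 2, subtest = FALSE)
  expect_equal(abs(fitf$boot$bsr_u), abs(fit$boot$bsr_u), tolerance = 1e-6)

  m <- threshold_map(fit)
  inj_cells <- m[c("delta", "theta"), inj]
  det <- colSums(inj_cells != 0) > 0
  expect_gte(sum(det), 8)
  signs <- sign(inj_cells[inj_cells != 0])
  expect_equal(length(unique(signs)), 1)   # consistent sign across electrodes
})

test_that("contrast saliences order period effects above part effects", {
  # injected ordering nonlink_a < nonlink_b < link_a < link_b
  ft <- synth_features(noise_sd = 0.4, seed = 15)
  bump <- c(nonlink_a = 0, nonlink_b = 1, link_a = 3, link_b = 4)
  ft$power_db <- ft$power_db + bump[ft$condition]
  fit <- task_pls(ft, n_perm = 0, n_boot = 300, seed = 3, subtest = FALSE)
  ct <- fit$contrasts
  getm <- function(a, b) abs(ct$mean[ct$contrast == paste(a, "vs", b)])
  expect_gt(getm("nonlink_a", "link_a"), getm("nonlink_a", "nonlink_b"))
  expect_gt(getm("nonlink_b", "link_b"), getm("link_a", "link_b"))
  expect_equal(nrow(ct), 6)
})

test_that("thresholded maps zero unstable or non-significant saliences", {
  ft <- synth_features(seed = 20)
  fit <- task_pls(ft, n_perm = 0, n_boot = 200, seed = 4, subtest = FALSE)
  # force a known BSR pattern: one stable entry, one below the stability cut
  fit$boot$bsr_u[, 1] <- 0
  fit$boot$bsr_u[1, 1] <- 6
  fit$boot$bsr_u[2, 1] <- 1.9
  m <- threshold_map(fit)
  expect_equal(sum(m != 0), 1)
  expect_equal(m[[1]], 6)
  # generic: every surviving entry satisfies both criteria
  fit2 <- task_pls(synth_features(effect_db = -3,
                                  effect_electrodes = paste0("E", sprintf("%02d", 1:10)),
                                  effect_bands = "delta",
                                  effect_conditions = c("link_a", "link_b"),
                                  seed = 21),
                   n_perm = 0, n_boot = 200, seed = 5, subtest = FALSE)
  m2 <- threshold_map(fit2)
  nz <- which(m2 != 0)
  expect_true(all(abs(m2[nz]) > 2))
})

test_that("subtests combine parts elementwise and suppress omnibus statistics", {
  ft <- synth_features(seed = 30)
  comb <- tmteeg:::combine_parts(ft)
  la <- ft[ft$condition == "link_a", ]
  key <- paste(la$participant, la$electrode, la$band)
  lb <- ft[ft$condition == "link_b", ]
  lb <- lb[match(key, paste(lb$participant, lb$electrode, lb$band)), ]
  lab <- comb[comb$condition == "link_ab", ]
  lab <- lab[match(key, paste(lab$participant, lab$electrode, lab$band)), ]
  expect_equal(lab$power_db, la$power_db + lb$power_db)

  fit <- run_subtest(ft, "link_vs_nonlink", n_perm = 0, n_boot = 50, seed = 6)
  expect_true(fit$subtest)
  expect_equal(nrow(fit$design$X), 32)
  expect_output(print(fit), "not meaningful")
  expect_error(run_subtest(ft, c("link_a", "banana")), "unknown condition")

  # near-identical conditions yield an empty thresholded map
  ft0 <- synth_features(seed = 31, participant_sd = 0)
  fit0 <- run_subtest(ft0, c("link_a", "link_b"), n_perm = 0, n_boot = 100,
                      seed = 7)
  expect_lte(sum(threshold_map(fit0) != 0) / 150, 0.05)
})

test_that("fits are reproducible for a fixed seed and expose S3 methods", {
  ft <- synth_features(n_participants = 6, electrodes = paste0("E", 1:4),
                       bands = c("b1", "b2"), seed = 40)
  f1 <- task_pls(ft, n_perm = 50, n_boot = 50, seed = 11, subtest = FALSE)
  f2 <- task_pls(ft, n_perm = 50, n_boot = 50, seed = 11, subtest = FALSE)
  expect_equal(f1$perm_p, f2$perm_p)
  expect_equal(f1$boot$bsr_u, f2$boot$bsr_u)
  expect_output(print(f1), "LV1")
  expect_output(summary(f1), "condition loadings")
  co <- coef(f1)
  expect_equal(rownames(co), f1$design$conditions)
  cs <- coef(f1, type = "spatial")
  expect_equal(nrow(cs), 8)
  pdf(NULL)
  on.exit(dev.off())
  m <- plot(f1)
  expect_true(is.matrix(m))
})
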