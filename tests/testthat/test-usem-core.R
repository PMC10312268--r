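test_that("lag augmentation counts pairs and respects boundaries", {
  ser <- sim_white(239, 3, seed = 1)
  d1 <- lag_augment(ser)
  expect_equal(d1$n_eff, 238L)

  ## two concatenated subjects: no pair spans the boundary
  ser2 <- sim_white(239, 3, seed = 2)
  d2 <- lag_augment(list(ser, ser2))
  expect_equal(d2$n_eff, 2L * 238L)

  ## explicit segment lengths; a length-1 segment contributes nothing
  d3 <- lag_augment(ser, boundaries = c(100L, 1L, 138L))
  expect_equal(d3$n_eff, 99L + 0L + 137L)
  expect_error(lag_augment(ser, boundaries = c(10L, 10L)), "sum to T")

  ## all segments too short
  expect_error(lag_augment(ser, boundaries = rep(1L, 239)),
               "no usable lag pairs")
})

test_that("the ML fit recovers a planted path within 3 SE", {
  A <- matrix(0, 3, 3); A[2, 1] <- 0.6
  ser <- sim_var(A, diag(0.5, 3), T = 2000, seed = 7)
  dat <- lag_augment(ser)
  free <- rbind_paths(ar_paths(paste0("n", 1:3)),
                      path_set("n1", "n2", 0L, "group"))
  m <- fit_usem(dat, free)
  expect_true(m$converged)
  row <- which(m$free_paths$level == "group")
  expect_lt(abs(m$free_paths$estimate[row] - 0.6),
            3 * m$free_paths$se[row])
  ## AR paths near 0.5 too
  ar_est <- m$free_paths$estimate[m$free_paths$level == "null_base"]
  expect_equal(unname(ar_est), rep(0.5, 3), tolerance = 0.1)
})

test_that("a saturated free set reproduces the data exactly", {
  ser <- sim_white(300, 4, seed = 3)
  dat <- lag_augment(ser)
  nodes <- paste0("n", 1:4)
  sat <- empty_path_set()
  for (i in 1:4) for (j in 1:4) {
    sat <- rbind_paths(sat, path_set(nodes[j], nodes[i], 1L,
                                     "individual"))
    if (j < i)
      sat <- rbind_paths(sat, path_set(nodes[j], nodes[i], 0L,
                                       "individual"))
  }
  m <- fit_usem(dat, sat, usem_options(se = "none"))
  expect_equal(m$fit$df, 0)
  expect_lt(m$fit$chi2, 1e-6)
  expect_equal(m$fit$CFI, 1)
  expect_equal(m$fit$RMSEA, 0)
  expect_lt(m$fit$SRMR, 1e-8)
})

test_that("the empty model estimates residual variances as sample variances", {
  ser <- sim_white(400, 3, seed = 4)
  dat <- lag_augment(ser)
  m <- fit_usem(dat, empty_path_set(), usem_options(se = "none"))
  expect_equal(unname(m$params$Psi),
               unname(diag(dat$S)[dat$pos$x]), tolerance = 1e-6)
})

test_that("free-parameter structure constraints are enforced", {
  ser <- sim_white(100, 3, seed = 5)
  dat <- lag_augment(ser)
  expect_error(fit_usem(dat, data.frame(from = "n1", to = "n1", lag = 0L,
                                        level = "individual")),
               "self-loops")
  expect_error(fit_usem(dat, path_set("n1", "n2", 0L, "individual")[
    rep(1, 2), ]), "duplicate")
})

test_that("modification indices match likelihood-ratio refits", {
  ser <- sim_var(matrix(0, 3, 3), diag(0.5, 3), T = 800, seed = 6)
  dat <- lag_augment(ser)
  free <- ar_paths(paste0("n", 1:3))
  m <- fit_usem(dat, free, usem_options(se = "none"))
  mi <- modification_indices(m)
  expect_true(all(mi$mi >= 0, na.rm = TRUE))
  for (k in 1:4) {
    f2 <- rbind_paths(free, path_set(mi$from[k], mi$to[k], mi$lag[k],
                                     "individual"))
    lr <- m$fit$chi2 - fit_usem(dat, f2, usem_options(se = "none"))$fit$chi2
    expect_equal(mi$mi[k], lr, tolerance = max(0.1 * lr, 0.1))
  }
  ## already-free paths never appear as candidates
  expect_false(any(path_key(mi) %in% path_key(free)))
})

test_that("null-data modification indices are chi-square(1) calibrated", {
  ## Monte-Carlo oracle: on white noise with the AR base model, every
  ## candidate MI is an asymptotic chi2(1) draw, so the mean is ~1
  mis <- unlist(lapply(1:25, function(s) {
    dat <- lag_augment(sim_var(matrix(0, 3, 3), diag(0.4, 3), T = 300,
                               seed = 100 + s))
    m <- fit_usem(dat, ar_paths(paste0("n", 1:3)),
                  usem_options(se = "none"))
    modification_indices(m)$mi
  }))
  expect_gt(length(mis), 200)
  expect_equal(mean(mis, na.rm = TRUE), 1, tolerance = 0.25)
})

test_that("fit indices match a hand-computed evaluation", {
  ser <- sim_white(250, 2, seed = 9)
  dat <- lag_augment(ser)
  m <- fit_usem(dat, empty_path_set(), usem_options(se = "none"))

  ## oracle: evaluate every index from the explicit matrices
  S <- dat$S; mm <- dat$m; N <- dat$n_eff - 1
  Sigma <- matrix(0, 4, 4)
  Sigma[1:2, 1:2] <- S[1:2, 1:2]
  diag(Sigma)[3:4] <- m$params$Psi
  F_ml <- log(det(Sigma)) + sum(diag(S %*% solve(Sigma))) -
    log(det(S)) - mm
  chi2 <- N * F_ml
  df <- mm * (mm + 1) / 2 - (2 * 3 / 2 + 2)
  F_b <- sum(log(diag(S))) - log(det(S))
  chi2_b <- N * F_b
  df_b <- mm * (mm + 1) / 2 - mm
  cfi <- 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)
  nnfi <- (chi2_b / df_b - chi2 / df) / (chi2_b / df_b - 1)
  rmsea <- sqrt(max(chi2 - df, 0) / (df * N))
  sdv <- sqrt(diag(S))
  resid <- (S - Sigma) / outer(sdv, sdv)
  srmr <- sqrt(mean(resid[lower.tri(resid, diag = TRUE)]^2))

  expect_equal(m$fit$chi2, chi2, tolerance = 1e-6)
  expect_equal(m$fit$df, df)
  expect_equal(m$fit$CFI, min(max(cfi, 0), 1), tolerance = 1e-6)
  expect_equal(m$fit$NNFI, nnfi, tolerance = 1e-6)
  expect_equal(m$fit$RMSEA, rmsea, tolerance = 1e-6)
  expect_equal(m$fit$SRMR, srmr, tolerance = 1e-6)
})

test_that("a model compared against itself as baseline gives CFI 0", {
  ser <- sim_white(150, 2, seed = 10)
  dat <- lag_augment(ser)
  m <- fit_usem(dat, empty_path_set(), usem_options(se = "none"))
  fake_baseline <- m
  fake_baseline$fit$df <- m$fit$df + 5  # must exceed the model's df
  fit <- fit_indices(m, baseline_model = fake_baseline)
  expect_equal(fit$CFI, 0)
  expect_error(fit_indices(m, baseline_model = m), "baseline")
})

test_that("fit evaluation counts criteria with inclusive comparisons", {
  fit <- list(CFI = 0.92, NNFI = 0.91, RMSEA = 0.06, SRMR = 0.05)
  expect_equal(evaluate_fit(fit)$n_met, 4L)
  fit$CFI <- 0.89
  expect_equal(evaluate_fit(fit)$n_met, 3L)
  boundary <- list(CFI = 0.90, NNFI = 0.90, RMSEA = 0.08, SRMR = 0.08)
  expect_equal(evaluate_fit(boundary)$n_met, 4L)
  exc <- list(CFI = 0.95, NNFI = 0.95, RMSEA = 0.05, SRMR = 0.05)
  expect_equal(evaluate_fit(exc)$n_excellent, 4L)
})

test_that("pruning removes noise paths and keeps real ones", {
  A <- matrix(0, 3, 3); A[2, 1] <- 0.6
  ser <- sim_var(A, diag(0.5, 3), T = 800, seed = 11)
  dat <- lag_augment(ser)
  free <- rbind_paths(ar_paths(paste0("n", 1:3)),
                      path_set(c("n1", "n3"), c("n2", "n2"), c(0L, 0L),
                               "individual"))
  m <- fit_usem(dat, free)
  pruned <- prune(m)
  keys <- path_key(pruned$free_paths)
  expect_true("n1->n2@0" %in% keys)     # true path kept
  expect_false("n3->n2@0" %in% keys)    # noise path pruned
  ## base paths are never pruned
  expect_equal(sum(pruned$free_paths$level == "null_base"), 3L)

  ## all-significant and empty non-base sets are no-ops
  expect_equal(NROW(prune(pruned)$free_paths), NROW(pruned$free_paths))
})

test_that("the likelihood never decreases along a freeing trajectory", {
  ser <- sim_var(matrix(c(0, 0.5, 0, 0, 0, 0.4, 0, 0, 0), 3, 3,
                        byrow = TRUE) * 0, diag(0.5, 3), T = 400,
                 seed = 12)
  dat <- lag_augment(ser)
  free <- ar_paths(paste0("n", 1:3))
  m <- fit_usem(dat, free, usem_options(se = "none"))
  f_prev <- m$fit$F_ml
  mi <- modification_indices(m)
  for (k in 1:5) {
    free <- rbind_paths(free, path_set(mi$from[k], mi$to[k], mi$lag[k],
                                       "individual"))
    m2 <- fit_usem(dat, free, usem_options(se = "none"))
    expect_lte(m2$fit$F_ml, f_prev + 1e-8)
    f_prev <- m2$fit$F_ml
  }
})
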