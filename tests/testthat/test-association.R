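test_that("feature matrices encode group betas and prevalent presence", {
  scen <- tiny_scenario(n = 10L, p = 5L, T = 250L, group = 2L,
                        pool = 2L, individual_prob = 0.6,
                        coef_range = c(0.5, 0.7), seed = 41L)
  cohort <- simulate_cohort(scen)
  gs <- suppressWarnings(group_search(cohort$series))
  fin <- finalize_individuals(cohort$series, gs$group_paths)
  X <- build_features(fin, min_fraction = 0.2)
  meta <- attr(X, "meta")
  expect_equal(nrow(meta), ncol(X))
  ## group features are continuous betas, others are 0/1
  for (j in seq_len(ncol(X))) {
    if (meta$encoding[j] == "presence")
      expect_true(all(X[, j] %in% c(0, 1)))
  }
  expect_equal(sum(meta$level == "group"), NROW(gs$group_paths))
  ## min_fraction = 1 keeps only group-beta features
  Xg <- suppressWarnings(build_features(fin, min_fraction = 1))
  expect_true(all(attr(Xg, "meta")$level == "group"))
})

test_that("composites average available z-scores with fallback", {
  cdi <- c(10, 20, 30, NA)
  mfq <- c(5, 15, NA, 25)
  comp <- suppressWarnings(composite_z(list(cdi = cdi, mfq = mfq)))
  zc <- as.numeric(scale(cdi)); zm <- as.numeric(scale(mfq))
  expect_equal(comp[1], mean(c(zc[1], zm[1])))
  expect_equal(comp[3], zc[3])  # missing scale falls back to the other
  expect_equal(comp[4], zm[4])
  ## identical scales give the shared z-score
  same <- composite_z(list(a = cdi[1:3], b = cdi[1:3]))
  expect_equal(same, as.numeric(scale(cdi[1:3])))
  expect_warning(composite_z(list(a = c(1, NA), b = c(2, NA))),
                 "missing every scale")
  expect_error(composite_z(list(a = 1:3, b = 1:4)), "same subjects")
})

test_that("adaptive lasso finds an exact linear feature with R2 = 1", {
  withr::local_seed(42)
  X <- matrix(rnorm(200 * 10), 200, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- as.numeric(scale(X[, 3]))
  res <- suppressWarnings(adaptive_lasso(X, y, seed = 1))
  expect_true("f3" %in% res$selected$feature)
  expect_equal(res$r2, 1, tolerance = 1e-6)
})

test_that("adaptive lasso with unit weights matches plain lasso", {
  withr::local_seed(43)
  n <- 150; f <- 12
  X <- matrix(rnorm(n * f), n, f, dimnames = list(NULL, paste0("f", 1:f)))
  y <- X[, 1] * 0.5 + rnorm(n)
  ## gamma = 0 forces all penalty factors to 1
  res <- adaptive_lasso(X, y, gamma = 0, seed = 7)
  expect_true(all(res$penalty_factors == 1))
  Xs <- scale(X)
  withr::local_seed(7)
  foldid <- sample(rep_len(1:10, n))
  ref <- glmnet::cv.glmnet(Xs, y, alpha = 1, foldid = foldid,
                           standardize = FALSE)
  ours <- as.numeric(coef(res$cv_fit, s = res$lambda))[-1]
  theirs <- as.numeric(coef(ref, s = "lambda.min"))[-1]
  expect_equal(ours, theirs, tolerance = 1e-6)
})

test_that("selection is invariant to affine rescaling of a column", {
  withr::local_seed(44)
  n <- 150
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- 0.8 * X[, 2] + rnorm(n, sd = 0.5)
  r1 <- adaptive_lasso(X, y, seed = 3)
  X2 <- X; X2[, 2] <- X2[, 2] * 50 + 7
  r2 <- adaptive_lasso(X2, y, seed = 3)
  expect_identical(r1$selected$feature, r2$selected$feature)
})

test_that("degenerate inputs are handled as specified", {
  X <- matrix(rnorm(100 * 3), 100, 3, dimnames = list(NULL, c("a", "b",
                                                              "c")))
  expect_error(adaptive_lasso(X, rep(1, 100)), "zero variance")
  expect_error(adaptive_lasso(X[1:8, ], rnorm(8)), "more observations")
  ## constant feature dropped with a warning, not an error
  X[, 2] <- 1
  expect_warning(res <- adaptive_lasso(X, rnorm(100), seed = 2),
                 "constant")
  expect_false("b" %in% res$selected$feature)
})

test_that("pure-noise outcomes yield empty or tiny selections", {
  withr::local_seed(45)
  X <- matrix(rnorm(120 * 10), 120, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- rnorm(120)
  res <- adaptive_lasso(X, y, seed = 5)
  expect_lte(NROW(res$selected), 3L)
  expect_gte(res$r2, 0)
})

test_that("binary outcomes route through the logistic variant", {
  withr::local_seed(52)
  n <- 200
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rbinom(n, 1, plogis(2 * X[, 4]))
  res <- adaptive_lasso(X, y, family = "binomial", seed = 9)
  expect_true("f4" %in% res$selected$feature)
  expect_gte(res$r2, 0); expect_lte(res$r2, 1)  # McFadden pseudo-R2
  expect_lte(res$adj_r2, res$r2)
  ph <- posthoc_ols(X[, res$selected$feature, drop = FALSE], y,
                    family = "binomial")
  expect_lt(ph$per_feature$p[ph$per_feature$feature == "f4"], 1e-4)
})

test_that("post hoc regressions recover simple-regression truths", {
  withr::local_seed(46)
  n <- 120
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- x1  # exact
  ph <- suppressWarnings(posthoc_ols(cbind(a = x1, b = x2), y))
  expect_equal(ph$per_feature$estimate[1], 1, tolerance = 1e-8)
  expect_lt(ph$per_feature$p[1], 1e-10)
  expect_lt(abs(ph$per_feature$estimate[2]), 0.2)
  expect_equal(ph$r2, 1, tolerance = 1e-10)
  expect_error(posthoc_ols(matrix(nrow = 5, ncol = 0), rnorm(5)),
               "empty")
})

test_that("post hoc estimator coverage is near nominal", {
  ## 2 SE coverage over replications for beta = 0.5, sigma = 1, n = 100
  withr::local_seed(47)
  cover <- replicate(60, {
    x <- rnorm(100)
    y <- 0.5 * x + rnorm(100)
    ph <- posthoc_ols(cbind(f = x), y)
    abs(ph$per_feature$estimate - 0.5) < 2 * ph$per_feature$se
  })
  expect_gte(mean(cover), 0.85)
})

test_that("subgroup ANOVAs detect shifts and gate pairwise tests", {
  withr::local_seed(48)
  mem <- rep(1:3, each = 30)
  null1 <- rnorm(90); null2 <- rnorm(90)
  shifted <- rnorm(90) + 3 * (mem == 2)  # one group 3 SD away
  res <- subgroup_anova(data.frame(null1, null2, shifted), mem)
  q <- res$omnibus$q[res$omnibus$outcome == "shifted"]
  expect_lt(q, 0.05)
  expect_gt(min(res$omnibus$q[res$omnibus$outcome != "shifted"]), 0.05)
  ## pairwise tests only for the significant outcome, right pair flagged
  expect_true(all(res$pairwise$outcome == "shifted"))
  sig_pairs <- res$pairwise[res$pairwise$p < 0.01, ]
  expect_setequal(unique(c(sig_pairs$group1, sig_pairs$group2)),
                  c("1", "2", "3"))
  expect_true(all(sig_pairs$group1 == "2" | sig_pairs$group2 == "2"))

  ## tiny groups are skipped with a warning
  expect_warning(subgroup_anova(data.frame(y = rnorm(5)),
                                c(1, 1, 1, 1, 2)), "skipping")
  expect_error(subgroup_anova(data.frame(y = rnorm(4)), rep(1, 4)),
               "at least 2 subgroups")
})

test_that("identical groups give null ANOVA results without pairwise tests", {
  withr::local_seed(49)
  mem <- rep(1:2, each = 25)
  res <- subgroup_anova(data.frame(a = rnorm(50), b = rnorm(50)), mem,
                        alpha = 0.05)
  expect_gt(min(res$omnibus$q), 0.05)
  expect_null(res$pairwise)
})
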