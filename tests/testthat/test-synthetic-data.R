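test_that("scenario construction is deterministic and respects structure", {
  s1 <- tiny_scenario(n = 6L, p = 5L, group = 3L, pool = 2L, seed = 42L,
                      individual_prob = 0.5)
  s2 <- tiny_scenario(n = 6L, p = 5L, group = 3L, pool = 2L, seed = 42L,
                      individual_prob = 0.5)
  expect_identical(s1$ledger, s2$ledger)
  expect_identical(s1$membership, s2$membership)

  ## no path targets an exogenous node; group set shared by everyone
  expect_true(all(s1$ledger$to %in% s1$node_names))
  for (id in s1$subject_ids)
    expect_setequal(truth_keys(s1, "group", id), truth_keys(s1, "group"))
})

test_that("default scenario matches the study dimensions", {
  scen <- make_scenario(list(max_retries = 2L))
  expect_equal(scen$config$n_subjects, 103L)
  expect_length(scen$node_names, 15L)
  expect_length(scen$exo_names, 2L)
  expect_equal(scen$config$n_timepoints, 239L)
  expect_equal(scen$config$tr_seconds, 2)
  expect_equal(nrow(scen$events), 48L)  # 24 anticipation + 24 outcome
})

test_that("empty structure leaves only AR self-paths", {
  scen <- tiny_scenario(p = 4L, group = 0L, pool = 0L)
  lev <- unique(scen$ledger$level)
  expect_identical(lev, "null_base")
  expect_true(all(scen$ledger$from == scen$ledger$to &
                    scen$ledger$lag == 1L))
})

test_that("unsatisfiable configs raise configuration errors", {
  expect_error(tiny_scenario(p = 3L, group = 100L), "slots")
  expect_error(make_scenario(list(n_endogenous = 1L)), "n_endogenous")
  expect_error(make_scenario(list(subgroup_fractions = c(0.5, 0.6),
                                  n_subgroup_paths = c(1L, 1L))),
               "sum to 1")
})

test_that("every realized subject system is stationary", {
  scen <- tiny_scenario(n = 8L, p = 5L, group = 3L, pool = 3L,
                        individual_prob = 0.6, seed = 9L)
  for (id in scen$subject_ids) {
    mats <- usemnet:::.subject_matrices(scen$ledger, id,
                                        scen$node_names, scen$exo_names)
    G <- solve(diag(5) - mats$A)
    expect_lt(usemnet:::spectral_radius(G %*% mats$Phi), 1)
  }
})

test_that("subgroup fractions translate into exact block sizes", {
  scen <- make_scenario(list(
    n_subjects = 10L, n_endogenous = 4L, n_exogenous = 0L,
    n_timepoints = 100L, n_group_paths = 1L,
    subgroup_fractions = c(0.5, 0.5), n_subgroup_paths = c(1L, 1L),
    n_individual_pool = 0L, n_trials = 0L, seed = 2L))
  expect_equal(unname(table(scen$membership)), c(5L, 5L),
               ignore_attr = TRUE)
})

test_that("inclusion probability 1 gives every subject every pool path", {
  scen <- tiny_scenario(n = 5L, p = 5L, group = 0L, pool = 3L,
                        individual_prob = 1)
  pool_keys <- unique(path_key(
    scen$ledger[scen$ledger$level == "individual", ]))
  expect_length(pool_keys, 3L)
  for (id in scen$subject_ids)
    expect_setequal(truth_keys(scen, "individual", id), pool_keys)
})

test_that("white-noise configuration produces uncorrelated series", {
  scen <- tiny_scenario(p = 4L, T = 4000L, group = 0L,
                        ar_range = c(0, 0), noise_sd = 1)
  X <- simulate_subject(scen, 1L)$values
  S <- cov(X)
  expect_lt(max(abs(S - diag(4))), 0.1)
})

test_that("a single AR(0.5) node shows the theoretical autocorrelation", {
  scen <- tiny_scenario(p = 2L, T = 5000L, group = 0L,
                        ar_range = c(0.5, 0.5))
  x <- simulate_subject(scen, 1L)$values[, 1L]
  r1 <- cor(x[-1L], x[-length(x)])
  expect_equal(r1, 0.5, tolerance = 0.05)
})

test_that("a planted contemporaneous path is recovered by OLS", {
  ## reduced-form oracle: regression of x_j on x_i at large T
  scen <- tiny_scenario(p = 3L, T = 4000L, group = 1L,
                        coef_range = c(0.6, 0.6),
                        positive_fraction = 1,
                        coef_subject_sd = 0, contemporaneous_fraction = 1)
  tr <- scen$ledger[scen$ledger$level == "group", ][1L, ]
  X <- simulate_subject(scen, 1L)$values
  ## the structural equation is x_to = 0.6 x_from + 0.5 x_to(lag) + e,
  ## so OLS with the lagged outcome as control is consistent
  Tn <- nrow(X)
  fit <- lm(X[-1, tr$to] ~ X[-1, tr$from] + X[-Tn, tr$to])
  expect_equal(unname(coef(fit)[2L]), 0.6, tolerance = 0.07)
})

test_that("cohort simulation is reproducible and ledger-complete", {
  scen <- tiny_scenario(n = 4L, p = 4L, group = 2L, pool = 2L,
                        individual_prob = 0.5, seed = 31L)
  c1 <- simulate_cohort(scen)
  c2 <- simulate_cohort(scen)
  expect_identical(c1$ledger, c2$ledger)
  expect_identical(c1$series[[3L]]$values, c2$series[[3L]]$values)
  ## ledger covers every subject with base + group rows at least
  for (id in scen$subject_ids) {
    rows <- c1$ledger[c1$ledger$subject_id == id, ]
    expect_gte(nrow(rows), 4L + 2L)
  }
})

test_that("task event schedule has the right shape and determinism", {
  ev <- simulate_task_events(n_trials = 24, trial_seconds = 17,
                             tr_seconds = 2, seed = 3L)
  expect_equal(sum(ev$trial_type == "anticipation"), 24L)
  expect_equal(sum(ev$trial_type == "outcome"), 24L)
  expect_identical(ev, simulate_task_events(n_trials = 24,
                                            trial_seconds = 17,
                                            tr_seconds = 2, seed = 3L))
  expect_equal(nrow(simulate_task_events(n_trials = 0)), 0L)
  expect_error(simulate_task_events(n_trials = 24, scan_seconds = 100),
               "configuration error")
})

test_that("behavioral outcomes follow the specified linear model", {
  scen <- tiny_scenario(n = 500L, p = 4L, group = 1L, pool = 1L,
                        individual_prob = 0.5, seed = 8L)
  led <- scen$ledger
  ip <- unique(led[led$level == "individual", c("from", "to", "lag")])
  eff <- data.frame(ip[1L, ], encoding = "presence", beta = 0.5)

  ## OLS oracle on the true presence indicator recovers the effect
  spec <- behavior_spec("y", eff, noise_sd = 1,
                        standardize_features = FALSE)
  y <- simulate_behavior(spec, led, seed = 4L)
  pres <- as.numeric(names(y) %in%
                       led$subject_id[path_key(led) == path_key(eff)])
  expect_equal(unname(coef(lm(y ~ pres))[2L]), 0.5, tolerance = 0.15)

  ## zero effects leave the outcome uncorrelated with the feature
  eff0 <- eff; eff0$beta <- 0
  y0 <- simulate_behavior(behavior_spec("y0", eff0, noise_sd = 1), led,
                          seed = 5L)
  expect_lt(abs(cor(y0, pres)), 0.12)

  ## noiseless binary effect reproduces the indicator exactly
  y1 <- simulate_behavior(
    behavior_spec("y1", eff, noise_sd = 0,
                  standardize_features = FALSE), led, seed = 6L)
  expect_equal(unname(y1), 0.5 * pres)

  expect_error(simulate_behavior(
    behavior_spec("bad", data.frame(from = "nope", to = "roi01",
                                    lag = 0L, encoding = "presence",
                                    beta = 1)), led),
    "unknown feature")
})

test_that("written cohorts round-trip through the text interface", {
  scen <- tiny_scenario(n = 2L, p = 4L, T = 60L, group = 1L, seed = 13L)
  cohort <- simulate_cohort(scen)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir, events = scen$events)
  back <- read_timeseries(file.path(dir, "sub001.tsv"), tr_seconds = 2,
                          min_length_factor = 3)
  expect_equal(back$values, cohort$series[[1L]]$values,
               tolerance = 1e-12)
  led <- utils::read.csv(file.path(dir, "ledger.csv"))
  expect_setequal(unique(led$subject_id), c("sub001", "sub002"))
})
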