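## Shared fixtures built in code.

## A small single-subgroup scenario for fast simulation-based tests.
tiny_scenario <- function(n = 1L, p = 4L, T = 200L, group = 2L,
                          pool = 0L, seed = 1L, ...) {
  make_scenario(utils::modifyList(list(
    n_subjects = n, n_endogenous = p, n_exogenous = 0L,
    n_timepoints = T, n_group_paths = group,
    subgroup_fractions = 1, n_subgroup_paths = 0L,
    n_individual_pool = pool, n_trials = 0L,
    coef_range = c(0.4, 0.7), ar_range = c(0.5, 0.5),
    benchmark_structure = TRUE, seed = seed), list(...)))
}

## Simulate a single series from explicit coefficient matrices
## (x_t = (I - A)^{-1} (Phi x_{t-1} + eps)), bypassing the scenario
## machinery; used as an independent data source in oracle tests.
sim_var <- function(A, Phi, T, seed = 1L, burn = 50L, sd = 1) {
  p <- nrow(A)
  G <- solve(diag(p) - A)
  withr::local_seed(seed)
  X <- matrix(0, T + burn, p)
  for (t in 2:(T + burn))
    X[t, ] <- G %*% (Phi %*% X[t - 1, ] + rnorm(p, sd = sd))
  X <- X[-(1:burn), , drop = FALSE]
  colnames(X) <- paste0("n", seq_len(p))
  roi_timeseries(X, tr_seconds = 2)
}

## White-noise series (no dynamics at all).
sim_white <- function(T, p, seed = 1L) {
  withr::local_seed(seed)
  X <- matrix(rnorm(T * p), T, p)
  colnames(X) <- paste0("n", seq_len(p))
  roi_timeseries(X, tr_seconds = 2)
}

## True group path keys of a scenario.
truth_keys <- function(scen, level = "group",
                       id = scen$subject_ids[1L]) {
  path_key(scen$ledger[scen$ledger$level == level &
                         scen$ledger$subject_id == id, ])
}
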