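## Minimal hand-built group-search result for similarity tests.
fake_gs <- function(mi_sets, group_signs, cand_keys, group_keys) {
  n <- length(mi_sets)
  mi_tables <- lapply(mi_sets, function(sig) {
    ps <- key_to_path(cand_keys)
    data.frame(ps[, c("from", "to", "lag")],
               mi = ifelse(cand_keys %in% sig, 10, 0.5), epc = 0.1)
  })
  models <- lapply(group_signs, function(sgn) {
    ps <- key_to_path(group_keys, "group")
    est <- sgn * 0.5
    list(free_paths = data.frame(ps, estimate = est, se = 0.1,
                                 z = est / 0.1))
  })
  ids <- sprintf("s%02d", seq_len(n))
  names(models) <- names(mi_tables) <- ids
  list(models = models, mi_tables = mi_tables,
       group_paths = key_to_path(group_keys, "group"),
       options = usem_options())
}

test_that("similarity counts shared MI candidates and same-sign paths", {
  cand <- c("a->b@0", "b->c@0", "c->a@1", "a->c@0")
  grp <- c("d->e@0", "e->f@0")
  gs <- fake_gs(
    mi_sets = list(c("a->b@0", "b->c@0"), c("a->b@0", "b->c@0"),
                   c("c->a@1")),
    group_signs = list(c(1, 1), c(1, 1), c(-1, 1)),
    cand_keys = cand, group_keys = grp)
  S <- build_similarity(gs)
  ## s1-s2: 2 shared candidates + 2 same-sign group paths
  expect_equal(S["s01", "s02"], 4)
  ## s1-s3: disjoint MI sets, one group path sign flips
  expect_equal(S["s01", "s03"], 1)
  expect_true(isSymmetric(unclass(S)))
  expect_true(all(diag(S) == 0))
})

test_that("similarity errors when a subject's MI table is missing", {
  gs <- fake_gs(list("a->b@0", "a->b@0"), list(1, 1), "a->b@0", "d->e@0")
  gs$mi_tables[[2L]] <- NULL
  gs$mi_tables["s02"] <- list(NULL)
  expect_error(build_similarity(gs), "s02")
})

test_that("walktrap separates disconnected blocks exactly", {
  S <- matrix(0, 8, 8)
  S[1:4, 1:4] <- 3; S[5:8, 5:8] <- 3; diag(S) <- 0
  mem <- walktrap_communities(S)
  expect_equal(length(unique(mem)), 2L)
  expect_equal(length(unique(mem[1:4])), 1L)
  expect_equal(length(unique(mem[5:8])), 1L)

  ## permutation invariance up to relabeling
  perm <- c(5, 1, 7, 3, 8, 2, 6, 4)
  mem2 <- walktrap_communities(S[perm, perm])
  expect_equal(partition_ari(mem2, mem[perm]), 1)

  expect_warning(walktrap_communities(matrix(0, 3, 3)), "all-zero")
})

test_that("modularity matches closed forms and the brute-force formula", {
  ## two equal disconnected cliques -> Q = 0.5
  S <- matrix(0, 6, 6)
  S[1:3, 1:3] <- 1; S[4:6, 4:6] <- 1; diag(S) <- 0
  expect_equal(modularity_q(S, c(1, 1, 1, 2, 2, 2)), 0.5)
  ## a single all-inclusive community -> Q = 0
  expect_equal(modularity_q(S, rep(1, 6)), 0)

  ## brute-force double-sum oracle on a random weighted graph
  withr::local_seed(5)
  W <- matrix(0, 10, 10)
  W[upper.tri(W)] <- rpois(45, 2)
  W <- W + t(W)
  mem <- sample(1:3, 10, replace = TRUE)
  m2 <- sum(W)
  k <- rowSums(W)
  Q_oracle <- sum((W - outer(k, k) / m2) *
                    outer(mem, mem, "==")) / m2
  expect_equal(modularity_q(W, mem), Q_oracle, tolerance = 1e-12)
  expect_error(modularity_q(matrix(0, 3, 3), rep(1, 3)), "zero total")
})

test_that("edge perturbation preserves the weight multiset", {
  withr::local_seed(6)
  S <- matrix(0, 12, 12)
  S[upper.tri(S)] <- sample(c(0, 0, 1, 2, 3), 66, replace = TRUE)
  S <- S + t(S)
  expect_identical(perturb_edges(S, 0), S)
  for (fr in c(0.3, 1)) {
    P <- suppressWarnings(perturb_edges(S, fr, seed = 7))
    expect_true(isSymmetric(P))
    expect_equal(sort(P[upper.tri(P)]), sort(S[upper.tri(S)]))
  }
  ## full perturbation moves support with overwhelming probability
  P1 <- suppressWarnings(perturb_edges(S, 1, seed = 8))
  expect_false(identical(P1 > 0, S > 0))
  ## dense matrix falls back to weight swapping with a warning
  D <- matrix(1, 5, 5); diag(D) <- 0
  expect_warning(perturb_edges(D, 1, seed = 9), "vacant")
})

test_that("partition metrics match their closed forms and an oracle", {
  expect_equal(partition_vi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 0)
  expect_equal(partition_ari(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  ## fully crossed partitions of 4 items
  expect_equal(partition_vi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 2 * log(2))
  expect_lte(partition_ari(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)

  ## igraph's implementations as the independent oracle
  withr::local_seed(10)
  for (r in 1:10) {
    p1 <- sample(1:4, 50, replace = TRUE)
    p2 <- sample(1:3, 50, replace = TRUE)
    expect_equal(partition_vi(p1, p2),
                 igraph::compare(p1, p2, method = "vi"),
                 tolerance = 1e-12)
    expect_equal(partition_ari(p1, p2),
                 igraph::compare(p1, p2, method = "adjusted.rand"),
                 tolerance = 1e-12)
  }
  expect_error(partition_vi(integer(), integer()), "empty")
  expect_error(partition_vi(1:3, 1:4), "equal length")
})

test_that("null modularity distribution is seeded and discriminates", {
  S <- matrix(0, 16, 16)
  S[1:8, 1:8] <- 4; S[9:16, 9:16] <- 4; diag(S) <- 0
  n1 <- random_null_modularity(S, n_draws = 30, seed = 11)
  n2 <- random_null_modularity(S, n_draws = 30, seed = 11)
  expect_identical(n1$q, n2$q)
  ## strongly modular observed matrix beats its null
  mem <- walktrap_communities(S)
  expect_gt(modularity_q(S, mem), n1$q95)
  expect_error(random_null_modularity(S, n_draws = 5), "at least 20")
})

test_that("robustness report passes a noiseless block structure", {
  S <- matrix(0, 20, 20)
  S[1:10, 1:10] <- 5; S[11:20, 11:20] <- 5; diag(S) <- 0
  rob <- robustness_report(S, reps = 10, n_null = 20, seed = 12,
                           fractions = seq(0.1, 1, by = 0.1))
  expect_true(rob$criteria$stability_pass)
  expect_true(rob$criteria$modularity_pass)
  expect_gte(rob$stability_crossing, 0.2)
  ## VI rises with perturbation up to the curve's peak; beyond it the
  ## re-clustered solutions collapse toward a single community (VI ->
  ## log 2 for a 2-block original), so monotonicity is only expected on
  ## the rising region that the stability criterion uses
  peak <- which.max(rob$vi_curve)
  expect_gte(min(diff(rob$vi_curve[seq_len(peak)])), -0.25)
  expect_gt(mean(rob$vi_curve[4:7]), mean(rob$vi_curve[1:2]))
})

test_that("planted similarity subgroups are detected from fitted models", {
  scen <- make_scenario(list(
    n_subjects = 16L, n_endogenous = 5L, n_exogenous = 0L,
    n_timepoints = 250L, n_group_paths = 2L,
    subgroup_fractions = c(0.5, 0.5), n_subgroup_paths = c(2L, 2L),
    n_individual_pool = 0L, n_trials = 0L,
    coef_range = c(0.5, 0.7), ar_range = c(0.5, 0.5),
    benchmark_structure = TRUE, seed = 28L))
  cohort <- simulate_cohort(scen)
  gs <- suppressWarnings(group_search(cohort$series))
  S <- build_similarity(gs)
  ## members of the same true subgroup are more similar on average
  same <- outer(cohort$membership, cohort$membership, "==")
  diag(same) <- NA
  expect_gt(mean(S[same & !is.na(same)]),
            mean(S[!same & !is.na(same)]))
  mem <- walktrap_communities(S)
  expect_gte(partition_ari(mem, cohort$membership), 0.5)
})
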