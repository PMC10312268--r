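#' Subject-similarity matrix from group-stage fits
#'
#' `s_ij` counts (a) candidate paths whose modification indices are
#' significant for both subjects i and j and (b) group paths whose
#' estimates are significant with the same sign for both. The two terms
#' can be weighted independently.
#'
#' @param gs A [group_search()] result (per-subject models and MI tables
#'   fitted at the group stage).
#' @param mi_weight,beta_weight Term weights (default 1 each).
#' @param alpha Significance level for estimate z-tests (default 0.05).
#' @return An n x n symmetric integer-valued matrix of class
#'   `similarity_matrix` with zero diagonal; subject ids as dimnames.
#' @export
build_similarity <- function(gs, mi_weight = 1, beta_weight = 1,
                             alpha = 0.05) {
  ids <- names(gs$models)
  n <- length(ids)
  missing_mi <- ids[vapply(gs$mi_tables, is.null, logical(1))]
  if (length(missing_mi))
    stop("missing MI table for subject(s): ",
         paste(missing_mi, collapse = ", "))
  mi_crit <- gs$options$mi_crit
  zcrit <- stats::qnorm(1 - alpha / 2)

  ## subjects-in-rows matrix from a per-subject vector-valued function
  per_subject <- function(items, k, f) {
    if (!k) return(matrix(0, n, 0L))
    v <- vapply(items, f, numeric(k))
    if (is.matrix(v)) t(v) else matrix(v, ncol = 1L)
  }

  ## candidate significance indicator matrix (subjects x candidate keys)
  keys <- path_key(gs$mi_tables[[1L]])
  Msig <- per_subject(gs$mi_tables, length(keys), function(mt) {
    v <- as.numeric(is.finite(mt$mi) & mt$mi >= mi_crit)
    v[match(keys, path_key(mt))]
  })

  ## group-path signed significance (+1 / -1 / 0)
  gkeys <- path_key(gs$group_paths)
  Gsgn <- per_subject(gs$models, length(gkeys), function(m) {
    row <- match(gkeys, path_key(m$free_paths))
    z <- m$free_paths$z[row]
    out <- numeric(length(gkeys))
    sig <- !is.na(z) & abs(z) >= zcrit
    out[sig] <- sign(m$free_paths$estimate[row][sig])
    out
  })

  S <- mi_weight * tcrossprod(Msig * 1) +
    beta_weight * (tcrossprod((Gsgn == 1) * 1) +
                     tcrossprod((Gsgn == -1) * 1))
  diag(S) <- 0
  dimnames(S) <- list(ids, ids)
  class(S) <- c("similarity_matrix", class(S))
  S
}

#' Walktrap community detection on a similarity matrix
#'
#' Random-walk agglomerative communities on the weighted undirected graph
#' whose edge weights are the similarity counts; the merge sequence is
#' cut at maximal modularity.
#'
#' @param sim Symmetric non-negative similarity matrix.
#' @param steps Random-walk length (default 4).
#' @return Integer membership vector (labels contiguous from 1), named by
#'   subject id.
#' @export
walktrap_communities <- function(sim, steps = 4) {
  sim <- unclass(as.matrix(sim))
  if (all(sim == 0)) {
    warning("all-zero similarity matrix; returning a single community")
    return(stats::setNames(rep(1L, nrow(sim)),
                           rownames(sim) %||% seq_len(nrow(sim))))
  }
  g <- igraph::graph_from_adjacency_matrix(sim, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  wt <- igraph::cluster_walktrap(g, steps = steps, merges = TRUE,
                                 modularity = TRUE, membership = TRUE)
  mem <- as.integer(igraph::membership(wt))
  mem <- match(mem, unique(mem))  # contiguous labels
  stats::setNames(mem, rownames(sim) %||% seq_along(mem))
}

#' Weighted Newman modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (w_ij - k_i k_j / 2m) * delta(c_i, c_j)`.
#'
#' @param sim Symmetric non-negative weight matrix (diagonal ignored).
#' @param membership Community labels, one per row of `sim`.
#' @return Modularity Q.
#' @export
modularity_q <- function(sim, membership) {
  sim <- unclass(as.matrix(sim))
  if (length(membership) != nrow(sim))
    stop("membership length must equal matrix dimension")
  if (sum(sim) == 0) stop("modularity undefined for zero total weight")
  g <- igraph::graph_from_adjacency_matrix(sim, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::modularity(g, membership,
                     weights = igraph::E(g)$weight)
}

#' Randomly rewire a fraction of similarity edges
#'
#' Moves `round(fraction * E)` randomly chosen nonzero upper-triangle
#' entries to uniformly chosen vacant pairs, preserving the multiset of
#' weights; when too few vacant pairs exist the remainder is handled by
#' swapping weights between edges.
#'
#' @param sim Symmetric non-negative matrix.
#' @param fraction Fraction of edges to perturb, in \[0, 1\].
#' @param seed Integer seed.
#' @return Perturbed symmetric matrix with identical weight multiset.
#' @export
perturb_edges <- function(sim, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  sim <- unclass(as.matrix(sim))
  n <- nrow(sim)
  up <- which(upper.tri(sim), arr.ind = TRUE)
  wts <- sim[upper.tri(sim)]
  edges <- which(wts > 0)
  k <- round(fraction * length(edges))
  if (!k) return(sim)
  withr::local_seed(seed)
  move <- edges[sample.int(length(edges), k)]
  vacant <- which(wts == 0)
  out <- wts
  n_move <- min(k, length(vacant))
  if (n_move < k)
    warning("insufficient vacant pairs; swapping weights for the rest")
  if (n_move) {
    dest <- vacant[sample.int(length(vacant), n_move)]
    out[dest] <- wts[move[seq_len(n_move)]]
    out[move[seq_len(n_move)]] <- 0
  }
  if (n_move < k) {
    rest <- move[(n_move + 1L):k]
    out[rest] <- out[sample(rest)]
  }
  res <- matrix(0, n, n, dimnames = dimnames(sim))
  res[upper.tri(res)] <- out
  res <- res + t(res)
  res
}

#' Null modularity distribution from weighted random matrices
#'
#' Each draw places the observed weight multiset on uniformly random
#' node pairs (all nodes statistically equivalent), runs Walktrap, and
#' records the resulting modularity.
#'
#' @param sim Observed similarity matrix.
#' @param n_draws Number of null draws (default 100, minimum 20).
#' @param seed Integer seed.
#' @param steps Walktrap walk length.
#' @return List with the empirical `q` values and their 95th percentile
#'   `q95`.
#' @export
random_null_modularity <- function(sim, n_draws = 100, seed = 1L,
                                   steps = 4) {
  if (n_draws < 20) stop("n_draws must be at least 20")
  sim <- unclass(as.matrix(sim))
  n <- nrow(sim)
  wts <- sim[upper.tri(sim)]
  npairs <- length(wts)
  withr::local_seed(seed)
  q <- vapply(seq_len(n_draws), function(d) {
    null <- matrix(0, n, n)
    null[upper.tri(null)] <- wts[sample.int(npairs)]
    null <- null + t(null)
    mem <- suppressWarnings(walktrap_communities(null, steps = steps))
    modularity_q(null, mem)
  }, numeric(1))
  list(q = q, q95 = stats::quantile(q, 0.95, names = FALSE))
}

.check_partitions <- function(p1, p2) {
  if (!length(p1) || !length(p2)) stop("empty partition")
  if (length(p1) != length(p2))
    stop("partitions must have equal length")
}

#' Variation of information between two partitions
#'
#' `VI = H(P1) + H(P2) - 2 I(P1; P2)` in nats; 0 iff the partitions are
#' identical up to relabeling.
#'
#' @param p1,p2 Label vectors of equal length.
#' @return Non-negative VI value.
#' @export
partition_vi <- function(p1, p2) {
  .check_partitions(p1, p2)
  n <- length(p1)
  tab <- table(p1, p2) / n
  px <- rowSums(tab); py <- colSums(tab)
  ent <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  mi <- sum(tab[tab > 0] *
              log(tab[tab > 0] / outer(px, py)[tab > 0]))
  ent(px) + ent(py) - 2 * mi
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-model chance-corrected Rand agreement; 1 iff identical up
#' to relabeling, about 0 for independent partitions.
#'
#' @param p1,p2 Label vectors of equal length.
#' @return ARI value (can be negative).
#' @export
partition_ari <- function(p1, p2) {
  .check_partitions(p1, p2)
  tab <- table(p1, p2)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (maxi - expected)
}

#' Perturbation robustness report for a subgrouping solution
#'
#' For each perturbation fraction, rewires that share of similarity
#' edges, re-clusters, and records the mean VI and ARI against the
#' original partition over `reps` repetitions. The stability criterion
#' passes when at least 20% of edges must be perturbed before the mean
#' VI reaches the reference VI of randomly reassigning 20% of
#' memberships; the modularity criterion passes when the observed Q is
#' at or above the 95th percentile of the weighted random-matrix null.
#'
#' @param sim Similarity matrix.
#' @param membership Partition to assess (default: Walktrap on `sim`).
#' @param fractions Perturbation grid in (0, 1].
#' @param reps Repetitions per fraction (minimum 10).
#' @param seed Integer seed.
#' @param n_null Draws for the modularity null.
#' @param stability_fraction Minimum fraction for stability (default
#'   0.20); also the share of relabeled memberships in the reference.
#' @param steps Walktrap walk length.
#' @return A `subgroup_solution` list: membership, Q, the VI/ARI curves,
#'   the null modularity distribution, the reference VI, the stability
#'   crossing fraction, and the two pass flags.
#' @export
robustness_report <- function(sim, membership = NULL,
                              fractions = seq(0.05, 1, by = 0.05),
                              reps = 20, seed = 1L, n_null = 100,
                              stability_fraction = 0.20, steps = 4) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  if (reps < 10) stop("reps must be at least 10")
  sim <- unclass(as.matrix(sim))
  n <- nrow(sim)
  if (is.null(membership))
    membership <- walktrap_communities(sim, steps = steps)
  Q <- modularity_q(sim, membership)

  vi_mean <- ari_mean <- numeric(length(fractions))
  for (fi in seq_along(fractions)) {
    vis <- aris <- numeric(reps)
    for (r in seq_len(reps)) {
      pert <- perturb_edges(sim, fractions[fi],
                            seed = derive_seed(seed, fi * 1000 + r))
      mem2 <- suppressWarnings(walktrap_communities(pert, steps = steps))
      vis[r] <- partition_vi(membership, mem2)
      aris[r] <- partition_ari(membership, mem2)
    }
    vi_mean[fi] <- mean(vis)
    ari_mean[fi] <- mean(aris)
  }

  ## reference: VI to a partition with `stability_fraction` of labels
  ## uniformly reassigned, averaged over reps
  labs <- sort(unique(membership))
  ref_vi <- mean(vapply(seq_len(reps), function(r) {
    withr::local_seed(derive_seed(seed, r, salt = 5L))
    relab <- membership
    k <- max(1L, round(stability_fraction * n))
    pick <- sample.int(n, k)
    relab[pick] <- sample(labs, k, replace = TRUE)
    partition_vi(membership, relab)
  }, numeric(1)))

  crossing <- fractions[which(vi_mean >= ref_vi)[1L]]
  if (is.na(crossing)) crossing <- Inf
  null <- random_null_modularity(sim, n_draws = n_null,
                                 seed = derive_seed(seed, salt = 9L),
                                 steps = steps)
  structure(list(
    membership = membership, modularity = Q,
    fractions = fractions, vi_curve = vi_mean, ari_curve = ari_mean,
    reference_vi = ref_vi, stability_crossing = crossing,
    null_modularity = null$q, null_q95 = null$q95,
    criteria = list(stability_pass = crossing >= stability_fraction,
                    modularity_pass = Q >= null$q95)),
    class = "subgroup_solution")
}

#' @export
print.subgroup_solution <- function(x, ...) {
  cat(sprintf("<subgroup_solution> %d communities, Q=%.3f (null 95th pct %.3f)\n",
              length(unique(x$membership)), x$modularity, x$null_q95))
  cat(sprintf("  stability crossing at %.0f%% of edges (reference VI %.3f): %s\n",
              100 * min(x$stability_crossing, 1), x$reference_vi,
              if (x$criteria$stability_pass) "PASS" else "FAIL"))
  cat(sprintf("  modularity criterion: %s\n",
              if (x$criteria$modularity_pass) "PASS" else "FAIL"))
  invisible(x)
}
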