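#' Default synthetic scenario configuration
#'
#' The defaults emulate the study conditions this generator is calibrated
#' to: 103 subjects, 15 endogenous nodes plus 2 HRF-convolved task
#' regressors, 239 timepoints at TR = 2 s, 19 group paths, three
#' subgroups with member fractions 28/31/44 of 103 carrying 6/14/10
#' distinctive paths, and a 17-path individual pool with 25% per-subject
#' inclusion. Coefficient magnitudes are uniform on [0.3, 0.7] with an
#' 80% positive fraction and per-subject jitter of SD 0.2
#' (`coef_subject_sd`); autoregressive coefficients uniform on
#' [0.4, 0.7]; unit innovation SD.
#'
#' Structure controls: `acyclic_contemporaneous` (default `TRUE`) keeps
#' the union of contemporaneous true paths acyclic;
#' `benchmark_structure` (default `FALSE`) additionally forbids
#' contemporaneous-skeleton triangles and allows at most one structural
#' path per node pair — the well-identified family used by the recovery
#' benchmarks. `stabilize` (default `TRUE`) rescales any subject whose
#' realized system is non-stationary after `max_retries` coefficient
#' redraws down to companion spectral radius `rho_target` (0.9);
#' with `stabilize = FALSE` a generation error is raised instead.
#' Task timing: `n_trials`, `trial_seconds`, `iti_mean_seconds`,
#' `iti_halfwidth_seconds` (the default ITI is compressed to mean 2.5 s
#' so 24 trials of 17 s fit a 478 s scan).
#'
#' @return Named list of configuration defaults.
#' @export
scenario_defaults <- function() {
  list(
    n_subjects = 103L, n_endogenous = 15L, n_exogenous = 2L,
    n_timepoints = 239L, tr_seconds = 2,
    n_group_paths = 19L,
    subgroup_fractions = c(28, 31, 44) / 103,
    n_subgroup_paths = c(6L, 14L, 10L),
    n_individual_pool = 17L, individual_prob = 0.25,
    n_exo_paths = 0L,
    coef_range = c(0.3, 0.7), positive_fraction = 0.8,
    coef_subject_sd = 0.2,
    ar_range = c(0.4, 0.7), noise_sd = 1,
    contemporaneous_fraction = 0.8,
    acyclic_contemporaneous = TRUE,
    benchmark_structure = FALSE,
    burn_in = 50L, max_retries = 20L,
    stabilize = TRUE, rho_target = 0.9,
    n_trials = 24L, trial_seconds = 17, iti_mean_seconds = 2.5,
    iti_halfwidth_seconds = 1.5,
    seed = 1L)
}

#' Build a simulation scenario with known multi-level network structure
#'
#' Draws a group path set, subgroup-specific path sets, an
#' individual-path pool, per-node autoregressive coefficients, and task
#' events; realizes each subject's structure (subgroup membership by
#' deterministic fraction blocks shuffled under the seed, individual
#' paths by independent inclusion draws) and redraws coefficients until
#' every subject's reduced-form lag-1 system is stationary.
#'
#' @param config Named list overriding entries of [scenario_defaults()].
#' @return An object of class `sim_scenario` containing the
#'   configuration, node names, the per-subject ground-truth `ledger`
#'   (subject_id, level, from, to, lag, beta, subgroup), the subgroup
#'   `membership`, the task `events` and exogenous regressor matrix.
#' @export
make_scenario <- function(config = list()) {
  cfg <- utils::modifyList(scenario_defaults(), config)
  p <- as.integer(cfg$n_endogenous); q <- as.integer(cfg$n_exogenous)
  if (p < 2) stop("configuration error: n_endogenous must be >= 2")
  if (cfg$n_timepoints < 50)
    stop("configuration error: n_timepoints must be >= 50")
  if (abs(sum(cfg$subgroup_fractions) - 1) > 1e-8)
    stop("configuration error: subgroup fractions must sum to 1")
  if (length(cfg$n_subgroup_paths) != length(cfg$subgroup_fractions))
    stop("configuration error: one path count per subgroup is required")
  if (cfg$individual_prob < 0 || cfg$individual_prob > 1)
    stop("configuration error: individual_prob must be in [0, 1]")

  nodes <- sprintf("roi%02d", seq_len(p))
  exo <- if (q) c("anticipation", "outcome",
                  sprintf("exo%d", seq_len(max(0, q - 2L))))[seq_len(q)]
         else character()

  withr::local_seed(cfg$seed)

  ## candidate structural slots: contemporaneous (i != j) and lag-1
  ## cross paths; AR self paths are handled separately
  grid <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  cross <- grid[grid$from != grid$to, ]
  slots <- rbind(data.frame(cross, lag = 0L), data.frame(cross, lag = 1L))
  n_struct <- sum(cfg$n_group_paths, cfg$n_subgroup_paths,
                  cfg$n_individual_pool)
  if (n_struct > nrow(slots))
    stop("configuration error: ", n_struct,
         " structural paths requested but only ", nrow(slots),
         " slots available")

  ## Draw structural slots one at a time. By default the union of all
  ## contemporaneous paths (across levels) is kept acyclic: feedback
  ## loops in A are near-unidentifiable at realistic scan lengths and
  ## simulation designs for this model family plant recursive
  ## contemporaneous structure.
  contemp_edges <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  pair_used <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  creates_cycle <- function(from, to) {
    ## path to -> ... -> from among existing lag-0 edges?
    reach <- contemp_edges[to, ]
    repeat {
      grown <- reach | (colSums(contemp_edges[reach, , drop = FALSE]) > 0)
      if (identical(grown, reach)) break
      reach <- grown
    }
    reach[from] || from == to
  }
  pool <- slots
  take <- function(n) {
    out <- pool[0, , drop = FALSE]
    while (nrow(out) < n) {
      if (!nrow(pool))
        stop("configuration error: structural path slots exhausted ",
             "(requested more paths than the acyclic pool allows)")
      pr <- ifelse(pool$lag == 0L, cfg$contemporaneous_fraction,
                   1 - cfg$contemporaneous_fraction)
      if (all(pr == 0)) pr <- rep(1, nrow(pool))
      k <- sample.int(nrow(pool), 1L, prob = pr)
      cand <- pool[k, , drop = FALSE]
      pool <<- pool[-k, , drop = FALSE]
      if (isTRUE(cfg$benchmark_structure) &&
          pair_used[cand$from, cand$to]) next
      if (cand$lag == 0L) {
        if (isTRUE(cfg$acyclic_contemporaneous) &&
            creates_cycle(cand$from, cand$to)) next
        if (isTRUE(cfg$benchmark_structure)) {
          skel <- contemp_edges | t(contemp_edges)
          if (any(skel[, cand$from] & skel[, cand$to])) next
        }
        contemp_edges[cand$from, cand$to] <<- TRUE
      }
      pair_used[cand$from, cand$to] <<- TRUE
      pair_used[cand$to, cand$from] <<- TRUE
      out <- rbind(out, cand)
    }
    out
  }
  group_struct <- take(cfg$n_group_paths)
  sub_struct <- lapply(cfg$n_subgroup_paths, take)
  ind_struct <- take(cfg$n_individual_pool)

  if (cfg$n_exo_paths) {
    if (!q) stop("configuration error: exogenous paths without exogenous nodes")
    ge <- expand.grid(from = exo, to = nodes, stringsAsFactors = FALSE)
    pick <- ge[sample.int(nrow(ge), cfg$n_exo_paths), ]
    group_struct <- rbind(group_struct, data.frame(pick, lag = 0L))
  }

  ## subgroup membership: fraction blocks, then shuffled
  n <- as.integer(cfg$n_subjects)
  sizes <- floor(cfg$subgroup_fractions * n)
  rem <- n - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  membership <- sample(rep.int(seq_along(sizes), sizes))

  ## individual inclusion draws
  incl <- if (nrow(ind_struct))
    matrix(stats::runif(n * nrow(ind_struct)) <= cfg$individual_prob,
           n, nrow(ind_struct))
  else matrix(FALSE, n, 0L)

  draw_coef <- function(k) {
    mag <- stats::runif(k, cfg$coef_range[1], cfg$coef_range[2])
    sgn <- ifelse(stats::runif(k) <= cfg$positive_fraction, 1, -1)
    mag * sgn
  }

  ids <- sprintf("sub%03d", seq_len(n))
  ok <- FALSE
  for (try in seq_len(cfg$max_retries)) {
    ar <- stats::runif(p, cfg$ar_range[1], cfg$ar_range[2])
    gcoef <- draw_coef(nrow(group_struct))
    scoef <- lapply(sub_struct, function(s) draw_coef(nrow(s)))
    icoef <- draw_coef(nrow(ind_struct))
    ledger <- .build_ledger(ids, membership, nodes, ar, group_struct,
                            gcoef, sub_struct, scoef, ind_struct, icoef,
                            incl, cfg$coef_subject_sd)
    if (.all_stationary(ledger, ids, nodes, exo)) { ok <- TRUE; break }
  }
  if (!ok) {
    if (!isTRUE(cfg$stabilize))
      stop("generation error: no stationary coefficient draw in ",
           cfg$max_retries, " retries")
    ## dense structures amplify along same-signed chains and no draw in
    ## the nominal range is stationary; rescale each unstable subject's
    ## cross-path coefficients to the target spectral radius
    ledger <- .stabilize_ledger(ledger, ids, nodes, exo, cfg$rho_target)
  }

  events <- simulate_task_events(
    n_trials = cfg$n_trials, trial_seconds = cfg$trial_seconds,
    tr_seconds = cfg$tr_seconds,
    iti_mean_seconds = cfg$iti_mean_seconds,
    iti_halfwidth_seconds = cfg$iti_halfwidth_seconds,
    scan_seconds = cfg$n_timepoints * cfg$tr_seconds,
    seed = derive_seed(cfg$seed, salt = 11L))
  exo_mat <- if (q) build_task_regressors(events, cfg$n_timepoints,
                                          cfg$tr_seconds,
                                          trial_types = exo)
             else matrix(0, cfg$n_timepoints, 0L)

  structure(list(config = cfg, node_names = nodes, exo_names = exo,
                 subject_ids = ids, membership = stats::setNames(
                   membership, ids),
                 ledger = ledger, events = events, exo_mat = exo_mat),
            class = "sim_scenario")
}

.build_ledger <- function(ids, membership, nodes, ar, group_struct,
                          gcoef, sub_struct, scoef, ind_struct, icoef,
                          incl, subject_sd = 0) {
  n <- length(ids)
  per <- vector("list", n)
  jitter <- function(b) {
    if (!length(b) || subject_sd == 0) return(b)
    b + stats::rnorm(length(b), sd = subject_sd)
  }
  for (i in seq_len(n)) {
    g <- membership[i]
    rows <- list(
      data.frame(level = "null_base", from = nodes, to = nodes, lag = 1L,
                 beta = ar, stringsAsFactors = FALSE))
    if (nrow(group_struct))
      rows <- c(rows, list(data.frame(level = "group", group_struct,
                                      beta = jitter(gcoef))))
    if (nrow(sub_struct[[g]]))
      rows <- c(rows, list(data.frame(level = "subgroup",
                                      sub_struct[[g]],
                                      beta = jitter(scoef[[g]]))))
    sel <- incl[i, ]
    if (any(sel))
      rows <- c(rows, list(data.frame(level = "individual",
                                      ind_struct[sel, , drop = FALSE],
                                      beta = jitter(icoef[sel]))))
    df <- do.call(rbind, rows)
    df$subject_id <- ids[i]
    df$subgroup <- g
    per[[i]] <- df
  }
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  out[, c("subject_id", "level", "from", "to", "lag", "beta", "subgroup")]
}

## subject coefficient matrices from the ledger
.subject_matrices <- function(ledger, id, nodes, exo) {
  p <- length(nodes); q <- length(exo)
  rows <- ledger[ledger$subject_id == id, , drop = FALSE]
  A <- matrix(0, p, p, dimnames = list(nodes, nodes))
  Phi <- matrix(0, p, p, dimnames = list(nodes, nodes))
  Lambda <- matrix(0, p, q, dimnames = list(nodes, exo))
  for (k in seq_len(nrow(rows))) {
    fr <- rows$from[k]; to <- rows$to[k]
    if (fr %in% nodes) {
      if (rows$lag[k] == 0L) A[to, fr] <- rows$beta[k]
      else Phi[to, fr] <- rows$beta[k]
    } else {
      Lambda[to, fr] <- rows$beta[k]
    }
  }
  list(A = A, Phi = Phi, Lambda = Lambda)
}

## Largest-modulus eigenvalue of the reduced-form lag-1 companion.
.subject_rho <- function(ledger, id, nodes, exo) {
  mats <- .subject_matrices(ledger, id, nodes, exo)
  G <- tryCatch(solve(diag(length(nodes)) - mats$A),
                error = function(e) NULL)
  if (is.null(G)) return(Inf)
  spectral_radius(G %*% mats$Phi)
}

## Shrink non-base coefficients of unstable subjects by a common factor
## (binary search) until the companion spectral radius reaches rho_target.
.stabilize_ledger <- function(ledger, ids, nodes, exo, rho_target) {
  for (id in ids) {
    if (.subject_rho(ledger, id, nodes, exo) < rho_target) next
    rows <- which(ledger$subject_id == id & ledger$level != "null_base")
    orig <- ledger$beta[rows]
    lo <- 0; hi <- 1
    for (iter in 1:30) {
      c0 <- (lo + hi) / 2
      ledger$beta[rows] <- orig * c0
      if (.subject_rho(ledger, id, nodes, exo) < rho_target) lo <- c0
      else hi <- c0
    }
    ledger$beta[rows] <- orig * lo
  }
  ledger
}

.all_stationary <- function(ledger, ids, nodes, exo) {
  for (id in ids) {
    mats <- .subject_matrices(ledger, id, nodes, exo)
    IA <- diag(length(nodes)) - mats$A
    G <- tryCatch(solve(IA), error = function(e) NULL)
    if (is.null(G)) return(FALSE)
    if (spectral_radius(G %*% mats$Phi) >= 1) return(FALSE)
  }
  TRUE
}

#' @export
print.sim_scenario <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<sim_scenario> n=%d subjects, p=%d nodes + %d exogenous, T=%d @ TR=%gs\n",
              cfg$n_subjects, cfg$n_endogenous, length(x$exo_names),
              cfg$n_timepoints, cfg$tr_seconds))
  cat(sprintf("  %d group, %s subgroup (fractions %s), %d pool paths (incl. prob %.2f)\n",
              sum(x$ledger$level == "group" &
                    x$ledger$subject_id == x$subject_ids[1]),
              paste(cfg$n_subgroup_paths, collapse = "/"),
              paste(round(cfg$subgroup_fractions, 2), collapse = "/"),
              cfg$n_individual_pool, cfg$individual_prob))
  invisible(x)
}

#' Simulate the jittered card-guessing task event schedule
#'
#' Each trial contributes an anticipation event (onset 4 s into the
#' trial, 6 s duration) and an outcome event (onset 10 s, 1 s duration),
#' followed by fixation; trials are separated by a jittered intertrial
#' interval uniform on `iti_mean_seconds +/- iti_halfwidth_seconds`.
#'
#' @param n_trials Number of trials (default 24).
#' @param trial_seconds Trial length in seconds (default 17).
#' @param tr_seconds Repetition time (default 2).
#' @param iti_mean_seconds Mean intertrial interval (default 4).
#' @param iti_halfwidth_seconds Half-width of the uniform jitter
#'   (default 2).
#' @param scan_seconds Optional scan length; trials overflowing it raise
#'   a configuration error.
#' @param seed Integer seed for the jitters.
#' @return A [task_events()] table with `n_trials` anticipation and
#'   `n_trials` outcome events.
#' @export
simulate_task_events <- function(n_trials = 24L, trial_seconds = 17,
                                 tr_seconds = 2, iti_mean_seconds = 4,
                                 iti_halfwidth_seconds = 2,
                                 scan_seconds = NULL, seed = 1L) {
  if (n_trials == 0L) return(task_events())
  withr::local_seed(seed)
  iti <- stats::runif(n_trials - 1L,
                      iti_mean_seconds - iti_halfwidth_seconds,
                      iti_mean_seconds + iti_halfwidth_seconds)
  starts <- cumsum(c(0, iti + trial_seconds))
  if (!is.null(scan_seconds) &&
      starts[n_trials] + trial_seconds > scan_seconds)
    stop(sprintf(
      "configuration error: %d trials need %.1f s but the scan is %.1f s",
      n_trials, starts[n_trials] + trial_seconds, scan_seconds))
  task_events(
    onset = c(starts + 4, starts + 10),
    duration = rep(c(6, 1), each = n_trials),
    trial_type = rep(c("anticipation", "outcome"), each = n_trials))
}

#' Simulate one subject's ROI time series from a scenario
#'
#' Generates `x_t = (I - A)^(-1) (Phi x_{t-1} + Lambda u_t + zeta_t)`
#' with i.i.d. Gaussian innovations, using the subject's realized
#' coefficient matrices; a burn-in (default 50 steps, exogenous inputs
#' zero) is discarded and exactly `n_timepoints` frames are returned.
#'
#' @param scenario A [make_scenario()] object.
#' @param subject_index Subject number (1-based).
#' @param seed Optional integer seed (defaults to a stream derived from
#'   the scenario seed and the subject index).
#' @return A [roi_timeseries()].
#' @export
simulate_subject <- function(scenario, subject_index, seed = NULL) {
  cfg <- scenario$config
  n <- cfg$n_subjects
  if (subject_index < 1L || subject_index > n)
    stop("subject_index out of range")
  id <- scenario$subject_ids[subject_index]
  mats <- .subject_matrices(scenario$ledger, id, scenario$node_names,
                            scenario$exo_names)
  p <- length(scenario$node_names); q <- length(scenario$exo_names)
  G <- tryCatch(solve(diag(p) - mats$A), error = function(e)
    stop("generation error: (I - A) singular for subject ", id))
  burn <- cfg$burn_in
  Tn <- cfg$n_timepoints
  U <- rbind(matrix(0, burn, q), scenario$exo_mat)
  noise_sd <- rep(cfg$noise_sd, length.out = p)
  withr::local_seed(seed %||% derive_seed(cfg$seed, subject_index,
                                          salt = 7L))
  X <- matrix(0, burn + Tn, p)
  eps <- matrix(stats::rnorm((burn + Tn) * p, sd = noise_sd), burn + Tn,
                p, byrow = TRUE)
  for (t in 2:(burn + Tn)) {
    drive <- mats$Phi %*% X[t - 1L, ]
    if (q) drive <- drive + mats$Lambda %*% U[t, ]
    X[t, ] <- G %*% (drive + eps[t, ])
  }
  X <- X[-seq_len(burn), , drop = FALSE]
  colnames(X) <- scenario$node_names
  roi_timeseries(X, exogenous = if (q) scenario$exo_mat,
                 subject_id = id, tr_seconds = cfg$tr_seconds)
}

#' Simulate a full cohort with its ground-truth ledger
#'
#' @param scenario A [make_scenario()] object.
#' @return List with `series` (one [roi_timeseries()] per subject),
#'   `ledger` (true paths and coefficients), and `membership` (true
#'   subgroup labels).
#' @export
simulate_cohort <- function(scenario) {
  series <- lapply(seq_len(scenario$config$n_subjects),
                   function(i) simulate_subject(scenario, i))
  names(series) <- scenario$subject_ids
  list(series = series, ledger = scenario$ledger,
       membership = scenario$membership)
}

#' Write a simulated cohort to delimited text files
#'
#' One headered TSV per subject plus `ledger.csv` (subject_id, level,
#' from, to, lag, beta, subgroup) and `events.tsv`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param events Optional [task_events()] table to write alongside.
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir, events = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$series)
    write_timeseries(s, file.path(dir, paste0(s$subject_id, ".tsv")))
  utils::write.csv(cohort$ledger, file.path(dir, "ledger.csv"),
                   row.names = FALSE)
  if (!is.null(events))
    utils::write.table(events, file.path(dir, "events.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Specify a behavioral outcome linked to network features
#'
#' @param outcome_name Label for the outcome.
#' @param effects A `data.frame` with columns `from`, `to`, `lag`,
#'   `encoding` (`"presence"` or `"beta"`), and `beta` (the linear
#'   coefficient on that feature).
#' @param noise_sd Residual standard deviation (identity link).
#' @param link `"identity"` or `"logistic"`.
#' @param standardize_features Apply effects to z-scored feature columns
#'   (default `TRUE`), so each coefficient is an effect per SD of the
#'   feature — the convention under which simulated effect sizes are
#'   stated.
#' @return A `behavior_spec` list.
#' @export
behavior_spec <- function(outcome_name, effects, noise_sd = 1,
                          link = c("identity", "logistic"),
                          standardize_features = TRUE) {
  stopifnot(all(c("from", "to", "lag", "encoding", "beta") %in%
                  names(effects)))
  if (!all(effects$encoding %in% c("presence", "beta")))
    stop("encoding must be 'presence' or 'beta'")
  structure(list(outcome_name = outcome_name, effects = effects,
                 noise_sd = noise_sd, link = match.arg(link),
                 standardize_features = standardize_features),
            class = "behavior_spec")
}

#' Simulate behavioral outcomes from network features
#'
#' Identity link: `y = sum(beta_f * f) + eps`; logistic link: Bernoulli
#' with `logit = sum(beta_f * f)`. Features resolve either against the
#' ground-truth ledger (presence = path in the subject's true set; beta =
#' the subject's realized coefficient, 0 when absent) or against a
#' supplied feature matrix with columns named by [path_key()].
#'
#' @param spec A [behavior_spec()].
#' @param ledger Ground-truth ledger from [simulate_cohort()].
#' @param features Optional numeric matrix (subjects x features) whose
#'   column names are path keys; overrides ledger-based resolution.
#' @param seed Integer seed.
#' @return Named numeric vector of per-subject outcomes.
#' @export
simulate_behavior <- function(spec, ledger, features = NULL, seed = 1L) {
  keys <- path_key(spec$effects)
  if (is.null(features)) {
    ids <- unique(ledger$subject_id)
    lkeys <- path_key(ledger)
    if (!all(keys %in% lkeys))
      stop("unknown feature reference: ",
           paste(setdiff(keys, lkeys), collapse = ", "))
    features <- matrix(0, length(ids), length(keys),
                       dimnames = list(ids, keys))
    for (j in seq_along(keys)) {
      rows <- ledger[lkeys == keys[j], , drop = FALSE]
      hit <- match(rows$subject_id, ids)
      features[hit, j] <- if (spec$effects$encoding[j] == "presence") 1
                          else rows$beta
    }
  } else {
    if (!all(keys %in% colnames(features)))
      stop("unknown feature reference: ",
           paste(setdiff(keys, colnames(features)), collapse = ", "))
    features <- as.matrix(features[, keys, drop = FALSE])
  }
  if (isTRUE(spec$standardize_features)) {
    sds <- apply(features, 2L, stats::sd)
    if (any(sds == 0))
      stop("cannot standardize constant feature: ",
           paste(colnames(features)[sds == 0], collapse = ", "))
    features <- scale(features, scale = sds)
  }
  eta <- drop(features %*% spec$effects$beta)
  withr::local_seed(seed)
  y <- if (spec$link == "identity")
    eta + stats::rnorm(length(eta), sd = spec$noise_sd)
  else
    stats::rbinom(length(eta), 1L, stats::plogis(eta))
  stats::setNames(y, rownames(features))
}
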