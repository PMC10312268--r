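## Greedy modification-index search shared by all procedures.
##
## Starting from `start_paths`, repeatedly adds the highest-MI
## significant candidate at `level`, refitting after each addition,
## until the configured stopping rule fires (see `usem_options`).
.greedy_mi_search <- function(data, start_paths, level, options,
                              max_add = Inf) {
  model <- fit_usem(data, start_paths, no_se(options))
  log <- list()
  step <- 0L
  repeat {
    if (!model$converged) break
    if (step >= max_add || model$fit$df <= 1) break
    if (options$stop_rule == "excellent" &&
        evaluate_fit(model$fit)$n_excellent >= 2) break
    mi <- modification_indices(model)
    mi <- mi[is.finite(mi$mi), , drop = FALSE]
    crit <- if (options$stop_rule == "mi_bonferroni")
      stats::qchisq(1 - options$mi_alpha / max(NROW(mi), 1L), 1)
    else options$mi_crit
    if (!NROW(mi) || mi$mi[1L] < crit) break
    step <- step + 1L
    add <- path_set(mi$from[1L], mi$to[1L], mi$lag[1L], level)
    log[[step]] <- data.frame(action = "add", from = add$from,
                              to = add$to, lag = add$lag, level = level,
                              statistic = mi$mi[1L], step = step,
                              stringsAsFactors = FALSE)
    model <- fit_usem(data, rbind_paths(model$free_paths, add),
                      no_se(options))
  }
  list(model = model,
       log = if (length(log)) do.call(rbind, log) else NULL)
}

no_se <- function(options) { options$se <- "none"; options }

.as_cohort <- function(cohort) {
  if (inherits(cohort, "roi_timeseries")) cohort <- list(cohort)
  stopifnot(length(cohort) >= 1L,
            all(vapply(cohort, inherits, logical(1), "roi_timeseries")))
  cohort
}

.base_paths <- function(node_names, options) {
  if (options$ar_base) ar_paths(node_names) else empty_path_set()
}

#' Aggregate-level network search on concatenated time series
#'
#' Standardizes each subject, concatenates the series (lag pairs never
#' span subject boundaries), then greedily adds the highest-MI significant
#' candidate path until the excellent-fit rule is met or no candidate is
#' significant, and prunes non-significant added paths.
#'
#' @param cohort A list of [roi_timeseries()] (or a single one).
#' @param options A [usem_options()] list.
#' @return A `usem_model` whose discovered paths carry level
#'   `"aggregate"`; the search log is in `attr(, "search_log")`.
#' @export
search_aggregate <- function(cohort, options = usem_options()) {
  cohort <- .as_cohort(cohort)
  std <- lapply(cohort, standardize)
  data <- lag_augment(std)
  res <- .greedy_mi_search(data, .base_paths(data$node_names, options),
                           "aggregate", options)
  model <- prune(res$model, levels = "aggregate")
  model <- fit_usem(data, model$free_paths[, c("from", "to", "lag",
                                               "level")], options)
  attr(model, "search_log") <- res$log
  model
}

#' Idiographic network search for a single subject
#'
#' The same greedy modification-index search as [search_aggregate()], run
#' on one subject's data alone with no group information.
#'
#' @param series A [roi_timeseries()].
#' @param options A [usem_options()] list.
#' @return A `usem_model` with discovered paths at level `"individual"`.
#' @export
search_individual <- function(series, options = usem_options()) {
  data <- lag_augment(standardize(series))
  res <- .greedy_mi_search(data, .base_paths(data$node_names, options),
                           "individual", options)
  model <- prune(res$model, levels = "individual")
  model <- fit_usem(data, model$free_paths[, c("from", "to", "lag",
                                               "level")], options)
  attr(model, "search_log") <- res$log
  model
}

## Fit every subject with a common free set; returns models list.
.fit_cohort <- function(datas, free_paths, options) {
  lapply(datas, function(d) fit_usem(d, free_paths, options))
}

#' Group-level network search (majority criterion)
#'
#' Iteratively adds the candidate path whose modification index is
#' significant for the largest number of subjects, provided that count
#' reaches `gamma` of the sample; stops otherwise. Afterwards prunes any
#' group path whose estimate is significant for fewer than `gamma` of
#' subjects (lowest proportion first, refitting all subjects after each
#' removal). Subjects that fail to converge at a step count as
#' non-significant and are flagged.
#'
#' @param cohort A list of [roi_timeseries()].
#' @param gamma Majority threshold (default 0.75).
#' @param options A [usem_options()] list.
#' @param alpha Significance level for the estimate-based pruning stage.
#' @return A list with `group_paths`, per-subject `models` (fitted with
#'   the final group set, with standard errors), per-subject `mi_tables`,
#'   `search_log`, and `nonconverged` subject ids.
#' @export
group_search <- function(cohort, gamma = 0.75, options = usem_options(),
                         alpha = 0.05) {
  cohort <- .as_cohort(cohort)
  if (length(cohort) < 2L) stop("group search needs at least 2 subjects")
  std <- lapply(cohort, standardize)
  datas <- lapply(std, lag_augment)
  n <- length(datas)
  base <- .base_paths(datas[[1L]]$node_names, options)
  group <- empty_path_set()
  log <- list(); step <- 0L
  nonconv <- character()

  repeat {
    free <- rbind_paths(base, group)
    models <- .fit_cohort(datas, free, no_se(options))
    ok <- vapply(models, function(m) m$converged, logical(1))
    nonconv <- unique(c(nonconv, vapply(cohort[!ok], function(s)
      s$subject_id, character(1))))
    mis <- vector("list", n)
    for (i in seq_len(n))
      if (ok[i]) mis[[i]] <- modification_indices(models[[i]])
    ## count significant MIs per candidate key across subjects
    counts <- list(); misum <- list()
    for (i in seq_len(n)) {
      mt <- mis[[i]]
      if (is.null(mt)) next
      sig <- mt[is.finite(mt$mi) & mt$mi >= options$mi_crit, ,
                drop = FALSE]
      for (k in seq_len(NROW(sig))) {
        key <- path_key(sig[k, ])
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
        misum[[key]] <- (misum[[key]] %||% 0) + sig$mi[k]
      }
    }
    if (!length(counts)) break
    tab <- data.frame(key = names(counts),
                      count = unlist(counts, use.names = FALSE),
                      misum = unlist(misum, use.names = FALSE)[
                        match(names(counts), names(misum))],
                      stringsAsFactors = FALSE)
    tab <- tab[order(-tab$count, -tab$misum, tab$key), , drop = FALSE]
    if (tab$count[1L] / n < gamma) break
    step <- step + 1L
    add <- key_to_path(tab$key[1L], "group")
    log[[length(log) + 1L]] <- data.frame(
      action = "add", from = add$from, to = add$to, lag = add$lag,
      level = "group", statistic = tab$count[1L], step = step,
      stringsAsFactors = FALSE)
    group <- rbind_paths(group, add)
  }

  ## pruning stage: significance proportion of estimates across subjects
  se_opt <- options; if (se_opt$se == "none") se_opt$se <- "expected"
  zcrit <- stats::qnorm(1 - alpha / 2)
  repeat {
    free <- rbind_paths(base, group)
    models <- .fit_cohort(datas, free, se_opt)
    if (!NROW(group)) break
    keys <- path_key(group)
    prop <- vapply(keys, function(key) {
      mean(vapply(models, function(m) {
        row <- match(key, path_key(m$free_paths))
        isTRUE(abs(m$free_paths$z[row]) >= zcrit)
      }, logical(1)))
    }, numeric(1))
    if (all(prop >= gamma)) break
    ord <- order(prop, group$from, group$to, group$lag)
    drop <- ord[1L]
    step <- step + 1L
    log[[length(log) + 1L]] <- data.frame(
      action = "prune", from = group$from[drop], to = group$to[drop],
      lag = group$lag[drop], level = "group", statistic = prop[drop],
      step = step, stringsAsFactors = FALSE)
    group <- group[-drop, , drop = FALSE]
  }

  mi_tables <- lapply(models, function(m)
    if (m$converged) modification_indices(m) else NULL)
  names(models) <- names(mi_tables) <-
    vapply(cohort, function(s) s$subject_id, character(1))
  list(group_paths = group, models = models, mi_tables = mi_tables,
       search_log = if (length(log)) do.call(rbind, log) else NULL,
       nonconverged = nonconv, datas = datas, gamma = gamma,
       options = options)
}

#' Subgroup-level path search within detected communities
#'
#' For each subgroup, iteratively adds candidate paths whose modification
#' indices are significant for more than `gamma_sub` of the subgroup's
#' members (strict majority), starting from the group set; then prunes
#' subgroup paths whose estimates are significant for at most `gamma_sub`
#' of members.
#'
#' @param gs A [group_search()] result.
#' @param membership Integer vector of subgroup labels, one per subject.
#' @param gamma_sub Subgroup majority threshold (default 0.5; strict).
#' @return Named list mapping subgroup label to its path set (level
#'   `"subgroup"`).
#' @export
subgroup_search <- function(gs, membership, gamma_sub = 0.5) {
  stopifnot(length(membership) == length(gs$datas))
  options <- gs$options
  base <- .base_paths(gs$datas[[1L]]$node_names, options)
  out <- list()
  for (lab in sort(unique(membership))) {
    idx <- which(membership == lab)
    datas <- gs$datas[idx]
    nk <- length(idx)
    sub <- empty_path_set()
    repeat {
      free <- rbind_paths(base, gs$group_paths, sub)
      models <- lapply(datas, fit_usem, free_paths = free,
                       options = no_se(options))
      counts <- list(); misum <- list()
      for (m in models) {
        if (!m$converged) next
        mt <- modification_indices(m)
        sig <- mt[is.finite(mt$mi) & mt$mi >= options$mi_crit, ,
                  drop = FALSE]
        for (k in seq_len(NROW(sig))) {
          key <- path_key(sig[k, ])
          counts[[key]] <- (counts[[key]] %||% 0L) + 1L
          misum[[key]] <- (misum[[key]] %||% 0) + sig$mi[k]
        }
      }
      if (!length(counts)) break
      tab <- data.frame(key = names(counts),
                        count = unlist(counts, use.names = FALSE),
                        misum = unlist(misum, use.names = FALSE)[
                          match(names(counts), names(misum))],
                        stringsAsFactors = FALSE)
      tab <- tab[order(-tab$count, -tab$misum, tab$key), , drop = FALSE]
      if (tab$count[1L] / nk <= gamma_sub) break
      sub <- rbind_paths(sub, key_to_path(tab$key[1L], "subgroup"))
    }
    ## prune subgroup paths by estimate significance within the subgroup
    se_opt <- options; if (se_opt$se == "none") se_opt$se <- "expected"
    zcrit <- stats::qnorm(0.975)
    repeat {
      if (!NROW(sub)) break
      free <- rbind_paths(base, gs$group_paths, sub)
      models <- lapply(datas, fit_usem, free_paths = free,
                       options = se_opt)
      keys <- path_key(sub)
      prop <- vapply(keys, function(key) {
        mean(vapply(models, function(m) {
          row <- match(key, path_key(m$free_paths))
          isTRUE(abs(m$free_paths$z[row]) >= zcrit)
        }, logical(1)))
      }, numeric(1))
      if (all(prop > gamma_sub)) break
      ord <- order(prop, sub$from, sub$to, sub$lag)
      sub <- sub[-ord[1L], , drop = FALSE]
    }
    out[[as.character(lab)]] <- sub
  }
  out
}

#' Finalize individual networks from the group (and subgroup) null
#'
#' Per subject: start from the group (plus, when available, the subject's
#' subgroup) free set, greedily add individual-level paths until the
#' excellent-fit stopping rule or no significant modification index,
#' prune individual-level paths, refit with standard errors, and record
#' the four-criteria fit evaluation (CFI/NNFI >= .90, RMSEA/SRMR <= .08).
#'
#' @param cohort A list of [roi_timeseries()].
#' @param group_paths Group-level path set (level `"group"`).
#' @param subgroup_paths Optional named list of subgroup path sets.
#' @param membership Optional subgroup labels (required with
#'   `subgroup_paths`).
#' @param options A [usem_options()] list.
#' @return A `cohort_search_result`: `group_paths`,
#'   `subgroup_membership`, `subgroup_paths`, `individual_models`,
#'   `fit_table` (per-subject indices and criteria counts), `search_log`.
#' @export
finalize_individuals <- function(cohort, group_paths,
                                 subgroup_paths = NULL, membership = NULL,
                                 options = usem_options()) {
  cohort <- .as_cohort(cohort)
  if (!is.null(subgroup_paths) && is.null(membership))
    stop("membership labels are required with subgroup paths")
  n <- length(cohort)
  models <- vector("list", n)
  logs <- list()
  fit_rows <- list()
  ids <- vapply(cohort, function(s) s$subject_id, character(1))
  for (i in seq_len(n)) {
    data <- lag_augment(standardize(cohort[[i]]))
    start <- rbind_paths(.base_paths(data$node_names, options),
                         group_paths)
    if (!is.null(subgroup_paths)) {
      sp <- subgroup_paths[[as.character(membership[i])]]
      if (!is.null(sp)) start <- rbind_paths(start, sp)
    }
    res <- tryCatch(
      .greedy_mi_search(data, start, "individual", options),
      error = function(e) NULL)
    if (is.null(res)) {
      warning("subject ", ids[i], " failed during individual search")
      models[[i]] <- NULL
      next
    }
    model <- prune(res$model, levels = "individual")
    model <- fit_usem(data, model$free_paths[, c("from", "to", "lag",
                                                 "level")], options)
    model$subject_id <- ids[i]
    models[[i]] <- model
    if (!is.null(res$log)) {
      res$log$subject_id <- ids[i]
      logs[[length(logs) + 1L]] <- res$log
    }
    ev <- evaluate_fit(model$fit)
    fit_rows[[i]] <- data.frame(
      subject_id = ids[i], chi2 = model$fit$chi2, df = model$fit$df,
      CFI = model$fit$CFI, NNFI = model$fit$NNFI,
      RMSEA = model$fit$RMSEA, SRMR = model$fit$SRMR,
      n_criteria_met = ev$n_met, converged = model$converged,
      n_individual = sum(model$free_paths$level == "individual"),
      stringsAsFactors = FALSE)
  }
  names(models) <- ids
  out <- structure(list(
    group_paths = group_paths,
    subgroup_membership = if (!is.null(membership))
      stats::setNames(membership, ids),
    subgroup_paths = subgroup_paths,
    individual_models = models,
    fit_table = do.call(rbind, fit_rows),
    search_log = if (length(logs)) do.call(rbind, logs) else NULL),
    class = "cohort_search_result")
  validate_cohort_result(out)
  out
}

#' @export
print.cohort_search_result <- function(x, ...) {
  n <- length(x$individual_models)
  cat(sprintf("<cohort_search_result> %d subjects, %d group paths%s\n",
              n, NROW(x$group_paths),
              if (!is.null(x$subgroup_paths))
                sprintf(", %d subgroups", length(x$subgroup_paths))
              else ""))
  if (!is.null(x$fit_table))
    cat(sprintf("  %d/%d subjects meet all four fit criteria\n",
                sum(x$fit_table$n_criteria_met == 4L), n))
  invisible(x)
}

## Nesting/disjointness invariants of a cohort result.
validate_cohort_result <- function(x) {
  gk <- path_key(x$group_paths)
  for (id in names(x$individual_models)) {
    m <- x$individual_models[[id]]
    if (is.null(m)) next
    mk <- path_key(m$free_paths)
    if (!all(gk %in% mk))
      stop("group set not nested in subject ", id, "'s free set")
    lev <- m$free_paths$level[match(gk, mk)]
    if (any(lev != "group"))
      stop("group paths relabeled in subject ", id)
    sk <- path_key(m$free_paths[m$free_paths$level == "subgroup", ])
    ik <- path_key(m$free_paths[m$free_paths$level == "individual", ])
    if (length(intersect(gk, c(sk, ik))) || length(intersect(sk, ik)))
      stop("path levels overlap for subject ", id)
  }
  invisible(x)
}

#' Flag subjects whose fitted models are numerical outliers
#'
#' @param result A `cohort_search_result`.
#' @param z_abs_max Maximum tolerated absolute z statistic (default 20).
#' @param beta_abs_max Maximum tolerated absolute estimate (default 10).
#' @param include_base Scan autoregressive base paths too (default
#'   `FALSE`: strong AR paths routinely reach large z at typical scan
#'   lengths without being pathological).
#' @return Character vector of flagged subject ids (estimate or z beyond
#'   bounds, or non-convergence).
#' @export
detect_outlier_models <- function(result, z_abs_max = 20,
                                  beta_abs_max = 10,
                                  include_base = FALSE) {
  flagged <- character()
  for (id in names(result$individual_models)) {
    m <- result$individual_models[[id]]
    if (is.null(m) || !m$converged) { flagged <- c(flagged, id); next }
    fp <- m$free_paths
    if (!include_base) fp <- fp[fp$level != "null_base", , drop = FALSE]
    if (any(abs(fp$estimate) > beta_abs_max, na.rm = TRUE) ||
        any(abs(fp$z) > z_abs_max, na.rm = TRUE))
      flagged <- c(flagged, id)
  }
  flagged
}
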