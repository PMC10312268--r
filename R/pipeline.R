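#' Default pipeline configuration
#'
#' @return Named list of defaults for [run_full()].
#' @export
pipeline_defaults <- function() {
  list(
    simulate = TRUE, input_dir = NULL, output_dir = "usemnet_run",
    scenario = list(),
    run_qc = FALSE, qc_file = NULL,
    run_aggregate = TRUE, run_idiographic = TRUE,
    run_gimme = TRUE, run_subgroups = TRUE,
    run_heterogeneity = TRUE, run_associations = TRUE,
    gamma = 0.75, gamma_sub = 0.5, mi_alpha = 0.05,
    prevalence_fraction = 0.20,
    perturbation_grid = seq(0.05, 1, by = 0.05),
    perturbation_reps = 20, null_draws = 100,
    cv_folds = 10, adaptive_gamma = 1,
    behavior = NULL,
    seed = 1L)
}

#' Validate and normalize a pipeline configuration
#'
#' Fills all defaults and reports every violation at once.
#'
#' @param config Named list overriding [pipeline_defaults()].
#' @return The normalized configuration, or an error listing all
#'   violations.
#' @export
validate_config <- function(config = list()) {
  cfg <- utils::modifyList(pipeline_defaults(), config)
  errors <- character()
  chk <- function(ok, msg) if (!ok) errors <<- c(errors, msg)
  chk(is.numeric(cfg$gamma) && cfg$gamma > 0 && cfg$gamma <= 1,
      "gamma must be in (0,1]")
  chk(is.numeric(cfg$gamma_sub) && cfg$gamma_sub >= 0 &&
        cfg$gamma_sub < 1, "gamma_sub must be in [0,1)")
  chk(is.numeric(cfg$mi_alpha) && cfg$mi_alpha > 0 && cfg$mi_alpha < 1,
      "mi_alpha must be in (0,1)")
  chk(is.numeric(cfg$prevalence_fraction) &&
        cfg$prevalence_fraction >= 0 && cfg$prevalence_fraction <= 1,
      "prevalence_fraction must be in [0,1]")
  chk(all(cfg$perturbation_grid > 0 & cfg$perturbation_grid <= 1),
      "perturbation_grid must lie in (0,1]")
  chk(cfg$perturbation_reps >= 10, "perturbation_reps must be >= 10")
  chk(cfg$null_draws >= 20, "null_draws must be >= 20")
  chk(cfg$cv_folds >= 2, "cv_folds must be >= 2")
  chk(isTRUE(cfg$simulate) || (!is.null(cfg$input_dir) &&
                                 dir.exists(cfg$input_dir)),
      "input_dir must exist when simulation is disabled")
  if (length(errors))
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "))
  cfg
}

#' Run the full heterogeneity analysis pipeline
#'
#' Executes the enabled stages in order — simulate (or load), QC,
#' aggregate search, idiographic searches, group search, subgroup
#' detection and robustness, individual finalization, heterogeneity
#' summaries, behavioral associations — writing every intermediate
#' artifact as CSV under the output directory plus a `report.md`
#' summary. Deterministic under the configured seed.
#'
#' @param config Named list, validated by [validate_config()].
#' @return Invisibly, a list with all in-memory results and the run
#'   directory.
#' @export
run_full <- function(config = list()) {
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$output_dir, ...)
  options <- usem_options(mi_alpha = cfg$mi_alpha)
  results <- list(config = cfg, dir = cfg$output_dir)
  report <- c("# usemnet pipeline report", "",
              sprintf("- seed: %d", cfg$seed))

  ## ---- inputs ----
  if (isTRUE(cfg$simulate)) {
    scen_cfg <- utils::modifyList(list(seed = cfg$seed), cfg$scenario)
    scenario <- make_scenario(scen_cfg)
    cohort <- simulate_cohort(scenario)
    series <- cohort$series
    utils::write.csv(cohort$ledger, out("ledger.csv"), row.names = FALSE)
    results$scenario <- scenario
    results$truth <- cohort
    report <- c(report, sprintf(
      "- simulated cohort: n=%d, p=%d (+%d exogenous), T=%d",
      length(series), length(scenario$node_names),
      length(scenario$exo_names), scenario$config$n_timepoints))
  } else {
    files <- list.files(cfg$input_dir, pattern = "\\.(tsv|csv|txt)$",
                        full.names = TRUE)
    files <- files[!grepl("ledger|events|qc", basename(files))]
    series <- lapply(files, read_timeseries)
    names(series) <- vapply(series, function(s) s$subject_id,
                            character(1))
    report <- c(report, sprintf("- loaded %d subjects from %s",
                                length(series), cfg$input_dir))
  }

  ## ---- QC ----
  if (isTRUE(cfg$run_qc) && !is.null(cfg$qc_file)) {
    qc <- utils::read.csv(cfg$qc_file, stringsAsFactors = FALSE)
    res <- qc_exclude(qc)
    series <- series[names(series) %in% res$kept]
    utils::write.csv(res$excluded, out("qc_excluded.csv"),
                     row.names = FALSE)
    results$qc <- res
    report <- c(report, sprintf("- QC: kept %d, excluded %d",
                                length(res$kept), nrow(res$excluded)))
  }

  edge_rows <- list()
  add_edges <- function(scope, model) {
    fp <- model$free_paths
    if (!NROW(fp)) return(invisible())
    edge_rows[[length(edge_rows) + 1L]] <<- data.frame(
      scope = scope, fp, stringsAsFactors = FALSE)
  }

  ## ---- aggregate ----
  if (isTRUE(cfg$run_aggregate)) {
    agg <- search_aggregate(series, options)
    results$aggregate <- agg
    add_edges("aggregate", agg)
    report <- c(report, sprintf(
      "- aggregate network: %d discovered paths",
      sum(agg$free_paths$level == "aggregate")))
  }

  ## ---- idiographic ----
  if (isTRUE(cfg$run_idiographic)) {
    idio <- lapply(series, search_individual, options = options)
    results$idiographic <- idio
    for (id in names(idio)) add_edges(paste0("idiographic:", id),
                                      idio[[id]])
    report <- c(report, sprintf(
      "- idiographic networks: median %.0f discovered paths",
      stats::median(vapply(idio, function(m)
        sum(m$free_paths$level == "individual"), numeric(1)))))
  }

  ## ---- GIMME-style multi-level search ----
  if (isTRUE(cfg$run_gimme)) {
    gs <- group_search(series, gamma = cfg$gamma, options = options)
    results$group_search <- gs
    utils::write.csv(gs$search_log %||% data.frame(),
                     out("search_log.csv"), row.names = FALSE)

    subgroup_paths <- NULL; membership <- NULL
    if (isTRUE(cfg$run_subgroups)) {
      sim <- build_similarity(gs)
      utils::write.csv(as.matrix(unclass(sim)), out("similarity.csv"))
      membership <- walktrap_communities(sim)
      rob <- robustness_report(
        sim, membership, fractions = cfg$perturbation_grid,
        reps = cfg$perturbation_reps, seed = derive_seed(cfg$seed, 2L),
        n_null = cfg$null_draws)
      results$similarity <- sim
      results$robustness <- rob
      utils::write.csv(data.frame(subject_id = names(membership),
                                  subgroup = as.integer(membership)),
                       out("partition.csv"), row.names = FALSE)
      utils::write.csv(data.frame(fraction = rob$fractions,
                                  mean_vi = rob$vi_curve,
                                  mean_ari = rob$ari_curve,
                                  reference_vi = rob$reference_vi),
                       out("robustness.csv"), row.names = FALSE)
      report <- c(report, sprintf(
        "- subgroups: %d communities, Q=%.3f, stability %s, modularity %s",
        length(unique(membership)), rob$modularity,
        if (rob$criteria$stability_pass) "PASS" else "FAIL",
        if (rob$criteria$modularity_pass) "PASS" else "FAIL"))
      ## subgroup-level paths searched only for a robust solution
      if (rob$criteria$stability_pass && rob$criteria$modularity_pass) {
        subgroup_paths <- subgroup_search(gs, membership,
                                          gamma_sub = cfg$gamma_sub)
      } else {
        membership_used <- NULL
        report <- c(report,
                    "- subgroup solution failed robustness criteria; individual stage run without subgroup paths")
      }
    }

    final <- finalize_individuals(
      series, gs$group_paths,
      subgroup_paths = subgroup_paths,
      membership = if (!is.null(subgroup_paths)) membership,
      options = options)
    flagged <- detect_outlier_models(final)
    if (length(flagged)) {
      report <- c(report, sprintf(
        "- outlier models flagged and removed: %s",
        paste(flagged, collapse = ", ")))
      series <- series[setdiff(names(series), flagged)]
      gs <- group_search(series, gamma = cfg$gamma, options = options)
      final <- finalize_individuals(series, gs$group_paths,
                                    options = options)
      results$group_search <- gs
    }
    results$final <- final
    for (id in names(final$individual_models)) {
      m <- final$individual_models[[id]]
      if (!is.null(m)) add_edges(id, m)
    }
    utils::write.csv(final$fit_table, out("fits.csv"), row.names = FALSE)
    report <- c(report, sprintf(
      "- group network: %d paths; %d/%d subjects meet all four fit criteria",
      NROW(gs$group_paths),
      sum(final$fit_table$n_criteria_met == 4L),
      nrow(final$fit_table)))
  }

  if (length(edge_rows))
    utils::write.csv(do.call(rbind, edge_rows), out("edges.csv"),
                     row.names = FALSE)

  ## ---- heterogeneity ----
  if (isTRUE(cfg$run_heterogeneity) && !is.null(results$aggregate) &&
      !is.null(results$idiographic)) {
    ov <- path_overlap(results$aggregate, results$idiographic)
    results$overlap <- ov
    utils::write.csv(data.frame(subject_id = names(ov$shared),
                                shared = ov$shared,
                                fraction = ov$shared /
                                  max(ov$n_aggregate, 1L)),
                     out("overlap.csv"), row.names = FALSE)
    report <- c(report, sprintf(
      "- overlap: median %.1f of %d aggregate paths; %.0f%% of subjects share less than half",
      ov$median_shared, ov$n_aggregate, 100 * ov$below_half_fraction))
    if (!is.null(results$final)) {
      prev <- prevalence(results$final$individual_models,
                         min_fraction = cfg$prevalence_fraction)
      results$prevalence <- prev
      utils::write.csv(prev, out("prevalence.csv"), row.names = FALSE)
      report <- c(report, sprintf(
        "- prevalent individual paths (>= %d%% of sample): %d",
        round(100 * cfg$prevalence_fraction), NROW(prev)))
    }
  }

  ## ---- associations ----
  if (isTRUE(cfg$run_associations) && !is.null(results$final)) {
    feats <- tryCatch(build_features(results$final,
                                     min_fraction =
                                       cfg$prevalence_fraction),
                      error = function(e) NULL)
    if (!is.null(feats)) {
      results$features <- feats
      utils::write.csv(data.frame(subject_id = rownames(feats),
                                  unclass(feats), check.names = FALSE),
                       out("features.csv"), row.names = FALSE)
      outcomes <- cfg$behavior
      if (is.null(outcomes) && isTRUE(cfg$simulate) &&
          !is.null(results$truth)) {
        ## default synthetic outcome: linear in the first (up to) three
        ## discovered features that exist and vary in the ground truth
        led <- results$truth$ledger
        meta <- attr(feats, "meta")
        usable <- logical(nrow(meta))
        for (k in seq_len(nrow(meta))) {
          rows <- led[path_key(led) == path_key(meta[k, ]), ]
          if (!nrow(rows)) next
          vals <- if (meta$encoding[k] == "presence")
            as.numeric(rownames(feats) %in% rows$subject_id)
          else rows$beta[match(rownames(feats), rows$subject_id)]
          vals[is.na(vals)] <- 0
          usable[k] <- stats::var(vals) > 0
        }
        pick <- utils::head(which(usable), 3L)
        if (length(pick)) {
          eff <- meta[pick, , drop = FALSE]
          eff$beta <- 0.5
          spec <- behavior_spec("synthetic_outcome", eff, noise_sd = 1)
          outcomes <- data.frame(synthetic_outcome = simulate_behavior(
            spec, led, seed = derive_seed(cfg$seed, 3L))[rownames(feats)])
        }
      }
      if (!is.null(outcomes)) {
        assoc <- list()
        for (nm in colnames(outcomes)) {
          y <- outcomes[[nm]]
          ok <- !is.na(y)
          ar <- adaptive_lasso(feats[ok, , drop = FALSE], y[ok],
                               folds = cfg$cv_folds,
                               gamma = cfg$adaptive_gamma,
                               seed = derive_seed(cfg$seed, 4L))
          assoc[[nm]] <- ar
          sel <- ar$selected
          utils::write.csv(
            if (NROW(sel)) data.frame(outcome = nm, sel)
            else data.frame(outcome = nm, feature = NA),
            out(paste0("assoc_", nm, ".csv")), row.names = FALSE)
          report <- c(report, sprintf(
            "- association '%s': %d features selected, R2=%.3f (adj %.3f)",
            nm, NROW(sel), ar$r2, ar$adj_r2))
        }
        results$associations <- assoc
      }
    }
  }

  writeLines(report, out("report.md"))
  results$report <- report
  invisible(results)
}
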