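#' Fit indices for a unified SEM against a baseline
#'
#' Computes CFI, NNFI (TLI), RMSEA and SRMR. The default baseline is the
#' independence model (all covariances zero, variances free), whose
#' discrepancy has the closed form `sum(log diag(S)) - log det(S)`.
#'
#' @param model A fitted [fit_usem()] model.
#' @param baseline_model Optional alternative baseline `usem_model`; must
#'   have more degrees of freedom than `model`.
#' @return The model's fit list augmented with `CFI`, `NNFI`, `RMSEA`,
#'   `SRMR`, `chi2_baseline`, `df_baseline`.
#' @export
fit_indices <- function(model, baseline_model = NULL) {
  data <- model$data
  S <- data$S; m <- data$m
  N <- data$n_eff - 1
  fit <- model$fit

  if (is.null(baseline_model)) {
    F_B <- sum(log(diag(S))) - 2 * sum(log(diag(chol(S))))
    chi2_B <- max(N * F_B, 0)
    df_B <- m * (m + 1) / 2 - m
  } else {
    chi2_B <- baseline_model$fit$chi2
    df_B <- baseline_model$fit$df
  }
  chi2_M <- fit$chi2; df_M <- fit$df
  if (df_B <= df_M)
    stop("baseline must have more degrees of freedom than the model")

  num <- max(chi2_M - df_M, 0)
  den <- max(chi2_B - df_B, chi2_M - df_M, 0)
  CFI <- if (den == 0) 1 else 1 - num / den
  CFI <- min(max(CFI, 0), 1)

  NNFI <- if (df_M == 0) 1 else {
    rB <- chi2_B / df_B; rM <- chi2_M / df_M
    if (abs(rB - 1) < 1e-12) 1 else (rB - rM) / (rB - 1)
  }

  RMSEA <- if (df_M == 0) 0 else sqrt(max(chi2_M - df_M, 0) / (df_M * N))

  ## standardized residual covariances over the unique elements
  mach <- .usem_machine(data, model$free_paths)
  cm <- mach$common(model$theta)
  sdv <- sqrt(diag(S))
  res <- (S - cm$Sigma) / outer(sdv, sdv)
  SRMR <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))

  idx_names <- c("CFI", "NNFI", "RMSEA", "SRMR", "chi2_baseline",
                 "df_baseline")
  c(fit[setdiff(names(fit), idx_names)],
    list(CFI = CFI, NNFI = NNFI, RMSEA = RMSEA, SRMR = SRMR,
         chi2_baseline = chi2_B, df_baseline = df_B))
}

#' Evaluate a fit result against acceptance thresholds
#'
#' Counts how many of the four conventional criteria are met
#' (CFI >= .90, NNFI >= .90, RMSEA <= .08, SRMR <= .08; all comparisons
#' inclusive) and likewise for the stricter "excellent" set used as the
#' greedy-search stopping rule (defaults .95/.95/.05/.05).
#'
#' @param fit A fit list from [fit_indices()] (or a fitted model's
#'   `$fit`).
#' @param thresholds Named list with `CFI`, `NNFI`, `RMSEA`, `SRMR`.
#' @param excellent Stricter threshold set.
#' @return List with `n_met`, `flags`, `n_excellent`, `excellent_flags`.
#' @export
evaluate_fit <- function(fit,
                         thresholds = list(CFI = 0.90, NNFI = 0.90,
                                           RMSEA = 0.08, SRMR = 0.08),
                         excellent = list(CFI = 0.95, NNFI = 0.95,
                                          RMSEA = 0.05, SRMR = 0.05)) {
  if (inherits(fit, "usem_model")) fit <- fit$fit
  check <- function(th) c(
    CFI = isTRUE(fit$CFI >= th$CFI),
    NNFI = isTRUE(fit$NNFI >= th$NNFI),
    RMSEA = isTRUE(fit$RMSEA <= th$RMSEA),
    SRMR = isTRUE(fit$SRMR <= th$SRMR))
  flags <- check(thresholds)
  exc <- check(excellent)
  list(n_met = sum(flags), flags = flags,
       n_excellent = sum(exc), excellent_flags = exc)
}

#' Prune non-significant free paths from a fitted model
#'
#' Iteratively removes the least significant non-base free path whose
#' two-tailed z-test p-value is at or above `alpha`, refitting after each
#' removal. Autoregressive base paths (level `"null_base"`) are never
#' pruned; `levels` restricts which levels are considered.
#'
#' @param model A fitted [fit_usem()] model.
#' @param alpha Significance level (default 0.05).
#' @param levels Path levels eligible for pruning (default all but
#'   `"null_base"`).
#' @return The refitted, pruned `usem_model`.
#' @export
prune <- function(model, alpha = 0.05,
                  levels = setdiff(path_levels, "null_base")) {
  data <- model$data
  options <- model$options
  if (options$se == "none") {  # z statistics are needed for pruning
    options$se <- "expected"
    model <- fit_usem(data, model$free_paths[, c("from", "to", "lag",
                                                 "level")], options)
  }
  repeat {
    fp <- model$free_paths
    cand <- which(fp$level %in% levels)
    if (!length(cand)) break
    pvals <- 2 * stats::pnorm(-abs(fp$z[cand]))
    pvals[is.na(pvals)] <- 1
    worst <- cand[pvals >= alpha]
    if (!length(worst)) break
    ## least significant first; deterministic lexicographic tie-break
    ord <- order(-pvals[match(worst, cand)], fp$from[worst], fp$to[worst],
                 fp$lag[worst])
    drop_row <- worst[ord[1L]]
    keep <- fp[-drop_row, c("from", "to", "lag", "level"), drop = FALSE]
    se_opt <- options
    se_opt$se <- if (options$se == "none") "expected" else options$se
    model <- fit_usem(data, keep, se_opt)
  }
  model
}
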