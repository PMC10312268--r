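#' Subject-level network feature matrix
#'
#' Group-level paths become continuous per-subject beta columns (they are
#' estimated for every individual); subgroup- and individual-level paths
#' passing the prevalence filter become binary presence columns. Presence
#' columns constant across subjects are dropped with a warning.
#'
#' @param result A `cohort_search_result` from [finalize_individuals()].
#' @param min_fraction Prevalence threshold for presence features
#'   (default 0.20).
#' @return A `feature_matrix`: numeric matrix (subjects x features) with
#'   `attr(, "meta")` describing each column (from, to, lag, level,
#'   encoding).
#' @export
build_features <- function(result, min_fraction = 0.20) {
  models <- Filter(Negate(is.null), result$individual_models)
  ids <- names(models)
  n <- length(ids)
  meta <- list(); cols <- list()

  gp <- result$group_paths
  for (k in seq_len(NROW(gp))) {
    key <- path_key(gp[k, ])
    betas <- vapply(models, function(m) {
      row <- match(key, path_key(m$free_paths))
      m$free_paths$estimate[row]
    }, numeric(1))
    cols[[length(cols) + 1L]] <- betas
    meta[[length(meta) + 1L]] <- data.frame(
      from = gp$from[k], to = gp$to[k], lag = gp$lag[k], level = "group",
      encoding = "beta", stringsAsFactors = FALSE)
  }

  prev <- prevalence(models, min_fraction = min_fraction)
  for (k in seq_len(NROW(prev))) {
    key <- path_key(prev[k, ])
    pres <- vapply(models, function(m) {
      ps <- .model_paths(m)
      key %in% path_key(ps[ps$level %in% c("individual", "subgroup"), ])
    }, logical(1)) * 1
    if (stats::var(pres) == 0) {
      warning("dropping constant presence feature ", key)
      next
    }
    lev <- unique(unlist(lapply(models, function(m) {
      ps <- m$free_paths
      ps$level[path_key(ps) == key & ps$level %in%
                 c("individual", "subgroup")]
    })))
    cols[[length(cols) + 1L]] <- pres
    meta[[length(meta) + 1L]] <- data.frame(
      from = prev$from[k], to = prev$to[k], lag = prev$lag[k],
      level = if ("subgroup" %in% lev) "subgroup" else "individual",
      encoding = "presence", stringsAsFactors = FALSE)
  }

  if (!length(cols)) stop("empty feature set")
  meta <- do.call(rbind, meta)
  X <- do.call(cbind, cols)
  colnames(X) <- path_key(meta)
  rownames(X) <- ids
  attr(X, "meta") <- meta
  class(X) <- c("feature_matrix", class(X))
  X
}

#' Composite z-score across scales with missingness fallback
#'
#' Each scale's sum scores are standardized over the subjects providing
#' them; a subject's composite is the mean of their available z-scores
#' (a subject with one missing scale keeps the other alone).
#'
#' @param scale_scores Named list of per-subject numeric vectors (equal
#'   length, `NA` for missing).
#' @return Numeric composite vector; subjects missing all scales get
#'   `NA` with a warning.
#' @export
composite_z <- function(scale_scores) {
  stopifnot(length(scale_scores) >= 1L)
  lens <- lengths(scale_scores)
  if (length(unique(lens)) != 1L)
    stop("all scales must cover the same subjects")
  Z <- vapply(scale_scores, function(x)
    as.numeric(scale(x)), numeric(lens[1L]))
  out <- rowMeans(Z, na.rm = TRUE)
  all_missing <- rowSums(!is.na(Z)) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " subject(s) missing every scale")
    out[all_missing] <- NA_real_
  }
  out
}

#' Adaptive lasso with ridge-derived penalty factors
#'
#' Stage 1: ridge regression with `folds`-fold cross-validated penalty
#' gives coefficients `b_j`; per-feature penalty factors are
#' `1 / |b_j|^gamma` (coefficients below machine tolerance get a large
#' finite factor). Stage 2: an L1 path with those factors, penalty again
#' chosen by `folds`-fold cross-validation (minimum-CV-error rule by
#' default). Columns are standardized; R-squared values come from an
#' unpenalized refit on the selected set.
#'
#' @param X Numeric matrix (subjects x features) or `feature_matrix`.
#' @param y Outcome vector (numeric, or binary 0/1 with
#'   `family = "binomial"`).
#' @param folds Cross-validation folds (default 10).
#' @param gamma Adaptive-weight exponent (default 1).
#' @param seed Integer seed for fold assignment.
#' @param family `"gaussian"` or `"binomial"`.
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @return An `assoc_result` list: `selected` data.frame (feature,
#'   coefficient, plus metadata when available), `penalty_factors`,
#'   `lambda`, `r2`, `adj_r2`, `r2_penalized`, and the fitted stage-2
#'   object.
#' @export
adaptive_lasso <- function(X, y, folds = 10, gamma = 1, seed = 1L,
                           family = c("gaussian", "binomial"),
                           lambda_rule = c("min", "1se")) {
  family <- match.arg(family)
  lambda_rule <- match.arg(lambda_rule)
  meta <- attr(X, "meta")
  X <- unclass(as.matrix(X))
  n <- nrow(X)
  if (n <= folds) stop("need more observations than folds")
  if (stats::var(y) == 0) stop("degenerate outcome: zero variance")
  keep <- apply(X, 2L, stats::var) > 0
  if (!all(keep)) {
    warning("dropping constant feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
    if (!is.null(meta)) meta <- meta[keep, , drop = FALSE]
  }
  Xs <- scale(X)

  withr::local_seed(seed)
  foldid <- sample(rep_len(seq_len(folds), n))
  ridge <- glmnet::cv.glmnet(Xs, y, alpha = 0, foldid = foldid,
                             family = family, standardize = FALSE)
  b <- as.numeric(stats::coef(ridge, s = "lambda.min"))[-1L]
  w <- 1 / pmax(abs(b), .Machine$double.eps^0.5)^gamma

  lasso <- glmnet::cv.glmnet(Xs, y, alpha = 1, foldid = foldid,
                             penalty.factor = w, family = family,
                             standardize = FALSE)
  s <- if (lambda_rule == "min") "lambda.min" else "lambda.1se"
  coefs <- as.numeric(stats::coef(lasso, s = s))[-1L]
  sel <- which(coefs != 0)

  selected <- data.frame(feature = colnames(X)[sel],
                         coefficient = coefs[sel],
                         stringsAsFactors = FALSE)
  if (!is.null(meta) && NROW(selected))
    selected <- cbind(selected, meta[sel, , drop = FALSE])

  r2 <- adj_r2 <- 0
  if (length(sel)) {
    refit <- .joint_fit(X[, sel, drop = FALSE], y, family)
    r2 <- refit$r2; adj_r2 <- refit$adj_r2
  }
  ## penalized-prediction R2 for transparency
  pred <- drop(stats::predict(lasso, Xs, s = s, type = "response"))
  r2_pen <- if (family == "gaussian")
    1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  else stats::cor(pred, y)^2

  structure(list(selected = selected, penalty_factors = w,
                 lambda = lasso[[s]],
                 r2 = r2, adj_r2 = adj_r2, r2_penalized = r2_pen,
                 family = family, cv_fit = lasso, foldid = foldid),
            class = "assoc_result")
}

.joint_fit <- function(Xsel, y, family) {
  df <- data.frame(y = y, Xsel, check.names = TRUE)
  if (family == "gaussian") {
    fit <- stats::lm(y ~ ., data = df)
    sm <- summary(fit)
    list(fit = fit, r2 = sm$r.squared, adj_r2 = sm$adj.r.squared)
  } else {
    fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
    ## McFadden pseudo-R2, adjusted by parameter count
    ll <- as.numeric(stats::logLik(fit))
    ll0 <- as.numeric(stats::logLik(stats::glm(y ~ 1, data = df,
                                               family = stats::binomial())))
    k <- length(stats::coef(fit)) - 1L
    list(fit = fit, r2 = 1 - ll / ll0, adj_r2 = 1 - (ll - k) / ll0)
  }
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> %d selected feature(s), lambda=%.4g, R2=%.3f (adj %.3f)\n",
              NROW(x$selected), x$lambda, x$r2, x$adj_r2))
  if (NROW(x$selected)) print(x$selected, row.names = FALSE)
  invisible(x)
}

#' Post hoc per-feature regressions for a selected feature set
#'
#' One simple regression of the outcome on each selected feature
#' (estimate, SE, p), plus a joint OLS on the full selected set for the
#' R-squared report.
#'
#' @param X_selected Numeric matrix of the selected features.
#' @param y Outcome vector.
#' @param family `"gaussian"` or `"binomial"`.
#' @return List with `per_feature` data.frame and `r2`, `adj_r2` from
#'   the joint fit.
#' @export
posthoc_ols <- function(X_selected, y,
                        family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  X_selected <- as.matrix(X_selected)
  if (!ncol(X_selected)) stop("selected set is empty")
  rows <- lapply(seq_len(ncol(X_selected)), function(j) {
    if (family == "gaussian") {
      sm <- summary(stats::lm(y ~ X_selected[, j]))
      cf <- sm$coefficients[2L, ]
    } else {
      sm <- summary(stats::glm(y ~ X_selected[, j],
                               family = stats::binomial()))
      cf <- sm$coefficients[2L, ]
    }
    data.frame(feature = colnames(X_selected)[j] %||% paste0("f", j),
               estimate = cf[1L], se = cf[2L], p = cf[4L],
               stringsAsFactors = FALSE)
  })
  joint <- .joint_fit(X_selected, y, family)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(per_feature = out, r2 = joint$r2, adj_r2 = joint$adj_r2,
       joint_fit = joint$fit)
}

#' Subgroup ANOVAs with Benjamini-Hochberg correction
#'
#' One-way ANOVA per outcome across subgroup membership, BH-adjusted over
#' the outcome family; pairwise Welch t-tests only for outcomes whose
#' adjusted q-value is below `alpha`.
#'
#' @param outcomes Data.frame or matrix (subjects x outcomes).
#' @param membership Subgroup labels.
#' @param alpha FDR level gating pairwise tests (default 0.05).
#' @return List with `omnibus` (outcome, F, df1, df2, p, q) and
#'   `pairwise` (outcome, group1, group2, t, p) data.frames.
#' @export
subgroup_anova <- function(outcomes, membership, alpha = 0.05) {
  outcomes <- as.data.frame(outcomes)
  membership <- factor(membership)
  sizes <- table(membership)
  if (length(sizes) < 2L)
    stop("need at least 2 subgroups")
  rows <- list(); skipped <- character()
  for (nm in names(outcomes)) {
    y <- outcomes[[nm]]
    keep <- !is.na(y)
    tab <- table(membership[keep])
    if (any(tab < 2L) || length(tab) < 2L) {
      warning("skipping outcome ", nm, ": a subgroup has < 2 members")
      skipped <- c(skipped, nm)
      next
    }
    an <- stats::anova(stats::lm(y[keep] ~ membership[keep]))
    rows[[nm]] <- data.frame(outcome = nm, F = an$`F value`[1L],
                             df1 = an$Df[1L], df2 = an$Df[2L],
                             p = an$`Pr(>F)`[1L],
                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(list(omnibus = NULL, pairwise = NULL, skipped = skipped))
  omnibus <- do.call(rbind, rows)
  omnibus$q <- stats::p.adjust(omnibus$p, method = "BH")
  rownames(omnibus) <- NULL

  pw <- list()
  labs <- levels(membership)
  for (nm in omnibus$outcome[omnibus$q < alpha]) {
    y <- outcomes[[nm]]
    for (a in seq_along(labs)) for (b in seq_along(labs)) {
      if (a >= b) next
      ya <- y[membership == labs[a] & !is.na(y)]
      yb <- y[membership == labs[b] & !is.na(y)]
      if (length(ya) < 2L || length(yb) < 2L) next
      tt <- stats::t.test(ya, yb)
      pw[[length(pw) + 1L]] <- data.frame(
        outcome = nm, group1 = labs[a], group2 = labs[b],
        t = unname(tt$statistic), p = tt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  list(omnibus = omnibus,
       pairwise = if (length(pw)) do.call(rbind, pw) else NULL,
       skipped = skipped)
}
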