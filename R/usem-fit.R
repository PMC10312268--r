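#' Estimation options for unified SEM fitting
#'
#' @param max_iter Optimizer iteration cap (default 500).
#' @param grad_tol Convergence tolerance on the max-norm of the fit
#'   function gradient (default 1e-6).
#' @param se Standard-error method: `"observed"` (inverse observed
#'   information via a finite-difference Jacobian of the analytic
#'   gradient), `"expected"` (inverse Fisher information), or `"none"`.
#' @param lag_exo_candidates Are lagged exogenous effects candidate paths
#'   in searches (default `FALSE`: exogenous inputs act contemporaneously)?
#' @param mi_alpha Significance level for modification-index tests
#'   (default 0.05).
#' @param mi_crit Chi-square(1) critical value declaring a single
#'   modification index significant (default `qchisq(1 - mi_alpha, 1)`);
#'   used for the group-level majority counting.
#' @param stop_rule Stopping rule for the greedy searches:
#'   `"mi_bonferroni"` (default) continues while any candidate MI
#'   exceeds the Bonferroni-corrected chi-square(1) critical value over
#'   the current candidate count — the search runs until no edge would
#'   still improve fit beyond multiplicity-corrected chance;
#'   `"mi"` uses the uncorrected critical value; `"excellent"` stops as
#'   soon as two of the four fit indices reach the excellent thresholds
#'   (CFI/NNFI >= .95, RMSEA/SRMR <= .05) or no uncorrected-significant
#'   candidate remains.
#' @param ar_base Free autoregressive (lag-1 self) paths in the null model
#'   of every search (default `TRUE`).
#' @return A list of class `usem_options`.
#' @export
usem_options <- function(max_iter = 500, grad_tol = 1e-6,
                         se = c("observed", "expected", "none"),
                         lag_exo_candidates = FALSE,
                         mi_alpha = 0.05,
                         mi_crit = stats::qchisq(1 - mi_alpha, 1),
                         stop_rule = c("mi_bonferroni", "mi",
                                       "excellent"),
                         ar_base = TRUE) {
  structure(list(max_iter = max_iter, grad_tol = grad_tol,
                 se = match.arg(se),
                 lag_exo_candidates = lag_exo_candidates,
                 mi_alpha = mi_alpha, mi_crit = mi_crit,
                 stop_rule = match.arg(stop_rule), ar_base = ar_base),
            class = "usem_options")
}

## Map each path to its coefficient matrix entry.
## type "A": contemporaneous endogenous -> endogenous, entry A[i, j]
## type "B": predictor-block coefficient, entry B[i, j] with j indexing
##           [x.l1 | u.l1 | u] columns.
.param_index <- function(data, free_paths) {
  validate_path_set(free_paths, exo_names = data$exo_names)
  n <- NROW(free_paths)
  type <- character(n); i <- integer(n); j <- integer(n)
  for (k in seq_len(n)) {
    fr <- free_paths$from[k]; to <- free_paths$to[k]
    lag <- free_paths$lag[k]
    ti <- match(to, data$node_names)
    if (is.na(ti)) stop("unknown target node: ", to)
    if (fr %in% data$node_names) {
      fi <- match(fr, data$node_names)
      if (lag == 0L) { type[k] <- "A"; i[k] <- ti; j[k] <- fi }
      else { type[k] <- "B"; i[k] <- ti; j[k] <- data$pos$xlag[fi] }
    } else if (fr %in% data$exo_names) {
      fi <- match(fr, data$exo_names)
      if (lag == 0L) { type[k] <- "B"; i[k] <- ti; j[k] <- data$pos$u[fi] }
      else {
        if (!data$include_lagged_exo)
          stop("lagged exogenous path requested but u_{t-1} not in data: ",
               fr, "->", to)
        type[k] <- "B"; i[k] <- ti; j[k] <- data$pos$ulag[fi]
      }
    } else stop("unknown source node: ", fr)
  }
  keys <- path_key(free_paths)
  if (anyDuplicated(keys))
    stop("duplicate free paths: ",
         paste(keys[duplicated(keys)], collapse = ", "))
  data.frame(type = type, i = i, j = j, stringsAsFactors = FALSE)
}

## Shared fitting machinery: closures over (data, free_paths).
## theta = c(path coefficients, log residual variances).
.usem_machine <- function(data, free_paths) {
  S <- data$S; p <- data$p; mv <- data$mv; m <- data$m
  vi <- seq_len(mv); xi <- data$pos$x
  Svv <- S[vi, vi, drop = FALSE]
  Sxx <- S[xi, xi, drop = FALSE]
  cS <- tryCatch(chol(S), error = function(e)
    stop("rank-deficient data: sample covariance is not positive definite"))
  logdetS <- 2 * sum(log(diag(cS)))
  idx <- .param_index(data, free_paths)
  nb <- nrow(idx)
  nfree <- nb + p

  unpack <- function(theta) {
    A <- matrix(0, p, p); B <- matrix(0, p, mv)
    if (nb) {
      isA <- idx$type == "A"
      A[cbind(idx$i[isA], idx$j[isA])] <- theta[seq_len(nb)][isA]
      B[cbind(idx$i[!isA], idx$j[!isA])] <- theta[seq_len(nb)][!isA]
    }
    list(A = A, B = B, psi = exp(theta[nb + seq_len(p)]))
  }

  common <- function(theta) {
    par <- unpack(theta)
    G <- tryCatch(solve(diag(p) - par$A), error = function(e) NULL)
    if (is.null(G) || !all(is.finite(G))) return(NULL)
    GB <- G %*% par$B
    GBS <- GB %*% Svv
    Sxx_mod <- tcrossprod(GBS, GB) + G %*% (par$psi * t(G))
    Sigma <- matrix(0, m, m)
    Sigma[vi, vi] <- Svv
    Sigma[xi, vi] <- GBS
    Sigma[vi, xi] <- t(GBS)
    Sigma[xi, xi] <- Sxx_mod
    R <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Siginv <- chol2inv(R)
    logdet <- 2 * sum(log(diag(R)))
    Fval <- logdet + sum(S * Siginv) - logdetS - m
    list(par = par, G = G, GBS = GBS, Sxx_mod = Sxx_mod, Sigma = Sigma,
         Siginv = Siginv, Fval = Fval)
  }

  ## cache the last evaluation so fn and gr at the same theta share work
  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL
  get_common <- function(theta) {
    if (!is.null(cache$theta) && identical(cache$theta, theta))
      return(cache$cm)
    cm <- common(theta)
    cache$theta <- theta; cache$cm <- cm
    cm
  }

  fn <- function(theta) {
    cm <- get_common(theta)
    if (is.null(cm) || !is.finite(cm$Fval)) return(1e10)
    cm$Fval
  }

  ## gradient matrices over ALL matrix entries (also used for MI scores)
  grad_mats <- function(cm) {
    E <- cm$Siginv - cm$Siginv %*% S %*% cm$Siginv
    Exv <- E[xi, vi, drop = FALSE]
    Exx <- E[xi, xi, drop = FALSE]
    tG <- t(cm$G)
    MA <- 2 * (tG %*% Exv %*% t(cm$GBS) + tG %*% Exx %*% cm$Sxx_mod)
    MB <- 2 * (tG %*% Exv %*% Svv + tG %*% Exx %*% cm$GBS)
    Mpsi <- colSums(cm$G * (Exx %*% cm$G))
    list(MA = MA, MB = MB, Mpsi = Mpsi, Exv = Exv, Exx = Exx)
  }

  gr <- function(theta) {
    cm <- get_common(theta)
    if (is.null(cm)) return(rep(0, nfree))
    gm <- grad_mats(cm)
    g <- numeric(nfree)
    if (nb) {
      isA <- idx$type == "A"
      g[seq_len(nb)][isA] <- gm$MA[cbind(idx$i[isA], idx$j[isA])]
      g[seq_len(nb)][!isA] <- gm$MB[cbind(idx$i[!isA], idx$j[!isA])]
    }
    g[nb + seq_len(p)] <- cm$par$psi * gm$Mpsi
    g
  }

  ## per-equation OLS starting values (ignoring simultaneity)
  theta_start <- function() {
    beta <- numeric(nb); psi <- diag(Sxx)
    for (eq in seq_len(p)) {
      rows <- which(idx$i == eq)
      if (!length(rows)) next
      pred <- ifelse(idx$type[rows] == "A", xi[idx$j[rows]], idx$j[rows])
      b <- tryCatch(solve(S[pred, pred, drop = FALSE], S[pred, xi[eq]]),
                    error = function(e) rep(0, length(pred)))
      beta[rows] <- b
      res <- Sxx[eq, eq] - sum(S[xi[eq], pred] * b)
      psi[eq] <- max(res, 0.05 * Sxx[eq, eq])
    }
    c(beta, log(psi))
  }

  list(fn = fn, gr = gr, common = common, grad_mats = grad_mats,
       unpack = unpack, theta_start = theta_start, idx = idx,
       nb = nb, nfree = nfree, Svv = Svv, Sxx = Sxx,
       vi = vi, xi = xi, logdetS = logdetS)
}

## Derivative of Sigma wrt one parameter, as a dense m x m matrix.
## Used by the information machinery (MI, expected SEs).
.dsigma <- function(type, i, j, cm, mach, m) {
  dS <- matrix(0, m, m)
  vi <- mach$vi; xi <- mach$xi
  G <- cm$G
  if (type == "A") {
    dxv <- outer(G[, i], cm$GBS[j, ])
    Rx <- outer(G[, i], cm$Sxx_mod[j, ])
    dS[xi, vi] <- dxv; dS[vi, xi] <- t(dxv)
    dS[xi, xi] <- Rx + t(Rx)
  } else if (type == "B") {
    dxv <- outer(G[, i], mach$Svv[j, ])
    Rx <- outer(G[, i], cm$GBS[, j])
    dS[xi, vi] <- dxv; dS[vi, xi] <- t(dxv)
    dS[xi, xi] <- Rx + t(Rx)
  } else { # psi
    dS[xi, xi] <- outer(G[, i], G[, i])
  }
  dS
}

## Expected (Fisher) information factor H with H_jk = tr(Siginv dSigma_j
## Siginv dSigma_k), over an arbitrary parameter list (natural psi scale).
.expected_H <- function(params, cm, mach, m) {
  k <- nrow(params)
  D <- matrix(0, m * m, k)
  U <- matrix(0, m * m, k)
  for (jj in seq_len(k)) {
    dS <- .dsigma(params$type[jj], params$i[jj], params$j[jj], cm, mach, m)
    D[, jj] <- dS
    U[, jj] <- cm$Siginv %*% dS %*% cm$Siginv
  }
  H <- crossprod(U, D)
  (H + t(H)) / 2
}

#' Fit a unified SEM by maximum likelihood
#'
#' Maximizes the multivariate-normal likelihood of the lag-augmented
#' observation vector in which the predictor block (lagged endogenous plus
#' exogenous) is saturated and the endogenous block follows
#' `x_t = A x_t + Phi x_{t-1} + Lambda u_t + zeta`, with `zeta ~ N(0,
#' diag(Psi))`. Reports estimates, standard errors, z statistics, the
#' discrepancy `F_ml`, `chi2 = (n - 1) F_ml`, degrees of freedom, and the
#' CFI/NNFI/RMSEA/SRMR fit indices against the independence baseline.
#'
#' @param data A [lag_augment()] dataset.
#' @param free_paths Path set of free directed paths.
#' @param options A [usem_options()] list.
#' @return An object of class `usem_model`.
#' @export
fit_usem <- function(data, free_paths = empty_path_set(),
                     options = usem_options()) {
  mach <- .usem_machine(data, free_paths)
  theta0 <- mach$theta_start()
  opt <- stats::optim(theta0, mach$fn, mach$gr, method = "BFGS",
                      control = list(maxit = options$max_iter,
                                     reltol = 1e-12))
  g <- mach$gr(opt$par)
  if (max(abs(g)) >= options$grad_tol) {
    opt2 <- stats::optim(opt$par, mach$fn, mach$gr, method = "BFGS",
                         control = list(maxit = options$max_iter,
                                        reltol = 1e-14))
    if (opt2$value <= opt$value) opt <- opt2
    g <- mach$gr(opt$par)
  }
  converged <- max(abs(g)) < options$grad_tol
  theta <- opt$par
  cm <- mach$common(theta)
  if (is.null(cm)) stop("estimation failed: implied covariance degenerate")
  par <- cm$par

  n_eff <- data$n_eff
  N <- n_eff - 1
  Fval <- cm$Fval
  npar_free <- mach$nfree
  npar <- npar_free + data$mv * (data$mv + 1) / 2
  df <- data$m * (data$m + 1) / 2 - npar
  chi2 <- max(N * Fval, 0)
  loglik <- -(n_eff / 2) *
    (data$m * log(2 * pi) + log(det(cm$Sigma)) + sum(data$S * cm$Siginv))

  fp <- free_paths
  fp$estimate <- if (mach$nb) theta[seq_len(mach$nb)] else numeric(0)
  fp$se <- rep(NA_real_, NROW(fp))
  fp$z <- rep(NA_real_, NROW(fp))

  if (options$se != "none" && mach$nb) {
    se <- .usem_se(theta, cm, mach, data, options)
    fp$se <- se
    fp$z <- ifelse(is.finite(se) & se > 0, fp$estimate / se, NA_real_)
  }

  fit <- list(F_ml = Fval, chi2 = chi2, df = df, n_effective = n_eff,
              loglik = loglik, converged = converged)
  model <- structure(list(
    node_names = data$node_names, exo_names = data$exo_names,
    free_paths = fp,
    params = .param_set(par, data),
    fit = fit, converged = converged, theta = theta,
    options = options, data = data,
    grad_norm = max(abs(g)), opt_value = opt$value), class = "usem_model")
  model$fit <- fit_indices(model)
  model
}

## Standard errors for path coefficients.
.usem_se <- function(theta, cm, mach, data, options) {
  N <- data$n_eff - 1
  nb <- mach$nb
  se <- rep(NA_real_, nb)
  if (options$se == "observed") {
    k <- length(theta)
    Hn <- matrix(0, k, k)
    h <- 1e-5 * pmax(abs(theta), 1)
    for (j in seq_len(k)) {
      tp <- theta; tp[j] <- tp[j] + h[j]
      tm <- theta; tm[j] <- tm[j] - h[j]
      Hn[, j] <- (mach$gr(tp) - mach$gr(tm)) / (2 * h[j])
    }
    Hn <- (Hn + t(Hn)) / 2
    info <- (N / 2) * Hn
    V <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(V)) {
      d <- diag(V)[seq_len(nb)]
      if (all(is.finite(d)) && all(d > 0)) return(sqrt(d))
    }
    ## fall through to expected information
  }
  params <- rbind(mach$idx,
                  data.frame(type = "psi", i = seq_len(data$p),
                             j = seq_len(data$p)))
  H <- .expected_H(params, cm, mach, data$m)
  ## chain rule to log-psi scale to match theta parameterization
  psi <- cm$par$psi
  sc <- c(rep(1, nb), psi)
  H <- H * outer(sc, sc)
  V <- tryCatch(solve((N / 2) * H), error = function(e) NULL)
  if (!is.null(V)) {
    d <- diag(V)[seq_len(nb)]
    d[!is.finite(d) | d <= 0] <- NA_real_
    se <- sqrt(d)
  }
  se
}

## Expose the fitted coefficient matrices in domain terms.
.param_set <- function(par, data) {
  p <- data$p; q <- data$q
  Phi_endo <- par$B[, data$pos$xlag, drop = FALSE]
  colnames(Phi_endo) <- data$node_names
  Phi_exo <- if (data$include_lagged_exo)
    par$B[, data$pos$ulag, drop = FALSE] else matrix(0, p, q)
  if (q) colnames(Phi_exo) <- data$exo_names
  Lambda <- if (q) par$B[, data$pos$u, drop = FALSE] else matrix(0, p, 0)
  if (q) colnames(Lambda) <- data$exo_names
  A <- par$A
  dimnames(A) <- list(data$node_names, data$node_names)
  rownames(Phi_endo) <- data$node_names
  Phi <- cbind(Phi_endo, Phi_exo)
  list(A = A, Phi = Phi, Lambda = Lambda, Psi = stats::setNames(
    par$psi, data$node_names))
}

#' @export
print.usem_model <- function(x, ...) {
  cat(sprintf("<usem_model> %d nodes, %d free paths, chi2=%.2f (df=%d), converged=%s\n",
              length(x$node_names), NROW(x$free_paths), x$fit$chi2,
              x$fit$df, x$converged))
  if (!is.null(x$fit$CFI))
    cat(sprintf("  CFI=%.3f NNFI=%.3f RMSEA=%.3f SRMR=%.3f\n",
                x$fit$CFI, x$fit$NNFI, x$fit$RMSEA, x$fit$SRMR))
  invisible(x)
}

#' Enumerate candidate paths not yet free
#'
#' All contemporaneous endogenous pairs (no self loops), all lag-1
#' endogenous entries (including autoregressive), contemporaneous
#' exogenous effects, and (if enabled) lagged exogenous effects — minus
#' the paths already free.
#'
#' @param data A [lag_augment()] dataset.
#' @param free_paths Currently free path set.
#' @param options A [usem_options()] list.
#' @return A path set of candidates (level `NA`-free, tagged
#'   `"individual"` by default).
#' @export
candidate_paths <- function(data, free_paths = empty_path_set(),
                            options = usem_options()) {
  nn <- data$node_names; en <- data$exo_names
  cand <- list()
  grid <- expand.grid(from = nn, to = nn, stringsAsFactors = FALSE)
  cand$contemp <- data.frame(from = grid$from[grid$from != grid$to],
                             to = grid$to[grid$from != grid$to],
                             lag = 0L, stringsAsFactors = FALSE)
  cand$lag1 <- data.frame(from = grid$from, to = grid$to, lag = 1L,
                          stringsAsFactors = FALSE)
  if (length(en)) {
    ge <- expand.grid(from = en, to = nn, stringsAsFactors = FALSE)
    cand$exo <- data.frame(from = ge$from, to = ge$to, lag = 0L,
                           stringsAsFactors = FALSE)
    if (options$lag_exo_candidates && data$include_lagged_exo)
      cand$exo_lag <- data.frame(from = ge$from, to = ge$to, lag = 1L,
                                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, cand)
  out$level <- "individual"
  rownames(out) <- NULL
  out <- order_paths(out)
  out[!path_key(out) %in% path_key(free_paths), , drop = FALSE]
}
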