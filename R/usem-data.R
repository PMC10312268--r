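#' Lag-augment time series into the paired-sample dataset for uSEM
#'
#' Builds observation vectors `z_t = [x_{t-1}; u_{t-1}; u_t; x_t]` for all
#' t inside segments (no pair spans a segment boundary) and returns their
#' maximum-likelihood sample covariance together with the effective sample
#' size `n = sum(segment length - 1)`.
#'
#' @param series A single [roi_timeseries()] or a list of them (e.g. a
#'   cohort to concatenate); every element contributes one segment.
#' @param boundaries Optional integer vector of segment lengths splitting
#'   a single series into additional segments (must sum to T).
#' @param include_lagged_exo Include `u_{t-1}` in the observation vector
#'   (default `TRUE`).
#' @return An object of class `usem_data`: the sample covariance `S`, the
#'   effective sample size `n_eff`, dimensions and name/index bookkeeping.
#' @export
lag_augment <- function(series, boundaries = NULL,
                        include_lagged_exo = TRUE) {
  if (inherits(series, "roi_timeseries")) {
    if (is.null(boundaries)) {
      segs <- list(series)
    } else {
      if (sum(boundaries) != nrow(series$values))
        stop("segment lengths must sum to T")
      start <- cumsum(c(1L, utils::head(boundaries, -1L)))
      segs <- lapply(seq_along(boundaries), function(k) {
        idx <- start[k]:(start[k] + boundaries[k] - 1L)
        list(values = series$values[idx, , drop = FALSE],
             exogenous = series$exogenous[idx, , drop = FALSE])
      })
    }
  } else if (is.list(series) && length(series) &&
             all(vapply(series, inherits, logical(1), "roi_timeseries"))) {
    nn <- colnames(series[[1L]]$values)
    en <- colnames(series[[1L]]$exogenous)
    for (s in series)
      if (!identical(colnames(s$values), nn) ||
          !identical(colnames(s$exogenous), en))
        stop("all series must share node and exogenous names")
    segs <- series
  } else {
    stop("series must be an roi_timeseries or a list of them")
  }

  ref <- if (inherits(series, "roi_timeseries")) series else series[[1L]]
  node_names <- colnames(ref$values)
  exo_names <- colnames(ref$exogenous)
  p <- length(node_names)
  q <- length(exo_names)
  if (q == 0L) include_lagged_exo <- FALSE

  rows <- lapply(segs, function(s) {
    X <- s$values; U <- s$exogenous; Tk <- nrow(X)
    if (Tk < 2L) return(NULL)
    cbind(X[-Tk, , drop = FALSE],
          if (include_lagged_exo) U[-Tk, , drop = FALSE],
          U[-1L, , drop = FALSE],
          X[-1L, , drop = FALSE])
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    stop("no usable lag pairs: every segment has length < 2")
  Z <- do.call(rbind, rows)
  n_eff <- nrow(Z)

  q_lag <- if (include_lagged_exo) q else 0L
  v_names <- c(paste0(node_names, ".l1"),
               if (include_lagged_exo) paste0(exo_names, ".l1"),
               exo_names)
  var_names <- c(v_names, node_names)
  colnames(Z) <- var_names
  Zc <- sweep(Z, 2L, colMeans(Z))
  S <- crossprod(Zc) / n_eff

  mv <- p + q_lag + q
  structure(list(
    S = S, n_eff = n_eff, p = p, q = q,
    include_lagged_exo = include_lagged_exo,
    node_names = node_names, exo_names = exo_names,
    v_names = v_names, var_names = var_names,
    m = mv + p, mv = mv,
    pos = list(xlag = seq_len(p),
               ulag = if (q_lag) p + seq_len(q) else integer(),
               u = p + q_lag + seq_len(q),
               x = mv + seq_len(p)),
    n_segments = length(rows)), class = "usem_data")
}

#' @export
print.usem_data <- function(x, ...) {
  cat(sprintf("<usem_data> %d nodes, %d exogenous, n_eff=%d pairs (%d segment%s)\n",
              x$p, x$q, x$n_eff, x$n_segments,
              if (x$n_segments == 1L) "" else "s"))
  invisible(x)
}
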