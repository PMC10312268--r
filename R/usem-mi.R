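#' Modification indices for a fitted unified SEM
#'
#' For every candidate fixed path, the 1-df score-test statistic (MI)
#' estimating the chi-square improvement from freeing that path, and the
#' expected parameter change (EPC). Candidates exclude paths into
#' exogenous nodes and contemporaneous self loops.
#'
#' @param model A fitted [fit_usem()] model.
#' @param data Optional [lag_augment()] dataset (defaults to the data the
#'   model was fitted on).
#' @param candidates Optional explicit candidate path set.
#' @return A `data.frame` (`from`, `to`, `lag`, `mi`, `epc`) sorted by
#'   decreasing MI with deterministic lexicographic tie-breaks.
#' @export
modification_indices <- function(model, data = NULL, candidates = NULL) {
  data <- data %||% model$data
  options <- model$options
  if (is.null(candidates))
    candidates <- candidate_paths(data, model$free_paths, options)
  if (!NROW(candidates))
    return(data.frame(from = character(), to = character(),
                      lag = integer(), mi = numeric(), epc = numeric()))
  mach <- .usem_machine(data, model$free_paths)
  cm <- mach$common(model$theta)
  if (is.null(cm)) stop("model state degenerate; refit before computing MIs")
  gm <- mach$grad_mats(cm)

  cidx <- .param_index(data, candidates)
  free_params <- rbind(mach$idx,
                       data.frame(type = "psi", i = seq_len(data$p),
                                  j = seq_len(data$p)))
  all_params <- rbind(free_params, cidx)
  H <- .expected_H(all_params, cm, mach, data$m)
  nf <- nrow(free_params)
  nc <- nrow(cidx)
  fidx <- seq_len(nf)
  Hff <- H[fidx, fidx, drop = FALSE]
  Hfc <- H[fidx, nf + seq_len(nc), drop = FALSE]
  Hcc <- diag(H)[nf + seq_len(nc)]

  cond <- tryCatch({
    W <- solve(Hff, Hfc)
    Hcc - colSums(Hfc * W)
  }, error = function(e) {
    warning("singular information matrix; conditioning MIs on diagonal only")
    Hcc
  })

  ## score of the fit function for each candidate entry
  dF <- numeric(nc)
  isA <- cidx$type == "A"
  dF[isA] <- gm$MA[cbind(cidx$i[isA], cidx$j[isA])]
  dF[!isA] <- gm$MB[cbind(cidx$i[!isA], cidx$j[!isA])]

  N <- data$n_eff - 1
  bad <- !is.finite(cond) | cond <= 1e-10
  if (any(bad))
    warning(sum(bad), " candidate(s) with degenerate information; MI set to NA")
  mi <- ifelse(bad, NA_real_, (N / 2) * dF^2 / cond)
  epc <- ifelse(bad, NA_real_, -dF / cond)

  out <- data.frame(from = candidates$from, to = candidates$to,
                    lag = candidates$lag, mi = mi, epc = epc,
                    stringsAsFactors = FALSE)
  out[order(-out$mi, out$from, out$to, out$lag), , drop = FALSE]
}
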