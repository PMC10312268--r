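#' Overlap between an aggregate network and idiographic networks
#'
#' Counts, per subject, the discovered paths shared with the aggregate
#' model (matching on from/to/lag, presence only). "Sharing less than
#' half" means a shared count below `ceiling(|aggregate| / 2)`.
#' Autoregressive base paths are excluded by default since they are
#' freed, not discovered.
#'
#' @param aggregate A `usem_model` from [search_aggregate()] (or a path
#'   set).
#' @param individuals List of per-subject `usem_model`s (or path sets).
#' @param include_base Count `null_base` paths too (default `FALSE`).
#' @return An `overlap_summary` list: per-subject shared counts, the
#'   aggregate path count, median/mean shared, the count and fraction of
#'   subjects sharing less than half, and the ids attaining the
#'   max/median/min counts.
#' @export
path_overlap <- function(aggregate, individuals, include_base = FALSE) {
  agg <- .model_paths(aggregate, include_base)
  vocab <- .model_vocab(aggregate)
  shared <- vapply(seq_along(individuals), function(i) {
    v <- .model_vocab(individuals[[i]])
    if (!is.null(vocab) && !is.null(v) && !setequal(vocab, v))
      stop("node vocabulary mismatch for subject ", i, ": ",
           paste(union(setdiff(vocab, v), setdiff(v, vocab)),
                 collapse = ", "))
    length(intersect(path_key(agg),
                     path_key(.model_paths(individuals[[i]],
                                           include_base))))
  }, numeric(1))
  ids <- names(individuals) %||% as.character(seq_along(individuals))
  half <- ceiling(NROW(agg) / 2)
  below <- shared < half
  med <- stats::median(shared)
  structure(list(
    shared = stats::setNames(shared, ids),
    n_aggregate = NROW(agg),
    median_shared = med, mean_shared = mean(shared),
    below_half_count = sum(below),
    below_half_fraction = mean(below),
    max_id = ids[which.max(shared)],
    median_id = ids[which.min(abs(shared - med))],
    min_id = ids[which.min(shared)]), class = "overlap_summary")
}

.model_paths <- function(x, include_base = FALSE) {
  ps <- if (inherits(x, "usem_model")) x$free_paths else x
  if (!include_base) ps <- ps[ps$level != "null_base", , drop = FALSE]
  ps
}

.model_vocab <- function(x) {
  if (inherits(x, "usem_model")) c(x$node_names, x$exo_names) else NULL
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("<overlap_summary> %d aggregate paths; median shared %.1f (mean %.1f)\n",
              x$n_aggregate, x$median_shared, x$mean_shared))
  cat(sprintf("  %d of %d subjects (%.0f%%) share less than half\n",
              x$below_half_count, length(x$shared),
              100 * x$below_half_fraction))
  invisible(x)
}

#' Prevalence of non-group paths across individual models
#'
#' Counts, for each discovered path (levels other than group or base),
#' the number of subjects whose final model retains it, and keeps paths
#' present for at least `ceiling(min_fraction * n)` subjects.
#'
#' @param individuals List of per-subject `usem_model`s or path sets.
#' @param min_fraction Prevalence threshold (default 0.20).
#' @param levels Path levels counted (default `"individual"` and
#'   `"subgroup"`).
#' @return `data.frame` (from, to, lag, count) sorted by decreasing
#'   count with lexicographic tie-breaks.
#' @export
prevalence <- function(individuals, min_fraction = 0.20,
                       levels = c("individual", "subgroup")) {
  n <- length(individuals)
  counts <- list()
  for (m in individuals) {
    ps <- .model_paths(m)
    ps <- ps[ps$level %in% levels, , drop = FALSE]
    for (key in path_key(ps))
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  if (!length(counts))
    return(data.frame(from = character(), to = character(),
                      lag = integer(), count = integer()))
  paths <- key_to_path(names(counts))
  out <- data.frame(paths[, c("from", "to", "lag")],
                    count = unlist(counts, use.names = FALSE))
  out <- out[out$count >= ceiling(min_fraction * n), , drop = FALSE]
  out <- out[order(-out$count, out$from, out$to, out$lag), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare two path sets
#'
#' Exact partition of the union by (from, to, lag).
#'
#' @param set_a,set_b Path sets (or `usem_model`s).
#' @return List with `shared`, `only_a`, `only_b` path sets.
#' @export
compare_path_sets <- function(set_a, set_b) {
  a <- .model_paths(set_a); b <- .model_paths(set_b)
  ka <- path_key(a); kb <- path_key(b)
  list(shared = a[ka %in% kb, , drop = FALSE],
       only_a = a[!ka %in% kb, , drop = FALSE],
       only_b = b[!kb %in% ka, , drop = FALSE])
}
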