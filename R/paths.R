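#' Construct a set of directed network paths
#'
#' A path set is a plain `data.frame` with columns `from`, `to`, `lag`
#' (0 = contemporaneous, 1 = lagged) and `level` (one of `"null_base"`,
#' `"group"`, `"subgroup"`, `"individual"`, `"aggregate"`). Paths always
#' point into an endogenous node; a lag-1 self path (`from == to`,
#' `lag == 1`) is the autoregressive path, and contemporaneous self loops
#' are disallowed.
#'
#' @param from,to Character vectors of node names (recycled to a common
#'   length).
#' @param lag Integer vector of 0s and 1s.
#' @param level Character vector of path levels.
#' @return A `data.frame` with one row per path.
#' @export
path_set <- function(from = character(), to = character(), lag = integer(),
                     level = "individual") {
  ps <- data.frame(from = as.character(from), to = as.character(to),
                   lag = as.integer(lag), level = as.character(level),
                   stringsAsFactors = FALSE)
  validate_path_set(ps)
  ps
}

path_levels <- c("null_base", "group", "subgroup", "individual", "aggregate")

validate_path_set <- function(ps, exo_names = character()) {
  stopifnot(is.data.frame(ps),
            all(c("from", "to", "lag", "level") %in% names(ps)))
  if (!all(ps$lag %in% c(0L, 1L)))
    stop("path lag must be 0 or 1")
  if (!all(ps$level %in% path_levels))
    stop("unknown path level: ",
         paste(setdiff(unique(ps$level), path_levels), collapse = ", "))
  bad_self <- ps$lag == 0L & ps$from == ps$to
  if (any(bad_self))
    stop("contemporaneous self-loops are not allowed: ",
         paste(ps$from[bad_self], collapse = ", "))
  if (length(exo_names) && any(ps$to %in% exo_names))
    stop("paths may not target exogenous nodes: ",
         paste(unique(ps$to[ps$to %in% exo_names]), collapse = ", "))
  invisible(ps)
}

#' Canonical string key for a directed path
#'
#' @param ps A path set (`data.frame` with `from`, `to`, `lag`).
#' @return Character vector `"from->to@lag"`, one entry per row.
#' @export
path_key <- function(ps) {
  if (NROW(ps) == 0L) return(character())
  paste0(ps$from, "->", ps$to, "@", ps$lag)
}

## inverse of path_key
key_to_path <- function(keys, level = "individual") {
  if (!length(keys)) return(empty_path_set())
  parts <- strsplit(sub("@", "->", keys, fixed = TRUE), "->", fixed = TRUE)
  path_set(from = vapply(parts, `[`, "", 1L),
           to = vapply(parts, `[`, "", 2L),
           lag = as.integer(vapply(parts, `[`, "", 3L)),
           level = level)
}

empty_path_set <- function() {
  data.frame(from = character(), to = character(), lag = integer(),
             level = character(), stringsAsFactors = FALSE)
}

rbind_paths <- function(...) {
  parts <- Filter(function(x) NROW(x) > 0L, list(...))
  if (!length(parts)) return(empty_path_set())
  out <- do.call(rbind, lapply(parts, function(x)
    x[, c("from", "to", "lag", "level")]))
  rownames(out) <- NULL
  out
}

## deterministic ordering used for tie-breaks: by from, then to, then lag
order_paths <- function(ps) {
  ps[order(ps$from, ps$to, ps$lag), , drop = FALSE]
}

#' Autoregressive base paths for a set of nodes
#'
#' Lag-1 self paths, freed in the null model of every search procedure by
#' default and never pruned.
#'
#' @param nodes Character vector of endogenous node names.
#' @return A path set at level `"null_base"`.
#' @export
ar_paths <- function(nodes) {
  path_set(from = nodes, to = nodes, lag = 1L, level = "null_base")
}
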