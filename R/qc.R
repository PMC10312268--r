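#' Participant-level quality-control exclusion
#'
#' Applies the staged exclusion arithmetic used for motion/noise control:
#' (1) behavioral compliance below `compliance_min`; (2) temporal
#' signal-to-noise ratio below `Q1 - iqr_factor * IQR`; (3) mean framewise
#' displacement above `Q3 + iqr_factor * IQR`; (4) fraction of frames with
#' FD at or above `frame_fd_threshold_mm` exceeding `frame_fraction`.
#' Rules are applied in that order and the tSNR/FD quartiles are computed
#' over the subjects still retained when each stage runs. Tukey fences are
#' one-sided per metric (only harmfully low tSNR and harmfully high FD
#' exclude).
#'
#' @param records A data.frame with columns `subject_id`, `mean_fd_mm`,
#'   `tsnr`, `compliance_fraction`, and either a `frame_fd_mm` list column
#'   of per-frame FD vectors or a precomputed `high_fd_fraction` column.
#' @param iqr_factor Tukey fence multiplier (default 1.5).
#' @param frame_fd_threshold_mm Per-frame FD threshold (default 2 mm).
#' @param frame_fraction Maximum tolerated fraction of high-FD frames
#'   (default 0.25).
#' @param compliance_min Minimum behavioral compliance (default 0.75).
#' @return A list with `kept` (subject ids) and `excluded` (data.frame of
#'   subject_id, rule, value).
#' @export
qc_exclude <- function(records, iqr_factor = 1.5,
                       frame_fd_threshold_mm = 2.0, frame_fraction = 0.25,
                       compliance_min = 0.75) {
  need <- c("subject_id", "mean_fd_mm", "tsnr", "compliance_fraction")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("QC records missing required field(s): ",
         paste(miss, collapse = ", "))
  if (nrow(records) < 4L)
    stop("at least 4 QC records are required for the IQR rules")
  if (!"high_fd_fraction" %in% names(records)) {
    if (!"frame_fd_mm" %in% names(records))
      stop("QC records missing required field(s): frame_fd_mm (or high_fd_fraction)")
    records$high_fd_fraction <- vapply(records$frame_fd_mm, function(fd)
      mean(fd >= frame_fd_threshold_mm), numeric(1))
  }
  excluded <- data.frame(subject_id = character(), rule = character(),
                         value = numeric(), stringsAsFactors = FALSE)
  drop <- function(ids, rule, vals) {
    if (!length(ids)) return(invisible())
    excluded <<- rbind(excluded, data.frame(
      subject_id = ids, rule = rule, value = vals,
      stringsAsFactors = FALSE))
  }
  cur <- records

  ## stage 1: behavioral compliance
  bad <- cur$compliance_fraction < compliance_min
  drop(cur$subject_id[bad], "compliance", cur$compliance_fraction[bad])
  cur <- cur[!bad, , drop = FALSE]

  ## stage 2: low tSNR (Tukey fence over retained subjects)
  if (nrow(cur)) {
    q <- stats::quantile(cur$tsnr, c(0.25, 0.75), names = FALSE)
    lo <- q[1] - iqr_factor * (q[2] - q[1])
    bad <- cur$tsnr < lo
    drop(cur$subject_id[bad], "tsnr", cur$tsnr[bad])
    cur <- cur[!bad, , drop = FALSE]
  }

  ## stage 3: high mean FD
  if (nrow(cur)) {
    q <- stats::quantile(cur$mean_fd_mm, c(0.25, 0.75), names = FALSE)
    hi <- q[2] + iqr_factor * (q[2] - q[1])
    bad <- cur$mean_fd_mm > hi
    drop(cur$subject_id[bad], "mean-FD", cur$mean_fd_mm[bad])
    cur <- cur[!bad, , drop = FALSE]
  }

  ## stage 4: fraction of high-FD frames
  if (nrow(cur)) {
    bad <- cur$high_fd_fraction > frame_fraction
    drop(cur$subject_id[bad], "frame-FD fraction", cur$high_fd_fraction[bad])
    cur <- cur[!bad, , drop = FALSE]
  }

  list(kept = cur$subject_id, excluded = excluded)
}
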