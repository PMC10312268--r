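#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two peak-parameterized gamma bumps,
#' `g(t) = (t/p)^(p/d) * exp(-(t - p)/d)`, whose mode is exactly at `t = p`:
#' a positive response peaking at `peak_seconds` minus `undershoot_ratio`
#' times an undershoot bump peaking at `undershoot_seconds`.
#'
#' @param t Time in seconds (vector).
#' @param peak_seconds Response peak (default 6).
#' @param undershoot_seconds Undershoot peak (default 16).
#' @param peak_disp,undershoot_disp Dispersions (default 1).
#' @param undershoot_ratio Undershoot amplitude ratio (default 1/6).
#' @return HRF values at `t` (unit peak amplitude of the positive bump).
#' @export
hrf_double_gamma <- function(t, peak_seconds = 6, undershoot_seconds = 16,
                             peak_disp = 1, undershoot_disp = 1,
                             undershoot_ratio = 1 / 6) {
  bump <- function(t, p, d) {
    out <- numeric(length(t))
    pos <- t > 0
    out[pos] <- (t[pos] / p)^(p / d) * exp(-(t[pos] - p) / d)
    out
  }
  bump(t, peak_seconds, peak_disp) -
    undershoot_ratio * bump(t, undershoot_seconds, undershoot_disp)
}

#' Build HRF-convolved task regressors
#'
#' One column per `trial_type`: a boxcar over (onset, onset + duration) on
#' a fine time grid, convolved with the canonical double-gamma HRF,
#' sampled at frame onsets `0, TR, 2 TR, ...` (0-based convention) and
#' scaled to unit peak. A zero-duration event is treated as a unit
#' impulse.
#'
#' @param events A [task_events()] table.
#' @param n_timepoints Number of frames T.
#' @param tr_seconds Repetition time in seconds.
#' @param hrf_params Optional named list of [hrf_double_gamma()]
#'   parameters; `length_seconds` (default 32) truncates the kernel.
#' @param oversample Fine-grid subdivisions per TR (default 16).
#' @param trial_types Column order; defaults to the sorted unique types in
#'   `events` (both standard types when `events` is empty).
#' @return T x (number of types) numeric matrix, columns named by type.
#' @export
build_task_regressors <- function(events, n_timepoints, tr_seconds = 2,
                                  hrf_params = list(), oversample = 16,
                                  trial_types = NULL) {
  scan_seconds <- n_timepoints * tr_seconds
  if (NROW(events) && any(events$onset > scan_seconds))
    stop("event onset beyond scan end (",
         max(events$onset), " > ", scan_seconds, " s)")
  if (is.null(trial_types))
    trial_types <- if (NROW(events)) sort(unique(events$trial_type))
                   else c("anticipation", "outcome")
  dt <- tr_seconds / oversample
  length_seconds <- hrf_params$length_seconds %||% 32
  hrf_args <- hrf_params[setdiff(names(hrf_params), "length_seconds")]
  kern <- do.call(hrf_double_gamma,
                  c(list(t = seq(0, length_seconds, by = dt)), hrf_args))
  n_fine <- ceiling(scan_seconds / dt) + 1L
  grid <- (seq_len(n_fine) - 1L) * dt
  out <- matrix(0, n_timepoints, length(trial_types),
                dimnames = list(NULL, trial_types))
  frame_idx <- round(((seq_len(n_timepoints) - 1L) * tr_seconds) / dt) + 1L
  for (ty in trial_types) {
    ev <- events[NROW(events) > 0 & events$trial_type == ty, , drop = FALSE]
    box <- numeric(n_fine)
    if (NROW(ev)) {
      for (k in seq_len(nrow(ev))) {
        if (ev$duration[k] == 0) {
          box[which.min(abs(grid - ev$onset[k]))] <-
            box[which.min(abs(grid - ev$onset[k]))] + 1
        } else {
          on <- grid >= ev$onset[k] & grid < ev$onset[k] + ev$duration[k]
          box[on] <- box[on] + 1
        }
      }
    }
    conv <- stats::convolve(box, rev(kern), type = "open")[seq_len(n_fine)]
    col <- conv[frame_idx]
    peak <- max(abs(col))
    if (peak > 0) col <- col / peak
    out[, ty] <- col
  }
  out
}
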