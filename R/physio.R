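#' Resample a beat-time series to an equal-interval IBI series
#'
#' The instantaneous inter-beat interval (IBI) at beat k is
#' `t_k - t_{k-1}`, located at the later beat's timestamp. Beats implying an
#' IBI outside the physiological screening bounds (default 300-2000 ms) are
#' flagged as artifacts and excluded before interpolation. The remaining
#' (time, IBI) points are linearly interpolated onto a fixed-rate grid
#' (default 4 Hz, i.e. one sample every 250 ms) spanning the observed IBI
#' timestamps; no extrapolation beyond the first/last valid beat.
#'
#' @param beat_times_ms strictly increasing beat times, ms from session
#'   start; >= 3 beats.
#' @param rate_hz sampling rate of the output grid (default 4).
#' @param artifact_bounds_ms length-2 IBI screening bounds, ms.
#' @return object of class `ibi_series`: `timestamps_s` (seconds, constant
#'   step 1/rate_hz), `ibi_ms`, `rate_hz`, `n_artifacts`.
#' @export
#' @examples
#' s <- resample_ibi(seq(0, 8000, by = 800))
#' range(s$ibi_ms) # flat at 800
resample_ibi <- function(beat_times_ms, rate_hz = 4,
                         artifact_bounds_ms = c(300, 2000)) {
  if (length(beat_times_ms) < 3) stop("need >= 3 beat times")
  if (any(diff(beat_times_ms) <= 0)) {
    stop("beat times must be strictly increasing")
  }
  ibi <- diff(beat_times_ms)
  at <- beat_times_ms[-1]
  ok <- ibi >= artifact_bounds_ms[1] & ibi <= artifact_bounds_ms[2]
  n_artifacts <- sum(!ok)
  if (sum(ok) < 2) stop("fewer than 2 artifact-free IBIs; cannot interpolate")
  ibi <- ibi[ok]
  at_s <- at[ok] / 1000
  step <- 1 / rate_hz
  grid <- seq(at_s[1], at_s[length(at_s)], by = step)
  vals <- stats::approx(at_s, ibi, xout = grid, method = "linear")$y
  structure(list(timestamps_s = grid, ibi_ms = vals, rate_hz = rate_hz,
                 n_artifacts = n_artifacts),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf(
    "<ibi_series: %d samples @ %g Hz, %.1f-%.1f s, mean IBI %.0f ms%s>\n",
    length(x$ibi_ms), x$rate_hz, x$timestamps_s[1],
    x$timestamps_s[length(x$timestamps_s)], mean(x$ibi_ms),
    if (x$n_artifacts > 0) paste0(", ", x$n_artifacts, " artifact(s)") else ""))
  invisible(x)
}

#' Per-trial IBI epoch means
#'
#' Extracts two windows per trial from an equal-interval IBI series: the
#' 6 s anticipatory period between cue presentation and reinforcer
#' presentation, and the reinforcer period from outcome onset to the next
#' cue onset (outcome display plus the jittered ITI, 4-7 s under the
#' default design). Windows are half-open \[start, end) so consecutive
#' epochs never share a grid sample. Epochs with fewer than 2 samples, or
#' falling outside the series span, are flagged and reported with `NA`
#' means.
#'
#' @param series an [resample_ibi()] result.
#' @param schedule a `session_schedule` with onset times.
#' @return data frame (`epoch_table`): `trial_index`, `condition`,
#'   `window` (`"anticipation"` / `"reinforcer"`), `start_s`, `end_s`,
#'   `mean_ibi_ms`, `n_samples`, `flagged`.
#' @export
epoch_means <- function(series, schedule) {
  stopifnot(inherits(series, "ibi_series"),
            inherits(schedule, "session_schedule"))
  trials <- schedule$trials
  n <- nrow(trials)
  next_cue <- c(trials$cue_onset_s[-1],
                trials$outcome_onset_s[n] +
                  schedule$config$outcome_duration_s + trials$iti_s[n])
  windows <- rbind(
    data.frame(trial_index = trials$trial_index, condition = trials$condition,
               window = "anticipation", start_s = trials$cue_onset_s,
               end_s = trials$cue_onset_s + 6, stringsAsFactors = FALSE),
    data.frame(trial_index = trials$trial_index, condition = trials$condition,
               window = "reinforcer", start_s = trials$outcome_onset_s,
               end_s = next_cue, stringsAsFactors = FALSE)
  )
  ts <- series$timestamps_s
  stats_one <- function(a, b) {
    sel <- ts >= a & ts < b
    k <- sum(sel)
    c(mean = if (k >= 1) mean(series$ibi_ms[sel]) else NA_real_, n = k)
  }
  m <- mapply(stats_one, windows$start_s, windows$end_s)
  windows$mean_ibi_ms <- m["mean", ]
  windows$n_samples <- as.integer(m["n", ])
  windows$flagged <- windows$n_samples < 2
  windows$mean_ibi_ms[windows$n_samples == 0] <- NA_real_
  windows <- windows[order(windows$trial_index, windows$window), ]
  rownames(windows) <- NULL
  windows
}

#' Condition-level epoch contrasts for one subject
#'
#' Convenience summary: mean epoch IBI per condition and window.
#'
#' @param epochs an epoch table from [epoch_means()].
#' @return data frame: `condition`, `window`, `mean_ibi_ms`, `n_epochs`.
#' @export
summarize_epochs <- function(epochs) {
  ok <- !epochs$flagged & !is.na(epochs$mean_ibi_ms)
  d <- epochs[ok, ]
  agg <- stats::aggregate(mean_ibi_ms ~ condition + window, data = d, FUN = mean)
  cnt <- stats::aggregate(mean_ibi_ms ~ condition + window, data = d,
                          FUN = length)
  agg$n_epochs <- cnt$mean_ibi_ms
  agg
}
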