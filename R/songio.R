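# Male song analysis: envelope segmentation into pulses and carrier
# frequency estimation, mirroring the recording-analysis procedure
# (rectification by squaring, 200 Hz low-pass, threshold crossing at
# 10-15% of the normalized envelope; carrier from the spectral peak of the
# raw waveform).

#' Segment pulsed song from a waveform envelope
#'
#' The envelope is obtained by squaring the signal and low-pass filtering at
#' `cutoff_hz` with a 4th-order Butterworth applied forward-backward (zero
#' phase, so pulse onsets are not biased), then taking the square root and
#' normalizing to peak 1. Pulses are maximal intervals where the envelope
#' is at or above `threshold`; pulses touching the recording edges are
#' discarded from the summaries. The 200 Hz cutoff limits temporal
#' resolution to about 2.5 ms, so recovered durations are accurate only to
#' that order.
#'
#' @param wave a `waveform` (or numeric vector, with `sample_rate` given)
#' @param sample_rate Hz (taken from the waveform object if supplied)
#' @param threshold envelope threshold fraction in (0, 1); default 0.125,
#'   the midpoint of the 10-15% range
#' @param cutoff_hz envelope low-pass cutoff, default 200
#' @return a `song_segmentation`: `pulses` (data frame `onset_ms`,
#'   `offset_ms`, `duration_ms`, `pause_ms`, `period_ms`) and `summary`
#'   (mean and sd of duration, pause, period, duty cycle, pulse rate)
#' @export
segment_song <- function(wave, sample_rate = NULL, threshold = 0.125,
                         cutoff_hz = 200) {
  if (inherits(wave, "waveform")) {
    sample_rate <- wave$sample_rate
    x <- wave$samples
  } else x <- wave
  if (is.null(sample_rate)) stop("sample_rate required")
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  if (all(x == 0)) {
    return(structure(list(pulses = data.frame(onset_ms = numeric(0),
                                              offset_ms = numeric(0),
                                              duration_ms = numeric(0),
                                              pause_ms = numeric(0),
                                              period_ms = numeric(0)),
                          summary = NULL, sample_rate = sample_rate),
                     class = "song_segmentation"))
  }
  bf <- signal::butter(4, cutoff_hz / (sample_rate / 2), type = "low")
  env <- signal::filtfilt(bf, x^2)
  env <- sqrt(pmax(env, 0))
  env <- env / max(env)
  above <- env >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on_idx <- starts[r$values]
  off_idx <- ends[r$values]
  # drop pulses touching the edges (partial at recording boundaries)
  keep <- on_idx > 1 & off_idx < length(env)
  on_idx <- on_idx[keep]; off_idx <- off_idx[keep]
  dt <- 1000 / sample_rate
  pulses <- data.frame(onset_ms = (on_idx - 1) * dt,
                       offset_ms = off_idx * dt)
  pulses$duration_ms <- pulses$offset_ms - pulses$onset_ms
  np <- nrow(pulses)
  pulses$pause_ms <- c(if (np > 1) pulses$onset_ms[-1] -
                         pulses$offset_ms[-np], NA)
  pulses$period_ms <- pulses$duration_ms + pulses$pause_ms
  smry <- if (np >= 2) {
    per <- pulses$period_ms[-np]
    dur <- pulses$duration_ms[-np]
    data.frame(
      quantity = c("duration_ms", "pause_ms", "period_ms", "duty_cycle",
                   "rate_hz"),
      mean = c(mean(pulses$duration_ms), mean(pulses$pause_ms[-np]),
               mean(per), mean(dur / per), mean(1000 / per)),
      sd = c(stats::sd(pulses$duration_ms), stats::sd(pulses$pause_ms[-np]),
             stats::sd(per), stats::sd(dur / per), stats::sd(1000 / per)))
  } else NULL
  structure(list(pulses = pulses, summary = smry,
                 sample_rate = sample_rate, threshold = threshold),
            class = "song_segmentation")
}

#' @export
print.song_segmentation <- function(x, ...) {
  cat(sprintf("song segmentation: %d pulses\n", nrow(x$pulses)))
  if (!is.null(x$summary)) {
    for (i in seq_len(nrow(x$summary)))
      cat(sprintf("  %-12s %.3g +/- %.2g\n", x$summary$quantity[i],
                  x$summary$mean[i], x$summary$sd[i]))
  }
  invisible(x)
}

#' Carrier frequency from the spectral peak of the raw waveform
#'
#' @param wave a `waveform` or numeric vector
#' @param sample_rate Hz (from the waveform object if supplied)
#' @param min_hz ignore spectral content below this frequency (excludes the
#'   DC/envelope band), default 500
#' @return frequency of the magnitude-spectrum maximum (Hz)
#' @export
carrier_frequency <- function(wave, sample_rate = NULL, min_hz = 500) {
  if (inherits(wave, "waveform")) {
    sample_rate <- wave$sample_rate
    x <- wave$samples
  } else x <- wave
  if (is.null(sample_rate)) stop("sample_rate required")
  if (all(x == 0)) stop("undefined spectral peak: all-zero input")
  n <- length(x)
  spec <- Mod(stats::fft(x))[seq_len(floor(n / 2))]
  freq <- (seq_len(floor(n / 2)) - 1) * sample_rate / n
  ok <- freq >= min_hz
  if (!any(ok)) stop("waveform too short for spectral analysis")
  freq[ok][which.max(spec[ok])]
}

#' Write a segmentation as delimited text
#'
#' @param seg a `song_segmentation`
#' @param path file path
#' @export
write_segmentation <- function(seg, path) {
  utils::write.table(seg$pulses, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
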