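#' Specify a rectangular pulse-train stimulus
#'
#' Cricket calling songs are trains of sound pulses. The models in this
#' package consume only the song envelope, so a stimulus is fully described
#' by its pulse duration \eqn{D}, pause \eqn{P}, total duration, amplitude,
#' and sample rate. Two derived quantities are attached: the period
#' \eqn{T = D + P} (the song's rhythm) and the duty cycle
#' \eqn{DC = D / T} (the fraction of the period filled by sound).
#'
#' @param pulse_ms pulse duration in ms (> 0)
#' @param pause_ms pause duration in ms (>= 0); a zero pause is a
#'   continuous tone
#' @param total_ms total stimulus duration in ms, default 400
#' @param amplitude pulse amplitude, default 1
#' @param sample_rate sampling rate in Hz
#' @return an object of class `pulse_train_spec`
#' @seealso [render_pulse_train()]
#' @export
pulse_train_spec <- function(pulse_ms, pause_ms, total_ms = 400,
                             amplitude = 1, sample_rate = 10000) {
  if (!is.numeric(pulse_ms) || length(pulse_ms) != 1 || pulse_ms <= 0)
    stop("pulse_ms must be a single positive number")
  if (!is.numeric(pause_ms) || length(pause_ms) != 1 || pause_ms < 0)
    stop("pause_ms must be a single non-negative number")
  if (total_ms <= pulse_ms)
    stop("total_ms must exceed pulse_ms")
  if (sample_rate <= 0)
    stop("sample_rate must be positive")
  structure(list(
    pulse_ms = pulse_ms, pause_ms = pause_ms, total_ms = total_ms,
    amplitude = amplitude, sample_rate = sample_rate,
    period_ms = pulse_ms + pause_ms,
    duty_cycle = pulse_ms / (pulse_ms + pause_ms)
  ), class = "pulse_train_spec")
}

#' Render a pulse-train stimulus to a sampled trace
#'
#' The trace alternates `pulse_ms` of `amplitude` and `pause_ms` of silence,
#' repeated until `total_ms`; the final partial cycle is truncated (models
#' exclude the stimulus edges from their response integral, so a cut pulse at
#' the end is harmless).
#'
#' @param spec a [pulse_train_spec()]
#' @return an object of class `pulse_train` with elements `samples`,
#'   `sample_rate` and `spec`
#' @export
render_pulse_train <- function(spec) {
  stopifnot(inherits(spec, "pulse_train_spec"))
  sr <- spec$sample_rate
  n <- round(spec$total_ms * sr / 1000)
  t <- (seq_len(n) - 1) * 1000 / sr
  phase <- t %% spec$period_ms
  # tolerance guards against floating-point phase jitter at pulse edges
  samples <- ifelse(phase < spec$pulse_ms - 1e-9, spec$amplitude, 0)
  structure(list(samples = samples, sample_rate = sr, spec = spec),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "pulse train: D = %.2f ms, P = %.2f ms (T = %.2f ms, DC = %.0f%%), %g ms @ %g Hz\n",
    s$pulse_ms, s$pause_ms, s$period_ms, 100 * s$duty_cycle, s$total_ms,
    x$sample_rate))
  invisible(x)
}

#' Build the pulse/pause stimulus lattice used for fitting
#'
#' All combinations of pulse and pause duration on a square lattice with the
#' given step, each coordinate running from `step_ms` to `max_ms`; the 0 ms
#' coordinates are excluded (a 0 ms pulse is no stimulus, a 0 ms pause a
#' tone), which keeps the count at exactly `(max_ms / step_ms)^2`.
#'
#' @param max_ms largest pulse/pause duration, default 20
#' @param step_ms lattice step, default 0.5; must divide `max_ms`
#' @return a `stimulus_grid`: a data frame with columns `pulse_ms`,
#'   `pause_ms`, `period_ms`, `duty_cycle` and a `step_ms` attribute
#' @examples
#' nrow(make_fit_grid(20, 0.5))  # 1600
#' @export
make_fit_grid <- function(max_ms = 20, step_ms = 0.5) {
  if (step_ms <= 0 || step_ms > max_ms)
    stop("need 0 < step_ms <= max_ms")
  k <- max_ms / step_ms
  if (abs(k - round(k)) > 1e-8)
    stop("step_ms must divide max_ms")
  ax <- seq_len(round(k)) * step_ms
  g <- expand.grid(pulse_ms = ax, pause_ms = ax, KEEP.OUT.ATTRS = FALSE)
  g$period_ms <- g$pulse_ms + g$pause_ms
  g$duty_cycle <- g$pulse_ms / g$period_ms
  attr(g, "step_ms") <- step_ms
  attr(g, "max_ms") <- max_ms
  class(g) <- c("stimulus_grid", class(g))
  g
}

#' Pulse/pause coordinates along a PPF transect
#'
#' Two families of one-dimensional slices through the pulse-pause plane are
#' used throughout: constant duty cycle (period tuning; diagonals) and
#' constant period (DC tuning; anti-diagonals).
#'
#' @param kind `"constant_dc"` or `"constant_period"`
#' @param value the duty cycle (in (0,1)) or the period (ms)
#' @param axis_range for `constant_dc`, the period range spanned; for
#'   `constant_period`, the pulse-duration range (defaults to the open
#'   interval (0, value))
#' @param n number of points
#' @return data frame with columns `pulse_ms`, `pause_ms`
#' @export
transect_points <- function(kind = c("constant_dc", "constant_period"),
                            value, axis_range = NULL, n = 50) {
  kind <- match.arg(kind)
  if (n < 1) stop("empty range")
  if (kind == "constant_dc") {
    if (value <= 0 || value >= 1) stop("duty cycle must be in (0, 1)")
    if (is.null(axis_range)) stop("axis_range (period interval) required")
    if (diff(range(axis_range)) < 0 || axis_range[1] <= 0)
      stop("empty range")
    Tv <- if (n == 1) axis_range[1] else
      seq(axis_range[1], axis_range[2], length.out = n)
    data.frame(pulse_ms = value * Tv, pause_ms = (1 - value) * Tv)
  } else {
    if (value <= 0) stop("period must be positive")
    if (is.null(axis_range)) axis_range <- c(value / (n + 1), value * n / (n + 1))
    if (axis_range[1] <= 0 || axis_range[2] >= value)
      stop("pulse durations must lie strictly inside (0, period)")
    D <- if (n == 1) axis_range[1] else
      seq(axis_range[1], axis_range[2], length.out = n)
    data.frame(pulse_ms = D, pause_ms = value - D)
  }
}

#' Write or read a stimulus grid as delimited text
#'
#' @param grid a `stimulus_grid`
#' @param path file path
#' @export
write_stimulus_grid <- function(grid, path) {
  utils::write.table(as.data.frame(grid), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_grid
#' @export
read_stimulus_grid <- function(path) {
  g <- utils::read.delim(path)
  stopifnot(all(c("pulse_ms", "pause_ms") %in% names(g)))
  if (is.null(g$period_ms)) g$period_ms <- g$pulse_ms + g$pause_ms
  if (is.null(g$duty_cycle)) g$duty_cycle <- g$pulse_ms / g$period_ms
  class(g) <- c("stimulus_grid", class(g))
  g
}

#' Resonance arithmetic for a song period
#'
#' Helper for reasoning about resonant recognition: given a fundamental song
#' period `Ts` (ms), returns the second harmonic (`Ts/2`), the fundamental,
#' the second subharmonic (`2 Ts`), and the pulse rate `1000/Ts` in pulses
#' per second.
#'
#' @param period_ms fundamental song period in ms
#' @return named numeric vector
#' @examples
#' song_harmonics(8.6)
#' @export
song_harmonics <- function(period_ms) {
  stopifnot(period_ms > 0)
  c(half_period_ms = period_ms / 2,
    period_ms = period_ms,
    double_period_ms = 2 * period_ms,
    pulse_rate_hz = 1000 / period_ms)
}
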