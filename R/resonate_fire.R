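#' Parameters of the resonate-and-fire neuron
#'
#' A two-variable spiking neuron with a current-like variable `x` and a
#' voltage-like variable `y` whose bidirectional coupling produces damped
#' intrinsic membrane oscillations at the characteristic frequency
#' `freq_hz`:
#' \deqn{dx/dt = b x - \omega y + g_s s(t), \quad dy/dt = \omega x + b y}
#' Inputs arriving during positive phases of the oscillation amplify it,
#' inputs during negative phases suppress it, which makes the neuron
#' resonant: it responds at integer multiples (subharmonics) of its
#' characteristic period but not at fractions.
#'
#' Units: `omega = 2 pi freq_hz / 1000` rad/ms and `damping` is per ms, so
#' the fitted damping (about -0.0005) is weak relative to the input gain.
#' Defaults are the values fitted to the Anurogryllus preference field.
#'
#' @param freq_hz characteristic frequency (Hz)
#' @param damping damping factor `b` (per ms); non-positive for damped
#'   dynamics
#' @param input_gain stimulus gain `g_s`
#' @param spike_amp output gain: the area of the delta-like spike event
#'   added to the output trace
#' @param y_thresh spike threshold on `y`, default 1
#' @param x_reset,y_reset post-spike reset values, defaults 0 and 1
#' @param dt_ms Euler integration step, default 0.1 ms
#' @export
rf_params <- function(freq_hz = 109.34, damping = -0.0005,
                      input_gain = 0.027, spike_amp = 0.0025,
                      y_thresh = 1, x_reset = 0, y_reset = 1, dt_ms = 0.1) {
  stopifnot(freq_hz > 0, dt_ms > 0, damping <= 0)
  structure(list(freq_hz = freq_hz, damping = damping,
                 input_gain = input_gain, spike_amp = spike_amp,
                 y_thresh = y_thresh, x_reset = x_reset, y_reset = y_reset,
                 dt_ms = dt_ms),
            class = c("rf_params", "model_params"))
}

#' Simulate the resonate-and-fire neuron
#'
#' Euler integration from `x = y = 0`. A spike is recorded on an upward
#' crossing of the threshold, after which `x` and `y` are reset. Since the
#' printed reset puts `y` back exactly at threshold, spike detection uses
#' crossing semantics: the detector re-arms only once `y` has fallen below
#' threshold, so a spike never retriggers itself on the next step.
#'
#' The spike output trace carries `spike_amp / dt` at spike samples (a
#' discrete delta of area `spike_amp`), so the integral of the spiking
#' response is `spike_amp` per spike independent of the sample rate;
#' [predict_phonotaxis()] of that trace is the model's phonotaxis score.
#'
#' @param stim a [render_pulse_train()] rendered at `1000 / dt_ms` Hz
#' @param params an [rf_params()]
#' @param keep_traces keep the full `x`/`y` traces (default TRUE)
#' @return an `rf_trace`: list with `t_ms`, `x`, `y`, `spike_times_ms`,
#'   `output` (the spike train), `sample_rate`
#' @export
rf_simulate <- function(stim, params = rf_params(), keep_traces = TRUE) {
  stopifnot(inherits(stim, "pulse_train"), inherits(params, "rf_params"))
  sr <- 1000 / params$dt_ms
  if (abs(stim$sample_rate - sr) > 1e-6)
    stop("stimulus sample rate (", stim$sample_rate,
         " Hz) incompatible with dt_ms = ", params$dt_ms)
  omega <- 2 * pi * params$freq_hz / 1000
  res <- .rf_core(stim$samples, params$dt_ms, omega, params$damping,
                  params$input_gain, params$x_reset, params$y_reset,
                  params$y_thresh, keep_traces)
  n <- length(stim$samples)
  out <- numeric(n)
  if (length(res$spikes) > 0)
    out[res$spikes] <- params$spike_amp / params$dt_ms
  structure(list(
    t_ms = (seq_len(n) - 1) * params$dt_ms,
    x = res$x, y = res$y,
    spike_times_ms = (res$spikes - 1) * params$dt_ms,
    output = out, sample_rate = sr, params = params
  ), class = "rf_trace")
}

#' Phonotaxis score of the resonate-and-fire model for one stimulus
#'
#' @param stim a rendered pulse train at the model rate
#' @param params an [rf_params()]
#' @export
rf_score <- function(stim, params = rf_params()) {
  tr <- rf_simulate(stim, params, keep_traces = FALSE)
  predict_phonotaxis(tr$output, tr$sample_rate)
}
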