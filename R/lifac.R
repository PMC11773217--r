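#' Parameters of the leaky integrate-and-fire neuron with adaptation
#'
#' The LIFAC combines the low-pass property of the cell membrane (time
#' constant `tau_m`) with the high-pass property of spike-frequency
#' adaptation, yielding a band-pass filter for pulse rate:
#' \deqn{\tau_m dV/dt = -V + I - A, \qquad \tau_{ada} dA/dt = -A}
#' On reaching `v_thres` a spike is emitted, `V` is reset, the adaptation
#' current is incremented by `alpha`, and both variables are frozen for the
#' refractory period. A downstream rectifier on the total spike count
#' (`relu_gain * max(0, count - theta_relu)`) sharpens the tuning.
#'
#' Shared defaults follow the spike-frequency-adaptation demonstration
#' (refractory 1 ms, `tau_ada` 5 ms, `alpha` 10 mV, threshold 0.5 mV);
#' `v_reset = 0` is the conventional LIF resting baseline. See
#' [lifac_presets()] for the per-period variants.
#'
#' @param tau_m membrane time constant (ms)
#' @param theta_relu spike-count threshold of the output rectifier
#' @param tau_ada adaptation time constant (ms)
#' @param alpha adaptation increment per spike (mV)
#' @param v_thres spike threshold (mV)
#' @param v_reset post-spike reset potential (mV)
#' @param tau_ref refractory period (ms)
#' @param relu_gain output rectifier gain
#' @export
lifac_params <- function(tau_m = 8.8, theta_relu = 72, tau_ada = 5,
                         alpha = 10, v_thres = 0.5, v_reset = 0,
                         tau_ref = 1, relu_gain = 1) {
  stopifnot(tau_m > 0, tau_ada > 0, tau_ref > 0, v_thres > v_reset)
  structure(list(tau_m = tau_m, theta_relu = theta_relu, tau_ada = tau_ada,
                 alpha = alpha, v_thres = v_thres, v_reset = v_reset,
                 tau_ref = tau_ref, relu_gain = relu_gain),
            class = c("lifac_params", "model_params"))
}

#' LIFAC presets that isolate individual resonant peaks
#'
#' Three parameter variants that, driven by the rebound model's output,
#' respectively favour the ~4 ms, ~9 ms and ~17 ms resonant peaks by
#' adjusting the membrane time constant and the output spike-count
#' threshold.
#'
#' @return named list of [lifac_params()] objects (`"4ms"`, `"8ms"`,
#'   `"16ms"`)
#' @export
lifac_presets <- function() {
  list("4ms" = lifac_params(tau_m = 4, theta_relu = 125),
       "8ms" = lifac_params(tau_m = 8.8, theta_relu = 72),
       "16ms" = lifac_params(tau_m = 12, theta_relu = 0))
}

#' Simulate the LIFAC neuron for an input current
#'
#' @param input_current numeric vector (current in mV-equivalent units)
#' @param params a [lifac_params()]
#' @param sample_rate sampling rate of the input in Hz
#' @param keep_traces keep `V` and `A` traces (default TRUE)
#' @return list with `spike_times_ms`, `n_spikes`, `V`, `A`, `t_ms`
#' @export
lifac_simulate <- function(input_current, params = lifac_params(),
                           sample_rate, keep_traces = TRUE) {
  stopifnot(inherits(params, "lifac_params"), all(is.finite(input_current)))
  dt <- 1000 / sample_rate
  res <- .lifac_core(input_current, dt, params$tau_m, params$tau_ada,
                     params$alpha, params$v_thres, params$v_reset,
                     params$tau_ref, keep_traces)
  structure(list(spike_times_ms = (res$spikes - 1) * dt,
                 n_spikes = length(res$spikes),
                 V = res$V, A = res$A,
                 t_ms = (seq_along(input_current) - 1) * dt,
                 sample_rate = sample_rate),
            class = "lifac_trace")
}

#' Preference field of the rebound + LIFAC model
#'
#' For each stimulus on the grid, the instantaneous (non-integrated) output
#' of the rebound model drives a LIFAC neuron; the total spike count is
#' passed through the output rectifier to give the field value.
#'
#' `input_gain` scales the rebound output (of order 0.1 at its transients)
#' into the near-threshold current regime, calibrated once so that the
#' membrane time constant controls which resonant line survives: narrow
#' rebound transients (short pauses, as on the ~9 ms line at high duty
#' cycle) are attenuated by a slow membrane and fail to reach threshold,
#' while the wider transients of the ~17 ms line still spike. In this
#' regime the neuron fires at most about one spike per pulse, i.e. tens of
#' spikes per 400 ms train.
#'
#' @param rebound_params a [rebound_params()]
#' @param lifac_params a [lifac_params()]
#' @param grid a [make_fit_grid()] result
#' @param sample_rate simulation rate in Hz, default 4000
#' @param input_gain scaling from rebound output to input current
#' @param total_ms stimulus duration
#' @return a [preference_field()] of rectified spike counts
#' @export
lifac_field <- function(rebound_params = cricketsong::rebound_params(),
                        lifac_params = cricketsong::lifac_params(),
                        grid = make_fit_grid(), sample_rate = 4000,
                        input_gain = 7, total_ms = 400) {
  ctx <- grid_context(grid, sample_rate, total_ms)
  counts <- lifac_grid_counts(rebound_params, lifac_params, ctx, input_gain)
  v <- lifac_params$relu_gain * pmax(0, counts - lifac_params$theta_relu)
  pulse_axis <- sort(unique(grid$pulse_ms))
  pause_axis <- sort(unique(grid$pause_ms))
  m <- matrix(NA_real_, length(pulse_axis), length(pause_axis))
  m[cbind(match(grid$pulse_ms, pulse_axis),
          match(grid$pause_ms, pause_axis))] <- v
  preference_field(pulse_axis, pause_axis, m)
}

#' Raw LIFAC spike counts for every stimulus of a grid context
#'
#' @param rebound_params,lifac_params model parameter objects
#' @param ctx a [grid_context()]
#' @param input_gain scaling from rebound output to input current
#' @return integer vector of spike counts, one per grid row
#' @export
lifac_grid_counts <- function(rebound_params, lifac_params, ctx,
                              input_gain = 7) {
  drive <- .rebound_drive_mat(rebound_params, ctx) * input_gain
  dt <- ctx$dt
  vapply(seq_len(ncol(drive)), function(j) {
    res <- .lifac_core(drive[, j], dt, lifac_params$tau_m,
                       lifac_params$tau_ada, lifac_params$alpha,
                       lifac_params$v_thres, lifac_params$v_reset,
                       lifac_params$tau_ref, FALSE)
    length(res$spikes)
  }, numeric(1))
}
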