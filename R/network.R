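# The 5-neuron song recognition network (AN1, LN2, LN5, LN3, LN4), a
# rate-based feed-forward cascade of linear filters, static nonlinearities
# and divisive-normalization adaptation. AN1 relays an intensity-invariant
# copy of the song envelope; LN2 provides feedforward inhibition; LN5
# produces a post-inhibitory rebound at each pulse offset; LN3 detects the
# coincidence of the rebound with a delayed AN1 input; LN4 combines LN3
# excitation with LN2 inhibition, which shapes the duty-cycle tuning.
#
# The parameter table gives lobe widths, durations, gains, delays,
# nonlinearity and adaptation constants, but not the functional forms; the
# forms used here are declared in the constructors below (and discussed in
# the vignette): Gaussian lobes are amplitude-parameterized and centred at
# half their duration, exponential lobes decay from t = 0, and the
# differentiated Gaussian is the first derivative of a Gaussian spanning the
# lobe duration, scaled so its positive lobe peaks at the stated gain.

#' Filter lobe, nonlinearity, adaptation and synapse constructors
#'
#' Building blocks of the network neurons. `free` lists the parameter names
#' counted as free (fitted) parameters; the default network has 45 free
#' parameters in total.
#'
#' @param shape `"gaussian"`, `"exponential"` or `"differentiated_gaussian"`
#' @param width_or_tau Gaussian sigma or exponential decay constant (ms);
#'   ignored for the differentiated Gaussian, whose width is tied to its
#'   duration
#' @param duration_ms kernel truncation length (ms)
#' @param gain signed lobe gain (negative = inhibitory)
#' @param free character vector of free parameter names
#' @export
filter_lobe <- function(shape = c("gaussian", "exponential",
                                  "differentiated_gaussian"),
                        width_or_tau = NULL, duration_ms, gain,
                        free = character()) {
  shape <- match.arg(shape)
  stopifnot(duration_ms > 0)
  structure(list(type = "lobe", shape = shape, width_or_tau = width_or_tau,
                 duration_ms = duration_ms, gain = gain, free = free),
            class = "filter_lobe")
}

#' @rdname filter_lobe
#' @param slope,shift sigmoid steepness and midpoint
#' @param baseline sigmoid lower asymptote offset
#' @export
nl_sigmoid <- function(slope, shift, gain, baseline, free = character()) {
  structure(list(type = "sigmoid", slope = slope, shift = shift, gain = gain,
                 baseline = baseline, free = free), class = "nonlinearity")
}

#' @rdname filter_lobe
#' @param threshold rectifier threshold
#' @export
nl_relu <- function(threshold, gain, free = character()) {
  structure(list(type = "relu", threshold = threshold, gain = gain,
                 free = free), class = "nonlinearity")
}

#' @rdname filter_lobe
#' @param tau_ms adaptation timescale (ms)
#' @param strength divisive strength w
#' @param offset offset x0 of the divisive denominator
#' @export
adaptation_spec <- function(tau_ms, strength, offset = 1,
                            free = character()) {
  stopifnot(tau_ms > 0)
  structure(list(type = "adapt", tau_ms = tau_ms, strength = strength,
                 offset = offset, free = free), class = "adaptation_spec")
}

#' @rdname filter_lobe
#' @param source `"stimulus"` or the name of an upstream neuron
#' @param delay_ms synaptic delay (ms, >= 0)
#' @export
synapse <- function(source, delay_ms, gain, free = character()) {
  stopifnot(delay_ms >= 0)
  structure(list(source = source, delay_ms = delay_ms, gain = gain,
                 free = free), class = "synapse")
}

# Discrete kernel for one lobe. Lobes are area-parameterized: the kernel of
# a gaussian or exponential lobe integrates to `gain` (in ms units), so a
# lobe's gain states how much signal mass it contributes regardless of its
# width — this is what makes the printed nonlinearity constants (sigmoid
# shift 0.62, relu thresholds 0.24/5.1) sit inside the operating range of
# their stages. The differentiated gaussian has zero net area; its positive
# lobe integrates to `gain`.
.lobe_kernel <- function(lobe, sample_rate) {
  dt <- 1000 / sample_rate
  nk <- max(1, round(lobe$duration_ms / dt))
  t <- (seq_len(nk) - 1) * dt
  if (lobe$shape == "gaussian") {
    mu <- lobe$duration_ms / 2
    k0 <- exp(-(t - mu)^2 / (2 * lobe$width_or_tau^2))
    lobe$gain * k0 / (sum(k0) * dt)
  } else if (lobe$shape == "exponential") {
    k0 <- exp(-t / lobe$width_or_tau)
    lobe$gain * k0 / (sum(k0) * dt)
  } else {  # differentiated_gaussian
    sigma <- lobe$duration_ms / 6
    mu <- lobe$duration_ms / 2
    # midpoint sampling keeps the discrete kernel exactly antisymmetric
    # about its centre, so it passes no DC at any sample rate
    tm <- t + dt / 2
    k0 <- -(tm - mu) / sigma^2 * exp(-(tm - mu)^2 / (2 * sigma^2))
    pos <- sum(k0[k0 > 0]) * dt
    lobe$gain * k0 / pos
  }
}

#' Apply a multi-lobe linear filter to a signal
#'
#' Causal convolution with the sum of the lobe kernels, scaled by the sample
#' interval so results are sample-rate invariant. An empty lobe list is the
#' identity.
#'
#' @param x numeric signal
#' @param lobes list of [filter_lobe()] objects
#' @param sample_rate Hz
#' @export
apply_filter <- function(x, lobes, sample_rate) {
  if (length(lobes) == 0) return(x)
  ks <- lapply(lobes, .lobe_kernel, sample_rate = sample_rate)
  nk <- max(vapply(ks, length, integer(1)))
  K <- rowSums(vapply(ks, function(k) c(k, numeric(nk - length(k))),
                      numeric(nk)))
  .causal_conv(x, K) * (1000 / sample_rate)
}

#' Divisive-normalization adaptation
#'
#' `a(t)` is a first-order low-pass of the signal with timescale `tau_ms`
#' (initial state 0); the output is `x / (offset + strength * a)`. Errors if
#' the denominator is not strictly positive at every step.
#'
#' @param x numeric signal
#' @param spec an [adaptation_spec()]
#' @param sample_rate Hz
#' @export
divisive_norm <- function(x, spec, sample_rate) {
  stopifnot(inherits(spec, "adaptation_spec"))
  a <- .lowpass_core(x, 1000 / sample_rate, spec$tau_ms)
  denom <- spec$offset + spec$strength * a
  if (any(denom <= 0))
    stop("divisive normalization denominator reached zero")
  x / denom
}

.apply_nonlin <- function(x, nl) {
  if (nl$type == "relu") nl$gain * pmax(0, x - nl$threshold)
  else nl$baseline + nl$gain / (1 + exp(-nl$slope * (x - nl$shift)))
}

.apply_stage <- function(x, stage, sample_rate) {
  if (inherits(stage, "nonlinearity")) .apply_nonlin(x, stage)
  else if (inherits(stage, "adaptation_spec"))
    divisive_norm(x, stage, sample_rate)
  else if (is.list(stage) && all(vapply(stage, inherits, logical(1),
                                        "filter_lobe")))
    apply_filter(x, stage, sample_rate)
  else stop("unknown stage type")
}

#' The five-neuron network fitted to the Anurogryllus preference data
#'
#' Returns the network parameterization fitted to the resonant Anurogryllus
#' preference field: per-neuron synaptic inputs (signed gains; inhibitory
#' connections negative), linear filter lobes, static nonlinearities and
#' divisive-normalization adaptation. The parameters marked free total 45.
#'
#' @param sample_rate simulation rate in Hz, default 10000
#' @return a `network_params` object
#' @export
anurogryllus_network <- function(sample_rate = 10000) {
  neurons <- list(
    AN1 = list(
      inputs = list(synapse("stimulus", 2.26, 1, free = "delay_ms")),
      stages = list(
        list(filter_lobe("gaussian", 3.88, 7.59, 1,
                         free = c("width_or_tau", "duration_ms")),
             filter_lobe("gaussian", 3.81, 293.04, -0.87,
                         free = c("width_or_tau", "duration_ms", "gain"))),
        nl_sigmoid(10.33, 0.62, 1.19, -0.29,
                   free = c("slope", "shift", "gain", "baseline")),
        adaptation_spec(9999.93, 85.75, 1, free = c("tau_ms", "strength")))),
    LN2 = list(
      inputs = list(synapse("AN1", 7.59, 1.93,
                            free = c("delay_ms", "gain"))),
      stages = list(
        list(filter_lobe("gaussian", 9.76, 11.87, 0.59,
                         free = c("width_or_tau", "duration_ms", "gain")),
             filter_lobe("exponential", 15.87, 1000, -1,
                         free = "width_or_tau")),
        nl_relu(0, 4.22, free = "gain"))),
    LN5 = list(
      inputs = list(synapse("LN2", 13.13, -0.43,
                            free = c("delay_ms", "gain"))),
      stages = list(
        list(filter_lobe("differentiated_gaussian", NULL, 8.94, 0.41,
                         free = c("duration_ms", "gain"))),
        nl_relu(0, 0.57, free = "gain"),
        list(filter_lobe("gaussian", 0.02, 5.18, -0.007,
                         free = c("duration_ms", "gain")),
             filter_lobe("exponential", 17.29, 1000, 6.5,
                         free = c("width_or_tau", "gain"))),
        nl_relu(0, 0.006, free = "gain"))),
    LN3 = list(
      inputs = list(synapse("AN1", 16.59, 0.65, free = c("delay_ms", "gain")),
                    synapse("LN5", 9.67, 43.73, free = c("delay_ms", "gain"))),
      stages = list(
        nl_relu(0.24, 6.82, free = c("threshold", "gain")),
        adaptation_spec(1463.98, 0.16, 1, free = c("tau_ms", "strength")),
        nl_relu(5.1, 3.51, free = c("threshold", "gain")))),
    LN4 = list(
      inputs = list(synapse("LN2", 11.44, -58.26,
                            free = c("delay_ms", "gain")),
                    synapse("LN3", 7.15, 3.75, free = c("delay_ms", "gain"))),
      stages = list(
        nl_relu(-0.003, 6.82, free = c("threshold", "gain")))))
  structure(list(neurons = neurons,
                 order = c("AN1", "LN2", "LN5", "LN3", "LN4"),
                 sample_rate = sample_rate),
            class = c("network_params", "model_params"))
}

#' Count the free parameters of a network
#'
#' @param params a `network_params` object
#' @export
n_free_params <- function(params) {
  stopifnot(inherits(params, "network_params"))
  count_free <- function(obj) {
    if (is.list(obj) && !is.null(obj$free)) length(obj$free)
    else if (is.list(obj)) sum(vapply(obj, count_free, numeric(1)))
    else 0
  }
  count_free(params$neurons)
}

#' Simulate the five-neuron network for one stimulus
#'
#' Evaluates the neurons in feed-forward order (AN1, LN2, LN5, LN3, LN4):
#' each neuron sums its delayed, gain-scaled inputs and passes the sum
#' through its ordered stages (filters, nonlinearities, adaptation). The
#' phonotaxis score is [predict_phonotaxis()] of the LN4 output.
#'
#' @param stim a [render_pulse_train()] rendered at the network sample rate
#' @param params a `network_params` (default [anurogryllus_network()])
#' @return list with `traces` (named per-neuron output list), `score`, and
#'   `an1_sustained` (peak AN1 output over the last 100 ms relative to its
#'   global peak; the physiological-realism constraint used when fitting)
#' @export
simulate_network <- function(stim, params = anurogryllus_network()) {
  stopifnot(inherits(stim, "pulse_train"),
            inherits(params, "network_params"))
  sr <- params$sample_rate
  if (abs(stim$sample_rate - sr) > 1e-6)
    stop("stimulus sample rate does not match the network sample rate")
  env <- list(stimulus = stim$samples)
  for (nm in params$order) {
    nrn <- params$neurons[[nm]]
    drive <- numeric(length(stim$samples))
    for (syn in nrn$inputs) {
      if (is.null(env[[syn$source]]))
        stop("missing source '", syn$source, "' for neuron ", nm)
      d <- round(syn$delay_ms * sr / 1000)
      drive <- drive + syn$gain * .shift(env[[syn$source]], d)
    }
    for (stage in nrn$stages) drive <- .apply_stage(drive, stage, sr)
    env[[nm]] <- drive
  }
  an1 <- env$AN1
  n <- length(an1)
  last100 <- an1[seq.int(max(1, n - round(100 * sr / 1000) + 1), n)]
  peak <- max(an1)
  structure(list(
    traces = env[params$order],
    stimulus = stim$samples,
    sample_rate = sr,
    score = predict_phonotaxis(env$LN4, sr),
    an1_sustained = if (peak > 0) max(last100) / peak else 0
  ), class = "network_sim")
}

#' Network phonotaxis scores along a set of stimuli
#'
#' @param params a `network_params`
#' @param stimuli data frame with `pulse_ms`, `pause_ms`
#' @param total_ms stimulus duration
#' @return numeric score vector
#' @export
network_scores <- function(params, stimuli, total_ms = 400) {
  vapply(seq_len(nrow(stimuli)), function(i) {
    st <- render_pulse_train(pulse_train_spec(
      stimuli$pulse_ms[i], stimuli$pause_ms[i], total_ms,
      sample_rate = params$sample_rate))
    simulate_network(st, params)$score
  }, numeric(1))
}

#' Effective delay between the two inputs to the coincidence detector LN3
#'
#' Simulates a single isolated pulse, extracts the two synaptic drives onto
#' LN3 (the delayed AN1 pathway and the LN5 rebound pathway) and returns the
#' lag (ms) at which their cross-correlation is maximal, i.e. by how much
#' the AN1-path drive must be delayed to best align with the LN5-path
#' drive.
#'
#' @param params a `network_params`
#' @param pulse_ms duration of the probe pulse, default 5
#' @param max_lag_ms largest lag searched, default 100
#' @export
effective_ln3_input_delay <- function(params = anurogryllus_network(),
                                      pulse_ms = 5, max_lag_ms = 100) {
  sr <- params$sample_rate
  total <- 400
  stim <- render_pulse_train(pulse_train_spec(pulse_ms, total - pulse_ms,
                                              total, sample_rate = sr))
  sim <- simulate_network(stim, params)
  syns <- params$neurons$LN3$inputs
  drv <- lapply(syns, function(syn) {
    src <- if (syn$source == "stimulus") stim$samples
           else sim$traces[[syn$source]]
    abs(syn$gain) * .shift(src, round(syn$delay_ms * sr / 1000))
  })
  a <- drv[[1]]; b <- drv[[2]]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined lag: at least one LN3 input drive is flat")
  lags <- seq(-round(max_lag_ms * sr / 1000), round(max_lag_ms * sr / 1000))
  cc <- vapply(lags, function(l) sum(.shift(a, max(l, 0)) *
                                       .shift(b, max(-l, 0))), numeric(1))
  lags[which.max(cc)] * 1000 / sr
}

#' Serialize network parameters to JSON and back
#'
#' Round-trips the full per-neuron structure (inputs, filter lobes,
#' nonlinearities, adaptation, free-parameter flags) losslessly.
#'
#' @param params a `network_params`
#' @param path file path
#' @export
write_network_params <- function(params, path) {
  strip <- function(x) {
    if (is.list(x)) {
      cl <- class(x)[1]
      out <- lapply(unclass(x), strip)
      if (cl != "list") out <- c(list(.class = cl), out)
      out
    } else x
  }
  jsonlite::write_json(strip(params), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_params
#' @export
read_network_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  restore <- function(x) {
    if (!is.list(x)) return(x)
    cl <- x[[".class"]]
    x[[".class"]] <- NULL
    out <- lapply(x, restore)
    if (!is.null(out$free)) out$free <- unlist(out$free)
    if (length(out) > 0 && all(vapply(out, function(e)
      is.atomic(e) && length(e) == 1, logical(1))) && is.null(names(out)))
      out <- unlist(out)
    if (!is.null(cl)) {
      cls <- if (identical(cl, "network_params"))
        c("network_params", "model_params") else cl
      class(out) <- cls
    }
    out
  }
  out <- restore(raw)
  out$order <- unlist(out$order)
  out$sample_rate <- as.numeric(out$sample_rate)
  out
}
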