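# Minimal recognition models: delay-line autocorrelation, post-inhibitory
# rebound + coincidence detection, and rebound + feedforward inhibition.
# All operate on the song envelope only. Default parameter values are the
# fitted values for the Anurogryllus preference data.

# causal discrete convolution: out[n] = sum_j k[j] x[n - j + 1]
.causal_conv <- function(x, k) {
  n <- length(x)
  stats::convolve(x, rev(k), type = "open")[seq_len(n)]
}

# delay by a (possibly fractional) number of samples with zero padding;
# fractional delays interpolate linearly between the two straddling integer
# shifts, which keeps fitted delays off the sample lattice differentiable
.shift <- function(x, n_samples) {
  n <- length(x)
  if (n_samples <= 0) return(x)
  if (n_samples >= n) return(numeric(n))
  d0 <- floor(n_samples)
  f <- n_samples - d0
  ishift <- function(d) {
    if (d >= n) return(numeric(n))
    c(numeric(d), x[seq_len(n - d)])
  }
  if (f < 1e-9) ishift(d0) else (1 - f) * ishift(d0) + f * ishift(d0 + 1)
}

#' Parameters of the autocorrelation model
#'
#' A delay line plus a multiplicative coincidence detector: the response is
#' `gain * s(t) * s(t - delay)`. Defaults are the values fitted to the
#' Anurogryllus preference field.
#'
#' @param delay_ms delay of the delayed pathway (ms)
#' @param gain output gain
#' @export
autocorr_params <- function(delay_ms = 17.0, gain = 0.21) {
  stopifnot(delay_ms > 0, gain > 0)
  structure(list(delay_ms = delay_ms, gain = gain),
            class = c("autocorr_params", "model_params"))
}

#' Parameters of the rebound model
#'
#' Extends the autocorrelation model: the non-delayed pathway is
#' sign-inverted and filtered with a bi-phasic rectangular kernel so that a
#' transient (the post-inhibitory rebound) appears at each pulse offset; the
#' rectified rebound is multiplied with the delayed stimulus. Defaults are
#' the fitted Anurogryllus values.
#'
#' @param delay_ms delay of the delayed pathway (ms)
#' @param inh_gain,inh_dur_ms inhibitory lobe gain magnitude and duration
#' @param exc_gain,exc_dur_ms excitatory lobe gain and duration
#' @export
rebound_params <- function(delay_ms = 22.93, inh_gain = 0.045,
                           inh_dur_ms = 5.06, exc_gain = 0.1,
                           exc_dur_ms = 2.00) {
  stopifnot(delay_ms > 0, inh_gain >= 0, inh_dur_ms > 0,
            exc_gain >= 0, exc_dur_ms > 0)
  structure(list(delay_ms = delay_ms, inh_gain = inh_gain,
                 inh_dur_ms = inh_dur_ms, exc_gain = exc_gain,
                 exc_dur_ms = exc_dur_ms),
            class = c("rebound_params", "model_params"))
}

#' Parameters of the rebound model with feedforward inhibition
#'
#' Adds an inhibitory side path to the rebound model: the (delayed) stimulus
#' is passed through a second bi-phasic filter, its negative part is added
#' to the coincidence output, and the sum is rectified. When fitting, the
#' underlying rebound parameters are held fixed. Defaults are the fitted
#' Anurogryllus values.
#'
#' @param delay_ms delay of the inhibitory path (ms)
#' @param inh_gain,inh_dur_ms,exc_gain,exc_dur_ms bi-phasic filter lobes of
#'   the inhibitory path
#' @param base a [rebound_params()] object (held fixed during fitting)
#' @export
ffi_params <- function(delay_ms = 7.29, inh_gain = 1.01, inh_dur_ms = 2.43,
                       exc_gain = 0.63, exc_dur_ms = 2.45,
                       base = rebound_params()) {
  stopifnot(delay_ms > 0, inh_gain >= 0, inh_dur_ms > 0,
            exc_gain >= 0, exc_dur_ms > 0,
            inherits(base, "rebound_params"))
  structure(list(delay_ms = delay_ms, inh_gain = inh_gain,
                 inh_dur_ms = inh_dur_ms, exc_gain = exc_gain,
                 exc_dur_ms = exc_dur_ms, base = base),
            class = c("ffi_params", "model_params"))
}

#' Predicted phonotaxis from a model response trace
#'
#' The predicted score is the average model response over the stimulus,
#' excluding the first 25 ms and the last 10 ms to remove onset/offset
#' transients:
#' \deqn{p = \frac{1}{D_s - 35\,\mathrm{ms}} \int_{25}^{D_s - 10} r(t)\,dt}
#'
#' @param output response trace (numeric vector), or a `response_trace`
#'   object (its `output` component is used)
#' @param sample_rate sampling rate in Hz (taken from the trace object if
#'   one is supplied)
#' @param onset_skip_ms,offset_skip_ms excluded margins, defaults 25 and 10
#' @return the predicted phonotaxis score
#' @export
predict_phonotaxis <- function(output, sample_rate = NULL,
                               onset_skip_ms = 25, offset_skip_ms = 10) {
  if (inherits(output, "response_trace")) {
    sample_rate <- output$sample_rate
    output <- output$output
  }
  if (is.null(sample_rate)) stop("sample_rate required")
  dt <- 1000 / sample_rate
  ds <- length(output) * dt
  if (ds <= onset_skip_ms + offset_skip_ms)
    stop("stimulus too short for the integration window")
  t <- (seq_along(output) - 1) * dt
  idx <- t >= onset_skip_ms & t < ds - offset_skip_ms
  mean(output[idx])
}

.response_trace <- function(sample_rate, ...) {
  comps <- list(...)
  n <- unique(vapply(comps, length, integer(1)))
  stopifnot(length(n) == 1)
  structure(c(list(t_ms = (seq_len(n) - 1) * 1000 / sample_rate,
                   sample_rate = sample_rate), comps),
            class = "response_trace")
}

#' Simulate the autocorrelation model
#'
#' `output(t) = gain * s(t) * s(t - delay)`, with the delayed copy zero
#' before stimulus onset. Off-lattice delays are applied by linear
#' interpolation between the two straddling sample shifts.
#'
#' @param stim a [render_pulse_train()] result
#' @param params an [autocorr_params()]
#' @return a `response_trace` with components `stimulus`, `delayed`,
#'   `output`
#' @export
autocorr_response <- function(stim, params = autocorr_params()) {
  stopifnot(inherits(stim, "pulse_train"), inherits(params, "autocorr_params"))
  s <- stim$samples
  d <- params$delay_ms * stim$sample_rate / 1000
  sd_ <- .shift(s, d)
  .response_trace(stim$sample_rate, stimulus = s, delayed = sd_,
                  output = params$gain * s * sd_)
}

#' Discrete bi-phasic rebound kernel
#'
#' A negative rectangle (gain `-inh_gain`, duration `inh_dur_ms`) followed by
#' a positive rectangle (`+exc_gain`, `exc_dur_ms`). The discrete lobe
#' heights are scaled so that the lobe integrals equal the continuous
#' products `gain * duration` (in ms) exactly at any sample rate (the
#' rounded support would otherwise quantize them), which also keeps the
#' fitting objective smooth in the duration parameters.
#'
#' @param params a [rebound_params()] (or any list with the four lobe
#'   fields)
#' @param sample_rate sampling rate in Hz
#' @return numeric kernel vector (values already scaled by the sample
#'   interval; convolve directly)
#' @export
rebound_kernel <- function(params, sample_rate) {
  dt <- 1000 / sample_rate
  ni <- round(params$inh_dur_ms / dt)
  ne <- round(params$exc_dur_ms / dt)
  if (ni < 1 || ne < 1) stop("kernel lobe shorter than one sample")
  c(rep(-params$inh_gain * params$inh_dur_ms / ni, ni),
    rep(params$exc_gain * params$exc_dur_ms / ne, ne))
}

#' Simulate the rebound model
#'
#' The non-delayed pathway is inverted and filtered with the bi-phasic
#' kernel to produce a transient at each pulse offset (the post-inhibitory
#' rebound); the positive part is isolated by rectification and multiplied
#' with the delayed stimulus.
#'
#' The kernel is applied in reversed time (the filter convention of the
#' underlying network models, where the lobe listed first is the one
#' closest to the present): the inverted stimulus is convolved with
#' `rev(rebound_kernel(...))`. This orientation is calibrated against the
#' model's known phenomenology — inhibition during the pulse, a rebound
#' transient beginning at pulse offset whose amplitude saturates once the
#' pulse outlasts the inhibitory lobe, and a reduced but non-zero response
#' to continuous tones; the opposite orientation puts the transient at
#' pulse onset instead.
#'
#' @param stim a [render_pulse_train()] result
#' @param params a [rebound_params()]
#' @return a `response_trace` with components `stimulus`, `delayed`,
#'   `filtered` (bi-phasic filter output), `rebound` (rectified), `output`
#' @export
rebound_response <- function(stim, params = rebound_params()) {
  stopifnot(inherits(stim, "pulse_train"), inherits(params, "rebound_params"))
  s <- stim$samples
  k <- rebound_kernel(params, stim$sample_rate)
  sF <- .causal_conv(-s, rev(k))
  sR <- pmax(sF, 0)
  d <- params$delay_ms * stim$sample_rate / 1000
  sd_ <- .shift(s, d)
  .response_trace(stim$sample_rate, stimulus = s, delayed = sd_,
                  filtered = sF, rebound = sR, output = sR * sd_)
}

#' Simulate the rebound model with feedforward inhibition
#'
#' The inhibitory path delays the stimulus, filters it with its own
#' bi-phasic kernel and keeps only the negative components, which are added
#' to the rebound-model coincidence output; the sum is passed through a
#' rectifier with threshold 0 and gain 1.
#'
#' @param stim a [render_pulse_train()] result
#' @param params an [ffi_params()]
#' @return a `response_trace` with components `stimulus`, `coincidence`
#'   (rebound-model output), `inhibition` (non-positive), `output`
#' @export
ffi_response <- function(stim, params = ffi_params()) {
  stopifnot(inherits(stim, "pulse_train"), inherits(params, "ffi_params"))
  rb <- rebound_response(stim, params$base)
  kf <- rebound_kernel(params, stim$sample_rate)
  d <- params$delay_ms * stim$sample_rate / 1000
  w <- .causal_conv(-.shift(stim$samples, d), rev(kf))
  inh <- pmin(w, 0)
  drive <- rb$output + inh
  .response_trace(stim$sample_rate, stimulus = stim$samples,
                  coincidence = rb$output, inhibition = inh,
                  output = pmax(drive, 0))
}

#' Export a response trace as delimited text
#'
#' @param trace a `response_trace`
#' @param path file path
#' @export
write_response_trace <- function(trace, path) {
  comps <- trace[setdiff(names(trace), "sample_rate")]
  utils::write.table(as.data.frame(comps), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
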