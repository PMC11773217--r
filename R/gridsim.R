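# Vectorized grid simulation. Fitting evaluates a model on all stimuli of
# the 0.5 ms lattice at every optimizer step, so the per-stimulus traces are
# precomputed once (a samples x stimuli matrix plus its running sums) and
# each model evaluates as a handful of matrix operations. The per-stimulus
# functions in models_minimal.R are the reference implementations; tests
# assert both routes agree.

#' Precompute stimulus traces for grid-wide model evaluation
#'
#' @param grid a [make_fit_grid()] result (or any data frame with
#'   `pulse_ms`, `pause_ms`)
#' @param sample_rate simulation rate in Hz
#' @param total_ms stimulus duration, default 400
#' @return a `grid_context` holding the rendered stimulus matrix and
#'   derived quantities
#' @export
grid_context <- function(grid, sample_rate, total_ms = 400) {
  n <- round(total_ms * sample_rate / 1000)
  dt <- 1000 / sample_rate
  t <- (seq_len(n) - 1) * dt
  m <- nrow(grid)
  S <- matrix(0, n, m)
  for (j in seq_len(m)) {
    Tj <- grid$pulse_ms[j] + grid$pause_ms[j]
    S[, j] <- ifelse((t %% Tj) < grid$pulse_ms[j] - 1e-9, 1, 0)
  }
  # cumulative sums (zero-padded first row) for O(1) box filters
  C <- rbind(0, apply(S, 2, cumsum))
  win <- which(t >= 25 & t < total_ms - 10)
  structure(list(S = S, C = C, grid = grid, sample_rate = sample_rate,
                 dt = dt, n = n, win = win, total_ms = total_ms),
            class = "grid_context")
}

# rows of S delayed by d (possibly fractional) samples, zero padded;
# fractional delays interpolate the two straddling integer shifts
.shift_mat <- function(S, d) {
  n <- nrow(S)
  ishift <- function(k) {
    if (k <= 0) return(S)
    if (k >= n) return(matrix(0, n, ncol(S)))
    rbind(matrix(0, k, ncol(S)), S[seq_len(n - k), , drop = FALSE])
  }
  d0 <- floor(d)
  f <- d - d0
  if (f < 1e-9) ishift(d0)
  else (1 - f) * ishift(d0) + f * ishift(d0 + 1)
}

# windowed column means of elementwise product of S and S delayed by d
.win_mean_prod <- function(ctx, A, B) {
  colMeans(A[ctx$win, , drop = FALSE] * B[ctx$win, , drop = FALSE])
}

# bi-phasic box filter of every stimulus column via cumulative sums;
# reversed-time application of the (inhibitory, excitatory) kernel, i.e.
# conv(-s, rev(k)):
# out[n] = dt * (-ge * sum(s[n-ne+1..n]) + gi * sum(s[n-ne-ni+1..n-ne]))
.biphasic_filter_mat <- function(ctx, inh_gain, inh_dur_ms, exc_gain,
                                 exc_dur_ms) {
  li <- .lobe_eff(inh_gain, inh_dur_ms, ctx$dt)
  le <- .lobe_eff(exc_gain, exc_dur_ms, ctx$dt)
  ni <- li$n; ne <- le$n
  n <- ctx$n
  C <- ctx$C  # (n + 1) x m, C[i + 1, ] = cumsum up to sample i
  idx <- seq_len(n) + 1
  box <- function(lag, len) {
    hi <- pmax(idx - lag, 1)
    lo <- pmax(idx - lag - len, 1)
    C[hi, , drop = FALSE] - C[lo, , drop = FALSE]
  }
  ctx$dt * (-le$g * box(0, ne) + li$g * box(ne, ni))
}

# grid-wide phonotaxis predictions per model ---------------------------------

.predict_grid_autocorr <- function(params, ctx) {
  d <- params$delay_ms * ctx$sample_rate / 1000
  .autocorr_scores_core(ctx$S, params$gain, d, min(ctx$win), max(ctx$win))
}

# effective lobe heights preserving the continuous lobe integrals (see
# rebound_kernel); the core multiplies by dt
.lobe_eff <- function(gain, dur_ms, dt) {
  n <- max(1, round(dur_ms / dt))
  list(n = n, g = gain * dur_ms / (n * dt))
}

.predict_grid_rebound <- function(params, ctx) {
  d <- params$delay_ms * ctx$sample_rate / 1000
  li <- .lobe_eff(params$inh_gain, params$inh_dur_ms, ctx$dt)
  le <- .lobe_eff(params$exc_gain, params$exc_dur_ms, ctx$dt)
  .rebound_scores_core(ctx$S, ctx$dt, li$g, li$n, le$g, le$n, d,
                       min(ctx$win), max(ctx$win), FALSE,
                       0, 0L, 0, 0L, 0L)
}

# instantaneous (non-integrated) rebound-model output for every stimulus;
# used as the drive of the LIFAC stage
.rebound_drive_mat <- function(params, ctx) {
  sF <- .biphasic_filter_mat(ctx, params$inh_gain, params$inh_dur_ms,
                             params$exc_gain, params$exc_dur_ms)
  sR <- pmax(sF, 0)
  d <- params$delay_ms * ctx$sample_rate / 1000
  sR * .shift_mat(ctx$S, d)
}

.predict_grid_ffi <- function(params, ctx) {
  b <- params$base
  d <- b$delay_ms * ctx$sample_rate / 1000
  li <- .lobe_eff(b$inh_gain, b$inh_dur_ms, ctx$dt)
  le <- .lobe_eff(b$exc_gain, b$exc_dur_ms, ctx$dt)
  df <- params$delay_ms * ctx$sample_rate / 1000
  lfi <- .lobe_eff(params$inh_gain, params$inh_dur_ms, ctx$dt)
  lfe <- .lobe_eff(params$exc_gain, params$exc_dur_ms, ctx$dt)
  .rebound_scores_core(ctx$S, ctx$dt, li$g, li$n, le$g, le$n, d,
                       min(ctx$win), max(ctx$win), TRUE,
                       lfi$g, lfi$n, lfe$g, lfe$n, df)
}

.predict_grid_rf <- function(params, ctx) {
  if (abs(ctx$sample_rate - 1000 / params$dt_ms) > 1e-6)
    stop("grid context sample rate incompatible with rf dt_ms")
  omega <- 2 * pi * params$freq_hz / 1000
  win_lo <- min(ctx$win); win_hi <- max(ctx$win)
  win_ms <- length(ctx$win) * ctx$dt
  vapply(seq_len(ncol(ctx$S)), function(j) {
    res <- .rf_core(ctx$S[, j], params$dt_ms, omega, params$damping,
                    params$input_gain, params$x_reset, params$y_reset,
                    params$y_thresh, FALSE)
    k <- sum(res$spikes >= win_lo & res$spikes <= win_hi)
    params$spike_amp * k / win_ms
  }, numeric(1))
}

#' Predict phonotaxis scores for every stimulus on a grid
#'
#' Evaluates a minimal model on all stimuli of a precomputed
#' [grid_context()] and returns one predicted score per stimulus. This is
#' the vectorized path used by the fitting machinery; it agrees with
#' simulating each stimulus through the corresponding `*_response()`
#' function and [predict_phonotaxis()].
#'
#' @param params an `autocorr_params`, `rebound_params`, `ffi_params` or
#'   `rf_params` object
#' @param ctx a [grid_context()]
#' @return numeric vector of predicted scores, one per grid row
#' @export
predict_grid <- function(params, ctx) {
  stopifnot(inherits(ctx, "grid_context"))
  if (inherits(params, "autocorr_params")) .predict_grid_autocorr(params, ctx)
  else if (inherits(params, "ffi_params")) .predict_grid_ffi(params, ctx)
  else if (inherits(params, "rebound_params")) .predict_grid_rebound(params, ctx)
  else if (inherits(params, "rf_params")) .predict_grid_rf(params, ctx)
  else stop("unknown model parameter class")
}

#' Evaluate a model over a grid and return a preference field
#'
#' @param params model parameters (see [predict_grid()])
#' @param grid a [make_fit_grid()] result
#' @param sample_rate simulation rate in Hz
#' @param total_ms stimulus duration
#' @return a [preference_field()] on the grid lattice
#' @export
model_field <- function(params, grid = make_fit_grid(),
                        sample_rate = 10000, total_ms = 400) {
  ctx <- grid_context(grid, sample_rate, total_ms)
  p <- predict_grid(params, ctx)
  pulse_axis <- sort(unique(grid$pulse_ms))
  pause_axis <- sort(unique(grid$pause_ms))
  v <- matrix(NA_real_, length(pulse_axis), length(pause_axis))
  v[cbind(match(grid$pulse_ms, pulse_axis),
          match(grid$pause_ms, pause_axis))] <- p
  preference_field(pulse_axis, pause_axis, pmax(v, 0))
}
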