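# Independent oracles and small fixtures shared across tests.

# Brute-force autocorrelation oracle: overlap of the periodic pulse set with
# its delayed copy by interval arithmetic (exact real arithmetic, no
# sampling), integrated over the phonotaxis window.
autocorr_oracle <- function(pulse_ms, pause_ms, delay_ms, gain,
                            total_ms = 400, win = c(25, total_ms - 10)) {
  Tp <- pulse_ms + pause_ms
  starts <- seq(0, total_ms, by = Tp)
  a <- cbind(starts, pmin(starts + pulse_ms, total_ms))      # pulses
  b <- cbind(starts + delay_ms, starts + delay_ms + pulse_ms) # delayed
  b[, 2] <- pmin(b[, 2], total_ms)
  b <- b[b[, 1] < total_ms, , drop = FALSE]
  ov <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a[i, 1], b[j, 1], win[1])
    hi <- min(a[i, 2], b[j, 2], win[2])
    if (hi > lo) ov <- ov + (hi - lo)
  }
  gain * ov / diff(win)
}

# step-by-step R reimplementation of the LIFAC Euler scheme (oracle for the
# compiled core)
lifac_oracle <- function(I, dt, tau_m, tau_ada, alpha, v_thres, v_reset,
                         tau_ref) {
  V <- 0; A <- 0; refrac <- 0
  n_ref <- round(tau_ref / dt)
  spikes <- integer(0)
  for (i in seq_along(I)) {
    if (refrac > 0) {
      refrac <- refrac - 1
    } else {
      V <- V + dt * (-V + I[i] - A) / tau_m
      A <- A + dt * (-A) / tau_ada
      if (V >= v_thres) {
        spikes <- c(spikes, i)
        V <- v_reset
        A <- A + alpha
        refrac <- n_ref
      }
    }
  }
  spikes
}

# indices of strict local maxima of a curve
local_maxima <- function(x) which(diff(sign(diff(x))) == -2) + 1

# small scattered phonotaxis fixture on the grid lattice (so the
# interpolating property can be checked against grid nodes exactly)
scatter_records <- function(n = 30, seed = 11) {
  set.seed(seed)
  g <- make_fit_grid(20, 0.5)
  idx <- sample(nrow(g), n)
  data.frame(pulse_ms = g$pulse_ms[idx], pause_ms = g$pause_ms[idx],
             score = runif(n))
}
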