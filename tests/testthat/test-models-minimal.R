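test_that("phonotaxis prediction integrates the right window", {
  sr <- 1000
  expect_equal(predict_phonotaxis(rep(1, 400), sr), 1)
  expect_equal(predict_phonotaxis(rep(0, 400), sr), 0)
  # output confined to the first 25 ms contributes nothing
  x <- c(rep(1, 25), rep(0, 375))
  expect_equal(predict_phonotaxis(x, sr), 0)
  expect_error(predict_phonotaxis(rep(1, 30), sr), "too short")
})

test_that("autocorrelation responses follow the delay-coincidence rule", {
  par <- autocorr_params(delay_ms = 17, gain = 0.21)
  sr <- 10000

  # continuous tone: output = gain once the delayed copy arrives
  tone <- render_pulse_train(pulse_train_spec(8, 0, 400, sample_rate = sr))
  rt <- autocorr_response(tone, par)
  expect_equal(unique(rt$output[rt$t_ms >= 17]), par$gain)

  # period equal to the delay: perfect coincidence after one period
  st <- render_pulse_train(pulse_train_spec(8.5, 8.5, 400, sample_rate = sr))
  rt2 <- autocorr_response(st, par)
  late <- rt2$t_ms >= 25
  expect_equal(rt2$output[late], par$gain * st$samples[late])

  # period 2*delay at DC 25%: pulses land in the delayed copy's pause
  st3 <- render_pulse_train(pulse_train_spec(8.5, 25.5, 400, sample_rate = sr))
  rt3 <- autocorr_response(st3, par)
  expect_equal(max(rt3$output[rt3$t_ms >= 34]), 0)
})

test_that("simulated autocorrelation scores match the interval-arithmetic oracle", {
  par <- autocorr_params(delay_ms = 17, gain = 0.21)
  cases <- data.frame(pulse_ms = c(4.25, 3, 5.1, 8, 2.5),
                      pause_ms = c(4.25, 9, 3.4, 8, 14.5))
  ctx <- grid_context(cases, 10000)
  fast <- predict_grid(par, ctx)
  for (i in seq_len(nrow(cases))) {
    oracle <- autocorr_oracle(cases$pulse_ms[i], cases$pause_ms[i], 17, 0.21)
    expect_equal(fast[i], oracle, tolerance = 0.04)
  }
})

test_that("autocorrelation output is bilinear in amplitude and gain", {
  sr <- 4000
  base <- render_pulse_train(pulse_train_spec(5, 4, 400, sample_rate = sr))
  loud <- render_pulse_train(pulse_train_spec(5, 4, 400, amplitude = 2,
                                              sample_rate = sr))
  p1 <- predict_phonotaxis(autocorr_response(base, autocorr_params(17, 0.2)))
  p2 <- predict_phonotaxis(autocorr_response(loud, autocorr_params(17, 0.2)))
  p3 <- predict_phonotaxis(autocorr_response(base, autocorr_params(17, 0.4)))
  expect_equal(p2, 4 * p1)  # quadratic in amplitude (two multiplied copies)
  expect_equal(p3, 2 * p1)  # linear in gain
})

test_that("the rebound kernel preserves the continuous lobe integrals", {
  par <- rebound_params()
  for (sr in c(4000, 10000)) {
    k <- rebound_kernel(par, sr)
    expect_equal(sum(k[k < 0]), -par$inh_gain * par$inh_dur_ms)  # -0.2277
    expect_equal(sum(k[k > 0]), par$exc_gain * par$exc_dur_ms)   # +0.2
    expect_equal(length(k), round(par$inh_dur_ms * sr / 1000) +
                   round(par$exc_dur_ms * sr / 1000))
  }
  expect_error(rebound_kernel(rebound_params(exc_dur_ms = 0.01), 4000),
               "shorter than one sample")
})

test_that("rebound transients occur at pulse offsets, not during pulses", {
  sr <- 4000
  st <- render_pulse_train(pulse_train_spec(8, 100, 400, sample_rate = sr))
  rb <- rebound_response(st, rebound_params())
  # second pulse spans 108-116 ms
  during <- rb$t_ms >= 109.5 & rb$t_ms < 116
  after <- rb$t_ms >= 116 & rb$t_ms < 126
  # the offset transient dominates; the residual in-pulse response equals
  # the small net lobe-integral difference gi*Ti - ge*Te (the reduced but
  # non-zero drive that remains for continuous tones)
  expect_lt(max(rb$rebound[during]), 0.15 * max(rb$rebound[after]))
  expect_equal(max(rb$rebound[during]), 0.045 * 5.06 - 0.1 * 2,
               tolerance = 0.01)
  # rebound amplitude saturates at the inhibitory lobe integral
  expect_equal(max(rb$rebound[after]), 0.045 * 5.06, tolerance = 0.01)

  # zero stimulus: all traces zero
  z <- render_pulse_train(pulse_train_spec(5, 5, 400, amplitude = 0,
                                           sample_rate = sr))
  expect_equal(max(abs(rebound_response(z)$output)), 0)
})

test_that("short pauses truncate the rebound", {
  sr <- 4000
  par <- rebound_params()
  per_offset_rebound <- function(pause) {
    st <- render_pulse_train(pulse_train_spec(8, pause, 400,
                                              sample_rate = sr))
    rb <- rebound_response(st, par)
    sum(rb$rebound) / sum(diff(st$samples) == -1)
  }
  expect_lt(per_offset_rebound(1), per_offset_rebound(10))
})

test_that("rebound DC tuning is band-pass with reduced, non-zero tone response", {
  fld <- model_field(rebound_params(), make_fit_grid(20, 0.5), 4000)
  ct <- dc_transect(fld, 8.5)
  peak <- max(ct$value)
  at95 <- ct$value[which.min(abs(ct$duty_cycle - 0.95))]
  expect_lt(at95, peak)              # suppressed at very high DC
  expect_gt(at95, 0)                 # but not silenced
  expect_gt(ct$duty_cycle[which.max(ct$value)], 0.3)
  expect_lt(ct$duty_cycle[which.max(ct$value)], 0.85)
})

test_that("feedforward inhibition reduces to the rebound model when disabled", {
  sr <- 4000
  st <- render_pulse_train(pulse_train_spec(5.1, 3.4, 400, sample_rate = sr))
  off <- ffi_params(inh_gain = 1e-12, exc_gain = 1e-12)
  expect_equal(ffi_response(st, off)$output, rebound_response(st)$output,
               tolerance = 1e-6)
  z <- render_pulse_train(pulse_train_spec(5, 5, 400, amplitude = 0,
                                           sample_rate = sr))
  expect_equal(max(abs(ffi_response(z)$output)), 0)
})

test_that("feedforward inhibition suppresses DC 50% at twice the song period", {
  sc <- function(D, P) {
    st <- render_pulse_train(pulse_train_spec(D, P, 400, sample_rate = 4000))
    predict_phonotaxis(ffi_response(st))
  }
  expect_lt(sc(8.6, 8.6), sc(12.9, 4.3))   # DC 50 < DC 75 at 2 Ts
})

test_that("grid predictions agree with per-stimulus reference simulations", {
  g <- make_fit_grid(20, 0.5)
  set.seed(2)
  idx <- sample(nrow(g), 6)
  ctx <- grid_context(g[idx, ], 4000)
  for (par in list(autocorr_params(), rebound_params(), ffi_params())) {
    fast <- predict_grid(par, ctx)
    ref <- vapply(idx, function(j) {
      st <- render_pulse_train(pulse_train_spec(g$pulse_ms[j], g$pause_ms[j],
                                                400, sample_rate = 4000))
      resp <- if (inherits(par, "autocorr_params")) autocorr_response(st, par)
      else if (inherits(par, "ffi_params")) ffi_response(st, par)
      else rebound_response(st, par)
      predict_phonotaxis(resp)
    }, numeric(1))
    expect_equal(fast, ref, tolerance = 1e-10)
  }
})

test_that("model parameter files round-trip", {
  path <- withr::local_tempfile(fileext = ".json")
  for (par in list(autocorr_params(12.5, 0.3), rebound_params(),
                   ffi_params(), rf_params(), lifac_params())) {
    write_model_params(par, path)
    back <- read_model_params(path)
    expect_equal(back, par)
  }
})

test_that("response traces export as delimited text", {
  st <- render_pulse_train(pulse_train_spec(5, 5, 400, sample_rate = 1000))
  tr <- autocorr_response(st)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_response_trace(tr, path)
  back <- utils::read.delim(path)
  expect_equal(back$output, tr$output)
})
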