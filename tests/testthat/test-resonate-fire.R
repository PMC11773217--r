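rf_count <- function(pulse_ms, pause_ms, params = rf_params()) {
  st <- render_pulse_train(pulse_train_spec(pulse_ms, pause_ms, 400,
                                            sample_rate = 1000 / params$dt_ms))
  length(rf_simulate(st, params, keep_traces = FALSE)$spike_times_ms)
}

test_that("silence leaves the resonate-and-fire neuron at rest", {
  st <- render_pulse_train(pulse_train_spec(5, 5, 400, amplitude = 0,
                                            sample_rate = 10000))
  tr <- rf_simulate(st)
  expect_equal(length(tr$spike_times_ms), 0)
  expect_equal(max(abs(tr$x)), 0)
  expect_equal(max(abs(tr$y)), 0)
})

test_that("an undamped impulse rotates at the characteristic frequency", {
  p <- rf_params(damping = 0, input_gain = 1)
  st <- render_pulse_train(pulse_train_spec(0.1, 399.9, 400,
                                            amplitude = 0.1,
                                            sample_rate = 10000))
  tr <- rf_simulate(st)
  zc <- which(diff(sign(tr$y)) != 0)
  # zero crossings of y separated by half the intrinsic period
  expect_equal(mean(diff(zc)) * p$dt_ms, 1000 / (2 * p$freq_hz),
               tolerance = 0.01)
})

test_that("damped free dynamics decay and subthreshold dynamics are linear", {
  # free decay from an impulse-injected state
  p <- rf_params(damping = -0.01, input_gain = 1)
  st <- render_pulse_train(pulse_train_spec(0.1, 399.9, 400, amplitude = 0.5,
                                            sample_rate = 10000))
  tr <- rf_simulate(st, p)
  env <- sqrt(tr$x^2 + tr$y^2)
  i0 <- 50; i1 <- 2000; i2 <- 3990
  expect_gt(env[i0], env[i1])
  expect_gt(env[i1], env[i2])

  # scaling the input scales (x, y) while subthreshold
  p1 <- rf_params(input_gain = 0.001)
  p2 <- rf_params(input_gain = 0.002)
  st2 <- render_pulse_train(pulse_train_spec(4.5, 4.5, 400,
                                             sample_rate = 10000))
  t1 <- rf_simulate(st2, p1); t2 <- rf_simulate(st2, p2)
  expect_equal(length(t1$spike_times_ms), 0)
  expect_equal(t2$y, 2 * t1$y, tolerance = 1e-10)
})

test_that("the neuron responds at multiples of its period but not fractions", {
  Trf <- 1000 / rf_params()$freq_hz
  # fractions of the characteristic period: silent
  expect_equal(rf_count(Trf / 4, Trf / 4), 0)        # Trf/2, DC 50
  expect_equal(rf_count(Trf / 2, Trf), 0)            # 1.5 Trf, DC 33
  # the characteristic period and its double: active
  expect_gt(rf_count(Trf / 2, Trf / 2), 10)          # Trf, DC 50
  expect_gt(rf_count(2 * Trf * 0.75, 2 * Trf * 0.25), 0)  # 2 Trf, DC 75
  # spike count at 2/f >= count at 1/(2f) for DC 50% trains
  expect_gte(rf_count(Trf, Trf), rf_count(Trf / 4, Trf / 4))
})

test_that("DC tuning at twice the characteristic period is bimodal", {
  Trf2 <- 2 * 1000 / rf_params()$freq_hz
  n25 <- rf_count(0.25 * Trf2, 0.75 * Trf2)
  n50 <- rf_count(0.50 * Trf2, 0.50 * Trf2)
  n75 <- rf_count(0.75 * Trf2, 0.25 * Trf2)
  expect_gt(n25, 0)
  expect_gt(n75, 0)
  expect_lt(n50, min(n25, n75))      # suppressed where the pulse spans a full cycle
  expect_gte(n75, n25)               # high-DC peak at least as strong
})

test_that("halving the time step leaves conspecific spike counts stable", {
  n1 <- rf_count(5.1, 3.4, rf_params(dt_ms = 0.1))
  n2 <- rf_count(5.1, 3.4, rf_params(dt_ms = 0.05))
  expect_lte(abs(n1 - n2), 1)
})

test_that("stimulus sample rate must match the integration step", {
  st <- render_pulse_train(pulse_train_spec(5, 5, 400, sample_rate = 4000))
  expect_error(rf_simulate(st), "incompatible")
})

test_that("the spike-train output integrates to spike_amp per spike", {
  p <- rf_params()
  st <- render_pulse_train(pulse_train_spec(4.57, 4.57, 400,
                                            sample_rate = 10000))
  tr <- rf_simulate(st, p)
  expect_equal(sum(tr$output) * p$dt_ms,
               p$spike_amp * length(tr$spike_times_ms))
  expect_equal(rf_score(st, p), predict_phonotaxis(tr$output, 10000))
})
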