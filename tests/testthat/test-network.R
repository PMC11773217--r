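test_that("the default network has exactly 45 free parameters", {
  expect_equal(n_free_params(anurogryllus_network()), 45)
})

test_that("filters, nonlinearities and adaptation behave as specified", {
  sr <- 1000
  # delta through a single gaussian lobe returns the kernel itself
  lob <- filter_lobe("gaussian", 2, 10, 0.5)
  x <- c(1 / (1000 / sr), numeric(99))  # discrete delta of unit area
  out <- apply_filter(x, list(lob), sr)
  k <- cricketsong:::.lobe_kernel(lob, sr)
  expect_equal(out[seq_along(k)], k, tolerance = 1e-9)
  # gaussian lobe kernel integrates to its gain
  expect_equal(sum(k) * (1000 / sr), 0.5)

  # constant input through a zero-mean differentiated gaussian dies out
  dg <- filter_lobe("differentiated_gaussian", NULL, 10, 1)
  outc <- apply_filter(rep(1, 200), list(dg), sr)
  expect_lt(max(abs(outc[50:200])), 1e-8)

  # step through an exponential inhibitory lobe: response approaches the
  # accumulated (negative) kernel area
  ex <- filter_lobe("exponential", 15.87, 1000, -1)
  outs <- apply_filter(rep(1, 400), list(ex), sr)
  expect_equal(outs[400],
               sum(cricketsong:::.lobe_kernel(ex, sr)[1:400]) * (1000 / sr),
               tolerance = 0.01)
  expect_lt(outs[400], -0.9)  # most of the unit lobe area within 400 ms

  # empty lobe list is the identity
  expect_equal(apply_filter(x, list(), sr), x)

  # divisive normalization: limits and guards
  spec <- adaptation_spec(50, 0.5, 1)
  expect_equal(divisive_norm(rep(2, 10), adaptation_spec(50, 0, 2), sr),
               rep(1, 10))
  cst <- divisive_norm(rep(3, 5000), spec, sr)
  expect_equal(cst[5000], 3 / (1 + 0.5 * 3), tolerance = 1e-3)
  expect_equal(divisive_norm(numeric(10), spec, sr), numeric(10))
  expect_error(divisive_norm(rep(-10, 2000), adaptation_spec(5, 1, 1), sr),
               "denominator")
})

test_that("network simulation respects rectifier bounds and silence", {
  np <- anurogryllus_network()
  z <- render_pulse_train(pulse_train_spec(5, 5, 400, amplitude = 0,
                                           sample_rate = np$sample_rate))
  simz <- simulate_network(z, np)
  st <- render_pulse_train(pulse_train_spec(5.1, 3.4, 400,
                                            sample_rate = np$sample_rate))
  sim <- simulate_network(st, np)
  # silence leaves only a negligible startup ripple (the sigmoid's negative
  # resting baseline makes the rest state non-zero upstream of the
  # rectifiers), far below the conspecific response
  expect_lt(simz$score, 0.05 * sim$score)
  for (nm in c("LN2", "LN5", "LN3", "LN4"))
    expect_gte(min(sim$traces[[nm]]), 0)
  # the sigmoid stage itself is bounded by baseline and baseline + gain
  sg <- nl_sigmoid(10.33, 0.62, 1.19, -0.29)
  x <- seq(-100, 100, length.out = 1001)
  y <- cricketsong:::.apply_nonlin(x, sg)
  expect_gte(min(y), -0.29 - 1e-9)
  expect_lte(max(y), -0.29 + 1.19 + 1e-9)
})

test_that("a mismatched stimulus or missing source is a configuration error", {
  np <- anurogryllus_network()
  st <- render_pulse_train(pulse_train_spec(5, 5, 400, sample_rate = 4000))
  expect_error(simulate_network(st, np), "sample rate")
  np2 <- np
  np2$neurons$LN3$inputs[[2]]$source <- "LN9"
  st2 <- render_pulse_train(pulse_train_spec(5, 5, 400,
                                             sample_rate = np$sample_rate))
  expect_error(simulate_network(st2, np2), "missing source")
})

test_that("the effective LN3 input delay reduces to delay differences", {
  # toy network: two pure-delay synapses from the stimulus onto LN3
  np <- anurogryllus_network()
  toy <- np
  toy$neurons$AN1 <- list(inputs = list(synapse("stimulus", 0, 1)),
                          stages = list())
  toy$neurons$LN2 <- list(inputs = list(synapse("stimulus", 0, 1)),
                          stages = list())
  toy$neurons$LN5 <- list(inputs = list(synapse("stimulus", 0, 1)),
                          stages = list())
  toy$neurons$LN3$inputs <- list(synapse("AN1", 5, 1), synapse("LN5", 12, 1))
  expect_equal(effective_ln3_input_delay(toy), 7, tolerance = 0.11)

  toy$neurons$LN3$inputs <- list(synapse("AN1", 9, 1), synapse("LN5", 9, 1))
  expect_equal(effective_ln3_input_delay(toy), 0, tolerance = 0.11)
})

test_that("removing LN2->LN4 inhibition disinhibits the output", {
  np <- anurogryllus_network()
  ablated <- np
  ablated$neurons$LN4$inputs[[1]]$gain <- 0
  st <- render_pulse_train(pulse_train_spec(8.6, 8.6, 400,
                                            sample_rate = np$sample_rate))
  with_inh <- simulate_network(st, np)$score
  without <- simulate_network(st, ablated)$score
  expect_gt(without, with_inh)
})

test_that("network parameters round-trip losslessly through JSON", {
  np <- anurogryllus_network()
  path <- withr::local_tempfile(fileext = ".json")
  write_network_params(np, path)
  back <- read_network_params(path)
  expect_equal(back, np)
  expect_equal(n_free_params(back), 45)
  st <- render_pulse_train(pulse_train_spec(8.6, 8.6, 400,
                                            sample_rate = np$sample_rate))
  expect_equal(simulate_network(st, back)$score,
               simulate_network(st, np)$score)
})
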