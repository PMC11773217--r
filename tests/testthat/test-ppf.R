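test_that("interpolation is exact at the data points and constant on constant data", {
  # four corners plus centre all scoring 0.5 -> constant field
  rec <- data.frame(pulse_ms = c(2, 2, 18, 18, 10),
                    pause_ms = c(2, 18, 2, 18, 10), score = 0.5)
  f <- interpolate_field(rec, resolution = 0.5, extent = 20)
  expect_equal(field_value(f, 10, 10), 0.5)
  expect_equal(max(abs(f$values - 0.5)), 0, tolerance = 1e-10)

  # interpolating property at scattered on-lattice records
  rec2 <- scatter_records(30)
  f2 <- interpolate_field(rec2, resolution = 0.5, extent = 20,
                          clip_negative = FALSE)
  at <- field_value(f2, rec2$pulse_ms, rec2$pause_ms)
  expect_equal(at, rec2$score, tolerance = 1e-8)
})

test_that("negative interpolated values are clipped and the hull is extended", {
  # a single triangle defines the plane f = 1 - 1.2 * pause/20, dipping to
  # -0.2 at one vertex: the clipped region is exactly 0
  rec <- data.frame(pulse_ms = c(0, 20, 0), pause_ms = c(0, 0, 20),
                    score = c(1, 1, -0.2))
  f <- interpolate_field(rec, resolution = 0.5, extent = 20)
  expect_equal(field_value(f, 0, 20), 0)
  expect_true(all(f$values >= 0))
  expect_equal(field_value(f, 10, 5), 1 - 1.2 * 5 / 20, tolerance = 1e-6)
  expect_equal(field_value(f, 2, 18), 0)  # plane is -0.08 there, clipped

  # outside the hull: nearest-record extension
  rec3 <- data.frame(pulse_ms = c(8, 12, 10), pause_ms = c(8, 8, 12),
                     score = c(0.2, 0.4, 0.9))
  f3 <- interpolate_field(rec3, resolution = 1, extent = 20)
  expect_equal(field_value(f3, 0, 20), 0.9)   # nearest record is (10,12)
  expect_equal(field_value(f3, 20, 0), 0.4)   # nearest record is (12,8)
})

test_that("degenerate record sets are rejected", {
  expect_error(interpolate_field(data.frame(pulse_ms = c(1, 2),
                                            pause_ms = c(1, 2),
                                            score = c(0, 1))),
               "at least 3")
  expect_error(interpolate_field(data.frame(pulse_ms = 1:6, pause_ms = 1:6,
                                            score = runif(6))),
               "collinear")
})

test_that("transects slice the field consistently", {
  rec <- data.frame(pulse_ms = c(2, 2, 18, 18, 10),
                    pause_ms = c(2, 18, 2, 18, 10), score = 0.7)
  f <- interpolate_field(rec, resolution = 0.5, extent = 20)
  tr <- period_transect(f, 0.5)
  expect_equal(unique(round(tr$value, 8)), 0.7)
  dt <- dc_transect(f, 17.2)
  expect_equal(unique(round(dt$value, 8)), 0.7)

  # a single Gaussian bump at (period 8.6, DC 50): transect argmax at 8.6
  spec <- synth_ppf_spec(data.frame(period_ms = 8.6, dc = 0.5,
                                    amplitude = 1, period_sd_ms = 1.5,
                                    dc_sd = 0.12), resolution = 0.1)
  fb <- synth_preference_field(spec)
  trb <- period_transect(fb, 0.5)
  expect_lt(abs(trb$period_ms[which.max(trb$value)] - 8.6),
            2 * fb$resolution + 1e-9)

  # symmetry: dc = 0.5 transect invariant under pulse<->pause transpose
  recs <- scatter_records(25, seed = 5)
  recs <- rbind(recs,
                data.frame(pulse_ms = recs$pause_ms, pause_ms = recs$pulse_ms,
                           score = recs$score))
  fs <- interpolate_field(recs, resolution = 0.5, extent = 20)
  ft <- preference_field(fs$pause_axis, fs$pulse_axis, t(fs$values))
  expect_equal(period_transect(fs, 0.5)$value, period_transect(ft, 0.5)$value,
               tolerance = 1e-8)

  # period and dc transects agree where their query lines cross
  f2 <- synth_preference_field()
  pt <- period_transect(f2, 0.5)
  ct <- dc_transect(f2, 17.2)
  v1 <- pt$value[which.min(abs(pt$period_ms - 17.2))]
  v2 <- ct$value[which.min(abs(ct$duty_cycle - 0.5))]
  expect_equal(v1, v2, tolerance = 1e-8)

  expect_error(period_transect(f, 1.5), "duty cycle")
  expect_error(dc_transect(f, 100), "reach")
})

test_that("transects of a non-negative field stay non-negative", {
  f <- synth_preference_field()
  expect_true(all(period_transect(f, 0.33)$value >= 0))
  expect_true(all(dc_transect(f, 8.6)$value >= 0))
})

test_that("the paired one-sided peak test matches hand computation", {
  # identical vectors: t = 0, p = 0.5 (degenerate, warned)
  expect_warning(p0 <- peak_significance(c(1, 1, 1), c(1, 1, 1)),
                 "zero variance")
  expect_equal(as.numeric(p0), 0.5)

  # constant positive shift: p -> 0 degenerate
  expect_warning(p1 <- peak_significance(c(2, 3, 4), c(1, 2, 3)),
                 "zero variance")
  expect_equal(as.numeric(p1), 0)

  # hand-computed t with 3 df
  d <- c(0.3, 0.1, 0.2, 0.4)
  p <- peak_significance(d + 1, rep(1, 4))
  expect_equal(p, stats::pt(mean(d) / (stats::sd(d) / 2), df = 3,
                            lower.tail = FALSE))

  expect_error(peak_significance(1:3, 1:4), "equal length")
  expect_error(peak_significance(1, 2), "at least 2")
})

test_that("phonotaxis tables and preference fields round-trip", {
  f <- synth_preference_field(synth_ppf_spec(
    data.frame(period_ms = 8.6, dc = 0.5, amplitude = 1,
               period_sd_ms = 1.5, dc_sd = 0.12), resolution = 0.5))
  stim <- make_fit_grid(20, 0.5)[c(5, 100, 700, 1500), c("pulse_ms", "pause_ms")]
  tab <- synth_phonotaxis_table(f, stim, noise_sd = 0.05, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phonotaxis_table(tab, path)
  tab2 <- read_phonotaxis_table(path)
  expect_equal(tab2$score, tab$score)
  expect_equal(tab2$n_females, tab$n_females)

  fp <- withr::local_tempfile(fileext = ".tsv")
  write_preference_field(f, fp)
  f2 <- read_preference_field(fp)
  expect_equal(f2$values, f$values, ignore_attr = TRUE)
  expect_equal(f2$resolution, f$resolution)

  # inconsistent per-female scores are flagged on read
  tab$female_1 <- tab$female_1 + 5
  write_phonotaxis_table(tab, path)
  expect_warning(read_phonotaxis_table(path), "inconsistent")
})
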