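# Synthetic inputs: an Anurogryllus-like resonant preference field, noisy
# phonotaxis tables derived from it, and carrier-gated song waveforms. These
# emulate the structure of the behavioural data (a broad peak at the song
# period over intermediate duty cycles, a strong peak at twice the period
# and high DC, a weak peak at twice the period and low DC) so the whole
# pipeline runs without any external download.

#' Specify a synthetic resonant preference field
#'
#' The field is a sum of two-dimensional Gaussians in (period, duty-cycle)
#' space, mapped onto the pulse/pause lattice and clipped at zero.
#'
#' @param peaks data frame with columns `period_ms`, `dc`, `amplitude`,
#'   `period_sd_ms`, `dc_sd`
#' @param extent lattice covers `[0, extent]` ms on both axes
#' @param resolution lattice step (ms)
#' @export
synth_ppf_spec <- function(peaks, extent = 20, resolution = 0.1) {
  need <- c("period_ms", "dc", "amplitude", "period_sd_ms", "dc_sd")
  stopifnot(all(need %in% names(peaks)), all(peaks$amplitude >= 0))
  structure(list(peaks = peaks, extent = extent, resolution = resolution),
            class = "synth_ppf_spec")
}

#' Default Anurogryllus-like field specification
#'
#' Three peaks around the song period Ts = 8.6 ms: a broad peak at Ts
#' centred at DC 56% (its +/- 2 sd span covers DCs of roughly 33-80%), a
#' strong peak at 2 Ts and DC 90%, and a weak peak at 2 Ts and DC 25%.
#' Amplitudes 1.0 / 0.9 / 0.4 with sds of 1.5 ms in period and 0.12 in DC
#' are fixture constants emulating the relative peak strengths of the
#' behavioural field. An optional fourth, weak harmonic peak at Ts/2 and
#' DC 33% can be enabled.
#'
#' @param ts_ms fundamental song period, default 8.6
#' @param include_harmonic include the weak Ts/2 peak (default FALSE, as
#'   the behavioural response there is weak and non-significant)
#' @export
anurogryllus_field_spec <- function(ts_ms = 8.6, include_harmonic = FALSE) {
  peaks <- data.frame(
    period_ms = c(ts_ms, 2 * ts_ms, 2 * ts_ms),
    dc = c(0.56, 0.90, 0.25),
    amplitude = c(1.0, 0.9, 0.4),
    period_sd_ms = 1.5,
    dc_sd = 0.12)
  if (include_harmonic)
    peaks <- rbind(peaks, data.frame(period_ms = ts_ms / 2, dc = 0.33,
                                     amplitude = 0.2, period_sd_ms = 1.5,
                                     dc_sd = 0.12))
  synth_ppf_spec(peaks)
}

#' Generate a synthetic preference field
#'
#' @param spec a [synth_ppf_spec()]
#' @return a [preference_field()]
#' @export
synth_preference_field <- function(spec = anurogryllus_field_spec()) {
  stopifnot(inherits(spec, "synth_ppf_spec"))
  ax <- seq(0, spec$extent, by = spec$resolution)
  D <- matrix(ax, length(ax), length(ax))
  P <- matrix(ax, length(ax), length(ax), byrow = TRUE)
  Tm <- D + P
  dc <- ifelse(Tm > 0, D / Tm, 0)
  v <- matrix(0, length(ax), length(ax))
  for (i in seq_len(nrow(spec$peaks))) {
    pk <- spec$peaks[i, ]
    cdc <- min(max(pk$dc, 1e-6), 1)  # DC-space centres truncated to (0, 1]
    v <- v + pk$amplitude *
      exp(-(Tm - pk$period_ms)^2 / (2 * pk$period_sd_ms^2) -
            (dc - cdc)^2 / (2 * pk$dc_sd^2))
  }
  v[Tm == 0] <- 0
  preference_field(ax, ax, pmax(v, 0), spec$resolution)
}

#' Generate a noisy phonotaxis table from a field
#'
#' Emulates the behavioural protocol: each stimulus is tested in a random
#' number of females; each female's score is the field value plus Gaussian
#' noise, deliberately not clipped (real scores can fall below 0, when the
#' female orients away, or above 1, when she outruns the attractive
#' control); the recorded score is the per-stimulus mean.
#'
#' @param field a [preference_field()]
#' @param stimuli data frame with `pulse_ms`, `pause_ms`
#' @param n_females_range inclusive integer range, default c(3, 8)
#' @param noise_sd per-female score noise sd, default 0.1
#' @param seed integer seed (regeneration is bit-identical)
#' @return phonotaxis record data frame (`pulse_ms`, `pause_ms`, `score`,
#'   `n_females`, `female_1` ... NA-padded)
#' @export
synth_phonotaxis_table <- function(field, stimuli,
                                   n_females_range = c(3, 8),
                                   noise_sd = 0.1, seed = 1) {
  stopifnot(inherits(field, "preference_field"))
  set.seed(seed)
  m <- nrow(stimuli)
  nf <- sample(seq(n_females_range[1], n_females_range[2]), m,
               replace = TRUE)
  kmax <- max(nf)
  fem <- matrix(NA_real_, m, kmax)
  truth <- field_value(field, stimuli$pulse_ms, stimuli$pause_ms)
  for (i in seq_len(m))
    fem[i, seq_len(nf[i])] <- truth[i] + stats::rnorm(nf[i], 0, noise_sd)
  colnames(fem) <- paste0("female_", seq_len(kmax))
  out <- data.frame(pulse_ms = stimuli$pulse_ms,
                    pause_ms = stimuli$pause_ms,
                    score = rowMeans(fem, na.rm = TRUE),
                    n_females = nf)
  cbind(out, as.data.frame(fem))
}

#' Synthesize a pulsed song waveform
#'
#' A sinusoidal carrier gated by the rectangular pulse envelope — a
#' synthetic stand-in for a recorded calling song, used to exercise the
#' segmentation and carrier-estimation routines.
#'
#' @param pulse_ms,pause_ms pulse geometry (ms)
#' @param carrier_hz carrier frequency, default 7000
#' @param duration_ms total duration, default 1000
#' @param sample_rate Hz; must exceed twice the carrier
#' @param amplitude peak amplitude
#' @return a `waveform`: list with `samples`, `sample_rate`
#' @export
synth_song_waveform <- function(pulse_ms = 5.1, pause_ms = 3.4,
                                carrier_hz = 7000, duration_ms = 1000,
                                sample_rate = 40000, amplitude = 1) {
  if (sample_rate <= 2 * carrier_hz)
    stop("sample_rate must exceed twice the carrier frequency (Nyquist)")
  env <- render_pulse_train(pulse_train_spec(pulse_ms, pause_ms,
                                             duration_ms, amplitude,
                                             sample_rate))
  t <- (seq_along(env$samples) - 1) / sample_rate
  structure(list(samples = env$samples * sin(2 * pi * carrier_hz * t),
                 sample_rate = sample_rate),
            class = "waveform")
}

#' Write or read a waveform as delimited text
#'
#' One sample per line after a `# sample_rate:` header; a plain-text mono
#' serialization used for fixtures and inspection.
#'
#' @param wave a `waveform`
#' @param path file path
#' @export
write_waveform <- function(wave, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# sample_rate: %g", wave$sample_rate), con)
  writeLines(format(wave$samples, digits = 8, trim = TRUE, scientific = FALSE),
             con)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  lines <- readLines(path)
  sr <- as.numeric(sub(".*: *", "", lines[1]))
  structure(list(samples = as.numeric(lines[-1]), sample_rate = sr),
            class = "waveform")
}
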