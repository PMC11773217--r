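#' Calling-song parameters of Anurogryllus muticus males
#'
#' Summary of the male trill: carrier frequency, pulse duration, pause,
#' period, pulse rate and duty cycle (mean, sd, range), from eight males.
#'
#' @return data frame with columns `parameter`, `mean`, `sd`, `lo`, `hi`,
#'   `unit`
#' @export
anurogryllus_song_params <- function() {
  data.frame(
    parameter = c("carrier_khz", "pulse_ms", "pause_ms", "period_ms",
                  "rate_pps", "duty_cycle_pct"),
    mean = c(7.0, 5.1, 3.4, 8.5, 117, 60),
    sd = c(0.3, 1.0, 0.8, 0.3, 4, 10),
    lo = c(6.5, 3.7, 2.1, 8.1, 111, 50),
    hi = c(7.5, 6.6, 4.4, 9.0, 124, 80),
    unit = c("kHz", "ms", "ms", "ms", "pulses/s", "%"),
    stringsAsFactors = FALSE)
}

#' Serialize minimal-model parameters to JSON and back
#'
#' Field names mirror the parameter constructors
#' ([autocorr_params()], [rebound_params()], [ffi_params()], [rf_params()],
#' [lifac_params()]); the model class is recorded so files round-trip.
#'
#' @param params a `model_params` object
#' @param path file path
#' @export
write_model_params <- function(params, path) {
  cls <- class(params)[1]
  flat <- unclass(params)
  if (!is.null(flat$base)) flat$base <- unclass(flat$base)
  jsonlite::write_json(c(list(model = cls), flat), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- raw$model
  raw$model <- NULL
  ctor <- switch(cls,
                 autocorr_params = autocorr_params,
                 rebound_params = rebound_params,
                 ffi_params = ffi_params,
                 rf_params = rf_params,
                 lifac_params = lifac_params,
                 stop("unknown model class: ", cls))
  if (cls == "ffi_params" && !is.null(raw$base))
    raw$base <- do.call(rebound_params, raw$base)
  do.call(ctor, raw)
}
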