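# Model fitting: multi-start Nelder-Mead minimisation of the mean-squared
# error between a model's predicted phonotaxis scores and a target
# preference field, evaluated on the 0.5 ms pulse/pause lattice.
# Positive-constrained parameters (delays, durations, gains, frequencies)
# are optimised in log-space so the simplex search stays unconstrained.

# free (fitted) parameter names per minimal model; all are positive, and
# for the resonate-and-fire model the damping magnitude is optimised
.fit_param_names <- function(params) {
  if (inherits(params, "autocorr_params")) c("delay_ms", "gain")
  else if (inherits(params, "ffi_params"))
    c("delay_ms", "inh_gain", "inh_dur_ms", "exc_gain", "exc_dur_ms")
  else if (inherits(params, "rebound_params"))
    c("delay_ms", "inh_gain", "inh_dur_ms", "exc_gain", "exc_dur_ms")
  else if (inherits(params, "rf_params"))
    c("freq_hz", "damping", "input_gain", "spike_amp")
  else stop("model not supported by the fitting interface")
}

.params_to_vec <- function(params) {
  nm <- .fit_param_names(params)
  v <- unlist(params[nm])
  # log transform; damping is negative, optimise log of its magnitude
  if ("damping" %in% nm) v["damping"] <- -v["damping"]
  log(pmax(v, 1e-12))
}

.vec_to_params <- function(vec, template) {
  nm <- .fit_param_names(template)
  v <- exp(vec)
  names(v) <- nm
  if ("damping" %in% nm) v["damping"] <- -v["damping"]
  out <- template
  out[nm] <- as.list(v)
  out
}

#' Fit configuration
#'
#' Fits are run several times from slightly perturbed initial conditions to
#' avoid local minima; restart 0 starts exactly at the initial vector and
#' the remaining restarts jitter it multiplicatively with seeded log-normal
#' noise of relative scale `jitter_scale`.
#'
#' @param initial model parameter object giving the initial values (chosen
#'   by hand, as is usual for these models)
#' @param n_restarts number of Nelder-Mead restarts, default 8
#' @param jitter_scale relative sd of the initial perturbation, default 0.1
#' @param seed integer seed making the restart sequence reproducible
#' @param max_iterations Nelder-Mead iteration cap per restart
#' @param tolerance relative convergence tolerance on the loss
#' @param n_rounds staged optimization rounds: each round warm-starts its
#'   restarts from the best parameters of the previous round (restarting
#'   the simplex escapes the shallow trade-off valleys between filter-lobe
#'   gains and durations); default 1
#' @export
fit_config <- function(initial, n_restarts = 8, jitter_scale = 0.1,
                       seed = 1, max_iterations = 500, tolerance = 1e-8,
                       n_rounds = 1) {
  stopifnot(n_restarts >= 1, jitter_scale >= 0, n_rounds >= 1)
  structure(list(initial = initial, n_restarts = n_restarts,
                 jitter_scale = jitter_scale, seed = seed,
                 max_iterations = max_iterations, tolerance = tolerance,
                 n_rounds = n_rounds),
            class = "fit_config")
}

# target values aligned with the grid rows
.target_on_grid <- function(target, grid) {
  if (inherits(target, "preference_field"))
    field_value(target, grid$pulse_ms, grid$pause_ms)
  else if (is.numeric(target) && length(target) == nrow(grid))
    target
  else stop("target must be a preference_field or a score per grid row")
}

#' Mean-squared-error objective of a model on a target field
#'
#' Non-finite predictions are replaced by a large penalty so the simplex
#' search can recover.
#'
#' @param params model parameter object
#' @param target a [preference_field()] or a numeric vector of target
#'   scores aligned with `grid`
#' @param grid stimulus grid (used when `ctx` is missing)
#' @param ctx optional precomputed [grid_context()]
#' @export
mse_objective <- function(params, target, grid = make_fit_grid(),
                          ctx = NULL) {
  if (is.null(ctx)) ctx <- grid_context(grid, 4000)
  y <- .target_on_grid(target, ctx$grid)
  p <- tryCatch(predict_grid(params, ctx), error = function(e) NULL)
  if (is.null(p) || any(!is.finite(p))) return(1e6)
  mean((p - y)^2)
}

#' Fit a model to a preference field by multi-start Nelder-Mead
#'
#' Minimises the mean-squared error between predicted and target phonotaxis
#' scores over the stimulus grid. Each restart perturbs the manually chosen
#' initial parameter vector (restart 0 is unjittered) and runs Nelder-Mead
#' to convergence in log-parameter space; the best restart is returned.
#'
#' @param target a [preference_field()] (or aligned numeric vector)
#' @param config a [fit_config()]; its `initial` element fixes the model
#'   class being fitted
#' @param grid stimulus lattice, default the 0.5 ms grid to 20 ms
#' @param sample_rate simulation rate for the fit, default 4000 Hz (10000
#'   for the resonate-and-fire model, whose 0.1 ms Euler step demands it)
#' @param total_ms stimulus duration
#' @return a `fit_result`: `best_params`, `best_loss`, `restarts` (data
#'   frame of per-restart loss/convergence), `seed`
#' @export
fit_model <- function(target, config, grid = make_fit_grid(),
                      sample_rate = NULL, total_ms = 400) {
  stopifnot(inherits(config, "fit_config"))
  template <- config$initial
  if (is.null(sample_rate))
    sample_rate <- if (inherits(template, "rf_params"))
      1000 / template$dt_ms else 4000
  ctx <- grid_context(grid, sample_rate, total_ms)
  y <- .target_on_grid(target, ctx$grid)
  obj <- function(v) {
    p <- tryCatch(predict_grid(.vec_to_params(v, template), ctx),
                  error = function(e) NULL)
    if (is.null(p) || any(!is.finite(p))) return(1e6)
    mean((p - y)^2)
  }
  v0 <- .params_to_vec(template)
  set.seed(config$seed)
  rows <- list()
  best <- NULL
  vstart <- v0
  for (round in seq_len(config$n_rounds)) {
    for (r in seq_len(config$n_restarts)) {
      vr <- if (r == 1) vstart else
        vstart + stats::rnorm(length(vstart), 0, config$jitter_scale)
      opt <- stats::optim(vr, obj, method = "Nelder-Mead",
                          control = list(maxit = config$max_iterations,
                                         reltol = config$tolerance))
      rows[[length(rows) + 1]] <-
        data.frame(round = round, restart = r - 1, loss = opt$value,
                   iterations = opt$counts[["function"]],
                   converged = opt$convergence == 0)
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    vstart <- best$par
  }
  if (!is.finite(best$value) || best$value >= 1e6)
    stop("fit failed: no restart produced a finite loss")
  structure(list(best_params = .vec_to_params(best$par, template),
                 best_loss = best$value,
                 restarts = do.call(rbind, rows),
                 seed = config$seed,
                 initial_loss = obj(v0),
                 sample_rate = sample_rate),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  nm <- .fit_param_names(x$best_params)
  cat("model fit (", class(x$best_params)[1], "), best MSE = ",
      format(x$best_loss, digits = 5), " over ",
      nrow(x$restarts), " restart(s), seed ", x$seed, "\n", sep = "")
  for (p in nm)
    cat(sprintf("  %-12s %.5g\n", p, x$best_params[[p]]))
  invisible(x)
}

#' Write a fit result as a structured text report plus parameter file
#'
#' @param fit a `fit_result`
#' @param path base path; `<path>.txt` gets the report and `<path>.json`
#'   the fitted parameters
#' @export
write_fit_result <- function(fit, path) {
  txt <- paste0(path, ".txt")
  con <- file(txt, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("model: %s", class(fit$best_params)[1]),
    sprintf("best_loss: %.8g", fit$best_loss),
    sprintf("initial_loss: %.8g", fit$initial_loss),
    sprintf("seed: %d", fit$seed),
    "restarts:"), con)
  utils::write.table(fit$restarts, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  pars <- fit$best_params
  pars$base <- NULL  # nested objects go in their own file if needed
  jsonlite::write_json(c(list(model = class(fit$best_params)[1]),
                         pars[.fit_param_names(fit$best_params)]),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
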