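#' Construct a preference field object
#'
#' A preference field (pulse-pause field, PPF) is a two-dimensional grid of
#' phonotaxis scores over pulse duration (rows) and pause duration
#' (columns), both in ms, with uniform axes.
#'
#' @param pulse_axis pulse-duration lattice (ms), uniformly spaced
#' @param pause_axis pause lattice (ms), uniformly spaced
#' @param values matrix of scores, dim `c(length(pulse_axis),
#'   length(pause_axis))`, non-negative
#' @param resolution lattice step in ms
#' @export
preference_field <- function(pulse_axis, pause_axis, values,
                             resolution = NULL) {
  stopifnot(is.matrix(values),
            nrow(values) == length(pulse_axis),
            ncol(values) == length(pause_axis))
  if (any(values < 0, na.rm = TRUE))
    stop("preference field values must be non-negative")
  if (is.null(resolution)) resolution <- diff(pulse_axis[1:2])
  chk <- function(ax) max(abs(diff(ax) - resolution)) < 1e-6
  if (length(pulse_axis) > 1 && !chk(pulse_axis))
    stop("pulse_axis not uniform at the stated resolution")
  if (length(pause_axis) > 1 && !chk(pause_axis))
    stop("pause_axis not uniform at the stated resolution")
  structure(list(pulse_axis = pulse_axis, pause_axis = pause_axis,
                 values = values, resolution = resolution),
            class = "preference_field")
}

#' @export
print.preference_field <- function(x, ...) {
  cat(sprintf(
    "preference field: %d x %d grid, pulse %.3g-%.3g ms, pause %.3g-%.3g ms, step %.3g ms\n",
    length(x$pulse_axis), length(x$pause_axis),
    min(x$pulse_axis), max(x$pulse_axis),
    min(x$pause_axis), max(x$pause_axis), x$resolution))
  cat(sprintf("  values in [%.3g, %.3g]\n", min(x$values), max(x$values)))
  invisible(x)
}

# bilinear lookup on the field lattice; points outside the lattice are
# clamped to the nearest edge
.bilinear <- function(field, pulse, pause) {
  px <- field$pulse_axis; py <- field$pause_axis
  x <- pmin(pmax(pulse, px[1]), px[length(px)])
  y <- pmin(pmax(pause, py[1]), py[length(py)])
  i <- pmin(pmax(findInterval(x, px), 1), length(px) - 1)
  j <- pmin(pmax(findInterval(y, py), 1), length(py) - 1)
  if (length(px) == 1) i <- rep(1L, length(x))
  if (length(py) == 1) j <- rep(1L, length(y))
  fx <- (x - px[i]) / (px[pmin(i + 1, length(px))] - px[i])
  fy <- (y - py[j]) / (py[pmin(j + 1, length(py))] - py[j])
  fx[!is.finite(fx)] <- 0; fy[!is.finite(fy)] <- 0
  i2 <- pmin(i + 1, length(px)); j2 <- pmin(j + 1, length(py))
  v <- field$values
  v[cbind(i, j)] * (1 - fx) * (1 - fy) +
    v[cbind(i2, j)] * fx * (1 - fy) +
    v[cbind(i, j2)] * (1 - fx) * fy +
    v[cbind(i2, j2)] * fx * fy
}

#' Look up field values at pulse/pause coordinates (bilinear)
#'
#' @param field a [preference_field()]
#' @param pulse_ms,pause_ms coordinate vectors (ms)
#' @export
field_value <- function(field, pulse_ms, pause_ms) {
  stopifnot(inherits(field, "preference_field"))
  .bilinear(field, pulse_ms, pause_ms)
}

#' Interpolate scattered phonotaxis records into a preference field
#'
#' Builds the two-dimensional preference function from a table of phonotaxis
#' measurements at scattered (pulse, pause) coordinates, via Delaunay-based
#' piecewise-linear interpolation (exact at the data points, continuous,
#' local). Grid nodes outside the convex hull of the records are filled with
#' the score of the nearest record; negative interpolated values are clipped
#' to zero, mirroring how behavioural scores (which can be negative when a
#' female orients away from the speaker) are treated when building the field.
#'
#' @param records data frame with columns `pulse_ms`, `pause_ms`, `score`
#'   (see [read_phonotaxis_table()])
#' @param resolution grid step in ms, default 0.1
#' @param extent grid covers `[0, extent]` on both axes, default 20
#' @param clip_negative clip negative values to 0 (default TRUE)
#' @return a [preference_field()]
#' @export
interpolate_field <- function(records, resolution = 0.1, extent = 20,
                              clip_negative = TRUE) {
  stopifnot(all(c("pulse_ms", "pause_ms", "score") %in% names(records)))
  pts <- as.matrix(records[, c("pulse_ms", "pause_ms")])
  if (anyDuplicated(pts)) {
    # average duplicate coordinates
    key <- paste(pts[, 1], pts[, 2])
    agg <- tapply(records$score, key, mean)
    first <- !duplicated(key)
    pts <- pts[first, , drop = FALSE]
    vals <- as.numeric(agg[paste(pts[, 1], pts[, 2])])
  } else {
    vals <- records$score
  }
  if (nrow(pts) < 3) stop("interpolation impossible: need at least 3 records")
  ax <- seq(0, extent, by = resolution)
  q <- as.matrix(expand.grid(pulse_ms = ax, pause_ms = ax,
                             KEEP.OUT.ATTRS = FALSE))
  z <- .delaunay_interp(pts, vals, q)
  outside <- is.na(z)
  if (any(outside)) {
    # nearest-record extension beyond the hull
    qo <- q[outside, , drop = FALSE]
    d2 <- outer(qo[, 1], pts[, 1], "-")^2 + outer(qo[, 2], pts[, 2], "-")^2
    z[outside] <- vals[max.col(-d2)]
  }
  if (clip_negative) z <- pmax(z, 0)
  preference_field(ax, ax, matrix(z, nrow = length(ax)), resolution)
}

#' Period tuning: transect of a preference field at constant duty cycle
#'
#' Samples the field along the diagonal (DC * T, (1 - DC) * T) for all
#' periods representable on the grid, by bilinear lookup.
#'
#' @param field a [preference_field()]
#' @param dc duty cycle in (0, 1)
#' @return data frame with columns `period_ms`, `pulse_ms`, `pause_ms`,
#'   `value`
#' @export
period_transect <- function(field, dc) {
  stopifnot(inherits(field, "preference_field"))
  if (dc <= 0 || dc >= 1) stop("duty cycle must be in (0, 1)")
  pmax_ax <- max(field$pulse_axis); qmax_ax <- max(field$pause_axis)
  tmax <- min(pmax_ax / dc, qmax_ax / (1 - dc))
  Tv <- seq(field$resolution, tmax, by = field$resolution)
  D <- dc * Tv; P <- (1 - dc) * Tv
  data.frame(period_ms = Tv, pulse_ms = D, pause_ms = P,
             value = .bilinear(field, D, P))
}

#' DC tuning: transect of a preference field at constant period
#'
#' Samples the field along the anti-diagonal (D, T - D) for pulse durations
#' D strictly inside (0, T).
#'
#' @param field a [preference_field()]
#' @param period_ms period of the transect (ms)
#' @return data frame with columns `duty_cycle`, `pulse_ms`, `pause_ms`,
#'   `value`
#' @export
dc_transect <- function(field, period_ms) {
  stopifnot(inherits(field, "preference_field"))
  ext <- max(field$pulse_axis) + max(field$pause_axis)
  if (period_ms <= 0 || period_ms > ext)
    stop("period beyond the reach of the grid")
  D <- seq(field$resolution, period_ms - field$resolution,
           by = field$resolution)
  D <- D[D <= max(field$pulse_axis) &
           (period_ms - D) <= max(field$pause_axis)]
  if (length(D) == 0) stop("period beyond the reach of the grid")
  data.frame(duty_cycle = D / period_ms, pulse_ms = D,
             pause_ms = period_ms - D,
             value = .bilinear(field, D, period_ms - D))
}

#' One-sided paired test for a preference peak
#'
#' Tests whether per-female phonotaxis scores at a candidate peak exceed
#' those at a reference stimulus, using a paired one-sided t-test
#' (alternative: peak > reference). If the paired differences have zero
#' variance the t statistic is degenerate; the function then returns p = 0
#' (all differences positive), p = 1 (all negative) or p = 0.5 (all zero),
#' with a warning.
#'
#' @param peak_scores,reference_scores numeric vectors of equal length >= 2,
#'   paired by female
#' @return the one-sided p-value, with attribute `"degenerate"` set when the
#'   zero-variance branch was taken
#' @export
peak_significance <- function(peak_scores, reference_scores) {
  if (length(peak_scores) != length(reference_scores))
    stop("peak and reference score vectors must have equal length")
  if (length(peak_scores) < 2)
    stop("need at least 2 paired scores")
  d <- peak_scores - reference_scores
  if (stats::sd(d) < .Machine$double.eps^0.5 * max(1, abs(mean(d)))) {
    warning("zero variance of paired differences; degenerate t-test")
    p <- if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5
    return(structure(p, degenerate = TRUE))
  }
  stats::t.test(peak_scores, reference_scores, paired = TRUE,
                alternative = "greater")$p.value
}

#' Read and write phonotaxis tables
#'
#' Tab- or comma-delimited text with header columns `pulse_ms`, `pause_ms`,
#' `score`, `n_females` and optional per-female columns `female_1` ...
#' `female_k` (NA-padded when playlists had different numbers of females).
#'
#' @param path file path
#' @export
read_phonotaxis_table <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("pulse_ms", "pause_ms", "score")
  if (!all(need %in% names(tab)))
    stop("malformed phonotaxis table: need columns ",
         paste(need, collapse = ", "))
  fem <- grep("^female_", names(tab), value = TRUE)
  if (length(fem) > 0 && "n_females" %in% names(tab)) {
    m <- as.matrix(tab[, fem, drop = FALSE])
    mu <- rowMeans(m, na.rm = TRUE)
    bad <- abs(mu - tab$score) > 1e-6 & rowSums(!is.na(m)) > 0
    if (any(bad))
      warning("per-female scores inconsistent with recorded mean in ",
              sum(bad), " record(s)")
  }
  tab
}

#' @rdname read_phonotaxis_table
#' @param records a phonotaxis record data frame
#' @export
write_phonotaxis_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read and write gridded preference fields
#'
#' Long-format delimited text (`pulse_ms`, `pause_ms`, `value`) preceded by
#' `#`-prefixed metadata lines recording the resolution and whether negative
#' values were clipped.
#'
#' @param field a [preference_field()]
#' @param path file path
#' @param clip_applied recorded in the metadata header
#' @export
write_preference_field <- function(field, path, clip_applied = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# resolution_ms: %g", field$resolution),
               sprintf("# extent_ms: %g", max(field$pulse_axis)),
               sprintf("# clip_negative: %s", clip_applied)), con)
  df <- expand.grid(pulse_ms = field$pulse_axis,
                    pause_ms = field$pause_axis, KEEP.OUT.ATTRS = FALSE)
  df$value <- as.vector(field$values)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_preference_field
#' @export
read_preference_field <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  df <- utils::read.delim(text = lines[!grepl("^#", lines)])
  pulse_axis <- sort(unique(df$pulse_ms))
  pause_axis <- sort(unique(df$pause_ms))
  v <- matrix(NA_real_, length(pulse_axis), length(pause_axis))
  v[cbind(match(df$pulse_ms, pulse_axis), match(df$pause_ms, pause_axis))] <-
    df$value
  res <- as.numeric(sub(".*: *", "", grep("resolution_ms", meta, value = TRUE)))
  preference_field(pulse_axis, pause_axis, v,
                   if (length(res)) res else NULL)
}
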