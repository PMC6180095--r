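#' Uniformly sampled scalar time series
#'
#' The basic container for an impact time history: a scalar quantity sampled
#' on a uniform time grid `t0, t0 + dt, ...`, with a unit tag so that
#' downstream metrics (notably the HIC, which requires acceleration in g)
#' can check they are fed the right quantity.
#'
#' @param samples Numeric vector of at least two finite values.
#' @param dt Sampling interval in seconds (> 0).
#' @param t0 Time of the first sample in seconds.
#' @param unit Unit tag, one of `"g"`, `"m_s2"`, `"rad_s"`, `"rad_s2"`,
#'   `"dimensionless"`.
#' @return An object of class `uniform_signal` with fields `t0`, `dt`,
#'   `samples` and `unit`.
#' @examples
#' s <- uniform_signal(sin(seq(0, 1, by = 0.001)), dt = 0.001, unit = "g")
#' signal_times(s)[1:3]
#' @export
uniform_signal <- function(samples, dt, t0 = 0, unit = "dimensionless") {
  unit <- match.arg(unit, c("g", "m_s2", "rad_s", "rad_s2", "dimensionless"))
  samples <- as.numeric(samples)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number (seconds)", call. = FALSE)
  if (length(samples) < 2L)
    stop("a uniform_signal needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("all samples must be finite", call. = FALSE)
  structure(
    list(t0 = as.numeric(t0), dt = dt, samples = samples, unit = unit),
    class = "uniform_signal"
  )
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf(
    "<uniform_signal> %d samples @ %.6g s (%.4g kHz), unit '%s', t0 = %g s\n",
    length(x$samples), x$dt, 1e-3 / x$dt, x$unit, x$t0
  ))
  cat(sprintf("  range [%.6g, %.6g]\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Sample times of a uniform signal
#'
#' @param s A `uniform_signal`.
#' @return Numeric vector of sample times in seconds.
#' @export
signal_times <- function(s) {
  stopifnot(inherits(s, "uniform_signal"))
  s$t0 + s$dt * (seq_along(s$samples) - 1L)
}

#' Triaxial kinematic signal
#'
#' Three channel-aligned [uniform_signal()] objects forming one vector
#' quantity (e.g. the x/y/z output of an accelerometer at the head's
#' centre of gravity). The channels must share `t0`, `dt`, length and unit.
#'
#' @param x,y,z `uniform_signal` channels.
#' @return An object of class `triax_signal`.
#' @export
triax_signal <- function(x, y, z) {
  for (ch in list(x, y, z))
    if (!inherits(ch, "uniform_signal"))
      stop("channels must be uniform_signal objects", call. = FALSE)
  aligned <- isTRUE(all.equal(x$t0, y$t0)) && isTRUE(all.equal(x$t0, z$t0)) &&
    isTRUE(all.equal(x$dt, y$dt)) && isTRUE(all.equal(x$dt, z$dt)) &&
    length(x$samples) == length(y$samples) &&
    length(x$samples) == length(z$samples) &&
    x$unit == y$unit && x$unit == z$unit
  if (!aligned)
    stop("triax channels are misaligned: t0, dt, length and unit must match",
         call. = FALSE)
  structure(list(x = x, y = y, z = z), class = "triax_signal")
}

#' @export
print.triax_signal <- function(x, ...) {
  cat(sprintf("<triax_signal> 3 x %d samples @ %.6g s, unit '%s'\n",
              length(x$x$samples), x$x$dt, x$x$unit))
  invisible(x)
}

#' Build a triax signal from three numeric vectors
#'
#' Convenience wrapper around [triax_signal()] for channels sharing one grid.
#'
#' @param cx,cy,cz Numeric vectors of equal length.
#' @inheritParams uniform_signal
#' @return A `triax_signal`.
#' @export
triax_from_vectors <- function(cx, cy, cz, dt, t0 = 0, unit = "dimensionless") {
  triax_signal(
    uniform_signal(cx, dt, t0, unit),
    uniform_signal(cy, dt, t0, unit),
    uniform_signal(cz, dt, t0, unit)
  )
}

#' Resultant (Euclidean norm) of a triaxial signal
#'
#' Per-sample Euclidean norm of the three channels, the "res.lin.accel.",
#' "res.ang.accel." and "res.ang.vel." quantities of drop-test reporting.
#' The unit tag is preserved.
#'
#' @param v A `triax_signal`.
#' @return A `uniform_signal` on the same grid.
#' @examples
#' tr <- triax_from_vectors(c(3, 3), c(4, 4), c(0, 0), dt = 1e-3, unit = "g")
#' resultant(tr)$samples  # 5 5
#' @export
resultant <- function(v) {
  if (!inherits(v, "triax_signal"))
    stop("`v` must be a triax_signal", call. = FALSE)
  uniform_signal(
    sqrt(v$x$samples^2 + v$y$samples^2 + v$z$samples^2),
    dt = v$x$dt, t0 = v$x$t0, unit = v$x$unit
  )
}
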