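#' Free-fall height to impact velocity
#'
#' `v = sqrt(2 * 9.81 * h)`; a critical height of 1.59 m corresponds to an
#' impact velocity of 5.59 m/s.
#'
#' @param h Drop height in m, >= 0.
#' @return Impact velocity in m/s.
#' @export
height_to_velocity <- function(h) {
  if (!is.numeric(h) || any(h < 0))
    stop("height must be >= 0", call. = FALSE)
  sqrt(2 * GRAVITY * h)
}

#' Impact velocity to free-fall height
#'
#' Inverse of [height_to_velocity()]: `h = v^2 / (2 * 9.81)`.
#'
#' @param v Impact velocity in m/s, >= 0.
#' @return Equivalent free-fall height in m.
#' @export
velocity_to_height <- function(v) {
  if (!is.numeric(v) || any(v < 0))
    stop("velocity must be >= 0", call. = FALSE)
  v^2 / (2 * GRAVITY)
}

#' Critical fall height of a surfacing material
#'
#' The critical height is the highest drop height from which the surfacing
#' still meets the impact-attenuation performance criterion (headform HIC
#' at most `hic_target`, 1000 by the current standard). It is found by
#' bisection on the monotone height-to-HIC response: the upper bracket is
#' expanded geometrically from 0.5 m until its HIC exceeds the target (and
#' the lower contracted until its HIC falls below it), then bisected to a
#' height tolerance `tol_m`. Each evaluation is a full
#' [simulate_drop()] + 2077.5 Hz zero-phase filter + unlimited [hic()].
#'
#' Softer surfacing has a higher critical height: scaling the stress curve
#' up (stiffer) lowers the returned height, scaling it down raises it.
#'
#' @inheritParams simulate_drop
#' @param hic_target HIC defining the performance criterion (default 1000).
#' @param tol_m Height convergence tolerance in m (default 0.005).
#' @param hic_fn Optional response function `height -> HIC` replacing the
#'   simulation pipeline (used to verify the search on closed-form
#'   responses).
#' @param dt,output_dt Integration and output steps for the simulated
#'   evaluations.
#' @param h_init Initial upper-bracket guess in m.
#' @return An object of class `critical_height_result`: `height` (m),
#'   `hic_at_height`, `iterations`, `bracket` (m, length 2) and `probes`
#'   (data.frame of all height/HIC pairs evaluated).
#' @export
find_critical_height <- function(mat = NULL, head = headform(),
                                 layer = surface_layer(),
                                 hic_target = 1000, tol_m = 0.005,
                                 hic_fn = NULL, dt = 1e-6, output_dt = 5e-5,
                                 h_init = 0.5) {
  if (is.null(hic_fn)) {
    if (!inherits(mat, "hysteretic_material"))
      stop("give `mat` (a hysteretic_material) or `hic_fn`", call. = FALSE)
    hic_fn <- function(h)
      drop_hic(mat, head, layer, h, dt = dt, output_dt = output_dt)
  }
  probes_h <- numeric(0)
  probes_hic <- numeric(0)
  eval_h <- function(h) {
    v <- hic_fn(h)
    probes_h <<- c(probes_h, h)
    probes_hic <<- c(probes_hic, v)
    v
  }
  diag_stop <- function(msg) {
    pairs <- paste(sprintf("(%.3g m, HIC %.4g)", probes_h, probes_hic),
                   collapse = ", ")
    stop(paste0(msg, "; probed: ", pairs), call. = FALSE)
  }

  hi <- h_init
  f_hi <- eval_h(hi)
  it <- 1L
  while (f_hi < hic_target) {
    if (hi > 50) diag_stop("HIC stays below target up to 50 m")
    hi <- hi * 1.6
    f_hi <- eval_h(hi)
    it <- it + 1L
  }
  lo <- hi / 1.6
  f_lo <- if (lo %in% probes_h) probes_hic[match(lo, probes_h)] else {
    it <- it + 1L
    eval_h(lo)
  }
  while (f_lo >= hic_target) {
    if (lo < 1e-3) diag_stop("HIC exceeds target even at millimetre heights")
    lo <- lo / 1.6
    f_lo <- eval_h(lo)
    it <- it + 1L
  }
  if (f_lo >= f_hi)
    diag_stop("height-to-HIC response is not increasing over the bracket")

  while (hi - lo > tol_m) {
    mid <- (lo + hi) / 2
    f_mid <- eval_h(mid)
    it <- it + 1L
    if (f_mid < hic_target) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid; f_hi <- f_mid
    }
  }
  height <- (lo + hi) / 2
  hic_at <- eval_h(height)
  it <- it + 1L

  structure(list(
    height = height, hic_at_height = hic_at, iterations = it,
    bracket = c(lo, hi),
    probes = data.frame(height_m = probes_h, hic = probes_hic)),
    class = "critical_height_result")
}

#' @export
print.critical_height_result <- function(x, ...) {
  cat(sprintf(
    "<critical_height_result> %.3f m (HIC %.1f there; %d evaluations; bracket [%.3f, %.3f] m)\n",
    x$height, x$hic_at_height, x$iterations, x$bracket[1L], x$bracket[2L]))
  invisible(x)
}
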