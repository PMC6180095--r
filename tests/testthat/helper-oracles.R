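# Independent brute-force oracles, deliberately written as plain double
# loops / closed forms so they share no code path with the implementation.

# Exhaustive HIC: trapezoid integral recomputed per pair with sum().
brute_force_hic <- function(samples, dt, window_limit = Inf) {
  n <- length(samples)
  best <- 0
  best_pair <- c(1L, 2L)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      w <- (j - i) * dt
      if (w > window_limit) next
      seg <- samples[i:j]
      integ <- sum((seg[-1] + seg[-length(seg)]) / 2) * dt
      val <- if (integ > 0) w * (integ / w)^2.5 else 0
      if (val > best) {
        best <- val
        best_pair <- c(i, j)
      }
    }
  }
  list(value = best, i = best_pair[1], j = best_pair[2])
}

# Haversine test pulse in g on a 20 kHz grid.
haversine_signal <- function(peak = 150, duration = 0.010, rate = 20000) {
  dt <- 1 / rate
  tt <- seq(0, duration, by = dt)
  uniform_signal(peak * sin(pi * tt / duration)^2, dt, unit = "g")
}

# Small drop-test fixtures shared across the surface-model tests; a coarse
# integration step keeps the unit suite quick (the acceptance suite runs
# the default step).
test_headform <- headform()
test_layer <- surface_layer()
test_material <- baseline_material()
DT_COARSE <- 5e-6
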