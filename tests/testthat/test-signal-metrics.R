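test_that("uniform and triax signal constructors enforce their invariants", {
  expect_error(uniform_signal(c(1, 2), dt = 0), "positive")
  expect_error(uniform_signal(1, dt = 1e-3), "at least 2")
  expect_error(uniform_signal(c(1, NA), dt = 1e-3), "finite")
  a <- uniform_signal(1:10, dt = 1e-3, unit = "g")
  b <- uniform_signal(1:10, dt = 2e-3, unit = "g")
  expect_error(triax_signal(a, a, b), "misaligned")
  c_ <- uniform_signal(1:10, dt = 1e-3, unit = "rad_s")
  expect_error(triax_signal(a, a, c_), "misaligned")
  expect_s3_class(triax_signal(a, a, a), "triax_signal")
})

test_that("resultant is the per-sample Euclidean norm, unit preserved", {
  tr <- triax_from_vectors(c(3, 3), c(4, 4), c(0, 0), dt = 1e-3, unit = "g")
  r <- resultant(tr)
  expect_equal(r$samples, c(5, 5))
  expect_identical(r$unit, "g")

  one_axis <- triax_from_vectors(c(-2, 7), c(0, 0), c(0, 0), dt = 1e-3)
  expect_equal(resultant(one_axis)$samples, c(2, 7))

  set.seed(11)
  m <- matrix(rnorm(300), ncol = 3)
  tr2 <- triax_from_vectors(m[, 1], m[, 2], m[, 3], dt = 1e-4)
  oracle <- apply(m, 1, function(row) sqrt(sum(row * row)))
  expect_equal(resultant(tr2)$samples, oracle, tolerance = 1e-12)
})

test_that("zero-phase filter has unit DC gain and half-amplitude at cutoff", {
  const <- uniform_signal(rep(42, 500), dt = 5e-5, unit = "g")
  out <- butterworth_filtfilt(const, 2077.5)
  expect_equal(out$samples, const$samples, tolerance = 1e-9)
  # repeated application of the filter leaves a constant unchanged
  out2 <- butterworth_filtfilt(butterworth_filtfilt(out, 180), 180)
  expect_equal(out2$samples, const$samples, tolerance = 1e-9)

  # two -3 dB passes: sinusoid at the cutoff emerges at half amplitude
  fs <- 20000; fc <- 500
  tt <- seq(0, 1, by = 1 / fs)
  sine <- uniform_signal(sin(2 * pi * fc * tt), 1 / fs)
  filt <- butterworth_filtfilt(sine, fc)
  steady <- filt$samples[5000:15000]
  expect_equal(max(abs(steady)), 0.5, tolerance = 0.02)
})

test_that("zero-phase filter preserves the argmax of a symmetric pulse", {
  hv <- haversine_signal(peak = 150, duration = 0.010)
  filt <- butterworth_filtfilt(hv, 2077.5)
  expect_identical(which.max(filt$samples), which.max(hv$samples))
  expect_identical(length(filt$samples), length(hv$samples))
  expect_identical(filt$dt, hv$dt)
})

test_that("filter rejects cutoffs at or above Nyquist, naming the limit", {
  s <- uniform_signal(rnorm(100), dt = 5e-5)
  expect_error(butterworth_filtfilt(s, 10000), "Nyquist")
  expect_error(butterworth_filtfilt(s, 12000), "Nyquist")
  expect_silent(butterworth_filtfilt(s, 9999))
})

test_that("HIC of constant pulses matches the closed form", {
  # 100 g for 10 ms: 0.01 * 100^2.5 = 1000, achieved on the full window
  p10 <- uniform_signal(rep(100, 201), dt = 5e-5, unit = "g")
  r <- hic(p10)
  expect_equal(r$value, 1000, tolerance = 1e-12)
  expect_equal(hic_window_duration(r), 0.010, tolerance = 1e-12)

  # 100 g for 20 ms with a 15 ms cap: 0.015 * 100^2.5 = 1500
  p20 <- uniform_signal(rep(100, 401), dt = 5e-5, unit = "g")
  r15 <- hic(p20, window_limit = 0.015)
  expect_equal(r15$value, 1500, tolerance = 1e-12)
  expect_lte(hic_window_duration(r15), 0.015 + 1e-12)

  # time-stretch of a constant pulse scales unbounded HIC by the stretch
  p30 <- uniform_signal(rep(100, 601), dt = 5e-5, unit = "g")
  expect_equal(hic(p30)$value, 3 * hic(p10)$value, tolerance = 1e-12)
})

test_that("HIC equals the exhaustive double-loop oracle on a haversine", {
  hv <- haversine_signal(peak = 150, duration = 0.010)
  oracle <- brute_force_hic(hv$samples, hv$dt)
  r <- hic(hv)
  expect_equal(r$value, oracle$value, tolerance = 1e-9)
  expect_equal(hic_window_duration(r), (oracle$j - oracle$i) * hv$dt,
               tolerance = 1e-12)
  expect_equal(r$t1, (oracle$i - 1) * hv$dt, tolerance = 1e-12)

  # windowed variant against the same oracle
  o36 <- brute_force_hic(hv$samples, hv$dt, window_limit = 0.004)
  expect_equal(hic(hv, 0.004)$value, o36$value, tolerance = 1e-9)
})

test_that("HIC is homogeneous of degree 2.5 in amplitude", {
  hv <- haversine_signal(peak = 80, duration = 0.012)
  scaled <- uniform_signal(3 * hv$samples, hv$dt, unit = "g")
  expect_equal(hic(scaled)$value, 3^2.5 * hic(hv)$value, tolerance = 1e-9)
})

test_that("HIC window ordering holds and sub-15 ms pulses collapse it", {
  set.seed(7)
  for (k in 1:5) {
    dt <- 5e-5
    n <- 1600  # 80 ms record
    base <- abs(stats::filter(rnorm(n, 50, 30), rep(1 / 9, 9),
                              circular = TRUE))
    s <- uniform_signal(as.numeric(base), dt, unit = "g")
    h15 <- hic(s, 0.015)$value
    h36 <- hic(s, 0.036)$value
    hun <- hic(s)$value
    expect_lte(h15, h36 + 1e-12)
    expect_lte(h36, hun + 1e-12)
  }

  # short pulse in a long quiet record: all three variants coincide
  hv <- haversine_signal(peak = 150, duration = 0.010)
  padded <- uniform_signal(c(hv$samples, rep(0, 1000)), hv$dt, unit = "g")
  expect_equal(hic(padded, 0.015)$value, hic(padded)$value, tolerance = 1e-12)
  expect_equal(hic(padded, 0.036)$value, hic(padded)$value, tolerance = 1e-12)
})

test_that("HIC rejects non-g units and reports zero for silent records", {
  ms2 <- uniform_signal(rep(10, 100), dt = 1e-4, unit = "m_s2")
  expect_error(hic(ms2), "unit")
  silent <- uniform_signal(rep(0, 100), dt = 1e-4, unit = "g")
  r <- hic(silent)
  expect_identical(r$value, 0)
  # tie-break: smallest admissible window, earliest start
  expect_equal(hic_window_duration(r), 1e-4, tolerance = 1e-12)
  expect_equal(r$t1, 0)
})

test_that("peak_metrics filters channel-wise then takes resultant maxima", {
  n <- 400; dt <- 5e-5
  lin <- triax_from_vectors(rep(100, n), rep(0, n), rep(0, n),
                            dt = dt, unit = "g")
  zero_ang <- triax_from_vectors(rep(0, n), rep(0, n), rep(0, n),
                                 dt = dt, unit = "rad_s2")
  pm <- peak_metrics(lin, ang_acc = zero_ang)
  expect_equal(pm$peak_lin_g, 100, tolerance = 1e-9)
  expect_equal(pm$peak_ang_acc_rad_s2, 0, tolerance = 1e-12)
  expect_true(is.na(pm$peak_ang_vel_rad_s))

  # oracle: resultant of the individually filtered channels
  set.seed(21)
  m <- matrix(abs(rnorm(3 * n, 40, 15)), ncol = 3)
  tr <- triax_from_vectors(m[, 1], m[, 2], m[, 3], dt = dt, unit = "g")
  fm <- sapply(1:3, function(i)
    butterworth_filtfilt(uniform_signal(m[, i], dt, unit = "g"), 180)$samples)
  oracle <- max(sqrt(rowSums(fm^2)))
  expect_equal(peak_metrics(tr)$peak_lin_g, oracle, tolerance = 1e-12)
})
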