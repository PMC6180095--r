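test_that("material curve and hysteretic material validate their fields", {
  expect_error(material_curve(c(0, 0.5, 0.4), c(0, 1, 2)), "increasing")
  expect_error(material_curve(c(0.1, 0.5), c(0, 1)), "start at")
  expect_error(material_curve(c(0, 0.5), c(0, -1)), "non-decreasing")
  crv <- material_curve(c(0, 0.5, 1), c(0, 1e5, 5e5))
  expect_error(hysteretic_material(crv, hu = 0), "\\(0, 1\\]")
  expect_error(hysteretic_material(crv, hu = 1.2), "\\(0, 1\\]")
  expect_error(hysteretic_material(crv, shape = -1), "> 0")
  expect_s3_class(hysteretic_material(crv), "hysteretic_material")
})

test_that("scale_material multiplies stress ordinates only", {
  mat <- baseline_material()
  expect_error(scale_material(mat, 0), "positive")
  expect_error(scale_material(mat, -2), "positive")

  x <- 0.02
  f1 <- contact_force(list(indentation = x, indentation_rate = 1,
                           peak_energy = 0, current_energy = 0),
                      mat, test_headform, test_layer)
  for (fac in c(1, 5, 0.2)) {
    m2 <- scale_material(mat, fac)
    expect_identical(m2$curve$strain, mat$curve$strain)
    f2 <- contact_force(list(indentation = x, indentation_rate = 1,
                             peak_energy = 0, current_energy = 0),
                        m2, test_headform, test_layer)
    expect_equal(f2, fac * f1, tolerance = 1e-12)
  }
})

test_that("loading contact force matches an independent interpolation oracle", {
  crv <- material_curve(c(0, 0.2, 0.6, 1), c(0, 4e4, 3e5, 1.1e6))
  mat <- hysteretic_material(crv, scale = 1.7)
  R <- test_headform$radius
  th <- test_layer$thickness
  for (x in c(0, 0.004, 0.031, 0.077, 0.099)) {
    eps <- x / th
    # piecewise-linear stress by hand
    sig <- if (eps <= 0.2) eps / 0.2 * 4e4
           else if (eps <= 0.6) 4e4 + (eps - 0.2) / 0.4 * (3e5 - 4e4)
           else 3e5 + (eps - 0.6) / 0.4 * (1.1e6 - 3e5)
    area <- min(pi * (2 * R * min(x, R) - min(x, R)^2), pi * R^2)
    f <- contact_force(list(indentation = x, indentation_rate = 0.5,
                            peak_energy = 0, current_energy = 0),
                       mat, test_headform, test_layer)
    expect_equal(f, 1.7 * sig * area, tolerance = 1e-9)
  }
  expect_identical(
    contact_force(list(indentation = 0, indentation_rate = 1,
                       peak_energy = 0, current_energy = 0),
                  mat, test_headform, test_layer), 0)
  expect_error(
    contact_force(list(indentation = th * 1.01, indentation_rate = 1,
                       peak_energy = 0, current_energy = 0),
                  mat, test_headform, test_layer), "thicker")
})

test_that("unloading force is continuous at onset and tends to hu at full unload", {
  mat <- baseline_material()  # hu = 0.5
  x <- 0.03
  Wmax <- 12
  load <- contact_force(list(indentation = x, indentation_rate = 1,
                             peak_energy = Wmax, current_energy = Wmax),
                        mat, test_headform, test_layer)
  onset <- contact_force(list(indentation = x, indentation_rate = -1,
                              peak_energy = Wmax, current_energy = Wmax),
                         mat, test_headform, test_layer)
  expect_equal(onset, load, tolerance = 1e-12)
  drained <- contact_force(list(indentation = x, indentation_rate = -1,
                                peak_energy = Wmax, current_energy = 1e-12),
                           mat, test_headform, test_layer)
  expect_equal(drained, 0.5 * load, tolerance = 1e-6)
})

test_that("a zero-velocity drop rests quasi-statically", {
  r <- simulate_drop(test_headform, test_layer, test_material,
                     impact_velocity = 0)
  expect_equal(max(abs(r$accel$samples)), 0, tolerance = 1e-9)
  expect_identical(r$rebound_velocity, 0)
  # contact force balances weight at the resting indentation
  f_rest <- contact_force(list(indentation = r$max_indentation,
                               indentation_rate = 0, peak_energy = 0,
                               current_energy = 0),
                          test_material, test_headform, test_layer)
  expect_equal(f_rest, test_headform$mass * 9.81, tolerance = 1e-6)
})

test_that("the energy audit closes and hu = 1 conserves energy", {
  r <- simulate_drop(test_headform, test_layer, test_material,
                     drop_height = 1.2, dt = DT_COARSE)
  expect_lte(r$rebound_velocity, r$impact_velocity)
  expect_gt(r$energy_dissipated, 0)
  expect_equal(r$energy_in, r$energy_returned + r$energy_dissipated,
               tolerance = 0.01 * r$energy_in)

  elastic <- hysteretic_material(test_material$curve, hu = 1,
                                 shape = test_material$shape,
                                 scale = test_material$scale)
  re <- simulate_drop(test_headform, test_layer, elastic,
                      drop_height = 1.2, dt = DT_COARSE)
  expect_equal(re$rebound_velocity, re$impact_velocity,
               tolerance = 0.01 * re$impact_velocity)
  expect_lte(abs(re$energy_dissipated), 0.01 * re$energy_in)
})

test_that("the impulse balances the momentum exchange", {
  for (h in c(0.8, 2.0)) {
    r <- simulate_drop(test_headform, test_layer, test_material,
                       drop_height = h, dt = DT_COARSE)
    m <- test_headform$mass
    expected <- m * (r$impact_velocity + r$rebound_velocity) +
      m * 9.81 * r$contact_duration
    expect_equal(r$impulse, expected, tolerance = 0.01 * expected)
  }
})

test_that("peak acceleration and HIC grow with height; indentation with softness", {
  heights <- c(0.5, 0.9, 1.3, 1.7, 2.1)
  runs <- lapply(heights, function(h)
    simulate_drop(test_headform, test_layer, test_material, drop_height = h,
                  dt = DT_COARSE, output_dt = 5e-5))
  peaks <- sapply(runs, function(r) max(r$accel$samples))
  hics <- sapply(runs, function(r)
    hic(butterworth_filtfilt(r$accel, 2077.5))$value)
  expect_true(all(diff(peaks) > 0))
  expect_true(all(diff(hics) > 0))

  # increasing material scale raises peak/HIC and lowers indentation
  scales <- c(0.5, 1, 2)
  sruns <- lapply(scales, function(s)
    simulate_drop(test_headform, test_layer, scale_material(test_material, s),
                  drop_height = 1.59, dt = DT_COARSE, output_dt = 5e-5))
  speaks <- sapply(sruns, function(r) max(r$accel$samples))
  shics <- sapply(sruns, function(r)
    hic(butterworth_filtfilt(r$accel, 2077.5))$value)
  sind <- sapply(sruns, function(r) r$max_indentation)
  expect_true(all(diff(speaks) > 0))
  expect_true(all(diff(shics) > 0))
  expect_true(all(diff(sind) < 0))
})

test_that("halving the integration step leaves HIC essentially unchanged", {
  h1 <- drop_hic(test_material, test_headform, test_layer, 1.2, dt = 1e-6)
  h2 <- drop_hic(test_material, test_headform, test_layer, 1.2, dt = 5e-7)
  expect_lte(abs(h2 - h1) / h1, 0.001)
})

test_that("calibrate_scale hits the target HIC and is a fixed point when met", {
  s <- calibrate_scale(test_material, test_headform, test_layer,
                       target_height = 1.2, target_hic = 800,
                       dt = DT_COARSE)
  achieved <- drop_hic(scale_material(test_material, as.numeric(s)),
                       test_headform, test_layer, 1.2, dt = DT_COARSE)
  expect_equal(achieved, 800, tolerance = 0.005 * 800)

  # recalibrating the already-calibrated family returns scale ~1
  calibrated <- scale_material(test_material, as.numeric(s))
  s2 <- calibrate_scale(calibrated, test_headform, test_layer,
                        target_height = 1.2, target_hic = 800,
                        dt = DT_COARSE)
  expect_equal(as.numeric(s2), 1, tolerance = 0.02)

  # a larger HIC target needs a stiffer (larger) scale
  s_hi <- calibrate_scale(test_material, test_headform, test_layer,
                          target_height = 1.2, target_hic = 1200,
                          dt = DT_COARSE)
  expect_gt(as.numeric(s_hi), as.numeric(s))
})
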