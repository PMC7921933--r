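test_that("bioyield detection recovers a clean synthetic peak exactly", {
  curve <- synth_puncture_curve(17.81, 1.5)
  met <- detect_bioyield(curve)
  expect_identical(met$bioyield_force, 17.81)
  expect_identical(met$bioyield_deformation, 1.5)
  expect_true(met$rupture_detected)
})

test_that("monotone increasing curves yield no rupture", {
  d <- seq(0, 5, by = 0.01)
  curve <- force_deformation_curve(d / 1.5, d, 3 * d, source = "synthetic")
  met <- detect_bioyield(curve)
  expect_false(met$rupture_detected)
  expect_equal(met$bioyield_force, max(curve$forces))
})

test_that("plateau fluctuations below the drop threshold are not bioyield", {
  # bounded plateau wobble (3% peak-to-trough) with the qualifying drop only
  # at the true bioyield; brute-force scan over raw local maxima as oracle
  curve <- synth_puncture_curve(15, 1.8, plateau_level = 0.6,
                                fluctuation_amplitude = 0.015,
                                noise_sd = 0.003, seed = 7)
  met <- detect_bioyield(curve, drop_fraction = 0.1)
  expect_true(met$rupture_detected)
  expect_equal(met$bioyield_deformation, 1.8, tolerance = 0.02)
  # oracle: first raw local maximum whose force drops by >= 10% before the
  # curve first climbs back above it
  f <- curve$forces
  raw_max <- which(diff(sign(diff(f))) == -2) + 1L
  qualifying <- raw_max[vapply(raw_max, function(i) {
    after <- f[seq(i + 1L, length(f))]
    above <- which(after > f[i])
    upto <- if (length(above)) above[1] - 1L else length(after)
    upto >= 1L && min(after[seq_len(upto)]) < 0.9 * f[i]
  }, logical(1))]
  expect_lte(abs(met$bioyield_index - qualifying[1]), 3)
})

test_that("detection is invariant to force rescaling and sampling rate", {
  c1 <- synth_puncture_curve(17.81, 1.5, seed = 3)
  m1 <- detect_bioyield(c1)
  c2 <- force_deformation_curve(c1$times, c1$depths, c1$forces * 3.7,
                                source = "synthetic")
  m2 <- detect_bioyield(c2)
  expect_identical(m1$bioyield_index, m2$bioyield_index)

  c4 <- synth_puncture_curve(17.81, 1.5, sampling_rate = 400, seed = 3)
  m4 <- detect_bioyield(c4)
  expect_equal(m4$bioyield_force, m1$bioyield_force)
  expect_equal(m4$bioyield_deformation, m1$bioyield_deformation)
})

test_that("measured bioyield pairs survive a noisy generate-detect loop", {
  tab <- bioyield_table()
  for (i in seq_len(nrow(tab))) {
    curve <- synth_puncture_curve(tab$force_measured[i],
                                  tab$deformation_measured[i],
                                  velocity = tab$velocity[i],
                                  noise_sd = 0.01, seed = 100 + i)
    met <- detect_bioyield(curve)
    expect_equal(met$bioyield_force, tab$force_measured[i], tolerance = 0.03)
  }
})

test_that("relative error matches its definition and worked values", {
  expect_equal(relative_error(17.81, 17.30), 2.86, tolerance = 0.005 / 2.86)
  expect_equal(relative_error(13.20, 11.29), 14.47, tolerance = 0.02 / 14.47)
  expect_equal(relative_error(3.2, 3.2), 0)
  expect_error(relative_error(0, 1), "undefined-reference")
  # non-negative, zero iff equal, normalised by the measured value only
  set.seed(11)
  xe <- runif(50, 1, 20); xf <- runif(50, 1, 20)
  re <- relative_error(xe, xf)
  expect_true(all(re >= 0))
  expect_equal(re, abs(xe - xf) / xe * 100)
})

test_that("sensitivity study contrasts the extreme property levels", {
  const <- sensitivity_study(function(sk, fl) 12)
  expect_equal(const$percent_decrease, 0)

  lookup <- sensitivity_study(function(sk, fl)
    if (sk$E == 15) 19 else if (sk$E == 2) 9 else 14)
  expect_equal(lookup$percent_decrease, (19 - 9) / 19 * 100, tolerance = 1e-12)
  expect_equal(lookup$percent_decrease, 52.6, tolerance = 0.002)

  # monotone runner: study output is monotone across levels
  mono <- sensitivity_study(function(sk, fl) 2 * sk$E + 3 * sk$sigma_y + fl$E)
  expect_true(all(diff(mono$table$bioyield_force) > 0))

  # a failing cell is flagged and the study continues
  flaky <- sensitivity_study(function(sk, fl)
    if (sk$E == 6) stop("boom") else sk$E)
  expect_false(flaky$table$ok[2])
  expect_true(all(flaky$table$ok[c(1, 3)]))
  expect_false(is.na(flaky$percent_decrease))
})

test_that("velocity-effect fit recovers exact quadratics and judges noise", {
  v <- c(1.5, 2, 2.5)
  f1 <- fit_velocity_effect(v, -2 * v^2 + 1.5 * v)
  expect_equal(f1$a, -2)
  expect_equal(f1$b, 1.5)
  expect_equal(f1$r_squared, 1)

  f2 <- fit_velocity_effect(v, 0.035 * v^2 + 0.12 * v)
  expect_equal(f2$a, 0.035)
  expect_equal(f2$b, 0.12)

  set.seed(5)
  vv <- seq(0.5, 3, by = 0.25)
  noise <- rnorm(length(vv), 0, 0.05)
  f3 <- fit_velocity_effect(vv, -2 * vv^2 + 1.5 * vv + noise)
  expect_lt(f3$r_squared, 1)
  expect_equal(f3$a, -2, tolerance = 0.1)
  expect_equal(f3$b, 1.5, tolerance = 0.25)
  expect_error(fit_velocity_effect(c(1, 2), c(1, 2)), "insufficient-data")
})

test_that("curve CSV round-trips through read/write", {
  curve <- synth_puncture_curve(10, 1.2, noise_sd = 0.02, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_curve_csv(curve, f)
  back <- read_curve_csv(f, source = "synthetic")
  expect_equal(back$forces, curve$forces)
  expect_equal(back$depths, curve$depths)
  expect_error(read_curve_csv(system.file("extdata", "material_levels.csv",
                                          package = "puncturesim")),
               "expected columns")
})

test_that("curve invariants are enforced", {
  expect_error(force_deformation_curve(1:3, c(1, 0.5, 2), c(1, 1, 1)),
               "non-decreasing")
  expect_error(force_deformation_curve(1:3, 1:3, c(1, -1, 1)),
               "non-negative")
  expect_error(force_deformation_curve(1:3, 1:2, 1:3), "equal length")
})
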