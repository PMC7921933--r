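test_that("moisture content is the relative oven-drying mass loss", {
  expect_equal(moisture_content(10, 1.5), 85)
  expect_equal(moisture_content(20, 20), 0)
  expect_equal(moisture_content(20, 2.4), 88)
  expect_error(moisture_content(0, 0), "invalid-measurement")
  expect_error(moisture_content(-1, 0.5), "invalid-measurement")
  expect_error(moisture_content(10, 11), "invalid-measurement")
})

test_that("Poisson's ratio interpolates fresh and dried endpoints", {
  expect_equal(poisson_from_moisture(100), 0.5)
  expect_equal(poisson_from_moisture(0), 0.1)
  expect_equal(poisson_from_moisture(85), 0.44)
  mc <- seq(0, 100, by = 0.5)
  nu <- poisson_from_moisture(mc)
  expect_true(all(diff(nu) > 0))
  expect_true(all(nu >= 0.1 & nu <= 0.5))
  expect_error(poisson_from_moisture(101), "\\[0, 100\\]")
  expect_error(poisson_from_moisture(-1), "\\[0, 100\\]")
})

test_that("cylinder density converts mm^3 to g/cm^3", {
  expect_equal(density_from_cylinder(6.83, 20, 25), 0.87, tolerance = 0.005 / 0.87)
  expect_equal(density_from_cylinder(7.854, 20, 25), 1.00, tolerance = 1e-4)
  expect_error(density_from_cylinder(1, 0, 25), "positive")
})

test_that("bilinear law is continuous with slopes E then Et", {
  p <- material_params(E = 2, sigma_y = 0.5, Et = 0.02, nu = 0.43, rho = 1000)
  expect_equal(bilinear_stress(0.1, p), 0.2)
  pa <- material_level_params("skin", "avg")
  expect_equal(bilinear_stress(pa$sigma_y / pa$E, pa), pa$sigma_y)
  expect_equal(bilinear_stress(0.5, pa), 2.5025)
  # piecewise-linear slopes on both branches, continuity at yield
  for (tissue in c("skin", "flesh")) for (lv in c("min", "avg", "max")) {
    q <- material_level_params(tissue, lv)
    ey <- q$sigma_y / q$E
    expect_equal((bilinear_stress(0.8 * ey, q) - bilinear_stress(0.4 * ey, q)) /
                   (0.4 * ey), q$E)
    expect_equal((bilinear_stress(3 * ey, q) - bilinear_stress(2 * ey, q)) / ey,
                 q$Et, tolerance = 1e-10)
    eps <- seq(0, 4 * ey, length.out = 101)
    expect_true(all(diff(bilinear_stress(eps, q)) >= 0))
  }
  expect_error(bilinear_stress(-0.1, pa), "non-negative")
})

test_that("hardening modulus converts Et and back to machine precision", {
  expect_equal(hardening_modulus(6, 0), 0)
  expect_equal(hardening_modulus(6, 0.03), 0.18 / 5.97)
  expect_equal(hardening_modulus(6, 0.03), 0.030151, tolerance = 1e-4)
  expect_error(hardening_modulus(6, 6), "invalid-hardening")
  for (i in seq_len(nrow(material_levels()))) {
    row <- material_levels()[i, ]
    H <- hardening_modulus(row$E, row$Et)
    expect_equal(tangent_from_hardening(row$E, H), row$Et, tolerance = 1e-14)
  }
})

test_that("level lookup returns the printed tuples and rejects typos", {
  sa <- material_level_params("skin", "avg")
  expect_equal(unlist(sa[c("E", "sigma_y", "Et", "nu", "rho")]),
               c(E = 6, sigma_y = 2.5, Et = 0.03, nu = 0.44, rho = 1100))
  fm <- material_level_params("flesh", "min")
  expect_equal(unlist(fm[c("E", "sigma_y", "Et", "nu", "rho")]),
               c(E = 0.5, sigma_y = 0.05, Et = 0.002, nu = 0.43, rho = 1000))
  expect_error(material_level_params("flesh", "typo"), "unknown level")
  expect_error(material_level_params("rind", "avg"), "unknown tissue")
  # packaged CSV is bit-identical to the in-memory table
  csv <- read.csv(system.file("extdata", "material_levels.csv",
                              package = "puncturesim"))
  expect_identical(csv$E, material_levels()$E)
  expect_identical(csv$sigma_y, material_levels()$sigma_y)
})

test_that("material parameter invariants are enforced", {
  expect_error(material_params(0, 1, 0, 0.4, 1000), "E must be positive")
  expect_error(material_params(2, 1, 2, 0.4, 1000), "Et")
  expect_error(material_params(2, 1, 0.1, 0.5, 1000), "nu")
  expect_error(material_params(2, -1, 0.1, 0.4, 1000), "sigma_y")
})

test_that("bilinear fit recovers generator parameters on clean records", {
  # pure linear input: slope recovered, yield flagged undetected
  rec <- stress_strain_record(seq(0, 0.3, length.out = 30),
                              2 * seq(0, 0.3, length.out = 30))
  fit <- fit_bilinear(rec)
  expect_equal(fit$E, 2)
  expect_false(fit$yield_detected)
  expect_true(is.na(fit$sigma_y))

  # noise-free round trip through the synthetic generator, every level
  for (tissue in c("skin", "flesh")) for (lv in c("min", "avg", "max")) {
    p <- material_level_params(tissue, lv)
    rec <- synth_bilinear_record(p, max_strain = 3 * p$sigma_y / p$E,
                                 n_points = 80)
    fit <- fit_bilinear(rec)
    expect_true(fit$yield_detected)
    expect_equal(fit$E, p$E, tolerance = 0.01)
    expect_equal(fit$sigma_y, p$sigma_y, tolerance = 0.01)
    expect_equal(fit$Et, p$Et, tolerance = 0.01)
  }
})

test_that("bilinear fit tolerates multiplicative noise", {
  p <- material_level_params("skin", "avg")
  rec <- synth_bilinear_record(p, max_strain = 3 * p$sigma_y / p$E,
                               n_points = 200, noise_sd = 0.02, seed = 42)
  fit <- fit_bilinear(rec, tol = 0.05)
  expect_equal(fit$E, p$E, tolerance = 0.10)
})

test_that("stress-strain records enforce their invariants", {
  expect_error(stress_strain_record(0.1, 0.2), "length >= 2")
  expect_error(stress_strain_record(c(0.1, 0.2), c(1, 2)),
               "increasing from 0")
  expect_error(stress_strain_record(c(0, 0.2, 0.2), c(1, 2, 3)),
               "increasing")
})
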