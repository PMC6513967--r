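test_that("model class enumeration returns the content-major Cartesian product", {
  expect_length(fascicle_classes(), 49L)
  expect_length(fascicle_classes(0.35, 70), 1L)

  cls6 <- fascicle_classes(c(0.35, 0.5), c(70, 73, 76))
  expect_length(cls6, 6L)
  expect_equal(cls6[[1]]$fiber_content, 0.35)
  expect_equal(cls6[[1]]$helix_angle, 70)
  # content-major: angles cycle fastest
  expect_equal(vapply(cls6, `[[`, 0, "helix_angle"), c(70, 73, 76, 70, 73, 76))
  expect_equal(vapply(cls6, `[[`, 0, "fiber_content"), rep(c(0.35, 0.5), each = 3))

  expect_error(fascicle_classes(c(0.35, 1.2), 70), "1.2")
  expect_error(fascicle_classes(0.35, c(70, 95)), "95")
  expect_error(fascicle_class(0, 70), "out of range")
})

test_that("elastic modulus follows the rule of mixtures with its limits", {
  p <- ref_truth()
  expect_equal(elastic_modulus(p, fascicle_class(0.35, 70)), 490.26)
  # pure-fiber degenerate limit
  expect_equal(elastic_modulus(p, fascicle_class(1, 70)), 1400)
  # homogeneous material
  ph <- material_params(100, 42000, 100)
  expect_equal(elastic_modulus(ph, fascicle_class(0.42, 72)), 100)
})

test_that("elastic modulus is Voigt-sandwiched and monotone", {
  set.seed(11)
  for (i in 1:50) {
    Ef <- runif(1, 500, 2500); Em <- runif(1, 0.01, 5); fr <- runif(1, 0.01, 0.99)
    p <- material_params(Ef, 42000, Em)
    e <- elastic_modulus(p, fascicle_class(fr, 70))
    expect_gte(e, min(Ef, Em)); expect_lte(e, max(Ef, Em))
  }
  # strictly increasing in E_f and in f_r when E_f > E_m
  cls <- fascicle_class(0.5, 70)
  e1 <- elastic_modulus(material_params(1000, 42000, 1), cls)
  e2 <- elastic_modulus(material_params(1100, 42000, 1), cls)
  expect_gt(e2, e1)
  e3 <- elastic_modulus(material_params(1000, 42000, 1), fascicle_class(0.6, 70))
  expect_gt(e3, e1)
})

test_that("Poisson surrogate hits its closed-form values and limits", {
  cls75 <- fascicle_class(0.35, 75)
  # rigid-fiber limit as E_m -> 0
  p0 <- material_params(1400, 42000, 1e-9)
  expect_equal(poisson_ratio(p0, cls75), tan(75 * pi / 180)^2, tolerance = 1e-6)
  expect_equal(tan(75 * pi / 180)^2, 1 / tan(15 * pi / 180)^2)  # cot^2(15 deg)

  expect_equal(poisson_ratio(ref_truth(), cls75), 1.10, tolerance = 0.01)
  p5 <- material_params(1400, 42000, 5)
  expect_equal(poisson_ratio(p5, cls75), 0.55, tolerance = 0.01)
})

test_that("Poisson surrogate is monotone in matrix modulus and angle, bounded by its limits", {
  cls <- fascicle_class(0.4, 73)
  Ems <- seq(0.01, 5, length.out = 20)
  nus <- vapply(Ems, function(em)
    poisson_ratio(material_params(1400, 42000, em), cls), 0)
  expect_true(all(diff(nus) < 0))           # strictly decreasing in E_m
  nu_h <- tan(73 * pi / 180)^2
  expect_true(all(nus > 0.5 & nus < nu_h))  # strictly between nu_m and nu_h

  angles <- seq(60, 80, by = 2)
  nth <- vapply(angles, function(th)
    poisson_ratio(ref_truth(), fascicle_class(0.4, th)), 0)
  expect_true(all(diff(nth) > 0))           # strictly increasing in theta
})

test_that("relaxation modulus matches the standard-linear-solid closed form", {
  p <- ref_truth()
  cls <- fascicle_class(0.35, 70)
  expect_equal(relaxation_modulus(p, cls, 0), 490.26)
  expect_equal(relaxation_modulus(p, cls, 0), elastic_modulus(p, cls))
  # t -> infinity: exponential branch gone
  expect_equal(relaxation_modulus(p, cls, 1e9), 196.26, tolerance = 1e-6)
  # one relaxation time: tau = eta / E_R = 42000 / 840 = 50 s
  expect_equal(relaxation_time(p), 50)
  expect_equal(relaxation_modulus(p, cls, 50),
               0.35 * (560 + 840 * exp(-1)) + 0.65 * 0.4, tolerance = 1e-12)
  expect_equal(relaxation_modulus(p, cls, 50), 304.4, tolerance = 1e-4)
  expect_error(relaxation_modulus(p, cls, -1), "non-negative")
  # strictly decreasing in t
  tt <- seq(0, 500, by = 10)
  expect_true(all(diff(relaxation_modulus(p, cls, tt)) < 0))
})

test_that("normalized relaxation starts at 1 and decays to the mixture asymptote", {
  p <- ref_truth()
  cls <- fascicle_class(0.35, 70)
  expect_identical(normalized_relaxation(p, cls, 0), 1)
  expect_equal(normalized_relaxation(p, cls, 1e9), 196.26 / 490.26,
               tolerance = 1e-9)
  # no relaxing branch: flat curve
  p1 <- material_params(1400, 42000, 0.4, retained_fraction = 1)
  expect_equal(normalized_relaxation(p1, cls, c(0, 50, 500)), rep(1, 3))
})

test_that("viscosity unit conversion round-trips and tau is unit-consistent", {
  p_g <- material_params(1400, 42, 0.4, retained_fraction = 0.4,
                         viscosity_unit = "GPa.s")
  p_m <- material_params(1400, 42000, 0.4, retained_fraction = 0.4)
  expect_identical(p_g$fiber_viscosity, p_m$fiber_viscosity)
  expect_identical(p_g$fiber_viscosity / 1000, 42)
  # tau in (MPa, MPa s) equals tau in (GPa, GPa s)
  expect_identical(relaxation_time(p_g), 42 / ((1 - 0.4) * 1.4))
})

test_that("closed-form curve agrees with explicit-Euler SLS integration", {
  p <- ref_truth()
  cls <- fascicle_class(0.35, 75)
  times <- seq(0, 500, by = 25)
  # independent oracle: Euler steps of dE/dt = -(E - E_inf)/tau on the fiber,
  # mixture with the constant matrix afterwards
  dt <- 1e-3
  Einf <- 0.4 * 1400; ER <- 0.6 * 1400; tau <- 42000 / ER
  n_steps <- round(times / dt)
  E_fiber <- Einf + (ER) * (1 - dt / tau)^n_steps  # exact solution of the Euler recurrence
  oracle <- (0.35 * E_fiber + 0.65 * 0.4) / (0.35 * 1400 + 0.65 * 0.4)
  got <- normalized_relaxation(p, cls, times)
  expect_lt(max(abs(got - oracle)), 1e-4)
})

test_that("predict_observables bundles the three quantities deterministically", {
  p <- ref_truth()
  cls <- fascicle_class(0.35, 75)
  tt <- seq(0, 300, length.out = 30)
  ob <- predict_observables(p, cls, tt)
  expect_equal(ob$elastic_modulus, 490.26)
  expect_equal(ob$poisson_ratio, 1.10, tolerance = 0.01)
  expect_identical(ob$curve$Ebar[1], 1)
  expect_true(all(diff(ob$curve$Ebar) < 0))
  # anchored absolute curve never disagrees with q1 at t = 0
  expect_identical(ob$curve$E_MPa[1], ob$elastic_modulus)
  ob2 <- predict_observables(p, cls, tt)
  expect_identical(ob, ob2)
  # r_inf = 1: flat q3, q1 unchanged
  p1 <- material_params(1400, 42000, 0.4, retained_fraction = 1)
  ob1 <- predict_observables(p1, cls, tt)
  expect_equal(ob1$curve$Ebar, rep(1, 30))
  expect_equal(ob1$elastic_modulus, ob$elastic_modulus)
})
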