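# Shape-fidelity scores and the extrusion-pressure model.

test_that("ideal print gives the exact score identities", {
  ng <- needle_geometry(0.41, 12.5)
  fm <- fiber_measurement(rep(0.41, 50))
  gm <- grid_measurement(20, 20, rep(20, 5), rep(20, 5))
  ss <- score_print(fm, gm, ng)
  expect_identical(ss$S, 100)
  expect_identical(ss$U, 1)
  expect_identical(ss$Pe, 1)
  expect_identical(ss$Pr, 1)
  expect_identical(ss$P, 1)
})

test_that("spreading factor is the percent diameter ratio", {
  ng <- needle_geometry(0.41, 12.5)
  expect_equal(spreading_factor(fiber_measurement(rep(0.82, 10)), ng), 200)
  expect_error(fiber_measurement(numeric(0)), "empty")
  expect_error(fiber_measurement(c(0.4, -0.1)), "positive")
})

test_that("scores match the independent oracle on 100 random measurement sets", {
  ng <- needle_geometry(0.41, 12.5)
  withr::with_seed(202, {
    for (i in 1:100) {
      diams <- runif(50, 0.3, 0.9)
      sx <- runif(5, 18, 22); sy <- runif(5, 18, 22)
      l0x <- runif(1, 15, 25); l0y <- runif(1, 15, 25)
      fm <- fiber_measurement(diams)
      gm <- grid_measurement(l0x, l0y, sx, sy)
      U <- uniformity_coefficient(fm, ng)
      Pe <- perimeter_coefficient(gm)
      Pr <- pore_coefficient(gm)
      expect_equal(spreading_factor(fm, ng), oracle_S(diams, 0.41),
                   tolerance = 1e-12)
      expect_equal(U, oracle_U(diams, 0.41), tolerance = 1e-12)
      expect_equal(Pe, oracle_Pe(l0x, l0y, sx, sy), tolerance = 1e-12)
      expect_equal(Pr, oracle_Pr(l0x, l0y, sx, sy), tolerance = 1e-12)
      expect_equal(printability_coefficient(U, Pe, Pr),
                   oracle_P(U, Pe, Pr), tolerance = 1e-12)
      expect_gt(abs(U - 1), 0)   # dispersion moves U off unity
    }
  })
})

test_that("single-point dispersion is undefined: U = 1 with a warning", {
  ng <- needle_geometry()
  expect_warning(u <- uniformity_coefficient(fiber_measurement(0.5), ng),
                 "single measurement")
  expect_equal(u, 1)
})

test_that("scores are invariant under a common length rescaling", {
  withr::with_seed(7, {
    diams <- runif(50, 0.3, 0.9)
    sx <- runif(5, 18, 22); sy <- runif(5, 19, 21)
  })
  for (k in c(0.1, 3, 40)) {
    ng1 <- needle_geometry(0.41, 12.5)
    ngk <- needle_geometry(0.41 * k, 12.5 * k)
    s1 <- score_print(fiber_measurement(diams),
                      grid_measurement(20, 20, sx, sy), ng1)
    sk <- score_print(fiber_measurement(diams * k),
                      grid_measurement(20 * k, 20 * k, sx * k, sy * k), ngk)
    expect_equal(sk$S, s1$S, tolerance = 1e-12)
    expect_equal(sk$U, s1$U, tolerance = 1e-12)
    expect_equal(sk$Pe, s1$Pe, tolerance = 1e-12)
    expect_equal(sk$Pr, s1$Pr, tolerance = 1e-12)
    expect_equal(sk$P, s1$P, tolerance = 1e-12)
  }
})

test_that("invalid grid or component inputs error", {
  expect_error(grid_measurement(20, 20, numeric(0), rep(20, 3)), "non-empty")
  expect_error(grid_measurement(20, 20, c(20, -1), rep(20, 3)), "> 0")
  expect_error(printability_coefficient(1, NaN, 1), "finite")
})

test_that("extrusion pressure equals the capillary wall-stress closed form", {
  # degenerate unit needle: L = R, tau = 1 Pa -> 2 Pa
  ng <- needle_geometry(inner_diameter_mm = 2, length_mm = 1)
  expect_equal(as.numeric(estimate_extrusion_pressure(1, ng)) * 1000, 2,
               tolerance = 1e-12)
  # general closed form dP = 2 L tau / R
  ng22 <- needle_geometry(0.41, 12.5)
  tau <- 205
  expect_equal(as.numeric(estimate_extrusion_pressure(tau, ng22)),
               2 * 0.0125 * tau / (0.41e-3 / 2) / 1000, tolerance = 1e-9)
  # Newtonian power-law variant coincides with the wall-stress form
  fitN <- fit_power_law(flow_curve(c(1, 10, 100), rep(5, 3)))
  pN <- estimate_extrusion_pressure(tau, ng22, flow = fitN)
  expect_equal(as.numeric(pN),
               as.numeric(estimate_extrusion_pressure(tau, ng22)),
               tolerance = 1e-9)
  expect_identical(attr(pN, "model"), "power_law")
})

test_that("pressure is monotone in stress and needle geometry", {
  taus <- c(50, 121, 205, 400)
  lens <- c(5, 12.5, 25)
  dias <- c(0.2, 0.41, 0.84)
  p <- function(tau, d, l)
    as.numeric(estimate_extrusion_pressure(tau, needle_geometry(d, l)))
  for (l in lens) for (d in dias)
    expect_true(all(diff(sapply(taus, p, d = d, l = l)) > 0))
  for (tau in taus) for (d in dias)
    expect_true(all(diff(sapply(lens, function(l) p(tau, d, l))) > 0))
  for (tau in taus) for (l in lens)
    expect_true(all(diff(sapply(dias, function(d) p(tau, d, l))) < 0))
  # doubling L doubles pressure; doubling R halves it
  expect_equal(p(100, 0.41, 25), 2 * p(100, 0.41, 12.5), tolerance = 1e-12)
  expect_equal(p(100, 0.82, 12.5), p(100, 0.41, 12.5) / 2, tolerance = 1e-12)
})

test_that("score_print is deterministic and near-unity prints are EBB-suitable", {
  tr <- print_job_truth(true_fiber_diameter = 0.45, fiber_waviness_amp = 0.03,
                        side_jitter_sd = 0.1, seed = 21)
  imgs <- simulate_print_images(tr, um_per_px = 25)
  ng <- needle_geometry(0.41, 12.5)
  s1 <- score_print(measure_fiber_profile(imgs$fiber, seed = 5),
                    measure_grid(imgs$grid, cad_side_x = 20, cad_side_y = 20),
                    ng)
  imgs2 <- simulate_print_images(tr, um_per_px = 25)
  s2 <- score_print(measure_fiber_profile(imgs2$fiber, seed = 5),
                    measure_grid(imgs2$grid, cad_side_x = 20, cad_side_y = 20),
                    ng)
  expect_identical(s1, s2)
  # slight displacement below unity (within -10%) still counts printable
  expect_gt(s1$P, 0.9)
  expect_lt(s1$P, 1.05)
})
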