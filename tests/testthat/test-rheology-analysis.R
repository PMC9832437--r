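# Gel-point, yield-point, power-law, recovery and LVE analyzers, plus the
# CSV table round trip.

test_that("gel point of a linear crossing sampled at the crossing is exact", {
  t <- seq(0, 120, by = 5)          # grid contains t = 60
  sw <- rheo_sweep("time_sweep", t, Gp = 2 * t + 1e-9, Gpp = t + 60)
  res <- detect_gel_point(sw)
  expect_equal(res$crossover_time, 60)
})

test_that("gel point is recovered within one sampling interval on synthetic sweeps", {
  grid <- seq(0, 300, by = 1)
  for (tc in c(45.3, 60, 120, 217.8)) {
    sw <- simulate_gelation_timesweep(gelation_params(tc), grid)
    res <- detect_gel_point(sw)
    expect_lt(abs(res$crossover_time - tc), 1)
  }
})

test_that("no sustained crossing returns absent, not an error", {
  t <- seq(1, 50, 1)
  sw <- rheo_sweep("time_sweep", t, Gp = rep(10, 50), Gpp = rep(20, 50))
  expect_true(is.na(detect_gel_point(sw)$crossover_time))
  # single-point noise flip is rejected as unsustained
  Gp <- rep(10, 50); Gp[25] <- 30
  res <- detect_gel_point(rheo_sweep("time_sweep", t, Gp, rep(20, 50)))
  expect_true(is.na(res$crossover_time))
})

test_that("crossing detectors are invariant under common modulus rescaling", {
  sw <- simulate_gelation_timesweep(gelation_params(75), seq(0, 200, 1))
  base <- detect_gel_point(sw)$crossover_time
  for (k in c(1e-3, 7, 1e4)) {
    scaled <- rheo_sweep("time_sweep", sw$abscissa, k * sw$Gp, k * sw$Gpp)
    expect_equal(detect_gel_point(scaled)$crossover_time, base)
  }
})

test_that("swapping the roles of G' and G'' never reproduces the gel point", {
  sw <- simulate_gelation_timesweep(gelation_params(75), seq(0, 200, 1))
  swapped <- rheo_sweep("time_sweep", sw$abscissa, sw$Gpp, sw$Gp)
  res <- detect_gel_point(swapped)
  # the swapped series crosses downward, which is not a gelation event
  expect_true(is.na(res$crossover_time))
})

test_that("yield point is recovered within grid resolution", {
  for (sy in c(205, 155, 121)) {
    sw <- simulate_yield_sweep(yield_sweep_params(sy))
    res <- detect_yield_point(sw)
    i <- res$bracketing_indices
    gap <- diff(sw$abscissa[i])
    expect_lt(abs(res$sigma_y - sy), max(gap, 1e-9))
  }
})

test_that("yield point of a linear symmetric crossing sampled at 205 is exact", {
  s <- seq(5, 405, by = 25)          # grid contains 205
  sw <- rheo_sweep("amplitude_sweep", s, Gp = 410 - s, Gpp = s)
  expect_equal(detect_yield_point(sw)$sigma_y, 205)
})

test_that("liquid-at-rest sweeps raise the distinct no_solid_regime error", {
  s <- exp(seq(log(0.1), log(100), length.out = 20))
  sw <- rheo_sweep("amplitude_sweep", s, Gp = rep(5, 20), Gpp = rep(50, 20))
  expect_error(detect_yield_point(sw), class = "no_solid_regime")
  # solid throughout: absent yield, not an error
  sw2 <- rheo_sweep("amplitude_sweep", s, Gp = rep(50, 20), Gpp = rep(5, 20))
  expect_true(is.na(detect_yield_point(sw2)$sigma_y))
})

test_that("power-law fit is exact on noiseless data", {
  fit <- fit_power_law(simulate_flow_curve(power_law_params(10, 0.3)))
  expect_equal(fit$K, 10, tolerance = 1e-9)
  expect_equal(fit$n, 0.3, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  # Newtonian constant viscosity
  fitN <- fit_power_law(flow_curve(c(1, 5, 25, 100), rep(5, 4)))
  expect_equal(fitN$n, 1, tolerance = 1e-12)
  expect_equal(fitN$K, 5, tolerance = 1e-12)
  expect_equal(fitN$r_squared, 1)
})

test_that("power-law estimator bias vanishes as noise shrinks", {
  err <- sapply(c(0.05, 0.005), function(ns) {
    med <- sapply(1:40, function(s) {
      fit <- fit_power_law(simulate_flow_curve(
        power_law_params(10, 0.3, noise_sd_rel = ns, seed = s)))
      abs(fit$n - 0.3)
    })
    median(med)
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.002)
})

test_that("recovery analyzer returns the constructed fraction", {
  expect_equal(compute_recovery(simulate_recovery_trace(1000, 50, 1))$recovery,
               1, tolerance = 1e-3)
  r <- compute_recovery(simulate_recovery_trace(1000, 50, 0.5,
                                                noise_sd_rel = 0.005,
                                                seed = 3))
  expect_equal(r$recovery, 0.5, tolerance = 0.01)
  # missing interval 2 coverage is a protocol violation
  tr <- simulate_recovery_trace(1000, 50, 0.5)
  keep <- tr$abscissa <= 100 | tr$abscissa > 300
  broken <- rheo_sweep("recovery", tr$abscissa[keep], tr$Gp[keep],
                       tr$Gpp[keep])
  expect_error(compute_recovery(broken), "interval 2")
})

test_that("LVE summary means match hand-computed values", {
  f <- c(0.1, 1, 10, 20)
  sw <- rheo_sweep("freq_sweep", f, Gp = rep(1000, 4), Gpp = rep(200, 4))
  s <- summarize_lve(sw)
  expect_equal(s$mean_Gp, 1000)
  expect_equal(s$mean_Gpp, 200)
  expect_equal(s$mean_tan_delta, 0.2)
  # two-point band arithmetic oracle
  sw2 <- rheo_sweep("freq_sweep", f, Gp = c(100, 200, 400, 800),
                    Gpp = c(10, 40, 40, 80))
  s2 <- summarize_lve(sw2, band = c(0.5, 12))
  expect_equal(s2$mean_Gp, (200 + 400) / 2)
  expect_equal(s2$mean_tan_delta, (40 / 200 + 40 / 400) / 2)
  expect_error(summarize_lve(sw2, band = c(30, 50)), "outside")
})

test_that("rheo table writer/reader round trip preserves records", {
  path <- tempfile(fileext = ".csv")
  sw <- simulate_gelation_timesweep(gelation_params(60, noise_sd_rel = 0.02,
                                                    seed = 8), seq(0, 150, 1))
  write_rheo_table(sw, path)
  back <- read_rheo_table(path)
  expect_equal(back$abscissa, sw$abscissa)
  expect_equal(back$Gp, sw$Gp)
  expect_equal(back$Gpp, sw$Gpp)
  expect_equal(back$test_type, "time_sweep")

  fc <- simulate_flow_curve(power_law_params(10, 0.5))
  write_rheo_table(fc, path)
  back2 <- read_rheo_table(path)
  expect_s3_class(back2, "flow_curve")
  expect_equal(back2$viscosity, fc$viscosity)
})

test_that("shuffled rows are sorted with a warning; bad files error", {
  path <- tempfile(fileext = ".csv")
  sw <- simulate_gelation_timesweep(gelation_params(60), seq(0, 30, 1))
  write_rheo_table(sw, path)
  df <- read.csv(path)
  write.csv(df[rev(seq_len(nrow(df))), ], path, row.names = FALSE)
  expect_warning(back <- read_rheo_table(path), "sort")
  expect_equal(back$abscissa, sw$abscissa)
  # missing modulus column
  df$Gpp_Pa <- NULL
  write.csv(df, path, row.names = FALSE)
  expect_error(read_rheo_table(path), "missing columns")
})
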