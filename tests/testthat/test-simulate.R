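test_that("metabolic power follows lag, saturating rise and exhaustion", {
  p_hold <- kinetic_profile(lag_s = 13 * 3600, rise_tau_s = 4 * 3600,
                            peak_pW_per_cell = 48)
  # silent during the lag
  expect_equal(metabolic_power(p_hold, c(0, 3600, 12.9 * 3600), 150000),
               rep(0, 3))
  # asymptote: 48 pW/cell x 150,000 cells = 7.2 uW
  expect_equal(metabolic_power(p_hold, 1e9, 150000), 7.2, tolerance = 1e-6)
  # zero-peak profile is identically zero
  p0 <- kinetic_profile(peak_pW_per_cell = 0)
  expect_true(all(metabolic_power(p0, seq(0, 2e5, by = 1e4), 150000) == 0))
  # power decays after exhaustion
  p_ex <- kinetic_profile(lag_s = 12 * 3600, rise_tau_s = 2 * 3600,
                          peak_pW_per_cell = 48, exhaustion_s = 32 * 3600)
  t <- c(31, 33, 40) * 3600
  pw <- metabolic_power(p_ex, t, 150000)
  expect_true(pw[2] < pw[1] && pw[3] < pw[2])
  expect_error(kinetic_profile(peak_pW_per_cell = 150), "0, 100")
  expect_error(kinetic_profile(rise_tau_s = 0))
})

test_that("closed-form total heat matches 1-s quadrature and is linear in cells", {
  profiles <- list(
    kinetic_profile(lag_s = 13 * 3600, rise_tau_s = 4 * 3600,
                    peak_pW_per_cell = 48),
    kinetic_profile(lag_s = 12 * 3600, rise_tau_s = 2 * 3600,
                    peak_pW_per_cell = 48, exhaustion_s = 32 * 3600,
                    exhaustion_tau_s = 4 * 3600),
    kinetic_profile(lag_s = 40 * 3600, rise_tau_s = 3600,
                    peak_pW_per_cell = 10)
  )
  t <- seq(0, 172800)
  for (p in profiles) {
    closed <- expected_total_heat(p, 150000, 172800)
    pw <- metabolic_power(p, t, 150000)
    quad <- sum(diff(t) * (pw[-length(pw)] + pw[-1]) / 2)
    expect_equal(closed, quad, tolerance = 1e-3)
    expect_equal(expected_total_heat(p, 300000, 172800), 2 * closed)
  }
  expect_equal(expected_total_heat(kinetic_profile(peak_pW_per_cell = 0),
                                   150000, 172800), 0)
  # run shorter than the lag produces nothing
  expect_equal(expected_total_heat(profiles[[1]], 150000, 3600), 0)
})

test_that("profile rescaling hits requested per-cell totals exactly", {
  targets <- c("No Cells" = 0.3725, "Cells Only" = 3.0325,
               "Cells + Glucose" = 2.7925, "Cells + Glutamine" = 1.8987)
  profs <- profiles_matching_means(targets)
  for (g in names(targets)) {
    expect_equal(expected_total_heat(profs[[g]], 150000, 172800) / 150000,
                 unname(targets[g]), tolerance = 1e-12)
  }
  expect_true(all(vapply(profs, function(p) p$peak_pW_per_cell, 1) <= 50))
})

test_that("simulation is deterministic in the seed and validates its config", {
  a <- simulate_plate(mini_sim_config(seed = 123))
  b <- simulate_plate(mini_sim_config(seed = 123))
  expect_identical(a$thermograms$powers, b$thermograms$powers)
  expect_identical(a$truth, b$truth)
  c <- simulate_plate(mini_sim_config(seed = 124))
  expect_false(identical(a$thermograms$powers, c$thermograms$powers))
  # byte-identical files from a fixed seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_thermograms(a$thermograms, f1)
  write_thermograms(b$thermograms, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(
    simulation_config(layout = mini_layout(), profiles = list(fast = NULL)),
    "no kinetic profile.*slow")
})

test_that("reference wells are unaffected by the group profiles", {
  cfg1 <- mini_sim_config(seed = 9)
  hot <- mini_profiles()
  hot$fast$peak_pW_per_cell <- 100
  hot$slow$peak_pW_per_cell <- 0
  cfg2 <- mini_sim_config(seed = 9, profiles = hot)
  s1 <- simulate_plate(cfg1)$thermograms$powers
  s2 <- simulate_plate(cfg2)$thermograms$powers
  refs <- c("A1", "F1", "A2", "F2")
  expect_identical(s1[, refs], s2[, refs])
  expect_false(identical(s1[, "B1"], s2[, "B1"]))
})

test_that("noiseless, driftless plates collapse to the pure metabolic component", {
  cfg <- mini_sim_config(noise_sd_uW = 0, drift_uW_per_h = 0,
                         common_drift_uW_per_h = 0, offset_sd_uW = 0,
                         spike_uW = 0, peak_cv = 0, seed = 2)
  sim <- simulate_plate(cfg)
  t <- sim$thermograms$time_s
  expected <- metabolic_power(mini_profiles()$fast, t, 2e5)
  expect_equal(sim$thermograms$powers[, "B1"], expected, tolerance = 1e-12)
  expect_true(all(sim$thermograms$powers[, "A1"] == 0))
  # pipeline recovers ground truth to quadrature tolerance
  res <- process_plate(sim$thermograms, mini_pipeline_config())
  j <- dplyr::inner_join(res, sim$truth, by = "well_id")
  expect_lt(max(abs(j$total_heat_uJ - j$true_total_uJ) / j$true_total_uJ),
            1e-3)
})

test_that("reference-corrected traces recover the programmed metabolic + drift component", {
  cfg <- mini_sim_config(seed = 31, peak_cv = 0)
  sim <- simulate_plate(cfg)
  ts <- sim$thermograms
  refs <- list(get_trace(ts, "A1"), get_trace(ts, "F1"))
  rc <- reference_correct(get_trace(ts, "B1"), refs)
  programmed <- metabolic_power(mini_profiles()$fast, ts$time_s, 2e5) +
    cfg$drift_uW_per_h[1] * ts$time_s / 3600
  resid <- rc$power_uW - programmed
  # residual = constant offset + noise: correct scale, no leftover trend
  expect_lt(sd(resid), cfg$noise_sd_uW * sqrt(1.5) * 1.1)
  expect_gt(sd(resid), cfg$noise_sd_uW * sqrt(1.5) * 0.9)
  slope <- coef(lm(resid ~ ts$time_s))[2]
  expect_lt(abs(slope), 6e-6)  # < 0.022 uW/h against 0.05 uW/h programmed
})

test_that("mean recovered heat stays unbiased at the study noise level", {
  # one-column plate, 50 seeds, default 0.2 uW noise: |mean bias| < 2% of truth
  lay <- plate_layout(data.frame(
    well_id = c("A1", "B1", "C1", "D1", "E1", "F1"),
    role = c("reference", rep("sample", 4), "reference"),
    group = c(NA, rep("Cells + Glucose", 4), NA),
    cells = c(0, rep(150000, 4), 0)
  ))
  profs <- default_profiles()["Cells + Glucose"]
  rel_bias <- vapply(1:50, function(s) {
    sim <- simulate_plate(simulation_config(
      layout = lay, profiles = profs, seed = s,
      sampling_rate_hz = 1, peak_cv = 0.1
    ))
    res <- process_plate(sim$thermograms)
    j <- dplyr::inner_join(res, sim$truth, by = "well_id")
    mean((j$total_heat_uJ - j$true_total_uJ) / j$true_total_uJ)
  }, numeric(1))
  expect_lt(abs(mean(rel_bias)), 0.02)
})

test_that("plates matched to the published group means separate under the Wald F", {
  targets <- c("No Cells" = 0.3725, "Cells Only" = 3.0325,
               "Cells + Glucose" = 2.7925, "Cells + Glutamine" = 1.8987)
  profs <- profiles_matching_means(targets)
  lay <- default_layout()
  # give the no-cell wells nominal cells so all four groups enter per-cell
  lay$cells[lay$role == "sample"] <- 150000L
  crit <- qf(0.95, 3, 28)
  rejections <- vapply(1:100, function(s) {
    sim <- simulate_plate(simulation_config(
      layout = lay, profiles = profs, seed = s, sampling_rate_hz = 0.2
    ))
    res <- process_plate(sim$thermograms)
    ft <- gls_wald_f(estimate_groups(res, heat_per_cell_uJ, group))
    ft$statistic > crit
  }, logical(1))
  expect_gte(mean(rejections), 0.95)
  # closed loop: recovered group means track the plate's realized ground
  # truth within 10% (well-to-well kinetic variability is part of the truth)
  sim <- simulate_plate(simulation_config(
    layout = lay, profiles = profs, seed = 1, sampling_rate_hz = 0.2
  ))
  res <- process_plate(sim$thermograms)
  means <- tapply(res$heat_per_cell_uJ, res$group, mean)
  truth_means <- tapply(sim$truth$true_per_cell_uJ, sim$truth$group, mean)
  for (g in setdiff(names(targets), "No Cells")) {
    expect_lt(abs(means[[g]] - truth_means[[g]]) / truth_means[[g]], 0.10)
  }
})
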