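test_that("run_config validates species references and reaction settings", {
  expect_error(run_config(species = list(oxygen(), oxygen()),
                          sparge = list(gas = pure_o2(), flow_slpm = 8)),
               "duplicate")
  expect_error(run_config(species = list(oxygen()),
                          sparge = list(gas = air(), flow_slpm = 8)),
               "undefined species")
  expect_error(run_config(species = list(oxygen()),
                          sparge = list(gas = pure_o2(), flow_slpm = 8),
                          reaction = list(mode = "uniform")),
               "rates")
  expect_error(run_config(species = list(oxygen()),
                          sparge = list(gas = pure_o2(), flow_slpm = 8),
                          reaction = list(mode = "contois")),
               "contois_params")
})

test_that("peak transfer fraction", {
  inflow <- 8 / 22.4 / 60
  expect_equal(peak_transfer_fraction(0.014, 3.9, 0.00143, inflow),
               0.014 * 3.9 * 0.00143 / inflow, tolerance = 1e-12)
  expect_lt(abs(peak_transfer_fraction(0.014, 3.9, 0.00143, inflow) /
                  0.0131 - 1), 2e-3)
  expect_identical(peak_transfer_fraction(0.014, 3.9, 0, inflow), 0)
  expect_equal(peak_transfer_fraction(0.028, 3.9, 0.00143, inflow),
               2 * peak_transfer_fraction(0.014, 3.9, 0.00143, inflow),
               tolerance = 1e-12)
  expect_error(peak_transfer_fraction(0.014, 3.9, 0.00143, 0), "> 0")
})

test_that("saturation scenario rises monotonically and stays below S c_b", {
  res <- simulate_saturation(saturation_config(duration = 12, seed = 21))
  ts <- res$timeseries
  expect_true(all(diff(ts$conc_O2) > -1e-15))
  expect_true(all(ts$conc_O2 <= res$saturation[["O2"]] * (1 + 1e-9)))
  expect_true(all(ledger_balance_error(res$ledger) < 1e-8))
  expect_error(simulate_saturation(uniform_reaction_config()), "none")
})

test_that("identical configs and seed give identical results", {
  r1 <- run_scenario(saturation_config(duration = 3, seed = 9))
  r2 <- run_scenario(saturation_config(duration = 3, seed = 9))
  expect_identical(r1$timeseries, r2$timeseries)
  expect_identical(as.data.frame(r1$ledger), as.data.frame(r2$ledger))
  r3 <- run_scenario(saturation_config(duration = 3, seed = 10))
  expect_false(identical(r1$timeseries$conc_O2, r3$timeseries$conc_O2))
})

test_that("per-step species conservation links liquid, ledger and bubbles", {
  cfg <- uniform_reaction_config(duration = 6, seed = 13)
  res <- run_scenario(cfg)
  led <- res$ledger
  V_l <- cfg$geometry$liquid_volume / 1000
  for (s in c("O2", "CO2")) {
    d <- led[led$species == s, ]
    cl <- res$timeseries[[paste0("conc_", s)]] * 1000   # mol/m^3
    liquid <- cl * V_l                                  # mol in liquid
    c0 <- cfg$liquid$initial_conc[[s]] * 1000 * V_l
    # liquid delta = transfer + reaction (both cumulative)
    expect_equal(liquid - c0, d$transfer_cum + d$reaction_cum,
                 tolerance = 1e-8)
    # gas-side: injection - removal - transfer = in flight
    expect_true(all(abs(d$injection_cum - d$removal_cum - d$transfer_cum -
                          d$inflight) <=
                      1e-8 * pmax(d$injection_cum, abs(d$transfer_cum),
                                  d$inflight, 1e-300)))
  }
})

test_that("uniform-reaction scenario strips CO2 with zero CO2 injection", {
  res <- simulate_uniform_reaction(uniform_reaction_config(duration = 8,
                                                           seed = 4))
  led <- res$ledger
  co2 <- led[led$species == "CO2", ]
  expect_true(all(co2$injection_cum == 0))
  expect_true(all(co2$injection_rate == 0))
  # CO2 leaves the liquid through the bubbles: transfer is negative
  expect_lt(sum(co2$transfer_cum), 0)
  # dissolved CO2 accumulates toward R/kla from below
  expect_true(all(diff(res$timeseries$conc_CO2) > -1e-12))
})

test_that("fermentation with zero biomass leaves the broth inert", {
  sat_gL <- saturation_concentration(air(), oxygen())$g_per_L
  init <- biokinetic_state(X = 0, P = 0, S = 150, O2 = sat_gL)
  cfg <- fermentation_config(duration = 200, dt = 0.5, init = init)
  res <- simulate_fermentation(cfg)
  kin <- res$kinetic_timeseries
  expect_true(all(kin$P == 0))
  expect_true(all(kin$S == 150))
  expect_equal(max(abs(kin$O2 - sat_gL)), 0, tolerance = 1e-12)
  expect_equal(res$dPdt_gLh, 0, tolerance = 1e-12)
})

test_that("fermentation reports dP/dt from the early product slope", {
  res <- simulate_fermentation(fermentation_config(duration = 3600, dt = 0.5))
  kin <- res$kinetic_timeseries
  # slope over the first hour computed independently
  w <- kin$time <= 3600
  ref <- unname(coef(lm(kin$P[w] ~ I(kin$time[w] / 3600)))[2])
  expect_equal(res$dPdt_gLh, ref, tolerance = 1e-10)
  expect_gt(res$dPdt_gLh, 0)
  expect_gt(res$xi, 0)
})

test_that("scenario matrix compares operating conditions per row", {
  configs <- list(
    air_8 = saturation_config(duration = 3, seed = 1),
    air_16 = saturation_config(duration = 3, seed = 1, flow_slpm = 16))
  out <- run_scenario_matrix(configs)
  expect_identical(nrow(out$table), 2L)
  expect_true(all(is.na(out$table$error)))
  # doubling the gas flow approximately doubles the standing bubble count
  ratio <- out$table$n_bubbles[2] / out$table$n_bubbles[1]
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
  # identical configs give identical rows
  out2 <- run_scenario_matrix(configs[c(1, 1)])
  expect_identical(out2$table$kla_hr[1], out2$table$kla_hr[2])
  # a failing scenario is reported without sinking the rest
  bad <- saturation_config(duration = 3)
  bad$reaction$mode <- "contois"            # inconsistent: no parameters
  out3 <- run_scenario_matrix(list(a = configs[[1]], b = bad))
  expect_true(is.na(out3$table$error[1]))
  expect_false(is.na(out3$table$error[2]))
})

test_that("dissolved O2 timescale split separates transfer from growth", {
  # synthetic two-phase curve: fast exponential settle + slow linear decline
  t <- seq(0, 18000, by = 30)
  o2 <- 0.002 + 0.006 * exp(-t / 70) - 1e-8 * t
  sc <- dissolved_o2_timescales(t, o2)
  expect_equal(sc$tau_fast, 70, tolerance = 0.05)
  expect_gt(sc$ratio, 100)
})
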