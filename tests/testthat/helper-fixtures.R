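# shared fixtures: species, gases, and small run configurations

oxygen <- function() species_spec("O2", solubility = 0.032, molar_mass = 32)
carbon_dioxide <- function()
  species_spec("CO2", solubility = 0.83, molar_mass = 44.01)
nitrogen <- function() species_spec("N2", solubility = 0.015, molar_mass = 28)

air <- function() gas_mixture(c(O2 = 0.21, N2 = 0.79))
pure_o2 <- function() gas_mixture(c(O2 = 1))

# quiescent water column tall enough that bubbles reach terminal velocity
still_water <- function(height = 10, radius = 1)
  uniform_field(radius = radius, height = height)

# a single 2 mm bubble of pure oxygen at a given position
one_bubble <- function(z = 0.1, d = 2e-3, vm = 22.4, species = "O2") {
  mol <- pi / 6 * d^3 / (vm / 1000)
  moles <- matrix(0, 1, length(species), dimnames = list(NULL, species))
  moles[1, 1] <- mol
  bubble_population(pos = c(0, 0, z), vel = c(0, 0, 0), moles = moles,
                    molar_volume = vm)
}

# independent oracle: terminal rise velocity from the Schiller-Naumann
# drag / buoyancy balance (root find, no shared code with verlet_step)
terminal_velocity_oracle <- function(d, rho_f = 1000, rho_b = 1.2,
                                     nu = 1e-6, g = 9.81) {
  cd_fun <- function(re) if (re > 1000) 0.44 else 24 / re * (1 + 0.15 * re^0.687)
  bal <- function(v) {
    re <- v * d / nu
    (rho_f - rho_b) * g * pi / 6 * d^3 -
      0.5 * rho_f * cd_fun(re) * pi * d^2 / 4 * v^2
  }
  stats::uniroot(bal, c(1e-4, 2), tol = 1e-12)$root
}

saturation_config <- function(duration = 10, dt = 0.005, seed = 1,
                              parcel_weight = 400, flow_slpm = 8,
                              output_interval = 1) {
  run_config(
    species = list(oxygen()),
    sparge = list(gas = pure_o2(), flow_slpm = flow_slpm,
                  parcel_weight = parcel_weight),
    numerics = simulation_config(duration = duration, dt = dt,
                                 rng_seed = seed,
                                 output_interval = output_interval))
}

uniform_reaction_config <- function(duration = 10, dt = 0.005, seed = 2,
                                    parcel_weight = 400,
                                    rates = c(O2 = -1e-5, CO2 = 1e-5),
                                    output_interval = 1) {
  run_config(
    species = list(oxygen(), carbon_dioxide()),
    sparge = list(gas = pure_o2(), flow_slpm = 8,
                  parcel_weight = parcel_weight),
    reaction = list(mode = "uniform", rates = rates),
    numerics = simulation_config(duration = duration, dt = dt,
                                 rng_seed = seed,
                                 output_interval = output_interval))
}

fermentation_config <- function(duration = 400, dt = 0.1, seed = 3,
                                kla = 0.014, params = NULL, init = NULL,
                                output_interval = NULL) {
  if (is.null(params)) params <- illustrative_contois_params()
  if (is.null(init)) {
    sat_gL <- saturation_concentration(air(), oxygen())$g_per_L
    init <- biokinetic_state(X = 1.5, P = 0, S = 150, O2 = sat_gL)
  }
  run_config(
    species = list(oxygen(), nitrogen()),
    sparge = list(gas = air(), flow_slpm = 8),
    reaction = list(mode = "contois", params = params, initial_state = init),
    mass_transfer = list(prescribed_kla = kla),
    numerics = simulation_config(
      duration = duration, dt = dt, rng_seed = seed,
      output_interval = output_interval %||% max(1, duration / 400)))
}

`%||%` <- function(a, b) if (is.null(b)) a else if (is.null(a)) b else a

# one randomized conservation case: run a short bubble-resolved scenario and
# assert every molar balance closes (used by the property and acceptance
# suites with different case counts)
check_conservation_case <- function(case) {
  flow <- runif(1, 2, 16)
  d_b <- runif(1, 1e-3, 3e-3)
  weight <- sample(c(400, 800, 1600), 1)
  dt <- runif(1, 0.004, 0.01)
  dur <- runif(1, 0.8, 1.6)
  mode <- sample(c("none", "uniform"), 1)
  r_o2 <- -10^runif(1, -5.5, -4.5)

  reaction <- if (mode == "uniform")
    list(mode = "uniform", rates = c(O2 = r_o2, CO2 = -r_o2)) else
    list(mode = "none")
  cfg <- run_config(
    species = list(oxygen(), carbon_dioxide()),
    sparge = list(gas = pure_o2(), flow_slpm = flow, bubble_diameter = d_b,
                  parcel_weight = weight),
    reaction = reaction,
    liquid = list(initial_conc = c(O2 = runif(1, 0, 1e-3),
                                   CO2 = runif(1, 0, 1e-3))),
    numerics = simulation_config(duration = dur, dt = dt,
                                 rng_seed = case, output_interval = dt * 20))
  res <- run_scenario(cfg)
  led <- res$ledger
  info <- sprintf("case %d (flow %.2f SLPM, d %.2f mm, mode %s)",
                  case, flow, d_b * 1000, mode)

  # gas-side closure at every sample: inj - rem - transfer = in flight
  testthat::expect_true(all(ledger_balance_error(led) < 1e-8), info = info)

  # liquid-side closure: delta(liquid moles) = transfer + reaction
  V_l <- cfg$geometry$liquid_volume / 1000
  for (s in c("O2", "CO2")) {
    d <- led[led$species == s, ]
    liquid <- res$timeseries[[paste0("conc_", s)]] * 1000 * V_l
    c0 <- cfg$liquid$initial_conc[[s]] * 1000 * V_l
    scale <- max(abs(liquid), abs(d$transfer_cum), 1e-12)
    testthat::expect_lt(
      max(abs((liquid - c0) - (d$transfer_cum + d$reaction_cum))) / scale,
      1e-8, label = paste(info, s))
  }

  # physical state sanity: non-negative moles, diameters consistent
  pop <- res$final_population
  testthat::expect_true(all(pop$moles >= 0), info = info)
  if (n_bubbles(pop) > 0) {
    v <- as.numeric(pop$moles %*% (pop$molar_volume / 1000))
    testthat::expect_lt(max(abs((6 * v / pi)^(1 / 3) / pop$diameter - 1)),
                        1e-9, label = info)
  }
  testthat::expect_true(all(res$timeseries$conc_O2 >= 0), info = info)
  testthat::expect_true(all(res$timeseries$conc_CO2 >= 0), info = info)
  invisible(NULL)
}

# independent reference integration of the fermentation ODEs (deSolve lsoda)
reference_fermentation <- function(times_h, init, params, kla_h, sat_gL) {
  rhs <- function(t, y, parms) {
    st <- structure(y, class = "biokinetic_state")
    r <- contois_rates(st, params)
    r[["O2"]] <- r[["O2"]] + kla_h * (sat_gL - y[["O2"]])
    list(r)
  }
  deSolve::ode(unclass(init), times_h, rhs, NULL, rtol = 1e-10, atol = 1e-12)
}
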