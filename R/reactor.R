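# Coupled well-mixed reactor simulation: sparge injection -> bubble motion ->
# surface removal -> interphase transfer -> reaction, all on one shared
# timestep, with a full molar-flux ledger per species (injection, removal,
# gas/fluid transfer, reaction) and cumulative integrals of each.

#' Assemble a validated run configuration
#'
#' Collects every block the simulation engine needs. Units at this interface
#' follow reporting conventions (L, SLPM, mol/L, RPM); the engine converts to
#' SI internally.
#'
#' @param geometry A [reactor_geometry()].
#' @param species List of [species_spec()] objects; names must be unique and
#'   cover every species referenced by the sparge gas, initial concentrations
#'   and reaction block.
#' @param sparge List: `gas` (a [gas_mixture()]), `flow_slpm`,
#'   `bubble_diameter` (m, default 2e-3), `parcel_weight` (default 400).
#' @param flow List: `kind` (`"synthetic"` or `"uniform"`), `mean_epsilon`
#'   (m^2/s^3; default from [mean_epsilon_from_power()]), `nu` (m^2/s,
#'   default 1e-6), and for `"uniform"` a `velocity` vector.
#' @param reaction List: `mode` (`"none"`, `"uniform"` or `"contois"`); for
#'   uniform, `rates` (named, mol/(L s)); for contois, `params` (a
#'   [contois_params()]) and `initial_state` (a [biokinetic_state()]).
#' @param mass_transfer List: `prescribed_kla` (1/s; when set the engine skips
#'   bubble tracking and applies the well-stirred transfer law directly) and
#'   `tau` (averaging window for local kla maps, s).
#' @param liquid List: `initial_conc` (named, mol/L; missing species start at
#'   0) and `rho` (kg/m^3, default 1000).
#' @param numerics A [simulation_config()].
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(geometry = reactor_geometry(),
                       species,
                       sparge,
                       flow = list(kind = "synthetic"),
                       reaction = list(mode = "none"),
                       mass_transfer = list(prescribed_kla = NULL, tau = 5),
                       liquid = list(initial_conc = NULL, rho = 1000),
                       numerics = simulation_config(duration = 60)) {
  stopifnot(inherits(geometry, "reactor_geometry"),
            inherits(numerics, "simulation_config"))
  if (!is.list(species) || !all(vapply(species, inherits, TRUE, "species_spec")))
    stop("species must be a list of species_spec objects")
  sp_names <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(sp_names)) stop("duplicate species name")
  names(species) <- sp_names

  stopifnot(is.list(sparge), inherits(sparge$gas, "gas_mixture"))
  missing_gas <- setdiff(names(sparge$gas$mole_fractions), sp_names)
  if (length(missing_gas))
    stop("sparge gas references undefined species: ",
         paste(missing_gas, collapse = ", "))
  sparge$bubble_diameter <- sparge$bubble_diameter %||% 2e-3
  sparge$parcel_weight <- sparge$parcel_weight %||% 400

  flow$kind <- match.arg(flow$kind %||% "synthetic", c("synthetic", "uniform"))
  flow$nu <- flow$nu %||% 1e-6

  reaction$mode <- match.arg(reaction$mode %||% "none",
                             c("none", "uniform", "contois"))
  if (reaction$mode == "uniform") {
    if (is.null(reaction$rates) || is.null(names(reaction$rates)))
      stop("uniform reaction requires named rates (mol/(L s))")
    missing_r <- setdiff(names(reaction$rates), sp_names)
    if (length(missing_r))
      stop("reaction rates reference undefined species: ",
           paste(missing_r, collapse = ", "))
  }
  if (reaction$mode == "contois") {
    if (!inherits(reaction$params, "contois_params"))
      stop("contois reaction requires reaction$params (contois_params)")
    if (!inherits(reaction$initial_state, "biokinetic_state"))
      stop("contois reaction requires reaction$initial_state (biokinetic_state)")
    if (!"O2" %in% sp_names)
      stop("contois reaction requires an O2 species")
  }

  mass_transfer$tau <- mass_transfer$tau %||% 5
  ic <- stats::setNames(numeric(length(sp_names)), sp_names)
  if (!is.null(liquid$initial_conc)) {
    missing_c <- setdiff(names(liquid$initial_conc), sp_names)
    if (length(missing_c))
      stop("initial_conc references undefined species: ",
           paste(missing_c, collapse = ", "))
    ic[names(liquid$initial_conc)] <- liquid$initial_conc
  }
  liquid$initial_conc <- ic
  liquid$rho <- liquid$rho %||% 1000

  structure(
    list(geometry = geometry, species = species, sparge = sparge,
         flow = flow, reaction = reaction, mass_transfer = mass_transfer,
         liquid = liquid, numerics = numerics),
    class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_flow_field <- function(cfg) {
  geom <- cfg$geometry
  if (cfg$flow$kind == "uniform") {
    uniform_field(velocity = cfg$flow$velocity %||% c(0, 0, 0),
                  epsilon = cfg$flow$mean_epsilon %||% 0.1,
                  nu = cfg$flow$nu,
                  radius = geom$tank_diameter / 2,
                  height = geom$liquid_height)
  } else {
    make_stirred_tank_field(geom, mean_epsilon = cfg$flow$mean_epsilon,
                            nu = cfg$flow$nu)
  }
}

#' Run the coupled well-mixed simulation
#'
#' Advances all physics on the shared timestep of `config$numerics`. With
#' bubble tracking (the default), each step injects parcels at the sparge
#' ring, integrates their motion through the flow field, removes parcels
#' crossing the (hold-up-raised) free surface, exchanges moles between every
#' parcel and the well-mixed liquid using the penetration-theory transfer
#' coefficient sampled at each bubble centre, and applies the configured
#' reaction. With `mass_transfer$prescribed_kla` set, bubble tracking is
#' skipped and the well-stirred transfer law `kla (S c_b - c)` is applied
#' directly (the configuration used to compare against reference ODE
#' solutions).
#'
#' @param config A [run_config()].
#' @return An object of class `scenario_result`: list with `timeseries`
#'   (data frame), `ledger` (long data frame, one row per sample time and
#'   species, with instantaneous rates in mol/s and cumulative mol),
#'   `kla` (named vector, 1/s, population-measured `sum(kL A)/V_l` averaged
#'   over the final quarter of the run), `steady_state` (named, mol/L, mean
#'   over the final fifth), `mean_gas_conc` (named, mol/m^3, in-bubble gas
#'   concentration weighted by each parcel's transfer conductance kL*A,
#'   final quarter), `bubble_stats`, `kinetic_timeseries` (contois mode),
#'   `deficit`, `inflight`, and `config`.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  set.seed(cfg$numerics$rng_seed)

  geom <- cfg$geometry
  field <- build_flow_field(cfg)
  sp_names <- names(cfg$species)
  k <- length(sp_names)
  S <- vapply(cfg$species, `[[`, 0, "solubility")
  D <- vapply(cfg$species, `[[`, 0, "diffusivity")
  M <- vapply(cfg$species, `[[`, 0, "molar_mass")
  Vm <- vapply(cfg$species, `[[`, 0, "gas_molar_volume")

  V_l <- geom$liquid_volume / 1000                       # m^3
  cross_area <- pi * (geom$tank_diameter / 2)^2
  conc <- cfg$liquid$initial_conc * 1000                 # mol/L -> mol/m^3
  rho_f <- cfg$liquid$rho

  use_bubbles <- is.null(cfg$mass_transfer$prescribed_kla)
  mode <- cfg$reaction$mode

  sparge <- sparge_spec(gas = cfg$sparge$gas, flow_slpm = cfg$sparge$flow_slpm,
                        bubble_diameter = cfg$sparge$bubble_diameter,
                        ring_diameter = geom$sparge_ring_diameter,
                        height = geom$sparge_height,
                        parcel_weight = cfg$sparge$parcel_weight,
                        molar_volume = mean(Vm))
  pop <- empty_population(sp_names, molar_volume = Vm)
  carry <- 0; next_id <- 1L

  # equilibrium dissolved concentration against the sparge gas (mol/m^3)
  y <- stats::setNames(numeric(k), sp_names)
  y[names(sparge$gas$mole_fractions)] <- sparge$gas$mole_fractions
  sat_vec <- S * (y / Vm) * 1000                 # S * y/Vm mol/L -> mol/m^3

  dt <- cfg$numerics$dt
  n_steps <- max(1L, round(cfg$numerics$duration / dt))
  out_every <- max(1L, round(cfg$numerics$output_interval / dt))
  n_out <- floor(n_steps / out_every)

  streams <- c("injection", "removal", "transfer", "reaction")
  cum <- matrix(0, 4, k, dimnames = list(streams, sp_names))
  prev_cum <- cum
  deficit <- stats::setNames(numeric(k), sp_names)
  klaA_acc <- stats::setNames(numeric(k), sp_names)
  cgw_num <- stats::setNames(numeric(k), sp_names)  # transfer-weighted c_g
  cgw_den <- stats::setNames(numeric(k), sp_names)
  explicit_dt_warned <- FALSE

  contois <- mode == "contois"
  if (contois) {
    kin <- cfg$reaction$initial_state
    kp <- cfg$reaction$params
    conc["O2"] <- g_L_to_mol_m3(kin[["O2"]], M[["O2"]])
    kin_out <- matrix(NA_real_, n_out, 4,
                      dimnames = list(NULL, c("X", "P", "S", "O2")))
    sat_o2_gL <- mol_m3_to_g_L(sat_vec[["O2"]], M[["O2"]])
    kla_h <- if (use_bubbles) NA_real_ else cfg$mass_transfer$prescribed_kla * 3600
  }
  if (mode == "uniform")
    rates_m3 <- {
      r <- stats::setNames(numeric(k), sp_names)
      r[names(cfg$reaction$rates)] <- cfg$reaction$rates * 1000  # mol/(m^3 s)
      r
    }

  ts_time <- numeric(n_out)
  ts_conc <- matrix(NA_real_, n_out, k, dimnames = list(NULL, sp_names))
  ts_nb <- numeric(n_out); ts_parcels <- numeric(n_out)
  ts_md <- numeric(n_out); ts_holdup <- numeric(n_out)
  ts_kla <- matrix(NA_real_, n_out, k, dimnames = list(NULL, sp_names))
  ts_cg <- matrix(NA_real_, n_out, k, dimnames = list(NULL, sp_names))
  led_rows <- vector("list", n_out)

  sqrtD <- sqrt(D)
  out_i <- 0L
  for (i in seq_len(n_steps)) {
    if (use_bubbles) {
      inj <- inject_bubbles(sparge, dt, carry, next_id, species = sp_names)
      carry <- inj$carry; next_id <- inj$next_id
      if (n_bubbles(inj$bubbles) > 0L) {
        cum["injection", ] <- cum["injection", ] + bubble_moles(inj$bubbles)
        pop <- pop_bind(pop, inj$bubbles)
      }
      if (n_bubbles(pop) > 0L) {
        pop <- verlet_step(pop, field, dt, rho_f)
        surface <- geom$liquid_height + bubble_gas_volume(pop) / cross_area
        rmv <- remove_at_surface(pop, field, surface)
        if (n_bubbles(rmv$removed) > 0L)
          cum["removal", ] <- cum["removal", ] + bubble_moles(rmv$removed)
        pop <- rmv$remaining
      }
      if (n_bubbles(pop) > 0L) {
        eps <- field$epsilon(pop$pos)
        nuv <- field$viscosity(pop$pos)
        kl <- (0.301 * (eps * nuv)^0.25 / sqrt(nuv)) %o% sqrtD   # n x k, m/s
        area_w <- pi * pop$diameter^2 * pop$weight
        klA <- kl * area_w
        klaA_acc <- klaA_acc + colSums(klA)
        c_g <- pop$moles / (pi / 6 * pop$diameter^3)             # mol/m^3
        cgw_num <- cgw_num + colSums(klA * c_g)
        cgw_den <- cgw_den + colSums(klA)
        flux <- bubble_species_flux(pop, conc, kl, S)
        if (!explicit_dt_warned) {
          kla_inst <- colSums(kl * area_w) / V_l
          if (max(kla_inst) * dt > 0.05) {
            warning(sprintf(paste0(
              "explicit transfer coupling: kla*dt = %.3g > 0.05; per-step ",
              "concentration change exceeds 5%% of the driving difference - ",
              "reduce dt"), max(kla_inst) * dt))
            explicit_dt_warned <- TRUE
          }
        }
        tr <- apply_transfer(pop, flux, dt, list(volume = V_l, conc = conc))
        pop <- tr$pop; conc <- tr$cell$conc
        cum["transfer", ] <- cum["transfer", ] + tr$transferred
        deficit <- deficit + tr$deficit
      }
    } else if (!contois) {
      d_conc <- cfg$mass_transfer$prescribed_kla * (sat_vec - conc) * dt
      conc <- conc + d_conc
      cum["transfer", ] <- cum["transfer", ] + d_conc * V_l
      klaA_acc <- klaA_acc + cfg$mass_transfer$prescribed_kla * V_l
    }

    if (mode == "uniform") {
      prop <- rates_m3 * dt
      act <- pmax(prop, -conc)                 # consumption limited by stock
      deficit <- deficit + (act - prop)
      conc <- conc + act
      cum["reaction", ] <- cum["reaction", ] + act * V_l
    } else if (contois) {
      dt_h <- dt / 3600
      if (use_bubbles) {
        kin[["O2"]] <- mol_m3_to_g_L(conc[["O2"]], M[["O2"]])
        before <- kin[["O2"]]
        kin <- rk4_step(kin, kp, 0, dt_h)
        conc[["O2"]] <- g_L_to_mol_m3(kin[["O2"]], M[["O2"]])
        cum["reaction", "O2"] <- cum["reaction", "O2"] +
          g_L_to_mol_m3(kin[["O2"]] - before, M[["O2"]]) * V_l
      } else {
        before <- kin[["O2"]]
        src <- function(s) kla_h * (sat_o2_gL - s[["O2"]])
        kin <- rk4_step(kin, kp, src, dt_h)
        d_o2 <- kin[["O2"]] - before           # g/L, transfer + reaction
        xfer <- kla_h * (sat_o2_gL - (before + kin[["O2"]]) / 2) * dt_h
        cum["transfer", "O2"] <- cum["transfer", "O2"] +
          g_L_to_mol_m3(xfer, M[["O2"]]) * V_l
        cum["reaction", "O2"] <- cum["reaction", "O2"] +
          g_L_to_mol_m3(d_o2 - xfer, M[["O2"]]) * V_l
        conc[["O2"]] <- g_L_to_mol_m3(kin[["O2"]], M[["O2"]])
        klaA_acc["O2"] <- klaA_acc["O2"] + cfg$mass_transfer$prescribed_kla * V_l
      }
    }

    if (i %% out_every == 0L && out_i < n_out) {
      out_i <- out_i + 1L
      ts_time[out_i] <- i * dt
      ts_conc[out_i, ] <- conc / 1000                       # mol/L
      ts_parcels[out_i] <- n_bubbles(pop)
      ts_nb[out_i] <- sum(pop$weight)
      ts_md[out_i] <- if (n_bubbles(pop)) {
        sum(pop$diameter * pop$weight) / sum(pop$weight)
      } else NA_real_
      ts_holdup[out_i] <- bubble_gas_volume(pop) / V_l
      ts_kla[out_i, ] <- klaA_acc / out_every / V_l
      klaA_acc[] <- 0
      ts_cg[out_i, ] <- ifelse(cgw_den > 0, cgw_num / cgw_den, NA_real_)
      cgw_num[] <- 0; cgw_den[] <- 0
      rate <- (cum - prev_cum) / (out_every * dt)
      prev_cum <- cum
      inflight <- bubble_moles(pop)
      led_rows[[out_i]] <- data.frame(
        time = i * dt, species = sp_names,
        injection_rate = rate["injection", ], removal_rate = rate["removal", ],
        transfer_rate = rate["transfer", ], reaction_rate = rate["reaction", ],
        injection_cum = cum["injection", ], removal_cum = cum["removal", ],
        transfer_cum = cum["transfer", ], reaction_cum = cum["reaction", ],
        inflight = inflight, row.names = NULL)
      if (contois) kin_out[out_i, ] <- unclass(kin)[c("X", "P", "S", "O2")]
    }
  }

  timeseries <- data.frame(time = ts_time, ts_conc, check.names = FALSE)
  names(timeseries)[-1] <- paste0("conc_", sp_names)
  timeseries$n_parcels <- ts_parcels
  timeseries$n_bubbles <- ts_nb
  timeseries$mean_diameter_mm <- ts_md * 1000
  timeseries$holdup <- ts_holdup
  for (s in sp_names) timeseries[[paste0("kla_", s)]] <- ts_kla[, s]

  ledger <- do.call(rbind, led_rows)
  class(ledger) <- c("flux_ledger", "data.frame")

  last_q <- ts_time > ts_time[n_out] * 0.75
  last_5 <- ts_time > ts_time[n_out] * 0.8
  kla_meas <- colMeans(ts_kla[last_q, , drop = FALSE])
  steady <- colMeans(ts_conc[last_5, , drop = FALSE])     # mol/L
  mean_cg <- colMeans(ts_cg[last_q, , drop = FALSE])      # mol/m^3

  res <- list(
    timeseries = timeseries, ledger = ledger,
    kla = kla_meas, steady_state = steady,
    saturation = sat_vec / 1000,                          # mol/L
    mean_gas_conc = mean_cg,
    bubble_stats = list(
      n_parcels = ts_parcels[n_out], n_bubbles = ts_nb[n_out],
      mean_diameter_mm = mean(ts_md[last_q], na.rm = TRUE) * 1000,
      holdup = mean(ts_holdup[last_q])),
    deficit = deficit, inflight = bubble_moles(pop),
    final_population = pop, config = cfg)
  if (contois) {
    res$kinetic_timeseries <- data.frame(time = ts_time, kin_out)
  }
  class(res) <- "scenario_result"
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  sp <- names(x$steady_state)
  cat("<scenario_result>\n")
  cat(sprintf("  mode: %s | duration: %g s | species: %s\n",
              x$config$reaction$mode, max(x$timeseries$time),
              paste(sp, collapse = ", ")))
  cat(sprintf("  steady dissolved (mol/L): %s\n",
              paste(sprintf("%s=%.4g", sp, x$steady_state), collapse = ", ")))
  cat(sprintf("  kla (1/s): %s\n",
              paste(sprintf("%s=%.4g", sp, x$kla), collapse = ", ")))
  if (!is.null(x$dPdt_gLh))
    cat(sprintf("  dP/dt: %.4g g/(L h)\n", x$dPdt_gLh))
  invisible(x)
}

#' Ledger balance error
#'
#' Conservation check of the flux ledger: at every sample time, cumulative
#' injection minus removal minus gas/liquid transfer must equal the moles
#' currently in flight in bubbles. Returns the maximum absolute mismatch per
#' species, relative to the species' total molar turnover.
#'
#' @param ledger A `flux_ledger` (from a [run_scenario()] result).
#' @return Named numeric vector of relative errors.
#' @export
ledger_balance_error <- function(ledger) {
  stopifnot(is.data.frame(ledger))
  out <- vapply(split(ledger, ledger$species), function(d) {
    mismatch <- d$injection_cum - d$removal_cum - d$transfer_cum - d$inflight
    scale <- pmax(d$injection_cum, d$removal_cum, abs(d$transfer_cum),
                  d$inflight, 1e-300)
    max(abs(mismatch) / scale)
  }, 0)
  out
}

#' Non-reacting oxygen saturation scenario
#'
#' Gassing-in of a non-reacting liquid: dissolved gas rises monotonically from
#' its initial value toward the saturation limit `S c_b`; at steady state the
#' gas/fluid transfer rate vanishes and injection balances removal. Adds a
#' nonlinear kLa fit of the saturation curve to the result (`kla_fit`).
#'
#' @param config A [run_config()] with `reaction$mode == "none"`.
#' @param fit_species Species whose gassing-in curve is fitted. Default `"O2"`.
#' @return A `scenario_result` with elements `kla_fit` (1/s) and
#'   `kla_direct` (the population average `sum(kL A)/V_l`).
#' @export
simulate_saturation <- function(config, fit_species = "O2") {
  stopifnot(inherits(config, "run_config"))
  if (config$reaction$mode != "none")
    stop("simulate_saturation requires reaction mode 'none'")
  res <- run_scenario(config)
  ts <- res$timeseries
  cl <- ts[[paste0("conc_", fit_species)]]
  sat <- res$steady_state[[fit_species]]
  c0 <- config$liquid$initial_conc[[fit_species]]   # model clock starts at 0
  fit <- tryCatch(
    fit_global_kla(ts$time, cl, sat_conc = sat, c0 = c0),
    error = function(e) NULL)
  res$kla_fit <- if (is.null(fit)) NA_real_ else fit$kla
  res$kla_direct <- res$kla[[fit_species]]
  res
}

#' Uniform consumption/production reaction scenario
#'
#' Superimposes a constant-rate reaction pair (by default oxygen consumed at
#' 1e-5 mol/(L s), carbon dioxide produced at the same rate) on the
#' gassing-in physics. Dissolved oxygen converges to `S c_b - R/kla`, the
#' produced species to `R/kla`, and at steady state the gas/fluid transfer
#' rate balances the reaction rate for both. Steady-state predictions from
#' these closed forms (evaluated with the run's own measured kla and mean
#' bubble gas concentration) are attached as `predicted_steady`.
#'
#' @param config A [run_config()] with `reaction$mode == "uniform"`.
#' @return A `scenario_result` with `predicted_steady` (named, mol/L) and
#'   `xi` (consumption/transfer ratio for consumed species).
#' @export
simulate_uniform_reaction <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$reaction$mode != "uniform")
    stop("simulate_uniform_reaction requires reaction mode 'uniform'")
  res <- run_scenario(config)
  rates <- config$reaction$rates                  # mol/(L s), signed
  S <- vapply(config$species, `[[`, 0, "solubility")
  pred <- res$steady_state * NA
  xi <- pred
  for (s in names(rates)) {
    kla <- res$kla[[s]]
    if (!is.finite(kla) || kla <= 0) next
    # equilibrium against the realised bubble composition: S * <c_g>
    # (transfer-weighted); reduces to S * c_b when bubbles keep the sparge
    # composition, recovering the pure closed forms
    sat_s <- if (is.finite(res$mean_gas_conc[[s]])) {
      S[[s]] * res$mean_gas_conc[[s]] / 1000      # mol/L
    } else res$saturation[[s]]
    if (rates[[s]] < 0) {
      pred[s] <- steady_state_dissolved(sat_s, -rates[[s]], kla, "consumed")
      xi[s] <- xi_ratio(-rates[[s]], sat_s, kla)
    } else {
      pred[s] <- sat_s + steady_state_dissolved(sat_s, rates[[s]], kla,
                                                "produced")
    }
  }
  res$predicted_steady <- pred
  res$xi <- xi
  res
}

#' Gluconic acid fermentation scenario
#'
#' Couples interphase oxygen transfer to the Contois fermentation system.
#' The product growth rate `dP/dt` is reported as the slope of a linear fit
#' of the product concentration over an early window (default: the first
#' 2 h, or the whole run if shorter).
#'
#' @param config A [run_config()] with `reaction$mode == "contois"`.
#' @param dpdt_window Window for the product-slope fit, h. Default 2.
#' @return A `scenario_result` with `dPdt_gLh`, `xi` (evaluated at the final
#'   state), and `kinetic_timeseries`.
#' @export
simulate_fermentation <- function(config, dpdt_window = 2) {
  stopifnot(inherits(config, "run_config"))
  if (config$reaction$mode != "contois")
    stop("simulate_fermentation requires reaction mode 'contois'")
  res <- run_scenario(config)
  kin <- res$kinetic_timeseries
  t_h <- kin$time / 3600
  w <- t_h <= min(dpdt_window, max(t_h))
  res$dPdt_gLh <- unname(stats::coef(stats::lm(kin$P[w] ~ t_h[w]))[2L])
  M_o2 <- config$species[["O2"]]$molar_mass
  sat_gL <- mol_m3_to_g_L(res$saturation[["O2"]] * 1000, M_o2)
  kla_s <- if (!is.null(config$mass_transfer$prescribed_kla))
    config$mass_transfer$prescribed_kla else res$kla[["O2"]]
  final <- biokinetic_state(X = kin$X[nrow(kin)], P = kin$P[nrow(kin)],
                            S = kin$S[nrow(kin)], O2 = kin$O2[nrow(kin)])
  res$xi <- xi_ratio_contois(final, config$reaction$params, sat_gL,
                             kla_s * 3600)
  res
}

#' Fast/slow timescales of the dissolved-oxygen trajectory
#'
#' In a fermentation the dissolved-oxygen history has two phases: a fast
#' settle from the initial value to the transfer/consumption quasi-equilibrium
#' (timescale ~ 1/kla) and a slow decline as growing biomass raises the oxygen
#' demand (timescale ~ 1/mu). Fits an exponential to the early phase and a
#' linear drift to the late phase and returns both timescales.
#'
#' @param times Sample times, s.
#' @param o2 Dissolved oxygen series (any unit).
#' @param settle_fraction Fraction of the run treated as the fast phase for
#'   fitting (default 0.1).
#' @return List with `tau_fast` (s), `tau_slow` (s), and `ratio`.
#' @export
dissolved_o2_timescales <- function(times, o2, settle_fraction = 0.1) {
  stopifnot(length(times) == length(o2), length(o2) >= 10)
  t_max <- max(times)
  early <- times <= settle_fraction * t_max
  df <- data.frame(t = times[early], c = o2[early])
  c0 <- df$c[1L]
  t_win <- max(df$t)
  fit <- NULL
  for (tau0 in t_win / c(3, 10, 30, 100)) {   # start ladder: nls is local
    fit <- tryCatch(
      minpack.lm::nlsLM(c ~ ceq + (c0 - ceq) * exp(-t / tau),
                        data = df,
                        start = list(ceq = df$c[nrow(df)], tau = tau0),
                        lower = c(0, 1e-9)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("could not fit the fast settling phase")
  tau_fast <- stats::coef(fit)[["tau"]]
  late <- times >= 0.5 * t_max
  lfit <- stats::lm(o2[late] ~ times[late])
  slope <- stats::coef(lfit)[[2L]]
  tau_slow <- abs(mean(o2[late]) / slope)
  list(tau_fast = tau_fast, tau_slow = tau_slow, ratio = tau_slow / tau_fast)
}

#' Peak fraction of sparged gas transferred to the liquid
#'
#' The transfer rate is maximal at zero dissolved concentration, where it is
#' `kla * V_l * sat`; dividing by the sparged molar inflow bounds the fraction
#' of incoming gas that can dissolve during the transient.
#'
#' @param kla Volumetric mass transfer coefficient, 1/s.
#' @param liquid_volume Liquid volume, L.
#' @param sat Saturation concentration, mol/L.
#' @param molar_inflow Sparged molar inflow, mol/s (> 0).
#' @return Dimensionless fraction.
#' @examples
#' peak_transfer_fraction(0.014, 3.9, 0.00143, 8 / 22.4 / 60)
#' @export
peak_transfer_fraction <- function(kla, liquid_volume, sat, molar_inflow) {
  if (molar_inflow <= 0) stop("molar_inflow must be > 0")
  kla * liquid_volume * sat / molar_inflow
}

#' Run a matrix of operating scenarios
#'
#' Executes each configuration and assembles a comparison table of operating
#' conditions and key outputs: impeller speed, gas, flow rate, kla (1/h),
#' mean bubble diameter (mm), time-average bubble count, oxygen saturation
#' concentration (g/L), and (for fermentation scenarios) the product growth
#' rate dP/dt (g/L/h). A failing scenario is reported in its row; the others
#' continue.
#'
#' @param configs Named list of [run_config()] objects (>= 1).
#' @return List with `table` (data frame) and `results` (list of
#'   `scenario_result` or error messages).
#' @export
run_scenario_matrix <- function(configs) {
  stopifnot(is.list(configs), length(configs) >= 1)
  if (is.null(names(configs)))
    names(configs) <- paste0("case_", seq_along(configs))
  results <- lapply(configs, function(cfg) {
    tryCatch(switch(cfg$reaction$mode,
                    none = simulate_saturation(cfg),
                    uniform = simulate_uniform_reaction(cfg),
                    contois = simulate_fermentation(cfg)),
             error = function(e) conditionMessage(e))
  })
  rows <- Map(function(nm, cfg, res) {
    gas <- paste(sprintf("%s:%.2g", names(cfg$sparge$gas$mole_fractions),
                         cfg$sparge$gas$mole_fractions), collapse = " ")
    sat_gL <- if ("O2" %in% names(cfg$species)) {
      saturation_concentration(cfg$sparge$gas, cfg$species[["O2"]])$g_per_L
    } else NA_real_
    if (is.character(res)) {
      data.frame(case = nm, rpm = cfg$geometry$impeller_speed, gas = gas,
                 flow_slpm = cfg$sparge$flow_slpm, kla_hr = NA_real_,
                 mean_d_mm = NA_real_, n_bubbles = NA_real_,
                 sat_O2_gL = sat_gL, dPdt_gLh = NA_real_, error = res)
    } else {
      data.frame(case = nm, rpm = cfg$geometry$impeller_speed, gas = gas,
                 flow_slpm = cfg$sparge$flow_slpm,
                 kla_hr = unname(res$kla["O2"] * 3600),
                 mean_d_mm = res$bubble_stats$mean_diameter_mm,
                 n_bubbles = res$bubble_stats$n_bubbles,
                 sat_O2_gL = sat_gL,
                 dPdt_gLh = res$dPdt_gLh %||% NA_real_, error = NA_character_)
    }
  }, names(configs), configs, results)
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       results = results)
}
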