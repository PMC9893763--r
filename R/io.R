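# Configuration parsing/validation and file outputs.
#
# Run configurations are YAML with blocks: run, geometry, species, sparge,
# flow, reaction, mass_transfer, liquid, numerics, spatial. Missing values
# fall back to documented defaults (echoed to the run log), unknown keys are
# rejected.

known_species_defaults <- list(
  O2 = list(solubility = 0.032, molar_mass = 32),
  CO2 = list(solubility = 0.83, molar_mass = 44.01),
  N2 = list(solubility = 0.015, molar_mass = 28.01))

config_blocks <- c("run", "geometry", "species", "sparge", "flow",
                   "reaction", "mass_transfer", "liquid", "numerics",
                   "spatial")

check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")))
}

#' Load and validate a run configuration
#'
#' Parses a YAML configuration into a [run_config()], applying defaults
#' where values are omitted and echoing every applied default to the run log
#' (via `message()`; suppress with `quiet = TRUE`). Dissolved-gas defaults:
#' solubility 0.032 (O2), 0.83 (CO2), 0.015 (N2); diffusivity 1e-9 m^2/s;
#' molar volume 22.4 L/mol; injected bubble diameter 2 mm. Unknown keys,
#' duplicate or undefined species, and contradictory settings (a prescribed
#' kla together with spatially resolved transfer) are rejected with
#' descriptive errors.
#'
#' @param source Path to a YAML file, or a YAML string.
#' @param quiet Suppress the default-provenance log. Default `FALSE`.
#' @return A [run_config()]; the run mode (if given) is attached as
#'   attribute `"mode"`.
#' @export
load_run_config <- function(source, quiet = FALSE) {
  raw <- if (file.exists(source)) yaml::read_yaml(source) else
    yaml::yaml.load(source)
  if (!is.list(raw)) stop("configuration must be a YAML mapping")
  check_keys(raw, config_blocks, "configuration")
  log_default <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  gb <- raw$geometry %||% list()
  check_keys(gb, names(formals(reactor_geometry)), "geometry")
  geometry <- do.call(reactor_geometry, gb)
  for (f in setdiff(names(formals(reactor_geometry)), names(gb)))
    log_default("default applied: geometry$%s = %s", f, format(geometry[[f]]))

  if (is.null(raw$species) || !length(raw$species))
    stop("configuration must define at least one species")
  species <- lapply(raw$species, function(s) {
    check_keys(s, c("name", "solubility", "molar_mass", "diffusivity",
                    "gas_molar_volume"), "species entry")
    if (is.null(s$name)) stop("every species needs a name")
    kd <- known_species_defaults[[s$name]]
    if (is.null(s$solubility)) {
      if (is.null(kd)) stop(sprintf(
        "species '%s' has no solubility and no built-in default", s$name))
      s$solubility <- kd$solubility
      log_default("default applied: %s solubility = %g", s$name, s$solubility)
    }
    if (is.null(s$molar_mass)) {
      if (is.null(kd)) stop(sprintf(
        "species '%s' has no molar_mass and no built-in default", s$name))
      s$molar_mass <- kd$molar_mass
      log_default("default applied: %s molar_mass = %g g/mol", s$name,
                  s$molar_mass)
    }
    if (is.null(s$diffusivity)) {
      s$diffusivity <- 1e-9
      log_default("default applied: %s diffusivity = 1e-9 m^2/s", s$name)
    }
    if (is.null(s$gas_molar_volume)) {
      s$gas_molar_volume <- 22.4
      log_default("default applied: %s gas_molar_volume = 22.4 L/mol", s$name)
    }
    do.call(species_spec, s)
  })
  sp_names <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(sp_names))
    stop("duplicate species name: ",
         sp_names[duplicated(sp_names)][1L])

  sb <- raw$sparge %||% stop("configuration must define a sparge block")
  check_keys(sb, c("gas", "flow_slpm", "bubble_diameter", "parcel_weight"),
             "sparge")
  if (is.null(sb$gas)) stop("sparge needs a gas composition")
  gas <- gas_mixture(unlist(sb$gas))
  if (is.null(sb$flow_slpm)) stop("sparge needs flow_slpm")
  if (is.null(sb$bubble_diameter))
    log_default("default applied: sparge bubble_diameter = 0.002 m")
  sparge <- list(gas = gas, flow_slpm = sb$flow_slpm,
                 bubble_diameter = sb$bubble_diameter %||% 2e-3,
                 parcel_weight = sb$parcel_weight %||% 400)

  fb <- raw$flow %||% list()
  check_keys(fb, c("kind", "mean_epsilon", "nu", "velocity"), "flow")
  flow <- list(kind = fb$kind %||% "synthetic",
               mean_epsilon = fb$mean_epsilon,
               nu = fb$nu %||% 1e-6,
               velocity = unlist(fb$velocity) %||% NULL)

  rb <- raw$reaction %||% list(mode = "none")
  check_keys(rb, c("mode", "rates", "contois", "initial_state"), "reaction")
  reaction <- list(mode = rb$mode %||% "none")
  if (reaction$mode == "uniform") reaction$rates <- unlist(rb$rates)
  if (reaction$mode == "contois") {
    if (is.null(rb$contois))
      stop("contois reaction requires a 'contois' parameter block")
    reaction$params <- do.call(contois_params, rb$contois)
    if (is.null(rb$initial_state))
      stop("contois reaction requires initial_state {X, P, S, O2}")
    reaction$initial_state <- do.call(biokinetic_state, rb$initial_state)
  }

  mb <- raw$mass_transfer %||% list()
  check_keys(mb, c("prescribed_kla", "tau"), "mass_transfer")
  mass_transfer <- list(prescribed_kla = mb$prescribed_kla,
                        tau = mb$tau %||% 5)

  spat <- raw$spatial %||% list()
  check_keys(spat, c("enabled", "n"), "spatial")
  if (isTRUE(spat$enabled) && !is.null(mass_transfer$prescribed_kla))
    stop(paste("contradictory settings: a prescribed kla cannot be combined",
               "with spatially resolved transfer (spatial$enabled)"))

  lb <- raw$liquid %||% list()
  check_keys(lb, c("initial_conc", "rho"), "liquid")
  liquid <- list(initial_conc = unlist(lb$initial_conc), rho = lb$rho %||% 1000)

  nb <- raw$numerics %||% list()
  check_keys(nb, c("duration", "dt", "courant_number", "seed",
                   "output_interval"), "numerics")
  if (is.null(nb$duration)) stop("numerics needs a duration (s)")
  numerics <- simulation_config(
    duration = nb$duration, dt = nb$dt %||% 0.005,
    courant_number = nb$courant_number %||% 0.1,
    rng_seed = nb$seed %||% 1L,
    output_interval = nb$output_interval %||% 1)
  if (is.null(nb$dt)) log_default("default applied: numerics$dt = 0.005 s")
  log_default("run seed: %d", numerics$rng_seed)

  cfg <- run_config(geometry = geometry, species = species, sparge = sparge,
                    flow = flow, reaction = reaction,
                    mass_transfer = mass_transfer, liquid = liquid,
                    numerics = numerics)
  attr(cfg, "mode") <- (raw$run %||% list())$mode
  cfg
}

#' Write scenario outputs to a directory
#'
#' Emits `timeseries.csv`, `ledger.csv`, `bubbles.csv` (final parcel
#' snapshot), `summary.txt` (fitted/measured kla, steady states, predictions,
#' xi, dP/dt, seed) and `config_echo.yaml`. Outputs are deterministic: the
#' same configuration and seed reproduce the files byte for byte.
#'
#' @param result A `scenario_result` from [run_scenario()] or a wrapper.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(result, dir) {
  stopifnot(inherits(result, "scenario_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = NA),
                     p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  w(result$timeseries, "timeseries.csv")
  led <- as.data.frame(result$ledger)
  # per-time sum check: injection - removal - transfer - inflight
  led$balance <- led$injection_cum - led$removal_cum - led$transfer_cum -
    led$inflight
  w(led, "ledger.csv")

  pop <- result$final_population
  bub <- if (n_bubbles(pop) > 0) {
    data.frame(id = pop$id, x = pop$pos[, 1], y = pop$pos[, 2],
               z = pop$pos[, 3], diameter_mm = pop$diameter * 1000,
               weight = pop$weight, pop$moles, check.names = FALSE)
  } else data.frame(id = integer(0))
  w(bub, "bubbles.csv")

  sm <- file.path(dir, "summary.txt")
  con <- file(sm, "w")
  on.exit(close(con))
  cat(sprintf("seed: %d\n", result$config$numerics$rng_seed), file = con)
  cat(sprintf("duration_s: %g\n", result$config$numerics$duration), file = con)
  for (s in names(result$steady_state)) {
    cat(sprintf("steady_state_%s_mol_per_L: %.8g\n", s,
                result$steady_state[[s]]), file = con)
    cat(sprintf("saturation_%s_mol_per_L: %.8g\n", s,
                result$saturation[[s]]), file = con)
    cat(sprintf("kla_measured_%s_per_s: %.8g\n", s, result$kla[[s]]),
        file = con)
  }
  if (!is.null(result$kla_fit))
    cat(sprintf("kla_fit_per_s: %.8g\n", result$kla_fit), file = con)
  if (!is.null(result$predicted_steady))
    for (s in names(result$predicted_steady))
      cat(sprintf("predicted_steady_%s_mol_per_L: %.8g\n", s,
                  result$predicted_steady[[s]]), file = con)
  if (!is.null(result$xi)) {
    xv <- result$xi
    if (length(xv) > 1) {
      for (s in names(xv)) if (is.finite(xv[[s]]))
        cat(sprintf("xi_%s: %.8g\n", s, xv[[s]]), file = con)
    } else cat(sprintf("xi: %.8g\n", xv), file = con)
  }
  if (!is.null(result$dPdt_gLh))
    cat(sprintf("dPdt_g_per_L_h: %.8g\n", result$dPdt_gLh), file = con)
  paths <- c(paths, sm)

  if (!is.null(result$kinetic_timeseries))
    w(result$kinetic_timeseries, "kinetics.csv")

  cfgp <- file.path(dir, "config_echo.yaml")
  yaml::write_yaml(config_as_list(result$config), cfgp)
  paths <- c(paths, cfgp)
  invisible(paths)
}

config_as_list <- function(cfg) {
  list(
    geometry = unclass(cfg$geometry),
    species = lapply(unname(cfg$species), unclass),
    sparge = list(gas = as.list(cfg$sparge$gas$mole_fractions),
                  flow_slpm = cfg$sparge$flow_slpm,
                  bubble_diameter = cfg$sparge$bubble_diameter,
                  parcel_weight = cfg$sparge$parcel_weight),
    flow = cfg$flow[!vapply(cfg$flow, is.null, TRUE)],
    reaction = list(mode = cfg$reaction$mode),
    mass_transfer = cfg$mass_transfer[!vapply(cfg$mass_transfer, is.null, TRUE)],
    numerics = unclass(cfg$numerics))
}
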