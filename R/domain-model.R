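# Core domain types and gas-phase composition arithmetic.
#
# Unit conventions: strictly SI internally (m, s, mol/m^3). Litre-based units
# (g/L, mol/L, L/mol, SLPM) appear only at constructor/report interfaces and
# are converted on entry. All gases default to a molar volume of 22.4 L/mol
# and a density of 1.2 kg/m^3; both can be overridden per species.

#' Define a chemical species
#'
#' A species carries the transport and equilibrium properties needed for
#' interphase mass transfer: the liquid-phase diffusion coefficient, the
#' dimensionless solubility (equilibrium ratio of dissolved to gas-phase
#' concentration, Henry partition in concentration form), the molar mass, and
#' the molar volume it occupies in the gas phase.
#'
#' @param name Species identifier, e.g. `"O2"`.
#' @param diffusivity Liquid-phase diffusion coefficient, m^2/s. Default
#'   `1e-9` m^2/s, representative of dissolved gases in water.
#' @param solubility Dimensionless solubility `S` (dissolved/gas concentration
#'   ratio at equilibrium). Must be >= 0.
#' @param molar_mass Molar mass, g/mol.
#' @param gas_molar_volume Molar volume in the gas phase, L/mol. Default 22.4.
#'
#' @return An object of class `species_spec`.
#' @examples
#' oxygen <- species_spec("O2", solubility = 0.032, molar_mass = 32)
#' @export
species_spec <- function(name, diffusivity = 1e-9, solubility,
                         molar_mass, gas_molar_volume = 22.4) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(diffusivity) || diffusivity <= 0)
    stop("diffusivity must be > 0 (m^2/s)")
  if (!is.numeric(solubility) || solubility < 0)
    stop("solubility must be >= 0 (dimensionless)")
  if (!is.numeric(molar_mass) || molar_mass <= 0)
    stop("molar_mass must be > 0 (g/mol)")
  if (!is.numeric(gas_molar_volume) || gas_molar_volume <= 0)
    stop("gas_molar_volume must be > 0 (L/mol)")
  structure(
    list(name = name, diffusivity = diffusivity, solubility = solubility,
         molar_mass = molar_mass, gas_molar_volume = gas_molar_volume),
    class = "species_spec")
}

#' @export
print.species_spec <- function(x, ...) {
  cat(sprintf(
    "<species_spec> %s: D = %.3g m^2/s, S = %.4g, M = %.4g g/mol, Vm = %.4g L/mol\n",
    x$name, x$diffusivity, x$solubility, x$molar_mass, x$gas_molar_volume))
  invisible(x)
}

#' Define a gas mixture by mole fractions
#'
#' @param mole_fractions Named numeric vector of mole fractions; names are
#'   species names. Must sum to 1 within 1e-12 and lie in `[0, 1]`.
#' @param density Gas density, kg/m^3. Default 1.2.
#'
#' @return An object of class `gas_mixture`.
#' @examples
#' air <- gas_mixture(c(O2 = 0.21, N2 = 0.79))
#' pure_o2 <- gas_mixture(c(O2 = 1))
#' @export
gas_mixture <- function(mole_fractions, density = 1.2) {
  if (is.null(names(mole_fractions)) || any(!nzchar(names(mole_fractions))))
    stop("mole_fractions must be a named numeric vector")
  if (anyDuplicated(names(mole_fractions)))
    stop("duplicate species name in mixture")
  if (any(mole_fractions < 0) || any(mole_fractions > 1))
    stop("mole fractions must lie in [0, 1]")
  if (abs(sum(mole_fractions) - 1) > 1e-12)
    stop(sprintf("mole fractions must sum to 1 (got %.15g)",
                 sum(mole_fractions)))
  if (density <= 0) stop("density must be > 0 (kg/m^3)")
  structure(list(mole_fractions = mole_fractions, density = density),
            class = "gas_mixture")
}

#' @export
print.gas_mixture <- function(x, ...) {
  comp <- paste(sprintf("%s=%.3g", names(x$mole_fractions), x$mole_fractions),
                collapse = ", ")
  cat(sprintf("<gas_mixture> %s (density %.3g kg/m^3)\n", comp, x$density))
  invisible(x)
}

mixture_fraction <- function(mix, sp) {
  stopifnot(inherits(mix, "gas_mixture"), inherits(sp, "species_spec"))
  if (!sp$name %in% names(mix$mole_fractions))
    stop(sprintf("species '%s' absent from mixture (has: %s)", sp$name,
                 paste(names(mix$mole_fractions), collapse = ", ")))
  unname(mix$mole_fractions[[sp$name]])
}

#' Gas-phase concentration of a species in a mixture
#'
#' Converts a mole fraction to a molar concentration via the ideal gas molar
#' volume: `c_g = y / Vm`. For air at 22.4 L/mol the oxygen concentration is
#' 0.21/22.4 mol/L = 9.375 mol/m^3 = 0.3 g/L.
#'
#' @param mix A [gas_mixture()].
#' @param sp A [species_spec()]; must be present in the mixture.
#'
#' @return List with components `mol_per_m3` and `g_per_L`.
#' @examples
#' o2 <- species_spec("O2", solubility = 0.032, molar_mass = 32)
#' gas_phase_concentration(gas_mixture(c(O2 = 0.21, N2 = 0.79)), o2)
#' @export
gas_phase_concentration <- function(mix, sp) {
  y <- mixture_fraction(mix, sp)
  mol_per_L <- y / sp$gas_molar_volume
  list(mol_per_m3 = mol_per_L * 1000, g_per_L = mol_per_L * sp$molar_mass)
}

#' Saturation (equilibrium dissolved) concentration of a sparged species
#'
#' The dissolved concentration in equilibrium with the gas phase is
#' `S * c_g`, the dimensionless solubility times the gas-phase concentration.
#' For pure oxygen at S = 0.032 and 22.4 L/mol this is 0.00143 mol/L
#' (0.0457 g/L); for air, 0.0096 g/L.
#'
#' @inheritParams gas_phase_concentration
#'
#' @return List with components `mol_per_L` and `g_per_L`.
#' @export
saturation_concentration <- function(mix, sp) {
  cg <- gas_phase_concentration(mix, sp)
  list(mol_per_L = sp$solubility * cg$mol_per_m3 / 1000,
       g_per_L = sp$solubility * cg$g_per_L)
}

#' Molar flow of one species through the sparger
#'
#' Converts a standard-litres-per-minute gas flow to a species molar flow:
#' `flow * y / (Vm * 60)` mol/s. 8 SLPM of pure oxygen at 22.4 L/mol is
#' 5.95e-3 mol/s.
#'
#' @param flow_slpm Total gas flow, standard L/min. Must be >= 0.
#' @inheritParams gas_phase_concentration
#'
#' @return Molar flow, mol/s.
#' @export
sparge_molar_flow <- function(flow_slpm, mix, sp) {
  if (!is.numeric(flow_slpm) || length(flow_slpm) != 1L || flow_slpm < 0)
    stop("flow_slpm must be a single number >= 0")
  flow_slpm * mixture_fraction(mix, sp) / (sp$gas_molar_volume * 60)
}

#' Reactor geometry
#'
#' Defaults describe a lab-scale baffled flat-bottomed vessel: a 0.185 m
#' diameter tank filled to 0.185 m, agitated by a 0.061 m Rushton impeller at
#' an off-bottom clearance equal to its diameter, gassed through a 0.05 m ring
#' sparger between the impeller and the bottom. The working liquid volume is
#' specified independently of the fill geometry (the cylinder with these
#' dimensions holds ~4.97 L; the nominal working volume used in all
#' volume-based balances is 3.9 L).
#'
#' @param tank_diameter Tank inner diameter, m.
#' @param liquid_height Ungassed liquid level, m.
#' @param liquid_volume Working liquid volume, L.
#' @param impeller_diameter Impeller diameter, m. Must be < `tank_diameter`.
#' @param off_bottom_clearance Impeller centre height above the bottom, m.
#' @param sparge_ring_diameter Ring sparger diameter, m.
#' @param sparge_height Height of the sparge ring above the bottom, m.
#' @param baffle_width Baffle width, m.
#' @param impeller_speed Impeller speed, RPM.
#'
#' @return An object of class `reactor_geometry`.
#' @export
reactor_geometry <- function(tank_diameter = 0.185,
                             liquid_height = 0.185,
                             liquid_volume = 3.9,
                             impeller_diameter = 0.061,
                             off_bottom_clearance = 0.061,
                             sparge_ring_diameter = 0.05,
                             sparge_height = 0.04,
                             baffle_width = 0.01,
                             impeller_speed = 300) {
  lens <- c(tank_diameter, liquid_height, liquid_volume, impeller_diameter,
            off_bottom_clearance, sparge_ring_diameter, sparge_height,
            baffle_width)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all geometric dimensions must be positive")
  if (impeller_diameter >= tank_diameter)
    stop("impeller_diameter must be smaller than tank_diameter")
  if (impeller_speed <= 0) stop("impeller_speed must be > 0 (RPM)")
  structure(
    list(tank_diameter = tank_diameter, liquid_height = liquid_height,
         liquid_volume = liquid_volume, impeller_diameter = impeller_diameter,
         off_bottom_clearance = off_bottom_clearance,
         sparge_ring_diameter = sparge_ring_diameter,
         sparge_height = sparge_height, baffle_width = baffle_width,
         impeller_speed = impeller_speed),
    class = "reactor_geometry")
}

#' @export
print.reactor_geometry <- function(x, ...) {
  cat(sprintf(paste0(
    "<reactor_geometry> T = %.3g m, fill = %.3g m (%.3g L), D_imp = %.3g m",
    " @ %g RPM (tip %.3g m/s)\n"),
    x$tank_diameter, x$liquid_height, x$liquid_volume, x$impeller_diameter,
    x$impeller_speed, tip_speed(x)))
  invisible(x)
}

#' Impeller tip speed
#'
#' `pi * D * N` with N in rev/s. The default geometry at 300 RPM gives
#' 0.958 m/s.
#'
#' @param geom A [reactor_geometry()].
#' @return Tip speed, m/s.
#' @export
tip_speed <- function(geom) {
  stopifnot(inherits(geom, "reactor_geometry"))
  pi * geom$impeller_diameter * geom$impeller_speed / 60
}

#' Simulation run controls
#'
#' @param duration Simulated time, s.
#' @param dt Global timestep, s. All physics (bubble motion, transfer,
#'   reaction) share this step; the bubble integrator may sub-step internally.
#' @param courant_number Courant number used when `dt` is derived from a grid
#'   spacing via [timestep_from_courant()]; must lie strictly in (0, 1).
#' @param rng_seed Integer seed; every stochastic element (injection position,
#'   parcel rounding) draws from one generator seeded with this value.
#' @param output_interval Sampling interval for time series, s.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(duration, dt = 0.005, courant_number = 0.1,
                              rng_seed = 1L, output_interval = 1) {
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0 (s)")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0 (s)")
  if (courant_number <= 0 || courant_number >= 1)
    stop("courant_number must lie strictly in (0, 1) (CFL)")
  if (output_interval < dt) output_interval <- dt
  structure(
    list(duration = duration, dt = dt, courant_number = courant_number,
         rng_seed = as.integer(rng_seed), output_interval = output_interval),
    class = "simulation_config")
}

# mol/m^3 <-> g/L for one species: g/L = mol/m^3 * (g/mol) / 1000
mol_m3_to_g_L <- function(conc, molar_mass) conc * molar_mass / 1000
g_L_to_mol_m3 <- function(conc, molar_mass) conc * 1000 / molar_mass
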