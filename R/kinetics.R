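# Reaction kinetics: constant-rate (uniform) source terms, Contois-type
# fermentation of gluconic acid by Aspergillus niger, a classical RK4 local
# integrator, the biomass-viscosity coupling, analytic steady-state
# predictors for dissolved gases, and the consumption/transfer ratio xi.
#
# Kinetic quantities are expressed in g/L and hours; dissolved oxygen is
# shared with the mass-transfer side through explicit mol <-> g conversion
# (molar mass 32 g/mol for O2).

#' Uniform (constant) volumetric reaction rates
#'
#' Signed rates in mol/(L s) per species, e.g. oxygen consumed at the same
#' constant rate at which carbon dioxide is produced:
#' `uniform_rates(c(O2 = -1e-5, CO2 = 1e-5))`.
#'
#' @param rates Named numeric vector, mol/(L s); positive = production.
#' @return An object of class `uniform_rates`.
#' @export
uniform_rates <- function(rates) {
  if (is.null(names(rates))) stop("rates must be named by species")
  if (any(!is.finite(rates))) stop("rates must be finite")
  structure(list(rates = rates), class = "uniform_rates")
}

#' Contois kinetic parameters
#'
#' Parameters of the four-component gluconic acid fermentation model: specific
#' growth rate `mu = mu_max * [S/(Ks' X + S)] * [O2/(Ko' X + O2)]` (Contois
#' form: half-saturation scales with biomass) and linear growth-associated /
#' maintenance laws for product, substrate and oxygen:
#' `R_X = mu X`, `R_P = (alpha mu + beta) X`, `R_S = -(gamma mu + lambda) X`,
#' `R_O2 = -(delta mu + phi) X`.
#'
#' @param mu_max Maximum specific growth rate, 1/h (> 0).
#' @param Ks_prime Contois substrate constant, g substrate / g biomass (> 0).
#' @param Ko_prime Contois oxygen constant, g O2 / g biomass (> 0).
#' @param alpha Growth-associated product yield, g P / g X.
#' @param beta Non-growth product formation, g P / (g X h).
#' @param gamma Growth-associated substrate use, g S / g X.
#' @param lambda Maintenance substrate use, g S / (g X h).
#' @param delta Growth-associated oxygen use, g O2 / g X.
#' @param phi Maintenance oxygen use, g O2 / (g X h).
#' @return An object of class `contois_params`.
#' @export
contois_params <- function(mu_max, Ks_prime, Ko_prime, alpha, beta,
                           gamma, lambda, delta, phi) {
  if (mu_max <= 0) stop("mu_max must be > 0 (1/h)")
  if (Ks_prime <= 0 || Ko_prime <= 0)
    stop("Ks_prime and Ko_prime must be > 0")
  if (alpha < 0 || gamma < 0 || delta < 0)
    stop("alpha, gamma and delta must be >= 0")
  structure(
    list(mu_max = mu_max, Ks_prime = Ks_prime, Ko_prime = Ko_prime,
         alpha = alpha, beta = beta, gamma = gamma, lambda = lambda,
         delta = delta, phi = phi),
    class = "contois_params")
}

#' Illustrative Contois parameter set
#'
#' The fermentation model requires experimentally fitted coefficients that
#' must be supplied by the user for any quantitative study. This set is
#' ILLUSTRATIVE ONLY: values chosen to be physiologically plausible for an
#' aerobic filamentous fungus on glucose (growth timescale of hours, oxygen
#' maintenance well below the transfer capacity of a stirred lab vessel). It
#' exists so examples and tests have a definite, documented configuration.
#'
#' @return A [contois_params()] object.
#' @export
illustrative_contois_params <- function() {
  contois_params(mu_max = 0.15, Ks_prime = 15, Ko_prime = 0.001,
                 alpha = 2.5, beta = 0.9, gamma = 2.2, lambda = 0.3,
                 delta = 0.4, phi = 0.08)
}

#' Biokinetic state
#'
#' Concentrations (g/L, all >= 0) of biomass `X`, product (gluconic acid) `P`,
#' substrate `S`, and dissolved oxygen `O2`.
#'
#' @param X,P,S,O2 Concentrations, g/L.
#' @return An object of class `biokinetic_state` (named numeric vector).
#' @export
biokinetic_state <- function(X, P = 0, S, O2) {
  v <- c(X = X, P = P, S = S, O2 = O2)
  if (any(!is.finite(v)) || any(v < 0))
    stop("all concentrations must be finite and >= 0 (g/L)")
  structure(v, class = "biokinetic_state")
}

#' Contois specific growth rate
#'
#' `mu = mu_max * [C_S / (Ks' C_X + C_S)] * [C_O2 / (Ko' C_X + C_O2)]`,
#' 1/h. Degenerate 0/0 factors (species exhausted with no biomass) resolve
#' to 0.
#'
#' @param state A [biokinetic_state()] (or named vector with `X`, `S`, `O2`).
#' @param p A [contois_params()].
#' @return Specific growth rate, 1/h.
#' @export
contois_mu <- function(state, p) {
  den_s <- p$Ks_prime * state[["X"]] + state[["S"]]
  den_o <- p$Ko_prime * state[["X"]] + state[["O2"]]
  f_s <- if (den_s > 0) state[["S"]] / den_s else 0
  f_o <- if (den_o > 0) state[["O2"]] / den_o else 0
  p$mu_max * f_s * f_o
}

#' Contois reaction rates
#'
#' @inheritParams contois_mu
#' @return Named vector of rates (g/L/h) for `X`, `P`, `S`, `O2`; biomass and
#'   product rates are non-negative, substrate and oxygen rates non-positive
#'   for non-negative parameters.
#' @export
contois_rates <- function(state, p) {
  mu <- contois_mu(state, p)
  x <- state[["X"]]
  c(X = mu * x,
    P = (p$alpha * mu + p$beta) * x,
    S = -(p$gamma * mu + p$lambda) * x,
    O2 = -(p$delta * mu + p$phi) * x)
}

#' One classical RK4 step of the fermentation system
#'
#' Advances `(X, P, S, O2)` by one fourth-order Runge-Kutta step of the
#' Contois system plus an external dissolved-oxygen source (interphase mass
#' transfer). The source may be a constant (g/L/h, explicit coupling to a
#' transfer rate evaluated outside) or a function `state -> g/L/h`, in which
#' case it is re-evaluated inside each RK4 stage (tight coupling, e.g.
#' `kla * (sat - O2)` for a prescribed transfer coefficient).
#'
#' @inheritParams contois_mu
#' @param dissolved_O2_source Constant source (g/L/h) or function of state.
#' @param dt Timestep, h (> 0).
#' @return The advanced state (class `biokinetic_state`). Negative
#'   concentrations produced by an overshooting step are clipped to zero with
#'   a warning.
#' @export
rk4_step <- function(state, p, dissolved_O2_source = 0, dt) {
  stopifnot(dt > 0)
  src <- if (is.function(dissolved_O2_source)) dissolved_O2_source else
    function(s) dissolved_O2_source
  deriv <- function(s) {
    r <- contois_rates(s, p)
    r[["O2"]] <- r[["O2"]] + src(s)
    r
  }
  y <- unclass(state)
  k1 <- deriv(y)
  k2 <- deriv(y + dt / 2 * k1)
  k3 <- deriv(y + dt / 2 * k2)
  k4 <- deriv(y + dt * k3)
  y1 <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(y1 < 0)) {
    warning("rk4_step: negative concentration clipped to 0")
    y1[y1 < 0] <- 0
  }
  structure(y1, class = "biokinetic_state")
}

#' Broth viscosity as a function of biomass concentration
#'
#' `nu = nu_ref * (1 + C_X)^exponent` with `C_X` in g/L, reducing to the
#' reference (water) viscosity in clean broth. NOTE: the functional form of
#' this correlation is configurable (`exponent`, or replace wholesale); the
#' default exponent is 2.26.
#'
#' @param nu_ref Reference (water) kinematic viscosity, m^2/s.
#' @param C_X Biomass concentration, g/L (>= 0); vectorised.
#' @param exponent Power-law exponent, default 2.26.
#' @return Kinematic viscosity, m^2/s.
#' @export
biomass_viscosity <- function(nu_ref, C_X, exponent = 2.26) {
  if (any(C_X < 0)) stop("C_X must be >= 0")
  nu_ref * (1 + C_X)^exponent
}

#' Steady-state dissolved concentration under constant reaction
#'
#' For a species consumed at constant volumetric rate `R` and supplied by
#' transfer from bubbles at saturation `sat`, the equilibrium dissolved
#' concentration is `sat - R/kla`; for a species produced at rate `R` with no
#' gas-phase inflow (stripping only), it is `R/kla`.
#'
#' @param sat Saturation concentration `S * c_b`, mol/L (consumed species).
#' @param R Reaction rate magnitude, mol/(L s) (> 0 consumption or
#'   production according to `type`).
#' @param kla Volumetric mass transfer coefficient, 1/s (> 0).
#' @param type `"consumed"` or `"produced"`.
#' @return Steady-state dissolved concentration, mol/L.
#' @export
steady_state_dissolved <- function(sat, R, kla,
                                   type = c("consumed", "produced")) {
  type <- match.arg(type)
  if (kla <= 0) stop("kla must be > 0 (no equilibrium without transfer)")
  if (type == "consumed") sat - R / kla else R / kla
}

#' Ratio of oxygen consumption to oxygen transfer capacity
#'
#' `xi = R / (sat * kla)`; the equilibrium dissolved oxygen obeys
#' `c_o = sat * (1 - xi)`. For the Contois system the consumption rate is
#' `(delta mu + phi) C_X` (use [xi_ratio_contois()]). `xi << 1` means the
#' dissolved-oxygen level is set by the bubble composition, not by kla.
#'
#' @param R Oxygen consumption rate, in units consistent with `sat * kla`
#'   (e.g. mol/(L s) against mol/L and 1/s).
#' @param sat Saturation concentration `S * c_b`.
#' @param kla Volumetric mass transfer coefficient.
#' @return Dimensionless ratio.
#' @export
xi_ratio <- function(R, sat, kla) {
  if (sat * kla <= 0) stop("sat * kla must be > 0")
  R / (sat * kla)
}

#' @rdname xi_ratio
#' @param state A [biokinetic_state()] (g/L).
#' @param p A [contois_params()].
#' @param sat_gL Oxygen saturation concentration, g/L.
#' @param kla_h Volumetric mass transfer coefficient, 1/h.
#' @export
xi_ratio_contois <- function(state, p, sat_gL, kla_h) {
  mu <- contois_mu(state, p)
  r_o2 <- (p$delta * mu + p$phi) * state[["X"]]   # g/(L h)
  xi_ratio(r_o2, sat_gL, kla_h)
}
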