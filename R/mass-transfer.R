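# Penetration-theory mass transfer coefficient, per-bubble interphase flux,
# conservative transfer bookkeeping, and kLa estimation (local time-average
# and global fit to the well-stirred saturation model).

#' Penetration-theory mass transfer coefficient
#'
#' `kL = C (eps * nu)^(1/4) * Sc^beta` with the turbulence-theory constants
#' `C = 0.301` and `beta = -1/2`. Inputs are vectorised.
#'
#' @param epsilon Specific energy dissipation rate, m^2/s^3 (> 0).
#' @param nu Kinematic viscosity, m^2/s (> 0).
#' @param schmidt Schmidt number `nu / D`, dimensionless (> 0).
#' @param C,beta Closure constants; defaults 0.301 and -0.5.
#' @return Mass transfer coefficient, m/s.
#' @examples
#' kl_penetration(1, 1e-6, 1000) # 3.01e-4 m/s
#' @export
kl_penetration <- function(epsilon, nu, schmidt, C = 0.301, beta = -0.5) {
  if (any(epsilon <= 0) || any(nu <= 0) || any(schmidt <= 0))
    stop("epsilon, nu and schmidt must all be > 0")
  C * (epsilon * nu)^0.25 * schmidt^beta
}

#' Per-bubble interphase molar flux
#'
#' For each parcel and species, the molar flow across the bubble interface is
#' `kL * A * (S * c_g - c_f)` with `A = pi d^2` the bubble surface area,
#' `c_g` the in-bubble gas-phase concentration (from the bubble's own molar
#' content and volume) and `c_f` the local dissolved concentration. Positive
#' flux is gas -> liquid; a liquid richer than equilibrium (`c_f > S c_g`)
#' gives a negative flux, i.e. stripping into the bubble.
#'
#' @param pop A [bubble_population()].
#' @param liquid_conc Named vector of dissolved concentrations, mol/m^3
#'   (one value per species; the well-mixed liquid seen by every bubble), or
#'   an `n x k` matrix for per-bubble local concentrations.
#' @param kl Mass transfer coefficient(s), m/s: scalar, length-`n` vector, or
#'   `n x k` matrix.
#' @param solubility Named vector of dimensionless solubilities per species.
#' @return `n x k` matrix of molar flows per PHYSICAL bubble, mol/s.
#' @export
bubble_species_flux <- function(pop, liquid_conc, kl, solubility) {
  n <- n_bubbles(pop)
  sp <- colnames(pop$moles)
  k <- length(sp)
  if (n == 0L) return(matrix(numeric(0), ncol = k, dimnames = list(NULL, sp)))
  if (any(pop$diameter <= 0)) stop("bubble diameter must be > 0")
  if (!is.matrix(liquid_conc))
    liquid_conc <- matrix(liquid_conc[sp], n, k, byrow = TRUE,
                          dimnames = list(NULL, sp))
  s <- solubility[sp]
  v_gas <- pi / 6 * pop$diameter^3
  c_g <- pop$moles / v_gas                        # mol/m^3, n x k
  area <- pi * pop$diameter^2
  driving <- sweep(c_g, 2, s, "*") - liquid_conc
  if (is.matrix(kl)) kl * area * driving else (kl * area) * driving
}

#' Apply interphase transfer to bubbles and a liquid cell
#'
#' Moves `flux * dt` moles between each bubble and the liquid cell. The two
#' sides change by exactly opposite amounts (machine precision): the realised
#' per-bubble transfer is clipped so no bubble's content and no dissolved
#' concentration goes negative, any clipped amount is logged as a deficit, and
#' bubble diameters are recomputed from the updated molar content.
#'
#' @param pop A [bubble_population()].
#' @param flux `n x k` molar flows per physical bubble (mol/s), positive
#'   gas -> liquid, as from [bubble_species_flux()].
#' @param dt Timestep, s (> 0).
#' @param cell List with `volume` (m^3, > 0) and `conc` (named mol/m^3).
#' @return List: `pop` (updated), `cell` (updated), `transferred` (named total
#'   gas -> liquid moles this step, weight-summed), `deficit` (named clipped
#'   moles).
#' @export
apply_transfer <- function(pop, flux, dt, cell) {
  stopifnot(dt > 0)
  if (is.null(cell$volume) || cell$volume <= 0)
    stop("cell volume must be > 0")
  sp <- colnames(pop$moles)
  zero <- stats::setNames(numeric(length(sp)), sp)
  if (n_bubbles(pop) == 0L)
    return(list(pop = pop, cell = cell, transferred = zero, deficit = zero))

  d_moles <- flux * dt                       # proposed per-bubble transfer
  deficit <- zero

  # gas -> liquid limited by bubble content
  over <- d_moles > pop$moles
  if (any(over)) {
    deficit <- deficit + colSums((d_moles - pop$moles) * over * pop$weight)
    d_moles[over] <- pop$moles[over]
  }
  # liquid -> gas limited by dissolved moles in the cell
  uptake <- -colSums(d_moles * (d_moles < 0) * pop$weight)   # mol from liquid
  avail <- cell$conc[sp] * cell$volume
  scale <- ifelse(uptake > avail & uptake > 0, avail / uptake, 1)
  if (any(scale < 1)) {
    deficit <- deficit + (uptake - uptake * scale)
    neg <- d_moles < 0
    d_moles <- d_moles * ifelse(neg, rep(scale, each = nrow(d_moles)), 1)
  }

  transferred <- colSums(d_moles * pop$weight)
  pop$moles <- pop$moles - d_moles
  pop$moles[pop$moles < 0] <- 0              # guard rounding at the floor
  pop <- update_diameters(pop)
  cell$conc[sp] <- cell$conc[sp] + transferred / cell$volume
  list(pop = pop, cell = cell, transferred = transferred, deficit = deficit)
}

#' Local time-averaged volumetric mass transfer coefficient
#'
#' Time average of `kl(t) * A_T(t) / V_site` per site over a trailing window
#' `tau`: sites with no bubbles at a sample time contribute zero at that time.
#' Records are point samples on a common clock; the average is taken over the
#' distinct sample times falling inside the window.
#'
#' @param records Data frame with columns `site_id`, `time` (s),
#'   `kl_times_area` (m^3/s, >= 0) and `site_volume` (m^3, > 0).
#' @param tau Averaging window, s (> 0).
#' @param t_end End of the window; defaults to the last record time.
#' @return Data frame with columns `site_id` and `kla` (1/s).
#' @export
local_kla_average <- function(records, tau, t_end = NULL) {
  stopifnot(is.data.frame(records), tau > 0)
  need <- c("site_id", "time", "kl_times_area", "site_volume")
  if (!all(need %in% names(records)))
    stop("records needs columns: ", paste(need, collapse = ", "))
  if (any(records$kl_times_area < 0)) stop("kl_times_area must be >= 0")
  if (any(records$site_volume <= 0)) stop("site_volume must be > 0")
  if (is.null(t_end)) t_end <- max(records$time)
  inside <- records$time > t_end - tau & records$time <= t_end
  if (!any(inside)) stop("no records inside the averaging window")
  w <- records[inside, ]
  n_times <- length(unique(w$time))
  val <- tapply(w$kl_times_area / w$site_volume, w$site_id, sum) / n_times
  data.frame(site_id = names(val), kla = as.numeric(val),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the global volumetric mass transfer coefficient
#'
#' Nonlinear least-squares fit of the well-stirred saturation model
#' `c(t) = sat - (sat - c0) exp(-kla t)` to a measured/simulated
#' dissolved-concentration series. Nonlinear (not log-linearised) so that
#' noise near saturation does not blow up.
#'
#' @param times Sample times, s (>= 5 samples).
#' @param concentrations Dissolved concentration series (any consistent unit).
#' @param sat_conc Saturation concentration (same unit); must exceed `c0`.
#' @param c0 Initial concentration; defaults to the first sample.
#' @return List with `kla` (1/s), `residual_norm`, and `fitted`.
#' @export
fit_global_kla <- function(times, concentrations, sat_conc, c0 = NULL) {
  stopifnot(length(times) == length(concentrations))
  if (length(times) < 5L) stop("need at least 5 samples to fit kla")
  if (is.null(c0)) c0 <- concentrations[[1L]]
  if (sat_conc <= c0)
    stop("sat_conc must exceed c0 (no transfer signal to fit)")
  if (stats::sd(concentrations) < 1e-12 * abs(sat_conc))
    stop("degenerate series: concentrations are constant")
  df <- data.frame(t = times, c = concentrations)
  # crude rate guess from the fraction of the gap closed by the end
  frac <- max(min((mean(tail(df$c, 3)) - c0) / (sat_conc - c0), 0.999), 1e-3)
  k0 <- -log(1 - frac) / max(df$t)
  fit <- tryCatch(
    minpack.lm::nlsLM(c ~ sat_conc - (sat_conc - c0) * exp(-k * t),
                      data = df, start = list(k = k0),
                      lower = 0, control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("kla fit failed to converge: ",
                             conditionMessage(e)))
  list(kla = unname(stats::coef(fit)[["k"]]),
       residual_norm = sqrt(sum(stats::residuals(fit)^2)),
       fitted = stats::fitted(fit))
}
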