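# Discrete spherical bubbles: injection, force balance, velocity Verlet
# integration, and removal at the free surface.
#
# A bubble "parcel" represents `weight` identical physical bubbles; dynamics
# use the physical bubble diameter, while molar bookkeeping (ledger, transfer
# into the liquid) multiplies by the weight. The per-parcel `moles` matrix is
# per PHYSICAL bubble. Diameter is always consistent with the molar content
# through the gas molar volume: V = sum_j moles_j * Vm_j, d = (6 V / pi)^(1/3).

#' Construct a bubble population
#'
#' @param pos `n x 3` positions, m.
#' @param vel `n x 3` velocities, m/s.
#' @param moles `n x k` matrix of per-bubble molar content, mol; column names
#'   are species names. All entries >= 0.
#' @param weight Number of physical bubbles each parcel represents (default 1).
#' @param density Gas density, kg/m^3.
#' @param molar_volume Named vector (or scalar recycled over species) of gas
#'   molar volumes, L/mol.
#' @param id Integer ids; generated if missing.
#'
#' @return An object of class `bubble_population`.
#' @export
bubble_population <- function(pos, vel, moles, weight = 1,
                              density = 1.2, molar_volume = 22.4,
                              id = NULL) {
  pos <- as_position_matrix(pos)
  vel <- as_position_matrix(vel)
  if (!is.matrix(moles)) moles <- matrix(moles, nrow = nrow(pos),
                                         dimnames = list(NULL, names(moles)))
  if (is.null(colnames(moles))) stop("moles must have species column names")
  n <- nrow(pos)
  stopifnot(nrow(vel) == n, nrow(moles) == n)
  if (any(moles < 0)) stop("per-species moles must be >= 0")
  k <- ncol(moles)
  vm <- rep_len(molar_volume, k)
  names(vm) <- colnames(moles)
  weight <- rep_len(weight, n)
  if (is.null(id)) id <- seq_len(n)
  pop <- structure(
    list(pos = pos, vel = vel, moles = moles, weight = weight,
         density = density, molar_volume = vm,
         id = as.integer(id), diameter = numeric(n)),
    class = "bubble_population")
  update_diameters(pop)
}

# recompute diameters from molar content (m); Vm is L/mol -> m^3/mol
update_diameters <- function(pop) {
  v_gas <- as.numeric(pop$moles %*% (pop$molar_volume / 1000))
  pop$diameter <- (6 * v_gas / pi)^(1 / 3)
  pop
}

#' @export
print.bubble_population <- function(x, ...) {
  cat(sprintf(
    "<bubble_population> %d parcels (%.4g physical bubbles), species: %s\n",
    n_bubbles(x), sum(x$weight), paste(colnames(x$moles), collapse = ", ")))
  invisible(x)
}

#' Number of parcels in a population
#' @param pop A [bubble_population()].
#' @export
n_bubbles <- function(pop) nrow(pop$pos)

#' Total gas moles held by a population, per species
#'
#' Accounts for parcel weights, i.e. returns physical moles.
#' @param pop A [bubble_population()].
#' @return Named vector, mol.
#' @export
bubble_moles <- function(pop) {
  if (n_bubbles(pop) == 0L)
    return(stats::setNames(numeric(ncol(pop$moles)), colnames(pop$moles)))
  colSums(pop$moles * pop$weight)
}

#' Total gas volume of a population (physical), m^3
#' @param pop A [bubble_population()].
#' @export
bubble_gas_volume <- function(pop) {
  if (n_bubbles(pop) == 0L) return(0)
  sum(pi / 6 * pop$diameter^3 * pop$weight)
}

pop_subset <- function(pop, idx) {
  pop$pos <- pop$pos[idx, , drop = FALSE]
  pop$vel <- pop$vel[idx, , drop = FALSE]
  pop$moles <- pop$moles[idx, , drop = FALSE]
  pop$weight <- pop$weight[idx]
  pop$id <- pop$id[idx]
  pop$diameter <- pop$diameter[idx]
  pop
}

pop_bind <- function(a, b) {
  if (n_bubbles(a) == 0L) return(b)
  if (n_bubbles(b) == 0L) return(a)
  stopifnot(identical(colnames(a$moles), colnames(b$moles)))
  a$pos <- rbind(a$pos, b$pos)
  a$vel <- rbind(a$vel, b$vel)
  a$moles <- rbind(a$moles, b$moles)
  a$weight <- c(a$weight, b$weight)
  a$id <- c(a$id, b$id)
  a$diameter <- c(a$diameter, b$diameter)
  a
}

empty_population <- function(species, density = 1.2, molar_volume = 22.4) {
  bubble_population(
    pos = matrix(numeric(0), ncol = 3),
    vel = matrix(numeric(0), ncol = 3),
    moles = matrix(numeric(0), ncol = length(species),
                   dimnames = list(NULL, species)),
    weight = numeric(0), density = density, molar_volume = molar_volume,
    id = integer(0))
}

#' Sparger definition
#'
#' @param gas A [gas_mixture()] describing the injected gas.
#' @param flow_slpm Total gas flow, standard L/min (>= 0).
#' @param bubble_diameter Injected bubble diameter, m (monodisperse point-mass
#'   distribution by default; pass a function `(n) -> diameters` for a custom
#'   size distribution). Default 2 mm.
#' @param ring_diameter Sparge-ring diameter, m.
#' @param height Height of the ring above the tank bottom, m.
#' @param parcel_weight Physical bubbles per simulated parcel (>= 1). Scales
#'   the computational population down at fixed gas flow; all molar accounting
#'   is weight-aware, so ledgers and transfer are unbiased.
#' @param molar_volume Gas molar volume, L/mol.
#' @param density Gas density, kg/m^3.
#'
#' @return An object of class `sparge_spec`.
#' @export
sparge_spec <- function(gas, flow_slpm, bubble_diameter = 0.002,
                        ring_diameter = 0.05, height = 0.04,
                        parcel_weight = 1, molar_volume = 22.4,
                        density = 1.2) {
  stopifnot(inherits(gas, "gas_mixture"))
  if (flow_slpm < 0) stop("flow_slpm must be >= 0")
  if (is.numeric(bubble_diameter) && any(bubble_diameter <= 0))
    stop("bubble diameters must be > 0")
  if (parcel_weight < 1) stop("parcel_weight must be >= 1")
  structure(
    list(gas = gas, flow_slpm = flow_slpm, bubble_diameter = bubble_diameter,
         ring_diameter = ring_diameter, height = height,
         parcel_weight = parcel_weight, molar_volume = molar_volume,
         density = density),
    class = "sparge_spec")
}

#' Inject bubbles for one timestep
#'
#' Parcels enter along the top of the sparge ring at zero velocity, uniformly
#' distributed in angle. The expected injected gas volume per unit time equals
#' the sparged flow; the fractional parcel per step is carried over between
#' calls so long-run volume bookkeeping is exact to within one bubble volume.
#'
#' @param sparge A [sparge_spec()].
#' @param dt Timestep, s (> 0).
#' @param carry Fractional-parcel remainder from the previous call (default 0).
#' @param next_id First id to assign.
#' @param species Full species set the parcels should carry (so bubbles can
#'   accumulate species absent from the injected gas, e.g. stripped CO2);
#'   defaults to the gas composition.
#' @return List with `bubbles` (a [bubble_population()] of the new parcels),
#'   `carry` (updated remainder), and `next_id`.
#' @export
inject_bubbles <- function(sparge, dt, carry = 0, next_id = 1L,
                           species = NULL) {
  stopifnot(inherits(sparge, "sparge_spec"), dt > 0)
  d0 <- if (is.function(sparge$bubble_diameter)) NULL else sparge$bubble_diameter
  vol_rate <- sparge$flow_slpm / 60 / 1000            # m^3/s of gas
  gas_sp <- names(sparge$gas$mole_fractions)
  if (is.null(species)) species <- gas_sp
  if (!all(gas_sp %in% species))
    stop("species must include every component of the sparged gas")
  if (vol_rate == 0) {
    return(list(bubbles = empty_population(species, sparge$density,
                                           sparge$molar_volume),
                carry = carry, next_id = next_id))
  }
  mean_d <- if (is.null(d0)) {
    mean(sparge$bubble_diameter(1000L))  # rate from the mean bubble volume
  } else d0
  v_b <- pi / 6 * mean_d^3
  rate <- vol_rate / v_b / sparge$parcel_weight        # parcels / s
  acc <- carry + rate * dt
  n <- floor(acc)
  carry <- acc - n
  if (n == 0) {
    return(list(bubbles = empty_population(species, sparge$density,
                                           sparge$molar_volume),
                carry = carry, next_id = next_id))
  }
  theta <- stats::runif(n, 0, 2 * pi)
  r <- sparge$ring_diameter / 2
  pos <- cbind(r * cos(theta), r * sin(theta), rep.int(sparge$height, n))
  d <- if (is.null(d0)) sparge$bubble_diameter(n) else rep.int(d0, n)
  mol_total <- pi / 6 * d^3 / (sparge$molar_volume / 1000)
  frac <- stats::setNames(numeric(length(species)), species)
  frac[gas_sp] <- sparge$gas$mole_fractions
  moles <- outer(mol_total, frac)
  pop <- bubble_population(
    pos = pos, vel = matrix(0, n, 3), moles = moles,
    weight = sparge$parcel_weight, density = sparge$density,
    molar_volume = sparge$molar_volume,
    id = seq.int(next_id, length.out = n))
  list(bubbles = pop, carry = carry, next_id = next_id + n)
}

# Schiller-Naumann drag coefficient as a function of bubble Reynolds number
schiller_naumann_cd <- function(re) {
  cd <- ifelse(re > 0, 24 / re * (1 + 0.15 * re^0.687), 0)
  ifelse(re > 1000, 0.44, cd)
}

#' Forces on bubbles
#'
#' Newtonian force balance on each spherical bubble, returned by component for
#' testability:
#' * `drag`: Schiller-Naumann drag on the slip velocity,
#'   `0.5 rho_f Cd (pi d^2/4) |u_f - u_b| (u_f - u_b)`;
#' * `pressure`: dynamic pressure-gradient force `rho_f V_b (Du/Dt)` from the
#'   local fluid material acceleration (the hydrostatic part is carried by the
#'   buoyancy term);
#' * `added_mass`: the fluid-acceleration part `Ca rho_f V_b (Du/Dt)` with
#'   `Ca = 0.5`; the reaction `-Ca rho_f V_b a_b` is absorbed into the
#'   effective mass by the integrator (see [verlet_step()]);
#' * `gravity_buoyancy`: `(rho_b - rho_f) V_b g`.
#'
#' @param pop A [bubble_population()]; all parcels must be inside the domain.
#' @param field A [flow_field()].
#' @param rho_f Liquid density, kg/m^3.
#' @param added_mass_coef Added-mass coefficient, default 0.5.
#' @return List of `n x 3` force matrices (N, per physical bubble):
#'   `drag`, `pressure`, `added_mass`, `gravity_buoyancy`.
#' @export
bubble_forces <- function(pop, field, rho_f = 1000, added_mass_coef = 0.5) {
  check_in_domain(field, pop$pos)
  u_f <- field$velocity(pop$pos)
  nu <- field$viscosity(pop$pos)
  a_f <- field$accel(pop$pos)
  d <- pop$diameter
  v_b <- pi / 6 * d^3
  slip <- u_f - pop$vel
  slip_mag <- sqrt(rowSums(slip^2))
  re <- slip_mag * d / nu
  cd <- schiller_naumann_cd(re)
  drag_coef <- 0.5 * rho_f * cd * (pi * d^2 / 4) * slip_mag  # N s/m
  g <- field$gravity
  list(
    drag = slip * drag_coef,
    pressure = a_f * (rho_f * v_b),
    added_mass = a_f * (added_mass_coef * rho_f * v_b),
    gravity_buoyancy = matrix(g, n_bubbles(pop), 3, byrow = TRUE) *
      ((pop$density - rho_f) * v_b))
}

# acceleration of each parcel given position/velocity matrices;
# (m_b + Ca rho_f V_b) a = F_drag + F_g + (1 + Ca) rho_f V_b (Du/Dt)
# a_f may be supplied to avoid re-differentiating the field at every stage
bubble_acceleration <- function(pop, field, pos, vel, rho_f, ca = 0.5,
                                a_f = NULL) {
  u_f <- field$velocity(pos)
  nu <- field$viscosity(pos)
  if (is.null(a_f)) a_f <- field$accel(pos)
  d <- pop$diameter
  v_b <- pi / 6 * d^3
  m_eff <- pop$density * v_b + ca * rho_f * v_b
  slip <- u_f - vel
  slip_mag <- sqrt(rowSums(slip^2))
  re <- slip_mag * d / nu
  cd <- schiller_naumann_cd(re)
  drag_coef <- 0.5 * rho_f * cd * (pi * d^2 / 4) * slip_mag
  f <- slip * drag_coef + a_f * ((1 + ca) * rho_f * v_b)
  f[, 3] <- f[, 3] + field$gravity[3] * (pop$density - rho_f) * v_b
  f / m_eff
}

# keep parcels inside the cylinder: slide along the wall / bottom
clamp_to_domain <- function(field, pos, vel) {
  r <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  out <- r > field$radius * 0.999
  if (any(out)) {
    s <- field$radius * 0.999 / r[out]
    pos[out, 1] <- pos[out, 1] * s
    pos[out, 2] <- pos[out, 2] * s
  }
  low <- pos[, 3] < 1e-9
  if (any(low)) {
    pos[low, 3] <- 1e-9
    vel[low, 3] <- pmax(vel[low, 3], 0)
  }
  # no top clamp: parcels overshoot the nominal height slightly until the
  # (possibly hold-up-raised) free surface removes them
  list(pos = pos, vel = vel)
}

#' Advance bubbles one timestep (velocity Verlet)
#'
#' Second-order velocity Verlet with force re-evaluation at the end of the
#' step (predicted velocity for the velocity-dependent drag). When the drag
#' relaxation time of the stiffest parcel is shorter than `dt`, the step is
#' subdivided internally so the integration stays accurate; the contract is
#' accuracy, not a fixed substep count.
#'
#' @param pop A [bubble_population()].
#' @param field A [flow_field()].
#' @param dt Timestep, s.
#' @param rho_f Liquid density, kg/m^3.
#' @param max_substeps Safety cap on internal subdivision.
#' @return The advanced population.
#' @export
verlet_step <- function(pop, field, dt, rho_f = 1000, max_substeps = 64L) {
  if (n_bubbles(pop) == 0L) return(pop)
  ca <- 0.5
  v_b <- pi / 6 * pop$diameter^3
  m_eff <- (pop$density + ca * rho_f) * v_b
  # drag relaxation time: linearise about the larger of Stokes drag and the
  # current finite-Re secant slope
  nu <- field$viscosity(pop$pos)
  slip <- field$velocity(pop$pos) - pop$vel
  slip_mag <- sqrt(rowSums(slip^2))
  re <- slip_mag * pop$diameter / nu
  b_stokes <- 3 * pi * rho_f * nu * pop$diameter
  b_now <- 0.5 * rho_f * schiller_naumann_cd(re) *
    (pi * pop$diameter^2 / 4) * slip_mag
  tau <- m_eff / pmax(b_stokes, b_now, 1e-300)
  n_sub <- min(max_substeps, max(1L, ceiling(dt / min(tau))))
  h <- dt / n_sub

  pos <- pop$pos
  vel <- pop$vel
  # fluid material acceleration frozen over the step: it varies on the flow
  # timescale, much longer than the drag relaxation resolved by substeps
  a_f <- field$accel(pos)
  for (s in seq_len(n_sub)) {
    a1 <- bubble_acceleration(pop, field, pos, vel, rho_f, ca, a_f)
    pos <- pos + vel * h + 0.5 * a1 * h^2
    cl <- clamp_to_domain(field, pos, vel)
    pos <- cl$pos; vel <- cl$vel
    a2 <- bubble_acceleration(pop, field, pos, vel + a1 * h, rho_f, ca, a_f)
    vel <- vel + 0.5 * (a1 + a2) * h
  }
  if (anyNA(pos) || anyNA(vel))
    stop("verlet_step: NaN in bubble state (dt too large or degenerate bubble)")
  pop$pos <- pos
  pop$vel <- vel
  pop
}

#' Remove bubbles crossing the free surface
#'
#' A parcel is removed once its top (`z + d/2`) reaches the free surface; its
#' molar content is returned so the caller can credit the ledger's bubble
#' removal stream. Moles are conserved exactly across the split.
#'
#' @param pop A [bubble_population()].
#' @param field A [flow_field()]; supplies the default surface level.
#' @param surface Override for the surface height, m (e.g. raised by the
#'   current gas hold-up).
#' @return List with `remaining` and `removed` populations.
#' @export
remove_at_surface <- function(pop, field, surface = NULL) {
  if (is.null(surface)) surface <- field$free_surface_height
  if (n_bubbles(pop) == 0L)
    return(list(remaining = pop, removed = pop))
  gone <- pop$pos[, 3] + pop$diameter / 2 >= surface
  list(remaining = pop_subset(pop, !gone), removed = pop_subset(pop, gone))
}

#' Reaction force of the bubbles on the fluid (two-way coupling hook)
#'
#' By Newton's third law the fluid feels the negative of the drag, pressure
#' and added-mass forces exerted on the bubbles. With the analytic flow fields
#' used here there is no fluid momentum solver to receive this force, so the
#' hook only reports it; it is documented for completeness and for coupling to
#' an external solver.
#'
#' @inheritParams bubble_forces
#' @return Length-3 net force on the fluid, N (weight-summed over parcels).
#' @export
fluid_reaction_force <- function(pop, field, rho_f = 1000) {
  if (n_bubbles(pop) == 0L) return(c(0, 0, 0))
  f <- bubble_forces(pop, field, rho_f)
  hydro <- f$drag + f$pressure + f$added_mass
  -colSums(hydro * pop$weight)
}

#' Simple break-up / coalescence plug-ins
#'
#' Bubble break-up and coalescence are OFF by default. These constructors
#' return functions `(pop, field, dt) -> pop` that can be passed to the
#' simulation engine for qualitative studies: `make_weber_breakup()` splits a
#' bubble into two equal daughters when its turbulent Weber number
#' `We = 2 rho (eps d)^{2/3} d / sigma` exceeds `we_crit`;
#' `make_overlap_coalescence()` merges parcel pairs whose centres are closer
#' than the sum of their radii (greedy, per step). Both conserve moles
#' exactly.
#'
#' @param we_crit Critical Weber number (default 1.2).
#' @param sigma Surface tension, N/m (default 0.072, water-air).
#' @param rho_f Liquid density, kg/m^3.
#' @return A function `(pop, field, dt) -> pop`.
#' @export
make_weber_breakup <- function(we_crit = 1.2, sigma = 0.072, rho_f = 1000) {
  force(we_crit); force(sigma); force(rho_f)
  function(pop, field, dt) {
    if (n_bubbles(pop) == 0L) return(pop)
    eps <- field$epsilon(pop$pos)
    we <- 2 * rho_f * (eps * pop$diameter)^(2 / 3) * pop$diameter / sigma
    split <- which(we > we_crit)
    if (length(split) == 0L) return(pop)
    daughters <- pop_subset(pop, split)
    daughters$moles <- daughters$moles / 2
    daughters <- update_diameters(daughters)
    pop$moles[split, ] <- pop$moles[split, , drop = FALSE] / 2
    pop <- update_diameters(pop)
    daughters$id <- max(pop$id) + seq_along(split)
    pop_bind(pop, daughters)
  }
}

#' @rdname make_weber_breakup
#' @export
make_overlap_coalescence <- function() {
  function(pop, field, dt) {
    n <- n_bubbles(pop)
    if (n < 2L) return(pop)
    # greedy pairwise merge on centre distance < sum of radii
    dmat <- as.matrix(stats::dist(pop$pos))
    radii <- pop$diameter / 2
    thresh <- outer(radii, radii, "+")
    diag(dmat) <- Inf
    merged <- rep(FALSE, n)
    drop <- integer(0)
    for (i in seq_len(n - 1L)) {
      if (merged[i]) next
      j <- which(!merged & dmat[i, ] < thresh[i, ])
      j <- j[j > i]
      if (length(j) == 0L) next
      j <- j[1L]
      # merge j into i (equal weights assumed; moles add per physical bubble)
      pop$moles[i, ] <- pop$moles[i, ] + pop$moles[j, ]
      pop$vel[i, ] <- (pop$vel[i, ] + pop$vel[j, ]) / 2
      merged[c(i, j)] <- TRUE
      drop <- c(drop, j)
    }
    if (length(drop)) pop <- pop_subset(pop, -drop)
    update_diameters(pop)
  }
}
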