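# Coarse explicit finite-volume solver for scalar advection-diffusion-
# reaction on a regular Cartesian lattice with a cylindrical liquid mask.
# First-order upwind advection + central diffusion in conservative flux form:
# interior faces between two liquid cells carry flux, all other faces are
# closed (no-flux walls), so total moles are conserved to rounding in the
# absence of sources.

#' Construct a scalar concentration grid
#'
#' Cartesian lattice over the tank bounding box `[-R, R] x [-R, R] x [0, H]`
#' with a staircase cylinder mask selecting liquid sites. Concentrations are
#' stored per species as 3D arrays in mol/m^3.
#'
#' @param n Lattice sites per axis, length 1 or 3. Default 32.
#' @param radius Tank radius, m.
#' @param height Liquid height, m.
#' @param species Character vector of species names.
#' @param initial_conc Named vector, mol/m^3 (default all 0).
#' @return An object of class `scalar_grid`: fields `n`, `dx` (length-3, m),
#'   `cell_volume` (m^3), `mask` (logical array), `conc` (named list of
#'   arrays), `centers` (list of axis coordinate vectors), `deficit`
#'   (named, mol, accumulated positivity clipping).
#' @export
scalar_grid <- function(n = 32, radius = 0.0925, height = 0.185,
                        species, initial_conc = NULL) {
  stopifnot(radius > 0, height > 0, length(species) >= 1)
  n <- rep_len(as.integer(n), 3L)
  if (any(n < 3)) stop("need at least 3 sites per axis")
  dx <- c(2 * radius / n[1], 2 * radius / n[2], height / n[3])
  xs <- -radius + (seq_len(n[1]) - 0.5) * dx[1]
  ys <- -radius + (seq_len(n[2]) - 0.5) * dx[2]
  zs <- (seq_len(n[3]) - 0.5) * dx[3]
  rr <- sqrt(outer(xs^2, ys^2, "+"))
  mask <- array(rep(as.vector(rr <= radius), n[3]), dim = n)
  conc <- lapply(stats::setNames(species, species), function(s) {
    a <- array(0, dim = n)
    if (!is.null(initial_conc) && s %in% names(initial_conc))
      a[mask] <- initial_conc[[s]]
    a
  })
  structure(
    list(n = n, dx = dx, cell_volume = prod(dx), radius = radius,
         height = height, mask = mask, conc = conc,
         centers = list(x = xs, y = ys, z = zs),
         deficit = stats::setNames(numeric(length(species)), species),
         vel = NULL),
    class = "scalar_grid")
}

#' @export
print.scalar_grid <- function(x, ...) {
  cat(sprintf(
    "<scalar_grid> %d x %d x %d (dx = %.3g m), %d liquid sites, species: %s\n",
    x$n[1], x$n[2], x$n[3], x$dx[1], sum(x$mask),
    paste(names(x$conc), collapse = ", ")))
  invisible(x)
}

#' Total moles held on the grid, per species
#' @param grid A [scalar_grid()].
#' @return Named vector, mol.
#' @export
grid_total_moles <- function(grid) {
  vapply(grid$conc, function(a) sum(a[grid$mask]) * grid$cell_volume, 0)
}

#' Volume-average concentration over liquid sites
#' @param grid A [scalar_grid()].
#' @param species Species name; default all.
#' @return Named vector, mol/m^3.
#' @export
grid_mean_conc <- function(grid, species = names(grid$conc)) {
  vapply(grid$conc[species], function(a) mean(a[grid$mask]), 0)
}

#' Sample a flow field at the grid cell centres (cached)
#'
#' Returns the grid with `$vel` populated (list of three arrays, m/s; zero on
#' masked sites). Re-attach whenever the field changes.
#'
#' @param grid A [scalar_grid()].
#' @param field A [flow_field()].
#' @return The grid with cached velocities.
#' @export
grid_attach_velocity <- function(grid, field) {
  pts <- as.matrix(expand.grid(x = grid$centers$x, y = grid$centers$y,
                               z = grid$centers$z))
  inside <- field_in_domain(field, pts)
  v <- matrix(0, nrow(pts), 3)
  v[inside, ] <- field$velocity(pts[inside, , drop = FALSE])
  grid$vel <- lapply(1:3, function(d) {
    a <- array(v[, d], dim = grid$n)
    a[!grid$mask] <- 0
    a
  })
  grid$faces <- build_faces(grid)
  grid
}

# slice an array along one axis
subarr <- function(x, a, idx) {
  switch(a,
         x[idx, , , drop = FALSE],
         x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE])
}

add_subarr <- function(x, a, idx, v) {
  switch(a,
         x[idx, , ] <- x[idx, , ] + v,
         x[, idx, ] <- x[, idx, ] + v,
         x[, , idx] <- x[, , idx] + v)
  x
}

# precompute, per axis, the open-face mask and the upwind-split face
# velocities (positive and negative parts, zero at closed faces)
build_faces <- function(grid) {
  lapply(1:3, function(a) {
    na <- grid$n[a]
    lo <- seq_len(na - 1L); hi <- lo + 1L
    open <- subarr(grid$mask, a, lo) & subarr(grid$mask, a, hi)
    uf <- if (is.null(grid$vel)) 0 else
      0.5 * (subarr(grid$vel[[a]], a, lo) + subarr(grid$vel[[a]], a, hi))
    list(lo = lo, hi = hi, open = open,
         up = pmax(uf, 0) * open, un = pmin(uf, 0) * open,
         umax = if (is.null(grid$vel)) 0 else max(abs(uf * open)))
  })
}

#' One explicit advection-diffusion-reaction step
#'
#' First-order upwind advection and central diffusion in conservative flux
#' form, plus per-site sources (e.g. bubble transfer) and reactions, advanced
#' one explicit Euler step. Walls (masked faces) are no-flux. Violating the
#' combined advective + diffusive stability bound raises an error naming the
#' binding constraint. Negative concentrations produced by sinks are clipped
#' with the clipped moles accumulated in `grid$deficit`.
#'
#' @param grid A [scalar_grid()] with velocities attached
#'   ([grid_attach_velocity()]); a grid without velocities is treated as
#'   quiescent.
#' @param diffusivity Named vector of diffusion coefficients, m^2/s.
#' @param sources Named list of arrays (or a function `conc -> array`) of
#'   volumetric source rates, mol/(m^3 s); optional.
#' @param reactions Named vector of uniform volumetric rates, mol/(m^3 s), or
#'   a function `conc_list -> named list of arrays`; optional.
#' @param dt Timestep, s.
#' @return The advanced grid.
#' @export
adr_step <- function(grid, diffusivity, sources = NULL, reactions = NULL,
                     dt) {
  stopifnot(inherits(grid, "scalar_grid"), dt > 0)
  sp <- names(grid$conc)
  D <- if (!is.null(names(diffusivity))) diffusivity[sp] else
    stats::setNames(rep_len(diffusivity, length(sp)), sp)
  if (is.null(grid$faces)) grid$faces <- build_faces(grid)
  faces <- grid$faces

  # stability: sum_a |u|_max dt/dx_a + 2 dt sum_a D/dx_a^2 <= 1
  adv <- sum(vapply(1:3, function(a) faces[[a]]$umax / grid$dx[a], 0)) * dt
  dif <- 2 * max(D) * sum(1 / grid$dx^2) * dt
  if (adv + dif > 1) {
    binding <- if (adv >= dif) "advective (CFL)" else "diffusive"
    stop(sprintf(
      "adr_step unstable: %s constraint violated (advective number %.3g, diffusive number %.3g; need sum <= 1)",
      binding, adv, dif))
  }

  rx <- NULL
  if (!is.null(reactions)) {
    rx <- if (is.function(reactions)) reactions(grid$conc) else
      lapply(stats::setNames(sp, sp), function(s) {
        r <- reactions[[s]] %||% 0
        array(r, dim = grid$n)
      })
  }

  for (s in sp) {
    ca <- grid$conc[[s]]
    dcdt <- array(0, dim = grid$n)
    for (a in 1:3) {
      fc <- faces[[a]]
      c1 <- subarr(ca, a, fc$lo)
      c2 <- subarr(ca, a, fc$hi)
      f <- (fc$up * c1 + fc$un * c2 -
              (D[[s]] / grid$dx[a]) * (c2 - c1) * fc$open) / grid$dx[a]
      dcdt <- add_subarr(dcdt, a, fc$lo, -f)
      dcdt <- add_subarr(dcdt, a, fc$hi, f)
    }
    if (!is.null(sources) && !is.null(sources[[s]])) {
      src <- sources[[s]]
      if (is.function(src)) src <- src(ca)
      dcdt <- dcdt + src
    }
    if (!is.null(rx) && !is.null(rx[[s]])) dcdt <- dcdt + rx[[s]]
    ca <- ca + dcdt * dt
    ca[!grid$mask] <- 0
    neg <- ca < 0
    if (any(neg)) {
      grid$deficit[s] <- grid$deficit[s] - sum(ca[neg]) * grid$cell_volume
      ca[neg] <- 0
    }
    grid$conc[[s]] <- ca
  }
  grid
}

#' Normalised spatial variation statistics
#'
#' Deviation of the concentration field from its liquid-volume mean:
#' `mean`, `min/mean - 1`, and `max/mean - 1` over liquid sites.
#'
#' @param grid A [scalar_grid()].
#' @param species Species name (default first).
#' @return List with `mean`, `min_rel`, `max_rel`.
#' @export
spatial_variation_stats <- function(grid, species = names(grid$conc)[1L]) {
  v <- grid$conc[[species]][grid$mask]
  if (length(v) == 0L) stop("grid has no liquid sites")
  m <- mean(v)
  if (m == 0) return(list(mean = 0, min_rel = 0, max_rel = 0))
  list(mean = m, min_rel = min(v) / m - 1, max_rel = max(v) / m - 1)
}

#' Per-site time-averaged kla map
#'
#' Averages `kl * A_T / V_site` per lattice site over a trailing window `tau`
#' (delegating to [local_kla_average()]; site ids are linear array indices)
#' and returns the result both as an array over the lattice and as a centre-
#' plane slice suitable for CSV export.
#'
#' @param grid A [scalar_grid()].
#' @param records Transfer records (see [local_kla_average()]); `site_id`
#'   must hold linear indices into the grid arrays.
#' @param tau Averaging window, s.
#' @param slice_axis,slice_index Plane to export; default the y mid-plane.
#' @return List with `array` (3D, 1/s; zero where no bubbles), `table`
#'   (site_id/kla data frame), and `slice` (data frame `i`, `k`, `x`, `z`,
#'   `kla`).
#' @export
kla_field <- function(grid, records, tau,
                      slice_axis = "y",
                      slice_index = ceiling(grid$n[2] / 2)) {
  avg <- local_kla_average(records, tau)
  arr <- array(0, dim = grid$n)
  arr[as.integer(avg$site_id)] <- avg$kla
  arr[!grid$mask] <- 0
  sl <- switch(slice_axis,
               x = arr[slice_index, , ],
               y = arr[, slice_index, ],
               z = arr[, , slice_index],
               stop("slice_axis must be x, y or z"))
  idx <- which(!is.na(sl), arr.ind = TRUE)
  axes <- switch(slice_axis, x = c("y", "z"), y = c("x", "z"), z = c("x", "y"))
  slice_df <- data.frame(
    i = idx[, 1], k = idx[, 2],
    a1 = grid$centers[[axes[1]]][idx[, 1]],
    a2 = grid$centers[[axes[2]]][idx[, 2]],
    kla = as.vector(sl))
  names(slice_df)[3:4] <- axes
  list(array = arr, table = avg, slice = slice_df)
}
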