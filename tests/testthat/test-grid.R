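test_that("constant field is a fixed point of the quiescent solver", {
  g <- scalar_grid(n = 16, species = "O2", initial_conc = c(O2 = 3))
  g1 <- adr_step(g, c(O2 = 1e-9), dt = 1)
  expect_equal(max(abs(g1$conc$O2[g1$mask] - 3)), 0, tolerance = 1e-12)
  # with a stirred velocity field, the drift of a constant field is bounded
  # by the discrete-divergence tolerance of the sampled field
  f <- make_stirred_tank_field(reactor_geometry(), mean_epsilon = 0.1)
  gv <- grid_attach_velocity(scalar_grid(n = 16, species = "O2",
                                         initial_conc = c(O2 = 3)), f)
  dt <- 0.9 / sum(sapply(1:3, function(a) max(abs(gv$vel[[a]])) / gv$dx[a]))
  g2 <- adr_step(gv, c(O2 = 1e-9), dt = dt)
  drift <- max(abs(g2$conc$O2[g2$mask] - 3))
  # drift is bounded by the discrete face divergence of the sampled field,
  # worst where the swirl runs along the staircase wall: under 1% per step
  expect_lt(drift / 3, 0.01)
})

test_that("closed-domain transport conserves total moles per step", {
  set.seed(31)
  f <- make_stirred_tank_field(reactor_geometry(), mean_epsilon = 0.1)
  g <- grid_attach_velocity(scalar_grid(n = 16, species = "O2"), f)
  blob <- array(0, g$n)
  blob[6:10, 6:10, 6:10] <- runif(125)
  blob[!g$mask] <- 0
  g$conc$O2 <- blob
  dt <- 0.5 / (sum(sapply(1:3, function(a) max(abs(g$vel[[a]])) / g$dx[a])) +
                 2 * 1e-4 * sum(1 / g$dx^2))
  m0 <- grid_total_moles(g)
  for (i in 1:50) {
    g <- adr_step(g, c(O2 = 1e-4), dt = dt)
    expect_equal(grid_total_moles(g), m0, tolerance = 1e-10)
  }
})

test_that("pure diffusion spreads a Gaussian blob at the closed-form rate", {
  g <- scalar_grid(n = 32, species = "O2")
  ctr <- c(0, 0, g$height / 2)
  sig0 <- 0.012
  D <- 2e-4    # large diffusivity so the signal swamps discretisation
  pts <- as.matrix(expand.grid(x = g$centers$x, y = g$centers$y,
                               z = g$centers$z))
  r2 <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 + (pts[, 3] - ctr[3])^2
  blob <- exp(-r2 / (2 * sig0^2))
  blob[!as.vector(g$mask)] <- 0
  g$conc$O2 <- array(blob, dim = g$n)
  var0 <- sum(r2 * blob) / sum(blob)
  dt <- 0.2 * min(g$dx)^2 / (6 * D)
  t_tot <- 0
  for (i in 1:150) { g <- adr_step(g, c(O2 = D), dt = dt); t_tot <- t_tot + dt }
  b <- as.vector(g$conc$O2)
  var1 <- sum(r2 * b) / sum(b)
  # in 3D the squared radius grows as 6 D t (2 D t per axis)
  expect_lt(abs((var1 - var0) / (6 * D * t_tot) - 1), 0.05)
})

test_that("stability violations name the binding constraint", {
  g <- scalar_grid(n = 16, species = "O2")
  expect_error(adr_step(g, c(O2 = 1), dt = 1), "diffusive")
  f <- uniform_field(velocity = c(0.5, 0, 0), radius = 0.0925, height = 0.185)
  gv <- grid_attach_velocity(scalar_grid(n = 16, species = "O2"), f)
  expect_error(adr_step(gv, c(O2 = 1e-9), dt = 1), "advective")
})

test_that("positivity is enforced by clipping with a logged deficit", {
  g <- scalar_grid(n = 8, species = "O2", initial_conc = c(O2 = 1e-4))
  g1 <- adr_step(g, c(O2 = 1e-9), reactions = c(O2 = -1), dt = 0.001)
  expect_true(all(g1$conc$O2 >= 0))
  expect_gt(g1$deficit[["O2"]], 0)
})

test_that("spatial variation statistics", {
  g <- scalar_grid(n = 8, species = "O2", initial_conc = c(O2 = 2))
  st <- spatial_variation_stats(g)
  expect_equal(st$min_rel, 0, tolerance = 1e-15)
  expect_equal(st$max_rel, 0, tolerance = 1e-15)
  # constructed +/- 5% split
  a <- g$conc$O2
  liquid <- which(g$mask)
  half <- liquid[seq_len(floor(length(liquid) / 2))]
  a[half] <- 2 * 1.05
  a[setdiff(liquid, half)] <- 2 * 0.95
  g$conc$O2 <- a
  st2 <- spatial_variation_stats(g)
  expect_equal(st2$max_rel, 0.05, tolerance = 1e-3)
  expect_equal(st2$min_rel, -0.05, tolerance = 1e-3)
})

test_that("kla map localises to the sites holding bubbles and is linear", {
  g <- scalar_grid(n = 8, species = "O2")
  site <- which(g$mask)[100]
  rec <- data.frame(site_id = site, time = 1:5,
                    kl_times_area = 2e-8, site_volume = g$cell_volume)
  kf <- kla_field(g, rec, tau = 5)
  expect_equal(sum(kf$array > 0), 1L)
  expect_equal(kf$array[site], 2e-8 / g$cell_volume, tolerance = 1e-12)
  # doubling the bubble surface area doubles <kla>
  rec2 <- rec; rec2$kl_times_area <- 4e-8
  kf2 <- kla_field(g, rec2, tau = 5)
  expect_equal(kf2$array[site], 2 * kf$array[site], tolerance = 1e-12)
})

test_that("kla map peaks near the impeller for an impeller-fed swarm", {
  geom <- reactor_geometry()
  f <- make_stirred_tank_field(geom, mean_epsilon = 0.137)
  g <- scalar_grid(n = 16, species = "O2")
  # constructed swarm: uniform bubble area everywhere; kl follows local eps,
  # so <kla> must peak where dissipation peaks (the impeller region)
  pts <- as.matrix(expand.grid(x = g$centers$x, y = g$centers$y,
                               z = g$centers$z))
  liquid <- which(g$mask)
  eps <- field_epsilon(f, pts[liquid, ])
  kl <- kl_penetration(eps, 1e-6, 1000)
  rec <- data.frame(site_id = liquid, time = 1,
                    kl_times_area = kl * 1e-5, site_volume = g$cell_volume)
  kf <- kla_field(g, rec, tau = 1)
  top <- liquid[order(kf$array[liquid], decreasing = TRUE)[1:10]]
  rr <- sqrt(pts[top, 1]^2 + pts[top, 2]^2)
  dist_imp <- sqrt((rr - geom$impeller_diameter / 2)^2 +
                     (pts[top, 3] - geom$off_bottom_clearance)^2)
  expect_lt(max(dist_imp), 0.05)   # all hotspots within 5 cm of the tip
})

test_that("dissolved O2 correlates positively with local kla under reaction", {
  # quiescent grid + weak diffusion: each site balances its own transfer
  # against the uniform consumption, so c ~ sat - R/kla(site) at steady state
  geom <- reactor_geometry()
  f <- make_stirred_tank_field(geom, mean_epsilon = 0.137)
  g <- scalar_grid(n = 8, species = "O2", initial_conc = c(O2 = 1.0))
  pts <- as.matrix(expand.grid(x = g$centers$x, y = g$centers$y,
                               z = g$centers$z))
  liquid <- g$mask
  eps <- array(0, g$n)
  eps[liquid] <- field_epsilon(f, pts[as.vector(liquid), ])
  kla_site <- array(0, g$n)
  kla_site[liquid] <- 0.05 * eps[liquid] / mean(eps[liquid])
  sat <- 1.43
  R <- 0.01                                   # mol/(m^3 s) uniform sink
  src <- function(ca) kla_site * (sat - ca)
  dt <- 0.2 * min(g$dx)^2 / (6 * 1e-6)
  dt <- min(dt, 0.5 / max(kla_site))
  for (i in 1:400)
    g <- adr_step(g, c(O2 = 1e-6), sources = list(O2 = src),
                  reactions = c(O2 = -R), dt = dt)
  co <- g$conc$O2[liquid]
  expect_gt(cor(co, kla_site[liquid], method = "spearman"), 0.5)
})
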