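test_that("penetration-theory kL", {
  # 0.301 * (1 * 1e-6)^(1/4) * 1000^(-1/2)
  expect_lt(abs(kl_penetration(1, 1e-6, 1000) / 3.01e-4 - 1), 1e-3)
  expect_equal(kl_penetration(1, 1e-6, 1000),
               0.301 * (1e-6)^0.25 / sqrt(1000), tolerance = 1e-12)
  # monotone increasing in epsilon, kL -> 0 with epsilon
  eps <- 10^seq(-6, 1, length.out = 20)
  kl <- kl_penetration(eps, 1e-6, 500)
  expect_true(all(diff(kl) > 0))
  expect_lt(kl[1], 2e-5)   # eps -> 0 drives kL toward 0
  # Sc quadrupled halves kL (exponent -1/2)
  expect_equal(kl_penetration(0.2, 1e-6, 400),
               kl_penetration(0.2, 1e-6, 100) / 2, tolerance = 1e-12)
  expect_error(kl_penetration(0, 1e-6, 100), "> 0")
  expect_error(kl_penetration(1, -1, 100), "> 0")
})

test_that("per-bubble species flux follows kL A (S c_g - c_f)", {
  b <- one_bubble(d = 2e-3)
  # c_g of pure O2 at 22.4 L/mol is 44.64 mol/m^3; A = pi d^2 = 1.2566e-5 m^2
  flux <- bubble_species_flux(b, c(O2 = 0), kl = 3.01e-4,
                              solubility = c(O2 = 0.032))
  expect_equal(unname(flux[1, "O2"]),
               3.01e-4 * pi * (2e-3)^2 * 0.032 * (1000 / 22.4),
               tolerance = 1e-12)
  expect_lt(abs(unname(flux[1, "O2"]) / 5.40e-9 - 1), 2e-3)

  # equilibrium: zero flux; super-saturated liquid: stripping (negative)
  ceq <- 0.032 * 1000 / 22.4
  expect_equal(unname(bubble_species_flux(b, c(O2 = ceq), 3.01e-4,
                                          c(O2 = 0.032))[1, "O2"]), 0)
  expect_lt(bubble_species_flux(b, c(O2 = 2 * ceq), 3.01e-4,
                                c(O2 = 0.032))[1, "O2"], 0)
})

test_that("transfer moves moles conservatively between bubble and cell", {
  b <- one_bubble(d = 2e-3)
  cell <- list(volume = 1e-3, conc = c(O2 = 0))
  flux <- bubble_species_flux(b, cell$conc, 3e-4, c(O2 = 0.032))
  out <- apply_transfer(b, flux, dt = 0.5, cell)
  d_bubble <- bubble_moles(out$pop) - bubble_moles(b)
  d_cell <- (out$cell$conc - cell$conc) * cell$volume
  expect_equal(d_bubble + d_cell, c(O2 = 0), tolerance = 1e-20)
  expect_lt(out$pop$diameter, b$diameter)  # bubble shrank
  # zero flux leaves both unchanged
  z <- apply_transfer(b, flux * 0, 0.5, cell)
  expect_identical(z$cell$conc, cell$conc)
  expect_equal(z$pop$moles, b$moles)
  expect_error(apply_transfer(b, flux, 0.5, list(volume = 0, conc = c(O2 = 0))),
               "volume")
})

test_that("a pure-oxygen bubble absorbs CO2 from CO2-rich liquid", {
  vm <- 22.4
  mol <- pi / 6 * (2e-3)^3 / (vm / 1000)
  b <- bubble_population(c(0, 0, 0.1), c(0, 0, 0),
                         matrix(c(mol, 0), 1, 2,
                                dimnames = list(NULL, c("O2", "CO2"))),
                         molar_volume = vm)
  cell <- list(volume = 1e-3, conc = c(O2 = 0, CO2 = 2))   # mol/m^3
  S <- c(O2 = 0.032, CO2 = 0.83)
  frac0 <- b$moles[1, "O2"] / sum(b$moles)
  for (i in 1:20) {
    flux <- bubble_species_flux(b, cell$conc, 3e-4, S)
    expect_lt(flux[1, "CO2"], 0)           # CO2 moves liquid -> gas
    out <- apply_transfer(b, flux, 0.1, cell)
    # hand-checked balance each step
    expect_equal((bubble_moles(out$pop) - bubble_moles(b)) +
                   (out$cell$conc - cell$conc) * cell$volume,
                 c(O2 = 0, CO2 = 0), tolerance = 1e-18)
    b <- out$pop; cell <- out$cell
  }
  frac1 <- b$moles[1, "O2"] / sum(b$moles)
  expect_lt(frac1, frac0)                  # oxygen fraction dropped
  expect_gt(b$moles[1, "CO2"], 0)
})

test_that("clipping floors bubble content at zero and logs the deficit", {
  b <- one_bubble(d = 2e-3)
  total <- sum(b$moles)
  huge_flux <- matrix(total * 10, 1, 1, dimnames = list(NULL, "O2"))
  cell <- list(volume = 1e-3, conc = c(O2 = 0))
  out <- apply_transfer(b, huge_flux, dt = 1, cell)
  expect_equal(sum(out$pop$moles), 0, tolerance = 1e-20)
  expect_equal(out$transferred[["O2"]], total, tolerance = 1e-15)
  expect_equal(out$deficit[["O2"]], total * 9, tolerance = 1e-12)
})

test_that("local kla average over a trailing window", {
  # constant integrand 0.02 over the window
  rec <- data.frame(site_id = "a", time = 1:10,
                    kl_times_area = 0.02 * 1e-6, site_volume = 1e-6)
  out <- local_kla_average(rec, tau = 10)
  expect_equal(out$kla, 0.02, tolerance = 1e-12)

  # square wave: present for half the sample times -> half the average;
  # a site with no bubbles contributes zero at those times
  rec2 <- rbind(rec,
                data.frame(site_id = "b", time = 6:10,
                           kl_times_area = 0.02 * 1e-6, site_volume = 1e-6))
  out2 <- local_kla_average(rec2, tau = 10)
  expect_equal(out2$kla[out2$site_id == "a"], 0.02, tolerance = 1e-12)
  expect_equal(out2$kla[out2$site_id == "b"], 0.01, tolerance = 1e-12)

  expect_error(local_kla_average(rec, tau = 2, t_end = 100), "window")
})

test_that("global kla fit recovers the generating coefficient", {
  sat <- 0.00143; kla <- 0.014
  t <- seq(0, 300, by = 1.5)
  c_clean <- sat * (1 - exp(-kla * t))
  fit <- fit_global_kla(t, c_clean, sat_conc = sat, c0 = 0)
  expect_equal(fit$kla, kla, tolerance = 1e-4 / kla)   # within 1e-4 absolute
  expect_lt(abs(fit$kla - kla), 1e-4)

  # 1% multiplicative Gaussian noise, 200 samples over 300 s, fixed seed
  set.seed(42)
  t2 <- seq(0, 300, length.out = 200)
  c_noisy <- sat * (1 - exp(-kla * t2)) * (1 + rnorm(200, 0, 0.01))
  fit2 <- fit_global_kla(t2, c_noisy, sat_conc = sat, c0 = 0)
  expect_lt(abs(fit2$kla / kla - 1), 0.02)

  # degenerate series at saturation
  expect_error(fit_global_kla(t, rep(sat, length(t)), sat_conc = sat,
                              c0 = sat), "exceed|degenerate")
  expect_error(fit_global_kla(1:3, 1:3, sat_conc = 10), "5 samples")
})
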