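# Coarser grids than the reference protocol keep the unit tests fast; the
# full Methods grids are exercised in test-acceptance.R.
coarse_grid <- function(...)
  scan_grid(rho_min = 0.02, rho_max = 0.50, rho_step = 0.01,
            rho_step_fine = NULL, share_ratio = 1.05, ...)

test_that("pathway occupancy is the volume-weighted concentration sum", {
  p <- pathway_params("metabolic")
  expect_equal(pathway_occupancy(0, 0, p), 0)
  # number density 5.18e-3 nm^-3 of 2.4 nm spheres occupies ~30% of volume
  expect_equal(pathway_occupancy(0, nm3_to_uM(5.18e-3), p), 0.2999,
               tolerance = 1e-3)
  # linearity in the two components
  expect_equal(pathway_occupancy(800, 900, p),
               pathway_occupancy(800, 0, p) + pathway_occupancy(0, 900, p))
  # composition round trip
  comp <- pathway_composition(0.25, 0.3, p)
  expect_equal(pathway_occupancy(comp$s_total, comp$E_total, p), 0.25)
  expect_error(pathway_occupancy(0, nm3_to_uM(0.2), p), "over-packed")
})

test_that("specific flux follows the lumped N-step rate law", {
  met <- pathway_params("metabolic")
  par <- pathway_params("ribosomal", N = 20)   # parallel topology
  lin <- pathway_params("ribosomal", N = 20, topology = "linear")

  # no catalyst, no flux
  st0 <- pathway_state(1000, 0, met)
  expect_equal(st0$flux, 0)
  expect_equal(st0$mu, 0)

  # parallel vs linear at identical composition: exactly N-fold
  sp <- pathway_state(500, 40, par)
  sl <- pathway_state(500, 40, lin)
  expect_equal(sp$flux, sl$flux)
  expect_equal(sp$mu, 20 * sl$mu)

  # N = 1, dilute: crowding-free Michaelis-Menten
  p1 <- pathway_params("metabolic", N = 1)
  s <- 1e-3; E <- 1e-4
  st <- pathway_state(s, E, p1)
  expect_equal(st$mu, 1 * s * E / ((130 + s) * st$rho), tolerance = 1e-4)
})

test_that("occupancy scans locate a unimodal optimum with convergent points", {
  rib <- scan_optimal_occupancy(pathway_params("ribosomal"), coarse_grid())
  expect_true(all(rib$envelope$n_failed == 0))
  expect_gt(rib$rho_opt, 0.05)
  expect_lt(rib$rho_opt, 0.30)
  # unimodal envelope: single sign change of smoothed discrete differences
  mu <- stats::filter(rib$envelope$mu, rep(1 / 3, 3), sides = 2)
  d <- sign(diff(mu[!is.na(mu)]))
  expect_equal(sum(diff(d[d != 0]) != 0), 1)

  # pathway length barely moves the optimum, but sharpens the penalty
  rib100 <- scan_optimal_occupancy(pathway_params("ribosomal", N = 100),
                                   coarse_grid())
  expect_lte(abs(rib100$rho_opt - rib$rho_opt), 0.02)
  at <- function(sc, r) sc$envelope$mu[which.min(abs(sc$envelope$rho - r))]
  pen20 <- 1 - at(rib, rib$rho_opt / 2) / at(rib, rib$rho_opt)
  pen100 <- 1 - at(rib100, rib100$rho_opt / 2) / at(rib100, rib100$rho_opt)
  expect_gt(pen100, pen20)

  # doubling theta for the metabolic system: the envelope near the optimum is
  # so flat that the argmax may drift, but the attainable maximum and the
  # specific flux at the theta = 2.3 optimum barely change
  met <- scan_optimal_occupancy(pathway_params("metabolic"), coarse_grid())
  met46 <- scan_optimal_occupancy(pathway_params("metabolic", theta = 4.6),
                                  coarse_grid())
  expect_lte(abs(met46$rho_opt - met$rho_opt), 0.06)
  mu46_at_old <- met46$envelope$mu[met46$envelope$rho == met$rho_opt]
  expect_lt(abs(mu46_at_old / met46$optimum$mu - 1), 0.02)
})

test_that("KM* decomposition separates diffusion and Gibbs-perturbation effects", {
  grid <- scan_grid(rho_min = 0.05, rho_max = 0.60, rho_step = 0.05,
                    rho_step_fine = NULL, share_ratio = 1.1)
  met <- km_star_decomposition_scan(pathway_params("metabolic"), grid)
  # diffusion-only: monotone increase of KM*; transition-only: decrease
  expect_true(all(diff(met$km_norm_diffusion) > 0))
  expect_true(all(diff(met$km_norm_transition) < 0))
  expect_true(all(met$km_norm_transition >= 1 / 3.3))
  # full ribosomal KM*/KM0 exceeds full metabolic at rho = 0.3
  rib <- km_star_decomposition_scan(pathway_params("ribosomal"), grid)
  i <- which(grid$rho_values == 0.3)
  expect_gt(rib$km_norm_full[i], met$km_norm_full[i])
})

test_that("two-regime kinetics reduce to plain MM at zero occupancy", {
  kin <- reaction_kinetics(1, 130, 2.3, sphere_species("s", 2.4),
                           sphere_species("E", 13))
  mm <- 1 * 500 * 50 / (500 + 130)
  expect_equal(vazquez_flux(500, 50, 0, "saturated", kin), mm)
  expect_equal(vazquez_flux(500, 50, 0, "diffusion", kin), mm)
  # fixed ratio between the regimes
  rho <- seq(0, 0.9, by = 0.1)
  expect_equal(vazquez_flux(500, 50, rho, "diffusion", kin) /
                 vazquez_flux(500, 50, rho, "saturated", kin),
               exp(-5.8 * rho))
  # saturated specific flux is monotone in rho; diffusion-regime flux has an
  # interior optimum (scan compositions at fixed share of occupied volume)
  p <- pathway_params("ribosomal")
  rho <- seq(0.02, 0.78, by = 0.02)
  comp <- lapply(rho, pathway_composition, share = 0.4, params = p)
  vsat <- mapply(function(c, r)
    vazquez_flux(c$s_total, c$E_total, r, "saturated", kin), comp, rho)
  vdif <- mapply(function(c, r)
    vazquez_flux(c$s_total, c$E_total, r, "diffusion", kin), comp, rho)
  expect_true(all(diff(vsat) > 0))
  i <- which.max(vdif)
  expect_gt(i, 1); expect_lt(i, length(rho))
  expect_error(vazquez_flux(500, 50, 1, "saturated", kin), "rho")
})
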