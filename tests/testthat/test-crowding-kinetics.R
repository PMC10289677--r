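kin_metab <- function(theta = 2.3)
  reaction_kinetics(1, 130, theta, sphere_species("s", 0.34),
                    sphere_species("E", 2.4))

test_that("hydrodynamic radius and diffusion exponent match hand evaluation", {
  expect_equal(hydrodynamic_radius(0), 0.182)
  expect_equal(hydrodynamic_radius(0.34), 1.3 * (0.34 + 0.14))
  expect_equal(hydrodynamic_radius(2.4), 3.302)
  expect_error(hydrodynamic_radius(-1), "non-negative")

  # hand arithmetic with xi = 0.51, R = 42, a = 0.53, rho_ref = 0.22
  g_hand <- function(r) {
    rh <- 1.3 * (r + 0.14)
    (0.51^2 / 42^2 + 0.51^2 / rh^2)^(-0.53 / 2) / 0.22
  }
  expect_equal(diffusion_exponent_g(0.34), g_hand(0.34))
  expect_equal(round(diffusion_exponent_g(0.34), 2), 5.06)
  expect_equal(round(diffusion_exponent_g(2.4), 1), 12.2)
  # strictly increasing in the substrate radius
  g <- diffusion_exponent_g(seq(0.1, 15, by = 0.1))
  expect_true(all(diff(g) > 0))
  expect_error(diffusion_exponent_g(0), "positive")
})

test_that("SPT activity coefficients obey dilute, monotonicity and packing limits", {
  expect_equal(ln_activity_coefficient(2.4, mixture_state()), 0)

  bg <- mixture_state(list(sphere_species("E", 2.4)),
                      conc = nm3_to_uM(0.2 / sphere_volume(2.4)))
  lg <- ln_activity_coefficient(c(2.4, 4.8), bg)
  expect_gt(lg[1], 0)
  expect_gt(lg[2], lg[1])          # doubling the probe radius increases gamma

  # moments are linear in densities: scaling all densities by lambda scales
  # every moment, and ln gamma grows monotonically with lambda
  lams <- seq(0.1, 1.5, by = 0.2)
  lgs <- vapply(lams, function(l) {
    m <- mixture_state(list(sphere_species("E", 2.4)),
                       conc = l * nm3_to_uM(0.2 / sphere_volume(2.4)))
    ln_activity_coefficient(2.4, m)
  }, numeric(1))
  expect_true(all(diff(lgs) > 0))

  expect_error(
    mixture_state(list(sphere_species("E", 2.4)),
                  conc = nm3_to_uM(1.2 / sphere_volume(2.4))),
    "over-packed")
})

test_that("Gibbs perturbation factor is 1 when dilute and exceeds 1 when crowded", {
  kin <- kin_metab()
  expect_equal(gibbs_perturbation(kin, mixture_state()), 1)
  bg <- mixture_state(list(sphere_species("c", 3)),
                      conc = nm3_to_uM(0.2 / sphere_volume(3)))
  expect_gt(gibbs_perturbation(kin, bg), 1)
  # nondecreasing as all densities are scaled up
  gam <- vapply(seq(0, 1.5, by = 0.25), function(l) {
    m <- mixture_state(list(sphere_species("c", 3)),
                       conc = l * nm3_to_uM(0.2 / sphere_volume(3)))
    gibbs_perturbation(kin, m)
  }, numeric(1))
  expect_true(all(diff(gam) >= 0))
})

test_that("KM* reproduces all limiting behaviours of the crowding model", {
  kin <- kin_metab()
  # no-crowding identity for any theta
  for (th in c(0, 0.5, 2.3, 10))
    expect_equal(km_star(kin_metab(th), 0, Gamma = 1)$KM_star, 130)
  # pure diffusion limit: theta = 0 gives KM0 * exp(g rho)
  g <- diffusion_exponent_g(0.34)
  expect_equal(km_star(kin_metab(0), 1 / g, Gamma = 7)$KM_star, 130 * exp(1))
  # pure transition-state limit: theta -> Inf gives KM0 / Gamma
  expect_equal(km_star(kin_metab(1e8), 0.3, Gamma = 2)$KM_star, 65,
               tolerance = 1e-6)
  # diffusion-only mode strictly increasing in rho
  kd <- vapply(seq(0, 0.8, by = 0.1), function(r)
    km_star(kin, r, Gamma = 5, mode = "diffusion_only")$KM_star, numeric(1))
  expect_true(all(diff(kd) > 0))
  # transition-only mode decreasing in Gamma with plateau KM0 / (1 + theta)
  kt <- vapply(c(1, 2, 5, 20, 1e6), function(G)
    km_star(kin, 0.3, Gamma = G, mode = "transition_only")$KM_star,
    numeric(1))
  expect_true(all(diff(kt) < 0))
  expect_true(all(kt >= 130 / 3.3 - 1e-9))
  expect_equal(kt[5], 130 / 3.3, tolerance = 1e-5)
  expect_equal(km_star(kin, 0, Gamma = 1, mode = "transition_only")$KM_star,
               130)
  expect_error(km_star(kin, 1, Gamma = 1), "rho")
  expect_error(km_star(kin, -0.1, Gamma = 1), "rho")
})

test_that("binding equilibrium converges to a self-consistent fixed point", {
  kin <- kin_metab()

  # no substrate: complex zero, catalyst fully free
  eq0 <- solve_binding_equilibrium(1000, 0, kin)
  expect_equal(eq0$complex, 0)
  expect_equal(eq0$free[["catalyst"]], 1000)

  # fixed point contract: binding relation holds exactly at the returned KM*
  eq <- solve_binding_equilibrium(2000, 50000, kin)
  expect_equal(eq$complex,
               eq$totals[["catalyst"]] * eq$free[["substrate"]] /
                 (eq$free[["substrate"]] + eq$KM_star),
               tolerance = 1e-12)
  # ... and re-evaluating KM* from the returned composition changes it by
  # less than the convergence tolerance
  mix <- mixture_state(
    list(sphere_species("s", 0.34), sphere_species("E", 2.4),
         complex_species(kin$catalyst, kin$substrate)),
    conc = c(eq$free[["substrate"]], eq$free[["catalyst"]], eq$complex))
  km2 <- km_star(kin, eq$occupancy, mixture = mix)$KM_star
  expect_equal(km2, eq$KM_star, tolerance = 2e-5)

  # mass conservation
  expect_equal(eq$free[["catalyst"]] + eq$complex, eq$totals[["catalyst"]])
  expect_equal(eq$free[["substrate"]] + eq$complex, eq$totals[["substrate"]])
  expect_true(eq$complex <= min(eq$totals))

  # dilute limit agrees with the crowding-free Michaelis-Menten closed form
  eqd <- solve_binding_equilibrium(1e-4, 1e-4, kin)
  expect_equal(eqd$complex, mm_complex(1e-4, 1e-4, 130), tolerance = 1e-4)
  expect_equal(eqd$KM_star, 130, tolerance = 1e-4)
})

test_that("complex geometry follows the volume-additivity rule", {
  cpl <- complex_species(sphere_species("E", 2.4), sphere_species("s", 0.34))
  expect_equal(cpl$radius^3, 2.4^3 + 0.34^3)
  expect_error(sphere_species("bad", -1), "positive")
})
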