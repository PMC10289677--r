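par150 <- wholecell_params(N = 150, s_ext = 1)

test_that("transporter flux is plain irreversible Michaelis-Menten", {
  par <- wholecell_params(N = 150, s_ext = 1e6 * 1)   # saturating nutrient
  expect_equal(transporter_flux(10, par), 13.7 * 10, tolerance = 1e-5)
  par2 <- wholecell_params(N = 150, s_ext = 1)        # s_ext = KM_T
  expect_equal(transporter_flux(10, par2), 13.7 * 10 / 2)
  expect_equal(transporter_flux(0, par2), 0)
  expect_error(transporter_flux(-1, par2), "non-negative")
})

test_that("whole-cell state computes growth rate, residuals and observables", {
  st <- wholecell_state(s = 2000, p = 150, T = 20, M = 400, R = 15, par150)
  # allocation fractions sum to 1 (balanced-growth identity)
  o <- st$observables
  expect_equal(o$alloc_T + o$alloc_M + o$alloc_R, 1, tolerance = 1e-9)
  expect_true(all(c(o$sat_M, o$sat_R) >= 0 & c(o$sat_M, o$sat_R) <= 1))
  expect_equal(o$volfrac_metab + o$volfrac_ribo, 1, tolerance = 1e-12)
  # growth rate definition
  expect_equal(st$mu,
               3600 * st$fluxes[["v_R"]] / (300 * 400 + 7459 * 15 + 300 * 20))
  # no precursor, no growth
  st0 <- wholecell_state(s = 2000, p = 0, T = 20, M = 400, R = 15, par150)
  expect_equal(st0$mu, 0)
  # all concentrations zero: residuals are exactly (0, 0)
  stz <- wholecell_state(0, 0, 0, 0, 0, par150)
  expect_equal(unname(balance_residuals(stz)), c(0, 0))

  # dilute, crowding-free: hand-evaluated closed form
  par0 <- wholecell_params(N = 150, s_ext = 1, crowding = FALSE)
  std <- wholecell_state(s = 1e-3, p = 1e-3, T = 1e-4, M = 1e-4, R = 1e-5,
                         par0)
  vR <- 22 * 1e-3 * 1e-5 / (120 + 1e-3)
  expect_equal(std$fluxes[["v_R"]], vR, tolerance = 1e-9)
  expect_equal(std$km_star_M, 130, tolerance = 1e-9)
  expect_equal(std$km_star_R, 120, tolerance = 1e-9)
})

test_that("R-level state evaluation agrees with the C++ solver path", {
  sol <- solve_at_occupancy(par150, 0.22, n_restarts = 8, seed = 3)
  st <- sol$state
  pv <- crowdcell:::wc_par_vector(par150)
  cst <- crowdcell:::".cc_wc_eval_spm"(
    uM_to_nm3(st$conc[["s"]]), uM_to_nm3(st$conc[["p"]]),
    uM_to_nm3(st$conc[["M"]]), 0.22, pv)
  expect_true(cst$ok)
  expect_equal(cst$mu * 3600, st$mu, tolerance = 1e-9)
  expect_equal(nm3_to_uM(cst$km_star_R), st$km_star_R, tolerance = 1e-6)
  expect_equal(nm3_to_uM(cst$T), st$conc[["T"]], tolerance = 1e-9)
})

test_that("constrained solutions are feasible, reproducible and seed-robust", {
  sol <- solve_at_occupancy(par150, 0.22, n_restarts = 10, seed = 1)
  expect_true(sol$converged)
  expect_true(all(abs(sol$residuals) <= 1e-9))
  expect_equal(sol$rho, 0.22, tolerance = 1e-12)

  # byte-identical under the same seed
  sol2 <- solve_at_occupancy(par150, 0.22, n_restarts = 10, seed = 1)
  expect_identical(sol$mu, sol2$mu)
  expect_identical(sol$state$conc, sol2$state$conc)

  # best mu agrees across independent seeds (restart robustness)
  mus <- vapply(1:3, function(s)
    solve_at_occupancy(par150, 0.22, n_restarts = 10, seed = s)$mu,
    numeric(1))
  expect_lt(diff(range(mus)) / mean(mus), 1e-4)

  # perturbing s upward from a feasible point over-consumes: res_s < 0
  st <- sol$state
  stp <- wholecell_state(1.1 * st$conc[["s"]], st$conc[["p"]],
                         st$conc[["T"]], st$conc[["M"]], st$conc[["R"]],
                         par150)
  expect_lt(balance_residuals(stp)[["res_s"]], 0)
})

test_that("occupancy scan returns a tidy table with the optimum marked", {
  sc <- optimal_occupancy(par150, rho_grid = seq(0.18, 0.24, by = 0.02),
                          n_restarts = 6, seed = 2)
  expect_equal(nrow(sc$table), 4)
  expect_true(all(c("mu", "mu_over_mumax", "km_star_M", "km_star_R",
                    "sat_M", "sat_R", "alloc_R", "res_s_rel") %in%
                    names(sc$table)))
  expect_equal(max(sc$table$mu_over_mumax), 1)
  expect_equal(sc$mu_max, max(sc$table$mu))
  expect_true(sc$rho_opt %in% sc$table$rho)
  obs <- derived_observables(solve_at_occupancy(par150, 0.22, 6, 1))
  expect_equal(obs$alloc_T + obs$alloc_M + obs$alloc_R, 1, tolerance = 1e-9)
})
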