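#' Parameters of the five-variable whole-cell growth model
#'
#' A self-replicating model cell: transporter T imports the external
#' nutrient (conventional Michaelis-Menten, no crowding, excluded from the
#' cytosolic occupancy), an N-step metabolic pathway (lumped, enzymes M,
#' substrates s) converts it into the precursor p, and the ribosome R
#' polymerises p into the three protein types at costs l_T, l_M, l_R
#' precursors each. The metabolic and ribosomal reactions follow
#' crowding-adjusted kinetics and, together with their substrates and
#' complexes, form the shared crowding background.
#'
#' @param N number of active metabolic reactions (lumped scaling); see
#'   [metabolic_reaction_presets()].
#' @param s_ext external nutrient concentration (uM).
#' @param theta_metabolic,theta_ribosomal diffusion/transition-state weights.
#' @param kcat_T,KM_T transporter kinetics (1/s, uM).
#' @param kcat_M,KM0_M metabolic kinetics (1/s, uM).
#' @param kcat_R,KM0_R ribosomal kinetics (1/s, uM).
#' @param l_T,l_M,l_R precursors per transporter / enzyme / ribosome.
#' @param r_s,r_M,r_p,r_R molecule radii (nm): metabolite, enzyme, precursor
#'   (ternary complex), ribosome.
#' @param crowding set FALSE for the crowding-unaware reference model
#'   (Gamma = 1, g = 0 everywhere).
#' @param constants a [crowding_constants()] object.
#' @return an object of class `wholecell_params`.
#' @examples
#' wholecell_params(N = 250, s_ext = 1)
#' @export
wholecell_params <- function(N = 250, s_ext = 1,
                             theta_metabolic = 2.3, theta_ribosomal = 2.3,
                             kcat_T = 13.7, KM_T = 1,
                             kcat_M = 13.7, KM0_M = 130,
                             kcat_R = 22.0, KM0_R = 120,
                             l_T = 300, l_M = 300, l_R = 7459,
                             r_s = 0.34, r_M = 2.4, r_p = 2.4, r_R = 13,
                             crowding = TRUE,
                             constants = crowding_constants()) {
  stopifnot(N >= 1, s_ext >= 0, kcat_T > 0, KM_T > 0, kcat_M > 0,
            KM0_M > 0, kcat_R > 0, KM0_R > 0, l_T > 0, l_M > 0, l_R > 0,
            r_s > 0, r_M > 0, r_p > 0, r_R > 0)
  structure(list(N = N, s_ext = s_ext,
                 theta_metabolic = theta_metabolic,
                 theta_ribosomal = theta_ribosomal,
                 kcat_T = kcat_T, KM_T = KM_T,
                 kcat_M = kcat_M, KM0_M = KM0_M,
                 kcat_R = kcat_R, KM0_R = KM0_R,
                 l_T = l_T, l_M = l_M, l_R = l_R,
                 r_s = r_s, r_M = r_M, r_p = r_p, r_R = r_R,
                 crowding = isTRUE(crowding), constants = constants),
            class = "wholecell_params")
}

# flat parameter vector consumed by the C++ kernels (internal units)
wc_par_vector <- function(params, tol = 1e-5, max_iter = 500, n_p_grid = 28) {
  p <- params
  c(p$kcat_T, uM_to_nm3(p$KM_T), uM_to_nm3(p$s_ext),
    p$kcat_M, uM_to_nm3(p$KM0_M), p$theta_metabolic,
    p$kcat_R, uM_to_nm3(p$KM0_R), p$theta_ribosomal,
    p$N, p$l_T, p$l_M, p$l_R,
    p$r_s, p$r_M, p$r_p, p$r_R,
    diffusion_exponent_g(p$r_s, p$constants),
    diffusion_exponent_g(p$r_p, p$constants),
    as.numeric(p$crowding), max_iter, tol, n_p_grid)
}

SEC_PER_HOUR <- 3600

#' Transporter flux
#'
#' v_T = kcat_T s_ext \[T\] / (s_ext + KM_T); conventional irreversible
#' Michaelis-Menten kinetics, no crowding adjustment.
#'
#' @param T_conc transporter concentration (uM), >= 0.
#' @param params a [wholecell_params()].
#' @return flux (uM/s), vectorised.
#' @export
transporter_flux <- function(T_conc, params) {
  if (any(T_conc < 0)) stop("T_conc must be non-negative")
  params$kcat_T * params$s_ext * T_conc / (params$s_ext + params$KM_T)
}

#' Evaluate the whole-cell model at given concentrations
#'
#' Solves the coupled self-consistent binding equilibria of the metabolic and
#' ribosomal reactions in their shared crowding background and evaluates the
#' fluxes, the growth rate mu = v_R / (l_M \[M\] + l_R \[R\] + l_T \[T\]), the
#' balanced-growth residuals, and the derived observables.
#'
#' @param s,p,T,M,R total concentrations (uM): metabolic substrate (summed),
#'   precursor, transporter, metabolic enzyme (summed), ribosome.
#' @param params a [wholecell_params()].
#' @return an object of class `wholecell_state`: concentrations, free/bound
#'   splits, `rho` (T excluded), `mu` (1/h), fluxes `v_T`, `v_M`, `v_R`
#'   (uM/s), `km_star_M`, `km_star_R` (uM), residuals `res_s`, `res_p`
#'   (uM/s), and `observables` (sector volume fractions, saturations,
#'   ribosome allocation fractions).
#' @examples
#' par <- wholecell_params(N = 150, s_ext = 1)
#' st <- wholecell_state(s = 2000, p = 150, T = 20, M = 400, R = 15, par)
#' st$mu
#' @export
wholecell_state <- function(s, p, T, M, R, params) {
  stopifnot(s >= 0, p >= 0, T >= 0, M >= 0, R >= 0)
  pv <- wc_par_vector(params)
  w <- uM_to_nm3(c(s, p, M, R))
  eq <- .cc_wc_equilibrium(w[1], w[2], w[3], w[4], pv)
  if (!eq$converged) stop("binding equilibria did not converge")
  km_M <- nm3_to_uM(eq$km_star_M)
  km_R <- nm3_to_uM(eq$km_star_R)
  v_M <- (params$kcat_M / params$N) * s * M / (params$N * km_M + s)
  v_R <- params$kcat_R * p * R / (km_R + p)
  v_T <- transporter_flux(T, params)
  prot <- params$l_M * M + params$l_R * R + params$l_T * T
  if (prot <= 0 && v_R > 0) stop("growth rate undefined: zero protein")
  mu <- if (prot > 0) v_R / prot else 0 # 1/s
  rho <- uM_to_nm3(s) * sphere_volume(params$r_s) +
    uM_to_nm3(M) * sphere_volume(params$r_M) +
    uM_to_nm3(p) * sphere_volume(params$r_p) +
    uM_to_nm3(R) * sphere_volume(params$r_R)
  obs <- list(
    volfrac_metab = if (rho > 0)
      (uM_to_nm3(s) * sphere_volume(params$r_s) +
         uM_to_nm3(M) * sphere_volume(params$r_M)) / rho else NA_real_,
    volfrac_ribo = if (rho > 0)
      (uM_to_nm3(p) * sphere_volume(params$r_p) +
         uM_to_nm3(R) * sphere_volume(params$r_R)) / rho else NA_real_,
    sat_M = s / (s + params$N * km_M),
    sat_R = p / (p + km_R),
    alloc_T = if (v_R > 0) mu * params$l_T * T / v_R else NA_real_,
    alloc_M = if (v_R > 0) mu * params$l_M * M / v_R else NA_real_,
    alloc_R = if (v_R > 0) mu * params$l_R * R / v_R else NA_real_)
  structure(list(
    conc = c(s = s, p = p, T = T, M = M, R = R),
    complex_M = nm3_to_uM(eq$complex_M),
    complex_R = nm3_to_uM(eq$complex_R),
    rho = rho, mu = mu * SEC_PER_HOUR,
    fluxes = c(v_T = v_T, v_M = v_M, v_R = v_R),
    km_star_M = km_M, km_star_R = km_R,
    res_s = v_T - v_M - mu * s,
    res_p = v_M - v_R - mu * p,
    observables = obs, params = params),
    class = "wholecell_state")
}

#' Growth rate of a whole-cell state
#' @param state a [wholecell_state()].
#' @return growth rate mu (1/h).
#' @export
growth_rate <- function(state) {
  stopifnot(inherits(state, "wholecell_state"))
  state$mu
}

#' Balanced-growth residuals of a whole-cell state
#'
#' res_s = v_T - v_M - mu \[s\] (substrate balance) and
#' res_p = v_M - v_R - mu \[p\] (precursor balance); both are zero at
#' balanced growth.
#'
#' @param state a [wholecell_state()].
#' @return named vector (res_s, res_p) in uM/s.
#' @export
balance_residuals <- function(state) {
  stopifnot(inherits(state, "wholecell_state"))
  c(res_s = state$res_s, res_p = state$res_p)
}

# state list from a C++ softmax-coordinate evaluation -> tidy row (uM, 1/h)
wc_row <- function(cst) {
  conv <- function(x) nm3_to_uM(x)
  data.frame(
    mu = cst$mu * SEC_PER_HOUR,
    s = conv(cst$s), p = conv(cst$p), T = conv(cst$T),
    M = conv(cst$M), R = conv(cst$R),
    km_star_M = conv(cst$km_star_M), km_star_R = conv(cst$km_star_R),
    res_s = conv(cst$res_s), res_p = conv(cst$res_p))
}

# deterministic + seeded random starting coordinates on the share simplex
wc_start_points <- function(n_random) {
  det <- rbind(c(0, 0), c(1, 1), c(-2, 1), c(1, -2), c(-1, -1),
               c(2, -1), c(-1, 2))
  if (n_random > 0) {
    u <- matrix(10^runif(3 * n_random, -4, 0), ncol = 3)
    sh <- u / rowSums(u)
    det <- rbind(det, cbind(log(sh[, 1] / sh[, 3]), log(sh[, 2] / sh[, 3])))
  }
  det
}

#' Maximize growth rate at fixed occupancy
#'
#' Maximizes mu over the five concentrations subject to the two
#' balanced-growth equalities and the occupancy constraint rho = rho_target.
#' The constraints are eliminated exactly: \[R\] from the occupancy relation
#' (linear), \[T\] from the substrate balance (closed-form quadratic; T is
#' excluded from crowding), and \[p\] from the precursor balance by bracketed
#' root finding (when two balanced solutions exist the higher-mu branch is
#' kept). The remaining two degrees of freedom (volume shares of s and M) are
#' optimized by Nelder-Mead from a deterministic warm start -- the optimum of
#' the crowding-unaware model -- plus `n_restarts` perturbed and random
#' starts, and the best feasible solution is returned. Reproducible under a
#' fixed seed.
#'
#' @param params a [wholecell_params()].
#' @param rho_target occupancy constraint in (0, 1).
#' @param n_restarts number of local searches (>= 1); default 20.
#' @param seed integer seed for the random restarts.
#' @param start optional starting coordinates (z_s, z_M) in softmax space,
#'   e.g. from a neighbouring occupancy.
#' @return an object of class `gba_solution`: `state` (a
#'   [wholecell_state()]), `mu` (1/h), `rho`, `residuals` (relative),
#'   `coords`, `restarts_run`, `best_restart`, `converged`.
#' @examples
#' \donttest{
#' sol <- solve_at_occupancy(wholecell_params(N = 150, s_ext = 1), 0.22,
#'                           n_restarts = 5, seed = 1)
#' sol$mu
#' }
#' @export
solve_at_occupancy <- function(params, rho_target, n_restarts = 20,
                               seed = 1, start = NULL) {
  stopifnot(rho_target > 0, rho_target < 1)
  pv <- wc_par_vector(params)
  neg_mu <- function(z, par_vec) {
    m <- .cc_wc_mu(z[1], z[2], rho_target, par_vec)
    if (!is.finite(m)) 1e3 else -m
  }
  run_nm <- function(z0, par_vec) {
    stats::optim(z0, neg_mu, par_vec = par_vec, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-12))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  # phase (i): crowding-unaware warm start
  pv0 <- pv; pv0[20] <- 0
  warm <- wc_start_points(3)
  zw <- warm[1, ]; fw <- Inf
  for (i in seq_len(nrow(warm))) {
    o <- run_nm(warm[i, ], pv0)
    if (o$value < fw) { fw <- o$value; zw <- o$par }
  }

  # phase (ii): crowding-adjusted multi-start from the warm start,
  # perturbations of it, and fresh random points
  n_restarts <- max(1, as.integer(n_restarts))
  starts <- matrix(rep(zw, n_restarts), ncol = 2, byrow = TRUE)
  if (n_restarts > 1) {
    n_pert <- min(n_restarts - 1, ceiling((n_restarts - 1) / 2))
    idx <- 2L
    for (k in seq_len(n_pert)) {
      starts[idx, ] <- zw + stats::rnorm(2, sd = 0.75); idx <- idx + 1L
    }
    if (idx <= n_restarts)
      starts[idx:n_restarts, ] <- wc_start_points(n_restarts - idx + 1)[
        -(1:7), , drop = FALSE][seq_len(n_restarts - idx + 1), , drop = FALSE]
  }
  if (!is.null(start)) starts[1, ] <- start  # continuation from a neighbour
  best <- NULL; best_f <- Inf; best_i <- NA_integer_
  for (i in seq_len(nrow(starts))) {
    o <- run_nm(starts[i, ], pv)
    if (o$value < best_f) { best_f <- o$value; best <- o$par; best_i <- i }
  }
  if (!is.finite(best_f) || best_f >= 1e3)
    stop(sprintf("no feasible balanced-growth state at rho = %g", rho_target))
  cst <- .cc_wc_state(best[1], best[2], rho_target, pv)
  st <- wholecell_state(nm3_to_uM(cst$s), nm3_to_uM(cst$p), nm3_to_uM(cst$T),
                        nm3_to_uM(cst$M), nm3_to_uM(cst$R), params)
  scale <- max(abs(st$fluxes))
  structure(list(
    state = st, mu = st$mu, rho = st$rho,
    residuals = c(res_s = st$res_s / scale, res_p = st$res_p / scale,
                  res_rho = (st$rho - rho_target) / rho_target),
    coords = best, restarts_run = nrow(starts), best_restart = best_i,
    converged = TRUE), class = "gba_solution")
}

#' @export
print.gba_solution <- function(x, ...) {
  cat(sprintf("Balanced-growth optimum at rho = %.4g: mu = %.5g 1/h\n",
              x$rho, x$mu))
  invisible(x)
}

#' Occupancy scan of the whole-cell model
#'
#' Runs [solve_at_occupancy()] on an occupancy grid (warm-starting each point
#' from its neighbour's optimum in addition to the usual restarts) and
#' locates the growth-optimal occupancy. Ties are broken towards the smaller
#' occupancy.
#'
#' @param params a [wholecell_params()].
#' @param rho_grid occupancy grid; default the pathway scan grid restricted
#'   to occupancies.
#' @param n_restarts restarts per grid point.
#' @param seed integer seed.
#' @param progress print one line per grid point.
#' @return an object of class `wholecell_scan`: `table` (one row per
#'   occupancy with mu, mu/mu_max, concentrations, KM*, saturations, volume
#'   fractions, allocations), `rho_opt`, `mu_max` (1/h), `params`.
#' @export
optimal_occupancy <- function(params, rho_grid = scan_grid()$rho_values,
                              n_restarts = 20, seed = 1, progress = FALSE) {
  stopifnot(all(rho_grid > 0), all(rho_grid < 1))
  rho_grid <- sort(unique(rho_grid))
  rows <- vector("list", length(rho_grid))
  prev <- NULL
  for (i in seq_along(rho_grid)) {
    sol <- tryCatch(
      solve_at_occupancy(params, rho_grid[i], n_restarts = n_restarts,
                         seed = seed + i, start = prev),
      error = function(e) NULL)
    if (!is.null(sol)) {
      prev <- sol$coords
      st <- sol$state
      rows[[i]] <- data.frame(
        rho = rho_grid[i], mu = sol$mu,
        conc_s = st$conc[["s"]], conc_p = st$conc[["p"]],
        conc_T = st$conc[["T"]], conc_M = st$conc[["M"]],
        conc_R = st$conc[["R"]],
        km_star_M = st$km_star_M, km_star_R = st$km_star_R,
        sat_M = st$observables$sat_M, sat_R = st$observables$sat_R,
        volfrac_metab = st$observables$volfrac_metab,
        volfrac_ribo = st$observables$volfrac_ribo,
        alloc_T = st$observables$alloc_T, alloc_M = st$observables$alloc_M,
        alloc_R = st$observables$alloc_R,
        res_s_rel = sol$residuals[["res_s"]],
        res_p_rel = sol$residuals[["res_p"]],
        res_rho_rel = sol$residuals[["res_rho"]],
        restarts = sol$restarts_run, converged = TRUE)
    }
    if (progress)
      message(sprintf("rho = %.3f: mu = %s", rho_grid[i],
                      if (is.null(sol)) "infeasible" else
                        format(sol$mu, digits = 6)))
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0)
    stop("no feasible occupancy on the grid")
  i <- which(tab$mu >= max(tab$mu) * (1 - 1e-12))[1]
  tab$mu_over_mumax <- tab$mu / tab$mu[i]
  structure(list(table = tab, rho_opt = tab$rho[i], mu_max = tab$mu[i],
                 params = params, n_restarts = n_restarts, seed = seed),
            class = "wholecell_scan")
}

#' @export
print.wholecell_scan <- function(x, ...) {
  cat(sprintf(
    "Whole-cell scan (N = %g, s_ext = %g uM): rho_opt = %.3f, mu_max = %.5g 1/h\n",
    x$params$N, x$params$s_ext, x$rho_opt, x$mu_max))
  invisible(x)
}

#' Derived physiological observables of a solution
#'
#' @param solution a `gba_solution` (or a `wholecell_state`).
#' @return one-row data.frame: sector volume fractions (complexes assigned to
#'   their constituents by volume additivity), substrate saturations of the
#'   metabolic and ribosomal reactions, KM* values (uM), and the ribosome
#'   allocation fractions mu l_i \[i\] / v_R, which sum to 1 at balanced
#'   growth.
#' @export
derived_observables <- function(solution) {
  st <- if (inherits(solution, "gba_solution")) solution$state else solution
  stopifnot(inherits(st, "wholecell_state"))
  o <- st$observables
  data.frame(volfrac_metab = o$volfrac_metab, volfrac_ribo = o$volfrac_ribo,
             sat_M = o$sat_M, sat_R = o$sat_R,
             km_star_M = st$km_star_M, km_star_R = st$km_star_R,
             alloc_T = o$alloc_T, alloc_M = o$alloc_M, alloc_R = o$alloc_R)
}

#' Optimal occupancy across pathway lengths and nutrient levels
#'
#' Runs [optimal_occupancy()] for every combination of `N_values` and
#' `s_ext_values`.
#'
#' @param N_values metabolic pathway lengths.
#' @param s_ext_values external nutrient concentrations (uM).
#' @param params_base a [wholecell_params()] supplying all other parameters.
#' @param rho_grid,n_restarts,seed passed to [optimal_occupancy()].
#' @param progress print one line per combination.
#' @return data.frame with one row per (N, s_ext): rho_opt, mu_max, and the
#'   KM* and saturations at the optimum.
#' @export
heatmap_scan <- function(N_values, s_ext_values,
                         params_base = wholecell_params(),
                         rho_grid = seq(0.08, 0.36, by = 0.005),
                         n_restarts = 20, seed = 1, progress = FALSE) {
  stopifnot(length(N_values) > 0, length(s_ext_values) > 0)
  rows <- list()
  for (N in N_values) for (sx in s_ext_values) {
    par <- params_base
    par$N <- N; par$s_ext <- sx
    sc <- optimal_occupancy(par, rho_grid = rho_grid,
                            n_restarts = n_restarts, seed = seed)
    opt <- sc$table[sc$table$rho == sc$rho_opt, ]
    rows[[length(rows) + 1]] <- data.frame(
      N = N, s_ext = sx, rho_opt = sc$rho_opt, mu_max = sc$mu_max,
      km_star_M = opt$km_star_M, km_star_R = opt$km_star_R,
      sat_M = opt$sat_M, sat_R = opt$sat_R)
    if (progress)
      message(sprintf("N = %g, s_ext = %g: rho_opt = %.3f", N, sx,
                      sc$rho_opt))
  }
  do.call(rbind, rows)
}
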