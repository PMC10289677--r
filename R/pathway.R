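#' Parameters of the N-step pathway model
#'
#' A pathway of `N` identical reactions: a linear chain (metabolic preset,
#' substrate r = 0.34 nm, catalyst r = 2.4 nm) or `N` parallel reactions
#' (ribosomal preset, ternary-complex substrate r = 2.4 nm, ribosome
#' r = 13 nm). All reactions share one crowding-adjusted Michaelis-Menten
#' rate law with kcat = 1/s and KM0 = 130 uM by default.
#'
#' @param preset "metabolic", "ribosomal", or "custom".
#' @param N number of reactions, >= 1; default 20.
#' @param kcat turnover number (1/s); appears only as a flux scale.
#' @param KM0 low-crowding Michaelis parameter (uM).
#' @param theta diffusion vs transition-state weight; default 2.3.
#' @param r_s,r_E substrate and catalyst radii (nm); defaulted by preset,
#'   required for "custom".
#' @param topology "linear" or "parallel"; defaulted by preset (metabolic =
#'   linear, ribosomal = parallel).
#' @param constants a [crowding_constants()] object.
#' @return an object of class `pathway_params`.
#' @examples
#' pathway_params("ribosomal")
#' @export
pathway_params <- function(preset = c("metabolic", "ribosomal", "custom"),
                           N = 20, kcat = 1, KM0 = 130, theta = 2.3,
                           r_s = NULL, r_E = NULL, topology = NULL,
                           constants = crowding_constants()) {
  preset <- match.arg(preset)
  if (preset == "metabolic") {
    if (is.null(r_s)) r_s <- 0.34
    if (is.null(r_E)) r_E <- 2.4
    if (is.null(topology)) topology <- "linear"
  } else if (preset == "ribosomal") {
    if (is.null(r_s)) r_s <- 2.4
    if (is.null(r_E)) r_E <- 13
    if (is.null(topology)) topology <- "parallel"
  } else {
    if (is.null(r_s) || is.null(r_E))
      stop("custom preset requires r_s and r_E")
    if (is.null(topology)) topology <- "linear"
  }
  topology <- match.arg(topology, c("linear", "parallel"))
  if (N < 1) stop("N must be >= 1")
  kin <- reaction_kinetics(kcat, KM0, theta,
                           sphere_species("substrate", r_s),
                           sphere_species("catalyst", r_E))
  structure(list(preset = preset, N = N, kinetics = kin,
                 topology = topology, constants = constants),
            class = "pathway_params")
}

#' Cytosolic occupancy of a pathway composition
#'
#' rho = N_A (4 pi / 3) (\[s\] r_s^3 + \[E\] r_E^3); by volume additivity of
#' the complex the free/bound split does not change rho.
#'
#' @param s_total,E_total summed substrate and catalyst concentrations (uM).
#' @param params a [pathway_params()].
#' @return occupancy (volume fraction), vectorised.
#' @examples
#' p <- pathway_params("metabolic")
#' pathway_occupancy(0, nm3_to_uM(5.18e-3), p)  # ~0.30
#' @export
pathway_occupancy <- function(s_total, E_total, params) {
  if (any(s_total < 0) || any(E_total < 0))
    stop("concentrations must be non-negative")
  rho <- uM_to_nm3(s_total) * sphere_volume(params$kinetics$substrate$radius) +
    uM_to_nm3(E_total) * sphere_volume(params$kinetics$catalyst$radius)
  if (any(rho >= 1)) stop("composition over-packed: rho >= 1")
  rho
}

#' Composition implied by (occupancy, substrate volume share)
#'
#' Inverts the occupancy relation: the substrate species jointly occupy
#' `share * rho` of the volume and the catalysts the rest.
#'
#' @param rho target occupancy in (0, 1).
#' @param share substrate share of the occupied volume, in (0, 1).
#' @param params a [pathway_params()].
#' @return list with `s_total` and `E_total` (uM).
#' @export
pathway_composition <- function(rho, share, params) {
  stopifnot(rho > 0, rho < 1, share > 0, share < 1)
  list(
    s_total = nm3_to_uM(share * rho /
                          sphere_volume(params$kinetics$substrate$radius)),
    E_total = nm3_to_uM((1 - share) * rho /
                          sphere_volume(params$kinetics$catalyst$radius)))
}

#' Pathway state: self-consistent flux and specific flux
#'
#' Solves the self-consistent binding equilibrium for the given composition
#' and evaluates the pathway flux per unit volume,
#' v = (kcat/N) \[s\]\[E\] / (N KM* + \[s\]), and the flux per unit dry mass
#' mu = v / rho (times N for the parallel topology).
#'
#' @param s_total,E_total summed substrate and catalyst concentrations (uM).
#' @param params a [pathway_params()].
#' @param mode KM* mode, see [km_star()].
#' @return an object of class `pathway_state` with `rho`, `flux`
#'   (uM/s), `mu` (flux per dry mass, 1/s), `equilibrium`
#'   (a `binding_equilibrium`), and `km_star` (uM).
#' @examples
#' p <- pathway_params("metabolic")
#' st <- pathway_state(5000, 3000, p)
#' st$mu
#' @export
pathway_state <- function(s_total, E_total, params,
                          mode = c("full", "diffusion_only",
                                   "transition_only")) {
  mode <- match.arg(mode)
  rho <- pathway_occupancy(s_total, E_total, params)
  eq <- solve_binding_equilibrium(E_total, s_total, params$kinetics,
                                  n_lump = params$N, mode = mode,
                                  constants = params$constants)
  kin <- params$kinetics
  flux <- (kin$kcat / params$N) * s_total * E_total /
    (params$N * eq$KM_star + s_total)
  if (rho <= 0 && flux > 0) stop("undefined objective: rho = 0 with flux > 0")
  mu <- if (rho > 0) flux / rho else 0
  if (params$topology == "parallel") mu <- mu * params$N
  structure(list(s_total = s_total, E_total = E_total, rho = rho,
                 equilibrium = eq, flux = flux, mu = mu,
                 km_star = eq$KM_star, mode = mode),
            class = "pathway_state")
}

#' Flux per unit dry mass of a pathway state
#'
#' @param state a [pathway_state()].
#' @return mu, the specific flux (already multiplied by N for the parallel
#'   topology).
#' @export
specific_flux <- function(state) {
  stopifnot(inherits(state, "pathway_state"))
  state$mu
}

#' Occupancy and substrate-share scan grids
#'
#' Defaults reproduce the reference scan protocol: occupancy from 0.01 to
#' 0.80 in steps of 0.01 with a refined window from 0.100 to 0.360 in steps
#' of `rho_step_fine`, and a geometric substrate-share grid from 0.1\% to
#' 97.7\% of the occupied volume growing by a factor 1.0023 per step.
#'
#' @param rho_min,rho_max,rho_step coarse occupancy grid.
#' @param fine_min,fine_max,rho_step_fine refined occupancy window (set
#'   `rho_step_fine = NULL` to skip refinement).
#' @param share_min,share_max,share_ratio geometric substrate-share grid.
#' @return an object of class `scan_grid` with sorted unique `rho_values`
#'   and `share_values`.
#' @export
scan_grid <- function(rho_min = 0.01, rho_max = 0.80, rho_step = 0.01,
                      fine_min = 0.100, fine_max = 0.360,
                      rho_step_fine = 0.001,
                      share_min = 0.001, share_max = 0.977,
                      share_ratio = 1.0023) {
  rho <- seq(rho_min, rho_max, by = rho_step)
  if (!is.null(rho_step_fine))
    rho <- c(rho, seq(fine_min, fine_max, by = rho_step_fine))
  rho <- sort(unique(round(rho, 12)))
  n <- floor(log(share_max / share_min) / log(share_ratio))
  share <- share_min * share_ratio^(0:n)
  share <- share[share < 1]
  if (any(rho <= 0) || any(rho >= 1)) stop("rho grid must lie in (0, 1)")
  structure(list(rho_values = rho, share_values = share),
            class = "scan_grid")
}

pathway_scan_raw <- function(params, grid, mode = "full", full = FALSE) {
  kin <- params$kinetics
  g_s <- diffusion_exponent_g(kin$substrate$radius, params$constants)
  .cc_pathway_scan(
    grid$rho_values, grid$share_values, params$N, kin$kcat,
    uM_to_nm3(kin$KM0), kin$theta, kin$substrate$radius, kin$catalyst$radius,
    params$topology == "parallel", g_s,
    switch(mode, full = 0L, diffusion_only = 1L, transition_only = 2L),
    1e-5, 500L, full)
}

#' Scan for the occupancy maximizing pathway output
#'
#' For every (occupancy, substrate share) grid point the composition is
#' solved self-consistently and the objective evaluated; per occupancy the
#' envelope (objective maximized over the share) is returned together with
#' the global optimum. Grid points whose equilibrium failed to converge are
#' excluded from the envelope with a warning. Ties are broken towards the
#' smaller occupancy (within 1e-12 relative of the maximum).
#'
#' @param params a [pathway_params()].
#' @param grid a [scan_grid()].
#' @param objective "mu" (flux per unit dry mass) or "flux" (total flux per
#'   volume).
#' @return an object of class `pathway_scan`: `envelope` (data.frame with
#'   rho, mu, flux, optimal shares, KM*/KM0 at the mu-optimal composition),
#'   `rho_opt`, `optimum` (envelope row at the optimum), `objective`.
#' @examples
#' \donttest{
#' sc <- scan_optimal_occupancy(pathway_params("ribosomal"),
#'                              scan_grid(rho_step_fine = NULL))
#' sc$rho_opt
#' }
#' @export
scan_optimal_occupancy <- function(params, grid = scan_grid(),
                                   objective = c("mu", "flux")) {
  objective <- match.arg(objective)
  res <- pathway_scan_raw(params, grid)
  env <- data.frame(rho = res$rho, mu = res$mu, flux = res$flux,
                    share_at_mu = res$share_at_mu,
                    share_at_flux = res$share_at_flux,
                    km_norm_at_mu = res$km_norm_at_mu,
                    n_failed = res$n_failed)
  if (all(!is.finite(env$mu))) stop("all grid points over-packed or failed")
  if (any(env$n_failed > 0))
    warning(sum(env$n_failed), " grid points excluded (non-converged)")
  obj <- env[[objective]]
  i <- which(obj >= max(obj, na.rm = TRUE) * (1 - 1e-12))[1] # smallest rho
  structure(list(envelope = env, rho_opt = env$rho[i], optimum = env[i, ],
                 objective = objective, params = params, grid = grid),
            class = "pathway_scan")
}

#' @export
print.pathway_scan <- function(x, ...) {
  cat(sprintf(
    "Pathway scan (%s, N = %d, objective = %s): rho_opt = %.3f\n",
    x$params$preset, x$params$N, x$objective, x$rho_opt))
  invisible(x)
}

#' Decomposition of KM* into diffusion and Gibbs-perturbation effects
#'
#' Tabulates KM*/KM0 against occupancy for the full model and for the two
#' hypothetical single-effect models (diffusion-only: Gamma = 1;
#' transition-only: g = 0), each evaluated at the composition that maximizes
#' the specific flux of that model at that occupancy.
#'
#' @param params a [pathway_params()].
#' @param grid a [scan_grid()].
#' @return data.frame with rho and km_norm_full / km_norm_diffusion /
#'   km_norm_transition.
#' @export
km_star_decomposition_scan <- function(params, grid = scan_grid()) {
  out <- data.frame(rho = grid$rho_values)
  for (m in c("full", "diffusion_only", "transition_only")) {
    res <- pathway_scan_raw(params, grid, mode = m)
    out[[paste0("km_norm_", sub("_only", "", m))]] <- res$km_norm_at_mu
  }
  out
}

#' Reaction rates under the two-regime crowding treatment
#'
#' The alternative kinetics in which reactions are classified as saturated
#' (rate enhanced by 1/(1 - rho) through increased contact) or
#' diffusion-limited (additionally slowed by exp(-5.8 rho)):
#' v_sat = kcat \[s\]\[E\] / ((1 - rho)(\[s\] + KM)),
#' v_diff = exp(-5.8 rho) v_sat.
#'
#' @param s,E substrate and catalyst concentrations (uM).
#' @param rho occupancy in \[0, 1).
#' @param regime "saturated" or "diffusion".
#' @param kin a [reaction_kinetics()] supplying kcat and KM0.
#' @return reaction rate (uM/s), vectorised over rho.
#' @export
vazquez_flux <- function(s, E, rho, regime = c("saturated", "diffusion"),
                         kin) {
  regime <- match.arg(regime)
  if (any(rho < 0) || any(rho >= 1)) stop("rho must lie in [0, 1)")
  v <- kin$kcat * (1 / (1 - rho)) * s * E / (s + kin$KM0)
  if (regime == "diffusion") v <- exp(-5.8 * rho) * v
  v
}
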