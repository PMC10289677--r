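#' Physical constants of the crowding model
#'
#' Parameters of the size-dependent diffusion slowdown in the crowded
#' cytosol and of the hydrodynamic radius relation, with defaults calibrated
#' for \emph{E. coli}.
#'
#' @param xi average surface-to-surface distance between volume-excluding
#'   co-solutes (nm); default 0.51.
#' @param R_big radius of the largest common crowders (nm); default 42.
#' @param a_exp empirical scaling exponent of the diffusion law; default 0.53.
#' @param rho_ref reference cytosolic volume occupancy at which the diffusion
#'   law was calibrated; default 0.22 (dry mass ~0.3 g/mL over a protein
#'   specific density of 1.35 g/mL).
#' @param hydration_scale,hydration_offset coefficients of the hydrodynamic
#'   radius relation r_h = hydration_scale * (r + hydration_offset), offset in
#'   nm; defaults 1.3 and 0.14 (= 1.4 Angstrom).
#' @return an object of class `crowding_constants`.
#' @examples
#' crowding_constants()
#' @export
crowding_constants <- function(xi = 0.51, R_big = 42, a_exp = 0.53,
                               rho_ref = 0.22, hydration_scale = 1.3,
                               hydration_offset = 0.14) {
  vals <- c(xi = xi, R_big = R_big, a_exp = a_exp, rho_ref = rho_ref,
            hydration_scale = hydration_scale,
            hydration_offset = hydration_offset)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all crowding constants must be strictly positive")
  if (rho_ref >= 1)
    stop("rho_ref must lie in (0, 1)")
  structure(as.list(vals), class = "crowding_constants")
}

#' Hydrodynamic radius of a molecule
#'
#' Effective radius including the hydration shell,
#' r_h = 1.3 (r + 0.14 nm) at the default constants.
#'
#' @param r molecular radius (nm), vectorised; must be >= 0.
#' @param constants a [crowding_constants()] object.
#' @return hydrodynamic radius (nm).
#' @examples
#' hydrodynamic_radius(0.34)  # 0.624
#' @export
hydrodynamic_radius <- function(r, constants = crowding_constants()) {
  if (any(r < 0)) stop("radius must be non-negative")
  constants$hydration_scale * (r + constants$hydration_offset)
}

#' Diffusion slowdown exponent g(r)
#'
#' Scaling factor of the crowding-induced diffusion slowdown exp(-g rho) for
#' a spherical substrate of radius `r_substrate`. Derived from the empirical
#' cytosolic scaling law ln(D0/Dcyto) = (xi^2/R^2 + xi^2/r_h^2)^(-a/2),
#' normalised by the reference occupancy at which that law was measured, so
#' that g is the slowdown per unit occupancy. g is strictly increasing in the
#' substrate radius: larger molecules are slowed more.
#'
#' @param r_substrate substrate radius (nm), vectorised; must be > 0.
#' @param constants a [crowding_constants()] object.
#' @return dimensionless exponent g.
#' @examples
#' diffusion_exponent_g(0.34)  # ~5.06, a small metabolite
#' diffusion_exponent_g(2.4)   # ~12.2, a tRNA-sized molecule
#' @export
diffusion_exponent_g <- function(r_substrate,
                                 constants = crowding_constants()) {
  if (any(r_substrate <= 0)) stop("substrate radius must be positive")
  rh <- hydrodynamic_radius(r_substrate, constants)
  base <- constants$xi^2 / constants$R_big^2 + constants$xi^2 / rh^2
  base^(-constants$a_exp / 2) / constants$rho_ref
}

#' A molecular species modelled as a hard sphere
#'
#' @param name species label.
#' @param radius hard-sphere radius (nm), > 0.
#' @param crowds does the species participate in the crowding background?
#' @return an object of class `sphere_species`.
#' @examples
#' sphere_species("enzyme", 2.4)
#' @export
sphere_species <- function(name, radius, crowds = TRUE) {
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stop("radius must be a single positive number")
  structure(list(name = as.character(name), radius = radius,
                 crowds = isTRUE(crowds)),
            class = "sphere_species")
}

#' Catalyst-substrate complex by volume additivity
#'
#' The complex is modelled as a sphere whose volume equals the catalyst
#' volume plus the substrate volume: r = (r_cat^3 + r_sub^3)^(1/3).
#'
#' @param catalyst,substrate `sphere_species` objects.
#' @return a `sphere_species` for the complex.
#' @examples
#' complex_species(sphere_species("E", 2.4), sphere_species("S", 0.34))
#' @export
complex_species <- function(catalyst, substrate) {
  sphere_species(paste0(catalyst$name, ":", substrate$name),
                 (catalyst$radius^3 + substrate$radius^3)^(1 / 3))
}

#' Hard-sphere mixture state
#'
#' Number densities of the co-solute species forming the crowding background,
#' with the density moments used by scaled particle theory.
#'
#' @param species list of [sphere_species()] objects (species with
#'   `crowds = FALSE` are kept in the table but excluded from the moments).
#' @param conc concentrations in uM, same length as `species`, all >= 0.
#' @return an object of class `mixture_state` with elements `table`
#'   (name, radius, conc_uM, w in nm^-3) and `moments`
#'   (m0, m_r, m_r2, m_S, m_V).
#' @examples
#' mixture_state(list(sphere_species("E", 2.4)), conc = 500)
#' @export
mixture_state <- function(species = list(), conc = numeric()) {
  if (length(species) != length(conc))
    stop("species and conc must have the same length")
  if (any(conc < 0)) stop("densities must be non-negative")
  radius <- vapply(species, function(s) s$radius, numeric(1))
  crowds <- vapply(species, function(s) s$crowds, logical(1))
  nm <- vapply(species, function(s) s$name, character(1))
  w <- uM_to_nm3(conc)
  wc <- ifelse(crowds, w, 0)
  moments <- list(
    m0 = sum(wc), m_r = sum(wc * radius), m_r2 = sum(wc * radius^2),
    m_S = sum(wc * 4 * pi * radius^2),
    m_V = sum(wc * sphere_volume(radius)))
  if (moments$m_V >= 1)
    stop("mixture over-packed: occupied fraction >= 1")
  structure(list(
    table = data.frame(name = nm, radius = radius, conc_uM = conc,
                       w = w, crowds = crowds,
                       stringsAsFactors = FALSE),
    moments = moments), class = "mixture_state")
}

#' @export
print.mixture_state <- function(x, ...) {
  cat("Hard-sphere mixture:", nrow(x$table), "species, occupied fraction",
      format(x$moments$m_V, digits = 4), "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

# crowding entries (w in nm^-3, radius in nm) of a mixture
mixture_wr <- function(mixture) {
  keep <- mixture$table$crowds
  list(w = mixture$table$w[keep], r = mixture$table$radius[keep])
}

#' Scaled-particle-theory activity coefficient
#'
#' Natural log of the activity coefficient of a probe hard sphere inserted
#' into a hard-sphere mixture, from scaled particle theory. With the density
#' moments `<<X>> = sum_i w_i X_i` over the mixture (S_i = 4 pi r_i^2,
#' V_i = 4/3 pi r_i^3):
#' \deqn{\ln\gamma_i = -\ln(1-\langle\langle V\rangle\rangle)
#'   + \frac{r_i\langle\langle S\rangle\rangle + S_i\langle\langle r\rangle\rangle
#'     + V_i\langle\langle 1\rangle\rangle}{1-\langle\langle V\rangle\rangle}
#'   + \frac{r_i^2\langle\langle S\rangle\rangle^2
#'     + 2V_i\langle\langle r\rangle\rangle\langle\langle S\rangle\rangle}
#'     {2(1-\langle\langle V\rangle\rangle)^2}
#'   + \frac{V_i\langle\langle r\rangle\rangle_2\langle\langle S\rangle\rangle^2}
#'     {3(1-\langle\langle V\rangle\rangle)^3}}
#' with \eqn{\langle\langle r\rangle\rangle_2 = \sum_i w_i r_i^2}. The last
#' term equals the scaled-particle pressure contribution
#' \eqn{V_i\langle\langle S\rangle\rangle^3/(12\pi(1-\langle\langle V\rangle\rangle)^3)}
#' identically. ln gamma >= 0, equal to 0 only for an empty mixture.
#'
#' @param radius probe radius (nm), vectorised.
#' @param mixture a [mixture_state()].
#' @return ln gamma (dimensionless).
#' @examples
#' bg <- mixture_state(list(sphere_species("E", 2.4)), conc = 2000)
#' ln_activity_coefficient(2.4, bg)
#' @export
ln_activity_coefficient <- function(radius, mixture) {
  stopifnot(inherits(mixture, "mixture_state"))
  wr <- mixture_wr(mixture)
  .cc_lngamma(radius, wr$w, wr$r)
}

#' Kinetics of one crowding-adjusted reaction
#'
#' @param kcat turnover number (1/s), > 0.
#' @param KM0 Michaelis parameter in the low-crowding limit (uM), > 0.
#' @param theta dimensionless weight between the diffusion (encounter) and
#'   transition-state (bound conversion) sub-steps; theta = 0 is the pure
#'   diffusion limit, theta -> Inf the pure transition-state limit.
#' @param substrate,catalyst [sphere_species()] objects; the complex is
#'   derived by volume additivity.
#' @return an object of class `reaction_kinetics`.
#' @examples
#' reaction_kinetics(1, 130, 2.3, sphere_species("s", 0.34),
#'                   sphere_species("E", 2.4))
#' @export
reaction_kinetics <- function(kcat, KM0, theta, substrate, catalyst) {
  if (kcat <= 0 || KM0 <= 0 || theta < 0)
    stop("require kcat > 0, KM0 > 0, theta >= 0")
  structure(list(kcat = kcat, KM0 = KM0, theta = theta,
                 substrate = substrate, catalyst = catalyst,
                 complex = complex_species(catalyst, substrate)),
            class = "reaction_kinetics")
}

#' Gibbs perturbation factor Gamma
#'
#' Excluded-volume shift of the substrate-catalyst binding equilibrium,
#' Gamma = gamma_E gamma_S / gamma_ES. Gamma = 1 in an empty mixture;
#' Gamma > 1 (crowding favours the more compact complex) whenever the
#' mixture is non-empty and the complex obeys volume additivity.
#'
#' @param kin a [reaction_kinetics()].
#' @param mixture a [mixture_state()] describing the crowding background.
#' @return Gamma (dimensionless).
#' @export
gibbs_perturbation <- function(kin, mixture) {
  lg <- ln_activity_coefficient(
    c(kin$substrate$radius, kin$catalyst$radius, kin$complex$radius), mixture)
  exp(lg[1] + lg[2] - lg[3])
}

#' Crowding-adjusted Michaelis parameter KM*
#'
#' \deqn{K_M^* = K_M^0\,\frac{\Gamma + \theta e^{-g\rho}}
#'   {(1+\theta)\,\Gamma\, e^{-g\rho}}}
#' where Gamma is the Gibbs perturbation factor and exp(-g rho) the diffusion
#' slowdown of the substrate. Limits: KM* = KM0 at rho = 0, Gamma = 1;
#' theta = 0 gives the pure diffusion limit KM0 exp(g rho); theta -> Inf the
#' pure transition-state limit KM0 / Gamma. `mode = "diffusion_only"` forces
#' Gamma = 1; `mode = "transition_only"` forces g = 0 (then KM* decreases
#' with Gamma towards the plateau KM0 / (1 + theta)).
#'
#' @param kin a [reaction_kinetics()].
#' @param rho volume occupancy in \[0, 1).
#' @param mixture optional [mixture_state()]; if supplied, Gamma and the
#'   individual ln gamma values are computed from it (and `Gamma` is ignored).
#' @param Gamma Gibbs perturbation factor, used when `mixture` is NULL.
#' @param mode one of "full", "diffusion_only", "transition_only".
#' @param constants a [crowding_constants()] object.
#' @return an object of class `km_star_breakdown`: ln gamma of substrate /
#'   catalyst / complex (NA without a mixture), `Gamma`, `g`,
#'   `diffusion_factor` = exp(-g rho), `KM_star` (uM), and `mode`.
#' @examples
#' kin <- reaction_kinetics(1, 130, 2.3, sphere_species("s", 0.34),
#'                          sphere_species("E", 2.4))
#' km_star(kin, rho = 0.2, Gamma = 1.5)
#' @export
km_star <- function(kin, rho, mixture = NULL, Gamma = 1,
                    mode = c("full", "diffusion_only", "transition_only"),
                    constants = crowding_constants()) {
  mode <- match.arg(mode)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  lg <- c(NA_real_, NA_real_, NA_real_)
  if (!is.null(mixture)) {
    lg <- ln_activity_coefficient(
      c(kin$substrate$radius, kin$catalyst$radius, kin$complex$radius),
      mixture)
    Gamma <- exp(lg[1] + lg[2] - lg[3])
  }
  g <- diffusion_exponent_g(kin$substrate$radius, constants)
  if (mode == "diffusion_only") Gamma <- 1
  ed <- if (mode == "transition_only") 1 else exp(-g * rho)
  structure(list(
    gamma_ln_substrate = lg[1], gamma_ln_catalyst = lg[2],
    gamma_ln_complex = lg[3], Gamma = Gamma,
    g = if (mode == "transition_only") 0 else g,
    diffusion_factor = ed,
    KM_star = .cc_km_star_formula(kin$KM0, Gamma, kin$theta, ed),
    mode = mode), class = "km_star_breakdown")
}

#' @export
print.km_star_breakdown <- function(x, ...) {
  cat(sprintf("KM* = %.6g uM (mode %s): Gamma = %.5g, exp(-g rho) = %.5g\n",
              x$KM_star, x$mode, x$Gamma, x$diffusion_factor))
  invisible(x)
}

#' Self-consistent binding equilibrium under crowding
#'
#' Solves the coupled system in which the complex concentration
#' \[ES\] = \[E_total\]\[S_free\]/(\[S_free\] + KM*) shifts the mixture
#' composition that determines KM* itself. Starting from the fully free
#' composition, KM* is recomputed from the current free/bound mixture (plus
#' an optional inert background) and the complex is reset to the exact
#' solution of the binding relation at that KM*, until every KM* changes by
#' less than `tol` relative (default 1e-5, i.e. 0.001\%). Catalyst and
#' substrate mass conservation hold exactly at every iteration. The complex
#' update is damped by 0.5 if the KM* iteration oscillates.
#'
#' @param catalyst_total,substrate_total total concentrations (uM), >= 0.
#' @param kin a [reaction_kinetics()].
#' @param background optional [mixture_state()] of additional inert crowders.
#' @param n_lump number of identical lumped reactions sharing the totals
#'   (the effective dissociation on totals is `n_lump * KM*`); default 1.
#' @param mode KM* mode, see [km_star()].
#' @param tol relative KM* convergence tolerance.
#' @param max_iter maximum iterations (default 500); non-convergence is an
#'   error carrying the last relative change.
#' @param constants a [crowding_constants()] object.
#' @return an object of class `binding_equilibrium` with totals, free
#'   concentrations, `complex` (all uM), `KM_star` (uM), `Gamma`,
#'   `diffusion_factor`, occupancy of the reaction mixture, `iterations`,
#'   and `converged`.
#' @examples
#' kin <- reaction_kinetics(1, 130, 2.3, sphere_species("s", 0.34),
#'                          sphere_species("E", 2.4))
#' solve_binding_equilibrium(1000, 5000, kin)
#' @export
solve_binding_equilibrium <- function(catalyst_total, substrate_total, kin,
                                      background = NULL, n_lump = 1,
                                      mode = c("full", "diffusion_only",
                                               "transition_only"),
                                      tol = 1e-5, max_iter = 500,
                                      constants = crowding_constants()) {
  mode <- match.arg(mode)
  if (catalyst_total < 0 || substrate_total < 0)
    stop("totals must be non-negative")
  bw <- numeric(0); br <- numeric(0)
  if (!is.null(background)) {
    wr <- mixture_wr(background)
    bw <- wr$w; br <- wr$r
  }
  g <- diffusion_exponent_g(kin$substrate$radius, constants)
  res <- .cc_binding_solve(
    uM_to_nm3(catalyst_total), uM_to_nm3(substrate_total),
    uM_to_nm3(kin$KM0), kin$theta,
    kin$substrate$radius, kin$catalyst$radius, kin$complex$radius,
    g, n_lump, bw, br,
    switch(mode, full = 0L, diffusion_only = 1L, transition_only = 2L),
    tol, as.integer(max_iter))
  if (!res$converged)
    stop(sprintf(
      "binding equilibrium did not converge within %d iterations", max_iter))
  structure(list(
    totals = c(catalyst = catalyst_total, substrate = substrate_total),
    free = c(catalyst = nm3_to_uM(res$catalyst_free),
             substrate = nm3_to_uM(res$substrate_free)),
    complex = nm3_to_uM(res$complex),
    KM_star = nm3_to_uM(res$km_star),
    Gamma = res$Gamma, diffusion_factor = res$diffusion_factor,
    gamma_ln = c(substrate = res$gamma_ln_substrate,
                 catalyst = res$gamma_ln_catalyst,
                 complex = res$gamma_ln_complex),
    occupancy = res$occupancy,
    n_lump = n_lump, mode = mode,
    iterations = res$iterations, converged = res$converged),
    class = "binding_equilibrium")
}

#' @export
print.binding_equilibrium <- function(x, ...) {
  cat(sprintf(
    "Binding equilibrium (%d iterations): [ES] = %.6g uM, KM* = %.6g uM\n",
    x$iterations, x$complex, x$KM_star))
  invisible(x)
}
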