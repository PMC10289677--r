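# Independent oracles and shared fixtures for the test suite.

# ---- hard-sphere fluid Monte Carlo + Widom insertion ------------------------
# Monodisperse hard spheres of radius 1 in a periodic cubic box, equilibrated
# by single-particle Metropolis displacements from a simple-cubic lattice.
# Used as the independent thermodynamic oracle for the SPT activity
# coefficients: ln gamma = -ln <e^{-beta dU}> = -ln P(random insertion of the
# probe is overlap-free).

hs_sweeps <- function(pos, L, n_sweeps, delta = 0.35) {
  n <- nrow(pos)
  for (sw in seq_len(n_sweeps)) {
    for (i in seq_len(n)) {
      prop <- (pos[i, ] + runif(3, -delta, delta)) %% L
      d <- sweep(pos[-i, , drop = FALSE], 2, prop)
      d <- d - L * round(d / L)          # minimum image
      if (min(rowSums(d * d)) >= 4) pos[i, ] <- prop
    }
  }
  pos
}

hs_insertion_prob <- function(pos, L, contact2, n_insert) {
  hits <- 0
  pts <- matrix(runif(3 * n_insert, 0, L), ncol = 3)
  for (j in seq_len(n_insert)) {
    d <- sweep(pos, 2, pts[j, ])
    d <- d - L * round(d / L)
    if (min(rowSums(d * d)) >= contact2) hits <- hits + 1
  }
  hits / n_insert
}

# Equilibrate a monodisperse hard-sphere fluid (radius 1) at packing fraction
# phi and estimate ln gamma for each probe radius in `probes` by Widom
# insertion, averaging over `n_samples` configurations taken `gap` sweeps
# apart after `burn` burn-in sweeps. The standard error is computed across
# configurations, so it includes both insertion noise and configurational
# correlation.
widom_chain <- function(phi, probes = 1, n = 500, burn = 200,
                        n_samples = 16, gap = 12, n_insert = 6500,
                        seed = 1) {
  set.seed(seed)
  L <- (n * 4 * pi / 3 / phi)^(1 / 3)
  k <- ceiling(n^(1 / 3))
  a <- L / k
  stopifnot(a >= 2)                      # lattice start must be overlap-free
  g <- as.matrix(expand.grid(0:(k - 1), 0:(k - 1), 0:(k - 1)))[seq_len(n), ]
  pos <- hs_sweeps((g + 0.5) * a, L, burn)
  lg <- matrix(NA_real_, n_samples, length(probes))
  for (s in seq_len(n_samples)) {
    if (s > 1) pos <- hs_sweeps(pos, L, gap)
    for (j in seq_along(probes))
      lg[s, j] <- -log(hs_insertion_prob(pos, L, (1 + probes[j])^2, n_insert))
  }
  data.frame(probe = probes,
             lngamma = colMeans(lg),
             se = apply(lg, 2, stats::sd) / sqrt(n_samples),
             n_insert_total = n_samples * n_insert)
}

# SPT ln gamma for a probe of radius q in a monodisperse radius-1 background
# at packing fraction phi, via the package mixture machinery.
spt_lngamma_mono <- function(q, phi) {
  conc <- nm3_to_uM(phi / (4 * pi / 3))
  mix <- mixture_state(list(sphere_species("bg", 1)), conc = conc)
  ln_activity_coefficient(q, mix)
}

# ---- crowding-free Michaelis-Menten closed form -----------------------------
mm_complex <- function(E_tot, S_tot, K) {
  b <- E_tot + S_tot + K
  2 * E_tot * S_tot / (b + sqrt(b^2 - 4 * E_tot * S_tot))
}

# ---- shared whole-cell scans (computed once per test run) -------------------
# Several acceptance criteria interrogate the same (N, s_ext) solution set;
# cache the scans in a session environment so each is computed once.
.wc_cache <- new.env(parent = emptyenv())

wc_scan_cached <- function(N, s_ext, rho_grid = seq(0.12, 0.30, by = 0.005),
                           n_restarts = 20, seed = 1, ...) {
  key <- paste(N, s_ext, min(rho_grid), max(rho_grid),
               length(rho_grid), n_restarts, seed, sep = "_")
  if (is.null(.wc_cache[[key]])) {
    .wc_cache[[key]] <- optimal_occupancy(
      wholecell_params(N = N, s_ext = s_ext, ...),
      rho_grid = rho_grid, n_restarts = n_restarts, seed = seed)
  }
  .wc_cache[[key]]
}
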