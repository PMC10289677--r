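#' Specific densities of the dry-mass components
#'
#' @param protein_density specific density of protein (g/mL); default 1.35.
#' @param ribosome_density specific density of the 70S ribosome (g/mL);
#'   default 1.637.
#' @param ribosome_rna_mass_fraction RNA mass fraction of the ribosome;
#'   default 0.6187 (the remaining mass is protein).
#' @return an object of class `composition_densities`.
#' @export
composition_densities <- function(protein_density = 1.35,
                                  ribosome_density = 1.637,
                                  ribosome_rna_mass_fraction = 0.6187) {
  stopifnot(protein_density > 0, ribosome_density > 0,
            ribosome_rna_mass_fraction > 0, ribosome_rna_mass_fraction < 1)
  structure(list(protein_density = protein_density,
                 ribosome_density = ribosome_density,
                 ribosome_rna_mass_fraction = ribosome_rna_mass_fraction),
            class = "composition_densities")
}

#' RNA specific density derived from ribosome composition
#'
#' Inverts the mass-fraction-weighted linear mixing rule
#' rho_ribosome = f_RNA rho_RNA + (1 - f_RNA) rho_protein for rho_RNA.
#' Defaults give 1.81 g/mL.
#'
#' @param cd a [composition_densities()] object.
#' @return RNA specific density (g/mL).
#' @examples
#' rna_density_from_ribosome()  # 1.81
#' @export
rna_density_from_ribosome <- function(cd = composition_densities()) {
  f <- cd$ribosome_rna_mass_fraction
  (cd$ribosome_density - (1 - f) * cd$protein_density) / f
}

#' Specific density of cytosolic dry mass
#'
#' D(r) = rho_protein / (1 + r) + rho_RNA r / (1 + r): the convex
#' combination of the protein and RNA specific densities weighted by their
#' mass shares, where r is the RNA/protein mass ratio. D is strictly
#' increasing in r, from rho_protein (1.35 g/mL) to rho_RNA (1.81 g/mL).
#'
#' @param r RNA/protein mass ratio, >= 0, vectorised.
#' @param protein_density,rna_density specific densities (g/mL).
#' @return D (g/mL).
#' @examples
#' specific_dry_mass_density(0.086)  # ~1.39
#' @export
specific_dry_mass_density <- function(r, protein_density = 1.35,
                                      rna_density = 1.81) {
  if (any(r < 0)) stop("RNA/protein ratio must be non-negative")
  protein_density / (1 + r) + rna_density * r / (1 + r)
}

#' Volume occupancy from dry-mass density
#'
#' rho = rho_DM / D(r): the fraction of cytosolic volume occupied by dry
#' mass, given the measured dry-mass density and the RNA/protein mass ratio.
#'
#' @param rho_dm cytosolic dry-mass density (g/mL), >= 0, vectorised.
#' @param r RNA/protein mass ratio.
#' @param ... passed to [specific_dry_mass_density()].
#' @return occupancy (volume fraction).
#' @examples
#' occupancy_from_density(0.31, 0.086)
#' occupancy_from_density(0.28, 0.33)
#' @export
occupancy_from_density <- function(rho_dm, r, ...) {
  if (any(rho_dm < 0)) stop("rho_dm must be non-negative")
  rho_dm / specific_dry_mass_density(r, ...)
}

#' RNA/protein mass ratio from growth rate
#'
#' The growth law r = 0.087 + mu / 4.5 h^-1 (`law = "scott"`), or linear
#' interpolation of user-supplied (mu, r) measurements (`law = "table"`,
#' clamped at the endpoints).
#'
#' @param mu growth rate (1/h), >= 0, vectorised.
#' @param law "scott" or "table".
#' @param table data.frame/list with elements `mu` and `r` for table mode.
#' @return RNA/protein mass ratio.
#' @examples
#' rna_protein_ratio(0)            # 0.087
#' rna_protein_ratio(0.35, "table",
#'                   table = list(mu = c(0, 0.7), r = c(0.086, 0.225)))
#' @export
rna_protein_ratio <- function(mu, law = c("scott", "table"), table = NULL) {
  law <- match.arg(law)
  if (any(mu < 0)) stop("mu must be non-negative")
  if (law == "scott") return(0.087 + mu / 4.5)
  if (is.null(table) || length(table$mu) == 0)
    stop("table mode requires (mu, r) pairs")
  if (length(table$mu) == 1) return(rep(table$r, length(mu)))
  stats::approx(table$mu, table$r, xout = mu, rule = 2)$y
}
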