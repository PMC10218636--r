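#' Carbon species registry
#'
#' All internal bookkeeping in this package is done in carbon-mmol
#' (mmol_C), so that uptake rates, product formation rates and yields can be
#' summed into a closing carbon balance. This registry maps the species
#' handled by the chemostat model to their carbon content and molar mass.
#'
#' @param extra optional `data.frame` with columns `name`, `carbon_atoms`,
#'   `molar_mass` appended to (or overriding) the built-in species.
#' @return A `data.frame` with columns `name`, `carbon_atoms` (C atoms per
#'   molecule) and `molar_mass` (g/mol).
#' @examples
#' species_registry()
#' @export
species_registry <- function(extra = NULL) {
  reg <- data.frame(
    name         = c("glucose", "ethanol", "glycerol", "acetate",
                     "succinate", "co2", "trehalose", "glycogen"),
    carbon_atoms = c(6, 2, 3, 2, 4, 1, 12, 6),
    molar_mass   = c(180.156, 46.068, 92.094, 60.052,
                     118.088, 44.009, 342.296, 162.141),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    stopifnot(all(c("name", "carbon_atoms", "molar_mass") %in% names(extra)))
    reg <- rbind(reg[!reg$name %in% extra$name, ], extra[names(reg)])
  }
  if (any(reg$carbon_atoms < 1)) stop("carbon_atoms must be >= 1")
  rownames(reg) <- reg$name
  reg
}

#' Define a single carbon species
#'
#' @param name species name.
#' @param carbon_atoms carbon atoms per molecule (>= 1).
#' @param molar_mass molar mass in g/mol.
#' @return one-row `data.frame` suitable for [species_registry()]'s `extra`.
#' @export
carbon_species <- function(name, carbon_atoms, molar_mass) {
  if (carbon_atoms < 1) stop("carbon_atoms must be >= 1")
  if (molar_mass <= 0) stop("molar_mass must be positive")
  data.frame(name = name, carbon_atoms = carbon_atoms,
             molar_mass = molar_mass, stringsAsFactors = FALSE)
}

#' Unit conversions between g/L, mmol/L and mmol_C/L
#'
#' @param x concentration value(s).
#' @param species species name resolved in `registry`.
#' @param registry species registry, see [species_registry()].
#' @return converted concentration value(s).
#' @name carbon_units
NULL

.species_row <- function(species, registry) {
  row <- registry[registry$name == species, ]
  if (nrow(row) != 1)
    stop("unknown species '", species, "'; add it to the registry")
  row
}

#' @rdname carbon_units
#' @export
g_to_mmol_c <- function(x, species, registry = species_registry()) {
  row <- .species_row(species, registry)
  x / row$molar_mass * 1000 * row$carbon_atoms
}

#' @rdname carbon_units
#' @export
mmol_to_mmol_c <- function(x, species, registry = species_registry()) {
  x * .species_row(species, registry)$carbon_atoms
}

#' @rdname carbon_units
#' @export
mmol_c_to_mmol <- function(x, species, registry = species_registry()) {
  x / .species_row(species, registry)$carbon_atoms
}

#' @rdname carbon_units
#' @export
mmol_c_to_g <- function(x, species, registry = species_registry()) {
  row <- .species_row(species, registry)
  x / row$carbon_atoms / 1000 * row$molar_mass
}

# mmol_C contained in one gram of dry biomass for a given carbon mass fraction
biomass_mmolc_per_g <- function(carbon_fraction) {
  carbon_fraction * 1000 / 12.011
}
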