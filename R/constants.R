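#' Physicochemical and stoichiometric model constants
#'
#' Bundle of all constants used by the flux bookkeeping: the CO2 hydration
#' equilibrium, the palmitate oxidation stoichiometry and energetics, the
#' glycolytic lactate yield, and mass/cell conversion factors. The canonical
#' rate unit throughout the package is nmol h^-1 cm^-2 of culture area.
#'
#' @param pka_co2 Overall pKa of CO2 in aqueous solution at 37 C (dimensionless).
#' @param rq_palmitate Respiratory quotient (mol CO2 per mol O2) for pure fat
#'   oxidation. The stoichiometric alternative for palmitate is 16/23.
#' @param h_per_o2_net Net H+ released to the medium per O2 consumed during
#'   complete palmitate oxidation, after accounting for incomplete CO2
#'   hydration (dimensionless).
#' @param caloric_equiv_o2 Caloric equivalent of oxygen, uJ per nmol O2.
#' @param gibbs_palmitate Gibbs energy of palmitate combustion, uJ per pmol.
#' @param o2_per_palmitate mol O2 required to fully oxidize one mol palmitate.
#' @param lactate_per_glucose mol lactate produced per mol glucose through
#'   glycolysis.
#' @param dna_per_cell pg DNA per cell.
#' @param mw_tripalmitin Molar mass of tripalmitin, g/mol.
#' @param mw_anhydroglucose Molar mass of the glucose residue within glycogen,
#'   g/mol.
#'
#' @return An object of class `model_constants` (a named list).
#' @examples
#' cst <- model_constants()
#' cst$h_per_o2_net
#' @export
model_constants <- function(pka_co2 = 6.093,
                            rq_palmitate = 0.7,
                            h_per_o2_net = 0.65,
                            caloric_equiv_o2 = 431,
                            gibbs_palmitate = 9.8,
                            o2_per_palmitate = 23,
                            lactate_per_glucose = 2,
                            dna_per_cell = 6,
                            mw_tripalmitin = 807.3,
                            mw_anhydroglucose = 162) {
  cst <- list(
    pka_co2 = pka_co2,
    rq_palmitate = rq_palmitate,
    h_per_o2_net = h_per_o2_net,
    caloric_equiv_o2 = caloric_equiv_o2,
    gibbs_palmitate = gibbs_palmitate,
    o2_per_palmitate = o2_per_palmitate,
    lactate_per_glucose = lactate_per_glucose,
    dna_per_cell = dna_per_cell,
    mw_tripalmitin = mw_tripalmitin,
    mw_anhydroglucose = mw_anhydroglucose
  )
  for (nm in names(cst)) {
    v <- cst[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("model_constants: '", nm, "' must be a single positive finite number",
           call. = FALSE)
    }
  }
  if (cst$h_per_o2_net > cst$rq_palmitate) {
    stop("model_constants: h_per_o2_net must not exceed rq_palmitate ",
         "(net acidification cannot exceed CO2 produced per O2)", call. = FALSE)
  }
  structure(cst, class = "model_constants")
}

#' @export
print.model_constants <- function(x, ...) {
  cat("Model constants (brown adipocyte flux bookkeeping)\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Culture geometry and normalization factors
#'
#' Describes one culture well: growth area, areal protein and DNA content,
#' the derived cell density, assay medium volume and supernatant accumulation
#' time. Defaults reflect typical differentiated primary brown adipocyte
#' cultures in an XF-96 microplate.
#'
#' @param area_cm2 Growth area per well, cm2 (XF-96 default 0.106).
#' @param protein_ug_per_cm2 ug protein per cm2.
#' @param dna_pg_per_cm2 pg DNA per cm2.
#' @param cells_per_cm2 Cells per cm2; when `NULL` derived from the DNA density
#'   via [cells_from_dna()].
#' @param dna_per_cell pg DNA per cell used for the derivation.
#' @param medium_volume_uL Assay medium volume per well, uL.
#' @param exposure_h Supernatant accumulation time, hours.
#'
#' @return An object of class `culture_geometry` (a named list).
#' @examples
#' culture_geometry()$cells_per_cm2  # 13819
#' @export
culture_geometry <- function(area_cm2 = 0.106,
                             protein_ug_per_cm2 = 89,
                             dna_pg_per_cm2 = 82916,
                             cells_per_cm2 = NULL,
                             dna_per_cell = 6,
                             medium_volume_uL = 180,
                             exposure_h = 1) {
  if (is.null(cells_per_cm2)) {
    cells_per_cm2 <- cells_from_dna(dna_pg_per_cm2, dna_per_cell)
  }
  geo <- list(
    area_cm2 = area_cm2,
    protein_ug_per_cm2 = protein_ug_per_cm2,
    dna_pg_per_cm2 = dna_pg_per_cm2,
    cells_per_cm2 = cells_per_cm2,
    dna_per_cell = dna_per_cell,
    medium_volume_uL = medium_volume_uL,
    exposure_h = exposure_h
  )
  for (nm in names(geo)) {
    v <- geo[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("culture_geometry: '", nm, "' must be a single positive finite number",
           call. = FALSE)
    }
  }
  structure(geo, class = "culture_geometry")
}

#' @export
print.culture_geometry <- function(x, ...) {
  cat("Culture geometry\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Cell number from areal DNA content
#'
#' Converts an areal DNA density into a cell density assuming a fixed DNA
#' content per cell, rounding to the nearest whole cell.
#'
#' @param dna_pg_per_cm2 Areal DNA density, pg per cm2. Must be positive.
#' @param pg_per_cell DNA content per cell, pg (default 6).
#' @return Cells per cm2 (integer-valued numeric).
#' @examples
#' cells_from_dna(82916, 6)  # 13819
#' @export
cells_from_dna <- function(dna_pg_per_cm2, pg_per_cell = 6) {
  stopifnot(is.numeric(dna_pg_per_cm2), is.numeric(pg_per_cell))
  if (any(!is.finite(dna_pg_per_cm2)) || any(dna_pg_per_cm2 <= 0)) {
    stop("cells_from_dna: dna_pg_per_cm2 must be positive", call. = FALSE)
  }
  if (any(!is.finite(pg_per_cell)) || any(pg_per_cell <= 0)) {
    stop("cells_from_dna: pg_per_cell must be positive", call. = FALSE)
  }
  round(dna_pg_per_cm2 / pg_per_cell)
}

#' Re-express an areal rate on another normalization basis
#'
#' The package's canonical rate unit is per cm2 of culture area. This helper
#' converts such a rate to a per-cell or per-ug-protein basis, or to a mass
#' rate, using the well geometry. Unit bookkeeping: a molar rate in
#' nmol h^-1 cm^-2 times a molar mass in g/mol yields ng h^-1 cm^-2.
#' The division by cells or protein is unit-agnostic, so a mass rate (e.g.
#' ng h^-1 cm^-2) may equally be passed with `molar_mass = NULL` to obtain a
#' mass rate per cell or per ug protein.
#'
#' @param rate Rate per cm2 (vectorized).
#' @param geometry A [culture_geometry()].
#' @param basis One of `"per_cell"`, `"per_ug_protein"`, `"mass_per_cm2"`.
#' @param molar_mass g/mol; required for `"mass_per_cm2"`, optional for the
#'   other bases (when supplied, the result is a mass rate in ng).
#' @return The converted rate (same length as `rate`).
#' @examples
#' convert_rate(28.2, basis = "mass_per_cm2", molar_mass = 807.3)  # ~22.77 ug equivalent in ng
#' @export
convert_rate <- function(rate, geometry = culture_geometry(),
                         basis = c("per_cell", "per_ug_protein", "mass_per_cm2"),
                         molar_mass = NULL) {
  basis <- match.arg(basis)
  stopifnot(is.numeric(rate))
  mass_factor <- 1
  if (!is.null(molar_mass)) {
    if (!is.numeric(molar_mass) || molar_mass <= 0) {
      stop("convert_rate: molar_mass must be positive", call. = FALSE)
    }
    mass_factor <- molar_mass  # nmol x g/mol -> ng
  }
  switch(basis,
    per_cell = {
      if (geometry$cells_per_cm2 <= 0) stop("convert_rate: zero cell density", call. = FALSE)
      rate * mass_factor / geometry$cells_per_cm2
    },
    per_ug_protein = {
      if (geometry$protein_ug_per_cm2 <= 0) stop("convert_rate: zero protein density", call. = FALSE)
      rate * mass_factor / geometry$protein_ug_per_cm2
    },
    mass_per_cm2 = {
      if (is.null(molar_mass)) {
        stop("convert_rate: molar_mass is required for a mass basis", call. = FALSE)
      }
      rate * molar_mass
    }
  )
}

#' Mass of a sphere
#'
#' Mass in ng of a sphere of given diameter and density, used to put areal
#' glycogen stores into an intuitive per-cell perspective (a 50-um water
#' droplet weighs about 65.5 ng).
#'
#' @param diameter_um Sphere diameter, um. Must be positive.
#' @param density_g_per_ml Density, g/mL (water = 1).
#' @return Mass in ng.
#' @examples
#' sphere_mass(50)  # 65.45 ng
#' @export
sphere_mass <- function(diameter_um, density_g_per_ml = 1) {
  stopifnot(is.numeric(diameter_um), is.numeric(density_g_per_ml))
  if (any(diameter_um <= 0) || any(density_g_per_ml <= 0)) {
    stop("sphere_mass: diameter and density must be positive", call. = FALSE)
  }
  # um^3 -> mL is 1e-12; g -> ng is 1e9; net factor 1e-3
  (4 / 3) * pi * (diameter_um / 2)^3 * density_g_per_ml * 1e-3
}

#' Display rounding used in flux tables
#'
#' One decimal, half away from zero, matching the precision at which areal
#' flux rates are conventionally reported.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
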