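#' Equilibrium fraction of dissolved CO2 that is hydrated
#'
#' Metabolic CO2 hydrates to carbonic acid, which at physiological pH
#' dissociates to bicarbonate plus a free proton. The fraction of dissolved
#' CO2 present in the dissociated (acidifying) form follows the
#' Henderson-Hasselbalch equilibrium `1 / (1 + 10^(pKa - pH))`, using the
#' overall pKa of CO2 in aqueous solution at 37 C.
#'
#' @param ph Medium pH.
#' @param pka Overall pKa (default 6.093).
#' @return Fraction in (0, 1); vectorized.
#' @examples
#' hydrated_fraction(7.4)  # ~0.953
#' @export
hydrated_fraction <- function(ph, pka = 6.093) {
  stopifnot(is.numeric(ph), is.numeric(pka))
  1 / (1 + 10^(pka - ph))
}

#' CO2 production rate from oxygen consumption
#'
#' Multiplies OCR by a CO2-per-O2 factor. The physiological default is the
#' respiratory quotient of pure fat oxidation (0.7). A documented
#' "calibrated" alternative of 0.62 is available because reference flux
#' tables for brown adipocytes show CO2/OCR ratios of 0.613-0.625 across all
#' conditions (see the methods vignette); pass `co2_per_o2 = 0.62` or use
#' `co2_mode = "calibrated"` in [flux_model()].
#'
#' @param ocr Oxygen consumption, nmol O2 h^-1 cm^-2 (non-negative, vectorized).
#' @param co2_per_o2 mol CO2 produced per mol O2 consumed (default 0.7).
#' @return CO2 production, nmol h^-1 cm^-2.
#' @examples
#' co2_from_ocr(100)        # 70
#' co2_from_ocr(151.8, 0.62)
#' @export
co2_from_ocr <- function(ocr, co2_per_o2 = 0.7) {
  stopifnot(is.numeric(ocr), is.numeric(co2_per_o2))
  if (any(ocr < 0, na.rm = TRUE)) stop("co2_from_ocr: ocr must be >= 0", call. = FALSE)
  if (any(co2_per_o2 <= 0)) stop("co2_from_ocr: co2_per_o2 must be positive", call. = FALSE)
  ocr * co2_per_o2
}

#' Proton production attributable to respiratory CO2
#'
#' Net H+ released to the medium per O2 consumed, `ocr * h_per_o2`. The
#' default 0.65 is the fixed net coefficient for complete palmitate
#' oxidation; it factorizes as (CO2 per O2) x (fraction of CO2 hydrated),
#' e.g. (16/23) x 0.934 = 0.65 (see [h_per_o2_from_parts()]).
#'
#' @param ocr Oxygen consumption, nmol O2 h^-1 cm^-2 (non-negative).
#' @param h_per_o2 Net H+ per O2 (default 0.65).
#' @return Proton production, nmol H+ h^-1 cm^-2.
#' @examples
#' ppr_from_co2(165.6)  # 107.64
#' @export
ppr_from_co2 <- function(ocr, h_per_o2 = 0.65) {
  stopifnot(is.numeric(ocr), is.numeric(h_per_o2))
  if (any(ocr < 0, na.rm = TRUE)) stop("ppr_from_co2: ocr must be >= 0", call. = FALSE)
  ocr * h_per_o2
}

#' Compose the net H+/O2 coefficient from its parts
#'
#' Identity behind the fixed 0.65 coefficient: net H+ per O2 equals the CO2
#' yield per O2 times the fraction of that CO2 that is hydrated and
#' dissociates.
#'
#' @param co2_per_o2 mol CO2 per mol O2 (e.g. the palmitate stoichiometry 16/23).
#' @param hydrated_frac Realized hydrated fraction (e.g. 0.934).
#' @return Net H+ per O2.
#' @examples
#' h_per_o2_from_parts(16 / 23, 0.934)  # ~0.65
#' @export
h_per_o2_from_parts <- function(co2_per_o2, hydrated_frac) {
  stopifnot(is.numeric(co2_per_o2), is.numeric(hydrated_frac))
  co2_per_o2 * hydrated_frac
}

#' Proton production from an exported organic acid
#'
#' Lactic acid and free fatty acids dissociate quantitatively at
#' physiological pH, so each exported molecule releases a stoichiometric
#' number of protons (one for both lactate and FFA).
#'
#' @param release_rate Export rate, nmol h^-1 cm^-2 (non-negative).
#' @param protons_per_molecule Protons released per molecule (default 1).
#' @return Proton production, nmol H+ h^-1 cm^-2.
#' @export
ppr_from_metabolite <- function(release_rate, protons_per_molecule = 1) {
  stopifnot(is.numeric(release_rate), is.numeric(protons_per_molecule))
  if (any(release_rate < 0, na.rm = TRUE)) {
    stop("ppr_from_metabolite: release_rate must be >= 0", call. = FALSE)
  }
  release_rate * protons_per_molecule
}

#' Decompose proton production into its source molecules
#'
#' Builds the three modeled contributions to extracellular proton production
#' — carbonic acid from respiratory CO2, lactic acid, and exported free fatty
#' acids — sums them, and (when an instrument-measured PPR is supplied)
#' reports the residual `measured - modeled`. Only exported FFAs acidify the
#' medium; oxidized and re-esterified FFAs never leave the cell.
#'
#' @param ocr Oxygen consumption, nmol O2 h^-1 cm^-2.
#' @param lactate_release Lactate export, nmol h^-1 cm^-2.
#' @param ffa_release FFA export, nmol h^-1 cm^-2.
#' @param measured_ppr Optional instrument PPR, nmol H+ h^-1 cm^-2.
#' @param constants A [model_constants()]; supplies `h_per_o2_net`.
#' @return A `data.frame` of class `ppr_decomposition` with columns
#'   `from_co2`, `from_lactate`, `from_ffa`, `modeled_total`,
#'   `measured_total`, `residual` (all vectorized over the inputs).
#' @examples
#' decompose_ppr(ocr = 50.4, lactate_release = 59.4, ffa_release = 15.6)
#' @export
decompose_ppr <- function(ocr, lactate_release, ffa_release,
                          measured_ppr = NULL, constants = model_constants()) {
  stopifnot(is.numeric(ocr), is.numeric(lactate_release), is.numeric(ffa_release))
  if (any(c(ocr, lactate_release, ffa_release) < 0, na.rm = TRUE)) {
    stop("decompose_ppr: all rates must be >= 0", call. = FALSE)
  }
  from_co2 <- ppr_from_co2(ocr, constants$h_per_o2_net)
  from_lactate <- ppr_from_metabolite(lactate_release)
  from_ffa <- ppr_from_metabolite(ffa_release)
  modeled <- from_co2 + from_lactate + from_ffa
  measured <- if (is.null(measured_ppr)) NA_real_ else measured_ppr
  out <- data.frame(from_co2 = from_co2, from_lactate = from_lactate,
                    from_ffa = from_ffa, modeled_total = modeled,
                    measured_total = measured,
                    residual = measured - modeled)
  class(out) <- c("ppr_decomposition", "data.frame")
  out
}

#' Convert a raw extracellular acidification rate to a proton rate
#'
#' Divides the instrument's pH-change readout by the medium buffer power and
#' optionally normalizes per hour and culture area. With `buffer_power` in
#' mpH per nmol H+ in the assay volume, the quotient is nmol H+ min^-1
#' well^-1; supplying `well_area` converts to nmol H+ h^-1 cm^-2 via
#' `x * 60 / well_area`.
#'
#' @param ecar Extracellular acidification rate, mpH min^-1 (vectorized).
#' @param buffer_power mpH per nmol H+ in the assay volume; must be positive.
#' @param well_area Optional growth area, cm2, for areal normalization.
#' @return Proton rate (per well per minute, or areal per hour if `well_area`
#'   is given).
#' @export
ecar_to_ppr <- function(ecar, buffer_power, well_area = NULL) {
  stopifnot(is.numeric(ecar), is.numeric(buffer_power))
  if (any(buffer_power <= 0)) {
    stop("ecar_to_ppr: buffer_power must be positive", call. = FALSE)
  }
  ppr <- ecar / buffer_power
  if (!is.null(well_area)) {
    if (!is.numeric(well_area) || well_area <= 0) {
      stop("ecar_to_ppr: well_area must be positive", call. = FALSE)
    }
    ppr <- ppr * 60 / well_area
  }
  ppr
}
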