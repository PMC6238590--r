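#' Glycolytic glucose demand implied by lactate output
#'
#' Glycolysis yields two lactate per glucose, so lactate export divided by
#' that yield is a deliberate lower bound on glycolytic glucose consumption
#' (pyruvate that is oxidized rather than reduced to lactate is ignored).
#'
#' @param lactate_release Lactate export, nmol h^-1 cm^-2 (non-negative).
#' @param lactate_per_glucose mol lactate per mol glucose (default 2).
#' @return Glucose-unit rate, nmol h^-1 cm^-2.
#' @examples
#' glucose_demand_from_lactate(98.4)  # 49.2
#' @export
glucose_demand_from_lactate <- function(lactate_release, lactate_per_glucose = 2) {
  stopifnot(is.numeric(lactate_release), is.numeric(lactate_per_glucose))
  if (any(lactate_release < 0, na.rm = TRUE)) {
    stop("glucose_demand_from_lactate: lactate_release must be >= 0", call. = FALSE)
  }
  if (any(lactate_per_glucose <= 0)) {
    stop("glucose_demand_from_lactate: lactate_per_glucose must be positive",
         call. = FALSE)
  }
  lactate_release / lactate_per_glucose
}

#' Inferred mobilization of internal glucose stores
#'
#' Glycolytic glucose demand in excess of measured glucose uptake must be
#' supplied internally — in brown adipocytes, by glycogen. Positive values
#' indicate net mobilization of internal stores.
#'
#' @param glucose_demand Glycolytic demand, nmol glucose h^-1 cm^-2.
#' @param glucose_uptake Measured uptake, nmol glucose h^-1 cm^-2.
#' @return Signed glucose-unit rate, nmol h^-1 cm^-2.
#' @examples
#' glycogen_mobilization_inferred(49.2, 3.5)  # 45.7
#' @export
glycogen_mobilization_inferred <- function(glucose_demand, glucose_uptake) {
  stopifnot(is.numeric(glucose_demand), is.numeric(glucose_uptake))
  if (any(c(glucose_demand, glucose_uptake) < 0, na.rm = TRUE)) {
    stop("glycogen_mobilization_inferred: inputs must be >= 0", call. = FALSE)
  }
  glucose_demand - glucose_uptake
}

#' Glycogen flux from a content time course
#'
#' Least-squares slope of glycogen content (ug per cm2) against time (h),
#' converted to glucose units via the 162 g/mol anhydroglucose residue:
#' `slope_ug_per_h * 1000 / mw` gives nmol glucose-units h^-1 cm^-2.
#' Negative values indicate depletion.
#'
#' @param time_h Time points, hours (>= 2 distinct values).
#' @param content_ug_per_cm2 Glycogen content at each time point, ug cm^-2.
#' @param mw_anhydroglucose g/mol per glucose residue (default 162).
#' @return Signed glucose-unit flux, nmol h^-1 cm^-2.
#' @examples
#' glycogen_flux_from_timecourse(c(0, 1), c(10, 8.38))  # -10
#' @export
glycogen_flux_from_timecourse <- function(time_h, content_ug_per_cm2,
                                          mw_anhydroglucose = 162) {
  stopifnot(is.numeric(time_h), is.numeric(content_ug_per_cm2))
  if (length(time_h) != length(content_ug_per_cm2)) {
    stop("glycogen_flux_from_timecourse: time and content lengths differ",
         call. = FALSE)
  }
  ok <- is.finite(time_h) & is.finite(content_ug_per_cm2)
  time_h <- time_h[ok]; content_ug_per_cm2 <- content_ug_per_cm2[ok]
  if (length(time_h) < 2L || length(unique(time_h)) < 2L) {
    stop("glycogen_flux_from_timecourse: need >= 2 points at distinct times",
         call. = FALSE)
  }
  if (any(content_ug_per_cm2 < 0)) {
    stop("glycogen_flux_from_timecourse: content must be >= 0", call. = FALSE)
  }
  slope <- stats::cov(time_h, content_ug_per_cm2) / stats::var(time_h)  # ug h^-1 cm^-2
  slope * 1000 / mw_anhydroglucose
}
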