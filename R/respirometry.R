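#' Construct a respirometry trace
#'
#' One well's extracellular-flux time series: oxygen consumption rate (OCR,
#' pmol O2 min^-1 well^-1), optionally proton production rate (PPR, pmol H+
#' min^-1 well^-1), and the ordered injection events that partition the run
#' into phases.
#'
#' @param well_id Well identifier (character scalar).
#' @param time_min Measurement times in minutes, strictly increasing.
#' @param ocr OCR per timepoint, pmol min^-1 well^-1.
#' @param ppr Optional PPR per timepoint, same length as `time_min`.
#' @param injections `data.frame` with columns `time_min` and `agent`; agents
#'   must be among oligomycin, isoproterenol, FCCP, antimycinA and the times
#'   must be ordered and lie within the trace's time range.
#' @param genotype Optional genotype label carried as metadata.
#' @return An object of class `respiration_trace`.
#' @examples
#' tr <- respiration_trace("w1", time_min = c(0, 6, 12, 18, 24),
#'                         ocr = c(100, 100, 100, 40, 40),
#'                         injections = data.frame(time_min = 15, agent = "oligomycin"))
#' @export
respiration_trace <- function(well_id, time_min, ocr, ppr = NULL,
                              injections = data.frame(time_min = numeric(),
                                                      agent = character()),
                              genotype = NA_character_) {
  stopifnot(is.character(well_id), length(well_id) == 1L)
  if (!is.numeric(time_min) || length(time_min) < 1L || any(!is.finite(time_min))) {
    stop("respiration_trace: time_min must be finite numeric", call. = FALSE)
  }
  if (any(diff(time_min) <= 0)) {
    stop("respiration_trace: time_min must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(ocr) || length(ocr) != length(time_min)) {
    stop("respiration_trace: ocr must match time_min in length", call. = FALSE)
  }
  if (!is.null(ppr) && (!is.numeric(ppr) || length(ppr) != length(time_min))) {
    stop("respiration_trace: ppr must match time_min in length", call. = FALSE)
  }
  injections <- as.data.frame(injections)
  if (!all(c("time_min", "agent") %in% names(injections))) {
    stop("respiration_trace: injections need columns time_min and agent", call. = FALSE)
  }
  injections$agent <- as.character(injections$agent)
  bad <- setdiff(injections$agent, respiration_agents())
  if (length(bad)) {
    stop("respiration_trace: unknown agent(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(injections)) {
    if (is.unsorted(injections$time_min, strictly = TRUE)) {
      stop("respiration_trace: injection times must be strictly increasing", call. = FALSE)
    }
    if (min(injections$time_min) <= min(time_min) ||
        max(injections$time_min) >= max(time_min)) {
      stop("respiration_trace: injection times must lie inside the trace time range",
           call. = FALSE)
    }
  }
  structure(list(well_id = well_id, genotype = genotype, time_min = time_min,
                 ocr = ocr, ppr = ppr, injections = injections),
            class = "respiration_trace")
}

respiration_agents <- function() c("oligomycin", "isoproterenol", "FCCP", "antimycinA")

#' @export
print.respiration_trace <- function(x, ...) {
  cat(sprintf("Respirometry trace '%s': %d timepoints (%.0f-%.0f min), %d injection(s)%s\n",
              x$well_id, length(x$time_min), min(x$time_min), max(x$time_min),
              nrow(x$injections),
              if (is.null(x$ppr)) "" else ", with PPR"))
  if (nrow(x$injections)) {
    cat("  injections:", paste(sprintf("%s@%g", x$injections$agent,
                                       x$injections$time_min), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Segment a trace into injection-phase means
#'
#' Averages the measurements within each inter-injection interval after
#' discarding the first `skip_first` measurement cycles that follow each
#' injection (mixing transient), and converts the per-well instrument unit
#' (pmol min^-1 well^-1) to the canonical areal unit nmol h^-1 cm^-2 via
#' `x * 60 / 1000 / well_area`.
#'
#' Phases are named `basal` and then `post_<agent>` in injection order.
#'
#' @param trace A [respiration_trace()].
#' @param well_area Growth area of the well, cm2.
#' @param skip_first Number of post-injection cycles to discard (default 1).
#' @return An object of class `respiration_phases`: a named list with `ocr`
#'   (named numeric of phase means, nmol h^-1 cm^-2), `ppr` (same, or `NULL`),
#'   `n_points`, `well_id`, `genotype` and the protocol order.
#' @examples
#' tr <- respiration_trace("w1", 0:4 * 6, c(10, 10, 10, 4, 4),
#'                         injections = data.frame(time_min = 15, agent = "oligomycin"))
#' segment_phases(tr, well_area = 0.1, skip_first = 1)
#' @export
segment_phases <- function(trace, well_area = 0.106, skip_first = 1) {
  stopifnot(inherits(trace, "respiration_trace"))
  if (!is.numeric(well_area) || well_area <= 0) {
    stop("segment_phases: well_area must be positive", call. = FALSE)
  }
  if (skip_first < 0) stop("segment_phases: skip_first must be >= 0", call. = FALSE)
  bounds <- c(-Inf, trace$injections$time_min, Inf)
  phase_names <- c("basal",
                   if (nrow(trace$injections)) paste0("post_", trace$injections$agent))
  conv <- 60 / 1000 / well_area
  ocr <- ppr <- n_pts <- setNames(numeric(length(phase_names)), phase_names)
  for (i in seq_along(phase_names)) {
    idx <- which(trace$time_min >= bounds[i] & trace$time_min < bounds[i + 1])
    if (i > 1L && skip_first > 0 && length(idx)) {
      idx <- idx[-seq_len(min(skip_first, length(idx)))]
    }
    if (!length(idx)) {
      stop("segment_phases: phase '", phase_names[i],
           "' has no usable timepoints after skipping", call. = FALSE)
    }
    n_pts[i] <- length(idx)
    ocr[i] <- mean(trace$ocr[idx]) * conv
    if (!is.null(trace$ppr)) ppr[i] <- mean(trace$ppr[idx]) * conv
  }
  out <- list(ocr = ocr,
              ppr = if (is.null(trace$ppr)) NULL else ppr,
              n_points = n_pts,
              well_id = trace$well_id,
              genotype = trace$genotype,
              protocol_order = if (nrow(trace$injections)) trace$injections$agent else character())
  out$flag_nonmito_exceeds_basal <- "post_antimycinA" %in% names(ocr) &&
    unname(ocr["post_antimycinA"] > ocr["basal"])
  structure(out, class = "respiration_phases")
}

#' @export
print.respiration_phases <- function(x, ...) {
  cat(sprintf("Respiration phase means for '%s' (nmol O2 h^-1 cm^-2)\n", x$well_id))
  print(round(x$ocr, 2))
  if (!is.null(x$ppr)) {
    cat("PPR (nmol H+ h^-1 cm^-2)\n")
    print(round(x$ppr, 2))
  }
  if (isTRUE(x$flag_nonmito_exceeds_basal)) {
    cat("flag: post-antimycin rate exceeds basal\n")
  }
  invisible(x)
}

#' Decompose phase means into respiration components
#'
#' Derives the interpretable respiration components from phase means:
#' non-mitochondrial (post-antimycin A), mitochondrial basal (basal minus
#' non-mitochondrial), coupled (drop upon oligomycin relative to the phase
#' immediately preceding it), isoproterenol-induced (rise over the phase
#' immediately preceding the isoproterenol injection), maximal capacity
#' (post-FCCP), and the isoproterenol response as a percentage of basal.
#' Components whose defining phases are absent are `NA`. Negative derived
#' components are preserved and flagged, never clamped.
#'
#' @param phases A [segment_phases()] result, or a named numeric vector of
#'   phase means (`basal`, `post_oligomycin`, `post_isoproterenol`,
#'   `post_FCCP`, `post_antimycinA`) in nmol h^-1 cm^-2.
#' @param protocol_order Injection order (character vector of agents). When
#'   `phases` is a `respiration_phases` object this defaults to its recorded
#'   order; for a plain vector it defaults to the standard order of whichever
#'   post-phases are present.
#' @return An object of class `respiration_components` (a named list), with a
#'   `flags` element marking negative coupled respiration and
#'   non-mitochondrial rates exceeding basal.
#' @examples
#' decompose_respiration(c(basal = 50.4, post_isoproterenol = 165.6))
#' @export
decompose_respiration <- function(phases, protocol_order = NULL) {
  if (inherits(phases, "respiration_phases")) {
    if (is.null(protocol_order)) protocol_order <- phases$protocol_order
    means <- phases$ocr
  } else {
    if (!is.numeric(phases) || is.null(names(phases))) {
      stop("decompose_respiration: phases must be respiration_phases or a named numeric vector",
           call. = FALSE)
    }
    means <- phases
    if (is.null(protocol_order)) {
      present <- sub("^post_", "", grep("^post_", names(means), value = TRUE))
      protocol_order <- intersect(respiration_agents(), present)
    }
  }
  if (!"basal" %in% names(means)) {
    stop("decompose_respiration: missing 'basal' phase", call. = FALSE)
  }
  needed <- paste0("post_", protocol_order)
  missing <- setdiff(needed, names(means))
  if (length(missing)) {
    stop("decompose_respiration: missing phase(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  phase_seq <- c("basal", needed)  # phases in protocol order
  ref_before <- function(agent) {
    pos <- match(agent, protocol_order)
    means[[phase_seq[pos]]]  # phase immediately preceding the injection
  }
  get <- function(ph) if (ph %in% names(means)) means[[ph]] else NA_real_
  total_basal <- means[["basal"]]
  non_mito <- get("post_antimycinA")
  coupled <- if ("oligomycin" %in% protocol_order) {
    ref_before("oligomycin") - means[["post_oligomycin"]]
  } else NA_real_
  iso_induced <- if ("isoproterenol" %in% protocol_order) {
    means[["post_isoproterenol"]] - ref_before("isoproterenol")
  } else NA_real_
  comp <- list(
    total_basal = total_basal,
    non_mito = non_mito,
    mito_basal = total_basal - non_mito,
    coupled = coupled,
    iso_induced = iso_induced,
    max_capacity = get("post_FCCP"),
    iso_percent_of_basal = if ("isoproterenol" %in% protocol_order && total_basal != 0) {
      100 * means[["post_isoproterenol"]] / total_basal
    } else NA_real_,
    flags = list(
      coupled_negative = isTRUE(coupled < 0),
      nonmito_exceeds_basal = isTRUE(non_mito > total_basal)
    ),
    protocol_order = protocol_order
  )
  structure(comp, class = "respiration_components")
}

#' @export
print.respiration_components <- function(x, ...) {
  cat("Respiration components (nmol O2 h^-1 cm^-2)\n")
  for (nm in c("total_basal", "non_mito", "mito_basal", "coupled",
               "iso_induced", "max_capacity")) {
    cat(sprintf("  %-22s %s\n", nm,
                if (is.na(x[[nm]])) "NA" else sprintf("%.2f", x[[nm]])))
  }
  if (!is.na(x$iso_percent_of_basal)) {
    cat(sprintf("  %-22s %.1f%%\n", "iso_percent_of_basal", x$iso_percent_of_basal))
  }
  set <- names(Filter(isTRUE, x$flags))
  if (length(set)) cat("  flags:", paste(set, collapse = ", "), "\n")
  invisible(x)
}

#' Oligomycin sensitivity of the adrenergic respiratory response
#'
#' Fraction of the isoproterenol-induced respiration that is abolished when
#' ATP synthase is blocked: `1 - induced_under_oligomycin / induced_free`,
#' clamped into the unit interval. A clamp is reported through the `clamped` attribute
#' rather than hidden; values above 1 arise when respiration under oligomycin
#' drops below its pre-isoproterenol reference, values below 0 when the
#' response under oligomycin exceeds the free response (as in cells where the
#' response is UCP1-mediated and hence ATP-synthesis independent).
#'
#' @param iso_induced_free Isoproterenol-induced respiration without
#'   oligomycin, nmol h^-1 cm^-2; must be positive.
#' @param iso_induced_under_oligo Isoproterenol-induced respiration in the
#'   presence of oligomycin, same unit.
#' @return Sensitivity in the unit interval with logical attribute `clamped`.
#' @examples
#' oligo_sensitivity(107.4, 27.6)  # ~0.743
#' @export
oligo_sensitivity <- function(iso_induced_free, iso_induced_under_oligo) {
  stopifnot(is.numeric(iso_induced_free), is.numeric(iso_induced_under_oligo))
  if (any(!is.finite(iso_induced_free)) || any(iso_induced_free <= 0)) {
    stop("oligo_sensitivity: undefined for non-positive free induced respiration",
         call. = FALSE)
  }
  raw <- 1 - iso_induced_under_oligo / iso_induced_free
  out <- pmin(1, pmax(0, raw))
  attr(out, "clamped") <- raw < 0 | raw > 1
  out
}
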