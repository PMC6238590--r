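# Unit-mean multiplicative lognormal noise: E[exp(N(-s^2/2, s))] = 1.
lognormal_multiplier <- function(n, sd) {
  if (sd == 0) return(rep(1, n))
  exp(stats::rnorm(n, mean = -sd^2 / 2, sd = sd))
}

#' Ground truth for a synthetic plate experiment
#'
#' Defines the condition-level true rates and the noise model from which
#' [simulate_experiment()] generates raw data. The default truth is the
#' reference brown adipocyte dataset ([reference_fluxes()]): WT and Ucp1-KO
#' cells in the basal, isoproterenol, and oligomycin blocks. Defaults the
#' reference does not fix — maximal (FCCP) respiration, non-mitochondrial
#' respiration, glycogen store and depletion flux — are stated in the
#' methods vignette.
#'
#' @param rates `data.frame` with columns `genotype`, `treatment`, `quantity`,
#'   `mean` giving the true measured rates (`glycerol_release`,
#'   `ffa_release`, `lactate_release`, `glucose_uptake`, `o2_consumption`)
#'   per condition, nmol h^-1 cm^-2. Default: the reference dataset's
#'   measured rows.
#' @param wells_per_condition Wells per condition (default 6).
#' @param noise_sd Lognormal sigma of the per-well multiplicative noise
#'   (default 0.1, a typical plate CV).
#' @param trace_jitter_sd Additive per-timepoint jitter on simulated traces,
#'   pmol min^-1 well^-1 (default 2).
#' @param fccp_factor Maximal (FCCP) respiration as a multiple of the larger
#'   of the basal and isoproterenol rates (default 1.25).
#' @param nonmito_ocr Non-mitochondrial (post-antimycin A) respiration,
#'   nmol h^-1 cm^-2 (default 5).
#' @param glycogen0_ug Initial glycogen content, ug cm^-2 (default 13.8,
#'   i.e. ~1 ng per cell at the reference cell density).
#' @param glycogen_flux Named vector of true glycogen fluxes in glucose
#'   units, nmol h^-1 cm^-2, for the `basal` and `iso` time courses
#'   (default `c(basal = 0, iso = -54)`).
#' @param unexplained_ppr Optional extra acidification added to simulated
#'   PPR traces but not to any source molecule, nmol H+ h^-1 cm^-2
#'   (default 0); exercises residual reporting.
#' @param seed Integer seed; required, fixes all draws.
#' @return An object of class `synthetic_truth`.
#' @examples
#' tr <- synthetic_truth(seed = 1)
#' @export
synthetic_truth <- function(rates = NULL,
                            wells_per_condition = 6,
                            noise_sd = 0.1,
                            trace_jitter_sd = 2,
                            fccp_factor = 1.25,
                            nonmito_ocr = 5,
                            glycogen0_ug = 13.8,
                            glycogen_flux = c(basal = 0, iso = -54),
                            unexplained_ppr = 0,
                            seed = 1) {
  measured <- c("glycerol_release", "ffa_release", "lactate_release",
                "glucose_uptake", "o2_consumption")
  if (is.null(rates)) {
    ref <- reference_fluxes()
    rates <- ref[ref$quantity %in% measured,
                 c("genotype", "treatment", "quantity", "mean")]
  }
  rates <- as.data.frame(rates)
  req <- c("genotype", "treatment", "quantity", "mean")
  if (!all(req %in% names(rates))) {
    stop("synthetic_truth: rates needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(rates$quantity), measured)
  if (length(bad)) {
    stop("synthetic_truth: unknown quantity(ies): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(rates$mean < 0, na.rm = TRUE)) {
    stop("synthetic_truth: true rates must be >= 0", call. = FALSE)
  }
  if (noise_sd < 0 || trace_jitter_sd < 0) {
    stop("synthetic_truth: noise sds must be >= 0", call. = FALSE)
  }
  if (wells_per_condition < 1) {
    stop("synthetic_truth: need at least one well per condition", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("synthetic_truth: a single finite numeric seed is required", call. = FALSE)
  }
  if (!all(c("basal", "iso") %in% names(glycogen_flux))) {
    stop("synthetic_truth: glycogen_flux needs named entries 'basal' and 'iso'",
         call. = FALSE)
  }
  structure(list(rates = rates,
                 wells_per_condition = as.integer(wells_per_condition),
                 noise_sd = noise_sd, trace_jitter_sd = trace_jitter_sd,
                 fccp_factor = fccp_factor, nonmito_ocr = nonmito_ocr,
                 glycogen0_ug = glycogen0_ug, glycogen_flux = glycogen_flux,
                 unexplained_ppr = unexplained_ppr,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic plate truth: %d conditions, %d wells/condition, noise sd %.2g, seed %d\n",
              nrow(unique(x$rates[c("genotype", "treatment")])),
              x$wells_per_condition, x$noise_sd, x$seed))
  invisible(x)
}

truth_rate <- function(truth, genotype, treatment, quantity) {
  sel <- truth$rates[truth$rates$genotype == genotype &
                       truth$rates$treatment == treatment &
                       truth$rates$quantity == quantity, "mean"]
  if (!length(sel)) NA_real_ else sel[1]
}

# Injection protocols used by the simulator; `block` maps each phase to the
# treatment condition whose true rates it expresses.
simulation_protocols <- function() {
  list(
    run1 = list(order = c("isoproterenol", "oligomycin", "FCCP", "antimycinA"),
                block = c(basal = "basal", post_isoproterenol = "iso",
                          post_oligomycin = "oligo_iso", post_FCCP = "oligo_iso",
                          post_antimycinA = "oligo_iso")),
    run2 = list(order = c("oligomycin", "isoproterenol", "FCCP", "antimycinA"),
                block = c(basal = "basal", post_oligomycin = "oligo_basal",
                          post_isoproterenol = "oligo_iso", post_FCCP = "oligo_iso",
                          post_antimycinA = "oligo_iso"))
  )
}

#' Simulate a raw plate experiment with known ground truth
#'
#' Generates the three raw inputs of the pipeline from a [synthetic_truth()]:
#' respirometry traces (piecewise-constant OCR at the phase-true levels plus
#' per-well multiplicative noise and per-point jitter, with the four-injection
#' protocol in both injection orders), per-well supernatant metabolite rates,
#' and glycogen content time courses. PPR traces are generated from the
#' truth via the acidification model itself (net H+/O2 on the phase OCR plus
#' the lactate and FFA release of the phase's treatment block), so the
#' proton-source decomposition has zero structural residual in expectation.
#' All draws are fixed by `truth$seed`.
#'
#' @param truth A [synthetic_truth()].
#' @param geometry A [culture_geometry()]; sets the well area used for
#'   areal-to-instrument unit conversion.
#' @param constants A [model_constants()]; supplies the net H+/O2.
#' @param cycles_per_phase Measurement cycles per injection phase (default 4).
#' @param cycle_min Minutes between measurement cycles (default 6).
#' @return An object of class `flux_simulation`: a list with `metabolites`
#'   (per-well rates), `traces` (long instrument-unit time series),
#'   `injections` (sidecar table keyed by `well_group`), `glycogen`
#'   (time courses) and `truth`.
#' @examples
#' sim <- simulate_experiment(synthetic_truth(seed = 7, wells_per_condition = 3))
#' head(sim$metabolites)
#' @export
simulate_experiment <- function(truth,
                                geometry = culture_geometry(),
                                constants = model_constants(),
                                cycles_per_phase = 4,
                                cycle_min = 6) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(geometry, "culture_geometry"),
            inherits(constants, "model_constants"))
  set.seed(truth$seed)
  conds <- unique(truth$rates[c("genotype", "treatment")])
  nw <- truth$wells_per_condition

  # --- supernatant metabolite rates, one row per well ---------------------
  met_q <- c("glycerol_release", "ffa_release", "lactate_release", "glucose_uptake")
  met <- list()
  for (i in seq_len(nrow(conds))) {
    g <- conds$genotype[i]; tr <- conds$treatment[i]
    draws <- sapply(met_q, function(q) {
      mu <- truth_rate(truth, g, tr, q)
      if (is.na(mu)) rep(NA_real_, nw) else mu * lognormal_multiplier(nw, truth$noise_sd)
    })
    met[[i]] <- cbind(data.frame(genotype = g, treatment = tr,
                                 well = sprintf("%s_%s_w%02d", g, tr, seq_len(nw)),
                                 stringsAsFactors = FALSE),
                      as.data.frame(draws))
  }
  metabolites <- do.call(rbind, met)

  # --- respirometry traces, two injection orders per genotype -------------
  to_pmol_min <- 1000 * geometry$area_cm2 / 60
  protos <- simulation_protocols()
  genotypes <- unique(conds$genotype)
  traces <- list(); injections <- list()
  for (g in genotypes) {
    basal <- truth_rate(truth, g, "basal", "o2_consumption")
    iso <- truth_rate(truth, g, "iso", "o2_consumption")
    fccp <- truth$fccp_factor * max(basal, iso, na.rm = TRUE)
    phase_ocr_all <- c(basal = basal, iso = iso,
                       oligo_basal = truth_rate(truth, g, "oligo_basal", "o2_consumption"),
                       oligo_iso = truth_rate(truth, g, "oligo_iso", "o2_consumption"))
    for (run in names(protos)) {
      proto <- protos[[run]]
      phases <- c("basal", paste0("post_", proto$order))
      np <- length(phases)
      t_all <- seq(0, by = cycle_min, length.out = np * cycles_per_phase)
      phase_of <- rep(phases, each = cycles_per_phase)
      inj_t <- t_all[seq_len(np - 1) * cycles_per_phase] + cycle_min / 2
      ocr_level <- vapply(phases, function(ph) {
        switch(ph,
               post_FCCP = fccp,
               post_antimycinA = truth$nonmito_ocr,
               phase_ocr_all[[proto$block[[ph]]]])
      }, numeric(1))
      ppr_level <- vapply(phases, function(ph) {
        blk <- proto$block[[ph]]
        ppr_from_co2(ocr_level[[ph]], constants$h_per_o2_net) +
          truth_rate(truth, g, blk, "lactate_release") +
          truth_rate(truth, g, blk, "ffa_release") +
          truth$unexplained_ppr
      }, numeric(1))
      grp <- paste(g, run, sep = "_")
      injections[[grp]] <- data.frame(well_group = grp, time_min = inj_t,
                                      agent = proto$order, stringsAsFactors = FALSE)
      for (k in seq_len(nw)) {
        m <- lognormal_multiplier(1, truth$noise_sd)
        jit_o <- stats::rnorm(length(t_all), 0, truth$trace_jitter_sd)
        jit_p <- stats::rnorm(length(t_all), 0, truth$trace_jitter_sd)
        traces[[paste(grp, k)]] <- data.frame(
          well = sprintf("%s_w%02d", grp, k), genotype = g, run = run,
          time_min = t_all,
          ocr_pmol_min = ocr_level[phase_of] * to_pmol_min * m + jit_o,
          ppr_pmol_min = ppr_level[phase_of] * to_pmol_min * m + jit_p,
          stringsAsFactors = FALSE)
      }
    }
  }

  # --- glycogen time courses ---------------------------------------------
  glyc <- list()
  times <- c(0, 0.5, 1)
  cst_mw <- constants$mw_anhydroglucose
  for (g in genotypes) {
    for (tr in c("basal", "iso")) {
      slope_ug <- truth$glycogen_flux[[tr]] * cst_mw / 1000
      for (k in seq_len(nw)) {
        content <- pmax(0, (truth$glycogen0_ug + slope_ug * times) *
                          lognormal_multiplier(length(times), truth$noise_sd))
        glyc[[paste(g, tr, k)]] <- data.frame(
          genotype = g, treatment = tr,
          well = sprintf("%s_%s_g%02d", g, tr, k),
          time_h = times, content_ug = content, stringsAsFactors = FALSE)
      }
    }
  }

  structure(list(metabolites = metabolites,
                 traces = do.call(rbind, c(traces, list(make.row.names = FALSE))),
                 injections = do.call(rbind, c(injections, list(make.row.names = FALSE))),
                 glycogen = do.call(rbind, c(glyc, list(make.row.names = FALSE))),
                 truth = truth),
            class = "flux_simulation")
}

#' @export
print.flux_simulation <- function(x, ...) {
  cat(sprintf("Synthetic plate dataset: %d metabolite wells, %d trace wells, %d glycogen series (seed %d)\n",
              nrow(x$metabolites), length(unique(x$traces$well)),
              length(unique(x$glycogen$well)), x$truth$seed))
  invisible(x)
}

#' Assemble per-well model input from raw traces and metabolite rates
#'
#' Segments every respirometry trace ([segment_phases()]), maps phases to
#' treatment blocks by injection order (isoproterenol-first traces provide
#' the basal and isoproterenol blocks; oligomycin-first traces provide the
#' oligomycin blocks), and joins the per-well OCR/PPR phase means to the
#' per-well metabolite rates of the same condition. When a condition has as
#' many trace wells as metabolite wells the two are paired in well order;
#' otherwise each metabolite well receives the condition-mean OCR/PPR.
#'
#' @param x A `flux_simulation` object from [simulate_experiment()], or a list
#'   with elements `traces`, `injections`, `metabolites` in the same layout
#'   (e.g. read back via [read_traces()] and [read_measurements()]).
#' @param geometry A [culture_geometry()]; sets the well area.
#' @param skip_first Post-injection cycles to discard (default 1).
#' @return A `data.frame` ready for [flux_model()].
#' @examples
#' sim <- simulate_experiment(synthetic_truth(seed = 3, wells_per_condition = 3))
#' wells <- assemble_wells(sim)
#' fit <- flux_model(wells)
#' @export
assemble_wells <- function(x, geometry = culture_geometry(), skip_first = 1) {
  traces <- as.data.frame(x$traces)
  injections <- as.data.frame(x$injections)
  met <- as.data.frame(x$metabolites)
  req <- c("well", "time_min", "ocr_pmol_min")
  if (!all(req %in% names(traces))) {
    stop("assemble_wells: traces need columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  has_ppr <- "ppr_pmol_min" %in% names(traces)
  # phase means per trace well, mapped to treatment blocks
  per_block <- list()
  for (w in unique(traces$well)) {
    tw <- traces[traces$well == w, ]
    grp_match <- vapply(unique(injections$well_group), function(gr) {
      startsWith(w, paste0(gr, "_")) || identical(w, gr)
    }, logical(1))
    grp <- unique(injections$well_group)[grp_match]
    if (length(grp) != 1L) {
      stop("assemble_wells: cannot match well '", w, "' to one injection group",
           call. = FALSE)
    }
    inj <- injections[injections$well_group == grp, c("time_min", "agent")]
    inj <- inj[order(inj$time_min), ]
    genotype <- if ("genotype" %in% names(tw)) tw$genotype[1] else
      strsplit(w, "_", fixed = TRUE)[[1]][1]
    tr_obj <- respiration_trace(w, tw$time_min, tw$ocr_pmol_min,
                                ppr = if (has_ppr) tw$ppr_pmol_min else NULL,
                                injections = inj, genotype = genotype)
    ph <- segment_phases(tr_obj, well_area = geometry$area_cm2,
                         skip_first = skip_first)
    first_agent <- inj$agent[1]
    block_map <- if (identical(first_agent, "oligomycin")) {
      c(post_oligomycin = "oligo_basal", post_isoproterenol = "oligo_iso")
    } else {
      c(basal = "basal", post_isoproterenol = "iso")
    }
    for (phase in intersect(names(block_map), names(ph$ocr))) {
      blk <- block_map[[phase]]
      per_block[[length(per_block) + 1L]] <- data.frame(
        genotype = genotype, treatment = blk, well = w,
        ocr = unname(ph$ocr[phase]),
        ppr = if (has_ppr) unname(ph$ppr[phase]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  blocks <- do.call(rbind, per_block)
  # join to metabolite wells
  out <- met
  out$o2_consumption <- NA_real_
  out$ppr_measured <- NA_real_
  conds <- unique(met[c("genotype", "treatment")])
  for (i in seq_len(nrow(conds))) {
    g <- conds$genotype[i]; tr <- conds$treatment[i]
    bi <- blocks[blocks$genotype == g & blocks$treatment == tr, ]
    mi <- which(out$genotype == g & out$treatment == tr)
    if (!nrow(bi)) {
      stop("assemble_wells: no trace data for condition ", g, "/", tr,
           call. = FALSE)
    }
    bi <- bi[order(bi$well), ]
    if (nrow(bi) == length(mi)) {
      out$o2_consumption[mi] <- bi$ocr
      out$ppr_measured[mi] <- bi$ppr
    } else {
      out$o2_consumption[mi] <- mean(bi$ocr)
      out$ppr_measured[mi] <- mean(bi$ppr)
    }
  }
  if (all(is.na(out$ppr_measured))) out$ppr_measured <- NULL
  out
}

#' Compare a fitted flux table against simulation ground truth
#'
#' For every measured rate, contrasts the fitted condition means with the
#' simulation truth across conditions: bias (mean estimate minus truth),
#' absolute RMSE, and relative RMSE over cells with nonzero truth.
#'
#' @param truth A [synthetic_truth()].
#' @param fit A [flux_model()] fitted to data simulated from `truth` (or a
#'   matrix/list of estimates in the layout of [coef.flux_model()]).
#' @return `data.frame` of class `recovery_report` with one row per
#'   quantity: `quantity`, `n_conditions`, `bias`, `rmse`, `rel_rmse`.
#' @export
recovery_report <- function(truth, fit) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cm <- if (inherits(fit, "flux_model")) coef(fit) else as.matrix(fit)
  tr_conds <- unique(truth$rates[c("genotype", "treatment")])
  keys <- condition_key(tr_conds$genotype, tr_conds$treatment)
  missing <- setdiff(keys, rownames(cm))
  if (length(missing)) {
    stop("recovery_report: estimates lack condition(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  quantities <- intersect(unique(truth$rates$quantity), colnames(cm))
  rows <- lapply(quantities, function(q) {
    tv <- vapply(seq_len(nrow(tr_conds)), function(i) {
      truth_rate(truth, tr_conds$genotype[i], tr_conds$treatment[i], q)
    }, numeric(1))
    ev <- cm[keys, q]
    ok <- !is.na(tv) & !is.na(ev)
    err <- ev[ok] - tv[ok]
    rel <- err[tv[ok] > 0] / tv[ok][tv[ok] > 0]
    data.frame(quantity = q, n_conditions = sum(ok),
               bias = mean(err), rmse = sqrt(mean(err^2)),
               rel_rmse = if (length(rel)) sqrt(mean(rel^2)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("recovery_report", "data.frame")
  out
}
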