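#' Fit the substrate-flux bookkeeping model to per-well measurements
#'
#' The central fitting function of the package. Takes per-well measured rates
#' — supernatant glycerol, FFA and lactate release, glucose uptake where
#' assayed, and the phase-mean oxygen consumption of the matching treatment —
#' and derives, per well, the bookkept fluxes: CO2 production, the
#' beta-oxidation upper bound, the re-esterification (futile cycling) rate,
#' triglyceride hydrolysis, the proton-source decomposition of extracellular
#' acidification, glycolytic glucose demand and inferred glycogen
#' mobilization. Derivation is per well first; condition cells are then
#' aggregated as mean and sample SD, mirroring per-replicate experimental
#' practice.
#'
#' @param data `data.frame` with one row per well and columns `genotype`,
#'   `treatment`, `well`, `glycerol_release`, `ffa_release`,
#'   `lactate_release`, `o2_consumption` (all nmol h^-1 cm^-2), optionally
#'   `glucose_uptake` and `ppr_measured`. `NA` marks a measurement that was
#'   not taken (e.g. glucose uptake under oligomycin).
#' @param constants A [model_constants()].
#' @param geometry A [culture_geometry()]; carried for unit conversions.
#' @param ffa_mode Mode for [ffa_oxidation_bound()]: `"stoichiometric"`
#'   (default) or `"energetic"`.
#' @param co2_mode `"rq"` (respiratory quotient, default) or `"calibrated"`
#'   (0.62; see [co2_from_ocr()]).
#' @return An object of class `flux_model` with elements `wells` (per-well
#'   measured and derived rates), `table` (long per-condition aggregate with
#'   `mean`, `sd`, `n`, `below_zero`), `constants`, `geometry`, `modes`.
#' @seealso [coef.flux_model()], [residuals.flux_model()],
#'   [predict.flux_model()], [simulate.flux_model()], [compare_conditions()],
#'   [write_flux_table()]
#' @examples
#' wells <- data.frame(genotype = "WT", treatment = "iso", well = "w1",
#'                     glycerol_release = 28.2, ffa_release = 66.6,
#'                     lactate_release = 98.4, glucose_uptake = 3.5,
#'                     o2_consumption = 165.6)
#' fit <- flux_model(wells)
#' coef(fit)
#' @export
flux_model <- function(data,
                       constants = model_constants(),
                       geometry = culture_geometry(),
                       ffa_mode = c("stoichiometric", "energetic"),
                       co2_mode = c("rq", "calibrated")) {
  ffa_mode <- match.arg(ffa_mode)
  co2_mode <- match.arg(co2_mode)
  stopifnot(inherits(constants, "model_constants"),
            inherits(geometry, "culture_geometry"))
  data <- as.data.frame(data)
  required <- c("genotype", "treatment", "well", "glycerol_release",
                "ffa_release", "lactate_release", "o2_consumption")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    stop("flux_model: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(data)) stop("flux_model: no wells supplied", call. = FALSE)
  if (!"glucose_uptake" %in% names(data)) data$glucose_uptake <- NA_real_
  has_ppr <- "ppr_measured" %in% names(data)
  for (col in c("glycerol_release", "ffa_release", "lactate_release",
                "o2_consumption", "glucose_uptake")) {
    v <- data[[col]]
    if (!is.numeric(v)) stop("flux_model: column '", col, "' must be numeric",
                             call. = FALSE)
    if (any(v < 0, na.rm = TRUE)) {
      stop("flux_model: negative values in '", col, "'", call. = FALSE)
    }
  }
  co2_per_o2 <- if (co2_mode == "rq") constants$rq_palmitate else 0.62

  w <- data
  w$co2_production <- co2_from_ocr(w$o2_consumption, co2_per_o2)
  w$ffa_oxidized <- ffa_oxidation_bound(w$o2_consumption, ffa_mode, constants)
  reest <- reesterification_rate(w$glycerol_release, w$ffa_release, w$ffa_oxidized)
  w$ffa_reesterified <- as.numeric(reest)
  w$tag_hydrolyzed <- tag_hydrolysis_rate(w$ffa_release, w$ffa_oxidized,
                                          w$ffa_reesterified)
  dec <- decompose_ppr(w$o2_consumption, w$lactate_release, w$ffa_release,
                       measured_ppr = if (has_ppr) w$ppr_measured else NULL,
                       constants = constants)
  w$ppr_co2 <- dec$from_co2
  w$ppr_lactate <- dec$from_lactate
  w$ppr_ffa <- dec$from_ffa
  w$ppr_modeled <- dec$modeled_total
  w$ppr_residual <- dec$residual
  w$glucose_demand <- glucose_demand_from_lactate(w$lactate_release,
                                                 constants$lactate_per_glucose)
  w$glycogen_mobilization <- w$glucose_demand - w$glucose_uptake

  quantities <- c("glycerol_release", "ffa_release", "ffa_oxidized",
                  "ffa_reesterified", "tag_hydrolyzed", "o2_consumption",
                  "co2_production", "glucose_uptake", "lactate_release",
                  if (has_ppr) "ppr_measured",
                  "ppr_co2", "ppr_lactate", "ppr_ffa", "ppr_modeled",
                  if (has_ppr) "ppr_residual",
                  "glucose_demand", "glycogen_mobilization")
  conds <- unique(w[c("genotype", "treatment")])
  rows <- list()
  for (i in seq_len(nrow(conds))) {
    sel <- w[w$genotype == conds$genotype[i] & w$treatment == conds$treatment[i], ]
    for (q in quantities) {
      v <- sel[[q]][!is.na(sel[[q]])]
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = conds$genotype[i], treatment = conds$treatment[i],
        quantity = q,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1L) stats::sd(v) else if (length(v) == 1L) 0 else NA_real_,
        n = length(v),
        below_zero = length(v) > 0 && mean(v) < 0,
        stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(wells = w, table = table, constants = constants,
                 geometry = geometry,
                 modes = list(ffa_mode = ffa_mode, co2_mode = co2_mode,
                              co2_per_o2 = co2_per_o2),
                 call = match.call()),
            class = "flux_model")
}

condition_key <- function(genotype, treatment) paste(genotype, treatment, sep = ":")

treatment_order <- function(x) {
  canonical <- c("basal", "iso", "oligo_basal", "oligo_iso")
  order(match(x, canonical, nomatch = length(canonical) + 1L), x)
}

#' Per-condition flux table of a fitted model
#'
#' @param object A [flux_model()] fit.
#' @return Long `data.frame` with columns `genotype`, `treatment`,
#'   `quantity`, `mean`, `sd`, `n`, `below_zero`.
#' @export
flux_table <- function(object) {
  stopifnot(inherits(object, "flux_model"))
  tab <- object$table
  tab[order(tab$genotype, treatment_order(tab$treatment)), , drop = FALSE]
}

#' @export
print.flux_model <- function(x, ...) {
  nc <- nrow(unique(x$wells[c("genotype", "treatment")]))
  cat(sprintf("Substrate-flux bookkeeping fit: %d wells, %d conditions\n",
              nrow(x$wells), nc))
  cat(sprintf("  FFA oxidation mode: %s; CO2 per O2: %.3g (%s)\n",
              x$modes$ffa_mode, x$modes$co2_per_o2, x$modes$co2_mode))
  bz <- subset(x$table, below_zero & quantity == "ffa_reesterified")
  if (nrow(bz)) {
    cat("  below-zero re-esterification in:",
        paste(condition_key(bz$genotype, bz$treatment), collapse = ", "), "\n")
  }
  cat("Use summary() for the condition table, coef() for the mean matrix.\n")
  invisible(x)
}

#' Condition-level mean matrix
#'
#' @param object A [flux_model()] fit.
#' @param ... Unused.
#' @return Numeric matrix, conditions (rows, `genotype:treatment`) by
#'   quantities (columns), of condition means in nmol h^-1 cm^-2.
#' @export
coef.flux_model <- function(object, ...) {
  tab <- flux_table(object)
  conds <- unique(tab[c("genotype", "treatment")])
  qs <- unique(tab$quantity)
  m <- matrix(NA_real_, nrow(conds), length(qs),
              dimnames = list(condition_key(conds$genotype, conds$treatment), qs))
  for (i in seq_len(nrow(tab))) {
    m[condition_key(tab$genotype[i], tab$treatment[i]), tab$quantity[i]] <- tab$mean[i]
  }
  m
}

#' Proton-production residuals of a fitted model
#'
#' Measured minus modeled proton production per well (`type = "well"`) or
#' averaged per condition (`type = "condition"`, default). All `NA` when no
#' measured PPR was supplied to the fit.
#'
#' @param object A [flux_model()] fit.
#' @param type `"condition"` or `"well"`.
#' @param ... Unused.
#' @return Named numeric vector of residuals, nmol H+ h^-1 cm^-2.
#' @export
residuals.flux_model <- function(object, type = c("condition", "well"), ...) {
  type <- match.arg(type)
  w <- object$wells
  if (type == "well") {
    return(stats::setNames(w$ppr_residual, w$well))
  }
  conds <- unique(w[c("genotype", "treatment")])
  out <- vapply(seq_len(nrow(conds)), function(i) {
    v <- w$ppr_residual[w$genotype == conds$genotype[i] &
                          w$treatment == conds$treatment[i]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  stats::setNames(out, condition_key(conds$genotype, conds$treatment))
}

#' Apply the fitted bookkeeping to new measured rates
#'
#' Runs the derivation layer (same modes and constants as the fit) on new
#' condition-level or well-level measured rates without refitting.
#'
#' @param object A [flux_model()] fit.
#' @param newdata `data.frame` with columns `o2_consumption`,
#'   `glycerol_release`, `ffa_release`, `lactate_release`, optionally
#'   `glucose_uptake`.
#' @param type `"fluxes"` (derived lipid/glyco fluxes) or `"ppr"`
#'   (proton-source decomposition).
#' @param ... Unused.
#' @return `data.frame` of derived quantities, one row per input row.
#' @export
predict.flux_model <- function(object, newdata,
                               type = c("fluxes", "ppr"), ...) {
  type <- match.arg(type)
  nd <- as.data.frame(newdata)
  req <- c("o2_consumption", "glycerol_release", "ffa_release", "lactate_release")
  missing <- setdiff(req, names(nd))
  if (length(missing)) {
    stop("predict.flux_model: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cst <- object$constants
  if (type == "ppr") {
    return(decompose_ppr(nd$o2_consumption, nd$lactate_release, nd$ffa_release,
                         constants = cst))
  }
  ox <- ffa_oxidation_bound(nd$o2_consumption, object$modes$ffa_mode, cst)
  reest <- as.numeric(reesterification_rate(nd$glycerol_release, nd$ffa_release, ox))
  out <- data.frame(
    co2_production = co2_from_ocr(nd$o2_consumption, object$modes$co2_per_o2),
    ffa_oxidized = ox,
    ffa_reesterified = reest,
    tag_hydrolyzed = tag_hydrolysis_rate(nd$ffa_release, ox, reest),
    glucose_demand = glucose_demand_from_lactate(nd$lactate_release,
                                                 cst$lactate_per_glucose))
  if ("glucose_uptake" %in% names(nd)) {
    out$glycogen_mobilization <- out$glucose_demand - nd$glucose_uptake
  }
  out
}

#' Simulate per-well measurement datasets from a fitted model
#'
#' Draws new per-well measured rates around the fitted condition means under
#' the package's multiplicative lognormal noise model (unit-mean multipliers)
#' and returns datasets in the exact input format of [flux_model()], so a
#' fit can be re-fitted to its own simulations.
#'
#' @param object A [flux_model()] fit.
#' @param nsim Number of datasets.
#' @param seed Optional integer seed.
#' @param wells_per_condition Wells per condition in each dataset.
#' @param noise_sd Lognormal sigma of the well-level multiplier (default 0.1).
#' @param ... Unused.
#' @return A list of `nsim` data frames.
#' @export
simulate.flux_model <- function(object, nsim = 1, seed = NULL,
                                wells_per_condition = 6, noise_sd = 0.1, ...) {
  if (!is.null(seed)) set.seed(seed)
  measured <- c("glycerol_release", "ffa_release", "lactate_release",
                "glucose_uptake", "o2_consumption")
  cm <- coef(object)
  conds <- do.call(rbind, strsplit(rownames(cm), ":", fixed = TRUE))
  lapply(seq_len(nsim), function(s) {
    out <- list()
    for (i in seq_len(nrow(cm))) {
      draws <- sapply(measured, function(q) {
        mu <- cm[i, q]
        if (is.na(mu)) return(rep(NA_real_, wells_per_condition))
        mu * lognormal_multiplier(wells_per_condition, noise_sd)
      })
      draws <- as.data.frame(draws)
      draws <- cbind(data.frame(genotype = conds[i, 1], treatment = conds[i, 2],
                                well = sprintf("%s_w%02d", rownames(cm)[i],
                                               seq_len(wells_per_condition)),
                                stringsAsFactors = FALSE),
                     draws)
      out[[i]] <- draws
    }
    do.call(rbind, out)
  })
}

#' @export
summary.flux_model <- function(object, digits = 1, ...) {
  structure(list(fit = object, digits = digits), class = "summary.flux_model")
}

#' @export
print.summary.flux_model <- function(x, ...) {
  fit <- x$fit
  tab <- flux_table(fit)
  core <- c("glycerol_release", "ffa_release", "ffa_oxidized", "ffa_reesterified",
            "tag_hydrolyzed", "o2_consumption", "co2_production",
            "glucose_uptake", "lactate_release")
  tab <- tab[tab$quantity %in% core, ]
  tab$quantity <- factor(tab$quantity, levels = core)
  cat("Per-condition flux table (mean ± SD, nmol h^-1 cm^-2)\n\n")
  for (g in unique(tab$genotype)) {
    for (tr in unique(tab$treatment[tab$genotype == g])) {
      sel <- tab[tab$genotype == g & tab$treatment == tr, ]
      sel <- sel[order(sel$quantity), ]
      cat(sprintf("%s / %s (n = %d)\n", g, tr, max(sel$n)))
      for (i in seq_len(nrow(sel))) {
        cat(sprintf("  %-18s %s\n", sel$quantity[i],
                    format_flux_cell(sel$mean[i], sel$sd[i], sel$below_zero[i],
                                     x$digits)))
      }
    }
  }
  res <- residuals(fit)
  if (any(!is.na(res))) {
    cat("\nPPR residual (measured - modeled), nmol H+ h^-1 cm^-2:\n")
    print(round(res, x$digits + 1))
  }
  invisible(x)
}

format_flux_cell <- function(mean, sd, below_zero, digits = 1) {
  if (is.na(mean)) return(if (isTRUE(below_zero)) "<0" else "-")
  if (isTRUE(below_zero)) return("<0")
  if (is.na(sd)) return(sprintf("%.*f", digits, round_half_away(mean, digits)))
  sprintf("%.*f ± %.*f", digits, round_half_away(mean, digits),
          digits, round_half_away(sd, digits))
}

#' Contrast one quantity between two conditions
#'
#' @param object A [flux_model()] fit (or its [flux_table()]).
#' @param quantity Quantity name (e.g. `"tag_hydrolyzed"`).
#' @param a,b Conditions as `c(genotype, treatment)` character vectors;
#'   the contrast reported is `b` relative to `a`.
#' @return List with `fold` (`mean_b / mean_a`, `NA` when `mean_a` is 0) and
#'   `diff` (`mean_b - mean_a`).
#' @examples
#' ## fold-change of TAG hydrolysis upon stimulation
#' @export
compare_conditions <- function(object, quantity, a, b) {
  tab <- if (inherits(object, "flux_model")) object$table else as.data.frame(object)
  pick <- function(key) {
    sel <- tab[tab$genotype == key[1] & tab$treatment == key[2] &
                 tab$quantity == quantity, ]
    if (!nrow(sel)) {
      stop("compare_conditions: no cell for ", key[1], "/", key[2], "/",
           quantity, call. = FALSE)
    }
    sel$mean[1]
  }
  ma <- pick(a); mb <- pick(b)
  list(fold = if (!is.na(ma) && ma != 0) mb / ma else NA_real_,
       diff = mb - ma)
}

#' Plot the proton-source decomposition of a fit
#'
#' Stacked bars of the three modeled proton sources (CO2-derived carbonic
#' acid, lactic acid, exported FFA) per condition, with the measured total
#' overlaid as a point when available.
#'
#' @param x A [flux_model()] fit.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the stacked matrix plotted.
#' @export
plot.flux_model <- function(x, ...) {
  cm <- coef(x)
  src <- t(cm[, c("ppr_co2", "ppr_lactate", "ppr_ffa"), drop = FALSE])
  cols <- c("grey30", "grey60", "grey85")
  mids <- graphics::barplot(src, col = cols, las = 2,
                            ylab = "PPR (nmol H+ h^-1 cm^-2)",
                            main = "Proton sources by condition", ...)
  if ("ppr_measured" %in% colnames(cm)) {
    graphics::points(mids, cm[, "ppr_measured"], pch = 19)
    graphics::legend("topleft", bty = "n", pch = c(22, 22, 22, 19),
                     pt.bg = c(cols, NA),
                     legend = c("CO2 (carbonic acid)", "lactic acid",
                                "FFA", "measured"))
  } else {
    graphics::legend("topleft", bty = "n", fill = cols,
                     legend = c("CO2 (carbonic acid)", "lactic acid", "FFA"))
  }
  invisible(src)
}
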