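#' Reference flux dataset for primary brown adipocytes
#'
#' Published group means and standard deviations (n = 3 independent
#' experiments) of measured and derived substrate fluxes in primary murine
#' brown adipocytes of wild-type (`WT`) and Ucp1-knockout (`KO`) origin, in
#' the basal state, under isoproterenol (`iso`), and with oligomycin present
#' (`oligo_basal`, `oligo_iso`). All rates are nmol h^-1 cm^-2. Derived rows
#' (CO2 production, FFA oxidized, FFA re-esterified, TAG hydrolyzed) were
#' computed per replicate and then averaged, so they deviate from the group
#' means of their inputs by up to ~2%. Two cells were reported only as
#' below zero; they carry `below_zero = TRUE` and `mean = NA`. Glucose uptake
#' was not measured in the oligomycin blocks.
#'
#' This table doubles as the default ground truth of the synthetic plate
#' generator ([synthetic_truth()]) and as the worked input of the package
#' examples.
#'
#' @return A `data.frame` with columns `genotype` (`WT`/`KO`), `treatment`
#'   (`basal`, `iso`, `oligo_basal`, `oligo_iso`), `quantity`, `mean`, `sd`,
#'   `below_zero`.
#' @examples
#' ref <- reference_fluxes()
#' subset(ref, genotype == "WT" & treatment == "iso")
#' @export
reference_fluxes <- function() {
  q9 <- c("glycerol_release", "ffa_release", "ffa_oxidized", "ffa_reesterified",
          "tag_hydrolyzed", "o2_consumption", "co2_production",
          "glucose_uptake", "lactate_release")
  block <- function(genotype, treatment, mean, sd) {
    data.frame(genotype = genotype, treatment = treatment,
               quantity = q9[seq_along(mean)], mean = mean, sd = sd,
               below_zero = FALSE, stringsAsFactors = FALSE)
  }
  ref <- rbind(
    block("KO", "basal",
          c(6.0, 9.6, 1.8, 6.4, 5.9, 44.4, 27.6, 2.3, 114.6),
          c(1.8, 1.8, 0.0, 4.6, 1.7, 6.6, 4.2, 0.0, 15.0)),
    block("WT", "basal",
          c(7.2, 15.6, 2.4, 4.0, 7.2, 50.4, 31.2, 2.2, 59.4),
          c(1.8, 7.2, 0.6, 1.8, 2.3, 19.2, 12.0, 0.0, 7.2)),
    block("KO", "iso",
          c(58.2, 124.8, 6.6, 43.7, 58.4, 151.8, 94.2, 3.8, 165.6),
          c(9.0, 24.0, 0.0, 4.6, 8.7, 6.6, 4.2, 0.6, 24.6)),
    block("WT", "iso",
          c(28.2, 66.6, 7.2, 10.9, 28.2, 165.6, 102.6, 3.5, 98.4),
          c(5.4, 3.6, 0.6, 19.3, 5.1, 10.8, 6.6, 0.6, 14.4))
  )
  # oligomycin blocks: glucose uptake not measured (8 quantities)
  q8 <- setdiff(q9, "glucose_uptake")
  block8 <- function(genotype, treatment, mean, sd) {
    data.frame(genotype = genotype, treatment = treatment, quantity = q8,
               mean = mean, sd = sd, below_zero = FALSE, stringsAsFactors = FALSE)
  }
  ref <- rbind(ref,
    block8("KO", "oligo_basal",
           c(3.0, 8.4, 0.6, NA, 3.0, 20.4, 12.6, 156.6),
           c(2.4, 1.8, 0.0, NA, 2.2, 4.8, 3.0, 19.2)),
    block8("WT", "oligo_basal",
           c(4.2, 11.4, 0.6, 0.6, 4.4, 18.6, 11.4, 102.6),
           c(1.2, 6.0, 0.0, 3.0, 1.0, 6.6, 4.2, 25.2)),
    block8("KO", "oligo_iso",
           c(38.4, 123.6, 2.4, NA, 38.2, 48.0, 30.0, 181.8),
           c(6.6, 21.6, 0.0, NA, 6.6, 2.4, 1.2, 16.2)),
    block8("WT", "oligo_iso",
           c(16.2, 38.4, 6.6, 3.9, 16.3, 152.4, 94.8, 126.6),
           c(3.6, 7.2, 1.8, 4.2, 4.0, 46.8, 29.4, 3.6))
  )
  # cells reported only as "<0"
  ref$below_zero[ref$quantity == "ffa_reesterified" & ref$genotype == "KO" &
                   ref$treatment %in% c("oligo_basal", "oligo_iso")] <- TRUE
  rownames(ref) <- NULL
  ref
}

#' Reference means for one condition as a named vector
#'
#' Convenience accessor over [reference_fluxes()].
#'
#' @param genotype `"WT"` or `"KO"`.
#' @param treatment One of `basal`, `iso`, `oligo_basal`, `oligo_iso`.
#' @param quantities Which quantities to return (default: all present).
#' @return Named numeric vector of group means, nmol h^-1 cm^-2.
#' @examples
#' reference_means("WT", "iso")[["o2_consumption"]]
#' @export
reference_means <- function(genotype, treatment, quantities = NULL) {
  ref <- reference_fluxes()
  sel <- ref[ref$genotype == genotype & ref$treatment == treatment, ]
  if (!nrow(sel)) {
    stop("reference_means: unknown condition ", genotype, "/", treatment,
         call. = FALSE)
  }
  if (!is.null(quantities)) sel <- sel[sel$quantity %in% quantities, ]
  stats::setNames(sel$mean, sel$quantity)
}
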