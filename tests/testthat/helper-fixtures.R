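# Shared fixtures built in code.

# A flat two-phase trace: constant OCR, one oligomycin injection.
flat_trace <- function(levels = c(100, 40), well = "w1", ppr = FALSE) {
  t <- 0:5 * 6
  ocr <- rep(levels, each = 3)
  respiration_trace(well, t, ocr,
                    ppr = if (ppr) ocr * 0.5 else NULL,
                    injections = data.frame(time_min = 15, agent = "oligomycin"))
}

# One well per condition carrying the reference measured means.
reference_wells <- function(genotypes = c("WT", "KO")) {
  ref <- reference_fluxes()
  measured <- c("glycerol_release", "ffa_release", "lactate_release",
                "glucose_uptake", "o2_consumption")
  ref <- ref[ref$quantity %in% measured & ref$genotype %in% genotypes, ]
  wide <- stats::reshape(ref[c("genotype", "treatment", "quantity", "mean")],
                         idvar = c("genotype", "treatment"),
                         timevar = "quantity", direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  wide$well <- paste0("ref_", seq_len(nrow(wide)))
  wide
}
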