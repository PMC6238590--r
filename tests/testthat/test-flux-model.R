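test_that("a single noise-free well yields the closed-form derived cells", {
  wells <- data.frame(genotype = "WT", treatment = "iso", well = "w1",
                      glycerol_release = 28.2, ffa_release = 66.6,
                      lactate_release = 98.4, glucose_uptake = 3.5,
                      o2_consumption = 165.6)
  fit <- flux_model(wells)
  cm <- coef(fit)
  expect_equal(cm[1, "ffa_oxidized"], 7.2)
  expect_equal(cm[1, "ffa_reesterified"], 10.8)
  expect_equal(cm[1, "tag_hydrolyzed"], 28.2)
  expect_equal(cm[1, "co2_production"], 165.6 * 0.7)
  expect_equal(cm[1, "glucose_demand"], 49.2)
  expect_equal(cm[1, "glycogen_mobilization"], 45.7)
  tab <- flux_table(fit)
  expect_true(all(tab$sd[tab$n == 1] == 0))
})

test_that("identical wells aggregate with zero SD; derivation commutes with aggregation", {
  w1 <- data.frame(genotype = "KO", treatment = "iso", well = paste0("w", 1:3),
                   glycerol_release = 58.2, ffa_release = 124.8,
                   lactate_release = 165.6, glucose_uptake = 3.8,
                   o2_consumption = 151.8)
  fit <- flux_model(w1)
  tab <- flux_table(fit)
  expect_true(all(tab$sd == 0))
  expect_true(all(tab$n == 3))
  # per-well-then-aggregate equals aggregate-then-derive when wells are identical
  one <- flux_model(w1[1, ])
  expect_equal(coef(fit), coef(one))
})

test_that("rebuilding from aggregated means reproduces derived cells (idempotence)", {
  set.seed(31)
  wells <- reference_wells("WT")
  wells$glycerol_release <- wells$glycerol_release * exp(rnorm(nrow(wells), 0, 0.05))
  fit <- flux_model(wells)
  cm <- coef(fit)
  pseudo <- data.frame(genotype = "WT",
                       treatment = sub("^WT:", "", rownames(cm)),
                       well = rownames(cm),
                       glycerol_release = cm[, "glycerol_release"],
                       ffa_release = cm[, "ffa_release"],
                       lactate_release = cm[, "lactate_release"],
                       glucose_uptake = cm[, "glucose_uptake"],
                       o2_consumption = cm[, "o2_consumption"])
  refit <- flux_model(pseudo)
  for (q in c("ffa_oxidized", "ffa_reesterified", "tag_hydrolyzed",
              "co2_production", "glucose_demand")) {
    expect_equal(coef(refit)[, q], cm[, q], info = q)
  }
})

test_that("the fit derives the reference WT and KO stimulated blocks", {
  fit <- flux_model(reference_wells())
  cm <- coef(fit)
  expect_equal(round_half_away(cm["WT:iso", "ffa_oxidized"]), 7.2)
  expect_equal(round_half_away(cm["WT:iso", "ffa_reesterified"]), 10.8)
  expect_equal(round_half_away(cm["WT:iso", "tag_hydrolyzed"]), 28.2)
  expect_equal(round_half_away(cm["KO:iso", "ffa_oxidized"]), 6.6)
  expect_equal(round_half_away(cm["KO:iso", "tag_hydrolyzed"]), 58.2)
  # derived table cells satisfy their defining formulas given the measured cells
  tab <- flux_table(fit)
  for (i in which(tab$quantity == "tag_hydrolyzed")) {
    g <- tab$genotype[i]; tr <- tab$treatment[i]
    cell <- function(q) tab$mean[tab$genotype == g & tab$treatment == tr &
                                   tab$quantity == q]
    expect_equal(tab$mean[i],
                 (cell("ffa_release") + cell("ffa_oxidized") +
                    cell("ffa_reesterified")) / 3)
  }
  # KO oligomycin blocks flag below-zero re-esterification
  bz <- tab[tab$quantity == "ffa_reesterified" & tab$below_zero, ]
  expect_setequal(paste(bz$genotype, bz$treatment),
                  c("KO oligo_basal", "KO oligo_iso"))
})

test_that("missing measurements stay absent rather than becoming zero", {
  wells <- reference_wells("WT")  # glucose uptake NA in oligomycin blocks
  fit <- flux_model(wells)
  tab <- flux_table(fit)
  cell <- tab[tab$treatment == "oligo_iso" & tab$quantity == "glucose_uptake", ]
  expect_equal(cell$n, 0)
  expect_true(is.na(cell$mean))
  expect_error(flux_model(transform(wells, lactate_release = -1)), "negative")
  expect_error(flux_model(wells[, -4]), "missing column")
})

test_that("condition contrasts report fold-change and difference", {
  fit <- flux_model(reference_wells())
  cc <- compare_conditions(fit, "tag_hydrolyzed", c("WT", "basal"), c("WT", "iso"))
  expect_equal(cc$fold, 3.92, tolerance = 0.01)
  cc2 <- compare_conditions(fit, "lactate_release", c("WT", "basal"), c("KO", "basal"))
  expect_equal(cc2$fold, 1.93, tolerance = 0.01)
  same <- compare_conditions(fit, "ffa_release", c("WT", "iso"), c("WT", "iso"))
  expect_equal(same$fold, 1)
  expect_equal(same$diff, 0)
  expect_error(compare_conditions(fit, "ffa_release", c("WT", "nope"), c("WT", "iso")),
               "no cell")
})

test_that("model methods: print, summary, residuals, predict, simulate, plot", {
  wells <- reference_wells()
  wells$ppr_measured <- decompose_ppr(wells$o2_consumption,
                                      wells$lactate_release,
                                      wells$ffa_release)$modeled_total + 2
  fit <- flux_model(wells)
  expect_output(print(fit), "conditions")
  expect_output(print(summary(fit)), "Per-condition flux table")
  expect_output(print(summary(fit)), "<0")  # censored re-esterification cells
  res <- residuals(fit)
  expect_equal(unname(res), rep(2, 8), tolerance = 1e-9)
  pr <- predict(fit, data.frame(o2_consumption = 165.6, glycerol_release = 28.2,
                                ffa_release = 66.6, lactate_release = 98.4))
  expect_equal(pr$tag_hydrolyzed, 28.2)
  pp <- predict(fit, data.frame(o2_consumption = 100, glycerol_release = 1,
                                ffa_release = 10, lactate_release = 50),
                type = "ppr")
  expect_equal(pp$modeled_total, 65 + 50 + 10)
  sims <- simulate(fit, nsim = 2, seed = 9, wells_per_condition = 4)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), 8 * 4)
  refit <- flux_model(sims[[1]])
  expect_equal(nrow(coef(refit)), nrow(coef(fit)))
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp))
  unlink(tmp)
})
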