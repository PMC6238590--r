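test_that("simulation is bit-reproducible under a fixed seed", {
  tr <- synthetic_truth(seed = 123, wells_per_condition = 3)
  s1 <- simulate_experiment(tr)
  s2 <- simulate_experiment(tr)
  expect_identical(s1$metabolites, s2$metabolites)
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$glycogen, s2$glycogen)
  s3 <- simulate_experiment(synthetic_truth(seed = 124, wells_per_condition = 3))
  expect_false(identical(s1$metabolites, s3$metabolites))
})

test_that("truth validation rejects invalid generators before drawing", {
  expect_error(synthetic_truth(noise_sd = -0.1), ">= 0")
  expect_error(synthetic_truth(wells_per_condition = 0), "at least one")
  bad <- data.frame(genotype = "WT", treatment = "basal",
                    quantity = "unicorn_release", mean = 1)
  expect_error(synthetic_truth(rates = bad), "unknown quantity")
  bad2 <- data.frame(genotype = "WT", treatment = "basal",
                     quantity = "ffa_release", mean = -5)
  expect_error(synthetic_truth(rates = bad2), ">= 0")
})

test_that("noise-free simulation round-trips to exact truth (master integration)", {
  tr0 <- synthetic_truth(seed = 5, wells_per_condition = 2,
                         noise_sd = 0, trace_jitter_sd = 0)
  sim <- simulate_experiment(tr0)
  fit <- flux_model(assemble_wells(sim))
  rep <- recovery_report(tr0, fit)
  expect_equal(rep$bias, rep(0, nrow(rep)), tolerance = 1e-12)
  expect_equal(rep$rmse, rep(0, nrow(rep)), tolerance = 1e-12)
  # PPR was generated from the model: residual is structurally zero
  expect_equal(unname(residuals(fit)), rep(0, 8), tolerance = 1e-9)
  # derived cells equal the closed-form bookkeeping of the truth
  cm <- coef(fit)
  expect_equal(cm["WT:iso", "tag_hydrolyzed"], 28.2)
  expect_equal(cm["KO:iso", "ffa_oxidized"], 6.6)
  # glycogen time course recovers the true depletion flux exactly
  gl <- sim$glycogen
  iso <- gl[gl$genotype == "WT" & gl$treatment == "iso", ]
  expect_equal(glycogen_flux_from_timecourse(iso$time_h, iso$content_ug), -54)
  basal <- gl[gl$genotype == "WT" & gl$treatment == "basal", ]
  expect_equal(glycogen_flux_from_timecourse(basal$time_h, basal$content_ug), 0)
})

test_that("below-zero re-esterification emerges in simulated KO oligomycin wells", {
  tr0 <- synthetic_truth(seed = 21, wells_per_condition = 4)
  fit <- flux_model(assemble_wells(simulate_experiment(tr0)))
  tab <- flux_table(fit)
  ko_oligo_iso <- tab[tab$genotype == "KO" & tab$treatment == "oligo_iso" &
                        tab$quantity == "ffa_reesterified", ]
  expect_true(ko_oligo_iso$below_zero)
  expect_lt(ko_oligo_iso$mean, 0)
})

test_that("recovery error of measured rates shrinks as 1/sqrt(wells)", {
  rel_rmse_at <- function(nw, seeds) {
    errs <- unlist(lapply(seeds, function(s) {
      tr <- synthetic_truth(seed = s, wells_per_condition = nw,
                            trace_jitter_sd = 0)
      sim <- simulate_experiment(tr)
      m <- sim$metabolites
      m$o2_consumption <- 1  # metabolite recovery only; OCR unused here
      cm <- coef(flux_model(m))
      unlist(lapply(c("glycerol_release", "ffa_release", "lactate_release"),
                    function(q) {
        conds <- do.call(rbind, strsplit(rownames(cm), ":", fixed = TRUE))
        tv <- mapply(function(g, tr2) {
          r <- tr$rates
          r$mean[r$genotype == g & r$treatment == tr2 & r$quantity == q]
        }, conds[, 1], conds[, 2])
        (cm[, q] - tv) / tv
      }))
    }))
    sqrt(mean(errs^2))
  }
  seeds <- 101:110
  r3 <- rel_rmse_at(3, seeds)
  r12 <- rel_rmse_at(12, seeds)
  r48 <- rel_rmse_at(48, seeds)
  expect_gt(r3, r12)
  expect_gt(r12, r48)
  # theoretical ratio sqrt(48/3) = 4
  expect_gt(r3 / r48, 2.2)
  expect_lt(r3 / r48, 7)
})

test_that("recovery_report demands matching condition keys", {
  tr <- synthetic_truth(seed = 2, wells_per_condition = 2)
  sim <- simulate_experiment(tr)
  wells <- assemble_wells(sim)
  fit <- flux_model(wells[wells$genotype == "WT", ])
  expect_error(recovery_report(tr, fit), "lack condition")
})

test_that("an injected unexplained acidification shows up as PPR residual", {
  tr <- synthetic_truth(seed = 8, wells_per_condition = 3,
                        noise_sd = 0, trace_jitter_sd = 0, unexplained_ppr = 12)
  fit <- flux_model(assemble_wells(simulate_experiment(tr)))
  expect_equal(unname(residuals(fit)), rep(12, 8), tolerance = 1e-9)
})
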