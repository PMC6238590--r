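test_that("hydrated CO2 fraction follows the Henderson-Hasselbalch equilibrium", {
  expect_equal(hydrated_fraction(6.093, 6.093), 0.5)
  expect_equal(hydrated_fraction(7.4), 0.953, tolerance = 1e-3)
  expect_equal(hydrated_fraction(20), 1, tolerance = 1e-8)
  # strictly increasing in pH, strictly decreasing in pKa, always in (0,1)
  ph <- seq(4, 9, by = 0.25)
  f <- hydrated_fraction(ph)
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 0 & f < 1))
  pk <- seq(5, 8, by = 0.25)
  expect_true(all(diff(hydrated_fraction(7.4, pk)) < 0))
})

test_that("CO2 and proton production scale linearly with OCR", {
  expect_equal(co2_from_ocr(100, 0.7), 70)
  expect_equal(co2_from_ocr(151.8, 0.62), 94.1, tolerance = 1e-3)
  expect_equal(co2_from_ocr(0), 0)
  expect_error(co2_from_ocr(-1), ">= 0")
  expect_equal(ppr_from_co2(165.6), 107.6, tolerance = 1e-3)
  expect_equal(ppr_from_co2(0), 0)
  expect_error(ppr_from_co2(-5), ">= 0")
})

test_that("the net H+/O2 coefficient factorizes into stoichiometry times hydration", {
  expect_equal(round(h_per_o2_from_parts(16 / 23, 0.934), 2), 0.65)
})

test_that("organic acids release protons stoichiometrically", {
  expect_equal(ppr_from_metabolite(59.4), 59.4)
  expect_equal(ppr_from_metabolite(15.6), 15.6)
  expect_equal(ppr_from_metabolite(0), 0)
  expect_error(ppr_from_metabolite(-1), ">= 0")
})

test_that("proton-source decomposition sums its three contributions", {
  # basal WT magnitudes: lactic acid is the largest single source
  d <- decompose_ppr(ocr = 50.4, lactate_release = 59.4, ffa_release = 15.6)
  expect_equal(d$from_co2, 32.76)
  expect_equal(d$from_lactate, 59.4)
  expect_equal(d$from_ffa, 15.6)
  expect_equal(d$modeled_total, 107.76)
  expect_identical(d$modeled_total, d$from_co2 + d$from_lactate + d$from_ffa)
  expect_gt(d$from_lactate, max(d$from_co2, d$from_ffa))
  # all-zero input -> all-zero decomposition
  z <- decompose_ppr(0, 0, 0)
  expect_equal(unlist(z[c("from_co2", "from_lactate", "from_ffa",
                          "modeled_total")]), rep(0, 4), ignore_attr = TRUE)
  # stimulation deltas: CO2 and FFA each exceed the lactate contribution
  dd <- decompose_ppr(115.2, 39.0, 51.0)
  expect_gt(dd$from_co2, dd$from_lactate)
  expect_gt(dd$from_ffa, dd$from_lactate)
  expect_error(decompose_ppr(-1, 0, 0), ">= 0")
})

test_that("decomposition is additive in its inputs", {
  set.seed(11)
  for (i in 1:20) {
    a <- runif(3, 0, 200); b <- runif(3, 0, 200)
    da <- decompose_ppr(a[1], a[2], a[3])
    db <- decompose_ppr(b[1], b[2], b[3])
    dsum <- decompose_ppr(a[1] + b[1], a[2] + b[2], a[3] + b[3])
    expect_equal(dsum$modeled_total, da$modeled_total + db$modeled_total)
    expect_equal(dsum$from_co2, da$from_co2 + db$from_co2)
  }
})

test_that("residual is measured minus modeled when a measured PPR is supplied", {
  d <- decompose_ppr(100, 50, 10, measured_ppr = 130)
  expect_equal(d$residual, 130 - (65 + 50 + 10))
  expect_true(is.na(decompose_ppr(100, 50, 10)$residual))
})

test_that("raw acidification converts to proton rate via buffer power", {
  expect_equal(ecar_to_ppr(0, 2), 0)
  expect_equal(ecar_to_ppr(10, 2), 5)
  expect_equal(ecar_to_ppr(10, 4), ecar_to_ppr(10, 2) / 2)
  expect_equal(ecar_to_ppr(10, 2, well_area = 0.1), 5 * 60 / 0.1)
  expect_error(ecar_to_ppr(1, 0), "positive")
})
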