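test_that("trace construction enforces its invariants", {
  expect_error(respiration_trace("w", c(0, 0, 6), c(1, 1, 1)), "increasing")
  expect_error(respiration_trace("w", 0:2, c(1, 1)), "length")
  expect_error(respiration_trace("w", 0:2 * 6, rep(1, 3),
                                 injections = data.frame(time_min = 30,
                                                         agent = "oligomycin")),
               "inside the trace")
  expect_error(respiration_trace("w", 0:2 * 6, rep(1, 3),
                                 injections = data.frame(time_min = 3,
                                                         agent = "rotenone")),
               "unknown agent")
})

test_that("phase segmentation averages and converts units", {
  # constant 100 pmol/min in a 0.1 cm2 well -> 60 nmol/h/cm2 in every phase
  tr <- flat_trace(c(100, 100))
  ph <- segment_phases(tr, well_area = 0.1)
  expect_equal(unname(ph$ocr), c(60, 60))
  # hand-averaged two-phase trace with skip_first = 1
  tr2 <- respiration_trace("w2", 0:4 * 6, c(10, 10, 10, 4, 4),
                           injections = data.frame(time_min = 15,
                                                   agent = "oligomycin"))
  ph2 <- segment_phases(tr2, well_area = 1, skip_first = 1)
  expect_equal(unname(ph2$ocr), c(10, 4) * 60 / 1000)
  expect_equal(unname(ph2$n_points), c(3, 1))
  # a phase emptied by skipping is an error naming the phase
  expect_error(segment_phases(tr2, well_area = 1, skip_first = 2),
               "post_oligomycin")
})

test_that("segmentation is invariant to uniform time translation", {
  tr <- respiration_trace("w", 0:5 * 6, c(90, 95, 100, 42, 40, 38),
                          injections = data.frame(time_min = 15,
                                                  agent = "oligomycin"))
  shifted <- respiration_trace("w", 0:5 * 6 + 37.5, c(90, 95, 100, 42, 40, 38),
                               injections = data.frame(time_min = 52.5,
                                                       agent = "oligomycin"))
  expect_equal(segment_phases(tr)$ocr, segment_phases(shifted)$ocr)
})

test_that("respiration components follow their defining differences", {
  # isoproterenol response over basal (reference WT magnitudes)
  comp <- decompose_respiration(c(basal = 50.4, post_isoproterenol = 165.6))
  expect_equal(comp$iso_induced, 115.2)
  expect_equal(comp$iso_percent_of_basal, 328.6, tolerance = 1e-3)
  # coupled respiration as the oligomycin drop (reference KO magnitudes)
  comp2 <- decompose_respiration(c(basal = 44.4, post_oligomycin = 20.4))
  expect_equal(comp2$coupled, 24.0)
  expect_false(comp2$flags$coupled_negative)
  # all-equal phases give zero difference components
  comp3 <- decompose_respiration(c(basal = 10, post_oligomycin = 10,
                                   post_isoproterenol = 10, post_FCCP = 10,
                                   post_antimycinA = 10))
  expect_equal(comp3$coupled, 0)
  expect_equal(comp3$iso_induced, 0)
  expect_equal(comp3$mito_basal, 0)
  expect_error(decompose_respiration(c(basal = 10),
                                     protocol_order = "oligomycin"),
               "missing phase")
})

test_that("basal respiration splits exactly into mitochondrial and non-mitochondrial", {
  for (b in c(20, 50.4, 151.8)) {
    nm <- b * 0.1
    comp <- decompose_respiration(c(basal = b, post_antimycinA = nm))
    expect_identical(comp$mito_basal + comp$non_mito, comp$total_basal)
  }
})

test_that("components are recovered exactly from a noise-free synthetic trace", {
  area <- 0.106
  lev <- c(basal = 50, post_oligomycin = 20, post_isoproterenol = 160,
           post_FCCP = 200, post_antimycinA = 5)
  to_pmol <- 1000 * area / 60
  tr <- respiration_trace("w", 0:19 * 6, rep(lev * to_pmol, each = 4),
                          injections = data.frame(time_min = c(21, 45, 69, 93),
                                                  agent = c("oligomycin",
                                                            "isoproterenol",
                                                            "FCCP", "antimycinA")))
  comp <- decompose_respiration(segment_phases(tr, well_area = area))
  expect_equal(comp$total_basal, 50)
  expect_equal(comp$coupled, 30)           # basal - post-oligomycin
  expect_equal(comp$iso_induced, 140)      # post-iso - post-oligomycin (preceding phase)
  expect_equal(comp$max_capacity, 200)
  expect_equal(comp$non_mito, 5)
  expect_equal(comp$mito_basal, 45)
})

test_that("oligomycin sensitivity is a clamped, flagged fraction", {
  # Ucp1-KO: induced respiration largely abolished by oligomycin
  s_ko <- oligo_sensitivity(151.8 - 44.4, 48.0 - 20.4)
  expect_equal(as.numeric(s_ko), 0.743, tolerance = 1e-3)
  expect_false(any(attr(s_ko, "clamped")))
  # WT: response under oligomycin exceeds the free response -> clamped to 0
  s_wt <- oligo_sensitivity(115.2, 152.4 - 18.6)
  expect_equal(as.numeric(s_wt), 0)
  expect_true(all(attr(s_wt, "clamped")))
  expect_equal(as.numeric(oligo_sensitivity(100, 0)), 1)
  expect_error(oligo_sensitivity(0, 10), "non-positive")
})
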