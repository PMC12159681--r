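test_that("body surface area formulas match their closed forms", {
  expect_equal(bsa(180, 80, "mosteller"), 2)
  # frozen high-precision evaluation of 0.007184 * 180^0.725 * 80^0.425
  expect_equal(bsa(180, 80, "dubois"), 1.9964210223, tolerance = 1e-9)
  expect_identical(formals(bsa)$formula[[2]], "dubois")  # default choice
  expect_error(bsa(0, 80), "positive")
  expect_error(bsa(180, -1), "positive")
})

test_that("BSA indexing is exact division with guarded input", {
  expect_equal(index_value(147, 2), 73.5)
  expect_equal(index_value(42, 1), 42)
  expect_equal(index_value(0, 1.7), 0)
  expect_error(index_value(100, 0), "positive")
})

test_that("area-length atrial volumes agree across variants", {
  # biplane with equal areas and shared length equals monoplane
  expect_equal(atrial_volume_biplane_ellipsoid(20, 20, 5, 5),
               atrial_volume_monoplane(20, 5))
  expect_equal(atrial_volume_monoplane(20, 5), 8 * 400 / (3 * pi * 5))
  expect_equal(atrial_volume_monoplane(20, 5), 67.906, tolerance = 1e-4)
  expect_equal(atrial_volume_monoplane(0, 5), 0)
  # calibrated variant and its near-unity ratio to the ellipsoid constant
  expect_equal(atrial_volume_biplane_calibrated(20, 20, 5, 5), 67.84)
  expect_equal(0.848 / (8 / (3 * pi)), 0.999, tolerance = 1e-3)
  # shortest-length rule vs mean-length rule
  vs <- atrial_volume_biplane_ellipsoid(18, 22, 6, 5, "shortest")
  vm <- atrial_volume_biplane_ellipsoid(18, 22, 6, 5, "mean")
  expect_gt(vs, vm)   # shorter denominator, larger volume
  # volume decreases monotonically as the length grows
  v <- atrial_volume_biplane_ellipsoid(20, 20, c(4, 6, 9, 15), c(4, 6, 9, 15))
  expect_true(all(diff(v) < 0))
})

test_that("sphericity index is 1 for a sphere and linear in volume", {
  r <- 3.1
  expect_equal(sphericity_index((4 * pi / 3) * r^3, 2 * r), 1)
  expect_equal(sphericity_index(150, 9), 150 / ((4 * pi / 3) * 4.5^3))
  expect_equal(sphericity_index(150, 9), 0.393, tolerance = 1e-3)
  expect_equal(sphericity_index(75, 9), sphericity_index(150, 9) / 2)
})

test_that("distensibility is a unit-free area ratio per pulse pressure", {
  expect_equal(distensibility(1, 1, 120, 80), 0)
  expect_equal(distensibility(1.1, 1.0, 120, 80), 2.5)  # 10^-3 / mmHg
  # same areas in mm^2 instead of cm^2
  expect_equal(distensibility(110, 100, 120, 80),
               distensibility(1.1, 1.0, 120, 80))
  expect_error(distensibility(1.1, 1.0, 80, 80), "pulse pressure")
  expect_error(distensibility(1.1, 0, 120, 80), "positive")
})

test_that("ECV follows the two-compartment delta-R1 ratio", {
  # equal myocardial and blood delta-R1: ECV = 1 - Hct
  expect_equal(ecv(1000, 500, 1000, 500, 0.42), 0.58)
  # delta-R1 ratio of one half at Hct 0.40
  expect_equal(ecv(1000, 2000 / 3, 1000, 500, 0.40), 0.30, tolerance = 1e-9)
  expect_equal(ecv(1000, 500, 1000, 500, 0.999), 0.001, tolerance = 1e-9)
  expect_error(ecv(-1, 500, 1600, 320, 0.4), "positive")
  expect_error(ecv(1000, 500, 1600, 320, 1.2), "hematocrit")
})

test_that("synthetic hematocrit requires a site calibration", {
  expect_error(synthetic_hct(1600), "calibration")
  expect_equal(synthetic_hct(1600, c(0, 0.4)), 0.4)
  # identity round-trip: invert the linear calibration
  cal <- c(900, -0.15)
  hct <- 0.45
  t1 <- cal[1] / (hct - cal[2])
  expect_equal(synthetic_hct(t1, cal), hct, tolerance = 1e-12)
  expect_warning(synthetic_hct(1600, c(0, 1.5)), "clipped")
  expect_error(synthetic_hct(-5, c(0, 0.4)), "positive")
})

test_that("T2*-derived quantities follow their power laws", {
  expect_equal(r2star(25), 40)
  expect_equal(r2star(1000), 1)
  expect_equal(1000 / r2star(17.3), 17.3)            # round trip
  # frozen high-precision value of 45 / 20^1.22
  expect_equal(iron_concentration(20), 1.1640078765, tolerance = 1e-9)
  t2 <- c(5, 10, 20, 40, 80)
  expect_true(all(diff(iron_concentration(t2)) < 0)) # strictly decreasing
  expect_lt(iron_concentration(1e6), 1e-5)
  expect_error(iron_concentration(0), "positive")
})

test_that("iron grading matches the threshold table at both field strengths", {
  expect_identical(as.character(grade_iron(25, "1.5T")), "normal")
  expect_identical(as.character(grade_iron(15, "1.5T")), "overload")
  expect_identical(as.character(grade_iron(4, "3T")), "severe")
  expect_identical(as.character(grade_iron(13, "3T")), "normal")
  # boundary values fall in the milder neighboring class below
  expect_identical(as.character(grade_iron(c(20, 10), "1.5T")),
                   c("overload", "overload"))
  expect_identical(as.character(grade_iron(c(12, 5.5), "3T")),
                   c("overload", "overload"))
})

test_that("iron grading partitions (0, Inf) at both field strengths", {
  t2 <- c(10^seq(-3, 3, length.out = 400),
          c(5.5, 10, 12, 20) + rep(c(-1e-9, 0, 1e-9), each = 4))
  for (f in c("1.5T", "3T")) {
    g <- grade_iron(t2, f)
    expect_false(anyNA(g))                    # no gaps
    # monotone: grade never worsens as T2* increases
    ord <- as.integer(factor(g[order(t2)],
                             levels = c("severe", "overload", "normal")))
    expect_true(all(diff(ord) >= 0))
  }
})

test_that("aortic stenosis staging takes the worst supplied criterion", {
  expect_identical(stage_aortic_stenosis(v_max = 4.2)$stage, "severe")
  expect_identical(stage_aortic_stenosis(v_max = 2.5)$stage, "mild")
  expect_identical(stage_aortic_stenosis(v_max = 3.0)$stage, "moderate")
  s <- stage_aortic_stenosis(orifice_area = 0.9)
  expect_identical(s$stage, "severe")
  expect_false(s$very_severe)
  expect_true(stage_aortic_stenosis(v_max = 5.1)$very_severe)
  # worst across criteria
  expect_identical(stage_aortic_stenosis(v_max = 2.5, area_bsa = 0.5)$stage,
                   "severe")
  expect_identical(stage_aortic_stenosis(v_max = 1.0)$stage, "none")
  expect_error(stage_aortic_stenosis(), "at least one")
})

test_that("diastolic classification returns all consistent classes", {
  expect_setequal(classify_diastolic(180, 1.5), c("normal", "type2"))
  expect_identical(classify_diastolic(300, 0.8), "type1")
  expect_identical(classify_diastolic(100, 2.5), "type3")
  expect_length(classify_diastolic(300, 1.5), 0)  # inconsistent combination
  expect_error(classify_diastolic(-10, 1), "positive")
})
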