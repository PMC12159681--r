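test_that("the packaged registry loads with all stores populated", {
  reg <- pkg_registry()
  expect_s3_class(reg, "cmr_registry")
  expect_gt(nrow(reg$parameters), 20)
  expect_false(anyDuplicated(reg$parameters$id) > 0)
  expect_gt(nrow(reg$ranges), 90)
  expect_length(reg$lms, 8)          # 2 atrial tables x 2 sexes + 2 aortic x 2
  expect_gt(length(reg$regression), 15)
  expect_length(reg$centiles, 4)     # 3 LV volume tables + LA volume
  expect_true(all(c("table02", "table36", "table71") %in% names(reg$meta)))
})

test_that("reference selection routes by stratum specificity", {
  reg <- pkg_registry()
  # adult man, LVEF: the pooled adult table row
  sel <- select_reference(measurement_record("lvef", 50, sex = "male",
                                             age = 50), reg)
  expect_identical(sel$kind, "range")
  expect_identical(sel$table, "table02")
  expect_equal(sel$obj$mean, 66)
  expect_equal(sel$obj$sd, 7)
  expect_equal(c(sel$obj$lower, sel$obj$upper), c(53, 79))
  # boy age 6, BSA-indexed maximal LA volume: the LMS model
  sel2 <- select_reference(measurement_record("la_maxvol_bsa", 30,
                                              sex = "male", age = 6), reg)
  expect_identical(sel2$kind, "lms")
  g <- lms_interpolate(sel2$obj, 6)
  expect_equal(g, LMS_BOY6)
  # unknown parameter
  expect_error(select_reference(measurement_record("nonsense", 1), reg),
               "unknown parameter")
})

test_that("selection is deterministic and group-tagged rows need a group", {
  reg <- pkg_registry()
  rec <- measurement_record("lvedv", 250, sex = "male", age = 30)
  s1 <- select_reference(rec, reg)
  s2 <- select_reference(rec, reg)
  expect_identical(s1$id, s2$id)       # pure function of record + registry
  expect_identical(s1$table, "table02")
  # athlete rows only via the group selector
  sa <- select_reference(rec, reg, group = "regular athletes")
  expect_identical(sa$table, "table41")
  expect_equal(sa$obj$mean, 250)
  # equally specific rows within a kind are a configuration error
  child <- measurement_record("t1_native_myo", 1017, age = 10,
                              field_strength = 1.5)
  expect_error(select_reference(child, reg, group = "MOLLI"),
               "ambiguous")
  # a forced table plus full group string disambiguates
  sg <- select_reference(child, reg, group = "GE MOLLI 3b")
  expect_equal(sg$obj$mean, 1017)
})

test_that("classification against packaged ranges matches the printed limits", {
  reg <- pkg_registry()
  # LVEF 50% in an adult man: below the 53-79 range, z = (50-66)/7
  cl <- classify(measurement_record("lvef", 50, sex = "male", age = 50), reg)
  expect_identical(cl$status, "below_range")
  expect_equal(cl$z, (50 - 66) / 7, tolerance = 1e-12)
  # a value equal to the lower limit is within range (inclusive limits)
  expect_identical(
    classify(measurement_record("lvef", 53, sex = "male", age = 50),
             reg)$status, "within_range")
  # pediatric native T1 at the study mean: z = 0
  cl2 <- classify(measurement_record("t1_native_myo", 1017, age = 10,
                                     field_strength = 1.5),
                  reg, group = "GE MOLLI 3b")
  expect_identical(cl2$status, "within_range")
  expect_equal(cl2$z, 0)
  # selection failure is a status, not an error
  cl3 <- classify(measurement_record("lvef", 60), reg)
  expect_identical(cl3$status, "no_reference")
})

test_that("every packaged range row treats its printed limits as within-range", {
  reg <- pkg_registry()
  rr <- reg$ranges
  for (i in seq_len(nrow(rr))) {
    row <- rr[i, ]
    mk <- function(value) measurement_record(
      row$parameter_id, value,
      sex = if (row$sex == "all") "male" else row$sex,
      age = if (is.na(row$age_hi)) 50 else (row$age_lo + row$age_hi) / 2,
      ethnicity = if (row$ethnicity == "all") NA else row$ethnicity,
      field_strength = if (is.na(row$field_strength) ||
                           row$field_strength == "") NA
                       else as.numeric(row$field_strength),
      convention = if (row$convention == "not_applicable") NA
                   else row$convention)
    grp <- if (is.na(row$group) || row$group == "") NULL else row$group
    for (v in c(row$lower, row$upper)) {
      cl <- classify(mk(v), reg, table = row$table_id, group = grp)
      expect_identical(cl$status, "within_range",
                       label = paste(row$row_id, "at", v))
    }
    cl_lo <- classify(mk(row$lower - 10^(-row$precision)), reg,
                      table = row$table_id, group = grp)
    expect_identical(cl_lo$status, "below_range",
                     label = paste(row$row_id, "below lower"))
  }
})

test_that("single-study rows reproduce their printed limits in bulk", {
  v <- verify_tables(pkg_registry())
  ss <- v[v$check == "mean_2sd_limits", ]
  expect_gt(nrow(ss), 0)
  expect_equal(ss$n_pass, ss$n_rows)
})

test_that("median/IQR rows classify by limits but carry no z-score", {
  reg <- pkg_registry()
  rec <- measurement_record("lvci", 3.0, sex = "female", age = 40)
  cl <- classify(rec, reg)
  expect_identical(cl$status, "within_range")
  expect_true(is.na(cl$z))
})

test_that("batch classification keeps going past per-row failures", {
  reg <- pkg_registry()
  df <- data.frame(
    parameter_id = c("lvef", "la_maxvol_bsa", "la_maxvol_bsa", "bogus"),
    value = c(50, 30, 30, 1),
    sex = c("male", "male", "male", "male"),
    age = c(50, 6, 99, 50),     # third row: age outside the LMS grid
    stringsAsFactors = FALSE)
  out <- classify_measurements(df, reg)
  expect_equal(nrow(out), 4)
  expect_identical(out$status[1], "below_range")
  expect_identical(out$status[2], "within_range")
  expect_identical(out$status[3], "no_reference")  # no applicable model
  expect_true(is.na(out$status[4]))
  expect_match(out$error[4], "unknown parameter")
})
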