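test_that("back reference is the unweighted mean and is permutation invariant", {
  expect_identical(back_reference(c(34, 34, 34)), 34)
  expect_identical(back_reference(c(33.5, 34.0, 34.5)), 34)
  expect_identical(back_reference(c(34.5, 33.5, 34.0)), 34)
  expect_error(back_reference(c(34, 34)), "three")
})

test_that("the temperature index is the Celsius ratio with the documented guards", {
  expect_identical(temperature_index(34, 34), 1)
  expect_identical(temperature_index(30.6, 34), 0.9)
  expect_equal(temperature_index(28.65, 34), 0.8426, tolerance = 1e-4)
  expect_error(temperature_index(30, 0), "> 0 degC")
  expect_error(temperature_index(30, -300), "absolute zero")
  ## Kelvin variant compresses the ratio toward 1
  expect_equal(temperature_index(30.6, 34, scale = "kelvin"),
               303.75 / 307.15, tolerance = 1e-12)
})

test_that("TI is invariant under common positive rescaling of both temperatures", {
  set.seed(31)
  for (i in 1:50) {
    tp <- runif(1, 25, 34); tb <- runif(1, 30, 36); k <- runif(1, 0.2, 5)
    expect_equal(temperature_index(k * tp, k * tb), temperature_index(tp, tb),
                 tolerance = 1e-12)
  }
})

test_that("composite scores are exact sums with validated ranges", {
  expect_identical(ti_total(c(1, 1, 1, 1)), 4)
  expect_identical(ti_total(c(0.9, 0.9, 0.9, 0.9)), 3.6)
  expect_identical(ti_total(c(0.9, 1, 0.8, 0.95)), ti_total(c(0.95, 0.8, 1, 0.9)))
  expect_identical(total_clinical_score(c(4, 4, 4, 4)), 16L)
  expect_identical(total_clinical_score(c(0, 0, 0, 0)), 0L)
  expect_identical(total_clinical_score(c(1, 2, 3, 4)), 10L)
  expect_error(total_clinical_score(c(1, 2, 3, 5)), "0..4")
  expect_equal(total_thickness(c(1.79, 1.79, 1.79, 1.80)), 7.17)
  expect_identical(total_thickness(c(2, 1, 3, 2)), total_thickness(c(3, 2, 2, 1)))
  expect_error(total_thickness(c(0, 2, 2, 2)), "positive")
})

test_that("severity bins follow the left-closed boundaries for all three modalities", {
  expect_identical(as.character(classify_severity(0.82, "TI")), "absent")
  expect_identical(as.character(classify_severity(0.92, "TI")), "moderate")
  expect_identical(as.character(classify_severity(0.90, "TI")), "moderate")
  expect_identical(as.character(classify_severity(c(0.85, 0.95), "TI")),
                   c("mild", "severe"))
  expect_identical(as.character(classify_severity(c(1.7, 2.0, 2.5, 3.0), "THK")),
                   c("absent", "mild", "moderate", "severe"))
  expect_identical(as.character(classify_severity(0:4, "CS")),
                   c("absent", "mild", "moderate", "moderate", "severe"))
  expect_error(classify_severity(2.5, "CS"), "integers")
})

test_that("severity classification is non-decreasing in the measured value", {
  ti_lv <- suppressWarnings(classify_severity(seq(0.7, 1.1, by = 0.01), "TI"))
  expect_true(all(diff(as.integer(ti_lv)) >= 0))
  thk_lv <- suppressWarnings(classify_severity(seq(1.2, 3.8, by = 0.05), "THK"))
  expect_true(all(diff(as.integer(thk_lv)) >= 0))
})

test_that("out-of-range TI values classify with a warning", {
  expect_warning(lv <- classify_severity(0.78, "TI"), "absent")
  expect_identical(as.character(lv), "absent")
  expect_warning(lv2 <- classify_severity(1.03, "TI"), "maximum")
  expect_identical(as.character(lv2), "severe")
})

test_that("the inclusion rule requires all four joints at TI >= 0.9, boundary inclusive", {
  expect_true(mouse_inclusion(c(0.92, 0.95, 0.91, 0.93)))
  expect_false(mouse_inclusion(c(0.92, 0.88, 0.95, 0.93)))
  expect_true(mouse_inclusion(c(0.90, 0.90, 0.90, 0.90)))
  expect_error(mouse_inclusion(c(0.92, NA, 0.95, 0.93)), "present")
})

test_that("scoring a hand-built table gives analytic ratios and sums", {
  tbl <- make_cohort_table("M1", "CIA", 28,
                           paw_temps = c(30.6, 34, 27.2, 32.3),
                           back_temps = c(33.5, 34.0, 34.5),
                           thickness = c(2.5, 3.0, 1.8, 2.7),
                           clinical = c(2L, 4L, 0L, 3L))
  sc <- score_cohort(tbl)
  expect_identical(nrow(sc), 1L)
  expect_equal(sc$t_back, 34)
  expect_equal(sc$ti_fl, 0.9)
  expect_equal(sc$ti_fr, 1.0)
  expect_equal(sc$ti_hl, 0.8)
  expect_equal(sc$ti_hr, 0.95)
  expect_equal(sc$ti_total, 3.65)
  expect_equal(sc$total_thickness, 10.0)
  expect_identical(sc$total_clinical, 9L)
  expect_false(sc$included)  # HL below 0.9
})

test_that("summing temperatures before normalizing is not equivalent to TI_total", {
  ## normalizing paw temperatures by *their own* back reference (as when
  ## measurements come from different frames) is not the same as summing
  ## temperatures first and normalizing by the average back; they coincide
  ## only in the degenerate equal-back case
  paws <- c(30.6, 31.5, 29.8, 32.0)
  backs <- c(33.2, 34.6, 33.9, 34.3) # one back reference per measurement
  ti_sum <- ti_total(temperature_index(paws, backs))
  wrong <- 4 * temperature_index(sum(paws), sum(backs))
  expect_false(isTRUE(all.equal(ti_sum, wrong)))
  ## degenerate case: a single shared back makes the two routes agree
  expect_equal(ti_total(temperature_index(paws, 34)), sum(paws) / 34,
               tolerance = 1e-12)
})

test_that("severity heatmap counts match a brute-force recount on random cohorts", {
  set.seed(32)
  for (i in 1:20) {
    co <- generate_cohort(cohort_config(seed = 400 + i))
    sc <- score_cohort(co)
    hm <- suppressWarnings(severity_heatmap(sc, day = 28, modality = "TI",
                                            group = "CIA"))
    d28 <- sc[sc$day == 28 & sc$group == "CIA", ]
    tis <- as.matrix(d28[, c("ti_fl", "ti_fr", "ti_hl", "ti_hr")])
    expect_identical(hm$n_moderate_severe,
                     sum(apply(tis >= 0.9, 1, all)))
    expect_identical(hm$n_mild_severe,
                     sum(apply(tis >= 0.85, 1, all)))
    expect_identical(hm$n_mice, nrow(d28))
    expect_identical(dim(hm$labels), c(nrow(d28), 4L))
  }
})

test_that("an all-healthy cohort shows no disease; uniform severe mice are flagged", {
  co <- generate_cohort(cohort_config(n_cia = 0, n_control = 6,
                                      n_nonresponders = 0, seed = 9))
  hm <- suppressWarnings(severity_heatmap(score_cohort(co), day = 28,
                                          modality = "TI"))
  expect_identical(hm$n_moderate_severe, 0L)
  sev <- make_cohort_table("S1", "CIA", 28,
                           paw_temps = rep(0.96 * 34, 4),
                           back_temps = rep(34, 3))
  hm2 <- severity_heatmap(score_cohort(sev), day = 28, modality = "TI")
  expect_identical(unname(hm2$labels[1, ]), rep("severe", 4))
})
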