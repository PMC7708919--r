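test_that("a half-pixel circle centered on a pixel center selects exactly that pixel", {
  roi <- ellipse_roi("x", 10, 7, 0.5, 0.5)
  m <- ellipse_mask(roi, c(20, 20))
  expect_identical(sum(m), 1L)
  expect_true(m[8, 11]) # 0-based (10, 7) -> row 8, col 11
})

test_that("mask pixel counts match the exhaustive pixel-center oracle", {
  set.seed(21)
  for (i in 1:100) {
    a <- runif(1, 0.6, 12); b <- runif(1, 0.6, 12)
    cx <- runif(1, 5, 70); cy <- runif(1, 5, 50)
    rot <- runif(1, 0, pi)
    roi <- ellipse_roi("r", cx, cy, a, b, rot)
    m <- ellipse_mask(roi, c(60, 80))
    expect_identical(m, oracle_ellipse_pixels(cx, cy, a, b, rot, 60, 80))
  }
})

test_that("large-ellipse pixel count approaches the continuous area pi*a*b", {
  roi <- ellipse_roi("big", 100, 100, 10, 5)
  count <- sum(ellipse_mask(roi, c(200, 200)))
  expect_lt(abs(count - pi * 10 * 5), 3)
})

test_that("circle masks are rotation invariant; off-frame ROIs raise errors", {
  for (rot in c(0, 0.3, 1.1, pi / 2)) {
    m <- ellipse_mask(ellipse_roi("c", 30, 30, 7, 7, rot), c(60, 80))
    expect_identical(sum(m), sum(ellipse_mask(ellipse_roi("c", 30, 30, 7, 7), c(60, 80))))
  }
  expect_error(ellipse_mask(ellipse_roi("off", 500, 500, 2, 2), c(60, 80)),
               "no pixel")
})

test_that("ROI statistics match the per-pixel oracle on random frames", {
  set.seed(22)
  for (i in 1:100) {
    img <- matrix(runif(40 * 50, 20, 40), 40, 50)
    fr <- thermal_frame(img)
    roi <- ellipse_roi("r", runif(1, 4, 45), runif(1, 4, 35),
                       runif(1, 1, 8), runif(1, 1, 8), runif(1, 0, pi))
    st <- roi_stats(fr, roi)
    ref <- oracle_stats(img[oracle_ellipse_pixels(roi$center_x, roi$center_y,
                                                  roi$semi_axis_a, roi$semi_axis_b,
                                                  roi$rotation, 40, 50)])
    expect_equal(st$mean, ref$mean, tolerance = 1e-9)
    expect_equal(st$sd, ref$sd, tolerance = 1e-9)
    expect_identical(st$min, ref$min)
    expect_identical(st$max, ref$max)
    expect_identical(st$n_pixels, ref$n)
  }
})

test_that("hand-computed two-pixel ROI statistics are exact", {
  img <- matrix(34, 3, 4)
  img[2, 2] <- 30
  img[2, 3] <- 34
  fr <- thermal_frame(img)
  ## ellipse covering exactly pixels (1,1) and (2,1) in 0-based coords
  st <- roi_stats(fr, ellipse_roi("p", 1.5, 1, 0.6, 0.1))
  expect_identical(st$n_pixels, 2L)
  expect_equal(st$mean, 32)
  expect_equal(st$sd, 2)       # population SD of {30, 34}
  expect_equal(st$min, 30)
  expect_equal(st$max, 34)
})

test_that("nested masks have monotone extrema (min up, max down as ROI shrinks)", {
  set.seed(23)
  for (i in 1:20) {
    img <- matrix(runif(60 * 80, 25, 38), 60, 80)
    fr <- thermal_frame(img)
    sizes <- c(10, 6, 3, 1.2)
    stats <- lapply(sizes, function(s)
      roi_stats(fr, ellipse_roi("n", 40, 30, s, s * 0.8)))
    mins <- vapply(stats, `[[`, 0, "min")
    maxs <- vapply(stats, `[[`, 0, "max")
    expect_true(all(diff(mins) >= 0))
    expect_true(all(diff(maxs) <= 0))
  }
})

test_that("uniform frames give mean equal to the constant and zero SD", {
  fr <- thermal_frame(matrix(34, 60, 80))
  st <- roi_stats(fr, default_roi_layout()$FL)
  expect_identical(st$mean, 34)
  expect_identical(st$sd, 0)
})

test_that("the standardized layout has 7 ROIs with the documented roles and scales linearly", {
  lay <- default_roi_layout(c(60, 80))
  expect_length(lay, 7L)
  expect_setequal(names(lay), c("FL", "FR", "HL", "HR", "back1", "back2", "back3"))
  roles <- vapply(lay, `[[`, "", "emissivity_role")
  expect_identical(unname(roles[c("FL", "FR", "HL", "HR")]), rep("skin", 4))
  expect_identical(unname(roles[c("back1", "back2", "back3")]), rep("fur", 3))
  expect_identical(default_roi_layout(c(60, 80)), lay) # deterministic
  big <- default_roi_layout(c(120, 160))
  for (nm in names(lay)) {
    for (f in c("center_x", "center_y", "semi_axis_a", "semi_axis_b"))
      expect_equal(big[[nm]][[f]], 2 * lay[[nm]][[f]])
  }
  expect_error(default_roi_layout(c(30, 40)), "too small")
})

test_that("ROI layouts survive a JSON round trip", {
  lay <- default_roi_layout()
  path <- withr::local_tempfile(fileext = ".json")
  write_roi_layout(lay, path)
  expect_equal(read_roi_layout(path), lay)
})

test_that("radiometric frames are corrected per ROI tissue role before statistics", {
  ## apparent-temperature phantom: ROI extraction must undo the per-role
  ## emissivity transform and recover the true surface temperatures
  st <- mouse_state(c(FL = 31.9, FR = 29.2, HL = 28.4, HR = 30.1),
                    back_temp = 34.2)
  ph <- generate_phantom_frame(st, camera_model(noise_sd = 0),
                               emit_apparent = TRUE, reflected_temp = 24)
  expect_true(ph$frame$metadata$radiometric)
  sc <- score_frame(ph$frame, ph$layout)
  expect_equal(unname(sc$roi$FL$mean), 31.9, tolerance = 1e-9)
  expect_equal(unname(sc$roi$back2$mean), 34.2, tolerance = 1e-9)
  expect_equal(sc$t_back, 34.2, tolerance = 1e-9)
})
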