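# Design arithmetic: critical diameters, shifts, resets, device spec.

test_that("critical diameter constructions match their closed forms", {
  # parabolic: root of 3x^2 - 2x^3 = 1/7 by independent bisection
  f <- function(x) 3 * x^2 - 2 * x^3 - 1 / 7
  lo <- 0; hi <- 0.5
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  x_ref <- (lo + hi) / 2
  expect_equal(x_ref, 0.2378968, tolerance = 1e-6)

  par <- critical_diameter(63, 1 / 7, "parabolic")
  expect_equal(par$profile_root, x_ref, tolerance = 1e-9)
  expect_equal(par$dc_um, 2 * 63 * x_ref, tolerance = 1e-9)
  expect_equal(round(par$dc_um), 30)
  expect_equal(par$dc_um, 2 * par$beta_um)

  plug <- critical_diameter(63, 1 / 7, "plug")
  expect_identical(plug$dc_um, 2 * 63 / 7)

  dav <- critical_diameter(63, 1 / 7, "davis")
  expect_equal(dav$dc_um, 1.4 * 63 * exp(0.48 * log(1 / 7)),
               tolerance = 1e-12)
  expect_equal(dav$dc_um, 34.66, tolerance = 0.01)
  expect_true(is.na(dav$beta_um))
})

test_that("critical diameter rejects invalid domains", {
  expect_error(critical_diameter(-1, 0.1), "positive")
  expect_error(critical_diameter(63, 0), "strictly in")
  expect_error(critical_diameter(63, 1), "strictly in")
})

test_that("critical diameter is increasing in gap and shift fraction", {
  for (method in c("plug", "parabolic", "davis")) {
    dc_g <- vapply(seq(20, 100, by = 20), function(g)
      critical_diameter(g, 1 / 7, method)$dc_um, numeric(1))
    expect_true(all(diff(dc_g) > 0), info = method)
    dc_e <- vapply(seq(0.05, 0.45, by = 0.1), function(e)
      critical_diameter(63, e, method)$dc_um, numeric(1))
    expect_true(all(diff(dc_e) > 0), info = method)
  }
})

test_that("parabolic exceeds plug for shift fractions below one half", {
  for (e in c(0.05, 1 / 7, 0.3, 0.45)) {
    expect_gt(critical_diameter(63, e, "parabolic")$dc_um,
              critical_diameter(63, e, "plug")$dc_um)
  }
})

test_that("row shifts reproduce the mask values", {
  expect_identical(row_shift(140, 1 / 7), 20)
  expect_identical(row_shift(113, 1 / 7, round_to_um = TRUE), 16)
  expect_equal(row_shift(113, 1 / 7), 113 / 7)
  expect_identical(row_shift(113, 0), 0)
})

test_that("reset budget is columns plus margin", {
  expect_equal(reset_requirements(32, 16),
               tibble::tibble(min_resets = 32, total_resets = 48))
  expect_equal(reset_requirements(8, 4),
               tibble::tibble(min_resets = 8, total_resets = 12))
  expect_equal(reset_requirements(1, 0),
               tibble::tibble(min_resets = 1, total_resets = 1))
  # minimum scales linearly with columns
  ns <- c(2, 5, 11, 40)
  expect_equal(reset_requirements(ns * 3, 0)$min_resets,
               3 * reset_requirements(ns, 0)$min_resets)
})

test_that("the two-stage device spec satisfies its own arithmetic", {
  dev <- two_stage_device()
  s1 <- dev$stage1; s2 <- dev$stage2
  expect_equal(s1$pitch, 50 + 63)
  expect_equal(s2$pitch, 77 + 63)
  expect_equal(s1$ceiling_height, 90)
  expect_equal(s2$ceiling_height, 30)
  expect_equal(s1$row_shift, round(s1$pitch * s1$shift_fraction))
  expect_equal(s2$row_shift, round(s2$pitch * s2$shift_fraction))
  expect_identical(s2$row_shift, 20)
  expect_identical(s1$row_shift, 16)
  expect_equal(s1$n_columns, 8)
  expect_equal(s2$n_resets, 48)
  expect_length(dev$outputs, 3)

  rep <- design_report(dev)
  expect_equal(rep$dc_nominal_um, c(30, 30))
  expect_equal(rep$reset_margin, c(4, 16))
})

test_that("stage and device tidiers give one row per stage", {
  dev <- two_stage_device()
  td <- tidy(dev)
  expect_equal(nrow(td), 2)
  expect_equal(td$pitch_um, c(113, 140))
  expect_equal(td$rows_per_reset, c(10, 10))
})

test_that("pillar constructors validate their inputs", {
  expect_error(pillar_cylinder(0))
  expect_error(pillar_hybrid(77, 60, groove_width_fraction = 1.2),
               "fractions")
  expect_error(pillar_hybrid(77, 60, ellipse_fraction = 0), "fractions")
  # degenerate grooves are allowed: plain rectangle + semi-ellipse
  p <- pillar_hybrid(77, 60, groove_width_fraction = 0,
                     groove_depth_fraction = 0)
  expect_equal(p$groove_width_fraction, 0)
})
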