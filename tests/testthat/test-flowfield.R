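# Unit-cell rasterization, Stokes solve, streamline critical diameter,
# wall shear and asymmetry.

test_that("rasterized masks match analytic footprint areas", {
  cell <- rasterize_pillar(pillar_cylinder(50), 63, 90, resolution = 1)
  area <- sum(cell$mask) * cell$dx^2
  expect_lt(abs(area - pi * 25^2) / (pi * 25^2), 0.02)

  hyb <- pillar_hybrid(77, 60)
  cellh <- rasterize_pillar(hyb, 63, 30, resolution = 1)
  areah <- sum(cellh$mask) * cellh$dx^2
  expect_lt(abs(areah - pillar_footprint_area(hyb)) /
              pillar_footprint_area(hyb), 0.02)
  # strictly asymmetric fore-aft: mirror difference > 0
  mirr <- cellh$mask[rev(seq_len(cellh$nx)), ]
  expect_gt(sum(cellh$mask != mirr), 0)

  # degenerate grooves: plain rectangle + semi-ellipse, still rasterizes
  plain <- pillar_hybrid(77, 60, groove_width_fraction = 0,
                         groove_depth_fraction = 0, corner_radius = 0)
  cellp <- rasterize_pillar(plain, 63, 30, resolution = 1)
  expect_lt(abs(sum(cellp$mask) * cellp$dx^2 -
                  pillar_footprint_area(plain)) /
              pillar_footprint_area(plain), 0.02)
})

test_that("too-coarse rasterization of grooved pillars is refused", {
  expect_error(rasterize_pillar(pillar_hybrid(77, 60), 63, 30,
                                resolution = 12), "coarser")
})

test_that("empty-cell solve recovers the plane-channel limit", {
  # a vanishing pillar leaves an unobstructed shallow channel: the
  # depth-averaged field is uniform and carries exactly the target flux
  cell <- rasterize_pillar(pillar_cylinder(1e-6), 63, 90,
                           resolution = 2)
  expect_equal(sum(cell$mask), 0)
  fld <- solve_unit_cell(cell, 4.9875)
  u_ref <- 4.9875 * 1e9 / 60 / (cell$Ly * cell$depth)
  expect_lt(max(abs(fld$ud - u_ref)) / u_ref, 0.01)
  expect_lt(max(abs(fld$vd)) / u_ref, 0.01)
  expect_equal(fld$um / fld$ud, matrix(1.5, cell$nx, cell$ny))
})

test_that("solved fields conserve mass and satisfy no-slip", {
  fld <- get_field("stage1")
  fx <- cross_section_flux(fld)
  expect_lt((max(fx) - min(fx)) / mean(fx), 1e-6)
  expect_equal(mean(fx), fld$per_gap_ulmin, tolerance = 1e-9)
  # velocities vanish on the mask
  expect_equal(max(abs(fld$um[fld$cell$mask])), 0)
  # discrete divergence of each mode vanishes in fluid cells
  cell <- fld$cell
  u <- fld$modes[[1]]$u
  v <- fld$modes[[1]]$v
  sh <- cell$shift_cells
  ue <- u[c(2:cell$nx, 1), ]
  ue[cell$nx, ] <- u[1, ((seq_len(cell$ny) - 1 - sh) %% cell$ny) + 1]
  vn <- v[, c(2:cell$ny, 1)]
  div <- (ue - u + vn - v) / cell$dx
  expect_lt(max(abs(div[!cell$mask])) / max(abs(u)), 1e-8)
})

test_that("Stokes linearity: the field scales exactly with flux", {
  cell <- rasterize_pillar(pillar_cylinder(50), 63, 90, resolution = 4,
                           row_shift = 16)
  f1 <- solve_unit_cell(cell, 2)
  f2 <- solve_unit_cell(cell, 4)
  expect_equal(f2$um, 2 * f1$um, tolerance = 1e-6)
  expect_equal(f2$vm, 2 * f1$vm, tolerance = 1e-6)
})

test_that("cylinder-cell speed is symmetric about the gap centerline", {
  # untilted cell: geometry is mirror-symmetric in y about the pillar
  cell <- rasterize_pillar(pillar_cylinder(50), 63, 90, resolution = 2)
  fld <- solve_unit_cell(cell, 4.9875)
  S <- sqrt(fld$um^2 + fld$vm^2)
  Sm <- S[, rev(seq_len(cell$ny))]
  keep <- !cell$mask & !cell$mask[, rev(seq_len(cell$ny))]
  expect_lt(sqrt(sum((S[keep] - Sm[keep])^2) / sum(S[keep]^2)), 0.02)
})

test_that("streamline critical diameter agrees with the parabolic oracle", {
  dc_cfd <- critical_diameter_from_field(get_field("stage1"), 1 / 7)
  dc_ref <- critical_diameter(63, 1 / 7, "parabolic")
  expect_lt(abs(dc_cfd$dc_um - dc_ref$dc_um) / dc_ref$dc_um, 0.10)
  expect_equal(dc_cfd$method, "cfd")
  expect_equal(dc_cfd$dc_um, 2 * dc_cfd$beta_um)
})

test_that("plug profile gives the first stream width g * eps", {
  # synthetic uniform midplane field across the gap
  cell <- rasterize_pillar(pillar_cylinder(50), 63, 90, resolution = 1,
                           row_shift = 16)
  um <- matrix(1000, cell$nx, cell$ny)
  fld <- synthetic_field(cell, um)
  b <- critical_diameter_from_field(fld, 1 / 7)
  expect_equal(b$beta_um, 63 / 7, tolerance = 0.15)
  # eps -> 1: the first stream fills the whole gap
  b99 <- critical_diameter_from_field(fld, 0.999)
  expect_equal(b99$beta_um, 63 * 0.999, tolerance = 0.15)
  # a real strong-drag (shallow) solve approaches the same limit
  bp <- critical_diameter_from_field(get_field("plug"), 1 / 7)
  expect_equal(bp$beta_um, 9, tolerance = 0.5)
})

test_that("flux fractions out of range are refused", {
  fld <- get_field("stage1")
  expect_error(critical_diameter_from_field(fld, 1.2), "strictly|TRUE")
})

test_that("wall shear is zero without flow and peaks at the throat", {
  cell <- rasterize_pillar(pillar_cylinder(50), 63, 90, resolution = 4,
                           row_shift = 16)
  f0 <- solve_unit_cell(cell, 0)
  s0 <- wall_shear_map(f0)
  expect_equal(s0$peak_pa, 0)

  sh <- wall_shear_map(get_field("stage1_3d"))
  # narrowest segment between pillars: the throat station
  expect_lt(abs(sh$peak_location[["x_um"]] -
                  get_field("stage1_3d")$cell$center[1]), 15)
  expect_gt(sh$peak_pa, 0)
})

test_that("peak shear and critical diameter are grid-converged", {
  q1 <- chip_flows()[["stage1"]]
  vals <- lapply(c(2, 1), function(res) {
    cell <- rasterize_pillar(pillar_cylinder(50), 63, 90, res,
                             row_shift = 16)
    fld <- solve_unit_cell(cell, q1)
    list(dc = critical_diameter_from_field(fld, 1 / 7)$dc_um,
         peak = wall_shear_map(fld)$peak_pa)
  })
  expect_lt(abs(vals[[1]]$dc - vals[[2]]$dc) / vals[[2]]$dc, 0.05)
  expect_lt(abs(vals[[1]]$peak - vals[[2]]$peak) / vals[[2]]$peak, 0.05)
})

test_that("asymmetry scores separate cylinder from hybrid pillars", {
  # untilted cells isolate pillar-shape asymmetry from the array tilt
  cyl <- solve_unit_cell(
    rasterize_pillar(pillar_cylinder(50), 63, 90, resolution = 2),
    4.9875)
  hyb <- solve_unit_cell(
    rasterize_pillar(pillar_hybrid(77, 60), 63, 30, resolution = 2),
    2.08125)
  a_cyl <- asymmetry_metric(cyl)
  a_hyb <- asymmetry_metric(hyb)
  expect_lt(a_cyl, 0.05)
  expect_gt(a_hyb, a_cyl)

  # an exactly mirror-symmetric synthetic field scores zero
  cell <- cyl$cell
  xs <- (seq_len(cell$nx) - 0.5) * cell$dx
  um <- matrix(rep(sin(pi * xs / cell$Lx)^2, cell$ny), cell$nx, cell$ny)
  expect_equal(asymmetry_metric(synthetic_field(cell, um)), 0,
               tolerance = 1e-12)
})

test_that("streamlines follow the field and report terminal status", {
  fld <- get_field("stage1")
  cell <- fld$cell
  sl <- streamlines(fld, cbind(1, cell$Ly / 8), max_length = 4 * cell$Lx)
  expect_true(all(sl$status %in% c("exited", "stagnated", "maxlen")))
  expect_gt(nrow(sl), 10)
  # a streamline seeded in open flow exits the cell downstream
  expect_equal(unique(sl$status), "exited")
})

test_that("field tidier and plot accessors work", {
  fld <- get_field("stage1")
  td <- tidy(fld)
  expect_equal(nrow(td), fld$cell$nx * fld$cell$ny)
  expect_true(all(c("x_um", "y_um", "speed_mms", "solid") %in% names(td)))
  p <- ggplot2::autoplot(fld)
  expect_s3_class(p, "ggplot")
})
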