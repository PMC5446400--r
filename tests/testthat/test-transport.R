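# Cluster geometry, DLD advection, mode classification and device
# partitioning.

test_that("cluster axes follow the two-sphere geometry", {
  r <- 10
  p <- rigid_cluster(cbind(c(0, 2 * r), 0, 0, r))
  ax <- cluster_axes(p)
  expect_equal(ax$longitudinal_um, 4 * r)
  expect_equal(ax$transverse_um, 2 * r)
  # tall ceiling, perfect vertical alignment: presents the transverse axis
  ax1 <- cluster_axes(p, ceiling_um = 90)
  expect_equal(ax1$regime, "vertical")
  expect_equal(ax1$effective_diameter_um, 2 * r)
  # shallow ceiling, long axis perpendicular to flow: presents 4r
  ax2 <- cluster_axes(p, ceiling_um = 30, angle = pi / 2)
  expect_equal(ax2$regime, "planar")
  expect_equal(ax2$effective_diameter_um, 4 * r)
  expect_false(ax2$jammed)
})

test_that("clusters taller than the ceiling in every pose are flagged", {
  # regular tetrahedron of 16 um radius spheres: thickness > 30 um
  s <- 2 * 16 / sqrt(2)
  verts <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    s / 2
  p <- rigid_cluster(cbind(verts, 16))
  ax <- cluster_axes(p, ceiling_um = 30)
  expect_true(ax$jammed)
  expect_error(
    advect_through_stage(p, get_field("stage2"), chip_stage("stage2"),
                         seed = 1),
    "jammed")
})

test_that("disconnected member sets are rejected", {
  expect_error(rigid_cluster(cbind(c(0, 100), 0, 0, 10)), "connected")
})

test_that("spheres follow the zigzag/displacement dichotomy", {
  fld <- get_field("stage1")
  st <- chip_stage("stage1")
  tr40 <- advect_through_stage(cell_particle(20), fld, st, seed = 7)
  expect_equal(tr40$mode, "displaced")
  # displaced particles advance one pitch per reset
  expect_equal(tr40$dy_per_reset_um, st$pitch, tolerance = 0.02)
  tr10 <- advect_through_stage(cell_particle(5), fld, st, seed = 7)
  expect_equal(tr10$mode, "zigzag")
  expect_lt(abs(tr10$dy_per_reset_um), 0.1 * st$pitch)
})

test_that("plug-flow oracle: dichotomy at the plug critical diameter", {
  # strong depth drag makes the cross-gap profile near-uniform, so the
  # closed-form plug critical diameter 2 g eps = 18 um applies
  fld <- get_field("plug")
  st <- chip_stage("stage1")
  dc_plug <- critical_diameter(63, 1 / 7, "plug")$dc_um
  below <- advect_through_stage(cell_particle(0.7 * dc_plug / 2),
                                fld, st, seed = 5)
  above <- advect_through_stage(cell_particle(1.3 * dc_plug / 2),
                                fld, st, seed = 5)
  expect_equal(below$mode, "zigzag")
  expect_equal(above$mode, "displaced")
})

test_that("recovery is monotone in effective diameter", {
  fld <- get_field("stage1")
  st <- chip_stage("stage1")
  ds <- seq(8, 44, by = 4)
  modes <- vapply(ds, function(d)
    advect_through_stage(cell_particle(d / 2), fld, st, seed = 11)$mode,
    character(1))
  score <- c(zigzag = 0, mixed = 1, displaced = 2)[modes]
  expect_true(all(diff(score) >= 0))
  expect_equal(modes[1], "zigzag")
  expect_equal(modes[length(modes)], "displaced")
})

test_that("advection is deterministic given a seed", {
  fld <- get_field("stage2")
  st <- chip_stage("stage2")
  p <- rigid_cluster(cbind(c(0, 16), 0, 0, 8))
  a <- advect_through_stage(p, fld, st, seed = 3, record = TRUE)
  b <- advect_through_stage(p, fld, st, seed = 3, record = TRUE)
  expect_identical(a$path[[1]], b$path[[1]])
  expect_identical(a$exit_y_um, b$exit_y_um)
  c_ <- advect_through_stage(p, fld, st, seed = 4)
  expect_false(isTRUE(all.equal(a$entry_y_um, c_$entry_y_um)))
})

test_that("mode classification thresholds are as specified", {
  st <- chip_stage("stage1")
  traj <- tibble::tibble(dy_per_reset_um = c(st$pitch, 0,
                                             0.5 * st$pitch),
                         rows_crossed = 14)
  expect_equal(classify_mode(traj, st),
               c("displaced", "zigzag", "mixed"))
  short <- tibble::tibble(dy_per_reset_um = 0, rows_crossed = 3)
  expect_error(classify_mode(short, st), "reset")
})

test_that("groove-impulse ablation strictly reduces small-cluster capture", {
  fld <- get_field("stage2")
  st <- chip_stage("stage2")
  p <- rigid_cluster(cbind(c(0, 16), 0, 0, 8)) # L = 32 um > ceiling
  n_disp <- function(imp) sum(vapply(1:12, function(s)
    advect_through_stage(p, fld, st, seed = s,
                         groove_impulse = imp)$mode == "displaced",
    logical(1)))
  expect_gt(n_disp(20), n_disp(0))
})

test_that("small clusters deflect in a majority of random phases", {
  fld <- get_field("stage2")
  st <- chip_stage("stage2")
  p <- rigid_cluster(cbind(c(0, 20), 0, 0, 10)) # T = 20 < Dc < L = 40
  modes <- vapply(1:10, function(s)
    advect_through_stage(p, fld, st, seed = s)$mode, character(1))
  expect_gt(mean(modes == "displaced"), 0.5)
})

test_that("device partition conserves particles and routes by size", {
  fields <- list(stage1 = get_field("stage1"),
                 stage2 = get_field("stage2"))
  pop <- c(
    lapply(1:4, function(i) cell_particle(4, "RBC")),
    lapply(1:3, function(i)
      rigid_cluster(cbind(c(0, 20), 0, 0, 10))),
    list(rigid_cluster(cbind(seq(0, 9) * 21.99, 0, 0, 11)))
  )
  part <- simulate_device(pop, fields, seed = 2)
  expect_equal(nrow(part$particles), length(pop))
  cts <- part$counts
  streams <- intersect(c("stage1_product", "stage2_product", "waste",
                         "jammed"), names(cts))
  expect_equal(sum(as.matrix(cts[streams])), length(pop))
  # per-class outlet fractions sum to one
  fr <- part$fractions
  expect_equal(fr$stage1_product + fr$stage2_product + fr$waste,
               rep(1, nrow(fr)), tolerance = 1e-9)
  # RBC-like spheres leave as waste
  rbc <- dplyr::filter(part$particles, label == "RBC")
  expect_true(all(rbc$outlet == "waste"))
  # a 10-cell chain has transverse axis 22 um: vertical alignment in
  # Stage 1 still presents < 30 um, but any planar pose presents more
  expect_true(all(c("size_class") %in% names(fr)))
})

test_that("large clusters with transverse axis above cutoff all exit at Stage 1", {
  fields <- list(stage1 = get_field("stage1"),
                 stage2 = get_field("stage2"))
  # 9-cell compact-ish blocks with all principal extents >= 34 um
  mk <- function() {
    off <- as.matrix(expand.grid(c(0, 17.5), c(0, 17.5), c(0, 17.5)))
    rigid_cluster(cbind(rbind(off, c(8.75, 8.75, 8.75)), 8.75))
  }
  pop <- lapply(1:3, function(i) mk())
  part <- simulate_device(pop, fields, seed = 5)
  expect_true(all(part$particles$outlet == "stage1_product"))
  expect_equal(part$particles$size_class, rep("large_cluster", 3))
})

test_that("partition tidiers expose fractions and recovery", {
  fields <- list(stage1 = get_field("stage1"),
                 stage2 = get_field("stage2"))
  pop <- lapply(c(10, 35), function(d) cell_particle(d / 2))
  part <- simulate_device(pop, fields, seed = 3)
  td <- tidy(part)
  expect_true(all(c("size_class", "outlet", "n", "fraction") %in%
                    names(td)))
  gl <- glance(part)
  expect_true(all(gl$recovery >= 0 & gl$recovery <= 1))
  expect_s3_class(ggplot2::autoplot(part), "ggplot")
})
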