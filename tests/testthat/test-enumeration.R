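# Segmentation, neighbor graphs, event classification, overlays and
# frame-set aggregation.

# paint discs into a blank image (px coordinates)
paint_discs <- function(W, H, centers, radii, value = 0.8) {
  img <- matrix(0, W, H)
  for (k in seq_len(nrow(centers))) {
    xs <- pmax(1, floor(centers[k, 1] - radii[k])):
      pmin(W, ceiling(centers[k, 1] + radii[k]))
    ys <- pmax(1, floor(centers[k, 2] - radii[k])):
      pmin(H, ceiling(centers[k, 2] + radii[k]))
    d2 <- outer((xs - centers[k, 1])^2, (ys - centers[k, 2])^2, "+")
    img[xs, ys][d2 <= radii[k]^2] <- value
  }
  img
}

as_frame <- function(img, pixel_scale = 0.65) {
  structure(list(img = img, ids = NULL, pixel_scale = pixel_scale,
                 channel = "synthetic", truth = NULL, seed = NA),
            class = "dld_frame")
}

test_that("blank frames give zero cells with a warning, not an error", {
  img <- matrix(0.02, 200, 200) + matrix(rnorm(4e4, 0, 0.004), 200)
  expect_warning(lab <- segment_cells(as_frame(img)), "blank")
  expect_equal(max(lab), 0)
})

test_that("well-separated discs are each segmented near truth area", {
  set.seed(1)
  centers <- cbind(rep(seq(40, 360, by = 80), 2),
                   rep(c(60, 160), each = 5))
  r <- 14
  img <- paint_discs(400, 220, centers, rep(r, 10))
  lab <- segment_cells(as_frame(img))
  expect_equal(max(lab), 10)
  areas <- tabulate(lab)
  expect_true(all(abs(areas - pi * r^2) / (pi * r^2) < 0.10))
})

test_that("touching cells with distinct peaks are declumped", {
  centers <- cbind(c(90, 114), c(60, 60)) # overlap: spacing 24 < 2r = 28
  img <- paint_discs(200, 120, centers, c(14, 14))
  img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = 1.5))
  lab <- segment_cells(as_frame(img))
  expect_equal(max(lab), 2)
})

test_that("neighbor graph uses the one-pixel-dilation contact rule", {
  # separated by > 2 px: no edge
  img <- paint_discs(160, 80, cbind(c(40, 100), c(40, 40)), c(14, 14))
  lab <- segment_cells(as_frame(img))
  expect_equal(nrow(neighbor_graph(lab)), 0)
  # abutting: one symmetric edge
  img2 <- paint_discs(160, 80, cbind(c(60, 88.5), c(40, 40)), c(14, 14))
  lab2 <- segment_cells(as_frame(img2))
  e2 <- neighbor_graph(lab2)
  expect_equal(nrow(e2), 1)
  expect_lt(e2$a, e2$b)
  # chain A-B-C: edges only between consecutive members
  img3 <- paint_discs(220, 80, cbind(c(50, 78.5, 107), c(40, 40, 40)),
                      c(14, 14, 14))
  lab3 <- segment_cells(as_frame(img3))
  e3 <- neighbor_graph(lab3)
  expect_equal(nrow(e3), 2)
  ends <- sort(setdiff(1:3, e3$a[duplicated(c(e3$a, e3$b))]))
  expect_false(any(e3$a == min(e3$a) & e3$b == max(e3$b) &
                     nrow(e3) > 2))
})

test_that("classification at the area cutoff is strict and order-free", {
  cfg <- enumeration_config(pixel_scale = 1) # 1 um/px: areas in px
  # two touching cells summing to just over / under the cutoff
  lab <- matrix(0L, 120, 60)
  lab[1:40, 1:40] <- 1L   # 1600 px
  lab[41:79, 1:41] <- 2L  # 1599 px; total 3199 > 3169
  edges <- tibble::tibble(a = 1L, b = 2L)
  ev_hi <- group_and_classify(lab, edges, cfg)
  expect_equal(ev_hi$class, "large_cluster")

  lab2 <- matrix(0L, 120, 60)
  lab2[1:40, 1:40] <- 1L          # 1600
  lab2[41:79, 1:40] <- 2L         # 1560; total 3160 < 3169
  ev_lo <- group_and_classify(lab2, edges, cfg)
  expect_equal(ev_lo$class, "small_cluster")

  # exactly the cutoff is NOT large ("greater than" is strict)
  lab3 <- matrix(0L, 120, 60)
  lab3[1:53, 1:53] <- 1L                 # 2809
  lab3[54:63, 1:36] <- 2L                # 360; total 3169 exactly
  ev_eq <- group_and_classify(lab3, edges, cfg)
  expect_equal(sum(tabulate(lab3)), 3169)
  expect_equal(ev_eq$class, "small_cluster")

  # label permutation does not change classes
  lab_p <- lab
  lab_p[lab == 1L] <- 2L
  lab_p[lab == 2L] <- 1L
  ev_p <- group_and_classify(lab_p, edges, cfg)
  expect_equal(sort(ev_p$class), sort(ev_hi$class))

  # isolated 400 um^2 cell is a single whatever its size
  lab4 <- matrix(0L, 60, 60)
  lab4[1:20, 1:20] <- 1L
  ev4 <- group_and_classify(lab4, tibble::tibble(a = integer(0),
                                                 b = integer(0)), cfg)
  expect_equal(ev4$class, "single")
})

test_that("every cell belongs to exactly one event and areas add up", {
  fr <- render_frame(frame_spec(width_px = 500, height_px = 400,
                                events_per_frame = 6), seed = 31)
  lab <- segment_cells(fr)
  ev <- group_and_classify(lab, neighbor_graph(lab))
  members <- unlist(ev$members)
  expect_equal(sort(members), seq_len(max(lab)))
  px2 <- 0.65^2
  expect_equal(sum(ev$area_um2), sum(lab > 0) * px2)
})

test_that("overlay colors outlines by class", {
  fr <- render_frame(frame_spec(width_px = 500, height_px = 400,
                                events_per_frame = 8,
                                cluster_size_range = c(2, 12)),
                     seed = 12)
  ev <- enumerate_frame(fr)
  expect_gt(nrow(ev), 0)
  rgb <- annotate_overlay(fr, ev)
  expect_s4_class(rgb, "Image")
  dat <- EBImage::imageData(rgb)
  expect_equal(dim(dat)[3], 3)
  # with no events the overlay stays grayscale
  blank <- as_frame(matrix(0.01, 100, 100))
  ev0 <- ev[0, ]
  attr(ev0, "labels") <- matrix(0L, 100, 100)
  rgb0 <- EBImage::imageData(annotate_overlay(blank, ev0))
  expect_equal(rgb0[, , 1], rgb0[, , 2])
  expect_equal(rgb0[, , 2], rgb0[, , 3])
})

test_that("frame aggregation is order-invariant and strict on scale", {
  spec <- frame_spec(width_px = 400, height_px = 300,
                     events_per_frame = 5)
  frames <- lapply(1:3, function(k) render_frame(spec, seed = 40 + k))
  a <- enumerate_frames(frames)
  b <- enumerate_frames(rev(frames))
  expect_equal(glance(a)[-1], glance(b)[-1])
  # duplicating a frame doubles its contribution
  d <- enumerate_frames(c(frames, frames[1]))
  extra <- glance(d)$total_events - glance(a)$total_events
  expect_equal(extra, sum(a$events$frame == 1))
  # mixed pixel scales are refused
  odd <- frames
  odd[[2]]$pixel_scale <- 0.5
  expect_error(enumerate_frames(odd), "mixed pixel scales")
})
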