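# Seeded generators: cluster populations, synthetic fluorescence frames
# with ground-truth labels, and multinomial count tables. Everything the
# other modules need for testing exists here, with no external data.

#' Draw cluster sizes from a truncated log-series distribution
#'
#' The default population puts most clusters at 2-4 cells with a tail to
#' 100+ cells, alongside single cells; `p(k) ~ theta^k / k` on
#' `1..max_cells`.
#'
#' @param n Number of draws.
#' @param theta Log-series parameter in (0, 1); larger means heavier tail.
#' @param max_cells Truncation (default 150, comfortably past 100 cells).
#' @return Integer vector of sizes.
#' @export
rlogseries <- function(n, theta = 0.85, max_cells = 150) {
  stopifnot(theta > 0, theta < 1, max_cells >= 1)
  k <- seq_len(max_cells)
  p <- theta^k / k
  sample.int(max_cells, n, replace = TRUE, prob = p / sum(p))
}

#' Build a rigid cluster by random sequential attachment
#'
#' Spheres are attached one at a time at a uniformly random direction
#' against a uniformly chosen existing member, touching its surface;
#' placements overlapping any other member are rejected and redrawn.
#' The result is always a connected contact graph and generically
#' asymmetric.
#'
#' @param radii Member sphere radii (um), length = cluster size.
#' @param max_tries Rejection retries per sphere before giving up.
#' @return A [rigid_cluster()] (or [cell_particle()] for length 1).
#' @export
grow_cluster <- function(radii, max_tries = 200) {
  n <- length(radii)
  if (n == 1) return(cell_particle(radii))
  centers <- matrix(0, n, 3)
  for (k in 2:n) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      j <- sample.int(k - 1, 1)
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- centers[j, ] + u * (radii[j] + radii[k])
      d <- sqrt(colSums((t(centers[seq_len(k - 1), , drop = FALSE]) -
                           cand)^2))
      if (all(d >= radii[seq_len(k - 1)] + radii[k] - 1e-9)) {
        centers[k, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place member ", k, " without overlap after ",
           max_tries, " tries", call. = FALSE)
    }
  }
  rigid_cluster(cbind(centers, radii))
}

#' Generate a seeded particle population
#'
#' Composition mixes cultured tumor cells/clusters with blood-like
#' singles. Tumor draws take a cluster size from the log-series; size-1
#' draws are single CTCs with diameters from `single_diameter_range`
#' (default the 4-30 um spread reported for patient CTCs); members of
#' clusters draw diameters from `member_diameter_range` (default
#' 10-20 um, cultured-cluster-like). RBC-like and WBC-like particles are
#' fixed-diameter spheres.
#'
#' @param n Number of particles.
#' @param seed Integer seed (required; the generator is fully
#'   deterministic given it).
#' @param composition Named probabilities for `ctc`, `rbc`, `wbc`;
#'   normalized internally.
#' @param size_theta,max_cells Log-series parameters for CTC draw sizes.
#' @param single_diameter_range Min/max diameter (um) of single CTCs.
#' @param member_diameter_range Min/max diameter (um) of cluster members.
#' @param rbc_diameter,wbc_diameter Fixed diameters (um).
#' @return List of `dld_particle` objects with labels `CTC`, `cluster`,
#'   `RBC`, `WBC`.
#' @examples
#' pop <- make_population(20, seed = 1)
#' table(vapply(pop, function(p) p$label, ""))
#' @export
make_population <- function(n, seed,
                            composition = c(ctc = 1, rbc = 0, wbc = 0),
                            size_theta = 0.85, max_cells = 150,
                            single_diameter_range = c(4, 30),
                            member_diameter_range = c(10, 20),
                            rbc_diameter = 8, wbc_diameter = 12) {
  stopifnot(n >= 1, all(composition >= 0), sum(composition) > 0)
  set.seed(seed)
  composition <- composition / sum(composition)
  types <- sample(names(composition), n, replace = TRUE,
                  prob = composition)
  lapply(types, function(ty) {
    if (ty == "rbc") return(cell_particle(rbc_diameter / 2, "RBC"))
    if (ty == "wbc") return(cell_particle(wbc_diameter / 2, "WBC"))
    size <- rlogseries(1, size_theta, max_cells)
    if (size == 1) {
      d <- stats::runif(1, single_diameter_range[1],
                        single_diameter_range[2])
      cell_particle(d / 2, "CTC")
    } else {
      radii <- stats::runif(size, member_diameter_range[1],
                            member_diameter_range[2]) / 2
      p <- grow_cluster(radii)
      p$label <- "cluster"
      p
    }
  })
}

#' Specification of a synthetic fluorescence frame
#'
#' Emulates single-channel (GFP-like) epifluorescence frames of cells and
#' clusters settled in a well: bright blurred discs on a dark noisy
#' background. Defaults follow a 10x camera field (1392 x 1040 px at
#' 0.65 um/px).
#'
#' @param width_px,height_px Frame size in pixels.
#' @param pixel_scale Microns per pixel.
#' @param events_per_frame Mean number of events (Poisson).
#' @param single_prob Probability an event is a single cell (otherwise a
#'   cluster of `cluster_size_range` cells, uniform).
#' @param cluster_size_range Min/max cells per rendered cluster.
#' @param cell_diameter_range Min/max rendered cell diameter (um).
#' @param intensity_range Per-cell peak intensity (0-1 scale).
#' @param background Background level.
#' @param noise_sd Gaussian noise SD.
#' @param blur_sigma_px Gaussian blur sigma (pixels).
#' @return A `dld_frame_spec` list.
#' @export
frame_spec <- function(width_px = 1392, height_px = 1040,
                       pixel_scale = 0.65, events_per_frame = 10,
                       single_prob = 0.5, cluster_size_range = c(2, 15),
                       cell_diameter_range = c(15, 25),
                       intensity_range = c(0.5, 1),
                       background = 0.05, noise_sd = 0.02,
                       blur_sigma_px = 1.5) {
  stopifnot(width_px > 0, height_px > 0, pixel_scale > 0, noise_sd >= 0)
  structure(
    list(width_px = as.integer(width_px),
         height_px = as.integer(height_px),
         pixel_scale = pixel_scale,
         events_per_frame = events_per_frame,
         single_prob = single_prob,
         cluster_size_range = cluster_size_range,
         cell_diameter_range = cell_diameter_range,
         intensity_range = intensity_range,
         background = background, noise_sd = noise_sd,
         blur_sigma_px = blur_sigma_px),
    class = "dld_frame_spec"
  )
}

#' Render one synthetic fluorescence frame with ground truth
#'
#' Cells are blurred discs with per-cell intensity variation; cluster
#' members touch (slight overlap so membranes are in contact). Events are
#' placed without inter-event contact. Ground truth records, per event,
#' the class under the area cutoff convention, pixel-exact area, member
#' count and centroid; events clipped by the frame edge are flagged.
#'
#' @param spec A [frame_spec()].
#' @param seed Integer seed; same seed, same frame, bit for bit.
#' @param area_cutoff_um2 Large/small cluster area boundary for the truth
#'   labels (um^2), default 3169.
#' @return A `dld_frame`: `img` (width x height matrix in `[0, 1]`),
#'   `pixel_scale`, `channel`, `truth` tibble and `seed`.
#' @export
render_frame <- function(spec, seed, area_cutoff_um2 = 3169) {
  stopifnot(inherits(spec, "dld_frame_spec"))
  set.seed(seed)
  W <- spec$width_px
  H <- spec$height_px
  px <- spec$pixel_scale
  img <- matrix(0, W, H)
  ids <- matrix(0L, W, H)
  n_events <- stats::rpois(1, spec$events_per_frame)
  placed <- list() # event bounding circles: x, y, r (px)
  truth <- list()
  eid <- 0L
  for (e in seq_len(n_events)) {
    single <- stats::runif(1) < spec$single_prob
    size <- if (single) 1L else
      sample(spec$cluster_size_range[1]:spec$cluster_size_range[2], 1)
    radii <- stats::runif(size, spec$cell_diameter_range[1],
                          spec$cell_diameter_range[2]) / 2 / px # px
    # member layout: planar sequential attachment with 10% overlap so
    # touching cells render as contiguous clusters
    cen <- matrix(0, size, 2)
    if (size > 1) {
      for (k in 2:size) {
        ok <- FALSE
        for (try in 1:100) {
          j <- sample.int(k - 1, 1)
          a <- stats::runif(1, 0, 2 * pi)
          cand <- cen[j, ] + 0.9 * (radii[j] + radii[k]) *
            c(cos(a), sin(a))
          d <- sqrt(rowSums((cen[seq_len(k - 1), , drop = FALSE] -
                               matrix(cand, k - 1, 2,
                                      byrow = TRUE))^2))
          if (all(d >= 0.8 * (radii[seq_len(k - 1)] + radii[k]))) {
            cen[k, ] <- cand
            ok <- TRUE
            break
          }
        }
        if (!ok) cen[k, ] <- cen[k - 1, ] + c(2 * radii[k], 0)
      }
    }
    ext <- max(sqrt(rowSums(cen^2)) + radii)
    # place the event; avoid contact with previously placed events
    pos <- NULL
    for (try in 1:50) {
      cand <- c(stats::runif(1, 1, W), stats::runif(1, 1, H))
      clear <- TRUE
      for (pl in placed) {
        if (sqrt(sum((cand - pl[1:2])^2)) < ext + pl[3] + 6) {
          clear <- FALSE
          break
        }
      }
      if (clear) { pos <- cand; break }
    }
    if (is.null(pos)) next
    eid <- eid + 1L
    placed[[eid]] <- c(pos, ext)
    intens <- stats::runif(size, spec$intensity_range[1],
                           spec$intensity_range[2])
    for (k in seq_len(size)) {
      cx <- pos[1] + cen[k, 1]
      cy <- pos[2] + cen[k, 2]
      r <- radii[k]
      xlo <- max(1, floor(cx - r)); xhi <- min(W, ceiling(cx + r))
      ylo <- max(1, floor(cy - r)); yhi <- min(H, ceiling(cy + r))
      if (xlo > xhi || ylo > yhi) next
      xs <- xlo:xhi
      ys <- ylo:yhi
      d2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
      inside <- d2 <= r^2
      # gentle radial falloff gives each cell an intensity peak
      val <- intens[k] * (1 - 0.3 * d2 / r^2)
      img[xs, ys][inside] <- pmax(img[xs, ys][inside], val[inside])
      ids[xs, ys][inside] <- eid
    }
    clipped <- any(pos[1] - ext < 1, pos[1] + ext > W,
                   pos[2] - ext < 1, pos[2] + ext > H)
    truth[[eid]] <- tibble::tibble(
      event = eid, n_cells = size,
      x_px = pos[1], y_px = pos[2], clipped = clipped)
  }
  truth <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble::tibble(event = integer(0), n_cells = integer(0),
                   x_px = numeric(0), y_px = numeric(0),
                   clipped = logical(0))
  if (nrow(truth)) {
    areas <- tabulate(ids, nbins = max(truth$event)) * px^2
    truth$area_um2 <- areas[truth$event]
    truth$class <- ifelse(truth$n_cells == 1, "single",
                          ifelse(truth$area_um2 > area_cutoff_um2,
                                 "large_cluster", "small_cluster"))
  } else {
    truth$area_um2 <- numeric(0)
    truth$class <- character(0)
  }
  if (spec$blur_sigma_px > 0) {
    img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                    sigma = spec$blur_sigma_px))
  }
  img <- img + spec$background +
    matrix(stats::rnorm(W * H, 0, spec$noise_sd), W, H)
  img <- pmin(pmax(img, 0), 1)
  structure(list(img = img, ids = ids, pixel_scale = px,
                 channel = "GFP-like", truth = truth, seed = seed),
            class = "dld_frame")
}

#' @export
print.dld_frame <- function(x, ...) {
  cat(sprintf(
    "<dld_frame> %d x %d px at %g um/px, %d ground-truth events\n",
    nrow(x$img), ncol(x$img), x$pixel_scale, nrow(x$truth)))
  invisible(x)
}

#' Write a frame to an image file
#'
#' @param frame A `dld_frame`.
#' @param path Output path; format from the extension (`.tif`, `.png`).
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  EBImage::writeImage(EBImage::Image(frame$img), path)
  invisible(path)
}

#' Read an intensity image as a frame
#'
#' @param path TIFF/PNG path.
#' @param pixel_scale Microns per pixel.
#' @return A `dld_frame` (no ground truth).
#' @export
read_frame <- function(path, pixel_scale = 0.65) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) > 2) img <- img[, , 1]
  structure(list(img = img, ids = NULL, pixel_scale = pixel_scale,
                 channel = "file", truth = NULL, seed = NA),
            class = "dld_frame")
}

#' Multinomial count tables for partition statistics
#'
#' Draws per-replicate, per-class counts routed to the three output
#' streams from the given probabilities — fixtures for the capture
#' statistics.
#'
#' @param probs Named list (per class) of length-3 probability vectors
#'   `(stage1_product, stage2_product, waste)`, each summing to 1.
#' @param n_per_class Events per class per replicate (single number or
#'   named vector).
#' @param replicates Number of replicates.
#' @param seed Integer seed.
#' @return Tidy tibble: `replicate`, `size_class`, `stage1_product`,
#'   `stage2_product`, `waste`.
#' @examples
#' make_count_table(list(large_cluster = c(.778, .209, .013)),
#'                  500, 5, seed = 1)
#' @export
make_count_table <- function(probs, n_per_class, replicates, seed) {
  stopifnot(is.list(probs), length(probs) >= 1, replicates >= 1)
  # printed stream fractions round to 0.1%, so allow slight excess and
  # renormalize
  bad <- vapply(probs, function(p)
    length(p) != 3 || abs(sum(p) - 1) > 5e-3, logical(1))
  if (any(bad)) {
    stop("each class's probabilities must be three values summing to 1",
         call. = FALSE)
  }
  probs <- lapply(probs, function(p) p / sum(p))
  if (length(n_per_class) == 1) {
    n_per_class <- stats::setNames(rep(n_per_class, length(probs)),
                                   names(probs))
  }
  set.seed(seed)
  purrr::map_dfr(seq_len(replicates), function(rep) {
    purrr::map_dfr(names(probs), function(cl) {
      cts <- stats::rmultinom(1, n_per_class[[cl]], probs[[cl]])[, 1]
      tibble::tibble(replicate = rep, size_class = cl,
                     stage1_product = cts[1], stage2_product = cts[2],
                     waste = cts[3])
    })
  })
}
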