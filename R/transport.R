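# Kinematic transport of spheres and rigid clusters through the two-stage
# array: ceiling-constrained orientation, rotation-driven deflection,
# zigzag/displacement classification and full device partitioning.

#' Single cell particle
#'
#' @param radius Sphere radius (um).
#' @param label Class label, e.g. `"RBC"`, `"WBC"`, `"CTC"`.
#' @return A `dld_particle` with one member sphere.
#' @export
cell_particle <- function(radius, label = "CTC") {
  stopifnot(radius > 0)
  new_particle(matrix(c(0, 0, 0, radius), 1), label)
}

#' Rigid multi-sphere cluster
#'
#' @param members Numeric matrix with columns `x`, `y`, `z`, `r`: member
#'   sphere centers (body frame, um) and radii (um). Members must form a
#'   single connected contact graph (surfaces within `tol` of touching).
#' @param label Class label.
#' @param tol Contact slack (um) for the connectivity check.
#' @return A `dld_particle`.
#' @export
rigid_cluster <- function(members, label = "cluster", tol = 1e-6) {
  members <- as.matrix(members)
  stopifnot(ncol(members) == 4, nrow(members) >= 2,
            all(members[, 4] > 0))
  if (!cluster_connected(members, tol)) {
    stop("cluster members do not form one connected contact graph",
         call. = FALSE)
  }
  new_particle(members, label)
}

new_particle <- function(members, label) {
  colnames(members) <- c("x", "y", "z", "r")
  structure(list(members = members, n_cells = nrow(members),
                 label = label),
            class = "dld_particle")
}

#' @export
print.dld_particle <- function(x, ...) {
  ax <- cluster_axes(x)
  cat(sprintf(
    "<dld_particle> %s, %d cell(s), L_ax %.1f um, T_ax %.1f um\n",
    x$label, x$n_cells, ax$longitudinal_um, ax$transverse_um))
  invisible(x)
}

cluster_connected <- function(members, tol = 1e-6) {
  k <- nrow(members)
  if (k == 1) return(TRUE)
  d <- as.matrix(stats::dist(members[, 1:3, drop = FALSE]))
  touch <- d <= outer(members[, 4], members[, 4], "+") + tol
  reach <- touch[1, ]
  for (it in seq_len(k)) reach <- reach | (reach %*% touch)[1, ] > 0
  all(reach)
}

# principal body axes of the member spheres; extent along a direction is
# max(center proj + r) - min(center proj - r)
principal_axes <- function(members) {
  C <- members[, 1:3, drop = FALSE]
  if (nrow(C) == 1) {
    ax <- diag(3)
  } else {
    Cc <- sweep(C, 2, colMeans(C))
    ax <- eigen(crossprod(Cc), symmetric = TRUE)$vectors
  }
  ax
}

axis_extent <- function(members, e) {
  pr <- members[, 1:3, drop = FALSE] %*% e
  max(pr + members[, 4]) - min(pr - members[, 4])
}

#' Principal axes and effective diameter of a particle
#'
#' The longitudinal axis is the largest principal extent of the member
#' spheres, the transverse axis the smallest. Under a tall ceiling
#' (`ceiling_um >= L_ax`) clusters align their long axis vertically and
#' present roughly their transverse extent to the array; under a shallow
#' ceiling (`ceiling_um < L_ax`) they lie flat and present the lateral
#' projection of their in-plane outline at the current angle.
#'
#' @param particle A `dld_particle`.
#' @param ceiling_um Optional channel depth (um) for the orientation
#'   regime, jam check and effective-diameter sampling.
#' @param angle In-plane angle (rad) for the flat regime; `NA` (default)
#'   reports the transverse extent for the vertical regime and the
#'   angle-averaged range otherwise.
#' @param tilt_sd Angular noise (rad, SD) of the near-vertical alignment
#'   in the tall-ceiling regime. Default 0.15.
#' @param tilt Tilt angle (rad) away from vertical; `NA` uses 0 (perfect
#'   alignment). Supply a sampled value for stochastic orientation.
#' @return One-row tibble: `longitudinal_um`, `transverse_um`,
#'   `effective_diameter_um`, `regime` (`"vertical"`, `"planar"` or
#'   `"unconstrained"`), `jammed`.
#' @examples
#' p <- rigid_cluster(cbind(c(0, 20), 0, 0, 10))  # two touching 20 um cells
#' cluster_axes(p, ceiling_um = 90)  # presents ~20 um
#' cluster_axes(p, ceiling_um = 30, angle = pi / 2)  # presents 40 um
#' @export
cluster_axes <- function(particle, ceiling_um = NULL, angle = NA,
                         tilt_sd = 0.15, tilt = NA) {
  stopifnot(inherits(particle, "dld_particle"))
  m <- particle$members
  ax <- principal_axes(m)
  ext <- vapply(1:3, function(k) axis_extent(m, ax[, k]), numeric(1))
  L <- max(ext)
  Tr <- min(ext)
  if (is.null(ceiling_um)) {
    return(tibble::tibble(longitudinal_um = L, transverse_um = Tr,
                          effective_diameter_um = NA_real_,
                          regime = "unconstrained", jammed = FALSE))
  }
  jammed <- Tr > ceiling_um
  if (ceiling_um >= L) {
    a <- if (is.na(tilt)) 0 else tilt
    deff <- Tr + (L - Tr) * abs(sin(a))
    regime <- "vertical"
  } else {
    regime <- "planar"
    pr <- in_plane_members(particle)
    deff <- if (is.na(angle)) {
      mean(vapply(seq(0, pi, length.out = 32),
                  function(th) 2 * lateral_half_extent(pr, th),
                  numeric(1)))
    } else {
      2 * lateral_half_extent(pr, angle)
    }
  }
  tibble::tibble(longitudinal_um = L, transverse_um = Tr,
                 effective_diameter_um = deff, regime = regime,
                 jammed = jammed)
}

# centroid-centered member offsets projected on the two longest
# principal axes (flat pose)
in_plane_members <- function(particle) {
  m <- particle$members
  ax <- principal_axes(m)
  ext <- vapply(1:3, function(k) axis_extent(m, ax[, k]), numeric(1))
  keep <- order(ext, decreasing = TRUE)[1:2]
  cen <- sweep(m[, 1:3, drop = FALSE], 2,
               colMeans(m[, 1:3, drop = FALSE]))
  cbind(cen %*% ax[, keep, drop = FALSE], m[, 4])
}

lateral_half_extent <- function(pr2, theta) {
  max(abs(pr2[, 1] * sin(theta) + pr2[, 2] * cos(theta)) + pr2[, 3])
}

# contact parameters of a stage's pillar for the C++ advection kernel;
# the hybrid pillar is approximated by its rectangular footprint, its
# grooves act through the rotation impulse band
pillar_contact <- function(stage) {
  p <- stage$pillar
  if (p$kind == "cylinder") {
    list(kind = 0L, param = p$diameter / 2,
         outline = matrix(0, 1, 4), gx0 = 0, gx1 = 0)
  } else {
    g <- hybrid_geom(p)
    list(kind = 1L,
         param = c(p$alongflow_extent / 2, p$lateral_extent / 2),
         outline = as.matrix(pillar_outline(p, 1)),
         gx0 = g$gx - g$gw, gx1 = g$gx + g$gw)
  }
}

#' Advect a particle through one DLD stage
#'
#' The centroid follows the midplane velocity field (4th-order
#' Runge-Kutta, step half a grid cell); a hard-contact constraint keeps
#' the centroid one effective radius clear of pillar surfaces, which
#' produces the DLD bump. In the shallow (planar) regime clusters rotate
#' with half the local vorticity plus a deterministic angular impulse
#' while passing grooved pillar faces. Deterministic given `seed` (which
#' sets the inlet lateral position and initial orientation only).
#'
#' @param particle A `dld_particle`.
#' @param field A [solve_unit_cell()] field for this stage's unit cell.
#' @param stage The `dld_stage`.
#' @param seed Integer seed for the entry position and orientation.
#' @param n_resets Resets to traverse (default 3).
#' @param rotation Enable rotation dynamics in the planar regime.
#' @param groove_impulse Strength of the aligning rotation induced by
#'   grooved pillar faces (dimensionless; 0 disables the groove kick).
#'   The groove disturbance torques the particle toward presenting its
#'   long axis laterally while it passes the post.
#' @param vorticity_factor Fraction of the free rigid-body rotation rate
#'   (half the local vorticity) retained under floor/ceiling confinement
#'   in the shallow regime. Default 0.2.
#' @param record Keep the path points?
#' @return One-row tibble (`dld_trajectory`): entry/exit positions, bump
#'   count, rows crossed, net and per-reset lateral displacement, `mode`
#'   (`"zigzag"`, `"displaced"`, `"mixed"`), residence time (s), peak
#'   shear exposure (Pa), `status`, and (if `record`) a `path`
#'   list-column.
#' @export
advect_through_stage <- function(particle, field, stage, seed = NULL,
                                 n_resets = 3, rotation = TRUE,
                                 groove_impulse = 20, vorticity_factor = 0.2,
                                 record = FALSE) {
  stopifnot(inherits(particle, "dld_particle"),
            inherits(field, "dld_field"), inherits(stage, "dld_stage"))
  cell <- field$cell
  if (!is.null(seed)) set.seed(seed)
  ax <- cluster_axes(particle, ceiling_um = stage$ceiling_height)
  if (ax$jammed) {
    stop("particle is taller than the stage ceiling in its flattest ",
         "pose (transverse axis ", signif(ax$transverse_um, 3), " um > ",
         stage$ceiling_height, " um); geometrically jammed",
         call. = FALSE)
  }
  planar <- ax$regime == "planar"
  if (planar) {
    members2 <- in_plane_members(particle)
    theta0 <- stats::runif(1, 0, 2 * pi)
  } else {
    tilt <- stats::rnorm(1, 0, 0.15)
    deff <- ax$transverse_um +
      (ax$longitudinal_um - ax$transverse_um) * abs(sin(tilt))
    members2 <- matrix(c(0, 0, deff / 2), 1)
    theta0 <- 0
  }
  y0 <- stats::runif(1, 0, cell$Ly)
  rows_per_reset <- round(1 / stage$shift_fraction)
  n_rows <- n_resets * rows_per_reset
  shear_proxy <- 6 * field$viscosity_pas / cell$depth *
    sqrt(field$ud^2 + field$vd^2)
  pc <- pillar_contact(stage)
  res <- .advect_dld(
    field$um, field$vm, shear_proxy,
    cell$dx, cell$Lx, cell$Ly, cell$shift_cells * cell$dx,
    pc$kind, pc$param, pc$outline, pc$gx0, pc$gx1,
    0, y0, members2, theta0,
    rotate = planar && rotation,
    grooveImpulse = if (planar && rotation) groove_impulse else 0,
    vorticityFactor = vorticity_factor,
    step = cell$dx / 2, nRows = n_rows,
    maxSteps = 500000L, recordEvery = if (record) 10L else 0L)
  if (res$status == "stalled") {
    stop("particle stalled (zero velocity off the pillar mask) near x = ",
         round(res$x, 1), ", y = ", round(res$y, 1), " um",
         call. = FALSE)
  }
  # measure net drift after a one-reset lead-in so the entry transient
  # (before the particle reaches its first pillar lane) is excluded
  row_y <- res$row_y
  n_done <- length(row_y) - 1
  lead <- min(rows_per_reset, max(n_done - rows_per_reset, 0))
  rows_meas <- n_done - lead
  dy_meas <- if (rows_meas > 0) row_y[n_done + 1] - row_y[lead + 1] else 0
  out <- tibble::tibble(
    label = particle$label, n_cells = particle$n_cells,
    longitudinal_um = ax$longitudinal_um,
    transverse_um = ax$transverse_um,
    effective_diameter_um = 2 * lateral_half_extent(members2, res$theta),
    regime = ax$regime,
    entry_y_um = y0, exit_y_um = res$y,
    rows_crossed = rows_meas, bumps = res$bumps,
    net_dy_um = dy_meas,
    dy_per_reset_um = dy_meas / (rows_meas / rows_per_reset),
    residence_s = res$time_s, peak_shear_pa = res$peak_shear_pa,
    status = res$status
  )
  # a particle that ran out of steps before completing a measurable
  # reset is mechanically stuck (e.g. a rigid cluster wider than every
  # clearance): report it as stalled rather than classifying
  out$mode <- if (res$status != "completed" &&
                  rows_meas < rows_per_reset) "stalled" else
    classify_mode(out, stage)
  if (record) out$path <- list(tibble::as_tibble(res$path))
  class(out) <- c("dld_trajectory", class(out))
  out
}

#' Classify a trajectory as zigzag, displaced or mixed
#'
#' Displaced particles advance one lateral pitch per reset (net lateral
#' drift per reset at least 0.9 pitch); zigzag particles follow the flow
#' (at most 0.1 pitch); anything between is mixed.
#'
#' @param traj Trajectory tibble from [advect_through_stage()] (needs
#'   `dy_per_reset_um` and `rows_crossed`).
#' @param stage The `dld_stage` (for the pitch and shift fraction).
#' @return Character vector of modes.
#' @export
classify_mode <- function(traj, stage) {
  rows_per_reset <- round(1 / stage$shift_fraction)
  if (any(traj$rows_crossed < rows_per_reset - 1e-9)) {
    stop("trajectory spans less than one full reset; extend n_resets",
         call. = FALSE)
  }
  ratio <- traj$dy_per_reset_um / stage$pitch
  dplyr::case_when(ratio >= 0.9 ~ "displaced",
                   abs(ratio) <= 0.1 ~ "zigzag",
                   TRUE ~ "mixed")
}

#' Run a particle population through the two-stage device
#'
#' Each particle first traverses Stage 1; displaced particles exit to the
#' Stage 1 product. The remainder re-orient under the Stage 2 ceiling and
#' traverse Stage 2; displaced particles exit to the Stage 2 product and
#' the rest leave as waste. Size classes follow the enumeration cutoffs:
#' single = 1 cell, small cluster = 2-8 cells, large cluster = >= 9
#' cells.
#'
#' @param population List of `dld_particle` (e.g. from
#'   [make_population()]).
#' @param fields Named list with solved `stage1` and `stage2` fields.
#' @param device A `dld_device` (default [two_stage_device()]).
#' @param seed Integer seed; per-particle seeds are drawn from it.
#' @param ... Passed to [advect_through_stage()] (e.g. `n_resets`,
#'   `rotation`, `groove_impulse`).
#' @return A `dld_partition` list: `particles` (per-particle tibble with
#'   `outlet`), `counts` (class x outlet tibble), `fractions` (per-class
#'   outlet fractions summing to 1).
#' @export
simulate_device <- function(population, fields,
                            device = two_stage_device(), seed = 1, ...) {
  stopifnot(all(c("stage1", "stage2") %in% names(fields)))
  if (inherits(population, "dld_particle")) population <- list(population)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2 * length(population))
  rows <- purrr::map_dfr(seq_along(population), function(k) {
    p <- population[[k]]
    if (cluster_axes(p, device$stage1$ceiling_height)$jammed) {
      return(tibble::tibble(
        particle = k, label = p$label, n_cells = p$n_cells,
        size_class = size_class(p$n_cells),
        stage1_mode = NA_character_, stage2_mode = NA_character_,
        peak_shear_pa = NA_real_, residence_s = NA_real_,
        outlet = "jammed"))
    }
    t1 <- advect_through_stage(p, fields$stage1, device$stage1,
                               seed = seeds[2 * k - 1], ...)
    if (t1$mode == "displaced") {
      out <- "stage1_product"
      t2 <- NULL
    } else if (t1$mode == "stalled") {
      out <- "jammed"
      t2 <- NULL
    } else if (cluster_axes(p, device$stage2$ceiling_height)$jammed) {
      # taller than the Stage 2 ceiling in its flattest pose: reported,
      # excluded from the flow
      out <- "jammed"
      t2 <- NULL
    } else {
      t2 <- advect_through_stage(p, fields$stage2, device$stage2,
                                 seed = seeds[2 * k], ...)
      out <- dplyr::case_when(t2$mode == "displaced" ~ "stage2_product",
                              t2$mode == "stalled" ~ "jammed",
                              TRUE ~ "waste")
    }
    tibble::tibble(
      particle = k, label = p$label, n_cells = p$n_cells,
      size_class = size_class(p$n_cells),
      stage1_mode = t1$mode,
      stage2_mode = if (is.null(t2)) NA_character_ else t2$mode,
      peak_shear_pa = max(t1$peak_shear_pa,
                          if (is.null(t2)) 0 else t2$peak_shear_pa),
      residence_s = t1$residence_s +
        (if (is.null(t2)) 0 else t2$residence_s),
      outlet = out)
  })
  counts <- rows |>
    dplyr::count(.data$size_class, .data$outlet) |>
    tidyr::pivot_wider(names_from = "outlet", values_from = "n",
                       values_fill = 0L)
  for (o in c("stage1_product", "stage2_product", "waste")) {
    if (!o %in% names(counts)) counts[[o]] <- 0L
  }
  fr <- counts
  tot <- fr$stage1_product + fr$stage2_product + fr$waste
  fr$stage1_product <- fr$stage1_product / tot
  fr$stage2_product <- fr$stage2_product / tot
  fr$waste <- fr$waste / tot
  structure(list(particles = rows, counts = counts, fractions = fr),
            class = "dld_partition")
}

size_class <- function(n_cells) {
  dplyr::case_when(n_cells == 1 ~ "single",
                   n_cells <= 8 ~ "small_cluster",
                   TRUE ~ "large_cluster")
}

#' @export
print.dld_partition <- function(x, ...) {
  cat("<dld_partition>", nrow(x$particles), "particles\n")
  print(x$fractions)
  invisible(x)
}

#' Tidy a device partition into long format
#'
#' @param x A `dld_partition` from [simulate_device()].
#' @param ... Unused.
#' @return Tibble with `size_class`, `outlet`, `n`, `fraction`.
#' @export
tidy.dld_partition <- function(x, ...) {
  long_n <- tidyr::pivot_longer(
    x$counts, cols = c("stage1_product", "stage2_product", "waste"),
    names_to = "outlet", values_to = "n")
  long_f <- tidyr::pivot_longer(
    x$fractions, cols = c("stage1_product", "stage2_product", "waste"),
    names_to = "outlet", values_to = "fraction")
  dplyr::left_join(long_n, long_f, by = c("size_class", "outlet"))
}

#' Overall recovery per size class (product streams)
#'
#' @param x A `dld_partition`.
#' @return Tibble with `size_class` and `recovery` (fraction in the two
#'   product streams).
#' @export
glance.dld_partition <- function(x, ...) {
  tibble::tibble(size_class = x$fractions$size_class,
                 recovery = x$fractions$stage1_product +
                   x$fractions$stage2_product)
}

#' Plot per-class outlet fractions of a partition
#'
#' @param object A `dld_partition`.
#' @param ... Unused.
#' @return A ggplot bar chart.
#' @export
autoplot.dld_partition <- function(object, ...) {
  td <- tidy.dld_partition(object)
  ggplot2::ggplot(td, ggplot2::aes(.data$size_class, .data$fraction,
                                   fill = .data$outlet)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(v) 100 * v,
                                name = "fraction of class (%)") +
    ggplot2::labs(x = NULL)
}
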