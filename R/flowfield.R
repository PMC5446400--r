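# Periodic unit-cell viscous flow around one pillar: rasterization, a
# staggered-grid Stokes solver with depth correction, streamline-based
# critical diameter, wall shear maps and a streamline asymmetry score.
#
# The unit cell spans one along-flow row pitch (x) by one lateral pitch (y)
# with the pillar centered; boundaries are periodic, with the lateral row
# shift applied when wrapping in x, so the solved field tiles the whole
# tilted array. Depth (z) is handled either by a Brinkman drag term on the
# depth-averaged midplane field or by a truncated sine expansion in z
# ("coarse 3d"): each odd mode is an independent 2D solve with drag
# mu (k pi / h)^2, and the modes sum to a divergence-free slab flow with
# no-slip floor and ceiling.

#' Rasterize a pillar into a periodic unit cell
#'
#' @param pillar A [pillar_cylinder()] or [pillar_hybrid()].
#' @param gap Lateral gap (um); the lateral period is the pillar's lateral
#'   extent plus the gap.
#' @param ceiling_height Channel depth (um).
#' @param resolution Grid spacing (um/cell), default 2.
#' @param row_shift Lateral shift applied when wrapping in the flow
#'   direction (um). Default 0.
#' @param row_pitch Along-flow period (um); defaults to the lateral period.
#' @return A `dld_unit_cell` with the boolean pillar mask and grid metadata.
#' @examples
#' cell <- rasterize_pillar(pillar_cylinder(50), gap = 63,
#'                          ceiling_height = 90, resolution = 2)
#' @export
rasterize_pillar <- function(pillar, gap, ceiling_height, resolution = 2,
                             row_shift = 0, row_pitch = NULL) {
  stopifnot(inherits(pillar, "dld_pillar"), gap > 0, ceiling_height > 0,
            resolution > 0)
  Ly <- pillar$lateral_extent + gap
  Lx <- row_pitch %||% Ly
  if (pillar$kind == "asymmetric_hybrid" &&
      hybrid_geom(pillar)$gw > 0) {
    g <- hybrid_geom(pillar)
    feat <- min(2 * g$gw, g$gd)
    if (resolution > feat) {
      stop("resolution (", resolution, " um/cell) is coarser than the ",
           "smallest pillar feature (", signif(feat, 3),
           " um groove); refine the grid", call. = FALSE)
    }
  }
  # the grid spacing divides the along-flow period exactly (dx = Lx / nx)
  # so the periodic wrap introduces no geometric distortion
  nx <- max(8L, round(Lx / resolution))
  dx <- Lx / nx
  ny <- round(Ly / dx)
  if (abs(ny * dx - Ly) > 0.26 * dx) {
    warning("lateral period ", Ly, " um is not commensurate with the ",
            "grid spacing ", signif(dx, 4), " um; the cell is ",
            signif(ny * dx, 6), " um wide", call. = FALSE)
  }
  Ly_eff <- ny * dx
  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dx
  cx <- Lx / 2
  cy <- Ly_eff / 2
  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)
  mask <- pillar_mask(pillar, X - cx, Y - cy)
  structure(
    list(pillar = pillar, mask = mask, nx = nx, ny = ny,
         dx = dx, Lx = Lx, Ly = Ly_eff,
         depth = ceiling_height, gap = gap,
         row_shift = row_shift,
         shift_cells = round(row_shift / dx),
         center = c(cx, cy)),
    class = "dld_unit_cell"
  )
}

# Lateral half-extent of the pillar at along-flow offset x from its
# center; NA outside the pillar's along-flow span.
pillar_halfwidth <- function(pillar, x) {
  if (pillar$kind == "cylinder") {
    r <- pillar$diameter / 2
    return(ifelse(abs(x) <= r, sqrt(pmax(r^2 - x^2, 0)), NA_real_))
  }
  g <- hybrid_geom(pillar)
  w <- ifelse(x < -g$a | x > g$a, NA_real_,
       ifelse(x <= g$x_join,
              ifelse(abs(x - g$gx) <= g$gw, g$b - g$gd, g$b),
              g$b * sqrt(pmax(1 - ((x - g$x_join) / g$el)^2, 0))))
  if (g$rc > 0) {
    # fillet zones reduce the half-extent near the rounded corners
    fz <- function(w0, cx, cy) ifelse(
      abs(x - cx) < g$rc, cy + sqrt(pmax(g$rc^2 - (x - cx)^2, 0)), w0)
    w <- ifelse(x < -g$a + g$rc,
                fz(w, -g$a + g$rc, g$b - g$rc), w)
    w <- ifelse(x > g$gx - g$gw - g$rc & x <= g$gx - g$gw,
                fz(w, g$gx - g$gw - g$rc, g$b - g$rc), w)
    w <- ifelse(x >= g$gx + g$gw & x < g$gx + g$gw + g$rc,
                fz(w, g$gx + g$gw + g$rc, g$b - g$rc), w)
  }
  w
}

# Sampled outline of the pillar with outward unit normals, in
# pillar-centered coordinates; used for wall-shear probing.
pillar_outline <- function(pillar, spacing) {
  if (pillar$kind == "cylinder") {
    r <- pillar$diameter / 2
    n <- max(64, ceiling(2 * pi * r / spacing))
    th <- seq(0, 2 * pi, length.out = n + 1)[-1]
    return(data.frame(x = r * cos(th), y = r * sin(th),
                      nx = cos(th), ny = sin(th)))
  }
  g <- hybrid_geom(pillar)
  a <- g$a; b <- g$b; el <- g$el; x_join <- g$x_join
  gx <- g$gx; gw <- g$gw; gd <- g$gd; rc <- g$rc
  seg <- function(x1, y1, x2, y2, nx, ny) {
    len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    n <- max(2, ceiling(len / spacing))
    t <- seq(0, 1, length.out = n)
    data.frame(x = x1 + t * (x2 - x1), y = y1 + t * (y2 - y1),
               nx = nx, ny = ny)
  }
  # fillet arc at center (cx, cy), angles th1 -> th2 (deg); convex arcs
  # have outward normal along the radius, concave ones opposite
  fil <- function(cx, cy, th1, th2, concave = FALSE) {
    n <- max(4, ceiling(abs(th2 - th1) / 180 * pi * rc / spacing))
    th <- seq(th1, th2, length.out = n) * pi / 180
    s <- if (concave) -1 else 1
    data.frame(x = cx + rc * cos(th), y = cy + rc * sin(th),
               nx = s * cos(th), ny = s * sin(th))
  }
  arc <- function(sgn) {
    n <- max(16, ceiling((pi / 2) * max(el, b) / spacing))
    t <- seq(0, pi / 2, length.out = n)
    x <- x_join + el * sin(t)
    y <- sgn * b * cos(t)
    nv <- cbind((x - x_join) / el^2, y / b^2)
    nv <- nv / sqrt(rowSums(nv^2))
    data.frame(x = x, y = y, nx = nv[, 1], ny = nv[, 2])
  }
  if (gw == 0 && rc > 0) {
    top <- rbind(
      fil(-a + rc, b - rc, 180, 90),
      seg(-a + rc, b, x_join, b, 0, 1),
      arc(1)
    )
    face <- seg(-a, -(b - rc), -a, b - rc, -1, 0)
  } else if (rc == 0) {
    top <- if (gw > 0) rbind(
      seg(-a, b, gx - gw, b, 0, 1),
      seg(gx - gw, b, gx - gw, b - gd, 1, 0),
      seg(gx - gw, b - gd, gx + gw, b - gd, 0, 1),
      seg(gx + gw, b - gd, gx + gw, b, -1, 0),
      seg(gx + gw, b, x_join, b, 0, 1),
      arc(1)
    ) else rbind(seg(-a, b, x_join, b, 0, 1), arc(1))
    face <- seg(-a, -b, -a, b, -1, 0)
  } else {
    top <- rbind(
      fil(-a + rc, b - rc, 180, 90),
      seg(-a + rc, b, gx - gw - rc, b, 0, 1),
      fil(gx - gw - rc, b - rc, 90, 0),
      seg(gx - gw, b - rc, gx - gw, b - gd + rc, 1, 0),
      fil(gx - gw + rc, b - gd + rc, 180, 270, concave = TRUE),
      seg(gx - gw + rc, b - gd, gx + gw - rc, b - gd, 0, 1),
      fil(gx + gw - rc, b - gd + rc, 270, 360, concave = TRUE),
      seg(gx + gw, b - gd + rc, gx + gw, b - rc, -1, 0),
      fil(gx + gw + rc, b - rc, 180, 90),
      seg(gx + gw + rc, b, x_join, b, 0, 1),
      arc(1)
    )
    face <- seg(-a, -(b - rc), -a, b - rc, -1, 0)
  }
  bottom <- top
  bottom$y <- -bottom$y
  bottom$ny <- -bottom$ny
  rbind(face, top, bottom)
}

# Point-in-pillar test in pillar-centered coordinates (x along flow).
pillar_mask <- function(pillar, x, y) {
  if (pillar$kind == "cylinder") {
    r <- pillar$diameter / 2
    return(x^2 + y^2 <= r^2)
  }
  g <- hybrid_geom(pillar)
  # Upstream block: rectangle [-a, x_join] x [-b, b] with grooves notched
  # into its lateral (top/bottom) faces, forming an "I" profile; the
  # downstream half is a semi-ellipse. yy folds the top/bottom symmetry.
  yy <- abs(y)
  rect <- x >= -g$a & x <= g$x_join & yy <= g$b
  groove <- g$gw > 0 & abs(x - g$gx) <= g$gw & yy >= g$b - g$gd
  ell <- x > g$x_join &
    ((x - g$x_join) / g$el)^2 + (y / g$b)^2 <= 1
  solid <- (rect & !groove) | ell
  rc <- g$rc
  if (rc > 0) {
    beyond <- function(qx, qy) (x - qx)^2 + (yy - qy)^2 > rc^2
    # convex fillet shaves the upstream corners
    cut <- x < -g$a + rc & yy > g$b - rc & beyond(-g$a + rc, g$b - rc)
    if (g$gw > 0) {
      # convex fillets at the groove mouths
      cut <- cut |
        (x <= g$gx - g$gw & x > g$gx - g$gw - rc & yy > g$b - rc &
           beyond(g$gx - g$gw - rc, g$b - rc)) |
        (x >= g$gx + g$gw & x < g$gx + g$gw + rc & yy > g$b - rc &
           beyond(g$gx + g$gw + rc, g$b - rc))
      # concave fillets add solid at the groove floor corners
      fill <- (x > g$gx - g$gw & x < g$gx - g$gw + rc &
                 yy > g$b - g$gd & yy < g$b - g$gd + rc &
                 beyond(g$gx - g$gw + rc, g$b - g$gd + rc)) |
        (x < g$gx + g$gw & x > g$gx + g$gw - rc &
           yy > g$b - g$gd & yy < g$b - g$gd + rc &
           beyond(g$gx + g$gw - rc, g$b - g$gd + rc))
    } else {
      fill <- FALSE
    }
    solid <- (solid & !cut) | fill
  }
  solid
}

# Derived dimensions of the hybrid pillar, shared by the mask, outline and
# area computations.
hybrid_geom <- function(pillar) {
  a <- pillar$alongflow_extent / 2
  b <- pillar$lateral_extent / 2
  el <- pillar$ellipse_fraction * pillar$alongflow_extent
  x_join <- a - el
  list(a = a, b = b, el = el, x_join = x_join,
       gx = (-a + x_join) / 2,
       gw = pillar$groove_width_fraction * (x_join + a) / 2,
       gd = pillar$groove_depth_fraction * b,
       rc = pillar$corner_radius %||% 0)
}

#' Analytic footprint area of a pillar (um^2)
#' @param pillar A `dld_pillar`.
#' @return Footprint area in um^2.
#' @export
pillar_footprint_area <- function(pillar) {
  if (pillar$kind == "cylinder") return(pi * (pillar$diameter / 2)^2)
  g <- hybrid_geom(pillar)
  rect_len <- g$x_join + g$a
  base <- rect_len * 2 * g$b - 2 * (2 * g$gw * g$gd) +
    pi * g$el * g$b / 2
  # 6 convex fillets (upstream corners, groove mouths) each shave
  # (1 - pi/4) rc^2; 4 concave groove-floor fillets each add the same
  base - 2 * (1 - pi / 4) * g$rc^2
}

#' @export
print.dld_unit_cell <- function(x, ...) {
  cat(sprintf(
    "<dld_unit_cell> %s pillar, %g x %g um cell at %g um/cell, depth %g um\n",
    x$pillar$kind, x$Lx, x$Ly, x$dx, x$depth))
  cat(sprintf("  solid fraction %.3f, row shift %g um (%d cells)\n",
              mean(x$mask), x$row_shift, x$shift_cells))
  invisible(x)
}

# --- sparse Stokes assembly ------------------------------------------------

# Periodic index helpers honoring the shifted wrap in x:
# field(x + Lx, y) = field(x, y - s).
wrap_j <- function(j, ny) ((j - 1) %% ny) + 1

# Vectorized bisection for the wall distance along a grid direction:
# from p0 (fluid side) toward and past p1 (the staircase-solid neighbor,
# one spacing away), searching up to two spacings. Returns the distance
# from p0 to the analytic wall; one spacing if no crossing is found.
wall_distance <- function(pillar, p0, p1) {
  n <- nrow(p0)
  p2 <- p0 + 2 * (p1 - p0)
  lo <- rep(0, n)
  hi <- rep(1, n)
  inside2 <- pillar_mask(pillar, p2[, 1], p2[, 2]) |
    pillar_mask(pillar, p1[, 1], p1[, 2])
  for (it in 1:16) {
    mid <- (lo + hi) / 2
    pm <- p0 + mid * (p2 - p0)
    ins <- pillar_mask(pillar, pm[, 1], pm[, 2])
    hi <- ifelse(ins, mid, hi)
    lo <- ifelse(ins, lo, mid)
  }
  step <- sqrt(rowSums((p1 - p0)^2))
  d <- (lo + hi) / 2 * 2 * step
  d[!inside2] <- step[!inside2]
  pmin(pmax(d, 0.1 * step), 2 * step)
}

# Solve steady 2D Stokes flow with a linear drag term on a masked periodic
# cell, for both unit forcings (x and y). Returns u, v (face matrices) and
# p for each forcing. No-slip on the pillar is imposed with a ghost-cell
# immersed boundary: stencil legs that cross the analytic outline are
# shortened to the true wall distance, giving near-second-order boundary
# accuracy instead of a staircase. Units: mu Pa s, dx um -> velocities
# um/s per unit force (Pa/um).
solve_stokes_modes <- function(cell, mu, drag) {
  nx <- cell$nx; ny <- cell$ny; dx <- cell$dx; sh <- cell$shift_cells
  solid <- cell$mask
  pillar <- cell$pillar
  cx <- cell$center[1]; cy <- cell$center[2]
  N <- nx * ny
  lid <- function(i, j) (j - 1L) * nx + i     # local face/cell index
  ij <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  i <- ij$i; j <- ij$j

  # cell neighbors (for face solidity fallback and pressure gradients)
  west_i <- ifelse(i == 1L, nx, i - 1L)
  west_j <- ifelse(i == 1L, wrap_j(j + sh, ny), j)
  south_j <- wrap_j(j - 1L, ny)
  sol <- function(ii, jj) solid[cbind(ii, jj)]

  # face positions (pillar-centered coordinates); a face is solid when
  # either adjacent cell center is solid, so no flux ever crosses into a
  # solid cell and mass is conserved exactly. The ghost-leg corrections
  # below restore near-second-order wall placement.
  xu <- (i - 1L) * dx - cx; yu <- (j - 0.5) * dx - cy
  xv <- (i - 0.5) * dx - cx; yv <- (j - 1L) * dx - cy
  u_solid <- sol(i, j) | sol(west_i, west_j)
  v_solid <- sol(i, j) | sol(i, south_j)

  rows <- list(); cols <- list(); vals <- list(); nb_ <- 0L
  addv <- function(r, c, v) {
    nb_ <<- nb_ + 1L
    rows[[nb_]] <<- r; cols[[nb_]] <<- c
    vals[[nb_]] <<- rep_len(v, length(r))
  }
  lap <- mu / dx^2
  off_u <- 0L; off_v <- N; off_p <- 2L * N

  # momentum rows for one velocity component with ghost-cell walls
  momentum <- function(fsolid, xf, yf, off, p_from, p_to) {
    ff <- which(!fsolid); fs <- which(fsolid)
    ii <- i[ff]; jj <- j[ff]
    r <- off + lid(ii, jj)
    nbE <- lid(ifelse(ii == nx, 1L, ii + 1L),
               ifelse(ii == nx, wrap_j(jj - sh, ny), jj))
    nbW <- lid(ifelse(ii == 1L, nx, ii - 1L),
               ifelse(ii == 1L, wrap_j(jj + sh, ny), jj))
    nbN <- lid(ii, wrap_j(jj + 1L, ny))
    nbS <- lid(ii, wrap_j(jj - 1L, ny))
    nbs <- list(nbE, nbW, nbN, nbS)
    dirs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    diagv <- rep(-4 * lap - drag, length(ff))
    for (k in 1:4) {
      nb <- nbs[[k]]
      ns <- fsolid[nb]
      if (any(!ns)) addv(r[!ns], off + nb[!ns], lap)
      if (any(ns)) {
        p0 <- cbind(xf[ff][ns], yf[ff][ns])
        p1 <- cbind(p0[, 1] + dirs[[k]][1] * dx,
                    p0[, 2] + dirs[[k]][2] * dx)
        d <- wall_distance(pillar, p0, p1)
        diagv[ns] <- diagv[ns] + lap * (d - dx) / d
      }
    }
    addv(r, r, diagv)
    addv(r, off_p + p_to[ff], -1 / dx)
    addv(r, off_p + p_from[ff], 1 / dx)
    if (length(fs)) addv(off + lid(i[fs], j[fs]), off + lid(i[fs], j[fs]), 1)
    r
  }
  ru <- momentum(u_solid, xu, yu, off_u,
                 p_from = lid(west_i, west_j), p_to = lid(i, j))
  rv <- momentum(v_solid, xv, yv, off_v,
                 p_from = lid(i, south_j), p_to = lid(i, j))

  # --- continuity / pressure ------------------------------------------
  fluid <- which(!solid[cbind(i, j)])
  solidc <- which(solid[cbind(i, j)])
  pin <- fluid[1]   # pressure gauge replaces this cell's continuity row
  fl <- setdiff(fluid, pin)
  ic <- i[fl]; jc <- j[fl]
  rc_ <- off_p + lid(ic, jc)
  addv(rc_, off_u + lid(ifelse(ic == nx, 1L, ic + 1L),
                        ifelse(ic == nx, wrap_j(jc - sh, ny), jc)), 1 / dx)
  addv(rc_, off_u + lid(ic, jc), -1 / dx)
  addv(rc_, off_v + lid(ic, wrap_j(jc + 1L, ny)), 1 / dx)
  addv(rc_, off_v + lid(ic, jc), -1 / dx)
  addv(off_p + lid(i[pin], j[pin]), off_p + lid(i[pin], j[pin]), 1)
  if (length(solidc)) {
    addv(off_p + lid(i[solidc], j[solidc]),
         off_p + lid(i[solidc], j[solidc]), 1)
  }

  A <- Matrix::sparseMatrix(
    i = unlist(rows), j = unlist(cols), x = unlist(vals),
    dims = c(3L * N, 3L * N))
  b <- matrix(0, 3L * N, 2L)
  b[ru, 1L] <- -1
  b[rv, 2L] <- -1
  sol2 <- as.matrix(Matrix::solve(A, b))
  lapply(1:2, function(k) {
    list(u = matrix(sol2[seq_len(N), k], nx, ny),
         v = matrix(sol2[N + seq_len(N), k], nx, ny),
         p = matrix(sol2[2L * N + seq_len(N), k], nx, ny))
  })
}

# Net fluxes of a face-field solution (per um of depth-weight; multiply by
# the caller's depth factor). Qx: mean over cross-sections of sum_j u * dx.
mode_fluxes <- function(sol, cell) {
  qx <- mean(rowSums(sol$u) * cell$dx)   # per x-station: sum over j
  qy <- mean(colSums(sol$v) * cell$dx)   # per y-station: sum over i
  c(qx = qx, qy = qy)
}

#' Solve the unit-cell flow at a target per-gap flow
#'
#' Solves steady viscous flow in a periodic pillar unit cell, by either of
#' two depth treatments:
#'
#' * `"midplane_2d_brinkman"` (default): one 2D solve of the
#'   depth-averaged field with the shallow-channel drag `-12 mu / h^2 u`;
#'   midplane velocities are 1.5x the depth average (parabolic profile).
#' * `"coarse_3d"`: a truncated sine expansion in depth; each odd mode
#'   `k = 1, 3, ...` is a 2D solve with drag `mu (k pi / h)^2` and force
#'   weight `4 / (k pi)`, and the modes sum to a slab flow with no-slip
#'   floor and ceiling. `n_modes` odd modes are used (default 3).
#'
#' The linear solution is rescaled exactly so the per-gap flux matches
#' `per_gap_ulmin` and combined so the net lateral flux is zero (mean flow
#' along the channel axis).
#'
#' @param cell A [rasterize_pillar()] unit cell.
#' @param per_gap_ulmin Target volumetric flow through the gap (uL/min).
#' @param viscosity_pas Viscosity (Pa s), default 1 mPa s.
#' @param model `"midplane_2d_brinkman"` or `"coarse_3d"`.
#' @param n_modes Number of odd depth modes for `"coarse_3d"`.
#' @return A `dld_field` object carrying per-mode face velocities plus
#'   cell-centered depth-averaged (`ud`, `vd`) and midplane (`um`, `vm`)
#'   velocity matrices in um/s.
#' @examples
#' cell <- rasterize_pillar(pillar_cylinder(50), 63, 90, resolution = 2,
#'                          row_shift = 16)
#' fld <- solve_unit_cell(cell, per_gap_ulmin = 4.9875)
#' @export
solve_unit_cell <- function(cell, per_gap_ulmin, viscosity_pas = 1e-3,
                            model = c("midplane_2d_brinkman", "coarse_3d"),
                            n_modes = 3) {
  stopifnot(inherits(cell, "dld_unit_cell"), per_gap_ulmin >= 0,
            viscosity_pas > 0)
  model <- match.arg(model)
  h <- cell$depth
  q_target <- per_gap_ulmin * ULMIN_TO_UM3S  # um^3/s

  if (model == "midplane_2d_brinkman") {
    ks <- 1
    drags <- 12 * viscosity_pas / h^2
    force_w <- 1
    depth_w <- h          # volumetric flux per unit depth-avg velocity
    mid_w <- 1.5
    floor_w <- 6 / h      # wall dU/dz per unit depth-avg velocity (1/um)
  } else {
    ks <- seq(1, by = 2, length.out = n_modes)
    drags <- viscosity_pas * (ks * pi / h)^2
    force_w <- 4 / (ks * pi)
    depth_w <- 2 * h / (ks * pi)
    mid_w <- sin(ks * pi / 2)
    floor_w <- ks * pi / h
  }

  sols_x <- vector("list", length(ks))
  sols_y <- vector("list", length(ks))
  for (m in seq_along(ks)) {
    s2 <- solve_stokes_modes(cell, viscosity_pas, drags[m])
    # scale by the mode's share of the uniform force
    for (f in c("u", "v", "p")) {
      s2[[1]][[f]] <- s2[[1]][[f]] * force_w[m]
      s2[[2]][[f]] <- s2[[2]][[f]] * force_w[m]
    }
    sols_x[[m]] <- s2[[1]]
    sols_y[[m]] <- s2[[2]]
  }
  # Net volumetric fluxes of the x- and y-forced composites
  flux_of <- function(sols) {
    qx <- 0; qy <- 0
    for (m in seq_along(ks)) {
      fx <- mode_fluxes(sols[[m]], cell)
      qx <- qx + fx["qx"] * depth_w[m]
      qy <- qy + fx["qy"] * depth_w[m]
    }
    c(qx, qy)
  }
  f1 <- flux_of(sols_x); f2 <- flux_of(sols_y)
  cc <- solve(matrix(c(f1[1], f1[2], f2[1], f2[2]), 2, 2),
              c(q_target, 0))
  modes <- lapply(seq_along(ks), function(m) {
    list(k = ks[m],
         u = cc[1] * sols_x[[m]]$u + cc[2] * sols_y[[m]]$u,
         v = cc[1] * sols_x[[m]]$v + cc[2] * sols_y[[m]]$v,
         p = cc[1] * sols_x[[m]]$p + cc[2] * sols_y[[m]]$p)
  })

  # cell-centered composites
  ud <- vd <- um <- vm <- matrix(0, cell$nx, cell$ny)
  for (m in seq_along(ks)) {
    uc <- face_to_center_u(modes[[m]]$u, cell)
    vc <- face_to_center_v(modes[[m]]$v, cell)
    wd <- if (model == "midplane_2d_brinkman") 1 else 2 / (ks[m] * pi)
    ud <- ud + uc * wd
    vd <- vd + vc * wd
    um <- um + uc * mid_w[m]
    vm <- vm + vc * mid_w[m]
  }
  ud[cell$mask] <- 0; vd[cell$mask] <- 0
  um[cell$mask] <- 0; vm[cell$mask] <- 0

  structure(
    list(cell = cell, model = model, viscosity_pas = viscosity_pas,
         modes = modes, floor_w = floor_w,
         ud = ud, vd = vd, um = um, vm = vm,
         per_gap_ulmin = per_gap_ulmin,
         achieved_per_gap_ulmin = per_gap_ulmin),
    class = "dld_field"
  )
}

face_to_center_u <- function(u, cell) {
  nx <- cell$nx; ny <- cell$ny; sh <- cell$shift_cells
  ue <- u[c(2:nx, 1), , drop = FALSE]
  # east face of column nx wraps with lateral shift
  ue[nx, ] <- u[1, wrap_j(seq_len(ny) - sh, ny)]
  (u + ue) / 2
}

face_to_center_v <- function(v, cell) {
  (v + v[, c(2:cell$ny, 1), drop = FALSE]) / 2
}

#' @export
print.dld_field <- function(x, ...) {
  cat(sprintf(
    "<dld_field> %s, %d x %d cells (%g um/cell), per-gap %.4g uL/min\n",
    x$model, x$cell$nx, x$cell$ny, x$cell$dx, x$per_gap_ulmin))
  cat(sprintf("  midplane speed max %.3g mm/s\n",
              max(sqrt(x$um^2 + x$vm^2)) * 1e-3))
  invisible(x)
}

#' Tidy a flow field into a long tibble
#'
#' @param x A `dld_field`.
#' @param ... Unused.
#' @return Tibble with `x_um`, `y_um`, `u_mms`, `v_mms` (midplane),
#'   `speed_mms`, `solid`.
#' @export
tidy.dld_field <- function(x, ...) {
  cell <- x$cell
  tibble::tibble(
    x_um = rep((seq_len(cell$nx) - 0.5) * cell$dx, cell$ny),
    y_um = rep((seq_len(cell$ny) - 0.5) * cell$dx, each = cell$nx),
    u_mms = as.vector(x$um) * 1e-3,
    v_mms = as.vector(x$vm) * 1e-3,
    speed_mms = as.vector(sqrt(x$um^2 + x$vm^2)) * 1e-3,
    solid = as.vector(cell$mask)
  )
}

#' Per-cross-section volumetric flux of a solved field
#'
#' Mass conservation diagnostic: the volumetric flux through every
#' cross-section perpendicular to the flow, in uL/min. For a converged
#' field all values agree with the target to solver precision.
#'
#' @param field A `dld_field`.
#' @return Numeric vector, one flux per x-station.
#' @export
cross_section_flux <- function(field) {
  cell <- field$cell
  qx <- rep(0, cell$nx)
  for (m in seq_along(field$modes)) {
    k <- field$modes[[m]]$k
    wd <- if (field$model == "midplane_2d_brinkman") cell$depth else
      2 * cell$depth / (k * pi)
    qx <- qx + rowSums(field$modes[[m]]$u) * cell$dx * wd
  }
  qx / ULMIN_TO_UM3S
}

#' Streamline-based critical diameter from a solved field
#'
#' Applies the first-streamline construction to the solved unit cell: at
#' the gap throat (minimum-clearance cross-section) the width `beta` of the
#' wall-adjacent midplane stream carrying flux fraction `eps` of the gap
#' flow is measured from each pillar wall and averaged; the critical
#' diameter is `2 beta`. Wall positions at the throat are taken from the
#' analytic pillar outline (not the rasterized staircase), and the
#' cross-gap profile is integrated trapezoidally with the no-slip anchors
#' at the true walls.
#'
#' @param field A `dld_field`.
#' @param shift_fraction Row shift fraction `eps`.
#' @return A one-row tibble like [critical_diameter()]'s, `method = "cfd"`.
#' @export
critical_diameter_from_field <- function(field, shift_fraction) {
  stopifnot(inherits(field, "dld_field"),
            shift_fraction > 0, shift_fraction < 1)
  cell <- field$cell
  if (!any(cell$mask)) {
    stop("no gap throat found in this cell", call. = FALSE)
  }
  # throat: x-station of minimum clearance (maximum pillar half-width)
  xs <- (seq_len(cell$nx) - 0.5) * cell$dx
  hw <- pillar_halfwidth(cell$pillar, xs - cell$center[1])
  i0 <- which.max(hw)
  x0 <- xs[i0]
  w <- hw[i0]
  cy <- cell$center[2]
  gap <- cell$Ly - 2 * w
  # midplane axial profile across the gap, unrolled from the pillar's top
  # wall (t = 0) through the periodic boundary to the neighbor's bottom
  # wall (t = gap)
  u <- field$um[i0, ]
  yc <- (seq_len(cell$ny) - 0.5) * cell$dx
  t_up <- yc - (cy + w)                 # cells above the pillar
  t_dn <- yc + cell$Ly - (cy + w)       # cells wrapped past y = Ly
  t_all <- c(t_up, t_dn)
  u_all <- c(u, u)
  keep <- t_all > 0 & t_all < gap
  ord <- order(t_all[keep])
  tk <- c(0, t_all[keep][ord], gap)
  uk <- c(0, pmax(u_all[keep][ord], 0), 0)
  cum <- cumsum(c(0, diff(tk) * (utils::head(uk, -1) +
                                   utils::tail(uk, -1)) / 2))
  tot <- cum[length(cum)]
  if (tot <= 0) stop("no through-flow at the throat", call. = FALSE)
  invert_cum <- function(target) {
    if (target > tot) {
      stop("flux fraction unattainable at the throat", call. = FALSE)
    }
    k <- which(cum >= target)[1]
    if (k == 1) return(tk[1])
    tk[k - 1] + (target - cum[k - 1]) / (cum[k] - cum[k - 1]) *
      (tk[k] - tk[k - 1])
  }
  beta_top <- invert_cum(shift_fraction * tot)
  beta_bot <- gap - invert_cum((1 - shift_fraction) * tot)
  beta <- mean(c(beta_top, beta_bot))
  tibble::tibble(method = "cfd", gap_um = gap,
                 shift_fraction = shift_fraction,
                 dc_um = 2 * beta, beta_um = beta,
                 profile_root = beta / gap)
}

#' Wall shear stress map of a solved field
#'
#' Shear is the viscosity times the wall-normal velocity gradient. Two wall
#' families are evaluated: the pillar side walls, from one-sided
#' second-order differences of the midplane speed into the fluid, and the
#' floor/ceiling, from the depth model's wall gradient (`6 mu u / h` on the
#' depth-averaged field for the Brinkman model; the mode sum
#' `mu sum_k u_k k pi / h` for the coarse-3d model). The global peak over
#' both families is reported.
#'
#' @param field A `dld_field`.
#' @return A list of class `dld_shear`: `peak_pa`, `peak_location`
#'   (um, with `wall` = `"pillar"` or `"floor"`), `pillar` tibble of
#'   boundary-cell shear values and `floor_pa` matrix.
#' @export
wall_shear_map <- function(field) {
  stopifnot(inherits(field, "dld_field"))
  cell <- field$cell
  mu <- field$viscosity_pas
  nx <- cell$nx; ny <- cell$ny; dx <- cell$dx; sh <- cell$shift_cells
  mask <- cell$mask

  # floor/ceiling shear from the depth model
  if (field$model == "midplane_2d_brinkman") {
    floor_pa <- mu * field$floor_w * sqrt(field$ud^2 + field$vd^2)
  } else {
    gu <- gv <- matrix(0, nx, ny)
    for (m in seq_along(field$modes)) {
      k <- field$modes[[m]]$k
      gu <- gu + face_to_center_u(field$modes[[m]]$u, cell) * (k * pi / cell$depth)
      gv <- gv + face_to_center_v(field$modes[[m]]$v, cell) * (k * pi / cell$depth)
    }
    floor_pa <- mu * sqrt(gu^2 + gv^2)
    floor_pa[mask] <- 0
  }

  # Pillar-wall shear: probe the tangential midplane velocity at two fixed
  # physical distances off the analytic pillar outline and extrapolate the
  # wall gradient quadratically (no-slip anchor at the true wall). Fixed
  # probe distances make the estimate mesh-convergent and regularize
  # stress singularities at re-entrant corners at the probe scale.
  d1 <- max(4, 2 * dx); d2 <- 2 * d1
  outl <- pillar_outline(cell$pillar, dx / 2)
  px <- outl$x + cell$center[1]
  py <- outl$y + cell$center[2]
  taus <- vapply(seq_len(nrow(outl)), function(r) {
    tx <- -outl$ny[r]; ty <- outl$nx[r]
    v1 <- field_velocity_at(field, px[r] + d1 * outl$nx[r],
                            py[r] + d1 * outl$ny[r])
    v2 <- field_velocity_at(field, px[r] + d2 * outl$nx[r],
                            py[r] + d2 * outl$ny[r])
    ut1 <- v1[1] * tx + v1[2] * ty
    ut2 <- v2[1] * tx + v2[2] * ty
    abs(mu * (d2^2 * ut1 - d1^2 * ut2) / (d1 * d2 * (d2 - d1)))
  }, numeric(1))
  pillar <- tibble::tibble(x_um = px, y_um = py, shear_pa = taus)

  pk_floor <- max(floor_pa)
  pk_pillar <- if (nrow(pillar)) max(pillar$shear_pa) else 0
  if (pk_pillar >= pk_floor) {
    w <- which.max(pillar$shear_pa)
    loc <- c(x_um = pillar$x_um[w], y_um = pillar$y_um[w])
    wall <- "pillar"
    peak <- pk_pillar
  } else {
    w <- which(floor_pa == pk_floor, arr.ind = TRUE)[1, ]
    loc <- c(x_um = (w[1] - 0.5) * dx, y_um = (w[2] - 0.5) * dx)
    wall <- "floor"
    peak <- pk_floor
  }
  structure(list(peak_pa = peak, peak_wall = wall, peak_location = loc,
                 pillar = pillar, floor_pa = floor_pa, field = field),
            class = "dld_shear")
}

#' @export
print.dld_shear <- function(x, ...) {
  cat(sprintf("<dld_shear> peak %.3g Pa on the %s wall at (%.0f, %.0f) um\n",
              x$peak_pa, x$peak_wall,
              x$peak_location[1], x$peak_location[2]))
  invisible(x)
}

#' Streamline-pattern asymmetry score of a field
#'
#' The L2 norm of the difference between the midplane speed field and its
#' mirror image about the laterally running centerline of the gap (the
#' throat line, reflecting the flow direction), normalized by the field
#' norm. Zero for a perfectly fore-aft symmetric pattern; symmetric
#' cylinder cells score near zero (discretization plus row-shift residue)
#' while the asymmetric hybrid pillar scores distinctly higher.
#'
#' @param field A `dld_field`.
#' @return Dimensionless score >= 0.
#' @export
asymmetry_metric <- function(field) {
  stopifnot(inherits(field, "dld_field"))
  cell <- field$cell
  S <- sqrt(field$um^2 + field$vm^2)
  Sm <- S[rev(seq_len(cell$nx)), , drop = FALSE]
  keep <- !cell$mask & !cell$mask[rev(seq_len(cell$nx)), , drop = FALSE]
  sqrt(sum((S[keep] - Sm[keep])^2) / sum(S[keep]^2))
}

#' Integrate midplane streamlines
#'
#' Fixed-step fourth-order Runge-Kutta integration of midplane streamlines
#' from given seeds, with step `dx / 2`, stopping on stagnation or after
#' `max_length` of arc.
#'
#' @param field A `dld_field`.
#' @param seeds Two-column matrix or data frame of seed points (um).
#' @param max_length Maximum arc length per streamline (um).
#' @return Tibble with `streamline`, `step`, `x_um`, `y_um`, `status`
#'   (`"exited"` right boundary, `"stagnated"`, or `"maxlen"`).
#' @export
streamlines <- function(field, seeds, max_length = NULL) {
  stopifnot(inherits(field, "dld_field"))
  cell <- field$cell
  seeds <- as.matrix(seeds)
  max_length <- max_length %||% (4 * cell$Lx)
  step <- cell$dx / 2
  vmax <- max(sqrt(field$um^2 + field$vm^2))
  out <- purrr::map_dfr(seq_len(nrow(seeds)), function(s) {
    x <- seeds[s, 1]; y <- seeds[s, 2]
    xs <- x; ys <- y
    status <- "maxlen"
    travelled <- 0
    while (travelled < max_length) {
      vel <- function(px, py) field_velocity_at(field, px, py)
      k1 <- vel(x, y)
      sp <- sqrt(sum(k1^2))
      if (sp < 1e-9 * vmax) { status <- "stagnated"; break }
      dt <- step / sp
      k2 <- vel(x + dt / 2 * k1[1], y + dt / 2 * k1[2])
      k3 <- vel(x + dt / 2 * k2[1], y + dt / 2 * k2[2])
      k4 <- vel(x + dt * k3[1], y + dt * k3[2])
      x <- x + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      y <- y + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
      travelled <- travelled + step
      xs <- c(xs, x); ys <- c(ys, y)
      if (x >= cell$Lx) { status <- "exited"; break }
    }
    tibble::tibble(streamline = s, step = seq_along(xs) - 1,
                   x_um = xs, y_um = ys, status = status)
  })
  out
}

# Bilinear midplane velocity lookup in cell coordinates (um), honoring the
# shifted periodic wrap in x and plain wrap in y.
field_velocity_at <- function(field, x, y) {
  cell <- field$cell
  m <- floor(x / cell$Lx)
  xl <- x - m * cell$Lx
  yl <- y - m * cell$row_shift
  yl <- yl - floor(yl / cell$Ly) * cell$Ly
  # cell-center grid
  gx <- xl / cell$dx + 0.5
  gy <- yl / cell$dx + 0.5
  i0 <- floor(gx); j0 <- floor(gy)
  fx <- gx - i0; fy <- gy - j0
  nx <- cell$nx; ny <- cell$ny
  ii <- c(i0, i0 + 1)
  jj <- c(j0, j0 + 1)
  val <- function(M) {
    v <- 0
    for (a in 1:2) for (b in 1:2) {
      iw <- ((ii[a] - 1) %% nx) + 1
      jw <- jj[b]
      # crossing the x wrap while indexing is ignored at interpolation
      # scale (half-cell error at one boundary column)
      jw <- ((jw - 1) %% ny) + 1
      w <- (if (a == 1) 1 - fx else fx) * (if (b == 1) 1 - fy else fy)
      v <- v + w * M[iw, jw]
    }
    v
  }
  c(val(field$um), val(field$vm))
}

#' Plot a solved unit-cell field
#'
#' @param object A `dld_field`.
#' @param what `"speed"` (midplane speed raster) or `"shear"` (floor shear).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dld_field <- function(object, what = c("speed", "shear"), ...) {
  what <- match.arg(what)
  td <- tidy.dld_field(object)
  if (what == "shear") {
    sh <- wall_shear_map(object)
    td$fill <- as.vector(sh$floor_pa)
    lab <- "floor shear (Pa)"
  } else {
    td$fill <- td$speed_mms
    lab <- "midplane speed (mm/s)"
  }
  td$fill[td$solid] <- NA
  ggplot2::ggplot(td, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey30", name = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um, flow)", y = "y (um, lateral)")
}
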