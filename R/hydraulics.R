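# Rectangular-channel resistance, flow-network solving, stage flow budgets
# and closed-form peak-shear screens at the pump rates used to run the chip.

#' Rectangular channel description
#'
#' @param length_mm Channel length (mm).
#' @param width_um Channel width (um).
#' @param height_um Channel height (um).
#' @param viscosity_pas Fluid viscosity (Pa s). Default 1 mPa s, the uniform
#'   Newtonian value assumed for all flow calculations in this package.
#' @return A `dld_channel` object.
#' @export
channel <- function(length_mm, width_um, height_um, viscosity_pas = 1e-3) {
  ok <- function(v) is.na(v) | v > 0   # NA marks a dimension to solve for
  stopifnot(ok(length_mm), ok(width_um), ok(height_um),
            viscosity_pas > 0)
  structure(list(length_mm = length_mm, width_um = width_um,
                 height_um = height_um, viscosity_pas = viscosity_pas),
            class = "dld_channel")
}

#' Hydraulic resistance of a rectangular channel
#'
#' Uses the standard wide-duct approximation
#' `R = 12 mu L / (w a^3 (1 - 0.63 a / w))` with `a` the shorter and `w`
#' the longer cross-section dimension (the shorter dimension is cubed).
#'
#' @param c A [channel()].
#' @return Resistance in Pa s / m^3.
#' @examples
#' channel_resistance(channel(340, 500, 200))
#' @export
channel_resistance <- function(c) {
  stopifnot(inherits(c, "dld_channel"),
            !is.na(c$length_mm), !is.na(c$width_um), !is.na(c$height_um))
  a <- min(c$width_um, c$height_um) * 1e-6
  w <- max(c$width_um, c$height_um) * 1e-6
  L <- c$length_mm * 1e-3
  12 * c$viscosity_pas * L / (w * a^3 * (1 - 0.63 * a / w))
}

#' Hydraulic resistance of a cylindrical tube
#'
#' Poiseuille resistance `8 mu L / (pi r^4)`, used for tubing appendages
#' such as the 0.25 mm inner-diameter outlet tubing sometimes added to
#' compensate for blood viscosity.
#'
#' @param length_mm Tube length (mm).
#' @param diameter_mm Inner diameter (mm).
#' @param viscosity_pas Viscosity (Pa s).
#' @return Resistance in Pa s / m^3.
#' @export
tube_resistance <- function(length_mm, diameter_mm, viscosity_pas = 1e-3) {
  stopifnot(length_mm > 0, diameter_mm > 0)
  8 * viscosity_pas * (length_mm * 1e-3) / (pi * (diameter_mm * 1e-3 / 2)^4)
}

#' Solve a hydraulic network for per-edge flows
#'
#' Linear conservation solve on a resistor network: nodes are junctions,
#' edges carry resistance; inlet flows are injected at named nodes and
#' terminal nodes (named in `outlets`) are held at the reference pressure.
#'
#' @param edges Data frame with columns `from`, `to`, `resistance`
#'   (Pa s / m^3) and optionally `edge` (label).
#' @param inlets Named numeric vector of injected flows (uL/min) keyed by
#'   node name.
#' @param outlets Character vector of reference-pressure node names.
#' @return Tibble of edges with a `flow_ulmin` column (positive from
#'   `from` to `to`); mass is conserved at every interior node to 1e-9
#'   relative.
#' @examples
#' edges <- data.frame(from = c("in", "in"), to = c("a", "b"),
#'                     resistance = c(1e12, 2e12))
#' solve_network(edges, c("in" = 30), c("a", "b"))
#' @export
solve_network <- function(edges, inlets, outlets) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("from", "to", "resistance") %in% names(edges)),
            all(edges$resistance > 0), length(outlets) >= 1)
  nodes <- union(union(edges$from, edges$to), names(inlets))
  if (!all(outlets %in% nodes)) {
    stop("outlet nodes not present in the network", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = nodes)
  comp <- igraph::components(g)
  keep <- comp$membership[outlets[1]]
  if (any(comp$membership != keep)) {
    bad <- names(comp$membership)[comp$membership != keep]
    stop("network is disconnected; unreachable nodes: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  # Nodal analysis: G p = q with conductances G, injected flows q.
  free <- setdiff(nodes, outlets)
  idx <- stats::setNames(seq_along(free), free)
  n <- length(free)
  G <- matrix(0, n, n)
  q <- stats::setNames(rep(0, n), free)
  conduct <- 1 / edges$resistance
  for (k in seq_len(nrow(edges))) {
    a <- edges$from[k]; b <- edges$to[k]; c_ <- conduct[k]
    if (a %in% free) G[idx[a], idx[a]] <- G[idx[a], idx[a]] + c_
    if (b %in% free) G[idx[b], idx[b]] <- G[idx[b], idx[b]] + c_
    if (a %in% free && b %in% free) {
      G[idx[a], idx[b]] <- G[idx[a], idx[b]] - c_
      G[idx[b], idx[a]] <- G[idx[b], idx[a]] - c_
    }
  }
  for (nm in names(inlets)) {
    if (nm %in% free) q[nm] <- q[nm] + inlets[[nm]] * ULMIN_TO_UM3S * 1e-18
    # um^3/s -> m^3/s
  }
  p <- stats::setNames(rep(0, length(nodes)), nodes)
  if (n > 0) p[free] <- solve(G, q)
  flow <- (p[edges$from] - p[edges$to]) * conduct      # m^3/s
  edges$flow_ulmin <- unname(flow) / (ULMIN_TO_UM3S * 1e-18)
  edges
}

#' Resistance required for a target flow split
#'
#' For two parallel branches from a common junction, returns the resistance
#' the free branch must have so that it carries `target_fraction` of the
#' total flow, given the fixed branch's resistance:
#' `R_free = R_fixed * (1 - target) / target`. With a target of 1/3 the
#' designed (deflected) branch gets twice the fixed branch's resistance and
#' carries one third of the flow.
#'
#' @param target_fraction Desired fraction of flow through the free branch,
#'   strictly in (0, 1).
#' @param fixed_resistance Resistance of the other branch (Pa s / m^3), or
#'   a [channel()] whose resistance is computed.
#' @return Required resistance of the free branch (Pa s / m^3).
#' @examples
#' design_split(1 / 3, 1e12)  # 2e12: deflected branch carries 1/3
#' @export
design_split <- function(target_fraction, fixed_resistance) {
  if (!is.numeric(target_fraction) || target_fraction <= 0 ||
      target_fraction >= 1) {
    stop("`target_fraction` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (inherits(fixed_resistance, "dld_channel")) {
    fixed_resistance <- channel_resistance(fixed_resistance)
  }
  fixed_resistance * (1 - target_fraction) / target_fraction
}

#' Solve a channel dimension for a target resistance
#'
#' The compensation channel that balances the undeflected product path is
#' printed as 340 mm long and 200 um high with its width unstated; this
#' helper solves whichever single dimension is `NA` in the template channel
#' so that the channel attains `target_resistance`.
#'
#' @param template A [channel()] with exactly one of `length_mm`,
#'   `width_um`, `height_um` set to `NA`.
#' @param target_resistance Desired resistance (Pa s / m^3).
#' @return The completed [channel()].
#' @export
solve_channel_dimension <- function(template, target_resistance) {
  stopifnot(inherits(template, "dld_channel"), target_resistance > 0)
  dims <- c("length_mm", "width_um", "height_um")
  free <- dims[vapply(dims, function(d) is.na(template[[d]]), logical(1))]
  if (length(free) != 1) {
    stop("exactly one of length_mm/width_um/height_um must be NA",
         call. = FALSE)
  }
  f <- function(v) {
    t2 <- template
    t2[[free]] <- v
    channel_resistance(t2) - target_resistance
  }
  lo <- 1e-3; hi <- 1e6
  v <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  template[[free]] <- v
  template
}

#' Stage-by-stage flow budget of the two-stage device
#'
#' Stage 1 carries the sample plus its buffer co-flow; Stage 2 carries the
#' undeflected remainder of Stage 1 plus the Stage 2 buffer. Per-gap flow
#' divides the stage total across its columns; the mean gap velocity uses
#' the gap cross-section `gap x ceiling`.
#'
#' @param device A [two_stage_device()] (or compatible `dld_device`).
#' @param q_sample Sample (blood/cell) inlet flow (uL/min). Default 8.3
#'   (0.5 mL/hr).
#' @param q_buffer1 Stage 1 buffer inlet flow (uL/min). Default 31.6.
#' @param q_buffer2 Stage 2 buffer inlet flow (uL/min). Default 40.
#' @param split_fractions Deflected fraction per stage; defaults to the
#'   device's design values (1/3 and 1/3).
#' @return Tibble, one row per stage: `total_ulmin`, `per_gap_ulmin`,
#'   `mean_gap_velocity_mms`, `deflected_ulmin`, `undeflected_ulmin`.
#' @examples
#' stage_flow_summary(two_stage_device())
#' @export
stage_flow_summary <- function(device, q_sample = 8.3, q_buffer1 = 31.6,
                               q_buffer2 = 40,
                               split_fractions = device$split_fractions) {
  stopifnot(inherits(device, "dld_device"),
            q_sample >= 0, q_buffer1 >= 0, q_buffer2 >= 0,
            all(split_fractions > 0), all(split_fractions < 1))
  f1 <- split_fractions[["stage1"]]
  f2 <- split_fractions[["stage2"]]
  tot1 <- q_sample + q_buffer1
  tot2 <- (1 - f1) * tot1 + q_buffer2
  per_stage <- function(st, total, frac) {
    per_gap <- total / st$n_columns
    u <- per_gap * ULMIN_TO_UM3S / (st$gap * st$ceiling_height) # um/s
    tibble::tibble(
      stage = st$name, total_ulmin = total,
      per_gap_ulmin = per_gap,
      mean_gap_velocity_mms = u * 1e-3,
      deflected_ulmin = frac * total,
      undeflected_ulmin = (1 - frac) * total
    )
  }
  dplyr::bind_rows(per_stage(device$stage1, tot1, f1),
                   per_stage(device$stage2, tot2, f2))
}

#' Closed-form peak wall-shear screen for a stage
#'
#' An order-of-magnitude estimate of the peak wall shear stress in a DLD
#' gap at a given per-gap flow, from parallel-plate profiles: the local
#' cross-gap maximum of the depth-averaged velocity is taken as 1.5x the
#' gap mean; the floor/ceiling shear is `6 mu u / h` and the pillar-wall
#' shear at the midplane is `4 mu u_mid_max / g` with
#' `u_mid_max = 1.5 * 1.5 * U`. The larger of the two is returned. This is
#' a design screen; [wall_shear_map()] on a solved unit cell gives the
#' resolved value.
#'
#' @param per_gap_ulmin Flow through one gap (uL/min).
#' @param stage A `dld_stage`.
#' @param viscosity_pas Viscosity (Pa s).
#' @return One-row tibble: `floor_shear_pa`, `pillar_shear_pa`,
#'   `peak_shear_pa`.
#' @export
analytic_peak_shear <- function(per_gap_ulmin, stage, viscosity_pas = 1e-3) {
  stopifnot(inherits(stage, "dld_stage"), per_gap_ulmin >= 0)
  g <- stage$gap
  h <- stage$ceiling_height
  U <- per_gap_ulmin * ULMIN_TO_UM3S / (g * h)  # depth-avg mean, um/s
  u_loc <- 1.5 * U                              # cross-gap local max
  u_mid <- 1.5 * u_loc                          # midplane value
  floor_shear <- 6 * viscosity_pas * u_loc / h  # Pa (um/s / um = 1/s)
  pillar_shear <- 4 * viscosity_pas * u_mid / g
  tibble::tibble(stage = stage$name,
                 floor_shear_pa = floor_shear,
                 pillar_shear_pa = pillar_shear,
                 peak_shear_pa = max(floor_shear, pillar_shear))
}

#' Outlet network reproducing the design splits
#'
#' Builds the three-output resistor network of the chip: at each stage's
#' exit the deflected branch splits off while the undeflected stream
#' continues. The Stage 1 deflected (compensation) branch is matched with
#' [design_split()] against the whole undeflected path -- the Stage 2
#' entry channel plus the parallel Stage 2 outlet pair -- exactly the
#' resistance-matching used to set the product splits on the chip.
#'
#' @param device A `dld_device`.
#' @param base_resistance Resistance assigned to each undeflected branch
#'   (Pa s / m^3); the absolute scale cancels in the splits.
#' @return An edge tibble suitable for [solve_network()].
#' @export
outlet_network <- function(device, base_resistance = 1e14) {
  f1 <- device$split_fractions[["stage1"]]
  f2 <- device$split_fractions[["stage2"]]
  r_d2 <- design_split(f2, base_resistance)
  r_par2 <- 1 / (1 / r_d2 + 1 / base_resistance)
  r_d1 <- design_split(f1, base_resistance + r_par2)
  tibble::tibble(
    from = c("stage1_exit", "stage1_exit", "stage2_exit", "stage2_exit"),
    to = c("stage1_product", "stage2_exit", "stage2_product", "waste"),
    edge = c("stage1_deflected", "stage1_undeflected",
             "stage2_deflected", "stage2_undeflected"),
    resistance = c(r_d1, base_resistance, r_d2, base_resistance)
  )
}
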