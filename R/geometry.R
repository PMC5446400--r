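# Pillar shapes, stage specifications and DLD design arithmetic.
#
# Unit conventions used throughout the package: lengths in micrometres (um),
# flow rates in uL/min, viscosity in Pa s, stresses in Pa. Coordinates:
# x = mean flow direction, y = lateral (deflection positive toward the
# product wall), z = depth.

#' Cylindrical pillar shape
#'
#' @param diameter Pillar diameter (um).
#' @return An object of class `dld_pillar` describing a circular pillar.
#' @examples
#' pillar_cylinder(50)
#' @export
pillar_cylinder <- function(diameter) {
  stopifnot(is.numeric(diameter), length(diameter) == 1, diameter > 0)
  structure(
    list(kind = "cylinder", diameter = diameter,
         lateral_extent = diameter, alongflow_extent = diameter),
    class = "dld_pillar"
  )
}

#' Asymmetric hybrid pillar shape
#'
#' An upstream "I"-profiled half (a rectangle with symmetric grooves notched
#' into its top and bottom faces) joined to a downstream semi-elliptical
#' half. This shape breaks fore-aft symmetry of the flow between pillars,
#' which is what drives rotation of asymmetric particles such as cell
#' clusters. The exact groove dimensions of the fabricated pillars are not
#' published; they are exposed here as free fractions of the footprint.
#'
#' @param lateral_extent Full lateral (y) width of the pillar footprint (um).
#' @param alongflow_extent Full along-flow (x) length of the footprint (um).
#' @param groove_width_fraction Groove opening along x as a fraction of the
#'   upstream half-length. Default 1/3.
#' @param groove_depth_fraction Groove depth along y as a fraction of the
#'   half-width. Default 1/4.
#' @param ellipse_fraction Fraction of the along-flow extent taken by the
#'   downstream semi-ellipse. Default 1/2 ("half ellipsoidal").
#' @param corner_radius Fillet radius (um) applied to the outline's sharp
#'   corners (upstream face corners, groove mouths and groove floors).
#'   Photolithographed and PDMS-molded pillars have finite corner radii;
#'   perfectly sharp corners would carry a non-physical wall-stress
#'   singularity. Default 4 um; 0 gives the idealized sharp outline.
#' @return An object of class `dld_pillar`.
#' @examples
#' pillar_hybrid(77, 60)
#' @export
pillar_hybrid <- function(lateral_extent, alongflow_extent,
                          groove_width_fraction = 1 / 3,
                          groove_depth_fraction = 1 / 4,
                          ellipse_fraction = 1 / 2,
                          corner_radius = 4) {
  stopifnot(lateral_extent > 0, alongflow_extent > 0, corner_radius >= 0)
  fr <- c(groove_width_fraction, groove_depth_fraction, ellipse_fraction)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr >= 1) ||
      ellipse_fraction <= 0) {
    stop("groove fractions must lie in [0, 1) and the ellipse fraction ",
         "strictly in (0, 1)", call. = FALSE)
  }
  if (xor(groove_width_fraction == 0, groove_depth_fraction == 0)) {
    groove_width_fraction <- groove_depth_fraction <- 0
  }
  rect_len <- (1 - ellipse_fraction) * alongflow_extent
  gw <- groove_width_fraction * rect_len / 2
  gd <- groove_depth_fraction * lateral_extent / 2
  if (corner_radius > 0 && gw > 0 &&
      (2 * corner_radius > gd || corner_radius > gw ||
       4 * corner_radius > rect_len - 2 * gw)) {
    stop("`corner_radius` too large for the groove geometry",
         call. = FALSE)
  }
  structure(
    list(kind = "asymmetric_hybrid",
         lateral_extent = lateral_extent,
         alongflow_extent = alongflow_extent,
         groove_width_fraction = groove_width_fraction,
         groove_depth_fraction = groove_depth_fraction,
         ellipse_fraction = ellipse_fraction,
         corner_radius = corner_radius),
    class = "dld_pillar"
  )
}

#' @export
print.dld_pillar <- function(x, ...) {
  if (x$kind == "cylinder") {
    cat(sprintf("<dld_pillar> cylinder, diameter %g um\n", x$diameter))
  } else {
    cat(sprintf(
      "<dld_pillar> asymmetric hybrid, %g um lateral x %g um along-flow\n",
      x$lateral_extent, x$alongflow_extent))
    cat(sprintf("  groove w/d fractions %.3g/%.3g, ellipse fraction %.3g\n",
                x$groove_width_fraction, x$groove_depth_fraction,
                x$ellipse_fraction))
  }
  invisible(x)
}

#' One-stage DLD array specification
#'
#' Bundles the pillar shape with the array geometry of one device stage.
#' The lateral pitch is `pillar lateral extent + gap`; the row shift is
#' `pitch * shift_fraction`, rounded to integer micrometres as fabricated
#' masks are.
#'
#' @param pillar A [pillar_cylinder()] or [pillar_hybrid()] object.
#' @param gap Lateral clearance between pillars (um).
#' @param shift_fraction Row shift fraction (the array tilt), in (0, 1).
#' @param rows_per_reset Rows per reset as laid out on the mask (metadata;
#'   trajectory logic uses `1 / shift_fraction`).
#' @param n_resets Total number of resets in the array.
#' @param n_columns Number of pillar columns (equals the number of gaps a
#'   flow cross-section crosses).
#' @param ceiling_height Channel depth (um).
#' @param row_pitch Along-flow row spacing (um). Defaults to the lateral
#'   pitch (square lattice); not printed for the fabricated devices.
#' @param name Optional stage label.
#' @return A `dld_stage` object (also a list).
#' @examples
#' dld_stage(pillar_cylinder(50), gap = 63, shift_fraction = 1 / 7,
#'           rows_per_reset = 10, n_resets = 12, n_columns = 8,
#'           ceiling_height = 90)
#' @export
dld_stage <- function(pillar, gap, shift_fraction, rows_per_reset,
                      n_resets, n_columns, ceiling_height,
                      row_pitch = NULL, name = NULL) {
  stopifnot(inherits(pillar, "dld_pillar"), gap > 0,
            shift_fraction > 0, shift_fraction < 1,
            rows_per_reset >= 1, n_resets >= 1, n_columns >= 1,
            ceiling_height > 0)
  pitch <- pillar$lateral_extent + gap
  if (is.null(row_pitch)) row_pitch <- pitch
  structure(
    list(pillar = pillar, gap = gap, pitch = pitch,
         shift_fraction = shift_fraction,
         row_shift = round(pitch * shift_fraction),
         rows_per_reset = rows_per_reset, n_resets = n_resets,
         n_columns = n_columns, ceiling_height = ceiling_height,
         row_pitch = row_pitch, name = name %||% "stage"),
    class = "dld_stage"
  )
}

#' @export
print.dld_stage <- function(x, ...) {
  cat(sprintf("<dld_stage> %s\n", x$name))
  print(x$pillar)
  cat(sprintf(
    "  gap %g um, pitch %g um, shift %g um (fraction %.4g), ceiling %g um\n",
    x$gap, x$pitch, x$row_shift, x$shift_fraction, x$ceiling_height))
  cat(sprintf("  %d columns, %d rows/reset, %d resets\n",
              x$n_columns, x$rows_per_reset, x$n_resets))
  invisible(x)
}

#' Tidy a stage specification into a one-row tibble
#'
#' @param x A `dld_stage`.
#' @param ... Unused.
#' @return A one-row tibble of the stage's geometric parameters.
#' @export
tidy.dld_stage <- function(x, ...) {
  tibble::tibble(
    stage = x$name,
    pillar_kind = x$pillar$kind,
    pillar_lateral_um = x$pillar$lateral_extent,
    pillar_alongflow_um = x$pillar$alongflow_extent,
    gap_um = x$gap,
    pitch_um = x$pitch,
    row_shift_um = x$row_shift,
    shift_fraction = x$shift_fraction,
    rows_per_reset = x$rows_per_reset,
    n_resets = x$n_resets,
    n_columns = x$n_columns,
    ceiling_um = x$ceiling_height
  )
}

#' Critical diameter of a DLD array
#'
#' The particle diameter separating zigzag from displacement transport, from
#' the gap width `g` and row shift fraction `eps`. Three closed-form
#' constructions are provided:
#'
#' * `"plug"`: uniform cross-gap velocity; the first stream carries flux
#'   fraction `eps` in width `g * eps`, so `Dc = 2 g eps`.
#' * `"parabolic"` (default): parabolic cross-gap profile; the first-stream
#'   width `beta = g x` solves the cubic flux equation
#'   `3 x^2 - 2 x^3 = eps` for `x` in (0, 1/2), and `Dc = 2 beta`. This is
#'   the flux-weighted construction that reproduces the devices' nominal
#'   30 um at `g = 63`, `eps = 1/7`.
#' * `"davis"`: the empirical correlation `Dc = 1.4 g eps^0.48`.
#'
#' A fourth, field-based construction (`method = "cfd"`) is produced by
#' [critical_diameter_from_field()] on a solved unit cell.
#'
#' @param gap Gap width `g` (um).
#' @param shift_fraction Row shift fraction `eps` in (0, 1).
#' @param method One of `"plug"`, `"parabolic"`, `"davis"`.
#' @return A one-row tibble with columns `method`, `gap_um`,
#'   `shift_fraction`, `dc_um`, `beta_um` (first-stream width, `NA` for
#'   `"davis"`) and `profile_root` (`beta / g`, `NA` for `"davis"`).
#' @examples
#' critical_diameter(63, 1 / 7)                  # ~30 um
#' critical_diameter(63, 1 / 7, method = "plug") # 18 um
#' @export
critical_diameter <- function(gap, shift_fraction, method = "parabolic") {
  stopifnot(is.numeric(gap), length(gap) == 1,
            is.numeric(shift_fraction), length(shift_fraction) == 1)
  if (!is.finite(gap) || gap <= 0) {
    stop("`gap` must be a positive length in um", call. = FALSE)
  }
  if (!is.finite(shift_fraction) || shift_fraction <= 0 ||
      shift_fraction >= 1) {
    stop("`shift_fraction` must lie strictly in (0, 1)", call. = FALSE)
  }
  method <- match.arg(method, c("parabolic", "plug", "davis"))
  beta <- root <- NA_real_
  dc <- switch(method,
    plug = {
      root <- shift_fraction
      beta <- gap * root
      2 * beta
    },
    parabolic = {
      root <- flux_profile_root(shift_fraction)
      beta <- gap * root
      2 * beta
    },
    davis = 1.4 * gap * shift_fraction^0.48
  )
  tibble::tibble(method = method, gap_um = gap,
                 shift_fraction = shift_fraction,
                 dc_um = dc, beta_um = beta, profile_root = root)
}

# Root x in (0, 1/2) of 3x^2 - 2x^3 = eps: the fraction of a parabolic
# gap profile's flux carried by the wall-adjacent band of width x * g.
flux_profile_root <- function(eps) {
  f <- function(x) 3 * x^2 - 2 * x^3 - eps
  r <- stats::uniroot(f, c(0, 0.5), tol = .Machine$double.eps^0.75)$root
  if (abs(f(r)) >= 1e-10) {
    stop("flux profile root did not converge", call. = FALSE) # nocov
  }
  r
}

#' Row shift from pitch and shift fraction
#'
#' @param pitch Lateral pitch (um).
#' @param shift_fraction Row shift fraction in `[0, 1)`.
#' @param round_to_um Round to the nearest integer um, as mask layouts do?
#' @return Row shift (um).
#' @examples
#' row_shift(140, 1 / 7)              # 20
#' row_shift(113, 1 / 7, TRUE)        # 16
#' @export
row_shift <- function(pitch, shift_fraction, round_to_um = FALSE) {
  stopifnot(pitch > 0, shift_fraction >= 0, shift_fraction < 1)
  s <- pitch * shift_fraction
  if (round_to_um) round(s) else s
}

#' Reset budget of a DLD array
#'
#' A continuously displaced particle crosses one lateral pillar pitch per
#' reset, so fully traversing an array `n_columns` pitches wide requires at
#' least `n_columns` resets; a safety margin absorbs deflection failures.
#'
#' @param n_columns Number of pillar columns.
#' @param safety_margin Extra resets beyond the theoretical minimum.
#' @return Tibble with `min_resets` and `total_resets`.
#' @examples
#' reset_requirements(32, 16) # 32, 48
#' @export
reset_requirements <- function(n_columns, safety_margin = 0) {
  stopifnot(n_columns >= 1, safety_margin >= 0)
  tibble::tibble(min_resets = n_columns,
                 total_resets = n_columns + safety_margin)
}

#' The two-stage cluster chip device specification
#'
#' The as-fabricated geometry of the two-stage cluster-sorting chip:
#' Stage 1 is a conventional cylinder-pillar DLD (50 um pillars, 63 um
#' gaps, 1/7 shift fraction, 90 um ceiling, 8 columns, 12 resets) that
#' deflects large clusters by size; Stage 2 is an asymmetric hybrid-pillar
#' DLD (77 x 60 um footprint, 63 um gaps, 1/7 shift fraction, 30 um
#' ceiling, 32 columns, 48 resets) that deflects small clusters by
#' rotation-exposed asymmetry. Both stages have nominal critical diameters
#' of 30 um. Three terminal outputs: Stage 1 product, Stage 2 product and
#' Waste; one third of each stage's flow is deflected to its product.
#'
#' @param groove_width_fraction,groove_depth_fraction Stage 2 pillar groove
#'   fractions (unpublished; defaults are the package's parameterization).
#' @return A `dld_device` object with elements `stage1`, `stage2`,
#'   `split_fractions` (deflected fraction per stage) and `outputs`.
#' @examples
#' dev <- two_stage_device()
#' dev$stage1$pitch  # 113
#' @export
two_stage_device <- function(groove_width_fraction = 1 / 3,
                             groove_depth_fraction = 1 / 4) {
  stage1 <- dld_stage(
    pillar = pillar_cylinder(50), gap = 63, shift_fraction = 1 / 7,
    rows_per_reset = 10, n_resets = 12, n_columns = 8,
    ceiling_height = 90, name = "stage1")
  stage2 <- dld_stage(
    pillar = pillar_hybrid(77, 60,
                           groove_width_fraction = groove_width_fraction,
                           groove_depth_fraction = groove_depth_fraction),
    gap = 63, shift_fraction = 1 / 7,
    rows_per_reset = 10, n_resets = 48, n_columns = 32,
    ceiling_height = 30, name = "stage2")
  new_dld_device(stage1, stage2,
                 split_fractions = c(stage1 = 1 / 3, stage2 = 1 / 3))
}

new_dld_device <- function(stage1, stage2, split_fractions) {
  stopifnot(inherits(stage1, "dld_stage"), inherits(stage2, "dld_stage"),
            all(split_fractions > 0), all(split_fractions < 1))
  structure(
    list(stage1 = stage1, stage2 = stage2,
         split_fractions = split_fractions,
         outputs = c("stage1_product", "stage2_product", "waste")),
    class = "dld_device"
  )
}

#' @export
print.dld_device <- function(x, ...) {
  cat("<dld_device> two-stage DLD cluster sorter\n")
  print(x$stage1)
  print(x$stage2)
  cat(sprintf("  deflected (product) fractions: stage1 %.3g, stage2 %.3g\n",
              x$split_fractions[["stage1"]], x$split_fractions[["stage2"]]))
  invisible(x)
}

#' @rdname tidy.dld_stage
#' @export
tidy.dld_device <- function(x, ...) {
  dplyr::bind_rows(tidy.dld_stage(x$stage1), tidy.dld_stage(x$stage2))
}

#' Design report for a device
#'
#' One row per stage: pitch/shift arithmetic, critical diameters by all
#' closed-form methods, and the reset budget.
#'
#' @param device A `dld_device`.
#' @return A tibble, one row per stage.
#' @export
design_report <- function(device) {
  stopifnot(inherits(device, "dld_device"))
  purrr::map_dfr(list(device$stage1, device$stage2), function(st) {
    dc_par <- critical_diameter(st$gap, st$shift_fraction, "parabolic")
    dc_plug <- critical_diameter(st$gap, st$shift_fraction, "plug")
    dc_dav <- critical_diameter(st$gap, st$shift_fraction, "davis")
    tibble::tibble(
      stage = st$name,
      gap_um = st$gap, pitch_um = st$pitch,
      shift_fraction = st$shift_fraction,
      row_shift_um = st$row_shift,
      ceiling_um = st$ceiling_height,
      n_columns = st$n_columns, n_resets = st$n_resets,
      min_resets = st$n_columns,
      reset_margin = st$n_resets - st$n_columns,
      dc_parabolic_um = dc_par$dc_um,
      dc_plug_um = dc_plug$dc_um,
      dc_davis_um = dc_dav$dc_um,
      dc_nominal_um = round(dc_par$dc_um)
    )
  })
}
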