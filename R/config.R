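# Human-readable device / run configuration (YAML).

#' Write a device specification to a YAML config
#'
#' @param device A `dld_device`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_device_config <- function(device, path) {
  stopifnot(inherits(device, "dld_device"))
  st <- function(s) {
    out <- list(
      pillar = s$pillar[names(s$pillar) != "kind"],
      pillar_kind = s$pillar$kind,
      gap_um = s$gap, shift_fraction = s$shift_fraction,
      rows_per_reset = s$rows_per_reset, n_resets = s$n_resets,
      n_columns = s$n_columns, ceiling_um = s$ceiling_height,
      row_pitch_um = s$row_pitch)
    out
  }
  yaml::write_yaml(list(stage1 = st(device$stage1),
                        stage2 = st(device$stage2),
                        split_fractions =
                          as.list(device$split_fractions)),
                   path, precision = 15)
  invisible(path)
}

#' Read a device specification from a YAML config
#'
#' @param path YAML file written by [write_device_config()].
#' @return A `dld_device`.
#' @export
read_device_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  st <- function(s, name) {
    pil <- if (s$pillar_kind == "cylinder") {
      pillar_cylinder(s$pillar$diameter)
    } else {
      pillar_hybrid(s$pillar$lateral_extent, s$pillar$alongflow_extent,
                    s$pillar$groove_width_fraction,
                    s$pillar$groove_depth_fraction,
                    s$pillar$ellipse_fraction,
                    s$pillar$corner_radius %||% 4)
    }
    dld_stage(pil, gap = s$gap_um, shift_fraction = s$shift_fraction,
              rows_per_reset = s$rows_per_reset, n_resets = s$n_resets,
              n_columns = s$n_columns, ceiling_height = s$ceiling_um,
              row_pitch = s$row_pitch_um, name = name)
  }
  new_dld_device(st(cfg$stage1, "stage1"), st(cfg$stage2, "stage2"),
                 unlist(cfg$split_fractions))
}
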