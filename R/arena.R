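#' Arena and odor-source geometry
#'
#' Describes the circular assay plate: a 150 mm diameter arena with a
#' single odor source placed 45 mm from the midline on the +x axis, a
#' rectangular starting zone centered on the arena (long axis along y),
#' a neutral middle stripe used only by the counted preference score, and
#' the radius beyond which tracking is considered unreliable.
#'
#' Coordinates are arena-centered millimetres with the odor axis along +x.
#'
#' @param radius_mm arena radius (default 75).
#' @param odor_source_xy_mm odor source position, length-2 (default c(45, 0)).
#' @param start_zone_width_mm,start_zone_depth_mm starting-zone rectangle:
#'   width is the extent along y (the long axis), depth along x.
#' @param neutral_zone_halfwidth_mm half-width of the neutral middle stripe
#'   (default 5, i.e. a 1 cm stripe), used by [pref_counted()] assays only.
#' @param tracking_cutoff_radius_mm radius beyond which tracked frames are
#'   discarded when fragmenting simulated data (default 67).
#' @return an object of class `arena_spec`.
#' @examples
#' arena_spec()
#' @export
arena_spec <- function(radius_mm = 75,
                       odor_source_xy_mm = c(45, 0),
                       start_zone_width_mm = 45,
                       start_zone_depth_mm = 8.5,
                       neutral_zone_halfwidth_mm = 5,
                       tracking_cutoff_radius_mm = 67) {
  stopifnot(is.numeric(radius_mm), length(radius_mm) == 1L, radius_mm > 0,
            is.numeric(odor_source_xy_mm), length(odor_source_xy_mm) == 2L,
            all(is.finite(odor_source_xy_mm)),
            start_zone_width_mm > 0, start_zone_depth_mm > 0,
            neutral_zone_halfwidth_mm > 0, tracking_cutoff_radius_mm > 0)
  if (sqrt(sum(odor_source_xy_mm^2)) >= radius_mm)
    stop("odor source must lie inside the arena")
  if (tracking_cutoff_radius_mm >= radius_mm)
    stop("tracking cutoff must be smaller than the arena radius")
  structure(
    list(radius_mm = radius_mm,
         odor_source_xy_mm = as.numeric(odor_source_xy_mm),
         start_zone_width_mm = start_zone_width_mm,
         start_zone_depth_mm = start_zone_depth_mm,
         neutral_zone_halfwidth_mm = neutral_zone_halfwidth_mm,
         tracking_cutoff_radius_mm = tracking_cutoff_radius_mm),
    class = "arena_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat("Circular assay arena\n")
  cat(sprintf("  radius: %.1f mm; odor source at (%.1f, %.1f) mm\n",
              x$radius_mm, x$odor_source_xy_mm[1], x$odor_source_xy_mm[2]))
  cat(sprintf("  start zone: %.1f x %.1f mm; neutral stripe halfwidth %.1f mm\n",
              x$start_zone_width_mm, x$start_zone_depth_mm,
              x$neutral_zone_halfwidth_mm))
  cat(sprintf("  tracking cutoff radius: %.1f mm\n",
              x$tracking_cutoff_radius_mm))
  invisible(x)
}

#' Read or write an arena specification as YAML
#'
#' @param path file path.
#' @return `read_arena()` returns an `arena_spec`;
#'   `write_arena()` returns `path` invisibly.
#' @export
read_arena <- function(path) {
  cfg <- yaml::read_yaml(path)
  keep <- intersect(names(cfg), names(formals(arena_spec)))
  do.call(arena_spec, cfg[keep])
}

#' @rdname read_arena
#' @param arena an `arena_spec`.
#' @export
write_arena <- function(arena, path) {
  stopifnot(inherits(arena, "arena_spec"))
  yaml::write_yaml(unclass(arena), path)
  invisible(path)
}
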