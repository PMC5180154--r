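#' Circular arena geometry
#'
#' Describes the circular test arena in the normalized coordinate frame used
#' throughout the package: origin at the arena centre, units of cm. The
#' default corresponds to a 29 cm diameter arena imaged at 1000 px across
#' (0.029 cm per pixel), with a 3 cm thigmotaxis ("edge") zone and a 1 x 1 cm
#' exploration grid.
#'
#' @param radius_cm Arena radius in cm (> 0).
#' @param pixel_scale Image scale in cm per pixel (> 0); used when converting
#'   raw tracker pixels to cm and to express the one-pixel stillness
#'   threshold.
#' @param edge_zone_width_cm Width of the annular edge zone in cm, measured
#'   inward from the wall; must lie in (0, radius_cm).
#' @param grid_cell_cm Side length of the square exploration-grid cells (cm).
#' @param grid_convention Which cells belong to the grid: `"intersects_disc"`
#'   keeps every cell whose square overlaps the arena disc (default);
#'   `"centre_in_disc"` keeps cells whose centre lies inside the disc. The
#'   grid origin is at the arena centre, on a cell corner.
#' @return An object of class `arena_geometry`.
#' @examples
#' arena <- arena_geometry()
#' arena
#' @export
arena_geometry <- function(radius_cm = 14.5,
                           pixel_scale = 0.029,
                           edge_zone_width_cm = 3.0,
                           grid_cell_cm = 1.0,
                           grid_convention = c("intersects_disc", "centre_in_disc")) {
  grid_convention <- match.arg(grid_convention)
  stopifnot(is.numeric(radius_cm), length(radius_cm) == 1L, radius_cm > 0)
  stopifnot(is.numeric(pixel_scale), length(pixel_scale) == 1L, pixel_scale > 0)
  if (!(edge_zone_width_cm > 0 && edge_zone_width_cm < radius_cm)) {
    stop("edge_zone_width_cm must lie strictly between 0 and radius_cm")
  }
  stopifnot(grid_cell_cm > 0)
  structure(
    list(
      radius_cm = radius_cm,
      pixel_scale = pixel_scale,
      edge_zone_width_cm = edge_zone_width_cm,
      grid_cell_cm = grid_cell_cm,
      grid_convention = grid_convention
    ),
    class = "arena_geometry"
  )
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat("Circular arena geometry\n")
  cat(sprintf("  radius:        %.3g cm (centre at (0, 0))\n", x$radius_cm))
  cat(sprintf("  pixel scale:   %.4g cm/px\n", x$pixel_scale))
  cat(sprintf("  edge zone:     %.3g cm (thigmotaxis band)\n", x$edge_zone_width_cm))
  cat(sprintf("  grid:          %.3g cm cells, convention '%s'\n",
              x$grid_cell_cm, x$grid_convention))
  invisible(x)
}

#' Recording metadata for one trial
#'
#' @param frame_rate Frames per second (> 0); 25 Hz for the reference setup.
#' @param duration_frames Number of frames in the recording (> 0);
#'   90,000 frames = 60 min at 25 Hz for the reference setup.
#' @param condition Condition label, one of `"ambient"`, `"OA"`,
#'   `"ambient_in_OA"`, `"simulated"`, `"synthetic"`.
#' @param batch_id Batch / experiment-number label (arenas are typically
#'   recorded several at a time, so trials share batches).
#' @param pixel_scale cm per pixel of the source video (> 0).
#' @return An object of class `recording_meta`.
#' @export
recording_meta <- function(frame_rate = 25,
                           duration_frames = 90000L,
                           condition = c("synthetic", "ambient", "OA",
                                         "ambient_in_OA", "simulated"),
                           batch_id = "batch1",
                           pixel_scale = 0.029) {
  condition <- match.arg(condition)
  stopifnot(frame_rate > 0, duration_frames > 0, pixel_scale > 0)
  structure(
    list(
      frame_rate = frame_rate,
      duration_frames = as.integer(duration_frames),
      condition = condition,
      batch_id = as.character(batch_id),
      pixel_scale = pixel_scale
    ),
    class = "recording_meta"
  )
}

#' @export
print.recording_meta <- function(x, ...) {
  cat(sprintf("Recording: %d frames @ %g Hz (%.1f min), condition '%s', batch '%s'\n",
              x$duration_frames, x$frame_rate,
              x$duration_frames / x$frame_rate / 60, x$condition, x$batch_id))
  invisible(x)
}

#' Stillness threshold implied by the pixel scale
#'
#' A fish is "still" between two frames when it moved less than one pixel.
#' Expressed per frame this is `pixel_scale` cm; expressed per second it is
#' `pixel_scale * frame_rate` cm/s (0.725 cm/s for 0.029 cm/px at 25 Hz,
#' conventionally rounded to 0.7 cm/s).
#'
#' @param arena An [arena_geometry()].
#' @param frame_rate Frames per second.
#' @return Named list with `cm_per_frame` and `cm_per_s`.
#' @export
stillness_threshold <- function(arena = arena_geometry(), frame_rate = 25) {
  list(cm_per_frame = arena$pixel_scale,
       cm_per_s = arena$pixel_scale * frame_rate)
}
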