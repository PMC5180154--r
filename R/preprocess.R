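#' Normalize raw tracker pixels to arena-centred cm
#'
#' Converts a raw pixel-unit trial into the standard analysis frame: arena
#' centre at (0, 0), coordinates in cm. The scale is `arena$radius_cm /
#' radius_px` when the pixel radius of the arena circle is supplied, else
#' `arena$pixel_scale`.
#'
#' @param raw A [trial_recording()] in pixel units.
#' @param arena An [arena_geometry()].
#' @param centre_px Length-2 numeric, pixel coordinates of the arena centre.
#' @param radius_px Optional pixel radius of the arena circle (> 0); when
#'   given it calibrates the scale.
#' @return A [trial_recording()] in cm.
#' @export
normalize_coordinates <- function(raw, arena = arena_geometry(),
                                  centre_px = c(0, 0), radius_px = NULL) {
  stopifnot(inherits(raw, "trial_recording"))
  if (is.null(radius_px)) {
    scale <- arena$pixel_scale
  } else {
    if (radius_px <= 0) stop("calibration radius_px must be > 0")
    scale <- arena$radius_cm / radius_px
  }
  out <- raw
  out$x <- (raw$x - centre_px[[1]]) * scale
  out$y <- (raw$y - centre_px[[2]]) * scale
  out$units <- "cm"
  out
}

#' Convert a cm trial back to tracker pixel coordinates
#'
#' Inverse of [normalize_coordinates()]: `px = cm / scale + centre_px`.
#'
#' @param trial A [trial_recording()] in cm.
#' @param arena An [arena_geometry()] supplying the pixel scale.
#' @param centre_px Pixel coordinates of the arena centre.
#' @return A [trial_recording()] in pixel units.
#' @export
to_pixel_coordinates <- function(trial, arena = arena_geometry(),
                                 centre_px = c(0, 0)) {
  stopifnot(trial$units == "cm")
  out <- trial
  out$x <- trial$x / arena$pixel_scale + centre_px[[1]]
  out$y <- trial$y / arena$pixel_scale + centre_px[[2]]
  out$units <- "px"
  out
}

#' Delete detections outside the arena
#'
#' Points with radial distance beyond the arena radius are tracker artifacts
#' (typically a fish's reflection near the wall); they are set to missing.
#'
#' @param trial A [trial_recording()] in cm.
#' @param arena An [arena_geometry()].
#' @return List with `trial` (cleaned) and `n_deleted`.
#' @export
delete_out_of_arena <- function(trial, arena = arena_geometry()) {
  stopifnot(trial$units == "cm")
  r <- radial_distance(trial)
  bad <- !is.na(r) & r > arena$radius_cm
  trial$x[bad] <- NA_real_
  trial$y[bad] <- NA_real_
  list(trial = trial, n_deleted = sum(bad))
}

#' Per-frame displacements and instantaneous speeds
#'
#' For each fish, the displacement between consecutive frames
#' `sqrt((x_t - x_(t-1))^2 + (y_t - y_(t-1))^2)` in cm/frame, and the
#' corresponding speed in cm/s (displacement times frame rate). Entry `t`
#' refers to the step arriving at frame `t + 1`; it is `NA` whenever either
#' endpoint is missing.
#'
#' @param trial A [trial_recording()] in cm with at least 2 frames.
#' @param frame_rate Frames per second; defaults to the trial's metadata.
#' @return List of two `(frames - 1) x fish` matrices: `displacement`
#'   (cm/frame) and `speed` (cm/s).
#' @export
instantaneous_speeds <- function(trial, frame_rate = trial$meta$frame_rate) {
  if (nrow(trial$x) < 2L) stop("need at least 2 frames to compute speeds")
  dx <- diff(trial$x)
  dy <- diff(trial$y)
  disp <- sqrt(dx^2 + dy^2)
  list(displacement = disp, speed = disp * frame_rate)
}

#' Delete physically impossible speed violations
#'
#' Any step faster than the maximum possible swimming speed (default
#' 91 cm/s, i.e. 0.91 m/s) indicates a mistracked point, typically an
#' identity swap. The *later* point of the offending pair is set to missing
#' and speeds are recomputed on the fly, so a single erroneous detection
#' cannot delete its valid neighbours: once point `t` is removed, the pair
#' `(t, t+1)` has a missing endpoint and `t+1` survives.
#'
#' @param trial A [trial_recording()] in cm.
#' @param v_max_cm_s Maximum possible speed in cm/s (> 0).
#' @param frame_rate Frames per second.
#' @return List with `trial` (cleaned) and `n_deleted`.
#' @export
delete_speed_violations <- function(trial, v_max_cm_s = 91,
                                    frame_rate = trial$meta$frame_rate) {
  if (v_max_cm_s <= 0) stop("v_max_cm_s must be > 0")
  max_disp <- v_max_cm_s / frame_rate   # cm per frame
  n_deleted <- 0L
  for (f in seq_len(ncol(trial$x))) {
    x <- trial$x[, f]; y <- trial$y[, f]
    disp <- sqrt(diff(x)^2 + diff(y)^2)
    viol <- !is.na(disp) & disp > max_disp   # step t-1 -> t too fast
    if (!any(viol)) next
    # Within a run of consecutive raw violations, deleting the first point
    # invalidates the next pair, so only the 1st, 3rd, ... of each run go.
    runs <- rle(viol)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    del <- integer(0)
    for (k in which(runs$values)) {
      del <- c(del, seq(starts[[k]], ends[[k]], by = 2L))
    }
    del_pts <- del + 1L   # violation at step t deletes point t+1 of the series
    trial$x[del_pts, f] <- NA_real_
    trial$y[del_pts, f] <- NA_real_
    n_deleted <- n_deleted + length(del_pts)
  }
  list(trial = trial, n_deleted = n_deleted)
}

# NA-run finder: start indices and lengths of maximal missing runs in a
# logical vector.
na_runs <- function(miss) {
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], length = r$lengths[keep])
}

#' Interpolate short tracking gaps
#'
#' Fills sequences of missing frames that are strictly shorter than
#' `max_gap_s` (one second by default) and flanked by at least
#' `context_frames` consecutive valid frames immediately before and after.
#' Each eligible gap is filled by the cubic polynomial that best
#' approximates (least squares) the flanking context, x and y independently
#' against frame index; a gap in an exactly cubic (or straight-line) path
#' is therefore recovered exactly. Filled points that would land outside
#' the arena are radially clamped to the boundary. Longer or under-flanked
#' gaps are left missing.
#'
#' @param trial A [trial_recording()] in cm, already cleaned.
#' @param arena An [arena_geometry()] (for boundary clamping).
#' @param max_gap_s Maximum gap duration in seconds; gaps of
#'   `max_gap_s * frame_rate` frames or longer are not filled.
#' @param context_frames Number of valid flanking frames required on each
#'   side, also the fitting window (>= 2).
#' @param frame_rate Frames per second.
#' @param v_max_cm_s Maximum plausible speed (cm/s); a fill whose steps
#'   (including the joints to the context) would exceed it is rejected and
#'   the gap stays missing, so interpolation never manufactures a
#'   physically impossible bridge (e.g. across an unresolved identity
#'   swap). `NULL` disables the check.
#' @return List with `trial` (filled) and `n_interpolated` (points filled).
#' @export
interpolate_gaps <- function(trial, arena = arena_geometry(),
                             max_gap_s = 1, context_frames = 5L,
                             frame_rate = trial$meta$frame_rate,
                             v_max_cm_s = 91) {
  if (context_frames < 2L) stop("context_frames must be >= 2 (cubic underdetermined)")
  max_gap <- max_gap_s * frame_rate   # gaps must be strictly shorter than this
  nfr <- nrow(trial$x)
  n_interp <- 0L
  for (f in seq_len(ncol(trial$x))) {
    x <- trial$x[, f]; y <- trial$y[, f]
    miss <- is.na(x) | is.na(y)
    if (!any(miss)) next
    runs <- na_runs(miss)
    for (g in seq_len(nrow(runs))) {
      s <- runs$start[[g]]; len <- runs$length[[g]]
      if (len >= max_gap) next
      before <- seq(s - context_frames, s - 1L)
      after <- seq(s + len, s + len + context_frames - 1L)
      if (before[[1]] < 1L || after[[length(after)]] > nfr) next
      ctx <- c(before, after)
      if (any(miss[ctx])) next
      gap <- seq(s, s + len - 1L)
      # least-squares cubic in frame index, centred for conditioning
      t0 <- mean(ctx)
      B <- outer(ctx - t0, 0:3, `^`)
      Bg <- outer(gap - t0, 0:3, `^`)
      gx <- drop(Bg %*% stats::.lm.fit(B, x[ctx])$coefficients)
      gy <- drop(Bg %*% stats::.lm.fit(B, y[ctx])$coefficients)
      r <- sqrt(gx^2 + gy^2)
      over <- r > arena$radius_cm
      if (any(over)) {
        # clamp just inside the wall so the point survives re-cleaning
        shrink <- (arena$radius_cm * (1 - 1e-12)) / r[over]
        gx[over] <- gx[over] * shrink
        gy[over] <- gy[over] * shrink
      }
      if (!is.null(v_max_cm_s)) {
        seg_x <- c(x[s - 1L], gx, x[s + len])
        seg_y <- c(y[s - 1L], gy, y[s + len])
        step <- sqrt(diff(seg_x)^2 + diff(seg_y)^2)
        if (any(step > v_max_cm_s / frame_rate)) next
      }
      x[gap] <- gx; y[gap] <- gy
      n_interp <- n_interp + len
    }
    trial$x[, f] <- x; trial$y[, f] <- y
  }
  list(trial = trial, n_interpolated = n_interp)
}

#' Cleaning and completeness report
#'
#' @param trial A cleaned [trial_recording()].
#' @param n_deleted_outside,n_deleted_speed,n_interpolated Counts from the
#'   cleaning chain.
#' @param v_max_cm_s Speed threshold used, logged for provenance.
#' @return An object of class `cleaning_report`: the counts plus
#'   `fraction_frames_complete`, the fraction of frames where every fish is
#'   present.
#' @export
completeness_report <- function(trial, n_deleted_outside = 0L,
                                n_deleted_speed = 0L, n_interpolated = 0L,
                                v_max_cm_s = 91) {
  present <- !(is.na(trial$x) | is.na(trial$y))
  structure(
    list(
      n_points_deleted_outside = as.integer(n_deleted_outside),
      n_points_deleted_speed = as.integer(n_deleted_speed),
      n_points_interpolated = as.integer(n_interpolated),
      fraction_frames_complete = mean(rowSums(present) == ncol(present)),
      v_max_cm_s = v_max_cm_s
    ),
    class = "cleaning_report"
  )
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Trajectory cleaning report\n")
  cat(sprintf("  deleted outside arena:  %d\n", x$n_points_deleted_outside))
  cat(sprintf("  deleted speed > %g cm/s: %d\n", x$v_max_cm_s, x$n_points_deleted_speed))
  cat(sprintf("  interpolated points:    %d\n", x$n_points_interpolated))
  cat(sprintf("  frames with all fish:   %.1f%%\n", 100 * x$fraction_frames_complete))
  invisible(x)
}

#' Run the full cleaning chain on one trial
#'
#' Applies, in order: out-of-arena deletion, speed-violation deletion, and
#' short-gap interpolation; then summarises the result. Input must already
#' be in cm (use [normalize_coordinates()] first for raw pixel tables). The
#' chain is idempotent: re-running it on its own output changes nothing.
#'
#' @param trial A [trial_recording()] in cm.
#' @param arena An [arena_geometry()].
#' @param v_max_cm_s Maximum possible speed, cm/s.
#' @param max_gap_s Maximum interpolatable gap, seconds (exclusive).
#' @param context_frames Valid frames required and used on each side of a gap.
#' @return List with `trial` (cleaned) and `report` (a `cleaning_report`).
#' @export
preprocess_trial <- function(trial, arena = arena_geometry(),
                             v_max_cm_s = 91, max_gap_s = 1,
                             context_frames = 5L) {
  st1 <- delete_out_of_arena(trial, arena)
  st2 <- delete_speed_violations(st1$trial, v_max_cm_s)
  st3 <- interpolate_gaps(st2$trial, arena, max_gap_s, context_frames,
                          v_max_cm_s = v_max_cm_s)
  report <- completeness_report(st3$trial,
                                n_deleted_outside = st1$n_deleted,
                                n_deleted_speed = st2$n_deleted,
                                n_interpolated = st3$n_interpolated,
                                v_max_cm_s = v_max_cm_s)
  list(trial = st3$trial, report = report)
}
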