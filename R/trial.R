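#' Group-trial container
#'
#' Holds one group trial: per-fish x and y coordinates (in cm once
#' normalized, in pixels straight off the tracker) as frames x fish matrices,
#' plus recording metadata. Missing detections are `NA`.
#'
#' @param x,y Numeric matrices, one row per frame, one column per fish.
#' @param meta A [recording_meta()].
#' @param source_id Trial label.
#' @param units `"cm"` for normalized coordinates or `"px"` for raw tracker
#'   output.
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(x, y, meta = recording_meta(),
                            source_id = "trial", units = c("cm", "px")) {
  units <- match.arg(units)
  x <- as.matrix(x); y <- as.matrix(y)
  if (!identical(dim(x), dim(y))) stop("x and y matrices must have identical dimensions")
  if (nrow(x) < 1L || ncol(x) < 1L) stop("trial must contain at least one frame and one fish")
  if (is.null(colnames(x))) colnames(x) <- colnames(y) <- paste0("fish", seq_len(ncol(x)))
  structure(
    list(x = x, y = y, meta = meta, source_id = source_id, units = units),
    class = "trial_recording"
  )
}

#' @export
print.trial_recording <- function(x, ...) {
  n_missing <- sum(is.na(x$x) | is.na(x$y))
  cat(sprintf("Trial '%s': %d fish x %d frames [%s], %d missing slots (%.1f%%)\n",
              x$source_id, ncol(x$x), nrow(x$x), x$units,
              n_missing, 100 * n_missing / length(x$x)))
  print(x$meta)
  invisible(x)
}

#' @export
dim.trial_recording <- function(x) dim(x$x)

n_fish <- function(trial) ncol(trial$x)
n_frames <- function(trial) nrow(trial$x)

#' Extract one fish's trajectory as a data frame
#'
#' @param trial A [trial_recording()].
#' @param fish Fish index or column name.
#' @return Data frame with columns `frame` (0-based), `x`, `y`.
#' @export
fish_trajectory <- function(trial, fish = 1L) {
  data.frame(frame = seq_len(nrow(trial$x)) - 1L,
             x = trial$x[, fish], y = trial$y[, fish])
}

# Radial distance of every point from the arena centre (frames x fish matrix).
radial_distance <- function(trial) sqrt(trial$x^2 + trial$y^2)
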