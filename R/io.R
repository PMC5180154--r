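#' Read an idTracker-style coordinate table
#'
#' Reads the plain-text trajectory tables produced by multi-animal video
#' trackers: one row per frame, two columns per individual in
#' `x1, y1, x2, y2, ...` order, with blank fields, `NaN` or `nan` marking
#' missing detections. Both comma- and tab/whitespace-delimited dialects are
#' accepted; a header row is autodetected (present when the first row does
#' not parse as numeric). If the table has an odd number of columns the
#' first column is taken as an explicit frame index (which must be strictly
#' increasing); otherwise frames are implicit row order, numbered from 0.
#'
#' Missing detections are preserved as `NA` — never silently filled.
#'
#' @param path Path to the coordinate table.
#' @param meta A [recording_meta()] describing the recording.
#' @param source_id Trial label; defaults to the file name.
#' @return A [trial_recording()] in pixel units (`units = "px"`), one column
#'   pair per fish.
#' @export
read_track_table <- function(path, meta = recording_meta(),
                             source_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty trajectory file: ", path)

  delim <- if (grepl(",", lines[[1]], fixed = TRUE)) "," else ""
  split1 <- function(l) {
    f <- if (delim == ",") strsplit(l, ",", fixed = TRUE)[[1]]
         else strsplit(trimws(l), "[ \t]+")[[1]]
    trimws(f)
  }
  fields1 <- split1(lines[[1]])
  is_missing_tok <- function(tok) tok == "" | tok %in% c("NaN", "nan", "NA")
  parses_numeric <- function(tok) {
    suppressWarnings(all(is_missing_tok(tok) | !is.na(as.numeric(tok))))
  }
  has_header <- !parses_numeric(fields1)
  data_lines <- if (has_header) lines[-1L] else lines
  first_data_line <- if (has_header) 2L else 1L
  if (length(data_lines) == 0L) stop("no data rows in: ", path)

  rows <- lapply(data_lines, split1)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[[1]])[[1]]
    stop(sprintf("inconsistent column count at line %d of %s (%d fields, expected %d)",
                 bad + first_data_line - 1L, path, ncols[[bad]], ncols[[1]]))
  }
  nc <- ncols[[1]]

  mat <- matrix(NA_real_, nrow = length(rows), ncol = nc)
  for (i in seq_along(rows)) {
    tok <- rows[[i]]
    val <- suppressWarnings(as.numeric(tok))
    bad <- is.na(val) & !is_missing_tok(tok)
    if (any(bad)) {
      stop(sprintf("malformed value '%s' at line %d of %s",
                   tok[which(bad)[[1]]], i + first_data_line - 1L, path))
    }
    val[is_missing_tok(tok)] <- NA_real_
    mat[i, ] <- val
  }

  if (nc %% 2L == 1L) {
    frames <- mat[, 1L]
    if (anyNA(frames) || any(diff(frames) <= 0)) {
      stop("explicit frame column must be strictly increasing with no missing values")
    }
    mat <- mat[, -1L, drop = FALSE]
    nc <- nc - 1L
  }
  if (nc < 2L) stop("trajectory table needs at least one x,y column pair")

  xi <- seq(1L, nc, by = 2L)
  trial_recording(x = mat[, xi, drop = FALSE], y = mat[, xi + 1L, drop = FALSE],
                  meta = meta, source_id = source_id, units = "px")
}

#' Write a trial's coordinates in tracker-table format
#'
#' Inverse of [read_track_table()]: one row per frame, columns
#' `x1, y1, ..., xn, yn`, missing detections written as `NaN`. Coordinates
#' are written with enough digits to round-trip to at least 6 decimals.
#'
#' @param trial A [trial_recording()].
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @param header Write a header row naming the columns?
#' @return `path`, invisibly.
#' @export
write_track_table <- function(trial, path, delim = ",", header = TRUE) {
  nf <- ncol(trial$x)
  out <- matrix(NA_real_, nrow = nrow(trial$x), ncol = 2L * nf)
  out[, seq(1L, 2L * nf, by = 2L)] <- trial$x
  out[, seq(2L, 2L * nf, by = 2L)] <- trial$y
  chr <- matrix(formatC(out, format = "f", digits = 8), nrow = nrow(out))
  chr[is.na(out)] <- "NaN"
  con <- file(path, "w")
  on.exit(close(con))
  if (header) {
    writeLines(paste(paste0(rep(c("x", "y"), nf),
                            rep(seq_len(nf), each = 2L)), collapse = delim), con)
  }
  writeLines(apply(chr, 1L, paste, collapse = delim), con)
  invisible(path)
}

#' Write / read a metadata sidecar
#'
#' Stores a [recording_meta()] next to its trajectory file as a plain-text
#' YAML key-value file.
#'
#' @param meta A [recording_meta()].
#' @param path Sidecar path (conventionally `<trial>.meta.yaml`).
#' @return `write_recording_meta()` returns `path` invisibly;
#'   `read_recording_meta()` returns a [recording_meta()].
#' @export
write_recording_meta <- function(meta, path) {
  yaml::write_yaml(unclass(meta), path)
  invisible(path)
}

#' @rdname write_recording_meta
#' @export
read_recording_meta <- function(path) {
  v <- yaml::read_yaml(path)
  recording_meta(frame_rate = v$frame_rate, duration_frames = v$duration_frames,
                 condition = v$condition, batch_id = v$batch_id,
                 pixel_scale = v$pixel_scale)
}

#' Write behavioural profiles to tidy CSV
#'
#' One row per analysis unit (fish or trial), one column per behavioural
#' variable plus the metadata columns. Values round-trip to at least 6
#' decimals through [read_profiles()].
#'
#' @param profiles Data frame of behavioural profiles, as returned by
#'   [build_behavioural_profile()] (possibly row-bound across trials).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (!is.data.frame(profiles) || nrow(profiles) == 0L) {
    stop("profiles must be a non-empty data frame")
  }
  utils::write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
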