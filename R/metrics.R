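#' Median swimming speed
#'
#' Median of the valid instantaneous speeds (cm/s) across frames, per fish
#' or pooled across the whole trial.
#'
#' @param trial A cleaned [trial_recording()] in cm.
#' @param frame_rate Frames per second.
#' @param per_fish If `TRUE` (default) a named vector, one median per fish;
#'   else a single pooled median.
#' @return Median speed(s) in cm/s; `NA` with a warning where no valid
#'   speed exists.
#' @export
median_speed <- function(trial, frame_rate = trial$meta$frame_rate,
                         per_fish = TRUE) {
  sp <- instantaneous_speeds(trial, frame_rate)$speed
  if (per_fish) {
    out <- apply(sp, 2L, function(v) {
      if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
    })
    if (anyNA(out)) warning("fish with no valid speeds: median is NA")
    out
  } else {
    if (all(is.na(sp))) {
      warning("no valid speeds in trial")
      return(NA_real_)
    }
    stats::median(sp, na.rm = TRUE)
  }
}

#' Proportion of time spent still
#'
#' A fish is still between two frames when it moved less than one pixel;
#' at the default scale of 0.029 cm/px and 25 Hz that is a speed below
#' 0.725 cm/s (the conventional "0.7 cm/s"). Computed as the fraction of
#' valid frame pairs with displacement below `still_threshold_cm`.
#'
#' @param trial A cleaned [trial_recording()] in cm.
#' @param still_threshold_cm Per-frame displacement threshold in cm
#'   (default one pixel, 0.029 cm).
#' @param per_fish Per-fish vector (default) or pooled scalar.
#' @return Proportion(s) in `[0, 1]`.
#' @export
proportion_still <- function(trial, still_threshold_cm = 0.029,
                             per_fish = TRUE) {
  disp <- instantaneous_speeds(trial)$displacement
  still <- disp < still_threshold_cm
  if (per_fish) apply(still, 2L, mean, na.rm = TRUE)
  else mean(still, na.rm = TRUE)
}

#' Proportion of time near the arena edge (thigmotaxis)
#'
#' Fraction of valid frames spent within `edge_zone_width_cm` of the wall,
#' i.e. at radial distance greater than `radius_cm - edge_zone_width_cm`.
#'
#' @param trial A cleaned [trial_recording()] in cm.
#' @param arena An [arena_geometry()].
#' @param per_fish Per-fish vector (default) or pooled scalar.
#' @return Proportion(s) in `[0, 1]`.
#' @export
proportion_near_edge <- function(trial, arena = arena_geometry(),
                                 per_fish = TRUE) {
  r <- radial_distance(trial)
  near <- r > (arena$radius_cm - arena$edge_zone_width_cm)
  if (per_fish) apply(near, 2L, mean, na.rm = TRUE)
  else mean(near, na.rm = TRUE)
}

#' Build the arena exploration grid
#'
#' Partitions the arena into square cells (1 x 1 cm by default) on a grid
#' whose origin sits at the arena centre on a cell corner. Under the default
#' `"intersects_disc"` convention a cell belongs to the grid when its square
#' overlaps the arena disc with positive area (minimum distance from centre
#' to the square strictly less than the radius); `"centre_in_disc"` keeps
#' cells whose centre lies inside the disc.
#'
#' @param arena An [arena_geometry()].
#' @return An object of class `exploration_grid` with the cell corner
#'   coordinates and `n_cells`.
#' @export
build_exploration_grid <- function(arena = arena_geometry()) {
  cs <- arena$grid_cell_cm
  R <- arena$radius_cm
  m <- ceiling(R / cs)
  idx <- seq(-m, m - 1L)                      # lower-left corner, cell units
  g <- expand.grid(ix = idx, iy = idx)
  x0 <- g$ix * cs; y0 <- g$iy * cs
  if (arena$grid_convention == "intersects_disc") {
    # min distance from origin to the closed square [x0, x0+cs] x [y0, y0+cs]
    dx <- pmax(0, pmax(x0 - 0, -(x0 + cs)))
    dy <- pmax(0, pmax(y0 - 0, -(y0 + cs)))
    keep <- sqrt(dx^2 + dy^2) < R
  } else {
    keep <- sqrt((x0 + cs / 2)^2 + (y0 + cs / 2)^2) < R
  }
  g <- g[keep, , drop = FALSE]
  key_mod <- 4L * m
  structure(
    list(
      cell_size = cs,
      ix = g$ix, iy = g$iy,
      keys = (g$ix + 2L * m) * key_mod + (g$iy + 2L * m),
      key_offset = 2L * m, key_mod = key_mod,
      n_cells = nrow(g),
      convention = arena$grid_convention,
      radius_cm = R
    ),
    class = "exploration_grid"
  )
}

#' @export
print.exploration_grid <- function(x, ...) {
  cat(sprintf("Exploration grid: %d cells of %.3g cm, convention '%s', arena radius %.3g cm\n",
              x$n_cells, x$cell_size, x$convention, x$radius_cm))
  invisible(x)
}

# Map points to grid cell keys; NA for missing points or points not in a
# grid cell (possible only for measure-zero boundary contacts).
grid_cell_keys <- function(grid, x, y) {
  ix <- floor(x / grid$cell_size)
  iy <- floor(y / grid$cell_size)
  key <- (ix + grid$key_offset) * grid$key_mod + (iy + grid$key_offset)
  key[!(key %in% grid$keys)] <- NA
  key
}

#' Arena exploration statistics
#'
#' For each fish: the time (s) at which it had entered at least 10% of the
#' grid cells (`ceiling(0.10 * n_cells)` whole cells), `NA` if never
#' reached, and the final fraction of cells entered at least once.
#'
#' @param trial A cleaned [trial_recording()] in cm.
#' @param grid An [build_exploration_grid()] result.
#' @param frame_rate Frames per second.
#' @param threshold Exploration fraction defining the latency milestone.
#' @return Data frame with one row per fish: `fish`, `time_to_explore_s`,
#'   `pct_explored`.
#' @export
exploration_stats <- function(trial, grid = build_exploration_grid(),
                              frame_rate = trial$meta$frame_rate,
                              threshold = 0.10) {
  target <- ceiling(threshold * grid$n_cells)
  out <- data.frame(fish = colnames(trial$x),
                    time_to_explore_s = NA_real_,
                    pct_explored = NA_real_)
  for (f in seq_len(ncol(trial$x))) {
    keys <- grid_cell_keys(grid, trial$x[, f], trial$y[, f])
    valid <- which(!is.na(keys))
    if (length(valid) == 0L) next
    first <- valid[!duplicated(keys[valid])]   # frames of first cell entries
    out$pct_explored[[f]] <- length(first) / grid$n_cells
    if (length(first) >= target) {
      out$time_to_explore_s[[f]] <- first[[target]] / frame_rate
    }
  }
  out
}

#' Per-frame pairwise and nearest-neighbour distances
#'
#' All inter-fish distances per frame (pairs with a missing member are
#' `NA`), each fish's per-frame nearest-neighbour distance, and the trial
#' median inter-fish distance.
#'
#' @param trial A cleaned [trial_recording()] in cm with >= 2 fish.
#' @return An object of class `neighbour_context`: `pairs` (2 x n_pairs
#'   index matrix), `pair_dist` (frames x n_pairs), `nn_dist` (frames x
#'   fish), `median_interfish_cm`.
#' @export
pairwise_distance_stats <- function(trial) {
  nf <- ncol(trial$x)
  if (nf < 2L) stop("need at least 2 fish for pairwise distances")
  pairs <- utils::combn(nf, 2L)
  np <- ncol(pairs)
  nfr <- nrow(trial$x)
  pd <- matrix(NA_real_, nfr, np)
  nn <- matrix(Inf, nfr, nf)
  for (p in seq_len(np)) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    d <- sqrt((trial$x[, i] - trial$x[, j])^2 + (trial$y[, i] - trial$y[, j])^2)
    pd[, p] <- d
    ok <- !is.na(d)
    nn[ok, i] <- pmin(nn[ok, i], d[ok])
    nn[ok, j] <- pmin(nn[ok, j], d[ok])
  }
  nn[!is.finite(nn)] <- NA_real_
  if (all(is.na(pd))) stop("no frame with at least 2 co-visible fish")
  structure(
    list(pairs = pairs, pair_dist = pd, nn_dist = nn,
         median_interfish_cm = stats::median(pd, na.rm = TRUE)),
    class = "neighbour_context"
  )
}

#' @export
print.neighbour_context <- function(x, ...) {
  cat(sprintf("Neighbour context: %d pairs x %d frames, median inter-fish distance %.2f cm\n",
              ncol(x$pair_dist), nrow(x$pair_dist), x$median_interfish_cm))
  invisible(x)
}

#' Dataset-wide local-neighbour radius
#'
#' Median of all pairwise inter-fish distances pooled over every frame,
#' pair and trial. Used as the radius within which conspecifics count as
#' "local neighbours" (6.9 cm in the reference dataset).
#'
#' @param trials List of cleaned [trial_recording()] objects.
#' @return Radius in cm.
#' @export
dataset_neighbour_radius <- function(trials) {
  if (length(trials) == 0L) stop("need at least one trial")
  pooled <- unlist(lapply(trials, function(tr) {
    pd <- pairwise_distance_stats(tr)$pair_dist
    pd[!is.na(pd)]
  }))
  stats::median(pooled)
}

#' Mean local-neighbour proportion
#'
#' For each fish, the mean over its valid frames of the proportion of the
#' rest of the group found within `radius_cm` (conspecifics missing in a
#' frame count as not within range; the denominator stays `group size - 1`).
#'
#' @param trial A cleaned [trial_recording()] in cm.
#' @param radius_cm Local-neighbour radius, cm (see
#'   [dataset_neighbour_radius()]).
#' @param ctx Optional precomputed [pairwise_distance_stats()] result.
#' @return Named per-fish vector of proportions in `[0, 1]`.
#' @export
mean_local_neighbour_prop <- function(trial, radius_cm = 6.9, ctx = NULL) {
  if (is.null(ctx)) ctx <- pairwise_distance_stats(trial)
  nf <- ncol(trial$x)
  counts <- matrix(0, nrow(trial$x), nf)
  for (p in seq_len(ncol(ctx$pairs))) {
    within <- !is.na(ctx$pair_dist[, p]) & ctx$pair_dist[, p] < radius_cm
    counts[within, ctx$pairs[1L, p]] <- counts[within, ctx$pairs[1L, p]] + 1
    counts[within, ctx$pairs[2L, p]] <- counts[within, ctx$pairs[2L, p]] + 1
  }
  focal_ok <- !(is.na(trial$x) | is.na(trial$y))
  out <- vapply(seq_len(nf), function(f) {
    mean(counts[focal_ok[, f], f]) / (nf - 1L)
  }, numeric(1))
  names(out) <- colnames(trial$x)
  out
}

#' Assemble the seven-variable behavioural profile
#'
#' Computes, for each fish (default) or for the trial as a whole, the seven
#' behavioural variables: median speed, proportion of time still, proportion
#' of time near the arena edge, time to explore 10% of the arena, overall
#' fraction of the arena explored, median nearest-neighbour distance and
#' mean local-neighbour proportion.
#'
#' @param trial A cleaned [trial_recording()] in cm.
#' @param arena An [arena_geometry()].
#' @param neighbour_radius_cm Local-neighbour radius in cm; `NULL` (default)
#'   uses this trial's median inter-fish distance. When profiles are built
#'   trial by trial across a dataset, pass the pooled value from
#'   [dataset_neighbour_radius()] instead.
#' @param still_threshold_cm Stillness displacement threshold, cm/frame.
#' @param unit `"fish"` for one profile per fish (default) or `"trial"` for
#'   a single pooled profile.
#' @param grid Optional prebuilt [build_exploration_grid()].
#' @return Data frame, one row per unit: `unit_id`, `condition`, `batch_id`
#'   and the seven variables (`median_speed`, `prop_still`,
#'   `prop_near_edge`, `time_to_explore_10pct`, `pct_arena_explored`,
#'   `median_nn_distance`, `mean_local_neighbour_prop`).
#' @export
build_behavioural_profile <- function(trial, arena = arena_geometry(),
                                      neighbour_radius_cm = NULL,
                                      still_threshold_cm = arena$pixel_scale,
                                      unit = c("fish", "trial"),
                                      grid = NULL) {
  unit <- match.arg(unit)
  if (is.null(grid)) grid <- build_exploration_grid(arena)
  ctx <- pairwise_distance_stats(trial)
  if (is.null(neighbour_radius_cm)) neighbour_radius_cm <- ctx$median_interfish_cm

  expl <- exploration_stats(trial, grid)
  nnp <- mean_local_neighbour_prop(trial, neighbour_radius_cm, ctx)
  med_nn <- apply(ctx$nn_dist, 2L, function(v) {
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
  })

  per_fish <- data.frame(
    unit_id = paste0(trial$source_id, ":", colnames(trial$x)),
    condition = trial$meta$condition,
    batch_id = trial$meta$batch_id,
    median_speed = unname(median_speed(trial)),
    prop_still = unname(proportion_still(trial, still_threshold_cm)),
    prop_near_edge = unname(proportion_near_edge(trial, arena)),
    time_to_explore_10pct = expl$time_to_explore_s,
    pct_arena_explored = expl$pct_explored,
    median_nn_distance = unname(med_nn),
    mean_local_neighbour_prop = unname(nnp),
    stringsAsFactors = FALSE
  )
  if (unit == "fish") return(per_fish)

  data.frame(
    unit_id = trial$source_id,
    condition = trial$meta$condition,
    batch_id = trial$meta$batch_id,
    median_speed = median_speed(trial, per_fish = FALSE),
    prop_still = proportion_still(trial, still_threshold_cm, per_fish = FALSE),
    prop_near_edge = proportion_near_edge(trial, arena, per_fish = FALSE),
    time_to_explore_10pct = mean(per_fish$time_to_explore_10pct, na.rm = TRUE),
    pct_arena_explored = mean(per_fish$pct_arena_explored),
    median_nn_distance = stats::median(ctx$nn_dist, na.rm = TRUE),
    mean_local_neighbour_prop = mean(per_fish$mean_local_neighbour_prop),
    stringsAsFactors = FALSE
  )
}

#' Names of the seven behavioural variables
#' @return Character vector in canonical order.
#' @export
behaviour_variables <- function() {
  c("median_speed", "prop_still", "prop_near_edge", "time_to_explore_10pct",
    "pct_arena_explored", "median_nn_distance", "mean_local_neighbour_prop")
}
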