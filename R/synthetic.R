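#' Generate one synthetic schooling trial
#'
#' Simulates a group of fish with a deliberately minimal social kernel on
#' top of the correlated-random-walk step update: each frame, a fish's
#' heading change is Gaussian turning noise plus `attraction_strength`
#' times the (wrapped) bearing error towards the group centroid plus
#' `wall_bias` times the bearing error towards a wall-following direction
#' (the local wall tangent tilted slightly outward, so wall-biased fish
#' spiral out to the wall and then follow it). Speed per frame is zero with
#' probability `stillness_prob`, else exponential with mean `speed_scale`.
#' Positions are reflected into the arena; all fish stay inside at every
#' frame.
#'
#' With `attraction_strength = 0` and `wall_bias = 0` the kernel reduces to
#' an interaction-free correlated random walk of the same family as the
#' null model.
#'
#' @param n_fish Number of fish (default 10).
#' @param duration_frames Frames to simulate (default 9,000 = 6 min at
#'   25 Hz).
#' @param frame_rate Frames per second.
#' @param arena An [arena_geometry()].
#' @param attraction_strength Sociability gain (>= 0); fraction of the
#'   bearing error to the group centroid corrected per frame. This and the
#'   next three parameters may be single values (shared by the group) or
#'   length-`n_fish` vectors (individual variation).
#' @param wall_bias Thigmotaxis gain (>= 0); fraction of the bearing error
#'   to the wall-following direction corrected per frame.
#' @param stillness_prob Probability a fish does not move in a frame.
#' @param speed_scale Mean moving speed, cm/frame (0.16 cm/frame = 4 cm/s
#'   at 25 Hz).
#' @param turn_sd SD of Gaussian turning noise, radians/frame.
#' @param outward_tilt Outward blend of the wall-following direction
#'   (0 = pure tangent).
#' @param wall_sense Circulation sense of the wall-following direction:
#'   `+1` (counter-clockwise), `-1` (clockwise) or `NULL` (default) to
#'   draw one at random for the trial. Groups adopt a common rotation
#'   direction, as milling fish schools do; a shared sense lets
#'   wall-following and cohesion coexist instead of shearing the group
#'   apart as fish pass in opposite directions.
#' @param seed Integer seed; the trial is reproducible from it.
#' @param condition,batch_id,source_id Metadata labels.
#' @return List with `trial` (a [trial_recording()] in cm) and `latents`
#'   (the latent behaviour parameters used).
#' @export
generate_school <- function(n_fish = 10L, duration_frames = 9000L,
                            frame_rate = 25, arena = arena_geometry(),
                            attraction_strength = 0.03, wall_bias = 0.02,
                            stillness_prob = 0.3, speed_scale = 0.16,
                            turn_sd = 0.4, outward_tilt = 2,
                            wall_sense = NULL,
                            seed = NULL, condition = "synthetic",
                            batch_id = "batch1", source_id = "synth") {
  stopifnot(all(attraction_strength >= 0), all(wall_bias >= 0),
            all(stillness_prob >= 0), all(stillness_prob <= 1),
            all(speed_scale > 0), duration_frames >= 2L)
  attraction_strength <- rep_len(attraction_strength, n_fish)
  wall_bias <- rep_len(wall_bias, n_fish)
  stillness_prob <- rep_len(stillness_prob, n_fish)
  speed_scale <- rep_len(speed_scale, n_fish)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(wall_sense)) wall_sense <- sample(c(-1, 1), 1L)
  stopifnot(wall_sense %in% c(-1, 1))
  R <- arena$radius_cm
  nfr <- as.integer(duration_frames)

  X <- matrix(NA_real_, nfr, n_fish)
  Y <- matrix(NA_real_, nfr, n_fish)
  r0 <- R * sqrt(stats::runif(n_fish))
  a0 <- stats::runif(n_fish, -pi, pi)
  x <- r0 * cos(a0); y <- r0 * sin(a0)
  theta <- stats::runif(n_fish, -pi, pi)
  X[1L, ] <- x; Y[1L, ] <- y

  for (t in seq_len(nfr - 1L)) {
    omega <- stats::rnorm(n_fish, 0, turn_sd)
    if (any(attraction_strength > 0)) {
      bearing_c <- atan2(mean(y) - y, mean(x) - x)
      omega <- omega + attraction_strength * wrap_angle(bearing_c - theta)
    }
    if (any(wall_bias > 0)) {
      phi <- atan2(y, x)
      # wall-following direction: local tangent in the trial's common
      # circulation sense, tilted slightly outward
      tang <- phi + wall_sense * pi / 2
      wx <- cos(tang) + outward_tilt * cos(phi)
      wy <- sin(tang) + outward_tilt * sin(phi)
      omega <- omega + wall_bias * wrap_angle(atan2(wy, wx) - theta)
    }
    omega <- wrap_angle(omega)
    v <- ifelse(stats::runif(n_fish) < stillness_prob, 0,
                stats::rexp(n_fish, rate = 1 / speed_scale))
    theta <- theta + omega
    xn <- x + v * cos(theta)
    yn <- y + v * sin(theta)
    r <- sqrt(xn^2 + yn^2)
    out <- r > R
    if (any(out)) {
      fac <- pmax(2 * R - r[out], 0) / r[out]
      xn[out] <- xn[out] * fac
      yn[out] <- yn[out] * fac
    }
    x <- xn; y <- yn
    X[t + 1L, ] <- x; Y[t + 1L, ] <- y
  }

  meta <- recording_meta(frame_rate = frame_rate, duration_frames = nfr,
                         condition = condition, batch_id = batch_id)
  list(
    trial = trial_recording(X, Y, meta = meta, source_id = source_id,
                            units = "cm"),
    latents = list(attraction_strength = attraction_strength,
                   wall_bias = wall_bias,
                   stillness_prob = stillness_prob,
                   speed_scale = speed_scale,
                   turn_sd = turn_sd,
                   outward_tilt = outward_tilt,
                   wall_sense = wall_sense)
  )
}

#' Inject tracker-like artifacts into a clean trial
#'
#' Corrupts a clean synthetic trial with the three error modes of video
#' tracking, recording every event in a ground-truth ledger: missing-
#' detection gaps (runs of 1-40 missing frames), reflection spikes (single
#' frames displaced outside the arena to a radius in `(R, 1.2R]` at the
#' same polar angle) and pairwise identity swaps (two fish exchange
#' coordinates for a stretch of frames, creating teleports at both ends).
#' Swaps are applied first, then gaps, then spikes (spikes only land on
#' frames still present), so the ledger exactly describes the corruption.
#'
#' @param trial A clean [trial_recording()] in cm.
#' @param gap_rate Per-fish per-frame probability of a gap starting.
#' @param spike_rate Per-fish per-frame probability of a reflection spike.
#' @param swap_rate Per-frame probability of an identity-swap event.
#' @param seed Integer seed.
#' @param arena An [arena_geometry()].
#' @return List with `trial` (corrupted) and `ledger` (class
#'   `ground_truth_ledger` with data frames `gaps`, `spikes`, `swaps`).
#' @export
inject_tracking_artifacts <- function(trial, gap_rate = 0.001,
                                      spike_rate = 5e-4, swap_rate = 0,
                                      seed = NULL,
                                      arena = arena_geometry()) {
  stopifnot(gap_rate >= 0, gap_rate < 1, spike_rate >= 0, spike_rate < 1,
            swap_rate >= 0, swap_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  nfr <- nrow(trial$x); nf <- ncol(trial$x)
  R <- arena$radius_cm
  gaps <- list(); spikes <- list(); swaps <- list()

  # identity swaps: exchange two fish's coordinates over a frame stretch
  if (swap_rate > 0 && nf >= 2L) {
    ev_frames <- which(stats::runif(nfr) < swap_rate)
    for (f0 in ev_frames) {
      len <- sample(5:50, 1L)
      end <- min(f0 + len - 1L, nfr)
      pair <- sample(nf, 2L)
      idx <- f0:end
      tmpx <- trial$x[idx, pair[[1]]]; tmpy <- trial$y[idx, pair[[1]]]
      trial$x[idx, pair[[1]]] <- trial$x[idx, pair[[2]]]
      trial$y[idx, pair[[1]]] <- trial$y[idx, pair[[2]]]
      trial$x[idx, pair[[2]]] <- tmpx
      trial$y[idx, pair[[2]]] <- tmpy
      swaps[[length(swaps) + 1L]] <- data.frame(
        frame = f0, length = length(idx),
        fish_a = pair[[1]], fish_b = pair[[2]])
    }
  }

  # missing-detection gaps
  if (gap_rate > 0) {
    for (f in seq_len(nf)) {
      starts <- which(stats::runif(nfr) < gap_rate)
      for (s in starts) {
        len <- sample(1:40, 1L)
        end <- min(s + len - 1L, nfr)
        if (anyNA(trial$x[s:end, f])) next   # keep gaps disjoint: exact ledger
        trial$x[s:end, f] <- NA_real_
        trial$y[s:end, f] <- NA_real_
        gaps[[length(gaps) + 1L]] <- data.frame(
          fish = f, start = s, length = end - s + 1L)
      }
    }
  }

  # reflection spikes: displaced outside the arena at the same angle
  if (spike_rate > 0) {
    for (f in seq_len(nf)) {
      frames <- which(stats::runif(nfr) < spike_rate & !is.na(trial$x[, f]))
      if (length(frames) == 0L) next
      ang <- atan2(trial$y[frames, f], trial$x[frames, f])
      rr <- stats::runif(length(frames), R, 1.2 * R)
      trial$x[frames, f] <- rr * cos(ang)
      trial$y[frames, f] <- rr * sin(ang)
      spikes[[length(spikes) + 1L]] <- data.frame(
        fish = f, frame = frames, radius = rr)
    }
  }

  empty <- function(cols) {
    as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  ledger <- structure(
    list(
      gaps = if (length(gaps)) do.call(rbind, gaps) else empty(c("fish", "start", "length")),
      spikes = if (length(spikes)) do.call(rbind, spikes) else empty(c("fish", "frame", "radius")),
      swaps = if (length(swaps)) do.call(rbind, swaps) else empty(c("frame", "length", "fish_a", "fish_b"))
    ),
    class = "ground_truth_ledger"
  )
  list(trial = trial, ledger = ledger)
}

#' @export
print.ground_truth_ledger <- function(x, ...) {
  cat(sprintf("Artifact ledger: %d gaps (%d frames), %d spikes, %d identity swaps\n",
              nrow(x$gaps), sum(x$gaps$length), nrow(x$spikes), nrow(x$swaps)))
  invisible(x)
}

#' Generate a synthetic cohort with planted three-factor structure
#'
#' Generates `n_trials` schooling trials whose latent sociability
#' (attraction), boldness (wall bias) and activity (stillness/speed) vary
#' independently across trials, split across three pseudo-conditions in
#' groups of 9 + 9 + 8 and batched three trials at a time, mirroring a
#' typical recording design. Behavioural profiles are computed per fish
#' with a cohort-wide local-neighbour radius (the pooled median inter-fish
#' distance). An optional additive condition effect on attraction supports
#' power studies.
#'
#' The activity axis is expressed mainly through `stillness_prob`; moving
#' speed varies only modestly, so arena coverage stays driven primarily by
#' the sociability axis (tightly schooling groups explore less).
#'
#' @param n_trials Number of trials (default 26).
#' @param n_fish Fish per trial.
#' @param duration_frames Frames per trial (default 9,000 = 6 min).
#' @param frame_rate Frames per second.
#' @param arena An [arena_geometry()].
#' @param seed Integer master seed.
#' @param attraction_range,wall_bias_range Uniform ranges for the latent
#'   draws.
#' @param activity_range Uniform range of the latent activity score `a` in
#'   `[0, 1]`.
#' @param stillness_range,speed_scale_range Ranges the activity score maps
#'   onto: `stillness_prob` runs from the first to the second element of
#'   `stillness_range` as `a` goes 0 to 1, `speed_scale` (cm/frame)
#'   likewise. The defaults keep the activity axis strongly expressed in
#'   median speed and stillness while its effect on arena coverage stays
#'   modest, so coverage is driven mainly by the sociability axis.
#' @param condition_effect_attraction Added to `attraction_strength` for
#'   trials in the second condition (`"OA"`-like), to plant a detectable
#'   condition effect; 0 (default) plants none.
#' @param unit Profile unit, `"fish"` (default) or `"trial"`.
#' @return List: `profiles` (row-bound profile data frame), `trials` (list
#'   of clean [trial_recording()]s), `latents` (per-trial latent data
#'   frame), `neighbour_radius_cm` (pooled median inter-fish distance).
#' @export
generate_cohort_for_pca <- function(n_trials = 26L, n_fish = 10L,
                                    duration_frames = 9000L, frame_rate = 25,
                                    arena = arena_geometry(), seed = 1L,
                                    attraction_range = c(0, 0.2),
                                    wall_bias_range = c(0, 0.06),
                                    activity_range = c(0, 1),
                                    stillness_range = c(0.40, 0.26),
                                    speed_scale_range = c(0.14, 0.16),
                                    outward_tilt = 6,
                                    condition_effect_attraction = 0,
                                    unit = "fish") {
  set.seed(seed)
  # conditions interleave across batches (arenas recorded simultaneously
  # hold different conditions), giving the 9+9+8 split at 26 trials and
  # keeping condition effects identifiable within batches
  conds <- rep(c("ambient", "OA", "ambient_in_OA"),
               length.out = n_trials + 2)[seq_len(n_trials)]
  # Stratified near-orthogonal latent design: each latent takes n_trials
  # equally spaced levels, permuted so pairwise correlations between the
  # planted axes are minimized (at n = 26 plain uniform draws routinely
  # show |r| ~ 0.3-0.5 by chance, which would blur the planted blocks).
  levels01 <- (seq_len(n_trials) - 0.5) / n_trials
  u1 <- sample(levels01)
  pick_perm <- function(existing, n_cand = 400L) {
    best <- NULL; best_r <- Inf
    for (i in seq_len(n_cand)) {
      cand <- sample(levels01)
      r <- max(abs(vapply(existing, function(e) stats::cor(e, cand), numeric(1))))
      if (r < best_r) { best_r <- r; best <- cand }
    }
    best
  }
  u2 <- pick_perm(list(u1))
  u3 <- pick_perm(list(u1, u2))
  latents <- data.frame(
    trial = sprintf("synth%02d", seq_len(n_trials)),
    condition = conds,
    batch_id = paste0("batch", (seq_len(n_trials) - 1L) %/% 3L + 1L),
    attraction = attraction_range[[1]] + diff(attraction_range) * u1,
    wall_bias = wall_bias_range[[1]] + diff(wall_bias_range) * u2,
    activity = activity_range[[1]] + diff(activity_range) * u3,
    stringsAsFactors = FALSE
  )
  latents$attraction <- latents$attraction +
    ifelse(latents$condition == "OA", condition_effect_attraction, 0)
  latents$stillness_prob <- stillness_range[[1]] +
    diff(stillness_range) * latents$activity
  latents$speed_scale <- speed_scale_range[[1]] +
    diff(speed_scale_range) * latents$activity

  trial_seeds <- sample.int(2^31 - 2L, n_trials)
  trials <- lapply(seq_len(n_trials), function(i) {
    generate_school(
      n_fish = n_fish, duration_frames = duration_frames,
      frame_rate = frame_rate, arena = arena,
      attraction_strength = latents$attraction[[i]],
      wall_bias = latents$wall_bias[[i]],
      stillness_prob = latents$stillness_prob[[i]],
      speed_scale = latents$speed_scale[[i]],
      outward_tilt = outward_tilt,
      seed = trial_seeds[[i]],
      condition = latents$condition[[i]],
      batch_id = latents$batch_id[[i]],
      source_id = latents$trial[[i]]
    )$trial
  })

  radius <- dataset_neighbour_radius(trials)
  grid <- build_exploration_grid(arena)
  profiles <- do.call(rbind, lapply(trials, build_behavioural_profile,
                                    arena = arena,
                                    neighbour_radius_cm = radius,
                                    unit = unit, grid = grid))
  list(profiles = profiles, trials = trials, latents = latents,
       neighbour_radius_cm = radius)
}

#' Generate a heterogeneous social cohort for real-versus-null comparison
#'
#' Generates a cohort of schooling, wall-attracted trials with marked
#' between-trial *and* between-fish (individual) variation in the latent
#' behaviour parameters, for comparing against the interaction-free null
#' model. Every group is at least moderately social (attraction floor), so
#' cohesion suppresses arena coverage relative to independent wanderers,
#' while the wide individual spread (each fish's gains scaled by a factor
#' uniform on 0-2) gives the cohort the fish-to-fish variability that the
#' memoryless null model cannot produce.
#'
#' @param n_trials,n_fish,duration_frames,frame_rate,arena As in
#'   [generate_cohort_for_pca()].
#' @param seed Integer master seed.
#' @param attraction_base Range of the trial-level attraction gain;
#'   the floor keeps every group social.
#' @param wall_bias_max Upper end of the trial-level wall-following gain.
#' @param individual_spread Range of the per-fish multiplicative factor
#'   applied to each latent.
#' @return List: `profiles` (per-fish), `trials`, `latents` (trial-level),
#'   `neighbour_radius_cm`.
#' @export
generate_comparison_cohort <- function(n_trials = 26L, n_fish = 10L,
                                       duration_frames = 9000L,
                                       frame_rate = 25,
                                       arena = arena_geometry(), seed = 1L,
                                       attraction_base = c(0.08, 0.2),
                                       wall_bias_max = 0.15,
                                       individual_spread = c(0, 2)) {
  set.seed(seed)
  levels01 <- (seq_len(n_trials) - 0.5) / n_trials
  u1 <- sample(levels01); u2 <- sample(levels01); u3 <- sample(levels01)
  latents <- data.frame(
    trial = sprintf("cmp%02d", seq_len(n_trials)),
    attraction = attraction_base[[1]] + diff(attraction_base) * u1,
    wall_bias = wall_bias_max * u2,
    stillness_prob = 0.40 - 0.14 * u3,
    speed_scale = 0.14 + 0.02 * u3
  )
  seeds <- sample.int(2^31 - 2L, n_trials)
  trials <- lapply(seq_len(n_trials), function(i) {
    set.seed(seeds[[i]])
    jit <- function(m) m * stats::runif(n_fish, individual_spread[[1]],
                                        individual_spread[[2]])
    generate_school(
      n_fish = n_fish, duration_frames = duration_frames,
      frame_rate = frame_rate, arena = arena,
      attraction_strength = jit(latents$attraction[[i]]),
      wall_bias = jit(latents$wall_bias[[i]]),
      stillness_prob = pmin(jit(latents$stillness_prob[[i]]), 0.95),
      speed_scale = jit(latents$speed_scale[[i]]),
      batch_id = paste0("batch", (i - 1L) %/% 3L + 1L),
      source_id = latents$trial[[i]]
    )$trial
  })
  radius <- dataset_neighbour_radius(trials)
  grid <- build_exploration_grid(arena)
  profiles <- do.call(rbind, lapply(trials, build_behavioural_profile,
                                    arena = arena,
                                    neighbour_radius_cm = radius,
                                    grid = grid))
  list(profiles = profiles, trials = trials, latents = latents,
       neighbour_radius_cm = radius)
}
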