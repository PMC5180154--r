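# Wrap angles into (-pi, pi].
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Harvest empirical speed and angular-speed pools
#'
#' Pools per-frame speeds (cm/frame) and angular speeds (radians/frame,
#' wrapped heading differences) across all fish and trials, for use as the
#' empirical step distributions of the null model. Headings are computed as
#' `atan2` of successive displacements; steps with sub-pixel displacement
#' have no defined heading and contribute no angular speed.
#'
#' @param trials A cleaned [trial_recording()] or list of them, in cm.
#' @param min_heading_disp_cm Displacement below which a step's heading is
#'   considered undefined (default one pixel, 0.029 cm).
#' @return An object of class `movement_pools`: `speeds` (cm/frame,
#'   >= 0), `angular_speeds` (radians in `(-pi, pi]`), `provenance`.
#' @export
harvest_pools <- function(trials, min_heading_disp_cm = 0.029) {
  if (inherits(trials, "trial_recording")) trials <- list(trials)
  speeds <- list(); omegas <- list()
  for (tr in trials) {
    dx <- diff(tr$x); dy <- diff(tr$y)
    disp <- sqrt(dx^2 + dy^2)
    speeds[[length(speeds) + 1L]] <- disp[!is.na(disp)]
    heading <- atan2(dy, dx)
    heading[is.na(disp) | disp < min_heading_disp_cm] <- NA
    om <- wrap_angle(diff(heading))
    omegas[[length(omegas) + 1L]] <- om[!is.na(om)]
  }
  speeds <- unlist(speeds); omegas <- unlist(omegas)
  if (length(speeds) == 0L || length(omegas) == 0L) {
    stop("empty movement pool: no valid steps/turns in input trials")
  }
  structure(
    list(speeds = speeds, angular_speeds = omegas,
         provenance = vapply(trials, function(tr) tr$source_id, character(1))),
    class = "movement_pools"
  )
}

#' @export
print.movement_pools <- function(x, ...) {
  cat(sprintf("Empirical movement pools: %d speeds (median %.3g cm/frame), %d angular speeds (sd %.3g rad)\n",
              length(x$speeds), stats::median(x$speeds),
              length(x$angular_speeds), stats::sd(x$angular_speeds)))
  cat(sprintf("  harvested from: %s\n", paste(x$provenance, collapse = ", ")))
  invisible(x)
}

#' Reflect a point back into the arena
#'
#' Points beyond the wall are replaced by their radial mirror image about
#' the boundary circle: radius `r` becomes `2R - r` at the same polar
#' angle. Points inside (or exactly on) the boundary are returned
#' unchanged. The degenerate case `r > 2R`, which cannot mirror inside, is
#' clamped to the centre with a warning; it cannot occur when the largest
#' pooled step is shorter than the radius.
#'
#' @param x,y Coordinates (vectors allowed), cm.
#' @param arena An [arena_geometry()].
#' @return List with reflected `x` and `y`.
#' @export
reflect_into_arena <- function(x, y, arena = arena_geometry()) {
  R <- arena$radius_cm
  r <- sqrt(x^2 + y^2)
  out <- !is.na(r) & r > R
  if (any(out)) {
    too_far <- out & r > 2 * R
    if (any(too_far)) {
      warning(sum(too_far), " point(s) beyond twice the radius; clamped to centre")
    }
    fac <- pmax(2 * R - r[out], 0) / r[out]
    x[out] <- x[out] * fac
    y[out] <- y[out] * fac
  }
  list(x = x, y = y)
}

#' Advance one agent by one frame
#'
#' The position update is `x(t+1) = x(t) + v cos(theta + omega)`,
#' `y(t+1) = y(t) + v sin(theta + omega)`; the heading advances to
#' `theta + omega`. A new position outside the arena is reflected by
#' [reflect_into_arena()] (the heading is not altered by reflection).
#'
#' @param state List with `x`, `y`, `theta`.
#' @param v Speed draw, cm/frame.
#' @param omega Angular-speed draw, radians/frame.
#' @param arena An [arena_geometry()].
#' @param reflect_heading If `TRUE`, a boundary reflection also mirrors the
#'   heading about the local wall tangent (billiard bounce), so motion
#'   continues away from the wall; by default the heading is left unchanged
#'   (the next turning draw is independent anyway).
#' @return Updated state list.
#' @export
step_agent <- function(state, v, omega, arena = arena_geometry(),
                       reflect_heading = FALSE) {
  phi <- state$theta + omega
  xn <- state$x + v * cos(phi)
  yn <- state$y + v * sin(phi)
  out <- sqrt(xn^2 + yn^2) > arena$radius_cm
  p <- reflect_into_arena(xn, yn, arena)
  if (reflect_heading && any(out)) {
    wall_ang <- atan2(p$y[out], p$x[out])
    phi[out] <- 2 * wall_ang - phi[out] + pi
  }
  list(x = p$x, y = p$y, theta = phi)
}

#' Run the interaction-free null model
#'
#' Places independent agents in the arena and advances each by the step
#' update of [step_agent()], with speed and angular speed drawn uniformly
#' at random (with replacement) from the empirical pools, independently per
#' fish and frame. Initial positions are uniform in the disc, initial
#' headings uniform in `(-pi, pi]`. Each replicate runs on its own RNG
#' substream derived from `seed`, so output is fully reproducible.
#'
#' @param pools A [harvest_pools()] result (or any list with `speeds` and
#'   `angular_speeds`).
#' @param arena An [arena_geometry()].
#' @param n_fish Agents per replicate (reference setup: 10).
#' @param duration_frames Frames per replicate (reference setup: 90,000).
#' @param frame_rate Frames per second (25).
#' @param n_replicates Number of replicate trials (reference setup: 26).
#' @param seed Master seed (integer).
#' @param batch_size Replicates per pseudo-batch label, mirroring arenas
#'   recorded simultaneously.
#' @param reflect_heading Mirror the heading at boundary reflections (see
#'   [step_agent()]); off by default.
#' @return List of [trial_recording()] objects, condition `"simulated"`.
#' @export
run_null_model <- function(pools, arena = arena_geometry(),
                           n_fish = 10L, duration_frames = 90000L,
                           frame_rate = 25, n_replicates = 26L,
                           seed = 1L, batch_size = 3L,
                           reflect_heading = FALSE) {
  stopifnot(n_fish >= 1L, duration_frames >= 2L, n_replicates >= 1L)
  lapply(seq_len(n_replicates), function(rep_i) {
    set.seed(seed + rep_i)
    nfr <- duration_frames
    v <- matrix(sample(pools$speeds, (nfr - 1L) * n_fish, replace = TRUE),
                nfr - 1L, n_fish)
    om <- matrix(sample(pools$angular_speeds, (nfr - 1L) * n_fish, replace = TRUE),
                 nfr - 1L, n_fish)
    theta0 <- stats::runif(n_fish, -pi, pi)
    r0 <- arena$radius_cm * sqrt(stats::runif(n_fish))
    a0 <- stats::runif(n_fish, -pi, pi)

    X <- matrix(NA_real_, nfr, n_fish)
    Y <- matrix(NA_real_, nfr, n_fish)
    X[1L, ] <- r0 * cos(a0); Y[1L, ] <- r0 * sin(a0)
    Rr <- arena$radius_cm
    xc <- X[1L, ]; yc <- Y[1L, ]
    theta <- theta0
    for (t in seq_len(nfr - 1L)) {
      theta <- theta + om[t, ]
      xn <- xc + v[t, ] * cos(theta)
      yn <- yc + v[t, ] * sin(theta)
      r <- sqrt(xn^2 + yn^2)
      out <- r > Rr
      if (any(out)) {
        fac <- pmax(2 * Rr - r[out], 0) / r[out]
        xn[out] <- xn[out] * fac
        yn[out] <- yn[out] * fac
        if (reflect_heading) {
          theta[out] <- 2 * atan2(yn[out], xn[out]) - theta[out] + pi
        }
      }
      X[t + 1L, ] <- xn; Y[t + 1L, ] <- yn
      xc <- xn; yc <- yn
    }
    meta <- recording_meta(frame_rate = frame_rate, duration_frames = nfr,
                           condition = "simulated",
                           batch_id = paste0("simbatch", (rep_i - 1L) %/% batch_size + 1L))
    trial_recording(X, Y, meta = meta,
                    source_id = sprintf("sim%02d", rep_i), units = "cm")
  })
}

#' Compare real and simulated behavioural profiles
#'
#' For the five variables not directly encoded in the null model
#' (proportion of time near the edge, time to explore 10%, overall fraction
#' explored, mean local-neighbour proportion, median nearest-neighbour
#' distance), fits a linear model `value ~ arm` with the simulated arm as
#' reference, so the estimate is real minus simulated; and runs a
#' median-centred Levene test of variance homogeneity per variable.
#'
#' @param real_profiles,sim_profiles Profile data frames from
#'   [build_behavioural_profile()], computed with identical metric
#'   configuration.
#' @return Data frame, one row per variable: `variable`, `estimate`, `se`,
#'   `t`, `p`, `levene_F`, `levene_p`, `var_real`, `var_sim`.
#' @export
compare_real_vs_sim <- function(real_profiles, sim_profiles) {
  vars <- c("prop_near_edge", "time_to_explore_10pct", "pct_arena_explored",
            "mean_local_neighbour_prop", "median_nn_distance")
  missing_cols <- setdiff(vars, intersect(names(real_profiles), names(sim_profiles)))
  if (length(missing_cols) > 0L) {
    stop("profile sets lack shared columns: ", paste(missing_cols, collapse = ", "),
         " (were both computed with the same metric config?)")
  }
  out <- lapply(vars, function(v) {
    df <- data.frame(
      value = c(real_profiles[[v]], sim_profiles[[v]]),
      arm = factor(rep(c("real", "simulated"),
                       c(nrow(real_profiles), nrow(sim_profiles))),
                   levels = c("simulated", "real"))
    )
    df <- df[!is.na(df$value), ]
    if (length(unique(df$arm)) < 2L || any(table(df$arm) < 2L)) {
      warning("variable '", v, "' has fewer than 2 non-missing values in an arm; reported as NA")
      return(data.frame(variable = v, estimate = NA_real_, se = NA_real_,
                        t = NA_real_, p = NA_real_, levene_F = NA_real_,
                        levene_p = NA_real_, var_real = NA_real_,
                        var_sim = NA_real_, stringsAsFactors = FALSE))
    }
    fit <- stats::lm(value ~ arm, data = df)
    cf <- summary(fit)$coefficients["armreal", ]
    lev <- levene_variance_test(df$value[df$arm == "real"],
                                df$value[df$arm == "simulated"])
    data.frame(variable = v,
               estimate = cf[["Estimate"]], se = cf[["Std. Error"]],
               t = cf[["t value"]], p = cf[["Pr(>|t|)"]],
               levene_F = lev$statistic, levene_p = lev$p.value,
               var_real = stats::var(df$value[df$arm == "real"]),
               var_sim = stats::var(df$value[df$arm == "simulated"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
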