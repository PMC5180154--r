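arena <- arena_geometry()

test_that("median speed matches direct computation and handles edge cases", {
  # constant 5 cm/s: 0.2 cm per frame at 25 Hz
  n <- 50
  tr <- trial_recording(matrix(seq(0, by = 0.2, length.out = n)), matrix(0, n, 1),
                        units = "cm")
  expect_equal(unname(median_speed(tr)), 5)

  # alternating 0 and 10 cm/s over an even number of steps -> median 5
  x <- cumsum(c(0, rep(c(0, 0.4), 20)))
  tra <- trial_recording(matrix(x - 5), matrix(0, length(x), 1), units = "cm")
  expect_equal(unname(median_speed(tra)), 5)

  trial <- make_random_trial(n_fish = 3, n_frames = 100, seed = 13,
                             missing_rate = 0.1)
  expect_equal(unname(median_speed(trial)), bf_median_speed(trial))

  gone <- trial
  gone$x[, 2] <- NA
  expect_warning(ms <- median_speed(gone), "no valid speeds")
  expect_true(is.na(ms[[2]]))
})

test_that("stillness proportion uses the one-pixel displacement rule", {
  n <- 40
  still <- trial_recording(matrix(1, n, 1), matrix(-2, n, 1), units = "cm")
  expect_equal(unname(proportion_still(still)), 1.0)
  fast <- trial_recording(matrix(seq(0, by = 0.4, length.out = n)),
                          matrix(0, n, 1), units = "cm")
  expect_equal(unname(proportion_still(fast)), 0.0)

  # the per-second restatement of the pixel threshold rounds to 0.7 cm/s
  thr <- stillness_threshold(arena, frame_rate = 25)
  expect_equal(thr$cm_per_frame, 0.029)
  expect_equal(round(thr$cm_per_s, 1), 0.7)

  trial <- make_random_trial(n_fish = 3, n_frames = 100, seed = 17)
  expect_equal(unname(proportion_still(trial, 0.5)), bf_prop_still(trial, 0.5))
})

test_that("edge-zone occupancy matches geometry", {
  n <- 30
  centre <- trial_recording(matrix(0, n, 1), matrix(0, n, 1), units = "cm")
  expect_equal(unname(proportion_near_edge(centre, arena)), 0.0)
  rim <- trial_recording(matrix(13.5, n, 1), matrix(0, n, 1), units = "cm")
  expect_equal(unname(proportion_near_edge(rim, arena)), 1.0)

  # uniform points in the disc: P(edge) = 1 - (11.5/14.5)^2 ~ 0.371
  trial <- make_random_trial(n_fish = 1, n_frames = 100000, seed = 19)
  expect_lt(abs(unname(proportion_near_edge(trial, arena)) -
                (1 - (11.5 / 14.5)^2)), 0.01)

  trial2 <- make_random_trial(n_fish = 3, n_frames = 100, seed = 23)
  expect_equal(unname(proportion_near_edge(trial2, arena)),
               unname(bf_prop_edge(trial2)))
})

test_that("exploration grid matches a fine rasterization and known cases", {
  grid <- build_exploration_grid(arena)
  # cell containing the centre is included
  expect_true(any(grid$ix == 0 & grid$iy == 0))
  expect_true(any(grid$ix == -1 & grid$iy == -1))

  # R = 1 with corner-aligned 1 cm cells: exactly the 4 cells around origin
  tiny <- arena_geometry(radius_cm = 1, edge_zone_width_cm = 0.5)
  expect_equal(build_exploration_grid(tiny)$n_cells, 4)

  expect_equal(grid$n_cells, bf_grid_cells(14.5))
  # centre-in-disc convention is smaller
  cgrid <- build_exploration_grid(
    arena_geometry(grid_convention = "centre_in_disc"))
  expect_lt(cgrid$n_cells, grid$n_cells)
})

test_that("exploration statistics track first visits", {
  grid <- build_exploration_grid(arena)
  n <- 100
  frozen <- trial_recording(matrix(3.2, n, 1), matrix(-1.7, n, 1), units = "cm")
  es <- exploration_stats(frozen, grid)
  expect_equal(es$pct_explored, 1 / grid$n_cells)
  expect_true(is.na(es$time_to_explore_s))

  # boustrophedon visit of every cell centre covers the whole grid
  ord <- order(grid$iy, ifelse(grid$iy %% 2 == 0, grid$ix, -grid$ix))
  sweep_tr <- trial_recording(matrix(grid$ix[ord] + 0.5),
                              matrix(grid$iy[ord] + 0.5), units = "cm")
  es2 <- exploration_stats(sweep_tr, grid)
  expect_equal(es2$pct_explored, 1.0)
  expect_false(is.na(es2$time_to_explore_s))

  # oracle equivalence incl. latency, and monotone coverage
  trial <- make_random_trial(n_fish = 2, n_frames = 400, seed = 29)
  es3 <- exploration_stats(trial, grid)
  bf <- bf_exploration(trial, grid)
  expect_equal(es3$pct_explored, bf$pct)
  expect_equal(es3$time_to_explore_s, bf$time)
})

test_that("pairwise and nearest-neighbour distances match the O(n^2) oracle", {
  n <- 20
  two <- trial_recording(cbind(rep(0, n), rep(5, n)), cbind(rep(0, n), rep(0, n)),
                         units = "cm")
  ctx <- pairwise_distance_stats(two)
  expect_equal(ctx$median_interfish_cm, 5)
  expect_true(all(ctx$nn_dist == 5))

  trial <- make_random_trial(n_fish = 3, n_frames = 100, seed = 31,
                             missing_rate = 0.15)
  ctx2 <- pairwise_distance_stats(trial)
  bf <- bf_pairwise(trial)
  expect_equal(ctx2$nn_dist, bf$nn, ignore_attr = TRUE)
  expect_equal(ctx2$median_interfish_cm, bf$med)
  # per frame, min pairwise <= median pairwise
  mins <- suppressWarnings(apply(ctx2$pair_dist, 1, min, na.rm = TRUE))
  meds <- apply(ctx2$pair_dist, 1, median, na.rm = TRUE)
  ok <- is.finite(mins)
  expect_true(all(mins[ok] <= meds[ok] + 1e-12))

  expect_error(pairwise_distance_stats(
    trial_recording(matrix(0, 5, 1), matrix(0, 5, 1), units = "cm")),
    "at least 2 fish")
})

test_that("the pooled neighbour radius is the median of all pairwise distances", {
  n <- 10
  two <- trial_recording(cbind(rep(0, n), rep(5, n)), cbind(rep(0, n), rep(0, n)),
                         units = "cm")
  expect_equal(dataset_neighbour_radius(list(two)), 5)

  trials <- lapply(1:3, function(i)
    make_random_trial(n_fish = 3, n_frames = 50, seed = 40 + i,
                      missing_rate = 0.1))
  pooled <- unlist(lapply(trials, function(tr) bf_pairwise(tr)$all))
  expect_equal(dataset_neighbour_radius(trials), median(sort(pooled)))
})

test_that("local-neighbour proportion counts conspecifics within the radius", {
  n <- 15
  coincident <- trial_recording(matrix(1.3, n, 4), matrix(0.2, n, 4), units = "cm")
  expect_equal(unname(mean_local_neighbour_prop(coincident, 6.9)), rep(1, 4))

  spread <- trial_recording(
    cbind(rep(-12, n), rep(12, n), rep(0, n)),
    cbind(rep(0, n), rep(0, n), rep(12, n)), units = "cm")
  expect_equal(unname(mean_local_neighbour_prop(spread, 6.9)), rep(0, 3))

  trial <- make_random_trial(n_fish = 3, n_frames = 100, seed = 37,
                             missing_rate = 0.1)
  expect_equal(unname(mean_local_neighbour_prop(trial, 6.9)),
               bf_local_prop(trial, 6.9), tolerance = 1e-12)
})

test_that("profiles are complete, permutation-invariant and rotation-invariant", {
  g <- generate_school(n_fish = 4, duration_frames = 1500, seed = 43)
  prof <- build_behavioural_profile(g$trial, arena, neighbour_radius_cm = 6.9)
  expect_equal(nrow(prof), 4)
  expect_true(all(behaviour_variables() %in% names(prof)))

  # relabelling fish permutes rows, nothing else
  perm <- c(3, 1, 4, 2)
  tp <- g$trial
  tp$x <- tp$x[, perm]; tp$y <- tp$y[, perm]
  colnames(tp$x) <- colnames(tp$y) <- paste0("fish", 1:4)
  prof_p <- build_behavioural_profile(tp, arena, neighbour_radius_cm = 6.9)
  for (v in behaviour_variables()) {
    expect_equal(prof_p[[v]], prof[[v]][perm], tolerance = 1e-12)
  }

  # global rotation about the arena centre changes nothing
  a <- 0.83
  tr <- g$trial
  xr <- tr$x * cos(a) - tr$y * sin(a)
  yr <- tr$x * sin(a) + tr$y * cos(a)
  tr$x <- xr; tr$y <- yr
  prof_r <- build_behavioural_profile(tr, arena, neighbour_radius_cm = 6.9)
  for (v in setdiff(behaviour_variables(),
                    c("time_to_explore_10pct", "pct_arena_explored"))) {
    expect_equal(prof_r[[v]], prof[[v]], tolerance = 1e-9)
  }
  # grid-based coverage is only approximately rotation-invariant (the grid
  # itself is square): allow a small tolerance
  expect_equal(prof_r$pct_arena_explored, prof$pct_arena_explored,
               tolerance = 0.1)

  # an all-stationary trial: everything still, one cell each
  n <- 60
  frozen <- trial_recording(matrix(rep(c(1, 4, -3), each = n), n, 3),
                            matrix(rep(c(2, -1, 0), each = n), n, 3),
                            units = "cm")
  pf <- build_behavioural_profile(frozen, arena, neighbour_radius_cm = 6.9)
  expect_equal(pf$prop_still, rep(1, 3))
  grid <- build_exploration_grid(arena)
  expect_equal(pf$pct_arena_explored, rep(1 / grid$n_cells, 3))

  # trial-level aggregation gives a single row
  pt <- build_behavioural_profile(g$trial, arena, neighbour_radius_cm = 6.9,
                                  unit = "trial")
  expect_equal(nrow(pt), 1)
})
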