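arena <- arena_geometry()

test_that("generated schools are reproducible and stay inside the arena", {
  a <- generate_school(n_fish = 4, duration_frames = 500, seed = 5)
  b <- generate_school(n_fish = 4, duration_frames = 500, seed = 5)
  expect_identical(a$trial$x, b$trial$x)
  r <- sqrt(a$trial$x^2 + a$trial$y^2)
  expect_true(all(r <= arena$radius_cm + 1e-9))
  expect_equal(a$latents$attraction_strength, rep(0.03, 4))
})

test_that("without social or wall terms the school matches its own null model", {
  # matched pools drawn from the school's generative step distributions:
  # an asocial school and the null model then share identical per-frame
  # kinematics and the same reflection rule, so no variable should differ.
  # (Pools harvested from realized trajectories inherit boundary-reflection
  # turns and are not exactly generative; see the methods vignette.)
  g <- generate_school(n_fish = 6, duration_frames = 6000,
                       attraction_strength = 0, wall_bias = 0,
                       stillness_prob = 0.3, speed_scale = 0.15, seed = 61)
  set.seed(63)
  n_pool <- 50000
  pools <- list(
    speeds = ifelse(runif(n_pool) < 0.3, 0, rexp(n_pool, 1 / 0.15)),
    angular_speeds = rnorm(n_pool, 0, 0.4))
  sims <- run_null_model(pools, arena, n_fish = 6, duration_frames = 6000,
                         n_replicates = 4, seed = 62)
  real_prof <- build_behavioural_profile(g$trial, arena,
                                         neighbour_radius_cm = 6.9)
  sim_prof <- do.call(rbind, lapply(sims, build_behavioural_profile,
                                    arena = arena, neighbour_radius_cm = 6.9))
  cmp <- compare_real_vs_sim(real_prof, sim_prof)
  # five simultaneous true-null tests: control the family-wise error rate
  expect_true(all(p.adjust(cmp$p, "holm") > 0.05, na.rm = TRUE))
  expect_true(all(p.adjust(cmp$levene_p, "holm") > 0.05, na.rm = TRUE))
})

test_that("attraction monotonically tightens the school", {
  levels <- c(0, 0.02, 0.05, 0.1, 0.2)
  med_nn <- vapply(levels, function(att) {
    g <- generate_school(n_fish = 8, duration_frames = 3000,
                         attraction_strength = att, wall_bias = 0, seed = 71)
    ctx <- pairwise_distance_stats(g$trial)
    median(ctx$nn_dist, na.rm = TRUE)
  }, numeric(1))
  rho <- suppressWarnings(
    cor(seq_along(levels), med_nn, method = "spearman"))
  expect_lt(rho, -0.9)
})

test_that("strong wall bias forces thigmotaxis", {
  g <- generate_school(n_fish = 6, duration_frames = 3000,
                       attraction_strength = 0, wall_bias = 0.3, seed = 73)
  edge <- proportion_near_edge(g$trial, arena, per_fish = FALSE)
  expect_gt(edge, 0.8)
})

test_that("artifact injection is exact: identity at zero rates, ledgered otherwise", {
  g <- generate_school(n_fish = 4, duration_frames = 1000, seed = 81)
  clean <- inject_tracking_artifacts(g$trial, gap_rate = 0, spike_rate = 0,
                                     swap_rate = 0, seed = 82)
  expect_identical(clean$trial$x, g$trial$x)
  expect_identical(clean$trial$y, g$trial$y)
  expect_equal(nrow(clean$ledger$gaps) + nrow(clean$ledger$spikes) +
                 nrow(clean$ledger$swaps), 0)

  spiked <- inject_tracking_artifacts(g$trial, gap_rate = 0, spike_rate = 5e-3,
                                      seed = 83)
  expect_gt(nrow(spiked$ledger$spikes), 0)
  expect_true(all(spiked$ledger$spikes$radius > arena$radius_cm))
  expect_true(all(spiked$ledger$spikes$radius <= 1.2 * arena$radius_cm))
  del <- delete_out_of_arena(spiked$trial, arena)
  expect_equal(del$n_deleted, nrow(spiked$ledger$spikes))

  gapped <- inject_tracking_artifacts(g$trial, gap_rate = 3e-3, spike_rate = 0,
                                      seed = 84)
  expect_equal(sum(is.na(gapped$trial$x)), sum(gapped$ledger$gaps$length))
})

test_that("preprocessing recovers ledgered gaps on smooth tracks", {
  # a slow, steadily swimming asocial school: per-frame speed jitter is the
  # main obstacle to polynomial gap recovery, so slow means smooth here
  g <- generate_school(n_fish = 3, duration_frames = 4000,
                       attraction_strength = 0, wall_bias = 0,
                       stillness_prob = 0, speed_scale = 0.05,
                       turn_sd = 0.05, seed = 91)$trial
  inj <- inject_tracking_artifacts(g, gap_rate = 0.0015, spike_rate = 0,
                                   seed = 92)
  res <- interpolate_gaps(inj$trial, arena)
  eligible <- 0L
  err <- c()
  for (f in seq_len(3)) {
    scan <- bf_eligible_gaps(inj$trial$x[, f])
    for (i in which(scan$ok == 1)) {
      idx <- scan$start[i]:(scan$start[i] + scan$len[i] - 1)
      eligible <- eligible + scan$len[i]
      err <- c(err, sqrt((res$trial$x[idx, f] - g$x[idx, f])^2 +
                         (res$trial$y[idx, f] - g$y[idx, f])^2))
    }
  }
  expect_gt(eligible, 50)
  expect_equal(res$n_interpolated, eligible)   # every eligible frame refilled
  expect_lt(mean(err), 0.1)                    # under a third of a pixel
})

test_that("cohort generation plants near-orthogonal latents with the 9+9+8 design", {
  coh <- generate_cohort_for_pca(n_trials = 26, n_fish = 3,
                                 duration_frames = 300, seed = 3)
  expect_equal(unname(table(coh$latents$condition)[c("ambient", "OA", "ambient_in_OA")]),
               c(9L, 9L, 8L), ignore_attr = TRUE)
  expect_equal(nrow(coh$profiles), 26 * 3)
  lat <- coh$latents[, c("attraction", "wall_bias", "activity")]
  cc <- cor(lat)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.1)
  expect_equal(length(unique(coh$latents$batch_id)), 9)

  # planting a condition effect shifts only the OA trials
  coh2 <- generate_cohort_for_pca(n_trials = 26, n_fish = 3,
                                  duration_frames = 300, seed = 3,
                                  condition_effect_attraction = 0.1)
  d <- coh2$latents$attraction - coh$latents$attraction
  expect_true(all(abs(d[coh$latents$condition == "OA"] - 0.1) < 1e-12))
  expect_true(all(abs(d[coh$latents$condition != "OA"]) < 1e-12))
})

test_that("doubling trial duration shrinks metric noise like 1/sqrt(2)", {
  est <- function(dur, seed) {
    g <- generate_school(n_fish = 3, duration_frames = dur,
                         attraction_strength = 0, wall_bias = 0,
                         stillness_prob = 0, speed_scale = 0.15, seed = seed)
    mean(instantaneous_speeds(g$trial)$speed, na.rm = TRUE)
  }
  sd1 <- sd(vapply(1:60, function(s) est(1000, s), numeric(1)))
  sd2 <- sd(vapply(1:60, function(s) est(2000, s + 500), numeric(1)))
  expect_equal(sd2 / sd1, 1 / sqrt(2), tolerance = 0.2)
})

test_that("the full pipeline detects a planted condition effect on sociability", {
  # 26 trials at 4000 frames, OA trials get +0.2 attraction; the trial is
  # the unit of analysis (fish within a trial share latents)
  detect <- function(seed) {
    coh <- generate_cohort_for_pca(seed = seed, duration_frames = 4000,
                                   condition_effect_attraction = 0.2,
                                   unit = "trial")
    z <- zscore_profiles(coh$profiles, trial_duration_s = 160)
    pc <- pca_varimax(z, 3)
    soc <- which.max(abs(pc$loadings["mean_local_neighbour_prop", ]))
    suppressWarnings(fit <- fit_condition_lmm(pc$scores,
                                              coh$profiles$condition,
                                              coh$profiles$batch_id))
    tab <- fit$table
    tab$p[tab$response == paste0("PC", soc) & tab$term == "conditionOA"] < 0.05
  }
  hits <- sum(vapply(1:10, detect, logical(1)))
  expect_gte(hits, 8)   # power > 0.8 at this effect size and design
})

test_that("with no condition effect the pipeline's condition contrasts are calibrated", {
  ps <- c()
  for (s in 1:30) {
    coh <- generate_cohort_for_pca(seed = s, duration_frames = 1500,
                                   unit = "trial")
    z <- zscore_profiles(coh$profiles, trial_duration_s = 60)
    pc <- pca_varimax(z, 3)
    suppressWarnings(fit <- fit_condition_lmm(pc$scores,
                                              coh$profiles$condition,
                                              coh$profiles$batch_id))
    tab <- fit$table
    # one p per cohort (PC1, OA contrast) so draws are independent
    ps <- c(ps, tab$p[tab$response == "PC1" & tab$term == "conditionOA"])
  }
  hits <- sum(ps < 0.05)
  ci <- qbinom(c(0.005, 0.995), length(ps), 0.05)  # 99% binomial band
  expect_gte(hits, ci[[1]])
  expect_lte(hits, ci[[2]])
})
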