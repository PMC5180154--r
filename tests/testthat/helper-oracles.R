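# Brute-force oracles, deliberately naive (scalar loops, direct formulas),
# independent of the vectorized implementations they check.

# random trial with optional missingness, all points inside the arena
make_random_trial <- function(n_fish = 3, n_frames = 100, seed = 1,
                              missing_rate = 0, radius = 14.5) {
  set.seed(seed)
  X <- matrix(NA_real_, n_frames, n_fish)
  Y <- matrix(NA_real_, n_frames, n_fish)
  for (f in seq_len(n_fish)) {
    r <- radius * sqrt(runif(n_frames))
    a <- runif(n_frames, -pi, pi)
    X[, f] <- r * cos(a); Y[, f] <- r * sin(a)
  }
  if (missing_rate > 0) {
    drop <- matrix(runif(n_frames * n_fish) < missing_rate, n_frames, n_fish)
    X[drop] <- NA; Y[drop] <- NA
  }
  trial_recording(X, Y,
                  meta = recording_meta(duration_frames = n_frames),
                  source_id = "oracle", units = "cm")
}

# smooth (slow, continuous) trial so interpolation is meaningful
make_smooth_trial <- function(n_fish = 3, n_frames = 2000, seed = 1,
                              radius = 14.5) {
  g <- generate_school(n_fish = n_fish, duration_frames = n_frames,
                       attraction_strength = 0, wall_bias = 0,
                       stillness_prob = 0.1, speed_scale = 0.15,
                       turn_sd = 0.3, seed = seed)
  g$trial
}

bf_speeds <- function(trial, frame_rate = 25) {
  n <- nrow(trial$x); nf <- ncol(trial$x)
  out <- matrix(NA_real_, n - 1, nf)
  for (f in seq_len(nf)) {
    for (t in 2:n) {
      x1 <- trial$x[t - 1, f]; x2 <- trial$x[t, f]
      y1 <- trial$y[t - 1, f]; y2 <- trial$y[t, f]
      if (!is.na(x1) && !is.na(x2)) {
        out[t - 1, f] <- sqrt((x2 - x1)^2 + (y2 - y1)^2) * frame_rate
      }
    }
  }
  out
}

bf_median_speed <- function(trial, frame_rate = 25) {
  sp <- bf_speeds(trial, frame_rate)
  apply(sp, 2, function(v) median(sort(v[!is.na(v)])))
}

bf_prop_still <- function(trial, thr = 0.029) {
  sp <- bf_speeds(trial, frame_rate = 1)  # displacement per frame
  apply(sp, 2, function(v) mean(v[!is.na(v)] < thr))
}

bf_prop_edge <- function(trial, radius = 14.5, zone = 3) {
  apply(sqrt(trial$x^2 + trial$y^2), 2,
        function(r) mean(r[!is.na(r)] > radius - zone))
}

bf_pairwise <- function(trial) {
  nf <- ncol(trial$x); n <- nrow(trial$x)
  nn <- matrix(NA_real_, n, nf)
  all_d <- c()
  for (t in seq_len(n)) {
    for (i in seq_len(nf)) {
      best <- NA_real_
      for (j in seq_len(nf)) {
        if (i == j) next
        d <- sqrt((trial$x[t, i] - trial$x[t, j])^2 +
                  (trial$y[t, i] - trial$y[t, j])^2)
        if (!is.na(d)) {
          if (j > i) all_d <- c(all_d, d)
          if (is.na(best) || d < best) best <- d
        }
      }
      nn[t, i] <- best
    }
  }
  list(nn = nn, all = all_d, med = median(all_d))
}

bf_local_prop <- function(trial, radius_cm) {
  nf <- ncol(trial$x); n <- nrow(trial$x)
  out <- numeric(nf)
  for (i in seq_len(nf)) {
    props <- c()
    for (t in seq_len(n)) {
      if (is.na(trial$x[t, i])) next
      cnt <- 0
      for (j in seq_len(nf)) {
        if (i == j) next
        d <- sqrt((trial$x[t, i] - trial$x[t, j])^2 +
                  (trial$y[t, i] - trial$y[t, j])^2)
        if (!is.na(d) && d < radius_cm) cnt <- cnt + 1
      }
      props <- c(props, cnt / (nf - 1))
    }
    out[i] <- mean(props)
  }
  out
}

bf_exploration <- function(trial, grid, frame_rate = 25, threshold = 0.10) {
  target <- ceiling(threshold * grid$n_cells)
  nf <- ncol(trial$x)
  res <- data.frame(time = rep(NA_real_, nf), pct = NA_real_)
  cells <- paste(grid$ix, grid$iy)
  for (f in seq_len(nf)) {
    seen <- character(0)
    t10 <- NA_real_
    for (t in seq_len(nrow(trial$x))) {
      if (is.na(trial$x[t, f])) next
      key <- paste(floor(trial$x[t, f] / grid$cell_size),
                   floor(trial$y[t, f] / grid$cell_size))
      if (!(key %in% cells)) next
      if (!(key %in% seen)) seen <- c(seen, key)
      if (is.na(t10) && length(seen) >= target) t10 <- t / frame_rate
    }
    res$time[f] <- t10
    res$pct[f] <- length(seen) / grid$n_cells
  }
  res
}

# brute-force count of grid cells whose square meets the disc, by sampling
bf_grid_cells <- function(radius, cell = 1, step = 0.01) {
  m <- ceiling(radius / cell)
  cnt <- 0
  for (ix in seq(-m, m - 1)) {
    for (iy in seq(-m, m - 1)) {
      xs <- seq(ix * cell, (ix + 1) * cell, by = step)
      ys <- seq(iy * cell, (iy + 1) * cell, by = step)
      gr <- expand.grid(x = xs, y = ys)
      if (any(gr$x^2 + gr$y^2 < radius^2)) cnt <- cnt + 1
    }
  }
  cnt
}

# varimax objective: variance of squared loadings, summed over columns
varimax_criterion <- function(L) {
  sum(apply(L^2, 2, function(col) mean((col - mean(col))^2)))
}

# eligible-gap scanner, independent of interpolate_gaps
bf_eligible_gaps <- function(xv, max_gap = 25, context = 5) {
  miss <- is.na(xv)
  n <- length(xv)
  res <- list()
  t <- 1
  while (t <= n) {
    if (miss[t]) {
      s <- t
      while (t <= n && miss[t]) t <- t + 1
      len <- t - s
      ok <- len < max_gap && s - context >= 1 && (s + len - 1) + context <= n &&
        !any(miss[(s - context):(s - 1)]) &&
        !any(miss[(s + len):(s + len + context - 1)])
      res[[length(res) + 1]] <- c(start = s, len = len, ok = as.integer(ok))
    } else t <- t + 1
  }
  if (length(res) == 0) return(data.frame(start = integer(0), len = integer(0), ok = integer(0)))
  as.data.frame(do.call(rbind, res))
}
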