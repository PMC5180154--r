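#' Z-score the behavioural variables
#'
#' Standardizes the seven behavioural variables of a profile table to mean
#' 0, sd 1. Fish that never reached the 10%-exploration milestone have a
#' missing `time_to_explore_10pct`; these are imputed as the full trial
#' duration (a conservative censoring) before standardization, and the
#' number of imputed values is recorded in the `"n_imputed_latency"`
#' attribute.
#'
#' @param profiles Profile data frame (rows = analysis units) containing
#'   the columns of [behaviour_variables()].
#' @param trial_duration_s Trial duration in seconds, used to impute
#'   missing exploration latencies. Required if any are missing.
#' @return Numeric matrix (units x 7) with attributes `scaled:center`,
#'   `scaled:scale` and `n_imputed_latency`.
#' @export
zscore_profiles <- function(profiles, trial_duration_s = NULL) {
  vars <- behaviour_variables()
  missing_cols <- setdiff(vars, names(profiles))
  if (length(missing_cols) > 0L) {
    stop("profiles lack variables: ", paste(missing_cols, collapse = ", "))
  }
  m <- as.matrix(profiles[, vars])
  if (nrow(m) < 2L) stop("need at least 2 analysis units to standardize")
  n_imp <- 0L
  lat_na <- is.na(m[, "time_to_explore_10pct"])
  if (any(lat_na)) {
    if (is.null(trial_duration_s)) {
      stop("missing exploration latencies present: supply trial_duration_s to impute them")
    }
    m[lat_na, "time_to_explore_10pct"] <- trial_duration_s
    n_imp <- sum(lat_na)
  }
  if (anyNA(m)) stop("profiles contain missing values outside time_to_explore_10pct")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance variable(s): ", paste(vars[sds == 0], collapse = ", "))
  }
  z <- scale(m)
  attr(z, "n_imputed_latency") <- n_imp
  z
}

#' Varimax-rotated principal components
#'
#' Eigendecomposes the correlation matrix of a standardized variable
#' matrix, retains the top `k` components, and rotates their loadings with
#' Kaiser-normalized varimax. Each rotated component is flipped so its
#' largest-magnitude loading is positive, and components are ordered by
#' decreasing explained variance. Scores are computed by the regression
#' method from the rotated loadings.
#'
#' @param z Standardized matrix from [zscore_profiles()] (columns mean 0,
#'   sd 1).
#' @param k Number of components to retain (default 3).
#' @param eps Varimax convergence tolerance.
#' @return Object of class `pca_varimax`: `loadings` (p x k, rotated),
#'   `unrotated` (p x k), `rotmat` (k x k orthogonal), `scores` (n x k),
#'   `eigenvalues`, `variance_explained`, `cumulative_variance`,
#'   `communalities`, `score_cor` (correlation matrix of the rotated
#'   scores, reported rather than assumed diagonal).
#' @export
pca_varimax <- function(z, k = 3L, eps = 1e-8) {
  z <- as.matrix(z)
  p <- ncol(z)
  if (k > p) stop("k cannot exceed the number of variables")
  C <- stats::cor(z)
  eig <- eigen(C, symmetric = TRUE)
  if (sum(eig$values > 1e-10) < k) stop("k exceeds the rank of the correlation matrix")
  L <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(k)]), k)
  rownames(L) <- colnames(z)

  if (k > 1L) {
    vm <- stats::varimax(L, normalize = TRUE, eps = eps)
    rot <- L %*% vm$rotmat
    rotmat <- vm$rotmat
  } else {
    rot <- L
    rotmat <- diag(1)
  }
  # sign convention: largest |loading| of each component positive
  flip <- vapply(seq_len(k), function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, numeric(1))
  rot <- sweep(rot, 2L, flip, `*`)
  rotmat <- sweep(rotmat, 2L, flip, `*`)
  # order by explained variance after rotation
  ve <- colSums(rot^2) / p
  ord <- order(ve, decreasing = TRUE)
  rot <- rot[, ord, drop = FALSE]
  rotmat <- rotmat[, ord, drop = FALSE]
  ve <- ve[ord]
  colnames(rot) <- paste0("PC", seq_len(k))

  scores <- z %*% solve(C, rot)   # regression-method factor scores
  colnames(scores) <- colnames(rot)

  structure(
    list(
      loadings = rot,
      unrotated = L,
      rotmat = rotmat,
      scores = scores,
      eigenvalues = eig$values,
      variance_explained = ve,
      cumulative_variance = cumsum(ve),
      communalities = rowSums(rot^2),
      score_cor = stats::cor(scores),
      k = k
    ),
    class = "pca_varimax"
  )
}

#' @export
print.pca_varimax <- function(x, digits = 3, ...) {
  cat(sprintf("Varimax-rotated PCA: %d components, %.1f%% of variance\n",
              x$k, 100 * x$cumulative_variance[[x$k]]))
  cat("\nRotated loadings:\n")
  print(round(x$loadings, digits))
  cat("\nVariance explained: ",
      paste(sprintf("%s %.1f%%", colnames(x$loadings), 100 * x$variance_explained),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Linear mixed models of component scores by condition
#'
#' Fits, per retained component, a linear mixed model with condition as a
#' categorical fixed effect and a random intercept for batch (experiment
#' number), to control for arenas recorded simultaneously:
#' `score ~ condition + (1 | batch)`. p-values use the Satterthwaite
#' approximation. Singular fits are reported with a warning, never an
#' error.
#'
#' @param scores Matrix or data frame of component scores (units x
#'   components), e.g. `pca_varimax(...)$scores`.
#' @param condition Factor or character of condition labels per unit; the
#'   reference level is `reference` when present, else the first level.
#' @param batch Factor or character of batch labels per unit.
#' @param reference Reference condition level (default `"ambient"`).
#' @return Object of class `condition_lmm`: `table` (one row per component
#'   x term: estimate, se, df, t, p), `ranef_sd` (batch and residual sd per
#'   component), `fits` (the underlying model objects).
#' @export
fit_condition_lmm <- function(scores, condition, batch, reference = "ambient") {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  condition <- factor(condition)
  if (nlevels(condition) < 2L) stop("need at least 2 conditions")
  if (reference %in% levels(condition)) {
    condition <- stats::relevel(condition, ref = reference)
  }
  batch <- factor(batch)
  if (nlevels(batch) < 2L) stop("need at least 2 batches for a batch random effect")

  rows <- list(); ranefs <- list(); fits <- list()
  for (pc in colnames(scores)) {
    df <- data.frame(score = scores[, pc], condition = condition, batch = batch)
    quiet_lmer <- function(expr) {
      withCallingHandlers(expr,
                          message = function(m) invokeRestart("muffleMessage"))
    }
    if (stats::var(df$score) == 0) {
      warning("response ", pc, " has zero variance; fitting ordinary ",
              "regression (all effects are exactly zero)")
      fit <- stats::lm(score ~ condition, data = df)
    } else fit <- tryCatch(
      quiet_lmer(lmerTest::lmer(score ~ condition + (1 | batch), data = df)),
      error = function(e) tryCatch({
        # Satterthwaite machinery can fail on degenerate responses; fall
        # back to the plain mixed fit with a normal approximation
        warning("Satterthwaite approximation unavailable for ", pc,
                " (", conditionMessage(e), "); using normal approximation")
        quiet_lmer(lme4::lmer(score ~ condition + (1 | batch), data = df))
      }, error = function(e2) {
        warning("mixed model failed for ", pc, " (", conditionMessage(e2),
                "); falling back to ordinary regression")
        stats::lm(score ~ condition, data = df)
      })
    )
    is_mer <- inherits(fit, "merMod")
    if (is_mer && lme4::isSingular(fit, tol = 1e-4)) {
      warning("singular batch random effect for ", pc,
              " (batch variance estimated at/near zero)")
    }
    cf <- stats::coef(summary(fit))
    if (inherits(fit, "lmerModLmerTest")) {
      dfs <- cf[, "df"]; ps <- cf[, "Pr(>|t|)"]
    } else if (is_mer) {
      dfs <- rep(NA_real_, nrow(cf))
      ps <- 2 * stats::pnorm(-abs(cf[, "t value"]))
    } else {
      dfs <- rep(stats::df.residual(fit), nrow(cf))
      ps <- cf[, "Pr(>|t|)"]
    }
    rows[[pc]] <- data.frame(
      response = pc,
      term = rownames(cf),
      estimate = cf[, "Estimate"],
      se = cf[, "Std. Error"],
      df = dfs,
      t = cf[, "t value"],
      p = ps,
      row.names = NULL, stringsAsFactors = FALSE
    )
    if (is_mer) {
      vc <- as.data.frame(lme4::VarCorr(fit))
      ranefs[[pc]] <- data.frame(
        response = pc,
        batch_sd = vc$sdcor[vc$grp == "batch"],
        residual_sd = vc$sdcor[vc$grp == "Residual"],
        stringsAsFactors = FALSE
      )
    } else {
      ranefs[[pc]] <- data.frame(response = pc, batch_sd = NA_real_,
                                 residual_sd = summary(fit)$sigma,
                                 stringsAsFactors = FALSE)
    }
    fits[[pc]] <- fit
  }
  structure(
    list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         ranef_sd = do.call(rbind, c(ranefs, list(make.row.names = FALSE))),
         fits = fits,
         reference = levels(condition)[[1]]),
    class = "condition_lmm"
  )
}

#' @export
print.condition_lmm <- function(x, digits = 3, ...) {
  cat(sprintf("Condition LMMs (reference level '%s', batch random intercept)\n",
              x$reference))
  tab <- x$table
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$t <- round(tab$t, digits)
  tab$p <- signif(tab$p, digits)
  tab$df <- round(tab$df, 1)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Levene variance-homogeneity test (median-centred)
#'
#' Brown-Forsythe variant of Levene's test: a one-way ANOVA on the absolute
#' deviations from each group's median. Robust to non-normality; the
#' standard choice for comparing behavioural variability between groups.
#'
#' @param x,y Numeric samples (each of length >= 2 after removing `NA`).
#' @return List with `statistic` (F), `p.value`, `df` (numerator,
#'   denominator).
#' @export
levene_variance_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("both samples must have at least 2 non-missing values")
  }
  z <- c(abs(x - stats::median(x)), abs(y - stats::median(y)))
  g <- rep(c(1L, 2L), c(length(x), length(y)))
  n <- length(z); k <- 2L
  zbar <- mean(z)
  zbar_g <- tapply(z, g, mean)
  n_g <- tabulate(g)
  ss_between <- sum(n_g * (zbar_g - zbar)^2)
  ss_within <- sum((z - zbar_g[g])^2)
  if (ss_within == 0) {
    # all deviations identical within groups: F degenerate
    stat <- if (ss_between == 0) 0 else Inf
    return(list(statistic = stat,
                p.value = if (ss_between == 0) 1 else 0,
                df = c(k - 1L, n - k)))
  }
  f <- (ss_between / (k - 1L)) / (ss_within / (n - k))
  list(statistic = f,
       p.value = stats::pf(f, k - 1L, n - k, lower.tail = FALSE),
       df = c(k - 1L, n - k))
}
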