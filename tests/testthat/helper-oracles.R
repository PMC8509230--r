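# Independent oracles used to cross-check the implementation. Each solves the
# same problem by a different, direct route (generalized least squares, brute
# force enumeration, naive refitting) and stays independent of the package
# code paths it checks.

# GLS / mixed-model-equation oracle: given variance components (G, sigma2),
# compute the GLS fixed effects and conditional (shrunken) per-patient
# effects directly: b_i = G Z_i' V_i^{-1} (y_i - X_i beta).
gls_growth_oracle <- function(outcomes, instrument, var_i, var_s, cov_is, var_resid) {
  d <- outcomes[outcomes$instrument == instrument, ]
  G <- matrix(c(var_i, cov_is, cov_is, var_s), 2, 2)
  ids <- unique(d$patient_id)
  XtVX <- matrix(0, 2, 2); XtVy <- numeric(2)
  parts <- lapply(ids, function(id) {
    di <- d[d$patient_id == id, ]
    Z <- cbind(1, di$week)          # random design == fixed design here
    V <- Z %*% G %*% t(Z) + var_resid * diag(nrow(di))
    Vi <- solve(V)
    list(X = Z, y = di$score, Vi = Vi, Z = Z)
  })
  for (p in parts) {
    XtVX <- XtVX + t(p$X) %*% p$Vi %*% p$X
    XtVy <- XtVy + t(p$X) %*% p$Vi %*% p$y
  }
  beta <- solve(XtVX, XtVy)
  blups <- t(vapply(parts, function(p)
    drop(G %*% t(p$Z) %*% p$Vi %*% (p$y - p$X %*% beta)), numeric(2)))
  list(beta = drop(beta),
       blups = data.frame(patient_id = ids, b_intercept = blups[, 1],
                          b_slope = blups[, 2], stringsAsFactors = FALSE))
}

# Brute-force all-subset minimum-AIC oracle (<= 10 candidates), using the
# same AIC convention via direct likelihood algebra, not gaussian_aic().
all_subset_oracle <- function(candidates, X, y) {
  X <- as.data.frame(X)
  n <- length(y)
  aic_direct <- function(terms) {
    f <- if (length(terms))
      stats::as.formula(paste("y ~", paste(sprintf("`%s`", terms), collapse = "+")))
    else y ~ 1
    fit <- stats::lm(f, data = cbind(X, y = y))
    rss <- sum(stats::residuals(fit)^2)
    n * log(rss / n) + 2 * (length(terms) + 2)
  }
  best <- list(terms = NULL, aic = Inf)
  for (k in 0:length(candidates)) {
    combs <- if (k == 0) list(character(0)) else
      asplit(utils::combn(candidates, k), 2)
    for (terms in combs) {
      a <- aic_direct(as.character(terms))
      if (a < best$aic - 1e-10) best <- list(terms = sort(as.character(terms)), aic = a)
    }
  }
  best
}

# Naive leave-one-out oracle: refit OLS from scratch for every fold.
naive_loo_oracle <- function(X, y, predictors) {
  X <- as.data.frame(X)
  vapply(seq_along(y), function(i) {
    d <- cbind(X[-i, predictors, drop = FALSE], y = y[-i])
    f <- if (length(predictors))
      stats::as.formula(paste("y ~", paste(sprintf("`%s`", predictors), collapse = "+")))
    else y ~ 1
    fit <- stats::lm(f, data = d)
    unname(stats::predict(fit, newdata = X[i, , drop = FALSE]))
  }, 0)
}

# Small balanced toy outcome set: n patients, individual lines plus optional
# noise, weeks 0/4/8/16.
make_toy_outcomes <- function(n = 6, intercepts = NULL, slopes = NULL,
                              sd_noise = 0, instrument = "CAPS5", seed = 1) {
  set.seed(seed)
  if (is.null(intercepts)) intercepts <- 40 + rnorm(n, 0, 5)
  if (is.null(slopes)) slopes <- -1 + rnorm(n, 0, 0.4)
  weeks <- c(0, 4, 8, 16)
  ids <- sprintf("T%02d", seq_len(n))
  data.frame(
    patient_id = rep(ids, each = length(weeks)),
    instrument = instrument,
    week = rep(weeks, n),
    score = rep(intercepts, each = 4) + rep(slopes, each = 4) * rep(weeks, n) +
      rnorm(4 * n, 0, sd_noise),
    stringsAsFactors = FALSE
  )
}

# Minimal cohort wrapper for engine-level tests that do not need simulation.
make_toy_cohort <- function(patients, outcomes = NULL, truth = NULL) {
  structure(list(patients = patients, outcomes = outcomes, truth = truth,
                 config = NULL, catalog = NULL), class = "pai_cohort")
}
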