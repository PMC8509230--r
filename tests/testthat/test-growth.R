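test_that("noiseless per-patient lines are recovered without shrinkage", {
  set.seed(4)
  ints <- 40 + rnorm(8, 0, 6)
  slps <- -1.2 + rnorm(8, 0, 0.5)
  out <- make_toy_outcomes(8, intercepts = ints, slopes = slps, sd_noise = 0)
  fit <- suppressWarnings(
    fit_growth_model(out, unique(out$patient_id), "CAPS5", group = "exposure"))
  got_slopes <- fit$fixed_slope + fit$blups$b_slope
  # per-patient least-squares slopes are exact on noiseless lines
  ls_slopes <- vapply(split(out, out$patient_id)[unique(out$patient_id)],
                      function(d) unname(coef(lm(score ~ week, d))[2]), 0)
  expect_equal(got_slopes, unname(ls_slopes), tolerance = 1e-4)
  cs <- change_scores(fit, out)
  expect_equal(cs$change, unname(-16 * ls_slopes), tolerance = 1e-3)
})

test_that("constant scores give a flat fit with zero conditional effects", {
  out <- make_toy_outcomes(5, intercepts = rep(30, 5), slopes = rep(0, 5))
  fit <- fit_growth_model(out, unique(out$patient_id), "CAPS5")
  expect_equal(fit$fixed_slope, 0)
  expect_equal(fit$blups$b_slope, rep(0, 5))
  expect_equal(fit$var_residual, 0)
  cs <- change_scores(fit, out)
  expect_equal(cs$change, rep(0, 5))
})

test_that("conditional effects match the direct GLS/mixed-model-equation oracle", {
  out <- make_toy_outcomes(6, sd_noise = 3, seed = 12)
  fit <- fit_growth_model(out, unique(out$patient_id), "CAPS5")
  orc <- gls_growth_oracle(out, "CAPS5", fit$var_intercept, fit$var_slope,
                           fit$cov_is, fit$var_residual)
  expect_equal(c(fit$fixed_intercept, fit$fixed_slope), orc$beta,
               tolerance = 1e-6)
  expect_equal(fit$blups$b_intercept, orc$blups$b_intercept, tolerance = 1e-6)
  expect_equal(fit$blups$b_slope, orc$blups$b_slope, tolerance = 1e-6)

  # change scores equal observed baseline minus the oracle's week-16 prediction
  cs <- change_scores(fit, out)
  pred16 <- orc$beta[1] + orc$blups$b_intercept +
    16 * (orc$beta[2] + orc$blups$b_slope)
  base <- out$score[out$week == 0][match(cs$patient_id,
                                         out$patient_id[out$week == 0])]
  expect_equal(cs$change, base - pred16, tolerance = 1e-6)

  # model-baseline mode replaces the observed baseline with the fitted one
  csm <- change_scores(fit, out, baseline = "model")
  expect_equal(csm$change, unname(-16 * (orc$beta[2] + orc$blups$b_slope)),
               tolerance = 1e-6)
})

test_that("a known linear decliner yields its exact change", {
  out <- make_toy_outcomes(4, intercepts = c(40, 45, 50, 38),
                           slopes = c(-20, -10, -4, 0) / 16, sd_noise = 0)
  fit <- suppressWarnings(fit_growth_model(out, unique(out$patient_id), "CAPS5"))
  cs <- change_scores(fit, out)
  expect_equal(cs$change, c(20, 10, 4, 0), tolerance = 1e-3)
})

test_that("conditional slopes are shrunken relative to least-squares slopes", {
  # componentwise between-ness is not guaranteed for the joint
  # intercept+slope BLUP (the shrinkage matrix mixes components when time is
  # uncentered), so assert the shrinkage facts that do hold: reduced spread,
  # strong agreement, and no deviation beyond the most extreme LS deviation
  out <- make_toy_outcomes(20, sd_noise = 6, seed = 77)
  fit <- fit_growth_model(out, unique(out$patient_id), "CAPS5")
  ls <- vapply(split(out, out$patient_id)[unique(out$patient_id)],
               function(d) unname(coef(lm(score ~ week, d))[2]), 0)
  cond <- fit$fixed_slope + fit$blups$b_slope
  expect_lt(var(cond), var(ls))
  expect_gt(cor(cond, ls), 0.5)
  expect_lte(max(abs(cond - fit$fixed_slope)), max(abs(ls - fit$fixed_slope)))
})

test_that("pure measurement noise does not bias the mean change", {
  reps <- 200
  set.seed(42)
  diffs <- vapply(seq_len(reps), function(r) {
    ints <- rep(40, 10); slps <- rep(-1, 10)
    clean <- make_toy_outcomes(10, ints, slps, sd_noise = 0, seed = 1000 + r)
    noisy <- clean
    noisy$score <- clean$score + rnorm(nrow(clean), 0, 4)
    fitn <- suppressWarnings(fit_growth_model(noisy, unique(noisy$patient_id), "CAPS5"))
    mean(change_scores(fitn, noisy)$change) - 16
  }, 0)
  se <- sd(diffs) / sqrt(reps)
  expect_lt(abs(mean(diffs)), 2 * se + 0.05)
})

test_that("fixed slope is recovered from data generated with known components", {
  set.seed(8)
  n <- 120; weeks <- c(0, 4, 8, 16)
  b0 <- rnorm(n, 0, 5); b1 <- rnorm(n, 0, 0.3)
  out <- data.frame(
    patient_id = rep(sprintf("R%03d", 1:n), each = 4),
    instrument = "CAPS5",
    week = rep(weeks, n),
    score = 45 + rep(b0, each = 4) + (-1.3 + rep(b1, each = 4)) * rep(weeks, n) +
      rnorm(4 * n, 0, 4),
    stringsAsFactors = FALSE)
  fit <- fit_growth_model(out, unique(out$patient_id), "CAPS5")
  se_approx <- sqrt(fit$var_slope / n + fit$var_residual / (n * sum((weeks - mean(weeks))^2)))
  expect_lt(abs(fit$fixed_slope - (-1.3)), 3 * se_approx)
})

test_that("growth model precondition and baseline-exclusion errors fire", {
  out <- make_toy_outcomes(4, sd_noise = 1)
  expect_error(fit_growth_model(out, "T01", "CAPS5"), "at least 2")
  expect_error(fit_growth_model(out, c("T01", "ZZZ"), "CAPS5"), "ZZZ")
  fit <- suppressWarnings(fit_growth_model(out, unique(out$patient_id), "CAPS5"))
  nobase <- out[!(out$patient_id == "T01" & out$week == 0), ]
  expect_warning(cs <- change_scores(fit, nobase), "T01")
  expect_false("T01" %in% cs$patient_id)
})
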