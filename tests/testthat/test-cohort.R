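test_that("paper preset reproduces the trial structure and is reproducible", {
  cfg <- cohort_config(seed = 5)
  coh <- generate_cohort(cfg)
  expect_identical(nrow(coh$patients), 149L)
  tab <- table(coh$patients$arm)
  expect_identical(as.integer(tab[c("PE", "iPE", "STAIRPE")]), c(48L, 51L, 50L))
  expect_identical(sum(coh$patients$arm != "STAIRPE"), 99L)

  coh2 <- generate_cohort(cfg)
  expect_identical(coh$patients, coh2$patients)
  expect_identical(coh$outcomes, coh2$outcomes)
  expect_identical(coh$truth, coh2$truth)

  # scores respect the instrument range; baselines always present
  expect_true(all(coh$outcomes$score >= 0 & coh$outcomes$score <= 80))
  base <- coh$outcomes[coh$outcomes$week == 0, ]
  for (instr in c("CAPS5", "PCL5"))
    expect_setequal(base$patient_id[base$instrument == instr],
                    coh$patients$patient_id)
})

test_that("degenerate configuration yields flat trajectories at the baseline mean", {
  cfg <- cohort_config(preset = "null", seed = 3,
                       arm_mean_change = list(CAPS5 = c(PE = 0, iPE = 0, STAIRPE = 0),
                                              PCL5 = c(PE = 0, iPE = 0, STAIRPE = 0)),
                       sd_random_intercept = 0, sd_random_slope = 0,
                       sd_slope_pcl5 = 0, sd_residual = 0,
                       baseline_sd = c(CAPS5 = 0, PCL5 = 0),
                       missing_rate = 0)
  coh <- generate_cohort(cfg)
  for (instr in c("CAPS5", "PCL5")) {
    sc <- coh$outcomes$score[coh$outcomes$instrument == instr]
    expect_equal(sc, rep(cfg$baseline_mean[[instr]], length(sc)))
  }
})

test_that("sampled predictor moments converge to catalog moments", {
  coh <- generate_cohort(cohort_config(preset = "null", seed = 17,
                                       n_pe = 2500, n_ipe = 2500,
                                       n_stairpe = 5000))
  cat24 <- default_catalog()
  for (grp in c("exposure", "stairpe")) {
    X <- coh$patients[(coh$patients$arm != "STAIRPE") == (grp == "exposure"), ]
    n <- nrow(X)
    for (j in seq_len(nrow(cat24))) {
      sp <- cat24[j, ]
      m <- if (grp == "exposure") sp$mean_exposure else sp$mean_stairpe
      s <- if (grp == "exposure") sp$sd_exposure else sp$sd_stairpe
      if (sp$kind == "binary") s <- sqrt(m * (1 - m))
      if (sp$kind == "count") s <- sqrt(m)
      se <- s / sqrt(n)
      expect_lt(abs(mean(X[[sp$name]]) - m), 3 * se + 1e-9,
                label = sprintf("|mean(%s) - %s| in %s", sp$name, m, grp))
      # sampled values respect the declared instrument ranges
      expect_true(all(X[[sp$name]] >= sp$range_min & X[[sp$name]] <= sp$range_max))
    }
  }
})

test_that("missingness never removes baselines and hits the configured rate", {
  cfg <- cohort_config(seed = 9, missing_rate = 0.25)
  coh <- generate_cohort(cfg)
  base <- coh$outcomes[coh$outcomes$week == 0, ]
  expect_identical(nrow(base), 149L * 2L)
  post <- coh$outcomes[coh$outcomes$week > 0, ]
  observed_rate <- 1 - nrow(post) / (149 * 2 * 3)
  expect_lt(abs(observed_rate - 0.25), 3 * sqrt(0.25 * 0.75 / (149 * 6)))
})

test_that("planted_pai reflects the construction and its symmetries", {
  # symmetric arms, no interactions -> advantage identically zero
  null_cfg <- cohort_config(preset = "null", seed = 21)
  coh0 <- generate_cohort(null_cfg)
  tp0 <- planted_pai(coh0)
  expect_equal(tp0$true_pai[tp0$instrument == "CAPS5"], rep(0, 149))

  # single exposure-side interaction -> advantage perfectly correlated with
  # the standardized predictor
  cfg1 <- cohort_config(preset = "null", seed = 22,
                        interaction_effects = list(BDI = c(exposure = 2, stairpe = 0)))
  coh1 <- generate_cohort(cfg1)
  tp1 <- planted_pai(coh1)
  caps <- tp1[tp1$instrument == "CAPS5", ]
  expect_equal(cor(caps$true_pai, coh1$patients$BDI), 1, tolerance = 1e-12)

  # empirical mean of planted advantage = difference of configured arm means
  cfg2 <- cohort_config(preset = "null", seed = 23,
                        arm_mean_change = list(CAPS5 = c(PE = 25, iPE = 25, STAIRPE = 18),
                                               PCL5 = c(PE = 22, iPE = 22, STAIRPE = 22)))
  coh2 <- generate_cohort(cfg2)
  tp2 <- planted_pai(coh2)
  expect_equal(mean(tp2$true_pai[tp2$instrument == "CAPS5"]), 7)
  expect_equal(mean(tp2$true_pai[tp2$instrument == "PCL5"]), 0)

  # antisymmetry under swapping the two groups' truth columns
  swapped <- coh1
  swapped$truth <- transform(coh1$truth,
                             true_pe = true_stairpe, true_ipe = true_stairpe,
                             true_stairpe = (true_pe + true_ipe) / 2)
  expect_equal(planted_pai(swapped)$true_pai, -tp1$true_pai)

  # truth absent -> error
  coh1$truth <- NULL
  expect_error(planted_pai(coh1), "truth")
})

test_that("config validation rejects bad arm sizes and unknown interaction targets", {
  expect_error(cohort_config(n_pe = 1), "at least 2")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  cfg <- cohort_config(seed = 1,
                       interaction_effects = list(NOSUCH = c(exposure = 1, stairpe = 0)))
  expect_error(generate_cohort(cfg), "NOSUCH")
})

test_that("cohort round-trips through delimited files", {
  coh <- generate_cohort(cohort_config(seed = 31, n_pe = 5, n_ipe = 5, n_stairpe = 5))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(file.path(dir, "cohort_patients.csv"),
                      file.path(dir, "cohort_outcomes.csv"),
                      file.path(dir, "truth.csv"))
  expect_equal(back$patients, coh$patients)
  expect_equal(back$outcomes, coh$outcomes, tolerance = 1e-12)
  expect_error(read_cohort(file.path(dir, "cohort_outcomes.csv"),
                           file.path(dir, "cohort_outcomes.csv")),
               "arm")
})
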