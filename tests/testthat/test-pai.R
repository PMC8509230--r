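# Minimal fixture: patients in both groups with known predictors and change
# scores, plus frozen model specs built through stepwise on fixed candidates.
make_pai_fixture <- function(n_exp = 12, n_st = 10, seed = 3, sd_noise = 1) {
  set.seed(seed)
  n <- n_exp + n_st
  patients <- data.frame(
    patient_id = sprintf("F%02d", 1:n),
    arm = c(rep(c("PE", "iPE"), length.out = n_exp), rep("STAIRPE", n_st)),
    x1 = rnorm(n), x2 = rnorm(n), stringsAsFactors = FALSE)
  change <- ifelse(patients$arm != "STAIRPE",
                   20 + 3 * patients$x1, 18 - 2 * patients$x2) +
    rnorm(n, 0, sd_noise)
  scores <- data.frame(patient_id = patients$patient_id, instrument = "CAPS5",
                       change = change, stringsAsFactors = FALSE)
  cohort <- make_toy_cohort(patients)
  exp_idx <- patients$arm != "STAIRPE"
  spec_exp <- stepwise_aic("x1", patients[exp_idx, ], change[exp_idx],
                           group = "exposure", instrument = "CAPS5")
  spec_st <- stepwise_aic("x2", patients[!exp_idx, ], change[!exp_idx],
                          group = "stairpe", instrument = "CAPS5")
  list(cohort = cohort, scores = scores, spec_exp = spec_exp, spec_st = spec_st)
}

test_that("LOO predictions equal the naive per-fold refit oracle", {
  fx <- make_pai_fixture(n_exp = 8, n_st = 8, seed = 13)
  preds <- loocv_predictions(fx$cohort, fx$scores, fx$spec_exp, fx$spec_st)
  pat <- fx$cohort$patients
  for (g in c("exposure", "stairpe")) {
    idx <- preds$group == g
    vars <- if (g == "exposure") fx$spec_exp$predictors else fx$spec_st$predictors
    orc <- naive_loo_oracle(pat[match(preds$patient_id[idx], pat$patient_id), ],
                            preds$change[idx], vars)
    expect_equal(preds$pred_received[idx], orc, tolerance = 1e-9)
  }
})

test_that("LOO excludes the held-out patient; identical patients get identical cross predictions", {
  fx <- make_pai_fixture(seed = 14)
  preds <- loocv_predictions(fx$cohort, fx$scores, fx$spec_exp, fx$spec_st)
  # perturb one patient's outcome only: that patient's received prediction is
  # built without it, so it cannot move
  i <- which(fx$cohort$patients$arm != "STAIRPE")[1]
  pid <- fx$cohort$patients$patient_id[i]
  sc2 <- fx$scores
  sc2$change[sc2$patient_id == pid] <- sc2$change[sc2$patient_id == pid] + 50
  preds2 <- loocv_predictions(fx$cohort, sc2, fx$spec_exp, fx$spec_st)
  expect_equal(preds2$pred_received[preds2$patient_id == pid],
               preds$pred_received[preds$patient_id == pid], tolerance = 1e-9)

  # two clones in the exposure group share the alternative-group prediction
  fx2 <- make_pai_fixture(seed = 15)
  pat <- fx2$cohort$patients
  clone_of <- which(pat$arm != "STAIRPE")[1:2]
  pat[clone_of[2], c("x1", "x2")] <- pat[clone_of[1], c("x1", "x2")]
  fx2$cohort$patients <- pat
  p <- loocv_predictions(fx2$cohort, fx2$scores, fx2$spec_exp, fx2$spec_st)
  expect_equal(p$pred_alternative[clone_of[1]], p$pred_alternative[clone_of[2]],
               tolerance = 1e-12)
})

test_that("the PAI arithmetic, recommendation rule and antisymmetry hold", {
  preds <- data.frame(patient_id = c("a", "b", "c"),
                      group = c("exposure", "stairpe", "exposure"),
                      pred_received = c(25, 20, 15),
                      pred_alternative = c(20, 25, 15),
                      pred_exposure = c(25, 25, 15),
                      pred_stairpe = c(20, 20, 15),
                      change = c(24, 21, 15), stringsAsFactors = FALSE)
  rec <- suppressMessages(compute_pai(preds))
  expect_equal(rec$pai, c(5, 5, 0))
  expect_identical(rec$recommended, c("exposure", "exposure", "exposure"))
  expect_identical(rec$optimal, c(TRUE, FALSE, TRUE))  # tie keeps received

  # swapping the group labels negates every PAI but fixes the optimal flags
  sw <- preds
  sw$group <- ifelse(preds$group == "exposure", "stairpe", "exposure")
  sw$pred_exposure <- preds$pred_stairpe
  sw$pred_stairpe <- preds$pred_exposure
  rec_sw <- suppressMessages(compute_pai(sw))
  expect_equal(rec_sw$pai, -rec$pai)
  expect_identical(rec_sw$optimal, rec$optimal)
  expect_message(compute_pai(preds), "PAI exactly 0")
})

test_that("each patient gets exactly one record and the flags partition the cohort", {
  fx <- make_pai_fixture(seed = 16)
  preds <- loocv_predictions(fx$cohort, fx$scores, fx$spec_exp, fx$spec_st)
  rec <- compute_pai(preds)
  expect_identical(nrow(rec), nrow(fx$cohort$patients))
  expect_false(anyDuplicated(rec$patient_id) > 0)
  expect_identical(sum(rec$optimal) + sum(!rec$optimal), nrow(rec))
})

test_that("prediction errors summarize absolute LOO error per group", {
  preds <- data.frame(patient_id = letters[1:5],
                      group = c("exposure", "exposure", "exposure",
                                "stairpe", "stairpe"),
                      pred_received = c(10, 12, 14, 20, 22),
                      pred_alternative = 0, pred_exposure = 0, pred_stairpe = 0,
                      change = c(10, 12, 14, 23, 19), stringsAsFactors = FALSE)
  pe <- prediction_errors(preds)
  expect_equal(pe$mean_abs_error[pe$group == "exposure"], 0)
  expect_equal(pe$sd_abs_error[pe$group == "exposure"], 0)
  expect_equal(pe$mean_abs_error[pe$group == "stairpe"], 3)  # |−3|, |3|
  expect_equal(pe$sd_abs_error[pe$group == "stairpe"], 0)

  # constant bias b gives mean |b| and SD 0
  preds$pred_received <- preds$change + 2.5
  pe2 <- prediction_errors(preds)
  expect_equal(pe2$mean_abs_error, c(2.5, 2.5))
  expect_equal(pe2$sd_abs_error, c(0, 0))
})

test_that("groups too small for the model error out", {
  fx <- make_pai_fixture(n_exp = 4, n_st = 10, seed = 17)
  expect_error(loocv_predictions(fx$cohort, fx$scores, fx$spec_exp, fx$spec_st),
               "too small")
})
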