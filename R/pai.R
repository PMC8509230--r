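# group membership helpers: the pipeline contrasts the pooled exposure arms
# (PE + iPE) against STAIR+PE throughout.
.patient_groups <- function(patients) {
  data.frame(patient_id = patients$patient_id,
             group = .arm_group(patients$arm), stringsAsFactors = FALSE)
}

#' Leave-one-out counterfactual predictions
#'
#' For every patient, the prediction of the treatment actually received comes
#' from an OLS refit of the received group's final model that excludes the
#' patient (leave-one-out; computed through the exact hat-matrix identity, so
#' it equals a from-scratch refit), while the prediction of the alternative
#' treatment comes from the full model of the other group — each patient ends
#' up with one prediction per treatment group. Variable sets are frozen in
#' the supplied model specs; selection is not rerun per fold.
#'
#' @param cohort a `pai_cohort` (or any object with a `patients` table).
#' @param scores combined change-score data frame (`patient_id`,
#'   `instrument`, `change`) covering both groups.
#' @param spec_exposure,spec_stairpe `pai_model_spec` objects for the pooled
#'   exposure group and STAIR+PE.
#' @param instrument which instrument's change scores to use.
#' @return Data frame: `patient_id`, `group` (received), `pred_received`,
#'   `pred_alternative`, `pred_exposure`, `pred_stairpe`, `change`.
#' @export
loocv_predictions <- function(cohort, scores, spec_exposure, spec_stairpe,
                              instrument = "CAPS5") {
  stopifnot(inherits(spec_exposure, "pai_model_spec"),
            inherits(spec_stairpe, "pai_model_spec"))
  sc <- scores[scores$instrument == instrument, ]
  pat <- merge(.patient_groups(cohort$patients), sc, by = "patient_id")
  vars <- union(spec_exposure$predictors, spec_stairpe$predictors)
  miss <- setdiff(vars, names(cohort$patients))
  if (length(miss)) stop("cohort lacks model predictors: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  pat <- merge(pat, cohort$patients[, c("patient_id", vars), drop = FALSE],
               by = "patient_id")

  specs <- list(exposure = spec_exposure, stairpe = spec_stairpe)
  pred_own <- pred_other <- setNames(numeric(nrow(pat)), pat$patient_id)
  for (g in c("exposure", "stairpe")) {
    spec <- specs[[g]]
    in_g <- pat$group == g
    ng <- sum(in_g)
    if (ng - 1 <= length(spec$predictors) + 2)
      stop(sprintf("group %s too small (%d) for %d predictors after leaving one out",
                   g, ng, length(spec$predictors)), call. = FALSE)
    A <- cbind(1, as.matrix(pat[in_g, spec$predictors, drop = FALSE]))
    yg <- pat$change[in_g]
    qra <- qr(A)
    if (qra$rank < ncol(A)) stop("rank-deficient design in group ", g, call. = FALSE)
    fitted <- qr.fitted(qra, yg)
    h <- rowSums(qr.Q(qra)^2)
    e <- yg - fitted
    # exact LOO fitted value at the held-out patient's own covariates
    pred_own[in_g] <- fitted - h * e / (1 - h)
    # full-group model predicts the *other* group's patients
    beta <- qr.coef(qra, yg)
    Aother <- cbind(1, as.matrix(pat[!in_g, spec$predictors, drop = FALSE]))
    pred_other[!in_g] <- drop(Aother %*% beta)
  }
  data.frame(patient_id = pat$patient_id, group = pat$group,
             pred_received = unname(pred_own),
             pred_alternative = unname(pred_other),
             pred_exposure = ifelse(pat$group == "exposure", pred_own, pred_other),
             pred_stairpe = ifelse(pat$group == "stairpe", pred_own, pred_other),
             change = pat$change, stringsAsFactors = FALSE)
}

#' Personalized advantage index per patient
#'
#' The PAI is the predicted change under the pooled exposure conditions minus
#' the predicted change under STAIR+PE; a positive PAI recommends exposure, a
#' negative one STAIR+PE. Patients whose randomized group matches the
#' recommendation are flagged optimal. A PAI of exactly zero carries no
#' evidence to switch: the received group counts as optimal and the tie is
#' reported via a message.
#'
#' @param preds output of [loocv_predictions()].
#' @param instrument label stored on the records.
#' @return Data frame of class `pai_records`: `patient_id`, `instrument`,
#'   `group`, `pred_exposure`, `pred_stairpe`, `pai`, `recommended`,
#'   `optimal`.
#' @export
compute_pai <- function(preds, instrument = "CAPS5") {
  pai <- preds$pred_exposure - preds$pred_stairpe
  recommended <- ifelse(pai > 0, "exposure", ifelse(pai < 0, "stairpe", preds$group))
  ties <- pai == 0
  if (any(ties))
    message(sum(ties), " patient(s) with PAI exactly 0; received group kept as optimal")
  out <- data.frame(patient_id = preds$patient_id, instrument = instrument,
                    group = preds$group,
                    pred_exposure = preds$pred_exposure,
                    pred_stairpe = preds$pred_stairpe,
                    pai = pai, recommended = recommended,
                    optimal = recommended == preds$group,
                    stringsAsFactors = FALSE)
  class(out) <- c("pai_records", "data.frame")
  out
}

#' Accuracy of the counterfactual predictions
#'
#' Per treatment group, the mean and SD of the absolute difference between
#' the received-group leave-one-out prediction and the calculated change.
#'
#' @param preds output of [loocv_predictions()] (carries the observed
#'   `change`).
#' @return Data frame: `group`, `n`, `mean_abs_error`, `sd_abs_error`.
#' @export
prediction_errors <- function(preds) {
  err <- abs(preds$pred_received - preds$change)
  out <- do.call(rbind, lapply(split(err, preds$group), function(e)
    data.frame(n = length(e), mean_abs_error = mean(e),
               sd_abs_error = stats::sd(e))))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out
}
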