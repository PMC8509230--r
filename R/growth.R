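#' Random-intercept/random-slope growth model for one treatment group
#'
#' Fits `score ~ 1 + week` with correlated random intercepts and slopes per
#' patient by maximum likelihood, the model used to turn the repeated CAPS-5 /
#' PCL-5 measurements (weeks 0, 4, 8, 16) into per-patient calculated change.
#' Singular fits trigger a documented fallback cascade: correlated random
#' effects, then independent random effects, then random intercept only, each
#' step with a warning.
#'
#' Degenerate inputs with zero score variance (all measurements equal) are
#' handled without the mixed-model machinery: the fit is the flat line at that
#' constant with all variance components and conditional effects zero.
#'
#' @param outcomes long outcome table (`patient_id`, `instrument`, `week`,
#'   `score`).
#' @param patient_ids patients forming the group (e.g. the pooled exposure
#'   arms); at least 2, each with at least one measurement.
#' @param instrument `"CAPS5"` or `"PCL5"`.
#' @param group optional label stored on the fit.
#' @return An object of class `growth_fit`: fixed intercept/slope, variance
#'   components (`var_intercept`, `var_slope`, `cov_is`, `var_residual`),
#'   per-patient conditional (empirical-Bayes) deviations `blups`
#'   (`patient_id`, `b_intercept`, `b_slope`), the random-effect `structure`
#'   actually used, a `converged` flag, and the underlying `lme4` fit (or
#'   `NULL` for the degenerate constant case).
#' @export
fit_growth_model <- function(outcomes, patient_ids, instrument,
                             group = NA_character_) {
  patient_ids <- as.character(patient_ids)
  if (length(unique(patient_ids)) < 2) stop("need at least 2 patients", call. = FALSE)
  d <- outcomes[outcomes$patient_id %in% patient_ids &
                outcomes$instrument == instrument, , drop = FALSE]
  missing <- setdiff(patient_ids, unique(d$patient_id))
  if (length(missing))
    stop("patients without any measurement: ", paste(missing, collapse = ", "),
         call. = FALSE)
  d$patient_id <- factor(d$patient_id, levels = unique(patient_ids))

  new_fit <- function(fi, fs, vi, vs, cis, vr, blups, restruct, converged, model) {
    out <- list(group = group, instrument = instrument,
                fixed_intercept = fi, fixed_slope = fs,
                var_intercept = vi, var_slope = vs, cov_is = cis,
                var_residual = vr, blups = blups, structure = restruct,
                converged = converged, model = model)
    class(out) <- "growth_fit"
    out
  }

  if (stats::var(d$score) < .Machine$double.eps) {
    blups <- data.frame(patient_id = levels(d$patient_id),
                        b_intercept = 0, b_slope = 0, stringsAsFactors = FALSE)
    return(new_fit(d$score[1], 0, 0, 0, 0, 0, blups, "constant", TRUE, NULL))
  }

  fit_one <- function(formula, structure) {
    m <- suppressMessages(suppressWarnings(
      lme4::lmer(formula, data = d, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    list(m = m, singular = lme4::isSingular(m, tol = 1e-5), structure = structure)
  }
  res <- fit_one(score ~ week + (week | patient_id), "correlated")
  if (res$singular) {
    warning("singular fit with correlated random effects; refitting with independent random effects",
            call. = FALSE)
    res <- fit_one(score ~ week + (week || patient_id), "independent")
  }
  if (res$singular && res$structure == "independent") {
    warning("still singular; falling back to random intercept only", call. = FALSE)
    res <- fit_one(score ~ week + (1 | patient_id), "intercept_only")
  }
  m <- res$m
  fe <- lme4::fixef(m)
  vc <- as.data.frame(lme4::VarCorr(m))
  getv <- function(v1, v2 = NA) {
    row <- vc$grp != "Residual" & vc$var1 %in% v1 &
      (is.na(v2) & is.na(vc$var2) | !is.na(vc$var2) & vc$var2 %in% v2)
    if (any(row)) sum(vc$vcov[row]) else 0
  }
  re <- lme4::ranef(m)$patient_id
  blups <- data.frame(patient_id = rownames(re),
                      b_intercept = re[["(Intercept)"]],
                      b_slope = if ("week" %in% colnames(re)) re[["week"]] else 0,
                      stringsAsFactors = FALSE)
  blups <- blups[match(levels(d$patient_id), blups$patient_id), ]
  rownames(blups) <- NULL
  conv <- length(m@optinfo$conv$lme4) == 0
  new_fit(unname(fe["(Intercept)"]), unname(fe["week"]),
          getv("(Intercept)"), getv("week"),
          if (res$structure == "correlated") getv("(Intercept)", "week") else 0,
          stats::sigma(m)^2, blups, res$structure, conv, m)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Growth model (%s, %s): score ~ week, ML, random effects: %s\n",
              x$group, x$instrument, x$structure))
  cat(sprintf("  fixed: intercept %.3f, slope %.4f pts/week\n",
              x$fixed_intercept, x$fixed_slope))
  cat(sprintf("  var(intercept) %.3f, var(slope) %.5f, cov %.4f, var(resid) %.3f\n",
              x$var_intercept, x$var_slope, x$cov_is, x$var_residual))
  cat(sprintf("  %d patients, converged: %s\n", nrow(x$blups), x$converged))
  invisible(x)
}

#' Calculated change scores from a growth fit
#'
#' The calculated change is the baseline score minus the model-predicted
#' week-16 score, so higher values mean a larger symptom decrease. The
#' prediction uses the population effects plus the patient's conditional
#' (shrunken) deviations: `(intercept + b_i0) + 16 * (slope + b_i1)`. By
#' default the observed week-0 measurement is the baseline; `baseline =
#' "model"` substitutes the model-implied baseline `intercept + b_i0`,
#' yielding a fully model-based change.
#'
#' @param fit a [fit_growth_model()] result.
#' @param outcomes the long outcome table the fit was computed from.
#' @param baseline `"observed"` (default) or `"model"`.
#' @return Data frame of class `change_scores`: `patient_id`, `instrument`,
#'   `change`. Patients without a week-0 measurement are excluded with a
#'   warning under `baseline = "observed"`.
#' @export
change_scores <- function(fit, outcomes, baseline = c("observed", "model")) {
  stopifnot(inherits(fit, "growth_fit"))
  baseline <- match.arg(baseline)
  pred16 <- (fit$fixed_intercept + fit$blups$b_intercept) +
    16 * (fit$fixed_slope + fit$blups$b_slope)
  if (baseline == "model") {
    base <- fit$fixed_intercept + fit$blups$b_intercept
    keep <- rep(TRUE, nrow(fit$blups))
  } else {
    d0 <- outcomes[outcomes$instrument == fit$instrument & outcomes$week == 0, ]
    idx <- match(fit$blups$patient_id, d0$patient_id)
    keep <- !is.na(idx)
    if (any(!keep))
      warning("excluding patients without a baseline measurement: ",
              paste(fit$blups$patient_id[!keep], collapse = ", "), call. = FALSE)
    base <- d0$score[idx]
  }
  if (!any(keep))
    stop("no patient has a baseline (week-0) measurement", call. = FALSE)
  out <- data.frame(patient_id = fit$blups$patient_id[keep],
                    instrument = fit$instrument,
                    change = (base - pred16)[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("change_scores", "data.frame")
  out
}
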