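#' Fit a personalized advantage index model to a trial cohort
#'
#' The central fitting routine. For one instrument it runs the full analysis
#' chain on a two-group comparison of the pooled exposure arms (PE + iPE)
#' versus STAIR+PE:
#' \enumerate{
#'   \item per group, a random-intercept/random-slope growth model over all
#'     available measurements turns the repeated scores into per-patient
#'     calculated change (baseline minus predicted week-16 score);
#'   \item per group, shadow-feature all-relevant selection screens the
#'     baseline predictors against the change score;
#'   \item the surviving candidates are refined to a final linear model by
#'     stepwise AIC, with bootstrap stability diagnostics;
#'   \item leave-one-out counterfactual predictions under both groups give
#'     each patient a PAI (predicted exposure change minus predicted STAIR+PE
#'     change) and an optimal/suboptimal flag;
#'   \item the calculated change of optimal versus suboptimal patients is
#'     compared (ANOVA F, Cohen's d with CI).
#' }
#' Selection runs once on the full sample and is frozen before the
#' leave-one-out stage; only the OLS coefficients vary across folds. The
#' optimal-vs-suboptimal contrast is evaluated in-sample, which is optimistic
#' (see the methods vignette).
#'
#' @param cohort a `pai_cohort` from [generate_cohort()] or [read_cohort()].
#' @param instrument `"CAPS5"` or `"PCL5"`.
#' @param seed master seed; per-stage substreams are derived from it.
#' @param alpha,max_rounds,ntree,mtry shadow-selection settings, see
#'   [shadow_select()].
#' @param B bootstrap replicates for the stability diagnostic (`B = 0` skips
#'   it).
#' @param direction stepwise direction, see [stepwise_aic()].
#' @param baseline change-score baseline mode, see [change_scores()].
#' @param keep_tentative pass predictors still tentative after `max_rounds`
#'   on to the stepwise stage (default `FALSE`).
#' @param rule,tau final-model rule, see [final_model()].
#' @param ci confidence-interval method for Cohen's d, see
#'   [compare_groups()].
#' @return An object of class `pai_fit` with components `change`, `growth`,
#'   `selection`, `models`, `predictions`, `records`, `errors`, `evaluation`
#'   and the call parameters; supports `print()`, `summary()`, `coef()`,
#'   `predict()`, `plot()` and `residuals()`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(seed = 11))
#' fit <- pai(coh, "CAPS5", seed = 11, ntree = 100, max_rounds = 40, B = 20)
#' fit
#' }
#' @export
pai <- function(cohort, instrument = c("CAPS5", "PCL5"), seed = 1,
                alpha = 0.01, max_rounds = 1000, ntree = 500, mtry = NULL,
                B = 100, direction = "both",
                baseline = c("observed", "model"), keep_tentative = FALSE,
                rule = c("fulldata_stepwise", "frequency_threshold"),
                tau = 0.5, ci = c("normal", "noncentral")) {
  stopifnot(inherits(cohort, "pai_cohort"))
  instrument <- match.arg(instrument)
  baseline <- match.arg(baseline)
  rule <- match.arg(rule)
  ci <- match.arg(ci)
  seeds <- .stage_seeds(seed, c("sel_exposure", "sel_stairpe",
                                "boot_exposure", "boot_stairpe"))
  groups <- .patient_groups(cohort$patients)
  pred_cols <- setdiff(names(cohort$patients), c("patient_id", "arm"))

  growth <- list(); scores <- NULL
  for (g in c("exposure", "stairpe")) {
    ids <- groups$patient_id[groups$group == g]
    fit <- fit_growth_model(cohort$outcomes, ids, instrument, group = g)
    growth[[g]] <- fit
    scores <- rbind(scores, change_scores(fit, cohort$outcomes, baseline))
  }

  selection <- list(); models <- list(); boots <- list()
  for (g in c("exposure", "stairpe")) {
    ids <- groups$patient_id[groups$group == g]
    sc <- scores[scores$patient_id %in% ids, ]
    Xg <- cohort$patients[match(sc$patient_id, cohort$patients$patient_id),
                          pred_cols, drop = FALSE]
    y <- sc$change
    sel <- shadow_select(Xg, y, alpha = alpha, max_rounds = max_rounds,
                         ntree = ntree, mtry = mtry,
                         seed = seeds[[paste0("sel_", g)]])
    selection[[g]] <- sel
    candidates <- sel$confirmed
    if (keep_tentative) candidates <- c(candidates, sel$tentative)
    bs <- if (B >= 1) bootstrap_stepwise(candidates, Xg, y, B = B,
                                         seed = seeds[[paste0("boot_", g)]],
                                         direction = direction)
    boots[[g]] <- bs
    models[[g]] <- final_model(candidates, Xg, y, summary = bs, rule = rule,
                               tau = tau, direction = direction,
                               group = g, instrument = instrument)
  }

  preds <- loocv_predictions(cohort, scores, models$exposure, models$stairpe,
                             instrument)
  records <- compute_pai(preds, instrument)
  errors <- prediction_errors(preds)
  evaluation <- compare_groups(preds$change, records$optimal,
                               instrument = instrument, ci = ci)

  out <- list(instrument = instrument, change = scores, growth = growth,
              selection = selection, bootstrap = boots, models = models,
              predictions = preds, records = records, errors = errors,
              evaluation = evaluation, n = nrow(preds),
              params = list(seed = seed, alpha = alpha,
                            max_rounds = max_rounds, ntree = ntree,
                            mtry = mtry, B = B, direction = direction,
                            baseline = baseline,
                            keep_tentative = keep_tentative, rule = rule,
                            tau = tau, ci = ci),
              call = match.call())
  class(out) <- "pai_fit"
  out
}

#' @export
print.pai_fit <- function(x, ...) {
  cat(sprintf("Personalized advantage index fit (%s), n = %d\n",
              x$instrument, x$n))
  cat(sprintf("  exposure model:  %s\n",
              if (length(x$models$exposure$predictors))
                paste(x$models$exposure$predictors, collapse = ", ")
              else "(intercept only)"))
  cat(sprintf("  STAIR+PE model:  %s\n",
              if (length(x$models$stairpe$predictors))
                paste(x$models$stairpe$predictors, collapse = ", ")
              else "(intercept only)"))
  cat(sprintf("  optimal %d / suboptimal %d; Cohen's d = %.2f [%.2f, %.2f]\n",
              x$evaluation$n_optimal, x$evaluation$n_suboptimal,
              x$evaluation$cohens_d, x$evaluation$ci[1], x$evaluation$ci[2]))
  invisible(x)
}

#' @export
summary.pai_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.pai_fit")
}

#' @export
print.summary.pai_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nFinal prediction models\n")
  print(f$models$exposure)
  print(f$models$stairpe)
  cat("\nSelection decisions\n")
  for (g in names(f$selection)) { cat("[", g, "]\n", sep = ""); print(f$selection[[g]]) }
  cat("\nPrediction errors (LOO, absolute)\n")
  print(f$errors, row.names = FALSE, digits = 3)
  cat("\n")
  print(f$evaluation)
  cat("\nNote: the optimal-vs-suboptimal contrast is evaluated in-sample on\n")
  cat("the cohort the models were selected on and is therefore optimistic.\n")
  invisible(x)
}

#' @export
coef.pai_fit <- function(object, ...) {
  lapply(object$models, coef)
}

#' Counterfactual predictions and PAI for new patients
#'
#' Applies the fitted full-group models to new baseline data: predicted
#' change under the pooled exposure conditions, under STAIR+PE, their
#' difference (the PAI) and the recommended group.
#'
#' @param object a `pai_fit`.
#' @param newdata data frame with the predictor columns of both final models.
#' @param ... unused.
#' @return Data frame `pred_exposure`, `pred_stairpe`, `pai`, `recommended`.
#' @export
predict.pai_fit <- function(object, newdata, ...) {
  pe <- predict(object$models$exposure, newdata)
  ps <- predict(object$models$stairpe, newdata)
  pai <- pe - ps
  data.frame(pred_exposure = pe, pred_stairpe = ps, pai = pai,
             recommended = ifelse(pai >= 0, "exposure", "stairpe"),
             stringsAsFactors = FALSE)
}

#' @export
residuals.pai_fit <- function(object, ...) {
  setNames(object$predictions$change - object$predictions$pred_received,
           object$predictions$patient_id)
}

#' Distribution of calculated change by optimal vs suboptimal assignment
#'
#' Overlaid histograms (density scale) of the calculated change for patients
#' randomized to their PAI-optimal versus suboptimal treatment.
#'
#' @param x a `pai_fit`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.pai_fit <- function(x, ...) {
  ch <- x$predictions$change
  opt <- x$records$optimal
  brk <- pretty(range(ch), 20)
  h1 <- graphics::hist(ch[opt], breaks = brk, plot = FALSE)
  h2 <- graphics::hist(ch[!opt], breaks = brk, plot = FALSE)
  ylim <- c(0, max(h1$density, h2$density) * 1.1)
  graphics::plot(h1, freq = FALSE, col = grDevices::adjustcolor("steelblue", 0.5),
                 ylim = ylim, border = "white",
                 xlab = sprintf("calculated change in %s (points)", x$instrument),
                 main = "Optimal vs suboptimal randomization", ...)
  graphics::plot(h2, freq = FALSE, col = grDevices::adjustcolor("firebrick", 0.5),
                 border = "white", add = TRUE)
  graphics::legend("topright", c("optimal", "suboptimal"),
                   fill = grDevices::adjustcolor(c("steelblue", "firebrick"), 0.5),
                   bty = "n")
  invisible(x)
}

#' Run the full PAI pipeline and write its artifacts
#'
#' Orchestrates the whole analysis for one or both instruments and, when
#' `out_dir` is given, writes the artifacts: `change_scores.csv`,
#' `selection_<group>_<instrument>.json`,
#' `final_model_<group>_<instrument>.json`, `pai_<instrument>.csv`,
#' distribution plots, and a combined `report.json` / `report.md` stamped
#' with the seed and a config hash.
#'
#' @param cohort a `pai_cohort`.
#' @param config a [run_config()]; its fields parameterize every stage.
#' @param out_dir optional output directory.
#' @return A list of class `pai_report`: one `pai_fit` per instrument plus a
#'   `summary` list (the report content).
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(cohort, "pai_cohort"), inherits(config, "pai_run_config"))
  fits <- list()
  for (instr in config$instruments) {
    fits[[instr]] <- pai(cohort, instr, seed = config$seed,
                         alpha = config$alpha, max_rounds = config$max_rounds,
                         ntree = config$ntree, mtry = config$mtry,
                         B = config$B, direction = config$direction,
                         baseline = config$baseline,
                         keep_tentative = config$keep_tentative,
                         rule = config$rule, tau = config$tau, ci = config$ci)
  }
  hash <- .config_hash(unclass(config))
  summary <- list(seed = config$seed, config_hash = hash,
                  n_patients = nrow(cohort$patients),
                  arms = as.list(table(cohort$patients$arm)),
                  instruments = lapply(fits, function(f) {
                    ev <- f$evaluation
                    list(n_optimal = ev$n_optimal,
                         n_suboptimal = ev$n_suboptimal,
                         mean_optimal = ev$mean_optimal,
                         sd_optimal = ev$sd_optimal,
                         mean_suboptimal = ev$mean_suboptimal,
                         sd_suboptimal = ev$sd_suboptimal,
                         F = ev$F, df = ev$df, p = ev$p,
                         cohens_d = ev$cohens_d, ci = ev$ci,
                         exposure_predictors = f$models$exposure$predictors,
                         stairpe_predictors = f$models$stairpe$predictors,
                         prediction_errors = f$errors)
                  }),
                  caveat = paste("Optimal-vs-suboptimal contrasts are evaluated",
                                 "in-sample on the cohort used for selection and",
                                 "model fitting; expect optimism relative to",
                                 "prospective application."))
  out <- list(fits = fits, summary = summary, config = config)
  class(out) <- "pai_report"
  if (!is.null(out_dir)) .write_report(out, cohort, out_dir)
  out
}

#' @export
print.pai_report <- function(x, ...) {
  cat("PAI pipeline report (seed ", x$summary$seed, ", config ",
      substr(x$summary$config_hash, 1, 8), ")\n", sep = "")
  for (f in x$fits) print(f)
  invisible(x)
}

.write_report <- function(report, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(seed = report$summary$seed,
                config_hash = report$summary$config_hash)
  all_change <- do.call(rbind, lapply(report$fits, `[[`, "change"))
  utils::write.csv(all_change, file.path(out_dir, "change_scores.csv"),
                   row.names = FALSE)
  for (instr in names(report$fits)) {
    f <- report$fits[[instr]]
    utils::write.csv(
      cbind(f$records, seed = stamp$seed, config_hash = stamp$config_hash),
      file.path(out_dir, sprintf("pai_%s.csv", instr)), row.names = FALSE)
    for (g in names(f$selection)) {
      sel <- f$selection[[g]]
      .write_json(list(stamp = stamp, group = g, instrument = instr,
                       decisions = sel$state, rounds = sel$rounds_completed,
                       params = sel$params,
                       z_history = lapply(sel$z_history, function(h)
                         list(z = as.list(h$z), shadow = as.list(h$shadow)))),
                  file.path(out_dir, sprintf("selection_%s_%s.json", g, instr)))
      m <- f$models[[g]]
      .write_json(list(stamp = stamp, group = g, instrument = instr,
                       predictors = m$predictors, coefficients = m$coefficients,
                       n = m$n, aic = m$aic, rule = m$rule,
                       bootstrap = if (!is.null(m$bootstrap))
                         list(B = m$bootstrap$B, summary = m$bootstrap$summary)),
                  file.path(out_dir, sprintf("final_model_%s_%s.json", g, instr)))
    }
    grDevices::png(file.path(out_dir, sprintf("distribution_%s.png", instr)),
                   width = 800, height = 600)
    plot(f)
    grDevices::dev.off()
  }
  .write_json(report$summary, file.path(out_dir, "report.json"))
  md <- c(sprintf("# PAI pipeline report"),
          sprintf("- seed: %d", report$summary$seed),
          sprintf("- config hash: %s", report$summary$config_hash),
          sprintf("- patients: %d (%s)", report$summary$n_patients,
                  paste(sprintf("%s=%s", names(report$summary$arms),
                                unlist(report$summary$arms)), collapse = ", ")),
          "")
  for (instr in names(report$fits)) {
    ev <- report$fits[[instr]]$evaluation
    md <- c(md, sprintf("## %s", instr),
            sprintf("- exposure model: %s",
                    paste(report$fits[[instr]]$models$exposure$predictors,
                          collapse = ", ")),
            sprintf("- STAIR+PE model: %s",
                    paste(report$fits[[instr]]$models$stairpe$predictors,
                          collapse = ", ")),
            sprintf("- optimal %d (mean %.2f, SD %.2f) vs suboptimal %d (mean %.2f, SD %.2f)",
                    ev$n_optimal, ev$mean_optimal, ev$sd_optimal,
                    ev$n_suboptimal, ev$mean_suboptimal, ev$sd_suboptimal),
            sprintf("- F(%d, %d) = %.2f, p = %.3g; Cohen's d = %.2f [%.2f, %.2f]",
                    ev$df[1], ev$df[2], ev$F, ev$p, ev$cohens_d,
                    ev$ci[1], ev$ci[2]),
            "")
  }
  md <- c(md, sprintf("Caveat: %s", report$summary$caveat))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
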