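#' Configuration of a synthetic three-arm trial
#'
#' Builds the configuration consumed by [generate_cohort()]. Defaults follow
#' the `"paper"` preset: a 48/51/50 randomization to prolonged exposure (PE),
#' intensified PE (iPE) and STAIR+PE, group mean 16-week improvements matching
#' the trial's reported calculated change, and treatment-by-predictor
#' interactions planted from the published final prediction models (estimate
#' times predictor SD, i.e. outcome points per SD of the predictor). The
#' `"null"` preset removes all interactions and equalizes arm means, giving a
#' cohort with no true differential response.
#'
#' @param preset `"paper"` or `"null"`; sets the defaults below.
#' @param n_pe,n_ipe,n_stairpe arm sizes (each at least 2).
#' @param seed integer seed governing all randomness of the generator.
#' @param arm_mean_change named list per instrument (`CAPS5`, `PCL5`) of named
#'   vectors (`PE`, `iPE`, `STAIRPE`): mean true 16-week improvement in points.
#' @param interaction_effects named list, predictor name to a length-2 vector
#'   `c(exposure = , stairpe = )`: additional true improvement (points) per SD
#'   of that predictor when treated in the respective group. Positive values
#'   mean high scorers do better in that group.
#' @param sd_random_intercept SD of the shared patient severity offset added
#'   to both instruments' latent baselines (points).
#' @param sd_random_slope SD of patient-level slope heterogeneity
#'   (points/week), shared across instruments.
#' @param sd_slope_pcl5 extra instrument-specific slope noise for the PCL-5
#'   (points/week), implementing parallel outcomes driven by one latent
#'   improvement.
#' @param sd_residual occasion-level measurement noise SD (points).
#' @param baseline_mean,baseline_sd named vectors per instrument: moments of
#'   the instrument-specific latent baseline component.
#' @param missing_rate probability in `[0, 1)` that a post-baseline
#'   measurement is missing (completely at random); week 0 is never dropped.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(preset = c("paper", "null"),
                          n_pe = 48, n_ipe = 51, n_stairpe = 50,
                          seed = 1,
                          arm_mean_change = NULL,
                          interaction_effects = NULL,
                          sd_random_intercept = 6,
                          sd_random_slope = 0.3,
                          sd_slope_pcl5 = 0.12,
                          sd_residual = 5,
                          baseline_mean = c(CAPS5 = 41.38, PCL5 = 45),
                          baseline_sd = c(CAPS5 = 6.5, PCL5 = 9),
                          missing_rate = 0.1) {
  preset <- match.arg(preset)
  if (is.null(arm_mean_change)) {
    arm_mean_change <- if (preset == "paper") {
      list(CAPS5 = c(PE = 21.38, iPE = 21.38, STAIRPE = 20.13),
           PCL5  = c(PE = 25.82, iPE = 25.82, STAIRPE = 20.16))
    } else {
      list(CAPS5 = c(PE = 20, iPE = 20, STAIRPE = 20),
           PCL5  = c(PE = 22, iPE = 22, STAIRPE = 22))
    }
  }
  if (is.null(interaction_effects)) {
    interaction_effects <- if (preset == "paper") {
      list(BDI              = c(exposure = -2.5, stairpe = 0),
           MOS              = c(exposure =  2.4, stairpe = 0),
           MINI_axis1_count = c(exposure = -1.6, stairpe = 0),
           CTQ_sexual_abuse = c(exposure = -1.3, stairpe = 0),
           EQ5D             = c(exposure =  0,   stairpe =  1.6),
           DERS             = c(exposure =  0,   stairpe = -2.1),
           CAPS5_baseline   = c(exposure =  0,   stairpe = -2.5))
    } else {
      list()
    }
  }
  cfg <- list(
    preset = preset, n_pe = n_pe, n_ipe = n_ipe, n_stairpe = n_stairpe,
    seed = seed, arm_mean_change = arm_mean_change,
    interaction_effects = interaction_effects,
    sd_random_intercept = sd_random_intercept,
    sd_random_slope = sd_random_slope, sd_slope_pcl5 = sd_slope_pcl5,
    sd_residual = sd_residual,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    missing_rate = missing_rate
  )
  class(cfg) <- "cohort_config"
  .validate_cohort_config(cfg)
  cfg
}

.validate_cohort_config <- function(cfg) {
  for (f in c("n_pe", "n_ipe", "n_stairpe"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 2)
      stop(sprintf("arm size `%s` must be at least 2", f), call. = FALSE)
  for (f in c("sd_random_intercept", "sd_random_slope", "sd_slope_pcl5", "sd_residual"))
    .assert_scalar_number(cfg[[f]], f, lo = 0)
  .assert_scalar_number(cfg$missing_rate, "missing_rate", lo = 0, hi = 1 - 1e-12)
  if (!all(c("CAPS5", "PCL5") %in% names(cfg$arm_mean_change)))
    stop("arm_mean_change needs entries for CAPS5 and PCL5", call. = FALSE)
  for (instr in c("CAPS5", "PCL5"))
    if (!all(c("PE", "iPE", "STAIRPE") %in% names(cfg$arm_mean_change[[instr]])))
      stop("arm_mean_change vectors need PE, iPE and STAIRPE entries", call. = FALSE)
  if (length(cfg$interaction_effects) &&
      is.null(names(cfg$interaction_effects)))
    stop("interaction_effects must be a named list", call. = FALSE)
  invisible(cfg)
}

.arm_group <- function(arm) ifelse(arm == "STAIRPE", "stairpe", "exposure")

#' Generate a synthetic randomized trial cohort
#'
#' Draws a wide baseline-predictor table and a long repeated-outcome table
#' with the statistical structure the downstream analysis assumes: predictors
#' sampled per arm from the catalog moments (moment-matched bounded
#' distributions), per-patient true 16-week improvement under every
#' counterfactual arm equal to the arm mean plus the planted
#' treatment-by-predictor interactions (in points per standardized predictor),
#' linear latent trajectories over weeks 0/4/8/16 with random
#' intercepts/slopes and residual noise, scores clipped to the 0–80 instrument
#' range, and post-baseline measurements dropped completely at random.
#'
#' @param config a [cohort_config()].
#' @param catalog a `predictor_catalog`; defaults to [default_catalog()].
#' @return An object of class `pai_cohort`: list with `patients` (wide data
#'   frame: `patient_id`, `arm`, one column per predictor), `outcomes` (long
#'   data frame: `patient_id`, `instrument`, `week`, `score`), `truth`
#'   (per-patient, per-instrument true improvement under each arm and the
#'   realized latent improvement under the received arm), plus the config and
#'   catalog used.
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 7))
#' nrow(coh$patients)            # 149
#' table(coh$patients$arm)
#' @export
generate_cohort <- function(config, catalog = default_catalog()) {
  stopifnot(inherits(config, "cohort_config"))
  .validate_cohort_config(config)
  if (!inherits(catalog, "predictor_catalog")) stop("`catalog` must be a predictor_catalog", call. = FALSE)
  unknown <- setdiff(names(config$interaction_effects), catalog$name)
  if (length(unknown))
    stop("interaction_effects reference unknown predictors: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  set.seed(as.integer(config$seed) %% .Machine$integer.max)
  arms <- c(rep("PE", config$n_pe), rep("iPE", config$n_ipe),
            rep("STAIRPE", config$n_stairpe))
  n <- length(arms)
  ids <- sprintf("P%03d", seq_len(n))

  # predictors per arm group, catalog moments per group
  X <- matrix(NA_real_, n, nrow(catalog), dimnames = list(NULL, catalog$name))
  grp <- .arm_group(arms)
  for (j in seq_len(nrow(catalog))) {
    sp <- catalog[j, ]
    for (g in c("exposure", "stairpe")) {
      idx <- which(grp == g)
      m <- if (g == "exposure") sp$mean_exposure else sp$mean_stairpe
      s <- if (g == "exposure") sp$sd_exposure else sp$sd_stairpe
      X[idx, j] <- switch(sp$kind,
        continuous = .rbounded_continuous(length(idx), m, s, sp$range_min, sp$range_max),
        binary     = rbinom(length(idx), 1, m),
        count      = .rtruncpois(length(idx), m, sp$range_max))
    }
  }

  # standardized predictors for the planted interactions
  std <- .catalog_standardization(catalog)
  Z <- sweep(sweep(X, 2, std$mean, "-"), 2, std$sd, "/")

  eff <- config$interaction_effects
  lin <- matrix(0, n, 2, dimnames = list(NULL, c("exposure", "stairpe")))
  for (nm in names(eff)) {
    lin[, "exposure"] <- lin[, "exposure"] + eff[[nm]][["exposure"]] * Z[, nm]
    lin[, "stairpe"]  <- lin[, "stairpe"]  + eff[[nm]][["stairpe"]]  * Z[, nm]
  }

  b0 <- rnorm(n, 0, config$sd_random_intercept)
  s_shared <- rnorm(n, 0, config$sd_random_slope)          # points/week
  u_pcl <- rnorm(n, 0, config$sd_slope_pcl5)
  weeks <- c(0, 4, 8, 16)

  truth <- NULL
  outcomes <- NULL
  for (instr in c("CAPS5", "PCL5")) {
    amc <- config$arm_mean_change[[instr]]
    true_arm <- sapply(c("PE", "iPE", "STAIRPE"), function(a)
      amc[[a]] + lin[, .arm_group(a)])
    true_received <- true_arm[cbind(seq_len(n), match(arms, c("PE", "iPE", "STAIRPE")))]
    slope_noise <- 16 * (s_shared + if (instr == "PCL5") u_pcl else 0)
    latent_impr <- true_received + slope_noise
    B <- config$baseline_mean[[instr]] + b0 +
      rnorm(n, 0, config$baseline_sd[[instr]])
    S <- -latent_impr / 16
    obs <- data.frame(
      patient_id = rep(ids, each = length(weeks)),
      instrument = instr,
      week = rep(weeks, n),
      score = rep(B, each = length(weeks)) +
        rep(S, each = length(weeks)) * rep(weeks, n) +
        rnorm(n * length(weeks), 0, config$sd_residual),
      stringsAsFactors = FALSE
    )
    obs$score <- pmin(pmax(obs$score, 0), 80)
    keep <- obs$week == 0 | runif(nrow(obs)) >= config$missing_rate
    outcomes <- rbind(outcomes, obs[keep, ])
    truth <- rbind(truth, data.frame(
      patient_id = ids, instrument = instr,
      true_pe = true_arm[, "PE"], true_ipe = true_arm[, "iPE"],
      true_stairpe = true_arm[, "STAIRPE"],
      latent_improvement = latent_impr, stringsAsFactors = FALSE
    ))
  }

  patients <- data.frame(patient_id = ids, arm = arms, stringsAsFactors = FALSE)
  patients <- cbind(patients, as.data.frame(X))
  rownames(outcomes) <- NULL

  structure(list(patients = patients, outcomes = outcomes, truth = truth,
                 config = config, catalog = catalog),
            class = "pai_cohort")
}

#' @export
print.pai_cohort <- function(x, ...) {
  tab <- table(x$patients$arm)
  cat(sprintf("Synthetic PAI cohort: %d patients (%s), %d predictors\n",
              nrow(x$patients),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              ncol(x$patients) - 2L))
  cat(sprintf("Outcome records: %d (%s), weeks %s\n",
              nrow(x$outcomes),
              paste(unique(x$outcomes$instrument), collapse = "/"),
              paste(sort(unique(x$outcomes$week)), collapse = "/")))
  if (!is.null(x$truth)) cat("Ground-truth improvement table present\n")
  invisible(x)
}

#' True per-patient treatment advantage of a simulated cohort
#'
#' Returns the planted counterfactual advantage of the pooled exposure
#' conditions over STAIR+PE — the same sign convention as the estimated PAI
#' (positive favors exposure). Only defined for simulated cohorts carrying a
#' truth table.
#'
#' @param cohort a `pai_cohort` from [generate_cohort()].
#' @return Data frame `patient_id`, `instrument`, `true_pai`.
#' @export
planted_pai <- function(cohort) {
  stopifnot(inherits(cohort, "pai_cohort"))
  if (is.null(cohort$truth))
    stop("cohort carries no truth table (real-data cohort?)", call. = FALSE)
  tr <- cohort$truth
  data.frame(patient_id = tr$patient_id, instrument = tr$instrument,
             true_pai = (tr$true_pe + tr$true_ipe) / 2 - tr$true_stairpe,
             stringsAsFactors = FALSE)
}

#' Planted optimal-vs-suboptimal contrast of a simulated cohort
#'
#' Computes, from the ground truth alone, the standardized mean difference in
#' realized latent improvement between patients whose randomized arm agrees
#' with the sign of their true advantage ("truly optimal") and those whose arm
#' does not. This is the effect size the estimation pipeline tries to recover.
#'
#' @inheritParams planted_pai
#' @param instrument `"CAPS5"` or `"PCL5"`.
#' @param scores optional calculated change scores (`patient_id`,
#'   `instrument`, `change`); when supplied, the contrast is evaluated on
#'   them instead of on the latent improvement, i.e. on the same outcome
#'   scale the estimation pipeline reports, still using the true flags.
#' @return Cohen's d (numeric scalar).
#' @export
planted_contrast <- function(cohort, instrument = "CAPS5", scores = NULL) {
  tp <- planted_pai(cohort)
  tp <- tp[tp$instrument == instrument, ]
  tr <- cohort$truth[cohort$truth$instrument == instrument, ]
  grp <- .arm_group(cohort$patients$arm[match(tp$patient_id, cohort$patients$patient_id)])
  optimal <- ifelse(tp$true_pai == 0, TRUE,
                    (grp == "exposure") == (tp$true_pai > 0))
  y <- if (is.null(scores)) {
    tr$latent_improvement
  } else {
    sc <- scores[scores$instrument == instrument, ]
    sc$change[match(tp$patient_id, sc$patient_id)]
  }
  .cohens_d(y[optimal], y[!optimal])$d
}

#' Write / read cohort tables as delimited text
#'
#' `write_cohort()` emits `cohort_patients.csv` (wide), `cohort_outcomes.csv`
#' (long: `patient_id,instrument,week,score`) and, for simulated cohorts,
#' `truth.csv`. `read_cohort()` rebuilds a `pai_cohort` from such files; real
#' datasets in the same layout load identically (no truth table).
#'
#' @param cohort a `pai_cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort()` the file paths invisibly; `read_cohort()` a
#'   `pai_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pai_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pf <- file.path(dir, "cohort_patients.csv")
  of <- file.path(dir, "cohort_outcomes.csv")
  utils::write.csv(cohort$patients, pf, row.names = FALSE)
  utils::write.csv(cohort$outcomes, of, row.names = FALSE)
  paths <- c(patients = pf, outcomes = of)
  if (!is.null(cohort$truth)) {
    tf <- file.path(dir, "truth.csv")
    utils::write.csv(cohort$truth, tf, row.names = FALSE)
    paths <- c(paths, truth = tf)
  }
  invisible(paths)
}

#' @rdname write_cohort
#' @param patients_csv,outcomes_csv,truth_csv paths to delimited files; truth
#'   is optional.
#' @export
read_cohort <- function(patients_csv, outcomes_csv, truth_csv = NULL) {
  patients <- utils::read.csv(patients_csv, stringsAsFactors = FALSE)
  outcomes <- utils::read.csv(outcomes_csv, stringsAsFactors = FALSE)
  for (col in c("patient_id", "arm")) if (!col %in% names(patients))
    stop(sprintf("%s: missing column `%s`", patients_csv, col), call. = FALSE)
  for (col in c("patient_id", "instrument", "week", "score"))
    if (!col %in% names(outcomes))
      stop(sprintf("%s: missing column `%s`", outcomes_csv, col), call. = FALSE)
  bad <- setdiff(unique(patients$arm), c("PE", "iPE", "STAIRPE"))
  if (length(bad)) stop("unknown arm labels: ", paste(bad, collapse = ", "), call. = FALSE)
  truth <- if (!is.null(truth_csv)) utils::read.csv(truth_csv, stringsAsFactors = FALSE)
  structure(list(patients = patients, outcomes = outcomes, truth = truth,
                 config = NULL, catalog = NULL),
            class = "pai_cohort")
}
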