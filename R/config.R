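#' Pipeline run configuration
#'
#' Bundles every stage's tunables for [run_pipeline()] and the command-line
#' wrappers. All randomness of a run descends from the single `seed`, which
#' deterministically spawns per-stage substreams.
#'
#' @param seed master seed (mandatory; integer).
#' @param instruments subset of `c("CAPS5", "PCL5")` to analyze.
#' @param alpha,max_rounds,ntree,mtry shadow-selection settings.
#' @param B,direction,rule,tau stepwise/bootstrap settings.
#' @param baseline change-score baseline mode.
#' @param keep_tentative admit tentative predictors to the stepwise stage.
#' @param ci CI method for Cohen's d.
#' @return A list of class `pai_run_config`.
#' @export
run_config <- function(seed = 1, instruments = c("CAPS5", "PCL5"),
                       alpha = 0.01, max_rounds = 1000, ntree = 500,
                       mtry = NULL, B = 100, direction = "both",
                       baseline = "observed", keep_tentative = FALSE,
                       rule = "fulldata_stepwise", tau = 0.5, ci = "normal") {
  .assert_scalar_number(seed, "seed")
  instruments <- match.arg(instruments, c("CAPS5", "PCL5"), several.ok = TRUE)
  cfg <- list(seed = as.integer(seed), instruments = instruments,
              alpha = alpha, max_rounds = max_rounds, ntree = ntree,
              mtry = mtry, B = B, direction = direction, baseline = baseline,
              keep_tentative = keep_tentative, rule = rule, tau = tau, ci = ci)
  class(cfg) <- "pai_run_config"
  cfg
}

#' Read configurations from YAML
#'
#' `run_config_from_yaml()` reads the stage tunables of [run_config()];
#' `cohort_config_from_yaml()` reads the generator fields of
#' [cohort_config()] (`arm_mean_change` as a mapping instrument -> arm ->
#' value, `interaction_effects` as predictor -> \{exposure, stairpe\}).
#' Unknown fields raise an error naming the field.
#'
#' @param path path to a YAML file.
#' @return A `pai_run_config` / `cohort_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), names(formals(run_config)))
  if (length(unknown)) stop("unknown run-config field(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  do.call(run_config, y)
}

#' @rdname run_config_from_yaml
#' @export
cohort_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), names(formals(cohort_config)))
  if (length(unknown)) stop("unknown cohort-config field(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(y$arm_mean_change))
    y$arm_mean_change <- lapply(y$arm_mean_change, unlist)
  if (!is.null(y$interaction_effects))
    y$interaction_effects <- lapply(y$interaction_effects, unlist)
  if (!is.null(y$baseline_mean)) y$baseline_mean <- unlist(y$baseline_mean)
  if (!is.null(y$baseline_sd)) y$baseline_sd <- unlist(y$baseline_sd)
  do.call(cohort_config, y)
}

#' Simulate a cohort and write its tables
#'
#' Command-style wrapper around [generate_cohort()] + [write_cohort()]: logs
#' the seed and config hash and writes the cohort CSVs (plus `truth.csv`).
#'
#' @param config a [cohort_config()] or path to a YAML file of its fields.
#' @param out_dir output directory.
#' @param catalog predictor catalog, defaults to [default_catalog()].
#' @return The generated `pai_cohort`, invisibly.
#' @export
simulate_cohort <- function(config = cohort_config(), out_dir,
                            catalog = default_catalog()) {
  if (is.character(config)) config <- cohort_config_from_yaml(config)
  cohort <- generate_cohort(config, catalog)
  paths <- write_cohort(cohort, out_dir)
  hash <- .config_hash(unclass(config))
  .write_json(list(seed = config$seed, config_hash = hash,
                   n_patients = nrow(cohort$patients),
                   arms = as.list(table(cohort$patients$arm))),
              file.path(out_dir, "simulate_log.json"))
  message(sprintf("simulated %d patients (seed %d, config %s) -> %s",
                  nrow(cohort$patients), config$seed, substr(hash, 1, 8), out_dir))
  invisible(cohort)
}
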