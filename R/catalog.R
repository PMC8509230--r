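#' Baseline predictor catalog
#'
#' A predictor catalog is a declarative description of the baseline variables
#' the synthetic-trial generator samples: one row per predictor with its kind
#' (continuous, binary, count), the instrument's scale bounds, and per-group
#' moments — mean/SD for the pooled exposure arms (PE + iPE) and for STAIR+PE
#' (for binary predictors the "mean" columns carry the proportion).
#'
#' @param name character vector of unique predictor names.
#' @param kind one of `"continuous"`, `"binary"`, `"count"` per predictor.
#' @param range_min,range_max numeric scale bounds, `range_min < range_max`.
#' @param mean_exposure,sd_exposure,mean_stairpe,sd_stairpe per-group moments;
#'   SDs may be `NA` for binary (Bernoulli) and count (Poisson) predictors.
#' @return An object of class `predictor_catalog` (a data frame).
#' @seealso [default_catalog()]
#' @export
predictor_catalog <- function(name, kind, range_min, range_max,
                              mean_exposure, sd_exposure,
                              mean_stairpe, sd_stairpe) {
  kind <- match.arg(kind, c("continuous", "binary", "count"), several.ok = TRUE)
  cat <- data.frame(
    name = as.character(name), kind = kind,
    range_min = as.numeric(range_min), range_max = as.numeric(range_max),
    mean_exposure = as.numeric(mean_exposure), sd_exposure = as.numeric(sd_exposure),
    mean_stairpe = as.numeric(mean_stairpe), sd_stairpe = as.numeric(sd_stairpe),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(cat$name)) stop("predictor names must be unique", call. = FALSE)
  if (any(cat$range_min >= cat$range_max))
    stop("range_min must be strictly below range_max", call. = FALSE)
  bin <- cat$kind == "binary"
  if (any(bin & (cat$mean_exposure < 0 | cat$mean_exposure > 1 |
                 cat$mean_stairpe < 0 | cat$mean_stairpe > 1)))
    stop("binary predictor proportions must lie in [0, 1]", call. = FALSE)
  if (any(!bin & !cat$kind == "count" &
          (is.na(cat$sd_exposure) | is.na(cat$sd_stairpe))))
    stop("continuous predictors need SDs for both groups", call. = FALSE)
  class(cat) <- c("predictor_catalog", "data.frame")
  cat
}

#' Default 24-predictor catalog of the CA-PTSD trial
#'
#' Returns the catalog of 24 baseline predictors measured in the three-arm
#' childhood-abuse-related PTSD trial the generator emulates, with published
#' per-group means/SDs (or proportions) and instrument scale ranges. Ordering
#' follows the descriptive table: patient expectancies, demographics, social
#' support, trauma background, general health, self-reported symptoms, and
#' clinician-assessed symptoms/disorders.
#'
#' Binary predictors carry the group proportion in the mean columns. The
#' axis-1 diagnosis count (MINI interview, PTSD excluded) is modelled as a
#' range-truncated Poisson on 0–10. Age bounds come from the trial's 18–65
#' inclusion window.
#'
#' @return A `predictor_catalog` with exactly 24 rows.
#' @examples
#' cat24 <- default_catalog()
#' nrow(cat24)
#' cat24[cat24$name == "BDI", ]
#' @export
default_catalog <- function() {
  predictor_catalog(
    name = c(
      "expected_burden", "credibility",
      "age", "gender_female", "background_western", "education_high", "employed",
      "MOS",
      "CTQ_emotional_abuse", "CTQ_emotional_neglect",
      "CTQ_physical_abuse", "CTQ_sexual_abuse",
      "EQ5D",
      "BDI", "PTCI", "IIP", "RSES", "DERS", "SDQ5", "psychotropic_medication",
      "SCID2_personality_disorder", "DSPI", "MINI_axis1_count", "CAPS5_baseline"
    ),
    kind = c(
      "continuous", "continuous",
      "continuous", "binary", "binary", "binary", "binary",
      "continuous",
      "continuous", "continuous", "continuous", "continuous",
      "continuous",
      "continuous", "continuous", "continuous", "continuous", "continuous",
      "continuous", "binary",
      "binary", "continuous", "count", "continuous"
    ),
    range_min = c(0, 0, 18, 0, 0, 0, 0, 1, 5, 5, 5, 5, 0, 0, 33, 0, 0, 36, 5, 0, 0, 0, 0, 0),
    range_max = c(10, 10, 65, 1, 1, 1, 1, 5, 25, 25, 25, 25, 100, 63, 231, 4, 30, 180, 25, 1, 1, 36, 10, 80),
    mean_exposure = c(5.98, 6.75, 36.76, 0.7576, 0.3939, 0.2121, 0.4040,
                      3.41, 17.06, 17.74, 13.09, 15.48, 55.56,
                      33.63, 133.26, 1.65, 12.52, 115.63, 6.78, 0.4949,
                      0.5960, 1.78, 2.99, 40.28),
    sd_exposure = c(2.56, 1.89, 11.47, NA, NA, NA, NA,
                    1.10, 6.04, 5.08, 6.97, 7.12, 26.31,
                    10.06, 36.40, 0.62, 5.84, 21.27, 2.93, NA,
                    NA, 3.20, NA, 8.73),
    mean_stairpe = c(6.73, 6.72, 37.07, 0.78, 0.52, 0.18, 0.34,
                     3.32, 17.54, 19.84, 14.42, 15.62, 58.18,
                     34.88, 149.64, 1.70, 11.32, 117.46, 7.64, 0.44,
                     0.62, 3.22, 3.38, 43.56),
    sd_stairpe = c(2.37, 1.74, 12.39, NA, NA, NA, NA,
                   1.04, 6.21, 5.38, 6.36, 7.68, 20.03,
                   11.15, 31.64, 0.50, 6.14, 20.46, 3.11, NA,
                   NA, 5.65, NA, 10.46)
  )
}

#' @export
print.predictor_catalog <- function(x, ...) {
  cat(sprintf("Predictor catalog: %d predictors (%d continuous, %d binary, %d count)\n",
              nrow(x), sum(x$kind == "continuous"), sum(x$kind == "binary"),
              sum(x$kind == "count")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

# Reference moments used to standardize a predictor when planting interaction
# effects (points per SD): midpoint of the two group means; SD likewise, with
# Bernoulli/Poisson SDs derived from the pooled mean.
.catalog_standardization <- function(catalog) {
  m <- (catalog$mean_exposure + catalog$mean_stairpe) / 2
  s <- (catalog$sd_exposure + catalog$sd_stairpe) / 2
  s[catalog$kind == "binary"] <- sqrt(m[catalog$kind == "binary"] *
                                      (1 - m[catalog$kind == "binary"]))
  s[catalog$kind == "count"] <- sqrt(m[catalog$kind == "count"])
  data.frame(name = catalog$name, mean = m, sd = s, stringsAsFactors = FALSE)
}
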