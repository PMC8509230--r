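# Cohen's d with pooled SD and its large-sample standard error
.cohens_d <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2))
  d <- (mean(a) - mean(b)) / sp
  se <- sqrt((1 / n1 + 1 / n2) + d^2 / (2 * (n1 + n2)))
  list(d = d, se = se, n1 = n1, n2 = n2)
}

# CI for d by inverting the noncentral-t distribution of the two-sample t
.noncentral_d_ci <- function(d, n1, n2, level = 0.95) {
  mult <- sqrt(n1 * n2 / (n1 + n2))
  tobs <- d * mult
  df <- n1 + n2 - 2
  lo_p <- (1 + level) / 2; hi_p <- (1 - level) / 2
  bound <- function(target) {
    f <- function(ncp) suppressWarnings(stats::pt(tobs, df, ncp)) - target
    lim <- max(abs(tobs) + 10, 20)
    uniroot(f, c(-lim, lim), extendInt = "yes")$root / mult
  }
  c(bound(lo_p), bound(hi_p))
}

#' Benefit of PAI-optimal randomization
#'
#' Compares the calculated change of patients randomized to their
#' PAI-recommended (optimal) treatment against the rest: group means and
#' sample SDs, a one-way ANOVA F statistic with (1, n-2) degrees of freedom,
#' and Cohen's d (pooled SD) with a 95% confidence interval. The default CI
#' is the normal approximation `d +/- 1.96 * SE(d)` with
#' `SE(d)^2 = 1/n1 + 1/n2 + d^2 / (2 (n1 + n2))`; `ci = "noncentral"` inverts
#' the noncentral-t distribution instead.
#'
#' @param scores change-score data frame (or numeric vector of changes).
#' @param optimal logical vector flagging PAI-optimal patients, aligned with
#'   `scores`.
#' @param instrument label stored on the summary.
#' @param ci `"normal"` or `"noncentral"`.
#' @return An object of class `pai_eval`: group sizes, means, SDs, `F`
#'   (1, n-2), `p`, `cohens_d`, `ci` (length 2), `ci_method`.
#' @export
compare_groups <- function(scores, optimal, instrument = NA_character_,
                           ci = c("normal", "noncentral")) {
  ci <- match.arg(ci)
  change <- if (is.data.frame(scores)) scores$change else as.numeric(scores)
  optimal <- as.logical(optimal)
  stopifnot(length(change) == length(optimal))
  if (sum(optimal) < 2 || sum(!optimal) < 2)
    stop("need at least 2 patients per flag level; all patients concordant?",
         call. = FALSE)
  a <- change[optimal]; b <- change[!optimal]
  fit <- stats::lm(change ~ optimal)
  an <- stats::anova(fit)
  Fv <- an$`F value`[1]
  p <- an$`Pr(>F)`[1]
  dd <- .cohens_d(a, b)
  ci_vals <- if (ci == "normal") {
    dd$d + c(-1, 1) * stats::qnorm(0.975) * dd$se
  } else {
    .noncentral_d_ci(dd$d, dd$n1, dd$n2)
  }
  out <- list(instrument = instrument,
              n_optimal = dd$n1, n_suboptimal = dd$n2,
              mean_optimal = mean(a), sd_optimal = stats::sd(a),
              mean_suboptimal = mean(b), sd_suboptimal = stats::sd(b),
              F = Fv, df = c(1L, length(change) - 2L), p = p,
              cohens_d = dd$d, se_d = dd$se, ci = ci_vals, ci_method = ci)
  class(out) <- "pai_eval"
  out
}

#' @export
print.pai_eval <- function(x, ...) {
  cat(sprintf("Optimal vs suboptimal randomization%s\n",
              if (is.na(x$instrument)) "" else paste0(" (", x$instrument, ")")))
  cat(sprintf("  optimal    n = %3d: mean improvement %6.2f (SD %5.2f)\n",
              x$n_optimal, x$mean_optimal, x$sd_optimal))
  cat(sprintf("  suboptimal n = %3d: mean improvement %6.2f (SD %5.2f)\n",
              x$n_suboptimal, x$mean_suboptimal, x$sd_suboptimal))
  cat(sprintf("  F(%d, %d) = %.2f, p = %.3g\n", x$df[1], x$df[2], x$F, x$p))
  cat(sprintf("  Cohen's d = %.2f [%.2f, %.2f] (%s CI)\n",
              x$cohens_d, x$ci[1], x$ci[2], x$ci_method))
  invisible(x)
}
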