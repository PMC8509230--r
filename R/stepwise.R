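# OLS fit via QR with explicit rank handling; X excludes the intercept.
.ols_fit <- function(X, y) {
  X <- as.matrix(X)
  A <- cbind(`(Intercept)` = 1, X)
  qra <- qr(A)
  if (qra$rank < ncol(A)) {
    drop_idx <- qra$pivot[seq.int(qra$rank + 1L, ncol(A))]
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(A)[drop_idx], collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qra, y)
  resid <- y - A %*% coefs
  list(coef = coefs, rss = sum(resid^2), n = length(y), p = ncol(X))
}

#' Gaussian AIC of an OLS fit
#'
#' The AIC convention used throughout the stepwise stage:
#' `AIC = n * ln(RSS/n) + 2 * (p + 2)`, counting the intercept and the error
#' variance alongside the `p` slope parameters. An intercept-only model with
#' `RSS = n` therefore has AIC exactly 4.
#'
#' @param X design matrix of the slope terms (may have zero columns).
#' @param y response; `length(y) > ncol(X) + 2` required.
#' @return Numeric AIC value.
#' @export
gaussian_aic <- function(X, y) {
  X <- as.matrix(X)
  if (length(y) <= ncol(X) + 2)
    stop("need n > p + 2 observations", call. = FALSE)
  fit <- .ols_fit(X, y)
  .aic_from_rss(fit$rss, fit$n, fit$p)
}

.aic_from_rss <- function(rss, n, p) n * log(rss / n) + 2 * (p + 2)

.model_spec <- function(terms, X, y, group = NA_character_,
                        instrument = NA_character_, path = NULL) {
  Xs <- X[, terms, drop = FALSE]
  fit <- .ols_fit(Xs, y)
  n <- fit$n; p <- fit$p
  sigma2 <- fit$rss / (n - p - 1)
  A <- cbind(1, as.matrix(Xs))
  XtX_inv <- chol2inv(chol(crossprod(A)))
  se <- sqrt(diag(XtX_inv) * sigma2)
  tval <- fit$coef / se
  pval <- 2 * stats::pt(abs(tval), df = n - p - 1, lower.tail = FALSE)
  coefs <- data.frame(term = c("(Intercept)", terms),
                      estimate = unname(fit$coef), std_error = unname(se),
                      t_value = unname(tval), p_value = unname(pval),
                      stringsAsFactors = FALSE)
  out <- list(group = group, instrument = instrument, predictors = terms,
              intercept = unname(fit$coef[1]),
              coefficients = coefs, n = n,
              aic = .aic_from_rss(fit$rss, n, p), rss = fit$rss, path = path)
  class(out) <- "pai_model_spec"
  out
}

#' @export
print.pai_model_spec <- function(x, digits = 3, ...) {
  cat(sprintf("Linear prediction model%s%s: %d predictors, n = %d, AIC = %.2f\n",
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              if (is.na(x$instrument)) "" else paste0(" (", x$instrument, ")"),
              length(x$predictors), x$n, x$aic))
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, digits)
  tab$std_error <- round(tab$std_error, digits)
  tab$t_value <- round(tab$t_value, digits)
  tab$p_value <- signif(tab$p_value, 2)
  names(tab) <- c("", "Estimate", "Std. Error", "t-Value", "p")
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pai_model_spec <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Predict from a linear prediction model
#'
#' @param object a `pai_model_spec`.
#' @param newdata data frame containing the model's predictor columns.
#' @param ... unused.
#' @return Numeric vector of predicted change scores.
#' @export
predict.pai_model_spec <- function(object, newdata, ...) {
  miss <- setdiff(object$predictors, names(newdata))
  if (length(miss)) stop("newdata lacks predictors: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(newdata[, object$predictors, drop = FALSE])
  drop(cbind(1, X) %*% coef(object))
}

#' Stepwise AIC model selection
#'
#' Greedy single-term selection minimizing the Gaussian AIC of
#' [gaussian_aic()]. `direction = "both"` (default) starts from the full
#' candidate model and considers drops and adds each move; `"backward"` only
#' drops from the full model; `"forward"` only adds from the intercept-only
#' model. A move is taken only if it strictly lowers the AIC; among equally
#' good moves the smaller model wins, then lexicographic term order.
#'
#' @param candidates character vector of candidate column names (possibly
#'   empty, yielding the intercept-only model).
#' @param X data frame or matrix holding the candidate columns.
#' @param y response (calculated change scores).
#' @param direction `"both"`, `"backward"` or `"forward"`.
#' @param group,instrument optional labels stored on the result.
#' @return A `pai_model_spec`: selected predictors, OLS coefficient table
#'   (estimate, SE, t, p), `n`, `aic`, and the visited `path` of AIC values.
#' @export
stepwise_aic <- function(candidates, X, y,
                         direction = c("both", "backward", "forward"),
                         group = NA_character_, instrument = NA_character_) {
  direction <- match.arg(direction)
  X <- as.data.frame(X)
  candidates <- as.character(candidates)
  miss <- setdiff(candidates, names(X))
  if (length(miss)) stop("candidates not in X: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (length(y) <= length(candidates) + 2)
    stop("need n > p + 2 for the full candidate model", call. = FALSE)
  Xm <- as.matrix(X[, candidates, drop = FALSE])

  current <- if (direction == "forward") character(0) else candidates
  aic_of <- function(terms) .aic_from_rss(
    .ols_fit(Xm[, terms, drop = FALSE], y)$rss, length(y), length(terms))
  cur_aic <- aic_of(current)
  path <- cur_aic
  tol <- 1e-10
  repeat {
    moves <- list()
    if (direction %in% c("both", "backward"))
      for (t in current) moves[[paste0("- ", t)]] <- setdiff(current, t)
    if (direction %in% c("both", "forward"))
      for (t in setdiff(candidates, current))
        moves[[paste0("+ ", t)]] <- sort(c(current, t))
    if (!length(moves)) break
    aics <- vapply(moves, aic_of, 0)
    best <- min(aics)
    if (best >= cur_aic - tol) break
    cand <- names(aics)[aics <= best + tol]
    sizes <- vapply(moves[cand], length, 0L)
    cand <- cand[sizes == min(sizes)]
    pick <- sort(cand)[1]
    current <- moves[[pick]]
    cur_aic <- aic_of(current)
    path <- c(path, cur_aic)
  }
  .model_spec(current[order(match(current, candidates))], Xm, y,
              group = group, instrument = instrument, path = path)
}

#' Bootstrap stability of stepwise AIC selection
#'
#' Reruns [stepwise_aic()] on `B` bootstrap resamples (rows drawn with
#' replacement) and summarizes, per candidate, how often it was selected and
#' how consistently its coefficient kept one sign when selected. Resamples
#' whose full candidate design is rank deficient are redrawn (at most 5
#' times, then skipped with a warning).
#'
#' @inheritParams stepwise_aic
#' @param B number of bootstrap replicates (default 100).
#' @param seed optional integer seed.
#' @return An object of class `bootstrap_summary`: `B` effective replicates
#'   and a `summary` data frame (`candidate`, `selection_freq`,
#'   `sign_consistency`, `mean_coef`).
#' @export
bootstrap_stepwise <- function(candidates, X, y, B = 100, seed = NULL,
                               direction = "both") {
  if (!is.null(seed)) set.seed(as.integer(seed))
  B <- as.integer(B)
  stopifnot(B >= 1)
  X <- as.data.frame(X)
  candidates <- as.character(candidates)
  n <- length(y)
  sel <- matrix(0L, B, length(candidates), dimnames = list(NULL, candidates))
  signs <- matrix(NA_real_, B, length(candidates), dimnames = list(NULL, candidates))
  coefs <- matrix(NA_real_, B, length(candidates), dimnames = list(NULL, candidates))
  skipped <- 0L
  for (b in seq_len(B)) {
    spec <- NULL
    for (try in seq_len(5)) {
      idx <- sample.int(n, n, replace = TRUE)
      spec <- tryCatch(
        stepwise_aic(candidates, X[idx, , drop = FALSE], y[idx], direction),
        error = function(e) NULL)
      if (!is.null(spec)) break
    }
    if (is.null(spec)) { skipped <- skipped + 1L; next }
    if (length(spec$predictors)) {
      est <- setNames(spec$coefficients$estimate[-1], spec$predictors)
      sel[b, spec$predictors] <- 1L
      signs[b, spec$predictors] <- sign(est)
      coefs[b, spec$predictors] <- est
    }
  }
  eff <- B - skipped
  if (skipped) warning(sprintf("%d bootstrap replicate(s) skipped (persistent rank deficiency)",
                               skipped), call. = FALSE)
  freq <- colSums(sel) / max(eff, 1L)
  sign_cons <- vapply(candidates, function(v) {
    s <- signs[sel[, v] == 1L, v]
    if (!length(s)) return(NA_real_)
    max(table(s)) / length(s)
  }, 0)
  out <- list(B = eff,
              summary = data.frame(candidate = candidates,
                                   selection_freq = unname(freq),
                                   sign_consistency = unname(sign_cons),
                                   mean_coef = unname(colMeans(coefs, na.rm = TRUE)),
                                   stringsAsFactors = FALSE))
  class(out) <- "bootstrap_summary"
  out
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("Bootstrap stepwise-AIC stability over %d replicates\n", x$B))
  print.data.frame(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Final prediction model from candidates and bootstrap diagnostics
#'
#' The default rule refits the full-data stepwise-AIC model over the
#' candidates and attaches the bootstrap summary as a stability diagnostic.
#' The alternative `"frequency_threshold"` rule keeps candidates whose
#' bootstrap selection frequency reaches `tau` and refits plain OLS on them.
#'
#' @inheritParams stepwise_aic
#' @param summary optional [bootstrap_stepwise()] result (required for the
#'   frequency rule).
#' @param rule `"fulldata_stepwise"` (default) or `"frequency_threshold"`.
#' @param tau selection-frequency threshold for the frequency rule.
#' @return A `pai_model_spec` with the bootstrap summary in `$bootstrap`.
#' @export
final_model <- function(candidates, X, y, summary = NULL,
                        rule = c("fulldata_stepwise", "frequency_threshold"),
                        tau = 0.5, direction = "both",
                        group = NA_character_, instrument = NA_character_) {
  rule <- match.arg(rule)
  X <- as.data.frame(X)
  if (rule == "fulldata_stepwise") {
    spec <- stepwise_aic(candidates, X, y, direction, group, instrument)
  } else {
    if (is.null(summary)) stop("frequency_threshold rule needs a bootstrap summary",
                               call. = FALSE)
    keep <- summary$summary$candidate[summary$summary$selection_freq >= tau]
    spec <- .model_spec(as.character(keep),
                        as.matrix(X[, as.character(candidates), drop = FALSE]),
                        y, group = group, instrument = instrument)
  }
  spec$bootstrap <- summary
  spec$rule <- rule
  spec
}
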