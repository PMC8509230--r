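#' Augment a predictor matrix with shadow features
#'
#' Appends, for every surviving original column, one shadow column obtained by
#' independently permuting that column's values. Shadows carry the original
#' association structure of the marginals but are independent of the outcome
#' by construction, providing the empirical importance null of all-relevant
#' selection.
#'
#' @param X numeric matrix or data frame, at least 1 column and 5 rows.
#' @return A matrix with `2k` columns: the originals followed by
#'   `shadow_<name>` permuted copies. Uses the current RNG stream.
#' @export
shadow_augment <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 1 || nrow(X) < 5)
    stop("X needs at least 1 column and 5 rows", call. = FALSE)
  sh <- apply(X, 2, function(col) col[sample.int(length(col))])
  colnames(sh) <- paste0("shadow_", colnames(X))
  cbind(X, sh)
}

# Z from per-tree importance moments, with the degenerate-spread sentinels:
# zero spread with nonzero mean is infinitely convincing evidence (+/-Inf),
# zero over zero carries no evidence (0).
.z_from_moments <- function(mean_imp, sd_imp) {
  z <- ifelse(sd_imp == 0,
              ifelse(mean_imp == 0, 0, sign(mean_imp) * Inf),
              mean_imp / sd_imp)
  names(z) <- names(mean_imp)
  z
}

#' Permutation-importance Z-scores from a random regression forest
#'
#' Fits a random forest regression of the (continuous) change score on the
#' augmented design and returns, per column, the importance Z-score: the mean
#' over trees of the out-of-bag MSE increase caused by permuting the column,
#' divided by the spread of that quantity across trees.
#'
#' @param X_aug augmented design (originals + shadows), numeric matrix.
#' @param y continuous outcome.
#' @param ntree number of trees (default 500).
#' @param mtry features tried per split; default `ceiling(p/3)` of the
#'   augmented design.
#' @return Named numeric vector of Z-scores, one per column of `X_aug`.
#' @export
importance_z <- function(X_aug, y, ntree = 500, mtry = NULL) {
  X_aug <- as.matrix(X_aug)
  if (!is.numeric(y) || length(y) != nrow(X_aug))
    stop("y must be numeric with one value per row of X_aug", call. = FALSE)
  if (is.null(mtry)) mtry <- ceiling(ncol(X_aug) / 3)
  rf <- randomForest::randomForest(X_aug, y, ntree = ntree, mtry = mtry,
                                   importance = TRUE)
  mean_imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  # importanceSD is the standard error over trees; rescale to the SD over
  # trees so Z is the mean per-tree accuracy loss over its SD, independent of
  # the forest size
  sd_imp <- rf$importanceSD * sqrt(ntree)
  .z_from_moments(mean_imp, sd_imp)
}

#' All-relevant predictor selection with shadow features
#'
#' From-scratch implementation of the shadow-feature selection loop: each
#' round the surviving predictors are augmented with freshly permuted shadow
#' copies, a random regression forest yields importance Z-scores, and every
#' original whose Z-score exceeds the maximum shadow Z-score records a hit.
#' After each round, each still-undecided predictor's hit count is tested
#' against Binomial(rounds, 1/2) — one-sided upward for confirmation,
#' one-sided downward for rejection — with a Bonferroni correction over the
#' full candidate set. Significantly many hits confirm the predictor;
#' significantly few reject it and delete its column (and shadow) from the
#' design. The loop stops when no predictor is left tentative or after
#' `max_rounds` rounds.
#'
#' @param X candidate predictor matrix or data frame (columns named).
#' @param y continuous outcome (the calculated change score).
#' @param alpha significance level of the binomial decision test (default
#'   0.01).
#' @param max_rounds maximum number of rounds (default 1000).
#' @param ntree,mtry forest size per round; see [importance_z()].
#' @param seed optional integer making the whole run reproducible.
#' @return An object of class `selection_result`: character vectors
#'   `confirmed`, `tentative`, `rejected` (a partition of the candidates), a
#'   `state` data frame (per predictor: hits, rounds in play, decision, the
#'   round it was decided), `z_history` (per round: originals' Z-scores and
#'   the shadow min/mean/max), and the call parameters.
#' @export
shadow_select <- function(X, y, alpha = 0.01, max_rounds = 1000,
                          ntree = 500, mtry = NULL, seed = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have column names", call. = FALSE)
  .assert_scalar_number(alpha, "alpha", lo = 1e-12, hi = 1 - 1e-12)
  if (!is.null(seed)) set.seed(as.integer(seed))
  vars <- colnames(X)
  decision <- setNames(rep("Tentative", length(vars)), vars)
  hits <- setNames(integer(length(vars)), vars)
  rounds_in_play <- setNames(integer(length(vars)), vars)
  decided_round <- setNames(rep(NA_integer_, length(vars)), vars)
  z_history <- vector("list", 0L)

  r <- 0L
  while (any(decision == "Tentative") && r < max_rounds) {
    r <- r + 1L
    active <- vars[decision != "Rejected"]
    aug <- shadow_augment(X[, active, drop = FALSE])
    z <- importance_z(aug, y, ntree = ntree, mtry = mtry)
    z_orig <- z[active]
    z_shadow <- z[paste0("shadow_", active)]
    bar <- max(z_shadow)
    hit <- z_orig > bar
    hits[active] <- hits[active] + as.integer(hit)
    rounds_in_play[active] <- rounds_in_play[active] + 1L
    z_history[[r]] <- list(z = z_orig,
                           shadow = c(min = min(z_shadow),
                                      mean = mean(z_shadow[is.finite(z_shadow)]),
                                      max = bar))

    undecided <- vars[decision == "Tentative"]
    k <- length(vars)                 # Bonferroni over the full candidate set
    for (v in undecided) {
      p_acc <- stats::pbinom(hits[[v]] - 1L, rounds_in_play[[v]], 0.5,
                             lower.tail = FALSE)
      p_rej <- stats::pbinom(hits[[v]], rounds_in_play[[v]], 0.5)
      if (p_acc * k < alpha) {
        decision[[v]] <- "Confirmed"; decided_round[[v]] <- r
      } else if (p_rej * k < alpha) {
        decision[[v]] <- "Rejected"; decided_round[[v]] <- r
      }
    }
  }

  state <- data.frame(predictor = vars, hits = unname(hits),
                      rounds = unname(rounds_in_play),
                      decision = unname(decision),
                      decided_round = unname(decided_round),
                      stringsAsFactors = FALSE)
  out <- list(confirmed = vars[decision == "Confirmed"],
              tentative = vars[decision == "Tentative"],
              rejected = vars[decision == "Rejected"],
              state = state, z_history = z_history,
              rounds_completed = r,
              params = list(alpha = alpha, max_rounds = max_rounds,
                            ntree = ntree, mtry = mtry, seed = seed))
  class(out) <- "selection_result"
  out
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Shadow-feature selection: %d rounds, alpha %.3g (Bonferroni over undecided)\n",
              x$rounds_completed, x$params$alpha))
  cat(sprintf("  Confirmed (%d): %s\n", length(x$confirmed),
              paste(x$confirmed, collapse = ", ")))
  cat(sprintf("  Tentative (%d): %s\n", length(x$tentative),
              paste(x$tentative, collapse = ", ")))
  cat(sprintf("  Rejected  (%d): %s\n", length(x$rejected),
              paste(x$rejected, collapse = ", ")))
  invisible(x)
}

#' Plot the Z-score history of a shadow-feature selection
#'
#' Box plots of per-round importance Z-scores per predictor, colored by final
#' decision (confirmed green, tentative yellow, rejected red) with the shadow
#' min/mean/max in blue — the conventional display of all-relevant selection
#' output.
#'
#' @param x a `selection_result`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.selection_result <- function(x, ...) {
  zs <- lapply(x$z_history, `[[`, "z")
  sh <- do.call(rbind, lapply(x$z_history, `[[`, "shadow"))
  vars <- x$state$predictor
  zmat <- lapply(vars, function(v) {
    vals <- vapply(zs, function(z) if (v %in% names(z)) z[[v]] else NA_real_, 0)
    vals[is.finite(vals)]
  })
  names(zmat) <- vars
  shadow_cols <- list(shadow_min = sh[, "min"], shadow_mean = sh[, "mean"],
                      shadow_max = sh[, "max"])
  all <- c(shadow_cols, zmat)
  med <- vapply(all, function(v) if (length(v)) stats::median(v) else -Inf, 0)
  all <- all[order(med)]
  dec <- setNames(x$state$decision, x$state$predictor)
  col <- vapply(names(all), function(nm) {
    if (startsWith(nm, "shadow_")) "steelblue"
    else switch(dec[[nm]], Confirmed = "forestgreen",
                Tentative = "gold", Rejected = "firebrick")
  }, "")
  graphics::boxplot(all, las = 2, col = col, ylab = "importance Z-score",
                    cex.axis = 0.6, ...)
  invisible(x)
}
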