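#' Fit a random forest predicting sqrt-frailty from the immune profile
#'
#' Trains a regression forest per sex stratum on the square-root
#' transformed frailty index, with the absolute counts of all enumerated
#' phenotypes plus age, CMV serostatus and the flow-measurement date
#' (encoded as days since the earliest draw) as predictors. Out-of-bag
#' (OOB) predictions give the OOB mean squared error and the percentage of
#' explained variance, PEV = 100 (1 - MSE_oob / var(response)).
#'
#' @param cm count matrix (participants x phenotypes).
#' @param cohort cohort data.frame (`participant_id`, `sex`, `age`,
#'   `cmv_status`, `blood_draw_date`, `frailty_index`).
#' @param sex_stratum `"M"` or `"F"` (or NULL for the pooled cohort).
#' @param n_trees,mtry forest settings; `mtry` defaults to p/3 (regression
#'   convention).
#' @param seed seed making the forest reproducible.
#' @return object of class `frailty_forest`: list with the fitted
#'   `randomForest`, `x`, `y`, `mse_oob`, `pev`, `settings`.
#' @export
fit_frailty_forest <- function(cm, cohort, sex_stratum = NULL,
                               n_trees = 1000L, mtry = NULL, seed = 1L) {
  cohort <- as.data.frame(cohort)
  if (!is.null(sex_stratum))
    cohort <- cohort[cohort$sex == sex_stratum, , drop = FALSE]
  cohort <- analysis_set(add_sqrt_frailty(cohort))
  if (!nrow(cohort)) stop("empty analysis set")
  idx <- match(cohort$participant_id, rownames(cm))
  if (anyNA(idx)) stop("count matrix is missing participants")
  x <- as.data.frame(cm[idx, , drop = FALSE])
  x$age <- cohort$age
  x$cmv <- as.numeric(cohort$cmv_status == "seropositive")
  if ("blood_draw_date" %in% names(cohort)) {
    d <- as.Date(cohort$blood_draw_date)
    x$measurement_date <- as.numeric(d - min(d))
  }
  drop_cols <- vapply(x, function(v) all(is.na(v)), TRUE)
  if (any(drop_cols)) {
    warning("dropping predictors with no observed values: ",
            paste(names(x)[drop_cols], collapse = ", "))
    x <- x[, !drop_cols, drop = FALSE]
  }
  complete <- stats::complete.cases(x)
  if (!all(complete)) {
    warning(sum(!complete), " participant(s) dropped for missing ",
            "predictor values")
    x <- x[complete, , drop = FALSE]
    cohort <- cohort[complete, , drop = FALSE]
  }
  y <- cohort$frailty_sqrt
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(x) / 3))
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                   mtry = mtry, keep.inbag = TRUE,
                                   keep.forest = TRUE)
  mse_oob <- mean((y - rf$predicted)^2)
  pev <- 100 * (1 - mse_oob / stats::var(y))
  structure(list(forest = rf, x = x, y = y, mse_oob = mse_oob, pev = pev,
                 settings = list(n_trees = n_trees, mtry = mtry,
                                 seed = seed, sex_stratum = sex_stratum)),
            class = "frailty_forest")
}

add_sqrt_frailty <- function(cohort) {
  if (!"frailty_sqrt" %in% names(cohort)) {
    if (!"frailty_index" %in% names(cohort))
      stop("cohort lacks a frailty index")
    cohort$frailty_sqrt <- sqrt_transform(cohort$frailty_index)
  }
  cohort
}

#' @export
print.frailty_forest <- function(x, ...) {
  cat(sprintf(
    "Frailty forest (%s): %d trees, mtry %d, n = %d\n  OOB MSE = %.5f, PEV = %.1f%%\n",
    if (is.null(x$settings$sex_stratum)) "pooled" else x$settings$sex_stratum,
    x$settings$n_trees, x$settings$mtry, length(x$y), x$mse_oob, x$pev))
  invisible(x)
}

## OOB-averaged predictions from per-tree predictions and the inbag matrix
oob_mean_prediction <- function(pred_by_tree, inbag) {
  oob <- inbag == 0
  rowSums(pred_by_tree * oob) / pmax(rowSums(oob), 1)
}

#' Permutation importance as percentage increase in MSE
#'
#' For each predictor, its column is permuted and the out-of-bag MSE
#' recomputed from the per-tree predictions; the importance is the raw
#' percentage increase, 100 (MSE_permuted - MSE_oob) / MSE_oob, averaged
#' over `n_repeats` independent permutations, with the standard error over
#' repeats. (This is the verbal definition of the measure; the SD-scaled
#' variant many implementations report by default can be obtained with
#' `sd_scaled = TRUE`, where the raw per-repeat MSE increases are divided
#' by their standard deviation.)
#'
#' @param fit a `frailty_forest`.
#' @param predictors which predictors (default all).
#' @param n_repeats permutation repeats per predictor.
#' @param seed seed.
#' @param sd_scaled report the SD-scaled variant instead of raw percent.
#' @return data.frame with `predictor`, `pct_inc_mse`, `se`, sorted as the
#'   predictors appear in the model.
#' @export
pct_inc_mse <- function(fit, predictors = NULL, n_repeats = 5L, seed = 1L,
                        sd_scaled = FALSE) {
  stopifnot(inherits(fit, "frailty_forest"))
  if (is.null(predictors)) predictors <- colnames(fit$x)
  bad <- setdiff(predictors, colnames(fit$x))
  if (length(bad)) stop("unknown predictor(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  inbag <- fit$forest$inbag
  n <- nrow(fit$x)
  out <- data.frame(predictor = predictors, pct_inc_mse = NA_real_,
                    se = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(predictors)) {
    pr <- predictors[k]
    vals <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      xp <- fit$x
      xp[[pr]] <- xp[[pr]][sample.int(n)]
      pred <- stats::predict(fit$forest, newdata = xp,
                             predict.all = TRUE)$individual
      mse_perm <- mean((fit$y - oob_mean_prediction(pred, inbag))^2)
      vals[r] <- 100 * (mse_perm - fit$mse_oob) / fit$mse_oob
    }
    if (sd_scaled) {
      s <- stats::sd(vals)
      out$pct_inc_mse[k] <- if (s > 0) mean(vals) / s else 0
      out$se[k] <- if (s > 0) 1 / sqrt(n_repeats) else 0
    } else {
      out$pct_inc_mse[k] <- mean(vals)
      out$se[k] <- stats::sd(vals) / sqrt(n_repeats)
    }
  }
  out
}

#' Rank variable importances and flag the strongest
#'
#' @param importance data.frame from [pct_inc_mse()].
#' @param threshold_pct importance threshold above which variables are
#'   flagged (the convention used when plotting is to embolden variables
#'   with more than a 50% MSE increase).
#' @return the importance table sorted by decreasing importance (ties
#'   broken by predictor-name order) with a logical `flagged` column.
#' @export
rank_importance <- function(importance, threshold_pct = 50) {
  ord <- order(-importance$pct_inc_mse, importance$predictor)
  out <- importance[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$flagged <- out$pct_inc_mse > threshold_pct
  rownames(out) <- NULL
  out
}

#' Partial dependence of the forest prediction on one or two predictors
#'
#' The partial dependence at a grid point is the forest prediction averaged
#' over the observed data with the target predictor(s) fixed at that point.
#' The grid covers the central range of the data (1st to 99th percentile by
#' default, mirroring plots restricted to the part containing most of the
#' data); predictor deciles are returned for axis rugs.
#'
#' @param fit a `frailty_forest`.
#' @param predictors one or two predictor names.
#' @param grid_size points per predictor.
#' @param trim quantile range covered by the grid.
#' @return data.frame of grid coordinates and the partial-dependence
#'   response `yhat` (on the sqrt-frailty scale), with attribute `deciles`.
#' @export
partial_dependence <- function(fit, predictors, grid_size = 25L,
                               trim = c(0.01, 0.99)) {
  stopifnot(inherits(fit, "frailty_forest"),
            length(predictors) %in% 1:2)
  bad <- setdiff(predictors, colnames(fit$x))
  if (length(bad)) stop("unknown predictor(s): ", paste(bad, collapse = ", "))
  grids <- lapply(predictors, function(pr) {
    q <- stats::quantile(fit$x[[pr]], trim, names = FALSE)
    seq(q[1], q[2], length.out = grid_size)
  })
  names(grids) <- predictors
  pts <- expand.grid(grids)
  yhat <- vapply(seq_len(nrow(pts)), function(i) {
    xg <- fit$x
    for (pr in predictors) xg[[pr]] <- pts[i, pr]
    mean(stats::predict(fit$forest, newdata = xg))
  }, 0)
  out <- cbind(pts, yhat = yhat)
  attr(out, "deciles") <- lapply(stats::setNames(predictors, predictors),
                                 function(pr)
                                   stats::quantile(fit$x[[pr]], 1:9 / 10))
  out
}

#' Summary report of a frailty forest
#'
#' @param fit a `frailty_forest`.
#' @param n_repeats,seed passed to [pct_inc_mse()].
#' @param threshold_pct passed to [rank_importance()].
#' @return list of class `forest_report` with `pev`, `mse_oob`,
#'   `importance` (ranked), `settings`.
#' @export
forest_report <- function(fit, n_repeats = 5L, seed = 1L,
                          threshold_pct = 50) {
  imp <- pct_inc_mse(fit, n_repeats = n_repeats, seed = seed)
  structure(list(pev = fit$pev, mse_oob = fit$mse_oob,
                 importance = rank_importance(imp, threshold_pct),
                 settings = fit$settings),
            class = "forest_report")
}

#' @export
print.forest_report <- function(x, ...) {
  cat(sprintf("Forest report: PEV = %.1f%%, OOB MSE = %.5f\n", x$pev,
              x$mse_oob))
  print(utils::head(x$importance, 10))
  invisible(x)
}
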