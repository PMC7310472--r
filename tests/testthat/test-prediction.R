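## small synthetic regression fixtures built directly on a cohort skeleton
make_forest_fixture <- function(n = 200, signal = TRUE, seed = 90,
                                noise_sd = 0.02) {
  set.seed(seed)
  cm <- cbind(sig = runif(n, 0, 1), noise1 = rnorm(n), noise2 = rnorm(n))
  rownames(cm) <- sprintf("p%03d", seq_len(n))
  fi <- if (signal) (0.1 + 0.8 * cm[, "sig"])^2 else runif(n, 0, 0.6)
  fi <- pmin(pmax(fi + rnorm(n, 0, noise_sd), 0), 1)
  cohort <- data.frame(participant_id = rownames(cm), sex = "F",
                       age = runif(n, 60, 87),
                       cmv_status = sample(c("seronegative",
                                             "seropositive"), n, TRUE),
                       frailty_index = fi)
  list(cm = cm, cohort = cohort)
}

test_that("PEV identity holds and the no-signal forest explains nothing", {
  fx <- make_forest_fixture(150, signal = FALSE, seed = 91)
  fit <- fit_frailty_forest(fx$cm, fx$cohort, n_trees = 300, seed = 92)
  expect_equal(fit$pev, 100 * (1 - fit$mse_oob / var(fit$y)))
  expect_lt(abs(fit$pev), 15)  # pure noise: no real explained variance
  ## identical seed and data -> identical report
  fit2 <- fit_frailty_forest(fx$cm, fx$cohort, n_trees = 300, seed = 92)
  expect_identical(fit$forest$predicted, fit2$forest$predicted)
  expect_identical(pct_inc_mse(fit, "sig", n_repeats = 2, seed = 1),
                   pct_inc_mse(fit2, "sig", n_repeats = 2, seed = 1))
})

test_that("a strong monotone signal is captured (PEV > 80) and ranked
           first", {
  fx <- make_forest_fixture(500, signal = TRUE, seed = 93, noise_sd = 0)
  fit <- fit_frailty_forest(fx$cm, fx$cohort, n_trees = 400, mtry = 3,
                            seed = 94)
  expect_gt(fit$pev, 80)
  imp <- pct_inc_mse(fit, n_repeats = 3, seed = 95)
  ranked <- rank_importance(imp)
  expect_identical(ranked$predictor[1], "sig")
})

test_that("duplicating a predictor dilutes its individual importance", {
  ## same predictor count and mtry in both forests, and enough response
  ## noise that the OOB baseline MSE is comparable, so the raw percentage
  ## increases are on the same footing
  set.seed(96)
  n <- 300
  sig <- runif(n)
  noise <- matrix(rnorm(4 * n), n)
  fi <- pmin(pmax(0.2 + 0.4 * sig + rnorm(n, 0, 0.12), 0), 1)
  cohort <- data.frame(participant_id = sprintf("p%03d", 1:n), sex = "F",
                       age = runif(n, 60, 87),
                       cmv_status = "seronegative", frailty_index = fi)
  cm1 <- cbind(sig = sig, n1 = noise[, 1], n2 = noise[, 2],
               n3 = noise[, 3], n4 = noise[, 4])
  cm2 <- cbind(sig = sig, n1 = noise[, 1], n2 = noise[, 2],
               n3 = noise[, 3], sig_copy = sig + rnorm(n, 0, 1e-4))
  rownames(cm1) <- rownames(cm2) <- cohort$participant_id
  fit1 <- fit_frailty_forest(cm1, cohort, n_trees = 500, mtry = 2,
                             seed = 97)
  fit2 <- fit_frailty_forest(cm2, cohort, n_trees = 500, mtry = 2,
                             seed = 97)
  imp1 <- pct_inc_mse(fit1, n_repeats = 5, seed = 98)
  i1 <- imp1$pct_inc_mse[imp1$predictor == "sig"]
  i2 <- pct_inc_mse(fit2, "sig", n_repeats = 5, seed = 98)$pct_inc_mse
  expect_lt(i2, i1)  # directional check only
  ## pure-noise predictors sit near zero importance
  expect_lt(max(abs(imp1$pct_inc_mse[grepl("^n[1-4]", imp1$predictor)])),
            10)
})

test_that("importance ranking flags variables above the threshold with a
           stable tie rule", {
  imp <- data.frame(predictor = c("b", "a", "c", "d"),
                    pct_inc_mse = c(60, 120, 40, 60),
                    se = 1)
  ranked <- rank_importance(imp, threshold_pct = 50)
  expect_identical(ranked$predictor, c("a", "b", "d", "c"))  # ties by name
  expect_identical(ranked$flagged, c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(rank_importance(imp, threshold_pct = 200)$flagged))
})

test_that("partial dependence is flat without signal and monotone with
           one", {
  fx <- make_forest_fixture(250, signal = TRUE, seed = 99)
  fit <- fit_frailty_forest(fx$cm, fx$cohort, n_trees = 300, seed = 100)
  pd <- partial_dependence(fit, "sig", grid_size = 15)
  expect_true(all(is.finite(pd$yhat)))
  ## planted increasing effect: non-decreasing up to forest noise
  expect_gt(cor(pd$sig, pd$yhat, method = "spearman"), 0.95)
  expect_gt(max(pd$yhat) - min(pd$yhat), 0.2)
  expect_length(attr(pd, "deciles")$sig, 9)
  ## grid respects the central-range trim
  expect_gte(min(pd$sig), quantile(fit$x$sig, 0.01) - 1e-9)
  expect_lte(max(pd$sig), quantile(fit$x$sig, 0.99) + 1e-9)
  ## near-constant response -> essentially flat curve
  fx0 <- make_forest_fixture(150, signal = FALSE, seed = 101,
                             noise_sd = 0)
  fx0$cohort$frailty_index <- 0.25
  fit0 <- suppressWarnings(
    fit_frailty_forest(fx0$cm, fx0$cohort, n_trees = 200, seed = 102))
  pd0 <- partial_dependence(fit0, "sig", grid_size = 10)
  expect_lt(max(pd0$yhat) - min(pd0$yhat), 1e-8)
})

test_that("a 2-D surface of additive effects is close to the sum of its
           1-D curves", {
  set.seed(103)
  n <- 400
  cm <- cbind(a = runif(n), b = runif(n), noise = rnorm(n))
  rownames(cm) <- sprintf("p%03d", seq_len(n))
  fi <- pmin(pmax((0.2 + 0.3 * cm[, "a"] + 0.3 * cm[, "b"])^2, 0), 1)
  cohort <- data.frame(participant_id = rownames(cm), sex = "F",
                       age = runif(n, 60, 87),
                       cmv_status = "seronegative", frailty_index = fi)
  fit <- fit_frailty_forest(cm, cohort, n_trees = 300, seed = 104)
  g <- 7
  pd_a <- partial_dependence(fit, "a", grid_size = g)
  pd_b <- partial_dependence(fit, "b", grid_size = g)
  pd_ab <- partial_dependence(fit, c("a", "b"), grid_size = g)
  additive <- outer(pd_a$yhat, pd_b$yhat, `+`) - mean(fit$y)
  surface <- matrix(pd_ab$yhat, g, g)  # a varies fastest
  expect_lt(max(abs(surface - additive)), 0.08)
  expect_error(partial_dependence(fit, c("a", "b", "noise")))
  expect_error(partial_dependence(fit, "zzz"), "zzz")
})

test_that("forests drop unusable predictors with a warning", {
  fx <- make_forest_fixture(100, seed = 105)
  cm <- cbind(fx$cm, dead = NA_real_)
  expect_warning(fit <- fit_frailty_forest(cm, fx$cohort, n_trees = 100,
                                           seed = 106),
                 "dead")
  expect_false("dead" %in% colnames(fit$x))
  expect_error(pct_inc_mse(fit, "dead"), "dead")
})
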