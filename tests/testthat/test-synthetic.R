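test_that("default cohort has the designed composition and is
           seed-reproducible", {
  sim <- generate_cohort(cohort_spec(seed = 60))
  coh <- sim$cohort
  expect_equal(sum(coh$sex == "M"), 145)
  expect_equal(sum(coh$sex == "F"), 144)
  expect_true(all(coh$age >= 60 & coh$age <= 87))
  expect_equal(sum(coh$frailty_missing & coh$sex == "M"), 5)
  expect_equal(sum(coh$frailty_missing & coh$sex == "F"), 7)
  expect_equal(ncol(sim$concentrations), 37)
  expect_true(all(sim$concentrations >= 0))
  expect_equal(sort(unique(coh$age_group)), 1:4)
  ## equal thirds per selection stratum (within 1)
  expect_true(max(abs(table(coh$stratum) - nrow(coh) / 3)) <= 1)
  ## byte-identical reproduction under the same seed
  sim2 <- generate_cohort(cohort_spec(seed = 60))
  expect_identical(sim, sim2)
  ## and a different seed changes the draws
  sim3 <- generate_cohort(cohort_spec(seed = 61))
  expect_false(identical(sim$concentrations, sim3$concentrations))
})

test_that("cohort invariants: deficits, dates, spec validation", {
  sim <- generate_cohort(cohort_spec(seed = 62))
  coh <- sim$cohort
  d <- as.matrix(coh[, grep("^deficit_", names(coh))])
  expect_equal(ncol(d), 36)
  expect_true(all(d %in% c(0, 1) | is.na(d)))
  expect_true(all(is.na(coh$frailty_index) == coh$frailty_missing))
  ## blood draw precedes (on average by ~1.6y) the frailty assessment gap
  gap <- as.numeric(coh$blood_draw_date - coh$frailty_assessment_date) /
    365.25
  expect_gt(mean(gap), 1.3); expect_lt(mean(gap), 1.9)
  expect_error(cohort_spec(strata_fractions = c(0.5, 0.4, 0.2)))
  expect_error(cohort_spec(effect_profile = list(men = c(neutrophils = 1.2),
                                                 women = c())),
               "rho")
})

test_that("zero effect profile gives near-zero within-block correlations", {
  spec <- cohort_spec(n_men = 0, n_women = 3000,
                      missing_frailty = c(men = 0, women = 0),
                      effect_profile = list(men = c(), women = c()),
                      seed = 63)
  sim <- generate_cohort(spec)
  coh <- sim$cohort
  coh$cmv_status <- factor(ifelse(coh$cmv_positive_true, "pos", "neg"))
  blocks <- make_blocks(coh, c("age_group", "cmv_status"))
  rho <- vapply(colnames(sim$concentrations), function(ph)
    as.numeric(weighted_rho(sim$concentrations[, ph], coh$frailty_index,
                            blocks)), 0)
  expect_lt(max(abs(rho)), 0.08)
})

test_that("a strong single-phenotype effect is recovered (rho 0.9)", {
  spec <- cohort_spec(n_men = 0, n_women = 2000,
                      missing_frailty = c(men = 0, women = 0),
                      effect_profile = list(men = c(),
                                            women = c(neutrophils = 0.9)),
                      seed = 64)
  sim <- generate_cohort(spec)
  coh <- sim$cohort
  coh$cmv_status <- factor(ifelse(coh$cmv_positive_true, "pos", "neg"))
  blocks <- make_blocks(coh, c("age_group", "cmv_status"))
  r <- as.numeric(weighted_rho(sim$concentrations[, "neutrophils"],
                               coh$frailty_index, blocks))
  expect_lt(abs(r - 0.9), 0.05)
})

test_that("rank-correlation recovery converges at n = 5000", {
  spec <- cohort_spec(n_men = 0, n_women = 5000,
                      missing_frailty = c(men = 0, women = 0),
                      effect_profile = list(men = c(),
                                            women = c(t_cd56pos = -0.3)),
                      seed = 65)
  sim <- generate_cohort(spec)
  coh <- sim$cohort
  coh$cmv_status <- factor(ifelse(coh$cmv_positive_true, "pos", "neg"))
  blocks <- make_blocks(coh, c("age_group", "cmv_status"))
  r <- as.numeric(weighted_rho(sim$concentrations[, "t_cd56pos"],
                               coh$frailty_index, blocks))
  expect_lt(abs(r - (-0.3)), 0.03)
})

test_that("the copula calibration matches the sin-transform oracle in the
           continuous no-selection limit", {
  ## oracle: for bivariate normal latents with Pearson correlation
  ## r = 2 sin(pi rho / 6), the Spearman correlation of any monotone
  ## transforms is rho -- checked by direct simulation, independent of the
  ## package's calibration machinery
  set.seed(66)
  rho_target <- 0.4
  r <- 2 * sin(pi * rho_target / 6)
  n <- 200000
  h <- rnorm(n)
  g <- r * h + sqrt(1 - r^2) * rnorm(n)
  expect_lt(abs(cor(exp(g), pnorm(h), method = "spearman") - rho_target),
            0.01)
})

test_that("unattainable targets fail loudly, naming the culprit", {
  spec <- cohort_spec(n_men = 0, n_women = 100,
                      missing_frailty = c(men = 0, women = 0),
                      effect_profile = list(men = c(),
                                            women = c(neutrophils = 0.999)),
                      seed = 67)
  expect_error(generate_cohort(spec), "neutrophils")
})

test_that("tube event counts follow the concentration x volume law", {
  part <- list(leaf_concentrations = c(neutrophils = 4000),
               spec = NULL)
  counts <- vapply(1:100, function(s) {
    ev <- generate_tube_events(part, "trucount", seed = s,
                               volume_ul = 50, beads_per_tube = 50000,
                               acquisition_fraction = 0.01)
    sum(ev$CD3 < exp(5))  # cells (beads are CD3 bright)
  }, 0)
  ## expectation: 4000 cells/uL x 50 uL x 0.01 = 2000 events
  expect_lt(abs(mean(counts) - 2000), 3 * sqrt(2000 / 100))
  ## beads: 50000 x 0.01 = 500 expected
  ev <- generate_tube_events(part, "trucount", seed = 1, volume_ul = 50,
                             beads_per_tube = 50000,
                             acquisition_fraction = 0.01)
  expect_lt(abs(count_bead_events(ev) - 500), 4 * sqrt(500))
  ## zero concentration -> zero events of that population
  part0 <- list(leaf_concentrations = c(neutrophils = 0, b_naive = 1000))
  ev0 <- generate_tube_events(part0, "trucount", seed = 2,
                              acquisition_fraction = 0.05)
  res <- classify_events(ev0)
  expect_equal(unname(res$counts["neutrophils"]), 0L)
  expect_gt(res$counts[["b_naive"]], 0)
  ## the plain tube carries no beads; zero volume errors
  evf <- generate_tube_events(part0, "falcon", seed = 3,
                              acquisition_fraction = 0.05)
  expect_equal(count_bead_events(cbind(evf, CD19 = exp(2),
                                       CD56 = exp(2), CD16 = exp(2),
                                       CD38 = exp(2), HLADR = exp(2),
                                       IgD = exp(2))), 0L)
  expect_error(generate_tube_events(part0, "trucount", volume_ul = 0),
               "volume")
  ## determinism under a fixed seed
  e1 <- generate_tube_events(part0, "trucount", seed = 9)
  e2 <- generate_tube_events(part0, "trucount", seed = 9)
  expect_identical(e1, e2)
})

test_that("CMV titer sampling matches mixture moments and is
           deterministic", {
  params <- list(meanlog = c(0, 2), sdlog = c(0.3, 0.3), weight = 0.5)
  t1 <- sample_cmv_titers(5000, params, seed = 68)
  expect_lt(abs(mean(log(t1$titer)) - 1.0), 0.05)
  expect_identical(t1, sample_cmv_titers(5000, params, seed = 68))
  ## degenerate weight is rejected; weight ~ 1 gives a unimodal sample
  expect_error(sample_cmv_titers(10, list(meanlog = c(0, 2),
                                          sdlog = c(0.3, 0.3),
                                          weight = 1)), "weight")
  t2 <- sample_cmv_titers(2000, list(meanlog = c(0, 2),
                                     sdlog = c(0.3, 0.3),
                                     weight = 0.999), seed = 69)
  expect_gt(mean(t2$component == 1), 0.99)
  expect_lt(diff(range(quantile(log(t2$titer), c(0.05, 0.95)))), 1.5)
})
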