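#' Derive a stage seed from the run seed
#'
#' Every pipeline stage consumes its own seed, derived deterministically
#' from the run seed and the stage name, so stages are independently
#' reproducible: the stage name is folded into a polynomial rolling hash
#' (base 31, modulus 2^31 - 1) seeded with `seed * 10007`, so distinct
#' stage names get distinct streams (a plain character-code sum would
#' collide for names like `"s19"` and `"s28"`).
#'
#' @param seed integer run seed.
#' @param stage stage name.
#' @return integer stage seed in `[1, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  h <- (as.double(seed) %% 2147483647) * 10007 %% 2147483647
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  as.integer(h %% 2147483646) + 1L
}

#' Assemble and validate a pipeline run configuration
#'
#' @param out_dir output directory for all tables and metadata.
#' @param seed run seed; stage seeds are derived via [derive_seed()].
#' @param cohort a [cohort_spec()] (its own seed is overridden by the
#'   derived simulate seed).
#' @param pipeline `"events"` runs the full event-level gate+count path;
#'   `"truth"` uses the generator's true concentrations as the count
#'   matrix (fast screening runs).
#' @param n_perm,fdr association-test settings.
#' @param n_trees forest size.
#' @param pdp_predictors predictors for 1-D partial dependence curves.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, cohort = cohort_spec(),
                       pipeline = c("events", "truth"),
                       n_perm = 10000L, fdr = 0.15, n_trees = 1000L,
                       pdp_predictors = c("neutrophils",
                                          "monocytes_cd16neg")) {
  pipeline <- match.arg(pipeline)
  stopifnot(is.character(out_dir), length(out_dir) == 1,
            inherits(cohort, "cohort_spec"),
            n_perm >= 100, fdr > 0, fdr < 1, n_trees >= 1)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 cohort = cohort, pipeline = pipeline,
                 n_perm = as.integer(n_perm), fdr = fdr,
                 n_trees = as.integer(n_trees),
                 pdp_predictors = pdp_predictors),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown top-level keys are rejected before any stage runs. Keys under
#' `cohort` are passed to [cohort_spec()].
#'
#' @param path YAML file.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("out_dir", "seed", "cohort", "pipeline", "n_perm", "fdr",
             "n_trees", "pdp_predictors")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$cohort)) {
    if (!is.null(raw$cohort$effect_profile))
      raw$cohort$effect_profile <- lapply(raw$cohort$effect_profile,
                                          unlist)
    if (!is.null(raw$cohort$cmv_mixture))
      raw$cohort$cmv_mixture <- lapply(raw$cohort$cmv_mixture, unlist)
    vec <- setdiff(names(raw$cohort), c("effect_profile", "cmv_mixture"))
    raw$cohort[vec] <- lapply(raw$cohort[vec], unlist)
    raw$cohort <- do.call(cohort_spec, raw$cohort)
  }
  do.call(run_config, raw)
}

## hash of the analysis-defining part of the config (the output location
## does not change what is computed)
config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  plain <- rapply(cfg, function(x)
    if (inherits(x, "Date")) as.character(x) else x, how = "replace")
  yaml::write_yaml(plain, f)
  unname(tools::md5sum(f))
}

write_table <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  path
}

write_matrix <- function(m, dir, name) {
  df <- data.frame(participant_id = rownames(m), m, check.names = FALSE)
  write_table(df, dir, name)
}

#' Run the whole analysis pipeline from a configuration
#'
#' Executes simulate, gate, count, frailty, serostatus, the association
#' studies (sex; CMV and frailty separately per sex; each on absolute
#' counts and on proportions) and the per-sex frailty forests, writing
#' every output table plus provenance metadata (config hash, seed, stage
#' seeds) under `config$out_dir`. A rerun with the same config reproduces
#' identical tables.
#'
#' @param config a `run_config`.
#' @param quiet suppress progress messages.
#' @return invisible list with the main in-memory results and file paths.
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[immunofrail] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## simulate
  spec <- config$cohort
  spec$seed <- derive_seed(config$seed, "simulate")
  say("simulate: ", spec$n_men, " men + ", spec$n_women, " women")
  sim <- stage("simulate", generate_cohort(spec))
  cohort <- sim$cohort

  ## gate + count
  if (config$pipeline == "events") {
    say("gate+count: event-level, ", nrow(cohort), " participants x 2 tubes")
    cm <- stage("gate+count", pipeline_count_matrix(sim, config$seed))
  } else {
    say("count: using generator truth concentrations")
    cm <- truth_count_matrix(sim)
  }

  ## frailty (already scored during simulation; recompute defensively)
  cohort <- stage("frailty", add_frailty_scores(cohort))

  ## serostatus
  say("serostatus: mixture fit on ", nrow(cohort), " titers")
  sero <- stage("serostatus",
                serostatus_pipeline(cohort$cmv_igg,
                                    seed = derive_seed(config$seed,
                                                       "serostatus")))
  cohort$cmv_status <- sero$status

  ## associations: 5 study strata x 2 scales
  prop <- compute_proportions(cm)
  assoc <- list()
  for (study in c("sex", "cmv_by_sex", "frailty_by_sex")) {
    for (scale in c("absolute", "proportion")) {
      say("associate: ", study, " / ", scale)
      mat <- if (scale == "absolute") cm else prop
      mat <- mat[, !apply(mat, 2, function(v) all(is.na(v))),
                 drop = FALSE]
      assoc[[paste(study, scale, sep = "_")]] <- stage(
        "associate",
        run_association_study(mat, cohort, study, scale,
                              n_perm = config$n_perm,
                              seed = derive_seed(config$seed,
                                                 paste0(study, scale)),
                              fdr = config$fdr))
    }
  }
  assoc_tab <- do.call(rbind, c(assoc, make.row.names = FALSE))
  assoc_tab$study <- rep(names(assoc), vapply(assoc, nrow, 0L))

  ## prediction per sex
  forests <- list(); pdps <- list()
  for (sx in c("M", "F")) {
    say("predict: frailty forest, sex ", sx)
    fit <- stage("predict",
                 fit_frailty_forest(cm, cohort, sx,
                                    n_trees = config$n_trees,
                                    seed = derive_seed(config$seed,
                                                       paste0("forest", sx))))
    rpt <- forest_report(fit, seed = derive_seed(config$seed,
                                                 paste0("imp", sx)))
    forests[[sx]] <- rpt
    pdps[[sx]] <- do.call(rbind, lapply(config$pdp_predictors, function(pr) {
      pd <- partial_dependence(fit, pr)
      data.frame(sex = sx, predictor = pr, value = pd[[pr]],
                 yhat = pd$yhat)
    }))
  }

  ## outputs + provenance
  meta <- data.frame(
    key = c("config_hash", "seed", "package_version", "pipeline"),
    value = c(config_hash(config), config$seed,
              as.character(utils::packageVersion("immunofrail")),
              config$pipeline))
  paths <- c(
    cohort = write_table(cohort, config$out_dir, "cohort.csv"),
    counts = write_matrix(cm, config$out_dir, "count_matrix.csv"),
    proportions = write_matrix(prop, config$out_dir, "proportions.csv"),
    associations = write_table(assoc_tab, config$out_dir,
                               "associations.csv"),
    importance_m = write_table(forests$M$importance, config$out_dir,
                               "importance_men.csv"),
    importance_f = write_table(forests$F$importance, config$out_dir,
                               "importance_women.csv"),
    pdp = write_table(do.call(rbind, pdps), config$out_dir,
                      "partial_dependence.csv"),
    forest_summary = write_table(
      data.frame(sex = c("M", "F"),
                 pev = c(forests$M$pev, forests$F$pev),
                 mse_oob = c(forests$M$mse_oob, forests$F$mse_oob)),
      config$out_dir, "forest_summary.csv"),
    metadata = write_table(meta, config$out_dir, "run_metadata.csv"))
  writeLines(data_dictionary(), file.path(config$out_dir,
                                          "data_dictionary.txt"))
  say("done: outputs in ", config$out_dir)
  invisible(list(sim = sim, cohort = cohort, counts = cm,
                 associations = assoc_tab, forests = forests,
                 serology = sero, paths = paths))
}

## full event-level gate + count path for every participant
pipeline_count_matrix <- function(sim, seed,
                                  defs = default_phenotypes(),
                                  models = default_population_models(),
                                  thresholds = default_thresholds()) {
  quantified <- list()
  for (i in seq_len(nrow(sim$cohort))) {
    p <- cohort_participant(sim, i)
    id <- p$row$participant_id
    tru <- generate_tube_events(p, "trucount", models,
                                seed = derive_seed(seed,
                                                   paste0("tru", id)))
    fal <- generate_tube_events(p, "falcon", models,
                                seed = derive_seed(seed,
                                                   paste0("fal", id)))
    cal <- trucount_calibration(attr(tru, "beads_per_tube"),
                                count_bead_events(tru, thresholds),
                                attr(tru, "volume_ul"))
    quantified[[id]] <- quantify_participant(
      classify_events(tru, defs, thresholds),
      classify_events(fal, defs, thresholds), cal, defs)
  }
  build_count_matrix(quantified)
}

data_dictionary <- function() {
  c("immunofrail output tables",
    "",
    "cohort.csv: one row per participant.",
    "  participant_id  stable id",
    "  sex             M/F",
    "  age             years at blood draw",
    "  age_group       1..4, cohort age quartile (blocking factor)",
    "  stratum         selection stratum (healthiest/intermediate/frailest)",
    "  cmv_igg         anti-CMV IgG concentration (arbitrary units)",
    "  cmv_positive_true  generator ground-truth serostatus",
    "  cmv_status      mixture-model serostatus used in analyses",
    "  frailty_missing TRUE if the frailty assessment is missing",
    "  blood_draw_date / frailty_assessment_date  ISO dates",
    "  deficit_01..36  health-deficit items in [0,1] (NA if missing)",
    "  frailty_index   mean of the 36 items, in [0,1]",
    "  frailty_sqrt    square-root transform (prediction response)",
    "",
    "count_matrix.csv: absolute concentrations, cells/uL, one column per",
    "  enumerated phenotype. proportions.csv: percent of the designated",
    "  parent population (see default_parent_map()).",
    "",
    "associations.csv: one row per phenotype x stratum x study x scale;",
    "  statistic is the blocked WMW standardized rank-sum statistic or the",
    "  block-weighted Spearman rho; p is the add-one simulated p-value",
    "  with Monte-Carlo SE mc_se; bh_reject is the Benjamini-Hochberg",
    "  decision within the study family.",
    "",
    "importance_*.csv: random-forest permutation importance, raw percent",
    "  increase in out-of-bag MSE. forest_summary.csv: percentage of",
    "  explained variance (PEV) and OOB MSE per sex.",
    "",
    "partial_dependence.csv: forest partial dependence on the sqrt-frailty",
    "  scale over the central (1st-99th percentile) predictor range.")
}
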