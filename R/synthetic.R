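## ---------------------------------------------------------------------
## Synthetic cohorts with a calibrated rank-correlation structure.
##
## A latent health score drives both the 36 deficit items (probit
## thresholding) and, through a Gaussian copula, the log cell
## concentrations, so that within each age-group x CMV block the Spearman
## correlation between a phenotype's concentration and the frailty index
## equals a configurable target. The cohort emulates the subcohort design:
## equal numbers selected from the healthiest 15%, middle 70% and frailest
## 15% of the latent health distribution of age- and sex-matched peers.
## ---------------------------------------------------------------------

#' Default per-sex effect profile
#'
#' Target within-block Spearman correlations between absolute cell counts
#' and the frailty index: in men an association with neutrophils only
#' (rho 0.25); in women stronger neutrophil (0.40) and classical monocyte
#' (0.24, with a weaker 0.10 on the non-classical subset so total monocytes
#' land near 0.23) associations, plus negative associations of CD56+ T
#' cells (-0.20) and CD4 TemRA cells (-0.13).
#'
#' @return list with named numeric vectors `men` and `women`.
#' @export
default_effect_profile <- function() {
  list(
    men = c(neutrophils = 0.25),
    women = c(neutrophils = 0.40, monocytes_cd16neg = 0.24,
              monocytes_cd16pos = 0.10, t_cd56pos = -0.20,
              cd4_temra = -0.13)
  )
}

#' Cohort generation specification
#'
#' @param n_men,n_women participant counts per sex.
#' @param age_range inclusive age range in years.
#' @param strata_fractions population fractions defining the healthiest /
#'   intermediate / frailest strata (must sum to 1); equal numbers are
#'   selected from each stratum.
#' @param missing_frailty named counts (`men`, `women`) of participants
#'   whose frailty index is missing.
#' @param effect_profile per-sex named vectors of target within-block
#'   Spearman correlations (phenotype or generator-leaf ids); see
#'   [default_effect_profile()].
#' @param cmv_mixture two-component lognormal IgG titer model: list with
#'   `meanlog` (length 2), `sdlog` (length 2) and `weight` (component 1 =
#'   seronegative).
#' @param deficit_prevalence marginal prevalences of the 36 deficit items
#'   at the reference age.
#' @param deficit_loading probit loading of each deficit item on the
#'   latent health score (item liability = loading x latent + residual);
#'   below 1 the items are noisy indicators rather than perfectly nested,
#'   which keeps the frailty index distribution realistic.
#' @param age_effect shift of the latent health score per age-group step
#'   (frailty increases with age).
#' @param volume_ul,beads_per_tube,acquisition_fraction event-generation
#'   defaults: stained volume (uL), nominal counting beads per bead tube,
#'   and the fraction of the tube actually acquired.
#' @param seed integer seed making the whole cohort reproducible.
#' @return validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_men = 145L, n_women = 144L,
                        age_range = c(60, 87),
                        strata_fractions = c(0.15, 0.70, 0.15),
                        missing_frailty = c(men = 5L, women = 7L),
                        effect_profile = default_effect_profile(),
                        cmv_mixture = list(meanlog = c(1, 4),
                                           sdlog = c(0.7, 0.8),
                                           weight = 0.45),
                        deficit_prevalence = seq(0.02, 0.40,
                                                 length.out = 36),
                        deficit_loading = 0.6,
                        age_effect = 0.2,
                        volume_ul = 50, beads_per_tube = 50000,
                        acquisition_fraction = 0.5,
                        seed = 1L) {
  stopifnot(n_men >= 0, n_women >= 0, n_men + n_women > 0,
            length(age_range) == 2, age_range[1] < age_range[2],
            length(strata_fractions) == 3, all(strata_fractions > 0),
            abs(sum(strata_fractions) - 1) < 1e-8,
            all(c("men", "women") %in% names(missing_frailty)),
            missing_frailty["men"] <= n_men,
            missing_frailty["women"] <= n_women,
            length(deficit_prevalence) == 36,
            all(deficit_prevalence > 0 & deficit_prevalence < 1),
            deficit_loading > 0, deficit_loading <= 1,
            volume_ul > 0, beads_per_tube > 0,
            acquisition_fraction > 0, acquisition_fraction <= 1)
  for (sx in names(effect_profile)) {
    rho <- effect_profile[[sx]]
    if (!length(rho)) next
    if (any(abs(rho) >= 1))
      stop("target correlations must satisfy |rho| < 1 (", sx, ": ",
           paste(names(rho)[abs(rho) >= 1], collapse = ", "), ")")
  }
  validate_mixture_params(cmv_mixture)
  spec <- list(n_men = as.integer(n_men), n_women = as.integer(n_women),
               age_range = age_range, strata_fractions = strata_fractions,
               missing_frailty = missing_frailty,
               effect_profile = effect_profile, cmv_mixture = cmv_mixture,
               deficit_prevalence = deficit_prevalence,
               deficit_loading = deficit_loading,
               age_effect = age_effect, volume_ul = volume_ul,
               beads_per_tube = beads_per_tube,
               acquisition_fraction = acquisition_fraction,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

validate_mixture_params <- function(p) {
  stopifnot(is.list(p), length(p$meanlog) == 2, length(p$sdlog) == 2,
            all(p$sdlog > 0), length(p$weight) == 1)
  if (p$weight <= 0 || p$weight >= 1)
    stop("mixture weight must lie strictly in (0, 1)")
  invisible(p)
}

#' Sample IgG titers from a two-component lognormal mixture
#'
#' Component labels are retained as ground truth for recovery tests; the
#' component with the higher log-mean is the seropositive one.
#'
#' @param n sample size.
#' @param params mixture parameters (see [cohort_spec()]).
#' @param seed optional seed.
#' @return data.frame with `titer`, `component` (1/2), and
#'   `seropositive_true`.
#' @export
sample_cmv_titers <- function(n, params = cohort_spec()$cmv_mixture,
                              seed = NULL) {
  validate_mixture_params(params)
  if (!is.null(seed)) set.seed(seed)
  comp <- ifelse(stats::runif(n) < params$weight, 1L, 2L)
  titer <- stats::rlnorm(n, params$meanlog[comp], params$sdlog[comp])
  pos_comp <- which.max(params$meanlog)
  data.frame(titer = titer, component = comp,
             seropositive_true = comp == pos_comp)
}

## run expr with a private, fixed RNG stream; the caller's stream is
## untouched, so cached and uncached calls leave identical global state
with_private_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## deterministic latent-health draws under the three-strata selection:
## equal thirds from the lower f1, middle f2 and upper f3 population
## quantiles (grid of mid-point probabilities, not random)
selection_u_grid <- function(m, fractions) {
  edges <- c(0, cumsum(fractions))
  thirds <- rep(floor(m / 3), 3) + c(rep(1, m %% 3), rep(0, 3 - m %% 3))
  unlist(lapply(1:3, function(s) {
    k <- thirds[s]
    edges[s] + (edges[s + 1] - edges[s]) * (seq_len(k) - 0.5) / k
  }))
}

## binary deficit matrix: item j present when its probit liability
## loading x latent + sqrt(1 - loading^2) x residual exceeds the item cut
simulate_deficits <- function(latent, tau, loading, residuals) {
  liab <- loading * latent + sqrt(1 - loading^2) * residuals
  matrix(as.numeric(sweep(liab, 2, tau, ">")), nrow = length(latent))
}

## random latent-health draws for n participants under the same selection
draw_selected_latent <- function(n, fractions) {
  edges <- c(0, cumsum(fractions))
  stratum <- rep(1:3, length.out = 3 * ceiling(n / 3))[seq_len(n)]
  stratum <- sample(stratum)
  u <- stats::runif(n, edges[stratum], edges[stratum + 1])
  list(h = stats::qnorm(u),
       stratum = c("healthiest", "intermediate", "frailest")[stratum])
}

## Calibration of the Gaussian-copula latent correlation.
##
## Returns a function mapping a target within-block Spearman correlation
## between a (continuous, monotone-in-latent) concentration and the
## *frailty index* -- a tied, monotone step function of the latent health
## score -- to the latent Pearson correlation r that attains it. The map
## rho(r) is estimated once on an r-grid by common-random-numbers Monte
## Carlo under the strata-selection distribution of the latent score, then
## inverted monotonically. In the no-selection, no-ties limit this reduces
## to the classical sin transform r = 2 sin(pi * rho / 6).
calibration_cache <- new.env(parent = emptyenv())

invert_monotone <- function(r_grid, rho_grid, what = "correlation") {
  rho_grid <- cummax(rho_grid)  # enforce monotone for inversion
  function(target) {
    if (abs(target) > max(rho_grid))
      stop("unattainable ", what, " ", signif(target, 3),
           ": the frailty index cannot exceed rank correlation ",
           signif(max(rho_grid), 3), " under this deficit model")
    sign(target) * stats::approx(rho_grid, r_grid, xout = abs(target),
                                 ties = "ordered")$y
  }
}

calibrate_latent_map <- function(tau, shift, fractions, loading,
                                 m = 16384L) {
  key <- paste(signif(c(tau, shift, fractions, loading, m), 8),
               collapse = ",")
  if (!is.null(calibration_cache[[key]])) return(calibration_cache[[key]])
  h <- stats::qnorm(selection_u_grid(m, fractions))
  fi <- simulate_deficits(shift + h, tau, loading,
                          with_private_rng(812026L,
                                           matrix(stats::rnorm(m *
                                                                 length(tau)),
                                                  m)))
  fi <- rowMeans(fi)
  z <- with_private_rng(902026L, stats::rnorm(m))
  fi_rank <- rank(fi)
  r_grid <- seq(0, 0.9995, length.out = 60)
  rho_grid <- vapply(r_grid, function(r) {
    g <- r * h + sqrt(1 - r^2) * z
    stats::cor(rank(g), fi_rank)
  }, 0)
  out <- list(f = invert_monotone(r_grid, rho_grid),
              h = h, fi_rank = fi_rank)
  calibration_cache[[key]] <- out
  out
}

## When one effect-profile entry covers several generator leaves, giving
## every leaf the latent correlation that a single leaf would need
## overshoots: the leaves' idiosyncratic noise partially cancels in the
## sum, so the aggregate's rank correlation with the frailty index exceeds
## the per-leaf one. Invert the aggregate map directly: find the common
## per-leaf latent r whose *summed* concentration attains the target.
calibrate_aggregate_r <- function(target, base, sdlog, cal) {
  k <- length(base)
  z <- with_private_rng(902027L + k,
                        matrix(stats::rnorm(length(cal$h) * k), ncol = k))
  r_grid <- seq(0, 0.9995, length.out = 40)
  rho_grid <- vapply(r_grid, function(r) {
    logc <- outer(r * cal$h, sdlog) +
      sweep(z, 2, sqrt(1 - r^2) * sdlog, `*`)
    agg <- exp(logc) %*% base
    stats::cor(rank(agg), cal$fi_rank)
  }, 0)
  invert_monotone(r_grid, rho_grid, "aggregate correlation")(target)
}

## expand a per-sex effect profile (phenotype or leaf ids -> rho) into an
## ordered list of (leaf set, target) entries; entries naming aggregates
## apply to all their leaves, with more specific (fewer-leaf) entries
## overriding broader ones
resolve_effect_profile <- function(profile, models, leaf_map) {
  leaves <- names(models)
  if (is.null(profile) || !length(profile)) return(list())
  sets <- lapply(names(profile), function(nm) {
    if (nm %in% leaves) nm
    else if (nm %in% names(leaf_map)) leaf_map[[nm]]
    else stop("effect profile names unknown phenotype '", nm, "'")
  })
  ord <- order(-lengths(sets))
  lapply(ord, function(i) list(name = names(profile)[i],
                               leaves = sets[[i]],
                               target = unname(profile[[i]])))
}

## per-leaf latent correlations attaining the targets within one age group
effect_latent_r <- function(entries, models, cal) {
  leaves <- names(models)
  r <- stats::setNames(rep(0, length(leaves)), leaves)
  for (e in entries) {
    val <- tryCatch({
      if (length(e$leaves) == 1) cal$f(e$target)
      else calibrate_aggregate_r(
        e$target, vapply(models[e$leaves], `[[`, 0, "base"),
        vapply(models[e$leaves], `[[`, 0, "sdlog"), cal)
    }, error = function(err)
      stop("effect profile entry '", e$name, "': ",
           conditionMessage(err), call. = FALSE))
    r[e$leaves] <- val
  }
  r
}

## multiplicative covariate effects on leaf baselines (constant within an
## age-group x CMV block, so they do not disturb within-block correlations)
covariate_multiplier <- function(leaves, sex, cmv_pos, age_group) {
  mult <- stats::setNames(rep(1, length(leaves)), leaves)
  if (sex == "F") {
    up <- grep("^(b_|cd4_)", leaves, value = TRUE)
    mult[up] <- mult[up] * 1.25
    mult["cd8_naive"] <- mult["cd8_naive"] * 1.2
    mult["mono_cd16neg"] <- mult["mono_cd16neg"] * 0.85
    mult["t_cd56pos"] <- mult["t_cd56pos"] * 0.7
    late <- c("cd4_tem_late", "cd8_tem_late", "cd8_temra_late")
    mult[late] <- mult[late] * 0.8
  }
  if (cmv_pos) {
    cmv_up <- c(cd8_temra_late = 2.5, cd8_tem_late = 2.0,
                cd4_temra_late = 1.8, cd4_tem_late = 1.8,
                t_cd56pos = 1.5, cd8_temra_other = 1.3)
    mult[names(cmv_up)] <- mult[names(cmv_up)] * cmv_up
  }
  naive <- c("cd4_naive_conv", "cd8_naive")
  mult[naive] <- mult[naive] * 0.92^(age_group - 2.5)
  mult
}

#' Generate a synthetic cohort
#'
#' Draws participants with age, sex, CMV IgG titer (with ground-truth
#' serostatus), 36 binary deficit items, and true absolute concentrations
#' (cells/uL) for all generator leaf populations and the 37 enumerated
#' phenotypes. Within every age-group x CMV block the Spearman correlation
#' between each targeted phenotype's concentration and the frailty index
#' matches the configured effect profile (Gaussian copula, calibrated under the
#' healthiest/intermediate/frailest selection design). Deterministic given
#' `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param models population models, see [default_population_models()].
#' @return object of class `synthetic_cohort`: list with `cohort`
#'   (data.frame), `concentrations` (n x 37 matrix, cells/uL),
#'   `leaf_concentrations` (n x leaves matrix) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            models = default_population_models()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_men + spec$n_women
  sex <- sample(rep(c("M", "F"), c(spec$n_men, spec$n_women)))

  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  age_group <- as.integer(cut(age,
                              stats::quantile(age, 0:4 / 4),
                              include.lowest = TRUE, labels = FALSE))

  cmv <- sample_cmv_titers(n, spec$cmv_mixture)

  ## latent health (higher = frailer), selected in equal thirds from the
  ## healthiest / intermediate / frailest population strata per sex
  h <- numeric(n); stratum <- character(n)
  for (sx in c("M", "F")) {
    idx <- which(sex == sx)
    drawn <- draw_selected_latent(length(idx), spec$strata_fractions)
    h[idx] <- drawn$h
    stratum[idx] <- drawn$stratum
  }

  tau <- stats::qnorm(1 - spec$deficit_prevalence)
  latent <- spec$age_effect * (age_group - 2.5) + h
  deficits <- simulate_deficits(latent, tau, spec$deficit_loading,
                                matrix(stats::rnorm(n * length(tau)), n))
  colnames(deficits) <- sprintf("deficit_%02d", 1:36)

  ## copula-calibrated concentrations
  leaf_map <- phenotype_leaf_map(models = models)
  leaves <- names(models)
  base <- vapply(models, `[[`, 0, "base")
  sdlog <- vapply(models, `[[`, 0, "sdlog")
  entries_by_sex <- list(
    M = resolve_effect_profile(spec$effect_profile$men, models, leaf_map),
    F = resolve_effect_profile(spec$effect_profile$women, models, leaf_map))
  ## latent correlation per (leaf, age group): the deficit cutpoints seen
  ## within a block shift with age, so each age group gets its own map
  r_by_group <- lapply(1:4, function(g) {
    cal <- calibrate_latent_map(tau, spec$age_effect * (g - 2.5),
                                spec$strata_fractions,
                                spec$deficit_loading)
    lapply(entries_by_sex, effect_latent_r, models = models, cal = cal)
  })

  leaf_conc <- matrix(NA_real_, n, length(leaves),
                      dimnames = list(NULL, leaves))
  eps <- matrix(stats::rnorm(n * length(leaves)), n)
  for (i in seq_len(n)) {
    r <- r_by_group[[age_group[i]]][[sex[i]]]
    mult <- covariate_multiplier(leaves, sex[i], cmv$seropositive_true[i],
                                 age_group[i])
    leaf_conc[i, ] <- exp(log(base) + log(mult) +
                            sdlog * (r * h[i] + sqrt(1 - r^2) * eps[i, ]))
  }

  conc <- vapply(leaf_map, function(ls)
    rowSums(leaf_conc[, ls, drop = FALSE]), numeric(n))

  ## frailty missingness and visit dates
  frailty_missing <- rep(FALSE, n)
  pick <- function(idx, k) idx[sample.int(length(idx), k)]
  frailty_missing[pick(which(sex == "M"),
                       spec$missing_frailty[["men"]])] <- TRUE
  frailty_missing[pick(which(sex == "F"),
                       spec$missing_frailty[["women"]])] <- TRUE
  draw_date <- as.Date("2016-08-01") +
    round(stats::runif(n, 0, as.numeric(as.Date("2017-03-31") -
                                          as.Date("2016-08-01"))))
  interval_y <- stats::runif(n, 0.005, 3.195)  # mean interval ~1.6 years
  frailty_date <- draw_date - round(interval_y * 365.25)

  cohort <- data.frame(
    participant_id = sprintf("p%04d", seq_len(n)),
    sex = factor(sex, c("M", "F")), age = age, age_group = age_group,
    stratum = stratum, cmv_igg = cmv$titer,
    cmv_positive_true = cmv$seropositive_true,
    frailty_missing = frailty_missing,
    blood_draw_date = draw_date, frailty_assessment_date = frailty_date,
    stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(deficits))
  cohort[frailty_missing, colnames(deficits)] <- NA_real_
  cohort <- add_frailty_scores(cohort)

  rownames(conc) <- rownames(leaf_conc) <- cohort$participant_id
  structure(list(cohort = cohort, concentrations = conc,
                 leaf_concentrations = leaf_conc, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$cohort$sex)
  cat("Synthetic cohort:", nrow(x$cohort), "participants (",
      tab[["M"]], "men,", tab[["F"]], "women ), ",
      ncol(x$concentrations), "phenotypes, seed", x$spec$seed, "\n")
  invisible(x)
}

#' Extract one participant for event generation
#'
#' @param sim a `synthetic_cohort`.
#' @param id participant id or row index.
#' @return list with the cohort row and the participant's true leaf
#'   concentrations.
#' @export
cohort_participant <- function(sim, id) {
  i <- if (is.character(id)) match(id, sim$cohort$participant_id) else id
  if (is.na(i) || i < 1 || i > nrow(sim$cohort))
    stop("unknown participant: ", id)
  list(row = sim$cohort[i, , drop = FALSE],
       leaf_concentrations = sim$leaf_concentrations[i, ],
       spec = sim$spec)
}

## bead intensity signature: bright in every antibody channel, low scatter,
## CD45-negative so beads stay outside the leukocyte tree
bead_intensities <- function(n_beads, channels) {
  m <- matrix(stats::rlnorm(n_beads * length(channels), 7, 0.2), n_beads)
  colnames(m) <- channels
  m[, "FSC"] <- stats::rlnorm(n_beads, 1.5, 0.2)
  m[, "SSC"] <- stats::rlnorm(n_beads, 1.5, 0.2)
  m[, "CD45"] <- stats::rlnorm(n_beads, 1.5, 0.2)
  m
}

#' Generate event-level cytometry data for one participant and tube
#'
#' Event counts per leaf population are Poisson with mean concentration x
#' acquired volume (volume x acquisition fraction); channel intensities are
#' lognormal per population. The bead tube additionally contains a bead
#' event population (known nominal beads per tube, same acquisition
#' fraction). Deterministic given `seed`.
#'
#' @param participant a participant from [cohort_participant()], or any
#'   list with a named `leaf_concentrations` vector.
#' @param tube `"trucount"` or `"falcon"`.
#' @param models population models.
#' @param seed optional seed.
#' @param volume_ul stained volume (uL); must be positive.
#' @param beads_per_tube nominal bead count (bead tube only).
#' @param acquisition_fraction fraction of the tube acquired.
#' @param keep_labels if TRUE, keep the true population label of every
#'   event in a `.label` column (for accuracy tests).
#' @return data.frame of events x channels with attributes `tube`,
#'   `volume_ul`, `beads_per_tube`, `acquisition_fraction`,
#'   `participant_id`.
#' @export
generate_tube_events <- function(participant,
                                 tube = c("trucount", "falcon"),
                                 models = default_population_models(),
                                 seed = NULL,
                                 volume_ul = NULL,
                                 beads_per_tube = NULL,
                                 acquisition_fraction = NULL,
                                 keep_labels = FALSE) {
  tube <- match.arg(tube)
  spec <- participant$spec
  if (is.null(volume_ul))
    volume_ul <- if (!is.null(spec)) spec$volume_ul else 50
  if (is.null(beads_per_tube))
    beads_per_tube <- if (!is.null(spec)) spec$beads_per_tube else 50000
  if (is.null(acquisition_fraction))
    acquisition_fraction <-
      if (!is.null(spec)) spec$acquisition_fraction else 0.5
  if (volume_ul <= 0) stop("acquired volume must be positive")
  stopifnot(acquisition_fraction > 0)
  conc <- participant$leaf_concentrations
  missing_models <- setdiff(names(conc), names(models))
  if (length(missing_models))
    stop("no population model for: ",
         paste(missing_models, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  channels <- tube_channels(tube)
  f <- acquisition_fraction
  blocks <- list()
  labels <- character(0)
  for (leaf in names(conc)) {
    k <- stats::rpois(1, conc[[leaf]] * volume_ul * f)
    if (k == 0) next
    mu <- leaf_channel_meanlog(models[[leaf]], channels)
    m <- matrix(stats::rlnorm(k * length(channels),
                              rep(mu, each = k), band_sdlog), k)
    colnames(m) <- channels
    blocks[[leaf]] <- m
    labels <- c(labels, rep(leaf, k))
  }
  if (tube == "trucount") {
    k <- stats::rpois(1, beads_per_tube * f)
    if (k > 0) {
      blocks[["bead"]] <- bead_intensities(k, channels)
      labels <- c(labels, rep("bead", k))
    }
  }
  ev <- as.data.frame(do.call(rbind, blocks))
  rownames(ev) <- NULL
  if (keep_labels) ev$.label <- labels
  attr(ev, "tube") <- tube
  attr(ev, "volume_ul") <- volume_ul
  attr(ev, "beads_per_tube") <- beads_per_tube
  attr(ev, "acquisition_fraction") <- acquisition_fraction
  attr(ev, "participant_id") <-
    if (!is.null(participant$row)) participant$row$participant_id else NA
  ev
}

#' True phenotype concentrations of a synthetic cohort as a count matrix
#'
#' @param sim a `synthetic_cohort`.
#' @return numeric matrix participants x 37 phenotypes (cells/uL).
#' @export
truth_count_matrix <- function(sim) {
  stopifnot(inherits(sim, "synthetic_cohort"))
  sim$concentrations
}

#' Simulate one flat association study for operating-characteristic checks
#'
#' Generates a single-sex study cohort (latent health, deficits, frailty
#' index, age blocks, CMV) in which a configurable subset of mutually
#' independent phenotypes carries a within-block rank correlation with the
#' frailty index and the rest are null. Used to measure empirical error
#' rates of the association pipeline; unlike [generate_cohort()], the
#' phenotypes have no hierarchy, so the null/non-null partition is exact.
#'
#' @param n participants.
#' @param rho named vector of target within-block Spearman correlations
#'   (one element per phenotype; zeros are nulls).
#' @param spec a [cohort_spec()] supplying the deficit and selection model.
#' @param seed optional seed.
#' @return list with `cohort` (data.frame incl. `frailty_index`,
#'   `age_group`, `cmv_status`) and `counts` (n x phenotypes matrix).
#' @export
simulate_flat_study <- function(n, rho, spec = cohort_spec(),
                                seed = NULL) {
  stopifnot(!is.null(names(rho)), all(abs(rho) < 1))
  if (!is.null(seed)) set.seed(seed)
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  age_group <- as.integer(cut(age, stats::quantile(age, 0:4 / 4),
                              include.lowest = TRUE, labels = FALSE))
  cmv <- sample_cmv_titers(n, spec$cmv_mixture)
  drawn <- draw_selected_latent(n, spec$strata_fractions)
  tau <- stats::qnorm(1 - spec$deficit_prevalence)
  latent <- spec$age_effect * (age_group - 2.5) + drawn$h
  deficits <- simulate_deficits(latent, tau, spec$deficit_loading,
                                matrix(stats::rnorm(n * length(tau)), n))
  fi <- rowMeans(deficits)

  counts <- matrix(NA_real_, n, length(rho),
                   dimnames = list(NULL, names(rho)))
  for (g in 1:4) {
    idx <- which(age_group == g)
    if (!length(idx)) next
    cal <- calibrate_latent_map(tau, spec$age_effect * (g - 2.5),
                                spec$strata_fractions,
                                spec$deficit_loading)
    r <- vapply(rho, cal$f, 0)
    eps <- matrix(stats::rnorm(length(idx) * length(rho)), length(idx))
    counts[idx, ] <- exp(log(500) + 0.45 *
                           (outer(drawn$h[idx], r) +
                              sweep(eps, 2, sqrt(1 - r^2), `*`)))
  }
  cohort <- data.frame(participant_id = sprintf("p%04d", seq_len(n)),
                       age = age, age_group = age_group,
                       cmv_status = factor(ifelse(cmv$seropositive_true,
                                                  "seropositive",
                                                  "seronegative")),
                       frailty_index = fi)
  rownames(counts) <- cohort$participant_id
  list(cohort = cohort, counts = counts)
}
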