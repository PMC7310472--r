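#' Default channel thresholds
#'
#' Per-channel intensity cuts separating the negative, dim, and bright bands
#' used by the gate predicates. Events are classified as negative below
#' `low`, dim in `[low, high)`, and bright at or above `high`; `positive`
#' means dim-or-bright. Ties exactly at a cut fall in the higher band.
#' Intensities are on an arbitrary linear fluorescence scale; the defaults
#' bisect the well-separated populations produced by the synthetic event
#' generator (negative, dim and bright populations centred at e^2, e^4 and
#' e^6 respectively).
#'
#' @param channels character vector of channel names to cover.
#' @param low,high numeric cut values recycled over channels.
#' @return data.frame with columns `channel`, `low`, `high`.
#' @export
default_thresholds <- function(channels = all_channels(),
                               low = exp(3), high = exp(5)) {
  stopifnot(all(low < high))
  data.frame(channel = channels, low = low, high = high,
             stringsAsFactors = FALSE)
}

#' @rdname default_thresholds
#' @export
all_channels <- function() {
  union(tube_channels("trucount"), tube_channels("falcon"))
}

#' Channels acquired in each tube
#'
#' The bead-containing (TruCOUNT-style) tube carries the lineage panel
#' (CD45, CD3, CD19, CD56, CD16, CD4, CD8, CD27, CD38, HLA-DR, IgD); the
#' plain (Falcon) tube carries the T-cell differentiation panel (CCR7,
#' CD45RA, CD27, CD28, CD25, CD127, CXCR5). Both include forward/side
#' scatter and CD3 so the tubes can be linked through the CD3 T-cell ratio.
#'
#' @param tube `"trucount"` or `"falcon"`.
#' @return character vector of channel names.
#' @export
tube_channels <- function(tube = c("trucount", "falcon")) {
  tube <- match.arg(tube)
  if (tube == "trucount") {
    c("FSC", "SSC", "CD45", "CD3", "CD19", "CD56", "CD16",
      "CD4", "CD8", "CD27", "CD38", "HLADR", "IgD")
  } else {
    c("FSC", "SSC", "CD45", "CD3", "CD4", "CD8", "CCR7",
      "CD45RA", "CD27", "CD28", "CD25", "CD127", "CXCR5")
  }
}

## One row per (phenotype, tube). `gate` is a comma-separated conjunction of
## channel=relation predicates, inherited down the tree. `primary` marks the
## tube in which the phenotype is enumerated for the count matrix; the
## remaining rows are structural gates needed to descend the hierarchy in
## the other tube. Exactly 37 rows are primary.
phenotype_rows <- function() {
  r <- function(phenotype, parent, tube, gate, primary = TRUE)
    data.frame(phenotype = phenotype, parent = parent, tube = tube,
               gate = gate, primary = primary, stringsAsFactors = FALSE)
  rbind(
    ## bead tube: lineages off the CD45/SSC plot
    r("leukocytes", NA, "trucount", "CD45=positive", FALSE),
    r("neutrophils", "leukocytes", "trucount", "SSC=bright,CD45=dim"),
    r("monocytes", "leukocytes", "trucount",
      "SSC=dim,CD45=dim,CD3=negative,CD19=negative"),
    r("monocytes_cd16neg", "monocytes", "trucount", "CD16=negative"),
    r("monocytes_cd16pos", "monocytes", "trucount", "CD16=positive"),
    r("lymphocytes", "leukocytes", "trucount", "SSC=negative,CD45=bright"),
    r("t_cells", "lymphocytes", "trucount", "CD3=positive"),
    r("t_cd56pos", "t_cells", "trucount", "CD56=positive"),
    r("t_cd4", "t_cells", "trucount",
      "CD56=negative,CD4=positive,CD8=negative"),
    r("t_cd8", "t_cells", "trucount",
      "CD56=negative,CD8=positive,CD4=negative"),
    r("b_cells", "lymphocytes", "trucount", "CD3=negative,CD19=positive"),
    r("b_transitional", "b_cells", "trucount", "CD38=bright,CD27=negative"),
    r("b_naive", "b_cells", "trucount", "CD38=dim,CD27=negative"),
    r("b_memory", "b_cells", "trucount", "CD38=dim,CD27=positive"),
    r("nk_cells", "lymphocytes", "trucount", "CD3=negative,CD19=negative"),
    r("nk_cd56bright_cd16neg", "nk_cells", "trucount",
      "CD56=bright,CD16=negative"),
    r("nk_cd56dim_cd16pos", "nk_cells", "trucount",
      "CD56=dim,CD16=positive"),
    r("nk_cd56dim_cd16neg", "nk_cells", "trucount",
      "CD56=dim,CD16=negative"),
    r("nk_cd56neg_cd16pos", "nk_cells", "trucount",
      "CD56=negative,CD16=positive"),
    ## plain tube: structural chain down to CD4/CD8, then differentiation
    r("leukocytes", NA, "falcon", "CD45=positive", FALSE),
    r("lymphocytes", "leukocytes", "falcon",
      "SSC=negative,CD45=bright", FALSE),
    r("t_cells", "lymphocytes", "falcon", "CD3=positive", FALSE),
    r("t_cd4", "t_cells", "falcon", "CD4=positive,CD8=negative", FALSE),
    r("t_cd8", "t_cells", "falcon", "CD8=positive,CD4=negative", FALSE),
    r("cd4_naive", "t_cd4", "falcon", "CCR7=positive,CD45RA=positive"),
    r("cd4_cm", "t_cd4", "falcon", "CCR7=positive,CD45RA=negative"),
    r("cd4_tem", "t_cd4", "falcon", "CCR7=negative,CD45RA=negative"),
    r("cd4_temra", "t_cd4", "falcon", "CCR7=negative,CD45RA=positive"),
    r("cd4_tem_early", "cd4_tem", "falcon", "CD27=positive,CD28=positive"),
    r("cd4_tem_late", "cd4_tem", "falcon", "CD27=negative,CD28=negative"),
    r("cd4_temra_early", "cd4_temra", "falcon",
      "CD27=positive,CD28=positive"),
    r("cd4_temra_late", "cd4_temra", "falcon",
      "CD27=negative,CD28=negative"),
    r("treg", "t_cd4", "falcon", "CD25=bright"),
    r("treg_naive", "treg", "falcon", "CD45RA=positive"),
    r("tfh", "t_cd4", "falcon", "CXCR5=positive"),
    r("cd8_naive", "t_cd8", "falcon", "CCR7=positive,CD45RA=positive"),
    r("cd8_cm", "t_cd8", "falcon", "CCR7=positive,CD45RA=negative"),
    r("cd8_tem", "t_cd8", "falcon", "CCR7=negative,CD45RA=negative"),
    r("cd8_temra", "t_cd8", "falcon", "CCR7=negative,CD45RA=positive"),
    r("cd8_tem_early", "cd8_tem", "falcon", "CD27=positive,CD28=positive"),
    r("cd8_tem_late", "cd8_tem", "falcon", "CD27=negative,CD28=negative"),
    r("cd8_temra_early", "cd8_temra", "falcon",
      "CD27=positive,CD28=positive"),
    r("cd8_temra_late", "cd8_temra", "falcon",
      "CD27=negative,CD28=negative")
  )
}

#' Default phenotype definition table
#'
#' The hierarchical gating table covering the 37 enumerated leukocyte
#' subpopulations plus the structural gates (the CD45+ leukocyte root and
#' the lymphocyte/T/CD4/CD8 chain repeated in the plain tube). Each row is
#' a conjunction of channel predicates applied on top of all ancestor
#' predicates; `primary` marks the 37 rows that enter the count matrix.
#'
#' The tree follows standard CD45/side-scatter lineage gating: neutrophils
#' are side-scatter bright and CD45 dim; monocytes side-scatter dim, CD45
#' dim and CD3-CD19- (split by CD16); lymphocytes side-scatter low and CD45
#' bright, then T (CD3+, with CD56+ T cells kept apart from the CD4/CD8
#' branches), B (CD19+, split into transitional/naive/memory by CD38 and
#' CD27) and NK (CD3-CD19-, subdivided into four CD56-by-CD16 subsets).
#' CD4 and CD8 T cells are partitioned into naive/central-memory/Tem/TemRA
#' quadrants by CCR7 and CD45RA, with Tem and TemRA further split into
#' early (CD27+CD28+) and late (CD27-CD28-) stages; regulatory T cells are
#' CD25-bright CD4 T cells (naive subset CD45RA+) and follicular helper T
#' cells are CXCR5+ CD4 T cells.
#'
#' @return data.frame with columns `phenotype`, `parent`, `tube`, `gate`,
#'   `primary`.
#' @seealso [classify_events()], [default_thresholds()]
#' @export
default_phenotypes <- function() {
  defs <- phenotype_rows()
  stopifnot(sum(defs$primary) == 37L)
  defs
}

#' Enumerated subpopulations in a phenotype table
#'
#' @param defs a phenotype definition table, see [default_phenotypes()].
#' @return character vector of the enumerated (primary) phenotype ids.
#' @export
enumerated_phenotypes <- function(defs = default_phenotypes()) {
  unique(defs$phenotype[defs$primary])
}

## activation-marker summaries requested alongside counts
default_marker_summaries <- function() {
  data.frame(
    phenotype = c("neutrophils", "monocytes", "monocytes",
                  "monocytes_cd16neg", "monocytes_cd16neg",
                  "monocytes_cd16pos", "monocytes_cd16pos"),
    channel = c("CD16", "HLADR", "CD38", "HLADR", "CD38", "HLADR", "CD38"),
    stringsAsFactors = FALSE
  )
}

## ---------------------------------------------------------------------
## Synthetic population models: the 30 generator leaves, their baseline
## concentrations (cells/uL, medians for a CMV-negative man in the middle
## age group) and their expected band (neg/dim/bright) on every channel.
## Channels not listed are negative. Baselines are round numbers in the
## range reported for healthy older adults.
## ---------------------------------------------------------------------

leaf_table <- function() {
  L <- function(leaf, base, sdlog, ...) {
    bands <- c(...)
    list(leaf = leaf, base = base, sdlog = sdlog, bands = bands)
  }
  list(
    L("neutrophils", 3800, 0.35,
      FSC = "dim", SSC = "bright", CD45 = "dim", CD16 = "bright"),
    L("mono_cd16neg", 400, 0.45,
      FSC = "dim", SSC = "dim", CD45 = "dim", HLADR = "bright",
      CD38 = "dim"),
    L("mono_cd16pos", 50, 0.50,
      FSC = "dim", SSC = "dim", CD45 = "dim", CD16 = "bright",
      HLADR = "bright", CD38 = "dim"),
    L("nk_cd56bright_cd16neg", 30, 0.50,
      FSC = "dim", CD45 = "bright", CD56 = "bright"),
    L("nk_cd56dim_cd16pos", 200, 0.50,
      FSC = "dim", CD45 = "bright", CD56 = "dim", CD16 = "bright"),
    L("nk_cd56dim_cd16neg", 40, 0.50,
      FSC = "dim", CD45 = "bright", CD56 = "dim"),
    L("nk_cd56neg_cd16pos", 25, 0.50,
      FSC = "dim", CD45 = "bright", CD16 = "bright"),
    L("b_transitional", 10, 0.55,
      FSC = "dim", CD45 = "bright", CD19 = "bright", CD38 = "bright",
      IgD = "bright"),
    L("b_naive", 120, 0.50,
      FSC = "dim", CD45 = "bright", CD19 = "bright", CD38 = "dim",
      IgD = "bright"),
    L("b_memory", 70, 0.50,
      FSC = "dim", CD45 = "bright", CD19 = "bright", CD38 = "dim",
      CD27 = "bright"),
    L("t_cd56pos", 55, 0.55,
      FSC = "dim", CD45 = "bright", CD3 = "bright", CD56 = "dim",
      CD45RA = "bright"),
    ## CD4 branch
    L("cd4_naive_conv", 300, 0.45,
      FSC = "dim", CD45 = "bright", CD3 = "bright", CD4 = "bright",
      CCR7 = "bright", CD45RA = "bright", CD27 = "bright", CD28 = "bright",
      CD127 = "bright"),
    L("cd4_cm_conv", 230, 0.45,
      FSC = "dim", CD45 = "bright", CD3 = "bright", CD4 = "bright",
      CCR7 = "bright", CD27 = "bright", CD28 = "bright", CD127 = "bright"),
    L("cd4_tem_early", 55, 0.50,
      FSC = "dim", CD45 = "bright", CD3 = "bright", CD4 = "bright",
      CD27 = "bright", CD28 = "bright"),
    L("cd4_tem_late", 15, 0.55,
      FSC = "dim", CD45 = "bright", CD3 = "bright", CD4 = "bright"),
    L("cd4_tem_other", 40, 0.50,
      FSC = "dim", CD45 = "bright", CD3 = "bright", CD4 = "bright",
      CD27 = "bright"),
    L("cd4_temra_early", 8, 0.55,
      FSC = "dim", CD45 = "bright", CD3 = "bright", CD4 = "bright",
      CD45RA = "bright", CD27 = "bright", CD28 = "bright"),
    L("cd4_temra_late", 14, 0.55,
      FSC = "dim", CD45 = "bright", CD3 = "bright", CD4 = "bright",
      CD45RA = "bright"),
    L("cd4_temra_other", 8, 0.55,
      FSC = "dim", CD45 = "bright", CD3 = "bright", CD4 = "bright",
      CD45RA = "bright", CD27 = "bright"),
    L("cd4_treg_naive", 18, 0.50,
      FSC = "dim", CD45 = "bright", CD3 = "bright", CD4 = "bright",
      CCR7 = "bright", CD45RA = "bright", CD25 = "bright", CD27 = "bright",
      CD28 = "bright"),
    L("cd4_treg_mem", 28, 0.50,
      FSC = "dim", CD45 = "bright", CD3 = "bright", CD4 = "bright",
      CCR7 = "bright", CD25 = "bright", CD27 = "bright", CD28 = "bright"),
    L("cd4_tfh", 25, 0.50,
      FSC = "dim", CD45 = "bright", CD3 = "bright", CD4 = "bright",
      CCR7 = "bright", CXCR5 = "bright", CD27 = "bright", CD28 = "bright"),
    ## CD8 branch
    L("cd8_naive", 95, 0.50,
      FSC = "dim", CD45 = "bright", CD3 = "bright", CD8 = "bright",
      CCR7 = "bright", CD45RA = "bright", CD27 = "bright", CD28 = "bright"),
    L("cd8_cm", 55, 0.50,
      FSC = "dim", CD45 = "bright", CD3 = "bright", CD8 = "bright",
      CCR7 = "bright", CD27 = "bright", CD28 = "bright"),
    L("cd8_tem_early", 35, 0.50,
      FSC = "dim", CD45 = "bright", CD3 = "bright", CD8 = "bright",
      CD27 = "bright", CD28 = "bright"),
    L("cd8_tem_late", 40, 0.55,
      FSC = "dim", CD45 = "bright", CD3 = "bright", CD8 = "bright"),
    L("cd8_tem_other", 30, 0.50,
      FSC = "dim", CD45 = "bright", CD3 = "bright", CD8 = "bright",
      CD27 = "bright"),
    L("cd8_temra_early", 18, 0.55,
      FSC = "dim", CD45 = "bright", CD3 = "bright", CD8 = "bright",
      CD45RA = "bright", CD27 = "bright", CD28 = "bright"),
    L("cd8_temra_late", 55, 0.55,
      FSC = "dim", CD45 = "bright", CD3 = "bright", CD8 = "bright",
      CD45RA = "bright"),
    L("cd8_temra_other", 18, 0.55,
      FSC = "dim", CD45 = "bright", CD3 = "bright", CD8 = "bright",
      CD45RA = "bright", CD27 = "bright")
  )
}

## intensity band parameters on the log scale
band_meanlog <- c(neg = 2, dim = 4, bright = 6)
band_sdlog <- 0.25

#' Default synthetic population models
#'
#' One model per generator leaf population: its id, baseline concentration
#' (cells/uL), lognormal dispersion of the between-participant concentration
#' distribution, and per-channel lognormal intensity parameters for both
#' tubes (band centres e^2 / e^4 / e^6 for negative / dim / bright, common
#' log-sd 0.25, giving populations separated by about 4 standard deviations
#' from the default gate cuts).
#'
#' @return a list of class `population_models`; one element per leaf with
#'   fields `leaf`, `base`, `sdlog`, and `bands` (named character vector of
#'   non-negative channel bands).
#' @export
default_population_models <- function() {
  models <- leaf_table()
  names(models) <- vapply(models, `[[`, "", "leaf")
  ## every referenced channel must exist in at least one tube
  for (m in models) {
    bad <- setdiff(names(m$bands), all_channels())
    if (length(bad))
      stop("unknown channel in model ", m$leaf, ": ",
           paste(bad, collapse = ", "))
  }
  class(models) <- "population_models"
  models
}

## channel intensity meanlog for a leaf in a tube (negative if unlisted)
leaf_channel_meanlog <- function(model, channels) {
  lvl <- rep("neg", length(channels))
  names(lvl) <- channels
  hit <- intersect(names(model$bands), channels)
  lvl[hit] <- model$bands[hit]
  unname(band_meanlog[lvl])
}

## Representative intensity centroid of a leaf over the given channels,
## used to decide which gates a leaf's events fall into.
leaf_centroid <- function(model, channels) {
  x <- exp(leaf_channel_meanlog(model, channels))
  names(x) <- channels
  x
}

#' Map phenotypes to the generator leaf populations they aggregate
#'
#' Derived, not hand-maintained: each leaf's intensity centroid is pushed
#' through the gating predicates of its tube, so the truth-level aggregation
#' is guaranteed to agree with what event-level gating recovers.
#'
#' @param defs phenotype definition table.
#' @param models population models, see [default_population_models()].
#' @param thresholds channel threshold table.
#' @return named list: phenotype id -> character vector of leaf ids.
#' @export
phenotype_leaf_map <- function(defs = default_phenotypes(),
                               models = default_population_models(),
                               thresholds = default_thresholds()) {
  map <- list()
  for (tube in unique(defs$tube)) {
    dtube <- defs[defs$tube == tube, , drop = FALSE]
    channels <- tube_channels(tube)
    cent <- do.call(rbind, lapply(models, leaf_centroid, channels))
    events <- as.data.frame(cent)
    res <- classify_events(events, dtube, thresholds = thresholds,
                           tube = tube)
    for (ph in dtube$phenotype[dtube$primary]) {
      map[[ph]] <- names(models)[res$membership[[ph]]]
    }
  }
  map[enumerated_phenotypes(defs)]
}

#' Parent map used for proportion denominators
#'
#' Subpopulations are expressed as a percentage of their major lineage
#' (T cells, B cells, NK cells, monocytes), except that CD4 and CD8
#' subpopulations are expressed as a percentage of CD4+ respectively CD8+
#' T cells. Top-level lineages have no denominator and get no proportion.
#'
#' @return named character vector: phenotype -> denominator phenotype
#'   (`NA` for top-level lineages).
#' @export
default_parent_map <- function() {
  c(neutrophils = NA, monocytes = NA, lymphocytes = NA,
    monocytes_cd16neg = "monocytes", monocytes_cd16pos = "monocytes",
    t_cells = "lymphocytes", b_cells = "lymphocytes",
    nk_cells = "lymphocytes",
    t_cd56pos = "t_cells", t_cd4 = "t_cells", t_cd8 = "t_cells",
    b_transitional = "b_cells", b_naive = "b_cells", b_memory = "b_cells",
    nk_cd56bright_cd16neg = "nk_cells", nk_cd56dim_cd16pos = "nk_cells",
    nk_cd56dim_cd16neg = "nk_cells", nk_cd56neg_cd16pos = "nk_cells",
    cd4_naive = "t_cd4", cd4_cm = "t_cd4", cd4_tem = "t_cd4",
    cd4_temra = "t_cd4", cd4_tem_early = "t_cd4", cd4_tem_late = "t_cd4",
    cd4_temra_early = "t_cd4", cd4_temra_late = "t_cd4",
    treg = "t_cd4", treg_naive = "t_cd4", tfh = "t_cd4",
    cd8_naive = "t_cd8", cd8_cm = "t_cd8", cd8_tem = "t_cd8",
    cd8_temra = "t_cd8", cd8_tem_early = "t_cd8", cd8_tem_late = "t_cd8",
    cd8_temra_early = "t_cd8", cd8_temra_late = "t_cd8")
}
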