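## Gate predicate machinery. A gate string is a comma-separated conjunction
## of channel=relation terms, e.g. "SSC=bright,CD45=dim". Relations refer to
## the per-channel neg/dim/bright bands defined by the threshold table:
##   negative: x <  low
##   positive: x >= low          (dim or bright)
##   dim:      low <= x < high
##   bright:   x >= high
## Ties exactly at a cut are assigned to the higher band.

parse_gate <- function(gate) {
  if (is.na(gate) || !nzchar(gate)) return(list())
  terms <- strsplit(gate, ",", fixed = TRUE)[[1]]
  out <- lapply(terms, function(t) {
    kv <- strsplit(trimws(t), "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("malformed gate term: '", t, "'")
    rel <- match.arg(kv[2], c("negative", "positive", "dim", "bright"))
    list(channel = kv[1], relation = rel)
  })
  out
}

eval_predicate <- function(events, channel, relation, thresholds,
                           phenotype = "<gate>") {
  if (!channel %in% names(events))
    stop("channel '", channel, "' required by phenotype '", phenotype,
         "' is missing from the event table")
  row <- thresholds[thresholds$channel == channel, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("no threshold defined for channel '", channel, "'")
  x <- events[[channel]]
  switch(relation,
         negative = x < row$low,
         positive = x >= row$low,
         dim = x >= row$low & x < row$high,
         bright = x >= row$high)
}

## order rows so parents precede children
topo_order <- function(defs) {
  placed <- character(0)
  order <- integer(0)
  remaining <- seq_len(nrow(defs))
  while (length(remaining)) {
    ready <- remaining[is.na(defs$parent[remaining]) |
                         defs$parent[remaining] %in% placed]
    if (!length(ready))
      stop("phenotype table is not a tree: unresolved parents ",
           paste(unique(defs$parent[remaining]), collapse = ", "))
    order <- c(order, ready)
    placed <- c(placed, defs$phenotype[ready])
    remaining <- setdiff(remaining, ready)
  }
  order
}

#' Classify events into hierarchical phenotypes
#'
#' Descends the phenotype tree, applying each gate's predicates on top of
#' all ancestor predicates, so a child's events are by construction a
#' subset of its parent's. Events inside the root that match none of the
#' root's direct children are reported as unclassified.
#'
#' @param events data.frame of events (rows) by channels (columns).
#' @param defs phenotype definition table (see [default_phenotypes()]);
#'   only rows for `tube` are used.
#' @param thresholds channel threshold table, see [default_thresholds()].
#' @param tube which tube's definitions to apply; defaults to the `tube`
#'   attribute of `events` if present.
#' @return an object of class `gating_result`: list with `counts` (named
#'   event counts), `membership` (named list of event row indices),
#'   `unclassified` (count), `n_events`, `tube`, and the `events` table
#'   (retained for marker-expression summaries).
#' @examples
#' ev <- data.frame(FSC = 60, SSC = 500, CD45 = 60, CD3 = 5, CD19 = 5,
#'                  CD56 = 5, CD16 = 500, CD4 = 5, CD8 = 5, CD27 = 5,
#'                  CD38 = 5, HLADR = 5, IgD = 5)
#' res <- classify_events(ev, tube = "trucount")
#' res$counts[["neutrophils"]]  # side-scatter bright, CD45 dim
#' @export
classify_events <- function(events, defs = default_phenotypes(),
                            thresholds = default_thresholds(),
                            tube = attr(events, "tube")) {
  if (is.null(tube))
    stop("tube must be given (or set as an attribute of the event table)")
  defs <- defs[defs$tube == tube, , drop = FALSE]
  if (!nrow(defs)) stop("no phenotype definitions for tube '", tube, "'")
  defs <- defs[topo_order(defs), , drop = FALSE]

  n <- nrow(events)
  membership <- vector("list", nrow(defs))
  names(membership) <- defs$phenotype
  member_mask <- list()
  for (i in seq_len(nrow(defs))) {
    ph <- defs$phenotype[i]
    base <- if (is.na(defs$parent[i])) rep(TRUE, n)
            else member_mask[[defs$parent[i]]]
    keep <- base
    for (p in parse_gate(defs$gate[i]))
      keep <- keep & eval_predicate(events, p$channel, p$relation,
                                    thresholds, ph)
    member_mask[[ph]] <- keep
    membership[[ph]] <- which(keep)
  }

  roots <- defs$phenotype[is.na(defs$parent)]
  unclassified <- 0L
  for (rt in roots) {
    kids <- defs$phenotype[!is.na(defs$parent) & defs$parent == rt]
    if (length(kids)) {
      in_kid <- Reduce(`|`, member_mask[kids], rep(FALSE, n))
      unclassified <- unclassified + sum(member_mask[[rt]] & !in_kid)
    }
  }

  structure(list(counts = lengths(membership),
                 membership = membership,
                 unclassified = unclassified,
                 n_events = n, tube = tube, events = events),
            class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  cat("Gating result (", x$tube, " tube): ", x$n_events, " events, ",
      x$unclassified, " unclassified in root\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Partition T cells into memory differentiation stages
#'
#' Applies the CCR7-by-CD45RA quadrant scheme to events already gated as
#' CD4+ or CD8+ T cells: naive (CCR7+CD45RA+), central memory
#' (CCR7+CD45RA-), effector memory (Tem, CCR7-CD45RA-) and effector memory
#' re-expressing CD45RA (TemRA, CCR7-CD45RA+). The four quadrants partition
#' the input exactly. Tem and TemRA events are further staged as early
#' (CD27+CD28+) or late (CD27-CD28-); the two mixed CD27/CD28 states belong
#' to neither stage and are reported as `other`. Stage is `NA` for naive
#' and central-memory events.
#'
#' @param t_events data.frame of T-cell events with CCR7, CD45RA, CD27 and
#'   CD28 columns.
#' @param thresholds channel threshold table.
#' @return data.frame with factor columns `subset`
#'   (naive/cm/tem/temra) and `stage` (early/late/other or `NA`).
#' @export
memory_t_partition <- function(t_events, thresholds = default_thresholds()) {
  ccr7 <- eval_predicate(t_events, "CCR7", "positive", thresholds, "memory")
  ra <- eval_predicate(t_events, "CD45RA", "positive", thresholds, "memory")
  cd27 <- eval_predicate(t_events, "CD27", "positive", thresholds, "memory")
  cd28 <- eval_predicate(t_events, "CD28", "positive", thresholds, "memory")
  subset <- ifelse(ccr7, ifelse(ra, "naive", "cm"),
                   ifelse(ra, "temra", "tem"))
  stage <- ifelse(cd27 & cd28, "early",
                  ifelse(!cd27 & !cd28, "late", "other"))
  stage[subset %in% c("naive", "cm")] <- NA
  data.frame(subset = factor(subset, c("naive", "cm", "tem", "temra")),
             stage = factor(stage, c("early", "late", "other")))
}

#' Label B-cell and NK subpopulations among lymphocyte events
#'
#' CD3+ events are labelled as T cells (CD56+ T cells if they co-express
#' CD56 -- they are not counted as NK cells). CD19+ B cells are split into
#' transitional (CD38 bright CD27-), naive (CD38 dim CD27-) and memory
#' (CD38 dim CD27+); remaining B cells are `b_other`. CD3-CD19- events are
#' NK cells subdivided by their CD56-by-CD16 bands; combinations outside
#' the four enumerated subsets are `nk_other`.
#'
#' @param events data.frame of lymphocyte events from the bead tube.
#' @param thresholds channel threshold table.
#' @return character vector of labels, one per event.
#' @export
b_nk_partition <- function(events, thresholds = default_thresholds()) {
  pred <- function(ch, rel) eval_predicate(events, ch, rel, thresholds,
                                           "b_nk_partition")
  cd3 <- pred("CD3", "positive")
  cd19 <- pred("CD19", "positive")
  cd56b <- pred("CD56", "bright"); cd56d <- pred("CD56", "dim")
  cd56n <- pred("CD56", "negative")
  cd16p <- pred("CD16", "positive"); cd16n <- pred("CD16", "negative")
  cd27p <- pred("CD27", "positive")
  cd38b <- pred("CD38", "bright"); cd38d <- pred("CD38", "dim")

  lab <- rep("nk_other", nrow(events))
  lab[cd3] <- ifelse(pred("CD56", "positive")[cd3], "t_cd56pos", "t_other")
  b <- !cd3 & cd19
  lab[b & cd38b & !cd27p] <- "b_transitional"
  lab[b & cd38d & !cd27p] <- "b_naive"
  lab[b & cd38d & cd27p] <- "b_memory"
  lab[b & !(cd38b & !cd27p) & !cd38d] <- "b_other"
  nk <- !cd3 & !cd19
  lab[nk & cd56b & cd16n] <- "nk_cd56bright_cd16neg"
  lab[nk & cd56d & cd16p] <- "nk_cd56dim_cd16pos"
  lab[nk & cd56d & cd16n] <- "nk_cd56dim_cd16neg"
  lab[nk & cd56n & cd16p] <- "nk_cd56neg_cd16pos"
  lab
}

#' Summarize marker expression within a gated phenotype
#'
#' @param result a `gating_result` from [classify_events()].
#' @param phenotype phenotype id present in the result.
#' @param channel channel name present in the event table.
#' @param stat summary function, default the median fluorescence intensity.
#' @return the summary statistic, or `NA_real_` for an empty gate (an
#'   absent population has no expression level; it is missing, not zero).
#' @export
marker_expression_summary <- function(result, phenotype, channel,
                                      stat = stats::median) {
  stopifnot(inherits(result, "gating_result"))
  if (!phenotype %in% names(result$membership))
    stop("phenotype '", phenotype, "' not in gating result")
  if (!channel %in% names(result$events))
    stop("channel '", channel, "' not in event table")
  idx <- result$membership[[phenotype]]
  if (!length(idx)) return(NA_real_)
  stat(result$events[[channel]][idx])
}

## all configured marker summaries for one gating result
marker_summary_table <- function(result,
                                 config = default_marker_summaries()) {
  config <- config[config$phenotype %in% names(result$membership) &
                     config$channel %in% names(result$events), ,
                   drop = FALSE]
  config$median <- mapply(function(ph, ch)
    marker_expression_summary(result, ph, ch), config$phenotype,
    config$channel)
  config
}

#' Restrict monocyte gates to HLA-DR positive events
#'
#' Sensitivity-analysis variant of the phenotype table in which every
#' monocyte population must additionally be HLA-DR positive, guarding the
#' monocyte gates against contamination by NK cells and neutrophils. All
#' other definitions are untouched; applying the filter twice is the same
#' as applying it once.
#'
#' @param defs phenotype definition table.
#' @return the modified definition table.
#' @export
hladr_sensitivity_filter <- function(defs = default_phenotypes()) {
  mono <- grepl("^monocytes", defs$phenotype) & defs$tube == "trucount"
  add <- mono & !grepl("HLADR=positive", defs$gate, fixed = TRUE)
  defs$gate[add] <- paste0(defs$gate[add], ",HLADR=positive")
  defs
}

#' Count bead events in a bead-tube event table
#'
#' Counting beads fluoresce brightly in all antibody channels; no cell is
#' simultaneously CD3 bright and CD19 bright, so that conjunction isolates
#' the bead population.
#'
#' @param events bead-tube event table.
#' @param thresholds channel threshold table.
#' @return integer bead-event count.
#' @export
count_bead_events <- function(events, thresholds = default_thresholds()) {
  sum(eval_predicate(events, "CD3", "bright", thresholds, "beads") &
        eval_predicate(events, "CD19", "bright", thresholds, "beads"))
}
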