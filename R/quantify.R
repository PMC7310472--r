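#' Absolute concentration from bead-tube counts
#'
#' Bead-ratio arithmetic for tubes spiked with a known number of counting
#' beads: the same acquisition fraction applies to cells and beads, so
#'
#'   cells/uL = gated events x (beads per tube / bead events) / volume.
#'
#' @param events_in_gate gated event count(s); vectorized.
#' @param cal list with `beads_per_tube`, `bead_events`, `sample_volume`
#'   (uL); see [trucount_calibration()].
#' @return concentration(s) in cells/uL.
#' @examples
#' trucount_concentration(1000,
#'   trucount_calibration(beads_per_tube = 50000, bead_events = 500,
#'                        sample_volume = 50))  # 2000 cells/uL
#' @export
trucount_concentration <- function(events_in_gate, cal) {
  stopifnot(all(events_in_gate >= 0))
  cal <- trucount_calibration(cal$beads_per_tube, cal$bead_events,
                              cal$sample_volume)
  events_in_gate * (cal$beads_per_tube / cal$bead_events) /
    cal$sample_volume
}

#' Bead-tube calibration record
#'
#' @param beads_per_tube nominal bead count in the tube.
#' @param bead_events bead events acquired.
#' @param sample_volume stained blood volume in uL.
#' @return validated list of class `trucount_calibration`.
#' @export
trucount_calibration <- function(beads_per_tube, bead_events,
                                 sample_volume) {
  if (bead_events == 0) stop("no bead events acquired: cannot calibrate")
  stopifnot(beads_per_tube > 0, bead_events > 0, sample_volume > 0)
  if (bead_events > beads_per_tube)
    warning("more bead events (", bead_events,
            ") than nominal beads per tube (", beads_per_tube,
            "): implausible calibration")
  structure(list(beads_per_tube = beads_per_tube,
                 bead_events = bead_events,
                 sample_volume = sample_volume),
            class = "trucount_calibration")
}

#' Scale plain-tube counts to absolute concentrations via the CD3 ratio
#'
#' Phenotypes gated in the bead-free tube are quantified through the CD3
#' T-cell bridge: the bead tube yields an absolute CD3 concentration, and a
#' plain-tube gate with `falcon_events` events among `cd3_events_falcon`
#' CD3 events has concentration
#'
#'   cells/uL = falcon events x (CD3 cells/uL from bead tube / CD3 events).
#'
#' Scaling the plain tube's own CD3 count recovers the bead-tube CD3
#' concentration exactly.
#'
#' @param falcon_events gated event count(s) in the plain tube; vectorized.
#' @param cd3_events_falcon CD3+ event count in the plain tube (> 0).
#' @param cd3_conc_trucount CD3 concentration (cells/uL) from the bead tube.
#' @return concentration(s) in cells/uL.
#' @export
falcon_scaling <- function(falcon_events, cd3_events_falcon,
                           cd3_conc_trucount) {
  if (cd3_events_falcon <= 0)
    stop("no CD3 events in the plain tube: cross-tube scaling impossible")
  stopifnot(all(falcon_events >= 0), cd3_conc_trucount >= 0)
  falcon_events * (cd3_conc_trucount / cd3_events_falcon)
}

#' Quantify one participant's two-tube gating results
#'
#' Bead-tube phenotypes are converted by [trucount_concentration()]; the
#' plain tube's T-cell differentiation phenotypes by [falcon_scaling()]
#' through the CD3 bridge. If the plain tube has no CD3 events, its
#' phenotypes are set to missing and the participant is flagged.
#'
#' @param trucount_result,falcon_result `gating_result`s for the two tubes.
#' @param cal `trucount_calibration` for the bead tube.
#' @param defs phenotype definition table.
#' @return named numeric vector over the 37 enumerated phenotypes with
#'   attribute `flagged` (TRUE if cross-tube scaling failed).
#' @export
quantify_participant <- function(trucount_result, falcon_result, cal,
                                 defs = default_phenotypes()) {
  phenos <- enumerated_phenotypes(defs)
  primary_tube <- vapply(phenos, function(ph)
    defs$tube[defs$phenotype == ph & defs$primary][1], "")
  conc <- stats::setNames(rep(NA_real_, length(phenos)), phenos)
  tru <- phenos[primary_tube == "trucount"]
  conc[tru] <- trucount_concentration(trucount_result$counts[tru], cal)
  flagged <- FALSE
  fal <- phenos[primary_tube == "falcon"]
  cd3_falcon <- falcon_result$counts[["t_cells"]]
  if (cd3_falcon <= 0) {
    flagged <- TRUE
    warning("participant flagged: no CD3 events in the plain tube; ",
            "plain-tube phenotypes set missing")
  } else {
    cd3_conc <- trucount_concentration(
      trucount_result$counts[["t_cells"]], cal)
    conc[fal] <- falcon_scaling(falcon_result$counts[fal], cd3_falcon,
                                cd3_conc)
  }
  attr(conc, "flagged") <- flagged
  conc
}

#' Assemble a participant-by-phenotype count matrix
#'
#' @param quantified named list: participant id -> vector from
#'   [quantify_participant()] (or any named concentration vector over the
#'   same phenotypes).
#' @return numeric matrix, participants in rows, phenotypes in columns.
#' @export
build_count_matrix <- function(quantified) {
  stopifnot(length(quantified) > 0)
  phenos <- names(quantified[[1]])
  m <- do.call(rbind, lapply(quantified, function(v) v[phenos]))
  rownames(m) <- names(quantified)
  colnames(m) <- phenos
  m
}

#' Proportions of subpopulations within their designated parent
#'
#' Each subpopulation is divided by its denominator phenotype (its major
#' lineage, or CD4+/CD8+ T cells for the CD4/CD8 subpopulations) and
#' expressed in percent. Phenotypes without a denominator, and cells whose
#' denominator is zero or missing, are missing.
#'
#' @param cm count matrix (participants x phenotypes).
#' @param parent_map named vector phenotype -> denominator phenotype; see
#'   [default_parent_map()].
#' @return matrix of percentages with the same shape as `cm`.
#' @export
compute_proportions <- function(cm, parent_map = default_parent_map()) {
  prop <- matrix(NA_real_, nrow(cm), ncol(cm), dimnames = dimnames(cm))
  for (ph in colnames(cm)) {
    par <- if (ph %in% names(parent_map)) parent_map[[ph]] else NA
    if (is.na(par)) next
    denom <- cm[, par]
    denom[!is.na(denom) & denom == 0] <- NA
    prop[, ph] <- 100 * cm[, ph] / denom
  }
  prop
}

## phenotypes wiped by each lineage exclusion flag
exclusion_scope <- function(defs = default_phenotypes()) {
  phenos <- enumerated_phenotypes(defs)
  list(
    lymphocytes = setdiff(phenos, c("neutrophils", "monocytes",
                                    "monocytes_cd16neg",
                                    "monocytes_cd16pos")),
    monocytes = c("monocytes", "monocytes_cd16neg", "monocytes_cd16pos")
  )
}

#' Apply manual debris-exclusion flags to a count matrix
#'
#' Mirrors the manual judgment that some lineages were not clearly
#' distinguishable from debris for some participants: flagged
#' participant-by-lineage cells are set to missing. Flags are input
#' metadata, not auto-detected.
#'
#' @param cm count matrix (participants x phenotypes, participant ids as
#'   row names).
#' @param flags data.frame with columns `participant_id` and `lineage`
#'   (`"lymphocytes"` or `"monocytes"`); a participant may be flagged for
#'   both lineages on two rows.
#' @return the count matrix with flagged cells missing; the number of
#'   participants affected per lineage is reported in a message.
#' @export
apply_exclusions <- function(cm, flags) {
  if (is.null(flags) || nrow(flags) == 0) return(cm)
  scope <- exclusion_scope()
  bad <- setdiff(unique(flags$lineage), names(scope))
  if (length(bad))
    stop("unknown exclusion lineage: ", paste(bad, collapse = ", "))
  missing_ids <- setdiff(flags$participant_id, rownames(cm))
  if (length(missing_ids))
    stop("flagged participants absent from the count matrix: ",
         paste(missing_ids, collapse = ", "))
  for (lin in unique(flags$lineage)) {
    ids <- unique(flags$participant_id[flags$lineage == lin])
    cm[ids, scope[[lin]]] <- NA_real_
    message(length(ids), " participant(s) excluded for the ", lin,
            " subpopulations")
  }
  cm
}
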