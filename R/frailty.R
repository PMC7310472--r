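#' Deficit-accumulation (Rockwood-type) frailty index
#'
#' The index is the mean of 36 health-deficit items, each scored in
#' \[0, 1\] (binary presence or graded severity), so it runs from 0 (no
#' deficit present, 'best') to 1 (all 36 present, 'worst'). With missing
#' items the index is computed over the observed items provided at least
#' `min_items` are observed; otherwise it is missing.
#'
#' @param deficits numeric vector of exactly `n_items` values in \[0, 1\]
#'   (NA allowed), or a matrix/data.frame with one row per participant.
#' @param n_items number of items the instrument defines (36).
#' @param min_items minimum observed items required for a score.
#' @return frailty index value(s) in \[0, 1\], NA where unscorable.
#' @examples
#' frailty_index(rep(1, 36))  # 1, 'worst'
#' frailty_index(rep(0, 36))  # 0, 'best'
#' frailty_index(c(rep(1, 9), rep(0, 27)))  # 0.25
#' @export
frailty_index <- function(deficits, n_items = 36L, min_items = 30L) {
  if (is.data.frame(deficits)) deficits <- as.matrix(deficits)
  if (!is.matrix(deficits)) deficits <- matrix(deficits, nrow = 1)
  if (ncol(deficits) != n_items)
    stop("expected exactly ", n_items, " deficit items, got ",
         ncol(deficits))
  rng <- suppressWarnings(range(deficits, na.rm = TRUE))
  if (any(is.finite(rng)) && (rng[1] < 0 || rng[2] > 1))
    stop("deficit items must lie in [0, 1]")
  n_obs <- rowSums(!is.na(deficits))
  idx <- rowMeans(deficits, na.rm = TRUE)
  idx[n_obs < min_items] <- NA_real_
  idx[n_obs == 0] <- NA_real_
  unname(idx)
}

#' Square-root transform of the frailty index
#'
#' Monotone, rank-preserving transform used as the prediction response to
#' make the right-skewed index distribution more symmetric.
#'
#' @param index frailty index value(s) in \[0, 1\].
#' @return transformed score(s) in \[0, 1\].
#' @export
sqrt_transform <- function(index) {
  stopifnot(all(is.na(index) | (index >= 0 & index <= 1)))
  sqrt(index)
}

#' Restrict a cohort to the frailty analysis set
#'
#' Participants without a frailty index score are removed from frailty
#' analyses only; sex and CMV association sets are unaffected and should
#' use the full cohort.
#'
#' @param cohort cohort data.frame containing a `frailty_index` column (or
#'   a `frailty_missing` flag).
#' @return the cohort rows with an observed frailty index.
#' @export
analysis_set <- function(cohort) {
  if ("frailty_index" %in% names(cohort)) {
    keep <- !is.na(cohort$frailty_index)
  } else if ("frailty_missing" %in% names(cohort)) {
    keep <- !cohort$frailty_missing
  } else {
    stop("cohort has neither 'frailty_index' nor 'frailty_missing'")
  }
  if (!any(keep)) warning("analysis set is empty: all frailty scores missing")
  cohort[keep, , drop = FALSE]
}

#' Add frailty scores to a cohort table
#'
#' Computes the frailty index from the cohort's deficit columns and its
#' square-root transform, respecting the missing-frailty flag.
#'
#' @param cohort cohort data.frame with deficit columns named
#'   `deficit_01` ... `deficit_36`.
#' @param min_items see [frailty_index()].
#' @return the cohort with `frailty_index` and `frailty_sqrt` columns.
#' @export
add_frailty_scores <- function(cohort, min_items = 30L) {
  cols <- grep("^deficit_", names(cohort), value = TRUE)
  cohort$frailty_index <- frailty_index(cohort[, cols],
                                        n_items = length(cols),
                                        min_items = min_items)
  if ("frailty_missing" %in% names(cohort))
    cohort$frailty_index[cohort$frailty_missing] <- NA_real_
  cohort$frailty_sqrt <- sqrt_transform(cohort$frailty_index)
  cohort
}
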