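#' Build a block design for stratified permutation analysis
#'
#' Blocks are the cross-classification of the chosen stratification
#' factors: four age groups for every analysis, and additionally CMV
#' serostatus for the sex and frailty analyses (the CMV analyses block on
#' age only). Empty blocks are dropped.
#'
#' @param cohort data.frame with the factor columns.
#' @param factors character vector of column names to cross.
#' @return factor of block ids (one per row) with attribute `sizes`.
#' @export
make_blocks <- function(cohort, factors = c("age_group", "cmv_status")) {
  missing <- setdiff(factors, names(cohort))
  if (length(missing))
    stop("blocking factors not in cohort: ", paste(missing, collapse = ", "))
  b <- interaction(cohort[, factors, drop = FALSE], drop = TRUE, sep = "/")
  attr(b, "sizes") <- table(b)
  b
}

## Per-block rank scores underlying both statistics. Returns NULL for
## blocks that cannot contribute (too small, one group absent, constant).
block_scores_spearman <- function(x, y, blocks, weights, min_block = 3L) {
  n <- length(x)
  s <- numeric(n)       # phenotype-side coefficients
  g <- numeric(n)       # permutable frailty-side scores (block ranks)
  used <- logical(nlevels(blocks))
  names(used) <- levels(blocks)
  wsum <- 0
  parts <- list()
  for (b in levels(blocks)) {
    idx <- which(blocks == b)
    if (length(idx) < min_block) next
    rx <- rank(x[idx]); ry <- rank(y[idx])
    ssx <- sum((rx - mean(rx))^2); ssy <- sum((ry - mean(ry))^2)
    if (ssx == 0 || ssy == 0) next
    w <- if (is.null(weights)) length(idx) else weights[[b]]
    parts[[b]] <- list(idx = idx, coef = w * (rx - mean(rx)) /
                         sqrt(ssx * ssy), g = ry)
    used[b] <- TRUE
    wsum <- wsum + w
  }
  if (!any(used)) return(NULL)
  for (p in parts) {
    s[p$idx] <- p$coef / wsum
    g[p$idx] <- p$g
  }
  list(s = s, g = g, used = used,
       n_used = sum(lengths(lapply(parts, `[[`, "idx"))))
}

block_scores_wmw <- function(x, group, blocks, min_block = 3L) {
  stopifnot(nlevels(factor(group)) == 2)
  group <- factor(group)
  n <- length(x)
  s <- numeric(n); g <- numeric(n)
  used <- logical(nlevels(blocks)); names(used) <- levels(blocks)
  n_used <- 0L
  for (b in levels(blocks)) {
    idx <- which(blocks == b)
    nb <- length(idx)
    if (nb < min_block) next
    n1 <- sum(group[idx] == levels(group)[2])
    n0 <- nb - n1
    if (n1 == 0 || n0 == 0) next
    r <- rank(x[idx])
    ## tie-corrected permutation variance of the rank sum of group 1
    v <- n1 * n0 * sum((r - mean(r))^2) / (nb * (nb - 1))
    if (v <= 0) next
    s[idx] <- (r - mean(r)) / sqrt(v)
    g[idx] <- as.numeric(group[idx] == levels(group)[2])
    used[b] <- TRUE
    n_used <- n_used + nb
  }
  if (!any(used)) return(NULL)
  list(s = s, g = g, used = used, n_used = n_used)
}

## matrix of n_perm columns, each the score vector g permuted independently
## within every block (only blocks marked used are permuted; others are 0)
permute_within_blocks <- function(g, blocks, used, n_perm) {
  out <- matrix(rep(g, n_perm), length(g), n_perm)
  for (b in names(used)[used]) {
    idx <- which(blocks == b)
    k <- length(idx)
    pm <- vapply(seq_len(n_perm), function(j) g[idx][sample.int(k)],
                 numeric(k))
    out[idx, ] <- pm
  }
  out
}

#' Block-weighted Spearman correlation
#'
#' Spearman's rho computed on within-block ranks in every block and
#' combined as a weighted average, with weights defaulting to the block
#' sizes. Blocks with fewer than `min_block` pairs, or with constant
#' values, are dropped (and reported via the `blocks_used` attribute).
#' With a single block this is plain Spearman's rho.
#'
#' @param x,y numeric vectors.
#' @param blocks factor of block ids (see [make_blocks()]); a single block
#'   is assumed if NULL.
#' @param weights optional named list/vector of block weights (default
#'   block sizes).
#' @param min_block minimum pairs for a block to contribute.
#' @return the weighted rho (NA with a diagnostic attribute if no block is
#'   usable), with attributes `blocks_used` and `n_used`.
#' @export
weighted_rho <- function(x, y, blocks = NULL, weights = NULL,
                         min_block = 3L) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  blocks <- if (is.null(blocks)) factor(rep("all", length(x)))
            else droplevels(factor(blocks[ok]))
  sc <- block_scores_spearman(x, y, blocks, weights, min_block)
  if (is.null(sc)) {
    out <- NA_real_
    attr(out, "diagnostic") <- "no block with >= min_block usable pairs"
    return(out)
  }
  structure(sum(sc$s * sc$g), blocks_used = sc$used, n_used = sc$n_used)
}

#' Stratified permutation test with a blocked rank statistic
#'
#' Permutes the outcome (or group labels) independently within each block
#' and computes a two-sided simulated p-value with the add-one estimator
#' `p = (1 + #\{|T*| >= |T|\}) / (n_perm + 1)`, which is valid for any
#' number of permutations. Two statistics are available: the block-weighted
#' Spearman rho ([weighted_rho()]) for a numeric outcome, and a blocked
#' (van Elteren-style) Wilcoxon-Mann-Whitney statistic -- the sum over
#' blocks of centered within-block rank sums, each scaled by its
#' permutation standard deviation -- for a two-level group.
#'
#' @param x numeric phenotype values.
#' @param y_or_group numeric outcome (Spearman) or two-level group (WMW).
#' @param blocks factor of block ids; single block if NULL.
#' @param statistic `"weighted_rho"` or `"wmw"`.
#' @param n_perm number of permutations (>= 100).
#' @param seed optional seed.
#' @param weights optional block weights for the Spearman statistic.
#' @param min_block minimum block size.
#' @return object of class `association_result`: list with `statistic`,
#'   `weighted_rho` (Spearman only), `p`, `mc_se`, `n_perm`, `n_used`,
#'   `blocks_used`.
#' @export
blocked_permutation_test <- function(x, y_or_group, blocks = NULL,
                                     statistic = c("weighted_rho", "wmw"),
                                     n_perm = 10000L, seed = NULL,
                                     weights = NULL, min_block = 3L) {
  statistic <- match.arg(statistic)
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  ok <- stats::complete.cases(x, y_or_group)
  x <- x[ok]; y <- y_or_group[ok]
  blocks <- if (is.null(blocks)) factor(rep("all", length(x)))
            else droplevels(factor(blocks[ok]))

  sc <- switch(statistic,
               weighted_rho = block_scores_spearman(x, y, blocks, weights,
                                                    min_block),
               wmw = block_scores_wmw(x, y, blocks, min_block))
  if (is.null(sc) || sum(abs(sc$s)) == 0) {
    warning("statistic undefined (constant values or no usable block); ",
            "p = 1")
    return(structure(list(statistic = NA_real_, weighted_rho = NA_real_,
                          p = 1, mc_se = 0, n_perm = n_perm, n_used = 0,
                          blocks_used = NULL),
                     class = "association_result"))
  }
  t_obs <- sum(sc$s * sc$g)
  t_perm <- perm_null_linear(sc, blocks, n_perm)
  p <- (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (n_perm + 1)
  structure(list(statistic = t_obs,
                 weighted_rho = if (statistic == "weighted_rho") t_obs
                                else NA_real_,
                 p = p, mc_se = sqrt(p * (1 - p) / n_perm),
                 n_perm = n_perm, n_used = sc$n_used,
                 blocks_used = sc$used),
            class = "association_result")
}

## permutation null of a statistic linear in the permuted score vector,
## chunked to bound memory
perm_null_linear <- function(sc, blocks, n_perm, chunk = 2000L) {
  out <- numeric(n_perm)
  done <- 0L
  while (done < n_perm) {
    k <- min(chunk, n_perm - done)
    G <- permute_within_blocks(sc$g, blocks, sc$used, k)
    out[done + seq_len(k)] <- drop(crossprod(G, sc$s))
    done <- done + k
  }
  out
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "Blocked permutation test: T = %.4f, p = %.4g (MC SE %.2g, %d perms, n = %d)\n",
    x$statistic, x$p, x$mc_se, x$n_perm, x$n_used))
  invisible(x)
}

#' Benjamini-Hochberg step-up decisions
#'
#' @param p_values numeric vector of p-values (one family).
#' @param q false discovery rate level.
#' @return data.frame with `p`, `p_adj` (BH-adjusted), `reject`, and
#'   attribute `threshold_index` (number of ordered p-values at or below
#'   the step-up line).
#' @export
bh_adjust <- function(p_values, q = 0.15) {
  stopifnot(q > 0, q < 1)
  p_adj <- stats::p.adjust(p_values, method = "BH")
  reject <- !is.na(p_adj) & p_adj <= q
  out <- data.frame(p = p_values, p_adj = p_adj, reject = reject)
  m <- sum(!is.na(p_values))
  ps <- sort(p_values[!is.na(p_values)])
  k <- which(ps <= seq_along(ps) / m * q)
  attr(out, "threshold_index") <- if (length(k)) max(k) else 0L
  out
}

#' Run a whole association study across phenotypes
#'
#' Applies the blocked permutation machinery to every phenotype column of a
#' count (or proportion) matrix, with the stratification the study design
#' prescribes: the sex study contrasts men and women blocking on age group
#' and CMV status; the CMV study contrasts serostatus separately per sex
#' blocking on age group; the frailty study correlates each phenotype with
#' the frailty index separately per sex, blocking on age group and CMV
#' status and restricted to the frailty analysis set. Benjamini-Hochberg
#' decisions are taken separately within each study family (per sex
#' stratum).
#'
#' Permutations are shared across phenotypes within a stratum (the outcome
#' side of the statistic is permuted once), which is what makes genome-scan
#' sized studies cheap; phenotypes with missing values fall back to
#' per-phenotype tests.
#'
#' @param cm count matrix (participants x phenotypes, ids as row names), or
#'   a proportion matrix for `scale = "proportion"` runs.
#' @param cohort cohort data.frame with `participant_id`, `sex`,
#'   `age_group`, `cmv_status`, `frailty_index`.
#' @param study `"sex"`, `"cmv_by_sex"` or `"frailty_by_sex"`.
#' @param scale label recorded in the output (`"absolute"` or
#'   `"proportion"`); the matrix passed in must already be on that scale.
#' @param n_perm,seed,weights,fdr,min_block test settings.
#' @return data.frame with one row per phenotype x stratum: `phenotype`,
#'   `stratum`, `test`, `statistic`, `weighted_rho`, `p`, `mc_se`,
#'   `bh_reject`, `scale`.
#' @export
run_association_study <- function(cm, cohort,
                                  study = c("sex", "cmv_by_sex",
                                            "frailty_by_sex"),
                                  scale = c("absolute", "proportion"),
                                  n_perm = 10000L, seed = NULL,
                                  weights = NULL, fdr = 0.15,
                                  min_block = 3L) {
  study <- match.arg(study)
  scale <- match.arg(scale)
  if (!is.null(seed)) set.seed(seed)
  cohort <- as.data.frame(cohort)
  idx <- match(cohort$participant_id, rownames(cm))
  if (anyNA(idx))
    stop("count matrix is missing participants: ",
         paste(utils::head(cohort$participant_id[is.na(idx)]),
               collapse = ", "))
  cm <- cm[idx, , drop = FALSE]

  strata <- switch(study,
                   sex = list(all = rep(TRUE, nrow(cohort))),
                   cmv_by_sex = ,
                   frailty_by_sex = list(M = cohort$sex == "M",
                                         F = cohort$sex == "F"))
  out <- list()
  for (st in names(strata)) {
    keep <- strata[[st]]
    if (!any(keep)) next
    coh <- cohort[keep, , drop = FALSE]
    mat <- cm[keep, , drop = FALSE]
    if (study == "frailty_by_sex") {
      sel <- !is.na(coh$frailty_index)
      coh <- coh[sel, , drop = FALSE]
      mat <- mat[sel, , drop = FALSE]
    }
    blocks <- switch(study,
                     sex = make_blocks(coh, c("age_group", "cmv_status")),
                     cmv_by_sex = make_blocks(coh, "age_group"),
                     frailty_by_sex = make_blocks(coh, c("age_group",
                                                         "cmv_status")))
    outcome <- switch(study, sex = coh$sex, cmv_by_sex = coh$cmv_status,
                      frailty_by_sex = coh$frailty_index)
    stat <- if (study == "frailty_by_sex") "weighted_rho" else "wmw"
    res <- batch_blocked_tests(mat, outcome, blocks, stat, n_perm,
                               weights, min_block)
    res$stratum <- st
    res$test <- stat
    out[[st]] <- res
  }
  out <- do.call(rbind, out)
  out$bh_reject <- FALSE
  for (st in unique(out$stratum)) {
    fam <- out$stratum == st
    out$bh_reject[fam] <- bh_adjust(out$p[fam], fdr)$reject
  }
  out$scale <- scale
  rownames(out) <- NULL
  out[, c("phenotype", "stratum", "test", "statistic", "weighted_rho",
          "p", "mc_se", "bh_reject", "scale")]
}

## shared-permutation engine: one permuted outcome matrix per stratum,
## reused by every complete phenotype column
batch_blocked_tests <- function(mat, outcome, blocks, statistic, n_perm,
                                weights, min_block) {
  phenos <- colnames(mat)
  res <- data.frame(phenotype = phenos, statistic = NA_real_,
                    weighted_rho = NA_real_, p = NA_real_,
                    mc_se = NA_real_, stringsAsFactors = FALSE)
  complete <- !apply(mat, 2, anyNA)
  Gshared <- NULL; used_shared <- NULL
  for (j in seq_along(phenos)) {
    x <- mat[, j]
    if (!complete[j]) {
      r <- suppressWarnings(
        blocked_permutation_test(x, outcome, blocks, statistic,
                                 n_perm = n_perm, weights = weights,
                                 min_block = min_block))
      res$statistic[j] <- r$statistic
      res$weighted_rho[j] <- r$weighted_rho
      res$p[j] <- r$p; res$mc_se[j] <- r$mc_se
      next
    }
    sc <- switch(statistic,
                 weighted_rho = block_scores_spearman(
                   x, outcome, blocks, weights, min_block),
                 wmw = block_scores_wmw(x, outcome, blocks, min_block))
    if (is.null(sc) || sum(abs(sc$s)) == 0) {
      res$p[j] <- 1; res$mc_se[j] <- 0
      next
    }
    if (is.null(Gshared) || !identical(sc$used, used_shared)) {
      Gshared <- permute_within_blocks(sc$g, blocks, sc$used, n_perm)
      used_shared <- sc$used
    } else if (statistic == "weighted_rho") {
      ## same usable blocks: the permuted y-rank matrix is reusable as is
    }
    t_obs <- sum(sc$s * sc$g)
    t_perm <- drop(crossprod(Gshared, sc$s))
    p <- (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (n_perm + 1)
    res$statistic[j] <- t_obs
    res$weighted_rho[j] <- if (statistic == "weighted_rho") t_obs
                           else NA_real_
    res$p[j] <- p
    res$mc_se[j] <- sqrt(p * (1 - p) / n_perm)
  }
  res
}
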