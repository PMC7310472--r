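## Independent oracles used across tests. These deliberately avoid the
## package's own computational paths (linear-score permutation engine),
## recomputing statistics from their definitions.

## weighted per-block Spearman rho, straight from the definition
oracle_weighted_rho <- function(x, y, blocks, min_block = 3L) {
  num <- 0; den <- 0
  for (b in unique(blocks)) {
    idx <- blocks == b
    if (sum(idx) < min_block) next
    r <- suppressWarnings(stats::cor(x[idx], y[idx], method = "spearman"))
    if (is.na(r)) next
    num <- num + sum(idx) * r
    den <- den + sum(idx)
  }
  if (den == 0) NA_real_ else num / den
}

## blocked WMW statistic: per-block centered rank sum of group 2 divided by
## its tie-corrected permutation SD, summed over blocks
oracle_wmw_stat <- function(x, g, blocks) {
  g <- factor(g)
  t_sum <- 0
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    nb <- length(idx)
    if (nb < 3) next
    gi <- g[idx]
    n1 <- sum(gi == levels(g)[2]); n0 <- nb - n1
    if (n1 == 0 || n0 == 0) next
    r <- rank(x[idx])
    w <- sum(r[gi == levels(g)[2]])
    v <- n1 * n0 * sum((r - mean(r))^2) / (nb * (nb - 1))
    t_sum <- t_sum + (w - n1 * mean(r)) / sqrt(v)
  }
  t_sum
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

## exact two-sided p over all within-block permutations of y (or labels)
oracle_exact_p <- function(x, y, blocks, statistic = c("weighted_rho",
                                                       "wmw")) {
  statistic <- match.arg(statistic)
  stat_fun <- switch(statistic,
                     weighted_rho = function(yy)
                       oracle_weighted_rho(x, yy, blocks),
                     wmw = function(yy) oracle_wmw_stat(x, yy, blocks))
  t_obs <- stat_fun(y)
  blks <- unique(blocks)
  perm_sets <- lapply(blks, function(b) all_perms(sum(blocks == b)))
  grid <- expand.grid(lapply(perm_sets, function(p) seq_len(nrow(p))))
  t_all <- vapply(seq_len(nrow(grid)), function(i) {
    yy <- y
    for (k in seq_along(blks)) {
      idx <- which(blocks == blks[k])
      yy[idx] <- y[idx][perm_sets[[k]][grid[i, k], ]]
    }
    stat_fun(yy)
  }, 0)
  list(p = mean(abs(t_all) >= abs(t_obs) - 1e-12), t_obs = t_obs,
       n_arrangements = nrow(grid))
}

## small labeled event cohort shared by gating tests
make_labeled_tubes <- function(seed = 101, frac = 0.05) {
  sim <- generate_cohort(cohort_spec(n_men = 1, n_women = 1,
                                     missing_frailty = c(men = 0,
                                                         women = 0),
                                     acquisition_fraction = frac,
                                     seed = seed))
  p <- cohort_participant(sim, 1)
  list(sim = sim, p = p,
       tru = generate_tube_events(p, "trucount", seed = seed + 1,
                                  keep_labels = TRUE),
       fal = generate_tube_events(p, "falcon", seed = seed + 2,
                                  keep_labels = TRUE))
}

## single synthetic event with the given channel values (others negative)
one_event <- function(tube, ...) {
  vals <- c(...)
  names(vals) <- sub("\\.(neg|dim|bright)$", "", names(vals))
  ch <- immunofrail::tube_channels(tube)
  ev <- as.data.frame(as.list(stats::setNames(rep(exp(2), length(ch)), ch)))
  for (nm in names(vals)) ev[[nm]] <- vals[[nm]]
  attr(ev, "tube") <- tube
  ev
}

band <- c(neg = exp(2), dim = exp(4), bright = exp(6))
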