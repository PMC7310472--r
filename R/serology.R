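#' Fit a two-component Gaussian mixture to log antibody concentrations
#'
#' EM for a two-component normal mixture on the log scale, the standard
#' model for IgG titer data in which the lower component represents
#' seronegative and the upper component seropositive individuals. Several
#' restarts (one quantile-based, the rest randomly perturbed) are run and
#' the best converged fit kept; component labels are ordered so that
#' `mu[1] < mu[2]`. The log-likelihood trace is retained; EM guarantees it
#' is non-decreasing.
#'
#' @param log_titers numeric vector of log concentrations (n >= 20,
#'   finite).
#' @param init optional list with `mu` (length 2), `sigma` (length 2),
#'   `weight` (scalar, component 1) used for the first start.
#' @param tol convergence tolerance on the log-likelihood increment.
#' @param max_iter maximum EM iterations per start.
#' @param n_restarts number of starts.
#' @param seed optional seed for the random restarts.
#' @return object of class `mixture_fit`: list with `mu`, `sigma`,
#'   `weight` (component 1), `loglik`, `loglik_trace`, `converged`,
#'   `n_iter`, `n`.
#' @export
fit_two_component_mixture <- function(log_titers, init = NULL, tol = 1e-8,
                                      max_iter = 500L, n_restarts = 5L,
                                      seed = NULL) {
  x <- log_titers
  if (length(x) < 20) stop("need at least 20 observations")
  if (!all(is.finite(x))) stop("log titers must be finite")
  if (!is.null(seed)) set.seed(seed)

  em_once <- function(mu, sigma, w) {
    trace <- numeric(0)
    ll_old <- -Inf
    conv <- FALSE
    it <- 0L
    degenerate <- FALSE
    min_sigma <- max(1e-6 * stats::sd(x), 1e-10 * max(abs(x), 1))
    for (it in seq_len(max_iter)) {
      d1 <- w * stats::dnorm(x, mu[1], sigma[1])
      d2 <- (1 - w) * stats::dnorm(x, mu[2], sigma[2])
      tot <- d1 + d2
      if (any(tot <= 0) || any(!is.finite(tot))) { degenerate <- TRUE; break }
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      if (is.finite(ll_old) && ll - ll_old < tol && ll - ll_old > -1e-6) {
        conv <- TRUE
        break
      }
      ll_old <- ll
      g1 <- d1 / tot
      n1 <- sum(g1); n2 <- length(x) - n1
      if (n1 < 1e-8 || n2 < 1e-8) { degenerate <- TRUE; break }
      mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
      sigma <- c(sqrt(sum(g1 * (x - mu[1])^2) / n1),
                 sqrt(sum((1 - g1) * (x - mu[2])^2) / n2))
      if (any(sigma < min_sigma)) { degenerate <- TRUE; break }
      w <- n1 / length(x)
    }
    list(mu = mu, sigma = sigma, weight = w,
         loglik = if (length(trace)) trace[length(trace)] else -Inf,
         loglik_trace = trace, converged = conv, n_iter = it,
         degenerate = degenerate)
  }

  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  s0 <- max(stats::sd(x) / 2, 1e-3)
  starts <- list(if (is.null(init)) list(mu = q, sigma = c(s0, s0), w = 0.5)
                 else list(mu = init$mu, sigma = init$sigma,
                           w = init$weight))
  if (n_restarts > 1) {
    for (k in seq_len(n_restarts - 1)) {
      mu0 <- sort(stats::rnorm(2, mean = mean(x), sd = stats::sd(x)))
      starts[[k + 1]] <- list(mu = mu0,
                              sigma = c(s0, s0) * stats::runif(1, 0.5, 2),
                              w = stats::runif(1, 0.2, 0.8))
    }
  }
  fits <- lapply(starts, function(s) em_once(s$mu, s$sigma, s$w))
  ok <- !vapply(fits, `[[`, TRUE, "degenerate")
  if (!any(ok))
    stop("all EM restarts collapsed to a degenerate fit: the sample may ",
         "be a single tight cluster")
  fits <- fits[ok]
  best <- fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]

  if (best$mu[1] > best$mu[2]) {
    best$mu <- rev(best$mu)
    best$sigma <- rev(best$sigma)
    best$weight <- 1 - best$weight
  }
  best$degenerate <- NULL
  best$n <- length(x)
  class(best) <- "mixture_fit"
  best
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Two-component Gaussian mixture (log scale), n =", x$n, "\n")
  cat(sprintf("  comp 1: mu = %.3f, sigma = %.3f, weight = %.3f\n",
              x$mu[1], x$sigma[1], x$weight))
  cat(sprintf("  comp 2: mu = %.3f, sigma = %.3f, weight = %.3f\n",
              x$mu[2], x$sigma[2], 1 - x$weight))
  cat(sprintf("  loglik = %.2f after %d iterations (converged: %s)\n",
              x$loglik, x$n_iter, x$converged))
  invisible(x)
}

#' Seropositivity cutoff at the intersection of the component densities
#'
#' Solves, in the log domain, the point between the two component means at
#' which the weighted component densities are equal (a quadratic in x; with
#' equal variances it reduces to
#' `(mu1+mu2)/2 + sigma^2 log(w/(1-w)) / (mu2-mu1)`). The root inside
#' `(mu1, mu2)` is returned on the concentration scale.
#'
#' @param fit a converged `mixture_fit`.
#' @return cutoff concentration with attribute `log_cutoff`.
#' @export
seropositivity_cutoff <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!fit$converged)
    warning("mixture fit did not converge; cutoff may be unreliable")
  m1 <- fit$mu[1]; m2 <- fit$mu[2]
  s1 <- fit$sigma[1]; s2 <- fit$sigma[2]
  w1 <- fit$weight; w2 <- 1 - w1
  ## w1/s1 exp(-(x-m1)^2/2s1^2) = w2/s2 exp(-(x-m2)^2/2s2^2)
  a <- 1 / s2^2 - 1 / s1^2
  b <- -2 * (m2 / s2^2 - m1 / s1^2)
  cc <- m2^2 / s2^2 - m1^2 / s1^2 - 2 * log(w2 * s1 / (w1 * s2))
  if (abs(a) < 1e-12) {
    roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop("component densities do not intersect")
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > m1 & roots < m2]
  if (!length(inside))
    stop("no density intersection between the component means; roots at ",
         paste(signif(roots, 6), collapse = ", "))
  structure(exp(inside[1]), log_cutoff = inside[1])
}

#' Classify serostatus from titers and a cutoff
#'
#' Titers at or above the cutoff are seropositive (ties at the boundary are
#' called positive).
#'
#' @param titers antibody concentrations (linear scale).
#' @param cutoff concentration cutoff, e.g. from [seropositivity_cutoff()].
#' @return factor with levels `seronegative`, `seropositive`.
#' @export
classify_serostatus <- function(titers, cutoff) {
  factor(ifelse(titers >= as.numeric(cutoff), "seropositive",
                "seronegative"),
         levels = c("seronegative", "seropositive"))
}

#' Fit, cut and classify in one step
#'
#' Convenience wrapper emulating pooled-cohort fitting: the mixture may be
#' fitted on one set of titers (e.g. a large pooled reference) and applied
#' to another.
#'
#' @param titers concentrations to classify.
#' @param fit_titers concentrations to fit the mixture on (default:
#'   `titers`).
#' @param ... passed to [fit_two_component_mixture()].
#' @return list with `status` (factor), `cutoff`, `fit`.
#' @export
serostatus_pipeline <- function(titers, fit_titers = titers, ...) {
  fit <- fit_two_component_mixture(log(fit_titers), ...)
  cutoff <- seropositivity_cutoff(fit)
  list(status = classify_serostatus(titers, cutoff), cutoff = cutoff,
       fit = fit)
}
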