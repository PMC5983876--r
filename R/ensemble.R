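# Population-level statistics over fitted odorant-OR pairs: Gaussian EC50
# model, two-exponential efficacy mixture (maximum-entropy form with two
# subpopulations), Hill-coefficient histogram, and the odorant-specific
# differential response.

#' Gaussian fit to an ensemble of EC50 values
#'
#' Maximum-likelihood normal fit (closed form: sample mean and the
#' 1/n-variance standard deviation) with the sample skewness reported
#' alongside, since cutoff-based screening truncates the weak-affinity tail
#' and skews real panels.
#'
#' @param ec50_values Numeric vector of EC50 values (log10 molar), length
#'   >= 10.
#' @return A list with `mu`, `sigma`, `skewness`, `n` and `degenerate`
#'   (TRUE when all values coincide so sigma = 0).
#' @export
fit_ec50_gaussian <- function(ec50_values) {
  x <- ec50_values[is.finite(ec50_values)]
  n <- length(x)
  if (n < 10L) {
    stop("fit_ec50_gaussian: need at least 10 finite EC50 values, got ", n)
  }
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  skew <- if (sigma > 0) mean((x - mu)^3) / sigma^3 else NA_real_
  list(mu = mu, sigma = sigma, skewness = skew, n = n,
       degenerate = sigma == 0)
}

#' Two-exponential mixture fit by expectation-maximization
#'
#' Fits the maximum-entropy-style density
#' \deqn{\rho(E) = \phi \frac{e^{-E/m_1}}{m_1} +
#'   (1-\phi) \frac{e^{-E/m_2}}{m_2}, \quad m_1 < m_2,}
#' to positive values by EM with random restarts. Components are returned
#' mean-ordered with `phi` the weight of the low-mean component. The
#' single-exponential null is fitted alongside and the likelihood-ratio
#' statistic reported, since the two-component form is a claim worth
#' checking rather than assuming.
#'
#' @param values Positive numeric vector, length >= 50.
#' @param n_restarts Random EM restarts, default 20.
#' @param max_iter EM iterations per restart, default 500.
#' @param tol Convergence tolerance on the log-likelihood, default 1e-8.
#' @param seed Optional integer seed for the restart draws.
#' @return A list with `phi`, `mean1`, `mean2`, `loglik`,
#'   `loglik_single`, `lr_stat` (2 * (loglik - loglik_single)),
#'   `n_iter`, `degenerate`.
#' @export
fit_exponential_mixture <- function(values, n_restarts = 20, max_iter = 500,
                                    tol = 1e-8, seed = NULL) {
  x <- values[is.finite(values)]
  if (any(x <= 0)) stop("fit_exponential_mixture: values must be > 0")
  n <- length(x)
  if (n < 50L) {
    stop("fit_exponential_mixture: need >= 50 values for a stable ",
         "two-component fit, got ", n)
  }
  m_hat <- mean(x)
  loglik_single <- sum(stats::dexp(x, rate = 1 / m_hat, log = TRUE))
  if (stats::sd(x) == 0) {
    return(list(phi = 1, mean1 = m_hat, mean2 = m_hat,
                loglik = NA_real_, loglik_single = loglik_single,
                lr_stat = NA_real_, n_iter = 0L, degenerate = TRUE))
  }
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }

  em_once <- function(phi, m1, m2) {
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      d1 <- phi * stats::dexp(x, rate = 1 / m1)
      d2 <- (1 - phi) * stats::dexp(x, rate = 1 / m2)
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      r1 <- d1 / tot
      ll <- sum(log(tot))
      phi <- mean(r1)
      if (phi < 1e-10 || phi > 1 - 1e-10) break
      m1 <- sum(r1 * x) / sum(r1)
      m2 <- sum((1 - r1) * x) / sum(1 - r1)
      if (abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    list(phi = phi, m1 = m1, m2 = m2, loglik = ll, n_iter = it)
  }

  # quantile-anchored initialization plus random restarts
  q <- stats::quantile(x, c(0.25, 0.9))
  inits <- list(c(0.7, q[[1]], q[[2]]))
  for (k in seq_len(max(0, n_restarts - 1))) {
    inits[[k + 1]] <- c(stats::runif(1, 0.2, 0.9),
                        m_hat * stats::runif(1, 0.05, 0.8),
                        m_hat * stats::runif(1, 1.2, 6))
  }
  best <- NULL
  for (ini in inits) {
    res <- em_once(ini[1], ini[2], ini[3])
    if (is.null(best) || (is.finite(res$loglik) &&
                          res$loglik > best$loglik)) best <- res
  }
  # mean-order: phi is the weight of the smaller-mean component
  if (best$m1 > best$m2) {
    best <- list(phi = 1 - best$phi, m1 = best$m2, m2 = best$m1,
                 loglik = best$loglik, n_iter = best$n_iter)
  }
  list(phi = best$phi, mean1 = best$m1, mean2 = best$m2,
       loglik = best$loglik, loglik_single = loglik_single,
       lr_stat = 2 * (best$loglik - loglik_single),
       n_iter = best$n_iter, degenerate = FALSE)
}

#' Sample from a two-exponential mixture
#'
#' @param n Number of draws.
#' @param phi Weight of the low-mean component, in (0, 1).
#' @param mean1,mean2 Component means (> 0).
#' @return Numeric vector of positive draws.
#' @export
rexp_mixture <- function(n, phi, mean1, mean2) {
  stopifnot(phi >= 0, phi <= 1, mean1 > 0, mean2 > 0)
  low <- stats::runif(n) < phi
  stats::rexp(n, rate = 1 / ifelse(low, mean1, mean2))
}

#' Density of the two-exponential mixture
#'
#' @param x Evaluation points (>= 0).
#' @inheritParams rexp_mixture
#' @return Density values.
#' @export
dexp_mixture <- function(x, phi, mean1, mean2) {
  phi * stats::dexp(x, 1 / mean1) + (1 - phi) * stats::dexp(x, 1 / mean2)
}

#' Hill-coefficient histogram over an ensemble of fits
#'
#' @param H_values Fitted Hill coefficients.
#' @param breaks Histogram breaks (passed to [hist()]); default half-unit
#'   bins covering the data.
#' @return A list with `breaks`, `counts`, `mids`.
#' @export
hill_histogram <- function(H_values, breaks = NULL) {
  x <- H_values[is.finite(H_values)]
  if (is.null(breaks)) {
    breaks <- seq(0, ceiling(max(x) * 2) / 2 + 0.5, by = 0.5)
  }
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids)
}

#' Odorant-specific differential response
#'
#' For one odorant, sums the analytic derivative of each responsive
#' partner receptor's fitted Hill curve with respect to log10 concentration
#' and normalizes to unit area over the grid:
#' \deqn{\psi_\lambda(x) \propto \sum_r
#'   \frac{\partial S_r}{\partial \log_{10} C_O}\Big|_{\log_{10} C_O = x}.}
#' The peak location identifies the concentration at which the odorant
#' recruits additional receptors fastest.
#'
#' @param odorant_id Odorant to profile.
#' @param fits Fit-record data frame (needs `odorant_id`, `status`, `B`,
#'   `dS_max`, `EC50`, `H`).
#' @param grid Log10 concentration grid; default `seq(-10, 0, by = 0.05)`.
#' @param include_deactivating Add |dS/dlog10 C| contributions of
#'   deactivating partners. Default FALSE (activating spectra only).
#' @param min_partners Minimum responsive partners required, default 2.
#' @return A list with `grid`, `density` (unit trapezoid area), `peak`
#'   (log10 molar location of the maximum) and `n_partners`.
#' @export
differential_response <- function(odorant_id, fits,
                                  grid = seq(-10, 0, by = 0.05),
                                  include_deactivating = FALSE,
                                  min_partners = 2) {
  sel <- fits$odorant_id == odorant_id & fits$status == "activating"
  if (include_deactivating) {
    sel <- sel | (fits$odorant_id == odorant_id &
                    fits$status == "deactivating")
  }
  part <- fits[sel, , drop = FALSE]
  if (nrow(part) < min_partners) {
    stop("differential_response: odorant '", odorant_id, "' has ",
         nrow(part), " responsive partner(s); need >= ", min_partners)
  }
  dens <- rep(0, length(grid))
  ln10 <- log(10)
  for (i in seq_len(nrow(part))) {
    u <- 10^(part$H[i] * (grid - part$EC50[i]))
    # dS/dlog10C = ln10 * H * dS_max * u/(1+u)^2
    contrib <- ln10 * part$H[i] * part$dS_max[i] * u / (1 + u)^2
    dens <- dens + if (part$dS_max[i] < 0) abs(contrib) else contrib
  }
  area <- sum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid))
  if (area <= 0) stop("differential_response: empty spectrum")
  dens <- dens / area
  list(grid = grid, density = dens, peak = grid[which.max(dens)],
       n_partners = nrow(part))
}

#' Fit the full ensemble model to a set of fit records
#'
#' Convenience wrapper producing the population model: Gaussian EC50 fits
#' (activating subset and all reliable pairs), the two-exponential mixture
#' on efficacies over all reliable pairs (the ensemble the efficacy law
#' describes) and on response amplitudes of activating pairs, and the
#' Hill-coefficient histogram.
#'
#' @param records Fit-record data frame.
#' @param corr_threshold Reliability threshold, default 0.9.
#' @param seed Seed for the mixture-EM restarts.
#' @return A list of class `ensemble_model`.
#' @export
fit_ensemble_model <- function(records, corr_threshold = 0.9, seed = NULL) {
  cls <- classify_and_filter(records, corr_threshold)
  act <- cls$activating
  reliable <- rbind(cls$activating, cls$deactivating)
  # small panels cannot support every population fit; report what holds
  maybe <- function(expr) tryCatch(expr, error = function(e) {
    warning("fit_ensemble_model: ", conditionMessage(e), call. = FALSE)
    NULL
  })
  model <- list(
    ec50_activating = maybe(fit_ec50_gaussian(act$EC50)),
    ec50_all = maybe(fit_ec50_gaussian(reliable$EC50)),
    efficacy_mixture = maybe(
      fit_exponential_mixture(reliable$E[reliable$E > 0], seed = seed)),
    dSmax_mixture = maybe(fit_exponential_mixture(act$dS_max[act$dS_max > 0],
                                                  seed = seed)),
    H_histogram = hill_histogram(reliable$H),
    counts = cls$counts
  )
  class(model) <- "ensemble_model"
  model
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model>\n")
  cat(sprintf("  pairs: %d activating / %d deactivating / %d unreliable\n",
              x$counts["activating"], x$counts["deactivating"],
              x$counts["unreliable"]))
  if (!is.null(x$ec50_activating)) {
    cat(sprintf("  EC50 (activating): mu = %.2f, sigma = %.2f\n",
                x$ec50_activating$mu, x$ec50_activating$sigma))
  }
  if (!is.null(x$efficacy_mixture)) {
    cat(sprintf("  efficacy mixture: phi = %.2f, means = (%.2f, %.2f)\n",
                x$efficacy_mixture$phi, x$efficacy_mixture$mean1,
                x$efficacy_mixture$mean2))
  }
  invisible(x)
}
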