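# Perception-level quantities: active-receptor fraction, Weber ratios,
# binarized ORN firing, and combinatorial coding capacity.

#' Expected fraction of recruited receptor types at a concentration
#'
#' Under the ensemble EC50 model, the fraction of the N_r receptor types
#' already recruited at log10 concentration x is the Gaussian CDF
#' \deqn{n_O / N_r = \int_{-\infty}^{x} \psi_{ens}(t) \, dt
#'   = \Phi\!\big((x - \mu)/\sigma\big).}
#'
#' @param log10_CO Log10 odorant concentration(s), molar; vectorized.
#' @param mu,sigma Ensemble EC50 Gaussian parameters (log10 molar, decades).
#' @return Fractions in [0, 1].
#' @export
expected_active_fraction <- function(log10_CO, mu, sigma) {
  stopifnot(sigma > 0)
  stats::pnorm(log10_CO, mean = mu, sd = sigma)
}

#' Concentration-dependent Weber-ratio lower bound
#'
#' The minimal relative concentration change that recruits one more
#' receptor type:
#' \deqn{\frac{\Delta C_O}{C_O} \gtrsim
#'   \frac{\ln 10}{N_r\, \psi_{ens}(\log_{10} C_O)} \equiv \frac{1}{\chi}.}
#'
#' @inheritParams expected_active_fraction
#' @param N_r Number of receptor types.
#' @return Lower bound(s) on the detectable relative change.
#' @export
weber_bound <- function(log10_CO, mu, sigma, N_r) {
  stopifnot(N_r >= 1, sigma > 0)
  log(10) / (N_r * stats::dnorm(log10_CO, mean = mu, sd = sigma))
}

#' Minimized Weber ratio at the sensitivity peak
#'
#' At the peak of the Gaussian EC50 ensemble the Weber bound attains its
#' minimum
#' \deqn{\frac{\Delta C_O}{C_O} = \frac{\sqrt{2\pi}\, \ln 10\,
#'   \sigma_{EC_{50}}}{N_r},}
#' about 0.03 (a 3% detectable change) for N_r = 330 receptor types and
#' sigma = 1.5 decades.
#'
#' @param N_r Number of receptor types (>= 1).
#' @param sigma Ensemble EC50 standard deviation in decades (> 0).
#' @return The minimized Weber ratio.
#' @export
#' @examples
#' weber_ratio_min(330, 1.5)  # ~0.026, rounds to 0.03
weber_ratio_min <- function(N_r, sigma) {
  stopifnot(N_r >= 1, sigma >= 0)
  sqrt(2 * pi) * log(10) * sigma / N_r
}

#' Uniform-ensemble Weber ratio
#'
#' The classic estimate assuming receptor thresholds uniformly distributed
#' over the responsive range `R` of natural-log concentration: `R / N_r`,
#' with `R = 2 * (2 sigma) * ln 10` spanning two standard deviations either
#' side of the ensemble mean.
#'
#' @inheritParams weber_ratio_min
#' @return A list with `R` (natural-log range) and `weber` (= R / N_r).
#' @export
weber_ratio_uniform <- function(N_r, sigma) {
  stopifnot(N_r >= 1, sigma > 0)
  R <- 2 * (2 * sigma) * log(10)
  list(R = R, weber = R / N_r)
}

#' Binarized ORN firing curve by binomial simulation
#'
#' An olfactory receptor neuron expresses L copies of one receptor type;
#' each copy activates independently with probability p(C_O), the
#' normalized Hill occupancy \eqn{f = (C_O/K_{1/2})^H / (1 + (C_O/K_{1/2})^H)}
#' (optionally floored at a basal activation probability `p0`). The cell
#' fires when the activated fraction exceeds `threshold_fraction`, so the
#' firing frequency is
#' \deqn{F(C_O) = \Pr[\ell / L > \ell^\theta / L], \quad
#'   \ell \sim \mathrm{Binomial}(L, p(C_O)),}
#' which sharpens to a step function at the threshold concentration as L
#' grows (law of large numbers): the cellular response is effectively
#' binary even though single receptors are stochastic.
#'
#' @param hill A [hill_params()] object (only `K_half` and `H` shape the
#'   activation probability).
#' @param log10_grid Log10 concentration grid to evaluate (molar).
#' @param L Receptor copies per neuron (>= 1). Default 2.5e4.
#' @param threshold_fraction Firing threshold on the activated fraction,
#'   strictly in (0, 1). Default 0.5.
#' @param n_trials Simulated trials per concentration. Default 1000.
#' @param seed Optional integer seed.
#' @param p0 Basal activation-probability floor in [0, 1). Default 0.
#' @param exact Use the exact binomial tail (pbinom) instead of
#'   simulation. Default FALSE.
#' @return A data frame with `log10_CO`, `p` (single-copy activation
#'   probability) and `F` (firing frequency), plus attribute
#'   `threshold_log10_CO`, the concentration where p crosses the
#'   threshold.
#' @export
orn_firing_curve <- function(hill, log10_grid, L = 2.5e4,
                             threshold_fraction = 0.5, n_trials = 1000,
                             seed = NULL, p0 = 0, exact = FALSE) {
  stopifnot(inherits(hill, "hill_params"), L >= 1, n_trials >= 1,
            p0 >= 0, p0 < 1)
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("orn_firing_curve: threshold_fraction must be strictly in (0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  u <- 10^(hill$H * (log10_grid - hill$EC50))
  p <- p0 + (1 - p0) * u / (1 + u)
  L <- round(L)
  ell_theta <- threshold_fraction * L
  F_emp <- if (exact) {
    # Pr(ell > ell_theta) with the same strict inequality as the simulation
    stats::pbinom(floor(ell_theta), size = L, prob = p, lower.tail = FALSE)
  } else {
    vapply(p, function(pp) {
      mean(stats::rbinom(n_trials, size = L, prob = pp) > ell_theta)
    }, numeric(1))
  }
  # threshold concentration: p(C) = threshold_fraction
  thr <- if (threshold_fraction > p0) {
    f_thr <- (threshold_fraction - p0) / (1 - p0)
    hill$EC50 + log10(f_thr / (1 - f_thr)) / hill$H
  } else {
    -Inf
  }
  out <- data.frame(log10_CO = log10_grid, p = p, F = F_emp)
  attr(out, "threshold_log10_CO") <- thr
  out
}

#' Width of the ORN firing transition
#'
#' Measures, by linear interpolation on the firing curve, the log10
#' concentration interval over which F rises from `lo` to `hi` (default
#' 0.05 to 0.95). The width shrinks like 1/sqrt(L) by the binomial central
#' limit theorem.
#'
#' @param curve Output of [orn_firing_curve()].
#' @param lo,hi Firing-frequency levels bracketing the transition.
#' @return Width in decades (NA when the curve does not span the levels).
#' @export
firing_transition_width <- function(curve, lo = 0.05, hi = 0.95) {
  x <- curve$log10_CO; F <- curve$F
  # enforce monotone envelope for interpolation robustness
  cross <- function(level) {
    idx <- which(F >= level)
    if (!length(idx) || idx[1] == 1L) return(NA_real_)
    i <- idx[1]
    x[i - 1] + (level - F[i - 1]) * (x[i] - x[i - 1]) / (F[i] - F[i - 1])
  }
  w <- cross(hi) - cross(lo)
  if (is.na(w) || w < 0) NA_real_ else w
}

#' Log10 of the combinatorial code capacity
#'
#' N_r receptor types with binary (ON/OFF) responses generate 2^N_r
#' distinct receptor codes; this returns `N_r * log10(2)` (about 99 for
#' the human repertoire of 330).
#'
#' @param N_r Number of receptor types (>= 1).
#' @return log10 of the number of codes.
#' @export
code_capacity_log10 <- function(N_r) {
  stopifnot(N_r >= 1)
  N_r * log10(2)
}

#' Maximal discriminable odorant-mixture size
#'
#' The number of m-component mixtures drawn from M odorants must not
#' exceed the 2^N_r receptor codes; with the Stirling-style approximation
#' \eqn{\binom{M}{m} \approx M^m / m!} the bound reads
#' \deqn{m \log_2 M - \log_2 \Gamma(m + 1) \le N_r.}
#' The continuous root is found by bisection; the largest integer
#' strictly satisfying the bound is scanned as well (the two can differ
#' by one).
#'
#' @param M Number of monomolecular odorants (> 1).
#' @param N_r Number of receptor types (>= 1).
#' @param exact_binomial Use the exact binomial coefficient
#'   `log2 choose(M, m)` instead of the `M^m / m!` approximation.
#'   Default FALSE.
#' @return A list with `m_continuous` (real root), `m_rounded`,
#'   `m_integer` (largest integer satisfying the bound), and `capped`
#'   (TRUE when the bound never binds on [1, M] and M is returned).
#' @export
#' @examples
#' mixture_capacity_mmax(1e4, 330)  # root ~34.7, rounds to 35
mixture_capacity_mmax <- function(M, N_r, exact_binomial = FALSE) {
  stopifnot(M > 1, N_r >= 1)
  bits <- if (exact_binomial) {
    function(m) (lgamma(M + 1) - lgamma(m + 1) - lgamma(M - m + 1)) / log(2)
  } else {
    function(m) m * log2(M) - lgamma(m + 1) / log(2)
  }
  g <- function(m) bits(m) - N_r
  # bits is increasing in m on [1, m_top]: up to M for the M^m/m! form,
  # up to the central coefficient M/2 for the exact binomial
  m_top <- if (exact_binomial) max(1, M / 2) else M
  if (g(m_top) < 0) {
    return(list(m_continuous = m_top, m_rounded = round(m_top),
                m_integer = floor(m_top), capped = TRUE))
  }
  if (g(1) > 0) {
    return(list(m_continuous = 1, m_rounded = 1L, m_integer = 0L,
                capped = TRUE))
  }
  root <- stats::uniroot(g, c(1, m_top), tol = 1e-10)$root
  m_int <- 1L
  for (m in seq_len(min(ceiling(root) + 5, floor(m_top)))) {
    if (g(m) <= 0) m_int <- m else break
  }
  list(m_continuous = root, m_rounded = as.integer(round(root)),
       m_integer = m_int, capped = FALSE)
}
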