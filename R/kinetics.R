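# Two-step kinetic activation model for odorant-OR signaling and its exact
# Hill-form equivalent. All concentrations are molar; C_G, K_G, K_OG appear
# only through the ratios C_G/K_G and C_G/K_OG and are carried in relative
# units (C_G = 1 by convention). The response-scale constant A is arbitrary
# and defaults to 1; every inferred quantity exposed downstream is A-free.

#' Microscopic kinetic parameters of one odorant-OR pair
#'
#' Bundles the rate and binding constants of the minimal two-step activation
#' scheme: a receptor binds G-protein at rate `k_G_f` when empty and at rate
#' `k_OG_f` when an odorant occupies its binding site; `K_G` and `K_OG` are
#' the corresponding G-protein dissociation constants, `K_O` the odorant
#' dissociation constant, `C_G` the intracellular G-protein concentration,
#' and `A` an arbitrary response-scale constant.
#'
#' @param A Response proportionality constant (> 0). Default 1.
#' @param C_G Intracellular G-protein concentration, relative units (> 0).
#' @param k_G_f G-protein binding rate without odorant (> 0).
#' @param k_OG_f G-protein binding rate with odorant bound (> 0).
#' @param K_G G-protein dissociation constant without odorant (> 0).
#' @param K_OG G-protein dissociation constant with odorant (> 0).
#' @param K_O Odorant dissociation constant, molar (> 0).
#' @return An object of class `kinetic_params`.
#' @export
#' @examples
#' p <- kinetic_params(k_OG_f = 5, K_OG = 0.1, K_O = 1e-4)
#' kinetic_activity(p, 1e-4)
kinetic_params <- function(A = 1, C_G = 1, k_G_f = 1, k_OG_f = 1,
                           K_G = 1, K_OG = 1, K_O = 1) {
  p <- list(A = A, C_G = C_G, k_G_f = k_G_f, k_OG_f = k_OG_f,
            K_G = K_G, K_OG = K_OG, K_O = K_O)
  bad <- vapply(p, function(x) !is.numeric(x) || length(x) != 1L ||
                  !is.finite(x) || x <= 0, logical(1))
  if (any(bad)) {
    stop("kinetic_params: all constants must be finite, positive scalars; ",
         "offending: ", paste(names(p)[bad], collapse = ", "))
  }
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  A = %g, C_G = %g\n", x$A, x$C_G))
  cat(sprintf("  k_G_f = %g, k_OG_f = %g (ratio %.3g)\n",
              x$k_G_f, x$k_OG_f, x$k_OG_f / x$k_G_f))
  cat(sprintf("  K_G = %g, K_OG = %g, K_O = %.3g M (log10 %.3g)\n",
              x$K_G, x$K_OG, x$K_O, log10(x$K_O)))
  invisible(x)
}

#' Empirical Hill parameters of a dose-response curve
#'
#' The four-parameter phenomenological description of a dose-response
#' relationship: basal activity `B`, response amplitude `dS_max` (negative
#' for deactivating, inverse-agonist pairs), half-maximum concentration
#' `K_half` in molar, and Hill coefficient `H`. The derived fields `EC50 =
#' log10(K_half / 1 M)` and efficacy `E = B + dS_max` are stored alongside.
#'
#' @param B Basal activity, response units (>= 0).
#' @param dS_max Response amplitude; sign encodes activation/deactivation.
#' @param K_half Half-maximum concentration in molar (> 0). Give either
#'   `K_half` or `EC50`.
#' @param H Hill coefficient (> 0).
#' @param EC50 Alternative to `K_half`: log10 of `K_half` in molar.
#' @return An object of class `hill_params`.
#' @export
#' @examples
#' h <- hill_params(B = 0.21, dS_max = 3.09, EC50 = -5.72, H = 1.4)
#' hill_activity(h, 10^-5.72)  # exactly B + dS_max/2
hill_params <- function(B, dS_max, K_half = NULL, H = 1, EC50 = NULL) {
  if (is.null(K_half) && is.null(EC50)) {
    stop("hill_params: supply K_half (molar) or EC50 (log10 molar)")
  }
  if (is.null(K_half)) K_half <- 10^EC50
  stopifnot(is.numeric(B), length(B) == 1L, is.finite(B), B >= 0,
            is.numeric(dS_max), length(dS_max) == 1L, is.finite(dS_max),
            is.numeric(K_half), length(K_half) == 1L, K_half > 0,
            is.numeric(H), length(H) == 1L, H > 0)
  structure(list(B = B, dS_max = dS_max, K_half = K_half, H = H,
                 EC50 = log10(K_half), E = B + dS_max),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat("<hill_params>\n")
  cat(sprintf("  B = %g, dS_max = %g (E = %g)\n", x$B, x$dS_max, x$E))
  cat(sprintf("  EC50 = %.3f (K_half = %.3g M), H = %g\n",
              x$EC50, x$K_half, x$H))
  invisible(x)
}

#' Receptor activity under the two-step kinetic scheme
#'
#' Evaluates the steady-state signaling output
#' \deqn{S(C_O) = \frac{A C_G k_{Gf} [1 + (k_{OGf}/k_{Gf}) C_O/K_O]}
#'   {1 + C_G/K_G + (1 + C_G/K_{OG}) C_O/K_O}}
#' a hyperbolic (Hill coefficient 1) function of odorant concentration,
#' rising from the basal level B to the efficacy E as the odorant saturates
#' the receptor (or falling, when odorant binding weakens G-protein
#' recruitment).
#'
#' @param p A [kinetic_params()] object.
#' @param C_O Odorant concentration(s) in molar (>= 0); vectorized.
#' @return Numeric vector of responses, same length as `C_O`.
#' @export
kinetic_activity <- function(p, C_O) {
  stopifnot(inherits(p, "kinetic_params"))
  if (any(!is.finite(C_O)) || any(C_O < 0)) {
    stop("kinetic_activity: C_O must be finite and >= 0")
  }
  x <- C_O / p$K_O
  num <- p$A * p$C_G * p$k_G_f * (1 + (p$k_OG_f / p$k_G_f) * x)
  den <- 1 + p$C_G / p$K_G + (1 + p$C_G / p$K_OG) * x
  num / den
}

#' Hill-form dose-response activity
#'
#' \deqn{S(C_O) = B + \delta S_{max} \frac{(C_O/K_{1/2})^H}{1 + (C_O/K_{1/2})^H}}
#' At `C_O = K_half` this returns exactly `B + dS_max/2`; at zero dose, `B`;
#' in the saturating limit, the efficacy `E = B + dS_max`.
#'
#' @param h A [hill_params()] object.
#' @param C_O Odorant concentration(s) in molar (>= 0); vectorized.
#' @return Numeric vector of responses.
#' @export
hill_activity <- function(h, C_O) {
  stopifnot(inherits(h, "hill_params"))
  if (any(!is.finite(C_O)) || any(C_O < 0)) {
    stop("hill_activity: C_O must be finite and >= 0")
  }
  u <- (C_O / h$K_half)^h$H
  f <- u / (1 + u)
  f[u == Inf] <- 1
  h$B + h$dS_max * f
}

#' Map microscopic kinetic constants to Hill parameters
#'
#' The kinetic scheme is exactly a Hill curve with H = 1:
#' \deqn{K_{1/2} = K_O \frac{1 + C_G/K_G}{1 + C_G/K_{OG}}, \quad
#'   E = \frac{A C_G k_{OGf}}{1 + C_G/K_{OG}}, \quad
#'   B = \frac{A C_G k_{Gf}}{1 + C_G/K_G}.}
#' The returned parameters reproduce [kinetic_activity()] on any
#' concentration grid to floating-point accuracy.
#'
#' @param p A [kinetic_params()] object.
#' @return A [hill_params()] object with `H = 1`.
#' @export
kinetic_to_hill <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  rG  <- p$C_G / p$K_G
  rOG <- p$C_G / p$K_OG
  B <- p$A * p$C_G * p$k_G_f / (1 + rG)
  E <- p$A * p$C_G * p$k_OG_f / (1 + rOG)
  K_half <- p$K_O * (1 + rG) / (1 + rOG)
  hill_params(B = B, dS_max = E - B, K_half = K_half, H = 1)
}

#' Triadic omega statistic
#'
#' \eqn{\omega = \log_{10} E - \log_{10} B - \log_{10}(K_{1/2}/[1\,M])}.
#' For parameters arising from the kinetic scheme this equals
#' \eqn{\log_{10}(k_{OGf} / (k_{Gf} K_O))} identically — the combination of
#' microscopic constants that survives the elimination of `C_G`, `K_G`,
#' `K_OG` and `A` — which is what makes it the handle for inferring odorant
#' binding constants from population fits.
#'
#' @param E Efficacy (> 0); vectorized.
#' @param B Basal activity (> 0).
#' @param K_half Half-maximum concentration in molar (> 0).
#' @return Numeric vector of omega values (dimensionless, log10 scale).
#' @export
omega <- function(E, B, K_half) {
  if (any(!is.finite(E) | E <= 0) || any(!is.finite(B) | B <= 0) ||
      any(!is.finite(K_half) | K_half <= 0)) {
    stop("omega: E, B and K_half must be finite and > 0")
  }
  log10(E) - log10(B) - log10(K_half)
}

#' Efficacy as a hyperbolic function of basal activity
#'
#' Receptors sharing an odorant's kinetics but differing in G-protein
#' concentration trace out the hyperbola
#' \deqn{E = \frac{r B}{1 + c B}, \quad r = k_{OGf}/k_{Gf}, \quad
#'   c = \frac{K_{OG}^{-1} - K_G^{-1}}{A k_{Gf}}.}
#' `c = 0` (the `K_OG = K_G` limit) reduces to a line through the origin.
#'
#' @param B Basal activity (>= 0); vectorized.
#' @param ratio Amplitude `r = k_OG_f / k_G_f` (> 0).
#' @param curvature Curvature parameter `c` (may be negative, but the
#'   denominator `1 + c B` must stay positive).
#' @return Efficacy values.
#' @export
efficacy_vs_basal <- function(B, ratio, curvature = 0) {
  stopifnot(all(B >= 0), ratio > 0)
  den <- 1 + curvature * B
  if (any(den <= 0)) {
    stop("efficacy_vs_basal: denominator 1 + curvature*B must be > 0 ",
         "(invalid regime)")
  }
  ratio * B / den
}

#' Basal activity as a function of the half-maximum concentration
#'
#' Companion to [efficacy_vs_basal()] with the same parameterization:
#' \eqn{B = \frac{1}{c} (K_O/K_{1/2} - 1)} where `c` is the curvature
#' \eqn{(K_{OG}^{-1} - K_G^{-1})/(A k_{Gf})}.
#'
#' @param K_half Half-maximum concentration, molar (> 0); vectorized.
#' @param K_O Odorant dissociation constant, molar (> 0).
#' @param curvature Curvature parameter (!= 0).
#' @return Basal activity values.
#' @export
basal_vs_khalf <- function(K_half, K_O, curvature) {
  stopifnot(all(K_half > 0), K_O > 0, curvature != 0)
  (K_O / K_half - 1) / curvature
}

#' Efficacy as a function of the half-maximum concentration
#'
#' \eqn{E = \frac{r}{c} (1 - K_{1/2}/K_O)}, with `r` and `c` as in
#' [efficacy_vs_basal()].
#'
#' @inheritParams basal_vs_khalf
#' @param ratio Amplitude `k_OG_f / k_G_f` (> 0).
#' @return Efficacy values.
#' @export
efficacy_vs_khalf <- function(K_half, K_O, ratio, curvature) {
  stopifnot(all(K_half > 0), K_O > 0, ratio > 0, curvature != 0)
  (ratio / curvature) * (1 - K_half / K_O)
}

#' Kinetic-consistency check
#'
#' For an activating, well-formed odorant-OR pair the model requires
#' \deqn{1 \le K_O / K_{1/2} \le K_G / K_{OG}:}
#' odorant binding must strengthen G-protein recruitment at least as much
#' as the signal cascade sharpens the effective threshold. The left
#' inequality is automatic whenever `K_OG <= K_G`; the right one fails when
#' odorant binding weakens G-protein binding (`K_OG > K_G`).
#'
#' @param p A [kinetic_params()] object.
#' @return A list with `pass` (logical), the two ratios `KO_over_Khalf`
#'   and `KG_over_KOG`, and a human-readable `message`.
#' @export
check_consistency <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  h <- kinetic_to_hill(p)
  r1 <- p$K_O / h$K_half
  r2 <- p$K_G / p$K_OG
  tol <- 1e-12 * max(1, r1, r2)
  pass <- (r1 >= 1 - tol) && (r1 <= r2 + tol)
  msg <- if (pass) {
    "consistent: 1 <= K_O/K_half <= K_G/K_OG"
  } else if (r2 < 1) {
    "inconsistent: K_OG > K_G (odorant-weakened G-protein binding)"
  } else {
    "inconsistent: K_O/K_half outside [1, K_G/K_OG]"
  }
  list(pass = pass, KO_over_Khalf = r1, KG_over_KOG = r2, message = msg)
}

#' Numeric sensitivity (effective Hill coefficient) of a response curve
#'
#' Measures the sharpness of a normalized monotone response `f(theta)` with
#' range (0, 1) as \eqn{n_H = 4 (\partial f / \partial \ln\theta)} evaluated
#' where `f = 1/2` (equivalently \eqn{2 \partial \log f / \partial
#' \log\theta} at the midpoint). For the Hill form
#' \eqn{f = \theta^H/(1+\theta^H)} this recovers `H` exactly.
#'
#' @param curve Function of a positive control parameter `theta`, monotone
#'   increasing with range (0, 1).
#' @param interval Log10 search interval for the midpoint, default
#'   `c(-12, 12)`.
#' @param h Relative step for the central-difference derivative in
#'   log-theta; default `1e-5`.
#' @return The effective Hill coefficient `n_H`.
#' @export
#' @examples
#' hill_sensitivity(function(th) th^3 / (1 + th^3))  # 3
hill_sensitivity <- function(curve, interval = c(-12, 12), h = 1e-5) {
  g <- function(l) curve(10^l) - 0.5
  lo <- g(interval[1]); hi <- g(interval[2])
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0) {
    stop("hill_sensitivity: curve does not cross 1/2 on the search interval",
         " (no midpoint)")
  }
  l_half <- stats::uniroot(g, interval, tol = 1e-12)$root
  # central difference of f w.r.t. ln(theta)
  dln <- h
  df <- (curve(exp(log(10^l_half) + dln)) -
           curve(exp(log(10^l_half) - dln))) / (2 * dln)
  4 * df
}

#' Full width at half maximum of the differential response
#'
#' The derivative of a Hill curve with respect to log10 concentration is a
#' bump peaked at `K_half`; its full width at half maximum, in decades of
#' concentration, is
#' \deqn{\mathrm{FWHM} = \frac{1}{H} \log_{10}\frac{3 + 2\sqrt 2}{3 - 2\sqrt 2}
#'   \approx 1.53 / H.}
#'
#' @param H Hill coefficient(s) (> 0); vectorized.
#' @return Width(s) in log10-concentration decades.
#' @export
#' @examples
#' response_fwhm(1)  # 1.5314...
response_fwhm <- function(H) {
  if (any(!is.finite(H) | H <= 0)) stop("response_fwhm: H must be > 0")
  (1 / H) * log10((3 + 2 * sqrt(2)) / (3 - 2 * sqrt(2)))
}
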