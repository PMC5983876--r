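# Inversion of population fits into odorant-specific microscopic constants:
# the efficacy-vs-basal hyperbola amplitude <k_OG_f/k_G_f>, the omega
# histogram, and <log10 K_O>. Receptors sharing one odorant differ only in
# their G-protein milieu (C_G, K_G), so the (B, E) cloud of that odorant's
# partners traces the hyperbola E = r*B/(1 + c*B) whose amplitude r is the
# G-protein on-rate enhancement.

#' Fit the efficacy-versus-basal hyperbola for one odorant
#'
#' Least squares of `E = ratio * B / (1 + curvature * B)` over the (B, E)
#' pairs of an odorant's partner receptors. `ratio` estimates the average
#' G-protein on-rate enhancement `<k_OG_f / k_G_f>`; `curvature` is
#' `(1/K_OG - 1/K_G) / (A k_G_f)` and is non-negative in the activating
#' regime (G-protein binds more tightly with odorant present).
#'
#' @param B,E Basal activities and efficacies (> 0), length >= 5.
#' @param weights Optional least-squares weights (default equal).
#' @param constrain_curvature Force `curvature >= 0`. Default FALSE; when
#'   off, a negative estimate is reported with a warning rather than
#'   clamped.
#' @return A list with `ratio`, `curvature`, `ssr`, `n`, and
#'   `curvature_identifiable` (FALSE when all B coincide, in which case
#'   `ratio` is the through-origin slope and `curvature` is NA).
#' @export
fit_E_vs_B <- function(B, E, weights = NULL, constrain_curvature = FALSE) {
  stopifnot(length(B) == length(E))
  ok <- is.finite(B) & is.finite(E) & B > 0 & E > 0
  B <- B[ok]; E <- E[ok]
  n <- length(B)
  if (n < 5L) stop("fit_E_vs_B: need >= 5 pairs with B > 0, E > 0, got ", n)
  w <- if (is.null(weights)) rep(1, n) else weights[ok]

  if (stats::sd(B) == 0) {
    warning("fit_E_vs_B: all B identical; curvature unidentifiable, ",
            "reporting through-origin slope")
    ratio <- sum(w * B * E) / sum(w * B^2)
    return(list(ratio = ratio, curvature = NA_real_,
                ssr = sum(w * (E - ratio * B)^2), n = n,
                curvature_identifiable = FALSE))
  }

  # linearized start: E = r B - c B E  (regress E on B and B*E, no intercept)
  X <- cbind(B, -B * E)
  co <- tryCatch(unname(stats::lm.wfit(X, E, w)$coefficients),
                 error = function(e) c(NA, NA))
  r0 <- if (is.finite(co[1]) && co[1] > 0) co[1] else mean(E / B)
  c0 <- if (is.finite(co[2])) co[2] else 0
  if (constrain_curvature) c0 <- max(c0, 0)

  obj <- function(par) {
    den <- 1 + par[2] * B
    if (any(den <= 0)) return(1e300)
    sum(w * (E - par[1] * B / den)^2)
  }
  grad <- function(par) {
    den <- 1 + par[2] * B
    if (any(den <= 0)) return(c(0, 0))
    res <- E - par[1] * B / den
    c(-2 * sum(w * res * B / den),
      2 * sum(w * res * par[1] * B^2 / den^2))
  }
  lower <- c(1e-12, if (constrain_curvature) 0 else -Inf)
  # the (ratio, curvature) profile can be a flat ridge when every receptor
  # sits in saturation; multistart + tight convergence keeps the fit stable
  starts <- list(c(r0, c0), c(max(mean(E / B), 1e-6), 0),
                 c(2 * r0, if (constrain_curvature) max(2 * c0, 0) else 2 * c0))
  res <- NULL
  for (st in starts) {
    cand <- tryCatch(
      stats::optim(st, obj, gr = grad, method = "L-BFGS-B", lower = lower,
                   control = list(maxit = 5000, factr = 10, pgtol = 0,
                                  parscale = c(max(st[1], 1), 1))),
      error = function(e) NULL)
    if (!is.null(cand) && (is.null(res) || cand$value < res$value)) {
      res <- cand
    }
  }
  ratio <- unname(res$par[1]); curv <- unname(res$par[2])
  if (!constrain_curvature && curv < 0) {
    warning("fit_E_vs_B: negative curvature estimate (K_OG > K_G regime)")
  }
  list(ratio = ratio, curvature = curv, ssr = res$value, n = n,
       curvature_identifiable = TRUE)
}

#' Estimate an odorant's binding constant from omega values
#'
#' Plugs the hyperbola amplitude into the triadic relation: with
#' `mean_omega` the arithmetic mean of the per-pair omega statistics,
#' \deqn{\langle \log_{10} K_O \rangle = \log_{10}\langle k_{OGf}/k_{Gf}
#'   \rangle - \langle \omega \rangle.}
#' Also returns the omega histogram and the equivalent binding free energy
#' `affinity_kBT = -ln K_O` in units of kT (both scales are exposed since
#' either convention is used for tabulating binding strengths).
#'
#' @param ratio Estimated `<k_OG_f / k_G_f>` (> 0).
#' @param omega_values Per-pair omega statistics, length >= 5.
#' @param breaks Histogram breaks, default 10 equal bins.
#' @return A list with `mean_omega`, `log10_KO`, `affinity_kBT`, and
#'   `omega_hist` (`breaks`, `counts`, `mids`).
#' @export
estimate_KO <- function(ratio, omega_values, breaks = 10) {
  stopifnot(ratio > 0)
  om <- omega_values[is.finite(omega_values)]
  if (length(om) < 5L) {
    stop("estimate_KO: need >= 5 omega values, got ", length(om))
  }
  mean_omega <- mean(om)
  log10_KO <- log10(ratio) - mean_omega
  h <- graphics::hist(om, breaks = breaks, plot = FALSE)
  list(mean_omega = mean_omega, log10_KO = log10_KO,
       affinity_kBT = -log(10^log10_KO),
       omega_hist = list(breaks = h$breaks, counts = h$counts,
                         mids = h$mids))
}

#' Build the odorant-averaged microscopic-constant table
#'
#' For every odorant with at least `min_partners` activating partner
#' receptors: fit the (B, E) hyperbola for `<k_OG_f/k_G_f>`, average the
#' per-pair omega statistics, and invert to `<log10 K_O>`. The triadic
#' identity `log10_KO = log10(ratio) - mean_omega` holds row-wise by
#' construction, and `KO_exceeds_Khalf` records whether the inferred
#' binding threshold exceeds the mean signaling threshold (the expected
#' signal-cascade ordering K_O > K_1/2).
#'
#' Basal and efficacy estimates carry correlated noise from the upstream
#' Hill fits, and the low-basal receptors that anchor the hyperbola's
#' initial slope are exactly the ones with the largest relative error in B
#' (a classic errors-in-variables attenuation). When the fit records carry
#' an `ssr` column, the hyperbola is therefore fitted by iterative
#' reweighting: weights `1 / (ssr * (1 + (dm/dB)^2))` fold the regressor
#' noise into the residual variance via the local slope `dm/dB =
#' ratio/(1 + curvature*B)^2`, iterated three times from the unweighted
#' fit. Set `irls = FALSE` for plain (equal-weight) least squares.
#'
#' @param fits Fit-record data frame (needs `odorant_id`, `status`, `B`,
#'   `E`, `EC50`; `ssr` enables the reweighting).
#' @param min_partners Minimum activating partners per odorant, default 10.
#' @param constrain_curvature Passed to [fit_E_vs_B()].
#' @param irls Use errors-in-variables reweighting when `ssr` is
#'   available. Default TRUE.
#' @return Data frame with one row per qualifying odorant: `odorant_id`,
#'   `n_receptors`, `ratio_kOG_kG`, `curvature`, `mean_omega`, `log10_KO`,
#'   `mean_EC50`, `KO_exceeds_Khalf`.
#' @export
build_micro_table <- function(fits, min_partners = 10,
                              constrain_curvature = FALSE, irls = TRUE) {
  act <- fits[fits$status == "activating" & is.finite(fits$B) &
                fits$B > 0 & fits$E > 0, , drop = FALSE]
  tab <- table(act$odorant_id)
  keep <- names(tab)[tab >= min_partners]
  rows <- lapply(keep, function(od) {
    sub <- act[act$odorant_id == od, , drop = FALSE]
    hyp <- tryCatch({
      h <- suppressWarnings(
        fit_E_vs_B(sub$B, sub$E, constrain_curvature = constrain_curvature))
      if (irls && !is.null(sub$ssr) && all(is.finite(sub$ssr)) &&
          h$curvature_identifiable) {
        sig2 <- pmax(sub$ssr, 1e-12)
        for (k in 1:3) {
          dmdB <- h$ratio / (1 + h$curvature * sub$B)^2
          h <- suppressWarnings(
            fit_E_vs_B(sub$B, sub$E, weights = 1 / (sig2 * (1 + dmdB^2)),
                       constrain_curvature = constrain_curvature))
        }
      }
      h
    }, error = function(e) NULL)
    if (is.null(hyp)) return(NULL)
    om <- omega(sub$E, sub$B, 10^sub$EC50)
    est <- estimate_KO(hyp$ratio, om)
    data.frame(odorant_id = od, n_receptors = nrow(sub),
               ratio_kOG_kG = hyp$ratio, curvature = hyp$curvature,
               mean_omega = est$mean_omega, log10_KO = est$log10_KO,
               mean_EC50 = mean(sub$EC50),
               KO_exceeds_Khalf = est$log10_KO > mean(sub$EC50),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(odorant_id = character(), n_receptors = integer(),
                      ratio_kOG_kG = numeric(), curvature = numeric(),
                      mean_omega = numeric(), log10_KO = numeric(),
                      mean_EC50 = numeric(), KO_exceeds_Khalf = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(-out$n_receptors), , drop = FALSE]
}
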