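# Synthetic odorant-OR screening panels with the statistical structure the
# analysis assumes: Gaussian EC50 on the log10-molar scale, efficacies from
# a two-exponential mixture, Hill coefficients concentrated near 1 with a
# right tail, a deactivating minority, receptor-specific basal activity,
# and additive noise on a log-spaced dose grid. Every activating pair is
# backed by a consistent set of microscopic kinetic constants (gauge:
# C_G = 1, K_G = 1, A = 1 — only ratios are identifiable), so the kinetic
# consistency inequality holds for every generated pair by construction.

#' Specification for a synthetic odorant-OR panel
#'
#' The defaults emulate the statistical structure of the published
#' high-throughput screening panel: 304 receptors x 89 odorants with an
#' interaction density giving 535 expected interacting pairs; EC50 ~
#' N(-3.6, 1.1^2) log10 molar; efficacy drawn for every pair from the
#' two-exponential mixture (phi = 0.79, means 1.50 and 10.06); Hill
#' coefficients log-normal about 1 (sdlog 0.3, truncated to [0.3, 6.6]);
#' receptor-level basal activity log-normal; measurement noise 5% of
#' |dS_max|; 8 doses at half-decade spacing centered on each pair's EC50
#' with half-decade uniform jitter.
#'
#' Whether a pair activates is emergent, not forced: dS_max = E - B, so a
#' pair deactivates exactly when its efficacy draw falls below the
#' receptor's basal level. The basal median is calibrated numerically
#' (given `basal_sdlog` and the efficacy mixture) so that the expected
#' deactivating fraction equals `deactivating_fraction` — the efficacy
#' marginal then follows the stated mixture exactly, with no truncation
#' bias. Supplying `basal_meanlog` explicitly bypasses the calibration.
#'
#' @param n_receptors,n_odorants Panel dimensions.
#' @param interaction_density Probability that a receptor-odorant pair
#'   interacts, in (0, 1].
#' @param ec50_mu,ec50_sigma EC50 Gaussian (log10 molar, decades).
#' @param mix_phi,mix_mean1,mix_mean2 Efficacy mixture parameters.
#' @param H_sdlog Log-sd of the Hill-coefficient law (0 = point mass at 1).
#' @param H_range Truncation range for H.
#' @param deactivating_fraction Target expected fraction of interacting
#'   pairs with dS_max < 0, in (0, 1); realized by calibrating the basal
#'   scale.
#' @param basal_meanlog,basal_sdlog Receptor basal-activity log-normal;
#'   `basal_meanlog = NULL` (default) triggers the calibration.
#' @param noise_sigma Measurement noise as a fraction of |dS_max|.
#' @param n_doses,dose_step Dose-grid size and spacing in decades.
#' @param grid_jitter Half-width of the uniform jitter on the grid center.
#' @param g_max Upper bound for the log-uniform K_O/K_half draw (>= 1).
#' @param seed Mandatory integer seed.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n_receptors = 304, n_odorants = 89,
                           interaction_density = 535 / (304 * 89),
                           ec50_mu = -3.6, ec50_sigma = 1.1,
                           mix_phi = 0.79, mix_mean1 = 1.50,
                           mix_mean2 = 10.06,
                           H_sdlog = 0.3, H_range = c(0.3, 6.6),
                           deactivating_fraction = 1 - 475 / 535,
                           basal_meanlog = NULL, basal_sdlog = 0.8,
                           noise_sigma = 0.05,
                           n_doses = 8, dose_step = 0.5,
                           grid_jitter = 0.5, g_max = 100, seed) {
  if (missing(seed) || !is.numeric(seed)) {
    stop("generator_spec: an integer seed is mandatory")
  }
  stopifnot(n_receptors >= 1, n_odorants >= 1,
            interaction_density > 0, interaction_density <= 1,
            ec50_sigma >= 0, mix_phi > 0, mix_phi < 1,
            mix_mean1 > 0, mix_mean2 > 0, H_sdlog >= 0,
            deactivating_fraction > 0, deactivating_fraction < 1,
            noise_sigma >= 0, n_doses >= 4, dose_step > 0, g_max >= 1)
  if (is.null(basal_meanlog)) {
    # calibrate the basal median so that P(E < B) under the efficacy
    # mixture equals the target deactivating fraction
    basal_meanlog <- local({
      p_deact <- function(m) {
        stats::integrate(function(b) {
          FE <- mix_phi * stats::pexp(b, 1 / mix_mean1) +
            (1 - mix_phi) * stats::pexp(b, 1 / mix_mean2)
          FE * stats::dlnorm(b, log(m), basal_sdlog)
        }, 0, Inf)$value
      }
      log(stats::uniroot(function(m) p_deact(m) - deactivating_fraction,
                         c(1e-6, 100 * mix_mean2), tol = 1e-10)$root)
    })
  }
  structure(as.list(environment()), class = "generator_spec")
}

#' Draw ground-truth parameters for every interacting pair
#'
#' Draws each pair's empirical parameters from the generator's laws and
#' back-solves the microscopic kinetic constants in the C_G = 1, K_G = 1,
#' A = 1 gauge: a ratio g = K_O/K_half is drawn log-uniform on
#' [1, g_max], which fixes K_OG = 1/(2g - 1) (so K_OG <= K_G and the
#' consistency inequality holds automatically), then k_G_f = 2B and
#' k_OG_f = (1 + 1/K_OG) E complete the pack via the closed-form maps.
#' Basal activity is drawn once per receptor and shared across that
#' receptor's pairs; efficacy is drawn per pair from the mixture, and the
#' pair deactivates when the draw lands below the receptor's basal level
#' (see [generator_spec()] for the calibration that fixes the expected
#' deactivating fraction).
#'
#' @param spec A [generator_spec()].
#' @return A data frame (truth table) with one row per interacting pair:
#'   ids, `B`, `dS_max`, `E`, `EC50`, `H`, `activating`, and the kinetic
#'   truth `k_G_f`, `k_OG_f`, `K_G`, `K_OG`, `K_O`, `log10_KO`, `omega`.
#' @export
sample_pair_parameters <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  rid <- sprintf("OR%03d", seq_len(spec$n_receptors))
  oid <- sprintf("odorant%03d", seq_len(spec$n_odorants))
  inter <- which(matrix(stats::runif(spec$n_receptors * spec$n_odorants) <
                          spec$interaction_density,
                        spec$n_receptors, spec$n_odorants),
                 arr.ind = TRUE)
  n <- nrow(inter)
  if (n == 0L) stop("sample_pair_parameters: no interacting pairs drawn")
  basal <- stats::rlnorm(spec$n_receptors, spec$basal_meanlog,
                         spec$basal_sdlog)
  B <- basal[inter[, 1]]
  EC50 <- stats::rnorm(n, spec$ec50_mu, spec$ec50_sigma)
  H <- if (spec$H_sdlog == 0) rep(1, n) else {
    pmin(pmax(stats::rlnorm(n, 0, spec$H_sdlog), spec$H_range[1]),
         spec$H_range[2])
  }
  E <- rexp_mixture(n, spec$mix_phi, spec$mix_mean1, spec$mix_mean2)
  activating <- E > B
  dS_max <- E - B
  # kinetic back-solve, gauge C_G = K_G = A = 1
  g <- 10^stats::runif(n, 0, log10(spec$g_max))  # K_O / K_half, >= 1
  K_half <- 10^EC50
  K_O <- g * K_half
  K_OG <- 1 / (2 * g - 1)
  k_G_f <- 2 * B
  k_OG_f <- (1 + 1 / K_OG) * E
  data.frame(receptor_id = rid[inter[, 1]], odorant_id = oid[inter[, 2]],
             B = B, dS_max = dS_max, E = E, EC50 = EC50, H = H,
             activating = activating,
             k_G_f = k_G_f, k_OG_f = k_OG_f, K_G = 1, K_OG = K_OG,
             K_O = K_O, log10_KO = log10(K_O),
             omega = log10(k_OG_f / (k_G_f * K_O)),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic dose-response panel
#'
#' Evaluates each pair's Hill curve on its log-spaced dose grid and adds
#' Gaussian noise with standard deviation `noise_sigma * |dS_max|`.
#' The same seed always reproduces the same panel exactly.
#'
#' @param spec A [generator_spec()].
#' @return A list with `data` (long-format dose-response data frame:
#'   `receptor_id`, `odorant_id`, `concentration_M`, `response`,
#'   `replicate`) and `truth` (the [sample_pair_parameters()] table).
#' @export
generate_dataset <- function(spec) {
  truth <- sample_pair_parameters(spec)  # seeds the RNG
  n <- nrow(truth)
  half_span <- (spec$n_doses - 1) / 2 * spec$dose_step
  center <- truth$EC50 + stats::runif(n, -spec$grid_jitter,
                                      spec$grid_jitter)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ld <- center[i] + seq(-half_span, half_span, by = spec$dose_step)
    h <- hill_params(B = truth$B[i], dS_max = truth$dS_max[i],
                     EC50 = truth$EC50[i], H = truth$H[i])
    s <- hill_activity(h, 10^ld)
    noise <- stats::rnorm(length(ld), 0,
                          spec$noise_sigma * abs(truth$dS_max[i]))
    rows[[i]] <- data.frame(receptor_id = truth$receptor_id[i],
                            odorant_id = truth$odorant_id[i],
                            concentration_M = 10^ld,
                            response = s + noise,
                            replicate = 1L,
                            stringsAsFactors = FALSE)
  }
  list(data = do.call(rbind, rows), truth = truth)
}

#' Generate a single-odorant panel with shared odorant kinetics
#'
#' All receptors share one odorant's microscopic constants (the on-rate
#' enhancement `ratio = k_OG_f/k_G_f` and binding constant `K_O`) and
#' differ only in G-protein concentration `C_G` (log-normal across
#' receptors), so their (B, E) pairs fall exactly on the
#' efficacy-vs-basal hyperbola — the geometry the microscopic-inference
#' stage inverts. Dose-response data are simulated on the same grid
#' conventions as [generate_dataset()].
#'
#' @param ratio True `k_OG_f / k_G_f` (> 0).
#' @param log10_KO True log10 odorant binding constant.
#' @param n_receptors Number of partner receptors.
#' @param K_OG G-protein dissociation constant with odorant bound
#'   (K_G = 1 gauge); sets the hyperbola curvature. Default
#'   `min(1, max(0.05, 1.5/ratio))`, which keeps every receptor activating
#'   (requires `K_G/K_OG < ratio`) while bending the hyperbola enough for
#'   the curvature to be identifiable.
#' @param cg_meanlog,cg_sdlog Log-normal law of the receptor C_G spread.
#'   The wide default (meanlog -1, sdlog 2) makes basal activities span
#'   both sides of the hyperbola knee, which is what identifies the
#'   amplitude; real panels show a comparably wide basal range.
#' @param noise_sigma Noise fraction of |dS_max|. Default 0.05.
#' @param n_doses,dose_step Dose grid, as in [generator_spec()].
#' @param seed Integer seed.
#' @return A list with `data`, `truth` (per-receptor B, E, EC50 and the
#'   shared constants) and `params` (the shared odorant truth).
#' @export
generate_odorant_panel <- function(ratio, log10_KO, n_receptors = 25,
                                   K_OG = NULL, cg_meanlog = -1,
                                   cg_sdlog = 2,
                                   noise_sigma = 0.05, n_doses = 8,
                                   dose_step = 0.5, seed) {
  if (is.null(K_OG)) K_OG <- min(1, max(0.05, 1.5 / ratio))
  stopifnot(ratio > 0, K_OG > 0, K_OG <= 1, n_receptors >= 5)
  if (1 / K_OG >= ratio && ratio > 1) {
    warning("generate_odorant_panel: K_G/K_OG >= ratio; high-C_G receptors ",
            "will be deactivating")
  }
  if (missing(seed)) stop("generate_odorant_panel: seed is mandatory")
  set.seed(seed)
  K_O <- 10^log10_KO
  C_G <- stats::rlnorm(n_receptors, cg_meanlog, cg_sdlog)
  rows <- vector("list", n_receptors)
  truth <- vector("list", n_receptors)
  half_span <- (n_doses - 1) / 2 * dose_step
  for (i in seq_len(n_receptors)) {
    p <- kinetic_params(A = 1, C_G = C_G[i], k_G_f = 1, k_OG_f = ratio,
                        K_G = 1, K_OG = K_OG, K_O = K_O)
    h <- kinetic_to_hill(p)
    ld <- h$EC50 + seq(-half_span, half_span, by = dose_step)
    s <- hill_activity(h, 10^ld)
    noise <- stats::rnorm(length(ld), 0, noise_sigma * abs(h$dS_max))
    rid <- sprintf("OR%03d", i)
    rows[[i]] <- data.frame(receptor_id = rid, odorant_id = "odorant001",
                            concentration_M = 10^ld,
                            response = s + noise, replicate = 1L,
                            stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(receptor_id = rid, C_G = C_G[i], B = h$B,
                             E = h$E, EC50 = h$EC50,
                             stringsAsFactors = FALSE)
  }
  list(data = do.call(rbind, rows), truth = do.call(rbind, truth),
       params = list(ratio = ratio, log10_KO = log10_KO, K_OG = K_OG,
                     curvature = (1 / K_OG - 1)))
}
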