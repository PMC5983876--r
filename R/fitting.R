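# Per-pair Hill-curve fitting with a free Hill coefficient, classification
# of fits, and the universal-collapse diagnostic.
#
# The optimizer profiles out the linear parameters: for fixed (log10 K_half,
# H) the model S = B + dS_max * f(C_O) is linear in (B, dS_max), so each
# multistart candidate costs one 2x2 least-squares solve. The best grid
# candidates are then polished by bounded L-BFGS-B over all four parameters.

#' Default fitting configuration
#'
#' @param corr_threshold Minimum Pearson correlation between observed and
#'   fitted responses for a fit to count as reliable. Default 0.9.
#' @param H_bounds Bounds on the Hill coefficient. Default `c(0.2, 10)`.
#' @param ec50_pad Decades by which the log10 dose range is extended to
#'   bound log10 K_half. Default 2.
#' @param n_starts Multistart grid size per axis (log10 K_half x H).
#'   Default 5.
#' @param constrain_B Lower-bound the basal activity at 0. Default TRUE.
#' @param weight_replicates Weight concentration means by replicate count
#'   when averaging. Default TRUE.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(corr_threshold = 0.9, H_bounds = c(0.2, 10),
                       ec50_pad = 2, n_starts = 5, constrain_B = TRUE,
                       weight_replicates = TRUE) {
  stopifnot(corr_threshold >= -1, corr_threshold <= 1,
            length(H_bounds) == 2L, H_bounds[1] > 0,
            H_bounds[2] > H_bounds[1], ec50_pad >= 0, n_starts >= 2)
  structure(list(corr_threshold = corr_threshold, H_bounds = H_bounds,
                 ec50_pad = ec50_pad, n_starts = n_starts,
                 constrain_B = constrain_B,
                 weight_replicates = weight_replicates),
            class = "fit_config")
}

# Profiled linear solve: given f = u/(1+u) at the doses, find (B, dS_max)
# minimizing weighted SSR, optionally with B >= 0.
.profile_linear <- function(f, y, w, constrain_B) {
  X <- cbind(1, f)
  fit <- stats::lm.wfit(X, y, w)
  B <- fit$coefficients[1]; dS <- fit$coefficients[2]
  if (any(!is.finite(c(B, dS)))) return(NULL)
  if (constrain_B && B < 0) {
    # re-solve with B pinned at 0: dS = <w f y> / <w f^2>
    B <- 0
    dS <- sum(w * f * y) / sum(w * f * f)
    if (!is.finite(dS)) return(NULL)
  }
  ssr <- sum(w * (y - (B + dS * f))^2)
  list(B = B, dS = dS, ssr = ssr)
}

.hill_f <- function(log_doses, logK, H) {
  u <- 10^(H * (log_doses - logK))
  f <- u / (1 + u)
  f[!is.finite(u)] <- 1
  f
}

#' Fit a Hill curve with free Hill coefficient to one dose-response series
#'
#' Bounded nonlinear least squares for (B, dS_max, log10 K_half, H), with a
#' multistart grid over (log10 K_half, H) to guard against the local minima
#' that free-H Hill fits are prone to, followed by an L-BFGS-B polish of
#' the best candidates. Ties in the final sum of squares are broken in
#' favor of the smaller Hill coefficient.
#'
#' @param doses Concentrations in molar (> 0), at least 4 distinct values.
#' @param responses Measured responses, same length as `doses`.
#' @param config A [fit_config()].
#' @param replicate Optional replicate index; responses are averaged per
#'   distinct concentration before fitting (weighted by replicate count
#'   when `config$weight_replicates`).
#' @return A one-row data frame with columns `B`, `dS_max`, `E`, `EC50`,
#'   `H`, `corr`, `ssr`, `converged`, `status` (one of "activating",
#'   "deactivating", "unreliable").
#' @export
#' @examples
#' h <- hill_params(B = 0.32, dS_max = 0.96, EC50 = -3.84, H = 6.6)
#' d <- 10^seq(-6, -2.5, by = 0.5)
#' fit_hill_curve(d, hill_activity(h, d))
fit_hill_curve <- function(doses, responses, config = fit_config(),
                           replicate = NULL) {
  stopifnot(length(doses) == length(responses))
  ok <- is.finite(doses) & is.finite(responses) & doses > 0
  doses <- doses[ok]; responses <- responses[ok]
  # collapse replicates to per-concentration means
  key <- signif(doses, 12)
  agg <- tapply(responses, key, mean)
  w <- as.numeric(table(key)[names(agg)])
  if (!config$weight_replicates) w <- rep(1, length(agg))
  d <- as.numeric(names(agg)); y <- as.numeric(agg)
  o <- order(d); d <- d[o]; y <- y[o]; w <- w[o]
  if (length(d) < 4L) {
    stop("fit_hill_curve: need >= 4 distinct positive concentrations")
  }
  ld <- log10(d)
  pad <- config$ec50_pad
  logK_lim <- c(min(ld) - pad, max(ld) + pad)
  Hb <- config$H_bounds

  # degenerate (flat) data: dS_max pinned near 0, unreliable
  if (stats::sd(y) == 0 || diff(range(y)) < 1e-12 * max(1, abs(mean(y)))) {
    return(data.frame(
      B = mean(y), dS_max = 0, E = mean(y), EC50 = mean(ld), H = 1,
      corr = NA_real_, ssr = 0, converged = TRUE, status = "unreliable",
      stringsAsFactors = FALSE))
  }

  n_st <- config$n_starts
  logK_grid <- seq(min(ld) - 0.5, max(ld) + 0.5, length.out = n_st)
  H_grid <- exp(seq(log(max(Hb[1], 0.3)), log(min(Hb[2], 6)),
                    length.out = n_st))
  cand <- expand.grid(logK = logK_grid, H = H_grid)
  cand$ssr <- Inf
  lin <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    f <- .hill_f(ld, cand$logK[i], cand$H[i])
    sol <- .profile_linear(f, y, w, config$constrain_B)
    if (!is.null(sol)) { cand$ssr[i] <- sol$ssr; lin[[i]] <- sol }
  }
  ord <- order(cand$ssr)
  best <- NULL; converged <- FALSE
  obj <- function(par) {
    f <- .hill_f(ld, par[3], par[4])
    sum(w * (y - (par[1] + par[2] * f))^2)
  }
  grad <- function(par) {
    f <- .hill_f(ld, par[3], par[4])
    r <- y - (par[1] + par[2] * f)
    f1f <- f * (1 - f)
    ln10 <- log(10)
    c(-2 * sum(w * r),
      -2 * sum(w * r * f),
      -2 * sum(w * r * par[2] * (-ln10 * par[4] * f1f)),
      -2 * sum(w * r * par[2] * (ln10 * (ld - par[3]) * f1f)))
  }
  lower <- c(if (config$constrain_B) 0 else -Inf, -Inf, logK_lim[1], Hb[1])
  upper <- c(Inf, Inf, logK_lim[2], Hb[2])
  for (i in ord[seq_len(min(3L, sum(is.finite(cand$ssr))))]) {
    sol <- lin[[i]]
    par0 <- c(max(sol$B, if (config$constrain_B) 0 else -Inf),
              sol$dS, cand$logK[i], cand$H[i])
    res <- tryCatch(
      stats::optim(par0, obj, gr = grad, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 1000, factr = 10, pgtol = 1e-14)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value - 1e-12 ||
        (abs(res$value - best$value) <= 1e-12 && res$par[4] < best$par[4])) {
      best <- res
      converged <- res$convergence == 0
    }
  }
  if (is.null(best)) {
    return(data.frame(
      B = NA_real_, dS_max = NA_real_, E = NA_real_, EC50 = NA_real_,
      H = NA_real_, corr = NA_real_, ssr = NA_real_, converged = FALSE,
      status = "unreliable", stringsAsFactors = FALSE))
  }
  par <- best$par
  fitted <- par[1] + par[2] * .hill_f(ld, par[3], par[4])
  corr <- if (stats::sd(fitted) > 0) stats::cor(y, fitted) else NA_real_
  data.frame(B = par[1], dS_max = par[2], E = par[1] + par[2],
             EC50 = par[3], H = par[4], corr = corr, ssr = best$value,
             converged = converged,
             status = .fit_status(par[2], corr, config$corr_threshold),
             stringsAsFactors = FALSE)
}

.fit_status <- function(dS_max, corr, threshold) {
  if (!is.finite(dS_max) || !is.finite(corr) || corr < threshold ||
      abs(dS_max) < 1e-8) {
    "unreliable"
  } else if (dS_max > 0) "activating" else "deactivating"
}

#' Fit all odorant-OR pairs of a long-format dose-response table
#'
#' @param data Data frame with columns `receptor_id`, `odorant_id`,
#'   `concentration_M`, `response` and optionally `replicate`.
#' @param config A [fit_config()].
#' @return A data frame of fit records, one row per pair: ids, `B`,
#'   `dS_max`, `E`, `EC50`, `H`, `corr`, `ssr`, `converged`, `status`.
#' @export
fit_panel <- function(data, config = fit_config()) {
  req <- c("receptor_id", "odorant_id", "concentration_M", "response")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("fit_panel: missing column(s): ", paste(miss, collapse = ", "))
  }
  keys <- interaction(data$receptor_id, data$odorant_id, drop = TRUE,
                      sep = "\r")
  out <- lapply(split(seq_len(nrow(data)), keys), function(idx) {
    sub <- data[idx, , drop = FALSE]
    rec <- tryCatch(
      fit_hill_curve(sub$concentration_M, sub$response, config),
      error = function(e) data.frame(
        B = NA_real_, dS_max = NA_real_, E = NA_real_, EC50 = NA_real_,
        H = NA_real_, corr = NA_real_, ssr = NA_real_, converged = FALSE,
        status = "unreliable", stringsAsFactors = FALSE))
    cbind(data.frame(receptor_id = sub$receptor_id[1],
                     odorant_id = sub$odorant_id[1],
                     stringsAsFactors = FALSE), rec)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Partition fit records into activating, deactivating and unreliable
#'
#' A pair counts as activating when `dS_max > 0` and the fit correlation
#' meets the threshold; deactivating when `dS_max < 0` at the same
#' standard; everything else (poor fits, flat curves) is unreliable.
#'
#' @param records Fit-record data frame from [fit_panel()].
#' @param corr_threshold Correlation threshold, default 0.9.
#' @return A list with the three sub-data-frames (`activating`,
#'   `deactivating`, `unreliable`) and a named `counts` vector.
#' @export
classify_and_filter <- function(records, corr_threshold = 0.9) {
  stopifnot(all(c("dS_max", "corr") %in% names(records)))
  status <- vapply(seq_len(nrow(records)), function(i) {
    .fit_status(records$dS_max[i], records$corr[i], corr_threshold)
  }, character(1))
  records$status <- status
  out <- list(activating = records[status == "activating", , drop = FALSE],
              deactivating = records[status == "deactivating", , drop = FALSE],
              unreliable = records[status == "unreliable", , drop = FALSE])
  out$counts <- c(activating = nrow(out$activating),
                  deactivating = nrow(out$deactivating),
                  unreliable = nrow(out$unreliable))
  out
}

#' Collapse dose-response data onto the universal Hill curve
#'
#' Each measurement is mapped to the rescaled coordinates
#' \eqn{\xi = H \log_{10}(C_O / K_{1/2})}, \eqn{f = (S - B)/\delta S_{max}};
#' on these axes every reliable Hill fit lies on the single curve
#' \eqn{f = 10^\xi / (1 + 10^\xi)}. The root-mean-square deviation from
#' that curve is the collapse diagnostic.
#'
#' @param records Fit-record data frame (needs `receptor_id`, `odorant_id`,
#'   `B`, `dS_max`, `EC50`, `H`, `corr`).
#' @param data The raw long-format dose-response table the records were
#'   fitted from.
#' @param corr_threshold Only records with `|dS_max| > 0` and `corr >=`
#'   this value participate. Default 0.9.
#' @return A list with `points` (data frame `xi`, `f`, ids) and
#'   `rms_deviation`.
#' @export
collapse_curves <- function(records, data, corr_threshold = 0.9) {
  keep <- is.finite(records$corr) & records$corr >= corr_threshold &
    is.finite(records$dS_max) & records$dS_max != 0
  dropped <- sum(!keep)
  if (dropped > 0) {
    message("collapse_curves: excluding ", dropped,
            " record(s) with dS_max = 0 or corr below threshold")
  }
  records <- records[keep, , drop = FALSE]
  pts <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    sub <- data[data$receptor_id == r$receptor_id &
                  data$odorant_id == r$odorant_id, , drop = FALSE]
    xi <- r$H * (log10(sub$concentration_M) - r$EC50)
    f <- (sub$response - r$B) / r$dS_max
    data.frame(receptor_id = r$receptor_id, odorant_id = r$odorant_id,
               xi = xi, f = f, stringsAsFactors = FALSE)
  })
  pts <- do.call(rbind, pts)
  universal <- 10^pts$xi / (1 + 10^pts$xi)
  list(points = pts,
       rms_deviation = sqrt(mean((pts$f - universal)^2)))
}
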