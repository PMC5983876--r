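# Population distributions: Gaussian EC50, two-exponential mixture,
# differential response.

test_that("Gaussian EC50 fit is a consistent, translation-equivariant MLE", {
  set.seed(101)
  x <- rnorm(5000, -3.6, 1.1)
  fit <- fit_ec50_gaussian(x)
  se_mu <- 1.1 / sqrt(5000)
  se_sigma <- 1.1 / sqrt(2 * 5000)
  expect_lt(abs(fit$mu - -3.6), 3 * se_mu)
  expect_lt(abs(fit$sigma - 1.1), 3 * se_sigma)
  # cross-check against an independent MLE implementation
  skip_if_not_installed("fitdistrplus")
  ref <- fitdistrplus::fitdist(x, "norm")
  expect_equal(fit$mu, unname(ref$estimate["mean"]), tolerance = 1e-8)
  expect_equal(fit$sigma, unname(ref$estimate["sd"]), tolerance = 1e-6)

  shifted <- fit_ec50_gaussian(x + 1)
  expect_equal(shifted$mu, fit$mu + 1)
  expect_equal(shifted$sigma, fit$sigma)

  degen <- fit_ec50_gaussian(rep(-4, 10))
  expect_true(degen$degenerate)
  expect_equal(degen$sigma, 0)
  expect_error(fit_ec50_gaussian(rep(-4, 9)), "at least 10")
})

test_that("single-exponential data reduce the mixture to its nested null", {
  set.seed(11)
  x <- rexp(2000, rate = 1 / 3)
  fit <- fit_exponential_mixture(x, seed = 1)
  # both components near the sample mean or phi near a pure component
  eff_mean <- fit$phi * fit$mean1 + (1 - fit$phi) * fit$mean2
  expect_equal(eff_mean, mean(x), tolerance = 0.05)
  expect_lt(fit$lr_stat, 8)  # no real evidence for a second component
  expect_error(fit_exponential_mixture(rexp(10)), ">= 50")
  expect_error(fit_exponential_mixture(c(-1, rexp(60))), "> 0")
})

test_that("EM recovers the efficacy-mixture and amplitude-mixture parameters at n = 5e4", {
  set.seed(202)
  x <- rexp_mixture(50000, 0.79, 1.50, 10.06)
  fit <- fit_exponential_mixture(x, seed = 3)
  expect_lt(abs(fit$phi - 0.79), 0.03)
  expect_lt(abs(fit$mean1 - 1.50), 0.15)
  expect_lt(abs(fit$mean2 - 10.06), 0.5)
  expect_lt(fit$mean1, fit$mean2)
  expect_gt(fit$lr_stat, 100)  # the two-component form is decisively better

  y <- rexp_mixture(50000, 0.57, 0.97, 5.77)
  fit2 <- fit_exponential_mixture(y, seed = 3)
  expect_lt(abs(fit2$phi - 0.57), 0.05)
  expect_lt(abs(fit2$mean1 - 0.97), 0.1)
  expect_lt(abs(fit2$mean2 - 5.77), 0.3)
})

test_that("EM log-likelihood is monotone across iterations", {
  set.seed(33)
  x <- rexp_mixture(2000, 0.6, 1, 8)
  # re-run the E/M updates by hand and track the log-likelihood
  phi <- 0.5; m1 <- quantile(x, 0.3)[[1]]; m2 <- quantile(x, 0.9)[[1]]
  ll_prev <- -Inf
  for (i in 1:100) {
    d1 <- phi * dexp(x, 1 / m1); d2 <- (1 - phi) * dexp(x, 1 / m2)
    tot <- d1 + d2
    ll <- sum(log(tot))
    expect_gte(ll, ll_prev - 1e-9)
    ll_prev <- ll
    r1 <- d1 / tot
    phi <- mean(r1)
    m1 <- sum(r1 * x) / sum(r1)
    m2 <- sum((1 - r1) * x) / sum(1 - r1)
  }
  # package fit attains at least this likelihood
  fit <- fit_exponential_mixture(x, seed = 5)
  expect_gte(fit$loglik, ll_prev - 1e-6)
})

test_that("differential response reduces to single-curve derivative and localizes the ensemble", {
  # single H = 1 receptor: peak at its EC50, FWHM 1.53 decades
  fits1 <- data.frame(receptor_id = "r1", odorant_id = "od", B = 1,
                      dS_max = 2, E = 3, EC50 = -5, H = 1,
                      corr = 1, status = "activating",
                      stringsAsFactors = FALSE)
  psi <- differential_response("od", fits1, grid = seq(-9, -1, 0.01),
                               min_partners = 1)
  expect_equal(psi$peak, -5, tolerance = 0.011)
  half <- max(psi$density) / 2
  width <- diff(range(psi$grid[psi$density >= half]))
  expect_equal(width, response_fwhm(1), tolerance = 0.02)
  area <- sum((psi$density[-1] + psi$density[-length(psi$density)]) / 2 *
                diff(psi$grid))
  expect_equal(area, 1, tolerance = 1e-9)
  expect_true(all(psi$density >= 0))

  # two equal receptors at -5 and -3: symmetric, mass centered at -4
  fits2 <- rbind(fits1, within(fits1, { receptor_id <- "r2"; EC50 <- -3 }))
  psi2 <- differential_response("od", fits2, grid = seq(-9, 1, 0.01))
  centroid <- sum(psi2$grid * psi2$density) / sum(psi2$density)
  expect_equal(centroid, -4, tolerance = 0.02)

  # broad odorant: the peak localizes near the ensemble mean; at 25
  # partners the smoothed mode still wanders (~0.35 sd), tightening with n
  set.seed(404)
  make_partners <- function(n) {
    data.frame(receptor_id = sprintf("r%03d", 1:n), odorant_id = "od",
               B = 1, dS_max = 2, E = 3, EC50 = rnorm(n, -4, 1), H = 1,
               corr = 1, status = "activating", stringsAsFactors = FALSE)
  }
  psi25 <- differential_response("od", make_partners(25))
  expect_lt(abs(psi25$peak - -4), 0.8)
  psi200 <- differential_response("od", make_partners(200))
  expect_lt(abs(psi200$peak - -4), 0.3)

  expect_error(differential_response("absent", fits1), "partner")
})

test_that("full-panel ensemble model recovers the generator laws", {
  spec <- quick_spec(seed = 51, n_receptors = 80, n_odorants = 20,
                     density = 0.35)
  sim <- generate_dataset(spec)
  fits <- fit_panel(sim$data)
  model <- fit_ensemble_model(fits, seed = 9)
  expect_lt(abs(model$ec50_activating$mu - spec$ec50_mu), 0.12)
  expect_lt(abs(model$ec50_activating$sigma - spec$ec50_sigma), 0.15)
  expect_s3_class(model, "ensemble_model")
  expect_identical(sum(model$counts), nrow(fits))
})
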