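# Hill-curve fitting, classification, and the universal collapse.

test_that("noiseless data are recovered to optimizer tolerance (steep and shallow)", {
  cases <- list(
    hill_params(B = 0.32, dS_max = 0.96, EC50 = -3.84, H = 6.6),
    hill_params(B = 2.18, dS_max = 4.76, EC50 = -7.56, H = 0.7),
    hill_params(B = 0.21, dS_max = 3.09, EC50 = -5.72, H = 1.4))
  for (h in cases) {
    s <- noiseless_series(h)
    rec <- fit_hill_curve(s$doses, s$responses)
    expect_equal(rec$B, h$B, tolerance = 1e-5)
    expect_equal(rec$dS_max, h$dS_max, tolerance = 1e-5)
    expect_equal(rec$EC50, h$EC50, tolerance = 1e-5)
    expect_equal(rec$H, h$H, tolerance = 1e-4)
    expect_equal(rec$corr, 1, tolerance = 1e-9)
    expect_identical(rec$status, "activating")
  }
})

test_that("fit agrees with an independent nonlinear least-squares implementation", {
  skip_if_not_installed("minpack.lm")
  h <- hill_params(B = 1.1, dS_max = 2.4, EC50 = -5, H = 1.8)
  set.seed(42)
  s <- noiseless_series(h)
  y <- s$responses + rnorm(length(s$responses), 0, 0.05 * h$dS_max)
  rec <- fit_hill_curve(s$doses, y)
  ld <- log10(s$doses)
  ref <- minpack.lm::nlsLM(
    y ~ B + dS * 10^(H * (ld - logK)) / (1 + 10^(H * (ld - logK))),
    start = list(B = rec$B, dS = rec$dS_max, logK = rec$EC50, H = rec$H),
    lower = c(0, -Inf, min(ld) - 2, 0.2), upper = c(Inf, Inf, max(ld) + 2, 10))
  co <- coef(ref)
  expect_equal(rec$B, unname(co["B"]), tolerance = 1e-4)
  expect_equal(rec$EC50, unname(co["logK"]), tolerance = 1e-4)
  expect_equal(rec$H, unname(co["H"]), tolerance = 1e-3)
})

test_that("degenerate and deactivating inputs are classified, never thrown", {
  d <- 10^seq(-7, -3.5, by = 0.5)
  flat <- fit_hill_curve(d, rep(2.0, length(d)))
  expect_equal(flat$dS_max, 0)
  expect_identical(flat$status, "unreliable")

  h <- hill_params(B = 2, dS_max = -1, EC50 = -5, H = 1)
  rec <- fit_hill_curve(d, hill_activity(h, d))
  expect_lt(rec$dS_max, 0)
  expect_identical(rec$status, "deactivating")
  expect_equal(rec$EC50, -5, tolerance = 1e-4)

  expect_error(fit_hill_curve(d[1:3], 1:3), ">= 4 distinct")
})

test_that("fitting is equivariant under response rescaling and idempotent", {
  h <- hill_params(B = 0.5, dS_max = 2, EC50 = -4.5, H = 1.2)
  set.seed(7)
  s <- noiseless_series(h)
  y <- s$responses + rnorm(8, 0, 0.05 * h$dS_max)
  r1 <- fit_hill_curve(s$doses, y)
  r2 <- fit_hill_curve(s$doses, 10 * y)
  expect_equal(r2$B, 10 * r1$B, tolerance = 1e-5)
  expect_equal(r2$dS_max, 10 * r1$dS_max, tolerance = 1e-5)
  expect_equal(r2$EC50, r1$EC50, tolerance = 1e-6)
  expect_equal(r2$H, r1$H, tolerance = 1e-6)
  expect_equal(r2$corr, r1$corr, tolerance = 1e-10)
  # refitting the fit's own predictions reproduces the fit
  hfit <- hill_params(B = r1$B, dS_max = r1$dS_max, EC50 = r1$EC50, H = r1$H)
  r3 <- fit_hill_curve(s$doses, hill_activity(hfit, s$doses))
  expect_equal(r3$B, r1$B, tolerance = 1e-8)
  expect_equal(r3$dS_max, r1$dS_max, tolerance = 1e-8)
  expect_equal(r3$EC50, r1$EC50, tolerance = 1e-8)
  expect_equal(r3$H, r1$H, tolerance = 1e-8)
})

test_that("replicates are averaged (with weighting) before fitting", {
  h <- hill_params(B = 1, dS_max = 2, EC50 = -5, H = 1)
  ld <- seq(-6.5, -3.5, by = 0.5)
  d <- 10^ld
  y <- hill_activity(h, d)
  # duplicate one dose with symmetric +/- noise: weighted mean == clean value
  d2 <- c(d, d[3], d[3]); y2 <- c(y, y[3] + 0.1, y[3] - 0.1)
  r <- fit_hill_curve(d2, y2)
  expect_equal(r$EC50, -5, tolerance = 1e-5)
  expect_equal(r$H, 1, tolerance = 1e-4)
})

test_that("classification thresholds work and generator fractions are recovered", {
  recs <- data.frame(
    receptor_id = c("a", "b", "c"), odorant_id = "o",
    B = 1, dS_max = c(1, -1, 1), E = 2, EC50 = -4, H = 1,
    corr = c(0.95, 0.95, 0.85), stringsAsFactors = FALSE)
  cls <- classify_and_filter(recs)
  expect_identical(unname(cls$counts), c(1L, 1L, 1L))
  expect_identical(cls$activating$receptor_id, "a")
  expect_identical(cls$unreliable$receptor_id, "c")

  # synthetic panel with the study's activating fraction (~0.888)
  spec <- quick_spec(seed = 21, n_receptors = 60, n_odorants = 12,
                     density = 0.6)
  sim <- generate_dataset(spec)
  fits <- fit_panel(sim$data)
  cls <- classify_and_filter(fits)
  n <- nrow(sim$truth)
  frac <- cls$counts["activating"] / n
  p0 <- 475 / 535
  expect_lt(abs(frac - p0), 3 * sqrt(p0 * (1 - p0) / n) + 0.03)
})

test_that("reliable fits collapse onto the universal curve", {
  # a midpoint datum maps to (0, 0.5)
  rec <- data.frame(receptor_id = "r", odorant_id = "o", B = 1,
                    dS_max = 2, E = 3, EC50 = -5, H = 1.3, corr = 1,
                    stringsAsFactors = FALSE)
  dat <- data.frame(receptor_id = "r", odorant_id = "o",
                    concentration_M = 1e-5, response = 2,
                    stringsAsFactors = FALSE)
  cc <- collapse_curves(rec, dat)
  expect_equal(cc$points$xi, 0)
  expect_equal(cc$points$f, 0.5)
  expect_equal(cc$rms_deviation, 0)

  # noiseless synthetic panel: exact collapse
  spec <- quick_spec(seed = 5, n_receptors = 25, n_odorants = 8,
                     density = 0.4, noise = 0)
  sim <- generate_dataset(spec)
  fits <- fit_panel(sim$data)
  cc0 <- collapse_curves(fits, sim$data)
  expect_lt(cc0$rms_deviation, 1e-5)

  # 5% noise, ~22 pairs: deviation within a factor 2 of the noise level
  spec2 <- quick_spec(seed = 6, n_receptors = 22, n_odorants = 1,
                      density = 1, noise = 0.05)
  sim2 <- generate_dataset(spec2)
  fits2 <- fit_panel(sim2$data)
  cc2 <- collapse_curves(fits2, sim2$data)
  expect_gt(cc2$rms_deviation, 0.05 / 2)
  expect_lt(cc2$rms_deviation, 0.05 * 2)
})

test_that("parameter recovery over a noisy synthetic ensemble stays within tolerance", {
  spec <- quick_spec(seed = 31, n_receptors = 40, n_odorants = 12,
                     density = 0.45, noise = 0.05)
  sim <- generate_dataset(spec)
  expect_gt(nrow(sim$truth), 200)
  fits <- fit_panel(sim$data)
  m <- merge(sim$truth, fits, by = c("receptor_id", "odorant_id"),
             suffixes = c(".true", ".fit"))
  act <- m[m$activating & m$status == "activating", ]
  expect_lt(median(abs(act$EC50.fit - act$EC50.true)), 0.1)
  expect_lt(median(abs(act$H.fit - act$H.true) / act$H.true), 0.15)
})
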