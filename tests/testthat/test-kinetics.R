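# Closed-form kinetic model, its Hill equivalent, and the parameter maps.

test_that("kinetic activity reduces to basal at zero dose and stays flat when odorant changes nothing", {
  p <- kinetic_params()  # all constants 1
  expect_equal(kinetic_activity(p, 0), 0.5)          # B = 1/(1 + 1) = 1/2
  expect_equal(kinetic_activity(p, 1e9), 0.5, tolerance = 1e-8)
  expect_error(kinetic_params(K_O = -1), "positive")
  expect_error(kinetic_activity(p, -1), ">= 0")
})

test_that("kinetic and Hill forms are the same curve (exact equivalence)", {
  p <- kinetic_params(A = 1, C_G = 1, k_G_f = 1, k_OG_f = 5, K_G = 1,
                      K_OG = 0.1, K_O = 1e-4)
  h <- kinetic_to_hill(p)
  grid <- 10^seq(-9, 0, length.out = 50)
  expect_lt(max(abs(kinetic_activity(p, grid) - hill_activity(h, grid))),
            1e-12 * (abs(h$E) + abs(h$B)))
  # over random parameter packs, on 100-point grids
  for (pk in random_kinetic_params(50, seed = 11)) {
    hk <- kinetic_to_hill(pk)
    g <- 10^seq(log10(pk$K_O) - 5, log10(pk$K_O) + 5, length.out = 100)
    expect_lt(max(abs(kinetic_activity(pk, g) - hill_activity(hk, g))),
              1e-10 * (abs(hk$E) + abs(hk$B)))
  }
})

test_that("kinetic_to_hill matches the closed-form parameter maps", {
  # odorant that changes nothing: K_half = K_O, dS_max = 0
  p0 <- kinetic_params(C_G = 2, K_O = 1e-5)
  h0 <- kinetic_to_hill(p0)
  expect_equal(h0$K_half, 1e-5)
  expect_equal(h0$dS_max, 0)
  # worked case: B = 1/2, E = 5/11, K_half = K_O * 2/11 (deactivating
  # geometry despite k_OG_f > k_G_f, because G-protein binds much tighter
  # with odorant present and saturates the response below basal scale)
  p <- kinetic_params(A = 1, C_G = 1, k_G_f = 1, k_OG_f = 5, K_G = 1,
                      K_OG = 0.1, K_O = 1e-4)
  h <- kinetic_to_hill(p)
  expect_equal(h$B, 0.5)
  expect_equal(h$E, 5 / 11, tolerance = 1e-12)
  expect_equal(h$K_half, 1e-4 * 2 / 11, tolerance = 1e-12)
  expect_lt(h$dS_max, 0)
})

test_that("closed-form K_half equals the brute-force bisection of the kinetic curve", {
  for (pk in random_kinetic_params(20, seed = 7)) {
    hk <- kinetic_to_hill(pk)
    if (abs(hk$dS_max) < 1e-9 * (hk$B + abs(hk$E))) next  # flat curve
    level <- (hk$B + hk$E) / 2
    g <- function(l) kinetic_activity(pk, 10^l) - level
    root <- uniroot(g, c(log10(pk$K_O) - 8, log10(pk$K_O) + 8),
                    tol = 1e-13)$root
    expect_equal(10^root, hk$K_half, tolerance = 1e-9)
  }
})

test_that("hill_activity honors the midpoint, zero-dose and saturation identities", {
  h <- hill_params(B = 0.21, dS_max = 3.09, EC50 = -5.72, H = 1.4)
  expect_equal(hill_activity(h, 10^-5.72), 0.21 + 3.09 / 2)  # 1.755
  expect_equal(hill_activity(h, 0), 0.21)
  h2 <- hill_params(B = 2.18, dS_max = 4.76, EC50 = -7.56, H = 0.7)
  expect_equal(hill_activity(h2, 1e9), 6.94, tolerance = 1e-3)
  expect_error(hill_activity(h, -1e-9), ">= 0")
})

test_that("omega equals log10(k_OG_f / (k_G_f K_O)) identically", {
  expect_equal(omega(1, 1, 1), 0)
  # Table-style inversion: ratio 4.96, log10 K_O = -1.82
  p <- kinetic_params(A = 3, C_G = 0.7, k_G_f = 2, k_OG_f = 2 * 4.96,
                      K_G = 1.3, K_OG = 0.4, K_O = 10^-1.82)
  h <- kinetic_to_hill(p)
  expect_equal(omega(h$E, h$B, h$K_half), log10(4.96) + 1.82,
               tolerance = 1e-12)
  # independent of A, C_G, K_G, K_OG: property sweep
  for (pk in random_kinetic_params(100, seed = 3)) {
    hk <- kinetic_to_hill(pk)
    expect_equal(omega(hk$E, hk$B, hk$K_half),
                 log10(pk$k_OG_f / (pk$k_G_f * pk$K_O)),
                 tolerance = 1e-10)
  }
  expect_error(omega(0, 1, 1), "> 0")
})

test_that("efficacy-vs-basal hyperbola matches C_G-elimination from the kinetic maps", {
  expect_equal(efficacy_vs_basal(2, ratio = 3, curvature = 0), 6)
  expect_equal(efficacy_vs_basal(0, ratio = 3, curvature = 1), 0)
  expect_error(efficacy_vs_basal(2, ratio = 3, curvature = -1),
               "invalid regime")
  # family sharing everything but C_G falls exactly on the hyperbola
  ratio <- 4.2; K_OG <- 0.25; K_G <- 2; k_G_f <- 1.5; A <- 0.8
  curv <- (1 / K_OG - 1 / K_G) / (A * k_G_f)
  for (C_G in 10^seq(-2, 2, by = 0.5)) {
    h <- kinetic_to_hill(kinetic_params(A = A, C_G = C_G, k_G_f = k_G_f,
                                        k_OG_f = ratio * k_G_f, K_G = K_G,
                                        K_OG = K_OG, K_O = 1e-4))
    expect_equal(h$E, efficacy_vs_basal(h$B, ratio, curv),
                 tolerance = 1e-12)
    # companion maps from K_half
    expect_equal(h$B, basal_vs_khalf(h$K_half, 1e-4, curv),
                 tolerance = 1e-10)
    expect_equal(h$E, efficacy_vs_khalf(h$K_half, 1e-4, ratio, curv),
                 tolerance = 1e-10)
  }
})

test_that("consistency inequality passes iff G-protein binds at least as tightly with odorant", {
  # boundary: K_OG = K_G makes both ratios 1
  expect_true(check_consistency(kinetic_params())$pass)
  # K_OG < K_G passes strictly for any C_G (sweep 6 decades)
  for (C_G in 10^seq(-3, 3)) {
    p <- kinetic_params(C_G = C_G, K_OG = 0.1, K_G = 1, K_O = 1e-4)
    res <- check_consistency(p)
    expect_true(res$pass)
    expect_gte(res$KG_over_KOG, res$KO_over_Khalf)
    expect_gte(res$KO_over_Khalf, 1)
  }
  # reversed: odorant-weakened G-protein binding fails
  bad <- check_consistency(kinetic_params(K_OG = 10, K_G = 1))
  expect_false(bad$pass)
  expect_match(bad$message, "weakened")
})

test_that("numeric sensitivity recovers the Hill coefficient and obeys the chain rule", {
  expect_equal(hill_sensitivity(function(th) th / (1 + th)), 1,
               tolerance = 1e-6)
  for (H in c(0.3, 1, 3, 7)) {
    f <- local({ Hh <- H; function(th) th^Hh / (1 + th^Hh) })
    expect_equal(hill_sensitivity(f), H, tolerance = 1e-6)
  }
  # composing theta -> theta^2 doubles the sensitivity
  expect_equal(hill_sensitivity(function(th) th^2 / (1 + th^2)), 2,
               tolerance = 1e-6)
  expect_error(hill_sensitivity(function(th) 0.2 + 0 * th), "midpoint")
})

test_that("closed-form FWHM matches the numeric width of the differential response", {
  expect_equal(response_fwhm(1), 1.53110, tolerance = 1e-5)
  expect_equal(response_fwhm(2), response_fwhm(1) / 2)
  numeric_fwhm <- function(H) {
    dens <- function(x) { u <- 10^(H * x); u / (1 + u)^2 }
    half <- dens(0) / 2               # peak sits at the EC50
    left <- uniroot(function(x) dens(x) - half, c(-12 / H, 0),
                    tol = 1e-12)$root
    right <- uniroot(function(x) dens(x) - half, c(0, 12 / H),
                     tol = 1e-12)$root
    right - left
  }
  for (H in c(0.3, 0.7, 1, 2, 7)) {
    expect_equal(response_fwhm(H), numeric_fwhm(H), tolerance = 1e-6)
  }
  # tighter check at H = 0.7 (half-decade grid curve from a shallow fit)
  expect_equal(response_fwhm(0.7), 2.1873, tolerance = 1e-3)
  expect_error(response_fwhm(0), "> 0")
})
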