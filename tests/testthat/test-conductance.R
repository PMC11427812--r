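test_that("bulk conductivity follows the Nernst-Einstein form", {
  expect_equal(bulk_conductivity(conc = 0)$kappa_bulk, 0)
  b1 <- bulk_conductivity(conc = 0.1)
  b2 <- bulk_conductivity(conc = 0.2)
  expect_equal(b2$kappa_bulk, 2 * b1$kappa_bulk, tolerance = 1e-12)
  # 0.15 M KCl at 300 K with the default diffusivities: ~2.23 S/m
  b <- bulk_conductivity()
  expect_equal(b$kappa_bulk, 2.2337, tolerance = 1e-3)
  expect_equal(b$rho_bulk * b$kappa_bulk, 1)
  expect_error(bulk_conductivity(temperature = -1), "positive")
})

test_that("the double-sigmoid conductivity saturates and stays below bulk", {
  b <- bulk_conductivity()
  p <- conductivity_params(1.5, 6)
  expect_equal(conductivity_model(1e6, 1e6, p, b), b$kappa_bulk,
               tolerance = 1e-9)
  expect_equal(conductivity_model(4, 4, p, b), b$kappa_bulk / 4,
               tolerance = 1e-12)  # a = b = c2/c1
  grid <- seq(0.5, 15, length.out = 20)
  k <- outer(grid, grid, function(a, bb) {
    conductivity_model(pmax(a, bb), pmin(a, bb), p, b)
  })
  expect_true(all(diff(k[, 10]) > 0))
  expect_true(all(diff(k[10, ]) > 0))
  expect_true(all(k > 0 & k < b$kappa_bulk))
  expect_warning(conductivity_params(-1, 2), "c1")
})

test_that("a uniform cylinder recovers the single-cylinder conductance", {
  b <- bulk_conductivity()
  z <- seq(0.5, 49.5, by = 1)
  prof <- make_sphere_profile(z, radius = 4.7)
  est <- channel_resistance(prof, b)
  g_hille <- b$kappa_bulk * pi * (4.7e-10)^2 / (50e-10) * 1e12
  expect_equal(est$g_pS, g_hille, tolerance = 1e-12)
  expect_equal(est$g_pS, 309, tolerance = 0.01)
  expect_equal(est$variant, "spherical-bulk")
  expect_equal(sum(est$slices$R_slice), est$R_ohm)
  expect_equal(est$g_pS * est$R_ohm, 1e12, tolerance = 1e-12)
})

test_that("resistance is invariant under slice subdivision and z reversal", {
  b <- bulk_conductivity()
  z <- seq(0.5, 49.5, by = 1)
  r <- 4 + sin(z / 3)
  R1 <- channel_resistance(make_sphere_profile(z, r), b)$R_ohm
  z2 <- seq(0.25, 49.75, by = 0.5)
  r2 <- rep(r, each = 2)
  R2 <- channel_resistance(make_sphere_profile(z2, r2), b)$R_ohm
  expect_equal(R2, R1, tolerance = 1e-12)
  R3 <- channel_resistance(make_sphere_profile(z, rev(r)), b)$R_ohm
  expect_equal(R3, R1, tolerance = 1e-12)
})

test_that("a stepped pore sums the series resistances of its segments", {
  b <- bulk_conductivity()
  z <- seq(0.5, 49.5, by = 1)
  r <- c(rep(8, 20), rep(3, 10), rep(8, 20))
  est <- channel_resistance(make_sphere_profile(z, r), b)
  hand <- (20e-10 / (b$kappa_bulk * pi * (8e-10)^2)) +
    (10e-10 / (b$kappa_bulk * pi * (3e-10)^2)) +
    (20e-10 / (b$kappa_bulk * pi * (8e-10)^2))
  expect_equal(est$R_ohm, hand, tolerance = 1e-12)
})

test_that("the conductivity model always reduces conductance below bulk", {
  b <- bulk_conductivity()
  p <- conductivity_params(1.5, 6)
  z <- seq(0.5, 29.5, by = 1)
  for (r in list(rep(4, 30), 3 + abs(z - 15) / 10)) {
    prof <- make_sphere_profile(z, r)
    expect_lt(channel_resistance(prof, b, p)$g_pS,
              channel_resistance(prof, b)$g_pS)
  }
  # ellipsoidal bulk estimate dominates spherical bulk (a >= r)
  el <- make_ellipse_profile(z, a = 6, b = 4)
  sp <- make_sphere_profile(z, radius = 4)
  expect_gte(channel_resistance(el, b)$g_pS,
             channel_resistance(sp, b)$g_pS)
})

test_that("the model estimate converges to bulk for wide pores", {
  b <- bulk_conductivity()
  p <- conductivity_params(1.5, 6)
  z <- seq(0.5, 29.5, by = 1)
  for (r in c(8, 10, 12)) {
    prof <- make_sphere_profile(z, rep(r, 30))
    g_model <- channel_resistance(prof, b, p)$g_pS
    g_bulk <- channel_resistance(prof, b)$g_pS
    gap <- (g_bulk - g_model) / g_bulk
    expect_lt(gap, 2 * exp(-(p$c1 * r - p$c2)))
  }
})

test_that("nonpositive radii are rejected with the slice named", {
  b <- bulk_conductivity()
  prof <- make_sphere_profile(seq(0.5, 9.5, 1), c(rep(3, 4), 0, rep(3, 5)))
  expect_error(channel_resistance(prof, b), "slice 5")
})

test_that("noise-free parameter recovery is exact on the training design", {
  b <- bulk_conductivity()
  truth <- conductivity_params(1.5, 6.0)
  rec <- simulate_conductance_records(truth, b)
  expect_equal(nrow(rec), 18)
  fit <- fit_conductivity(rec, b)
  expect_equal(fit$params$c1, 1.5, tolerance = 1e-3)
  expect_equal(fit$params$c2, 6.0, tolerance = 1e-3)
  expect_lt(fit$residual_ss, 1e-10)
  expect_gt(fit$r_squared, 1 - 1e-8)
  td <- tidy(fit)
  expect_equal(td$term, c("c1", "c2"))
  expect_equal(glance(fit)$n, 18)
})

test_that("two distinct records are interpolated exactly", {
  b <- bulk_conductivity()
  rec <- tibble::tibble(
    a_angstrom = c(6, 10), b_angstrom = c(4, 5), L_angstrom = 50,
    g_pS = c(150, 700)
  )
  fit <- fit_conductivity(rec, b)
  expect_lt(fit$residual_ss, 1e-8)
  expect_equal(fit$fitted$g_fit_pS, rec$g_pS, tolerance = 1e-3)
})

test_that("degenerate or malformed training inputs are rejected", {
  b <- bulk_conductivity()
  same <- tibble::tibble(a_angstrom = 5, b_angstrom = 4, L_angstrom = 50,
                         g_pS = c(100, 110))
  expect_error(fit_conductivity(same[c(1, 1), ], b), "distinct")
  bad <- tibble::tibble(a_A = 5, b_angstrom = 4, L_angstrom = 50, g_pS = 1)
  expect_error(fit_conductivity(bad, b), "a_angstrom")
})

test_that("the fit objective beats random restarts", {
  b <- bulk_conductivity()
  truth <- conductivity_params(1.2, 5)
  rec <- simulate_conductance_records(truth, b, noise = 0.05, seed = 42)
  fit <- fit_conductivity(rec, b)
  kobs <- observed_conductivity(rec)
  ssq <- function(p) {
    pred <- plogis(rec$a_angstrom * p[1] - p[2]) *
      plogis(rec$b_angstrom * p[1] - p[2]) * b$kappa_bulk
    sum((pred - kobs)^2)
  }
  withr::with_seed(9, {
    rand <- replicate(100, ssq(c(runif(1, 0.1, 4), runif(1, 0, 12))))
  })
  expect_lte(fit$residual_ss, min(rand) + 1e-12)
})
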