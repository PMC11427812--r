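test_that("atom discs are the in-plane sphere cross-sections", {
  atoms <- discs_as_atoms(tibble::tibble(x = 0, y = 0, rho = 2), z = 0)
  expect_equal(atom_discs(atoms, 0)$rho, 2)
  expect_equal(atom_discs(atoms, 1)$rho, sqrt(3), tolerance = 1e-12)
  expect_equal(nrow(atom_discs(atoms, 2)), 0)   # |dz| = r excluded
  expect_equal(nrow(atom_discs(atoms, -2.5)), 0)
})

test_that("ellipse clearance reduces to the circular formula when a = b", {
  discs <- tibble::tibble(x = c(3, 0, -4), y = c(0, 5, 1),
                          rho = c(1, 1.5, 0.8))
  circ <- ellipse_clearance(list(x = 0, y = 0, a = 1.2, b = 1.2, theta = 0.7),
                            discs)
  expect_equal(circ, min(sqrt(discs$x^2 + discs$y^2) - 1.2 - discs$rho),
               tolerance = 1e-9)
  # on-axis disc at distance a + 3 has clearance 3 - rho
  onax <- ellipse_clearance(list(x = 0, y = 0, a = 2.5, b = 1.2, theta = 0),
                            tibble::tibble(x = 5.5, y = 0, rho = 1))
  expect_equal(onax, 2, tolerance = 1e-9)
  expect_identical(
    ellipse_clearance(list(x = 0, y = 0, a = 2, b = 1, theta = 0),
                      tibble::tibble(x = numeric(0), y = numeric(0),
                                     rho = numeric(0))),
    Inf
  )
})

test_that("ellipse clearance matches a dense boundary-sampling oracle", {
  withr::with_seed(11, {
    for (rep in 1:4) {
      a <- runif(1, 2, 6); b <- runif(1, 1, a); th <- runif(1, 0, pi)
      discs <- tibble::tibble(
        x = runif(20, -8, 8), y = runif(20, -8, 8),
        rho = runif(20, 0.5, 2)
      )
      got <- ellipse_clearance(list(x = 0.3, y = -0.2, a = a, b = b,
                                    theta = th), discs)
      ref <- sampling_ellipse_clearance(0.3, -0.2, a, b, th, discs, k = 1e6)
      expect_equal(got, ref, tolerance = 1e-4)
    }
  })
})

test_that("compiled and pure-R clearance kernels agree", {
  withr::with_seed(12, {
    for (rep in 1:10) {
      a <- runif(1, 1.5, 8); b <- runif(1, 0.8, a); th <- runif(1, 0, pi)
      discs <- tibble::tibble(x = runif(30, -10, 10), y = runif(30, -10, 10),
                              rho = runif(30, 0.3, 2))
      expect_equal(
        ellipore:::ellipse_clearance_r(0.1, 0.4, a, b, th, discs),
        ellipse_clearance(list(x = 0.1, y = 0.4, a = a, b = b, theta = th),
                          discs),
        tolerance = 1e-9
      )
    }
  })
})

test_that("an isotropic wall admits no elongation", {
  ang <- seq(0, 2 * pi, length.out = 73)[-73]
  ring <- tibble::tibble(x = 10 * cos(ang), y = 10 * sin(ang), rho = 1.85)
  sph <- tibble::tibble(z = 0, x = 0, y = 0, radius = 8.15, flag = "ok")
  es <- suppressWarnings(expand_slice(sph, ring))
  expect_equal(es$a, es$b, tolerance = 0.1)
  expect_identical(es$b, 8.15)
})

test_that("an elliptical wall yields the offset-geometry maximal ellipse", {
  t <- seq(0, 2 * pi, length.out = 401)[-401]
  ring <- tibble::tibble(x = 12 * cos(t), y = 6 * sin(t), rho = 1.85)
  sph <- tibble::tibble(z = 0, x = 0, y = 0, radius = 4.15, flag = "ok")
  es <- suppressWarnings(expand_slice(sph, ring))
  # dense-sampling offset computation gives a_max ~= 9.59 for the
  # continuous wall (plus a small bead-gap allowance)
  expect_gt(es$a, 9.45)
  expect_lt(es$a, 9.80)
  expect_lt(min(es$theta, pi - es$theta), 5 * pi / 180)
  expect_identical(es$b, 4.15)
})

test_that("a slit admits elongation along the free direction", {
  # side discs close enough that the only elongation is along x
  discs <- tibble::tibble(x = c(0, 0, 4.5, -4.5), y = c(3, -3, 0, 0),
                          rho = 1.5)
  sph <- tibble::tibble(z = 0, x = 0, y = 0, radius = 1.5, flag = "ok")
  es <- expand_slice(sph, discs)
  orc <- reference_slice_ellipse(discs, b = 1.5, half = 0.45, step = 0.05,
                                 a_hi = 8)
  expect_equal(es$a, unname(orc["a"]), tolerance = 0.1)
  expect_equal(es$a, 3.0, tolerance = 0.05)
  expect_lt(min(es$theta, pi - es$theta), 5 * pi / 180)
})

test_that("stage two never regresses below stage one", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      sl <- make_ring_slice(100 + rep)
      s <- optimize_slice(discs_as_atoms(sl$discs), 0, c(0, 0), rng_seed = rep)
      es <- suppressWarnings(expand_slice(s, sl$discs))
      st <- attr(es, "stage_a")
      expect_gte(st["stage2"], st["stage1"] - 1e-9)
      expect_gte(es$a, es$b)
      expect_gte(es$theta, 0)
      expect_lt(es$theta, pi)
      # final ellipse satisfies the clearance invariant
      expect_gte(ellipse_clearance(as.list(es), sl$discs), -1.1e-3)
    }
  })
})

test_that("rotating the slice rotates theta and preserves the radii", {
  t <- seq(0, 2 * pi, length.out = 241)[-241]
  ring <- tibble::tibble(x = 9 * cos(t), y = 5 * sin(t), rho = 1.6)
  sph <- tibble::tibble(z = 0, x = 0, y = 0, radius = 5 - 1.6, flag = "ok")
  e0 <- suppressWarnings(expand_slice(sph, ring))
  phi <- 37 * pi / 180
  rring <- tibble::tibble(x = cos(phi) * ring$x - sin(phi) * ring$y,
                          y = sin(phi) * ring$x + cos(phi) * ring$y,
                          rho = ring$rho)
  e1 <- suppressWarnings(expand_slice(sph, rring))
  dth <- (e1$theta - e0$theta - phi) %% pi
  expect_lt(min(dth, pi - dth), 2 * pi / 180)
  expect_equal(e1$a, e0$a, tolerance = 0.05)
  expect_identical(e1$b, e0$b)
})

test_that("profile expansion preserves slice structure and b identity", {
  cyl <- fixture_cylinder(length = 14)
  pr <- trace_pathway(cyl, dz = 1, end_radius = 12, rng_seed = 42)
  el <- suppressWarnings(expand_profile(pr, cyl))
  expect_equal(el$z, pr$z)
  ok <- el$flag == "ok"   # slices with atoms in their plane
  expect_identical(el$b[ok], pr$radius[ok])
  expect_true(all(el$a[ok] / el$b[ok] <= 1.05))
  expect_true(all(el$eccentricity[ok] >= 0 & el$eccentricity[ok] < 1))
  # sentinel slices are flagged and carry the termination radius
  expect_true(all(el$flag[!ok] == "open"))
  expect_true(all(el$a[!ok] == 12))
  # every slice the sphere walk kept is represented
  expect_true(all(pr$flag[!ok] %in% c("open", "empty") |
                    nrow(atom_discs(cyl, pr$z[!ok])) == 0))
})
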