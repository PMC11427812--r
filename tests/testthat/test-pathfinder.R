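test_that("clearance is the minimum over atoms of distance minus radius", {
  at <- discs_as_atoms(tibble::tibble(x = c(5, -5), y = 0, rho = 2))
  expect_equal(clearance_radius(c(0, 0, 0), at), 3)
  at1 <- discs_as_atoms(tibble::tibble(x = 0, y = 0, rho = 1.85))
  expect_equal(clearance_radius(c(0, 0, 0), at1), -1.85)

  # brute-force oracle over random configurations
  withr::with_seed(3, {
    atoms <- tibble::tibble(
      x = runif(10, -5, 5), y = runif(10, -5, 5), z = runif(10, -5, 5),
      radius = runif(10, 1, 2), mass = 12, element = "C",
      name = "C", resname = "F", resid = 1L
    )
    pts <- matrix(runif(300, -6, 6), ncol = 3)
    got <- clearance_radius(pts, atoms)
    ref <- apply(pts, 1, function(p) {
      best <- Inf
      for (i in 1:10) {
        best <- min(best, sqrt(sum((p - c(atoms$x[i], atoms$y[i], atoms$z[i]))^2)) -
                      atoms$radius[i])
      }
      best
    })
    expect_equal(got, ref, tolerance = 1e-12)
  })
})

test_that("slice optimisation finds the symmetric optimum from any seed", {
  ang <- c(0, 2 * pi / 3, 4 * pi / 3)
  ring <- discs_as_atoms(tibble::tibble(x = 5 * cos(ang), y = 5 * sin(ang),
                                        rho = 1.5))
  s <- optimize_slice(ring, 0, c(0, 0), rng_seed = 7)
  expect_lt(max(abs(c(s$x, s$y))), 1e-2)
  expect_equal(s$radius, 3.5, tolerance = 1e-2)
  expect_equal(s$flag, "ok")

  s2 <- optimize_slice(ring, 0, c(1.0, -0.8), rng_seed = 99)
  expect_equal(c(s2$x, s2$y), c(s$x, s$y), tolerance = 1e-2)
  expect_equal(s2$radius, s$radius, tolerance = 1e-2)

  # exhaustive grid agrees
  g <- reference_slice_sphere(ring, 0, half = 1.5, step = 0.01)
  expect_equal(s$radius, unname(g["radius"]), tolerance = 0.02)
})

test_that("an unbounded direction pins the optimum to the box and flags it", {
  two <- discs_as_atoms(tibble::tibble(x = c(3, -3), y = 0, rho = 1.5))
  s <- optimize_slice(two, 0, c(0, 0), rng_seed = 5, box_half = 3)
  expect_equal(s$flag, "boundary")
  expect_equal(abs(s$y), 3, tolerance = 1e-3)
  g <- reference_slice_sphere(two, 0, half = 3, step = 0.01)
  expect_equal(s$radius, unname(g["radius"]), tolerance = 0.02)
})

test_that("the traced cylinder pathway matches the analytic wall", {
  cyl <- fixture_cylinder()
  pr <- trace_pathway(cyl, dz = 1, end_radius = 15, rng_seed = 42)
  inner <- dplyr::filter(pr, abs(z) < 20)
  expect_true(all(abs(inner$radius - 8.15) < 0.05))
  # self-consistency: radius equals the clearance at the centre
  cl <- vapply(seq_len(nrow(inner)), function(i) {
    clearance_radius(c(inner$x[i], inner$y[i], inner$z[i]), cyl)
  }, numeric(1))
  expect_true(all(cl >= inner$radius - 1e-6))
  # termination: walks end with an open slice beyond the mouths
  expect_equal(pr$flag[1], "open")
  expect_equal(pr$flag[nrow(pr)], "open")
  expect_true(all(pr$radius[c(1, nrow(pr))] > 15))
})

test_that("uniformly enlarging atoms shrinks the cylinder pathway by the same amount", {
  cyl <- fixture_cylinder(length = 14)
  fat <- cyl
  fat$radius <- fat$radius + 0.3
  p0 <- trace_pathway(cyl, dz = 1, end_radius = 12, rng_seed = 1)
  p1 <- trace_pathway(fat, dz = 1, end_radius = 12, rng_seed = 1)
  z_common <- intersect(p0$z[p0$flag == "ok" & abs(p0$z) < 6],
                        p1$z[p1$flag == "ok"])
  r0 <- p0$radius[match(z_common, p0$z)]
  r1 <- p1$radius[match(z_common, p1$z)]
  expect_true(all(r1 <= r0 + 1e-9))
  expect_equal(r0 - r1, rep(0.3, length(z_common)), tolerance = 1e-3)
})

test_that("translating the structure translates the pathway rigidly", {
  cyl <- fixture_cylinder(length = 14)
  shifted <- cyl
  shifted$x <- shifted$x + 3.2
  shifted$y <- shifted$y - 1.7
  p0 <- trace_pathway(cyl, dz = 1, end_radius = 12, rng_seed = 42)
  p1 <- trace_pathway(shifted, start = attr(p0, "start") + c(3.2, -1.7, 0),
                      dz = 1, end_radius = 12, rng_seed = 42)
  # compare interior slices matched by z: past the mouths the clearance
  # landscape is flat and termination z need not coincide
  z_in <- p0$z[p0$flag == "ok" & abs(p0$z) < 6]
  i0 <- match(z_in, p0$z); i1 <- match(z_in, p1$z)
  expect_equal(p1$x[i1], p0$x[i0] + 3.2, tolerance = 1e-6)
  expect_equal(p1$y[i1], p0$y[i0] - 1.7, tolerance = 1e-6)
  expect_equal(p1$radius[i1], p0$radius[i0], tolerance = 1e-6)
})

test_that("a buried start point is a fatal error", {
  cyl <- fixture_cylinder(length = 14)
  expect_error(
    trace_pathway(cyl, start = c(10, 0, 0), dz = 1, end_radius = 12),
    "buried"
  )
})

test_that("the hourglass constriction is located at the waist", {
  hg <- build_bead_pore("hourglass", length = 30, waist = 4, slope = 0.4,
                        beads_per_ring = 144, ring_spacing = 1)
  pr <- trace_pathway(hg, dz = 1, end_radius = 12, rng_seed = 42)
  ok <- dplyr::filter(pr, flag == "ok")
  expect_lte(abs(ok$z[which.min(ok$radius)]), 1)
  expect_equal(min(ok$radius), 4 - 1.85, tolerance = 0.05)
})
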