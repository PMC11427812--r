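# Fixtures and independent oracles shared across the suite. All fixtures
# are generated in code; nothing is read from disk.

# Minimal in-plane atom set (z = 0) from disc positions.
discs_as_atoms <- function(discs, z = 0) {
  tibble::tibble(
    x = discs$x, y = discs$y, z = z,
    radius = discs$rho, mass = 12.011, element = "C",
    name = "C", resname = "FIX", resid = 1L
  )
}

# Point-symmetric jittered elliptical ring of 20 discs: the constraint set
# is symmetric under p -> -p, so the maximal-ellipse centre stays at the
# origin and a small oracle search box around the sphere centre is
# exhaustive. Walls are large and smooth (fixed disc radius, small mirrored
# radial jitter) so the in-box optimum is interior and single-basin.
make_ring_slice <- function(seed) {
  withr::with_seed(seed, {
    A <- runif(1, 5.5, 7.5)
    B <- runif(1, 3.5, 4.5)
    phi0 <- runif(1, 0, pi)
    n <- 10L
    t <- (seq_len(n) - 1 + runif(n, 0.3, 0.7)) * pi / n
    jit <- 1 + runif(n, -0.04, 0.04)   # mirrored radial jitter
    px <- A * cos(t) * jit; py <- B * sin(t) * jit
    x <- c(px, -px); y <- c(py, -py)
    ct <- cos(phi0); st <- sin(phi0)
    xr <- ct * x - st * y
    yr <- st * x + ct * y
    list(
      discs = tibble::tibble(x = xr, y = yr, rho = 1.85),
      wall = c(A = A, B = B), phi0 = phi0
    )
  })
}

# Dense sampling oracle for the signed clearance of an ellipse against
# discs: boundary sampled at `k` points (upper bound on the true minimum
# distance; error O((perimeter/k)^2)).
sampling_ellipse_clearance <- function(x, y, a, b, theta, discs,
                                       k = 1e6) {
  t <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  bx <- x + a * cos(t) * cos(theta) - b * sin(t) * sin(theta)
  by <- y + a * cos(t) * sin(theta) + b * sin(t) * cos(theta)
  best <- Inf
  ct <- cos(theta); st <- sin(theta)
  for (j in seq_len(nrow(discs))) {
    d <- sqrt(min((bx - discs$x[j])^2 + (by - discs$y[j])^2))
    rx <- discs$x[j] - x; ry <- discs$y[j] - y
    u <- ct * rx + st * ry; v <- -st * rx + ct * ry
    if ((u / a)^2 + (v / b)^2 < 1) d <- -d
    best <- min(best, d - discs$rho[j])
  }
  best
}

# Hand-built profiles for the metrics/conductance arithmetic.
make_sphere_profile <- function(z, radius, dz = diff(z[1:2])) {
  out <- tibble::tibble(z = z, x = 0, y = 0, radius = radius, flag = "ok")
  attr(out, "dz") <- dz
  class(out) <- c("sphere_profile", class(out))
  out
}

make_ellipse_profile <- function(z, a, b, theta = 0, dz = diff(z[1:2])) {
  out <- tibble::tibble(z = z, x = 0, y = 0, a = a, b = b, theta = theta,
                        eccentricity = sqrt(1 - (b / a)^2), flag = "ok")
  attr(out, "dz") <- dz
  class(out) <- c("ellipse_profile", class(out))
  out
}

# Shared small fixtures (built once per test file load).
fixture_cylinder <- function(length = 50, radius = 10, spacing = 1) {
  build_bead_pore("cylinder", length = length, radius = radius,
                  beads_per_ring = 72, ring_spacing = spacing)
}
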