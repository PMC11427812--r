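#' Build an armchair carbon nanotube
#'
#' Places carbons on the rolled-graphene lattice of an (n, n) armchair
#' tube: circumference `3 n cc`, ideal radius `3 n cc / (2 pi)`,
#' translational period `sqrt(3) cc` with `4n` carbons per period. The
#' tube axis lies on z and the structure is centred at the origin. Rim
#' carbons can be capped with axial hydrogens (C-H 1.09 A). Controlled
#' ellipticity is imposed by the area-preserving map `x -> x / sqrt(s)`,
#' `y -> y * sqrt(s)`, giving wall semi-axes `r / sqrt(s)` and
#' `r * sqrt(s)` with minor/major ratio `s`.
#'
#' @param n Chirality integer (armchair (n, n)), `n >= 4`.
#' @param length Target tube length in Angstrom; realised as the nearest
#'   whole number of lattice periods.
#' @param ratio Minor/major wall axis ratio `s` in (0, 1].
#' @param cc_bond Carbon-carbon bond length (A).
#' @param cap_hydrogens Add axial rim hydrogens.
#' @param radius_table Radius table applied to the result.
#' @return A `pore_atoms` tibble with a `ground_truth` attribute: list with
#'   `radius_ideal`, `semi_axes` (deformed wall), `ratio`, `length`
#'   (realised atom extent), `n_periods`, `n`.
#' @export
#' @examples
#' cnt <- build_cnt(8, length = 49.2)
#' attr(cnt, "ground_truth")$radius_ideal  # ~5.43 A
build_cnt <- function(n, length = 50, ratio = 1, cc_bond = 1.421,
                      cap_hydrogens = TRUE,
                      radius_table = default_radius_table()) {
  stopifnot(n == round(n), n >= 4)
  if (ratio <= 0 || ratio > 1) stop_ellipore("ratio must be in (0, 1]")
  period <- sqrt(3) * cc_bond
  if (length <= period) stop_ellipore("length must exceed one lattice period")
  n_periods <- max(1L, as.integer(round(length / period)))
  r <- 3 * n * cc_bond / (2 * pi)
  circ <- 3 * n * cc_bond

  # two armchair rows per period; x is the circumferential coordinate
  j <- rep(seq_len(n) - 1L, each = 2L)
  row0_x <- 3 * cc_bond * j + rep(c(0, cc_bond), times = n)
  row1_x <- 3 * cc_bond * j + rep(c(1.5, 2.5) * cc_bond, times = n)
  per <- rep(seq_len(n_periods) - 1L, each = 4L * n)
  xc <- rep(c(row0_x, row1_x), times = n_periods)
  zc <- per * period + rep(rep(c(0, period / 2), each = 2L * n),
                           times = n_periods)
  phi <- 2 * pi * xc / circ
  X <- r * cos(phi); Y <- r * sin(phi); Z <- zc
  element <- rep("C", length(X))

  if (cap_hydrogens) {
    bot <- which(abs(Z - min(Z)) < 1e-9)
    top <- which(abs(Z - max(Z)) < 1e-9)
    X <- c(X, X[bot], X[top])
    Y <- c(Y, Y[bot], Y[top])
    Z <- c(Z, Z[bot] - 1.09, Z[top] + 1.09)
    element <- c(element, rep("H", length(bot) + length(top)))
  }
  Z <- Z - (max(Z) + min(Z)) / 2

  s <- ratio
  X <- X / sqrt(s)
  Y <- Y * sqrt(s)

  atoms <- new_pore_atoms(tibble(
    x = X, y = Y, z = Z,
    element = element,
    name = element,
    resname = "CNT",
    resid = 1L,
    mass = element_mass(element)
  ))
  atoms <- assign_radii(atoms, radius_table)
  attr(atoms, "ground_truth") <- list(
    radius_ideal = r,
    semi_axes = c(r / sqrt(s), r * sqrt(s)),
    ratio = s,
    length = diff(range(Z)),
    carbon_length = n_periods * period,
    n_periods = n_periods,
    n = n
  )
  atoms
}

#' Build a bead-wall test pore
#'
#' Rings of beads trace a prescribed wall, giving fixtures with analytic
#' ground truth: a cylinder (constant radius), an elliptical channel
#' (constant semi-axes) or an hourglass (`radius(z) = waist + slope |z|`).
#' The inscribed pathway radius is `wall - bead_radius` up to the bead
#' discretisation error.
#'
#' @param profile `"cylinder"`, `"ellipse"` or `"hourglass"`.
#' @param length Pore length in Angstrom.
#' @param radius Wall radius (cylinder), A.
#' @param semi_axes Wall semi-axes c(A, B) (ellipse), A.
#' @param waist,slope Hourglass waist radius and cone slope.
#' @param bead_radius Van der Waals radius given to every bead (A).
#' @param beads_per_ring,ring_spacing Discretisation of the wall.
#' @return A `pore_atoms` tibble with a `ground_truth` attribute
#'   (`pathway_radius` or `semi_axes` net of the bead radius, `waist_z`
#'   for the hourglass).
#' @export
build_bead_pore <- function(profile = c("cylinder", "ellipse", "hourglass"),
                            length = 50, radius = 10, semi_axes = c(12, 6),
                            waist = 4, slope = 0.4, bead_radius = 1.85,
                            beads_per_ring = 72, ring_spacing = 1) {
  profile <- match.arg(profile)
  zs <- seq(-length / 2, length / 2, by = ring_spacing)
  ang <- seq(0, 2 * pi, length.out = beads_per_ring + 1L)[-(beads_per_ring + 1L)]
  wall <- switch(profile,
    cylinder = list(A = rep(radius, length(zs)), B = rep(radius, length(zs))),
    ellipse = list(A = rep(semi_axes[1], length(zs)),
                   B = rep(semi_axes[2], length(zs))),
    hourglass = {
      r <- waist + slope * abs(zs)
      list(A = r, B = r)
    }
  )
  if (any(pmin(wall$A, wall$B) <= bead_radius)) {
    stop_ellipore("wall radius must exceed the bead radius everywhere")
  }
  X <- as.numeric(outer(cos(ang), wall$A))
  Y <- as.numeric(outer(sin(ang), wall$B))
  Z <- rep(zs, each = length(ang))
  atoms <- new_pore_atoms(tibble(
    x = X, y = Y, z = Z,
    element = "C", name = "C", resname = "PORE", resid = 1L,
    mass = element_mass(rep("C", length(X)))
  ))
  atoms$radius <- bead_radius
  gt <- switch(profile,
    cylinder = list(pathway_radius = radius - bead_radius),
    ellipse = list(
      pathway_radius = min(semi_axes) - bead_radius,
      wall_semi_axes = semi_axes
    ),
    hourglass = list(pathway_radius = waist - bead_radius, waist_z = 0,
                     slope = slope)
  )
  gt$bead_radius <- bead_radius
  gt$profile <- profile
  attr(atoms, "ground_truth") <- gt
  atoms
}

#' Write atoms to a PDB file
#'
#' @param atoms `pore_atoms` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path) {
  n <- nrow(atoms)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(cbind(atoms$x, atoms$y, atoms$z))),
    resno = atoms$resid %||% rep(1L, n),
    resid = atoms$resname %||% rep("MOL", n),
    elety = atoms$name %||% atoms$element,
    elesy = atoms$element,
    chain = rep("A", n)
  )
  invisible(path)
}
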