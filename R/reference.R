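#' Brute-force reference searches
#'
#' Exhaustive grid searches used to validate the stochastic slice
#' optimizers on small problems. They are deliberately independent of the
#' production code paths: the sphere reference scans a 2-D grid of centres
#' with the naive clearance loop, and the ellipse reference scans centres
#' and orientations, finding the maximal feasible major semi-axis per grid
#' cell by bisection against a densely sampled ellipse boundary.
#'
#' @param atoms `pore_atoms` tibble (sphere variant).
#' @param z Slice plane (A).
#' @param centre Length-2 grid centre.
#' @param half Half-width of the centre grid (A).
#' @param step Grid resolution (A).
#' @return `reference_slice_sphere()`: named vector `x`, `y`, `radius`.
#' @export
reference_slice_sphere <- function(atoms, z, centre = c(0, 0), half = 1,
                                   step = 0.01) {
  v <- cpp_grid_sphere(atoms$x, atoms$y, atoms$z, atoms$radius, z,
                       centre[1], centre[2], half, step)
  setNames(as.numeric(v), c("x", "y", "radius"))
}

#' @rdname reference_slice_sphere
#' @param discs Disc tibble from [atom_discs()] (ellipse variant).
#' @param b Fixed minor semi-axis (A).
#' @param theta_step Orientation resolution in degrees.
#' @param a_hi Upper bound of the major semi-axis search (A).
#' @param a_tol Bisection tolerance on a (A).
#' @param m_samples Boundary sample count of the overlap test.
#' @param feas_tol Allowed residual overlap (A), matching [expand_slice()].
#' @return `reference_slice_ellipse()`: named vector `x`, `y`, `a`,
#'   `theta`.
#' @export
reference_slice_ellipse <- function(discs, b, centre = c(0, 0), half = 0.25,
                                    step = 0.05, theta_step = 2, a_hi = 12,
                                    a_tol = 1e-4, m_samples = 1440,
                                    feas_tol = 1e-3) {
  v <- cpp_grid_ellipse(discs$x, discs$y, discs$rho, b, centre[1], centre[2],
                        half, step, theta_step, a_hi, a_tol, m_samples,
                        feas_tol)
  setNames(as.numeric(v), c("x", "y", "a", "theta"))
}
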