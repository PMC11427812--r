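#' In-plane atom discs for a z slice
#'
#' Reduces each van der Waals sphere intersecting the plane `z = const` to
#' its circular cross-section: an atom at height `z_a` with radius `r`
#' contributes a disc of radius `rho = sqrt(r^2 - dz^2)` when `|dz| < r`
#' (open interval, so `rho > 0`).
#'
#' @param atoms Aligned `pore_atoms` tibble with radii.
#' @param z Plane height (A).
#' @return Tibble with columns `x`, `y`, `rho`; possibly zero rows.
#' @export
atom_discs <- function(atoms, z) {
  dz <- atoms$z - z
  sel <- abs(dz) < atoms$radius
  tibble(
    x = atoms$x[sel],
    y = atoms$y[sel],
    rho = sqrt(atoms$radius[sel]^2 - dz[sel]^2)
  )
}

# Signed distance from points (px, py) to the axis-aligned ellipse with
# semi-axes a >= b centred at the origin; negative inside. Vectorised over
# points. Safeguarded bisection on the Eberly t-parameterisation of the
# closest-point condition; absolute tolerance well below 1e-6 A.
signed_point_ellipse <- function(px, py, a, b) {
  n <- length(px)
  if (n == 0) return(numeric(0))
  pu <- abs(px); pv <- abs(py)
  out <- numeric(n)

  if (abs(a - b) < 1e-12) {  # circle
    return(sqrt(pu^2 + pv^2) - a)
  }

  E <- (pu / a)^2 + (pv / b)^2
  inside <- E < 1

  # Degenerate branch: interior points on the major axis have a closed-form
  # closest point (the generic bracket collapses when pv = 0).
  tinyv <- pv < 1e-12 & inside
  if (any(tinyv)) {
    crit <- (a^2 - b^2) / a
    pui <- pu[tinyv]
    xstar <- pmin(a^2 * pui / (a^2 - b^2), a)
    near_vertex <- pui >= crit
    d <- numeric(sum(tinyv))
    d[near_vertex] <- a - pui[near_vertex]
    if (any(!near_vertex)) {
      xs <- xstar[!near_vertex]
      ys <- b * sqrt(pmax(1 - (xs / a)^2, 0))
      d[!near_vertex] <- sqrt((pui[!near_vertex] - xs)^2 + ys^2)
    }
    out[tinyv] <- -d
  }

  gen <- !tinyv
  if (any(gen)) {
    pug <- pu[gen]; pvg <- pv[gen]; ins <- inside[gen]
    lo <- ifelse(ins, -b^2 * (1 - 1e-14) , 0)
    hi <- ifelse(ins, 0, sqrt((a * pug)^2 + (b * pvg)^2))
    # F(t) = (a*pu/(t+a^2))^2 + (b*pv/(t+b^2))^2 - 1 is decreasing on the
    # bracket; F(lo) > 0 > F(hi).
    for (i in 1:64) {
      mid <- 0.5 * (lo + hi)
      Fm <- (a * pug / (mid + a^2))^2 + (b * pvg / (mid + b^2))^2 - 1
      pos <- Fm > 0
      lo <- ifelse(pos, mid, lo)
      hi <- ifelse(pos, hi, mid)
    }
    t <- 0.5 * (lo + hi)
    xs <- a^2 * pug / (t + a^2)
    ys <- b^2 * pvg / (t + b^2)
    d <- sqrt((xs - pug)^2 + (ys - pvg)^2)
    out[gen] <- ifelse(ins, -d, d)
  }
  out
}

#' Clearance of an ellipse against atom discs
#'
#' Minimum over discs of the signed distance from the disc centre to the
#' ellipse boundary minus the disc radius; the signed distance is negative
#' when the disc centre lies inside the ellipse. With `a = b` this reduces
#' exactly to the spherical clearance per disc. Returns `Inf` for an empty
#' disc list.
#'
#' @param ellipse A list or one-row tibble with fields `x`, `y`, `a`, `b`,
#'   `theta` (radians, orientation of the major axis).
#' @param discs Tibble from [atom_discs()].
#' @return Clearance in Angstrom (possibly negative, `Inf` if no discs).
#' @export
ellipse_clearance <- function(ellipse, discs) {
  ellipse_clearance_xy(ellipse$x, ellipse$y, ellipse$a, ellipse$b,
                       ellipse$theta, discs)
}

ellipse_clearance_xy <- function(x, y, a, b, theta, discs) {
  if (nrow(discs) == 0) return(Inf)
  stopifnot(a >= b, b > 0)
  cpp_ellipse_clearance(x, y, a, b, theta, discs$x, discs$y, discs$rho)
}

# Pure-R variant of the clearance kernel, retained as an independent
# cross-check of the compiled implementation.
ellipse_clearance_r <- function(x, y, a, b, theta, discs) {
  if (nrow(discs) == 0) return(Inf)
  dx <- discs$x - x
  dy <- discs$y - y
  ct <- cos(theta); st <- sin(theta)
  u <- ct * dx + st * dy
  v <- -st * dx + ct * dy
  min(signed_point_ellipse(u, v, a, b) - discs$rho)
}
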