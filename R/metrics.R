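profile_slices <- function(profile) {
  sl <- as_tibble(profile)
  if (!("a" %in% names(sl))) {
    sl$a <- sl$radius
    sl$b <- sl$radius
  }
  sl
}

usable_slices <- function(profile) {
  sl <- profile_slices(profile)
  dplyr::filter(sl, .data$flag %in% c("ok", "boundary"),
                is.finite(.data$a), is.finite(.data$b), .data$b > 0)
}

# Maximal contiguous run of usable slices containing the global minimum of
# b: the "pore proper" integration range used by default.
default_z_range <- function(profile) {
  sl <- profile_slices(profile)
  ok <- sl$flag %in% c("ok", "boundary") & is.finite(sl$a) & is.finite(sl$b)
  if (!any(ok)) stop_ellipore("profile has no usable slices")
  imin <- which(ok)[which.min(sl$b[ok])]
  run <- cumsum(!ok)  # constant within each contiguous ok-run
  sel <- ok & run == run[imin]
  range(sl$z[sel])
}

#' Pore volume from a profile
#'
#' Stacked-slab quadrature of the cross-sectional area: each usable slice
#' contributes `pi * a * b * dz` (with `a = b = r` for a spherical
#' profile). Flagged (open/empty/buried) slices are excluded. The default
#' z range is the maximal contiguous run of usable slices containing the
#' global minimum of `b`.
#'
#' @param profile A `sphere_profile` or `ellipse_profile`.
#' @param z_range Length-2 numeric `[z_min, z_max]`, or `NULL` for the
#'   default range.
#' @param dz Slab thickness; defaults to the profile's `dz` attribute (or
#'   the median z spacing when absent).
#' @return Volume in cubic Angstrom.
#' @export
pore_volume <- function(profile, z_range = NULL, dz = NULL) {
  sl <- usable_slices(profile)
  if (is.null(z_range)) z_range <- default_z_range(profile)
  stopifnot(length(z_range) == 2)
  z_range <- sort(z_range)
  dz <- dz %||% attr(profile, "dz") %||% median(diff(sort(unique(sl$z))))
  sl <- dplyr::filter(sl, .data$z >= z_range[1] - 1e-9,
                      .data$z <= z_range[2] + 1e-9)
  if (nrow(sl) < 2) stop_ellipore("fewer than 2 usable slices in z_range")
  sum(pi * sl$a * sl$b) * dz
}

#' Summarise a pore from its spherical and ellipsoidal profiles
#'
#' @param sphere `sphere_profile` from [trace_pathway()].
#' @param ellipse `ellipse_profile` from [expand_profile()].
#' @param z_range Optional integration range; default as in [pore_volume()]
#'   (computed from the ellipsoidal profile).
#' @return One-row tibble: `z_min`, `z_max`, `volume_sphere`,
#'   `volume_ellipse`, `volume_ratio`, `min_b`, `z_min_b`, `min_a`,
#'   `z_min_a`.
#' @export
pore_summary <- function(sphere, ellipse, z_range = NULL) {
  if (is.null(z_range)) z_range <- default_z_range(ellipse)
  vs <- pore_volume(sphere, z_range)
  ve <- pore_volume(ellipse, z_range)
  el <- dplyr::filter(usable_slices(ellipse), .data$z >= z_range[1] - 1e-9,
                      .data$z <= z_range[2] + 1e-9)
  tibble(
    z_min = z_range[1], z_max = z_range[2],
    volume_sphere = vs, volume_ellipse = ve,
    volume_ratio = ve / vs,
    min_b = min(el$b), z_min_b = el$z[which.min(el$b)],
    min_a = min(el$a), z_min_a = el$z[which.min(el$a)]
  )
}

#' Effective radius of a spherocylinder cross-section
#'
#' Converts a capsule (sphere of radius `r` swept along a segment of
#' length `Lc`) into the radius of the circle with the same in-plane area
#' `pi r^2 + 2 r Lc`: `r_eff = sqrt(r^2 + 2 Lc r / pi)`. Used to compare
#' legacy capsule-based anisotropy measures with ellipse profiles.
#'
#' @param r Capsule radius (A), positive.
#' @param Lc Segment length between the two capsule centres (A),
#'   non-negative.
#' @return Effective radius in Angstrom.
#' @export
capsule_effective_radius <- function(r, Lc) {
  if (any(r <= 0) || any(Lc < 0)) {
    stop_ellipore("capsule_effective_radius: need r > 0 and Lc >= 0")
  }
  sqrt(r^2 + 2 * Lc * r / pi)
}

#' Eccentricity of an ellipse
#'
#' `e = sqrt(1 - b^2/a^2)`, zero iff the cross-section is circular.
#'
#' @param a,b Semi-axes with `a >= b > 0` (vectorised).
#' @return Eccentricity in `[0, 1)`.
#' @export
eccentricity <- function(a, b) {
  if (any(b <= 0) || any(a < b)) stop_ellipore("eccentricity: need a >= b > 0")
  sqrt(1 - (b / a)^2)
}
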