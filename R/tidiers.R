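#' Tidy a conductivity fit
#'
#' @param x `conductivity_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @method tidy conductivity_fit
#' @export
tidy.conductivity_fit <- function(x, ...) {
  tibble(term = c("c1", "c2"),
         estimate = c(x$params$c1, x$params$c2),
         unit = c("1/Angstrom", "1"))
}

#' @rdname tidy.conductivity_fit
#' @method glance conductivity_fit
#' @export
glance.conductivity_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, residual_ss = x$residual_ss,
         n = x$n, convergence = x$convergence)
}

#' Tidy a conductance estimate
#'
#' @param x `conductance_estimate`.
#' @param ... Unused.
#' @return Per-slice resistance decomposition tibble.
#' @method tidy conductance_estimate
#' @export
tidy.conductance_estimate <- function(x, ...) {
  dplyr::mutate(x$slices, variant = x$variant)
}

#' @rdname tidy.conductance_estimate
#' @method glance conductance_estimate
#' @export
glance.conductance_estimate <- function(x, ...) {
  tibble(variant = x$variant, R_ohm = x$R_ohm, g_pS = x$g_pS,
         n_slices = nrow(x$slices))
}

#' Tidy a pore analysis
#'
#' @param x `pore_analysis`.
#' @param ... Unused.
#' @return The ellipsoidal profile joined with the spherical radius, one
#'   row per slice.
#' @method tidy pore_analysis
#' @export
tidy.pore_analysis <- function(x, ...) {
  sph <- dplyr::select(as_tibble(x$sphere_profile), "z",
                       radius_sphere = "radius")
  dplyr::left_join(as_tibble(x$ellipse_profile), sph, by = "z")
}

#' @rdname tidy.pore_analysis
#' @method glance pore_analysis
#' @export
glance.pore_analysis <- function(x, ...) {
  out <- x$summary
  for (nm in names(x$conductance)) {
    out[[paste0("g_", gsub("-", "_", nm), "_pS")]] <- x$conductance[[nm]]$g_pS
  }
  out
}
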