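#' Bulk conductivity of a KCl solution
#'
#' Nernst-Einstein form: `kappa = q_e^2 * n * (D_K + D_Cl) / (k_B * T)`
#' with `n` the ion-pair number density (`c * N_A * 1e3` per cubic metre).
#' Defaults reflect 0.15 M KCl at 300 K with literature diffusion
#' coefficients for potassium and chloride.
#'
#' @param conc Salt concentration in mol/L.
#' @param temperature Temperature in K (> 0).
#' @param D_K,D_Cl Ion diffusion coefficients in m^2/s (> 0).
#' @return A `bulk_conductivity` list: `kappa_bulk` (S/m), `rho_bulk`
#'   (Ohm m) and the input fields.
#' @export
#' @examples
#' bulk_conductivity()$kappa_bulk  # ~2.23 S/m
bulk_conductivity <- function(conc = 0.15, temperature = 300,
                              D_K = 1.96e-9, D_Cl = 2.03e-9) {
  if (temperature <= 0) stop_ellipore("temperature must be positive")
  if (conc < 0 || D_K <= 0 || D_Cl <= 0) {
    stop_ellipore("need conc >= 0 and positive diffusivities")
  }
  n_density <- conc * .const$N_A * 1e3  # 1/m^3
  kappa <- .const$q_e^2 * n_density * (D_K + D_Cl) / (.const$k_B * temperature)
  structure(
    list(kappa_bulk = kappa,
         rho_bulk = if (kappa > 0) 1 / kappa else Inf,
         conc = conc, temperature = temperature, D_K = D_K, D_Cl = D_Cl),
    class = "bulk_conductivity"
  )
}

#' Parameters of the double-sigmoid conductivity model
#'
#' @param c1 Sigmoid steepness in 1/A; must be positive for conductivity to
#'   increase with radius (a warning is raised otherwise).
#' @param c2 Dimensionless offset.
#' @return A `conductivity_params` list.
#' @export
conductivity_params <- function(c1, c2) {
  stopifnot(is.numeric(c1), is.numeric(c2))
  if (c1 <= 0) warn("c1 <= 0: conductivity will not increase with radius")
  structure(list(c1 = c1, c2 = c2), class = "conductivity_params")
}

#' Radius-dependent conductivity
#'
#' Double-sigmoid model
#' `kappa(a, b) = sigma(a c1 - c2) * sigma(b c1 - c2) * kappa_bulk` with
#' `sigma` the logistic function: ions confined by small radii have
#' reduced mobility, and `kappa -> kappa_bulk` as both radii grow.
#'
#' @param a,b Ellipse semi-axes in Angstrom (vectorised, > 0).
#' @param params `conductivity_params`.
#' @param bulk `bulk_conductivity`.
#' @return Conductivity in S/m, strictly between 0 and `kappa_bulk`.
#' @export
conductivity_model <- function(a, b, params, bulk) {
  stopifnot(inherits(params, "conductivity_params"),
            inherits(bulk, "bulk_conductivity"))
  if (any(a <= 0) || any(b <= 0)) stop_ellipore("radii must be positive")
  plogis(a * params$c1 - params$c2) * plogis(b * params$c1 - params$c2) *
    bulk$kappa_bulk
}

#' Channel resistance and conductance from a pore profile
#'
#' Stacked-cylinder Ohmic model: each usable slice is a slab of thickness
#' `dz` and elliptical area `pi a b`, contributing
#' `dz / (kappa_i * pi * a_i * b_i)` to the series resistance. With
#' `params = NULL` the bulk conductivity is used for every slice
#' (recovering the classic spherical-probe estimate when `a = b = r`);
#' otherwise the double-sigmoid model sets a per-slice conductivity.
#'
#' @param profile `sphere_profile` or `ellipse_profile` (or any tibble with
#'   columns `z` and either `radius` or `a`, `b`).
#' @param bulk `bulk_conductivity`.
#' @param params Optional `conductivity_params`.
#' @param z_range Optional integration range, as in [pore_volume()]; by
#'   default all usable slices are integrated.
#' @param dz Slab thickness (A); defaults to the profile `dz` attribute or
#'   the median z spacing.
#' @return A `conductance_estimate`: list with `R_ohm`, `g_pS`, `variant`
#'   and a per-slice tibble `slices` (columns `z`, `dz`, `a`, `b`, `kappa`,
#'   `kappa_ratio`, `R_slice`).
#' @export
channel_resistance <- function(profile, bulk, params = NULL,
                               z_range = NULL, dz = NULL) {
  stopifnot(inherits(bulk, "bulk_conductivity"))
  sl <- profile_slices(profile)
  if (!"flag" %in% names(sl)) sl$flag <- "ok"
  sl <- dplyr::filter(sl, .data$flag %in% c("ok", "boundary"),
                      is.finite(.data$a), is.finite(.data$b))
  if (!is.null(z_range)) {
    z_range <- sort(z_range)
    sl <- dplyr::filter(sl, .data$z >= z_range[1] - 1e-9,
                        .data$z <= z_range[2] + 1e-9)
  }
  if (nrow(sl) < 2) stop_ellipore("need at least 2 usable slices")
  bad <- which(sl$a <= 0 | sl$b <= 0)
  if (length(bad)) {
    stop_ellipore(sprintf(
      "nonpositive radius at slice %d (z = %.3f A)", bad[1], sl$z[bad[1]]
    ))
  }
  dz <- dz %||% attr(profile, "dz") %||% median(diff(sort(unique(sl$z))))
  kappa <- if (is.null(params)) {
    rep(bulk$kappa_bulk, nrow(sl))
  } else {
    conductivity_model(sl$a, sl$b, params, bulk)
  }
  # dz and radii in A; R_slice = (dz m) / (kappa * pi * a * b m^2)
  R_slice <- (dz * .ang) / (kappa * pi * sl$a * sl$b * .ang^2)
  R <- sum(R_slice)
  spherical <- !("theta" %in% names(profile_slices(profile))) &&
    ("radius" %in% names(profile_slices(profile)))
  variant <- paste0(if (spherical) "spherical" else "ellipsoidal",
                    "-", if (is.null(params)) "bulk" else "model")
  structure(
    list(
      R_ohm = R,
      g_pS = 1e12 / R,
      variant = variant,
      slices = tibble(z = sl$z, dz = dz, a = sl$a, b = sl$b,
                      kappa = kappa, kappa_ratio = kappa / bulk$kappa_bulk,
                      R_slice = R_slice),
      bulk = bulk, params = params
    ),
    class = "conductance_estimate"
  )
}

#' @export
print.conductance_estimate <- function(x, ...) {
  cat(sprintf("<conductance_estimate> %s\n", x$variant))
  cat(sprintf("  R = %.4g Ohm, g = %.4g pS over %d slices\n",
              x$R_ohm, x$g_pS, nrow(x$slices)))
  invisible(x)
}

validate_records <- function(records) {
  required <- c("a_angstrom", "b_angstrom", "L_angstrom", "g_pS")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop_ellipore(sprintf(
      "training records lack column(s): %s", paste(missing, collapse = ", ")
    ), class = "ellipore_schema_error")
  }
  with(records, {
    if (any(b_angstrom <= 0) || any(a_angstrom < b_angstrom) ||
        any(L_angstrom <= 0) || any(g_pS < 0)) {
      stop_ellipore("training records must satisfy a >= b > 0, L > 0, g >= 0")
    }
  })
  as_tibble(records)
}

#' Observed confined conductivity of a training record
#'
#' Inverts the single-cylinder conductance relation:
#' `kappa_obs = g * L / (pi * a * b)` with unit conversion from (pS, A) to
#' S/m (factor 0.01).
#'
#' @param records Tibble with columns `a_angstrom`, `b_angstrom`,
#'   `L_angstrom`, `g_pS`.
#' @return Numeric vector of conductivities in S/m.
#' @export
observed_conductivity <- function(records) {
  records <- validate_records(records)
  0.01 * records$g_pS * records$L_angstrom /
    (pi * records$a_angstrom * records$b_angstrom)
}

#' Fit the double-sigmoid conductivity parameters
#'
#' Converts each training conductance into an observed conductivity via
#' [observed_conductivity()] and least-squares fits `(c1, c2)` by
#' Nelder-Mead from a 3 x 3 grid of starting points (the two-parameter
#' surface can be flat for wide pores). Reports the residual sum of
#' squares on conductivity and the R-squared between predicted and
#' observed conductances.
#'
#' @param records Training records tibble (see [observed_conductivity()]).
#' @param bulk `bulk_conductivity` of the training condition.
#' @param starts Data frame of starting values with columns `c1`, `c2`.
#' @return A `conductivity_fit`: `params` (`conductivity_params`),
#'   `residual_ss` (S/m)^2, `r_squared`, `fitted` tibble, `n`.
#' @export
fit_conductivity <- function(records, bulk,
                             starts = expand.grid(c1 = c(0.5, 1, 2),
                                                  c2 = c(2, 4, 8))) {
  records <- validate_records(records)
  key <- paste(records$a_angstrom, records$b_angstrom)
  if (length(unique(key)) < 2) {
    stop_ellipore("need >= 2 records with distinct (a, b) for a 2-parameter fit",
                  class = "ellipore_singular_fit")
  }
  kappa_obs <- observed_conductivity(records)
  a <- records$a_angstrom; b <- records$b_angstrom
  kb <- bulk$kappa_bulk
  ssq <- function(p) {
    pred <- plogis(a * p[1] - p[2]) * plogis(b * p[1] - p[2]) * kb
    sum((pred - kappa_obs)^2)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- optim(c(starts$c1[i], starts$c2[i]), ssq, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 3000))
    # restart once from the incumbent to tighten convergence
    o <- optim(o$par, ssq, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 3000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (best$par[1] <= 0) {
    warn(sprintf("fitted c1 = %.4g <= 0: conductivity not increasing in radius",
                 best$par[1]))
  }
  params <- structure(list(c1 = best$par[1], c2 = best$par[2]),
                      class = "conductivity_params")
  kappa_fit <- plogis(a * params$c1 - params$c2) *
    plogis(b * params$c1 - params$c2) * kb
  g_obs <- records$g_pS
  g_fit <- 100 * kappa_fit * pi * a * b / records$L_angstrom
  ss_res <- sum((g_obs - g_fit)^2)
  ss_tot <- sum((g_obs - mean(g_obs))^2)
  structure(
    list(
      params = params,
      residual_ss = best$value,
      r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
      fitted = tibble(
        a_angstrom = a, b_angstrom = b, L_angstrom = records$L_angstrom,
        g_pS = g_obs, g_fit_pS = g_fit,
        kappa_obs = kappa_obs, kappa_fit = kappa_fit
      ),
      bulk = bulk,
      n = nrow(records),
      convergence = best$convergence
    ),
    class = "conductivity_fit"
  )
}

#' @export
print.conductivity_fit <- function(x, ...) {
  cat("<conductivity_fit>\n")
  cat(sprintf("  c1 = %.4f 1/A, c2 = %.4f (n = %d)\n",
              x$params$c1, x$params$c2, x$n))
  cat(sprintf("  residual SS (kappa) = %.4g, R^2 (g) = %.4f\n",
              x$residual_ss, x$r_squared))
  invisible(x)
}

#' The 18-system nanotube training design
#'
#' Six circular pore radii crossed with axis ratios 1, 3/4 and 1/2 at a
#' fixed 50 A length; the elliptical deformation preserves the
#' cross-sectional area, so `a = r / sqrt(s)` and `b = r * sqrt(s)`.
#'
#' @param radii Circular pore radii in Angstrom.
#' @param ratios Minor/major axis ratios in (0, 1].
#' @param length Pore length in Angstrom.
#' @return Records tibble (without conductances).
#' @export
cnt_training_design <- function(radii = c(3.4, 4.7, 5.9, 7.0, 8.3, 9.8),
                                ratios = c(1, 0.75, 0.5), length = 50) {
  grid <- tidyr::expand_grid(r = radii, s = ratios)
  tibble(
    a_angstrom = grid$r / sqrt(grid$s),
    b_angstrom = grid$r * sqrt(grid$s),
    L_angstrom = length,
    ratio = grid$s
  )
}

#' Simulate training conductances from known model parameters
#'
#' Generates `g = kappa(a, b) * pi * a * b / L` (in pS) on a design grid,
#' optionally with multiplicative Gaussian noise, for parameter-recovery
#' studies of [fit_conductivity()].
#'
#' @param params True `conductivity_params`.
#' @param bulk `bulk_conductivity`.
#' @param design Design tibble from [cnt_training_design()].
#' @param noise Multiplicative noise standard deviation (e.g. 0.05 for 5%).
#' @param seed RNG seed used when `noise > 0`.
#' @return Records tibble with column `g_pS`.
#' @export
simulate_conductance_records <- function(params, bulk,
                                         design = cnt_training_design(),
                                         noise = 0, seed = 1L) {
  kappa <- conductivity_model(design$a_angstrom, design$b_angstrom,
                              params, bulk)
  g <- 100 * kappa * pi * design$a_angstrom * design$b_angstrom /
    design$L_angstrom
  if (noise > 0) {
    g <- with_local_seed(seed, g * (1 + rnorm(length(g), sd = noise)))
    g <- pmax(g, 0)
  }
  out <- design
  out$g_pS <- g
  out
}
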