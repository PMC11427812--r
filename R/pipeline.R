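#' Full pore analysis pipeline
#'
#' Align -> spherical trace -> ellipsoidal expansion -> summary ->
#' conductance. Accepts a PDB path or an in-memory `pore_atoms` tibble.
#' Conductance is estimated with the bulk-conductivity variant for both
#' profiles, plus the double-sigmoid model variants when `params` is
#' supplied.
#'
#' @param input PDB file path or `pore_atoms` tibble (radii assigned).
#' @param align Align the principal axis to z first (default TRUE).
#' @param start Optional pathway start point (length 3, A).
#' @param dz Slice spacing (A).
#' @param end_radius Termination radius (A).
#' @param rng_seed Integer seed for the per-slice annealing.
#' @param radius_table Radius table used when `input` is a path.
#' @param bulk `bulk_conductivity` for the conductance heuristic.
#' @param params Optional `conductivity_params`.
#' @param z_range Optional integration range for volumes/conductance.
#' @param sa_steps Annealing proposals per slice.
#' @return A `pore_analysis` list: `atoms`, `transform`, `sphere_profile`,
#'   `ellipse_profile`, `summary` (tibble), `conductance` (named list of
#'   `conductance_estimate`s), `config`.
#' @export
analyze_pore <- function(input, align = TRUE, start = NULL, dz = 0.25,
                         end_radius = 15, rng_seed = 42L,
                         radius_table = default_radius_table(),
                         bulk = bulk_conductivity(), params = NULL,
                         z_range = NULL, sa_steps = 500L) {
  atoms <- if (is.character(input)) {
    read_structure(input, radius_table = radius_table)
  } else {
    input
  }
  if (!"radius" %in% names(atoms) || anyNA(atoms$radius)) {
    atoms <- assign_radii(atoms, radius_table)
  }
  transform <- NULL
  if (align) {
    al <- align_principal_axis(atoms)
    atoms <- al$atoms
    transform <- al$transform
  }
  sphere <- trace_pathway(atoms, start = start, dz = dz,
                          end_radius = end_radius, rng_seed = rng_seed,
                          sa_steps = sa_steps)
  ellipse <- expand_profile(sphere, atoms, end_radius = end_radius)
  summ <- pore_summary(sphere, ellipse, z_range = z_range)
  cond <- list(
    `spherical-bulk` = channel_resistance(sphere, bulk, NULL, z_range = z_range),
    `ellipsoidal-bulk` = channel_resistance(ellipse, bulk, NULL, z_range = z_range)
  )
  if (!is.null(params)) {
    cond$`spherical-model` <-
      channel_resistance(sphere, bulk, params, z_range = z_range)
    cond$`ellipsoidal-model` <-
      channel_resistance(ellipse, bulk, params, z_range = z_range)
  }
  config <- list(
    input = if (is.character(input)) input else "<in-memory atoms>",
    align = align, start = start, dz = dz, end_radius = end_radius,
    rng_seed = rng_seed, sa_steps = sa_steps,
    conc = bulk$conc, temperature = bulk$temperature,
    D_K = bulk$D_K, D_Cl = bulk$D_Cl,
    c1 = params$c1 %||% NA_real_, c2 = params$c2 %||% NA_real_,
    z_range = z_range
  )
  config$hash <- config_hash(config)
  structure(
    list(atoms = atoms, transform = transform, sphere_profile = sphere,
         ellipse_profile = ellipse, summary = summ, conductance = cond,
         config = config),
    class = "pore_analysis"
  )
}

#' @export
print.pore_analysis <- function(x, ...) {
  cat("<pore_analysis>\n")
  cat(sprintf("  %d atoms, %d slices (dz = %.3g A)\n",
              nrow(x$atoms), nrow(x$sphere_profile), x$config$dz))
  s <- x$summary
  cat(sprintf("  pore z range [%.1f, %.1f] A, min b = %.2f A at z = %.1f\n",
              s$z_min, s$z_max, s$min_b, s$z_min_b))
  cat(sprintf("  volumes: sphere %.1f A^3, ellipse %.1f A^3 (ratio %.2f)\n",
              s$volume_sphere, s$volume_ellipse, s$volume_ratio))
  for (nm in names(x$conductance)) {
    cat(sprintf("  g[%s] = %.1f pS\n", nm, x$conductance[[nm]]$g_pS))
  }
  invisible(x)
}

#' Ensemble conductance over structure frames
#'
#' Runs [analyze_pore()] on each frame and reports the mean and standard
#' deviation of the conductance estimates and pore volumes across frames,
#' the standard way to attach an uncertainty to the heuristic.
#'
#' @param inputs List (length >= 2) of PDB paths or `pore_atoms` tibbles
#'   with identical atom counts.
#' @param ... Passed to [analyze_pore()].
#' @return A `pore_ensemble` list: `frames` tibble (one row per frame with
#'   volumes and conductances) and `summary` tibble of means and sds.
#' @export
ensemble_conductance <- function(inputs, ...) {
  if (!is.list(inputs) || length(inputs) < 2) {
    stop_ellipore("ensemble requires a list of at least 2 frames")
  }
  analyses <- purrr::map(inputs, analyze_pore, ...)
  counts <- purrr::map_int(analyses, ~ nrow(.x$atoms))
  if (length(unique(counts)) != 1) {
    stop_ellipore("frames have inconsistent atom counts")
  }
  frames <- purrr::imap_dfr(analyses, function(a, i) {
    row <- tibble(
      frame = i,
      volume_sphere = a$summary$volume_sphere,
      volume_ellipse = a$summary$volume_ellipse
    )
    for (nm in names(a$conductance)) {
      row[[paste0("g_", gsub("-", "_", nm), "_pS")]] <- a$conductance[[nm]]$g_pS
    }
    row
  })
  num <- dplyr::select(frames, -"frame")
  summary <- tibble(
    quantity = names(num),
    mean = purrr::map_dbl(num, mean),
    sd = purrr::map_dbl(num, sd)
  )
  structure(list(frames = frames, summary = summary, n = length(inputs)),
            class = "pore_ensemble")
}

#' @export
print.pore_ensemble <- function(x, ...) {
  cat(sprintf("<pore_ensemble> %d frames\n", x$n))
  print(x$summary)
  invisible(x)
}

#' Read conductance training records from CSV
#'
#' Expects the columns `a_angstrom`, `b_angstrom`, `L_angstrom`, `g_pS`;
#' raises a schema error naming any missing column.
#'
#' @param path CSV file path.
#' @return Validated records tibble.
#' @export
read_conductance_records <- function(path) {
  if (!file.exists(path)) stop_ellipore(sprintf("records file not found: %s", path))
  validate_records(readr::read_csv(path, show_col_types = FALSE))
}

#' Write a profile to CSV
#'
#' Spherical profiles get columns `z, x, y, radius, flag`; ellipsoidal
#' profiles `z, x, y, a, b, theta_deg, eccentricity, flag`. A JSON sidecar
#' (`<path>.meta.json`) records dz, seed, termination radius and the
#' config hash, so outputs are reproducible byte for byte.
#'
#' @param profile `sphere_profile` or `ellipse_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  df <- as_tibble(profile)
  if ("theta" %in% names(df)) {
    df <- dplyr::mutate(df, theta_deg = .data$theta * 180 / pi)
    df <- dplyr::select(df, "z", "x", "y", "a", "b", "theta_deg",
                        "eccentricity", "flag")
  } else {
    df <- dplyr::select(df, "z", "x", "y", "radius", "flag")
  }
  readr::write_csv(df, path)
  meta <- list(
    dz = attr(profile, "dz"),
    end_radius = attr(profile, "end_radius"),
    rng_seed = attr(profile, "rng_seed"),
    start = attr(profile, "start"),
    n_slices = nrow(df)
  )
  meta$hash <- config_hash(meta)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
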