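#' Clearance radius of a point against the atom set
#'
#' The clearance is the largest sphere radius a probe centred at `point`
#' can take without overlapping any atom's van der Waals sphere:
#' `min_i ( |point - centre_i| - radius_i )`. It is negative when the point
#' lies inside an atom.
#'
#' @param point Numeric length-3 vector, or an n x 3 matrix of points (A).
#' @param atoms `pore_atoms` tibble with `radius` assigned.
#' @return Numeric clearance(s) in Angstrom.
#' @export
clearance_radius <- function(point, atoms) {
  if (nrow(atoms) == 0) stop_ellipore("clearance_radius: empty atom set")
  if (is.matrix(point)) {
    clearance_field(point[, 1], point[, 2], point[, 3], atoms)
  } else {
    stopifnot(length(point) == 3)
    clearance_field(point[1], point[2], point[3], atoms)
  }
}

# Single points vectorise over atoms; point batches loop over atoms with
# vectorised point arithmetic.
clearance_field <- function(px, py, pz, atoms) {
  ax <- atoms$x; ay <- atoms$y; az <- atoms$z; ar <- atoms$radius
  if (length(px) == 1L) {
    return(min(sqrt((px - ax)^2 + (py - ay)^2 + (pz - az)^2) - ar))
  }
  best <- rep(Inf, length(px))
  for (i in seq_along(ax)) {
    d <- sqrt((px - ax[i])^2 + (py - ay[i])^2 + (pz - az[i])^2) - ar[i]
    best <- pmin(best, d)
  }
  best
}

# Atoms whose spheres can influence clearance values up to `reach` around
# plane z. Anything further can only yield clearances beyond the
# termination radius, which the walk treats as open anyway.
slab_atoms <- function(atoms, z, reach) {
  rmax <- max(atoms$radius)
  sel <- abs(atoms$z - z) <= reach + rmax
  atoms[sel, , drop = FALSE]
}

#' Maximise the spherical probe in one z slice
#'
#' Runs Monte Carlo simulated annealing over in-plane positions, followed
#' by a Nelder-Mead polish, to find the centre that maximises
#' [clearance_radius()] in the plane `z = const`. Deterministic for a given
#' `rng_seed`.
#'
#' @param atoms Aligned `pore_atoms` tibble.
#' @param z Plane height (A).
#' @param seed_xy In-plane starting point, numeric length 2.
#' @param rng_seed Integer seed for the annealing proposals.
#' @param end_radius Radii beyond this value terminate the pathway walk;
#'   slices that reach it are flagged `"open"`.
#' @param box_half Half-width of the in-plane search box around `seed_xy`
#'   (A). The probe search is local by construction (the pathway walk
#'   re-seeds each slice from the previous optimum), so the box keeps the
#'   probe from escaping through wall gaps; optima on the box edge are
#'   flagged `"boundary"`.
#' @param sa_steps Number of annealing proposals.
#' @return One-row tibble with `z`, `x`, `y`, `radius`, `flag`
#'   (`"ok"`, `"open"`, `"boundary"` or `"empty"`).
#' @export
optimize_slice <- function(atoms, z, seed_xy, rng_seed = 42L,
                           end_radius = 15, box_half = 3,
                           sa_steps = 500L) {
  stopifnot(all(is.finite(seed_xy)), length(seed_xy) == 2)
  local <- slab_atoms(atoms, z, end_radius)
  if (nrow(local) == 0) {
    return(tibble(z = z, x = seed_xy[1], y = seed_xy[2],
                  radius = Inf, flag = "empty"))
  }
  lo <- seed_xy - box_half
  hi <- seed_xy + box_half
  f <- function(p) clearance_field(p[1], p[2], z, local)

  best <- with_local_seed(rng_seed, {
    pos <- seed_xy
    cur <- f(pos)
    bpos <- pos; bval <- cur
    step <- 0.5
    temp <- 0.5
    step_decay <- 0.99
    temp_decay <- (0.005 / 0.5)^(1 / max(sa_steps - 1, 1))
    for (k in seq_len(sa_steps)) {
      prop <- clamp(pos + rnorm(2, sd = step), lo, hi)
      val <- f(prop)
      if (val > cur || runif(1) < exp((val - cur) / temp)) {
        pos <- prop; cur <- val
        if (val > bval) { bpos <- pos; bval <- val }
      }
      step <- step * step_decay
      temp <- temp * temp_decay
    }
    list(pos = bpos, val = bval)
  })

  # derivative-free local polish from both the annealing optimum and the
  # seed (the annealing walk can drift off the seed's basin), clamped to
  # the search box; optimising the displacement keeps the polish
  # translation equivariant (the initial simplex does not depend on
  # absolute position)
  polish <- function(from) {
    opt <- optim(c(0, 0), function(p) -f(clamp(from + p, lo, hi)),
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 500))
    pos <- clamp(from + opt$par, lo, hi)
    list(pos = pos, val = f(pos))
  }
  cand <- list(polish(best$pos), polish(seed_xy), best)
  pick <- which.max(vapply(cand, `[[`, numeric(1), "val"))
  ppos <- cand[[pick]]$pos
  pval <- cand[[pick]]$val

  flag <- "ok"
  if (pval > end_radius) flag <- "open"
  else if (any(abs(ppos - lo) < 1e-3) || any(abs(ppos - hi) < 1e-3)) flag <- "boundary"
  tibble(z = z, x = ppos[1], y = ppos[2], radius = pval, flag = flag)
}

#' Trace the spherical pore pathway
#'
#' Walks parallel xy planes outward from a start point (default: centre of
#' mass), maximising the probe in each plane and seeding each slice with
#' the previous slice's optimum. A direction terminates when the slice
#' radius exceeds `end_radius` or no atoms remain near the plane.
#'
#' @param atoms Aligned `pore_atoms` tibble with radii.
#' @param start Length-3 starting point; default mass-weighted centre of mass.
#' @param dz Slice spacing (A).
#' @param end_radius Termination radius (A).
#' @param rng_seed Integer; each slice uses a seed derived from it.
#' @param box_half Search box half-width per slice (A).
#' @param sa_steps Annealing proposals per slice.
#' @param max_steps Safety cap on slices per direction.
#' @return A `sphere_profile` tibble (columns `z`, `x`, `y`, `radius`,
#'   `flag`), ordered by z, with attributes `dz`, `start`, `end_radius`,
#'   `rng_seed`.
#' @export
trace_pathway <- function(atoms, start = NULL, dz = 0.25, end_radius = 15,
                          rng_seed = 42L, box_half = 3,
                          sa_steps = 500L, max_steps = 4000L) {
  stopifnot(dz > 0, end_radius > 0)
  if (is.null(start)) {
    m <- atoms$mass %||% rep(1, nrow(atoms))
    start <- c(
      weighted.mean(atoms$x, m),
      weighted.mean(atoms$y, m),
      weighted.mean(atoms$z, m)
    )
  }
  stopifnot(length(start) == 3, all(is.finite(start)))

  slice_at <- function(z, seed_xy, k) {
    optimize_slice(atoms, z, seed_xy, rng_seed = rng_seed + k,
                   end_radius = end_radius, box_half = box_half,
                   sa_steps = sa_steps)
  }
  start_clear <- clearance_radius(start, atoms)
  s0 <- slice_at(start[3], start[1:2], 0L)
  if (start_clear < 0) {
    stop_ellipore(paste0(
      "start point is buried (negative clearance at the starting slice); ",
      "supply `start` manually inside the pore lumen"
    ))
  }
  walk <- function(dir, offset) {
    out <- list()
    seed_xy <- c(s0$x, s0$y)
    for (k in seq_len(max_steps)) {
      zk <- start[3] + dir * k * dz
      sl <- slice_at(zk, seed_xy, offset + k)
      out[[k]] <- sl
      if (sl$flag %in% c("open", "empty")) break
      seed_xy <- c(sl$x, sl$y)
    }
    dplyr::bind_rows(out)
  }
  up <- walk(+1, 0L)
  down <- walk(-1, 1000000L)
  prof <- dplyr::arrange(dplyr::bind_rows(down, s0, up), .data$z)
  attr(prof, "dz") <- dz
  attr(prof, "start") <- start
  attr(prof, "end_radius") <- end_radius
  attr(prof, "rng_seed") <- rng_seed
  class(prof) <- c("sphere_profile", class(prof))
  prof
}
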