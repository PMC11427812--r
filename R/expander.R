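#' Inflate one spherical probe into a maximal in-plane ellipse
#'
#' Starting from the circle `a = b = r` at the sphere centre, runs two
#' stages of Nelder-Mead optimisation over `(x, y, a, theta)` with the
#' minor semi-axis `b` held fixed at the spherical radius. The objective
#' maximises `a` with a quadratic penalty on van der Waals overlap; each
#' stage's result is made feasible by shrinking `a` until the clearance is
#' within tolerance, and the stage with the larger feasible `a` is
#' returned (so stage 2 never regresses below stage 1). Stage 1 uses tight
#' bounds (`|dx|,|dy| <= b/2`, `a <= 2b`), stage 2 wider ones
#' (`|dx|,|dy| <= 2b`, `a <= min(8b, end_radius)`).
#'
#' @param sphere One-row tibble from [optimize_slice()].
#' @param discs Disc tibble from [atom_discs()] for the same plane.
#' @param end_radius Cap on the major semi-axis (A).
#' @param penalty Overlap penalty coefficient (1/A).
#' @param feas_tol Allowed residual overlap (A).
#' @return One-row tibble with `z`, `x`, `y`, `a`, `b`, `theta` (radians in
#'   `[0, pi)`), `eccentricity`, `flag`; attribute `stage_a` records the
#'   feasible major semi-axis after each stage.
#' @export
expand_slice <- function(sphere, discs, end_radius = 15,
                         penalty = 1e4, feas_tol = 1e-3) {
  z <- sphere$z
  if (sphere$flag %in% c("open", "empty") || !is.finite(sphere$radius) ||
      nrow(discs) == 0) {
    return(tibble(z = z, x = sphere$x, y = sphere$y,
                  a = end_radius, b = end_radius, theta = 0,
                  eccentricity = 0, flag = "open"))
  }
  b <- sphere$radius
  if (b <= 0) {
    return(tibble(z = z, x = sphere$x, y = sphere$y, a = b, b = b,
                  theta = 0, eccentricity = 0, flag = "buried"))
  }
  x0 <- sphere$x; y0 <- sphere$y

  # The sphere is optimal against 3-D atom spheres, but the ellipse is
  # constrained by the in-plane discs - a strictly stronger condition when
  # the binding atoms sit out of plane. If the starting circle violates
  # the disc constraints, relocate the centre to the best disc-feasible
  # point nearby before any elongation is attempted.
  cx <- x0; cy <- y0
  circle_clear <- function(x, y) {
    ellipse_clearance_xy(clamp(x, x0 - 2 * b, x0 + 2 * b),
                         clamp(y, y0 - 2 * b, y0 + 2 * b), b, b, 0, discs)
  }
  if (circle_clear(x0, y0) < -feas_tol) {
    offs <- c(-b, -b / 2, 0, b / 2, b)
    grid0 <- expand.grid(dx = offs, dy = offs)
    v <- vapply(seq_len(nrow(grid0)), function(i) {
      circle_clear(x0 + grid0$dx[i], y0 + grid0$dy[i])
    }, numeric(1))
    gi <- which.max(v)
    o <- optim(c(x0 + grid0$dx[gi], y0 + grid0$dy[gi]),
               function(p) -circle_clear(p[1], p[2]),
               method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10,
                              parscale = c(0.25 * b, 0.25 * b)))
    if (-o$value >= -feas_tol) {
      cx <- clamp(o$par[1], x0 - 2 * b, x0 + 2 * b)
      cy <- clamp(o$par[2], y0 - 2 * b, y0 + 2 * b)
    }
  }

  run_stage <- function(par, dmax, amax) {
    clamp_par <- function(p) c(
      clamp(p[1], cx - dmax, cx + dmax),
      clamp(p[2], cy - dmax, cy + dmax),
      clamp(p[3], b, amax),
      p[4]
    )
    obj <- function(p) {
      p <- clamp_par(p)
      cl <- ellipse_clearance_xy(p[1], p[2], p[3], b, p[4], discs)
      -(p[3] - penalty * max(0, -cl)^2)
    }
    opt <- optim(par, obj, method = "Nelder-Mead",
                 control = list(
                   maxit = 600, reltol = 1e-10,
                   parscale = c(0.25 * b, 0.25 * b, 0.5 * b, 0.35)
                 ))
    clamp_par(opt$par)
  }

  # shrink a (keeping centre and orientation) until clearance >= -feas_tol;
  # falls back to the original circle if even a = b overlaps off-centre
  restore <- function(p) {
    violated <- FALSE
    if (ellipse_clearance_xy(p[1], p[2], p[3], b, p[4], discs) < -feas_tol) {
      violated <- TRUE
      if (ellipse_clearance_xy(p[1], p[2], b, b, p[4], discs) < -feas_tol) {
        p[1] <- cx; p[2] <- cy
      }
      alo <- b; ahi <- p[3]
      for (i in 1:60) {
        mid <- 0.5 * (alo + ahi)
        if (ellipse_clearance_xy(p[1], p[2], mid, b, p[4], discs) >= -feas_tol) {
          alo <- mid
        } else {
          ahi <- mid
        }
      }
      p[3] <- alo
    }
    list(par = p, violated = violated)
  }

  amax2 <- max(min(8 * b, end_radius), b)
  s1 <- restore(run_stage(c(cx, cy, b, 0), dmax = 0.5 * b,
                          amax = max(2 * b, b)))
  s2 <- restore(run_stage(s1$par, dmax = 2 * b, amax = amax2))
  best <- if (s2$par[3] >= s1$par[3]) s2 else s1
  stage_a <- c(stage1 = s1$par[3], stage2 = best$par[3])

  # Feasible-direction polish: the penalised 4-D search can stall on the
  # active-constraint ridge (growing a requires a coordinated centre
  # shift). Feasibility is monotone in a, so the maximal feasible a at a
  # given centre/orientation is a cheap bisection; polishing over
  # (x, y, theta) with that implicit objective follows the ridge.
  amax_at <- function(x, y, th) {
    x <- clamp(x, cx - 2 * b, cx + 2 * b)
    y <- clamp(y, cy - 2 * b, cy + 2 * b)
    if (ellipse_clearance_xy(x, y, b, b, th, discs) < -feas_tol) return(b - 1)
    if (ellipse_clearance_xy(x, y, amax2, b, th, discs) >= -feas_tol) {
      return(amax2)
    }
    alo <- b; ahi <- amax2
    for (i in 1:20) {
      mid <- 0.5 * (alo + ahi)
      if (ellipse_clearance_xy(x, y, mid, b, th, discs) >= -feas_tol) {
        alo <- mid
      } else {
        ahi <- mid
      }
    }
    alo
  }
  # The set of centres where the b-circle fits can consist of several
  # small disconnected islands (discrete walls), and Nelder-Mead cannot
  # cross the infeasible valleys between them. Enumerate islands by a
  # fine scan of the circle clearance over the stage-2 box, then polish
  # from each island's best centre (theta chosen by a coarse scan, since
  # theta = 0 can be a saddle where the objective is flat).
  th_grid <- seq(0, pi, length.out = 13)[-13]
  # circle clearance is distance - b - rho: vectorise the scan directly.
  # Islands are a sub-Angstrom phenomenon; scanning only a tight
  # neighbourhood keeps the search anchored to the pore (a wide scan can
  # "discover" the pore exterior through open fixtures).
  step <- 0.05
  gx <- seq(cx - b / 2, cx + b / 2, by = step)
  gy <- seq(cy - b / 2, cy + b / 2, by = step)
  cells <- expand.grid(x = gx, y = gy)
  cc <- rep(Inf, nrow(cells))
  for (j in seq_len(nrow(discs))) {
    cc <- pmin(cc, sqrt((cells$x - discs$x[j])^2 +
                          (cells$y - discs$y[j])^2) - b - discs$rho[j])
  }
  # near-feasible cells are island candidates (the grid phase can just
  # miss a marginal island); each is refined by a short climb on the
  # closed-form circle clearance and kept only if truly feasible
  cand <- which(cc >= -(feas_tol + 0.05))
  centres <- list(c(cx, cy))
  sep2 <- max(b / 4, 0.2)^2
  if (length(cand)) {
    ord <- cand[order(cc[cand], decreasing = TRUE)]
    tries <- 0L
    for (i in ord) {
      if (tries >= 8L) break
      p <- c(cells$x[i], cells$y[i])
      if (any(vapply(centres, function(q) {
        sum((p - q)^2) <= sep2
      }, logical(1)))) next
      tries <- tries + 1L
      o <- optim(p, function(q) -circle_clear(q[1], q[2]),
                 method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-10,
                                parscale = c(0.1, 0.1)))
      if (-o$value >= -feas_tol &&
          !any(vapply(centres, function(q) {
            sum((o$par - q)^2) <= sep2
          }, logical(1)))) {
        centres <- c(centres, list(o$par))
      }
      if (length(centres) >= 3) break
    }
  }
  starts <- list(best$par[c(1, 2, 4)])
  for (ctr in centres) {
    a_th <- vapply(th_grid, function(th) amax_at(ctr[1], ctr[2], th),
                   numeric(1))
    starts <- c(starts, list(c(ctr, th_grid[which.max(a_th)])))
  }
  # drop near-duplicate starts
  keep <- !duplicated(round(do.call(rbind, starts) / c(0.05, 0.05, 0.05)))
  starts <- starts[keep]
  for (p0 in starts) {
    if (amax_at(p0[1], p0[2], p0[3]) >= amax2 - 1e-9) {
      best <- list(par = c(clamp(p0[1], cx - 2 * b, cx + 2 * b),
                           clamp(p0[2], cy - 2 * b, cy + 2 * b),
                           amax2, p0[3]),
                   violated = best$violated)
      break
    }
    o3 <- optim(p0, function(p) -amax_at(p[1], p[2], p[3]),
                method = "Nelder-Mead",
                control = list(maxit = 150, reltol = 1e-8,
                               parscale = c(0.25 * b, 0.25 * b, 0.6)))
    a3 <- amax_at(o3$par[1], o3$par[2], o3$par[3])
    if (a3 > best$par[3]) {
      best <- list(par = c(clamp(o3$par[1], cx - 2 * b, cx + 2 * b),
                           clamp(o3$par[2], cy - 2 * b, cy + 2 * b),
                           a3, o3$par[3]),
                   violated = best$violated)
    }
  }
  if (best$violated) {
    warn(sprintf(
      "slice z = %.3f: optimizer violated clearance; major axis restored to %.3f A",
      z, best$par[3]
    ))
  }
  p <- best$par
  out <- tibble(z = z, x = p[1], y = p[2], a = p[3], b = b,
                theta = p[4] %% pi,
                eccentricity = sqrt(1 - (b / p[3])^2),
                flag = if (identical(sphere$flag, "boundary")) "boundary" else "ok")
  attr(out, "stage_a") <- stage_a
  out
}

#' Inflate every sphere of a profile into an ellipse
#'
#' Applies [expand_slice()] independently to each slice of a spherical
#' profile (results do not depend on processing order). Slices flagged
#' open/empty, or with no atom discs in their plane, carry the sentinel
#' `a = b = end_radius` and are excluded from volume integration.
#'
#' @param profile `sphere_profile` from [trace_pathway()].
#' @param atoms The same aligned `pore_atoms` the profile was traced on.
#' @param end_radius Cap on the major semi-axis; defaults to the profile's
#'   own termination radius.
#' @param penalty,feas_tol Passed to [expand_slice()].
#' @return An `ellipse_profile` tibble (columns `z`, `x`, `y`, `a`, `b`,
#'   `theta`, `eccentricity`, `flag`) with the same z grid as `profile` and
#'   attribute `dz` copied from it.
#' @export
expand_profile <- function(profile, atoms,
                           end_radius = attr(profile, "end_radius") %||% 15,
                           penalty = 1e4, feas_tol = 1e-3) {
  rows <- purrr::map(seq_len(nrow(profile)), function(i) {
    sph <- profile[i, ]
    expand_slice(sph, atom_discs(atoms, sph$z),
                 end_radius = end_radius, penalty = penalty,
                 feas_tol = feas_tol)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "dz") <- attr(profile, "dz")
  attr(out, "end_radius") <- end_radius
  attr(out, "rng_seed") <- attr(profile, "rng_seed")
  class(out) <- c("ellipse_profile", class(out))
  out
}
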