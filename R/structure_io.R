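#' Default van der Waals radius table
#'
#' A HOLE-style element-to-radius lookup used when no user table is supplied.
#' Radii are in Angstrom: C 1.85, O 1.65, N 1.75, S 2.00, P 2.10, H 1.00;
#' any element not listed falls back to the table's `default_radius`
#' attribute (2.00 A).
#'
#' @param default_radius Radius in Angstrom assigned to elements without a
#'   rule. Must be positive.
#' @return A tibble with columns `element` and `radius`, carrying a
#'   `default_radius` attribute.
#' @export
#' @examples
#' default_radius_table()
default_radius_table <- function(default_radius = 2.00) {
  stopifnot(is.numeric(default_radius), default_radius > 0)
  tbl <- tibble(
    element = c("C", "O", "N", "S", "P", "H"),
    radius  = c(1.85, 1.65, 1.75, 2.00, 2.10, 1.00)
  )
  attr(tbl, "default_radius") <- default_radius
  class(tbl) <- c("radius_table", class(tbl))
  tbl
}

# Atomic masses (Da) for principal-axis weighting; unknown elements fall
# back to carbon, which only matters for exotic hetero groups.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, K = 39.098,
  NA. = 22.990, MG = 24.305, CA = 40.078, ZN = 65.38, FE = 55.845
)

element_mass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- .atomic_masses[key]
  m[is.na(m)] <- 12.011
  unname(m)
}

new_pore_atoms <- function(df) {
  df <- as_tibble(df)
  class(df) <- c("pore_atoms", class(df))
  df
}

#' Read a structure from a PDB file
#'
#' Parses ATOM (and optionally HETATM) records into a per-atom tibble.
#' Alternate locations other than blank or 'A' are dropped; waters and
#' common monoatomic ions are excluded by default because the pore wall is
#' defined by the protein or nanotube atoms. The element is taken from the
#' element column when present, falling back to parsing the atom name.
#' Van der Waals radii are assigned on read via [assign_radii()].
#'
#' @param path Path to a PDB file.
#' @param radius_table Radius lookup, see [default_radius_table()]. Use
#'   `NULL` to skip radius assignment.
#' @param include_hetero Keep HETATM records (default TRUE; waters/ions are
#'   still excluded unless `include_solvent` is set).
#' @param include_hydrogens Keep hydrogen atoms (default TRUE: they carry a
#'   van der Waals radius and nanotube rims are hydrogen-capped).
#' @param include_solvent Keep water and monoatomic ion residues.
#' @return A `pore_atoms` tibble with columns `x`, `y`, `z` (Angstrom),
#'   `element`, `name`, `resname`, `resid`, `mass`, and `radius` when a
#'   radius table was given.
#' @export
read_structure <- function(path, radius_table = default_radius_table(),
                           include_hetero = TRUE, include_hydrogens = TRUE,
                           include_solvent = FALSE) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    stop_ellipore(sprintf("PDB file not found or unreadable: %s", path))
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop_ellipore(sprintf("failed to parse '%s': %s", path, conditionMessage(e)))
  )
  at <- pdb$atom
  keep <- at$type == "ATOM"
  if (include_hetero) keep <- keep | at$type == "HETATM"
  alt <- at$alt
  keep <- keep & (is.na(alt) | alt %in% c("", "A"))
  if (!include_solvent) {
    solvent <- c("HOH", "WAT", "SOL", "TIP3", "TIP4", "SPC",
                 "K", "CL", "NA", "MG", "CA", "ZN", "IOD", "BR")
    keep <- keep & !(toupper(at$resid) %in% solvent)
  }
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop_ellipore(sprintf("no atoms retained from '%s'", path))

  elesy <- if ("elesy" %in% names(at)) trimws(at$elesy) else rep("", nrow(at))
  element <- toupper(elesy)
  miss <- is.na(element) | element == ""
  if (any(miss)) element[miss] <- guess_element(at$elety[miss])
  if (!include_hydrogens) {
    h <- element == "H"
    at <- at[!h, , drop = FALSE]
    element <- element[!h]
    if (nrow(at) == 0) stop_ellipore(sprintf("no atoms retained from '%s'", path))
  }

  atoms <- new_pore_atoms(tibble(
    x = at$x, y = at$y, z = at$z,
    element = element,
    name = trimws(at$elety),
    resname = trimws(at$resid),
    resid = at$resno,
    mass = element_mass(element)
  ))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop_ellipore(sprintf("non-finite coordinates in '%s'", path))
  }
  if (!is.null(radius_table)) atoms <- assign_radii(atoms, radius_table)
  atoms
}

# Element from a PDB atom name: strip digits/primes, two-letter elements
# only recognised for common cases, otherwise first alphabetic character.
guess_element <- function(name) {
  nm <- toupper(trimws(name))
  stripped <- gsub("[^A-Z]", "", nm)
  two <- c("CL", "BR", "FE", "ZN", "MG", "NA", "CA", "MN", "CU", "SE")
  el <- substr(stripped, 1, 1)
  first2 <- substr(stripped, 1, 2)
  hit <- first2 %in% two & !grepl("^C[ABGDEZ]", nm) & !grepl("^N[ABGDEZ]", nm)
  el[hit] <- first2[hit]
  # leading digit followed by H (e.g. 1HB2) is a hydrogen
  el[grepl("^[0-9]*H", nm)] <- "H"
  el
}

#' Assign van der Waals radii to atoms
#'
#' Total lookup: atoms whose element matches a table rule receive that
#' radius; unmatched atoms receive the table's default radius and a warning
#' is raised naming the elements involved.
#'
#' @param atoms A `pore_atoms` tibble.
#' @param table Radius table from [default_radius_table()] or a tibble with
#'   columns `element`, `radius` (positive) and optionally a
#'   `default_radius` attribute.
#' @return `atoms` with a `radius` column filled in.
#' @export
assign_radii <- function(atoms, table = default_radius_table()) {
  stopifnot(nrow(table) > 0, all(table$radius > 0))
  default_radius <- attr(table, "default_radius") %||% 2.00
  idx <- match(toupper(atoms$element), toupper(table$element))
  radius <- table$radius[idx]
  unmatched <- is.na(radius)
  if (any(unmatched)) {
    warn(sprintf(
      "no radius rule for element(s) %s; using default %.2f A",
      paste(sort(unique(atoms$element[unmatched])), collapse = ", "),
      default_radius
    ))
    radius[unmatched] <- default_radius
  }
  atoms$radius <- radius
  atoms
}

#' Align the principal axis of a structure to the z axis
#'
#' Moves the mass-weighted centre of mass to the origin and rotates the
#' structure so the eigenvector of the mass-weighted gyration tensor with
#' the largest eigenvalue is parallel to +z. The axis sign is chosen so the
#' z coordinate increases with residue index (falling back to the +z
#' hemisphere of the original frame), making the orientation deterministic.
#'
#' @param atoms A `pore_atoms` tibble with a `mass` column.
#' @return A list with elements `atoms` (the aligned tibble) and
#'   `transform`, a list with fields `rotation` (3x3, det +1) and
#'   `translation` (length 3) such that
#'   `aligned = original %*% t(rotation) + translation`.
#' @export
align_principal_axis <- function(atoms) {
  n <- nrow(atoms)
  if (n < 3) stop_ellipore("need at least 3 atoms to define a principal axis")
  X <- cbind(atoms$x, atoms$y, atoms$z)
  m <- atoms$mass
  if (is.null(m)) m <- rep(1, n)
  com <- colSums(X * m) / sum(m)
  Xc <- sweep(X, 2, com)
  S <- crossprod(Xc * m, Xc) / sum(m)  # gyration tensor
  eg <- eigen(S, symmetric = TRUE)
  axis <- eg$vectors[, 1]  # largest eigenvalue first

  # deterministic sign: along increasing residue index if informative
  proj <- Xc %*% axis
  s <- 0
  if (!is.null(atoms$resid) && length(unique(atoms$resid)) > 2) {
    cc <- suppressWarnings(cor(as.numeric(proj), atoms$resid))
    if (is.finite(cc) && abs(cc) > 1e-8) s <- sign(cc)
  }
  if (s == 0) {
    s <- if (abs(axis[3]) > 1e-12) sign(axis[3]) else {
      nz <- which(abs(axis) > 1e-12)[1]
      sign(axis[nz])
    }
  }
  e3 <- s * axis
  # complete a right-handed orthonormal basis with the remaining eigenvectors
  e1 <- eg$vectors[, 3]
  e1 <- e1 - sum(e1 * e3) * e3
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    e3[2] * e1[3] - e3[3] * e1[2],
    e3[3] * e1[1] - e3[1] * e1[3],
    e3[1] * e1[2] - e3[2] * e1[1]
  )
  R <- rbind(e1, e2, e3)  # e2 = e3 x e1, so det(R) = +1 by construction
  dimnames(R) <- NULL
  Xa <- Xc %*% t(R)
  out <- atoms
  out$x <- Xa[, 1]; out$y <- Xa[, 2]; out$z <- Xa[, 3]
  transform <- list(rotation = R, translation = as.numeric(-R %*% com))
  list(atoms = out, transform = transform)
}

#' Invert an alignment transform
#'
#' Maps aligned coordinates back to the original frame.
#'
#' @param atoms Aligned `pore_atoms` tibble.
#' @param transform Transform list returned by [align_principal_axis()].
#' @return `pore_atoms` tibble in the original coordinate frame.
#' @export
unalign <- function(atoms, transform) {
  X <- cbind(atoms$x, atoms$y, atoms$z)
  X0 <- sweep(X, 2, transform$translation) %*% transform$rotation
  atoms$x <- X0[, 1]; atoms$y <- X0[, 2]; atoms$z <- X0[, 3]
  atoms
}
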