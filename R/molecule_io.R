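# Structure and Hessian ingestion: minimal PDB reader/writer, mode counting,
# Hessian symmetrisation and local-minimum validation via mass-weighted
# Eckart projection.

#' Molecular structure container
#'
#' Holds the reference (local-minimum) geometry on which the whole pipeline
#' operates: atom identities, standard masses and Cartesian coordinates, plus
#' optional relaxation-probe annotations (a 13C atom and its attached
#' proton(s)).
#'
#' @param element Character vector of element symbols.
#' @param position n x 3 numeric matrix of coordinates in Angstrom.
#' @param mass Optional numeric vector of masses (u); defaults to the
#'   standard table via [element_mass()].
#' @param atom_name Optional atom names (defaults to element symbols).
#' @param probes Optional list of probes, each `list(C = i, H = j)` with `j`
#'   an integer vector of one (CH) or two (CH2) attached protons.
#' @param rigid Logical; if `TRUE` the molecule is treated as a rigid body
#'   (no internal modes), as for the rigid-rotor fixture.
#' @return An object of class `MolecularStructure`.
#' @export
molecular_structure <- function(element, position, mass = NULL,
                                atom_name = NULL, probes = list(),
                                rigid = FALSE) {
  position <- as.matrix(position)
  if (ncol(position) != 3L) stop("position must be an n x 3 matrix")
  n <- nrow(position)
  if (n < 2L) stop("structure must contain at least 2 atoms")
  if (length(element) != n) stop("element/position length mismatch")
  if (!all(is.finite(position))) stop("non-finite coordinates")
  if (is.null(mass)) mass <- element_mass(element)
  if (any(mass <= 0)) stop("all masses must be positive")
  if (is.null(atom_name)) atom_name <- element
  st <- structure(
    list(atom_id = seq_len(n), element = toupper(trimws(element)),
         atom_name = atom_name, mass = mass, position = position,
         probes = list(), rigid = isTRUE(rigid)),
    class = "MolecularStructure")
  for (p in probes) st <- add_probe(st, p$C, p$H)
  st
}

#' @export
print.MolecularStructure <- function(x, ...) {
  cat(sprintf("MolecularStructure: %d atoms (%s)%s, %d probe(s)\n",
              length(x$atom_id), paste(unique(x$element), collapse = ","),
              if (x$rigid) ", rigid" else "", length(x$probes)))
  invisible(x)
}

#' Annotate a 13C-1H(n) relaxation probe on a structure
#'
#' @param structure A [molecular_structure()].
#' @param C Integer index of the carbon atom.
#' @param H Integer vector of one or two attached proton indices.
#' @return The structure with the probe appended.
#' @export
add_probe <- function(structure, C, H) {
  n <- length(structure$atom_id)
  idx <- c(C, H)
  if (any(idx < 1L | idx > n)) stop("probe references non-existent atoms")
  for (h in H) {
    d <- sqrt(sum((structure$position[C, ] - structure$position[h, ])^2))
    if (d < 0.8 || d > 1.5)
      stop(sprintf("probe C-H distance %.3f A outside 0.8-1.5 A", d))
  }
  structure$probes <- c(structure$probes,
                        list(list(C = as.integer(C), H = as.integer(H))))
  structure
}

#' Number of SFB modes for an n-atom nonlinear molecule
#'
#' The flexible rotator carries N = 6n - 9 dimensionless modes: 3n - 6
#' internal coordinates, their 3n - 6 conjugate momenta and the 3 body-frame
#' angular momentum components.
#'
#' @param n Atom count (>= 2).
#' @return A list with `N`, `n_coordinates`, `n_momenta`,
#'   `n_angular_momentum`.
#' @export
mode_count <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("atom count must be an integer >= 2")
  nc <- max(3L * n - 6L, 0L)
  list(N = 6L * n - 9L, n_coordinates = nc, n_momenta = nc,
       n_angular_momentum = 3L)
}

# --- PDB -------------------------------------------------------------------

.pdb_element <- function(line) {
  el <- ""
  if (nchar(line) >= 78) el <- trimws(substr(line, 77, 78))
  if (el == "") {
    # fall back to atom-name inference: first alphabetic character(s)
    nm <- trimws(substr(line, 13, 16))
    el <- sub("^[0-9]*", "", nm)
    el <- substr(el, 1, 1)
  }
  el
}

#' Read a molecular structure from a PDB file
#'
#' Only ATOM/HETATM coordinate records are interpreted; the element column is
#' used when present, with a fallback to atom-name inference. For alternate
#' locations the first one wins.
#'
#' @param path Path to a PDB file.
#' @return A [molecular_structure()] with masses from the standard table.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(rec) < 2L) stop("PDB must contain at least 2 ATOM/HETATM records")
  altloc <- substr(rec, 17, 17)
  rec <- rec[altloc %in% c(" ", "A", "1", "")]
  nm <- trimws(substr(rec, 13, 16))
  x <- as.numeric(substr(rec, 31, 38))
  y <- as.numeric(substr(rec, 39, 46))
  z <- as.numeric(substr(rec, 47, 54))
  if (anyNA(x) || anyNA(y) || anyNA(z)) stop("malformed coordinate fields")
  el <- vapply(rec, .pdb_element, character(1), USE.NAMES = FALSE)
  mass <- tryCatch(element_mass(el), error = function(e) {
    bad <- which(!toupper(el) %in% c(names(.element_masses), "NA"))
    stop(sprintf("unresolvable element '%s' in PDB record: %s",
                 el[bad[1]], rec[bad[1]]), call. = FALSE)
  })
  molecular_structure(el, cbind(x, y, z), mass = mass, atom_name = nm)
}

#' Write a structure as a minimal PDB file
#'
#' @param structure A [molecular_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  n <- length(structure$atom_id)
  lines <- character(n)
  for (i in seq_len(n)) {
    lines[i] <- sprintf(
      "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, substr(structure$atom_name[i], 1, 4), "LIG", 1,
      structure$position[i, 1], structure$position[i, 2],
      structure$position[i, 3], 1.0, 0.0, structure$element[i])
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# --- Hessian ---------------------------------------------------------------

#' Read a Hessian matrix from a plain-text file
#'
#' Accepts a dense whitespace- or comma-delimited 3n x 3n matrix, or
#' upper-triangle triples "i j value" (mirrored on read). The matrix is
#' symmetrised as (H + H^T)/2 and the maximum relative asymmetry recorded.
#'
#' @param path File path.
#' @param n Atom count the Hessian must match.
#' @param units Unit convention of the entries; `"kcal_mol_A2"` (the Tinker
#'   convention, default) or `"si"` (J m^-2 = N/m).
#' @return Object of class `HessianMatrix`: the symmetrised matrix in the
#'   declared units plus `units`, `max_asymmetry` fields.
#' @export
read_hessian <- function(path, n, units = c("kcal_mol_A2", "si")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("Hessian file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(trimws(txt)) & !grepl("^#", txt)]
  toks <- strsplit(trimws(gsub(",", " ", txt)), "[[:space:]]+")
  ncols <- lengths(toks)
  dim3n <- 3L * n
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) stop("non-numeric token in Hessian file")
  if (all(ncols == 3L) && length(txt) != dim3n) {
    # triples i j value
    m <- matrix(vals, ncol = 3, byrow = TRUE)
    H <- matrix(0, dim3n, dim3n)
    ij <- cbind(as.integer(m[, 1]), as.integer(m[, 2]))
    if (any(ij < 1L | ij > dim3n)) stop("Hessian triple index out of range")
    H[ij] <- m[, 3]
    H[ij[, 2:1]] <- m[, 3]
  } else {
    if (length(vals) != dim3n^2)
      stop(sprintf("Hessian has %d entries; expected %d x %d",
                   length(vals), dim3n, dim3n))
    H <- matrix(vals, dim3n, dim3n, byrow = TRUE)
  }
  hessian_matrix(H, units = units)
}

#' Construct a HessianMatrix from a numeric matrix
#'
#' @param H Square 3n x 3n numeric matrix.
#' @param units Unit tag, see [read_hessian()].
#' @param asym_tol Relative asymmetry above which a warning is emitted.
#' @return Object of class `HessianMatrix`.
#' @export
hessian_matrix <- function(H, units = "kcal_mol_A2", asym_tol = 1e-6) {
  H <- as.matrix(H)
  if (nrow(H) != ncol(H) || nrow(H) %% 3L != 0L)
    stop("Hessian must be square with dimension a multiple of 3")
  scale <- max(abs(H), 1e-300)
  asym <- max(abs(H - t(H))) / scale
  if (asym > asym_tol)
    warning(sprintf("Hessian asymmetry %.2e relative; symmetrising", asym))
  structure(list(matrix = (H + t(H)) / 2, units = units,
                 max_asymmetry = asym),
            class = "HessianMatrix")
}

# Hessian in SI units (N/m), whatever it was declared in.
hessian_si <- function(hessian) {
  switch(hessian$units,
         kcal_mol_A2 = hessian$matrix * sfb_constants$kcalmol_A2,
         si = hessian$matrix,
         stop("unknown Hessian unit tag: ", hessian$units))
}

# --- Eckart projection -----------------------------------------------------

# Orthonormal basis (columns) of the rigid-body subspace in mass-weighted
# Cartesian coordinates: 3 translations and up to 3 rotations about the
# centre of mass. Masses in kg, positions in m.
rigid_body_basis <- function(mass_kg, pos_m) {
  n <- length(mass_kg)
  sq <- sqrt(mass_kg)
  com <- colSums(pos_m * mass_kg) / sum(mass_kg)
  r <- sweep(pos_m, 2, com)
  vecs <- matrix(0, 3 * n, 6)
  for (p in 1:3) vecs[seq(p, 3 * n, by = 3), p] <- sq
  e <- diag(3)
  for (p in 1:3) {
    w <- t(vapply(seq_len(n), function(a) crossprod_vec(e[p, ], r[a, ]) * sq[a],
                  numeric(3)))
    vecs[, 3 + p] <- as.vector(t(w))
  }
  qr_ <- qr(vecs)
  keep <- qr_$rank
  qr.Q(qr_)[, seq_len(keep), drop = FALSE]
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Mass-weighted Hessian (s^-2) with rigid-body modes projected out.
projected_mass_weighted_hessian <- function(hessian, structure) {
  K <- hessian_si(hessian)
  m_kg <- structure$mass * sfb_constants$amu
  pos_m <- structure$position * sfb_constants$angstrom
  if (nrow(K) != 3L * length(m_kg)) stop("Hessian/structure size mismatch")
  sqm <- rep(sqrt(m_kg), each = 3)
  Hm <- K / outer(sqm, sqm)
  Rb <- rigid_body_basis(m_kg, pos_m)
  P <- diag(nrow(Hm)) - Rb %*% t(Rb)
  list(H = (P %*% Hm %*% P + t(P %*% Hm %*% P)) / 2, P = P, n_rigid = ncol(Rb))
}

#' Check that a Hessian describes a local minimum
#'
#' Projects out the 3 translations and (up to) 3 rotations with mass-weighted
#' Eckart projectors and inspects the remaining spectrum.
#'
#' @param hessian A [hessian_matrix()].
#' @param structure The matching [molecular_structure()].
#' @param tol Relative tolerance for zero/negative eigenvalue classification.
#' @return A list: `is_minimum`, `smallest_eigenvalue` (s^-2),
#'   `n_zero_modes`, `eigenvalues`, `degenerate_geometry` flag.
#' @export
validate_minimum <- function(hessian, structure, tol = 1e-8) {
  pr <- projected_mass_weighted_hessian(hessian, structure)
  ev <- eigen(pr$H, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), .Machine$double.eps)
  nzero <- sum(abs(ev) < tol * scale)
  smallest <- min(ev[abs(ev) >= tol * scale], Inf)
  degenerate <- nzero > pr$n_rigid
  if (degenerate)
    warning(sprintf("%d near-zero modes beyond the %d rigid-body modes: ",
                    nzero, pr$n_rigid),
            "possible linear or disconnected geometry")
  list(is_minimum = is.finite(smallest) && smallest > -tol * scale ||
         !is.finite(smallest),
       smallest_eigenvalue = if (is.finite(smallest)) smallest else NA_real_,
       n_zero_modes = nzero, eigenvalues = ev,
       degenerate_geometry = degenerate)
}

# TRUE when the geometry is linear (smallest inertia eigenvalue negligible).
is_linear_geometry <- function(structure, tol = 1e-8) {
  I <- inertia_tensor(structure)
  ev <- eigen(I, symmetric = TRUE, only.values = TRUE)$values
  min(ev) < tol * max(ev)
}

#' Inertia tensor of a structure
#'
#' @param structure A [molecular_structure()].
#' @param about Optional 3-vector (Angstrom) to take moments about; defaults
#'   to the centre of mass.
#' @return 3 x 3 inertia tensor in kg m^2.
#' @export
inertia_tensor <- function(structure, about = NULL) {
  m <- structure$mass * sfb_constants$amu
  r <- structure$position * sfb_constants$angstrom
  ref <- if (is.null(about)) colSums(r * m) / sum(m)
         else about * sfb_constants$angstrom
  r <- sweep(r, 2, ref)
  I <- matrix(0, 3, 3)
  for (a in seq_along(m)) {
    ra <- r[a, ]
    I <- I + m[a] * (sum(ra^2) * diag(3) - outer(ra, ra))
  }
  I
}

#' Adapter for an external minimization / Hessian program
#'
#' The package never minimizes geometries itself: the reference structure
#' and Hessian are inputs, normally produced by a force-field program. This
#' adapter documents that interface: it substitutes `{pdb_in}`, `{pdb_out}`
#' and `{hessian_out}` into a user-supplied command template, runs it, and
#' returns the re-read structure and Hessian. It is optional and untested
#' by design; nothing in the pipeline requires it.
#'
#' @param command Command template, e.g.
#'   `"mytool minimize {pdb_in} -o {pdb_out} --hessian {hessian_out}"`.
#' @param pdb_in Input structure path.
#' @param workdir Directory for outputs (default tempdir()).
#' @param hessian_units Unit tag for [read_hessian()].
#' @return List with `structure` and `hessian`, as [make_fixture()].
#' @export
run_external_minimizer <- function(command, pdb_in, workdir = tempdir(),
                                   hessian_units = "kcal_mol_A2") {
  pdb_out <- file.path(workdir, "minimized.pdb")
  hessian_out <- file.path(workdir, "minimized.hess")
  cmd <- gsub("{pdb_in}", shQuote(pdb_in), command, fixed = TRUE)
  cmd <- gsub("{pdb_out}", shQuote(pdb_out), cmd, fixed = TRUE)
  cmd <- gsub("{hessian_out}", shQuote(hessian_out), cmd, fixed = TRUE)
  status <- system(cmd)
  if (status != 0) stop("external minimizer failed with status ", status)
  st <- read_pdb(pdb_out)
  list(structure = st,
       hessian = read_hessian(hessian_out, n = length(st$atom_id),
                              units = hessian_units))
}
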