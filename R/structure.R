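#' Coordinate ensembles
#'
#' A `coord_ensemble` is the package's container for multi-frame, multi-chain
#' structures: an atom roster (constant across frames) plus a
#' `frames x atoms x 3` coordinate array in Angstrom.
#'
#' @param atoms A data frame with columns `chain`, `resnum`, `resname`,
#'   `atom` (atom name) and `element`.
#' @param coords Either a `n_atoms x 3` matrix (single frame) or a
#'   `n_frames x n_atoms x 3` array.
#' @return An object of class `coord_ensemble`.
#' @export
coord_ensemble <- function(atoms, coords) {
  atoms <- as_tibble(atoms)
  required <- c("chain", "resnum", "resname", "atom", "element")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atoms table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  stopifnot_named(
    "coords must be a frames x atoms x 3 array" =
      length(dim(coords)) == 3 && dim(coords)[3] == 3,
    "atom roster and coordinate array disagree" = dim(coords)[2] == nrow(atoms),
    "coordinates must be finite" = is.finite(coords)
  )
  structure(list(atoms = atoms, coords = coords), class = "coord_ensemble")
}

#' @export
print.coord_ensemble <- function(x, ...) {
  cat(sprintf("<coord_ensemble> %d frame(s), %d atoms, chains: %s\n",
              n_frames(x), nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ", ")))
  invisible(x)
}

#' @rdname coord_ensemble
#' @param x A `coord_ensemble`.
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' Extract one frame's coordinates as an atoms x 3 matrix
#' @param x A `coord_ensemble`.
#' @param i Frame index.
#' @return Numeric matrix with columns x, y, z.
#' @export
frame_coords <- function(x, i = 1L) {
  m <- x$coords[i, , , drop = FALSE]
  dim(m) <- dim(x$coords)[2:3]
  colnames(m) <- c("x", "y", "z")
  m
}

#' Tidy a coordinate ensemble into a long tibble
#' @param x A `coord_ensemble`.
#' @param ... Unused.
#' @return A tibble with one row per frame x atom.
#' @export
tidy.coord_ensemble <- function(x, ...) {
  nf <- n_frames(x)
  na <- nrow(x$atoms)
  out <- x$atoms[rep(seq_len(na), times = nf), ]
  out$frame <- rep(seq_len(nf), each = na)
  out$x <- as.vector(t(x$coords[, , 1, drop = TRUE]))
  out$y <- as.vector(t(x$coords[, , 2, drop = TRUE]))
  out$z <- as.vector(t(x$coords[, , 3, drop = TRUE]))
  if (nf == 1L) { # drop=TRUE collapses the frame dimension
    out$x <- x$coords[1, , 1]; out$y <- x$coords[1, , 2]; out$z <- x$coords[1, , 3]
  }
  as_tibble(out)
}

# ---- selection mini-grammar -------------------------------------------------

# "chain A and resid 40-45 and name CA and elem C" -> logical mask over atoms
parse_selection_clause <- function(clause, atoms) {
  clause <- trimws(clause)
  toks <- strsplit(clause, "\\s+")[[1]]
  if (length(toks) < 2) abort(paste0("cannot parse selection clause: ", clause))
  key <- toks[1]
  vals <- toks[-1]
  expand_range <- function(v) {
    unlist(lapply(v, function(s) {
      if (grepl("^-?[0-9]+--?[0-9]+$", s)) {
        parts <- regmatches(s, regexec("^(-?[0-9]+)-(-?[0-9]+)$", s))[[1]]
        seq(as.integer(parts[2]), as.integer(parts[3]))
      } else as.integer(s)
    }))
  }
  switch(key,
    chain = atoms$chain %in% vals,
    resid = atoms$resnum %in% expand_range(vals),
    resname = atoms$resname %in% vals,
    name = atoms$atom %in% vals,
    elem = atoms$element %in% vals,
    abort(paste0("unknown selection keyword: ", key))
  )
}

#' Select atoms with a mini-grammar string
#'
#' Clauses joined by `" and "`; keywords: `chain`, `resid` (values or
#' `lo-hi` ranges), `resname`, `name`, `elem`.
#'
#' @param x A `coord_ensemble`.
#' @param selection Selection string, e.g.
#'   `"chain A and resid 40-45 and name CA"`.
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(x, selection) {
  clauses <- strsplit(selection, "\\s+and\\s+")[[1]]
  mask <- rep(TRUE, nrow(x$atoms))
  for (cl in clauses) mask <- mask & parse_selection_clause(cl, x$atoms)
  which(mask)
}

# standard atomic masses for the elements a PDB is likely to contain
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                    P = 30.974, MG = 24.305, FE = 55.845, ZN = 65.38)

atom_masses <- function(elements) {
  m <- .atomic_masses[toupper(elements)]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Mass-weighted center of a selection, per frame
#' @param x A `coord_ensemble`.
#' @param idx Atom indices (e.g. from [select_atoms()]).
#' @return `n_frames x 3` matrix of centers.
#' @export
center_of_mass <- function(x, idx) {
  w <- atom_masses(x$atoms$element[idx])
  w <- w / sum(w)
  nf <- n_frames(x)
  out <- matrix(0, nf, 3)
  for (f in seq_len(nf)) {
    out[f, ] <- colSums(frame_coords(x, f)[idx, , drop = FALSE] * w)
  }
  out
}

# ---- PDB I/O ----------------------------------------------------------------

#' Read a (multi-model) PDB file into a coordinate ensemble
#'
#' Parsing is delegated to [bio3d::read.pdb()]; models become frames.
#'
#' @param path PDB file path.
#' @return A `coord_ensemble`.
#' @export
read_pdb_ensemble <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  elem <- a$elesy
  blank <- is.na(elem) | trimws(elem) == ""
  # fall back to the first letter of the atom name when the element column is empty
  elem[blank] <- substr(gsub("[0-9]", "", a$elety[blank]), 1, 1)
  atoms <- tibble(chain = a$chain, resnum = a$resno, resname = a$resid,
                  atom = a$elety, element = trimws(elem))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- nrow(atoms)
  coords <- array(0, c(nf, na, 3))
  for (f in seq_len(nf)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  coord_ensemble(atoms, coords)
}

#' Write a coordinate ensemble as a multi-model PDB file
#'
#' @param x A `coord_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  a <- x$atoms
  nf <- n_frames(x)
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(x, f)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)),
      ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom),
      a$resname, a$chain, a$resnum, xyz[, 1], xyz[, 2], xyz[, 3],
      toupper(a$element))
    writeLines(lines, con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- geometry helpers -------------------------------------------------------

# pairwise Euclidean distances between two coordinate matrices (n x 3, m x 3)
cross_distances <- function(a, b) {
  sq <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sq[sq < 0] <- 0
  sqrt(sq)
}

# Kabsch least-squares superposition: rotation+translation of `mobile` onto `ref`
kabsch_fit <- function(mobile, ref, fit_idx) {
  pm <- mobile[fit_idx, , drop = FALSE]
  pr <- ref[fit_idx, , drop = FALSE]
  cm <- colMeans(pm)
  cr <- colMeans(pr)
  h <- crossprod(sweep(pm, 2, cm), sweep(pr, 2, cr))
  s <- svd(h)
  d <- sign(det(tcrossprod(s$v, s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(mobile, 2, cm) %*% t(rot), 2, cr, "+")
}

# random rigid-body transform, used by property tests
rigid_transform <- function(coords, angles = c(0.3, -0.5, 1.1),
                            translation = c(5, -3, 8)) {
  rx <- matrix(c(1, 0, 0, 0, cos(angles[1]), -sin(angles[1]),
                 0, sin(angles[1]), cos(angles[1])), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(angles[2]), 0, sin(angles[2]), 0, 1, 0,
                 -sin(angles[2]), 0, cos(angles[2])), 3, 3, byrow = TRUE)
  rz <- matrix(c(cos(angles[3]), -sin(angles[3]), 0,
                 sin(angles[3]), cos(angles[3]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  sweep(coords %*% t(rz %*% ry %*% rx), 2, translation, "+")
}

#' Apply a rigid transform to every frame of an ensemble
#' @param x A `coord_ensemble`.
#' @param angles Euler angles (radians) about x, y, z.
#' @param translation Length-3 translation vector (Angstrom).
#' @return A transformed `coord_ensemble`.
#' @export
transform_ensemble <- function(x, angles = c(0.3, -0.5, 1.1),
                               translation = c(5, -3, 8)) {
  out <- x
  for (f in seq_len(n_frames(x))) {
    out$coords[f, , ] <- rigid_transform(frame_coords(x, f), angles, translation)
  }
  out
}
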