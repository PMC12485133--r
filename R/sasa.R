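# van der Waals radii (Angstrom) by element; deterministic fixed table
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, MG = 1.73, FE = 1.80, ZN = 1.39)

vdw_radii <- function(elements) {
  r <- .vdw_radii[toupper(elements)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# theoretical maximum accessible surface areas per residue type (Angstrom^2),
# Gly-X-Gly based reference values (Tien et al. 2013, "theoretical" column)
.max_asa <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
              GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
              LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
              SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

# rotate coordinates into the principal-axis frame (sign fixed by the third
# moment along each axis) so downstream lattice sampling is orientation-free
canonical_frame <- function(coords) {
  if (nrow(coords) < 3) {
    return(sweep(coords, 2, colMeans(coords)))
  }
  centered <- sweep(coords, 2, colMeans(coords))
  ev <- eigen(crossprod(centered), symmetric = TRUE)$vectors
  proj <- centered %*% ev
  for (k in 1:3) {
    s <- sum(proj[, k]^3)
    if (abs(s) > 1e-9 && s < 0) proj[, k] <- -proj[, k]
  }
  proj
}

# deterministic quasi-uniform sphere points (golden-spiral lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical rolling-probe SASA: each atom's accessible sphere (vdW radius +
#' probe radius) is sampled on a fixed quasi-uniform point lattice and points
#' buried inside any neighbour's accessible sphere are discarded. Point count
#' and radii are fixed for determinism.
#'
#' @param coords `n_atoms x 3` coordinate matrix (Angstrom).
#' @param elements Character vector of element symbols, one per atom.
#' @param probe Probe radius in Angstrom.
#' @param n_points Lattice points per atom.
#' @param canonicalize Rotate into the principal-axis frame first (see
#'   Details); callers comparing subsets of one structure should
#'   canonicalize once themselves and pass `FALSE`.
#' @return Numeric vector of per-atom SASA (Angstrom^2).
#' @details Coordinates are first rotated into the structure's principal-axis
#'   frame so the result is invariant under rigid motion of the input (the
#'   lattice orientation follows the molecule).
#' @export
sasa_atoms <- function(coords, elements, probe = 1.4, n_points = 960,
                       canonicalize = TRUE) {
  if (canonicalize) coords <- canonical_frame(coords)
  n <- nrow(coords)
  radii <- vdw_radii(elements) + probe
  pts <- sphere_points(n_points)
  out <- numeric(n)
  # neighbour lists via one cross-distance pass
  d <- cross_distances(coords, coords)
  max_r <- max(radii)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < radii[i] + radii & seq_len(n) != i)
    p <- sweep(pts * radii[i], 2, coords[i, ], "+")
    if (length(nb) > 0) {
      dist2 <- outer(rowSums(p^2), rowSums(coords[nb, , drop = FALSE]^2), "+") -
        2 * tcrossprod(p, coords[nb, , drop = FALSE])
      exposed <- rowSums(sweep(dist2, 2, radii[nb]^2, "<")) == 0
    } else {
      exposed <- rep(TRUE, n_points)
    }
    out[i] <- 4 * pi * radii[i]^2 * mean(exposed)
  }
  out
}

#' Relative solvent accessibility per residue
#'
#' RSA = SASA(residue in context) / SASA_max(residue type), with SASA from
#' the rolling-probe numerical method. Two normalizations are available:
#' `"isolated"` (default) divides by the SASA of the residue's own atoms with
#' all context stripped, which is exactly 1 for an isolated residue and is
#' well defined for reduced-representation structures; `"theoretical"` uses
#' the fixed published Gly-X-Gly reference maxima shipped with the package
#' (Tien et al. 2013 theoretical values), the convention used for full-atom
#' protein structures. Hydrogens are excluded so structures with and without
#' protons give comparable values.
#'
#' @param structure A `coord_ensemble`; the first frame is used.
#' @param chain Optional chain to restrict to.
#' @param probe Probe radius (Angstrom).
#' @param n_points SASA lattice points per atom.
#' @param reference `"isolated"` or `"theoretical"`.
#' @return A tibble with `chain`, `resnum`, `resname`, `sasa`, `rsa`.
#' @export
relative_solvent_accessibility <- function(structure, chain = NULL,
                                           probe = 1.4, n_points = 960,
                                           reference = c("isolated",
                                                         "theoretical")) {
  reference <- match.arg(reference)
  atoms <- structure$atoms
  xyz <- frame_coords(structure, 1L)
  keep <- toupper(atoms$element) != "H"
  if (!is.null(chain)) keep <- keep & atoms$chain %in% chain
  atoms <- atoms[keep, ]
  xyz <- xyz[keep, , drop = FALSE]
  if (reference == "theoretical") {
    unknown <- setdiff(unique(atoms$resname), names(.max_asa))
    if (length(unknown) > 0) {
      abort(paste0("no reference maximum SASA for residue type(s): ",
                   paste(unknown, collapse = ", ")))
    }
  }
  sasa <- sasa_atoms(xyz, atoms$element, probe = probe, n_points = n_points)
  res <- tibble(chain = atoms$chain, resnum = atoms$resnum,
                resname = atoms$resname, sasa = sasa) |>
    group_by(.data$chain, .data$resnum, .data$resname) |>
    summarise(sasa = sum(.data$sasa), .groups = "drop") |>
    arrange(.data$chain, .data$resnum)
  if (reference == "theoretical") {
    res$rsa <- res$sasa / unname(.max_asa[res$resname])
  } else {
    key <- paste(atoms$chain, atoms$resnum)
    max_sasa <- vapply_dbl(paste(res$chain, res$resnum), function(k) {
      sel <- key == k
      sum(sasa_atoms(xyz[sel, , drop = FALSE], atoms$element[sel],
                     probe = probe, n_points = n_points))
    })
    res$rsa <- res$sasa / unname(max_sasa)
  }
  res
}
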