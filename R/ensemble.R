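#' Mean inter-chain residue contact counts
#'
#' Per frame, a residue of one chain scores one contact per distinct residue
#' of the other chain having any heavy-atom pair within `cutoff`; the table
#' reports the mean count over frames for both chains.
#'
#' @param ens A `coord_ensemble`.
#' @param chain_a,chain_b Chain identifiers.
#' @param cutoff Heavy-atom distance cutoff in Angstrom.
#' @param granularity `"residue"` counts distinct partner residues;
#'   `"atom"` counts contacting heavy-atom pairs.
#' @return Tibble with `chain`, `resnum`, `contacts` (mean over frames).
#' @export
interface_contacts <- function(ens, chain_a, chain_b, cutoff = 3.5,
                               granularity = c("residue", "atom")) {
  granularity <- match.arg(granularity)
  atoms <- ens$atoms
  heavy <- toupper(atoms$element) != "H"
  ia <- which(heavy & atoms$chain == chain_a)
  ib <- which(heavy & atoms$chain == chain_b)
  if (length(ia) == 0 || length(ib) == 0) abort("empty chain selection")
  res_a <- atoms$resnum[ia]
  res_b <- atoms$resnum[ib]
  ua <- sort(unique(res_a)); ub <- sort(unique(res_b))
  acc_a <- setNames(numeric(length(ua)), ua)
  acc_b <- setNames(numeric(length(ub)), ub)
  nf <- n_frames(ens)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(ens, f)
    d <- cross_distances(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
    hit <- d <= cutoff
    if (granularity == "residue") {
      pairs <- unique(cbind(res_a[row(hit)[hit]], res_b[col(hit)[hit]]))
      if (length(pairs) > 0) {
        ta <- table(pairs[, 1]); tb <- table(pairs[, 2])
        acc_a[names(ta)] <- acc_a[names(ta)] + as.numeric(ta)
        acc_b[names(tb)] <- acc_b[names(tb)] + as.numeric(tb)
      }
    } else {
      ta <- tapply(rowSums(hit), res_a, sum)
      tb <- tapply(colSums(hit), res_b, sum)
      acc_a[names(ta)] <- acc_a[names(ta)] + ta
      acc_b[names(tb)] <- acc_b[names(tb)] + tb
    }
  }
  bind_rows(
    tibble(chain = chain_a, resnum = as.integer(names(acc_a)),
           contacts = unname(acc_a) / nf),
    tibble(chain = chain_b, resnum = as.integer(names(acc_b)),
           contacts = unname(acc_b) / nf))
}

propensity_class <- function(fraction, stable = 0.5, transient = 0.1) {
  ifelse(fraction >= stable, "stable",
         ifelse(fraction >= transient, "transient", "absent"))
}

#' Hydrogen-bond propensity across an ensemble
#'
#' Fraction of frames in which any donor-acceptor pair satisfies both the
#' heavy-atom distance and the D-H...A angle criterion (any attached
#' hydrogen, any acceptor atom in the selection). When the ensemble carries
#' no hydrogens on the donors, detection degrades to the distance criterion
#' alone, with a warning.
#'
#' @param ens A `coord_ensemble`.
#' @param donor_sel,acceptor_sel Selection strings ([select_atoms()]) for the
#'   donor heavy atoms and the acceptor atoms.
#' @param dist Donor-acceptor heavy-atom distance cutoff (Angstrom).
#' @param angle Minimum D-H...A angle in degrees.
#' @return One-row tibble: `fraction`, `class` (stable/transient/absent).
#' @export
hbond_propensity <- function(ens, donor_sel, acceptor_sel,
                             dist = 3.5, angle = 135) {
  atoms <- ens$atoms
  don <- select_atoms(ens, donor_sel)
  acc <- select_atoms(ens, acceptor_sel)
  if (length(don) == 0 || length(acc) == 0) abort("empty donor/acceptor selection")
  # hydrogens attached to each donor: same residue, name starts with H,
  # within 1.3 A in the first frame
  xyz1 <- frame_coords(ens, 1L)
  hyd <- lapply(don, function(i) {
    cand <- which(atoms$chain == atoms$chain[i] &
                    atoms$resnum == atoms$resnum[i] &
                    toupper(atoms$element) == "H")
    if (length(cand) == 0) return(integer())
    cand[cross_distances(xyz1[cand, , drop = FALSE],
                         xyz1[i, , drop = FALSE])[, 1] < 1.3]
  })
  use_angle <- any(lengths(hyd) > 0)
  if (!use_angle) {
    warn("no donor hydrogens found; hydrogen bonds detected by heavy-atom distance only")
  }
  nf <- n_frames(ens)
  hits <- 0L
  for (f in seq_len(nf)) {
    xyz <- frame_coords(ens, f)
    satisfied <- FALSE
    for (k in seq_along(don)) {
      i <- don[k]
      d_da <- cross_distances(xyz[i, , drop = FALSE],
                              xyz[acc, , drop = FALSE])[1, ]
      close <- which(d_da <= dist)
      if (length(close) == 0) next
      if (!use_angle || length(hyd[[k]]) == 0) { satisfied <- TRUE; break }
      for (j in acc[close]) {
        for (h in hyd[[k]]) {
          v1 <- xyz[i, ] - xyz[h, ]
          v2 <- xyz[j, ] - xyz[h, ]
          ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                     sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
          if (ang >= angle) { satisfied <- TRUE; break }
        }
        if (satisfied) break
      }
      if (satisfied) break
    }
    hits <- hits + satisfied
  }
  frac <- hits / nf
  tibble(donor = donor_sel, acceptor = acceptor_sel, fraction = frac,
         class = propensity_class(frac))
}

#' Salt-bridge propensity across an ensemble
#'
#' Fraction of frames with any basic side-chain nitrogen within `cutoff` of
#' any acidic side-chain (or phosphate) oxygen. Classified stable at >= 0.5,
#' transient in 0.1-0.5, absent below.
#'
#' @param ens A `coord_ensemble`.
#' @param basic_sel,acidic_sel Selection strings; the basic selection is
#'   restricted to nitrogen atoms and the acidic one to oxygens.
#' @param cutoff N-O distance cutoff (Angstrom).
#' @param stable,transient Classification thresholds on the frame fraction.
#' @return One-row tibble: `fraction`, `class`.
#' @export
salt_bridge_propensity <- function(ens, basic_sel, acidic_sel, cutoff = 4.0,
                                   stable = 0.5, transient = 0.1) {
  atoms <- ens$atoms
  bi <- intersect(select_atoms(ens, basic_sel),
                  which(toupper(atoms$element) == "N"))
  ai <- intersect(select_atoms(ens, acidic_sel),
                  which(toupper(atoms$element) == "O"))
  if (length(bi) == 0 || length(ai) == 0) abort("empty basic/acidic selection")
  nf <- n_frames(ens)
  hits <- 0L
  for (f in seq_len(nf)) {
    xyz <- frame_coords(ens, f)
    d <- cross_distances(xyz[bi, , drop = FALSE], xyz[ai, , drop = FALSE])
    hits <- hits + any(d <= cutoff)
  }
  frac <- hits / nf
  tibble(basic = basic_sel, acidic = acidic_sel, fraction = frac,
         class = propensity_class(frac, stable, transient))
}

#' Distance distribution between two selections
#'
#' Per frame, the distance between the mass-weighted centers (or single
#' atoms) of two selections; returned as a normalized histogram plus mean
#' and standard deviation.
#'
#' @param ens A `coord_ensemble`.
#' @param sel_a,sel_b Selection strings.
#' @param bin_width Histogram bin width (Angstrom).
#' @return List with `histogram` (tibble: `mid`, `density`; densities sum to
#'   1), `distances`, `mean`, `sd`.
#' @export
distance_distribution <- function(ens, sel_a, sel_b, bin_width = 0.2) {
  ca <- center_of_mass(ens, select_atoms(ens, sel_a))
  cb <- center_of_mass(ens, select_atoms(ens, sel_b))
  d <- sqrt(rowSums((ca - cb)^2))
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- hist(d, breaks = breaks, plot = FALSE)
  list(histogram = tibble(mid = h$mids, density = h$counts / sum(h$counts)),
       distances = d, mean = mean(d), sd = sqrt(mean((d - mean(d))^2)))
}

#' Per-residue C-alpha RMSD about the ensemble mean structure
#'
#' Frames are least-squares superposed on the alignment selection, a mean
#' structure is computed, and frames are re-superposed on the mean (two
#' iterations). The per-residue RMSD is the root-mean-square over frames of
#' each residue's C-alpha deviation from the mean structure.
#'
#' @param ens A `coord_ensemble` with at least two frames.
#' @param residue_range Selection string for the residues to report (their
#'   CA atoms are used).
#' @param align_sel Selection string for the alignment atoms (>= 3 atoms).
#' @return List with `per_residue` (tibble: `chain`, `resnum`, `rmsd`) and
#'   `range_mean`.
#' @export
per_residue_rmsd <- function(ens, residue_range, align_sel) {
  if (n_frames(ens) < 2) abort("need at least two frames")
  fit_idx <- select_atoms(ens, align_sel)
  if (length(fit_idx) < 3) abort("alignment selection must contain >= 3 atoms")
  ca_idx <- intersect(select_atoms(ens, residue_range),
                      which(ens$atoms$atom == "CA"))
  nf <- n_frames(ens)
  frames <- lapply(seq_len(nf), function(f) frame_coords(ens, f))
  ref <- frames[[1]]
  for (iter in 1:2) {
    fitted <- lapply(frames, kabsch_fit, ref = ref, fit_idx = fit_idx)
    ref <- Reduce(`+`, fitted) / nf
  }
  fitted <- lapply(frames, kabsch_fit, ref = ref, fit_idx = fit_idx)
  dev2 <- sapply(fitted, function(m) rowSums((m[ca_idx, , drop = FALSE] -
                                                ref[ca_idx, , drop = FALSE])^2))
  rmsd <- sqrt(rowMeans(matrix(dev2, nrow = length(ca_idx))))
  per_res <- tibble(chain = ens$atoms$chain[ca_idx],
                    resnum = ens$atoms$resnum[ca_idx], rmsd = rmsd)
  list(per_residue = per_res, range_mean = mean(rmsd))
}

#' Buried surface area between two chains
#'
#' `BSA = SASA(A alone) + SASA(B alone) - SASA(complex)` per frame, averaged
#' over frames; the total over both surfaces (set `halve_bsa = TRUE` for the
#' per-surface convention). SASA uses the fixed-lattice rolling-probe method.
#'
#' @param ens A `coord_ensemble`.
#' @param chain_a,chain_b Chain identifiers.
#' @param probe Probe radius (Angstrom).
#' @param n_points SASA lattice points per atom.
#' @param halve_bsa Halve the total (per-surface convention).
#' @return Mean BSA in Angstrom^2.
#' @export
buried_surface_area <- function(ens, chain_a, chain_b, probe = 1.4,
                                n_points = 960, halve_bsa = FALSE) {
  atoms <- ens$atoms
  ia <- which(atoms$chain == chain_a)
  ib <- which(atoms$chain == chain_b)
  if (length(ia) == 0 || length(ib) == 0) abort("empty chain selection")
  ic <- c(ia, ib)
  nf <- n_frames(ens)
  bsa <- numeric(nf)
  for (f in seq_len(nf)) {
    # one canonical frame for the complex so the isolated-chain terms use
    # the same lattice orientation and a noninteracting pair gives exactly 0
    xyz <- canonical_frame(frame_coords(ens, f)[ic, , drop = FALSE])
    sel_a <- seq_along(ia)
    sel_b <- length(ia) + seq_along(ib)
    sa <- sum(sasa_atoms(xyz[sel_a, , drop = FALSE], atoms$element[ia],
                         probe, n_points, canonicalize = FALSE))
    sb <- sum(sasa_atoms(xyz[sel_b, , drop = FALSE], atoms$element[ib],
                         probe, n_points, canonicalize = FALSE))
    sc <- sum(sasa_atoms(xyz, atoms$element[ic], probe, n_points,
                         canonicalize = FALSE))
    bsa[f] <- sa + sb - sc
  }
  out <- mean(bsa)
  if (halve_bsa) out / 2 else out
}
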