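# small in-code fixtures shared across test files

# a minimal peak table with adjustable shifts
make_peaks <- function(shift_h, shift_x, residues = seq_along(shift_h),
                       nucleus = "C13", intensity = 100, snr = 50,
                       atom_group = "CG",
                       resname = rep("LEU", length(shift_h)),
                       state_id = "free") {
  peak_table(tibble::tibble(
    residue = residues, resname = resname,
    atom_group = atom_group, nucleus = nucleus,
    shift_h = shift_h, shift_x = shift_x,
    intensity = intensity, snr = snr), state_id = state_id)
}

# two-chain micro ensemble: n_frames copies of explicit coordinates
make_micro_ensemble <- function(coords_list, atoms) {
  arr <- array(0, c(length(coords_list), nrow(atoms), 3))
  for (f in seq_along(coords_list)) arr[f, , ] <- coords_list[[f]]
  coord_ensemble(atoms, arr)
}

micro_atoms <- function(chain, resnum, resname, atom, element) {
  tibble::tibble(chain = chain, resnum = resnum, resname = resname,
                 atom = atom, element = element)
}

# a pair of atoms on two chains separated by `d` along x, replicated per frame
two_atom_ensemble <- function(d, n_frames = 3, element = "C") {
  atoms <- micro_atoms(c("A", "B"), c(1L, 1L), c("ALA", "ALA"),
                       c("CB", "CB"), c(element, element))
  xyz <- rbind(c(0, 0, 0), c(d, 0, 0))
  make_micro_ensemble(rep(list(xyz), n_frames), atoms)
}

hbond_frame <- function(ok) {
  # donor N with H, acceptor O; `ok` gives ideal linear geometry at 2.9 A
  if (ok) rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0))
  else rbind(c(0, 0, 0), c(1, 0, 0), c(4.0, 0, 0))
}

# independent brute-force PRE oracle: plain nested loops over frames, labels
# and protons, no shared code with gamma2_ensemble beyond the rate formula
brute_force_gamma2 <- function(ensemble, labels, probes, params) {
  tc <- 1 / (1 / (params$tau_r * 1e-9) + 1 / (params$tau_s * 1e-9))
  omega <- 2 * pi * params$field_mhz * 1e6
  spectral <- 4 * tc + 3 * tc / (1 + omega^2 * tc^2)
  out <- numeric(nrow(probes))
  for (ip in seq_len(nrow(probes))) {
    pr <- probes[ip, ]
    hsel <- which(ensemble$atoms$chain == pr$chain &
                    ensemble$atoms$resnum == pr$resnum &
                    startsWith(ensemble$atoms$atom,
                               paste0("H", sub("^C", "", pr$atom_group))))
    frame_vals <- numeric(0)
    for (f in seq_len(dim(ensemble$coords)[1])) {
      proton_vals <- numeric(0)
      for (h in hsel) {
        lab_vals <- numeric(0)
        for (l in seq_len(nrow(labels[[f]]))) {
          r <- sqrt(sum((ensemble$coords[f, h, ] - labels[[f]][l, ])^2))
          lab_vals <- c(lab_vals, params$kappa * spectral * (r * 1e-8)^-6)
        }
        proton_vals <- c(proton_vals, mean(lab_vals))
      }
      frame_vals <- c(frame_vals, mean(proton_vals))
    }
    out[ip] <- mean(frame_vals)
  }
  out
}
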