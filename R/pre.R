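#' Parameters of the PRE forward calculation
#'
#' @param kappa Electron-proton dipolar constant (cm^6 s^-2).
#' @param tau_r Protein rotational correlation time (ns).
#' @param tau_s Electron longitudinal relaxation time (ns).
#' @param field_mhz Proton Larmor frequency (MHz).
#' @param t_evolution Total evolution time of the pulse sequence (s).
#' @param r2_default Intrinsic transverse relaxation rate (s^-1) used for
#'   probes lacking a diamagnetic linewidth.
#' @return List of class `pre_params`. The effective correlation time
#'   `tau_c` is derived, never stored: `1/tau_c = 1/tau_r + 1/tau_s`.
#' @export
pre_params <- function(kappa = 1.23e-32, tau_r = 70, tau_s = 100,
                       field_mhz = 850, t_evolution = 6.89e-3,
                       r2_default = 30) {
  stopifnot_named("all PRE parameters must be positive" =
                    c(kappa, tau_r, tau_s, field_mhz, t_evolution,
                      r2_default) > 0)
  structure(list(kappa = kappa, tau_r = tau_r, tau_s = tau_s,
                 field_mhz = field_mhz, t_evolution = t_evolution,
                 r2_default = r2_default),
            class = "pre_params")
}

#' Effective electron-nuclear correlation time
#'
#' Harmonic combination of the rotational and electronic relaxation times:
#' `1/tau_c = 1/tau_r + 1/tau_s`.
#'
#' @param params A [pre_params()].
#' @return tau_c in seconds.
#' @export
tau_c <- function(params) {
  1 / (1 / (params$tau_r * 1e-9) + 1 / (params$tau_s * 1e-9))
}

#' Transverse PRE rate for a single electron-proton distance
#'
#' Solomon-Bloembergen transverse rate
#' `Gamma_2 = kappa * (4 tau_c + 3 tau_c / (1 + omega_H^2 tau_c^2)) * r^-6`,
#' with the distance converted from Angstrom to cm before applying `kappa`
#' and `omega_H = 2 pi * field_mhz * 1e6` rad/s.
#'
#' @param r Electron-proton distance in Angstrom (vectorized).
#' @param params A [pre_params()].
#' @return Gamma_2 in s^-1.
#' @export
gamma2_single <- function(r, params = pre_params()) {
  if (any(r <= 0)) abort("electron-proton distance must be positive")
  tc <- tau_c(params)
  omega <- 2 * pi * params$field_mhz * 1e6
  spectral <- 4 * tc + 3 * tc / (1 + omega^2 * tc^2)
  params$kappa * spectral * (r * 1e-8)^-6
}

#' Intrinsic R2 from a diamagnetic linewidth
#'
#' Lorentzian relation `R2 = pi * delta_nu_half`.
#'
#' @param linewidth_h Half-height proton linewidth (Hz).
#' @return R2 in s^-1.
#' @export
r2_from_linewidth <- function(linewidth_h) {
  if (any(!is.finite(linewidth_h)) || any(linewidth_h <= 0)) {
    abort("linewidth must be positive and finite")
  }
  pi * linewidth_h
}

#' Convert a PRE rate to a paramagnetic/diamagnetic intensity ratio
#'
#' `I/I0 = R2 * exp(-Gamma_2 * t) / (R2 + Gamma_2)`; monotone decreasing in
#' `Gamma_2`, equal to 1 at `Gamma_2 = 0`.
#'
#' @param gamma2 PRE rate (s^-1), vectorized.
#' @param r2 Intrinsic transverse relaxation rate (s^-1).
#' @param params A [pre_params()] supplying the evolution time.
#' @return Dimensionless intensity ratio in `[0, 1]`.
#' @export
gamma_to_ratio <- function(gamma2, r2 = NULL, params = pre_params()) {
  r2 <- r2 %||% params$r2_default
  if (any(r2 <= 0)) abort("R2 must be positive")
  if (any(gamma2 < 0)) abort("Gamma_2 must be nonnegative")
  r2 * exp(-gamma2 * params$t_evolution) / (r2 + gamma2)
}

#' Back-calculate PRE rates from a coordinate ensemble
#'
#' For each frame, the PRE rate of each probe proton is averaged over the `N`
#' spin-label positions of that frame; methyl probes then average their three
#' proton rates, and the per-frame values are arithmetically averaged over
#' frames (fast-exchange convention: averaging is done on rates, the
#' conversion to intensity ratios happens once at the end).
#'
#' @param ensemble A `coord_ensemble`.
#' @param labels A list with one `n_positions x 3` matrix of electron
#'   coordinates per frame (a `label_ensemble` from [place_label_ensemble()]
#'   or [gen_toy_complex()]), optionally with a `weights` attribute per frame.
#' @param probes Tibble with columns `probe`, `chain`, `resnum`, `atom_group`;
#'   probe protons are all hydrogens named `H<atom_group>*` of that residue
#'   (or the heavy atom itself when the ensemble lacks hydrogens).
#' @param params A [pre_params()].
#' @return Tibble with `probe`, `gamma2` (s^-1) and `ratio` (I/I0 at
#'   `params$r2_default`).
#' @export
gamma2_ensemble <- function(ensemble, labels, probes, params = pre_params()) {
  nf <- n_frames(ensemble)
  if (length(labels) != nf) {
    abort("label ensemble and coordinate ensemble disagree in frame count")
  }
  atoms <- ensemble$atoms
  idx_list <- lapply(seq_len(nrow(probes)), function(i) {
    p <- probes[i, ]
    # methyl carbon "CD1" carries protons "HD11/HD12/HD13" (PDB convention)
    h_prefix <- paste0("H", sub("^C", "", p$atom_group))
    sel <- atoms$chain == p$chain & atoms$resnum == p$resnum &
      startsWith(atoms$atom, h_prefix)
    if (!any(sel)) {  # heavy-atom fallback for proton-less ensembles
      sel <- atoms$chain == p$chain & atoms$resnum == p$resnum &
        atoms$atom == p$atom_group
    }
    if (!any(sel)) {
      abort(paste0("probe atoms not found for probe ", p$probe))
    }
    which(sel)
  })
  acc <- numeric(nrow(probes))
  for (f in seq_len(nf)) {
    xyz <- frame_coords(ensemble, f)
    lab <- labels[[f]]
    w <- attr(lab, "weights") %||% rep(1 / nrow(lab), nrow(lab))
    for (i in seq_along(idx_list)) {
      d <- cross_distances(xyz[idx_list[[i]], , drop = FALSE], lab)
      g_per_label <- gamma2_single(d, params)        # protons x labels
      # weight over label positions, then average over the probe's protons
      acc[i] <- acc[i] + mean(g_per_label %*% w)
    }
  }
  gamma2 <- acc / nf
  tibble(probe = probes$probe, gamma2 = gamma2,
         ratio = gamma_to_ratio(gamma2, params = params))
}

#' Place a simple tether ensemble for a spin label
#'
#' When no explicit label-position ensemble is available, positions the
#' paramagnetic centre on a sphere of fixed tether length around a chosen
#' anchor atom (conventionally the C-beta of the labelled residue), at
#' `n_positions` deterministic quasi-uniform orientations, replicated for
#' every frame of the ensemble.
#'
#' @param ensemble A `coord_ensemble`.
#' @param chain,resnum,atom Anchor atom of the labelled residue.
#' @param tether Tether length in Angstrom.
#' @param n_positions Number of label orientations per frame.
#' @return A list of `n_positions x 3` matrices, one per frame.
#' @export
place_label_ensemble <- function(ensemble, chain, resnum, atom = "CB",
                                 tether = 8, n_positions = 20) {
  sel <- which(ensemble$atoms$chain == chain &
                 ensemble$atoms$resnum == resnum &
                 ensemble$atoms$atom == atom)
  if (length(sel) != 1) abort("label anchor atom not found (or ambiguous)")
  dirs <- sphere_points(n_positions) * tether
  lapply(seq_len(n_frames(ensemble)), function(f) {
    sweep(dirs, 2, frame_coords(ensemble, f)[sel, ], "+")
  })
}
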