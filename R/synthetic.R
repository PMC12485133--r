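#' Specification of the synthetic data generators
#'
#' Bundles every knob of the synthetic-data generators with its ground truth,
#' so each pipeline stage can be tested against known answers. All generators
#' are pure functions of (spec, seed): identical seeds give identical output.
#'
#' @param seed Integer seed.
#' @param n_frames Frames per conformational state ensemble.
#' @param jitter_sd Per-atom Gaussian jitter between frames (Angstrom).
#' @param state_populations Populations of the two poses (sum to 1); the
#'   first is the major state.
#' @param interface_residues Chain-B residue numbers receiving injected
#'   perturbations in the bound peak table.
#' @param interface_delta Injected proton shift change (ppm) for interface
#'   residues.
#' @param pre_noise_sd Gaussian noise on synthetic intensity ratios.
#' @param kinetic_noise_sd Gaussian noise on synthetic endpoint fractions.
#' @param replicates Replicate count for kinetic curves.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1, n_frames = 10, jitter_sd = 0.3,
                           state_populations = c(0.9, 0.1),
                           interface_residues = c(6, 8, 10, 12, 14),
                           interface_delta = 0.15,
                           pre_noise_sd = 0.03, kinetic_noise_sd = 0.03,
                           replicates = 1) {
  stopifnot_named(
    "populations must sum to 1" = abs(sum(state_populations) - 1) < 1e-12,
    "noise sds must be nonnegative" = c(pre_noise_sd, kinetic_noise_sd,
                                        jitter_sd) >= 0,
    "two states required" = length(state_populations) == 2
  )
  structure(list(seed = seed, n_frames = n_frames, jitter_sd = jitter_sd,
                 state_populations = state_populations,
                 interface_residues = interface_residues,
                 interface_delta = interface_delta,
                 pre_noise_sd = pre_noise_sd,
                 kinetic_noise_sd = kinetic_noise_sd,
                 replicates = replicates),
            class = "synthetic_spec")
}

# idealized helical pseudo-protein chain: N, CA, C, O, CB per residue, plus a
# methyl group (CG + 3 protons) on the probe residues
build_chain <- function(chain_id, n_res = 30, probe_residues = integer(),
                        origin = c(0, 0, 0), flip = FALSE) {
  resnames <- rep(c("ILE", "LEU", "VAL", "ALA", "THR", "SER"), length.out = n_res)
  rows <- list(); xyz <- list()
  for (i in seq_len(n_res)) {
    ang <- 100 * pi / 180 * i
    radial <- c(cos(ang), sin(ang), 0)
    if (flip) radial <- -radial
    ca <- origin + c(2.3 * radial[1:2], 1.6 * i)
    add <- function(name, elem, pos) {
      rows[[length(rows) + 1]] <<- tibble(chain = chain_id, resnum = i,
                                          resname = resnames[i], atom = name,
                                          element = elem)
      xyz[[length(xyz) + 1]] <<- pos
    }
    add("N", "N", ca + c(-1.2, 0.3, -0.5))
    add("CA", "C", ca)
    add("C", "C", ca + c(1.2, 0.4, 0.5))
    add("O", "O", ca + c(1.9, 1.3, 0.3))
    cb <- ca + 1.5 * radial
    add("CB", "C", cb)
    if (i %in% probe_residues) {
      cg <- ca + 3.0 * radial
      add("CG", "C", cg)
      add("HG1", "H", cg + c(0.6, 0.6, 0.6))
      add("HG2", "H", cg + c(-0.6, -0.6, 0.6))
      add("HG3", "H", cg + c(0.6, -0.6, -0.6))
    }
  }
  list(atoms = bind_rows(rows), xyz = do.call(rbind, xyz))
}

#' Generate a toy two-chain complex in two poses
#'
#' Builds two compact idealized chains (~30 residues each): chain A carries a
#' spin-label site (C-beta anchor, 10 label positions per frame on a fixed
#' tether), chain B carries a methyl probe on every residue. The two states place chain
#' B on opposite sides of chain A: the major pose spans the strongly
#' broadened (I/I0 < 0.2) through unperturbed (> 0.8) regimes, while the
#' minor pose brings its own probe patch near the label, which is what makes
#' the minor population resolvable (its probes respond ~1/rho_b times more
#' strongly to the population than major-pose probes).
#' Frames are Gaussian-jittered copies of the ideal pose.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `state_a`/`state_b` (`coord_ensemble`s), `labels_a` /
#'   `labels_b` (label-position lists), `probes`, `label_site`, and `truth`
#'   (effective label-probe distances per state, jitter-free geometry).
#' @export
gen_toy_complex <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  probe_res <- 1:30
  cha <- build_chain("A", 30)
  label_res <- 15
  chb_a <- build_chain("B", 30, probe_residues = probe_res,
                       origin = c(24, 0, 0))
  chb_b <- build_chain("B", 30, probe_residues = probe_res,
                       origin = c(-14, 2, 0), flip = TRUE)
  atoms <- bind_rows(cha$atoms, chb_a$atoms)
  mk_ensemble <- function(chb) {
    base <- rbind(cha$xyz, chb$xyz)
    coords <- array(0, c(spec$n_frames, nrow(base), 3))
    for (f in seq_len(spec$n_frames)) {
      coords[f, , ] <- base + rnorm(length(base), sd = spec$jitter_sd)
    }
    coord_ensemble(atoms, coords)
  }
  state_a <- mk_ensemble(chb_a)
  state_b <- mk_ensemble(chb_b)
  label_site <- list(chain = "A", resnum = label_res, atom = "CB")
  labels_a <- place_label_ensemble(state_a, "A", label_res, "CB",
                                   tether = 8, n_positions = 10)
  labels_b <- place_label_ensemble(state_b, "A", label_res, "CB",
                                   tether = 8, n_positions = 10)
  probes <- tibble(chain = "B", resnum = probe_res,
                   resname = atoms$resname[match(probe_res, atoms$resnum)],
                   atom_group = "CG") |>
    mutate(probe = probe_id(.data$resnum, .data$resname, .data$atom_group))
  # jitter-free effective distances: <r^-6>^(-1/6) over labels x protons
  eff_dist <- function(chb) {
    base <- rbind(cha$xyz, chb$xyz)
    anchor <- base[atoms$chain == "A" & atoms$resnum == label_res &
                     atoms$atom == "CB", , drop = FALSE]
    lab <- sweep(sphere_points(10) * 8, 2, anchor[1, ], "+")
    vapply_dbl(probes$resnum, function(rn) {
      hsel <- atoms$chain == "B" & atoms$resnum == rn &
        startsWith(atoms$atom, "HG")
      d <- cross_distances(base[hsel, , drop = FALSE], lab)
      mean(d^-6)^(-1 / 6)
    })
  }
  truth <- tibble(probe = probes$probe,
                  dist_state_a = eff_dist(chb_a),
                  dist_state_b = eff_dist(chb_b))
  list(state_a = state_a, state_b = state_b,
       labels_a = labels_a, labels_b = labels_b,
       probes = probes, label_site = label_site, truth = truth, spec = spec)
}

#' Generate an experimental-like PRE profile from a toy complex
#'
#' Forward-calculates the pure-state intensity-ratio profiles, mixes the
#' underlying PRE rates by the state populations, converts once to ratios,
#' adds truncated Gaussian noise (clipped to `[0, 1]`) and marks ratios below
#' 0.02 as vanished.
#'
#' @param toy Output of [gen_toy_complex()].
#' @param populations Two state populations (default: the toy's spec).
#' @param params A [pre_params()].
#' @param noise_sd Gaussian noise sd on the ratios.
#' @param seed Seed for the noise draws.
#' @return Tibble with `probe`, `residue`, `resname`, `atom_group`, `ratio`,
#'   `ratio_error`, `vanished`; attributes `"profile_a"`/`"profile_b"` carry
#'   the pure-state back-calculations.
#' @export
gen_pre_profiles <- function(toy, populations = toy$spec$state_populations,
                             params = pre_params(),
                             noise_sd = toy$spec$pre_noise_sd,
                             seed = toy$spec$seed) {
  prof_a <- gamma2_ensemble(toy$state_a, toy$labels_a, toy$probes, params)
  prof_b <- gamma2_ensemble(toy$state_b, toy$labels_b, toy$probes, params)
  gamma_mix <- populations[1] * prof_a$gamma2 + populations[2] * prof_b$gamma2
  ratio <- gamma_to_ratio(gamma_mix, params = params)
  set.seed(seed)
  if (noise_sd > 0) {
    ratio <- pmin(pmax(ratio + rnorm(length(ratio), sd = noise_sd), 0), 1)
  }
  out <- tibble(probe = toy$probes$probe, residue = toy$probes$resnum,
                resname = toy$probes$resname,
                atom_group = toy$probes$atom_group,
                ratio = ratio, ratio_error = noise_sd,
                vanished = ratio < 0.02)
  attr(out, "profile_a") <- prof_a
  attr(out, "profile_b") <- prof_b
  out
}

#' Generate free/bound peak tables with a known interface
#'
#' Baseline methyl shifts are drawn from residue-type-typical ranges; the
#' bound table adds the injected proton shift change to the interface
#' residues and digital-resolution-scale noise elsewhere, with
#' signal-to-noise ratios assigned so intensity-ratio error propagation is
#' exercisable.
#'
#' @param spec A [synthetic_spec()].
#' @param residues Probed residue numbers (default: the toy probe set).
#' @param resnames Residue names (recycled).
#' @param noise_ppm Proton-shift noise applied to non-interface residues in
#'   the bound state (0 gives the exactly recoverable noiseless case).
#' @return List with `free` and `bound` [peak_table()]s.
#' @export
gen_peak_tables <- function(spec = synthetic_spec(),
                            residues = seq(2, 30, by = 2),
                            resnames = c("ILE", "LEU", "VAL", "ALA", "THR",
                                         "SER"),
                            noise_ppm = 0.002) {
  set.seed(spec$seed)
  n <- length(residues)
  base <- tibble(
    residue = residues,
    resname = rep(resnames, length.out = 30)[residues],
    atom_group = "CG", nucleus = "C13",
    shift_h = runif(n, 0.3, 1.4), shift_x = runif(n, 12, 25),
    intensity = runif(n, 50, 150), snr = runif(n, 20, 60),
    linewidth_h = runif(n, 8, 15))
  bound <- base
  on_interface <- base$residue %in% spec$interface_residues
  bound$shift_h <- bound$shift_h + ifelse(on_interface, spec$interface_delta, 0)
  if (noise_ppm > 0) {
    bound$shift_h <- bound$shift_h +
      ifelse(on_interface, 0, rnorm(n, sd = noise_ppm))
  }
  bound$intensity <- bound$intensity * runif(n, 0.6, 0.9)
  list(free = peak_table(base, state_id = "free"),
       bound = peak_table(bound, state_id = "bound"))
}

#' Generate noisy endpoint titration data from the kinetic model
#'
#' Simulates titration curves at ground-truth parameters for a list of assay
#' conditions and adds truncated Gaussian noise (clipped to `[0, 1]`), with
#' the stated replicate count.
#'
#' @param params Ground-truth [kinetic_params()].
#' @param conditions List of [assay_condition()]s.
#' @param noise_sd Gaussian noise sd on fractions.
#' @param replicates Replicates per concentration.
#' @param seed Seed for the noise draws.
#' @return List of `list(condition, curve)` entries ready for [fit_global()];
#'   each curve has `conc`, `fraction`, `sd` and a `"true_fraction"` column.
#' @export
gen_kinetic_data <- function(params = default_kinetic_params(),
                             conditions = default_fit_conditions(),
                             noise_sd = 0.03, replicates = 1, seed = 1) {
  set.seed(seed)
  lapply(conditions, function(cond) {
    network <- build_network(cond, params)
    clean <- titration_curve(network)
    curve <- clean[rep(seq_len(nrow(clean)), each = replicates), ]
    noisy <- curve$fraction
    if (noise_sd > 0) {
      noisy <- pmin(pmax(noisy + rnorm(length(noisy), sd = noise_sd), 0), 1)
    }
    list(condition = cond,
         curve = tibble(conc = curve$conc, fraction = noisy,
                        sd = max(noise_sd, 1e-6),
                        true_fraction = curve$fraction))
  })
}

#' Default condition set for global fitting
#'
#' The four endpoint assays fitted simultaneously: the GAP domain alone, the
#' tandem enzyme with and without PIP2, and the in-trans assay (GAP domain
#' titrated at fixed 5 uM PH).
#'
#' @param n_conc Concentrations per titration (log-spaced 1e-11 to 1e-4 M).
#' @return List of [assay_condition()]s.
#' @export
default_fit_conditions <- function(n_conc = 12) {
  grid <- 10^seq(-11, -4, length.out = n_conc)
  list(assay_condition("ZA", titration = grid),
       assay_condition("PZA", pip2_mol_percent = 0, titration = grid),
       assay_condition("PZA", titration = grid),
       assay_condition("trans", titration = grid))
}
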