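test_that("interface contacts respect the cutoff and average over frames", {
  expect_equal(interface_contacts(two_atom_ensemble(3.4), "A", "B")$contacts,
               c(1, 1))
  expect_equal(interface_contacts(two_atom_ensemble(3.6), "A", "B")$contacts,
               c(0, 0))
  # contact present in half the frames scores 0.5
  atoms <- micro_atoms(c("A", "B"), c(1L, 1L), "ALA", c("CB", "CB"), "C")
  half <- make_micro_ensemble(list(rbind(c(0, 0, 0), c(3, 0, 0)),
                                   rbind(c(0, 0, 0), c(6, 0, 0))), atoms)
  expect_equal(interface_contacts(half, "A", "B")$contacts, c(0.5, 0.5))
  # totals are symmetric across the two chains
  toy <- gen_toy_complex(synthetic_spec(seed = 4, n_frames = 3))
  ct <- interface_contacts(toy$state_a, "A", "B", cutoff = 6)
  expect_equal(sum(ct$contacts[ct$chain == "A"]),
               sum(ct$contacts[ct$chain == "B"]))
  expect_error(interface_contacts(toy$state_a, "A", "Z"), "empty chain")
})

test_that("hydrogen-bond propensity applies distance and angle criteria", {
  atoms <- micro_atoms(c("A", "A", "B"), c(1L, 1L, 2L), c("LYS", "LYS", "GLU"),
                       c("NZ", "HZ1", "OE1"), c("N", "H", "O"))
  ideal <- make_micro_ensemble(rep(list(hbond_frame(TRUE)), 4), atoms)
  expect_equal(hbond_propensity(ideal, "name NZ", "name OE1")$fraction, 1)
  far <- make_micro_ensemble(rep(list(hbond_frame(FALSE)), 4), atoms)
  expect_equal(hbond_propensity(far, "name NZ", "name OE1")$fraction, 0)
  # a bent D-H...A arrangement fails the angle criterion despite the distance
  bent <- make_micro_ensemble(
    list(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1.2, 0))), atoms)
  expect_equal(hbond_propensity(bent, "name NZ", "name OE1")$fraction, 0)
  # hydrogen-free ensembles degrade to distance-only detection with a warning
  atoms_noh <- atoms[-2, ]
  noh <- make_micro_ensemble(list(hbond_frame(TRUE)[-2, ]), atoms_noh)
  expect_warning(out <- hbond_propensity(noh, "name NZ", "name OE1"),
                 "distance only")
  expect_equal(out$fraction, 1)
})

test_that("a built-in 0.25 difference in H-bond satisfaction is recovered exactly", {
  atoms <- micro_atoms(c("A", "A", "B"), c(1L, 1L, 2L), c("LYS", "LYS", "GLU"),
                       c("NZ", "HZ1", "OE1"), c("N", "H", "O"))
  ens_lo <- make_micro_ensemble(
    c(rep(list(hbond_frame(TRUE)), 2), rep(list(hbond_frame(FALSE)), 6)),
    atoms)  # 25% satisfied
  ens_hi <- make_micro_ensemble(
    c(rep(list(hbond_frame(TRUE)), 4), rep(list(hbond_frame(FALSE)), 4)),
    atoms)  # 50% satisfied
  d <- hbond_propensity(ens_hi, "name NZ", "name OE1")$fraction -
    hbond_propensity(ens_lo, "name NZ", "name OE1")$fraction
  expect_equal(d, 0.25)
})

test_that("salt-bridge propensity classifies stable, transient and absent", {
  atoms <- micro_atoms(c("A", "B"), c(1L, 2L), c("ARG", "ASP"),
                       c("NH1", "OD1"), c("N", "O"))
  close_f <- rbind(c(0, 0, 0), c(3, 0, 0))
  far_f <- rbind(c(0, 0, 0), c(6, 0, 0))
  stable <- make_micro_ensemble(rep(list(close_f), 5), atoms)
  expect_equal(salt_bridge_propensity(stable, "resname ARG", "resname ASP")$class,
               "stable")
  trans <- make_micro_ensemble(c(rep(list(close_f), 3), rep(list(far_f), 7)),
                               atoms)
  out <- salt_bridge_propensity(trans, "resname ARG", "resname ASP")
  expect_equal(out$fraction, 0.3)
  expect_equal(out$class, "transient")
  absent <- make_micro_ensemble(c(rep(list(close_f), 1), rep(list(far_f), 19)),
                                atoms)
  expect_equal(salt_bridge_propensity(absent, "resname ARG",
                                      "resname ASP")$class, "absent")
})

test_that("distance distributions use mass-weighted centers and normalize", {
  # symmetric diatomic: COM at the midpoint
  atoms <- micro_atoms(c("A", "A", "B"), c(1L, 1L, 2L), "ALA",
                       c("C1", "C2", "CB"), "C")
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 5, 0))
  ens <- make_micro_ensemble(list(xyz), atoms)
  dd <- distance_distribution(ens, "chain A", "chain B")
  expect_equal(dd$mean, 5)
  expect_equal(dd$sd, 0)
  expect_equal(sum(dd$histogram$density), 1, tolerance = 1e-12)
  # two equal-weight distances average to their midpoint
  ens2 <- make_micro_ensemble(list(xyz, rbind(c(0, 0, 0), c(2, 0, 0),
                                              c(1, 7, 0))), atoms)
  dd2 <- distance_distribution(ens2, "chain A", "chain B")
  expect_equal(dd2$mean, 6)
  # unequal masses shift the center toward the heavy atom
  atoms_m <- micro_atoms(c("A", "A", "B"), c(1L, 1L, 2L), "ALA",
                         c("C1", "H1", "CB"), c("C", "H", "C"))
  com <- center_of_mass(make_micro_ensemble(list(xyz), atoms_m), 1:2)
  expect_lt(com[1, 1], 1)
})

test_that("per-residue RMSD matches the explicit two-frame oracle", {
  # chain A is the fixed alignment frame; one chain-B CA moves by delta
  delta <- 2
  atoms <- dplyr::bind_rows(
    micro_atoms("A", 1:4, "ALA", "CA", "C"),
    micro_atoms("B", 1L, "ALA", "CA", "C"))
  base <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3), c(5, 5, 5))
  moved <- base
  moved[5, 1] <- base[5, 1] + delta
  ens <- make_micro_ensemble(list(base, moved), atoms)
  out <- per_residue_rmsd(ens, "chain B", "chain A")
  # mean structure sits at delta/2; RMS over the two frames is delta/2
  expect_equal(out$per_residue$rmsd, delta / 2, tolerance = 1e-10)
  # identical frames give zero everywhere
  ens0 <- make_micro_ensemble(list(base, base), atoms)
  expect_equal(per_residue_rmsd(ens0, "chain B", "chain A")$range_mean, 0)
  expect_error(per_residue_rmsd(make_micro_ensemble(list(base), atoms),
                                "chain B", "chain A"), "two frames")
})

test_that("ensemble statistics are invariant under rigid motion", {
  toy <- gen_toy_complex(synthetic_spec(seed = 4, n_frames = 3))
  moved <- transform_ensemble(toy$state_a, angles = c(1.2, 0.4, -0.8),
                              translation = c(-7, 11, 3))
  ct1 <- interface_contacts(toy$state_a, "A", "B", cutoff = 6)
  ct2 <- interface_contacts(moved, "A", "B", cutoff = 6)
  expect_equal(ct2$contacts, ct1$contacts)
  dd1 <- distance_distribution(toy$state_a, "chain A and resid 1-5",
                               "chain B and resid 1-5")
  dd2 <- distance_distribution(moved, "chain A and resid 1-5",
                               "chain B and resid 1-5")
  expect_equal(dd2$mean, dd1$mean, tolerance = 1e-9)
  r1 <- per_residue_rmsd(toy$state_a, "chain B", "chain A and name CA")
  r2 <- per_residue_rmsd(moved, "chain B", "chain A and name CA")
  expect_equal(r2$per_residue$rmsd, r1$per_residue$rmsd, tolerance = 1e-6)
  b1 <- buried_surface_area(toy$state_a, "A", "B", n_points = 240)
  b2 <- buried_surface_area(moved, "A", "B", n_points = 240)
  expect_equal(b2, b1, tolerance = 1e-6)
})

test_that("buried surface area matches the two-sphere closed form", {
  # far-apart chains bury nothing
  expect_lt(abs(buried_surface_area(two_atom_ensemble(50, n_frames = 1),
                                    "A", "B")), 1)
  # two identical carbon spheres at center distance d: each buries a cap of
  # area 2*pi*R*h with h = R - d/2 on the accessible sphere R = r_vdw + probe
  d <- 3
  R <- 1.7 + 1.4
  analytic <- 2 * (2 * pi * R * (R - d / 2))
  num <- buried_surface_area(two_atom_ensemble(d, n_frames = 1), "A", "B",
                             n_points = 960)
  expect_equal(num, analytic, tolerance = 0.02)
  # halved convention available
  expect_equal(buried_surface_area(two_atom_ensemble(d, n_frames = 1),
                                   "A", "B", halve_bsa = TRUE),
               num / 2)
  # BSA is nonnegative up to lattice noise for arbitrary configurations
  toy <- gen_toy_complex(synthetic_spec(seed = 9, n_frames = 2))
  expect_gte(buried_surface_area(toy$state_a, "A", "B", n_points = 240), -1)
})

test_that("selection mini-grammar resolves chains, ranges, names, elements", {
  toy <- gen_toy_complex(synthetic_spec(seed = 1, n_frames = 1))
  idx <- select_atoms(toy$state_a, "chain A and resid 40-45 and name CA")
  expect_length(idx, 0)  # chain has 30 residues
  idx2 <- select_atoms(toy$state_a, "chain A and resid 10-12 and name CA")
  expect_equal(toy$state_a$atoms$resnum[idx2], 10:12)
  idx3 <- select_atoms(toy$state_a, "chain B and elem H")
  expect_true(all(toy$state_a$atoms$element[idx3] == "H"))
  expect_error(select_atoms(toy$state_a, "flavour good"), "unknown selection")
})
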