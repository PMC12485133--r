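test_that("tau_c is the harmonic combination of tau_R and tau_S", {
  expect_equal(tau_c(pre_params(tau_r = 70, tau_s = 100)), 700 / 17 * 1e-9)
  # tau_S -> infinity leaves tau_R
  expect_equal(tau_c(pre_params(tau_r = 70, tau_s = 1e12)), 70e-9,
               tolerance = 1e-6)
  # equal times halve
  expect_equal(tau_c(pre_params(tau_r = 8, tau_s = 8)), 4e-9)
})

test_that("gamma2_single follows the r^-6 dipolar law", {
  p <- pre_params()
  # frozen high-precision evaluation at the default parameters, r = 16 A:
  # tau_c = 700/17 ns, omega = 2*pi*850e6, kappa = 1.23e-32 cm^6 s^-2
  tc <- 700 / 17 * 1e-9
  om <- 2 * pi * 850e6
  expected <- 1.23e-32 * (4 * tc + 3 * tc / (1 + om^2 * tc^2)) * (16e-8)^-6
  expect_equal(gamma2_single(16, p), expected, tolerance = 1e-12)
  expect_equal(expected, 120.7, tolerance = 1e-3)
  # halving r multiplies the rate by exactly 2^6
  expect_equal(gamma2_single(8, p) / gamma2_single(16, p), 64)
  # large omega*tau_c limit: the spectral term collapses to 4*tau_c
  limit <- p$kappa * 4 * tc * (16e-8)^-6
  expect_equal(gamma2_single(16, p), limit, tolerance = 1e-4)
  expect_error(gamma2_single(0, p), "positive")
})

test_that("R2 from linewidth and the ratio conversion behave as stated", {
  expect_equal(r2_from_linewidth(10), pi * 10)
  expect_equal(r2_from_linewidth(20), 2 * r2_from_linewidth(10))
  expect_error(r2_from_linewidth(0), "positive")
  p <- pre_params()
  expect_equal(gamma_to_ratio(0, params = p), 1)
  expect_lt(gamma_to_ratio(1e7, params = p), 1e-10)
  # arithmetic oracle: Gamma_2 = R2 = 30, t = 6.89 ms
  expect_equal(gamma_to_ratio(30, r2 = 30, params = p),
               0.5 * exp(-30 * 6.89e-3), tolerance = 1e-12)
  # monotone decreasing in Gamma_2
  g <- seq(0, 500, by = 25)
  expect_true(all(diff(gamma_to_ratio(g, params = p)) < 0))
})

test_that("gamma2_ensemble matches a brute-force nested-loop oracle", {
  p <- pre_params()
  toy <- gen_toy_complex(synthetic_spec(seed = 11, n_frames = 10))
  probes <- toy$probes[1:3, ]
  labels <- lapply(toy$labels_a, function(m) m[1:5, , drop = FALSE])
  fast <- gamma2_ensemble(toy$state_a, labels, probes, p)
  slow <- brute_force_gamma2(toy$state_a, labels, probes, p)
  expect_equal(fast$gamma2, slow, tolerance = 1e-10)
  # degenerate ensemble: one frame, one label, one proton
  atoms <- micro_atoms("B", 1L, "LEU", c("CG", "HG1"), c("C", "H"))
  ens <- make_micro_ensemble(list(rbind(c(0, 0, 0), c(0, 0, 1))), atoms)
  lab <- list(matrix(c(0, 0, 13), 1, 3))
  pr <- tibble::tibble(probe = "1.LEU.CG", chain = "B", resnum = 1L,
                       atom_group = "CG")
  one <- gamma2_ensemble(ens, lab, pr, p)
  expect_equal(one$gamma2, gamma2_single(12, p))
  # two identical label positions equal one
  lab2 <- list(matrix(c(0, 0, 13, 0, 0, 13), 2, 3, byrow = TRUE))
  expect_equal(gamma2_ensemble(ens, lab2, pr, p)$gamma2, one$gamma2)
  # a missing probe atom is a hard error naming the probe
  pr_bad <- tibble::tibble(probe = "9.LEU.CG", chain = "B", resnum = 9L,
                           atom_group = "CG")
  expect_error(gamma2_ensemble(ens, lab, pr_bad, p), "9.LEU.CG")
})

test_that("two-state fit recovers populations, with convexity of mixtures", {
  toy <- gen_toy_complex(synthetic_spec(seed = 7))
  prof <- gen_pre_profiles(toy, populations = c(0.9, 0.1), noise_sd = 0)
  pa <- attr(prof, "profile_a"); pb <- attr(prof, "profile_b")
  fit <- fit_two_state(pa, pb, prof)
  expect_equal(fit$rho_a, 0.9, tolerance = 0.011)
  expect_equal(fit$slope, 1.0, tolerance = 1e-3)
  expect_gte(fit$pearson_r, 0.9999)
  # endpoints: experimental equals a pure state exactly (no vanished zeroing)
  pure_a <- tibble::tibble(probe = pa$probe, ratio = pa$ratio,
                           vanished = FALSE)
  expect_equal(fit_two_state(pa, pb, pure_a)$rho_a, 1)
  pure_b <- tibble::tibble(probe = pb$probe, ratio = pb$ratio,
                           vanished = FALSE)
  expect_equal(fit_two_state(pa, pb, pure_b)$rho_a, 0)
  # convex combination: every mixed ratio lies between the pure-state ratios
  for (rho in c(0.25, 0.6, 0.9)) {
    g <- rho * pa$gamma2 + (1 - rho) * pb$gamma2
    mix <- gamma_to_ratio(g, params = pre_params())
    expect_true(all(mix >= pmin(pa$ratio, pb$ratio) - 1e-12 &
                      mix <= pmax(pa$ratio, pb$ratio) + 1e-12))
  }
  # degenerate inputs are rejected
  expect_error(fit_two_state(pa[1:2, ], pb[1:2, ], prof), "fewer than 3")
  flat <- tibble::tibble(probe = pa$probe, ratio = rep(0.5, nrow(pa)),
                         vanished = FALSE)
  expect_error(fit_two_state(pa, pb, flat), "zero variance")
})

test_that("label placement is deterministic and anchored on the tether", {
  toy <- gen_toy_complex(synthetic_spec(seed = 2, n_frames = 2))
  lab <- place_label_ensemble(toy$state_a, "A", 15, "CB", tether = 8,
                              n_positions = 20)
  expect_length(lab, 2)
  anchor <- frame_coords(toy$state_a, 1)[
    which(toy$state_a$atoms$chain == "A" & toy$state_a$atoms$resnum == 15 &
            toy$state_a$atoms$atom == "CB"), ]
  d <- sqrt(rowSums(sweep(lab[[1]], 2, anchor)^2))
  expect_equal(d, rep(8, 20))
})
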