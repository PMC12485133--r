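params <- default_kinetic_params()

test_that("networks are assembled per construct with working toggles", {
  za <- build_network(assay_condition("ZA"), params)
  expect_false(any(grepl("PH|E_", za$species$name)))
  expect_equal(nrow(za$species), 4L)
  # no PIP2: membrane-anchored enzyme states stay empty
  pza0 <- build_network(assay_condition("PZA", pip2_mol_percent = 0), params)
  traj <- simulate_trajectory(pza0, 1e-6)
  expect_true(all(traj$E_m == 0 & traj$EA_m == 0))
  # alpha = 1 collapses both hydrolysis channels onto kcat_basal
  pza1 <- build_network(assay_condition("PZA"), params, alpha = 1)
  kcats <- pza1$reactions$rate[vapply(pza1$reactions$products,
                                      function(p) "ArfGDP" %in% p,
                                      logical(1))]
  expect_true(all(kcats == params$kcat_basal))
  expect_error(build_network(assay_condition("PZA"), params,
                             alpha = NULL)$condition, NA)
})

test_that("trajectories conserve every total and keep fractions in [0, 1]", {
  for (construct in c("ZA", "PZA", "PHdZA", "trans")) {
    net <- build_network(assay_condition(construct), params)
    drift <- conservation_drift(net, enzyme_conc = 2e-6)
    expect_true(all(drift$max_rel_drift < 1e-6),
                label = paste("conservation for", construct))
    traj <- simulate_trajectory(net, 2e-6)
    frac <- traj$ArfGDP / net$condition$arf_total
    expect_true(all(frac >= -1e-9 & frac <= 1 + 1e-9))
  }
})

test_that("binding-only equilibrium matches the closed-form quadratic", {
  net <- build_network(assay_condition("ZA"), params)
  net$reactions$rate[3] <- 0  # switch off hydrolysis; pure binding remains
  e0 <- 2e-4; a0 <- 1e-6; kd <- params$kd_za_arf
  traj <- simulate_trajectory(net, e0, times = c(0, 1e7))
  c_eq <- ((e0 + a0 + kd) - sqrt((e0 + a0 + kd)^2 - 4 * e0 * a0)) / 2
  expect_equal(traj$ZAA[2], c_eq, tolerance = 1e-6)
})

test_that("endpoint fraction behaves monotonically", {
  net <- build_network(assay_condition("trans"), params)
  grid <- 10^seq(-8, -4, length.out = 6)
  fr <- vapply(grid, function(e) simulate_endpoint(net, e), numeric(1))
  expect_true(all(diff(fr) >= -1e-9))
  expect_equal(simulate_endpoint(net, 0), 0)
  # saturating tandem enzyme on PIP2 membranes hydrolyzes essentially all GTP
  pza <- build_network(assay_condition("PZA"), params)
  expect_gt(simulate_endpoint(pza, 1e-5), 0.95)
  # weaker PH-Arf binding lowers, stronger allostery raises, the endpoint
  fr_by_kd <- vapply(c(1e-6, 1e-5, 1e-4), function(kd) {
    p <- kinetic_params(kd_ph_arf = kd)
    simulate_endpoint(build_network(assay_condition("trans"), p), 1e-6)
  }, numeric(1))
  expect_true(all(diff(fr_by_kd) <= 1e-9))
  fr_by_alpha <- vapply(c(1e2, 1e3, 1e4), function(a) {
    net_a <- build_network(assay_condition("trans"), params, alpha = a)
    simulate_endpoint(net_a, 1e-7)
  }, numeric(1))
  expect_true(all(diff(fr_by_alpha) >= -1e-9))
})

test_that("C50 extraction interpolates log-linearly and validates input", {
  conc <- 10^seq(-9, -5, length.out = 15)
  logistic <- function(c, mid, h = 1) 1 / (1 + (mid / c)^h)
  curve <- tibble::tibble(conc = conc, fraction = logistic(conc, 1e-7))
  expect_equal(c50(curve), 1e-7, tolerance = 0.05)
  # inserting the exact midpoint returns it untouched
  curve2 <- dplyr::bind_rows(curve, tibble::tibble(conc = 1e-7,
                                                   fraction = 0.5)) |>
    dplyr::arrange(conc)
  expect_identical(c50(curve2), 1e-7)
  low <- tibble::tibble(conc = conc, fraction = logistic(conc, 1e-7) * 0.4)
  expect_error(c50(low), "does not cross")
})

test_that("catalytic efficiency reports the initial-rate second-order constant", {
  za <- build_network(assay_condition("ZA"), params)
  e1 <- catalytic_efficiency(za, enzyme_conc = 1e-8)
  e2 <- catalytic_efficiency(za, enzyme_conc = 5e-9)
  expect_equal(e1 / e2, 1, tolerance = 0.01)  # independent of enzyme conc
  expect_error(catalytic_efficiency(za, enzyme_conc = 1e-6), "arf_total")
  # Michaelis-type limit oracle: kcat/Kd = 1 with fast-equilibrium binding
  p_mm <- kinetic_params(kon_za_arf = 1e5, kd_za_arf = 5e-4,
                         kcat_basal = 5e-4)
  mm <- build_network(assay_condition("ZA"), p_mm)
  expect_equal(catalytic_efficiency(mm), 5e-4 / (5e-4 + 1e-6),
               tolerance = 0.1)
  # saturated-binding regime: alpha multiplies the efficiency through k_cat
  # (kcat small enough that binding equilibration stays fast vs turnover)
  p_sat <- kinetic_params(kd_ph_arf = 1e-9, kcat_basal = 1e-6)
  cond <- assay_condition("PZA", pip2_mol_percent = 0)
  eff_a <- catalytic_efficiency(build_network(cond, p_sat, alpha = 1e4))
  eff_1 <- catalytic_efficiency(build_network(cond, p_sat, alpha = 1))
  expect_equal(eff_a / eff_1, 1e4, tolerance = 0.05)
})

test_that("global fit is self-consistent on noiseless data", {
  data <- gen_kinetic_data(params, default_fit_conditions(8), noise_sd = 0,
                           seed = 3)
  # fixing every parameter returns the start and the plain objective
  fixed <- fit_global(data, params, free = character())
  expect_equal(fixed$objective, 0, tolerance = 1e-4)
  expect_identical(fixed$params, params)
  # a perturbed allostery multiplier is recovered within 1% in log10
  p_start <- kinetic_params(alpha_allostery = 3e3)
  fit <- fit_global(data, p_start, free = "alpha_allostery", seed = 1,
                    n_starts = 1)
  expect_equal(log10(fit$params$alpha_allostery), 4, tolerance = 0.01)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_true(glance(fit)$converged)
})

test_that("decomposition terms vanish when their mechanism is disabled", {
  # alpha = 1: the allostery term is zero by construction
  p1 <- kinetic_params(alpha_allostery = 1 + 1e-12)
  dec1 <- decompose_activation(p1)
  expect_equal(unname(dec1$gains["allostery"]), 0, tolerance = 1e-3)
  # no membrane sites: recruitment adds nothing
  dec2 <- decompose_activation(params,
                               assay_condition("PZA", pip2_mol_percent = 0))
  expect_equal(unname(dec2$gains["recruitment_only"]), 0, tolerance = 0.02)
  expect_equal(unname(dec2$gains["total"]),
               unname(dec2$gains["combined_no_allostery"] +
                        dec2$gains["allostery"]), tolerance = 1e-9)
})

test_that("a YAML network override drives the same solver", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "species:",
    "  - {name: A, compartment: solution}",
    "  - {name: B, compartment: solution}",
    "  - {name: C, compartment: solution}",
    "reactions:",
    "  - {rate: 1.0e+5, reactants: [A, B], products: [C]}",
    "  - {rate: 1.0, reactants: [C], products: [A, B]}",
    "init: {B: 1.0e-5}",
    "enzyme_species: A",
    "groups: {a_total: [A, C], b_total: [B, C]}"), path)
  net <- network_from_yaml(path, assay_condition("ZA", arf_total = 1e-5))
  traj <- simulate_trajectory(net, 2e-5, times = c(0, 100))
  kd <- 1 / 1e5; e0 <- 2e-5; a0 <- 1e-5
  c_eq <- ((e0 + a0 + kd) - sqrt((e0 + a0 + kd)^2 - 4 * e0 * a0)) / 2
  expect_equal(traj$C[2], c_eq, tolerance = 1e-6)
  drift <- conservation_drift(net, 2e-5, times = c(0, 50, 100))
  expect_true(all(drift$max_rel_drift < 1e-6))
})
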