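test_that("CSP combines proton and heteronucleus shifts as printed", {
  cfg <- csp_config(average_stereo = FALSE)
  free <- make_peaks(shift_h = c(1.0, 0.8), shift_x = c(20, 15))
  # identity case and a direct arithmetic oracle
  bound <- make_peaks(shift_h = c(1.0, 0.9), shift_x = c(20, 15.2),
                      state_id = "bound")
  out <- compute_csp(free, bound, cfg)
  expect_equal(out$csp[1], 0)
  expect_equal(out$csp[2], sqrt(0.1^2 + 0.185 * 0.2^2), tolerance = 1e-12)
  # N15 swaps in the other scale factor, all else equal
  free_n <- make_peaks(c(8.0), c(120), nucleus = "N15", atom_group = "N")
  bound_n <- make_peaks(c(8.1), c(120.2), nucleus = "N15", atom_group = "N",
                        state_id = "bound")
  out_n <- compute_csp(free_n, bound_n, cfg)
  expect_equal(out_n$csp, sqrt(0.1^2 + 0.17 * 0.2^2), tolerance = 1e-12)
  # squared-factor convention available behind the flag
  cfg2 <- csp_config(csp_convention = "square_of_product",
                     average_stereo = FALSE)
  out2 <- compute_csp(free, bound, cfg2)
  expect_equal(out2$csp[2], sqrt(0.1^2 + (0.185 * 0.2)^2), tolerance = 1e-12)
})

test_that("CSP is symmetric under swapping the two states", {
  cfg <- csp_config(average_stereo = FALSE)
  set.seed(42)
  free <- make_peaks(runif(8, 0.3, 1.4), runif(8, 12, 25))
  bound <- make_peaks(runif(8, 0.3, 1.4), runif(8, 12, 25),
                      state_id = "bound")
  expect_equal(compute_csp(free, bound, cfg)$csp,
               compute_csp(bound, free, cfg)$csp)
})

test_that("stereo-paired methyls are averaged when requested", {
  tab <- function(h2, state) peak_table(tibble::tibble(
    residue = c(5L, 5L), resname = "LEU", atom_group = c("CD1", "CD2"),
    nucleus = "C13", shift_h = c(0.9, h2), shift_x = c(24, 23),
    intensity = 100, snr = 50), state_id = state)
  out <- compute_csp(tab(0.7, "free"), tab(0.9, "bound"),
                     csp_config(average_stereo = TRUE))
  expect_equal(nrow(out), 1L)
  expect_equal(out$csp, 0.1)  # mean of 0 and 0.2
})

test_that("mismatched heteronucleus and unmatched probes are handled", {
  free <- make_peaks(1.0, 20, nucleus = "C13")
  bound <- make_peaks(1.0, 20, nucleus = "N15", state_id = "bound")
  expect_error(compute_csp(free, bound), "mismatched heteronucleus")
  free2 <- make_peaks(c(1, 1.2), c(20, 21), residues = 1:2)
  bound2 <- make_peaks(1.05, 20, residues = 1, state_id = "bound")
  expect_warning(out <- compute_csp(free2, bound2, csp_config()),
                 "only one table")
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "unmatched"), "2.LEU.CG")
})

test_that("CSP error follows the digital-resolution propagation", {
  cfg <- csp_config(digital_resolution_h = 0.005, digital_resolution_x = 0.02,
                    average_stereo = FALSE)
  # hand evaluation: only the proton term contributes
  rec <- tibble::tibble(delta_h = 0.1, delta_x = 0, nucleus = "C13", csp = 0.1)
  expect_equal(csp_error(rec, cfg), 0.005)
  # zero CSP never divides by zero
  rec0 <- tibble::tibble(delta_h = 0, delta_x = 0, nucleus = "C13", csp = 0)
  expect_true(is.na(csp_error(rec0, cfg)))
  # linearity in the resolutions
  cfg2 <- csp_config(digital_resolution_h = 0.01, digital_resolution_x = 0.04,
                     average_stereo = FALSE)
  rec2 <- tibble::tibble(delta_h = 0.07, delta_x = 0.3, nucleus = "C13",
                         csp = sqrt(0.07^2 + 0.185 * 0.09))
  expect_equal(csp_error(rec2, cfg2), 2 * csp_error(rec2, cfg))
  # printed-constant variant stays available
  cfgp <- csp_config(digital_resolution_h = 0.005, digital_resolution_x = 0.02,
                     error_convention = "printed_squared")
  recx <- tibble::tibble(delta_h = 0, delta_x = 0.2, nucleus = "C13", csp = 0.086)
  expect_equal(csp_error(recx, cfgp), 0.185^2 * 0.2 * 0.02 / 0.086)
})

test_that("intensity ratios propagate S/N errors and flag vanished peaks", {
  den <- peak_table(tibble::tibble(
    residue = 1:3, resname = "VAL", atom_group = "CG", nucleus = "C13",
    shift_h = 1, shift_x = 20, intensity = c(100, 100, 80),
    snr = c(1e12, 50, 40)), state_id = "dia")
  num <- peak_table(tibble::tibble(
    residue = 1:3, resname = "VAL", atom_group = "CG", nucleus = "C13",
    shift_h = 1, shift_x = 20, intensity = c(100, 20, NA),
    snr = c(1e12, 10, NA)), state_id = "para")
  out <- intensity_ratio_profile(num, den)
  expect_equal(out$ratio[1], 1)
  expect_lt(out$ratio_error[1], 1e-10)
  expect_equal(out$ratio[2], 0.2)
  expect_equal(out$ratio_error[2], 0.2 * sqrt(0.01 + 4e-4), tolerance = 1e-12)
  # vanished peak: ratio 0, error from the 3x noise floor
  expect_true(out$vanished[3])
  expect_equal(out$ratio[3], 0)
  expect_equal(out$ratio_error[3], 3 / 40)
  # nonpositive denominator is a hard error naming the probe
  den_bad <- peak_table(tibble::tibble(
    residue = 1, resname = "VAL", atom_group = "CG", nucleus = "C13",
    shift_h = 1, shift_x = 20, intensity = 0, snr = 40), state_id = "dia")
  num1 <- peak_table(tibble::tibble(
    residue = 1, resname = "VAL", atom_group = "CG", nucleus = "C13",
    shift_h = 1, shift_x = 20, intensity = 10, snr = 10), state_id = "para")
  expect_error(intensity_ratio_profile(num1, den_bad), "1.VAL.CG")
})

test_that("peak tables validate probes and round-trip through CSV", {
  dup <- tibble::tibble(residue = c(1, 1), resname = "ILE",
                        atom_group = "CD1", nucleus = "C13", shift_h = 1,
                        shift_x = 12, intensity = 10, snr = 5)
  expect_error(peak_table(dup), "duplicate probe")
  tab <- make_peaks(c(0.9, 1.1), c(20, 22))
  path <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(tab, path)
  back <- read_peak_table(path, state_id = "free")
  expect_equal(as.data.frame(back), as.data.frame(tab))
})
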