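#' Configuration for CSP computation and residue classification
#'
#' @param a_n15,a_c13 Heteronucleus scale factors applied to the squared
#'   X-shift difference when X is 15N or 13C (dimensionless; conventional
#'   values 0.17 and 0.185).
#' @param digital_resolution_h,digital_resolution_x Spectral digital
#'   resolutions (ppm) used for the CSP error estimate.
#' @param active_csp_threshold CSP (ppm) above which a solvent-exposed residue
#'   is classified active.
#' @param passive_band Named list of per-probe-type passive bands, each a
#'   `c(low, high)` pair in ppm: `methyl` and `amide`. A solvent-exposed
#'   residue with a CSP inside the band joins the passive set.
#' @param rsa_threshold Relative solvent accessibility fraction at or above
#'   which a residue counts as solvent exposed.
#' @param passive_radius Heavy-atom minimum distance (Angstrom) from any
#'   active residue within which solvent-exposed residues become passive.
#' @param csp_convention `"a_times_square"` applies the scale factor to the
#'   squared X shift difference, `sqrt(dH^2 + A*dX^2)`; `"square_of_product"`
#'   uses `sqrt(dH^2 + (A*dX)^2)`.
#' @param error_convention `"a_consistent"` uses the same A as the CSP formula
#'   in the error propagation; `"printed_squared"` divides the X term by the
#'   squared constant (1/A)^2 instead.
#' @param average_stereo Average the CSPs of pro-R/pro-S methyl pairs (two
#'   methyl atom groups on one residue) into one record.
#' @return A list of class `csp_config`.
#' @export
csp_config <- function(a_n15 = 0.17, a_c13 = 0.185,
                       digital_resolution_h = 0.002,
                       digital_resolution_x = 0.02,
                       active_csp_threshold = 0.1,
                       passive_band = list(methyl = c(0.047, 0.095),
                                           amide = c(0.02, 0.04)),
                       rsa_threshold = 0.20,
                       passive_radius = 6.5,
                       csp_convention = c("a_times_square", "square_of_product"),
                       error_convention = c("a_consistent", "printed_squared"),
                       average_stereo = TRUE) {
  csp_convention <- match.arg(csp_convention)
  error_convention <- match.arg(error_convention)
  stopifnot_named(
    "scale factors must lie in (0,1)" = c(a_n15, a_c13) > 0 & c(a_n15, a_c13) < 1,
    "thresholds must be positive" = c(active_csp_threshold, rsa_threshold,
                                      passive_radius) > 0,
    "digital resolutions must be >= 0" = c(digital_resolution_h,
                                           digital_resolution_x) >= 0,
    "passive bands must satisfy low < high" =
      vapply_dbl(passive_band, function(b) b[1]) <
      vapply_dbl(passive_band, function(b) b[2])
  )
  structure(list(a_n15 = a_n15, a_c13 = a_c13,
                 digital_resolution_h = digital_resolution_h,
                 digital_resolution_x = digital_resolution_x,
                 active_csp_threshold = active_csp_threshold,
                 passive_band = passive_band,
                 rsa_threshold = rsa_threshold,
                 passive_radius = passive_radius,
                 csp_convention = csp_convention,
                 error_convention = error_convention,
                 average_stereo = average_stereo),
            class = "csp_config")
}

a_factor <- function(nucleus, cfg) {
  ifelse(nucleus == "N15", cfg$a_n15, cfg$a_c13)
}

csp_combine <- function(d_h, d_x, a, convention) {
  if (convention == "a_times_square") sqrt(d_h^2 + a * d_x^2)
  else sqrt(d_h^2 + (a * d_x)^2)
}

#' Chemical shift perturbations between two states
#'
#' Combines proton and heteronucleus shift differences between matched probes
#' of a free and a bound peak table into a single perturbation per probe,
#' `CSP = sqrt(ddH^2 + A*ddX^2)`, with the scale factor `A` chosen by the
#' probe's heteronucleus. Pro-R/pro-S methyl pairs (two methyl groups on one
#' residue) are averaged when `cfg$average_stereo` is `TRUE`. Probes present
#' in only one table are dropped and reported via the `"unmatched"` attribute.
#'
#' @param free,bound `peak_table` objects for the two states.
#' @param cfg A [csp_config()].
#' @return A tibble with columns `probe`, `residue`, `resname`, `atom_group`,
#'   `nucleus`, `probe_type` (`"methyl"`/`"amide"`), `delta_h`, `delta_x`,
#'   `csp` and `csp_error` (ppm). Attribute `"unmatched"` lists dropped probe
#'   ids.
#' @export
compute_csp <- function(free, bound, cfg = csp_config()) {
  f <- as_tibble(free)
  b <- as_tibble(bound)
  shared <- intersect(f$probe, b$probe)
  unmatched <- setdiff(union(f$probe, b$probe), shared)
  if (length(unmatched) > 0) {
    warn(paste0(length(unmatched), " probe(s) present in only one table: ",
                paste(head(unmatched, 5), collapse = ", ")))
  }
  m <- inner_join(
    select(f, "probe", "residue", "resname", "atom_group",
           nucleus_free = "nucleus", h_free = "shift_h", x_free = "shift_x"),
    select(b, "probe", nucleus_bound = "nucleus",
           h_bound = "shift_h", x_bound = "shift_x"),
    by = "probe")
  bad <- m$nucleus_free != m$nucleus_bound
  if (any(bad)) {
    abort(paste0("mismatched heteronucleus between states for probe(s): ",
                 paste(m$probe[bad], collapse = ", ")))
  }
  out <- m |>
    mutate(nucleus = .data$nucleus_free,
           probe_type = ifelse(.data$atom_group %in% c("N", "NH", "NE1"),
                               "amide", "methyl"),
           delta_h = abs(.data$h_bound - .data$h_free),
           delta_x = abs(.data$x_bound - .data$x_free),
           a = a_factor(.data$nucleus, cfg),
           csp = csp_combine(.data$delta_h, .data$delta_x, .data$a,
                             cfg$csp_convention)) |>
    select("probe", "residue", "resname", "atom_group", "nucleus",
           "probe_type", "delta_h", "delta_x", "csp")
  out$csp_error <- csp_error(out, cfg)
  if (isTRUE(cfg$average_stereo)) {
    out <- out |>
      group_by(.data$residue, .data$resname, .data$nucleus, .data$probe_type) |>
      summarise(probe = .data$probe[1],
                atom_group = paste(sort(.data$atom_group), collapse = "/"),
                delta_h = mean(.data$delta_h),
                delta_x = mean(.data$delta_x),
                csp = mean(.data$csp),
                csp_error = mean(.data$csp_error),
                .groups = "drop") |>
      select("probe", "residue", "resname", "atom_group", "nucleus",
             "probe_type", "delta_h", "delta_x", "csp", "csp_error") |>
      arrange(.data$residue)
  }
  attr(out, "unmatched") <- unmatched
  out
}

#' Digital-resolution error of a CSP
#'
#' Propagates the spectral digital resolutions through the CSP formula:
#' `error = (ddH * R_H + A * ddX * R_X) / CSP` with the same heteronucleus
#' scale factor `A` as the CSP itself. With
#' `cfg$error_convention = "printed_squared"` the X term is divided by
#' `(1/A)^2` instead. Probes with zero CSP get `NA` (the error is undefined;
#' no division by zero occurs).
#'
#' @param records A data frame with columns `delta_h`, `delta_x`, `nucleus`
#'   and `csp` (as produced inside [compute_csp()]).
#' @param cfg A [csp_config()].
#' @return Numeric vector of errors (ppm), `NA` where `csp == 0`.
#' @export
csp_error <- function(records, cfg = csp_config()) {
  a <- a_factor(records$nucleus, cfg)
  x_scale <- if (cfg$error_convention == "a_consistent") a else a^2
  num <- records$delta_h * cfg$digital_resolution_h +
    x_scale * records$delta_x * cfg$digital_resolution_x
  ifelse(records$csp > 0, num / records$csp, NA_real_)
}

#' Intensity-ratio profile between two peak tables
#'
#' Per matched probe, `ratio = I_num / I_den` with error
#' `ratio * sqrt((1/snr_num)^2 + (1/snr_den)^2)`. Probes whose numerator peak
#' has vanished (`NA` or zero intensity) are flagged and reported with ratio 0
#' and an error derived from a noise-floor intensity of three times the
#' denominator noise level (`3 * I_den / snr_den`).
#'
#' @param numerator,denominator `peak_table` objects (e.g. paramagnetic over
#'   diamagnetic, or protonated-partner over deuterated-partner).
#' @return A tibble with columns `probe`, `residue`, `resname`, `atom_group`,
#'   `ratio`, `ratio_error`, `vanished`.
#' @export
intensity_ratio_profile <- function(numerator, denominator) {
  num <- as_tibble(numerator)
  den <- as_tibble(denominator)
  m <- inner_join(
    select(den, "probe", "residue", "resname", "atom_group",
           i_den = "intensity", snr_den = "snr"),
    select(num, "probe", i_num = "intensity", snr_num = "snr"),
    by = "probe")
  bad <- is.na(m$i_den) | m$i_den <= 0
  if (any(bad)) {
    abort(paste0("denominator intensity missing or <= 0 for probe(s): ",
                 paste(m$probe[bad], collapse = ", ")))
  }
  vanished <- is.na(m$i_num) | m$i_num <= 0
  ratio <- ifelse(vanished, 0, m$i_num / m$i_den)
  err <- ifelse(
    vanished,
    (3 / m$snr_den),                       # noise floor: 3 x denominator noise
    ratio * sqrt((1 / m$snr_num)^2 + (1 / m$snr_den)^2))
  tibble(probe = m$probe, residue = m$residue, resname = m$resname,
         atom_group = m$atom_group, ratio = ratio, ratio_error = err,
         vanished = vanished)
}
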