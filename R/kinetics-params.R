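#' Kinetic parameters of the GAP activation model
#'
#' Rate constants and equilibrium constants of the mass-action reaction
#' networks. Dissociation rate constants are never supplied directly: each
#' `koff` is derived as `kon * Kd`, so Kd/kon/koff consistency holds by
#' construction.
#'
#' @param kd_ph_membrane PH-PIP2 dissociation constant (M).
#' @param kon_ph_membrane PH-membrane-site association rate (M^-1 s^-1).
#' @param kd_ph_arf PH-Arf(GTP) dissociation constant in solution (M).
#' @param kon_ph_arf PH-Arf association rate in solution (M^-1 s^-1).
#' @param kd_za_arf GAP(ZA)-Arf dissociation constant (M).
#' @param kon_za_arf Productive engagement rate of the GAP domain with free
#'   Arf.GTP (M^-1 s^-1). Effective and deliberately slow: the measured
#'   sub-millimolar Kd is dominated by nonproductive encounters, and this
#'   constant absorbs the scarcity of catalytically competent ones.
#' @param kon_za_arf_activated Engagement rate of the GAP domain with
#'   PH-bound ("primed") Arf.GTP (M^-1 s^-1); the Kd is unchanged.
#' @param k_engage,k_disengage Intramolecular engagement/disengagement rates
#'   (s^-1) of the GAP domain onto PH-bound Arf within the tandem enzyme.
#' @param kcat_basal Hydrolysis rate constant of the GAP-engaged complex
#'   without PH bound to Arf (s^-1).
#' @param alpha_allostery Dimensionless k_cat multiplier when the PH domain
#'   is bound to Arf.
#' @param lambda_membrane Dimensionless local-concentration enhancement
#'   applied to association rates between membrane-resident partners
#'   (volume-to-surface dimensional reduction).
#' @param site_density Membrane binding sites per PIP2 lipid.
#' @return List of class `kinetic_params` with derived `koff_*` entries.
#' @export
kinetic_params <- function(kd_ph_membrane = 1e-6,
                           kon_ph_membrane = 1e7,
                           kd_ph_arf = 3.5e-5,
                           kon_ph_arf = 1e6,
                           kd_za_arf = 5e-4,
                           kon_za_arf = 1.05,
                           kon_za_arf_activated = 1e3,
                           k_engage = 2e3,
                           k_disengage = 5e2,
                           kcat_basal = 1e-2,
                           alpha_allostery = 1e4,
                           lambda_membrane = 1e3,
                           site_density = 1) {
  p <- list(kd_ph_membrane = kd_ph_membrane,
            kon_ph_membrane = kon_ph_membrane,
            kd_ph_arf = kd_ph_arf, kon_ph_arf = kon_ph_arf,
            kd_za_arf = kd_za_arf, kon_za_arf = kon_za_arf,
            kon_za_arf_activated = kon_za_arf_activated,
            k_engage = k_engage, k_disengage = k_disengage,
            kcat_basal = kcat_basal, alpha_allostery = alpha_allostery,
            lambda_membrane = lambda_membrane, site_density = site_density)
  stopifnot_named("all kinetic parameters must be positive" =
                    unlist(p) > 0)
  p$koff_ph_membrane <- p$kon_ph_membrane * p$kd_ph_membrane
  p$koff_ph_arf <- p$kon_ph_arf * p$kd_ph_arf
  p$koff_za_arf <- p$kon_za_arf * p$kd_za_arf
  p$koff_za_arf_activated <- p$kon_za_arf_activated * p$kd_za_arf
  structure(p, class = "kinetic_params")
}

#' Shipped calibrated default parameters
#'
#' The default parameter set reproducing the model's published anchors
#' (GAP-domain-only catalytic efficiency near 1 M^-1 s^-1, in-trans
#' half-maximal GAP concentration near 4 uM, full-enzyme efficiency on
#' PIP2 membranes near 1e8 M^-1 s^-1, with the allosteric k_cat multiplier
#' fixed at 1e4). Produced by `scripts/calibrate_defaults.R` and stored in
#' `inst/extdata/kinetic-defaults.yaml`.
#'
#' @return A `kinetic_params` object.
#' @export
default_kinetic_params <- function() {
  path <- system.file("extdata", "kinetic-defaults.yaml", package = "allogap")
  vals <- yaml::read_yaml(path)
  do.call(kinetic_params, vals)
}

#' Define an endpoint GAP assay condition
#'
#' @param construct One of `"ZA"` (GAP domain alone), `"PZA"` (tandem
#'   PH-GAP enzyme), `"PHdZA"` (tandem with a PH domain that binds membranes
#'   but not Arf), `"trans"` (isolated GAP domain titrated in the presence of
#'   a fixed concentration of isolated PH domain).
#' @param pip2_mol_percent PIP2 content of the membrane (mol %); 0 removes
#'   all membrane sites.
#' @param lipid_total Total lipid concentration (M).
#' @param arf_total Substrate Arf.GTP concentration (M).
#' @param endpoint Assay endpoint (s).
#' @param titration Enzyme concentrations (M) for titration curves.
#' @param ph_fixed Fixed free-PH concentration (M), used by `"trans"`.
#' @return List of class `assay_condition`.
#' @export
assay_condition <- function(construct = c("PZA", "ZA", "PHdZA", "trans"),
                            pip2_mol_percent = 5, lipid_total = 5e-4,
                            arf_total = 1e-6, endpoint = 180,
                            titration = 10^seq(-11, -4, length.out = 12),
                            ph_fixed = 5e-6) {
  construct <- match.arg(construct)
  stopifnot_named(
    "concentrations must be nonnegative" =
      c(pip2_mol_percent, lipid_total, arf_total, titration, ph_fixed) >= 0,
    "endpoint must be positive" = endpoint > 0
  )
  structure(list(construct = construct,
                 pip2_mol_percent = pip2_mol_percent,
                 lipid_total = lipid_total, arf_total = arf_total,
                 endpoint = endpoint, titration = titration,
                 ph_fixed = ph_fixed),
            class = "assay_condition")
}

membrane_sites <- function(condition, params) {
  condition$lipid_total * condition$pip2_mol_percent / 100 * params$site_density
}
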