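#!/usr/bin/env Rscript
# Calibrates the shipped default kinetic parameters against the model's
# published anchors and writes inst/extdata/kinetic-defaults.yaml.
#
# Anchors (with the allosteric multiplier fixed at 1e4):
#   * GAP-domain-only catalytic efficiency  ~ 1 M^-1 s^-1
#   * in-trans C50 (GAP titrated, 5 uM PH)  ~ 4e-6 M
#   * binding-only gain                     ~ 3 log10 units
#   * recruitment-only gain                 ~ 3 log10 units
#   * tandem enzyme on PIP2 membranes       ~ 1e8 M^-1 s^-1 (total ~ 8 log10)
#
# The calibration is closed-form, not a fit to data:
#   kcat_basal = 1e-2 s^-1 so the allosteric channel (alpha*kcat = 100 s^-1)
#     can carry an efficiency of 1e8 M^-1 s^-1 at 1 uM substrate;
#   kon_za_arf ~ 1 M^-1 s^-1 makes the basal channel association-limited with
#     efficiency kon * kcat/(kcat + koff) ~ 1 (koff = kon * Kd with the
#     measured Kd of 0.5 mM);
#   kon_za_arf_activated = 1e3 M^-1 s^-1 places the in-trans C50 at
#     -ln(0.5)/endpoint / kon ~ 4 uM when PH saturates Arf;
#   k_engage/k_disengage = 4 and kd_ph_arf = 3.5e-5 M put the engaged-complex
#     occupancy of the solution tandem enzyme at 0.1 (binding-only gain 3);
#   lambda_membrane = 1e3 is the standard volume-to-surface concentration
#     gain, giving the recruitment-only channel its ~3 log10 units.
# This script verifies the anchors by simulation and errors if any drifts.

suppressPackageStartupMessages(library(allogap))

defaults <- list(
  kd_ph_membrane = 1e-6, kon_ph_membrane = 1e7,
  kd_ph_arf = 3.5e-5, kon_ph_arf = 1e6,
  kd_za_arf = 5e-4, kon_za_arf = 1.05,
  kon_za_arf_activated = 1e3,
  k_engage = 2e3, k_disengage = 5e2,
  kcat_basal = 1e-2, alpha_allostery = 1e4,
  lambda_membrane = 1e3, site_density = 1)
params <- do.call(kinetic_params, defaults)

check <- function(label, value, target, factor) {
  ok <- value >= target / factor & value <= target * factor
  message(sprintf("%-28s %12.4g (target %g, factor %g) %s",
                  label, value, target, factor, if (ok) "ok" else "DRIFTED"))
  if (!ok) stop("calibration anchor drifted: ", label)
}

dec <- decompose_activation(params)
eff_za <- dec$efficiencies$efficiency[dec$efficiencies$variant == "za_only"]
check("ZA-only efficiency", eff_za, 1, 10)
check("recruitment gain (log10)", unname(dec$gains["recruitment_only"]), 3, 1.2)
check("binding gain (log10)", unname(dec$gains["binding_only"]), 3, 1.2)
check("combined gain (log10)", unname(dec$gains["combined_no_allostery"]), 4, 1.2)
check("total gain (log10)", unname(dec$gains["total"]), 8, 1.1)
trans <- build_network(assay_condition("trans"), params)
check("in-trans C50", c50(titration_curve(trans)), 4e-6, 2)

out <- file.path("inst", "extdata", "kinetic-defaults.yaml")
header <- c(
  "# Calibrated default kinetic parameters (written by scripts/calibrate_defaults.R).",
  "# Anchors: GAP-domain-only efficiency ~1 M^-1 s^-1; in-trans C50 ~4e-6 M;",
  "# tandem enzyme on PIP2 membranes ~1e8 M^-1 s^-1; allosteric multiplier fixed at 1e4.")
# YAML requires a decimal point in the mantissa for scientific notation
fmt <- function(x) {
  if (x == round(x) && abs(x) < 1e4) return(format(x))
  e <- floor(log10(abs(x)))
  m <- x / 10^e
  sprintf("%se%+d", format(m, nsmall = 1), e)
}
body <- vapply(names(defaults),
               function(nm) paste0(nm, ": ", fmt(defaults[[nm]])),
               character(1))
writeLines(c(header, body), out)
message("wrote ", out)
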