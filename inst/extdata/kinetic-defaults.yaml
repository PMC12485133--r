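# Calibrated default kinetic parameters (written by scripts/calibrate_defaults.R).
# Anchors: GAP-domain-only efficiency ~1 M^-1 s^-1; in-trans C50 ~4e-6 M;
# tandem enzyme on PIP2 membranes ~1e8 M^-1 s^-1; allosteric multiplier fixed at 1e4.
kd_ph_membrane: 1.0e-6
kon_ph_membrane: 1.0e+7
kd_ph_arf: 3.5e-5
kon_ph_arf: 1.0e+6
kd_za_arf: 5.0e-4
kon_za_arf: 1.05e+0
kon_za_arf_activated: 1000
k_engage: 2000
k_disengage: 500
kcat_basal: 1.0e-2
alpha_allostery: 1.0e+4
lambda_membrane: 1000
site_density: 1
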