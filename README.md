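# allogap

Tools for dissecting how a pleckstrin-homology (PH) domain actively
accelerates GTP hydrolysis on a membrane-anchored small GTPase (Arf1) by its
GTPase-activating protein (GAP). The package is aimed at structural
biologists and enzymologists combining NMR interface mapping, docking
restraints, paramagnetic relaxation enhancement (PRE) and endpoint GAP
assays into one quantitative picture.

Four analysis layers, each usable on its own:

* **NMR perturbation mapping** — chemical shift perturbations between free
  and bound peak tables, `CSP = sqrt(ddH^2 + A*ddX^2)` (A = 0.17 for 15N,
  0.185 for 13C), digital-resolution error propagation, intensity-ratio
  profiles with S/N error bars, and active/passive residue classification
  (solvent exposed by relative accessibility >= 0.20; active above 0.1 ppm;
  passive within 6.5 Å of the active set or inside a per-probe-type CSP
  band).
* **Restraint generation** — ambiguous interaction restraints (one per
  active residue, pooled against the partner's active+passive set) and
  unambiguous 1.8–16 Å distance restraints for probes with PRE ratio
  I/I0 < 0.2, serialized as CNS-style `.tbl` with a round-trip parser.
* **PRE forward calculation** — Solomon–Bloembergen transverse rates
  `Gamma_2 = kappa (4 tau_c + 3 tau_c/(1+w^2 tau_c^2)) r^-6` averaged over
  label positions and ensemble frames, converted to intensity ratios via
  `I/I0 = R2 exp(-Gamma_2 t)/(R2 + Gamma_2)`, and a two-state population
  fit (`Gamma_2 = rho_A Gamma_2^A + (1-rho_A) Gamma_2^B`, grid + golden
  section on the Pearson correlation) — plus ensemble statistics: interface
  contacts, H-bond/salt-bridge propensities, distance distributions,
  per-residue RMSD, buried surface area, all rigid-motion invariant.
* **Kinetic decomposition** — a mass-action ODE model of 3-minute endpoint
  GAP assays (stiff solver with a compiled right-hand side) in which the PH
  module (i) is recruited to PIP2 membranes, (ii) binds the substrate
  GTPase with a membrane local-concentration gain, and (iii) multiplies the
  hydrolysis k_cat by an allosteric factor alpha. Simulation, C50
  extraction, initial-rate catalytic efficiency, global fitting and a
  recruitment/binding/allostery decomposition.

Seeded synthetic-data generators produce every input (two-pose coordinate
ensembles with a spin label, peak tables with a known interface, noisy
titration curves), so each stage is testable against known ground truth.

## Worked example

```r
library(allogap)

params <- default_kinetic_params()

# GAP domain alone: catalytic efficiency from the initial-rate protocol
za <- build_network(assay_condition("ZA"), params)
catalytic_efficiency(za)
#> [1] 0.997828        # M^-1 s^-1 -- the weak basal GAP

# half-maximal GAP concentration in the in-trans assay
# (GAP domain titrated at fixed 5 uM PH on PIP2 membranes)
trans <- build_network(assay_condition("trans"), params)
c50(titration_curve(trans))
#> [1] 3.591526e-06    # M -- PH turns the weak GAP into a uM-scale enzyme

# where does the activation come from?
dec <- decompose_activation(params)
tidy(dec)
#> # A tibble: 5 x 2
#>   contribution          log10_gain
#>   <chr>                      <dbl>
#> 1 recruitment_only            2.91
#> 2 binding_only                3.00
#> 3 combined_no_allostery       3.90
#> 4 allostery                   3.81
#> 5 total                       7.72
```

Reading the decomposition: membrane recruitment alone or substrate binding
alone each buy about three orders of magnitude in catalytic efficiency over
the GAP domain; together they saturate near four (the enzyme–substrate
complex is maximal); the remaining ~4 orders come from the allosteric
k_cat enhancement, for ~8 total — the gap between ~1 and ~1e8 M^-1 s^-1.

The PRE side:

```r
toy  <- gen_toy_complex(synthetic_spec(seed = 1))
prof <- gen_pre_profiles(toy, noise_sd = 0)        # 90:10 two-pose mixture
fit  <- fit_two_state(attr(prof, "profile_a"), attr(prof, "profile_b"), prof)
glance(fit)
#> # A tibble: 1 x 7
#>   rho_a rho_b population_ratio pearson_r slope slope_origin n_probes
#>   <dbl> <dbl>            <dbl>     <dbl> <dbl>        <dbl>    <int>
#> 1 0.900 0.0997            9.03      1.00  1.00         1.00       30
```

The fitted 9:1 pose ratio is the ground truth the generator encoded.
`autoplot(fit)`, `plot_csp_profile()`, `plot_pre_profile()`,
`plot_titration()` and `autoplot()` on a decomposition give the standard
figures. `run_pipeline("config.yaml")` wires synthetic data, CSP
classification, restraints, the PRE fit and the kinetics into one run with
a digest manifest.

See the methods vignette (`vignettes/allosteric-gap-activation.Rmd`) for
the models, conventions, numerical choices and limitations.

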