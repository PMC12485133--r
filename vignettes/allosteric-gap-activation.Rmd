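---
title: "Methods: interface mapping, PRE back-calculation and kinetic decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface mapping, PRE back-calculation and kinetic decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allogap)
```

`allogap` implements the computational side of a question in GTPase enzymology:
how does a pleckstrin-homology (PH) domain, long regarded as a passive membrane
anchor, actively accelerate GTP hydrolysis on a membrane-anchored small GTPase
(Arf1) by its GTPase-activating protein (GAP)? The package covers four layers:
NMR perturbation analysis, docking-restraint generation, paramagnetic
relaxation enhancement (PRE) forward calculation with two-state population
fitting, and a mass-action kinetic model of endpoint GAP assays that splits
the observed activation into membrane recruitment, substrate binding and
allosteric catalysis.

## Chemical shift perturbations and interface classification

For a methyl or amide probe observed free and bound, the combined perturbation
is

$$\mathrm{CSP}_{H\text{-}X} = \sqrt{\Delta\delta_H^2 + A\,\Delta\delta_X^2},$$

with $A = 0.17$ for $^{15}$N and $0.185$ for $^{13}$C. Note that $A$ scales
the *squared* X-shift difference; the squared-factor variant
$\sqrt{\Delta\delta_H^2 + (A\,\Delta\delta_X)^2}$ is available through
`csp_config(csp_convention = "square_of_product")` for users who prefer that
convention. The CSP error propagates the spectral digital resolutions,
$(\Delta\delta_H R_H + A\,\Delta\delta_X R_X)/\mathrm{CSP}$. We use the same
$A$ in the error as in the CSP itself, for internal consistency; a variant
that divides the X term by $(1/A)^2$ is provided behind
`error_convention = "printed_squared"` since both conventions circulate. A
zero CSP returns `NA` rather than dividing by zero. Pro-R/pro-S methyl pairs
are averaged arithmetically when both stereo probes are present.

Classification for ambiguous interaction restraints (AIRs) follows the
standard data-driven docking recipe: a residue is **active** when solvent
exposed (relative solvent accessibility, RSA, at least 0.20) with CSP above
0.1 ppm, and **passive** when solvent exposed and either within 6.5 Å
(minimum heavy-atom distance) of an active residue or carrying an
intermediate CSP inside a per-probe-type band (defaults 0.047–0.095 ppm for
methyls, 0.02–0.04 ppm for amides; both configurable, since these bands are
1–2 sigma marks whose underlying sigma depends on the data set). Active
membership wins; the sets are disjoint.

RSA needs a per-residue maximum. We default to a context-stripped
normalization — the residue's own atoms recomputed in isolation — which is
exactly 1 for a free residue and remains meaningful for
reduced-representation structures such as the synthetic test complexes; the
published Gly-X-Gly theoretical maxima (Tien et al. 2013) ship as
`reference = "theoretical"` for full-atom proteins. SASA itself is numerical
Shrake–Rupley with a 1.4 Å probe and a fixed 960-point golden-spiral lattice
per atom. Coordinates are rotated into the principal-axis frame before
sampling, so all SASA-derived quantities are invariant under rigid motion of
the input rather than merely approximately so.

## Restraints

Each active residue yields one AIR against the union of the partner
molecule's active and passive residues, serialized in CNS `assign` syntax
with the docking suite's standard 2 Å effective distance (1/r^6 pooling).
PRE-derived unambiguous restraints are emitted for every probe whose
paramagnetic/diamagnetic intensity ratio $I/I_0$ falls below 0.2 — including
probes broadened beyond detection — with bounds 1.8–16 Å between the label's
paramagnetic centre and the probe protons. The `.tbl` writer is byte-stable
and round-trips through `read_tbl()`.

## PRE forward calculation and two-state fitting

The transverse PRE rate for one electron–proton distance $r$ is the
Solomon–Bloembergen expression

$$\Gamma_2 = \kappa\left(4\tau_c + \frac{3\tau_c}{1+\omega_H^2\tau_c^2}\right) r^{-6},
\qquad \frac{1}{\tau_c} = \frac{1}{\tau_R} + \frac{1}{\tau_S},$$

with $\kappa = 1.23\times10^{-32}\,\mathrm{cm^6 s^{-2}}$, $\tau_R = 70$ ns
(protein tumbling), $\tau_S = 100$ ns (electron relaxation) and $\omega_H$
the proton Larmor frequency (default 850 MHz). Distances are converted from
Å to cm before applying $\kappa$. Rates are averaged over the label-position
ensemble within each frame, then over frames — averaging happens on rates
(fast-exchange convention) and is converted to intensity ratios once, via

$$I/I_0 = \frac{R_2\,e^{-\Gamma_2 t}}{R_2 + \Gamma_2},$$

with $t = 6.89$ ms and $R_2$ from the diamagnetic linewidth
($R_2 = \pi\,\Delta\nu_{1/2}$) or a 30 s$^{-1}$ default when no linewidth is
available. When no explicit label ensemble exists, `place_label_ensemble()`
puts the paramagnetic centre at 20 deterministic orientations on an 8 Å
tether around the labelled residue's C$\beta$; rotamer-library convolution is
deliberately out of scope and explicit label ensembles are the first-class
interface.

Two-state fitting mixes the pure-state rates as a convex combination
$\Gamma_2 = \rho_A \Gamma_2^A + (1-\rho_A)\Gamma_2^B$, converts to ratios and
maximizes the Pearson correlation with the experimental profile over a
$\rho_A$ grid of step 0.01, refined by golden-section search only when the
refinement genuinely improves the correlation; ties break toward slope 1.
Fitting happens in intensity-ratio space — the measured quantity — with
`fit_space = "gamma"` available; the free-intercept slope is reported
alongside the through-origin slope since published slopes do not always say
which was used. Vanished experimental probes enter with ratio 0.

## Ensemble structural statistics

Contacts between chains count, per frame, the distinct partner residues with
any heavy-atom pair within 3.5 Å (atom-pair granularity behind a flag, since
published interaction counts do not always state their convention).
Hydrogen bonds require donor–acceptor heavy-atom distance ≤ 3.5 Å and a
D–H···A angle ≥ 135°; when the ensemble carries no hydrogens the test
degrades, with a warning, to the distance criterion. Salt bridges use basic
N to acidic O within 4 Å, classified stable at ≥ 50% of frames and transient
between 10% and 50% — configurable bands chosen to mirror the usual
stable/transient language. Distance distributions use mass-weighted centres
and normalized histograms. Per-residue RMSD superposes all frames on an
alignment selection, forms a mean structure, re-superposes (two iterations)
and reports the root-mean-square (1/n over frames) C$\alpha$ deviation; the
C$\alpha$-based convention was chosen where the alternative (all heavy atoms)
was also defensible. Buried surface area is
$\mathrm{SASA}_A + \mathrm{SASA}_B - \mathrm{SASA}_{AB}$ per frame, averaged,
reported as the total over both surfaces (`halve_bsa` for the per-surface
convention).

## The kinetic model

Endpoint GAP assays measure the fraction of Arf-bound GTP hydrolyzed after
3 minutes as enzyme is titrated. The model is a mass-action reaction network
with solution and membrane-resident species, integrated with a stiff solver
(`deSolve::lsoda`, compiled right-hand side and analytic Jacobian, relative
tolerance 1e-8, absolute tolerance 1e-12 times the smallest conserved total).
Arf starts fully GTP-loaded (single-turnover design), hydrolysis is
irreversible, and there is no intrinsic enzyme-free hydrolysis.

The mechanism has three layers:

* **Recruitment.** The PH module binds PIP2 sites (default Kd 1 µM; sites =
  total lipid × PIP2 mol fraction). Associations in which both partners are
  membrane-resident gain a local-concentration factor
  `lambda_membrane = 1e3`, the standard volume-to-surface dimensional
  reduction scale. Thermodynamic cycles close exactly: the PH·Arf complex
  retains its membrane attachment as an avidity species, and the remaining
  rate constant of each cycle is derived, not free.
* **Binding.** PH binds Arf·GTP (solution Kd 35 µM; at the membrane the
  λ-enhancement makes the effective affinity sub-µM so complex formation
  saturates, matching the observation that the enzyme–substrate complex is
  maximal when both mechanisms operate). In the tandem enzyme the GAP domain
  then engages the PH-bound substrate intramolecularly
  (`k_engage/k_disengage = 2000/500 s^-1`).
* **Catalysis.** The engaged complex hydrolyzes at
  `alpha_allostery × kcat_basal` when PH is bound to Arf and at `kcat_basal`
  (0.01 s$^{-1}$) otherwise; `alpha_allostery = 1e4` is the allosteric k_cat
  multiplier. Productive engagement of the GAP domain with *free* Arf·GTP is
  modeled as a slow effective association (~1 M$^{-1}$s$^{-1}$): the measured
  sub-millimolar Kd is dominated by nonproductive encounters, and this
  constant absorbs how rare catalytically competent ones are. Engagement
  with PH-bound, conformationally primed Arf is three orders of magnitude
  faster at unchanged Kd — this is what lets the in-trans assay (isolated PH
  plus isolated GAP domain) run to completion in minutes.

The shipped defaults come from `scripts/calibrate_defaults.R`, a closed-form
calibration against the model's anchors — GAP-domain-only efficiency
~1 M$^{-1}$s$^{-1}$, in-trans C50 ~4 µM, full-enzyme efficiency on PIP2
membranes ~1e8 M$^{-1}$s$^{-1}$, allosteric multiplier fixed at 1e4 — with a
simulation check that errors if any anchor drifts. The exact published
reaction systems (18 equations in trans, 20 in tandem) are not reproduced
line by line; this network is a faithful reconstruction of the stated
mechanism at slightly coarser granularity (11 species each), and
`network_from_yaml()` lets a user swap in any other mass-action system
without code changes.

```{r decomposition}
params <- default_kinetic_params()
dec <- decompose_activation(params)
tidy(dec)
```

`decompose_activation()` recomputes the initial-rate catalytic efficiency
($v_0 / ([E][\mathrm{Arf\cdot GTP}])$ at enzyme ≤ 1% of substrate, measured
over the first 1% of turnover) for five model variants — GAP domain alone,
recruitment only, binding only, both without allostery, full — and reports
log10 gains. With the defaults, recruitment and binding each contribute
about three orders of magnitude, saturate jointly near four, and the k_cat
multiplier carries the remaining ~4, for ~8 total.

`fit_global()` fits the model to several titration curves simultaneously by
weighted least squares in log10 parameter space, multi-start (50 by default;
the replicate studies in the tests use 2 starts around the calibrated values
and 10 concentrations per curve to keep runtimes in minutes — those are the
package's chosen problem sizes). Identifiability is screened by the rank of
the finite-difference sensitivity matrix, and objective-threshold confidence
scans are available with `profile = TRUE`.

## Synthetic data: what it emulates and what it does not

`gen_toy_complex()` builds two idealized ~30-residue helical pseudo-chains
(N, CA, C, O, CB per residue, plus a methyl group with explicit protons on
every probe residue) in two distinct relative poses, with a spin-label site
on one chain and 30 methyl probes on the other spanning the strongly
broadened ($I/I_0 < 0.2$) through unperturbed ($> 0.8$) PRE regimes; frames
are Gaussian-jittered copies (default sd 0.3 Å). The two poses sit on
opposite faces of the labelled chain, and the minor pose brings its own
probe patch near the label: because those probes' broadening scales with
$\rho_B$ itself, they respond roughly $1/\rho_B$ times more strongly to the
population than major-pose probes, which is precisely the property that
makes a 90:10 equilibrium resolvable from a single profile — in the real
system, the two PRE patches on opposite faces of the domain play this
role. `gen_peak_tables()` injects
known shift perturbations into a chosen interface; `gen_pre_profiles()`
mixes the pure-state forward calculations at known populations (default
0.9/0.1, the two-pose equilibrium the PRE analysis is designed to resolve);
`gen_kinetic_data()` adds truncated Gaussian noise (default sd 0.03, the
visual scatter scale of typical endpoint assays) to model titrations. Every
generator is a pure function of its spec and seed.

These generators share the statistical *structure* of real data — not its
physics. The pseudo-proteins have no packing, sequence realism or force-field
energetics; the peak tables contain no overlap, exchange broadening or
assignment errors; the kinetic noise is homoscedastic. Passing tests
therefore demonstrate that the estimators recover known ground truth under
the stated noise model, not that real spectra or assays meet those
assumptions. Quantities that require the original deposited trajectories
(switch-region RMSDs, the ~1100 Å² buried interface, the 9:1 pose ratio
against measured PREs) are validated here only through the operations that
compute them, against geometric and brute-force oracles.

## Numerical choices and limitations

Degenerate inputs are rejected early: nonpositive distances or linewidths,
fewer than three shared probes, zero-variance experimental vectors,
titrations that never cross 50%. C50 uses log-linear interpolation, taking
the first crossing from low concentration on noisy curves. The two-state
grid is 0.01 with refinement only on genuine improvement, so endpoint
mixtures return exact grid values. The PRE model omits Curie-spin and
cross-correlated relaxation and anisotropic tumbling; the kinetic model
omits nucleotide exchange/rebinding, spatial effects beyond the λ factor,
autoinhibition and temperature dependence. The slow productive-engagement
constant for free Arf is an effective parameter, identifiable only as a
lumped rate — the titration data cannot separate "rare productive binding"
from "slow chemistry on unprimed substrate", and the decomposition is
insensitive to that distinction.
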