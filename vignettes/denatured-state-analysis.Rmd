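---
title: "Detecting residual structure in denatured peptides: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting residual structure in denatured peptides: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denatr)
```

This vignette documents the science implemented in `denatr`: the models,
their assumptions, the parameters that matter (with units and defaults),
the numerical choices, and what the synthetic-data validation does and
does not demonstrate about real data.

## The problem

A chemically denatured protein is an ensemble of rapidly interconverting
conformers. If parts of the chain transiently associate — typically a
cluster of hydrophobic side chains — the ensemble is not a random coil,
and that deviation is measurable: transverse ¹⁵N relaxation is locally
elevated, the heteronuclear NOE rises, J(0) grows, ¹³C chemical shifts
deviate from sequence-corrected random-coil values, and side-chain NOEs
appear between residues that a random coil would keep apart. `denatr`
quantifies each of these observables and fits an explicit
sequence-dependent model to the R₂ profile.

## Relaxation decays

R₁ and R₂ are obtained by fitting peak heights to the two-parameter model
$I(t) = I_0 e^{-R t}$. There is deliberately no offset term: relaxation
decays of correctly processed spectra decay to baseline, and a third
parameter on a ten-point schedule mostly absorbs noise. An offset can be
enabled (`offset = TRUE`) for quality control only.

* **Delay schedules** (generator defaults): ten delays spanning
  10–1200 ms for R₁ and ten multiples of 15.65 ms spanning
  15.6–469.4 ms for R₂ (a constant-increment echo-train grid). Two
  delays per series carry duplicate measurements.
* **Intensity errors** (`replicate_error`): replicate variances are
  pooled across the repeated delays, expressed as a *fractional* error,
  and applied to all points as $\sigma_i = f\,|I_i|$. With a single
  replicate pair the pooled estimate is Rayleigh-biased low by ~11%;
  this is inherent to two-point error estimation, and the package
  reports the estimator rather than attempting a bias correction.
* **Rate uncertainties**: the default is residual-resampling Monte Carlo
  (`n_mc = 200` refits; parametric resampling when per-point sigmas are
  supplied). Linearized covariance errors (`error_method = "cov"`) are
  available but unreliable on ten-point schedules. Fits whose relative
  rate error exceeds 50% are flagged `unreliable` rather than dropped.

The heteronuclear NOE is computed as `noe = I_sat / I_unsat` (saturated
over reference), the convention under which flexible backbones give
values well below 1 and sub-nanosecond motion can push them negative.
The package treats this as the physically meaningful convention; an
`invert` flag exists for data recorded with the opposite bookkeeping.
No saturation-transfer or recycle-delay corrections are applied.

Slowly exchanging proline cis/trans isomers produce duplicate peak sets;
`isomer_fraction` estimates the minor population as
minor/(major + minor) per residue and summarizes across residues.

## Reduced spectral density mapping

With a single static field one cannot determine J(ω) at all five
frequencies entering ¹⁵N relaxation; the reduction assumes J varies
slowly around the proton frequency so the three high-frequency terms
collapse onto an effective J(0.87 ω_H). The forward expressions
implemented (and inverted exactly) are

$$R_1 = \tfrac{d^2}{4}\,[3J(\omega_N) + 7J(0.87\,\omega_H)] + c^2 J(\omega_N)$$
$$R_2 = \tfrac{d^2}{8}\,[4J(0) + 3J(\omega_N) + 13J(0.87\,\omega_H)]
       + \tfrac{c^2}{6}\,[4J(0) + 3J(\omega_N)]$$
$$\mathrm{NOE} = 1 + \frac{\gamma_H}{\gamma_N}\,\frac{d^2}{4}\,
       \frac{5\,J(0.87\,\omega_H)}{R_1}$$

with $d = (\mu_0/4\pi)\,\hbar\,\gamma_H |\gamma_N| / r_{NH}^3$ and
$c = \omega_N\,\Delta\sigma/\sqrt{3}$. Defaults: $r_{NH}$ = 1.02 Å,
$\Delta\sigma$ = 172 ppm, CODATA gyromagnetic ratios with the *signed*
$\gamma_N < 0$, so positive high-frequency density lowers the NOE below
1 — the sign convention is asserted by test. Conventions and caveats:

* A single lumping frequency 0.87 ω_H is used for both R₁ and R₂. The
  effective factor is stored on the constants object
  (`high_freq_factor`) and can be changed.
* No exchange term is fitted: any R_ex broadening is absorbed into J(0).
  Elevated J(0) therefore means "slow motion and/or exchange".
* Noise can push mapped J(0) negative; such residues are flagged in the
  `mask` column, never clipped, because clipping would bias profile
  averages.
* Uncertainties propagate by 1000-draw Monte Carlo over the rate triple.

Because the reduction is an exact linear solve, `reduced_jmap` composed
with `forward_rates` is an identity to floating-point precision — this
is the central correctness oracle of the module. A second oracle is the
single-Lorentzian density $J(\omega) = \frac{2}{5}\tau/(1+(\omega\tau)^2)$:
mapped values must match the closed form at each frequency. Note that at
a ~600 MHz proton frequency even $\tau$ = 50 ps is not fully in the
extreme-narrowing regime: $(0.87\,\omega_H \tau)^2 \approx 0.027$, so
J(0.87 ω_H) sits ≈ 2.6% below the $\frac{2}{5}\tau$ plateau while J(0)
and J(ω_N) are within 0.04%. Tests comparing against the plateau must
budget for this.

## The cluster model for R₂ profiles

The model assumes the motional restriction a residue experiences from
its neighbours decays exponentially with sequence separation:

$$R_2(i) = A \sum_{j=1}^{N} w_j\, e^{-|i-j|/\lambda_0}
  \;+\; \sum_c R_{2c}\, e^{-(i-x_c)^2 / (2\Delta^2)}$$

* **A** (s⁻¹ per weight unit, ≥ 0) — empirical scaling of the intrinsic
  baseline. Its absolute value has no direct physical interpretation;
  only the profile shape is meaningful.
* **λ₀** (residues, bounds (0.1, 20]) — persistence length for segmental
  motion. The bounds reflect identifiability on 20-residue chains; λ₀
  can also be fixed (`lambda0_fixed`) to a literature value, since both
  fitting modes are defensible and short chains constrain λ₀ weakly.
* **w_j** — proxy for the intrinsic correlation time of residue j. The
  size-weighted variant sets 1 for Gly/Ala and 7 for everything else
  (small residues allow more backbone flexibility); the uniform variant
  sets all weights to 1. `compare_variants` fits both side by side; on
  clustered profiles the two variants localize the same cluster.
* **Cluster terms** — amplitude R₂c ≥ 0 (so adding a component can never
  lower the prediction), continuous centre x_c allowed 2 residues beyond
  the chain ends, and half-width Δ ∈ (0.5, N]. "Half-width" is
  interpreted as the Gaussian σ in $e^{-(i-x_c)^2/(2\Delta^2)}$; the
  alternative $e^{-((i-x_c)/\Delta)^2}$ convention is available
  (`width_convention = "exp2"`) because usage in the literature is
  ambiguous.

**Fitting.** Weighted Levenberg–Marquardt (minpack.lm), multistarted: a
cluster-free prefit establishes (A, λ₀), cluster centres are initialized
at up to five local maxima of the residual, and ties are broken by
lowest χ². The number of clusters is selected by small-sample-corrected
AIC (`select_n_clusters`, default K ∈ {0, 1, 2}); one cluster suffices
for typical 20-mers. Parameter errors come from a residue-level
bootstrap (default 100 resamples) whose refits warm-start at the
full-data optimum — a deliberate speed/robustness trade-off that leaves
the sigmas unchanged on test cases while avoiding a full multistart per
replicate. K clusters require at least 3K + 2 unmasked residues.

**Null behaviour.** On cluster-free data the fitted amplitude should be
statistically insignificant (we use R₂c < 3 bootstrap sigmas) and the
baseline alone should correlate strongly with the data. This is the
signature distinguishing "no residual structure" from "cluster present",
and it is exercised as an explicit control in the tests.

## Chemical shifts and CSI

Reference shifts are sequence-corrected random-coil values:
$\delta_{rc}(i) = \mathrm{base}(\mathrm{type}_i) + \sum_{o \in \{-2,-1,+1,+2\}}
\mathrm{corr}(\mathrm{type}_{i+o}, o)$, chain ends using only existing
neighbours. The offset convention is explicit: *o* is the neighbour's
position relative to the residue being corrected. Input shifts are
assumed referenced consistently with the table; no re-referencing is
attempted.

The packaged base table (`random_coil_consensus.tsv`) is an approximate
consensus ¹³C set — adequate for method development and for all
difference-based tests, but **not** a substitute for a calibration
matched to the sample's denaturant, pH and temperature; the packaged
correction file is synthetic (labelled as such) and exists to exercise
the correction machinery. Supply your own tables via `read_coil_table`
for quantitative work.

Downstream analyses:

* **Secondary shifts** Δδ = δ_obs − δ_rc. When sample pH differs from
  the reference calibration, Asp and Glu shifts track their side-chain
  ionization rather than conformation and are flagged `excluded`
  (default on; His can be added).
* **Consensus CSI**: per-nucleus index via thresholds (defaults ±0.7 ppm
  CA, ±0.5 ppm CB and C′, CB sign inverted), majority vote across
  nuclei, ties to coil, and helix/strand runs shorter than 3 residues
  reset to coil.
* **Deviant flags**: |Δδ| above a per-nucleus threshold (defaults
  0.3 ppm CA/C′, 0.5 ppm CB — common practice for ¹³C secondary shifts;
  the choice is attached to the output since reported deviant sets
  depend on it). Flagging is monotone in the threshold.
* **Karplus inversion**: $J = A\cos^2(\phi-60^\circ) + B\cos(\phi-60^\circ) + C$
  solved in closed form (quadratic in cos), returning all of up to four
  φ solutions in (−180°, 180°]; couplings above the curve maximum return
  an empty set, which is a result, not an error. Defaults are the HNHA
  calibration A = 6.51, B = −1.76, C = 1.60 Hz.

## NOE connectivities and AABUF

Contacts are canonicalized (res_i ≤ res_j) and classified purely from
proton classes (HN; HA including glycine HA2/HA3; any other proton =
side chain) and sequence separation. Duplicate atom pairs (e.g. from
different mixing times) collapse to one contact with recorded
multiplicity. Class counts always enumerate every defined class so the
*absence* of, say, HN–HN (i,i+2) contacts — diagnostic against helical
structure — is reported explicitly. Side-chain–HN classes cover
separations 2 and 3; other combinations go to an explicit catch-all
rather than being silently mislabelled.

The AABUF profile maps each residue to its average area buried upon
folding, applies an edge-truncated uniform sliding window (default 5 —
appropriate for 20-mers; configurable since longer chains warrant wider
windows) and min–max normalizes to [0, 1]. A constant profile cannot be
normalized and is flagged instead. Helix-propensity predictions from
external tools are parsed (`read_helix_propensity`), not computed.

## Diffusion

Gradient decays follow $I(g) = I_0 \exp(-D\gamma^2 g^2 \delta^2
(\Delta - \delta/3)\,s)$ with shape factor *s* = 1 (rectangular pulses)
by default; sine-shaped gradients need $s = 4/\pi^2$. The recommended
route to hydrodynamic radii is an internal reference compound
(R_H = (D_ref/D)·R_H,ref), which cancels the solvent viscosity — the
viscosity of concentrated denaturant solutions is deliberately **not**
defaulted. Stokes–Einstein mode (k_B T / 6πηD) is available when
temperature and viscosity are known. Gross non-monotonicity of a decay
(an increase exceeding 10% of the intensity range) triggers a warning,
as it usually indicates convection.

## The synthetic-data generator

`sim_config()` fixes the study conditions: the 20-residue Trp-cage
sequence, the delay schedules above, 2% fractional intensity noise,
0.1 s⁻¹ additive R₂-profile noise, 0.02 ppm shift noise, two replicate
delays, and a cluster truth of A = 0.1 s⁻¹, λ₀ = 2, R₂c = 2 s⁻¹,
x_c = 6.5, Δ = 3 — an intrinsic baseline of 1.7–2.6 s⁻¹ with the cluster
rising ≈ 2 s⁻¹ above it near the tryptophan, the magnitude scale typical
of short urea-denatured chains at 14 T. In the default preset,
prolines and the N-terminal residue are masked in HN-detected
observables, giving the characteristic 15-of-20 coverage of a
tetra-proline 20-mer.

Every generator returns (truth, data) pairs and is a deterministic
function of (config, seed); every downstream fit has a
parameter-recovery test keyed to the truth. Test problem sizes — 200
decay series for rate recovery, 100 seeds for cluster recovery and the
null control, 500 simulations for error-bar coverage, 100 random
parameter sets for the algebraic oracles — were chosen as the smallest
sizes at which the recovery statistics are stable.

What passing these tests shows: the estimators are unbiased and
well-calibrated *under the generative model* (single-exponential decays,
Gaussian noise, the cluster model itself). What they cannot show:
robustness to peak overlap, baseline distortions, chemical-exchange
line broadening, correlated noise between delays, or model mismatch in
the baseline form — all of which occur in real spectra and are upstream
of this package's inputs.

## Known limitations

* Spectral processing, peak picking and assignment are out of scope;
  inputs are tabulated heights, shifts and contacts.
* The cluster-model scaling A is empirical; no attempt is made to map
  it onto absolute correlation times, and the proportionality between
  intrinsic correlation time and residue size is carried entirely by
  the 1/7 weight rule.
* Exchange contributions are not separated from J(0); multi-field data
  would be required.
* The NMR-STAR reader handles the assigned-chemical-shift loop only.
* cis/trans quantification assumes both peak sets are quantified with
  comparable linewidths; differential broadening biases the fraction.
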