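# denatr

Denatured-state NMR analysis of peptides and small proteins in R.

Chemically denatured and intrinsically disordered polypeptides are not
featureless random coils: clusters of hydrophobic side chains can remain
transiently associated and leave quantitative fingerprints in solution NMR
observables. `denatr` implements the full analysis chain used to detect
and model such residual structure from backbone ¹⁵N relaxation, chemical
shifts, NOESY connectivities and pulsed-field-gradient diffusion — aimed
at spectroscopists and structural biologists characterizing unfolded-state
ensembles of small proteins (the worked examples use a 20-residue
Trp-cage mini-protein sequence).

## What it computes

**Relaxation rates.** Per-residue ¹⁵N R₁/R₂ from peak-height decays,
fitted as `I(t) = I₀·exp(−R·t)` with replicate-based intensity errors and
Monte Carlo rate uncertainties; steady-state heteronuclear NOEs
(`I_sat/I_unsat`), R₂/R₁ ratios, and cis/trans proline populations from
duplicate peak sets.

**Reduced spectral density mapping.** Exact inversion of the (R₁, R₂,
NOE) triple into J(0), J(ω_N) and J(0.87 ω_H) for the ¹⁵N–¹H pair, using
a dipolar constant from r(NH) = 1.02 Å and a ¹⁵N CSA of 172 ppm by
default, with Monte Carlo error propagation.

**Transverse-relaxation cluster model.** The core of the package: the
observed R₂ profile of a denatured chain is decomposed into an intrinsic
segmental-motion baseline plus Gaussian cluster terms,

```
R₂(i) = A · Σⱼ wⱼ · exp(−|i−j|/λ₀)  +  Σ_c R₂c · exp(−(i−x_c)²/(2Δ²))
```

where λ₀ is the persistence length for segmental motion (residues), the
weights wⱼ are 1 for Gly/Ala and 7 otherwise (size-weighted variant) or
all 1 (uniform variant), and each cluster has amplitude R₂c (s⁻¹),
centre x_c and half-width Δ. Fitting is multistart weighted nonlinear
least squares with residue-level bootstrap uncertainties and
information-criterion model selection over the number of clusters.

**Chemical shifts.** Sequence-corrected random-coil referencing,
secondary shifts Δδ = δ_obs − δ_rc, consensus chemical-shift-index
(helix/coil/strand) calls with run-length filtering, deviant-residue
flagging (with Asp/Glu exclusion under pH mismatch), and Karplus
inversion of ³J(HN,Hα) couplings to φ angles.

**Contacts and profiles.** Classification of assigned NOE contacts into
d_NN/d_αN/side-chain connectivity classes with presence matrices and
class counts, side-chain contact tables around a focus residue, and
0–1-normalized AABUF (average area buried upon folding) hydrophobicity
profiles.

**Diffusion.** Stejskal–Tanner fits of gradient decays and hydrodynamic
radii via an internal reference compound or Stokes–Einstein.

**Synthetic data.** Every input above can be generated with known ground
truth (`sim_config()`, `simulate_*()`), which is how the test suite
validates each stage by parameter recovery.

## Worked example

Simulate a denatured 20-mer (one hydrophobic cluster near the
tryptophan, prolines invisible to HN-detected experiments), then fit the
cluster model:

```r
library(denatr)

cfg <- sim_config(seed = 42)           # truth: A=0.1, lambda0=2, R2c=2, xc=6.5, Delta=3
sim <- simulate_r2_profile(cfg)
fit <- fit_cluster_model(sim$profile, sim$seq, k = 1, n_boot = 100, seed = 42)
fit
#> cluster_fit (size_weighted, K = 1): A = 0.1007 1/s, lambda0 = 1.99 residues
#>   cluster 1: R2c = 2.07 1/s at residue 6.58, half-width 2.97
#>   chi-square = 9.866, AICc = -58.7
round(fit$boot_sigma, 3)
#>      A lambda0    R2c1     xc1  Delta1
#>  0.014   0.499   0.088   0.167   0.139
```

The fit recovers the generating truth: a cluster of amplitude ≈ 2 s⁻¹
centred between residues 6 and 7 (the Trp region) of half-width ≈ 3
residues, on an intrinsic baseline with persistence length ≈ 2 residues.
The bootstrap errors say the centre is localized to a fraction of a
residue. The AABUF profile independently highlights the same region:

```r
prof <- aabuf_profile(sim$seq)
round(prof$normalized[4:8], 2)    # hydrophobic N-terminal cluster region
#> 1.00 1.00 0.86 0.73 0.61
round(prof$normalized[16:20], 2)  # polar, proline-rich tail
#> 0.23 0.25 0.30 0.14 0.14
```

A command-line wrapper over the same functions is installed at
`system.file("cli", "denatr.R", package = "denatr")` with subcommands
`simulate`, `fit-rates`, `hetnoe`, `jmap`, `cluster-fit`, `shifts-csi`,
`noe-classify`, `aabuf`, `karplus` and `diffusion`.

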