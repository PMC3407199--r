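Package: denatr
Title: Denatured-State NMR Analysis of Peptides and Small Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for characterizing residual structure in
    chemically denatured or intrinsically disordered peptides from solution
    NMR observables. Fits single-exponential 15N R1/R2 relaxation decays
    with replicate-based error models, computes steady-state heteronuclear
    NOEs and R2/R1 ratios, performs reduced spectral density mapping at
    J(0), J(wN) and J(0.87wH), and fits the sequence-dependent transverse
    relaxation cluster model (exponential segmental-motion baseline plus
    Gaussian hydrophobic-cluster terms). Also provides sequence-corrected
    random-coil referencing and consensus chemical shift index calls,
    NOESY connectivity classification, average-area-buried-upon-folding
    (AABUF) hydrophobicity profiles, Karplus conversion of 3J(HN,HA)
    couplings to phi angles, Stejskal-Tanner diffusion fitting with
    hydrodynamic radii, and a synthetic-data generator that emulates the
    full experimental workflow for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    seqinr,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
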