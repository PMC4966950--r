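Package: mdcrowd
Title: Trajectory Analysis of Proteins in Crowded Molecular Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of molecular dynamics trajectories of proteins in
    crowded environments: Calpha contact maps with an explored-contact rule,
    quinary (inter-protein) contact composition, two-step GROMOS
    conformational clustering and conformational-change timing, helix
    elevation/azimuth geometry, Einstein-relation self-diffusion with the
    Yeh-Hummer periodic-box correction, quasi-harmonic conformational
    entropy, Shrake-Rupley solvent-accessible surface area with
    polar/apolar decomposition, and classical structural descriptors
    (RMSD, radius of gyration, RMSF, helicity, 2-D sampling maps).
    Includes seeded synthetic-trajectory generators (Brownian particles,
    Gaussian ensembles with planted covariance spectra, ideal helices,
    freely jointed coils with planted contacts, two-state switchers and
    crowded boxes at a target mass concentration) so that every estimator
    can be validated against known ground truth, plus a pipeline that
    aggregates per-protein crowding effects into a disorder-vs-effect
    trend table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
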