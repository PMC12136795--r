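Package: cosmosKinetics
Title: Single-Molecule Colocalization (CoSMoS) Binding Kinetics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of colocalization single-molecule spectroscopy (CoSMoS)
    experiments measuring protein binding kinetics on surface-tethered RNAs.
    Provides a synthetic-data generator with known ground truth (continuous-time
    Markov binding schemes, camera-resolution intensity traces, two-channel image
    stacks, dwell-time mixtures, fluorescence-polarization titrations), an image
    front end (fiducial-based channel registration, drift correction, GLRT spot
    detection, 2D Gaussian fitting, trace extraction), divisive
    segmentation-and-clustering (DISC) trace idealization, censored
    exponential-mixture dwell-time maximum likelihood with log-likelihood-ratio
    model selection, global aggregated-Markov rate estimation across ligand
    concentrations with BIC scheme selection, and four-parameter logistic
    binding-curve fits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    minpack.lm,
    fitdistrplus,
    jsonlite,
    yaml,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: SingleCell, Software, TimeCourse, Visualization
RoxygenNote: 7.3.3
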